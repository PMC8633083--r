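# The generating-function engine: recursion, sweep embedding, inverse
# Laplace transform in the sweep rate, i-Ton collapse.

test_that("neutral GF reproduces the pairwise Laplace transform and classic moments", {
  phi2 <- neutral_gf(lineage_sample(2))
  g <- sweepGF:::gf_subst_linear(phi2, c("w_a", "w_b"), "w")
  for (w in c(0, 0.3, 1.7)) expect_equal(gf_eval(g, c(w = w)), 1 / (1 + w))
  # E[tmrca] for n = 3: sum_{k=2..3} 1/choose(k,2) = 4/3
  phi3 <- neutral_gf(lineage_sample(3))
  vs <- gf_vars(phi3)
  amap <- stats::setNames(rep("wm", sum(grepl("a", vs))), vs[grepl("a", vs)])
  g3 <- sweepGF:::gf_rename(phi3, amap)
  expect_equal(-gf_eval(gf_deriv(g3, "wm"), sweepGF:::gf_zero_omega(g3)), 4 / 3,
               tolerance = 1e-12)
  expect_error(neutral_gf(list()), "nonempty")
  expect_error(neutral_gf(lineage_sample(7)), "at most")
})

test_that("every constructed GF is normalised and label-symmetric", {
  for (n in 2:5) {
    g <- neutral_gf(lineage_sample(n))
    expect_equal(gf_eval(g, sweepGF:::gf_zero_omega(g)), 1, tolerance = 1e-12)
  }
  for (alpha in c(0, 0.3, 2)) for (Ta in c(0, 0.5, 1.5)) {
    g <- invert_sweep_time(gf_with_sweep(lineage_sample(4), starlike_model(alpha)))
    expect_equal(gf_eval(g, sweepGF:::gf_zero_omega(g), Ta = Ta), 1,
                 tolerance = 1e-12)
  }
  # symmetry: permuting labels leaves the GF invariant at permuted arguments
  g <- neutral_gf(lineage_sample(3))
  om <- c(w_a = 0.2, w_b = 0.9, w_c = 0.4,
          w_a.b = 0.1, w_a.c = 0.55, w_b.c = 0.3)
  perm <- c(w_a = "w_b", w_b = "w_c", w_c = "w_a",
            w_a.b = "w_b.c", w_a.c = "w_a.b", w_b.c = "w_a.c")
  om2 <- stats::setNames(om, perm[names(om)])
  expect_equal(gf_eval(g, om), gf_eval(g, om2), tolerance = 1e-12)
})

test_that("sweep GF matches the printed two-lineage closed forms term by term", {
  alpha <- 0.3
  pe <- escape_probability(alpha)
  P02 <- (1 - pe)^2; P12 <- 2 * pe * (1 - pe); P22 <- pe^2
  gs <- gf_with_sweep(lineage_sample(2), starlike_model(alpha))
  gs <- sweepGF:::gf_subst_linear(gs, c("w_a", "w_b"), "w")
  phistar <- function(w, delta) {
    1 / (1 + delta + w) + delta * P02 / (1 + delta + w) +
      delta * (P12 + P22) / ((1 + delta + w) * (1 + w))
  }
  for (w in c(0, 0.6, 2.4)) for (dd in c(0.1, 1, 5)) {
    expect_equal(gf_eval(gs, c(w = w), delta = dd), phistar(w, dd),
                 tolerance = 1e-12)
  }
  # delta -> 0: the sweep never happens
  expect_equal(gf_eval(gs, c(w = 0.4), delta = 1e-12), 1 / 1.4, tolerance = 1e-9)
  # P_{0,2} = 1 (alpha = 0) collapses to (1+delta)/(1+delta+w)
  g0 <- gf_with_sweep(lineage_sample(2), starlike_model(0))
  g0 <- sweepGF:::gf_subst_linear(g0, c("w_a", "w_b"), "w")
  for (w in c(0.2, 1.1)) for (dd in c(0.5, 2)) {
    expect_equal(gf_eval(g0, c(w = w), delta = dd), (1 + dd) / (1 + dd + w),
                 tolerance = 1e-12)
  }
})

test_that("inverse transform in delta yields the printed time-parameterised GF", {
  alpha <- 0.3
  P02 <- exp(-2 * alpha)
  g <- invert_sweep_time(gf_with_sweep(lineage_sample(2), starlike_model(alpha)))
  g <- sweepGF:::gf_subst_linear(g, c("w_a", "w_b"), "w")
  phiTa <- function(w, Ta) {
    exp(-Ta * (1 + w)) * P02 +
      (1 / (1 + w)) * ((1 - exp(-Ta * (1 + w))) + exp(-Ta * (1 + w)) * (1 - P02))
  }
  for (w in c(0, 0.6, 2)) for (Ta in c(0, 0.2, 1.5)) {
    expect_equal(gf_eval(g, c(w = w), Ta = Ta), phiTa(w, Ta), tolerance = 1e-12)
  }
  # Ta -> infinity recovers the neutral GF; omega -> 0 normalises
  expect_equal(gf_eval(g, c(w = 0.8), Ta = 50), 1 / 1.8, tolerance = 1e-12)
  expect_equal(gf_eval(g, c(w = 0), Ta = 0.123), 1, tolerance = 1e-12)
  expect_error(invert_sweep_time(neutral_gf(lineage_sample(2))), "delta")
})

test_that("repeated delta-poles invert to polynomial-in-Ta coefficients", {
  # artificial expression: delta / (2 + delta + w)^2, inverse transform of
  # F/delta is Ta * exp(-Ta (2 + w))
  tm <- sweepGF:::new_gf_term(coef = 1, dpow = 1L, poles = list(
    sweepGF:::new_gf_pole(2, d = 1L, w = c(w = 1)),
    sweepGF:::new_gf_pole(2, d = 1L, w = c(w = 1))))
  g <- sweepGF:::new_gf_expr(list(tm))
  gi <- gf_invert_delta(g)
  for (w in c(0, 0.7)) for (Ta in c(0.2, 1.3)) {
    expect_equal(gf_eval(gi, c(w = w), Ta = Ta), Ta * exp(-Ta * (2 + w)),
                 tolerance = 1e-12)
  }
  # with the pole at zero: L^{-1}[1/(delta (b+delta)^2)]
  tm2 <- sweepGF:::new_gf_term(coef = 1, poles = list(
    sweepGF:::new_gf_pole(3, d = 1L), sweepGF:::new_gf_pole(3, d = 1L)))
  g2 <- gf_invert_delta(sweepGF:::new_gf_expr(list(tm2)))
  for (Ta in c(0.1, 0.9)) {
    expect_equal(gf_eval(g2, Ta = Ta),
                 (1 - exp(-3 * Ta)) / 9 - Ta * exp(-3 * Ta) / 3,
                 tolerance = 1e-12)
  }
})

test_that("i-Ton collapse preserves moments and substitution identities", {
  phi4 <- neutral_gf(lineage_sample(4))
  it4 <- collapse_to_iton(phi4, 4)
  z <- sweepGF:::gf_zero_omega(it4)
  for (i in 1:3) {
    expect_equal(-gf_eval(gf_deriv(it4, paste0("w", i)), z), 2 / i,
                 tolerance = 1e-12)
  }
  # merged GF at a common value equals the labeled GF with every omega there
  u <- 0.37
  oml <- sweepGF:::gf_zero_omega(phi4); oml[] <- u
  omc <- sweepGF:::gf_zero_omega(it4); omc[] <- u
  expect_equal(gf_eval(it4, omc), gf_eval(phi4, oml), tolerance = 1e-12)
})

test_that("first moments from the GF agree with an independent brute-force sampler", {
  set.seed(101)
  alpha <- 0.3; Ta <- 0.4
  reps <- 60000L
  sim <- oracle_sim_ti(4, alpha, Ta, reps)
  g <- sweepGF:::iton_gf(4, starlike_model(alpha))
  z <- sweepGF:::gf_zero_omega(g)
  for (i in 1:3) {
    Egf <- -gf_eval(gf_deriv(g, paste0("w", i)), z, Ta = Ta)
    se <- stats::sd(sim$t[, i]) / sqrt(reps)
    expect_within_3se(mean(sim$t[, i]), Egf, se, label = paste("i-Ton", i))
  }
  # nesting: all lineages escape (Pe = 1) is the neutral model for any Ta
  g1 <- sweepGF:::iton_gf(4, structure(list(kind = "starlike", Pe = 1),
                                       class = "sweep_partition_model"))
  gn <- sweepGF:::iton_gf(4)
  om <- c(w1 = 0.3, w2 = 0.11, w3 = 0.7)
  for (Ta in c(0, 0.4, 2)) {
    expect_equal(gf_eval(g1, om, Ta = Ta), gf_eval(gn, om), tolerance = 1e-10)
  }
})

test_that("truncated Taylor coefficients match closed-form derivatives", {
  phi2 <- neutral_gf(lineage_sample(2))
  g <- sweepGF:::gf_subst_linear(phi2, c("w_a", "w_b"), "w")
  tc <- gf_taylor(g, at = c(w = 0.5), orders = c(w = 3L))
  expect_equal(as.numeric(tc), (-1 / 1.5)^(0:3) / 1.5, tolerance = 1e-12)
  # mixed partials of the collapsed 4-lineage GF against numeric differences
  g4 <- sweepGF:::iton_gf(4, starlike_model(0.2))
  at <- c(w1 = 0.25, w2 = 0.25, w3 = 0.25)
  tc4 <- gf_taylor(g4, at = at, orders = c(w1 = 1L, w2 = 1L, w3 = 0L), Ta = 0.3)
  h <- 1e-5
  f <- function(d1, d2) gf_eval(g4, at + c(d1, d2, 0), Ta = 0.3)
  num <- (f(h, h) - f(h, -h) - f(-h, h) + f(-h, -h)) / (4 * h * h)
  expect_equal(tc4[2, 2, 1], num, tolerance = 1e-5)
})
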