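# Sweep parameter algebra and the two instantaneous partition models.

test_that("alpha, escape probability and sweep duration follow the defining formulas", {
  expect_equal(sweep_alpha(1e-7, 10000, 0.05, 10000),
               (1e-3 / 0.05) * log(1000), tolerance = 1e-12)
  expect_equal(sweep_alpha(1e-7, 0, 0.05, 10000), 0)
  expect_error(sweep_alpha(1e-7, 100, 1e-6, 10000), "2\\*Ne\\*s")
  # alpha = r*d*t_fix/2 for random parameter draws
  set.seed(1)
  for (z in 1:100) {
    Ne <- runif(1, 1e3, 1e5); s <- runif(1, 0.005, 0.5)
    r <- runif(1, 1e-9, 1e-6); d <- runif(1, 0, 1e5)
    tfix <- 2 * log(2 * Ne * s) / s
    expect_equal(sweep_alpha(r, d, s, Ne), r * d * tfix / 2, tolerance = 1e-10)
  }
  expect_equal(escape_probability(0), 0)
  expect_equal(escape_probability(log(2)), 0.5)
  expect_equal(escape_probability(100), 1)
  expect_error(escape_probability(-0.1), "nonnegative")
  p1 <- sweep_params(Ne = 10000, s = 0.005, r = 1e-7)
  expect_equal(fixation_time_coalescent(p1), 0.0921, tolerance = 1e-3)
  expect_equal(round(fixation_time_coalescent(p1), 1), 0.1)
  p2 <- sweep_params(Ne = 10000, s = 0.05, r = 1e-7)
  expect_equal(p2$t_fix, 2 * log(1000) / 0.05, tolerance = 1e-10)
  # monotone decreasing duration in s
  svals <- seq(0.005, 0.5, length.out = 20)
  durs <- vapply(svals, function(s)
    fixation_time_coalescent(sweep_params(1e4, s, 1e-7)), numeric(1))
  expect_true(all(diff(durs) < 0))
  expect_error(sweep_params(Ne = 100, s = 1e-4, r = 1e-7), "2\\*Ne\\*s")
})

test_that("star-like partition probabilities are binomial and match subset enumeration", {
  for (alpha in c(0.1, 0.7)) {
    pe <- escape_probability(alpha)
    expect_equal(unname(starlike_partition_probs(2, alpha)["0"]), exp(-2 * alpha),
                 tolerance = 1e-12)
    for (n in 2:6) {
      pr <- starlike_partition_probs(n, alpha)
      expect_equal(sum(pr), 1, tolerance = 1e-12)
      # brute force over all 2^n escape outcomes
      outcomes <- expand.grid(rep(list(c(FALSE, TRUE)), n))
      brute <- vapply(0:n, function(m) {
        sum(apply(outcomes, 1, function(e)
          if (sum(e) == m) pe^m * (1 - pe)^(n - m) else 0))
      }, numeric(1))
      expect_equal(unname(pr), brute, tolerance = 1e-12)
    }
  }
  expect_equal(unname(starlike_partition_probs(4, -log(0.5))["1"]),
               4 * 0.5^4, tolerance = 1e-12)
  # labeled outcomes from the model interface sum to one and merge correctly
  out <- partition_outcomes(starlike_model(0.4), lapply(1:4, identity))
  expect_equal(sum(vapply(out, function(o) o$prob, numeric(1))), 1,
               tolerance = 1e-12)
  # escape_probability(alpha(d)) nondecreasing in d
  al <- sweep_alpha(1e-7, seq(0, 1e5, length.out = 50), 0.05, 1e4)
  expect_true(all(diff(escape_probability(al)) >= 0))
})

test_that("marked-Yule sampler obeys its structural limits", {
  pp <- sweep_params(Ne = 1e4, s = 0.05, r = 1e-7, Ta = 0.1)
  # no recombination: everything in the nonrecombinant family
  p0 <- sweep_params(Ne = 1e4, s = 0.05, r = 0, Ta = 0.1)
  t0 <- yule_partition_sample(4, p0, 5000, reps = 500, seed = 1)
  expect_equal(nrow(t0), 1L)
  expect_equal(t0$n0[1], 4L)
  expect_equal(t0$prob[1], 1)
  # huge recombination: everything a late singleton
  pl <- sweep_params(Ne = 1e4, s = 0.05, r = 1e-4, Ta = 0.1)
  tl <- yule_partition_sample(3, pl, 50000, reps = 500, seed = 2)
  expect_gt(sum(tl$prob[tl$l == 3]), 0.99)
  # family sizes always partition n
  tm <- yule_partition_sample(5, pp, 20000, reps = 2000, seed = 3)
  sizes <- lapply(strsplit(tm$shape, "+", fixed = TRUE), as.integer)
  expect_true(all(vapply(sizes, sum, integer(1)) == 5L))
  # more founders required than sampled lineages
  expect_error(yule_partition_sample(10, sweep_params(100, 0.02, 1e-7), 100),
               "founders")
})

test_that("Yule and star-like approximations agree for a pair at small alpha", {
  pp <- sweep_params(Ne = 1e4, s = 0.05, r = 1e-7, Ta = 0.1)
  d <- 2500
  al <- sweep_alpha(pp$r, d, pp$s, pp$Ne)
  reps <- 40000L
  tab <- yule_partition_sample(2, pp, d, reps = reps, seed = 11)
  pN <- sum(tab$prob[tab$n0 == 2])
  # the two approximations differ at order alpha/log(2*Ne*s); assert
  # agreement at that scale rather than at pure Monte-Carlo precision
  expect_lt(abs(pN - exp(-2 * al)), 0.01)
  # marginal single-lineage late-recombination probability approaches Pe
  t1 <- yule_partition_sample(1, pp, 5000, reps = 20000L, seed = 12)
  pL <- sum(t1$prob[t1$n0 == 0])
  pe <- escape_probability(sweep_alpha(pp$r, 5000, pp$s, pp$Ne))
  expect_lt(abs(pL - pe), 3 * sqrt(pe * (1 - pe) / 20000) + 0.05 * pe)
})

test_that("a Yule model plugs into the GF with valid probabilities", {
  pp <- sweep_params(Ne = 1e4, s = 0.05, r = 1e-7, Ta = 0.2)
  ym <- yule_model(4, pp, 5000, reps = 2000, seed = 21)
  expect_s3_class(ym, "sweep_partition_model")
  for (k in 2:4) {
    out <- partition_outcomes(ym, lapply(seq_len(k), identity))
    expect_equal(sum(vapply(out, function(o) o$prob, numeric(1))), 1,
                 tolerance = 1e-9)
  }
  g <- invert_sweep_time(gf_with_sweep(lineage_sample(3), ym))
  expect_equal(gf_eval(g, sweepGF:::gf_zero_omega(g), Ta = 0.2), 1,
               tolerance = 1e-9)
  expect_gte(ym$multi_family_freq, 0)
})
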