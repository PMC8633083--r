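# Analytic observables: tmrca distribution, SFS, topology classes, i-Ton
# marginals, blockwise SFS.

test_that("expected tmrca: closed form and GF differentiation agree on a grid", {
  for (alpha in seq(0.05, 2, length.out = 10)) {
    for (Ta in seq(0, 1.8, length.out = 10)) {
      expect_equal(expected_tmrca(alpha, Ta, method = "gf"),
                   1 - exp(-Ta - 2 * alpha), tolerance = 1e-10)
    }
  }
  expect_equal(expected_tmrca(Inf, 0), 1)
  expect_equal(expected_tmrca(Inf, 0, method = "gf"), 1, tolerance = 1e-12)
  expect_equal(expected_tmrca(0, 0), 0)
  expect_equal(expected_tmrca(0.25, 0.5), 1 - exp(-1), tolerance = 1e-12)
})

test_that("tmrca distribution has the neutral body, thinned tail and sweep atom", {
  d <- tmrca_distribution(0.1, 0.3)
  expect_equal(d$masses$mass, exp(-0.5), tolerance = 1e-12)
  expect_equal(d$masses$loc, 0.3)
  expect_equal(pwe_pdf(d, 0.2), exp(-0.2), tolerance = 1e-12)
  expect_equal(pwe_pdf(d, 0.8), exp(-0.8) * (1 - exp(-0.2)), tolerance = 1e-12)
  expect_equal(pwe_cdf(d, 1e9), 1, tolerance = 1e-9)
  expect_equal(pwe_cdf(d, 0.25), 1 - exp(-0.25), tolerance = 1e-12)
  # neutral limit: pure exponential, no atom
  dn <- tmrca_distribution(Inf, 0.7)
  expect_equal(nrow(dn$masses), 0L)
  expect_equal(pwe_pdf(dn, 1.1), exp(-1.1), tolerance = 1e-12)
  # the closed form equals the generic GF inversion machinery
  g <- invert_sweep_time(gf_with_sweep(lineage_sample(2), starlike_model(0.1)))
  g <- sweepGF:::gf_subst_linear(g, c("w_a", "w_b"), "w")
  d2 <- gf_to_density(g, "w", 0.3)
  ts <- c(0.05, 0.29, 0.31, 1.2, 3)
  expect_equal(pwe_pdf(d2, ts), pwe_pdf(d, ts), tolerance = 1e-10)
  expect_equal(d2$masses$mass, d$masses$mass, tolerance = 1e-12)
})

test_that("expected SFS matches Kingman under neutrality and shows sweep signatures", {
  expect_equal(expected_sfs(4, Inf, 0), c(6, 3, 2) / 11, tolerance = 1e-12)
  # marginal-moments path equals GF differentiation for n = 4
  alpha <- 0.3; Ta <- 0.4
  g <- sweepGF:::iton_gf(4, starlike_model(alpha))
  z <- sweepGF:::gf_zero_omega(g)
  Egf <- vapply(1:3, function(i)
    -gf_eval(gf_deriv(g, paste0("w", i)), z, Ta = Ta), numeric(1))
  expect_equal(expected_iton_lengths(4, alpha, Ta), Egf, tolerance = 1e-10)
  # singleton excess at the sweep center for n = 9
  sfs_sweep <- expected_sfs(9, 0, 0.1)
  sfs_neut <- expected_sfs(9, Inf, 0)
  expect_gt(sfs_sweep[1], sfs_neut[1])
  # away from the center the footprint shifts with sweep age: the recent
  # sweep piles mass on high-frequency classes (hitchhiking of the merged
  # lineage), intermediate classes recover monotonically with age, and an
  # older sweep leaves a high-frequency uptick relative to intermediate
  # classes (U-shaped ratio to the neutral spectrum)
  hi0 <- expected_sfs(9, 0.25, 0)[8]
  expect_gt(hi0, 2 * sfs_neut[8])
  mid <- vapply(c(0, 0.5, 1), function(Ta) expected_sfs(9, 0.25, Ta)[4], numeric(1))
  expect_true(all(diff(mid) > 0))
  ratio <- expected_sfs(9, 0.25, 0.5) / sfs_neut
  expect_gt(ratio[8], ratio[5])
  expect_error(expected_sfs(4, 0, 0), "degenerate")
  expect_equal(sum(expected_sfs(6, 0.2, 0.3)), 1, tolerance = 1e-12)
})

test_that("topology class probabilities behave as printed", {
  # neutral limit
  expect_equal(unname(topology_probs_n4(Inf, 0.5)), c(1 / 3, 2 / 3, 0),
               tolerance = 1e-12)
  # sampling at fixation at the sweep center: the star genealogy
  expect_equal(unname(topology_probs_n4(0, 0)), c(0, 0, 1), tolerance = 1e-12)
  # algebraic sum-to-one at random parameter points
  set.seed(5)
  for (z in 1:50) {
    p <- topology_probs_n4(runif(1, 0, 3), runif(1, 0, 2))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= -1e-12))
  }
  expect_equal(unname(topology_probs_n4(0, 0.2)["Pstar"]), exp(-1.2),
               tolerance = 1e-12)
})

test_that("topology probabilities match hybrid-simulator frequencies", {
  set.seed(31)
  reps <- 50000L
  sim <- simulate_iton_batch(4, reps, Ta = 0.4, model = starlike_model(0.3))
  freq <- table(factor(sim$topo, levels = c("sym", "asym", "star"))) / reps
  ana <- topology_probs_n4(0.3, 0.4)
  for (i in 1:3) {
    se <- sqrt(ana[i] * (1 - ana[i]) / reps)
    expect_within_3se(as.numeric(freq[i]), unname(ana[i]), se,
                      label = names(ana)[i])
  }
})

test_that("i-Ton marginal distributions carry the printed atoms and discontinuity counts", {
  # neutrality: tripleton atom 1/3 at zero; singleton and doubleton smooth
  d3 <- iton_marginal_distribution(3, Inf, 0)
  expect_equal(d3$masses$mass, 1 / 3, tolerance = 1e-10)
  expect_equal(d3$masses$loc, 0)
  expect_length(pwe_discontinuities(iton_marginal_distribution(1, Inf, 0)), 0)
  expect_length(pwe_discontinuities(iton_marginal_distribution(2, Inf, 0)), 0)
  # sweep: n-1 = 3 singleton discontinuities; floor(n/i)+1 for i > 1
  Ta <- 0.25
  for (alpha in c(0.069, 0.14)) {
    dd1 <- iton_marginal_distribution(1, alpha, Ta)
    expect_equal(pwe_discontinuities(dd1), c(Ta, 2 * Ta, 4 * Ta),
                 tolerance = 1e-8)
    dd2 <- iton_marginal_distribution(2, alpha, Ta)
    expect_length(pwe_discontinuities(dd2), 3L)   # floor(4/2) + 1
    dd3 <- iton_marginal_distribution(3, alpha, Ta)
    expect_length(pwe_discontinuities(dd3), 2L)   # floor(4/3) + 1
    for (dd in list(dd1, dd2, dd3)) {
      expect_equal(pwe_total_mass(dd), 1, tolerance = 1e-8)
    }
  }
  expect_error(iton_marginal_distribution(4, 0.1, 0.1), "i must be")
})

test_that("i-Ton marginal CDFs match the hybrid simulator", {
  set.seed(57)
  reps <- 40000L
  alpha <- 0.14; Ta <- 0.25
  sim <- simulate_iton_batch(4, reps, Ta = Ta, model = starlike_model(alpha))
  for (i in 1:3) {
    dd <- iton_marginal_distribution(i, alpha, Ta)
    xs <- sort(sim$t[, i])
    D <- ks_distance(xs, function(t) pwe_cdf(dd, t))
    expect_lt(D, 3 * ks_crit99(reps))
    # atoms: empirical frequency of exact values at mass locations
    for (z in seq_len(nrow(dd$masses))) {
      emp <- mean(abs(sim$t[, i] - dd$masses$loc[z]) < 1e-9)
      m <- dd$masses$mass[z]
      expect_within_3se(emp, m, sqrt(m * (1 - m) / reps),
                        label = sprintf("atom i=%d loc=%.3g", i, dd$masses$loc[z]))
    }
  }
})

test_that("blockwise SFS tables are complete, normalised and convention-consistent", {
  mm <- mutation_model(0.5, 2)
  tb <- bsfs_probabilities(0.1, 0.1, mm)
  expect_length(tb, 64L)
  expect_equal(sum(tb), 1, tolerance = 1e-8)
  expect_true(all(tb >= -1e-12))
  tn <- bsfs_probabilities(Inf, 0, mm)
  expect_equal(sum(tn), 1, tolerance = 1e-10)
  # mutation convention: a pair of lineages sees geometric block counts
  # P[k] = (1/(1+theta)) (theta/(1+theta))^k; check via the n = 2 GF
  theta <- 0.8
  g2 <- collapse_to_iton(neutral_gf(lineage_sample(2)), 2)
  tc <- gf_taylor(g2, at = c(w1 = theta / 2), orders = c(w1 = 4L))
  pk <- (theta / 2)^(0:4) * (-1)^(0:4) * as.numeric(tc)
  expect_equal(pk, (1 / (1 + theta)) * (theta / (1 + theta))^(0:4),
               tolerance = 1e-10)
  # degenerate mutation model rejected
  expect_error(mutation_model(0), "positive")
})

test_that("analytic bSFS matches simulated block configurations", {
  set.seed(77)
  mm <- mutation_model(0.5, 2)
  alpha <- 0.14; Ta <- 0.1
  reps <- 60000L
  sim <- simulate_iton_batch(4, reps, Ta = Ta, model = starlike_model(alpha))
  counts <- matrix(rpois(3 * reps, mm$theta / 2 * sim$t), ncol = 3)
  counts <- pmin(counts, mm$k_max + 1L)
  idx <- config_index(counts, mm$k_max)
  obs <- tabulate(idx, 64L)
  expected <- as.vector(bsfs_probabilities(alpha, Ta, mm)) * reps
  # Poisson-scale bound per configuration
  expect_true(all(abs(obs - expected) <= 3 * sqrt(expected) + 3))
  # neutral all-zero configuration frequency
  simn <- simulate_iton_batch(4, reps, Ta = 0, model = NULL)
  cn <- pmin(matrix(rpois(3 * reps, mm$theta / 2 * simn$t), ncol = 3), 3L)
  p00 <- mean(rowSums(cn) == 0)
  a00 <- as.vector(bsfs_probabilities(Inf, 0, mm))[1]
  expect_within_3se(p00, a00, sqrt(a00 * (1 - a00) / reps))
})

test_that("bSFS via Pe-polynomial reconstruction equals direct construction", {
  mm <- mutation_model(0.5, 2)
  P <- sweepGF:::bsfs_prob_matrix(c(0.3, Inf), 0.25, mm)
  expect_equal(P[, 1], as.vector(bsfs_probabilities(0.3, 0.25, mm)),
               tolerance = 1e-12)
  expect_equal(P[, 2], as.vector(bsfs_probabilities(Inf, 0, mm)),
               tolerance = 1e-12)
})

test_that("duration correction shifts the effective sweep age", {
  pp <- sweep_params(Ne = 1e4, s = 0.05, r = 1e-7, Ta = 0.1)
  s1 <- expected_sfs(4, 0.2, 0.1 + fixation_time_coalescent(pp))
  s2 <- expected_sfs(4, 0.2, 0.1, correct_duration = TRUE, params = pp)
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_error(expected_sfs(4, 0.2, 0.1, correct_duration = TRUE), "params")
})
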