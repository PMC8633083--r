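# Coalescent simulators: exactness, determinism, and agreement with the
# closed forms they are meant to sample from.

test_that("hybrid simulator is an exact sampler of the analytic model", {
  set.seed(7)
  reps <- 30000L
  m <- starlike_model(0.25)
  sim <- simulate_iton_batch(2, reps, Ta = 0.5, model = m)
  se <- stats::sd(sim$tmrca) / sqrt(reps)
  expect_within_3se(mean(sim$tmrca), 1 - exp(-1), se, label = "pair tmrca")
  # degenerate sweep: everything merges at sampling
  g <- simulate_hybrid_genealogy(4, Ta = 0, model = starlike_model(0), seed = 1)
  expect_equal(g$tmrca, 0)
  expect_equal(g$t_i, c(0, 0, 0))
  # remote sweep: neutral pair coalescence, KS against Exp(1)
  simn <- simulate_iton_batch(2, 20000L, Ta = 25, model = m)
  ks <- suppressWarnings(stats::ks.test(simn$tmrca, "pexp"))
  expect_gt(ks$p.value, 0.01)
})

test_that("batch and generic samplers draw from the same distribution", {
  set.seed(17)
  reps <- 20000L
  m <- starlike_model(0.3)
  fast <- simulate_iton_batch(4, reps, Ta = 0.4, model = m)
  slow <- t(replicate(8000L, {
    g <- simulate_hybrid_genealogy(4, Ta = 0.4, model = m)
    c(g$t_i, g$tmrca)
  }))
  for (i in 1:3) {
    se <- sqrt(stats::var(fast$t[, i]) / reps + stats::var(slow[, i]) / 8000)
    expect_within_3se(mean(fast$t[, i]), mean(slow[, i]), se,
                      label = paste("t", i))
  }
  se <- sqrt(stats::var(fast$tmrca) / reps + stats::var(slow[, 4]) / 8000)
  expect_within_3se(mean(fast$tmrca), mean(slow[, 4]), se, label = "tmrca")
})

test_that("simulated genealogies are exchangeable and seed-deterministic", {
  g1 <- simulate_hybrid_genealogy(5, Ta = 0.3, model = starlike_model(0.2),
                                  seed = 99)
  g2 <- simulate_hybrid_genealogy(5, Ta = 0.3, model = starlike_model(0.2),
                                  seed = 99)
  expect_identical(g1, g2)
  # exchangeability: pendant branch lengths have the same mean across labels
  set.seed(23)
  pend <- t(replicate(6000L, {
    g <- simulate_hybrid_genealogy(3, Ta = 0.3, model = starlike_model(0.3))
    out <- numeric(3)
    for (e in g$edges) if (length(e$desc) == 1L)
      out[e$desc] <- e$death - e$birth
    out
  }))
  se <- sqrt(sum(apply(pend, 2, stats::var)) / 6000)
  expect_within_3se(mean(pend[, 1]), mean(pend[, 3]), se)
})

test_that("blockwise simulation reproduces the mutation convention and the bSFS", {
  pp <- sweep_params(Ne = 1e4, s = 0.05, r = 1e-7, Ta = 0.1)
  mm <- mutation_model(0.5, 2)
  # neutral pairs: mean pairwise differences = theta
  set.seed(41)
  geom <- block_geometry(B = 10000, l = 100)
  dsn <- simulate_blocks(pp, geom, n = 2L, mut = mutation_model(0.5, 50),
                         mode = "neutral")
  se <- stats::sd(dsn$k1) / sqrt(nrow(dsn))
  expect_within_3se(mean(dsn$k1), 0.5, se, label = "E[pi] = theta")
  # sweep mode at a fixed distance: configuration frequencies match tables
  ds <- simulate_blocks(pp, block_geometry(B = 30000, l = 100), n = 4L,
                        mut = mm, mode = "sweep", seed = 42)
  near <- ds[ds$d == 50, ]        # all blocks at d = 50 share one alpha
  # distant blocks are indistinguishable from neutral (chi-square)
  pn <- as.vector(bsfs_probabilities(Inf, 0, mm))
  far <- ds[ds$alpha > 1.3, ]
  obs <- tabulate(config_index(as.matrix(far[, c("k1", "k2", "k3")]), 2L), 64L)
  keep <- pn * nrow(far) > 5
  chi <- sum((obs[keep] - pn[keep] * nrow(far))^2 / (pn[keep] * nrow(far)))
  expect_gt(stats::pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 0.001)
})

test_that("replicate datasets round-trip through TSV + JSON", {
  pp <- sweep_params(Ne = 1e4, s = 0.05, r = 1e-7, Ta = 0.1)
  ds <- simulate_blocks(pp, block_geometry(B = 20, l = 100), n = 4L,
                        mut = mutation_model(0.5, 2), mode = "sweep", seed = 5)
  path <- file.path(tempdir(), "ds.tsv")
  write_replicate_dataset(ds, path)
  back <- read_replicate_dataset(path)
  expect_equal(as.data.frame(back), as.data.frame(ds), tolerance = 1e-12)
  expect_equal(attr(back, "params")$Ne, 1e4)
  expect_equal(attr(back, "mut")$theta, 0.5)
})

test_that("trajectory structured coalescent approaches the star-like limit", {
  pp <- sweep_params(Ne = 1e4, s = 0.05, r = 1e-7, Ta = 0.1)
  # r = 0: no lineage can escape; every pair coalesces during or before sweep
  p0 <- sweep_params(Ne = 1e4, s = 0.05, r = 0, Ta = 0.1)
  tr0 <- simulate_pair_trajectory(2000, p0, d = 5000, seed = 3)
  expect_true(all(tr0$phase %in% c("pre", "sweep")))
  # escape probability close to the star-like value; the residual excess is
  # the competing-risk effect of coalescence near the origin truncating
  # recombination exposure (vanishes only as 2*Ne*s grows)
  set.seed(4)
  tr <- simulate_pair_trajectory(40000, pp, d = 5000)
  reach <- tr$phase != "pre"
  fail <- sum(tr$background == "beneficial", na.rm = TRUE) / sum(reach)
  al <- sweep_alpha(pp$r, 5000, pp$s, pp$Ne)
  expect_lt(abs(fail - exp(-2 * al)), 0.025)
  # the coalescence burst sits near the sweep origin
  ben <- tr$phase == "sweep" & !is.na(tr$background) &
    tr$background == "beneficial"
  mb <- mean(tr$tmrca[ben])
  lo <- pp$Ta + 0.5 * pp$t_fix / (2 * pp$Ne)
  hi <- pp$Ta + pp$t_fix / (2 * pp$Ne)
  expect_gt(mb, lo)
  expect_lte(mb, hi)
  # trajectory invariants
  trj <- sweep_trajectory(pp)
  expect_equal(trj$X[1], 1)
  expect_equal(trj$X[nrow(trj)], 1 / (2 * pp$Ne))
  expect_true(all(diff(trj$X) <= 1e-12))
})
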