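# Independent oracles for the analytic machinery: a deliberately naive
# brute-force sampler of the hybrid sweep model (block sizes only, no
# shared code with the package simulators) and small comparison utilities.

oracle_sim_ti <- function(n, alpha, Ta, reps) {
  pe <- if (is.infinite(alpha)) 1 else 1 - exp(-alpha)
  TI <- matrix(0, reps, n - 1L)
  TM <- numeric(reps)
  for (r in seq_len(reps)) {
    sizes <- rep(1L, n); t <- 0; ti <- numeric(n - 1L)
    swept <- FALSE
    repeat {
      k <- length(sizes)
      if (k == 1L) break
      tau <- rexp(1L, k * (k - 1) / 2)
      if (!swept && t + tau > Ta) {
        dt <- Ta - t
        for (sz in sizes) if (sz < n) ti[sz] <- ti[sz] + dt
        t <- Ta; swept <- TRUE
        esc <- runif(k) < pe
        sizes <- c(sizes[esc], if (any(!esc)) sum(sizes[!esc]))
        next
      }
      for (sz in sizes) if (sz < n) ti[sz] <- ti[sz] + tau
      t <- t + tau
      pair <- sample.int(k, 2L)
      sizes <- c(sizes[-pair], sum(sizes[pair]))
    }
    TI[r, ] <- ti
    TM[r] <- t
  }
  list(t = TI, tmrca = TM)
}

# Kolmogorov-Smirnov distance between a sample and a right-continuous CDF
# with possible atoms: compare at each distinct value both the CDF and its
# left limit against the matching empirical quantities.
ks_distance <- function(x, cdf_fun) {
  n <- length(x)
  r <- rle(sort(x))
  v <- r$values
  cnt <- r$lengths
  Fn <- cumsum(cnt) / n
  Fn_left <- Fn - cnt / n
  Fv <- cdf_fun(v)
  Fv_left <- cdf_fun(v - 1e-11)
  max(abs(Fv - Fn), abs(Fv_left - Fn_left))
}

# 99% critical value for the one-sample KS statistic
ks_crit99 <- function(n) 1.628 / sqrt(n)

expect_within_3se <- function(est, truth, se, label = "") {
  expect_lt(abs(est - truth), 3 * se + 1e-12, label = label)
}
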