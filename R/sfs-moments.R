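# Expected i-Ton branch lengths under the star-like sweep model via the
# marginal-moments decomposition, without building the full joint GF.
#
# The ancestral process is Kingman for t < Ta, an instantaneous partition of
# the extant blocks at t = Ta (independent escapes, non-escapees merge), and
# Kingman again afterwards. Because the jump chain of the Kingman coalescent
# is independent of its holding times, the block-size configuration at a
# given number of extant lineages has a fixed, time-free distribution; the
# expected total length of branches with i descendants decomposes over
# levels as E[time at level] x E[# size-i blocks at level].

part_key <- function(sizes) paste(sort(sizes, decreasing = TRUE), collapse = "+")

part_sizes <- function(key) as.integer(strsplit(key, "+", fixed = TRUE)[[1L]])

# Distribution over block-size configurations of the Kingman jump chain,
# one list entry per level k = n..1; each entry maps key -> probability.
kingman_partition_dist <- function(n) {
  out <- vector("list", n)
  names(out) <- as.character(n:1)
  cur <- stats::setNames(1, part_key(rep(1L, n)))
  out[[as.character(n)]] <- cur
  for (k in n:2) {
    nxt <- new.env(parent = emptyenv())
    for (key in names(cur)) {
      p <- cur[[key]]
      sizes <- part_sizes(key)
      tab <- table(sizes)
      vals <- as.integer(names(tab)); mult <- as.integer(tab)
      npairs <- k * (k - 1) / 2
      for (ia in seq_along(vals)) for (ib in ia:length(vals)) {
        a <- vals[ia]; b <- vals[ib]
        w <- if (ia == ib) mult[ia] * (mult[ia] - 1) / 2 else mult[ia] * mult[ib]
        if (w == 0) next
        new_sizes <- sizes
        new_sizes <- new_sizes[-c(match(a, new_sizes))]
        new_sizes <- new_sizes[-c(match(b, new_sizes))]
        new_sizes <- c(new_sizes, a + b)
        nk <- part_key(new_sizes)
        nxt[[nk]] <- (nxt[[nk]] %||% 0) + p * w / npairs
      }
    }
    out[[as.character(k - 1L)]] <- unlist(as.list(nxt))
    cur <- out[[as.character(k - 1L)]]
  }
  out
}

# Jump-chain distribution over configurations per level, starting from an
# arbitrary configuration distribution `start` (key -> prob) whose keys all
# have the same number of blocks k0. Returns list indexed by level.
jump_chain_from <- function(start, k0) {
  out <- list()
  out[[as.character(k0)]] <- start
  cur <- start
  k <- k0
  while (k > 1L) {
    nxt <- new.env(parent = emptyenv())
    npairs <- k * (k - 1) / 2
    for (key in names(cur)) {
      p <- cur[[key]]
      sizes <- part_sizes(key)
      tab <- table(sizes)
      vals <- as.integer(names(tab)); mult <- as.integer(tab)
      for (ia in seq_along(vals)) for (ib in ia:length(vals)) {
        a <- vals[ia]; b <- vals[ib]
        w <- if (ia == ib) mult[ia] * (mult[ia] - 1) / 2 else mult[ia] * mult[ib]
        if (w == 0) next
        new_sizes <- sizes
        new_sizes <- new_sizes[-c(match(a, new_sizes))]
        new_sizes <- new_sizes[-c(match(b, new_sizes))]
        new_sizes <- c(new_sizes, a + b)
        nk <- part_key(new_sizes)
        nxt[[nk]] <- (nxt[[nk]] %||% 0) + p * w / npairs
      }
    }
    cur <- unlist(as.list(nxt))
    k <- k - 1L
    out[[as.character(k)]] <- cur
  }
  out
}

count_size <- function(key, i) sum(part_sizes(key) == i)

# Tavare's formula: probability of k ancestral lineages at time t, starting
# from n (time in units of 2Ne generations; pairwise coalescence rate 1).
#' Number-of-lineages distribution of the Kingman coalescent
#'
#' @param n Starting sample size (2..around 40; alternating-series formula).
#' @param k Number of surviving ancestral lineages.
#' @param t Time, in units of 2Ne generations (vectorised).
#' @return `P[k lineages at time t | n at time 0]`.
#' @keywords internal
kingman_gnk <- function(n, k, t) {
  stopifnot(k >= 1, k <= n)
  acc <- numeric(length(t))
  for (j in k:n) {
    rate <- j * (j - 1) / 2
    rising <- function(a, b) if (b == 0) 1 else prod(a + 0:(b - 1))
    falling <- function(a, b) if (b == 0) 1 else prod(a - 0:(b - 1))
    coef <- (2 * j - 1) * (-1)^(j - k) * rising(k, j - 1) * falling(n, j) /
      (factorial(k) * factorial(j - k) * rising(n, j))
    acc <- acc + coef * exp(-rate * t)
  }
  acc
}

# integral of g_{n,k} over [0, Ta]
kingman_gnk_int <- function(n, k, Ta) {
  acc <- 0
  for (j in k:n) {
    rate <- j * (j - 1) / 2
    rising <- function(a, b) if (b == 0) 1 else prod(a + 0:(b - 1))
    falling <- function(a, b) if (b == 0) 1 else prod(a - 0:(b - 1))
    coef <- (2 * j - 1) * (-1)^(j - k) * rising(k, j - 1) * falling(n, j) /
      (factorial(k) * factorial(j - k) * rising(n, j))
    acc <- acc + if (rate == 0) coef * Ta else coef * (1 - exp(-rate * Ta)) / rate
  }
  acc
}

# Apply independent escapes (prob pe per block) followed by the merger of
# all non-escapees to a configuration distribution at the sweep time.
# Returns key -> prob over post-sweep configurations.
apply_starlike_partition <- function(dist, pe) {
  out <- new.env(parent = emptyenv())
  for (key in names(dist)) {
    p0 <- dist[[key]]
    sizes <- part_sizes(key)
    k <- length(sizes)
    esc_patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))
    for (r in seq_len(nrow(esc_patterns))) {
      esc <- as.logical(esc_patterns[r, ])
      m <- sum(esc)
      pr <- pe^m * (1 - pe)^(k - m)
      if (pr == 0) next
      new_sizes <- c(sizes[esc], if (any(!esc)) sum(sizes[!esc]))
      nk <- part_key(new_sizes)
      out[[nk]] <- (out[[nk]] %||% 0) + p0 * pr
    }
  }
  unlist(as.list(out))
}

#' Expected i-Ton branch lengths under a star-like sweep
#'
#' Expected total length of branches with `i` descendants (i = 1..n-1), in
#' units of 2Ne generations, for a sample of size `n` at scaled distance
#' `alpha` from a sweep that completed `Ta` time units before sampling.
#' Under neutrality (`alpha = Inf`) this is the Kingman value `2/i`.
#'
#' @param n Sample size (2..12).
#' @param alpha Scaled recombination distance ([sweep_alpha()]); `Inf` for
#'   the neutral model.
#' @param Ta Time since fixation, units of 2Ne generations.
#' @return Numeric vector `E[t_1], ..., E[t_{n-1}]`.
#' @export
expected_iton_lengths <- function(n, alpha, Ta) {
  if (n < 2 || n > 12) stop("n must be between 2 and 12")
  if (alpha < 0 || Ta < 0) stop("alpha and Ta must be nonnegative")
  pe <- if (is.infinite(alpha)) 1 else escape_probability(alpha)
  Q <- kingman_partition_dist(n)
  Ei <- numeric(n - 1L)
  # phase 1: neutral Kingman restricted to [0, Ta)
  if (Ta > 0) {
    for (k in 2:n) {
      tau_k <- kingman_gnk_int(n, k, Ta)
      qk <- Q[[as.character(k)]]
      for (i in seq_len(n - 1L)) {
        cnt <- sum(vapply(names(qk), function(ky) qk[[ky]] * count_size(ky, i),
                          numeric(1)))
        Ei[i] <- Ei[i] + tau_k * cnt
      }
    }
  }
  # sweep partition at Ta, then neutral continuation
  for (k in 1:n) {
    pk <- if (Ta == 0) as.numeric(k == n) else kingman_gnk(n, k, Ta)
    if (pk < 1e-15) next
    if (k == 1L) next   # already fully coalesced; contributes nothing
    post <- apply_starlike_partition(Q[[as.character(k)]], pe)
    # group post-sweep configurations by block count
    kcounts <- vapply(names(post), function(ky) length(part_sizes(ky)), integer(1))
    for (k2 in sort(unique(kcounts), decreasing = TRUE)) {
      sel <- post[kcounts == k2]
      tot <- sum(sel)
      if (tot < 1e-15 || k2 < 2L) next
      chain <- jump_chain_from(sel / tot, k2)
      for (j in as.integer(names(chain))) {
        if (j < 2L) next
        lev <- chain[[as.character(j)]]
        hold <- 1 / (j * (j - 1) / 2)
        for (i in seq_len(n - 1L)) {
          cnt <- sum(vapply(names(lev), function(ky) lev[[ky]] * count_size(ky, i),
                            numeric(1)))
          Ei[i] <- Ei[i] + pk * tot * hold * cnt
        }
      }
    }
  }
  Ei
}

#' Expected site frequency spectrum near a sweep
#'
#' Normalised expected i-Ton branch lengths: the expected proportion of
#' segregating sites at derived-allele count `i` in a sample of `n`, at
#' scaled distance `alpha` from a sweep of age `Ta`.
#'
#' @inheritParams expected_iton_lengths
#' @param correct_duration If `TRUE`, replace `Ta` by `Ta + t_fix/(2Ne)` to
#'   account for the burst of coalescence sitting at the sweep's origin
#'   rather than its completion; requires `params`.
#' @param params A [sweep_params()] object (only used for the correction).
#' @return Numeric vector of proportions summing to 1.
#' @export
expected_sfs <- function(n, alpha, Ta, correct_duration = FALSE, params = NULL) {
  if (correct_duration) {
    if (is.null(params)) stop("duration correction requires `params`")
    Ta <- Ta + fixation_time_coalescent(params)
  }
  if (!is.infinite(alpha) && alpha == 0 && Ta == 0)
    stop("degenerate genealogy: alpha = 0 and Ta = 0 give a zero-length tree")
  Ei <- expected_iton_lengths(n, alpha, Ta)
  tot <- sum(Ei)
  if (tot <= 0) stop("degenerate genealogy: expected tree length is zero")
  Ei / tot
}
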