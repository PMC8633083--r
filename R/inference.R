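# Composite-likelihood estimation of (theta, Ta, s), sweep support
# Delta lnCL, grid optimisation, and ROC-based power evaluation.
#
# Key computational device: every blockwise-configuration probability is a
# polynomial of degree <= 4 in the per-lineage escape probability
# Pe = 1 - exp(-alpha), because each event history contains exactly one
# sweep partition whose probability is binomial in Pe over at most four
# lineages. Evaluating the table at five Pe nodes therefore reconstructs
# it exactly (not approximately) at every block distance, which is what
# makes grid fits over thousands of blocks cheap.

.pkg_cache <- new.env(parent = emptyenv())

PE_NODES <- c(0, 0.25, 0.5, 0.75, 1)

# GF skeletons at the Pe nodes (independent of theta, Ta and the data)
gf_at_pe_nodes <- function() {
  hit <- .pkg_cache$gf_pe
  if (!is.null(hit)) return(hit)
  gfs <- lapply(PE_NODES, function(pe) {
    mdl <- structure(list(kind = "starlike", alpha = NA_real_, Pe = pe),
                     class = "sweep_partition_model")
    iton_gf(4L, mdl)
  })
  .pkg_cache$gf_pe <- gfs
  gfs
}

neutral_gf_n4 <- function() {
  hit <- .pkg_cache$gf_neutral
  if (!is.null(hit)) return(hit)
  g <- iton_gf(4L)
  .pkg_cache$gf_neutral <- g
  g
}

# 64-vector of probabilities (k1 fastest) at the Pe nodes: 64 x 5 matrix.
bsfs_node_tables <- function(Ta, mut) {
  key <- sprintf("nodes|%.10g|%.10g|%d", Ta, mut$theta, mut$k_max)
  hit <- .pkg_cache[[key]]
  if (!is.null(hit)) return(hit)
  gfs <- gf_at_pe_nodes()
  out <- vapply(gfs, function(g)
    as.vector(bsfs_from_gf(g, Ta = Ta, mut = mut, meta = list())),
    numeric((mut$k_max + 2L)^3))
  .pkg_cache[[key]] <- out
  out
}

neutral_bsfs_vec <- function(mut) {
  key <- sprintf("neutral|%.10g|%d", mut$theta, mut$k_max)
  hit <- .pkg_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- as.vector(bsfs_from_gf(neutral_gf_n4(), Ta = NULL, mut = mut,
                                meta = list()))
  .pkg_cache[[key]] <- out
  out
}

#' Blockwise configuration probabilities at arbitrary distances
#'
#' Exact bSFS probabilities for each value of `alpha`, reconstructed from
#' the five Pe-node tables by polynomial interpolation (exact, since the
#' probabilities are degree-4 polynomials in Pe).
#'
#' @param alpha Vector of scaled distances (may be `Inf`).
#' @param Ta Sweep time.
#' @param mut A [mutation_model()].
#' @return Matrix `(k_max+2)^3 x length(alpha)` of probabilities.
#' @keywords internal
bsfs_prob_matrix <- function(alpha, Ta, mut) {
  nodes <- bsfs_node_tables(Ta, mut)              # 64 x 5
  V <- outer(PE_NODES, 0:4, `^`)                  # 5 x 5 Vandermonde
  coefs <- nodes %*% t(solve(V))                  # 64 x 5 polynomial coefs
  pe <- ifelse(is.infinite(alpha), 1, -expm1(-alpha))
  PE <- outer(pe, 0:4, `^`)                       # D x 5
  P <- coefs %*% t(PE)                            # 64 x D
  pmax(P, 1e-300)
}

#' Linear index of a capped configuration
#'
#' @param k Matrix or data.frame with columns `k1, k2, k3` (capped counts,
#'   `k_max + 1` codes the `> k_max` bin).
#' @param k_max Cap.
#' @return Integer index into the flattened bSFS table (k1 fastest).
#' @export
config_index <- function(k, k_max) {
  nb <- k_max + 2L
  1L + k[, 1L] + nb * k[, 2L] + nb * nb * k[, 3L]
}

## ---- tabulation --------------------------------------------------------

#' Tabulate blockwise configurations over subsamples
#'
#' For per-haplotype derived-allele data (from [extract_blocks()]), counts
#' the i-Ton configuration of every subsample of `x` haplotypes in every
#' block. Sites monomorphic within a subsample (derived count 0 or `x`)
#' contribute nothing. For a [simulate_blocks()] dataset with `n = x` the
#' per-block totals are returned unchanged with a subsample index.
#'
#' @param data A `replicate_dataset` or a list of per-block 0/1 matrices
#'   (variants x haplotypes).
#' @param x Subsample size (4 for the topology-aware bSFS).
#' @param k_max Cap for binning.
#' @param d Optional per-block distances (for list input).
#' @return data.frame with columns `block`, `j` (subsample), `k1..k{x-1}`
#'   and, when available, `d`.
#' @export
tabulate_bsfs <- function(data, x = 4L, k_max = 2L, d = NULL) {
  if (inherits(data, "replicate_dataset")) {
    n <- attr(data, "n")
    if (n != x) stop("dataset holds class totals for n = ", n,
                     "; per-lineage data are needed to subsample x = ", x)
    out <- data.frame(block = seq_len(nrow(data)), j = 1L,
                      k1 = pmin(data$k1, k_max + 1L),
                      k2 = pmin(data$k2, k_max + 1L),
                      k3 = pmin(data$k3, k_max + 1L),
                      d = data$d)
    return(out)
  }
  if (!is.list(data)) stop("unsupported input to tabulate_bsfs")
  rows <- list()
  for (b in seq_along(data)) {
    M <- data[[b]]
    nh <- ncol(M)
    if (nh < x) stop("fewer haplotypes than subsample size")
    subs <- utils::combn(nh, x, simplify = FALSE)
    for (j in seq_along(subs)) {
      cnt <- if (nrow(M)) rowSums(M[, subs[[j]], drop = FALSE]) else integer(0)
      kk <- vapply(seq_len(x - 1L), function(i)
        as.integer(min(sum(cnt == i), k_max + 1L)), integer(1))
      row <- as.list(c(block = b, j = j, stats::setNames(kk, paste0("k", seq_len(x - 1L)))))
      if (!is.null(d)) row$d <- d[b]
      rows[[length(rows) + 1L]] <- as.data.frame(row)
    }
  }
  do.call(rbind, rows)
}

## ---- composite likelihood ----------------------------------------------

LOG_FLOOR <- log(1e-300)

#' Composite log-likelihood of blockwise configurations
#'
#' `lnCL = sum_blocks sum_subsamples ln P[k]` under either the sweep model
#' at `(theta, Ta, s)` (each block evaluated at its own scaled distance
#' `alpha_i = sweep_alpha(r, d_i, s, Ne)`) or the neutral model at `theta`.
#'
#' @param tab Tabulated configurations ([tabulate_bsfs()] output or a
#'   `replicate_dataset`): needs columns `k1..k3` and `d`.
#' @param theta Scaled block mutation rate.
#' @param Ta,s Sweep parameters; leave `NULL` for the neutral model.
#' @param params A [sweep_params()] carrying `Ne` and `r` (required for the
#'   sweep model).
#' @param k_max Cap (must match the tabulation).
#' @param correct_duration If `TRUE`, evaluate the sweep model at
#'   `Ta + t_fix/(2Ne)` (duration bias correction).
#' @return The composite log-likelihood (scalar). Configurations with zero
#'   model probability are floored at `log(1e-300)` with a warning.
#' @export
ln_cl <- function(tab, theta, Ta = NULL, s = NULL, params = NULL,
                  k_max = 2L, correct_duration = FALSE) {
  if (inherits(tab, "replicate_dataset")) tab <- tabulate_bsfs(tab, k_max = k_max)
  mut <- mutation_model(theta, k_max)
  idx <- config_index(as.matrix(tab[, c("k1", "k2", "k3")]), k_max)
  if (is.null(Ta) != is.null(s))
    stop("supply both Ta and s for the sweep model, or neither for neutral")
  if (is.null(Ta)) {
    p <- neutral_bsfs_vec(mut)[idx]
  } else {
    if (is.null(params)) stop("sweep-model lnCL needs `params` (Ne and r)")
    if (2 * params$Ne * s <= 1) stop("grid value violates 2*Ne*s > 1")
    Taeff <- if (correct_duration)
      Ta + 2 * log(2 * params$Ne * s) / s / (2 * params$Ne) else Ta
    dd <- sort(unique(tab$d))
    al <- sweep_alpha(params$r, dd, s, params$Ne)
    P <- bsfs_prob_matrix(al, Taeff, mut)
    p <- P[cbind(idx, match(tab$d, dd))]
  }
  if (any(p <= 1e-300)) {
    warning("configuration(s) with vanishing model probability; flooring log")
    return(sum(pmax(log(p), LOG_FLOOR)))
  }
  sum(log(p))
}

#' Grid specification for the composite-likelihood fit
#'
#' @param theta Increasing vector of candidate scaled mutation rates.
#' @param Ta Increasing vector of candidate sweep times.
#' @param s Increasing vector of candidate selection coefficients.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(theta, Ta, s) {
  chk <- function(x, nm) {
    if (!length(x) || is.unsorted(x, strictly = TRUE))
      stop("grid axis `", nm, "` must be nonempty and strictly increasing")
  }
  chk(theta, "theta"); chk(Ta, "Ta"); chk(s, "s")
  structure(list(theta = theta, Ta = Ta, s = s), class = "grid_spec")
}

#' Estimate the scaled mutation rate from distant blocks
#'
#' Maximises the neutral composite likelihood over the `theta` grid using
#' only blocks far enough from the sweep target that the sweep cannot have
#' touched them appreciably: a block qualifies if its scaled distance
#' exceeds `alpha_threshold` under every selection coefficient on the grid.
#'
#' @param tab Tabulated configurations with columns `k1..k3`, `d`.
#' @param grid A [grid_spec()].
#' @param params A [sweep_params()].
#' @param alpha_threshold Distance threshold on the scaled distance
#'   (default 0.5).
#' @param k_max Cap.
#' @return List with `theta_hat` and the profile of neutral lnCL values.
#' @export
estimate_theta <- function(tab, grid, params, alpha_threshold = 0.5, k_max = 2L) {
  if (inherits(tab, "replicate_dataset")) tab <- tabulate_bsfs(tab, k_max = k_max)
  al_min <- do.call(pmin, lapply(grid$s, function(s)
    sweep_alpha(params$r, tab$d, s, params$Ne)))
  keep <- al_min > alpha_threshold
  if (!any(keep)) stop("no blocks beyond the distance threshold; cannot estimate theta")
  sub <- tab[keep, , drop = FALSE]
  prof <- vapply(grid$theta, function(th) ln_cl(sub, th), numeric(1))
  list(theta_hat = grid$theta[which.max(prof)], profile = prof,
       n_blocks = sum(keep))
}

#' Two-step composite-likelihood grid fit
#'
#' First estimates `theta` from distant blocks under the neutral model,
#' then maximises the sweep composite likelihood over the `(Ta, s)` grid
#' conditional on `theta_hat`, and reports the sweep support
#' `Delta lnCL = lnCL_sweep - lnCL_neutral` (both at `theta_hat`). Grid
#' ties are broken toward the neutral-most cell (largest `Ta`, then
#' smallest `s`).
#'
#' @inheritParams estimate_theta
#' @param correct_duration Evaluate the sweep model at `Ta + t_fix/(2Ne)`.
#' @return A `cl_result`: estimates, both log-likelihoods, `delta_lnCL`
#'   and the `(Ta, s)` log-likelihood surface.
#' @export
fit_grid <- function(tab, grid, params, alpha_threshold = 0.5, k_max = 2L,
                     correct_duration = FALSE) {
  if (inherits(tab, "replicate_dataset")) tab <- tabulate_bsfs(tab, k_max = k_max)
  est <- estimate_theta(tab, grid, params, alpha_threshold, k_max)
  th <- est$theta_hat
  ln0 <- ln_cl(tab, th)
  surf <- matrix(NA_real_, length(grid$Ta), length(grid$s),
                 dimnames = list(Ta = grid$Ta, s = grid$s))
  for (i in seq_along(grid$Ta)) for (j in seq_along(grid$s)) {
    surf[i, j] <- ln_cl(tab, th, Ta = grid$Ta[i], s = grid$s[j],
                        params = params, k_max = k_max,
                        correct_duration = correct_duration)
  }
  best <- which(surf == max(surf), arr.ind = TRUE)
  # neutral-most tie-break: largest Ta, then smallest s
  best <- best[order(-best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
  res <- list(theta_hat = th, Ta_hat = grid$Ta[best[1L]],
              s_hat = grid$s[best[2L]],
              lnCL_sweep = surf[best[1L], best[2L]],
              lnCL_neutral = ln0,
              delta_lnCL = surf[best[1L], best[2L]] - ln0,
              surface = surf, theta_profile = est$profile,
              grid = grid)
  class(res) <- "cl_result"
  res
}

#' @export
print.cl_result <- function(x, ...) {
  cat(sprintf("cl_result: theta=%.3g, Ta=%.3g, s=%.3g, DlnCL=%.3f (sweep %.2f vs neutral %.2f)\n",
              x$theta_hat, x$Ta_hat, x$s_hat, x$delta_lnCL,
              x$lnCL_sweep, x$lnCL_neutral))
  invisible(x)
}

## ---- batched fitting for power studies ---------------------------------

# Precompute, for a fixed set of block distances and a grid, the log
# probability of every configuration at every grid cell: the expensive part
# of a power study, shared across replicates.
#' Precompute composite-likelihood lookup tables for a block layout
#'
#' @param d Vector of block distances (as in the datasets to be fitted).
#' @param grid A [grid_spec()].
#' @param params A [sweep_params()].
#' @param k_max Cap.
#' @param correct_duration Apply the duration bias correction.
#' @return An opaque list consumed by [fit_grid_batch()].
#' @export
precompute_cl_tables <- function(d, grid, params, k_max = 2L,
                                 correct_duration = FALSE) {
  dd <- sort(unique(d))
  dmatch <- match(d, dd)
  neut <- lapply(grid$theta, function(th)
    log(pmax(neutral_bsfs_vec(mutation_model(th, k_max)), 1e-300)))
  sweep_tabs <- list()
  for (ti in seq_along(grid$theta)) {
    mut <- mutation_model(grid$theta[ti], k_max)
    for (ai in seq_along(grid$Ta)) for (si in seq_along(grid$s)) {
      s <- grid$s[si]
      Taeff <- if (correct_duration)
        grid$Ta[ai] + 2 * log(2 * params$Ne * s) / s / (2 * params$Ne)
      else grid$Ta[ai]
      al <- sweep_alpha(params$r, dd, s, params$Ne)
      P <- bsfs_prob_matrix(al, Taeff, mutation_model(grid$theta[ti], k_max))
      sweep_tabs[[paste(ti, ai, si)]] <- log(P)   # 64 x length(dd)
    }
  }
  al_min <- do.call(pmin, lapply(grid$s, function(s)
    sweep_alpha(params$r, d, s, params$Ne)))
  list(grid = grid, d = d, dmatch = dmatch, neutral = neut,
       sweep = sweep_tabs, k_max = k_max, params = params,
       distant = al_min > 0.5)
}

#' Fit one replicate with precomputed tables
#'
#' Same estimator as [fit_grid()] (two-step theta-then-(Ta,s), identical
#' tie-breaks) but using the lookup tables from [precompute_cl_tables()].
#'
#' @param k Integer matrix `B x 3` of capped counts (block order must match
#'   the `d` used for precomputation).
#' @param tabs Result of [precompute_cl_tables()].
#' @return A `cl_result` (without the theta profile).
#' @export
fit_grid_batch <- function(k, tabs) {
  grid <- tabs$grid
  idx <- config_index(k, tabs$k_max)
  pos <- cbind(idx, tabs$dmatch)
  ln0_prof <- vapply(seq_along(grid$theta), function(ti)
    sum(tabs$neutral[[ti]][idx[tabs$distant]]), numeric(1))
  ti <- which.max(ln0_prof)
  ln0 <- sum(tabs$neutral[[ti]][idx])
  surf <- matrix(NA_real_, length(grid$Ta), length(grid$s),
                 dimnames = list(Ta = grid$Ta, s = grid$s))
  for (ai in seq_along(grid$Ta)) for (si in seq_along(grid$s)) {
    surf[ai, si] <- sum(tabs$sweep[[paste(ti, ai, si)]][pos])
  }
  best <- which(surf == max(surf), arr.ind = TRUE)
  best <- best[order(-best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
  res <- list(theta_hat = grid$theta[ti], Ta_hat = grid$Ta[best[1L]],
              s_hat = grid$s[best[2L]],
              lnCL_sweep = surf[best[1L], best[2L]], lnCL_neutral = ln0,
              delta_lnCL = surf[best[1L], best[2L]] - ln0,
              surface = surf, grid = grid)
  class(res) <- "cl_result"
  res
}

## ---- ROC ---------------------------------------------------------------

#' ROC curve and AUC from sweep-support scores
#'
#' Jointly ranks the `Delta lnCL` values of true (sweep) and false
#' (neutral) replicates in descending order and walks the ranking,
#' pooling ties at equal thresholds.
#'
#' @param delta_sweep Scores of true-sweep replicates.
#' @param delta_neutral Scores of neutral replicates.
#' @return List with a data.frame `curve` (`fpr`, `tpr`, nondecreasing
#'   step curve from (0,0) to (1,1)) and the `auc` (ties counted 1/2).
#' @export
roc_curve <- function(delta_sweep, delta_neutral) {
  if (!length(delta_sweep) || !length(delta_neutral))
    stop("both score lists must be nonempty")
  thr <- sort(unique(c(delta_sweep, delta_neutral)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(delta_sweep >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(delta_neutral >= t), numeric(1))
  curve <- rbind(data.frame(fpr = 0, tpr = 0), data.frame(fpr = fpr, tpr = tpr))
  # Mann-Whitney AUC with ties counted 1/2
  r <- rank(c(delta_sweep, delta_neutral))
  n1 <- length(delta_sweep); n2 <- length(delta_neutral)
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  list(curve = curve, auc = auc)
}
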