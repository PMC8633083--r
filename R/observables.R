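# Closed-form observables derived from the generating function: tmrca
# distribution, expected SFS, i-Ton marginal distributions, topology-class
# probabilities, and blockwise SFS probabilities.

#' Block mutation model
#'
#' Mutations drop on a branch class as a Poisson process with rate `theta/2`
#' per unit of total branch length (time in 2Ne generations), where
#' `theta = 4*Ne*mu*l` is the scaled mutation rate of a block of `l` bases.
#' Counts above `k_max` per i-Ton type are binned into a single category.
#'
#' @param theta Scaled block mutation rate, `4*Ne*mu*l`.
#' @param k_max Per-type count cap (binning threshold).
#' @return A `mutation_model` object.
#' @export
mutation_model <- function(theta, k_max = 2L) {
  if (theta <= 0) stop("theta must be positive")
  if (k_max < 0) stop("k_max must be nonnegative")
  structure(list(theta = theta, k_max = as.integer(k_max)),
            class = "mutation_model")
}

#' Expected time to the most recent common ancestor near a sweep
#'
#' For a pair of lineages at scaled distance `alpha` from a sweep of age
#' `Ta`: `E[tmrca] = 1 - exp(-Ta - 2*alpha)` (in units of 2Ne generations).
#' `method = "gf"` recomputes the same quantity by differentiating the
#' generating function built from the coalescent recursion, as a
#' consistency check of the machinery.
#'
#' @param alpha Scaled recombination distance; `Inf` for neutrality.
#' @param Ta Time since fixation (2Ne generations).
#' @param method `"closed"` (default) or `"gf"`.
#' @return Expected tmrca in `[0, 1]`.
#' @export
expected_tmrca <- function(alpha, Ta, method = c("closed", "gf")) {
  method <- match.arg(method)
  if (alpha < 0 || Ta < 0) stop("alpha and Ta must be nonnegative")
  if (method == "closed") return(1 - exp(-Ta - 2 * alpha))
  if (is.infinite(alpha)) {
    g <- gf_subst_linear(neutral_gf(lineage_sample(2)), c("w_a", "w_b"), "w")
    return(-gf_eval(gf_deriv(g, "w"), c(w = 0)))
  }
  g <- invert_sweep_time(gf_with_sweep(lineage_sample(2), starlike_model(alpha)))
  g <- gf_subst_linear(g, c("w_a", "w_b"), "w")
  -gf_eval(gf_deriv(g, "w"), c(w = 0), Ta = Ta)
}

#' Distribution of the pairwise tmrca near a sweep
#'
#' Piecewise density: neutral `exp(-t)` before the sweep epoch `t < Ta`, a
#' point mass `exp(-Ta - 2*alpha)` at `t = Ta` (the burst of coalescence),
#' and the neutral density thinned by the pair-escape probability,
#' `exp(-t)*(1 - exp(-2*alpha))`, for `t > Ta`.
#'
#' @inheritParams expected_tmrca
#' @return A [pwe_density()].
#' @export
tmrca_distribution <- function(alpha, Ta) {
  if (alpha < 0 || Ta < 0) stop("alpha and Ta must be nonnegative")
  P02 <- if (is.infinite(alpha)) 0 else exp(-2 * alpha)
  piece <- function(cf) data.frame(coef = cf, rate = 1, pow = 0)
  if (P02 == 0) {
    return(pwe_density(0, list(piece(1))))
  }
  if (Ta == 0) {
    return(pwe_density(0, list(piece(1 - P02)),
                       data.frame(loc = 0, mass = P02)))
  }
  pwe_density(c(0, Ta), list(piece(1), piece(1 - P02)),
              data.frame(loc = Ta, mass = exp(-Ta) * P02))
}

#' Probabilities of genealogical topology classes for n = 4
#'
#' Classifies genealogies of four lineages by their root structure:
#' asymmetric (a branch with three descendants exists, i.e. a 3+1 root
#' bipartition), star (neither a doubleton nor a tripleton branch ever
#' exists: the four lineages merge in a single sweep event), and symmetric
#' (the rest, including trifurcating roots, which carry a doubleton but no
#' tripleton). Under neutrality this gives the classic (1/3, 2/3, 0).
#'
#' Closed forms are available for the star-like model. For a marked-Yule
#' model the probabilities are estimated by Monte Carlo from the hybrid
#' simulator (with a warning).
#'
#' @inheritParams expected_tmrca
#' @param model A `sweep_partition_model`; defaults to the star-like model
#'   at `alpha`.
#' @param mc_reps Replicates for the Monte-Carlo fallback.
#' @return Named vector `c(Psym, Pasym, Pstar)` summing to 1.
#' @export
topology_probs_n4 <- function(alpha, Ta, model = NULL, mc_reps = 200000L) {
  if (is.null(model)) model <- starlike_model(if (is.infinite(alpha)) 0 else alpha)
  if (model$kind != "starlike") {
    warning("closed-form topology probabilities are star-like only; ",
            "falling back to Monte Carlo")
    cls <- replicate(mc_reps,
                     classify_topology_n4(simulate_hybrid_genealogy(4, Ta = Ta, model = model)))
    tab <- table(factor(cls, levels = c("sym", "asym", "star"))) / mc_reps
    return(stats::setNames(as.numeric(tab), c("Psym", "Pasym", "Pstar")))
  }
  pe <- if (is.infinite(alpha)) 1 else model$Pe
  P03 <- (1 - pe)^3
  P04 <- (1 - pe)^4
  P14 <- 4 * pe * (1 - pe)^3
  A4 <- exp(-6 * Ta)                       # no coalescence before the sweep
  P3 <- 2 * (exp(-3 * Ta) - exp(-6 * Ta))  # exactly one coalescence before
  Pstar <- A4 * P04
  Pasym <- (2 / 3) * (1 - A4 - P3) +
    (2 / 3) * P3 * (1 - P03) +
    A4 * (P14 + (2 / 3) * (1 - P04 - P14))
  Psym <- (1 / 3) * (1 - A4 - P3) +
    P3 * (P03 + (1 / 3) * (1 - P03)) +
    A4 * ((1 / 3) * (1 - P04 - P14))
  c(Psym = Psym, Pasym = Pasym, Pstar = Pstar)
}

# Full collapsed, inverted GF for a sample of n with a sweep (or the neutral
# GF for alpha = Inf / model = NULL), over i-Ton variables w1..w(n-1).
# Star-like and neutral builds are memoised (the expensive part of table
# construction); Yule models carry Monte-Carlo tables and are not cached.
iton_gf <- function(n, model = NULL) {
  if (is.null(model)) {
    key <- sprintf("itongf|%d|neutral", n)
    hit <- .pkg_cache[[key]]
    if (!is.null(hit)) return(hit)
    g <- collapse_to_iton(neutral_gf(lineage_sample(n)), n)
    .pkg_cache[[key]] <- g
    return(g)
  }
  if (model$kind == "starlike") {
    key <- sprintf("itongf|%d|pe%.15g", n, model$Pe)
    hit <- .pkg_cache[[key]]
    if (!is.null(hit)) return(hit)
    g <- collapse_to_iton(invert_sweep_time(gf_with_sweep(lineage_sample(n), model)), n)
    .pkg_cache[[key]] <- g
    return(g)
  }
  collapse_to_iton(invert_sweep_time(gf_with_sweep(lineage_sample(n), model)), n)
}

#' Marginal distribution of i-Ton branch lengths (n = 4)
#'
#' Inverts the joint generating function with respect to the chosen i-Ton
#' variable (all other classes marginalised) to obtain the distribution of
#' the total length of branches with `i` descendants. Near a sweep these
#' densities are piecewise exponential with point masses at multiples of
#' `Ta` determined by how many i-Ton branches can be present when the sweep
#' hits; under neutrality the tripleton distribution carries an atom of
#' 1/3 at zero (asymmetric-topology probability) and the singleton and
#' doubleton distributions are continuous.
#'
#' @param i i-Ton class, 1..3.
#' @inheritParams expected_tmrca
#' @param model Optional `sweep_partition_model`; default star-like at
#'   `alpha` (ignored when `alpha = Inf`: neutral model).
#' @param n Sample size; the full joint GF restricts this to 4.
#' @return A [pwe_density()].
#' @export
iton_marginal_distribution <- function(i, alpha, Ta, model = NULL, n = 4L) {
  if (n != 4L) stop("marginal i-Ton distributions are provided for n = 4")
  if (!(i %in% 1:3)) stop("i must be 1, 2 or 3 for n = 4")
  neutral <- is.infinite(alpha) && is.null(model)
  if (!neutral && is.null(model)) model <- starlike_model(alpha)
  g <- if (neutral) iton_gf(n) else iton_gf(n, model)
  v <- paste0("w", i)
  gf_to_density(g, v, Ta = if (neutral) 0 else Ta)
}

## ---- blockwise SFS -----------------------------------------------------

#' Analytic blockwise SFS probabilities (n = 4)
#'
#' Probability of every blockwise mutation configuration `(k1, k2, k3)` --
#' counts of singleton, doubleton and tripleton mutations in a
#' non-recombining block -- with each count capped at `k_max` (the last bin
#' collects `> k_max`). Interior probabilities come from mixed derivatives
#' of the generating function at `omega = theta/2`:
#' `P[k] = prod_i (theta/2)^{k_i} * (-1)^{sum k} * d^k phi / prod k_i!`,
#' and the capped bins follow by complementation from partially
#' marginalised evaluations (setting the corresponding `omega` to zero).
#'
#' @inheritParams expected_tmrca
#' @param mut A [mutation_model()].
#' @param model Optional `sweep_partition_model`; default star-like at
#'   `alpha`; `alpha = Inf` gives the neutral table.
#' @return A `bsfs_table`: numeric array of dim `(k_max+2)^3` with
#'   attributes recording `alpha`, `Ta`, `theta`, `k_max` and model kind.
#' @export
bsfs_probabilities <- function(alpha, Ta, mut, model = NULL) {
  stopifnot(inherits(mut, "mutation_model"))
  neutral <- is.infinite(alpha) && is.null(model)
  if (!neutral && is.null(model)) model <- starlike_model(alpha)
  g <- if (neutral) iton_gf(4L) else iton_gf(4L, model)
  bsfs_from_gf(g, Ta = if (neutral) NULL else Ta, mut = mut,
               meta = list(alpha = alpha, Ta = Ta,
                           model = if (neutral) "neutral" else model$kind))
}

# Core table assembly from a collapsed (and, for sweeps, delta-inverted)
# GF over w1..w3. Ta = NULL for the neutral GF.
bsfs_from_gf <- function(g, Ta, mut, meta = list()) {
  theta <- mut$theta; kmax <- mut$k_max
  vars <- c("w1", "w2", "w3")
  at <- stats::setNames(rep(theta / 2, 3), vars)
  # probability arrays P[k_V = vec] for every active subset V (others free)
  subsets <- unlist(lapply(0:3, function(m) utils::combn(3, m, simplify = FALSE)),
                    recursive = FALSE)
  ptab <- list()
  for (V in subsets) {
    key <- paste(V, collapse = "")
    if (length(V) == 0L) { ptab[[key]] <- 1; next }
    act <- vars[V]
    gz <- gf_subst_zero(g, setdiff(vars, act))
    ords <- stats::setNames(rep(kmax, length(act)), act)
    tc <- gf_taylor(gz, at = at[act], orders = ords, Ta = Ta)
    idx <- as.matrix(expand.grid(lapply(seq_along(act), function(z) 0:kmax)))
    pv <- apply(idx, 1L, function(e)
      prod((theta / 2)^e) * (-1)^sum(e) * tc[matrix(e + 1L, 1L)])
    ptab[[key]] <- array(pv, dim = rep(kmax + 1L, length(act)))
  }
  nb <- kmax + 2L
  out <- array(0, dim = rep(nb, 3L),
               dimnames = rep(list(c(0:kmax, paste0(">", kmax))), 3L))
  cfgs <- as.matrix(expand.grid(k1 = 0:(nb - 1L), k2 = 0:(nb - 1L), k3 = 0:(nb - 1L)))
  for (r in seq_len(nrow(cfgs))) {
    kk <- cfgs[r, ]
    S <- which(kk == kmax + 1L)          # classes binned as "> k_max"
    R <- setdiff(1:3, S)
    val <- 0
    subs <- unlist(lapply(0:length(S), function(m)
      utils::combn(S, m, simplify = FALSE)), recursive = FALSE)
    for (Tset in subs) {
      act <- sort(c(R, Tset))
      A <- ptab[[paste(act, collapse = "")]]
      if (length(act) == 0L) { val <- val + 1; next }
      # sum A over k_T in 0..kmax at fixed k_R
      pos <- lapply(act, function(v) if (v %in% R) kk[v] + 1L else 1:(kmax + 1L))
      block <- do.call(`[`, c(list(A), pos, list(drop = FALSE)))
      val <- val + (-1)^length(Tset) * sum(block)
    }
    out[r] <- val
  }
  structure(out, class = "bsfs_table", theta = theta, k_max = kmax,
            alpha = meta$alpha, Ta = meta$Ta, model = meta$model)
}

#' @export
print.bsfs_table <- function(x, ...) {
  cat(sprintf("<bsfs_table> %d configurations (k_max=%d), theta=%g, alpha=%s, Ta=%s, model=%s\n",
              length(x), attr(x, "k_max"), attr(x, "theta"),
              format(attr(x, "alpha")), format(attr(x, "Ta")),
              attr(x, "model")))
  cat("  total probability:", format(sum(x), digits = 10), "\n")
  invisible(x)
}

#' Export a bSFS table as a data.frame
#'
#' @param x A `bsfs_table`.
#' @return data.frame with columns `k1, k2, k3` (labels, capped counts) and
#'   `prob`, plus the model metadata as attributes.
#' @export
bsfs_as_data_frame <- function(x) {
  dn <- dimnames(x)
  gr <- expand.grid(k1 = dn[[1]], k2 = dn[[2]], k3 = dn[[3]],
                    stringsAsFactors = FALSE)
  gr$prob <- as.vector(x)
  attr(gr, "theta") <- attr(x, "theta")
  attr(gr, "k_max") <- attr(x, "k_max")
  attr(gr, "alpha") <- attr(x, "alpha")
  attr(gr, "Ta") <- attr(x, "Ta")
  gr
}
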