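# Instantaneous-sweep partition models and the selection-parameter algebra
# connecting (Ne, s, r, d) to the scaled recombination distance alpha and
# the sweep duration t_fix.

#' Sweep model parameters
#'
#' Bundles the population-genetic parameters of a hard sweep. Time since
#' fixation `Ta` is measured in units of 2Ne generations; `s` is the
#' heterozygous selection coefficient per generation; `r` the per-base,
#' per-generation recombination rate.
#'
#' @param Ne Diploid effective population size (individuals).
#' @param s Heterozygous selection coefficient; requires `2*Ne*s > 1`.
#' @param r Per-base per-generation recombination rate.
#' @param Ta Time since fixation of the beneficial allele, in units of 2Ne
#'   generations.
#' @return An object of class `sweep_params` with derived field `t_fix`
#'   (expected sweep duration `2*log(2*Ne*s)/s`, in generations).
#' @export
sweep_params <- function(Ne, s, r, Ta = 0) {
  if (Ne < 1) stop("Ne must be at least 1")
  if (s <= 0) stop("s must be positive")
  if (2 * Ne * s <= 1) stop("2*Ne*s must exceed 1 (sweep duration undefined otherwise)")
  if (r < 0) stop("r must be nonnegative")
  if (Ta < 0) stop("Ta must be nonnegative")
  structure(list(Ne = Ne, s = s, r = r, Ta = Ta,
                 t_fix = 2 * log(2 * Ne * s) / s),
            class = "sweep_params")
}

#' @export
print.sweep_params <- function(x, ...) {
  cat(sprintf("sweep_params: Ne=%g, s=%g, r=%g, Ta=%g (t_fix=%.1f generations)\n",
              x$Ne, x$s, x$r, x$Ta, x$t_fix))
  invisible(x)
}

#' Scaled recombination distance from the selected site
#'
#' `alpha = (r*d/s) * log(2*Ne*s)`, equivalently `r*d*t_fix/2`: the expected
#' number of recombination events between the neutral locus and the selected
#' site over (half) the sweep duration. It controls the per-lineage escape
#' probability `1 - exp(-alpha)`.
#'
#' @param r Per-base per-generation recombination rate.
#' @param d Distance from the selected site, in bases.
#' @param s Heterozygous selection coefficient.
#' @param Ne Diploid population size.
#' @return Nonnegative scalar (vectorised over `d`).
#' @export
sweep_alpha <- function(r, d, s, Ne) {
  if (2 * Ne * s <= 1) stop("2*Ne*s must exceed 1")
  if (any(d < 0)) stop("distance must be nonnegative")
  (r * d / s) * log(2 * Ne * s)
}

#' Per-lineage probability of escaping the sweep
#'
#' @param alpha Scaled recombination distance, see [sweep_alpha()].
#' @return `1 - exp(-alpha)`, in `[0, 1]`.
#' @export
escape_probability <- function(alpha) {
  if (any(alpha < 0)) stop("alpha must be nonnegative")
  -expm1(-alpha)
}

#' Star-like partition probabilities
#'
#' Under the star-like approximation the `n` lineages present at the sweep
#' escape independently, so the number of escapees is binomial:
#' `P[m,n] = choose(n,m) * Pe^m * (1-Pe)^(n-m)`.
#'
#' @param n Number of extant lineages hit by the sweep.
#' @param alpha Scaled recombination distance.
#' @return Numeric vector of length `n + 1`, named `"0" ... "n"`.
#' @export
starlike_partition_probs <- function(n, alpha) {
  if (n < 1) stop("n must be at least 1")
  pe <- escape_probability(alpha)
  stats::setNames(stats::dbinom(0:n, n, pe), as.character(0:n))
}

#' Expected sweep duration on the coalescent time scale
#'
#' @param params A [sweep_params()] object.
#' @return `t_fix / (2*Ne) = log(2*Ne*s) / (s*Ne)`, in units of 2Ne
#'   generations.
#' @export
fixation_time_coalescent <- function(params) {
  stopifnot(inherits(params, "sweep_params"))
  params$t_fix / (2 * params$Ne)
}

## ---- partition model objects -------------------------------------------

#' Star-like sweep partition model
#'
#' Each lineage present when the sweep occurs escapes independently with
#' probability `Pe = 1 - exp(-alpha)`; all non-escapees merge in a single
#' multiple-merger event at the origin of the beneficial mutation.
#'
#' @param alpha Scaled recombination distance, see [sweep_alpha()].
#' @return A `sweep_partition_model` of kind `"starlike"`.
#' @export
starlike_model <- function(alpha) {
  if (length(alpha) != 1L || alpha < 0) stop("alpha must be a nonnegative scalar")
  structure(list(kind = "starlike", alpha = alpha,
                 Pe = escape_probability(alpha)),
            class = "sweep_partition_model")
}

#' @export
print.sweep_partition_model <- function(x, ...) {
  if (x$kind == "starlike") {
    cat(sprintf("sweep partition model: star-like (alpha=%.4g, Pe=%.4g)\n",
                x$alpha, x$Pe))
  } else {
    cat(sprintf("sweep partition model: marked Yule (alpha=%.4g, founders=%d, %d reps/size)\n",
                x$alpha, x$founders, x$reps))
    cat("  multi-family (more than one early-recombinant family) frequency at n=",
        x$n, ": ", signif(x$multi_family_freq, 3), "\n", sep = "")
  }
  invisible(x)
}

# Enumerate all set partitions of `blocks` whose group-size multiset matches
# `shape` (sizes of groups of original blocks). Groups of size >= 2 are
# merged into a single lineage; singleton groups stay as they are.
partitions_of_shape <- function(k, shape) {
  shape <- sort(shape, decreasing = TRUE)
  stopifnot(sum(shape) == k)
  rec <- function(idx, sizes) {
    if (length(sizes) == 0L) return(list(list()))
    s <- sizes[1L]
    rest_sizes <- sizes[-1L]
    out <- list()
    # first remaining element always goes in the current group to avoid
    # duplicate enumeration of equal-sized groups
    first <- idx[1L]
    others <- idx[-1L]
    chooseN <- if (s - 1L == 0L) list(integer(0)) else
      utils::combn(others, s - 1L, simplify = FALSE)
    for (cc in chooseN) {
      grp <- c(first, cc)
      remaining <- setdiff(idx, grp)
      for (sub in rec(remaining, rest_sizes)) {
        out[[length(out) + 1L]] <- c(list(grp), sub)
      }
    }
    out
  }
  rec(seq_len(k), shape)
}

apply_grouping <- function(blocks, grouping) {
  lapply(grouping, function(grp) unlist(blocks[grp], use.names = FALSE))
}

#' Partition outcomes of a sweep model applied to extant lineages
#'
#' Lists every labeled partition the sweep can induce on the given blocks of
#' lineages, with its probability. This is the interface through which a
#' partition model enters the generating-function recursion and the hybrid
#' simulator.
#'
#' @param model A `sweep_partition_model`.
#' @param blocks List of label sets (the extant lineages).
#' @return List of `list(prob=, blocks=)` entries; probabilities sum to 1.
#' @export
partition_outcomes <- function(model, blocks) {
  UseMethod("partition_outcomes")
}

#' @export
partition_outcomes.sweep_partition_model <- function(model, blocks) {
  k <- length(blocks)
  if (model$kind == "starlike") {
    pe <- model$Pe
    out <- list()
    for (m in 0:k) {
      p_subset <- pe^m * (1 - pe)^(k - m)   # probability of one labeled subset
      esc_sets <- utils::combn(k, m, simplify = FALSE)
      for (S in esc_sets) {
        rest <- setdiff(seq_len(k), S)
        nb <- c(blocks[S],
                if (length(rest)) list(unlist(blocks[rest], use.names = FALSE)))
        out[[length(out) + 1L]] <- list(prob = p_subset, blocks = nb)
      }
    }
    out
  } else {
    tab <- model$shapes[[as.character(k)]]
    if (is.null(tab)) stop("yule model has no table for subset size ", k)
    out <- list()
    for (i in seq_len(nrow(tab))) {
      shape <- as.integer(strsplit(tab$shape[i], "+", fixed = TRUE)[[1L]])
      groupings <- partitions_of_shape(k, shape)
      p_each <- tab$prob[i] / length(groupings)
      for (g in groupings) {
        out[[length(out) + 1L]] <- list(prob = p_each,
                                        blocks = apply_grouping(blocks, g))
      }
    }
    out
  }
}

## ---- marked-Yule sampler -----------------------------------------------

# Precompute, for m lines among j background lineages, cumulative
# log-survival against "two of our m lines merge" over the backward jump
# chain of the Yule tree with K founders. Mergers at the level-j boundary
# pick a uniform pair of the j lines, so the hazard is C(m,2)/C(j,2).
.yule_logsurv <- function(K, m) {
  j <- 2:K
  h <- choose(m, 2) / choose(j, 2)
  ls <- log1p(-pmin(h, 1))
  # position j-1 holds L[j] = sum_{i=j}^{K} log(1 - h_i); position K is L[K+1] = 0
  c(rev(cumsum(rev(ls))), 0)
}

# Duration (in units of 2Ne generations) spent going from just after the
# level-(a+1) boundary down to just after the level-j boundary: the sum of
# Exp(i*lambda) holding times for i = j..a, sampled in O(1) as an
# exponential order statistic via a single beta draw.
.yule_segment_time <- function(a, j, lambda) {
  if (j > a) return(0)
  k <- a - j + 1L
  -log1p(-stats::rbeta(1L, k, j)) / lambda
}

#' Monte-Carlo sampler of the marked-Yule sweep partition
#'
#' Simulates the instantaneous-Yule description of a hard sweep: the
#' beneficial allele's ancestry during the sweep is a pure-birth (Yule)
#' process with per-lineage split rate `2*Ne*s` (time in 2Ne generations),
#' stopped at `ceiling(4*Ne*s)` lineages; recombination marks fall on its
#' branches as a Poisson process with rate `2*Ne*r*d` per lineage. Tracing
#' `n` sampled lineages pastward through the marked tree partitions them
#' into late recombinant singletons (L), early-recombinant families (a
#' family that coalesced during the sweep and then recombined out), and the
#' nonrecombinant family (N), identical by descent to the sweep founder.
#'
#' The sampler never builds the full Yule tree: it draws the induced
#' genealogy of the sample through the backward jump chain (uniform pair
#' mergers with hazard `C(m,2)/C(j,2)` at the level-`j` boundary) and draws
#' segment durations as exponential order statistics, then scatters marks
#' along the induced branches.
#'
#' The instantaneous-Yule approximation asserts at most one early family;
#' replicates with two or more marked families of size >= 2 are recorded
#' as-is and their frequency reported as a diagnostic.
#'
#' @param n Number of sampled lineages.
#' @param params A [sweep_params()] object.
#' @param d Distance from the selected site in bases.
#' @param reps Number of Monte-Carlo replicates.
#' @param seed Optional RNG seed.
#' @return A data.frame with one row per observed partition type: columns
#'   `l` (late singletons), `e` (size of the first early family, 0 if none),
#'   `n0` (nonrecombinant family size), `extra` (members in additional
#'   marked families), `shape` (the induced block-size multiset, `+`
#'   separated), `count`, `prob`, `se`.
#' @export
yule_partition_sample <- function(n, params, d, reps = 10000L, seed = NULL) {
  stopifnot(inherits(params, "sweep_params"))
  if (!is.null(seed)) set.seed(seed)
  K <- as.integer(ceiling(4 * params$Ne * params$s))
  if (K < n) stop("fewer sweep founders (ceiling(4*Ne*s) = ", K,
                  ") than sampled lineages")
  lambda <- 2 * params$Ne * params$s        # split rate, 2Ne-generation units
  rho <- 2 * params$Ne * params$r * d       # mark rate per lineage
  Ltab <- lapply(2:max(2L, n), function(m) .yule_logsurv(K, m))

  draw_merge_level <- function(a, m) {
    # largest j <= a with L_m[j] <= L_m[a+1] + log(1-u); L is stored with
    # position j-1 holding L[j]. The merge is certain by level m (hazard 1).
    L <- Ltab[[m - 1L]]
    thr <- L[a] + log1p(-stats::runif(1L))
    i0 <- findInterval(thr, L[seq_len(a - 1L)])
    i0 + 1L
  }

  res <- new.env(parent = emptyenv())
  record <- function(key) {
    res[[key]] <- (res[[key]] %||% 0L) + 1L
  }

  for (rep in seq_len(reps)) {
    # --- induced genealogy of the n sample lines through the Yule tree ---
    # nodes: 1..n are leaves born at backward time 0 (level K);
    # internal nodes appended as mergers happen.
    births <- rep(0, n)            # backward time each line starts
    deaths <- rep(NA_real_, n)     # backward time each line merges away
    child1 <- integer(0); child2 <- integer(0)
    active <- seq_len(n)
    a <- K                          # current level (lines exist at level a)
    t <- 0
    while (length(active) > 1L) {
      m <- length(active)
      j <- draw_merge_level(a, m)
      # holding at level K is zero: the process stops at the K-th split
      t <- t + .yule_segment_time(min(a, K - 1L), j, lambda)
      pair <- sample(active, 2L)
      newid <- length(births) + 1L
      births[newid] <- t
      deaths[newid] <- NA_real_
      deaths[pair] <- t
      child1[newid - n] <- pair[1L]; child2[newid - n] <- pair[2L]
      active <- c(setdiff(active, pair), newid)
      a <- j - 1L
    }
    root <- active[1L]
    # close the root branch at the founder's origin (level-1 entry time)
    t_root <- t + .yule_segment_time(min(a, K - 1L), 2L, lambda)
    deaths[root] <- max(t_root, births[root])
    # --- marks: each line escapes if a Poisson(rho) mark falls on it ---
    nn <- length(births)
    durs <- deaths - births
    escapes <- if (rho > 0) stats::rexp(nn, rho) < durs else rep(FALSE, nn)
    # --- classify: propagate member sets leafward-to-rootward ---
    members <- vector("list", nn)
    for (i in seq_len(n)) members[[i]] <- i
    l_cnt <- 0L; fams <- integer(0); escaped <- rep(FALSE, nn)
    for (v in seq_len(nn)) {
      if (v > n) {
        ms <- c(if (!escaped[child1[v - n]]) members[[child1[v - n]]],
                if (!escaped[child2[v - n]]) members[[child2[v - n]]])
        members[[v]] <- if (is.null(ms)) integer(0) else ms
      }
      if (length(members[[v]]) == 0L) { escaped[v] <- TRUE; next }
      if (escapes[v]) {
        escaped[v] <- TRUE
        if (length(members[[v]]) == 1L) l_cnt <- l_cnt + 1L
        else fams <- c(fams, length(members[[v]]))
      }
    }
    n0 <- if (escaped[root]) 0L else length(members[[root]])
    e1 <- if (length(fams)) fams[1L] else 0L
    extra <- if (length(fams) > 1L) sum(fams[-1L]) else 0L
    shape <- sort(c(rep(1L, l_cnt), fams, if (n0 > 0L) n0))
    key <- paste(l_cnt, e1, n0, extra, paste(shape, collapse = "+"), sep = "|")
    record(key)
  }

  keys <- ls(res)
  counts <- vapply(keys, function(k) res[[k]], integer(1))
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  out <- data.frame(l = as.integer(parts[, 1L]), e = as.integer(parts[, 2L]),
                    n0 = as.integer(parts[, 3L]), extra = as.integer(parts[, 4L]),
                    shape = parts[, 5L], count = unname(counts),
                    stringsAsFactors = FALSE)
  out$prob <- out$count / reps
  out$se <- sqrt(out$prob * (1 - out$prob) / reps)
  out[order(-out$count), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Marked-Yule sweep partition model
#'
#' Builds empirical partition tables (via [yule_partition_sample()]) for
#' every subset size up to `n`, so the model can be plugged into the
#' generating-function recursion and the hybrid simulator exactly as the
#' star-like probabilities are.
#'
#' @param n Maximal subset size the model will be asked to partition.
#' @param params A [sweep_params()] object.
#' @param d Distance from the selected site in bases.
#' @param reps Monte-Carlo replicates per subset size.
#' @param seed Optional RNG seed.
#' @return A `sweep_partition_model` of kind `"yule"` with per-size shape
#'   tables, the full (l, e, n0) table at size `n`, and the multi-family
#'   diagnostic frequency.
#' @export
yule_model <- function(n, params, d, reps = 20000L, seed = NULL) {
  stopifnot(inherits(params, "sweep_params"))
  if (!is.null(seed)) set.seed(seed)
  shapes <- list()
  full_tab <- NULL
  mf <- 0
  for (k in 1:n) {
    if (k == 1L) {
      # a single lineage is trivially its own block whatever happens
      shapes[["1"]] <- data.frame(shape = "1", prob = 1)
      next
    }
    tab <- yule_partition_sample(k, params, d, reps = reps)
    agg <- stats::aggregate(tab$prob, by = list(shape = tab$shape), FUN = sum)
    names(agg)[2L] <- "prob"
    shapes[[as.character(k)]] <- agg
    if (k == n) {
      full_tab <- tab
      mf <- sum(tab$prob[tab$extra > 0L])
    }
  }
  structure(list(kind = "yule", n = n,
                 alpha = sweep_alpha(params$r, d, params$s, params$Ne),
                 founders = as.integer(ceiling(4 * params$Ne * params$s)),
                 reps = as.integer(reps), shapes = shapes, table = full_tab,
                 multi_family_freq = mf),
            class = "sweep_partition_model")
}
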