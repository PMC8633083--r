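# Recursive construction of the generating function for the branch-length
# distribution of a sample genealogy, with and without an embedded sweep.
#
# A sample is a set of disjoint, nonempty label sets (the partition Omega of
# the sampled lineages). Each extant lineage x carries a dummy variable
# omega_x named after the sampled individuals it is ancestral to, e.g.
# "w_b.c" for the branch ancestral to b and c.

#' Create a sample of labeled lineages
#'
#' @param n Number of sampled lineages (haploid samples), 1..6 for the full
#'   joint generating function.
#' @param labels Optional character labels; defaults to letters.
#' @return A list of single-element character vectors, one per lineage.
#' @export
lineage_sample <- function(n, labels = NULL) {
  if (length(n) != 1L || is.na(n) || n < 1L) stop("`n` must be a positive integer")
  if (is.null(labels)) {
    if (n > 26L) stop("supply explicit labels for n > 26")
    labels <- letters[seq_len(n)]
  }
  if (anyDuplicated(labels)) stop("lineage labels must be unique")
  lapply(labels, function(x) x)
}

branch_var <- function(block) paste0("w_", paste(sort(block), collapse = "."))

state_key <- function(blocks) {
  paste(sort(vapply(blocks, function(b) paste(sort(b), collapse = "."),
                    character(1))), collapse = "|")
}

check_sample <- function(sample) {
  if (!is.list(sample) || length(sample) < 1L)
    stop("sample must be a nonempty list of label sets")
  labs <- unlist(sample)
  if (anyDuplicated(labs)) stop("lineage labels must be disjoint across blocks")
  invisible(sample)
}

# omega coefficients of the extant lineages of a state: one per block.
state_w <- function(blocks) {
  vs <- vapply(blocks, branch_var, character(1))
  stats::setNames(rep(1, length(vs)), vs)
}

# Practical cap: the number of event histories grows super-exponentially.
MAX_FULL_GF_N <- 6L

#' Neutral generating function of a sample genealogy
#'
#' Builds, by recursion over all pairwise coalescence histories, the joint
#' Laplace transform of the lengths of every labeled branch that ever exists
#' in the genealogy of the sample under the neutral Kingman coalescent (time
#' in units of 2Ne generations). Each term carries one coalescence factor
#' per event; the recursion ends at a single lineage with value 1.
#'
#' @param sample A list of disjoint label sets, e.g. [lineage_sample()].
#' @return A [`gf_expr`] over variables `w_<labels>`.
#' @examples
#' phi <- neutral_gf(lineage_sample(2))
#' # the tmrca transform: substitute w_a + w_b -> w, giving 1/(1+w)
#' gf_eval(gf_subst_linear(phi, c("w_a", "w_b"), "w"), c(w = 0.5))
#' @export
neutral_gf <- function(sample) {
  check_sample(sample)
  if (length(unlist(sample)) > MAX_FULL_GF_N)
    stop("full joint GF is limited to samples of at most ", MAX_FULL_GF_N,
         " lineages; use the marginal-moments interface (expected_sfs) above that")
  memo <- new.env(parent = emptyenv())
  rec <- function(blocks) {
    k <- length(blocks)
    if (k == 1L) return(gf_one())
    key <- state_key(blocks)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    inner <- new_gf_expr()
    for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
      merged <- c(blocks[-c(i, j)], list(c(blocks[[i]], blocks[[j]])))
      inner <- gf_add(inner, rec(merged))
    }
    res <- gf_simplify(gf_mul_pole(inner, b = k * (k - 1) / 2, w = state_w(blocks)))
    memo[[key]] <- res
    res
  }
  rec(sample)
}

#' Generating function with an embedded sweep event
#'
#' Extends the neutral recursion by a competing exponential process with
#' rate `delta`: in every state, the next event is either a pairwise
#' coalescence or the sweep. When the sweep happens it instantaneously
#' partitions the extant lineages according to `model` (star-like or
#' marked-Yule) and the recursion continues neutrally, so `delta` never
#' appears after the sweep term (the sweep occurs at most once) and each
#' term has at most n factors.
#'
#' @param sample A list of disjoint label sets.
#' @param model A sweep partition model, see [starlike_model()] and
#'   [yule_model()].
#' @return A [`gf_expr`] over the `w_*` variables and `delta`.
#' @export
gf_with_sweep <- function(sample, model) {
  check_sample(sample)
  if (!inherits(model, "sweep_partition_model"))
    stop("`model` must be a sweep_partition_model")
  if (length(unlist(sample)) > MAX_FULL_GF_N)
    stop("full joint GF is limited to samples of at most ", MAX_FULL_GF_N, " lineages")
  nmemo <- new.env(parent = emptyenv())
  smemo <- new.env(parent = emptyenv())
  neut <- function(blocks) {
    k <- length(blocks)
    if (k == 1L) return(gf_one())
    key <- state_key(blocks)
    hit <- nmemo[[key]]
    if (!is.null(hit)) return(hit)
    inner <- new_gf_expr()
    for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
      inner <- gf_add(inner, neut(c(blocks[-c(i, j)], list(c(blocks[[i]], blocks[[j]])))))
    }
    res <- gf_simplify(gf_mul_pole(inner, b = k * (k - 1) / 2, w = state_w(blocks)))
    nmemo[[key]] <- res
    res
  }
  swept <- function(blocks) {
    # Phi*: instantaneous partition, then neutral continuation. No delta.
    outs <- partition_outcomes(model, blocks)
    pr <- vapply(outs, function(o) o$prob, numeric(1))
    if (abs(sum(pr) - 1) > 1e-8)
      stop("partition probabilities do not sum to 1 (model validation failed)")
    acc <- new_gf_expr()
    for (o in outs) {
      if (o$prob == 0) next
      acc <- gf_add(acc, gf_scale(neut(o$blocks), o$prob))
    }
    gf_simplify(acc)
  }
  rec <- function(blocks) {
    k <- length(blocks)
    if (k == 1L) return(gf_one())
    key <- state_key(blocks)
    hit <- smemo[[key]]
    if (!is.null(hit)) return(hit)
    inner <- gf_mul_delta(swept(blocks))
    for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
      inner <- gf_add(inner, rec(c(blocks[-c(i, j)], list(c(blocks[[i]], blocks[[j]])))))
    }
    res <- gf_simplify(gf_mul_pole(inner, b = k * (k - 1) / 2, d = 1L,
                                   w = state_w(blocks)))
    smemo[[key]] <- res
    res
  }
  rec(sample)
}

#' Replace the exponential sweep rate by a discrete sweep time
#'
#' Thin, intention-revealing wrapper around [gf_invert_delta()]: takes the
#' generating function of the competing-exponential embedding and returns
#' the one conditioned on the sweep completing exactly `Ta` time units
#' before sampling (the result is symbolic in `Ta`; supply a value at
#' evaluation time).
#'
#' @param gf A [`gf_expr`] containing `delta` (from [gf_with_sweep()]).
#' @return A [`gf_expr`] in the omega variables and `Ta`.
#' @export
invert_sweep_time <- function(gf) gf_invert_delta(gf)

#' Collapse labeled branch variables to i-Ton classes
#'
#' Branches are distinguished only by their number of descendants among the
#' sample: every `w_<labels>` with `i` labels is merged into `wi` (e.g.
#' `w_a.c` -> `w2`). The class variable then transforms the *total* length
#' of all branches of that class.
#'
#' @param gf A [`gf_expr`] in fully labeled variables.
#' @param n Sample size (to validate the i-Ton range).
#' @return A [`gf_expr`] over `w1 ... w<n-1>`.
#' @export
collapse_to_iton <- function(gf, n) {
  vs <- gf_vars(gf)
  vs <- vs[startsWith(vs, "w_")]
  sz <- vapply(strsplit(sub("^w_", "", vs), ".", fixed = TRUE), length, integer(1))
  if (any(sz >= n)) stop("found a branch subtending the whole sample; not an i-Ton")
  map <- stats::setNames(paste0("w", sz), vs)
  gf_rename(gf, map)
}

iton_vars <- function(n) paste0("w", seq_len(n - 1L))
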