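# Internal coalescent simulators.
#
# (a) hybrid Kingman + instantaneous-partition sweep: an exact sampler of
#     the analytic model (the testing oracle and synthetic-data generator);
# (b) a vectorised n = 4 star-like batch sampler for large block
#     simulations (cross-checked against (a) in the tests);
# (c) a structured coalescent along the beneficial-allele frequency
#     trajectory (the "full model" reference).

#' Simulate one genealogy under the hybrid sweep model
#'
#' Kingman coalescent on `[0, Ta)`, instantaneous partition of the extant
#' lineages at `Ta` according to `model` (non-escapees merge in a single
#' event), Kingman afterwards. This samples exactly from the model the
#' generating function describes.
#'
#' @param n Sample size.
#' @param Ta Time since fixation (2Ne generations).
#' @param model A `sweep_partition_model`, or `NULL` for the neutral
#'   coalescent.
#' @param seed Optional RNG seed.
#' @return A `genealogy` object: `t_i` (total i-Ton branch lengths),
#'   `tmrca`, and `edges` (descendant set, descendant count, birth and
#'   death time of every branch).
#' @export
simulate_hybrid_genealogy <- function(n, Ta = 0, model = NULL, seed = NULL) {
  if (n < 2) stop("n must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  blocks <- lapply(seq_len(n), function(i) i)   # descendant index sets
  births <- rep(0, n)
  t <- 0
  swept <- is.null(model)
  edges <- list()
  close_edge <- function(desc, birth, death) {
    edges[[length(edges) + 1L]] <<- list(desc = desc, birth = birth, death = death)
  }
  repeat {
    k <- length(blocks)
    if (k == 1L) break
    tau <- stats::rexp(1L, k * (k - 1) / 2)
    if (!swept && t + tau > Ta) {
      t <- Ta
      swept <- TRUE
      grp <- draw_partition(model, k)
      keep <- vapply(grp, length, integer(1)) == 1L
      new_blocks <- list(); new_births <- numeric(0)
      for (gi in seq_along(grp)) {
        ids <- grp[[gi]]
        if (length(ids) == 1L) {
          new_blocks <- c(new_blocks, blocks[ids])
          new_births <- c(new_births, births[ids])
        } else {
          for (id in ids) close_edge(blocks[[id]], births[id], t)
          new_blocks <- c(new_blocks, list(sort(unlist(blocks[ids]))))
          new_births <- c(new_births, t)
        }
      }
      blocks <- new_blocks; births <- new_births
      next
    }
    t <- t + tau
    pair <- sample.int(k, 2L)
    close_edge(blocks[[pair[1L]]], births[pair[1L]], t)
    close_edge(blocks[[pair[2L]]], births[pair[2L]], t)
    blocks <- c(blocks[-pair], list(sort(unlist(blocks[pair]))))
    births <- c(births[-pair], t)
  }
  ti <- numeric(n - 1L)
  for (e in edges) {
    cnt <- length(e$desc)
    if (cnt < n) ti[cnt] <- ti[cnt] + (e$death - e$birth)
  }
  structure(list(n = n, t_i = ti, tmrca = t, edges = edges,
                 Ta = if (is.null(model)) NA_real_ else Ta,
                 model = if (is.null(model)) "neutral" else model$kind),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("<genealogy> n=%d, tmrca=%.4f, t_i = %s (%s model)\n", x$n,
              x$tmrca, paste(signif(x$t_i, 4), collapse = ", "), x$model))
  invisible(x)
}

# Draw one labeled partition (a grouping of 1..k) from a partition model.
draw_partition <- function(model, k) {
  if (model$kind == "starlike") {
    esc <- stats::runif(k) < model$Pe
    grp <- c(lapply(which(esc), identity),
             if (any(!esc)) list(which(!esc)))
    return(grp)
  }
  tab <- model$shapes[[as.character(k)]]
  if (is.null(tab)) stop("yule model has no table for subset size ", k)
  shape <- as.integer(strsplit(
    sample(tab$shape, 1L, prob = tab$prob), "+", fixed = TRUE)[[1L]])
  perm <- sample.int(k)
  grp <- list(); off <- 0L
  for (s in shape) {
    grp[[length(grp) + 1L]] <- sort(perm[(off + 1L):(off + s)])
    off <- off + s
  }
  grp
}

#' Topology class of a four-lineage genealogy
#'
#' `"asym"` if a branch with three descendants ever existed, `"star"` if
#' neither a doubleton nor a tripleton branch ever existed (single four-way
#' merger), `"sym"` otherwise.
#'
#' @param gen A `genealogy` with `n = 4`.
#' @return One of `"sym"`, `"asym"`, `"star"`.
#' @export
classify_topology_n4 <- function(gen) {
  stopifnot(inherits(gen, "genealogy"), gen$n == 4L)
  cnts <- vapply(gen$edges, function(e) length(e$desc), integer(1))
  if (any(cnts == 3L)) return("asym")
  if (any(cnts == 2L)) return("sym")
  "star"
}

## ---- vectorised batch samplers ----------------------------------------

#' Batch-simulate pairwise coalescence times under the hybrid model
#'
#' @param reps Number of replicates.
#' @param pe Escape probability per lineage (scalar or length `reps`).
#' @param Ta Sweep time.
#' @return Numeric vector of `tmrca` values.
#' @keywords internal
sim_tmrca_n2_batch <- function(reps, pe, Ta) {
  tau <- stats::rexp(reps)
  pre <- tau < Ta
  out <- numeric(reps)
  out[pre] <- tau[pre]
  late <- !pre
  nl <- sum(late)
  if (nl) {
    pe2 <- if (length(pe) == 1L) rep(pe, nl) else pe[late]
    merged <- stats::runif(nl) < (1 - pe2)^2
    extra <- ifelse(merged, 0, stats::rexp(nl))
    out[late] <- Ta + extra
  }
  out
}

# Vectorised i-Ton lengths, tmrca and topology class for n = 4 under the
# star-like model. `pe` may vary across replicates (one block each).
# Case analysis over the level at which the sweep interrupts the Kingman
# coalescent; cross-checked against simulate_hybrid_genealogy in the tests.
sim_iton_n4_batch <- function(reps, pe, Ta) {
  if (length(pe) == 1L) pe <- rep(pe, reps)
  t1 <- numeric(reps); t2 <- numeric(reps); t3 <- numeric(reps)
  topo <- character(reps)
  done <- rep(FALSE, reps)       # reached MRCA
  tm <- numeric(reps)            # tmrca accumulator

  tau4 <- stats::rexp(reps, 6)
  tau3 <- stats::rexp(reps, 3)
  tau2 <- stats::rexp(reps, 1)
  sym0 <- stats::runif(reps) < 1 / 3      # level-2 state {2,2} vs {3,1}

  lvl <- ifelse(tau4 > Ta, 4L,
         ifelse(tau4 + tau3 > Ta, 3L,
         ifelse(tau4 + tau3 + tau2 > Ta, 2L, 0L)))

  ## sweep never interrupts (coalesced before Ta)
  i <- which(lvl == 0L)
  if (length(i)) {
    t1[i] <- 4 * tau4[i] + 2 * tau3[i] + ifelse(sym0[i], 0, tau2[i])
    t2[i] <- tau3[i] + ifelse(sym0[i], 2, 0) * tau2[i]
    t3[i] <- ifelse(sym0[i], 0, tau2[i])
    tm[i] <- tau4[i] + tau3[i] + tau2[i]
    topo[i] <- ifelse(sym0[i], "sym", "asym")
    done[i] <- TRUE
  }

  ## helper: continue neutrally from a {2,1,1} state (3 lineages)
  cont_211 <- function(idx) {
    a3 <- stats::rexp(length(idx), 3)
    a2 <- stats::rexp(length(idx), 1)
    pair_singles <- stats::runif(length(idx)) < 1 / 3
    t1[idx] <<- t1[idx] + 2 * a3
    t2[idx] <<- t2[idx] + a3 + ifelse(pair_singles, 2, 0) * a2
    t1[idx] <<- t1[idx] + ifelse(pair_singles, 0, a2)
    t3[idx] <<- t3[idx] + ifelse(pair_singles, 0, a2)
    tm[idx] <<- tm[idx] + a3 + a2
    topo[idx] <<- ifelse(pair_singles, "sym", "asym")
  }

  ## sweep at level 2 (two lineages left, state sym {2,2} or asym {3,1})
  i <- which(lvl == 2L & !done)
  if (length(i)) {
    dt <- Ta - tau4[i] - tau3[i]
    t1[i] <- 4 * tau4[i] + 2 * tau3[i] + ifelse(sym0[i], 0, dt)
    t2[i] <- tau3[i] + ifelse(sym0[i], 2, 0) * dt
    t3[i] <- ifelse(sym0[i], 0, dt)
    topo[i] <- ifelse(sym0[i], "sym", "asym")
    m0 <- stats::runif(length(i)) < (1 - pe[i])^2      # both fail to escape
    extra <- ifelse(m0, 0, stats::rexp(length(i)))
    t1[i] <- t1[i] + ifelse(sym0[i], 0, extra)
    t2[i] <- t2[i] + ifelse(sym0[i], 2, 0) * extra
    t3[i] <- t3[i] + ifelse(sym0[i], 0, extra)
    tm[i] <- Ta + extra
    done[i] <- TRUE
  }

  ## sweep at level 3 (state {2,1,1}: doubleton D and singles A, B)
  i <- which(lvl == 3L & !done)
  if (length(i)) {
    dt <- Ta - tau4[i]
    t1[i] <- 4 * tau4[i] + 2 * dt
    t2[i] <- dt
    tm[i] <- Ta
    eD <- stats::runif(length(i)) < pe[i]
    eA <- stats::runif(length(i)) < pe[i]
    eB <- stats::runif(length(i)) < pe[i]
    q <- (!eD) + (!eA) + (!eB)
    # q = 3: trifurcating merger of {2,1,1}: done at Ta; doubleton existed
    j <- i[q == 3L]; topo[j] <- "sym"; done[j] <- TRUE
    # q = 2: the two non-escapees merge, then one more coalescence
    j2 <- q == 2L
    if (any(j2)) {
      jj <- i[j2]
      ab_merge <- (!eA & !eB)[j2]            # A,B merge -> {2,2}; else {3,1}
      extra <- stats::rexp(length(jj))
      t1[jj] <- t1[jj] + ifelse(ab_merge, 0, extra)
      t2[jj] <- t2[jj] + ifelse(ab_merge, 2, 0) * extra
      t3[jj] <- t3[jj] + ifelse(ab_merge, 0, extra)
      tm[jj] <- tm[jj] + extra
      topo[jj] <- ifelse(ab_merge, "sym", "asym")
      done[jj] <- TRUE
    }
    # q <= 1: no merger; continue neutrally from {2,1,1}
    j3 <- i[q <= 1L]
    if (length(j3)) { cont_211(j3); done[j3] <- TRUE }
  }

  ## sweep at level 4 (four singleton lineages)
  i <- which(lvl == 4L & !done)
  if (length(i)) {
    t1[i] <- 4 * Ta
    tm[i] <- Ta
    m <- stats::rbinom(length(i), 4L, pe[i])
    q <- 4L - m
    # q = 4: single four-way merger: the star genealogy
    j <- i[q == 4L]; topo[j] <- "star"; done[j] <- TRUE
    # q = 3: three merge into a tripleton, plus the escapee
    j <- i[q == 3L]
    if (length(j)) {
      extra <- stats::rexp(length(j))
      t1[j] <- t1[j] + extra; t3[j] <- t3[j] + extra
      tm[j] <- tm[j] + extra
      topo[j] <- "asym"; done[j] <- TRUE
    }
    # q = 2: two merge -> state {2,1,1}
    j <- i[q == 2L]
    if (length(j)) { cont_211(j); done[j] <- TRUE }
    # q <= 1: no merger: full neutral Kingman from four lineages
    j <- i[q <= 1L]
    if (length(j)) {
      a4 <- stats::rexp(length(j), 6)
      a3 <- stats::rexp(length(j), 3)
      a2 <- stats::rexp(length(j), 1)
      sy <- stats::runif(length(j)) < 1 / 3
      t1[j] <- t1[j] + 4 * a4 + 2 * a3 + ifelse(sy, 0, a2)
      t2[j] <- t2[j] + a3 + ifelse(sy, 2, 0) * a2
      t3[j] <- t3[j] + ifelse(sy, 0, a2)
      tm[j] <- tm[j] + a4 + a3 + a2
      topo[j] <- ifelse(sy, "sym", "asym")
      done[j] <- TRUE
    }
  }
  list(t = cbind(t1 = t1, t2 = t2, t3 = t3), tmrca = tm, topo = topo)
}

#' Batch-simulate i-Ton branch lengths under the hybrid model
#'
#' Fast exact sampler of the analytic model for many replicates at once.
#' `n = 2` and `n = 4` with a star-like model use vectorised case analysis;
#' other settings fall back to the generic per-replicate simulator.
#'
#' @param n Sample size.
#' @param reps Number of replicates.
#' @param Ta Sweep time.
#' @param model `sweep_partition_model` or `NULL` (neutral).
#' @param seed Optional RNG seed.
#' @return List with matrix `t` (`reps` x `n-1`), vector `tmrca`, and (for
#'   `n = 4`) the topology class per replicate.
#' @export
simulate_iton_batch <- function(n, reps, Ta = 0, model = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pe <- if (is.null(model)) 1 else if (model$kind == "starlike") model$Pe else NA
  if (n == 2L && !is.na(pe)) {
    tm <- sim_tmrca_n2_batch(reps, pe, if (is.null(model)) 0 else Ta)
    return(list(t = cbind(t1 = 2 * tm), tmrca = tm, topo = NULL))
  }
  if (n == 4L && !is.na(pe)) {
    return(sim_iton_n4_batch(reps, pe, if (is.null(model)) 0 else Ta))
  }
  t <- matrix(0, reps, n - 1L)
  tm <- numeric(reps)
  topo <- if (n == 4L) character(reps) else NULL
  for (r in seq_len(reps)) {
    g <- simulate_hybrid_genealogy(n, Ta = Ta, model = model)
    t[r, ] <- g$t_i
    tm[r] <- g$tmrca
    if (n == 4L) topo[r] <- classify_topology_n4(g)
  }
  colnames(t) <- paste0("t", seq_len(n - 1L))
  list(t = t, tmrca = tm, topo = topo)
}

## ---- blockwise replicate datasets --------------------------------------

#' Block geometry around a sweep target
#'
#' `B` non-overlapping blocks of `l` bases, split evenly left and right of
#' the anchor; the i-th block on each side has midpoint distance
#' `d_i = i*l - l/2`.
#'
#' @param B Total number of blocks (even).
#' @param l Block length in bases.
#' @return A `block_geometry` data.frame with columns `block`, `side`, `d`.
#' @export
block_geometry <- function(B, l) {
  if (B %% 2L != 0L) stop("B must be even (blocks split left/right)")
  if (l < 1) stop("block length must be at least 1")
  i <- seq_len(B / 2L)
  out <- rbind(data.frame(block = i, side = "right", d = i * l - l / 2),
               data.frame(block = i, side = "left", d = i * l - l / 2))
  attr(out, "l") <- l
  attr(out, "B") <- as.integer(B)
  class(out) <- c("block_geometry", "data.frame")
  out
}

#' Simulate a blockwise replicate dataset
#'
#' Draws an independent genealogy for every block at that block's scaled
#' distance from the sweep target, drops mutations on each i-Ton class at
#' rate `theta/2` per unit branch length, and bins counts at `k_max`
#' (capped counts are recorded as `k_max + 1`). In neutral mode the sweep
#' is ignored.
#'
#' @param params A [sweep_params()].
#' @param geometry A [block_geometry()].
#' @param n Sample size (4 for the vectorised path).
#' @param mut A [mutation_model()].
#' @param mode `"sweep"` or `"neutral"`.
#' @param seed Optional RNG seed.
#' @return A `replicate_dataset`: data.frame with per-block `d`, `alpha`
#'   and capped counts `k1..k{n-1}`, with parameters in attributes.
#' @export
simulate_blocks <- function(params, geometry, n = 4L, mut, mode = c("sweep", "neutral"),
                            seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "sweep_params"), inherits(mut, "mutation_model"))
  if (!is.null(seed)) set.seed(seed)
  B <- nrow(geometry)
  alpha <- sweep_alpha(params$r, geometry$d, params$s, params$Ne)
  if (mode == "neutral") {
    sims <- simulate_iton_batch(n, B, Ta = 0, model = NULL)
  } else if (n %in% c(2L, 4L)) {
    pe <- escape_probability(alpha)
    sims <- if (n == 4L) sim_iton_n4_batch(B, pe, params$Ta) else
      list(t = cbind(t1 = 2 * sim_tmrca_n2_batch(B, pe, params$Ta)))
  } else {
    t <- matrix(0, B, n - 1L)
    for (b in seq_len(B)) {
      g <- simulate_hybrid_genealogy(n, Ta = params$Ta,
                                     model = starlike_model(alpha[b]))
      t[b, ] <- g$t_i
    }
    sims <- list(t = t)
  }
  counts <- matrix(stats::rpois(B * (n - 1L), mut$theta / 2 * sims$t),
                   nrow = B)
  counts <- pmin(counts, mut$k_max + 1L)
  out <- data.frame(geometry, alpha = alpha)
  for (i in seq_len(n - 1L)) out[[paste0("k", i)]] <- counts[, i]
  attr(out, "params") <- params
  attr(out, "mut") <- mut
  attr(out, "mode") <- mode
  attr(out, "n") <- as.integer(n)
  class(out) <- c("replicate_dataset", "data.frame")
  out
}

## ---- structured coalescent along a frequency trajectory ----------------

#' Deterministic logistic sweep trajectory
#'
#' The beneficial-allele frequency path used by the full-model simulator: a
#' logistic curve with effective starting frequency `1/(1 + 2*Ne*s)` (the
#' standard deterministic stand-in for a trajectory conditioned on
#' fixation: the conditioned stochastic early phase is faster than the
#' unconditioned logistic, which an inflated starting frequency mimics).
#' Its natural duration between the effective boundaries is exactly
#' `t_fix = 2*log(2*Ne*s)/s` generations, and by symmetry
#' `integral (1-X) dt = t_fix/2`, reproducing the per-lineage escape
#' probability `1 - exp(-alpha)` with `alpha = r*d*t_fix/2`. The grid ends
#' are clamped to 1 (fixation) and `1/(2*Ne)` (the founder copy).
#'
#' @param params A [sweep_params()].
#' @param step Grid step in generations.
#' @return data.frame with `tau` (generations pastward from fixation) and
#'   `X` (allele frequency, monotone nonincreasing pastward).
#' @export
sweep_trajectory <- function(params, step = 1) {
  stopifnot(inherits(params, "sweep_params"))
  Ne <- params$Ne; s <- params$s
  x0 <- 1 / (1 + 2 * Ne * s)
  tfix <- params$t_fix
  tau <- seq(0, tfix, by = step)           # pastward from fixation
  u <- tfix - tau                          # forward time since origin
  X <- 1 / (1 + ((1 - x0) / x0) * exp(-s * u))
  X[1L] <- 1
  X[length(X)] <- 1 / (2 * Ne)
  data.frame(tau = tau, X = X)
}

#' Structured coalescent for a pair of lineages along the sweep trajectory
#'
#' Full-model reference for `n = 2`: neutral coalescence between sampling
#' and `Ta`; during the sweep (pastward from `Ta`), lineages on the
#' beneficial background coalesce pairwise at rate `1/(2*Ne*X)` per
#' generation and recombine onto the ancestral background with probability
#' `r*d*(1-X)` per generation; escaped lineages coalesce at rate
#' `1/(2*Ne*(1-X))` with each other while the sweep segregates; any
#' lineages still on the beneficial background at the sweep's origin
#' coalesce there; the remainder coalesce neutrally before the sweep.
#'
#' @param reps Number of replicates.
#' @param params A [sweep_params()].
#' @param d Distance from the selected site (bases).
#' @param seed Optional RNG seed.
#' @param trajectory Optional trajectory data.frame ([sweep_trajectory()]).
#' @return data.frame per replicate: `tmrca` (2Ne generations) and `phase`
#'   (`"pre"` neutral before `Ta`, `"sweep"`, `"post"` deeper than the
#'   sweep origin).
#' @export
simulate_pair_trajectory <- function(reps, params, d, seed = NULL,
                                     trajectory = NULL) {
  stopifnot(inherits(params, "sweep_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(trajectory)) trajectory <- sweep_trajectory(params)
  Ne <- params$Ne; Ta <- params$Ta
  rd <- params$r * d
  X <- trajectory$X
  nstep <- length(X)
  tmrca <- numeric(reps)
  phase <- character(reps)
  # neutral phase between sampling and the sweep
  tau0 <- stats::rexp(reps)
  pre <- tau0 < Ta
  tmrca[pre] <- tau0[pre]
  phase[pre] <- "pre"
  act <- which(!pre)
  # states during the sweep: 2 = both beneficial, 1 = one escaped, 0 = both
  state <- rep(2L, length(act))
  ctime <- rep(NA_real_, length(act))      # coalescence time (generations past Ta)
  for (g in seq_len(nstep)) {
    x <- X[g]
    alive <- which(is.na(ctime))
    if (!length(alive)) break
    st <- state[alive]
    u <- stats::runif(length(alive))
    # both-beneficial: coalesce, else each may escape
    i2 <- alive[st == 2L]
    if (length(i2)) {
      pc <- min(1, 1 / (2 * Ne * x))
      co <- stats::runif(length(i2)) < pc
      ctime[i2[co]] <- g
      rest <- i2[!co]
      if (length(rest)) {
        nesc <- stats::rbinom(length(rest), 2L, min(1, rd * (1 - x)))
        state[rest] <- 2L - nesc
      }
    }
    # both escaped: coalesce on the ancestral background
    i0 <- alive[st == 0L]
    if (length(i0) && x < 1) {
      pc <- min(1, 1 / (2 * Ne * (1 - x)))
      co <- stats::runif(length(i0)) < pc
      ctime[i0[co]] <- -g                  # negative marks neutral-background
    }
    # one escaped: the beneficial one may still recombine out
    i1 <- alive[st == 1L]
    if (length(i1)) {
      esc <- stats::runif(length(i1)) < min(1, rd * (1 - x))
      state[i1[esc]] <- 0L
    }
  }
  twoNe <- 2 * Ne
  background <- rep(NA_character_, reps)
  for (z in seq_along(act)) {
    r <- act[z]
    if (!is.na(ctime[z])) {
      tmrca[r] <- Ta + abs(ctime[z]) / twoNe
      phase[r] <- "sweep"
      background[r] <- if (ctime[z] > 0) "beneficial" else "ancestral"
    } else if (state[z] == 2L) {
      # both still beneficial at the origin: coalesce in the founder
      tmrca[r] <- Ta + params$t_fix / twoNe
      phase[r] <- "sweep"
      background[r] <- "beneficial"
    } else {
      tmrca[r] <- Ta + params$t_fix / twoNe + stats::rexp(1L)
      phase[r] <- "post"
    }
  }
  data.frame(tmrca = tmrca, phase = phase, background = background,
             stringsAsFactors = FALSE)
}
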