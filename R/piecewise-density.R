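# Piecewise sum-of-exponentials densities with explicit point masses.
#
# Branch-length distributions near a sweep are continuous mixtures of
# (shifted) exponential pieces plus probability atoms created by the
# instantaneous burst of coalescence. Point masses are represented
# explicitly and never smeared into the density; they show up in the CDF.

#' Construct a piecewise-exponential density
#'
#' The density on the interval `[breaks[i], breaks[i+1])` (the last interval
#' extends to infinity) is `sum_r coef_r * t^pow_r * exp(-rate_r * t)`;
#' atoms are listed separately.
#'
#' @param breaks Increasing vector of interval endpoints, starting at 0.
#' @param pieces List (one per interval) of data.frames with columns
#'   `coef`, `rate`, `pow`.
#' @param masses data.frame with columns `loc`, `mass` (possibly 0 rows).
#' @param validate Check nonnegativity on a grid and total probability 1.
#' @return An object of class `pwe_density`.
#' @export
pwe_density <- function(breaks, pieces, masses = NULL, validate = TRUE) {
  if (breaks[1L] != 0 || is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing and start at 0")
  if (length(pieces) != length(breaks))
    stop("need one piece per interval (last interval extends to Inf)")
  if (is.null(masses)) masses <- data.frame(loc = numeric(0), mass = numeric(0))
  obj <- structure(list(breaks = breaks, pieces = pieces, masses = masses),
                   class = "pwe_density")
  if (validate) pwe_validate(obj)
  obj
}

# integral of t^p * exp(-a t) over [l, u], u possibly Inf. Growing modes
# (a < 0) are allowed on finite intervals only: they arise legitimately on
# interior pieces of sweep branch-length densities.
.int_texp <- function(coef, rate, pow, l, u) {
  if (coef == 0) return(0)
  if (rate > 0) {
    Fu <- if (is.infinite(u)) 1 else stats::pgamma(u, pow + 1, rate = rate)
    Fl <- stats::pgamma(l, pow + 1, rate = rate)
    coef * factorial(pow) / rate^(pow + 1) * (Fu - Fl)
  } else {
    if (is.infinite(u)) stop("non-integrable exponential tail in density")
    if (rate == 0) return(coef * (u^(pow + 1) - l^(pow + 1)) / (pow + 1))
    # antiderivative of t^p e^{b t} with b = -rate > 0
    b <- -rate
    anti <- function(t) {
      jj <- 0:pow
      exp(b * t) * sum((-1)^jj * factorial(pow) / factorial(pow - jj) *
                         t^(pow - jj) / b^(jj + 1))
    }
    coef * (anti(u) - anti(l))
  }
}

pwe_piece_integral <- function(piece, l, u) {
  if (nrow(piece) == 0L) return(0)
  sum(vapply(seq_len(nrow(piece)), function(r)
    .int_texp(piece$coef[r], piece$rate[r], piece$pow[r], l, u), numeric(1)))
}

#' @rdname pwe_density
#' @param obj A `pwe_density`.
#' @param t Evaluation points.
#' @export
pwe_pdf <- function(obj, t) {
  idx <- findInterval(t, obj$breaks)
  out <- numeric(length(t))
  for (i in seq_along(t)) {
    if (idx[i] == 0L || t[i] < 0) next
    pc <- obj$pieces[[idx[i]]]
    if (nrow(pc)) out[i] <- sum(pc$coef * t[i]^pc$pow * exp(-pc$rate * t[i]))
  }
  out
}

# vectorised integral of coef * t^pow * exp(-rate t) from l to each u
.int_texp_vec <- function(coef, rate, pow, l, u) {
  if (coef == 0) return(numeric(length(u)))
  if (rate > 0) {
    Fu <- ifelse(is.infinite(u), 1, stats::pgamma(u, pow + 1, rate = rate))
    Fl <- stats::pgamma(l, pow + 1, rate = rate)
    coef * factorial(pow) / rate^(pow + 1) * (Fu - Fl)
  } else if (rate == 0) {
    coef * (u^(pow + 1) - l^(pow + 1)) / (pow + 1)
  } else {
    b <- -rate
    jj <- 0:pow
    anti <- function(x) {
      acc <- 0
      for (j in jj) acc <- acc + (-1)^j * factorial(pow) / factorial(pow - j) *
          x^(pow - j) / b^(j + 1)
      exp(b * x) * acc
    }
    coef * (anti(u) - anti(l))
  }
}

#' @rdname pwe_density
#' @export
pwe_cdf <- function(obj, t) {
  nb <- length(obj$breaks)
  # cumulative integral up to the start of each interval
  cum <- numeric(nb)
  for (j in seq_len(nb - 1L)) {
    cum[j + 1L] <- cum[j] +
      pwe_piece_integral(obj$pieces[[j]], obj$breaks[j], obj$breaks[j + 1L])
  }
  out <- numeric(length(t))
  idx <- findInterval(t, obj$breaks)
  ok <- t >= 0
  out[ok] <- cum[idx[ok]]
  for (j in unique(idx[ok])) {
    sel <- ok & idx == j
    pc <- obj$pieces[[j]]
    if (nrow(pc) == 0L) next
    part <- numeric(sum(sel))
    for (r in seq_len(nrow(pc))) {
      part <- part + .int_texp_vec(pc$coef[r], pc$rate[r], pc$pow[r],
                                   obj$breaks[j], t[sel])
    }
    out[sel] <- out[sel] + part
  }
  if (nrow(obj$masses)) {
    for (z in seq_len(nrow(obj$masses))) {
      out <- out + obj$masses$mass[z] * (t >= obj$masses$loc[z] & ok)
    }
  }
  out
}

#' @rdname pwe_density
#' @export
pwe_total_mass <- function(obj) {
  nb <- length(obj$breaks)
  acc <- sum(obj$masses$mass)
  for (j in seq_len(nb)) {
    u <- if (j < nb) obj$breaks[j + 1L] else Inf
    acc <- acc + pwe_piece_integral(obj$pieces[[j]], obj$breaks[j], u)
  }
  acc
}

#' Discontinuity locations of the density
#'
#' A location counts as a discontinuity if the analytic form of the density
#' changes there (the defining pieces of the mixture switch on or off,
#' whether or not the left and right limits happen to coincide) or if a
#' point mass sits there. This matches how removable discontinuities of the
#' piecewise closed forms are counted: the singleton density of a sample of
#' n has n-1 of them, at multiples of the sweep time.
#'
#' @param obj A `pwe_density`.
#' @param tol Relative tolerance for comparing the pieces.
#' @return Sorted numeric vector of locations.
#' @export
pwe_discontinuities <- function(obj, tol = 1e-7) {
  locs <- numeric(0)
  form_eval <- function(piece, t) {
    if (nrow(piece) == 0L) return(numeric(length(t)))
    vapply(t, function(tt)
      sum(piece$coef * tt^piece$pow * exp(-piece$rate * tt)), numeric(1))
  }
  scale <- max(1e-12, abs(pwe_pdf(obj, seq(0, max(obj$breaks) + 1, length.out = 64))))
  if (length(obj$breaks) > 1L) {
    for (bi in 2:length(obj$breaks)) {
      b <- obj$breaks[bi]
      probe <- b + c(0.05, 0.3, 0.8)
      if (max(abs(form_eval(obj$pieces[[bi]], probe) -
                  form_eval(obj$pieces[[bi - 1L]], probe))) > tol * scale)
        locs <- c(locs, b)
    }
  }
  if (nrow(obj$masses)) locs <- c(locs, obj$masses$loc[obj$masses$mass > tol])
  sort(unique(round(locs, 9)))
}

pwe_validate <- function(obj, tol_total = 1e-8, tol_neg = 1e-8) {
  if (nrow(obj$masses) && (any(obj$masses$mass < -1e-12) || any(obj$masses$mass > 1 + 1e-12)))
    stop("point masses must lie in [0, 1]")
  tot <- pwe_total_mass(obj)
  if (abs(tot - 1) > tol_total)
    stop(sprintf("density + masses integrate to %.10f, not 1", tot))
  hi <- max(obj$breaks) * 1.5 + 8
  grid <- seq(0, hi, length.out = 10000L)
  dens <- pwe_pdf(obj, grid)
  if (min(dens) < -tol_neg * max(abs(dens), 1))
    stop("density is negative on the evaluation grid")
  invisible(obj)
}

#' @export
print.pwe_density <- function(x, ...) {
  cat("<pwe_density> intervals:", paste(signif(x$breaks, 4), collapse = ", "),
      "... Inf\n")
  if (nrow(x$masses)) {
    cat("  point masses:",
        paste(sprintf("%.4g @ t=%.4g", x$masses$mass, x$masses$loc),
              collapse = "; "), "\n")
  } else cat("  no point masses\n")
  invisible(x)
}

## ---- inversion of a univariate GF into a pwe_density -------------------

# numeric partial fractions: given poles rho (distinct) with multiplicities
# M, decompose prod (omega + rho_j)^(-M_j) = sum_j sum_k c_{jk}/(omega+rho_j)^k
.partial_fractions <- function(rho, M) {
  res <- list()
  for (j in seq_along(rho)) {
    # derivatives of Q(omega) = prod_{l != j} (omega + rho_l)^(-M_l)
    prods <- list(list(coef = 1, exps = -M * (seq_along(rho) != j)))
    for (l in 0:(M[j] - 1L)) {
      k <- M[j] - l
      val <- 0
      for (pr in prods) {
        v <- pr$coef
        for (q in seq_along(rho)) if (q != j && pr$exps[q] != 0)
          v <- v * (rho[q] - rho[j])^pr$exps[q]
        val <- val + v
      }
      res[[length(res) + 1L]] <- list(j = j, k = k, c = val / factorial(l))
      if (l < M[j] - 1L) {
        nxt <- list()
        for (pr in prods) for (q in seq_along(rho)) {
          if (q == j || pr$exps[q] == 0) next
          p2 <- pr
          p2$coef <- p2$coef * p2$exps[q]
          p2$exps[q] <- p2$exps[q] - 1L
          nxt[[length(nxt) + 1L]] <- p2
        }
        prods <- nxt
      }
    }
  }
  res
}

#' Invert a univariate generating function into a branch-length density
#'
#' Takes a `gf_expr` that depends on a single omega variable (all others
#' already set to zero) and a numeric `Ta`, and computes the inverse Laplace
#' transform term by term: exponential factors `exp(-g*Ta*omega)` become
#' shifts by `g*Ta`, rational factors become (shifted) gamma-kernel pieces
#' by partial fractions, and omega-free terms become point masses. Exactly
#' cancelling growing modes are removed by coefficient pooling; surviving
#' growing modes raise an error.
#'
#' @param g A `gf_expr` depending on one omega variable.
#' @param var The variable to invert with respect to.
#' @param Ta Numeric sweep time (defines the shift locations).
#' @param validate Passed to [pwe_density()].
#' @return A [pwe_density()].
#' @export
gf_to_density <- function(g, var, Ta, validate = TRUE) {
  if (gf_has_delta(g)) stop("invert delta before inverting an omega variable")
  extra <- setdiff(gf_vars(g), var)
  if (length(extra)) g <- gf_subst_zero(g, extra)
  g <- gf_simplify(g)
  shifted <- list()   # entries: coef, shift, rate, pow
  masses <- new.env(parent = emptyenv())
  add_mass <- function(loc, m) {
    key <- sprintf("%.12g", loc)
    masses[[key]] <- (masses[[key]] %||% 0) + m
  }
  for (tm in g$terms) {
    c0 <- tm$coef * (if (tm$tpow > 0L) Ta^tm$tpow else 1) * exp(-Ta * tm$eb)
    gshift <- if (var %in% names(tm$ew)) tm$ew[[var]] else 0
    s <- gshift * Ta
    rho <- numeric(0); M <- integer(0)
    for (p in tm$poles) {
      h <- if (var %in% names(p$w)) p$w[[var]] else 0
      if (h == 0) {
        c0 <- c0 / p$b^p$m
      } else {
        c0 <- c0 / h^p$m
        r <- p$b / h
        hit <- which(abs(rho - r) < 1e-9)
        if (length(hit)) M[hit] <- M[hit] + p$m
        else { rho <- c(rho, r); M <- c(M, p$m) }
      }
    }
    if (length(rho) == 0L) {
      add_mass(s, c0)
      next
    }
    for (pf in .partial_fractions(rho, M)) {
      shifted[[length(shifted) + 1L]] <- list(
        coef = c0 * pf$c / factorial(pf$k - 1L),
        shift = s, rate = rho[pf$j], pow = pf$k - 1L)
    }
  }
  mloc <- as.numeric(ls(masses))
  mdf <- data.frame(loc = mloc,
                    mass = vapply(ls(masses), function(k) masses[[k]], numeric(1)))
  mdf <- mdf[abs(mdf$mass) > 1e-12, , drop = FALSE]
  mdf <- mdf[order(mdf$loc), , drop = FALSE]
  rownames(mdf) <- NULL
  breaks <- sort(unique(round(c(0, vapply(shifted, function(x) x$shift, numeric(1))), 10)))
  pieces <- vector("list", length(breaks))
  for (bi in seq_along(breaks)) {
    b <- breaks[bi]
    act <- Filter(function(x) x$shift <= b + 1e-10, shifted)
    if (length(act) == 0L) {
      pieces[[bi]] <- data.frame(coef = numeric(0), rate = numeric(0), pow = numeric(0))
      next
    }
    # expand (t - s)^p e^{-a(t-s)} into absolute-time monomials t^q e^{-a t}
    rows <- list()
    for (x in act) {
      ea <- exp(x$rate * x$shift)
      for (q in 0:x$pow) {
        rows[[length(rows) + 1L]] <- c(
          coef = x$coef * choose(x$pow, q) * (-x$shift)^(x$pow - q) * ea,
          rate = x$rate, pow = q)
      }
    }
    df <- as.data.frame(do.call(rbind, rows))
    # pool identical (rate, pow) groups; on the final (infinite) interval
    # exact algebra makes growing modes cancel, so zero tiny pooled
    # coefficients relative to the group scale
    key <- paste(signif(df$rate, 7), df$pow)
    agg <- lapply(split(df, key), function(d) {
      sc <- max(abs(d$coef))
      cf <- sum(d$coef)
      if (sc > 0 && abs(cf) < 1e-8 * sc) cf <- 0
      data.frame(coef = cf, rate = d$rate[1L], pow = d$pow[1L])
    })
    df <- do.call(rbind, agg)
    df <- df[df$coef != 0, , drop = FALSE]
    if (bi == length(breaks) && any(df$rate <= 0))
      stop("non-decaying mode survived on the final interval; inversion failed")
    rownames(df) <- NULL
    pieces[[bi]] <- df
  }
  pwe_density(breaks, pieces, mdf, validate = validate)
}
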