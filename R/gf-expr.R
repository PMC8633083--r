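# Closed-form generating-function expressions.
#
# A `gf_expr` is a canonical sum of path terms. Each term is
#
#   coef * delta^dpow * Ta^tpow * exp(-Ta*(eb + sum(ew*omega))) *
#     prod_j (b_j [+ delta] + sum(w_j*omega))^(-m_j)
#
# where the omega are the dummy (Laplace) variables attached to branch
# classes and delta is the rate of the competing exponential process used to
# embed a discrete event (the sweep) in the recursion. Terms built by the
# coalescent recursion only ever contain products of simple linear-rational
# and exponential factors, so differentiation, limits, substitution and the
# inverse Laplace transform with respect to delta stay closed and exact.

new_gf_term <- function(coef = 1, dpow = 0L, tpow = 0L, eb = 0,
                        ew = numeric(0), poles = list()) {
  list(coef = coef, dpow = as.integer(dpow), tpow = as.integer(tpow),
       eb = eb, ew = ew, poles = poles)
}

new_gf_pole <- function(b, d = 0L, w = numeric(0), m = 1L) {
  w <- w[w != 0]
  if (length(w)) w <- w[order(names(w))]
  list(b = b, d = as.integer(d), w = w, m = as.integer(m))
}

#' @keywords internal
new_gf_expr <- function(terms = list()) {
  structure(list(terms = terms), class = "gf_expr")
}

gf_one <- function() new_gf_expr(list(new_gf_term()))

is_gf_expr <- function(x) inherits(x, "gf_expr")

#' @export
print.gf_expr <- function(x, ...) {
  cat("<gf_expr> with", length(x$terms), "terms over variables:",
      paste(gf_vars(x), collapse = ", "), "\n")
  invisible(x)
}

#' Variables appearing in a generating function
#'
#' @param g A `gf_expr`.
#' @return Character vector of dummy-variable names.
#' @export
gf_vars <- function(g) {
  vs <- unlist(lapply(g$terms, function(tm) {
    c(names(tm$ew), unlist(lapply(tm$poles, function(p) names(p$w))))
  }))
  sort(unique(vs))
}

gf_has_delta <- function(g) {
  any(vapply(g$terms, function(tm) {
    tm$dpow > 0L || any(vapply(tm$poles, function(p) p$d > 0L, logical(1)))
  }, logical(1)))
}

## ---- canonicalisation -------------------------------------------------

pole_key <- function(p) {
  paste0(signif(p$b, 14), "|", p$d, "|",
         paste(names(p$w), signif(p$w, 14), sep = ":", collapse = ","))
}

term_key <- function(tm) {
  pk <- vapply(tm$poles, function(p) paste0(pole_key(p), "^", p$m), character(1))
  ew <- tm$ew[tm$ew != 0]
  if (length(ew)) ew <- ew[order(names(ew))]
  paste0("d", tm$dpow, "|T", tm$tpow, "|e", signif(tm$eb, 14), ";",
         paste(names(ew), signif(ew, 14), sep = ":", collapse = ","), "|",
         paste(sort(pk), collapse = "*"))
}

# Merge identical pole factors inside a term (summing exponents) and then
# merge structurally identical terms (summing coefficients).
gf_simplify <- function(g, tol = 0) {
  terms <- lapply(g$terms, function(tm) {
    if (length(tm$poles) > 1L) {
      keys <- vapply(tm$poles, pole_key, character(1))
      if (anyDuplicated(keys)) {
        sp <- split(tm$poles, keys)
        tm$poles <- lapply(sp, function(ps) {
          p <- ps[[1L]]
          p$m <- sum(vapply(ps, function(q) q$m, integer(1)))
          p
        })
        names(tm$poles) <- NULL
      }
    }
    tm
  })
  keys <- vapply(terms, term_key, character(1))
  out <- list()
  for (k in unique(keys)) {
    idx <- which(keys == k)
    tm <- terms[[idx[1L]]]
    tm$coef <- sum(vapply(terms[idx], function(t) t$coef, numeric(1)))
    out[[length(out) + 1L]] <- tm
  }
  if (tol > 0) {
    mx <- max(c(1, abs(vapply(out, function(t) t$coef, numeric(1)))))
    out <- Filter(function(t) abs(t$coef) > tol * mx, out)
  }
  out <- Filter(function(t) t$coef != 0, out)
  new_gf_expr(out)
}

## ---- algebra ----------------------------------------------------------

gf_add <- function(g1, g2) new_gf_expr(c(g1$terms, g2$terms))

gf_scale <- function(g, c) {
  new_gf_expr(lapply(g$terms, function(tm) { tm$coef <- tm$coef * c; tm }))
}

# Multiply every term by a factor 1 / (b [+ delta] + sum(w*omega)).
gf_mul_pole <- function(g, b, w = numeric(0), d = 0L) {
  p <- new_gf_pole(b = b, d = d, w = w)
  new_gf_expr(lapply(g$terms, function(tm) {
    tm$poles <- c(tm$poles, list(p))
    tm
  }))
}

gf_mul_delta <- function(g) {
  new_gf_expr(lapply(g$terms, function(tm) { tm$dpow <- tm$dpow + 1L; tm }))
}

## ---- evaluation -------------------------------------------------------

lin_eval <- function(b, w, omega) {
  if (length(w) == 0L) return(b)
  miss <- setdiff(names(w), names(omega))
  if (length(miss)) stop("no value supplied for variable(s): ",
                         paste(miss, collapse = ", "))
  b + sum(w * omega[names(w)])
}

#' Evaluate a generating function at numeric arguments
#'
#' @param g A `gf_expr`.
#' @param omega Named numeric vector of dummy-variable values. Variables not
#'   named are an error; pass 0 explicitly to marginalise a branch class.
#' @param Ta Numeric sweep-completion time (needed once the expression
#'   contains `Ta`, i.e. after [invert_sweep_time()]).
#' @param delta Numeric rate of the competing sweep process (needed for
#'   expressions still parameterised by `delta`).
#' @return A single numeric value.
#' @export
gf_eval <- function(g, omega = numeric(0), Ta = NULL, delta = NULL) {
  val <- 0
  for (tm in g$terms) {
    v <- tm$coef
    if (tm$dpow > 0L) {
      if (is.null(delta)) stop("expression contains delta; supply `delta`")
      v <- v * delta^tm$dpow
    }
    if (tm$tpow > 0L || tm$eb != 0 || length(tm$ew)) {
      if (is.null(Ta)) stop("expression contains Ta; supply `Ta`")
      v <- v * Ta^tm$tpow * exp(-Ta * lin_eval(tm$eb, tm$ew, omega))
    }
    for (p in tm$poles) {
      den <- lin_eval(p$b, p$w, omega)
      if (p$d > 0L) {
        if (is.null(delta)) stop("expression contains delta; supply `delta`")
        den <- den + p$d * delta
      }
      v <- v / den^p$m
    }
    val <- val + v
  }
  val
}

# Named zero vector over all variables of g (handy for limits at the origin).
gf_zero_omega <- function(g) {
  vs <- gf_vars(g)
  stats::setNames(rep(0, length(vs)), vs)
}

## ---- substitution and limits ------------------------------------------

# Rename / merge variables: map is a named character vector old -> new.
# Coefficients of variables mapped onto the same name are summed.
gf_rename <- function(g, map) {
  ren <- function(w) {
    if (!length(w)) return(w)
    nm <- names(w)
    hit <- nm %in% names(map)
    nm[hit] <- map[nm[hit]]
    tapply_sum <- tapply(w, nm, sum)
    out <- as.numeric(tapply_sum)
    names(out) <- names(tapply_sum)
    out[out != 0]
  }
  g <- new_gf_expr(lapply(g$terms, function(tm) {
    tm$ew <- ren(tm$ew)
    tm$poles <- lapply(tm$poles, function(p) { p$w <- ren(p$w); p <- new_gf_pole(p$b, p$d, p$w, p$m); p })
    tm
  }))
  gf_simplify(g)
}

# Substitute omega = 0 for the given variables (marginalise those classes).
gf_subst_zero <- function(g, vars) {
  new_gf_expr(lapply(g$terms, function(tm) {
    tm$ew <- tm$ew[!(names(tm$ew) %in% vars)]
    tm$poles <- lapply(tm$poles, function(p) {
      p$w <- p$w[!(names(p$w) %in% vars)]
      p
    })
    tm
  }))
}

# Limit omega -> +Inf for the given variables: every term in which one of
# them appears (in a pole or in the exponential rate) vanishes.
gf_limit_inf <- function(g, vars) {
  keep <- vapply(g$terms, function(tm) {
    inexp <- any(names(tm$ew) %in% vars)
    inpole <- any(vapply(tm$poles, function(p) any(names(p$w) %in% vars),
                         logical(1)))
    !(inexp || inpole)
  }, logical(1))
  new_gf_expr(g$terms[keep])
}

# Replace a linear combination sum(omega[vars]) by a single fresh variable.
# Requires the listed variables to appear with a common coefficient in every
# factor they occur in (e.g. omega_a + omega_b -> omega_mrca for n = 2).
gf_subst_linear <- function(g, vars, new) {
  check_w <- function(w) {
    cf <- w[names(w) %in% vars]
    if (length(cf) == 0L) return(NULL)
    if (length(cf) != length(vars) || length(unique(cf)) != 1L)
      stop("variables ", paste(vars, collapse = "+"),
           " do not occur as a unit; cannot substitute")
    unname(cf[1L])
  }
  g2 <- new_gf_expr(lapply(g$terms, function(tm) {
    cf <- check_w(tm$ew)
    if (!is.null(cf)) {
      tm$ew <- tm$ew[!(names(tm$ew) %in% vars)]
      tm$ew[new] <- cf
    }
    tm$poles <- lapply(tm$poles, function(p) {
      cf <- check_w(p$w)
      if (!is.null(cf)) {
        p$w <- p$w[!(names(p$w) %in% vars)]
        p$w[new] <- cf
        p <- new_gf_pole(p$b, p$d, p$w, p$m)
      }
      p
    })
    tm
  }))
  gf_simplify(g2)
}

## ---- differentiation ---------------------------------------------------

#' Partial derivative of a generating function
#'
#' Term-wise closed-form differentiation with respect to one dummy variable.
#' Minus the derivative evaluated at the origin gives the expected total
#' length of the corresponding branch class.
#'
#' @param g A `gf_expr`.
#' @param var Variable name to differentiate with respect to.
#' @return A `gf_expr`.
#' @export
gf_deriv <- function(g, var) {
  out <- list()
  for (tm in g$terms) {
    ce <- if (var %in% names(tm$ew)) tm$ew[[var]] else 0
    if (ce != 0) {
      t2 <- tm
      t2$coef <- t2$coef * (-ce)
      t2$tpow <- t2$tpow + 1L
      out[[length(out) + 1L]] <- t2
    }
    for (j in seq_along(tm$poles)) {
      p <- tm$poles[[j]]
      cj <- if (var %in% names(p$w)) p$w[[var]] else 0
      if (cj != 0) {
        t2 <- tm
        t2$coef <- t2$coef * (-p$m * cj)
        p2 <- p
        p2$m <- p$m + 1L
        t2$poles[[j]] <- p2
        out[[length(out) + 1L]] <- t2
      }
    }
  }
  gf_simplify(new_gf_expr(out))
}

## ---- inverse Laplace transform in delta --------------------------------

# Differentiate (d/d delta)^l a product prod_k (lb_k + lc_k*delta)^(e_k)
# with e_k possibly negative, then evaluate at delta = -beta_j. Used for
# residues at repeated poles. Products are kept as lists of factors
# (b, w, c = delta coefficient, e = exponent) with a numeric coefficient.
.pf_deriv <- function(prods) {
  out <- list()
  for (pr in prods) {
    for (k in seq_along(pr$facs)) {
      f <- pr$facs[[k]]
      if (f$c == 0 || f$e == 0) next
      p2 <- pr
      p2$coef <- p2$coef * f$e * f$c
      p2$facs[[k]]$e <- f$e - 1L
      out[[length(out) + 1L]] <- p2
    }
  }
  out
}

#' Inverse Laplace transform with respect to the sweep rate
#'
#' Converts a generating function parameterised by the competing-exponential
#' sweep rate `delta` into one parameterised by the discrete sweep-completion
#' time `Ta`, by partial-fraction expansion in `delta` of each term divided
#' by `delta`, followed by term-wise inversion. Repeated `delta`-poles are
#' merged beforehand and produce polynomial-in-`Ta` coefficients.
#'
#' @param gf A `gf_expr` containing `delta`.
#' @return A `gf_expr` in the omega variables and `Ta`.
#' @export
gf_invert_delta <- function(gf) {
  if (!is_gf_expr(gf)) stop("`gf` must be a gf_expr")
  if (!gf_has_delta(gf)) stop("expression does not contain delta; nothing to invert")
  gf <- gf_simplify(gf)
  out <- list()
  emit <- function(tm) out[[length(out) + 1L]] <<- tm
  for (tm in gf$terms) {
    if (tm$tpow > 0L || tm$eb != 0 || length(tm$ew))
      stop("term already contains Ta; cannot invert in delta twice")
    dpoles <- Filter(function(p) p$d > 0L, tm$poles)
    opoles <- Filter(function(p) p$d == 0L, tm$poles)
    e0 <- 1L - tm$dpow            # exponent of the pole at delta = 0
    if (e0 < 0L) stop("delta power above one is not supported")
    if (length(dpoles) == 0L) {
      if (tm$dpow > 0L)
        stop("term is polynomial in delta; its inverse transform is singular")
      # L^{-1}[c/delta] = c for all Ta >= 0.
      tm$dpow <- 0L
      emit(tm)
      next
    }
    base <- new_gf_term(coef = tm$coef, poles = opoles)
    # Residue at delta = 0 (neutral completion, only when F/delta).
    if (e0 == 1L) {
      t0 <- base
      t0$poles <- c(t0$poles, lapply(dpoles, function(p) new_gf_pole(p$b, 0L, p$w, p$m)))
      emit(t0)
    }
    # Residues at delta = -beta_j.
    for (j in seq_along(dpoles)) {
      pj <- dpoles[[j]]
      mj <- pj$m
      # H_j(delta) = delta^{-e0} prod_{i != j} (beta_i + delta)^{-m_i}
      facs <- list()
      if (e0 == 1L) facs[[length(facs) + 1L]] <- list(b = 0, w = numeric(0), c = 1, e = -1L)
      for (i in seq_along(dpoles)) if (i != j) {
        pi <- dpoles[[i]]
        facs[[length(facs) + 1L]] <- list(b = pi$b, w = pi$w, c = 1, e = -pi$m)
      }
      prods <- list(list(coef = 1, facs = facs))
      for (l in 0:(mj - 1L)) {
        # c_{j, mj - l} = H_j^{(l)}(-beta_j) / l!
        k <- mj - l          # order of the (beta_j + delta) pole piece
        for (pr in prods) {
          t2 <- base
          t2$coef <- t2$coef * pr$coef / factorial(l) / factorial(k - 1L)
          t2$tpow <- k - 1L
          t2$eb <- pj$b
          t2$ew <- pj$w
          ok <- TRUE
          for (f in pr$facs) {
            if (f$e == 0L) next
            b2 <- f$b - f$c * pj$b
            w2 <- f$w
            if (f$c != 0 && length(pj$w)) {
              allv <- union(names(w2), names(pj$w))
              w2full <- stats::setNames(rep(0, length(allv)), allv)
              if (length(w2)) w2full[names(w2)] <- w2
              w2full[names(pj$w)] <- w2full[names(pj$w)] - f$c * pj$w
              w2 <- w2full
            }
            w2 <- w2[w2 != 0]
            if (length(w2) == 0L && abs(b2) < 1e-12)
              stop("degenerate coinciding poles in delta inversion")
            if (f$e > 0L) {
              # positive power: multiply coefficient-side (linear factor)
              for (r in seq_len(f$e))
                t2$poles <- c(t2$poles, list(new_gf_pole(b2, 0L, w2, m = -1L)))
              ok <- FALSE  # not representable; should not occur (e always <= 0 here)
              break
            } else {
              t2$poles <- c(t2$poles, list(new_gf_pole(b2, 0L, w2, m = -f$e)))
            }
          }
          if (ok) emit(t2)
        }
        if (l < mj - 1L) prods <- .pf_deriv(prods)
      }
    }
  }
  gf_simplify(new_gf_expr(out))
}

## ---- truncated Taylor expansion ---------------------------------------

# Cache of index maps for truncated multivariate convolution.
.ts_cache <- new.env(parent = emptyenv())

ts_setup <- function(orders) {
  key <- paste(orders, collapse = "x")
  hit <- .ts_cache[[key]]
  if (!is.null(hit)) return(hit)
  dims <- orders + 1L
  N <- prod(dims)
  E <- as.matrix(expand.grid(lapply(dims, function(d) 0:(d - 1L))))
  colnames(E) <- NULL
  strides <- cumprod(c(1L, dims[-length(dims)]))
  posn <- function(e) as.integer(e %*% strides) + 1L
  Pq <- vector("list", N); Tq <- vector("list", N)
  for (q in seq_len(N)) {
    eq <- E[q, ]
    ok <- which(apply(E, 1L, function(ep) all(ep + eq <= orders)))
    Pq[[q]] <- ok
    Tq[[q]] <- vapply(ok, function(p) posn(E[p, ] + eq), integer(1))
  }
  val <- list(N = N, E = E, Pq = Pq, Tq = Tq, dims = dims)
  .ts_cache[[key]] <- val
  val
}

ts_mul <- function(a, b, ctx) {
  res <- numeric(ctx$N)
  nz <- which(b != 0)
  for (q in nz) {
    res[ctx$Tq[[q]]] <- res[ctx$Tq[[q]]] + a[ctx$Pq[[q]]] * b[q]
  }
  res
}

# Series (truncated) of sum_j coefs[j] * x^j where x is the linear form
# given by `lin` (a length-N vector with entries only at first-order
# positions), coefs has length J+1.
ts_poly_in_linear <- function(coefs, lin, ctx) {
  res <- numeric(ctx$N)
  cur <- numeric(ctx$N); cur[1L] <- 1
  res <- res + coefs[1L] * cur
  J <- length(coefs) - 1L
  if (J >= 1L) for (j in 1:J) {
    cur <- ts_mul(cur, lin, ctx)
    if (coefs[j + 1L] != 0) res <- res + coefs[j + 1L] * cur
    if (all(cur == 0)) break
  }
  res
}

lin_form_vec <- function(w, vars, ctx) {
  lin <- numeric(ctx$N)
  for (v in names(w)) {
    iv <- match(v, vars)
    if (is.na(iv)) next
    # order-0 variables have no linear slot; their first-order term is
    # discarded by the truncation
    if (ctx$dims[iv] < 2L) next
    e <- integer(length(vars)); e[iv] <- 1L
    strides <- cumprod(c(1L, ctx$dims[-length(ctx$dims)]))
    lin[as.integer(e %*% strides) + 1L] <- w[[v]]
  }
  lin
}

#' Truncated Taylor expansion of a generating function
#'
#' Computes the array of Taylor coefficients of the expression around a
#' given point of the omega variables: entry `(e1, ..., ek)` holds
#' `d^e g / (prod_i e_i!)` evaluated there. Mixed partial derivatives of the
#' generating function at `omega = theta/2` are what turns it into blockwise
#' mutation-configuration probabilities.
#'
#' @param g A `gf_expr` (must not contain `delta`).
#' @param at Named numeric, the expansion point; variables of `g` not named
#'   here are expanded around 0.
#' @param orders Named integer vector of maximal derivative orders; variables
#'   of `g` not named get order 0.
#' @param Ta Numeric value of `Ta` (if present in `g`).
#' @return Numeric array with `dim = orders + 1` (dimension names follow
#'   `names(orders)`); a scalar if `orders` is empty.
#' @export
gf_taylor <- function(g, at = numeric(0), orders = integer(0), Ta = NULL) {
  if (gf_has_delta(g)) stop("expression still contains delta; invert it first")
  vars <- names(orders)
  orders <- as.integer(orders)
  names(orders) <- vars
  allv <- gf_vars(g)
  pt <- stats::setNames(rep(0, length(allv)), allv)
  if (length(at)) pt[names(at)[names(at) %in% allv]] <- at[names(at) %in% allv]
  if (length(orders) == 0L) return(gf_eval(g, omega = pt, Ta = Ta))
  ctx <- ts_setup(orders)
  J <- sum(orders)
  acc <- numeric(ctx$N)
  for (tm in g$terms) {
    cst <- tm$coef
    if (tm$tpow > 0L || tm$eb != 0 || length(tm$ew)) {
      if (is.null(Ta)) stop("expression contains Ta; supply `Ta`")
    }
    series <- NULL
    cur <- numeric(ctx$N); cur[1L] <- 1
    # exponential factor
    if (tm$eb != 0 || length(tm$ew) || tm$tpow > 0L) {
      cst <- cst * (if (tm$tpow > 0L) Ta^tm$tpow else 1)
      cst <- cst * exp(-Ta * lin_eval(tm$eb, tm$ew, pt))
      wex <- tm$ew[names(tm$ew) %in% vars]
      if (length(wex)) {
        lin <- lin_form_vec(wex, vars, ctx)
        coefs <- (-Ta)^(0:J) / factorial(0:J)
        cur <- ts_mul(cur, ts_poly_in_linear(coefs, lin, ctx), ctx)
      }
    }
    ok <- TRUE
    for (p in tm$poles) {
      A <- lin_eval(p$b, p$w, pt)
      if (abs(A) < 1e-11) stop("pole at the expansion point; perturb the evaluation point")
      wp <- p$w[names(p$w) %in% vars]
      if (length(wp) == 0L) {
        cst <- cst / A^p$m
        next
      }
      jj <- 0:J
      coefs <- choose(p$m - 1L + jj, jj) * (-1)^jj * A^(-p$m - jj)
      lin <- lin_form_vec(wp, vars, ctx)
      cur <- ts_mul(cur, ts_poly_in_linear(coefs, lin, ctx), ctx)
    }
    if (ok) acc <- acc + cst * cur
  }
  array(acc, dim = ctx$dims)
}
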