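# ---------------------------------------------------------------------------
# Mean-field theory: rate equations, stationary states, spinodals, cusp
# ---------------------------------------------------------------------------
#
# Under perfect mixing the compartment fractions obey
#   du_int/dt = p (1 - a) - q  u_int
#   du_ext/dt = r (1 - a) E(a) - q' u_ext,      a = u_int + u_ext,
# where E(a) is the probability that a node sits in a critically damaged
# neighborhood (<= m active neighbors) when each neighbor is independently
# failed with probability a:
#   E(a) = sum_k f_k sum_{j=0}^{min(m,k)} C(k,j) (1-a)^j a^(k-j)
#        = sum_k f_k P[Binomial(k, 1-a) <= m].
# Stationary states depend only on the effective rates x = p/q, y = r/q'
# through F(a) = x (1-a) + y (1-a) E(a) - a = 0; writing G(a) = (1-a) E(a),
# the saddle-node (spinodal) conditions F = F' = 0 solve linearly for (x, y)
# at fixed a, and the cusp adds F'' = 0, i.e. G''(a) = 0.

#' Critically-damaged-neighborhood probability E(a)
#'
#' Probability that a node is in a CDN (at most `m` active neighbors) when
#' every neighbor is independently failed with probability `a`, averaged
#' over the degree distribution.
#'
#' @param a failed fraction(s) in `[0, 1]`.
#' @param f_k degree distribution: a named numeric vector of probabilities
#'   indexed by degree, or a single integer degree `k` as shorthand for the
#'   k-regular case.
#' @param m CDN threshold.
#' @return E(a), same length as `a`, in `[0, 1]`; non-decreasing in `a`
#'   whenever `m < k`.
#' @export
cdn_probability <- function(a, f_k, m) {
  if (any(a < -1e-12 | a > 1 + 1e-12)) stop("a must lie in [0, 1]")
  a <- pmin(pmax(a, 0), 1)
  f_k <- as_fk(f_k)
  ks <- as.integer(names(f_k))
  out <- numeric(length(a))
  for (ii in seq_along(ks))
    out <- out + f_k[[ii]] * pbinom(m, ks[ii], 1 - a)
  out
}

# dE/da; for a degree-k term with m < k this is
# k * C(k-1, m) * (1-a)^m * a^(k-1-m), and 0 when m >= k.
cdn_probability_deriv <- function(a, f_k, m) {
  f_k <- as_fk(f_k)
  ks <- as.integer(names(f_k))
  out <- numeric(length(a))
  for (ii in seq_along(ks)) {
    k <- ks[ii]
    if (m < k)
      out <- out + f_k[[ii]] * k * choose(k - 1, m) * (1 - a)^m * a^(k - 1 - m)
  }
  out
}

# --- polynomial machinery (coefficients ascending in a) --------------------
# E(a), and hence G(a) = (1-a) E(a), are polynomials with rational (integer,
# for single-degree f_k) coefficients; used for the spinodal/cusp algebra
# and the exact-root path.

poly_mul <- function(p1, p2) {
  out <- numeric(length(p1) + length(p2) - 1)
  for (i in seq_along(p1))
    out[i:(i + length(p2) - 1)] <- out[i:(i + length(p2) - 1)] + p1[i] * p2
  out
}
poly_deriv <- function(p) {
  if (length(p) <= 1) return(0)
  p[-1] * seq_len(length(p) - 1)
}
poly_eval <- function(p, x) {
  out <- 0
  for (c in rev(p)) out <- out * x + c
  out
}

# coefficients of E_k(a) = sum_{j=0}^{min(m,k)} C(k,j) (1-a)^j a^(k-j)
poly_E_single <- function(k, m) {
  coef <- numeric(k + 1)
  for (j in 0:min(m, k)) {
    term <- choose(k, j) * choose(j, 0:j) * (-1)^(0:j)  # C(k,j)(1-a)^j
    lo <- k - j  # times a^(k-j)
    coef[(lo + 1):(lo + j + 1)] <- coef[(lo + 1):(lo + j + 1)] + term
  }
  coef
}

poly_G <- function(f_k, m) {
  f_k <- as_fk(f_k)
  ks <- as.integer(names(f_k))
  deg <- max(ks)
  E <- numeric(deg + 1)
  for (ii in seq_along(ks)) {
    ek <- poly_E_single(ks[ii], m)
    E[seq_along(ek)] <- E[seq_along(ek)] + f_k[[ii]] * ek
  }
  poly_mul(c(1, -1), E)  # (1 - a) * E(a)
}

G_funs <- function(f_k, m) {
  G <- poly_G(f_k, m)
  G1 <- poly_deriv(G)
  G2 <- poly_deriv(G1)
  list(G = function(a) poly_eval(G, a),
       G1 = function(a) poly_eval(G1, a),
       G2 = function(a) poly_eval(G2, a),
       coef = G, coef1 = G1, coef2 = G2)
}

# stationary condition F(a) = x(1-a) + y G(a)/(1-a)*(1-a)... kept direct:
mf_F <- function(a, x, y, f_k, m) {
  x * (1 - a) + y * (1 - a) * cdn_probability(a, f_k, m) - a
}

#' Mean-field time derivatives
#'
#' Right-hand side of the coupled rate equations for the internally and
#' externally failed fractions.
#'
#' @param state numeric `c(u_int, u_ext)` (or a list with those names).
#' @param params an [fr_params()].
#' @param f_k degree distribution (see [cdn_probability()]).
#' @return numeric `c(du_int, du_ext)`.
#' @export
mf_rhs <- function(state, params, f_k) {
  u_int <- state[[1]]; u_ext <- state[[2]]
  a <- u_int + u_ext
  E <- cdn_probability(min(max(a, 0), 1), f_k, params$m)
  c(du_int = params$p * (1 - a) - params$q * u_int,
    du_ext = params$r * (1 - a) * E - params$qprime * u_ext)
}

#' Integrate the mean-field rate equations
#'
#' Adaptive integration (deSolve, lsoda, rtol 1e-8) of the two-compartment
#' system; the trajectory stays in the simplex `u_int, u_ext >= 0`,
#' `u_int + u_ext <= 1`.
#'
#' @inheritParams mf_rhs
#' @param init initial `c(u_int, u_ext)`; the all-active state is `c(0, 0)`.
#' @param t_max end time.
#' @param dt_out output sampling interval.
#' @return data.frame with columns `time`, `u_int`, `u_ext`, `a`, `z`.
#' @export
mf_integrate <- function(params, f_k, init = c(0, 0), t_max, dt_out = t_max / 2000) {
  f_k <- as_fk(f_k)
  deriv <- function(t, y, parms) list(mf_rhs(y, params, f_k))
  times <- seq(0, t_max, by = dt_out)
  sol <- deSolve::ode(y = c(u_int = init[[1]], u_ext = init[[2]]),
                      times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  out$a <- out$u_int + out$u_ext
  out$z <- 1 - out$a
  out
}

#' Stationary states of the mean-field dynamics
#'
#' All roots in `[0, 1]` of the stationary condition
#' `a = (1 - a) (p/q + (r/q') E(a))`, found by a sign-change scan on a fine
#' grid followed by bisection polishing. The stationary fractions follow as
#' `u_int* = (p/q)(1 - a*)`, `u_ext* = (r/q')(1 - a*) E(a*)`. Stability is
#' labelled from the Jacobian eigenvalues of the two-compartment system
#' when the absolute rates `q`, `qprime` are supplied (the roots themselves
#' depend only on the two effective ratios); labels are omitted otherwise.
#'
#' @param p_over_q effective internal failure rate `p/q` (>= 0).
#' @param r_over_qprime effective external failure rate `r/q'` (>= 0).
#' @param f_k degree distribution (see [cdn_probability()]).
#' @param m CDN threshold.
#' @param q,qprime optional absolute recovery rates for stability labels.
#' @param n_grid scan resolution (>= 1000).
#' @return data.frame with columns `a`, `u_int`, `u_ext` and (if `q`,
#'   `qprime` given) `stability` in `{stable, unstable,
#'   oscillatory-unstable}`; attribute `control = c(p_over_q,
#'   r_over_qprime)`.
#' @export
stationary_states <- function(p_over_q, r_over_qprime, f_k, m,
                              q = NULL, qprime = NULL, n_grid = 2000) {
  stopifnot(p_over_q >= 0, r_over_qprime >= 0)
  f_k <- as_fk(f_k)
  Ff <- function(a) mf_F(a, p_over_q, r_over_qprime, f_k, m)
  grid <- seq(0, 1, length.out = max(n_grid, 1000) + 1)
  fv <- Ff(grid)
  roots <- grid[fv == 0]
  sgn <- sign(fv)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in cross) {
    rt <- uniroot(Ff, c(grid[i], grid[i + 1]), tol = 1e-14)$root
    roots <- c(roots, rt)
  }
  roots <- sort(unique(round(roots, 12)))
  # drop near-duplicates from a root sitting on a grid point
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > 1e-9)]
  E <- cdn_probability(roots, f_k, m)
  out <- data.frame(a = roots,
                    u_int = p_over_q * (1 - roots),
                    u_ext = r_over_qprime * (1 - roots) * E)
  if (!is.null(q) && !is.null(qprime)) {
    p <- p_over_q * q; r <- r_over_qprime * qprime
    out$stability <- vapply(roots, function(a) {
      Ep <- cdn_probability_deriv(a, f_k, m)
      Gp <- -cdn_probability(a, f_k, m) + (1 - a) * Ep  # d/da (1-a)E(a)
      J <- matrix(c(-p - q, -p,
                    r * Gp, r * Gp - qprime), 2, 2, byrow = TRUE)
      ev <- eigen(J, only.values = TRUE)$values
      re <- max(Re(ev))
      if (re < 0) "stable"
      else if (any(abs(Im(ev)) > 1e-12)) "oscillatory-unstable"
      else "unstable"
    }, character(1))
  }
  attr(out, "control") <- c(p_over_q = p_over_q, r_over_qprime = r_over_qprime)
  out
}

# --- exact rational arithmetic (small fractions; doubles as integers) ------
frac <- function(num, den = 1) {
  if (den == 0) stop("zero denominator")
  if (den < 0) { num <- -num; den <- -den }
  g <- frac_gcd(abs(num), den)
  c(num = num / g, den = den / g)
}
frac_gcd <- function(a, b) { while (b > 0) { t <- a %% b; a <- b; b <- t }; max(a, 1) }
f_add <- function(x, y) frac(x[1] * y[2] + y[1] * x[2], x[2] * y[2])
f_mul <- function(x, y) frac(x[1] * y[1], x[2] * y[2])
f_div <- function(x, y) { if (y[1] == 0) stop("division by zero"); frac(x[1] * y[2], x[2] * y[1]) }
f_poly_eval <- function(coef, x) {  # integer coefficients, rational x
  out <- frac(0)
  for (c in rev(coef)) out <- f_add(f_mul(out, x), frac(c))
  out
}

# rational roots of an integer-coefficient polynomial in (0, 1)
rational_roots_01 <- function(coef) {
  # strip powers of a and trailing zeros
  coef <- coef[seq_len(max(which(coef != 0)))]
  s <- which(coef != 0)[1]
  coef <- coef[s:length(coef)]
  if (length(coef) < 2) return(list())
  c0 <- abs(coef[1]); cL <- abs(coef[length(coef)])
  divisors <- function(n) { d <- seq_len(n); d[n %% d == 0] }
  cands <- list()
  for (pp in divisors(c0)) for (qq in divisors(cL)) {
    if (pp < qq && frac_gcd(pp, qq) == 1) {
      val <- f_poly_eval(coef, frac(pp, qq))
      if (val[1] == 0) cands[[length(cands) + 1]] <- frac(pp, qq)
    }
  }
  cands
}

#' Spinodal (saddle-node bifurcation) curves
#'
#' Parametric solution of the two saddle-node conditions `F(a) = 0` and
#' `F'(a) = 0` for the effective rates as functions of the failed fraction
#' `a`: with `G(a) = (1 - a) E(a)` and `D(a) = (1 - a) G'(a) + G(a)`,
#' `r/q' = 1 / D(a)` and `p/q = G'(a) / D(a) - 1`. Only points with both
#' ratios non-negative are returned; the two branches (one on each side of
#' the cusp `a*`, where `G''(a*) = 0`) merge at the cusp and exist only for
#' `r/q'` above its cusp value.
#'
#' @inheritParams stationary_states
#' @param a_grid failed-fraction grid parameterizing the curves.
#' @return object of class `fr_spinodals`: list with `points` (data.frame
#'   `a`, `p_over_q`, `r_over_qprime`, `branch` in `{low_a, high_a}`) and
#'   `cusp` (from [cusp_point()]).
#' @export
spinodals <- function(f_k, m, a_grid = seq(1e-4, 1 - 1e-4, length.out = 4000)) {
  f_k <- as_fk(f_k)
  if (m >= max(as.integer(names(f_k)))) stop("no induced bistability: m >= max degree")
  gf <- G_funs(f_k, m)
  cusp <- cusp_point(f_k, m)
  D <- (1 - a_grid) * gf$G1(a_grid) + gf$G(a_grid)
  y <- ifelse(D > 0, 1 / D, NA_real_)
  x <- gf$G1(a_grid) / D - 1
  ok <- !is.na(y) & x >= 0 & y >= 0
  pts <- data.frame(a = a_grid[ok], p_over_q = x[ok], r_over_qprime = y[ok],
                    branch = ifelse(a_grid[ok] < cusp$a_star, "low_a", "high_a"))
  structure(list(points = pts, cusp = cusp), class = "fr_spinodals")
}

#' @export
#' @method print fr_spinodals
print.fr_spinodals <- function(x, ...) {
  cat(sprintf("<fr_spinodals> %d points; cusp at a* = %.6g, p/q = %.6g, r/q' = %.6g\n",
              nrow(x$points), x$cusp$a_star, x$cusp$p_over_q,
              x$cusp$r_over_qprime))
  invisible(x)
}

#' Cusp point of the mean-field phase diagram
#'
#' Solves the three degeneracy conditions `F = F' = F'' = 0`. Since
#' `F''(a) = (r/q') G''(a)`, the cusp abscissa `a*` is a root of `G''` in
#' `(0, 1)`; the effective rates follow from the linear saddle-node system.
#' For a single-degree distribution the polynomial `G''` has integer
#' coefficients, and an exact rational root is searched first (rational
#' root theorem + exact fraction arithmetic), so e.g. the degree-4,
#' `m = 1` cusp comes out as the exact fractions `a* = 2/5`,
#' `p/q = 19/81`, `r/q' = 3125/1296`; otherwise the root is found
#' numerically (residuals below 1e-12).
#'
#' @inheritParams stationary_states
#' @return list with `a_star`, `p_over_q`, `r_over_qprime`, logical
#'   `exact`, and (when exact) numerator/denominator pairs
#'   `a_star_frac`, `p_over_q_frac`, `r_over_qprime_frac`.
#' @export
cusp_point <- function(f_k, m) {
  f_k <- as_fk(f_k)
  ks <- as.integer(names(f_k))
  if (m >= max(ks)) stop("no induced bistability: m >= max degree")
  gf <- G_funs(f_k, m)

  admissible <- function(a) {
    D <- (1 - a) * gf$G1(a) + gf$G(a)
    if (D <= 0) return(NULL)
    y <- 1 / D; x <- gf$G1(a) / D - 1
    if (x < 0 || y < 0) return(NULL)
    list(a_star = a, p_over_q = x, r_over_qprime = y)
  }

  # exact path: single degree => integer-coefficient G''
  if (length(ks) == 1 && all(abs(gf$coef2 - round(gf$coef2)) < 1e-9)) {
    for (rt in rational_roots_01(round(gf$coef2))) {
      a <- rt[1] / rt[2]
      res <- admissible(a)
      if (is.null(res)) next
      # exact linear solve: y = 1/D, x = G1/D - 1 in fractions
      af <- frac(rt[1], rt[2])
      one_minus_a <- f_add(frac(1), f_mul(frac(-1), af))
      Gf <- f_poly_eval(round(gf$coef), af)
      G1f <- f_poly_eval(round(gf$coef1), af)
      Df <- f_add(f_mul(one_minus_a, G1f), Gf)
      yf <- f_div(frac(1), Df)
      xf <- f_add(f_div(G1f, Df), frac(-1))
      return(list(a_star = af[[1]] / af[[2]],
                  p_over_q = xf[[1]] / xf[[2]],
                  r_over_qprime = yf[[1]] / yf[[2]],
                  exact = TRUE, a_star_frac = unname(af),
                  p_over_q_frac = unname(xf),
                  r_over_qprime_frac = unname(yf)))
    }
  }

  # numeric path: scan G'' for sign changes, polish, pick admissible root
  g2 <- function(a) gf$G2(a)
  grid <- seq(1e-9, 1 - 1e-9, length.out = 20001)
  v <- g2(grid)
  cross <- which(sign(v[-1]) * sign(v[-length(v)]) < 0)
  for (i in cross) {
    a <- uniroot(g2, c(grid[i], grid[i + 1]), tol = 1e-15)$root
    res <- admissible(a)
    if (!is.null(res)) {
      res$exact <- FALSE
      return(res)
    }
  }
  stop("no admissible cusp root of G'' in (0, 1)")
}

#' Classify a point of the mean-field phase diagram
#'
#' `BISTABLE` when the stationary condition has three roots of which two
#' are stable; `OSCILLATORY` when the unique stationary point is unstable
#' and the integrated trajectory settles on a periodic attractor (Fourier
#' detection); otherwise `LOW` / `HIGH` by whether the stable stationary
#' failed fraction is below or above one half.
#'
#' @inheritParams stationary_states
#' @param q,qprime absolute recovery rates (needed for stability).
#' @param t_max integration horizon for the oscillation probe; defaults to
#'   `100 / min(q, qprime)`.
#' @return character label.
#' @export
classify_phase <- function(p_over_q, r_over_qprime, q, qprime, f_k, m,
                           t_max = NULL) {
  st <- stationary_states(p_over_q, r_over_qprime, f_k, m, q = q, qprime = qprime)
  n_stable <- sum(st$stability == "stable")
  if (nrow(st) >= 3 && n_stable >= 2) return("BISTABLE")
  if (nrow(st) == 1 && st$stability[1] != "stable") {
    if (is.null(t_max)) t_max <- 100 / min(q, qprime)
    params <- fr_params(p_over_q * q, r_over_qprime * qprime, q, qprime, m)
    tr <- mf_integrate(params, f_k, init = c(1e-3, 0), t_max = t_max)
    half <- tr[tr$time >= t_max / 2, ]
    det <- oscillation_detect(half$time, half$z)
    if (det$is_periodic) return("OSCILLATORY")
  }
  a_ref <- if (n_stable >= 1) st$a[st$stability == "stable"][1] else st$a[1]
  if (a_ref < 0.5) "LOW" else "HIGH"
}

#' Area of the hysteresis (bistable) region
#'
#' Integrates the `p/q` width between the two spinodal branches over
#' `r/q'`, clipped to a rectangular window, by the trapezoid rule on the
#' continuation output. Zero when the window lies entirely below the cusp.
#'
#' @param sp an `fr_spinodals` object.
#' @param window list with elements `r_over_qprime = c(lo, hi)` and
#'   `p_over_q = c(lo, hi)`.
#' @return non-negative area.
#' @export
hysteresis_area <- function(sp, window) {
  stopifnot(inherits(sp, "fr_spinodals"))
  ylo <- max(window$r_over_qprime[1], sp$cusp$r_over_qprime)
  yhi <- window$r_over_qprime[2]
  if (yhi <= ylo) return(0)
  b1 <- sp$points[sp$points$branch == "low_a", ]
  b2 <- sp$points[sp$points$branch == "high_a", ]
  if (nrow(b1) < 2 || nrow(b2) < 2) return(0)
  # fixed absolute step so that enlarging the window refines consistently
  ygrid <- seq(ylo, yhi, by = min(0.005, (yhi - ylo) / 100))
  xi1 <- stats::approx(b1$r_over_qprime, b1$p_over_q, xout = ygrid,
                       ties = mean, rule = 1)$y
  xi2 <- stats::approx(b2$r_over_qprime, b2$p_over_q, xout = ygrid,
                       ties = mean, rule = 1)$y
  # beyond the end of the high-a branch the failed phase persists down to
  # p/q = 0, so the wedge is bounded below by zero there
  xi2[is.na(xi2) & !is.na(xi1)] <- 0
  lo <- pmin(xi1, xi2); hi <- pmax(xi1, xi2)
  lo <- pmax(lo, window$p_over_q[1]); hi <- pmin(hi, window$p_over_q[2])
  width <- pmax(hi - lo, 0)
  width[is.na(width)] <- 0
  sum((width[-1] + width[-length(width)]) / 2 * diff(ygrid))
}

#' Closed-form stationary failed fractions in the decoupled limits
#'
#' With `r = 0` the nodes are independent two-state units and
#' `a* = (p/q) / (1 + p/q)`; with `m >= k` every node is always in a CDN
#' and `a* = s / (1 + s)` with `s = p/q + r/q'`.
#'
#' @param params an [fr_params()].
#' @param limit `"r0"` or `"cdn_always"`.
#' @return stationary failed fraction.
#' @export
closed_form_failed_fraction <- function(params, limit = c("r0", "cdn_always")) {
  limit <- match.arg(limit)
  if (limit == "r0") {
    s <- params$p / params$q
  } else {
    s <- params$p / params$q + params$r / params$qprime
  }
  s / (1 + s)
}
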