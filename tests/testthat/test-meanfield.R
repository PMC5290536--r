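# independent brute-force expansion of the stationary polynomial
# F(a) = x (1-a) + y (1-a) E_k(a) - a for a single degree k, built from
# direct binomial enumeration (not via the package's polynomial helpers)
expand_F_poly <- function(x, y, k, m) {
  # coefficients ascending; start with x(1-a) - a
  coef <- numeric(k + 2)
  coef[1] <- x
  coef[2] <- -x - 1
  for (j in 0:min(m, k)) {
    # y * (1-a)^(j+1) * a^(k-j) * C(k,j)
    binj <- choose(j + 1, 0:(j + 1)) * (-1)^(0:(j + 1))
    lo <- k - j
    coef[(lo + 1):(lo + j + 2)] <- coef[(lo + 1):(lo + j + 2)] +
      y * choose(k, j) * binj
  }
  coef
}

test_that("CDN probability matches binomial enumeration", {
  expect_equal(cdn_probability(1, 4, 1), 1)
  expect_equal(cdn_probability(0.5, 4, 1), 0.3125)  # (1 + 4) * 0.5^4
  expect_equal(cdn_probability(0.3, 7, 7), 1)       # m >= k
  expect_equal(cdn_probability(0, 4, 1), 0)
  a <- seq(0, 1, 0.01)
  expect_true(all(diff(cdn_probability(a, 4, 1)) >= 0))  # monotone for m < k
  # mixed degree distribution
  fk <- c("2" = 0.5, "4" = 0.5)
  manual <- 0.5 * (0.4^2 + 2 * 0.6 * 0.4) + 0.5 * (0.4^4 + 4 * 0.6 * 0.4^3)
  expect_equal(cdn_probability(0.4, fk, 1), manual)
  expect_error(cdn_probability(1.2, 4, 1), "\\[0, 1\\]")
})

test_that("mean-field derivatives vanish at the closed-form fixed points", {
  params <- fr_params(0.9, 0.95, 1.0, 0.1, m = 1)
  expect_equal(unname(mf_rhs(c(0, 0), params, 4)), c(0.9, 0))  # E(0) = 0
  # r = 0: decoupled internal channel
  p0 <- fr_params(0.5, 0, 1.0, 0.1, m = 1)
  a0 <- 0.5 / (0.5 + 1)
  expect_equal(unname(mf_rhs(c(a0, 0), p0, 4)), c(0, 0), tolerance = 1e-12)
  # m >= k: E identically 1
  pm <- fr_params(0.25, 0.5, 1.0, 1.0, m = 9)
  s <- 0.25 + 0.5
  a1 <- s / (1 + s)
  st <- c(0.25 * (1 - a1), 0.5 * (1 - a1))
  expect_equal(unname(mf_rhs(st, pm, 4)), c(0, 0), tolerance = 1e-12)
})

test_that("mean-field integration conserves the simplex and shows the
           internal-then-external failure takeover", {
  # constant when nothing fails
  tr0 <- mf_integrate(fr_params(0, 0, 1, 1, 1), 4, t_max = 10)
  expect_true(all(tr0$u_int == 0 & tr0$u_ext == 0))
  # strong-coupling compartment takeover from the all-active state
  params <- fr_params(0.9, 0.95, 1.0, 0.1, m = 1)
  tr <- mf_integrate(params, 4, init = c(0, 0), t_max = 200)
  expect_true(all(tr$u_int > -1e-9 & tr$u_ext > -1e-9 & tr$a < 1 + 1e-9))
  early <- tr[which(tr$time > 0.5)[1], ]
  late <- tr[nrow(tr), ]
  expect_gt(early$u_int, early$u_ext)   # internal failures rise first
  expect_gt(late$u_ext, late$u_int)     # external failures dominate late
})

test_that("stationary roots agree with the brute-force polynomial oracle", {
  set.seed(99)
  for (rep in 1:20) {
    k <- sample(c(3, 4, 6, 10), 1)
    m <- sample(0:(k - 1), 1)
    x <- runif(1, 0, 1.5); y <- runif(1, 0, 12)
    roots <- stationary_states(x, y, k, m)$a
    pr <- polyroot(expand_F_poly(x, y, k, m))
    pr <- Re(pr[abs(Im(pr)) < 1e-8])
    pr <- sort(pr[pr > -1e-10 & pr < 1 + 1e-10])
    pr <- pr[c(TRUE, diff(pr) > 1e-8)]
    expect_equal(length(roots), length(pr), info = sprintf(
      "k=%d m=%d x=%.3f y=%.3f", k, m, x, y))
    expect_equal(roots, pr, tolerance = 1e-7)
    # every root satisfies the stationary condition
    resid <- x * (1 - roots) + y * (1 - roots) * cdn_probability(roots, k, m) - roots
    expect_true(all(abs(resid) < 1e-10))
  }
})

test_that("simple stationary examples come out in closed form", {
  expect_equal(stationary_states(1, 0, 4, 1)$a, 0.5, tolerance = 1e-10)
  expect_equal(stationary_states(0.25, 0.75, 4, 4)$a, 0.5, tolerance = 1e-10)
  st <- stationary_states(19 / 81, 3125 / 1296, 4, 1)
  expect_equal(st$a, 0.4, tolerance = 1e-5)  # triple root at the cusp
})

test_that("stationary roots depend only on the effective ratios", {
  base <- stationary_states(0.2, 8, 4, 1)$a
  for (cfac in c(0.1, 3)) {
    # p,q scaled by c and r,q' by c' leave p/q and r/q' unchanged
    scaled <- stationary_states(0.2 * cfac / cfac, 8, 4, 1)$a
    expect_equal(scaled, base, tolerance = 1e-12)
  }
  # and stability labelling needs the absolute rates but not the roots
  lab <- stationary_states(0.2, 8, 4, 1, q = 1, qprime = 0.1)
  expect_equal(lab$a, base, tolerance = 1e-12)
  expect_true(all(lab$stability %in%
                    c("stable", "unstable", "oscillatory-unstable")))
})

test_that("smallest stationary root grows with the internal failure rate", {
  y <- 8
  xs <- seq(0.01, 0.5, length.out = 25)
  a_min <- vapply(xs, function(x) min(stationary_states(x, y, 4, 1)$a),
                  numeric(1))
  expect_true(all(diff(a_min) > -1e-9))
})

test_that("the degree-4 cusp point comes out as exact fractions", {
  cp <- cusp_point(4, 1)
  expect_true(cp$exact)
  expect_identical(cp$a_star_frac, c(2, 5))
  expect_identical(cp$p_over_q_frac, c(19, 81))
  expect_identical(cp$r_over_qprime_frac, c(3125, 1296))
  # closed-form check: G''(a) = 12a(5a-2)(a-1) vanishes at a* = 2/5 and the
  # numeric continuation agrees with the exact fractions to 1e-10
  num <- uniroot(function(a) 12 * a * (5 * a - 2) * (a - 1),
                 c(0.2, 0.6), tol = 1e-15)$root
  expect_equal(cp$a_star, num, tolerance = 1e-10)
  expect_error(cusp_point(1, 1), "no induced bistability")
})

test_that("numeric cusp solving works beyond the closed-form case", {
  cp <- cusp_point(10, 4)
  # the cusp satisfies all three degeneracy conditions
  Ffun <- function(a) cp$p_over_q * (1 - a) +
    cp$r_over_qprime * (1 - a) * cdn_probability(a, 10, 4) - a
  eps <- 1e-6
  expect_lt(abs(Ffun(cp$a_star)), 1e-10)
  d1 <- (Ffun(cp$a_star + eps) - Ffun(cp$a_star - eps)) / (2 * eps)
  d2 <- (Ffun(cp$a_star + eps) - 2 * Ffun(cp$a_star) + Ffun(cp$a_star - eps)) / eps^2
  expect_lt(abs(d1), 1e-6)
  expect_lt(abs(d2), 1e-3)
  # and sits at the common endpoint of the two spinodal branches
  sp <- spinodals(10, 4)
  for (br in split(sp$points, sp$points$branch)) {
    iend <- which.min(abs(br$a - cp$a_star))
    expect_lt(abs(br$r_over_qprime[iend] - cp$r_over_qprime), 0.01)
  }
})

test_that("spinodal curves enclose the bistable wedge above the cusp", {
  sp <- spinodals(4, 1)
  expect_true(all(sp$points$r_over_qprime >= 3125 / 1296 - 1e-6))
  # just above the cusp both saddle-node branches sit at positive p/q
  at28 <- vapply(split(sp$points, sp$points$branch), function(br)
    approx(br$r_over_qprime, br$p_over_q, xout = 2.8, ties = mean)$y,
    numeric(1))
  expect_equal(length(at28), 2)
  expect_gt(max(at28), min(at28))
  # between the two spinodal p/q values the system is tristationary
  expect_equal(nrow(stationary_states(mean(at28), 2.8, 4, 1)), 3)
  # outside, it is monostable
  expect_equal(nrow(stationary_states(max(at28) * 1.3, 2.8, 4, 1)), 1)
  # further from the cusp the high-failure state persists down to p/q = 0:
  # the wedge is then bounded by the low-a branch and the p/q = 0 axis
  expect_equal(nrow(stationary_states(0.01, 5, 4, 1)), 3)
  low5 <- with(subset(sp$points, branch == "low_a"),
               approx(r_over_qprime, p_over_q, xout = 5, ties = mean)$y)
  expect_equal(nrow(stationary_states(low5 * 1.2, 5, 4, 1)), 1)
  expect_error(spinodals(4, 4), "no induced bistability")
})

test_that("phase classification distinguishes LOW, HIGH and BISTABLE", {
  expect_equal(classify_phase(0.01, 0, q = 1, qprime = 0.1, 4, 1), "LOW")
  expect_equal(classify_phase(3, 0, q = 1, qprime = 0.1, 4, 1), "HIGH")
  sp <- spinodals(4, 1)
  at28 <- vapply(split(sp$points, sp$points$branch), function(br)
    approx(br$r_over_qprime, br$p_over_q, xout = 2.8, ties = mean)$y,
    numeric(1))
  expect_equal(classify_phase(mean(at28), 2.8, q = 1, qprime = 0.1, 4, 1),
               "BISTABLE")
  expect_equal(classify_phase(0.05, 5, q = 1, qprime = 0.1, 4, 1),
               "BISTABLE")
  # q > q': no oscillatory label anywhere on a small sweep
  set.seed(2)
  for (i in 1:6) {
    lab <- classify_phase(runif(1, 0, 1), runif(1, 0, 10),
                          q = 1, qprime = 0.1, 4, 1)
    expect_true(lab %in% c("LOW", "HIGH", "BISTABLE"))
  }
})

test_that("hysteresis area integrates the spinodal wedge", {
  sp <- spinodals(4, 1)
  below <- list(r_over_qprime = c(0, 2), p_over_q = c(0, 1))
  expect_equal(hysteresis_area(sp, below), 0)
  win <- list(r_over_qprime = c(0, 10), p_over_q = c(0, 1))
  a1 <- hysteresis_area(sp, win)
  expect_gt(a1, 0)
  win2 <- list(r_over_qprime = c(0, 20), p_over_q = c(0, 1))
  expect_gte(hysteresis_area(sp, win2), a1)  # monotone in window extent
})

test_that("conservation holds identically in the rate equations", {
  set.seed(5)
  for (i in 1:20) {
    u <- runif(2); u <- u / max(1, sum(u) + 0.1)
    params <- fr_params(runif(1), runif(1), runif(1) + 0.1,
                        runif(1) + 0.1, m = 1)
    d <- mf_rhs(u, params, 4)
    dz <- -(d[1] + d[2])
    expect_equal(unname(dz + d[1] + d[2]), 0)  # d(z + u_int + u_ext)/dt = 0
  }
})
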