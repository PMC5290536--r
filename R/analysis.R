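# ---------------------------------------------------------------------------
# Phase-switching statistics, hysteresis protocol, oscillation detection,
# simulation-based phase classification
# ---------------------------------------------------------------------------

#' Phase-switching statistics of an activity time series
#'
#' Assigns a high/low activity phase by hysteresis-band crossing (enter
#' HIGH when `z` exceeds the upper band edge, LOW when it drops below the
#' lower edge) and counts the transitions between the two phases, together
#' with the dwell time spent in each visited phase and a bimodality
#' coefficient of the `z` histogram (Sarle's `b = (g1^2 + 1) / (g2 +
#' 3(n-1)^2 / ((n-2)(n-3)))`; values above 5/9 indicate bimodality).
#'
#' @param traj an `fr_trajectory` or data.frame with `time` and `z`.
#' @param band numeric `c(low, high)` with `low < high`; defaults
#'   `c(0.3, 0.7)`.
#' @return list of class `fr_switching`: `n_switches`, `dwell_times`,
#'   `phases`, `switch_times`, `bimodality`, `band`.
#' @export
detect_switching <- function(traj, band = c(0.3, 0.7)) {
  if (band[1] >= band[2]) stop("band low must be < high")
  if (nrow(traj) < 10) stop("trajectory shorter than 10 samples")
  z <- traj$z; tm <- traj$time
  phase <- character(0)
  cur <- NA_character_
  switch_times <- numeric(0)
  enter_times <- numeric(0)
  for (i in seq_along(z)) {
    new <- if (z[i] > band[2]) "HIGH" else if (z[i] < band[1]) "LOW" else cur
    if (!is.na(new) && (is.na(cur) || new != cur)) {
      if (!is.na(cur)) switch_times <- c(switch_times, tm[i])
      enter_times <- c(enter_times, tm[i])
      phase <- c(phase, new)
      cur <- new
    }
  }
  dwell <- if (length(enter_times) > 1) diff(enter_times) else numeric(0)
  n <- length(z)
  zc <- z - mean(z)
  s2 <- mean(zc^2)
  bim <- if (s2 < 1e-20 || n < 4) 0 else {
    g1 <- mean(zc^3) / s2^1.5
    g2 <- mean(zc^4) / s2^2 - 3
    (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  }
  structure(list(n_switches = length(switch_times),
                 switch_times = switch_times, dwell_times = dwell,
                 phases = phase, bimodality = bim, band = band),
            class = "fr_switching")
}

#' @export
#' @method print fr_switching
print.fr_switching <- function(x, ...) {
  cat(sprintf("<fr_switching> %d switches, bimodality %.3f (band %.2f-%.2f)\n",
              x$n_switches, x$bimodality, x$band[1], x$band[2]))
  invisible(x)
}

#' Hysteresis loop protocol
#'
#' Sweeps the internal failure rate `p` upward through `p_grid` and back
#' down at fixed `r`, `q`, `q'`, `m`. Each step continues from the final
#' node configuration of the previous step, discards a relaxation window
#' and then time-averages the active fraction over a measurement window.
#'
#' @param net an `frnet`.
#' @param params_base an [fr_params()]; its `p` is overridden by the sweep.
#' @param p_grid ascending internal-failure rates.
#' @param t_relax,t_measure relaxation / measurement time per step.
#' @param seed RNG seed for the whole loop.
#' @param sample_dt sampling interval within the measurement window.
#' @param init initial configuration for the first (lowest-p) step.
#' @return list of class `fr_hysteresis`: data.frame `sweep` with columns
#'   `p`, `z_forward`, `se_forward`, `z_backward`, `se_backward`, plus
#'   `gap` (max branch separation) and `gap_se` (pooled SE at that point).
#' @export
hysteresis_loop <- function(net, params_base, p_grid, t_relax, t_measure,
                            seed = NULL, sample_dt = 0.5, init = "all-active") {
  if (is.unsorted(p_grid)) stop("p_grid must be sorted ascending")
  if (t_relax <= 0 || t_measure <= 0) stop("times must be > 0")
  if (!is.null(seed)) set.seed(seed)
  state <- resolve_init(init, net$n)
  step <- function(p, state) {
    pr <- fr_params(p, params_base$r, params_base$q, params_base$qprime,
                    params_base$m)
    rel <- run_gillespie(net, pr, init = state, t_max = t_relax,
                         sample_dt = t_relax)
    mea <- run_gillespie(net, pr, init = attr(rel, "final_state"),
                         t_max = t_measure, sample_dt = sample_dt)
    ss <- stationary_summary(mea, burn_in = 0, n_batches = 20)
    list(z = ss["z", "mean"], se = ss["z", "se"],
         state = attr(mea, "final_state"))
  }
  nsteps <- length(p_grid)
  zf <- sef <- zb <- seb <- numeric(nsteps)
  for (i in seq_len(nsteps)) {
    res <- step(p_grid[i], state)
    zf[i] <- res$z; sef[i] <- res$se; state <- res$state
  }
  for (i in rev(seq_len(nsteps))) {
    res <- step(p_grid[i], state)
    zb[i] <- res$z; seb[i] <- res$se; state <- res$state
  }
  gap_i <- which.max(abs(zf - zb))
  structure(list(sweep = data.frame(p = p_grid, z_forward = zf,
                                    se_forward = sef, z_backward = zb,
                                    se_backward = seb),
                 gap = abs(zf - zb)[gap_i],
                 gap_se = sqrt(sef[gap_i]^2 + seb[gap_i]^2)),
            class = "fr_hysteresis")
}

#' @export
#' @method print fr_hysteresis
print.fr_hysteresis <- function(x, ...) {
  cat(sprintf("<fr_hysteresis> %d steps, gap = %.4f (SE %.4f)\n",
              nrow(x$sweep), x$gap, x$gap_se))
  invisible(x)
}

#' Fourier-based periodicity detection
#'
#' Computes the power spectrum of the linearly detrended last half of a
#' uniformly sampled series and flags periodicity when the dominant
#' non-zero-frequency peak exceeds 10 times the median spectral power.
#' Invariant to adding a constant offset.
#'
#' @param times uniformly spaced sample times (at least 64).
#' @param z_series the series (e.g. fraction of active nodes).
#' @param peak_factor detection threshold on peak / median power.
#' @return list: `is_periodic`, `frequency` (inverse time units),
#'   `peak_ratio`.
#' @export
oscillation_detect <- function(times, z_series, peak_factor = 10) {
  n0 <- length(times)
  if (n0 < 64) stop("need at least 64 samples")
  dts <- diff(times)
  if (max(dts) - min(dts) > 1e-6 * mean(dts)) stop("non-uniform sampling")
  keep <- seq(floor(n0 / 2) + 1, n0)
  x <- z_series[keep]; tt <- times[keep]
  dt <- mean(diff(tt))
  # linear detrend removes offset and slow drift
  fit <- stats::lm.fit(cbind(1, tt), x)
  x <- x - cbind(1, tt) %*% fit$coefficients
  n <- length(x)
  if (var(as.numeric(x)) < 1e-20)
    return(list(is_periodic = FALSE, frequency = NA_real_, peak_ratio = 0))
  pw <- Mod(fft(as.numeric(x)))^2 / n
  idx <- 2:floor(n / 2)  # positive non-zero frequencies
  freqs <- (idx - 1) / (n * dt)
  pk <- which.max(pw[idx])
  med <- stats::median(pw[idx])
  ratio <- if (med <= 0) Inf else pw[idx][pk] / med
  list(is_periodic = is.infinite(ratio) || ratio >= peak_factor,
       frequency = freqs[pk], peak_ratio = ratio)
}

#' Numeric check that the mean-field flow has no closed orbits
#'
#' For each `(p, r)` pair, integrates the mean-field equations from several
#' random initial states and reports whether the trajectory converged to a
#' fixed point (late-time derivative norm below 1e-8) or sustained an
#' oscillation (Fourier detection on the last half). With `q > q'` no pair
#' should oscillate.
#'
#' @param f_k degree distribution.
#' @param m CDN threshold.
#' @param q,qprime recovery rates.
#' @param parameter_sample data.frame with columns `p`, `r`.
#' @param t_max integration horizon; defaults to `100 / min(q, qprime)`.
#' @param n_init random initial states per pair.
#' @param seed RNG seed for the initial states.
#' @return data.frame, one row per (pair, init): `p`, `r`, `u_int0`,
#'   `u_ext0`, `converged`, `is_periodic`, `oscillatory`, `peak_ratio`;
#'   attribute `n_oscillatory`.
#' @export
no_closed_orbits_check <- function(f_k, m, q, qprime, parameter_sample,
                                   t_max = NULL, n_init = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(t_max)) t_max <- 100 / min(q, qprime)
  rows <- list()
  for (i in seq_len(nrow(parameter_sample))) {
    p <- parameter_sample$p[i]; r <- parameter_sample$r[i]
    params <- fr_params(p, r, q, qprime, m)
    for (j in seq_len(n_init)) {
      u0 <- runif(2)
      u0 <- u0 / max(1, sum(u0))  # stay in the simplex
      tr <- mf_integrate(params, f_k, init = u0, t_max = t_max,
                         dt_out = t_max / 4000)
      nlast <- nrow(tr)
      d <- mf_rhs(c(tr$u_int[nlast], tr$u_ext[nlast]), params, f_k)
      converged <- sqrt(sum(d^2)) < 1e-8
      half <- tr[tr$time >= t_max / 2, ]
      det <- oscillation_detect(half$time, half$z)
      amplitude <- diff(range(half$z))
      turns <- sum(diff(sign(diff(half$z))) != 0)
      # a sustained limit cycle has macroscopic amplitude and many turning
      # points; an algebraically slow crawl near a degenerate fixed point
      # is monotone and would otherwise false-flag via spectral leakage
      rows[[length(rows) + 1]] <- data.frame(
        p = p, r = r, u_int0 = u0[1], u_ext0 = u0[2],
        converged = converged, is_periodic = det$is_periodic,
        amplitude = amplitude, n_turns = turns,
        oscillatory = det$is_periodic && !converged &&
          amplitude > 1e-2 && turns >= 4,
        peak_ratio = det$peak_ratio)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_oscillatory") <- sum(out$oscillatory)
  out
}

#' Simulation-based phase diagram
#'
#' For each `(p/q, r/q')` grid point, runs the stochastic dynamics from
#' both the all-active and the all-failed configuration, discards a
#' relaxation window and compares the stationary active fractions.
#' A point is `BISTABLE` when the two initial conditions settle on active
#' fractions separated by more than 3 pooled standard errors *and* more
#' than `min_gap`; otherwise `LOW` / `HIGH` by the pooled mean failed
#' fraction.
#'
#' @param net an `frnet`.
#' @param grid data.frame with columns `p_over_q`, `r_over_qprime`.
#' @param q,qprime recovery rates.
#' @param m CDN threshold.
#' @param t_relax,t_measure relaxation / measurement windows.
#' @param sample_dt sampling interval.
#' @param min_gap minimum active-fraction separation for a bistable call.
#' @param seed RNG seed.
#' @return the grid with added columns `z_active_init`, `z_failed_init`,
#'   `se_pooled`, `label`.
#' @export
simulated_phase_diagram <- function(net, grid, q, qprime, m, t_relax,
                                    t_measure, sample_dt = 0.5,
                                    min_gap = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  run_point <- function(p, r, init) {
    pr <- fr_params(p, r, q, qprime, m)
    rel <- run_gillespie(net, pr, init = init, t_max = t_relax,
                         sample_dt = t_relax)
    mea <- run_gillespie(net, pr, init = attr(rel, "final_state"),
                         t_max = t_measure, sample_dt = sample_dt)
    ss <- stationary_summary(mea, burn_in = 0, n_batches = 20)
    c(z = ss["z", "mean"], se = ss["z", "se"])
  }
  out <- grid
  out$z_active_init <- out$z_failed_init <- out$se_pooled <- NA_real_
  out$label <- NA_character_
  for (i in seq_len(nrow(grid))) {
    p <- grid$p_over_q[i] * q
    r <- grid$r_over_qprime[i] * qprime
    up <- run_point(p, r, "all-active")
    # probe the failed basin with externally failed nodes: their slow
    # recovery (q') matches the composition of the high-failure phase,
    # whereas all-X initial states decay at the fast internal rate q
    # before induced failures can establish
    dn <- run_point(p, r, "all-failed-ext")
    se <- sqrt(up["se"]^2 + dn["se"]^2)
    gapz <- abs(up["z"] - dn["z"])
    out$z_active_init[i] <- up["z"]
    out$z_failed_init[i] <- dn["z"]
    out$se_pooled[i] <- se
    out$label[i] <- if (gapz > 3 * se && gapz > min_gap) "BISTABLE"
      else if (1 - mean(c(up["z"], dn["z"])) < 0.5) "LOW" else "HIGH"
  }
  out
}
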