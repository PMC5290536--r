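# ---------------------------------------------------------------------------
# Model parameters and the exact stochastic simulator
# ---------------------------------------------------------------------------

#' Model parameters of the failure-recovery dynamics
#'
#' Five control parameters: active nodes fail spontaneously at rate `p`
#' (A -> X) and, when located in a critically damaged neighborhood (CDN, at
#' most `m` active neighbors), additionally at rate `r` (A -> Y). Failed
#' nodes recover spontaneously: X -> A at rate `q`, Y -> A at rate `qprime`.
#' X and Y never interconvert and failed nodes cannot fail again.
#'
#' @param p internal failure rate (>= 0, per unit time).
#' @param r external (induced) failure rate (>= 0).
#' @param q internal recovery rate (>= 0).
#' @param qprime external recovery rate (>= 0).
#' @param m CDN threshold: a node is critically damaged when its number of
#'   active neighbors is `<= m` (non-negative integer).
#' @return an object of class `fr_params`.
#' @export
fr_params <- function(p, r, q, qprime, m) {
  for (nm in c("p", "r", "q", "qprime")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stop(sprintf("'%s' must be a finite non-negative rate", nm))
  }
  if (m != round(m) || m < 0) stop("'m' must be a non-negative integer")
  structure(list(p = p, r = r, q = q, qprime = qprime, m = as.integer(m)),
            class = "fr_params")
}

#' @export
#' @method print fr_params
print.fr_params <- function(x, ...) {
  cat(sprintf("<fr_params> p = %g, r = %g, q = %g, q' = %g, m = %d\n",
              x$p, x$r, x$q, x$qprime, x$m))
  invisible(x)
}

# state codes used throughout: 0 = A (active), 1 = X (int. failed),
# 2 = Y (ext. failed)
STATE_A <- 0L
STATE_X <- 1L
STATE_Y <- 2L

#' Is a node in a critically damaged neighborhood?
#'
#' @param net an `frnet`.
#' @param states integer vector of node states (0 = active, 1 = internally
#'   failed, 2 = externally failed).
#' @param node node id (1-based).
#' @param m CDN threshold.
#' @return `TRUE` iff the node's number of active neighbors is `<= m`.
#' @export
is_cdn <- function(net, states, node, m) {
  if (node < 1 || node > net$n) stop("unknown node id")
  nb <- c(net$edges[net$edges[, 1] == node, 2],
          net$edges[net$edges[, 2] == node, 1])
  sum(states[nb] == STATE_A) <= m
}

#' Per-node transition rates
#'
#' The exit-rate menu of a single node given the current configuration:
#' an active node carries channel A -> X at rate `p` plus, if in a CDN,
#' A -> Y at rate `r`; an internally failed node recovers at rate `q`; an
#' externally failed node at rate `qprime`.
#'
#' @inheritParams is_cdn
#' @param params an [fr_params()].
#' @return list with `total` (exit rate) and `channels` (named rates).
#' @export
node_rates <- function(net, states, params, node) {
  s <- states[node]
  if (s == STATE_A) {
    ch <- c("A->X" = params$p)
    if (is_cdn(net, states, node, params$m)) ch <- c(ch, "A->Y" = params$r)
  } else if (s == STATE_X) {
    ch <- c("X->A" = params$q)
  } else {
    ch <- c("Y->A" = params$qprime)
  }
  list(total = sum(ch), channels = ch)
}

resolve_init <- function(init, n) {
  if (is.character(init) && length(init) == 1) {
    if (init == "all-active") return(rep(STATE_A, n))
    if (init == "all-failed") return(rep(STATE_X, n))
    if (init == "all-failed-ext") return(rep(STATE_Y, n))
    stop("unknown init keyword: ", init)
  }
  if (length(init) != n) stop("invalid init length")
  s <- as.integer(init)
  if (any(!s %in% 0:2)) stop("states must be 0, 1 or 2")
  s
}

#' Exact stochastic simulation of the failure-recovery dynamics
#'
#' Statistically exact realization of the continuous-time Markov chain on
#' `net` defined by [node_rates()], via the direct Gillespie method with
#' per-node exit rates held in a sum tree (rates change only locally, so
#' each event costs O(log N)). The trajectory is sampled on a uniform time
#' grid with piecewise-constant interpolation between events.
#'
#' @param net an `frnet`.
#' @param params an [fr_params()].
#' @param init `"all-active"`, `"all-failed"` (all nodes typed X), or an
#'   integer state vector of length `net$n` with codes 0/1/2.
#' @param t_max simulation end time (> 0).
#' @param sample_dt sampling interval (> 0).
#' @param seed RNG seed; same seed and inputs give the identical event
#'   sequence.
#' @param snapshot_times optional increasing times at which the full node
#'   state vector is recorded.
#' @return an `fr_trajectory`: a data.frame with columns `time`, `z`
#'   (fraction active), `u_int`, `u_ext`, carrying attributes `params`,
#'   `seed`, `n`, `event_count`, `final_state`, `snapshots`, and the
#'   network's lattice metadata when present.
#' @export
run_gillespie <- function(net, params, init = "all-active", t_max, sample_dt,
                          seed = NULL, snapshot_times = numeric(0)) {
  stopifnot(inherits(net, "frnet"), inherits(params, "fr_params"))
  if (t_max <= 0) stop("t_max must be > 0")
  if (sample_dt <= 0) stop("sample_dt must be > 0")
  s0 <- resolve_init(init, net$n)
  if (!is.null(seed)) set.seed(seed)
  csr <- adjacency_csr(net)
  res <- .gillespie_core(csr$ptr, csr$nbr, s0, params$p, params$r, params$q,
                         params$qprime, params$m, t_max, sample_dt,
                         as.numeric(sort(snapshot_times)))
  traj <- data.frame(time = res$time, z = res$z, u_int = res$u_int,
                     u_ext = res$u_ext)
  structure(traj, class = c("fr_trajectory", "data.frame"),
            params = params, seed = seed, n = net$n,
            event_count = res$event_count, final_state = res$final_state,
            snapshots = res$snapshots, L = net$L, periodic = net$periodic)
}

#' Extract a lattice snapshot as an L x L state matrix
#'
#' @param traj an `fr_trajectory` produced with `snapshot_times` on a
#'   network with lattice coordinates.
#' @param index which snapshot (1-based).
#' @return integer `L x L` matrix of state codes (0 = A, 1 = X, 2 = Y);
#'   rows are lattice rows (node id `i * L + j`, 0-based, maps to row
#'   `i + 1`, column `j + 1`).
#' @export
export_snapshot <- function(traj, index) {
  snaps <- attr(traj, "snapshots")
  if (is.null(snaps) || length(snaps) == 0) stop("no snapshots were requested")
  L <- attr(traj, "L")
  if (is.null(L)) stop("network has no lattice coordinates")
  if (index < 1 || index > length(snaps)) stop("snapshot index out of range")
  s <- snaps[[index]]$state
  m <- matrix(s, nrow = L, ncol = L, byrow = TRUE)
  attr(m, "time") <- snaps[[index]]$time
  m
}

#' Write / read a lattice snapshot as a plain-text integer matrix
#'
#' One lattice row per line, space-separated state codes.
#' @param mat integer matrix from [export_snapshot()].
#' @param path file path.
#' @return `read_snapshot` returns the integer matrix.
#' @export
write_snapshot <- function(mat, path) {
  writeLines(apply(mat, 1, paste, collapse = " "), path)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  rows <- strsplit(readLines(path), " +")
  do.call(rbind, lapply(rows, as.integer))
}

#' Stationary time-averages of a trajectory with Monte Carlo errors
#'
#' Discards an initial burn-in fraction, then estimates the long-run mean of
#' each compartment fraction together with a batch-means standard error
#' (appropriate for the autocorrelated samples of a single run).
#'
#' @param traj an `fr_trajectory` (or any data.frame with `z`, `u_int`,
#'   `u_ext`).
#' @param burn_in fraction of the samples discarded from the start.
#' @param n_batches number of equal batches for the standard error.
#' @return data.frame with rows `z`, `u_int`, `u_ext` and columns `mean`,
#'   `se`.
#' @export
stationary_summary <- function(traj, burn_in = 0.2, n_batches = 30) {
  keep <- seq(floor(nrow(traj) * burn_in) + 1, nrow(traj))
  out <- lapply(c(z = "z", u_int = "u_int", u_ext = "u_ext"), function(col) {
    x <- traj[[col]][keep]
    b <- cut(seq_along(x), n_batches, labels = FALSE)
    bm <- tapply(x, b, mean)
    c(mean = mean(x), se = sd(bm) / sqrt(length(bm)))
  })
  as.data.frame(do.call(rbind, out))
}
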