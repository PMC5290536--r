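# ---------------------------------------------------------------------------
# Exact master-equation solution for tiny networks
# ---------------------------------------------------------------------------

#' Exact stationary distribution of the full 3^N-state master equation
#'
#' Builds the generator matrix of the continuous-time Markov chain on all
#' 3^N node-state configurations (feasible for N up to about 10) and solves
#' for the stationary distribution by a sparse linear solve. This is the
#' brute-force ground truth against which the stochastic simulator is
#' validated.
#'
#' @param net an `frnet` with at most 12 nodes.
#' @param params an [fr_params()].
#' @return list: `pi` (stationary probabilities over configurations in
#'   base-3 order, node 1 least significant), `z`, `u_int`, `u_ext`
#'   (stationary expected compartment fractions).
#' @export
exact_stationary <- function(net, params) {
  N <- net$n
  if (N > 12) stop("exact generator limited to N <= 12 nodes")
  S <- 3L^N
  pow <- 3^(0:(N - 1))
  # digit matrix: D[s, i] = state of node i in configuration s (0-based s)
  s_idx <- 0:(S - 1)
  D <- matrix(0L, S, N)
  for (i in seq_len(N)) D[, i] <- (s_idx %/% pow[i]) %% 3L
  A <- D == 0L
  adj <- matrix(0L, N, N)
  for (e in seq_len(nrow(net$edges))) {
    adj[net$edges[e, 1], net$edges[e, 2]] <- 1L
    adj[net$edges[e, 2], net$edges[e, 1]] <- 1L
  }
  n_act <- A %*% adj  # S x N active-neighbor counts

  from <- integer(0); to <- integer(0); rate <- numeric(0)
  for (i in seq_len(N)) {
    si <- D[, i]
    act <- si == 0L
    # A -> X at rate p
    if (params$p > 0) {
      from <- c(from, s_idx[act]); to <- c(to, s_idx[act] + pow[i])
      rate <- c(rate, rep(params$p, sum(act)))
    }
    # A -> Y at rate r when in a CDN
    cdn <- act & (n_act[, i] <= params$m)
    if (params$r > 0 && any(cdn)) {
      from <- c(from, s_idx[cdn]); to <- c(to, s_idx[cdn] + 2 * pow[i])
      rate <- c(rate, rep(params$r, sum(cdn)))
    }
    # X -> A at rate q
    xs <- si == 1L
    if (params$q > 0) {
      from <- c(from, s_idx[xs]); to <- c(to, s_idx[xs] - pow[i])
      rate <- c(rate, rep(params$q, sum(xs)))
    }
    # Y -> A at rate q'
    ys <- si == 2L
    if (params$qprime > 0) {
      from <- c(from, s_idx[ys]); to <- c(to, s_idx[ys] - 2 * pow[i])
      rate <- c(rate, rep(params$qprime, sum(ys)))
    }
  }
  exit <- numeric(S)
  agg <- rowsum(rate, from)
  exit[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  Q <- Matrix::sparseMatrix(i = c(from, s_idx) + 1L, j = c(to, s_idx) + 1L,
                            x = c(rate, -exit), dims = c(S, S))
  if (S <= 3^7) {
    # small systems: direct dense solve of pi Q = 0, sum(pi) = 1
    Aeq <- t(as.matrix(Q))
    Aeq[S, ] <- 1
    pi <- solve(Aeq, c(rep(0, S - 1), 1))
  } else {
    # large systems: uniformization P = I + Q / lambda and power iteration
    # (the sparse LU of the 3^N generator suffers catastrophic fill-in)
    lambda <- max(exit) * 1.000001
    PT <- Matrix::t(Q) / lambda + Matrix::Diagonal(S)
    pi <- rep(1 / S, S)
    for (sweep in seq_len(3000)) {
      for (it in seq_len(100)) pi <- as.numeric(PT %*% pi)
      pi <- pi / sum(pi)
      resid <- max(abs(as.numeric(PT %*% pi) - pi)) * lambda
      if (resid < 1e-12) break
    }
    if (resid >= 1e-12)
      warning(sprintf("power iteration stalled at residual %.2e", resid))
  }
  pi[pi < 0] <- 0
  pi <- pi / sum(pi)
  list(pi = pi,
       z = sum(pi * rowSums(D == 0L)) / N,
       u_int = sum(pi * rowSums(D == 1L)) / N,
       u_ext = sum(pi * rowSums(D == 2L)) / N)
}
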