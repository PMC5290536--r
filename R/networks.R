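#' @useDynLib failrecov, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pbinom runif setNames uniroot fft sd var
#' @importFrom utils head tail
NULL

# ---------------------------------------------------------------------------
# Network container
# ---------------------------------------------------------------------------

#' Construct a network object
#'
#' Light-weight container for an undirected simple graph, optionally carrying
#' square-lattice embedding coordinates. Node ids are 1-based integers
#' internally; file interfaces use 0-based ids.
#'
#' @param n number of nodes.
#' @param edges two-column integer matrix of undirected edges (1-based ids).
#' @param coords optional `n x 2` integer matrix of lattice coordinates in
#'   `[0, L)^2` (row index i, column index j).
#' @param L optional lattice side length.
#' @param periodic logical; whether lattice coordinates wrap around.
#' @return an object of class `frnet`.
#' @export
frnet <- function(n, edges, coords = NULL, L = NULL, periodic = FALSE) {
  stopifnot(n >= 1)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 1L) || any(edges > n)) stop("edge endpoint out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loop in edge list")
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    key <- (edges[, 1] - 1) * as.double(n) + edges[, 2]
    if (anyDuplicated(key)) stop("duplicate edge in edge list")
  }
  if (!is.null(coords)) {
    coords <- matrix(as.integer(coords), ncol = 2)
    stopifnot(nrow(coords) == n, !is.null(L), n == L^2)
    if (anyDuplicated(coords)) stop("duplicate lattice coordinates")
    if (any(coords < 0L) || any(coords >= L)) stop("coordinates outside [0, L)")
  }
  structure(list(n = as.integer(n), edges = edges, coords = coords,
                 L = if (is.null(L)) NULL else as.integer(L),
                 periodic = isTRUE(periodic)),
            class = "frnet")
}

#' @export
#' @method print frnet
print.frnet <- function(x, ...) {
  cat(sprintf("<frnet> %d nodes, %d edges%s\n", x$n, nrow(x$edges),
              if (!is.null(x$L))
                sprintf(" (L = %d, %s lattice coords)", x$L,
                        if (x$periodic) "periodic" else "open")
              else ""))
  invisible(x)
}

#' Node degrees of a network
#' @param net an `frnet` object.
#' @return integer vector of length `net$n`.
#' @export
degrees <- function(net) {
  tabulate(c(net$edges[, 1], net$edges[, 2]), nbins = net$n)
}

# adjacency in compressed sparse row form (0-based, for the C++ core)
adjacency_csr <- function(net) {
  deg <- degrees(net)
  ptr <- c(0L, cumsum(deg))
  nbr <- integer(2L * nrow(net$edges))
  pos <- ptr[-length(ptr)]  # running insert position per node
  e <- net$edges
  for (idx in seq_len(nrow(e))) {
    u <- e[idx, 1]; v <- e[idx, 2]
    pos[u] <- pos[u] + 1L; nbr[pos[u]] <- v - 1L
    pos[v] <- pos[v] + 1L; nbr[pos[v]] <- u - 1L
  }
  list(ptr = ptr, nbr = nbr)
}

# ---------------------------------------------------------------------------
# Generators
# ---------------------------------------------------------------------------

#' Square lattice network
#'
#' @param L side length; the lattice has `L^2` nodes at integer coordinates
#'   `(i, j)` with 0-based row-major node ids `i * L + j`.
#' @param periodic wrap boundaries (torus); the periodic lattice is 4-regular.
#'   Requires `L >= 3` (smaller periodic lattices would create duplicate
#'   edges).
#' @return an `frnet`.
#' @export
make_square_lattice <- function(L, periodic = TRUE) {
  L <- as.integer(L)
  if (periodic && L < 3) stop("periodic lattice needs L >= 3 (duplicate edges otherwise)")
  if (!periodic && L < 2) stop("lattice needs L >= 2")
  idx <- function(i, j) i * L + j + 1L  # 0-based (i, j) -> 1-based id
  i <- rep(0:(L - 1), each = L)
  j <- rep(0:(L - 1), times = L)
  if (periodic) {
    right <- cbind(idx(i, j), idx(i, (j + 1L) %% L))
    down  <- cbind(idx(i, j), idx((i + 1L) %% L, j))
    edges <- rbind(right, down)
  } else {
    right <- cbind(idx(i[j < L - 1], j[j < L - 1]), idx(i[j < L - 1], j[j < L - 1] + 1L))
    down  <- cbind(idx(i[i < L - 1], j[i < L - 1]), idx(i[i < L - 1] + 1L, j[i < L - 1]))
    edges <- rbind(right, down)
  }
  frnet(L^2, edges, coords = cbind(i, j), L = L, periodic = periodic)
}

#' Random regular graph
#'
#' Simple k-regular graph on N nodes, generated by the configuration model
#' with rejection of self-loops and multi-edges (via igraph).
#'
#' @param N number of nodes; `N * k` must be even and `k < N`.
#' @param k degree.
#' @param seed RNG seed for reproducibility.
#' @return an `frnet`.
#' @export
make_regular_random_graph <- function(N, k, seed = NULL) {
  N <- as.integer(N); k <- as.integer(k)
  if ((as.double(N) * k) %% 2 != 0) stop("N * k must be even (odd stub count)")
  if (k >= N) stop("k must be smaller than N")
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_k_regular(N, k, directed = FALSE, multiple = FALSE)
  frnet(N, igraph::as_edgelist(g, names = FALSE))
}

#' Specification of a spatially embedded network
#'
#' @param L side of the underlying periodic lattice of node positions.
#' @param zeta characteristic link length of the exponential length
#'   distribution `P(l) ~ exp(-l / zeta)`; small `zeta` recovers the square
#'   lattice, large `zeta` a random regular graph.
#' @param k target degree (4 in the reference setting).
#' @param seed RNG seed.
#' @return a list of class `fr_embedded_spec`.
#' @export
embedded_spec <- function(L, zeta, k = 4, seed = NULL) {
  L <- as.integer(L)
  if (L < 3) stop("L must be >= 3")
  if (!is.numeric(zeta) || zeta <= 0) stop("zeta must be > 0")
  structure(list(L = L, zeta = zeta, k = as.integer(k), seed = seed),
            class = "fr_embedded_spec")
}

# offsets (dx, dy) on the periodic L-lattice whose rounded Euclidean
# minimal-image distance is l, for each l = 1..floor(L/2)
length_offsets <- function(L) {
  half <- L %/% 2
  d <- seq(-half, half - (L %% 2 == 0), by = 1)  # minimal-image range
  grid <- expand.grid(dx = d, dy = d)
  grid <- grid[!(grid$dx == 0 & grid$dy == 0), ]
  l <- as.integer(round(sqrt(grid$dx^2 + grid$dy^2)))
  keep <- l >= 1L & l <= half
  km <- as.matrix(grid[keep, , drop = FALSE])
  lapply(split(seq_len(nrow(km)), l[keep]),
         function(ix) km[ix, , drop = FALSE])
}

#' Spatially embedded network with exponential link lengths
#'
#' Nodes sit on a periodic L x L lattice; each of the `k` stubs per node is
#' matched to a partner at a link length `l` drawn from the truncated
#' geometric law with weights proportional to `exp(-l / zeta)` on
#' `{1, ..., floor(L/2)}`. Partners at drawn length `l` are nodes whose
#' rounded minimal-image Euclidean distance equals `l`. When no partner at
#' the drawn length has a free stub, an augmenting random walk displaces
#' existing edges (degree-preserving; every edge still carries a drawn
#' length) before the draw is relaxed to the nearest feasible length as a
#' last resort. Exact k-regularity is attempted but not guaranteed; the
#' achieved degree sequence is always consistent with the returned edge
#' set, and a mean degree off target by more than 1% warns.
#'
#' @param spec an [embedded_spec()].
#' @return an `frnet` with lattice coordinates.
#' @export
make_embedded_network <- function(spec) {
  stopifnot(inherits(spec, "fr_embedded_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  L <- spec$L
  N <- L^2
  offs <- length_offsets(L)
  support <- as.integer(names(offs))
  w <- exp(-support / spec$zeta)
  w <- w / sum(w)

  ci <- rep(0:(L - 1), each = L)
  cj <- rep(0:(L - 1), times = L)
  free <- rep(spec$k, N)
  adj <- vector("list", N)

  partners_at <- function(u, l) {
    om <- offs[[as.character(l)]]
    unique(as.integer(((ci[u] + om[, 1]) %% L) * L +
                        ((cj[u] + om[, 2]) %% L) + 1L))
  }
  add_edge <- function(u, v) {
    adj[[u]] <<- c(adj[[u]], v); adj[[v]] <<- c(adj[[v]], u)
    free[u] <<- free[u] - 1L; free[v] <<- free[v] - 1L
  }
  rm_edge <- function(u, v) {
    adj[[u]] <<- adj[[u]][adj[[u]] != v]
    adj[[v]] <<- adj[[v]][adj[[v]] != u]
    free[u] <<- free[u] + 1L; free[v] <<- free[v] + 1L
  }
  draw_len <- function() support[sample.int(length(support), 1L, prob = w)]

  # place one stub of u at exactly length l (partner with a free stub)
  place <- function(u, l) {
    cand <- partners_at(u, l)
    cand <- cand[cand != u & free[cand] > 0L]
    if (length(cand)) {
      cand <- setdiff(cand, adj[[u]])
      if (length(cand)) {
        add_edge(u, cand[sample.int(length(cand), 1L)])
        return(TRUE)
      }
    }
    FALSE
  }
  # augmenting random walk: connect the free stub to a saturated partner v
  # at a drawn length, displacing one of v's edges; the displaced endpoint
  # inherits the free stub and the walk continues from there; every edge
  # placed this way still carries a drawn length
  augment <- function(u, max_steps = 400L) {
    cur <- u
    for (step in seq_len(max_steps)) {
      if (place(cur, draw_len())) return(TRUE)
      l <- draw_len()
      cand <- partners_at(cur, l)
      cand <- setdiff(cand[cand != cur], adj[[cur]])
      if (!length(cand)) next
      v <- cand[sample.int(length(cand), 1L)]
      ws <- setdiff(adj[[v]], cur)
      if (!length(ws)) next
      wnode <- ws[sample.int(length(ws), 1L)]
      rm_edge(v, wnode)
      add_edge(cur, v)
      cur <- wnode
    }
    FALSE
  }
  # last resort: nearest feasible length to a fresh draw
  relax_place <- function(u) {
    l0 <- draw_len()
    for (l in support[order(abs(support - l0), support)])
      if (place(u, l)) return(TRUE)
    FALSE
  }

  target_edges <- (N * spec$k) %/% 2L
  n_placed <- 0L
  guard <- 0L
  while (n_placed < target_edges && guard < 20L * target_edges) {
    guard <- guard + 1L
    open <- which(free > 0L)
    if (length(open) < 2L) break
    u <- open[sample.int(length(open), 1L)]
    if (place(u, draw_len()) || augment(u) || relax_place(u)) {
      n_placed <- n_placed + 1L
    } else {
      break  # give up: report achieved degree sequence as-is
    }
  }

  edges <- do.call(rbind, lapply(seq_len(N), function(u) {
    v <- adj[[u]]; v <- v[v > u]
    if (length(v)) cbind(u, v) else NULL
  }))
  net <- frnet(N, edges, coords = cbind(ci, cj), L = L, periodic = TRUE)
  mean_deg <- 2 * nrow(edges) / N
  if (abs(mean_deg - spec$k) / spec$k > 0.01)
    warning(sprintf("achieved mean degree %.3f deviates from target %d by > 1%%",
                    mean_deg, spec$k))
  attr(net, "zeta") <- spec$zeta
  attr(net, "target_degree") <- spec$k
  net
}

#' Euclidean link lengths of an embedded network
#'
#' Minimal-image Euclidean distances (rounded to integers) of all edges.
#' @param net an `frnet` with lattice coordinates.
#' @return integer vector, one length per edge.
#' @export
link_lengths <- function(net) {
  if (is.null(net$coords)) stop("network has no lattice coordinates")
  L <- net$L
  dx <- abs(net$coords[net$edges[, 1], 1] - net$coords[net$edges[, 2], 1])
  dy <- abs(net$coords[net$edges[, 1], 2] - net$coords[net$edges[, 2], 2])
  if (net$periodic) {
    dx <- pmin(dx, L - dx)
    dy <- pmin(dy, L - dy)
  }
  as.integer(round(sqrt(dx^2 + dy^2)))
}

#' Empirical degree distribution
#'
#' @param net an `frnet`.
#' @return named numeric vector `f_k`: probabilities indexed by degree
#'   (names are degrees as character), summing to 1.
#' @export
degree_distribution <- function(net) {
  d <- degrees(net)
  tab <- table(d) / net$n
  setNames(as.numeric(tab), names(tab))
}

# normalize a degree distribution argument: a single integer degree k is
# shorthand for the k-regular point mass
as_fk <- function(f_k) {
  if (is.numeric(f_k) && length(f_k) == 1 && is.null(names(f_k))) {
    if (f_k != round(f_k) || f_k < 0) stop("degree must be a non-negative integer")
    return(setNames(1, as.character(as.integer(f_k))))
  }
  if (is.null(names(f_k))) stop("f_k must be named by degree")
  if (any(f_k < 0)) stop("probabilities must be non-negative")
  if (abs(sum(f_k) - 1) > 1e-12) stop("f_k must sum to 1")
  f_k
}
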