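#' Nodal graph metrics
#'
#' Degree centrality, normalized betweenness centrality and the
#' Watts-Strogatz local clustering coefficient of a binary network.
#'
#' * `degree_centrality()`: number of neighbours of each node.
#' * `betweenness_centrality()`: for each node, the fraction of shortest paths
#'   between the other node pairs that pass through it, normalized by
#'   `(J-1)(J-2)/2` so values lie in `[0, 1]`; disconnected pairs contribute 0.
#' * `clustering_coefficient()`: `2 e_v / (k_v (k_v - 1))` where `e_v` counts
#'   edges among the neighbours of `v`; nodes with degree < 2 get 0.
#'
#' @param net A [binary_network()].
#' @return A named numeric vector over regions.
#' @name node_metrics_individual
NULL

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
}

#' @rdname node_metrics_individual
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  rowSums(net$adjacency)
}

#' @rdname node_metrics_individual
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  j <- nrow(net$adjacency)
  b <- igraph::betweenness(as_igraph(net), directed = FALSE, normalized = FALSE)
  denom <- (j - 1) * (j - 2) / 2
  out <- if (denom > 0) b / denom else b * 0
  stats::setNames(as.numeric(out), net$region_names)
}

#' @rdname node_metrics_individual
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  a <- net$adjacency
  k <- rowSums(a)
  closed3 <- diag(a %*% a %*% a) # = 2 * triangles through each node
  cc <- ifelse(k < 2, 0, closed3 / (k * (k - 1)))
  stats::setNames(as.numeric(cc), net$region_names)
}

#' Global and local efficiency
#'
#' Global efficiency is the mean over ordered node pairs of the inverse
#' shortest-path length (disconnected pairs contribute 0). Local efficiency
#' is the mean over nodes of the global efficiency of the subgraph induced on
#' each node's neighbours; nodes with degree < 2 contribute 0.
#'
#' @param net A [binary_network()].
#' @return A scalar in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  efficiency_from_adjacency(net$adjacency)
}

efficiency_from_adjacency <- function(a) {
  j <- nrow(a)
  if (j < 2) return(0)
  d <- if (j <= 16) {
    adjacency_distances_small(a)
  } else {
    igraph::distances(
      igraph::graph_from_adjacency_matrix(a, mode = "undirected"))
  }
  inv <- 1 / d
  diag(inv) <- 0 # exclude self pairs; 1/Inf = 0 handles disconnected pairs
  sum(inv) / (j * (j - 1))
}

# Unweighted shortest-path distances by breadth-first reachability through
# boolean matrix products; faster than building an igraph for tiny graphs,
# identical results.
adjacency_distances_small <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a > 0] <- 1
  diag(d) <- 0
  cur <- a > 0
  s <- 1
  while (s < n - 1) {
    s <- s + 1
    cur <- (cur %*% a) > 0
    upd <- cur & !is.finite(d)
    if (!any(upd)) break
    d[upd] <- s
  }
  d
}

#' @rdname global_efficiency
#' @export
local_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  a <- net$adjacency
  k <- rowSums(a)
  vals <- vapply(seq_len(nrow(a)), function(v) {
    if (k[v] < 2) return(0)
    nb <- which(a[v, ] > 0)
    efficiency_from_adjacency(a[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

#' All nodal metrics of one network as a tidy table
#'
#' @param net A [binary_network()].
#' @param metrics Which metrics to compute.
#' @return A tibble with columns `region`, `metric`, `value`.
#' @export
node_metrics <- function(net, metrics = c("degree", "betweenness", "clustering")) {
  metrics <- match.arg(metrics, c("degree", "betweenness", "clustering"),
                       several.ok = TRUE)
  fns <- list(degree = degree_centrality,
              betweenness = betweenness_centrality,
              clustering = clustering_coefficient)
  purrr::map_dfr(metrics, function(m) {
    tibble::tibble(region = net$region_names, metric = m,
                   value = as.numeric(fns[[m]](net)))
  })
}

#' Degree-matched random and edge-matched lattice reference graphs
#'
#' Random references are degree-preserving double-edge-swap randomizations of
#' the input (10 x edge_count attempted swaps per realization); lattice
#' references are deterministic ring lattices on the same nodes with the same
#' edge count (nearest-neighbour rings filled first, the remainder placed at
#' the next ring distance in node order). Used by the small-world feasibility
#' criterion for cost-threshold selection.
#'
#' @param net A [binary_network()].
#' @param kind `"random"` or `"lattice"`.
#' @param n_realizations Number of realizations (lattice realizations are all
#'   identical by construction).
#' @param seed Integer seed for the random rewiring.
#' @return A list of `binary_network` objects.
#' @export
reference_graphs <- function(net, kind = c("random", "lattice"),
                             n_realizations = 1L, seed = NULL) {
  stopifnot(inherits(net, "binary_network"))
  kind <- match.arg(kind)
  if (n_realizations < 1L) abort("`n_realizations` must be >= 1.")
  if (kind == "lattice") {
    lat <- ring_lattice_adjacency(nrow(net$adjacency), net$edge_count)
    dimnames(lat) <- dimnames(net$adjacency)
    one <- structure(list(adjacency = lat, cost = net$cost,
                          edge_count = net$edge_count,
                          region_names = net$region_names),
                     class = "binary_network")
    return(rep(list(one), n_realizations))
  }
  g <- as_igraph(net)
  niter <- max(1L, 10L * net$edge_count)
  run <- function() {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = niter))
    adj <- as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE))
    dimnames(adj) <- dimnames(net$adjacency)
    structure(list(adjacency = adj, cost = net$cost,
                   edge_count = net$edge_count,
                   region_names = net$region_names),
              class = "binary_network")
  }
  if (is.null(seed)) {
    replicate(n_realizations, run(), simplify = FALSE)
  } else {
    withr::with_seed(seed, replicate(n_realizations, run(), simplify = FALSE))
  }
}

# Ring lattice on j nodes with exactly m edges: fill ring distance 1, 2, ...
# completely while edges remain, then place the remainder at the next
# distance for nodes 1, 2, ... in order.
ring_lattice_adjacency <- function(j, m) {
  max_m <- j * (j - 1) / 2
  if (m > max_m) abort("More edges requested than the complete graph holds.")
  adj <- matrix(0, j, j)
  left <- m
  d <- 1L
  while (left > 0) {
    ring <- if (2 * d == j) j / 2 else j # distance j/2 ring has j/2 edges
    take <- min(left, ring)
    starts <- seq_len(take)
    ends <- ((starts + d - 1L) %% j) + 1L
    adj[cbind(starts, ends)] <- 1
    adj[cbind(ends, starts)] <- 1
    left <- left - take
    d <- d + 1L
  }
  adj
}
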