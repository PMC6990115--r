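#' Community detection by greedy modularity agglomeration
#'
#' Deterministic greedy agglomerative maximization of
#' resolution-parameterized Newman modularity
#' `Q(gamma) = sum_c (e_cc - gamma * a_c^2)`, where `e_cc` is the fraction of
#' edge ends falling inside community `c` and `a_c` its total degree
#' fraction. Starting from singletons, the pair of connected communities with
#' the largest modularity gain is merged at every step (ties broken by
#' ascending lexicographic order of community labels, a label being the
#' smallest member node), and the partition attaining the maximum modularity
#' along the merge path is returned. `gamma > 1` favours smaller modules,
#' `gamma < 1` larger ones. The procedure is seed-free: identical inputs give
#' identical partitions.
#'
#' @param net A [binary_network()].
#' @param gamma Resolution parameter, > 0 (default 1, the standard setting).
#' @return An object of class `community_partition`: fields `labels`
#'   (integers `1..n_communities`, contiguous, in order of first appearance),
#'   `n_communities`, `gamma`, `modularity`. An empty graph returns each node
#'   as its own community with modularity 0.
#' @export
newman_communities <- function(net, gamma = 1.0) {
  stopifnot(inherits(net, "binary_network"))
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    abort("`gamma` must be a positive scalar.")
  }
  a <- net$adjacency
  j <- nrow(a)
  m2 <- sum(a) # twice the edge count
  singletons <- function(q) {
    structure(list(labels = seq_len(j), n_communities = j,
                   gamma = gamma, modularity = q),
              class = "community_partition")
  }
  if (m2 == 0) return(singletons(0))

  e <- a / m2                      # community x community edge-end fractions
  deg_frac <- rowSums(e)           # a_c
  label <- seq_len(j)              # community label = smallest member node
  alive <- rep(TRUE, j)
  membership <- seq_len(j)
  q_now <- -gamma * sum(deg_frac^2) # all singletons (diag(e) = 0, no loops)
  best_q <- q_now
  best_membership <- membership

  repeat {
    idx <- which(alive)
    if (length(idx) < 2L) break
    esub <- e[idx, idx, drop = FALSE]
    gain <- 2 * (esub - gamma * outer(deg_frac[idx], deg_frac[idx]))
    cand <- upper.tri(esub) & esub > 0
    if (!any(cand)) break
    gain[!cand] <- -Inf
    gmax <- max(gain)
    hits <- which(gain == gmax, arr.ind = TRUE)
    # Lexicographic tie-break on (smaller label, larger label).
    lab_i <- label[idx[hits[, 1L]]]
    lab_j <- label[idx[hits[, 2L]]]
    lo <- pmin(lab_i, lab_j)
    hi <- pmax(lab_i, lab_j)
    pick <- order(lo, hi)[1L]
    ci <- idx[hits[pick, 1L]]
    cj <- idx[hits[pick, 2L]]
    if (label[cj] < label[ci]) { tmp <- ci; ci <- cj; cj <- tmp }
    # Merge cj into ci.
    e[ci, ] <- e[ci, ] + e[cj, ]
    e[, ci] <- e[, ci] + e[, cj]
    e[cj, ] <- 0
    e[, cj] <- 0
    deg_frac[ci] <- deg_frac[ci] + deg_frac[cj]
    deg_frac[cj] <- 0
    alive[cj] <- FALSE
    membership[membership == cj] <- ci
    q_now <- q_now + gmax
    if (q_now > best_q + 1e-12) {
      best_q <- q_now
      best_membership <- membership
    }
  }

  labels <- match(best_membership, unique(best_membership))
  structure(list(labels = labels, n_communities = length(unique(labels)),
                 gamma = gamma, modularity = best_q),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities (gamma = %g, Q = %.4f)\n",
              x$n_communities, x$gamma, x$modularity))
  invisible(x)
}
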