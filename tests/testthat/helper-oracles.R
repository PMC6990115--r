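# Independent brute-force oracles for graph metrics, modularity and the
# small-instance Tucker problem. All pure R, definition-level implementations
# kept deliberately separate from the package's computation paths.

bf_net <- function(adj) binary_network(adj)

rand_adjacency <- function(n, p = 0.4) {
  a <- matrix(0, n, n)
  ut <- which(upper.tri(a))
  a[ut] <- as.numeric(stats::runif(length(ut)) < p)
  a + t(a)
}

# All labeled graphs on n nodes as adjacency matrices (2^(n(n-1)/2) graphs).
all_graphs <- function(n) {
  m <- n * (n - 1) / 2
  ut <- which(upper.tri(matrix(0, n, n)))
  lapply(0:(2^m - 1), function(code) {
    bits <- as.numeric(intToBits(code))[seq_len(m)]
    a <- matrix(0, n, n)
    a[ut] <- bits
    a + t(a)
  })
}

# Floyd-Warshall distances with shortest-path counts (row-vectorized).
bf_fw <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  cnt <- matrix(0, n, n)
  d[adj > 0] <- 1
  cnt[adj > 0] <- 1
  diag(d) <- 0
  diag(cnt) <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i == k) next
      alt <- d[i, k] + d[k, ]
      ok <- seq_len(n) != i & seq_len(n) != k
      better <- ok & alt < d[i, ]
      equal <- ok & is.finite(alt) & alt == d[i, ]
      if (any(better)) {
        d[i, better] <- alt[better]
        cnt[i, better] <- cnt[i, k] * cnt[k, better]
      }
      if (any(equal)) {
        cnt[i, equal] <- cnt[i, equal] + cnt[i, k] * cnt[k, equal]
      }
    }
  }
  list(d = d, cnt = cnt)
}

bf_degree <- function(adj) {
  vapply(seq_len(nrow(adj)), function(v) sum(adj[v, ] > 0), numeric(1))
}

bf_betweenness <- function(adj) {
  n <- nrow(adj)
  fw <- bf_fw(adj)
  b <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) {
      if (s == v) next
      t_ok <- seq_len(n) != v & seq_len(n) != s & is.finite(fw$d[s, ]) &
        is.finite(fw$d[s, v]) & is.finite(fw$d[v, ]) &
        fw$d[s, v] + fw$d[v, ] == fw$d[s, ]
      if (any(t_ok)) {
        tot <- tot + sum(fw$cnt[s, v] * fw$cnt[v, t_ok] / fw$cnt[s, t_ok])
      }
    }
    b[v] <- tot / 2 # each unordered pair counted twice
  }
  denom <- (n - 1) * (n - 2) / 2
  if (denom > 0) b / denom else b
}

bf_clustering <- function(adj) {
  vapply(seq_len(nrow(adj)), function(v) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    e <- sum(adj[nb, nb]) / 2
    2 * e / (k * (k - 1))
  }, numeric(1))
}

bf_global_eff <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- bf_fw(adj)$d
  inv <- 1 / d # 1/Inf = 0 covers disconnected pairs
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

bf_local_eff <- function(adj) {
  vals <- vapply(seq_len(nrow(adj)), function(v) {
    nb <- which(adj[v, ] > 0)
    if (length(nb) < 2) return(0)
    bf_global_eff(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

# Resolution-parameterized modularity, straight from the definition.
bf_modularity <- function(adj, membership, gamma = 1) {
  m2 <- sum(adj)
  if (m2 == 0) return(0)
  k <- rowSums(adj)
  same <- outer(membership, membership, "==")
  sum((adj - gamma * outer(k, k) / m2) * same) / m2
}

# All set partitions of 1..n via restricted growth strings.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(rgs, maxv) {
    if (length(rgs) == n) {
      out[[length(out) + 1L]] <<- rgs
      return(invisible())
    }
    for (v in seq_len(maxv + 1L)) {
      recurse(c(rgs, v), max(maxv, v))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Dense-grid oracle for the Q = R = 1 supervised Tucker fit with K = 2
# metrics: maximize ||W (c (x) b)||^2 over unit vectors. For a fixed unit
# c = (cos t, sin t), the optimum over b is the top singular value of
# M(t) = c1 W1 + c2 W2 (slices of the weighted class-mean matrix), solved
# exactly; t is scanned on a fine grid over [0, pi) (c and -c are
# equivalent) and refined by 1-D optimization. Independent of the
# alternating HOOI route.
bf_t3_loss_q1r1 <- function(xm, u, j, k, n_grid = 2000) {
  stopifnot(k == 2)
  ng <- colSums(u)
  w <- crossprod(u, xm) / sqrt(ng)
  ss <- sum(xm^2)
  w1 <- w[, seq_len(j), drop = FALSE]
  w2 <- w[, j + seq_len(j), drop = FALSE]
  g <- function(theta) {
    m <- cos(theta) * w1 + sin(theta) * w2
    max(svd(m, nu = 0, nv = 0)$d)^2
  }
  thetas <- seq(0, pi, length.out = n_grid + 1)
  vals <- vapply(thetas, g, numeric(1))
  i0 <- which.max(vals)
  lo <- thetas[max(1L, i0 - 1L)]
  hi <- thetas[min(length(thetas), i0 + 1L)]
  ref <- stats::optimize(g, c(lo, hi), maximum = TRUE, tol = 1e-12)$objective
  ss - max(ref, vals[i0])
}
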