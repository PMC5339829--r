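# Independent brute-force oracles used to validate the graph-metric and
# inference implementations. These deliberately share no code with the
# package: explicit loops, Floyd-Warshall, and the textbook step-up rule.

oracle_floyd <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (a in seq_along(nb))
      for (b in seq_along(nb))
        if (a < b && adj[nb[a], nb[b]] == 1) e <- e + 1
    ci[i] <- 2 * e / (k * (k - 1))
  }
  list(per_node = ci, Cp = mean(ci))
}

oracle_path_length <- function(adj) {
  d <- oracle_floyd(adj)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

oracle_global_eff <- function(adj) {
  d <- oracle_floyd(adj)
  n <- nrow(adj)
  per <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) if (j != i && is.finite(d[i, j])) s <- s + 1 / d[i, j]
    per[i] <- s / (n - 1)
  }
  list(per_node = per, Eglob = mean(per))
}

oracle_local_eff <- function(adj) {
  n <- nrow(adj)
  per <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) next
    per[i] <- oracle_global_eff(adj[nb, nb, drop = FALSE])$Eglob
  }
  list(per_node = per, Eloc = mean(per))
}

# textbook BH step-up: q_(k) = min_{j >= k} m * p_(j) / j, mapped back
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

random_adjacency <- function(n, p_edge = 0.3) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p_edge)
  a + t(a)
}

# tiny connectivity_matrix with planted group structure, bypassing simulation
fake_cm <- function(z) {
  n <- nrow(z)
  fisher_z(tanh((z + t(z)) / 2), roi_labels = sprintf("R%02d", seq_len(n)))
}
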