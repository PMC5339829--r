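test_that("metrics match closed forms on canonical toy graphs", {
  k3 <- as_binary_network(matrix(1, 3, 3))
  expect_equal(clustering_coefficient(k3)$per_node, rep(1, 3))
  expect_equal(characteristic_path_length(shortest_path_matrix(k3))$Lp, 1)
  expect_equal(global_efficiency(shortest_path_matrix(k3))$Eglob, 1)
  expect_equal(local_efficiency(k3)$per_node, rep(1, 3))

  star <- matrix(0L, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1L
  star <- as_binary_network(star)
  expect_equal(clustering_coefficient(star)$Cp, 0)
  expect_equal(local_efficiency(star)$Eloc, 0)

  p3 <- as_binary_network(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  d3 <- shortest_path_matrix(p3)
  expect_equal(d3[1, 3], 2)                         # path a-b-c
  expect_equal(characteristic_path_length(d3)$Lp, 4 / 3)
  ge <- global_efficiency(d3)
  expect_equal(ge$Eglob, 5 / 6)
  expect_equal(ge$per_node, c(3 / 4, 1, 3 / 4))

  # ring lattice N = 10, 2 neighbours per side: Cp = 0.5, Lp = 5/3
  ring <- ring_lattice(10, 2)
  expect_equal(clustering_coefficient(ring)$Cp, 0.5)
  expect_equal(characteristic_path_length(shortest_path_matrix(ring))$Lp,
               5 / 3)

  # complete graph: everything is 1
  k8 <- as_binary_network(matrix(1, 8, 8))
  expect_equal(clustering_coefficient(k8)$Cp, 1)
  expect_equal(local_efficiency(k8)$Eloc, 1)
  expect_equal(global_efficiency(shortest_path_matrix(k8))$Eglob, 1)
})

test_that("disconnected pairs are flagged and handled by both Lp conventions", {
  pair <- matrix(0L, 4, 4)
  pair[1, 2] <- pair[2, 1] <- 1L
  net <- as_binary_network(pair)
  d <- shortest_path_matrix(net)
  expect_true(is.infinite(d[1, 3]))
  res <- characteristic_path_length(d, "exclude")
  expect_equal(res$Lp, 1)
  expect_equal(res$n_excluded, 10)
  # harmonic convention: 1 / mean(1/d) over all ordered pairs
  expect_equal(characteristic_path_length(d, "harmonic")$Lp, 6)

  empty <- as_binary_network(matrix(0L, 3, 3))
  expect_error(characteristic_path_length(shortest_path_matrix(empty)),
               "no edges")
  expect_equal(global_efficiency(shortest_path_matrix(empty))$Eglob, 0)
})

test_that("metrics agree with independent brute-force oracles on random graphs", {
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(5:14, 1)
    adj <- random_adjacency(n, runif(1, 0.15, 0.6))
    net <- as_binary_network(adj)
    expect_equal(shortest_path_matrix(net), oracle_floyd(adj),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(clustering_coefficient(net)$per_node,
                 oracle_clustering(adj)$per_node, tolerance = 1e-12)
    d <- shortest_path_matrix(net)
    expect_equal(global_efficiency(d)$per_node,
                 oracle_global_eff(adj)$per_node, tolerance = 1e-12)
    expect_equal(local_efficiency(net)$per_node,
                 oracle_local_eff(adj)$per_node, tolerance = 1e-12)
  }
})

test_that("AUC integration matches closed forms and is linear", {
  g <- sparsity_grid()
  expect_equal(auc_of_curve(rep(3, 25), g), 0.72, tolerance = 1e-12)
  expect_equal(auc_of_curve(as.numeric(g), g), (0.34^2 - 0.10^2) / 2,
               tolerance = 1e-12)
  set.seed(6)
  y1 <- rnorm(25); y2 <- rnorm(25)
  expect_equal(auc_of_curve(2 * y1 - 3 * y2, g),
               2 * auc_of_curve(y1, g) - 3 * auc_of_curve(y2, g),
               tolerance = 1e-12)
  expect_error(auc_of_curve(1, structure(0.2, class = "sparsity_grid")),
               "2 grid points")
  expect_error(auc_of_curve(rep(1, 10), g), "values")
})

test_that("degree-preserving rewiring conserves degrees and destroys lattice clustering", {
  ring <- ring_lattice(20, 2)
  ens <- degree_preserving_randomize(ring, n_nets = 20, seed = 3)
  deg0 <- sort(colSums(ring$adjacency))
  for (b in ens) {
    expect_equal(sort(colSums(b$adjacency)), deg0, ignore_attr = TRUE)
    expect_equal(sum(b$adjacency) / 2, ring$edge_count)
  }
  cp_null <- mean(vapply(ens, function(b) clustering_coefficient(b)$Cp, 0))
  expect_lt(cp_null, clustering_coefficient(ring)$Cp)

  # determinism
  ens2 <- degree_preserving_randomize(ring, n_nets = 20, seed = 3)
  expect_equal(lapply(ens, `[[`, "adjacency"),
               lapply(ens2, `[[`, "adjacency"))

  # graphs without a legal swap return copies with a warning
  star <- matrix(0L, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1L
  expect_warning(copies <- degree_preserving_randomize(
    as_binary_network(star), n_nets = 3, seed = 1), "copies")
  expect_equal(copies[[1]]$adjacency, star, ignore_attr = TRUE)
})

test_that("small-world normalization is exact against self-ensembles", {
  net <- ring_lattice(30, 3)
  sw <- normalized_smallworld(net, list(net, net, net))
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)
  expect_error(normalized_smallworld(net, list()), "empty")
})

test_that("metric curves are node-relabel invariant with monotone Lp", {
  set.seed(12)
  cm <- fisher_z(stats::cor(matrix(rnorm(40 * 200), 200, 40)))
  g <- sparsity_grid(0.10, 0.30, 0.05)
  mc <- metric_curves(cm, g, n_null = 0)
  expect_equal(dim(mc$global), c(5, 7))
  expect_equal(dim(mc$nodal$degree), c(5, 40))

  # relabelling nodes leaves global curves unchanged
  perm <- sample(40)
  cmp <- cm
  cmp$z_values <- cm$z_values[perm, perm]
  cmp$roi_labels <- cm$roi_labels[perm]
  mcp <- metric_curves(cmp, g, n_null = 0)
  expect_equal(mcp$global[, c("Cp", "Lp", "Eglob", "Eloc")],
               mc$global[, c("Cp", "Lp", "Eglob", "Eloc")], tolerance = 1e-12)
  # nodal curves follow the permutation
  expect_equal(mcp$nodal$nodalEglob[, ], mc$nodal$nodalEglob[, perm],
               tolerance = 1e-12)

  # on (connected) random matrices Lp decreases with density
  lcf <- mc$admissibility$largest_component
  if (all(lcf == 1)) expect_true(all(diff(mc$global[, "Lp"]) <= 1e-12))

  # AUC summary covers 7 global + 3 x N nodal rows
  au <- auc_summary(mc)
  expect_equal(nrow(au), 7 + 3 * 40)
  expect_true(all(is.na(au$auc[au$metric %in% c("agamma", "alambda",
                                                "asigma")])))
})
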