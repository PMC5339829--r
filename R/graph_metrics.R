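#' Clustering coefficient (per node and network mean)
#'
#' For node i with degree k_i and e_i edges among its neighbours,
#' `C_i = 2 e_i / (k_i (k_i - 1))`, the fraction of a node's neighbour pairs
#' that are themselves connected; `C_i = 0` when `k_i < 2`. The network value
#' Cp -- a segregation measure -- is the mean over all N nodes.
#'
#' @param net a `binary_network`.
#' @return List with `per_node` (length-N vector) and `Cp`.
#' @export
#' @examples
#' tri <- as_binary_network(matrix(1, 3, 3))
#' clustering_coefficient(tri)$Cp  # 1
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  ci <- igraph::transitivity(net_graph(net), type = "local", isolates = "zero")
  list(per_node = ci, Cp = mean(ci))
}

#' Hop-distance matrix by breadth-first search
#'
#' @param net a `binary_network`.
#' @return N x N symmetric matrix of shortest hop counts, `Inf` for
#'   unreachable pairs, zero diagonal.
#' @export
shortest_path_matrix <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  igraph::distances(net_graph(net), algorithm = "unweighted")
}

#' Characteristic path length Lp
#'
#' Mean shortest hop distance over node pairs -- an integration measure
#' (smaller means better integrated). Two conventions for disconnected pairs
#' are provided: `"exclude"` (default) averages finite distances over
#' connected ordered pairs only and reports the exclusion count;
#' `"harmonic"` uses the harmonic mean `1 / mean(1/d)` with `1/Inf = 0`,
#' which penalizes disconnection instead of ignoring it.
#'
#' @param dist distance matrix from [shortest_path_matrix()].
#' @param disconnected `"exclude"` or `"harmonic"`.
#' @return List with `Lp` and `n_excluded` (ordered disconnected pairs).
#' @export
#' @examples
#' p3 <- as_binary_network(rbind(c(0,1,0), c(1,0,1), c(0,1,0)))
#' characteristic_path_length(shortest_path_matrix(p3))$Lp  # 4/3
characteristic_path_length <- function(dist,
                                       disconnected = c("exclude", "harmonic")) {
  disconnected <- match.arg(disconnected)
  off <- dist[row(dist) != col(dist)]
  finite <- is.finite(off)
  if (!any(finite)) stop_param("graph has no edges: path length undefined")
  n_excluded <- sum(!finite)
  lp <- switch(disconnected,
               exclude = mean(off[finite]),
               harmonic = 1 / mean(1 / off))
  list(Lp = lp, n_excluded = n_excluded)
}

#' Global efficiency (network and per node)
#'
#' `nodalEglob(i) = mean_{j != i} 1/d(i,j)` with `1/Inf = 0`; the network
#' global efficiency Eglob is the mean over nodes. Efficiency handles
#' disconnected pairs natively (they contribute zero).
#'
#' @param dist distance matrix from [shortest_path_matrix()].
#' @return List with `per_node` and `Eglob`.
#' @export
#' @examples
#' p3 <- as_binary_network(rbind(c(0,1,0), c(1,0,1), c(0,1,0)))
#' global_efficiency(shortest_path_matrix(p3))$Eglob  # 5/6
global_efficiency <- function(dist) {
  n <- nrow(dist)
  inv <- 1 / dist
  diag(inv) <- 0
  per_node <- rowSums(inv) / (n - 1)
  list(per_node = per_node, Eglob = mean(per_node))
}

#' Local efficiency (network and per node)
#'
#' The local efficiency of node i is the global efficiency of the subgraph
#' induced on i's neighbours (zero when the node has fewer than two
#' neighbours); the network value Eloc is the mean over nodes.
#'
#' @param net a `binary_network`.
#' @return List with `per_node` and `Eloc`.
#' @export
local_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  adj <- net$adjacency
  n <- nrow(adj)
  per_node <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1L)
    if (length(nb) < 2L) next
    sub <- adj[nb, nb, drop = FALSE]
    if (sum(sub) == 0L) next
    per_node[i] <- global_efficiency(dist_binary(sub))$Eglob
  }
  list(per_node = per_node, Eloc = mean(per_node))
}

# all-pairs hop distances of a small dense 0/1 adjacency by matrix-power BFS;
# avoids per-subgraph graph-object overhead in the local-efficiency loop
dist_binary <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  storage.mode(adj) <- "double"
  reach <- adj
  step <- 1
  repeat {
    new <- reach > 0 & !is.finite(d)
    if (!any(new)) break
    d[new] <- step
    if (step >= n) break
    reach <- reach %*% adj
    step <- step + 1
  }
  d
}

#' Degree-preserving random network ensemble
#'
#' Generates null networks with the same number of nodes, edges, and exactly
#' the same degree sequence as the input, by Maslov-Sneppen double-edge swaps
#' (rewiring trials default to 10x the edge count; swaps creating self-loops
#' or multi-edges are rejected). If rewiring cannot change the graph (e.g. a
#' star), unchanged copies are returned with a warning.
#'
#' @param net a `binary_network` with at least 2 edges.
#' @param n_nets ensemble size (the conventional null uses 100).
#' @param seed integer seed; the ensemble is reproducible given it.
#' @param swaps_per_edge rewiring trials per edge.
#' @return List of `binary_network` objects.
#' @export
#' @examples
#' ring <- ring_lattice(20, 2)
#' ens <- degree_preserving_randomize(ring, n_nets = 5, seed = 1)
#' identical(sort(colSums(ens[[1]]$adjacency)), sort(colSums(ring$adjacency)))
degree_preserving_randomize <- function(net, n_nets = 100, seed = 1,
                                        swaps_per_edge = 10) {
  stopifnot(inherits(net, "binary_network"))
  if (net$edge_count < 2) stop_param("need at least 2 edges to rewire")
  g <- net_graph(net)
  niter <- swaps_per_edge * igraph::ecount(g)
  set.seed(as.integer(seed))
  out <- vector("list", n_nets)
  changed <- FALSE
  for (k in seq_len(n_nets)) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                   niter = niter))
    adj <- as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE))
    if (!changed && any(adj != net$adjacency)) changed <- TRUE
    bn <- as_binary_network(adj, net$sparsity)
    bn$igraph <- gr
    out[[k]] <- bn
  }
  if (!changed)
    warning("no legal degree-preserving swap changed the graph; returning copies")
  out
}

#' Small-world normalization against a null ensemble
#'
#' gamma = Cp / <Cp_rand>, lambda = Lp / <Lp_rand>, sigma = gamma / lambda,
#' where the angle brackets are means over the degree-preserving ensemble.
#' A small-world network has gamma >> 1, lambda ~ 1, hence sigma > 1.
#'
#' @param net a `binary_network`.
#' @param ensemble list of null networks from
#'   [degree_preserving_randomize()].
#' @param disconnected passed to [characteristic_path_length()].
#' @return List with `gamma`, `lambda`, `sigma`, `Cp`, `Lp`, `Cp_rand`,
#'   `Lp_rand`.
#' @export
normalized_smallworld <- function(net, ensemble,
                                  disconnected = c("exclude", "harmonic")) {
  disconnected <- match.arg(disconnected)
  if (length(ensemble) == 0L) stop_param("null ensemble is empty")
  cp <- clustering_coefficient(net)$Cp
  lp <- characteristic_path_length(shortest_path_matrix(net), disconnected)$Lp
  cps <- vapply(ensemble, function(b) clustering_coefficient(b)$Cp, 0)
  lps <- vapply(ensemble, function(b)
    characteristic_path_length(shortest_path_matrix(b), disconnected)$Lp, 0)
  cp_rand <- mean(cps)
  lp_rand <- mean(lps)
  if (cp_rand <= 0 || lp_rand <= 0)
    stop_param("null ensemble mean metrics must be positive")
  gamma <- cp / cp_rand
  lambda <- lp / lp_rand
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       Cp = cp, Lp = lp, Cp_rand = cp_rand, Lp_rand = lp_rand)
}

#' All metric curves for one subject across the sparsity grid
#'
#' At each grid point the connectivity matrix is thresholded and the global
#' metrics (Cp, Lp, gamma, lambda, sigma, Eglob, Eloc) and nodal metrics
#' (degree, nodal global efficiency, nodal local efficiency) are computed;
#' gamma/lambda/sigma use a fresh degree-preserving ensemble per sparsity
#' (set `n_null = 0` to skip normalization, leaving them `NA`).
#'
#' @param cm a `connectivity_matrix` (made non-negative internally).
#' @param grid a [sparsity_grid()].
#' @param n_null null networks per sparsity.
#' @param seed integer seed for the null ensembles.
#' @param disconnected convention for disconnected pairs in Lp.
#' @param log_base degree-criterion log base for admissibility flags.
#' @param metrics subset of `c("Cp", "Lp", "Eglob", "Eloc", "degree",
#'   "nodalEglob", "nodalEloc")` to compute (all by default); skipped
#'   metrics are `NA` in the output. Restricting the set (local efficiency
#'   in particular) speeds up large simulation studies.
#' @return Object of class `metric_curves`: `grid`; `global` (matrix,
#'   grid x 7 metrics); `nodal` (list of three grid x N matrices: `degree`,
#'   `nodalEglob`, `nodalEloc`); `admissibility` (data.frame per grid point);
#'   `roi_labels`.
#' @export
metric_curves <- function(cm, grid = sparsity_grid(), n_null = 100, seed = 1,
                          disconnected = c("exclude", "harmonic"),
                          log_base = "e",
                          metrics = c("Cp", "Lp", "Eglob", "Eloc", "degree",
                                      "nodalEglob", "nodalEloc")) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  disconnected <- match.arg(disconnected)
  cm <- positive_part(cm)
  n <- length(cm$roi_labels)
  ng <- length(grid)
  gl <- matrix(NA_real_, ng, 7,
               dimnames = list(NULL, c("Cp", "Lp", "gamma", "lambda", "sigma",
                                       "Eglob", "Eloc")))
  nodal <- list(degree = matrix(NA_real_, ng, n),
                nodalEglob = matrix(NA_real_, ng, n),
                nodalEloc = matrix(NA_real_, ng, n))
  adm <- data.frame(sparsity = as.numeric(grid), edge_count = NA_integer_,
                    mean_degree = NA_real_, largest_component = NA_real_,
                    n_excluded_pairs = NA_integer_, saturated = FALSE,
                    admissible_degree = NA, admissible_smallworld = NA)
  need_dist <- any(c("Lp", "Eglob", "nodalEglob") %in% metrics)
  for (gi in seq_len(ng)) {
    net <- suppressWarnings(threshold_by_sparsity(cm, grid[gi]))
    lp <- list(Lp = NA_real_, n_excluded = NA_integer_)
    if ("Cp" %in% metrics) gl[gi, "Cp"] <- clustering_coefficient(net)$Cp
    if (need_dist) {
      dist <- shortest_path_matrix(net)
      if ("Lp" %in% metrics) {
        lp <- characteristic_path_length(dist, disconnected)
        gl[gi, "Lp"] <- lp$Lp
      }
      if (any(c("Eglob", "nodalEglob") %in% metrics)) {
        ge <- global_efficiency(dist)
        if ("Eglob" %in% metrics) gl[gi, "Eglob"] <- ge$Eglob
        if ("nodalEglob" %in% metrics) nodal$nodalEglob[gi, ] <- ge$per_node
      }
    }
    if (any(c("Eloc", "nodalEloc") %in% metrics)) {
      le <- local_efficiency(net)
      if ("Eloc" %in% metrics) gl[gi, "Eloc"] <- le$Eloc
      if ("nodalEloc" %in% metrics) nodal$nodalEloc[gi, ] <- le$per_node
    }
    sigma <- NA_real_
    if (n_null > 0) {
      ens <- degree_preserving_randomize(net, n_nets = n_null,
                                         seed = derive_seed(seed, "nulls", gi))
      sw <- normalized_smallworld(net, ens, disconnected)
      gl[gi, "gamma"] <- sw$gamma
      gl[gi, "lambda"] <- sw$lambda
      gl[gi, "sigma"] <- sigma <- sw$sigma
      gl[gi, "Cp"] <- sw$Cp
      gl[gi, "Lp"] <- sw$Lp
    }
    if ("degree" %in% metrics) nodal$degree[gi, ] <- colSums(net$adjacency)
    net <- check_admissibility(net, sigma, log_base)
    adm$edge_count[gi] <- net$edge_count
    adm$mean_degree[gi] <- net$mean_degree
    adm$largest_component[gi] <- largest_component_fraction(net)
    adm$n_excluded_pairs[gi] <- lp$n_excluded
    adm$saturated[gi] <- net$saturated
    adm$admissible_degree[gi] <- net$admissible_degree
    adm$admissible_smallworld[gi] <- net$admissible_smallworld
  }
  structure(list(grid = as.numeric(grid), global = gl, nodal = nodal,
                 admissibility = adm, roi_labels = cm$roi_labels),
            class = "metric_curves")
}

#' Area under a metric curve over the sparsity grid
#'
#' Trapezoidal integration of a metric's values across the sparsity grid,
#' yielding one threshold-independent scalar per metric (aCp, aLp, ...).
#' Exact for piecewise-linear curves; for a constant curve c the result is
#' `c * (s_max - s_min)`.
#'
#' @param values numeric vector of metric values, one per grid point.
#' @param grid matching [sparsity_grid()] (>= 2 points).
#' @return The AUC scalar.
#' @export
#' @examples
#' auc_of_curve(rep(3, 25), sparsity_grid())  # 0.72
auc_of_curve <- function(values, grid = sparsity_grid()) {
  grid <- as.numeric(grid)
  if (length(grid) < 2L) stop_param("AUC needs at least 2 grid points")
  if (length(values) != length(grid))
    stop_param("curve has %d values but the grid has %d points",
               length(values), length(grid))
  sum((values[-1] + values[-length(values)]) / 2 * diff(grid))
}

#' AUC summaries of all curves of one subject
#'
#' @param curves a [metric_curves()] object.
#' @return data.frame with columns `metric` (aCp, aLp, agamma, alambda,
#'   asigma, aEglob, aEloc, anodalDeg, anodalEglob, anodalEloc), `node`
#'   (label, `"global"` for global metrics), `auc`.
#' @export
auc_summary <- function(curves) {
  stopifnot(inherits(curves, "metric_curves"))
  grid <- curves$grid
  gl <- curves$global
  global_names <- c(Cp = "aCp", Lp = "aLp", gamma = "agamma",
                    lambda = "alambda", sigma = "asigma", Eglob = "aEglob",
                    Eloc = "aEloc")
  rows <- lapply(colnames(gl), function(m) {
    v <- gl[, m]
    data.frame(metric = unname(global_names[m]), node = "global",
               auc = if (any(is.na(v))) NA_real_ else auc_of_curve(v, grid))
  })
  nodal_names <- c(degree = "anodalDeg", nodalEglob = "anodalEglob",
                   nodalEloc = "anodalEloc")
  for (m in names(curves$nodal)) {
    aucs <- apply(curves$nodal[[m]], 2L, auc_of_curve, grid = grid)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = unname(nodal_names[m]), node = curves$roi_labels, auc = aucs)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ring lattice generator
#'
#' Each of n nodes is linked to its k nearest neighbours per side; the
#' canonical locally clustered, long-pathed reference topology.
#'
#' @param n number of nodes.
#' @param k neighbours per side.
#' @return A `binary_network`.
#' @export
#' @examples
#' clustering_coefficient(ring_lattice(10, 2))$Cp  # 0.5
ring_lattice <- function(n, k) {
  d <- ring_distance(n)
  as_binary_network((d >= 1 & d <= k) * 1L)
}

#' @export
print.metric_curves <- function(x, ...) {
  cat(sprintf("<metric_curves> %d sparsities x (7 global + 3 x %d nodal) metrics\n",
              length(x$grid), length(x$roi_labels)))
  invisible(x)
}
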