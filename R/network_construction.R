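#' Sparsity grid for network thresholding
#'
#' The sparsity S of a binary network is the fraction of all possible edges
#' retained. Small-world parameters are estimated over a range of sparsities
#' rather than a single arbitrary threshold; the default grid 0.10-0.34 in
#' steps of 0.01 (25 points) spans the range where such parameters are
#' estimable while spurious edges stay limited.
#'
#' @param s_min,s_max grid endpoints, `0 < s_min <= s_max < 1`.
#' @param step grid spacing (> 0).
#' @return Numeric vector of class `sparsity_grid` containing the inclusive
#'   grid.
#' @export
#' @examples
#' length(sparsity_grid())  # 25
sparsity_grid <- function(s_min = 0.10, s_max = 0.34, step = 0.01) {
  if (!(s_min > 0 && s_min <= s_max && s_max < 1))
    stop_param("need 0 < s_min <= s_max < 1")
  if (step <= 0) stop_param("step must be > 0")
  k <- floor((s_max - s_min) / step + 1e-9)
  structure(s_min + step * (0:k), class = "sparsity_grid")
}

#' Threshold a connectivity matrix at a fixed sparsity
#'
#' Keeps the `K = round_half_up(s * N(N-1)/2)` edges with the largest
#' connectivity values and binarizes. Ties are broken deterministically by
#' ascending (row, column) index after sorting by descending value. If fewer
#' than K positive entries exist the network saturates: all positive entries
#' are kept and a warning is recorded on the returned object.
#'
#' @param cm a `connectivity_matrix`; should be non-negative (apply
#'   [positive_part()] first).
#' @param s target sparsity in (0, 1).
#' @return An object of class `binary_network`: `adjacency` (0/1 symmetric,
#'   zero diagonal), `sparsity`, `edge_count`, `saturated`, and admissibility
#'   flags (`NA` until [check_admissibility()] fills them).
#' @export
#' @examples
#' cm <- fisher_z(cor(matrix(rnorm(2000), 100, 20)))
#' net <- threshold_by_sparsity(positive_part(cm), 0.2)
#' net$edge_count
threshold_by_sparsity <- function(cm, s) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (!is.numeric(s) || length(s) != 1L || s <= 0 || s >= 1)
    stop_param("sparsity must lie strictly between 0 and 1, got %s", format(s))
  z <- cm$z_values
  n <- nrow(z)
  max_edges <- n * (n - 1) / 2
  k <- round_half_up(s * max_edges)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  vals <- z[upper.tri(z)]
  pos <- vals > 0
  saturated <- sum(pos) < k
  if (saturated) {
    warning(sprintf(
      "only %d positive entries available for %d requested edges (s = %g); keeping all",
      sum(pos), k, s))
    keep <- which(pos)
  } else {
    ord <- order(-vals, ut[, 1], ut[, 2])
    keep <- ord[seq_len(k)]
  }
  adj <- matrix(0L, n, n)
  adj[ut[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  dimnames(adj) <- list(cm$roi_labels, cm$roi_labels)
  structure(list(adjacency = adj, sparsity = s,
                 edge_count = length(keep), saturated = saturated,
                 admissible_degree = NA, admissible_smallworld = NA),
            class = "binary_network")
}

#' Wrap an adjacency matrix as a binary network
#'
#' Convenience constructor for metric functions and tests; the diagonal is
#' zeroed and the matrix is taken as undirected.
#'
#' @param adj 0/1 symmetric adjacency matrix.
#' @param sparsity optional sparsity annotation.
#' @return A `binary_network`.
#' @export
as_binary_network <- function(adj, sparsity = NA_real_) {
  adj <- as.matrix(adj)
  mode(adj) <- "integer"
  diag(adj) <- 0L
  structure(list(adjacency = adj, sparsity = sparsity,
                 edge_count = sum(adj) / 2, saturated = FALSE,
                 admissible_degree = NA, admissible_smallworld = NA),
            class = "binary_network")
}

net_graph <- function(net) {
  if (!is.null(net$igraph)) return(net$igraph)
  adj <- net$adjacency
  ij <- which(adj == 1L & upper.tri(adj), arr.ind = TRUE)
  igraph::make_graph(as.numeric(t(ij)), n = nrow(adj), directed = FALSE)
}

#' Fraction of nodes in the largest connected component
#'
#' Used to verify that thresholded networks remain (nearly) connected across
#' the sparsity grid.
#'
#' @param net a `binary_network`.
#' @return A fraction in (0, 1]; 1 iff the network is connected.
#' @export
largest_component_fraction <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  comp <- igraph::components(net_graph(net))
  max(comp$csize) / nrow(net$adjacency)
}

#' Evaluate threshold admissibility criteria
#'
#' Two criteria are recorded per network: the mean degree must exceed
#' `2 * log(N)` (the log base is configurable because the convention is
#' ambiguous: with the natural log the densest end of the default grid is
#' marginal, with base 10 it passes easily), and the small-worldness sigma
#' must exceed 1.1 (strict inequality). Failures do not abort an analysis;
#' they are flagged and reported.
#'
#' @param net a `binary_network`.
#' @param sigma small-worldness of this network, as computed by
#'   [normalized_smallworld()]; `NA` leaves the small-world flag `NA`.
#' @param log_base one of `"e"`, `"10"`, `"2"`.
#' @return `net` with `admissible_degree`, `admissible_smallworld`, and
#'   `mean_degree` filled in.
#' @export
#' @examples
#' adj <- matrix(1, 6, 6); diag(adj) <- 0
#' check_admissibility(as_binary_network(adj), sigma = 1.0)$admissible_degree
check_admissibility <- function(net, sigma = NA_real_, log_base = c("e", "10", "2")) {
  stopifnot(inherits(net, "binary_network"))
  log_base <- match.arg(log_base)
  n <- nrow(net$adjacency)
  base <- switch(log_base, e = exp(1), `10` = 10, `2` = 2)
  mean_degree <- 2 * net$edge_count / n
  net$mean_degree <- mean_degree
  net$admissible_degree <- mean_degree > 2 * log(n, base = base)
  net$admissible_smallworld <- if (is.na(sigma)) NA else sigma > 1.1
  net
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges (sparsity %.3f)%s\n",
              nrow(x$adjacency), x$edge_count,
              x$sparsity, if (isTRUE(x$saturated)) " [saturated]" else ""))
  invisible(x)
}
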