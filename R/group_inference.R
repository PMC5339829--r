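#' Pooled-variance two-sample t-test
#'
#' Two-tailed t statistic with pooled variance and `n_x + n_y - 2` degrees of
#' freedom.
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @return List with `t`, `p`, `df`.
#' @seealso [t_from_summary()] for the same test from printed summary
#'   statistics.
#' @export
#' @examples
#' two_sample_t(rnorm(10), rnorm(10))$df  # 18
two_sample_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop_param("each sample needs at least 2 observations")
  t_from_summary(mean(x), stats::sd(x), length(x),
                 mean(y), stats::sd(y), length(y))
}

#' Pooled two-sample t from summary statistics
#'
#' Computes the pooled-variance two-sample t-test from group means, standard
#' deviations and sizes, e.g. to check statistics against values printed in a
#' demographics table.
#'
#' @param mean_x,sd_x,n_x first group summary.
#' @param mean_y,sd_y,n_y second group summary.
#' @return List with `t` (sign of `mean_x - mean_y`), `p`, `df`.
#' @export
#' @examples
#' # LSAS-style comparison: 69.40 (26.84) vs 20.29 (15.71), n = 42 each
#' t_from_summary(69.40, 26.84, 42, 20.29, 15.71, 42)$t
t_from_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y) {
  if (n_x < 2 || n_y < 2) stop_param("each group needs n >= 2")
  df <- n_x + n_y - 2
  sp2 <- ((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / df
  if (sp2 <= 0) stop_param("zero pooled variance: t undefined")
  t <- (mean_x - mean_y) / sqrt(sp2 * (1 / n_x + 1 / n_y))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up FDR adjustment with monotonicity enforcement.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop_param("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Edgewise group comparison of connectivity matrices
#'
#' One pooled two-sample t-test per unique off-diagonal region pair
#' (`N(N-1)/2` tests) on Fisher-z connectivity values, followed by
#' Benjamini-Hochberg FDR across the whole edge family.
#'
#' @param z_list list of `connectivity_matrix` objects, one per subject.
#' @param groups factor/character vector; the first level (or `"patient"` if
#'   present) minus the other defines the reported direction.
#' @return data.frame with one row per edge: `i`, `j`, `i_label`, `j_label`,
#'   `t`, `p`, `q`, `direction` (sign of patient - control mean).
#' @export
edgewise_group_test <- function(z_list, groups) {
  stopifnot(length(z_list) == length(groups))
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stop_param("exactly two groups required, got %d",
                                   length(lv))
  if ("patient" %in% lv) lv <- c("patient", setdiff(lv, "patient"))
  labels <- z_list[[1]]$roi_labels
  n <- length(labels)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  zmat <- vapply(z_list, function(cm) cm$z_values[upper.tri(cm$z_values)],
                 numeric(nrow(ut)))
  g1 <- groups == lv[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop_param("each group needs >= 2 subjects")
  m1 <- rowMeans(zmat[, g1, drop = FALSE])
  m2 <- rowMeans(zmat[, !g1, drop = FALSE])
  v1 <- apply(zmat[, g1, drop = FALSE], 1L, stats::var)
  v2 <- apply(zmat[, !g1, drop = FALSE], 1L, stats::var)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tval), df)
  # edges with zero pooled variance (e.g. uniformly zeroed negatives)
  degen <- sp2 <= 0
  tval[degen] <- ifelse(m1[degen] == m2[degen], 0, Inf * sign(m1 - m2)[degen])
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  data.frame(i = ut[, 1], j = ut[, 2],
             i_label = labels[ut[, 1]], j_label = labels[ut[, 2]],
             t = tval, p = p, q = bh_fdr(p),
             direction = sign(m1 - m2))
}

#' Residualize a per-subject quantity on nuisance covariates
#'
#' Ordinary least-squares residuals of the values on an intercept plus the
#' supplied covariates over the pooled sample (age and sex in the canonical
#' design; sex is coded 0/1 internally). Collinear covariates trigger a
#' pseudo-inverse fit with a warning.
#'
#' @param values numeric vector, one value per subject.
#' @param covariates data.frame or matrix of per-subject covariates; factors
#'   and character columns are coded as 0/1 contrasts.
#' @return Residual vector (mean zero, orthogonal to the covariates).
#' @export
covariate_adjust <- function(values, covariates = NULL) {
  values <- as.numeric(values)
  x <- matrix(1, length(values), 1L)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(values))
      stop_param("covariates have %d rows for %d values", nrow(covariates),
                 length(values))
    for (nm in names(covariates)) {
      col <- covariates[[nm]]
      if (is.character(col) || is.factor(col))
        col <- as.numeric(factor(col)) - 1
      x <- cbind(x, as.numeric(col))
    }
  }
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x))
    warning("collinear covariates; residualizing with a pseudo-inverse fit")
  as.numeric(qr.resid(qr_x, values))
}

#' Covariate-adjusted permutation test for a group difference
#'
#' The statistic is the difference of group means of covariate-adjusted
#' values (first group minus second, with `"patient"` taken first when
#' present). The null distribution is built by permuting group labels
#' (preserving group sizes); the two-tailed p-value uses the add-one
#' estimator `p = (1 + #{|delta_perm| >= |delta_obs|}) / (1 + n_perm)`, so
#' the smallest attainable p is `1/(n_perm + 1)`.
#'
#' @param values per-subject scalar (e.g. an AUC metric).
#' @param groups two-group labels.
#' @param covariates optional covariates passed to [covariate_adjust()].
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return List of class `permutation_result`: `observed_difference`, `p`,
#'   `n_perm`, `null_mean`, `null_sd`, `groups` (ordered levels).
#' @export
permutation_group_test <- function(values, groups, covariates = NULL,
                                   n_perm = 10000, seed = 1) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stop_param("exactly two groups required")
  if ("patient" %in% lv) lv <- c("patient", setdiff(lv, "patient"))
  g1 <- groups == lv[1]
  if (sum(g1) < 2 || sum(!g1) < 2) stop_param("each group needs >= 2 subjects")
  adj <- covariate_adjust(values, covariates)
  delta_obs <- mean(adj[g1]) - mean(adj[!g1])
  set.seed(as.integer(seed))
  n <- length(adj)
  n1 <- sum(g1)
  deltas <- vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(n, n1)
    (sum(adj[idx]) / n1) - (sum(adj[-idx]) / (n - n1))
  }, 0)
  # scale-aware tolerance so numerically-zero observed differences are not
  # beaten by exactly-zero permutation draws
  eps <- 1e-12 * (max(abs(adj)) + 1)
  p <- (1 + sum(abs(deltas) >= abs(delta_obs) - eps)) / (1 + n_perm)
  structure(list(observed_difference = delta_obs, p = p, n_perm = n_perm,
                 null_mean = mean(deltas), null_sd = stats::sd(deltas),
                 groups = lv),
            class = "permutation_result")
}

#' Permutation tests across a family of metrics
#'
#' Applies [permutation_group_test()] to each column of a subject x metric
#' matrix and, for nodal families, adds Benjamini-Hochberg q-values across
#' the family. Global metrics are conventionally reported unadjusted
#' (`fdr = FALSE`).
#'
#' @param value_matrix numeric matrix, subjects in rows, metrics in columns.
#' @param groups,covariates,n_perm,seed as in [permutation_group_test()].
#' @param fdr apply BH across the columns.
#' @return data.frame with `metric`, `delta` (patient - control, adjusted),
#'   `p`, and `q` when `fdr` is `TRUE`.
#' @export
permutation_family_test <- function(value_matrix, groups, covariates = NULL,
                                    n_perm = 10000, seed = 1, fdr = TRUE) {
  value_matrix <- as.matrix(value_matrix)
  res <- lapply(seq_len(ncol(value_matrix)), function(j)
    permutation_group_test(value_matrix[, j], groups, covariates, n_perm,
                           derive_seed(seed, "family", j)))
  out <- data.frame(metric = colnames(value_matrix) %||%
                      sprintf("m%03d", seq_len(ncol(value_matrix))),
                    delta = vapply(res, `[[`, 0, "observed_difference"),
                    p = vapply(res, `[[`, 0, "p"))
  if (fdr) out$q <- bh_fdr(out$p)
  out
}

#' Spearman correlation between a network metric and a clinical scale
#'
#' Rank correlation with mid-rank ties, computed over the patient group.
#' The two-tailed p-value uses the t approximation for n >= 10 and exact
#' enumeration below that.
#'
#' @param values per-patient network metric.
#' @param score per-patient clinical score.
#' @return List with `rho`, `p`, `n`.
#' @export
#' @examples
#' spearman_clinical(1:5, c(2, 1, 4, 3, 5))$rho  # 0.8
spearman_clinical <- function(values, score) {
  ok <- is.finite(values) & is.finite(score)
  values <- values[ok]; score <- score[ok]
  n <- length(values)
  if (n < 4L) stop_param("need at least 4 paired observations, got %d", n)
  if (stats::sd(values) == 0 || stats::sd(score) == 0)
    stop_param("constant input: rank correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(values, score, method = "spearman", exact = n < 10))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> delta(%s - %s) = %.4g, p = %.4g (%d permutations)\n",
              x$groups[1], x$groups[2], x$observed_difference, x$p, x$n_perm))
  invisible(x)
}
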