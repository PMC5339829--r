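#' Construct a regional time-series object
#'
#' Wraps a T x N matrix of regional (ROI) BOLD signals together with the
#' sampling interval and region labels. Columns are network nodes; the study
#' design this package targets uses the 90-region AAL parcellation sampled at
#' TR = 2 s for 200 volumes, but any T x N matrix with N >= 3 is accepted.
#'
#' @param values numeric T x N matrix (timepoints x regions).
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @param roi_labels character vector of N region names; defaults to the
#'   AAL-90 abbreviations when N = 90, otherwise `ROI_001` style labels.
#' @return An object of class `roi_time_series` with elements `values`,
#'   `tr_seconds`, `roi_labels`.
#' @export
#' @examples
#' ts <- roi_time_series(matrix(rnorm(60), 20, 3), tr_seconds = 2)
#' dim(ts$values)
roi_time_series <- function(values, tr_seconds = 2, roi_labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_param("time-series values must be numeric")
  if (any(!is.finite(values))) stop_param("time series contains NaN/Inf values")
  n <- ncol(values)
  if (n < 3L) stop_param("need at least 3 regions, got %d", n)
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop_param("`tr_seconds` must be a positive duration")
  sds <- apply(values, 2L, stats::sd)
  if (is.null(roi_labels)) roi_labels <- default_roi_labels(n)
  if (length(roi_labels) != n)
    stop_param("roi_labels has length %d but there are %d regions",
               length(roi_labels), n)
  if (any(sds == 0))
    stop_param("constant (zero-variance) column(s): %s",
               paste(roi_labels[sds == 0], collapse = ", "))
  colnames(values) <- roi_labels
  structure(list(values = values, tr_seconds = tr_seconds,
                 roi_labels = roi_labels),
            class = "roi_time_series")
}

default_roi_labels <- function(n) {
  if (n == 90L) aal90_labels()$abbrev else sprintf("ROI_%03d", seq_len(n))
}

#' AAL-90 region labels
#'
#' The 90 cortical/subcortical regions of the Automated Anatomical Labeling
#' atlas (45 per hemisphere, odd indices left, even right), shipped as package
#' data and used as default node labels.
#'
#' @return data.frame with columns `index`, `abbrev`, `name`.
#' @export
#' @examples
#' head(aal90_labels())
aal90_labels <- function() {
  path <- system.file("extdata", "aal90_labels.tsv", package = "restnet")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read one subject's time series from a TSV file
#'
#' Plain-text format: T rows x N tab-separated numbers, no header.
#'
#' @param path file path.
#' @inheritParams roi_time_series
#' @return A [roi_time_series()] object.
#' @export
read_time_series <- function(path, tr_seconds = 2, roi_labels = NULL) {
  if (!file.exists(path)) stop_param("time-series file not found: %s", path)
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
  if (any(is.na(m))) stop_param("NaN cells in time-series file: %s", path)
  dimnames(m) <- NULL
  roi_time_series(m, tr_seconds = tr_seconds, roi_labels = roi_labels)
}

#' Write one subject's time series to TSV
#'
#' @param ts a [roi_time_series()] object or numeric matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_time_series <- function(ts, path) {
  m <- if (inherits(ts, "roi_time_series")) ts$values else as.matrix(ts)
  utils::write.table(format(m, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pearson correlation matrix between regional time series
#'
#' Interregional functional connectivity: the Pearson correlation between the
#' regional mean time series of every pair of regions.
#'
#' @param ts a [roi_time_series()] object or numeric T x N matrix.
#' @return N x N symmetric correlation matrix with unit diagonal.
#' @export
#' @examples
#' ts <- roi_time_series(matrix(rnorm(300), 100, 3))
#' range(pearson_matrix(ts))
pearson_matrix <- function(ts) {
  m <- if (inherits(ts, "roi_time_series")) ts$values else as.matrix(ts)
  labels <- colnames(m) %||% default_roi_labels(ncol(m))
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop_param("cannot correlate constant region(s): %s",
               paste(labels[sds == 0], collapse = ", "))
  r <- stats::cor(m)
  dimnames(r) <- list(labels, labels)
  r
}

#' Fisher z transform of a correlation matrix
#'
#' Applies z = atanh(r) elementwise off the diagonal. To keep the transform
#' finite for (near-)duplicated signals, |r| is clamped at 1 - 1e-7 first; the
#' diagonal is fixed at zero and excluded from all downstream edge counts.
#'
#' @param corr numeric correlation matrix with entries in `[-1, 1]`.
#' @param roi_labels optional region names (defaults to `corr` dimnames).
#' @return An object of class `connectivity_matrix` with elements `z_values`
#'   (symmetric, zero diagonal, finite) and `roi_labels`.
#' @export
#' @examples
#' fisher_z(diag(3))$z_values
fisher_z <- function(corr, roi_labels = NULL) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr)) stop_param("correlation matrix must be square")
  if (any(is.na(corr)) || any(abs(corr) > 1 + 1e-12))
    stop_param("correlation entries must be finite and within [-1, 1]")
  labels <- roi_labels %||% colnames(corr) %||% default_roi_labels(ncol(corr))
  r <- pmin(pmax(corr, -1 + 1e-7), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2
  dimnames(z) <- list(labels, labels)
  structure(list(z_values = z, roi_labels = labels),
            class = "connectivity_matrix")
}

#' Restrict a connectivity matrix to positive couplings
#'
#' Negative edges have an ambiguous physiological interpretation and are
#' zeroed before network construction; the operation is idempotent.
#'
#' @param cm a `connectivity_matrix`.
#' @return A `connectivity_matrix` with all entries >= 0.
#' @export
positive_part <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  cm$z_values <- pmax(cm$z_values, 0)
  cm
}

#' Write a connectivity matrix as labelled TSV
#'
#' @param cm a `connectivity_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  df <- data.frame(roi = cm$roi_labels, cm$z_values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d regions, Fisher-z range [%.3f, %.3f]\n",
              length(x$roi_labels), min(x$z_values), max(x$z_values)))
  invisible(x)
}

#' @export
print.roi_time_series <- function(x, ...) {
  cat(sprintf("<roi_time_series> %d timepoints x %d regions, TR = %g s\n",
              nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}
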