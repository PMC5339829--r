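#' t-test feature screening
#'
#' Keeps the feature columns whose pooled two-sample t-test between the
#' groups has `p < alpha` (uncorrected). In honest cross-validation the
#' screening is re-run inside every training fold ([loocv()] does this by
#' default); applying it once on the whole sample before cross-validation
#' reproduces the optimistic historical protocol and is available as
#' `whole_sample_selection` there.
#'
#' @param features numeric matrix, subjects x named features.
#' @param labels two-group labels.
#' @param alpha screening level.
#' @return Integer vector of selected column indices (named).
#' @export
select_features <- function(features, labels, alpha = 0.05) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stop_param("exactly two groups required")
  g1 <- labels == lv[1]
  p <- vapply(seq_len(ncol(features)), function(j) {
    x <- features[g1, j]; y <- features[!g1, j]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) return(1)
    two_sample_t(x, y)$p
  }, 0)
  keep <- which(p < alpha)
  if (length(keep) == 0L)
    stop_param("no feature passed screening at alpha = %g", alpha)
  names(keep) <- colnames(features)[keep]
  keep
}

#' Fit a maximum-uncertainty linear discriminant (MLDA) model
#'
#' Classical LDA inverts the pooled within-class covariance, which is
#' singular when features outnumber subjects. MLDA replaces it by a
#' maximum-entropy selection: the pooled covariance is eigendecomposed and
#' every eigenvalue below the eigenvalue mean is raised to that mean,
#' giving a well-conditioned, always-invertible S*. The discriminant is
#' `w = S*^-1 (mu1 - mu2)` with the equal-prior midpoint threshold
#' `w . (mu1 + mu2) / 2`. When all eigenvalues already equal their mean
#' (spherical pooled covariance) the repair is a no-op and MLDA coincides
#' with classical LDA.
#'
#' @param features numeric matrix, subjects x features.
#' @param labels two-group labels; `"patient"` (when present) is class 1,
#'   the positive class.
#' @return Object of class `mlda_model`: `class_means`, `pooled_covariance`,
#'   `repaired_covariance`, `w`, `threshold`, `classes`, `feature_names`.
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(40, 2), 20), matrix(rnorm(40, -2), 20))
#' m <- mlda_fit(x, rep(c("patient", "control"), each = 20))
#' m$classes
mlda_fit <- function(features, labels) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("f%03d", seq_len(ncol(features)))
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stop_param("exactly two classes required")
  if ("patient" %in% lv) lv <- c("patient", setdiff(lv, "patient"))
  x1 <- features[labels == lv[1], , drop = FALSE]
  x2 <- features[labels == lv[2], , drop = FALSE]
  if (nrow(x1) < 2L || nrow(x2) < 2L)
    stop_param("each class needs at least 2 subjects")
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  df <- nrow(x1) + nrow(x2) - 2
  sp <- ((nrow(x1) - 1) * stats::cov(x1) +
           (nrow(x2) - 1) * stats::cov(x2)) / df
  sp <- (sp + t(sp)) / 2
  e <- eigen(sp, symmetric = TRUE)
  lam_bar <- mean(e$values)
  if (lam_bar <= 0) stop_param("degenerate features: pooled covariance is zero")
  lam_star <- pmax(e$values, lam_bar)
  s_star <- e$vectors %*% (lam_star * t(e$vectors))
  s_star <- (s_star + t(s_star)) / 2
  dimnames(s_star) <- dimnames(sp)
  w <- solve(s_star, mu1 - mu2)
  structure(list(class_means = list(mu1, mu2),
                 pooled_covariance = sp, repaired_covariance = s_star,
                 w = as.numeric(w),
                 threshold = sum(w * (mu1 + mu2) / 2),
                 classes = lv, feature_names = colnames(features)),
            class = "mlda_model")
}

#' Predict class labels from an MLDA model
#'
#' `w . x > threshold` assigns class 1; exact ties are assigned to class 1
#' (documented convention).
#'
#' @param model an [mlda_fit()] model.
#' @param features matrix (or vector) with the training feature columns.
#' @return Character vector of predicted labels.
#' @export
mlda_predict <- function(model, features) {
  stopifnot(inherits(model, "mlda_model"))
  features <- if (is.null(dim(features))) matrix(features, nrow = 1L)
  else as.matrix(features)
  if (ncol(features) != length(model$w))
    stop_param("model has %d features but input has %d columns",
               length(model$w), ncol(features))
  score <- as.numeric(features %*% model$w)
  ifelse(score >= model$threshold, model$classes[1], model$classes[2])
}

#' Leave-one-out cross-validated classification
#'
#' Each subject is classified by an MLDA model fitted on all remaining
#' subjects. With `nested_selection` (default) the t-test feature screening
#' is re-run inside every training fold; if no feature survives in a fold
#' the single smallest-p feature is used (deterministic fallback).
#' `nested_selection = FALSE` assumes the supplied columns were already
#' selected (whole-sample pre-selection protocol).
#'
#' @param features numeric matrix, subjects x features.
#' @param labels two-group labels; sensitivity counts `"patient"` (class 1)
#'   as positive.
#' @param nested_selection re-screen features per fold.
#' @param alpha screening level.
#' @return Object of class `classification_report`: `accuracy`,
#'   `sensitivity`, `specificity`, `predictions` (data.frame), `classes`.
#' @export
loocv <- function(features, labels, nested_selection = TRUE, alpha = 0.05) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("f%03d", seq_len(ncol(features)))
  labels <- as.character(labels)
  n <- nrow(features)
  if (n < 4L) stop_param("leave-one-out needs at least 4 subjects")
  preds <- character(n)
  for (k in seq_len(n)) {
    tr_x <- features[-k, , drop = FALSE]
    tr_y <- labels[-k]
    cols <- seq_len(ncol(features))
    if (nested_selection) {
      cols <- tryCatch(select_features(tr_x, tr_y, alpha), error = function(e) {
        p <- vapply(seq_len(ncol(tr_x)), function(j)
          tryCatch(two_sample_t(tr_x[tr_y == tr_y[1], j],
                                tr_x[tr_y != tr_y[1], j])$p,
                   error = function(e) 1), 0)
        which.min(p)
      })
    }
    model <- mlda_fit(tr_x[, cols, drop = FALSE], tr_y)
    preds[k] <- mlda_predict(model, features[k, cols, drop = FALSE])
  }
  classification_report(labels, preds)
}

classification_report <- function(labels, predictions) {
  lv <- unique(labels)
  if ("patient" %in% lv) lv <- c("patient", setdiff(lv, "patient"))
  pos <- lv[1]
  tp <- sum(predictions == pos & labels == pos)
  tn <- sum(predictions != pos & labels != pos)
  fn <- sum(predictions != pos & labels == pos)
  fp <- sum(predictions == pos & labels != pos)
  structure(list(accuracy = (tp + tn) / length(labels),
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 predictions = data.frame(truth = labels,
                                          predicted = predictions),
                 classes = lv),
            class = "classification_report")
}

#' Permutation significance of the cross-validated accuracy
#'
#' Repeats the full leave-one-out pipeline (including any nested feature
#' screening) under randomly permuted labels, giving a null distribution of
#' accuracies; reports `z = (acc_obs - mean_null) / sd_null` and the add-one
#' p-value `(1 + #{acc_null >= acc_obs}) / (1 + n_perm)`.
#'
#' @param features,labels,nested_selection,alpha as in [loocv()].
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return List with `z`, `p`, `accuracy`, `null_accuracies`, `n_perm`.
#' @export
permutation_significance <- function(features, labels, n_perm = 1000,
                                     seed = 1, nested_selection = TRUE,
                                     alpha = 0.05) {
  obs <- loocv(features, labels, nested_selection, alpha)$accuracy
  set.seed(as.integer(seed))
  null_acc <- vapply(seq_len(n_perm), function(k)
    loocv(features, sample(labels), nested_selection, alpha)$accuracy, 0)
  sd_null <- stats::sd(null_acc)
  if (sd_null == 0) {
    warning("null accuracy distribution is degenerate; z reported as Inf")
    z <- Inf * sign(obs - mean(null_acc))
    if (is.nan(z)) z <- 0
  } else z <- (obs - mean(null_acc)) / sd_null
  list(z = z, p = (1 + sum(null_acc >= obs)) / (1 + n_perm),
       accuracy = obs, null_accuracies = null_acc, n_perm = n_perm)
}

#' Feature weights of a fitted MLDA model
#'
#' The discriminant coefficients quantify each feature's contribution to the
#' classification. Raw signed weights, absolute weights, and absolute weights
#' normalized to unit Euclidean norm are reported; a single-feature model has
#' normalized weight 1 by construction.
#'
#' @param model an [mlda_fit()] model.
#' @return data.frame with `feature`, `weight_raw`, `weight_abs`,
#'   `weight_normalized`.
#' @export
feature_weights <- function(model) {
  stopifnot(inherits(model, "mlda_model"))
  w <- model$w
  data.frame(feature = model$feature_names, weight_raw = w,
             weight_abs = abs(w),
             weight_normalized = abs(w) / sqrt(sum(w^2)))
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> accuracy %.3f, sensitivity %.3f, specificity %.3f (positive class: %s)\n",
              x$accuracy, x$sensitivity, x$specificity, x$classes[1]))
  invisible(x)
}

#' @export
print.mlda_model <- function(x, ...) {
  cat(sprintf("<mlda_model> %d features, classes %s vs %s\n",
              length(x$w), x$classes[1], x$classes[2]))
  invisible(x)
}
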