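sep_gauss <- function(n_per, p = 2, delta = 4, sd = 1, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p, delta / 2, sd), n_per),
             matrix(rnorm(n_per * p, -delta / 2, sd), n_per))
  colnames(x) <- sprintf("f%02d", seq_len(p))
  list(x = x, y = rep(c("patient", "control"), each = n_per))
}

test_that("MLDA reduces to classical LDA when the covariance repair is inert", {
  # engineered data whose pooled covariance is exactly spherical
  base <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  x <- rbind(sweep(base, 2, c(3, 0), "+"), sweep(base, 2, c(-3, 0), "+"))
  y <- rep(c("patient", "control"), each = 4)
  m <- mlda_fit(x, y)
  expect_equal(m$repaired_covariance, m$pooled_covariance, tolerance = 1e-12)
  dmu <- m$class_means[[1]] - m$class_means[[2]]
  expect_equal(m$w, as.numeric(solve(m$pooled_covariance, dmu)),
               tolerance = 1e-12)

  # prediction agreement with MASS::lda on well-separated spherical data
  skip_if_not_installed("MASS")
  d <- sep_gauss(25, p = 3, delta = 5, seed = 5)
  m2 <- mlda_fit(d$x, d$y)
  ref <- MASS::lda(d$x, grouping = d$y)
  agree <- mean(mlda_predict(m2, d$x) ==
                  as.character(predict(ref, d$x)$class))
  expect_equal(agree, 1)
})

test_that("the scalar case follows the midpoint rule with ties to class 1", {
  x <- matrix(c(2, 3, 4, -2, -3, -4), ncol = 1)
  y <- c("patient", "patient", "patient", "control", "control", "control")
  m <- mlda_fit(x, y)
  expect_equal(m$w, (3 - (-3)) / stats::var(c(2, 3, 4)), tolerance = 1e-12)
  expect_equal(mlda_predict(m, matrix(3)), "patient")
  expect_equal(mlda_predict(m, matrix(-3)), "control")
  expect_equal(mlda_predict(m, matrix(0)), "patient")  # exact midpoint tie
})

test_that("the eigenvalue floor keeps singular problems solvable", {
  set.seed(21)
  # p >> n: naive LDA would need the inverse of a singular matrix
  n_per <- 5; p <- 30
  x <- rbind(matrix(rnorm(n_per * p, 1), n_per),
             matrix(rnorm(n_per * p, -1), n_per))
  y <- rep(c("patient", "control"), each = n_per)
  m <- mlda_fit(x, y)
  ev_pooled <- eigen(m$pooled_covariance, symmetric = TRUE,
                     only.values = TRUE)$values
  ev_star <- eigen(m$repaired_covariance, symmetric = TRUE,
                   only.values = TRUE)$values
  expect_lt(min(ev_pooled), 1e-10)             # genuinely singular input
  expect_gte(min(ev_star), mean(ev_pooled) - 1e-10)
  expect_true(all(is.finite(m$w)))
  expect_error(solve(m$pooled_covariance), "singular|computationally")

  expect_error(mlda_fit(x[c(1, 6:10), ], y[c(1, 6:10)]), "2 subjects")
  expect_error(mlda_predict(m, matrix(0, 1, 3)), "features")
})

test_that("leave-one-out classification is exact on separable data and order-invariant", {
  d <- sep_gauss(10, delta = 8, seed = 6)
  rep1 <- loocv(d$x, d$y)
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$sensitivity, 1)
  expect_equal(rep1$specificity, 1)

  perm <- sample(length(d$y))
  rep2 <- loocv(d$x[perm, ], d$y[perm])
  expect_equal(rep2$accuracy, rep1$accuracy)

  # sensitivity counts patients as positives
  d2 <- sep_gauss(10, delta = 3, seed = 7)
  r <- loocv(d2$x, d2$y)
  tab <- r$predictions
  expect_equal(r$sensitivity,
               mean(tab$predicted[tab$truth == "patient"] == "patient"))
  expect_error(loocv(d$x[1:3, ], d$y[1:3]), "at least 4")
})

test_that("nested feature screening selects informative columns and falls back gracefully", {
  set.seed(22)
  y <- rep(c("patient", "control"), each = 15)
  informative <- ifelse(y == "patient", 1, -1) + rnorm(30, sd = 0.3)
  noise <- matrix(rnorm(30 * 5), 30)
  x <- cbind(sig = informative, noise)
  keep <- select_features(x, y, alpha = 0.05)
  expect_true("sig" %in% names(keep))
  expect_length(select_features(x, y, alpha = 1), 6)
  expect_error(select_features(noise, y, alpha = 1e-12), "alpha")

  # type-I control of the screen on pure-noise features
  hits <- replicate(100, {
    xn <- matrix(rnorm(30), 30, 1)
    length(tryCatch(select_features(xn, y, 0.05), error = function(e) NULL))
  })
  expect_lt(mean(hits), 0.12)

  # loocv survives folds where nothing passes the screen
  r <- loocv(noise, y, nested_selection = TRUE, alpha = 1e-6)
  expect_true(is.finite(r$accuracy))
})

test_that("classification is invariant to isotropic affine rescaling end-to-end", {
  # the eigenvalue floor commutes with a common scale factor and with
  # translations; raw weights change, predictions do not
  d <- sep_gauss(12, p = 2, delta = 3, seed = 8)
  m1 <- mlda_fit(d$x, d$y)
  scaled <- d$x * 10 + 3
  m2 <- mlda_fit(scaled, d$y)
  expect_equal(mlda_predict(m2, scaled), mlda_predict(m1, d$x))
  expect_equal(loocv(scaled, d$y)$accuracy, loocv(d$x, d$y)$accuracy)
  expect_equal(m2$w * 10, m1$w, tolerance = 1e-10)  # w scales as 1/c
})

test_that("feature weights normalize sensibly and respect symmetry", {
  d <- sep_gauss(12, p = 1, delta = 3, seed = 9)
  m1 <- mlda_fit(d$x, d$y)
  w1 <- feature_weights(m1)
  expect_equal(w1$weight_normalized, 1)  # single feature

  # an exactly duplicated feature receives an identical share
  x2 <- cbind(a = d$x[, 1], b = d$x[, 1])
  m2 <- mlda_fit(x2, d$y)
  w2 <- feature_weights(m2)
  expect_equal(w2$weight_normalized[1], w2$weight_normalized[2],
               tolerance = 1e-10)
})

test_that("permutation significance is reproducible and calibrated on nulls", {
  set.seed(23)
  y <- rep(c("patient", "control"), each = 10)
  x <- matrix(rnorm(20 * 2), 20)
  s1 <- permutation_significance(x, y, n_perm = 60, seed = 12)
  s2 <- permutation_significance(x, y, n_perm = 60, seed = 12)
  expect_identical(s1[c("z", "p", "accuracy")], s2[c("z", "p", "accuracy")])
  expect_gte(s1$p, 1 / 61)

  # null features should rarely look significant
  expect_gt(s1$p, 0.01)
})
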