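test_that("ground truth is deterministic, PSD, and handles the null and full-attenuation cases", {
  cfg <- synthetic_config(n_per_group = 3, seed = 5)
  gt1 <- make_ground_truth(cfg)
  gt2 <- make_ground_truth(cfg)
  expect_identical(gt1, gt2)

  for (g in c("control", "patient")) {
    w <- gt1$coupling[[g]]
    expect_equal(w, t(w))
    expect_equal(diag(w), rep(1, cfg$n_rois))
    expect_gt(min(eigen(w, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }

  # null case: identical matrices
  gt0 <- make_ground_truth(synthetic_config(n_per_group = 3, effect_size = 0,
                                            seed = 5))
  expect_identical(gt0$coupling$control, gt0$coupling$patient)

  # full attenuation, long-chords only: exactly k couplings zeroed in the
  # pre-repair template
  k <- 17L
  cfg1 <- synthetic_config(n_per_group = 3, effect_size = 1,
                           n_targeted_edges = k, local_target_band = 0,
                           seed = 5)
  gtf <- make_ground_truth(cfg1)
  diff_idx <- which(gtf$template$control != gtf$template$patient &
                      upper.tri(gtf$template$control))
  expect_length(diff_idx, k)
  expect_true(all(gtf$template$patient[diff_idx] == 0))
  expect_identical(nrow(gtf$targeted_edges), k)

  # too many chords requested
  expect_error(make_ground_truth(synthetic_config(n_targeted_edges = 10000)),
               "exceeds")
  expect_error(synthetic_config(effect_size = 1.2), "effect_size")
})

test_that("simulated series recover the planted correlation structure", {
  # independence under identity coupling
  cfg <- synthetic_config(n_per_group = 3, n_rois = 6, n_timepoints = 2000,
                          noise_sd = 0, seed = 2)
  ts <- simulate_subject(diag(6), cfg, subject_seed = 11)
  r <- pearson_matrix(ts)
  expect_lt(max(abs(r[upper.tri(r)])), 0.15)

  # planted r = 0.8 pair, Monte-Carlo over 50 seeds: band-pass filtering
  # attenuates only slightly
  coupling <- diag(6)
  coupling[1, 2] <- coupling[2, 1] <- 0.8
  rs <- vapply(1:50, function(s) {
    x <- simulate_subject(coupling, cfg, subject_seed = 1000 + s)
    stats::cor(x$values[, 1], x$values[, 2])
  }, 0)
  expect_lt(abs(mean(rs) - 0.8), 0.1)
  expect_gt(mean(abs(rs - 0.8) < 0.1), 0.9)

  # determinism
  a <- simulate_subject(coupling, cfg, subject_seed = 7)
  b <- simulate_subject(coupling, cfg, subject_seed = 7)
  expect_identical(a$values, b$values)

  # non-PSD coupling rejected
  bad <- diag(3); bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(simulate_subject(bad, cfg, 1), "positive semi-definite")
})

test_that("band-pass filter keeps in-band signal and rejects invalid bands", {
  t_sec <- seq(0, by = 2, length.out = 400)
  inband <- sin(2 * pi * 0.05 * t_sec)
  lowout <- sin(2 * pi * 0.004 * t_sec)
  highout <- sin(2 * pi * 0.2 * t_sec)
  x <- cbind(inband, lowout, highout)
  y <- bandpass_filter(x, 0.01, 0.1, tr_seconds = 2)
  expect_gte(sd(y[, 1]) / sd(x[, 1]), 0.9)    # mid-band retained
  expect_lt(sd(y[, 2]) / sd(x[, 2]), 0.5)     # drift attenuated
  expect_lt(sd(y[, 3]) / sd(x[, 3]), 0.5)     # high frequency attenuated

  # band edge beyond Nyquist (1/(2*2) = 0.25 Hz) is rejected up front
  expect_error(bandpass_filter(x, 0.01, 0.3, tr_seconds = 2), "Nyquist")
  expect_error(bandpass_filter(x, 0.2, 0.1, tr_seconds = 2), "Nyquist")

  # constant column becomes all-zero through mean removal
  z <- bandpass_filter(cbind(rep(5, 100), rnorm(100)), 0.01, 0.1,
                       tr_seconds = 2)
  expect_equal(max(abs(z[, 1])), 0)

  # matches the reference single-column implementation exactly
  bf <- signal::butter(2, c(0.01, 0.1) / 0.25, type = "pass")
  x1 <- matrix(rnorm(300), 100, 3)
  ref <- apply(sweep(x1, 2, colMeans(x1)), 2,
               function(col) signal::filtfilt(bf, col))
  expect_equal(bandpass_filter(x1, 0.01, 0.1, tr_seconds = 2), ref,
               tolerance = 1e-12)
})

test_that("nuisance regression yields residuals orthogonal to the regressor span", {
  set.seed(9)
  x <- matrix(rnorm(300), 100, 3)
  ones <- matrix(1, 100, 1)
  r1 <- regress_nuisance(x, ones)
  expect_equal(colMeans(r1), rep(0, 3), tolerance = 1e-12)

  reg <- cbind(1, rnorm(100), rnorm(100))
  r2 <- regress_nuisance(x, reg)
  expect_lt(max(abs(crossprod(reg, r2))) / max(abs(x)), 1e-8)

  # a column equal to a regressor is annihilated
  x2 <- cbind(reg[, 2], x[, 1], x[, 2])
  r3 <- regress_nuisance(x2, reg)
  expect_lt(max(abs(r3[, 1])), 1e-10)

  expect_warning(regress_nuisance(x, cbind(rep(1, 100), rep(1, 100))),
                 "rank-deficient")
  expect_error(regress_nuisance(x, matrix(1, 50, 1)), "rows")
})

test_that("cohort simulation writes a coherent, reproducible set of files", {
  cfg <- synthetic_config(n_per_group = 5, n_timepoints = 60, seed = 21)
  dir1 <- withr::local_tempdir()
  res <- simulate_cohort(cfg, dir1)
  mf <- res$manifest
  expect_equal(nrow(mf), 10)
  expect_setequal(unique(mf$group), c("patient", "control"))
  expect_equal(sum(file.exists(file.path(dir1, mf$timeseries_path))), 10)

  # clinical scores respect instrument ranges and group ordering
  expect_true(all(mf$lsas_total >= 0 & mf$lsas_total <= 144))
  expect_true(all(mf$hamd >= 0))
  expect_gt(mean(mf$lsas_total[mf$group == "patient"]),
            mean(mf$lsas_total[mf$group == "control"]))

  # same seed => byte-identical outputs
  dir2 <- withr::local_tempdir()
  simulate_cohort(cfg, dir2)
  for (f in c("manifest.csv", mf$timeseries_path[1], mf$timeseries_path[10]))
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))

  # round-trips through the manifest reader
  cohort <- read_manifest(res$manifest_path, tr_seconds = cfg$tr_seconds)
  expect_s3_class(cohort, "cohort")
  expect_length(cohort$series, 10)
  expect_equal(ncol(cohort$series[[1]]$values), 90)
})
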