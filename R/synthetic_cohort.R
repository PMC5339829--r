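#' Configuration for the synthetic cohort generator
#'
#' Bundles all parameters of the two-group synthetic resting-state cohort.
#' Defaults reproduce the study conditions the pipeline targets: two groups of
#' 42 subjects, 90 regions, 200 volumes at TR = 2 s, signals band-limited to
#' 0.01-0.1 Hz.
#'
#' The ground-truth coupling template is a distance-decay ring lattice
#' (coupling `coupling_local * exp(-d/coupling_decay)` at ring distance d)
#' carrying `n_targeted_edges` strong long-range chords; see
#' [make_ground_truth()] for how group 2 ("patient") couplings are attenuated.
#'
#' @param n_per_group subjects per group (>= 3).
#' @param n_rois number of regions (network nodes).
#' @param n_timepoints number of volumes T per subject.
#' @param tr_seconds sampling interval in seconds.
#' @param base_density fraction of region pairs with a nonzero ground-truth
#'   coupling; values below 1 zero the weakest distance-decay couplings.
#'   The default keeps the full decay tail: the mid-range coupling reservoir
#'   is what keeps freed edge budget local when couplings are attenuated,
#'   mirroring the distance-dependent correlation structure of real
#'   functional connectomes.
#' @param effect_size fractional attenuation of the targeted couplings in
#'   group 2; 0 gives two identical groups (the null), 1 removes them.
#' @param n_targeted_edges number of long-range chords planted (and targeted).
#' @param noise_sd standard deviation of white observation noise added after
#'   band-pass filtering (signal columns have unit variance before filtering).
#' @param coupling_local peak local coupling (at ring distance 1 it is
#'   `coupling_local * exp(-1/coupling_decay)`).
#' @param coupling_decay ring-distance e-folding length of the local coupling.
#' @param chord_strength length-2 range of the long-range chord couplings.
#' @param local_target_band local couplings at ring distance <= this value are
#'   also attenuated in group 2 (alternate pairs at the boundary distance);
#'   0 targets the long-range chords only.
#' @param band_hz length-2 pass band in Hz for the zero-phase filter.
#' @param clinical_link in `[0, 1)`: correlation planted between the patients'
#'   subject-level attenuation depth and their depression (HAMD) score; 0
#'   (default) leaves clinical scores independent of topology.
#' @param covariate_link if nonzero, subject observation noise is scaled by
#'   `1 + covariate_link * z_age`, weakly linking age to signal quality.
#' @param seed master RNG seed; together with the config it fully determines
#'   every generated output.
#' @return A list of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_per_group = 5, seed = 1)
#' cfg$n_rois
synthetic_config <- function(n_per_group = 42, n_rois = 90, n_timepoints = 200,
                             tr_seconds = 2, base_density = 1,
                             effect_size = 0.6, n_targeted_edges = 100,
                             noise_sd = 0.1, coupling_local = 0.55,
                             coupling_decay = 8, chord_strength = c(0.5, 0.6),
                             local_target_band = 3, band_hz = c(0.01, 0.1),
                             clinical_link = 0, covariate_link = 0, seed = 1) {
  if (n_per_group < 3) stop_param("n_per_group must be >= 3")
  if (n_rois < 6) stop_param("n_rois must be >= 6")
  check_prob(effect_size, "effect_size")
  check_prob(base_density, "base_density")
  if (noise_sd < 0) stop_param("noise_sd must be non-negative")
  if (length(chord_strength) != 2L || any(chord_strength <= 0) ||
      chord_strength[1] > chord_strength[2])
    stop_param("chord_strength must be an increasing positive range")
  nyquist <- 1 / (2 * tr_seconds)
  if (band_hz[1] < 0 || band_hz[1] >= band_hz[2] || band_hz[2] >= nyquist)
    stop_param("band_hz must satisfy 0 <= low < high < Nyquist (%.3f Hz)",
               nyquist)
  structure(list(n_per_group = as.integer(n_per_group),
                 n_rois = as.integer(n_rois),
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds, base_density = base_density,
                 effect_size = effect_size,
                 n_targeted_edges = as.integer(n_targeted_edges),
                 noise_sd = noise_sd, coupling_local = coupling_local,
                 coupling_decay = coupling_decay,
                 chord_strength = chord_strength,
                 local_target_band = local_target_band, band_hz = band_hz,
                 clinical_link = clinical_link,
                 covariate_link = covariate_link, seed = as.integer(seed)),
            class = "synthetic_config")
}

ring_distance <- function(n) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  pmin(d, n - d)
}

# deterministic, evenly spread long-range chord endpoints:
# diameters (offset n/2) first, then offset n/3 chords; any subset is taken
# evenly spaced around the ring so no arc is left without shortcuts
long_chords <- function(n, n_long) {
  half <- floor(n / 2)
  third <- floor(n / 3)
  spread <- function(m, k) {
    if (k >= nrow(m)) m else m[round(seq(1, nrow(m), length.out = k)), ,
                               drop = FALSE]
  }
  diam <- cbind(seq_len(half), seq_len(half) + half)
  extra <- cbind(seq_len(n), (seq_len(n) + third - 1L) %% n + 1L)
  extra <- t(apply(extra, 1L, sort))
  extra <- extra[!duplicated(extra) &
                   !(extra[, 2] - extra[, 1] == half), , drop = FALSE]
  avail <- nrow(diam) + nrow(extra)
  if (n_long > avail)
    stop_param("n_targeted_edges = %d exceeds the %d available long-range chords",
               n_long, avail)
  if (n_long <= nrow(diam)) return(spread(diam, n_long))
  rbind(diam, spread(extra, n_long - nrow(diam)))
}

# eigenvalue flooring at 1e-6 followed by renormalization to unit diagonal
psd_repair <- function(m, floor = 1e-6) {
  diag(m) <- 1
  e <- eigen(m, symmetric = TRUE)
  v <- pmax(e$values, floor)
  m2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(m2))
  m2 <- m2 / outer(d, d)
  (m2 + t(m2)) / 2
}

#' Build the two-group ground-truth coupling matrices
#'
#' Group 1 ("control") couplings follow a distance-decay ring lattice -- a
#' locally clustered, long-pathed substrate -- overlaid with
#' `n_targeted_edges` strong long-range chords that act as integration
#' shortcuts. Group 2 ("patient") equals group 1 with two targeted sets
#' attenuated by `(1 - effect_size)`: all long-range chords (raising
#' characteristic path length) and the strongest local lattice couplings
#' (ring distance <= `local_target_band`, thinned at the boundary distance;
#' lowering the clustering coefficient). Both matrices are repaired to
#' positive semi-definiteness by eigenvalue flooring and diagonal
#' renormalization; the construction is a pure function of the config.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `ground_truth`: `coupling` (list of two symmetric
#'   unit-diagonal PSD matrices named `control`, `patient`), `template` (the
#'   same two matrices before the PSD repair), `targeted_edges` (data.frame
#'   `i`, `j`, `type` in `long`/`local`, `strength`), and
#'   `expected_direction` (patients: lower clustering, higher path length).
#' @export
#' @examples
#' gt <- make_ground_truth(synthetic_config(n_per_group = 5, effect_size = 0))
#' identical(gt$coupling$control, gt$coupling$patient)
make_ground_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, "ground_truth"))
  n <- config$n_rois
  d <- ring_distance(n)
  w <- config$coupling_local * exp(-d / config$coupling_decay)
  diag(w) <- 1

  ch <- long_chords(n, config$n_targeted_edges)
  strength <- stats::runif(nrow(ch), config$chord_strength[1],
                           config$chord_strength[2])
  for (r in seq_len(nrow(ch))) {
    w[ch[r, 1], ch[r, 2]] <- w[ch[r, 2], ch[r, 1]] <- strength[r]
  }

  # enforce base_density: zero the weakest couplings beyond the quota
  ut <- upper.tri(w)
  n_keep <- round_half_up(config$base_density * sum(ut))
  vals <- w[ut]
  if (n_keep < sum(vals > 0)) {
    cut <- sort(vals, decreasing = TRUE)[n_keep]
    w[ut & w < cut] <- 0
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
  }

  # targeted local couplings: full band up to local_target_band - 1,
  # alternate pairs (odd lower index) at the boundary distance
  band <- config$local_target_band
  loc_mask <- ut & ((d < band) |
                      (d == band & (pmin(row(w), col(w)) %% 2 == 1L))) & d > 0
  loc <- which(loc_mask & w > 0, arr.ind = TRUE)

  w2 <- w
  att <- 1 - config$effect_size
  for (r in seq_len(nrow(ch))) {
    w2[ch[r, 1], ch[r, 2]] <- w2[ch[r, 2], ch[r, 1]] <- strength[r] * att
  }
  if (nrow(loc) > 0) {
    for (r in seq_len(nrow(loc))) {
      i <- loc[r, 1]; j <- loc[r, 2]
      w2[i, j] <- w2[j, i] <- w[i, j] * att
    }
  }

  targeted <- rbind(
    data.frame(i = ch[, 1], j = ch[, 2], type = "long", strength = strength),
    if (nrow(loc) > 0)
      data.frame(i = loc[, 1], j = loc[, 2], type = "local",
                 strength = w[loc])
  )
  targeted <- targeted[order(targeted$i, targeted$j), ]
  rownames(targeted) <- NULL

  structure(list(
    coupling = list(control = psd_repair(w), patient = psd_repair(w2)),
    template = list(control = w, patient = w2),
    targeted_edges = targeted,
    expected_direction = c(clustering = "lower in patient group",
                           path_length = "higher in patient group"),
    config = config), class = "ground_truth")
}

#' Simulate one subject's band-limited regional time series
#'
#' Draws T x N Gaussian series with the supplied coupling matrix as the target
#' correlation (via its Cholesky factor), band-pass filters each column with a
#' zero-phase Butterworth filter, and adds white observation noise.
#'
#' @param coupling symmetric positive-(semi)definite N x N target correlation.
#' @param config a [synthetic_config()] (supplies T, TR, band, noise).
#' @param subject_seed integer seed for this subject's draw.
#' @param noise_scale multiplier on `config$noise_sd` (used by the optional
#'   age-covariate link).
#' @return A [roi_time_series()] object.
#' @export
simulate_subject <- function(coupling, config, subject_seed, noise_scale = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- tryCatch(chol(coupling + diag(1e-10, nrow(coupling))),
                 error = function(e)
                   stop_param("coupling matrix is not positive semi-definite"))
  set.seed(as.integer(subject_seed))
  tn <- config$n_timepoints
  n <- nrow(coupling)
  x <- matrix(stats::rnorm(tn * n), tn, n) %*% cf
  x <- bandpass_matrix(x, config$band_hz[1], config$band_hz[2],
                       config$tr_seconds)
  if (config$noise_sd > 0)
    x <- x + matrix(stats::rnorm(tn * n, sd = config$noise_sd * noise_scale),
                    tn, n)
  roi_time_series(x, tr_seconds = config$tr_seconds,
                  roi_labels = default_roi_labels(n))
}

#' Zero-phase band-pass filter for regional time series
#'
#' Removes each column's mean and applies a second-order Butterworth band-pass
#' forwards and backwards (zero phase). The canonical resting-state band is
#' 0.01-0.1 Hz.
#'
#' @param ts a [roi_time_series()] object or plain numeric matrix
#'   (columns = regions).
#' @param low_hz,high_hz pass-band edges; must satisfy
#'   `0 <= low_hz < high_hz < 1/(2 TR)`.
#' @param tr_seconds sampling interval, required when `ts` is a bare matrix.
#' @param order Butterworth filter order.
#' @return Same type as the input (`roi_time_series` or matrix).
#' @export
#' @examples
#' t_sec <- seq(0, 398, by = 2)
#' x <- cbind(sin(2 * pi * 0.05 * t_sec), cos(2 * pi * 0.05 * t_sec),
#'            sin(2 * pi * 0.02 * t_sec))
#' filtered <- bandpass_filter(x, 0.01, 0.1, tr_seconds = 2)
#' sd(filtered[, 1]) / sd(x[, 1])  # mid-band amplitude retained
bandpass_filter <- function(ts, low_hz = 0.01, high_hz = 0.1,
                            tr_seconds = NULL, order = 2) {
  is_ts <- inherits(ts, "roi_time_series")
  m <- if (is_ts) ts$values else as.matrix(ts)
  tr <- if (is_ts) ts$tr_seconds else tr_seconds
  if (is.null(tr)) stop_param("tr_seconds is required for matrix input")
  out <- bandpass_matrix(m, low_hz, high_hz, tr, order)
  if (is_ts) {
    ts$values <- out
    colnames(ts$values) <- ts$roi_labels
    ts
  } else out
}

bandpass_matrix <- function(m, low_hz, high_hz, tr_seconds, order = 2) {
  nyquist <- 1 / (2 * tr_seconds)
  if (low_hz < 0 || low_hz >= high_hz || high_hz >= nyquist)
    stop_param("pass band [%g, %g] Hz must satisfy 0 <= low < high < Nyquist (%g Hz)",
               low_hz, high_hz, nyquist)
  m <- sweep(m, 2L, colMeans(m))
  bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  filtfilt_matrix(bf$b, bf$a, m)
}

# zero-phase IIR applied to all columns at once; numerically identical to
# signal::filtfilt per column (zero initial state, 2*max(len) zero padding)
filtfilt_matrix <- function(b, a, x) {
  iir <- function(x) {
    nb <- length(b)
    xp <- rbind(matrix(0, nb - 1, ncol(x)), x)
    z <- stats::filter(xp, b / a[1], method = "convolution", sides = 1)
    z <- z[nb:nrow(xp), , drop = FALSE]
    y <- stats::filter(z, -a[-1] / a[1], method = "recursive")
    matrix(as.numeric(y), nrow(x), ncol(x))
  }
  npad <- 2 * max(length(a), length(b))
  y <- iir(rbind(x, matrix(0, npad, ncol(x))))
  y <- iir(y[nrow(y):1, , drop = FALSE])
  y[nrow(y):1, , drop = FALSE][seq_len(nrow(x)), , drop = FALSE]
}

#' Regress nuisance signals out of regional time series
#'
#' Ordinary least-squares residualization of every region on the supplied
#' regressor matrix (no intercept is added implicitly; include a column of
#' ones to remove means). Residuals are orthogonal to the regressor span.
#'
#' @param ts a [roi_time_series()] or numeric matrix.
#' @param regressors numeric T x k matrix.
#' @return Same type as the input, containing residuals.
#' @export
regress_nuisance <- function(ts, regressors) {
  is_ts <- inherits(ts, "roi_time_series")
  m <- if (is_ts) ts$values else as.matrix(ts)
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != nrow(m))
    stop_param("regressors have %d rows but the series has %d timepoints",
               nrow(regressors), nrow(m))
  qr_x <- qr(regressors)
  if (qr_x$rank < ncol(regressors))
    warning("rank-deficient nuisance regressors; using pseudo-inverse fit")
  res <- qr.resid(qr_x, m)
  if (is_ts) {
    ts$values <- res
    colnames(ts$values) <- ts$roi_labels
    ts
  } else res
}

#' Simulate and write a full two-group cohort
#'
#' Writes one time-series TSV per subject plus a manifest CSV with group
#' labels, ages, sexes and clinical scores (LSAS total/fear/avoidance, HAMD,
#' HAMA) drawn from group-conditional normal distributions truncated at the
#' instrument ranges, matching the demographic/clinical summary table shipped
#' with the package. The manifest round-trips through [read_manifest()].
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `manifest` (data.frame), `manifest_path`,
#'   and `ground_truth`.
#' @export
#' @examples
#' \donttest{
#' cfg <- synthetic_config(n_per_group = 3, seed = 7)
#' res <- simulate_cohort(cfg, file.path(tempdir(), "demo_cohort"))
#' nrow(res$manifest)
#' }
simulate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_param("cannot create directory: %s", out_dir)
  gt <- make_ground_truth(config)
  n <- config$n_per_group
  groups <- rep(c("patient", "control"), each = n)
  ids <- sprintf("sub-%03d", seq_len(2L * n))

  set.seed(derive_seed(config$seed, "covariates"))
  cs <- clinical_summaries()
  draw_trunc <- function(mu, sd, lo, hi, k) {
    x <- stats::rnorm(k, mu, sd)
    pmin(pmax(x, lo), hi)
  }
  row_of <- function(v) cs[cs$variable == v, ]
  age <- numeric(2L * n)
  scores <- matrix(0, 2L * n, 5L,
                   dimnames = list(NULL, c("lsas_total", "lsas_fear",
                                           "lsas_avoid", "hamd", "hama")))
  # patient attenuation-depth latent, reused for the optional clinical link
  latent <- stats::rnorm(2L * n)
  for (g in c("patient", "control")) {
    sel <- groups == g
    a <- row_of("age")
    mu <- if (g == "patient") a$patient_mean else a$control_mean
    sd <- if (g == "patient") a$patient_sd else a$control_sd
    age[sel] <- round(draw_trunc(mu, sd, a$scale_min, a$scale_max, sum(sel)), 1)
    for (v in colnames(scores)) {
      r <- row_of(v)
      mu <- if (g == "patient") r$patient_mean else r$control_mean
      sd <- if (g == "patient") r$patient_sd else r$control_sd
      z <- stats::rnorm(sum(sel))
      if (v == "hamd" && g == "patient" && config$clinical_link > 0) {
        rho <- config$clinical_link
        z <- rho * latent[sel] + sqrt(1 - rho^2) * z
      }
      scores[sel, v] <- round(pmin(pmax(mu + sd * z, r$scale_min),
                                   r$scale_max), 1)
    }
  }
  n_male <- round(n * 26 / 42)  # study sex ratio 26M:16F per group
  sex <- unlist(lapply(c("patient", "control"), function(g)
    c(rep("M", n_male), rep("F", n - n_male))))

  paths <- character(2L * n)
  mean_age <- mean(age)
  sd_age <- stats::sd(age)
  for (k in seq_len(2L * n)) {
    coupling <- gt$coupling[[groups[k]]]
    if (groups[k] == "patient" && config$clinical_link > 0) {
      # deepen/lighten this patient's attenuation with the latent score
      e_k <- min(max(config$effect_size * (1 + 0.4 * latent[k]), 0), 1)
      cfg_k <- config
      cfg_k$effect_size <- e_k
      coupling <- make_ground_truth(cfg_k)$coupling$patient
    }
    nscale <- if (config$covariate_link != 0 && sd_age > 0)
      max(1 + config$covariate_link * (age[k] - mean_age) / sd_age, 0.1)
    else 1
    ts <- simulate_subject(coupling, config,
                           derive_seed(config$seed, "subject", k), nscale)
    paths[k] <- file.path(out_dir, paste0(ids[k], ".tsv"))
    write_time_series(ts, paths[k])
  }

  manifest <- data.frame(subject_id = ids, group = groups, age = age,
                         sex = sex, lsas_total = scores[, "lsas_total"],
                         lsas_fear = scores[, "lsas_fear"],
                         lsas_avoid = scores[, "lsas_avoid"],
                         hamd = scores[, "hamd"], hama = scores[, "hama"],
                         timeseries_path = basename(paths))
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(list(manifest = manifest, manifest_path = manifest_path,
                 ground_truth = gt))
}

clinical_summaries <- function() {
  path <- system.file("extdata", "clinical_scale_summaries.tsv",
                      package = "restnet")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
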