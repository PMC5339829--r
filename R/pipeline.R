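#' Pipeline run configuration
#'
#' Collects every tunable of an end-to-end run. All stochastic steps derive
#' their seeds deterministically from `master_seed`, so a run with identical
#' config and seed reproduces all numeric outputs exactly.
#'
#' @param manifest path to a cohort manifest CSV (see [read_manifest()]);
#'   `NULL` to simulate a cohort from `synthetic` instead.
#' @param synthetic a [synthetic_config()] used when `manifest` is `NULL`.
#' @param grid a [sparsity_grid()].
#' @param n_null null networks per sparsity for gamma/lambda/sigma (100 in
#'   the canonical protocol; 0 skips normalization).
#' @param n_perm_group permutations for the group metric tests.
#' @param n_perm_classifier permutations for classifier significance.
#' @param degree_log_base log base of the mean-degree admissibility criterion.
#' @param lp_disconnected disconnected-pair convention for Lp.
#' @param whole_sample_selection use whole-sample feature pre-selection in
#'   the classifier (the historical protocol) instead of fold-nested
#'   screening.
#' @param tr_seconds sampling interval used when reading manifest time series.
#' @param master_seed master RNG seed.
#' @param out_dir output directory for result tables.
#' @return A list of class `run_config`.
#' @export
run_config <- function(manifest = NULL, synthetic = synthetic_config(),
                       grid = sparsity_grid(), n_null = 100,
                       n_perm_group = 10000, n_perm_classifier = 1000,
                       degree_log_base = "e",
                       lp_disconnected = c("exclude", "harmonic"),
                       whole_sample_selection = FALSE, tr_seconds = 2,
                       master_seed = 1, out_dir = "restnet_results") {
  lp_disconnected <- match.arg(lp_disconnected)
  structure(list(manifest = manifest, synthetic = synthetic, grid = grid,
                 n_null = n_null, n_perm_group = n_perm_group,
                 n_perm_classifier = n_perm_classifier,
                 degree_log_base = degree_log_base,
                 lp_disconnected = lp_disconnected,
                 whole_sample_selection = whole_sample_selection,
                 tr_seconds = tr_seconds,
                 master_seed = as.integer(master_seed), out_dir = out_dir),
            class = "run_config")
}

manifest_columns <- c("subject_id", "group", "age", "sex", "lsas_total",
                      "lsas_fear", "lsas_avoid", "hamd", "hama",
                      "timeseries_path")

#' Read a cohort manifest and its subjects' time series
#'
#' The manifest is a CSV with header
#' `subject_id,group,age,sex,lsas_total,lsas_fear,lsas_avoid,hamd,hama,timeseries_path`;
#' time-series paths are resolved relative to the manifest's directory. The
#' reader validates the columns, requires exactly two group labels, and
#' loads every subject's TSV, insisting on a consistent region count.
#'
#' @param path manifest CSV path.
#' @param tr_seconds sampling interval of the series.
#' @return A list of class `cohort`: `manifest` (data.frame) and `series`
#'   (named list of [roi_time_series()]).
#' @export
read_manifest <- function(path, tr_seconds = 2) {
  if (!file.exists(path)) stop_param("manifest not found: %s", path)
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(manifest_columns, names(mf))
  if (length(missing) > 0)
    stop_param("manifest is missing column(s): %s",
               paste(missing, collapse = ", "))
  lv <- unique(mf$group)
  if (length(lv) != 2L)
    stop_param("manifest must contain exactly two group labels, found: %s",
               paste(lv, collapse = ", "))
  base <- dirname(path)
  series <- vector("list", nrow(mf))
  names(series) <- mf$subject_id
  n_rois <- NA_integer_
  for (k in seq_len(nrow(mf))) {
    f <- mf$timeseries_path[k]
    if (!file.exists(f)) f <- file.path(base, f)
    ts <- tryCatch(read_time_series(f, tr_seconds = tr_seconds),
                   error = function(e)
                     stop_param("subject %s: %s", mf$subject_id[k],
                                conditionMessage(e)))
    if (is.na(n_rois)) n_rois <- ncol(ts$values)
    if (ncol(ts$values) != n_rois)
      stop_param("subject %s has %d regions but the cohort has %d",
                 mf$subject_id[k], ncol(ts$values), n_rois)
    series[[k]] <- ts
  }
  structure(list(manifest = mf, series = series), class = "cohort")
}

#' Export significant edges in BrainNet Viewer text format
#'
#' Writes `<prefix>.node` (label, coordinates, size = number of altered
#' connections at the node, color class) and `<prefix>.edge` (N x N matrix
#' of t statistics for the significant edges, zero elsewhere).
#'
#' @param edge_results data.frame from [edgewise_group_test()].
#' @param roi_labels node labels (defines N and the order).
#' @param prefix output path prefix.
#' @param q_threshold edges with `q <` this value are exported.
#' @param coords optional N x 3 coordinate matrix (zeros when absent).
#' @return Invisibly, the two file paths.
#' @export
write_brainnet <- function(edge_results, roi_labels, prefix,
                           q_threshold = 0.05, coords = NULL) {
  n <- length(roi_labels)
  sig <- edge_results[edge_results$q < q_threshold, , drop = FALSE]
  counts <- integer(n)
  emat <- matrix(0, n, n)
  if (nrow(sig) > 0) {
    for (r in seq_len(nrow(sig))) {
      i <- sig$i[r]; j <- sig$j[r]
      counts[i] <- counts[i] + 1L
      counts[j] <- counts[j] + 1L
      emat[i, j] <- emat[j, i] <- sig$t[r]
    }
  }
  if (is.null(coords)) coords <- matrix(0, n, 3)
  node <- data.frame(coords[, 1], coords[, 2], coords[, 3],
                     color = as.integer(counts > 0), size = counts,
                     label = roi_labels)
  node_path <- paste0(prefix, ".node")
  edge_path <- paste0(prefix, ".edge")
  utils::write.table(node, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(emat, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(node_path, edge_path))
}

#' Run the full pipeline
#'
#' Executes connectivity construction, sparsity thresholding, metric curves
#' and AUC summaries, edgewise and permutation group inference, Spearman
#' clinical correlations, and MLDA classification, writing all result tables
#' into `config$out_dir`:
#' `admissibility.tsv`, `auc_global.tsv`, `auc_nodal.tsv`,
#' `group_global.tsv`, `group_nodal.tsv`, `edge_tests.tsv`,
#' `significant_edges.node/.edge`, `clinical_correlations.tsv`,
#' `classification.json`, and `provenance.json` (config, seeds, versions,
#' stage timings).
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the main in-memory results (`cohort`,
#'   `auc_global`, `auc_nodal`, `group_global`, `group_nodal`, `edge_tests`,
#'   `correlations`, `classification`, `paths`).
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- cohort ---------------------------------------------------------------
  if (is.null(config$manifest)) {
    sim_dir <- file.path(config$out_dir, "synthetic_cohort")
    sim <- simulate_cohort(config$synthetic, sim_dir)
    cohort <- read_manifest(sim$manifest_path,
                            tr_seconds = config$synthetic$tr_seconds)
  } else {
    cohort <- read_manifest(config$manifest, tr_seconds = config$tr_seconds)
  }
  mf <- cohort$manifest
  n_subj <- nrow(mf)
  groups <- mf$group
  tick("cohort")

  # --- connectivity ---------------------------------------------------------
  z_list <- lapply(cohort$series, function(ts)
    positive_part(fisher_z(pearson_matrix(ts))))
  labels <- z_list[[1]]$roi_labels
  tick("connectivity")

  # --- metrics --------------------------------------------------------------
  curves <- vector("list", n_subj)
  for (k in seq_len(n_subj)) {
    curves[[k]] <- metric_curves(
      z_list[[k]], grid = config$grid, n_null = config$n_null,
      seed = derive_seed(config$master_seed, "metrics", k),
      disconnected = config$lp_disconnected,
      log_base = config$degree_log_base)
  }
  adm <- do.call(rbind, lapply(seq_len(n_subj), function(k)
    cbind(subject_id = mf$subject_id[k], curves[[k]]$admissibility)))
  utils::write.table(adm, file.path(config$out_dir, "admissibility.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  aucs <- lapply(seq_len(n_subj), function(k)
    cbind(subject_id = mf$subject_id[k], auc_summary(curves[[k]])))
  auc_long <- do.call(rbind, aucs)
  auc_global_long <- auc_long[auc_long$node == "global", ]
  auc_nodal_long <- auc_long[auc_long$node != "global", ]
  utils::write.table(auc_global_long,
                     file.path(config$out_dir, "auc_global.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(auc_nodal_long,
                     file.path(config$out_dir, "auc_nodal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tick("metrics")

  # --- group inference ------------------------------------------------------
  covars <- mf[, c("age", "sex")]
  global_metrics <- unique(auc_global_long$metric)
  gmat <- sapply(global_metrics, function(m)
    auc_global_long$auc[auc_global_long$metric == m])
  rownames(gmat) <- mf$subject_id
  keep <- colSums(is.na(gmat)) == 0
  group_global <- permutation_family_test(
    gmat[, keep, drop = FALSE], groups, covars,
    n_perm = config$n_perm_group,
    seed = derive_seed(config$master_seed, "perm_global"), fdr = FALSE)
  utils::write.table(group_global,
                     file.path(config$out_dir, "group_global.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  nodal_rows <- list()
  for (m in unique(auc_nodal_long$metric)) {
    sub <- auc_nodal_long[auc_nodal_long$metric == m, ]
    nmat <- sapply(split(sub$auc, sub$node), identity)[, labels, drop = FALSE]
    fam <- permutation_family_test(
      nmat, groups, covars, n_perm = config$n_perm_group,
      seed = derive_seed(config$master_seed, paste0("perm_", m)), fdr = TRUE)
    fam <- cbind(metric = m, node = fam$metric,
                 fam[, c("delta", "p", "q")])
    nodal_rows[[m]] <- fam
  }
  group_nodal <- do.call(rbind, nodal_rows)
  rownames(group_nodal) <- NULL
  utils::write.table(group_nodal,
                     file.path(config$out_dir, "group_nodal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  edge_tests <- edgewise_group_test(z_list, groups)
  utils::write.table(edge_tests, file.path(config$out_dir, "edge_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_brainnet(edge_tests, labels,
                 file.path(config$out_dir, "significant_edges"))

  pat <- groups == "patient"
  cors <- NULL
  if (any(pat)) {
    scales <- c("lsas_total", "lsas_fear", "lsas_avoid", "hamd", "hama")
    for (m in c("aCp", "aLp")) {
      v <- gmat[pat, m]
      for (sc in scales) {
        ct <- tryCatch(spearman_clinical(v, mf[[sc]][pat]),
                       error = function(e) NULL)
        if (!is.null(ct))
          cors <- rbind(cors, data.frame(metric = m, scale = sc,
                                         rho = ct$rho, p = ct$p, n = ct$n))
      }
    }
    if (!is.null(cors)) {
      cors$p_bonferroni <- pmin(cors$p * nrow(cors), 1)
      utils::write.table(cors,
                         file.path(config$out_dir,
                                   "clinical_correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  tick("group_inference")

  # --- classification -------------------------------------------------------
  feat <- gmat[, intersect(c("aCp", "aLp"), colnames(gmat)[keep]),
               drop = FALSE]
  cls_report <- loocv(feat, groups,
                      nested_selection = !config$whole_sample_selection)
  sig <- permutation_significance(
    feat, groups, n_perm = config$n_perm_classifier,
    seed = derive_seed(config$master_seed, "classifier"),
    nested_selection = !config$whole_sample_selection)
  model <- mlda_fit(feat, groups)
  classification <- list(
    features = colnames(feat),
    selection = if (config$whole_sample_selection) "whole-sample" else "nested",
    weights = feature_weights(model),
    accuracy = cls_report$accuracy, sensitivity = cls_report$sensitivity,
    specificity = cls_report$specificity,
    z = sig$z, p = sig$p, n_permutations = sig$n_perm)
  jsonlite::write_json(classification,
                       file.path(config$out_dir, "classification.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.table(cbind(subject_id = mf$subject_id,
                           cls_report$predictions),
                     file.path(config$out_dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tick("classification")

  # --- provenance -----------------------------------------------------------
  cfg_json <- jsonlite::serializeJSON(config)
  provenance <- list(
    package_version = as.character(utils::packageVersion("restnet")),
    r_version = R.version.string,
    master_seed = config$master_seed,
    n_subjects = n_subj,
    n_edge_tests = nrow(edge_tests),
    selection_scheme = classification$selection,
    config_hash = sprintf("%08x",
                          sum(utf8ToInt(cfg_json) *
                                (seq_along(utf8ToInt(cfg_json)) %% 997)) %%
                            .Machine$integer.max),
    stage_seconds = as.list(timings))
  jsonlite::write_json(provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, auc_global = auc_global_long,
                 auc_nodal = auc_nodal_long, group_global = group_global,
                 group_nodal = group_nodal, edge_tests = edge_tests,
                 correlations = cors, classification = classification,
                 paths = list(out_dir = config$out_dir)))
}
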