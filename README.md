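# restnet

Graph-theoretic analysis of resting-state functional brain networks in R.

`restnet` is for researchers who have per-subject regional fMRI time series
(for example, mean BOLD signals of the 90 AAL atlas regions) and want the
standard whole-brain connectome workflow with honest statistics: functional
connectivity, small-world topology, group inference, and individual-level
classification. Because clinical resting-state datasets are rarely shareable,
the package also ships a synthetic cohort generator with a known ground
truth, so every stage can be exercised, calibrated, and power-checked without
any data download.

## The model

For each subject with a T x N time-series matrix the pipeline computes:

1. **Connectivity** — Pearson correlations between all region pairs,
   Fisher-transformed (`z = atanh(r)`) and restricted to positive couplings.
2. **Binary networks over a sparsity grid** — at each sparsity
   `S in {0.10, 0.11, ..., 0.34}` the strongest
   `K = round_half_up(S * N(N-1)/2)` edges are kept, giving 25 graphs per
   subject. Admissibility (mean degree > 2 log N, small-worldness > 1.1) is
   flagged, not enforced.
3. **Topological metrics** — clustering coefficient `Cp`, characteristic
   path length `Lp`, global/local efficiency, and their nodal versions;
   `Cp` and `Lp` are normalized by the means of 100 degree-preserving
   (Maslov–Sneppen) random networks into `gamma`, `lambda`, and
   small-worldness `sigma = gamma / lambda`.
4. **AUC summaries** — each metric's curve over the grid is integrated
   (trapezoid) into one threshold-independent scalar (`aCp`, `aLp`, ...).
5. **Group inference** — edgewise two-sample t-tests with Benjamini–Hochberg
   FDR over all N(N-1)/2 connections; age/sex-adjusted permutation tests
   (10,000 label permutations) on the AUC metrics; Spearman correlations with
   clinical scales (LSAS, HAMD, HAMA) in the patient group.
6. **Classification** — maximum-uncertainty LDA (pooled covariance
   eigenvalues below their mean are raised to the mean, so the model stays
   solvable with more features than subjects), leave-one-out
   cross-validation with fold-nested feature screening, and label-permutation
   significance (`z`, add-one `p`).

See the methods vignette (`vignettes/connectome-pipeline.Rmd`) for the full
model description, parameter meanings and defaults, and design rationale.

## Worked example

```r
library(restnet)

# 1. simulate a small two-group cohort with a planted topological deficit
cfg <- synthetic_config(n_per_group = 20, effect_size = 0.6, seed = 42)
sim <- simulate_cohort(cfg, file.path(tempdir(), "demo_cohort"))
cohort <- read_manifest(sim$manifest_path)

# 2. connectivity and AUC metrics for every subject
grid <- sparsity_grid()
aucs <- t(vapply(cohort$series, function(ts) {
  cm <- positive_part(fisher_z(pearson_matrix(ts)))
  mc <- metric_curves(cm, grid, n_null = 0, metrics = c("Cp", "Lp"))
  c(aCp = auc_of_curve(mc$global[, "Cp"], grid),
    aLp = auc_of_curve(mc$global[, "Lp"], grid))
}, c(aCp = 0, aLp = 0)))

# 3. covariate-adjusted permutation tests for the group difference
groups <- cohort$manifest$group
covars <- cohort$manifest[, c("age", "sex")]
for (m in colnames(aucs)) {
  r <- permutation_group_test(aucs[, m], groups, covars,
                              n_perm = 2000, seed = 1)
  cat(sprintf("%s: patient - control = %+.4f, permutation p = %.4f\n",
              m, r$observed_difference, r$p))
}

# 4. individual classification from the two AUC features
report <- loocv(aucs, groups)
sig <- permutation_significance(aucs, groups, n_perm = 200, seed = 2)
cat(sprintf("LOOCV accuracy %.3f (sens %.3f, spec %.3f), z = %.2f, p = %.4f\n",
            report$accuracy, report$sensitivity, report$specificity,
            sig$z, sig$p))
```

Output (about a minute on one core):

```
aCp: patient - control = -0.0024, permutation p = 0.0935
aLp: patient - control = +0.0063, permutation p = 0.0005
LOOCV accuracy 0.800 (sens 0.650, spec 0.950), z = 2.28, p = 0.0050
```

The planted deficit shows exactly the expected pattern: patients have a
longer characteristic path length (higher `aLp`, strongly significant) and
lower clustering (negative `aCp` difference; at this demonstration size of 20
per group the clustering test is underpowered — the test suite verifies that
at the study scale of 40 per group both effects are detected with q < 0.05 in
over 80% of replicates). The two AUC features classify individuals well above
chance (permutation p = 0.005).

One call runs everything and writes all result tables (admissibility report,
AUC tables, permutation and edgewise results, BrainNet Viewer `.node`/`.edge`
exports, classification report, provenance JSON):

```r
res <- run_all(run_config(synthetic = cfg, out_dir = "results_demo"))
```

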