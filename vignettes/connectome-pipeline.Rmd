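---
title: "Methods: small-world analysis of resting-state functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-world analysis of resting-state functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis model

`restnet` implements the canonical graph-theoretic workflow for resting-state
functional brain networks. Nodes are anatomical regions (by default the 90
regions of the AAL parcellation); edges are statistical dependencies between
regional BOLD time series.

**Connectivity.** For each subject the package computes the Pearson
correlation between every pair of regional mean time series, applies Fisher's
variance-stabilizing transform `z = atanh(r)` (with `|r|` clamped at
`1 - 1e-7` so duplicated signals keep finite, sortable edge weights), and
zeroes negative values: negative couplings have an ambiguous physiological
reading and the thresholding step below is defined on positive weights only.

**Thresholding.** Because no single cutoff is privileged, each connectivity
matrix is binarized over a *sparsity grid*: at sparsity `S` the strongest
`K = round_half_up(S * N(N-1)/2)` edges are kept. The default grid is 0.10 to
0.34 in steps of 0.01 (25 networks per subject), the range over which
small-world parameters are estimable while spurious edges stay limited.
Half-up rounding and lexicographic tie-breaking (descending weight, then
ascending node pair) make the edge set a deterministic function of the
matrix. Two admissibility criteria are recorded per network, not enforced:
mean degree above `2 log(N)` and small-worldness above 1.1. The base of that
logarithm is genuinely ambiguous in the field's usage — with the natural log
the densest end of the default grid (S = 0.10, mean degree 8.91 at N = 90)
marginally fails, with base 10 it passes — so the base is a configuration
option (`degree_log_base`, default natural log) and failures are flagged in
the run report rather than aborting, since analyses conventionally retain the
full grid.

**Metrics.** On each binary network the package computes the clustering
coefficient `Cp` (mean over nodes of the fraction of neighbour pairs that are
connected; 0 for degree < 2), characteristic path length `Lp` (mean shortest
hop distance), global and local efficiency (`Eglob`, `Eloc`), and their nodal
counterparts (degree, nodal global efficiency, nodal local efficiency — the
global efficiency of the induced neighbour subgraph). `Cp` and `Lp` are
normalized by their means over 100 degree-preserving random networks
(Maslov–Sneppen double-edge swaps, 10 rewiring trials per edge), giving
`gamma`, `lambda`, and small-worldness `sigma = gamma / lambda`. Each metric's
curve over the grid is reduced to a single threshold-independent scalar by
trapezoidal integration (the AUC: `aCp`, `aLp`, ...), which is exact for the
piecewise-linear curves being summarized.

**Disconnected pairs.** Thresholded networks can disconnect. The default
`Lp` convention averages over connected pairs only and logs the exclusion
count (the admissibility report tracks the largest-component fraction, which
stays near 1 over the default grid); a harmonic-mean alternative
(`lp_disconnected = "harmonic"`), which penalizes disconnection instead of
ignoring it, is exposed because toolboxes differ and neither convention is
universal. Efficiencies need no convention: unreachable pairs contribute
zero.

**Group inference.** Edgewise two-sample pooled-variance t-tests are run on
the Fisher-z values of all `N(N-1)/2` unique pairs (4005 at N = 90) with
Benjamini–Hochberg FDR across the whole edge family. AUC metrics are compared
by permutation: values are residualized once on age and sex over the pooled
sample, then group labels are permuted (10,000 draws by default, sizes
preserved) and the two-tailed add-one p-value is reported. Simple
residualization-then-permutation was chosen over Freedman–Lane style schemes
for transparency; with covariates independent of group labels under the null
the two agree asymptotically, and the permutation suite verifies the
uniformity of the resulting p-values empirically. Nodal metric families get
BH correction across nodes within each family; the seven global AUCs are
reported unadjusted, as is conventional for a small fixed set of global
parameters. Spearman rank correlations (mid-rank ties; exact p below n = 10,
t approximation otherwise) relate metrics to clinical scales in the patient
group, with a Bonferroni column for the tested (metric, scale) family.

**Classification.** Individual-level discrimination uses
maximum-uncertainty LDA: the pooled within-class covariance is
eigendecomposed and every eigenvalue below the eigenvalue mean is raised to
that mean, yielding an always-invertible covariance even with more features
than subjects; the discriminant is `w = S*^-1 (mu1 - mu2)` with the
equal-prior midpoint threshold, ties to the patient class. Performance is
estimated by leave-one-out cross-validation with t-test feature screening
(`p < 0.05`, uncorrected) re-run inside every training fold; if a fold has no
surviving feature the single smallest-p feature is used, a deterministic
fallback that keeps null-data folds well defined. `whole_sample_selection = TRUE`
switches to whole-sample pre-selection — the historical protocol, kept
reproducible but not the default because it leaks test information into the
screen. Significance comes from repeating the *entire* pipeline (screening
included) under permuted labels, reporting `z = (acc - mean_null)/sd_null`
and the add-one p-value. Sensitivity takes "patient" as the positive class.
Feature weights are reported raw and normalized to unit Euclidean norm; a
single-feature model has normalized weight 1 by construction.

A note on invariances: MLDA is invariant to *isotropic* affine rescaling of
the features (predictions unchanged, weights scale as `1/c`), but the
eigenvalue floor does not commute with feature-specific rescaling, so
anisotropic unit changes can move the decision boundary slightly. This is a
property of the estimator, not of the implementation; features on comparable
scales (such as the AUC metrics used here) are unaffected in practice.

# The synthetic cohort generator

The clinical dataset this pipeline was designed around is not publicly
deposited, so the package ships a generator whose output exercises every
downstream stage with a known ground truth.

**What it emulates.** Two groups of subjects with 90-region time series of
200 volumes at TR = 2 s, band-limited to 0.01–0.1 Hz (zero-phase second-order
Butterworth), with demographic covariates and clinical scores (LSAS
total/fear/avoidance, HAMD, HAMA) drawn from group-conditional normals
truncated at the instrument ranges, matching the published group summary
table shipped in `inst/extdata/clinical_scale_summaries.tsv`.

**Ground-truth topology.** The control coupling matrix is a distance-decay
ring lattice — coupling `a * exp(-d/l)` at ring distance `d`, defaults
`a = 0.55`, `l = 8` — overlaid with 100 deterministic, evenly spread
long-range chords (45 diameters plus offset-`N/3` chords) of strength
0.5–0.6. The decay tail mimics the distance-dependent correlation structure
of real functional connectomes and doubles as a *local reservoir*: when
couplings are attenuated, the edges that replace them at fixed sparsity come
from the next tier of local couplings rather than from uniform sampling
noise. That matters because uniformly placed noise edges act as random
shortcuts; early design iterations with purely modular templates (dense
within-module, sparse between) produced the clustering effect in the wrong
direction — removing between-module couplings purifies module neighbourhoods
and *raises* mean clustering — and could not raise path length at all once
freed edge budget leaked into noise shortcuts. The published phenotype
(patients: lower `aCp` *and* higher `aLp`) is only reproducible at fixed edge
count when the attenuation targets both systems against a spatially
structured reservoir.

**The planted effect.** Patient couplings equal control couplings with two
targeted sets multiplied by `(1 - effect_size)`: all long-range chords
(integration loss, raising `Lp`) and the local lattice couplings at ring
distance <= 2 plus alternate pairs at distance 3 (segregation loss, lowering
`Cp`). Both matrices are repaired to positive semi-definiteness (eigenvalue
floor `1e-6`, diagonal renormalization) — a deterministic function of the
configuration. At `effect_size = 0` the groups are identical (the null);
`effect_size = 1` removes the targeted couplings entirely. Defaults
(`effect_size = 0.6`, `noise_sd = 0.1`, `n_targeted_edges = 100`) were fixed
at design time as the operating point where a cohort of 40 per group detects
both directions with high power while single subjects still look noisy, and
were not revisited afterwards.

**Optional links.** `clinical_link > 0` correlates the patients' subject
level attenuation depth with their HAMD score (to give the Spearman stage a
detectable signal); `covariate_link` scales observation noise with age.
Both default to off, so clinical scores carry no built-in association with
topology.

**What it does not emulate.** No hemodynamic forward model, head motion,
physiological confounds, scanner drift, or spatial autocorrelation beyond the
ring metric; no NIfTI volumes (the package starts at regional time series,
with ROI-level band-pass and nuisance regression as optional preprocessing
analogues of the voxel-level chain). Passing tests on synthetic cohorts
therefore demonstrate the pipeline's statistical correctness and power under
a controlled generative model, not performance on clinical data.

# Numerical and reproducibility choices

* All randomness derives from one master seed through a counter-based child
  seed scheme (`derive_seed(master, stream, index)`), so per-subject and
  per-stage results are independent of execution order; identical
  configuration plus seed reproduces every numeric output byte for byte.
* Permutation p-values use the add-one estimator `(1 + #{|d*| >= |d|}) /
  (1 + P)`, with a scale-aware tolerance so numerically-zero observed
  differences are not undercut by exactly-zero permutation draws.
* The band-pass filter is applied to all columns at once through a
  vectorized zero-phase IIR pass that is numerically identical to the
  reference per-column `filtfilt`.
* Thresholding saturates gracefully: if a matrix has fewer positive entries
  than requested edges, all positive entries are kept and the network is
  flagged.
* Local efficiency uses a matrix-power BFS on each induced neighbour
  subgraph; all metric implementations are validated to `1e-12` against
  independent brute-force oracles (Floyd–Warshall, explicit neighbour-pair
  counting) on random graphs.

# Problem sizes used by the test suite

The shipped suites use scaled, stated sizes chosen to make the Monte-Carlo
assertions stable: the metric oracle suite checks 200 random graphs of up to
15 nodes; the calibration suite runs 100 null cohorts of 20 subjects per
group with 999 permutations on `aLp`; the planted-effect suite runs 20
cohorts of 40 per group at `effect_size = 0.6` with 2000 permutations; the
classifier suites use up to 40 subjects per group and 200–500 label
permutations. The acceptance script reruns the study-scale inference
(n = 40/group) once and the small-world profile on a 10-per-group cohort
with 20-network null ensembles.

# Interface

The package is driven from R: `simulate_cohort()` writes a cohort to disk,
`read_manifest()` loads one, and `run_all()` executes every stage and writes
the result tables (admissibility report, AUC tables, permutation and edgewise
results, BrainNet Viewer exports, classification report, provenance record).
The individual stage functions are exported and compose, so partial
pipelines — or a different orchestration — are one-liners away.

# Known limitations

* The generator's ring geometry is a one-dimensional stand-in for cortical
  distance; it reproduces the qualitative small-world regime (`gamma >> 1`,
  `lambda ~ 1`) but not the modular community structure of real connectomes.
* Connected-pair averaging makes `Lp` slightly optimistic on fragmented
  networks; prefer the harmonic convention (or the efficiency metrics) if
  analyses must go below the default sparsity range.
* Permutation tests assume exchangeability of residualized values under the
  null; strong covariate-group dependence would call for a Freedman–Lane
  scheme, which is not implemented.
* Leave-one-out estimates of accuracy have high variance at these sample
  sizes; the permutation z-score is the more stable summary.
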