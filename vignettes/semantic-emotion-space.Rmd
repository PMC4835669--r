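---
title: "Mapping semantic emotion space by multi-source metric MDS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping semantic emotion space by multi-source metric MDS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emospace)
```

## The measurement model

Sixteen emotion words are judged on four aspects — valence, arousal,
control, utility — by marking a 10 cm line; the mark position in millimeters
from the left end is the rating, a continuous scale from 0 to 100 with the
left end as the low pole (unpleasant, calm, uncontrolled, harmful).
`rating_dataset` stores one such value per participant × emotion × aspect;
ratings are kept as decimal millimeters, since the instrument is continuous
even though published tables print one decimal. Missing entries are allowed
(real answer sheets have skips), are excluded cell-wise from summaries and
pairwise from correlations, and get weight zero in the scaling engine.
`aspect_summary` reports the arithmetic mean and the sample (n − 1) standard
deviation per cell — the sample denominator is the reporting convention in
this literature; the data do not determine it.

Two dissimilarity families are built from the tensor:

1. **Profile distances** (`profile_distances`): each emotion's four mean
   ratings are coordinates in a theoretical 4D space, and the dissimilarity
   of two emotions is the Euclidean norm of their difference
   $s = \sqrt{w^2 + x^2 + y^2 + z^2}$. The attainable range is $[0, 200]$,
   $200 = 100\sqrt{4}$ being the main diagonal of a hypercube of side 100.
   The formula is defined for exactly four aspects; a $\sqrt{\sum}$
   generalization exists but must be requested explicitly
   (`generalized = TRUE`), because silently accepting other aspect counts
   would change the scale's meaning.
2. **Correlation-derived proximities** (`mds_sources`): per aspect, the
   emotions' rating vectors are correlated across participants (Spearman by
   default, average ranks for ties — ties are rare in continuous mm data)
   and mapped through $d = 1 - r$. The three stated anchor points
   ($r = 1 \to 0$, $r = 0 \to 1$, $r = -1 \to 2$) determine this line
   exactly, so no further rescaling is applied. Correlating across
   participants (one matrix per aspect) is the only reading consistent with
   "multiple source matrices" for this design: with a single rating per
   participant × emotion × aspect there is nothing to correlate within a
   participant.

## The scaling engine

`mds_fit` fits one common configuration $X \in \mathbb{R}^{n \times p}$ to
all $K$ sources at once — the identity (unweighted, common-space) model; no
per-source weighting of dimensions is estimated, because the analysis this
package implements reports a single shared space. The loss is the
normalized raw stress

$$\sigma(X) \;=\; \frac{\sum_k \sum_{i<j} w_{ijk}\,(\delta_{ijk} - d_{ij}(X))^2}
                       {\sum_k \sum_{i<j} w_{ijk}\,\delta_{ijk}^2},$$

with $d_{ij}(X)$ the Euclidean distance between rows of $X$. The
denominator is constant in $X$, so minimizing $\sigma$ is SMACOF
majorization of the raw-stress numerator: each iteration applies the
pooled Guttman transform $X^+ = V^+ B(X)\,X$, which provably never
increases stress. With unit weights $V^+ X = X/(nK)$ for centered $X$; with
general weights the Moore–Penrose inverse of the pooled weight Laplacian is
computed once (`MASS::ginv`; the matrices here are 16 × 16). Proximities
are treated metrically (ratio level); no ordinal transformation stage is
offered.

Numerical choices:

* **Initialization.** Default is classical Torgerson scaling
  (`stats::cmdscale`) of the element-wise mean source — exact when that
  source is Euclidean of rank ≤ p, and deterministic. A `simplex` start
  (regular-simplex vertices projected to p dimensions) is provided to
  mirror the originating analysis; `random` starts are seeded, and
  `restarts` adds seeded random multistarts keeping the best stress, the
  usual guard against local minima.
* **Stopping.** Iteration stops when the stress improvement falls below
  `tol` (default `1e-4`, the conventional PROXSCAL criterion; the published
  run's trajectory stops at an improvement of exactly 0.00010) or at
  `max_iter` (1000). The full trajectory — iteration, stress,
  improvement, with iteration 0 the initial stress — is returned, and
  improvements are asserted nonnegative in every test run.
* **Identifiability.** Solutions are defined only up to rotation,
  reflection and translation. Configurations are mean-centered but *not*
  rotated to principal axes; all cross-configuration comparisons go through
  `procrustes_align` (closed-form SVD solution; disparity = minimized SS
  over the centered SS of the target, in $[0,1]$ with scaling) or through
  distance matrices.
* **Stress terminology.** The engine reports normalized raw stress
  $\sigma$ and, for reference, Stress-1 $=\sqrt{\sigma}$. Total fit
  $= 1 - \sigma$ is the scree quantity; the Kruskal rule of thumb
  (`kruskal_label`) bins stress at 0.2 / 0.1 / 0.05 / 0.025 / 0 as
  poor / fair / good / excellent / perfect, half-open on the right.

`mds_scree` runs the fit over a dimensionality range (default 1–12). The
first row of a range starting at $p = 1$ carries its full fit as its
"gain" — the gain over the trivial zero-dimensional model — so that
`select_ndim`'s elbow rule ("smallest $p$ whose successor adds less than
`gain_threshold = 0.01` of fit") indexes gains consistently from $p = 1$.
With `warm_start = TRUE` each solution seeds the next (padded with a zero
column), making fit non-decreasing in $p$ by construction.

## Analysing a fitted space

* `config_distances` gives the aggregated-space distance matrix from the
  final coordinates.
* `matrix_cor` correlates the strict lower triangles of two aligned
  distance matrices — $k(k-1)/2 = 120$ pairs for 16 emotions. The naive
  p-value treats those pairs as independent, which distance-matrix entries
  are not; it is reported for comparability, but a Mantel permutation p
  (simultaneous row/column permutations, seeded) is available and is the
  defensible test.
* `frontiers` reports, per dimension and direction, the extreme emotion and
  any runner-ups within `margin = 0.05` of it. The margin was chosen so
  that coordinates published as jointly bordering a dimension (three
  emotions within 0.042 of each other on the first axis of the shipped
  configuration) are reported together; exact ties are broken by label
  order and flagged.
* `central_area_check` asks whether any emotion lies in an origin-centered
  ball of radius `radius_fraction` (default 0.25) times the largest object
  norm. "Central area" has no published quantitative definition, so the
  radius is an explicit parameter; the default reproduces the qualitative
  claim on the shipped configuration with a wide margin (smallest norm
  0.457 vs. radius 0.227), so the conclusion is insensitive to the choice.
* `project_config` selects two coordinate columns — a projection is a view
  of the same space, never a re-fit.

## The shipped study tables and their inconsistencies

`study_aspect_summary()`, `study_configuration()` and `study_distances()`
load the published tables (plain CSVs under `inst/extdata`). Two
documented inconsistencies are preserved verbatim, not repaired:

* The printed 4D distance matrix's **envy column** cannot be derived from
  the printed means (e.g. love–envy prints 114.2 but recomputes to ≈ 97.1);
  either the means' envy row or the distance matrix's envy column is a
  transcription error. All other entries recompute to within 0.15 (the
  printed means have only 1 decimal; recomputation from unrounded means
  explains discrepancies of that order, e.g. anger–sadness 33.5 vs 33.6).
* Three printed SDs (envy arousal 49.3, contempt arousal 43.8, happiness
  control 62.2) are implausibly large: the last two exceed the maximum SD
  of *any* distribution on $[0, 100]$ with the printed mean
  ($\sqrt{m(100-m)}$).

The published 3D solution itself (its 0.96 total fit, its iteration
trajectory, its coordinates) depends on the unreleased 187-participant
correlation matrices and cannot be recomputed here; the shipped
configuration is used as a fixture input for the space analyses, and the
engine's correctness is established by the property checks below.

## The rating simulator

`generator_spec`/`simulate_ratings` emulate the study conditions: 187
raters, 16 emotions, 4 aspects, per-cell target means and SDs defaulting to
the published table. Draws are truncated normals on $[0, 100]$ obtained by
**rejection sampling**, never by clipping — clipping would put point masses
at the scale ends, which a mark on a line does not produce.

The parent parameters are **moment-matched**: for each cell,
$(\mu_0, \sigma_0)$ are solved (2-parameter Nelder–Mead on the closed-form
truncated-normal moments) so that the *truncated* distribution has the
target mean and SD. Using the targets directly as parent parameters would
bias boundary-adjacent cells by several millimeters (a mean of 18 with SD
18 truncated at 0 shifts up by ≈ 5 mm), and the generator's contract is
that its targets are the realized moments. Two safeguards apply:

* The solver keeps the rejection-sampling acceptance probability above 2%.
  A truncated normal on a 100 mm scale cannot exceed SD ≈ 28.9 (the
  uniform limit), and near-boundary means constrain it further; cells whose
  target SD is unattainable get the closest attainable spread *with the
  mean preserved* and are flagged in `sd_capped` (on the default table
  this flags 13 of 64 cells, including the three anomalous SDs above).
  Realized means still match the targets to ≈ 0.2 mm.
* A target mean exactly at a scale boundary with positive SD is rejected as
  infeasible: approaching it drives the rejection rate above 99%.

With `planted` structure, a latent configuration induces target
inter-emotion correlations $1 - d/\max d$ (mirroring the $d = 1 - r$
transform, so planted geometry survives the pipeline), realized per aspect
through a Gaussian copula onto the same truncated-normal margins — the
eigenvalue-clipped nearest-PSD factor of the target matrix generates
correlated latents, and rank correlations survive the monotone margin
transform. `simulate_sources` is the direct recovery fixture: distance
matrices of a known configuration with independent multiplicative noise
$d(1+\varepsilon)$, $\varepsilon \sim N(0, \text{noise\_sd})$, truncated at
zero and symmetrized.

**What the simulator does not model:** participant random effects beyond
the optional latent factors, anchoring or acquiescence styles, and the true
(unknown) participant-level covariance of the study sample. Its defaults
are calibrated study *conditions*, not estimates of the study's raw data —
in particular, without planted structure the per-aspect correlation
matrices are pure noise, so a 3D solution fitted to such data is a valid
exercise of the engine but carries no semantic structure, and its distance
matrix is uncorrelated with the 4D profile distances. Passing tests on
synthetic data therefore demonstrate algorithmic correctness (calibration,
monotone convergence, recovery of planted geometry), not psychological
claims.

## Verification strategy and problem sizes

The test suite establishes, among others:

* exact reproduction oracles — stress against a double-loop summation,
  Spearman against first-principles average ranks, Procrustes against the
  closed form and against `vegan::procrustes`, Mantel against
  `vegan::mantel`;
* engine optimality — final stress within $10^{-4}$ of a 50-multistart
  BFGS minimization over raw coordinates on 5–6-object instances (the
  engine run at `tol = 1e-9` with 10 restarts, since the property concerns
  the reachable minimizer, not the default stopping rule);
* recovery — planted 16 × 3 configurations at 5% multiplicative distance
  noise over 4 sources are recovered with Procrustes disparity < 0.05
  across 20 seeds (observed ≈ 0.002–0.006); zero-noise sources give stress
  < $10^{-6}$ and scree fit saturating at the planting dimensionality;
* calibration — simulated means at n = 187 fall within 3 standard errors
  of every target cell; the Bonferroni aspect-independence check holds its
  familywise error level over 1000 null replicates.

Problem sizes were chosen to keep the full suite and the acceptance script
in the tens-of-seconds range on a single core: a 16-object, 4-source, 3D
fit converges in ≈ 15 ms, so 12-dimensional screes, 20-seed recovery
studies and 1000-replicate null simulations are all cheap.

## Known limitations

* Metric MDS only; no ordinal (non-metric) transformation stage, and no
  individual-differences (weighted) models — one shared space is the
  object of study.
* The scree's elbow rule inherits the arbitrariness of its threshold; for
  noiseless planted data saturation (fit ≈ 1, zero further gain) is the
  reliable signature, while the 0.01 elbow can select $p - 1$ when the
  planted geometry's last axis is flat.
* `frontiers` reports coordinate extremes; it does not test whether an
  emotion is *significantly* peripheral.
* The aspect-independence check offers two units of analysis (pooled
  observations or the 16 emotion means) because the original claim's unit
  is unstated; with pooled observations, mean differences between emotions
  alone can induce aspect correlations even when rater noise is
  independent.
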