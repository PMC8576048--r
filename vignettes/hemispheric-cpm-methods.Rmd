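---
title: "Methods: hemispheric connectome-based prediction of DBS outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hemispheric connectome-based prediction of DBS outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemiconn)
```

## The problem and the model

Subthalamic deep brain stimulation (STN-DBS) improves motor function in
Parkinson's disease, but the size of the improvement varies widely between
patients. The quantity being predicted here is the fractional motor
improvement

$$\Delta = \frac{\mathrm{UPDRS\text{-}III}_{pre} - \mathrm{UPDRS\text{-}III}_{post}}{\mathrm{UPDRS\text{-}III}_{pre}},$$

where UPDRS-III is the 27-item motor scale (items scored 0-4, totals on
0-108; lower is better). The predictors are pre-surgical resting-state
functional connectivity (FC) values: Pearson correlations between the
band-limited BOLD signals of all pairs of regions in a 246-region
bilateral parcellation (105 cortical + 18 subcortical regions per
hemisphere).

Because hemispheric asymmetry is the scientific question, the
$\binom{246}{2} = 30135$ edges are split into four disjoint networks by
`partition_edges()`:

* **LH** — both endpoints in the left hemisphere (7503 edges),
* **RH** — both endpoints in the right hemisphere (7503 edges),
* **Ho** — homotopic inter-hemispheric edges, linking each region to its
  geometrically corresponding partner (123 edges),
* **He** — all remaining (heterotopic) inter-hemispheric edges (15006).

Each network is modelled separately with the same two-stage estimator:

1. **Feature selection.** A bagged regression forest (20 trees; each tree
   trained on a bootstrap of the subjects) scores every edge by its
   out-of-bag (OOB) permutation importance
   $$X_k = \frac{1}{T}\sum_{t=1}^{T}\left(\mathrm{errOOB2}_{t,k} -
   \mathrm{errOOB1}_t\right),$$
   the average inflation in a tree's OOB mean squared error when edge $k$
   is permuted among that tree's OOB subjects. Edges with $X_k > 0.005$
   are kept.
2. **Prediction.** Ridge regression on the selected edges,
   $J(\theta) = \mathrm{MSE}(y, \hat y; \theta) +
   \alpha\,\tfrac12\sum_i \theta_i^2$ with an unpenalized intercept,
   with $\alpha$ (and a solver iteration cap) chosen by inner five-fold
   grid search.

Performance is evaluated by nested cross-validation: an outer
leave-one-subject-out loop in which, by default, *both* stages are refit
on the training subjects of every fold (`selection_scope = "per_fold"`),
so the held-out subject's connectivity and outcome touch nothing during
training. The report is the Pearson correlation $r$ (with its two-sided
t-transform $p$) between the $N$ held-out predictions and the true rates,
plus $R^2 = r^2$.

## The homotopic pairing is data, not geometry

The package never infers homotopic partners from coordinates: the
pairing is an explicit `partner_id` column of the atlas table, validated
as an involution that always crosses the midline. For the bundled
246-region atlas the partner of region $2k-1$ (left) is region $2k$
(right), following the odd/even interleaving of the bilateral labels.
Subcortical regions are lateralized and carry hemisphere labels exactly
like cortical ones, so they participate in all four networks. The
bundled table is generated programmatically from the parcellation's
published gyrus/subregion counts (24 gyri per hemisphere, seven lobes);
its systematic subregion names (`SFG_L_1`) are display labels, not
anatomical subregion names.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| trees (`n_trees`) | 20 | the published selection procedure |
| importance threshold | 0.005 | the published cut, on the MSE scale of an improvement-rate fraction in [0, 1] |
| `mtry` | $\lceil d/3 \rceil$ | conventional regression-forest default; depth unlimited, minimum node size 2 |
| perturbation | permute | classical OOB permutation; `gaussian_noise` implements the literal "add noise" reading |
| $\alpha$ grid | $10^{-3}\ldots10^{3}$, 13 points | log-spaced; the published grid is not stated |
| `max_iter` grid | 1000/5000/10000 | kept for grid-interface fidelity; the ridge solver is an exact SVD closed form, so this dimension never changes estimates and ties resolve to the smallest value |
| inner folds | 5 | the published inner loop |
| standardize | TRUE | penalized coefficients are scale-sensitive; training-fold statistics only |

Grid-search ties are broken toward larger $\alpha$ (stronger
regularization), then smaller `max_iter`. The threshold, grids and tree
controls are all configuration values, never hard-coded.

Two deliberate choices where the procedure was genuinely open:

* **No Fisher z-transform** — raw Pearson coefficients are the features;
  negative correlations are kept and nothing is sparsified.
* **Out-of-sample $R^2$** — the reported $R^2$ is the squared Pearson
  correlation of the LOOCV predictions against truth. An in-sample
  training $R^2$ would be the optimistic alternative; the out-of-sample
  number is the one that means anything.

Bootstrapping is over *subjects* (N draws with replacement per tree): an
OOB set can only arise from resampling observations, so this is the only
reading of the selection procedure consistent with its own OOB
definition. A bootstrap whose OOB set would be empty is redrawn (up to
100 attempts), which matters only at very small N.

## The synthetic cohort generator

No patient data ship with the package; `generate_cohort()` exists so the
whole pipeline can be validated by *parameter recovery*. Per subject $s$:

* a latent $u_s \sim \mathrm{Uniform}(0,1)$ sets the target correlation
  of every planted edge, $r_s = b + c\,u_s$ (defaults $b = 0.31$,
  $c = 0.70$, clipped to $(-0.95, 0.95)$);
* ROI signals are shared-component Gaussian mixtures: every region loads
  $\sqrt{\rho}$ on a global component (background correlation
  $\rho = 0.1$, a typical weak resting-state coupling), and each planted
  pair shares an extra private component raising its population
  correlation to exactly $r_s$; signals are band-limited to 0.01-0.1 Hz
  at TR = 2 s (identical linear filtering of two channels preserves their
  zero-lag correlation, so planted values survive filtering); 240
  volumes are emitted so that the standard discard-10 stage leaves 230;
* the outcome is $y_s = \sum_k \beta_k r_s + \varepsilon_s$,
  $\varepsilon_s \sim N(0, \sigma^2)$ (default $\sigma = 0.05$), clipped
  to $[0.05, 0.98]$ and converted to integer UPDRS-III scores: a
  pre-surgical score drawn around 43.79 (SD 11.78, truncated to
  [15, 105]) and a post score rounded from $pre\,(1-y_s)$ and forced
  below it. With $\sum_k \beta_k = 1$ the defaults give improvement rates
  with mean $\approx 0.66$ and SD $\approx 0.20$, matching the reported
  cohort moments (mean 65.62% ± 20.48%); the shared-component form is
  used because its population correlation is analytic, which makes
  planted effects verifiable.

`generate_null_cohort()` draws identical connectivity but outcomes that
are pure noise around the mean improvement — the calibration control. A
`signal_group` switch confines the planted outcome effect to one sex, to
exercise the group analysis.

What the generator does **not** emulate: hemodynamics, head motion,
scanner drift and physiological noise, spatially structured FC beyond a
uniform background, and any age/sex physiology. Passing recovery tests
therefore show the *estimator* works when its assumptions hold; they are
not evidence about patient data.

## Study sizes used by the validation suite

The packaged validation studies run on reduced synthetic atlases, chosen
so the full nested procedure (a forest plus importance scan inside every
outer fold) remains a desk-scale computation while every code path is the
production one:

* parameter recovery: 32 regions (RH = 120 edges), 60 subjects, 5
  disjoint planted RH edges with $\beta_k = 0.2$, $\sigma = 0.05$. The
  pipeline recovers at least 4 of the 5 planted edges in over 80% of
  outer folds and reaches LOOCV $r \ge 0.5$ on RH (about 0.95 in the
  packaged run), with all three signal-free networks lower.
* null calibration: 8 regions (RH = 6 edges), 40 subjects, 200
  replicate cohorts.
* group analysis: 12 regions, 60 subjects, a single concentrated planted
  edge confined to one sex.

## Known limitations

**Correlation-evaluated LOOCV is biased under the null.** When a
training fold selects no edges, the fallback model predicts the fold's
training mean $(\sum y - y_i)/(N-1)$ — which is *exactly*
anti-correlated with the held-out outcome across folds. Folds that do
select noise edges shrink toward the same training mean under the
CV-chosen penalty. On null cohorts (no edge-outcome association) the
LOOCV Pearson $r$ is therefore systematically negative, not centred at
zero (in the degenerate case where every fold falls back, $r = -1$
exactly): the packaged 200-replicate null study finds roughly
two-thirds of two-sided $p$ values below 0.05 instead of the nominal
5%. This is a known property of
correlation-evaluated leave-one-out prediction, not leakage — a mutation
test verifies that corrupting a held-out subject's outcome never changes
its prediction. The practical consequences: (i) a *positive* LOOCV $r$
cannot be manufactured by this artifact, so positive findings survive
it; (ii) the parametric two-sided $p$ on LOOCV predictions should not be
read as calibrated evidence against a null — a permutation test of the
whole pipeline is the honest alternative when calibration matters.

**Other limitations.** Voxel-level preprocessing (motion correction,
normalization, nuisance regression) is out of scope — inputs are
ROI-level series or precomputed connectivity, and no global-signal
regression or scrubbing stage is exposed. The gyrus-level report
aggregates by maximum (preserving the identity of the top edge; mean
available), since the aggregation statistic is a convention. With 7503+
edge features and ~60 subjects, per-fold forests on the full atlas are
computationally heavy; the four networks are seeded independently, so
they can be run separately or in parallel with identical results.

## Numerical choices

* Ridge is solved by SVD of the centred (optionally scaled) design; the
  $\alpha = 0$ limit returns the minimum-norm least-squares solution, so
  square full-rank problems interpolate exactly.
* Zero-variance feature columns never produce silent `NA`s: connectivity
  computation rejects them by ROI name.
* The band-pass is a zero-phase forward-backward Butterworth (order 4 per
  edge); columns are demeaned first, which removes DC exactly and avoids
  filter edge transients.
* All randomness flows through `derive_seed()`: cohorts, bootstraps, tree
  growing, per-(tree, feature) permutation sub-streams, inner-fold
  shuffles and per-fold seeds are reproducible from one integer and
  independent of evaluation order.
* Selection ties at equal importance are broken by canonical edge order
  $(i, j)$; grid ties toward larger $\alpha$, then smaller `max_iter`.
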