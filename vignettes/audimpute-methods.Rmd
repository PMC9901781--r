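---
title: "Validating audiometric imputation: models, sparsity simulation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating audiometric imputation: models, sparsity simulation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(audimpute)
```

This vignette is the package's own account of its methods: what is being
estimated, the modelling assumptions behind each component, the numerical
and design choices that were genuinely open, and what the synthetic test
bed does and does not establish about real data.

## The estimation target

Given a table of pure-tone thresholds (dB HL, eleven standard frequencies
from 125 Hz to 8 kHz) with realistic missingness, the question is: *how
much missing audiometric data can a given imputation model fill in before
the error becomes clinically meaningful?* The package operationalizes
this as the pooled root mean squared error over deliberately deleted
entries, with 10 dB as the safety threshold — anchored to the ±5 dB
test–retest reliability of routine audiometry (below which apparent
accuracy would indicate leakage rather than skill) and to ototoxicity
monitoring conventions for a clinically significant change.

Because the error depends on *which* entries are missing as much as on
how many, amputation is controlled along two independent axes:

- **Quantity** — either exactly `k` features deleted per audiogram, or
  per-audiogram counts drawn from a source dataset's own missing-count
  histogram truncated at a cap and renormalized (the `mirrored` policy,
  which keeps count 0 at its source probability so some scored subsets
  contain untouched rows, exactly as a matched real dataset would).
- **Distribution** — per-feature deletion weights. `real_world` uses a
  profiled dataset's per-frequency missing rates (with a 10⁻⁶ floor so
  never-missing features remain drawable); `random` is uniform;
  `terminal` and `central` place 3-fold weight on the outer six and
  central five frequencies respectively, normalized to sum to one.

Features are deleted by successive weighted draws without replacement
(draw, remove, renormalize). The simplest scheme consistent with fixed
per-row counts; its per-feature marginals equal the weight vector exactly
only at `k = 1`, and only approximately for larger `k`. This is
documented rather than corrected — the weights are a specification of
*relative preference*, not of exact marginal rates.

## The assessment engine

`run_nested_cv()` repeats, for each of `n_simulations`:

1. shuffle instances and split into disjoint outer folds;
2. per fold, profile the sparsity of the train and test subsets
   *independently, after the split* — the real-world weights and mirrored
   histograms used to amputate each subset come from that subset's own
   profile, so no missingness structure crosses the boundary;
3. drop incomplete instances to obtain dense subsets, amputate each under
   the policy, tune hyperparameters by inner k-fold grid search on
   freshly amputated splits of the dense training subset (objective:
   RMSE on masked entries), refit the winner, impute the amputated test
   subset;
4. pool scored entries across all outer folds into per-simulation MAE,
   RMSE and R², then aggregate simulations as mean ± Student-t interval.

Model comparisons use the two-sided Wilcoxon rank-sum test on the
per-simulation metric values (unpaired). Where exactly the rank-sum test
is applied — per-simulation aggregates, per-fold aggregates, or per-entry
errors — changes its power; per-simulation aggregates are used because
the simulation is the unit of independent replication here, and the
per-fold and per-entry alternatives share instances and are not
exchangeable. R²'s reference mean is the mean of the *true masked values
in the pooled sample*, which is why a constant (univariate) imputer can
score near or below zero.

If a run's pooled MAE falls below 4 dB the engine warns: real audiometric
data carries ±5 dB of test–retest noise, so sub-noise accuracy on real
data indicates overfitting or leakage. Synthetic data has no such noise
floor and may legitimately trigger this warning.

## The six model families

- **UI** — one statistic per feature (mean, median or mode; modal ties
  break toward the smaller threshold). The benchmark every multivariate
  model must beat.
- **INT** — within-audiogram interpolation. The abscissa is
  `log2(frequency)` by default: octave spacing is the audiological
  convention and makes adjacent test frequencies approximately
  equidistant (an integer-index axis is available for sensitivity
  checks). Interior gaps come from the interpolant through the
  neighboring observed points; exterior gaps extend the nearest
  interpolant. Linear uses the exact two-point closed form; `pchip` is
  monotone piecewise cubic Hermite (Fritsch–Carlson, no overshoot);
  `cubic_spline` is a natural spline falling back to linear below three
  observed points. A single observed point degenerates to constant
  extension for every method; zero observed points is an error.
- **KNN** — donor distance is the root *mean* squared difference over the
  features both rows observe (a partial Euclidean distance, so rows with
  different overlap sizes are comparable). Each missing entry is filled
  from the k nearest donors observing that feature, uniformly or with
  inverse-distance weights normalized to sum to one; exact-match donors
  (distance 0) take precedence under distance weighting. A query sharing
  no feature with any donor falls back to the training column mean and is
  counted in `n_fallback`.
- **MICE** — missing entries are initialized from univariate training
  statistics, then re-predicted for `m` rounds of round-robin penalized
  regressions of each feature on all others, fitted on the training rows
  where that feature was genuinely observed. The visit order is fixed
  ascending frequency (the choice is arbitrary but must be fixed for
  reproducibility). Estimators are lasso (`l1`) and ridge (`l2`) at fixed
  penalty `lambda`; both are appropriate for strongly multicollinear
  thresholds. `glmnet` parameterizes its penalty with constant factors
  that differ from the plain sum-of-squares-plus-penalty form, which is
  immaterial here because `lambda` is a tuned hyperparameter, not an
  interpreted quantity. Output is the final round or the per-entry mean
  of all rounds (SICE); `m = 0` returns the initialization. The procedure
  is a deterministic point-imputation engine — no posterior draws and no
  Rubin's-rules pooling, by design.
- **XGB** — one boosted-tree regressor per feature, trained on amputated
  inputs paired with the true (pre-amputation) values; missing inputs are
  routed by the trees' native default branches. Supervised pairs come
  from amputating the dense training subset under the same policy as the
  test subset, so training sees the same missingness process that testing
  measures.
- **NN** — a feed-forward perceptron mapping the whole encoded audiogram
  (observed values scaled to [0, 1], missing encoded as −1) to all eleven
  outputs, ReLU hidden layers, linear output, minibatch Adam on mean
  squared error. Zero hidden layers gives the linear-regression limit.
  The network is implemented in the package itself — initialization and
  minibatch order are driven by R's seeded RNG, so fits are exactly
  reproducible, which matters more for a validation framework than raw
  throughput.

All families obey two invariants: observed entries pass through
untouched, and every imputed value is clipped to [0, 120] dB. Clipping is
applied uniformly to all models (not only interpolation): the audiometer
range bounds any physically meaningful prediction, and uniform clipping
keeps the comparison fair.

Default search grids (overridable per `imputer_spec()`): UI strategy
{mean, median, mode}; INT method {linear, pchip, cubic_spline}; KNN
k ∈ {3, 5, 10, 20, 40} × weighting {uniform, distance}; MICE estimator
{l1, l2} × λ ∈ {0.01, 0.1, 1} × m ∈ {5, 10, 20} × init {mean, median} ×
output {last_round, sice_mean}; XGB trees {100, 300} × depth {3, 6} ×
learning rate {0.05, 0.1} × subsample {0.8, 1}; NN layers {1, 2} × width
{32, 64, 128} × learning rate {10⁻³, 10⁻²}. Grid search is exhaustive
with an optional deterministic truncation (`max_grid`) as a runtime
guard.

### Degenerate amputations

At extreme quantities (e.g. `k = 9` of 11 under real-world weights) the
most deletion-prone features survive so rarely that a dense subset of a
few hundred rows can lose a column entirely. Direct fits keep the strict
contract — fitting a univariate imputer on a feature with no observed
values is an error naming the feature — but the assessment engine fits
with `strict = FALSE`, substituting the grand mean of all observed
training entries for such features, mirroring how mainstream imputation
stacks skip empty features rather than abort. Inner-loop candidates that
fail on a degenerate split simply drop out of the search.

## The synthetic generator

`generate_dense()` draws from a multivariate normal whose correlation
between frequencies *i* and *j* is `exp(−|log2 fᵢ − log2 fⱼ| / ℓ)`,
quantizes to the 5 dB clinical step and clips to [0, 120] dB. The default
correlation length ℓ = 13 was calibrated once so the empirical 125–250 Hz
Pearson correlation of generated data is ≈ 0.92, the value reported for
pooled CI-candidate audiograms; the kernel reproduces the reported
falloff of correlation with octave distance. The default mean profile
(55 → 103 dB from low to high frequency, reflecting the high-frequency
losses typical of CI candidates) and marginal SD (22 dB) are calibration
choices — no published values exist for them — and are exposed for
override. `generate_sparse()` deletes each entry independently with its
frequency's target rate; the five elevated defaults (125 Hz 45.0 %,
750 Hz 65.4 %, 1500 Hz 72.9 %, 3000 Hz 30.7 %, 6000 Hz 29.5 %) are the
published rates, and the routinely tested frequencies default to 5 %.
Rows left with no observed value are redrawn.

**What the generator does not emulate.** Real registry missingness
co-occurs strongly within an audiogram (the same few frequencies are
skipped together), which leaves roughly 17 % of real audiograms complete.
Independent per-entry deletion at the same rates leaves only ≈ 2 %
complete. Test-bed consequences: a synthetic parent of a given size
yields far smaller dense fold subsets than a real parent of the same
size, so pipeline-level checks size the synthetic parent by the *dense
subset scale they need* — n = 24,000 for the model-selection surrogate
(dense training subsets of several hundred) and n = 96,000 for the
quantity sweep (≈ 1,200, at which point the rarely-surviving inter-octave
features retain enough observed rows to support their regressions).
These sizes are stated here as the package's own design choices for its
test bed. The generator also produces no audiogram-shape taxonomy
(notches, corner audiograms), no test–retest noise, and missingness that
is MCAR given the rates — so passing synthetic tests demonstrates that
the machinery is correct and that the qualitative model ordering holds
under the documented correlation structure, not that any specific dB
figure transfers to real data.

## Reproducibility

One root seed drives everything: simulation seeds and per-fold seeds are
derived deterministically (and kept below 2³¹), so any (simulation, fold)
cell can be re-run in isolation. XGB fits pin `nthread = 1` with
per-feature seeds; the perceptron's initialization and batching use R's
RNG; chained equations are deterministic given the data. The test suite
asserts bit-for-bit reproducibility of the full pipeline under a fixed
root seed.

## Known limitations

- Rows are treated as independent audiograms; if both ears of one
  patient appear, the framework does not account for their correlation.
- The Wilcoxon comparisons are uncorrected across model pairs by default
  (a Holm adjustment can be applied to the returned p-values); with 10
  simulations the test's resolution is limited.
- The mirrored policy preserves the truncated count histogram but not
  joint patterns of which features are missing together.
- Air/bone conduction, laterality and proprietary audiometer formats are
  out of scope; input is plain CSV with one column per frequency.
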