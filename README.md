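# audimpute

Validation of imputation models for sparse audiometric data.

## The problem

Pure-tone audiograms record hearing thresholds (dB HL) at eleven standard
frequencies: 125, 250, 500, 750, 1000, 1500, 2000, 3000, 4000, 6000 and
8000 Hz. In pooled clinical registries — cochlear-implant candidacy data in
particular — most audiograms are incomplete, because 125 Hz and the
inter-octave frequencies (750, 1500, 3000, 6000 Hz) are tested
inconsistently. Complete case analysis discards the large majority of
records and biases what remains, while naive imputation can introduce
clinically meaningful error (a threshold change of ≥ 10 dB).

`audimpute` implements a validation framework for audiometric imputation
built around two ideas:

1. **Structured amputation.** Test sets are built by deleting known values
   from dense audiograms under an explicit *sparsity policy* controlling
   two independent axes: the *quantity* of missing features per audiogram
   (a fixed count k, or counts mirrored from a source dataset's own
   histogram truncated at a cap) and the *distribution* of which features
   go missing (weights matching the real-world per-frequency missing
   rates, uniform, or 3-fold skews towards terminal or central
   frequencies).
2. **Repeated nested cross-validation.** Models are scored on the deleted
   entries only, with outer folds for performance estimation and inner
   folds for hyperparameter grid search. Sparsity is profiled per subset
   *after* the train/test split so no missingness information leaks, and
   whole simulations are repeated under reshuffled folds to stabilize the
   estimates.

Six model families share one fit/transform contract: univariate statistics
(UI), within-audiogram interpolation on the octave axis (INT: linear,
monotone piecewise cubic, cubic spline), k-nearest neighbors with partial
Euclidean distances (KNN), chained-equation penalized regression (MICE,
with the SICE mean-of-rounds variant), gradient boosted trees (XGB) and a
feed-forward perceptron (NN). Pooled errors over the masked entries are

    MAE  = Σ|yᵢ − fᵢ| / n
    RMSE = sqrt(Σ(yᵢ − fᵢ)² / n)
    R²   = 1 − Σ(yᵢ − fᵢ)² / Σ(yᵢ − ȳ)²

aggregated across simulations as mean ± t-interval, with Wilcoxon
rank-sum comparisons between models. Imputation of a given amount of
missing data is considered *safe* when pooled RMSE stays below 10 dB, the
conventional threshold for a clinically meaningful audiometric change.

A calibrated synthetic generator (multivariate normal on the octave axis
with exponentially decaying correlation, 5 dB quantization, clipping to
[0, 120] dB, and per-frequency missing rates matching published
CI-candidate data) makes the entire pipeline testable without any data
download.

## Worked example

```r
library(audimpute)

params <- generator_params(n = 8000, seed = 42)   # study-condition defaults
parent <- generate_sparse(params)
parent
#> <audiogram_matrix> 8000 audiograms x 11 frequencies (125/250/500/750/1000/1500/2000/3000/4000/6000/8000 Hz), 22017 missing cells

round(profile_sparsity(parent)$feature_missing_rate, 3)
#>   125   250   500   750  1000  1500  2000  3000  4000  6000  8000
#> 0.449 0.056 0.053 0.661 0.049 0.726 0.046 0.313 0.054 0.298 0.048

cfg <- cv_config(n_simulations = 2, outer_folds = 3, inner_folds = 2, seed = 7)
report <- run_nested_cv(parent,
                        imputer_spec("MICE", grid = list(lambda = c(0.01, 0.1))),
                        distribution = "real_world", quantity = "mirrored",
                        cfg = cfg)
report
#> <metric_report> MICE | real_world/mirrored | 2 sims
#>   MAE  5.64 (5.27-6.02)
#>   RMSE 7.77 (7.54-8.00)
#>   R2   0.896 (0.881-0.912)
```

Reading the output: per-instance missing counts were mirrored from the
parent's own histogram (capped at 6), the features to delete were drawn
with real-world weights, hyperparameters were tuned per outer fold by
inner grid search, and the chained-equation imputer recovered the deleted
thresholds with a pooled RMSE of 7.8 dB — under the 10 dB clinical
threshold, so this amount of missingness is safely imputable on data with
this structure.

Higher-level experiment drivers:

- `select_model()` — every model × every sparsity distribution, with
  pairwise Wilcoxon verdicts (a model-selection table);
- `sweep_quantity_distribution()` + `find_safe_cap()` — error as a
  function of the number of deleted features and the largest safely
  imputable count;
- `sweep_dataset_size()` — error as a function of dataset size.

A thin command-line front end (`inst/cli/audimpute`) exposes the same
machinery as `profile`, `amputate`, `impute`, `validate` and `simulate`
subcommands, each writing a JSON provenance manifest alongside its
outputs.

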