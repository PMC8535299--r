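# diafusion

Fusion of calibrated classifiers for diabetes-onset prediction from eight
routine clinical features (2-h plasma glucose, pregnancies, diastolic blood
pressure, triceps skinfold, 2-h serum insulin, BMI, diabetes pedigree
function, age).

The package is aimed at biostatisticians and ML practitioners who want a
fully reproducible, leak-free implementation of a multi-source fusion
architecture for tabular clinical data:

* **Data fusion** — schema-aligned concatenation of multiple sources
  (data-in/data-out), plus standalone Dempster–Shafer evidence utilities:
  basic probability assignments m(A) over a frame of discernment, the
  conflict coefficient K = Σ_{A₁∩A₂=∅} m₁(A₁)m₂(A₂), and the renormalized
  orthogonal sum m = m₁ ⊗ m₂.
* **Preprocessing** — explicit zero-to-missing marking, per-feature
  training-mean imputation, and z-score standardization S(x) = (x − x̄)/σ,
  always fit on training folds only.
* **Base classifiers** — a soft-margin SVM (dual: max Σaᵢ − ½ΣΣ aᵢaⱼyᵢyⱼ
  K(xᵢ,xⱼ) s.t. 0 ≤ aᵢ ≤ C, Σaᵢyᵢ = 0; linear/RBF/polynomial/sigmoid
  kernels) with cross-validated Platt calibration, and a from-scratch
  single-hidden-layer sigmoid network trained by per-sample backpropagation
  on E = ½Σ(τ − φ)².
* **Fusion decision layer** — member posteriors Pᵢ(φₜ|x) combined by the
  mean (or min/max/product) rule, μ(φₜ|x) = (1/L)ΣPᵢ(φₜ|x); decisions either
  by posterior comparison or against the tunable outlier threshold
  θ̄ = (P(φₒ)/P(φₜ))·(1/L)Σθᵢ.
* **Validation & evaluation** — stratified nested 5×3-fold cross-validation
  with grid search, mean ± sample-SD aggregation per fold, and the
  seven-entry evaluation matrix (accuracy, miss rate, sensitivity,
  specificity, precision, FPR, FNR).
* **Synthetic generator** — seedable multi-source two-class Gaussian tables
  with the study schema, configurable prevalence (default 33.5% diabetic),
  class separation, and zero-encoded missingness, so every stage is testable
  without any download.

See `vignettes/fusion-architecture.Rmd` for the model, conventions, and
design rationale.

## Worked example

```r
library(diafusion)

# two synthetic sources at one-tenth study scale, fused into one table
spec <- synthetic_spec(sources = c(survey = 986L, registry = 77L),
                       prevalence = 0.335, missing_rate = 0.05,
                       seed = derive_seed(42, "cv"))
fused <- fuse_datasets(generate_sources(spec))
print(fused$report)
#> Fusion report: 986 + 77 -> 1063 records ( 0 duplicates removed )
print(class_summary(fused$dataset))
#> n = 1063 records
#>   class 0 (non-diabetic): 720 (67.73%)
#>   class 1 (diabetic):     343 (32.27%)

# nested cross-validation of SVM, ANN and their fusion
ds <- mark_missing(fused$dataset)
grid <- grid_spec(svm_C = c(1, 10), svm_gamma = NA,
                  ann_hidden = c(4L, 8L), ann_rate = 0.5)
cv <- nested_cv(ds, grid, K = 5, inner_k = 3, seed = 42, ann_epochs = 40L)
metrics_table(list(SVM = cv$pooled_metrics$svm,
                   ANN = cv$pooled_metrics$ann,
                   `SVM-ANN` = cv$pooled_metrics$fusion))
#> Evaluation Matrix                     SVM          ANN      SVM-ANN
#> Accuracy                           82.50%       80.81%       82.31%
#> Specificity                        90.56%       88.47%       89.72%
#> Sensitivity                        65.60%       64.72%       66.76%
#> Precision                          76.79%       72.79%       75.58%
#> Miss rate                          17.50%       19.19%       17.69%
#> False Positive Ratio (FPR)           0.09         0.12         0.10
#> False Negative Ratio (FNR)           0.34         0.35         0.33
```

Reading the table: pooled over the five outer test folds, the SVM classifies
82.5% of held-out records correctly, the network 80.8%, and the fused model
82.3% — on this moderately overlapping synthetic mixture all three sit near
the generator's Bayes limit, the fused model trading a little specificity for
the best sensitivity (66.8% of diabetic records found). Miss rate is exactly
100 − accuracy, and FNR/FPR are the sensitivity/specificity complements as
proportions.

For deployment, `run_pipeline()` writes a `fusion_model.json` bundle
(preprocessing statistics, support vectors and multipliers, calibration,
network weights, priors); `predict_bundle(load_bundle(path), new_data)`
then returns per-row decisions with every intermediate quantity —
`mu_target`, `mu_outlier`, `y_avg`, `threshold`, and `label`.

## Command line

```sh
Rscript inst/cli/diafusion.R simulate --n 9858,769 --outdir data --seed 1
Rscript inst/cli/diafusion.R run --inputs data/source1.csv,data/source2.csv \
    --outdir out --seed 1
Rscript inst/cli/diafusion.R predict --bundle out/fusion_model.json \
    --inputs new_patients.csv --outdir out
```

Subcommands `simulate`, `fuse`, `run`, `train`, `predict`, `evaluate` share
one flag grammar; a YAML file via `--config` supplies defaults that explicit
flags override.

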