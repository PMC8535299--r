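#' Pipeline configuration
#'
#' Describes one end-to-end run: input CSV paths *or* a synthetic generator
#' spec (exactly one of the two), schema options, fusion-layer options,
#' cross-validation options, master seed, and output directory. Can be read
#' from a YAML file by the command-line wrapper; flags override file values.
#'
#' @param inputs character vector of CSV paths (one per source), or `NULL`.
#' @param synthetic a [synthetic_spec()], or `NULL`.
#' @param outdir output directory for artifacts.
#' @param seed master seed fanned out to every random stage.
#' @param rule,mode,theta_i fusion options (see [fusion_model()]).
#' @param K,inner_k fold counts.
#' @param grid a [grid_spec()].
#' @param ann_epochs epochs for network fits.
#' @param zero_is_missing,label_name schema options (see [default_schema()]).
#' @param dedup collapse exact duplicates at fusion time.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = NULL, synthetic = NULL, outdir = "diafusion-out",
                            seed = 1L, rule = "mean", mode = "mean_posterior",
                            theta_i = 1, K = 5L, inner_k = 3L, grid = grid_spec(),
                            ann_epochs = 40L,
                            zero_is_missing = c("Glucose", "BloodPressure",
                                                "SkinThickness", "Insulin", "BMI"),
                            label_name = "Outcome", dedup = FALSE) {
  if (is.null(inputs) == is.null(synthetic))
    stop("exactly one of 'inputs' and 'synthetic' must be given")
  if (!is.null(inputs)) {
    missing_files <- inputs[!file.exists(inputs)]
    if (length(missing_files))
      stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_spec"))
  structure(list(inputs = inputs, synthetic = synthetic, outdir = outdir,
                 seed = as.integer(seed), rule = rule, mode = mode,
                 theta_i = theta_i, K = as.integer(K), inner_k = as.integer(inner_k),
                 grid = grid, ann_epochs = as.integer(ann_epochs),
                 zero_is_missing = zero_is_missing, label_name = label_name,
                 dedup = dedup),
            class = "pipeline_config")
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = "")))
}

#' Run the full fusion architecture end to end
#'
#' Executes the study workflow in order: input, data fusion, preprocessing
#' (fit inside each training fold), stratified nested cross-validation with
#' grid search, SVM/ANN classification, classifier fusion, and evaluation.
#' Artifacts written to `config$outdir`: the fused CSV, the CV report JSON, a
#' metrics table (text), and a final fused-model bundle JSON trained on the
#' full dataset with the modal cross-validated hyperparameters.
#'
#' @param config a [pipeline_config()].
#' @return list with `cv` (the [nested_cv()] report), `bundle` (final model
#'   bundle), and `artifacts` (named file paths), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  schema <- default_schema(zero_is_missing = config$zero_is_missing,
                           label_name = config$label_name)

  sources <- if (!is.null(config$inputs)) {
    .log_stage("input", length(config$inputs), " CSV source(s)")
    lapply(config$inputs, read_table, schema = schema)
  } else {
    .log_stage("input", "synthetic sources: ",
               paste(config$synthetic$sources, collapse = " + "))
    generate_sources(config$synthetic)
  }

  fused <- fuse_datasets(sources, schema, dedup = config$dedup)
  .log_stage("fuse", fused$report$n_out, " records (",
             fused$report$duplicates_removed, " duplicates removed)")
  paths <- c(fused = file.path(config$outdir, "fused.csv"))
  write_table(fused$dataset, paths[["fused"]])

  ds <- mark_missing(fused$dataset)
  .log_stage("preprocess", sum(is.na(ds$values)),
             " missing cells marked (imputation fit per training fold)")

  cv <- nested_cv(ds, grid = config$grid, K = config$K, inner_k = config$inner_k,
                  seed = config$seed, ann_epochs = config$ann_epochs,
                  rule = config$rule, mode = config$mode, theta_i = config$theta_i)
  .log_stage("validate", "nested CV done; pooled fusion accuracy ",
             sprintf("%.2f%%", cv$pooled_metrics$fusion$accuracy))
  paths[["cv_report"]] <- file.path(config$outdir, "cv_report.json")
  writeLines(cv_report_to_json(cv), paths[["cv_report"]])
  paths[["metrics"]] <- file.path(config$outdir, "metrics_table.txt")
  tbl <- utils::capture.output(metrics_table(list(SVM = cv$pooled_metrics$svm,
                                                  ANN = cv$pooled_metrics$ann,
                                                  `SVM-ANN` = cv$pooled_metrics$fusion)))
  writeLines(tbl, paths[["metrics"]])

  bundle <- fit_bundle(ds, cv, config)
  paths[["bundle"]] <- file.path(config$outdir, "fusion_model.json")
  save_bundle(bundle, paths[["bundle"]])
  .log_stage("finish", "artifacts in ", config$outdir)
  invisible(list(cv = cv, bundle = bundle, artifacts = paths))
}

.modal_choice <- function(chosen, what) {
  keys <- vapply(chosen, function(ch) paste(unlist(ch[[what]]), collapse = "/"), "")
  pick <- names(sort(table(keys), decreasing = TRUE))[1]
  chosen[[match(pick, keys)]][[what]]
}

#' Fit a deployable fused-model bundle on a full dataset
#'
#' Trains preprocessing, SVM (+ Platt calibration), the network, and the
#' fusion layer on all rows, using the modal hyperparameters chosen across
#' the outer CV folds (first fold wins ties).
#'
#' @param ds a [mark_missing()]-ed [labeled_dataset()].
#' @param cv a [nested_cv()] report on the same data.
#' @param config the [pipeline_config()].
#' @return An object of class `fusion_bundle`.
#' @export
fit_bundle <- function(ds, cv, config) {
  svm_hp <- .modal_choice(cv$chosen, "svm")
  ann_hp <- .modal_choice(cv$chosen, "ann")
  prep <- fit_preprocessor(ds)
  z <- prep$transform(ds)
  kern <- kernel_spec("rbf", gamma = .resolve_gamma(svm_hp$gamma, ncol(z$values)))
  svm_cal <- calibrated_svm(z, C = svm_hp$C, kernel = kern,
                            seed = derive_seed(config$seed, "platt-bundle"))
  svm_fit <- svm_cal$model
  cal <- svm_cal$cal
  ann_fit <- train_ann(z, ann_config(n_hidden = ann_hp$n_hidden,
                                     learning_rate = ann_hp$rate,
                                     epochs = config$ann_epochs,
                                     seed = derive_seed(config$seed, "ann-bundle")))
  fm <- fit_fusion(list(svm_member(svm_fit, cal), ann_member(ann_fit)), z$labels,
                   theta_i = config$theta_i, rule = config$rule, mode = config$mode)
  structure(list(imputer = prep$imputer, standardizer = prep$standardizer,
                 svm = svm_fit, cal = cal, ann = ann_fit,
                 priors = fm$priors, theta_i = fm$theta_i,
                 rule = fm$rule, mode = fm$mode,
                 zero_is_missing = ds$schema$zero_is_missing,
                 label_name = ds$schema$label_name),
            class = "fusion_bundle")
}

#' Predict with a fused-model bundle
#'
#' Applies the bundled zero-to-missing marking, imputation, standardization,
#' and fusion decision to new rows.
#'
#' @param bundle a [fit_bundle()] or [load_bundle()] object.
#' @param ds a raw-scale [labeled_dataset()].
#' @return the [fusion_classify()] decision data.frame.
#' @export
predict_bundle <- function(bundle, ds) {
  z <- standardize(bundle$standardizer, impute(bundle$imputer, mark_missing(ds)))
  fm <- fusion_model(list(svm_member(bundle$svm, bundle$cal), ann_member(bundle$ann)),
                     bundle$priors, theta_i = bundle$theta_i,
                     rule = bundle$rule, mode = bundle$mode)
  fusion_classify(fm, z$values)
}

#' Save a fused-model bundle as a JSON manifest
#' @param bundle a [fit_bundle()] object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_bundle <- function(bundle, path) {
  obj <- list(
    preprocessing = list(feature_names = bundle$imputer$feature_names,
                         impute_means = bundle$imputer$means,
                         location = bundle$standardizer$location,
                         scale = bundle$standardizer$scale),
    svm = jsonlite::fromJSON(svm_to_json(bundle$svm, bundle$cal)),
    ann = jsonlite::fromJSON(ann_to_json(bundle$ann)),
    fusion = list(p_target = bundle$priors$p_target, theta_i = bundle$theta_i,
                  rule = bundle$rule, mode = bundle$mode),
    schema = list(zero_is_missing = bundle$zero_is_missing,
                  label_name = bundle$label_name)
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Load a fused-model bundle from its JSON manifest
#' @param path JSON path from [save_bundle()].
#' @return An object of class `fusion_bundle`.
#' @export
load_bundle <- function(path) {
  o <- jsonlite::fromJSON(path)
  svm_pair <- svm_from_json(jsonlite::toJSON(o$svm, auto_unbox = TRUE, digits = NA))
  feats <- o$preprocessing$feature_names
  structure(list(
    imputer = structure(list(means = stats::setNames(unlist(o$preprocessing$impute_means), feats),
                             feature_names = feats), class = "imputation_model"),
    standardizer = structure(list(location = stats::setNames(unlist(o$preprocessing$location), feats),
                                  scale = stats::setNames(unlist(o$preprocessing$scale), feats),
                                  feature_names = feats), class = "standardization_model"),
    svm = svm_pair$model, cal = svm_pair$cal,
    ann = ann_from_json(jsonlite::toJSON(o$ann, auto_unbox = TRUE, digits = NA)),
    priors = class_priors(o$fusion$p_target),
    theta_i = o$fusion$theta_i, rule = o$fusion$rule, mode = o$fusion$mode,
    zero_is_missing = o$schema$zero_is_missing, label_name = o$schema$label_name
  ), class = "fusion_bundle")
}
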