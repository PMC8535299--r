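#' Specification of the synthetic multi-source diabetes generator
#'
#' Emulates the study design — several tabular sources sharing the
#' eight-feature schema, an imbalanced two-class outcome, and optional
#' zero-encoded missingness — with class-conditional Gaussian features. The
#' default class profiles loosely mimic published Pima-style class summaries
#' (higher glucose, insulin, BMI and age in the diabetic class); they are
#' deliberately simple and make no claim of clinical realism. `separation`
#' scales the gap between the class mean vectors around their midpoint:
#' 1 keeps the default (moderately overlapping) profiles, 0 makes the classes
#' indistinguishable, 3 makes them nearly separable.
#'
#' @param sources named integer vector of per-source record counts
#'   (default: a large survey-sized source of 9858 and a small registry-sized
#'   source of 769).
#' @param prevalence probability of the diabetic class (default 0.335, the
#'   fused-study share).
#' @param class_means 2 x 8 matrix of class mean vectors (row 1 = class 0).
#' @param class_sds length-8 positive within-class standard deviations.
#' @param separation non-negative multiplier on the class mean gap.
#' @param missing_rate per-cell missingness probability applied to
#'   zero-is-missing features in [generate_sources()].
#' @param seed integer seed.
#' @param schema a [feature_schema()].
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(sources = c(survey = 9858L, registry = 769L),
                           prevalence = 0.335,
                           class_means = default_class_means(),
                           class_sds = default_class_sds(),
                           separation = 1,
                           missing_rate = 0,
                           seed = 1L,
                           schema = default_schema()) {
  if (!length(sources) || any(sources < 1)) stop("each source needs n >= 1")
  if (is.null(names(sources)) || any(!nzchar(names(sources))))
    names(sources) <- paste0("source", seq_along(sources))
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  stopifnot(nrow(class_means) == 2, ncol(class_means) == nrow(schema$features),
            length(class_sds) == nrow(schema$features), all(class_sds > 0),
            separation >= 0, missing_rate >= 0, missing_rate < 1)
  structure(list(sources = sources, prevalence = prevalence,
                 class_means = class_means, class_sds = class_sds,
                 separation = separation, missing_rate = missing_rate,
                 seed = as.integer(seed), schema = schema),
            class = "synthetic_spec")
}

#' Default class-conditional mean profiles
#' @return 2 x 8 matrix (row 1 = non-diabetic, row 2 = diabetic).
#' @export
default_class_means <- function() {
  m <- rbind(
    `0` = c(110, 3.3, 68, 27, 130, 30.9, 0.43, 31),
    `1` = c(142, 4.9, 71, 33, 207, 35.1, 0.55, 37)
  )
  colnames(m) <- default_schema()$features$name
  m
}

#' Default within-class standard deviations
#' @return length-8 positive vector.
#' @export
default_class_sds <- function() {
  stats::setNames(c(26, 3.2, 12, 10, 100, 6.9, 0.3, 11),
                  default_schema()$features$name)
}

#' Generate synthetic multi-source datasets
#'
#' Per source, labels are Bernoulli(prevalence) and features are drawn from
#' independent class-conditional Gaussians whose mean gap is scaled by
#' `separation`. Values are then coerced to the schema kinds: integer
#' features are rounded, age is clipped into [21, 77], and all features are
#' floored at zero (negative clinical measurements do not occur). If
#' `missing_rate > 0`, [inject_missing()] is applied to each source.
#' Everything is deterministic given the spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @return named list of [labeled_dataset()] objects, one per source.
#' @export
generate_sources <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sc <- spec$schema
  d <- nrow(sc$features)
  mid <- colMeans(spec$class_means)
  mu <- sweep(sweep(spec$class_means, 2, mid, "-") * spec$separation, 2, mid, "+")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  out <- vector("list", length(spec$sources))
  names(out) <- names(spec$sources)
  for (s in seq_along(spec$sources)) {
    n <- spec$sources[[s]]
    set.seed(derive_seed(spec$seed, paste0("source-", names(spec$sources)[s])))
    labels <- stats::rbinom(n, 1, spec$prevalence)
    vals <- matrix(stats::rnorm(n * d), n, d)
    vals <- sweep(vals, 2, spec$class_sds, "*") + mu[labels + 1L, , drop = FALSE]
    int_cols <- which(sc$features$kind == "integer")
    vals[, int_cols] <- round(vals[, int_cols])
    vals <- pmax(vals, 0)
    age_col <- which(sc$features$name == "Age")
    if (length(age_col)) vals[, age_col] <- pmin(pmax(vals[, age_col], 21), 77)
    ds <- labeled_dataset(vals, labels, names(spec$sources)[s], sc)
    if (spec$missing_rate > 0)
      ds <- inject_missing(ds, spec$missing_rate,
                           seed = derive_seed(spec$seed, paste0("missing-", s)))
    out[[s]] <- ds
  }
  out
}

#' Randomly blank eligible cells
#'
#' Each cell of a zero-is-missing feature is independently set missing with
#' probability `rate`; labels and other features are untouched. Deterministic
#' given the seed.
#'
#' @param ds a [labeled_dataset()].
#' @param rate missingness probability in [0, 1).
#' @param seed integer seed.
#' @return A [labeled_dataset()] with injected missing cells.
#' @export
inject_missing <- function(ds, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0,1)")
  if (rate == 0) return(ds)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  vals <- ds$values
  for (nm in ds$schema$zero_is_missing) {
    hit <- stats::runif(nrow(vals)) < rate
    vals[hit, nm] <- NA
  }
  labeled_dataset(vals, ds$labels, ds$sources, ds$schema)
}
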