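#' Basic probability assignment over a frame of discernment
#'
#' A mass function assigns belief mass to non-empty subsets (focal elements)
#' of a finite frame of hypotheses; the masses sum to one. The larger the
#' mass on a focal element, the stronger the support of the evidence for it.
#'
#' @param frame character vector of distinct hypothesis labels.
#' @param focal list of character vectors, each a non-empty subset of `frame`.
#' @param mass numeric vector of masses, one per focal element, each >= 0 and
#'   summing to 1 (within 1e-9).
#' @return An object of class `mass_function`. Focal elements are stored in a
#'   canonical (sorted, deduplicated) form.
#' @examples
#' m <- mass_function(c("A", "B"), list("A", "B"), c(0.6, 0.4))
#' @export
mass_function <- function(frame, focal, mass) {
  frame <- as.character(frame)
  if (anyDuplicated(frame) || length(frame) == 0L)
    stop("frame must be a non-empty set of distinct hypotheses")
  if (!is.list(focal) || length(focal) != length(mass))
    stop("focal and mass must have equal length")
  focal <- lapply(focal, function(s) sort(unique(as.character(s))))
  for (s in focal) {
    if (length(s) == 0L) stop("focal elements must be non-empty")
    if (!all(s %in% frame)) stop("focal element outside frame: {", paste(s, collapse = ","), "}")
  }
  keys <- vapply(focal, paste, "", collapse = "\r")
  if (anyDuplicated(keys)) {
    # aggregate duplicated focal sets, preserving first-seen order
    ord <- unique(keys)
    mass <- vapply(ord, function(k) sum(mass[keys == k]), 0)
    focal <- focal[match(ord, keys)]
    keys <- ord
  }
  mass <- as.numeric(mass)
  if (any(mass < -1e-12)) stop("masses must be non-negative")
  mass <- pmax(mass, 0)
  if (abs(sum(mass) - 1) > 1e-9)
    stop("masses must sum to 1 (got ", format(sum(mass)), ")")
  structure(list(frame = sort(frame), focal = focal, mass = mass, keys = keys),
            class = "mass_function")
}

#' Vacuous mass function
#'
#' All mass on the full frame: total ignorance, the identity element of
#' Dempster's combination rule.
#'
#' @param frame character vector of hypotheses.
#' @return A [mass_function()].
#' @export
vacuous_mass <- function(frame) mass_function(frame, list(frame), 1)

#' @export
print.mass_function <- function(x, ...) {
  cat("Mass function over {", paste(x$frame, collapse = ", "), "}\n", sep = "")
  for (i in seq_along(x$focal))
    cat(sprintf("  m({%s}) = %.6g\n", paste(x$focal[[i]], collapse = ","), x$mass[i]))
  invisible(x)
}

.same_frame <- function(m1, m2) identical(m1$frame, m2$frame)

#' Conflict between two bodies of evidence
#'
#' The conflict coefficient K: the total product mass that two sources assign
#' to incompatible (empty-intersection) pairs of focal elements. K = 0 means
#' fully compatible evidence, K = 1 total conflict (Dempster combination
#' undefined).
#'
#' @param m1,m2 [mass_function()] objects over the same frame.
#' @return K in [0, 1].
#' @export
conflict <- function(m1, m2) {
  if (!.same_frame(m1, m2)) stop("mass functions are defined over different frames")
  k <- 0
  for (i in seq_along(m1$focal))
    for (j in seq_along(m2$focal))
      if (length(intersect(m1$focal[[i]], m2$focal[[j]])) == 0L)
        k <- k + m1$mass[i] * m2$mass[j]
  min(max(k, 0), 1)
}

#' Combine two bodies of evidence by Dempster's rule
#'
#' Orthogonal sum of two basic probability assignments: product masses of
#' focal pairs are routed to their intersections and renormalized by
#' 1/(1 - K) where K is the [conflict()] coefficient.
#'
#' @param m1,m2 [mass_function()] objects over the same frame.
#' @return The combined [mass_function()].
#' @export
combine_bpa <- function(m1, m2) {
  if (!.same_frame(m1, m2)) stop("mass functions are defined over different frames")
  acc <- new.env(parent = emptyenv())
  k <- 0
  for (i in seq_along(m1$focal)) {
    for (j in seq_along(m2$focal)) {
      inter <- intersect(m1$focal[[i]], m2$focal[[j]])
      w <- m1$mass[i] * m2$mass[j]
      if (length(inter) == 0L) {
        k <- k + w
      } else {
        key <- paste(inter, collapse = "\r")
        acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + w
      }
    }
  }
  if (k >= 1 - 1e-12)
    stop("total conflict (K = 1): Dempster combination undefined")
  keys <- ls(acc)
  focal <- strsplit(keys, "\r", fixed = TRUE)
  mass <- vapply(keys, function(key) acc[[key]], 0) / (1 - k)
  mass_function(m1$frame, focal, mass / sum(mass))
}

#' Combine a list of mass functions
#'
#' Left fold of [combine_bpa()]; Dempster's rule is commutative and
#' associative, so the result is order-independent.
#'
#' @param ms non-empty list of [mass_function()] objects sharing a frame.
#' @return The combined [mass_function()].
#' @export
combine_many <- function(ms) {
  if (!length(ms)) stop("need at least one mass function")
  Reduce(combine_bpa, ms)
}

#' Serialize a mass function to JSON
#' @param m a [mass_function()].
#' @return JSON string `{"frame": [...], "masses": [{"subset": [...], "mass": x}, ...]}`.
#' @export
mass_to_json <- function(m) {
  obj <- list(
    frame = m$frame,
    masses = lapply(seq_along(m$focal),
                    function(i) list(subset = m$focal[[i]], mass = m$mass[i]))
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}

#' Deserialize a mass function from JSON
#' @param txt JSON string or file path produced by [mass_to_json()].
#' @return A [mass_function()].
#' @export
mass_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt, simplifyDataFrame = FALSE, simplifyVector = FALSE)
  mass_function(unlist(obj$frame),
                lapply(obj$masses, function(e) unlist(e$subset)),
                vapply(obj$masses, function(e) as.numeric(e$mass), 0))
}
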