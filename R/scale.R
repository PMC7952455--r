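#' Ordered abundance scale
#'
#' The ordinal outcome space shared by the models, prediction machinery and
#' metrics: CFU values \eqn{c_1 < c_2 < \dots < c_K} observed in a serial
#' dilution experiment. The total-microbial-load experiment uses five classes
#' (`0.84e2 ... 0.84e6` CFU); the taxon-specific experiment uses four
#' (`2e2 ... 2e5` CFU per taxon).
#'
#' @param classes strictly increasing positive CFU values, length >= 2.
#' @return an object of class `abundance_scale` with elements `classes` and `K`.
#' @examples
#' total_scale() # 0.84e2 .. 0.84e6
#' taxon_scale() # 2e2 .. 2e5
#' @export
abundance_scale <- function(classes) {
  classes <- as.numeric(classes)
  if (length(classes) < 2) stop("an abundance scale needs at least 2 classes")
  if (any(!is.finite(classes)) || any(classes <= 0))
    stop("class values must be finite and positive")
  if (any(diff(classes) <= 0)) stop("class values must be strictly increasing")
  structure(list(classes = classes, K = length(classes)),
            class = "abundance_scale")
}

#' @rdname abundance_scale
#' @export
total_scale <- function() abundance_scale(0.84 * 10^(2:6))

#' @rdname abundance_scale
#' @export
taxon_scale <- function() abundance_scale(2 * 10^(2:5))

#' @export
print.abundance_scale <- function(x, ...) {
  cat("<abundance_scale> K =", x$K, "classes (CFU):",
      paste(format(x$classes, scientific = TRUE), collapse = ", "), "\n")
  invisible(x)
}

#' Map CFU values to class indices on a scale
#'
#' Values must match scale classes up to small relative tolerance; used to
#' translate recorded true abundances into ordinal outcomes.
#'
#' @param cfu numeric CFU values.
#' @param scale an [abundance_scale()].
#' @return integer class indices in `1..K`.
#' @export
class_index <- function(cfu, scale) {
  stopifnot(inherits(scale, "abundance_scale"))
  idx <- vapply(cfu, function(v) {
    hit <- which(abs(log10(v) - log10(scale$classes)) < 1e-8)
    if (length(hit) != 1L)
      stop("CFU value ", v, " is not a class of the scale")
    hit
  }, integer(1))
  idx
}

#' Nearest scale class in log10 space
#'
#' Used to turn continuous expectation-based CFU predictions into ordinal
#' classes when computing classification metrics.
#'
#' @inheritParams class_index
#' @return integer class indices in `1..K`.
#' @export
nearest_class <- function(cfu, scale) {
  stopifnot(inherits(scale, "abundance_scale"))
  if (any(cfu <= 0)) stop("CFU values must be positive")
  lc <- log10(scale$classes)
  vapply(cfu, function(v) which.min(abs(log10(v) - lc)), integer(1))
}

#' Modeling-scale transform of read counts
#'
#' `log10(count + 1)`: the pseudocount keeps zero counts finite, and the log10
#' scale matches the orders-of-magnitude spread of amplicon library sizes.
#'
#' @param counts non-negative numeric vector.
#' @return `log10(counts + 1)`.
#' @examples
#' model_scale(c(0, 999)) # 0, 3
#' @export
model_scale <- function(counts) {
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  log10(counts + 1)
}
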