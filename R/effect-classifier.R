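#' @title Equivalence-range effect classification
#' @description
#' A pooled ratio estimate is classified on three dimensions relative to a
#' prespecified equivalence range (default 0.9 to 1.11): direction (where
#' the point estimate sits), precision (whether the 95% CI crosses a range
#' boundary), and interpretation (their combination). Outcome polarity says
#' which side of the range is desirable: for mortality a ratio below the
#' range is benefit; for clinical improvement it is harm.
#' @name effect_classifier
NULL

#' Equivalence-range configuration
#'
#' @param range_low,range_high Boundaries of the equivalence range on the
#'   ratio scale; the range is closed, so a point estimate equal to a
#'   boundary counts as no-or-minimal effect.
#' @return Object of class `equivalence_config`.
#' @export
equivalence_config <- function(range_low = 0.9, range_high = 1.11) {
  if (!(range_low > 0 && range_low < range_high)) {
    stop("need 0 < range_low < range_high", call. = FALSE)
  }
  structure(list(range_low = range_low, range_high = range_high),
            class = "equivalence_config")
}

#' Direction of an effect relative to the equivalence range
#'
#' @param point Point estimate on the ratio scale (> 0).
#' @param polarity `"lower_is_benefit"` (e.g. mortality) or
#'   `"higher_is_benefit"` (e.g. clinical improvement).
#' @param config An [equivalence_config()].
#' @return `"benefit"`, `"harm"` or `"no_or_minimal"`.
#' @export
classify_direction <- function(point,
                               polarity = c("lower_is_benefit",
                                            "higher_is_benefit"),
                               config = equivalence_config()) {
  polarity <- match.arg(polarity)
  if (!is.finite(point) || point <= 0) {
    stop("point estimate must be a positive ratio", call. = FALSE)
  }
  if (point >= config$range_low && point <= config$range_high) {
    return("no_or_minimal")
  }
  below <- point < config$range_low
  if (polarity == "lower_is_benefit") {
    if (below) "benefit" else "harm"
  } else {
    if (below) "harm" else "benefit"
  }
}

#' Precision of an effect relative to the equivalence range
#'
#' Imprecise iff the open interval `(ci_low, ci_high)` contains a range
#' boundary; a CI endpoint exactly on a boundary does not count as a
#' crossing.
#'
#' @param ci_low,ci_high 95% CI bounds on the ratio scale.
#' @inheritParams classify_direction
#' @return `"precise"` or `"imprecise"`.
#' @export
classify_precision <- function(ci_low, ci_high, config = equivalence_config()) {
  if (!(is.finite(ci_low) && is.finite(ci_high)) || ci_low <= 0 ||
      ci_low > ci_high) {
    stop("need 0 < ci_low <= ci_high", call. = FALSE)
  }
  crosses <- function(b) ci_low < b && b < ci_high
  if (crosses(config$range_low) || crosses(config$range_high)) {
    "imprecise"
  } else {
    "precise"
  }
}

#' Full interpretation of an effect estimate
#'
#' @param point,ci_low,ci_high Estimate and CI on the ratio scale; ignored
#'   when `estimable` is `FALSE`.
#' @param estimable Logical; a meta-analysis with no contributing trials (or
#'   one outside re-analysis scope) passes through as `not_estimable`.
#' @inheritParams classify_direction
#' @return Object of class `effect_class`: list with `direction`,
#'   `precision`, `interpretation` (e.g. `"precise_benefit"`, or
#'   `"not_estimable"`).
#' @examples
#' interpret_effect(0.63, 0.54, 0.72, "lower_is_benefit")
#' @export
interpret_effect <- function(point = NA, ci_low = NA, ci_high = NA,
                             polarity = c("lower_is_benefit",
                                          "higher_is_benefit"),
                             estimable = TRUE,
                             config = equivalence_config()) {
  polarity <- match.arg(polarity)
  if (!isTRUE(estimable)) {
    return(structure(list(direction = NA_character_,
                          precision = NA_character_,
                          interpretation = "not_estimable"),
                     class = "effect_class"))
  }
  dir <- classify_direction(point, polarity, config)
  prec <- classify_precision(ci_low, ci_high, config)
  structure(list(direction = dir, precision = prec,
                 interpretation = paste(prec, dir, sep = "_")),
            class = "effect_class")
}

#' @export
print.effect_class <- function(x, ...) {
  cat(gsub("_", " ", x$interpretation), "\n")
  invisible(x)
}

#' Classify a pooled meta-analysis result
#'
#' @param x An `ria_meta` object from [meta_pool()] or friends.
#' @inheritParams classify_direction
#' @return An `effect_class`.
#' @export
interpret_meta <- function(x, polarity = c("lower_is_benefit",
                                           "higher_is_benefit"),
                           config = equivalence_config()) {
  stopifnot(inherits(x, "ria_meta"))
  interpret_effect(x$point, x$ci_low, x$ci_high, polarity,
                   estimable = x$estimable, config = config)
}

#' Compare original and sensitivity classifications
#'
#' @param original,sensitivity `effect_class` objects.
#' @return List with logical fields `direction_changed`,
#'   `precision_changed`, `interpretation_changed`, `became_not_estimable`.
#' @export
compare_classes <- function(original, sensitivity) {
  stopifnot(inherits(original, "effect_class"),
            inherits(sensitivity, "effect_class"))
  became_ne <- sensitivity$interpretation == "not_estimable" &&
    original$interpretation != "not_estimable"
  dir_chg <- !became_ne && !identical(original$direction, sensitivity$direction)
  prec_chg <- !became_ne && !identical(original$precision, sensitivity$precision)
  list(direction_changed = dir_chg,
       precision_changed = prec_chg,
       interpretation_changed = dir_chg || prec_chg || became_ne,
       became_not_estimable = became_ne)
}

#' Colour token for report rendering
#'
#' Green = benefit, yellow = no or minimal effect, red = harm; dark for
#' precise, light for imprecise; grey for not estimable.
#'
#' @param x An `effect_class`.
#' @return Character token like `"dark_green"`.
#' @export
class_color <- function(x) {
  stopifnot(inherits(x, "effect_class"))
  if (x$interpretation == "not_estimable") return("grey")
  hue <- c(benefit = "green", no_or_minimal = "yellow", harm = "red")[x$direction]
  shade <- c(precise = "dark", imprecise = "light")[x$precision]
  paste(shade, hue, sep = "_")
}
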