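# Five-level heat-stress classification shared by all three methods.
# Labels are stored as ordinal indices 0 (safest) .. 4 (most severe);
# display names per method are presentation only.  Published cutpoint
# tables print small gaps and one overlap (rounding artifacts); bins here
# are half-open and contiguous so classification is total and monotone.

.HI_LEVELS   <- c("Safe", "Caution", "Extreme Caution", "Danger",
                  "Extreme Danger")
.WBGT_LEVELS <- c("Green", "Yellow", "Orange", "Red", "Black")

#' Heat-stress category scale
#'
#' The five-level scales used for athletic-activity guidance: heat index
#' (C) with cutpoints 26.7 / 32.2 / 40.6 / 54.4; energy budget (W/m2) with
#' 60 / 120 / 200 / 340; WBGT (C) with 27.9 / 30.6 / 32.4 / 33.4 (the
#' Category-3 regional athletics thresholds).  Bins are half-open:
#' `value < cut[1]` is level 0, `value >= cut[4]` is level 4.
#'
#' @param method `"HI"`, `"WBGT"` or `"EB"`.
#' @return An object of class `category_scale` with fields `method`,
#'   `levels` (five labels, safest first), `cutpoints` (four ascending
#'   thresholds) and `units`.
#' @examples
#' category_scale("EB")
#' @export
category_scale <- function(method = c("HI", "WBGT", "EB")) {
  method <- match.arg(method)
  sc <- switch(method,
    HI   = list(levels = .HI_LEVELS,
                cutpoints = c(26.7, 32.2, 40.6, 54.4), units = "°C"),
    WBGT = list(levels = .WBGT_LEVELS,
                cutpoints = c(27.9, 30.6, 32.4, 33.4), units = "°C"),
    EB   = list(levels = .HI_LEVELS,
                cutpoints = c(60, 120, 200, 340), units = "W/m²"))
  stopifnot(all(diff(sc$cutpoints) > 0), length(sc$levels) == 5L)
  structure(c(list(method = method), sc), class = "category_scale")
}

#' @export
print.category_scale <- function(x, ...) {
  cat("<category_scale> ", x$method, " (", x$units, ")\n", sep = "")
  lo <- c("-Inf", format(x$cutpoints))
  hi <- c(format(x$cutpoints), "Inf")
  for (i in seq_along(x$levels))
    cat(sprintf("  %d %-16s [%s, %s)\n", i - 1L, x$levels[i], lo[i], hi[i]))
  invisible(x)
}

#' Classify values on a heat-stress scale
#'
#' Total, monotone mapping of finite values to ordinal levels 0..4 on the
#' scale's half-open bins.
#'
#' @param values numeric vector in the scale's units.
#' @param scale a [category_scale()] or a method name.
#' @return An object of class `category_series`: integer levels 0..4 with
#'   the scale attached; `as.character()` yields the display labels.
#' @examples
#' classify_heat(c(376.5, 150, 59.9), "EB")
#' classify_heat(36.2, "HI")    # Extreme Caution
#' classify_heat(28.8, "WBGT")  # Yellow
#' @export
classify_heat <- function(values, scale) {
  if (is.character(scale)) scale <- category_scale(scale)
  stopifnot(inherits(scale, "category_scale"))
  if (any(!is.finite(values)))
    stop("classify_heat: values must be finite")
  lev <- findInterval(values, scale$cutpoints)  # 0..4, left-closed on cuts
  structure(as.integer(lev), scale = scale, class = "category_series")
}

#' @export
print.category_series <- function(x, ...) {
  sc <- attr(x, "scale")
  cat("<category_series> ", sc$method, ", ", length(x), " label(s)\n",
      sep = "")
  print(stats::setNames(as.integer(x), category_labels(x)), ...)
  invisible(x)
}

#' @export
as.character.category_series <- function(x, ...) category_labels(x)

#' Display labels of a category series
#' @param x a `category_series` from [classify_heat()].
#' @return Character vector of level names.
#' @export
category_labels <- function(x) {
  sc <- attr(x, "scale")
  sc$levels[as.integer(x) + 1L]
}

#' Energy budget to heat-index band
#'
#' The published correspondence between energy-budget intervals and
#' heat-index intervals (Harlan et al.): EB 60-120 W/m2 maps to HI
#' 26.7-31.7 C "Caution", 121-200 to 32.2-40 "Extreme Caution", 201-339 to
#' 40.6-53.9 "Danger", >= 340 to >= 54.4 "Extreme Danger", and below 60 to
#' below 26.7 "Safe".  The level is derived from the same half-open EB bins
#' as [classify_heat()], so the two never disagree.
#'
#' @param eb energy budget, W/m2 (vectorized).
#' @return data frame with columns `level` (0..4), `label`, `hi_band`
#'   (the corresponding heat-index interval as text, degrees C).
#' @examples
#' eb_to_hi_band(c(150, 59.9, 376.5))
#' @export
eb_to_hi_band <- function(eb) {
  cs <- classify_heat(eb, "EB")
  bands <- c("<26.7", "26.7-31.7", "32.2-40", "40.6-53.9", ">=54.4")
  data.frame(level = as.integer(cs), label = category_labels(cs),
             hi_band = bands[as.integer(cs) + 1L])
}

#' Inter-method agreement percentage
#'
#' Percentage of timesteps on which two category series assign the same
#' ordinal level.  Both series must classify the same timesteps; the
#' shared 0..4 ordinal scale is what makes cross-method agreement
#' well-defined.
#'
#' @param a,b `category_series` (or plain integer vectors) of equal length.
#' @return Agreement, percent.
#' @examples
#' a <- classify_heat(c(10, 70, 130, 250), "EB")
#' b <- classify_heat(c(20, 65, 210, 250), "EB")
#' agreement_pct(a, b)  # 75
#' @export
agreement_pct <- function(a, b) {
  if (length(a) != length(b))
    stop("agreement_pct: series lengths differ (", length(a), " vs ",
         length(b), ")")
  if (length(a) == 0L) stop("agreement_pct: empty series")
  100 * mean(as.integer(a) == as.integer(b))
}

#' Time in category
#'
#' Percentage of timesteps spent at each of the five levels; sums to 100.
#'
#' @param x a `category_series` (or integer vector of levels 0..4).
#' @return Named numeric vector of five percentages, safest level first.
#' @export
time_in_category <- function(x) {
  if (length(x) == 0L) stop("time_in_category: empty series")
  lev <- as.integer(x)
  stopifnot(all(lev >= 0 & lev <= 4))
  nm <- if (inherits(x, "category_series")) attr(x, "scale")$levels
        else paste0("level", 0:4)
  stats::setNames(100 * tabulate(lev + 1L, nbins = 5L) / length(lev), nm)
}

#' Observed category range
#'
#' The span of levels observed in a series, rendered the way session
#' summaries report it: a single label when one level occurs, otherwise
#' `"lowest-highest"`.
#'
#' @param x a `category_series`.
#' @return Character scalar, with attributes `min_level` and `max_level`.
#' @examples
#' category_range(classify_heat(c(250, 380), "EB"))  # "Danger-Extreme Danger"
#' @export
category_range <- function(x) {
  if (length(x) == 0L) stop("category_range: empty series")
  lev <- as.integer(x)
  nm <- if (inherits(x, "category_series")) attr(x, "scale")$levels
        else paste0("level", 0:4)
  lo <- min(lev); hi <- max(lev)
  out <- if (lo == hi) nm[lo + 1L] else paste0(nm[lo + 1L], "-", nm[hi + 1L])
  structure(out, min_level = lo, max_level = hi)
}
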