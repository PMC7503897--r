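#' Temperature unit conversions
#'
#' Exact affine Celsius/Fahrenheit conversions.  All package internals work
#' in degrees C; Fahrenheit appears only inside the heat-index regression
#' (which is F-native) and at explicitly requested conversions.
#'
#' @param t temperature (vectorized).
#' @return Converted temperature.
#' @examples
#' c_to_f(28)      # 82.4
#' f_to_c(82.4)    # 28
#' @export
c_to_f <- function(t) t * 9 / 5 + 32

#' @rdname c_to_f
#' @export
f_to_c <- function(t) (t - 32) * 5 / 9

#' NWS heat index
#'
#' The National Weather Service practical procedure: air temperature is
#' converted to Fahrenheit and the simple averaged formula
#' `0.5 * (T + 61 + (T - 68) * 1.2 + RH * 0.094)` is evaluated; when the
#' average of that value and `T` reaches 80 F the full Rothfusz regression
#' replaces it, with the NWS low-humidity (RH < 13 %, 80-112 F) and
#' high-humidity (RH > 85 %, 80-87 F) adjustments.  The result is returned
#' in degrees C.
#'
#' @param ta_c air temperature, degrees C, in \[-20, 60\] (vectorized).
#' @param rh_pct relative humidity, percent, in \[0, 100\] (vectorized).
#' @return Heat index ("apparent temperature"), degrees C.
#' @examples
#' heat_index(34.0, 42.9)   # 36.2 C at the hot-afternoon session mean
#' heat_index(21.1, 50)     # cool conditions: simple branch
#' @export
heat_index <- function(ta_c, rh_pct) {
  n <- max(length(ta_c), length(rh_pct))
  ta_c <- rep_len(ta_c, n); rh_pct <- rep_len(rh_pct, n)
  if (any(!is.finite(ta_c)) || any(!is.finite(rh_pct)))
    stop("heat_index: inputs must be finite")
  if (any(rh_pct < 0 | rh_pct > 100))
    stop("heat_index: rh_pct must be in [0, 100]")
  if (any(ta_c < -20 | ta_c > 60))
    stop("heat_index: ta_c must be in [-20, 60]")
  tf <- c_to_f(ta_c)
  rh <- rh_pct
  hi <- 0.5 * (tf + 61.0 + (tf - 68) * 1.2 + rh * 0.094)
  reg <- (hi + tf) / 2 >= 80
  if (any(reg)) {
    t <- tf[reg]; r <- rh[reg]
    h <- -42.379 + 2.04901523 * t + 10.14333127 * r -
      0.22475541 * t * r - 6.83783e-3 * t^2 - 5.481717e-2 * r^2 +
      1.22874e-3 * t^2 * r + 8.5282e-4 * t * r^2 - 1.99e-6 * t^2 * r^2
    lo <- r < 13 & t >= 80 & t <= 112
    h[lo] <- h[lo] - ((13 - r[lo]) / 4) *
      sqrt((17 - abs(t[lo] - 95)) / 17)
    hidamp <- r > 85 & t >= 80 & t <= 87
    h[hidamp] <- h[hidamp] + ((r[hidamp] - 85) / 10) * ((87 - t[hidamp]) / 2)
    hi[reg] <- h
  }
  f_to_c(hi)
}

#' Stull empirical wet-bulb temperature
#'
#' Evaluates Stull's (2011) one-line empirical fit of the wet-bulb
#' temperature as a function of air temperature and relative humidity at
#' standard sea-level pressure (arctangents in radians).  The fit is stated
#' for RH in \[5, 99\] %; outside that range the function warns and still
#' evaluates.  Accuracy against the underlying psychrometric balance is
#' about 0.3 C on average, degrading towards 1 C in hot, very dry air.
#'
#' @param ta_c air temperature, degrees C (vectorized).
#' @param rh_pct relative humidity, percent (vectorized).
#' @return Wet-bulb temperature, degrees C.
#' @examples
#' wet_bulb_stull(20, 50)    # 13.7
#' wet_bulb_stull(20, 100)   # ~20: saturation near-identity
#' @export
wet_bulb_stull <- function(ta_c, rh_pct) {
  n <- max(length(ta_c), length(rh_pct))
  ta <- rep_len(ta_c, n); rh <- rep_len(rh_pct, n)
  if (any(rh < 5 | rh > 99))
    warning("wet_bulb_stull: rh_pct outside the formula's stated ",
            "validity range [5, 99]; evaluating anyway")
  ta * atan(0.151977 * sqrt(rh + 8.313659)) +
    atan(ta + rh) - atan(rh - 1.676331) +
    0.00391838 * rh^1.5 * atan(0.023101 * rh) - 4.686035
}

#' Wet bulb globe temperature
#'
#' The ISO 7243 outdoor weighting `0.7 Tw + 0.2 Tg + 0.1 Ta`: a convex
#' combination of natural wet-bulb, black-globe and air temperature, so the
#' result always lies between the smallest and largest input.
#'
#' @param tw_c natural wet-bulb temperature, C.
#' @param tg_c black-globe temperature, C.
#' @param ta_c air temperature, C.
#' @return WBGT, degrees C (vectorized).
#' @examples
#' wbgt(25, 40, 34)   # 28.9
#' @export
wbgt <- function(tw_c, tg_c, ta_c) {
  if (any(!is.finite(tw_c)) || any(!is.finite(tg_c)) || any(!is.finite(ta_c)))
    stop("wbgt: inputs must be finite")
  0.7 * tw_c + 0.2 * tg_c + 0.1 * ta_c
}

#' WBGT from weather observations
#'
#' Composes [wet_bulb_stull()] (Tw from Ta and RH) with [wbgt()] using the
#' measured black-globe temperature.  A series without a `tg_c` column is an
#' error: no globe model is substituted here (the synthetic generator is the
#' place where a globe closure exists).
#'
#' @param rec a [micromet_series()] or a data frame with columns `ta_c`,
#'   `rh_pct` and `tg_c`.
#' @return WBGT per record, degrees C.
#' @export
wbgt_from_weather <- function(rec) {
  df <- as.data.frame(rec)
  need <- c("ta_c", "rh_pct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("wbgt_from_weather: missing column(s): ", paste(miss, collapse = ", "))
  if (!"tg_c" %in% names(df) || anyNA(df$tg_c))
    stop("wbgt_from_weather: black-globe temperature 'tg_c' is required; ",
         "refusing to substitute a globe model for a measurement")
  tw <- wet_bulb_stull(df$ta_c, df$rh_pct)
  wbgt(tw, df$tg_c, df$ta_c)
}

#' Append index columns to a series
#'
#' Convenience wrapper computing per-record `hi_c`, `tw_c` and (when `tg_c`
#' is available) `wbgt_c`.
#'
#' @param series a [micromet_series()].
#' @return A plain data frame: the series columns plus the index columns.
#' @export
index_table <- function(series) {
  df <- as.data.frame(series)
  df$hi_c <- heat_index(df$ta_c, df$rh_pct)
  df$tw_c <- wet_bulb_stull(df$ta_c, df$rh_pct)
  if ("tg_c" %in% names(df))
    df$wbgt_c <- wbgt(df$tw_c, df$tg_c, df$ta_c)
  df
}
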