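#' Solar elevation angle
#'
#' NOAA-style solar geometry: fractional-year declination and equation of
#' time (Spencer series), true solar time from longitude, elevation from the
#' hour angle.  Accurate to a fraction of a degree, which is ample for
#' partitioning beam and diffuse irradiance on a sports field.
#'
#' @param timestamp POSIXct (any timezone; converted to UTC).
#' @param latitude,longitude site coordinates, degrees (east positive).
#' @return Solar elevation above the horizon, degrees (negative at night).
#' @examples
#' solar_elevation(as.POSIXct("2020-05-19 19:30", tz = "UTC"),
#'                 30.628, -96.334)
#' @export
solar_elevation <- function(timestamp, latitude, longitude) {
  stopifnot(inherits(timestamp, "POSIXct"),
            is.numeric(latitude), is.numeric(longitude),
            abs(latitude) <= 90, abs(longitude) <= 180)
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  doy <- lt$yday + 1
  hour_utc <- lt$hour + lt$min / 60 + lt$sec / 3600
  g <- 2 * pi / 365 * (doy - 1 + (hour_utc - 12) / 24)  # fractional year, rad
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))  # min
  tst <- hour_utc * 60 + eqtime + 4 * longitude       # true solar time, min
  ha <- (tst / 4 - 180) * pi / 180                    # hour angle, rad
  lat <- latitude * pi / 180
  cos_zen <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  asin(pmin(1, pmax(-1, cos_zen))) * 180 / pi
}
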