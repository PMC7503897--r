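# Human energy budget as a series resistance network:
#   budget = M + Rabs - Conv - Evap - TRemitted   (all W per m2 of body area)
# Sensible heat leaves the core through tissue (rt), clothing (rc) and the
# boundary layer (ra) in series; the same network yields skin and
# clothing-surface temperatures, which drive evaporation and emitted
# longwave.  Sub-model constants live in heat_constants().

#' DuBois body surface area
#'
#' `0.007184 * (100 h)^0.725 * m^0.425` with height in metres and mass in
#' kilograms.
#'
#' @param height_m height, m.
#' @param mass_kg mass, kg.
#' @return Body surface area, m2.
#' @examples
#' body_surface_area(1.70, 67)     # ~1.78
#' body_surface_area(1.378, 31.9)  # ~1.11 (10-year-old boy)
#' @export
body_surface_area <- function(height_m, mass_kg) {
  if (any(height_m <= 0) || any(mass_kg <= 0))
    stop("body_surface_area: height and mass must be positive")
  0.007184 * (100 * height_m)^0.725 * mass_kg^0.425
}

#' Metabolic heat production
#'
#' `M = MET * RMR * (1 - work_fraction)`, W per m2 of body surface.  A
#' 10-year-old playing football (MET 7, RMR 52) produces 364 W/m2; an adult
#' coaching (MET 4, RMR 42) produces 168 W/m2.
#'
#' @param profile a [person_profile()].
#' @param constants a [heat_constants()] registry (for `work_fraction`).
#' @return Metabolic heat, W/m2.
#' @export
metabolic_heat <- function(profile, constants = heat_constants()) {
  stopifnot(inherits(profile, "person_profile"))
  profile$met * profile$rmr_wm2 * (1 - constants$work_fraction)
}

#' Core temperature closure
#'
#' Linear rise of body core temperature with metabolic heat:
#' `Tc = tc_base + tc_slope * M` (default 36.5 C + 0.0043 C per W/m2),
#' providing the driving gradient for sensible heat loss.
#'
#' @param m_wm2 metabolic heat, W/m2 (>= 0).
#' @param constants a [heat_constants()] registry.
#' @return Core temperature, degrees C.
#' @export
core_temperature <- function(m_wm2, constants = heat_constants()) {
  if (any(m_wm2 < 0)) stop("core_temperature: m_wm2 must be >= 0")
  constants$tc_base + constants$tc_slope * m_wm2
}

# Hilpert forced-convection correlation for a cylinder in cross-flow:
# Nu = C * Re^n with coefficients per Reynolds-number band.
.hilpert_nu <- function(re) {
  C <- ifelse(re < 4, 0.989,
       ifelse(re < 40, 0.911,
       ifelse(re < 4000, 0.683,
       ifelse(re < 40000, 0.193, 0.027))))
  n <- ifelse(re < 4, 0.330,
       ifelse(re < 40, 0.385,
       ifelse(re < 4000, 0.466,
       ifelse(re < 40000, 0.618, 0.805))))
  C * re^n
}

#' Heat-transfer resistances of the body
#'
#' The three series resistances of the network, in s/m:
#' clothing `rc = clo * 0.155 * rho_cp`; aerodynamic
#' `ra = rho_cp * d / (Nu * k_air)` treating the body as a cylinder of
#' diameter `d = BSA / (pi * height)` in cross-flow (Hilpert `Nu(Re)`), with
#' wind floored at the free-convection limit; and tissue
#' `rt = clamp(rt_rest - k_rt * M, rt_min, rt_rest)`, vasodilating as
#' metabolic heat rises.
#'
#' @param profile a [person_profile()].
#' @param rec a [micromet_series()], data frame, or list with `ws_ms`.
#' @param m_wm2 metabolic heat, W/m2; computed from the profile when `NULL`.
#' @param constants a [heat_constants()] registry.
#' @return data frame with columns `ra`, `rc`, `rt` (s/m), one row per record.
#' @examples
#' boy <- person_profile("athlete", "child", met = 7, clo = 1.3)
#' resistances(boy, list(ws_ms = 2.4))
#' @export
resistances <- function(profile, rec, m_wm2 = NULL,
                        constants = heat_constants()) {
  stopifnot(inherits(profile, "person_profile"))
  cn <- constants
  ws <- pmax(as.data.frame(rec)$ws_ms, cn$wind_floor)
  if (is.null(m_wm2)) m_wm2 <- metabolic_heat(profile, cn)
  bsa <- body_surface_area(profile$height_m, profile$mass_kg)
  d <- bsa / (pi * profile$height_m)
  re <- ws * d / cn$nu_air
  nu <- .hilpert_nu(re)
  ra <- cn$rho_cp * d / (nu * cn$k_air)
  rc <- profile$clo * 0.155 * cn$rho_cp
  rt <- pmin(pmax(cn$rt_rest - cn$k_rt * m_wm2, cn$rt_min), cn$rt_rest)
  data.frame(ra = ra, rc = rep_len(rc, length(ra)),
             rt = rep_len(rt, length(ra)))
}

# Tetens saturation vapour pressure, kPa, over water
.tetens_es <- function(t_c) 0.6108 * exp(17.27 * t_c / (t_c + 237.3))

# Idso clear-sky atmospheric emissivity (vapour pressure in hPa)
.idso_eps_sky <- function(ta_c, rh_pct) {
  ea_hpa <- 10 * (rh_pct / 100) * .tetens_es(ta_c)
  ta_k <- ta_c + 273.15
  pmin(1, 0.70 + 5.95e-5 * ea_hpa * exp(1500 / ta_k))
}

#' Absorbed short- and longwave radiation
#'
#' Shortwave: the global horizontal irradiance is split into beam and
#' diffuse by the site's diffuse fraction; the beam is projected onto a
#' vertical cylinder (`f_cyl = cos(beta) / pi`), sky diffuse is weighted by
#' half the sky view factor, ground-reflected by half the ground albedo,
#' and overhead shade attenuates beam and sky-diffuse (not the
#' ground-reflected term); the sum is scaled by clothing absorptivity.
#' Longwave: half the view is sky (Idso clear-sky emissivity) plus
#' obstructions at air temperature, half is ground at its surface
#' temperature.
#'
#' @param rec a [micromet_series()] or data frame with `ta_c`, `rh_pct`,
#'   `sr_wm2` and optionally `ts_c` / `solar_elev_deg`.
#' @param site a [site_context()].
#' @param profile a [person_profile()] (for clothing albedo/emissivity
#'   overrides).
#' @param constants a [heat_constants()] registry.
#' @param solar_elev_deg solar elevation, degrees; overrides any
#'   `solar_elev_deg` column.  When both are absent it is computed from the
#'   record timestamps and `latitude`/`longitude`.
#' @param latitude,longitude site coordinates for the solar-geometry
#'   fallback.
#' @return Absorbed radiation, W per m2 of body surface, one value per
#'   record.
#' @export
absorbed_radiation <- function(rec, site, profile,
                               constants = heat_constants(),
                               solar_elev_deg = NULL,
                               latitude = NULL, longitude = NULL) {
  stopifnot(inherits(site, "site_context"),
            inherits(profile, "person_profile"))
  cn <- constants
  df <- as.data.frame(rec)
  sr <- df$sr_wm2
  if (any(sr < 0)) stop("absorbed_radiation: sr_wm2 must be >= 0")
  ta <- df$ta_c
  rh <- df$rh_pct

  if (is.null(solar_elev_deg)) {
    if ("solar_elev_deg" %in% names(df)) {
      solar_elev_deg <- df$solar_elev_deg
    } else if (!is.null(latitude) && !is.null(longitude) &&
               "timestamp" %in% names(df)) {
      solar_elev_deg <- solar_elevation(df$timestamp, latitude, longitude)
    } else {
      stop("absorbed_radiation: solar elevation must be supplied ",
           "(argument or column) or derivable from timestamp + lat/lon")
    }
  }
  beta <- rep_len(solar_elev_deg, length(sr)) * pi / 180
  if (any(beta <= 2 * pi / 180 & sr > 50))
    warning("absorbed_radiation: solar elevation <= 2 deg with SR > 50 ",
            "W/m2; inputs look inconsistent")

  alb_cloth <- if (!is.null(profile$clothing_albedo)) profile$clothing_albedo
               else cn$clothing_albedo
  eps <- if (!is.null(profile$emissivity)) profile$emissivity
         else cn$emissivity

  kd <- site$diffuse_fraction * sr
  sinb <- sin(beta)
  kbn <- ifelse(sinb > 0, (sr - kd) / pmax(sinb, 0.05), 0)  # beam normal
  fcyl <- pmax(cos(beta), 0) / pi
  tau <- site$shade_transmissivity
  svf <- site$sky_view_factor
  shortwave <- (1 - alb_cloth) *
    (tau * fcyl * kbn + tau * 0.5 * svf * kd + 0.5 * site$ground_albedo * sr)

  ts <- if (!is.na(site$ground_surface_temp_c)) site$ground_surface_temp_c
        else if (site$ground_surface == "series" && "ts_c" %in% names(df))
          df$ts_c
        else ta
  ta_k <- ta + 273.15
  ts_k <- ts + 273.15
  eps_sky <- .idso_eps_sky(ta, rh)
  longwave <- eps * (0.5 * svf * eps_sky * cn$sigma * ta_k^4 +
                       0.5 * (1 - svf) * cn$sigma * ta_k^4 +
                       0.5 * cn$ground_emissivity * cn$sigma * ts_k^4)
  out <- shortwave + longwave
  if (any(shortwave < 0) || any(longwave < 0))
    stop("absorbed_radiation: internal error, negative component")
  out
}

#' Sensible convective exchange and network temperatures
#'
#' The sensible flux through the series network,
#' `Conv = rho_cp * (Tc - Ta) / (rt + rc + ra)`, with the skin and
#' clothing-surface temperatures read off the same network:
#' `Tsk = Ta + Conv * (ra + rc) / rho_cp`,
#' `Tsurf = Ta + Conv * ra / rho_cp`.  Negative values mean sensible heat
#' gain (air hotter than the body core).
#'
#' @inheritParams resistances
#' @return data frame with columns `conv_wm2`, `tsk_c`, `tsurf_c`.
#' @export
convective_loss <- function(profile, rec, m_wm2 = NULL,
                            constants = heat_constants()) {
  cn <- constants
  if (is.null(m_wm2)) m_wm2 <- metabolic_heat(profile, cn)
  tc <- core_temperature(m_wm2, cn)
  r <- resistances(profile, rec, m_wm2 = m_wm2, constants = cn)
  ta <- as.data.frame(rec)$ta_c
  flux <- cn$rho_cp * (tc - ta) / (r$rt + r$rc + r$ra)
  data.frame(conv_wm2 = flux,
             tsk_c = ta + flux * (r$ra + r$rc) / cn$rho_cp,
             tsurf_c = ta + flux * r$ra / cn$rho_cp)
}

#' Evaporative heat loss
#'
#' Potential evaporation from Tetens psychrometrics,
#' `E_pot = (rho_cp / gamma) * (e_s(Tsk) - e_air) / (ra + r_cv)`, throttled
#' by a skin-wettedness ramp that rises linearly from `w_min` at rest to 1
#' at `m_wmax`, and capped by the profile's sweat capacity
#' (`sweat_capacity_factor * s_cap_adult`; 0.5 for a child).  Never
#' negative: condensation is not modelled.
#'
#' @inheritParams resistances
#' @param tsk_c skin temperature, C (from [convective_loss()]).
#' @return Evaporative loss, W/m2.
#' @export
evaporative_loss <- function(profile, rec, tsk_c, m_wm2 = NULL,
                             constants = heat_constants()) {
  cn <- constants
  df <- as.data.frame(rec)
  if (is.null(m_wm2)) m_wm2 <- metabolic_heat(profile, cn)
  r <- resistances(profile, rec, m_wm2 = m_wm2, constants = cn)
  e_air <- (df$rh_pct / 100) * .tetens_es(df$ta_c)
  e_pot <- (cn$rho_cp / cn$gamma_kpa) * (.tetens_es(tsk_c) - e_air) /
    (r$ra + cn$r_cv)
  w <- pmin(pmax(cn$w_min + (1 - cn$w_min) * (m_wm2 - profile$rmr_wm2) /
                   (cn$m_wmax - profile$rmr_wm2), cn$w_min), 1)
  cap <- profile$sweat_capacity_factor * cn$s_cap_adult
  pmax(0, pmin(w * e_pot, cap))
}

#' Emitted longwave radiation
#'
#' Stefan-Boltzmann emission from the clothing surface,
#' `eps * sigma * (Tsurf + 273.15)^4`.
#'
#' @param tsurf_c clothing-surface temperature, C.
#' @param profile a [person_profile()] (emissivity override).
#' @param constants a [heat_constants()] registry.
#' @return Emitted longwave, W/m2.
#' @export
emitted_longwave <- function(tsurf_c, profile = NULL,
                             constants = heat_constants()) {
  if (any(!is.finite(tsurf_c))) stop("emitted_longwave: tsurf must be finite")
  eps <- if (!is.null(profile) && !is.null(profile$emissivity))
    profile$emissivity else constants$emissivity
  eps * constants$sigma * (tsurf_c + 273.15)^4
}

#' Full energy-budget decomposition
#'
#' Composes the five streams into
#' `budget = M + Rabs - Conv - Evap - TRemitted`, returning every stream,
#' the derived temperatures and the resistances so the decomposition can be
#' inspected term by term.  The identity holds exactly by construction.
#'
#' @inheritParams absorbed_radiation
#' @return An object of class `budget_breakdown` (a data frame, one row per
#'   record) with columns `m_wm2`, `rabs_wm2`, `conv_wm2`, `evap_wm2`,
#'   `tremit_wm2`, `budget_wm2`, `tc_c`, `tsk_c`, `tsurf_c`, `ra`, `rc`,
#'   `rt`.
#' @examples
#' boy <- person_profile("athlete", "child", met = 7, clo = 1.3)
#' turf <- site_context(ground_albedo = 0.08, ground_surface_temp_c = 60)
#' rec <- list(ta_c = 33.3, rh_pct = 48, ws_ms = 2.4, sr_wm2 = 886.8)
#' energy_budget(boy, rec, turf, solar_elev_deg = 60)
#' @export
energy_budget <- function(profile, rec, site,
                          constants = heat_constants(),
                          solar_elev_deg = NULL,
                          latitude = NULL, longitude = NULL) {
  cn <- constants
  df <- as.data.frame(rec)
  m <- metabolic_heat(profile, cn)
  tc <- core_temperature(m, cn)
  r <- resistances(profile, df, m_wm2 = m, constants = cn)
  rabs <- absorbed_radiation(df, site, profile, constants = cn,
                             solar_elev_deg = solar_elev_deg,
                             latitude = latitude, longitude = longitude)
  cv <- convective_loss(profile, df, m_wm2 = m, constants = cn)
  evap <- evaporative_loss(profile, df, cv$tsk_c, m_wm2 = m, constants = cn)
  trem <- emitted_longwave(cv$tsurf_c, profile, cn)
  n <- nrow(df)
  out <- data.frame(
    m_wm2 = rep_len(m, n), rabs_wm2 = rabs,
    conv_wm2 = cv$conv_wm2, evap_wm2 = evap, tremit_wm2 = trem,
    budget_wm2 = rep_len(m, n) + rabs - cv$conv_wm2 - evap - trem,
    tc_c = rep_len(tc, n), tsk_c = cv$tsk_c, tsurf_c = cv$tsurf_c,
    ra = r$ra, rc = r$rc, rt = r$rt
  )
  class(out) <- c("budget_breakdown", "data.frame")
  out
}

#' @export
print.budget_breakdown <- function(x, ...) {
  cat("<budget_breakdown> ", nrow(x), " record(s); mean budget ",
      round(mean(x$budget_wm2), 1), " W/m2\n", sep = "")
  print(round(utils::head(as.data.frame(x), 5), 2), ...)
  if (nrow(x) > 5) cat("... (", nrow(x) - 5, " more rows)\n", sep = "")
  invisible(x)
}
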