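#' Physical and physiological constants registry
#'
#' The energy-budget model is a series-resistance network whose closures
#' (core-temperature response, cylinder convection, Tetens psychrometrics,
#' the sweat-wettedness ramp, view-factor radiation) require a set of
#' physical and physiological constants that are not part of the model's
#' public surface.  They are collected in a single named registry so a run
#' can be recalibrated against field aggregates without code changes, and so
#' the full configuration can be echoed with every report.
#'
#' @param ... named overrides for any registry entry, e.g.
#'   `heat_constants(emissivity = 0.98)`.  Unknown names are an error.
#'
#' @return An object of class `heat_constants`: a named list with entries
#' \describe{
#'   \item{rho_cp}{volumetric heat capacity of air, J m-3 K-1 (1212).}
#'   \item{gamma_kpa}{psychrometric constant, kPa K-1 (0.0667).}
#'   \item{nu_air}{kinematic viscosity of air, m2 s-1 (1.6e-5).}
#'   \item{k_air}{thermal conductivity of air, W m-1 K-1 (0.0267).}
#'   \item{sigma}{Stefan-Boltzmann constant, W m-2 K-4.}
#'   \item{emissivity}{longwave emissivity of skin/clothing (0.95).}
#'   \item{ground_emissivity}{longwave emissivity of the ground (0.95).}
#'   \item{clothing_albedo}{default shortwave albedo of clothing (0.37).}
#'   \item{rt_rest, rt_min, k_rt}{tissue resistance at rest (s/m), its
#'     vasodilated floor, and its linear decline per W m-2 of metabolic
#'     heat: `rt = clamp(rt_rest - k_rt * M, rt_min, rt_rest)`.}
#'   \item{r_cv}{clothing vapour resistance added to the aerodynamic
#'     resistance in the evaporation pathway, s/m (150).}
#'   \item{w_min}{minimum skin wettedness (0.06).}
#'   \item{m_wmax}{metabolic rate at which wettedness saturates, W m-2 (400).}
#'   \item{s_cap_adult}{adult maximum evaporative (sweat) capacity,
#'     W m-2 (365); a child carries a `sweat_capacity_factor` of 0.5.}
#'   \item{tc_base, tc_slope}{core temperature closure
#'     `Tc = tc_base + tc_slope * M` (36.5 C, 0.0043 C per W m-2).}
#'   \item{wind_floor}{minimum wind speed used by the forced-convection
#'     correlation, m/s (0.3).}
#'   \item{work_fraction}{fraction of metabolic energy converted to external
#'     mechanical work rather than heat (0).}
#' }
#' @examples
#' cn <- heat_constants()
#' cn$rho_cp
#' heat_constants(emissivity = 0.98)$emissivity
#' @export
heat_constants <- function(...) {
  cn <- list(
    rho_cp           = 1212,
    gamma_kpa        = 0.0667,
    nu_air           = 1.6e-5,
    k_air            = 0.0267,
    sigma            = 5.670374419e-8,
    emissivity       = 0.95,
    ground_emissivity = 0.95,
    clothing_albedo  = 0.37,
    rt_rest          = 104,
    rt_min           = 10,
    k_rt             = 0.25,
    r_cv             = 150,
    w_min            = 0.06,
    m_wmax           = 400,
    s_cap_adult      = 365,
    tc_base          = 36.5,
    tc_slope         = 0.0043,
    wind_floor       = 0.3,
    work_fraction    = 0
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cn))
    if (length(bad) || is.null(names(ov)) || any(names(ov) == ""))
      stop("unknown constant(s): ", paste(bad, collapse = ", "))
    for (nm in names(ov)) {
      v <- ov[[nm]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
        stop("constant '", nm, "' must be a single non-negative number")
      cn[[nm]] <- v
    }
  }
  structure(cn, class = "heat_constants")
}

#' @export
print.heat_constants <- function(x, ...) {
  cat("<heat_constants> registry with", length(x), "entries\n")
  df <- data.frame(value = unlist(x))
  print(df, ...)
  invisible(x)
}
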