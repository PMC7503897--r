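#' Person profile for the energy-budget model
#'
#' Bundles the anthropometric and physiological parameters that drive the
#' human energy budget.  Child physiology enters purely through this
#' profile: a higher resting metabolic rate per unit surface area, a higher
#' activity MET, child anthropometry (hence a higher surface-area-to-mass
#' ratio) and half the adult sweat capacity — there is one model code path
#' and two parameterizations.
#'
#' @param label display name.
#' @param age_class `"child"` or `"adult"`.
#' @param height_m standing height, m.
#' @param mass_kg body mass, kg.
#' @param rmr_wm2 resting metabolic rate per unit body surface area, W/m2
#'   (child default 52, adult 42).
#' @param met activity intensity as a multiple of RMR (>= 1).
#' @param clo clothing insulation, clo units (1 clo = 0.155 m2 K/W).
#' @param clothing_albedo shortwave albedo of the clothed body; `NULL` takes
#'   the registry default.
#' @param emissivity longwave emissivity of the clothed body; `NULL` takes
#'   the registry default.
#' @param sweat_capacity_factor fraction of the adult maximum evaporative
#'   capacity available (child default 0.5, adult 1).
#' @param posture `"standing"` or `"seated"`.
#' @return An object of class `person_profile`.
#' @examples
#' boy <- person_profile("athlete", "child", met = 7)
#' boy$rmr_wm2 * boy$met   # 364 W/m2 of metabolic heat
#' @export
person_profile <- function(label,
                           age_class = c("adult", "child"),
                           height_m = NULL, mass_kg = NULL,
                           rmr_wm2 = NULL, met = 1,
                           clo = 0.6,
                           clothing_albedo = NULL, emissivity = NULL,
                           sweat_capacity_factor = NULL,
                           posture = c("standing", "seated")) {
  age_class <- match.arg(age_class)
  posture <- match.arg(posture)
  # WHO-median defaults: 10-y boy 1.378 m / 31.9 kg; adult man 1.75 m / 70 kg
  if (is.null(height_m)) height_m <- if (age_class == "child") 1.378 else 1.75
  if (is.null(mass_kg))  mass_kg  <- if (age_class == "child") 31.9 else 70
  if (is.null(rmr_wm2))  rmr_wm2  <- if (age_class == "child") 52 else 42
  if (is.null(sweat_capacity_factor))
    sweat_capacity_factor <- if (age_class == "child") 0.5 else 1
  stopifnot(height_m > 0, mass_kg > 0, rmr_wm2 > 0, met >= 1, clo > 0,
            sweat_capacity_factor > 0, sweat_capacity_factor <= 1)
  if (!is.null(clothing_albedo))
    stopifnot(clothing_albedo >= 0, clothing_albedo <= 1)
  if (!is.null(emissivity))
    stopifnot(emissivity >= 0, emissivity <= 1)
  structure(list(
    label = as.character(label), age_class = age_class,
    height_m = height_m, mass_kg = mass_kg,
    rmr_wm2 = rmr_wm2, met = met, clo = clo,
    clothing_albedo = clothing_albedo, emissivity = emissivity,
    sweat_capacity_factor = sweat_capacity_factor, posture = posture
  ), class = "person_profile")
}

#' @export
print.person_profile <- function(x, ...) {
  cat("<person_profile> ", x$label, " (", x$age_class, ", ", x$posture,
      ")\n", sep = "")
  cat(sprintf("  %.3f m / %.1f kg (BSA %.2f m2), RMR %g W/m2, MET %g, clo %g\n",
              x$height_m, x$mass_kg, body_surface_area(x$height_m, x$mass_kg),
              x$rmr_wm2, x$met, x$clo))
  cat("  sweat capacity factor:", x$sweat_capacity_factor, "\n")
  invisible(x)
}

#' Site context for the radiation environment
#'
#' Describes what the person is standing on and under: the fraction of the
#' sky hemisphere visible (sky view factor), the shortwave transmissivity of
#' overhead shade (1 = unshaded), the ground albedo, the ground surface
#' temperature (falls back to air temperature when `NA`, the natural-grass
#' assumption) and the diffuse fraction of global radiation.
#'
#' @param sky_view_factor fraction of the sky hemisphere visible, \[0, 1\].
#' @param shade_transmissivity shortwave transmissivity of overhead canopy,
#'   \[0, 1\]; 1 = unshaded, 0.175 = dense oak.
#' @param ground_albedo shortwave albedo of the ground (turf ~0.08,
#'   grass ~0.25).
#' @param ground_surface_temp_c fixed ground surface temperature, C; when
#'   given it overrides `ground_surface`.
#' @param ground_surface where the surface temperature comes from when no
#'   fixed value is given: `"series"` (the series' measured `ts_c`, falling
#'   back to air temperature when absent) or `"air"` (always air
#'   temperature — the natural-grass assumption, appropriate for someone
#'   standing off a hot synthetic field).
#' @param diffuse_fraction fraction of global solar radiation that is
#'   diffuse (clear-sky default 0.15).
#' @return An object of class `site_context`.
#' @examples
#' site_context(ground_albedo = 0.08, ground_surface_temp_c = 60)  # hot turf
#' site_context(sky_view_factor = 0.5, shade_transmissivity = 0.175)
#' @export
site_context <- function(sky_view_factor = 1,
                         shade_transmissivity = 1,
                         ground_albedo = 0.25,
                         ground_surface_temp_c = NA_real_,
                         ground_surface = c("series", "air"),
                         diffuse_fraction = 0.15) {
  ground_surface <- match.arg(ground_surface)
  for (v in list(sky_view_factor, shade_transmissivity, ground_albedo,
                 diffuse_fraction))
    stopifnot(is.numeric(v), length(v) == 1L, v >= 0, v <= 1)
  stopifnot(is.na(ground_surface_temp_c) ||
              (ground_surface_temp_c > -60 && ground_surface_temp_c < 90))
  structure(list(
    sky_view_factor = sky_view_factor,
    shade_transmissivity = shade_transmissivity,
    ground_albedo = ground_albedo,
    ground_surface_temp_c = ground_surface_temp_c,
    ground_surface = ground_surface,
    diffuse_fraction = diffuse_fraction
  ), class = "site_context")
}

#' @export
print.site_context <- function(x, ...) {
  cat("<site_context> SVF", x$sky_view_factor,
      "| shade tau", x$shade_transmissivity,
      "| ground albedo", x$ground_albedo,
      "| Ts", if (!is.na(x$ground_surface_temp_c))
        paste0(x$ground_surface_temp_c, " C")
      else if (x$ground_surface == "air") "= Ta" else "from series",
      "| diffuse", x$diffuse_fraction, "\n")
  invisible(x)
}
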