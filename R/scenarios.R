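#' Analysis scenario: one persona, one site, a set of methods
#'
#' A scenario binds a [person_profile()], a [site_context()] and the
#' heat-stress methods to evaluate: `"HI"`, `"WBGT"`, and the energy budget
#' as `"CK"` (the child parameterization) or `"COMFA"` (the adult one).
#' `"CK"` demands a child persona and `"COMFA"` an adult persona, so a
#' method label always says whose physiology produced the number.
#'
#' @param persona a [person_profile()].
#' @param site a [site_context()].
#' @param methods character subset of `c("HI", "WBGT", "CK", "COMFA")`.
#' @return An object of class `heat_scenario`.
#' @export
heat_scenario <- function(persona, site,
                          methods = c("HI", "WBGT", "CK")) {
  stopifnot(inherits(persona, "person_profile"),
            inherits(site, "site_context"))
  if (!length(methods)) stop("heat_scenario: at least one method")
  methods <- match.arg(methods, c("HI", "WBGT", "CK", "COMFA"),
                       several.ok = TRUE)
  if ("CK" %in% methods && persona$age_class != "child")
    stop("heat_scenario: CK requires a child persona")
  if ("COMFA" %in% methods && persona$age_class != "adult")
    stop("heat_scenario: COMFA requires an adult persona")
  if (all(c("CK", "COMFA") %in% methods))
    stop("heat_scenario: a scenario carries one persona, so CK and COMFA ",
         "cannot both apply")
  structure(list(persona = persona, site = site, methods = methods),
            class = "heat_scenario")
}

#' @export
print.heat_scenario <- function(x, ...) {
  cat("<heat_scenario> ", x$persona$label, " | methods: ",
      paste(x$methods, collapse = ", "), "\n", sep = "")
  print(x$site)
  invisible(x)
}

#' Run a scenario over a series
#'
#' The single orchestration path for all methods: computes per-timestep
#' index/budget values and their five-level categories on one shared
#' timeline, then derives every report block from that table — the session
#' summary (max/min/mean), the observed category range per method, the
#' time-in-category percentages, and the pairwise agreement matrix.
#' Deterministic given series and configuration; a method whose required
#' input column is missing fails the whole run with a named error rather
#' than dropping rows.
#'
#' @param series a [micromet_series()].
#' @param scenario a [heat_scenario()].
#' @param constants a [heat_constants()] registry.
#' @return An object of class `heat_run` with elements `per_timestep`
#'   (data frame), `summary` (max/min/mean block), `category_range`,
#'   `time_in_category`, `agreement` (method x method %), `breakdown`
#'   (the [energy_budget()] streams when an EB method ran) and `config`
#'   (persona, site, methods, constants echo).
#' @examples
#' defs <- study_defaults()
#' s <- generate_micromet(may_session_spec(seed = 7))
#' run <- run_scenario(s, defs$scenarios$athlete)
#' summary(run)
#' @export
run_scenario <- function(series, scenario, constants = heat_constants()) {
  stopifnot(is_micromet_series(series), inherits(scenario, "heat_scenario"))
  methods <- scenario$methods
  df <- as.data.frame(series)
  pt <- df[intersect(c("timestamp", "ta_c", "rh_pct", "ws_ms", "sr_wm2",
                       "tg_c", "ts_c", "solar_elev_deg"), names(df))]
  cats <- list()
  breakdown <- NULL

  if ("HI" %in% methods) {
    pt$hi_c <- heat_index(df$ta_c, df$rh_pct)
    cats$HI <- classify_heat(pt$hi_c, "HI")
    pt$hi_level <- as.integer(cats$HI)
  }
  if ("WBGT" %in% methods) {
    if (!"tg_c" %in% names(df))
      stop("run_scenario: method WBGT needs column 'tg_c' (black-globe ",
           "temperature), absent from the series")
    pt$tw_c <- wet_bulb_stull(df$ta_c, df$rh_pct)
    pt$wbgt_c <- wbgt(pt$tw_c, df$tg_c, df$ta_c)
    cats$WBGT <- classify_heat(pt$wbgt_c, "WBGT")
    pt$wbgt_level <- as.integer(cats$WBGT)
  }
  ebm <- intersect(c("CK", "COMFA"), methods)
  if (length(ebm)) {
    breakdown <- energy_budget(scenario$persona, series, scenario$site,
                               constants = constants)
    pt$eb_wm2 <- breakdown$budget_wm2
    cats[[ebm]] <- classify_heat(pt$eb_wm2, "EB")
    pt$eb_level <- as.integer(cats[[ebm]])
  }

  numvars <- setdiff(names(pt)[vapply(pt, is.numeric, logical(1))],
                     c("hi_level", "wbgt_level", "eb_level"))
  summ <- summarize_series(pt, numvars)

  agree <- NULL
  if (length(cats) > 1) {
    mn <- names(cats)
    agree <- matrix(100, length(mn), length(mn), dimnames = list(mn, mn))
    for (i in seq_along(mn)) for (j in seq_along(mn))
      agree[i, j] <- agreement_pct(cats[[i]], cats[[j]])
  }

  structure(list(
    per_timestep = pt,
    summary = summ,
    category_range = lapply(cats, category_range),
    time_in_category = lapply(cats, time_in_category),
    agreement = agree,
    breakdown = breakdown,
    config = list(persona = scenario$persona, site = scenario$site,
                  methods = methods, constants = unclass(constants),
                  interval_s = series_interval(series),
                  n_records = nrow(df))
  ), class = "heat_run")
}

#' @export
print.heat_run <- function(x, ...) {
  cat("<heat_run> ", x$config$persona$label, ", ", x$config$n_records,
      " timesteps, methods: ", paste(x$config$methods, collapse = ", "),
      "\n", sep = "")
  for (m in names(x$category_range))
    cat("  ", m, ": ", as.character(x$category_range[[m]]), "\n", sep = "")
  invisible(x)
}

#' @export
summary.heat_run <- function(object, ...) {
  cat("Session summary (max/min/mean):\n")
  print(object$summary)
  cat("\nTime in category (%):\n")
  tic <- do.call(rbind, lapply(object$time_in_category, round, 1))
  if (!is.null(tic)) { colnames(tic) <- paste0("L", 0:4); print(tic) }
  if (!is.null(object$agreement)) {
    cat("\nPairwise agreement (%):\n")
    print(round(object$agreement, 1))
  }
  invisible(object)
}

#' @export
plot.heat_run <- function(x, ...) {
  pt <- x$per_timestep
  if ("eb_wm2" %in% names(pt)) {
    sc <- category_scale("EB")
    graphics::plot(pt$timestamp, pt$eb_wm2, type = "l",
                   xlab = "time (UTC)", ylab = "energy budget (W/m2)",
                   main = x$config$persona$label, ...)
    graphics::abline(h = sc$cutpoints, lty = 3, col = "grey40")
    graphics::text(rep(min(pt$timestamp), 4), sc$cutpoints,
                   sc$levels[-1], pos = 3, cex = 0.7, col = "grey40")
  } else if ("hi_c" %in% names(pt)) {
    graphics::plot(pt$timestamp, pt$hi_c, type = "l",
                   xlab = "time (UTC)", ylab = "heat index (C)",
                   main = x$config$persona$label, ...)
  }
  invisible(x)
}

#' Bundled personas, sites, scales and scenarios
#'
#' The three study personas with their sites, the three category scales,
#' and ready-made scenarios: a 10-year-old boy playing football on
#' artificial turf (RMR 52 W/m2, MET 7, clo 1.3, half sweat capacity;
#' turf albedo 0.08, surface temperature from the series), a 40-year-old
#' coach standing on natural grass beside the field (RMR 42, MET 4,
#' clo 0.6; surface temperature = air temperature), and a 40-year-old
#' parent seated under an oak (MET 1.3, clo 0.5, seated; shade
#' transmissivity 17.5 %, sky view factor 50 %).
#'
#' @return A list with elements `profiles`, `sites`, `scales`, `scenarios`.
#' @examples
#' defs <- study_defaults()
#' defs$profiles$athlete$met * defs$profiles$athlete$rmr_wm2  # 364 W/m2
#' @export
study_defaults <- function() {
  profiles <- list(
    athlete = person_profile("athlete (10-y boy, football)", "child",
                             met = 7, clo = 1.3),
    coach   = person_profile("coach (40-y man, sideline)", "adult",
                             met = 4, clo = 0.6),
    parent  = person_profile("parent (40-y man, seated, shade)", "adult",
                             met = 1.3, clo = 0.5, posture = "seated")
  )
  sites <- list(
    turf  = site_context(ground_albedo = 0.08, ground_surface = "series"),
    grass = site_context(ground_albedo = 0.25, ground_surface = "air"),
    oak_shade = site_context(sky_view_factor = 0.5,
                             shade_transmissivity = 0.175,
                             ground_albedo = 0.25, ground_surface = "air")
  )
  scales <- list(HI = category_scale("HI"), WBGT = category_scale("WBGT"),
                 EB = category_scale("EB"))
  scenarios <- list(
    athlete = heat_scenario(profiles$athlete, sites$turf,
                            c("HI", "WBGT", "CK")),
    coach   = heat_scenario(profiles$coach, sites$grass,
                            c("HI", "WBGT", "COMFA")),
    parent  = heat_scenario(profiles$parent, sites$oak_shade, "COMFA")
  )
  list(profiles = profiles, sites = sites, scales = scales,
       scenarios = scenarios)
}
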