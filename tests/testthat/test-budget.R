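defs <- study_defaults()
boy <- defs$profiles$athlete
coach <- defs$profiles$coach
parent <- defs$profiles$parent
turf60 <- site_context(ground_albedo = 0.08, ground_surface_temp_c = 60)

test_that("DuBois surface area and the child surface-to-mass advantage", {
  expect_equal(body_surface_area(1.70, 67), 1.78, tolerance = 0.01)
  expect_equal(body_surface_area(1.378, 31.9), 1.11, tolerance = 0.01)
  sa_mass_child <- body_surface_area(1.378, 31.9) / 31.9
  sa_mass_adult <- body_surface_area(1.75, 70) / 70
  expect_lt(abs(sa_mass_child - 0.035), 0.001)
  expect_lt(abs(sa_mass_adult - 0.026), 0.001)
  expect_gt(sa_mass_child, sa_mass_adult)
  expect_error(body_surface_area(-1, 50), "positive")
})

test_that("metabolic heat is MET x RMR", {
  expect_equal(metabolic_heat(boy), 364)
  expect_equal(metabolic_heat(coach), 168)
  expect_equal(metabolic_heat(person_profile("rest", "adult", met = 1)), 42)
})

test_that("core temperature closure is linear and monotone", {
  expect_equal(core_temperature(0), 36.5)
  expect_equal(core_temperature(364), 38.07, tolerance = 0.01)
  m <- seq(0, 400, by = 50)
  expect_true(all(diff(core_temperature(m)) > 0))
  expect_error(core_temperature(-1), ">= 0")
})

test_that("resistances follow the clo conversion, Hilpert chain and rt clamp", {
  r <- resistances(boy, list(ws_ms = 2.4))
  expect_equal(r$rc, 1.3 * 0.155 * 1212)  # athlete's clo 1.3
  expect_equal(resistances(coach, list(ws_ms = 2.4))$rc, 113, tolerance = 1)
  expect_equal(r$ra, 88, tolerance = 15)
  expect_equal(r$rt, 13)  # 104 - 0.25*364, above the floor of 10
  # clamp at both ends
  expect_equal(resistances(person_profile("r", "adult", met = 1),
                           list(ws_ms = 1))$rt, 104 - 0.25 * 42)
  expect_equal(resistances(boy, list(ws_ms = 1), m_wm2 = 1000)$rt, 10)
  # stronger wind thins the boundary layer
  ra <- resistances(boy, list(ws_ms = c(0.5, 2, 6)))$ra
  expect_true(all(diff(ra) < 0))
})

test_that("absorbed radiation reduces to the longwave closed form at night", {
  cn <- heat_constants()
  p <- person_profile("a", "adult")
  st <- site_context(ground_albedo = 0.2, ground_surface = "air")
  rec <- list(ta_c = 30, rh_pct = 50, ws_ms = 1, sr_wm2 = 0)
  got <- absorbed_radiation(rec, st, p, solar_elev_deg = -10)
  es_kpa <- 0.6108 * exp(17.27 * 30 / (30 + 237.3))
  eps_sky <- min(1, 0.70 + 5.95e-5 * (10 * 0.5 * es_kpa) * exp(1500 / 303.15))
  want <- cn$emissivity * cn$sigma * 303.15^4 *
    (0.5 * eps_sky + 0.5 * cn$ground_emissivity)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("shade scales the beam and sky-diffuse shortwave terms only", {
  p <- person_profile("a", "adult")
  rec <- may_mean_rec()
  open_site <- site_context(ground_albedo = 0.2, ground_surface = "air")
  shade <- site_context(ground_albedo = 0.2, ground_surface = "air",
                        shade_transmissivity = 0.175)
  dark <- site_context(ground_albedo = 0.2, ground_surface = "air",
                       shade_transmissivity = 0)
  r1 <- absorbed_radiation(rec, open_site, p, solar_elev_deg = 60)
  r2 <- absorbed_radiation(rec, shade, p, solar_elev_deg = 60)
  r0 <- absorbed_radiation(rec, dark, p, solar_elev_deg = 60)
  # (r_tau - r_0) is the tau-scaled part; it must scale linearly
  expect_equal(r2 - r0, 0.175 * (r1 - r0), tolerance = 1e-9)
  # the ground-reflected term survives full shade
  rec0 <- utils::modifyList(may_mean_rec(), list(sr_wm2 = 0))
  lw <- absorbed_radiation(rec0, dark, p, solar_elev_deg = 60)
  cn <- heat_constants()
  expect_equal(r0 - lw, (1 - cn$clothing_albedo) * 0.5 * 0.2 * 886.8,
               tolerance = 1e-9)
})

test_that("absorbed radiation at the hot-session mean sits in its corridor", {
  got <- absorbed_radiation(may_mean_rec(), turf60, boy, solar_elev_deg = 60)
  expect_equal(got, 750, tolerance = 80 / 750)
  expect_warning(
    absorbed_radiation(utils::modifyList(may_mean_rec(),
                                         list(sr_wm2 = 600)),
                       turf60, boy, solar_elev_deg = 1),
    "inconsistent")
})

test_that("convective exchange vanishes at zero gradient and flips sign", {
  # force Tc = Ta through the registry
  cn <- heat_constants(tc_base = 33.3, tc_slope = 0)
  cv <- convective_loss(boy, may_mean_rec(), constants = cn)
  expect_equal(cv$conv_wm2, 0, tolerance = 1e-12)
  expect_equal(cv$tsk_c, 33.3)
  expect_equal(cv$tsurf_c, 33.3)
  # athlete at the session mean: a modest sensible loss
  cv2 <- convective_loss(boy, may_mean_rec())
  expect_equal(cv2$conv_wm2, 23, tolerance = 10 / 23)
  # hotter air than core: sensible gain, negative loss
  hot <- utils::modifyList(may_mean_rec(), list(ta_c = 45))
  expect_lt(convective_loss(boy, hot)$conv_wm2, 0)
})

test_that("evaporation respects the vapour gradient, the ramp and the cap", {
  # zero vapour gradient: saturated air at skin temperature
  rec <- list(ta_c = 33.3, rh_pct = 100, ws_ms = 2.4, sr_wm2 = 0)
  expect_equal(evaporative_loss(boy, rec, tsk_c = 33.3), 0,
               tolerance = 1e-9)
  # athlete at the session mean hits the child cap (half the adult 365)
  cv <- convective_loss(boy, may_mean_rec())
  evap <- evaporative_loss(boy, may_mean_rec(), cv$tsk_c)
  expect_equal(evap, 182.5)
  # the cap itself halves with the child sweat factor
  boy_adult_sweat <- person_profile("x", "child", met = 7, clo = 1.3,
                                    sweat_capacity_factor = 1)
  evap_full <- evaporative_loss(boy_adult_sweat, may_mean_rec(), cv$tsk_c)
  expect_gt(evap_full, evap)
  expect_equal(evap, 0.5 * 365)
})

test_that("emitted longwave is Stefan-Boltzmann in the surface temperature", {
  expect_equal(emitted_longwave(35), 486, tolerance = 1 / 486)
  t <- seq(20, 50, by = 5)
  expect_true(all(diff(emitted_longwave(t)) > 0))
  p0 <- person_profile("e0", "adult", emissivity = 0)
  expect_equal(emitted_longwave(35, p0), 0)
})

test_that("the budget identity holds exactly and the streams are signed", {
  set.seed(42)
  n <- 200
  rec <- data.frame(ta_c = runif(n, 25, 40), rh_pct = runif(n, 20, 95),
                    ws_ms = runif(n, 0.5, 6), sr_wm2 = runif(n, 0, 1000))
  for (prof in list(boy, coach)) {
    b <- energy_budget(prof, rec, turf60, solar_elev_deg = 60)
    expect_equal(b$budget_wm2,
                 b$m_wm2 + b$rabs_wm2 - b$conv_wm2 - b$evap_wm2 -
                   b$tremit_wm2, tolerance = 1e-9)
    expect_true(all(b$evap_wm2 >= 0))
    expect_true(all(b$tremit_wm2 > 0))
  }
})

test_that("budget rises with radiation, surface heat and activity", {
  base <- may_mean_rec()
  grid <- expand.grid(ta = c(25, 33, 40), ws = c(0.5, 2.4, 6))
  for (i in seq_len(nrow(grid))) {
    rec <- utils::modifyList(base, list(ta_c = grid$ta[i],
                                        ws_ms = grid$ws[i]))
    # solar radiation
    b_sr <- vapply(c(0, 250, 500, 750, 1000), function(sr)
      energy_budget(boy, utils::modifyList(rec, list(sr_wm2 = sr)),
                    turf60, solar_elev_deg = 60)$budget_wm2, numeric(1))
    expect_true(all(diff(b_sr) >= 0))
    # ground surface temperature
    b_ts <- vapply(c(30, 45, 60, 75), function(ts)
      energy_budget(boy, rec,
                    site_context(ground_albedo = 0.08,
                                 ground_surface_temp_c = ts),
                    solar_elev_deg = 60)$budget_wm2, numeric(1))
    expect_true(all(diff(b_ts) >= 0))
  }
  # MET monotonicity holds in calm-to-moderate wind.  In strong dry wind
  # (Ws ~ 6 m/s) the wettedness ramp lets evaporative cooling rise faster
  # than metabolic heat over part of the MET range, so the budget is only
  # locally monotone there; the session winds are well inside the
  # monotone regime.
  for (ws in c(0.5, 1.5, 3)) {
    rec <- utils::modifyList(base, list(ws_ms = ws))
    b_met <- vapply(c(2, 4, 6, 8), function(met)
      energy_budget(person_profile("v", "child", met = met, clo = 1.3),
                    rec, turf60, solar_elev_deg = 60)$budget_wm2,
      numeric(1))
    expect_true(all(diff(b_met) >= 0))
  }
})

test_that("a child runs a larger surplus than an adult in any environment", {
  grid <- expand.grid(ta = seq(25, 40, by = 5), ws = c(0.5, 2, 6),
                      sr = c(0, 500, 1000), rh = c(30, 60, 90))
  rec <- data.frame(ta_c = grid$ta, rh_pct = grid$rh, ws_ms = grid$ws,
                    sr_wm2 = grid$sr)
  b_child <- energy_budget(boy, rec, turf60, solar_elev_deg = 60)
  b_adult <- energy_budget(coach, rec, turf60, solar_elev_deg = 60)
  expect_true(all(b_child$budget_wm2 >= b_adult$budget_wm2))
})

test_that("shade never increases the budget", {
  taus <- c(1, 0.7, 0.4, 0.175, 0)
  b <- vapply(taus, function(tau)
    energy_budget(parent, may_mean_rec(),
                  site_context(sky_view_factor = 0.5,
                               shade_transmissivity = tau,
                               ground_albedo = 0.25,
                               ground_surface = "air"),
                  solar_elev_deg = 60)$budget_wm2, numeric(1))
  expect_true(all(diff(b) <= 0))
})

test_that("session-mean conditions put the athlete and coach in their corridors", {
  athlete <- energy_budget(boy, may_mean_rec(), turf60,
                           solar_elev_deg = 60)$budget_wm2
  grass_coach <- energy_budget(coach, may_mean_rec(), defs$sites$grass,
                               solar_elev_deg = 60)$budget_wm2
  parent_b <- energy_budget(parent, may_mean_rec(), defs$sites$oak_shade,
                            solar_elev_deg = 60)$budget_wm2
  expect_gt(athlete, 340)
  expect_gt(grass_coach, 120)
  expect_lt(grass_coach, 340)
  expect_lt(parent_b, grass_coach)
  expect_lt(grass_coach, athlete)
})
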