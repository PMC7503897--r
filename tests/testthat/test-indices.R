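test_that("heat index reproduces hand-evaluated branch values", {
  # hot branch: the full regression at a hot-afternoon session mean
  expect_equal(round(heat_index(34.0, 42.9), 1), 36.2)
  # cool branch: the simple averaged formula, evaluated by hand in F
  expect_equal(c_to_f(heat_index(f_to_c(70), 50)), 69.05, tolerance = 1e-9)
  expect_equal(c_to_f(heat_index(f_to_c(70), 0)), 66.7, tolerance = 1e-9)
})

test_that("heat index rejects out-of-range inputs", {
  expect_error(heat_index(34, 101), "rh_pct")
  expect_error(heat_index(34, -1), "rh_pct")
  expect_error(heat_index(70, 50), "ta_c")
  expect_error(heat_index(NA_real_, 50), "finite")
})

test_that("heat index is approximately continuous across the branch switch", {
  # scan the 75..85 F band; the NWS procedure is only approximately
  # continuous at the hand-off.  Max observed jump: ~2.11 F at RH 80
  # (the regression sits above the simple formula at the switch point);
  # bound it at 2.5 F.
  for (rh in c(40, 60, 80)) {
    tf <- seq(75, 85, by = 0.01)
    hi <- c_to_f(heat_index(f_to_c(tf), rh))
    expect_lt(max(abs(diff(hi))), 2.5)
  }
})

test_that("heat index increases with humidity on the hot grid", {
  grid <- expand.grid(ta = seq(27, 43, by = 2), rh = seq(40, 88, by = 2))
  d <- heat_index(grid$ta, grid$rh + 1) - heat_index(grid$ta, grid$rh)
  expect_true(all(d > 0))
})

test_that("Stull wet bulb matches direct evaluation and physics bounds", {
  expect_equal(wet_bulb_stull(20, 50), 13.7, tolerance = 0.05)
  expect_equal(wet_bulb_stull(20, 99), 20.0, tolerance = 0.1)
  expect_warning(out <- wet_bulb_stull(20, 100), "validity")
  expect_equal(out, 20.0, tolerance = 0.1)

  # the empirical fit overshoots the Tw <= Ta bound by ~0.01 C at the
  # hot-saturated corner (Ta 45, RH 99); allow that fit tolerance
  grid <- expand.grid(ta = seq(5, 45, by = 2.5), rh = seq(5, 99, by = 2))
  tw <- wet_bulb_stull(grid$ta, grid$rh)
  expect_true(all(tw < grid$ta + 0.02))
  # monotone nondecreasing in RH at fixed Ta
  for (ta in seq(5, 45, by = 5)) {
    tw <- wet_bulb_stull(ta, seq(5, 99, by = 1))
    expect_true(all(diff(tw) > -1e-9))
  }
})

test_that("Stull tracks the iterative psychrometric balance at its stated accuracy", {
  # the closed form was fit to the psychrometric wet bulb with a mean
  # absolute error near 0.3 C, degrading toward 1 C in hot dry air
  grid <- expand.grid(ta = seq(5, 45, by = 2.5), rh = seq(5, 99, by = 2))
  oracle <- mapply(psychro_wet_bulb, grid$ta, grid$rh)
  err <- abs(wet_bulb_stull(grid$ta, grid$rh) - oracle)
  expect_lt(mean(err), 0.5)   # measured ~0.32 C over this grid
  expect_lt(max(err), 1.5)    # measured ~1.15 C, in the hot-dry corner
  # at the moderate reference point the two agree closely
  expect_equal(wet_bulb_stull(20, 50), psychro_wet_bulb(20, 50),
               tolerance = 0.1)
})

test_that("WBGT is the exact convex combination 0.7/0.2/0.1", {
  expect_equal(wbgt(30, 30, 30), 30)
  expect_equal(wbgt(25, 40, 34), 28.9)
  set.seed(1)
  for (i in 1:50) {
    v <- runif(3, 10, 60)
    w <- wbgt(v[1], v[2], v[3])
    expect_gte(w, min(v)); expect_lte(w, max(v))
  }
  # linear in Tg with weight 0.2
  expect_equal(wbgt(25, 41, 34) - wbgt(25, 40, 34), 0.2)
})

test_that("wbgt_from_weather composes Stull with the globe reading", {
  rec <- data.frame(ta_c = 30, rh_pct = 100, tg_c = 30)
  expect_warning(w <- wbgt_from_weather(rec), "validity")
  expect_equal(w, 30.0, tolerance = 0.1)
  expect_error(wbgt_from_weather(data.frame(ta_c = 30, rh_pct = 50)),
               "tg_c")
})

test_that("temperature conversions are exact inverses", {
  expect_equal(c_to_f(28), 82.4)
  expect_equal(round(c_to_f(28)), 82)
  expect_equal(c_to_f(0), 32)
  x <- seq(-40, 60, by = 0.37)
  expect_equal(f_to_c(c_to_f(x)), x, tolerance = 1e-12)
})

test_that("index_table appends hi, tw and wbgt columns", {
  s <- make_series(3, tg = 40)
  out <- index_table(s)
  expect_true(all(c("hi_c", "tw_c", "wbgt_c") %in% names(out)))
  expect_equal(out$hi_c, heat_index(s$ta_c, s$rh_pct))
})
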