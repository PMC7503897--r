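# Small in-code fixtures shared across test files.

make_series <- function(n = 3, ta = 33, rh = 48, ws = 2.4, sr = 800,
                        tg = NULL, ts = NULL, interval_s = 10,
                        start = as.POSIXct("2020-05-19 18:30:00",
                                           tz = "UTC")) {
  df <- data.frame(
    timestamp = start + (seq_len(n) - 1) * interval_s,
    ta_c = rep_len(ta, n), rh_pct = rep_len(rh, n),
    ws_ms = rep_len(ws, n), sr_wm2 = rep_len(sr, n)
  )
  if (!is.null(tg)) df$tg_c <- rep_len(tg, n)
  if (!is.null(ts)) df$ts_c <- rep_len(ts, n)
  micromet_series(df, interval_s = interval_s)
}

# representative session-mean forcing used by several single-point checks:
# Ta 33.3 C, RH 48 %, Ws 2.4 m/s, SR 886.8 W/m2, solar elevation 60 deg
may_mean_rec <- function() {
  list(ta_c = 33.3, rh_pct = 48, ws_ms = 2.4, sr_wm2 = 886.8)
}

# iterative psychrometric-balance wet bulb: adiabatic saturation with
# Bolton saturation vapour pressure and temperature-dependent latent heat;
# independent of the Stull closed form it cross-checks
psychro_wet_bulb <- function(ta_c, rh_pct, p_hpa = 1013.25) {
  esb <- function(t) 6.112 * exp(17.67 * t / (t + 243.5))
  e <- rh_pct / 100 * esb(ta_c)
  w <- 0.622 * e / (p_hpa - e)
  f <- function(tw) 1005 * (ta_c - tw) -
    (2.501e6 - 2370 * tw) * (0.622 * esb(tw) / (p_hpa - esb(tw)) - w)
  stats::uniroot(f, c(-60, ta_c + 1e-9), tol = 1e-10)$root
}
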