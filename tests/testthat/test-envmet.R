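test_that("daily GDD follows the capped-average rule", {
  expect_equal(gdd_daily(15, 25, 10, 30), 10)
  expect_equal(gdd_daily(4, 8, 10, 30), 0)
  expect_equal(gdd_daily(20, 36, 10, 30), 15)
  expect_error(gdd_daily(20, 15), "tmax < tmin")
  # vectorized, and cumulative thermal time is non-decreasing from sowing
  w <- simulate_weather("cool_humid", n_days = 120, seed = 1)
  tt <- thermal_time(w, w$date[10])
  expect_true(all(diff(tt) >= 0))
  expect_true(all(tt[w$date <= w$date[10]] == 0))
})

# independent FAO-56 coding used as the oracle: scalar, written from the
# standard's equation sequence rather than the package's vectorized path
fao56_oracle <- function(tmin, tmax, rh, rs, u2, doy, lat_deg, z) {
  es_t <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  tmean <- (tmax + tmin) / 2
  slope <- 4098 * es_t(tmean) / (tmean + 237.3)^2
  p <- 101.3 * ((293 - 0.0065 * z) / 293)^5.26
  gam <- 0.000665 * p
  es <- (es_t(tmax) + es_t(tmin)) / 2
  ea <- rh / 100 * es
  phi <- pi / 180 * lat_deg
  dr <- 1 + 0.033 * cos(2 * pi / 365 * doy)
  dec <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  ws <- acos(min(max(-tan(phi) * tan(dec), -1), 1))
  ra <- 24 * 60 / pi * 0.082 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
  rso <- (0.75 + 2e-5 * z) * ra
  rns <- 0.77 * rs
  fcd <- 1.35 * min(rs / rso, 1) - 0.35
  rnl <- max(4.903e-9 * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
               (0.34 - 0.14 * sqrt(ea)) * fcd, 0)
  rn <- rns - rnl
  num <- 0.408 * slope * rn + gam * 900 / (tmean + 273) * u2 * (es - ea)
  max(num / (slope + gam * (1 + 0.34 * u2)), 0)
}

test_that("reference evapotranspiration matches an independent FAO-56 coding", {
  set.seed(42)
  n <- 25
  w <- data.frame(
    date = seq(as.Date("2018-04-01"), by = "9 days", length.out = n),
    tmin = runif(n, 2, 16), tmax = 0, rh_mean = runif(n, 40, 95),
    radiation = runif(n, 3, 28), wind2m = runif(n, 0.3, 5), precip = 0)
  w$tmax <- w$tmin + runif(n, 2, 14)
  et <- et0_penman_monteith(w, latitude = 51, elevation = 10)
  doy <- as.integer(format(w$date, "%j"))
  oracle <- vapply(seq_len(n), function(i)
    fao56_oracle(w$tmin[i], w$tmax[i], w$rh_mean[i], w$radiation[i],
                 w$wind2m[i], doy[i], 51, 10), numeric(1))
  expect_true(all(abs(et - oracle) < 0.05))
})

test_that("ET0 limit cases and monotonicity hold", {
  base <- data.frame(date = as.Date("2018-07-01"), tmin = 12, tmax = 22,
                     rh_mean = 100, radiation = 0, wind2m = 0, precip = 0)
  expect_equal(et0_penman_monteith(base, 51, 10), 0)
  rads <- seq(2, 28, by = 2)
  ets <- vapply(rads, function(r) {
    w <- base; w$radiation <- r; w$rh_mean <- 60; w$wind2m <- 2
    et0_penman_monteith(w, 51, 10)
  }, numeric(1))
  expect_true(all(diff(ets) > 0))
  bad <- base; bad$wind2m <- NA
  expect_error(et0_penman_monteith(bad, 51, 10), "wind2m")
})

test_that("cumulative water deficit is the prefix sum of ET0 minus rain", {
  d <- seq(as.Date("2018-04-01"), by = "day", length.out = 10)
  expect_equal(cumulative_water_deficit(d, rep(5, 10), rep(0, 10))[10], 50)
  expect_equal(cumulative_water_deficit(d, rep(3, 10), rep(3, 10)),
               rep(0, 10))
  set.seed(7)
  e <- runif(30, 0, 6); p <- rpois(30, 2)
  d30 <- seq(as.Date("2018-04-01"), by = "day", length.out = 30)
  expect_equal(cumulative_water_deficit(d30, e, p),
               cumsum(e - p), tolerance = 1e-12)
  # days before the start date are undefined
  d2 <- seq(as.Date("2018-03-25"), by = "day", length.out = 10)
  cwd <- cumulative_water_deficit(d2, rep(1, 10), rep(0, 10))
  expect_true(all(is.na(cwd[d2 < as.Date("2018-04-01")])))
})

test_that("CWSI interpolates between its baselines and clamps", {
  expect_equal(cwsi(24, 26, -2, 6), 0)     # dT at lower baseline
  expect_equal(cwsi(32, 26, -2, 6), 1)     # dT at upper baseline
  expect_equal(cwsi(28, 26, -2, 6), 0.5)   # midpoint
  expect_equal(cwsi(20, 26, -2, 6), 0)     # clamped below
  expect_equal(cwsi(40, 26, -2, 6), 1)     # clamped above
  expect_error(cwsi(25, 26, 3, 1), "exceed")
})

test_that("baseline estimation recovers generator stress levels", {
  dT <- c(rep(-2, 8), rep(6, 10))
  ww <- c(rep(TRUE, 8), rep(FALSE, 10))
  bl <- estimate_baselines(dT, ww, margin = 0)
  expect_equal(bl$dT_ll, -2)
  expect_equal(bl$dT_ul, 6)
  expect_error(estimate_baselines(rep(1, 20), rep(c(TRUE, FALSE), 10)),
               "degenerate")

  # known stress levels spanning the full range: noise-free inversion is
  # exact with true baselines, and quantile baselines recover them within
  # 0.05 mean absolute error
  set.seed(11)
  stress <- c(rep(0, 60), runif(300, 0, 1))
  ta <- 26; ll <- -3; ul <- 5
  tc <- ta + ll + stress * (ul - ll)
  expect_equal(cwsi(tc, ta, ll, ul), stress, tolerance = 1e-12)
  bl2 <- estimate_baselines(tc - ta, stress == 0)
  est <- cwsi(tc, ta, bl2$dT_ll, bl2$dT_ul)
  expect_lt(mean(abs(est - stress)), 0.05)
})
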