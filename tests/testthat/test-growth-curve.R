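test_that("beta curve endpoints and refitting are exact on noiseless data", {
  tt <- seq(40, 1000, length.out = 14)
  for (par in list(c(80, 400, 800), c(0.95, 300, 650), c(60, 250, 900))) {
    y <- beta_growth(tt, par[1], par[2], par[3])
    f <- fit_beta_curve(tt, y)
    expect_true(f$converged)
    expect_lt(abs(f$wmax - par[1]) / par[1], 1e-4)
    expect_lt(abs(f$tm - par[2]) / par[2], 1e-4)
    expect_lt(abs(f$te - par[3]) / par[3], 1e-4)
    expect_equal(beta_growth(f$te, f$wmax, f$tm, f$te), f$wmax)
    expect_equal(beta_growth(0, f$wmax, f$tm, f$te), 0)
  }
  # degenerate inputs flag non-convergence instead of erroring
  expect_false(fit_beta_curve(tt, rep(0, length(tt)))$converged)
  expect_false(fit_beta_curve(tt[1:3], c(1, 2, 3))$converged)
})

test_that("AGRmax closed form equals the numerical derivative maximum", {
  f <- list(wmax = 80, tm = 400, te = 800, converged = TRUE)
  class(f) <- "beta_fit"
  grid <- seq(1, 799, by = 0.05)
  num <- 100 * max(diff(beta_growth(grid, 80, 400, 800)) / diff(grid))
  expect_lt(abs(agrmax(f) - num), 1e-3)
  num2 <- 100 * max(beta_growth_rate(grid, 80, 400, 800))
  expect_lt(abs(agrmax(f) - num2), 1e-6)
  # linear in wmax, positive, attained at tm
  f2 <- f; f2$wmax <- 160
  expect_equal(agrmax(f2), 2 * agrmax(f))
  expect_gt(agrmax(f), 0)
  expect_equal(100 * beta_growth_rate(400, 80, 400, 800), agrmax(f))
})

test_that("CH is the fitted asymptote, invariant to the time parameters", {
  f <- structure(list(wmax = 80, tm = 400, te = 800, converged = TRUE),
                 class = "beta_fit")
  expect_equal(canopy_height_trait(f), 80)
  f2 <- f; f2$tm <- 200; f2$te <- 1200
  expect_equal(canopy_height_trait(f2), 80)
})

test_that("CC75 is the bisection root of the rising limb", {
  f <- structure(list(wmax = 0.95, tm = 300, te = 650, converged = TRUE),
                 class = "beta_fit")
  t75 <- cc75(f)
  expect_equal(beta_growth(t75, 0.95, 300, 650), 0.75, tolerance = 1e-6)
  # grid-scan oracle
  grid <- seq(0, 650, by = 0.1)
  scan <- grid[which(beta_growth(grid, 0.95, 300, 650) >= 0.75)[1]]
  expect_lt(abs(t75 - scan), 0.1)
  # asymptote below the target: trait is missing
  f_low <- structure(list(wmax = 0.70, tm = 300, te = 650, converged = TRUE),
                     class = "beta_fit")
  expect_true(is.na(cc75(f_low)))
})

test_that("R-stage curve crossings are ordered and recovered", {
  tt <- seq(100, 1900, length.out = 16)
  y <- beta_growth(tt, 7.5, 1000, 1700)
  fr <- fit_rstage_curve(tt, y)
  expect_true(fr$fit$converged)
  expect_true(fr$r1 < fr$r2 && fr$r2 < fr$r5)
  # recovered crossings match the generating curve within 10 GDD
  truth <- vapply(c(1, 2, 5), function(lv) {
    g <- seq(1, 1700, by = 0.05)
    g[which(beta_growth(g, 7.5, 1000, 1700) >= lv)[1]]
  }, numeric(1))
  expect_lt(max(abs(c(fr$r1, fr$r2, fr$r5) - truth)), 10)
  # scores above stage 6 are excluded from the fit by contract
  y_noisy <- c(y[1:14], 7.9, 8)
  fr2 <- fit_rstage_curve(tt, y_noisy)
  expect_true(fr2$fit$converged)
  # asymptote below 5: R5 missing
  y_low <- beta_growth(tt, 4.5, 900, 1500)
  fr3 <- fit_rstage_curve(tt, y_low)
  expect_true(is.na(fr3$r5))
  expect_false(is.na(fr3$r2))
  expect_false(fit_rstage_curve(tt, rep(3, 16))$fit$converged)
})

test_that("durations telescope and propagate missingness", {
  d <- durations(850, 1150, 1690)
  expect_equal(unlist(d), c(r2r5 = 300, r5r8 = 540, r2r8 = 840))
  expect_equal(d$r2r5 + d$r5r8, d$r2r8)
  dm <- durations(850, NA, 1690)
  expect_true(is.na(dm$r2r5) && is.na(dm$r5r8))
  expect_equal(dm$r2r8, 840)
})

test_that("DET is the post-flowering growth duration, unclamped", {
  expect_equal(det_trait(900, 500), 400)
  expect_equal(det_trait(500, 500), 0)
  expect_equal(det_trait(450, 500), -50)
  expect_equal(det_trait(900 + 25, 500), det_trait(900, 500) + 25)
})

test_that("SNC measures the post-peak cover drop", {
  cov1 <- c(0.2, 0.5, 0.9, 0.88, 0.6, 0.3, 0.3)
  expect_equal(snc(cov1, k_tail = 2), 0.88 - 0.3, tolerance = 1e-9)
  expect_equal(snc(rep(0.8, 8)), 0)
  expect_true(is.na(snc(c(0.2, 0.5, 0.9))))   # no tail after the max
  # accelerated senescence scores higher (noise-free generator ordering)
  tt <- seq(150, 1800, length.out = 15)
  base <- beta_growth(tt, 0.95, 300, 650)
  decay <- function(t_sen, rate) {
    cv <- base
    late <- tt > t_sen
    cv[late] <- pmax(0, cv[late] - rate * (tt[late] - t_sen))
    cv
  }
  expect_gt(snc(decay(1350, 0.0021)), snc(decay(1500, 0.0012)))
})
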