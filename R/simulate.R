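#' Simulate a daily weather season
#'
#' Two season archetypes for a temperate maritime trial site: a hot, dry,
#' sunny season and a cool, humid one. Daily mean temperature follows a
#' seasonal sinusoid with AR(1) day-to-day variation; solar radiation is a
#' cloudiness-damped fraction of the clear-sky envelope; precipitation is a
#' Bernoulli-gamma process. The same seed produces an identical series.
#'
#' @param archetype "hot_dry" or "cool_humid".
#' @param start_date first day (Date).
#' @param n_days length of the series (days).
#' @param seed integer seed.
#' @param latitude degrees north, used for the clear-sky envelope.
#' @return data.frame: date, tmin, tmax, rh_mean, radiation, wind2m, precip.
#' @export
simulate_weather <- function(archetype = c("hot_dry", "cool_humid"),
                             start_date = as.Date("2018-04-01"),
                             n_days = 200, seed = 1, latitude = 51) {
  archetype <- match.arg(archetype)
  if (n_days < 1) stopf("simulate_weather: empty date range")
  set.seed(seed)
  p <- switch(archetype,
    hot_dry = list(tmean0 = 12.5, amp = 8.5, noise_sd = 2.2, drange = 10.5,
                   clear = c(8, 3), rh0 = 62, rh_sd = 8, wet_p = 0.18,
                   rain_mean = 4.5, wind_mu = 0.55),
    cool_humid = list(tmean0 = 10.0, amp = 7.0, noise_sd = 2.2, drange = 8.0,
                      clear = c(4, 4), rh0 = 78, rh_sd = 7, wet_p = 0.45,
                      rain_mean = 4.0, wind_mu = 0.75))
  dates <- seq(as.Date(start_date), by = "day", length.out = n_days)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- p$tmean0 + p$amp * cos(2 * pi * (doy - 200) / 365)
  ar <- stats::filter(stats::rnorm(n_days, 0, p$noise_sd), 0.6, "recursive")
  tmean <- seasonal + as.numeric(ar)
  cloud <- stats::rbeta(n_days, p$clear[1], p$clear[2])   # clear-sky fraction
  drange <- p$drange * (0.5 + 0.7 * cloud)
  tmin <- tmean - drange / 2
  tmax <- tmean + drange / 2
  ra <- extraterrestrial_radiation(doy, latitude)
  radiation <- pmax(0.75 * ra * (0.25 + 0.75 * cloud), 0.5)
  rh <- clamp(p$rh0 + stats::rnorm(n_days, 0, p$rh_sd) - 8 * (cloud - mean(cloud)), 20, 100)
  wind <- stats::rlnorm(n_days, p$wind_mu, 0.35)
  wet <- stats::runif(n_days) < p$wet_p * (1.3 - 0.8 * cloud)
  precip <- ifelse(wet, stats::rgamma(n_days, shape = 1.1, scale = p$rain_mean), 0)
  data.frame(date = dates, tmin = tmin, tmax = tmax, rh_mean = rh,
             radiation = radiation, wind2m = wind, precip = round(precip, 2))
}

#' Default per-trait generative configuration
#'
#' Growth-group means, variance components and drought multipliers for the
#' manually scored traits, set to magnitudes typical of a diverse soybean
#' collection under a temperate trial (heights in cm, phenology in GDD,
#' seed traits per plant). \code{drought_mult} is the multiplicative effect
#' of drought on the genetic value of the trait.
#'
#' @param long_drought logical; if TRUE use the stronger yield/senescence
#'   effects of a long-duration drought treatment.
#' @return named list of per-trait configurations.
#' @export
default_trait_config <- function(long_drought = FALSE) {
  cfg <- list(
    PLV = list(mu = c(11.0, 10.9, 10.7, 10.5), sg2 = 2.0, sblock2 = 0.15,
               srow2 = 0.05, scol2 = 0.05, se2 = 1.0, drought_mult = 1.0),
    R8 = list(mu = c(1800, 1720, 1640, 1560), sg2 = 8000, sblock2 = 400,
              srow2 = 150, scol2 = 150, se2 = 2500, drought_mult = 0.99),
    PPS = list(mu = c(26, 25, 23, 22), sg2 = 6, sblock2 = 0.5,
               srow2 = 0.2, scol2 = 0.2, se2 = 6, drought_mult = 0.93),
    SN = list(mu = c(85, 80, 70, 65), sg2 = 300, sblock2 = 20,
              srow2 = 8, scol2 = 8, se2 = 180, drought_mult = 0.83),
    SW = list(mu = c(14.5, 13.5, 12.5, 11.5), sg2 = 9, sblock2 = 0.6,
              srow2 = 0.25, scol2 = 0.25, se2 = 5, drought_mult = 0.84)
  )
  if (long_drought) {
    cfg$SN$drought_mult <- 0.62
    cfg$SW$drought_mult <- 0.57
    cfg$PPS$drought_mult <- 0.74
  }
  cfg
}

#' Simulate genotype, spatial and residual effects
#'
#' Generative twin of the analysis mixed model: for each trait, the plot
#' value is the growth-group mean plus a genotype effect, block, field-row
#' and field-column effects and a residual, each centred Gaussian with the
#' configured variance. Genotype effects are drawn once per genotype and
#' shared across all designs passed in (so control and drought fields share
#' genetics); spatial and residual effects are drawn per field. Drought
#' plots have their genetic value (mean + genotype effect) multiplied by
#' the trait's \code{drought_mult}.
#'
#' @param designs one design or a list of [build_design()] tables.
#' @param trait_config named list as in [default_trait_config()]; variances
#'   \code{sg2}, \code{sblock2}, \code{srow2}, \code{scol2}, \code{se2}
#'   must be non-negative; \code{mu} is a scalar or one mean per growth
#'   group.
#' @param seed integer seed.
#' @return list with \code{plot_values} (data.frame, one row per plot,
#'   traits as columns) and \code{truth} (genotype effects per trait,
#'   variance components, implied broad-sense heritability
#'   \code{sg2/(sg2+se2)}).
#' @export
simulate_effects <- function(designs, trait_config = default_trait_config(),
                             seed = 1) {
  if (is.data.frame(designs)) designs <- list(designs)
  for (tc in trait_config) {
    v <- unlist(tc[c("sg2", "sblock2", "srow2", "scol2", "se2")])
    if (any(v < 0)) stopf("simulate_effects: negative variance component")
  }
  set.seed(seed)
  all_geno <- sort(unique(unlist(lapply(designs, function(d) d$genotype_id))))
  geno_eff <- list()
  truth_vc <- list()
  for (tr in names(trait_config)) {
    tc <- trait_config[[tr]]
    geno_eff[[tr]] <- stats::setNames(
      stats::rnorm(length(all_geno), 0, sqrt(tc$sg2)), all_geno)
    truth_vc[[tr]] <- data.frame(
      trait = tr, sg2 = tc$sg2, sblock2 = tc$sblock2 %||% 0,
      srow2 = tc$srow2 %||% 0, scol2 = tc$scol2 %||% 0, se2 = tc$se2,
      h2_implied = if (tc$sg2 + tc$se2 > 0) tc$sg2 / (tc$sg2 + tc$se2) else NA_real_)
  }
  vals <- lapply(designs, function(d) {
    out <- d[, c("plot_id", "genotype_id", "growth_group", "treatment",
                 "year_label", "block", "row", "column", "field_row", "field_col")]
    for (tr in names(trait_config)) {
      tc <- trait_config[[tr]]
      mu <- if (length(tc$mu) == 4) tc$mu[d$growth_group] else rep(tc$mu, nrow(d))
      blocks <- sort(unique(d$block))
      rows <- sort(unique(d$field_row))
      cols <- sort(unique(d$field_col))
      be <- stats::setNames(stats::rnorm(length(blocks), 0, sqrt(tc$sblock2 %||% 0)), blocks)
      re <- stats::setNames(stats::rnorm(length(rows), 0, sqrt(tc$srow2 %||% 0)), rows)
      ce <- stats::setNames(stats::rnorm(length(cols), 0, sqrt(tc$scol2 %||% 0)), cols)
      ee <- stats::rnorm(nrow(d), 0, sqrt(tc$se2))
      genetic <- mu + geno_eff[[tr]][d$genotype_id]
      mult <- if (identical(d$treatment[1], "drought")) tc$drought_mult %||% 1 else 1
      out[[tr]] <- genetic * mult + be[as.character(d$block)] +
        re[as.character(d$field_row)] + ce[as.character(d$field_col)] + ee
    }
    rownames(out) <- NULL
    out
  })
  list(plot_values = do.call(rbind, vals),
       truth = list(genotype_effects = geno_eff,
                    varcomps = do.call(rbind, truth_vc)))
}

#' Default growth-curve generator configuration
#'
#' True beta-curve parameters per growth group for canopy height, canopy
#' cover (with post-peak linear senescence) and reproductive-stage
#' progression, plus the canopy-temperature stress model. Late growth
#' groups (GP1) develop over more thermal time than early ones (GP4).
#'
#' @return nested list of generator parameters.
#' @export
default_series_config <- function() {
  list(
    height = list(wmax_mu = c(94, 90, 86, 82), wmax_sg2 = 30, wmax_se2 = 18,
                  te_mu = c(1060, 1020, 980, 940), te_sd = 30, tm_frac = 0.42),
    cover = list(wmax = 0.95, te_mu = c(680, 660, 640, 620), te_sd = 20,
                 tm_frac = 0.45,
                 t_sen_mu = c(1580, 1530, 1480, 1430), t_sen_sd = 40,
                 sen_rate = 0.0012),
    rstage = list(rmax = 7.5, tm_mu = c(1100, 1050, 1000, 950), tm_sd = 25,
                  dte = 700),
    thermal = list(ta = 26, dT_ll = -3, dT_ul = 5,
                   stress_control = 0.10, stress_drought = 0.60),
    treatment_effect = list(wmax_mult = 0.89, te_shift = -60,
                            senescence_accel = 120, sen_rate_mult = 1.4),
    noise = list(height = 1.5, cover = 0.02, rstage = 0.25, tc = 0.3),
    flights = seq(150, 1800, length.out = 15),
    thermal_flights = c(900, 1000, 1100, 1200)
  )
}

#' Simulate plot-level time series
#'
#' Generates, for every plot of one or more designs, canopy height, canopy
#' cover and R-stage observations at the configured thermal flight times,
#' plus canopy temperature at the thermal flights. Values are sampled from
#' the beta growth curve (inverting the trait-extraction model) with
#' independent Gaussian measurement noise; drought plots have their height
#' asymptote multiplied by \code{wmax_mult}, their development shifted by
#' \code{te_shift} GDD and their senescence accelerated. Canopy temperature
#' is \code{Ta + dT_ll + stress (dT_ul - dT_ll) + noise} so the crop water
#' stress index is exactly recoverable from the true baselines.
#'
#' @param designs one design or list of designs.
#' @param config generator parameters, see [default_series_config()].
#' @param seed integer seed.
#' @return list with \code{series} (long data.frame: plot_id,
#'   thermal_time, variable in height/cover/rstage, value), \code{thermal}
#'   (plot_id, flight, thermal_time, tc, ta, stress_true) and \code{truth}
#'   (per-plot true curve parameters and stress levels).
#' @export
simulate_plot_series <- function(designs, config = default_series_config(),
                                 seed = 1) {
  if (is.data.frame(designs)) designs <- list(designs)
  set.seed(seed)
  cf <- config
  tre <- cf$treatment_effect
  if (any(unlist(tre[c("wmax_mult", "sen_rate_mult")]) <= 0))
    stopf("simulate_plot_series: multipliers must be > 0")
  all_geno <- sort(unique(unlist(lapply(designs, function(d) d$genotype_id))))
  ng <- length(all_geno)
  # per-genotype deviations, shared across fields
  g <- list(
    h_wmax = stats::setNames(stats::rnorm(ng, 0, sqrt(cf$height$wmax_sg2)), all_geno),
    h_te = stats::setNames(stats::rnorm(ng, 0, cf$height$te_sd), all_geno),
    c_te = stats::setNames(stats::rnorm(ng, 0, cf$cover$te_sd), all_geno),
    c_sen = stats::setNames(stats::rnorm(ng, 0, cf$cover$t_sen_sd), all_geno),
    r_tm = stats::setNames(stats::rnorm(ng, 0, cf$rstage$tm_sd), all_geno)
  )
  series <- list(); thermal <- list(); truth <- list()
  for (d in designs) {
    n <- nrow(d)
    dr <- identical(d$treatment[1], "drought")
    gp <- d$growth_group
    gid <- d$genotype_id
    wmax_h <- cf$height$wmax_mu[gp] + g$h_wmax[gid] +
      stats::rnorm(n, 0, sqrt(cf$height$wmax_se2))
    te_h <- cf$height$te_mu[gp] + g$h_te[gid]
    if (dr) {
      wmax_h <- wmax_h * tre$wmax_mult
      te_h <- te_h + tre$te_shift
    }
    tm_h <- cf$height$tm_frac * te_h
    te_c <- cf$cover$te_mu[gp] + g$c_te[gid]
    tm_c <- cf$cover$tm_frac * te_c
    wmax_c <- rep(cf$cover$wmax, n)
    t_sen <- cf$cover$t_sen_mu[gp] + g$c_sen[gid]
    sen_rate <- rep(cf$cover$sen_rate, n)
    if (dr) {
      t_sen <- t_sen - tre$senescence_accel
      sen_rate <- sen_rate * tre$sen_rate_mult
    }
    tm_r <- cf$rstage$tm_mu[gp] + g$r_tm[gid]
    te_r <- tm_r + cf$rstage$dte
    if (dr) {
      tm_r <- tm_r + tre$te_shift
      te_r <- te_r + tre$te_shift
    }
    stress <- rep(if (dr) cf$thermal$stress_drought else cf$thermal$stress_control, n)
    if (any(te_h <= tm_h) || any(te_c <= tm_c) || any(te_r <= tm_r))
      stopf("simulate_plot_series: degenerate truth (te <= tm)")
    truth[[length(truth) + 1L]] <- data.frame(
      plot_id = d$plot_id, genotype_id = gid, treatment = d$treatment,
      year_label = d$year_label,
      wmax_h = wmax_h, tm_h = tm_h, te_h = te_h,
      wmax_c = wmax_c, tm_c = tm_c, te_c = te_c,
      t_sen = t_sen, sen_rate = sen_rate,
      rmax = cf$rstage$rmax, tm_r = tm_r, te_r = te_r, stress = stress)
    ft <- cf$flights
    nf <- length(ft)
    # vectorized over plot x flight: rows vary fastest over flights
    tt <- rep(ft, times = n)
    idx <- rep(seq_len(n), each = nf)
    h <- beta_growth_v(tt, wmax_h[idx], tm_h[idx], te_h[idx]) +
      stats::rnorm(n * nf, 0, cf$noise$height)
    cov_true <- beta_growth_v(tt, wmax_c[idx], tm_c[idx], te_c[idx])
    late <- tt > t_sen[idx]
    cov_true[late] <- pmax(0, cov_true[late] -
                             (sen_rate[idx] * (tt - t_sen[idx]))[late])
    cov <- clamp(cov_true + stats::rnorm(n * nf, 0, cf$noise$cover), 0, 1)
    rs <- clamp(beta_growth_v(tt, cf$rstage$rmax, tm_r[idx], te_r[idx]) +
                  stats::rnorm(n * nf, 0, cf$noise$rstage), 0, 8)
    series[[length(series) + 1L]] <- data.frame(
      plot_id = rep(d$plot_id[idx], 3L),
      thermal_time = rep(tt, 3L),
      variable = rep(c("height", "cover", "rstage"), each = n * nf),
      value = c(pmax(h, 0), cov, rs))
    tf <- cf$thermal_flights
    th <- cf$thermal
    for (j in seq_along(tf)) {
      tc_vals <- th$ta + th$dT_ll + stress * (th$dT_ul - th$dT_ll) +
        stats::rnorm(n, 0, cf$noise$tc)
      thermal[[length(thermal) + 1L]] <- data.frame(
        plot_id = d$plot_id, treatment = d$treatment, year_label = d$year_label,
        flight = j, thermal_time = tf[j], tc = tc_vals, ta = th$ta,
        stress_true = stress)
    }
  }
  list(series = do.call(rbind, series),
       thermal = do.call(rbind, thermal),
       truth = do.call(rbind, truth))
}
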