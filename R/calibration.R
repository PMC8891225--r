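#' Canopy-height drought-index calibration run
#'
#' End-to-end generator calibration check: simulates one pair of full-size
#' fields (454 plots, 359 genotypes each) in which every drought plot has
#' its height asymptote multiplied by \code{wmax_mult}, extracts maximum
#' canopy height from the noisy series by curve fitting, computes genotype
#' BLUPs per treatment with AIC model selection, and returns the mean
#' drought index Yr(CH) over the genotypes present in both treatments.
#' With a multiplier of \code{1 - f} the mean Yr converges to \code{f} as
#' noise decreases.
#'
#' @param seed integer seed for the run (design randomization, effects and
#'   measurement noise all derive from it).
#' @param wmax_mult multiplicative drought effect on the height asymptote.
#' @param height_noise measurement noise sd on canopy height (cm).
#' @return list with \code{mean_yr}, \code{n_common}, \code{h2_control}.
#' @export
ch_drought_calibration <- function(seed, wmax_mult = 0.71, height_noise = 0.5) {
  dc <- build_design(seed = derive_seed(seed, 71), treatment = "control")
  dd <- build_design(seed = derive_seed(seed, 72), treatment = "drought")
  cfg <- default_series_config()
  cfg$treatment_effect$wmax_mult <- wmax_mult
  cfg$noise$height <- height_noise
  sim <- simulate_plot_series(list(dc, dd), cfg, seed = derive_seed(seed, 73))
  ex <- extract_traits(sim$series, variables = "height")
  both <- rbind(as.data.frame(dc), as.data.frame(dd))
  tr <- merge(ex$traits, both[, c("plot_id", "treatment")], by = "plot_id")
  fit_c <- fit_trait_blups(tr[tr$treatment == "control", ], dc, "CH",
                           transform = "none")
  fit_d <- fit_trait_blups(tr[tr$treatment == "drought", ], dd, "CH",
                           transform = "none")
  if (is.null(fit_c) || is.null(fit_d))
    stopf("ch_drought_calibration: BLUP stage failed to converge")
  blups <- rbind(cbind(trait = "CH", treatment = "control", fit_c$blups),
                 cbind(trait = "CH", treatment = "drought", fit_d$blups))
  yt <- yr_table(blups, skip_traits = character(0))
  list(mean_yr = mean(yt$yr, na.rm = TRUE), n_common = yt$n_common[1],
       h2_control = fit_c$fit$h2)
}
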