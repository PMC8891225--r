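#' Extract plot-level traits from time series
#'
#' Fits growth curves per plot and derives the phenology and growth traits:
#' maximum canopy height (CH, the fitted asymptote), maximum absolute
#' growth rate (AGRmax, cm per 100 GDD), thermal time to 75\% canopy cover
#' (CC75), rate of senescence (SNC), thermal times to full flowering (R2)
#' and begin seed (R5) from the fitted R-stage curve, reproductive phase
#' durations (using the field-observed R8 passed through \code{manual}),
#' degree of indeterminacy (DET = te of the height curve minus thermal time
#' to R1), and per-flight crop water stress index (CWSI) when thermal data
#' are supplied. Plots whose fits do not converge get missing traits; they
#' are not dropped here.
#'
#' @param series long data.frame: plot_id, thermal_time, variable
#'   (height/cover/rstage), value.
#' @param manual optional data.frame of manually scored traits, one row per
#'   plot_id (e.g. R8, PLV, PPS, SN, SW); joined onto the output.
#' @param thermal optional data.frame of canopy-temperature flights:
#'   plot_id, treatment, flight, tc, ta.
#' @param baselines "estimate" for per-flight quantile baselines using
#'   control plots as the well-watered reference, or a list with
#'   \code{dT_ll}, \code{dT_ul} applied to every flight.
#' @param variables which series to fit (subset of height, cover, rstage).
#' @param k_tail passed to [snc()].
#' @return list with \code{traits} (one row per plot) and \code{curvefits}
#'   (fitted parameters and convergence flag per plot x variable).
#' @export
extract_traits <- function(series, manual = NULL, thermal = NULL,
                           baselines = "estimate",
                           variables = c("height", "cover", "rstage"),
                           k_tail = 2) {
  plots <- unique(series$plot_id)
  sp <- split(series[, c("thermal_time", "variable", "value")], series$plot_id)
  res <- vector("list", length(plots))
  fits <- vector("list", length(plots))
  for (k in seq_along(plots)) {
    s <- sp[[plots[k]]]
    row <- list(plot_id = plots[k],
                CH = NA_real_, AGRmax = NA_real_, te_height = NA_real_,
                CC75 = NA_real_, SNC = NA_real_,
                R1 = NA_real_, R2 = NA_real_, R5 = NA_real_, DET = NA_real_)
    frows <- list()
    if ("height" %in% variables) {
      h <- s[s$variable == "height", ]
      h <- h[order(h$thermal_time), ]
      fh <- fit_beta_curve(h$thermal_time, h$value)
      if (fh$converged) {
        row$CH <- canopy_height_trait(fh)
        row$AGRmax <- agrmax(fh)
        row$te_height <- fh$te
      }
      frows$height <- fh
    }
    if ("cover" %in% variables) {
      cv <- s[s$variable == "cover", ]
      cv <- cv[order(cv$thermal_time), ]
      if (nrow(cv) >= 4) {
        sm <- stats::runmed(cv$value, 3)
        imax <- which.max(sm)
        fc <- fit_beta_curve(cv$thermal_time[1:imax], cv$value[1:imax],
                             wmax_max = 1.5)
        if (fc$converged) row$CC75 <- cc75(fc)
        frows$cover <- fc
        row$SNC <- snc(cv$value, k_tail = k_tail)
      }
    }
    if ("rstage" %in% variables) {
      rs <- s[s$variable == "rstage", ]
      rs <- rs[order(rs$thermal_time), ]
      fr <- fit_rstage_curve(rs$thermal_time, rs$value)
      row$R1 <- fr$r1; row$R2 <- fr$r2; row$R5 <- fr$r5
      frows$rstage <- fr$fit
    }
    if (is.finite(row$te_height) && is.finite(row$R1))
      row$DET <- det_trait(row$te_height, row$R1)
    res[[k]] <- as.data.frame(row)
    fits[[k]] <- do.call(rbind, lapply(names(frows), function(v) {
      f <- frows[[v]]
      data.frame(plot_id = plots[k], variable = v, wmax = f$wmax, tm = f$tm,
                 te = f$te, rss = f$rss, n_points = f$n_points,
                 converged = f$converged)
    }))
  }
  traits <- do.call(rbind, res)

  if (!is.null(manual)) {
    traits <- merge(traits, manual, by = "plot_id", all.x = TRUE, sort = FALSE)
  }
  if (all(c("R2", "R5", "R8") %in% names(traits))) {
    dur <- durations(traits$R2, traits$R5, traits$R8)
    traits$R2R5 <- dur$r2r5
    traits$R5R8 <- dur$r5r8
    traits$R2R8 <- dur$r2r8
  }
  if (!is.null(thermal)) {
    cw <- compute_cwsi_flights(thermal, baselines)
    traits <- merge(traits, cw, by = "plot_id", all.x = TRUE, sort = FALSE)
  }
  list(traits = traits, curvefits = do.call(rbind, fits))
}

# per-flight CWSI table, wide (one CWSI.<flight> column per flight)
compute_cwsi_flights <- function(thermal, baselines = "estimate") {
  out <- data.frame(plot_id = unique(thermal$plot_id))
  for (fl in sort(unique(thermal$flight))) {
    ti <- thermal[thermal$flight == fl, ]
    dT <- ti$tc - ti$ta
    if (identical(baselines, "estimate")) {
      bl <- estimate_baselines(dT, ti$treatment == "control")
    } else {
      bl <- baselines
    }
    ti_cwsi <- data.frame(plot_id = ti$plot_id,
                          v = cwsi(ti$tc, ti$ta, bl$dT_ll, bl$dT_ul))
    names(ti_cwsi)[2] <- paste0("CWSI.", fl)
    out <- merge(out, ti_cwsi, by = "plot_id", all.x = TRUE, sort = FALSE)
  }
  out
}
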