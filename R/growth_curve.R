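#' Beta growth function
#'
#' Determinate growth curve used for canopy height, canopy cover and
#' reproductive-stage progression on a thermal-time axis. The curve rises
#' from 0 at \code{t = 0} to the asymptote \code{wmax} at \code{t = te},
#' with the maximum growth rate attained at \code{t = tm}, and stays at
#' \code{wmax} beyond \code{te}:
#' \deqn{w(t) = w_{max}\left(1 + \frac{t_e - t}{t_e - t_m}\right)
#'   \left(\frac{t}{t_e}\right)^{t_e/(t_e - t_m)}, \quad 0 \le t \le t_e.}
#'
#' @param t thermal time (GDD, degree C day), may be a vector.
#' @param wmax asymptote (trait units).
#' @param tm thermal time of maximum growth rate; \code{0 < tm < te}.
#' @param te thermal time at which the asymptote is reached.
#' @return growth curve value(s), same length as \code{t}.
#' @export
beta_growth <- function(t, wmax, tm, te) {
  if (!(te > tm && tm > 0)) stopf("beta_growth requires 0 < tm < te (got tm=%g, te=%g)", tm, te)
  w <- numeric(length(t))
  lo <- t <= 0
  hi <- t >= te
  mid <- !lo & !hi
  w[hi] <- wmax
  if (any(mid)) {
    tt <- t[mid]
    w[mid] <- wmax * (1 + (te - tt) / (te - tm)) * (tt / te)^(te / (te - tm))
  }
  w
}

#' Growth rate of the beta growth function
#'
#' Analytic derivative dw/dt of [beta_growth()]; zero outside \code{(0, te)}.
#'
#' @inheritParams beta_growth
#' @return derivative value(s), trait units per GDD.
#' @export
beta_growth_rate <- function(t, wmax, tm, te) {
  if (!(te > tm && tm > 0)) stopf("beta_growth_rate requires 0 < tm < te")
  d <- numeric(length(t))
  mid <- t > 0 & t < te
  if (any(mid)) {
    tt <- t[mid]
    p <- te / (te - tm)
    # w = wmax * (1 + (te-t)/(te-tm)) * (t/te)^p
    u <- 1 + (te - tt) / (te - tm)
    du <- -1 / (te - tm)
    v <- (tt / te)^p
    dv <- p * (tt / te)^(p - 1) / te
    d[mid] <- wmax * (du * v + u * dv)
  }
  d
}

# elementwise beta growth over vectors of t and parameters (recycled)
beta_growth_v <- function(t, wmax, tm, te) {
  n <- max(length(t), length(wmax), length(tm), length(te))
  t <- rep_len(t, n); wmax <- rep_len(wmax, n)
  tm <- rep_len(tm, n); te <- rep_len(te, n)
  w <- numeric(n)
  hi <- t >= te
  mid <- t > 0 & !hi
  w[hi] <- wmax[hi]
  if (any(mid)) {
    w[mid] <- wmax[mid] * (1 + (te[mid] - t[mid]) / (te[mid] - tm[mid])) *
      (t[mid] / te[mid])^(te[mid] / (te[mid] - tm[mid]))
  }
  w
}

#' Fit the beta growth curve to a plot time series
#'
#' Nonlinear least squares with multistart. Parameters are estimated on the
#' scale (wmax, tm, dte) with \code{te = tm + dte} so the constraint
#' \code{tm < te} is a simple box bound. Three starting values for \code{tm}
#' (0.3/0.5/0.7 of the observed time range) are tried and the lowest-RSS
#' converged fit is returned. Non-convergence is reported through the
#' \code{converged} flag rather than an error, so batch extraction can flag
#' the trait as missing and continue.
#'
#' @param thermal_time increasing vector of observation times (GDD).
#' @param response observed values (height cm, cover fraction, or stage).
#' @param wmax_max upper bound for the asymptote (default 4x max observed).
#' @return an object of class \code{beta_fit}: list with \code{wmax},
#'   \code{tm}, \code{te}, \code{rss}, \code{n_points}, \code{converged}.
#' @export
fit_beta_curve <- function(thermal_time, response, wmax_max = NULL) {
  ok <- is.finite(thermal_time) & is.finite(response)
  tt <- thermal_time[ok]
  y <- response[ok]
  failed <- structure(list(wmax = NA_real_, tm = NA_real_, te = NA_real_,
                           rss = NA_real_, n_points = length(y),
                           converged = FALSE), class = "beta_fit")
  if (length(y) < 4L) return(failed)
  if (is.unsorted(tt, strictly = TRUE)) stopf("thermal_time must be strictly increasing")
  if (max(y) <= 0 || stats::sd(y) == 0) return(failed)

  rng <- max(tt) - min(tt)
  wmax0 <- max(y)
  te0 <- 1.2 * max(tt)
  if (is.null(wmax_max)) wmax_max <- 4 * wmax0
  lower <- c(wmax = 1e-6, tm = 1e-3, dte = 1e-3)
  upper <- c(wmax = wmax_max, tm = 5 * max(tt), dte = 5 * max(tt))

  resid_fn <- function(p) beta_growth_v(tt, p[1], p[2], p[2] + p[3]) - y
  jac_fn <- function(p) beta_jacobian(tt, p[1], p[2], p[3])

  best <- NULL
  for (f in c(0.5, 0.3, 0.7)) {
    tm0 <- min(tt) + f * rng
    dte0 <- max(te0 - tm0, 10)
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = c(wmax = wmax0, tm = tm0, dte = dte0),
        lower = lower, upper = upper, fn = resid_fn, jac = jac_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    rss <- fit$deviance
    if (is.null(best) || rss < best$rss) {
      cf <- fit$par
      best <- list(wmax = unname(cf["wmax"]), tm = unname(cf["tm"]),
                   te = unname(cf["tm"] + cf["dte"]), rss = rss)
    }
    # essentially exact fit: further starts cannot improve
    if (best$rss < 1e-16 * length(y) * wmax0^2) break
  }
  if (is.null(best)) return(failed)
  structure(c(best, list(n_points = length(y), converged = TRUE)),
            class = "beta_fit")
}

# analytic Jacobian of beta_growth residuals in (wmax, tm, dte), te = tm+dte
beta_jacobian <- function(t, wmax, tm, dte) {
  te <- tm + dte
  n <- length(t)
  J <- matrix(0, n, 3)
  hi <- t >= te
  J[hi, 1] <- 1
  mid <- t > 0 & !hi
  if (any(mid)) {
    tt <- t[mid]
    a <- te - tm
    u <- 1 + (te - tt) / a
    p <- te / a
    lv <- p * log(tt / te)
    v <- exp(lv)
    du_tm <- (te - tt) / a^2
    du_te <- (tt - tm) / a^2
    dv_tm <- v * log(tt / te) * te / a^2
    dv_te <- v * (log(tt / te) * (-tm / a^2) - p / te)
    J[mid, 1] <- u * v
    dw_tm <- wmax * (du_tm * v + u * dv_tm)
    dw_te <- wmax * (du_te * v + u * dv_te)
    J[mid, 2] <- dw_tm + dw_te   # tm moves te with it
    J[mid, 3] <- dw_te
  }
  J
}

#' @export
print.beta_fit <- function(x, ...) {
  if (!x$converged) {
    cat("beta growth fit: NOT converged (n =", x$n_points, ")\n")
  } else {
    cat(sprintf("beta growth fit: wmax=%.3f tm=%.1f te=%.1f rss=%.4g (n=%d)\n",
                x$wmax, x$tm, x$te, x$rss, x$n_points))
  }
  invisible(x)
}

check_fit <- function(fit) {
  inherits(fit, "beta_fit") && isTRUE(fit$converged) &&
    is.finite(fit$wmax) && fit$te > fit$tm && fit$tm > 0
}

#' Maximum absolute growth rate (AGRmax)
#'
#' Peak slope of the fitted canopy-height curve, attained at \code{t = tm}.
#' Closed form
#' \deqn{AGR_{max} = w_{max}\,\frac{2t_e - t_m}{t_e(t_e - t_m)}
#'   \left(\frac{t_m}{t_e}\right)^{t_m/(t_e - t_m)},}
#' reported per 100 GDD (cm GDD^-100) to match the conventional trait scale.
#'
#' @param fit a \code{beta_fit} (or list with wmax, tm, te).
#' @return AGRmax in cm per 100 GDD; \code{NA} for non-converged fits.
#' @export
agrmax <- function(fit) {
  if (!check_fit(fit)) {
    if (is.list(fit) && isFALSE(fit$converged)) return(NA_real_)
    stopf("agrmax requires a converged fit with 0 < tm < te")
  }
  with(fit, 100 * wmax * (2 * te - tm) / (te * (te - tm)) * (tm / te)^(tm / (te - tm)))
}

#' Maximum canopy height trait (CH)
#'
#' The asymptote of the fitted height curve.
#' @param fit a \code{beta_fit}.
#' @return CH in cm; \code{NA} if the fit did not converge.
#' @export
canopy_height_trait <- function(fit) {
  if (!check_fit(fit)) return(NA_real_)
  fit$wmax
}

# smallest t in (0, te] with beta_growth(t) = level, by bisection on the
# monotone rising limb; NA if the asymptote never reaches the level
beta_crossing_time <- function(fit, level, tol = 1e-8) {
  if (!check_fit(fit)) return(NA_real_)
  if (fit$wmax < level) return(NA_real_)
  lo <- 0
  hi <- fit$te
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (beta_growth(mid, fit$wmax, fit$tm, fit$te) < level) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Thermal time to 75\% canopy cover (CC75)
#'
#' Smallest thermal time at which the fitted cover curve reaches the target
#' cover fraction, found by bisection on the rising limb. If the fitted
#' asymptote never reaches the target the trait is missing (\code{NA}).
#'
#' @param fit a \code{beta_fit} of canopy cover (0-1 scale).
#' @param target cover fraction, default 0.75.
#' @return thermal time in GDD, or \code{NA}.
#' @export
cc75 <- function(fit, target = 0.75) {
  beta_crossing_time(fit, target)
}

#' Fit the reproductive-stage progression curve
#'
#' Fits the same beta growth family to R-stage scores as a function of
#' thermal time, using only observations scored in stages 1-6 (the early,
#' single-sigmoid part of the developmental trajectory). Thermal times to
#' stages R1, R2 and R5 are read off the fitted curve as level crossings.
#'
#' @param thermal_time observation times (GDD).
#' @param r_scores stage scores; values outside [1, 6] are dropped before
#'   fitting.
#' @return list with \code{fit} (a \code{beta_fit}) and \code{r1},
#'   \code{r2}, \code{r5} crossing times (GDD, \code{NA} when the fitted
#'   asymptote stays below the stage).
#' @export
fit_rstage_curve <- function(thermal_time, r_scores) {
  keep <- is.finite(r_scores) & r_scores >= 1 & r_scores <= 6
  fit <- fit_beta_curve(thermal_time[keep], r_scores[keep], wmax_max = 12)
  list(fit = fit,
       r1 = beta_crossing_time(fit, 1),
       r2 = beta_crossing_time(fit, 2),
       r5 = beta_crossing_time(fit, 5))
}

#' Reproductive phase durations
#'
#' Pairwise thermal-time differences between full flowering (R2), begin seed
#' (R5) and maturity (R8). Missing inputs propagate to the durations that
#' use them.
#'
#' @param r2,r5,r8 thermal times (GDD); vectors recycle as usual.
#' @return data.frame with columns \code{r2r5}, \code{r5r8}, \code{r2r8}.
#' @export
durations <- function(r2, r5, r8) {
  data.frame(r2r5 = r5 - r2, r5r8 = r8 - r5, r2r8 = r8 - r2)
}

#' Degree of indeterminacy (DET)
#'
#' Thermal-time duration of continued height growth after the start of
#' flowering: \code{te} of the height curve minus the thermal time to R1.
#' Can be negative for strongly determinate plots; left unclamped.
#'
#' @param te_height te of the fitted height curve (GDD).
#' @param r1 thermal time to start of flowering (GDD).
#' @return DET in GDD (\code{NA} propagates).
#' @export
det_trait <- function(te_height, r1) {
  te_height - r1
}

#' Rate of senescence (SNC)
#'
#' Difference between the maximum canopy cover and the average of the lowest
#' cover values observed after the maximum, on a 3-point running-median
#' smoothed series, clamped to [0, 1]. Missing when fewer than \code{k_tail}
#' observations follow the maximum.
#'
#' @param cover canopy cover series (0-1), in time order.
#' @param k_tail number of lowest post-peak values averaged (default 2).
#' @return SNC in [0, 1], or \code{NA}.
#' @export
snc <- function(cover, k_tail = 2) {
  cover <- cover[is.finite(cover)]
  n <- length(cover)
  if (n < 3L) return(NA_real_)
  sm <- stats::runmed(cover, 3)
  imax <- which.max(sm)
  tail_vals <- if (imax < n) sm[(imax + 1L):n] else numeric(0)
  if (length(tail_vals) < k_tail) return(NA_real_)
  val <- max(sm) - mean(sort(tail_vals)[seq_len(k_tail)])
  clamp(val, 0, 1)
}
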