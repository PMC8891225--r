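#' Filter plots on seedling emergence
#'
#' Removes plots whose emergence percentage is below the threshold; a plot
#' exactly at the threshold is retained.
#'
#' @param plots data.frame with an \code{emergence_pct} column.
#' @param threshold_pct emergence threshold (default 30).
#' @return list with \code{retained}, \code{removed} (data.frames) and
#'   \code{report} (removal counts per treatment x year where available).
#' @export
filter_emergence <- function(plots, threshold_pct = 30) {
  keep <- !is.na(plots$emergence_pct) & plots$emergence_pct >= threshold_pct
  removed <- plots[!keep, , drop = FALSE]
  rep_by <- intersect(c("treatment", "year_label"), names(plots))
  report <- if (length(rep_by) > 0 && nrow(removed) > 0) {
    stats::aggregate(removed$plot_id, by = removed[rep_by], FUN = length)
  } else {
    data.frame(n_removed = nrow(removed))
  }
  list(retained = plots[keep, , drop = FALSE], removed = removed, report = report)
}

#' Tukey outlier mask
#'
#' Flags values outside the fences Q1 - 1.5 IQR and Q3 + 1.5 IQR, with
#' quartiles by linear interpolation between order statistics
#' (\code{quantile} type 7). Intended to be applied per trait x treatment x
#' season.
#'
#' @param values numeric vector (NA allowed).
#' @return logical vector, TRUE where the value is an outlier (NA values
#'   are FALSE).
#' @export
tukey_clean <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 4L) return(rep(FALSE, length(values)))
  q <- stats::quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  out <- values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
  out & !is.na(out)
}

#' Automatic transformation rule
#'
#' Operationalizes "transform where the distribution requires it" as a
#' skewness rule: if the absolute sample skewness exceeds 1 and the values
#' admit it (min > -1), a log1p transform is applied; otherwise none.
#'
#' @param values numeric vector.
#' @return list with \code{values} (possibly transformed), \code{transform}
#'   ("none" or "log1p").
#' @export
maybe_transform <- function(values) {
  sk <- sample_skewness(values)
  if (is.finite(sk) && abs(sk) > 1) {
    if (min(values, na.rm = TRUE) > -1) {
      return(list(values = log1p(values), transform = "log1p"))
    }
    warning("skewed response but log1p not applicable (values <= -1); no transform")
  }
  list(values = values, transform = "none")
}

#' Candidate mixed-model structures
#'
#' The six random-effect structures considered for each trait. All include
#' Genotype; the spatial part varies over block, row and column effects and
#' their within-block nested versions (the fully crossed base structure is
#' overparameterized when columns are nested in blocks).
#'
#' @return list of six model specs (label + random term names).
#' @export
candidate_models <- function() {
  specs <- list(
    list(label = "G+B", terms = c("Block")),
    list(label = "G+B+R", terms = c("Block", "Row")),
    list(label = "G+B+C(B)", terms = c("Block", "Col-in-Block")),
    list(label = "G+B+R+C(B)", terms = c("Block", "Row", "Col-in-Block")),
    list(label = "G+R+C", terms = c("Row", "Column")),
    list(label = "G+B+R(B)+C(B)", terms = c("Block", "Row-in-Block", "Col-in-Block"))
  )
  lapply(specs, function(s) { s$terms <- c("Genotype", s$terms); s })
}

term_formula <- function(term) {
  switch(term,
         "Genotype" = "(1 | genotype)",
         "Block" = "(1 | block)",
         "Row" = "(1 | field_row)",
         "Column" = "(1 | field_col)",
         "Row-in-Block" = "(1 | block:row)",
         "Col-in-Block" = "(1 | block:column)",
         stopf("unknown model term '%s'", term))
}

#' Fit one REML mixed model
#'
#' Intercept-only fixed part with the spec's random terms, fitted by REML
#' (lme4). Variance components are constrained non-negative by the
#' optimizer's parameterization and may converge to zero. The information
#' criterion used for model choice is \code{-2 loglik_REML + 2 k} with
#' \code{k} = number of variance components (residual included) + 1 for the
#' intercept; the fixed part is identical across candidates so the
#' comparison is valid.
#'
#' @param data data.frame with columns \code{value}, \code{genotype},
#'   \code{block}, \code{row}, \code{column}, \code{field_row},
#'   \code{field_col} (spatial columns only needed when the spec uses them).
#' @param spec one element of [candidate_models()].
#' @return object of class \code{reml_fit}: variance components, REML
#'   log-likelihood, AIC, parameter count, intercept, per-genotype BLUPs
#'   (intercept + predicted genotype effect), broad-sense heritability and
#'   a convergence flag.
#' @export
fit_reml <- function(data, spec) {
  needed <- vapply(spec$terms, function(tm) switch(tm,
    "Genotype" = "genotype", "Block" = "block", "Row" = "field_row",
    "Column" = "field_col", "Row-in-Block" = "row", "Col-in-Block" = "column"),
    character(1))
  for (col in unique(c("value", needed))) {
    if (is.null(data[[col]])) stopf("fit_reml: data lacks column '%s'", col)
  }
  df <- data[is.finite(data$value), , drop = FALSE]
  for (col in setdiff(unique(needed), "value")) df[[col]] <- factor(df[[col]])
  for (tm in spec$terms) {
    col <- needed[[tm]]
    if (nlevels(df[[col]]) < 2L)
      stopf("fit_reml: factor for term '%s' has fewer than 2 levels", tm)
  }
  fml <- stats::as.formula(paste("value ~ 1 +",
                                 paste(vapply(spec$terms, term_formula, ""),
                                       collapse = " + ")))
  conv <- TRUE
  m <- withCallingHandlers(
    tryCatch(fit_lmer_polished(fml, df),
             error = function(e) NULL),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w))) conv <<- FALSE
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  if (is.null(m)) {
    return(structure(list(spec = spec, converged = FALSE), class = "reml_fit"))
  }
  vc <- as.data.frame(lme4::VarCorr(m))
  varcomps <- stats::setNames(vc$vcov, vc$grp)
  ll <- as.numeric(stats::logLik(m, REML = TRUE))
  k <- length(varcomps) + 1L
  inter <- unname(lme4::fixef(m)[1])
  re <- lme4::ranef(m)$genotype
  blups <- stats::setNames(inter + re[, 1], rownames(re))
  vg <- unname(varcomps["genotype"])
  ve <- unname(varcomps["Residual"])
  h2 <- if (is.finite(vg) && vg + ve > 0) vg / (vg + ve) else NA_real_
  structure(list(spec = spec, varcomps = varcomps, loglik_reml = ll,
                 aic = -2 * ll + 2 * k, n_params = k, intercept = inter,
                 genotype_blups = blups, h2 = h2, n_obs = nrow(df),
                 converged = conv),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("REML fit [", x$spec$label, "]: NOT converged\n")
    return(invisible(x))
  }
  cat(sprintf("REML fit [%s]: n=%d, AIC=%.2f, H2=%.3f\n",
              x$spec$label, x$n_obs, x$aic, x$h2))
  print(round(x$varcomps, 4))
  invisible(x)
}

# REML fit via lme4's modular interface with a Newton polish of the
# variance parameters. The derivative-free optimizer stops within ~1e-8 of
# the optimum, which is visible in shrinkage predictions; a few damped
# Newton steps on the profiled REML deviance (central differences) refine
# interior components. Boundary components (theta ~ 0) are left at zero.
fit_lmer_polished <- function(fml, df) {
  ctl <- lme4::lmerControl(calc.derivs = FALSE, optimizer = "bobyqa",
                           optCtrl = list(rhoend = 1e-12))
  lmod <- lme4::lFormula(fml, data = df, REML = TRUE, control = ctl)
  devfun <- do.call(lme4::mkLmerDevfun, lmod)
  opt <- lme4::optimizeLmer(devfun, optimizer = "bobyqa",
                            control = list(rhoend = 1e-12))
  th <- opt$par
  free <- th > 1e-7
  if (any(free)) {
    k <- length(th)
    for (it in 1:4) {
      idx <- which(free)
      h <- pmax(1e-5 * (abs(th) + 0.1), 1e-7)
      f0 <- devfun(th)
      gr <- numeric(length(idx))
      He <- matrix(0, length(idx), length(idx))
      for (a in seq_along(idx)) {
        i <- idx[a]; ei <- rep(0, k); ei[i] <- h[i]
        fp <- devfun(th + ei); fm <- devfun(pmax(th - ei, 0))
        gr[a] <- (fp - fm) / (2 * h[i])
        He[a, a] <- (fp - 2 * f0 + fm) / h[i]^2
        if (a > 1) for (b in seq_len(a - 1)) {
          j <- idx[b]; ej <- rep(0, k); ej[j] <- h[j]
          fpp <- devfun(th + ei + ej); fpm <- devfun(pmax(th + ei - ej, 0))
          fmp <- devfun(pmax(th - ei + ej, 0)); fmm <- devfun(pmax(th - ei - ej, 0))
          He[a, b] <- He[b, a] <- (fpp - fpm - fmp + fmm) / (4 * h[i] * h[j])
        }
      }
      step <- tryCatch(solve(He, gr), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      # keep the polish local: it refines, it does not explore
      cap <- 0.1 * (abs(th[idx]) + 0.1)
      scl <- max(abs(step) / cap, 1)
      step <- step / scl
      cand <- th
      cand[idx] <- pmax(th[idx] - step, 0)
      # near the optimum the deviance improvement drops below float
      # resolution; a provably tiny step is accepted on trust, anything
      # larger must strictly decrease the deviance
      tiny <- max(abs(cand[idx] - th[idx]) / (abs(th[idx]) + 0.1)) < 1e-4
      moved <- FALSE
      if (tiny) {
        th <- cand; moved <- TRUE
      } else {
        for (half in 1:4) {
          if (devfun(cand) < f0) { th <- cand; moved <- TRUE; break }
          cand[idx] <- th[idx] - (th[idx] - cand[idx]) / 2
        }
      }
      if (!moved || max(abs(step)) < 1e-10) break
    }
  }
  opt$par <- th
  opt$fval <- devfun(th)
  lme4::mkMerMod(environment(devfun), opt, lmod$reTrms, fr = lmod$fr)
}

#' Select the best model by AIC
#'
#' Lowest AIC among converged fits; ties broken by fewest parameters, then
#' by candidate order.
#'
#' @param fits list of [fit_reml()] results.
#' @return the chosen \code{reml_fit}.
#' @export
select_model <- function(fits) {
  ok <- which(vapply(fits, function(f) isTRUE(f$converged), logical(1)))
  if (length(ok) == 0) stopf("select_model: no converged fits")
  aics <- vapply(fits[ok], function(f) f$aic, numeric(1))
  ks <- vapply(fits[ok], function(f) f$n_params, numeric(1))
  best <- ok[order(aics, ks, seq_along(ok))[1]]
  fits[[best]]
}

#' Broad-sense heritability and its class
#'
#' \code{H2 = Var(Genotype) / (Var(Genotype) + Var(Residual))}, classed as
#' low (< 0.30), medium (0.30-0.60) or high (> 0.60).
#'
#' @param fit a converged \code{reml_fit}, or a numeric h2 value.
#' @return list with \code{h2} and \code{h2_class}.
#' @export
heritability <- function(fit) {
  h2 <- if (inherits(fit, "reml_fit")) fit$h2 else as.numeric(fit)
  cls <- if (!is.finite(h2)) NA_character_
         else if (h2 < 0.30) "low"
         else if (h2 <= 0.60) "medium"
         else "high"
  list(h2 = h2, h2_class = cls)
}

#' Summary statistics of BLUP values
#'
#' One row for the full collection plus one per growth group: n, min, max,
#' mean, sd and CV\% (100 sd / |mean|).
#'
#' @param fit a converged \code{reml_fit}.
#' @param metadata data.frame mapping \code{genotype_id} to
#'   \code{growth_group}.
#' @param trait,treatment,year labels copied into the output.
#' @return data.frame of summary rows.
#' @export
summarize_blups <- function(fit, metadata, trait = NA, treatment = NA, year = NA) {
  b <- data.frame(genotype_id = names(fit$genotype_blups),
                  blup = unname(fit$genotype_blups))
  b <- merge(b, metadata[, c("genotype_id", "growth_group")], by = "genotype_id")
  h <- heritability(fit)
  one <- function(vals, group) {
    if (length(vals) == 0) return(NULL)
    m <- mean(vals)
    data.frame(trait = trait, treatment = treatment, year = year,
               group = group, n_obs = length(vals), min = min(vals),
               max = max(vals), mean = m, sd = stats::sd(vals),
               cv_pct = if (abs(m) > 0) 100 * stats::sd(vals) / abs(m) else NA_real_,
               h2 = h$h2, h2_class = h$h2_class)
  }
  rows <- c(list(one(b$blup, "all")),
            lapply(1:4, function(g) one(b$blup[b$growth_group == g],
                                        paste0("GP", g))))
  out <- do.call(rbind, rows)
  out$sd[out$n_obs == 1] <- 0
  out$cv_pct[out$n_obs == 1] <- 0
  out
}

#' Clean and model one trait
#'
#' Full per-trait analysis: Tukey outlier removal, automatic transform,
#' fitting of the six candidate structures and AIC selection. The trait
#' values must already be filtered on emergence.
#'
#' @param traits data.frame with \code{plot_id} and the trait column.
#' @param design the matching design table (spatial factors per plot).
#' @param trait name of the trait column.
#' @param transform "auto" to apply [maybe_transform()], "none" to skip.
#' @return list with \code{fit} (selected \code{reml_fit}), \code{blups}
#'   (data.frame genotype_id, blup), \code{n_outliers}, \code{transform},
#'   \code{label} of the chosen structure; or NULL if no model converged.
#' @export
fit_trait_blups <- function(traits, design, trait, transform = "auto") {
  df <- merge(design[, c("plot_id", "genotype_id", "block", "row", "column",
                         "field_row", "field_col")],
              traits[, c("plot_id", trait)], by = "plot_id")
  names(df)[names(df) == trait] <- "value"
  names(df)[names(df) == "genotype_id"] <- "genotype"
  out_mask <- tukey_clean(df$value)
  df$value[out_mask] <- NA_real_
  tr <- "none"
  if (identical(transform, "auto")) {
    mt <- maybe_transform(df$value)
    df$value <- mt$values
    tr <- mt$transform
  }
  if (sum(is.finite(df$value)) < 10) return(NULL)
  fits <- lapply(candidate_models(), function(sp)
    tryCatch(fit_reml(df, sp),
             error = function(e) structure(list(spec = sp, converged = FALSE),
                                           class = "reml_fit")))
  sel <- tryCatch(select_model(fits), error = function(e) NULL)
  if (is.null(sel)) return(NULL)
  list(fit = sel,
       blups = data.frame(genotype_id = names(sel$genotype_blups),
                          blup = unname(sel$genotype_blups)),
       n_outliers = sum(out_mask), transform = tr, label = sel$spec$label)
}
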