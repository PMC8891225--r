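#' Default pipeline configuration
#'
#' Study conditions for the synthetic two-season drought trial: two fields
#' (control, drought) of 454 plots each per season, 359 genotypes, a hot
#' dry season with a short drought treatment (height asymptote reduced 11\%
#' on drought plots) and a cool humid season with a long drought treatment
#' (29\% reduction, stronger yield and senescence effects).
#'
#' @param seed master seed.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    design = list(n_unreplicated = 334,
                  check_classes = list(c(3, 9), c(9, 6), c(13, 3)),
                  grid = c(6, 9), n_blocks = 9),
    weather = list(n_days = 200, latitude = 51, elevation = 10),
    emergence_failure_rate = 0.07,
    series = default_series_config(),
    years = list(
      year1 = list(archetype = "hot_dry", long_drought = FALSE,
                   wmax_mult = 0.89, start_date = "2018-04-01",
                   sowing_dates = c("2018-04-20", "2018-05-02",
                                    "2018-05-08", "2018-05-11")),
      year2 = list(archetype = "cool_humid", long_drought = TRUE,
                   wmax_mult = 0.71, start_date = "2019-04-01",
                   sowing_dates = c("2019-04-19", "2019-04-30",
                                    "2019-05-10", "2019-05-15"))
    ),
    model_traits = c("PLV", "R2", "R5", "R8", "R2R5", "R5R8", "R2R8",
                     "PPS", "SN", "SW", "CC75", "AGRmax", "CH", "DET", "SNC")
  )
}

# per-date visually scored stress traits (drought field only)
score_trait_config <- function() {
  list(
    CW.1 = list(mu = 4.2, sg2 = 0.35, sblock2 = 0.05, srow2 = 0.02,
                scol2 = 0.02, se2 = 0.5, drought_mult = 1),
    CW.2 = list(mu = 5.1, sg2 = 0.35, sblock2 = 0.05, srow2 = 0.02,
                scol2 = 0.02, se2 = 0.5, drought_mult = 1),
    CW.3 = list(mu = 3.0, sg2 = 0.35, sblock2 = 0.05, srow2 = 0.02,
                scol2 = 0.02, se2 = 0.5, drought_mult = 1),
    LSEN.1 = list(mu = 2.8, sg2 = 0.20, sblock2 = 0.03, srow2 = 0.01,
                  scol2 = 0.01, se2 = 0.35, drought_mult = 1),
    LSEN.2 = list(mu = 3.3, sg2 = 0.25, sblock2 = 0.03, srow2 = 0.01,
                  scol2 = 0.01, se2 = 0.35, drought_mult = 1),
    LSEN.3 = list(mu = 4.1, sg2 = 0.35, sblock2 = 0.03, srow2 = 0.01,
                  scol2 = 0.01, se2 = 0.35, drought_mult = 1)
  )
}

#' Simulate a complete two-season trial
#'
#' Builds both fields per season, simulates emergence, weather, manual
#' traits and plot time series with the season's drought-treatment
#' strength.
#'
#' @param config a [default_config()] list.
#' @param seed overrides \code{config$seed} when given.
#' @return list per year: designs (control, drought), weather, effects,
#'   sim (series/thermal/truth).
#' @export
simulate_trial <- function(config = default_config(), seed = NULL) {
  seed <- seed %||% config$seed
  out <- list()
  yi <- 0L
  for (yr in names(config$years)) {
    yi <- yi + 1L
    ycf <- config$years[[yr]]
    sdates <- as.Date(ycf$sowing_dates)
    dcfg <- config$design
    des <- list(
      control = build_design(dcfg$n_unreplicated, dcfg$check_classes,
                             dcfg$grid, dcfg$n_blocks,
                             seed = derive_seed(seed, 10 + yi),
                             treatment = "control", year_label = yr,
                             sowing_dates = sdates),
      drought = build_design(dcfg$n_unreplicated, dcfg$check_classes,
                             dcfg$grid, dcfg$n_blocks,
                             seed = derive_seed(seed, 20 + yi),
                             treatment = "drought", year_label = yr,
                             sowing_dates = sdates))
    des <- lapply(des, simulate_emergence,
                  failure_rate = config$emergence_failure_rate,
                  seed = derive_seed(seed, 30 + yi))
    weather <- simulate_weather(ycf$archetype,
                                start_date = as.Date(ycf$start_date),
                                n_days = config$weather$n_days,
                                seed = derive_seed(seed, 40 + yi),
                                latitude = config$weather$latitude)
    tcfg <- c(default_trait_config(long_drought = isTRUE(ycf$long_drought)),
              score_trait_config())
    eff <- simulate_effects(des, tcfg, seed = derive_seed(seed, 50 + yi))
    # stress scores are only recorded in the drought field
    ctl <- eff$plot_values$treatment == "control"
    for (v in grep("^(CW|LSEN)\\.", names(eff$plot_values), value = TRUE))
      eff$plot_values[[v]][ctl] <- NA_real_
    scfg <- config$series
    scfg$treatment_effect$wmax_mult <- ycf$wmax_mult
    if (isTRUE(ycf$long_drought)) {
      scfg$treatment_effect$senescence_accel <- 220
      scfg$treatment_effect$sen_rate_mult <- 1.8
      scfg$treatment_effect$te_shift <- -90
    }
    sim <- simulate_plot_series(des, scfg, seed = derive_seed(seed, 60 + yi))
    out[[yr]] <- list(designs = des, weather = weather, effects = eff, sim = sim)
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order (simulate, extract, fit, respond,
#' report), writing the stage outputs as CSV files plus a machine-readable
#' run manifest with configuration hash, seed, row counts and file
#' checksums. Identical configuration and seed reproduce identical files.
#'
#' @param config a [default_config()] list, or a path to a YAML file with
#'   the same structure.
#' @param outdir output directory (created if needed).
#' @param stages subset of c("simulate", "extract", "fit", "respond",
#'   "report"); earlier stages must have run in the same call (stage
#'   results are kept in memory).
#' @param seed optional master-seed override.
#' @return the run manifest (invisibly), as a list.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("run"),
                         stages = c("simulate", "extract", "fit", "respond",
                                    "report"),
                         seed = NULL) {
  if (is.character(config)) config <- load_config(config)
  seed <- seed %||% config$seed
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "log.txt")
  cat(sprintf("run started, seed %d\n", seed), file = logf)
  logline <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  counts <- list()

  cfg_file <- file.path(outdir, "config.yaml")
  yaml::write_yaml(config, cfg_file)

  trial <- NULL; traits_all <- NULL; fits_df <- NULL; blups_df <- NULL
  yr_df <- NULL; summary_df <- NULL

  if ("simulate" %in% stages) {
    trial <- simulate_trial(config, seed)
    design_df <- do.call(rbind, lapply(trial, function(y)
      do.call(rbind, lapply(y$designs, as.data.frame))))
    rownames(design_df) <- NULL
    utils::write.csv(design_df, file.path(outdir, "design.csv"), row.names = FALSE)
    weather_df <- do.call(rbind, lapply(names(trial), function(yr)
      cbind(year_label = yr, trial[[yr]]$weather)))
    utils::write.csv(weather_df, file.path(outdir, "weather.csv"), row.names = FALSE)
    series_df <- do.call(rbind, lapply(trial, function(y) y$sim$series))
    utils::write.csv(series_df, file.path(outdir, "series.csv"), row.names = FALSE)
    truth_df <- do.call(rbind, lapply(trial, function(y) y$sim$truth))
    utils::write.csv(truth_df, file.path(outdir, "truth.csv"), row.names = FALSE)
    counts$plots_per_field <- nrow(trial[[1]]$designs$control)
    counts$n_genotypes <- length(unique(design_df$genotype_id))
    logline("simulate: %d plots per field, %d genotypes",
            counts$plots_per_field, counts$n_genotypes)
    # environment tables per year (GP1 sowing cohort)
    env_df <- do.call(rbind, lapply(names(trial), function(yr) {
      ycf <- config$years[[yr]]
      cbind(year_label = yr,
            env_series(trial[[yr]]$weather, as.Date(ycf$sowing_dates[1]),
                       latitude = config$weather$latitude,
                       elevation = config$weather$elevation))
    }))
    utils::write.csv(env_df, file.path(outdir, "env.csv"), row.names = FALSE)
  }

  if ("extract" %in% stages) {
    if (is.null(trial)) stopf("stage 'extract' needs 'simulate' in the same run")
    traits_all <- list(); curvefits <- list(); cwsi_rows <- list()
    for (yr in names(trial)) {
      y <- trial[[yr]]
      manual_cols <- setdiff(names(y$effects$plot_values),
                             c("genotype_id", "growth_group", "treatment",
                               "year_label", "block", "row", "column",
                               "field_row", "field_col"))
      manual <- y$effects$plot_values[, manual_cols]
      ex <- extract_traits(y$sim$series, manual = manual, thermal = y$sim$thermal)
      ex$traits$year_label <- yr
      tr <- merge(ex$traits,
                  do.call(rbind, lapply(y$designs, function(d)
                    d[, c("plot_id", "treatment", "genotype_id",
                          "growth_group", "emergence_pct")])),
                  by = "plot_id")
      traits_all[[yr]] <- tr
      ex$curvefits$year_label <- yr
      curvefits[[yr]] <- ex$curvefits
      th <- y$sim$thermal
      cwsi_rows[[yr]] <- cbind(year_label = yr, th[, c("plot_id", "treatment",
                                                      "flight", "tc", "ta")])
    }
    traits_all <- do.call(rbind, traits_all)
    rownames(traits_all) <- NULL
    utils::write.csv(traits_all, file.path(outdir, "traits.csv"), row.names = FALSE)
    utils::write.csv(do.call(rbind, curvefits),
                     file.path(outdir, "curvefits.csv"), row.names = FALSE)
    utils::write.csv(do.call(rbind, cwsi_rows),
                     file.path(outdir, "cwsi.csv"), row.names = FALSE)
    counts$fits_converged <- sum(do.call(rbind, curvefits)$converged)
    logline("extract: %d plot rows, %d converged curve fits",
            nrow(traits_all), counts$fits_converged)
  }

  if ("fit" %in% stages) {
    if (is.null(traits_all)) stopf("stage 'fit' needs 'extract' in the same run")
    model_traits <- c(config$model_traits,
                      grep("^(CW|LSEN|CWSI)\\.", names(traits_all), value = TRUE))
    model_traits <- intersect(model_traits, names(traits_all))
    fits_df <- list(); blups_df <- list(); summary_df <- list()
    for (yr in names(trial)) {
      for (tmt in c("control", "drought")) {
        d <- trial[[yr]]$designs[[tmt]]
        flt <- filter_emergence(d)
        logline("fit %s/%s: %d plots removed on emergence", yr, tmt,
                nrow(flt$removed))
        tt <- traits_all[traits_all$year_label == yr &
                           traits_all$treatment == tmt &
                           traits_all$plot_id %in% flt$retained$plot_id, ]
        meta <- unique(d[, c("genotype_id", "growth_group")])
        for (tr in model_traits) {
          if (all(is.na(tt[[tr]]))) next
          res <- fit_trait_blups(tt, d, tr)
          if (is.null(res)) { logline("fit %s/%s/%s: no converged model",
                                      yr, tmt, tr); next }
          vc <- res$fit$varcomps
          fits_df[[length(fits_df) + 1L]] <- data.frame(
            trait = tr, treatment = tmt, year = yr, model = res$label,
            transform = res$transform, n_obs = res$fit$n_obs,
            n_outliers = res$n_outliers, aic = res$fit$aic,
            var_genotype = unname(vc["genotype"]),
            var_residual = unname(vc["Residual"]),
            h2 = res$fit$h2, h2_class = heritability(res$fit)$h2_class)
          blups_df[[length(blups_df) + 1L]] <- cbind(
            trait = tr, treatment = tmt, year = yr, res$blups)
          summary_df[[length(summary_df) + 1L]] <-
            summarize_blups(res$fit, meta, trait = tr, treatment = tmt, year = yr)
        }
      }
    }
    fits_df <- do.call(rbind, fits_df)
    blups_df <- do.call(rbind, blups_df)
    summary_df <- do.call(rbind, summary_df)
    utils::write.csv(fits_df, file.path(outdir, "fits.csv"), row.names = FALSE)
    utils::write.csv(blups_df, file.path(outdir, "blups.csv"), row.names = FALSE)
    utils::write.csv(summary_df, file.path(outdir, "summary.csv"), row.names = FALSE)
    counts$models_fitted <- nrow(fits_df)
  }

  if ("respond" %in% stages) {
    if (is.null(blups_df)) stopf("stage 'respond' needs 'fit' in the same run")
    yr_df <- list(); cors <- list(); pca_out <- list()
    for (yr in names(trial)) {
      byr <- blups_df[blups_df$year == yr, ]
      ytab <- tryCatch(yr_table(byr), error = function(e) NULL)
      if (is.null(ytab)) next
      ytab$year <- yr
      yr_df[[yr]] <- ytab
      wide <- function(df, valcol) {
        stats::reshape(df[, c("genotype_id", "trait", valcol)],
                       idvar = "genotype_id", timevar = "trait",
                       direction = "wide")
      }
      wc <- wide(ytab, "control"); names(wc) <- sub("^control\\.", "", names(wc))
      wy <- wide(ytab, "yr"); names(wy) <- sub("^yr\\.", "", names(wy))
      cors[[paste0(yr, "_cd")]] <- cbind(year = yr,
        correlation_between(wc, wide_d <- {
          wd <- wide(ytab, "drought"); names(wd) <- sub("^drought\\.", "", names(wd)); wd
        }, family = "control_vs_drought"))
      cors[[paste0(yr, "_yc")]] <- cbind(year = yr,
        correlation_between(wy, wc, family = "yr_vs_control"))
      # PCA input: Yr traits at the genotype level, max-over-dates CW/LSEN
      pvars <- setdiff(unique(ytab$trait),
                       grep("^CWSI\\.", unique(ytab$trait), value = TRUE))
      cwsi_tr <- grep("^CWSI\\.", unique(ytab$trait), value = TRUE)
      if (length(cwsi_tr) > 0) pvars <- c(pvars, cwsi_tr[length(cwsi_tr)])
      pmat <- wy[, c("genotype_id", intersect(pvars, names(wy))), drop = FALSE]
      for (sv in c("CW", "LSEN")) {
        bsv <- byr[grepl(paste0("^", sv, "\\."), byr$trait) &
                     byr$treatment == "drought", ]
        if (nrow(bsv) > 0) {
          mx <- stats::aggregate(blup ~ genotype_id, data = bsv, FUN = max)
          names(mx)[2] <- sv
          pmat <- merge(pmat, mx, by = "genotype_id", all.x = TRUE)
        }
      }
      red <- reduce_variables(pmat[, -1, drop = FALSE])
      keep <- red$retained
      pca <- tryCatch(pca_biplot(pmat[, c("genotype_id", keep)]),
                      error = function(e) NULL)
      if (!is.null(pca)) {
        pca_out[[yr]] <- pca
        utils::write.csv(data.frame(year = yr, genotype_id = rownames(pca$scores),
                                    pca$scores[, 1:min(4, ncol(pca$scores))]),
                         file.path(outdir, sprintf("pca_scores_%s.csv", yr)),
                         row.names = FALSE)
        utils::write.csv(data.frame(year = yr, variable = rownames(pca$loadings),
                                    pca$loadings[, 1:min(4, ncol(pca$loadings))]),
                         file.path(outdir, sprintf("pca_loadings_%s.csv", yr)),
                         row.names = FALSE)
        utils::write.csv(data.frame(year = yr,
                                    pc = seq_along(pca$var_explained),
                                    var_explained = pca$var_explained,
                                    n_genotypes = pca$n_used),
                         file.path(outdir, sprintf("pca_summary_%s.csv", yr)),
                         row.names = FALSE)
        logline("respond %s: PCA on %d genotypes, %d variables (%d dropped)",
                yr, pca$n_used, length(keep), nrow(red$dropped))
      }
    }
    yr_df <- do.call(rbind, yr_df)
    utils::write.csv(yr_df, file.path(outdir, "yr.csv"), row.names = FALSE)
    utils::write.csv(do.call(rbind, cors), file.path(outdir, "correlations.csv"),
                     row.names = FALSE)
    counts$genotypes_in_yr <- length(unique(yr_df$genotype_id))
  }

  if ("report" %in% stages) {
    if (is.null(summary_df)) stopf("stage 'report' needs 'fit' in the same run")
    rep <- pipeline_report(summary_df, yr_df)
    utils::write.csv(rep$trait_table, file.path(outdir, "report_traits.csv"),
                     row.names = FALSE)
    utils::write.csv(rep$date_table, file.path(outdir, "report_dates.csv"),
                     row.names = FALSE)
    sink(file.path(outdir, "report.txt"))
    cat("Per-trait summary (BLUP scale)\n\n")
    print(rep$trait_table, digits = 4)
    cat("\nPer-date stress traits\n\n")
    print(rep$date_table, digits = 4)
    sink()
  }

  files <- list.files(outdir, pattern = "\\.(csv|txt|yaml)$", full.names = TRUE)
  manifest <- list(
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    stages = stages,
    counts = counts,
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(md5 = unname(tools::md5sum(f)),
           rows = if (grepl("\\.csv$", f)) length(readLines(f)) - 1L else NA))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with the [default_config()] structure; missing
#'   keys are filled from the defaults.
#' @return configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  if (!is.numeric(cfg$seed)) stopf("config: 'seed' must be numeric")
  cfg
}

#' Tabular report of trait and per-date summaries
#'
#' Builds the two standard report tables: one row per trait x treatment x
#' season with n, mean, sd, CV\%, H2 and (where applicable) the mean and sd
#' of the drought index over common genotypes; and one row per date x
#' treatment for the repeatedly scored stress traits (CW, LSEN, CWSI).
#' Yr columns stay empty for PLV and CC75 (scored before the drought
#' period) and DET (a growth-habit trait).
#'
#' @param summary_df output of the fit stage ([summarize_blups()] rows).
#' @param yr_df output of [yr_table()] with a \code{year} column (optional).
#' @return list with \code{trait_table} and \code{date_table} data.frames.
#' @export
pipeline_report <- function(summary_df, yr_df = NULL) {
  allrows <- summary_df[summary_df$group == "all", ]
  dated <- grepl("^(CW|LSEN|CWSI)\\.", allrows$trait)
  no_yr <- c("PLV", "CC75", "DET")
  base <- allrows[!dated, c("trait", "treatment", "year", "n_obs", "mean",
                            "sd", "cv_pct", "h2", "h2_class")]
  base$yr_mean <- NA_real_; base$yr_sd <- NA_real_; base$n_common <- NA_integer_
  if (!is.null(yr_df)) {
    agg <- stats::aggregate(yr ~ trait + year, data = yr_df,
                            FUN = function(v) c(mean(v, na.rm = TRUE),
                                                stats::sd(v, na.rm = TRUE)))
    agg <- data.frame(trait = agg$trait, year = agg$year,
                      yr_mean = agg$yr[, 1], yr_sd = agg$yr[, 2])
    nc <- unique(yr_df[, c("trait", "year", "n_common")])
    for (i in seq_len(nrow(base))) {
      if (base$trait[i] %in% no_yr) next
      j <- which(agg$trait == base$trait[i] & agg$year == base$year[i])
      if (length(j) == 1) {
        base$yr_mean[i] <- agg$yr_mean[j]; base$yr_sd[i] <- agg$yr_sd[j]
        k <- which(nc$trait == base$trait[i] & nc$year == base$year[i])
        if (length(k) == 1) base$n_common[i] <- nc$n_common[k]
      }
    }
  }
  datetab <- allrows[dated, c("trait", "treatment", "year", "n_obs", "mean",
                              "sd", "cv_pct", "h2", "h2_class")]
  if (nrow(datetab) > 0) {
    parts <- strsplit(datetab$trait, ".", fixed = TRUE)
    datetab$date_index <- as.integer(vapply(parts, `[`, "", 2))
    datetab$trait <- vapply(parts, `[`, "", 1)
    datetab <- datetab[order(datetab$trait, datetab$year, datetab$date_index), ]
  }
  rownames(base) <- rownames(datetab) <- NULL
  list(trait_table = base, date_table = datetab)
}
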