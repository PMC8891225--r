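test_that("emergence filtering keeps the boundary and reports removals", {
  p <- data.frame(plot_id = c("a", "b", "c"),
                  emergence_pct = c(29.9, 30, 45),
                  treatment = "control", year_label = "year1")
  f <- filter_emergence(p)
  expect_equal(f$retained$plot_id, c("b", "c"))
  expect_equal(nrow(f$removed), 1)
  all_ok <- filter_emergence(p[p$emergence_pct >= 30, ])
  expect_equal(nrow(all_ok$removed), 0)
  expect_equal(all_ok$retained$plot_id, c("b", "c"))
})

test_that("Tukey fences flag the right points under type-7 quartiles", {
  x <- c(1:9, 100)
  expect_equal(which(tukey_clean(x)), 10L)
  expect_equal(sum(tukey_clean(rep(5, 10))), 0)
  set.seed(1)
  expect_equal(sum(tukey_clean(qnorm(seq(0.05, 0.95, length.out = 40)))), 0)
  expect_equal(tukey_clean(c(1, 2, NA)), rep(FALSE, 3))
})

test_that("the transform rule reacts to skewness only", {
  set.seed(2)
  expect_equal(maybe_transform(rnorm(200))$transform, "none")
  chosen <- vapply(1:20, function(s) {
    set.seed(s)
    maybe_transform(rlnorm(200, 0, 1))$transform
  }, character(1))
  expect_gte(mean(chosen == "log1p"), 0.95)
  set.seed(3)
  skewed_neg <- -rlnorm(100, 2, 1)
  expect_warning(mt <- maybe_transform(skewed_neg), "not applicable")
  expect_equal(mt$transform, "none")
})

test_that("the six candidate structures are valid and distinct", {
  cm <- candidate_models()
  expect_length(cm, 6)
  for (s in cm) {
    expect_true("Genotype" %in% s$terms)
    expect_false(any(duplicated(s$terms)))
    expect_false(all(c("Column", "Col-in-Block") %in% s$terms))
    expect_false(all(c("Row", "Row-in-Block") %in% s$terms))
  }
  keys <- vapply(cm, function(s) paste(sort(s$terms), collapse = "+"), "")
  expect_false(any(duplicated(keys)))
})

test_that("REML matches the closed-form ANOVA oracle on balanced layouts", {
  spec <- list(label = "G", terms = "Genotype")
  for (s in 1:8) {
    g <- sample(5:30, 1)
    # interior instances: at the zero boundary the truncated ANOVA residual
    # and the REML residual are different estimators by construction
    df <- balanced_oneway(g, r = 5, sg2 = runif(1, 0.5, 4), se2 = runif(1, 0.2, 1),
                          seed = 100 + s)
    fit <- fit_reml(df, spec)
    orc <- oneway_oracle(df)
    expect_lt(abs(fit$varcomps[["genotype"]] - orc$sg2), 1e-6)
    expect_lt(abs(fit$varcomps[["Residual"]] - orc$se2), 1e-6)
    expect_lt(max(abs(fit$genotype_blups[names(orc$blups)] - orc$blups)), 1e-8)
    # shrinkage: BLUP spread never exceeds raw mean spread
    raw <- tapply(df$value, df$genotype, mean)
    expect_lte(sd(fit$genotype_blups), sd(raw) + 1e-12)
  }
})

test_that("REML is deterministic and its AIC follows the declared count", {
  df <- balanced_oneway(12, 4, 1.5, 1, seed = 5)
  spec <- list(label = "G", terms = "Genotype")
  f1 <- fit_reml(df, spec)
  f2 <- fit_reml(df, spec)
  expect_identical(f1$varcomps, f2$varcomps)
  expect_identical(f1$genotype_blups, f2$genotype_blups)
  # k = 2 variance components + intercept
  expect_equal(f1$aic, -2 * f1$loglik_reml + 2 * 3)
  expect_error(fit_reml(data.frame(value = 1:5, genotype = "a"), spec),
               "fewer than 2 levels")
})

test_that("a null genotype variance yields near-zero heritability", {
  h2s <- vapply(1:20, function(s) {
    df <- balanced_oneway(25, 4, sg2 = 0, se2 = 1, seed = 400 + s)
    fit_reml(df, list(label = "G", terms = "Genotype"))$h2
  }, numeric(1))
  expect_lt(median(h2s), 0.05)
})

test_that("heritability is invariant to adding a constant to the response", {
  df <- balanced_oneway(20, 4, 2, 1, seed = 9)
  spec <- list(label = "G", terms = "Genotype")
  h1 <- fit_reml(df, spec)$h2
  df$value <- df$value + 1000
  h2 <- fit_reml(df, spec)$h2
  expect_equal(h1, h2, tolerance = 1e-6)
})

test_that("model selection prefers low AIC, then parsimony, then order", {
  mk <- function(aic, k, conv = TRUE)
    structure(list(aic = aic, n_params = k, converged = conv,
                   spec = list(label = paste0("m", aic, "_", k))),
              class = "reml_fit")
  expect_equal(select_model(list(mk(206, 3), mk(210, 4), mk(204, 5)))$aic, 204)
  sel <- select_model(list(mk(204, 4), mk(204, 3)))
  expect_equal(sel$n_params, 3)
  sel2 <- select_model(list(mk(204, 3), mk(204, 3, TRUE)))
  expect_equal(sel2$spec$label, "m204_3")
  expect_error(select_model(list(mk(1, 1, FALSE))), "no converged")
  # AIC arithmetic: loglik -100, 3 parameters
  f <- structure(list(loglik_reml = -100, n_params = 3), class = "reml_fit")
  expect_equal(-2 * f$loglik_reml + 2 * f$n_params, 206)
})

test_that("heritability classes follow the conventional thresholds", {
  expect_equal(heritability(3 / (3 + 1)), list(h2 = 0.75, h2_class = "high"))
  expect_equal(heritability(0), list(h2 = 0, h2_class = "low"))
  expect_equal(heritability(0.5), list(h2 = 0.5, h2_class = "medium"))
  expect_equal(heritability(0.29999), list(h2 = 0.29999, h2_class = "low"))
})

test_that("model selection finds the block structure that generated the data", {
  d <- build_design(n_unreplicated = 60, check_classes = list(c(6, 6)),
                    grid = c(6, 6), n_blocks = 4, seed = 21)
  hits <- vapply(1:12, function(s) {
    eff <- simulate_effects(d, list(
      X = list(mu = 50, sg2 = 4, sblock2 = 6, srow2 = 2, scol2 = 0, se2 = 1)),
      seed = 600 + s)
    df <- eff$plot_values
    names(df)[names(df) == "genotype_id"] <- "genotype"
    names(df)[names(df) == "X"] <- "value"
    fits <- lapply(candidate_models(), function(sp) fit_reml(df, sp))
    "Block" %in% select_model(fits)$spec$terms
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("BLUP summaries report group rows with sane statistics", {
  fit <- structure(list(
    genotype_blups = c(a = 10, b = 10, c = 10, d = 12),
    h2 = 0.5, varcomps = c(genotype = 1, Residual = 1), converged = TRUE),
    class = "reml_fit")
  meta <- data.frame(genotype_id = c("a", "b", "c", "d"),
                     growth_group = c(1, 1, 1, 2))
  s <- summarize_blups(fit, meta, trait = "X", treatment = "control", year = "y1")
  expect_equal(s$cv_pct[s$group == "GP1"], 0)
  expect_equal(s$sd[s$group == "GP2"], 0)     # single-genotype group
  expect_true(all(s$min <= s$mean & s$mean <= s$max))
  expect_equal(s$n_obs[s$group == "all"], 4)
  expect_equal(s$h2_class[1], "medium")
})
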