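# small trial fixtures, generated in code

small_design <- function(seed = 1, treatment = "control", year_label = "year1") {
  build_design(n_unreplicated = 30, check_classes = list(c(2, 3)),
               grid = c(4, 5), n_blocks = 4, seed = seed,
               treatment = treatment, year_label = year_label)
}

small_config <- function(seed = 1) {
  cfg <- default_config(seed)
  cfg$design <- list(n_unreplicated = 30, check_classes = list(c(2, 3)),
                     grid = c(4, 5), n_blocks = 4)
  cfg$weather$n_days <- 170
  cfg$model_traits <- c("PLV", "R8", "SN", "CH", "AGRmax", "SNC", "CC75", "DET")
  cfg
}

# balanced one-way layout: g genotypes x r reps
balanced_oneway <- function(g, r, sg2, se2, seed) {
  set.seed(seed)
  geno <- rep(sprintf("g%03d", seq_len(g)), each = r)
  eff <- rnorm(g, 0, sqrt(sg2))
  data.frame(value = eff[as.integer(factor(geno))] + rnorm(g * r, 0, sqrt(se2)),
             genotype = geno, block = rep(seq_len(r), g))
}

# closed-form ANOVA estimators and BLUPs on a balanced one-way layout
oneway_oracle <- function(df) {
  g <- length(unique(df$genotype))
  r <- nrow(df) / g
  means <- tapply(df$value, df$genotype, mean)
  grand <- mean(df$value)
  msb <- r * sum((means - grand)^2) / (g - 1)
  mse <- sum((df$value - means[df$genotype])^2) / (g * (r - 1))
  sg2 <- max((msb - mse) / r, 0)
  shrink <- if (sg2 + mse / r > 0) sg2 / (sg2 + mse / r) else 0
  list(sg2 = sg2, se2 = mse,
       blups = grand + shrink * (means - grand))
}
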