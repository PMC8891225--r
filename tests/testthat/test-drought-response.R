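test_that("the drought index obeys its definition and sign convention", {
  # worked example at the trial's canopy-height treatment means
  expect_equal(round(drought_index(87.57, 78.00), 2), 0.11)
  expect_equal(drought_index(5, 5), 0)
  expect_equal(drought_index(5, 6), -0.2)   # higher under drought
  expect_equal(drought_index(10, 7.5), 0.25)
  expect_warning(yr <- drought_index(c(10, 0), c(5, 5), floor = 1e-8), "floor")
  expect_true(is.na(yr[2]) && yr[1] == 0.5)
})

test_that("yr_table joins treatments, skips pre-drought traits and errors on disjoint keys", {
  b <- rbind(
    data.frame(trait = "CH", treatment = "control",
               genotype_id = c("a", "b", "c"), blup = c(90, 80, 70)),
    data.frame(trait = "CH", treatment = "drought",
               genotype_id = c("a", "b", "d"), blup = c(63, 56, 10)),
    data.frame(trait = "PLV", treatment = "control",
               genotype_id = c("a", "b"), blup = c(10, 11)),
    data.frame(trait = "PLV", treatment = "drought",
               genotype_id = c("a", "b"), blup = c(10, 11)))
  yt <- yr_table(b)
  expect_setequal(unique(yt$trait), "CH")          # PLV skipped
  expect_equal(yt$n_common, rep(2, 2))             # only a, b shared
  expect_equal(yt$yr, c(0.3, 0.3))
  # identical treatments give all-zero Yr
  b2 <- b[b$trait == "CH" & b$treatment == "control", ]
  b2d <- b2; b2d$treatment <- "drought"
  yt2 <- yr_table(rbind(b2, b2d))
  expect_true(all(yt2$yr == 0))
  expect_equal(yt2$n_common[1], 3)
  # disjoint genotype sets
  b3 <- b[b$trait == "CH", ]
  b3$genotype_id[b3$treatment == "drought"] <- c("x", "y", "z")
  expect_error(yr_table(b3), "common")
})

test_that("CV of Yr matches a two-pass oracle", {
  expect_equal(cv_of_yr(c(0.1, 0.1, 0.1)), 0)
  set.seed(4)
  v <- rnorm(50, 0.2, 0.05)
  expect_equal(cv_of_yr(v), 100 * sqrt(sum((v - mean(v))^2) / 49) / abs(mean(v)),
               tolerance = 1e-12)
  expect_true(is.na(cv_of_yr(0.5)))
  expect_true(is.na(cv_of_yr(c(-1, 1))))   # zero mean
})

test_that("correlations equal their definition and sit in symmetric matrices", {
  set.seed(5)
  x <- rnorm(40); y <- 2 * x + rnorm(40)
  m <- data.frame(x = x, y = y, z = -x)
  r <- correlation_matrix(m)
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r, t(r))
  expect_equal(r["x", "z"], -1)
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r["x", "y"], brute, tolerance = 1e-12)
  # keyed cross-table version
  a <- data.frame(genotype_id = letters[1:10], T1 = 1:10)
  b <- data.frame(genotype_id = letters[1:10], T1 = 10:1)
  cb <- correlation_between(a, b, family = "f")
  expect_equal(cb$r, -1)
  expect_equal(cb$n, 10)
  # too few pairs is missing
  cb2 <- correlation_between(a[1:2, ], b[1:2, ])
  expect_true(is.na(cb2$r))
})

test_that("variable reduction drops redundant columns deterministically", {
  set.seed(6)
  a <- rnorm(60); b <- rnorm(60)
  m <- data.frame(r2r5 = a, r5r8 = b, r2r8 = a + b, other = rnorm(60))
  # the sum of two components is highly correlated with them jointly, not
  # necessarily pairwise; use an explicit duplicate for the exact case
  dup <- data.frame(v1 = a, v2 = a, v3 = b)
  red <- reduce_variables(dup)
  expect_equal(red$retained, c("v1", "v3"))
  expect_equal(red$dropped$variable, "v2")
  low <- data.frame(x = a, y = b)
  expect_equal(nrow(reduce_variables(low)$dropped), 0)
  # correlated composite is dropped in most random draws
  hits <- vapply(1:20, function(s) {
    set.seed(700 + s)
    p <- rnorm(80); q <- 0.4 * p + rnorm(80, 0, 0.3)
    mm <- data.frame(r2r5 = p, r5r8 = q, r2r8 = p + q)
    "r2r8" %in% reduce_variables(mm)$dropped$variable
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("PCA is a faithful correlation-scaled decomposition", {
  set.seed(8)
  n <- 50
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  x$d <- x$a * 0.5 + rnorm(n, 0, 0.4)
  rownames(x) <- sprintf("g%02d", 1:n)
  p <- pca_biplot(x)
  expect_equal(sum(p$var_explained), 1)
  expect_equal(crossprod(p$loadings), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  # reconstruction with all PCs retained reproduces the standardized input
  z <- scale(as.matrix(x))
  expect_equal(p$scores %*% t(p$loadings), z, tolerance = 1e-8,
               ignore_attr = TRUE)
  # invariance to column order and affine rescaling
  x2 <- x[, c("d", "b", "a", "c")]
  x2$a <- 100 + 7 * x2$a
  p2 <- pca_biplot(x2)
  expect_equal(p$var_explained, p2$var_explained, tolerance = 1e-10)
  # perfectly correlated pair: one component carries everything
  twin <- data.frame(u = x$a, v = 3 * x$a + 2)
  rownames(twin) <- rownames(x)
  pt <- pca_biplot(twin)
  expect_equal(pt$var_explained[1], 1, tolerance = 1e-10)
  # constant column is a named error
  bad <- x; bad$c <- 1
  expect_error(pca_biplot(bad), "'c'")
})
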