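#' Drought index (Yr)
#'
#' \code{Yr = (Control - Drought) / Control}, computed on genotype BLUPs.
#' Yr = 0 means equal value under both treatments, Yr > 0 a lower value
#' under drought, Yr < 0 a higher value under drought. Undefined (missing)
#' when the control value is too close to zero.
#'
#' @param control,drought numeric vectors (recycled).
#' @param floor minimum |control| for the ratio to be defined.
#' @return Yr values, NA where |control| <= floor.
#' @export
drought_index <- function(control, drought, floor = 1e-8) {
  yr <- (control - drought) / control
  bad <- !is.finite(control) | abs(control) <= floor
  if (any(bad, na.rm = TRUE)) {
    yr[bad] <- NA_real_
    warning(sprintf("drought_index: %d control value(s) below floor; Yr set missing",
                    sum(bad, na.rm = TRUE)))
  }
  yr
}

#' Per-genotype drought index table
#'
#' Inner-joins control and drought BLUPs on genotype and computes Yr per
#' genotype and trait. Pre-drought traits (PLV, CC75) and growth-habit
#' traits (DET) are skipped. The zero floor for the control denominator is
#' 1e-6 times the trait's control BLUP standard deviation.
#'
#' @param blups data.frame with columns \code{trait}, \code{treatment}
#'   ("control"/"drought"), \code{genotype_id}, \code{blup} (optionally
#'   \code{year}).
#' @param skip_traits traits for which Yr is not computed.
#' @return data.frame: trait, genotype_id, control, drought, yr, n_common
#'   (count of genotypes present in both treatments for that trait).
#' @export
yr_table <- function(blups, skip_traits = c("PLV", "CC75", "DET")) {
  traits <- setdiff(unique(blups$trait), skip_traits)
  out <- list()
  for (tr in traits) {
    ctl <- blups[blups$trait == tr & blups$treatment == "control", ]
    drt <- blups[blups$trait == tr & blups$treatment == "drought", ]
    if (nrow(ctl) == 0 || nrow(drt) == 0) next
    m <- merge(ctl[, c("genotype_id", "blup")], drt[, c("genotype_id", "blup")],
               by = "genotype_id", suffixes = c("_c", "_d"))
    if (nrow(m) == 0)
      stopf("yr_table: no genotypes common to control and drought for '%s'", tr)
    floor <- 1e-6 * stats::sd(m$blup_c)
    yr <- suppressWarnings(drought_index(m$blup_c, m$blup_d, floor = floor))
    out[[tr]] <- data.frame(trait = tr, genotype_id = m$genotype_id,
                            control = m$blup_c, drought = m$blup_d,
                            yr = yr, n_common = nrow(m))
  }
  if (length(out) == 0) stopf("yr_table: no trait with both treatments present")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Coefficient of variation of drought-index values
#'
#' \code{100 sd / |mean|}; missing when fewer than two values or the mean
#' is numerically zero.
#'
#' @param yr numeric vector of Yr values.
#' @param floor minimum |mean|.
#' @return CV in percent, or NA.
#' @export
cv_of_yr <- function(yr, floor = 1e-12) {
  yr <- yr[is.finite(yr)]
  if (length(yr) < 2L) return(NA_real_)
  m <- mean(yr)
  if (abs(m) <= floor) return(NA_real_)
  100 * stats::sd(yr) / abs(m)
}

#' Pairwise Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlations; entries with fewer than
#' \code{min_pairs} complete pairs are missing.
#'
#' @param x data.frame or matrix of numeric columns.
#' @param min_pairs minimum complete pairs per entry (default 3).
#' @return correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x, min_pairs = 3) {
  x <- as.matrix(x)
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  npair <- crossprod(!is.na(x))
  r[npair < min_pairs] <- NA_real_
  diag(r) <- 1
  r
}

#' Correlation between two keyed trait tables
#'
#' Per-trait Pearson correlation between matched observations of two tables
#' (e.g. control vs drought BLUPs, Yr vs control, season 1 vs season 2),
#' joined on a key column.
#'
#' @param a,b data.frames with the key column plus numeric trait columns.
#' @param key join column (default "genotype_id").
#' @param family label copied into the output.
#' @param min_pairs minimum complete pairs.
#' @return long data.frame: family, trait, r, n.
#' @export
correlation_between <- function(a, b, key = "genotype_id", family = "pair",
                                min_pairs = 3) {
  traits <- intersect(setdiff(names(a), key), setdiff(names(b), key))
  m <- merge(a, b, by = key, suffixes = c("_a", "_b"))
  rows <- lapply(traits, function(tr) {
    xa <- m[[paste0(tr, "_a")]]
    xb <- m[[paste0(tr, "_b")]]
    ok <- is.finite(xa) & is.finite(xb)
    r <- if (sum(ok) >= min_pairs)
      suppressWarnings(stats::cor(xa[ok], xb[ok])) else NA_real_
    data.frame(family = family, trait = tr, r = r, n = sum(ok))
  })
  do.call(rbind, rows)
}

#' Greedy redundancy reduction within variable subsets
#'
#' Within each declared subset (developmental, growth, resistance, yield
#' responses), walks the variables in their declared order and drops any
#' variable whose absolute correlation with an already-retained variable of
#' the same subset reaches the threshold. Deterministic given the ordering.
#'
#' @param x data.frame/matrix of candidate variables (columns).
#' @param subsets named list of character vectors partitioning the columns.
#' @param r_threshold absolute-correlation threshold (default 0.8).
#' @return list with \code{retained} (character vector) and \code{dropped}
#'   (data.frame: variable, because_of, r).
#' @export
reduce_variables <- function(x, subsets = list(all = colnames(x)),
                             r_threshold = 0.8) {
  r <- correlation_matrix(x)
  retained <- character(0)
  dropped <- list()
  for (sub in subsets) {
    kept <- character(0)
    for (v in sub) {
      if (!v %in% colnames(x)) next
      hit <- kept[!is.na(r[v, kept]) & abs(r[v, kept]) >= r_threshold]
      if (length(hit) > 0) {
        dropped[[length(dropped) + 1L]] <- data.frame(
          variable = v, because_of = hit[1], r = r[v, hit[1]])
      } else {
        kept <- c(kept, v)
      }
    }
    retained <- c(retained, kept)
  }
  list(retained = retained,
       dropped = if (length(dropped)) do.call(rbind, dropped)
                 else data.frame(variable = character(0),
                                 because_of = character(0), r = numeric(0)))
}

#' PCA of multi-trait drought responses
#'
#' Complete-case, correlation-scaled principal component analysis (columns
#' centred and scaled to unit variance) of per-genotype drought responses,
#' for biplot display: standardized loadings, genotype scores and variance
#' explained per component.
#'
#' @param x data.frame of numeric variables, rownames (or a genotype_id
#'   column) identifying genotypes.
#' @return object of class \code{trial_pca}: list with \code{scores},
#'   \code{loadings} (orthonormal columns), \code{var_explained}
#'   (fractions summing to 1), \code{sdev}, \code{n_used},
#'   \code{variables}.
#' @export
pca_biplot <- function(x) {
  if (!is.null(x$genotype_id)) {
    rownames(x) <- x$genotype_id
    x$genotype_id <- NULL
  }
  x <- as.data.frame(x)
  cc <- stats::complete.cases(x)
  xc <- x[cc, , drop = FALSE]
  if (nrow(xc) < ncol(xc) + 1)
    stopf("pca_biplot: only %d complete cases for %d variables", nrow(xc), ncol(xc))
  sds <- vapply(xc, stats::sd, numeric(1))
  if (any(sds == 0))
    stopf("pca_biplot: constant column '%s'", names(sds)[sds == 0][1])
  p <- stats::prcomp(xc, center = TRUE, scale. = TRUE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, loadings = p$rotation, var_explained = ve,
                 sdev = p$sdev, n_used = nrow(xc), variables = colnames(xc)),
            class = "trial_pca")
}

#' @export
print.trial_pca <- function(x, ...) {
  cat(sprintf("PCA: %d genotypes x %d variables\n", x$n_used, length(x$variables)))
  cat("variance explained:",
      paste0(sprintf("PC%d %.1f%%", seq_along(x$var_explained),
                     100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}
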