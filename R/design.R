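#' Plot geometry and sowing density per growth group
#'
#' Row spacing, plot area, recommended sowing density and post-thinning
#' plant density for the four earliness groups. Late groups (GP1, GP2) are
#' sown at 0.4 m row spacing and thinned to 60\% of the seeding density;
#' early groups (GP3, GP4) at 0.25 m spacing without thinning.
#'
#' @param growth_group integer vector with values in 1:4.
#' @return data.frame with columns \code{growth_group}, \code{row_spacing}
#'   (m), \code{plot_area} (m2), \code{sowing_density} (seeds m-2),
#'   \code{thinned_density} (plants m-2).
#' @export
plot_geometry <- function(growth_group) {
  if (!all(growth_group %in% 1:4)) stopf("plot_geometry: growth_group must be in 1..4")
  spacing <- c(0.4, 0.4, 0.25, 0.25)
  density <- c(45, 55, 65, 75)
  thinned <- ifelse(1:4 %in% c(1, 2), 0.60 * density, density)
  data.frame(
    growth_group = growth_group,
    row_spacing = spacing[growth_group],
    plot_area = rep(1.20 * 0.75, length(growth_group)),
    sowing_density = density[growth_group],
    thinned_density = thinned[growth_group]
  )
}

# accession table: checks (replicated) first, then unreplicated entries.
# growth groups are cycled 1..4 so every group is represented.
make_accessions <- function(n_unreplicated, check_classes) {
  acc <- list()
  ci <- 0L
  for (cls in check_classes) {
    n_checks <- cls[[1]]
    reps <- cls[[2]]
    if (n_checks < 0 || reps < 1) stopf("check class counts must be non-negative")
    if (n_checks == 0) next
    ids <- sprintf("CHK%d_%02d", reps, seq_len(n_checks))
    acc[[length(acc) + 1L]] <- data.frame(
      genotype_id = ids,
      growth_group = ((ci + seq_len(n_checks) - 1L) %% 4L) + 1L,
      is_check = TRUE, rep_class = reps)
    ci <- ci + n_checks
  }
  if (n_unreplicated > 0) {
    acc[[length(acc) + 1L]] <- data.frame(
      genotype_id = sprintf("G%03d", seq_len(n_unreplicated)),
      growth_group = ((ci + seq_len(n_unreplicated) - 1L) %% 4L) + 1L,
      is_check = FALSE, rep_class = 1L)
  }
  do.call(rbind, acc)
}

#' Build an augmented row-column trial design
#'
#' Lays out one field: replicated check genotypes spread over blocks for
#' spatial connectivity, unreplicated entries filling the remaining cells,
#' with seeded randomization of block assignment and within-block position.
#' The default replication scheme (3 checks x 9 reps, 9 x 6, 13 x 3, 334
#' unreplicated) gives 454 plots of 359 distinct genotypes.
#'
#' @param n_unreplicated number of unreplicated genotypes.
#' @param check_classes list of \code{c(n_checks, reps)} pairs.
#' @param grid \code{c(rows, columns)} available per block.
#' @param n_blocks number of blocks in the field.
#' @param seed integer seed for the randomization.
#' @param treatment "control" or "drought".
#' @param year_label season label.
#' @param sowing_dates Date vector of length 4, sowing date per growth group.
#' @return data.frame of plot records (class \code{trial_design}): plot_id,
#'   genotype_id, growth_group, is_check, rep_class, block, row, column,
#'   field_row, field_col, treatment, year_label, sowing_date, row_spacing,
#'   plot_area, seeds_sown, emergence_pct (NA until simulated).
#' @export
build_design <- function(n_unreplicated = 334,
                         check_classes = list(c(3, 9), c(9, 6), c(13, 3)),
                         grid = c(6, 9), n_blocks = 9, seed = 1,
                         treatment = c("control", "drought"),
                         year_label = "year1",
                         sowing_dates = as.Date(c("2018-04-20", "2018-05-02",
                                                  "2018-05-08", "2018-05-11"))) {
  treatment <- match.arg(treatment)
  rows <- grid[[1]]; cols <- grid[[2]]
  acc <- make_accessions(n_unreplicated, check_classes)
  total <- sum(acc$rep_class)
  capacity <- n_blocks * rows * cols
  if (total > capacity)
    stopf("design capacity exceeded: %d plots requested, %d cells available (%d blocks x %d x %d)",
          total, capacity, n_blocks, rows, cols)
  set.seed(seed)

  cap_left <- rep(rows * cols, n_blocks)
  assign_block <- integer(0)
  assign_geno <- character(0)
  checks <- acc[acc$is_check, , drop = FALSE]
  checks <- checks[order(-checks$rep_class), , drop = FALSE]
  for (i in seq_len(nrow(checks))) {
    r <- checks$rep_class[i]
    open <- which(cap_left > 0)
    if (r <= length(open)) {
      b <- sample(open, r, prob = cap_left[open])
    } else {
      b <- c(rep(open, length.out = r %/% length(open) * length(open)),
             sample(open, r %% length(open)))
    }
    assign_block <- c(assign_block, b)
    assign_geno <- c(assign_geno, rep(checks$genotype_id[i], r))
    for (bb in b) cap_left[bb] <- cap_left[bb] - 1L
  }
  unrep <- acc$genotype_id[!acc$is_check]
  if (length(unrep) > 0) {
    slots <- sample(rep.int(seq_len(n_blocks), cap_left))
    b <- slots[seq_along(unrep)]
    assign_block <- c(assign_block, b)
    assign_geno <- c(assign_geno, sample(unrep))
  }

  # positions within each block
  out <- vector("list", n_blocks)
  block_cols <- ceiling(sqrt(n_blocks))
  for (b in seq_len(n_blocks)) {
    g <- assign_geno[assign_block == b]
    if (length(g) == 0) next
    cells <- sample(rows * cols, length(g))
    r_i <- (cells - 1L) %/% cols + 1L
    c_i <- (cells - 1L) %% cols + 1L
    out[[b]] <- data.frame(genotype_id = g, block = b, row = r_i, column = c_i)
  }
  d <- do.call(rbind, out)
  d <- merge(d, acc, by = "genotype_id", sort = FALSE)
  d <- d[order(d$block, d$row, d$column), ]
  d$plot_id <- sprintf("%s_%s_P%03d", year_label, substr(treatment, 1, 1), seq_len(nrow(d)))
  block_row <- (d$block - 1L) %/% block_cols
  block_col <- (d$block - 1L) %% block_cols
  d$field_row <- block_row * rows + d$row
  d$field_col <- block_col * cols + d$column
  d$treatment <- treatment
  d$year_label <- year_label
  d$sowing_date <- sowing_dates[d$growth_group]
  geom <- plot_geometry(d$growth_group)
  d$row_spacing <- geom$row_spacing
  d$plot_area <- geom$plot_area
  d$seeds_sown <- round(geom$sowing_density * geom$plot_area)
  d$emergence_pct <- NA_real_
  rownames(d) <- NULL
  d <- d[, c("plot_id", "genotype_id", "growth_group", "is_check", "rep_class",
             "block", "row", "column", "field_row", "field_col", "treatment",
             "year_label", "sowing_date", "row_spacing", "plot_area",
             "seeds_sown", "emergence_pct")]
  class(d) <- c("trial_design", "data.frame")
  d
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("trial design: %d plots, %d genotypes (%d checks), %d blocks [%s, %s]\n",
              nrow(x), length(unique(x$genotype_id)),
              length(unique(x$genotype_id[x$is_check])),
              length(unique(x$block)), x$treatment[1], x$year_label[1]))
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Simulate seedling emergence per plot
#'
#' A fraction of plots fail establishment (emergence below 30\%, uniform in
#' [0, 30)); all other plots emerge well (uniform in [60, 100]).
#'
#' @param design a [build_design()] table.
#' @param failure_rate probability of establishment failure, in [0, 1].
#' @param seed integer seed.
#' @return the design with \code{emergence_pct} filled in.
#' @export
simulate_emergence <- function(design, failure_rate = 0.07, seed = 1) {
  if (failure_rate < 0 || failure_rate > 1) stopf("failure_rate must be in [0,1]")
  set.seed(seed)
  n <- nrow(design)
  fail <- stats::runif(n) < failure_rate
  e <- numeric(n)
  e[fail] <- stats::runif(sum(fail), 0, 30 - 1e-9)
  e[!fail] <- stats::runif(sum(!fail), 60, 100)
  design$emergence_pct <- e
  design
}
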