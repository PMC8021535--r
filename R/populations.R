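#' Tabulate populations by region (and diagnosis group)
#'
#' Counts and percentages of the eight marker-combination populations per
#' (group, region) stratum, with percentage = count / all cells in that
#' stratum x 100. Cells with region `"none"` are excluded from the strata
#' and reported in the `n_region_none` attribute. Within any non-empty
#' stratum the eight percentages sum to 100; empty strata report `NA`
#' percentages.
#'
#' @param cells An `imic_classified` data.frame (needs `population` and
#'   `region` columns).
#' @param group Optional vector of diagnosis labels, one per cell (or the
#'   name of a column in `cells`).
#' @return data.frame of class `imic_population_table`: `group` (if any),
#'   `region`, `population`, `count`, `percentage`.
#' @export
tabulate_populations <- function(cells, group = NULL) {
  stopifnot(is.data.frame(cells), !is.null(cells$population),
            !is.null(cells$region))
  if (is.character(group) && length(group) == 1L && !is.null(cells[[group]]))
    group <- cells[[group]]
  grp <- if (is.null(group)) factor(rep("all", nrow(cells)))
         else factor(group)
  keep <- cells$region != "none"
  pop <- factor(cells$population, levels = POPULATION_LEVELS)
  reg <- factor(as.character(cells$region),
                levels = c("epithelium", "lamina_propria"))
  tab <- table(group = grp[keep], region = reg[keep],
               population = pop[keep])
  df <- as.data.frame(tab, responseName = "count")
  totals <- as.data.frame(table(group = grp[keep], region = reg[keep]),
                          responseName = "total")
  df <- merge(df, totals, by = c("group", "region"), sort = FALSE)
  df$percentage <- ifelse(df$total > 0L, 100 * df$count / df$total, NA_real_)
  df <- df[order(df$group, df$region,
                 match(df$population, POPULATION_LEVELS)), ]
  rownames(df) <- NULL
  if (is.null(group)) df$group <- NULL
  attr(df, "n_region_none") <- sum(!keep)
  class(df) <- c("imic_population_table", "data.frame")
  df
}

#' Paired region comparison (Wilcoxon signed rank)
#'
#' Two-sided Wilcoxon signed-rank test of a per-patient metric in
#' epithelium versus lamina propria: exact p-value for n <= 25 pairs
#' (when there are no zero differences or ties), normal approximation
#' beyond. Fewer than 5 pairs triggers a warning; all-zero differences
#' make the test undefined, reported as such.
#'
#' @param epithelium,lamina_propria Paired per-patient values.
#' @return data.frame of class `imic_comparison`: `test`, `statistic`,
#'   `p_value`, `adjustment`, `note`.
#' @export
paired_region_test <- function(epithelium, lamina_propria) {
  stopifnot(length(epithelium) == length(lamina_propria))
  n <- length(epithelium)
  note <- ""
  if (n < 5L) {
    warnf("only %d pairs; exact small-sample p-value used", n)
    note <- "fewer than 5 pairs"
  }
  d <- epithelium - lamina_propria
  if (all(d == 0)) {
    return(structure(
      data.frame(test = "wilcoxon_signed_rank", statistic = NA_real_,
                 p_value = NA_real_, adjustment = "none",
                 note = "all differences zero; test undefined"),
      class = c("imic_comparison", "data.frame")))
  }
  exact <- n <= 25L && !any(d == 0) && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    wilcox.test(epithelium, lamina_propria, paired = TRUE, exact = exact,
                correct = !exact))
  structure(
    data.frame(test = "wilcoxon_signed_rank",
               statistic = unname(wt$statistic), p_value = wt$p.value,
               adjustment = "none", note = note),
    class = c("imic_comparison", "data.frame"))
}

#' Pairwise two-proportion z-tests within a population row
#'
#' For each pair of diagnosis groups, the two-sided pooled-variance
#' two-proportion z-test on the population's counts, Bonferroni-adjusted
#' over the number of pairs in the row. For each significant pair
#' (adjusted p < `alpha`) the group with the larger proportion is flagged,
#' following the column-proportion letter convention.
#'
#' @param counts Named vector of population counts per group.
#' @param totals Named vector of stratum totals per group (same names).
#' @param alpha Significance level applied to adjusted p-values.
#' @return data.frame of class `imic_comparison_set`: one row per pair with
#'   `group1`, `group2`, `statistic` (z), `p_value`, `p_adjusted`,
#'   `m_comparisons`, `larger` (group with the larger proportion, `NA` if
#'   not significant), `note`.
#' @export
pairwise_proportion_tests <- function(counts, totals, alpha = 0.05) {
  stopifnot(length(counts) == length(totals),
            identical(names(counts), names(totals)))
  g <- names(counts) %||% as.character(seq_along(counts))
  if (length(g) < 2L) stopf("need at least 2 groups")
  pairs <- utils::combn(g, 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    n1 <- totals[[g1]]; n2 <- totals[[g2]]
    if (n1 == 0L || n2 == 0L) {
      return(data.frame(group1 = g1, group2 = g2, statistic = NA_real_,
                        p_value = NA_real_, p_adjusted = NA_real_,
                        m_comparisons = m, larger = NA_character_,
                        note = "zero denominator; pair skipped"))
    }
    p1 <- counts[[g1]] / n1; p2 <- counts[[g2]] / n2
    p_pool <- (counts[[g1]] + counts[[g2]]) / (n1 + n2)
    se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
    z <- if (se == 0) 0 else (p1 - p2) / se
    p <- 2 * pnorm(-abs(z))
    p_adj <- min(1, m * p)
    larger <- if (!is.na(p_adj) && p_adj < alpha) {
      if (p1 >= p2) g1 else g2
    } else NA_character_
    data.frame(group1 = g1, group2 = g2, statistic = z, p_value = p,
               p_adjusted = p_adj, m_comparisons = m, larger = larger,
               note = "")
  })
  structure(do.call(rbind, rows),
            class = c("imic_comparison_set", "data.frame"))
}

#' Median and quartiles
#'
#' Summary used for areas, cell counts and densities: median, lower and
#' upper quartile with linear interpolation between order statistics
#' (quantile type 7).
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric `c(median, q1, q3)`.
#' @export
summarize_quartiles <- function(values) {
  stopifnot(length(values) > 0L)
  q <- quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1L], q1 = q[2L], q3 = q[3L])
}

#' Per-region tissue area, cell count and density
#'
#' The region-level summary conventionally reported next to the population
#' table: analyzed tissue area (mm^2), recognized cell count and cell
#' density per region of a run.
#'
#' @param run An `imic_run`.
#' @return data.frame with `region`, `tissue_area_mm2`, `cell_count`,
#'   `cell_density_per_mm2`.
#' @export
region_summary <- function(run) {
  stopifnot(inherits(run, "imic_run"))
  regions <- c("epithelium", "lamina_propria")
  area <- if (!is.null(run$regions)) {
    role <- rasterize_regions(run$regions, run$dim)
    c(sum(role == 1L), sum(role == 2L)) * run$pixel_size_um^2 / 1e6
  } else c(NA_real_, NA_real_)
  cnt <- vapply(regions, function(r) sum(run$cells$region == r), 0L)
  data.frame(region = regions, tissue_area_mm2 = area,
             cell_count = as.integer(cnt),
             cell_density_per_mm2 = cnt / area, row.names = NULL)
}
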