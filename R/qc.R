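#' Isotype-control ROC per channel
#'
#' Compares a marker channel's per-cell mean intensities in patient tissue
#' against the corresponding isotype-control cells via ROC analysis. The
#' AUC is computed by the rank-sum (Mann-Whitney) construction with
#' mid-ranks for ties, tissue as the positive class; the accompanying
#' p-value is the two-sided Mann-Whitney test. AUC is invariant under any
#' strictly increasing transform of the intensities.
#'
#' @param tissue Per-cell intensities from the specifically stained tissue.
#' @param isotype Per-cell intensities from the isotype control.
#' @param channel Optional channel name carried into the result.
#' @return data.frame of class `imic_roc`: `channel`, `auc`, `p_value`,
#'   `n_tissue`, `n_isotype`.
#' @export
isotype_roc <- function(tissue, isotype, channel = NA_character_) {
  tissue <- tissue[!is.na(tissue)]
  isotype <- isotype[!is.na(isotype)]
  if (length(tissue) == 0L || length(isotype) == 0L)
    stopf("both arms must be non-empty for ROC analysis")
  n1 <- length(tissue); n2 <- length(isotype)
  r <- rank(c(tissue, isotype))          # mid-ranks for ties
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  p <- suppressWarnings(wilcox.test(tissue, isotype)$p.value)
  structure(data.frame(channel = channel, auc = auc, p_value = p,
                       n_tissue = n1, n_isotype = n2),
            class = c("imic_roc", "data.frame"))
}

#' Channel-spillover estimate from single-stain runs
#'
#' For each single-immunostained run (one source channel carrying specific
#' signal), the fraction of cells called positive in each of the two
#' off-target channels, using thresholds from the corresponding multiplexed
#' run. With three channels this yields the six source-to-target pairs.
#' Fractions are compared against a configurable bound (default 1%).
#'
#' @param single_runs Named list (names = source channels) of
#'   `imic_classified` cell tables from single-stain runs, each classified
#'   with the multiplexed run's thresholds.
#' @param bound Pass/fail bound on the off-target positive fraction.
#' @return data.frame of class `imic_spillover`: `source`, `target`,
#'   `fraction`, `n_cells`, `pass`.
#' @export
spillover_estimate <- function(single_runs, bound = 0.01) {
  stopifnot(is.list(single_runs),
            all(names(single_runs) %in% CH_MARKERS))
  rows <- list()
  for (src in names(single_runs)) {
    cells <- single_runs[[src]]
    n <- nrow(cells)
    if (n == 0L) stopf("no classified cells in the %s single-stain run", src)
    for (tgt in setdiff(CH_MARKERS, src)) {
      frac <- mean(cells[[paste0("pos_", tgt)]])
      rows[[paste0(src, ".", tgt)]] <-
        data.frame(source = src, target = tgt, fraction = frac,
                   n_cells = n, pass = frac < bound)
    }
  }
  structure(do.call(rbind, c(rows, make.row.names = FALSE)),
            class = c("imic_spillover", "data.frame"))
}

#' ROC curve coordinates
#'
#' The empirical ROC curve of tissue (positive class) versus isotype
#' intensities: one point per distinct threshold, suitable for plain-text
#' export and plotting.
#'
#' @inheritParams isotype_roc
#' @return data.frame with `threshold`, `tpr`, `fpr`, sorted by descending
#'   threshold.
#' @export
roc_curve <- function(tissue, isotype) {
  tissue <- tissue[!is.na(tissue)]; isotype <- isotype[!is.na(isotype)]
  if (length(tissue) == 0L || length(isotype) == 0L)
    stopf("both arms must be non-empty for ROC analysis")
  th <- sort(unique(c(tissue, isotype)), decreasing = TRUE)
  data.frame(threshold = th,
             tpr = vapply(th, function(t) mean(tissue >= t), 0),
             fpr = vapply(th, function(t) mean(isotype >= t), 0))
}
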