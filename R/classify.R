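## The eight marker-combination populations, ordered as conventionally
## tabulated. Names double as lineage names in the phantom generator.
POPULATION_LEVELS <- c("ck_single", "vim_single", "cd_single",
                       "vim_cd_double", "ck_vim_double", "ck_cd_double",
                       "triple_positive", "triple_negative")

#' Human-readable population labels
#'
#' @return Named character vector mapping population codes to display
#'   labels.
#' @export
population_labels <- function() {
  c(ck_single = "Cytokeratin-single positive",
    vim_single = "Vimentin-single positive",
    cd_single = "CD45/CD18-single positive",
    vim_cd_double = "CD45/CD18-vimentin-double positive",
    ck_vim_double = "Cytokeratin-vimentin-double positive",
    ck_cd_double = "Cytokeratin-CD45/CD18-double positive",
    triple_positive = "Triple positive",
    triple_negative = "Triple negative")
}

#' Cell/background ratio
#'
#' The per-cell statistic comparing a cell's mean channel intensity `m`
#' to the sample's background median `b`. Two algebraically linked
#' definitions are supported: the quotient `m / b` (default) and the
#' relative difference `(m - b) / m = 1 - b / m`. They are related by the
#' strictly increasing map `d = 1 - 1/r` for `m, b > 0`, so quantile-based
#' thresholds classify identically under either; the quotient is the
#' default because realized thresholds are conventionally quoted on that
#' scale (values above 1). Domain violations (`b <= 0` for quotient,
#' `m <= 0` for relative difference) yield `NA`; such cells are excluded
#' from threshold estimation and classified negative.
#'
#' @param m Cell mean intensities (vector).
#' @param b Background median (scalar or vector).
#' @param definition `"quotient"` or `"printed_difference"`.
#' @return Numeric vector of ratios, `NA` where the definition's domain is
#'   violated.
#' @export
cell_background_ratio <- function(m, b,
                                  definition = c("quotient",
                                                 "printed_difference")) {
  definition <- match.arg(definition)
  if (definition == "quotient") {
    r <- m / b
    r[b <= 0] <- NA_real_
  } else {
    r <- 1 - b / m
    r[m <= 0] <- NA_real_
  }
  r
}

#' Draw the threshold-estimation sample
#'
#' A simple random sample without replacement of `floor(n * fraction)`
#' cells, pooled across all cells passed in (pool across samples before
#' calling for the pooled mode). Reproducible under `seed`. Cells flagged
#' `excluded` are never sampled.
#'
#' @param cells An `imic_cells` data.frame.
#' @param fraction Sampling fraction in (0, 1].
#' @param seed Integer seed or `NULL`.
#' @return The sampled subset of `cells`.
#' @export
draw_threshold_sample <- function(cells, fraction = 0.30, seed = NULL) {
  stopifnot(is.data.frame(cells))
  if (!(fraction > 0 && fraction <= 1)) stopf("fraction must be in (0, 1]")
  pool <- cells[!(cells$excluded %||% FALSE), , drop = FALSE]
  n <- nrow(pool)
  k <- if (fraction == 1) n else floor(n * fraction)
  if (k < 20L)
    stopf("threshold sample would have %d cells (< 20); CI unreliable", k)
  idx <- with_seed(seed, sample.int(n, k))
  pool[sort(idx), , drop = FALSE]
}

#' Confidence interval for the median ratio
#'
#' Default is the distribution-free order-statistic interval: with
#' `X_(1) <= ... <= X_(n)` the sorted ratios, the interval
#' `(X_(k), X_(n-k+1))` where `k` is the largest integer with
#' `P(Binom(n, 1/2) <= k - 1) <= alpha/2`, guaranteeing coverage at least
#' `level`. The percentile bootstrap over `B` resamples is offered for
#' comparison. Ties are broken by stable sort order. A degenerate sample
#' (all ratios equal) yields a zero-width interval at that value.
#'
#' @param ratios Numeric vector; `NA`s (domain-violating cells) are
#'   dropped.
#' @param level Confidence level.
#' @param method `"order_statistic"` or `"bootstrap"`.
#' @param B Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return Numeric `c(lower, upper)` with attributes `n`, `method` and (for
#'   the order-statistic method) the ranks used.
#' @export
median_ratio_ci <- function(ratios, level = 0.95,
                            method = c("order_statistic", "bootstrap"),
                            B = 2000L, seed = NULL) {
  method <- match.arg(method)
  r <- ratios[!is.na(ratios)]
  n <- length(r)
  if (n < 20L) stopf("need at least 20 ratios for the CI, got %d", n)
  if (diff(range(r)) == 0) {
    out <- c(lower = r[1L], upper = r[1L])
    attr(out, "n") <- n; attr(out, "method") <- method
    return(out)
  }
  alpha <- 1 - level
  if (method == "order_statistic") {
    s <- sort(r, method = "radix")
    k <- 0L
    while (pbinom(k, n, 0.5) <= alpha / 2) k <- k + 1L
    # k is now the largest integer with P(X <= k-1) <= alpha/2
    k_lo <- max(1L, k)
    k_hi <- n - k_lo + 1L
    out <- c(lower = s[k_lo], upper = s[k_hi])
    attr(out, "ranks") <- c(k_lo, k_hi)
  } else {
    meds <- with_seed(seed, {
      vapply(seq_len(B), function(i) median(r[sample.int(n, n, TRUE)]), 0)
    })
    qs <- quantile(meds, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
    out <- c(lower = qs[1L], upper = qs[2L])
  }
  attr(out, "n") <- n
  attr(out, "method") <- method
  out
}

#' Per-channel positivity thresholds
#'
#' For each marker channel: compute the cell/background ratios of the
#' (non-excluded) cells, draw the 30% threshold sample, and set the
#' threshold tau to the upper bound of the 95% CI of the median ratio.
#' A cell is positive in a channel iff its ratio is strictly greater than
#' tau.
#'
#' @param cells An `imic_cells` data.frame.
#' @param background An `imic_background` estimate.
#' @param definition Ratio definition, see [cell_background_ratio()].
#' @param fraction Sampling fraction.
#' @param level CI level.
#' @param ci_method CI method, see [median_ratio_ci()].
#' @param B Bootstrap resamples (bootstrap method only).
#' @param seed Seed for sampling (and bootstrap).
#' @param channels Marker channels to threshold.
#' @return data.frame of class `imic_thresholds`: `channel`, `tau`,
#'   `ci_lower`, `n_sample`, `n_domain_excluded`, `ci_method`.
#' @export
channel_thresholds <- function(cells, background,
                               definition = c("quotient",
                                              "printed_difference"),
                               fraction = 0.30, level = 0.95,
                               ci_method = c("order_statistic", "bootstrap"),
                               B = 2000L, seed = NULL,
                               channels = CH_MARKERS) {
  definition <- match.arg(definition)
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(background, "imic_background"))
  smp <- draw_threshold_sample(cells, fraction, seed)
  rows <- lapply(channels, function(ch) {
    m <- smp[[paste0("mean_", ch)]]
    r <- cell_background_ratio(m, background$median[[ch]], definition)
    ci <- median_ratio_ci(r, level = level, method = ci_method, B = B,
                          seed = seed)
    data.frame(channel = ch, tau = unname(ci["upper"]),
               ci_lower = unname(ci["lower"]),
               n_sample = attr(ci, "n"),
               n_domain_excluded = sum(is.na(r)),
               ci_method = ci_method)
  })
  out <- do.call(rbind, rows)
  attr(out, "definition") <- definition
  attr(out, "level") <- level
  class(out) <- c("imic_thresholds", "data.frame")
  out
}

#' Strict-exceedance positivity call
#'
#' @param ratio Cell/background ratio(s).
#' @param tau Channel threshold.
#' @return Logical; positive iff `ratio > tau` (strict). `NA` ratios
#'   (domain-violating cells) are negative.
#' @export
classify_cell <- function(ratio, tau) {
  out <- ratio > tau
  out[is.na(out)] <- FALSE
  out
}

#' Map a marker triple to its population
#'
#' The bijection from the boolean triple (cytokeratin, vimentin, CD45/CD18)
#' onto the eight populations.
#'
#' @param ck,vim,cd Logical vectors.
#' @return Factor over the eight population levels.
#' @export
assign_population <- function(ck, vim, cd) {
  key <- ck * 4L + vim * 2L + cd * 1L
  map <- c("triple_negative", "cd_single", "vim_single", "vim_cd_double",
           "ck_single", "ck_cd_double", "ck_vim_double", "triple_positive")
  factor(map[key + 1L], levels = POPULATION_LEVELS)
}

#' Classify cells against channel thresholds
#'
#' Adds per-channel ratios and positivity booleans and the population
#' label. Cells flagged `excluded` (empty mask) and domain-violating
#' ratios are classified negative in the affected channels.
#'
#' @param cells An `imic_cells` data.frame.
#' @param thresholds An `imic_thresholds` table.
#' @param background The `imic_background` used for the ratios.
#' @param definition Ratio definition; defaults to the one stored in
#'   `thresholds`.
#' @return `cells` with columns `ratio_<ch>`, `pos_<ch>` and `population`,
#'   class `imic_classified`.
#' @export
classify_cells <- function(cells, thresholds, background,
                           definition = NULL) {
  stopifnot(inherits(thresholds, "imic_thresholds"),
            inherits(background, "imic_background"))
  definition <- definition %||% attr(thresholds, "definition")
  for (i in seq_len(nrow(thresholds))) {
    ch <- thresholds$channel[i]
    r <- cell_background_ratio(cells[[paste0("mean_", ch)]],
                               background$median[[ch]], definition)
    r[cells$excluded] <- NA_real_
    cells[[paste0("ratio_", ch)]] <- r
    cells[[paste0("pos_", ch)]] <- classify_cell(r, thresholds$tau[i])
  }
  cells$population <- assign_population(cells$pos_af488, cells$pos_efluor570,
                                        cells$pos_af594)
  class(cells) <- c("imic_classified", class(cells))
  cells
}
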