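#' Per-cell, per-channel mean intensities
#'
#' One record per gated nucleus: the arithmetic mean of raw pixel values
#' over that channel's grown cell mask, the mask area, the nucleus geometry
#' and the tissue region of the nucleus centroid. Cells with an empty mask
#' in some channel are flagged (`excluded`) and are skipped by threshold
#' estimation and classification downstream.
#'
#' An optional per-channel affine rescale (`normalize`) is provided for
#' completeness but is a no-op by default: the downstream cell/background
#' ratio is invariant to channel scaling, so classification does not depend
#' on it.
#'
#' @param stack An `imic_stack`.
#' @param masks Named list of `imic_cell_masks`, one per marker channel.
#' @param regions Optional `imic_regions` for region assignment.
#' @param nuclei Nucleus geometry: the gated label map or a
#'   [nucleus_records()] data.frame.
#' @param normalize Optional named list `list(channel = c(scale, offset))`
#'   applied as `scale * x + offset` to that channel's intensities.
#' @return data.frame of class `imic_cells` with columns `cell_id`, `x`,
#'   `y`, `nucleus_area_um2`, `region`, and per channel `mean_<ch>`,
#'   `area_<ch>`, plus logical `excluded`.
#' @export
quantify_cells <- function(stack, masks, regions = NULL, nuclei,
                           normalize = NULL) {
  stopifnot(is_image_stack(stack), is.list(masks))
  if (is.matrix(nuclei))
    nuclei <- nucleus_records(nuclei, stack$pixel_size_um)
  out <- data.frame(cell_id = nuclei$label, x = nuclei$x, y = nuclei$y,
                    nucleus_area_um2 = nuclei$area_um2)
  out$region <- if (!is.null(regions)) {
    assign_region(nuclei$x, nuclei$y, regions)
  } else factor(rep("none", nrow(out)), levels = REGION_LEVELS)
  for (ch in names(masks)) {
    mk <- masks[[ch]]
    stopifnot(inherits(mk, "imic_cell_masks"))
    raster <- stack$channels[[ch]]
    tr <- normalize[[ch]]
    if (length(mk$idx)) {
      v <- as.numeric(raster[mk$idx])
      if (!is.null(tr)) v <- tr[1L] * v + (if (length(tr) > 1L) tr[2L] else 0)
      dt <- data.table(lab = mk$label, v = v)
      agg <- dt[, .(m = mean(v), n = .N), keyby = lab]
    } else {
      agg <- data.table(lab = integer(), m = numeric(), n = integer())
    }
    i <- match(out$cell_id, agg$lab)
    out[[paste0("mean_", ch)]] <- agg$m[i]
    out[[paste0("area_", ch)]] <- agg$n[i] * stack$pixel_size_um^2
  }
  mean_cols <- paste0("mean_", names(masks))
  out$excluded <- rowSums(is.na(as.matrix(out[mean_cols]))) > 0L
  if (any(out$excluded))
    msgf("quantify_cells: %d cell(s) with an empty mask flagged and excluded",
         sum(out$excluded))
  class(out) <- c("imic_cells", "data.frame")
  out
}

#' Background estimate per channel
#'
#' The median intensity of the background events from [background_area()],
#' per channel — the `b` of the cell/background ratio.
#'
#' @param bg_events An `imic_background_events` object.
#' @return An object of class `imic_background`: named numeric medians and
#'   the event count.
#' @export
estimate_background <- function(bg_events) {
  stopifnot(inherits(bg_events, "imic_background_events"))
  if (bg_events$n_events == 0L) stopf("no background events")
  med <- vapply(bg_events$events, function(v) {
    if (is.integer(v)) median_int(v) else median(v)
  }, 0)
  structure(list(median = med, n_events = bg_events$n_events),
            class = "imic_background")
}

#' @export
print.imic_background <- function(x, ...) {
  cat(sprintf("<imic_background> %d events; medians: %s\n", x$n_events,
              paste(sprintf("%s=%.1f", names(x$median), x$median),
                    collapse = ", ")))
  invisible(x)
}
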