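#' Nuclear segmentation parameters
#'
#' The DAPI-channel segmentation is the classical smoothing + threshold +
#' watershed family: Gaussian smoothing, a global intensity threshold
#' (Otsu's method or a fixed value), connected components, and a
#' distance-transform watershed that splits touching nuclei. The
#' `remove labels` area gate (40-100 um^2 by default) is applied separately
#' by [remove_labels()].
#'
#' @param intensity_threshold `"otsu"` or a fixed numeric threshold in
#'   camera units.
#' @param smoothing_sigma_um Gaussian smoothing SD; 0 disables smoothing.
#' @param min_split_distance_um Minimum separation of watershed seeds:
#'   distance-map basins whose depth difference is below half this value
#'   are merged, so structures closer than this are not split. 0 disables
#'   watershed splitting (plain connected components).
#' @param area_min_um2,area_max_um2 Default bounds for the nucleus-area gate.
#' @return An object of class `imic_seg_params`.
#' @export
segmentation_params <- function(intensity_threshold = "otsu",
                                smoothing_sigma_um = 0.5,
                                min_split_distance_um = 2,
                                area_min_um2 = 40, area_max_um2 = 100) {
  if (!(identical(intensity_threshold, "otsu") ||
        is_scalar_num(intensity_threshold)))
    stopf("intensity_threshold must be \"otsu\" or a number")
  if (smoothing_sigma_um < 0 || min_split_distance_um < 0)
    stopf("negative segmentation parameter")
  if (!(area_min_um2 > 0 && area_min_um2 < area_max_um2))
    stopf("need 0 < area_min_um2 < area_max_um2")
  structure(list(intensity_threshold = intensity_threshold,
                 smoothing_sigma_um = smoothing_sigma_um,
                 min_split_distance_um = min_split_distance_um,
                 area_min_um2 = area_min_um2, area_max_um2 = area_max_um2),
            class = "imic_seg_params")
}

## Separable Gaussian smoothing; border pixels where the kernel runs off the
## image keep their unsmoothed values.
.smooth_gaussian <- function(x, sigma_px) {
  if (sigma_px <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  y <- stats::filter(x, k, sides = 2)
  y <- t(y)
  y <- stats::filter(y, k, sides = 2)
  y <- t(y)
  y <- matrix(as.numeric(y), nrow(x), ncol(x))
  na <- which(is.na(y))
  y[na] <- x[na]
  y
}

#' Segment nuclei in the DAPI master channel
#'
#' Smooths, thresholds and labels the DAPI raster, then splits touching
#' nuclei with a distance-transform watershed. The watershed runs per
#' connected component on cropped windows, which is equivalent to a global
#' watershed (basins never cross background) and fast on large rasters.
#' A blank raster yields an empty label map, not an error.
#'
#' @param dapi Single-channel intensity matrix (camera units).
#' @param params An `imic_seg_params`.
#' @param pixel_size_um Micrometres per pixel.
#' @return Integer label matrix with attributes `pixel_size_um` and
#'   `threshold` (the realized intensity threshold).
#' @export
segment_nuclei <- function(dapi, params = segmentation_params(),
                           pixel_size_um = DEFAULT_PIXEL_SIZE_UM) {
  stopifnot(is.matrix(dapi), inherits(params, "imic_seg_params"))
  H <- nrow(dapi); W <- ncol(dapi)
  sm <- .smooth_gaussian(dapi, params$smoothing_sigma_um / pixel_size_um)
  thr <- if (identical(params$intensity_threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(sm), range = c(0, INTENSITY_MAX),
                  levels = INTENSITY_MAX + 1L)
  } else params$intensity_threshold
  mask <- sm > thr
  rm(sm)
  if (!any(mask)) {
    out <- matrix(0L, H, W)
    attr(out, "pixel_size_um") <- pixel_size_um
    attr(out, "threshold") <- thr
    return(out)
  }
  storage.mode(mask) <- "integer"
  comp <- EBImage::imageData(EBImage::bwlabel(mask))
  storage.mode(comp) <- "integer"
  if (params$min_split_distance_um <= 0) {
    out <- comp
  } else {
    dm <- EBImage::imageData(EBImage::distmap(mask))
    rm(mask); gc(verbose = FALSE)
    tol <- params$min_split_distance_um / pixel_size_um / 2
    out <- matrix(0L, H, W)
    idx <- which(comp > 0L)
    lab <- comp[idx]
    ri <- (idx - 1L) %% H + 1L
    ci <- (idx - 1L) %/% H + 1L
    rr <- vapply(split(ri, lab), range, integer(2L))
    cc <- vapply(split(ci, lab), range, integer(2L))
    next_lab <- 0L
    for (i in seq_len(ncol(rr))) {
      r1 <- max(1L, rr[1L, i] - 1L); r2 <- min(H, rr[2L, i] + 1L)
      c1 <- max(1L, cc[1L, i] - 1L); c2 <- min(W, cc[2L, i] + 1L)
      sub <- dm[r1:r2, c1:c2] * (comp[r1:r2, c1:c2] == i)
      ws <- EBImage::imageData(
        EBImage::watershed(EBImage::Image(sub), tolerance = tol, ext = 1L))
      sel <- ws > 0
      out[r1:r2, c1:c2][sel] <- as.integer(ws[sel]) + next_lab
      next_lab <- next_lab + as.integer(max(ws))
    }
  }
  attr(out, "pixel_size_um") <- pixel_size_um
  attr(out, "threshold") <- thr
  out
}

#' Remove segmented labels outside an area interval
#'
#' The nucleus-area gate: labels whose area lies outside the closed
#' interval `[area_min_um2, area_max_um2]` are deleted, discarding flawed
#' events such as nuclear conglomerates (too large) and nuclei cut at a
#' marginal sphere segment (too small), so that only biologically plausible
#' nuclei remain. Endpoints are retained (closed interval). Surviving
#' labels keep their ids; the removed labels are reported in the
#' `"removed"` attribute and a message.
#'
#' @param labelmap Integer label matrix (from [segment_nuclei()]).
#' @param area_min_um2,area_max_um2 Gate bounds in um^2; use `c(0, Inf)` to
#'   disable.
#' @param pixel_size_um Micrometres per pixel (taken from the label map's
#'   attribute when present).
#' @return The gated label map with attribute `removed`, a data.frame of
#'   the deleted labels and their areas.
#' @export
remove_labels <- function(labelmap, area_min_um2 = 40, area_max_um2 = 100,
                          pixel_size_um = NULL) {
  pixel_size_um <- pixel_size_um %||% attr(labelmap, "pixel_size_um") %||%
    DEFAULT_PIXEL_SIZE_UM
  stopifnot(is.matrix(labelmap))
  counts <- tabulate(labelmap)
  areas <- counts * pixel_size_um^2
  bad <- which(counts > 0L & (areas < area_min_um2 | areas > area_max_um2))
  if (length(bad)) {
    labelmap[labelmap %in% bad] <- 0L
    msgf("remove_labels: removed %d of %d labels outside [%g, %g] um^2",
         length(bad), sum(counts > 0L), area_min_um2, area_max_um2)
  }
  attr(labelmap, "removed") <- data.frame(label = bad,
                                          area_um2 = areas[bad])
  attr(labelmap, "pixel_size_um") <- pixel_size_um
  labelmap
}

#' Per-label geometry of a nucleus label map
#'
#' @param labelmap Integer label matrix.
#' @param pixel_size_um Micrometres per pixel.
#' @return data.frame with `label`, `area_um2`, centroid `x`, `y` (0-based
#'   pixels) and the bounding box (`xmin`..`ymax`).
#' @export
nucleus_records <- function(labelmap, pixel_size_um = NULL) {
  pixel_size_um <- pixel_size_um %||% attr(labelmap, "pixel_size_um") %||%
    DEFAULT_PIXEL_SIZE_UM
  H <- nrow(labelmap)
  idx <- which(labelmap > 0L)
  if (length(idx) == 0L)
    return(data.frame(label = integer(), area_um2 = numeric(), x = numeric(),
                      y = numeric(), xmin = integer(), xmax = integer(),
                      ymin = integer(), ymax = integer()))
  dt <- data.table(lab = labelmap[idx],
                   y = (idx - 1L) %% H,
                   x = (idx - 1L) %/% H)
  rec <- dt[, .(area_um2 = .N * pixel_size_um^2, x = mean(x), y = mean(y),
                xmin = min(x), xmax = max(x), ymin = min(y), ymax = max(y)),
            keyby = lab]
  out <- as.data.frame(rec)
  names(out)[1L] <- "label"
  out
}

#' Nucleus-free background events
#'
#' Emulates re-running the segmentation with the nuclear parameters set
#' to 0: the complement of all pre-gate nuclear pixels, intersected with the
#' analyzed tissue regions, is tiled into small events whose per-channel
#' intensities form the background sample. Events default to individual
#' pixels; `events = "tile"` aggregates square tiles (mean per tile) to tame
#' noise.
#'
#' @param labelmap Pre-gate label map from [segment_nuclei()] (all nuclear
#'   pixels, including those later removed by the area gate, are excluded
#'   from the background).
#' @param stack The `imic_stack` the label map came from.
#' @param regions Optional `imic_regions`; when given, only pixels inside
#'   epithelium or lamina propria (and outside exclusions) are used.
#' @param events `"pixel"` or `"tile"`.
#' @param tile_um Tile edge length for `events = "tile"`.
#' @return An object of class `imic_background_events`: per-channel numeric
#'   intensity samples plus the event count.
#' @export
background_area <- function(labelmap, stack, regions = NULL,
                            events = c("pixel", "tile"), tile_um = 2) {
  events <- match.arg(events)
  stopifnot(is_image_stack(stack), is.matrix(labelmap))
  d <- stack_dim(stack)
  if (!identical(dim(labelmap), d)) stopf("label map and stack disagree in size")
  bg <- labelmap == 0L
  if (!is.null(regions)) {
    role <- rasterize_regions(regions, d)
    bg <- bg & role > 0L
  }
  idx <- which(bg)
  if (length(idx) == 0L)
    stopf("background unestimable: no nucleus-free pixels in the analyzed area")
  samples <- if (events == "pixel") {
    # keep integer storage: pixel samples can be large on full slides
    lapply(stack$channels, function(ch) ch[idx])
  } else {
    t_px <- max(1L, round(tile_um / stack$pixel_size_um))
    H <- d[1L]
    tile_id <- ((idx - 1L) %% H) %/% t_px +
      (((idx - 1L) %/% H) %/% t_px) * (H %/% t_px + 1L)
    lapply(stack$channels, function(ch) {
      dt <- data.table(t = tile_id, v = as.numeric(ch[idx]))
      dt[, mean(v), keyby = t]$V1
    })
  }
  structure(list(events = samples, n_events = length(samples[[1L]]),
                 mode = events),
            class = "imic_background_events")
}

#' @export
print.imic_background_events <- function(x, ...) {
  cat(sprintf("<imic_background_events> %d %s events, channels: %s\n",
              x$n_events, x$mode, paste(names(x$events), collapse = ", ")))
  invisible(x)
}

#' Read or write a label map as 16-bit single-channel TIFF
#'
#' Label ids are stored as 16-bit grey values, so maps with more than
#' 65535 labels are rejected.
#'
#' @param labelmap Integer label matrix.
#' @param path TIFF file path.
#' @return [read_label_map()] returns an integer matrix;
#'   [write_label_map()] returns `path` invisibly.
#' @export
write_label_map <- function(labelmap, path) {
  stopifnot(is.matrix(labelmap))
  if (max(labelmap) > 65535L)
    stopf("label map has ids beyond the 16-bit range")
  tiff::writeTIFF(labelmap / 65535, path, bits.per.sample = 16L,
                  compression = "deflate")
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}
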