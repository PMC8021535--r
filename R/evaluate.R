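#' Match segmented nuclei to ground truth by IoU
#'
#' Greedy one-to-one matching between truth nuclei and segmented labels:
#' candidate pairs are every (truth, segmented) pair with overlapping
#' pixels; pairs are accepted in decreasing order of intersection-over-
#' union, each truth nucleus and each segmented label at most once, and
#' only if IoU >= `iou_min`.
#'
#' @param labelmap Segmented (typically gated) label map.
#' @param truth Truth object from [generate_phantom()] (or its
#'   `label_map`).
#' @param iou_min Minimum IoU for an accepted match.
#' @return data.frame with `truth_id`, `seg_label`, `iou` (one row per
#'   accepted match) and attribute `n_truth`.
#' @export
match_truth <- function(labelmap, truth, iou_min = 0.5) {
  tl <- if (is.matrix(truth)) truth else truth$label_map
  stopifnot(identical(dim(tl), dim(labelmap)))
  idx <- which(tl > 0L | labelmap > 0L)
  empty <- data.frame(truth_id = integer(), seg_label = integer(),
                      iou = numeric())
  n_truth <- length(setdiff(unique(as.integer(tl)), 0L))
  if (length(idx) == 0L) { attr(empty, "n_truth") <- n_truth; return(empty) }
  dt <- data.table(t = tl[idx], s = labelmap[idx])
  a_t <- dt[t > 0L, .N, keyby = t]
  a_s <- dt[s > 0L, .N, keyby = s]
  inter <- dt[t > 0L & s > 0L, .N, keyby = .(t, s)]
  if (nrow(inter) == 0L) { attr(empty, "n_truth") <- n_truth; return(empty) }
  inter[a_t, at := i.N, on = "t"]
  inter[a_s, as := i.N, on = "s"]
  inter[, iou := N / (at + as - N)]
  setorder(inter, -iou, t, s)
  used_t <- integer(); used_s <- integer()
  keep <- logical(nrow(inter))
  seen_t <- new.env(hash = TRUE); seen_s <- new.env(hash = TRUE)
  for (i in seq_len(nrow(inter))) {
    if (inter$iou[i] < iou_min) break
    kt <- as.character(inter$t[i]); ks <- as.character(inter$s[i])
    if (is.null(seen_t[[kt]]) && is.null(seen_s[[ks]])) {
      keep[i] <- TRUE
      seen_t[[kt]] <- TRUE; seen_s[[ks]] <- TRUE
    }
  }
  out <- data.frame(truth_id = inter$t[keep], seg_label = inter$s[keep],
                    iou = inter$iou[keep])
  attr(out, "n_truth") <- n_truth
  out
}

#' Per-channel classification performance against truth
#'
#' Joins a classified cell table to the phantom truth via [match_truth()]
#' and computes per-channel sensitivity and specificity of the positivity
#' calls, with the truth positivity of a cell defined by its lineage's
#' expression triple.
#'
#' @param run An `imic_run` with a `truth` element (phantom input).
#' @param profiles Lineage profiles used for the phantom.
#' @param iou_min Matching threshold.
#' @return data.frame with one row per marker channel: `channel`,
#'   `sensitivity`, `specificity`, `n_matched`.
#' @export
classification_performance <- function(run, profiles = lineage_profiles(),
                                       iou_min = 0.5) {
  stopifnot(inherits(run, "imic_run"), !is.null(run$truth))
  mm <- match_truth_cells(run)
  truth_cells <- run$truth$cells
  expr <- profiles[, c("cytokeratin", "vimentin", "cd45cd18")]
  rownames(expr) <- profiles$name
  out <- lapply(seq_along(CH_MARKERS), function(k) {
    ch <- CH_MARKERS[k]
    truth_pos <- expr[truth_cells$lineage[mm$truth_row], k]
    called <- run$cells[[paste0("pos_", ch)]][mm$cell_row]
    data.frame(channel = ch,
               sensitivity = mean(called[truth_pos]),
               specificity = mean(!called[!truth_pos]),
               n_matched = length(called))
  })
  do.call(rbind, out)
}

## Match rows of run$cells to rows of run$truth$cells by nucleus centroid
## nearest-neighbour (cheap; phantom nuclei are well separated).
match_truth_cells <- function(run, max_dist_px = NULL) {
  tc <- run$truth$cells
  cc <- run$cells
  if (nrow(tc) == 0L || nrow(cc) == 0L)
    return(data.frame(truth_row = integer(), cell_row = integer()))
  max_dist_px <- max_dist_px %||%
    (sqrt(median(tc$nucleus_area_um2) / pi) / run$pixel_size_um)
  dt_t <- data.table(tx = tc$x, ty = tc$y, trow = seq_len(nrow(tc)))
  # grid-hash nearest neighbour
  cell_px <- max(1, max_dist_px)
  dt_t[, `:=`(gx = floor(tx / cell_px), gy = floor(ty / cell_px))]
  lookup <- split(dt_t$trow, paste(dt_t$gx, dt_t$gy))
  res_t <- integer(nrow(cc)); res_d <- rep(Inf, nrow(cc))
  gx <- floor(cc$x / cell_px); gy <- floor(cc$y / cell_px)
  for (i in seq_len(nrow(cc))) {
    cand <- integer()
    for (dx in -1:1) for (dy in -1:1) {
      key <- paste(gx[i] + dx, gy[i] + dy)
      cand <- c(cand, lookup[[key]])
    }
    if (length(cand)) {
      d2 <- (tc$x[cand] - cc$x[i])^2 + (tc$y[cand] - cc$y[i])^2
      j <- which.min(d2)
      res_t[i] <- cand[j]; res_d[i] <- sqrt(d2[j])
    }
  }
  ok <- res_d <= max_dist_px
  data.frame(truth_row = res_t[ok], cell_row = which(ok))
}
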