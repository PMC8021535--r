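ROLE_LEVELS <- c("epithelium", "lamina_propria", "excluded")
REGION_LEVELS <- c("epithelium", "lamina_propria", "none")

#' Region-of-interest set
#'
#' Named polygons outlining the tissue compartments that are surveyed
#' separately (epithelium, lamina propria) and zones excluded from analysis
#' (artifacts, debris, air bubbles). Vertices are 0-based pixel coordinates
#' `(x, y)`; polygons are simple (non-self-intersecting) and implicitly
#' closed. Excluded polygons take precedence over tissue polygons; among
#' tissue polygons the first one containing a point wins. Points on a
#' polygon boundary count as inside (closed-boundary convention).
#'
#' @param ... Polygons built with [region_polygon()], or a single list of
#'   them.
#' @return An object of class `imic_regions`.
#' @export
region_set <- function(...) {
  polys <- list(...)
  if (length(polys) == 1L && !inherits(polys[[1L]], "imic_polygon") &&
      is.list(polys[[1L]]))
    polys <- polys[[1L]]
  for (p in polys) {
    if (!inherits(p, "imic_polygon"))
      stopf("all elements must be created with region_polygon()")
  }
  structure(polys, class = "imic_regions")
}

#' @rdname region_set
#' @param name Polygon name.
#' @param role One of `"epithelium"`, `"lamina_propria"`, `"excluded"`.
#' @param vertices Numeric matrix with columns `(x, y)`, 0-based pixel
#'   coordinates, at least 3 rows.
#' @export
region_polygon <- function(name, role, vertices) {
  role <- match.arg(role, ROLE_LEVELS)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L || !all(is.finite(vertices)))
    stopf("`vertices` must be a finite n x 2 matrix with n >= 3")
  dimnames(vertices) <- list(NULL, c("x", "y"))
  structure(list(name = name, role = role, vertices = vertices),
            class = "imic_polygon")
}

#' @export
print.imic_regions <- function(x, ...) {
  cat(sprintf("<imic_regions> %d polygon(s)\n", length(x)))
  for (p in x)
    cat(sprintf("  %-20s %-15s %d vertices\n", p$name, p$role,
                nrow(p$vertices)))
  invisible(x)
}

#' Read or write a region set as JSON
#'
#' One record per polygon with `name`, `role` and a vertex list; a plain,
#' diff-able interchange format for manually outlined regions.
#'
#' @param path File path.
#' @param regions An `imic_regions` object.
#' @return [read_regions()] returns an `imic_regions`; [write_regions()]
#'   returns `path` invisibly.
#' @export
read_regions <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE)$regions
  if (is.null(recs)) stopf("%s has no 'regions' records", path)
  polys <- lapply(seq_len(nrow(recs)), function(i) {
    v <- recs$vertices[[i]]
    if (!is.matrix(v)) v <- do.call(rbind, lapply(v, unlist))
    region_polygon(recs$name[[i]], recs$role[[i]], v)
  })
  region_set(polys)
}

#' @rdname read_regions
#' @export
write_regions <- function(regions, path) {
  stopifnot(inherits(regions, "imic_regions"))
  recs <- lapply(unclass(regions), function(p)
    list(name = p$name, role = p$role,
         vertices = lapply(seq_len(nrow(p$vertices)),
                           function(i) unname(p$vertices[i, ]))))
  jsonlite::write_json(list(regions = recs), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

## Vectorized point-in-polygon (crossing number); points on an edge are
## inside. px, py: point coordinates; v: vertex matrix.
.points_in_polygon <- function(px, py, v, eps = 1e-9) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- v[j, 1L]; y1 <- v[j, 2L]; x2 <- v[i, 1L]; y2 <- v[i, 2L]
    # collinear and within the segment's bounding box
    cr <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    tol <- eps * max(1, sqrt(seg_len2))
    on_seg <- abs(cr) <= tol &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    on_edge <- on_edge | on_seg
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside | on_edge
}

#' Assign nucleus centroids to tissue regions
#'
#' Returns the role of the containing tissue polygon, `"none"` for points
#' inside an excluded polygon (exclusions take precedence) or outside every
#' polygon. Cells straddling a boundary are assigned by their nucleus
#' centroid only.
#'
#' @param x,y Point coordinates (0-based pixels); vectors of equal length.
#' @param regions An `imic_regions` object.
#' @return Factor with levels `epithelium`, `lamina_propria`, `none`.
#' @export
assign_region <- function(x, y, regions) {
  stopifnot(inherits(regions, "imic_regions"), length(x) == length(y))
  out <- rep("none", length(x))
  excluded <- rep(FALSE, length(x))
  for (p in unclass(regions)) {
    if (p$role == "excluded")
      excluded <- excluded | .points_in_polygon(x, y, p$vertices)
  }
  for (p in unclass(regions)) {
    if (p$role == "excluded") next
    hit <- out == "none" & !excluded & .points_in_polygon(x, y, p$vertices)
    out[hit] <- p$role
  }
  factor(out, levels = REGION_LEVELS)
}

## Scanline rasterization of one polygon onto pixel centres (0-based integer
## coordinates). Returns linear indices into an nrow x ncol matrix.
.rasterize_polygon <- function(v, nrow_px, ncol_px) {
  ys <- seq.int(max(0, floor(min(v[, 2L]))), min(nrow_px - 1L, ceiling(max(v[, 2L]))))
  if (length(ys) == 0L) return(integer())
  n <- nrow(v)
  idx <- vector("list", length(ys))
  for (k in seq_along(ys)) {
    y <- ys[k]
    xs <- numeric()
    j <- n
    for (i in seq_len(n)) {
      y1 <- v[j, 2L]; y2 <- v[i, 2L]
      if ((y1 > y) != (y2 > y)) {
        xs <- c(xs, v[j, 1L] + (y - y1) * (v[i, 1L] - v[j, 1L]) / (y2 - y1))
      }
      j <- i
    }
    if (length(xs) >= 2L) {
      xs <- sort(xs)
      spans <- matrix(xs[seq_len(2L * (length(xs) %/% 2L))], ncol = 2L,
                      byrow = TRUE)
      cols <- unlist(lapply(seq_len(nrow(spans)), function(s) {
        lo <- max(0L, ceiling(spans[s, 1L]))
        hi <- min(ncol_px - 1L, floor(spans[s, 2L]))
        if (hi < lo) integer() else seq.int(lo, hi)
      }))
      if (length(cols)) idx[[k]] <- (y + 1L) + cols * nrow_px
    }
  }
  unlist(idx) %||% integer()
}

#' Rasterize a region set to a role map
#'
#' Fills polygons onto the pixel grid: 1 = epithelium, 2 = lamina propria,
#' 0 = none. Tissue polygons fill in list order without overwriting each
#' other; excluded polygons then reset their pixels to 0, mirroring the
#' precedence rule of [assign_region()].
#'
#' @param regions An `imic_regions` object.
#' @param dim Image dimensions `c(nrow, ncol)` in pixels.
#' @return Integer matrix of role codes.
#' @export
rasterize_regions <- function(regions, dim) {
  stopifnot(inherits(regions, "imic_regions"), length(dim) == 2L)
  out <- matrix(0L, dim[1L], dim[2L])
  for (p in unclass(regions)) {
    if (p$role == "excluded") next
    code <- match(p$role, ROLE_LEVELS)
    ii <- .rasterize_polygon(p$vertices, dim[1L], dim[2L])
    ii <- ii[out[ii] == 0L]
    out[ii] <- code
  }
  for (p in unclass(regions)) {
    if (p$role != "excluded") next
    out[.rasterize_polygon(p$vertices, dim[1L], dim[2L])] <- 0L
  }
  out
}

#' Physical area of a mask or of polygons
#'
#' Areas are pixel counts converted to square micrometres
#' (`count * pixel_size_um^2`). Polygons are rasterized onto the pixel grid
#' first, so polygon areas and mask areas agree exactly and areas of
#' disjoint regions add.
#'
#' @param x A matrix (non-zero entries form the mask) or an `imic_regions`
#'   object.
#' @param pixel_size_um Micrometres per pixel.
#' @param ... Passed to methods.
#' @return Area in square micrometres.
#' @export
area_um2 <- function(x, pixel_size_um, ...) UseMethod("area_um2")

#' @rdname area_um2
#' @export
area_um2.default <- function(x, pixel_size_um, ...) {
  stopifnot(is.matrix(x) || is.logical(x) || is.numeric(x))
  sum(x != 0) * pixel_size_um^2
}

#' @rdname area_um2
#' @param dim Image dimensions `c(nrow, ncol)` used for rasterization.
#' @param name Optional polygon name(s) to restrict to.
#' @param role Optional role(s) to restrict to.
#' @param apply_exclusions Subtract excluded polygons from the selection.
#' @export
area_um2.imic_regions <- function(x, pixel_size_um, dim, name = NULL,
                                  role = NULL, apply_exclusions = FALSE, ...) {
  sel <- unclass(x)
  if (!is.null(name)) sel <- Filter(function(p) p$name %in% name, sel)
  if (!is.null(role)) sel <- Filter(function(p) p$role %in% role, sel)
  if (length(sel) == 0L) return(0)
  mask <- matrix(FALSE, dim[1L], dim[2L])
  for (p in sel)
    mask[.rasterize_polygon(p$vertices, dim[1L], dim[2L])] <- TRUE
  if (apply_exclusions) {
    for (p in unclass(x))
      if (p$role == "excluded")
        mask[.rasterize_polygon(p$vertices, dim[1L], dim[2L])] <- FALSE
  }
  sum(mask) * pixel_size_um^2
}
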