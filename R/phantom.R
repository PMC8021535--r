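#' Canonical lineage profiles
#'
#' The eight lineage classes defined by the binary triple
#' (cytokeratin, vimentin, CD45/CD18) — one per element of \{0,1\}^3 —
#' with the mean specific signal and its coefficient of variation for every
#' expressed channel. Names use the marker combination
#' (`ck_single` ... `triple_negative`) and double as population labels, so
#' truth lineages map one-to-one onto the populations recovered downstream.
#'
#' @param signal_level Mean specific intensity (camera units) added on the
#'   cytoplasmic mask of an expressing cell.
#' @param signal_cv Coefficient of variation of the per-cell amplitude
#'   (lognormal).
#' @return A data.frame with columns `name`, `cytokeratin`, `vimentin`,
#'   `cd45cd18`, `signal_level`, `signal_cv`.
#' @export
lineage_profiles <- function(signal_level = 2400, signal_cv = 0.35) {
  data.frame(
    name = POPULATION_LEVELS,
    cytokeratin = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
    vimentin    = c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
    cd45cd18    = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    signal_level = signal_level,
    signal_cv = signal_cv,
    stringsAsFactors = FALSE
  )
}

## Group-mean region composition of upper-airway mucosa (fractions of cells
## per lineage in each compartment), normalized to sum exactly to 1.
.default_fractions <- function() {
  epi <- c(ck_single = 66.8333, vim_single = 0.7, cd_single = 0.5333,
           vim_cd_double = 0.4667, ck_vim_double = 1.1667,
           ck_cd_double = 21.6333, triple_positive = 7.5333,
           triple_negative = 1.1333)
  lp <- c(ck_single = 16.4667, vim_single = 15.1667, cd_single = 8.9667,
          vim_cd_double = 30.4, ck_vim_double = 2.9667,
          ck_cd_double = 7.0333, triple_positive = 9.7,
          triple_negative = 9.4)
  list(epithelium = epi / sum(epi), lamina_propria = lp / sum(lp))
}

#' Phantom configuration
#'
#' Parameters of the synthetic 4-channel tissue phantom: a pseudostratified
#' epithelial band over a lamina-propria block, populated with
#' non-overlapping elliptical nuclei whose areas follow a lognormal law,
#' cytoplasmic marker signal on halos around expressing nuclei, diffuse
#' per-channel autofluorescence background, additive Gaussian noise, and a
#' 3x3 marker spillover matrix. Defaults reproduce the tissue statistics the
#' pipeline is calibrated for: 3486 cells/mm^2, median nucleus area
#' 64 um^2, 0.25378 um pixels, 14-bit intensities, sub-1% spillover.
#'
#' @param width_px,height_px Image size in pixels.
#' @param pixel_size_um Micrometres per pixel.
#' @param epithelium_fraction Fraction of image height occupied by the
#'   epithelial band (top of the image).
#' @param cell_density_per_mm2 Target cell density.
#' @param nucleus_area_um2_median,nucleus_area_log_sd Lognormal nucleus-area
#'   law (median in um^2; SD on the log scale).
#' @param lineage_fractions Named list with elements `epithelium` and
#'   `lamina_propria`, each a named vector of fractions over the 8 lineages
#'   summing to 1 (tolerance 1e-9).
#' @param profiles Lineage intensity profiles, see [lineage_profiles()].
#' @param background_level Per-channel diffuse background mean, named over
#'   `dapi, af488, efluor570, af594` (camera units).
#' @param noise_sd Per-channel additive Gaussian noise SD (scalar recycled).
#' @param spillover 3x3 mixing matrix over the marker channels
#'   (rows = observed, cols = source); unit diagonal, off-diagonals in
#'   `[0, 1)`.
#' @param dapi_level Mean nuclear DAPI amplitude; `dapi_cv` its CV.
#' @param dapi_cv See `dapi_level`.
#' @param cytoplasm_width_um Width of the cytoplasmic halo around the
#'   nucleus.
#' @param fibroblast_halo_um Major-axis halo extension for fibroblast-like
#'   lineages (vimentin-positive, cytokeratin-negative), emulating elongated
#'   connective-tissue cells.
#' @param axis_ratio_range Range of the nucleus ellipse axis ratio.
#' @param glands_per_mm2,gland_sd_um Submucosal glands are modeled as
#'   clusters of cytokeratin-expressing cells in the lamina propria: number
#'   of gland centres per mm^2 and the Gaussian scatter of member cells.
#' @param max_place_attempts Rejection-sampling attempts per cell before
#'   placement fails.
#' @param seed Integer seed; the same configuration and seed give
#'   bit-identical phantoms.
#' @return An object of class `imic_phantom_config`.
#' @export
phantom_config <- function(width_px = 1970L, height_px = 1970L,
                           pixel_size_um = DEFAULT_PIXEL_SIZE_UM,
                           epithelium_fraction = 0.15,
                           cell_density_per_mm2 = 3486,
                           nucleus_area_um2_median = 64,
                           nucleus_area_log_sd = 0.09,
                           lineage_fractions = .default_fractions(),
                           profiles = lineage_profiles(),
                           background_level = c(dapi = 100, af488 = 300,
                                                efluor570 = 300, af594 = 300),
                           noise_sd = 50,
                           spillover = diag(3) + 0.005 * (1 - diag(3)),
                           dapi_level = 3000, dapi_cv = 0.2,
                           cytoplasm_width_um = 2,
                           fibroblast_halo_um = 4,
                           axis_ratio_range = c(1, 2.5),
                           glands_per_mm2 = 12, gland_sd_um = 80,
                           max_place_attempts = 200L,
                           seed = 1L) {
  cfg <- list(width_px = as.integer(width_px),
              height_px = as.integer(height_px),
              pixel_size_um = pixel_size_um,
              epithelium_fraction = epithelium_fraction,
              cell_density_per_mm2 = cell_density_per_mm2,
              nucleus_area_um2_median = nucleus_area_um2_median,
              nucleus_area_log_sd = nucleus_area_log_sd,
              lineage_fractions = lineage_fractions,
              profiles = profiles,
              background_level = background_level,
              noise_sd = rep_len(noise_sd, 4L),
              spillover = spillover,
              dapi_level = dapi_level, dapi_cv = dapi_cv,
              cytoplasm_width_um = cytoplasm_width_um,
              fibroblast_halo_um = fibroblast_halo_um,
              axis_ratio_range = axis_ratio_range,
              glands_per_mm2 = glands_per_mm2, gland_sd_um = gland_sd_um,
              max_place_attempts = as.integer(max_place_attempts),
              seed = as.integer(seed))
  names(cfg$noise_sd) <- CH_ALL
  validate_phantom_config(cfg)
  structure(cfg, class = "imic_phantom_config")
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (width_px < 8L || height_px < 8L) stopf("image too small")
    if (pixel_size_um <= 0) stopf("pixel_size_um must be positive")
    if (epithelium_fraction < 0 || epithelium_fraction >= 1)
      stopf("epithelium_fraction must be in [0, 1)")
    if (cell_density_per_mm2 < 0) stopf("negative cell density")
    if (nucleus_area_log_sd < 0) stopf("negative nucleus_area_log_sd")
    if (!setequal(names(lineage_fractions),
                  c("epithelium", "lamina_propria")))
      stopf("lineage_fractions needs elements 'epithelium','lamina_propria'")
    for (rg in names(lineage_fractions)) {
      fr <- lineage_fractions[[rg]]
      if (!setequal(names(fr), POPULATION_LEVELS))
        stopf("lineage_fractions$%s must be named over the 8 lineages", rg)
      if (any(fr < 0)) stopf("negative lineage fraction in %s", rg)
      if (abs(sum(fr) - 1) > 1e-9)
        stopf("lineage fractions in %s sum to %.12f, not 1", rg, sum(fr))
    }
    if (!setequal(names(background_level), CH_ALL))
      stopf("background_level must be named over %s",
            paste(CH_ALL, collapse = ", "))
    if (!identical(dim(spillover), c(3L, 3L)))
      stopf("spillover must be a 3x3 matrix")
    if (any(abs(diag(spillover) - 1) > 1e-12))
      stopf("spillover diagonal must be 1")
    off <- spillover[row(spillover) != col(spillover)]
    if (any(off < 0 | off >= 1)) stopf("spillover off-diagonals must be in [0,1)")
    lvl <- c(background_level, dapi_level, profiles$signal_level)
    if (any(lvl < 0 | lvl > INTENSITY_MAX))
      stopf("intensity levels must lie in [0, %d]", INTENSITY_MAX)
    if (any(profiles$signal_level <= max(background_level[CH_MARKERS])))
      stopf("specific signal_level must exceed the marker background level")
    invisible(NULL)
  })
}

## Pixels of an ellipse centred at (cx, cy) (0-based), semi-axes a >= b in
## px, orientation theta. Returns linear indices into an H x W matrix.
.ellipse_idx <- function(cx, cy, a, b, theta, H, W) {
  r0 <- max(0L, floor(cy - a)); r1 <- min(H - 1L, ceiling(cy + a))
  c0 <- max(0L, floor(cx - a)); c1 <- min(W - 1L, ceiling(cx + a))
  if (r1 < r0 || c1 < c0) return(integer())
  ys <- r0:r1; xs <- c0:c1
  dy <- ys - cy; dx <- xs - cx
  ct <- cos(theta); st <- sin(theta)
  # outer product grids: rows = y, cols = x
  u <- outer(dy * st, dx * ct, "+")     # dx*ct + dy*st
  w <- outer(dy * ct, -dx * st, "+")    # -dx*st + dy*ct
  inside <- (u / a)^2 + (w / b)^2 <= 1
  which(inside) -> k
  if (length(k) == 0L) return(integer())
  ri <- (k - 1L) %% length(ys) + r0 + 1L
  ci <- (k - 1L) %/% length(ys) + c0 + 1L
  ri + (ci - 1L) * H
}

## Shared generator behind the phantom entry points. mode: "full" paints
## every expressed marker; "isotype" paints none; "single" paints only
## `channel`. All random draws are made identically in every mode so the
## nuclear content (and the DAPI channel) is bit-identical across modes for
## one config.
.generate <- function(config, mode = c("full", "isotype", "single"),
                      channel = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "imic_phantom_config"))
  if (mode == "single") {
    if (!channel %in% CH_MARKERS)
      stopf("channel must be one of %s", paste(CH_MARKERS, collapse = ", "))
  }
  cfg <- config
  H <- cfg$height_px; W <- cfg$width_px; px <- cfg$pixel_size_um
  px_area <- px^2
  area_mm2 <- H * W * px_area / 1e6
  h_epi <- round(cfg$epithelium_fraction * H)
  gap_px <- 1.5                      # enforced clearance between nuclei
  halo_px <- cfg$cytoplasm_width_um / px
  fibro_px <- cfg$fibroblast_halo_um / px
  prof <- cfg$profiles
  expr_mat <- as.matrix(prof[, c("cytokeratin", "vimentin", "cd45cd18")])
  rownames(expr_mat) <- prof$name
  S <- cfg$spillover

  truth_lab <- matrix(0L, H, W)
  # painted signal accumulates in camera units (integers): halves the
  # footprint on full-slide rasters at sub-unit rounding cost
  acc <- list(dapi = matrix(0L, H, W), af488 = matrix(0L, H, W),
              efluor570 = matrix(0L, H, W), af594 = matrix(0L, H, W))

  out <- with_seed(cfg$seed, {
    n_cells <- rpois(1L, cfg$cell_density_per_mm2 * area_mm2)
    lp_mm2 <- (H - h_epi) * W * px_area / 1e6
    n_glands <- if (h_epi < H) rpois(1L, cfg$glands_per_mm2 * lp_mm2) else 0L
    gland_x <- runif(n_glands, 0, W - 1)
    gland_y <- runif(n_glands, h_epi, H - 1)
    gland_sd_px <- cfg$gland_sd_um / px

    cells <- vector("list", n_cells)
    placed <- 0L
    epi_frac_area <- h_epi / H
    sdlog_amp <- sqrt(log(1 + prof$signal_cv^2))
    sdlog_dapi <- sqrt(log(1 + cfg$dapi_cv^2))

    for (i in seq_len(n_cells)) {
      region <- if (runif(1) < epi_frac_area) "epithelium" else "lamina_propria"
      lin <- sample.int(8L, 1L, prob = cfg$lineage_fractions[[region]])
      lin_name <- prof$name[lin]
      area_i <- rlnorm(1, log(cfg$nucleus_area_um2_median),
                       cfg$nucleus_area_log_sd)
      q <- runif(1, cfg$axis_ratio_range[1L], cfg$axis_ratio_range[2L])
      b <- sqrt(area_i / px_area / (pi * q)); a <- b * q
      theta <- if (region == "epithelium") pi / 2 + rnorm(1, 0, 0.15)
               else runif(1, 0, pi)
      m <- a + gap_px
      if (region == "epithelium") { ylo <- m; yhi <- h_epi - 1 - m }
      else { ylo <- h_epi + m; yhi <- H - 1 - m }
      xlo <- m; xhi <- W - 1 - m
      if (yhi <= ylo || xhi <= xlo)
        stopf("tissue band too thin for nuclei of ~%.0f um^2", area_i)
      gland_cell <- region == "lamina_propria" &&
        expr_mat[lin, 1L] && n_glands > 0L
      ok <- FALSE
      for (t in seq_len(cfg$max_place_attempts)) {
        if (gland_cell) {
          g <- sample.int(n_glands, 1L)
          cx <- min(max(gland_x[g] + rnorm(1, 0, gland_sd_px), xlo), xhi)
          cy <- min(max(gland_y[g] + rnorm(1, 0, gland_sd_px), ylo), yhi)
        } else {
          cx <- runif(1, xlo, xhi); cy <- runif(1, ylo, yhi)
        }
        test_idx <- .ellipse_idx(cx, cy, a + gap_px, b + gap_px, theta, H, W)
        if (length(test_idx) && !any(truth_lab[test_idx] > 0L)) { ok <- TRUE; break }
      }
      if (!ok)
        stopf(paste0("nucleus placement failed after %d attempts for cell %d;",
                     " achievable density ~%.0f cells/mm^2 of requested %.0f"),
              cfg$max_place_attempts, i, placed / area_mm2,
              cfg$cell_density_per_mm2)
      nuc_idx <- .ellipse_idx(cx, cy, a, b, theta, H, W)
      truth_lab[nuc_idx] <- i
      placed <- placed + 1L

      dapi_amp <- rlnorm(1, log(cfg$dapi_level) - sdlog_dapi^2 / 2, sdlog_dapi)
      amps <- rlnorm(3L, log(prof$signal_level[lin]) - sdlog_amp[lin]^2 / 2,
                     sdlog_amp[lin])
      amps[!expr_mat[lin, ]] <- 0
      if (mode == "isotype") amps[] <- 0
      if (mode == "single") amps[CH_MARKERS != channel] <- 0

      acc$dapi[nuc_idx] <- acc$dapi[nuc_idx] + as.integer(round(dapi_amp))
      if (any(amps > 0)) {
        fibro <- expr_mat[lin, 2L] && !expr_mat[lin, 1L]
        ha <- a + (if (fibro) fibro_px else halo_px)
        hb <- b + (if (fibro) max(1, halo_px / 2) else halo_px)
        halo_idx <- .ellipse_idx(cx, cy, ha, hb, theta, H, W)
        for (s in which(amps > 0)) {
          for (cch in 1:3) {
            inc <- as.integer(round(S[cch, s] * amps[s]))
            if (inc > 0L)
              acc[[CH_MARKERS[cch]]][halo_idx] <-
                acc[[CH_MARKERS[cch]]][halo_idx] + inc
          }
        }
      }
      # truth geometry from the painted pixels
      ri <- (nuc_idx - 1L) %% H; ci <- (nuc_idx - 1L) %/% H
      cells[[i]] <- list(id = i, x = mean(ci), y = mean(ri),
                         nucleus_area_um2 = length(nuc_idx) * px_area,
                         lineage = lin_name)
      if (i %% 2000L == 0L) gc(verbose = FALSE)  # cap heap growth on big rasters
    }

    channels <- vector("list", 4L)
    names(channels) <- CH_ALL
    for (ch in CH_ALL) {
      v <- acc[[ch]] + cfg$background_level[[ch]] +
        rnorm(H * W, 0, cfg$noise_sd[[ch]])
      acc[[ch]] <- NULL
      channels[[ch]] <- clip14(v)
      rm(v); gc(verbose = FALSE)
    }
    list(cells = cells, channels = channels)
  })

  cells_df <- if (length(out$cells)) {
    df <- data.frame(
      id = vapply(out$cells, `[[`, 0L, "id"),
      x = vapply(out$cells, `[[`, 0, "x"),
      y = vapply(out$cells, `[[`, 0, "y"),
      nucleus_area_um2 = vapply(out$cells, `[[`, 0, "nucleus_area_um2"),
      lineage = vapply(out$cells, `[[`, "", "lineage"),
      stringsAsFactors = FALSE)
    df$region <- ifelse(df$y < h_epi - 0.5, "epithelium", "lamina_propria")
    df$label <- df$id
    df
  } else {
    data.frame(id = integer(), x = numeric(), y = numeric(),
               nucleus_area_um2 = numeric(), lineage = character(),
               region = character(), label = integer(),
               stringsAsFactors = FALSE)
  }

  stack <- image_stack(out$channels, pixel_size_um = px)
  regions <- region_set(
    region_polygon("epithelium", "epithelium",
                   rbind(c(-0.5, -0.5), c(W - 0.5, -0.5),
                         c(W - 0.5, h_epi - 0.5), c(-0.5, h_epi - 0.5))),
    region_polygon("lamina_propria", "lamina_propria",
                   rbind(c(-0.5, h_epi - 0.5), c(W - 0.5, h_epi - 0.5),
                         c(W - 0.5, H - 0.5), c(-0.5, H - 0.5))))
  list(stack = stack,
       truth = structure(list(cells = cells_df, label_map = truth_lab),
                         class = "imic_truth"),
       regions = regions)
}

#' Generate a four-channel tissue phantom with ground truth
#'
#' Places non-overlapping elliptical nuclei (rejection sampling) in an
#' epithelial band over a lamina-propria block, paints nuclear DAPI signal
#' and cytoplasmic marker signal on halos of expressing lineages, mixes the
#' marker channels through the spillover matrix, and adds per-channel
#' background and Gaussian noise. Cytokeratin-expressing cells in the lamina
#' propria cluster around gland centres. The same configuration and seed
#' give bit-identical output.
#'
#' @param config An `imic_phantom_config`.
#' @return A list of class `imic_phantom` with elements `stack`
#'   (an `imic_stack`), `truth` (list with per-cell data.frame `cells` and
#'   the `label_map` truth raster) and `regions` (an `imic_regions`).
#' @export
generate_phantom <- function(config) {
  structure(.generate(config, "full"), class = "imic_phantom")
}

#' Generate an isotype-control phantom
#'
#' Identical nuclear/DAPI content to [generate_phantom()] for the same
#' configuration, but the marker channels contain only background and noise
#' — the negative-reference slide used to validate the positivity gate.
#'
#' @inheritParams generate_phantom
#' @return An `imic_stack`.
#' @export
generate_isotype_control <- function(config) {
  .generate(config, "isotype")$stack
}

#' Generate a single-stain phantom
#'
#' Only the named marker channel carries specific signal; the other marker
#' channels receive spillover times that signal plus background, emulating
#' the single-immunostained slides used to quantify channel spillover.
#'
#' @inheritParams generate_phantom
#' @param channel One of `"af488"`, `"efluor570"`, `"af594"`.
#' @return List with elements `stack` and `truth`.
#' @export
generate_single_stain <- function(config, channel) {
  out <- .generate(config, "single", channel = channel)
  out[c("stack", "truth")]
}
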