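#' Run the full image-cytometry pipeline
#'
#' Orchestrates the stages in order: (simulate) -> segment -> gate ->
#' background -> grow -> quantify -> classify -> tabulate. Input is either
#' a phantom configuration (simulated in place), a ready `imic_phantom`, or
#' a stack plus regions (objects or file paths). Identical configuration
#' and seed give an identical run.
#'
#' @param phantom An `imic_phantom_config` or `imic_phantom`.
#' @param stack An `imic_stack` or TIFF path (alternative to `phantom`).
#' @param regions An `imic_regions` or JSON path; required for region
#'   stratification of user-supplied stacks (phantoms carry their own).
#' @param seg_params [segmentation_params()].
#' @param grow_params [growing_params()].
#' @param definition Ratio definition, see [cell_background_ratio()].
#' @param sample_fraction Threshold-sample fraction.
#' @param ci_method,ci_level,B CI options, see [median_ratio_ci()].
#' @param thresholds Optional externally derived `imic_thresholds` (e.g.,
#'   classify an isotype-control run with the thresholds of the multiplexed
#'   tissue run); when given, threshold estimation is skipped.
#' @param seed Seed for the threshold sample (phantom generation uses the
#'   seed inside its own config).
#' @return An object of class `imic_run`: nuclei counts and records,
#'   background estimate, thresholds, classified cell table, population
#'   table, per-stage log, and the truth table when simulating.
#' @export
run_pipeline <- function(phantom = NULL, stack = NULL, regions = NULL,
                         seg_params = segmentation_params(),
                         grow_params = growing_params(),
                         definition = c("quotient", "printed_difference"),
                         sample_fraction = 0.30,
                         ci_method = c("order_statistic", "bootstrap"),
                         ci_level = 0.95, B = 2000L,
                         thresholds = NULL, seed = 1L) {
  definition <- match.arg(definition)
  ci_method <- match.arg(ci_method)
  log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[[3L]]
    out <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    gc(verbose = FALSE)   # large rasters: return freed pages between stages
    log[[name]] <<- proc.time()[[3L]] - t0
    out
  }
  truth <- NULL
  if (!is.null(phantom)) {
    if (inherits(phantom, "imic_phantom_config"))
      phantom <- stage("simulate", generate_phantom(phantom))
    stopifnot(inherits(phantom, "imic_phantom"))
    stack <- phantom$stack
    regions <- regions %||% phantom$regions
    truth <- phantom$truth
  } else {
    if (is.character(stack)) stack <- stage("read", read_stack(stack))
    if (is.character(regions)) regions <- read_regions(regions)
    if (is.null(stack)) stopf("configuration error: no input stack given")
  }
  stopifnot(is_image_stack(stack))
  px <- stack$pixel_size_um

  pregate <- stage("segment",
                   segment_nuclei(stack$channels$dapi, seg_params, px))
  n_identified <- length(setdiff(unique(as.integer(pregate)), 0L))
  background <- stage("background",
                      estimate_background(
                        background_area(pregate, stack, regions)))
  gated <- stage("gate", remove_labels(pregate, seg_params$area_min_um2,
                                       seg_params$area_max_um2, px))
  n_removed <- nrow(attr(gated, "removed"))
  rm(pregate)
  records <- nucleus_records(gated, px)

  masks <- stage("grow", {
    reach <- max(fractional_step_reach(grow_params$max_growing_steps,
                                       grow_params$step_width_um))
    geom <- growth_geometry(gated, px, max_reach_um = reach)
    out <- lapply(CH_MARKERS, function(ch)
      grow_cell_masks(gated, stack$channels[[ch]], grow_params, ch, px,
                      geometry = geom))
    names(out) <- CH_MARKERS
    out
  })
  cells <- stage("quantify",
                 quantify_cells(stack, masks, regions, nuclei = records))
  if (is.null(thresholds)) {
    thresholds <- stage("thresholds",
                        channel_thresholds(cells, background, definition,
                                           fraction = sample_fraction,
                                           level = ci_level,
                                           ci_method = ci_method, B = B,
                                           seed = seed))
  }
  classified <- stage("classify",
                      classify_cells(cells, thresholds, background,
                                     definition))
  populations <- stage("tabulate", tabulate_populations(classified))

  structure(list(
    pixel_size_um = px, dim = stack_dim(stack),
    nuclei = list(n_identified = n_identified, n_removed = n_removed,
                  records = records),
    background = background, thresholds = thresholds,
    cells = classified, populations = populations,
    truth = truth, regions = regions, seed = seed,
    params = list(seg = seg_params, grow = grow_params,
                  definition = definition,
                  sample_fraction = sample_fraction,
                  ci_method = ci_method, ci_level = ci_level),
    log = data.frame(stage = names(log),
                     seconds = round(unlist(log), 3), row.names = NULL)),
    class = "imic_run")
}

#' @export
print.imic_run <- function(x, ...) {
  cat(sprintf("<imic_run> %d x %d px; %d nuclei identified, %d removed by gate, %d cells\n",
              x$dim[2L], x$dim[1L], x$nuclei$n_identified, x$nuclei$n_removed,
              nrow(x$cells)))
  cat("thresholds:\n"); print(as.data.frame(x$thresholds))
  invisible(x)
}

#' Tabular entry point: classify a user-supplied cell table
#'
#' For users bringing their own segmentation: a per-cell intensity table
#' (with `mean_<channel>` columns and optionally `region`) plus per-channel
#' background medians are enough to run threshold estimation,
#' classification and tabulation.
#'
#' @param cells data.frame or path to a delimited file with columns
#'   `mean_af488`, `mean_efluor570`, `mean_af594` and optionally `region`.
#' @param background Named numeric vector of per-channel background medians
#'   or an `imic_background`.
#' @param ... Passed to [channel_thresholds()].
#' @return List with `thresholds`, `cells` (classified) and `populations`.
#' @export
classify_cell_table <- function(cells, background, ...) {
  if (is.character(cells))
    cells <- utils::read.delim(cells, check.names = FALSE)
  if (!inherits(background, "imic_background"))
    background <- structure(list(median = unlist(background),
                                 n_events = NA_integer_),
                            class = "imic_background")
  need <- paste0("mean_", CH_MARKERS)
  if (!all(need %in% names(cells)))
    stopf("cell table must have columns %s", paste(need, collapse = ", "))
  if (is.null(cells$excluded)) cells$excluded <- FALSE
  if (is.null(cells$region))
    cells$region <- factor("none", levels = REGION_LEVELS)
  thresholds <- channel_thresholds(cells, background, ...)
  classified <- classify_cells(cells, thresholds, background)
  list(thresholds = thresholds, cells = classified,
       populations = tabulate_populations(classified))
}

#' Quality controls for a phantom run
#'
#' Generates the isotype-control and the three single-stain phantoms for a
#' configuration, runs segmentation/growing/quantification on each with the
#' same parameters as the tissue run, and reports (1) the per-channel ROC
#' of tissue versus isotype cell intensities, (2) the fraction of isotype
#' cells classified triple negative under the tissue run's thresholds, and
#' (3) the six off-target spillover fractions from the single-stain runs,
#' also under the tissue thresholds.
#'
#' @param tissue_run An `imic_run` from the multiplexed phantom.
#' @param config The same `imic_phantom_config`.
#' @param single_config Optional smaller config for the single-stain
#'   phantoms (defaults to `config`).
#' @param spillover_bound Bound for [spillover_estimate()].
#' @return List of class `imic_qc` with `roc`, `isotype_triple_negative`,
#'   `spillover`.
#' @export
run_qc <- function(tissue_run, config, single_config = NULL,
                   spillover_bound = 0.01) {
  stopifnot(inherits(tissue_run, "imic_run"),
            inherits(config, "imic_phantom_config"))
  single_config <- single_config %||% config
  quantify_stack <- function(stk, regions) {
    px <- stk$pixel_size_um
    pre <- segment_nuclei(stk$channels$dapi, tissue_run$params$seg, px)
    bg <- estimate_background(background_area(pre, stk, regions))
    gated <- remove_labels(pre, tissue_run$params$seg$area_min_um2,
                           tissue_run$params$seg$area_max_um2, px)
    geom <- growth_geometry(gated, px, max_reach_um = max(
      fractional_step_reach(tissue_run$params$grow$max_growing_steps,
                            tissue_run$params$grow$step_width_um)))
    masks <- lapply(CH_MARKERS, function(ch)
      grow_cell_masks(gated, stk$channels[[ch]], tissue_run$params$grow, ch,
                      px, geometry = geom))
    names(masks) <- CH_MARKERS
    quantify_cells(stk, masks, regions, nuclei = nucleus_records(gated, px))
  }

  iso_stack <- generate_isotype_control(config)
  iso_regions <- tissue_run$regions
  iso_cells <- quantify_stack(iso_stack, iso_regions)
  rm(iso_stack)
  roc <- do.call(rbind, lapply(CH_MARKERS, function(ch)
    isotype_roc(tissue_run$cells[[paste0("mean_", ch)]],
                iso_cells[[paste0("mean_", ch)]], channel = ch)))
  iso_classified <- classify_cells(iso_cells, tissue_run$thresholds,
                                   tissue_run$background,
                                   tissue_run$params$definition)
  iso_tn <- mean(iso_classified$population == "triple_negative")

  singles <- list()
  for (ch in CH_MARKERS) {
    ss <- generate_single_stain(single_config, ch)
    ss_regions <- generate_phantom_regions(single_config)
    ss_cells <- quantify_stack(ss$stack, ss_regions)
    singles[[ch]] <- classify_cells(ss_cells, tissue_run$thresholds,
                                    tissue_run$background,
                                    tissue_run$params$definition)
  }
  structure(list(roc = roc, isotype_triple_negative = iso_tn,
                 spillover = spillover_estimate(singles,
                                                bound = spillover_bound)),
            class = "imic_qc")
}

## Region polygons implied by a phantom configuration (no rendering).
generate_phantom_regions <- function(config) {
  H <- config$height_px; W <- config$width_px
  h_epi <- round(config$epithelium_fraction * H)
  region_set(
    region_polygon("epithelium", "epithelium",
                   rbind(c(-0.5, -0.5), c(W - 0.5, -0.5),
                         c(W - 0.5, h_epi - 0.5), c(-0.5, h_epi - 0.5))),
    region_polygon("lamina_propria", "lamina_propria",
                   rbind(c(-0.5, h_epi - 0.5), c(W - 0.5, h_epi - 0.5),
                         c(W - 0.5, H - 0.5), c(-0.5, H - 0.5))))
}

#' Write the artifacts of a run
#'
#' Classified cells, thresholds and population table as tab-delimited text,
#' plus a JSON run report (counts, background, thresholds, stage log).
#'
#' @param run An `imic_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "imic_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(run$cells, "cells.tsv")
  wt(as.data.frame(run$thresholds), "thresholds.tsv")
  wt(as.data.frame(run$populations), "populations.tsv")
  if (!is.null(run$truth)) wt(run$truth$cells, "truth_cells.tsv")
  report <- list(
    n_identified = run$nuclei$n_identified,
    n_removed = run$nuclei$n_removed,
    n_cells = nrow(run$cells),
    background = as.list(run$background$median),
    thresholds = setNames(as.list(run$thresholds$tau),
                          run$thresholds$channel),
    definition = run$params$definition,
    sample_fraction = run$params$sample_fraction,
    ci_method = run$params$ci_method,
    seed = run$seed,
    stage_seconds = setNames(as.list(run$log$seconds), run$log$stage))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a pipeline configuration file
#'
#' YAML with optional sections `phantom` (arguments of [phantom_config()]),
#' `segmentation`, `growing`, `classify`
#' (`definition`, `sample_fraction`, `ci_method`, `ci_level`), `stack`,
#' `regions` (paths) and `seed`. Used by the command-line interface.
#'
#' @param path YAML file.
#' @return List of arguments for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("configuration error: no such file: %s", path)
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$phantom)) {
    ph <- y$phantom
    if (!is.null(ph$spillover)) ph$spillover <- matrix(unlist(ph$spillover),
                                                       3L, 3L, byrow = TRUE)
    args$phantom <- do.call(phantom_config, ph)
  } else {
    if (is.null(y$stack))
      stopf("configuration error: need either 'phantom' or 'stack'")
    args$stack <- y$stack
    if (!is.null(y$regions)) {
      if (!file.exists(y$regions))
        stopf("configuration error: regions file not found: %s", y$regions)
      args$regions <- y$regions
    }
  }
  if (!is.null(y$segmentation))
    args$seg_params <- do.call(segmentation_params, y$segmentation)
  if (!is.null(y$growing)) {
    gr <- y$growing
    if (!is.null(gr$max_growing_steps))
      gr$max_growing_steps <- unlist(gr$max_growing_steps)
    args$grow_params <- do.call(growing_params, gr)
  }
  for (f in c("definition", "sample_fraction", "ci_method", "ci_level"))
    if (!is.null(y$classify[[f]])) args[[f]] <- y$classify[[f]]
  if (!is.null(y$seed)) args$seed <- y$seed
  args
}
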