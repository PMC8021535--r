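px1 <- 1  # 1 um pixels keep the fixtures easy to reason about

test_that("blank raster yields an empty label map", {
  lm <- segment_nuclei(matrix(0L, 64L, 64L), segmentation_params(),
                       pixel_size_um = px1)
  expect_equal(sum(lm), 0L)
})

test_that("two separated disks give two labels", {
  img <- matrix(100L, 64L, 64L)
  img <- paint_disk(img, 16, 32, 5, 4000L)
  img <- paint_disk(img, 48, 32, 5, 4000L)
  lm <- segment_nuclei(img, segmentation_params(), pixel_size_um = px1)
  expect_equal(length(setdiff(unique(as.integer(lm)), 0L)), 2L)
})

test_that("touching nuclei are split by the distance-transform watershed", {
  img <- matrix(100L, 80L, 80L)
  img <- paint_disk(img, 30, 40, 8, 4000L)
  img <- paint_disk(img, 47, 40, 8, 4000L)   # overlapping pair
  split_params <- segmentation_params(min_split_distance_um = 2)
  lm <- segment_nuclei(img, split_params, pixel_size_um = px1)
  expect_equal(length(setdiff(unique(as.integer(lm)), 0L)), 2L)
  no_split <- segmentation_params(min_split_distance_um = 0)
  lm0 <- segment_nuclei(img, no_split, pixel_size_um = px1)
  expect_equal(length(setdiff(unique(as.integer(lm0)), 0L)), 1L)
})

test_that("remove_labels applies the closed-interval gate and keeps ids", {
  # areas 30, 50, 120 um^2 at 1 um pixels
  lm <- matrix(0L, 40L, 40L)
  lm[1:5, 1:6] <- 1L       # 30
  lm[10:14, 1:10] <- 2L    # 50
  lm[20:29, 1:12] <- 3L    # 120
  suppressMessages(out <- remove_labels(lm, 40, 100, pixel_size_um = px1))
  expect_equal(setdiff(unique(as.integer(out)), 0L), 2L)
  expect_setequal(attr(out, "removed")$label, c(1L, 3L))
})

test_that("areas exactly at 40 and 100 um^2 are retained (closed interval)", {
  lm <- matrix(0L, 40L, 40L)
  lm[1:4, 1:10] <- 1L      # exactly 40
  lm[10:19, 1:10] <- 2L    # exactly 100
  out <- remove_labels(lm, 40, 100, pixel_size_um = px1)
  expect_setequal(setdiff(unique(as.integer(out)), 0L), c(1L, 2L))
})

test_that("a disabled gate is the identity", {
  lm <- matrix(sample(0:5, 400L, replace = TRUE), 20L, 20L)
  out <- remove_labels(lm, .Machine$double.eps, Inf, pixel_size_um = px1)
  expect_equal(as.integer(out), as.integer(lm))
})

test_that("widening the gate never decreases the retained count", {
  set.seed(42)
  lm <- matrix(0L, 120L, 120L)
  for (i in 1:20)
    lm <- paint_disk(lm, runif(1, 10, 110), runif(1, 10, 110),
                     runif(1, 1.5, 7), i)
  gates <- list(c(40, 100), c(30, 110), c(20, 150), c(1e-9, Inf))
  kept <- vapply(gates, function(g) {
    out <- suppressMessages(remove_labels(lm, g[1], g[2], pixel_size_um = px1))
    length(setdiff(unique(as.integer(out)), 0L))
  }, 0L)
  expect_true(all(diff(kept) >= 0L))
})

test_that("background events cover the nucleus-free analyzed area", {
  chans <- list(dapi = matrix(7L, 30L, 30L), af488 = matrix(3L, 30L, 30L),
                efluor570 = matrix(4L, 30L, 30L),
                af594 = matrix(5L, 30L, 30L))
  stk <- image_stack(chans, pixel_size_um = px1)
  # blank label map -> the whole image is background
  ev <- background_area(matrix(0L, 30L, 30L), stk)
  expect_equal(ev$n_events, 900L)
  # constant channel value v -> every event intensity v
  expect_true(all(ev$events$af488 == 3L))
  expect_true(all(ev$events$af594 == 5L))
  # nuclear pixels are excluded
  lm <- matrix(0L, 30L, 30L); lm[1:10, 1:10] <- 1L
  ev2 <- background_area(lm, stk)
  expect_equal(ev2$n_events, 800L)
  # everything nuclear -> background unestimable
  expect_error(background_area(matrix(1L, 30L, 30L), stk), "unestimable")
})

test_that("tile events average pixels and regions restrict the background", {
  chans <- lapply(c(dapi = 1L, af488 = 2L, efluor570 = 3L, af594 = 4L),
                  function(v) matrix(v, 20L, 20L))
  stk <- image_stack(chans, pixel_size_um = px1)
  rs <- region_set(region_polygon("epi", "epithelium",
                                  rbind(c(-0.5, -0.5), c(19.5, -0.5),
                                        c(19.5, 9.5), c(-0.5, 9.5))))
  ev <- background_area(matrix(0L, 20L, 20L), stk, regions = rs)
  expect_equal(ev$n_events, 200L)
  evt <- background_area(matrix(0L, 20L, 20L), stk, events = "tile",
                         tile_um = 5)
  expect_true(all(evt$events$efluor570 == 3))
  expect_lt(evt$n_events, 400L)
})

test_that("segmentation recovers phantom nuclei sizes", {
  ph <- seg_phantom()
  cfg <- seg_cfg()
  lm <- segment_nuclei(ph$stack$channels$dapi, segmentation_params(),
                       cfg$pixel_size_um)
  gated <- suppressMessages(remove_labels(lm, pixel_size_um = cfg$pixel_size_um))
  rec <- nucleus_records(gated, cfg$pixel_size_um)
  expect_gt(nrow(rec), 0.9 * nrow(ph$truth$cells))
  expect_lt(abs(median(rec$area_um2) - 64) / 64, 0.05)
})

test_that("label maps round-trip through 16-bit TIFF", {
  lm <- matrix(0L, 25L, 30L)
  lm <- paint_disk(lm, 8, 8, 4, 3L)
  lm <- paint_disk(lm, 20, 18, 4, 117L)
  path <- withr::local_tempfile(fileext = ".tiff")
  write_label_map(lm, path)
  expect_identical(read_label_map(path), lm)
  expect_error(write_label_map(matrix(70000L, 2, 2), path), "16-bit")
})
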