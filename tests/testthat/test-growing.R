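px1 <- 1

# three well-separated disks as a gated label map
disk_labelmap <- function(n = 96L, r = 6) {
  lm <- matrix(0L, n, n)
  lm <- paint_disk(lm, 20, 20, r, 1L)
  lm <- paint_disk(lm, 70, 25, r, 2L)
  lm <- paint_disk(lm, 40, 70, r, 3L)
  lm
}

test_that("fractional step counts translate to physical reach", {
  expect_equal(fractional_step_reach(2.0, 0.5), 1.0)
  expect_equal(fractional_step_reach(4.0, 0.5), 2.0)
  expect_equal(fractional_step_reach(2.5, 0.5), 1.25)
  expect_equal(fractional_step_reach(0, 0.5), 0)
})

test_that("max_growing_steps = 0 leaves only the nucleus-interior reach", {
  lm <- disk_labelmap()
  params <- growing_params(step_width_um = 1,
                           max_growing_steps = c(af488 = 0))
  mk <- grow_cell_masks(lm, matrix(100L, 96L, 96L), params, "af488", px1)
  expect_true(all(lm[mk$idx] > 0L))        # no pixel outside any nucleus
  expect_true(all(mk$reach$out_steps == 0))
  # uniform image: inward growth reaches the whole nucleus
  expect_equal(sort(mk$idx), which(lm > 0L))
})

test_that("on a uniform raster every cell reaches exactly max steps", {
  lm <- disk_labelmap()
  img <- matrix(500L, 96L, 96L)
  params <- growing_params(step_width_um = 1,
                           max_growing_steps = c(af488 = 2, efluor570 = 4))
  geom <- growth_geometry(lm, px1, max_reach_um = 4)
  mk2 <- grow_cell_masks(lm, img, params, "af488", px1, geom)
  mk4 <- grow_cell_masks(lm, img, params, "efluor570", px1, geom)
  expect_true(all(mk2$reach$out_reach_um == 2))
  expect_true(all(mk4$reach$out_reach_um == 4))
  # exact reach: outward mask pixels are those within the reach distance
  dist_out <- EBImage::imageData(EBImage::distmap(1L - (lm > 0L)))
  expect_setequal(mk2$idx, which(lm > 0L | (dist_out > 0 & dist_out <= 2)))
  expect_setequal(mk4$idx, which(lm > 0L | (dist_out > 0 & dist_out <= 4)))
  # deeper eFluor 570 growing strictly contains the AF488 mask
  expect_true(all(mk2$idx %in% mk4$idx))
  expect_gt(length(mk4$idx), length(mk2$idx))
})

test_that("an intensity step stops outward growth at the configured drop", {
  lm <- matrix(0L, 96L, 96L)
  lm <- paint_disk(lm, 48, 48, 8, 1L)
  # intensity halves beyond a 1-ring (1 um) annulus around the nucleus
  dist_out <- EBImage::imageData(EBImage::distmap(1L - (lm > 0L)))
  img <- matrix(1000L, 96L, 96L)
  img[dist_out > 1] <- 500L
  params <- growing_params(step_width_um = 1,
                           max_growing_steps = c(af488 = 4),
                           step_drop_fraction = 0.4)
  mk <- grow_cell_masks(lm, img, params, "af488", px1)
  expect_equal(mk$reach$out_steps, 1)
  expect_equal(mk$reach$out_reach_um, 1)
  # a drop threshold above the 50% step lets growth continue to the limit
  tolerant <- growing_params(step_width_um = 1,
                             max_growing_steps = c(af488 = 4),
                             step_drop_fraction = 0.6)
  mk2 <- grow_cell_masks(lm, img, tolerant, "af488", px1)
  expect_equal(mk2$reach$out_steps, 4)
})

test_that("masks are pairwise disjoint and contested pixels go to the nearer nucleus", {
  lm <- matrix(0L, 60L, 60L)
  lm <- paint_disk(lm, 22, 30, 5, 1L)
  lm <- paint_disk(lm, 38, 30, 5, 2L)   # 16 px apart: growth zones touch
  img <- matrix(300L, 60L, 60L)
  params <- growing_params(step_width_um = 1,
                           max_growing_steps = c(efluor570 = 4))
  mk <- grow_cell_masks(lm, img, params, "efluor570", px1)
  expect_equal(anyDuplicated(mk$idx), 0L)
  area <- mask_areas(mk)
  expect_equal(sum(area$area_um2), length(mk$idx) * px1^2)  # disjoint union
  # pixels on each side of the midline belong to the nearer nucleus
  cols <- (mk$idx - 1L) %/% 60L       # 0-based x
  expect_true(all(cols[mk$label == 1L] < 30))
  expect_true(all(cols[mk$label == 2L] >= 29))
})

test_that("increasing max steps never shrinks a mask on a uniform image", {
  lm <- disk_labelmap()
  img <- matrix(200L, 96L, 96L)
  geom <- growth_geometry(lm, px1, max_reach_um = 5)
  sizes <- vapply(c(0, 1, 2.5, 4, 5), function(s) {
    params <- growing_params(step_width_um = 1,
                             max_growing_steps = c(af488 = s))
    length(grow_cell_masks(lm, img, params, "af488", px1, geom)$idx)
  }, 0L)
  expect_true(all(diff(sizes) > 0L))
})

test_that("fractional steps truncate the final ring by distance", {
  lm <- matrix(0L, 60L, 60L)
  lm <- paint_disk(lm, 30, 30, 6, 1L)
  img <- matrix(100L, 60L, 60L)
  params <- growing_params(step_width_um = 1,
                           max_growing_steps = c(af488 = 2.5))
  mk <- grow_cell_masks(lm, img, params, "af488", px1)
  dist_out <- EBImage::imageData(EBImage::distmap(1L - (lm > 0L)))
  got <- mk$idx[lm[mk$idx] == 0L]
  expect_setequal(got, which(dist_out > 0 & dist_out <= 2.5))
})

test_that("label maps materialize masks faithfully", {
  lm <- disk_labelmap()
  img <- matrix(50L, 96L, 96L)
  mk <- grow_cell_masks(lm, img, growing_params(), "af488", px1)
  m <- as_label_map(mk)
  expect_equal(which(m > 0L), sort(mk$idx))
  expect_equal(m[mk$idx], mk$label)
})
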