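# Small phantoms (0.2-0.35 mm) are enough for the constructive properties;
# statistical properties that need >= 2000 cells reuse the cached fixtures.

test_that("zero density gives an empty truth and background-only images", {
  cfg <- phantom_config(width_px = 400L, height_px = 400L,
                        cell_density_per_mm2 = 0, seed = 3L)
  ph <- generate_phantom(cfg)
  expect_equal(nrow(ph$truth$cells), 0L)
  expect_true(all(ph$truth$label_map == 0L))
  for (ch in names(ph$stack$channels)) {
    m <- ph$stack$channels[[ch]]
    expect_equal(mean(m), cfg$background_level[[ch]], tolerance = 0.05)
    expect_lt(abs(sd(as.numeric(m)) - cfg$noise_sd[[ch]]), 2)
  }
})

test_that("same config and seed give bit-identical phantoms", {
  cfg <- phantom_config(width_px = 400L, height_px = 400L, seed = 11L)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$cells, b$truth$cells)
  expect_identical(a$truth$label_map, b$truth$label_map)
})

test_that("cell count matches the density within Poisson placement error", {
  ph <- balanced_phantom()          # 1 mm^2 at 3486 cells/mm^2
  expect_lt(abs(nrow(ph$truth$cells) - 3486), 3 * sqrt(3486))
})

test_that("truth lineage fractions match the config within 3 sigma", {
  ph <- balanced_phantom()
  cfg <- balanced_cfg()
  tc <- ph$truth$cells
  for (rg in c("epithelium", "lamina_propria")) {
    sub <- tc[tc$region == rg, ]
    n <- nrow(sub)
    for (lin in names(cfg$lineage_fractions[[rg]])) {
      p <- cfg$lineage_fractions[[rg]][[lin]]
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(mean(sub$lineage == lin) - p), 3 * se + 1e-12)
    }
  }
})

test_that("pixel values stay inside the 14-bit range", {
  ph <- balanced_phantom()
  for (m in ph$stack$channels) {
    expect_gte(min(m), 0L)
    expect_lte(max(m), 16383L)
  }
})

test_that("nucleus-area sample median converges to the configured median", {
  ph <- balanced_phantom()
  expect_gt(nrow(ph$truth$cells), 2000L)
  med <- median(ph$truth$cells$nucleus_area_um2)
  expect_lt(abs(med - 64) / 64, 0.05)
})

test_that("nuclei are non-overlapping and regions match the geometric band", {
  cfg <- phantom_config(width_px = 600L, height_px = 600L, seed = 5L)
  ph <- generate_phantom(cfg)
  tc <- ph$truth$cells
  # every truth id maps to exactly one connected nucleus
  lm <- ph$truth$label_map
  cnt <- tabulate(lm[lm > 0L])
  expect_equal(sum(cnt > 0L), nrow(tc))
  comps <- EBImage::bwlabel(lm > 0L)
  expect_equal(max(comps), nrow(tc))
  h_epi <- round(cfg$epithelium_fraction * 600L)
  expect_equal(tc$region,
               ifelse(tc$y < h_epi - 0.5, "epithelium", "lamina_propria"))
})

test_that("excessive density fails with the achievable density named", {
  cfg <- phantom_config(width_px = 300L, height_px = 300L,
                        cell_density_per_mm2 = 40000, seed = 2L,
                        epithelium_fraction = 0,
                        max_place_attempts = 10L)
  expect_error(generate_phantom(cfg), "achievable density")
})

test_that("isotype control has phantom DAPI but background-only markers", {
  cfg <- phantom_config(width_px = 500L, height_px = 500L, seed = 9L)
  ph <- generate_phantom(cfg)
  iso <- generate_isotype_control(cfg)
  expect_identical(iso$channels$dapi, ph$stack$channels$dapi)
  for (ch in c("af488", "efluor570", "af594")) {
    expect_equal(mean(iso$channels[[ch]]), cfg$background_level[[ch]],
                 tolerance = 0.05)
  }
  iso2 <- generate_isotype_control(cfg)
  expect_identical(iso$channels, iso2$channels)
})

test_that("single-stain phantoms put signal only in the named channel", {
  cfg <- phantom_config(width_px = 500L, height_px = 500L, seed = 9L,
                        spillover = diag(3))
  iso <- generate_isotype_control(cfg)
  ss <- generate_single_stain(cfg, "af488")
  # with identity spillover the off-target channels equal the isotype ones
  expect_identical(ss$stack$channels$efluor570, iso$channels$efluor570)
  expect_identical(ss$stack$channels$af594, iso$channels$af594)
  expect_gt(mean(ss$stack$channels$af488), mean(iso$channels$af488))
  expect_identical(ss$truth$cells, generate_phantom(cfg)$truth$cells)
  expect_error(generate_single_stain(cfg, "dapi"), "channel")
})

test_that("off-diagonal spillover deposits the configured signal fraction", {
  sp <- diag(3); sp[2, 1] <- 0.05   # af488 -> efluor570 at 5%
  cfg0 <- phantom_config(width_px = 500L, height_px = 500L, seed = 9L,
                         spillover = diag(3))
  cfg1 <- phantom_config(width_px = 500L, height_px = 500L, seed = 9L,
                         spillover = sp)
  s0 <- generate_single_stain(cfg0, "af488")$stack
  s1 <- generate_single_stain(cfg1, "af488")$stack
  src <- mean(s1$channels$af488) - cfg1$background_level[["af488"]]
  tgt <- mean(s1$channels$efluor570) - mean(s0$channels$efluor570)
  expect_equal(tgt / src, 0.05, tolerance = 0.02)
})
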