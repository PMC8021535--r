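test_that("ratio arithmetic matches both definitions", {
  expect_equal(cell_background_ratio(144, 100, "quotient"), 1.44)
  expect_equal(cell_background_ratio(200, 100, "printed_difference"), 0.5)
  expect_equal(cell_background_ratio(100, 100, "printed_difference"), 0)
  # domain violations flag as NA
  expect_true(is.na(cell_background_ratio(5, 0, "quotient")))
  expect_true(is.na(cell_background_ratio(0, 5, "printed_difference")))
})

test_that("threshold sampling uses the floor convention and is seeded", {
  cells <- data.frame(cell_id = 1:10000,
                      mean_af488 = rlnorm(10000), excluded = FALSE)
  s1 <- draw_threshold_sample(cells, 0.30, seed = 4L)
  expect_equal(nrow(s1), 3000L)
  s2 <- draw_threshold_sample(cells, 0.30, seed = 4L)
  expect_identical(s1, s2)
  expect_equal(nrow(draw_threshold_sample(cells, 1)), 10000L)
  small <- cells[1:50, ]
  expect_error(draw_threshold_sample(small, 0.30), "< 20")
})

test_that("order-statistic CI matches a brute-force binomial oracle", {
  # oracle: enumerate the binomial CDF to pick the ranks; the largest k
  # with P(Binom(n, 1/2) <= k - 1) <= alpha/2 keeps coverage >= level
  oracle_ranks <- function(n, level = 0.95) {
    alpha <- 1 - level
    cdf <- vapply(0:n, function(j) sum(choose(n, 0:j)) * 0.5^n, 0)
    k <- max(which(cdf <= alpha / 2))  # index of largest j = k - 1, plus 1
    c(k, n - k + 1L)
  }
  for (n in c(20L, 47L, 100L, 201L)) {
    x <- seq_len(n)
    ci <- median_ratio_ci(x, method = "order_statistic")
    expect_equal(unname(attr(ci, "ranks")), unname(oracle_ranks(n)))
    expect_equal(as.numeric(ci), as.numeric(oracle_ranks(n)))
    # and the implied coverage really is at least 95%
    k <- oracle_ranks(n)[1]
    expect_lte(2 * pbinom(k - 1, n, 0.5), 0.05)
  }
})

test_that("degenerate ratios give a zero-width CI", {
  ci <- median_ratio_ci(rep(3.5, 30))
  expect_equal(as.numeric(ci), c(3.5, 3.5))
})

test_that("bootstrap CI brackets the median and approaches the exact interval", {
  x <- 1:100
  ci_b <- median_ratio_ci(x, method = "bootstrap", B = 10000L, seed = 2L)
  expect_lt(ci_b[["lower"]], 50.5)
  expect_gt(ci_b[["upper"]], 50.5)
  ci_o <- median_ratio_ci(x, method = "order_statistic")
  expect_lt(abs(ci_b[["lower"]] - ci_o[["lower"]]), 5)
  expect_lt(abs(ci_b[["upper"]] - ci_o[["upper"]]), 5)
})

test_that("positivity is strict exceedance of tau", {
  expect_false(classify_cell(2, 2))
  expect_true(classify_cell(2 + 1e-12, 2))
  expect_false(classify_cell(NA_real_, 2))   # flagged cell -> negative
})

test_that("population assignment is the stated bijection", {
  expect_equal(as.character(assign_population(TRUE, FALSE, FALSE)),
               "ck_single")
  expect_equal(as.character(assign_population(FALSE, TRUE, TRUE)),
               "vim_cd_double")
  expect_equal(as.character(assign_population(FALSE, FALSE, FALSE)),
               "triple_negative")
  expect_equal(population_labels()[["ck_single"]],
               "Cytokeratin-single positive")
  expect_equal(population_labels()[["vim_cd_double"]],
               "CD45/CD18-vimentin-double positive")
  # bijection over all 8 combinations
  g <- expand.grid(ck = c(FALSE, TRUE), vim = c(FALSE, TRUE),
                   cd = c(FALSE, TRUE))
  pops <- assign_population(g$ck, g$vim, g$cd)
  expect_equal(sort(as.character(pops)), sort(levels(pops)))
})

test_that("classification is invariant to channel rescaling", {
  set.seed(31)
  n <- 400L
  cells <- data.frame(cell_id = seq_len(n),
                      mean_af488 = rlnorm(n, log(500), 1),
                      mean_efluor570 = rlnorm(n, log(400), 1),
                      mean_af594 = rlnorm(n, log(300), 1),
                      region = "none", excluded = FALSE)
  bg <- structure(list(median = c(af488 = 100, efluor570 = 90, af594 = 80),
                       n_events = 1000L), class = "imic_background")
  th1 <- channel_thresholds(cells, bg, seed = 7L)
  cl1 <- classify_cells(cells, th1, bg)
  k <- 11.3
  cells2 <- cells
  cells2$mean_af488 <- cells2$mean_af488 * k
  bg2 <- bg; bg2$median["af488"] <- bg2$median["af488"] * k
  th2 <- channel_thresholds(cells2, bg2, seed = 7L)
  cl2 <- classify_cells(cells2, th2, bg2)
  expect_identical(cl1$pos_af488, cl2$pos_af488)
  expect_identical(cl1$population, cl2$population)
})

test_that("quotient and printed-difference gates classify identically", {
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(60:500, 1)
    cells <- data.frame(cell_id = seq_len(n),
                        mean_af488 = rlnorm(n, log(300), 0.8),
                        mean_efluor570 = rlnorm(n, log(300), 0.8),
                        mean_af594 = rlnorm(n, log(300), 0.8),
                        region = "none", excluded = FALSE)
    bg <- structure(list(median = c(af488 = 120, efluor570 = 110,
                                    af594 = 100), n_events = 500L),
                    class = "imic_background")
    clq <- classify_cells(cells, channel_thresholds(
      cells, bg, "quotient", seed = rep), bg, "quotient")
    clp <- classify_cells(cells, channel_thresholds(
      cells, bg, "printed_difference", seed = rep), bg,
      "printed_difference")
    expect_identical(clq$population, clp$population)
  }
})

test_that("the gate recovers truth positivity on well-separated phantoms", {
  # expressing-vs-background separation in the phantom is far above 4
  # noise SD; on a phantom big enough that the threshold's rank noise is
  # small, per-channel sensitivity and specificity both reach 0.95
  run <- recovery_run()
  perf <- classification_performance(run, lineage_profiles())
  expect_gt(nrow(run$cells), 8000L)
  expect_true(all(perf$sensitivity >= 0.95))
  expect_true(all(perf$specificity >= 0.95))
})
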