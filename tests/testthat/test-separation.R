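test_that("focus pairing gates at the diffraction limit", {
  one <- function(x, y) tibble::tibble(x_nm = x, y_nm = y, sigma_nm = 10)
  expect_equal(nrow(pair_foci(one(0, 0), one(50, 0))), 1)
  expect_equal(nrow(pair_foci(one(0, 0), one(500, 0))), 0)
  # 20 true pairs plus 5 lone foci: exactly the 20 recovered
  withr::with_seed(21, {
    ax <- runif(20, 0, 20000); ay <- runif(20, 0, 20000)
  })
  fa <- tibble::tibble(x_nm = ax, y_nm = ay, sigma_nm = 10)
  fb <- tibble::tibble(x_nm = c(ax + 40, runif(5, 30000, 40000)),
                       y_nm = c(ay, runif(5, 30000, 40000)), sigma_nm = 10)
  pairs <- pair_foci(fa, fb)
  expect_equal(nrow(pairs), 20)
  expect_equal(nrow(attr(pairs, "unpaired_b")), 5)
})

test_that("separation records propagate uncertainty by root-sum-square", {
  p <- tibble::tibble(x_a = 0, y_a = 0, sigma_a = 0, x_b = 30, y_b = 40,
                      sigma_b = 0)
  rec <- separations(p, r_nm = 0)
  expect_equal(rec$d_nm, 50)             # 3-4-5
  expect_equal(rec$combined_uncertainty_nm, 0)
  expect_true(rec$significant)
  # the worked uncertainty budget: 15, 15 and 21 nm combine to ~30 nm
  p2 <- tibble::tibble(x_a = 0, y_a = 0, sigma_a = 15, x_b = 0, y_b = 0,
                       sigma_b = 15)
  rec2 <- separations(p2, r_nm = 21)
  expect_equal(rec2$combined_uncertainty_nm, sqrt(225 + 225 + 441),
               tolerance = 1e-9)
  expect_equal(rec2$combined_uncertainty_nm, 29.85, tolerance = 1e-3)
  expect_false(rec2$significant)         # d = 0 is never significant
  # uncertainty is mandatory
  expect_error(separations(p2[, c("x_a", "y_a", "x_b", "y_b")], r_nm = 21),
               class = "nanosep_domain_error")
  expect_error(separations(p2, r_nm = NA), class = "nanosep_domain_error")
})

test_that("histograms use half-open 30-nm bins that conserve counts", {
  h <- histogram_separations(c(10, 20, 40), 30)
  expect_equal(h$counts, c(2L, 1L))
  expect_equal(h$breaks, c(0, 30, 60))
  # a value on a bin edge belongs to the upper bin
  expect_equal(histogram_separations(c(30), 30)$counts, c(0L, 1L))
  # everything in one bin
  h1 <- histogram_separations(rep(12, 7), 30)
  expect_equal(sum(h1$counts), 7)
  expect_equal(h1$counts[1], 7L)
  expect_error(histogram_separations(numeric(0)),
               class = "nanosep_domain_error")
})

test_that("zero-separation pairs at 15-nm precision peak in the first bins", {
  withr::with_seed(77, {
    dx <- rnorm(1000, 0, 15) - rnorm(1000, 0, 15)
    dy <- rnorm(1000, 0, 15) - rnorm(1000, 0, 15)
  })
  h <- histogram_separations(sqrt(dx^2 + dy^2), 30)
  expect_lte(which.max(h$counts), 2)
})

test_that("the histogram Gaussian fit recovers a known mean", {
  withr::with_seed(123, d <- abs(rnorm(500, 68, 25)))
  h <- fit_histogram_gaussian(histogram_separations(d, 30))
  expect_false(h$fit$degenerate)
  expect_lt(abs(h$fit$mean - 68), 4)
  # symmetric histogram: fitted mean at the center
  withr::with_seed(5, dsym <- rnorm(800, 150, 20))
  hs <- fit_histogram_gaussian(histogram_separations(dsym, 30))
  expect_lt(abs(hs$fit$mean - 150), 5)
})

test_that("area normalization equalizes analytic areas exactly", {
  withr::with_seed(9, {
    d1 <- abs(rnorm(300, 60, 20)); d2 <- abs(rnorm(900, 140, 35))
  })
  h1 <- fit_histogram_gaussian(histogram_separations(d1, 30))
  h2 <- fit_histogram_gaussian(histogram_separations(d2, 30))
  norm <- normalize_distributions(list(h1, h2), reference_area = 1)
  areas <- vapply(norm, function(h) {
    h$fit$amplitude_normalized * h$fit$sd * sqrt(2 * pi)
  }, numeric(1))
  expect_equal(areas[1], areas[2], tolerance = 1e-9)
  # normalization does not touch the bin counts
  expect_equal(norm[[1]]$counts, h1$counts)
})

test_that("degenerate histograms fall back to the empirical mean", {
  h <- fit_histogram_gaussian(histogram_separations(c(5, 8, 11, 14), 30))
  expect_true(h$fit$degenerate)
  expect_equal(h$fit$mean, mean(c(5, 8, 11, 14)))
})

test_that("autoplot draws the histogram with its fitted curve", {
  withr::with_seed(2, d <- abs(rnorm(400, 90, 30)))
  h <- fit_histogram_gaussian(histogram_separations(d, 30))
  p <- ggplot2::autoplot(h)
  expect_s3_class(p, "ggplot")
})

test_that("chance colocalization is rare for small spots in a nucleus", {
  # 200-nm diameter spots, 10 x 10 um visible nuclear area, 2 foci each
  p <- chance_colocalization(pi * 100^2, 1e8, 2, 2)
  expect_lt(p$p_overlap, 0.01)
  expect_equal(p$p_overlap, p$p_overlap_poisson, tolerance = 0.01)
  # Monte-Carlo dart-throwing oracle
  withr::with_seed(55, {
    hits <- vapply(1:4000, function(i) {
      ax <- runif(2, 0, 1e4); ay <- runif(2, 0, 1e4)
      bx <- runif(2, 0, 1e4); by <- runif(2, 0, 1e4)
      any(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2 < 200^2)
    }, logical(1))
  })
  expect_lt(abs(mean(hits) - p$p_overlap), 0.005)
  # no channel-A foci, no chance overlap
  expect_equal(chance_colocalization(pi * 100^2, 1e8, 0, 3)$p_overlap, 0)
  # monotone in spot area
  areas <- pi * c(50, 100, 150, 200)^2
  probs <- vapply(areas, function(s) {
    chance_colocalization(s, 1e8, 2, 2)$p_overlap
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
  expect_error(chance_colocalization(1e8, 1e8, 2, 2),
               class = "nanosep_domain_error")
})
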