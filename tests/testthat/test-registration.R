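test_that("fiducial matching pairs identical lists and drops singletons", {
  pos <- tibble::tibble(x_nm = seq(1000, 15000, length.out = 15),
                        y_nm = rep(c(2000, 8000, 14000), 5))
  pairs <- match_fiducials(pos, pos)
  expect_equal(nrow(pairs), 15)
  expect_true(all(pairs$pair_dist_nm == 0))
  # a bead present only in channel A stays unmatched
  pos_a <- dplyr::bind_rows(pos, tibble::tibble(x_nm = 500, y_nm = 500))
  pairs2 <- match_fiducials(pos_a, pos)
  expect_equal(nrow(pairs2), 15)
  expect_false(any(pairs2$x_a == 500))
  expect_error(match_fiducials(pos[1:5, ], pos[1:5, ]),
               class = "nanosep_insufficient_fiducials")
})

test_that("matching recovers the ground-truth correspondence under a warp", {
  fr <- frame_geometry(96, 96, 200)
  w <- warp_random(fr, 40, seed = 2)
  tp <- warped_truth_pairs(20, w, fr, seed = 6)
  pairs <- match_fiducials(tibble::tibble(x_nm = tp$x_a, y_nm = tp$y_a),
                           tibble::tibble(x_nm = tp$x_b, y_nm = tp$y_b))
  expect_equal(nrow(pairs), 20)
  ord <- order(pairs$x_a)
  tord <- order(tp$x_a)
  expect_equal(pairs$x_b[ord], tp$x_b[tord])
  expect_equal(pairs$y_b[ord], tp$y_b[tord])
})

test_that("identity and translation fields are reproduced almost exactly", {
  fr <- frame_geometry(96, 96, 200)
  tp <- warped_truth_pairs(25, warp_identity(fr), fr, seed = 8)
  m <- build_lwm_transform(tp, k = 12)
  q <- expand.grid(x_nm = seq(4000, 15000, by = 1000),
                   y_nm = seq(4000, 15000, by = 1000))
  corr <- suppressWarnings(apply_transform(m, tibble::tibble(q)))
  expect_lt(max(abs(corr$x_nm - q$x_nm)), 0.5)
  expect_lt(max(abs(corr$y_nm - q$y_nm)), 0.5)
  # pure translation: corrected B equals A to < 0.5 nm
  tp2 <- warped_truth_pairs(25, warp_translation(fr, 50, 0), fr, seed = 8)
  m2 <- build_lwm_transform(tp2, k = 12)
  corr2 <- suppressWarnings(
    apply_transform(m2, tibble::tibble(x_nm = tp2$x_b, y_nm = tp2$y_b)))
  expect_lt(max(abs(corr2$x_nm - tp2$x_a)), 0.5)
  expect_lt(max(abs(corr2$y_nm - tp2$y_a)), 0.5)
})

test_that("quadratic warps are corrected to < 2 nm on held-out beads", {
  fr <- frame_geometry(128, 128, 200)
  w <- warp_random(fr, 50, seed = 4)
  tp <- warped_truth_pairs(40, w, fr, seed = 10)
  control <- tp[1:28, ]; heldout <- tp[29:40, ]
  for (ev in c("grid", "direct")) {
    m <- build_lwm_transform(control, k = 12, evaluation = ev)
    expect_lt(residual_error(m, heldout), 2)
  }
})

test_that("residual error tracks the localization noise floor", {
  fr <- frame_geometry(128, 128, 200)
  w <- warp_random(fr, 40, seed = 9)
  n <- 200
  tp <- warped_truth_pairs(n, w, fr, seed = 12)
  sigma <- 15   # per axis; per-channel radial RMS error is sqrt(2) * 15
  withr::with_seed(31, {
    tp$x_a <- tp$x_a + rnorm(n, 0, sigma)
    tp$y_a <- tp$y_a + rnorm(n, 0, sigma)
    tp$x_b <- tp$x_b + rnorm(n, 0, sigma)
    tp$y_b <- tp$y_b + rnorm(n, 0, sigma)
  })
  m <- build_lwm_transform(tp[1:80, ], k = 12)
  r <- residual_error(m, tp[81:n, ])
  # floor: root-sum-square of the two per-channel radial errors
  floor <- sqrt(2 * sigma^2 + 2 * sigma^2)   # 30 nm
  expect_gt(r, 0)
  expect_lt(abs(r - floor) / floor, 0.2)
})

test_that("registration is deterministic and validates its inputs", {
  fr <- frame_geometry(96, 96, 200)
  tp <- warped_truth_pairs(20, warp_random(fr, 30, seed = 1), fr, seed = 2)
  m1 <- build_lwm_transform(tp, k = 12)
  m2 <- build_lwm_transform(tp, k = 12)
  q <- tibble::tibble(x_nm = c(5000, 9000), y_nm = c(6000, 11000))
  expect_identical(suppressWarnings(apply_transform(m1, q)),
                   suppressWarnings(apply_transform(m2, q)))
  expect_error(build_lwm_transform(tp[1:8, ], k = 12),
               class = "nanosep_insufficient_fiducials")
  coll <- tibble::tibble(x_a = 1:15 * 1000, y_a = 5000,
                         x_b = 1:15 * 1000, y_b = 5000)
  expect_error(build_lwm_transform(coll, k = 12),
               class = "nanosep_conditioning_error")
  expect_error(residual_error(m1, tp[0, ]), class = "nanosep_domain_error")
})

test_that("queries outside the fiducial hull are flagged as extrapolation", {
  fr <- frame_geometry(96, 96, 200)
  tp <- warped_truth_pairs(20, warp_identity(fr), fr, seed = 3,
                           margin_frac = 0.25)
  m <- build_lwm_transform(tp, k = 12)
  expect_warning(
    out <- apply_transform(m, tibble::tibble(x_nm = 100, y_nm = 100)),
    "extrapolated")
  expect_true(out$extrapolated)
})

test_that("serialized models survive a round trip", {
  fr <- frame_geometry(96, 96, 200)
  tp <- warped_truth_pairs(24, warp_random(fr, 30, seed = 5), fr, seed = 4)
  m <- build_lwm_transform(tp[1:18, ], k = 12)
  m$residual_nm <- residual_error(m, tp[19:24, ])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_registration_model(m, path)
  m2 <- read_registration_model(path)
  expect_equal(m2$residual_nm, m$residual_nm, tolerance = 1e-6)
  expect_equal(m2$k, m$k)
  q <- tibble::tibble(x_nm = c(6000, 12000), y_nm = c(7000, 9000))
  expect_equal(suppressWarnings(apply_transform(m2, q)),
               suppressWarnings(apply_transform(m, q)), tolerance = 1e-6)
})

test_that("residual misalignment does not grow with bead brightness", {
  fr <- frame_geometry(128, 128, 200)
  opA <- test_optics(594); opB <- test_optics(647)
  w <- warp_random(fr, 30, seed = 6)
  mean_r <- vapply(c(200, 2000, 20000), function(photons) {
    rs <- vapply(1:2, function(seed) {
      bf <- render_bead_field(30, w, fr, opA, opB, noise_model(5, 2, 1),
                              seed = 40 + seed, bead_photons = photons)
      la <- localize_spots(bf$image_a)
      lb <- localize_spots(bf$image_b)
      pairs <- match_fiducials(la, lb)
      ho <- seq(4, nrow(pairs), by = 4)
      m <- build_lwm_transform(pairs[-ho, ], k = 12)
      residual_error(m, pairs[ho, ])
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_r) < 0))
})
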