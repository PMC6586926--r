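test_that("white, black and greyscale map to the CIELAB neutral axis", {
  expect_equal(srgb_to_lab(c(255, 255, 255), scale = "byte")[1, ],
               c(L = 100, A = 0, B = 0), tolerance = 1e-9)
  expect_equal(srgb_to_lab(c(0, 0, 0), scale = "byte")[1, ],
               c(L = 0, A = 0, B = 0), tolerance = 1e-9)

  # mid grey against the step-by-step CIE oracle
  lab119 <- srgb_to_lab(c(119, 119, 119), scale = "byte")
  expect_equal(unname(lab119[1, "L"]), oracle_grey_L(119 / 255),
               tolerance = 1e-9)
  expect_true(abs(lab119[1, "L"] - 50) < 0.1)

  # greyscale ramp: strictly increasing L*, exactly neutral a*/b*
  ramp <- (0:255) / 255
  lab <- srgb_to_lab(cbind(ramp, ramp, ramp))
  expect_true(all(diff(lab[, "L"]) > 0))
  expect_true(all(abs(lab[, "A"]) < 1e-6))
  expect_true(all(abs(lab[, "B"]) < 1e-6))
})

test_that("sRGB <-> Lab round trip is the identity and out-of-gamut colours are clipped and flagged", {
  set.seed(1)
  rgb <- matrix(runif(3000), ncol = 3)
  lab <- srgb_to_lab(rgb)
  back <- lab_to_srgb(lab)
  expect_lt(max(abs(back - rgb)), 0.5 / 255)
  expect_false(any(attr(back, "clipped")))
  # Lab-space round trip for in-gamut colours
  expect_lt(max(abs(srgb_to_lab(back) - lab)), 1e-9)

  # L* = 100 maps back to reference white
  expect_equal(lab_to_srgb(c(100, 0, 0), scale = "byte")[1, ],
               c(R = 255, G = 255, B = 255), tolerance = 1e-9)

  # forced out-of-gamut colour: clipped, flagged, still in range
  oog <- lab_to_srgb(c(50, 200, 200))
  expect_true(attr(oog, "clipped"))
  expect_true(all(oog >= 0 & oog <= 1))
})

test_that("conversion agrees with an independent reference converter", {
  set.seed(2)
  rgb <- matrix(runif(150), ncol = 3)
  ours <- srgb_to_lab(rgb)
  ref <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  expect_lt(max(delta_e(ours, ref)), 0.5)
})

test_that("input domain errors name the offending channel", {
  expect_error(srgb_to_lab(c(300, 10, 10), scale = "byte"), "channel R")
  expect_error(srgb_to_lab(c(0.2, -0.1, 0.2)), "channel G")
  expect_error(srgb_to_lab(c(0.2, 0.3, NA)), "channel B")
  expect_error(lab_to_srgb(c(50, Inf, 0)), "non-finite")
})

test_that("chart calibration: identity data give the identity map with zero residuals", {
  ref <- as.matrix(colorchecker_reference()[, c("R", "G", "B")])
  obs <- chart_observation(ref, ref, scale = "byte")
  corr <- fit_colour_correction(obs)
  expect_equal(corr$matrix, diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(corr$offset, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(max(corr$residual_deltaE), 1e-6)
})

test_that("chart calibration recovers a known 3x3 channel mixing", {
  ref <- as.matrix(colorchecker_reference()[, c("R", "G", "B")]) / 255
  D <- matrix(c(0.90, 0.08, 0.02,
                0.05, 0.85, 0.10,
                0.02, 0.07, 0.91), 3, 3, byrow = TRUE)
  meas <- distort_colours(ref, D)
  corr <- fit_colour_correction(chart_observation(meas, ref))
  expect_lt(max(abs(corr$matrix %*% D - diag(3))), 1e-6)
  expect_lt(max(abs(corr$offset)), 1e-6)
  expect_lt(corr$mean_deltaE_after, 0.1)
  expect_lt(corr$mean_deltaE_after, corr$mean_deltaE_before)
})

test_that("calibration recovery holds across random well-conditioned distortions", {
  ref <- as.matrix(colorchecker_reference()[, c("R", "G", "B")]) / 255
  set.seed(3)
  for (i in 1:20) {
    D <- random_distortion()
    expect_lt(kappa(D, exact = TRUE), 10)
    corr <- fit_colour_correction(chart_observation(distort_colours(ref, D), ref))
    expect_lt(max(abs(corr$matrix %*% D - diag(3))), 1e-6)
  }
})

test_that("under-determined or degenerate patch sets are rejected", {
  ref <- as.matrix(colorchecker_reference()[, c("R", "G", "B")]) / 255
  expect_error(chart_observation(ref[1:3, ], ref[1:3, ]), "at least 4")
  expect_error(fit_colour_correction(ref[1:4, ], ref[1:4, ], model = "affine"),
               NA) # 4 patches suffice for affine
  grey <- matrix(rep(c(0.2, 0.4, 0.6, 0.8), 3), ncol = 3) # rank-1 design
  expect_error(fit_colour_correction(grey, grey, model = "affine"),
               "rank-deficient")
  expect_error(chart_observation(ref[1:5, ], ref[1:5, ],
                                 patch_id = c(1, 1, 2, 3, 4)), "unique")
})

test_that("applying a correction is deterministic, near-identity for the identity map, and clips flagged", {
  ref <- as.matrix(colorchecker_reference()[, c("R", "G", "B")]) / 255
  ident <- fit_colour_correction(chart_observation(ref, ref))
  set.seed(4)
  x <- matrix(runif(300), ncol = 3)
  y <- apply_colour_correction(x, ident)
  expect_lt(max(abs(y - x)), 1 / 255)
  expect_identical(y, apply_colour_correction(x, ident))

  # a gain > 1 pushes bright colours out of range: clipped and flagged
  gain <- structure(list(matrix = diag(3) * 1.5, offset = c(0, 0, 0),
                         model = "linear", white_point = "D65"),
                    class = "colour_correction")
  out <- apply_colour_correction(matrix(c(0.95, 0.95, 0.95), 1), gain)
  expect_true(attr(out, "clipped"))
  expect_true(all(out <= 1))
})

test_that("colour corrections survive a JSON round trip", {
  ref <- as.matrix(colorchecker_reference()[, c("R", "G", "B")]) / 255
  set.seed(5)
  corr <- fit_colour_correction(chart_observation(distort_colours(ref, random_distortion()), ref))
  path <- withr::local_tempfile(fileext = ".json")
  write_colour_correction(corr, path)
  corr2 <- read_colour_correction(path)
  expect_equal(corr2$matrix, corr$matrix, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(corr2$offset, corr$offset, tolerance = 1e-12)
  x <- matrix(runif(30), ncol = 3)
  expect_equal(apply_colour_correction(x, corr2),
               apply_colour_correction(x, corr), tolerance = 1e-9)
})
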