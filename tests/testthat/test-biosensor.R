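test_that("synthetic array units carry the programmed linear grays", {
  img <- synth_array_image(c(0.1, 1), gain = 17.62, intercept = 30,
                           noise_variance = 0, size = 128, radius = 20)
  expect_s3_class(img, "psi_array_image")
  expect_equal(diff(img$nominal), 17.62 * 0.9)   # 15.858
  # noiseless: unit pixels equal the nominal exactly
  units <- extract_units(img)
  expect_equal(length(units$masks), 2)
  for (i in 1:2)
    expect_lt(abs(units$agl[i] - sort(img$nominal)[i]), 1e-9)
})

test_that("synthetic arrays are reproducible and validate their layout", {
  a <- synth_array_image(c(0.5, 1), noise_variance = 0.3, seed = 5,
                         size = 128, radius = 20)
  b <- synth_array_image(c(0.5, 1), noise_variance = 0.3, seed = 5,
                         size = 128, radius = 20)
  expect_identical(a$rgb, b$rgb)
  expect_error(synth_array_image(c(1, 2), radius = 80, size = 128),
               "overlap")
  expect_error(synth_array_image(1, gain = -1), "gain")
  expect_error(synth_array_image(0, intercept = 5, background = 8),
               "darker")
})

test_that("segmentation recovers the circular units with high overlap", {
  img <- synth_array_image(c(0.1, 0.25, 0.5, 1), gain = 17.62,
                           intercept = 30, noise_variance = 0.2, seed = 6)
  units <- extract_units(img)
  expect_equal(length(units$masks), 4)
  size <- dim(img$rgb)[1]
  rg <- matrix(rep(seq_len(size) - 0.5, size), size, size); cg <- t(rg)
  for (i in 1:4) {
    truth <- (rg - img$centers[i, "row"])^2 +
      (cg - img$centers[i, "col"])^2 <= img$radius^2
    ious <- vapply(units$masks, function(m) mask_iou(m, truth), 0)
    expect_gte(max(ious), 0.95)
  }
})

test_that("segmentation fails cleanly on background-only images", {
  blank <- array(8, c(64, 64, 3))
  expect_error(extract_units(blank), "no array units")
})

test_that("interior holes are closed without changing the component count", {
  img <- synth_array_image(c(0.5, 1), intercept = 40, noise_variance = 0,
                           size = 128, radius = 20)
  # poke dark holes inside each unit
  rgb <- img$rgb
  for (i in 1:2) {
    r0 <- round(img$centers[i, "row"]); c0 <- round(img$centers[i, "col"])
    rgb[r0 + (-1:1), c0 + (-1:1), 1] <- 0
  }
  units <- extract_units(rgb)
  expect_equal(length(units$masks), 2)
  # the holes are inside the recovered masks (filled)
  for (i in 1:2) {
    r0 <- round(img$centers[i, "row"]); c0 <- round(img$centers[i, "col"])
    expect_true(any(vapply(units$masks, function(m) m[r0, c0], NA)))
  }
})

test_that("segmentation ignores a uniform sub-threshold background shift", {
  img <- synth_array_image(c(0.5, 1), intercept = 40, noise_variance = 0,
                           size = 128, radius = 20, background = 5)
  u1 <- extract_units(img)
  rgb2 <- img$rgb
  rgb2[, , 1][rgb2[, , 1] < 10] <- rgb2[, , 1][rgb2[, , 1] < 10] + 6
  u2 <- extract_units(rgb2)
  expect_equal(length(u1$masks), length(u2$masks))
  expect_equal(u1$masks[[1]], u2$masks[[1]])
})

test_that("calibration line recovers noiseless points exactly", {
  x <- c(0.1, 0.25, 0.5, 1)
  fit <- concentration_fit(x, 17.62 * x + 0.837)
  expect_equal(fit$slope, 17.62, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.837, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  fit2 <- concentration_fit(c(0, 1, 2), c(0, 2, 4))
  expect_equal(unname(coef(fit2)), c(0, 2), tolerance = 1e-12)
  expect_error(concentration_fit(c(0, 1), c(0, 1)), "at least 3")
})

test_that("calibration object methods work", {
  fit <- concentration_fit(c(0, 1, 2, 3), c(0.1, 2.2, 3.9, 6.1),
                           sigma = 0.27)
  expect_output(print(fit), "LOD")
  expect_equal(predict(fit, 2), fit$intercept + 2 * fit$slope)
  expect_false(is.na(fit$lod))
})

test_that("detection limit reproduces the 3-sigma arithmetic and scaling", {
  expect_equal(detection_limit(0.27, 17.62), 3 * 0.27 / 17.62 * 1000)
  expect_equal(detection_limit(0, 17.62), 0)
  expect_equal(detection_limit(0.54, 17.62), 2 * detection_limit(0.27, 17.62))
  expect_equal(detection_limit(0.27, 2 * 17.62),
               detection_limit(0.27, 17.62) / 2)
  expect_error(detection_limit(0.27, 0), "slope")
  expect_error(detection_limit(-1, 1), "sigma")
})
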