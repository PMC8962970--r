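test_that("non-local means maps constants to constants and matches brute force", {
  expect_equal(nlm_smooth(const_image(50, 32), 21, 7, h = 10),
               const_image(50, 32))
  img <- noisy_const(80, 14, 0.4, seed = 12)
  fast <- nlm_smooth(img, search = 7, patch = 3, h = 60)
  expect_equal(fast, bf_nlm(img, 7, 3, 60), tolerance = 1e-8)
})

test_that("non-local means strongly reduces the variance of gamma noise", {
  img <- noisy_const(50, 128, 0.3, seed = 13)
  sm <- nlm_smooth(img, h = nlm_h(img, factor = 20))
  expect_lt(var(as.vector(sm)), 0.1 * var(as.vector(img)))
})

test_that("non-local means validates its parameters", {
  img <- const_image(50, 32)
  expect_error(nlm_smooth(img, 21, 7, h = 0), "positive")
  expect_error(nlm_smooth(img, 20, 7, h = 1), "odd")
  expect_error(nlm_smooth(img, 7, 7, h = 1), "odd")
})

test_that("compression coefficient follows exp(-I/ref)", {
  ref <- const_image(50, 8)
  expect_equal(compression_coefficient(const_image(50, 8), ref),
               matrix(exp(-1), 8, 8))
  expect_equal(compression_coefficient(matrix(0, 8, 8), ref),
               matrix(1, 8, 8))
  expect_equal(compression_coefficient(const_image(100, 8), ref),
               matrix(exp(-2), 8, 8))
  expect_error(compression_coefficient(const_image(50, 8), matrix(0, 8, 8)),
               "luminance floor")
})

test_that("one compression step matches the update rule arithmetic", {
  # single pixel at 100 over reference 50: down-step by e^-2 * 100 / 10
  out <- gvc_iterate(matrix(100, 1, 1), matrix(50, 1, 1), k_max = 1)
  expect_equal(out[1, 1], 100 - exp(-2) * 100 / 10, tolerance = 1e-12)
  # below the reference the same step is taken upward
  out_up <- gvc_iterate(matrix(10, 1, 1), matrix(50, 1, 1), k_max = 1)
  expect_equal(out_up[1, 1], 10 + exp(-10 / 50) * 10 / 10, tolerance = 1e-12)
  # k_max = 0 is the identity
  img <- noisy_const(50, 16, 0.5, seed = 14)
  expect_identical(gvc_iterate(img, const_image(50, 16), 0), img)
  expect_error(gvc_iterate(img, const_image(50, 16), -1), "non-negative")
})

test_that("compression contracts toward the reference and stays non-negative", {
  set.seed(15)
  img <- matrix(runif(400, 0, 255), 20, 20)
  ref <- const_image(60, 20)
  out <- gvc_iterate(img, ref, 1)
  gam <- exp(-img / ref)
  no_overshoot <- gam * img / 10 <= 2 * abs(img - ref)
  expect_true(all((abs(out - ref) <= abs(img - ref))[no_overshoot]))
  # many iterations never produce negative intensities
  out50 <- gvc_iterate(img, ref, 50)
  expect_true(all(out50 >= 0))
})

test_that("compression is deterministic and preserves extent", {
  img <- noisy_const(50, 32, 0.5, seed = 16)
  ref <- nlm_smooth(img, h = 200)
  expect_identical(gvc_iterate(img, ref, 20), gvc_iterate(img, ref, 20))
  expect_equal(dim(gvc_iterate(img, ref, 20)), dim(img))
})

test_that("histogram peak uses the rounded mode with ties toward the reference", {
  img <- matrix(c(49.6, 49.8, 51.4, 51.2, 48.9, 50.1), 2, 3)
  # rounded values: 50 50 51 51 49 50 -> modal bin 50, sub-bin refinement
  # keeps the peak inside that bin
  expect_lt(abs(qdenoise:::hist_peak(img, 50) - 50), 0.5)
  # a symmetric concentration peaks exactly at its centre
  sym <- matrix(c(49, 50, 50, 50, 51), 1, 5)
  expect_equal(qdenoise:::hist_peak(sym, 50), 50)
  tie <- matrix(c(40, 40, 60, 60), 2, 2)
  expect_equal(qdenoise:::hist_peak(tie, 45), 40)
  expect_equal(qdenoise:::hist_peak(tie, 55), 60)
})

test_that("iteration count from the CV is monotone, clamps, and is 0 at 0", {
  curve <- structure(data.frame(delta = c(0, 0.3, 0.6, 0.9),
                                k_max = c(0, 20, 150, 500)),
                     class = c("gvc_calibration", "data.frame"))
  expect_identical(iterations_from_cv(0, curve), 0L)
  k1 <- iterations_from_cv(0.3, curve)
  k2 <- iterations_from_cv(0.8, curve)
  expect_lte(k1, k2)
  expect_warning(k3 <- iterations_from_cv(1.4, curve), "clamping")
  expect_identical(k3, 500L)
  expect_error(iterations_from_cv(-1, curve), "non-negative")
})

test_that("the packaged calibration curve is monotone and starts at zero", {
  curve <- qdenoise:::default_gvc_calibration()
  expect_equal(curve$delta[1], 0)
  expect_equal(curve$k_max[1], 0)
  expect_true(!is.unsorted(curve$delta))
  expect_true(!is.unsorted(curve$k_max))
})

test_that("calibration curves round-trip through CSV", {
  curve <- structure(data.frame(delta = c(0, 0.5), k_max = c(0, 100)),
                     class = c("gvc_calibration", "data.frame"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_gvc_calibration(curve, path)
  rt <- read_gvc_calibration(path)
  expect_equal(rt$delta, curve$delta)
  expect_equal(rt$k_max, curve$k_max)
})
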