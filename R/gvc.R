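#' Non-local means smoothing
#'
#' Patch-similarity weighted average over a square search window: each
#' output pixel is \eqn{\sum_k w(i,k) I_k} with
#' \eqn{w(i,k) = \exp(-\|P_i - P_k\|^2 / h^2) / Z(i)} and \eqn{Z(i)} the
#' normalizer that makes the weights sum to one.  Serves as the compression
#' reference for gray-value compression; the non-local average preserves
#' edges that a mean or Gaussian filter would blur.
#'
#' @param image numeric matrix (gray levels).
#' @param search search window side (odd; default 21).
#' @param patch patch side (odd, smaller than `search`; default 7).
#' @param h smoothing strength, in the units of the summed squared patch
#'   difference; larger `h` averages more aggressively.  A practical choice
#'   is about `10 * sigma` for noise of standard deviation `sigma`
#'   (see [nlm_h()]).
#' @return smoothed numeric matrix of the same size.
#' @export
nlm_smooth <- function(image, search = 21, patch = 7, h) {
  check_gray_image(image)
  if (search %% 2 == 0 || patch %% 2 == 0 || patch >= search)
    stop("`search` and `patch` must be odd with patch < search",
         call. = FALSE)
  if (!is.numeric(h) || length(h) != 1 || h <= 0)
    stop("`h` must be a single positive number", call. = FALSE)
  cpp_nlm(image, as.integer(search), as.integer(patch), h)
}

#' Automatic NLM smoothing strength from the image noise level
#'
#' Sets `h = factor * sigma_hat` where `sigma_hat = delta * AGL` is the
#' noise standard deviation implied by the coefficient of variation.  With
#' the default `factor = 10`, patches one noise-sd apart per pixel
#' (expected summed squared difference `~2 * p^2 * sigma^2` for 7x7
#' patches) still receive substantial weight, which is the heavily
#' smoothing regime appropriate for a compression reference.
#'
#' @param image numeric matrix.
#' @param delta optional known coefficient of variation; estimated with
#'   [estimate_cv()] when missing.
#' @param factor multiplier on the implied noise sd.
#' @return positive scalar `h`.
#' @export
nlm_h <- function(image, delta = NULL, factor = 10) {
  if (is.null(delta)) delta <- estimate_cv(image)$delta
  max(factor * delta * mean(image), 1e-8)
}

#' Per-pixel gray compression coefficient
#'
#' \eqn{\gamma(x, y) = \exp(-I(x, y) / \tilde I(x, y))}: strictly decreasing
#' in the ratio of the pixel to its non-local-means reference, equal to
#' \eqn{e^{-1}} where the pixel matches the reference and approaching 1 for
#' pixels far below it.
#'
#' @param image numeric matrix.
#' @param reference strictly positive reference image (NLM-smoothed).
#' @return matrix of coefficients in (0, 1] for non-negative `image`.
#' @export
compression_coefficient <- function(image, reference) {
  check_gray_image(image)
  if (any(reference <= 0))
    stop("reference must be strictly positive; add a luminance floor ",
         "before compressing", call. = FALSE)
  exp(-image / reference)
}

#' Iterative gray-value compression
#'
#' Per iteration, pixels at or above the reference move down by
#' \eqn{\gamma I / 10} and pixels below it move up by the same step, with
#' \eqn{\gamma} recomputed each iteration from the current image against
#' the fixed reference.  After enough iterations the gray histogram
#' concentrates near the reference level.
#'
#' @param image numeric matrix (the noisy image).
#' @param reference strictly positive reference image, fixed across
#'   iterations.
#' @param k_max number of compression iterations (0 = identity).
#' @param step_divisor step-size constant (the 10 above).
#' @return compressed numeric matrix.
#' @export
gvc_iterate <- function(image, reference, k_max, step_divisor = 10) {
  check_gray_image(image)
  if (!is.numeric(k_max) || length(k_max) != 1 || k_max < 0)
    stop("`k_max` must be a non-negative count", call. = FALSE)
  if (any(reference <= 0))
    stop("reference must be strictly positive", call. = FALSE)
  cpp_gvc_run(image, reference, as.integer(k_max), step_divisor)
}

# Mode of the integer-rounded gray histogram; ties broken toward ref_mean.
hist_peak <- function(image, ref_mean) cpp_hist_peak(image, ref_mean)

#' Calibrate the CV-to-iteration-count mapping for GVC
#'
#' The iteration count of gray-value compression is driven by the image's
#' coefficient of variation.  The mapping is derived empirically: for
#' constant images at the given gray levels and multiplicative gamma noise
#' variances, find the smallest `k` at which compression is complete --
#' the peak of the integer gray histogram falls within `peak_tol` of the
#' true gray value *and* the mean absolute distance to the reference has
#' reached the compression oscillation floor (`floor_tol`; a converged
#' pixel keeps stepping by about `gamma * I / 10 ~ 1.8` gray around the
#' reference, so the mean distance cannot drop much below 1) -- then fit a
#' monotone (isotonic) curve of `k` against the measured coefficient of
#' variation.  The peak criterion alone is met within a handful of
#' iterations, long before the skewed bright tail of the gamma noise has
#' been compressed, so it is paired with the distance criterion that
#' captures the near-delta histogram concentration compression is meant to
#' produce.  The fitted curve ships with the package
#' (`extdata/gvc_calibration.csv`) and can be regenerated with this
#' function.
#'
#' @param grays base gray levels of the calibration images.
#' @param variances gamma noise variances.
#' @param seeds noise seeds per condition.
#' @param size image side length.
#' @param k_cap largest iteration count tried.
#' @param peak_tol histogram-peak tolerance in gray levels (0.5).
#' @param floor_tol compression-complete threshold on mean `|I - ref|`
#'   (gray levels).
#' @param h_factor NLM smoothing factor passed to [nlm_h()].
#' @return object of class `gvc_calibration`: data frame with columns
#'   `delta`, `k_max` (monotone non-decreasing), plus attribute `points`
#'   holding the raw (delta, k) measurements.
#' @export
calibrate_gvc <- function(grays = c(50, 60), variances = seq(0.1, 0.9, 0.1),
                          seeds = 1:5, size = 256, k_cap = 800,
                          peak_tol = 0.5, floor_tol = 1.2, h_factor = 20) {
  deltas <- numeric(0); ks <- numeric(0)
  for (g in grays) for (v in variances) for (s in seeds) {
    clean <- matrix(g, size, size)
    noisy <- apply_multiplicative_noise(clean, v, seed = s * 10000 + g * 10 +
                                          round(100 * v))
    delta <- estimate_cv(noisy)$delta
    ref <- nlm_smooth(noisy, h = nlm_h(noisy, delta, h_factor))
    res <- cpp_gvc_floor_k(noisy, pmax(ref, .Machine$double.eps),
                           as.integer(k_cap), 10, floor_tol, peak_tol, g)
    deltas <- c(deltas, delta); ks <- c(ks, res$k)
  }
  ord <- order(deltas)
  iso <- stats::isoreg(deltas[ord], ks[ord])
  curve <- data.frame(delta = c(0, iso$x), k_max = ceiling(c(0, iso$yf)))
  curve <- curve[!duplicated(curve$delta), ]
  curve$k_max <- cummax(curve$k_max)
  structure(curve, class = c("gvc_calibration", "data.frame"),
            points = data.frame(delta = deltas, k = ks))
}

#' Write / read a GVC calibration curve as CSV
#'
#' @param curve a [calibrate_gvc()] result (columns delta, k_max).
#' @param path CSV path.
#' @return `write_gvc_calibration`: the path, invisibly;
#'   `read_gvc_calibration`: the curve.
#' @export
write_gvc_calibration <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[, c("delta", "k_max")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_gvc_calibration
#' @export
read_gvc_calibration <- function(path) {
  curve <- utils::read.csv(path)
  stopifnot(all(c("delta", "k_max") %in% names(curve)))
  structure(curve, class = c("gvc_calibration", "data.frame"))
}

default_gvc_calibration <- function() {
  read_gvc_calibration(system.file("extdata", "gvc_calibration.csv",
                                   package = "qdenoise", mustWork = TRUE))
}

#' Iteration count from the coefficient of variation
#'
#' Monotone non-decreasing lookup of the GVC iteration budget from the
#' measured coefficient of variation, by linear interpolation of the
#' calibration curve.  A zero coefficient (noiseless image) maps to zero
#' iterations; values above the calibrated range are clamped with a
#' warning.
#'
#' @param delta coefficient of variation (scalar or a [estimate_cv()]
#'   result).
#' @param curve calibration curve; the packaged one when `NULL`.
#' @return integer iteration count.
#' @export
iterations_from_cv <- function(delta, curve = NULL) {
  if (inherits(delta, "cv_estimate")) delta <- delta$delta
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0)
    stop("`delta` must be a single non-negative number", call. = FALSE)
  if (is.null(curve)) curve <- default_gvc_calibration()
  if (delta > max(curve$delta)) {
    warning("coefficient of variation ", format(delta, digits = 3),
            " above calibrated range; clamping")
    delta <- max(curve$delta)
  }
  k <- stats::approx(curve$delta, curve$k_max, xout = delta,
                     rule = 2, ties = "ordered")$y
  as.integer(ceiling(k))
}
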