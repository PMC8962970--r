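#' Synthetic porous-silicon array fluorescence image
#'
#' Generates an RGB image of circular porous-silicon array units on a dark
#' background, emulating the linear relation between red-channel gray level
#' and target concentration: each unit's nominal red gray is
#' `intercept + gain * concentration`, then the red channel is corrupted by
#' multiplicative gamma noise.  This is a synthetic stand-in for real
#' micrographs; the ground-truth layout travels with the object so
#' segmentation and recovery can be scored exactly.
#'
#' @param concentrations per-unit concentrations in nM (one circle each).
#' @param gain gray-difference per nM (slope of the emulated calibration).
#' @param intercept baseline red gray level of a unit at concentration 0.
#' @param noise_variance multiplicative gamma noise variance (0 disables).
#' @param seed integer seed; a fixed seed reproduces the image exactly.
#' @param size image side in pixels.
#' @param radius unit radius in pixels (layout is a near-square grid; an
#'   error is raised if the requested circles cannot fit without overlap).
#' @param background background gray level (must stay below every unit).
#' @return object of class `psi_array_image`: list with `rgb`
#'   (size x size x 3 array, gray levels 0-255), `centers`, `radius`,
#'   `nominal` (per-unit true red gray), `concentrations`.
#' @export
synth_array_image <- function(concentrations, gain = 17.62,
                              intercept = 30, noise_variance = 0,
                              seed = NULL, size = 256, radius = 36,
                              background = 8) {
  if (gain <= 0) stop("`gain` must be positive", call. = FALSE)
  n <- length(concentrations)
  nominal <- intercept + gain * concentrations
  if (background >= min(nominal))
    stop("background must be darker than every unit", call. = FALSE)
  ncol_g <- ceiling(sqrt(n)); nrow_g <- ceiling(n / ncol_g)
  pitch_c <- size / ncol_g; pitch_r <- size / nrow_g
  if (2 * radius + 8 > min(pitch_c, pitch_r))
    stop("units would overlap: reduce `radius` or enlarge `size`",
         call. = FALSE)
  centers <- t(sapply(seq_len(n) - 1L, function(i) {
    c(row = (i %/% ncol_g + 0.5) * pitch_r,
      col = (i %% ncol_g + 0.5) * pitch_c)
  }))
  rg <- matrix(rep(seq_len(size) - 0.5, size), size, size)  # row coordinate
  cg <- t(rg)                                               # col coordinate
  red <- matrix(background, size, size)
  for (i in seq_len(n)) {
    inside <- (rg - centers[i, "row"])^2 + (cg - centers[i, "col"])^2 <=
      radius^2
    red[inside] <- nominal[i]
  }
  if (noise_variance > 0)
    red <- apply_multiplicative_noise(red, noise_variance, seed)
  rgb <- array(0, c(size, size, 3))
  rgb[, , 1] <- pmin(pmax(red, 0), 255)
  rgb[, , 2] <- pmin(red * 0.08, 255)   # faint leakage into G/B
  rgb[, , 3] <- pmin(red * 0.04, 255)
  structure(list(rgb = rgb, centers = centers, radius = radius,
                 nominal = nominal, concentrations = concentrations),
            class = "psi_array_image")
}

#' @export
print.psi_array_image <- function(x, ...) {
  cat("Synthetic PSi array image:", dim(x$rgb)[1], "x", dim(x$rgb)[2],
      "with", nrow(x$centers), "units (radius", x$radius, "px)\n")
  invisible(x)
}

#' Segment porous-silicon array units
#'
#' Extracts the red channel (the signal carrier), thresholds it by Otsu's
#' method, fills holes and smooths unit edges by morphological closing plus
#' opening, and labels connected components -- one mask per array unit.
#'
#' @param image a `psi_array_image`, or an RGB array (H x W x 3, gray
#'   levels 0-255).
#' @param min_area drop components smaller than this many pixels.
#' @param brush_size diameter of the disc brush used for closing/erosion.
#' @param smooth_sigma Gaussian blur (pixels) applied to the red channel
#'   before thresholding, so multiplicative noise cannot fragment the
#'   binary mask (the mask would otherwise exclude dark noise dips inside
#'   units and bias their mean gray upward).  Per-unit gray levels are
#'   always measured on the raw channel.  Set to 0 to threshold raw
#'   pixels.
#' @return list with `masks` (list of logical matrices), `gray` (the red
#'   channel as a gray image), `agl` (per-unit mean gray over an
#'   interior-eroded copy of the mask, so threshold placement cannot mix
#'   background into the readout), `labels` (integer component map).
#' @export
extract_units <- function(image, min_area = 50, brush_size = 5,
                          smooth_sigma = 2) {
  rgb <- if (inherits(image, "psi_array_image")) image$rgb else image
  if (length(dim(rgb)) != 3 || dim(rgb)[3] < 3)
    stop("need an RGB image", call. = FALSE)
  red <- rgb[, , 1]
  x <- red / 255
  xs <- if (smooth_sigma > 0)
    EBImage::imageData(EBImage::gblur(EBImage::Image(x),
                                      sigma = smooth_sigma)) else x
  thr <- EBImage::otsu(EBImage::Image(xs), range = c(0, 1))
  mask <- xs > thr
  brush <- EBImage::makeBrush(brush_size, shape = "disc")
  m <- EBImage::Image(mask * 1)
  m <- EBImage::fillHull(m)
  m <- EBImage::closing(m, brush)
  m <- EBImage::opening(m, brush)   # edge smoothing without net shrinkage
  lab <- EBImage::bwlabel(m)
  labm <- EBImage::imageData(lab)
  ids <- setdiff(unique(as.vector(labm)), 0)
  ids <- ids[vapply(ids, function(i) sum(labm == i), 0) >= min_area]
  if (length(ids) == 0)
    stop("no array units found in the image", call. = FALSE)
  # order units row-major by centroid for a stable unit index; rows are
  # binned by the typical unit diameter so jitter in the centroid cannot
  # scramble units that sit on the same grid row
  cent <- t(vapply(ids, function(i) {
    w <- which(labm == i, arr.ind = TRUE)
    colMeans(w)
  }, numeric(2)))
  areas <- vapply(ids, function(i) sum(labm == i), 0)
  diam <- 2 * sqrt(stats::median(areas) / pi)
  ids <- ids[order(round(cent[, 1] / diam), cent[, 2])]
  masks <- lapply(ids, function(i) labm == i)
  # gray levels are measured on an interior-eroded copy of each mask: the
  # smoothed-channel threshold can place the mask boundary a pixel or two
  # outside the true unit, and boundary pixels would mix in background
  margin <- 2 * ceiling(smooth_sigma) + 3
  mbrush <- EBImage::makeBrush(margin, shape = "disc")
  measure <- lapply(masks, function(m) {
    mm <- EBImage::imageData(EBImage::erode(EBImage::Image(m * 1),
                                            mbrush)) > 0
    if (any(mm)) mm else m
  })
  structure(list(masks = masks, gray = red,
                 agl = vapply(measure, function(m) mean(red[m]), 0),
                 labels = labm),
            class = "psi_units")
}

#' Mask overlap (intersection over union)
#'
#' @param a,b logical matrices.
#' @return scalar IoU in `[0, 1]`.
#' @export
mask_iou <- function(a, b) sum(a & b) / sum(a | b)

#' Fit the gray-difference / concentration calibration line
#'
#' Ordinary least squares of the average-gray-level difference on
#' concentration; the goodness of fit is the squared Pearson correlation.
#' When the standard deviation `sigma` of repeated blank (pre-reaction)
#' measurements is supplied, the 3-sigma/slope detection limit is attached.
#'
#' @param concs concentrations in nM (at least 3).
#' @param delta_agls gray differences (AGL after minus before reaction).
#' @param sigma optional blank-measurement standard deviation (gray
#'   levels).
#' @return object of class `psi_calibration` with `slope` (gray per nM),
#'   `intercept`, `r_squared`, `sigma`, `lod` (pM, or NA), and the
#'   underlying `lm` fit.
#' @export
concentration_fit <- function(concs, delta_agls, sigma = NULL) {
  if (length(concs) < 3 || length(concs) != length(delta_agls))
    stop("need at least 3 matched (concentration, gray-difference) points",
         call. = FALSE)
  fit <- stats::lm(delta_agls ~ concs)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  r2 <- stats::cor(concs, delta_agls)^2
  lod <- if (!is.null(sigma)) detection_limit(sigma, slope) else NA_real_
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 sigma = if (is.null(sigma)) NA_real_ else sigma,
                 lod = lod, fit = fit,
                 data = data.frame(conc = concs, delta_agl = delta_agls)),
            class = "psi_calibration")
}

#' @export
print.psi_calibration <- function(x, ...) {
  cat(sprintf("Calibration: dAGL = %.3f * conc + %.3f   (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  if (!is.na(x$lod))
    cat(sprintf("  sigma = %.3f gray  ->  LOD = 3*sigma/slope = %.1f pM\n",
                x$sigma, x$lod))
  invisible(x)
}

#' @export
summary.psi_calibration <- function(object, ...) {
  print(object)
  print(summary(object$fit))
  invisible(object)
}

#' @export
coef.psi_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.psi_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object$fit))
  concs <- if (is.data.frame(newdata)) newdata$conc else newdata
  object$intercept + object$slope * concs
}

#' @export
plot.psi_calibration <- function(x, ...) {
  plot(x$data$conc, x$data$delta_agl, xlab = "concentration (nM)",
       ylab = expression(Delta * "AGL (gray levels)"),
       main = sprintf("slope %.2f, R2 %.3f", x$slope, x$r_squared), ...)
  graphics::abline(x$fit)
  invisible(x)
}

#' 3-sigma/slope detection limit
#'
#' The limit of detection of the gray-value readout: three times the
#' standard deviation of repeated blank measurements divided by the
#' calibration slope (gray per nM), converted to pM.
#'
#' @param sigma blank-measurement standard deviation (gray levels),
#'   non-negative.
#' @param slope calibration slope (gray per nM), positive.
#' @return detection limit in pM.
#' @examples
#' detection_limit(0.27, 17.62)  # ~46 pM
#' detection_limit(0.27, 9.21)   # ~87.9 pM
#' @export
detection_limit <- function(sigma, slope) {
  if (!is.numeric(slope) || slope <= 0)
    stop("`slope` must be positive", call. = FALSE)
  if (!is.numeric(sigma) || sigma < 0)
    stop("`sigma` must be non-negative", call. = FALSE)
  3 * sigma / slope * 1000
}
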