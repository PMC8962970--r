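#' Eight-direction Laplacian high-frequency map
#'
#' Convolves the image with the 3x3 kernel that has -8 at the center and +1
#' at all eight neighbors.  The border is handled by reflection, so the
#' response has the same extent as the input; the kernel sums to zero, so
#' constant images (and, in the interior, linear ramps) give zero response.
#'
#' @param image numeric matrix, at least 3x3.
#' @return numeric matrix of the same size.
#' @export
laplacian8 <- function(image) {
  check_gray_image(image, min_dim = 3L)
  P <- cpp_reflect_pad(image, 1L)
  H <- nrow(image); W <- ncol(image)
  out <- -8 * image
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    out <- out + P[(2L + dy):(H + 1L + dy), (2L + dx):(W + 1L + dx)]
  }
  out
}

# Sliding-window sum of squared values via a summed-area table; returns the
# (H-w+1) x (W-w+1) map of window energies anchored at the top-left corner.
window_energy_map <- function(hf, w) {
  sq <- hf^2
  S <- matrix(0, nrow(sq) + 1L, ncol(sq) + 1L)
  S[-1, -1] <- apply(sq, 2, cumsum)
  S[-1, -1] <- t(apply(S[-1, -1, drop = FALSE], 1, cumsum))
  H <- nrow(sq); W <- ncol(sq)
  i <- seq_len(H - w + 1L); j <- seq_len(W - w + 1L)
  S[i + w, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
    S[i + w, j, drop = FALSE] + S[i, j, drop = FALSE]
}

#' Select homogeneous windows by Laplacian energy
#'
#' Ranks the disjoint `window_size` x `window_size` tiles of the image by
#' the sum of squared [laplacian8()] responses they contain and picks the
#' `count` lowest-energy tiles; ties in energy are broken in row-major
#' order, so selection is deterministic.  Non-overlap holds by
#' construction.  (Ranking the full stride-1 window set instead would
#' select an extreme order statistic among tens of thousands of
#' overlapping candidates, which systematically under-represents the
#' image's noise level; the tile grid keeps the selection bias of the
#' downstream coefficient-of-variation estimate within its documented
#' bound.)
#'
#' @param image numeric matrix larger than `window_size`.
#' @param window_size square window side (default 20).
#' @param count number of windows wanted (20 for classifier sampling, 8 for
#'   coefficient-of-variation estimation).
#' @return object of class `homog_windows`: data frame with 0-based `row`,
#'   `col`, `size`, `energy` (sorted non-decreasing).
#' @export
select_homogeneous_windows <- function(image, window_size = 20, count = 8) {
  check_gray_image(image, min_dim = 3L)
  H <- nrow(image); W <- ncol(image)
  if (H < window_size || W < window_size)
    stop("image smaller than window_size", call. = FALSE)
  nt <- floor(H / window_size) * floor(W / window_size)
  if (count > nt)
    stop("cannot fit ", count, " non-overlapping ", window_size, "x",
         window_size, " windows in a ", H, "x", W, " image", call. = FALSE)
  E <- window_energy_map(laplacian8(image), window_size)
  ti <- seq(1L, H - window_size + 1L, by = window_size)
  tj <- seq(1L, W - window_size + 1L, by = window_size)
  tiles <- expand.grid(r = ti, c = tj)
  te <- E[cbind(tiles$r, tiles$c)]
  ord <- order(te, tiles$r, tiles$c)[seq_len(count)]
  structure(data.frame(row = tiles$r[ord] - 1L, col = tiles$c[ord] - 1L,
                       size = window_size, energy = te[ord]),
            class = c("homog_windows", "data.frame"))
}

window_pixels <- function(image, row0, col0, size) {
  image[(row0 + 1L):(row0 + size), (col0 + 1L):(col0 + size)]
}

#' Coefficient of variation from homogeneous regions
#'
#' Estimates the image noise level as the mean, over `P` non-overlapping
#' homogeneous windows, of each window's coefficient of variation.  The
#' default `variant = "sd"` uses the standard CV \eqn{s_i/\mu_i};
#' `variant = "var"` uses \eqn{s_i^2/\mu_i} for sensitivity checks.  On
#' constant images carrying multiplicative gamma noise the estimate grows
#' monotonically with the noise variance, which is what makes it usable as
#' the driver for the gray-value-compression iteration count.
#'
#' @param image numeric matrix.
#' @param P number of homogeneous regions (default 8).
#' @param window_size window side (default 20).
#' @param variant `"sd"` (standard CV) or `"var"`.
#' @return object of class `cv_estimate`: list with `delta`, `per_region`
#'   (data frame of sigma2, mu), `P`, `windows`.
#' @export
estimate_cv <- function(image, P = 8, window_size = 20,
                        variant = c("sd", "var")) {
  variant <- match.arg(variant)
  win <- select_homogeneous_windows(image, window_size, P)
  mu <- numeric(P); s2 <- numeric(P)
  for (i in seq_len(P)) {
    px <- window_pixels(image, win$row[i], win$col[i], win$size[i])
    mu[i] <- mean(px)
    s2[i] <- stats::var(as.vector(px))
  }
  if (any(mu == 0))
    stop("degenerate dark region: window mean of 0", call. = FALSE)
  delta <- if (variant == "sd") mean(sqrt(s2) / mu) else mean(s2 / mu)
  structure(list(delta = delta,
                 per_region = data.frame(sigma2 = s2, mu = mu),
                 P = P, windows = win, variant = variant),
            class = "cv_estimate")
}

#' @export
print.cv_estimate <- function(x, ...) {
  cat("Coefficient of variation (", x$variant, " variant): ",
      format(x$delta, digits = 4), " from ", x$P, " regions\n", sep = "")
  invisible(x)
}
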