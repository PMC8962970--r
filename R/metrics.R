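#' Average gray level
#'
#' The arithmetic mean of all pixels -- the biosensing readout, directly
#' proportional to the number of bound quantum dots.
#'
#' @param image numeric matrix.
#' @return scalar.
#' @export
agl <- function(image) mean(image)

#' Root-mean-squared error between two images
#'
#' @param a,b equal-shaped numeric matrices.
#' @return scalar `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  sqrt(mean((a - b)^2))
}

# Valid-region sliding box mean via a summed-area table.
box_mean <- function(img, w) {
  S <- matrix(0, nrow(img) + 1L, ncol(img) + 1L)
  S[-1, -1] <- apply(img, 2, cumsum)
  S[-1, -1] <- t(apply(S[-1, -1, drop = FALSE], 1, cumsum))
  i <- seq_len(nrow(img) - w + 1L); j <- seq_len(ncol(img) - w + 1L)
  (S[i + w, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
     S[i + w, j, drop = FALSE] + S[i, j, drop = FALSE]) / (w * w)
}

#' Structural similarity index
#'
#' Mean local SSIM over sliding windows, product of the luminance,
#' contrast and structure comparisons:
#' \deqn{\mathrm{SSIM} = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'   {(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)}}
#' with the standard stabilizing constants \eqn{C_1 = (K_1 L)^2},
#' \eqn{C_2 = (K_2 L)^2}.  Windows are uniform `window` x `window`
#' (default 7); a Gaussian-weighted 11x11 variant (sd 1.5) is available
#' with `gaussian = TRUE`.
#'
#' @param a,b equal-shaped numeric matrices.
#' @param window uniform window side.
#' @param K1,K2,L SSIM constants (defaults 0.01, 0.03, 255).
#' @param gaussian use the Gaussian-weighted 11x11 window instead.
#' @return scalar in `[-1, 1]`; exactly 1 for identical images.
#' @export
ssim <- function(a, b, window = 7, K1 = 0.01, K2 = 0.03, L = 255,
                 gaussian = FALSE) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  if (gaussian) {
    w <- 11
    g <- exp(-((-5:5)^2) / (2 * 1.5^2)); g <- g / sum(g)
    smooth <- function(m) {
      m2 <- apply(m, 2, function(col) stats::filter(col, g, sides = 2))
      t(apply(m2, 1, function(row) stats::filter(row, g, sides = 2)))
    }
    pad <- 5L
    P <- function(m) cpp_reflect_pad(m, pad)
    crop <- function(m) m[(pad + 1):(nrow(m) - pad),
                          (pad + 1):(ncol(m) - pad), drop = FALSE]
    mu_a <- crop(smooth(P(a))); mu_b <- crop(smooth(P(b)))
    va <- crop(smooth(P(a * a))) - mu_a^2
    vb <- crop(smooth(P(b * b))) - mu_b^2
    vab <- crop(smooth(P(a * b))) - mu_a * mu_b
  } else {
    mu_a <- box_mean(a, window); mu_b <- box_mean(b, window)
    va <- box_mean(a * a, window) - mu_a^2
    vb <- box_mean(b * b, window) - mu_b^2
    vab <- box_mean(a * b, window) - mu_a * mu_b
  }
  s <- ((2 * mu_a * mu_b + C1) * (2 * vab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

#' Benchmark the pipeline over a noise-variance grid
#'
#' Reproduces the simulation-study layout: constant-gray images corrupted
#' by multiplicative gamma noise at each variance, evaluated by AGL, RMSE
#' and SSIM for the raw image (`"unprocessed"`) and the full pipeline
#' (`"proposed"`).
#'
#' @param variances gamma noise variances.
#' @param gray base gray level (default 50).
#' @param seeds integer vector of noise seeds (one run per seed).
#' @param methods subset of `c("unprocessed", "proposed")`.
#' @param size image side length.
#' @param config pipeline configuration for the proposed method.
#' @return data frame with columns variance, method, seed, agl, rmse, ssim;
#'   per-variance means via [summarize_benchmark()].
#' @export
run_benchmark <- function(variances = seq(0.1, 0.9, by = 0.1), gray = 50,
                          seeds = 1:20,
                          methods = c("unprocessed", "proposed"),
                          size = 256, config = qd_config()) {
  methods <- match.arg(methods, several.ok = TRUE)
  clean <- matrix(gray, size, size)
  rows <- vector("list", 0)
  for (v in variances) for (s in seeds) {
    noisy <- apply_multiplicative_noise(clean, v,
                                        seed = s * 1000 + round(100 * v))
    imgs <- list()
    if ("unprocessed" %in% methods) imgs$unprocessed <- noisy
    if ("proposed" %in% methods) imgs$proposed <- denoise(noisy, config)$image
    for (m in names(imgs))
      rows[[length(rows) + 1L]] <-
        data.frame(variance = v, method = m, seed = s,
                   agl = agl(imgs[[m]]), rmse = rmse(imgs[[m]], clean),
                   ssim = ssim(imgs[[m]], clean))
  }
  do.call(rbind, rows)
}

#' @rdname run_benchmark
#' @param results a `run_benchmark()` data frame.
#' @export
summarize_benchmark <- function(results) {
  agg <- stats::aggregate(results[, c("agl", "rmse", "ssim")],
                   by = results[, c("variance", "method")], FUN = mean)
  agg[order(agg$variance, agg$method), ]
}
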