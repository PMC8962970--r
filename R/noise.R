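#' Multiplicative gamma noise field
#'
#' Draws an i.i.d. field from the unit-mean gamma distribution
#' \eqn{N \sim \Gamma(L, L)} with \eqn{L = 1/v}, so that \eqn{E(N) = 1} and
#' \eqn{Var(N) = v = 1/L}.  This is the speckle-like noise model identified
#' for quantum-dot fluorescence on porous silicon: the observed image is the
#' clean image multiplied pointwise by such a field.
#'
#' @param height,width dimensions of the field.
#' @param variance noise variance \eqn{v \in (0, 1]}; the gamma "look" number
#'   is \eqn{L = 1/v}.
#' @param seed optional integer seed for reproducibility.
#' @return a `height x width` numeric matrix with mean ~1.
#' @examples
#' N <- gamma_noise_field(64, 64, variance = 0.5, seed = 1)
#' mean(N)  # ~ 1
#' @export
gamma_noise_field <- function(height, width, variance, seed = NULL) {
  check_variance(variance)
  if (!is.null(seed)) set.seed(seed)
  L <- 1 / variance
  matrix(stats::rgamma(height * width, shape = L, rate = L), height, width)
}

check_variance <- function(variance) {
  if (!is.numeric(variance) || length(variance) != 1L || !is.finite(variance) ||
      variance <= 0 || variance > 1)
    stop("`variance` must be a single value in (0, 1]", call. = FALSE)
  invisible(variance)
}

#' Apply multiplicative gamma noise to a clean image
#'
#' Returns \eqn{F = U \odot N} at full float precision; quantization to
#' 8 bits is a separate, explicit step ([quantize8()]) because clipping and
#' rounding are themselves a source of gray-value depression.
#'
#' @param clean non-negative numeric matrix (gray levels, nominally 0-255).
#' @inheritParams gamma_noise_field
#' @return numeric matrix of the same shape as `clean`.
#' @seealso [gamma_noise_field()], [quantize8()]
#' @export
apply_multiplicative_noise <- function(clean, variance, seed = NULL) {
  check_gray_image(clean)
  clean * gamma_noise_field(nrow(clean), ncol(clean), variance, seed)
}

check_gray_image <- function(img, min_dim = 1L) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(img)) || any(img < 0))
    stop("image must be finite and non-negative", call. = FALSE)
  if (nrow(img) < min_dim || ncol(img) < min_dim)
    stop("image must be at least ", min_dim, "x", min_dim, call. = FALSE)
  invisible(img)
}

#' Quantize a float image to 8 bits
#'
#' Rounds to integers and clips to `[0, value_range]`.
#'
#' @param img numeric matrix.
#' @param value_range nominal maximum (255 for 8-bit).
#' @return integer-valued matrix.
#' @export
quantize8 <- function(img, value_range = 255) {
  pmin(pmax(round(img), 0), value_range)
}

#' The ten noise families of the simulator
#'
#' @return character vector of family names, in canonical order.
#' @export
noise_families <- function() {
  c("poisson", "gamma", "rayleigh", "exponential", "uniform", "gaussian",
    "salt_pepper", "gaussian+exponential", "gaussian+salt_pepper",
    "gamma+salt_pepper")
}

# Default intensity grids per family.  Only the gamma grid is consumed by the
# denoising pipeline; the rest parameterize the classifier's training data.
# gaussian/rayleigh/exponential intensities are additive-noise scales in gray
# levels, uniform is the half-width, salt_pepper the impulse density, poisson
# a photon-count scale (larger = cleaner), gamma the multiplicative variance.
qd_noise_intensities <- function() {
  list(
    poisson = c(0.25, 0.5, 1, 2, 4),
    gamma = c(0.1, 0.3, 0.5, 0.7, 0.9),
    rayleigh = c(5, 10, 15, 20, 25),
    exponential = c(5, 10, 15, 20, 25),
    uniform = c(10, 20, 30, 40, 50),
    gaussian = c(5, 10, 15, 20, 25),
    salt_pepper = c(0.02, 0.05, 0.1, 0.15, 0.2),
    `gaussian+exponential` = c(5, 10, 15, 20, 25),
    `gaussian+salt_pepper` = c(0.02, 0.05, 0.1, 0.15, 0.2),
    `gamma+salt_pepper` = c(0.1, 0.3, 0.5, 0.7, 0.9)
  )
}

rrayleigh <- function(n, scale) scale * sqrt(-2 * log(stats::runif(n)))

apply_salt_pepper <- function(img, density, value_range = 255) {
  n <- length(img)
  hit <- stats::runif(n) < density
  salt <- stats::runif(n) < 0.5
  img[hit & salt] <- value_range
  img[hit & !salt] <- 0
  img
}

# Corrupt a constant-gray image with one of the ten families.  Mixture
# classes apply their component noises sequentially in the order named by
# the label.  Additive families are zero-mean; negative results are floored
# at 0 when quantizing, not here.
add_noise <- function(clean, family, intensity) {
  n <- length(clean)
  switch(family,
    poisson = matrix(stats::rpois(n, clean * intensity) / intensity,
                     nrow(clean), ncol(clean)),
    gamma = clean * matrix(stats::rgamma(n, 1 / intensity, 1 / intensity),
                           nrow(clean), ncol(clean)),
    rayleigh = clean + matrix(rrayleigh(n, intensity) -
                              intensity * sqrt(pi / 2),
                              nrow(clean), ncol(clean)),
    exponential = clean + matrix(stats::rexp(n, 1 / intensity) - intensity,
                                 nrow(clean), ncol(clean)),
    uniform = clean + matrix(stats::runif(n, -intensity, intensity),
                             nrow(clean), ncol(clean)),
    gaussian = clean + matrix(stats::rnorm(n, 0, intensity),
                              nrow(clean), ncol(clean)),
    salt_pepper = apply_salt_pepper(clean, intensity),
    `gaussian+exponential` = {
      x <- add_noise(clean, "gaussian", intensity)
      x + matrix(stats::rexp(n, 1 / intensity) - intensity,
                 nrow(clean), ncol(clean))
    },
    `gaussian+salt_pepper` = {
      x <- clean + matrix(stats::rnorm(n, 0, 15), nrow(clean), ncol(clean))
      apply_salt_pepper(x, intensity)
    },
    `gamma+salt_pepper` = {
      x <- add_noise(clean, "gamma", intensity)
      apply_salt_pepper(x, 0.05)
    },
    stop("unknown noise family: ", family, call. = FALSE)
  )
}

#' Generate the ten-class labeled noise dataset
#'
#' Builds constant-gray images at gray levels 30-100, corrupts each with one
#' of the ten noise families at a family-specific intensity, quantizes to
#' 8 bits and splits into disjoint train/test sets (1700/300 at the default
#' 2000 images).  Used to train and evaluate the noise-type classifier.
#'
#' @param gray_levels base gray levels of the constant images.
#' @param intensities named list of per-family intensity grids; see
#'   `qdenoise:::qd_noise_intensities` for the defaults.
#' @param per_class_count images per family (default 200, for 2000 total).
#' @param size image side length.  Classifier features are 256-bin
#'   histograms, so modest images suffice.
#' @param test_fraction held-out fraction (default 300/2000).
#' @param seed integer seed; generation is bit-reproducible under a fixed
#'   seed.
#' @return an object of class `noise_dataset`: list with `images` (list of
#'   integer matrices), `labels` (factor over the ten families),
#'   `gray_level`, `intensity`, `split` ("train"/"test").
#' @export
make_noise_dataset <- function(gray_levels = seq(30, 100, by = 10),
                               intensities = qd_noise_intensities(),
                               per_class_count = 200,
                               size = 64,
                               test_fraction = 0.15,
                               seed = 1) {
  fams <- noise_families()
  if (!all(fams %in% names(intensities)))
    stop("`intensities` must name all ten families", call. = FALSE)
  set.seed(seed)
  n <- length(fams) * per_class_count
  images <- vector("list", n)
  labels <- character(n)
  glev <- numeric(n)
  inten <- numeric(n)
  idx <- 0L
  for (fam in fams) {
    grid <- expand.grid(gray = gray_levels, intensity = intensities[[fam]])
    for (r in seq_len(per_class_count)) {
      row <- grid[((r - 1L) %% nrow(grid)) + 1L, ]
      clean <- matrix(row$gray, size, size)
      idx <- idx + 1L
      images[[idx]] <- quantize8(add_noise(clean, fam, row$intensity))
      labels[idx] <- fam
      glev[idx] <- row$gray
      inten[idx] <- row$intensity
    }
  }
  labels <- factor(labels, levels = fams)
  test_n <- round(n * test_fraction)
  test_idx <- sort(sample.int(n, test_n))
  split <- rep("train", n)
  split[test_idx] <- "test"
  structure(list(images = images, labels = labels, gray_level = glev,
                 intensity = inten, split = split),
            class = "noise_dataset")
}

#' @export
print.noise_dataset <- function(x, ...) {
  cat("Noise dataset:", length(x$images), "images,",
      nlevels(x$labels), "families\n")
  cat("  split:", sum(x$split == "train"), "train /",
      sum(x$split == "test"), "test\n")
  cat("  image size:", nrow(x$images[[1]]), "x", ncol(x$images[[1]]), "\n")
  invisible(x)
}

#' Write a noise dataset to disk
#'
#' Writes each image as an 8-bit PNG plus a `manifest.csv` with columns
#' path, family, gray_level, intensity, split.
#'
#' @param dataset a [make_noise_dataset()] result.
#' @param dir output directory (created if missing).
#' @return the manifest data frame, invisibly.
#' @export
write_noise_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "noise_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(dataset$images)
  paths <- file.path(dir, sprintf("noise_%04d.png", seq_len(n)))
  for (i in seq_len(n)) write_gray_image(dataset$images[[i]], paths[i])
  manifest <- data.frame(path = paths,
                         family = as.character(dataset$labels),
                         gray_level = dataset$gray_level,
                         intensity = dataset$intensity,
                         split = dataset$split)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
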