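#' Cosine similarity between two patches
#'
#' Standard cosine of the angle between the two patches viewed as vectors,
#' \eqn{d = \langle a, b\rangle / (\|a\| \|b\|)}; in `[0, 1]` for
#' non-negative patches.  Conventions for empty patches: both all-zero
#' gives 1 (identical), exactly one all-zero gives 0.  With
#' `exact = FALSE` the denominator omits the square roots (the no-root
#' variant kept for comparison).
#'
#' @param a,b equal-sized numeric patches (vectors or matrices).
#' @param exact use the standard cosine (default) or the no-root variant.
#' @return scalar similarity.
#' @export
cosine_similarity <- function(a, b, exact = TRUE) {
  a <- as.vector(a); b <- as.vector(b)
  if (length(a) != length(b)) stop("patches must have equal size",
                                   call. = FALSE)
  na <- sum(a * a); nb <- sum(b * b)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  if (exact) sum(a * b) / sqrt(na * nb) else sum(a * b) / (na * nb)
}

#' Spatial weight kernel for the variation field
#'
#' The fixed 7x7 ring-constant kernel that down-weights cosine distances by
#' spatial distance from the search-box center: center 1, then rings 0.8,
#' 0.6, 0.4.
#'
#' @return 7x7 numeric matrix.
#' @export
spatial_kernel_G <- function() {
  G <- matrix(0.4, 7, 7)
  G[2:6, 2:6] <- 0.6
  G[3:5, 3:5] <- 0.8
  G[4, 4] <- 1
  G
}

#' Cosine-distance variation field
#'
#' The per-pixel edge statistic of CNLAD: for every pixel, the cosine
#' similarities between its centered `patch` x `patch` neighborhood and the
#' patches centered at every position (stride 1) inside its
#' `search` x `search` box are averaged with the spatial weights `G`
#' (normalized by `sum(G)`).  Homogeneous surroundings give `q` near 1;
#' structure lowers it.  The diffusion threshold `T` is the image-wide mean
#' of `q`.  The image is reflect-padded so every pixel has a full search
#' box.
#'
#' @param image non-negative numeric matrix.
#' @param search search box side (default 9).
#' @param patch patch side (default 3).
#' @param G spatial weight matrix of side `search - patch + 1`.
#' @param exact_cosine standard cosine (default) or the no-root variant.
#' @return object of class `variation_field`: list with `q` (matrix in
#'   `[0, 1]`), `T` (scalar mean of `q`), and the parameters.
#' @export
variation_field <- function(image, search = 9, patch = 3,
                            G = spatial_kernel_G(), exact_cosine = TRUE) {
  check_gray_image(image, min_dim = 1L)
  if (search %% 2 == 0 || patch %% 2 == 0 || patch >= search)
    stop("`search` and `patch` must be odd with patch < search",
         call. = FALSE)
  q <- cpp_variation_field(image, as.integer(search), as.integer(patch),
                           G, exact_cosine)
  structure(list(q = q, T = mean(q), search = search, patch = patch, G = G),
            class = "variation_field")
}

#' Diffusion coefficient from the variation field
#'
#' \eqn{c(q) = 1 / (1 + (q - T)^2)}: equal to 1 where the local statistic
#' matches the global threshold, decreasing symmetrically as it departs.
#'
#' @param q per-pixel variation statistic (matrix or scalar).
#' @param T scalar diffusion threshold (mean of `q`), or a
#'   `variation_field` object in place of `q`.
#' @return values in (0, 1].
#' @export
diffusion_coefficient <- function(q, T = NULL) {
  if (inherits(q, "variation_field")) { T <- q$T; q <- q$q }
  1 / (1 + (q - T)^2)
}

#' Mean of k-middle
#'
#' Average of the central order statistics of a sample: the `2k - 1` (odd
#' `n`) or `2k` (even `n`) middle values.  `k = 1` is the classical median;
#' `k = ceiling(n / 2)` (odd `n`) recovers the mean.
#'
#' @param values numeric vector.
#' @param k half-width of the central block.
#' @return scalar.
#' @export
mean_k_middle <- function(values, k) {
  n <- length(values)
  if (n == 0) stop("empty sample", call. = FALSE)
  h <- if (n %% 2 == 1) (n + 1) / 2 else n / 2
  if (k < 1 || k > h) stop("`k` must lie in [1, ", h, "] for n = ", n,
                           call. = FALSE)
  e <- sort(values)
  if (n %% 2 == 1) mean(e[(h - k + 1):(h + k - 1)])
  else mean(e[(h - k + 1):(h + k)])
}

#' Type-2 fuzzy diffusion gate
#'
#' Per pixel, the window mean is the mean-of-k-middle (`k = 2`) of its 3x3
#' neighborhood; upper and lower memberships are Gaussians in the centre
#' value with standard deviations `delta_u` and `delta_l` around that mean,
#' and the type-2 membership is their average.  A membership near 1 marks a
#' pixel consistent with its neighborhood (not noise), which the diffusion
#' step then leaves alone via the factor `1 - U`.
#'
#' `scale` sets the intensity units of the memberships: pixel values are
#' divided by it before evaluating the Gaussians.  The default 1 evaluates
#' them on the raw gray scale, i.e. `delta_u`/`delta_l` are in gray levels;
#' `scale = 255` evaluates them on a normalized [0, 1] intensity scale.
#'
#' @param image numeric matrix.
#' @param delta_u,delta_l standard deviations of the upper and lower
#'   membership functions (defaults 0.2 and 0.1).
#' @param k mean-of-k-middle parameter (default 2).
#' @param H window radius (default 1, i.e. 3x3).
#' @param scale intensity divisor applied before membership evaluation.
#' @return matrix `U` of memberships in `[0, 1]` (lower membership never
#'   exceeds upper).
#' @export
type2_gate <- function(image, delta_u = 0.2, delta_l = 0.1, k = 2, H = 1,
                       scale = 1) {
  check_gray_image(image)
  if (delta_u <= 0 || delta_l <= 0 || delta_l > delta_u)
    stop("need 0 < delta_l <= delta_u", call. = FALSE)
  cpp_type2_gate(image / scale, delta_u, delta_l, as.integer(k),
                 as.integer(H))
}

#' One explicit CNLAD diffusion step
#'
#' \deqn{I^+ = I + \Delta t \frac{1 - U}{4}
#'   \sum_{n \in 4\mathrm{-neighbours}} c_n (I_n - I)}
#' with the diffusion coefficient taken at the neighbor position and
#' zero-flux (mirrored) boundaries.  For `c <= 1`, `U in [0, 1]` and
#' `dt <= 0.25` the step obeys the discrete maximum principle.
#'
#' @param image numeric matrix.
#' @param c_field per-pixel diffusion coefficients (same size).
#' @param U_field per-pixel type-2 memberships (same size).
#' @param dt time step (0 < dt <= 0.25 for stability).
#' @return updated image.
#' @export
cnlad_step <- function(image, c_field, U_field, dt) {
  if (!all(dim(image) == dim(c_field)) || !all(dim(image) == dim(U_field)))
    stop("fields must be co-registered with the image", call. = FALSE)
  if (dt <= 0 || dt > 0.25)
    stop("`dt` must lie in (0, 0.25] for explicit stability", call. = FALSE)
  cpp_cnlad_step(image, c_field, U_field, dt)
}

#' Denoise a quantum-dot fluorescence image
#'
#' Full pipeline for multiplicative gamma noise: estimate the coefficient
#' of variation from homogeneous regions, derive the gray-value-compression
#' iteration budget from the calibration curve, build the non-local-means
#' reference and compress the image toward it, then run cosine-distance
#' nonlocal anisotropic diffusion gated by the type-2 fuzzy membership
#' until the update stalls or `n_iter` is reached.
#'
#' @param image non-negative numeric matrix (gray levels, nominally 0-255).
#' @param config a [qd_config()] list; individual entries can be overridden
#'   via `...`.
#' @param ... named config overrides, e.g. `denoise(x, n_iter = 50)`.
#' @return object of class `qd_denoise`; the denoised image is in
#'   `$image` (also available via `as.matrix()`).
#' @examples
#' \donttest{
#' clean <- matrix(50, 128, 128)
#' noisy <- apply_multiplicative_noise(clean, 0.5, seed = 1)
#' out <- denoise(noisy)
#' c(agl = agl(out$image), rmse = rmse(out$image, clean))
#' }
#' @export
denoise <- function(image, config = qd_config(), ...) {
  config <- qd_config_update(config, ...)
  check_gray_image(image)
  cv <- NULL
  k_max <- config$gvc_k_max
  delta <- NULL
  if (is.null(k_max) || is.null(config$nlm_h)) {
    cv <- estimate_cv(image, P = config$cv_P, window_size = config$cv_window,
                      variant = config$cv_variant)
    delta <- cv$delta
  }
  if (is.null(k_max))
    k_max <- iterations_from_cv(delta, config$gvc_curve)
  h <- config$nlm_h
  if (is.null(h)) h <- nlm_h(image, delta, config$nlm_h_factor)
  reference <- nlm_smooth(image, config$nlm_search, config$nlm_patch, h)
  reference <- pmax(reference, .Machine$double.eps)
  I <- gvc_iterate(image, reference, k_max, config$gvc_step_divisor)
  run <- cpp_cnlad_run(I, as.integer(config$cnlad_search),
                       as.integer(config$cnlad_patch), spatial_kernel_G(),
                       config$exact_cosine, config$gate_delta_u,
                       config$gate_delta_l, as.integer(config$gate_k),
                       config$gate_scale, config$dt,
                       as.integer(config$n_iter), config$stop_tol)
  I <- run$image
  iters <- run$iters
  updates <- run$updates
  structure(list(image = I, input = image, reference = reference,
                 cv = cv, k_max = k_max, h = h, n_iter_run = iters,
                 updates = updates, config = config),
            class = "qd_denoise")
}

#' @export
as.matrix.qd_denoise <- function(x, ...) x$image

#' @export
print.qd_denoise <- function(x, ...) {
  cat("CNLAD denoising result (", nrow(x$image), "x", ncol(x$image), ")\n",
      sep = "")
  if (!is.null(x$cv))
    cat("  coefficient of variation:", format(x$cv$delta, digits = 4), "\n")
  cat("  GVC iterations:", x$k_max, " (NLM h =",
      format(x$h, digits = 4), ")\n")
  cat("  diffusion iterations:", x$n_iter_run,
      if (length(x$updates) && x$updates[length(x$updates)] <
            x$config$stop_tol) "(converged)" else "", "\n")
  cat("  AGL in:", format(mean(x$input), digits = 5),
      " out:", format(mean(x$image), digits = 5), "\n")
  invisible(x)
}

#' @export
summary.qd_denoise <- function(object, ...) {
  print(object)
  cat("  mean |update| by iteration:\n")
  print(utils::head(round(object$updates, 5), 20))
  invisible(object)
}

#' @export
plot.qd_denoise <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  rng <- range(x$input, x$image)
  for (nm in c("input", "image")) {
    m <- x[[nm]]
    graphics::image(t(m)[, nrow(m):1], col = grDevices::gray.colors(256),
                    zlim = rng, axes = FALSE,
                    main = if (nm == "input") "noisy" else "denoised")
  }
  invisible(x)
}
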