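#' Histogram features from homogeneous windows
#'
#' One normalized 256-bin intensity histogram per window, the feature the
#' noise-type classifier consumes.  Pixels are quantized to 8 bits before
#' binning; bins sum to 1.
#'
#' @param image numeric matrix (gray levels).
#' @param windows a [select_homogeneous_windows()] result.
#' @return list of length-256 numeric vectors, one per window, in window
#'   order; each carries its window coordinates as the `"window"`
#'   attribute.
#' @export
extract_features <- function(image, windows) {
  if (!inherits(windows, "homog_windows") || nrow(windows) == 0)
    stop("`windows` must be a non-empty homogeneous-window set",
         call. = FALSE)
  lapply(seq_len(nrow(windows)), function(i) {
    px <- window_pixels(image, windows$row[i], windows$col[i],
                        windows$size[i])
    h <- image_histogram(px)
    attr(h, "window") <- c(row = windows$row[i], col = windows$col[i],
                           size = windows$size[i])
    h
  })
}

image_histogram <- function(px) {
  v <- as.integer(quantize8(px))
  tabulate(v + 1L, nbins = 256L) / length(v)
}

# Internal model representation of a 256-bin histogram: the (scaled)
# histogram itself plus low-order moment summaries.  The moments make the
# distributional shape available directly, which a convolutional network
# would otherwise have to learn as shift-invariant filters; an MLP benefits
# from having them spelled out.
classifier_features <- function(h) {
  x <- 0:255
  mu <- sum(x * h)
  s <- sqrt(sum((x - mu)^2 * h))
  z <- (x - mu) / max(s, 1e-9)
  c(h * 4,
    mu = mu / 255, s = s / 64,
    skew = sum(z^3 * h) / 4, kurt = sum(z^4 * h) / 16,
    p0 = h[1], p255 = h[256])
}

#' Train the noise-type classifier
#'
#' Fits a single-hidden-layer softmax network (via \pkg{nnet}) on the
#' whole-image 256-bin histogram (augmented internally with moment
#' summaries) of every training image in a [make_noise_dataset()] dataset,
#' with the ten noise families as classes.  Training is deterministic
#' under a fixed seed.
#'
#' @param dataset a `noise_dataset`.
#' @param size hidden units.
#' @param decay weight decay.
#' @param maxit optimizer iterations.
#' @param seed integer seed.
#' @return object of class `noise_classifier` holding the fitted network,
#'   the class levels, and the held-out test accuracy (`$test_accuracy`).
#' @export
train_classifier <- function(dataset, size = 24, decay = 5e-4,
                             maxit = 150, seed = 1) {
  stopifnot(inherits(dataset, "noise_dataset"))
  if (nlevels(dataset$labels) != 10)
    stop("dataset must carry exactly the 10 noise families", call. = FALSE)
  H <- t(vapply(dataset$images, image_histogram, numeric(256)))
  X <- t(apply(H, 1, classifier_features))
  y <- dataset$labels
  tr <- dataset$split == "train"
  set.seed(seed)
  net <- nnet::nnet(X[tr, , drop = FALSE], nnet::class.ind(y[tr]),
                    size = size, decay = decay, maxit = maxit,
                    softmax = TRUE, MaxNWts = 100000, trace = FALSE)
  pred_te <- predict_posteriors(net, H[!tr, , drop = FALSE])
  acc <- mean(levels(y)[max.col(pred_te)] == as.character(y[!tr]))
  structure(list(net = net, levels = levels(y), test_accuracy = acc),
            class = "noise_classifier")
}

# histograms -> posteriors (rows sum to 1)
predict_posteriors <- function(net, H) {
  X <- t(apply(H, 1, classifier_features))
  p <- predict(net, X, type = "raw")
  p / rowSums(p)
}

#' @export
print.noise_classifier <- function(x, ...) {
  cat("Noise-type classifier (softmax network,", x$net$n[2],
      "hidden units)\n")
  cat("  held-out accuracy:", sprintf("%.1f%%", 100 * x$test_accuracy), "\n")
  invisible(x)
}

#' Classify the noise type of an image
#'
#' Extracts `n_windows` homogeneous windows, computes their histogram
#' features, evaluates the classifier on each and averages the softmax
#' posteriors; the argmax is the predicted noise family.
#'
#' @param image numeric matrix (gray levels).
#' @param model a [train_classifier()] result.
#' @param n_windows homogeneous windows to average over (default 8).
#' @param window_size window side (default 20).
#' @return object of class `class_posterior`: named numeric vector of the
#'   ten averaged posteriors (summing to 1), with the predicted family as
#'   the `"family"` attribute.
#' @export
classify_noise <- function(image, model, n_windows = 8, window_size = 20) {
  stopifnot(inherits(model, "noise_classifier"))
  win <- select_homogeneous_windows(image, window_size, n_windows)
  feats <- extract_features(image, win)
  X <- do.call(rbind, feats)
  post <- colMeans(predict_posteriors(model$net, X))
  names(post) <- model$levels
  structure(post, family = model$levels[which.max(post)],
            class = "class_posterior")
}

#' @export
print.class_posterior <- function(x, ...) {
  cat("Predicted noise family:", attr(x, "family"), "\n")
  print(round(unclass(x), 4))
  invisible(x)
}
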