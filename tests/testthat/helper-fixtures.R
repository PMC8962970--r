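# Shared fixtures, built in code.

const_image <- function(gray = 50, size = 64) matrix(gray, size, size)

noisy_const <- function(gray = 50, size = 64, variance = 0.5, seed = 1) {
  apply_multiplicative_noise(const_image(gray, size), variance, seed = seed)
}

# Brute-force variation field: literal double loop over pixels and patch
# positions, independent of the fast implementation.
bf_variation_field <- function(img, search = 9, patch = 3,
                               G = spatial_kernel_G(), exact = TRUE) {
  pr <- (patch - 1) / 2
  m <- (search - patch) / 2
  pad <- m + pr
  P <- qdenoise:::cpp_reflect_pad(img, pad)
  H <- nrow(img); W <- ncol(img)
  q <- matrix(0, H, W)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    i <- y + pad; j <- x + pad
    a <- P[(i - pr):(i + pr), (j - pr):(j + pr)]
    num <- 0
    for (dy in -m:m) for (dx in -m:m) {
      b <- P[(i + dy - pr):(i + dy + pr), (j + dx - pr):(j + dx + pr)]
      num <- num + G[dy + m + 1, dx + m + 1] * cosine_similarity(a, b, exact)
    }
    q[y, x] <- num / sum(G)
  }
  q
}

# Brute-force non-local means, same definition written independently.
bf_nlm <- function(img, search, patch, h) {
  m <- (search - 1) / 2; pr <- (patch - 1) / 2; pad <- m + pr
  P <- qdenoise:::cpp_reflect_pad(img, pad)
  out <- matrix(0, nrow(img), ncol(img))
  for (y in seq_len(nrow(img))) for (x in seq_len(ncol(img))) {
    i <- y + pad; j <- x + pad
    a <- P[(i - pr):(i + pr), (j - pr):(j + pr)]
    w <- 0; acc <- 0
    for (dy in -m:m) for (dx in -m:m) {
      b <- P[(i + dy - pr):(i + dy + pr), (j + dx - pr):(j + dx + pr)]
      wk <- exp(-sum((a - b)^2) / h^2)
      w <- w + wk
      acc <- acc + wk * P[i + dy, j + dx]
    }
    out[y, x] <- acc / w
  }
  out
}
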