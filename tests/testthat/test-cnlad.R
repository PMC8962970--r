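test_that("cosine similarity obeys its boundary conventions", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(cosine_similarity(c(1, 2, 3), 4.2 * c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(rep(0, 9), rep(0, 9)), 1)
  expect_equal(cosine_similarity(rep(0, 9), rep(1, 9)), 0)
  expect_error(cosine_similarity(1:4, 1:9), "equal size")
})

test_that("the spatial kernel is the printed ring-constant matrix", {
  G <- spatial_kernel_G()
  expect_equal(dim(G), c(7, 7))
  expect_equal(G[4, 4], 1)
  expect_equal(max(G), G[4, 4])
  expect_true(all(G[1, ] == 0.4) && all(G[, 1] == 0.4))
  expect_equal(G[2, 2:6], rep(0.6, 5))
  expect_equal(G[3, 3:5], rep(0.8, 3))
  expect_equal(G, G[7:1, ])          # symmetric rings
  expect_equal(G, t(G))
})

test_that("variation field is 1 with threshold 1 on constant images", {
  vf <- variation_field(const_image(50, 24))
  expect_equal(vf$q, matrix(1, 24, 24), tolerance = 1e-12)
  expect_equal(vf$T, 1, tolerance = 1e-12)
})

test_that("variation field matches the brute-force oracle on random images", {
  set.seed(17)
  for (rep in 1:3) {
    img <- matrix(runif(256, 0, 255), 16, 16)
    vf <- variation_field(img)
    expect_equal(vf$q, bf_variation_field(img), tolerance = 1e-10)
    expect_equal(vf$T, mean(vf$q), tolerance = 1e-12)
    expect_true(all(vf$q >= 0 & vf$q <= 1 + 1e-12))
  }
  # the printed no-square-root variant is also exposed
  img <- matrix(runif(256, 1, 255), 16, 16)
  vf2 <- variation_field(img, exact_cosine = FALSE)
  expect_equal(vf2$q, bf_variation_field(img, exact = FALSE),
               tolerance = 1e-10)
})

test_that("variation statistic is lower at edges than in flat noisy areas", {
  set.seed(18)
  img <- matrix(30, 20, 20); img[, 11:20] <- 160
  img <- img * matrix(rgamma(400, 100, 100), 20, 20)   # mild noise
  vf <- variation_field(img)
  edge_q <- mean(vf$q[5:16, 10:11])
  flat_q <- mean(vf$q[5:16, 3:4])
  expect_lt(edge_q, flat_q)
})

test_that("diffusion coefficient is 1 at the threshold and even in q - T", {
  expect_equal(diffusion_coefficient(0.7, 0.7), 1)
  expect_equal(diffusion_coefficient(1.5, 0.5), 0.5)
  expect_equal(diffusion_coefficient(0.2, 0.5),
               diffusion_coefficient(0.8, 0.5))
  q <- seq(0, 1, 0.1)
  cc <- diffusion_coefficient(q, 0.5)
  expect_true(all(diff(cc[q <= 0.5]) > 0) && all(diff(cc[q >= 0.5]) < 0))
})

test_that("mean of k-middle interpolates between median and mean", {
  expect_equal(mean_k_middle(1:9, 1), 5)
  expect_equal(mean_k_middle(1:9, 2), 5)
  expect_equal(mean_k_middle(c(9, 1, 5, 3, 7, 2, 8, 4, 6), 2), 5)
  expect_equal(mean_k_middle(1:9, 5), mean(1:9))
  expect_equal(mean_k_middle(c(1, 2, 10, 100), 1), 6)    # even n: 2k middle
  expect_equal(mean_k_middle(1:8, 4), mean(1:8))
  expect_error(mean_k_middle(1:9, 0), "k")
  expect_error(mean_k_middle(1:9, 6), "k")
})

test_that("type-2 gate is 1 where the center equals its window M2", {
  U <- type2_gate(const_image(50, 12))
  expect_equal(U, matrix(1, 12, 12))
})

test_that("type-2 gate matches an R oracle and satisfies LMF <= UMF", {
  set.seed(19)
  img <- matrix(runif(144, 0, 1), 12, 12)
  U <- type2_gate(img, scale = 1)
  P <- qdenoise:::cpp_reflect_pad(img, 1)
  for (y in c(1, 5, 12)) for (x in c(1, 7, 12)) {
    w <- P[y:(y + 2), x:(x + 2)]
    mu <- mean_k_middle(as.vector(w), 2)
    e <- img[y, x]
    umf <- exp(-(e - mu)^2 / (2 * 0.2^2))
    lmf <- exp(-(e - mu)^2 / (2 * 0.1^2))
    expect_lte(lmf, umf)
    expect_equal(U[y, x], (umf + lmf) / 2, tolerance = 1e-12)
  }
  # far from the window mean the membership vanishes
  spike <- const_image(0.2, 9); spike[5, 5] <- 0.9999
  expect_lt(type2_gate(spike, scale = 1)[5, 5], 1e-3)
})

test_that("diffusion step fixes constants, freezes gated pixels, and is a heat step", {
  img <- const_image(42, 8)
  ones <- matrix(1, 8, 8); zeros <- matrix(0, 8, 8)
  expect_equal(cnlad_step(img, ones, zeros, 0.25), img)
  # U = 1 freezes a pixel regardless of its neighbors
  set.seed(20)
  rnd <- matrix(runif(64, 0, 255), 8, 8)
  expect_equal(cnlad_step(rnd, ones, ones, 0.25), rnd)
  # c = 1, U = 0, dt = 0.25: standard 4-neighbor explicit heat step
  img5 <- matrix(c(0, 0, 0, 0, 0,
                   0, 0, 0, 0, 0,
                   0, 0, 100, 0, 0,
                   0, 0, 0, 0, 0,
                   0, 0, 0, 0, 0), 5, 5, byrow = TRUE)
  heat <- function(I, dt) {
    out <- I
    for (y in 1:5) for (x in 1:5) {
      nb <- c(I[max(y - 1, 1), x], I[min(y + 1, 5), x],
              I[y, max(x - 1, 1)], I[y, min(x + 1, 5)])
      out[y, x] <- I[y, x] + dt / 4 * sum(nb - I[y, x])
    }
    out
  }
  expect_equal(cnlad_step(img5, matrix(1, 5, 5), matrix(0, 5, 5), 0.25),
               heat(img5, 0.25), tolerance = 1e-12)
})

test_that("diffusion step obeys the discrete maximum principle", {
  set.seed(21)
  for (rep in 1:5) {
    img <- matrix(runif(400, 0, 255), 20, 20)
    cf <- matrix(runif(400, 0.2, 1), 20, 20)
    U <- matrix(runif(400), 20, 20)
    out <- cnlad_step(img, cf, U, 0.25)
    expect_gte(min(out), min(img) - 1e-12)
    expect_lte(max(out), max(img) + 1e-12)
  }
  expect_error(cnlad_step(img, cf, U, 0.3), "dt")
})

test_that("the fused diffusion loop equals composing the building blocks", {
  img <- noisy_const(50, 24, 0.5, seed = 22)
  run <- qdenoise:::cpp_cnlad_run(img, 9L, 3L, spatial_kernel_G(), TRUE,
                                  0.2, 0.1, 2L, 1, 0.2, 5L, 0)
  I <- img
  for (it in 1:5) {
    vf <- variation_field(I)
    I <- cnlad_step(I, diffusion_coefficient(vf), type2_gate(I), 0.2)
  }
  expect_equal(run$image, I, tolerance = 1e-14)
  expect_equal(run$iters, 5L)
})

test_that("denoising a clean constant image is the identity", {
  img <- const_image(50, 64)
  out <- denoise(img)
  expect_lt(max(abs(out$image - img)), 1e-6)
  expect_equal(out$k_max, 0L)
})

test_that("denoising is deterministic given the input and config", {
  img <- noisy_const(50, 64, 0.4, seed = 23)
  cfg <- qd_config(n_iter = 10)
  o1 <- denoise(img, cfg)
  o2 <- denoise(img, cfg)
  expect_identical(o1$image, o2$image)
  expect_identical(o1$k_max, o2$k_max)
})

test_that("denoise result object prints and converts", {
  img <- noisy_const(50, 64, 0.4, seed = 24)
  out <- denoise(img, qd_config(n_iter = 5))
  expect_s3_class(out, "qd_denoise")
  expect_identical(as.matrix(out), out$image)
  expect_output(print(out), "GVC iterations")
})
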