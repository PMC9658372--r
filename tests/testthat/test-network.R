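test_that("architecture spec validates its invariants", {
  expect_error(amcnn_spec(1), "n_classes")
  expect_error(amcnn_spec(5, spp_levels = c(2, 1)), "increasing")
  expect_error(amcnn_spec(5, spp_levels = c(1, 1)), "increasing")
  expect_error(amcnn_spec(5, omega = 0), "omega")
  sp <- amcnn_spec(10)
  expect_equal(sp$spp_levels, c(1L, 2L, 4L))
  expect_equal(sp$omega, 1.2)
  expect_equal(sp$backbone_channels, c(64L, 64L, 128L, 256L, 512L))
})

test_that("shape ladder follows the convolution arithmetic", {
  # stem: floor((224 + 2*3 - 7)/2) + 1 = 112; floor((112 + 2*1 - 3)/2) + 1 = 56
  expect_equal((224 + 2 * 3 - 7) %/% 2 + 1, 112)
  expect_equal((112 + 2 * 1 - 3) %/% 2 + 1, 56)

  m <- amcnn_model(amcnn_spec(10), seed = 0)
  probe <- amcnn_shape_probe(m)
  expect_equal(probe$conv, c(112L, 112L, 64L))
  expect_equal(probe$pool, c(56L, 56L, 64L))
  expect_equal(probe$stages$stage1, c(56L, 56L, 64L))
  expect_equal(probe$stages$stage2, c(28L, 28L, 128L))
  expect_equal(probe$stages$stage3, c(14L, 14L, 256L))
  expect_equal(probe$stages$stage4, c(7L, 7L, 512L))
  expect_equal(probe$spp_length, 64 * (1 + 4 + 16))   # 1344
  expect_equal(probe$concat_length, 1344 + 512)        # 1856
})

test_that("zero input with zero-centred statistics gives zero stem pre-activation", {
  m <- amcnn_model(amcnn_spec(4), seed = 1)
  x <- array(0, c(224, 224, 3, 1))
  z <- amcnn:::cpp_conv2d_fwd(x, m$layers$conv1$w, NULL, 2L, 3L)
  expect_true(all(z == 0))
})

test_that("SPP yields fixed-length vectors and matches a bin-max oracle", {
  cst <- array(2.5, c(56, 56, 64))
  v <- spp_pool(cst, c(1, 2, 4))
  expect_length(v, 1344)
  expect_true(all(v == 2.5))

  set.seed(21)
  f <- array(rnorm(12 * 12 * 3), c(12, 12, 3))
  expect_equal(spp_pool(f, 1L), apply(f, 3, max), ignore_attr = TRUE)

  # exhaustive bin enumeration oracle on a random map
  g <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  v2 <- spp_pool(g, c(1, 2))
  ref <- c()
  for (L in c(1, 2)) for (bj in 1:L) for (bi in 1:L) {
    ri <- (floor((bi - 1) * 8 / L) + 1):floor(bi * 8 / L)
    ci <- (floor((bj - 1) * 8 / L) + 1):floor(bj * 8 / L)
    for (c in 1:2) ref <- c(ref, max(g[ri, ci, c]))
  }
  expect_equal(v2, ref, ignore_attr = TRUE)

  # fixed length regardless of spatial size
  h1 <- array(rnorm(56 * 56 * 4), c(56, 56, 4))
  h2 <- array(rnorm(28 * 28 * 4), c(28, 28, 4))
  expect_length(spp_pool(h1, c(1, 2, 4)), length(spp_pool(h2, c(1, 2, 4))))

  expect_error(spp_pool(g, c(1, 16)), "level")
  # mean pooling variant
  expect_equal(spp_pool(g, 1L, pool = "mean"), apply(g, 3, mean),
               ignore_attr = TRUE)
})

test_that("forward pass normalises, is deterministic, and rejects bad shapes", {
  set.seed(22)
  sp <- tiny_spec(n_classes = 5L)
  m <- amcnn_model(sp, seed = 2)
  x <- array(rnorm(32 * 32 * 3 * 3), c(32, 32, 3, 3))
  fw <- amcnn_forward(m, x)
  expect_equal(dim(fw$probs), c(3L, 5L))
  expect_equal(rowSums(fw$probs), rep(1, 3), tolerance = 1e-6)
  expect_identical(fw$probs, amcnn_forward(m, x)$probs)

  expect_error(amcnn_forward(m, array(0, c(16, 16, 3, 1))), "shape")
  expect_error(amcnn_forward(m, array(0, c(32, 32, 1, 1))), "shape")
  expect_error(amcnn_forward(m, x, weight_maps = matrix(1, 5, 5)), "shape")

  m2 <- amcnn_model(tiny_spec(n_classes = 2L), seed = 2)
  expect_equal(ncol(amcnn_forward(m2, x)$probs), 2L)
})

test_that("omega = 1 weight maps leave the network exactly unchanged", {
  set.seed(23)
  sp <- tiny_spec(n_classes = 3L)
  m <- amcnn_model(sp, seed = 9)
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  wm <- array(1, c(8, 8, 2))   # any mask at omega 1 maps to all-ones weights
  expect_identical(amcnn_forward(m, x, weight_maps = wm)$probs,
                   amcnn_forward(m, x)$probs)

  # and at the full input scale through compute_weight_map
  mfull <- amcnn_model(amcnn_spec(3), seed = 1)
  xf <- array(rnorm(224 * 224 * 3), c(224, 224, 3, 1))
  w1 <- compute_weight_map(random_binary_mask(), omega = 1)
  expect_identical(amcnn_forward(mfull, xf, weight_maps = array(w1, c(56, 56, 1)))$probs,
                   amcnn_forward(mfull, xf)$probs)
})

test_that("gradient reaches both the shallow (SPP) and deep (Block4) branches", {
  set.seed(24)
  sp <- tiny_spec(n_classes = 3L)
  m <- amcnn_model(sp, seed = 4)
  x <- array(rnorm(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  lg <- amcnn:::loss_and_grads(m, x, NULL, c(1L, 2L, 3L, 1L))
  D_spp <- amcnn:::spp_length(sp)
  W1g <- lg$grads$fc1$w
  expect_gt(sum(abs(W1g[, seq_len(D_spp)])), 0)
  expect_gt(sum(abs(W1g[, (D_spp + 1):ncol(W1g)])), 0)
  # the deepest residual stage receives gradient as well
  expect_gt(sum(abs(lg$grads$stage4$block2$conv2$w)), 0)
  expect_gt(sum(abs(lg$grads$conv1$w)), 0)
})
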