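# The layer kernels against independent double-precision oracles: direct
# convolution loops, naive pooling, and numeric differentiation of the
# oracle for every analytic gradient.

conv_oracle <- function(x, w, stride, pad) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[4]
  wd <- dim(w); kh <- wd[1]; kw <- wd[2]; F <- wd[4]
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, d[3], N))
  xp[pad + (1:H), pad + (1:W), , ] <- x
  y <- array(0, c(Ho, Wo, F, N))
  for (n in 1:N) for (f in 1:F) for (jo in 1:Wo) for (io in 1:Ho) {
    i0 <- (io - 1) * stride; j0 <- (jo - 1) * stride
    y[io, jo, f, n] <- sum(xp[i0 + (1:kh), j0 + (1:kw), , n] * w[, , , f])
  }
  y
}

numeric_grad <- function(f, x, idx, h = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}

test_that("convolution matches a direct-loop oracle, forward and backward", {
  set.seed(10)
  for (case in list(list(9, 2, 3, 2, 1), list(8, 3, 5, 2, 2))) {
    side <- case[[1]]; C <- case[[2]]; F <- case[[3]]
    stride <- case[[4]]; pad <- case[[5]]
    x <- array(rnorm(side * side * C * 2), c(side, side, C, 2))
    w <- array(rnorm(3 * 3 * C * F), c(3, 3, C, F))
    y <- amcnn:::cpp_conv2d_fwd(x, w, NULL, stride, pad)
    y_ref <- conv_oracle(x, w, stride, pad)
    expect_equal(y, y_ref, tolerance = 1e-5)

    proj <- array(rnorm(length(y_ref)), dim(y_ref))
    g <- amcnn:::cpp_conv2d_bwd(x, w, proj, stride, pad, TRUE, FALSE)
    idx <- sample(length(x), 20)
    nd <- numeric_grad(function(xx) sum(conv_oracle(xx, w, stride, pad) * proj),
                       x, idx)
    expect_equal(g$dx[idx], nd, tolerance = 1e-3)
    idw <- sample(length(w), 20)
    ndw <- numeric_grad(function(ww) sum(conv_oracle(x, ww, stride, pad) * proj),
                        w, idw)
    expect_equal(g$dw[idw], ndw, tolerance = 1e-3)
  }
})

test_that("max pooling matches a naive oracle and routes gradients to argmaxes", {
  set.seed(12)
  x <- array(rnorm(9 * 9 * 2 * 2), c(9, 9, 2, 2))
  mp <- amcnn:::cpp_maxpool_fwd(x, 3L, 2L, 1L)
  ref <- array(0, dim(mp$y))
  d <- dim(x)
  for (n in 1:2) for (c in 1:2) for (jo in 1:dim(mp$y)[2]) for (io in 1:dim(mp$y)[1]) {
    ii <- ((io - 1) * 2 - 1) + (1:3); jj <- ((jo - 1) * 2 - 1) + (1:3)
    ii <- ii[ii >= 1 & ii <= 9]; jj <- jj[jj >= 1 & jj <= 9]
    ref[io, jo, c, n] <- max(x[ii, jj, c, n])
  }
  expect_equal(mp$y, ref)

  dy <- array(rnorm(length(mp$y)), dim(mp$y))
  dx <- amcnn:::cpp_maxpool_bwd(dy, mp$idx, dim(x))
  expect_equal(sum(dx), sum(dy))
  # gradient only lands where the max was attained
  expect_true(all(dx[setdiff(seq_along(x), mp$idx + 1)] == 0))
})

test_that("batch norm statistics, normalisation and gradient are exact", {
  set.seed(13)
  x <- array(rnorm(6 * 6 * 3 * 4, mean = 2, sd = 3), c(6, 6, 3, 4))
  st <- amcnn:::cpp_bn_stats(x)
  expect_equal(st$mean, apply(x, 3, mean))
  expect_equal(st$var, apply(x, 3, function(z) mean((z - mean(z))^2)))

  gam <- runif(3, 0.5, 2); bet <- rnorm(3)
  bn_ref <- function(x) {
    m <- apply(x, 3, mean)
    v <- apply(x, 3, function(z) mean((z - mean(z))^2))
    y <- x
    for (c in 1:3) y[, , c, ] <- (x[, , c, ] - m[c]) / sqrt(v[c] + 1e-5) * gam[c] + bet[c]
    y
  }
  y <- amcnn:::cpp_bn_apply(x, gam, bet, st$mean, st$var, 1e-5)
  expect_equal(y, bn_ref(x), tolerance = 1e-12)

  proj <- array(rnorm(length(x)), dim(x))
  g <- amcnn:::cpp_bn_bwd(x, gam, st$mean, st$var, 1e-5, proj)
  idx <- sample(length(x), 20)
  nd <- numeric_grad(function(xx) sum(bn_ref(xx) * proj), x, idx, h = 1e-5)
  expect_equal(g$dx[idx], nd, tolerance = 1e-6)
  expect_equal(g$dbeta, apply(proj, 3, sum))
})

test_that("the fused backbone agrees with composed primitive kernels", {
  set.seed(14)
  sp <- tiny_spec(n_classes = 3L)
  m <- amcnn_model(sp, seed = 5)
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))

  # primitive-composed stem: conv -> bn(batch stats) -> relu -> maxpool
  ly <- m$layers
  z1 <- amcnn:::cpp_conv2d_fwd(x, ly$conv1$w, NULL, 2L, 3L)
  st <- amcnn:::cpp_bn_stats(z1)
  r1 <- amcnn:::cpp_relu(amcnn:::cpp_bn_apply(z1, ly$bn1$gamma, ly$bn1$beta,
                                              st$mean, st$var, ly$bn1$eps))
  p_ref <- amcnn:::cpp_maxpool_fwd(r1, 3L, 2L, 1L)$y
  p_fused <- primary_conv_forward(m, x, training = TRUE)
  expect_equal(p_fused, p_ref, tolerance = 1e-5)

  # fused whole-network forward is finite, normalised and deterministic
  fw1 <- amcnn_forward(m, x, training = TRUE)
  fw2 <- amcnn_forward(m, x, training = TRUE)
  expect_identical(fw1$probs, fw2$probs)
  expect_equal(rowSums(fw1$probs), c(1, 1), tolerance = 1e-6)
})

test_that("end-to-end analytic gradients match numeric differentiation", {
  set.seed(15)
  sp <- tiny_spec(n_classes = 3L)
  m <- amcnn_model(sp, seed = 3)
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  wm <- array(ifelse(matrix(runif(8 * 8 * 2), 8) > 0.5, 1.3, 1), c(8, 8, 2))
  y <- c(1L, 3L)
  lg <- amcnn:::loss_and_grads(m, x, wm, y)

  loss_of <- function(model) {
    fw <- amcnn_forward(model, x, wm, training = TRUE, keep_cache = TRUE)
    P <- fw$cache$probs_km
    -mean(log(P[cbind(y, 1:2)]))
  }
  check <- function(path, field, idx, h = 1e-3) {
    g <- lg$grads
    for (p in path) g <- g[[p]]
    ana <- g[[field]][idx]
    mp <- m; mm <- m
    expr <- paste0("layers", paste0('[["', path, '"]]', collapse = ""),
                   '[["', field, '"]][', idx, "]")
    base <- eval(parse(text = paste0("m$", expr)))
    eval(parse(text = paste0("mp$", expr, " <- base + h")))
    eval(parse(text = paste0("mm$", expr, " <- base - h")))
    num <- (loss_of(mp) - loss_of(mm)) / (2 * h)
    list(ana = ana, num = num)
  }
  cases <- list(
    list("conv1", "w", 7), list("bn1", "gamma", 2), list("bn1", "beta", 5),
    list(c("stage1", "block1", "conv1"), "w", 13),
    list(c("stage2", "block1", "down", "conv"), "w", 4),
    list(c("stage3", "block2", "conv2"), "w", 21),
    list("fc1", "w", 10), list("fc2", "b", 2))
  for (cs in cases) {
    r <- check(cs[[1]], cs[[2]], cs[[3]])
    expect_equal(r$ana, r$num, tolerance = 5e-2,
                 label = paste(c(cs[[1]], cs[[2]]), collapse = "/"))
  }
})
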