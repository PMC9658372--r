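test_that("accuracy is an exact recount", {
  p <- prediction_set(true = c(0, 1, 2, 1), pred = c(0, 1, 2, 1))
  expect_equal(accuracy(p), 1)
  p2 <- prediction_set(true = c(0, 1, 2, 3), pred = c(0, 1, 2, 0))
  expect_equal(accuracy(p2), 0.75)

  set.seed(31)
  for (i in 1:20) {
    n <- sample(1:50, 1)
    true <- sample(0:4, n, replace = TRUE)
    pred <- sample(0:4, n, replace = TRUE)
    expect_equal(accuracy(prediction_set(true, pred)),
                 sum(true == pred) / n)
  }
  expect_error(prediction_set(integer(0), integer(0)), "empty")
})

make_tax_manifest <- function() {
  build_manifest(fake_records(
    c(a1 = 2L, a2 = 2L, b1 = 2L, b2 = 2L),
    family_of = list(a1 = "F1", a2 = "F1", b1 = "F2", b2 = "F2"),
    genus_of = list(a1 = "G1", a2 = "G1", b1 = "G2", b2 = "G2")))
}

test_that("roll-up maps labels upward and accuracy is monotone in the hierarchy", {
  m <- make_tax_manifest()
  idx <- m$class_index$species
  # correct species prediction is correct at all levels
  p <- prediction_set(true = idx[["a1"]], pred = idx[["a1"]])
  expect_equal(accuracy(rollup(p, m, "genus")), 1)
  expect_equal(accuracy(rollup(p, m, "family")), 1)

  # wrong species but same genus counts at genus and family
  p2 <- prediction_set(true = idx[["a1"]], pred = idx[["a2"]])
  expect_equal(accuracy(p2), 0)
  expect_equal(accuracy(rollup(p2, m, "genus")), 1)
  expect_equal(accuracy(rollup(p2, m, "family")), 1)

  set.seed(32)
  K <- length(idx)
  for (i in 1:100) {
    n <- sample(1:30, 1)
    ps <- prediction_set(sample(0:(K - 1), n, TRUE), sample(0:(K - 1), n, TRUE))
    acc_sp <- accuracy(ps)
    acc_ge <- accuracy(rollup(ps, m, "genus"))
    acc_fa <- accuracy(rollup(ps, m, "family"))
    expect_gte(acc_ge, acc_sp)
    expect_gte(acc_fa, acc_ge)
  }

  expect_error(rollup(prediction_set(0L, 99L), m, "genus"), "mapping error")
})

test_that("roll-up aggregates probability mass over the upper-level classes", {
  m <- make_tax_manifest()
  prob <- matrix(c(0.4, 0.3, 0.2, 0.1), 1)
  p <- prediction_set(true = 0L, pred = 0L, prob = prob)
  pg <- rollup(p, m, "genus")
  expect_equal(rowSums(pg$prob), 1)
  expect_equal(ncol(pg$prob), 2L)
})

test_that("per-class accuracies bin with a closed middle interval", {
  expect_equal(unname(bin_per_class(c(1, 1, 1))), c(0, 0, 1))
  expect_equal(unname(bin_per_class(c(0.84, 0.85, 0.90, 0.91))),
               c(0.25, 0.5, 0.25))
  expect_equal(unname(bin_per_class(0.85)), c(0, 1, 0))
  set.seed(33)
  for (i in 1:20) {
    acc <- runif(sample(1:40, 1))
    b <- bin_per_class(acc)
    expect_equal(sum(b), 1, tolerance = 1e-9)
  }
  # moving one class across an edge moves exactly 1/K of mass
  accs <- c(0.5, 0.86, 0.95, 0.99)
  b1 <- bin_per_class(accs)
  accs[1] <- 0.87
  b2 <- bin_per_class(accs)
  expect_equal(b2[["low"]] - b1[["low"]], -0.25)
  expect_equal(b2[["mid"]] - b1[["mid"]], 0.25)
  expect_error(bin_per_class(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("top_k ranks by confidence with index tie-breaking", {
  s <- c(0.1, 0.5, 0.15, 0.25)
  full <- top_k(s, k = 4)
  expect_equal(full$class, c(1L, 3L, 2L, 0L))
  expect_equal(full$confidence, sort(s, decreasing = TRUE))

  uni <- top_k(rep(0.25, 4), k = 2)
  expect_equal(uni$class, c(0L, 1L))

  set.seed(34)
  for (i in 1:25) {
    p <- runif(10); p <- p / sum(p)
    k <- sample(1:10, 1)
    tk <- top_k(p, k)
    ord <- order(-p, seq_along(p))[seq_len(k)]
    expect_equal(tk$class, ord - 1L)
    expect_equal(tk$confidence, p[ord])
  }
  expect_error(top_k(c(0.5, 0.5), k = 3), "parameter error")
})

test_that("named probability vectors keep their labels through top_k", {
  s <- c(alpha = 0.2, beta = 0.7, gamma = 0.1)
  tk <- top_k(s, k = 2)
  expect_equal(tk$label, c("beta", "alpha"))
})
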