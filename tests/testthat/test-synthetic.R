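test_that("generation is deterministic and byte-identical per seed", {
  spec <- synthetic_spec(2L, 1L, 2L, 3L, seed = 7L)
  d1 <- file.path(tempdir(), "det_a")
  d2 <- file.path(tempdir(), "det_b")
  m1 <- generate_dataset(spec, d1)
  m2 <- generate_dataset(spec, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  expect_identical(m1$records, m2$records)
})

test_that("the class plan and per-class counts match the spec arithmetic", {
  ds <- toy_dataset(2L, 2L, 2L, 4L, seed = 3L)
  s <- summarize_manifest(ds$manifest)
  expect_equal(s$classes, c(2L, 4L, 8L))
  expect_equal(s$mean_images[s$level == "species"], 4)
  expect_equal(nrow(ds$manifest$records), 32L)
  counts <- table(ds$manifest$records$species)
  expect_true(all(counts == 4L))
  # appearance factors: hue per genus, stripe frequency per species in genus
  plan <- ds$spec$plan
  expect_equal(length(unique(plan$hue)), 4L)
  expect_true(all(tapply(plan$stripe_freq, plan$genus,
                         function(v) length(unique(v))) == 2L))
})

test_that("rendered masks are exact, binary and reasonably sized", {
  spec <- synthetic_spec(3L, 1L, 1L, 1L, seed = 5L)
  fractions <- c()
  for (i in 1:30) {
    r <- render_image(spec, spec$plan$species[(i %% 3) + 1], seed = 1000 + i)
    expect_true(all(r$mask %in% c(0, 1)))
    expect_true(all(r$image >= 0 & r$image <= 1))
    fractions <- c(fractions, mean(r$mask))
    # determinism of a single render
    r2 <- render_image(spec, spec$plan$species[(i %% 3) + 1], seed = 1000 + i)
    expect_identical(r$image, r2$image)
    expect_identical(r$mask, r2$mask)
  }
  expect_true(all(fractions >= 0.05 & fractions <= 0.40))
})

test_that("nearest-neighbour downsampling keeps masks binary", {
  spec <- synthetic_spec(1L, 1L, 1L, 1L, seed = 9L)
  r <- render_image(spec, 1, seed = 77)
  small <- resize_nearest(r$mask, 56)
  expect_equal(dim(small), c(56L, 56L))
  expect_true(all(small %in% c(0, 1)))
  expect_gt(sum(small), 0)
})

test_that("written mask files reproduce the in-memory mask support", {
  dir <- file.path(tempdir(), "mask_rt")
  spec <- synthetic_spec(1L, 1L, 1L, 2L, seed = 11L, format = "png")
  man <- if (dir.exists(dir)) read_manifest(file.path(dir, "manifest.csv"))
         else generate_dataset(spec, dir)
  rec <- man$records[1, ]
  mask_path <- file.path(dir, paste0(tools::file_path_sans_ext(rec$path),
                                     ".mask.png"))
  expect_true(file.exists(mask_path))
  disk <- png::readPNG(mask_path)
  r <- render_image(spec, rec$species, amcnn:::image_seed(spec$seed, 1L))
  expect_equal(disk, r$mask, ignore_attr = TRUE)
  # PNG images are written losslessly
  img <- png::readPNG(file.path(dir, rec$path))
  expect_equal(img, round(r$image * 255) / 255, tolerance = 1/255)
})

test_that("oracle masks sharpen foreground attention on the stem features", {
  ds <- toy_dataset(2L, 1L, 2L, 3L, seed = 2L)
  rec <- ds$manifest$records[1, ]
  img <- read_image(file.path(ds$dir, rec$path))
  x <- (array(img, c(224, 224, 3, 1)) - 0.5) / 0.25
  model <- amcnn_model(amcnn_spec(4), seed = 0)
  p <- primary_conv_forward(model, x, training = TRUE)
  mask <- mask_provider_oracle(ds$dir)(rec)
  w <- compute_weight_map(mask, omega = 5)
  pw <- apply_attention(p[, , , 1], w)
  fg <- mask == 1
  gain_fg <- mean(abs(pw[, , 1][fg])) / mean(abs(p[, , 1, 1][fg]))
  gain_bg <- mean(abs(pw[, , 1][!fg])) / mean(abs(p[, , 1, 1][!fg]))
  expect_gt(gain_fg, gain_bg)
  expect_equal(gain_bg, 1, tolerance = 1e-12)
})
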