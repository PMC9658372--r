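test_that("build_manifest indexes classes densely and validates taxonomy", {
  m1 <- build_manifest(fake_records(c(sp_a = 1L)))
  expect_s3_class(m1, "amcnn_manifest")
  expect_length(m1$class_index$family, 1L)
  expect_length(m1$class_index$genus, 1L)
  expect_length(m1$class_index$species, 1L)

  m2 <- build_manifest(fake_records(c(sp_a = 2L)))
  expect_equal(nrow(m2$records), 2L)
  expect_length(m2$class_index$species, 1L)

  for (lvl in c("family", "genus", "species")) {
    idx <- m2$class_index[[lvl]]
    expect_identical(sort(unname(idx)), seq_along(idx) - 1L)
  }

  # species "x" under two genera is inconsistent
  recs <- rbind(
    data.frame(record_id = "a", path = "a.jpg", family = "f", genus = "g1",
               species = "x", stringsAsFactors = FALSE),
    data.frame(record_id = "b", path = "b.jpg", family = "f", genus = "g2",
               species = "x", stringsAsFactors = FALSE))
  expect_error(build_manifest(recs), "taxonomy error.*x")

  dup <- fake_records(c(sp_a = 2L))
  dup$record_id <- "same"
  expect_error(build_manifest(dup), "duplicate record_id")
  expect_error(build_manifest(fake_records(c(sp_a = 1L))[0, ]), "non-empty")
})

test_that("filter_min_images drops sparse species at the stated boundary", {
  m <- build_manifest(fake_records(c(rare = 19L, edge = 20L, rich = 30L)))
  f <- filter_min_images(m, k = 20L)
  expect_setequal(names(f$class_index$species), c("edge", "rich"))
  expect_equal(nrow(f$records), 50L)
  # indices rebuilt dense
  expect_identical(sort(unname(f$class_index$species)), 0:1)
  # k = 1 is vacuous; filtering is idempotent
  expect_identical(filter_min_images(m, 1L)$records, m$records)
  f2 <- filter_min_images(f, k = 20L)
  expect_identical(f2$records, f$records)
  expect_error(filter_min_images(m, k = 100L), "empty manifest")
})

test_that("summarize matches a brute-force recount", {
  m <- build_manifest(fake_records(
    c(s1 = 10L, s2 = 10L),
    family_of = list(s1 = "F", s2 = "F"),
    genus_of = list(s1 = "G", s2 = "G")))
  s <- summarize_manifest(m)
  expect_equal(s$classes[s$level == "species"], 2L)
  expect_equal(s$mean_images[s$level == "species"], 10)
  expect_equal(s$classes[s$level == "genus"], 1L)
  expect_equal(s$mean_images[s$level == "genus"], 20)

  # random manifest vs independent recount
  set.seed(42)
  counts <- sample(1:12, 7)
  names(counts) <- paste0("sp", 1:7)
  m2 <- build_manifest(fake_records(counts))
  s2 <- summarize_manifest(m2)
  for (lvl in c("family", "genus", "species")) {
    expect_equal(s2$classes[s2$level == lvl],
                 length(unique(m2$records[[lvl]])))
    expect_equal(s2$mean_images[s2$level == lvl],
                 nrow(m2$records) / length(unique(m2$records[[lvl]])))
  }
})

test_that("split respects the floor-then-remainder rule", {
  m100 <- build_manifest(fake_records(stats::setNames(rep(10L, 10), paste0("s", 1:10))))
  sp <- split_manifest(m100, seed = 3L)
  tab <- table(sp$assignment)
  expect_equal(unname(tab[c("train", "val", "test")]), c(80L, 10L, 10L),
               ignore_attr = TRUE)

  m10 <- build_manifest(fake_records(c(only = 10L)))
  tab10 <- table(split_manifest(m10, seed = 1L)$assignment)
  expect_equal(unname(tab10[c("train", "val", "test")]), c(8L, 1L, 1L),
               ignore_attr = TRUE)

  # n = 13: floor(1.3) = 1 to val and test, remainder 11 to train
  m13 <- build_manifest(fake_records(c(only = 13L)))
  tab13 <- table(split_manifest(m13, seed = 1L)$assignment)
  expect_equal(unname(tab13[c("train", "val", "test")]), c(11L, 1L, 1L),
               ignore_attr = TRUE)

  expect_error(split_manifest(m10, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_warning(
    expect_warning(split_manifest(build_manifest(fake_records(c(tiny = 4L)))),
                   "received 0 records"),
    "received 0 records")
})

test_that("split is a deterministic partition for any seed", {
  set.seed(7)
  counts <- stats::setNames(sample(3:9, 5, replace = TRUE), paste0("s", 1:5))
  m <- build_manifest(fake_records(counts))
  for (seed in c(0L, 1L, 99L)) {
    for (strat in c(TRUE, FALSE)) {
      a <- suppressWarnings(split_manifest(m, seed = seed, stratify = strat))
      b <- suppressWarnings(split_manifest(m, seed = seed, stratify = strat))
      expect_identical(a$assignment, b$assignment)
      # partition: every record exactly once
      expect_setequal(names(a$assignment), m$records$record_id)
      expect_true(all(a$assignment %in% c("train", "val", "test")))
    }
  }
  # stratified default: every species with >= 3 images reaches train
  a <- suppressWarnings(split_manifest(m, seed = 5L))
  tr <- split_records(m, a, "train")
  expect_setequal(unique(tr$species), names(counts))
})

test_that("manifests round-trip through CSV and JSON", {
  m <- build_manifest(fake_records(c(s1 = 3L, s2 = 2L)))
  for (ext in c("csv", "json")) {
    path <- file.path(tempdir(), paste0("manifest_rt.", ext))
    write_manifest(m, path)
    m2 <- read_manifest(path)
    expect_equal(m2$records$record_id, m$records$record_id)
    expect_equal(m2$records$species, m$records$species)
    expect_identical(m2$class_index, m$class_index)
  }
})

test_that("a directory tree ingests as a manifest", {
  ds <- toy_dataset(2L, 1L, 2L, 3L, seed = 2L)
  m <- manifest_from_dir(ds$dir)
  expect_equal(nrow(m$records), nrow(ds$manifest$records))
  expect_identical(m$class_index, ds$manifest$class_index)
  expect_false(any(grepl("mask", m$records$path)))
})
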