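# Shared fixtures.  Synthetic datasets are generated once per test run and
# cached in the session temp directory; everything is built in code.

.fixture_env <- new.env(parent = emptyenv())

# A small on-disk synthetic dataset (full-size 224px images).
toy_dataset <- function(n_families = 2L, genera = 1L, species = 2L,
                        images = 10L, seed = 1L) {
  key <- paste("ds", n_families, genera, species, images, seed, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    dir <- file.path(tempdir(), paste0("amcnn_", key))
    spec <- synthetic_spec(n_families, genera, species, images, seed = seed)
    manifest <- if (dir.exists(dir)) read_manifest(file.path(dir, "manifest.csv"))
                else generate_dataset(spec, dir)
    .fixture_env[[key]] <- list(dir = dir, spec = spec, manifest = manifest)
  }
  .fixture_env[[key]]
}

# In-memory record table for manifest-level tests (no images on disk).
fake_records <- function(species_counts, family_of = NULL, genus_of = NULL) {
  rows <- list()
  i <- 0L
  for (sp in names(species_counts)) {
    fam <- if (is.null(family_of)) paste0("fam_", substr(sp, 1, 1)) else family_of[[sp]]
    gen <- if (is.null(genus_of)) paste0("gen_", substr(sp, 1, 2)) else genus_of[[sp]]
    for (k in seq_len(species_counts[[sp]])) {
      i <- i + 1L
      rows[[i]] <- data.frame(record_id = sprintf("r%04d", i),
                              path = sprintf("img/%s_%03d.jpg", sp, k),
                              family = fam, genus = gen, species = sp,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# A tiny architecture for fast network-level tests.
tiny_spec <- function(n_classes = 3L, ...) {
  amcnn_spec(n_classes = n_classes, spp_levels = c(1L, 2L), input_side = 32L,
             backbone_channels = c(8L, 8L, 12L, 16L, 24L), hidden = 16L, ...)
}

random_binary_mask <- function(side = 56L, p = 0.3) {
  matrix(as.numeric(stats::runif(side * side) < p), side, side)
}
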