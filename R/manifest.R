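#' Build a dataset manifest from image records
#'
#' A manifest is the unit of curation, splitting and evaluation: an ordered
#' table of image records, each carrying a three-level taxonomic label
#' (family, genus, species), together with dense 0-based class indices at
#' every level.  The taxonomy must be functionally consistent: a species
#' belongs to exactly one genus and a genus to exactly one family.
#'
#' @param records A data.frame with character columns `record_id`, `path`,
#'   `family`, `genus`, `species`, and optionally integer `width`, `height`,
#'   character `format` (`"jpeg"` or `"png"`; inferred from the path
#'   extension when absent) and logical `curated` (outcome of any manual
#'   screening, default `TRUE`; carried through, never interpreted).
#' @return An object of class `amcnn_manifest`: a list with `records` (the
#'   validated data.frame, order preserved) and `class_index`, a per-level
#'   list of named integer vectors mapping class name to a dense 0-based
#'   index.
#' @examples
#' recs <- data.frame(
#'   record_id = c("a", "b"), path = c("a.jpg", "b.jpg"),
#'   family = "Anatidae", genus = "Anas",
#'   species = c("Anas crecca", "Anas crecca")
#' )
#' m <- build_manifest(recs)
#' length(m$class_index$species)  # 1 class, 2 records
#' @export
build_manifest <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame")
  needed <- c("record_id", "path", "family", "genus", "species")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in needed) {
    records[[col]] <- as.character(records[[col]])
    if (anyNA(records[[col]]) || any(!nzchar(records[[col]])))
      stop("column '", col, "' contains empty or missing values")
  }
  dup <- records$record_id[duplicated(records$record_id)]
  if (length(dup))
    stop("duplicate record_id: ", paste(unique(dup), collapse = ", "))

  # Functional-dependency check: species -> genus -> family.
  sp <- unique(records[, c("family", "genus", "species")])
  bad_sp <- unique(sp$species[duplicated(sp$species)])
  if (length(bad_sp))
    stop("taxonomy error: species under multiple genera/families: ",
         paste(bad_sp, collapse = ", "))
  ge <- unique(sp[, c("family", "genus")])
  bad_ge <- unique(ge$genus[duplicated(ge$genus)])
  if (length(bad_ge))
    stop("taxonomy error: genus under multiple families: ",
         paste(bad_ge, collapse = ", "))

  if (is.null(records$format))
    records$format <- ifelse(grepl("\\.png$", records$path, ignore.case = TRUE),
                             "png", "jpeg")
  if (!all(records$format %in% c("jpeg", "png")))
    stop("format must be 'jpeg' or 'png'")
  if (is.null(records$width)) records$width <- NA_integer_
  if (is.null(records$height)) records$height <- NA_integer_
  ok_dim <- function(v) all(is.na(v) | v >= 1L)
  if (!ok_dim(records$width) || !ok_dim(records$height))
    stop("width and height must be >= 1")
  # manual curation (non-bird/caricature/torso screening) is outside this
  # package; its outcome travels along as a boolean flag
  if (is.null(records$curated)) records$curated <- TRUE
  records$curated <- as.logical(records$curated)
  if (anyNA(records$curated)) stop("curated must be logical")

  class_index <- lapply(c(family = "family", genus = "genus", species = "species"),
                        function(col) {
                          cls <- sort(unique(records[[col]]))
                          stats::setNames(seq_along(cls) - 1L, cls)
                        })
  structure(list(records = records, class_index = class_index),
            class = "amcnn_manifest")
}

#' @export
print.amcnn_manifest <- function(x, ...) {
  cat("Dataset manifest:", nrow(x$records), "images;",
      length(x$class_index$family), "families,",
      length(x$class_index$genus), "genera,",
      length(x$class_index$species), "species\n")
  invisible(x)
}

#' Discard species classes with too few images
#'
#' Curation rule applied before training: any species with fewer than `k`
#' images is dropped entirely (a species with exactly `k` images is kept).
#' Class indices are rebuilt dense on the surviving records; record order is
#' preserved.  The default threshold of 20 reflects the minimum class size
#' commonly required for CNN training on curated bird image collections.
#'
#' @param manifest An `amcnn_manifest`.
#' @param k Minimum number of images per species (default 20).
#' @return A new `amcnn_manifest` containing only surviving species.
#' @export
filter_min_images <- function(manifest, k = 20L) {
  stopifnot(inherits(manifest, "amcnn_manifest"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  counts <- table(manifest$records$species)
  keep <- names(counts)[counts >= k]
  recs <- manifest$records[manifest$records$species %in% keep, , drop = FALSE]
  if (nrow(recs) == 0L)
    stop("empty manifest: no species has at least ", k, " images")
  rownames(recs) <- NULL
  build_manifest(recs)
}

#' Summarize a manifest per taxonomic level
#'
#' @param manifest An `amcnn_manifest`.
#' @return A data.frame with one row per level (`family`, `genus`,
#'   `species`) and columns `level`, `classes`, `images`, `mean_images`
#'   (total images / class count).
#' @export
summarize_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "amcnn_manifest"))
  n <- nrow(manifest$records)
  if (n == 0L) stop("manifest is empty")
  levels <- c("family", "genus", "species")
  classes <- vapply(levels, function(l) length(manifest$class_index[[l]]), 0L)
  data.frame(level = levels, classes = classes, images = n,
             mean_images = n / classes, row.names = NULL)
}

#' @export
summary.amcnn_manifest <- function(object, ...) {
  s <- summarize_manifest(object)
  class(s) <- c("summary.amcnn_manifest", "data.frame")
  s
}

#' Split a manifest into train/validation/test parts
#'
#' Records are assigned at random to the three parts.  The non-train part
#' sizes are floored (`floor(n * fraction)`), the remainder going to train,
#' so train never starves.  By default the split is stratified per species,
#' which guarantees every species with at least 3 images appears in the
#' training part; set `stratify = FALSE` for a plain global shuffle.
#'
#' @param manifest An `amcnn_manifest`.
#' @param fractions Numeric vector of train/val/test fractions, positive,
#'   summing to 1 (default `c(0.8, 0.1, 0.1)`).
#' @param seed Integer RNG seed; the same seed always yields the same
#'   assignment.
#' @param stratify Stratify per species (default `TRUE`).
#' @return An object of class `amcnn_split`: list with `assignment` (named
#'   character vector record_id -> `"train"`/`"val"`/`"test"`), `seed`,
#'   `fractions` and `stratified`.
#' @export
split_manifest <- function(manifest, fractions = c(train = 0.8, val = 0.1, test = 0.1),
                           seed = 0L, stratify = TRUE) {
  stopifnot(inherits(manifest, "amcnn_manifest"))
  fractions <- unname(as.numeric(fractions))
  if (length(fractions) != 3L || any(fractions <= 0))
    stop("fractions must be three positive numbers (train, val, test)")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1")

  assign_group <- function(ids) {
    n <- length(ids)
    n_val <- floor(n * fractions[2L])
    n_test <- floor(n * fractions[3L])
    n_train <- n - n_val - n_test
    perm <- sample(n)
    parts <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
    stats::setNames(parts[order(perm)], ids)
  }

  assignment <- with_seed(seed, {
    if (stratify) {
      out <- character(nrow(manifest$records))
      names(out) <- manifest$records$record_id
      for (sp in names(manifest$class_index$species)) {
        ids <- manifest$records$record_id[manifest$records$species == sp]
        out[ids] <- assign_group(ids)
      }
      out
    } else {
      assign_group(manifest$records$record_id)
    }
  })

  n <- length(assignment)
  for (part in c("train", "val", "test")) {
    if (n >= 3L && !any(assignment == part))
      warning("split part '", part, "' received 0 records")
  }
  structure(list(assignment = assignment, seed = as.integer(seed),
                 fractions = c(train = fractions[1L], val = fractions[2L],
                               test = fractions[3L]),
                 stratified = isTRUE(stratify)),
            class = "amcnn_split")
}

#' @export
print.amcnn_split <- function(x, ...) {
  tab <- table(factor(x$assignment, levels = c("train", "val", "test")))
  cat("Split (seed ", x$seed, if (x$stratified) ", stratified" else "", "): ",
      paste(names(tab), as.integer(tab), sep = "=", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Subset a manifest's records by split part
#'
#' @param manifest An `amcnn_manifest`.
#' @param split An `amcnn_split` for that manifest.
#' @param part One of `"train"`, `"val"`, `"test"`.
#' @return The record data.frame restricted to the part, order preserved.
#' @export
split_records <- function(manifest, split, part = c("train", "val", "test")) {
  part <- match.arg(part)
  stopifnot(inherits(split, "amcnn_split"))
  ids <- names(split$assignment)[split$assignment == part]
  recs <- manifest$records[manifest$records$record_id %in% ids, , drop = FALSE]
  rownames(recs) <- NULL
  recs
}

#' Read and write manifests (CSV or JSON)
#'
#' The on-disk manifest is a plain table with columns `record_id`, `path`,
#' `family`, `genus`, `species`, `width`, `height`, `format`; the format is
#' chosen from the file extension (`.csv` or `.json`).
#'
#' @param manifest An `amcnn_manifest`.
#' @param path Output (or input) file path.
#' @return `read_manifest` returns an `amcnn_manifest`; `write_manifest`
#'   returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "amcnn_manifest"))
  cols <- c("record_id", "path", "family", "genus", "species",
            "width", "height", "format", "curated")
  df <- manifest$records[, cols]
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else stop("unsupported manifest extension: ", ext)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (ext == "json") {
    jsonlite::fromJSON(path)
  } else stop("unsupported manifest extension: ", ext)
  build_manifest(df)
}

#' Build a manifest from a directory tree
#'
#' Ingests the layout `<root>/<family>/<genus>/<species>/<image>` with JPEG
#' or PNG images; `.mask.png` companions are ignored.  Record ids are paths
#' relative to `root`.
#'
#' @param root Directory holding the taxonomy tree.
#' @return An `amcnn_manifest` with paths relative to `root`.
#' @export
manifest_from_dir <- function(root) {
  files <- list.files(root, pattern = "\\.(jpe?g|png)$", recursive = TRUE,
                      ignore.case = TRUE)
  files <- files[!grepl("\\.mask\\.png$", files, ignore.case = TRUE)]
  if (!length(files)) stop("no images found under ", root)
  parts <- strsplit(files, "/", fixed = TRUE)
  depth <- lengths(parts)
  if (any(depth != 4L))
    stop("expected <family>/<genus>/<species>/<image> layout")
  df <- data.frame(
    record_id = files,
    path = files,
    family = vapply(parts, `[[`, "", 1L),
    genus = vapply(parts, `[[`, "", 2L),
    species = vapply(parts, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$record_id), , drop = FALSE]
  rownames(df) <- NULL
  build_manifest(df)
}
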