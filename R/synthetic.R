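# Seeded generator of hierarchically labelled images with exact foreground
# masks.  The class signal is deliberately local and shallow, mirroring
# what the attention + shallow-feature architecture is built to exploit:
# the family determines the foreground silhouette (ellipse / triangle /
# rectangle), the genus a distinct base hue, and the species the stripe
# frequency of the foreground texture.  Backgrounds are cluttered (corner
# colour gradient + soft ellipses + Gaussian noise) so the foreground mask
# genuinely matters.

#' Synthetic dataset specification
#'
#' @param n_families,genera_per_family,species_per_genus Class plan; total
#'   species = product of the three.
#' @param images_per_species Images rendered per species (default 50).
#' @param image_side Image side in pixels (default 224).
#' @param seed Root seed; every image derives its own RNG stream from it,
#'   so generation is deterministic and order-independent.
#' @param background_noise_sd Gaussian pixel noise added after compositing
#'   (default 0.05 on the `[0, 1]` intensity scale).
#' @param format `"jpeg"` (default) or `"png"` image files; masks are
#'   always lossless PNG.
#' @return An object of class `amcnn_synthetic_spec` with the per-species
#'   appearance `plan`.
#' @export
synthetic_spec <- function(n_families = 2L, genera_per_family = 2L,
                           species_per_genus = 2L, images_per_species = 50L,
                           image_side = 224L, seed = 0L,
                           background_noise_sd = 0.05,
                           format = c("jpeg", "png")) {
  stopifnot(n_families >= 1L, genera_per_family >= 1L, species_per_genus >= 1L,
            images_per_species >= 1L, image_side >= 32L,
            background_noise_sd >= 0)
  format <- match.arg(format)
  shapes <- c("ellipse", "triangle", "rect")
  n_genera <- n_families * genera_per_family
  plan <- expand.grid(si = seq_len(species_per_genus),
                      gi = seq_len(genera_per_family),
                      fi = seq_len(n_families))
  plan <- plan[, c("fi", "gi", "si")]
  plan$family <- sprintf("family%02d", plan$fi)
  plan$genus <- sprintf("family%02d_genus%02d", plan$fi, plan$gi)
  plan$species <- sprintf("family%02d_genus%02d_species%02d",
                          plan$fi, plan$gi, plan$si)
  plan$shape <- shapes[(plan$fi - 1L) %% length(shapes) + 1L]
  g_global <- (plan$fi - 1L) * genera_per_family + plan$gi
  plan$hue <- (g_global - 1L) / n_genera
  plan$stripe_freq <- 2 + 8 * (plan$si - 1L)
  structure(list(n_families = as.integer(n_families),
                 genera_per_family = as.integer(genera_per_family),
                 species_per_genus = as.integer(species_per_genus),
                 images_per_species = as.integer(images_per_species),
                 image_side = as.integer(image_side), seed = as.integer(seed),
                 background_noise_sd = background_noise_sd,
                 format = format, plan = plan),
            class = "amcnn_synthetic_spec")
}

# Per-image RNG stream: a fixed multiplicative hash of (root seed, counter),
# kept inside the 32-bit integer range set.seed() accepts.
image_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(counter) * 7919 + 17) %%
             2147483647)
}

#' Render one synthetic image and its exact mask
#'
#' Draws a cluttered background, then a single foreground shape whose
#' silhouette, hue and stripe frequency encode family, genus and species.
#' Position, rotation and scale are random within margins that keep the
#' shape fully inside the frame and its area between roughly 5% and 40% of
#' the image.  The returned mask is the exact pixel support of the shape
#' (no anti-aliasing).
#'
#' @param spec An [synthetic_spec()].
#' @param species Species name from `spec$plan$species` (or its row index).
#' @param seed Integer seed for this render.
#' @return List with `image` `(side, side, 3)` in `[0, 1]` and binary
#'   `mask` `(side, side)`.
#' @export
render_image <- function(spec, species, seed) {
  stopifnot(inherits(spec, "amcnn_synthetic_spec"))
  row <- if (is.numeric(species)) spec$plan[species, , drop = FALSE]
         else spec$plan[spec$plan$species == species, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown species: ", species)
  with_seed(seed, render_core(row$shape, row$hue, row$stripe_freq,
                              spec$image_side, spec$background_noise_sd))
}

render_core <- function(shape, hue, stripe_freq, S, noise_sd) {
  xs <- matrix(rep(seq_len(S), each = S), S, S)   # column index
  ys <- matrix(rep(seq_len(S), S), S, S)          # row index

  # background: bilinear gradient between four corner colours
  cc <- matrix(runif(12, 0.15, 0.85), 4, 3)
  wy <- (ys - 1) / (S - 1); wx <- (xs - 1) / (S - 1)
  img <- array(0, c(S, S, 3))
  for (ch in 1:3)
    img[, , ch] <- (1 - wy) * (1 - wx) * cc[1, ch] + (1 - wy) * wx * cc[2, ch] +
                   wy * (1 - wx) * cc[3, ch] + wy * wx * cc[4, ch]

  # clutter: soft ellipses blended into the background
  for (k in seq_len(5)) {
    ccx <- runif(1, 1, S); ccy <- runif(1, 1, S)
    ra <- runif(1, 0.05, 0.2) * S; rb <- runif(1, 0.05, 0.2) * S
    th <- runif(1, 0, pi)
    u <- (xs - ccx) * cos(th) + (ys - ccy) * sin(th)
    v <- -(xs - ccx) * sin(th) + (ys - ccy) * cos(th)
    inside <- (u / ra)^2 + (v / rb)^2 <= 1
    col <- runif(3, 0.1, 0.9)
    for (ch in 1:3)
      img[, , ch][inside] <- 0.4 * img[, , ch][inside] + 0.6 * col[ch]
  }

  # foreground geometry: random centre/rotation/area within margins
  cx <- runif(1, 0.4, 0.6) * S
  cy <- runif(1, 0.4, 0.6) * S
  theta <- runif(1, 0, pi)
  area <- runif(1, 0.12, 0.3) * S^2
  margin <- min(cx, cy, S - cx, S - cy) - 1
  u <- (xs - cx) * cos(theta) + (ys - cy) * sin(theta)
  v <- -(xs - cx) * sin(theta) + (ys - cy) * cos(theta)

  if (shape == "ellipse") {
    q <- runif(1, 0.5, 0.85)
    a <- min(sqrt(area / (pi * q)), margin)
    b <- q * a
    mask <- (u / a)^2 + (v / b)^2 <= 1
    extent <- a
  } else if (shape == "triangle") {
    r <- min(sqrt(area / (3 * sqrt(3) / 4)), margin)
    ang <- 2 * pi * (0:2) / 3
    mask <- matrix(TRUE, S, S)
    for (ak in ang) mask <- mask & (u * cos(ak) + v * sin(ak) <= r / 2)
    extent <- r
  } else {
    q <- runif(1, 0.45, 0.8)
    w <- sqrt(area / q); h <- q * w
    hd <- sqrt(w^2 + h^2) / 2
    if (hd > margin) { s <- margin / hd; w <- w * s; h <- h * s }
    mask <- abs(u) <= w / 2 & abs(v) <= h / 2
    extent <- w / 2
  }

  # foreground colour: genus hue, species stripe frequency along the
  # object's own axis
  base <- col2rgb(hsv(hue, 0.75, 0.9))[, 1] / 255
  phase <- runif(1, 0, 2 * pi)
  mod <- ifelse(sin(2 * pi * stripe_freq * u / (2 * extent) + phase) > 0, 1, 0.05)
  for (ch in 1:3)
    img[, , ch][mask] <- (base[ch] * mod)[mask]

  if (noise_sd > 0)
    img <- img + array(rnorm(S * S * 3, 0, noise_sd), c(S, S, 3))
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask * 1)
}

#' Generate a synthetic dataset on disk
#'
#' Writes images, exact `.mask.png` masks and a CSV manifest under
#' `output_dir` in the layout `<family>/<genus>/<species>/img_NNNN.<ext>`.
#' Generation is deterministic given `spec$seed`: rerunning into a fresh
#' directory reproduces byte-identical files.
#'
#' @param spec An [synthetic_spec()].
#' @param output_dir Output directory (created if missing; its parent must
#'   exist).
#' @return The dataset's [build_manifest()] manifest (paths relative to
#'   `output_dir`); also written to `manifest.csv` there.
#' @export
generate_dataset <- function(spec, output_dir) {
  stopifnot(inherits(spec, "amcnn_synthetic_spec"))
  if (!dir.exists(output_dir)) {
    if (!dir.exists(dirname(output_dir)))
      stop("I/O error: parent directory does not exist: ", dirname(output_dir))
    dir.create(output_dir)
  }
  ext <- if (spec$format == "jpeg") "jpg" else "png"
  plan <- spec$plan
  counter <- 0L
  rows <- vector("list", nrow(plan) * spec$images_per_species)
  for (p in seq_len(nrow(plan))) {
    rel_dir <- file.path(plan$family[p], plan$genus[p], plan$species[p])
    dir.create(file.path(output_dir, rel_dir), recursive = TRUE,
               showWarnings = FALSE)
    for (i in seq_len(spec$images_per_species)) {
      counter <- counter + 1L
      r <- render_image(spec, plan$species[p], image_seed(spec$seed, counter))
      rel <- file.path(rel_dir, sprintf("img_%04d.%s", i, ext))
      path <- file.path(output_dir, rel)
      if (spec$format == "jpeg") jpeg::writeJPEG(r$image, path, quality = 0.95)
      else png::writePNG(r$image, path)
      png::writePNG(r$mask, paste0(tools::file_path_sans_ext(path), ".mask.png"))
      rows[[counter]] <- data.frame(
        record_id = rel, path = rel,
        family = plan$family[p], genus = plan$genus[p],
        species = plan$species[p],
        width = spec$image_side, height = spec$image_side,
        format = spec$format, stringsAsFactors = FALSE)
    }
  }
  manifest <- build_manifest(do.call(rbind, rows))
  write_manifest(manifest, file.path(output_dir, "manifest.csv"))
  manifest
}
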