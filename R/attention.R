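# The attention mechanism: a 56x56 binary foreground mask U is mapped to a
# multiplicative weight map A that amplifies bird-region feature-map
# positions by a factor omega and leaves background positions at 1, i.e.
# A(i,j) = omega where U(i,j) = 1 and A(i,j) = 1 where U(i,j) = 0.  The
# weight map is applied to the stem feature map by an elementwise product
# broadcast over channels.

MASK_SIDE <- 56L

validate_binary_mask <- function(mask, side = MASK_SIDE) {
  if (!is.matrix(mask) || nrow(mask) != side || ncol(mask) != side)
    stop("shape error: mask must be a ", side, "x", side, " matrix")
  if (!all(mask %in% c(0, 1)))
    stop("mask entries must be exactly 0 or 1")
  invisible(mask)
}

#' Map a binary foreground mask to a multiplicative weight map
#'
#' Foreground positions (mask value 1) receive the weight `omega`;
#' background positions receive 1, so `omega = 1` disables the attention
#' mechanism entirely.  The default `omega = 1.2` is the value at which the
#' attention-weighted model performs best in a sweep over amplification
#' factors: larger values increasingly amplify mask errors (background
#' pixels leaking into the mask), smaller ones under-use the foreground.
#'
#' @param mask 56x56 matrix with entries in \{0, 1\} (1 = bird region).
#' @param omega Positive amplification factor (default 1.2).
#' @return 56x56 numeric weight map whose entries are exactly `omega` on
#'   the mask's foreground and 1 elsewhere.
#' @export
compute_weight_map <- function(mask, omega = 1.2) {
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) || omega <= 0)
    stop("parameter error: omega must be a positive number")
  validate_binary_mask(mask)
  ifelse(mask == 1, omega, 1)
}

#' Reweight a feature map with an attention weight map
#'
#' Elementwise product of the weight map with every channel of the feature
#' map: `out[i,j,c] = features[i,j,c] * weights[i,j]`.
#'
#' @param features `(H, W, C)` or `(H, W, C, N)` numeric array.
#' @param weights `(H, W)` weight map, or `(H, W, N)` for a batch.
#' @return Array of the same shape as `features`.
#' @export
apply_attention <- function(features, weights) {
  fd <- dim(features)
  if (is.null(fd) || !(length(fd) %in% c(3L, 4L)))
    stop("features must be an (H, W, C[, N]) array")
  single <- length(fd) == 3L
  x <- if (single) array(features, c(fd, 1L)) else features
  wd <- dim(weights)
  w <- if (length(wd %||% 0L) == 3L) weights
       else array(weights, c(dim(weights), dim(x)[4L]))
  if (!all(dim(w)[1:2] == dim(x)[1:2]) || dim(w)[3L] != dim(x)[4L])
    stop("shape error: weight map does not match feature map spatially")
  out <- cpp_scale_spatial(x, w)
  if (single) array(out, fd) else out
}

#' Union, threshold and downsample soft instance masks
#'
#' Adapter for external instance-segmentation output: any number of
#' real-valued `(H, W)` masks in `[0, 1]` (one per detected bird) are
#' combined by pixelwise maximum, thresholded at `>= threshold`, and
#' downsampled to 56x56 by nearest neighbour (which preserves binarity).
#' When no instance is supplied, or no pixel survives the threshold, the
#' fallback is an all-ones mask: with no detection the attention layer then
#' degrades gracefully to the unweighted backbone.
#'
#' @param soft_masks A single matrix or list of `(H, W)` matrices in `[0, 1]`.
#' @param threshold Foreground threshold in (0, 1), default 0.5.
#' @param side Output side (default 56).
#' @return `side` x `side` binary matrix.
#' @export
binarize_and_resize <- function(soft_masks, threshold = 0.5, side = MASK_SIDE) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("parameter error: threshold must lie in (0, 1)")
  if (is.matrix(soft_masks)) soft_masks <- list(soft_masks)
  if (length(soft_masks) == 0L)
    return(matrix(1, side, side))
  d <- dim(soft_masks[[1L]])
  for (m in soft_masks) {
    if (!is.matrix(m) || !all(dim(m) == d))
      stop("shape error: instance masks must be matrices of equal size")
  }
  u <- Reduce(pmax, soft_masks)
  bin <- (u >= threshold) * 1
  if (!any(bin == 1)) return(matrix(1, side, side))
  resize_nearest(bin, side)
}

#' Mask providers
#'
#' A mask provider is a function taking one manifest record (a one-row
#' data.frame or list with at least `path`) and returning a 56x56 binary
#' foreground mask.  Three implementations are supplied:
#' `mask_provider_oracle()` reads the ground-truth mask stored next to the
#' image (same stem, suffix `.mask.png`, 0 = background);
#' `mask_provider_constant()` returns an all-foreground mask, which makes
#' the attention layer a uniform scaling by omega;
#' `mask_provider_external(fn)` adapts any soft instance-segmentation
#' backend through [binarize_and_resize()].
#'
#' @param image_root Optional directory that record paths are relative to.
#' @param fn Function(record) returning a matrix or list of `(H, W)` soft
#'   masks in `[0, 1]`.
#' @param threshold Threshold passed to [binarize_and_resize()].
#' @return A function `record -> 56x56 binary matrix`, classed
#'   `amcnn_mask_provider`.
#' @export
mask_provider_oracle <- function(image_root = NULL) {
  structure(function(record) {
    path <- if (is.null(image_root)) record$path else file.path(image_root, record$path)
    mask_path <- paste0(tools::file_path_sans_ext(path), ".mask.png")
    if (!file.exists(mask_path)) stop("no mask file: ", mask_path)
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    bin <- (m >= 0.5) * 1
    if (!any(bin == 1)) return(matrix(1, MASK_SIDE, MASK_SIDE))
    resize_nearest(bin, MASK_SIDE)
  }, class = c("amcnn_mask_provider", "function"))
}

#' @rdname mask_provider_oracle
#' @export
mask_provider_constant <- function() {
  structure(function(record) matrix(1, MASK_SIDE, MASK_SIDE),
            class = c("amcnn_mask_provider", "function"))
}

#' @rdname mask_provider_oracle
#' @export
mask_provider_external <- function(fn, threshold = 0.5) {
  stopifnot(is.function(fn))
  structure(function(record) binarize_and_resize(fn(record), threshold),
            class = c("amcnn_mask_provider", "function"))
}

# Fetch weight maps for a set of records: (56, 56, N) array.
weight_map_stack <- function(records, mask_provider, omega) {
  n <- nrow(records)
  out <- array(1, c(MASK_SIDE, MASK_SIDE, n))
  for (i in seq_len(n)) {
    mask <- mask_provider(records[i, , drop = FALSE])
    out[, , i] <- compute_weight_map(mask, omega)
  }
  out
}
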