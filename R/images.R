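# Image reading, resizing and tensor assembly.  Images live in [0, 1] as
# (H, W, 3) arrays; network input tensors are (side, side, 3, N) after
# channel normalisation (x - 0.5) / 0.25.

#' Read an image file as an (H, W, 3) array in [0, 1]
#'
#' @param path JPEG or PNG file.
#' @return Numeric array `(H, W, 3)`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("jpg", "jpeg")) jpeg::readJPEG(path)
         else if (ext == "png") png::readPNG(path)
         else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

#' Bilinear resize of an image array
#'
#' @param img `(H, W)` matrix or `(H, W, C)` array.
#' @param side Output side length (square output).
#' @return Resized array with the same number of channels.
#' @export
resize_bilinear <- function(img, side) {
  d <- dim(img)
  H <- d[1L]; W <- d[2L]
  if (H == side && W == side) return(img)
  # centre-aligned sample positions
  yi <- (seq_len(side) - 0.5) * H / side + 0.5
  xi <- (seq_len(side) - 0.5) * W / side + 0.5
  y0 <- pmin(pmax(floor(yi), 1L), H); y1 <- pmin(y0 + 1L, H)
  x0 <- pmin(pmax(floor(xi), 1L), W); x1 <- pmin(x0 + 1L, W)
  wy <- pmin(pmax(yi - y0, 0), 1); wx <- pmin(pmax(xi - x0, 0), 1)
  C <- if (length(d) == 3L) d[3L] else 1L
  m <- if (length(d) == 3L) img else array(img, c(H, W, 1L))
  out <- array(0, c(side, side, C))
  WY <- matrix(wy, side, side); WX <- matrix(wx, side, side, byrow = TRUE)
  for (c in seq_len(C)) {
    ch <- m[, , c]
    out[, , c] <- (1 - WY) * ((1 - WX) * ch[cbind(rep(y0, side), rep(x0, each = side))] +
                              WX * ch[cbind(rep(y0, side), rep(x1, each = side))]) +
                  WY * ((1 - WX) * ch[cbind(rep(y1, side), rep(x0, each = side))] +
                        WX * ch[cbind(rep(y1, side), rep(x1, each = side))])
  }
  if (length(d) == 3L) out else out[, , 1L]
}

#' Nearest-neighbour resize of a matrix (binarity-preserving)
#'
#' @param m Numeric matrix.
#' @param side Output side length.
#' @return `side` x `side` matrix whose entries are drawn from `m`.
#' @export
resize_nearest <- function(m, side) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(floor((seq_len(side) - 0.5) * H / side) + 1L, 1L), H)
  ci <- pmin(pmax(floor((seq_len(side) - 0.5) * W / side) + 1L, 1L), W)
  m[ri, ci, drop = FALSE]
}

# Load images into a normalized (side, side, 3, N) tensor.
load_image_tensor <- function(paths, side = 224L, normalize = TRUE) {
  n <- length(paths)
  out <- array(0, c(side, side, 3L, n))
  for (i in seq_len(n)) {
    img <- read_image(paths[i])
    if (dim(img)[1L] != side || dim(img)[2L] != side)
      img <- resize_bilinear(img, side)
    out[, , , i] <- img
  }
  if (normalize) out <- (out - 0.5) / 0.25
  out
}

resolve_paths <- function(records, image_root = NULL) {
  if (is.null(image_root)) records$path
  else file.path(image_root, records$path)
}
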