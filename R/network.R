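# The attention-masked CNN.  Dataflow (input 224x224x3):
#
#   stem: 7x7/2 conv (64ch) + BN + ReLU -> 112x112; 3x3/2 max-pool -> 56x56
#   attention: elementwise product with the 56x56 weight map (all channels)
#   Block1 (2 residual blocks, 64ch, stride 1)      -> 56x56x64
#     +-- SFEL: spatial pyramid pooling, levels (1,2,4) -> 64*21 = 1344 vector
#   Block2 (128ch, /2) -> 28; Block3 (256ch, /2) -> 14; Block4 (512ch, /2) -> 7
#   global average pool Block4 -> 512 vector
#   concat(SFEL, GAP) = 1856 -> linear 512 + ReLU -> linear n_classes -> softmax
#
# Residual blocks are the standard two-conv basic blocks with a projection
# shortcut on the downsampling block of each stage.

#' Architecture specification
#'
#' @param n_classes Number of output classes (>= 2).
#' @param spp_levels Strictly increasing pyramid levels for the
#'   shallow-feature branch; level L contributes an L x L grid of pooled
#'   bins per channel.  Default `c(1, 2, 4)`, the canonical pyramid, giving
#'   a 21-bin, 1344-long shallow vector on the 64-channel Block1 output.
#' @param omega Foreground amplification factor of the attention layer
#'   (default 1.2; 1 disables attention).
#' @param input_side Input image side in pixels; the network requires
#'   exactly this size (no silent resizing inside the network).
#' @param backbone_channels Channel plan for stem and the four residual
#'   stages, default `c(64, 64, 128, 256, 512)`.
#' @param spp_pool Bin pooling operator, `"max"` (default) or `"mean"`.
#' @param hidden Width of the fully connected feature layer between the
#'   concatenated features and the classifier (default 512).
#' @return An object of class `amcnn_spec`.
#' @export
amcnn_spec <- function(n_classes, spp_levels = c(1L, 2L, 4L), omega = 1.2,
                       input_side = 224L,
                       backbone_channels = c(64L, 64L, 128L, 256L, 512L),
                       spp_pool = c("max", "mean"), hidden = 512L) {
  n_classes <- as.integer(n_classes)
  if (is.na(n_classes) || n_classes < 2L) stop("n_classes must be >= 2")
  spp_levels <- as.integer(spp_levels)
  if (length(spp_levels) < 1L || any(spp_levels < 1L) ||
      any(diff(spp_levels) <= 0L))
    stop("spp_levels must be strictly increasing positive integers")
  if (!is.numeric(omega) || omega <= 0) stop("omega must be > 0")
  if (length(backbone_channels) != 5L || any(backbone_channels < 1L))
    stop("backbone_channels must be five positive integers")
  spp_pool <- match.arg(spp_pool)
  input_side <- as.integer(input_side)
  if (input_side %% 32L != 0L)
    stop("input_side must be a multiple of 32")
  structure(list(n_classes = n_classes, spp_levels = spp_levels,
                 omega = omega, input_side = input_side,
                 backbone_channels = as.integer(backbone_channels),
                 spp_pool = spp_pool, hidden = as.integer(hidden)),
            class = "amcnn_spec")
}

spp_length <- function(spec) spec$backbone_channels[2L] * sum(spec$spp_levels^2)
concat_length <- function(spec) spp_length(spec) + spec$backbone_channels[5L]
mask_side_of <- function(spec) spec$input_side %/% 4L

block_make <- function(cin, cout, stride) {
  bl <- list(conv1 = conv_make(3L, 3L, cin, cout, stride = stride, pad = 1L),
             bn1 = bn_make(cout),
             conv2 = conv_make(3L, 3L, cout, cout, stride = 1L, pad = 1L),
             bn2 = bn_make(cout))
  if (stride != 1L || cin != cout)
    bl$down <- list(conv = conv_make(1L, 1L, cin, cout, stride = stride, pad = 0L),
                    bn = bn_make(cout))
  bl
}

stage_make <- function(cin, cout, stride) {
  list(block1 = block_make(cin, cout, stride),
       block2 = block_make(cout, cout, 1L))
}

#' Build and initialise an attention-masked CNN
#'
#' Weights are randomly initialised (He initialisation for convolutions and
#' linear layers, unit batch-norm scale), reproducibly from `seed`.
#'
#' @param spec An [amcnn_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `amcnn_model`: the layer tree plus the spec.
#' @export
amcnn_model <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "amcnn_spec"))
  ch <- spec$backbone_channels
  with_seed(seed, {
    layers <- list(
      conv1 = conv_make(7L, 7L, 3L, ch[1L], stride = 2L, pad = 3L),
      bn1 = bn_make(ch[1L]),
      stage1 = stage_make(ch[1L], ch[2L], 1L),
      stage2 = stage_make(ch[2L], ch[3L], 2L),
      stage3 = stage_make(ch[3L], ch[4L], 2L),
      stage4 = stage_make(ch[4L], ch[5L], 2L),
      fc1 = linear_make(concat_length(spec), spec$hidden),
      fc2 = linear_make(spec$hidden, spec$n_classes)
    )
    structure(list(layers = layers, spec = spec), class = "amcnn_model")
  })
}

#' @export
print.amcnn_model <- function(x, ...) {
  s <- x$spec
  cat("Attention-masked CNN: input ", s$input_side, "x", s$input_side,
      "x3, ", s$n_classes, " classes\n", sep = "")
  cat("  stem 7x7/2 (", s$backbone_channels[1L], "ch) + 3x3/2 max-pool; ",
      "attention omega=", s$omega, "\n", sep = "")
  cat("  stages ", paste(s$backbone_channels[-1L], collapse = "/"),
      "; SPP levels (", paste(s$spp_levels, collapse = ","), ") -> ",
      spp_length(s), " + ", s$backbone_channels[5L], " = ",
      concat_length(s), " -> ", s$hidden, " -> ", s$n_classes, "\n", sep = "")
  invisible(x)
}

block_params <- function(bl) {
  p <- list(conv1_w = bl$conv1$w,
            bn1_gamma = bl$bn1$gamma, bn1_beta = bl$bn1$beta,
            bn1_rm = bl$bn1$run_mean, bn1_rv = bl$bn1$run_var,
            conv2_w = bl$conv2$w,
            bn2_gamma = bl$bn2$gamma, bn2_beta = bl$bn2$beta,
            bn2_rm = bl$bn2$run_mean, bn2_rv = bl$bn2$run_var)
  if (!is.null(bl$down)) {
    p$down_w <- bl$down$conv$w
    p$dbn_gamma <- bl$down$bn$gamma; p$dbn_beta <- bl$down$bn$beta
    p$dbn_rm <- bl$down$bn$run_mean; p$dbn_rv <- bl$down$bn$run_var
  }
  p
}

block_fwd <- function(bl, x, training, keep = TRUE) {
  params <- block_params(bl)
  r <- cpp_block_fwd(x, params, bl$conv1$stride, training, bl$bn1$eps, keep)
  list(y = r$y,
       cache = if (keep) list(ptr = r$cache, params = params, stats = r) else NULL)
}

block_bwd <- function(bl, cache, dy, need_dx = TRUE) {
  g <- cpp_block_bwd(cache$ptr, cache$params, bl$bn1$eps, dy, need_dx)
  st <- cache$stats
  grads <- list(conv1 = list(w = g$conv1_dw),
                bn1 = list(gamma = g$bn1_dgamma, beta = g$bn1_dbeta,
                           batch_mean = st$bn1_mean, batch_var = st$bn1_var),
                conv2 = list(w = g$conv2_dw),
                bn2 = list(gamma = g$bn2_dgamma, beta = g$bn2_dbeta,
                           batch_mean = st$bn2_mean, batch_var = st$bn2_var))
  if (!is.null(bl$down)) {
    grads$down <- list(conv = list(w = g$down_dw),
                       bn = list(gamma = g$dbn_dgamma, beta = g$dbn_dbeta,
                                 batch_mean = st$dbn_mean,
                                 batch_var = st$dbn_var))
  }
  list(dx = g$dx, grads = grads)
}

stage_fwd <- function(stage, x, training, keep = TRUE) {
  r1 <- block_fwd(stage$block1, x, training, keep)
  r2 <- block_fwd(stage$block2, r1$y, training, keep)
  list(y = r2$y, cache = list(block1 = r1$cache, block2 = r2$cache))
}

stage_bwd <- function(stage, cache, dy, need_dx = TRUE) {
  b2 <- block_bwd(stage$block2, cache$block2, dy, need_dx = TRUE)
  b1 <- block_bwd(stage$block1, cache$block1, b2$dx, need_dx = need_dx)
  list(dx = b1$dx, grads = list(block1 = b1$grads, block2 = b2$grads))
}

as_batch <- function(images, side) {
  d <- dim(images)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("shape error: images must be an (H, W, 3[, N]) array")
  if (length(d) == 3L) images <- array(images, c(d, 1L))
  d <- dim(images)
  if (d[1L] != side || d[2L] != side || d[3L] != 3L)
    stop("shape error: network requires ", side, "x", side,
         "x3 input, got ", d[1L], "x", d[2L], "x", d[3L])
  images
}

#' Forward pass through the network
#'
#' @param model An [amcnn_model()].
#' @param images `(side, side, 3)` array or `(side, side, 3, N)` batch.
#' @param weight_maps Optional attention weight maps from
#'   [compute_weight_map()]: a `(side/4, side/4)` matrix or
#'   `(side/4, side/4, N)` array.  `NULL` skips the attention product
#'   (equivalent to omega = 1).
#' @param training Use batch statistics in batch norm (training mode)
#'   instead of running statistics (inference mode).
#' @param keep_cache Keep intermediate activations (needed for backward).
#' @param reuse_cache An activation cache from a previous call (same batch
#'   geometry) whose buffers are reused, avoiding reallocation inside the
#'   training loop.
#' @return List with `probs` (N x n_classes matrix, rows summing to 1),
#'   `logits` (n_classes x N) and, if requested, `cache`.
#' @export
amcnn_forward <- function(model, images, weight_maps = NULL, training = FALSE,
                          keep_cache = FALSE, reuse_cache = NULL) {
  stopifnot(inherits(model, "amcnn_model"))
  spec <- model$spec
  x <- as_batch(images, spec$input_side)
  N <- dim(x)[4L]
  ly <- model$layers

  w <- NULL
  if (!is.null(weight_maps)) {
    ms <- mask_side_of(spec)
    wd <- dim(weight_maps)
    w <- if (length(wd) == 2L) array(weight_maps, c(wd, N)) else weight_maps
    if (!all(dim(w) == c(ms, ms, N)))
      stop("shape error: weight maps must be ", ms, "x", ms, " (x N)")
  }

  bb <- cpp_backbone_fwd(x, ly, w, spec$spp_levels, spec$spp_pool == "max",
                         training, ly$bn1$eps, keep_cache,
                         reuse_cache %||% NULL)
  feat <- bb$feat                                      # concat x N
  h <- pmax(ly$fc1$w %*% feat + ly$fc1$b, 0)
  logits <- ly$fc2$w %*% h + ly$fc2$b                  # K x N

  m <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, m))
  probs <- sweep(e, 2L, colSums(e), "/")

  out <- list(probs = t(probs), logits = logits)
  if (keep_cache) {
    out$cache <- list(bb = bb$cache, feat = feat, h = h, probs_km = probs)
  }
  out
}

# Backward pass from d(loss)/d(logits) (K x N); returns the gradient tree
# mirroring model$layers.  Batch-norm gradient nodes carry the batch
# statistics used in the forward pass so running statistics can be updated
# by the optimizer step.
amcnn_backward <- function(model, cache, dlogits) {
  ly <- model$layers
  spec <- model$spec
  dW2 <- dlogits %*% t(cache$h)
  db2 <- rowSums(dlogits)
  dh <- t(ly$fc2$w) %*% dlogits
  dh <- dh * (cache$h > 0)
  dW1 <- dh %*% t(cache$feat)
  db1 <- rowSums(dh)
  dfeat <- t(ly$fc1$w) %*% dh

  grads <- cpp_backbone_bwd(cache$bb, ly, dfeat, spec$spp_levels,
                            spec$spp_pool == "max", ly$bn1$eps)
  grads$fc1 <- list(w = dW1, b = db1)
  grads$fc2 <- list(w = dW2, b = db2)
  grads
}

# Mean cross-entropy loss and full gradient tree for a labelled batch.
# y: 1-based class indices.
loss_and_grads <- function(model, images, weight_maps, y, reuse_cache = NULL) {
  fw <- amcnn_forward(model, images, weight_maps, training = TRUE,
                      keep_cache = TRUE, reuse_cache = reuse_cache)
  P <- fw$cache$probs_km                      # K x N
  N <- ncol(P)
  py <- P[cbind(y, seq_len(N))]
  loss <- -mean(log(pmax(py, 1e-12)))
  dlogits <- P
  dlogits[cbind(y, seq_len(N))] <- dlogits[cbind(y, seq_len(N))] - 1
  dlogits <- dlogits / N
  grads <- amcnn_backward(model, fw$cache, dlogits)
  list(loss = loss, grads = grads, probs = fw$probs, cache = fw$cache$bb)
}

#' Probe the network's shape ladder
#'
#' Runs a single image through the stem and the four residual stages,
#' reporting the spatial side and channel count after each step together
#' with the shallow-branch (SPP) and concatenated feature lengths.
#'
#' @param model An [amcnn_model()].
#' @return A list with `conv` (stem convolution output dims), `pool`
#'   (pooled stem dims), `stages` (4 x dims after each residual stage),
#'   `spp_length` and `concat_length`, measured by a forward probe.
#' @export
amcnn_shape_probe <- function(model) {
  stopifnot(inherits(model, "amcnn_model"))
  spec <- model$spec
  ly <- model$layers
  x <- array(0, c(spec$input_side, spec$input_side, 3L, 1L))
  z1 <- conv_fwd(ly$conv1, x)
  p <- cpp_maxpool_fwd(cpp_relu(z1), 3L, 2L, 1L)$y
  dims <- list(conv = dim(z1)[1:3], pool = dim(p)[1:3])
  cur <- p
  stages <- list()
  for (s in paste0("stage", 1:4)) {
    cur <- stage_fwd(ly[[s]], cur, training = FALSE, keep = FALSE)$y
    stages[[s]] <- dim(cur)[1:3]
  }
  dims$stages <- stages
  dims$spp_length <- spp_length(spec)
  dims$concat_length <- concat_length(spec)
  dims
}

#' Stem (primary convolutional layer) forward pass
#'
#' Runs only the 7x7/2 convolution + batch norm + ReLU + 3x3/2 max-pool,
#' returning the feature map the attention layer operates on.
#'
#' @param model An [amcnn_model()].
#' @param images Input image or batch (side x side x 3 [x N]).
#' @param training Batch-norm mode as in [amcnn_forward()].
#' @return `(side/4, side/4, channels, N)` array.
#' @export
primary_conv_forward <- function(model, images, training = FALSE) {
  stopifnot(inherits(model, "amcnn_model"))
  x <- as_batch(images, model$spec$input_side)
  ly <- model$layers
  cpp_stem_fwd(x, ly$conv1$w, ly$bn1$gamma, ly$bn1$beta, ly$bn1$run_mean,
               ly$bn1$run_var, training, ly$bn1$eps, FALSE)$y
}

#' Spatial pyramid pooling of a feature map
#'
#' Partitions the map into an L x L grid of near-equal spatial bins for
#' every level L and pools each bin per channel, concatenating the results
#' into a fixed-length vector: length `channels * sum(L^2)` regardless of
#' the input spatial size.  Bin b (0-based) of a level-L partition over S
#' cells spans rows `floor(b*S/L) .. floor((b+1)*S/L) - 1`.
#'
#' @param features `(H, W, C)` array (or `(H, W, C, N)` batch).
#' @param levels Strictly increasing positive integers, each `<= min(H, W)`.
#' @param pool `"max"` (default) or `"mean"` bin pooling.
#' @return A numeric vector of length `C * sum(levels^2)` (or a matrix with
#'   one column per batch element).
#' @export
spp_pool <- function(features, levels = c(1L, 2L, 4L), pool = c("max", "mean")) {
  pool <- match.arg(pool)
  d <- dim(features)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("features must be an (H, W, C[, N]) array")
  single <- length(d) == 3L
  x <- if (single) array(features, c(d, 1L)) else features
  levels <- as.integer(levels)
  if (any(levels < 1L) || any(diff(levels) <= 0L))
    stop("levels must be strictly increasing positive integers")
  v <- spp_fwd(x, levels, pool)$v
  if (single) drop(v) else v
}

# Batched inference: probability matrix (N x K).
predict_probs <- function(model, images, weight_maps = NULL, batch_size = 32L) {
  x <- as_batch(images, model$spec$input_side)
  N <- dim(x)[4L]
  K <- model$spec$n_classes
  out <- matrix(0, N, K)
  ms <- mask_side_of(model$spec)
  w_all <- if (is.null(weight_maps)) NULL
           else if (length(dim(weight_maps)) == 2L) array(weight_maps, c(ms, ms, N))
           else weight_maps
  for (i0 in seq(1L, N, by = batch_size)) {
    i1 <- min(i0 + batch_size - 1L, N)
    w <- if (is.null(w_all)) NULL else w_all[, , i0:i1, drop = FALSE]
    out[i0:i1, ] <- amcnn_forward(model, x[, , , i0:i1, drop = FALSE], w)$probs
  }
  out
}
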