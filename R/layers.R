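# Internal layer framework.  Layers are plain lists with a `type` field and
# parameter arrays; forward passes return the output plus whatever the
# analytic backward pass needs.  The heavy kernels live in src/amcnn_ops.cpp;
# everything here is composition and bookkeeping.

conv_make <- function(kh, kw, cin, cout, stride = 1L, pad = 0L, bias = FALSE) {
  sd <- sqrt(2 / (kh * kw * cin))  # He initialisation for ReLU nets
  list(type = "conv",
       w = array(rnorm(kh * kw * cin * cout, sd = sd), c(kh, kw, cin, cout)),
       b = if (bias) numeric(cout) else NULL,
       stride = as.integer(stride), pad = as.integer(pad))
}

bn_make <- function(c) {
  list(type = "bn", gamma = rep(1, c), beta = rep(0, c),
       run_mean = rep(0, c), run_var = rep(1, c),
       eps = 1e-5, momentum = 0.1)
}

linear_make <- function(din, dout) {
  k <- 1 / sqrt(din)   # uniform fan-in initialisation for linear layers
  list(type = "linear",
       w = matrix(runif(din * dout, -k, k), dout, din),
       b = runif(dout, -k, k))
}

conv_fwd <- function(L, x) {
  cpp_conv2d_fwd(x, L$w, L$b, L$stride, L$pad)
}

# ---- spatial pyramid pooling -------------------------------------------

# Half-open bin edges for an L-way partition of S cells: bin b spans
# floor(b*S/L) .. floor((b+1)*S/L) - 1 (0-based).
spp_edges <- function(S, L) floor((0:L) * S / L)

# x: (H, W, C, N).  Output rows are ordered level-major, then bin
# (row-major within the level grid), then channel.  Returns the pooled
# matrix (D x N) and, for max pooling, flat 1-based argmax indices into x.
spp_fwd <- function(x, levels, pool = "max") {
  d <- dim(x); H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  if (any(levels > min(H, W)))
    stop("parameter error: SPP level exceeds feature map size")
  D <- C * sum(levels^2)
  v <- matrix(0, D, N)
  idx <- if (pool == "max") matrix(0L, D, N) else NULL
  row0 <- 0L
  for (L in levels) {
    re <- spp_edges(H, L); ce <- spp_edges(W, L)
    for (bj in seq_len(L)) {
      for (bi in seq_len(L)) {
        ri <- (re[bi] + 1L):re[bi + 1L]
        ci <- (ce[bj] + 1L):ce[bj + 1L]
        sub <- x[ri, ci, , , drop = FALSE]
        hw <- length(ri) * length(ci)
        m <- matrix(sub, hw, C * N)
        rows <- row0 + seq_len(C)
        if (pool == "max") {
          am <- max.col(t(m), ties.method = "first")      # per (c, n)
          vals <- m[cbind(am, seq_len(C * N))]
          v[rows, ] <- matrix(vals, C, N)
          # map bin-local argmax to a flat index into x
          li <- (am - 1L) %% length(ri)
          lj <- (am - 1L) %/% length(ri)
          gi <- re[bi] + li             # 0-based global row
          gj <- ce[bj] + lj
          cn <- seq_len(C * N) - 1L     # 0-based (c + C*n)
          flat <- gi + H * gj + H * W * cn + 1L
          idx[rows, ] <- matrix(as.integer(flat), C, N)
        } else {
          v[rows, ] <- matrix(colMeans(m), C, N)
        }
        row0 <- row0 + C
      }
    }
  }
  list(v = v, idx = idx, dim = d, levels = levels, pool = pool)
}

# ---- SGD with momentum over the nested layer tree ----------------------

TRAINABLE <- c("w", "b", "gamma", "beta")

# Walks model/grads/velocity trees in parallel.  Nodes are recognised as
# layers by their `type` field; bn grads also carry the batch statistics
# used in the step so running statistics update here too.
sgd_update <- function(model, grads, vel, lr, momentum) {
  walk <- function(m, g, v) {
    if (is.list(m) && !is.null(m$type)) {
      if (is.null(v)) v <- list()
      for (p in TRAINABLE) {
        if (is.null(m[[p]]) || is.null(g[[p]])) next
        if (is.null(v[[p]])) v[[p]] <- m[[p]] * 0
        v[[p]] <- momentum * v[[p]] - lr * g[[p]]
        m[[p]] <- m[[p]] + v[[p]]
      }
      if (m$type == "bn" && !is.null(g$batch_mean)) {
        mom <- m$momentum
        m$run_mean <- (1 - mom) * m$run_mean + mom * g$batch_mean
        m$run_var <- (1 - mom) * m$run_var + mom * g$batch_var
      }
      return(list(m = m, v = v))
    }
    if (is.list(m)) {
      if (is.null(v)) v <- stats::setNames(vector("list", length(m)), names(m))
      for (k in names(m)) {
        if (is.null(g[[k]])) next
        r <- walk(m[[k]], g[[k]], v[[k]])
        m[[k]] <- r$m
        v[[k]] <- r$v
      }
      return(list(m = m, v = v))
    }
    list(m = m, v = v)
  }
  walk(model, grads, vel)
}
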