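# Minimal neural-network layer kit: forward and backward passes written in
# base R on H x W x C arrays, with convolutions as im2col + BLAS matrix
# products. Only what the stain-translation model needs is implemented.
# Feature maps and parameters are double precision throughout.

# cache of im2col index matrices, keyed by geometry (they are reused for
# every patch of the same size)
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  hit <- get0(key, envir = .im2col_cache)
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L; Wo <- (Wp - k) %/% stride + 1L
  if (Ho < 1L || Wo < 1L)
    stop_eberstain(sprintf(
      "feature map %dx%d too small for a %dx%d kernel: use larger input patches",
      H, W, k, k), "eberstain_format_error")
  pos_i <- rep(0:(Ho - 1L), times = Wo)         # output positions, column-major
  pos_j <- rep(0:(Wo - 1L), each = Ho)
  di <- rep(0:(k - 1L), times = k * C)          # kernel offsets, column-major
  dj <- rep(rep(0:(k - 1L), each = k), times = C)
  cc <- rep(0:(C - 1L), each = k * k)
  idx <- outer(pos_i * stride, di, "+") + 1L +
    Hp * outer(pos_j * stride, dj, "+") +
    Hp * Wp * matrix(cc, length(pos_i), length(cc), byrow = TRUE)
  out <- list(idx = idx, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo)
  assign(key, out, envir = .im2col_cache)
  out
}

conv_forward <- function(x, W, b, k, stride, pad) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]
  ii <- im2col_index(H, Wd, C, k, stride, pad)
  if (pad > 0L) {
    xp <- array(0, c(ii$Hp, ii$Wp, C))
    xp[pad + seq_len(H), pad + seq_len(Wd), ] <- x
  } else xp <- x
  cols <- matrix(xp[ii$idx], nrow(ii$idx), ncol(ii$idx))
  y <- cols %*% W
  y <- y + rep(b, each = nrow(y))
  list(out = array(y, c(ii$Ho, ii$Wo, ncol(W))),
       cache = list(cols = cols, ii = ii, H = H, Wd = Wd, C = C,
                    k = k, stride = stride, pad = pad))
}

conv_backward <- function(cache, W, dout) {
  ii <- cache$ii
  dY <- matrix(dout, ii$Ho * ii$Wo, ncol(W))
  dW <- crossprod(cache$cols, dY)
  db <- colSums(dY)
  dcols <- dY %*% t(W)
  g <- rowsum(as.vector(dcols), group = as.vector(ii$idx))
  dxp <- numeric(ii$Hp * ii$Wp * cache$C)
  dxp[as.integer(rownames(g))] <- g
  dxp <- array(dxp, c(ii$Hp, ii$Wp, cache$C))
  p <- cache$pad
  dx <- if (p > 0L) dxp[p + seq_len(cache$H), p + seq_len(cache$Wd), , drop = FALSE]
        else dxp
  list(dx = dx, dW = dW, db = db)
}

instnorm_forward <- function(x, eps = 1e-5) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  inv_std <- 1 / sqrt(v + eps)
  xhat <- (xm - rep(mu, each = n)) * rep(inv_std, each = n)
  list(out = array(xhat, d), cache = list(xhat = xhat, inv_std = inv_std,
                                          d = d, n = n))
}

instnorm_backward <- function(cache, dout) {
  n <- cache$n; d <- cache$d
  dxh <- matrix(dout, n, d[3])
  m1 <- colMeans(dxh)
  m2 <- colMeans(dxh * cache$xhat)
  dx <- (dxh - rep(m1, each = n) - cache$xhat * rep(m2, each = n)) *
    rep(cache$inv_std, each = n)
  array(dx, d)
}

upsample2_forward <- function(x) {
  d <- dim(x)
  list(out = x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
               drop = FALSE],
       cache = d)
}

upsample2_backward <- function(cache, dout) {
  H <- cache[1]; W <- cache[2]
  a <- dout[seq(1L, 2L * H, by = 2L), , , drop = FALSE] +
       dout[seq(2L, 2L * H, by = 2L), , , drop = FALSE]
  a[, seq(1L, 2L * W, by = 2L), , drop = FALSE] +
    a[, seq(2L, 2L * W, by = 2L), , drop = FALSE]
}

# ---- layer objects -------------------------------------------------------

new_conv_layer <- function(in_ch, out_ch, k, stride = 1L, pad = 0L) {
  list(type = "conv", k = k, stride = stride, pad = pad,
       in_ch = in_ch, out_ch = out_ch,
       W = matrix(stats::rnorm(k * k * in_ch * out_ch, 0, 0.02),
                  k * k * in_ch, out_ch),
       b = numeric(out_ch))
}

new_resblock <- function(ch) {
  list(type = "resblock", ch = ch,
       conv1 = new_conv_layer(ch, ch, 3L, 1L, 1L),
       conv2 = new_conv_layer(ch, ch, 3L, 1L, 1L))
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = conv_forward(x, layer$W, layer$b, layer$k, layer$stride, layer$pad),
    instnorm = instnorm_forward(x),
    relu = list(out = pmax(x, 0), cache = x > 0),
    lrelu = list(out = ifelse(x > 0, x, 0.2 * x), cache = x > 0),
    tanh = { y <- tanh(x); list(out = y, cache = y) },
    upsample = upsample2_forward(x),
    resblock = {
      f1 <- conv_forward(x, layer$conv1$W, layer$conv1$b, 3L, 1L, 1L)
      n1 <- instnorm_forward(f1$out)
      r <- pmax(n1$out, 0)
      f2 <- conv_forward(r, layer$conv2$W, layer$conv2$b, 3L, 1L, 1L)
      n2 <- instnorm_forward(f2$out)
      list(out = x + n2$out,
           cache = list(f1 = f1$cache, n1 = n1$cache, rmask = n1$out > 0,
                        f2 = f2$cache, n2 = n2$cache))
    },
    stop("unknown layer type ", layer$type))
}

# returns list(dx, grads); grads NULL for parameter-free layers
layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv = {
      cb <- conv_backward(cache, layer$W, dout)
      list(dx = cb$dx, grads = list(W = cb$dW, b = cb$db))
    },
    instnorm = list(dx = instnorm_backward(cache, dout), grads = NULL),
    relu = list(dx = dout * cache, grads = NULL),
    lrelu = list(dx = dout * ifelse(cache, 1, 0.2), grads = NULL),
    tanh = list(dx = dout * (1 - cache^2), grads = NULL),
    upsample = list(dx = upsample2_backward(cache, dout), grads = NULL),
    resblock = {
      dn2 <- instnorm_backward(cache$n2, dout)
      cb2 <- conv_backward(cache$f2, layer$conv2$W, dn2)
      dr <- cb2$dx * cache$rmask
      dn1 <- instnorm_backward(cache$n1, dr)
      cb1 <- conv_backward(cache$f1, layer$conv1$W, dn1)
      list(dx = dout + cb1$dx,
           grads = list(conv1 = list(W = cb1$dW, b = cb1$db),
                        conv2 = list(W = cb2$dW, b = cb2$db)))
    },
    stop("unknown layer type ", layer$type))
}

# ---- sequential networks -------------------------------------------------

# forward through layers 1..upto, caching everything; `taps` are layer
# indices whose outputs are recorded (feature taps for contrastive loss)
net_forward <- function(layers, x, upto = length(layers), taps = integer(0)) {
  caches <- vector("list", upto)
  tap_out <- list()
  for (i in seq_len(upto)) {
    f <- layer_forward(layers[[i]], x)
    x <- f$out
    caches[[i]] <- f$cache
    if (i %in% taps) tap_out[[as.character(i)]] <- x
  }
  list(out = x, caches = caches, taps = tap_out)
}

# backward from layer `upto` down to 1. `dout` is the gradient at the output
# of layer `upto`; `extra` is a named list (by layer index) of gradients to
# inject at that layer's output (used for feature taps and the encoder head).
net_backward <- function(layers, caches, dout, upto = length(caches),
                         extra = list()) {
  grads <- vector("list", length(layers))
  d <- dout
  for (i in seq(upto, 1L)) {
    e <- extra[[as.character(i)]]
    if (!is.null(e)) d <- d + e
    b <- layer_backward(layers[[i]], caches[[i]], d)
    d <- b$dx
    grads[i] <- list(b$grads)   # keep NULL slots (grads[[i]] <- NULL would drop them)
  }
  list(dx = d, grads = grads)
}

# ---- parameter bookkeeping ----------------------------------------------

PARAM_NAMES <- list(conv = c("W", "b"),
                    resblock = c("conv1", "conv2"))

net_params <- function(layers) {
  lapply(layers, function(l) switch(l$type,
    conv = list(W = l$W, b = l$b),
    resblock = list(conv1 = list(W = l$conv1$W, b = l$conv1$b),
                    conv2 = list(W = l$conv2$W, b = l$conv2$b)),
    NULL))
}

net_set_params <- function(layers, params) {
  for (i in seq_along(layers)) {
    p <- params[[i]]
    if (is.null(p)) next
    if (layers[[i]]$type == "conv") {
      layers[[i]]$W <- p$W; layers[[i]]$b <- p$b
    } else {
      layers[[i]]$conv1$W <- p$conv1$W; layers[[i]]$conv1$b <- p$conv1$b
      layers[[i]]$conv2$W <- p$conv2$W; layers[[i]]$conv2$b <- p$conv2$b
    }
  }
  layers
}

# recursive elementwise combination of two parameter/gradient trees
tree_map2 <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  if (is.null(a)) return(NULL)
  out <- vector("list", length(a)); names(out) <- names(a)
  for (i in seq_along(a)) out[i] <- list(tree_map2(a[[i]], b[[i]], f))
  out
}

tree_map <- function(a, f) {
  if (is.numeric(a)) return(f(a))
  if (is.null(a)) return(NULL)
  out <- vector("list", length(a)); names(out) <- names(a)
  for (i in seq_along(a)) out[i] <- list(tree_map(a[[i]], f))
  out
}

# sum two gradient trees; a NULL subtree on either side (e.g. decoder layers
# untouched by an encoder-only pass) yields the other side unchanged
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  out <- vector("list", length(a)); names(out) <- names(a)
  for (i in seq_along(a)) out[i] <- list(add_grads(a[[i]], b[[i]]))
  out
}

scale_grads <- function(g, s) tree_map(g, function(x) x * s)

grads_finite <- function(g) {
  ok <- TRUE
  walk <- function(a) {
    if (is.numeric(a)) { if (!all(is.finite(a))) ok <<- FALSE }
    else if (!is.null(a)) for (x in a) walk(x)
  }
  walk(g)
  ok
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_map(params, function(x) x * 0),
       v = tree_map(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  list(params = tree_map2(params, upd, `-`), state = state)
}
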