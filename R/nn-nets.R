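# Network builders for the stain-translation model. The generator is the
# standard residual encoder-decoder (c7s1, two stride-2 downsamplings,
# n residual blocks, two upsamplings, c7s1 + tanh); its encoder half (through
# the residual blocks) is exposed for the fidelity classifier and for the
# contrastive feature taps. The discriminator is the 70x70 patch-based
# convolutional discriminator. Channel widths are configurable so the same
# code runs at desk scale.

build_generator <- function(ngf = 64L, n_res = 9L, in_ch = 3L, out_ch = 3L) {
  layers <- list(
    new_conv_layer(in_ch, ngf, 7L, 1L, 3L),   # 1 c7s1
    list(type = "instnorm"),                  # 2
    list(type = "relu"),                      # 3  <- tap
    new_conv_layer(ngf, 2L * ngf, 3L, 2L, 1L),# 4 d2
    list(type = "instnorm"),                  # 5
    list(type = "relu"),                      # 6  <- tap
    new_conv_layer(2L * ngf, 4L * ngf, 3L, 2L, 1L), # 7 d2
    list(type = "instnorm"),                  # 8
    list(type = "relu")                       # 9  <- tap
  )
  for (i in seq_len(n_res)) layers[[length(layers) + 1L]] <- new_resblock(4L * ngf)
  enc_end <- length(layers)                   # encoder output (G_enc)
  layers <- c(layers, list(
    list(type = "upsample"),
    new_conv_layer(4L * ngf, 2L * ngf, 3L, 1L, 1L),
    list(type = "instnorm"),
    list(type = "relu"),
    list(type = "upsample"),
    new_conv_layer(2L * ngf, ngf, 3L, 1L, 1L),
    list(type = "instnorm"),
    list(type = "relu"),
    new_conv_layer(ngf, out_ch, 7L, 1L, 3L),
    list(type = "tanh")
  ))
  taps <- c(3L, 6L, 9L, enc_end)
  tap_ch <- c(ngf, 2L * ngf, 4L * ngf, 4L * ngf)
  list(layers = layers, enc_end = enc_end, taps = taps, tap_ch = tap_ch,
       enc_ch = 4L * ngf, n_res = n_res, ngf = ngf)
}

build_discriminator <- function(ndf = 64L, in_ch = 3L) {
  list(layers = list(
    new_conv_layer(in_ch, ndf, 4L, 2L, 1L),
    list(type = "lrelu"),
    new_conv_layer(ndf, 2L * ndf, 4L, 2L, 1L),
    list(type = "instnorm"),
    list(type = "lrelu"),
    new_conv_layer(2L * ndf, 4L * ndf, 4L, 2L, 1L),
    list(type = "instnorm"),
    list(type = "lrelu"),
    new_conv_layer(4L * ndf, 8L * ndf, 4L, 1L, 1L),
    list(type = "instnorm"),
    list(type = "lrelu"),
    new_conv_layer(8L * ndf, 1L, 4L, 1L, 1L)
  ), ndf = ndf)
}

# two-layer perceptron feature projector (one per tapped encoder depth),
# followed by L2 normalisation
build_mlp_head <- function(in_ch, dim = 256L) {
  list(W1 = matrix(stats::rnorm(in_ch * dim, 0, 0.02), in_ch, dim),
       b1 = numeric(dim),
       W2 = matrix(stats::rnorm(dim * dim, 0, 0.02), dim, dim),
       b2 = numeric(dim))
}

mlp_forward <- function(head, feats) {
  a <- feats %*% head$W1 + rep(head$b1, each = nrow(feats))
  h <- pmax(a, 0)
  z <- h %*% head$W2 + rep(head$b2, each = nrow(h))
  norms <- sqrt(rowSums(z^2))
  if (any(norms < 1e-12))
    stop_eberstain("zero-norm feature vector in contrastive projection",
                   "eberstain_numeric_error")
  zn <- z / norms
  list(out = zn, cache = list(feats = feats, amask = a > 0, h = h, z = z,
                              norms = norms, zn = zn))
}

mlp_backward <- function(head, cache, dzn) {
  # through z/||z||
  dz <- (dzn - cache$zn * rowSums(dzn * cache$zn)) / cache$norms
  dW2 <- crossprod(cache$h, dz)
  db2 <- colSums(dz)
  dh <- dz %*% t(head$W2)
  da <- dh * cache$amask
  dW1 <- crossprod(cache$feats, da)
  db1 <- colSums(da)
  dfeats <- da %*% t(head$W1)
  list(dfeats = dfeats, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# one-layer classifier on globally average-pooled encoder features,
# sigmoid output in [0, 1]
build_classifier <- function(in_ch) {
  list(W = matrix(stats::rnorm(in_ch, 0, 0.02), in_ch, 1L), b = 0)
}

cls_forward <- function(cls, enc) {
  d <- dim(enc)
  gap <- colMeans(matrix(enc, d[1] * d[2], d[3]))
  logit <- sum(gap * cls$W) + cls$b
  p <- 1 / (1 + exp(-logit))
  list(out = p, cache = list(gap = gap, p = p, d = d))
}

cls_backward <- function(cls, cache, dp) {
  dlogit <- dp * cache$p * (1 - cache$p)
  dW <- matrix(cache$gap * dlogit, ncol = 1L)
  db <- dlogit
  dgap <- as.vector(cls$W) * dlogit
  n <- cache$d[1] * cache$d[2]
  denc <- array(rep(dgap / n, each = n), cache$d)
  list(denc = denc, grads = list(W = dW, b = db))
}

# gather feature vectors at sampled spatial locations of an H x W x C map
gather_locations <- function(feat, ids) {
  d <- dim(feat)
  matrix(feat, d[1] * d[2], d[3])[ids, , drop = FALSE]
}

scatter_locations <- function(dfeats, ids, d) {
  m <- matrix(0, d[1] * d[2], d[3])
  m[ids, ] <- dfeats
  array(m, d)
}

encode_img <- function(patch) {
  x <- patch / 255 * 2 - 1
  storage.mode(x) <- "double"
  x
}

decode_img <- function(x) {
  out <- round((x + 1) / 2 * 255)
  out <- clamp(out, 0, 255)
  storage.mode(out) <- "integer"
  out
}
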