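#' Training configuration for the stain-translation model
#'
#' Defaults are the reference training settings: Adam with momentum
#' parameters 0.5/0.999, initial learning rate 2e-4, 200 epochs at batch
#' size 4, learning-rate decay starting at the midpoint of training, and a
#' residual generator with 9 residual blocks. Channel widths (`ngf`, `ndf`),
#' contrastive sampling (`n_nce` locations, `nce_dim` projection width,
#' temperature `tau`) follow the contrastive-unpaired-translation defaults
#' and are configurable for desk-scale runs.
#'
#' @param epochs total training epochs (>= 0).
#' @param batch_size patches per optimisation step.
#' @param lr initial learning rate.
#' @param beta1,beta2 Adam momentum parameters.
#' @param decay_start epoch at which linear learning-rate decay begins
#'   (default: midpoint).
#' @param ngf,ndf generator/discriminator base channel widths.
#' @param n_res number of residual blocks in the generator.
#' @param n_nce sampled feature locations per image and tap layer.
#' @param nce_dim projection-head width.
#' @param tau contrastive softmax temperature.
#' @param seed master seed; sub-seeds for weight initialisation of each
#'   network and for the data order are derived from it, so components can
#'   be added or removed without perturbing the others' streams.
#' @return An object of class `pfgan_config`.
#' @export
pfgan_config <- function(epochs = 200L, batch_size = 4L, lr = 2e-4,
                         beta1 = 0.5, beta2 = 0.999,
                         decay_start = epochs %/% 2L,
                         ngf = 64L, ndf = 64L, n_res = 9L,
                         n_nce = 256L, nce_dim = 256L, tau = 0.07,
                         seed = 1L) {
  if (epochs < 0L || decay_start > epochs)
    stop_eberstain("need epochs >= 0 and decay_start <= epochs",
                   "eberstain_config_error")
  if (n_nce < 1L || tau <= 0)
    stop_eberstain("need n_nce >= 1 and tau > 0", "eberstain_config_error")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 decay_start = as.integer(decay_start),
                 ngf = as.integer(ngf), ndf = as.integer(ndf),
                 n_res = as.integer(n_res), n_nce = as.integer(n_nce),
                 nce_dim = as.integer(nce_dim), tau = tau,
                 seed = as.integer(seed)),
            class = "pfgan_config")
}

#' @export
print.pfgan_config <- function(x, ...) {
  cat(sprintf(
    "stain-translation training config: %d epochs (decay from %d), batch %d, lr %g, Adam(%.1f, %.3f)\n",
    x$epochs, x$decay_start, x$batch_size, x$lr, x$beta1, x$beta2))
  cat(sprintf("  generator ngf %d with %d residual blocks; discriminator ndf %d\n",
              x$ngf, x$n_res, x$ndf))
  cat(sprintf("  contrastive: %d locations, %d-dim projection, tau %.2f; seed %d\n",
              x$n_nce, x$nce_dim, x$tau, x$seed))
  invisible(x)
}

init_pfgan_model <- function(config, weights, pf_head = TRUE) {
  seeds <- derive_seeds(config$seed, 5L)
  G <- with_seed(seeds[1], build_generator(config$ngf, config$n_res))
  D <- with_seed(seeds[2], build_discriminator(config$ndf))
  H <- with_seed(seeds[3], lapply(G$tap_ch, build_mlp_head, dim = config$nce_dim))
  cls <- if (pf_head) with_seed(seeds[4], build_classifier(G$enc_ch)) else NULL
  structure(list(generator = G, discriminator = D, heads = H, cls = cls,
                 config = config, weights = weights,
                 data_seed = seeds[5],
                 history = empty_history(), trained_epochs = 0L,
                 version = "eberstain-checkpoint-1"),
            class = "pfgan")
}

empty_history <- function() {
  data.frame(epoch = integer(0), loss_gan = numeric(0),
             loss_nce_x = numeric(0), loss_nce_y = numeric(0),
             loss_pf = numeric(0), loss_d = numeric(0))
}

# contrastive loss between two tapped feature sets; returns loss, gradients
# for the tapped maps (as named extra-gradient lists) and projector grads.
# `wscale` multiplies the gradients (loss weight / number of taps).
nce_between <- function(model, taps_q, taps_k, wscale) {
  G <- model$generator; cfg <- model$config
  total <- 0
  extra_q <- list(); extra_k <- list(); hgrads <- vector("list", length(G$taps))
  for (t in seq_along(G$taps)) {
    l <- as.character(G$taps[t])
    fq <- taps_q[[l]]; fk <- taps_k[[l]]
    d <- dim(fq); npos <- d[1] * d[2]
    ids <- sample.int(npos, min(cfg$n_nce, npos))
    zq <- mlp_forward(model$heads[[t]], gather_locations(fq, ids))
    zk <- mlp_forward(model$heads[[t]], gather_locations(fk, ids))
    ncg <- nce_loss_grad(zq$out, zk$out, cfg$tau)
    total <- total + ncg$loss
    bq <- mlp_backward(model$heads[[t]], zq$cache, ncg$dzq * wscale)
    bk <- mlp_backward(model$heads[[t]], zk$cache, ncg$dzk * wscale)
    hgrads[[t]] <- add_grads(bq$grads, bk$grads)
    extra_q[[l]] <- scatter_locations(bq$dfeats, ids, d)
    extra_k[[l]] <- scatter_locations(bk$dfeats, ids, d)
  }
  list(loss = total / length(G$taps), extra_q = extra_q, extra_k = extra_k,
       hgrads = hgrads)
}

merge_extra <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

# one optimisation step on a batch: D update then G/heads/classifier update
gan_train_step <- function(model, opt, xb, yb, ylabs, lr, weights) {
  G <- model$generator; D <- model$discriminator; cfg <- model$config
  B <- length(xb)
  n_taps <- length(G$taps)
  use_pf <- !is.null(model$cls) && weights$lambda_pf > 0

  fwd_x <- vector("list", B); fwd_y <- vector("list", B)
  for (i in seq_len(B)) {
    fwd_x[[i]] <- net_forward(G$layers, encode_img(xb[[i]]), taps = G$taps)
    fwd_y[[i]] <- net_forward(G$layers, encode_img(yb[[i]]), taps = G$taps)
  }

  # ---- discriminator update (generated images treated as constants) ----
  d_grads <- NULL; loss_d <- 0
  for (i in seq_len(B)) {
    dr <- net_forward(D$layers, encode_img(yb[[i]]))
    df <- net_forward(D$layers, fwd_x[[i]]$out)
    loss_d <- loss_d + lsgan_d_loss(dr$out, df$out)
    nr <- length(dr$out); nf <- length(df$out)
    br <- net_backward(D$layers, dr$caches, (dr$out - 1) / nr / B)
    bf <- net_backward(D$layers, df$caches, df$out / nf / B)
    d_grads <- add_grads(d_grads, add_grads(br$grads, bf$grads))
  }
  loss_d <- loss_d / B
  if (!is.finite(loss_d))
    stop_eberstain("NaN in adversarial discriminator loss", "eberstain_numeric_error")
  stp <- adam_step(net_params(D$layers), d_grads, opt$D, lr, cfg$beta1, cfg$beta2)
  model$discriminator$layers <- net_set_params(D$layers, stp$params)
  opt$D <- stp$state
  D <- model$discriminator

  # ---- generator / projector / classifier update ----
  g_grads <- NULL; h_grads <- NULL; c_grads <- NULL
  loss_gan <- 0; loss_nx <- 0; loss_ny <- 0; loss_pf_sum <- 0
  enc_key <- as.character(G$enc_end)
  zero_enc <- NULL
  for (i in seq_len(B)) {
    fake <- fwd_x[[i]]$out; idt <- fwd_y[[i]]$out
    if (is.null(zero_enc))
      zero_enc <- array(0, dim(fwd_x[[i]]$taps[[enc_key]]))

    df <- net_forward(D$layers, fake)
    loss_gan <- loss_gan + lsgan_g_loss(df$out)
    bD <- net_backward(D$layers, df$caches,
                       weights$lambda_gan * 2 * (df$out - 1) / length(df$out) / B)
    dfake <- bD$dx

    # queries: encoder features of the translated images
    fq <- net_forward(G$layers, fake, upto = G$enc_end, taps = G$taps)
    ncx <- nce_between(model, fq$taps, fwd_x[[i]]$taps,
                       weights$lambda_nce_x / n_taps / B)
    loss_nx <- loss_nx + ncx$loss
    bfq <- net_backward(G$layers, fq$caches, zero_enc, upto = G$enc_end,
                        extra = ncx$extra_q)
    dfake <- dfake + bfq$dx
    g_grads <- add_grads(g_grads, bfq$grads)
    h_grads <- add_grads(h_grads, ncx$hgrads)

    iq <- net_forward(G$layers, idt, upto = G$enc_end, taps = G$taps)
    ncy <- nce_between(model, iq$taps, fwd_y[[i]]$taps,
                       weights$lambda_nce_y / n_taps / B)
    loss_ny <- loss_ny + ncy$loss
    biq <- net_backward(G$layers, iq$caches, zero_enc, upto = G$enc_end,
                        extra = ncy$extra_q)
    didt <- biq$dx
    g_grads <- add_grads(g_grads, biq$grads)
    h_grads <- add_grads(h_grads, ncy$hgrads)

    extra_y <- ncy$extra_k
    if (!is.null(model$cls)) {
      cf <- cls_forward(model$cls, fwd_y[[i]]$taps[[enc_key]])
      loss_pf_sum <- loss_pf_sum + abs(cf$out - ylabs[i])
      if (use_pf) {
        cb <- cls_backward(model$cls, cf$cache,
                           weights$lambda_pf * sign(cf$out - ylabs[i]) / B)
        c_grads <- add_grads(c_grads, cb$grads)
        extra_y <- merge_extra(extra_y, stats::setNames(list(cb$denc), enc_key))
      }
    }

    bx <- net_backward(G$layers, fwd_x[[i]]$caches, dfake, extra = ncx$extra_k)
    by <- net_backward(G$layers, fwd_y[[i]]$caches, didt, extra = extra_y)
    g_grads <- add_grads(g_grads, add_grads(bx$grads, by$grads))
  }
  comps <- c(gan = loss_gan / B, nce_x = loss_nx / B, nce_y = loss_ny / B,
             pf = if (!is.null(model$cls)) loss_pf_sum / B else NA_real_)
  bad <- names(comps)[!is.na(comps) & !is.finite(comps)]
  if (length(bad))
    stop_eberstain(sprintf("NaN in loss component '%s'", bad[1]),
                   "eberstain_numeric_error")

  stp <- adam_step(net_params(G$layers), g_grads, opt$G, lr, cfg$beta1, cfg$beta2)
  model$generator$layers <- net_set_params(G$layers, stp$params)
  opt$G <- stp$state
  stp <- adam_step(model$heads, h_grads, opt$H, lr, cfg$beta1, cfg$beta2)
  model$heads <- stp$params
  opt$H <- stp$state
  if (use_pf) {
    stp <- adam_step(model$cls, c_grads, opt$C, lr, cfg$beta1, cfg$beta2)
    model$cls <- stp$params
    opt$C <- stp$state
  }
  list(model = model, opt = opt, losses = c(comps, d = loss_d))
}

#' Fit the pathology-fidelity stain-translation model
#'
#' Trains the unpaired image-to-image translation model on source-domain
#' (H&E-style) and target-domain (EBER-style) patch sets. The objective
#' combines a least-squares adversarial loss, two contrastive PatchNCE
#' losses (source/translated and target/re-translated, internal negatives)
#' and the pathology-fidelity term: an L1 penalty between a one-layer
#' sigmoid classifier on pooled encoder features of real target patches and
#' their 0/1 labels (normally produced by [auto_annotate()]). Discriminator
#' and generator alternate each step; the fidelity gradient flows into the
#' generator encoder jointly with the translation losses.
#'
#' With `weights = loss_weights(lambda_pf = 0)` the model, losses and
#' update order are exactly the contrastive-unpaired-translation (CUT)
#' objective.
#'
#' @param x list of source-domain patches (H x W x 3, 8-bit; H and W must
#'   be divisible by 4).
#' @param y list of target-domain patches.
#' @param y_labels 0/1 labels for `y`; required when `lambda_pf > 0`.
#' @param config a [pfgan_config()].
#' @param weights a [loss_weights()].
#' @param pf_head keep the fidelity classifier head at all (set `FALSE` to
#'   instantiate the bare translation model; only meaningful with
#'   `lambda_pf = 0`).
#' @param max_restarts at desk scale (a few hundred optimisation steps) the
#'   adversarial game occasionally collapses to translating everything into
#'   negative-looking tissue. After training, the model stains its source
#'   training patches and compares the fraction of rule-cascade-positive
#'   outputs with the positive fraction of the (auto-annotated) target
#'   domain; if the target domain is at least 20% positive but no stained
#'   patch is, the run is declared collapsed and restarted from the next
#'   derived initialisation seed, at most `max_restarts` times. The check
#'   uses no ground truth and the whole procedure is deterministic in
#'   `config$seed`. Default 0 (no restarts).
#' @param verbose print per-epoch loss components.
#' @return An object of class `pfgan` with the trained parameters and a
#'   per-epoch `history` of the loss components (`loss_gan` is the
#'   generator's adversarial term; `loss_d` the discriminator's).
#' @seealso [predict.pfgan()], [stain()], [lr_at_epoch()]
#' @export
pfgan <- function(x, y, y_labels = NULL, config = pfgan_config(),
                  weights = loss_weights(), pf_head = TRUE,
                  max_restarts = 0L, verbose = FALSE) {
  stopifnot(inherits(config, "pfgan_config"), inherits(weights, "loss_weights"))
  attempt_cfg <- config
  for (attempt in 0:max_restarts) {
    model <- pfgan_fit_once(x, y, y_labels, attempt_cfg, weights, pf_head,
                            verbose)
    model$restarts <- attempt
    if (attempt == max_restarts || config$epochs == 0L) return(model)
    if (!stain_collapsed(model, x, y, y_labels)) return(model)
    if (verbose)
      message("translation collapsed (no positive stained output); restarting")
    attempt_cfg$seed <- config$seed + attempt + 1L
  }
  model
}

# truth-free collapse check: the target domain carries positive patches but
# no stained source patch triggers the rule cascade
stain_collapsed <- function(model, x, y, y_labels,
                            thresholds = decision_thresholds()) {
  tgt_labels <- if (!is.null(y_labels) && !anyNA(y_labels)) y_labels
                else auto_annotate(y, thresholds)$label
  if (mean(tgt_labels) < 0.2) return(FALSE)
  idx <- seq_len(min(length(x), 40L))
  stained_pos <- vapply(x[idx], function(p)
    patch_decision(pixel_decision(stain(p, model), thresholds),
                   thresholds)$label, integer(1))
  sum(stained_pos) == 0L
}

pfgan_fit_once <- function(x, y, y_labels, config, weights, pf_head,
                           verbose) {
  if (weights$lambda_pf > 0 && is.null(y_labels))
    stop_eberstain("lambda_pf > 0 requires y_labels (see auto_annotate())",
                   "eberstain_config_error")
  if (weights$lambda_pf > 0 && !pf_head)
    stop_eberstain("lambda_pf > 0 requires the fidelity head", "eberstain_config_error")
  if (!is.null(y_labels) && (length(y_labels) != length(y) ||
                             !all(y_labels %in% c(0, 1))))
    stop_eberstain("y_labels must be one 0/1 label per target patch",
                   "eberstain_config_error")
  for (p in x) check_stride_compat(p)
  for (p in y) check_stride_compat(p)

  model <- init_pfgan_model(config, weights, pf_head)
  if (config$epochs == 0L) return(model)
  if (is.null(y_labels)) y_labels <- rep(NA_real_, length(y))

  opt <- list(G = adam_init(net_params(model$generator$layers)),
              D = adam_init(net_params(model$discriminator$layers)),
              H = adam_init(model$heads),
              C = if (pf_head) adam_init(model$cls) else NULL)

  nx <- length(x); ny <- length(y)
  B <- min(config$batch_size, nx, ny)
  n_iter <- max(1L, min(nx, ny) %/% B)
  hist <- empty_history()

  set.seed(model$data_seed)
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config, epoch - 1L)
    perm_x <- sample.int(nx); perm_y <- sample.int(ny)
    acc <- c(gan = 0, nce_x = 0, nce_y = 0, pf = 0, d = 0); npf <- 0L
    for (it in seq_len(n_iter)) {
      ix <- perm_x[((it - 1L) * B) %% nx + seq_len(B)]
      iy <- perm_y[((it - 1L) * B) %% ny + seq_len(B)]
      res <- gan_train_step(model, opt, x[ix], y[iy], y_labels[iy], lr, weights)
      model <- res$model; opt <- res$opt
      l <- res$losses
      if (!is.na(l["pf"])) { acc["pf"] <- acc["pf"] + l["pf"]; npf <- npf + 1L }
      acc[c("gan", "nce_x", "nce_y", "d")] <-
        acc[c("gan", "nce_x", "nce_y", "d")] + l[c("gan", "nce_x", "nce_y", "d")]
    }
    hist <- rbind(hist, data.frame(
      epoch = epoch,
      loss_gan = acc[["gan"]] / n_iter,
      loss_nce_x = acc[["nce_x"]] / n_iter,
      loss_nce_y = acc[["nce_y"]] / n_iter,
      loss_pf = if (npf > 0L) acc[["pf"]] / npf else NA_real_,
      loss_d = acc[["d"]] / n_iter))
    if (verbose)
      message(sprintf(
        "epoch %3d  lr %.2e  G_adv %.4f  NCE_X %.4f  NCE_Y %.4f  PF %s  D %.4f",
        epoch, lr, hist$loss_gan[epoch], hist$loss_nce_x[epoch],
        hist$loss_nce_y[epoch],
        ifelse(is.na(hist$loss_pf[epoch]), "-", sprintf("%.4f", hist$loss_pf[epoch])),
        hist$loss_d[epoch]))
  }
  model$history <- hist
  model$trained_epochs <- config$epochs
  model
}

check_stride_compat <- function(patch) {
  assert_rgb_patch(patch)
  d <- dim(patch)
  if (d[1] %% 4L != 0L || d[2] %% 4L != 0L)
    stop_eberstain(sprintf(
      "patch size %dx%d incompatible with the network stride: height and width must be divisible by 4",
      d[1], d[2]), "eberstain_format_error")
  invisible(patch)
}

#' Digitally stain a source-domain patch
#'
#' Applies the trained translation mapping (H&E-style to EBER-style) to one
#' patch. Inference is deterministic: the generator has no stochastic
#' layers.
#'
#' @param patch H x W x 3 array (8-bit), H and W divisible by 4.
#' @param model a fitted [pfgan()] object.
#' @return H x W x 3 integer array in 0..255.
#' @export
stain <- function(patch, model) {
  stopifnot(inherits(model, "pfgan"))
  check_stride_compat(patch)
  decode_img(net_forward(model$generator$layers, encode_img(patch))$out)
}

#' Predict method: digital staining of new source patches
#'
#' @param object a fitted [pfgan()] object.
#' @param newdata one patch (H x W x 3 array) or a list of patches.
#' @param ... unused.
#' @return a stained patch or list of stained patches.
#' @export
predict.pfgan <- function(object, newdata, ...) {
  if (is.list(newdata)) lapply(newdata, stain, model = object)
  else stain(newdata, object)
}

#' Loss components on a batch (forward only)
#'
#' Recomputes the four components of the combined objective on given
#' batches without touching the parameters: generator adversarial loss,
#' the two contrastive terms and the fidelity term, plus their weighted
#' total. Location sampling for the contrastive terms uses the current RNG
#' stream.
#'
#' @param model a [pfgan()] object (fitted or freshly initialised).
#' @param x,y lists of source/target patches.
#' @param y_labels 0/1 labels for `y`; required when the fidelity weight is
#'   positive.
#' @param weights a [loss_weights()]; defaults to the model's.
#' @return list with `components` (named vector `gan, nce_x, nce_y, pf`)
#'   and `total` (weighted sum; an `NA` fidelity term with zero weight
#'   contributes 0).
#' @export
pfgan_loss_components <- function(model, x, y, y_labels = NULL,
                                  weights = model$weights) {
  stopifnot(inherits(model, "pfgan"))
  if (weights$lambda_pf > 0 && is.null(y_labels))
    stop_eberstain("lambda_pf > 0 requires y_labels", "eberstain_config_error")
  G <- model$generator
  gan <- 0; nx <- 0; ny <- 0; pf <- 0; npf <- 0L
  for (i in seq_along(x)) {
    fx <- net_forward(G$layers, encode_img(x[[i]]), taps = G$taps)
    df <- net_forward(model$discriminator$layers, fx$out)
    gan <- gan + lsgan_g_loss(df$out)
    fq <- net_forward(G$layers, fx$out, upto = G$enc_end, taps = G$taps)
    nx <- nx + nce_between(model, fq$taps, fx$taps, 0)$loss
  }
  for (i in seq_along(y)) {
    fy <- net_forward(G$layers, encode_img(y[[i]]), taps = G$taps)
    iq <- net_forward(G$layers, fy$out, upto = G$enc_end, taps = G$taps)
    ny <- ny + nce_between(model, iq$taps, fy$taps, 0)$loss
    if (!is.null(model$cls) && !is.null(y_labels)) {
      p <- cls_forward(model$cls, fy$taps[[as.character(G$enc_end)]])$out
      pf <- pf + abs(p - y_labels[i]); npf <- npf + 1L
    }
  }
  comps <- c(gan = gan / length(x), nce_x = nx / length(x),
             nce_y = ny / length(y),
             pf = if (npf > 0L) pf / npf else NA_real_)
  total <- weights$lambda_gan * comps[["gan"]] +
    weights$lambda_nce_x * comps[["nce_x"]] +
    weights$lambda_nce_y * comps[["nce_y"]] +
    if (is.na(comps[["pf"]])) 0 else weights$lambda_pf * comps[["pf"]]
  list(components = comps, total = total)
}

#' @export
print.pfgan <- function(x, ...) {
  cat(sprintf(
    "stain-translation model: generator ngf %d (%d residual blocks), trained %d epoch(s)\n",
    x$config$ngf, x$config$n_res, x$trained_epochs))
  cat(sprintf("  fidelity head: %s (lambda_pf = %g)\n",
              if (is.null(x$cls)) "absent" else "present", x$weights$lambda_pf))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final losses: G_adv %.4f  NCE_X %.4f  NCE_Y %.4f  PF %s  D %.4f\n",
                last$loss_gan, last$loss_nce_x, last$loss_nce_y,
                ifelse(is.na(last$loss_pf), "-", sprintf("%.4f", last$loss_pf)),
                last$loss_d))
  }
  invisible(x)
}

#' @export
summary.pfgan <- function(object, ...) {
  cat("Loss history (per-epoch means):\n")
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' @export
plot.pfgan <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) { warning("model has no training history"); return(invisible(x)) }
  cols <- c("loss_gan", "loss_nce_x", "loss_nce_y", "loss_pf")
  keep <- cols[colSums(!is.na(h[cols])) > 0]
  graphics::matplot(h$epoch, h[keep], type = "l", lty = 1,
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", legend = keep, lty = 1,
                   col = seq_along(keep), bty = "n")
  invisible(x)
}

#' @export
coef.pfgan <- function(object, ...) {
  list(generator = net_params(object$generator$layers),
       discriminator = net_params(object$discriminator$layers),
       heads = object$heads, cls = object$cls)
}

#' Save / load model checkpoints
#'
#' Checkpoints carry an explicit version tag and reload bit-compatibly
#' (identical parameters, hence identical inference output).
#'
#' @param model a [pfgan()] object.
#' @param path checkpoint file path.
#' @return `load_pfgan` returns the model; `save_pfgan` the path,
#'   invisibly.
#' @export
save_pfgan <- function(model, path) {
  stopifnot(inherits(model, "pfgan"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_pfgan
#' @export
load_pfgan <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pfgan") ||
      !identical(model$version, "eberstain-checkpoint-1"))
    stop_eberstain("not a compatible model checkpoint", "eberstain_io_error")
  model
}
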