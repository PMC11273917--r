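# Independent reference training loop for the bare contrastive unpaired
# translation objective (adversarial + two PatchNCE terms, no fidelity
# head). The loss wiring and update sequencing are written out here from
# first principles, sharing only the layer primitives and the seeded
# initialisation with the package, so that `pfgan(..., lambda_pf = 0)`
# can be checked against it trajectory-for-trajectory.
cut_reference_fit <- function(x, y, config) {
  ns <- asNamespace("eberstain")
  derive_seeds <- ns$derive_seeds; with_seed <- ns$with_seed
  net_forward <- ns$net_forward; net_backward <- ns$net_backward
  net_params <- ns$net_params; net_set_params <- ns$net_set_params
  adam_init <- ns$adam_init; adam_step <- ns$adam_step
  add_grads <- ns$add_grads
  mlp_forward <- ns$mlp_forward; mlp_backward <- ns$mlp_backward
  nce_loss_grad <- ns$nce_loss_grad
  gather <- ns$gather_locations; scatter <- ns$scatter_locations
  encode <- ns$encode_img

  seeds <- derive_seeds(config$seed, 5L)
  G <- with_seed(seeds[1], ns$build_generator(config$ngf, config$n_res))
  D <- with_seed(seeds[2], ns$build_discriminator(config$ndf))
  H <- with_seed(seeds[3], lapply(G$tap_ch, ns$build_mlp_head, dim = config$nce_dim))
  # seeds[4] belongs to the fidelity head, absent here by construction

  optG <- adam_init(net_params(G$layers))
  optD <- adam_init(net_params(D$layers))
  optH <- adam_init(H)
  n_taps <- length(G$taps); enc_key <- as.character(G$enc_end)
  nx <- length(x); ny <- length(y)
  hist <- NULL

  set.seed(seeds[5])
  for (epoch in seq_len(config$epochs)) {
    lr <- eberstain::lr_at_epoch(config, epoch - 1L)
    perm_x <- sample.int(nx); perm_y <- sample.int(ny)
    n_iter <- min(nx, ny)
    acc <- c(gan = 0, nce_x = 0, nce_y = 0, d = 0)
    for (it in seq_len(n_iter)) {
      xi <- x[[perm_x[it]]]; yi <- y[[perm_y[it]]]
      fx <- net_forward(G$layers, encode(xi), taps = G$taps)
      fy <- net_forward(G$layers, encode(yi), taps = G$taps)
      fake <- fx$out; idt <- fy$out

      # --- discriminator: least-squares real-vs-fake, fake held constant
      dr <- net_forward(D$layers, encode(yi))
      df <- net_forward(D$layers, fake)
      acc["d"] <- acc["d"] + 0.5 * (mean((dr$out - 1)^2) + mean(df$out^2))
      br <- net_backward(D$layers, dr$caches, (dr$out - 1) / length(dr$out))
      bf <- net_backward(D$layers, df$caches, df$out / length(df$out))
      st <- adam_step(net_params(D$layers), add_grads(br$grads, bf$grads),
                      optD, lr, config$beta1, config$beta2)
      D$layers <- net_set_params(D$layers, st$params); optD <- st$state

      # --- generator + projectors against the updated discriminator
      df2 <- net_forward(D$layers, fake)
      acc["gan"] <- acc["gan"] + mean((df2$out - 1)^2)
      bD <- net_backward(D$layers, df2$caches, 2 * (df2$out - 1) / length(df2$out))
      dfake <- bD$dx

      one_nce <- function(q_taps, k_taps) {
        loss <- 0; eq <- list(); ek <- list(); hg <- vector("list", n_taps)
        for (t in seq_len(n_taps)) {
          l <- as.character(G$taps[t])
          d <- dim(q_taps[[l]]); npos <- d[1] * d[2]
          ids <- sample.int(npos, min(config$n_nce, npos))
          zq <- mlp_forward(H[[t]], gather(q_taps[[l]], ids))
          zk <- mlp_forward(H[[t]], gather(k_taps[[l]], ids))
          ng <- nce_loss_grad(zq$out, zk$out, config$tau)
          loss <- loss + ng$loss
          bq <- mlp_backward(H[[t]], zq$cache, ng$dzq / n_taps)
          bk <- mlp_backward(H[[t]], zk$cache, ng$dzk / n_taps)
          hg[[t]] <- add_grads(bq$grads, bk$grads)
          eq[[l]] <- scatter(bq$dfeats, ids, d)
          ek[[l]] <- scatter(bk$dfeats, ids, d)
        }
        list(loss = loss / n_taps, eq = eq, ek = ek, hg = hg)
      }

      zero_enc <- array(0, dim(fx$taps[[enc_key]]))
      fq <- net_forward(G$layers, fake, upto = G$enc_end, taps = G$taps)
      nx_ <- one_nce(fq$taps, fx$taps)
      acc["nce_x"] <- acc["nce_x"] + nx_$loss
      bfq <- net_backward(G$layers, fq$caches, zero_enc, upto = G$enc_end,
                          extra = nx_$eq)
      dfake <- dfake + bfq$dx

      iq <- net_forward(G$layers, idt, upto = G$enc_end, taps = G$taps)
      ny_ <- one_nce(iq$taps, fy$taps)
      acc["nce_y"] <- acc["nce_y"] + ny_$loss
      biq <- net_backward(G$layers, iq$caches, zero_enc, upto = G$enc_end,
                          extra = ny_$eq)
      didt <- biq$dx

      bx <- net_backward(G$layers, fx$caches, dfake, extra = nx_$ek)
      by <- net_backward(G$layers, fy$caches, didt, extra = ny_$ek)
      g_grads <- add_grads(add_grads(bfq$grads, biq$grads),
                           add_grads(bx$grads, by$grads))
      h_grads <- add_grads(nx_$hg, ny_$hg)

      st <- adam_step(net_params(G$layers), g_grads, optG, lr,
                      config$beta1, config$beta2)
      G$layers <- net_set_params(G$layers, st$params); optG <- st$state
      st <- adam_step(H, h_grads, optH, lr, config$beta1, config$beta2)
      H <- st$params; optH <- st$state
    }
    hist <- rbind(hist, data.frame(
      epoch = epoch, loss_gan = acc[["gan"]] / n_iter,
      loss_nce_x = acc[["nce_x"]] / n_iter,
      loss_nce_y = acc[["nce_y"]] / n_iter,
      loss_d = acc[["d"]] / n_iter))
  }
  list(history = hist, generator = G)
}
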