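ns <- asNamespace("eberstain")

tiny_config <- function(epochs = 2L, seed = 5L)
  pfgan_config(epochs = epochs, batch_size = 1L, ngf = 8L, ndf = 8L,
               n_res = 2L, n_nce = 32L, nce_dim = 32L, seed = seed)

tiny_set <- function(n = 8L, seed = 11L)
  make_unpaired_set(n, n, 0.5, seed = seed, patch_size = 32L)

test_that("analytic gradients match finite differences through every layer type", {
  set.seed(42)
  G <- ns$with_seed(1, ns$build_generator(ngf = 4L, n_res = 1L))
  x <- array(runif(12 * 12 * 3) * 2 - 1, c(12, 12, 3))
  tgt <- array(rnorm(12 * 12 * 3), c(12, 12, 3))
  lossG <- function(L) sum(ns$net_forward(L, x)$out * tgt)
  fwd <- ns$net_forward(G$layers, x)
  bwd <- ns$net_backward(G$layers, fwd$caches, tgt)
  fd <- function(L, mod, eps = 1e-6) (lossG(mod(L, eps)) - lossG(mod(L, -eps))) / (2 * eps)
  # conv before instance norm, residual block, decoder conv
  for (spec in list(list(1L, "W"), list(4L, "W"),
                    list(10L, c("conv1", "W")), list(19L, "W"), list(19L, "b"))) {
    li <- spec[[1]]; path <- spec[[2]]
    g <- bwd$grads[[li]]; for (nm in path) g <- g[[nm]]
    k <- sample(length(g), 1)
    mod <- function(L, d) {
      if (length(path) == 1) L[[li]][[path[1]]][k] <- L[[li]][[path[1]]][k] + d
      else L[[li]][[path[1]]][[path[2]]][k] <- L[[li]][[path[1]]][[path[2]]][k] + d
      L
    }
    expect_equal(g[k], fd(G$layers, mod), tolerance = 1e-5)
  }
  # gradient with respect to the input image
  k <- 5L
  num <- {
    f <- function(d) { xx <- x; xx[k] <- xx[k] + d
      sum(ns$net_forward(G$layers, xx)$out * tgt) }
    (f(1e-6) - f(-1e-6)) / 2e-6
  }
  expect_equal(bwd$dx[k], num, tolerance = 1e-5)

  # discriminator
  xd <- array(runif(32 * 32 * 3) * 2 - 1, c(32, 32, 3))
  D <- ns$with_seed(2, ns$build_discriminator(ndf = 4L))
  fD <- ns$net_forward(D$layers, xd)
  tD <- array(rnorm(length(fD$out)), dim(fD$out))
  bD <- ns$net_backward(D$layers, fD$caches, tD)
  LD <- function(L) sum(ns$net_forward(L, xd)$out * tD)
  g <- bD$grads[[6]]$W; k <- sample(length(g), 1)
  Lp <- D$layers; Lp[[6]]$W[k] <- Lp[[6]]$W[k] + 1e-6
  Lm <- D$layers; Lm[[6]]$W[k] <- Lm[[6]]$W[k] - 1e-6
  expect_equal(g[k], (LD(Lp) - LD(Lm)) / 2e-6, tolerance = 1e-5)

  # contrastive projection head, through the NCE loss and L2 normalisation
  hd <- ns$with_seed(3, ns$build_mlp_head(8L, 16L))
  fq <- matrix(rnorm(5 * 8), 5); fk <- matrix(rnorm(5 * 8), 5)
  nceL <- function(h, fq, fk)
    ns$nce_loss_grad(ns$mlp_forward(h, fq)$out, ns$mlp_forward(h, fk)$out, 0.07)$loss
  zq <- ns$mlp_forward(hd, fq); zk <- ns$mlp_forward(hd, fk)
  ng <- ns$nce_loss_grad(zq$out, zk$out, 0.07)
  bq <- ns$mlp_backward(hd, zq$cache, ng$dzq)
  bk <- ns$mlp_backward(hd, zk$cache, ng$dzk)
  hg <- ns$add_grads(bq$grads, bk$grads)
  k <- 7L
  hp <- hd; hp$W1[k] <- hp$W1[k] + 1e-6
  hm <- hd; hm$W1[k] <- hm$W1[k] - 1e-6
  expect_equal(hg$W1[k], (nceL(hp, fq, fk) - nceL(hm, fq, fk)) / 2e-6,
               tolerance = 1e-5)
  expect_equal(bq$dfeats[2], {
    f <- function(d) { ff <- fq; ff[2] <- ff[2] + d; nceL(hd, ff, fk) }
    (f(1e-6) - f(-1e-6)) / 2e-6
  }, tolerance = 1e-5)

  # fidelity classifier head (L1 to the label, through pooling and sigmoid)
  cl <- ns$with_seed(4, ns$build_classifier(8L))
  enc <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  cf <- ns$cls_forward(cl, enc)
  cb <- ns$cls_backward(cl, cf$cache, sign(cf$out - 1))
  clsL <- function(cl, enc) abs(ns$cls_forward(cl, enc)$out - 1)
  cp <- cl; cp$W[3] <- cp$W[3] + 1e-6
  cm <- cl; cm$W[3] <- cm$W[3] - 1e-6
  expect_equal(cb$grads$W[3], (clsL(cp, enc) - clsL(cm, enc)) / 2e-6,
               tolerance = 1e-5)
  expect_equal(cb$denc[9], {
    f <- function(d) { ee <- enc; ee[9] <- ee[9] + d; clsL(cl, ee) }
    (f(1e-6) - f(-1e-6)) / 2e-6
  }, tolerance = 1e-5)
})

test_that("zero-epoch training returns an initialised model with empty history", {
  ds <- tiny_set(2L)
  m <- pfgan(ds$source, ds$target, ds$target_labels,
             tiny_config(epochs = 0L))
  expect_s3_class(m, "pfgan")
  expect_equal(nrow(m$history), 0L)
  expect_equal(m$trained_epochs, 0L)
  out <- stain(ds$source[[1]], m)
  expect_equal(dim(out), dim(ds$source[[1]]))
})

test_that("with zero fidelity weight the trajectory is the bare translation model's", {
  ds <- tiny_set(8L)
  w0 <- loss_weights(lambda_pf = 0)
  m_with_head <- pfgan(ds$source, ds$target, ds$target_labels,
                       tiny_config(), weights = w0, pf_head = TRUE)
  m_no_head <- pfgan(ds$source, ds$target, config = tiny_config(),
                     weights = w0, pf_head = FALSE)
  cols <- c("loss_gan", "loss_nce_x", "loss_nce_y", "loss_d")
  expect_equal(m_with_head$history[cols], m_no_head$history[cols],
               tolerance = 1e-12)
  expect_identical(stain(ds$source[[1]], m_with_head),
                   stain(ds$source[[1]], m_no_head))
})

test_that("loss components sum to the reported total; zero weight drops the term", {
  ds <- tiny_set(4L)
  cfg <- tiny_config(epochs = 0L)
  m <- pfgan(ds$source, ds$target, ds$target_labels, cfg)
  set.seed(77)
  lc <- pfgan_loss_components(m, ds$source[1:2], ds$target[1:2],
                              ds$target_labels[1:2])
  # independent scalar re-summation of the components
  expect_equal(lc$total,
               lc$components[["gan"]] + lc$components[["nce_x"]] +
                 lc$components[["nce_y"]] + lc$components[["pf"]],
               tolerance = 1e-12)
  set.seed(77)
  lc0 <- pfgan_loss_components(m, ds$source[1:2], ds$target[1:2],
                               ds$target_labels[1:2],
                               weights = loss_weights(lambda_pf = 0))
  expect_equal(lc0$total,
               lc0$components[["gan"]] + lc0$components[["nce_x"]] +
                 lc0$components[["nce_y"]], tolerance = 1e-12)
  # identical RNG stream: the three shared components agree across calls
  expect_equal(lc0$components[c("gan", "nce_x", "nce_y")],
               lc$components[c("gan", "nce_x", "nce_y")], tolerance = 1e-12)
  expect_error(pfgan_loss_components(m, ds$source[1:2], ds$target[1:2]),
               class = "eberstain_config_error")
})

test_that("training requires labels only when the fidelity term is active", {
  ds <- tiny_set(2L)
  expect_error(pfgan(ds$source, ds$target, config = tiny_config(epochs = 0L)),
               class = "eberstain_config_error")
  expect_silent(pfgan(ds$source, ds$target, config = tiny_config(epochs = 0L),
                      weights = loss_weights(lambda_pf = 0), pf_head = FALSE))
})

test_that("inference is deterministic, range-safe and checks divisibility", {
  ds <- tiny_set(2L)
  m <- pfgan(ds$source, ds$target, ds$target_labels, tiny_config(epochs = 1L))
  s1 <- stain(ds$source[[1]], m)
  s2 <- stain(ds$source[[1]], m)
  expect_identical(s1, s2)
  expect_gte(min(s1), 0)
  expect_lte(max(s1), 255)
  expect_identical(predict(m, ds$source[[1]]), s1)
  bad <- array(100L, c(30, 30, 3))
  expect_error(stain(bad, m), regexp = "divisible by 4",
               class = "eberstain_format_error")
})

test_that("checkpoints reload bit-compatibly", {
  ds <- tiny_set(2L)
  m <- pfgan(ds$source, ds$target, ds$target_labels, tiny_config(epochs = 1L))
  tmp <- tempfile(fileext = ".rds")
  save_pfgan(m, tmp)
  m2 <- load_pfgan(tmp)
  expect_identical(coef(m2), coef(m))
  expect_identical(stain(ds$source[[2]], m2), stain(ds$source[[2]], m))
  unlink(tmp)
  bad <- tempfile(fileext = ".rds"); saveRDS(list(a = 1), bad)
  expect_error(load_pfgan(bad), class = "eberstain_io_error")
  unlink(bad)
})

test_that("training history tracks all loss components per epoch", {
  ds <- tiny_set(4L)
  m <- pfgan(ds$source, ds$target, ds$target_labels, tiny_config(epochs = 2L))
  expect_equal(m$history$epoch, 1:2)
  expect_true(all(c("loss_gan", "loss_nce_x", "loss_nce_y", "loss_pf",
                    "loss_d") %in% names(m$history)))
  expect_true(all(is.finite(unlist(m$history))))
})
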