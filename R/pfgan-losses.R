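#' Pathology-fidelity loss
#'
#' Mean absolute difference between the fidelity classifier's predictions
#' (sigmoid outputs of the one-layer head on pooled encoder features) and
#' the 0/1 patch labels of real target-domain images,
#' `E_y || cls(G_enc(y)) - l_y ||_1`. Bounded in \[0, 1\] for predictions in
#' \[0, 1\] and invariant to batch permutation.
#'
#' @param predictions numeric vector of per-image predictions in \[0, 1\].
#' @param labels 0/1 vector of the same length.
#' @return scalar mean L1 loss.
#' @examples
#' pf_loss(c(0.3, 0.9), c(1, 1))  # 0.4
#' @export
pf_loss <- function(predictions, labels) {
  if (length(predictions) != length(labels) || length(labels) == 0L)
    stop_eberstain("predictions and labels must be non-empty and equal length",
                   "eberstain_format_error")
  if (!all(labels %in% c(0, 1)))
    stop_eberstain("labels must be 0 or 1", "eberstain_format_error")
  mean(abs(predictions - labels))
}

#' Contrastive PatchNCE loss over feature vectors
#'
#' Cross-entropy of the softmax over similarity logits (scaled by `1/tau`)
#' between each query and its positive against negatives, with the positive
#' as the true class. Feature vectors must be unit-normalised. When
#' `negatives` is `NULL`, each query's negatives are the other queries'
#' positives (internal negatives, the unpaired-translation convention);
#' otherwise the supplied negative set is shared by every query.
#'
#' In the uninformative limit (positive and all `K` negatives equally
#' similar) the loss equals `log(K + 1)`.
#'
#' @param query n x d matrix of unit-normalised query features.
#' @param positive n x d matrix of matching positive features.
#' @param negatives optional K x d matrix of shared negatives.
#' @param tau softmax temperature (> 0), default 0.07.
#' @return scalar mean cross-entropy.
#' @examples
#' q <- matrix(c(1, 0), 1); p <- matrix(c(1, 0), 1); n <- matrix(c(-1, 0), 1)
#' patchnce_loss(q, p, n, tau = 1)  # -log(e / (e + exp(-1))) ~ 0.1269
#' @export
patchnce_loss <- function(query, positive, negatives = NULL, tau = 0.07) {
  if (tau <= 0) stop_eberstain("tau must be > 0", "eberstain_format_error")
  query <- as.matrix(query); positive <- as.matrix(positive)
  check_unit <- function(m, nm) {
    if (any(sqrt(rowSums(m^2)) < 1e-12))
      stop_eberstain(sprintf("zero-norm feature vector in %s", nm),
                     "eberstain_numeric_error")
  }
  check_unit(query, "query"); check_unit(positive, "positive")
  if (is.null(negatives)) {
    if (nrow(query) < 2L)
      stop_eberstain("internal negatives need at least 2 locations",
                     "eberstain_format_error")
    return(nce_loss_grad(query, positive, tau)$loss)
  }
  negatives <- as.matrix(negatives); check_unit(negatives, "negatives")
  lpos <- rowSums(query * positive) / tau            # n
  lneg <- query %*% t(negatives) / tau               # n x K
  logits <- cbind(lpos, lneg)
  m <- apply(logits, 1, max)
  mean(-(lpos - m) + log(rowSums(exp(logits - m))))
}

# internal-negative formulation with gradients: logits_ij = <q_i, k_j>/tau,
# true class on the diagonal
nce_loss_grad <- function(zq, zk, tau) {
  n <- nrow(zq)
  logits <- zq %*% t(zk) / tau
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  P <- e / rowSums(e)
  loss <- mean(-(diag(logits) - m) + log(rowSums(e)))
  G <- (P - diag(n)) / n
  list(loss = loss, dzq = (G %*% zk) / tau, dzk = (t(G) %*% zq) / tau)
}

# least-squares adversarial losses (the stable default the translation
# baseline uses); D outputs are patch-wise score maps
lsgan_d_loss <- function(d_real, d_fake) {
  0.5 * (mean((d_real - 1)^2) + mean(d_fake^2))
}

lsgan_g_loss <- function(d_fake) mean((d_fake - 1)^2)

#' Learning rate at a given epoch
#'
#' Constant at the initial rate until `decay_start`, then linear decay to 0
#' at the final epoch (continuous at the junction). With the defaults
#' (200 epochs, decay from the midpoint) epoch 0 gives 2e-4, epoch 150
#' gives 1e-4 and epoch 200 gives 0.
#'
#' @param config a [pfgan_config()].
#' @param epoch epoch index in `0..config$epochs`.
#' @return learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  stopifnot(inherits(config, "pfgan_config"))
  if (epoch < 0 || epoch > config$epochs)
    stop_eberstain(sprintf("epoch must be in [0, %d]", config$epochs),
                   "eberstain_format_error")
  if (epoch <= config$decay_start || config$epochs == config$decay_start)
    return(config$lr)
  config$lr * (1 - (epoch - config$decay_start) /
                 (config$epochs - config$decay_start))
}

#' Loss weights of the combined objective
#'
#' The total objective is
#' `L = lambda_gan * L_GAN + lambda_nce_x * L_NCE(X) +
#'  lambda_nce_y * L_NCE(Y) + lambda_pf * L_PF`;
#' all weights default to 1 (the two contrastive weights and the fidelity
#' weight are set to 1 in the reference configuration). With
#' `lambda_pf = 0` the objective is exactly the contrastive unpaired
#' translation (CUT) objective.
#'
#' @param lambda_gan,lambda_nce_x,lambda_nce_y,lambda_pf non-negative
#'   weights.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_gan = 1, lambda_nce_x = 1, lambda_nce_y = 1,
                         lambda_pf = 1) {
  w <- list(lambda_gan = lambda_gan, lambda_nce_x = lambda_nce_x,
            lambda_nce_y = lambda_nce_y, lambda_pf = lambda_pf)
  if (any(unlist(w) < 0))
    stop_eberstain("loss weights must be >= 0", "eberstain_format_error")
  structure(w, class = "loss_weights")
}
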