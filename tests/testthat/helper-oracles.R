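# Independent oracles, deliberately written differently from the package
# implementations they check.

# stack-based flood fill over all components; returns the maximal area
flood_fill_max_area <- function(mask, connectivity) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  if (connectivity == 4L) {
    nb <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    nb <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
               c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  best <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] != 1 || seen[i, j]) next
    stack <- list(c(i, j)); seen[i, j] <- TRUE; area <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      area <- area + 1L
      for (d in nb) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= H && q[2] >= 1 && q[2] <= W &&
            mask[q[1], q[2]] == 1 && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    best <- max(best, area)
  }
  best
}

# double-loop RMSE straight from the definition
naive_rmse <- function(a, b) {
  a <- as.array(a); b <- as.array(b)
  if (max(a) > 1) a <- a / 255
  if (max(b) > 1) b <- b / 255
  s <- 0; n <- 0L
  for (k in seq_len(length(a))) { s <- s + (a[k] - b[k])^2; n <- n + 1L }
  sqrt(s / n)
}

# brute-force confusion tally
naive_confusion <- function(pred, truth) {
  tp <- 0L; tn <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1L
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# small random binary mask with tunable density
random_mask <- function(H, W, p) matrix(as.integer(runif(H * W) < p), H, W)
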