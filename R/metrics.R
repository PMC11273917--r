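# Image-quality metrics (RMSE / PSNR / SSIM) and classification metrics.
# Intensities are compared on the [0, 1] scale: 8-bit inputs (max > 1) are
# divided by 255 first, which is the scale on which reported RMSE magnitudes
# of ~0.01 live.

to_unit <- function(img) {
  img <- as.array(img)
  if (max(img) > 1) img / 255 else img
}

#' Root-mean-square error between two images
#'
#' Square root of the mean squared per-pixel difference, channels included
#' in the mean, on intensities rescaled to \[0, 1\].
#'
#' @param generated,reference arrays of identical dimensions (H x W or
#'   H x W x C), 8-bit or already in \[0, 1\].
#' @return scalar RMSE.
#' @export
rmse <- function(generated, reference) {
  if (!identical(dim(as.array(generated)), dim(as.array(reference))))
    stop_eberstain("images must have identical dimensions", "eberstain_format_error")
  a <- to_unit(generated); b <- to_unit(reference)
  sqrt(mean((a - b)^2))
}

#' Peak signal-to-noise ratio
#'
#' `20 * log10(max_intensity / rmse)`, in decibels. A zero RMSE (identical
#' images) is reported as `Inf` with attribute `identical = TRUE` rather
#' than an error.
#'
#' @inheritParams rmse
#' @param max_intensity peak intensity `MAX_I` on the comparison scale
#'   (default 1, matching the \[0, 1\] rescaling of [rmse()]).
#' @return scalar PSNR in dB.
#' @export
psnr <- function(generated, reference, max_intensity = 1) {
  r <- rmse(generated, reference)
  if (r == 0) return(structure(Inf, identical = TRUE))
  20 * log10(max_intensity / r)
}

# separable valid-mode filtering with a 1-D kernel along rows then columns
filter2_valid <- function(m, k) {
  n <- length(k); H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H - n + 1L, W)
  for (t in seq_len(n)) out <- out + k[t] * m[t:(t + H - n), , drop = FALSE]
  out2 <- matrix(0, nrow(out), W - n + 1L)
  for (t in seq_len(n)) out2 <- out2 + k[t] * out[, t:(t + W - n), drop = FALSE]
  out2
}

rgb_to_gray <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  # ITU-R BT.709 luma weights
  0.2125 * img[, , 1] + 0.7154 * img[, , 2] + 0.0721 * img[, , 3]
}

#' Structural similarity index
#'
#' Mean over local Gaussian windows of the luminance/contrast/structure
#' statistic `((2 mu_x mu_y + C1)(2 sigma_xy + C2)) /`
#' `((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`. Defaults follow
#' the SSIM literature: 11-pixel Gaussian window (sigma 1.5),
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with dynamic range `L = 1` on the
#' \[0, 1\] scale; RGB images are converted to grayscale luminance first.
#' Windows are restricted to positions fully inside the image.
#'
#' @inheritParams rmse
#' @param C1,C2 stabilising constants (> 0).
#' @param window_size odd window edge in pixels.
#' @param sigma Gaussian window standard deviation.
#' @return scalar in \[-1, 1\].
#' @export
ssim <- function(generated, reference, C1 = 0.01^2, C2 = 0.03^2,
                 window_size = 11L, sigma = 1.5) {
  if (!identical(dim(as.array(generated)), dim(as.array(reference))))
    stop_eberstain("images must have identical dimensions", "eberstain_format_error")
  if (C1 <= 0 || C2 <= 0)
    stop_eberstain("C1 and C2 must be positive", "eberstain_format_error")
  x <- rgb_to_gray(to_unit(generated)); y <- rgb_to_gray(to_unit(reference))
  if (window_size > min(dim(x)))
    stop_eberstain("window larger than image", "eberstain_format_error")
  half <- (window_size - 1) / 2
  k <- exp(-((seq_len(window_size) - 1 - half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  mu_x <- filter2_valid(x, k);  mu_y <- filter2_valid(y, k)
  xx <- filter2_valid(x * x, k); yy <- filter2_valid(y * y, k)
  xy <- filter2_valid(x * y, k)
  var_x <- xx - mu_x^2; var_y <- yy - mu_y^2; cov_xy <- xy - mu_x * mu_y
  s <- ((2 * mu_x * mu_y + C1) * (2 * cov_xy + C2)) /
       ((mu_x^2 + mu_y^2 + C1) * (var_x + var_y + C2))
  mean(s)
}

#' Confusion counts
#'
#' @param TP,TN,FP,FN non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0)) stop_eberstain("counts must be non-negative",
                                 "eberstain_format_error")
  structure(as.list(v), class = "confusion_counts")
}

#' Tally a confusion matrix from label vectors
#'
#' @param predicted,truth equal-length vectors of 0/1 labels.
#' @return A [confusion_counts()] with `TP + TN + FP + FN = n`.
#' @export
confusion_from_labels <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop_eberstain("predicted and truth must have equal length",
                   "eberstain_format_error")
  if (!all(c(predicted, truth) %in% c(0, 1)))
    stop_eberstain("labels must be 0 or 1", "eberstain_format_error")
  confusion_counts(TP = sum(predicted == 1 & truth == 1),
                   TN = sum(predicted == 0 & truth == 0),
                   FP = sum(predicted == 1 & truth == 0),
                   FN = sum(predicted == 0 & truth == 1))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall (sensitivity), specificity and F1 score.
#' A metric whose denominator is zero is reported as `NA` (undefined), not
#' as 0.
#'
#' @param counts a [confusion_counts()].
#' @return named numeric vector
#'   `c(accuracy, precision, recall, specificity, f1)`.
#' @examples
#' # worked example: 8617/8686 negatives and 8480/8481 positives correct
#' m <- classification_metrics(confusion_counts(TP = 8480, TN = 8617,
#'                                              FP = 69, FN = 1))
#' round(100 * m[["accuracy"]], 2)   # 99.59
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, {
    precision <- sdiv(TP, TP + FP)
    recall <- sdiv(TP, TP + FN)
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    c(accuracy = sdiv(TP + TN, TP + TN + FP + FN),
      precision = precision, recall = recall,
      specificity = sdiv(TN, TN + FP), f1 = f1)
  })
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 P R / (P + R)`; convenient when only the rates are
#' available (e.g. re-checking published tables).
#'
#' @param precision,recall rates in \[0, 1\].
#' @return scalar F1.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' Evaluate a set of generated/reference image pairs
#'
#' Per-image RMSE, SSIM and PSNR, then the unweighted mean over images
#' (reported set-level RMSE and PSNR are per-image averages, which is the
#' only convention under which the two are mutually consistent).
#'
#' @param generated,reference lists of images (equal length, matched order).
#' @return list with `per_image` (data frame) and `mean` (named vector).
#' @export
evaluate_pairs <- function(generated, reference) {
  if (length(generated) != length(reference))
    stop_eberstain("pair lists must have equal length", "eberstain_format_error")
  per <- do.call(rbind, lapply(seq_along(generated), function(i) {
    data.frame(index = i,
               rmse = rmse(generated[[i]], reference[[i]]),
               ssim = ssim(generated[[i]], reference[[i]]),
               psnr = as.numeric(psnr(generated[[i]], reference[[i]])))
  }))
  list(per_image = per,
       mean = c(rmse = mean(per$rmse), ssim = mean(per$ssim),
                psnr = mean(per$psnr)))
}
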