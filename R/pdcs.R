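#' Decision thresholds for the prior-driven classification cascade
#'
#' The cascade exploits two pathological priors of EBER-ISH: (i) EBV-positive
#' tumour nuclei are dark in the R channel (below 100 on the 8-bit scale)
#' while all negative tissue is pink (above 200), and (ii) the smallest
#' tumour cell averages about 125 px at the working resolution, so a
#' component-size threshold of 100 px separates genuine nuclei from noise
#' while preserving sensitivity.
#'
#' @param pixel_positive_r_max 8-bit R intensity; a foreground pixel is
#'   positive iff its R value is strictly below this (default 100).
#' @param component_min_area pixels; a patch is positive iff its largest
#'   positive component strictly exceeds this (default 100).
#' @param background_min_intensity 8-bit intensity; a pixel is glass
#'   background iff `min(R, G, B)` is at or above this (default 230). The
#'   criterion is a package choice: near-white in every channel.
#' @param wsi_positive_count_min number of positive patches required to call
#'   a slide NPC (default 1: a single positive patch suffices).
#' @param connectivity pixel adjacency for components, 4 or 8 (default 8:
#'   stained nuclei are blob-like and diagonal contact should not split a
#'   cell).
#' @return An object of class `decision_thresholds`.
#' @examples
#' th <- decision_thresholds()
#' th
#' @export
decision_thresholds <- function(pixel_positive_r_max = 100L,
                                component_min_area = 100L,
                                background_min_intensity = 230L,
                                wsi_positive_count_min = 1L,
                                connectivity = 8L) {
  if (!(pixel_positive_r_max > 0 &&
        pixel_positive_r_max < background_min_intensity &&
        background_min_intensity <= 255))
    stop_eberstain("need 0 < pixel_positive_r_max < background_min_intensity <= 255",
                   "eberstain_threshold_error")
  if (component_min_area < 1 || wsi_positive_count_min < 1)
    stop_eberstain("component_min_area and wsi_positive_count_min must be >= 1",
                   "eberstain_threshold_error")
  if (!connectivity %in% c(4L, 8L))
    stop_eberstain("connectivity must be 4 or 8", "eberstain_threshold_error")
  structure(list(
    pixel_positive_r_max = as.integer(pixel_positive_r_max),
    component_min_area = as.integer(component_min_area),
    background_min_intensity = as.integer(background_min_intensity),
    wsi_positive_count_min = as.integer(wsi_positive_count_min),
    connectivity = as.integer(connectivity)
  ), class = "decision_thresholds")
}

#' @export
print.decision_thresholds <- function(x, ...) {
  cat("Prior-driven decision thresholds\n")
  cat(sprintf("  positive pixel:   R < %d (foreground only)\n", x$pixel_positive_r_max))
  cat(sprintf("  background:       min(R,G,B) >= %d\n", x$background_min_intensity))
  cat(sprintf("  positive patch:   largest component > %d px (%d-connectivity)\n",
              x$component_min_area, x$connectivity))
  cat(sprintf("  NPC slide:        >= %d positive patch(es)\n", x$wsi_positive_count_min))
  invisible(x)
}

# glass background: near-white in every channel
background_mask <- function(patch, thresholds) {
  pmin(patch[, , 1], pmin(patch[, , 2], patch[, , 3])) >=
    thresholds$background_min_intensity
}

#' Pixel-level decision: EBER-positivity mask
#'
#' Background pixels are filtered out first; among foreground (tissue)
#' pixels, those with R-channel intensity strictly below the positive
#' threshold are marked 1, all others 0.
#'
#' @param patch H x W x 3 array of 8-bit RGB intensities.
#' @param thresholds a [decision_thresholds()].
#' @return H x W 0/1 matrix with attribute `thresholds` recording the
#'   parameters used.
#' @export
pixel_decision <- function(patch, thresholds = decision_thresholds()) {
  assert_rgb_patch(patch)
  fg <- !background_mask(patch, thresholds)
  mask <- matrix(as.integer(fg & patch[, , 1] < thresholds$pixel_positive_r_max),
                 nrow(fg), ncol(fg))
  attr(mask, "thresholds") <- thresholds
  mask
}

#' Patch-level decision from a positivity mask
#'
#' A patch is called positive iff the largest connected component of
#' positive pixels strictly exceeds the component-area threshold
#' (read "exceeds" as a strict inequality: a component of exactly the
#' threshold size is negative).
#'
#' @param mask H x W 0/1 matrix (typically from [pixel_decision()]).
#' @param thresholds a [decision_thresholds()].
#' @return An object of class `patch_verdict`: list with `label` (0/1),
#'   `largest_component_area` and `mask`.
#' @export
patch_decision <- function(mask, thresholds = decision_thresholds()) {
  assert_binary_mask(mask)
  area <- largest_component_area(mask, thresholds$connectivity)
  structure(list(
    label = as.integer(area > thresholds$component_min_area),
    largest_component_area = as.integer(area),
    mask = mask
  ), class = "patch_verdict")
}

#' @export
print.patch_verdict <- function(x, ...) {
  cat(sprintf("patch verdict: %s (largest positive component %d px)\n",
              if (x$label == 1L) "positive (1)" else "negative (0)",
              x$largest_component_area))
  invisible(x)
}

#' Slide-level decision from patch verdicts
#'
#' A slide is diagnosed NPC iff at least `wsi_positive_count_min` patches
#' are positive; with the default of 1 this is the pathologist's rule that
#' one identified EBER-positive image makes the slide NPC.
#'
#' @param verdicts non-empty list of `patch_verdict` objects, or a 0/1
#'   vector of patch labels.
#' @param thresholds a [decision_thresholds()].
#' @return An object of class `slide_verdict`: list with `diagnosis`
#'   (`"NPC"` or `"non-NPC"`), `positive_patch_count`, `total_patch_count`.
#' @export
wsi_decision <- function(verdicts, thresholds = decision_thresholds()) {
  if (length(verdicts) == 0L)
    stop_eberstain("no foreground patches: cannot issue a slide diagnosis",
                   "eberstain_no_foreground")
  labels <- if (is.numeric(verdicts)) as.integer(verdicts)
            else vapply(verdicts, function(v) v$label, integer(1))
  if (!all(labels %in% c(0L, 1L)))
    stop_eberstain("patch labels must be 0 or 1", "eberstain_format_error")
  npos <- sum(labels)
  structure(list(
    diagnosis = if (npos >= thresholds$wsi_positive_count_min) "NPC" else "non-NPC",
    positive_patch_count = npos,
    total_patch_count = length(labels)
  ), class = "slide_verdict")
}

#' @export
print.slide_verdict <- function(x, ...) {
  cat(sprintf("slide diagnosis: %s (%d of %d patches positive)\n",
              x$diagnosis, x$positive_patch_count, x$total_patch_count))
  invisible(x)
}

#' Automatic annotation of EBER-style patches
#'
#' Runs the pixel- and patch-level decisions over a set of target-domain
#' patches and returns a label manifest, the procedure used to label the
#' translation model's training data without a pathologist.
#'
#' @param patches list of H x W x 3 arrays, or a character vector of image
#'   paths.
#' @param thresholds a [decision_thresholds()].
#' @return data frame with columns `path` (or index), `label`,
#'   `largest_component_area`, in input order; thresholds recorded in the
#'   `thresholds` attribute.
#' @export
auto_annotate <- function(patches, thresholds = decision_thresholds()) {
  paths <- if (is.character(patches)) patches
           else sprintf("patch_%05d", seq_along(patches))
  n <- length(patches)
  label <- integer(n); area <- integer(n)
  for (i in seq_len(n)) {
    patch <- if (is.character(patches)) read_patch(patches[i]) else patches[[i]]
    v <- tryCatch(
      patch_decision(pixel_decision(patch, thresholds), thresholds),
      eberstain_error = function(e) stop_eberstain(
        sprintf("patch %d: %s", i, conditionMessage(e)), class(e)[1]))
    label[i] <- v$label; area[i] <- v$largest_component_area
  }
  out <- data.frame(path = paths, label = label,
                    largest_component_area = area, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  out
}

#' Per-class channel histograms of mean foreground intensity
#'
#' For every patch, the mean R, G and B intensity over foreground (tissue)
#' pixels; grouped by class label. Negative EBER-style patches cluster at
#' high R means (above 200) and tumour-dominated positive patches at low R
#' means (below 100), which is the separation justifying the pixel rule.
#'
#' @param patches list of H x W x 3 arrays.
#' @param labels 0/1 vector, one per patch.
#' @param thresholds a [decision_thresholds()] (used for the background
#'   criterion only).
#' @return data frame with columns `index`, `label`, `r_mean`, `g_mean`,
#'   `b_mean` (patches with no foreground get `NA` means).
#' @export
channel_histograms <- function(patches, labels,
                               thresholds = decision_thresholds()) {
  if (length(patches) != length(labels))
    stop_eberstain("patches and labels must have equal length",
                   "eberstain_format_error")
  rows <- lapply(seq_along(patches), function(i) {
    p <- patches[[i]]
    assert_rgb_patch(p)
    fg <- !background_mask(p, thresholds)
    m <- if (any(fg)) vapply(1:3, function(ch) mean(p[, , ch][fg]), numeric(1))
         else rep(NA_real_, 3)
    data.frame(index = i, label = as.integer(labels[i]),
               r_mean = m[1], g_mean = m[2], b_mean = m[3])
  })
  do.call(rbind, rows)
}
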