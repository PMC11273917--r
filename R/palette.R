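#' Stain palette for the two-domain synthetic generator
#'
#' A palette fixes, per stain domain and tissue class, the closed 8-bit
#' interval from which pixel intensities are drawn. The EBER-style (target)
#' domain is constrained the way real EBER-ISH behaves: EBV-positive tumour
#' nuclei are dark (R channel below 100) while all negative tissue is pink
#' (R channel above 200), which is exactly the separation the prior-driven
#' pixel rule exploits. Glass background is near-saturated in all channels.
#'
#' Each `*_rgb_range` is a 2 x 3 matrix; row 1 holds per-channel lower
#' bounds, row 2 upper bounds, columns are R, G, B.
#'
#' @param positive_rgb_range EBER-positive nucleus intensities; the R upper
#'   bound must stay below 100.
#' @param negative_rgb_range EBER-negative tissue; the R lower bound must
#'   exceed 200 (and the interval must not look like background).
#' @param background_rgb_range glass background; all lower bounds must be at
#'   least `background_cutoff`.
#' @param he_tumor_rgb_range,he_stroma_rgb_range,he_nontumor_rgb_range source
#'   (H&E-style) appearance of tumour nuclei, stroma, and non-tumour cells
#'   (lymphocyte-like). Chosen clearly separable; this is a documented
#'   simplification of real H&E morphology.
#' @param background_cutoff 8-bit intensity above which a pixel counts as
#'   glass; default 230.
#' @return An object of class `stain_palette`.
#' @examples
#' pal <- stain_palette()
#' pal$positive_rgb_range
#' @export
stain_palette <- function(positive_rgb_range  = rgb_range(c(30, 70),  c(40, 90),  c(90, 140)),
                          negative_rgb_range  = rgb_range(c(215, 245), c(120, 170), c(140, 190)),
                          background_rgb_range = rgb_range(c(240, 252), c(240, 252), c(240, 252)),
                          he_tumor_rgb_range  = rgb_range(c(60, 100), c(55, 95),  c(150, 200)),
                          he_stroma_rgb_range = rgb_range(c(220, 245), c(140, 180), c(170, 210)),
                          he_nontumor_rgb_range = rgb_range(c(120, 160), c(40, 80), c(140, 180)),
                          background_cutoff = 230) {
  pal <- structure(
    list(
      positive_rgb_range = positive_rgb_range,
      negative_rgb_range = negative_rgb_range,
      background_rgb_range = background_rgb_range,
      he_tumor_rgb_range = he_tumor_rgb_range,
      he_stroma_rgb_range = he_stroma_rgb_range,
      he_nontumor_rgb_range = he_nontumor_rgb_range,
      background_cutoff = background_cutoff
    ),
    class = "stain_palette"
  )
  validate_palette(pal)
  pal
}

#' Build a per-channel intensity interval
#'
#' @param r,g,b length-2 numeric vectors `c(lower, upper)` in \[0, 255\].
#' @return A 2 x 3 matrix with rows `lo`, `hi` and columns `R`, `G`, `B`.
#' @export
rgb_range <- function(r, g, b) {
  m <- cbind(R = r, G = g, B = b)
  rownames(m) <- c("lo", "hi")
  if (any(m[1, ] > m[2, ]) || min(m) < 0 || max(m) > 255)
    stop_eberstain("intensity intervals must satisfy 0 <= lo <= hi <= 255",
                   "eberstain_palette_error")
  m
}

validate_palette <- function(pal) {
  if (pal$positive_rgb_range["hi", "R"] >= 100)
    stop_eberstain("EBER-positive R-channel upper bound must be < 100",
                   "eberstain_palette_error")
  if (pal$negative_rgb_range["lo", "R"] <= 200)
    stop_eberstain("EBER-negative R-channel lower bound must be > 200",
                   "eberstain_palette_error")
  if (any(pal$background_rgb_range["lo", ] < pal$background_cutoff))
    stop_eberstain("background interval must lie at or above the background cutoff in every channel",
                   "eberstain_palette_error")
  invisible(pal)
}

#' @export
print.stain_palette <- function(x, ...) {
  cat("Two-domain stain palette (8-bit intervals)\n")
  cat(sprintf("  EBER positive R: [%d, %d] (< 100)\n",
              x$positive_rgb_range["lo", "R"], x$positive_rgb_range["hi", "R"]))
  cat(sprintf("  EBER negative R: [%d, %d] (> 200)\n",
              x$negative_rgb_range["lo", "R"], x$negative_rgb_range["hi", "R"]))
  cat(sprintf("  background cutoff: %d\n", as.integer(x$background_cutoff)))
  invisible(x)
}
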