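#' Tile layout for a slide
#'
#' Computes the grid of tile origins for a sliding window of size
#' `tile_size` and step `stride` over an `slide_dim = c(H, W)` image.
#' Coordinates are 0-based `(row, col)` with half-open tile extents; the
#' last row/column origins are clamped so every tile lies fully inside the
#' slide (extra overlap at the edges, no invented pixels).
#'
#' @param slide_dim slide size `c(H, W)` in pixels.
#' @param tile_size tile edge (default 256).
#' @param stride window step, `1 <= stride <= tile_size` (overlap allowed).
#' @param origins optional pre-selected origin matrix (two columns, 0-based)
#'   as produced by foreground filtering.
#' @return An object of class `slide_layout`: list with `slide_dim`,
#'   `tile_size`, `stride`, `origins` (n x 2 integer matrix).
#' @export
slide_layout <- function(slide_dim, tile_size = 256L, stride = tile_size,
                         origins = NULL) {
  slide_dim <- as.integer(slide_dim); tile_size <- as.integer(tile_size)
  stride <- as.integer(stride)
  if (stride < 1L || stride > tile_size)
    stop_eberstain("stride must satisfy 1 <= stride <= tile_size",
                   "eberstain_layout_error")
  if (any(slide_dim < tile_size))
    stop_eberstain("slide smaller than one tile", "eberstain_layout_error")
  axis_origins <- function(n) {
    o <- seq(0L, n - tile_size, by = stride)
    if (o[length(o)] != n - tile_size) o <- c(o, n - tile_size)  # clamp last
    o
  }
  if (is.null(origins)) {
    oy <- axis_origins(slide_dim[1]); ox <- axis_origins(slide_dim[2])
    origins <- cbind(row = rep(oy, times = length(ox)),
                     col = rep(ox, each = length(oy)))
  } else {
    origins <- matrix(as.integer(origins), ncol = 2,
                      dimnames = list(NULL, c("row", "col")))
    if (nrow(origins) && (min(origins) < 0L ||
        any(origins[, 1] > slide_dim[1] - tile_size) ||
        any(origins[, 2] > slide_dim[2] - tile_size)))
      stop_eberstain("tile origins out of bounds", "eberstain_layout_error")
    if (anyDuplicated(origins))
      stop_eberstain("tile origins must be unique", "eberstain_layout_error")
  }
  structure(list(slide_dim = slide_dim, tile_size = tile_size,
                 stride = stride, origins = origins),
            class = "slide_layout")
}

#' @export
print.slide_layout <- function(x, ...) {
  cat(sprintf("slide layout: %d x %d px, tile %d, stride %d, %d tiles\n",
              x$slide_dim[1], x$slide_dim[2], x$tile_size, x$stride,
              nrow(x$origins)))
  invisible(x)
}

#' Detect foreground tiles on a slide
#'
#' A tile is kept iff its fraction of non-background pixels (background:
#' `min(R,G,B)` at or above `background_min_intensity`) reaches
#' `min_foreground_fraction`.
#'
#' @param slide H x W x 3 array (8-bit) or an image path.
#' @param thresholds a [decision_thresholds()]; supplies the background
#'   criterion.
#' @param tile_size,stride tiling parameters, see [slide_layout()].
#' @param min_foreground_fraction minimum tissue fraction per tile
#'   (default 0.05; 0 retains every tile).
#' @return A `slide_layout` containing only foreground tile origins (may
#'   have zero rows).
#' @export
detect_foreground <- function(slide, thresholds = decision_thresholds(),
                              tile_size = 256L, stride = tile_size,
                              min_foreground_fraction = 0.05) {
  if (is.character(slide)) slide <- read_patch(slide)
  assert_rgb_patch(slide, "slide")
  full <- slide_layout(dim(slide)[1:2], tile_size, stride)
  bg <- background_mask(slide, thresholds)
  keep <- vapply(seq_len(nrow(full$origins)), function(i) {
    o <- full$origins[i, ]
    sub <- bg[o[1] + seq_len(tile_size), o[2] + seq_len(tile_size)]
    mean(!sub) >= min_foreground_fraction
  }, logical(1))
  slide_layout(dim(slide)[1:2], tile_size, stride,
               origins = full$origins[keep, , drop = FALSE])
}

#' Extract tiles from a slide
#'
#' @param slide H x W x 3 array (8-bit) or an image path.
#' @param layout a [slide_layout()].
#' @return list of H x W x 3 patches, one per layout origin, with the
#'   origin attached as attribute `origin`.
#' @export
extract_tiles <- function(slide, layout) {
  if (is.character(slide)) slide <- read_patch(slide)
  assert_rgb_patch(slide, "slide")
  stopifnot(inherits(layout, "slide_layout"))
  if (any(dim(slide)[1:2] != layout$slide_dim))
    stop_eberstain("layout does not match slide dimensions",
                   "eberstain_layout_error")
  ts <- layout$tile_size
  lapply(seq_len(nrow(layout$origins)), function(i) {
    o <- layout$origins[i, ]
    tile <- slide[o[1] + seq_len(ts), o[2] + seq_len(ts), , drop = FALSE]
    attr(tile, "origin") <- o
    tile
  })
}

#' Reconstruct a slide-sized image or mask from per-tile outputs
#'
#' Image tiles overlapping the same pixels are combined by their unweighted
#' mean; mask tiles by logical OR. Pixels covered by no tile take
#' `background_value`.
#'
#' @param tiles list of tile outputs (H x W x 3 arrays, or H x W 0/1
#'   matrices when `type = "mask"`), in layout order.
#' @param layout a [slide_layout()]; every origin must have a tile.
#' @param type `"image"` (mean blend) or `"mask"` (OR).
#' @param background_value fill for uncovered pixels (default 255 for
#'   images, 0 for masks).
#' @return Slide-sized array (image) or 0/1 matrix (mask).
#' @export
reconstruct_slide <- function(tiles, layout, type = c("image", "mask"),
                              background_value = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(layout, "slide_layout"))
  n <- nrow(layout$origins)
  if (length(tiles) != n)
    stop_eberstain(sprintf(
      "missing tile outputs: layout has %d origins, got %d tiles", n,
      length(tiles)), "eberstain_layout_error")
  H <- layout$slide_dim[1]; W <- layout$slide_dim[2]; ts <- layout$tile_size
  if (is.null(background_value))
    background_value <- if (type == "image") 255 else 0

  if (type == "mask") {
    acc <- matrix(0L, H, W); covered <- matrix(FALSE, H, W)
    for (i in seq_len(n)) {
      o <- layout$origins[i, ]
      assert_binary_mask(tiles[[i]], sprintf("tiles[[%d]]", i))
      ys <- o[1] + seq_len(ts); xs <- o[2] + seq_len(ts)
      acc[ys, xs] <- pmax(acc[ys, xs], tiles[[i]])
      covered[ys, xs] <- TRUE
    }
    acc[!covered] <- as.integer(background_value)
    return(acc)
  }

  acc <- array(0, c(H, W, 3L)); cnt <- matrix(0L, H, W)
  for (i in seq_len(n)) {
    o <- layout$origins[i, ]
    ys <- o[1] + seq_len(ts); xs <- o[2] + seq_len(ts)
    acc[ys, xs, ] <- acc[ys, xs, , drop = FALSE] + tiles[[i]]
    cnt[ys, xs] <- cnt[ys, xs] + 1L
  }
  covered <- cnt > 0L
  for (ch in 1:3) {
    plane <- acc[, , ch]
    plane[covered] <- plane[covered] / cnt[covered]
    plane[!covered] <- background_value
    acc[, , ch] <- plane
  }
  acc
}
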