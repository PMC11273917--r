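#' Synthetic two-domain stained scenes
#'
#' A scene is a canvas plus a list of circular cells, each tumour or
#' non-tumour. Rendered once per stain domain it yields a matched pair of
#' patches with exact per-pixel ground truth, standing in for clinical
#' H&E/EBER patch pairs. Tumour cells must meet a minimum rendered pixel
#' footprint (default 125 px, the measured average pixel count of the
#' smallest tumour cell per image in EBER-positive material).
#'
#' @param canvas integer length-2, canvas size `c(H, W)` in pixels.
#' @param cells data frame with columns `y`, `x` (centre, 1-based), `radius`
#'   (pixels) and `class` (`"tumor"` or `"non_tumor"`). May have zero rows.
#' @param seed integer RNG seed; fully determines the rendering.
#' @param min_footprint minimum rendered pixel area for a tumour cell.
#' @return An object of class `synthetic_scene`.
#' @examples
#' sc <- synthetic_scene(c(64, 64),
#'                       data.frame(y = 32, x = 32, radius = 7, class = "tumor"),
#'                       seed = 1)
#' @export
synthetic_scene <- function(canvas, cells = empty_cells(), seed = 1L,
                            min_footprint = 125L) {
  canvas <- as.integer(canvas)
  if (length(canvas) != 2L || any(canvas < 1L))
    stop_eberstain("canvas must be two positive integers", "eberstain_scene_error")
  cells <- as.data.frame(cells)
  if (nrow(cells)) {
    need <- c("y", "x", "radius", "class")
    if (!all(need %in% names(cells)))
      stop_eberstain("cells must have columns y, x, radius, class",
                     "eberstain_scene_error")
    if (!all(cells$class %in% c("tumor", "non_tumor")))
      stop_eberstain("cell class must be 'tumor' or 'non_tumor'",
                     "eberstain_scene_error")
    inside <- cells$y - cells$radius >= 1 & cells$y + cells$radius <= canvas[1] &
              cells$x - cells$radius >= 1 & cells$x + cells$radius <= canvas[2]
    if (!all(inside))
      stop_eberstain("canvas too small: every cell disc must lie fully within the canvas",
                     "eberstain_scene_error")
    tum <- cells$class == "tumor"
    if (any(tum)) {
      areas <- vapply(cells$radius[tum], disc_area, numeric(1))
      if (any(areas < min_footprint))
        stop_eberstain(
          sprintf("tumor cell footprint below the %d px minimum", min_footprint),
          "eberstain_scene_error")
    }
  }
  structure(list(canvas = canvas, cells = cells, seed = as.integer(seed),
                 min_footprint = as.integer(min_footprint)),
            class = "synthetic_scene")
}

empty_cells <- function() {
  data.frame(y = numeric(0), x = numeric(0), radius = numeric(0),
             class = character(0))
}

# exact pixel count of a rasterized disc of given radius
disc_area <- function(radius) {
  r <- seq(-floor(radius), floor(radius))
  sum(outer(r^2, r^2, "+") <= radius^2)
}

#' Randomly populated scene
#'
#' Places non-overlap-unconstrained discs uniformly (fully inside the
#' canvas). Tumour radii default to 7-10 px, giving footprints of 149-317 px,
#' all above the 125 px minimum; non-tumour (lymphocyte-like) radii default
#' to 3-5 px, i.e. below the 100 px component threshold even if misstained.
#'
#' @param canvas canvas size `c(H, W)`.
#' @param n_tumor,n_nontumor cell counts.
#' @param seed RNG seed.
#' @param tumor_radius,nontumor_radius inclusive integer radius ranges.
#' @inheritParams synthetic_scene
#' @return A `synthetic_scene`.
#' @export
random_scene <- function(canvas, n_tumor, n_nontumor, seed,
                         tumor_radius = c(7L, 10L),
                         nontumor_radius = c(3L, 5L),
                         min_footprint = 125L) {
  canvas <- as.integer(canvas)
  cells <- with_seed(seed, {
    one <- function(n, rng, cls) {
      if (n == 0L) return(empty_cells())
      r <- sample(seq(rng[1], rng[2]), n, replace = TRUE)
      if (any(canvas[1] < 2 * r + 1) || any(canvas[2] < 2 * r + 1))
        stop_eberstain("canvas too small for requested cell radii",
                       "eberstain_scene_error")
      y <- vapply(r, function(ri) sample(seq(ri + 1L, canvas[1] - ri), 1L), numeric(1))
      x <- vapply(r, function(ri) sample(seq(ri + 1L, canvas[2] - ri), 1L), numeric(1))
      data.frame(y = y, x = x, radius = r, class = cls)
    }
    rbind(one(n_tumor, tumor_radius, "tumor"),
          one(n_nontumor, nontumor_radius, "non_tumor"))
  })
  synthetic_scene(canvas, cells, seed = seed, min_footprint = min_footprint)
}

# class map: 0 stroma, 1 non_tumor cell, 2 tumor cell
scene_class_map <- function(scene) {
  H <- scene$canvas[1]; W <- scene$canvas[2]
  cm <- matrix(0L, H, W)
  paint <- function(cm, cells, value) {
    for (i in seq_len(nrow(cells))) {
      r <- cells$radius[i]
      ys <- seq(max(1, cells$y[i] - r), min(H, cells$y[i] + r))
      xs <- seq(max(1, cells$x[i] - r), min(W, cells$x[i] + r))
      d2 <- outer((ys - cells$y[i])^2, (xs - cells$x[i])^2, "+")
      sub <- cm[ys, xs, drop = FALSE]
      sub[d2 <= r^2] <- value
      cm[ys, xs] <- sub
    }
    cm
  }
  cells <- scene$cells
  # non-tumour first so that overlapping tumour pixels win, keeping the
  # ground-truth mask exactly the tumour pixel set
  cm <- paint(cm, cells[cells$class == "non_tumor", , drop = FALSE], 1L)
  cm <- paint(cm, cells[cells$class == "tumor", , drop = FALSE], 2L)
  cm
}

# fill an H x W x 3 patch: for each class region draw uniform integers from
# the per-channel palette interval
render_from_class_map <- function(cm, ranges) {
  H <- nrow(cm); W <- ncol(cm)
  out <- array(0, c(H, W, 3L))
  for (cls in sort(unique(as.vector(cm)))) {
    idx <- which(cm == cls)
    rng <- ranges[[as.character(cls)]]
    for (ch in 1:3) {
      lo <- rng["lo", ch]; hi <- rng["hi", ch]
      v <- lo + floor(stats::runif(length(idx)) * (hi - lo + 1))
      plane <- out[, , ch]
      plane[idx] <- pmin(v, hi)
      out[, , ch] <- plane
    }
  }
  storage.mode(out) <- "integer"
  out
}

#' Render a scene in both stain domains
#'
#' Produces the matched source-domain (H&E-style) patch, target-domain
#' (EBER-style) patch and the ground-truth tumour mask. Rendering is fully
#' determined by the scene seed; the mask marks exactly the pixels painted
#' with the EBER-positive palette.
#'
#' @param scene a [synthetic_scene()].
#' @param palette a [stain_palette()].
#' @return list with elements `source`, `target` (H x W x 3 integer arrays)
#'   and `mask` (H x W 0/1 matrix).
#' @export
render_pair <- function(scene, palette = stain_palette()) {
  stopifnot(inherits(scene, "synthetic_scene"))
  validate_palette(palette)
  cm <- scene_class_map(scene)
  with_seed(scene$seed, {
    src <- render_from_class_map(cm, list(
      `0` = palette$he_stroma_rgb_range,
      `1` = palette$he_nontumor_rgb_range,
      `2` = palette$he_tumor_rgb_range,
      `3` = palette$background_rgb_range))
    tgt <- render_from_class_map(cm, list(
      `0` = palette$negative_rgb_range,
      `1` = palette$negative_rgb_range,
      `2` = palette$positive_rgb_range,
      `3` = palette$background_rgb_range))
    list(source = src, target = tgt,
         mask = matrix(as.integer(cm == 2L), nrow(cm), ncol(cm)))
  })
}

#' Render a pseudo whole-slide image as a tile grid
#'
#' Lays out `n_tiles_y` x `n_tiles_x` independently generated scenes on one
#' large canvas per domain. Tiles listed in `tumor_tiles` receive at least
#' one tumour cell above the minimum footprint; all other tissue tiles carry
#' only non-tumour cells; tiles in `background_tiles` are bare glass.
#'
#' @param n_tiles_x,n_tiles_y grid dimensions (>= 1).
#' @param tumor_tiles two-column matrix (or list of length-2 vectors) of
#'   1-based `(row, col)` grid positions that must contain tumour.
#' @param palette a [stain_palette()].
#' @param seed RNG seed.
#' @param tile_size tile edge in pixels.
#' @param background_tiles optional positions rendered as pure glass.
#' @return list with `source`, `target` (large images), `labels`
#'   (`n_tiles_y` x `n_tiles_x` 0/1 matrix), `mask` (full-size ground-truth
#'   tumour mask) and `tile_size`.
#' @export
render_pseudo_wsi <- function(n_tiles_x, n_tiles_y, tumor_tiles = NULL,
                              palette = stain_palette(), seed = 1L,
                              tile_size = 64L, background_tiles = NULL) {
  if (n_tiles_x < 1L || n_tiles_y < 1L)
    stop_eberstain("grid dimensions must be >= 1", "eberstain_scene_error")
  as_pos <- function(p) {
    if (is.null(p)) return(matrix(integer(0), 0, 2))
    if (is.list(p)) p <- do.call(rbind, p)
    p <- matrix(as.integer(p), ncol = 2)
    if (nrow(p) && (min(p) < 1L || any(p[, 1] > n_tiles_y) || any(p[, 2] > n_tiles_x)))
      stop_eberstain("tile positions outside the grid", "eberstain_scene_error")
    p
  }
  tumor_tiles <- as_pos(tumor_tiles)
  background_tiles <- as_pos(background_tiles)
  tile_size <- as.integer(tile_size)

  H <- n_tiles_y * tile_size; W <- n_tiles_x * tile_size
  src <- array(0L, c(H, W, 3L)); tgt <- array(0L, c(H, W, 3L))
  labels <- matrix(0L, n_tiles_y, n_tiles_x)
  mask <- matrix(0L, H, W)
  tile_seeds <- derive_seeds(seed, n_tiles_y * n_tiles_x + 1L)

  k <- 0L
  for (i in seq_len(n_tiles_y)) for (j in seq_len(n_tiles_x)) {
    k <- k + 1L
    is_tumor <- any(tumor_tiles[, 1] == i & tumor_tiles[, 2] == j)
    is_bg <- any(background_tiles[, 1] == i & background_tiles[, 2] == j)
    if (is_bg) {
      sc <- synthetic_scene(c(tile_size, tile_size), seed = tile_seeds[k])
      cm <- matrix(3L, tile_size, tile_size)
      pair <- with_seed(tile_seeds[k], list(
        source = render_from_class_map(cm, list(`3` = palette$background_rgb_range)),
        target = render_from_class_map(cm, list(`3` = palette$background_rgb_range)),
        mask = matrix(0L, tile_size, tile_size)))
    } else {
      n_t <- if (is_tumor) 1L + with_seed(tile_seeds[k] + 1L, sample(0:2, 1)) else 0L
      n_n <- with_seed(tile_seeds[k] + 2L, sample(1:4, 1))
      sc <- random_scene(c(tile_size, tile_size), n_t, n_n, seed = tile_seeds[k])
      pair <- render_pair(sc, palette)
    }
    ys <- (i - 1L) * tile_size + seq_len(tile_size)
    xs <- (j - 1L) * tile_size + seq_len(tile_size)
    src[ys, xs, ] <- pair$source
    tgt[ys, xs, ] <- pair$target
    mask[ys, xs] <- pair$mask
    labels[i, j] <- as.integer(is_tumor)
  }
  list(source = src, target = tgt, labels = labels, mask = mask,
       tile_size = tile_size)
}

#' Generate an unpaired two-domain training set with ground truth
#'
#' Emulates the unpaired H&E / EBER patch collections used to train the
#' stain-translation model: `n_source` source-domain patches and `n_target`
#' target-domain patches, each patch tumour-bearing with probability
#' `tumor_fraction` (independent draws, so the realised fraction varies
#' within binomial error). Ground-truth labels are returned for validation
#' only; the translation model itself never sees them directly.
#'
#' @param n_source,n_target patch counts (>= 1).
#' @param tumor_fraction probability a patch contains tumour, in \[0, 1\].
#' @param seed RNG seed.
#' @param patch_size patch edge in pixels (default 64, the desk-scale size).
#' @param palette a [stain_palette()].
#' @param out_dir if non-`NULL`, patches are written there as PNG and the
#'   manifest as `manifest.csv`.
#' @return list with `source`, `target` (lists of H x W x 3 integer arrays),
#'   `source_labels`, `target_labels` (0/1 integer vectors),
#'   `target_masks` (ground-truth masks for the target patches) and
#'   `manifest` (data frame with columns `path,label,domain,seed`).
#' @export
make_unpaired_set <- function(n_source, n_target, tumor_fraction, seed,
                              patch_size = 64L, palette = stain_palette(),
                              out_dir = NULL) {
  if (n_source < 1L || n_target < 1L)
    stop_eberstain("patch counts must be >= 1", "eberstain_scene_error")
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stop_eberstain("tumor_fraction must be in [0, 1]", "eberstain_scene_error")
  seeds <- derive_seeds(seed, 2L * (n_source + n_target))
  gen_side <- function(n, offset, domain) {
    patches <- vector("list", n); labels <- integer(n); masks <- vector("list", n)
    for (i in seq_len(n)) {
      s <- seeds[offset + 2L * i - 1L]
      lab <- as.integer(with_seed(seeds[offset + 2L * i], stats::runif(1)) < tumor_fraction)
      n_t <- if (lab == 1L) 1L + with_seed(s + 1L, sample(0:2, 1)) else 0L
      n_n <- with_seed(s + 2L, sample(1:4, 1))
      sc <- random_scene(c(patch_size, patch_size), n_t, n_n, seed = s)
      pair <- render_pair(sc, palette)
      patches[[i]] <- if (domain == "source") pair$source else pair$target
      masks[[i]] <- pair$mask
      labels[i] <- lab
    }
    list(patches = patches, labels = labels, masks = masks)
  }
  src <- gen_side(n_source, 0L, "source")
  tgt <- gen_side(n_target, 2L * n_source, "target")
  manifest <- data.frame(
    path = c(sprintf("source_%05d.png", seq_len(n_source)),
             sprintf("target_%05d.png", seq_len(n_target))),
    label = c(src$labels, tgt$labels),
    domain = rep(c("source", "target"), c(n_source, n_target)),
    seed = seed,
    stringsAsFactors = FALSE
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_source))
      write_patch(src$patches[[i]], file.path(out_dir, manifest$path[i]))
    for (i in seq_len(n_target))
      write_patch(tgt$patches[[i]], file.path(out_dir, manifest$path[n_source + i]))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(source = src$patches, source_labels = src$labels,
       target = tgt$patches, target_labels = tgt$labels,
       target_masks = tgt$masks, manifest = manifest)
}
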