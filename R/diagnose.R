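#' End-to-end slide diagnosis
#'
#' Runs the full pipeline on one slide image: foreground tile detection,
#' tile extraction, digital staining of each tile (skipped when the slide
#' is already target-domain), the pixel/patch/slide decision cascade, and
#' reconstruction of the stained slide and the tumour-region mask (OR of
#' the positivity masks of positive patches).
#'
#' @param slide H x W x 3 array (8-bit) or an image path.
#' @param model a fitted [pfgan()] object, or `NULL` if the slide is
#'   already EBER-style.
#' @param thresholds a [decision_thresholds()].
#' @param tile_size,stride,min_foreground_fraction tiling parameters, see
#'   [detect_foreground()].
#' @param out_dir optional directory; when given, the stained slide
#'   (`stained.png`), tumour mask (`tumor_mask.png`), per-patch report
#'   (`patches.csv`) and a provenance manifest (`run.yaml`) are written
#'   there.
#' @return list with `verdict` (a `slide_verdict`), `stained` (slide-sized
#'   image), `tumor_mask` (slide-sized 0/1 matrix), `patches` (data frame
#'   with origin, label and largest component area per tile) and `layout`.
#'   Raises an error of class `eberstain_no_foreground` (not a diagnosis)
#'   when no tissue is detected.
#' @export
diagnose_slide <- function(slide, model = NULL,
                           thresholds = decision_thresholds(),
                           tile_size = 256L, stride = tile_size,
                           min_foreground_fraction = 0.05,
                           out_dir = NULL) {
  if (is.character(slide)) slide <- read_patch(slide)
  layout <- detect_foreground(slide, thresholds, tile_size, stride,
                              min_foreground_fraction)
  if (nrow(layout$origins) == 0L)
    stop_eberstain("no tissue detected on the slide", "eberstain_no_foreground")
  tiles <- extract_tiles(slide, layout)
  stained <- if (is.null(model)) tiles else lapply(tiles, stain, model = model)
  masks <- lapply(stained, pixel_decision, thresholds = thresholds)
  verdicts <- lapply(masks, patch_decision, thresholds = thresholds)
  verdict <- wsi_decision(verdicts, thresholds)

  labels <- vapply(verdicts, function(v) v$label, integer(1))
  patches <- data.frame(
    origin_row = layout$origins[, 1], origin_col = layout$origins[, 2],
    label = labels,
    largest_component_area = vapply(verdicts, function(v)
      v$largest_component_area, integer(1)))

  pos_masks <- lapply(seq_along(masks), function(i)
    if (labels[i] == 1L) masks[[i]] else matrix(0L, tile_size, tile_size))
  out <- list(
    verdict = verdict,
    stained = reconstruct_slide(stained, layout, "image"),
    tumor_mask = reconstruct_slide(pos_masks, layout, "mask"),
    patches = patches,
    layout = layout)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    img <- clamp(round(out$stained), 0, 255)
    storage.mode(img) <- "integer"
    write_patch(img, file.path(out_dir, "stained.png"))
    write_patch(out$tumor_mask, file.path(out_dir, "tumor_mask.png"))
    utils::write.csv(patches, file.path(out_dir, "patches.csv"),
                     row.names = FALSE)
    yaml::write_yaml(run_manifest(list(
      thresholds = unclass(thresholds), tile_size = tile_size,
      stride = stride, min_foreground_fraction = min_foreground_fraction,
      diagnosis = verdict$diagnosis)),
      file.path(out_dir, "run.yaml"))
  }
  out
}

#' Provenance record for a run
#'
#' Serialises the configuration canonically (YAML) and attaches an MD5
#' hash, the package version and a timestamp, so two runs with identical
#' configuration carry identical hashes.
#'
#' @param config named list of run parameters.
#' @return list with `config`, `config_hash`, `package_version`, `created`.
#' @export
run_manifest <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  list(config = config,
       config_hash = unname(tools::md5sum(tmp)),
       package_version = as.character(utils::packageVersion("eberstain")),
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
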