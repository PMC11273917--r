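#' Read an 8-bit RGB patch from PNG or TIFF
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @return H x W x 3 integer array with values in 0..255.
#' @export
read_patch <- function(path) {
  if (!file.exists(path))
    stop_eberstain(sprintf("cannot read image '%s'", path), "eberstain_io_error")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_eberstain(sprintf("unsupported image format '%s'", ext),
                   "eberstain_io_error"))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  out <- round(img * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write an 8-bit RGB patch or a binary mask
#'
#' Masks (0/1 matrices) are written as single-channel images with 0/255
#' encoding.
#'
#' @param img H x W x 3 array in 0..255, or an H x W 0/1 matrix.
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @export
write_patch <- function(img, path) {
  if (is.matrix(img)) {
    assert_binary_mask(img)
    arr <- img + 0.0    # 0/1 -> 0/255 via the [0,1] encoding; writers need doubles
  } else {
    assert_rgb_patch(img, "img")
    arr <- img / 255
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    stop_eberstain(sprintf("unsupported image format '%s'", ext),
                   "eberstain_io_error"))
  invisible(path)
}
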