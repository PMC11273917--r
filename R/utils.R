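# internal helpers shared across modules

# Run code with a temporarily fixed RNG state; restores (or removes)
# .Random.seed afterwards so callers' RNG streams are untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive k reproducible sub-seeds (< 2^31) from one master seed, so that
# independent components (weight init, data order, ...) consume disjoint
# RNG streams.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

stop_eberstain <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "eberstain_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 8-bit RGB patch validation: H x W x 3 array, intensities in [0, 255]
assert_rgb_patch <- function(patch, arg = "patch") {
  if (!is.array(patch) || length(dim(patch)) != 3L || dim(patch)[3] != 3L)
    stop_eberstain(
      sprintf("`%s` must be an H x W x 3 array of 8-bit RGB intensities", arg),
      "eberstain_format_error"
    )
  if (anyNA(patch) || min(patch) < 0 || max(patch) > 255)
    stop_eberstain(
      sprintf("`%s` has intensities outside [0, 255]", arg),
      "eberstain_format_error"
    )
  invisible(patch)
}

assert_binary_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask))
    stop_eberstain(sprintf("`%s` must be a matrix", arg), "eberstain_format_error")
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1)))
    stop_eberstain(sprintf("`%s` must contain only 0 and 1", arg),
                   "eberstain_format_error")
  invisible(mask)
}
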