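test_that("empty scenes render as pure negative tissue with empty masks", {
  sc <- synthetic_scene(c(48, 48), seed = 3)
  pr <- render_pair(sc)
  pal <- stain_palette()
  expect_equal(sum(pr$mask), 0)
  expect_true(all(pr$target[, , 1] >= pal$negative_rgb_range["lo", "R"]))
  expect_true(all(pr$target[, , 1] <= pal$negative_rgb_range["hi", "R"]))
  expect_true(all(pr$target[, , 1] > 200))
})

test_that("ground-truth mask area equals the rendered disc pixel count", {
  sc <- synthetic_scene(c(64, 64),
                        data.frame(y = 30, x = 30, radius = 7, class = "tumor"),
                        seed = 5)
  pr <- render_pair(sc)
  # pixel-count oracle: rasterise the disc directly
  painted <- 0L
  for (i in 1:64) for (j in 1:64)
    if ((i - 30)^2 + (j - 30)^2 <= 49) painted <- painted + 1L
  expect_equal(sum(pr$mask), painted)
  expect_gte(painted, 125)   # a radius-7 nucleus meets the minimum footprint
  expect_equal(largest_component_area(pr$mask, 8), painted)
})

test_that("rendering is deterministic and domains depict the same scene", {
  sc <- random_scene(c(64, 64), 2, 3, seed = 17)
  a <- render_pair(sc); b <- render_pair(sc)
  expect_identical(a$source, b$source)
  expect_identical(a$target, b$target)
  expect_identical(a$mask, b$mask)
  # same geometry in both domains: tumour pixels are dark-R in the target
  # and blue-purple (R <= 100) in the source
  expect_true(all(a$target[, , 1][a$mask == 1] < 100))
  expect_true(all(a$source[, , 1][a$mask == 1] <= 100))
})

test_that("palette compliance: positive pixels and mask coincide exactly", {
  for (seed in 1:5) {
    pr <- render_pair(random_scene(c(64, 64), 2, 2, seed = seed))
    dark <- pr$target[, , 1] < 100
    expect_identical(which(dark), which(pr$mask == 1))
    expect_true(all(pr$target[, , 1][pr$mask == 0] > 200))
  }
})

test_that("scene and palette validation reject bad inputs", {
  expect_error(synthetic_scene(c(10, 10),
                               data.frame(y = 5, x = 5, radius = 7,
                                          class = "tumor")),
               class = "eberstain_scene_error")
  expect_error(synthetic_scene(c(64, 64),
                               data.frame(y = 32, x = 32, radius = 5,
                                          class = "tumor")),
               class = "eberstain_scene_error")   # footprint 81 < 125
  expect_error(stain_palette(positive_rgb_range =
                               rgb_range(c(30, 120), c(40, 90), c(90, 140))),
               class = "eberstain_palette_error")
  expect_error(stain_palette(negative_rgb_range =
                               rgb_range(c(180, 245), c(120, 170), c(140, 190))),
               class = "eberstain_palette_error")
})

test_that("pseudo-WSI label grids match the requested tumour tiles", {
  w0 <- render_pseudo_wsi(2, 2, seed = 2, tile_size = 48)
  expect_equal(sum(w0$labels), 0)
  w1 <- render_pseudo_wsi(3, 3, tumor_tiles = rbind(c(1, 1)), seed = 2,
                          tile_size = 48)
  expect_equal(sum(w1$labels), 1)
  expect_equal(w1$labels[1, 1], 1L)
  expect_equal(dim(w1$source), c(144, 144, 3))
  expect_error(render_pseudo_wsi(2, 2, tumor_tiles = rbind(c(3, 1)), seed = 2),
               class = "eberstain_scene_error")
})

test_that("unpaired set: fractions, determinism and manifest layout", {
  ds0 <- make_unpaired_set(3, 20, tumor_fraction = 0, seed = 9, patch_size = 48)
  expect_true(all(ds0$target_labels == 0))
  ds1 <- make_unpaired_set(3, 40, tumor_fraction = 0.5, seed = 10, patch_size = 48)
  ds2 <- make_unpaired_set(3, 40, tumor_fraction = 0.5, seed = 10, patch_size = 48)
  expect_identical(ds1$target_labels, ds2$target_labels)
  expect_identical(ds1$target[[7]], ds2$target[[7]])
  # realised fraction within binomial error (4 sd) of the request
  expect_lt(abs(mean(ds1$target_labels) - 0.5), 4 * sqrt(0.25 / 40))
  expect_equal(names(ds1$manifest), c("path", "label", "domain", "seed"))
  expect_error(make_unpaired_set(0, 5, 0.5, 1), class = "eberstain_scene_error")
  expect_error(make_unpaired_set(5, 5, 1.5, 1), class = "eberstain_scene_error")
})

test_that("patch PNG round-trip preserves 8-bit values", {
  pr <- render_pair(random_scene(c(48, 48), 1, 1, seed = 12))
  tmp <- tempfile(fileext = ".png")
  write_patch(pr$target, tmp)
  expect_identical(read_patch(tmp), pr$target)
  unlink(tmp)
})
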