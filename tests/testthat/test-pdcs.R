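make_uniform_patch <- function(rgb, H = 8, W = 8) {
  p <- array(0L, c(H, W, 3L))
  for (ch in 1:3) p[, , ch] <- rgb[ch]
  p
}

test_that("pixel rule: dark-R foreground is positive, background excluded", {
  expect_true(all(pixel_decision(make_uniform_patch(c(50, 60, 120))) == 1))
  expect_true(all(pixel_decision(make_uniform_patch(c(250, 250, 250))) == 0))
  # boundary behaviour at exactly R = 100 (strictly less-than rule)
  p <- array(50L, c(2, 2, 3))
  p[, , 1] <- matrix(c(50L, 99L, 100L, 200L), 2, 2)
  expect_equal(as.vector(pixel_decision(p)), c(1L, 1L, 0L, 0L))
  expect_error(pixel_decision(matrix(0, 4, 4)), class = "eberstain_format_error")
})

test_that("pixel rule is a pure per-pixel function (permutation equivariant)", {
  set.seed(31)
  p <- array(sample(0:255, 6 * 6 * 3, replace = TRUE), c(6, 6, 3))
  m <- pixel_decision(p)
  perm <- sample(36)
  q <- p
  for (ch in 1:3) q[, , ch] <- matrix(p[, , ch][perm], 6, 6)
  expect_equal(as.vector(pixel_decision(q)), as.vector(m)[perm])
})

test_that("largest component area: closed forms and flood-fill oracle", {
  expect_equal(largest_component_area(matrix(0L, 10, 10)), 0L)
  rect <- matrix(0L, 20, 20); rect[4:13, 5:17] <- 1L   # 10 x 13 rectangle
  expect_equal(largest_component_area(rect, 4), 130L)
  expect_equal(largest_component_area(rect, 8), 130L)
  set.seed(7)
  for (i in 1:40) {
    m <- random_mask(32, 32, runif(1, 0.1, 0.6))
    for (conn in c(4L, 8L))
      expect_equal(largest_component_area(m, conn),
                   flood_fill_max_area(m, conn))
  }
})

test_that("4-connectivity labelling agrees with EBImage::bwlabel", {
  set.seed(8)
  for (i in 1:10) {
    m <- random_mask(24, 24, 0.4)
    lab <- label_components(m, 4L)
    ref <- EBImage::bwlabel(m)
    expect_equal(max(lab), max(ref))
    if (max(ref) > 0)
      expect_equal(sort(tabulate(lab[lab > 0])), sort(tabulate(ref[ref > 0])))
  }
})

test_that("patch rule: strict 'exceeds' semantics at the 100 px threshold", {
  disc125 <- matrix(0L, 30, 30); disc125[which(outer((1:30 - 15)^2, (1:30 - 15)^2, "+") <= 38)] <- 1L
  area <- sum(disc125)
  expect_gte(area, 100)   # a ~125 px nucleus footprint
  expect_equal(patch_decision(disc125)$label, 1L)
  m100 <- matrix(0L, 20, 20); m100[1:10, 1:10] <- 1L   # exactly 100 px
  v <- patch_decision(m100)
  expect_equal(v$largest_component_area, 100L)
  expect_equal(v$label, 0L)
  three40 <- matrix(0L, 30, 30)
  three40[1:5, 1:8] <- 1L; three40[10:14, 11:18] <- 1L; three40[20:24, 21:28] <- 1L
  expect_equal(patch_decision(three40)$label, 0L)
})

test_that("slide rule counts positive patches against the slide threshold", {
  v <- wsi_decision(c(0, 0, 1, 0))
  expect_equal(v$diagnosis, "NPC")
  expect_equal(v$positive_patch_count, 1L)
  expect_equal(wsi_decision(rep(0, 50))$diagnosis, "non-NPC")
  labs <- rep(0, 1000); labs[123] <- 1
  th2 <- decision_thresholds(wsi_positive_count_min = 2L)
  expect_equal(wsi_decision(labs, th2)$diagnosis, "non-NPC")
  expect_equal(wsi_decision(labs)$diagnosis, "NPC")
  expect_error(wsi_decision(integer(0)), class = "eberstain_no_foreground")
})

test_that("raising each threshold only moves decisions one way", {
  set.seed(11)
  pr <- render_pair(random_scene(c(64, 64), 2, 2, seed = 41))
  for (r1 in c(60L, 100L, 140L)) {
    m1 <- pixel_decision(pr$target, decision_thresholds(pixel_positive_r_max = r1))
    m2 <- pixel_decision(pr$target, decision_thresholds(pixel_positive_r_max = r1 + 40L))
    expect_true(all(m2[m1 == 1] == 1))   # raising r_max never removes 1s
  }
  m <- pixel_decision(pr$target)
  for (a in c(50L, 100L, 200L, 400L)) {
    l1 <- patch_decision(m, decision_thresholds(component_min_area = a))$label
    l2 <- patch_decision(m, decision_thresholds(component_min_area = a + 100L))$label
    expect_gte(l1, l2)                   # raising min area never flips 0 -> 1
  }
  labs <- rbinom(30, 1, 0.3)
  for (k in 1:4) {
    d1 <- wsi_decision(labs, decision_thresholds(wsi_positive_count_min = k))$diagnosis
    d2 <- wsi_decision(labs, decision_thresholds(wsi_positive_count_min = k + 1L))$diagnosis
    expect_false(d1 == "non-NPC" && d2 == "NPC")
  }
})

test_that("auto-annotation matches generator ground truth and is stable", {
  neg <- lapply(1:10, function(i)
    render_pair(random_scene(c(48, 48), 0, 2, seed = 100 + i))$target)
  man <- auto_annotate(neg)
  expect_true(all(man$label == 0))
  ds <- make_unpaired_set(2, 60, 0.5, seed = 33, patch_size = 64)
  m1 <- auto_annotate(ds$target)
  m2 <- auto_annotate(ds$target)
  expect_identical(m1, m2)
  expect_gte(mean(m1$label == ds$target_labels), 0.99)
  expect_equal(names(m1), c("path", "label", "largest_component_area"))
})

test_that("channel histograms separate classes on the R channel", {
  p <- make_uniform_patch(c(10, 20, 30), 4, 4)
  h <- channel_histograms(list(p), 0)
  expect_equal(c(h$r_mean, h$g_mean, h$b_mean), c(10, 20, 30))
  negs <- lapply(1:5, function(i)
    render_pair(random_scene(c(64, 64), 0, 3, seed = 200 + i))$target)
  hn <- channel_histograms(negs, rep(0, 5))
  expect_true(all(hn$r_mean > 200))
  # tumour-dominated positive patch (~83% coverage)
  cells <- data.frame(y = c(32, 16, 16, 48, 48), x = c(32, 16, 48, 16, 48),
                      radius = c(28, 15, 15, 15, 15), class = "tumor")
  pos <- render_pair(synthetic_scene(c(64, 64), cells, seed = 3))$target
  hp <- channel_histograms(list(pos), 1)
  expect_lt(hp$r_mean, 100)
  expect_error(channel_histograms(negs, c(0, 1)), class = "eberstain_format_error")
})
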