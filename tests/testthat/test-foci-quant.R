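one_nucleus_scene <- function(spot_at = c(64, 64), snr = 10, seed = 1) {
  # nucleus centred at (64, 64) with radius 30; spot wherever requested
  shape <- c(128, 128)
  yy <- matrix(seq_len(shape[1]), shape[1], shape[2])
  xx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  nuc <- matrix(0L, shape[1], shape[2])
  nuc[((yy - 64) / 30)^2 + ((xx - 64) / 30)^2 <= 1] <- 1L
  img <- matrix(0, shape[1], shape[2])
  if (!is.null(spot_at)) {
    img <- img + 10 * 10 *
      exp(-((yy - spot_at[1])^2 + (xx - spot_at[2])^2) / (2 * 9))
  }
  withr::with_seed(seed, img <- img + rnorm(length(img), 0, 10))
  list(img = img, nuc = nucleoquant:::new_label_mask(nuc))
}

test_that("a constant image produces zero foci with a warning", {
  nuc <- matrix(0L, 64, 64); nuc[20:40, 20:40] <- 1L
  expect_warning(
    tab <- detect_foci(matrix(3, 64, 64), nucleoquant:::new_label_mask(nuc)),
    "zero-variance")
  expect_identical(nrow(tab), 0L)
})

test_that("a single in-nucleus Gaussian spot is found within 1 px", {
  sc <- one_nucleus_scene(spot_at = c(60, 70))
  tab <- detect_foci(sc$img, sc$nuc)
  expect_identical(nrow(tab), 1L)
  expect_lt(abs(tab$centroid_y - 60), 1)
  expect_lt(abs(tab$centroid_x - 70), 1)
  expect_gte(tab$area, 1)
})

test_that("spots outside every nucleus are filtered out", {
  sc <- one_nucleus_scene(spot_at = c(15, 110))  # far outside the nucleus
  tab <- detect_foci(sc$img, sc$nuc)
  expect_identical(nrow(tab), 0L)
})

test_that("detection is invariant under global intensity rescaling", {
  f <- gen_foci_field(4, 3, shape = c(300, 300), seed = 23)
  foci_img <- get_channel(f$stack, "foci")
  nuc <- segment_nuclei(get_channel(f$stack, "dye"))
  t1 <- detect_foci(foci_img, nuc)
  t2 <- detect_foci(foci_img * 41.7, nuc)
  expect_identical(t1[c("nucleus_id", "focus_id", "area",
                        "centroid_y", "centroid_x")],
                   t2[c("nucleus_id", "focus_id", "area",
                        "centroid_y", "centroid_x")])
  expect_equal(t2$mean_intensity, t1$mean_intensity * 41.7)
})

test_that("adding a disjoint above-threshold spot never lowers the count", {
  sc <- one_nucleus_scene(spot_at = c(55, 55))
  base <- nrow(detect_foci(sc$img, sc$nuc))
  yy <- matrix(seq_len(128), 128, 128)
  xx <- matrix(seq_len(128), 128, 128, byrow = TRUE)
  img2 <- sc$img + 100 * exp(-((yy - 75)^2 + (xx - 75)^2) / (2 * 9))
  more <- nrow(detect_foci(img2, sc$nuc))
  expect_gte(more, base)
  expect_identical(more, base + 1L)
})

test_that("connected components match the flood-fill oracle on small rasters", {
  for (seed in 1:4) {
    m <- withr::with_seed(seed, matrix(runif(64 * 64) < 0.25, 64, 64))
    for (conn in c(4, 8)) {
      mine <- nucleoquant:::label_components(m, connectivity = conn)
      orc <- oracle_label(m, connectivity = conn)
      expect_true(same_partition(mine, orc))
    }
  }
  m3 <- withr::with_seed(9, array(runif(16 * 16 * 4) < 0.2, c(16, 16, 4)))
  expect_true(same_partition(
    nucleoquant:::label_components(m3, connectivity = 6),
    oracle_label(m3, connectivity = 6)))
})

test_that("per-nucleus summaries zero-fill nuclei without foci", {
  f <- gen_foci_field(5, 0, shape = c(340, 340), noise_sd = 0, seed = 31)
  nuc <- segment_nuclei(get_channel(f$stack, "dye"))
  expect_warning(
    tab <- detect_foci(get_channel(f$stack, "foci"), nuc),
    "zero-variance")
  s <- summarize_foci(tab, grouping = "ctrl", include_border = TRUE)
  expect_identical(nrow(s$per_nucleus), 5L)
  expect_identical(s$per_nucleus$n_foci, rep(0L, 5))
  expect_identical(s$per_condition$mean_count, 0)
})

test_that("counts are stable when all intensities are doubled", {
  f <- gen_foci_field(6, 4, shape = c(400, 400), seed = 37)
  nuc <- segment_nuclei(get_channel(f$stack, "dye"))
  img <- get_channel(f$stack, "foci")
  s1 <- summarize_foci(detect_foci(img, nuc), include_border = TRUE)
  s2 <- summarize_foci(detect_foci(img * 2, nuc), include_border = TRUE)
  expect_identical(s1$per_nucleus$n_foci, s2$per_nucleus$n_foci)
})

test_that("mean recovered count is accurate across many nuclei", {
  counts <- integer(0)
  for (seed in c(41, 42)) {
    f <- gen_foci_field(10, 5, shape = c(512, 512), snr = 10, seed = seed)
    nuc <- segment_nuclei(get_channel(f$stack, "dye"))
    s <- summarize_foci(detect_foci(get_channel(f$stack, "foci"), nuc),
                        include_border = TRUE)
    counts <- c(counts, s$per_nucleus$n_foci)
  }
  expect_lt(abs(mean(counts) - 5), 0.25)
})

test_that("grouping labels are validated", {
  f <- gen_foci_field(3, 1, shape = c(256, 256), seed = 43)
  nuc <- segment_nuclei(get_channel(f$stack, "dye"))
  tab <- detect_foci(get_channel(f$stack, "foci"), nuc)
  expect_error(summarize_foci(tab, grouping = c("a", "b")), "length")
  expect_error(detect_foci(get_channel(f$stack, "foci"), NULL), "required")
})
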