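test_that("generators are deterministic: identical seeds give identical arrays", {
  a <- gen_foci_field(3, 2, shape = c(256, 256), seed = 11)
  b <- gen_foci_field(3, 2, shape = c(256, 256), seed = 11)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$objects$foci, b$truth$objects$foci)
  c <- gen_foci_field(3, 2, shape = c(256, 256), seed = 12)
  expect_false(identical(a$stack$data, c$stack$data))

  d1 <- gen_droplet_field(5, seed = 3)
  d2 <- gen_droplet_field(5, seed = 3)
  expect_identical(d1$stack$data, d2$stack$data)

  n1 <- gen_null_ratio_dataset(n_cells = 4, n_frames = 4, n_reps = 2, seed = 9)
  n2 <- gen_null_ratio_dataset(n_cells = 4, n_frames = 4, n_reps = 2, seed = 9)
  expect_identical(n1, n2)
})

test_that("zero-foci fields carry zero truth and a pure-noise focus channel", {
  f <- gen_foci_field(4, 0, shape = c(300, 300), noise_sd = 5, seed = 2)
  expect_identical(f$truth$expected$foci_count, rep(0L, 4))
  ch <- get_channel(f$stack, "foci")
  # pure Gaussian noise: mean ~ 0, sd ~ noise_sd
  expect_lt(abs(mean(ch)), 0.5)
  expect_lt(abs(sd(as.vector(ch)) - 5), 0.5)
})

test_that("impossible placements raise errors", {
  expect_error(gen_foci_field(20, 1, shape = c(100, 100), seed = 1),
               "could not place")
  expect_error(gen_droplet_field(4, radius_range = c(60, 80),
                                 shape = c(100, 100), seed = 1),
               "bounds")
})

test_that("timelapse conserves total nuclear intensity before noise", {
  g <- gen_timelapse(n_cells = 3, n_frames = 10, r0 = 1.5, t0 = 4, tau = 2,
                     group = "treated", noise_sd = 0, seed = 5)
  fl1 <- get_channel(g$stack, "gfp", t = 1)
  nuclear <- fl1 > 0
  totals <- vapply(seq_len(10), function(t) {
    sum(get_channel(g$stack, "gfp", t = t)[nuclear])
  }, numeric(1))
  expect_lt(max(abs(totals - totals[1])) / totals[1], 1e-6)
})

test_that("timelapse ratio truth follows the exponential depletion model", {
  g <- gen_timelapse(n_cells = 2, n_frames = 12, r0 = 1.4, t0 = 6, tau = 3,
                     group = "treated", seed = 8)
  r <- g$truth$expected$ratio
  one_cell <- r[r$cell_id == 1 & r$nucleolus_id == 1, ]
  expect_equal(one_cell$ratio[one_cell$frame <= 6], rep(1.4, 6))
  expect_equal(one_cell$ratio[one_cell$frame == 9],
               1 + 0.4 * exp(-3 / 3))
  # control stays flat; the treated limit is full depletion (ratio -> 1)
  gc <- gen_timelapse(n_cells = 2, n_frames = 12, r0 = 1.4, group = "control",
                      seed = 8)
  expect_true(all(gc$truth$expected$ratio$ratio == 1.4))
  expect_equal(ratio_profile(1e6, 1.4, 6, 3, "treated"), 1, tolerance = 1e-12)
  expect_error(gen_timelapse(2, 5, r0 = 0.8, seed = 1), "r0")
})

test_that("droplet truth matches the closed-form disk area", {
  d <- gen_droplet_field(1, radius_range = c(20, 20), shape = c(512, 512),
                         noise_sd = 0, seed = 6)
  expect_equal(d$truth$expected$condensed_fraction_analytic,
               pi * 400 / 512^2, tolerance = 1e-12)
  # rasterised truth within 2% of the analytic disk area
  expect_equal(d$truth$expected$condensed_fraction,
               pi * 400 / 512^2, tolerance = 0.02)
  d0 <- gen_droplet_field(0, seed = 1)
  expect_identical(d0$truth$expected$condensed_fraction, 0)
})

test_that("truth metrics agree with an independent paint-and-measure oracle", {
  f <- gen_fc_eu_field(n_cells = 3, fc_per_cell = 2, eu_fc_level = 80,
                       eu_nucleoplasm_level = 30, noise_sd = 0, seed = 13)
  eu <- get_channel(f$stack, "eu", drop = FALSE)
  fcv <- f$truth$objects$fc_voxels
  measured <- mean(eu[fcv])
  expect_equal(measured, 80, tolerance = 0.01)
  # per-cell oracle via the recorded nucleus labels
  labs <- f$truth$objects$nucleus_labels
  for (cid in 1:3) {
    expect_equal(mean(eu[fcv & labs == cid]),
                 f$truth$expected$eu_fc_mean[cid], tolerance = 0.01)
  }
})

test_that("EU field rejects negative levels and allows zero FCs", {
  expect_error(gen_fc_eu_field(2, 2, eu_fc_level = -1, seed = 1), "negative")
  f <- gen_fc_eu_field(2, 0, shape = c(128, 128, 5), seed = 1)
  expect_identical(sum(f$truth$objects$fc_voxels), 0L)
})

test_that("null ratio data reject degenerate inputs and flag zero noise", {
  expect_error(gen_null_ratio_dataset(n_cells = 4, n_frames = 1, seed = 1),
               "n_frames")
  expect_warning(gen_null_ratio_dataset(n_cells = 4, n_frames = 4,
                                        noise_sd = 0, seed = 1),
                 "degenerate")
})
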