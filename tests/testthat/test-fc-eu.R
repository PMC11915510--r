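fc_scene <- function(seed = 7, n_cells = 3, fc_per_cell = 3,
                     eu_fc = 100, eu_np = 40, noise_sd = 5) {
  f <- gen_fc_eu_field(n_cells = n_cells, fc_per_cell = fc_per_cell,
                       eu_fc_level = eu_fc, eu_nucleoplasm_level = eu_np,
                       shape = c(160, 160, 9), noise_sd = noise_sd,
                       seed = seed)
  nuc <- segment_nuclei(get_channel(f$stack, "dye", drop = FALSE))
  list(f = f, nuc = nuc,
       ubf = get_channel(f$stack, "ubf", drop = FALSE),
       fib = get_channel(f$stack, "fib", drop = FALSE),
       eu = get_channel(f$stack, "eu", drop = FALSE))
}

test_that("uniform fibrillarin gives a degenerate Otsu and an empty DFC", {
  nuc <- array(0L, c(32, 32, 3)); nuc[10:20, 10:20, ] <- 1L
  fib <- array(50, c(32, 32, 3))
  expect_warning(dfc <- segment_dfc(fib, nucleoquant:::new_label_mask(nuc)),
                 "degenerate")
  expect_false(any(dfc))
  expect_error(segment_dfc(fib, nucleoquant:::new_label_mask(array(0L, c(32, 32, 3)))),
               "empty")
})

test_that("DFC volume is recovered within 10% and stays inside nuclei", {
  sc <- fc_scene(seed = 19)
  dfc <- segment_dfc(sc$fib, sc$nuc)
  truth_vol <- sc$f$truth$expected$dfc_volume
  expect_lt(abs(sum(dfc) - truth_vol) / truth_vol, 0.10)
  expect_false(any(dfc & unclass(sc$nuc) == 0L))
})

test_that("uniform UBF yields no fibrillar centres", {
  sc <- fc_scene(seed = 20)
  dfc <- segment_dfc(sc$fib, sc$nuc)
  flat_ubf <- array(30, dim(sc$ubf))
  expect_warning(fc <- detect_fc(flat_ubf, dfc, sc$nuc), "maxima")
  expect_identical(max(fc), 0L)
})

test_that("the programmed FC count per cell is recovered exactly", {
  sc <- fc_scene(seed = 21)
  dfc <- segment_dfc(sc$fib, sc$nuc)
  fc <- detect_fc(sc$ubf, dfc, sc$nuc)
  per_cell <- table(attr(fc, "fc_cells")$cell_id)
  expect_identical(as.integer(per_cell), rep(3L, 3))
})

test_that("the containment chain FC within DFC within nucleus holds voxelwise", {
  for (seed in c(22, 23)) {
    sc <- fc_scene(seed = seed)
    dfc <- segment_dfc(sc$fib, sc$nuc)
    fc <- detect_fc(sc$ubf, dfc, sc$nuc)
    expect_false(any(fc > 0L & !dfc))
    expect_false(any(dfc & unclass(sc$nuc) == 0L))
  }
})

test_that("watershed label count equals surviving seed count", {
  # 1D-profile phantom: two bright peaks separated by a dim saddle
  prof <- c(10, 10, 60, 90, 60, 45, 60, 90, 60, 10, 10)
  img <- array(10, c(11, 11, 3))
  img[, , 2] <- matrix(rep(prof, each = 11), 11, 11)
  seeds <- array(0L, dim(img))
  seeds[6, 4, 2] <- 1L; seeds[6, 8, 2] <- 2L
  mask <- img > 40
  ws <- nucleoquant:::seeded_watershed(img, seeds, mask)
  expect_identical(sort(unique(ws[ws > 0L])), c(1L, 2L))
  # both peaks keep their own basin: saddle splits the two labels
  expect_identical(ws[6, 4, 2], 1L)
  expect_identical(ws[6, 8, 2], 2L)
  expect_true(all(ws[img <= 40] == 0L))
})

test_that("EU measurement reports the channel mean inside FCs", {
  sc <- fc_scene(seed = 24)
  dfc <- segment_dfc(sc$fib, sc$nuc)
  fc <- detect_fc(sc$ubf, dfc, sc$nuc)
  const <- array(42, dim(sc$eu))
  m <- measure_eu(const, fc, sc$nuc)
  expect_true(all(abs(m$mean_eu_in_fc - 42) < 1e-12))
  # with noise sigma 5 and hundreds of FC voxels, the mean is within 1 a.u.
  m2 <- measure_eu(sc$eu, fc, sc$nuc)
  expect_true(all(abs(m2$mean_eu_in_fc - 100) < 1))
})

test_that("cells without FCs propagate missing values, not zeros", {
  sc <- fc_scene(seed = 25)
  dfc <- segment_dfc(sc$fib, sc$nuc)
  fc <- detect_fc(sc$ubf, dfc, sc$nuc)
  # drop cell 2's FCs from the map to simulate a zero-FC cell
  map <- attr(fc, "fc_cells")
  fc2 <- fc
  fc2[fc2 %in% map$fc_id[map$cell_id == 2]] <- 0L
  attr(fc2, "fc_cells") <- map[map$cell_id != 2, ]
  m <- measure_eu(sc$eu, fc2, sc$nuc, group = "x")
  expect_true(is.na(m$mean_eu_in_fc[m$cell_id == 2]))
  expect_identical(m$n_fc[m$cell_id == 2], 0L)
  norm <- normalize_to_control(m, "x")
  expect_false(any(is.na(norm$normalized[norm$cell_id != 2])))
})

test_that("normalisation maps the control mean to 1 and is scale-free", {
  rows <- tibble::tibble(cell_id = 1:6, n_fc = 1L,
                         mean_eu_in_fc = c(90, 100, 110, 55, 60, 65),
                         group = rep(c("ctrl", "drug"), each = 3))
  norm <- normalize_to_control(rows, "ctrl")
  expect_equal(mean(norm$normalized[norm$group == "ctrl"]), 1)
  expect_equal(mean(norm$normalized[norm$group == "drug"]), 0.6)
  rows2 <- rows; rows2$mean_eu_in_fc <- rows$mean_eu_in_fc * 3.7
  expect_equal(normalize_to_control(rows2, "ctrl")$normalized,
               norm$normalized)
  expect_error(normalize_to_control(rows, "nope"), "control")
  # all equal values normalise to exactly 1
  rows3 <- rows; rows3$mean_eu_in_fc <- 80
  expect_true(all(normalize_to_control(rows3, "ctrl")$normalized == 1))
})

test_that("a programmed EU reduction survives the full pipeline", {
  run_group <- function(level, seeds) {
    out <- list()
    for (s in seeds) {
      sc <- fc_scene(seed = s, n_cells = 3, eu_fc = level)
      dfc <- segment_dfc(sc$fib, sc$nuc)
      fc <- detect_fc(sc$ubf, dfc, sc$nuc)
      out[[length(out) + 1]] <- measure_eu(sc$eu, fc, sc$nuc)
    }
    dplyr::bind_rows(out)
  }
  ctrl <- run_group(100, c(31, 32)); ctrl$group <- "ctrl"
  drug <- run_group(60, c(33, 34)); drug$group <- "drug"
  norm <- normalize_to_control(dplyr::bind_rows(ctrl, drug), "ctrl")
  reduction <- (1 - mean(norm$normalized[norm$group == "drug"])) * 100
  expect_lt(abs(reduction - 40), 5)
})
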