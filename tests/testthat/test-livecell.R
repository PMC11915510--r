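test_that("phase-contrast nucleolus detection finds dark disks", {
  shape <- c(96, 96)
  yy <- matrix(seq_len(shape[1]), shape[1], shape[2])
  xx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  nuc <- matrix(0L, shape[1], shape[2])
  nuc[((yy - 48) / 36)^2 + ((xx - 48) / 36)^2 <= 1] <- 1L
  ph <- matrix(100, shape[1], shape[2])
  ph[nuc == 1L] <- 130
  disk <- ((yy - 48) / 9)^2 + ((xx - 48) / 9)^2 <= 1
  ph[disk] <- 60
  lab <- detect_nucleoli_phase(ph, nucleoquant:::new_label_mask(nuc))
  expect_identical(max(lab), 1L)
  expect_lt(abs(sum(lab > 0) - sum(disk)) / sum(disk), 0.10)
  # two disks, both mapped to the same parent nucleus
  ph2 <- matrix(100, shape[1], shape[2]); ph2[nuc == 1L] <- 130
  d1 <- ((yy - 40) / 7)^2 + ((xx - 35) / 7)^2 <= 1
  d2 <- ((yy - 58) / 7)^2 + ((xx - 62) / 7)^2 <= 1
  ph2[d1 | d2] <- 60
  lab2 <- detect_nucleoli_phase(ph2, nucleoquant:::new_label_mask(nuc))
  expect_identical(max(lab2), 2L)
  expect_identical(attr(lab2, "parents")$nucleus_id, c(1L, 1L))
})

test_that("a uniform nucleus yields no nucleoli", {
  nuc <- matrix(0L, 64, 64); nuc[16:48, 16:48] <- 1L
  ph <- matrix(100, 64, 64); ph[nuc == 1L] <- 130
  lab <- detect_nucleoli_phase(ph, nucleoquant:::new_label_mask(nuc))
  expect_identical(max(lab), 0L)
})

test_that("object exclusion drops collapsing cells and nothing else", {
  obj <- tidyr::crossing(cell_id = 1:4, frame = 1:5)
  obj$area <- 900
  obj$area[obj$cell_id == 3 & obj$frame >= 4] <- 300  # dying: area collapse
  kept <- exclude_objects(obj)
  expect_false(3 %in% kept$cell_id)
  expect_identical(sort(unique(kept$cell_id)), c(1L, 2L, 4L))
  expect_identical(attr(kept, "excluded")$reason, "area_collapse")
  # rows of surviving cells are untouched
  expect_equal(kept[kept$cell_id == 1, ], obj[obj$cell_id == 1, ],
               ignore_attr = TRUE)
  # all-clean input: identity
  clean <- exclude_objects(obj[obj$cell_id != 3, ])
  expect_identical(nrow(attr(clean, "excluded")), 0L)
})

test_that("uniform nuclear fluorescence gives ratio 1 at every frame", {
  shape <- c(64, 64)
  nuc <- matrix(0L, shape[1], shape[2]); nuc[10:50, 10:50] <- 1L
  nucl <- matrix(0L, shape[1], shape[2]); nucl[25:35, 25:35] <- 1L
  fl <- matrix(0, shape[1], shape[2]); fl[nuc == 1L] <- 77
  rs <- ratio_timeseries(list(fl, fl), list(nuc, nuc), list(nucl, nucl))
  expect_equal(rs$ratio, rep(1, 2))
  # invariance under per-frame linear rescaling
  rs2 <- ratio_timeseries(list(fl * 3, fl * 12), list(nuc, nuc),
                          list(nucl, nucl))
  expect_equal(rs2$ratio, rs$ratio)
})

test_that("the measured ratio tracks the programmed enrichment", {
  g <- gen_timelapse(n_cells = 3, n_frames = 6, r0 = 1.4, group = "control",
                     seed = 51)
  rs <- livecell_pipeline(g$stack, group = "control")
  expect_equal(mean(rs$ratio), 1.4, tolerance = 0.02)
  expect_identical(length(unique(rs$cell_id)), 3L)
})

test_that("the RM-ANOVA table reproduces hand-computed sums of squares", {
  # 2 groups x 2 subjects x 2 frames, worked by direct SS arithmetic:
  # SS_group = 10.125, SS_subj = 0.25, SS_time = 1.125, SS_int = 0.125,
  # SS_err = 1.25  =>  F_group = 81, F_time = 1.8, F_int = 0.2
  dat <- tibble::tibble(
    cell_id = rep(c("A1", "A2", "B1", "B2"), each = 2),
    nucleolus_id = 1L,
    frame = rep(1:2, 4),
    ratio = c(1, 2, 2, 2, 3, 5, 4, 4),
    group = rep(c("A", "B"), each = 4))
  fit <- rm_anova_onset(dat)
  an <- fit$anova
  expect_equal(an$sumsq, c(10.125, 0.25, 1.125, 0.125, 1.25))
  expect_equal(an$statistic[an$term == "group"], 81)
  expect_equal(an$statistic[an$term == "time"], 1.8)
  expect_equal(an$statistic[an$term == "time:group"], 0.2)
})

test_that("the RM-ANOVA agrees with aov on balanced and unbalanced designs", {
  check_against_aov <- function(dat) {
    fit <- rm_anova_onset(dat)
    a <- summary(stats::aov(ratio ~ group * factor(frame) +
                              Error(factor(cell_id)), data = dat))
    btw <- a[["Error: factor(cell_id)"]][[1]]
    wth <- a[["Error: Within"]][[1]]
    an <- fit$anova
    expect_equal(an$statistic[an$term == "group"], btw[["F value"]][1])
    expect_equal(an$p.value[an$term == "group"], btw[["Pr(>F)"]][1])
    expect_equal(an$statistic[an$term == "time"], wth[["F value"]][1])
    expect_equal(an$statistic[an$term == "time:group"], wth[["F value"]][2])
    expect_equal(an$p.value[an$term == "time:group"], wth[["Pr(>F)"]][2])
  }
  bal <- gen_null_ratio_dataset(n_cells = 6, n_frames = 5, seed = 61)[[1]]
  check_against_aov(bal)
  unbal <- bal[!(bal$cell_id %in% c("treated_5", "treated_6")), ]
  check_against_aov(unbal)
})

test_that("Tukey contrasts match stats::TukeyHSD per frame", {
  dat <- gen_null_ratio_dataset(n_cells = 8, n_frames = 3, seed = 67)[[1]]
  fit <- rm_anova_onset(dat)
  for (fr in 1:3) {
    d <- dat[dat$frame == fr, ]
    tk <- stats::TukeyHSD(stats::aov(ratio ~ group, data = d))$group
    mine <- fit$contrasts[fit$contrasts$frame == fr, ]
    expect_equal(mine$estimate, tk[, "diff"], ignore_attr = TRUE)
    expect_equal(mine$adj.p.value, tk[, "p adj"], ignore_attr = TRUE,
                 tolerance = 1e-6)
  }
})

test_that("identical groups by construction produce no onset call", {
  base <- gen_null_ratio_dataset(n_cells = 5, n_frames = 4, seed = 71)[[1]]
  ctrl <- base[base$group == "control", ]
  fake <- ctrl; fake$group <- "treated"; fake$cell_id <- paste0("t", fake$cell_id)
  fit <- rm_anova_onset(dplyr::bind_rows(ctrl, fake))
  expect_true(is.na(fit$first_significant))
  expect_equal(fit$anova$statistic[fit$anova$term == "group"], 0)
})

test_that("incomplete tracks are dropped and counted", {
  dat <- gen_null_ratio_dataset(n_cells = 5, n_frames = 4, seed = 73)[[1]]
  dat$ratio[dat$cell_id == "control_2" & dat$frame == 3] <- NA
  fit <- rm_anova_onset(dat)
  expect_identical(fit$n_dropped, 1L)
  expect_identical(fit$n_subjects, 9L)
  small <- dat[dat$cell_id %in% c("control_1", "treated_1", "treated_2"), ]
  expect_error(rm_anova_onset(small), "at least 2")
})

test_that("greenhouse-geisser correction shrinks within-subject df", {
  dat <- gen_null_ratio_dataset(n_cells = 8, n_frames = 5, seed = 79)[[1]]
  f0 <- rm_anova_onset(dat)
  f1 <- rm_anova_onset(dat, sphericity = "greenhouse-geisser")
  expect_lte(f1$epsilon, 1)
  expect_gte(f1$epsilon, 1 / 4)
  expect_equal(f0$anova$statistic[1], f1$anova$statistic[1])  # F unchanged
  # the correction only rescales degrees of freedom
  expect_equal(f1$anova$df[f1$anova$term == "time"],
               f0$anova$df[f0$anova$term == "time"] * f1$epsilon)
})

test_that("tidiers expose the effect table and onset summary", {
  dat <- gen_null_ratio_dataset(n_cells = 5, n_frames = 4, seed = 83)[[1]]
  fit <- rm_anova_onset(dat)
  td <- generics::tidy(fit)
  expect_identical(td$term[1], "group")
  gl <- generics::glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(all(c("p_interaction", "first_significant") %in% names(gl)))
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
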