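# Synthetic microscopy scenes with closed-form ground truth.
#
# Every generator takes an explicit `seed` and is deterministic: the same
# seed yields byte-identical arrays. Geometry is recorded in a `scene_truth`
# object whose expected metrics are computable from the object parameters
# alone, so downstream pipelines can be validated without real data.

new_scene_truth <- function(objects, expected, seed, noise) {
  structure(list(objects = objects, expected = expected,
                 seed = seed, noise = noise),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat("<scene_truth> seed", x$seed, "\n")
  cat("  objects:", paste(names(x$objects), collapse = ", "), "\n")
  cat("  expected:", paste(names(x$expected), collapse = ", "), "\n")
  invisible(x)
}

# Rejection-sample n non-overlapping ellipse centres in a ny x nx field.
place_ellipses <- function(n, shape, ry_range, rx_range, gap = 4,
                           margin = 2, max_tries = 5000L) {
  if (n == 0L) {
    return(tibble(id = integer(), cy = numeric(), cx = numeric(),
                  ry = numeric(), rx = numeric()))
  }
  ny <- shape[1]; nx <- shape[2]
  out <- matrix(NA_real_, n, 4)
  tries <- 0L
  i <- 1L
  while (i <= n) {
    tries <- tries + 1L
    if (tries > max_tries)
      abort(sprintf("could not place %d objects in a %dx%d field", n, ny, nx))
    ry <- runif(1, ry_range[1], ry_range[2])
    rx <- runif(1, rx_range[1], rx_range[2])
    r <- max(ry, rx)
    cy <- runif(1, r + margin, ny - r - margin)
    cx <- runif(1, r + margin, nx - r - margin)
    if (cy < r + margin || cy > ny - r - margin) next
    if (i > 1L) {
      prev <- out[seq_len(i - 1L), , drop = FALSE]
      dd <- sqrt((prev[, 1] - cy)^2 + (prev[, 2] - cx)^2)
      if (any(dd < r + pmax(prev[, 3], prev[, 4]) + gap)) next
    }
    out[i, ] <- c(cy, cx, ry, rx)
    i <- i + 1L
  }
  tibble(id = seq_len(n), cy = out[, 1], cx = out[, 2],
         ry = out[, 3], rx = out[, 4])
}

ellipse_mask <- function(shape, cy, cx, ry, rx) {
  yy <- matrix(seq_len(shape[1]), shape[1], shape[2])
  xx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
}

# Normalised squared elliptical radius (0 at centre, 1 on the boundary).
ellipse_r2 <- function(shape, cy, cx, ry, rx) {
  yy <- matrix(seq_len(shape[1]), shape[1], shape[2])
  xx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2
}

ellipsoid_mask <- function(shape3, cy, cx, cz, ry, rx, rz) {
  d <- shape3
  yy <- array(seq_len(d[1]), d)
  xx <- aperm(array(seq_len(d[2]), d[c(2, 1, 3)]), c(2, 1, 3))
  zz <- aperm(array(seq_len(d[3]), d[c(3, 1, 2)]), c(2, 3, 1))
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 + ((zz - cz) / rz)^2 <= 1
}

# Sample k points inside an ellipse (shrunk by `shrink`), pairwise at least
# `min_sep` apart.
sample_points_in_ellipse <- function(k, cy, cx, ry, rx, shrink = 0.7,
                                     min_sep = 0, max_tries = 5000L) {
  if (k == 0L) return(matrix(numeric(), 0, 2))
  pts <- matrix(NA_real_, k, 2)
  i <- 1L; tries <- 0L
  while (i <= k) {
    tries <- tries + 1L
    if (tries > max_tries)
      abort(sprintf("could not place %d separated points inside the nucleus", k))
    th <- runif(1, 0, 2 * pi)
    u <- sqrt(runif(1))
    py <- cy + u * shrink * ry * sin(th)
    px <- cx + u * shrink * rx * cos(th)
    if (i > 1L) {
      prev <- pts[seq_len(i - 1L), , drop = FALSE]
      if (any(sqrt((prev[, 1] - py)^2 + (prev[, 2] - px)^2) < min_sep)) next
    }
    pts[i, ] <- c(py, px)
    i <- i + 1L
  }
  pts
}

add_gaussian_spot <- function(img, cy, cx, amplitude, sigma) {
  r <- ceiling(4 * sigma)
  ys <- max(1, floor(cy - r)):min(nrow(img), ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(ncol(img), ceiling(cx + r))
  g <- outer(ys, xs, function(y, x)
    amplitude * exp(-((y - cy)^2 + (x - cx)^2) / (2 * sigma^2)))
  img[ys, xs] <- img[ys, xs] + g
  img
}

#' Synthetic field of nuclei with DNA-damage-like foci
#'
#' Renders a nuclear-dye channel (smoothly shaded ellipses) and a focus
#' channel containing isotropic Gaussian spots at known positions inside
#' each nucleus, over additive Gaussian noise. The signal-to-noise ratio is
#' defined as spot amplitude divided by the noise standard deviation. Spots
#' within one nucleus are kept at least `5 * spot_sigma` apart so that the
#' programmed per-nucleus count is resolvable by a spot detector.
#'
#' @param n_nuclei Number of nuclei.
#' @param foci_per_nucleus Single count or per-nucleus integer vector.
#' @param spot_sigma Gaussian spot sigma in pixels.
#' @param snr Spot amplitude / noise sigma.
#' @param shape Field size `c(ny, nx)` in pixels.
#' @param noise_sd Noise standard deviation (a.u.).
#' @param nucleus_radius Range of nuclear semi-axes in pixels.
#' @param poisson Add Poisson (shot) noise on top of the rendered signal.
#' @param seed Integer RNG seed.
#' @return A list with `stack` (channels `dye`, `foci`) and `truth`
#'   (a `scene_truth` whose `expected$foci_count` gives per-nucleus counts).
#' @export
gen_foci_field <- function(n_nuclei, foci_per_nucleus, spot_sigma = 3,
                           snr = 10, shape = c(512, 512), noise_sd = 10,
                           nucleus_radius = c(24, 30), poisson = FALSE,
                           seed = 1L) {
  stopifnot(n_nuclei >= 0, spot_sigma > 0, snr >= 0, noise_sd >= 0)
  k <- rep_len(as.integer(foci_per_nucleus), max(n_nuclei, 1L))
  with_seed_(seed, {
    nuclei <- place_ellipses(n_nuclei, shape, nucleus_radius, nucleus_radius,
                             gap = 6)
    dye <- matrix(0, shape[1], shape[2])
    foci_img <- matrix(0, shape[1], shape[2])
    spots <- list()
    for (i in seq_len(n_nuclei)) {
      nc <- nuclei[i, ]
      r2 <- ellipse_r2(shape, nc$cy, nc$cx, nc$ry, nc$rx)
      inside <- r2 <= 1
      dye[inside] <- dye[inside] + 200 * (1.05 - 0.25 * r2[inside])
      if (k[i] > 0L) {
        pts <- sample_points_in_ellipse(k[i], nc$cy, nc$cx, nc$ry, nc$rx,
                                        shrink = 0.7, min_sep = 4 * spot_sigma,
                                        max_tries = 20000L)
        for (j in seq_len(k[i])) {
          foci_img <- add_gaussian_spot(foci_img, pts[j, 1], pts[j, 2],
                                        snr * noise_sd, spot_sigma)
        }
        spots[[i]] <- tibble(nucleus_id = i, focus_id = seq_len(k[i]),
                             cy = pts[, 1], cx = pts[, 2],
                             amplitude = snr * noise_sd, sigma = spot_sigma)
      }
    }
    if (poisson) {
      dye <- dye + (stats::rpois(length(dye), pmax(dye, 0)) - pmax(dye, 0))
      foci_img <- foci_img +
        (stats::rpois(length(foci_img), pmax(foci_img, 0)) - pmax(foci_img, 0))
    }
    dye <- dye + rnorm(length(dye), 0, noise_sd)
    foci_img <- foci_img + rnorm(length(foci_img), 0, noise_sd)
    stack <- image_stack(array(c(dye, foci_img), c(shape[1], shape[2], 1, 2)),
                         channels = c("dye", "foci"))
    truth <- new_scene_truth(
      objects = list(nuclei = nuclei,
                     foci = if (length(spots)) dplyr::bind_rows(spots) else
                       tibble(nucleus_id = integer(), focus_id = integer(),
                              cy = numeric(), cx = numeric(),
                              amplitude = numeric(), sigma = numeric())),
      expected = list(foci_count = if (n_nuclei > 0) k[seq_len(n_nuclei)] else integer()),
      seed = seed,
      noise = list(sd = noise_sd, poisson = poisson)
    )
    list(stack = stack, truth = truth)
  })
}

#' Synthetic 3D nuclei with nested DFC/FC bodies and an EU channel
#'
#' Builds a four-channel z-stack emulating nucleolar substructure: a
#' nuclear-dye channel (`dye`), a UBF-like channel bright in fibrillar
#' centres (`ubf`), a fibrillarin-like channel bright in the dense fibrillar
#' component (`fib`), and a nascent-RNA channel (`eu`) whose mean intensity
#' inside true FC voxels is programmable per cell.
#'
#' @param n_cells Number of nuclei.
#' @param fc_per_cell FC bodies per cell (each nested in its own DFC body).
#' @param eu_fc_level Mean EU intensity inside FC voxels (a.u.).
#' @param eu_nucleoplasm_level Mean EU intensity elsewhere in the nucleus.
#' @param shape Volume size `c(ny, nx, nz)` in voxels.
#' @param noise_sd Gaussian noise sigma (a.u.).
#' @param seed Integer RNG seed.
#' @return A list with `stack` (4 channels, z-stacked) and `truth`; the
#'   truth records per-cell FC centres and `expected$eu_fc_mean`.
#' @export
gen_fc_eu_field <- function(n_cells = 6, fc_per_cell = 3, eu_fc_level = 100,
                            eu_nucleoplasm_level = 40,
                            shape = c(192, 192, 9), noise_sd = 5, seed = 1L) {
  if (eu_fc_level < 0 || eu_nucleoplasm_level < 0)
    abort("EU levels must be non-negative")
  stopifnot(n_cells >= 0, fc_per_cell >= 0)
  nz <- shape[3]
  with_seed_(seed, {
    nuclei <- place_ellipses(n_cells, shape[1:2], c(22, 27), c(22, 27), gap = 6)
    d3 <- shape[c(1, 2, 3)]
    dye <- array(0, d3); ubf <- array(0, d3); fib <- array(0, d3); eu <- array(0, d3)
    cz <- (nz + 1) / 2
    rz_nuc <- max(nz * 0.45, 1.2)
    fc_list <- list()
    nuc_lab <- array(0L, d3)
    fc_vox <- array(FALSE, d3)
    dfc_vox <- array(FALSE, d3)
    for (i in seq_len(n_cells)) {
      nc <- nuclei[i, ]
      nmask <- ellipsoid_mask(d3, nc$cy, nc$cx, cz, nc$ry, nc$rx, rz_nuc)
      nuc_lab[nmask] <- i
      dye[nmask] <- 150
      if (fc_per_cell > 0L) {
        pts <- sample_points_in_ellipse(fc_per_cell, nc$cy, nc$cx,
                                        nc$ry, nc$rx, shrink = 0.65,
                                        min_sep = 15, max_tries = 50000L)
        for (j in seq_len(fc_per_cell)) {
          dm <- ellipsoid_mask(d3, pts[j, 1], pts[j, 2], cz, 7, 7, 2.4) & nmask
          fm <- ellipsoid_mask(d3, pts[j, 1], pts[j, 2], cz, 3, 3, 1.2) & nmask
          dfc_vox <- dfc_vox | dm
          fc_vox <- fc_vox | fm
          fc_list[[length(fc_list) + 1L]] <-
            tibble(cell_id = i, fc_id = j, cy = pts[j, 1], cx = pts[j, 2], cz = cz)
        }
      }
    }
    innuc <- nuc_lab > 0L
    fib[innuc] <- 10; fib[dfc_vox] <- 120
    ubf[innuc] <- 15; ubf[fc_vox] <- 150
    eu[innuc] <- eu_nucleoplasm_level; eu[fc_vox] <- eu_fc_level
    dye <- dye + rnorm(length(dye), 0, noise_sd)
    ubf <- ubf + rnorm(length(ubf), 0, noise_sd)
    fib <- fib + rnorm(length(fib), 0, noise_sd)
    eu <- eu + rnorm(length(eu), 0, noise_sd)
    a <- array(0, c(d3[1], d3[2], d3[3], 4))
    a[, , , 1] <- dye; a[, , , 2] <- ubf; a[, , , 3] <- fib; a[, , , 4] <- eu
    stack <- image_stack(a, channels = c("dye", "ubf", "fib", "eu"),
                         z_step = 0.5)
    truth <- new_scene_truth(
      objects = list(
        nuclei = nuclei,
        fc = if (length(fc_list)) dplyr::bind_rows(fc_list) else
          tibble(cell_id = integer(), fc_id = integer(),
                 cy = numeric(), cx = numeric(), cz = numeric()),
        nucleus_labels = nuc_lab, fc_voxels = fc_vox, dfc_voxels = dfc_vox
      ),
      expected = list(eu_fc_mean = rep(eu_fc_level, n_cells),
                      fc_count = rep(fc_per_cell, n_cells),
                      dfc_volume = sum(dfc_vox)),
      seed = seed, noise = list(sd = noise_sd, poisson = FALSE)
    )
    list(stack = stack, truth = truth)
  })
}

ratio_profile <- function(frames, r0, t0, tau, group) {
  if (group == "control") return(rep(r0, length(frames)))
  ifelse(frames < t0, r0, 1 + (r0 - 1) * exp(-(frames - t0) / tau))
}

#' Synthetic nucleolar-depletion time-lapse
#'
#' Renders a fluorescence channel (`gfp`) and a phase-contrast-like channel
#' (`phase`, nucleoli as dark disks on a brighter nucleoplasm) for cells
#' whose nucleolus-to-nucleoplasm intensity ratio follows
#' `r(t) = 1 + (r0 - 1) * exp(-(t - t0)/tau)` after the programmed onset
#' frame `t0` (treated group) or stays at `r0` (control). The total nuclear
#' integrated fluorescence of each cell is held constant across frames
#' before noise: signal redistributes from the nucleolus to the
#' nucleoplasm, it does not disappear.
#'
#' @param n_cells Number of cells.
#' @param n_frames Number of frames.
#' @param r0 Baseline nucleolus/nucleoplasm ratio (must be >= 1).
#' @param t0 Onset frame (treated group).
#' @param tau Exponential decay constant in frames.
#' @param group `"control"` or `"treated"`.
#' @param nucleoli_per_cell Nucleoli per nucleus (1 or 2 typical).
#' @param shape Frame size `c(ny, nx)`.
#' @param frame_interval_min Minutes between frames (metadata only).
#' @param noise_sd Gaussian noise sigma (a.u.).
#' @param seed Integer RNG seed.
#' @return A list with `stack` (channels `gfp`, `phase`; time axis) and
#'   `truth` (`expected$ratio` is a tibble of per-nucleolus true ratios).
#' @export
gen_timelapse <- function(n_cells = 6, n_frames = 48, r0 = 1.4, t0 = 36,
                          tau = 10, group = c("treated", "control"),
                          nucleoli_per_cell = 1L, shape = c(256, 256),
                          frame_interval_min = 5, noise_sd = 2, seed = 1L) {
  group <- match.arg(group)
  if (r0 < 1) abort("r0 must be >= 1 (nucleolar enrichment assumed)")
  stopifnot(n_frames >= 1, n_cells >= 0)
  with_seed_(seed, {
    nuclei <- place_ellipses(n_cells, shape, c(24, 30), c(24, 30), gap = 6)
    nuc_masks <- list(); nucl_masks <- list()
    nucl_tab <- list()
    for (i in seq_len(n_cells)) {
      nc <- nuclei[i, ]
      nuc_masks[[i]] <- ellipse_mask(shape, nc$cy, nc$cx, nc$ry, nc$rx)
      pts <- sample_points_in_ellipse(nucleoli_per_cell, nc$cy, nc$cx,
                                      nc$ry, nc$rx, shrink = 0.45,
                                      min_sep = 22)
      ms <- vector("list", nucleoli_per_cell)
      for (j in seq_len(nucleoli_per_cell)) {
        rr <- runif(1, 7, 9)
        ms[[j]] <- ellipse_mask(shape, pts[j, 1], pts[j, 2], rr, rr)
        nucl_tab[[length(nucl_tab) + 1L]] <-
          tibble(cell_id = i, nucleolus_id = j,
                 cy = pts[j, 1], cx = pts[j, 2], radius = rr)
      }
      nucl_masks[[i]] <- ms
    }
    frames <- seq_len(n_frames)
    rtruth <- ratio_profile(frames, r0, t0, tau, group)
    a <- array(0, c(shape[1], shape[2], 1, 2, n_frames))
    a0 <- 100  # baseline nucleoplasm intensity at frame 1
    cell_geo <- lapply(seq_len(n_cells), function(i) {
      numask <- Reduce(`|`, nucl_masks[[i]])
      npmask <- nuc_masks[[i]] & !numask
      list(numask = numask, npmask = npmask,
           A_nu = sum(numask), A_np = sum(npmask),
           total = sum(npmask) * a0 + sum(numask) * a0 * r0)
    })
    for (t in frames) {
      fl <- matrix(0, shape[1], shape[2])
      ph <- matrix(100, shape[1], shape[2])  # phase background
      rt <- rtruth[t]
      for (i in seq_len(n_cells)) {
        g <- cell_geo[[i]]
        at <- g$total / (g$A_np + g$A_nu * rt)
        fl[g$npmask] <- at
        fl[g$numask] <- rt * at
        ph[nuc_masks[[i]]] <- 130
        ph[g$numask] <- 60
      }
      a[, , 1, 1, t] <- fl
      a[, , 1, 2, t] <- ph
    }
    a <- a + rnorm(length(a), 0, noise_sd)
    stack <- image_stack(a, channels = c("gfp", "phase"), has_t = TRUE)
    truth_ratio <- tidyr::crossing(
      dplyr::bind_rows(nucl_tab)[, c("cell_id", "nucleolus_id")],
      tibble(frame = frames)
    )
    truth_ratio$ratio <- rtruth[truth_ratio$frame]
    truth_ratio$group <- group
    truth <- new_scene_truth(
      objects = list(nuclei = nuclei,
                     nucleoli = dplyr::bind_rows(nucl_tab)),
      expected = list(ratio = truth_ratio, r0 = r0, t0 = t0, tau = tau,
                      frame_interval_min = frame_interval_min),
      seed = seed, noise = list(sd = noise_sd, poisson = FALSE)
    )
    list(stack = stack, truth = truth)
  })
}

#' Synthetic two-channel droplet field
#'
#' Non-overlapping disks on a uniform background: the protein channel
#' (`gfp488`) has interior intensity `background * protein_enrichment`, the
#' probe channel (`cy647`) has `background * probe_partition`. Truth records
#' the rasterised condensed fraction and the programmed partition ratios.
#'
#' @param n_droplets Number of droplets.
#' @param radius_range Disk radius range in pixels.
#' @param protein_enrichment Interior/background ratio of the protein channel.
#' @param probe_partition Interior/background ratio of the probe channel.
#' @param background Background intensity (a.u.).
#' @param shape Field size `c(ny, nx)`.
#' @param noise_sd Gaussian noise sigma (a.u.).
#' @param seed Integer RNG seed.
#' @return A list with `stack` (channels `gfp488`, `cy647`) and `truth`
#'   (`expected$condensed_fraction`, `expected$protein_partition`,
#'   `expected$probe_partition`).
#' @export
gen_droplet_field <- function(n_droplets = 40, radius_range = c(6, 14),
                              protein_enrichment = 5, probe_partition = 3,
                              background = 100, shape = c(512, 512),
                              noise_sd = 2, seed = 1L) {
  stopifnot(n_droplets >= 0, protein_enrichment > 0, probe_partition > 0,
            background > 0)
  if (max(radius_range) * 2 + 8 > min(shape))
    abort("droplet radius range exceeds the image bounds")
  with_seed_(seed, {
    disks <- place_ellipses(n_droplets, shape, radius_range, radius_range,
                            gap = 3, margin = 3)
    disks$ry <- disks$rx <- pmin(disks$ry, disks$rx)  # circular droplets
    protein <- matrix(background, shape[1], shape[2])
    probe <- matrix(background, shape[1], shape[2])
    inside_any <- matrix(FALSE, shape[1], shape[2])
    for (i in seq_len(n_droplets)) {
      dmask <- ellipse_mask(shape, disks$cy[i], disks$cx[i],
                            disks$ry[i], disks$rx[i])
      inside_any <- inside_any | dmask
      protein[dmask] <- background * protein_enrichment
      probe[dmask] <- background * probe_partition
    }
    protein <- protein + rnorm(length(protein), 0, noise_sd)
    probe <- probe + rnorm(length(probe), 0, noise_sd)
    stack <- image_stack(array(c(protein, probe),
                               c(shape[1], shape[2], 1, 2)),
                         channels = c("gfp488", "cy647"))
    truth <- new_scene_truth(
      objects = list(droplets = disks, droplet_mask = inside_any),
      expected = list(
        condensed_fraction = sum(inside_any) / prod(shape),
        condensed_fraction_analytic = sum(pi * disks$ry^2) / prod(shape),
        protein_partition = protein_enrichment,
        probe_partition = probe_partition
      ),
      seed = seed, noise = list(sd = noise_sd, poisson = FALSE)
    )
    list(stack = stack, truth = truth)
  })
}

#' Null ratio datasets for validating the onset statistics
#'
#' Draws replicate ratio time-series in which both "groups" come from the
#' identical constant-ratio process (`r0` plus a per-subject intercept plus
#' i.i.d. frame noise), so any rejection by [rm_anova_onset()] is a type-I
#' error.
#'
#' @param n_cells Subjects (nucleoli) per group.
#' @param n_frames Frames per subject (must be >= 2).
#' @param noise_sd Residual (within-subject) noise sd on the ratio scale.
#' @param n_reps Number of replicate datasets.
#' @param r0 Constant true ratio.
#' @param subject_sd Between-subject intercept sd.
#' @param seed Integer RNG seed.
#' @return A list of `n_reps` tibbles with columns `cell_id`,
#'   `nucleolus_id`, `frame`, `time_min`, `ratio`, `group`.
#' @export
gen_null_ratio_dataset <- function(n_cells = 10, n_frames = 8,
                                   noise_sd = 0.05, n_reps = 1,
                                   r0 = 1.4, subject_sd = 0.05, seed = 1L) {
  if (n_frames < 2) abort("n_frames must be >= 2")
  stopifnot(n_cells >= 2, n_reps >= 1)
  if (noise_sd == 0)
    warn("noise_sd = 0: degenerate ratios, no rejections are possible")
  with_seed_(seed, {
    lapply(seq_len(n_reps), function(rep) {
      grid <- tidyr::crossing(group = c("control", "treated"),
                              cell_id = seq_len(n_cells),
                              frame = seq_len(n_frames))
      subj <- tidyr::crossing(group = c("control", "treated"),
                              cell_id = seq_len(n_cells))
      subj$intercept <- rnorm(nrow(subj), 0, subject_sd)
      grid <- dplyr::left_join(grid, subj, by = c("group", "cell_id"))
      grid$ratio <- r0 + grid$intercept + rnorm(nrow(grid), 0, noise_sd)
      tibble(cell_id = paste(grid$group, grid$cell_id, sep = "_"),
             nucleolus_id = 1L, frame = grid$frame,
             time_min = (grid$frame - 1) * 5,
             ratio = grid$ratio, group = grid$group)
    })
  })
}
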