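# Segmentation of nucleolar substructure (dense fibrillar component and
# fibrillar centres) in 3D, and quantification of nascent-RNA (EU) signal
# inside fibrillar centres.

#' Segment the dense fibrillar component (DFC)
#'
#' Otsu-thresholds the fibrillarin channel restricted to nuclear voxels,
#' refines the regions with a binary opening, and intersects the result
#' with the nuclei, so DFC voxels never extend outside a nucleus. A uniform
#' fibrillarin signal gives a degenerate threshold and an empty mask with a
#' warning.
#'
#' @param fib_channel 3D `[y, x, z]` fibrillarin intensity array.
#' @param nuclei 3D nucleus `label_mask`.
#' @param opening_radius Radius of the binary opening (a 6-connected cross
#'   element is applied `opening_radius` times).
#' @return Logical 3D DFC mask.
#' @export
segment_dfc <- function(fib_channel, nuclei, opening_radius = 1L) {
  if (!identical(dim(fib_channel), dim(nuclei)))
    abort("`fib_channel` and `nuclei` must have the same shape")
  if (max(nuclei) == 0L) abort("empty nucleus mask")
  vals <- fib_channel[nuclei > 0L]
  thr <- otsu_threshold(vals)
  if (!is.finite(thr)) {
    warn("degenerate fibrillarin histogram: returning an empty DFC mask")
    return(array(FALSE, dim(fib_channel)))
  }
  dfc <- fib_channel > thr & nuclei > 0L
  offs <- se_offsets(dims = 3L, cross3d = TRUE)
  for (i in seq_len(opening_radius)) dfc <- binary_opening(dfc, offs)
  dfc & nuclei > 0L
}

#' Detect fibrillar centres (FCs) by seeded watershed
#'
#' Blob-detects candidate FC seeds with a difference-of-Gaussians on the
#' UBF channel; local maxima inside the DFC are kept only when their DoG
#' value exceeds `mean + alpha_sd * sd` of the DoG local-maxima values in
#' the nucleoplasm (the background-puncta reference). Surviving seeds are
#' grown by a watershed on the (inverted) UBF intensity, confined to the
#' Otsu foreground of the UBF channel intersected with the DFC — the Otsu
#' region acts as the spatial stop criterion, and confinement to the DFC
#' guarantees the containment chain FC within DFC within nucleus. The
#' number of FC labels equals the number of surviving seeds.
#'
#' @param ubf_channel 3D UBF intensity array.
#' @param dfc_mask Logical 3D DFC mask from [segment_dfc()].
#' @param nuclei 3D nucleus `label_mask`.
#' @param dog_sigmas Pair of DoG sigmas in pixels (inner, outer).
#' @param alpha_sd Seed-filter multiplier over the nucleoplasm reference.
#' @return An integer 3D FC label array; attribute `fc_cells` maps each FC
#'   label to its parent nucleus id.
#' @export
detect_fc <- function(ubf_channel, dfc_mask, nuclei, dog_sigmas = c(1, 2),
                      alpha_sd = 1) {
  if (!identical(dim(ubf_channel), dim(nuclei)) ||
      !identical(dim(ubf_channel), dim(dfc_mask)))
    abort("channel, DFC mask and nuclei must share one shape")
  nucleoplasm <- nuclei > 0L & !dfc_mask
  if (!any(nucleoplasm)) abort("no nucleoplasm voxels available as reference")
  dog <- blur3d(ubf_channel, dog_sigmas[1]) - blur3d(ubf_channel, dog_sigmas[2])
  maxima <- local_maxima(dog)
  ref_vals <- dog[maxima & nucleoplasm]
  if (length(ref_vals) < 2L) {
    warn("too few nucleoplasm maxima for a reference distribution; no FCs")
    return(empty_fc(dim(ubf_channel)))
  }
  cut <- mean(ref_vals) + alpha_sd * sd(ref_vals)
  seeds_idx <- which(maxima & dfc_mask & dog > cut)
  if (length(seeds_idx) == 0L) {
    return(empty_fc(dim(ubf_channel)))
  }
  # deterministic seed labelling: raster order
  seeds <- array(0L, dim(ubf_channel))
  seeds[sort(seeds_idx)] <- seq_along(seeds_idx)
  thr <- otsu_threshold(ubf_channel[nuclei > 0L])
  # Otsu foreground as the spatial stop criterion; FCs are confined to the
  # DFC so the containment chain FC <= DFC <= nucleus holds voxelwise
  stop_region <- (ubf_channel > thr & dfc_mask) | seeds > 0L
  fc <- seeded_watershed(ubf_channel, seeds, stop_region)
  fc_ids <- sort(unique(fc[fc > 0L]))  # == 1..n_seeds (every seed keeps its label)
  cells <- vapply(fc_ids, function(id) {
    ids <- nuclei[fc == id]
    ids <- ids[ids > 0L]
    if (length(ids) == 0L) 0L else as.integer(names(which.max(table(ids))))
  }, integer(1))
  attr(fc, "fc_cells") <- tibble(fc_id = fc_ids, cell_id = cells)
  fc
}

empty_fc <- function(d) {
  out <- array(0L, d)
  attr(out, "fc_cells") <- tibble(fc_id = integer(), cell_id = integer())
  out
}

#' Mean EU intensity within fibrillar centres, per cell
#'
#' For each cell, computes the mean EU intensity over the union of that
#' cell's FC voxels. Cells without FCs receive `NA` (a missing value, not
#' zero), so they drop out of group means rather than biasing them.
#'
#' @param eu_channel 3D EU intensity array.
#' @param fc_labels FC label array from [detect_fc()].
#' @param cells 3D nucleus `label_mask`.
#' @param group Optional condition label recycled across cells.
#' @return A tibble with `cell_id`, `n_fc`, `mean_eu_in_fc`, `group`.
#' @export
measure_eu <- function(eu_channel, fc_labels, cells, group = NA_character_) {
  if (!identical(dim(eu_channel), dim(cells)) ||
      !identical(dim(eu_channel), dim(fc_labels)))
    abort("channel, FC labels and cells must share one shape")
  map <- attr(fc_labels, "fc_cells")
  if (is.null(map)) abort("`fc_labels` must carry the `fc_cells` attribute")
  n_cells <- max(cells)
  rows <- lapply(seq_len(n_cells), function(cid) {
    fids <- map$fc_id[map$cell_id == cid]
    if (length(fids) == 0L) {
      return(tibble(cell_id = cid, n_fc = 0L, mean_eu_in_fc = NA_real_))
    }
    vox <- fc_labels %in% fids & cells == cid
    tibble(cell_id = cid, n_fc = length(fids),
           mean_eu_in_fc = mean(eu_channel[vox]))
  })
  out <- dplyr::bind_rows(rows)
  out$group <- rep_len(group, nrow(out))
  out
}

#' Normalise per-cell EU measurements to the control-group mean
#'
#' Divides every `mean_eu_in_fc` by the mean of the control group, so the
#' control mean maps to exactly 1 and a treated mean of 0.6 reads as a 40%
#' reduction in nascent RNA. The ratio is invariant under global intensity
#' rescaling of all rows.
#'
#' @param rows A tibble from [measure_eu()] (rows from several fields may
#'   be bound together first).
#' @param control_label The `group` value identifying the control.
#' @return The input with a `normalized` column added.
#' @export
normalize_to_control <- function(rows, control_label) {
  ctrl <- rows$mean_eu_in_fc[rows$group == control_label]
  ctrl <- ctrl[is.finite(ctrl)]
  if (length(ctrl) == 0L) abort("control group is empty")
  rows$normalized <- rows$mean_eu_in_fc / mean(ctrl)
  rows
}
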