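#' Parameters for LoG focus detection
#'
#' @param log_sigma Laplacian-of-Gaussian sigma in pixels.
#' @param k_sd Threshold multiplier: the binarisation threshold is
#'   `mean + k_sd * sd` of the filter response over the whole image.
#' @param opening_size Side of the square (all-ones) structuring element
#'   used for the morphological opening that removes noise specks.
#' @param log_sign `"negated"` (default) thresholds the negated LoG so that
#'   bright spots give positive responses; `"raw"` thresholds the raw LoG.
#' @param threshold_scope `"image"` computes the threshold statistics over
#'   the whole projected image; `"nuclei"` restricts them to nuclear pixels.
#' @param exclude_border Drop nuclei touching the image border (and their
#'   foci) from summaries; excluded nuclei are flagged in the output.
#' @return A `foci_params` list.
#' @export
foci_params <- function(log_sigma = 3, k_sd = 1.5, opening_size = 3,
                        log_sign = c("negated", "raw"),
                        threshold_scope = c("image", "nuclei"),
                        exclude_border = TRUE) {
  stopifnot(log_sigma > 0, k_sd > 0, opening_size >= 1)
  structure(list(log_sigma = log_sigma, k_sd = k_sd,
                 opening_size = as.integer(opening_size),
                 log_sign = match.arg(log_sign),
                 threshold_scope = match.arg(threshold_scope),
                 exclude_border = isTRUE(exclude_border)),
            class = "foci_params")
}

#' Detect DNA-damage foci in a projected image
#'
#' Implements the classical spot pipeline for punctate DNA-damage markers
#' (gamma-H2AX, 53BP1): filter the maximum projection with a
#' Laplacian-of-Gaussian, threshold the response at `mean + k_sd * sd`
#' (whole-image statistics), binarise, clean with a morphological opening
#' (square all-ones element), label 8-connected components, and keep only
#' foci whose centroid lies inside a nucleus. The LoG response is negated
#' by default so that bright blobs produce positive responses and the
#' mean-plus-k-SD rule selects spot cores. The threshold is a linear
#' statistic of a linear filter, so the detected focus set is invariant
#' under global intensity rescaling.
#'
#' @param proj_img 2D matrix: max projection of the focus channel.
#' @param nuclei 2D nucleus `label_mask` (from the dye channel projection).
#' @param params A [foci_params()].
#' @return A tibble with one row per focus: `nucleus_id`, `focus_id`,
#'   `area`, `mean_intensity`, `centroid_y`, `centroid_x`,
#'   `border_nucleus`. The nucleus table (including zero-focus nuclei) is
#'   attached as attribute `nuclei_info`.
#' @export
detect_foci <- function(proj_img, nuclei, params = foci_params()) {
  if (missing(nuclei) || is.null(nuclei)) abort("a nucleus mask is required")
  if (!identical(dim(proj_img), dim(nuclei)))
    abort("`proj_img` and `nuclei` must have the same shape")
  stopifnot(inherits(params, "foci_params"))
  resp <- filter2_replicate(proj_img, log_kernel(params$log_sigma))
  if (params$log_sign == "negated") resp <- -resp
  stat_px <- if (params$threshold_scope == "nuclei") resp[nuclei > 0L] else resp
  mu <- mean(stat_px); sdv <- sd(as.vector(stat_px))
  empty <- tibble(nucleus_id = integer(), focus_id = integer(),
                  area = numeric(), mean_intensity = numeric(),
                  centroid_y = numeric(), centroid_x = numeric(),
                  border_nucleus = logical())
  nuc_info <- nucleus_info(nuclei)
  # guard against numerically-constant responses (FFT ripple on flat input):
  # compare the response spread to the input intensity scale
  if (is.finite(sdv) && sdv < 1e-10 * max(abs(proj_img), 1)) sdv <- 0
  if (!is.finite(sdv) || sdv == 0) {
    warn("zero-variance filter response: no foci detected")
    attr(empty, "nuclei_info") <- nuc_info
    return(empty)
  }
  bw <- resp >= (mu + params$k_sd * sdv)
  bw <- binary_opening(bw, se_offsets(params$opening_size, dims = 2L))
  lab <- label_components(bw, connectivity = 8)
  n <- max(lab)
  if (n == 0L) {
    attr(empty, "nuclei_info") <- nuc_info
    return(empty)
  }
  idx <- which(lab > 0L)
  co <- arrayInd(idx, dim(lab))
  df <- tibble(label = lab[idx], y = co[, 1], x = co[, 2],
               inten = proj_img[idx])
  per <- df |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(area = dplyr::n(),
                     mean_intensity = mean(.data$inten),
                     centroid_y = mean(.data$y),
                     centroid_x = mean(.data$x), .groups = "drop")
  cy <- pmin(pmax(round(per$centroid_y), 1L), nrow(proj_img))
  cx <- pmin(pmax(round(per$centroid_x), 1L), ncol(proj_img))
  per$nucleus_id <- as.integer(nuclei[cbind(cy, cx)])
  per <- per[per$nucleus_id > 0L, , drop = FALSE]
  per <- per[order(per$nucleus_id, per$centroid_y, per$centroid_x), ]
  out <- per |>
    dplyr::group_by(.data$nucleus_id) |>
    dplyr::mutate(focus_id = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::left_join(nuc_info[, c("nucleus_id", "border_nucleus")],
                     by = "nucleus_id") |>
    dplyr::select("nucleus_id", "focus_id", "area", "mean_intensity",
                  "centroid_y", "centroid_x", "border_nucleus")
  attr(out, "nuclei_info") <- nuc_info
  out
}

# Per-nucleus geometry: area and whether the nucleus touches the border.
nucleus_info <- function(nuclei) {
  n <- max(nuclei)
  if (n == 0L)
    return(tibble(nucleus_id = integer(), nucleus_area = integer(),
                  border_nucleus = logical()))
  border_labels <- unique(c(nuclei[1, ], nuclei[nrow(nuclei), ],
                            nuclei[, 1], nuclei[, ncol(nuclei)]))
  sizes <- tabulate(nuclei[nuclei > 0L], nbins = n)
  tibble(nucleus_id = seq_len(n), nucleus_area = sizes,
         border_nucleus = seq_len(n) %in% border_labels)
}

#' Summarise foci per nucleus and per condition
#'
#' Produces per-nucleus counts (zero-filled for nuclei without foci) and
#' per-condition mean, SD and SEM of the count, focus size and focus
#' intensity. Border-touching nuclei are excluded by default (flagged in
#' the per-nucleus table). Group significance testing is handed off to the
#' ANOVA utilities (see [rm_anova_onset()] for the repeated-measures case).
#'
#' @param foci A foci tibble from [detect_foci()] (its `nuclei_info`
#'   attribute supplies the zero-focus nuclei).
#' @param grouping Either a single condition label for the whole field, or
#'   a vector mapping each nucleus id to a condition.
#' @param include_border Keep border-touching nuclei (default `FALSE`).
#' @return A list with `per_nucleus` and `per_condition` tibbles.
#' @export
summarize_foci <- function(foci, grouping = "all", include_border = FALSE) {
  info <- attr(foci, "nuclei_info")
  if (is.null(info)) abort("`foci` must carry a `nuclei_info` attribute")
  n <- nrow(info)
  if (length(grouping) == 1L) grouping <- rep(grouping, n)
  if (length(grouping) != n)
    abort("`grouping` must be length 1 or one label per nucleus")
  counts <- table(factor(foci$nucleus_id, levels = info$nucleus_id))
  per_nucleus <- info
  per_nucleus$condition <- as.character(grouping)
  per_nucleus$n_foci <- as.integer(counts)
  mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
  fsum <- foci |>
    dplyr::group_by(.data$nucleus_id) |>
    dplyr::summarise(mean_focus_area = mean(.data$area),
                     mean_focus_intensity = mean(.data$mean_intensity),
                     .groups = "drop")
  per_nucleus <- dplyr::left_join(per_nucleus, fsum, by = "nucleus_id")
  kept <- if (include_border) per_nucleus else
    per_nucleus[!per_nucleus$border_nucleus, , drop = FALSE]
  per_condition <- kept |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_nuclei = dplyr::n(),
      mean_count = mean(.data$n_foci),
      sd_count = sd(.data$n_foci),
      sem_count = sd(.data$n_foci) / sqrt(dplyr::n()),
      mean_focus_area = mean_or_na(na.omit(.data$mean_focus_area)),
      mean_focus_intensity = mean_or_na(na.omit(.data$mean_focus_intensity)),
      .groups = "drop"
    )
  list(per_nucleus = per_nucleus, per_condition = per_condition)
}
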