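# Live-cell nucleolus-to-nucleoplasm ratio tracking and onset statistics.

#' Detect nucleoli in a masked phase-contrast image
#'
#' Nucleoli appear as dark, compact bodies on the brighter nucleoplasm in
#' phase contrast. Within each nucleus the (smoothed, inverted) phase image
#' is Otsu-thresholded; dark objects above `min_area` are labelled and
#' assigned to their parent nucleus. This classical detector stands behind
#' the same contract as the trained pixel classifiers used in practice, so
#' external probability maps can be substituted upstream.
#'
#' @param phase_img 2D phase-contrast matrix.
#' @param nucleus_mask 2D nucleus `label_mask`.
#' @param min_area Minimum nucleolus size in pixels.
#' @param smooth_sigma Gaussian smoothing sigma before thresholding.
#' @param min_contrast Minimum relative darkening (dark-class mean at least
#'   this fraction below the bright-class mean) for a split to count as a
#'   nucleolus; guards against Otsu splitting pure noise in nucleolus-free
#'   nuclei.
#' @return An integer nucleolus label matrix; attribute `parents` maps each
#'   nucleolus label to its parent nucleus id.
#' @export
detect_nucleoli_phase <- function(phase_img, nucleus_mask, min_area = 20,
                                  smooth_sigma = 1.5, min_contrast = 0.1) {
  if (!identical(dim(phase_img), dim(nucleus_mask)))
    abort("`phase_img` and `nucleus_mask` must have the same shape")
  mask <- matrix(FALSE, nrow(phase_img), ncol(phase_img))
  for (nid in seq_len(max(nucleus_mask))) {
    px <- nucleus_mask == nid
    idx <- which(px, arr.ind = TRUE)
    y0 <- min(idx[, 1]); y1 <- max(idx[, 1])
    x0 <- min(idx[, 2]); x1 <- max(idx[, 2])
    crop <- phase_img[y0:y1, x0:x1, drop = FALSE]
    inmask <- px[y0:y1, x0:x1, drop = FALSE]
    # neutralise non-nuclear pixels so smoothing does not bleed the
    # background across the nuclear boundary
    crop[!inmask] <- stats::median(crop[inmask])
    sm <- as.matrix(EBImage::gblur(crop, sigma = smooth_sigma,
                                   boundary = "replicate"))
    vals <- sm[inmask]
    inv <- max(vals) - vals
    thr <- otsu_threshold(inv)
    if (!is.finite(thr)) next  # uniform nucleus: no nucleolus detected
    dark <- inv > thr
    # contrast guard: a unimodal (noise-only) split has near-equal class
    # means and is not a nucleolus
    if ((mean(vals[dark]) - mean(vals[!dark])) > -min_contrast * mean(vals[!dark])) next
    # column-major order of `which(px)` matches `sm[inmask]` within the crop
    mask[which(px)[dark]] <- TRUE
  }
  lab <- label_components(mask, connectivity = 4)
  lab <- prune_small(lab, min_area)
  lab <- relabel_consecutive(lab)
  n <- max(lab)
  parents <- vapply(seq_len(n), function(j) {
    ids <- nucleus_mask[lab == j]
    ids <- ids[ids > 0L]
    if (length(ids) == 0L) 0L else as.integer(names(which.max(table(ids))))
  }, integer(1))
  attr(lab, "parents") <- tibble(nucleolus_label = seq_len(n),
                                 nucleus_id = parents)
  lab
}

#' Exclude aberrant objects from a per-frame feature table
#'
#' A rule-based stand-in for the trained object classifiers used to remove
#' dividing and dying cells: any nucleus violating a rule in any frame is
#' dropped for all frames. Default rules flag an area collapse of more than
#' `max_area_drop` between consecutive frames and extreme eccentricity.
#' Exclusion of one cell never alters another cell's rows.
#'
#' @param objects Tibble with at least `cell_id` and `frame`; optional
#'   feature columns `area`, `eccentricity`, `mean_intensity`.
#' @param max_area_drop Fractional frame-to-frame area drop that flags a
#'   cell (default 0.4).
#' @param eccentricity_max Maximum allowed eccentricity.
#' @param area_range,intensity_range Optional `c(min, max)` bounds.
#' @return The filtered tibble; attribute `excluded` is a tibble logging
#'   each dropped cell and the rule it violated.
#' @export
exclude_objects <- function(objects, max_area_drop = 0.4,
                            eccentricity_max = 0.95,
                            area_range = NULL, intensity_range = NULL) {
  bad <- list()
  flag <- function(ids, reason) {
    if (length(ids)) bad[[length(bad) + 1L]] <<-
        tibble(cell_id = unique(ids), reason = reason)
  }
  if ("area" %in% names(objects)) {
    drops <- objects |>
      dplyr::arrange(.data$cell_id, .data$frame) |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::mutate(rel_drop = 1 - .data$area / dplyr::lag(.data$area)) |>
      dplyr::filter(!is.na(.data$rel_drop), .data$rel_drop > max_area_drop)
    flag(drops$cell_id, "area_collapse")
    if (!is.null(area_range)) {
      out <- objects$cell_id[objects$area < area_range[1] |
                               objects$area > area_range[2]]
      flag(out, "area_bounds")
    }
  }
  if ("eccentricity" %in% names(objects)) {
    flag(objects$cell_id[objects$eccentricity > eccentricity_max],
         "eccentricity")
  }
  if ("mean_intensity" %in% names(objects) && !is.null(intensity_range)) {
    out <- objects$cell_id[objects$mean_intensity < intensity_range[1] |
                             objects$mean_intensity > intensity_range[2]]
    flag(out, "intensity_bounds")
  }
  log <- if (length(bad)) dplyr::distinct(dplyr::bind_rows(bad)) else
    tibble(cell_id = objects$cell_id[0], reason = character())
  kept <- objects[!(objects$cell_id %in% log$cell_id), , drop = FALSE]
  if (nrow(kept) == 0L && nrow(objects) > 0L)
    warn("all objects excluded by the filtering rules")
  attr(kept, "excluded") <- log
  kept
}

# Link current labels to previous track ids by maximum mask overlap.
# Ties go to the larger overlap, then the lower track id. Unmatched labels
# open new tracks.
link_by_overlap <- function(prev_track_px, cur_labels, next_track_id) {
  n_cur <- max(cur_labels)
  assign_ <- integer(n_cur)
  both <- prev_track_px > 0L & cur_labels > 0L
  if (any(both)) {
    ov <- as.data.frame(table(prev = prev_track_px[both],
                              cur = cur_labels[both]),
                        stringsAsFactors = FALSE)
    ov$prev <- as.integer(ov$prev); ov$cur <- as.integer(ov$cur)
    ov <- ov[order(-ov$Freq, ov$prev), ]
    used_prev <- integer(0)
    for (i in seq_len(nrow(ov))) {
      cu <- ov$cur[i]; pr <- ov$prev[i]
      if (assign_[cu] == 0L && !(pr %in% used_prev)) {
        assign_[cu] <- pr
        used_prev <- c(used_prev, pr)
      }
    }
  }
  for (cu in seq_len(n_cur)) {
    if (assign_[cu] == 0L) {
      assign_[cu] <- next_track_id
      next_track_id <- next_track_id + 1L
    }
  }
  list(assignment = assign_, next_track_id = next_track_id)
}

#' Nucleolus-to-nucleoplasm ratio time series
#'
#' For every frame and nucleolus, computes the mean fluorescence over the
#' nucleolus pixels divided by the mean fluorescence over the parent
#' nucleus's nucleoplasm (nucleus minus all its nucleoli, via
#' [nucleoplasm_mask()]). Nucleolus and nucleus identities are carried
#' across frames by maximum mask overlap with the previous frame. The ratio
#' is invariant under any global linear intensity rescaling of a frame.
#'
#' @param fluor_frames List of 2D fluorescence matrices, one per frame.
#' @param nuclei_frames List of nucleus label rasters, one per frame.
#' @param nucleoli_frames List of nucleolus label rasters, one per frame.
#' @param frame_interval_min Minutes between frames.
#' @param group Condition label attached to every row.
#' @return A tibble with `cell_id`, `nucleolus_id`, `frame`, `time_min`,
#'   `ratio`, `group`; empty nucleoplasm yields a missing ratio.
#' @export
ratio_timeseries <- function(fluor_frames, nuclei_frames, nucleoli_frames,
                             frame_interval_min = 5, group = "control") {
  n_frames <- length(fluor_frames)
  stopifnot(length(nuclei_frames) == n_frames,
            length(nucleoli_frames) == n_frames)
  rows <- list()
  prev_nuc_track <- NULL; prev_nucl_track <- NULL
  next_nuc <- 1L; next_nucl <- 1L
  for (t in seq_len(n_frames)) {
    fl <- fluor_frames[[t]]
    nuc <- nuclei_frames[[t]]
    nucl <- nucleoli_frames[[t]]
    # track ids
    if (is.null(prev_nuc_track)) {
      nuc_assign <- seq_len(max(nuc, 0L)); next_nuc <- max(nuc, 0L) + 1L
      nucl_assign <- seq_len(max(nucl, 0L)); next_nucl <- max(nucl, 0L) + 1L
    } else {
      ln <- link_by_overlap(prev_nuc_track, nuc, next_nuc)
      nuc_assign <- ln$assignment; next_nuc <- ln$next_track_id
      lo <- link_by_overlap(prev_nucl_track, nucl, next_nucl)
      nucl_assign <- lo$assignment; next_nucl <- lo$next_track_id
    }
    npm <- suppressWarnings(nucleoplasm_mask(new_label_mask(unclass(nuc)), nucl))
    for (j in seq_len(max(nucl, 0L))) {
      px <- nucl == j
      parent_ids <- nuc[px]; parent_ids <- parent_ids[parent_ids > 0L]
      if (length(parent_ids) == 0L) next
      parent <- as.integer(names(which.max(table(parent_ids))))
      np_px <- npm == parent
      ratio <- if (any(np_px)) mean(fl[px]) / mean(fl[np_px]) else NA_real_
      rows[[length(rows) + 1L]] <- tibble(
        cell_id = nuc_assign[parent], nucleolus_id = nucl_assign[j],
        frame = t, time_min = (t - 1) * frame_interval_min,
        ratio = ratio, group = group)
    }
    # carry track maps as pixel rasters for the next frame's overlap
    nt <- nuc; if (max(nuc) > 0L) nt[nuc > 0L] <- nuc_assign[nuc[nuc > 0L]]
    lt <- nucl; if (max(nucl) > 0L) lt[nucl > 0L] <- nucl_assign[nucl[nucl > 0L]]
    prev_nuc_track <- nt; prev_nucl_track <- lt
  }
  if (length(rows) == 0L) {
    return(tibble(cell_id = integer(), nucleolus_id = integer(),
                  frame = integer(), time_min = numeric(),
                  ratio = numeric(), group = character()))
  }
  dplyr::bind_rows(rows)
}

#' Segment and quantify a live-cell stack end to end
#'
#' Convenience wrapper: per frame, segments nuclei from the fluorescence
#' channel, nucleoli from the masked phase channel, then computes the ratio
#' time series with [ratio_timeseries()].
#'
#' @param stack A time-indexed [image_stack()] with `gfp` and `phase`
#'   channels.
#' @param group Condition label.
#' @param frame_interval_min Minutes between frames.
#' @param min_nucleus_area,min_nucleolus_area Size filters in pixels.
#' @return A ratio tibble (see [ratio_timeseries()]).
#' @export
livecell_pipeline <- function(stack, group = "control",
                              frame_interval_min = 5,
                              min_nucleus_area = 200,
                              min_nucleolus_area = 20) {
  stopifnot(inherits(stack, "image_stack"))
  n_frames <- dim(stack$data)[5]
  fl <- vector("list", n_frames); nu <- vector("list", n_frames)
  no <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    fl[[t]] <- get_channel(stack, "gfp", t = t)
    nu[[t]] <- segment_nuclei(fl[[t]], min_area = min_nucleus_area)
    ph <- get_channel(stack, "phase", t = t)
    no[[t]] <- detect_nucleoli_phase(ph, nu[[t]], min_area = min_nucleolus_area)
  }
  ratio_timeseries(fl, nu, no, frame_interval_min = frame_interval_min,
                   group = group)
}

#' Two-way repeated-measures ANOVA with per-frame Tukey onset detection
#'
#' Fits the mixed (split-plot) two-way ANOVA with `group` as the
#' between-subject factor and `frame` (time) as the within-subject factor,
#' on subjects (nucleoli) with complete tracks; incomplete tracks are
#' dropped and counted. F statistics are computed from the classical
#' sum-of-squares decomposition: the group effect is tested against
#' subjects-within-groups, time and the time-by-group interaction against
#' the within-subject residual. Sphericity is uncorrected by default, with
#' an optional Greenhouse-Geisser adjustment of the within-subject tests.
#'
#' Post hoc, every frame receives Tukey-HSD-adjusted pairwise group
#' comparisons (studentized-range p-values on that frame's one-way fit).
#' `first_significant` is the earliest frame with any adjusted p below
#' `alpha`, reported only when the interaction or the group main effect is
#' itself significant.
#'
#' @param series Ratio tibble with columns `cell_id`, `nucleolus_id`,
#'   `frame`, `ratio`, `group` (e.g. from [ratio_timeseries()]).
#' @param alpha Significance level.
#' @param sphericity `"none"` or `"greenhouse-geisser"`.
#' @return An object of class `onset_anova` with components `anova`
#'   (effect table), `contrasts` (per-frame Tukey table),
#'   `first_significant`, `alpha`, `n_subjects`, `n_dropped`.
#' @export
rm_anova_onset <- function(series, alpha = 0.05,
                           sphericity = c("none", "greenhouse-geisser")) {
  sphericity <- match.arg(sphericity)
  need <- c("cell_id", "nucleolus_id", "frame", "ratio", "group")
  if (!all(need %in% names(series)))
    abort(paste("`series` must have columns:", paste(need, collapse = ", ")))
  series$subject <- paste(series$group, series$cell_id, series$nucleolus_id,
                          sep = "::")
  frames <- sort(unique(series$frame))
  t_n <- length(frames)
  if (t_n < 2L) abort("at least 2 frames are required")
  if (length(unique(series$group)) < 2L) abort("at least 2 groups are required")
  ok <- series[is.finite(series$ratio), , drop = FALSE]
  per_subj <- table(ok$subject)
  complete <- names(per_subj)[per_subj == t_n]
  n_dropped <- length(per_subj) - length(complete)
  dat <- ok[ok$subject %in% complete, , drop = FALSE]
  subj_group <- dat |>
    dplyr::distinct(.data$subject, .data$group)
  gsizes <- table(subj_group$group)
  if (any(gsizes < 2L))
    abort("every group needs at least 2 complete-track subjects")
  # cell means
  y <- dat$ratio
  grand <- mean(y)
  m_subj <- tapply(y, dat$subject, mean)
  m_g <- tapply(y, dat$group, mean)
  m_t <- tapply(y, dat$frame, mean)
  m_gt <- tapply(y, list(dat$group, dat$frame), mean)
  g_n <- length(m_g)
  N <- length(m_subj)
  n_of <- as.numeric(gsizes[names(m_g)])
  ss_between <- t_n * sum((m_subj - grand)^2)
  ss_group <- t_n * sum(n_of * (m_g - grand)^2)
  ss_subj <- ss_between - ss_group
  ss_time <- N * sum((m_t - grand)^2)
  ss_int <- sum(outer(n_of, rep(1, t_n)) *
                  (m_gt - outer(m_g - grand, m_t - grand, `+`) - grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_within <- ss_total - ss_between
  ss_err <- ss_within - ss_time - ss_int
  df_group <- g_n - 1
  df_subj <- N - g_n
  df_time <- t_n - 1
  df_int <- (g_n - 1) * (t_n - 1)
  df_err <- (N - g_n) * (t_n - 1)
  eps <- 1
  if (sphericity == "greenhouse-geisser") {
    # pooled within-group covariance across frames
    wide <- tapply(dat$ratio, list(dat$subject, dat$frame), mean)
    grp <- subj_group$group[match(rownames(wide), subj_group$subject)]
    centered <- wide
    for (g in unique(grp)) {
      rows_g <- grp == g
      centered[rows_g, ] <- sweep(wide[rows_g, , drop = FALSE], 2,
                                  colMeans(wide[rows_g, , drop = FALSE]))
    }
    S <- crossprod(centered) / (N - g_n)
    Sc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
    eps <- sum(diag(Sc))^2 / ((t_n - 1) * sum(Sc^2))
    eps <- min(max(eps, 1 / (t_n - 1)), 1)
  }
  f_group <- (ss_group / df_group) / (ss_subj / df_subj)
  f_time <- (ss_time / df_time) / (ss_err / df_err)
  f_int <- (ss_int / df_int) / (ss_err / df_err)
  an <- tibble(
    term = c("group", "subjects_within_group", "time", "time:group",
             "within_residual"),
    df = c(df_group, df_subj, df_time * eps, df_int * eps, df_err * eps),
    sumsq = c(ss_group, ss_subj, ss_time, ss_int, ss_err),
    statistic = c(f_group, NA, f_time, f_int, NA),
    p.value = c(pf(f_group, df_group, df_subj, lower.tail = FALSE), NA,
                pf(f_time, df_time * eps, df_err * eps, lower.tail = FALSE),
                pf(f_int, df_int * eps, df_err * eps, lower.tail = FALSE),
                NA)
  )
  # per-frame Tukey HSD group comparisons
  contrasts <- dplyr::bind_rows(lapply(frames, function(fr) {
    d <- dat[dat$frame == fr, , drop = FALSE]
    tukey_pairs(d$ratio, d$group, fr)
  }))
  p_int <- an$p.value[an$term == "time:group"]
  p_grp <- an$p.value[an$term == "group"]
  gate_passed <- isTRUE(p_int < alpha) || isTRUE(p_grp < alpha)
  sig_frames <- contrasts$frame[contrasts$adj.p.value < alpha]
  first_sig <- if (gate_passed && length(sig_frames)) min(sig_frames) else NA_integer_
  structure(
    list(anova = an, contrasts = contrasts,
         first_significant = first_sig, alpha = alpha,
         sphericity = sphericity, epsilon = eps,
         n_subjects = N, n_dropped = n_dropped,
         group_sizes = gsizes, frames = frames,
         series = dat),
    class = "onset_anova"
  )
}

# Tukey HSD pairwise comparisons of `y` across levels of `g` (one frame).
tukey_pairs <- function(y, g, frame) {
  g <- factor(g)
  k <- nlevels(g)
  ns <- tapply(y, g, length)
  ms <- tapply(y, g, mean)
  N <- length(y)
  mse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / (N - k)
  combs <- utils::combn(levels(g), 2)
  est <- ms[combs[2, ]] - ms[combs[1, ]]
  se <- sqrt(mse / 2 * (1 / ns[combs[1, ]] + 1 / ns[combs[2, ]]))
  q <- abs(est) / se
  p <- ptukey(q, k, N - k, lower.tail = FALSE)
  tibble(frame = frame,
         contrast = paste(combs[2, ], "-", combs[1, ]),
         estimate = as.numeric(est), se = as.numeric(se),
         statistic = as.numeric(q), df = N - k,
         adj.p.value = as.numeric(p))
}

#' @export
print.onset_anova <- function(x, ...) {
  cat("Two-way repeated-measures ANOVA (between: group, within: time)\n")
  cat(sprintf("  %d complete subjects (%d dropped), %d frames\n",
              x$n_subjects, x$n_dropped, length(x$frames)))
  print(as.data.frame(x$anova), row.names = FALSE, digits = 4)
  if (is.na(x$first_significant)) {
    cat("No significant group divergence at alpha =", x$alpha, "\n")
  } else {
    cat("First significant frame (Tukey-adjusted):", x$first_significant, "\n")
  }
  invisible(x)
}

#' @rdname rm_anova_onset
#' @param x An `onset_anova` object.
#' @param ... Unused.
#' @export
tidy.onset_anova <- function(x, ...) {
  x$anova
}

#' @rdname rm_anova_onset
#' @method glance onset_anova
#' @export
glance.onset_anova <- function(x, ...) {
  an <- x$anova
  tibble(
    p_group = an$p.value[an$term == "group"],
    p_time = an$p.value[an$term == "time"],
    p_interaction = an$p.value[an$term == "time:group"],
    first_significant = x$first_significant,
    n_subjects = x$n_subjects,
    n_dropped = x$n_dropped,
    alpha = x$alpha
  )
}
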