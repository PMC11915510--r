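#' Classical nucleus segmentation
#'
#' A deterministic fallback segmenter for nuclear-dye images (the original
#' analyses used trained Cellpose/Ilastik models, whose weights are not
#' distributable; externally produced masks can be ingested with
#' [load_external_labels()] instead). The procedure is: Gaussian smooth,
#' Otsu threshold, fill holes, split touching objects by a
#' distance-transform watershed, drop objects below `min_area`, and relabel
#' consecutively. The threshold operates on the normalised image, so label
#' counts are invariant under global intensity rescaling.
#'
#' 2D images use 4-connectivity; 3D volumes are thresholded in 3D and
#' labelled with 6-connectivity (the watershed split runs on the projected
#' footprint for 3D input, adequate for mono-layered fields of round
#' nuclei).
#'
#' @param dye_img Single-channel 2D matrix or 3D `[y, x, z]` array.
#' @param min_area Minimum object size in pixels (2D) or voxels (3D).
#'   Defaults to 200 px in 2D and 2000 voxels in 3D.
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @return A `label_mask`: integer raster with `0` background and objects
#'   numbered `1..N`, with attributes `provenance = "classical"`.
#' @export
segment_nuclei <- function(dye_img, min_area = NULL, smooth_sigma = 2) {
  nd <- length(dim(dye_img))
  if (is.null(nd) || !(nd %in% c(2L, 3L)))
    abort("`dye_img` must be a 2D matrix or 3D array")
  if (is.null(min_area)) min_area <- if (nd == 2L) 200 else 2000
  rng <- range(dye_img)
  if (diff(rng) <= 0) {
    warn("constant image: returning an empty mask")
    return(new_label_mask(array(0L, dim(dye_img)), "classical"))
  }
  norm <- (dye_img - rng[1]) / diff(rng)
  sm <- if (nd == 2L) {
    as.matrix(EBImage::gblur(norm, sigma = smooth_sigma, boundary = "replicate"))
  } else {
    blur3d(norm, smooth_sigma)
  }
  thr <- otsu_threshold(sm)
  fg <- sm > thr
  if (!any(fg)) {
    warn("no foreground after thresholding: returning an empty mask")
    return(new_label_mask(array(0L, dim(dye_img)), "classical"))
  }
  fg <- fill_holes(fg)
  if (nd == 2L) {
    lab <- watershed_split(fg)
  } else {
    foot <- apply(fg, c(1, 2), any)
    lab2 <- watershed_split(foot)
    lab <- array(0L, dim(fg))
    for (z in seq_len(dim(fg)[3])) {
      sl <- lab2
      sl[!fg[, , z]] <- 0L
      lab[, , z] <- sl
    }
  }
  lab <- prune_small(lab, min_area)
  new_label_mask(relabel_consecutive(lab), "classical")
}

# Split touching 2D objects with a distance-transform watershed. Single
# objects come back unchanged; watershed regions are relabelled in raster
# order for determinism.
watershed_split <- function(fg) {
  dm <- EBImage::distmap(fg)
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  relabel_consecutive(as.integer(ws) |> array(dim(fg)))
}

new_label_mask <- function(labels, provenance = c("classical", "external")) {
  provenance <- match.arg(provenance)
  structure(labels, provenance = provenance, class = c("label_mask", class(labels)))
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %s, %d object(s), provenance: %s\n",
              paste(dim(x), collapse = "x"), max(x),
              attr(x, "provenance")))
  invisible(x)
}

#' Ingest an externally produced label mask
#'
#' Reads an integer-valued TIFF (e.g. exported from a trained Cellpose or
#' Ilastik model), validates it and relabels objects consecutively. Labels
#' written by [write_labels()] round-trip exactly.
#'
#' @param path TIFF path (single page = 2D; multi-page = 3D, page per z).
#' @param expect_shape Optional expected raster shape; a mismatch is an
#'   error.
#' @return A `label_mask` with `provenance = "external"`.
#' @export
load_external_labels <- function(path, expect_shape = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lab <- if (length(pages) == 1L) pages[[1]] else
    array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  if (any(lab != round(lab)) || any(lab < 0))
    abort("label image must contain non-negative integers")
  if (!is.null(expect_shape) && !identical(dim(lab), as.integer(expect_shape)))
    abort(sprintf("label shape (%s) does not match expected (%s)",
                  paste(dim(lab), collapse = "x"),
                  paste(expect_shape, collapse = "x")))
  storage.mode(lab) <- "integer"
  new_label_mask(relabel_consecutive(lab), "external")
}

#' Write a label mask as an integer TIFF
#'
#' @param labels Integer label raster (2D or 3D).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  mx <- max(labels, 1L)
  if (mx > 65535L) abort("more than 65535 labels cannot be stored as 16-bit")
  if (length(dim(labels)) == 3L) {
    pages <- lapply(seq_len(dim(labels)[3]),
                    function(z) labels[, , z] / 65535)
  } else {
    pages <- list(labels / 65535)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Nucleoplasm mask: nuclei minus subregions
#'
#' Retains each nucleus label on the nucleus pixels not covered by any
#' subregion (e.g. nucleoli), so that `nucleoplasm + (subregions within
#' nuclei)` partitions the nuclei exactly. Subregion pixels outside any
#' nucleus are ignored. Nuclei fully covered by subregions end up with an
#' empty nucleoplasm and are reported in the `empty_nucleoplasm` attribute.
#'
#' @param nuclei Nucleus `label_mask`.
#' @param subregions Subregion label raster (any non-zero value is treated
#'   as covered).
#' @return A `label_mask` of the nucleoplasm.
#' @export
nucleoplasm_mask <- function(nuclei, subregions) {
  if (!identical(dim(nuclei), dim(subregions)))
    abort("`nuclei` and `subregions` must have the same shape")
  out <- unclass(nuclei)
  attr(out, "provenance") <- NULL
  out[subregions > 0L] <- 0L
  ids <- setdiff(unique(as.integer(nuclei[nuclei > 0L])), 0L)
  empty <- setdiff(ids, unique(as.integer(out[out > 0L])))
  if (length(empty) > 0L)
    warn(sprintf("nuclei with empty nucleoplasm: %s",
                 paste(sort(empty), collapse = ", ")))
  res <- new_label_mask(out, attr(nuclei, "provenance") %||% "classical")
  attr(res, "empty_nucleoplasm") <- sort(empty)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
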