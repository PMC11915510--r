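#' Multi-channel image stack
#'
#' An `ImageStack` holds a multi-channel raster, optionally z-stacked and/or
#' time-indexed, together with channel names and pixel-size metadata. Data
#' are canonicalised internally to a 5D array indexed `[y, x, z, channel, t]`
#' with singleton axes where an axis is absent, so a single code path serves
#' 2D, 3D and time-lapse inputs. Intensities are stored as doubles in
#' arbitrary units.
#'
#' @param data A 2D `[y, x]`, 3D `[y, x, z]`, 4D `[y, x, z, channel]` or 5D
#'   `[y, x, z, channel, t]` numeric array.
#' @param channels Character vector of channel names; its length must match
#'   the channel axis.
#' @param pixel_size Optional pixel size in micrometres per pixel (xy).
#' @param z_step Optional axial step size in micrometres.
#' @param has_z,has_t Logical flags recording whether the z / time axes are
#'   meaningful (as opposed to padded singletons).
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, channels = "ch1", pixel_size = NULL,
                        z_step = NULL, has_z = NULL, has_t = NULL) {
  nd <- length(dim(data))
  if (is.null(dim(data))) abort("`data` must be an array, not a vector")
  if (nd < 2L || nd > 5L) abort("`data` must have 2 to 5 dimensions")
  d <- dim(data)
  full <- c(d, rep(1L, 5L - nd))
  data <- array(as.numeric(data), full)
  if (length(channels) != full[4])
    abort(sprintf("got %d channel names for a channel axis of length %d",
                  length(channels), full[4]))
  structure(
    list(
      data = data,
      channels = as.character(channels),
      pixel_size = pixel_size,
      z_step = z_step,
      has_z = if (is.null(has_z)) full[3] > 1L else has_z,
      has_t = if (is.null(has_t)) full[5] > 1L else has_t
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d px, %d z, %d channel(s), %d frame(s)\n",
              d[1], d[2], d[3], d[4], d[5]))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  if (!is.null(x$pixel_size))
    cat(sprintf("  pixel size: %g um/px\n", x$pixel_size))
  invisible(x)
}

#' Extract one channel plane from an image stack
#'
#' @param stack An [image_stack()].
#' @param channel Channel name or index.
#' @param t Frame index (default 1).
#' @param drop Drop the singleton z axis when present (default `TRUE`),
#'   returning a matrix for single-z data and a `[y, x, z]` array otherwise.
#' @return A matrix or 3D array of intensities.
#' @export
get_channel <- function(stack, channel, t = 1L, drop = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  ci <- if (is.character(channel)) match(channel, stack$channels) else as.integer(channel)
  if (is.na(ci) || ci < 1L || ci > length(stack$channels))
    abort(sprintf("unknown channel: %s", as.character(channel)))
  a <- stack$data[, , , ci, t, drop = FALSE]
  a <- array(a, dim(a)[1:3])
  if (drop && dim(a)[3] == 1L) a[, , 1L] else a
}

#' Write an image stack to a multi-page TIFF with a JSON sidecar
#'
#' Planes are written in `(t, z, channel)` order as 32-bit float TIFF pages.
#' Because the TIFF writer stores float data on a \[0, 1\] scale, intensities
#' are divided by a recorded scale factor; the sidecar
#' (`<path>.json`) holds the scale, axis sizes, channel names and pixel
#' size, making [read_stack()] a faithful inverse (to 32-bit float
#' precision).
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  offset <- min(stack$data, 0)
  mx <- max(stack$data - offset, 1e-12)
  pages <- list()
  for (t in seq_len(d[5])) for (z in seq_len(d[3])) for (ci in seq_len(d[4])) {
    pages[[length(pages) + 1L]] <- (stack$data[, , z, ci, t] - offset) / mx
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(
    shape = d, scale = mx, offset = offset, channels = stack$channels,
    pixel_size = stack$pixel_size, z_step = stack$z_step,
    has_z = stack$has_z, has_t = stack$has_t,
    page_order = "t,z,channel"
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must be present).
#' @param channel_map Optional named integer vector renaming channels by
#'   index, e.g. `c(hoechst = 1, gfp = 2)`.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_map = NULL) {
  side <- paste0(path, ".json")
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (!file.exists(side)) abort(sprintf("missing metadata sidecar: %s", side))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(meta$shape)
  if (length(pages) != d[3] * d[4] * d[5])
    abort(sprintf("page count %d does not match recorded shape", length(pages)))
  a <- array(0, d)
  i <- 0L
  for (t in seq_len(d[5])) for (z in seq_len(d[3])) for (ci in seq_len(d[4])) {
    i <- i + 1L
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]  # grey written as 1-sample
    a[, , z, ci, t] <- pg * meta$scale + (meta$offset %||% 0)
  }
  channels <- meta$channels
  if (!is.null(channel_map)) {
    channels[as.integer(channel_map)] <- names(channel_map)
  }
  image_stack(a, channels = channels,
              pixel_size = meta$pixel_size, z_step = meta$z_step,
              has_z = isTRUE(meta$has_z), has_t = isTRUE(meta$has_t))
}

#' Maximum-intensity projection along z
#'
#' Collapses the z axis by the per-pixel maximum, leaving channels and time
#' untouched. Idempotent, and commutes with channel selection.
#'
#' @param stack An [image_stack()] with a z axis.
#' @return An [image_stack()] with a singleton z axis.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (!stack$has_z && dim(stack$data)[3] == 1L) {
    # single-slice input: projection is the identity
    return(stack)
  }
  d <- dim(stack$data)
  out <- array(0, c(d[1], d[2], 1L, d[4], d[5]))
  for (t in seq_len(d[5])) for (ci in seq_len(d[4])) {
    out[, , 1L, ci, t] <- apply(stack$data[, , , ci, t, drop = FALSE], c(1, 2), max)
  }
  image_stack(out, channels = stack$channels, pixel_size = stack$pixel_size,
              z_step = stack$z_step, has_z = FALSE, has_t = stack$has_t)
}

#' Flat-field gain image
#'
#' A gain image models the smooth illumination profile of the optical path.
#' It is normalised to mean 1 so that flat-field correction preserves the
#' mean intensity of a uniformly lit field.
#'
#' @param gain Strictly positive numeric matrix `[y, x]`.
#' @return An object of class `flat_field`.
#' @export
flat_field <- function(gain) {
  gain <- as.matrix(gain)
  if (any(!is.finite(gain)) || any(gain <= 0))
    abort("gain image must be strictly positive and finite everywhere")
  structure(list(gain = gain / mean(gain)), class = "flat_field")
}

#' Flat-field correction
#'
#' Divides every plane of the stack by the (mean-1 normalised) gain image.
#' Applied to time-lapse fluorescence before any ratio quantification.
#'
#' @param stack An [image_stack()].
#' @param ff A [flat_field()].
#' @return A corrected [image_stack()].
#' @export
flatfield_correct <- function(stack, ff) {
  stopifnot(inherits(stack, "image_stack"), inherits(ff, "flat_field"))
  d <- dim(stack$data)
  if (!identical(dim(ff$gain), d[1:2]))
    abort("gain image shape does not match the stack's (y, x) shape")
  out <- stack
  out$data <- stack$data / as.vector(ff$gain)  # gain recycles along y,x
  out
}
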