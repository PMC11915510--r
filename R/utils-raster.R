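# Internal raster helpers shared by the imaging pipelines.
#
# Conventions: 2D rasters are R matrices indexed [y, x]; 3D rasters are
# arrays [y, x, z]. All coordinates are 1-based (R convention).

# Evaluate `code` under a fixed RNG seed without touching global RNG state.
with_seed_ <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

gauss_kernel1d <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Laplacian-of-Gaussian kernel; zero-sum so constant images map to zero
# response. Returned unnegated (bright blobs give negative centre values).
log_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- seq(-radius, radius)
  g <- outer(x, x, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  lg <- outer(x, x, function(a, b) (a^2 + b^2 - 2 * sigma^2) / sigma^4) * g
  lg <- lg / sum(g)
  lg - mean(lg)
}

filter2_replicate <- function(img, kernel) {
  EBImage::filter2(img, kernel, boundary = "replicate")
}

# Separable Gaussian blur of a [y, x, z] array: EBImage 2D blur per slice,
# then 1D convolution along z with symmetric (edge-replicating) padding.
blur3d <- function(arr, sigma_xy, sigma_z = sigma_xy / 2) {
  stopifnot(length(dim(arr)) == 3L)
  if (sigma_xy > 0) {
    arr <- EBImage::gblur(arr, sigma = sigma_xy, boundary = "replicate")
    arr <- unclass(arr)
  }
  nz <- dim(arr)[3]
  if (sigma_z > 0 && nz > 1L) {
    k <- gauss_kernel1d(sigma_z, radius = min(ceiling(4 * sigma_z), nz - 1L))
    r <- (length(k) - 1L) %/% 2L
    idx <- c(rep(1L, r), seq_len(nz), rep(nz, r))
    m <- matrix(arr, ncol = nz)[, idx, drop = FALSE]
    out <- matrix(0, nrow(m), nz)
    for (j in seq_len(nz)) {
      out[, j] <- as.vector(m[, j:(j + 2L * r), drop = FALSE] %*% k)
    }
    arr <- array(out, dim(arr))
  }
  arr
}

# Neighbour offsets (dy, dx, dz) for a given connectivity.
# 2D: 4 or 8; 3D: 6 or 26. Returns full set (both directions).
neighbour_offsets <- function(connectivity) {
  offs <- switch(as.character(connectivity),
    "4" = rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0)),
    "6" = rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1)),
    "8" = {
      g <- expand.grid(dy = -1:1, dx = -1:1, dz = 0)
      as.matrix(g[!(g$dy == 0 & g$dx == 0), ])
    },
    "26" = {
      g <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
      as.matrix(g[!(g$dy == 0 & g$dx == 0 & g$dz == 0), ])
    },
    abort(paste0("unsupported connectivity: ", connectivity))
  )
  unname(offs)
}

as_arr3 <- function(a) {
  if (length(dim(a)) == 2L || is.null(dim(a))) {
    array(a, c(dim(as.matrix(a)), 1L))
  } else {
    a
  }
}

# Shift a [y, x, z] array by (dy, dx, dz), filling exposed cells.
shift3 <- function(a, dy, dx, dz, fill = 0) {
  d <- dim(a)
  ys <- seq_len(d[1]) - dy
  xs <- seq_len(d[2]) - dx
  zs <- seq_len(d[3]) - dz
  ok_y <- ys >= 1 & ys <= d[1]
  ok_x <- xs >= 1 & xs <= d[2]
  ok_z <- zs >= 1 & zs <= d[3]
  out <- array(fill, d)
  out[ok_y, ok_x, ok_z] <- a[ys[ok_y], xs[ok_x], zs[ok_z]]
  out
}

# Connected-component labelling at explicit connectivity via igraph.
# Components are numbered 1..N in raster-scan order of their first pixel.
label_components <- function(mask, connectivity = if (length(dim(mask)) == 3L) 6 else 8) {
  nd <- length(dim(mask))
  m3 <- as_arr3(mask) > 0
  d <- dim(m3)
  fg <- which(m3)
  out <- array(0L, d)
  if (length(fg) > 0L) {
    rank <- integer(prod(d))
    rank[fg] <- seq_along(fg)
    offs <- neighbour_offsets(connectivity)
    edges <- vector("list", nrow(offs))
    coord <- arrayInd(fg, d)
    for (i in seq_len(nrow(offs))) {
      ny <- coord[, 1] + offs[i, 1]
      nx <- coord[, 2] + offs[i, 2]
      nz <- coord[, 3] + offs[i, 3]
      ok <- ny >= 1 & ny <= d[1] & nx >= 1 & nx <= d[2] & nz >= 1 & nz <= d[3]
      if (!any(ok)) next
      nb <- (nz[ok] - 1L) * d[1] * d[2] + (nx[ok] - 1L) * d[1] + ny[ok]
      both <- m3[nb]
      if (!any(both)) next
      edges[[i]] <- cbind(rank[fg[ok][both]], rank[nb[both]])
    }
    e <- do.call(rbind, edges)
    g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
    if (!is.null(e) && nrow(e) > 0L) g <- igraph::add_edges(g, t(e))
    memb <- igraph::components(g)$membership
    # renumber so label order follows raster order of first pixel
    first <- tapply(seq_along(fg), memb, min)
    newid <- integer(length(first))
    newid[order(first)] <- seq_along(first)
    out[fg] <- newid[memb]
  }
  if (nd == 2L) out <- out[, , 1L]
  out
}

# Otsu threshold of the values in `v` (vector form, so masks are easy).
# Returns +Inf for degenerate (zero-range) input so that nothing passes.
otsu_threshold <- function(v, levels = 256L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (length(v) < 2L || diff(rng) <= 0) return(Inf)
  as.numeric(EBImage::otsu(matrix(v, ncol = 1L), range = rng, levels = levels))
}

# Strict local maxima of `arr` restricted to `mask`.
local_maxima <- function(arr, mask = NULL, connectivity = if (length(dim(arr)) == 3L) 26 else 8) {
  nd <- length(dim(arr))
  a3 <- as_arr3(arr)
  offs <- neighbour_offsets(connectivity)
  is_max <- array(TRUE, dim(a3))
  for (i in seq_len(nrow(offs))) {
    nb <- shift3(a3, offs[i, 1], offs[i, 2], offs[i, 3], fill = -Inf)
    is_max <- is_max & (a3 > nb)
  }
  if (!is.null(mask)) is_max <- is_max & (as_arr3(mask) > 0)
  if (nd == 2L) is_max <- is_max[, , 1L]
  is_max
}

# Seeded watershed: grow labelled seeds into `mask`, flooding from high to
# low `intensity`; ties between competing basins resolved toward the lowest
# label. Label count equals seed-region count by construction. Each
# connected component of the mask is flooded inside its own bounding box,
# which keeps the level-set iteration cheap on sparse masks.
seeded_watershed <- function(intensity, seeds, mask, n_levels = 64L) {
  a <- as_arr3(intensity)
  s <- as_arr3(seeds)
  m <- as_arr3(mask) > 0
  stopifnot(identical(dim(a), dim(s)), identical(dim(a), dim(m)))
  connectivity <- if (dim(a)[3] > 1L) 6 else 4
  lab <- array(0L, dim(a))
  comp <- label_components(m, connectivity = connectivity)
  comp <- as_arr3(comp)
  for (ci in seq_len(max(comp))) {
    sel <- which(comp == ci)
    if (!any(s[sel] > 0L)) next
    co <- arrayInd(sel, dim(a))
    y0 <- min(co[, 1]); y1 <- max(co[, 1])
    x0 <- min(co[, 2]); x1 <- max(co[, 2])
    z0 <- min(co[, 3]); z1 <- max(co[, 3])
    sub <- flood_box(a[y0:y1, x0:x1, z0:z1, drop = FALSE],
                     s[y0:y1, x0:x1, z0:z1, drop = FALSE],
                     comp[y0:y1, x0:x1, z0:z1, drop = FALSE] == ci,
                     connectivity, n_levels)
    nz <- sub > 0L
    lab[y0:y1, x0:x1, z0:z1][nz] <- sub[nz]
  }
  if (length(dim(intensity)) == 2L) lab <- lab[, , 1L]
  lab
}

# Level-set flooding inside one cropped component.
flood_box <- function(a, s, m, connectivity, n_levels) {
  offs <- neighbour_offsets(connectivity)
  d <- dim(a)
  lab <- array(0L, d)
  lab[m & s > 0L] <- s[m & s > 0L]
  todo <- m & lab == 0L
  if (!any(todo) || !any(lab > 0L)) return(lab)
  neigh_min <- function() {
    nmin <- array(Inf, d)
    for (i in seq_len(nrow(offs))) {
      nb <- shift3(lab, offs[i, 1], offs[i, 2], offs[i, 3], fill = 0L)
      nmin <- pmin(nmin, ifelse(nb > 0L, nb, Inf))
    }
    nmin
  }
  vals <- a[todo]
  levels <- rev(sort(unique(stats::quantile(
    vals, probs = seq(0, 1, length.out = min(n_levels, length(vals))),
    names = FALSE, type = 1L))))
  for (lev in levels) {
    repeat {
      nmin <- neigh_min()
      cand <- todo & is.finite(nmin) & a >= lev
      if (!any(cand)) break
      lab[cand] <- as.integer(nmin[cand])
      todo[cand] <- FALSE
    }
  }
  repeat {  # residual voxels below the lowest sampled level
    nmin <- neigh_min()
    cand <- todo & is.finite(nmin)
    if (!any(cand)) break
    lab[cand] <- as.integer(nmin[cand])
    todo[cand] <- FALSE
  }
  lab
}

# Local (box) mean with symmetric edge padding, via integral image.
box_mean <- function(img, w) {
  stopifnot(w %% 2 == 1, w >= 3)
  r <- (w - 1L) %/% 2L
  ny <- nrow(img); nx <- ncol(img)
  if (ny < w || nx < w) abort("image smaller than the neighbourhood window")
  iy <- c(r:1, seq_len(ny), ny:(ny - r + 1L))
  ix <- c(r:1, seq_len(nx), nx:(nx - r + 1L))
  p <- img[iy, ix, drop = FALSE]
  cs <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  z <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  z[-1, -1] <- cs
  y1 <- seq_len(ny); x1 <- seq_len(nx)
  s <- z[y1 + w, x1 + w, drop = FALSE] - z[y1, x1 + w, drop = FALSE] -
    z[y1 + w, x1, drop = FALSE] + z[y1, x1, drop = FALSE]
  s / (w * w)
}

# Binary morphology with an explicit structuring element, done with shifts
# so it works identically in 2D and 3D (EBImage's brushes are 2D only).
erode_se <- function(mask, offs) {
  m <- as_arr3(mask) > 0
  out <- array(TRUE, dim(m))
  for (i in seq_len(nrow(offs))) {
    out <- out & shift3(m, offs[i, 1], offs[i, 2], offs[i, 3], fill = FALSE)
  }
  if (length(dim(mask)) == 2L) out[, , 1L] else out
}

dilate_se <- function(mask, offs) {
  m <- as_arr3(mask) > 0
  out <- array(FALSE, dim(m))
  for (i in seq_len(nrow(offs))) {
    out <- out | shift3(m, -offs[i, 1], -offs[i, 2], -offs[i, 3], fill = FALSE)
  }
  if (length(dim(mask)) == 2L) out[, , 1L] else out
}

# Structuring-element offsets: full box (ones) of side `size` in 2D, or a
# 6-connected cross in 3D when `cross3d`.
se_offsets <- function(size = 3L, dims = 2L, cross3d = TRUE) {
  r <- (size - 1L) %/% 2L
  if (dims == 2L) {
    g <- expand.grid(dy = -r:r, dx = -r:r, dz = 0L)
  } else if (cross3d) {
    g <- as.data.frame(rbind(c(0, 0, 0), neighbour_offsets(6)))
    names(g) <- c("dy", "dx", "dz")
  } else {
    g <- expand.grid(dy = -r:r, dx = -r:r, dz = -r:r)
  }
  unname(as.matrix(g))
}

binary_opening <- function(mask, offs) {
  dilate_se(erode_se(mask, offs), offs)
}

# Fill background holes of a 2D or 3D binary mask: background components
# not touching the array border become foreground.
fill_holes <- function(mask) {
  m3 <- as_arr3(mask)
  d <- dim(m3)
  bg <- label_components(!(m3 > 0), connectivity = if (d[3] > 1L) 6 else 4)
  bg3 <- as_arr3(bg)
  border <- array(FALSE, d)
  border[c(1L, d[1]), , ] <- TRUE
  border[, c(1L, d[2]), ] <- TRUE
  if (d[3] > 1L) border[, , c(1L, d[3])] <- TRUE
  touching <- unique(bg3[border & bg3 > 0L])
  hole <- bg3 > 0L & !(bg3 %in% touching)
  out <- (m3 > 0) | hole
  if (length(dim(mask)) == 2L) out[, , 1L] else out
}

# Object sizes of a label array as a named integer vector.
label_sizes <- function(labels) {
  tab <- tabulate(labels[labels > 0L])
  setNames(tab, seq_along(tab))
}

# Drop labels below `min_size` pixels and renumber consecutively.
prune_small <- function(labels, min_size) {
  if (max(labels) == 0L) return(labels)
  sizes <- tabulate(labels[labels > 0L], nbins = max(labels))
  keep <- which(sizes >= min_size)
  map <- integer(max(labels))
  map[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0L] <- map[labels[labels > 0L]]
  out
}

# Renumber arbitrary non-negative integer labels to consecutive 1..N,
# ordered by first raster occurrence.
relabel_consecutive <- function(labels) {
  pos <- which(labels > 0L)
  if (length(pos) == 0L) return(labels)
  u <- unique(labels[pos])  # first-occurrence order == raster order
  map <- integer(max(u))
  map[u] <- seq_along(u)
  out <- labels
  out[pos] <- map[labels[pos]]
  out
}
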