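# Independent brute-force oracles used to validate the package's raster and
# sequence primitives. These deliberately share no code with the package
# implementation.

# Flood-fill connected-component labelling (queue-based BFS).
oracle_label <- function(mask, connectivity = 8) {
  m <- mask > 0
  nd <- length(dim(m))
  if (nd == 2L) m <- array(m, c(dim(m), 1L))
  d <- dim(m)
  offs <- switch(as.character(connectivity),
    "4" = list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0)),
    "8" = {
      o <- list()
      for (dy in -1:1) for (dx in -1:1)
        if (!(dy == 0 && dx == 0)) o[[length(o) + 1]] <- c(dy, dx, 0)
      o
    },
    "6" = list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
               c(0, 0, -1), c(0, 0, 1))
  )
  lab <- array(0L, d)
  nextlab <- 0L
  for (start in seq_len(prod(d))) {
    if (!m[start] || lab[start] > 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      cc <- arrayInd(cur, d)
      for (o in offs) {
        y <- cc[1] + o[1]; x <- cc[2] + o[2]; z <- cc[3] + o[3]
        if (y < 1 || y > d[1] || x < 1 || x > d[2] || z < 1 || z > d[3]) next
        li <- (z - 1L) * d[1] * d[2] + (x - 1L) * d[1] + y
        if (m[li] && lab[li] == 0L) {
          lab[li] <- nextlab
          queue <- c(queue, li)
        }
      }
    }
  }
  if (nd == 2L) lab <- lab[, , 1L]
  lab
}

# Label arrays agree up to renumbering.
same_partition <- function(a, b) {
  if (!identical(dim(a), dim(b))) return(FALSE)
  if (!identical(a > 0, b > 0)) return(FALSE)
  fa <- as.integer(a[a > 0]); fb <- as.integer(b[b > 0])
  length(unique(fa)) == length(unique(fb)) &&
    !anyDuplicated(unique(cbind(fa, fb)))
}

# Naive windowed mean with symmetric padding (loop form).
oracle_box_mean <- function(img, w) {
  r <- (w - 1) / 2
  ny <- nrow(img); nx <- ncol(img)
  iy <- c(r:1, 1:ny, ny:(ny - r + 1))
  ix <- c(r:1, 1:nx, nx:(nx - r + 1))
  p <- img[iy, ix]
  out <- matrix(0, ny, nx)
  for (y in 1:ny) for (x in 1:nx)
    out[y, x] <- mean(p[y:(y + w - 1), x:(x + w - 1)])
  out
}

# Regex-free quadruplex enumerator: walks every window and every tract
# placement directly on the character vector.
oracle_g4_candidates <- function(seq, min_g = 2, max_len = 20) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  hits <- list()
  is_g_run <- function(p, g) p + g - 1 <= n && all(chars[p:(p + g - 1)] == "G")
  safe_seq <- function(from, to) if (from > to) integer(0) else from:to
  for (s in seq_len(n)) {
    last <- min(n, s + max_len - 1)  # window end bound
    for (g in safe_seq(min_g, floor(max_len / 4))) {
      if (!is_g_run(s, g)) next
      for (p2 in safe_seq(s + g, last)) {
        if (!is_g_run(p2, g)) next
        for (p3 in safe_seq(p2 + g, last)) {
          if (!is_g_run(p3, g)) next
          for (p4 in safe_seq(p3 + g, last)) {
            if (p4 + g - 1 > last) next
            if (!is_g_run(p4, g)) next
            hits[[length(hits) + 1]] <- c(start = s, end = p4 + g - 1,
                                          g_group = g,
                                          loop1 = p2 - s - g,
                                          loop2 = p3 - p2 - g,
                                          loop3 = p4 - p3 - g)
          }
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), end = integer(), g_group = integer(),
                      loop1 = integer(), loop2 = integer(), loop3 = integer()))
  }
  unique(as.data.frame(do.call(rbind, hits)))
}

# Independent net-charge / pI arithmetic on a fine pH grid.
oracle_pi_grid <- function(sequence, nterm, cterm, pos, neg, step = 1e-4) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  charge <- function(pH) {
    z <- 1 / (1 + 10^(pH - nterm)) - 1 / (1 + 10^(cterm - pH))
    for (r in names(pos)) z <- z + sum(aa == r) / (1 + 10^(pH - pos[[r]]))
    for (r in names(neg)) z <- z - sum(aa == r) / (1 + 10^(neg[[r]] - pH))
    z
  }
  grid <- seq(0, 14, by = step)
  zz <- vapply(grid, charge, numeric(1))
  grid[which.min(abs(zz))]
}

# Random G-rich test sequence.
random_grich <- function(n, p_g = 0.4, seed = 1) {
  withr::with_seed(seed, {
    paste(sample(c("G", "A", "U", "C"), n, replace = TRUE,
                 prob = c(p_g, (1 - p_g) / 3, (1 - p_g) / 3, (1 - p_g) / 3)),
          collapse = "")
  })
}
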