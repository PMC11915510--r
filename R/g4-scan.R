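# G-quadruplex motif scanner: four equal-length G-tracts within a bounded
# window, QGRS-style pattern parameters (minimal G-group, maximum length).

#' Scan a sequence for G-quadruplex-forming motifs
#'
#' Enumerates every window of at most `max_len` nucleotides matching
#' `G{g} N* G{g} N* G{g} N* G{g}` with four G-tracts of equal length
#' `g >= min_g` (loops may contain G). Overlapping candidates are collapsed
#' deterministically: within each overlap family the hit with the largest
#' `g`, then the shortest total length, then the smallest start is kept, so
#' retained hits never overlap. Numeric motif scoring is a pluggable hook
#' (`score_fun`); the default collapse rule approximates
#' highest-score-first selection.
#'
#' All positions are 1-based and inclusive.
#'
#' @param seq DNA/RNA string over `A C G T U` (case-insensitive).
#' @param min_g Minimal G-tract (G-group) length, default 2.
#' @param max_len Maximum motif length in nucleotides, default 20.
#' @param min_loop Minimal loop length (default 0).
#' @param regions Optional region annotation tibble with columns `name`,
#'   `start`, `end` (1-based inclusive, non-overlapping) for per-region
#'   counting of retained hits by start position.
#' @param score_fun Optional function `(g_group, loops, total_len) -> numeric`
#'   used to rank candidates before the deterministic tie-breaks.
#' @return A tibble of retained hits: `start`, `end`, `g_group`, `loop1`,
#'   `loop2`, `loop3`, `total_len`, `sequence`. If `regions` is supplied, a
#'   per-region count tibble is attached as attribute `region_counts`.
#' @export
scan_g4 <- function(seq, min_g = 2, max_len = 20, min_loop = 0,
                    regions = NULL, score_fun = NULL) {
  s <- toupper(gsub("\\s", "", seq))
  chars <- strsplit(s, "")[[1]]
  if (length(chars) && !all(chars %in% c("A", "C", "G", "T", "U")))
    abort("sequence must be over {A, C, G, T, U}")
  n <- length(chars)
  cand <- enumerate_g4(chars, min_g, max_len, min_loop)
  kept <- collapse_g4(cand, score_fun)
  kept$sequence <- if (nrow(kept)) substring(s, kept$start, kept$end) else character()
  if (!is.null(regions)) {
    check_regions(regions, n)
    counts <- vapply(seq_len(nrow(regions)), function(i) {
      sum(kept$start >= regions$start[i] & kept$start <= regions$end[i])
    }, integer(1))
    attr(kept, "region_counts") <- tibble(name = regions$name, n_hits = counts)
  }
  kept
}

# All candidate quadruplex windows. Vectorised over start positions for
# each (g, loop-composition) pair.
enumerate_g4 <- function(chars, min_g, max_len, min_loop) {
  n <- length(chars)
  isg <- as.integer(chars == "G")
  cg <- c(0L, cumsum(isg))
  all_g <- function(p, g) cg[p + g] - cg[p] == g  # tract of g Gs at p
  out <- list()
  g_max <- (max_len - 3 * min_loop) %/% 4
  for (g in seq_len(max(g_max, 0))) {
    if (g < min_g) next
    loop_budget <- max_len - 4 * g
    if (loop_budget < 3 * min_loop) next
    loops <- expand.grid(l1 = min_loop:loop_budget,
                         l2 = min_loop:loop_budget,
                         l3 = min_loop:loop_budget)
    loops <- loops[rowSums(loops) <= loop_budget, , drop = FALSE]
    for (i in seq_len(nrow(loops))) {
      l1 <- loops$l1[i]; l2 <- loops$l2[i]; l3 <- loops$l3[i]
      total <- 4 * g + l1 + l2 + l3
      if (total > n) next
      starts <- seq_len(n - total + 1L)
      p2 <- starts + g + l1
      p3 <- p2 + g + l2
      p4 <- p3 + g + l3
      ok <- all_g(starts, g) & all_g(p2, g) & all_g(p3, g) & all_g(p4, g)
      if (any(ok)) {
        out[[length(out) + 1L]] <- tibble(
          start = as.integer(starts[ok]), g_group = as.integer(g),
          loop1 = as.integer(l1), loop2 = as.integer(l2),
          loop3 = as.integer(l3), total_len = as.integer(total))
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(start = integer(), g_group = integer(), loop1 = integer(),
                  loop2 = integer(), loop3 = integer(), total_len = integer(),
                  end = integer()))
  }
  cand <- dplyr::bind_rows(out)
  cand$end <- cand$start + cand$total_len - 1L
  cand
}

# Greedy non-overlapping selection: best score first, then largest g,
# shortest total length, smallest start.
collapse_g4 <- function(cand, score_fun = NULL) {
  cols <- c("start", "end", "g_group", "loop1", "loop2", "loop3", "total_len")
  if (nrow(cand) == 0L) return(cand[, cols])
  if (!is.null(score_fun)) {
    sc <- vapply(seq_len(nrow(cand)), function(i) {
      score_fun(cand$g_group[i],
                c(cand$loop1[i], cand$loop2[i], cand$loop3[i]),
                cand$total_len[i])
    }, numeric(1))
    ord <- order(-sc, -cand$g_group, cand$total_len, cand$start)
  } else {
    ord <- order(-cand$g_group, cand$total_len, cand$start)
  }
  cand <- cand[ord, , drop = FALSE]
  kept_start <- integer(0); kept_end <- integer(0); keep_idx <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] <= kept_end & cand$end[i] >= kept_start)) {
      keep_idx <- c(keep_idx, i)
      kept_start <- c(kept_start, cand$start[i])
      kept_end <- c(kept_end, cand$end[i])
    }
  }
  kept <- cand[keep_idx, , drop = FALSE]
  kept <- kept[order(kept$start), cols]
  kept
}

check_regions <- function(regions, n) {
  need <- c("name", "start", "end")
  if (!all(need %in% names(regions)))
    abort("`regions` must have columns name, start, end")
  if (any(regions$start < 1 | regions$end > n | regions$start > regions$end))
    abort("regions must lie within the sequence bounds")
  r <- regions[order(regions$start), ]
  if (nrow(r) > 1L && any(r$start[-1] <= r$end[-nrow(r)]))
    abort("regions must not overlap")
  invisible(TRUE)
}

#' Read a BED-like region annotation
#'
#' Three-column TSV (`name`, `start`, `end`) with BED-convention 0-based
#' half-open coordinates, converted on read to the 1-based inclusive
#' positions used by [scan_g4()].
#'
#' @param path TSV path (no header).
#' @return A tibble with `name`, `start`, `end` (1-based inclusive).
#' @export
read_regions_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("name", "start", "end"),
                          stringsAsFactors = FALSE)
  tibble(name = as.character(df$name),
         start = as.integer(df$start) + 1L,
         end = as.integer(df$end))
}
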