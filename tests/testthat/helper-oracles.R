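# Independent brute-force oracles used across the suite.  These are kept
# deliberately naive (linear scans, double loops) so they share no code
# path with the implementations they check.

brute_overlap <- function(records, region) {
  which(records$chrom == region$chrom &
          records$start < region$end &
          records$end > region$start)
}

# Bin edges per the summary contract: integer width, last bin absorbs the
# remainder, bin count clamped to the region width.
oracle_bin_edges <- function(region, nbins) {
  len <- region$end - region$start
  nbins <- max(1, min(nbins, len))
  w <- floor(len / nbins)
  list(nbins = nbins,
       lo = region$start + (seq_len(nbins) - 1) * w,
       hi = c(region$start + seq_len(nbins - 1) * w, region$end))
}

oracle_summary_count <- function(records, region, nbins) {
  be <- oracle_bin_edges(region, nbins)
  vapply(seq_len(be$nbins), function(b) {
    sum(records$chrom == region$chrom &
          records$start < be$hi[b] & records$end > be$lo[b])
  }, 0)
}

oracle_summary_stat <- function(records, region, nbins, stat) {
  be <- oracle_bin_edges(region, nbins)
  vapply(seq_len(be$nbins), function(b) {
    sel <- records$chrom == region$chrom &
      records$start < be$hi[b] & records$end > be$lo[b]
    if (!any(sel)) return(NA_real_)
    v <- records$value[sel]
    if (stat == "max") return(max(v))
    if (stat == "min") return(min(v))
    ov <- pmin(records$end[sel], be$hi[b]) - pmax(records$start[sel], be$lo[b])
    sum(ov * v) / sum(ov)
  }, 0)
}

# Maximum interval overlap depth via an event sweep.
sweep_line_depth <- function(starts, ends) {
  if (!length(starts)) return(0L)
  ev <- rbind(data.frame(pos = starts, d = 1L), data.frame(pos = ends, d = -1L))
  ev <- ev[order(ev$pos, ev$d), ]  # ends (-1) before starts at equal pos
  as.integer(max(cumsum(ev$d)))
}

oracle_filter_keep <- function(records, filters) {
  vapply(seq_len(nrow(records)), function(i) {
    for (f in filters) {
      v <- if (f$attribute == "score") {
        records$score[i]
      } else {
        a <- records$attributes[[i]]
        if (f$attribute %in% names(a)) suppressWarnings(as.numeric(a[[f$attribute]]))
        else NA_real_
      }
      ok <- if (is.na(v)) f$missing_passes else (v >= f$min && v <= f$max)
      if (!ok) return(FALSE)
    }
    TRUE
  }, TRUE)
}

random_region <- function(genome, min_width = 10) {
  ci <- sample.int(nrow(genome$chromosomes), 1)
  len <- genome$chromosomes$length[ci]
  w <- sample.int(max(len - 1, min_width), 1)
  w <- max(w, min_width)
  s <- sample.int(max(len - w, 1), 1) - 1
  gv_region(genome$chromosomes$name[ci], s, min(s + w, len))
}

canonical_features <- function(f) {
  d <- data.frame(chrom = f$chrom, start = f$start, end = f$end,
                  name = f$name, score = f$score, strand = f$strand,
                  stringsAsFactors = FALSE)
  d[order(d$chrom, d$start, d$end, d$name), , drop = FALSE]
}

tree_isomorphic <- function(a, b) {
  if (!identical(a$name %||% "", b$name %||% "")) return(FALSE)
  la <- a$branch_length; lb <- b$branch_length
  if (is.null(la) != is.null(lb)) return(FALSE)
  if (!is.null(la) && abs(la - lb) > 1e-12 * max(1, abs(la))) return(FALSE)
  if (length(a$children) != length(b$children)) return(FALSE)
  all(vapply(seq_along(a$children), function(i) {
    tree_isomorphic(a$children[[i]], b$children[[i]])
  }, TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_tree <- function(n_leaves, with_lengths = TRUE) {
  generate_tree(sample.int(1e6, 1), n_leaves = n_leaves,
                bl_range = if (with_lengths) c(0.01, 2) else c(1, 1))
}
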