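#' Feature records
#'
#' Parsed annotation records are held in an ordinary data frame of class
#' `gv_features` with columns `chrom`, `start`, `end` (0-based half-open),
#' `name`, `score`, `strand` (`"+"`, `"-"`, `"*"`), `thick_start`,
#' `thick_end`, `blocks` (list column of two-column matrices
#' `cbind(start, size)` in absolute coordinates, or `NULL`), `attributes`
#' (list column of named character vectors; empty for BED) and
#' `source_line` (1-based line number in the source file).
#'
#' @param df Data frame with at least `chrom`, `start`, `end`.
#' @param skipped Number of non-record lines (track/browser/comment)
#'   skipped during parsing; stored as attribute `skipped`.
#' @return A `gv_features` data frame.
#' @export
gv_features <- function(df, skipped = 0L) {
  n <- nrow(df)
  out <- data.frame(
    chrom = as.character(df$chrom),
    start = as.numeric(df$start),
    end = as.numeric(df$end),
    name = if (!is.null(df$name)) as.character(df$name) else rep(NA_character_, n),
    score = if (!is.null(df$score)) as.numeric(df$score) else rep(NA_real_, n),
    strand = if (!is.null(df$strand)) as.character(df$strand) else rep("*", n),
    thick_start = if (!is.null(df$thick_start)) as.numeric(df$thick_start) else rep(NA_real_, n),
    thick_end = if (!is.null(df$thick_end)) as.numeric(df$thick_end) else rep(NA_real_, n),
    source_line = if (!is.null(df$source_line)) as.integer(df$source_line) else seq_len(n),
    stringsAsFactors = FALSE
  )
  out$blocks <- if (!is.null(df$blocks)) df$blocks else rep(list(NULL), n)
  out$attributes <- if (!is.null(df$attributes)) df$attributes else rep(list(character(0)), n)
  class(out) <- c("gv_features", "data.frame")
  attr(out, "skipped") <- as.integer(skipped)
  out
}

is_skip_line <- function(lines) {
  !nzchar(trimws(lines)) | startsWith(lines, "#") |
    startsWith(lines, "track") | startsWith(lines, "browser")
}

check_coords <- function(start, end, lineno, what = "feature") {
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad)) {
    i <- bad[1]
    gv_error(sprintf("line %d: invalid %s coordinates [%s, %s)",
                     lineno[i], what, format(start[i]), format(end[i])),
             "gv_parse_error")
  }
  invisible(TRUE)
}

parse_score <- function(x) {
  x[x == "." | x == ""] <- NA_character_
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(v))
  if (length(bad)) gv_error(sprintf("non-numeric score '%s'", x[bad[1]]),
                            "gv_parse_error")
  v
}

norm_strand <- function(x) {
  x[is.na(x) | x == "." | x == ""] <- "*"
  bad <- which(!x %in% c("+", "-", "*"))
  if (length(bad)) gv_error(sprintf("invalid strand '%s'", x[bad[1]]),
                            "gv_parse_error")
  x
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

field_or_na <- function(parts, i) {
  vapply(parts, function(p) if (length(p) >= i) p[[i]] else NA_character_, "")
}

#' Read an annotation file into feature records
#'
#' Supported formats: BED 3-12 (`"bed"`), GFF3 (`"gff3"`), GTF (`"gtf"`)
#' and a configurable tab-separated interval dialect (`"interval"`), plus a
#' minimal text SAM reader (`"sam"`) that maps each aligned read to a
#' feature carrying a `mapq` attribute.  The format is always declared by
#' the caller; there is no sniffing.  GFF/GTF 1-based closed coordinates
#' are converted to the internal 0-based half-open convention at parse
#' time; BED passes through.  Track, browser and comment lines are skipped
#' and counted in the `skipped` attribute of the result.
#'
#' @param path Input file path.
#' @param format One of `"bed"`, `"gff3"`, `"gtf"`, `"interval"`, `"sam"`.
#' @param interval_cols For `format = "interval"`: named list giving the
#'   1-based column indices of `chrom`, `start`, `end` and optionally
#'   `strand` and `name` (the dialect is configuration, not guessed).
#' @return A [gv_features()] data frame.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tfA\t960\t+", bed)
#' read_features(bed, "bed")
#' @export
read_features <- function(path, format = c("bed", "gff3", "gtf", "interval", "sam"),
                          interval_cols = list(chrom = 1, start = 2, end = 3)) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  skip <- if (format == "sam") startsWith(lines, "@") | !nzchar(trimws(lines))
          else is_skip_line(lines)
  skipped <- sum(skip)
  lines <- lines[!skip]; lineno <- lineno[!skip]
  if (!length(lines)) return(gv_features(data.frame(chrom = character(0),
                                                    start = numeric(0),
                                                    end = numeric(0)),
                                         skipped))
  parts <- split_fields(lines)
  switch(format,
    bed = parse_bed(parts, lineno, skipped),
    gff3 = parse_gff(parts, lineno, skipped, dialect = "gff3"),
    gtf = parse_gff(parts, lineno, skipped, dialect = "gtf"),
    interval = parse_interval(parts, lineno, skipped, interval_cols),
    sam = parse_sam(parts, lineno, skipped)
  )
}

parse_bed <- function(parts, lineno, skipped) {
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    i <- which(nf < 3L)[1]
    gv_error(sprintf("line %d: BED needs at least 3 fields, got %d",
                     lineno[i], nf[i]), "gv_parse_error")
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  check_coords(start, end, lineno)
  name <- field_or_na(parts, 4L)
  name[name == "."] <- NA_character_
  score <- parse_score(field_or_na(parts, 5L))
  strand <- norm_strand(field_or_na(parts, 6L))
  thick_start <- suppressWarnings(as.numeric(field_or_na(parts, 7L)))
  thick_end <- suppressWarnings(as.numeric(field_or_na(parts, 8L)))
  blocks <- rep(list(NULL), length(parts))
  has12 <- nf >= 12L
  for (i in which(has12)) {
    nb <- as.integer(parts[[i]][10L])
    sizes <- as.numeric(strsplit(parts[[i]][11L], ",", fixed = TRUE)[[1]])
    starts <- as.numeric(strsplit(parts[[i]][12L], ",", fixed = TRUE)[[1]])
    if (length(sizes) != nb || length(starts) != nb) {
      gv_error(sprintf("line %d: blockCount %d does not match block lists",
                       lineno[i], nb), "gv_parse_error")
    }
    abs_start <- start[i] + starts
    if (is.unsorted(abs_start, strictly = TRUE) ||
        any(abs_start < start[i]) || any(abs_start + sizes > end[i]) ||
        any(abs_start[-1] < (abs_start + sizes)[-nb])) {
      gv_error(sprintf("line %d: blocks must be sorted, non-overlapping, within the feature",
                       lineno[i]), "gv_parse_error")
    }
    blocks[[i]] <- cbind(start = abs_start, size = sizes)
  }
  d <- data.frame(chrom = chrom, start = start, end = end, name = name,
                  score = score, strand = strand,
                  thick_start = thick_start, thick_end = thick_end,
                  source_line = lineno, stringsAsFactors = FALSE)
  d$blocks <- blocks
  gv_features(d, skipped)
}

parse_gff_attributes <- function(text, dialect) {
  if (is.na(text) || text == "." || !nzchar(text)) return(character(0))
  items <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  items <- items[nzchar(items)]
  if (dialect == "gtf") {
    keys <- sub("^(\\S+)\\s.*$", "\\1", items)
    vals <- sub('^\\S+\\s+"?([^"]*)"?$', "\\1", items)
  } else {
    keys <- sub("=.*$", "", items)
    vals <- sub("^[^=]*=", "", items)
  }
  stats::setNames(vals, keys)
}

parse_gff <- function(parts, lineno, skipped, dialect) {
  nf <- lengths(parts)
  if (any(nf < 8L)) {
    i <- which(nf < 8L)[1]
    gv_error(sprintf("line %d: %s needs 9 tab-separated fields, got %d",
                     lineno[i], toupper(dialect), nf[i]), "gv_parse_error")
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4L))) - 1
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 5L)))
  check_coords(start, end, lineno)
  score <- parse_score(vapply(parts, `[[`, "", 6L))
  strand <- norm_strand(vapply(parts, `[[`, "", 7L))
  attrs <- lapply(field_or_na(parts, 9L), parse_gff_attributes, dialect = dialect)
  name <- vapply(attrs, function(a) {
    for (k in c("Name", "ID", "gene_id")) {
      if (k %in% names(a)) return(unname(a[[k]]))
    }
    NA_character_
  }, "")
  d <- data.frame(chrom = chrom, start = start, end = end, name = name,
                  score = score, strand = strand, source_line = lineno,
                  stringsAsFactors = FALSE)
  d$attributes <- attrs
  gv_features(d, skipped)
}

parse_interval <- function(parts, lineno, skipped, cols) {
  need <- max(unlist(cols))
  nf <- lengths(parts)
  if (any(nf < need)) {
    i <- which(nf < need)[1]
    gv_error(sprintf("line %d: interval dialect needs %d fields, got %d",
                     lineno[i], need, nf[i]), "gv_parse_error")
  }
  start <- suppressWarnings(as.numeric(field_or_na(parts, cols$start)))
  end <- suppressWarnings(as.numeric(field_or_na(parts, cols$end)))
  check_coords(start, end, lineno)
  d <- data.frame(
    chrom = field_or_na(parts, cols$chrom), start = start, end = end,
    name = if (!is.null(cols$name)) field_or_na(parts, cols$name) else NA_character_,
    strand = if (!is.null(cols$strand)) norm_strand(field_or_na(parts, cols$strand)) else "*",
    source_line = lineno, stringsAsFactors = FALSE
  )
  gv_features(d, skipped)
}

# Reference bases consumed by a CIGAR string; M/D/N (and =/X) consume,
# I/S do not.  Unsupported operators are an error.
cigar_ref_span <- function(cigar) {
  if (cigar == "*") return(NA_real_)
  ops <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1]]
  if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cigar)) {
    gv_error(sprintf("unparseable CIGAR '%s'", cigar), "gv_parse_error")
  }
  n <- as.numeric(sub("[A-Z=]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  if (any(!op %in% c("M", "I", "D", "N", "S", "=", "X", "H", "P"))) {
    gv_error(sprintf("unsupported CIGAR operator in '%s'", cigar), "gv_parse_error")
  }
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}

parse_sam <- function(parts, lineno, skipped) {
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    i <- which(nf < 11L)[1]
    gv_error(sprintf("line %d: SAM alignment needs 11 fields, got %d",
                     lineno[i], nf[i]), "gv_parse_error")
  }
  flag <- as.integer(vapply(parts, `[[`, "", 2L))
  rname <- vapply(parts, `[[`, "", 3L)
  mapped <- rname != "*" & bitwAnd(flag, 4L) == 0L
  parts <- parts[mapped]; lineno <- lineno[mapped]
  skipped <- skipped + sum(!mapped)
  if (!length(parts)) {
    return(gv_features(data.frame(chrom = character(0), start = numeric(0),
                                  end = numeric(0)), skipped))
  }
  pos <- as.numeric(vapply(parts, `[[`, "", 4L))
  span <- vapply(parts, function(p) cigar_ref_span(p[[6L]]), 0)
  span[is.na(span)] <- 1
  start <- pos - 1
  end <- start + pmax(span, 1)
  check_coords(start, end, lineno, "alignment")
  mapq <- vapply(parts, `[[`, "", 5L)
  strand <- ifelse(bitwAnd(as.integer(vapply(parts, `[[`, "", 2L)), 16L) != 0L, "-", "+")
  d <- data.frame(chrom = vapply(parts, `[[`, "", 3L), start = start, end = end,
                  name = vapply(parts, `[[`, "", 1L), strand = strand,
                  source_line = lineno, stringsAsFactors = FALSE)
  d$attributes <- lapply(mapq, function(q) c(mapq = q))
  gv_features(d, skipped)
}

#' Write feature records to BED or GFF3
#'
#' Writing then re-reading reproduces coordinates, names, scores and
#' strands exactly (canonical form).  GFF3 output converts the internal
#' 0-based half-open coordinates back to 1-based closed (column 4 is
#' `start + 1`).  Features carrying GFF attributes written to BED lose
#' their attributes; this produces a warning, not an error.
#'
#' @param features A [gv_features()] data frame.
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`.
#' @return The number of records written, invisibly.
#' @export
write_features <- function(features, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  n <- nrow(features)
  if (format == "bed") {
    if (any(lengths(features$attributes) > 0)) {
      warning("GFF attributes are dropped when writing BED", call. = FALSE)
    }
    has_blocks <- any(!vapply(features$blocks, is.null, TRUE))
    lines <- vapply(seq_len(n), function(i) {
      f <- features[i, ]
      base <- c(f$chrom, format(f$start, scientific = FALSE),
                format(f$end, scientific = FALSE),
                if (is.na(f$name)) "." else f$name,
                if (is.na(f$score)) "." else format(f$score, scientific = FALSE),
                if (f$strand == "*") "." else f$strand)
      b <- features$blocks[[i]]
      if (!is.null(b)) {
        base <- c(base,
                  format(if (is.na(f$thick_start)) f$start else f$thick_start, scientific = FALSE),
                  format(if (is.na(f$thick_end)) f$end else f$thick_end, scientific = FALSE),
                  "0", as.character(nrow(b)),
                  paste0(paste(format(b[, "size"], scientific = FALSE, trim = TRUE), collapse = ","), ","),
                  paste0(paste(format(b[, "start"] - f$start, scientific = FALSE, trim = TRUE), collapse = ","), ","))
      } else if (has_blocks) {
        base <- c(base, format(f$start, scientific = FALSE),
                  format(f$end, scientific = FALSE), "0", "1",
                  paste0(format(f$end - f$start, scientific = FALSE), ","),
                  "0,")
      }
      paste(base, collapse = "\t")
    }, "")
  } else {
    lines <- vapply(seq_len(n), function(i) {
      f <- features[i, ]
      a <- features$attributes[[i]]
      if (!is.na(f$name) && !"Name" %in% names(a)) {
        a <- c(a, c(Name = f$name))
      }
      attr_text <- if (length(a)) paste(names(a), unname(a), sep = "=", collapse = ";") else "."
      paste(c(f$chrom, "genovis", "feature",
              format(f$start + 1, scientific = FALSE),
              format(f$end, scientific = FALSE),
              if (is.na(f$score)) "." else format(f$score, scientific = FALSE),
              if (f$strand == "*") "." else f$strand,
              ".", attr_text), collapse = "\t")
    }, "")
  }
  writeLines(lines, path)
  invisible(n)
}
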