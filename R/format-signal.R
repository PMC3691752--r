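#' Signal records
#'
#' Quantitative signal is held as a `gv_signal` data frame with columns
#' `chrom`, `start`, `end` (0-based half-open), `value` (finite) and
#' `source_line`.
#'
#' @param df Data frame with `chrom`, `start`, `end`, `value`.
#' @param skipped Count of skipped non-data lines.
#' @return A `gv_signal` data frame.
#' @export
gv_signal <- function(df, skipped = 0L) {
  n <- nrow(df)
  out <- data.frame(
    chrom = as.character(df$chrom), start = as.numeric(df$start),
    end = as.numeric(df$end), value = as.numeric(df$value),
    source_line = if (!is.null(df$source_line)) as.integer(df$source_line) else seq_len(n),
    stringsAsFactors = FALSE
  )
  if (n && any(!is.finite(out$value))) {
    gv_error("signal values must be finite", "gv_parse_error")
  }
  class(out) <- c("gv_signal", "data.frame")
  attr(out, "skipped") <- as.integer(skipped)
  out
}

parse_wig_decl <- function(line, lineno) {
  kind <- sub("\\s.*$", "", line)
  kv <- regmatches(line, gregexpr("[A-Za-z]+=[^ \t]+", line))[[1]]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  d <- as.list(stats::setNames(vals, keys))
  if (is.null(d$chrom)) {
    gv_error(sprintf("line %d: wiggle declaration without chrom=", lineno),
             "gv_parse_error")
  }
  span <- as.numeric(d$span %||% "1")
  step <- as.numeric(d$step %||% "1")
  if (kind == "fixedStep" && is.null(d$start)) {
    gv_error(sprintf("line %d: fixedStep declaration without start=", lineno),
             "gv_parse_error")
  }
  if (span <= 0 || step <= 0) {
    gv_error(sprintf("line %d: step and span must be > 0", lineno), "gv_parse_error")
  }
  list(kind = kind, chrom = d$chrom, span = span, step = step,
       # wiggle is 1-based; internal cursor is the 0-based start of the
       # next emitted point
       cursor = if (!is.null(d$start)) as.numeric(d$start) - 1 else NA_real_)
}

#' Read quantitative signal from Wiggle or BedGraph
#'
#' BedGraph intervals are natively 0-based half-open and pass through
#' unchanged.  Wiggle `fixedStep`/`variableStep` 1-based starts are
#' converted; each value becomes one signal point of length `span`
#' (default 1), with `fixedStep` advancing the position by `step` per
#' value.
#'
#' @param path Input file path.
#' @param format `"wiggle"` or `"bedgraph"`.
#' @return A [gv_signal()] data frame.
#' @examples
#' wig <- tempfile(fileext = ".wig")
#' writeLines(c("fixedStep chrom=chr1 start=11 step=10 span=5", "1.0", "2.0"), wig)
#' read_signal(wig, "wiggle")
#' @export
read_signal <- function(path, format = c("wiggle", "bedgraph")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  skip <- is_skip_line(lines)
  if (format == "bedgraph") {
    lines <- lines[!skip]; lineno <- lineno[!skip]
    if (!length(lines)) {
      return(gv_signal(data.frame(chrom = character(0), start = numeric(0),
                                  end = numeric(0), value = numeric(0)), sum(skip)))
    }
    parts <- split_fields(lines)
    nf <- lengths(parts)
    if (any(nf < 4L)) {
      i <- which(nf < 4L)[1]
      gv_error(sprintf("line %d: bedgraph needs 4 fields, got %d", lineno[i], nf[i]),
               "gv_parse_error")
    }
    start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    check_coords(start, end, lineno, "signal")
    value <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4L)))
    bad <- which(is.na(value))
    if (length(bad)) {
      gv_error(sprintf("line %d: non-numeric signal value", lineno[bad[1]]),
               "gv_parse_error")
    }
    return(gv_signal(data.frame(chrom = vapply(parts, `[[`, "", 1L),
                                start = start, end = end, value = value,
                                source_line = lineno, stringsAsFactors = FALSE),
                     sum(skip)))
  }
  # wiggle: stateful scan over declaration + data lines
  decl <- NULL
  skipped <- 0L
  acc <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (skip[i]) { skipped <- skipped + 1L; next }
    if (startsWith(line, "fixedStep") || startsWith(line, "variableStep")) {
      decl <- parse_wig_decl(line, lineno[i])
      next
    }
    if (is.null(decl)) {
      gv_error(sprintf("line %d: wiggle data before any fixedStep/variableStep declaration",
                       lineno[i]), "gv_parse_error")
    }
    if (decl$kind == "fixedStep") {
      v <- suppressWarnings(as.numeric(line))
      if (is.na(v)) gv_error(sprintf("line %d: non-numeric wiggle value", lineno[i]),
                             "gv_parse_error")
      acc[[i]] <- data.frame(chrom = decl$chrom, start = decl$cursor,
                             end = decl$cursor + decl$span, value = v,
                             source_line = lineno[i], stringsAsFactors = FALSE)
      decl$cursor <- decl$cursor + decl$step
    } else {
      p <- strsplit(trimws(line), "[ \t]+")[[1]]
      pos <- suppressWarnings(as.numeric(p[1]))
      v <- suppressWarnings(as.numeric(p[2]))
      if (length(p) < 2L || is.na(pos) || is.na(v)) {
        gv_error(sprintf("line %d: variableStep line needs 'position value'",
                         lineno[i]), "gv_parse_error")
      }
      acc[[i]] <- data.frame(chrom = decl$chrom, start = pos - 1,
                             end = pos - 1 + decl$span, value = v,
                             source_line = lineno[i], stringsAsFactors = FALSE)
    }
  }
  acc <- acc[!vapply(acc, is.null, TRUE)]
  if (!length(acc)) {
    return(gv_signal(data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0), value = numeric(0)), skipped))
  }
  gv_signal(do.call(rbind, acc), skipped)
}

#' Write signal records as BedGraph
#' @param signal A [gv_signal()] data frame.
#' @param path Output path.
#' @return Number of records written, invisibly.
#' @export
write_signal <- function(signal, path) {
  writeLines(paste(signal$chrom,
                   format(signal$start, scientific = FALSE, trim = TRUE),
                   format(signal$end, scientific = FALSE, trim = TRUE),
                   format(signal$value, scientific = FALSE, trim = TRUE),
                   sep = "\t"),
             path)
  invisible(nrow(signal))
}

#' Read site-level variants from a VCF file
#'
#' The 1-based `POS` is converted to a 0-based start; the record region
#' spans `max(nchar(REF), 1)` bases.  Multi-allelic `ALT` values are split
#' into a list but kept as a single record.  `INFO` is parsed into a named
#' character map (flags get value `""`).
#'
#' @param path VCF file path (plain text, header lines begin `#`).
#' @return A data frame of class `gv_variants` with columns `chrom`,
#'   `start`, `end`, `ref`, `qual`, list columns `alts` and `info`, and
#'   `source_line`.
#' @export
read_variants <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  skip <- startsWith(lines, "#") | !nzchar(trimws(lines))
  lines <- lines[!skip]; lineno <- lineno[!skip]
  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      ref = character(0), qual = numeric(0),
                      stringsAsFactors = FALSE)
  empty$alts <- list(); empty$info <- list()
  empty$source_line <- integer(0)
  class(empty) <- c("gv_variants", "data.frame")
  attr(empty, "skipped") <- sum(skip)
  if (!length(lines)) return(empty)
  parts <- split_fields(lines)
  nf <- lengths(parts)
  if (any(nf < 8L)) {
    i <- which(nf < 8L)[1]
    gv_error(sprintf("line %d: VCF record needs 8 mandatory columns, got %d",
                     lineno[i], nf[i]), "gv_parse_error")
  }
  pos <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(is.na(pos) | pos != floor(pos))
  if (length(bad)) {
    gv_error(sprintf("line %d: non-integer POS", lineno[bad[1]]), "gv_parse_error")
  }
  ref <- vapply(parts, `[[`, "", 4L)
  start <- pos - 1
  end <- start + pmax(nchar(ref), 1)
  qual <- parse_score(vapply(parts, `[[`, "", 6L))
  out <- data.frame(chrom = vapply(parts, `[[`, "", 1L), start = start,
                    end = end, ref = ref, qual = qual,
                    stringsAsFactors = FALSE)
  out$alts <- lapply(parts, function(p) {
    a <- strsplit(p[[5L]], ",", fixed = TRUE)[[1]]
    a[a != "."]
  })
  out$info <- lapply(parts, function(p) {
    txt <- p[[8L]]
    if (txt == "." || !nzchar(txt)) return(character(0))
    items <- strsplit(txt, ";", fixed = TRUE)[[1]]
    keys <- sub("=.*$", "", items)
    vals <- ifelse(grepl("=", items, fixed = TRUE), sub("^[^=]*=", "", items), "")
    stats::setNames(vals, keys)
  })
  out$source_line <- lineno
  class(out) <- c("gv_variants", "data.frame")
  attr(out, "skipped") <- sum(skip)
  out
}

MISSING_MARKERS <- c("", "NA", ".")

#' Read a delimited table with type inference
#'
#' A column is numeric when every non-missing cell parses as a number
#' (missing markers: empty string, `NA`, `.`); otherwise it is a string
#' column.  With `header = "auto"` the first line is treated as a header
#' when none of its cells parses as a number.
#'
#' @param path Input file path.
#' @param delimiter Field delimiter, default tab.
#' @param header `"auto"`, `TRUE` or `FALSE`.
#' @return An object of class `gv_table`: a list with `col_names`,
#'   `col_types` (`"numeric"`/`"string"`) and `data` (a data frame;
#'   missing cells are `NA`).
#' @export
read_table <- function(path, delimiter = "\t", header = "auto") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) gv_error("no data rows", "gv_parse_error")
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != nf[1])) {
    i <- which(nf != nf[1])[1]
    gv_error(sprintf("line %d: ragged row (%d fields, expected %d)",
                     i, nf[i], nf[1]), "gv_parse_error")
  }
  first_numeric <- suppressWarnings(!is.na(as.numeric(parts[[1]])))
  has_header <- isTRUE(header) ||
    (identical(header, "auto") && !any(first_numeric) && length(parts) > 1L)
  if (has_header) {
    col_names <- parts[[1]]
    parts <- parts[-1]
  } else {
    col_names <- paste0("V", seq_len(nf[1]))
  }
  if (!length(parts)) gv_error("no data rows", "gv_parse_error")
  cols <- lapply(seq_len(nf[1]), function(j) vapply(parts, `[[`, "", j))
  col_types <- character(length(cols))
  data <- stats::setNames(vector("list", length(cols)), col_names)
  for (j in seq_along(cols)) {
    x <- cols[[j]]
    miss <- x %in% MISSING_MARKERS
    v <- suppressWarnings(as.numeric(x))
    if (all(miss | !is.na(v))) {
      col_types[j] <- "numeric"
      v[miss] <- NA_real_
      data[[j]] <- v
    } else {
      col_types[j] <- "string"
      x[miss] <- NA_character_
      data[[j]] <- x
    }
  }
  structure(list(col_names = col_names, col_types = col_types,
                 data = as.data.frame(data, stringsAsFactors = FALSE,
                                      check.names = FALSE)),
            class = "gv_table")
}
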