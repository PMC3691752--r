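#' Genome: an ordered chromosome registry
#'
#' A genome is an identifier plus an ordered list of chromosome
#' (name, length) pairs.  Order is meaningful: it is the layout order used
#' by the circular layout engine and by genome-wide providers, and it is
#' taken from the input (file order of a chrom.sizes file), never sorted.
#'
#' @param id Short genome identifier (e.g. `"hg19"`, `"toy1"`).
#' @param chromosomes Data frame with columns `name` and `length`, or a
#'   named numeric vector of lengths.
#' @return An object of class `gv_genome`.
#' @examples
#' g <- gv_genome("toy", c(chr1 = 1000, chr2 = 500))
#' chrom_length(g, "chr2")
#' @export
gv_genome <- function(id, chromosomes) {
  if (is.numeric(chromosomes) && !is.null(names(chromosomes))) {
    chromosomes <- data.frame(
      name = names(chromosomes), length = as.numeric(chromosomes),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is_string(id), is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  chromosomes <- data.frame(
    name = as.character(chromosomes$name),
    length = as.numeric(chromosomes$length),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(chromosomes$name)) {
    gv_error("chromosome names must be unique", "gv_genome_error")
  }
  if (any(chromosomes$length <= 0) || any(chromosomes$length != floor(chromosomes$length))) {
    gv_error("chromosome lengths must be positive integers", "gv_genome_error")
  }
  structure(list(id = id, chromosomes = chromosomes), class = "gv_genome")
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two tab-separated columns, `name<TAB>length`.  Chromosome order in the
#' returned genome is the file order.
#'
#' @param path Path to the chrom.sizes file.
#' @param id Genome identifier; defaults to the file name without extension.
#' @return A [gv_genome()].
#' @export
read_chrom_sizes <- function(path, id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    gv_error(sprintf("chrom.sizes line %d: expected name<TAB>length", bad[1]),
             "gv_parse_error")
  }
  gv_genome(
    id %||% sub("\\.[^.]*$", "", basename(path)),
    data.frame(
      name = vapply(parts, `[[`, "", 1L),
      length = as.numeric(vapply(parts, `[[`, "", 2L)),
      stringsAsFactors = FALSE
    )
  )
}

#' Write a genome back to chrom.sizes format
#' @param genome A [gv_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  writeLines(paste(genome$chromosomes$name, genome$chromosomes$length, sep = "\t"),
             path)
  invisible(path)
}

#' @export
print.gv_genome <- function(x, ...) {
  cat(sprintf("<gv_genome '%s': %d chromosomes, %s bases>\n",
              x$id, nrow(x$chromosomes),
              format(sum(x$chromosomes$length), big.mark = ",")))
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$name)
  if (is.na(i)) {
    gv_error(sprintf("unknown chromosome '%s' in genome '%s'", chrom, genome$id),
             "gv_genome_error")
  }
  genome$chromosomes$length[i]
}

#' Genomic region in 0-based half-open coordinates
#'
#' All internal coordinates in the package are 0-based half-open
#' `[start, end)`; display strings (see [parse_region_string()]) are
#' 1-based inclusive, the UCSC browser convention.
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start, `>= 0`.
#' @param end Exclusive end, `> start`.
#' @param strand One of `"+"`, `"-"`, `"*"` (unspecified).
#' @param genome Optional [gv_genome()]; when given, `chrom` must be known
#'   and `end` must not exceed the chromosome length.
#' @return An object of class `gv_region`.
#' @examples
#' r <- gv_region("chr17", 7569898, 7591385)
#' region_width(r)  # 21487
#' @export
gv_region <- function(chrom, start, end, strand = "*", genome = NULL) {
  stopifnot(is_string(chrom), length(start) == 1L, length(end) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || end <= start) {
    gv_error(sprintf("invalid region %s:[%s,%s): need 0 <= start < end",
                     chrom, format(start), format(end)), "gv_region_error")
  }
  if (!strand %in% c("+", "-", "*")) {
    gv_error("strand must be '+', '-' or '*'", "gv_region_error")
  }
  if (!is.null(genome) && end > chrom_length(genome, chrom)) {
    gv_error(sprintf("region end %s exceeds length of %s (%s)",
                     format(end), chrom, format(chrom_length(genome, chrom))),
             "gv_region_error")
  }
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "gv_region")
}

#' @rdname gv_region
#' @param region A `gv_region`.
#' @export
region_width <- function(region) region$end - region$start

#' @export
print.gv_region <- function(x, ...) {
  cat(sprintf("<gv_region %s>\n", format_region_string(x)))
  invisible(x)
}

#' Parse a display-format region string
#'
#' Display strings are 1-based inclusive (`chr17:7569899-7591385`); the
#' returned region uses internal 0-based half-open coordinates, so the
#' display start maps to `start - 1`.  Commas in numbers are permitted.
#' A bare chromosome name yields the whole chromosome when a genome is
#' supplied.
#'
#' @param text Region string, `chrom` or `chrom:start-end`.
#' @param genome Optional [gv_genome()] used to validate the chromosome and
#'   resolve bare-chromosome strings.
#' @return A [gv_region()].
#' @examples
#' parse_region_string("chr17:7569899-7591385")
#' @export
parse_region_string <- function(text, genome = NULL) {
  stopifnot(is_string(text))
  text <- trimws(text)
  if (!grepl(":", text, fixed = TRUE)) {
    if (is.null(genome)) {
      gv_error("bare chromosome region string requires a genome", "gv_parse_error")
    }
    return(gv_region(text, 0, chrom_length(genome, text), genome = genome))
  }
  m <- regmatches(text, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", text))[[1]]
  if (length(m) != 4L) {
    gv_error(sprintf("malformed region string '%s' (expected chrom:start-end)", text),
             "gv_parse_error")
  }
  s <- as.numeric(gsub(",", "", m[3], fixed = TRUE))
  e <- as.numeric(gsub(",", "", m[4], fixed = TRUE))
  if (s < 1 || e < s) {
    gv_error(sprintf("region string '%s': start must be >= 1 and <= end", text),
             "gv_parse_error")
  }
  gv_region(m[2], s - 1, e, genome = genome)
}

#' Format a region as a display string (inverse of [parse_region_string()])
#' @param region A [gv_region()].
#' @return `chrom:start-end` with 1-based inclusive coordinates.
#' @export
format_region_string <- function(region) {
  sprintf("%s:%s-%s", region$chrom,
          format(region$start + 1, scientific = FALSE),
          format(region$end, scientific = FALSE))
}

#' Pan or zoom a viewing window
#'
#' `navigate()` is total: requests that would leave the chromosome are
#' clamped, never rejected.  Zooming scales the width by `value` about the
#' view center and truncates at chromosome ends; panning shifts by
#' `value * width` and slides back inside the chromosome, preserving width
#' where possible.  Width never drops below one base.
#'
#' @param view Current [gv_region()].
#' @param action `"zoom"` or `"pan"`.
#' @param value Zoom factor (`> 0`; `< 1` zooms in) or pan distance as a
#'   fraction of the current width (negative pans left).
#' @param genome [gv_genome()] supplying the chromosome length for clamping.
#' @return The new [gv_region()].
#' @examples
#' g <- gv_genome("toy", c(chr1 = 10000))
#' navigate(gv_region("chr1", 1000, 2000), "zoom", 0.5, g)
#' @export
navigate <- function(view, action = c("zoom", "pan"), value, genome) {
  action <- match.arg(action)
  len <- chrom_length(genome, view$chrom)
  w <- region_width(view)
  if (action == "zoom") {
    if (value <= 0) gv_error("zoom factor must be > 0", "gv_region_error")
    nw <- max(1, round(w * value))
    center <- (view$start + view$end) / 2
    s <- round(center - nw / 2)
    e <- s + nw
    s <- max(0, s)
    e <- min(len, e)
    if (e - s < 1) { s <- max(0, e - 1); e <- s + 1 }
  } else {
    s <- round(view$start + value * w)
    e <- s + w
    if (s < 0) { s <- 0; e <- min(len, w) }
    if (e > len) { e <- len; s <- max(0, len - w) }
  }
  gv_region(view$chrom, s, e, view$strand, genome = genome)
}

#' Bookmark: an annotated region
#' @param region A [gv_region()].
#' @param annotation Free-text note.
#' @return An object of class `gv_bookmark`.
#' @export
gv_bookmark <- function(region, annotation = "") {
  stopifnot(inherits(region, "gv_region"), is.character(annotation))
  structure(list(region = region, annotation = annotation), class = "gv_bookmark")
}
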