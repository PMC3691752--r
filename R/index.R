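DEFAULT_BIN_SIZE <- 4096

#' Open a dataset file as a provider-ready handle
#'
#' Parses the file with the matching reader and bundles the records with
#' the path, declared format and a content checksum.  The handle is what
#' data providers and the sweep engine operate on.
#'
#' @param path Dataset file path.
#' @param format One of the supported format names (see [read_features()],
#'   [read_signal()], [read_variants()]).
#' @param ... Passed to the underlying reader (e.g. `interval_cols`).
#' @return An object of class `gv_dataset` with fields `path`, `format`,
#'   `kind` (`"features"`, `"signal"` or `"variants"`), `records` and
#'   `checksum`.
#' @export
open_dataset <- function(path, format, ...) {
  kind <- switch(format,
    bed = , gff3 = , gtf = , interval = , sam = "features",
    wiggle = , bedgraph = "signal",
    vcf = "variants",
    gv_error(sprintf("unsupported dataset format '%s'", format), "gv_io_error")
  )
  records <- switch(kind,
    features = read_features(path, format, ...),
    signal = read_signal(path, format),
    variants = read_variants(path)
  )
  structure(list(path = path, format = format, kind = kind,
                 records = records, checksum = file_checksum(path)),
            class = "gv_dataset")
}

#' @export
print.gv_dataset <- function(x, ...) {
  cat(sprintf("<gv_dataset %s (%s): %d records>\n", x$path, x$format,
              nrow(x$records)))
  invisible(x)
}

bin_key <- function(chrom, bin) paste0(chrom, "\r", bin)

#' Build a binned interval index
#'
#' Single-level fixed-width bins with multi-bin registration: a record is
#' listed in every bin its span overlaps, so a region query touches only
#' the bins covering the query.  Construction is order-independent up to
#' ordinal relabeling.
#'
#' @param records Data frame with columns `chrom`, `start`, `end` and
#'   optionally `offset` (a record locator in the source file; defaults to
#'   row number).
#' @param bin_size Bin width in bases (default 4096).
#' @return An object of class `gv_bin_index`.
#' @seealso [query_index()], [persist_index()], [index_dataset()]
#' @export
build_index <- function(records, bin_size = DEFAULT_BIN_SIZE) {
  if (bin_size <= 0) gv_error("bin_size must be > 0", "gv_index_error")
  n <- nrow(records)
  tab <- data.frame(
    chrom = as.character(records$chrom),
    start = as.numeric(records$start),
    end = as.numeric(records$end),
    offset = if (!is.null(records$offset)) as.numeric(records$offset)
             else if (!is.null(records$source_line)) as.numeric(records$source_line)
             else seq_len(n),
    stringsAsFactors = FALSE
  )
  if (n && any(tab$start < 0 | tab$end <= tab$start)) {
    gv_error("invalid record region in index input", "gv_index_error")
  }
  bins <- new.env(parent = emptyenv())
  if (n) {
    b0 <- as.integer(floor(tab$start / bin_size))
    b1 <- as.integer(floor((tab$end - 1) / bin_size))
    k <- b1 - b0 + 1L
    ord <- rep.int(seq_len(n), k)
    bin <- sequence(k, from = b0, by = 1L)
    grouped <- split(ord, bin_key(tab$chrom[ord], bin))
    for (key in names(grouped)) assign(key, grouped[[key]], envir = bins)
  }
  counters <- new.env(parent = emptyenv())
  counters$bins_touched <- 0
  counters$queries <- 0
  structure(list(bin_size = bin_size, bins = bins, records = tab,
                 record_count = n, checksum = NULL, source = NULL,
                 counters = counters),
            class = "gv_bin_index")
}

#' Index an opened dataset
#'
#' Convenience wrapper around [build_index()] that records the source path
#' and checksum so the index can be persisted and later validated against
#' the file it was built from.
#'
#' @param dataset A [open_dataset()] handle.
#' @param bin_size Bin width in bases.
#' @return A `gv_bin_index`.
#' @export
index_dataset <- function(dataset, bin_size = DEFAULT_BIN_SIZE) {
  recs <- dataset$records
  idx <- build_index(
    data.frame(chrom = recs$chrom, start = recs$start, end = recs$end,
               offset = recs$source_line, stringsAsFactors = FALSE),
    bin_size
  )
  idx$checksum <- dataset$checksum
  idx$source <- dataset$path
  idx
}

#' Query a binned index for records overlapping a region
#'
#' Equivalent to a linear scan with the half-open overlap test
#' `record.start < region.end && record.end > region.start`, but touching
#' only the bins the query region covers.  An unknown chromosome yields an
#' empty result, not an error.
#'
#' @param index A [build_index()] result.
#' @param region A [gv_region()].
#' @return Integer vector of record ordinals (1-based rows of the index
#'   record table), deduplicated and sorted by `(start, end, ordinal)`.
#' @export
query_index <- function(index, region) {
  bs <- index$bin_size
  b0 <- floor(region$start / bs)
  b1 <- floor((region$end - 1) / bs)
  keys <- bin_key(region$chrom, b0:b1)
  index$counters$bins_touched <- index$counters$bins_touched + length(keys)
  index$counters$queries <- index$counters$queries + 1
  hits <- unlist(lapply(keys, function(k) {
    if (exists(k, envir = index$bins, inherits = FALSE)) {
      get(k, envir = index$bins)
    } else integer(0)
  }), use.names = FALSE)
  if (!length(hits)) return(integer(0))
  hits <- unique(hits)
  tab <- index$records
  hits <- hits[tab$start[hits] < region$end & tab$end[hits] > region$start]
  hits[order(tab$start[hits], tab$end[hits], hits)]
}

#' Persist an index to (and load it from) a sidecar file
#'
#' The sidecar (conventionally `<dataset>.gvx`) is a JSON document with a
#' magic string, format version, bin size, source checksum and the record
#' table; bins are rebuilt deterministically on load.  `load_index()`
#' verifies the stored checksum against the source file and raises a
#' stale-index error (`gv_stale_index`) when the source has changed.
#'
#' @param index A `gv_bin_index` (with a source checksum, i.e. built via
#'   [index_dataset()] — or not, for anonymous indices).
#' @param path Sidecar path.
#' @return `persist_index`: bytes written, invisibly; `load_index`: a
#'   `gv_bin_index`.
#' @export
persist_index <- function(index, path) {
  doc <- list(
    magic = "GVX", version = 1L, bin_size = index$bin_size,
    record_count = index$record_count,
    source = index$source, checksum = index$checksum,
    records = list(chrom = index$records$chrom, start = index$records$start,
                   end = index$records$end, offset = index$records$offset)
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA)
  writeLines(json, path)
  invisible(file.size(path))
}

#' @rdname persist_index
#' @param source Source dataset path for checksum validation; defaults to
#'   the path stored in the sidecar.  Use `NULL` stored source to skip.
#' @export
load_index <- function(path, source = NULL) {
  doc <- tryCatch(jsonlite::fromJSON(readLines(path, warn = FALSE)),
                  error = function(e) {
                    gv_error(sprintf("cannot read index file %s: %s", path,
                                     conditionMessage(e)), "gv_index_error")
                  })
  if (!identical(doc$magic, "GVX") || !identical(as.integer(doc$version), 1L)) {
    gv_error(sprintf("%s is not a version-1 index sidecar", path), "gv_index_error")
  }
  src <- source %||% doc$source
  if (!is.null(doc$checksum) && !is.null(src)) {
    now <- file_checksum(src)
    if (!identical(now$md5, doc$checksum$md5) ||
        !identical(as.numeric(now$size), as.numeric(doc$checksum$size))) {
      gv_error(sprintf("stale index: %s has changed since %s was written",
                       src, path), "gv_stale_index")
    }
  }
  recs <- doc$records
  n <- doc$record_count
  df <- if (n > 0) {
    data.frame(chrom = recs$chrom, start = recs$start, end = recs$end,
               offset = recs$offset, stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               offset = numeric(0), stringsAsFactors = FALSE)
  }
  idx <- build_index(df, doc$bin_size)
  idx$checksum <- doc$checksum
  idx$source <- doc$source
  idx
}

index_sidecar_path <- function(dataset_path) paste0(dataset_path, ".gvx")
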