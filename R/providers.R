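DEFAULT_MAX_DETAIL <- 5000
DEFAULT_NBINS <- 1000

#' Dynamic filter specification
#'
#' A numeric pass band `[min, max]` on one record attribute: `"score"`,
#' `"mapq"` (SAM reads) or any named GFF/GTF attribute.  Records whose
#' attribute is missing pass when `missing_passes` is `TRUE` (the
#' default): filters are opt-in restrictive, a record is never hidden for
#' lacking an annotation.
#'
#' @param attribute Attribute name.
#' @param min,max Inclusive bounds; `-Inf`/`Inf` leave a side open.
#' @param missing_passes Whether records without the attribute pass.
#' @return An object of class `gv_filter`.
#' @export
filter_spec <- function(attribute, min = -Inf, max = Inf, missing_passes = TRUE) {
  stopifnot(is_string(attribute))
  if (is.na(min) || is.na(max) || min > max) {
    gv_error(sprintf("invalid filter range [%s, %s]: need min <= max",
                     format(min), format(max)), "gv_filter_error")
  }
  structure(list(attribute = attribute, min = as.numeric(min),
                 max = as.numeric(max),
                 missing_passes = isTRUE(missing_passes)),
            class = "gv_filter")
}

summary_bins <- function(region, nbins, stat, values) {
  structure(list(region = region, nbins = as.integer(nbins), stat = stat,
                 values = as.numeric(values)),
            class = "gv_summary_bins")
}

payload <- function(mode, records = NULL, summary = NULL, total, message = NULL) {
  structure(list(mode = mode, records = records, summary = summary,
                 total_in_region = total, message = message),
            class = "gv_payload")
}

#' @export
print.gv_payload <- function(x, ...) {
  cat(sprintf("<gv_payload %s: %d in region%s>\n", x$mode, x$total_in_region,
              if (is.null(x$message)) "" else paste0("; ", x$message)))
  invisible(x)
}

#' Count records overlapping a region
#' @param dataset A [open_dataset()] handle.
#' @param index Its [index_dataset()] index.
#' @param region A [gv_region()].
#' @return Integer count, equal to a linear-scan overlap count.
#' @export
count_in_region <- function(dataset, index, region) {
  length(query_index(index, region))
}

#' Fetch individual records in a region (detail mode)
#'
#' Returns the records overlapping `region`, sorted by `(start, end)`.
#' Filters are not applied here; see [apply_filters()].  When the region
#' holds more than `max_detail` records this raises a `gv_over_limit`
#' error directing the caller to summary mode — use [get_data()] for
#' automatic mode selection.
#'
#' @inheritParams count_in_region
#' @param max_detail Maximum number of records a detail payload may carry.
#' @return A `gv_payload` with `mode = "detail"`.
#' @export
get_detail <- function(dataset, index, region, max_detail = DEFAULT_MAX_DETAIL) {
  hits <- query_index(index, region)
  if (length(hits) > max_detail) {
    gv_error(sprintf("%d records in %s exceed max_detail = %d; request a summary instead",
                     length(hits), format_region_string(region), max_detail),
             "gv_over_limit")
  }
  payload("detail", records = dataset$records[hits, , drop = FALSE],
          total = length(hits))
}

summary_bin_edges <- function(region, nbins) {
  len <- region_width(region)
  nbins <- max(1L, min(as.integer(nbins), as.integer(len)))
  w <- floor(len / nbins)
  list(nbins = nbins, w = w,
       edges = c(region$start + (seq_len(nbins) - 1) * w, region$end))
}

#' Per-bin summary of a region (coverage and signal statistics)
#'
#' Divides `region` into `nbins` equal-width bins (integer width, last bin
#' absorbs the remainder) and aggregates per bin.  `stat = "count"` is
#' coverage semantics: a record contributes to every bin it overlaps.
#' `"mean"`, `"max"`, `"min"` apply to signal datasets only; the mean is
#' base-weighted (each overlapped base contributes its value once), so
#' results are independent of how the signal is segmented.  Empty bins are
#' 0 under `count` and `NA` under the other statistics.
#'
#' @inheritParams count_in_region
#' @param nbins Number of bins (clamped to the region width).
#' @param stat One of `"count"`, `"mean"`, `"max"`, `"min"`.
#' @return A `gv_summary_bins` object.
#' @export
get_summary <- function(dataset, index, region, nbins = DEFAULT_NBINS,
                        stat = c("count", "mean", "max", "min")) {
  stat <- match.arg(stat)
  if (stat != "count" && dataset$kind != "signal") {
    gv_error(sprintf("stat '%s' requires a signal dataset; '%s' is %s",
                     stat, dataset$path, dataset$kind), "gv_provider_error")
  }
  be <- summary_bin_edges(region, nbins)
  nb <- be$nbins; w <- be$w
  hits <- query_index(index, region)
  recs <- dataset$records[hits, , drop = FALSE]
  rs <- region$start
  bin_of <- function(pos) pmin(floor((pos - rs) / w), nb - 1) + 1
  if (stat == "count") {
    vals <- numeric(nb)
    if (nrow(recs)) {
      b0 <- bin_of(pmax(recs$start, region$start))
      b1 <- bin_of(pmin(recs$end, region$end) - 1)
      for (i in seq_along(b0)) {
        vals[b0[i]:b1[i]] <- vals[b0[i]:b1[i]] + 1
      }
    }
    return(summary_bins(region, nb, stat, vals))
  }
  wsum <- numeric(nb); wtot <- numeric(nb)
  vmax <- rep(-Inf, nb); vmin <- rep(Inf, nb)
  if (nrow(recs)) {
    edges <- be$edges
    for (i in seq_len(nrow(recs))) {
      s <- max(recs$start[i], region$start)
      e <- min(recs$end[i], region$end)
      v <- recs$value[i]
      b0 <- bin_of(s); b1 <- bin_of(e - 1)
      b <- b0:b1
      ov <- pmin(edges[b + 1], e) - pmax(edges[b], s)
      wsum[b] <- wsum[b] + ov * v
      wtot[b] <- wtot[b] + ov
      vmax[b] <- pmax(vmax[b], v)
      vmin[b] <- pmin(vmin[b], v)
    }
  }
  vals <- switch(stat,
    mean = ifelse(wtot > 0, wsum / wtot, NA_real_),
    max = ifelse(is.finite(vmax), vmax, NA_real_),
    min = ifelse(is.finite(vmin), vmin, NA_real_)
  )
  summary_bins(region, nb, stat, vals)
}

#' Region query with automatic detail/summary switching
#'
#' The central provider contract: when at most `max_detail` records
#' overlap the region (ties included — exactly `max_detail` still returns
#' detail), individual records are returned; otherwise a per-bin count
#' summary is returned and `message` explains the summarization.
#'
#' @inheritParams get_summary
#' @param max_detail Detail-mode record budget (default 5000).
#' @return A `gv_payload`; `total_in_region` is always the exact overlap
#'   count.
#' @export
get_data <- function(dataset, index, region, max_detail = DEFAULT_MAX_DETAIL,
                     nbins = DEFAULT_NBINS) {
  n <- count_in_region(dataset, index, region)
  if (n <= max_detail) {
    get_detail(dataset, index, region, max_detail)
  } else {
    payload("summary",
            summary = get_summary(dataset, index, region, nbins, "count"),
            total = n,
            message = sprintf("%d records exceed max_detail = %d; showing %s-bin coverage",
                              n, max_detail,
                              summary_bin_edges(region, nbins)$nbins))
  }
}

#' Genome-wide per-chromosome summaries
#'
#' One `gv_summary_bins` per chromosome, each identical to calling
#' [get_summary()] on the whole chromosome — the payload a circular
#' genome-wide view renders initially.
#'
#' @inheritParams get_summary
#' @param genome A [gv_genome()].
#' @param bins_per_chrom Bins per chromosome.
#' @return Named list (chromosome name) of `gv_summary_bins`.
#' @export
get_genome_wide <- function(dataset, index, genome, bins_per_chrom = 100,
                            stat = "count") {
  chroms <- genome$chromosomes
  out <- lapply(seq_len(nrow(chroms)), function(i) {
    get_summary(dataset, index,
                gv_region(chroms$name[i], 0, chroms$length[i]),
                bins_per_chrom, stat)
  })
  stats::setNames(out, chroms$name)
}

#' Aligned multi-track summary matrix (rainbow tracks)
#'
#' Summarizes several datasets over identical bin boundaries, one row per
#' dataset, so grouped quantitative tracks can be collapsed into a single
#' dense composite band.
#'
#' @param datasets Ordered list of [open_dataset()] handles.
#' @param indexes Parallel list of their indices.
#' @param region,nbins,stat As in [get_summary()]; non-count statistics
#'   require all datasets to be signal.
#' @return Numeric matrix, `length(datasets)` rows.
#' @export
composite_summary <- function(datasets, indexes, region, nbins = DEFAULT_NBINS,
                              stat = "count") {
  stopifnot(length(datasets) == length(indexes), length(datasets) >= 1)
  if (stat != "count" &&
      !all(vapply(datasets, function(d) d$kind == "signal", TRUE))) {
    gv_error(sprintf("stat '%s' requires all datasets to be signal", stat),
             "gv_provider_error")
  }
  rows <- lapply(seq_along(datasets), function(k) {
    get_summary(datasets[[k]], indexes[[k]], region, nbins, stat)$values
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(datasets, function(d) d$path, "")
  m
}

filter_value <- function(records, attribute, i) {
  if (attribute == "score") {
    return(if (is.null(records$score)) NA_real_ else records$score[i])
  }
  if (is.null(records$attributes)) return(NA_real_)
  a <- records$attributes[[i]]
  if (is.null(a) || !attribute %in% names(a)) return(NA_real_)
  suppressWarnings(as.numeric(a[[attribute]]))
}

#' Apply dynamic filters to a detail payload
#'
#' A record is retained iff every filter passes (conjunction); each filter
#' compares a numeric attribute against `[min, max]` inclusive, with
#' missing attributes handled per the filter's `missing_passes`.  Filters
#' act on individual records, so a summary payload is an error.
#' Idempotent: applying the same filters twice changes nothing.
#'
#' @param pl A detail-mode `gv_payload`.
#' @param filters List of [filter_spec()] objects.
#' @return A `gv_payload` with filtered records and updated
#'   `total_in_region`.
#' @export
apply_filters <- function(pl, filters) {
  if (pl$mode != "detail") {
    gv_error("filters act on records; summary payloads cannot be filtered",
             "gv_filter_error")
  }
  recs <- pl$records
  keep <- rep(TRUE, nrow(recs))
  for (f in filters) {
    stopifnot(inherits(f, "gv_filter"))
    for (i in which(keep)) {
      v <- filter_value(recs, f$attribute, i)
      keep[i] <- if (is.na(v)) f$missing_passes else (v >= f$min && v <= f$max)
    }
  }
  payload("detail", records = recs[keep, , drop = FALSE], total = sum(keep),
          message = pl$message)
}

#' Column statistics for numeric table columns
#'
#' Missing values are excluded from every statistic; `sd` uses the n-1
#' denominator and is `NA` when fewer than two values remain.  These are
#' the numbers a scatter-plot view needs to derive its axes.
#'
#' @param table A [read_table()] result.
#' @param columns Column names (default: all numeric columns).
#' @return Data frame with one row per column: `column`, `min`, `max`,
#'   `mean`, `sd`, `n`, `n_missing`.
#' @export
column_stats <- function(table, columns = NULL) {
  stopifnot(inherits(table, "gv_table"))
  columns <- columns %||% table$col_names[table$col_types == "numeric"]
  bad <- setdiff(columns, table$col_names)
  if (length(bad)) {
    gv_error(sprintf("no such column '%s'", bad[1]), "gv_provider_error")
  }
  nonnum <- columns[table$col_types[match(columns, table$col_names)] != "numeric"]
  if (length(nonnum)) {
    gv_error(sprintf("column '%s' is not numeric", nonnum[1]), "gv_provider_error")
  }
  rows <- lapply(columns, function(cn) {
    x <- table$data[[cn]]
    miss <- sum(is.na(x))
    x <- x[!is.na(x)]
    data.frame(column = cn,
               min = if (length(x)) min(x) else NA_real_,
               max = if (length(x)) max(x) else NA_real_,
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
               n = length(x), n_missing = miss,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' LRU payload cache
#'
#' Fixed-capacity least-recently-used cache for provider payloads.
#' [cached_get_data()] is transparent: its result is identical to an
#' uncached [get_data()] call.  Exact-key repeats are served from the
#' cache; additionally, a cached detail payload whose region contains the
#' query region (same dataset and `max_detail`) is reused by
#' sub-selection.  Hit/miss counters are exposed via [cache_stats()].
#'
#' @param capacity Maximum number of cached payloads (>= 1).
#' @return An object of class `gv_cache`.
#' @export
gv_cache <- function(capacity = 32) {
  stopifnot(is_count(capacity), capacity >= 1)
  e <- new.env(parent = emptyenv())
  e$capacity <- capacity
  e$entries <- list()
  e$order <- character(0)  # most recently used first
  e$hits <- 0L
  e$misses <- 0L
  class(e) <- "gv_cache"
  e
}

#' @rdname gv_cache
#' @param cache A `gv_cache`.
#' @export
cache_stats <- function(cache) {
  list(hits = cache$hits, misses = cache$misses, size = length(cache$entries))
}

cache_touch <- function(cache, key) {
  cache$order <- c(key, setdiff(cache$order, key))
}

#' @rdname gv_cache
#' @inheritParams get_data
#' @export
cached_get_data <- function(cache, dataset, index, region,
                            max_detail = DEFAULT_MAX_DETAIL,
                            nbins = DEFAULT_NBINS) {
  stopifnot(inherits(cache, "gv_cache"))
  id <- dataset$checksum$md5 %||% dataset$path
  key <- paste(id, region$chrom, region$start, region$end, max_detail, nbins,
               sep = "|")
  if (!is.null(cache$entries[[key]])) {
    cache$hits <- cache$hits + 1L
    cache_touch(cache, key)
    return(cache$entries[[key]]$payload)
  }
  # containment reuse: sub-select from a cached detail payload covering us
  for (k in cache$order) {
    ent <- cache$entries[[k]]
    if (ent$id == id && ent$max_detail == max_detail &&
        ent$payload$mode == "detail" &&
        ent$region$chrom == region$chrom &&
        ent$region$start <= region$start && ent$region$end >= region$end) {
      recs <- ent$payload$records
      sel <- recs$start < region$end & recs$end > region$start
      cache$hits <- cache$hits + 1L
      cache_touch(cache, k)
      return(payload("detail", records = recs[sel, , drop = FALSE],
                     total = sum(sel)))
    }
  }
  cache$misses <- cache$misses + 1L
  pl <- get_data(dataset, index, region, max_detail, nbins)
  cache$entries[[key]] <- list(payload = pl, id = id, region = region,
                               max_detail = max_detail, nbins = nbins)
  cache_touch(cache, key)
  while (length(cache$entries) > cache$capacity) {
    drop <- cache$order[length(cache$order)]
    cache$entries[[drop]] <- NULL
    cache$order <- setdiff(cache$order, drop)
  }
  pl
}

#' Serialize a payload to the documented JSON schema
#'
#' `{"mode": ..., "total": n, "message": m, "data": [...]}` where detail
#' features serialize as `[start, end, name, score, strand, attributes]`
#' and summary data as `{"nbins": b, "stat": s, "values": [...]}`.
#'
#' @param pl A `gv_payload`.
#' @return JSON string.
#' @export
payload_to_json <- function(pl) {
  data <- if (pl$mode == "detail") {
    recs <- pl$records
    lapply(seq_len(nrow(recs)), function(i) {
      list(recs$start[i], recs$end[i],
           if (!is.null(recs$name)) recs$name[i] else NULL,
           if (!is.null(recs$score)) recs$score[i] else NULL,
           if (!is.null(recs$strand)) recs$strand[i] else NULL,
           if (!is.null(recs$attributes)) as.list(recs$attributes[[i]]) else NULL)
    })
  } else {
    list(nbins = pl$summary$nbins, stat = pl$summary$stat,
         values = pl$summary$values)
  }
  as.character(jsonlite::toJSON(
    list(mode = pl$mode, total = pl$total_in_region,
         message = pl$message, data = data),
    auto_unbox = TRUE, null = "null", na = "null", digits = NA))
}
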