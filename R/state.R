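GV_APPS <- c("trackster", "circster", "sweepster", "phyloviz", "scatterplot")
GV_FORMATS <- c("bed", "gff3", "gtf", "interval", "sam",
                "wiggle", "bedgraph", "vcf", "table")
GV_DISPLAY_MODES <- c("dense", "squish", "pack", "coverage", "auto")
GV_STATE_SCHEMA_VERSION <- 1L

#' Track configuration for a saved visualization
#'
#' @param dataset_path Path of the dataset the track displays.
#' @param format One of the supported format names (`"bed"`, `"gff3"`,
#'   `"gtf"`, `"interval"`, `"sam"`, `"wiggle"`, `"bedgraph"`, `"vcf"`,
#'   `"table"`).
#' @param display_mode One of `"dense"`, `"squish"`, `"pack"`,
#'   `"coverage"`, `"auto"` (default).
#' @param color Hex color string.
#' @param filters List of [filter_spec()] objects.
#' @param group Optional group id: tracks sharing a group are drawn as one
#'   composite ("rainbow") band.
#' @return An object of class `gv_track_config`.
#' @export
track_config <- function(dataset_path, format, display_mode = "auto",
                         color = "#2c7fb8", filters = list(), group = NULL) {
  if (!format %in% GV_FORMATS) {
    gv_error(sprintf("unsupported format '%s'", format), "gv_state_error")
  }
  if (!display_mode %in% GV_DISPLAY_MODES) {
    gv_error(sprintf("unsupported display mode '%s'", display_mode), "gv_state_error")
  }
  if (!grepl("^#[0-9a-fA-F]{6}$", color)) {
    gv_error(sprintf("color '%s' is not a hex string", color), "gv_state_error")
  }
  structure(
    list(dataset_path = dataset_path, format = format,
         display_mode = display_mode, color = color,
         filters = filters, group = group),
    class = "gv_track_config"
  )
}

#' Saved visualization state
#'
#' The complete state of one visual application, serializable to JSON with
#' [encode_state()] so a visualization can be saved and reopened later.
#'
#' @param app Application type: one of `"trackster"`, `"circster"`,
#'   `"sweepster"`, `"phyloviz"`, `"scatterplot"`.
#' @param genome_id Genome identifier string.
#' @param view Current viewing window ([gv_region()]) or `NULL`.
#' @param tracks Ordered list of [track_config()]s.
#' @param bookmarks List of [gv_bookmark()]s.
#' @param settings Named list of scalar preferences.
#' @param schema_version Integer schema version, currently 1.
#' @return An object of class `gv_state`.
#' @export
gv_state <- function(app, genome_id, view = NULL, tracks = list(),
                     bookmarks = list(), settings = list(),
                     schema_version = GV_STATE_SCHEMA_VERSION) {
  if (!app %in% GV_APPS) {
    gv_error(sprintf("unsupported app '%s' (known: %s)",
                     app, paste(GV_APPS, collapse = ", ")), "gv_state_error")
  }
  structure(
    list(app = app, genome_id = genome_id, view = view, tracks = tracks,
         bookmarks = bookmarks, settings = settings,
         schema_version = as.integer(schema_version), extra = list()),
    class = "gv_state"
  )
}

region_to_list <- function(r) {
  if (is.null(r)) return(NULL)
  list(chrom = r$chrom, start = r$start, end = r$end, strand = r$strand)
}

region_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  gv_region(x$chrom, x$start, x$end, x$strand %||% "*")
}

filter_to_list <- function(f) {
  list(attribute = f$attribute,
       min = if (is.finite(f$min)) f$min else NULL,
       max = if (is.finite(f$max)) f$max else NULL,
       missing_passes = f$missing_passes)
}

filter_from_list <- function(x) {
  filter_spec(x$attribute, min = x$min %||% -Inf, max = x$max %||% Inf,
              missing_passes = x$missing_passes %||% TRUE)
}

#' Serialize visualization state to JSON (and back)
#'
#' The round trip is lossless: `decode_state(encode_state(s))` is
#' structurally identical to `s`.  Decoding is forward-compatible — keys
#' the current schema does not know are preserved under `$extra` and
#' re-emitted by `encode_state()` — but a document without a
#' `schema_version` or with an unknown `app` is rejected.
#'
#' @param state A [gv_state()].
#' @return `encode_state`: a JSON string; `decode_state`: a [gv_state()].
#' @examples
#' s <- gv_state("circster", "toy")
#' identical(decode_state(encode_state(s)), s)
#' @export
encode_state <- function(state) {
  stopifnot(inherits(state, "gv_state"))
  doc <- list(
    schema_version = state$schema_version,
    app = state$app,
    genome_id = state$genome_id,
    view = region_to_list(state$view),
    tracks = lapply(state$tracks, function(t) {
      list(dataset_path = t$dataset_path, format = t$format,
           display_mode = t$display_mode, color = t$color,
           filters = lapply(t$filters, filter_to_list),
           group = t$group)
    }),
    bookmarks = lapply(state$bookmarks, function(b) {
      list(region = region_to_list(b$region), annotation = b$annotation)
    }),
    settings = state$settings
  )
  doc <- c(doc, state$extra)
  # 17 significant digits: doubles survive the round trip bit-exactly
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                                digits = I(17)))
}

#' @rdname encode_state
#' @param json JSON document produced by `encode_state` (or a compatible
#'   newer writer).
#' @export
decode_state <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (is.null(doc$schema_version)) {
    gv_error("state document has no schema_version", "gv_state_error")
  }
  if (is.null(doc$app) || !doc$app %in% GV_APPS) {
    gv_error(sprintf("state document has unsupported app '%s'",
                     doc$app %||% "<missing>"), "gv_state_error")
  }
  known <- c("schema_version", "app", "genome_id", "view", "tracks",
             "bookmarks", "settings")
  st <- gv_state(
    app = doc$app,
    genome_id = doc$genome_id,
    view = region_from_list(doc$view),
    tracks = lapply(doc$tracks, function(t) {
      track_config(t$dataset_path, t$format, t$display_mode, t$color,
                   filters = lapply(t$filters, filter_from_list),
                   group = t$group)
    }),
    bookmarks = lapply(doc$bookmarks, function(b) {
      gv_bookmark(region_from_list(b$region), b$annotation %||% "")
    }),
    settings = doc$settings %||% list(),
    schema_version = doc$schema_version
  )
  extra <- doc[setdiff(names(doc), known)]
  st$extra <- if (length(extra)) extra else list()
  st
}
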