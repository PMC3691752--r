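#' Pack features into non-overlapping display rows
#'
#' Greedy first-fit over features ordered by `(start, end, name)`: each
#' feature goes into the lowest-numbered slot whose last occupant (with
#' `label_pad` bases appended for its label) ends at or before the
#' feature's start.  On interval inputs first-fit by sorted start is
#' optimal, so `n_slots` equals the maximum overlap depth of the padded
#' intervals.
#'
#' @param features A [gv_features()] data frame (one chromosome).
#' @param label_pad Extra bases reserved after each feature for its label
#'   (label length times per-character base width, supplied by the
#'   caller so the core stays resolution-agnostic).
#' @return List with `slots` (integer row per input feature, 0-based) and
#'   `n_slots`.
#' @export
pack_features <- function(features, label_pad = 0) {
  n <- nrow(features)
  if (n && length(unique(features$chrom)) > 1L) {
    gv_error("pack_features expects features on a single chromosome",
             "gv_layout_error")
  }
  slots <- integer(n)
  if (!n) return(list(slots = slots, n_slots = 0L))
  nm <- features$name
  nm[is.na(nm)] <- ""
  ord <- order(features$start, features$end, nm)
  slot_free_at <- numeric(0)   # first base at which each slot is free
  for (i in ord) {
    s <- features$start[i]
    e <- features$end[i] + label_pad
    fit <- which(slot_free_at <= s)
    if (length(fit)) {
      slot <- fit[1]
    } else {
      slot_free_at <- c(slot_free_at, 0)
      slot <- length(slot_free_at)
    }
    slot_free_at[slot] <- e
    slots[i] <- slot - 1L
  }
  list(slots = slots, n_slots = length(slot_free_at))
}

#' Circular (Circos-style) chromosome layout
#'
#' Places chromosomes as arcs of a circle in genome order, clockwise from
#' the origin angle (default 12 o'clock), separated by fixed gaps.  Each
#' arc spans `(2 * pi - n * gap) * length / total_length` radians, so arc
#' widths are proportional to chromosome lengths and the arcs plus gaps
#' tile the full circle exactly.
#'
#' @param genome A [gv_genome()].
#' @param gap Gap between adjacent chromosomes, radians (default 0.01).
#' @param origin Angle of the first chromosome's start, radians clockwise
#'   from 12 o'clock.
#' @return An object of class `gv_circular_layout`: data frame `arcs`
#'   (`chrom`, `length`, `start_angle`, `end_angle`) plus `gap` and
#'   `origin`.  Angles are clockwise from 12 o'clock.
#' @export
circular_chromosome_layout <- function(genome, gap = 0.01, origin = 0) {
  chroms <- genome$chromosomes
  n <- nrow(chroms)
  if (gap < 0 || n * gap >= 2 * pi) {
    gv_error(sprintf("gap %g too large: need 0 <= n * gap < 2 * pi", gap),
             "gv_layout_error")
  }
  span <- (2 * pi - n * gap) * chroms$length / sum(chroms$length)
  start_angle <- origin + cumsum(c(0, (span + gap)[-n]))
  arcs <- data.frame(chrom = chroms$name, length = chroms$length,
                     start_angle = start_angle,
                     end_angle = start_angle + span,
                     stringsAsFactors = FALSE)
  structure(list(arcs = arcs, gap = gap, origin = origin),
            class = "gv_circular_layout")
}

layout_arc <- function(layout, chrom) {
  i <- match(chrom, layout$arcs$chrom)
  if (is.na(i)) {
    gv_error(sprintf("chromosome '%s' not in layout", chrom), "gv_layout_error")
  }
  layout$arcs[i, ]
}

#' Map a chromosome position to its angle on the circle
#'
#' Affine within each chromosome — `start_angle + (pos / length) * arc` —
#' hence strictly monotone in position and continuous within a
#' chromosome.
#'
#' @param layout A [circular_chromosome_layout()].
#' @param chrom Chromosome name.
#' @param pos Position in `[0, length]`.
#' @return Angle in radians (clockwise from 12 o'clock).
#' @export
position_to_angle <- function(layout, chrom, pos) {
  arc <- layout_arc(layout, chrom)
  if (any(pos < 0) || any(pos > arc$length)) {
    gv_error(sprintf("position out of range for %s (length %s)", chrom,
                     format(arc$length)), "gv_layout_error")
  }
  arc$start_angle + (pos / arc$length) * (arc$end_angle - arc$start_angle)
}

# clockwise-from-12-o'clock polar to cartesian
angle_to_xy <- function(angle, r, cx = 0, cy = 0) {
  c(cx + r * sin(angle), cy - r * cos(angle))
}

#' Chord path between two loci across the circle interior
#'
#' Interaction data (3-D contacts, gene fusions) is drawn as chords:
#' quadratic curves anchored at the angle of each region's midpoint on
#' radius `r_chord`, with the control point at the circle center, keeping
#' chords inside the innermost data annulus.
#'
#' @param layout A [circular_chromosome_layout()].
#' @param region_a,region_b The two loci ([gv_region()]).
#' @param r_chord Anchor radius; must lie below the innermost annulus
#'   when `annuli` is supplied.
#' @param annuli Optional annulus table (see [track_annuli()]) used to
#'   validate `r_chord`.
#' @param cx,cy Circle center.
#' @return List with anchor points `a`, `b`, `control`, and an SVG `path`
#'   string.
#' @export
chord_endpoints <- function(layout, region_a, region_b, r_chord,
                            annuli = NULL, cx = 0, cy = 0) {
  if (!is.null(annuli) && r_chord >= min(annuli$r_inner)) {
    gv_error(sprintf("r_chord %g intrudes into the innermost annulus (r_inner %g)",
                     r_chord, min(annuli$r_inner)), "gv_layout_error")
  }
  mid_a <- (region_a$start + region_a$end) / 2
  mid_b <- (region_b$start + region_b$end) / 2
  a <- angle_to_xy(position_to_angle(layout, region_a$chrom, mid_a), r_chord, cx, cy)
  b <- angle_to_xy(position_to_angle(layout, region_b$chrom, mid_b), r_chord, cx, cy)
  list(a = a, b = b, control = c(cx, cy),
       path = sprintf("M %s %s Q %s %s %s %s",
                      fmt_num(a[1]), fmt_num(a[2]), fmt_num(cx), fmt_num(cy),
                      fmt_num(b[1]), fmt_num(b[2])))
}

#' Allocate disjoint annuli for circular tracks
#'
#' Divides the radial band `[r_inner, r_outer]` into one annulus per
#' track, ordered inside-out, with a fixed pad between adjacent annuli.
#'
#' @param n_tracks Number of tracks.
#' @param r_inner,r_outer Radial extent of the data band.
#' @param pad Radial padding between annuli.
#' @return Data frame with `track`, `r_inner`, `r_outer`.
#' @export
track_annuli <- function(n_tracks, r_inner, r_outer, pad = 2) {
  stopifnot(n_tracks >= 1, r_outer > r_inner)
  h <- (r_outer - r_inner - (n_tracks - 1) * pad) / n_tracks
  if (h <= 0) gv_error("annulus band too thin for the track count", "gv_layout_error")
  r0 <- r_inner + (seq_len(n_tracks) - 1) * (h + pad)
  data.frame(track = seq_len(n_tracks), r_inner = r0, r_outer = r0 + h)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

svg_open <- function(width, height, background = "#ffffff") {
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt_num(width, 0), fmt_num(height, 0), fmt_num(width, 0), fmt_num(height, 0)),
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="%s"/>',
            fmt_num(width, 0), fmt_num(height, 0), background))
}

# step-outline histogram path over [x0, x1] from per-bin values
linear_hist_path <- function(values, x0, x1, y_base, y_top) {
  nb <- length(values)
  vmax <- max(c(values, 0), na.rm = TRUE)
  scale <- if (vmax > 0) (y_base - y_top) / vmax else 0
  xs <- x0 + (x1 - x0) * (0:nb) / nb
  v <- ifelse(is.na(values), 0, values)
  parts <- sprintf("L %s %s L %s %s",
                   fmt_num(xs[-length(xs)]), fmt_num(y_base - v * scale),
                   fmt_num(xs[-1]), fmt_num(y_base - v * scale))
  paste0(sprintf("M %s %s ", fmt_num(x0), fmt_num(y_base)),
         paste(parts, collapse = " "),
         sprintf(" L %s %s Z", fmt_num(x1), fmt_num(y_base)))
}

# radial histogram path for one chromosome arc: steps at value radius,
# closed along the inner radius
circular_hist_path <- function(values, a0, a1, r0, r1, vmax, cx, cy) {
  nb <- length(values)
  v <- ifelse(is.na(values), 0, values)
  scale <- if (vmax > 0) (r1 - r0) / vmax else 0
  ang <- a0 + (a1 - a0) * (0:nb) / nb
  pts_out <- character(2 * nb)
  for (i in seq_len(nb)) {
    r <- r0 + v[i] * scale
    p1 <- angle_to_xy(ang[i], r, cx, cy)
    p2 <- angle_to_xy(ang[i + 1], r, cx, cy)
    pts_out[2 * i - 1] <- sprintf("L %s %s", fmt_num(p1[1]), fmt_num(p1[2]))
    pts_out[2 * i] <- sprintf("L %s %s", fmt_num(p2[1]), fmt_num(p2[2]))
  }
  start <- angle_to_xy(a0, r0, cx, cy)
  end <- angle_to_xy(a1, r0, cx, cy)
  paste0(sprintf("M %s %s ", fmt_num(start[1]), fmt_num(start[2])),
         paste(pts_out, collapse = " "),
         sprintf(" L %s %s Z", fmt_num(end[1]), fmt_num(end[2])))
}

#' Render payloads as a static SVG document
#'
#' A pure function of its inputs: rerendering the same payloads yields a
#' byte-identical document.  Linear mode stacks one horizontal band per
#' track over a shared region axis; detail payloads are drawn as packed
#' feature rectangles (one row per slot), summary payloads as a single
#' histogram path per track.  Circular mode draws chromosome arcs from a
#' [circular_chromosome_layout()] and one histogram path per track per
#' chromosome in concentric annuli, with optional interaction chords in
#' the interior.
#'
#' @param payloads Linear mode: list of `gv_payload` for one region.
#'   Circular mode: list of [get_genome_wide()] results (one per track).
#' @param mode `"linear"` or `"circular"`.
#' @param region Linear mode: the rendered [gv_region()].
#' @param genome,layout Circular mode: the genome and its layout (layout
#'   computed from `genome` when `NULL`).
#' @param chords Circular mode: optional list of `list(a = region, b =
#'   region)` interaction pairs.
#' @param width,height Canvas size in pixels.
#' @param style Named list overriding defaults: `colors` (per track),
#'   `track_height`, `background`, `r_inner`, `r_outer`, `chord_r`,
#'   `label_pad`.
#' @return The SVG document as a single string.
#' @export
render_svg <- function(payloads, mode = c("linear", "circular"),
                       region = NULL, genome = NULL, layout = NULL,
                       chords = NULL, width = 800, height = NULL,
                       style = list()) {
  mode <- match.arg(mode)
  if (width <= 0 || (!is.null(height) && height <= 0)) {
    gv_error("SVG dimensions must be positive", "gv_layout_error")
  }
  defaults <- list(colors = rep(c("#2c7fb8", "#d95f02", "#1b9e77", "#7570b3",
                                  "#e7298a", "#66a61e"),
                                length.out = max(1, length(payloads))),
                   track_height = 80, background = "#ffffff",
                   r_inner = 0.25, r_outer = 0.95, chord_r = 0.22,
                   label_pad = 0)
  style <- utils::modifyList(defaults, style)
  if (mode == "linear") {
    render_svg_linear(payloads, region, width, style)
  } else {
    render_svg_circular(payloads, genome, layout, chords, width, style)
  }
}

render_svg_linear <- function(payloads, region, width, style) {
  if (is.null(region) && length(payloads)) {
    gv_error("linear rendering needs the rendered region", "gv_layout_error")
  }
  th <- style$track_height
  height <- max(th * length(payloads), th)
  body <- svg_open(width, height, style$background)
  x_of <- function(pos) (pos - region$start) / region_width(region) * width
  for (k in seq_along(payloads)) {
    pl <- payloads[[k]]
    col <- style$colors[[k]]
    y0 <- (k - 1) * th
    body <- c(body, sprintf('<g id="track%d">', k))
    if (pl$mode == "summary") {
      body <- c(body, sprintf('<path d="%s" fill="%s"/>',
                              linear_hist_path(pl$summary$values, 0, width,
                                               y0 + th - 4, y0 + 4),
                              col))
    } else {
      recs <- pl$records
      pk <- pack_features(recs, style$label_pad)
      rows <- max(pk$n_slots, 1)
      rh <- (th - 8) / rows
      for (i in seq_len(nrow(recs))) {
        xs <- x_of(max(recs$start[i], region$start))
        xe <- x_of(min(recs$end[i], region$end))
        body <- c(body, sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
                                fmt_num(xs), fmt_num(y0 + 4 + pk$slots[i] * rh),
                                fmt_num(max(xe - xs, 0.5)),
                                fmt_num(max(rh - 1, 1)), col))
      }
    }
    body <- c(body, "</g>")
  }
  paste(c(body, "</svg>"), collapse = "\n")
}

render_svg_circular <- function(track_summaries, genome, layout, chords,
                                width, style) {
  if (is.null(genome)) {
    gv_error("circular rendering needs a genome", "gv_layout_error")
  }
  layout <- layout %||% circular_chromosome_layout(genome)
  height <- width
  cx <- width / 2; cy <- height / 2
  rmax <- width / 2 * 0.98
  body <- svg_open(width, height, style$background)
  # chromosome backbone arcs
  backbone_r <- rmax
  for (i in seq_len(nrow(layout$arcs))) {
    arc <- layout$arcs[i, ]
    p0 <- angle_to_xy(arc$start_angle, backbone_r, cx, cy)
    p1 <- angle_to_xy(arc$end_angle, backbone_r, cx, cy)
    large <- if ((arc$end_angle - arc$start_angle) > pi) 1 else 0
    body <- c(body, sprintf('<path d="M %s %s A %s %s 0 %d 1 %s %s" fill="none" stroke="#444444" stroke-width="2"/>',
                            fmt_num(p0[1]), fmt_num(p0[2]),
                            fmt_num(backbone_r), fmt_num(backbone_r), large,
                            fmt_num(p1[1]), fmt_num(p1[2])))
  }
  n_tracks <- length(track_summaries)
  if (n_tracks) {
    ann <- track_annuli(n_tracks, style$r_inner * rmax, style$r_outer * rmax)
    for (k in seq_len(n_tracks)) {
      per_chrom <- track_summaries[[k]]
      col <- style$colors[[k]]
      vmax <- max(c(unlist(lapply(per_chrom, `[[`, "values")), 0), na.rm = TRUE)
      body <- c(body, sprintf('<g id="track%d">', k))
      for (i in seq_len(nrow(layout$arcs))) {
        arc <- layout$arcs[i, ]
        sb <- per_chrom[[arc$chrom]]
        if (is.null(sb)) next
        body <- c(body, sprintf('<path d="%s" fill="%s" fill-opacity="0.8"/>',
                                circular_hist_path(sb$values,
                                                   arc$start_angle, arc$end_angle,
                                                   ann$r_inner[k], ann$r_outer[k],
                                                   vmax, cx, cy),
                                col))
      }
      body <- c(body, "</g>")
    }
  }
  for (ch in chords %||% list()) {
    ce <- chord_endpoints(layout, ch$a, ch$b, style$chord_r * rmax,
                          cx = cx, cy = cy)
    body <- c(body, sprintf('<path d="%s" fill="none" stroke="#cc4444" stroke-width="1"/>',
                            ce$path))
  }
  paste(c(body, "</svg>"), collapse = "\n")
}
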