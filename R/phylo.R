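#' Phylogenetic tree node
#'
#' Trees are rooted, nested lists: each node carries `name` (or `NULL`),
#' `branch_length` (non-negative, or `NULL` when the source gave none),
#' `annotation` (free text), `children` (ordered list) and `collapsed`.
#' Missing branch lengths are preserved as `NULL` in the data and only
#' rendered as unit lengths at layout time.
#'
#' @param name Node label or `NULL`.
#' @param branch_length Branch length to the parent, `>= 0`, or `NULL`.
#' @param children Ordered list of child nodes.
#' @param annotation Free-text annotation.
#' @param collapsed Whether the subtree is displayed collapsed.
#' @return A node (class `gv_phylo_node`).
#' @export
phylo_node <- function(name = NULL, branch_length = NULL, children = list(),
                       annotation = "", collapsed = FALSE) {
  if (!is.null(branch_length) && (is.na(branch_length) || branch_length < 0)) {
    gv_error("branch length must be >= 0", "gv_phylo_error")
  }
  structure(list(name = name, branch_length = branch_length,
                 annotation = annotation, children = children,
                 collapsed = collapsed),
            class = "gv_phylo_node")
}

is_leaf <- function(node) length(node$children) == 0L

#' @export
print.gv_phylo_node <- function(x, ...) {
  n <- count_tree_nodes(x)
  cat(sprintf("<gv_phylo_node: %d nodes, %d leaves>\n", n$nodes, n$leaves))
  invisible(x)
}

count_tree_nodes <- function(node) {
  if (is_leaf(node)) return(list(nodes = 1L, leaves = 1L))
  sub <- lapply(node$children, count_tree_nodes)
  list(nodes = 1L + sum(vapply(sub, `[[`, 0L, "nodes")),
       leaves = sum(vapply(sub, `[[`, 0L, "leaves")))
}

# --- newick ---------------------------------------------------------------

NWK_SPECIALS <- c("(", ")", ",", ";", ":")

newick_tokenize <- function(text) {
  # protect quoted labels ('' is an escaped quote), then split on specials
  quoted <- character(0)
  m <- gregexpr("'(?:[^']|'')*'", text, perl = TRUE)[[1]]
  if (m[1] != -1) {
    quoted <- regmatches(text, list(m))[[1]]
    for (i in seq_along(quoted)) {
      text <- sub(quoted[i], sprintf("\x01%d\x01", i), text, fixed = TRUE)
    }
  }
  text <- gsub("[\\s]+", "", text, perl = TRUE)
  toks <- strsplit(text, "(?<=[(),;:])|(?=[(),;:])", perl = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  attr(toks, "quoted") <- quoted
  toks
}

newick_decode_label <- function(tok, quoted) {
  m <- regmatches(tok, regexec("^\x01([0-9]+)\x01$", tok))[[1]]
  if (length(m)) {
    q <- quoted[as.integer(m[2])]
    return(gsub("''", "'", substr(q, 2, nchar(q) - 1), fixed = TRUE))
  }
  gsub("_", " ", tok, fixed = TRUE)
}

parse_newick <- function(text) {
  toks <- newick_tokenize(text)
  quoted <- attr(toks, "quoted")
  pos <- local({ i <- 1L; list(peek = function() if (i <= length(toks)) toks[i] else NA_character_,
                               take = function() { t <- toks[i]; i <<- i + 1L; t },
                               at = function() i) })
  expect <- function(t) {
    got <- pos$take()
    if (!identical(got, t)) {
      gv_error(sprintf("newick parse error near token %d: expected '%s', got '%s'",
                       pos$at() - 1L, t, got %||% "<end>"), "gv_phylo_error")
    }
  }
  subtree <- function() {
    name <- NULL; children <- list()
    if (identical(pos$peek(), "(")) {
      pos$take()
      children <- list(subtree())
      while (identical(pos$peek(), ",")) {
        pos$take()
        children <- c(children, list(subtree()))
      }
      expect(")")
    }
    tk <- pos$peek()
    if (!is.na(tk) && !tk %in% NWK_SPECIALS) {
      name <- newick_decode_label(pos$take(), quoted)
    }
    bl <- NULL
    if (identical(pos$peek(), ":")) {
      pos$take()
      bl <- suppressWarnings(as.numeric(pos$take()))
      if (is.na(bl)) gv_error("newick: non-numeric branch length", "gv_phylo_error")
    }
    phylo_node(name, bl, children)
  }
  root <- subtree()
  if (!identical(pos$peek(), ";")) {
    gv_error("newick: missing terminating ';' (or unbalanced parentheses)",
             "gv_phylo_error")
  }
  root
}

#' Write a tree as a Newick string
#'
#' The inverse of Newick parsing: `parse_tree(write_newick(t), "newick")`
#' is isomorphic to `t` with identical names and branch lengths.  Labels
#' needing protection (spaces, underscores, punctuation) are
#' single-quoted; branch lengths are written with full (17 significant
#' digit) precision so they survive the round trip exactly.
#'
#' @param root A [phylo_node()] tree.
#' @return Newick text (including the terminating semicolon).
#' @export
write_newick <- function(root) {
  fmt_label <- function(name) {
    if (is.null(name) || !nzchar(name)) return("")
    if (grepl("[^A-Za-z0-9.+/|-]", name)) {
      paste0("'", gsub("'", "''", name, fixed = TRUE), "'")
    } else name
  }
  fmt_node <- function(node) {
    base <- if (is_leaf(node)) {
      fmt_label(node$name)
    } else {
      paste0("(", paste(vapply(node$children, fmt_node, ""), collapse = ","),
             ")", fmt_label(node$name))
    }
    if (!is.null(node$branch_length)) {
      base <- paste0(base, ":", sprintf("%.17g", node$branch_length))
    }
    base
  }
  paste0(fmt_node(root), ";")
}

# --- phyloxml and nexus ---------------------------------------------------

parse_phyloxml <- function(text) {
  doc <- xml2::read_xml(text)
  xml2::xml_ns_strip(doc)
  clade <- xml2::xml_find_first(doc, ".//phylogeny/clade")
  if (inherits(clade, "xml_missing")) {
    gv_error("phyloxml: no phylogeny/clade element", "gv_phylo_error")
  }
  supported <- c("clade", "name", "branch_length", "confidence")
  unknown <- new.env(parent = emptyenv()); unknown$seen <- character(0)
  walk <- function(cl) {
    kids <- xml2::xml_children(cl)
    tags <- xml2::xml_name(kids)
    unknown$seen <- union(unknown$seen, setdiff(tags, supported))
    name <- if ("name" %in% tags) xml2::xml_text(kids[[which(tags == "name")[1]]]) else NULL
    bl <- xml2::xml_attr(cl, "branch_length")
    if (is.na(bl) && "branch_length" %in% tags) {
      bl <- xml2::xml_text(kids[[which(tags == "branch_length")[1]]])
    }
    bl <- if (is.na(bl) || is.null(bl)) NULL else as.numeric(bl)
    children <- lapply(kids[tags == "clade"], walk)
    phylo_node(name, bl, children)
  }
  root <- walk(clade)
  if (length(unknown$seen)) {
    warning(sprintf("phyloxml: skipped unsupported elements: %s",
                    paste(sort(unknown$seen), collapse = ", ")), call. = FALSE)
  }
  root
}

parse_nexus <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lower <- tolower(trimws(lines))
  b0 <- which(lower == "begin trees;")
  if (!length(b0)) gv_error("nexus: no TREES block", "gv_phylo_error")
  b1 <- which(lower == "end;" | lower == "endblock;")
  b1 <- b1[b1 > b0[1]]
  if (!length(b1)) gv_error("nexus: unterminated TREES block", "gv_phylo_error")
  block <- paste(lines[(b0[1] + 1):(b1[1] - 1)], collapse = "\n")
  other_blocks <- grepl("begin (?!trees)", tolower(text), perl = TRUE)
  if (other_blocks) {
    warning("nexus: blocks other than TREES are ignored", call. = FALSE)
  }
  translate <- character(0)
  tm <- regmatches(block, regexpr("(?is)translate\\s+.*?;", block, perl = TRUE))
  if (length(tm)) {
    body <- sub(";$", "", sub("(?is)^translate\\s+", "", tm, perl = TRUE))
    pairs <- strsplit(trimws(strsplit(body, ",")[[1]]), "\\s+")
    translate <- stats::setNames(
      vapply(pairs, function(p) gsub("'", "", p[2]), ""),
      vapply(pairs, `[[`, "", 1)
    )
    block <- sub("(?is)translate\\s+.*?;", "", block, perl = TRUE)
  }
  tstmt <- regmatches(block, regexpr("(?is)tree\\s+[^=]+=\\s*(\\[[^]]*\\])?\\s*[^;]+;",
                                     block, perl = TRUE))
  if (!length(tstmt)) gv_error("nexus: no tree statement in TREES block", "gv_phylo_error")
  nwk <- sub("(?is)^tree\\s+[^=]+=\\s*", "", tstmt, perl = TRUE)
  nwk <- gsub("\\[[^]]*\\]", "", nwk)  # drop comments like [&U]
  root <- parse_newick(nwk)
  if (length(translate)) {
    rename <- function(node) {
      if (!is.null(node$name) && node$name %in% names(translate)) {
        node$name <- unname(translate[[node$name]])
      }
      node$children <- lapply(node$children, rename)
      node
    }
    root <- rename(root)
  }
  root
}

#' Parse a phylogenetic tree
#'
#' Reads the three common interchange formats: Newick (quoted labels and
#' the underscore-for-space convention handled), a PhyloXML subset (clade
#' nesting, names, branch lengths; other elements are skipped with a
#' warning) and Nexus (the newick embedded in the TREES block, honoring a
#' `translate` table; other blocks are ignored with a warning).
#'
#' @param x Path to a tree file, or the tree text itself.
#' @param format `"newick"`, `"phyloxml"` or `"nexus"`.
#' @return The root [phylo_node()].
#' @examples
#' parse_tree("(A:1,B:2):0;", "newick")
#' @export
parse_tree <- function(x, format = c("newick", "phyloxml", "nexus")) {
  format <- match.arg(format)
  text <- if (length(x) == 1L && !grepl("[(<\n]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  switch(format,
    newick = parse_newick(text),
    phyloxml = parse_phyloxml(text),
    nexus = parse_nexus(text)
  )
}

# --- layout ---------------------------------------------------------------

#' Rectangular dendrogram layout
#'
#' Leaves take vertical rows 0, 1, 2, ... in traversal order; each
#' internal node sits at the arithmetic mean of its children's rows.
#' Horizontal position is the cumulative distance from the root, using a
#' unit length wherever a branch length is missing.  With
#' `collapse_respected = TRUE` (default), collapsed nodes are treated as
#' leaves, occupying a single row.
#'
#' @param root A [phylo_node()] tree.
#' @param collapse_respected Honor `collapsed` flags.
#' @return Data frame with one row per laid-out node: `path` (dotted
#'   child-index address, `""` for the root), `name`, `x`, `y`, `leaf`.
#' @export
layout_tree <- function(root, collapse_respected = TRUE) {
  acc <- new.env(parent = emptyenv())
  acc$rows <- vector("list", 256)
  acc$i <- 0L
  acc$next_y <- 0
  push <- function(row) {
    acc$i <- acc$i + 1L
    if (acc$i > length(acc$rows)) acc$rows <- c(acc$rows, vector("list", length(acc$rows)))
    acc$rows[[acc$i]] <- row
  }
  walk <- function(node, path, x0) {
    x <- x0 + (node$branch_length %||% if (identical(path, "")) 0 else 1)
    terminal <- is_leaf(node) || (collapse_respected && node$collapsed)
    if (terminal) {
      y <- acc$next_y
      acc$next_y <- acc$next_y + 1
    } else {
      ys <- vapply(seq_along(node$children), function(i) {
        walk(node$children[[i]],
             if (identical(path, "")) as.character(i) else paste(path, i, sep = "."),
             x)
      }, 0)
      y <- mean(ys)
    }
    push(list(path = path, name = node$name %||% NA_character_,
              x = x, y = y, leaf = terminal))
    y
  }
  walk(root, "", 0)
  rows <- acc$rows[seq_len(acc$i)]
  data.frame(
    path = vapply(rows, `[[`, "", "path"),
    name = vapply(rows, `[[`, "", "name"),
    x = vapply(rows, `[[`, 0, "x"),
    y = vapply(rows, `[[`, 0, "y"),
    leaf = vapply(rows, `[[`, TRUE, "leaf"),
    stringsAsFactors = FALSE
  )
}

# --- search and edit ------------------------------------------------------

node_at <- function(root, path) {
  if (!nzchar(path)) return(root)
  idx <- as.integer(strsplit(path, ".", fixed = TRUE)[[1]])
  node <- root
  for (i in idx) {
    if (i < 1 || i > length(node$children)) {
      gv_error(sprintf("no node at path '%s'", path), "gv_phylo_error")
    }
    node <- node$children[[i]]
  }
  node
}

#' Search tree nodes by name, annotation, or root distance
#'
#' Exactly one criterion must be given.  Name and annotation queries are
#' case-insensitive substring matches (an empty query string is an error,
#' not an everything-match).  Distance queries select nodes whose
#' cumulative distance from the root is `>=` (or `<=`, per
#' `distance_mode`) the threshold; missing branch lengths contribute 0.
#' Results are independent of collapse state.
#'
#' @param root A [phylo_node()] tree.
#' @param name,annotation Substring queries.
#' @param distance Numeric root-distance threshold.
#' @param distance_mode `">="` or `"<="`.
#' @return Data frame of matches: `path`, `name`, `distance`.
#' @export
search_tree <- function(root, name = NULL, annotation = NULL, distance = NULL,
                        distance_mode = c(">=", "<=")) {
  distance_mode <- match.arg(distance_mode)
  given <- c(!is.null(name), !is.null(annotation), !is.null(distance))
  if (sum(given) != 1L) {
    gv_error("give exactly one of name, annotation, distance", "gv_phylo_error")
  }
  if ((!is.null(name) && !nzchar(name)) ||
      (!is.null(annotation) && !nzchar(annotation))) {
    gv_error("empty search string is ambiguous; refusing to match everything",
             "gv_phylo_error")
  }
  hits <- new.env(parent = emptyenv())
  hits$paths <- character(0); hits$names <- character(0); hits$dist <- numeric(0)
  walk <- function(node, path, d) {
    d <- d + (node$branch_length %||% 0)
    match <- if (!is.null(name)) {
      !is.null(node$name) && grepl(tolower(name), tolower(node$name), fixed = TRUE)
    } else if (!is.null(annotation)) {
      nzchar(node$annotation) &&
        grepl(tolower(annotation), tolower(node$annotation), fixed = TRUE)
    } else {
      if (distance_mode == ">=") d >= distance else d <= distance
    }
    if (isTRUE(match)) {
      hits$paths <- c(hits$paths, path)
      hits$names <- c(hits$names, node$name %||% NA_character_)
      hits$dist <- c(hits$dist, d)
    }
    for (i in seq_along(node$children)) {
      walk(node$children[[i]],
           if (nzchar(path)) paste(path, i, sep = ".") else as.character(i), d)
    }
  }
  d0 <- -(root$branch_length %||% 0)  # root's own edge does not count
  walk(root, "", d0)
  data.frame(path = hits$paths, name = hits$names, distance = hits$dist,
             stringsAsFactors = FALSE)
}

#' Edit a tree node in place
#'
#' Local edits addressed by the dotted child-index `path` used throughout
#' the tree API: set the annotation, set the branch length (must be
#' non-negative), or toggle the collapse flag.  Untouched subtrees are
#' structurally unchanged.
#'
#' @param root A [phylo_node()] tree.
#' @param path Node address (`""` for the root).
#' @param op `"set_annotation"`, `"set_branch_length"`,
#'   `"toggle_collapse"`.
#' @param value New annotation text or branch length.
#' @return The modified tree.
#' @export
edit_tree <- function(root, path, op = c("set_annotation", "set_branch_length",
                                         "toggle_collapse"), value = NULL) {
  op <- match.arg(op)
  node_at(root, path)  # validates
  modify <- function(node) {
    switch(op,
      set_annotation = { node$annotation <- as.character(value); node },
      set_branch_length = {
        if (is.null(value) || is.na(value) || value < 0) {
          gv_error("branch length must be >= 0", "gv_phylo_error")
        }
        node$branch_length <- as.numeric(value); node
      },
      toggle_collapse = { node$collapsed <- !node$collapsed; node }
    )
  }
  assign_at <- function(node, idx) {
    if (!length(idx)) return(modify(node))
    node$children[[idx[1]]] <- assign_at(node$children[[idx[1]]], idx[-1])
    node
  }
  if (!nzchar(path)) return(modify(root))
  assign_at(root, as.integer(strsplit(path, ".", fixed = TRUE)[[1]]))
}
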