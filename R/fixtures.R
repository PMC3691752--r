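#' Seeded synthetic genomic data
#'
#' Deterministic generators so every component is testable without any
#' external download: a genome (chrom.sizes), feature files (BED/GFF3),
#' signal files (BedGraph/Wiggle) and random phylogenetic trees (Newick).
#' Each generator draws from its own pseudorandom stream derived from
#' `(seed, generator name)`, so adding one generator to a pipeline never
#' perturbs the output of another, and identical configuration yields
#' byte-identical files.
#'
#' @param seed Integer seed.
#' @param n_chrom Number of chromosomes.
#' @param length_range Chromosome length range (bases).
#' @param path Optional chrom.sizes output path.
#' @param id Genome identifier.
#' @return `generate_genome`: a [gv_genome()] (written to `path` when
#'   given).
#' @name fixtures
#' @examples
#' g <- generate_genome(1, n_chrom = 2)
#' f <- generate_features(1, g, n = 50, path = tempfile(fileext = ".bed"))
#' @export
generate_genome <- function(seed, n_chrom = 3, length_range = c(5e4, 2e5),
                            path = NULL, id = "synthetic") {
  stopifnot(n_chrom >= 1)
  lens <- with_stream(seed, "genome", {
    round(stats::runif(n_chrom, length_range[1], length_range[2]))
  })
  g <- gv_genome(id, stats::setNames(lens, paste0("chr", seq_len(n_chrom))))
  if (!is.null(path)) write_chrom_sizes(g, path)
  g
}

#' @rdname fixtures
#' @param genome A [gv_genome()] to place records on.
#' @param n Number of records.
#' @param feature_length Feature length range (bases).
#' @param score_range Score range (BED scores).
#' @param overlap_factor In `[0, 1]`: 0 packs features disjointly, larger
#'   values place them freely so overlaps occur.
#' @param format Output format, `"bed"` or `"gff3"`.
#' @return `generate_features`: the [gv_features()] frame (written to
#'   `path` when given).
#' @export
generate_features <- function(seed, genome, n = 500,
                              feature_length = c(50, 2000),
                              score_range = c(0, 1000),
                              overlap_factor = 1, path = NULL,
                              format = c("bed", "gff3")) {
  format <- match.arg(format)
  chroms <- genome$chromosomes
  feats <- with_stream(seed, "features", {
    if (n == 0) {
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 name = character(0), score = numeric(0), strand = character(0),
                 stringsAsFactors = FALSE)
    } else {
      chrom_i <- sample.int(nrow(chroms), n, replace = TRUE,
                            prob = chroms$length / sum(chroms$length))
      out <- vector("list", nrow(chroms))
      for (ci in seq_len(nrow(chroms))) {
        k <- sum(chrom_i == ci)
        if (!k) next
        clen <- chroms$length[ci]
        len <- pmin(round(stats::runif(k, feature_length[1], feature_length[2])),
                    clen)
        if (overlap_factor <= 0) {
          # disjoint packing: distribute the slack between sorted features
          total <- sum(len)
          if (total > clen) {
            len <- pmax(1, floor(len * clen / (2 * total)))
            total <- sum(len)
          }
          gaps <- stats::runif(k + 1)
          gaps <- floor(gaps / sum(gaps) * (clen - total))
          start <- cumsum(gaps[seq_len(k)]) + cumsum(c(0, len[-k]))
        } else {
          start <- floor(stats::runif(k, 0, pmax(clen - len, 1)))
        }
        out[[ci]] <- data.frame(
          chrom = chroms$name[ci], start = start, end = start + len,
          stringsAsFactors = FALSE
        )
      }
      d <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
      d$name <- sprintf("f%04d", seq_len(nrow(d)))
      d$score <- round(stats::runif(nrow(d), score_range[1], score_range[2]), 1)
      d$strand <- sample(c("+", "-"), nrow(d), replace = TRUE)
      d
    }
  })
  feats <- gv_features(feats)
  if (!is.null(path)) write_features(feats, path, format)
  feats
}

#' @rdname fixtures
#' @param n_segments Number of piecewise-constant signal segments.
#' @param segment_length Segment length range (bases).
#' @param value_range Signal value range.
#' @return `generate_signal`: the [gv_signal()] frame (written to `path`,
#'   BedGraph, when given).
#' @export
generate_signal <- function(seed, genome, n_segments = 400,
                            segment_length = c(100, 5000),
                            value_range = c(0, 100), path = NULL) {
  chroms <- genome$chromosomes
  sig <- with_stream(seed, "signal", {
    if (n_segments == 0) {
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 value = numeric(0), stringsAsFactors = FALSE)
    } else {
      chrom_i <- sample.int(nrow(chroms), n_segments, replace = TRUE,
                            prob = chroms$length / sum(chroms$length))
      clen <- chroms$length[chrom_i]
      len <- pmin(round(stats::runif(n_segments, segment_length[1],
                                     segment_length[2])), clen)
      start <- floor(stats::runif(n_segments, 0, pmax(clen - len, 1)))
      data.frame(chrom = chroms$name[chrom_i], start = start,
                 end = start + len,
                 value = round(stats::runif(n_segments, value_range[1],
                                            value_range[2]), 3),
                 stringsAsFactors = FALSE)
    }
  })
  ord <- order(sig$chrom, sig$start, sig$end)
  sig <- gv_signal(sig[ord, , drop = FALSE])
  sig$source_line <- seq_len(nrow(sig))
  if (!is.null(path)) write_signal(sig, path)
  sig
}

#' @rdname fixtures
#' @param n_leaves Number of leaves (`>= 1`).
#' @param bl_range Branch-length range.
#' @return `generate_tree`: the root [phylo_node()] (Newick written to
#'   `path` when given).
#' @export
generate_tree <- function(seed, n_leaves = 32, bl_range = c(0.01, 1),
                          path = NULL) {
  stopifnot(n_leaves >= 1)
  root <- with_stream(seed, "tree", {
    rbl <- function() round(stats::runif(1, bl_range[1], bl_range[2]), 6)
    tree <- phylo_node("t1", rbl())
    leaf_paths <- list(integer(0))
    if (n_leaves > 1) {
      for (k in 2:n_leaves) {
        pick <- sample.int(length(leaf_paths), 1)
        p <- leaf_paths[[pick]]
        old <- if (length(p)) tree[[rep_path(p)]] else tree
        split <- phylo_node(NULL, old$branch_length,
                            children = list(
                              phylo_node(old$name, rbl()),
                              phylo_node(sprintf("t%d", k), rbl())
                            ))
        if (length(p)) tree[[rep_path(p)]] <- split else tree <- split
        leaf_paths[[pick]] <- c(p, 1L)
        leaf_paths[[length(leaf_paths) + 1L]] <- c(p, 2L)
      }
    }
    tree
  })
  if (!is.null(path)) writeLines(write_newick(root), path)
  root
}

# recursive [[ ]] index vector for a child path; positional indexing into
# the node list, where `children` is the 4th field of phylo_node()
rep_path <- function(p) as.integer(rbind(4L, p))
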