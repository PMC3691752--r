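write_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

test_that("BED fields map literally, with '.' as missing", {
  p <- write_tmp(c("track name=demo",
                   "chr1\t100\t200\tfA\t960\t+",
                   "chr1\t300\t400\t.\t.\t.",
                   "chr2\t0\t50"))
  f <- read_features(p, "bed")
  expect_equal(nrow(f), 3)
  expect_equal(attr(f, "skipped"), 1L)
  expect_equal(f$start[1], 100)
  expect_equal(f$end[1], 200)
  expect_identical(f$name[1], "fA")
  expect_equal(f$score[1], 960)
  expect_identical(f$strand[1], "+")
  expect_true(is.na(f$name[2]) && is.na(f$score[2]))
  expect_identical(f$strand[2], "*")
  expect_true(is.na(f$score[3]))
})

test_that("BED12 blocks are decoded to absolute coordinates and validated", {
  p <- write_tmp("chr1\t100\t500\tg\t0\t+\t100\t500\t0\t2\t50,100,\t0,300,")
  f <- read_features(p, "bed")
  b <- f$blocks[[1]]
  expect_equal(b[, "start"], c(100, 400))
  expect_equal(b[, "size"], c(50, 100))
  bad <- write_tmp("chr1\t100\t500\tg\t0\t+\t100\t500\t0\t2\t50,100,\t300,0,")
  expect_error(read_features(bad, "bed"), "blocks", class = "gv_parse_error")
})

test_that("GFF3 and GTF convert 1-based closed coordinates and parse attributes", {
  p <- write_tmp(c("##gff-version 3",
                   "chr1\tsrc\tgene\t101\t200\t5.5\t+\t.\tID=g1;Name=alpha"))
  f <- read_features(p, "gff3")
  expect_equal(f$start[1], 100)
  expect_equal(f$end[1], 200)
  expect_identical(f$name[1], "alpha")
  expect_identical(unname(f$attributes[[1]]["ID"]), "g1")

  p2 <- write_tmp("chr1\tsrc\texon\t1\t50\t.\t-\t.\tgene_id \"g1\"; transcript_id \"t1\";")
  f2 <- read_features(p2, "gtf")
  expect_equal(f2$start[1], 0)
  expect_identical(unname(f2$attributes[[1]][c("gene_id", "transcript_id")]),
                   c("g1", "t1"))
})

test_that("malformed feature lines report the line number", {
  p <- write_tmp(c("chr1\t100\t200", "chr1\t500\t400"))
  expect_error(read_features(p, "bed"), "line 2", class = "gv_parse_error")
  p2 <- write_tmp("chr1\t-5\t10")
  expect_error(read_features(p2, "bed"), class = "gv_parse_error")
  p3 <- write_tmp("chr1\t100")
  expect_error(read_features(p3, "bed"), "3 fields", class = "gv_parse_error")
})

test_that("interval dialect columns are configuration", {
  p <- write_tmp("geneX\tchr5\t+\t100\t200")
  f <- read_features(p, "interval",
                     interval_cols = list(chrom = 2, start = 4, end = 5,
                                          strand = 3, name = 1))
  expect_identical(f$chrom[1], "chr5")
  expect_equal(f$start[1], 100)
  expect_identical(f$name[1], "geneX")
  expect_identical(f$strand[1], "+")
})

test_that("minimal SAM reader maps aligned reads with mapq attribute", {
  p <- write_tmp(c("@HD\tVN:1.6",
                   "r1\t0\tchr1\t101\t60\t10M\t*\t0\t0\tAAAAAAAAAA\t*",
                   "r2\t16\tchr1\t201\t13\t5M2D3M\t*\t0\t0\tAAAAAAAA\t*",
                   "r3\t4\t*\t0\t0\t*\t*\t0\t0\tAAAA\t*"))
  f <- read_features(p, "sam")
  expect_equal(nrow(f), 2)                # unmapped read skipped
  expect_equal(f$start[1], 100)
  expect_equal(f$end[1], 110)
  expect_equal(f$end[2], 200 + 5 + 2 + 3) # M and D consume reference
  expect_identical(f$strand[2], "-")
  expect_identical(unname(f$attributes[[1]]["mapq"]), "60")
})

test_that("BED and GFF3 write-read round trips are canonical", {
  g <- generate_genome(11, n_chrom = 2)
  f <- generate_features(11, g, n = 100)
  for (fmt in c("bed", "gff3")) {
    out <- tempfile(fileext = paste0(".", fmt))
    n <- write_features(f, out, fmt)
    expect_equal(n, 100)
    back <- read_features(out, fmt)
    expect_equal(canonical_features(back), canonical_features(f),
                 ignore_attr = TRUE)
    # idempotence: a second write-read cycle is byte-stable
    out2 <- tempfile(fileext = paste0(".", fmt))
    write_features(back, out2, fmt)
    expect_identical(readLines(out2), readLines(out))
  }
})

test_that("GFF3 writing restores 1-based closed columns", {
  f <- gv_features(data.frame(chrom = "chr1", start = 100, end = 200))
  out <- tempfile()
  write_features(f, out, "gff3")
  cols <- strsplit(readLines(out), "\t")[[1]]
  expect_identical(cols[4:5], c("101", "200"))
  empty <- tempfile()
  expect_equal(write_features(f[0, ], empty, "bed"), 0)
  expect_equal(nrow(read_features(empty, "bed")), 0)
})

test_that("attributes are dropped with a warning when writing BED", {
  p <- write_tmp("chr1\tsrc\tgene\t1\t10\t.\t+\t.\tID=g1")
  f <- read_features(p, "gff3")
  expect_warning(write_features(f, tempfile(), "bed"), "attributes")
})

test_that("wiggle declarations drive coordinates; bedgraph passes through", {
  p <- write_tmp(c("track type=wiggle_0",
                   "fixedStep chrom=chr1 start=11 step=10 span=5",
                   "1.0", "2.0"))
  s <- read_signal(p, "wiggle")
  expect_equal(s$start, c(10, 20))
  expect_equal(s$end, c(15, 25))
  expect_equal(s$value, c(1, 2))

  pv <- write_tmp(c("variableStep chrom=chr2 span=3", "101 7.5", "201 8.5"))
  sv <- read_signal(pv, "wiggle")
  expect_equal(sv$start, c(100, 200))
  expect_equal(sv$end, c(103, 203))

  pb <- write_tmp("chr1\t0\t10\t3.5")
  sb <- read_signal(pb, "bedgraph")
  expect_equal(sb$start, 0)
  expect_equal(sb$end, 10)
  expect_equal(sb$value, 3.5)

  expect_error(read_signal(write_tmp("1.0"), "wiggle"),
               "declaration", class = "gv_parse_error")
  expect_error(read_signal(write_tmp(c("fixedStep chrom=chr1 start=1 step=0", "1")),
                           "wiggle"), class = "gv_parse_error")
  expect_error(read_signal(write_tmp(c("fixedStep chrom=chr1 start=1 step=1", "x")),
                           "wiggle"), class = "gv_parse_error")
})

test_that("coordinate conversion preserves source lengths", {
  # GFF record [start, end] closed: internal width = end - start + 1
  p <- write_tmp("chr1\tsrc\tgene\t101\t250\t.\t+\t.\tID=a")
  f <- read_features(p, "gff3")
  expect_equal(f$end[1] - f$start[1], 250 - 101 + 1)
  # wiggle span
  pw <- write_tmp(c("fixedStep chrom=chr1 start=5 step=10 span=7", "1"))
  s <- read_signal(pw, "wiggle")
  expect_equal(s$end - s$start, 7)
  # VCF region length = nchar(REF)
  pv <- write_tmp(c("##fileformat=VCFv4.2",
                    "chr1\t101\t.\tATG\tA\t50\tPASS\t."))
  v <- read_variants(pv)
  expect_equal(v$end - v$start, 3)
})

test_that("VCF records convert POS and split multi-allelic ALT", {
  p <- write_tmp(c("##fileformat=VCFv4.2",
                   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                   "chr1\t101\t.\tA\tT\t50\tPASS\t.",
                   "chr1\t201\trs1\tG\tT,C\t.\tPASS\tDP=10;DB"))
  v <- read_variants(p)
  expect_equal(nrow(v), 2)
  expect_equal(v$start[1], 100)
  expect_equal(v$end[1], 101)
  expect_identical(v$alts[[1]], "T")
  expect_equal(v$qual[1], 50)
  expect_identical(v$alts[[2]], c("T", "C"))
  expect_true(is.na(v$qual[2]))
  expect_identical(unname(v$info[[2]]["DP"]), "10")
  expect_identical(unname(v$info[[2]]["DB"]), "")

  hdr_only <- write_tmp(c("##fileformat=VCFv4.2", "#CHROM\tPOS"))
  expect_equal(nrow(read_variants(hdr_only)), 0)
  expect_error(read_variants(write_tmp("chr1\tx\t.\tA\tT\t.\t.\t.")),
               "POS", class = "gv_parse_error")
})

test_that("table reader infers column types and detects headers", {
  p <- write_tmp(c("a\tb", "1\t2", "3\t4"))
  t <- read_table(p)
  expect_identical(t$col_names, c("a", "b"))
  expect_identical(t$col_types, c("numeric", "numeric"))
  expect_equal(nrow(t$data), 2)

  mixed <- read_table(write_tmp(c("x", "1.5", "x")))
  expect_identical(mixed$col_types, "string")

  nohdr <- read_table(write_tmp(c("1\t2", "3\t4")))
  expect_identical(nohdr$col_names, c("V1", "V2"))

  miss <- read_table(write_tmp(c("a", "1", ".", "3")))
  expect_equal(sum(is.na(miss$data$a)), 1)

  expect_error(read_table(write_tmp(character(0))), "no data",
               class = "gv_parse_error")
  expect_error(read_table(write_tmp(c("a\tb", "1"))), "line 2",
               class = "gv_parse_error")
})

test_that("parser line accounting is total", {
  p <- write_tmp(c("# comment", "track name=x", "chr1\t1\t10", "",
                   "chr1\t5\t20"))
  f <- read_features(p, "bed")
  expect_equal(nrow(f) + attr(f, "skipped"), 5)
})
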