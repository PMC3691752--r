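make_feature_ds <- function(seed, n = 300, n_chrom = 2) {
  g <- generate_genome(seed, n_chrom = n_chrom)
  p <- tempfile(fileext = ".bed")
  generate_features(seed, g, n = n, path = p)
  ds <- open_dataset(p, "bed")
  list(g = g, ds = ds, idx = index_dataset(ds))
}

make_signal_ds <- function(seed, n = 200) {
  g <- generate_genome(seed, n_chrom = 2)
  p <- tempfile(fileext = ".bedgraph")
  generate_signal(seed, g, n_segments = n, path = p)
  ds <- open_dataset(p, "bedgraph")
  list(g = g, ds = ds, idx = index_dataset(ds))
}

test_that("count and detail match the linear-scan oracle", {
  x <- make_feature_ds(31)
  set.seed(31)
  for (q in 1:40) {
    region <- random_region(x$g)
    want <- brute_overlap(x$ds$records, region)
    expect_equal(count_in_region(x$ds, x$idx, region), length(want))
    pl <- get_detail(x$ds, x$idx, region)
    expect_identical(pl$mode, "detail")
    expect_equal(pl$total_in_region, length(want))
    expect_equal(nrow(pl$records), length(want))
    expect_false(is.unsorted(pl$records$start))
    expect_setequal(pl$records$name, x$ds$records$name[want])
  }
  # empty intersection is a payload, not an error
  empty <- get_detail(x$ds, x$idx, gv_region("chr1", 0, 1))
  expect_equal(empty$total_in_region, 0)
})

test_that("detail requests beyond max_detail raise an over-limit error", {
  x <- make_feature_ds(32, n = 50)
  region <- gv_region("chr1", 0, x$g$chromosomes$length[1])
  n <- count_in_region(x$ds, x$idx, region)
  expect_error(get_detail(x$ds, x$idx, region, max_detail = n - 1),
               "summary", class = "gv_over_limit")
  expect_silent(get_detail(x$ds, x$idx, region, max_detail = n))
})

test_that("summary count bins match hand-computed and oracle values", {
  recs <- data.frame(chrom = "chr1", start = c(0, 5), end = c(10, 15))
  ds <- structure(list(path = "mem", format = "bed", kind = "features",
                       records = gv_features(recs),
                       checksum = list(size = 0, md5 = "mem")),
                  class = "gv_dataset")
  idx <- build_index(recs)
  region <- gv_region("chr1", 0, 20)
  expect_equal(get_summary(ds, idx, region, 2, "count")$values, c(2, 1))

  one <- data.frame(chrom = "chr1", start = 0, end = 40)
  ds1 <- ds; ds1$records <- gv_features(one)
  expect_equal(get_summary(ds1, build_index(one), gv_region("chr1", 0, 40),
                           4, "count")$values,
               c(1, 1, 1, 1))

  x <- make_feature_ds(33)
  set.seed(33)
  for (q in 1:30) {
    region <- random_region(x$g, min_width = 50)
    nb <- sample(c(1, 7, 20), 1)
    got <- get_summary(x$ds, x$idx, region, nb, "count")
    expect_equal(got$values, oracle_summary_count(x$ds$records, region, nb))
  }
})

test_that("signal summaries match the brute-force per-bin oracle", {
  x <- make_signal_ds(34)
  set.seed(34)
  for (q in 1:25) {
    region <- random_region(x$g, min_width = 100)
    nb <- sample(c(1, 5, 13), 1)
    for (stat in c("mean", "max", "min")) {
      got <- get_summary(x$ds, x$idx, region, nb, stat)$values
      want <- oracle_summary_stat(x$ds$records, region, nb, stat)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
  # non-count stats demand signal data
  f <- make_feature_ds(34)
  expect_error(get_summary(f$ds, f$idx, gv_region("chr1", 0, 100), 4, "mean"),
               "signal", class = "gv_provider_error")
})

test_that("get_data switches modes exactly at max_detail + 1", {
  x <- make_feature_ds(35, n = 60)
  region <- gv_region("chr1", 0, x$g$chromosomes$length[1])
  n <- count_in_region(x$ds, x$idx, region)
  at <- get_data(x$ds, x$idx, region, max_detail = n)
  expect_identical(at$mode, "detail")
  expect_null(at$message)
  over <- get_data(x$ds, x$idx, region, max_detail = n - 1, nbins = 10)
  expect_identical(over$mode, "summary")
  expect_false(is.null(over$message))
  expect_equal(over$total_in_region, n)
  expect_identical(over$summary$stat, "count")
})

test_that("genome-wide payloads agree with whole-chromosome summaries", {
  x <- make_feature_ds(36)
  gw <- get_genome_wide(x$ds, x$idx, x$g, bins_per_chrom = 12)
  expect_named(gw, x$g$chromosomes$name)
  for (i in seq_len(nrow(x$g$chromosomes))) {
    chrom <- x$g$chromosomes$name[i]
    direct <- get_summary(x$ds, x$idx,
                          gv_region(chrom, 0, x$g$chromosomes$length[i]),
                          12, "count")
    expect_equal(gw[[chrom]]$values, direct$values)
  }
  # one bin per chromosome recovers per-chromosome record counts
  gw1 <- get_genome_wide(x$ds, x$idx, x$g, bins_per_chrom = 1)
  for (chrom in names(gw1)) {
    expect_equal(gw1[[chrom]]$values,
                 sum(x$ds$records$chrom == chrom))
  }
})

test_that("composite summaries stack aligned rows per dataset", {
  a <- make_signal_ds(37)
  b_path <- tempfile(fileext = ".bedgraph")
  generate_signal(38, a$g, n_segments = 150, path = b_path)
  b_ds <- open_dataset(b_path, "bedgraph")
  b_idx <- index_dataset(b_ds)
  region <- gv_region("chr1", 0, a$g$chromosomes$length[1])
  m <- composite_summary(list(a$ds, b_ds), list(a$idx, b_idx), region,
                         nbins = 16, stat = "mean")
  expect_equal(dim(m), c(2, 16))
  expect_equal(m[1, ], get_summary(a$ds, a$idx, region, 16, "mean")$values)
  expect_equal(m[2, ], get_summary(b_ds, b_idx, region, 16, "mean")$values)

  single <- composite_summary(list(a$ds), list(a$idx), region, 16, "mean")
  expect_equal(dim(single), c(1, 16))

  f <- make_feature_ds(37)
  expect_error(composite_summary(list(a$ds, f$ds), list(a$idx, f$idx),
                                 region, 8, "mean"),
               class = "gv_provider_error")
})

test_that("filters are conjunctive, idempotent and match the predicate oracle", {
  x <- make_feature_ds(39, n = 200)
  region <- gv_region("chr1", 0, x$g$chromosomes$length[1])
  pl <- get_detail(x$ds, x$idx, region)

  keep_all <- apply_filters(pl, list(filter_spec("score", 0, 1000)))
  expect_equal(keep_all$total_in_region, pl$total_in_region)

  f1 <- filter_spec("score", 200, 800)
  once <- apply_filters(pl, list(f1))
  twice <- apply_filters(once, list(f1))
  expect_equal(once$records$name, twice$records$name)
  expect_true(all(once$records$score >= 200 & once$records$score <= 800))

  set.seed(39)
  for (i in 1:20) {
    lo <- runif(1, 0, 500); hi <- lo + runif(1, 0, 500)
    fs <- list(filter_spec("score", lo, hi),
               filter_spec("absent_attr", 0, 1,
                           missing_passes = sample(c(TRUE, FALSE), 1)))
    got <- apply_filters(pl, fs)
    want <- oracle_filter_keep(pl$records, fs)
    expect_equal(got$records$name, pl$records$name[want])
    expect_equal(got$total_in_region, sum(want))
    # monotonicity: tightening the band never adds records
    span <- hi - lo
    tighter <- apply_filters(pl, list(filter_spec("score", lo + 0.25 * span,
                                                  hi - 0.1 * span)))
    wider <- apply_filters(pl, list(filter_spec("score", lo, hi)))
    expect_true(all(tighter$records$name %in% wider$records$name))
    expect_lte(tighter$total_in_region, wider$total_in_region)
  }

  expect_error(filter_spec("score", 1001, 1000), class = "gv_filter_error")
  sm <- get_data(x$ds, x$idx, region, max_detail = 1, nbins = 4)
  expect_error(apply_filters(sm, list(f1)), class = "gv_filter_error")
})

test_that("GFF attribute filters reach into the attribute map", {
  p <- tempfile(fileext = ".gff3")
  writeLines(c("chr1\ts\tgene\t1\t100\t.\t+\t.\tID=a;depth=5",
               "chr1\ts\tgene\t200\t300\t.\t+\t.\tID=b;depth=50",
               "chr1\ts\tgene\t400\t500\t.\t+\t.\tID=c"), p)
  ds <- open_dataset(p, "gff3")
  idx <- index_dataset(ds)
  pl <- get_detail(ds, idx, gv_region("chr1", 0, 1000))
  hi <- apply_filters(pl, list(filter_spec("depth", 10, Inf,
                                           missing_passes = FALSE)))
  expect_identical(hi$records$name, "b")
  lax <- apply_filters(pl, list(filter_spec("depth", 10, Inf,
                                            missing_passes = TRUE)))
  expect_setequal(lax$records$name, c("b", "c"))
})

test_that("column statistics use n-1 variance and exclude missing values", {
  p <- tempfile()
  writeLines(c("a\tb", "1\tx", "3\ty"), p)
  t <- read_table(p)
  st <- column_stats(t, "a")
  expect_equal(st$min, 1)
  expect_equal(st$max, 3)
  expect_equal(st$mean, 2)
  expect_equal(st$sd, sqrt(2))
  expect_error(column_stats(t, "b"), "numeric", class = "gv_provider_error")

  p1 <- tempfile(); writeLines(c("v", "5"), p1)
  expect_true(is.na(column_stats(read_table(p1), "v")$sd))

  set.seed(40)
  vals <- round(runif(1000, -50, 50), 4)
  vals[sample.int(1000, 37)] <- NA
  p2 <- tempfile()
  writeLines(c("x", ifelse(is.na(vals), "NA", format(vals, scientific = FALSE))),
             p2)
  st2 <- column_stats(read_table(p2), "x")
  ok <- vals[!is.na(vals)]
  # independent two-pass mean/sd
  m <- sum(ok) / length(ok)
  s2 <- sum((ok - m)^2) / (length(ok) - 1)
  expect_equal(st2$mean, m, tolerance = 1e-12)
  expect_equal(st2$sd, sqrt(s2), tolerance = 1e-12)
  expect_equal(st2$n, length(ok))
  expect_equal(st2$n_missing, 37)
})

test_that("the payload cache is transparent and evicts LRU", {
  x <- make_feature_ds(41, n = 150)
  cache <- gv_cache(capacity = 8)
  set.seed(41)
  regions <- replicate(12, random_region(x$g), simplify = FALSE)
  for (r in regions) {
    cached <- cached_get_data(cache, x$ds, x$idx, r, nbins = 10)
    direct <- get_data(x$ds, x$idx, r, nbins = 10)
    expect_equal(cached$records, direct$records)
    expect_equal(cached$total_in_region, direct$total_in_region)
  }

  # exact repeat is a hit with an identical payload
  cache2 <- gv_cache(4)
  r <- regions[[1]]
  p1 <- cached_get_data(cache2, x$ds, x$idx, r)
  h0 <- cache_stats(cache2)$hits
  p2 <- cached_get_data(cache2, x$ds, x$idx, r)
  expect_equal(cache_stats(cache2)$hits, h0 + 1)
  expect_identical(p1, p2)

  # sub-region of a cached detail payload is served by sub-selection
  big <- gv_region(r$chrom, 0, x$g$chromosomes$length[
    match(r$chrom, x$g$chromosomes$name)])
  cache3 <- gv_cache(4)
  cached_get_data(cache3, x$ds, x$idx, big)
  sub <- gv_region(r$chrom, big$end %/% 4, big$end %/% 2)
  served <- cached_get_data(cache3, x$ds, x$idx, sub)
  expect_equal(cache_stats(cache3)$hits, 1)
  direct <- get_data(x$ds, x$idx, sub)
  expect_equal(served$records$name, direct$records$name)
  expect_equal(served$total_in_region, direct$total_in_region)

  # capacity-1 cache: second distinct query evicts the first
  cache4 <- gv_cache(1)
  ra <- gv_region("chr1", 0, 100)
  rb <- gv_region("chr1", 200, 5000)
  cached_get_data(cache4, x$ds, x$idx, ra)
  cached_get_data(cache4, x$ds, x$idx, rb)
  m0 <- cache_stats(cache4)$misses
  cached_get_data(cache4, x$ds, x$idx, ra)
  expect_equal(cache_stats(cache4)$misses, m0 + 1)
})

test_that("payload JSON follows the documented schema", {
  x <- make_feature_ds(42, n = 20)
  region <- gv_region("chr1", 0, x$g$chromosomes$length[1])
  j <- jsonlite::fromJSON(payload_to_json(get_data(x$ds, x$idx, region)),
                          simplifyVector = FALSE)
  expect_identical(j$mode, "detail")
  expect_true(is.numeric(j$total))
  expect_equal(length(j$data), j$total)
  expect_length(j$data[[1]], 6)

  js <- jsonlite::fromJSON(payload_to_json(
    get_data(x$ds, x$idx, region, max_detail = 1, nbins = 5)),
    simplifyVector = FALSE)
  expect_identical(js$mode, "summary")
  expect_identical(js$data$stat, "count")
  expect_length(js$data$values, js$data$nbins)
})
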