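test_that("numeric sampling is evenly spaced with exact endpoints", {
  s <- sample_parameter(param_spec("pre_mrna_fraction", "numeric", 0, 0.2, 5))
  expect_equal(s, c(0, 0.05, 0.1, 0.15, 0.2))
  expect_identical(s[1], 0)
  expect_identical(s[5], 0.2)

  expect_identical(sample_parameter(param_spec("p", "categorical",
                                               values = c("Yes", "No"))),
                   c("Yes", "No"))
  expect_equal(sample_parameter(param_spec("q", "numeric", 0.1, 0.9, 1)), 0.1)

  set.seed(60)
  for (i in 1:30) {
    lo <- runif(1, -10, 10); hi <- lo + runif(1, 0, 20)
    n <- sample(2:25, 1)
    v <- sample_parameter(param_spec("x", "numeric", lo, hi, n))
    expect_identical(v[1], lo)
    expect_identical(v[n], hi)
    expect_lt(max(abs(diff(v) - (hi - lo) / (n - 1))), 1e-12)
  }
})

test_that("parameter trees have product-of-samples leaves", {
  tr <- build_param_tree(list(param_spec("a", "numeric", 0, 1, 3),
                              param_spec("b", "numeric", 0, 1, 5)))
  expect_equal(count_leaves(tr), 15)
  expect_length(tr$root$children, 3)
  expect_length(tr$root$children[[1]]$children, 5)
  expect_length(tr$root$children[[1]]$children[[1]]$children, 0)

  cat2 <- build_param_tree(list(param_spec("c", "categorical",
                                           values = c("x", "y"))))
  expect_equal(count_leaves(cat2), 2)

  three <- build_param_tree(list(param_spec("a", "numeric", 0, 1, 2),
                                 param_spec("b", "numeric", 0, 1, 2),
                                 param_spec("c", "numeric", 0, 1, 2)))
  expect_equal(count_leaves(three), 8)

  expect_error(build_param_tree(list(param_spec("z", "numeric", 0, 1, 2,
                                                in_tree = FALSE))),
               class = "gv_sweep_error")
})

test_that("node enumeration fixes ancestors and expands descendants", {
  tr <- build_param_tree(list(
    param_spec("minimum_isoform_fraction", "numeric", 0, 0.5, 3),
    param_spec("pre_mrna_fraction", "numeric", 0, 0.2, 5)
  ))
  # interior node: one job per value of the second parameter
  runs <- enumerate_runs(tr, c(1L))
  expect_length(runs, 5)
  expect_true(all(vapply(runs, function(r) {
    r$assignment$minimum_isoform_fraction == 0
  }, TRUE)))
  expect_equal(vapply(runs, function(r) r$assignment$pre_mrna_fraction, 0),
               c(0, 0.05, 0.1, 0.15, 0.2))
  expect_identical(runs[[2]]$path_labels,
                   c("minimum_isoform_fraction=0", "pre_mrna_fraction=0.05"))

  expect_length(enumerate_runs(tr), 15)
  expect_length(enumerate_runs(tr, c(2L, 3L)), 1)
  expect_error(enumerate_runs(tr, c(9L)), class = "gv_sweep_error")

  # out-of-tree parameters ride along at their fixed value
  tr2 <- build_param_tree(list(
    param_spec("a", "numeric", 0, 1, 2),
    param_spec("fixed", "numeric", 0, 9, 1, in_tree = FALSE, fixed_value = 7)
  ))
  r2 <- enumerate_runs(tr2)
  expect_length(r2, 2)
  expect_equal(r2[[1]]$assignment$fixed, 7)
})

test_that("child run counts sum to the parent's count for every node", {
  set.seed(61)
  for (i in 1:10) {
    k <- sample(2:3, 1)
    specs <- lapply(seq_len(k), function(j) {
      param_spec(paste0("p", j), "numeric", 0, 1, sample(1:4, 1))
    })
    tr <- build_param_tree(specs)
    expect_length(enumerate_runs(tr), count_leaves(tr))
    n_children <- length(tr$root$children)
    child_sum <- sum(vapply(seq_len(n_children), function(ci) {
      length(enumerate_runs(tr, ci))
    }, 0))
    expect_equal(child_sum, length(enumerate_runs(tr)))
  }
})

test_that("tool templates validate placeholders and fill deterministically", {
  expect_error(tool_spec("t", "cmd {param:ghost} {input} {output}", "bed", "bed"),
               "ghost", class = "gv_sweep_error")
  tool <- tool_spec("t", "run -x {param:x} {input} {output}", "bed", "bed",
                    list(param_spec("x", "numeric", 0, 1, 2)))
  expect_identical(
    genovis:::fill_template(tool$command, "in.bed", "out.bed", list(x = 0.5)),
    "run -x 0.5 in.bed out.bed")
})

sweep_fixture <- function(seed, n = 120) {
  g <- generate_genome(seed, n_chrom = 2)
  p <- tempfile(fileext = ".bed")
  generate_features(seed, g, n = n, path = p)
  ds <- open_dataset(p, "bed")
  list(g = g, ds = ds, idx = index_dataset(ds))
}

test_that("dataset subsetting equals the brute-force overlap filter and caches", {
  x <- sweep_fixture(62)
  set.seed(62)
  regions <- list(random_region(x$g, 500), random_region(x$g, 500))
  cache_dir <- file.path(tempdir(), paste0("gvsub", as.integer(runif(1, 1, 1e6))))
  sp <- subset_dataset(x$ds, x$idx, regions, cache_dir)
  sub <- read_features(sp, "bed")
  want <- sort(unique(unlist(lapply(regions, function(r) {
    brute_overlap(x$ds$records, r)
  }))))
  expect_equal(canonical_features(sub), canonical_features(x$ds$records[want, ]),
               ignore_attr = TRUE)
  # source order is preserved
  expect_false(is.unsorted(sub$source_line))

  # cached: identical path, file untouched
  mt <- file.mtime(sp)
  sp2 <- subset_dataset(x$ds, x$idx, regions, cache_dir)
  expect_identical(sp, sp2)
  expect_identical(file.mtime(sp2), mt)

  # empty region set -> empty subset
  tiny <- gv_region("chr1", 0, 1)
  none <- subset_dataset(x$ds, x$idx, list(tiny), cache_dir)
  nf <- read_features(none, "bed")
  expect_equal(nrow(nf), length(brute_overlap(x$ds$records, tiny)))
})

test_that("sweeps run the toy tools per assignment and slice per region", {
  x <- sweep_fixture(63)
  set.seed(63)
  regions <- list(random_region(x$g, 2000), random_region(x$g, 2000))
  tool <- builtin_tool("score_scale")
  tr <- build_param_tree(tool$parameters)
  runs <- execute_sweep(tool, x$ds, x$idx, tr, c(2L), regions,
                        cache_dir = tempfile("gvsw"))
  expect_length(runs, 1)         # leaf node
  full <- execute_sweep(tool, x$ds, x$idx, tr, integer(0), regions,
                        cache_dir = tempfile("gvsw"))
  expect_length(full, 4)
  expect_true(all(vapply(full, function(r) r$status == "ok", TRUE)))
  expect_true(all(vapply(full, function(r) length(r$outputs) == 2, TRUE)))

  # identity tool reproduces the subset restricted to each region
  idt <- builtin_tool("identity")
  itr <- build_param_tree(list(param_spec("dummy", "numeric", 1, 1, 1)))
  ir <- execute_sweep(idt, x$ds, x$idx, itr, integer(0), regions,
                      cache_dir = tempfile("gvsw"))[[1]]
  for (k in seq_along(regions)) {
    want <- x$ds$records[brute_overlap(x$ds$records, regions[[k]]), ]
    expect_equal(canonical_features(ir$outputs[[k]]), canonical_features(want),
                 ignore_attr = TRUE)
  }

  # counter tool: per-region record counts equal brute-force overlap counts
  ctr <- builtin_tool("counter")
  cr <- execute_sweep(ctr, x$ds, x$idx, itr, integer(0), regions,
                      cache_dir = tempfile("gvsw"))[[1]]
  for (k in seq_along(regions)) {
    expect_equal(nrow(cr$outputs[[k]]),
                 length(brute_overlap(x$ds$records, regions[[k]])))
    expect_true(all(cr$outputs[[k]]$score == 1))
  }
})

test_that("run-on-subset equals restriction of run-on-full for local tools", {
  x <- sweep_fixture(64)
  set.seed(64)
  regions <- list(random_region(x$g, 3000), random_region(x$g, 3000))
  for (tool_id in c("identity", "counter")) {
    tool <- builtin_tool(tool_id)
    tr <- build_param_tree(list(param_spec("d", "numeric", 1, 1, 1)))
    sub_run <- execute_sweep(tool, x$ds, x$idx, tr, integer(0), regions,
                             cache_dir = tempfile("gvsw"))[[1]]
    full_out <- run_full(tool, x$ds, sub_run$assignment)
    for (k in seq_along(regions)) {
      r <- regions[[k]]
      sel <- brute_overlap(full_out$records, r)
      expect_equal(canonical_features(sub_run$outputs[[k]]),
                   canonical_features(full_out$records[sel, ]),
                   ignore_attr = TRUE)
    }
  }
  # identity on the full fixture reproduces the input byte-for-byte
  out <- run_full(builtin_tool("identity"), x$ds, list())
  expect_identical(readLines(out$path), readLines(x$ds$path))
})

test_that("failing and unparseable tools are reported, not fatal", {
  x <- sweep_fixture(65, n = 30)
  bad <- tool_spec("boom", "exit 3", "bed", "bed")
  tr <- build_param_tree(list(param_spec("d", "numeric", 1, 1, 1)))
  runs <- execute_sweep(bad, x$ds, x$idx, tr, integer(0),
                        list(gv_region("chr1", 0, 1000)),
                        cache_dir = tempfile("gvsw"))
  expect_identical(runs[[1]]$status, "failed")
  expect_match(runs[[1]]$diagnostics, "exit 3")

  expect_error(run_full(bad, x$ds, list()), "exit 3", class = "gv_tool_error")

  garbled <- tool_spec("garble", "echo 'not a bed line' > {output}", "bed", "bed")
  runs2 <- execute_sweep(garbled, x$ds, x$idx, tr, integer(0),
                         list(gv_region("chr1", 0, 1000)),
                         cache_dir = tempfile("gvsw"))
  expect_identical(runs2[[1]]$status, "failed")
  expect_match(runs2[[1]]$diagnostics, "unparseable")

  # format mismatch is caught before any execution
  expect_error(execute_sweep(tool_spec("t", "cp {input} {output}", "vcf", "vcf"),
                             x$ds, x$idx, tr, integer(0), list(),
                             cache_dir = tempfile("gvsw")),
               class = "gv_sweep_error")
})

test_that("sweep manifests and tool configs round-trip through JSON", {
  x <- sweep_fixture(66, n = 40)
  set.seed(66)
  regions <- list(random_region(x$g, 1000))
  tool <- builtin_tool("counter")
  tr <- build_param_tree(list(param_spec("d", "numeric", 1, 2, 2)))
  runs <- execute_sweep(tool, x$ds, x$idx, tr, integer(0), regions,
                        cache_dir = tempfile("gvsw"))
  mpath <- tempfile(fileext = ".json")
  write_sweep_manifest(runs, mpath)
  m <- jsonlite::fromJSON(mpath, simplifyVector = FALSE)
  expect_length(m, 2)
  expect_identical(m[[1]]$status, "ok")
  expect_true(file.exists(m[[1]]$output))

  cfg <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    id = "scale", command = "awk -v f={param:f} '1' {input} > {output}",
    input_format = "bed", output_format = "bed",
    parameters = list(list(name = "f", kind = "numeric",
                           min = 0, max = 1, n_samples = 3))
  ), auto_unbox = TRUE), cfg)
  t2 <- read_tool_config(cfg)
  expect_identical(t2$id, "scale")
  expect_equal(sample_parameter(t2$parameters[[1]]), c(0, 0.5, 1))
})
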