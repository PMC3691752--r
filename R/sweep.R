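#' Tool parameter specification
#'
#' Numeric parameters are sampled by minimum, maximum and number of
#' samples in the range; categorical parameters contribute all their
#' values.  A parameter can be taken out of the sweep tree
#' (`in_tree = FALSE`), in which case every run uses `fixed_value`.
#'
#' @param name Parameter name (used in `{param:name}` placeholders).
#' @param kind `"numeric"` or `"categorical"`.
#' @param min,max,n_samples Numeric sampling range and count
#'   (`n_samples >= 1`).
#' @param values Categorical values (non-empty, unique), in order.
#' @param in_tree Whether the parameter is a level of the sweep tree.
#' @param fixed_value Value used when `in_tree` is `FALSE`.
#' @return An object of class `gv_param_spec`.
#' @export
param_spec <- function(name, kind = c("numeric", "categorical"),
                       min = NULL, max = NULL, n_samples = NULL,
                       values = NULL, in_tree = TRUE, fixed_value = NULL) {
  kind <- match.arg(kind)
  stopifnot(is_string(name))
  if (kind == "numeric") {
    if (is.null(min) || is.null(max) || is.null(n_samples) ||
        min > max || n_samples < 1 || n_samples != floor(n_samples)) {
      gv_error(sprintf("parameter '%s': need min <= max and integer n_samples >= 1",
                       name), "gv_sweep_error")
    }
  } else {
    if (!length(values) || anyDuplicated(values)) {
      gv_error(sprintf("parameter '%s': categorical values must be non-empty and unique",
                       name), "gv_sweep_error")
    }
  }
  structure(list(name = name, kind = kind, min = min, max = max,
                 n_samples = n_samples, values = values,
                 in_tree = isTRUE(in_tree), fixed_value = fixed_value),
            class = "gv_param_spec")
}

#' Sample the values of one parameter
#'
#' Numeric parameters with `n_samples >= 2` are sampled evenly with both
#' endpoints included: `value_i = min + i * (max - min) / (n - 1)`.
#' `n_samples = 1` yields `[min]`.  Categorical parameters return their
#' declared values in order.
#'
#' @param spec A [param_spec()].
#' @return Vector of sampled values, in tree order.
#' @examples
#' sample_parameter(param_spec("pre_mrna_fraction", "numeric", 0, 0.2, 5))
#' @export
sample_parameter <- function(spec) {
  stopifnot(inherits(spec, "gv_param_spec"))
  if (spec$kind == "categorical") return(spec$values)
  if (spec$n_samples == 1) return(spec$min)
  spec$min + (0:(spec$n_samples - 1)) * (spec$max - spec$min) / (spec$n_samples - 1)
}

#' Tool specification
#'
#' A tool is a shell command template with placeholders `{input}`,
#' `{output}` and `{param:name}` for each declared parameter, plus its
#' input and output formats.  Every `{param:...}` placeholder must match a
#' declared parameter.
#'
#' @param id Tool identifier.
#' @param command Command template.
#' @param input_format,output_format Dataset formats (see
#'   [open_dataset()]).
#' @param parameters List of [param_spec()]s.
#' @return An object of class `gv_tool`.
#' @export
tool_spec <- function(id, command, input_format, output_format,
                      parameters = list()) {
  stopifnot(is_string(id), is_string(command))
  declared <- vapply(parameters, function(p) p$name, "")
  ph <- regmatches(command, gregexpr("\\{param:[^}]+\\}", command))[[1]]
  ph_names <- sub("^\\{param:(.*)\\}$", "\\1", ph)
  undeclared <- setdiff(ph_names, declared)
  if (length(undeclared)) {
    gv_error(sprintf("command references undeclared parameter '%s'", undeclared[1]),
             "gv_sweep_error")
  }
  structure(list(id = id, command = command, input_format = input_format,
                 output_format = output_format, parameters = parameters),
            class = "gv_tool")
}

#' Build the parameter-space tree
#'
#' Level `d` of the tree is the `d`-th in-tree parameter; each node at
#' depth `d - 1` has one child per sampled value of that parameter, so
#' leaves are complete in-tree assignments and the leaf count is the
#' product of per-parameter sample counts.
#'
#' @param specs List of [param_spec()]s; the in-tree ones, in order,
#'   become the tree levels (at least one required).
#' @return An object of class `gv_param_tree` with `params` (level
#'   names), `samples` (per-level value vectors) and `root` (nested nodes
#'   `list(param, value, children)`).
#' @export
build_param_tree <- function(specs) {
  in_tree <- Filter(function(p) p$in_tree, specs)
  if (!length(in_tree)) {
    gv_error("no in-tree parameters: cannot build a parameter tree", "gv_sweep_error")
  }
  params <- vapply(in_tree, function(p) p$name, "")
  samples <- lapply(in_tree, sample_parameter)
  grow <- function(depth) {
    if (depth > length(params)) return(list())
    lapply(seq_along(samples[[depth]]), function(i) {
      list(param = params[depth], value = samples[[depth]][[i]],
           children = grow(depth + 1))
    })
  }
  structure(list(params = params, samples = samples,
                 specs = specs,
                 root = list(param = NULL, value = NULL, children = grow(1))),
            class = "gv_param_tree")
}

#' @rdname build_param_tree
#' @param tree A `gv_param_tree`.
#' @export
count_leaves <- function(tree) prod(lengths(tree$samples))

tree_node <- function(tree, path) {
  node <- tree$root
  for (i in path) {
    if (i < 1 || i > length(node$children)) {
      gv_error(sprintf("no node at path [%s]", paste(path, collapse = ", ")),
               "gv_sweep_error")
    }
    node <- node$children[[i]]
  }
  node
}

#' Enumerate the tool runs under a tree node
#'
#' One complete assignment per leaf under the node: ancestors of the node
#' (and the node itself) contribute their fixed sampled values, the
#' remaining levels expand to all combinations (depth-first leaf order),
#' and parameters kept out of the tree take their `fixed_value`.
#' Clicking the root enumerates the full sweep; clicking a depth-1 node
#' of a two-parameter tree runs one job per value of the second
#' parameter.
#'
#' @param tree A [build_param_tree()] result.
#' @param path Integer vector of child indices addressing the node
#'   (`integer(0)` = root).
#' @param tool Optional [tool_spec()] supplying out-of-tree fixed
#'   parameters.
#' @return List of runs; each has `assignment` (named list) and
#'   `path_labels` (character vector of `"name=value"` ancestry labels).
#' @export
enumerate_runs <- function(tree, path = integer(0), tool = NULL) {
  tree_node(tree, path)  # validates the path
  d <- length(path)
  nlev <- length(tree$params)
  fixed_idx <- path
  free_levels <- if (d < nlev) (d + 1):nlev else integer(0)
  combos <- if (length(free_levels)) {
    g <- expand.grid(rev(lapply(free_levels, function(l) {
      seq_along(tree$samples[[l]])
    })), KEEP.OUT.ATTRS = FALSE)
    g[, rev(seq_len(ncol(g))), drop = FALSE]
  } else {
    data.frame(row.names = 1)  # single empty combo
  }
  out_of_tree <- Filter(function(p) !p$in_tree, tree$specs %||% list())
  fixed_extra <- stats::setNames(
    lapply(out_of_tree, function(p) {
      p$fixed_value %||% (if (p$kind == "numeric") p$min else p$values[[1]])
    }),
    vapply(out_of_tree, function(p) p$name, "")
  )
  lapply(seq_len(nrow(combos)), function(r) {
    idx <- c(fixed_idx,
             if (length(free_levels)) as.integer(unlist(combos[r, ])) else integer(0))
    vals <- lapply(seq_along(idx), function(l) tree$samples[[l]][[idx[l]]])
    names(vals) <- tree$params[seq_along(idx)]
    labels <- sprintf("%s=%s", names(vals),
                      vapply(vals, function(v) format(v, scientific = FALSE), ""))
    list(assignment = c(vals, fixed_extra), path_labels = labels)
  })
}

default_executor <- function(cmd) {
  out <- suppressWarnings(system2("/bin/sh", c("-c", shQuote(cmd)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  list(exit = status, output = paste(out, collapse = "\n"))
}

fill_template <- function(command, input, output, assignment) {
  cmd <- gsub("{input}", input, command, fixed = TRUE)
  cmd <- gsub("{output}", output, cmd, fixed = TRUE)
  for (nm in names(assignment)) {
    cmd <- gsub(paste0("{param:", nm, "}"),
                format(assignment[[nm]], scientific = FALSE), cmd, fixed = TRUE)
  }
  left <- regmatches(cmd, gregexpr("\\{param:[^}]+\\}", cmd))[[1]]
  if (length(left)) {
    gv_error(sprintf("unfilled placeholder %s", left[1]), "gv_sweep_error")
  }
  cmd
}

LINE_RECORD_FORMATS <- c("bed", "gff3", "gtf", "interval", "bedgraph", "vcf", "sam")

#' Extract and cache the subset of a dataset overlapping regions
#'
#' Writes the records overlapping any of `regions`, in source order and in
#' the source format (original lines byte-for-byte, header lines kept), to
#' a file keyed by the dataset checksum and the canonicalized region set.
#' A repeated call with the same key returns the cached path without
#' rewriting, which is what makes repeated tool runs on the same view
#' fast.
#'
#' @param dataset A [open_dataset()] handle in a line-per-record format.
#' @param index Its index.
#' @param regions List of [gv_region()]s.
#' @param cache_dir Directory for cached subsets.
#' @return Path of the subset file.
#' @export
subset_dataset <- function(dataset, index, regions,
                           cache_dir = file.path(tempdir(), "gv_subsets")) {
  if (!dataset$format %in% LINE_RECORD_FORMATS) {
    gv_error(sprintf("cannot subset '%s' datasets line-wise", dataset$format),
             "gv_sweep_error")
  }
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(cache_dir, 2) != 0) {
    gv_error(sprintf("subset cache directory '%s' is not writable", cache_dir),
             "gv_io_error")
  }
  canon <- sort(vapply(regions, function(r) {
    sprintf("%s:%s-%s", r$chrom, format(r$start, scientific = FALSE),
            format(r$end, scientific = FALSE))
  }, ""))
  keyfile <- tempfile()
  writeLines(c(dataset$checksum$md5, canon), keyfile)
  key <- unname(tools::md5sum(keyfile))
  unlink(keyfile)
  ext <- sub("^.*\\.", "", basename(dataset$path))
  path <- file.path(cache_dir, paste0("subset-", key, ".", ext))
  if (file.exists(path)) return(path)
  hit_lines <- sort(unique(unlist(lapply(regions, function(r) {
    index$records$offset[query_index(index, r)]
  }))))
  lines <- readLines(dataset$path, warn = FALSE)
  header <- which(if (dataset$format == "sam") startsWith(lines, "@")
                  else is_skip_line(lines))
  keep <- sort(unique(c(header, hit_lines)))
  writeLines(lines[keep], path)
  path
}

slice_records <- function(records, region) {
  sel <- records$chrom == region$chrom & records$start < region$end &
    records$end > region$start
  records[sel, , drop = FALSE]
}

#' Run a parameter sweep over the runs under a tree node
#'
#' Subsets the dataset to the union of the selected regions once, then
#' runs the tool once per assignment enumerated under the node, parses
#' each output in the tool's declared output format, and slices it into
#' one payload per region (the track tiles of the sweep view).  Runs are
#' independent; a failing run is recorded with its diagnostics and does
#' not abort the sweep.
#'
#' @param tool A [tool_spec()].
#' @param dataset,index Input dataset and its index.
#' @param tree A [build_param_tree()] result.
#' @param path Node address (see [enumerate_runs()]).
#' @param regions List of [gv_region()]s to evaluate on.
#' @param executor Function taking a command string and returning
#'   `list(exit, output)`; sequential shell execution by default.
#' @param cache_dir Subset cache directory.
#' @param per_region Run the tool once per (assignment, region) on
#'   per-region subsets instead of slicing one union-subset run; results
#'   are identical for region-local tools.
#' @return List of `gv_sweep_run` objects: `assignment`, `path_labels`,
#'   `status` (`"ok"`/`"failed"`), `output_path`, `outputs` (per-region
#'   record frames) and `diagnostics`.
#' @export
execute_sweep <- function(tool, dataset, index, tree, path = integer(0),
                          regions, executor = default_executor,
                          cache_dir = file.path(tempdir(), "gv_subsets"),
                          per_region = FALSE) {
  if (tool$input_format != dataset$format) {
    gv_error(sprintf("tool '%s' expects %s input, dataset is %s",
                     tool$id, tool$input_format, dataset$format), "gv_sweep_error")
  }
  runs <- enumerate_runs(tree, path, tool)
  run_one <- function(input_path, assignment) {
    out_path <- tempfile(fileext = paste0(".", tool$output_format))
    cmd <- fill_template(tool$command, input_path, out_path, assignment)
    res <- executor(cmd)
    if (res$exit != 0L) {
      return(list(ok = FALSE, path = out_path,
                  diag = sprintf("exit %d: %s", res$exit, res$output)))
    }
    parsed <- tryCatch(open_dataset(out_path, tool$output_format),
                       error = function(e) e)
    if (inherits(parsed, "error")) {
      return(list(ok = FALSE, path = out_path,
                  diag = sprintf("unparseable output: %s", conditionMessage(parsed))))
    }
    list(ok = TRUE, path = out_path, records = parsed$records)
  }
  if (!per_region) {
    subset_path <- subset_dataset(dataset, index, regions, cache_dir)
  }
  lapply(runs, function(run) {
    if (per_region) {
      outputs <- list(); status <- "ok"; diag <- NULL; opath <- NULL
      for (r in regions) {
        sp <- subset_dataset(dataset, index, list(r), cache_dir)
        res <- run_one(sp, run$assignment)
        if (!res$ok) { status <- "failed"; diag <- res$diag; break }
        outputs[[format_region_string(r)]] <- slice_records(res$records, r)
        opath <- res$path
      }
    } else {
      res <- run_one(subset_path, run$assignment)
      opath <- res$path
      if (res$ok) {
        status <- "ok"; diag <- NULL
        outputs <- stats::setNames(
          lapply(regions, function(r) slice_records(res$records, r)),
          vapply(regions, format_region_string, "")
        )
      } else {
        status <- "failed"; diag <- res$diag; outputs <- list()
      }
    }
    structure(list(assignment = run$assignment, path_labels = run$path_labels,
                   status = status, output_path = opath,
                   outputs = outputs, diagnostics = diag),
              class = "gv_sweep_run")
  })
}

#' Run a tool with one assignment on the complete dataset
#'
#' The promotion step after a sweep: once good settings are found, run
#' them on the un-subset dataset and register the output as a new
#' dataset.
#'
#' @inheritParams execute_sweep
#' @param assignment Complete named parameter assignment.
#' @param out_path Output dataset path.
#' @return The output [open_dataset()] handle.
#' @export
run_full <- function(tool, dataset, assignment, executor = default_executor,
                     out_path = tempfile(fileext = paste0(".", tool$output_format))) {
  cmd <- fill_template(tool$command, dataset$path, out_path, assignment)
  res <- executor(cmd)
  if (res$exit != 0L) {
    gv_error(sprintf("tool '%s' failed with exit %d: %s", tool$id, res$exit,
                     res$output), "gv_tool_error")
  }
  open_dataset(out_path, tool$output_format)
}

#' Write the sweep manifest
#'
#' JSON report mapping each run's tree path to its assignment, status and
#' output location.
#'
#' @param runs Result of [execute_sweep()].
#' @param manifest_path Output JSON path.
#' @return `manifest_path`, invisibly.
#' @export
write_sweep_manifest <- function(runs, manifest_path) {
  doc <- lapply(runs, function(run) {
    list(path = paste(run$path_labels, collapse = " / "),
         assignment = run$assignment, status = run$status,
         output = run$output_path,
         regions = names(run$outputs),
         records_per_region = unname(vapply(run$outputs, nrow, 0L)))
  })
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA),
             manifest_path)
  invisible(manifest_path)
}

#' Read a tool configuration file
#'
#' JSON document with `id`, `command`, `input_format`, `output_format` and
#' `parameters` (each with the [param_spec()] fields).
#'
#' @param path Tool config path.
#' @return A [tool_spec()].
#' @export
read_tool_config <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  params <- lapply(doc$parameters %||% list(), function(p) {
    param_spec(p$name, p$kind %||% "numeric", min = p$min, max = p$max,
               n_samples = p$n_samples, values = unlist(p$values),
               in_tree = p$in_tree %||% TRUE, fixed_value = p$fixed_value)
  })
  tool_spec(doc$id, doc$command, doc$input_format, doc$output_format, params)
}

#' Bundled toy tools
#'
#' Small region-local tools used to exercise the sweep engine without any
#' external dependency: `"identity"` copies its input; `"counter"`
#' rewrites each BED record with score 1 (so per-region record counts
#' equal overlap counts); `"score_scale"` multiplies BED scores by the
#' numeric parameter `factor`.  All three are per-record maps, hence
#' running them on a region subset equals restricting a full run to the
#' region.
#'
#' @param id One of `"identity"`, `"counter"`, `"score_scale"`.
#' @return A [tool_spec()].
#' @export
builtin_tool <- function(id = c("identity", "counter", "score_scale")) {
  id <- match.arg(id)
  switch(id,
    identity = tool_spec("identity", "cp {input} {output}", "bed", "bed"),
    counter = tool_spec(
      "counter",
      paste0("awk -F'\t' -v OFS='\t' ",
             "'{print $1, $2, $3, ($4 == \"\" ? \".\" : $4), 1, ($6 == \"\" ? \".\" : $6)}' ",
             "{input} > {output}"),
      "bed", "bed"),
    score_scale = tool_spec(
      "score_scale",
      paste0("awk -F'\t' -v OFS='\t' -v f={param:factor} ",
             "'{print $1, $2, $3, ($4 == \"\" ? \".\" : $4), $5 * f, ($6 == \"\" ? \".\" : $6)}' ",
             "{input} > {output}"),
      "bed", "bed",
      parameters = list(param_spec("factor", "numeric", 0.5, 2, 4)))
  )
}
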