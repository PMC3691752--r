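`%||%` <- function(a, b) if (is.null(a)) b else a

gv_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "gv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

# Deterministic 32-bit seed for a named random stream.  Adding a stream never
# perturbs an existing one because each name hashes independently.
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(derive_seed(seed, name))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# File fingerprint used by index sidecars and the subset cache: byte size
# plus whole-file md5.  mtime deliberately excluded so a byte-identical
# regeneration of a dataset does not invalidate its index.
file_checksum <- function(path) {
  if (!file.exists(path)) gv_error(sprintf("no such file: %s", path), "gv_io_error")
  list(size = file.size(path), md5 = unname(tools::md5sum(path)))
}

# Fixed-precision coordinate formatting so rendered SVG is byte-stable.
fmt_num <- function(x, digits = 3) {
  out <- formatC(x, format = "f", digits = digits)
  sub("^-(0(\\.0+)?)$", "\\1", out)
}
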