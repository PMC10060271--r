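# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

assert_scalar_num <- function(x, field, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_field(field, "must be a single finite number")
  if (strict_lower && x <= lower)
    abort_field(field, sprintf("must be > %g", lower))
  if (!strict_lower && x < lower)
    abort_field(field, sprintf("must be >= %g", lower))
  if (x > upper)
    abort_field(field, sprintf("must be <= %g", upper))
  invisible(x)
}

assert_matrix <- function(x, what = "input") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("%s must be a 2-D numeric raster (matrix)", what),
         call. = FALSE)
  invisible(x)
}

# Pixel mask of a filled disk on an nr x nc raster. Centers are 0-based
# (cx = column, cy = row, origin top-left); returns a logical matrix.
disk_mask <- function(nr, nc, cx, cy, r) {
  cols <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  rows <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
  (cols - cx)^2 + (rows - cy)^2 <= r^2
}

# Deterministic per-(well, frame) sub-seed below 2^31, derived from the
# master seed so every well renders independently of iteration order.
derive_seed <- function(seed, well_index, frame = 0L) {
  (seed * 10007L + well_index * 131L + frame * 7L) %% 2147483399L + 1L
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

geom_mean <- function(x) exp(mean(log(x)))
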