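#' @keywords internal
"_PACKAGE"

# Input checkers shared across modules. All stop() with the offending
# argument name so callers get actionable errors.

stop_input <- function(...) {
  stop(..., call. = FALSE)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    stop_input(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop_input(sprintf(
      "`%s` must be a number in %s%g, %g%s", name,
      if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"
    ))
  }
  as.numeric(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_input(sprintf("`%s` must be TRUE or FALSE", name))
  }
  x
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_input("`seed` must be a single integer")
  }
  as.integer(seed)
}

# Derive a reproducible sub-seed from a master seed and a stream label,
# so each generator consumes an independent stream. Kept below 2^31.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

check_expression_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop_input("`expr` must be a numeric genes x samples matrix")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop_input("`expr` must have gene rownames and sample colnames")
  }
  if (any(!is.finite(expr))) stop_input("`expr` contains non-finite values")
  invisible(expr)
}
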