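#' @keywords internal
"_PACKAGE"

## Shared helpers: argument checks, rounding, small numerics.

stop_domain <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0)
    stop_domain(sprintf("'%s' must be > 0 (got %g)", name, x))
  if (nonneg && x < 0)
    stop_domain(sprintf("'%s' must be >= 0 (got %g)", name, x))
  invisible(x)
}

check_times <- function(times, name = "times") {
  if (length(times) < 1L || any(!is.finite(times)) || any(times < 0))
    stop_domain(sprintf("'%s' must be finite and >= 0", name))
  if (is.unsorted(times, strictly = TRUE))
    stop_domain(sprintf("'%s' must be strictly increasing", name))
  invisible(times)
}

#' Round half-up to a fixed number of decimals
#'
#' Commercial (half-up) rounding, used when reproducing printed SUV ranges:
#' 15.66 rounds to 15.7 and 1.57 to 1.6 at one decimal. Base R's `round()`
#' rounds half to even, which differs exactly at the ties this convention
#' must break upward.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Stable non-cryptographic content hash for provenance (md5 of the
## serialized JSON written to a temp file; base R only).
content_hash <- function(obj) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

## Derive a reproducible 32-bit sub-seed from a parent seed and indices.
sub_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 69069 + i * 1013 + 1) %% 2147483647
  as.integer(s)
}
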