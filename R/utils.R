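# Internal helpers shared across modules.

REGIONS <- c("patella", "femur", "tibia", "patellar_tendon")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Checks a numeric vector of per-region values named (or orderable) over the
# four foreground regions and returns it named in canonical order.
as_region_vector <- function(x, what = "value") {
  if (length(x) != 4L) stopf("%s must have one entry per region (4), got %d", what, length(x))
  if (!is.null(names(x)) && all(names(x) %in% REGIONS)) x <- x[REGIONS]
  stats::setNames(as.numeric(x), REGIONS)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

# Binary mask sanity check: logical or 0/1 numeric matrix.
check_mask <- function(m, what = "mask") {
  if (!is.matrix(m)) stopf("%s must be a matrix", what)
  v <- as.vector(m)
  if (is.logical(v)) return(matrix(as.integer(v), nrow(m), ncol(m)))
  if (!all(v %in% c(0, 1))) stopf("%s must be binary (0/1)", what)
  matrix(as.integer(v), nrow(m), ncol(m))
}

check_label_map <- function(lm, what = "label_map") {
  if (!is.matrix(lm)) stopf("%s must be a matrix", what)
  if (!all(lm %in% 0:4)) stopf("%s may only contain labels 0..4", what)
  matrix(as.integer(lm), nrow(lm), ncol(lm))
}
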