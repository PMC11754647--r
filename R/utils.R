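#' @keywords internal
"_PACKAGE"

## Axial rise per base pair of B-form DNA, in nm. Every edge-length ->
## nucleotide conversion in the package goes through this constant.
BP_RISE_NM <- 0.34

## Length of the M13mp18 single-stranded scaffold, in nucleotides.
M13MP18_NT <- 7249L

#' Signal a classed error
#'
#' All package errors carry a condition class (e.g. "triangulation_error")
#' so callers can dispatch on the failure mode rather than match message
#' strings.
#'
#' @param message error message.
#' @param class condition class, in addition to "wireframegen_error".
#' @param ... fields attached to the condition.
#' @noRd
abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "wireframegen_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## Cross product of two 3-vectors.
cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalise a zero vector", "degenerate_vector_error")
  v / n
}

## Twice the area of triangle (a, b, c); rows are 3D points.
tri_area2 <- function(a, b, c) vnorm(cross3(b - a, c - a))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
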