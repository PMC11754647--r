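#' Parallelepiped bounding box
#'
#' The design space is a parallelepiped spanned by three axes: the `a` axis
#' along x, the `b` axis in the xy plane at an angle `gamma` to `a`, and the
#' `c` axis along z. Its volume is `a * b * c * sin(gamma)`. All coordinates
#' are in nanometres; the origin sits at the box corner from which the three
#' axes emanate.
#'
#' @param a,b,c side lengths in nm (positive).
#' @param gamma angle between the `a` and `b` axes in degrees, in (0, 180).
#' @param origin numeric length-3, corner of the box (nm).
#' @return an object of class `bounding_box`.
#' @examples
#' box <- bounding_box(50, 50, 50)
#' box_volume(box)
#' @export
bounding_box <- function(a, b, c, gamma = 90, origin = c(0, 0, 0)) {
  if (!is_scalar_num(a) || !is_scalar_num(b) || !is_scalar_num(c) ||
      a <= 0 || b <= 0 || c <= 0)
    abort("bounding box side lengths must be positive finite numbers",
          "schema_error")
  if (!is_scalar_num(gamma) || gamma <= 0 || gamma >= 180)
    abort("gamma must lie strictly between 0 and 180 degrees", "schema_error")
  if (!is.numeric(origin) || length(origin) != 3L || !all(is.finite(origin)))
    abort("origin must be a finite 3D point", "schema_error")
  structure(
    list(a = a, b = b, c = c, gamma = gamma, origin = as.numeric(origin)),
    class = "bounding_box"
  )
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("bounding box: a=%.3g b=%.3g c=%.3g nm, gamma=%.3g deg, volume=%.4g nm^3\n",
              x$a, x$b, x$c, x$gamma, box_volume(x)))
  invisible(x)
}

#' Bounding-box volume
#'
#' @param box a [bounding_box()].
#' @return volume `a * b * c * sin(gamma)` in nm^3.
#' @export
box_volume <- function(box) {
  box$a * box$b * box$c * sin(box$gamma * pi / 180)
}

## Fractional coordinates (along the a, b, c axes) of Cartesian points.
## pts: n x 3 matrix. Returns n x 3 matrix u with the box interior being
## 0 <= u[,1] <= a, 0 <= u[,2] <= b, 0 <= u[,3] <= c.
box_fractional <- function(box, pts) {
  pts <- rbind(pts)
  g <- box$gamma * pi / 180
  x <- pts[, 1L] - box$origin[1L]
  y <- pts[, 2L] - box$origin[2L]
  z <- pts[, 3L] - box$origin[3L]
  u2 <- y / sin(g)
  u1 <- x - y * cos(g) / sin(g)
  cbind(u1, u2, z)
}

## Logical vector: which points lie inside the box (closed, with tolerance).
box_contains <- function(box, pts, tol = 1e-9) {
  u <- box_fractional(box, pts)
  dims <- c(box$a, box$b, box$c)
  lo <- u >= -tol
  hi <- sweep(u, 2L, dims + tol, "<=")
  rowSums(lo & hi) == 3L
}

#' Axis-aligned excluded region
#'
#' A convex axis-aligned box that must stay free of structure material
#' (e.g. space reserved for a guest nanoparticle). Any vertex inside the
#' region, or any edge segment crossing its interior, makes a design
#' spatially infeasible.
#'
#' @param min_corner,max_corner numeric length-3 corners (nm), componentwise
#'   `min_corner < max_corner`.
#' @return an object of class `excluded_region`.
#' @export
excluded_region <- function(min_corner, max_corner) {
  min_corner <- as.numeric(min_corner)
  max_corner <- as.numeric(max_corner)
  if (length(min_corner) != 3L || length(max_corner) != 3L ||
      !all(is.finite(c(min_corner, max_corner))))
    abort("excluded region corners must be finite 3D points", "schema_error")
  if (!all(min_corner < max_corner))
    abort("excluded region min corner must be strictly below max corner componentwise",
          "schema_error")
  structure(list(min = min_corner, max = max_corner), class = "excluded_region")
}

#' @export
print.excluded_region <- function(x, ...) {
  cat(sprintf("excluded region: [%s] to [%s] nm\n",
              paste(signif(x$min, 4), collapse = ", "),
              paste(signif(x$max, 4), collapse = ", ")))
  invisible(x)
}

## Which points fall strictly inside the region interior.
region_contains <- function(region, pts, tol = 1e-9) {
  pts <- rbind(pts)
  inside <- sweep(pts, 2L, region$min + tol, ">") &
    sweep(pts, 2L, region$max - tol, "<")
  rowSums(inside) == 3L
}

## Slab-method test: do segments (p, q) pass through the open interior of an
## axis-aligned box? p, q: n x 3 matrices of endpoints. Returns logical n.
## Grazing contact with the boundary (zero-measure overlap) does not count.
segment_crosses_region <- function(region, p, q, tol = 1e-9) {
  p <- rbind(p); q <- rbind(q)
  n <- nrow(p)
  t0 <- rep(0, n)
  t1 <- rep(1, n)
  alive <- rep(TRUE, n)
  for (k in 1:3) {
    d <- q[, k] - p[, k]
    par <- abs(d) < 1e-14
    ## parallel to this slab: must already be inside it
    out <- par & (p[, k] <= region$min[k] + tol | p[, k] >= region$max[k] - tol)
    alive <- alive & !out
    tn <- (region$min[k] - p[, k]) / d
    tf <- (region$max[k] - p[, k]) / d
    swap <- !par & tn > tf
    tmp <- tn[swap]; tn[swap] <- tf[swap]; tf[swap] <- tmp
    t0 <- ifelse(par, t0, pmax(t0, tn))
    t1 <- ifelse(par, t1, pmin(t1, tf))
  }
  alive & (t1 - t0 > tol)
}
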