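#' Preserved-vertex fixture: cube corners
#'
#' The eight corners of an axis-aligned cube of the given side, the
#' starting preserved region of the single-objective study (a bounding box
#' whose every dimension is at most 50 nm).
#'
#' @param side cube side in nm (> 0).
#' @return an 8 x 3 matrix of points.
#' @export
fixture_cube_corners <- function(side) {
  if (!is_scalar_num(side) || side <= 0)
    abort("side must be a positive length in nm", "schema_error")
  as.matrix(expand.grid(x = c(0, side), y = c(0, side), z = c(0, side)))[, 1:3,
                                                                         drop = FALSE]
}

#' Preserved-vertex fixture: parallelepiped midfaces
#'
#' The six face-centre points of a parallelepiped with sides `a`, `b`, `c`
#' and angle `gamma` between the `a` and `b` axes — the preserved regions
#' of the multi-objective study, held at the midface of each box face.
#' Their convex hull is a (sheared) octahedron.
#'
#' @param a,b,c side lengths in nm.
#' @param gamma angle between the `a` and `b` axes, degrees.
#' @return a 6 x 3 matrix of points.
#' @export
fixture_parallelepiped_midfaces <- function(a, b, c, gamma = 90) {
  box <- bounding_box(a, b, c, gamma)   # validates the inputs
  g <- gamma * pi / 180
  av <- c(a, 0, 0)
  bv <- c(b * cos(g), b * sin(g), 0)
  cv <- c(0, 0, c)
  ctr <- (av + bv + cv) / 2
  pts <- rbind(
    ctr - cv / 2,            # bottom (z = 0)
    ctr + cv / 2,            # top
    ctr - bv / 2,            # b = 0 face
    ctr + bv / 2,            # b = b face
    ctr - av / 2,            # a = 0 face
    ctr + av / 2             # a = a face
  )
  dimnames(pts) <- NULL
  stopifnot(all(box_contains(box, pts)))
  pts
}
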