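## 3D convex hull triangulation.
##
## Design initialization only ever hulls the handful of preserved vertices a
## user prescribes, so a robust brute-force formulation is preferred over an
## incremental algorithm: enumerate supporting planes (triples of points with
## all remaining points on one side), group coplanar triples into a face,
## order each face polygon with the 2D hull, and fan-triangulate. Complexity
## O(n^4) — irrelevant at the tens-of-points scale this package sees, and
## free of the degeneracy special-casing incremental hulls need for exactly
## coplanar facets (cube faces, midface fixtures).

## pts: n x 3 matrix. Returns list(faces = F x 3 integer matrix of outward-
## oriented triangles, on_hull = logical n).
hull_triangulation <- function(pts, tol = 1e-7) {
  n <- nrow(pts)
  if (n < 4L)
    abort("at least 4 points are required for a closed triangulation",
          "triangulation_error")
  if (anyDuplicated(round(pts / tol)) > 0L)
    abort("duplicate points in triangulation input", "triangulation_error")
  ctr <- colMeans(pts)
  centred <- sweep(pts, 2L, ctr)
  scale <- max(1, max(abs(centred)))
  if (svd(centred, nu = 0L, nv = 0L)$d[3L] < 1e-9 * scale * n)
    abort("points are coplanar: no closed 3D triangulation exists",
          "triangulation_error")
  eps <- tol * scale

  triples <- utils::combn(n, 3L)
  face_keys <- character(0)
  planes <- list()
  for (j in seq_len(ncol(triples))) {
    i1 <- triples[1L, j]; i2 <- triples[2L, j]; i3 <- triples[3L, j]
    nrm <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
    nn <- vnorm(nrm)
    if (nn < 1e-10 * scale^2) next   # collinear triple
    nrm <- nrm / nn
    off <- sum(nrm * pts[i1, ])
    s <- drop(pts %*% nrm) - off
    if (all(s <= eps)) {
      ## normal already points away from the point cloud
    } else if (all(s >= -eps)) {
      nrm <- -nrm; off <- -off; s <- -s
    } else next
    on_face <- which(abs(s) <= eps)
    key <- paste(on_face, collapse = ",")
    if (key %in% face_keys) next
    face_keys <- c(face_keys, key)
    planes[[length(planes) + 1L]] <- list(normal = nrm, idx = on_face)
  }
  if (length(planes) < 4L)
    abort("failed to enumerate hull faces (degenerate input)",
          "triangulation_error")

  faces <- NULL
  used <- rep(FALSE, n)
  for (pl in planes) {
    idx <- pl$idx
    used[idx] <- TRUE
    ## 2D coordinates in the face plane
    o <- pts[idx[1L], ]
    u <- NULL
    for (k in idx[-1L]) {
      v <- pts[k, ] - o
      if (vnorm(v) > eps) { u <- v / vnorm(v); break }
    }
    w <- cross3(pl$normal, u)
    rel <- sweep(pts[idx, , drop = FALSE], 2L, o)
    xy <- cbind(drop(rel %*% u), drop(rel %*% w))
    ord <- grDevices::chull(xy[, 1L], xy[, 2L])
    poly <- idx[ord]
    if (length(poly) < length(idx))
      abort("a preserved point lies inside a hull face and cannot appear as a mesh vertex",
            "triangulation_error")
    ## fan-triangulate, then orient each triangle outward
    for (t in 2:(length(poly) - 1L)) {
      tri <- c(poly[1L], poly[t], poly[t + 1L])
      nrm_t <- cross3(pts[tri[2L], ] - pts[tri[1L], ],
                      pts[tri[3L], ] - pts[tri[1L], ])
      if (sum(nrm_t * pl$normal) < 0) tri <- tri[c(1L, 3L, 2L)]
      faces <- rbind(faces, tri)
    }
  }
  dimnames(faces) <- NULL
  list(faces = faces, on_hull = used)
}

## Unique undirected edges of a face matrix, as a 2-column matrix with
## edge[, 1] < edge[, 2].
faces_to_edges <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}
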