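#' @title Design states: graph-backed triangulated wireframe meshes
#'
#' @description A design state is the unit the generative process evolves: a
#' closed, edge-manifold, all-triangle surface mesh stored as a labelled
#' graph (vertex positions and preserved flags as node labels, preserved
#' flags on edges), together with the bounding box, edge type and excluded
#' regions of the problem. States are immutable: every grammar rule returns
#' a modified copy.
#'
#' @name design_state
NULL

## Internal constructor; performs no validation.
new_design_state <- function(pos, v_preserved, edges, e_preserved, faces,
                             box, edge_type, excluded = list()) {
  structure(
    list(pos = pos, v_preserved = v_preserved,
         edges = edges, e_preserved = e_preserved,
         faces = faces, box = box, edge_type = edge_type,
         excluded = excluded),
    class = "design_state"
  )
}

#' Initialize a design state from preserved regions
#'
#' Builds the starting design `s1` without requiring an input mesh file: the
#' preserved vertices (and preserved-edge endpoints) are triangulated as
#' their 3D convex hull, the canonical minimal closed triangulation. All
#' preserved geometry must lie on that hull — an interior preserved point or
#' a chord that is not a hull edge cannot survive as mesh geometry and is an
#' error.
#'
#' @param preserved_vertices matrix (n x 3) or list of 3D points (nm) that
#'   must appear as mesh vertices in every generated design.
#' @param preserved_edges optional list of point pairs (each a 2 x 3 matrix
#'   or list of two points) that must appear as mesh edges.
#' @param excluded optional list of [excluded_region()] objects.
#' @param box a [bounding_box()].
#' @param edge_type an [edge_type()].
#' @param constraints optional [constraint_set()]; when supplied the
#'   triangulated state must be feasible, otherwise the generative process
#'   cannot begin and an error of class `infeasible_start_error` is raised.
#' @return a `design_state` (the initial solution `s1`).
#' @examples
#' st <- initialize_design(fixture_cube_corners(50), box = bounding_box(50, 50, 50),
#'                         edge_type = edge_type("2HB"))
#' st
#' @export
initialize_design <- function(preserved_vertices,
                              preserved_edges = list(),
                              excluded = list(),
                              box,
                              edge_type,
                              constraints = NULL) {
  pts <- as_point_matrix(preserved_vertices)
  edge_pts <- lapply(preserved_edges, function(e) {
    m <- as_point_matrix(e)
    if (nrow(m) != 2L)
      abort("a preserved edge must be a pair of 3D points", "schema_error")
    m
  })
  if (!inherits(box, "bounding_box")) abort("box must be a bounding_box", "schema_error")
  if (!inherits(edge_type, "edge_type")) abort("edge_type must be an edge_type", "schema_error")
  for (r in excluded)
    if (!inherits(r, "excluded_region"))
      abort("excluded must be a list of excluded_region objects", "schema_error")

  ## merge edge endpoints into the vertex set (tolerant match)
  all_pts <- pts
  edge_idx <- matrix(integer(0), 0L, 2L)
  for (m in edge_pts) {
    ij <- integer(2)
    for (k in 1:2) {
      d2 <- rowSums(sweep(all_pts, 2L, m[k, ])^2)
      hit <- which(d2 < 1e-12)
      if (length(hit)) ij[k] <- hit[1L]
      else { all_pts <- rbind(all_pts, m[k, ]); ij[k] <- nrow(all_pts) }
    }
    edge_idx <- rbind(edge_idx, sort(ij))
  }

  if (!all(box_contains(box, all_pts)))
    abort("preserved geometry must lie inside the bounding box",
          "region_conflict_error")
  for (r in excluded) {
    if (any(region_contains(r, all_pts)))
      abort("a preserved vertex lies inside an excluded region",
            "region_conflict_error")
    if (nrow(edge_idx) &&
        any(segment_crosses_region(r, all_pts[edge_idx[, 1L], , drop = FALSE],
                                   all_pts[edge_idx[, 2L], , drop = FALSE])))
      abort("a preserved edge crosses an excluded region",
            "region_conflict_error")
  }

  hull <- hull_triangulation(all_pts)
  if (!all(hull$on_hull))
    abort("preserved vertices interior to the convex hull cannot appear in a closed triangulation",
          "triangulation_error")
  faces <- hull$faces
  edges <- faces_to_edges(faces)
  e_pres <- rep(FALSE, nrow(edges))
  if (nrow(edge_idx)) {
    key <- edges[, 1L] * (nrow(all_pts) + 1) + edges[, 2L]
    want <- edge_idx[, 1L] * (nrow(all_pts) + 1) + edge_idx[, 2L]
    pos_in <- match(want, key)
    if (anyNA(pos_in))
      abort("a preserved edge is not an edge of the triangulated hull",
            "triangulation_error")
    e_pres[pos_in] <- TRUE
  }

  state <- new_design_state(
    pos = all_pts,
    v_preserved = rep(TRUE, nrow(all_pts)),
    edges = edges, e_preserved = e_pres,
    faces = faces, box = box, edge_type = edge_type, excluded = excluded
  )
  rep_v <- validate_mesh(state)
  if (!rep_v$valid)
    abort(paste0("triangulated start is not a valid mesh: ",
                 paste(rep_v$violations, collapse = "; ")),
          "triangulation_error")
  if (!is.null(constraints)) {
    rep_f <- is_feasible(state, constraints)
    if (!rep_f$feasible)
      abort(paste0("triangulated start violates constraints: ",
                   paste(rep_f$violations$constraint, collapse = ", "),
                   " - the generative process cannot begin"),
            "infeasible_start_error")
  }
  state
}

as_point_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, lapply(x, as.numeric))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L || !all(is.finite(x)))
    abort("points must be finite 3D coordinates (n x 3)", "schema_error")
  dimnames(x) <- NULL
  x
}

#' @export
print.design_state <- function(x, ...) {
  cat(sprintf("wireframe design state: V=%d E=%d F=%d (%s edges)\n",
              nrow(x$pos), nrow(x$edges), nrow(x$faces), x$edge_type$name))
  cat(sprintf("  estimated scaffold: %d nt; preserved: %d vertices, %d edges\n",
              estimate_scaffold_nt(x), sum(x$v_preserved), sum(x$e_preserved)))
  print(x$box)
  invisible(x)
}

#' Validate a design-state mesh
#'
#' Checks the structural invariants every design state must satisfy: all
#' faces are triangles over valid vertex indices, no self-loop or duplicate
#' edges, no zero-area faces, the surface is closed and edge-manifold (every
#' undirected edge borders exactly two faces, once in each direction, so the
#' surface is consistently oriented), every vertex link is a single cycle
#' (vertex-manifold), no isolated vertices, and the Euler characteristic
#' V - E + F equals 2 (genus-0 closed surface).
#'
#' @param state a `design_state`.
#' @param strict also run O(F^2) face-face self-intersection tests between
#'   non-adjacent triangles. Off by default: grammar moves are local and the
#'   cheap manifoldness checks run on every candidate.
#' @return list with `valid` (flag) and `violations` (character vector).
#' @export
validate_mesh <- function(state, strict = FALSE) {
  v <- character(0)
  pos <- state$pos; edges <- state$edges; faces <- state$faces
  nv <- nrow(pos)
  if (!all(is.finite(pos))) v <- c(v, "non-finite vertex positions")
  if (nrow(faces) == 0L || ncol(faces) != 3L) {
    return(list(valid = FALSE, violations = c(v, "no triangular faces")))
  }
  if (any(faces < 1L | faces > nv) || any(edges < 1L | edges > nv))
    return(list(valid = FALSE, violations = c(v, "vertex index out of range")))
  if (any(edges[, 1L] == edges[, 2L])) v <- c(v, "self-loop edge")
  ekey <- edges[, 1L] * (nv + 1) + edges[, 2L]
  if (anyDuplicated(ekey)) v <- c(v, "duplicate edges")
  if (any(faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
          faces[, 1L] == faces[, 3L]))
    v <- c(v, "degenerate face (repeated vertex)")

  ## zero-area faces
  ab <- pos[faces[, 2L], , drop = FALSE] - pos[faces[, 1L], , drop = FALSE]
  ac <- pos[faces[, 3L], , drop = FALSE] - pos[faces[, 1L], , drop = FALSE]
  cx <- cbind(ab[, 2L] * ac[, 3L] - ab[, 3L] * ac[, 2L],
              ab[, 3L] * ac[, 1L] - ab[, 1L] * ac[, 3L],
              ab[, 1L] * ac[, 2L] - ab[, 2L] * ac[, 1L])
  if (any(sqrt(rowSums(cx^2)) < 1e-9)) v <- c(v, "zero-area face")

  ## directed face edges: closed oriented manifold iff every undirected edge
  ## appears exactly twice, once per direction, and matches the edge table
  de_from <- c(faces[, 1L], faces[, 2L], faces[, 3L])
  de_to <- c(faces[, 2L], faces[, 3L], faces[, 1L])
  dkey <- de_from * (nv + 1) + de_to
  if (anyDuplicated(dkey)) v <- c(v, "inconsistent face orientation (repeated directed edge)")
  ukey <- pmin(de_from, de_to) * (nv + 1) + pmax(de_from, de_to)
  uniq <- sort(unique(ukey))
  cnt <- tabulate(match(ukey, uniq))
  if (any(cnt != 2L)) v <- c(v, sprintf("%d edge(s) not bordering exactly 2 faces",
                                        sum(cnt != 2L)))
  if (length(uniq) != length(ekey) || !all(sort(ekey) == uniq))
    v <- c(v, "edge table does not match face edges")

  ## vertex link connectivity: the faces around each vertex must form one fan
  if (!length(v)) {
    deg_f <- tabulate(c(faces), nv)
    deg_e <- tabulate(c(edges), nv)
    if (any(deg_f == 0L | deg_e == 0L)) v <- c(v, "isolated vertex")
    else if (any(deg_f != deg_e)) v <- c(v, "non-manifold vertex (open fan)")
    else {
      ## each face corner contributes a directed link edge frm -> nxt around
      ## its vertex; the link of a manifold vertex is a single cycle
      vert <- c(faces[, 1L], faces[, 2L], faces[, 3L])
      frm_all <- c(faces[, 2L], faces[, 3L], faces[, 1L])
      nxt_all <- c(faces[, 3L], faces[, 1L], faces[, 2L])
      ord <- order(vert)
      vert <- vert[ord]; frm_all <- frm_all[ord]; nxt_all <- nxt_all[ord]
      ends <- cumsum(deg_f)
      starts <- c(1L, ends[-nv] + 1L)
      for (vi in seq_len(nv)) {
        m <- deg_f[vi]
        if (m <= 2L) next
        sel <- starts[vi]:ends[vi]
        frm <- frm_all[sel]; nxt <- nxt_all[sel]
        reach <- 1L
        cur <- 1L
        for (s in seq_len(m - 1L)) {
          cur <- match(nxt[cur], frm)
          if (is.na(cur) || cur == 1L) break
          reach <- reach + 1L
        }
        if (reach != m) {
          v <- c(v, "non-manifold vertex (disconnected link)")
          break
        }
      }
    }
  }

  if (!length(v)) {
    chi <- nv - nrow(edges) + nrow(faces)
    if (chi != 2L) v <- c(v, sprintf("Euler characteristic %d != 2", chi))
  }
  if (strict && !length(v) && mesh_self_intersects(state))
    v <- c(v, "surface self-intersection between non-adjacent faces")
  list(valid = length(v) == 0L, violations = v)
}

## O(F^2) strict self-intersection: any edge of a face piercing a face it
## shares no vertex with (Moller-Trumbore segment/triangle test).
mesh_self_intersects <- function(state, tol = 1e-9) {
  faces <- state$faces; pos <- state$pos
  nf <- nrow(faces)
  seg_a <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  for (fi in seq_len(nf)) {
    tri <- faces[fi, ]
    v0 <- pos[tri[1L], ]; e1 <- pos[tri[2L], ] - v0; e2 <- pos[tri[3L], ] - v0
    share <- seg_a[, 1L] %in% tri | seg_a[, 2L] %in% tri
    segs <- seg_a[!share, , drop = FALSE]
    if (!nrow(segs)) next
    p <- pos[segs[, 1L], , drop = FALSE]
    d <- pos[segs[, 2L], , drop = FALSE] - p
    h1 <- d[, 2L] * e2[3L] - d[, 3L] * e2[2L]
    h2 <- d[, 3L] * e2[1L] - d[, 1L] * e2[3L]
    h3 <- d[, 1L] * e2[2L] - d[, 2L] * e2[1L]
    a <- e1[1L] * h1 + e1[2L] * h2 + e1[3L] * h3
    ok <- abs(a) > tol
    s1 <- p[, 1L] - v0[1L]; s2 <- p[, 2L] - v0[2L]; s3 <- p[, 3L] - v0[3L]
    u <- (s1 * h1 + s2 * h2 + s3 * h3) / a
    q1 <- s2 * e1[3L] - s3 * e1[2L]
    q2 <- s3 * e1[1L] - s1 * e1[3L]
    q3 <- s1 * e1[2L] - s2 * e1[1L]
    vv <- (d[, 1L] * q1 + d[, 2L] * q2 + d[, 3L] * q3) / a
    t <- (e2[1L] * q1 + e2[2L] * q2 + e2[3L] * q3) / a
    hit <- ok & u > tol & vv > tol & (u + vv) < 1 - tol & t > tol & t < 1 - tol
    if (any(hit)) return(TRUE)
  }
  FALSE
}

## Euclidean edge lengths (nm) of all edges.
edge_lengths <- function(state) {
  d <- state$pos[state$edges[, 1L], , drop = FALSE] -
    state$pos[state$edges[, 2L], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Nucleotide length of a mesh edge
#'
#' Quantises an edge's Euclidean length to base pairs via the 0.34 nm
#' B-form rise (round-half-to-even), and reports the scaffold contribution
#' `scaffold_passes * bp`.
#'
#' @param state a `design_state`.
#' @param edge integer edge index (row of `state$edges`) or a length-2
#'   vector of vertex indices.
#' @param spec [edge_type()] to use; defaults to the state's.
#' @return list with `bp_per_helix` and `scaffold_nt` (integers).
#' @export
edge_length_nt <- function(state, edge, spec = state$edge_type) {
  if (length(edge) == 2L) {
    key <- state$edges[, 1L] * (nrow(state$pos) + 1) + state$edges[, 2L]
    edge <- match(min(edge) * (nrow(state$pos) + 1) + max(edge), key)
  }
  if (is.na(edge) || edge < 1L || edge > nrow(state$edges))
    abort("edge not present in the design state", "schema_error")
  len <- edge_lengths(state)[edge]
  bp <- as.integer(round(len / BP_RISE_NM))
  if (bp < 1L)
    abort(sprintf("edge length %.4g nm rounds to zero base pairs", len),
          "zero_length_edge_error")
  list(bp_per_helix = bp, scaffold_nt = spec$scaffold_passes * bp)
}

## Base pairs per helix for every edge at once (no zero-length check).
edge_bp <- function(state) as.integer(round(edge_lengths(state) / BP_RISE_NM))

#' Estimated scaffold demand of a design
#'
#' Total scaffold nucleotides: for each edge, its per-helix base-pair count
#' (length / 0.34 nm, rounded) times the number of scaffold passes, summed
#' over edges, plus an optional per-vertex additive correction. This is the
#' estimate traced per iteration during annealing and compared against the
#' scaffold budget; it carries no vertex/staple overhead by default because
#' that accounting belongs to the downstream routing tool.
#'
#' @param state a `design_state`.
#' @param per_vertex_nt additive correction per mesh vertex (default 0).
#' @return integer nucleotide count.
#' @export
estimate_scaffold_nt <- function(state, per_vertex_nt = 0L) {
  as.integer(state$edge_type$scaffold_passes * sum(edge_bp(state)) +
               per_vertex_nt * nrow(state$pos))
}

#' Minimum distance between non-adjacent edges
#'
#' Smallest Euclidean segment-segment distance over all pairs of edges that
#' share no vertex; `Inf` when no such pair exists (e.g. a single triangle).
#' This is the quantity the repulsion cutoff constraint bounds from below so
#' that helix bundles are never packed closer than electrostatics allows.
#'
#' @param state a `design_state`.
#' @return distance in nm.
#' @export
min_nonadjacent_edge_distance <- function(state) {
  e <- state$edges
  ne <- nrow(e)
  if (ne < 2L) return(Inf)
  i <- rep.int(seq_len(ne - 1L), (ne - 1L):1L)
  j <- sequence((ne - 1L):1L) + i
  a <- e[i, , drop = FALSE]
  b <- e[j, , drop = FALSE]
  keep <- a[, 1L] != b[, 1L] & a[, 1L] != b[, 2L] &
    a[, 2L] != b[, 1L] & a[, 2L] != b[, 2L]
  if (!any(keep)) return(Inf)
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  min(segment_pair_distance(state$pos[a[, 1L], , drop = FALSE],
                            state$pos[a[, 2L], , drop = FALSE],
                            state$pos[b[, 1L], , drop = FALSE],
                            state$pos[b[, 2L], , drop = FALSE]))
}

## Vectorised closest distance between segments (p1,p2) and (q1,q2);
## all arguments n x 3 matrices. Standard clamped closest-point algorithm.
segment_pair_distance <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1
  d2 <- q2 - q1
  r <- p1 - q1
  a <- rowSums(d1 * d1)
  e <- rowSums(d2 * d2)
  f <- rowSums(d2 * r)
  cc <- rowSums(d1 * r)
  b <- rowSums(d1 * d2)
  denom <- a * e - b * b
  s <- numeric(length(a))
  ok <- denom > 1e-14
  s[ok] <- clamp(((b * f - cc * e)[ok]) / denom[ok], 0, 1)
  t <- (b * s + f) / pmax(e, 1e-14)
  tc <- clamp(t, 0, 1)
  re <- t != tc
  if (any(re))
    s[re] <- clamp(((b * tc - cc)[re]) / pmax(a[re], 1e-14), 0, 1)
  cp <- p1 + d1 * s - (q1 + d2 * tc)
  sqrt(rowSums(cp * cp))
}
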