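#' @title Graph-grammar rules
#'
#' @description The move set of the generative process. Each rule takes a
#' design state and returns a modified copy that is again a closed
#' triangulated manifold; preserved geometry is never moved or removed.
#' The canonical family is \{vertex extension (displacement quantised to
#' multiples of the 0.34 nm rise), edge flip, face subdivision, vertex
#' merge, bounding-box resize\} — the minimal closed set of local edits
#' that keeps every intermediate a triangulation while reaching arbitrary
#' triangulated genus-0 shapes.
#'
#' @name grammar
NULL

## Shared guard: rule outputs must be valid meshes.
assert_valid <- function(state, what) {
  rep_v <- validate_mesh(state)
  if (!rep_v$valid)
    abort(paste0(what, " produced an invalid mesh: ",
                 paste(rep_v$violations, collapse = "; ")),
          "mesh_invalid_error")
  state
}

#' Extend a vertex along a direction
#'
#' Displaces a non-preserved vertex by `k` multiples of the 0.34 nm
#' nucleotide rise along a unit direction. Quantising the displacement (not
#' each edge length, which would be geometrically overconstrained) keeps
#' design changes commensurate with whole-nucleotide edits while still
#' searching the space efficiently; the annealing ramp shrinks `k` late in
#' a run to fine-tune.
#'
#' @param state a `design_state`.
#' @param vertex vertex index.
#' @param direction 3D direction (normalised internally).
#' @param k non-negative integer number of 0.34 nm steps.
#' @return a new `design_state`.
#' @export
extend_vertex <- function(state, vertex, direction, k) {
  if (!is_count(k + 1)) abort("k must be a non-negative integer", "schema_error")
  if (state$v_preserved[vertex])
    abort("cannot move a preserved vertex", "preserved_geometry_error")
  if (k == 0) return(state)
  new <- state
  new$pos[vertex, ] <- state$pos[vertex, ] + k * BP_RISE_NM * unit3(direction)
  assert_valid(new, "extend_vertex")
}

#' Flip an interior edge
#'
#' Replaces the shared edge AB of triangles ABC and ABD by the opposite
#' diagonal CD, rotating the diagonal inside the quad. Vertex, edge and
#' face counts are unchanged; applying the flip twice restores the original
#' connectivity.
#'
#' @param state a `design_state`.
#' @param edge edge index or a length-2 vector of vertex indices.
#' @return a new `design_state`.
#' @export
edge_flip <- function(state, edge) {
  nv <- nrow(state$pos)
  if (length(edge) == 2L) {
    key <- state$edges[, 1L] * (nv + 1) + state$edges[, 2L]
    edge <- match(min(edge) * (nv + 1) + max(edge), key)
  }
  if (is.na(edge) || edge < 1L || edge > nrow(state$edges))
    abort("edge not present in the design state", "schema_error")
  if (state$e_preserved[edge])
    abort("cannot flip a preserved edge", "preserved_geometry_error")
  a <- state$edges[edge, 1L]; b <- state$edges[edge, 2L]
  faces <- state$faces
  inc <- which(rowSums(faces == a) + rowSums(faces == b) == 2L)
  if (length(inc) != 2L)
    abort("edge does not border exactly two faces", "flip_blocked_error")
  ## orient: f1 contains directed a->b, f2 contains b->a
  has_dir <- function(f, from, to) {
    any(f == from & c(f[-1L], f[1L]) == to)
  }
  f1 <- faces[inc[1L], ]; f2 <- faces[inc[2L], ]
  if (!has_dir(f1, a, b)) { tmp <- f1; f1 <- f2; f2 <- tmp }
  cc <- setdiff(f1, c(a, b))
  d <- setdiff(f2, c(a, b))
  key <- state$edges[, 1L] * (nv + 1) + state$edges[, 2L]
  if (!is.na(match(min(cc, d) * (nv + 1) + max(cc, d), key)))
    abort("flip blocked: opposite diagonal already an edge", "flip_blocked_error")
  ## degenerate result?
  p <- state$pos
  if (tri_area2(p[a, ], p[d, ], p[cc, ]) < 1e-9 ||
      tri_area2(p[b, ], p[cc, ], p[d, ]) < 1e-9)
    abort("flip blocked: degenerate resulting face", "flip_blocked_error")
  new <- state
  new$edges[edge, ] <- c(min(cc, d), max(cc, d))
  new$e_preserved[edge] <- FALSE
  first_has_ab <- has_dir(faces[inc[1L], ], a, b)
  which1 <- if (first_has_ab) inc[1L] else inc[2L]
  which2 <- if (first_has_ab) inc[2L] else inc[1L]
  new$faces[which1, ] <- c(a, d, cc)
  new$faces[which2, ] <- c(b, cc, d)
  assert_valid(new, "edge_flip")
}

#' Subdivide a face at its centroid
#'
#' Inserts a new (non-preserved) vertex at the centroid of a triangle and
#' replaces the triangle by three, keeping the mesh all-triangle and
#' preserving the Euler characteristic (V+1, E+3, F+2).
#'
#' @param state a `design_state`.
#' @param face face index (row of `state$faces`).
#' @return a new `design_state`.
#' @export
divide_face <- function(state, face) {
  if (face < 1L || face > nrow(state$faces))
    abort("face not present in the design state", "schema_error")
  tri <- state$faces[face, ]
  p <- colMeans(state$pos[tri, , drop = FALSE])
  for (r in state$excluded)
    if (region_contains(r, matrix(p, 1L)))
      abort("subdivision vertex would fall inside an excluded region",
            "spatial_constraint_error")
  new <- state
  new$pos <- rbind(state$pos, p, deparse.level = 0)
  dimnames(new$pos) <- NULL
  new$v_preserved <- c(state$v_preserved, FALSE)
  nvtx <- nrow(new$pos)
  new$faces[face, ] <- c(tri[1L], tri[2L], nvtx)
  new$faces <- rbind(new$faces,
                     c(tri[2L], tri[3L], nvtx),
                     c(tri[3L], tri[1L], nvtx))
  new$edges <- rbind(state$edges, cbind(tri, nvtx))
  new$e_preserved <- c(state$e_preserved, rep(FALSE, 3L))
  assert_valid(new, "divide_face")
}

#' Merge (remove) a vertex
#'
#' The inverse of [divide_face()]. A degree-3 vertex is removed and its
#' triangular hole closed with a single face. A higher-degree vertex is
#' collapsed along an incident edge onto a neighbouring `target` vertex;
#' the two faces shared with the target disappear and the remaining
#' incident geometry is reconnected. Any move that would touch preserved
#' geometry or break manifoldness is rejected.
#'
#' @param state a `design_state`.
#' @param vertex vertex index to remove.
#' @param target for vertices of degree > 3, the neighbour to collapse onto.
#' @return a new `design_state`.
#' @export
merge_vertex <- function(state, vertex, target = NULL) {
  if (state$v_preserved[vertex])
    abort("cannot remove a preserved vertex", "preserved_geometry_error")
  inc_e <- which(state$edges[, 1L] == vertex | state$edges[, 2L] == vertex)
  if (any(state$e_preserved[inc_e]))
    abort("cannot remove a vertex with preserved incident edges",
          "preserved_geometry_error")
  deg <- length(inc_e)
  faces <- state$faces
  inc_f <- which(faces[, 1L] == vertex | faces[, 2L] == vertex |
                   faces[, 3L] == vertex)
  new <- state
  if (deg == 3L && is.null(target)) {
    ## close the triangular hole with the link cycle, oriented consistently
    f <- faces[inc_f, , drop = FALSE]
    tri0 <- f[1L, ]
    i <- which(tri0 == vertex)
    x <- tri0[(i %% 3L) + 1L]
    y <- tri0[((i + 1L) %% 3L) + 1L]
    z <- setdiff(unique(c(f)), c(vertex, x, y))
    if (length(z) != 1L)
      abort("vertex neighbourhood is not a simple triangle fan",
            "mesh_invalid_error")
    new$faces <- rbind(faces[-inc_f, , drop = FALSE], c(x, y, z))
    new$edges <- state$edges[-inc_e, , drop = FALSE]
    new$e_preserved <- state$e_preserved[-inc_e]
  } else {
    if (is.null(target))
      abort("a collapse target is required for vertices of degree > 3",
            "schema_error")
    nbrs <- setdiff(unique(c(state$edges[inc_e, ])), vertex)
    if (!(target %in% nbrs))
      abort("collapse target must be a neighbour of the vertex", "schema_error")
    shared_f <- inc_f[rowSums(faces[inc_f, , drop = FALSE] == target) > 0L]
    if (length(shared_f) != 2L)
      abort("collapse edge does not border exactly two faces",
            "mesh_invalid_error")
    ## link condition: vertex and target may share only the two opposite
    ## corners of the collapsed edge, else the collapse pinches the surface
    opp <- setdiff(unique(c(faces[shared_f, , drop = FALSE])), c(vertex, target))
    t_e <- which(state$edges[, 1L] == target | state$edges[, 2L] == target)
    t_nbrs <- setdiff(unique(c(state$edges[t_e, ])), target)
    if (length(setdiff(intersect(nbrs, t_nbrs), opp)) > 0L)
      abort("collapse would create a non-manifold pinch", "mesh_invalid_error")
    keep_f <- faces[-shared_f, , drop = FALSE]
    keep_f[keep_f == vertex] <- target
    new$faces <- keep_f
    e <- state$edges
    e[e == vertex] <- target
    e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    drop <- e[, 1L] == e[, 2L] | duplicated(e)
    new$edges <- e[!drop, , drop = FALSE]
    new$e_preserved <- state$e_preserved[!drop]
  }
  ## drop the vertex and reindex
  new$pos <- new$pos[-vertex, , drop = FALSE]
  new$v_preserved <- new$v_preserved[-vertex]
  shift <- function(m) { m[m > vertex] <- m[m > vertex] - 1L; m }
  new$edges <- shift(new$edges)
  new$faces <- shift(new$faces)
  assert_valid(new, "merge_vertex")
}

#' Resize the bounding box
#'
#' Changes one box dimension (`a`, `b`, `c` in nm or `gamma` in degrees) by
#' `delta`. Used in multi-objective studies where the box itself is a
#' design variable. The mesh does not move; if any vertex falls outside
#' the resized box the move is rejected.
#'
#' @param state a `design_state`.
#' @param dimension one of `"a"`, `"b"`, `"c"`, `"gamma"`.
#' @param delta signed change (nm or degrees).
#' @param bounds list of length-2 ranges per dimension the result must stay
#'   inside; default `a`, `b`, `c` in \[10, 100\] nm and gamma in
#'   \[45, 135\] degrees.
#' @return a new `design_state`.
#' @export
resize_box <- function(state, dimension, delta, bounds = box_move_bounds()) {
  dimension <- match.arg(dimension, c("a", "b", "c", "gamma"))
  box <- state$box
  val <- box[[dimension]] + delta
  rng <- bounds[[dimension]]
  if (val < rng[1L] || val > rng[2L])
    abort(sprintf("resized %s=%.4g outside allowed range [%g, %g]",
                  dimension, val, rng[1L], rng[2L]),
          "spatial_constraint_error")
  box[[dimension]] <- val
  new <- state
  new$box <- bounding_box(box$a, box$b, box$c, box$gamma, box$origin)
  if (!all(box_contains(new$box, new$pos)))
    abort("a vertex would fall outside the resized bounding box",
          "spatial_constraint_error")
  new
}

#' Default bounds for bounding-box moves
#'
#' @return named list of length-2 numeric ranges for `a`, `b`, `c` (nm) and
#'   `gamma` (degrees).
#' @export
box_move_bounds <- function() {
  list(a = c(10, 100), b = c(10, 100), c = c(10, 100), gamma = c(45, 135))
}

#' Rule set for random grammar application
#'
#' @param rules character vector of enabled rule names among
#'   `"extend_vertex"`, `"edge_flip"`, `"divide_face"`, `"merge_vertex"`,
#'   `"resize_box"`.
#' @param weights positive selection weights, normalised at draw time;
#'   default equal.
#' @param k_min,k_max integer range for the extension multiple `k`.
#' @param allow_box_moves convenience switch adding/removing `"resize_box"`.
#' @param box_delta_nm,box_delta_deg half-ranges for box-dimension moves.
#' @param box_bounds see [resize_box()].
#' @return an object of class `rule_set`.
#' @export
rule_set <- function(rules = c("extend_vertex", "edge_flip", "divide_face",
                               "merge_vertex"),
                     weights = NULL,
                     k_min = 1L, k_max = 30L,
                     allow_box_moves = FALSE,
                     box_delta_nm = 2, box_delta_deg = 5,
                     box_bounds = box_move_bounds()) {
  known <- c("extend_vertex", "edge_flip", "divide_face", "merge_vertex",
             "resize_box")
  bad <- setdiff(rules, known)
  if (length(bad))
    abort(paste0("unknown grammar rule(s): ", paste(bad, collapse = ", ")),
          "schema_error")
  if (allow_box_moves && !("resize_box" %in% rules))
    rules <- c(rules, "resize_box")
  if (!allow_box_moves && "resize_box" %in% rules) allow_box_moves <- TRUE
  weights <- weights %||% rep(1, length(rules))
  if (length(weights) != length(rules) || any(weights <= 0))
    abort("weights must be positive, one per rule", "schema_error")
  if (!is_count(k_min) || !is_count(k_max) || k_min > k_max)
    abort("k_min/k_max must be positive integers with k_min <= k_max",
          "schema_error")
  structure(
    list(rules = rules, weights = weights / sum(weights),
         k_min = as.integer(k_min), k_max = as.integer(k_max),
         allow_box_moves = allow_box_moves,
         box_delta_nm = box_delta_nm, box_delta_deg = box_delta_deg,
         box_bounds = box_bounds),
    class = "rule_set"
  )
}

## Weighted draw of a rule name from a rule set.
draw_rule <- function(ruleset) {
  sample(ruleset$rules, 1L, prob = ruleset$weights)
}

## Uniform direction on the unit sphere.
runif_sphere <- function() {
  repeat {
    v <- stats::rnorm(3L)
    n <- vnorm(v)
    if (n > 1e-8) return(v / n)
  }
}

#' Apply a random grammar rule until a feasible candidate is sampled
#'
#' Draws rules (weighted) and random rule parameters until the resulting
#' candidate passes [is_feasible()], mirroring the generative step: rules
#' are "randomly selected and applied until a feasible solution is
#' sampled". Infeasible or inapplicable draws are retried; after
#' `max_retries` failures an error of class `exhausted_retries_error` is
#' raised so the optimizer can count a null move.
#'
#' @param state a feasible `design_state`.
#' @param ruleset a [rule_set()].
#' @param constraints a [constraint_set()].
#' @param max_retries attempts before giving up.
#' @param k_max_override optional ramped ceiling on the extension multiple.
#' @return list with `state` (the feasible candidate), `rule` (name) and
#'   `attempts`.
#' @export
apply_random_rule <- function(state, ruleset, constraints, max_retries = 100L,
                              k_max_override = NULL) {
  k_hi <- min(ruleset$k_max, k_max_override %||% ruleset$k_max)
  k_hi <- max(k_hi, ruleset$k_min)
  for (attempt in seq_len(max_retries)) {
    rule <- draw_rule(ruleset)
    cand <- tryCatch(
      switch(rule,
        extend_vertex = {
          free <- which(!state$v_preserved)
          if (!length(free)) abort("no movable vertex", "rule_inapplicable")
          vtx <- free[sample.int(length(free), 1L)]
          k <- sample(ruleset$k_min:k_hi, 1L)
          extend_vertex(state, vtx, runif_sphere(), k)
        },
        edge_flip = {
          free <- which(!state$e_preserved)
          if (!length(free)) abort("no flippable edge", "rule_inapplicable")
          edge_flip(state, free[sample.int(length(free), 1L)])
        },
        divide_face = divide_face(state, sample.int(nrow(state$faces), 1L)),
        merge_vertex = {
          free <- which(!state$v_preserved)
          if (!length(free)) abort("no removable vertex", "rule_inapplicable")
          vtx <- free[sample.int(length(free), 1L)]
          deg <- sum(state$edges == vtx)
          if (deg == 3L) merge_vertex(state, vtx)
          else {
            nbrs <- setdiff(unique(c(state$edges[state$edges[, 1L] == vtx |
                                                   state$edges[, 2L] == vtx, ])),
                            vtx)
            merge_vertex(state, vtx, target = nbrs[sample.int(length(nbrs), 1L)])
          }
        },
        resize_box = {
          dim <- sample(c("a", "b", "c", "gamma"), 1L)
          delta <- if (dim == "gamma")
            stats::runif(1L, -ruleset$box_delta_deg, ruleset$box_delta_deg)
          else stats::runif(1L, -ruleset$box_delta_nm, ruleset$box_delta_nm)
          resize_box(state, dim, delta, bounds = ruleset$box_bounds)
        }
      ),
      wireframegen_error = function(e) NULL,
      error = function(e) NULL
    )
    if (is.null(cand)) next
    if (feasible_quick(cand, constraints))
      return(list(state = cand, rule = rule, attempts = attempt))
  }
  abort(sprintf("no feasible candidate found in %d attempts", max_retries),
        "exhausted_retries_error")
}
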