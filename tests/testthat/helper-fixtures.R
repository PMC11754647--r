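# Shared fixtures and independent oracles. Fixtures are built in code; the
# oracles are deliberately naive (sampling, exhaustive pairwise filters) and
# never share code with the implementation paths they check.

## A regular tetrahedron with the given edge length, centred in a box.
regular_tetra_points <- function(edge = 10) {
  p <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  p * edge / (2 * sqrt(2))
}

tetra_state <- function(edge = 10, et = edge_type("2HB"), pad = 5) {
  pts <- regular_tetra_points(edge)
  pts <- sweep(pts, 2L, apply(pts, 2L, min)) + pad
  side <- max(pts) + pad
  initialize_design(pts, box = bounding_box(side, side, side),
                    edge_type = et)
}

cube_state <- function(side = 50, et = edge_type("2HB")) {
  initialize_design(fixture_cube_corners(side),
                    box = bounding_box(side, side, side), edge_type = et)
}

octa_state <- function(a = 50, b = 50, c = 50, gamma = 90,
                       et = edge_type("2HB")) {
  initialize_design(fixture_parallelepiped_midfaces(a, b, c, gamma),
                    box = bounding_box(a, b, c, gamma), edge_type = et)
}

## Random points on a sphere are in convex position, so their hull uses all
## of them: a convenient generator of random small closed meshes.
random_hull_state <- function(n = 8, radius = 15, et = edge_type("2HB"),
                              box_side = 60) {
  repeat {
    v <- matrix(stats::rnorm(3L * n), n, 3L)
    v <- v / sqrt(rowSums(v^2)) * radius
    pts <- sweep(v, 2L, rep(box_side / 2, 3L), "+")
    st <- tryCatch(
      initialize_design(pts, box = bounding_box(box_side, box_side, box_side),
                        edge_type = et),
      wireframegen_error = function(e) NULL)
    if (!is.null(st)) return(st)
  }
}

## Mark all vertices/edges of a state non-preserved so every grammar rule is
## applicable (tests that exercise moves on initial hull vertices).
unlock_state <- function(state) {
  state$v_preserved[] <- FALSE
  state$e_preserved[] <- FALSE
  state
}

## Independent segment-segment distance oracle: nested grid sampling with
## three refinement passes around the best cell.
oracle_segment_distance <- function(p1, p2, q1, q2, n = 60L, passes = 3L) {
  lo_s <- 0; hi_s <- 1; lo_t <- 0; hi_t <- 1
  best <- Inf
  for (pass in seq_len(passes)) {
    s <- seq(lo_s, hi_s, length.out = n)
    t <- seq(lo_t, hi_t, length.out = n)
    g <- expand.grid(s = s, t = t)
    a <- outer(g$s, p2 - p1) + matrix(p1, nrow(g), 3L, byrow = TRUE)
    b <- outer(g$t, q2 - q1) + matrix(q1, nrow(g), 3L, byrow = TRUE)
    d <- sqrt(rowSums((a - b)^2))
    k <- which.min(d)
    best <- min(best, d[k])
    hs <- (hi_s - lo_s) / (n - 1); ht <- (hi_t - lo_t) / (n - 1)
    lo_s <- max(0, g$s[k] - hs); hi_s <- min(1, g$s[k] + hs)
    lo_t <- max(0, g$t[k] - ht); hi_t <- min(1, g$t[k] + ht)
  }
  best
}

## Oracle for the minimum non-adjacent edge distance of a state.
oracle_min_nonadjacent <- function(state) {
  e <- state$edges
  best <- Inf
  ne <- nrow(e)
  for (i in seq_len(ne - 1L)) for (j in (i + 1L):ne) {
    if (length(intersect(e[i, ], e[j, ]))) next
    best <- min(best, oracle_segment_distance(
      state$pos[e[i, 1L], ], state$pos[e[i, 2L], ],
      state$pos[e[j, 1L], ], state$pos[e[j, 2L], ]))
  }
  best
}

## Exhaustive O(n^2) non-dominated filter over rows of a matrix
## (minimisation), the Pareto-archive oracle.
oracle_pareto_front <- function(m) {
  n <- nrow(m)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(m[j, ] <= m[i, ]) && any(m[j, ] < m[i, ])) { keep[i] <- FALSE; break }
    }
  }
  unique(m[keep, , drop = FALSE])
}

## A state of two disjoint segments (plus a dummy mesh-free structure) for
## raw segment-distance examples; bypasses mesh validity on purpose.
segment_pair_state <- function(p1, p2, q1, q2) {
  wireframegen:::new_design_state(
    pos = rbind(p1, p2, q1, q2),
    v_preserved = rep(FALSE, 4L),
    edges = rbind(c(1L, 2L), c(3L, 4L)),
    e_preserved = c(FALSE, FALSE),
    faces = matrix(integer(0), 0L, 3L),
    box = bounding_box(100, 100, 100, origin = c(-50, -50, -50)),
    edge_type = edge_type("1HB")
  )
}
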