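test_that("initialization triangulates preserved vertices as their convex hull", {
  tet <- tetra_state()
  expect_equal(nrow(tet$pos), 4L)
  expect_equal(nrow(tet$edges), 6L)
  expect_equal(nrow(tet$faces), 4L)
  expect_equal(nrow(tet$pos) - nrow(tet$edges) + nrow(tet$faces), 2L)
  expect_true(all(tet$v_preserved))
  expect_true(validate_mesh(tet)$valid)

  oct <- octa_state()
  expect_equal(nrow(oct$pos), 6L)
  expect_equal(nrow(oct$edges), 12L)
  expect_equal(nrow(oct$faces), 8L)
  expect_true(validate_mesh(oct)$valid)

  cube <- cube_state()
  expect_equal(nrow(cube$pos), 8L)
  expect_equal(nrow(cube$edges), 18L)
  expect_equal(nrow(cube$faces), 12L)
})

test_that("degenerate or conflicting preserved regions are rejected", {
  flat <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(10, 10, 0))
  expect_error(
    initialize_design(flat, box = bounding_box(20, 20, 20),
                      edge_type = edge_type("2HB")),
    class = "triangulation_error")

  pts <- regular_tetra_points(10) + 10
  expect_error(
    initialize_design(pts, box = bounding_box(5, 5, 5),
                      edge_type = edge_type("2HB")),
    class = "region_conflict_error")
  expect_error(
    initialize_design(pts, box = bounding_box(30, 30, 30),
                      excluded = list(excluded_region(c(9, 9, 9), c(16, 16, 16))),
                      edge_type = edge_type("2HB")),
    class = "region_conflict_error")

  # interior point cannot survive as a mesh vertex
  with_centre <- rbind(fixture_cube_corners(20), c(10, 10, 10))
  expect_error(
    initialize_design(with_centre, box = bounding_box(20, 20, 20),
                      edge_type = edge_type("2HB")),
    class = "triangulation_error")
})

test_that("preserved edges must be hull edges and keep their flags", {
  pts <- fixture_cube_corners(50)
  st <- initialize_design(
    pts, preserved_edges = list(rbind(c(0, 0, 0), c(50, 0, 0))),
    box = bounding_box(50, 50, 50), edge_type = edge_type("2HB"))
  i <- which(st$e_preserved)
  expect_length(i, 1L)
  expect_setequal(sort(st$edges[i, ]),
                  which(apply(st$pos, 1L, function(p)
                    all(p == c(0, 0, 0)) || all(p == c(50, 0, 0)))))

  # interior diagonal is not a hull edge
  expect_error(
    initialize_design(pts,
                      preserved_edges = list(rbind(c(0, 0, 0), c(50, 50, 50))),
                      box = bounding_box(50, 50, 50),
                      edge_type = edge_type("2HB")),
    class = "triangulation_error")
})

test_that("infeasible triangulated starts cannot begin the generative process", {
  expect_error(
    initialize_design(fixture_cube_corners(50),
                      box = bounding_box(50, 50, 50),
                      edge_type = edge_type("2HB"),
                      constraints = constraint_set(scaffold_budget = 500)),
    class = "infeasible_start_error")
})

test_that("validate_mesh flags open, non-manifold and degenerate meshes", {
  tet <- tetra_state()
  expect_true(validate_mesh(tet)$valid)

  open <- tet
  open$faces <- open$faces[-1L, , drop = FALSE]
  rep_open <- validate_mesh(open)
  expect_false(rep_open$valid)
  expect_true(any(grepl("not bordering exactly 2 faces", rep_open$violations)))

  # two tetrahedra glued at a single vertex: non-manifold
  p1 <- regular_tetra_points(10)
  apex <- p1[1L, ]
  p2 <- sweep(-regular_tetra_points(10), 2L, 2 * apex, "+")  # mirrored copy sharing apex
  pos <- rbind(p1, p2[-1L, ])
  f1 <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  f2 <- f1
  f2[f2 > 1] <- f2[f2 > 1] + 3L
  f2 <- f2[, c(1L, 3L, 2L)]  # mirrored copy: flip orientation
  glued <- wireframegen:::new_design_state(
    pos = pos, v_preserved = rep(FALSE, 7L),
    edges = wireframegen:::faces_to_edges(rbind(f1, f2)),
    e_preserved = rep(FALSE, 12L),
    faces = rbind(f1, f2),
    box = bounding_box(100, 100, 100, origin = c(-50, -50, -50)),
    edge_type = edge_type("2HB"))
  rep_glued <- validate_mesh(glued)
  expect_false(rep_glued$valid)
  expect_true(any(grepl("non-manifold|Euler", rep_glued$violations)))
})

test_that("edge lengths quantise to nucleotides through the 0.34 nm rise", {
  mk <- function(len, et) segment_pair_state(c(0, 0, 0), c(len, 0, 0),
                                             c(0, 5, 0), c(len, 5, 0)) |>
    (\(s) { s$edge_type <- et; s })()

  s <- mk(3.4, edge_type("2HB"))
  r <- edge_length_nt(s, 1L)
  expect_identical(r$bp_per_helix, 10L)
  expect_identical(r$scaffold_nt, 20L)

  s <- mk(0.34, edge_type("1HB"))
  expect_identical(edge_length_nt(s, 1L)$bp_per_helix, 1L)

  s <- mk(13.6, edge_type("6HB"))
  r <- edge_length_nt(s, 1L)
  expect_identical(r$bp_per_helix, 40L)
  expect_identical(r$scaffold_nt, 240L)

  s <- mk(0.1, edge_type("1HB"))
  expect_error(edge_length_nt(s, 1L), class = "zero_length_edge_error")
})

test_that("scaffold estimate sums per-edge contributions and scales linearly", {
  tet <- tetra_state(edge = 17)
  expect_identical(estimate_scaffold_nt(tet), 600L)  # 6 edges x 2 passes x 50 bp

  # permutation invariance over edge ordering
  perm <- tet
  ord <- rev(seq_len(nrow(perm$edges)))
  perm$edges <- perm$edges[ord, , drop = FALSE]
  perm$e_preserved <- perm$e_preserved[ord]
  expect_identical(estimate_scaffold_nt(perm), estimate_scaffold_nt(tet))

  # strictly increasing when edges are added
  div <- divide_face(unlock_state(tet), 1L)
  expect_gt(estimate_scaffold_nt(div), estimate_scaffold_nt(tet))

  # doubling coordinates doubles the estimate within per-edge rounding
  big <- tet
  big$pos <- tet$pos * 2
  big$box <- bounding_box(100, 100, 100)
  expect_lt(abs(estimate_scaffold_nt(big) - 2L * estimate_scaffold_nt(tet)),
            2L * nrow(tet$edges))

  # per-vertex correction is additive
  expect_identical(estimate_scaffold_nt(tet, per_vertex_nt = 10L),
                   estimate_scaffold_nt(tet) + 40L)
})

test_that("minimum non-adjacent edge distance matches geometry", {
  s <- segment_pair_state(c(0, 0, 0), c(1, 0, 0), c(0, 0, 2), c(1, 0, 2))
  expect_equal(min_nonadjacent_edge_distance(s), 2.0)

  crossing <- segment_pair_state(c(-1, 0, 0), c(1, 0, 0),
                                 c(0, -1, 0), c(0, 1, 0))
  expect_equal(min_nonadjacent_edge_distance(crossing), 0)

  tet <- tetra_state(edge = 1, pad = 2)
  expect_equal(min_nonadjacent_edge_distance(tet), 1 / sqrt(2),
               tolerance = 1e-9)

  single <- tetra_state()
  single$edges <- single$edges[1:2, , drop = FALSE]  # share a vertex
  expect_identical(min_nonadjacent_edge_distance(single), Inf)
})

test_that("edge-distance computation agrees with a sampling oracle on random meshes", {
  set.seed(42)
  for (i in 1:100) {
    st <- tryCatch(random_hull_state(n = 5, radius = 2, box_side = 10),
                   error = function(e) NULL)
    if (is.null(st)) next
    expect_equal(min_nonadjacent_edge_distance(st), oracle_min_nonadjacent(st),
                 tolerance = 1e-3)
  }
})
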