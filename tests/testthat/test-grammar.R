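test_that("vertex extension displaces by quantised multiples of the rise", {
  tet <- unlock_state(tetra_state())
  expect_identical(extend_vertex(tet, 1L, c(1, 0, 0), 0L), tet)

  moved <- extend_vertex(tet, 1L, c(1, 0, 0), 10L)
  expect_equal(moved$pos[1L, ] - tet$pos[1L, ], c(3.4, 0, 0))
  expect_true(validate_mesh(moved)$valid)
  # input state untouched (immutability)
  expect_equal(tet$pos, tetra_state()$pos)

  pres <- tetra_state()  # all vertices preserved
  expect_error(extend_vertex(pres, 1L, c(1, 0, 0), 5L),
               class = "preserved_geometry_error")
})

test_that("edge flip rotates the diagonal and is an involution", {
  oct <- unlock_state(octa_state())
  e <- 1L
  a <- oct$edges[e, 1L]; b <- oct$edges[e, 2L]
  flipped <- edge_flip(oct, e)
  expect_true(validate_mesh(flipped)$valid)
  expect_equal(dim(flipped$faces), dim(oct$faces))
  expect_equal(nrow(flipped$edges), nrow(oct$edges))
  # AB gone, CD present
  key <- function(s) sort(s$edges[, 1L] * 1000 + s$edges[, 2L])
  expect_false(any(flipped$edges[, 1L] == a & flipped$edges[, 2L] == b))

  back <- edge_flip(flipped, which(
    !(flipped$edges[, 1L] * 1000 + flipped$edges[, 2L]) %in%
      (oct$edges[, 1L] * 1000 + oct$edges[, 2L])))
  expect_equal(key(back), key(oct))
  expect_equal(sort(as.vector(back$faces)), sort(as.vector(oct$faces)))

  # tetrahedron: every flip target CD already exists
  tet <- unlock_state(tetra_state())
  expect_error(edge_flip(tet, 1L), class = "flip_blocked_error")

  pres <- octa_state()
  pres$e_preserved[1L] <- TRUE
  expect_error(edge_flip(pres, 1L), class = "preserved_geometry_error")
})

test_that("face subdivision adds a centroid vertex and keeps Euler characteristic", {
  tet <- tetra_state()
  div <- divide_face(tet, 1L)
  expect_equal(nrow(div$pos), nrow(tet$pos) + 1L)
  expect_equal(nrow(div$edges), nrow(tet$edges) + 3L)
  expect_equal(nrow(div$faces), nrow(tet$faces) + 2L)
  expect_equal(nrow(div$pos) - nrow(div$edges) + nrow(div$faces), 2L)
  expect_true(validate_mesh(div)$valid)

  tri <- tet$faces[1L, ]
  expect_equal(div$pos[nrow(div$pos), ],
               colMeans(tet$pos[tri, ]))
  expect_false(div$v_preserved[nrow(div$pos)])

  # a centroid falling into an excluded region rejects the move
  ctr <- colMeans(tet$pos[tet$faces[1L, ], ])
  tet_ex <- tet
  tet_ex$excluded <- list(excluded_region(ctr - 0.5, ctr + 0.5))
  expect_error(divide_face(tet_ex, 1L), class = "spatial_constraint_error")
})

test_that("vertex merge inverts subdivision and collapses higher degrees", {
  tet <- tetra_state()
  div <- divide_face(tet, 1L)
  merged <- merge_vertex(div, nrow(div$pos))
  expect_equal(merged$pos, tet$pos)
  expect_equal(sort(merged$edges[, 1L] * 100 + merged$edges[, 2L]),
               sort(tet$edges[, 1L] * 100 + tet$edges[, 2L]))
  expect_true(validate_mesh(merged)$valid)

  expect_error(merge_vertex(tet, 1L), class = "preserved_geometry_error")

  # degree-4 collapse on an octahedron
  oct <- unlock_state(octa_state())
  nbrs <- setdiff(unique(c(oct$edges[oct$edges[, 1L] == 1L |
                                       oct$edges[, 2L] == 1L, ])), 1L)
  col <- merge_vertex(oct, 1L, target = nbrs[1L])
  expect_equal(nrow(col$pos), nrow(oct$pos) - 1L)
  expect_true(validate_mesh(col)$valid)
})

test_that("box resizing recomputes volume and rejects stranded vertices", {
  cube <- cube_state()
  grown <- resize_box(cube, "a", 1)
  expect_equal(box_volume(grown$box), 51 * 50 * 50)

  # gamma shear: volume formula, on a mesh small enough to stay contained
  tet <- tetra_state(edge = 5, pad = 20)  # deep inside its box
  sheared <- resize_box(tet, "gamma", -30, bounds = box_move_bounds())
  expect_equal(box_volume(sheared$box),
               tet$box$a * tet$box$b * tet$box$c * sin(60 * pi / 180))
  expect_equal(box_volume(bounding_box(50, 50, 50, 60)),
               125000 * sin(60 * pi / 180))

  # shearing a fully-occupied cube strands its corners
  expect_error(resize_box(cube_state(30), "gamma", -30),
               class = "spatial_constraint_error")

  expect_error(resize_box(cube, "a", -10), class = "spatial_constraint_error")
  expect_error(resize_box(cube, "a", 1000), class = "spatial_constraint_error")
})

test_that("random rule application is seeded-deterministic and feasibility-gated", {
  cs <- constraint_set(repulsion_cutoff = 2.5)
  cube <- cube_state()
  rs <- rule_set()

  set.seed(7); r1 <- apply_random_rule(cube, rs, cs)
  set.seed(7); r2 <- apply_random_rule(cube, rs, cs)
  expect_identical(r1$rule, r2$rule)
  expect_identical(r1$state, r2$state)

  # an unsatisfiable budget exhausts the retries
  expect_error(
    apply_random_rule(cube, rs, constraint_set(scaffold_budget = 100),
                      max_retries = 20L),
    class = "exhausted_retries_error")
})

test_that("rule draws follow the configured weights", {
  rs <- rule_set(rules = c("extend_vertex", "edge_flip", "divide_face"),
                 weights = c(0.5, 0.3, 0.2))
  set.seed(11)
  draws <- replicate(10000, wireframegen:::draw_rule(rs))
  freq <- table(factor(draws, levels = rs$rules)) / 10000
  for (i in seq_along(rs$rules)) {
    p <- rs$weights[i]
    expect_lt(abs(freq[[i]] - p), 3 * sqrt(p * (1 - p) / 10000))
  }
})

test_that("fuzzed rule applications never break mesh invariants or preserved geometry", {
  set.seed(99)
  cs <- constraint_set(scaffold_budget = 20000)
  for (rep in 1:5) {
    st <- random_hull_state(n = 6, radius = 12)
    pres_pos <- st$pos[st$v_preserved, , drop = FALSE]
    for (i in 1:100) {
      r <- tryCatch(apply_random_rule(st, rule_set(), cs, max_retries = 30L),
                    exhausted_retries_error = function(e) NULL)
      if (is.null(r)) break
      st <- r$state
      expect_true(validate_mesh(st)$valid)
    }
    # preserved vertices still present at their original positions
    for (k in seq_len(nrow(pres_pos)))
      expect_true(any(rowSums(abs(sweep(st$pos, 2L, pres_pos[k, ]))) < 1e-9))
    expect_equal(sum(st$v_preserved), nrow(pres_pos))
  }
})
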