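test_that("porosity matches the cylindrical volume model exactly", {
  # one 10 nm edge in a 10x10x10 box
  s <- segment_pair_state(c(0, 0, 0), c(10, 0, 0), c(0, 5, 0), c(10, 5, 0))
  s$edges <- s$edges[1L, , drop = FALSE]
  s$e_preserved <- s$e_preserved[1L]
  s$box <- bounding_box(10, 10, 10)
  s$edge_type <- edge_type("2HB")  # 4 nm diameter
  expect_equal(porosity(s), 1000 / (pi * 4 * 10), tolerance = 1e-9)

  s$edge_type <- edge_type("6HB")  # 6 nm diameter
  expect_equal(porosity(s), 1000 / (pi * 9 * 10), tolerance = 1e-9)
  expect_lt(porosity(s), 1000 / (pi * 4 * 10))

  # V_DNA constructed equal to V_box -> exactly 1
  d <- sqrt(4 * 1000 / (pi * 10))
  s$edge_type <- edge_type("custom", helices_per_edge = 1L,
                           bundle_diameter = d)
  expect_equal(porosity(s), 1.0, tolerance = 1e-12)

  empty <- s
  empty$edges <- empty$edges[0L, , drop = FALSE]
  expect_error(porosity(empty), class = "zero_volume_error")
})

test_that("porosity orders bundle widths and decreases as edges are added", {
  oct <- octa_state()
  p1 <- porosity(oct, bundle_diameter = 2)
  p2 <- porosity(oct, bundle_diameter = 4)
  p6 <- porosity(oct, bundle_diameter = 6)
  expect_lt(p6, p2)
  expect_lt(p2, p1)

  div <- divide_face(oct, 1L)
  expect_lt(porosity(div), porosity(oct))
})

test_that("variation index is the population sd of mean-normalised lengths", {
  oct <- octa_state()  # all edges equal
  expect_equal(variation_index(oct), 0, tolerance = 1e-12)

  # lengths {1, 1, 3}: normalised {0.6, 0.6, 1.8}, sigma = sqrt(0.32)
  s <- wireframegen:::new_design_state(
    pos = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(1, 2, 0),
                c(0, 4, 0), c(3, 4, 0)),
    v_preserved = rep(FALSE, 6L),
    edges = rbind(c(1L, 2L), c(3L, 4L), c(5L, 6L)),
    e_preserved = rep(FALSE, 3L),
    faces = matrix(integer(0), 0L, 3L),
    box = bounding_box(10, 10, 10), edge_type = edge_type("1HB"))
  expect_equal(variation_index(s), sqrt(0.32), tolerance = 1e-9)

  # invariant under uniform scaling
  big <- s
  big$pos <- s$pos * 2.5
  expect_equal(variation_index(big), variation_index(s), tolerance = 1e-12)
})

test_that("scaffold usage is the relative deviation from the scaffold length", {
  tet <- tetra_state(edge = 17)  # 600 nt
  expect_equal(scaffold_usage(tet, L = 600), 0)
  expect_equal(scaffold_usage(tet, L = 300), 1.0)
  expect_equal(scaffold_usage(tet, L = 7249), abs(600 - 7249) / 7249,
               tolerance = 1e-12)

  # a design at 3624 nt against M13mp18
  st <- tetra_state(edge = 17)
  st$pos <- st$pos * (3624 / 600)  # scales bp per edge to 302
  st$box <- bounding_box(200, 200, 200)
  expect_equal(estimate_scaffold_nt(st), 3624L)
  expect_equal(scaffold_usage(st), abs(3624 - 7249) / 7249, tolerance = 1e-9)
  expect_equal(scaffold_usage(st), 0.5001, tolerance = 1e-4)
})

test_that("custom objectives register, negate for maximisation, and reject non-finite values", {
  on.exit(rm(list = ls(envir = wireframegen:::.objective_registry),
             envir = wireframegen:::.objective_registry), add = TRUE)

  spec <- register_custom_objective("edge_count", "minimize",
                                    function(s) nrow(s$edges))
  tet <- tetra_state()
  expect_equal(wireframegen:::objective_value(spec, tet), 6)
  expect_identical(get_objective("edge_count")$name, "edge_count")

  expect_error(register_custom_objective("edge_count", "minimize",
                                         function(s) 0),
               class = "duplicate_name_error")

  mx <- register_custom_objective("edge_count_max", "maximize",
                                  function(s) nrow(s$edges))
  expect_equal(wireframegen:::objective_energy(mx, tet), -6)
  expect_equal(wireframegen:::objective_value(mx, tet), 6)

  bad <- register_custom_objective("nan_obj", "minimize", function(s) NaN)
  expect_error(wireframegen:::objective_energy(bad, tet),
               class = "non_finite_objective_error")

  expect_error(get_objective("porosty"), class = "unknown_objective_error")
})
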