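test_that("Metropolis acceptance follows the exponential rule", {
  set.seed(1)
  expect_true(metropolis_accept(1.0, 2.0, 0.5))     # better: always
  expect_false(metropolis_accept(2.0, 1.0, 1e-12))  # worse at T -> 0+: never
  expect_error(metropolis_accept(NaN, 1, 1), class = "non_finite_energy_error")
  expect_error(metropolis_accept(1, 2, 0), class = "schema_error")

  # dE = 2T -> acceptance frequency exp(-2)
  set.seed(10)
  acc <- replicate(20000, metropolis_accept(3, 1, 1))
  p <- exp(-2)
  expect_lt(abs(mean(acc) - p), 3 * sqrt(p * (1 - p) / 20000))
})

test_that("geometric cooling and the extension ramp behave as scheduled", {
  sch <- annealing_schedule(t0 = 1, alpha = 0.95)
  temp <- 1
  for (i in 1:10) temp <- next_temperature(sch, temp)
  expect_equal(temp, 0.95^10, tolerance = 1e-12)
  expect_equal(next_temperature(annealing_schedule(t0 = 2, alpha = 1), 2), 2)

  rs <- rule_set(k_min = 1L, k_max = 30L)
  sch2 <- annealing_schedule(max_iter = 1000L, ramp_fraction = 0.3)
  expect_identical(wireframegen:::ramp_k_max(rs, sch2, 1L), 30L)
  expect_identical(wireframegen:::ramp_k_max(rs, sch2, 700L), 30L)
  expect_identical(wireframegen:::ramp_k_max(rs, sch2, 1000L), 1L)
  k <- vapply(1:1000, function(i) wireframegen:::ramp_k_max(rs, sch2, i),
              integer(1))
  expect_true(all(diff(k) <= 0L))
})

test_that("annealing at near-zero temperature is pure descent", {
  cube <- cube_state()
  cs <- constraint_set(repulsion_cutoff = 2.5)
  fit <- shape_anneal(cube, "porosity", cs,
                      schedule = annealing_schedule(t0 = 1e-9, alpha = 0.5,
                                                    max_iter = 300L),
                      seed = 2)
  acc_e <- fit$trace$candidate_energy[fit$trace$accepted]
  cur_e <- fit$trace$energy[fit$trace$accepted]
  expect_true(all(acc_e <= cur_e + 1e-12))
  # best-so-far series is monotone non-increasing
  best <- cummin(ifelse(fit$trace$accepted, fit$trace$candidate_energy,
                        fit$trace$energy))
  expect_true(all(diff(best) <= 1e-12))
})

test_that("a toy edge-count minimisation converges to the closed-mesh minimum", {
  spec <- objective_spec("n_edges", "minimize", function(s) nrow(s$edges))
  tet <- tetra_state(edge = 12)
  st <- divide_face(divide_face(tet, 1L), 2L)  # 12 edges
  fit <- shape_anneal(st, spec,
                      constraints = constraint_set(scaffold_budget = 50000,
                                                   min_edge_nt = 1L),
                      ruleset = rule_set(rules = c("divide_face", "merge_vertex")),
                      schedule = annealing_schedule(t0 = 0.5, alpha = 0.8,
                                                    max_iter = 400L),
                      seed = 4)
  expect_identical(nrow(fit$best_state$edges), 6L)  # a tetrahedron
  expect_equal(fit$best_value, 6)
})

test_that("runs are pure functions of (problem, seed)", {
  cube <- cube_state()
  cs <- constraint_set(repulsion_cutoff = 2.5)
  sch <- annealing_schedule(max_iter = 150L)
  f1 <- shape_anneal(cube, "porosity", cs, schedule = sch, seed = 42)
  f2 <- shape_anneal(cube, "porosity", cs, schedule = sch, seed = 42)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$best_state, f2$best_state)
  f3 <- shape_anneal(cube, "porosity", cs, schedule = sch, seed = 43)
  expect_false(identical(f1$trace, f3$trace))
})

test_that("worsening moves are accepted early and squeezed out as T cools", {
  cube <- cube_state()
  cs <- constraint_set(repulsion_cutoff = 2.5)
  fit <- shape_anneal(cube, "porosity", cs,
                      schedule = annealing_schedule(alpha = 0.7,
                                                    moves_per_stage = 100L,
                                                    max_iter = 1200L),
                      seed = 8)
  tr <- fit$trace
  worse <- !is.na(tr$candidate_energy) & tr$candidate_energy >= tr$energy
  early <- worse & tr$iteration <= 300
  late <- worse & tr$iteration > 900
  expect_gt(mean(tr$accepted[early]), mean(tr$accepted[late]))
  expect_gt(sum(tr$accepted[early]), 0)
})

test_that("an infeasible start refuses to anneal", {
  cube <- cube_state()
  expect_error(
    shape_anneal(cube, "porosity",
                 constraints = constraint_set(scaffold_budget = 100),
                 schedule = annealing_schedule(max_iter = 10L), seed = 1),
    class = "infeasible_start_error")
})
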