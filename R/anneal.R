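#' Annealing schedule
#'
#' Geometric cooling: the temperature is multiplied by `alpha` after every
#' stage of `moves_per_stage` proposals, starting from `t0`. When `t0` is
#' `NULL` it is auto-calibrated at run time so that roughly 80% of
#' objectively worse moves would be accepted over a 100-proposal random
#' walk from the initial state — hot enough to explore, cold enough to
#' converge within the budget. A ramp linearly shrinks the extension
#' multiple ceiling `k_max` down to `k_min` over the final
#' `ramp_fraction` of the run so late moves fine-tune the design.
#'
#' @param t0 initial temperature, or `NULL` for auto-calibration.
#' @param alpha cooling factor in (0, 1].
#' @param moves_per_stage proposals per temperature stage.
#' @param max_iter total proposal budget.
#' @param ramp_fraction final fraction of the run over which `k_max` decays
#'   to `k_min`.
#' @param stall_stages stop early after this many consecutive stages with
#'   no accepted move; `Inf` (default) always spends the full budget.
#' @return an object of class `annealing_schedule`.
#' @export
annealing_schedule <- function(t0 = NULL, alpha = 0.95, moves_per_stage = 50L,
                               max_iter = 20000L, ramp_fraction = 0.3,
                               stall_stages = Inf) {
  if (!is.null(t0) && (!is_scalar_num(t0) || t0 <= 0))
    abort("t0 must be positive (or NULL for auto-calibration)", "schema_error")
  if (!is_scalar_num(alpha) || alpha <= 0 || alpha > 1)
    abort("alpha must lie in (0, 1]", "schema_error")
  if (!is_count(moves_per_stage) || !is_count(max_iter))
    abort("moves_per_stage and max_iter must be positive integers", "schema_error")
  if (!is_scalar_num(ramp_fraction) || ramp_fraction < 0 || ramp_fraction > 1)
    abort("ramp_fraction must lie in [0, 1]", "schema_error")
  structure(
    list(t0 = t0, alpha = alpha, moves_per_stage = as.integer(moves_per_stage),
         max_iter = as.integer(max_iter), ramp_fraction = ramp_fraction,
         stall_stages = stall_stages),
    class = "annealing_schedule"
  )
}

#' Metropolis acceptance
#'
#' Under minimisation, a candidate with lower energy is always accepted;
#' otherwise it is accepted with probability `exp(-(e_new - e_old) / temp)`,
#' compared against a uniform draw in (0, 1).
#'
#' @param e_new,e_old candidate and current energies (finite).
#' @param temp temperature (> 0).
#' @return logical: accept the candidate?
#' @export
metropolis_accept <- function(e_new, e_old, temp) {
  if (!is_scalar_num(e_new) || !is_scalar_num(e_old))
    abort("energies must be finite", "non_finite_energy_error")
  if (!is_scalar_num(temp) || temp <= 0)
    abort("temperature must be positive", "schema_error")
  if (e_new < e_old) return(TRUE)
  stats::runif(1L) < exp(-(e_new - e_old) / temp)
}

#' Next temperature of a geometric schedule
#'
#' @param schedule an [annealing_schedule()].
#' @param temp current temperature.
#' @return `temp * alpha`.
#' @export
next_temperature <- function(schedule, temp) temp * schedule$alpha

## Ramped ceiling for the extension multiple at a given iteration.
ramp_k_max <- function(ruleset, schedule, iter) {
  start <- 1 - schedule$ramp_fraction
  frac <- iter / schedule$max_iter
  if (frac <= start || schedule$ramp_fraction == 0) return(ruleset$k_max)
  prog <- (frac - start) / schedule$ramp_fraction
  as.integer(max(ruleset$k_min,
                 round(ruleset$k_max + (ruleset$k_min - ruleset$k_max) * prog)))
}

## Auto-calibrate t0: random walk accepting every feasible proposal, then
## pick t0 so the mean worsening step would be accepted with probability
## `target`.
calibrate_t0 <- function(state, spec, ruleset, constraints, n = 100L,
                         target = 0.8, max_retries = 100L) {
  e_cur <- objective_energy(spec, state)
  deltas <- numeric(0)
  for (i in seq_len(n)) {
    cand <- tryCatch(
      apply_random_rule(state, ruleset, constraints, max_retries = max_retries),
      exhausted_retries_error = function(e) NULL
    )
    if (is.null(cand)) next
    e_new <- objective_energy(spec, cand$state)
    if (e_new > e_cur) deltas <- c(deltas, e_new - e_cur)
    state <- cand$state
    e_cur <- e_new
  }
  if (!length(deltas)) return(max(abs(e_cur), 1) * 0.1)
  mean(deltas) / (-log(target))
}

#' Single-objective shape annealing
#'
#' Evolves a feasible initial design by randomly applied grammar rules
#' under Metropolis acceptance with geometric cooling, returning the best
#' feasible design encountered together with the full per-proposal trace
#' (objective value, candidate value, temperature, accepted flag, rule
#' name and estimated scaffold nucleotides). Runs are pure functions of
#' `(problem, seed)`.
#'
#' @param state a feasible initial `design_state` (see
#'   [initialize_design()]).
#' @param objective an `objective_spec` (see [get_objective()]) or an
#'   objective name.
#' @param constraints a [constraint_set()].
#' @param ruleset a [rule_set()].
#' @param schedule an [annealing_schedule()].
#' @param seed integer RNG seed for a reproducible run, or `NULL` to use
#'   the current RNG state.
#' @param max_retries feasible-candidate retries per proposal before a null
#'   move is recorded.
#' @param trace_states also keep every accepted state (memory-heavy; used
#'   by tests asserting feasibility along trajectories).
#' @return an object of class `shape_anneal` with components `best_state`,
#'   `best_value` (raw objective at the best state), `final_state`,
#'   `trace` (data frame), `t0`, `objective`, `schedule` and
#'   `acceptance_rate`.
#' @examples
#' st <- initialize_design(fixture_cube_corners(50),
#'                         box = bounding_box(50, 50, 50),
#'                         edge_type = edge_type("2HB"))
#' fit <- shape_anneal(st, "porosity",
#'                     constraints = constraint_set(repulsion_cutoff = 2.5),
#'                     schedule = annealing_schedule(max_iter = 200),
#'                     seed = 1)
#' fit
#' @export
shape_anneal <- function(state, objective,
                         constraints = constraint_set(),
                         ruleset = rule_set(),
                         schedule = annealing_schedule(),
                         seed = NULL,
                         max_retries = 100L,
                         trace_states = FALSE) {
  if (is.character(objective)) objective <- get_objective(objective)
  if (!inherits(objective, "objective_spec"))
    abort("objective must be an objective_spec or a known name", "schema_error")
  if (!is.null(seed)) set.seed(seed)
  start_rep <- is_feasible(state, constraints)
  if (!start_rep$feasible)
    abort(paste0("initial state is infeasible: ",
                 paste(start_rep$violations$constraint, collapse = ", ")),
          "infeasible_start_error")

  temp <- schedule$t0 %||%
    calibrate_t0(state, objective, ruleset, constraints,
                 max_retries = max_retries)
  t0 <- temp
  n <- schedule$max_iter
  tr_energy <- tr_cand <- tr_temp <- numeric(n)
  tr_acc <- logical(n)
  tr_rule <- character(n)
  tr_nt <- integer(n)

  e_cur <- objective_energy(objective, state)
  best_state <- state
  best_e <- e_cur
  accepted_states <- if (trace_states) list(state) else NULL
  n_acc <- 0L
  stage_acc <- 0L
  stalled <- 0L
  it <- 0L

  while (it < n) {
    it <- it + 1L
    k_hi <- ramp_k_max(ruleset, schedule, it)
    cand <- tryCatch(
      apply_random_rule(state, ruleset, constraints,
                        max_retries = max_retries, k_max_override = k_hi),
      exhausted_retries_error = function(e) NULL
    )
    if (is.null(cand)) {
      tr_energy[it] <- e_cur; tr_cand[it] <- NA_real_
      tr_temp[it] <- temp; tr_acc[it] <- FALSE
      tr_rule[it] <- "none"; tr_nt[it] <- estimate_scaffold_nt(state)
    } else {
      e_new <- objective_energy(objective, cand$state)
      acc <- metropolis_accept(e_new, e_cur, temp)
      tr_energy[it] <- e_cur; tr_cand[it] <- e_new
      tr_temp[it] <- temp; tr_acc[it] <- acc
      tr_rule[it] <- cand$rule
      if (acc) {
        state <- cand$state
        e_cur <- e_new
        n_acc <- n_acc + 1L
        stage_acc <- stage_acc + 1L
        if (trace_states) accepted_states[[length(accepted_states) + 1L]] <- state
        if (e_cur < best_e) { best_e <- e_cur; best_state <- state }
      }
      tr_nt[it] <- estimate_scaffold_nt(state)
    }
    if (it %% schedule$moves_per_stage == 0L) {
      temp <- next_temperature(schedule, temp)
      stalled <- if (stage_acc == 0L) stalled + 1L else 0L
      stage_acc <- 0L
      if (stalled >= schedule$stall_stages) break
    }
  }

  keep <- seq_len(it)
  trace <- data.frame(
    iteration = keep, energy = tr_energy[keep],
    candidate_energy = tr_cand[keep], temperature = tr_temp[keep],
    accepted = tr_acc[keep], rule = tr_rule[keep],
    scaffold_nt = tr_nt[keep]
  )
  best_value <- objective_value(objective, best_state)
  structure(
    list(best_state = best_state, best_value = best_value,
         best_energy = best_e, final_state = state, trace = trace,
         t0 = t0, objective = objective, schedule = schedule,
         constraints = constraints, ruleset = ruleset, seed = seed,
         acceptance_rate = n_acc / it,
         accepted_states = accepted_states),
    class = "shape_anneal"
  )
}

#' @export
print.shape_anneal <- function(x, ...) {
  cat(sprintf("shape annealing (%s %s): %d proposals, %.1f%% accepted\n",
              x$objective$direction, x$objective$name, nrow(x$trace),
              100 * x$acceptance_rate))
  cat(sprintf("  best %s: %.6g; best design V=%d E=%d F=%d, scaffold %d nt\n",
              x$objective$name, x$best_value, nrow(x$best_state$pos),
              nrow(x$best_state$edges), nrow(x$best_state$faces),
              estimate_scaffold_nt(x$best_state)))
  invisible(x)
}

#' @export
summary.shape_anneal <- function(object, ...) {
  tr <- object$trace
  worse <- tr$accepted & !is.na(tr$candidate_energy) &
    tr$candidate_energy >= tr$energy
  out <- list(
    objective = object$objective$name,
    direction = object$objective$direction,
    proposals = nrow(tr),
    accepted = sum(tr$accepted),
    accepted_worse = sum(worse),
    null_moves = sum(tr$rule == "none"),
    t0 = object$t0,
    final_temperature = tr$temperature[nrow(tr)],
    best_value = object$best_value,
    best_scaffold_nt = estimate_scaffold_nt(object$best_state),
    rule_counts = table(tr$rule[tr$accepted])
  )
  class(out) <- "summary.shape_anneal"
  out
}

#' @export
print.summary.shape_anneal <- function(x, ...) {
  cat(sprintf("shape annealing summary (%s %s)\n", x$direction, x$objective))
  cat(sprintf("  proposals: %d, accepted: %d (of which worse: %d), null moves: %d\n",
              x$proposals, x$accepted, x$accepted_worse, x$null_moves))
  cat(sprintf("  T0 = %.4g -> final T = %.4g\n", x$t0, x$final_temperature))
  cat(sprintf("  best %s = %.6g, scaffold estimate %d nt\n",
              x$objective, x$best_value, x$best_scaffold_nt))
  cat("  accepted rules:\n")
  print(x$rule_counts)
  invisible(x)
}

#' Plot a shape-annealing trace
#'
#' Two stacked panels: the objective value of the current design per
#' iteration (top) and the estimated scaffold length (bottom), the
#' standard convergence view of a run.
#'
#' @param x a `shape_anneal` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.shape_anneal <- function(x, ...) {
  tr <- x$trace
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$iteration, tr$energy, type = "l",
                 xlab = "iteration", ylab = x$objective$name, ...)
  graphics::abline(h = x$best_energy, lty = 3)
  graphics::plot(tr$iteration, tr$scaffold_nt, type = "l",
                 xlab = "iteration", ylab = "estimated scaffold (nt)", ...)
  graphics::abline(h = x$constraints$scaffold_budget, lty = 2)
  invisible(x)
}

#' Residuals of an annealing run
#'
#' Defined as the per-iteration gap between the current objective value and
#' the converged best value — the transient the optimizer still has to
#' burn off at each iteration.
#'
#' @param object a `shape_anneal` object.
#' @param ... unused.
#' @export
residuals.shape_anneal <- function(object, ...) {
  object$trace$energy - object$best_energy
}
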