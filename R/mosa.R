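#' Pareto dominance (minimisation)
#'
#' `u` dominates `v` iff `u <= v` in every component and `u < v` in at
#' least one. Equal vectors do not dominate each other.
#'
#' @param u,v numeric objective vectors of equal length.
#' @return logical flag.
#' @export
dominates <- function(u, v) {
  if (length(u) != length(v))
    abort("objective vectors must have the same arity", "arity_mismatch_error")
  all(u <= v) && any(u < v)
}

#' Create an empty Pareto archive
#'
#' The archive holds mutually non-dominated feasible designs together with
#' their objective vectors (all mapped to minimisation). One member is kept
#' per distinct objective vector.
#'
#' @param n_objectives arity of the objective vectors.
#' @return an object of class `pareto_archive`.
#' @export
pareto_archive <- function(n_objectives) {
  structure(
    list(states = list(),
         values = matrix(numeric(0), 0L, n_objectives)),
    class = "pareto_archive"
  )
}

#' Update a Pareto archive with a candidate
#'
#' Inserts the candidate iff no member dominates it; members dominated by
#' the candidate are removed. A candidate whose objective vector duplicates
#' an existing member (within `tol`) is not re-inserted, so archive size
#' counts unique solutions.
#'
#' @param archive a [pareto_archive()].
#' @param state the candidate `design_state` (may be `NULL` for pure
#'   objective-space streams, e.g. in tests).
#' @param values numeric objective vector of the candidate (minimisation).
#' @param tol equality tolerance for duplicate vectors.
#' @return the updated archive.
#' @export
update_archive <- function(archive, state, values, tol = 1e-12) {
  if (length(values) != ncol(archive$values))
    abort("objective vector arity does not match the archive",
          "arity_mismatch_error")
  m <- nrow(archive$values)
  if (m > 0L) {
    diff_lo <- archive$values <= rep(values + tol, each = m)
    diff_hi <- archive$values >= rep(values - tol, each = m)
    le_all <- rowSums(diff_lo) == length(values)
    eq_all <- rowSums(diff_lo & diff_hi) == length(values)
    if (any(eq_all) || any(le_all & !eq_all)) return(archive)
    dominated <- rowSums(archive$values >= rep(values, each = m)) ==
      length(values) &
      rowSums(archive$values > rep(values, each = m)) > 0L
    if (any(dominated)) {
      archive$states <- archive$states[!dominated]
      archive$values <- archive$values[!dominated, , drop = FALSE]
    }
  }
  archive$states[[length(archive$states) + 1L]] <- state
  archive$values <- rbind(archive$values, values)
  rownames(archive$values) <- NULL
  archive
}

archive_dominates_candidate <- function(archive, values) {
  m <- nrow(archive$values)
  if (m == 0L) return(FALSE)
  le <- rowSums(archive$values <= rep(values, each = m)) == length(values)
  lt <- rowSums(archive$values < rep(values, each = m)) > 0L
  any(le & lt)
}

#' @export
print.pareto_archive <- function(x, ...) {
  cat(sprintf("Pareto archive: %d non-dominated design(s), %d objective(s)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Multi-objective shape annealing
#'
#' Evolves a feasible design under 2-3 competing objectives, maintaining a
#' Pareto archive of mutually non-dominated feasible solutions. A
#' candidate is accepted outright when it is dominated neither by the
#' current state nor by the archive; otherwise it is accepted with
#' probability `prod_i exp(-max(0, dE_i) / T_i)` under per-objective
#' temperatures cooled on a shared geometric schedule. Every `base_return`
#' stages the current state returns to a uniformly drawn archive member to
#' spread coverage along the front.
#'
#' @param state a feasible initial `design_state`.
#' @param objectives list of 2-3 `objective_spec`s (or names). More than 3
#'   raises an `objective_count_error` unless `allow_many = TRUE` (the
#'   algorithm has only been validated with two or three objectives).
#' @param constraints a [constraint_set()].
#' @param ruleset a [rule_set()]; enable box moves to let the bounding box
#'   itself vary.
#' @param schedule an [annealing_schedule()].
#' @param seed RNG seed, or `NULL`.
#' @param base_return archive return-to-base period in stages; `Inf`
#'   disables.
#' @param normalize min-max normalise objective deltas against running
#'   extrema before the acceptance rule (useful when objective scales
#'   differ wildly).
#' @param allow_many override the 2-3 objective limit (with a warning).
#' @param max_retries as in [shape_anneal()].
#' @param trace_states keep accepted states (tests).
#' @return an object of class `mosa` with components `archive`, `trace`,
#'   `objectives`, `t0` (per-objective) and `final_state`.
#' @export
run_mosa <- function(state, objectives,
                     constraints = constraint_set(),
                     ruleset = rule_set(allow_box_moves = TRUE),
                     schedule = annealing_schedule(),
                     seed = NULL,
                     base_return = 5L,
                     normalize = FALSE,
                     allow_many = FALSE,
                     max_retries = 100L,
                     trace_states = FALSE) {
  objectives <- lapply(objectives, function(o)
    if (is.character(o)) get_objective(o) else o)
  for (o in objectives)
    if (!inherits(o, "objective_spec"))
      abort("objectives must be objective_specs or known names", "schema_error")
  k <- length(objectives)
  if (k < 2L)
    abort("multi-objective shape annealing needs at least 2 objectives",
          "objective_count_error")
  if (k > 3L) {
    if (!allow_many)
      abort("multi-objective shape annealing has only been validated with two or three objectives; set allow_many = TRUE to override",
            "objective_count_error")
    warning("running with more than 3 objectives; the acceptance rule is unvalidated in this regime")
  }
  if (!is.null(seed)) set.seed(seed)
  start_rep <- is_feasible(state, constraints)
  if (!start_rep$feasible)
    abort(paste0("initial state is infeasible: ",
                 paste(start_rep$violations$constraint, collapse = ", ")),
          "infeasible_start_error")

  eval_vec <- function(s) vapply(objectives, objective_energy, numeric(1L),
                                 state = s)
  e_cur <- eval_vec(state)
  temps <- vapply(objectives, function(o)
    schedule$t0 %||% calibrate_t0(state, o, ruleset, constraints,
                                  max_retries = max_retries),
    numeric(1L))
  t0 <- temps
  lo <- e_cur; hi <- e_cur   # running extrema for optional normalisation

  archive <- pareto_archive(k)
  archive <- update_archive(archive, state, e_cur)

  n <- schedule$max_iter
  tr_acc <- logical(n)
  tr_rule <- character(n)
  tr_nt <- integer(n)
  tr_arch <- integer(n)
  tr_e <- matrix(NA_real_, n, k)
  tr_cand <- matrix(NA_real_, n, k)
  accepted_states <- if (trace_states) list(state) else NULL

  it <- 0L
  stage <- 0L
  while (it < n) {
    it <- it + 1L
    k_hi <- ramp_k_max(ruleset, schedule, it)
    cand <- tryCatch(
      apply_random_rule(state, ruleset, constraints,
                        max_retries = max_retries, k_max_override = k_hi),
      exhausted_retries_error = function(e) NULL
    )
    if (is.null(cand)) {
      tr_rule[it] <- "none"
      tr_e[it, ] <- e_cur
      tr_nt[it] <- estimate_scaffold_nt(state)
      tr_arch[it] <- nrow(archive$values)
      next
    }
    e_new <- eval_vec(cand$state)
    lo <- pmin(lo, e_new); hi <- pmax(hi, e_new)
    acc <- if (!dominates(e_cur, e_new) &&
               !archive_dominates_candidate(archive, e_new)) TRUE
    else {
      d <- e_new - e_cur
      if (normalize) d <- d / pmax(hi - lo, 1e-12)
      p <- prod(exp(-pmax(0, d) / temps))
      stats::runif(1L) < p
    }
    archive <- update_archive(archive, cand$state, e_new)
    tr_e[it, ] <- e_cur
    tr_cand[it, ] <- e_new
    tr_acc[it] <- acc
    tr_rule[it] <- cand$rule
    if (acc) {
      state <- cand$state
      e_cur <- e_new
      if (trace_states) accepted_states[[length(accepted_states) + 1L]] <- state
    }
    tr_nt[it] <- estimate_scaffold_nt(state)
    tr_arch[it] <- nrow(archive$values)
    if (it %% schedule$moves_per_stage == 0L) {
      temps <- temps * schedule$alpha
      stage <- stage + 1L
      if (is.finite(base_return) && stage %% base_return == 0L &&
          nrow(archive$values) > 0L) {
        pick <- sample.int(nrow(archive$values), 1L)
        if (!is.null(archive$states[[pick]])) {
          state <- archive$states[[pick]]
          e_cur <- archive$values[pick, ]
        }
      }
    }
  }

  trace <- data.frame(iteration = seq_len(n), accepted = tr_acc,
                      rule = tr_rule, scaffold_nt = tr_nt,
                      archive_size = tr_arch)
  for (j in seq_len(k)) {
    trace[[paste0("energy_", objectives[[j]]$name)]] <- tr_e[, j]
    trace[[paste0("candidate_", objectives[[j]]$name)]] <- tr_cand[, j]
  }
  structure(
    list(archive = archive, trace = trace, objectives = objectives,
         t0 = t0, final_state = state, constraints = constraints,
         ruleset = ruleset, schedule = schedule, seed = seed,
         accepted_states = accepted_states),
    class = "mosa"
  )
}

#' Objective vectors of the archive, on the user scale
#'
#' Maximised objectives are negated back to their natural sign.
#'
#' @param x a `mosa` object.
#' @return numeric matrix, one row per archive member, named columns.
#' @export
archive_values <- function(x) {
  v <- x$archive$values
  for (j in seq_along(x$objectives))
    if (x$objectives[[j]]$direction == "maximize") v[, j] <- -v[, j]
  colnames(v) <- vapply(x$objectives, function(o) o$name, character(1L))
  v
}

#' @export
print.mosa <- function(x, ...) {
  nm <- vapply(x$objectives, function(o) o$name, character(1L))
  cat(sprintf("multi-objective shape annealing (%s): %d proposals\n",
              paste(nm, collapse = " vs "), nrow(x$trace)))
  cat(sprintf("  Pareto archive: %d unique non-dominated design(s)\n",
              nrow(x$archive$values)))
  invisible(x)
}

#' @export
summary.mosa <- function(object, ...) {
  v <- archive_values(object)
  out <- list(
    objectives = colnames(v),
    proposals = nrow(object$trace),
    accepted = sum(object$trace$accepted),
    archive_size = nrow(v),
    ranges = apply(v, 2L, range),
    t0 = object$t0
  )
  class(out) <- "summary.mosa"
  out
}

#' @export
print.summary.mosa <- function(x, ...) {
  cat(sprintf("MOSA summary (%s)\n", paste(x$objectives, collapse = " vs ")))
  cat(sprintf("  proposals: %d, accepted: %d, archive: %d designs\n",
              x$proposals, x$accepted, x$archive_size))
  cat("  objective ranges across the archive:\n")
  print(x$ranges)
  invisible(x)
}

#' Plot a Pareto front
#'
#' Scatter of the archive in objective space (first two objectives).
#'
#' @param x a `mosa` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mosa <- function(x, ...) {
  v <- archive_values(x)
  graphics::plot(v[, 1L], v[, 2L], xlab = colnames(v)[1L],
                 ylab = colnames(v)[2L], pch = 19, ...)
  ord <- order(v[, 1L])
  graphics::lines(v[ord, 1L], v[ord, 2L], lty = 3)
  invisible(x)
}
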