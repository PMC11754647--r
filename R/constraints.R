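#' Constraint set for design feasibility
#'
#' Bundles the feasibility checks every generated solution must satisfy:
#'
#' * topological — the estimated scaffold demand must not exceed the
#'   scaffold budget `scaffold_budget` (default: the 7249 nt M13mp18
#'   scaffold), and every edge must be at least `min_edge_nt` base pairs
#'   per helix so a downstream routing algorithm accepts it;
#' * spatial (Boolean) — every vertex inside the bounding box, and no edge
#'   passing through an excluded region;
#' * repulsion — no two edges sharing no vertex closer than
#'   `repulsion_cutoff` nm (a distance-threshold stand-in for the linear
#'   repulsive force between negatively charged helix bundles);
#' * custom — named user predicates on the full design state.
#'
#' @param scaffold_budget scaffold length budget in nucleotides.
#' @param min_edge_nt minimum base pairs per helix per edge; `NULL` defers
#'   to the state's [edge_type()].
#' @param repulsion_cutoff minimum allowed nm between non-adjacent edges,
#'   or `NULL` to disable.
#' @param excluded extra [excluded_region()] objects checked in addition to
#'   the state's own.
#' @param custom named list of predicates `function(state) TRUE/FALSE`.
#' @return an object of class `constraint_set`.
#' @examples
#' cs <- constraint_set(scaffold_budget = 7249, repulsion_cutoff = 2.5)
#' @export
constraint_set <- function(scaffold_budget = M13MP18_NT,
                           min_edge_nt = NULL,
                           repulsion_cutoff = NULL,
                           excluded = list(),
                           custom = list()) {
  if (!is_scalar_num(scaffold_budget) || scaffold_budget <= 0)
    abort("scaffold_budget must be a positive nucleotide count", "schema_error")
  if (!is.null(min_edge_nt) && !is_count(min_edge_nt))
    abort("min_edge_nt must be a positive integer", "schema_error")
  if (!is.null(repulsion_cutoff) &&
      (!is_scalar_num(repulsion_cutoff) || repulsion_cutoff < 0))
    abort("repulsion_cutoff must be a non-negative length in nm", "schema_error")
  if (length(custom) && (is.null(names(custom)) || any(names(custom) == "")))
    abort("custom constraints must be a named list of predicates", "schema_error")
  for (f in custom) if (!is.function(f))
    abort("custom constraints must be functions of the design state", "schema_error")
  structure(
    list(scaffold_budget = scaffold_budget, min_edge_nt = min_edge_nt,
         repulsion_cutoff = repulsion_cutoff, excluded = excluded,
         custom = custom),
    class = "constraint_set"
  )
}

feasibility_report <- function(violations = NULL) {
  if (is.null(violations))
    violations <- data.frame(constraint = character(0), value = numeric(0),
                             bound = numeric(0))
  structure(list(feasible = nrow(violations) == 0L, violations = violations),
            class = "feasibility_report")
}

#' @export
print.feasibility_report <- function(x, ...) {
  if (x$feasible) cat("feasible: no constraint violations\n")
  else {
    cat(sprintf("infeasible: %d violation(s)\n", nrow(x$violations)))
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}

viol_row <- function(constraint, value, bound) {
  data.frame(constraint = constraint, value = value, bound = bound)
}

#' Topological constraints
#'
#' Scaffold budget and minimum edge length, the "equality-style" mesh
#' bookkeeping a routing algorithm requires.
#'
#' @param state a `design_state`.
#' @param cs a [constraint_set()].
#' @return a `feasibility_report`.
#' @export
check_topological <- function(state, cs) {
  v <- NULL
  nt <- estimate_scaffold_nt(state)
  if (nt > cs$scaffold_budget)
    v <- rbind(v, viol_row("scaffold_length", nt, cs$scaffold_budget))
  min_bp <- cs$min_edge_nt %||% state$edge_type$min_edge_nt
  bp <- edge_bp(state)
  if (any(bp < min_bp))
    v <- rbind(v, viol_row("min_edge", min(bp), min_bp))
  feasibility_report(v)
}

#' Spatial (Boolean) constraints
#'
#' Containment of every vertex in the bounding box and emptiness of all
#' excluded regions (no vertex inside, no edge segment crossing the
#' interior; crossings are found by exact slab clipping of the segment
#' against the axis-aligned box).
#'
#' @inheritParams check_topological
#' @return a `feasibility_report`.
#' @export
check_spatial <- function(state, cs = NULL) {
  v <- NULL
  outside <- !box_contains(state$box, state$pos)
  if (any(outside))
    v <- rbind(v, viol_row("bounding_box", sum(outside), 0))
  regions <- c(state$excluded, if (!is.null(cs)) cs$excluded)
  if (length(regions) && nrow(state$edges)) {
    p <- state$pos[state$edges[, 1L], , drop = FALSE]
    q <- state$pos[state$edges[, 2L], , drop = FALSE]
    for (r in regions) {
      n_bad <- sum(region_contains(r, state$pos)) +
        sum(segment_crosses_region(r, p, q))
      if (n_bad > 0L)
        v <- rbind(v, viol_row("excluded_region", n_bad, 0))
    }
  }
  feasibility_report(v)
}

#' Inter-edge repulsion constraint
#'
#' @param state a `design_state`.
#' @param cutoff minimum allowed distance (nm) between edges sharing no
#'   vertex.
#' @return a `feasibility_report`.
#' @export
check_repulsion <- function(state, cutoff) {
  d <- min_nonadjacent_edge_distance(state)
  if (d < cutoff) feasibility_report(viol_row("repulsion", d, cutoff))
  else feasibility_report()
}

#' Full feasibility check
#'
#' Evaluates topological, spatial, repulsion and custom constraints in that
#' order without short-circuiting, so the report lists every violation. A
#' custom predicate that throws is recorded as a `custom_error` violation
#' (the state counts as infeasible) with the error attached as a warning.
#'
#' @inheritParams check_topological
#' @return a `feasibility_report`.
#' @export
is_feasible <- function(state, cs) {
  v <- NULL
  r <- check_topological(state, cs); v <- rbind(v, r$violations)
  r <- check_spatial(state, cs); v <- rbind(v, r$violations)
  if (!is.null(cs$repulsion_cutoff)) {
    r <- check_repulsion(state, cs$repulsion_cutoff)
    v <- rbind(v, r$violations)
  }
  for (nm in names(cs$custom)) {
    ok <- tryCatch(isTRUE(cs$custom[[nm]](state)), error = function(e) {
      warning(structure(
        class = c("custom_constraint_error", "warning", "condition"),
        list(message = sprintf("custom constraint '%s' raised: %s",
                               nm, conditionMessage(e)),
             call = NULL)))
      NA
    })
    if (is.na(ok)) v <- rbind(v, viol_row(paste0(nm, ":custom_error"), NA, NA))
    else if (!ok) v <- rbind(v, viol_row(nm, 0, 1))
  }
  feasibility_report(v)
}

## Fast boolean version of is_feasible used in the optimizer inner loop:
## same conjunction of checks, early exits, no report allocation.
feasible_quick <- function(state, cs) {
  min_bp <- cs$min_edge_nt %||% state$edge_type$min_edge_nt
  bp <- edge_bp(state)
  if (any(bp < min_bp)) return(FALSE)
  if (state$edge_type$scaffold_passes * sum(bp) > cs$scaffold_budget)
    return(FALSE)
  if (!all(box_contains(state$box, state$pos))) return(FALSE)
  regions <- c(state$excluded, cs$excluded)
  if (length(regions)) {
    p <- state$pos[state$edges[, 1L], , drop = FALSE]
    q <- state$pos[state$edges[, 2L], , drop = FALSE]
    for (r in regions) {
      if (any(region_contains(r, state$pos))) return(FALSE)
      if (any(segment_crosses_region(r, p, q))) return(FALSE)
    }
  }
  if (!is.null(cs$repulsion_cutoff) &&
      min_nonadjacent_edge_distance(state) < cs$repulsion_cutoff)
    return(FALSE)
  for (f in cs$custom)
    if (!tryCatch(isTRUE(f(state)), error = function(e) FALSE)) return(FALSE)
  TRUE
}
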