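#' @title Objective (evaluation) functions
#'
#' @description An objective maps a design state to a finite scalar with a
#' declared optimisation direction. Three built-ins cover the design goals
#' of the framework — utility ([porosity()]), uniformity
#' ([variation_index()]) and manufacturability ([scaffold_usage()]) — and
#' any user function of the design state can be registered alongside them.
#' Internally everything is minimised; maximisation is handled by negating
#' the value before the Metropolis comparison.
#'
#' @name objectives
NULL

#' Porosity of a design
#'
#' Bounding-box volume divided by the DNA volume, where the DNA is modelled
#' as one cylinder per edge with the bundle diameter of the edge type:
#' `V_box / sum(pi * (d/2)^2 * length)`. Lower porosity means a denser
#' structure; the value approaches 1 as DNA fills the box. Cylinder overlap
#' at vertices is deliberately not de-duplicated — the measure is an
#' estimate and the simple sum keeps it strictly decreasing as edges are
#' added. Wider bundles (6HB) naturally score lower than thinner ones (2HB,
#' 1HB) on the same mesh.
#'
#' @param state a `design_state`.
#' @param bundle_diameter cylinder diameter in nm; defaults to the edge
#'   type's.
#' @return dimensionless ratio (>= 1 in practice).
#' @export
porosity <- function(state, bundle_diameter = state$edge_type$bundle_diameter) {
  if (nrow(state$edges) == 0L)
    abort("porosity is undefined for a design with no edges",
          "zero_volume_error")
  v_dna <- pi * (bundle_diameter / 2)^2 * sum(edge_lengths(state))
  box_volume(state$box) / v_dna
}

#' Edge-length variation index
#'
#' Population standard deviation of the normalised edge lengths (each
#' length divided by the mean length). Zero for perfectly uniform meshes;
#' invariant under uniform scaling. This is the coefficient of variation of
#' the edge lengths, used as the design-uniformity objective.
#'
#' @param state a `design_state` with at least one edge.
#' @return non-negative real.
#' @export
variation_index <- function(state) {
  len <- edge_lengths(state)
  if (!length(len)) abort("variation index needs at least one edge",
                          "zero_volume_error")
  norm <- len / mean(len)
  sqrt(mean((norm - mean(norm))^2))
}

#' Scaffold usage
#'
#' Relative deviation of the estimated scaffold demand from a fixed
#' scaffold length `L`: `|N_nt - L| / L`. Zero means the design consumes
#' exactly the scaffold; minimising it drives designs manufacturable with a
#' specific scaffold (default M13mp18, 7249 nt).
#'
#' @param state a `design_state`.
#' @param L scaffold length in nucleotides.
#' @return non-negative real.
#' @export
scaffold_usage <- function(state, L = M13MP18_NT) {
  if (!is_scalar_num(L) || L <= 0)
    abort("L must be a positive scaffold length in nucleotides", "schema_error")
  abs(estimate_scaffold_nt(state) - L) / L
}

## Registry of named objectives available to config files and the CLI.
.objective_registry <- new.env(parent = emptyenv())

#' Construct an objective specification
#'
#' @param name objective name.
#' @param direction `"minimize"` or `"maximize"`.
#' @param evaluate function mapping a `design_state` to a finite scalar.
#' @param params list of extra arguments passed to `evaluate`.
#' @return an object of class `objective_spec`.
#' @export
objective_spec <- function(name, direction = c("minimize", "maximize"),
                           evaluate, params = list()) {
  direction <- match.arg(direction)
  if (!is.function(evaluate)) abort("evaluate must be a function", "schema_error")
  structure(list(name = name, direction = direction, evaluate = evaluate,
                 params = params),
            class = "objective_spec")
}

#' @export
print.objective_spec <- function(x, ...) {
  cat(sprintf("objective '%s' (%s)\n", x$name, x$direction))
  invisible(x)
}

#' Register a custom objective
#'
#' Makes a user objective available by name to both optimizers and to
#' configuration files. Maximisation is handled internally by negation, so
#' user functions always return the natural value.
#'
#' @inheritParams objective_spec
#' @param overwrite replace an existing registration instead of raising a
#'   `duplicate_name_error`.
#' @return the registered `objective_spec`, invisibly.
#' @export
register_custom_objective <- function(name, direction, evaluate,
                                      params = list(), overwrite = FALSE) {
  if (!overwrite && exists(name, envir = .objective_registry, inherits = FALSE))
    abort(sprintf("an objective named '%s' is already registered", name),
          "duplicate_name_error")
  spec <- objective_spec(name, direction, evaluate, params)
  assign(name, spec, envir = .objective_registry)
  invisible(spec)
}

#' Look up an objective by name
#'
#' Built-in names are `"porosity"`, `"variation_index"` and
#' `"scaffold_usage"`; custom objectives registered with
#' [register_custom_objective()] are found as well.
#'
#' @param name objective name.
#' @param direction optional direction override.
#' @param params optional parameter override (e.g. `list(L = 7249)`).
#' @return an `objective_spec`.
#' @export
get_objective <- function(name, direction = NULL, params = NULL) {
  builtin <- list(
    porosity = objective_spec("porosity", "minimize", porosity),
    variation_index = objective_spec("variation_index", "minimize",
                                     variation_index),
    scaffold_usage = objective_spec("scaffold_usage", "minimize",
                                    scaffold_usage)
  )
  spec <- if (exists(name, envir = .objective_registry, inherits = FALSE))
    get(name, envir = .objective_registry)
  else builtin[[name]]
  if (is.null(spec))
    abort(sprintf("unknown objective '%s'", name), "unknown_objective_error")
  if (!is.null(direction)) spec$direction <- match.arg(direction,
                                                       c("minimize", "maximize"))
  if (!is.null(params)) spec$params <- params
  spec
}

## Evaluate an objective as an energy (always minimised). Non-finite values
## are a contract violation of the objective, not of the optimizer.
objective_energy <- function(spec, state) {
  val <- do.call(spec$evaluate, c(list(state), spec$params))
  if (!is_scalar_num(val))
    abort(sprintf("objective '%s' returned a non-finite value", spec$name),
          "non_finite_objective_error")
  if (spec$direction == "maximize") -val else val
}

## Raw (user-facing) objective value.
objective_value <- function(spec, state) {
  val <- do.call(spec$evaluate, c(list(state), spec$params))
  if (!is_scalar_num(val))
    abort(sprintf("objective '%s' returned a non-finite value", spec$name),
          "non_finite_objective_error")
  val
}
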