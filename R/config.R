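#' @title Problem configuration files
#'
#' @description A whole generative-design problem — preserved/excluded
#' regions, bounding box, edge type, rules, constraints, objectives and
#' schedule — can be described in one YAML or JSON file, schema-validated
#' before any run. Unknown keys are rejected with their key path so typos
#' fail loudly rather than silently falling back to defaults.
#'
#' @name configuration
NULL

check_keys <- function(x, allowed, path) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    abort(sprintf("unknown configuration key(s) at %s: %s",
                  path, paste(bad, collapse = ", ")),
          "schema_error")
  invisible(x)
}

#' Load and validate a problem configuration
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON (`.json`) file.
#' @return the validated configuration list with defaults filled in,
#'   classed `problem_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found", path),
                                "schema_error")
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                abort(sprintf("unsupported config format '%s'", ext),
                      "unsupported_format_error"))
  validate_config(raw)
}

#' Validate a problem configuration list
#'
#' @param cfg a named list as produced by [load_config()].
#' @return the config with defaults filled, classed `problem_config`.
#' @export
validate_config <- function(cfg) {
  check_keys(cfg, c("seed", "box", "edge_type", "preserved", "excluded",
                    "rules", "constraints", "objectives", "schedule"),
             "(top level)")
  if (is.null(cfg$box)) abort("config requires a 'box' section", "schema_error")
  check_keys(cfg$box, c("a", "b", "c", "gamma", "origin"), "box")
  cfg$box$gamma <- cfg$box$gamma %||% 90
  bounding_box(cfg$box$a, cfg$box$b, cfg$box$c, cfg$box$gamma)  # validates

  cfg$edge_type <- cfg$edge_type %||% list(name = "2HB")
  check_keys(cfg$edge_type, c("name", "helices_per_edge", "bundle_diameter",
                              "min_edge_nt", "scaffold_passes"), "edge_type")

  if (is.null(cfg$preserved))
    abort("config requires a 'preserved' section", "schema_error")
  check_keys(cfg$preserved, c("vertices", "edges", "fixture"), "preserved")
  if (!is.null(cfg$preserved$fixture)) {
    check_keys(cfg$preserved$fixture, c("name", "side", "a", "b", "c", "gamma"),
               "preserved.fixture")
    if (!cfg$preserved$fixture$name %in% c("cube_corners",
                                           "parallelepiped_midfaces"))
      abort(sprintf("unknown fixture '%s'", cfg$preserved$fixture$name),
            "schema_error")
  } else if (is.null(cfg$preserved$vertices) && is.null(cfg$preserved$edges)) {
    abort("preserved section must give vertices, edges or a fixture",
          "schema_error")
  }

  for (i in seq_along(cfg$excluded))
    check_keys(cfg$excluded[[i]], c("min", "max"),
               sprintf("excluded[%d]", i))

  cfg$rules <- cfg$rules %||% list()
  check_keys(cfg$rules, c("enabled", "weights", "k_min", "k_max", "box_moves",
                          "box_delta_nm", "box_delta_deg"), "rules")

  cfg$constraints <- cfg$constraints %||% list()
  check_keys(cfg$constraints, c("scaffold_budget", "min_edge_nt",
                                "repulsion_cutoff_nm"), "constraints")
  sb <- cfg$constraints$scaffold_budget %||% M13MP18_NT
  if (!is_scalar_num(sb) || sb <= 0)
    abort("constraints.scaffold_budget must be positive", "schema_error")

  cfg$objectives <- cfg$objectives %||% list(list(name = "porosity"))
  if (is.data.frame(cfg$objectives))
    cfg$objectives <- lapply(seq_len(nrow(cfg$objectives)), function(i)
      as.list(cfg$objectives[i, , drop = FALSE]))
  for (i in seq_along(cfg$objectives)) {
    check_keys(cfg$objectives[[i]], c("name", "direction", "params"),
               sprintf("objectives[%d]", i))
    get_objective(cfg$objectives[[i]]$name)   # unknown_objective_error if bad
  }

  cfg$schedule <- cfg$schedule %||% list()
  check_keys(cfg$schedule, c("t0", "alpha", "moves_per_stage", "max_iter",
                             "ramp_fraction", "stall_stages"), "schedule")
  structure(cfg, class = c("problem_config", "list"))
}

#' Assemble a runnable problem from a validated configuration
#'
#' @param cfg a `problem_config` (see [load_config()]).
#' @return list with `state` (the initialized design), `objectives`,
#'   `constraints`, `ruleset`, `schedule` and `seed`.
#' @export
build_problem <- function(cfg) {
  if (!inherits(cfg, "problem_config")) cfg <- validate_config(cfg)
  box <- bounding_box(cfg$box$a, cfg$box$b, cfg$box$c, cfg$box$gamma,
                      cfg$box$origin %||% c(0, 0, 0))
  et_args <- cfg$edge_type
  et <- edge_type(et_args$name,
                  helices_per_edge = et_args$helices_per_edge,
                  bundle_diameter = et_args$bundle_diameter,
                  min_edge_nt = et_args$min_edge_nt %||% 31L,
                  scaffold_passes = et_args$scaffold_passes)
  excl <- lapply(cfg$excluded, function(r)
    excluded_region(as.numeric(unlist(r$min)), as.numeric(unlist(r$max))))

  verts <- if (!is.null(cfg$preserved$fixture)) {
    fx <- cfg$preserved$fixture
    switch(fx$name,
           cube_corners = fixture_cube_corners(fx$side),
           parallelepiped_midfaces =
             fixture_parallelepiped_midfaces(fx$a %||% cfg$box$a,
                                             fx$b %||% cfg$box$b,
                                             fx$c %||% cfg$box$c,
                                             fx$gamma %||% cfg$box$gamma))
  } else {
    as_point_matrix(cfg$preserved$vertices)
  }
  pres_edges <- cfg$preserved$edges %||% list()

  cs <- constraint_set(
    scaffold_budget = cfg$constraints$scaffold_budget %||% M13MP18_NT,
    min_edge_nt = cfg$constraints$min_edge_nt,
    repulsion_cutoff = cfg$constraints$repulsion_cutoff_nm
  )
  rl <- cfg$rules
  ruleset <- rule_set(
    rules = rl$enabled %||% c("extend_vertex", "edge_flip", "divide_face",
                              "merge_vertex"),
    weights = rl$weights,
    k_min = rl$k_min %||% 1L, k_max = rl$k_max %||% 30L,
    allow_box_moves = isTRUE(rl$box_moves),
    box_delta_nm = rl$box_delta_nm %||% 2,
    box_delta_deg = rl$box_delta_deg %||% 5
  )
  sc <- cfg$schedule
  schedule <- annealing_schedule(
    t0 = sc$t0, alpha = sc$alpha %||% 0.95,
    moves_per_stage = sc$moves_per_stage %||% 50L,
    max_iter = sc$max_iter %||% 20000L,
    ramp_fraction = sc$ramp_fraction %||% 0.3,
    stall_stages = sc$stall_stages %||% Inf
  )
  objectives <- lapply(cfg$objectives, function(o)
    get_objective(o$name, direction = o$direction, params = o$params))

  state <- initialize_design(verts, preserved_edges = pres_edges,
                             excluded = excl, box = box, edge_type = et,
                             constraints = cs)
  list(state = state, objectives = objectives, constraints = cs,
       ruleset = ruleset, schedule = schedule, seed = cfg$seed)
}
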