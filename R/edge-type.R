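#' Edge type: DNA helix bundle per mesh edge
#'
#' Wireframe origami edges are bundles of parallel double helices. The
#' built-in types follow the automated scaffold-routing families:
#' `"1HB"` (single duplex edges, vHelix-style), `"2HB"` (two-helix bundles,
#' ATHENA/DAEDALUS-style) and `"6HB"` (six-helix bundles). The bundle
#' diameter drives the cylindrical DNA volume model used by [porosity()];
#' `scaffold_passes` is how many times the scaffold traverses an edge and
#' converts base pairs per helix into scaffold nucleotides.
#'
#' @param name `"1HB"`, `"2HB"` or `"6HB"` for a built-in spec, or any other
#'   name if all other fields are supplied.
#' @param helices_per_edge number of helices in the bundle (N).
#' @param bundle_diameter bundle cross-section diameter in nm.
#' @param min_edge_nt minimum edge length in base pairs per helix a routing
#'   algorithm will accept; default 31 bp.
#' @param scaffold_passes times the scaffold runs along an edge; defaults to
#'   the number of helices (the scaffold visits every helix once).
#' @return an object of class `edge_type`.
#' @examples
#' edge_type("2HB")
#' edge_type("2HB", bundle_diameter = 5)  # override the cylinder model
#' @export
edge_type <- function(name,
                      helices_per_edge = NULL,
                      bundle_diameter = NULL,
                      min_edge_nt = 31L,
                      scaffold_passes = NULL) {
  builtin <- list(
    `1HB` = list(helices_per_edge = 1L, bundle_diameter = 2),
    `2HB` = list(helices_per_edge = 2L, bundle_diameter = 4),
    `6HB` = list(helices_per_edge = 6L, bundle_diameter = 6)
  )
  if (name %in% names(builtin)) {
    defaults <- builtin[[name]]
    helices_per_edge <- helices_per_edge %||% defaults$helices_per_edge
    bundle_diameter <- bundle_diameter %||% defaults$bundle_diameter
  }
  if (is.null(helices_per_edge) || is.null(bundle_diameter))
    abort(sprintf("edge type '%s' is not built in; supply helices_per_edge and bundle_diameter",
                  name), "schema_error")
  scaffold_passes <- scaffold_passes %||% helices_per_edge
  if (!is_count(helices_per_edge) || !is_count(scaffold_passes) ||
      !is_count(min_edge_nt))
    abort("helices_per_edge, scaffold_passes and min_edge_nt must be positive integers",
          "schema_error")
  if (!is_scalar_num(bundle_diameter) || bundle_diameter <= 0)
    abort("bundle_diameter must be a positive length in nm", "schema_error")
  structure(
    list(name = name,
         helices_per_edge = as.integer(helices_per_edge),
         bundle_diameter = bundle_diameter,
         min_edge_nt = as.integer(min_edge_nt),
         scaffold_passes = as.integer(scaffold_passes)),
    class = "edge_type"
  )
}

#' @export
print.edge_type <- function(x, ...) {
  cat(sprintf("edge type %s: %d helices/edge, bundle diameter %.3g nm, min edge %d bp, %d scaffold passes\n",
              x$name, x$helices_per_edge, x$bundle_diameter, x$min_edge_nt,
              x$scaffold_passes))
  invisible(x)
}
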