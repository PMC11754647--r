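#' @title Mesh serialization
#'
#' @description Designs export to open text formats so downstream
#' scaffold-routing tools (ATHENA, vHelix, DNAforge) and diff-based tests
#' can consume them: ASCII PLY and OBJ for geometry, JSON for the full
#' labelled state (preserved flags, edge type, box, excluded regions).
#' Coordinates are written in nm with 6 decimal places, so an
#' export-import-export cycle is byte-identical.
#'
#' @name serialization
NULL

fmt_coord <- function(x) sprintf("%.6f", x)

#' Export a design to PLY, OBJ or JSON
#'
#' @param state a `design_state`.
#' @param path output file path.
#' @param format `"ply"`, `"obj"` or `"json"` (case-insensitive); guessed
#'   from the file extension when omitted.
#' @return `path`, invisibly.
#' @export
export_design <- function(state, path, format = NULL) {
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
         ply = write_ply(state, path),
         obj = write_obj(state, path),
         json = write_design_json(state, path),
         abort(sprintf("unsupported export format '%s' (use ply, obj or json)",
                       format), "unsupported_format_error"))
  invisible(path)
}

#' Write / read ASCII PLY
#'
#' @param state a `design_state`.
#' @param path file path.
#' @return `write_ply`: `path` invisibly. `read_ply`: list with `pos`
#'   (n x 3 matrix) and `faces` (m x 3 integer matrix, 1-based).
#' @export
write_ply <- function(state, path) {
  nv <- nrow(state$pos); nf <- nrow(state$faces)
  header <- c("ply", "format ascii 1.0",
              "comment wireframegen design mesh (nm)",
              sprintf("element vertex %d", nv),
              "property float x", "property float y", "property float z",
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices",
              "end_header")
  verts <- apply(state$pos, 1L, function(p) paste(fmt_coord(p), collapse = " "))
  faces <- apply(state$faces - 1L, 1L, function(f)
    paste(c(3L, f), collapse = " "))
  writeLines(c(header, verts, faces), path)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1L] != "ply") abort("not a PLY file", "unsupported_format_error")
  end <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", lines, value = TRUE)))
  vl <- lines[(end + 1L):(end + nv)]
  fl <- lines[(end + nv + 1L):(end + nv + nf)]
  pos <- do.call(rbind, lapply(strsplit(vl, " "), as.numeric))
  faces <- do.call(rbind, lapply(strsplit(fl, " "), function(x)
    as.integer(x[-1L]) + 1L))
  list(pos = pos, faces = faces)
}

#' Write / read Wavefront OBJ
#'
#' @inheritParams write_ply
#' @return as in [write_ply()]/[read_ply()].
#' @export
write_obj <- function(state, path) {
  verts <- apply(state$pos, 1L, function(p)
    paste(c("v", fmt_coord(p)), collapse = " "))
  faces <- apply(state$faces, 1L, function(f)
    paste(c("f", f), collapse = " "))
  writeLines(c("# wireframegen design mesh (nm)", verts, faces), path)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  pos <- do.call(rbind, lapply(strsplit(vl, " "), function(x)
    as.numeric(x[-1L])))
  faces <- do.call(rbind, lapply(strsplit(fl, " "), function(x)
    as.integer(sub("/.*", "", x[-1L]))))
  list(pos = pos, faces = faces)
}

#' Write / read the full labelled design as JSON
#'
#' Unlike PLY/OBJ, the JSON form round-trips every label: preserved flags,
#' edge table, edge type, bounding box and excluded regions.
#'
#' @inheritParams write_ply
#' @return `read_design_json` returns a `design_state`.
#' @export
write_design_json <- function(state, path) {
  obj <- list(
    format = "wireframegen-design",
    version = 1L,
    vertices = lapply(seq_len(nrow(state$pos)), function(i)
      list(position = round(state$pos[i, ], 6L),
           preserved = state$v_preserved[i])),
    edges = lapply(seq_len(nrow(state$edges)), function(i)
      list(endpoints = state$edges[i, ],
           preserved = state$e_preserved[i])),
    faces = lapply(seq_len(nrow(state$faces)), function(i) state$faces[i, ]),
    box = state$box[c("a", "b", "c", "gamma", "origin")],
    edge_type = unclass(state$edge_type),
    excluded = lapply(state$excluded, function(r) list(min = r$min, max = r$max))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_design_json
#' @export
read_design_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "wireframegen-design"))
    abort("not a wireframegen design JSON file", "unsupported_format_error")
  pos <- do.call(rbind, lapply(obj$vertices, function(v)
    as.numeric(unlist(v$position))))
  vp <- vapply(obj$vertices, function(v) isTRUE(v$preserved), logical(1L))
  edges <- do.call(rbind, lapply(obj$edges, function(e)
    as.integer(unlist(e$endpoints))))
  ep <- vapply(obj$edges, function(e) isTRUE(e$preserved), logical(1L))
  faces <- do.call(rbind, lapply(obj$faces, function(f) as.integer(unlist(f))))
  et <- obj$edge_type
  new_design_state(
    pos = pos, v_preserved = vp, edges = edges, e_preserved = ep,
    faces = faces,
    box = bounding_box(obj$box$a, obj$box$b, obj$box$c, obj$box$gamma,
                       as.numeric(unlist(obj$box$origin))),
    edge_type = edge_type(et$name, et$helices_per_edge, et$bundle_diameter,
                          et$min_edge_nt, et$scaffold_passes),
    excluded = lapply(obj$excluded, function(r)
      excluded_region(as.numeric(unlist(r$min)), as.numeric(unlist(r$max))))
  )
}

#' Write a run manifest
#'
#' A JSON record sufficient to reproduce a run: config echo, seed, package
#' version, objective values of the produced design(s) and the file
#' inventory.
#'
#' @param path output path.
#' @param config the problem configuration (list).
#' @param seed RNG seed used.
#' @param results named list of scalar results (objective values etc.).
#' @param files character vector of produced files.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, results = list(),
                           files = character(0)) {
  obj <- list(
    package = "wireframegen",
    version = as.character(utils::packageVersion("wireframegen")),
    seed = seed,
    config = config,
    results = results,
    files = files
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
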