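Package: wireframegen
Title: Generative Design of Wireframe DNA Origami by Shape Annealing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constrained generative design of wireframe DNA origami
    nanostructures without a predefined input mesh. A candidate design is a
    labelled graph backing a closed triangulated surface mesh inside a
    parallelepiped bounding box. Graph-grammar rules (vertex extension
    quantised to the 0.34 nm B-form rise, edge flips, face subdivision,
    vertex merges, bounding-box resizing) evolve the design under
    origami-aware feasibility constraints: a scaffold-length budget, a
    minimum edge length in base pairs, spatial containment and excluded
    regions, an inter-edge repulsion cutoff, and user-defined predicates.
    Single-objective shape annealing (Metropolis acceptance with geometric
    cooling and a late extension ramp) minimises or maximises built-in or
    custom objectives such as porosity, edge-length variation index and
    scaffold usage; multi-objective shape annealing maintains a Pareto
    archive of mutually non-dominated feasible designs. Designs export to
    ASCII PLY, OBJ and JSON for downstream scaffold-routing tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
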