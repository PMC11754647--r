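# wireframegen

Constrained generative design of **wireframe DNA origami** nanostructures,
without a predefined input mesh.

Wireframe origami folds a long single-stranded scaffold (typically the
7249-nucleotide M13mp18 phage genome) along the edges of a polyhedral mesh,
each edge a bundle of 1, 2 or 6 parallel double helices. Automated tools
route the scaffold and generate staples *given* a mesh — but producing a
mesh that is closed, triangulated, within the scaffold budget, clear of
forbidden regions and shaped toward a design goal is the hard, manual step.
`wireframegen` replaces it with a generative process: the user prescribes
only *preserved regions* (vertices/edges that must exist), optional
*excluded regions* (space that must stay empty), a bounding box, an edge
type and one or more objectives; a shape-annealing optimizer grows a valid
mesh from that minimal input. The package is aimed at DNA-nanotechnology
designers feeding meshes into routing tools such as ATHENA, vHelix or
DNAforge.

## The method in brief

A design state *s* is a labelled graph backing a closed, edge-manifold
triangulated surface inside a parallelepiped box (a, b, c, γ). Graph-grammar
rules propose local edits — vertex extension quantised to the 0.34 nm
B-form rise, edge flips, centroid face subdivision, vertex merges, and
bounding-box resizing — and only candidates passing every feasibility
constraint are considered:

- scaffold estimate N<sub>nt</sub> = Σ<sub>edges</sub> passes ·
  round(length / 0.34 nm) ≤ L<sub>scaffold</sub>,
- every edge ≥ 31 bp per helix (routing-algorithm floor, configurable),
- containment in the box, emptiness of excluded regions,
- minimum non-adjacent edge separation ≥ a repulsion cutoff,
- arbitrary user predicates.

Single-objective search uses Metropolis acceptance,
P = exp(−(E<sub>s′</sub> − E<sub>s</sub>)/T), with geometric cooling and a
late ramp that shrinks move sizes. Multi-objective search (2–3 objectives)
maintains a Pareto archive of mutually non-dominated feasible designs.
Built-in objectives:

- **porosity** = V<sub>box</sub> / V<sub>DNA</sub> (cylindrical bundle
  model; lower = denser, → 1 as DNA fills the box),
- **variation index** = σ of mean-normalised edge lengths (0 = uniform),
- **scaffold usage** = |N<sub>nt</sub> − L| / L (0 = consumes the scaffold
  exactly).

## Worked example

Minimise porosity in a 50 nm cube with 2HB edges under the M13mp18 budget
and a 2.5 nm inter-edge repulsion cutoff, starting from the cube's corners:

```r
library(wireframegen)

st <- initialize_design(fixture_cube_corners(50),
                        box = bounding_box(50, 50, 50),
                        edge_type = edge_type("2HB"))
st
#> wireframe design state: V=8 E=18 F=12 (2HB edges)
#>   estimated scaffold: 6024 nt; preserved: 8 vertices, 0 edges
#> bounding box: a=50 b=50 c=50 nm, gamma=90 deg, volume=1.25e+05 nm^3

cs <- constraint_set(scaffold_budget = 7249, repulsion_cutoff = 2.5)
fit <- shape_anneal(st, "porosity", cs,
                    schedule = annealing_schedule(max_iter = 5000), seed = 7)
fit
#> shape annealing (minimize porosity): 5000 proposals, 70.1% accepted
#>   best porosity: 8.06979; best design V=10 E=24 F=16, scaffold 7248 nt
```

The starting hull of the eight corners (12 cube edges + 6 face diagonals)
already demands 6024 nt; the optimizer subdivides faces and repositions the
free vertices until the estimated scaffold presses against the 7249 nt
budget (7248 nt here) — porosity is then limited by the scaffold itself,
the same budget-bound convergence the trace shows when plotted with
`plot(fit)` (objective on top, scaffold estimate against the budget line
below). `summary(fit)` breaks down acceptances per rule; early stages
accept most worsening moves (T0 is auto-calibrated to ~80%), late cold
stages are effectively pure descent.

The multi-objective front between edge-length uniformity and porosity,
with the bounding box itself free to vary:

```r
oct <- initialize_design(fixture_parallelepiped_midfaces(50, 50, 50, 90),
                         box = bounding_box(50, 50, 50),
                         edge_type = edge_type("2HB"))
mo <- run_mosa(oct, list("variation_index", "porosity"), cs,
               ruleset = rule_set(allow_box_moves = TRUE),
               schedule = annealing_schedule(max_iter = 5000), seed = 1)
head(archive_values(mo))   # one row per unique non-dominated design
plot(mo)                   # the found Pareto front
```

Designs export to ASCII PLY/OBJ for routing tools, or JSON with all labels
(`export_design(fit$best_state, "design.ply")`). Whole problems can live in
a YAML config and run from the shell via the bundled CLI:

```sh
exec/wireframe-design generate --config cube.yaml --seed 7 --outdir out/
exec/wireframe-design pareto   --config front.yaml --outdir pareto/
```

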