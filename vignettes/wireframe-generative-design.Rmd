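---
title: "Generative design of wireframe DNA origami by shape annealing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative design of wireframe DNA origami by shape annealing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wireframegen)
```

## The problem

Wireframe DNA origami folds a long single-stranded scaffold (typically
M13mp18, 7249 nucleotides) along the edges of a polyhedral mesh, with each
edge realised as a bundle of one, two or six parallel double helices. The
design bottleneck sits upstream of the well-automated scaffold-routing
tools: producing a *mesh* that is simultaneously closed, triangulated,
within the scaffold budget, free of forbidden regions, and shaped toward a
design goal. `wireframegen` generates such meshes without requiring the
user to draw one. The user states only what must exist (preserved vertices
and edges), what must stay empty (excluded regions), a bounding box, an
edge type, and one or more objectives; a stochastic optimizer grows and
reshapes a candidate mesh from that minimal input.

## Design representation and initialization

A candidate design is a labelled undirected graph backing a closed,
edge-manifold, all-triangle surface: vertex positions (nm) and preserved
flags are node labels, preserved flags sit on edges, and oriented triangles
close the surface. Triangles are used throughout because they distribute
load without shape change, and because local triangle edits keep validity
checkable cheaply.

The initial solution is the 3D convex hull of the preserved vertices (plus
preserved-edge endpoints) — the canonical minimal closed triangulation of a
point set. Preserved geometry interior to the hull cannot appear on a
closed triangulated surface, so it is rejected as an error rather than
forced through a constrained triangulation; in practice users prescribe
hull-extreme points (box corners, face centres). The hull is computed
in-package by supporting-plane enumeration with 2D hulls per coplanar face:
the O(n^4) cost is irrelevant at the tens-of-points scale of preserved
regions, and the formulation handles exactly coplanar facets (cube faces,
midface octahedra) without perturbation tricks. If the triangulated start
violates any constraint, the generative process cannot begin and
initialization fails.

## The grammar

Five local rules evolve a design, each returning a new state (states are
immutable so a rejected candidate can never corrupt the current one):

* **vertex extension** — a non-preserved vertex moves `k` steps of
  0.34 nm (the B-form rise) along a uniformly random direction. The
  *displacement* is quantised, not each edge length: demanding exact
  0.34 nm multiples of every edge simultaneously is geometrically
  overconstrained, and nucleotide counts are quantised where they matter,
  in the scaffold estimate. `k` is drawn uniformly from `[k_min, k_max]`
  (defaults 1–30, i.e. up to ~10 nm moves in a 50 nm box).
* **edge flip** — the shared edge of two adjacent triangles rotates to the
  opposite diagonal of their quad; an involution that changes connectivity
  without moving material.
* **face subdivision** — a new vertex at a face centroid splits one
  triangle into three (V+1, E+3, F+2), the move that adds material.
* **vertex merge** — the inverse: a degree-3 vertex is removed and its
  hole closed; higher degrees collapse along an incident edge, guarded by
  the usual link condition against pinching the surface.
* **box resize** — one of (a, b, c, gamma) changes by a bounded delta
  (defaults ±2 nm, ±5°, within 10–100 nm and 45–135°); used in
  multi-objective studies where the box is itself a design variable.
  Preserved vertices never move, so a shrink that would strand one outside
  the box is simply rejected.

Rule selection is weighted-uniform (equal weights by default). A proposal
draws rules and parameters until the candidate passes *all* constraints;
after `max_retries` failures the optimizer records a null move. Every rule
output is re-validated against the full mesh invariant set (closedness,
orientation, edge-manifoldness, vertex-link connectivity, Euler
characteristic 2, no degenerate faces); an optional strict mode adds
O(F^2) face–face self-intersection tests, off by default since moves are
local and the annealing loop calls the validator on every candidate.

## Constraints

Feasibility is the conjunction of:

* **topological** — estimated scaffold demand ≤ budget, and every edge at
  least `min_edge_nt` base pairs per helix (default 31 bp, a typical floor
  for automated routing algorithms; configurable per edge type). The
  scaffold estimate is `scaffold_passes × round(length / 0.34 nm)` summed
  over edges; vertex/staple overhead is not included (that accounting
  belongs to the routing tool), but a per-vertex additive correction is
  exposed, defaulting to 0.
* **spatial** — all vertices inside the (possibly sheared) bounding box;
  no vertex inside and no edge crossing the interior of any excluded
  region, tested by exact slab clipping of segments against the
  axis-aligned box rather than sampling.
* **repulsion** — the minimum segment–segment distance over edge pairs
  sharing no vertex must not fall below a cutoff, a distance-threshold
  form of the electrostatic repulsion between helix bundles. The distance
  uses the exact clamped closest-point computation, vectorised over all
  pairs.
* **custom** — named user predicates on the full design state; a predicate
  that throws marks the state infeasible and surfaces as a classed
  warning, never as a crash of the run.

Feasibility is monotone in the natural directions (a larger budget or a
smaller cutoff never makes a feasible state infeasible), which the test
suite asserts on random meshes.

## Objectives

* **porosity** = `V_box / V_DNA` with `V_box = a·b·c·sin(gamma)` and
  `V_DNA` the sum of one cylinder per edge at the bundle diameter
  (defaults 2/4/6 nm for 1HB/2HB/6HB). Bundle-level cylinders (rather than
  per-helix ones) make the measure respond to the bundle cross-section,
  which is why 6HB designs score systematically lower than 2HB on the same
  mesh. Cylinder overlap at vertices is not de-duplicated: the measure is
  an estimate, and the simple sum keeps porosity strictly decreasing as
  edges are added.
* **variation index** = population standard deviation of edge lengths
  divided by their mean (the normalisation is by the mean; both choices
  are recorded in output metadata). Zero for uniform meshes, invariant
  under uniform scaling.
* **scaffold usage** = `|N_nt − L| / L` against a fixed scaffold length
  (default 7249 nt M13mp18); minimising it drives manufacturable designs
  that consume the actual scaffold.

Any user function of the design state can be registered alongside these;
maximisation is handled by internal negation so the Metropolis comparison
always minimises. Non-finite objective values raise a classed error at
first evaluation.

## Single-objective shape annealing

A proposal that lowers the energy always replaces the current state;
otherwise it is accepted with probability `exp(-(E_new − E_old) / T)`
against a uniform draw. The temperature cools geometrically (`alpha`,
default 0.95) every `moves_per_stage` proposals (default 50). `T0` is
auto-calibrated unless given: a 100-proposal random walk from the start
measures typical worsening steps, and `T0` is set so the mean worsening
step would be accepted with probability 0.8 — hot enough to escape the
initial basin, while still cooling to effectively greedy descent within a
20 000-proposal budget. A ramp linearly shrinks `k_max` to `k_min` over
the final 30% of the run, so late moves refine rather than explore.

A stall stop (no acceptances for a configurable number of consecutive
stages) is available but disabled by default: studies here are defined by
their proposal budgets, and a silent early stop would make budgeted runs
incomparable. The returned object keeps the best-so-far state (elitism)
and a per-proposal trace (current and candidate energy, temperature,
acceptance, rule, scaffold estimate) that `plot()` renders as the usual
two-panel convergence view.

## Multi-objective shape annealing

With 2–3 objectives (more raise an error unless explicitly overridden —
the acceptance rule is unvalidated beyond that), the optimizer maintains a
Pareto archive of mutually non-dominated feasible designs, with one member
per distinct objective vector. The published description of the
multi-objective variant leaves the acceptance and archiving details to its
own references, so this package declares its convention explicitly, a
Suppapitnarm-style rule: a candidate dominated neither by the current
state nor by any archive member is accepted outright; otherwise it is
accepted with probability `prod_i exp(-max(0, dE_i) / T_i)` under
per-objective temperatures cooled on the shared schedule. Every
`base_return` stages (default 5) the current state returns to a uniformly
drawn archive member, spreading coverage along the front. Objective values
are not normalised by default; optional min–max normalisation against
running extrema is available because porosity (~10) and variation index
(~0.1) live on very different scales.

## Study fixtures and what the generator emulates

Two fixture generators reproduce the study inputs used throughout the
tests: the eight corners of a 50 nm cube (single-objective porosity study:
2HB edges, 7249 nt budget, 2.5 nm repulsion cutoff), and the six face
centres of a parallelepiped (multi-objective studies with box moves
enabled; their hull is an octahedron with perfectly uniform edges, so a
variation index of zero is attainable from the start). These fixtures
emulate the *geometry* of the published studies. They do not emulate
everything about real design practice: no staple-level accounting, no
sequence effects, no mechanical deformation of the assembled object —
passing tests demonstrate correct generative behaviour over meshes, not
experimental foldability, which remains the job of downstream routing
tools and simulation.

Problem sizes in the test suite are chosen to exercise convergence on a
single CPU: 20 000 proposals per seed for the two study reproductions
(5 seeds for the single-objective median), 4 000 per seed for the
archive-size comparison between the uniformity and manufacturability
studies, and 10 000 fuzzed rule applications for the invariant suite.

## Numerical choices and degenerate inputs

* Rounding of lengths to base pairs uses round-half-to-even (R's `round`).
* Hull and mesh tolerances are absolute at the nm scale (1e-7 relative to
  the point-cloud extent for plane incidence, 1e-9 for zero-area faces);
  coordinates serialize at 6 decimals, which round-trips exactly.
* Coplanar preserved vertices, duplicate points, interior points,
  non-hull preserved edges, zero-length edges, empty meshes and
  unsatisfiable constraint sets all raise classed errors
  (`triangulation_error`, `region_conflict_error`,
  `zero_length_edge_error`, `exhausted_retries_error`, ...), never
  silent misbehaviour.
* Ties in the Metropolis rule (`E_new == E_old`) take the probabilistic
  branch with probability `exp(0) = 1`, so plateau moves are accepted.

## Known limitations

* The initial triangulation is the convex hull, so non-convex preserved
  skeletons cannot seed a run directly (they can still *emerge* through
  vertex extension inward).
* Excluded regions are axis-aligned boxes; arbitrary convex polyhedra are
  deferred.
* The porosity cylinder model double-counts vertex joints slightly and
  carries the bundle diameter as a single effective width.
* The scaffold estimate ignores vertex/staple overhead unless the user
  supplies a per-vertex correction; the true demand is fixed only by the
  downstream routing tool.
* Shape annealing is a stochastic ideation tool: converged values depend
  on the schedule, and no claim of global optimality is made.
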