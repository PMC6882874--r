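---
title: "Designing 2D wireframe DNA origami with six-helix-bundle edges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing 2D wireframe DNA origami with six-helix-bundle edges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(origami6hb)
```

## The model

A 2D wireframe origami is specified as a planar straight-line graph: vertex
coordinates in nanometres and edges between them, either given completely
("boundary and internal" input) or as a boundary polygon whose interior mesh
the package generates. Each wireframe edge is realized as a six-helix bundle
(6HB): six parallel B-form duplexes on a hexagonal honeycomb ring of
circumradius equal to the interhelix distance, forming three layers stacked
along the out-of-plane axis with the middle layer in the design plane.
Polarity alternates around the ring, so every ring-adjacent duplex pair is
antiparallel and can host antiparallel double crossovers.

At a vertex, the incident edge-ends are ordered by angle and every edge-end
is connected to its counter-clockwise neighbour in all three layers: within
each layer, the duplex facing the wedge on one side continues covalently
into the facing duplex of the neighbouring edge. Because the two duplexes of
a layer are antiparallel, exactly one scaffold strand points into the vertex
and one out on each side, so each layer contributes one scaffold and one
staple crossing per neighbouring-edge pair — three of each over the bundle.
This multiway vertex motif, combined with unpaired nucleotides sized from
the physical gap, is what makes arbitrary (non-integer-turn) edge lengths
and arbitrary vertex angles designable.

Scaffold routing follows the loop-crossover picture: walking every duplex's
scaffold strand through the vertex connections partitions all scaffold
positions into disjoint closed loops; geometrically allowed scaffold double
crossovers between ring-adjacent duplexes connect them. The dual graph (one
node per loop, one edge per candidate crossover) is spanned by a minimum
spanning tree, and applying exactly the tree crossovers — each an
antiparallel strand exchange that merges two cycles — leaves a single closed
cycle visiting every scaffold position once: the scaffold routing.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `rise_per_bp` | 0.34 | nm/bp | axial rise; discretization and all frames |
| `bp_per_turn` | 10.5 | bp | B-form helicity; crossover phases, twist 34.29°/bp |
| `interhelix_distance` | 2.5 | nm | honeycomb ring radius (configurable 2.25–2.6) |
| `unpaired_nt_spacing` | 0.42 | nm/nt | contour length per unpaired vertex nucleotide |
| `min_edge_bp` | 42 | bp | shortest designable edge (~4 turns) |
| `crossover_end_guard_bp` | 10 | bp | no crossover near an edge end |
| `staple_min_nt`, `staple_max_nt` | 20, 60 | nt | staple length window |
| `nick_domain_min_bp` | 7 | bp | duplex between a nick and the nearest junction |

The 0.42 nm/nt vertex-loop spacing is the design default for both scaffold
and staple loops; the gap between two connected duplex ends is measured in
3D between the trimmed axis endpoints and converted to nucleotides by
explicit half-up rounding (base R `round()` is banker's rounding and would
round 5.5 down in half of the cases).

## Numerical and design choices

**Discretization is the ceiling of length/rise.** Among the single rounding
rules, only the ceiling reproduces the 25-nm-circumradius series this
geometry implies: triangle 128 bp, hexagon 74 bp, octagon 57 bp. The square
is the known misfit: `2·25·sin(45°)/0.34 = 103.99`, which no single rounding
takes to the 105 sometimes quoted for that design; our rule gives 104 and we
document rather than chase the discrepancy.

**Bisector trims floor.** A duplex offset `|u|` toward a wedge of opening
`phi` is trimmed by `|u|/tan(phi/2)`, floored to whole bp and clamped at
zero — duplexes on the wide side keep full length and the residual gap goes
into unpaired nucleotides instead. For a 60° wedge and a 2.5 nm offset this
is 4.33 nm = 12 bp.

**Internal meshing** is hand-written: ear clipping of the simple boundary
polygon, Lawson edge flips to the Delaunay criterion with the boundary
constrained, and at most one Steiner point at the centroid when the coarse
triangulation's interior edges exceed the target edge length (for a regular
hexagon at target ≈ R this produces the 6-spoke fan; a square at a coarse
target keeps its single diagonal). Quadrilateral meshes pair adjacent
triangles across their longest shared diagonals into convex quads and fail
loudly if any triangle is left over. Holes (multiple boundary loops) pass
validation but are not auto-meshed.

**Crossover phases.** The scaffold backbone of a duplex faces its ring
neighbour where the twist phase matches the cross-section angle between the
two axes; candidates are the nearest integer bp to each such phase (period
10.5 bp), inside the end guard and both duplexes' trimmed ranges. Dual-graph
weights are uniform with a fully lexicographic tie-break (weight, loop pair,
helix pair, position) and Prim's algorithm started from the first loop, so
routing is deterministic. Candidates that would rewire the same backbone
link as an earlier candidate are dropped so that any subset of survivors can
be applied together; an exchange is only ever applied to an intact
antiparallel pair (asserted at application time).

**Staple layout.** Staple crossovers sit half a turn offset from the
scaffold phases, thinned to every fourth phase per helix pair with a
pair-dependent stagger. This spacing is what keeps the staple cycles
nickable: junctions on any one helix then alternate roughly 12/30 bp apart,
so every cycle retains runs of at least 14 bp where a nick can sit 7 bp from
both flanking junctions. Nick positions are chosen by a deterministic
feasibility DP around each staple cycle, targeting mid-window lengths
(~40 nt); vertex staples span the connection with poly-T loops and a nick is
allowed inside the loop, in which case the loop bases are omitted (the
staple ends flush at the duplex). The scaffold itself stays circular; its
threading start defaults to the first scaffold-sense position of helix 0 of
edge 1 and is configurable.

**Exports.** caDNAno helix numbers are `6·(edge−1)+k` (parity matching
duplex polarity); each bundle occupies one hexagonal honeycomb face, three
cells in each of two rows, packed left-to-right with fixed row+column
parity, so ring-adjacent duplexes always map to lattice-adjacent cells.
Vertex loops are written as caDNAno insertions at the 5'-side base of their
connection. The atomic model places a coarse three-pseudo-atom template (P,
C1', base N at B-form radii) per nucleotide on each helix frame (0.34 nm
rise, 34.29°/bp twist, staple strand at +154° across the groove); PDB I/O
goes through bio3d, with scaffold as chain A and staples cycling the
remaining chain characters. oxDNA positions are nucleotide centres in
simulation units (0.8518 nm) with unit backbone/normal versors; the scaffold
strand is circular in the topology.

## The trajectory analysis

Atoms are grouped per bp-sextet: for each edge, only axial indices where all
six duplexes still have a bp after end trimming form groups (incomplete
groups near trimmed ends would drag the centre off the helix axis and bias
the fitted end vectors by over 10°, which is why the grouping is restricted
to complete sextets; `M` is therefore the trimmed common range, e.g. 60 for
the 84-bp triangle). Per frame and edge, group centres are unweighted atom
means; the edge basis comes from the principal axes of the centre cloud with
signs fixed by the c1→cM span (`b1`), the outward direction from the object
centroid (`b2`, our reading of "inner to outer"), and right-handedness
(`b3`). End vectors use the first/last `L` centres (`L` defaults to 40 when
M ≥ 60 and 20 — capped at M — otherwise, matching the convention of 40 for
84-bp and 20 for 42-bp objects). The object plane passes through the three
mid-edge centres (`c_{M/2}`, taking `floor(M/2)+1` for odd M); the internal
angle at a vertex is the arccos of the normalized dot product of the two end
vectors projected into that plane, and the out-of-plane angle is the arccos
between the vertex normal (cross product of the unprojected end vectors) and
the plane normal, folded into [0°, 90°]. These angles are sometimes written
as bare dot products in shorthand; a dot product is not an angle, so we take
the arccos of the normalized product and report degrees. Vertices are identified
by proximity matching of terminal centres, which keeps the procedure
agnostic to edge ordering in the input.

RMSD superposes every frame onto the reference (t = 0) over all mapped atoms
and supports bin means over time windows (e.g. 50–100, 100–150, 150–200 ns)
plus their grand mean; RMSF reports per-atom fluctuation about the
time-average structure after the same superposition. Superposition uses
bio3d's least-squares fitting — the same standard step the field performs
with ProDy — while the tests verify both against an independent
SVD-Kabsch implementation and closed-form cases.

## The synthetic trajectory generator

`synth_trajectory()` emulates the dominant soft modes of a wireframe
triangle: per-frame rigid rotation of each edge about its midpoint, in-plane
(drawn from N(0, sd_theta/√2), so a vertex angle — the difference of two
independent edge rotations — has standard deviation `sd_theta`) and
out-of-plane (N(0, sd_omega/√2) about the in-plane perpendicular), plus
isotropic Gaussian atomic noise. Ground-truth angles are recorded by running
the same geometric construction on the exactly-rotated ideal centre
polylines. What it does *not* emulate: edge bending (edges stay straight),
correlated vertex mechanics, breathing of the cross-section, solvent and ion
effects, or any force field — so passing recovery tests validates the
measurement procedure, not the physics of real trajectories. Ensemble values
from explicit-solvent MD (hundreds of ns on GPU clusters) are out of desk
scale; the analysis module consumes such trajectories via multi-model PDB or
the plain XYZ dialect but does not produce them.

## Problem sizes and determinism

The shipped tests design the 25-nm triangle/square/pentagon/hexagon/octagon
series (57–128 bp edges, up to ~2700 scaffold nt) and the 84-bp triangle MD
object; parameter-recovery uses 500 frames of the 84-bp triangle model
(~8500 mapped atoms), which keeps the whole suite under a couple of minutes.
Every stage is deterministic given the seed: the only randomness is the
seeded random scaffold generator and the synthetic trajectory, and re-running
a design with the same seed and configuration is byte-identical, which the
suite asserts on the exported CSV.

## Known limitations

- Internal angles and out-of-plane angles are defined for triangular objects
  only (the plane construction uses exactly three mid-edge centres);
  `angle_series()` refuses other edge counts rather than guessing a
  generalization.
- Auto-meshing handles a single simple boundary polygon with at most one
  Steiner point; heavily non-convex outlines mesh, but without refinement
  quality guarantees. Holes are not meshed.
- The caDNAno honeycomb placement is self-consistent and round-trips through
  the bundled reader, but the upstream tool's exact helix-numbering
  convention is not published, so files may differ from it cosmetically.
- The bundled 7249-nt scaffold is a labelled synthetic stand-in (M13mp18's
  length, not its sequence).
- Multilayer generalizations beyond three layers, DX-edge designs, and 3D
  polyhedra are out of scope.
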