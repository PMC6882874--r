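Package: origami6hb
Title: Automated Sequence Design of 2D Wireframe DNA Origami with
    Six-Helix-Bundle Edges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Top-down inverse sequence design of two-dimensional wireframe
    scaffolded DNA origami whose edges are honeycomb six-helix bundles (6HB).
    Takes a piecewise-linear 2D target geometry (boundary-only or boundary plus
    internal mesh), discretizes edges into base pairs, builds three-layer 6HB
    edge bundles with multiway vertex crossover joints, routes a single circular
    scaffold through the design by inverting the minimum spanning tree of the
    scaffold loop-crossover dual graph, places and sequences staple strands, and
    exports caDNAno JSON, PDB atomic models, oxDNA topology/configuration, CSV
    and FASTA.  A companion analysis module measures structural fidelity of
    coordinate trajectories of such designs: per-edge principal-axis bases,
    internal vertex angles, out-of-plane angles, RMSD and RMSF.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
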