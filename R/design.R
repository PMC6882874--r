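#' Design a 2D wireframe origami with 6HB edges, end to end
#'
#' Runs the full top-down pipeline on a target geometry: optional automatic
#' internal meshing (boundary-only input), uniform scaling and bp
#' discretization, 6HB bundle construction with bisector end trims, multiway
#' vertex joints, scaffold loop formation, dual-graph minimum-spanning-tree
#' routing inversion, staple placement/nicking, and sequence assignment.
#'
#' @param geom a `target_geometry` (either mode).
#' @param scale_source,value anchor for [scale_and_discretize()].
#' @param scaffold_seq scaffold sequence string; `NULL` uses a seeded random
#'   scaffold exactly as long as required.
#' @param mesh_target_edge_len target internal mesh edge length in nm (only
#'   used for boundary-only input); default: the mean boundary edge length.
#' @param config full or partial design configuration, see [default_config()].
#' @return An `origami_design` holding every intermediate stage: `dgeom`,
#'   `bundles`, `joints`, `loops`, `candidates`, `tree`, `routing`,
#'   `staples`, `strands`, `config`.
#' @export
design_origami <- function(geom,
                           scale_source = "shortest_edge_bp", value = 84,
                           scaffold_seq = NULL,
                           mesh_target_edge_len = NULL,
                           config = list()) {
  cfg <- resolve_config(config)
  if (geom$mode == "boundary_only") {
    if (is.null(mesh_target_edge_len))
      mesh_target_edge_len <- mean(edge_lengths(geom))
    geom <- generate_internal_mesh(geom, cfg$mesh_type, mesh_target_edge_len)
  }
  dgeom <- scale_and_discretize(geom, scale_source, value, cfg)
  bundles <- build_edge_bundles(dgeom, cfg)
  bundles <- trim_ends_to_bisector(bundles, dgeom)
  joints <- build_vertex_joints(bundles, dgeom, cfg)
  loops <- build_scaffold_loops(bundles, joints)
  candidates <- enumerate_crossover_candidates(bundles, loops, cfg)
  tree <- minimum_spanning_tree(candidates, loops$n_loops)
  routing <- invert_tree_to_routing(loops, tree)
  if (is.null(scaffold_seq))
    scaffold_seq <- random_scaffold(routing$length_nt, cfg$seed)
  staples <- place_staples(bundles, joints, loops, routing, cfg)
  seq_assign <- assign_scaffold_sequence(routing, scaffold_seq, cfg)
  strands <- staple_sequences(staples, seq_assign)
  structure(list(geometry = geom, dgeom = dgeom, bundles = bundles,
                 joints = joints, loops = loops, candidates = candidates,
                 tree = tree, routing = routing, staples = staples,
                 strands = strands, scaffold_seq = scaffold_seq, config = cfg),
            class = "origami_design")
}

#' Design a bare regular polygon (no internal mesh)
#'
#' Convenience wrapper: regular N-gon inscribed in a circle of radius R nm,
#' designed without internal structure.
#'
#' @param n_sides,circumradius polygon parameters (nm).
#' @param scaffold_seq optional scaffold sequence.
#' @param config full or partial design configuration.
#' @return An `origami_design`.
#' @export
design_polygon <- function(n_sides, circumradius, scaffold_seq = NULL,
                           config = list()) {
  geom <- generate_regular_polygon(n_sides, circumradius)
  geom$mode <- "boundary_internal"   # design the bare frame, do not mesh it
  design_origami(geom, scale_source = "circumradius_nm", value = circumradius,
                 scaffold_seq = scaffold_seq, config = config)
}

#' @export
print.origami_design <- function(x, ...) {
  cat(sprintf("origami_design: %d vertices, %d edges (6HB), scaffold %d nt, %d staples\n",
              nrow(x$geometry$vertices), nrow(x$geometry$edges),
              x$routing$length_nt, length(x$strands$staples)))
  invisible(x)
}
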