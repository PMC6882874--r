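## Six-helix-bundle edge construction and multiway vertex joints.
##
## Cross-section convention: in the plane perpendicular to a wireframe edge,
## coordinates are (u, w) with u along the in-plane left normal of the edge
## direction and w along the global out-of-plane axis (+z). The six duplexes
## sit on a hexagonal honeycomb ring of circumradius equal to the interhelix
## distance d, at angles 60*k degrees (k = 0..5), so ring-adjacent helices are
## d apart. The ring splits into three layers by w: bottom (k = 4,5), middle
## in the design plane (k = 0,3), top (k = 1,2). Polarity (scaffold 5'->3'
## sense along the edge direction) alternates around the ring, so every
## ring-adjacent pair is antiparallel.

HB6_RING_ANGLE <- 60 * (0:5)                # degrees
HB6_LAYER     <- c(1L, 2L, 2L, 1L, 0L, 0L)  # by ring index k+1
HB6_POLARITY  <- ifelse(0:5 %% 2 == 0, 1L, -1L)

hb6_cross_section <- function(d) {
  a <- HB6_RING_ANGLE * pi / 180
  data.frame(k = 0:5,
             u = d * cos(a),
             w = d * sin(a),
             layer = HB6_LAYER,
             row = ave(seq_len(6), HB6_LAYER,
                       FUN = function(i) order(i) - 1L),  # placeholder, fixed below
             polarity = HB6_POLARITY)
}

#' Build six-helix-bundle edge bundles
#'
#' Places one 6HB bundle on each wireframe edge of a discretized geometry:
#' six duplex axes parallel to the edge on a honeycomb ring, three layers
#' stacked along the out-of-plane axis with the middle layer in the design
#' plane. The bp grid of each bundle is centred on the geometric edge.
#'
#' @param dgeom a `discretized_geometry` from [scale_and_discretize()].
#' @param config full or partial design configuration.
#' @return List of `edge_bundle` objects (one per edge), each with the 2D
#'   anchor/direction of the bp grid and a `helices` data frame
#'   (ring index `k`, cross-section offsets `u`,`w`, `layer`, `row`,
#'   `polarity`, bp range `lo`..`hi-1`, global helix id `hid`).
#' @export
build_edge_bundles <- function(dgeom, config = list()) {
  cfg <- resolve_config(c(dgeom$config[setdiff(names(dgeom$config), names(config))],
                          config)[names(default_config())])
  d <- cfg$interhelix_distance
  rise <- cfg$rise_per_bp
  geom <- dgeom$geometry
  cs <- hb6_cross_section(d)
  # row within layer: 0 for the smaller-u duplex, 1 for the larger
  cs$row <- ave(cs$u, cs$layer, FUN = function(u) as.integer(rank(u) - 1L))
  bundles <- vector("list", nrow(geom$edges))
  for (e in seq_len(nrow(geom$edges))) {
    va <- geom$edges[e, 1]; vb <- geom$edges[e, 2]
    pa <- geom$vertices[va, ]; pb <- geom$vertices[vb, ]
    len <- sqrt(sum((pb - pa)^2))
    dir <- (pb - pa) / len
    nrm <- c(-dir[2], dir[1])
    bp <- dgeom$bp_per_edge[e]
    anchor <- pa + dir * (len - bp * rise) / 2   # centre the grid on the edge
    hel <- cs
    hel$lo <- 0L; hel$hi <- bp
    hel$hid <- 6L * (e - 1L) + hel$k + 1L
    bundles[[e]] <- structure(
      list(edge = e, va = va, vb = vb, anchor = anchor, dir = dir,
           normal = nrm, len_nm = len, bp = bp, rise = rise, helices = hel),
      class = "edge_bundle")
  }
  bundles
}

# 3D position of the centre of bp t (0-based, on the edge grid) of ring helix k
helix_bp_position <- function(bundle, k, t) {
  h <- bundle$helices[bundle$helices$k == k, ]
  xy <- bundle$anchor + bundle$dir * (t + 0.5) * bundle$rise + bundle$normal * h$u
  c(xy, h$w)
}

# 3D point where the trimmed axis of ring helix k meets the end `end` ("A"/"B")
helix_end_point <- function(bundle, k, end) {
  h <- bundle$helices[bundle$helices$k == k, ]
  t_edge <- if (end == "A") h$lo else h$hi
  xy <- bundle$anchor + bundle$dir * t_edge * bundle$rise + bundle$normal * h$u
  c(xy, h$w)
}

# incident edge-ends at each vertex, with outgoing direction angles
vertex_fan <- function(geom) {
  nv <- nrow(geom$vertices)
  fans <- vector("list", nv)
  for (e in seq_len(nrow(geom$edges))) {
    va <- geom$edges[e, 1]; vb <- geom$edges[e, 2]
    dirv <- geom$vertices[vb, ] - geom$vertices[va, ]
    ang_out_a <- atan2(dirv[2], dirv[1])
    ang_out_b <- atan2(-dirv[2], -dirv[1])
    fans[[va]] <- rbind(fans[[va]], c(edge = e, end = 1, angle = ang_out_a))
    fans[[vb]] <- rbind(fans[[vb]], c(edge = e, end = 2, angle = ang_out_b))
  }
  lapply(fans, function(f) {
    if (is.null(f)) return(NULL)
    f <- as.data.frame(f)
    f$end <- c("A", "B")[f$end]
    f[order(f$angle), , drop = FALSE]
  })
}

# signed in-plane offset of helix k w.r.t. the OUTGOING direction at edge end
u_out <- function(bundle, k, end) {
  u <- bundle$helices$u[bundle$helices$k == k]
  if (end == "A") u else -u
}

#' Trim duplex ends to the vertex angle bisector
#'
#' At every vertex each duplex axis is shortened so that its end lies on the
#' bisector plane of the wedge between its edge and the angularly adjacent
#' edge on the duplex's side: a duplex at in-plane offset `|u|` toward a wedge
#' of opening angle `phi` is trimmed by `|u| / tan(phi / 2)` (floored to whole
#' bp; never negative, so duplexes on the wide side keep their full length and
#' the residual gap is absorbed by unpaired vertex nucleotides).
#'
#' @param bundles list of `edge_bundle` from [build_edge_bundles()].
#' @param dgeom the `discretized_geometry` the bundles were built from.
#' @return The bundles with per-duplex bp ranges (`lo`, `hi`) updated and a
#'   `trims` data frame attached as an attribute.
#' @export
trim_ends_to_bisector <- function(bundles, dgeom) {
  geom <- dgeom$geometry
  fans <- vertex_fan(geom)
  rise <- dgeom$rise
  trims <- list()
  for (v in seq_along(fans)) {
    fan <- fans[[v]]
    if (is.null(fan)) next
    if (nrow(fan) < 2)
      stop("dangling edge at vertex ", v, ": every vertex needs degree >= 2")
    n <- nrow(fan)
    for (i in seq_len(n)) {
      ed <- fan$edge[i]; end <- fan$end[i]
      # wedge to the CCW neighbour (left side, u_out > 0) and CW neighbour
      ang <- fan$angle[i]
      ang_ccw <- fan$angle[if (i == n) 1 else i + 1]
      ang_cw  <- fan$angle[if (i == 1) n else i - 1]
      phi_ccw <- (ang_ccw - ang) %% (2 * pi)
      phi_cw  <- (ang - ang_cw) %% (2 * pi)
      if (n == 2) { # both wedges present also for degree 2 (phi and 2*pi - phi)
        phi_ccw <- (fan$angle[3 - i] - ang) %% (2 * pi)
        phi_cw  <- (ang - fan$angle[3 - i]) %% (2 * pi)
      }
      b <- bundles[[ed]]
      for (k in 0:5) {
        uo <- u_out(b, k, end)
        phi <- if (uo > 0) phi_ccw else phi_cw
        trim_nm <- if (phi >= pi - 1e-12) 0 else abs(uo) / tan(phi / 2)
        trim_bp <- max(0L, as.integer(floor(trim_nm / rise + 1e-9)))
        if (trim_bp > b$bp / 2)
          stop("edge ", ed, " too short for vertex ", v,
               " geometry: bisector trim of ", trim_bp, " bp exceeds half the edge")
        row <- which(b$helices$k == k)
        if (end == "A") b$helices$lo[row] <- b$helices$lo[row] + trim_bp
        else            b$helices$hi[row] <- b$helices$hi[row] - trim_bp
        trims[[length(trims) + 1L]] <-
          data.frame(vertex = v, edge = ed, end = end, k = k,
                     trim_nm = trim_nm, trim_bp = trim_bp)
      }
      bundles[[ed]] <- b
    }
  }
  attr(bundles, "trims") <- do.call(rbind, trims)
  bundles
}

#' Unpaired nucleotide count for a vertex connection gap
#'
#' Converts the physical gap between two connected duplex ends into a number
#' of unpaired (single-stranded) nucleotides at the stated contour spacing,
#' rounding half-up. Applied independently to the scaffold and staple loop of
#' each connection.
#'
#' @param gap_nm gap distance(s), nm (>= 0).
#' @param spacing nm of contour length per unpaired nucleotide (default 0.42).
#' @return Integer vector of unpaired nucleotide counts.
#' @export
compute_unpaired_counts <- function(gap_nm, spacing = default_config()$unpaired_nt_spacing) {
  if (any(gap_nm < 0)) stop("gap distances must be >= 0")
  if (spacing <= 0) stop("spacing must be > 0")
  as.integer(round_half_up(gap_nm / spacing))
}

#' Build multiway vertex joints
#'
#' At every vertex, incident edge-ends are ordered by angle; each edge-end is
#' covalently connected to its counter-clockwise neighbour in all three
#' layers, pairing the duplex facing the wedge on each side. Every connection
#' records its gap distance and the unpaired scaffold/staple nucleotides that
#' absorb it, and the sense in which the scaffold strand crosses (fixed by
#' duplex polarity).
#'
#' @param bundles trimmed bundles from [trim_ends_to_bisector()].
#' @param dgeom the `discretized_geometry`.
#' @param config full or partial design configuration.
#' @return Data frame of connections, one row per (vertex, edge pair, layer).
#' @export
build_vertex_joints <- function(bundles, dgeom, config = list()) {
  cfg <- resolve_config(config)
  geom <- dgeom$geometry
  fans <- vertex_fan(geom)
  conns <- list()
  for (v in seq_along(fans)) {
    fan <- fans[[v]]
    if (is.null(fan)) next
    n <- nrow(fan)
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1          # CCW neighbour
      if (n == 2 && i == 2) j <- 1           # degree-2: second wedge wraps back
      ea <- fan$edge[i]; enda <- fan$end[i]
      eb <- fan$edge[j]; endb <- fan$end[j]
      ba <- bundles[[ea]]; bb <- bundles[[eb]]
      for (layer in 0:2) {
        ka_cand <- ba$helices$k[ba$helices$layer == layer]
        kb_cand <- bb$helices$k[bb$helices$layer == layer]
        ka <- ka_cand[vapply(ka_cand, function(k) u_out(ba, k, enda), 0) > 0]
        kb <- kb_cand[vapply(kb_cand, function(k) u_out(bb, k, endb), 0) < 0]
        stopifnot(length(ka) == 1, length(kb) == 1)
        pa <- helix_end_point(ba, ka, enda)
        pb <- helix_end_point(bb, kb, endb)
        gap <- sqrt(sum((pa - pb)^2))
        # scaffold sense: strand pointing into the vertex continues outward
        pol_a <- ba$helices$polarity[ba$helices$k == ka]
        a_into <- (enda == "B" && pol_a == 1L) || (enda == "A" && pol_a == -1L)
        unp <- compute_unpaired_counts(gap, cfg$unpaired_nt_spacing)
        conns[[length(conns) + 1L]] <- data.frame(
          vertex = v, layer = layer,
          edge_a = ea, end_a = enda, k_a = ka, hid_a = 6L * (ea - 1L) + ka + 1L,
          edge_b = eb, end_b = endb, k_b = kb, hid_b = 6L * (eb - 1L) + kb + 1L,
          gap_nm = gap, unpaired_scaffold = unp, unpaired_staple = unp,
          scaffold_a_to_b = a_into)
      }
    }
  }
  joints <- do.call(rbind, conns)
  # every duplex end must appear in exactly one same-layer connection
  ends <- c(paste(joints$hid_a, joints$end_a), paste(joints$hid_b, joints$end_b))
  if (anyDuplicated(ends))
    stop("internal error: a duplex end participates in more than one connection")
  joints
}
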