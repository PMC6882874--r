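#' Construct a 2D target geometry
#'
#' A target geometry is a connected planar straight-line graph: vertices in
#' nanometres, edges as 1-based vertex-index pairs. In `boundary_only` mode
#' the edges must form one or more simple closed polygons (an outer boundary
#' plus optional holes); in `boundary_internal` mode the graph is taken as the
#' complete wireframe, internal members included.
#'
#' @param vertices numeric matrix, n x 2, coordinates in nm.
#' @param edges integer matrix, m x 2, 1-based vertex indices.
#' @param mode `"boundary_internal"` or `"boundary_only"`.
#' @param faces optional list of integer vertex cycles (1-based).
#' @return An object of class `target_geometry`.
#' @export
target_geometry <- function(vertices, edges,
                            mode = c("boundary_internal", "boundary_only"),
                            faces = NULL) {
  mode <- match.arg(mode)
  vertices <- matrix(as.numeric(vertices), ncol = 2)
  edges <- matrix(as.integer(edges), ncol = 2)
  geom <- structure(list(vertices = vertices, edges = edges,
                         mode = mode, faces = faces),
                    class = "target_geometry")
  validate_geometry(geom)
  geom
}

#' @export
print.target_geometry <- function(x, ...) {
  cat(sprintf("target_geometry: %d vertices, %d edges, mode=%s\n",
              nrow(x$vertices), nrow(x$edges), x$mode))
  invisible(x)
}

edge_lengths <- function(geom) {
  p <- geom$vertices
  e <- geom$edges
  sqrt(rowSums((p[e[, 1], , drop = FALSE] - p[e[, 2], , drop = FALSE])^2))
}

validate_geometry <- function(geom) {
  v <- geom$vertices; e <- geom$edges
  if (nrow(v) < 2 || nrow(e) < 1)
    stop("geometry needs at least 2 vertices and 1 edge")
  if (any(!is.finite(v))) stop("non-finite vertex coordinates")
  if (any(e < 1L) || any(e > nrow(v)))
    stop("edge endpoint references a non-existent vertex")
  if (any(e[, 1] == e[, 2])) stop("self-loop edge (both endpoints identical)")
  len <- edge_lengths(geom)
  if (any(len < 1e-9)) stop("zero-length edge(s): ", paste(which(len < 1e-9), collapse = ", "))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (anyDuplicated(key)) stop("duplicate edge(s): ", paste(which(duplicated(key)), collapse = ", "))
  ## connectivity of the used vertex set
  used <- sort(unique(as.vector(e)))
  comp <- graph_components(nrow(v), e)
  if (length(unique(comp[used])) > 1)
    stop("edge set is disconnected: the wireframe must be a single connected graph")
  if (geom$mode == "boundary_only") {
    deg <- tabulate(as.vector(e), nbins = nrow(v))
    open_v <- which(deg[used] != 2L)
    if (length(open_v))
      stop("boundary_only geometry is not a union of closed polygons: ",
           "vertex degree != 2 at vertex index ", paste(used[open_v], collapse = ", "))
    if (polygon_self_intersects(v, e))
      stop("boundary_only geometry self-intersects: boundary must be simple polygons")
  }
  invisible(TRUE)
}

# connected components by BFS; returns component id per vertex
graph_components <- function(n, e) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(e))) {
    adj[[e[i, 1]]] <- c(adj[[e[i, 1]]], e[i, 2])
    adj[[e[i, 2]]] <- c(adj[[e[i, 2]]], e[i, 1])
  }
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L || is.null(adj[[s]])) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      for (y in adj[[x]]) if (comp[y] == 0L) { comp[y] <- cur; queue <- c(queue, y) }
    }
  }
  comp
}

# proper-crossing test between non-adjacent boundary segments (O(E^2), fine here)
polygon_self_intersects <- function(v, e) {
  m <- nrow(e)
  if (m < 4) return(FALSE)
  seg <- lapply(seq_len(m), function(i) rbind(v[e[i, 1], ], v[e[i, 2], ]))
  cross2 <- function(o, a, b) (a[1]-o[1])*(b[2]-o[2]) - (a[2]-o[2])*(b[1]-o[1])
  for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
    if (length(intersect(e[i, ], e[j, ]))) next  # shared endpoint
    a <- seg[[i]][1, ]; b <- seg[[i]][2, ]; c <- seg[[j]][1, ]; d <- seg[[j]][2, ]
    d1 <- cross2(a, b, c); d2 <- cross2(a, b, d)
    d3 <- cross2(c, d, a); d4 <- cross2(c, d, b)
    if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
  }
  FALSE
}

#' Read a 2D target geometry from file
#'
#' Accepts the plain-text `wf2d` CSV dialect (`v,x,y` vertex lines then
#' `e,i,j` edge lines with 0-based vertex indices; `#` comments) or an ASCII
#' PLY file with a vertex element (`x`,`y`, optional `z` which must be 0) and
#' an edge element (`vertex1`,`vertex2`). Coordinates are interpreted as nm.
#'
#' @param path file path; `.ply` files are parsed as PLY, anything else as wf2d.
#' @param mode geometry input mode, see [target_geometry()].
#' @return A validated `target_geometry`.
#' @export
read_geometry <- function(path, mode = c("boundary_internal", "boundary_only")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("geometry file not found: ", path)
  if (grepl("\\.ply$", path, ignore.case = TRUE)) read_geometry_ply(path, mode)
  else read_geometry_wf2d(path, mode)
}

read_geometry_wf2d <- function(path, mode) {
  lines <- readLines(path, warn = FALSE)
  vs <- list(); es <- list()
  for (k in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[k]))
    if (!nzchar(ln)) next
    f <- trimws(strsplit(ln, ",", fixed = TRUE)[[1]])
    tag <- f[1]
    if (tag == "v") {
      if (length(f) != 3 || anyNA(suppressWarnings(as.numeric(f[2:3]))))
        stop("wf2d parse error at line ", k, ": expected 'v,x,y'")
      vs[[length(vs) + 1L]] <- as.numeric(f[2:3])
    } else if (tag == "e") {
      ij <- suppressWarnings(as.integer(f[2:3]))
      if (length(f) != 3 || anyNA(ij))
        stop("wf2d parse error at line ", k, ": expected 'e,i,j'")
      es[[length(es) + 1L]] <- ij + 1L  # file is 0-based
    } else {
      stop("wf2d parse error at line ", k, ": unknown record '", tag, "'")
    }
  }
  if (!length(vs) || !length(es))
    stop("wf2d parse error: file must contain both vertex and edge records")
  target_geometry(do.call(rbind, vs), do.call(rbind, es), mode)
}

read_geometry_ply <- function(path, mode) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply")
    stop("PLY parse error at line 1: missing 'ply' magic")
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop("PLY parse error: no end_header")
  hdr <- trimws(lines[seq_len(hdr_end)])
  elems <- list(); cur <- NULL
  for (k in seq_along(hdr)) {
    f <- strsplit(hdr[k], "\\s+")[[1]]
    if (f[1] == "format" && f[2] != "ascii")
      stop("PLY parse error at line ", k, ": only ascii PLY is supported")
    if (f[1] == "element") {
      cur <- f[2]
      elems[[cur]] <- list(count = as.integer(f[3]), props = character())
    } else if (f[1] == "property" && !is.null(cur)) {
      elems[[cur]]$props <- c(elems[[cur]]$props, f[length(f)])
    }
  }
  if (is.null(elems$vertex)) stop("PLY parse error: no vertex element")
  if (is.null(elems$edge)) stop("PLY parse error: no edge element")
  body <- trimws(lines[(hdr_end + 1):length(lines)])
  body <- body[nzchar(body)]
  nv <- elems$vertex$count; ne <- elems$edge$count
  if (length(body) < nv + ne) stop("PLY parse error: truncated body")
  vp <- elems$vertex$props
  ix <- match(c("x", "y"), vp)
  if (anyNA(ix)) stop("PLY parse error: vertex element lacks x/y properties")
  vmat <- t(vapply(body[seq_len(nv)], function(ln) {
    as.numeric(strsplit(ln, "\\s+")[[1]])
  }, numeric(length(vp)), USE.NAMES = FALSE))
  if (!is.na(match("z", vp)) && any(abs(vmat[, match("z", vp)]) > 1e-6))
    stop("PLY geometry is not planar: nonzero z coordinates")
  ep <- elems$edge$props
  je <- match(c("vertex1", "vertex2"), ep)
  if (anyNA(je)) stop("PLY parse error: edge element lacks vertex1/vertex2")
  emat <- t(vapply(body[nv + seq_len(ne)], function(ln) {
    as.integer(strsplit(ln, "\\s+")[[1]])
  }, integer(length(ep)), USE.NAMES = FALSE))
  target_geometry(vmat[, ix, drop = FALSE], emat[, je, drop = FALSE] + 1L, mode)
}

#' Write a geometry in the wf2d dialect
#'
#' @param geom a `target_geometry`.
#' @param path output file path.
#' @export
write_geometry <- function(geom, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# wf2d geometry (coordinates in nm, 0-based edge indices)", con)
  for (i in seq_len(nrow(geom$vertices)))
    writeLines(sprintf("v,%.6f,%.6f", geom$vertices[i, 1], geom$vertices[i, 2]), con)
  for (i in seq_len(nrow(geom$edges)))
    writeLines(sprintf("e,%d,%d", geom$edges[i, 1] - 1L, geom$edges[i, 2] - 1L), con)
  invisible(path)
}

#' Generate a regular polygon geometry
#'
#' Vertices lie on the circle of radius `circumradius` centred at the origin,
#' the first vertex at +90 degrees, in counter-clockwise order; all edge
#' chords have length `2 R sin(pi/N)`.
#'
#' @param n_sides number of sides, >= 3.
#' @param circumradius circumscribed-circle radius in nm.
#' @return `target_geometry` in `boundary_only` mode.
#' @export
generate_regular_polygon <- function(n_sides, circumradius) {
  n_sides <- as.integer(n_sides)
  if (n_sides < 3L) stop("a polygon needs n_sides >= 3")
  if (!is.finite(circumradius) || circumradius <= 0) stop("circumradius must be > 0")
  ang <- pi / 2 + 2 * pi * (seq_len(n_sides) - 1L) / n_sides
  v <- cbind(circumradius * cos(ang), circumradius * sin(ang))
  e <- cbind(seq_len(n_sides), c(seq_len(n_sides)[-1], 1L))
  target_geometry(v, e, mode = "boundary_only")
}

## ---- internal meshing ------------------------------------------------------

signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

# ordered vertex cycle of a degree-2 boundary graph, starting at the lowest index
boundary_cycle <- function(geom) {
  e <- geom$edges
  used <- sort(unique(as.vector(e)))
  adj <- lapply(seq_len(nrow(geom$vertices)), function(i)
    sort(unique(c(e[e[, 1] == i, 2], e[e[, 2] == i, 1]))))
  start <- used[1]
  cyc <- start; prev <- NA_integer_; cur <- start
  repeat {
    nb <- adj[[cur]]
    nxt <- if (is.na(prev)) nb[1] else setdiff(nb, prev)[1]
    if (nxt == start) break
    cyc <- c(cyc, nxt); prev <- cur; cur <- nxt
  }
  if (length(cyc) != length(used))
    stop("automatic meshing supports a single boundary polygon (no holes)")
  cyc
}

in_circle <- function(a, b, c, d) {
  # >0 when d is inside the circumcircle of CCW triangle (a,b,c)
  m <- rbind(c(a - d, sum((a - d)^2)),
             c(b - d, sum((b - d)^2)),
             c(c - d, sum((c - d)^2)))
  det(m)
}

point_in_polygon <- function(pt, poly) {
  n <- nrow(poly); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (((poly[i, 2] > pt[2]) != (poly[j, 2] > pt[2])) &&
        (pt[1] < (poly[j, 1] - poly[i, 1]) * (pt[2] - poly[i, 2]) /
           (poly[j, 2] - poly[i, 2]) + poly[i, 1])) inside <- !inside
    j <- i
  }
  inside
}

# ear-clipping triangulation of a simple polygon given as CCW index cycle
ear_clip <- function(pts, cyc) {
  tri <- list()
  idx <- cyc
  cross2 <- function(o, a, b) (a[1]-o[1])*(b[2]-o[2]) - (a[2]-o[2])*(b[1]-o[1])
  pt_in_tri <- function(p, a, b, c) {
    d1 <- cross2(a, b, p); d2 <- cross2(b, c, p); d3 <- cross2(c, a, p)
    (d1 >= -1e-12) && (d2 >= -1e-12) && (d3 >= -1e-12)
  }
  guard <- 0L
  while (length(idx) > 3) {
    n <- length(idx); clipped <- FALSE
    for (k in seq_len(n)) {
      i0 <- idx[if (k == 1) n else k - 1]; i1 <- idx[k]; i2 <- idx[if (k == n) 1 else k + 1]
      a <- pts[i0, ]; b <- pts[i1, ]; c <- pts[i2, ]
      if (cross2(a, b, c) <= 1e-12) next         # reflex or degenerate corner
      others <- setdiff(idx, c(i0, i1, i2))
      blocked <- FALSE
      for (o in others) if (pt_in_tri(pts[o, ], a, b, c)) { blocked <- TRUE; break }
      if (blocked) next
      tri[[length(tri) + 1L]] <- c(i0, i1, i2)
      idx <- idx[-k]; clipped <- TRUE
      break
    }
    if (!clipped) stop("meshing failure: degenerate boundary near vertex ", idx[1])
    guard <- guard + 1L
    if (guard > 10000L) stop("meshing failure: ear clipping did not terminate")
  }
  tri[[length(tri) + 1L]] <- idx
  tri
}

# Lawson flips toward the Delaunay criterion; triangles are CCW index triplets
lawson_flip <- function(pts, tri, fixed_edges) {
  ekey <- function(i, j) paste(min(i, j), max(i, j))
  fixed <- ekey(fixed_edges[, 1], fixed_edges[, 2])
  repeat {
    changed <- FALSE
    # map interior edges to the two triangles sharing them
    emap <- new.env(parent = emptyenv())
    for (t in seq_along(tri)) {
      tr <- tri[[t]]
      for (s in 1:3) {
        k <- ekey(tr[s], tr[if (s == 3) 1 else s + 1])
        assign(k, c(mget(k, envir = emap, ifnotfound = list(integer()))[[1]], t), envir = emap)
      }
    }
    for (k in ls(emap)) {
      ts <- get(k, envir = emap)
      if (length(ts) != 2 || k %in% fixed) next
      ij <- as.integer(strsplit(k, " ")[[1]])
      t1 <- tri[[ts[1]]]; t2 <- tri[[ts[2]]]
      p <- setdiff(t1, ij); q <- setdiff(t2, ij)
      if (length(p) != 1 || length(q) != 1 || p == q) next
      # flip if the opposite vertex lies inside the circumcircle
      a <- pts[t1[1], ]; b <- pts[t1[2], ]; c <- pts[t1[3], ]
      if (in_circle(a, b, c, pts[q, ]) > 1e-9) {
        # new triangles (p, i, q) and (p, q, j), kept CCW
        mk <- function(u, v, w) {
          tr <- c(u, v, w)
          if (signed_area(pts[tr, , drop = FALSE]) < 0) tr <- rev(tr)
          tr
        }
        # convexity check of the quad: both new triangles must have positive area
        n1 <- c(p, ij[1], q); n2 <- c(p, q, ij[2])
        a1 <- signed_area(pts[n1, , drop = FALSE]); a2 <- signed_area(pts[n2, , drop = FALSE])
        if (abs(a1) < 1e-12 || abs(a2) < 1e-12) next
        tri[[ts[1]]] <- mk(p, ij[1], q)
        tri[[ts[2]]] <- mk(p, q, ij[2])
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  tri
}

mesh_edges <- function(tri) {
  e <- do.call(rbind, lapply(tri, function(tr)
    rbind(tr[c(1, 2)], tr[c(2, 3)], tr[c(3, 1)])))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Generate an internal mesh for a boundary-only geometry
#'
#' Triangulates the interior of a simple boundary polygon (ear clipping
#' followed by Lawson flips toward the Delaunay criterion). When the coarse
#' triangulation contains interior edges longer than `target_edge_len`, one
#' Steiner point is inserted at the polygon centroid and the triangulation is
#' re-flipped (for a regular polygon this yields the spoke fan). With
#' `mesh_type = "quadrilateral"`, triangles are greedily paired across shared
#' interior diagonals into convex quadrilaterals.
#'
#' @param geom `target_geometry` in boundary_only mode (single polygon).
#' @param mesh_type `"triangular"` or `"quadrilateral"`.
#' @param target_edge_len target internal edge length, nm.
#' @return `target_geometry` in boundary_internal mode with a `faces` list.
#' @export
generate_internal_mesh <- function(geom, mesh_type = c("triangular", "quadrilateral"),
                                   target_edge_len) {
  mesh_type <- match.arg(mesh_type)
  if (geom$mode != "boundary_only")
    stop("generate_internal_mesh expects a boundary_only geometry")
  cyc <- boundary_cycle(geom)
  pts <- geom$vertices
  if (signed_area(pts[cyc, , drop = FALSE]) < 0) cyc <- rev(cyc)
  tri <- ear_clip(pts, cyc)
  tri <- lawson_flip(pts, tri, geom$edges)
  # one centroid Steiner point if the coarse interior edges are too long
  bkey <- paste(pmin(geom$edges[, 1], geom$edges[, 2]),
                pmax(geom$edges[, 1], geom$edges[, 2]))
  me <- mesh_edges(tri)
  interior <- !(paste(me[, 1], me[, 2]) %in% bkey)
  if (any(interior)) {
    elen <- sqrt(rowSums((pts[me[, 1], , drop = FALSE] - pts[me[, 2], , drop = FALSE])^2))
    if (max(elen[interior]) > target_edge_len) {
      cen <- colMeans(pts[cyc, , drop = FALSE])
      if (point_in_polygon(cen, pts[cyc, , drop = FALSE])) {
        pts <- rbind(pts, cen); ci <- nrow(pts)
        hit <- which(vapply(tri, function(tr) {
          cross2 <- function(o, a, b) (a[1]-o[1])*(b[2]-o[2]) - (a[2]-o[2])*(b[1]-o[1])
          a <- pts[tr[1], ]; b <- pts[tr[2], ]; c <- pts[tr[3], ]
          cross2(a, b, cen) >= -1e-9 && cross2(b, c, cen) >= -1e-9 && cross2(c, a, cen) >= -1e-9
        }, logical(1)))[1]
        tr <- tri[[hit]]
        tri[[hit]] <- NULL
        tri <- c(tri, list(c(tr[1], tr[2], ci), c(tr[2], tr[3], ci), c(tr[3], tr[1], ci)))
        tri <- lawson_flip(pts, tri, geom$edges)
      }
    }
  }
  faces <- tri
  if (mesh_type == "quadrilateral") {
    paired <- pair_triangles(pts, tri, bkey)
    faces <- paired
  }
  edges <- unique(do.call(rbind, lapply(faces, function(f) {
    n <- length(f)
    cbind(pmin(f, f[c(2:n, 1)]), pmax(f, f[c(2:n, 1)]))
  })))
  out <- target_geometry(pts, edges, mode = "boundary_internal", faces = faces)
  out
}

# greedy pairing of adjacent triangles into convex quads (longest diagonal first)
pair_triangles <- function(pts, tri, boundary_keys) {
  ekey <- function(i, j) paste(min(i, j), max(i, j))
  emap <- list()
  for (t in seq_along(tri)) {
    tr <- tri[[t]]
    for (s in 1:3) {
      k <- ekey(tr[s], tr[if (s == 3) 1 else s + 1])
      emap[[k]] <- c(emap[[k]], t)
    }
  }
  cand <- names(emap)[vapply(emap, length, 1L) == 2 & !(names(emap) %in% boundary_keys)]
  dlen <- vapply(cand, function(k) {
    ij <- as.integer(strsplit(k, " ")[[1]])
    sqrt(sum((pts[ij[1], ] - pts[ij[2], ])^2))
  }, numeric(1))
  cand <- cand[order(-dlen)]
  used <- logical(length(tri)); quads <- list()
  for (k in cand) {
    ts <- emap[[k]]
    if (any(used[ts])) next
    ij <- as.integer(strsplit(k, " ")[[1]])
    p <- setdiff(tri[[ts[1]]], ij); q <- setdiff(tri[[ts[2]]], ij)
    quad <- c(p, ij[1], q, ij[2])
    if (signed_area(pts[quad, , drop = FALSE]) < 0) quad <- rev(quad)
    # convexity: all cross products same sign
    n <- 4; ok <- TRUE
    for (s in 1:4) {
      o <- pts[quad[s], ]; a <- pts[quad[s %% 4 + 1], ]; b <- pts[quad[(s + 1) %% 4 + 1], ]
      if ((a[1]-o[1])*(b[2]-o[2]) - (a[2]-o[2])*(b[1]-o[1]) <= 1e-12) { ok <- FALSE; break }
    }
    if (!ok) next
    used[ts] <- TRUE
    quads[[length(quads) + 1L]] <- quad
  }
  if (!all(used))
    stop("cannot form an all-quadrilateral mesh: ", sum(!used),
         " unpaired triangle(s); use mesh_type='triangular'")
  quads
}

## ---- scaling & discretization ----------------------------------------------

#' Scale a geometry and discretize its edges into base pairs
#'
#' The geometry is uniformly scaled so that the anchor condition holds, then
#' each edge receives `ceiling(length_nm / rise)` base pairs. Edge lengths are
#' free: they are not required to be multiples of a full helical turn.
#'
#' @param geom `target_geometry`.
#' @param scale_source one of `"shortest_edge_bp"` (anchor: the shortest edge
#'   gets `value` bp), `"circumradius_nm"` (anchor: the maximum vertex distance
#'   from the vertex centroid becomes `value` nm) or `"direct_nm"` (no scaling;
#'   `value` ignored).
#' @param value anchor value (bp or nm per `scale_source`).
#' @param config full or partial design configuration, see [default_config()].
#' @return A `discretized_geometry`: the scaled geometry plus `bp_per_edge`.
#' @export
scale_and_discretize <- function(geom,
                                 scale_source = c("shortest_edge_bp",
                                                  "circumradius_nm", "direct_nm"),
                                 value = NULL, config = list()) {
  scale_source <- match.arg(scale_source)
  cfg <- resolve_config(config)
  rise <- cfg$rise_per_bp
  len <- edge_lengths(geom)
  s <- switch(scale_source,
    shortest_edge_bp = {
      if (is.null(value) || value <= 0) stop("value must be a positive bp count")
      if (value < cfg$min_edge_bp)
        stop("anchor bp count ", value, " is below the minimum edge length (",
             cfg$min_edge_bp, " bp)")
      value * rise / min(len)
    },
    circumradius_nm = {
      if (is.null(value) || value <= 0) stop("value must be a positive radius in nm")
      cen <- colMeans(geom$vertices)
      value / max(sqrt(rowSums(sweep(geom$vertices, 2, cen)^2)))
    },
    direct_nm = 1.0
  )
  scaled <- geom
  scaled$vertices <- geom$vertices * s
  bp <- as.integer(ceiling(len * s / rise - 1e-9))
  bad <- which(bp < cfg$min_edge_bp)
  if (length(bad))
    stop("edge(s) shorter than the ", cfg$min_edge_bp, "-bp minimum after scaling: ",
         paste(sprintf("edge %d (%d bp)", bad, bp[bad]), collapse = ", "))
  structure(list(geometry = scaled, bp_per_edge = bp, rise = rise,
                 scale_source = scale_source, scale_factor = s, config = cfg),
            class = "discretized_geometry")
}

#' @export
print.discretized_geometry <- function(x, ...) {
  cat(sprintf("discretized_geometry: %d edges, bp per edge [%s], rise %.2f nm/bp\n",
              length(x$bp_per_edge),
              paste(x$bp_per_edge, collapse = ", "), x$rise))
  invisible(x)
}
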