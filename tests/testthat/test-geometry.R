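test_that("wf2d parsing round-trips a triangle and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# a triangle", "v,0,0", "v,40,0", "v,20,30",
               "e,0,1", "e,1,2", "e,2,0"), f)
  g <- read_geometry(f, "boundary_internal")
  expect_s3_class(g, "target_geometry")
  expect_equal(nrow(g$vertices), 3)
  expect_equal(nrow(g$edges), 3)
  expect_equal(g$vertices[2, ], c(40, 0))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("v,0,0", "v,1,0", "x,nonsense"), bad)
  expect_error(read_geometry(bad), "line 3")

  # boundary_only input whose edges do not close a polygon
  open_f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("v,0,0", "v,40,0", "v,20,30", "e,0,1", "e,1,2"), open_f)
  expect_error(read_geometry(open_f, "boundary_only"), "degree")
})

test_that("ASCII PLY star outline parses to a 10-vertex, 10-edge geometry", {
  ang <- pi / 2 + 2 * pi * (0:9) / 10
  r <- ifelse(0:9 %% 2 == 0, 30, 12)
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 10", "property float x", "property float y",
               "element edge 10", "property int vertex1", "property int vertex2",
               "end_header",
               sprintf("%.4f %.4f", r * cos(ang), r * sin(ang)),
               sprintf("%d %d", 0:9, c(1:9, 0))), f)
  g <- read_geometry(f, "boundary_only")
  expect_equal(nrow(g$vertices), 10)
  expect_equal(nrow(g$edges), 10)
})

test_that("geometry validation catches broken graphs", {
  expect_error(target_geometry(rbind(c(0, 0), c(1, 0)), rbind(c(1, 3)), "boundary_internal"),
               "non-existent")
  expect_error(target_geometry(rbind(c(0, 0), c(0, 0), c(1, 0)),
                               rbind(c(1, 2), c(2, 3)), "boundary_internal"),
               "zero-length")
  expect_error(target_geometry(rbind(c(0, 0), c(1, 0), c(0, 1)),
                               rbind(c(1, 2), c(1, 2)), "boundary_internal"),
               "duplicate")
  # two disjoint segments
  expect_error(target_geometry(rbind(c(0, 0), c(1, 0), c(5, 5), c(6, 5)),
                               rbind(c(1, 2), c(3, 4)), "boundary_internal"),
               "disconnected")
})

test_that("regular polygons have the exact chord edge length 2 R sin(pi/N)", {
  g3 <- generate_regular_polygon(3, 25)
  expect_equal(unique(round(edge_lengths(g3), 6)), round(2 * 25 * sin(pi / 3), 6))
  expect_equal(edge_lengths(g3)[1], 43.3013, tolerance = 1e-4)  # approx 43 nm
  g6 <- generate_regular_polygon(6, 25)
  expect_equal(edge_lengths(g6), rep(25, 6), tolerance = 1e-12)  # hexagon = R
  g4 <- generate_regular_polygon(4, 25)
  expect_equal(edge_lengths(g4)[1], 2 * 25 * sin(pi / 4), tolerance = 1e-12) # 35.355
  # first vertex at +90 degrees
  expect_equal(g3$vertices[1, ], c(0, 25), tolerance = 1e-9)
})

test_that("internal meshing: triangle stays itself, square gains one diagonal,
           hexagon at target ~R fans from a centroid Steiner point", {
  tri <- generate_regular_polygon(3, 25)
  m <- generate_internal_mesh(tri, "triangular", 100)
  expect_equal(nrow(m$edges), 3)
  expect_equal(length(m$faces), 1)

  sq <- generate_regular_polygon(4, 25)
  m <- generate_internal_mesh(sq, "triangular", 100)   # coarse target
  expect_equal(nrow(m$edges), 5)                       # 4 sides + 1 diagonal
  expect_equal(length(m$faces), 2)

  hx <- generate_regular_polygon(6, 25)
  m <- generate_internal_mesh(hx, "triangular", 25)    # target ~ R
  expect_equal(nrow(m$vertices), 7)                    # centroid Steiner point
  expect_equal(length(m$faces), 6)                     # 6-triangle fan
  expect_equal(nrow(m$edges), 12)                      # 6 sides + 6 spokes
})

test_that("mesh output satisfies Euler's formula V - E + F = 2", {
  for (n in c(4, 5, 6, 8)) {
    m <- generate_internal_mesh(generate_regular_polygon(n, 25), "triangular", 20)
    V <- nrow(m$vertices); E <- nrow(m$edges); F <- length(m$faces) + 1L # + outer
    expect_equal(V - E + F, 2, info = paste("n =", n))
  }
})

test_that("quadrilateral meshing pairs triangles into convex quads", {
  sq <- generate_regular_polygon(4, 25)
  m <- generate_internal_mesh(sq, "quadrilateral", 100)
  expect_equal(length(m$faces), 1)
  expect_equal(length(m$faces[[1]]), 4)
})

test_that("ceiling discretization reproduces the R = 25 nm polygon series", {
  mk <- function(n) {
    g <- generate_regular_polygon(n, 25); g$mode <- "boundary_internal"
    scale_and_discretize(g, "circumradius_nm", 25)
  }
  expect_equal(unique(mk(3)$bp_per_edge), 128L)   # triangle
  expect_equal(unique(mk(6)$bp_per_edge), 74L)    # hexagon
  expect_equal(unique(mk(8)$bp_per_edge), 57L)    # octagon
  # the ceiling rule gives 104 for the square (2*25*sin(45)/0.34 = 103.99)
  expect_equal(unique(mk(4)$bp_per_edge), 104L)
})

test_that("discretization is scale-consistent and monotone", {
  # same bp counts whether the polygon starts at unit radius or at 25 nm
  g1 <- generate_regular_polygon(5, 1);  g1$mode <- "boundary_internal"
  g2 <- generate_regular_polygon(5, 25); g2$mode <- "boundary_internal"
  d1 <- scale_and_discretize(g1, "circumradius_nm", 25)
  d2 <- scale_and_discretize(g2, "circumradius_nm", 25)
  expect_equal(d1$bp_per_edge, d2$bp_per_edge)

  # monotone: longer edges never get fewer bp
  set.seed(42)
  v <- cbind(runif(8, 0, 80), runif(8, 0, 80))
  e <- cbind(1:7, 2:8)
  g <- target_geometry(v, e, "boundary_internal")
  d <- scale_and_discretize(g, "shortest_edge_bp", 50)
  len <- edge_lengths(g)
  expect_true(all(diff(d$bp_per_edge[order(len)]) >= 0))
})

test_that("edges below the minimum bp length are rejected with the edge named", {
  g <- target_geometry(rbind(c(0, 0), c(10, 0), c(10, 2)),
                       rbind(c(1, 2), c(2, 3), c(3, 1)), "boundary_internal")
  expect_error(scale_and_discretize(g, "direct_nm", 1), "edge")
  expect_error(scale_and_discretize(g, "shortest_edge_bp", 10), "minimum")
})
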