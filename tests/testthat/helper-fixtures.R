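## shared fixtures, memoized so expensive designs are built once per run

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache, inherits = FALSE))
    assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache, inherits = FALSE)
}

# bare regular polygon design (no internal mesh), R = 25 nm unless stated
fixture_polygon_design <- function(n, value = 25, source = "circumradius_nm") {
  memo(paste0("poly_", n, "_", source, "_", value), {
    g <- generate_regular_polygon(n, 25)
    g$mode <- "boundary_internal"
    design_origami(g, scale_source = source, value = value)
  })
}

fixture_triangle84 <- function() {
  memo("tri84", {
    g <- generate_regular_polygon(3, 25)
    g$mode <- "boundary_internal"
    design_origami(g, "shortest_edge_bp", 84)
  })
}

fixture_triangle84_model <- function() {
  memo("tri84_model", build_atomic_model(fixture_triangle84()))
}

# synthetic triangular bp-centre trajectory: one atom per bp group, centres
# laid out along the sides of an arbitrary triangle
triangle_center_traj <- function(verts, M = 80, z = 0) {
  stopifnot(nrow(verts) == 3)
  verts <- cbind(verts, rep(z, 3))[, 1:3]
  if (ncol(verts) < 3) verts <- cbind(verts, 0)
  pts <- list()
  for (e in 1:3) {
    a <- verts[e, ]; b <- verts[e %% 3 + 1, ]
    f <- (seq_len(M) - 0.5) / M
    pts[[e]] <- cbind(a[1] + f * (b[1] - a[1]),
                      a[2] + f * (b[2] - a[2]),
                      a[3] + f * (b[3] - a[3]))
  }
  all_pts <- do.call(rbind, pts)
  coords <- array(0, dim = c(1, nrow(all_pts), 3))
  coords[1, , ] <- all_pts
  bp_map <- data.frame(eleno = seq_len(nrow(all_pts)),
                       edge = rep(1:3, each = M), m = rep(seq_len(M), 3))
  trajectory(coords, bp_map)
}

# triangle with prescribed interior angles (A at origin), unit-free scale
triangle_from_angles <- function(A_deg, B_deg, scale = 100) {
  C_deg <- 180 - A_deg - B_deg
  stopifnot(C_deg > 0)
  # side c from A to B along +x; vertex C above
  a <- scale * sin(A_deg * pi / 180) / sin(C_deg * pi / 180)
  Cx <- scale - a * cos(B_deg * pi / 180)
  Cy <- a * sin(B_deg * pi / 180)
  rbind(c(0, 0), c(scale, 0), c(Cx, Cy))
}

# independent Kabsch superposition (SVD), used as the RMSD/RMSF oracle
kabsch_fit <- function(ref, mob) {
  # ref, mob: N x 3
  cr <- colMeans(ref); cm <- colMeans(mob)
  R0 <- sweep(ref, 2, cr); M0 <- sweep(mob, 2, cm)
  s <- svd(t(M0) %*% R0)
  d <- sign(det(s$v %*% t(s$u)))
  U <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(M0 %*% U, 2, cr, "+")
}

brute_rmsd <- function(ref, mob_fitted) {
  sqrt(mean(rowSums((ref - mob_fitted)^2)))
}

# hand-written base-by-base complement (test oracle, independent of Biostrings)
comp_base <- function(b) c(A = "T", T = "A", G = "C", C = "G")[b]
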