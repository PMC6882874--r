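test_that("bp group centres are unweighted means of their atoms", {
  coords <- array(0, dim = c(1, 4, 3))
  coords[1, 1, ] <- c(0, 0, 0); coords[1, 2, ] <- c(2, 0, 0)
  coords[1, 3, ] <- c(5, 5, 5); coords[1, 4, ] <- c(9, 9, 9)
  bp_map <- data.frame(eleno = 1:4, edge = 1L, m = c(1L, 1L, 2L, 3L))
  # two atoms -> their midpoint; single-atom group -> that atom
  tr <- suppressWarnings(trajectory(coords, bp_map))
  cen <- bp_centers(tr, 1)[["1"]]
  expect_equal(cen[1, ], c(1, 0, 0))
  expect_equal(cen[2, ], c(5, 5, 5))
  expect_equal(cen[3, ], c(9, 9, 9))
  # duplicate atom assignment is rejected
  expect_error(trajectory(coords, data.frame(eleno = c(1, 1), edge = 1, m = 1:2)),
               "more than one")
})

test_that("synthetic-helix centres land on the known axis", {
  # atoms placed symmetrically around the x axis
  M <- 30; per <- 4
  pts <- do.call(rbind, lapply(seq_len(M), function(i) {
    ang <- 2 * pi * (seq_len(per) - 1) / per + i
    cbind(i * 3.4, 9 * cos(ang), 9 * sin(ang))
  }))
  coords <- array(0, dim = c(1, nrow(pts), 3)); coords[1, , ] <- pts
  tr <- trajectory(coords, data.frame(eleno = seq_len(nrow(pts)),
                                      edge = 1L, m = rep(seq_len(M), each = per)))
  cen <- bp_centers(tr, 1)[["1"]]
  expect_equal(cen[, 2], rep(0, M), tolerance = 1e-12)
  expect_equal(cen[, 3], rep(0, M), tolerance = 1e-12)
})

test_that("edge basis: orientation conventions and degeneracy handling", {
  cen <- cbind(seq(0, 99), 0, 0)
  b <- edge_basis(cen + cbind(0, stats::rnorm(100, 0, 1e-3), 0), L = 20)
  expect_equal(abs(sum(b$b1 * c(1, 0, 0))), 1, tolerance = 1e-6)
  expect_gt(sum(b$b1 * c(1, 0, 0)), 0)         # points c_1 -> c_M
  expect_gt(sum(b$e1 * c(1, 0, 0)), 0)
  # reversing the bp order flips b1
  b_rev <- edge_basis(cen[100:1, ] + cbind(0, stats::rnorm(100, 0, 1e-3), 0), L = 20)
  expect_lt(sum(b_rev$b1 * c(1, 0, 0)), 0)
  # planar scatter: b3 is the plane normal; right-handed triple
  set.seed(2)
  cloud <- cbind(seq(0, 99), stats::rnorm(100, 0, 3), stats::rnorm(100, 0, 1e-4))
  bp <- edge_basis(cloud, L = 20)
  expect_equal(abs(sum(bp$b3 * c(0, 0, 1))), 1, tolerance = 1e-6)
  cross <- c(bp$b1[2] * bp$b2[3] - bp$b1[3] * bp$b2[2],
             bp$b1[3] * bp$b2[1] - bp$b1[1] * bp$b2[3],
             bp$b1[1] * bp$b2[2] - bp$b1[2] * bp$b2[1])
  expect_equal(cross, bp$b3, tolerance = 1e-9)
  # exactly collinear points are rank-1: degenerate
  expect_error(edge_basis(cen, L = 20), "degenerate")
})

test_that("internal angles recover constructed triangle angles to 1e-6 deg", {
  # ideal equilateral triangle of synthetic centres
  eq <- triangle_center_traj(triangle_from_angles(60, 60))
  th <- internal_angles(eq, 1, L = 40)
  expect_equal(th$theta, rep(60, 3), tolerance = 1e-9)
  expect_equal(th$theta_mean, 60, tolerance = 1e-9)
  # a 70/55/55 triangle against the direct two-vector oracle
  v <- triangle_from_angles(70, 55)
  tr <- triangle_center_traj(v)
  th <- internal_angles(tr, 1, L = 40)
  oracle <- vapply(1:3, function(i) {
    p <- v[i, ]; q <- v[i %% 3 + 1, ]; r <- v[(i + 1) %% 3 + 1, ]
    u1 <- q - p; u2 <- r - p
    acos(sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))) * 180 / pi
  }, 1)
  expect_equal(sort(th$theta), sort(oracle), tolerance = 1e-6)
  # sweep: constructed angles across [20, 160] are recovered
  for (A in c(20, 45, 90, 120, 160)) {
    B <- (180 - A) / 2
    tri <- triangle_center_traj(triangle_from_angles(A, B))
    got <- internal_angles(tri, 1, L = 40)
    expect_equal(sort(got$theta)[ifelse(A < 60, 1, 3)], A, tolerance = 1e-6,
                 info = paste("A =", A))
  }
})

test_that("out-of-plane angles: planar zero, analytic tilt, reflection invariance", {
  flat <- triangle_center_traj(triangle_from_angles(60, 60))
  om <- out_of_plane_angles(flat, 1, L = 40)
  expect_equal(om$omega, rep(0, 3), tolerance = 1e-9)

  # tilt edge 3 (v3 -> v1) by 10 degrees about the opposite edge's axis
  # (the line through edge 1, v1 -> v2); edge 3 pivots at v1
  v <- triangle_from_angles(60, 60)
  v3d <- cbind(v, 0)
  M <- 80
  tr <- triangle_center_traj(v)
  coords <- tr$coords
  axis <- (v3d[2, ] - v3d[1, ]) / sqrt(sum((v3d[2, ] - v3d[1, ])^2))
  ang <- 10 * pi / 180
  a <- axis; c_ <- cos(ang); s_ <- sin(ang); C <- 1 - c_
  R <- matrix(c(a[1]^2*C+c_, a[1]*a[2]*C-a[3]*s_, a[1]*a[3]*C+a[2]*s_,
                a[1]*a[2]*C+a[3]*s_, a[2]^2*C+c_, a[2]*a[3]*C-a[1]*s_,
                a[1]*a[3]*C-a[2]*s_, a[2]*a[3]*C+a[1]*s_, a[3]^2*C+c_),
              3, 3, byrow = TRUE)
  rot <- function(p) as.numeric(R %*% (p - v3d[1, ])) + v3d[1, ]
  sel <- 2 * M + seq_len(M)   # third edge's centres
  coords[1, sel, ] <- t(apply(coords[1, sel, ], 1, rot))
  tilted <- trajectory(coords, tr$bp_map)
  om_t <- out_of_plane_angles(tilted, 1, L = 40)
  # analytic oracle: exact away-from-vertex direction vectors per vertex
  cen <- bp_centers(tilted, 1)
  mids <- t(vapply(cen, function(m) m[40, ], numeric(3)))
  w1 <- mids[2, ] - mids[1, ]; w2 <- mids[3, ] - mids[1, ]
  nrm <- c(w1[2]*w2[3]-w1[3]*w2[2], w1[3]*w2[1]-w1[1]*w2[3],
           w1[1]*w2[2]-w1[2]*w2[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  v3p <- rot(v3d[3, ])                    # moved far end of edge 3
  pairs <- list(list(u = rot(v3d[3, ]) - v3d[1, ], w = v3d[2, ] - v3d[1, ]), # at v1
                list(u = v3d[1, ] - v3d[2, ], w = v3d[3, ] - v3d[2, ]),      # at v2
                list(u = v3d[2, ] - v3d[3, ], w = v3d[1, ] - v3p))           # at v3
  want <- vapply(pairs, function(p) {
    en <- c(p$u[2]*p$w[3]-p$u[3]*p$w[2], p$u[3]*p$w[1]-p$u[1]*p$w[3],
            p$u[1]*p$w[2]-p$u[2]*p$w[1])
    acos(abs(sum(en * nrm)) / sqrt(sum(en^2))) * 180 / pi
  }, 1)
  expect_equal(sort(om_t$omega), sort(want), tolerance = 1e-6)
  expect_gt(max(om_t$omega), 1)   # the tilt is visible

  # reflection through the plane leaves omega unchanged
  coords_ref <- tilted$coords; coords_ref[1, , 3] <- -coords_ref[1, , 3]
  om_r <- out_of_plane_angles(trajectory(coords_ref, tr$bp_map), 1, L = 40)
  expect_equal(sort(om_r$omega), sort(om_t$omega), tolerance = 1e-9)
})

test_that("RMSD: identity, rigid motion and displaced-atom formula", {
  set.seed(4)
  N <- 100
  ref <- matrix(stats::rnorm(N * 3, sd = 20), N, 3)
  mk_traj <- function(frames) {
    coords <- array(0, dim = c(length(frames), N, 3))
    for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
    trajectory(coords, data.frame(eleno = 1:N, edge = 1, m = 1:N))
  }
  # identical frames -> 0
  r0 <- rmsd_series(mk_traj(list(ref, ref, ref)))
  expect_equal(r0$rmsd, rep(0, 3), tolerance = 1e-8)
  # rigid rotation + translation removed by superposition
  ang <- 0.7; Rz <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  moved <- sweep(ref %*% Rz, 2, c(10, -4, 2), "+")
  r1 <- rmsd_series(mk_traj(list(ref, moved)))
  expect_equal(r1$rmsd[2], 0, tolerance = 1e-8)
  # one atom displaced by d: compare against the independent Kabsch oracle
  d <- 5
  disp <- ref; disp[1, 1] <- disp[1, 1] + d
  r2 <- rmsd_series(mk_traj(list(ref, disp)))
  fitted <- kabsch_fit(ref, disp)
  expect_equal(r2$rmsd[2], brute_rmsd(ref, fitted), tolerance = 1e-6)
  expect_equal(r2$rmsd[2], d / sqrt(N), tolerance = 0.02)
  # bin means over stated windows
  frames <- list(ref, disp, ref, disp)
  rb <- rmsd_series(mk_traj(frames), bins = list(c(0, 2), c(2, 4)))
  expect_equal(length(rb$bin_means), 2)
  expect_equal(rb$grand_mean, mean(rb$bin_means))
})

test_that("RMSF: static zero, oscillator amplitude, rigid-motion invariance", {
  set.seed(5)
  N <- 120; nf <- 40
  base <- matrix(stats::rnorm(N * 3, sd = 30), N, 3)
  coords <- array(0, dim = c(nf, N, 3))
  for (f in seq_len(nf)) coords[f, , ] <- base
  tr <- trajectory(coords, data.frame(eleno = 1:N, edge = 1, m = 1:N))
  expect_equal(max(rmsf_atoms(tr)), 0, tolerance = 1e-8)
  # one atom oscillating +/- a along x
  a <- 3
  osc <- coords
  for (f in seq_len(nf)) osc[f, 7, 1] <- base[7, 1] + a * (-1)^f
  tr_o <- trajectory(osc, data.frame(eleno = 1:N, edge = 1, m = 1:N))
  rf <- rmsf_atoms(tr_o)
  expect_equal(unname(rf["7"]), a, tolerance = 0.05)
  expect_lt(max(rf[names(rf) != "7"]), 0.2)
  # adding a global rigid motion to every frame changes nothing
  ang <- 0.3; Rz <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  osc2 <- osc
  for (f in seq_len(nf)) osc2[f, , ] <- sweep(osc[f, , ] %*% Rz, 2, c(5, 5, -2), "+")
  rf2 <- rmsf_atoms(trajectory(osc2, data.frame(eleno = 1:N, edge = 1, m = 1:N)))
  expect_equal(unname(rf2), unname(rf), tolerance = 1e-6)
})

test_that("synthetic trajectories: zero noise is static, seeds reproduce", {
  m <- fixture_triangle84_model()
  s0 <- synth_trajectory(m, sd_theta = 0, sd_omega = 0, noise_A = 0,
                         n_frames = 5, seed = 9)
  ser <- angle_series(s0$traj, L = 40)
  expect_lt(stats::sd(ser$theta_mean), 1e-9)
  expect_equal(mean(ser$theta_mean), 60, tolerance = 0.2)
  s1 <- synth_trajectory(m, 3, 3, 1, n_frames = 3, seed = 11)
  s2 <- synth_trajectory(m, 3, 3, 1, n_frames = 3, seed = 11)
  expect_identical(s1$traj$coords, s2$traj$coords)
  expect_identical(s1$truth, s2$truth)
})

test_that("trajectory IO round-trips through XYZ and multi-model PDB", {
  m <- fixture_triangle84_model()
  s <- synth_trajectory(m, 2, 2, 0.5, n_frames = 3, seed = 2)
  f <- withr::local_tempfile(fileext = ".xyz")
  write_traj_xyz(s$traj, f)
  back <- read_traj_xyz(f, m$bp_map)
  expect_equal(back$n_frames, 3)
  expect_equal(back$coords[2, 5, ], s$traj$coords[2, 5, ], tolerance = 1e-3)
  th1 <- internal_angles(s$traj, 2, L = 40)
  th2 <- internal_angles(back, 2, L = 40)
  expect_equal(th1$theta_mean, th2$theta_mean, tolerance = 1e-2)
  # bp map JSON round trip
  bj <- withr::local_tempfile(fileext = ".json")
  write_bp_map(m, bj)
  bm <- read_bp_map(bj)
  expect_equal(bm$eleno, m$bp_map$eleno)
  expect_equal(bm$m, m$bp_map$m)
})
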