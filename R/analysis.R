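## Trajectory geometry analysis: bp centres, per-edge principal-axis bases,
## internal vertex angles (theta), out-of-plane angles (omega), RMSD and RMSF.
##
## The angle procedure works on per-edge point clouds of bp group centres
## (the sextet of bp sharing an axial index, for 6HB edges): a right-handed
## orthonormal basis is fitted from the principal axes of the centres, edge
## end vectors from the first/last L centres, the object plane from the three
## mid-edge centres, and the vertex angles from the projected (theta) or
## unprojected-cross (omega) end vectors.

#' Construct a trajectory object
#'
#' @param coords numeric array frames x atoms x 3, Angstrom.
#' @param bp_map data frame with columns `eleno` (atom index into the atom
#'   dimension), `edge`, `m` (1-based bp index along the edge).
#' @param dt_ns sampling interval in ns/frame.
#' @return A `trajectory` object.
#' @export
trajectory <- function(coords, bp_map, dt_ns = 1) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (any(bp_map$eleno > dim(coords)[2]))
    stop("bp map references atoms beyond the trajectory")
  if (anyDuplicated(bp_map$eleno))
    stop("an atom maps to more than one bp group")
  M <- tapply(bp_map$m, bp_map$edge, max)
  structure(list(coords = coords, bp_map = bp_map, dt_ns = dt_ns,
                 n_frames = dim(coords)[1], n_atoms = dim(coords)[2],
                 edges = sort(unique(bp_map$edge)), M = M),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, %d edges (M = %s), dt %.3g ns\n",
              x$n_frames, x$n_atoms, length(x$edges),
              paste(x$M, collapse = ","), x$dt_ns))
  invisible(x)
}

#' Single-frame trajectory from an atomic model
#'
#' @param model an `atomic_model`.
#' @return A one-frame `trajectory` over the model's mapped atoms.
#' @export
traj_from_model <- function(model) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  coords <- array(0, dim = c(1, nrow(xyz), 3))
  coords[1, , ] <- xyz
  trajectory(coords, model$bp_map, dt_ns = 1)
}

#' Per-edge bp group centres at one frame
#'
#' The centre of axial index i is the unweighted mean of the coordinates of
#' all atoms in that bp group (the bp sextet for a 6HB edge).
#'
#' @param traj a `trajectory`.
#' @param frame frame number (1-based).
#' @return Named list (by edge) of M x 3 matrices.
#' @export
bp_centers <- function(traj, frame = 1) {
  xyz <- traj$coords[frame, , ]
  out <- list()
  for (e in traj$edges) {
    sel <- traj$bp_map[traj$bp_map$edge == e, ]
    if (!nrow(sel)) stop("empty bp group set for edge ", e)
    M <- max(sel$m)
    cen <- matrix(NA_real_, M, 3)
    sums <- rowsum(xyz[sel$eleno, , drop = FALSE], sel$m)
    cnt <- as.integer(table(factor(sel$m, levels = sort(unique(sel$m)))))
    got <- sort(unique(sel$m))
    cen[got, ] <- sums / cnt
    if (anyNA(cen)) stop("empty bp group(s) on edge ", e, ": index ",
                         paste(which(is.na(cen[, 1])), collapse = ","))
    out[[as.character(e)]] <- cen
  }
  out
}

principal_axis <- function(pts) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)
  list(center = ctr, axes = ev$vectors, values = ev$values)
}

#' Principal-axis basis of one edge's bp centres
#'
#' `b1` is the first principal axis pointing from `c_1` to `c_M`; `b2` the
#' second, pointing from the object centroid outward (inner to outer bp);
#' `b3` completes the right-handed orthonormal triple. `e1` is the first
#' principal axis of the first `L` centres, pointing from `c_1` to `c_L`.
#'
#' @param centers M x 3 matrix of bp group centres.
#' @param L end-region length in bp.
#' @param object_centroid 3-vector used to orient `b2` outward; defaults to
#'   the centroid of `centers`.
#' @return List with `b1`, `b2`, `b3`, `e1`, `center`.
#' @export
edge_basis <- function(centers, L, object_centroid = NULL) {
  M <- nrow(centers)
  if (M < 3) stop("need at least 3 bp centres")
  if (L > M) stop("L exceeds the number of bp centres")
  pa <- principal_axis(centers)
  if (pa$values[2] < 1e-18)
    stop("degenerate bp-centre cloud (rank < 2)")
  b1 <- pa$axes[, 1]
  span <- centers[M, ] - centers[1, ]
  if (sum(b1 * span) < 0) b1 <- -b1
  b2 <- pa$axes[, 2]
  ref <- if (is.null(object_centroid)) pa$center else object_centroid
  outward <- pa$center - ref
  if (sum(outward^2) > 1e-18 && sum(b2 * outward) < 0) b2 <- -b2
  b3 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  e1 <- principal_axis(centers[seq_len(L), , drop = FALSE])$axes[, 1]
  if (sum(e1 * (centers[L, ] - centers[1, ])) < 0) e1 <- -e1
  list(b1 = b1, b2 = b2, b3 = b3, e1 = e1, center = pa$center)
}

# end vector of an edge at one of its two ends, over L centres, pointing
# away from the end (into the edge)
edge_end_vector <- function(centers, L, end) {
  M <- nrow(centers)
  idx <- if (end == 1L) seq_len(L) else seq(M - L + 1L, M)
  v <- principal_axis(centers[idx, , drop = FALSE])$axes[, 1]
  sense <- if (end == 1L) centers[idx[L], ] - centers[idx[1], ]
           else centers[idx[1], ] - centers[idx[L], ]
  if (sum(v * sense) < 0) v <- -v
  v
}

mid_index <- function(M) if (M %% 2 == 0) M %/% 2 else M %/% 2 + 1L

# pair up edge ends into vertices by proximity of terminal centres
match_vertices <- function(cen) {
  ends <- do.call(rbind, lapply(seq_along(cen), function(i) {
    M <- nrow(cen[[i]])
    rbind(c(i, 1, cen[[i]][1, ]), c(i, 2, cen[[i]][M, ]))
  }))
  n <- nrow(ends)
  d <- as.matrix(stats::dist(ends[, 3:5]))
  diag(d) <- Inf
  used <- logical(n); pairs <- list()
  repeat {
    d[used, ] <- Inf; d[, used] <- Inf
    # never pair the two ends of one edge
    if (all(!is.finite(d))) break
    ij <- arrayInd(which.min(d), dim(d))
    i <- ij[1]; j <- ij[2]
    if (ends[i, 1] == ends[j, 1]) { d[i, j] <- Inf; d[j, i] <- Inf; next }
    pairs[[length(pairs) + 1L]] <- data.frame(
      edge_l = ends[i, 1], end_l = ends[i, 2],
      edge_r = ends[j, 1], end_r = ends[j, 2])
    used[c(i, j)] <- TRUE
    if (all(used)) break
  }
  do.call(rbind, pairs)
}

# plane normal from the three mid-edge centres
plane_normal <- function(cen) {
  mids <- t(vapply(cen, function(m) m[mid_index(nrow(m)), ], numeric(3)))
  v1 <- mids[2, ] - mids[1, ]; v2 <- mids[3, ] - mids[1, ]
  n <- c(v1[2] * v2[3] - v1[3] * v2[2],
         v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("degenerate mid-edge plane")
  n / nn
}

vec_angle_deg <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) stop("zero-norm vector in angle computation")
  acos(max(-1, min(1, sum(a * b) / (na * nb)))) * 180 / pi
}

#' Internal vertex angles of a triangular object at one frame
#'
#' Fits the object plane through the three mid-edge bp centres, projects the
#' two end vectors meeting at each vertex into that plane, and reports the
#' angle between the projections, in degrees, plus their mean.
#'
#' @param traj a `trajectory` of a 3-edge object.
#' @param frame frame number.
#' @param L end-region length in bp; default 20 below 60 bp edges, else 40.
#' @return List: `theta` (per vertex), `theta_mean`, `c_norm`.
#' @export
internal_angles <- function(traj, frame = 1, L = NULL) {
  cen <- bp_centers(traj, frame)
  if (length(cen) != 3) stop("internal_angles expects a triangular (3-edge) object")
  if (is.null(L)) { Mmin <- min(vapply(cen, nrow, 1L)); L <- if (Mmin >= 60) 40L else min(20L, Mmin) }
  cn <- plane_normal(cen)
  vx <- match_vertices(cen)
  theta <- numeric(nrow(vx))
  for (i in seq_len(nrow(vx))) {
    el <- edge_end_vector(cen[[vx$edge_l[i]]], L, vx$end_l[i])
    er <- edge_end_vector(cen[[vx$edge_r[i]]], L, vx$end_r[i])
    elp <- el - sum(el * cn) * cn
    erp <- er - sum(er * cn) * cn
    theta[i] <- vec_angle_deg(elp, erp)
  }
  list(theta = theta, theta_mean = mean(theta), c_norm = cn, vertices = vx)
}

#' Out-of-plane vertex angles of a triangular object at one frame
#'
#' The vertex normal is the cross product of the two (unprojected) end
#' vectors; omega is its angle to the object-plane normal, folded into
#' [0, 90] degrees.
#'
#' @inheritParams internal_angles
#' @return List: `omega` (per vertex), `omega_mean`.
#' @export
out_of_plane_angles <- function(traj, frame = 1, L = NULL) {
  cen <- bp_centers(traj, frame)
  if (length(cen) != 3) stop("out_of_plane_angles expects a triangular object")
  if (is.null(L)) { Mmin <- min(vapply(cen, nrow, 1L)); L <- if (Mmin >= 60) 40L else min(20L, Mmin) }
  cn <- plane_normal(cen)
  vx <- match_vertices(cen)
  omega <- numeric(nrow(vx))
  for (i in seq_len(nrow(vx))) {
    el <- edge_end_vector(cen[[vx$edge_l[i]]], L, vx$end_l[i])
    er <- edge_end_vector(cen[[vx$edge_r[i]]], L, vx$end_r[i])
    en <- c(el[2] * er[3] - el[3] * er[2],
            el[3] * er[1] - el[1] * er[3],
            el[1] * er[2] - el[2] * er[1])
    if (sqrt(sum(en^2)) < 1e-12) stop("degenerate vertex normal (parallel edges)")
    a <- vec_angle_deg(en, cn)
    omega[i] <- min(a, 180 - a)
  }
  list(omega = omega, omega_mean = mean(omega))
}

#' Angle time series over all frames
#'
#' @inheritParams internal_angles
#' @return Data frame: frame, time_ns, theta columns (per vertex and mean),
#'   omega columns (per vertex and mean).
#' @export
angle_series <- function(traj, L = NULL) {
  rows <- lapply(seq_len(traj$n_frames), function(f) {
    th <- internal_angles(traj, f, L)
    om <- out_of_plane_angles(traj, f, L)
    data.frame(frame = f, time_ns = (f - 1) * traj$dt_ns,
               theta_1 = th$theta[1], theta_2 = th$theta[2], theta_3 = th$theta[3],
               theta_mean = th$theta_mean,
               omega_1 = om$omega[1], omega_2 = om$omega[2], omega_3 = om$omega[3],
               omega_mean = om$omega_mean)
  })
  do.call(rbind, rows)
}

## ---- RMSD / RMSF -----------------------------------------------------------

#' Per-frame RMSD after rigid superposition, with bin averages
#'
#' Each frame is optimally superposed onto the reference frame over all
#' mapped atoms (bio3d least-squares fitting), then the RMSD over those atoms
#' is taken. Bin means are computed over time windows in ns.
#'
#' @param traj a `trajectory`.
#' @param reference_frame reference frame (default 1, i.e. t = 0).
#' @param bins list of `c(lo, hi)` time windows in ns, or NULL.
#' @return List: `rmsd` (per frame, Angstrom), `time_ns`, `bin_means`,
#'   `grand_mean` (mean over bins, or over all frames when `bins` is NULL).
#' @export
rmsd_series <- function(traj, reference_frame = 1, bins = NULL) {
  atoms <- sort(traj$bp_map$eleno)
  nf <- traj$n_frames
  flat <- matrix(0, nf, length(atoms) * 3)
  for (f in seq_len(nf))
    flat[f, ] <- as.numeric(t(traj$coords[f, atoms, ]))
  ref <- flat[reference_frame, ]
  fitted <- bio3d::fit.xyz(fixed = ref, mobile = flat,
                           fixed.inds = seq_along(ref),
                           mobile.inds = seq_along(ref))
  r <- vapply(seq_len(nf), function(f)
    sqrt(sum((ref - fitted[f, ])^2) / length(atoms)), numeric(1))
  time_ns <- (seq_len(nf) - 1) * traj$dt_ns
  bin_means <- NULL
  if (!is.null(bins)) {
    bin_means <- vapply(bins, function(w) {
      sel <- time_ns >= w[1] & time_ns < w[2]
      if (!any(sel)) return(NA_real_)
      mean(r[sel])
    }, numeric(1))
  }
  grand <- if (is.null(bin_means)) mean(r) else mean(bin_means, na.rm = TRUE)
  list(rmsd = r, time_ns = time_ns, bin_means = bin_means, grand_mean = grand)
}

#' Per-atom RMSF after superposition
#'
#' All frames are superposed onto the reference, and each mapped atom's RMS
#' fluctuation about its time-average position is reported.
#'
#' @param traj a `trajectory` (>= 2 frames).
#' @param reference_frame frame used for superposition.
#' @return Numeric vector, one value per mapped atom (Angstrom), named by
#'   atom index.
#' @export
rmsf_atoms <- function(traj, reference_frame = 1) {
  if (traj$n_frames < 2) stop("RMSF needs at least 2 frames")
  atoms <- sort(traj$bp_map$eleno)
  nf <- traj$n_frames
  flat <- matrix(0, nf, length(atoms) * 3)
  for (f in seq_len(nf))
    flat[f, ] <- as.numeric(t(traj$coords[f, atoms, ]))
  fitted <- bio3d::fit.xyz(fixed = flat[reference_frame, ], mobile = flat,
                           fixed.inds = seq_len(ncol(flat)),
                           mobile.inds = seq_len(ncol(flat)))
  out <- bio3d::rmsf(fitted)
  names(out) <- atoms
  out
}

## ---- synthetic trajectories ------------------------------------------------

rot_axis_angle <- function(axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle_rad); s_ <- sin(angle_rad); C <- 1 - c_
  matrix(c(a[1]^2 * C + c_,       a[1] * a[2] * C - a[3] * s_, a[1] * a[3] * C + a[2] * s_,
           a[1] * a[2] * C + a[3] * s_, a[2]^2 * C + c_,       a[2] * a[3] * C - a[1] * s_,
           a[1] * a[3] * C - a[2] * s_, a[2] * a[3] * C + a[1] * s_, a[3]^2 * C + c_),
         3, 3, byrow = TRUE)
}

#' Synthetic perturbed trajectory of an atomic model
#'
#' Generates frames by rotating each edge's atoms rigidly about the edge
#' midpoint: an in-plane rotation drawn from N(0, sd_theta/sqrt(2)) (so that
#' the angle between two independently perturbed edges has standard
#' deviation `sd_theta`) and an out-of-plane tilt from N(0, sd_omega/sqrt(2)),
#' plus isotropic Gaussian atomic noise. Ground-truth per-frame angles are
#' computed by applying the same angle procedure to the exactly rotated ideal
#' bp-centre polylines.
#'
#' @param model an `atomic_model`.
#' @param sd_theta in-plane angular noise, degrees (sd of the vertex angle).
#' @param sd_omega out-of-plane tilt noise, degrees.
#' @param noise_A isotropic per-atom Gaussian noise sd, Angstrom.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param dt_ns sampling interval.
#' @return List: `traj` (a `trajectory`), `truth` (data frame of ground-truth
#'   theta/omega means per frame).
#' @export
synth_trajectory <- function(model, sd_theta = 3, sd_omega = 3, noise_A = 1,
                             n_frames = 100, seed = 1L, dt_ns = 1) {
  set.seed(as.integer(seed))
  a <- model$atoms
  mapped <- !a$unpaired
  edges <- sort(unique(a$edge[mapped]))
  xyz0 <- as.matrix(a[, c("x", "y", "z")])
  ## ideal bp-centre polylines per edge (frame 0)
  base_traj <- traj_from_model(model)
  cen0 <- bp_centers(base_traj, 1)
  coords <- array(NA_real_, dim = c(n_frames, nrow(a), 3))
  truth <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- xyz0
    cenf <- cen0
    for (ei in seq_along(edges)) {
      e <- edges[ei]
      cen_mat <- cen0[[as.character(e)]]
      mid <- colMeans(cen_mat)
      axis_dir <- cen_mat[nrow(cen_mat), ] - cen_mat[1, ]
      axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
      tilt_axis <- c(-axis_dir[2], axis_dir[1], 0)  # in-plane, perp. to edge
      d_in <- stats::rnorm(1, 0, sd_theta / sqrt(2)) * pi / 180
      d_out <- stats::rnorm(1, 0, sd_omega / sqrt(2)) * pi / 180
      R <- rot_axis_angle(tilt_axis, d_out) %*% rot_axis_angle(c(0, 0, 1), d_in)
      sel <- which(a$edge == e & !is.na(a$edge))
      xyz[sel, ] <- sweep(sweep(xyz[sel, , drop = FALSE], 2, mid) %*% t(R), 2, mid, "+")
      cenf[[as.character(e)]] <- sweep(sweep(cen_mat, 2, mid) %*% t(R), 2, mid, "+")
    }
    ## unmapped (unpaired) atoms stay put; add isotropic noise everywhere
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise_A), nrow(xyz), 3)
    coords[f, , ] <- xyz
    th <- angles_from_centers(cenf, L = NULL)
    truth[[f]] <- data.frame(frame = f,
                             theta_1 = th$theta[1], theta_2 = th$theta[2],
                             theta_3 = th$theta[3], theta_mean = th$theta_mean,
                             omega_mean = th$omega_mean)
  }
  list(traj = trajectory(coords, model$bp_map, dt_ns),
       truth = do.call(rbind, truth))
}

# angle procedure applied directly to exact centre polylines (ground truth)
angles_from_centers <- function(cen, L = NULL) {
  if (is.null(L)) { Mmin <- min(vapply(cen, nrow, 1L)); L <- if (Mmin >= 60) 40L else min(20L, Mmin) }
  cn <- plane_normal(cen)
  vx <- match_vertices(cen)
  theta <- numeric(nrow(vx)); omega <- numeric(nrow(vx))
  for (i in seq_len(nrow(vx))) {
    el <- edge_end_vector(cen[[vx$edge_l[i]]], L, vx$end_l[i])
    er <- edge_end_vector(cen[[vx$edge_r[i]]], L, vx$end_r[i])
    elp <- el - sum(el * cn) * cn; erp <- er - sum(er * cn) * cn
    theta[i] <- vec_angle_deg(elp, erp)
    en <- c(el[2] * er[3] - el[3] * er[2],
            el[3] * er[1] - el[1] * er[3],
            el[1] * er[2] - el[2] * er[1])
    aa <- vec_angle_deg(en, cn)
    omega[i] <- min(aa, 180 - aa)
  }
  list(theta = theta, theta_mean = mean(theta),
       omega = omega, omega_mean = mean(omega))
}

## ---- trajectory IO ---------------------------------------------------------

#' Write a trajectory in the whitespace XYZ-per-frame dialect
#'
#' Each frame: a line with the atom count, a comment line, then one
#' `x y z` line per atom (Angstrom).
#'
#' @param traj a `trajectory`.
#' @param path output path.
#' @export
write_traj_xyz <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(traj$n_frames)) {
    writeLines(as.character(traj$n_atoms), con)
    writeLines(sprintf("frame %d t= %.4f ns", f, (f - 1) * traj$dt_ns), con)
    m <- traj$coords[f, , ]
    writeLines(sprintf("%.4f %.4f %.4f", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Read a whitespace XYZ-per-frame trajectory
#'
#' @param path file written by [write_traj_xyz()] (or compatible).
#' @param bp_map bp grouping map (see [trajectory()]).
#' @param dt_ns sampling interval.
#' @return A `trajectory`.
#' @export
read_traj_xyz <- function(path, bp_map, dt_ns = 1) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("XYZ parse error at line ", i, ": expected atom count")
    block <- lines[(i + 2L):(i + 1L + n)]
    m <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), function(f)
      as.numeric(f[(length(f) - 2):length(f)])))
    frames[[length(frames) + 1L]] <- m
    i <- i + 2L + n
  }
  coords <- array(0, dim = c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  trajectory(coords, bp_map, dt_ns)
}

#' Read a multi-model PDB as a trajectory
#'
#' @param path multi-model PDB file.
#' @param bp_map bp grouping map.
#' @param dt_ns sampling interval.
#' @return A `trajectory`.
#' @export
read_traj_pdb <- function(path, bp_map, dt_ns = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  nf <- nrow(xyz); na <- ncol(xyz) / 3
  coords <- array(0, dim = c(nf, na, 3))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  trajectory(coords, bp_map, dt_ns)
}
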