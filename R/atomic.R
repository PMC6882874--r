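## Ground-state atomic model generation and PDB / oxDNA export.
##
## Each base pair is modelled by placing a fixed coarse base-pair template on
## the helix-axis frame of its duplex: 0.34 nm rise, 34.3 deg/bp right-handed
## twist, one template per strand (three pseudo-atoms per nucleotide: P, C1'
## and the glycosidic base nitrogen) at B-form radii. Staple nucleotides sit
## across the minor groove at +154 deg from their scaffold partner. Unpaired
## vertex-loop nucleotides are placed by linear interpolation between the
## flanking duplex positions (they are unstructured single strands).

ATOM_TEMPLATE <- data.frame(
  elety = c("P", "C1'", "N9"),
  radius_nm = c(0.89, 0.585, 0.25),
  dangle = c(0, -25, -10))   # degrees relative to the backbone angle

TWIST_DEG_PER_BP <- 360 / 10.5     # 34.2857 deg (10.5 bp/turn)
STAPLE_GROOVE_DEG <- 154           # minor-groove offset of the partner strand

# backbone angular position of the scaffold strand of one helix at bp t
backbone_angle <- function(t) t * TWIST_DEG_PER_BP

# 3D centre (nm) of bp t on helix hid, from the bundle list
bp_center_3d <- function(bundles, hid, t) {
  e <- (hid - 1L) %/% 6L + 1L
  k <- (hid - 1L) %% 6L
  b <- bundles[[e]]
  h <- b$helices[b$helices$k == k, ]
  xy <- b$anchor + b$dir * (t + 0.5) * b$rise + b$normal * h$u
  cbind(xy[1], xy[2], h$w)
}

#' Build the ground-state atomic model of a design
#'
#' @param design an `origami_design`.
#' @return An `atomic_model`: `atoms` data frame (coordinates in Angstrom,
#'   PDB-style fields, provenance columns `edge`, `bp`, `helix`, `strand`)
#'   and `bp_map` (atom index -> edge, bp index m = 1..M).
#' @export
build_atomic_model <- function(design) {
  bundles <- design$bundles
  rt <- design$strands$seq_assign$routing_ordered
  base_by_node <- design$strands$seq_assign$base_by_node
  idx <- design$routing$idx
  chain_pool <- c(LETTERS[-1], letters, as.character(0:9))
  nt <- list()
  ## scaffold chain (paired positions in routing order; vertex loops ss)
  n_rt <- nrow(rt)
  for (i in seq_len(n_rt)) {
    nt[[length(nt) + 1L]] <- data.frame(
      chain = "A", kind = "scaffold", node = rt$node[i],
      helix = rt$helix[i], bp = rt$bp[i],
      base = base_by_node[rt$node[i]], unpaired = FALSE)
    if (rt$unpaired_after[i] > 0L)
      nt[[length(nt) + 1L]] <- data.frame(
        chain = "A", kind = "scaffold", node = NA_integer_,
        helix = NA_integer_, bp = NA_integer_,
        base = "N", unpaired = TRUE)[rep(1, rt$unpaired_after[i]), ]
  }
  ## staple chains
  for (s in seq_along(design$strands$staples)) {
    st <- design$strands$staples[[s]]
    ch <- chain_pool[(s - 1L) %% length(chain_pool) + 1L]
    seq_chars <- strsplit(st$sequence, "")[[1]]
    p <- 0L
    for (j in seq_len(nrow(st$path))) {
      it <- st$path[j, ]
      if (it$unpaired) {
        for (q in seq_len(it$n_nt)) {
          p <- p + 1L
          nt[[length(nt) + 1L]] <- data.frame(
            chain = ch, kind = "staple", node = NA_integer_,
            helix = NA_integer_, bp = NA_integer_, base = seq_chars[p],
            unpaired = TRUE)
        }
      } else {
        p <- p + 1L
        nt[[length(nt) + 1L]] <- data.frame(
          chain = ch, kind = "staple", node = it$node,
          helix = it$helix, bp = it$bp, base = seq_chars[p], unpaired = FALSE)
      }
    }
  }
  nt <- do.call(rbind, nt)
  rownames(nt) <- NULL
  ## positions: paired nts from helix frames, unpaired by interpolation
  ctr <- matrix(NA_real_, nrow(nt), 3)
  paired <- which(!nt$unpaired)
  for (i in paired) {
    cen <- bp_center_3d(bundles, nt$helix[i], nt$bp[i])
    ctr[i, ] <- cen * 10    # nm -> Angstrom
  }
  # scaffold-strand backbone angle at each paired position
  beta <- ifelse(nt$kind == "staple",
                 backbone_angle(nt$bp) + STAPLE_GROOVE_DEG,
                 backbone_angle(nt$bp))
  ## frame vectors per paired nt (normal/out-of-plane of its edge)
  nvec <- matrix(NA_real_, nrow(nt), 3); zvec <- matrix(NA_real_, nrow(nt), 3)
  for (i in paired) {
    e <- (nt$helix[i] - 1L) %/% 6L + 1L
    b <- bundles[[e]]
    nvec[i, ] <- c(b$normal, 0)
    zvec[i, ] <- c(0, 0, 1)
  }
  ## interpolate unpaired positions between flanking paired neighbours (per chain)
  for (ch in unique(nt$chain[nt$unpaired])) {
    sel <- which(nt$chain == ch)
    loc_p <- sel[!nt$unpaired[sel]]
    for (i in sel[nt$unpaired[sel]]) {
      prv <- loc_p[loc_p < i]; nxt <- loc_p[loc_p > i]
      a <- if (length(prv)) max(prv) else max(loc_p)
      b <- if (length(nxt)) min(nxt) else min(loc_p)
      span <- if (b > a) (b - a) else 2
      f <- if (b > a) (i - a) / span else 0.5
      ctr[i, ] <- ctr[a, ] * (1 - f) + ctr[b, ] * f
      nvec[i, ] <- nvec[a, ]; zvec[i, ] <- zvec[a, ]
      beta[i] <- 0
    }
  }
  ## expand nucleotides into template atoms
  natom_per_nt <- nrow(ATOM_TEMPLATE)
  n_nt <- nrow(nt)
  rep_i <- rep(seq_len(n_nt), each = natom_per_nt)
  ang <- (beta[rep_i] + ATOM_TEMPLATE$dangle) * pi / 180
  rad <- ATOM_TEMPLATE$radius_nm * 10
  radial <- nvec[rep_i, ] * cos(ang) + zvec[rep_i, ] * sin(ang)
  xyz <- ctr[rep_i, ] + radial * rad
  atoms <- data.frame(
    elety = rep(ATOM_TEMPLATE$elety, n_nt),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    chain = nt$chain[rep_i],
    resid = paste0("D", ifelse(nt$base[rep_i] == "N", "T", nt$base[rep_i])),
    kind = nt$kind[rep_i],
    helix = nt$helix[rep_i], bp = nt$bp[rep_i],
    unpaired = nt$unpaired[rep_i])
  atoms$edge <- ifelse(is.na(atoms$helix), NA_integer_, (atoms$helix - 1L) %/% 6L + 1L)
  ## residue numbering, 1-based per chain
  nt_id_in_chain <- stats::ave(rep_i, nt$chain[rep_i], FUN = function(v) {
    match(v, unique(v))
  })
  atoms$resno <- nt_id_in_chain
  atoms$eleno <- seq_len(nrow(atoms))
  if (anyDuplicated(atoms$eleno)) stop("internal error: overlapping atom ids")
  ## bp grouping: only complete sextets (axial indices where all six duplexes
  ## of the edge still have a bp after end trimming), so group centres sit on
  ## the edge axis; m is renumbered 1..M within the complete range
  bp_map <- atoms[!atoms$unpaired, c("eleno", "edge", "bp")]
  rng <- do.call(rbind, lapply(seq_along(bundles), function(e) {
    h <- bundles[[e]]$helices
    data.frame(edge = e, lo = max(h$lo), hi = min(h$hi))
  }))
  bp_map <- merge(bp_map, rng, by = "edge")
  bp_map <- bp_map[bp_map$bp >= bp_map$lo & bp_map$bp < bp_map$hi, ]
  bp_map <- bp_map[order(bp_map$eleno), ]
  bp_map$m <- bp_map$bp - bp_map$lo + 1L
  structure(list(atoms = atoms, bp_map = bp_map[, c("eleno", "edge", "m")],
                 n_nt = n_nt, design_bp = design$dgeom$bp_per_edge),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic_model: %d nucleotides, %d atoms, %d edges\n",
              x$n_nt, nrow(x$atoms), length(x$design_bp)))
  invisible(x)
}

#' Write an atomic model to PDB
#'
#' @param model an `atomic_model`.
#' @param path output PDB path.
#' @export
write_pdb_model <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid, eleno = a$eleno,
                   elety = a$elety, chain = substr(a$chain, 1, 1))
  invisible(path)
}

#' Write the base-pair grouping map as JSON
#'
#' Maps each atom serial to its (edge, bp index) group for trajectory
#' analysis.
#'
#' @param model an `atomic_model`.
#' @param path output JSON path.
#' @export
write_bp_map <- function(model, path) {
  jsonlite::write_json(model$bp_map, path, dataframe = "columns", digits = NA)
  invisible(path)
}

#' Read a base-pair grouping map from JSON
#'
#' @param path JSON written by [write_bp_map()].
#' @return Data frame with columns `eleno`, `edge`, `m`.
#' @export
read_bp_map <- function(path) {
  df <- jsonlite::fromJSON(path)
  as.data.frame(df)
}

## ---- oxDNA export ----------------------------------------------------------

OXDNA_LENGTH_NM <- 0.8518   # one oxDNA simulation unit in nm

#' Write oxDNA topology and configuration files
#'
#' The topology lists one line per nucleotide (strand id, base, 3' and 5'
#' neighbour); the scaffold strand is circular, staples are linear. The
#' configuration holds positions (oxDNA simulation units) and unit backbone
#' and normal versors consistent with the atomic-model helix frames.
#'
#' @param design an `origami_design`.
#' @param model its `atomic_model` (provides per-nucleotide frames).
#' @param top_path,conf_path output paths.
#' @export
write_oxdna <- function(design, model, top_path, conf_path) {
  a <- model$atoms
  first <- a[a$elety == ATOM_TEMPLATE$elety[1], ]   # one row per nucleotide
  nts <- data.frame(chain = first$chain, kind = first$kind,
                    base = sub("^D", "", first$resid),
                    x = NA_real_, y = NA_real_, z = NA_real_)
  # nucleotide centre = mean over its template atoms
  grp <- rep(seq_len(model$n_nt), each = nrow(ATOM_TEMPLATE))
  k <- nrow(ATOM_TEMPLATE)
  nts$x <- rowsum(a$x, grp)[, 1] / k
  nts$y <- rowsum(a$y, grp)[, 1] / k
  nts$z <- rowsum(a$z, grp)[, 1] / k
  chains <- unique(nts$chain)
  strand_id <- match(nts$chain, chains)
  n <- nrow(nts)
  n3 <- integer(n); n5 <- integer(n)
  for (s in seq_along(chains)) {
    ii <- which(strand_id == s)
    circ <- s == 1L                       # scaffold circular
    n5[ii] <- c(if (circ) ii[length(ii)] else -1L, ii[-length(ii)]) - 1L
    n3[ii] <- c(ii[-1], if (circ) ii[1] else -1L) - 1L
    if (!circ) { n5[ii[1]] <- -1L; n3[ii[length(ii)]] <- -1L }
  }
  ## topology
  con <- file(top_path, "w")
  writeLines(sprintf("%d %d", n, length(chains)), con)
  writeLines(sprintf("%d %s %d %d", strand_id, nts$base, n3, n5), con)
  close(con)
  ## configuration: positions in su; backbone-base versor from atom template,
  ## normal versor along the strand direction
  pos <- as.matrix(nts[, c("x", "y", "z")]) / 10 / OXDNA_LENGTH_NM
  nxt <- ifelse(n3 >= 0, n3 + 1L, NA_integer_)
  prv <- ifelse(n5 >= 0, n5 + 1L, NA_integer_)
  nrm <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    j <- if (!is.na(nxt[i])) nxt[i] else i
    k <- if (!is.na(prv[i])) prv[i] else i
    d <- pos[j, ] - pos[k, ]
    if (sqrt(sum(d^2)) < 1e-9) d <- c(0, 0, 1)
    nrm[i, ] <- d / sqrt(sum(d^2))
  }
  # backbone vector: perpendicular component of the template P direction
  bvec <- matrix(0, n, 3)
  patom <- as.matrix(a[a$elety == "P", c("x", "y", "z")]) / 10 / OXDNA_LENGTH_NM
  for (i in seq_len(n)) {
    d <- patom[i, ] - pos[i, ]
    d <- d - sum(d * nrm[i, ]) * nrm[i, ]
    if (sqrt(sum(d^2)) < 1e-9) {
      d <- c(1, 0, 0) - nrm[i, 1] * nrm[i, ]
    }
    bvec[i, ] <- d / sqrt(sum(d^2))
  }
  box <- max(apply(pos, 2, function(v) diff(range(v)))) * 2 + 10
  con <- file(conf_path, "w")
  writeLines(c("t = 0", sprintf("b = %.4f %.4f %.4f", box, box, box),
               "E = 0 0 0"), con)
  writeLines(sprintf(
    "%.6f %.6f %.6f %.6f %.6f %.6f %.6f %.6f %.6f 0 0 0 0 0 0",
    pos[, 1], pos[, 2], pos[, 3],
    bvec[, 1], bvec[, 2], bvec[, 3],
    nrm[, 1], nrm[, 2], nrm[, 3]), con)
  close(con)
  invisible(c(top_path, conf_path))
}

#' Read back an oxDNA topology
#'
#' @param top_path topology file from [write_oxdna()].
#' @return List: `n_nucleotides`, `n_strands`, `strand_lengths`, `bases`.
#' @export
read_oxdna_topology <- function(top_path) {
  lines <- readLines(top_path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- strsplit(trimws(lines[-1]), "\\s+")
  sid <- vapply(body, function(f) as.integer(f[1]), 1L)
  bases <- vapply(body, function(f) f[2], "")
  if (length(sid) != hdr[1]) stop("oxDNA topology: nucleotide count mismatch")
  if (length(unique(sid)) != hdr[2]) stop("oxDNA topology: strand count mismatch")
  list(n_nucleotides = hdr[1], n_strands = hdr[2],
       strand_lengths = as.integer(table(factor(sid, levels = unique(sid)))),
       bases = bases)
}

#' Read an oxDNA configuration's vectors
#'
#' @param conf_path configuration file from [write_oxdna()].
#' @return List of matrices `pos`, `bvec`, `nvec`.
#' @export
read_oxdna_configuration <- function(conf_path) {
  lines <- readLines(conf_path, warn = FALSE)
  body <- do.call(rbind, lapply(strsplit(trimws(lines[-(1:3)]), "\\s+"), as.numeric))
  list(pos = body[, 1:3], bvec = body[, 4:6], nvec = body[, 7:9])
}
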