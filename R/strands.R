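## Staple placement, nick assignment and sequence threading.

#' Seeded random scaffold sequence
#'
#' @param n length in nt.
#' @param seed integer seed.
#' @return Single character string over ACGT.
#' @export
random_scaffold <- function(n, seed = 1L) {
  set.seed(as.integer(seed))
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Load the bundled synthetic 7249-nt scaffold
#'
#' A fixed, seeded synthetic stand-in with the length of the M13mp18 scaffold
#' (7249 nt). It is *not* the M13mp18 sequence; supply your own FASTA via
#' [read_scaffold_fasta()] for wet-lab designs.
#'
#' @return Single character string of length 7249.
#' @export
synthetic_scaffold_7249 <- function() {
  path <- system.file("extdata", "scaffold_synthetic_7249.fasta",
                      package = "origami6hb")
  read_scaffold_fasta(path)
}

#' Read a scaffold sequence from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @return Character string (uppercase ACGT).
#' @export
read_scaffold_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop("no sequences in ", path)
  toupper(as.character(seqs[[1]]))
}

# staple-sense successor map: strand runs against helix polarity, bridges
# vertices in the direction opposite to the scaffold crossing
staple_successors <- function(bundles, joints, loops) {
  idx <- loops$idx
  n <- sum(idx$count)
  succ <- integer(n)
  link_unpaired <- integer(n)
  link_site <- logical(n)     # TRUE when succ[i] is a vertex link
  for (r in seq_len(nrow(idx))) {
    lo <- idx$lo[r]; hi <- idx$hi[r]; off <- idx$offset[r]
    cnt <- hi - lo
    ids <- off + seq_len(cnt)
    if (idx$polarity[r] == -1L) succ[ids[-cnt]] <- ids[-1]   # staple runs +t
    else                        succ[ids[-1]]  <- ids[-cnt]
  }
  term_node <- function(hid, end) {
    r <- idx[hid, ]
    t <- if (end == "A") r$lo else r$hi - 1L
    node_id(idx, hid, t)
  }
  for (i in seq_len(nrow(joints))) {
    cn <- joints[i, ]
    # staple bridges opposite to the scaffold crossing
    if (cn$scaffold_a_to_b) { from <- term_node(cn$hid_b, cn$end_b); to <- term_node(cn$hid_a, cn$end_a) }
    else                    { from <- term_node(cn$hid_a, cn$end_a); to <- term_node(cn$hid_b, cn$end_b) }
    if (succ[from] != 0L) stop("internal error: staple terminal already connected")
    succ[from] <- to
    link_unpaired[from] <- cn$unpaired_staple
    link_site[from] <- TRUE
  }
  if (any(succ == 0L)) stop("topology error: staple network has open ends")
  list(succ = succ, link_unpaired = link_unpaired, link_site = link_site)
}

#' Place staple crossovers and nicks
#'
#' Builds the staple-strand network: the same-layer staple crossing of every
#' vertex connection (with its unpaired poly-T loop), plus antiparallel staple
#' double-crossovers between ring-adjacent duplexes at backbone-facing phases
#' offset half a turn from the scaffold phases, greedily accepted so that
#' crossovers sharing a helix stay at least `staple_xover_min_sep_bp` apart
#' (counting applied scaffold crossovers). The resulting closed staple cycles
#' are then nicked into staples whose lengths lie within
#' `[staple_min_nt, staple_max_nt]`, every nick at least `nick_domain_min_bp`
#' of duplex away from the nearest crossover or vertex junction on its helix.
#'
#' @param bundles trimmed bundles.
#' @param joints vertex connection table.
#' @param loops `scaffold_loops` (for the shared position index).
#' @param routing `scaffold_routing` (for applied scaffold crossovers).
#' @param config full or partial design configuration.
#' @return List of staple paths; each a data frame with per-item `node`
#'   (0 = unpaired insert), `helix`, `bp`, `n_nt`.
#' @export
place_staples <- function(bundles, joints, loops, routing, config = list()) {
  cfg <- resolve_config(config)
  idx <- loops$idx
  st <- staple_successors(bundles, joints, loops)
  succ <- st$succ
  ## --- staple crossover selection -----------------------------------------
  used_pos <- new.env(parent = emptyenv())  # hid -> integer positions in use
  add_pos <- function(hid, t) {
    key <- as.character(hid)
    cur <- if (exists(key, used_pos, inherits = FALSE)) get(key, used_pos) else integer()
    assign(key, c(cur, t), used_pos)
  }
  ok_pos <- function(hid, t, sep) {
    key <- as.character(hid)
    if (!exists(key, used_pos, inherits = FALSE)) return(TRUE)
    all(abs(get(key, used_pos) - t) >= sep)
  }
  if (nrow(routing$applied)) for (i in seq_len(nrow(routing$applied))) {
    add_pos(routing$applied$hid_a[i], routing$applied$t[i])
    add_pos(routing$applied$hid_b[i], routing$applied$t[i])
  }
  turn <- cfg$bp_per_turn
  guard <- cfg$crossover_end_guard_bp
  sep <- cfg$staple_xover_min_sep_bp
  stap_x <- list()
  for (b in bundles) {
    h <- b$helices
    for (s in 0:5) {
      ka <- s; kb <- (s + 1L) %% 6L
      ha <- h[h$k == ka, ]; hb <- h[h$k == kb, ]
      phi <- atan2(hb$w - ha$w, hb$u - ha$u) * 180 / pi
      t0 <- (phi %% 360) / 360 * turn + turn / 2   # half-turn offset from scaffold
      m <- seq(-4, ceiling(b$bp / turn) + 4)
      # every fourth allowed phase per pair (~4 turns apart), staggered between
      # pairs so that runs between junctions on a shared helix stay long
      # enough for legal nicks while all six interfaces receive staples
      m <- m[m %% 4L == s %% 4L]
      ts <- unique(as.integer(round(t0 + turn * m)))
      ts <- ts[ts >= guard & (ts + 1L) <= (b$bp - 1L - guard)]
      ts <- ts[ts >= ha$lo & (ts + 1L) < ha$hi & ts >= hb$lo & (ts + 1L) < hb$hi]
      for (t in ts) {
        if (ok_pos(ha$hid, t, sep) && ok_pos(hb$hid, t, sep)) {
          add_pos(ha$hid, t); add_pos(hb$hid, t)
          stap_x[[length(stap_x) + 1L]] <- c(ha$hid, hb$hid, t)
          succ <- apply_crossover(succ, idx, ha$hid, hb$hid, t, sense = -1L)
        }
      }
    }
  }
  stap_x <- if (length(stap_x)) do.call(rbind, stap_x) else matrix(integer(), ncol = 3)
  ## --- junction map per helix (crossovers + trimmed ends are junctions) ----
  ## cut legality is judged per staple run below, using run boundaries
  cycles <- staple_cycles(succ, idx, st)
  staples <- list()
  for (cy in cycles) {
    pieces <- nick_cycle(cy, cfg)
    staples <- c(staples, pieces)
  }
  attr(staples, "staple_crossovers") <- stap_x
  staples
}

# decompose the staple permutation into annotated cycles; each cycle is a data
# frame: node, helix, bp, link_unpaired (nt inserted AFTER this node; -1 none)
staple_cycles <- function(succ, idx, st) {
  n <- length(succ)
  seen <- logical(n)
  out <- list()
  for (s0 in seq_len(n)) {
    if (seen[s0]) next
    ids <- integer(0); x <- s0
    repeat {
      ids <- c(ids, x); seen[x] <- TRUE
      x <- succ[x]
      if (x == s0) break
    }
    nd <- node_of(idx, ids)
    out[[length(out) + 1L]] <- data.frame(
      node = ids, helix = nd$hid, bp = nd$t,
      link = st$link_site[ids], link_unpaired = st$link_unpaired[ids])
  }
  out
}

# cut one closed staple cycle into staples within the configured length
# bounds, respecting the nick-to-junction domain rule
nick_cycle <- function(cy, cfg) {
  n <- nrow(cy)
  lmin <- cfg$staple_min_nt; lmax <- cfg$staple_max_nt
  dom <- cfg$nick_domain_min_bp
  ## runs: maximal same-helix consecutive stretches (cyclic)
  brk <- which(cy$link | cy$helix != cy$helix[c(2:n, 1)] |
                 abs(cy$bp[c(2:n, 1)] - cy$bp) != 1L)
  # brk[i] means a junction between position i and i+1 (cyclic)
  if (!length(brk)) stop("staple cycle with no junctions: cannot measure runs")
  ## cut sites: after position i (between i and i+1 cyclically)
  ## coords: cumulative nt; position i contributes 1 nt, plus link_unpaired
  ## nt after it when the link stays uncut
  unp <- ifelse(cy$link, cy$link_unpaired, 0L)
  cum_end <- cumsum(1L + unp)            # coordinate just after item i (+its loop)
  total <- cum_end[n]
  pos_end <- cumsum(c(0L, (1L + unp)[-n])) + 1L  # coordinate right after nt of item i
  ## run id per position
  run_id <- integer(n)
  r <- 1L
  # start numbering right after the first junction
  start <- brk[1] %% n + 1L
  ordr <- ((start - 1L + 0:(n - 1L)) %% n) + 1L
  cuts_after <- logical(n); cuts_after[brk] <- TRUE
  rid <- 0L
  for (p in ordr) {
    if (rid == 0L) rid <- 1L
    run_id[p] <- rid
    if (cuts_after[p]) rid <- rid + 1L
  }
  run_len <- tabulate(run_id)
  ## position-in-run by walking
  pir <- integer(n); cnt <- 0L
  for (p in ordr) { cnt <- cnt + 1L; pir[p] <- cnt; if (cuts_after[p]) cnt <- 0L }
  ## legal sites
  sites <- list()
  for (i in seq_len(n)) {
    if (cy$link[i]) {
      # cut inside the vertex loop: both flanking runs must be long enough
      left_run <- run_len[run_id[i]]
      nxt <- i %% n + 1L
      right_run <- run_len[run_id[nxt]]
      if (left_run >= dom && right_run >= dom)
        sites[[length(sites) + 1L]] <- data.frame(
          i = i, end_coord = pos_end[i], start_coord = cum_end[i], link_cut = TRUE)
    } else if (!cuts_after[i]) {
      # mid-run cut between i and i+1 on the same helix
      L <- run_len[run_id[i]]
      if (pir[i] >= dom && (L - pir[i]) >= dom)
        sites[[length(sites) + 1L]] <- data.frame(
          i = i, end_coord = pos_end[i], start_coord = pos_end[i], link_cut = FALSE)
    }
  }
  if (!length(sites))
    stop("infeasible staple nicking: cycle through helix ", cy$helix[1],
         " has no legal nick site")
  sites <- do.call(rbind, sites)
  ## choose cut subset: cyclic partition with all arc lengths in [lmin, lmax]
  K <- nrow(sites)
  choose_cuts <- function(first) {
    ord <- c(first:K, seq_len(first - 1L))
    s <- sites[ord, ]
    base <- s$start_coord[1]
    off_start <- (s$start_coord - base) %% total
    off_end <- (s$end_coord - base) %% total
    # unrolled: virtual terminal at first site + total
    term_end <- (s$end_coord[1] - base) %% total + total
    feas <- logical(K + 1L); feas[K + 1L] <- TRUE
    nxt_ok <- vector("list", K)
    for (a in K:1) {
      lens_end <- c(off_end[-seq_len(a)], term_end)
      js <- (a + 1L):(K + 1L)
      # monotone unroll: any later site with coordinate < current start wraps
      le <- ifelse(lens_end <= off_start[a], lens_end + total, lens_end)
      ok <- which(le - off_start[a] >= lmin & le - off_start[a] <= lmax & feas[js])
      nxt_ok[[a]] <- js[ok]
      feas[a] <- length(ok) > 0
    }
    if (!feas[1]) return(NULL)
    picked <- 1L; cur <- 1L
    target <- (lmin + lmax) / 2
    while (TRUE) {
      cand <- nxt_ok[[cur]]
      if ((K + 1L) %in% cand) {
        break
      }
      lens_end <- off_end[cand]
      le <- ifelse(lens_end <= off_start[cur], lens_end + total, lens_end)
      pick <- cand[order(abs(le - off_start[cur] - target))][1]
      picked <- c(picked, pick); cur <- pick
    }
    ord[picked]
  }
  chosen <- NULL
  for (first in seq_len(K)) { chosen <- choose_cuts(first); if (!is.null(chosen)) break }
  if (is.null(chosen))
    stop("infeasible staple nicking: no cut set satisfies the length bounds ",
         "on a cycle through helix ", cy$helix[1])
  chosen <- sites[chosen, ]
  ## materialize staples between consecutive cuts
  pieces <- list()
  nc <- nrow(chosen)
  for (ci in seq_len(nc)) {
    a <- chosen[ci, ]
    b <- chosen[if (ci == nc) 1 else ci + 1, ]
    # staple starts just after cut a, ends at cut b
    items <- list()
    p <- a$i %% n + 1L
    repeat {
      items[[length(items) + 1L]] <- data.frame(
        node = cy$node[p], helix = cy$helix[p], bp = cy$bp[p], n_nt = 1L,
        unpaired = FALSE)
      if (p == b$i) break
      if (cy$link[p] && cy$link_unpaired[p] > 0L)
        items[[length(items) + 1L]] <- data.frame(
          node = 0L, helix = cy$helix[p], bp = cy$bp[p],
          n_nt = cy$link_unpaired[p], unpaired = TRUE)
      p <- p %% n + 1L
    }
    pieces[[length(pieces) + 1L]] <- do.call(rbind, items)
  }
  pieces
}

#' Thread the scaffold sequence along the routing
#'
#' Assigns scaffold bases 5'->3' along the routing cycle, starting from the
#' configured start nick (first scaffold-sense position of the start helix).
#' Unpaired vertex nucleotides consume scaffold between duplex positions;
#' leftover scaffold is reported as an unpaired loop at the start position.
#'
#' @param routing `scaffold_routing`.
#' @param scaffold_seq character scaffold sequence (ACGT).
#' @param config full or partial design configuration (`scaffold_start`).
#' @return List: `base_by_node` (one base per scaffold position),
#'   `routing_ordered` (the routing rotated to the start), `used_nt`,
#'   `scaffold_length_nt`, `leftover_nt`.
#' @export
assign_scaffold_sequence <- function(routing, scaffold_seq, config = list()) {
  cfg <- resolve_config(config)
  need <- routing$length_nt
  have <- nchar(scaffold_seq)
  if (have < need)
    stop("scaffold too short: design needs ", need, " nt, scaffold has ", have)
  idx <- routing$idx
  ss <- cfg$scaffold_start
  hid0 <- 6L * (as.integer(ss$edge) - 1L) + as.integer(ss$helix) + 1L
  if (hid0 < 1L || hid0 > nrow(idx)) stop("scaffold_start names a non-existent helix")
  r0 <- idx[hid0, ]
  t0 <- if (r0$polarity == 1L) r0$lo else r0$hi - 1L
  start_node <- node_id(idx, hid0, t0)
  rt <- routing$routing
  k <- match(start_node, rt$node)
  rt <- rt[c(k:nrow(rt), seq_len(k - 1L)), ]
  rownames(rt) <- NULL
  bases <- strsplit(toupper(scaffold_seq), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("scaffold sequence contains non-ACGT characters")
  base_by_node <- character(length(routing$succ))
  pos <- 0L
  for (i in seq_len(nrow(rt))) {
    pos <- pos + 1L
    base_by_node[rt$node[i]] <- bases[pos]
    pos <- pos + rt$unpaired_after[i]   # unpaired loop nt consumed after this node
  }
  list(base_by_node = base_by_node, routing_ordered = rt,
       used_nt = need, scaffold_length_nt = have, leftover_nt = have - need)
}

#' Assign staple sequences by Watson-Crick complementarity
#'
#' Every paired staple base is the complement of the scaffold base at the same
#' position, read 5'->3' along the staple; unpaired vertex-loop staple bases
#' are poly-T.
#'
#' @param staples staple paths from [place_staples()].
#' @param seq_assign output of [assign_scaffold_sequence()].
#' @return A `strand_set`: scaffold sequence-on-routing and sequenced staples.
#' @export
staple_sequences <- function(staples, seq_assign) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  base_by_node <- seq_assign$base_by_node
  out <- vector("list", length(staples))
  for (i in seq_along(staples)) {
    sp <- staples[[i]]
    chunks <- character(nrow(sp))
    for (j in seq_len(nrow(sp))) {
      if (sp$unpaired[j]) chunks[j] <- strrep("T", sp$n_nt[j])
      else {
        b <- base_by_node[sp$node[j]]
        if (!nzchar(b)) stop("internal error: staple claims an unsequenced scaffold position")
        chunks[j] <- unname(comp[b])
      }
    }
    out[[i]] <- list(path = sp, sequence = paste(chunks, collapse = ""))
  }
  structure(list(staples = out, seq_assign = seq_assign), class = "strand_set")
}

#' @export
print.strand_set <- function(x, ...) {
  lens <- vapply(x$staples, function(s) nchar(s$sequence), 1L)
  cat(sprintf("strand_set: %d staples (%d-%d nt), scaffold %d/%d nt used\n",
              length(x$staples), min(lens), max(lens),
              x$seq_assign$used_nt, x$seq_assign$scaffold_length_nt))
  invisible(x)
}

#' Summarize a finished design
#'
#' @param design a full `origami_design` from [design_origami()].
#' @return A `design_report` list: scaffold usage, staple count and length
#'   histogram, crossover counts, per-vertex connection counts.
#' @export
design_report <- function(design) {
  lens <- vapply(design$strands$staples, function(s) nchar(s$sequence), 1L)
  joints <- design$joints
  per_vertex <- as.data.frame(table(vertex = joints$vertex))
  names(per_vertex)[2] <- "connections"
  structure(list(
    scaffold_used_nt = design$strands$seq_assign$used_nt,
    scaffold_length_nt = design$strands$seq_assign$scaffold_length_nt,
    staple_count = length(lens),
    staple_length_histogram = table(lens),
    scaffold_crossovers_applied = nrow(design$routing$applied),
    staple_crossovers = nrow(attr(design$staples, "staple_crossovers")),
    n_loops = design$loops$n_loops,
    bp_per_edge = design$dgeom$bp_per_edge,
    per_vertex_connections = per_vertex), class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat("design_report\n")
  cat(sprintf("  scaffold: %d / %d nt used\n", x$scaffold_used_nt, x$scaffold_length_nt))
  cat(sprintf("  staples: %d (lengths %s)\n", x$staple_count,
              paste(range(as.integer(names(x$staple_length_histogram))), collapse = "-")))
  cat(sprintf("  scaffold loops: %d, scaffold crossovers applied: %d, staple crossovers: %d\n",
              x$n_loops, x$scaffold_crossovers_applied, x$staple_crossovers))
  cat(sprintf("  bp per edge: %s\n", paste(x$bp_per_edge, collapse = ", ")))
  invisible(x)
}

#' Export staples as CSV
#'
#' Columns: staple id, start/end helix and base, length and 5'->3' sequence.
#'
#' @param strands a `strand_set`.
#' @param path output CSV path.
#' @export
write_staples_csv <- function(strands, path) {
  rows <- lapply(seq_along(strands$staples), function(i) {
    s <- strands$staples[[i]]
    p <- s$path[!s$path$unpaired, ]
    data.frame(staple_id = i,
               start_helix = p$helix[1] - 1L, start_base = p$bp[1],
               end_helix = p$helix[nrow(p)] - 1L, end_base = p$bp[nrow(p)],
               length_nt = nchar(s$sequence), sequence = s$sequence)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export scaffold and staples as FASTA
#'
#' @param strands a `strand_set`.
#' @param scaffold_seq the full scaffold sequence used.
#' @param path output FASTA path.
#' @export
write_strands_fasta <- function(strands, scaffold_seq, path) {
  seqs <- c(scaffold = scaffold_seq,
            stats::setNames(vapply(strands$staples, function(s) s$sequence, ""),
                            paste0("staple_", seq_along(strands$staples))))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
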