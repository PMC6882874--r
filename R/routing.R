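## Scaffold loop-crossover structure, dual graph, MST and routing inversion.
##
## The scaffold is modelled as a permutation over flat node ids, one node per
## scaffold position (helix hid, bp t on the edge grid, t in [lo, hi)). The
## successor map follows the scaffold 5'->3': along each helix in its polarity
## sense, and across vertices through the joint connections. Applying an
## antiparallel double crossover between helices i (polarity +) and j
## (polarity -) at bp t rewires succ(i,t): (i,t+1)->(j,t) and
## succ(j,t+1): (j,t)->(i,t+1), which merges the two incident cycles.

# flat indexing over scaffold positions of a trimmed bundle set
scaffold_index <- function(bundles) {
  hel <- do.call(rbind, lapply(bundles, function(b) {
    h <- b$helices
    h$edge <- b$edge
    h
  }))
  hel <- hel[order(hel$hid), ]
  hel$count <- hel$hi - hel$lo
  hel$offset <- cumsum(c(0L, hel$count[-nrow(hel)]))
  rownames(hel) <- NULL
  hel
}

node_id <- function(idx, hid, t) {
  r <- idx[hid, ]
  stopifnot(all(t >= r$lo), all(t < r$hi))
  r$offset + (t - r$lo) + 1L
}

node_of <- function(idx, id) {
  hid <- findInterval(id - 1L, idx$offset)
  t <- (id - 1L) - idx$offset[hid] + idx$lo[hid]
  list(hid = hid, t = t)
}

# scaffold successor permutation from helix runs plus vertex connections;
# vertex links are annotated with their unpaired scaffold nt
scaffold_successors <- function(bundles, joints) {
  idx <- scaffold_index(bundles)
  n <- sum(idx$count)
  succ <- integer(n)
  link_unpaired <- integer(n)   # unpaired nt inserted after node i (vertex links)
  for (r in seq_len(nrow(idx))) {
    lo <- idx$lo[r]; hi <- idx$hi[r]; off <- idx$offset[r]
    cnt <- hi - lo
    if (cnt <= 0) stop("helix ", idx$hid[r], " has no scaffold positions after trimming")
    ids <- off + seq_len(cnt)       # node ids for t = lo..hi-1
    if (idx$polarity[r] == 1L) succ[ids[-cnt]] <- ids[-1]
    else                       succ[ids[-1]]  <- ids[-cnt]
  }
  # terminal node of a helix in scaffold sense at a given edge end
  term_node <- function(hid, end) {
    r <- idx[hid, ]
    t <- if (end == "A") r$lo else r$hi - 1L
    node_id(idx, hid, t)
  }
  for (i in seq_len(nrow(joints))) {
    cn <- joints[i, ]
    if (cn$scaffold_a_to_b) { from <- term_node(cn$hid_a, cn$end_a); to <- term_node(cn$hid_b, cn$end_b) }
    else                    { from <- term_node(cn$hid_b, cn$end_b); to <- term_node(cn$hid_a, cn$end_a) }
    if (succ[from] != 0L)
      stop("internal error: scaffold terminal already connected at node ", from)
    succ[from] <- to
    link_unpaired[from] <- cn$unpaired_scaffold
  }
  if (any(succ == 0L))
    stop("topology error: unconnected duplex end(s); ",
         sum(succ == 0L), " scaffold position(s) have no successor")
  list(idx = idx, succ = succ, link_unpaired = link_unpaired)
}

cycles_of_permutation <- function(succ) {
  n <- length(succ)
  cyc <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (cyc[s] != 0L) next
    cur <- cur + 1L
    x <- s
    repeat {
      cyc[x] <- cur
      x <- succ[x]
      if (x == s) break
      if (cyc[x] != 0L) stop("successor map is not a permutation")
    }
  }
  cyc
}

#' Build the closed scaffold loops of the design
#'
#' Walks the scaffold strand of every duplex and follows the same-layer
#' vertex connections, partitioning all scaffold positions into disjoint
#' closed loops (the loop-crossover structure before any scaffold double
#' crossover is applied).
#'
#' @param bundles trimmed bundles.
#' @param joints connection table from [build_vertex_joints()].
#' @return A `scaffold_loops` object: flat index, successor map, per-node
#'   loop id, and loop count.
#' @export
build_scaffold_loops <- function(bundles, joints) {
  sc <- scaffold_successors(bundles, joints)
  loop_id <- cycles_of_permutation(sc$succ)
  structure(list(idx = sc$idx, succ = sc$succ, link_unpaired = sc$link_unpaired,
                 loop_id = loop_id, n_loops = max(loop_id)),
            class = "scaffold_loops")
}

#' @export
print.scaffold_loops <- function(x, ...) {
  cat(sprintf("scaffold_loops: %d loops over %d scaffold positions\n",
              x$n_loops, length(x$succ)))
  invisible(x)
}

#' Enumerate candidate scaffold double-crossovers (dual-graph edges)
#'
#' Between every ring-adjacent (hence antiparallel) duplex pair of each edge
#' bundle, backbones face each other periodically under the 10.5 bp/turn
#' twist; candidate crossover positions are the nearest integer bp to each
#' allowed phase, excluding positions within the end guard of the edge ends
#' and positions outside either duplex's trimmed bp range. Candidates joining
#' a loop to itself are dropped, as are candidates that would share a
#' within-helix backbone link with a lexicographically earlier candidate (so
#' any subset of the surviving candidates can be applied together).
#'
#' @param bundles trimmed bundles.
#' @param loops `scaffold_loops` from [build_scaffold_loops()].
#' @param config full or partial design configuration.
#' @return Data frame of candidates: edge, ring pair, bp position, helix ids,
#'   incident loops and weight (uniform 1.0).
#' @export
enumerate_crossover_candidates <- function(bundles, loops, config = list()) {
  cfg <- resolve_config(config)
  guard <- cfg$crossover_end_guard_bp
  turn <- cfg$bp_per_turn
  idx <- loops$idx
  cand <- list()
  for (b in bundles) {
    h <- b$helices
    bp <- b$bp
    for (s in 0:5) {
      ka <- s; kb <- (s + 1L) %% 6L
      ha <- h[h$k == ka, ]; hb <- h[h$k == kb, ]
      # cross-section angle from helix a to helix b sets the phase offset
      phi <- atan2(hb$w - ha$w, hb$u - ha$u) * 180 / pi
      t0 <- (phi %% 360) / 360 * turn
      m <- seq(-1, ceiling(bp / turn) + 1)
      ts <- unique(as.integer(round(t0 + turn * m)))
      ts <- ts[ts >= guard & (ts + 1L) <= (bp - 1L - guard)]
      ts <- ts[ts >= ha$lo & (ts + 1L) < ha$hi & ts >= hb$lo & (ts + 1L) < hb$hi]
      if (!length(ts)) next
      for (t in ts)
        cand[[length(cand) + 1L]] <- data.frame(
          edge = b$edge, k_a = ka, k_b = kb, t = t,
          hid_a = ha$hid, hid_b = hb$hid)
    }
    if (!length(cand) || !any(vapply(cand, function(x) x$edge == b$edge, TRUE)))
      warning("edge ", b$edge, " has no candidate crossover positions (too short)")
  }
  if (!length(cand)) stop("no candidate crossovers anywhere: design too small")
  cand <- do.call(rbind, cand)
  # loops incident to each candidate
  cand$loop_a <- loops$loop_id[node_id(idx, cand$hid_a, cand$t)]
  cand$loop_b <- loops$loop_id[node_id(idx, cand$hid_b, cand$t)]
  cand$weight <- 1.0
  # canonical order and deterministic filtering
  lo_l <- pmin(cand$loop_a, cand$loop_b); hi_l <- pmax(cand$loop_a, cand$loop_b)
  lo_h <- pmin(cand$hid_a, cand$hid_b);   hi_h <- pmax(cand$hid_a, cand$hid_b)
  cand <- cand[order(cand$weight, lo_l, hi_l, lo_h, hi_h, cand$t), ]
  rownames(cand) <- NULL
  keep <- rep(TRUE, nrow(cand))
  used <- new.env(parent = emptyenv())   # scaffold successor nodes rewired
  for (i in seq_len(nrow(cand))) {
    # an antiparallel crossover at t rewires succ at (plus-helix, t) and
    # (minus-helix, t+1); candidates clash iff those nodes collide
    plus  <- if (idx$polarity[cand$hid_a[i]] == 1L) cand$hid_a[i] else cand$hid_b[i]
    minus <- if (plus == cand$hid_a[i]) cand$hid_b[i] else cand$hid_a[i]
    keys <- c(paste(plus, cand$t[i]), paste(minus, cand$t[i] + 1L))
    if (any(vapply(keys, exists, TRUE, envir = used, inherits = FALSE))) {
      keep[i] <- FALSE; next
    }
    for (kk in keys) assign(kk, TRUE, envir = used)
  }
  cand <- cand[keep, ]
  cand <- cand[cand$loop_a != cand$loop_b, ]   # self-edges leave the dual graph
  rownames(cand) <- NULL
  cand
}

#' Deterministic minimum spanning tree of the dual graph
#'
#' Prim's algorithm started from the lowest-numbered loop, with ties broken
#' lexicographically by (weight, loop pair, helix pair, bp position), so the
#' routing is reproducible.
#'
#' @param candidates candidate table from [enumerate_crossover_candidates()].
#' @param n_loops number of dual-graph nodes (scaffold loops).
#' @return The selected rows of `candidates` (n_loops - 1 of them).
#' @export
minimum_spanning_tree <- function(candidates, n_loops) {
  if (n_loops == 1L) return(candidates[0, ])
  lo_l <- pmin(candidates$loop_a, candidates$loop_b)
  hi_l <- pmax(candidates$loop_a, candidates$loop_b)
  lo_h <- pmin(candidates$hid_a, candidates$hid_b)
  hi_h <- pmax(candidates$hid_a, candidates$hid_b)
  ord <- order(candidates$weight, lo_l, hi_l, lo_h, hi_h, candidates$t)
  candidates <- candidates[ord, ]
  in_tree <- rep(FALSE, n_loops); in_tree[1] <- TRUE
  picked <- integer(0)
  for (step in seq_len(n_loops - 1L)) {
    found <- 0L
    for (i in seq_len(nrow(candidates))) {
      if (i %in% picked) next
      a <- in_tree[candidates$loop_a[i]]; b <- in_tree[candidates$loop_b[i]]
      if (xor(a, b)) { found <- i; break }
    }
    if (found == 0L) {
      miss <- which(!in_tree)
      stop("dual graph is disconnected: loop(s) ", paste(miss, collapse = ", "),
           " unreachable from loop 1")
    }
    picked <- c(picked, found)
    in_tree[candidates$loop_a[found]] <- TRUE
    in_tree[candidates$loop_b[found]] <- TRUE
  }
  out <- candidates[picked, ]
  rownames(out) <- NULL
  out
}

# apply one antiparallel double crossover to a successor map; sense = +1 for
# the scaffold map (strand runs along helix polarity), -1 for the staple map
apply_crossover <- function(succ, idx, hid_a, hid_b, t, sense = 1L) {
  if (idx$polarity[hid_a] * sense == -1L) { tmp <- hid_a; hid_a <- hid_b; hid_b <- tmp }
  i_t  <- node_id(idx, hid_a, t);      i_t1 <- node_id(idx, hid_a, t + 1L)
  j_t  <- node_id(idx, hid_b, t);      j_t1 <- node_id(idx, hid_b, t + 1L)
  if (succ[i_t] != i_t1 || succ[j_t1] != j_t)
    stop("internal consistency error: crossover site (", hid_a, ",", hid_b, ",",
         t, ") is not an intact antiparallel backbone pair")
  succ[i_t]  <- j_t
  succ[j_t1] <- i_t1
  succ
}

#' Invert the spanning tree into a single scaffold routing
#'
#' Applies every tree crossover to the scaffold successor map; each
#' application merges the two incident loops, so after all `n_loops - 1`
#' applications exactly one closed cycle remains, covering every scaffold
#' position exactly once. Unpaired vertex nucleotides stay attached to their
#' vertex links.
#'
#' @param loops `scaffold_loops`.
#' @param tree selected crossovers from [minimum_spanning_tree()].
#' @return A `scaffold_routing`: ordered cycle of (helix, bp, direction) with
#'   per-step unpaired insertions, plus the applied crossovers.
#' @export
invert_tree_to_routing <- function(loops, tree) {
  succ <- loops$succ
  idx <- loops$idx
  n_before <- loops$n_loops
  if (nrow(tree)) for (i in seq_len(nrow(tree))) {
    succ <- apply_crossover(succ, idx, tree$hid_a[i], tree$hid_b[i], tree$t[i])
    n_now <- max(cycles_of_permutation(succ))
    if (n_now != n_before - i)
      stop("internal consistency error: crossover ", i,
           " did not merge two loops (", n_now, " cycles after it)")
  }
  cyc <- cycles_of_permutation(succ)
  if (max(cyc) != 1L)
    stop("internal consistency error: ", max(cyc),
         " cycles remain after applying the spanning tree")
  # unrolled cycle from node 1
  n <- length(succ)
  order_ids <- integer(n)
  x <- 1L
  for (i in seq_len(n)) { order_ids[i] <- x; x <- succ[x] }
  nd <- node_of(idx, order_ids)
  routing <- data.frame(node = order_ids, helix = nd$hid, bp = nd$t,
                        direction = idx$polarity[nd$hid],
                        unpaired_after = loops$link_unpaired[order_ids])
  structure(list(routing = routing, succ = succ, idx = idx,
                 applied = tree,
                 n_paired = n, n_unpaired = sum(loops$link_unpaired),
                 length_nt = n + sum(loops$link_unpaired)),
            class = "scaffold_routing")
}

#' @export
print.scaffold_routing <- function(x, ...) {
  cat(sprintf("scaffold_routing: 1 closed cycle, %d paired + %d unpaired = %d nt, %d crossovers\n",
              x$n_paired, x$n_unpaired, x$length_nt, nrow(x$applied)))
  invisible(x)
}

#' Dump the routing construction for inspection
#'
#' Writes a JSON record of the loop structure, dual-graph candidates, tree
#' edges and applied crossovers (the schema used by the test harness).
#'
#' @param loops,candidates,tree,routing the four routing-stage objects.
#' @param path output JSON path.
#' @export
write_routing_debug <- function(loops, candidates, tree, routing, path) {
  obj <- list(
    n_loops = loops$n_loops,
    loop_sizes = as.integer(table(loops$loop_id)),
    dual_graph = candidates[, c("loop_a", "loop_b", "hid_a", "hid_b", "t", "weight")],
    tree = tree[, c("loop_a", "loop_b", "hid_a", "hid_b", "t")],
    routing_length_nt = routing$length_nt,
    n_paired = routing$n_paired,
    n_unpaired = routing$n_unpaired)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
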