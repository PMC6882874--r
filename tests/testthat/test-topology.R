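make_dgeom <- function(n, R = 25) {
  g <- generate_regular_polygon(n, R); g$mode <- "boundary_internal"
  scale_and_discretize(g, "circumradius_nm", R)
}

test_that("edge bundles carry six duplexes each at the interhelix spacing", {
  dg <- make_dgeom(3)
  b <- build_edge_bundles(dg)
  expect_length(b, 3)
  expect_equal(sum(vapply(b, function(x) nrow(x$helices), 1L)), 18)
  # ring-adjacent duplex axes are exactly one interhelix distance apart
  h <- b[[1]]$helices
  for (k in 0:5) {
    a <- h[h$k == k, ]; bb <- h[h$k == (k + 1) %% 6, ]
    expect_equal(sqrt((a$u - bb$u)^2 + (a$w - bb$w)^2), 2.5, tolerance = 1e-9)
  }
  # three layers stacked along the out-of-plane axis, middle layer in-plane
  expect_equal(sort(unique(h$w[h$layer == 1L])), c(0, 0))
  expect_true(all(h$w[h$layer == 2L] > 0), all(h$w[h$layer == 0L] < 0))

  # hexagon meshed with spokes: 12 edges -> 72 duplex axes
  hx <- generate_internal_mesh(generate_regular_polygon(6, 25), "triangular", 25)
  dgh <- scale_and_discretize(hx, "circumradius_nm", 25)
  bh <- build_edge_bundles(dgh)
  expect_equal(sum(vapply(bh, function(x) nrow(x$helices), 1L)), 72)
})

test_that("bisector trims follow offset/tan(theta/2), floored to bp", {
  # equilateral triangle: 60-degree wedges; middle-layer duplex offset 2.5 nm
  dg <- make_dgeom(3)
  b <- trim_ends_to_bisector(build_edge_bundles(dg), dg)
  tr <- attr(b, "trims")
  mid_inner <- tr[tr$trim_nm > 4, ]
  expect_true(all(abs(mid_inner$trim_nm - 2.5 / tan(pi / 6)) < 1e-9))  # 4.330 nm
  expect_true(all(mid_inner$trim_bp == 12L))    # floor(4.330/0.34) = 12
  # top/bottom-layer inner duplexes: offset 1.25 nm -> floor(2.165/0.34) = 6
  expect_true(any(tr$trim_bp == 6L))
  # duplexes facing the reflex (outside) wedge are not trimmed
  expect_true(any(tr$trim_bp == 0L))

  # two collinear edges meeting at 180 degrees: zero trim everywhere
  g <- target_geometry(rbind(c(0, 0), c(30, 0), c(60, 0), c(30, 40)),
                       rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)),
                       "boundary_internal")
  dgc <- scale_and_discretize(g, "direct_nm", 1)
  bc <- trim_ends_to_bisector(build_edge_bundles(dgc), dgc)
  trc <- attr(bc, "trims")
  straight <- trc[trc$vertex == 2, ]   # the collinear junction
  expect_true(all(straight$trim_bp == 0L))
  expect_true(all(straight$trim_nm < 1e-9))
})

test_that("unpaired counts are round-half-up of gap / spacing", {
  expect_equal(compute_unpaired_counts(0), 0L)
  expect_equal(compute_unpaired_counts(0.84, 0.42), 2L)
  expect_equal(compute_unpaired_counts(2.31, 0.42), 6L)  # 5.5 rounds up
  expect_equal(compute_unpaired_counts(c(0.2, 0.63), 0.42), c(0L, 2L))
  expect_error(compute_unpaired_counts(-1), ">= 0")
})

test_that("scaffold loops partition all positions; pass-level oracle agrees", {
  for (n in c(3, 4)) {
    dg <- make_dgeom(n)
    b <- trim_ends_to_bisector(build_edge_bundles(dg), dg)
    j <- build_vertex_joints(b, dg)
    L <- build_scaffold_loops(b, j)
    # partition: every position in exactly one loop
    expect_equal(length(L$loop_id), sum(L$idx$hi - L$idx$lo))
    expect_true(all(L$loop_id >= 1L & L$loop_id <= L$n_loops))
    # independent oracle: cycle count of the duplex-pass graph built straight
    # from the joint table (each helix is one pass; scaffold enters at one
    # end and leaves at the other)
    n_hel <- nrow(L$idx)
    nxt <- integer(n_hel)
    for (i in seq_len(nrow(j))) {
      cn <- j[i, ]
      if (cn$scaffold_a_to_b) nxt[cn$hid_a] <- cn$hid_b else nxt[cn$hid_b] <- cn$hid_a
    }
    expect_true(all(nxt > 0))
    seen <- logical(n_hel); ncyc <- 0L
    for (s in seq_len(n_hel)) {
      if (seen[s]) next
      ncyc <- ncyc + 1L; x <- s
      while (!seen[x]) { seen[x] <- TRUE; x <- nxt[x] }
    }
    expect_equal(L$n_loops, ncyc)
  }
})

test_that("a single edge with layer-wise self-connected ends forms 3 loops", {
  # degenerate harness: both ends of one bundle close onto themselves per layer
  g <- target_geometry(rbind(c(0, 0), c(40, 0), c(20, 30)),
                       rbind(c(1, 2), c(2, 3), c(3, 1)), "boundary_internal")
  dg <- scale_and_discretize(g, "direct_nm", 1)
  b <- build_edge_bundles(dg)[1]   # keep only edge 1, untrimmed
  cs <- b[[1]]$helices
  joints <- do.call(rbind, lapply(c("A", "B"), function(end) {
    do.call(rbind, lapply(0:2, function(layer) {
      ks <- cs$k[cs$layer == layer]
      pol <- cs$polarity[cs$layer == layer]
      into <- if (end == "B") ks[pol == 1L] else ks[pol == -1L]
      out  <- setdiff(ks, into)
      data.frame(vertex = if (end == "A") 1L else 2L, layer = layer,
                 edge_a = 1L, end_a = end, k_a = into, hid_a = into + 1L,
                 edge_b = 1L, end_b = end, k_b = out, hid_b = out + 1L,
                 gap_nm = 0, unpaired_scaffold = 0L, unpaired_staple = 0L,
                 scaffold_a_to_b = TRUE)
    }))
  }))
  L <- build_scaffold_loops(b, joints)
  expect_equal(L$n_loops, 3L)   # one loop per layer
})

test_that("crossover candidates are mid-edge, guarded and loop-labelled", {
  d <- fixture_polygon_design(6)    # 74-bp edges
  cand <- d$candidates
  # no candidate within the 10-bp guard of an edge end
  bp <- d$dgeom$bp_per_edge[cand$edge]
  expect_true(all(cand$t >= 10 & cand$t + 1 <= bp - 11))
  # at least one candidate per edge for every inter-layer interface
  expect_true(all(table(cand$edge) >= 1))
  # candidates never join a loop to itself
  expect_true(all(cand$loop_a != cand$loop_b))
  # an 84-bp edge has candidates for adjacent helix pairs near mid-edge
  tri <- fixture_triangle84()
  expect_true(nrow(tri$candidates) > 0)
  expect_true(any(abs(tri$candidates$t - 42) < 21))
})

test_that("deterministic Prim MST matches brute force and igraph on small graphs", {
  set.seed(7)
  for (rep in 1:12) {
    nv <- sample(3:8, 1)
    # random connected graph with random positive weights
    base <- cbind(seq_len(nv - 1), 2:nv)
    extra_n <- sample(0:4, 1)
    extra <- if (extra_n > 0) t(replicate(extra_n, sample(nv, 2))) else NULL
    ed <- rbind(base, extra)
    ed <- ed[ed[, 1] != ed[, 2], , drop = FALSE]
    w <- sample(1:5, nrow(ed), replace = TRUE)
    cand <- data.frame(edge = 1L, k_a = 0L, k_b = 1L, t = seq_len(nrow(ed)),
                       hid_a = ed[, 1], hid_b = ed[, 2],
                       loop_a = pmin(ed[, 1], ed[, 2]),
                       loop_b = pmax(ed[, 1], ed[, 2]), weight = w)
    tree <- minimum_spanning_tree(cand, nv)
    expect_equal(nrow(tree), nv - 1L)
    # spanning: union-find over tree edges reaches one component
    parent <- seq_len(nv)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(nrow(tree)))
      parent[find(tree$loop_a[i])] <- find(tree$loop_b[i])
    expect_equal(length(unique(vapply(seq_len(nv), find, 1L))), 1L)
    # weight matches igraph's MST
    ig <- igraph::graph_from_edgelist(as.matrix(cand[, c("loop_a", "loop_b")]),
                                      directed = FALSE)
    igraph::E(ig)$weight <- cand$weight
    expect_equal(sum(tree$weight), sum(igraph::E(igraph::mst(ig))$weight))
  }
  # exhaustive oracle on very small graphs: enumerate all spanning trees
  set.seed(11)
  for (rep in 1:6) {
    nv <- sample(3:5, 1)
    ed <- rbind(cbind(seq_len(nv - 1), 2:nv), t(replicate(2, sample(nv, 2))))
    ed <- unique(t(apply(ed, 1, sort)))
    ed <- ed[ed[, 1] != ed[, 2], , drop = FALSE]
    w <- sample(1:9, nrow(ed), replace = TRUE)
    cand <- data.frame(edge = 1L, k_a = 0L, k_b = 1L, t = seq_len(nrow(ed)),
                       hid_a = ed[, 1], hid_b = ed[, 2],
                       loop_a = ed[, 1], loop_b = ed[, 2], weight = w)
    tree <- minimum_spanning_tree(cand, nv)
    best <- Inf
    for (subset in utils::combn(nrow(ed), nv - 1, simplify = FALSE)) {
      parent <- seq_len(nv)
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      ok <- TRUE
      for (i in subset) {
        ra <- find(ed[i, 1]); rb <- find(ed[i, 2])
        if (ra == rb) { ok <- FALSE; break }
        parent[ra] <- rb
      }
      if (ok) best <- min(best, sum(w[subset]))
    }
    expect_equal(sum(tree$weight), best)
  }
})

test_that("MST edge cases: single loop and disconnected dual graph", {
  cand0 <- data.frame(edge = integer(), k_a = integer(), k_b = integer(),
                      t = integer(), hid_a = integer(), hid_b = integer(),
                      loop_a = integer(), loop_b = integer(), weight = numeric())
  expect_equal(nrow(minimum_spanning_tree(cand0, 1L)), 0L)
  cand <- data.frame(edge = 1L, k_a = 0L, k_b = 1L, t = 1L, hid_a = 1L,
                     hid_b = 2L, loop_a = 1L, loop_b = 2L, weight = 1)
  expect_error(minimum_spanning_tree(cand, 4L), "disconnected")
})

test_that("tree inversion merges one loop per crossover into a single cycle", {
  for (n in c(3, 6)) {
    d <- fixture_polygon_design(n)
    expect_equal(nrow(d$tree), d$loops$n_loops - 1L)
    expect_equal(max(table(d$routing$routing$node)), 1L)  # each position once
    # conservation: |routing| = paired + unpaired
    paired <- sum(d$loops$idx$hi - d$loops$idx$lo)
    expect_equal(d$routing$n_paired, paired)
    expect_equal(d$routing$length_nt, paired + sum(d$joints$unpaired_scaffold))
  }
})

test_that("final cycle is independent of tree-edge application order", {
  d <- fixture_polygon_design(4)
  set.seed(1)
  ref <- sort(d$routing$routing$node)
  for (rep in 1:3) {
    sh <- d$tree[sample(nrow(d$tree)), ]
    rt <- invert_tree_to_routing(d$loops, sh)
    expect_equal(sort(rt$routing$node), ref)
    expect_equal(rt$length_nt, d$routing$length_nt)
  }
})

test_that("every neighbouring edge pair is joined by exactly 3 same-layer connections", {
  for (n in c(3, 5)) {
    d <- fixture_polygon_design(n)
    j <- d$joints
    key <- paste(j$vertex, j$edge_a, j$end_a, j$edge_b, j$end_b)
    expect_true(all(table(key) == 3))
    expect_setequal(unique(j$layer), 0:2)
    # and each duplex end participates in exactly one connection
    ends <- c(paste(j$hid_a, j$end_a), paste(j$hid_b, j$end_b))
    expect_equal(anyDuplicated(ends), 0L)
  }
})
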