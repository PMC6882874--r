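## caDNAno v2 JSON (honeycomb) writer and round-trip reader.
##
## Lattice placement: each 6HB bundle occupies one hexagonal face of the
## honeycomb lattice, three cells in row 0 plus three in row 1, packed
## left-to-right by edge id (bundle e starts at column 4*(e-1), keeping
## row+column parity fixed). Ring index k maps around the face so that
## ring-adjacent duplexes always land on lattice-adjacent cells. Helix
## number = 6*(edge-1)+k, whose parity matches duplex polarity. Unpaired
## vertex nucleotides are recorded in the `loop` (insertion) array at the
## 5'-side base of their connection.

cadnano_ring_cells <- function(e) {
  c0 <- 4L * (e - 1L)
  # ring cycle: (0,c0) (0,c0+1) (0,c0+2) (1,c0+2) (1,c0+1) (1,c0)
  data.frame(k = 0:5,
             row = c(0L, 0L, 0L, 1L, 1L, 1L),
             col = c(c0, c0 + 1L, c0 + 2L, c0 + 2L, c0 + 1L, c0))
}

#' Write a design as caDNAno v2 JSON
#'
#' @param design an `origami_design` with sequenced strands.
#' @param path output JSON path.
#' @export
write_cadnano <- function(design, path) {
  if (is.null(design$strands) || !length(design$strands$staples))
    stop("cannot export an empty design (no staples)")
  idx <- design$routing$idx
  n_hel <- nrow(idx)
  num_bases <- as.integer(ceiling(max(idx$hi) / 21) * 21)
  empty4 <- function() lapply(seq_len(num_bases), function(i) c(-1L, -1L, -1L, -1L))
  vs <- vector("list", n_hel)
  for (h in seq_len(n_hel)) {
    e <- (h - 1L) %/% 6L + 1L; k <- (h - 1L) %% 6L
    cells <- cadnano_ring_cells(e)
    vs[[h]] <- list(num = h - 1L,
                    row = cells$row[cells$k == k],
                    col = cells$col[cells$k == k],
                    scaf = empty4(), stap = empty4(),
                    loop = rep(0L, num_bases), skip = rep(0L, num_bases),
                    stap_colors = list(),
                    scafLoop = list(), stapLoop = list())
  }
  nd <- function(id) node_of(idx, id)
  ## scaffold connectivity (circular): entry = [5p_helix, 5p_base, 3p_helix, 3p_base]
  succ <- design$routing$succ
  prev <- integer(length(succ)); prev[succ] <- seq_along(succ)
  for (id in seq_along(succ)) {
    a <- nd(id); p <- nd(prev[id]); s <- nd(succ[id])
    vs[[a$hid]]$scaf[[a$t + 1L]] <- c(p$hid - 1L, p$t, s$hid - 1L, s$t)
  }
  ## scaffold vertex insertions
  rt <- design$routing$routing
  ins <- rt[rt$unpaired_after > 0L, ]
  if (nrow(ins)) for (i in seq_len(nrow(ins)))
    vs[[ins$helix[i]]]$loop[ins$bp[i] + 1L] <-
      vs[[ins$helix[i]]]$loop[ins$bp[i] + 1L] + ins$unpaired_after[i]
  ## staples
  palette <- c(13369344L, 16204552L, 16225054L, 11184640L, 5749504L,
               29184L, 243362L, 1507550L, 7536862L, 12060012L, 3355443L)
  for (s in seq_along(design$strands$staples)) {
    p <- design$strands$staples[[s]]$path
    pp <- p[!p$unpaired, ]
    n <- nrow(pp)
    for (j in seq_len(n)) {
      h <- pp$helix[j]; t <- pp$bp[j]
      p5 <- if (j == 1) c(-1L, -1L) else c(pp$helix[j - 1] - 1L, pp$bp[j - 1])
      p3 <- if (j == n) c(-1L, -1L) else c(pp$helix[j + 1] - 1L, pp$bp[j + 1])
      vs[[h]]$stap[[t + 1L]] <- c(p5, p3)
    }
    # staple vertex loops as insertions at the 5'-side base of the link
    if (any(p$unpaired)) for (j in which(p$unpaired)) {
      h <- p$helix[j]; t <- p$bp[j]
      vs[[h]]$loop[t + 1L] <- vs[[h]]$loop[t + 1L] + p$n_nt[j]
    }
    vs[[pp$helix[1]]]$stap_colors <-
      c(vs[[pp$helix[1]]]$stap_colors,
        list(c(pp$bp[1], palette[(s - 1L) %% length(palette) + 1L])))
  }
  obj <- list(name = basename(path), vstrands = vs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a caDNAno v2 JSON file
#'
#' Reconstructs the scaffold cycle and staple paths (as 0-based
#' `(helix num, base)` node lists) and the per-base insertion counts.
#'
#' @param path caDNAno JSON path.
#' @return List: `scaffold` (matrix num/base), `staples` (list of matrices),
#'   `insertions` (data frame num/base/count), `n_helices`, `num_bases`.
#' @export
read_cadnano <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  vs <- obj$vstrands
  nums <- vapply(vs, function(v) as.integer(v$num), 1L)
  byname <- stats::setNames(seq_along(vs), nums)
  get4 <- function(v, field, t) as.integer(unlist(v[[field]][[t + 1L]]))
  num_bases <- length(vs[[1]]$scaf)
  ## scaffold: start anywhere defined, follow 3'
  start <- local({
    for (v in seq_along(vs)) for (t in seq_len(num_bases) - 1L)
      if (any(get4(vs[[v]], "scaf", t) != -1L)) return(c(nums[v], t))
    NULL
  })
  if (is.null(start)) stop("caDNAno file has no scaffold")
  walk <- function(field, v0, t0, stop_at_start = TRUE) {
    out <- list(); v <- v0; t <- t0
    repeat {
      out[[length(out) + 1L]] <- c(v, t)
      e4 <- get4(vs[[byname[[as.character(v)]]]], field, t)
      if (e4[3] == -1L) break
      v <- e4[3]; t <- e4[4]
      if (stop_at_start && v == v0 && t == t0) break
      if (length(out) > 10 * length(vs) * num_bases) stop("caDNAno walk did not terminate")
    }
    do.call(rbind, out)
  }
  scaffold <- walk("scaf", start[1], start[2])
  ## staples: all 5' ends
  staples <- list()
  for (v in seq_along(vs)) for (t in seq_len(num_bases) - 1L) {
    e4 <- get4(vs[[v]], "stap", t)
    if (all(e4 == -1L)) next
    if (e4[1] == -1L && e4[2] == -1L)     # 5' end
      staples[[length(staples) + 1L]] <- walk("stap", nums[v], t)
  }
  ins <- list()
  for (v in seq_along(vs)) {
    lp <- as.integer(unlist(vs[[v]]$loop))
    hit <- which(lp != 0L)
    if (length(hit))
      ins[[length(ins) + 1L]] <- data.frame(num = nums[v], base = hit - 1L,
                                            count = lp[hit])
  }
  list(scaffold = scaffold, staples = staples,
       insertions = if (length(ins)) do.call(rbind, ins) else
         data.frame(num = integer(), base = integer(), count = integer()),
       n_helices = length(vs), num_bases = num_bases)
}
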