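#' Default design configuration
#'
#' Returns the full set of tunable design parameters with their defaults.
#' All lengths are in nanometres unless the name says otherwise.
#'
#' @details
#' \describe{
#'   \item{rise_per_bp}{axial rise of B-form DNA, nm per bp (0.34).}
#'   \item{bp_per_turn}{helicity of B-form DNA, bp per full turn (10.5).}
#'   \item{min_edge_bp}{shortest designable edge, bp (42).}
#'   \item{interhelix_distance}{centre-to-centre spacing of adjacent duplexes
#'     in the honeycomb cross-section, nm (2.5).}
#'   \item{unpaired_nt_spacing}{contour length budgeted per unpaired vertex
#'     nucleotide, nm per nt (0.42), applied to both scaffold and staple
#'     vertex loops.}
#'   \item{crossover_end_guard_bp}{no crossover is placed within this many bp
#'     of an edge end (10).}
#'   \item{staple_min_nt, staple_max_nt}{allowed staple lengths (20, 60).}
#'   \item{nick_domain_min_bp}{minimum duplex domain between a staple nick and
#'     the nearest crossover or vertex junction on the same helix (7).}
#'   \item{staple_xover_min_sep_bp}{minimum bp separation enforced between
#'     crossovers sharing a helix when staple crossovers are placed (8).}
#'   \item{mesh_type}{automatic internal mesh flavour, "triangular" or
#'     "quadrilateral".}
#'   \item{scaffold_start}{start of scaffold threading, list(edge, helix)
#'     using 1-based edge and 0-based ring helix index.}
#'   \item{seed}{seed for the random scaffold generator and synthetic data.}
#' }
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    rise_per_bp           = 0.34,
    bp_per_turn           = 10.5,
    min_edge_bp           = 42L,
    interhelix_distance   = 2.5,
    unpaired_nt_spacing   = 0.42,
    crossover_end_guard_bp = 10L,
    staple_min_nt         = 20L,
    staple_max_nt         = 60L,
    nick_domain_min_bp    = 7L,
    staple_xover_min_sep_bp = 8L,
    mesh_type             = "triangular",
    scaffold_start        = list(edge = 1L, helix = 0L),
    seed                  = 1L
  )
}

#' Read a key-value configuration file
#'
#' Parses a plain-text `key = value` file (one pair per line, `#` comments)
#' and overlays it on [default_config()]. Unknown keys are an error.
#'
#' @param path file path.
#' @param base configuration list to overlay onto.
#' @return Full configuration list.
#' @export
read_config <- function(path, base = default_config()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(base))
      stop("unknown config key: '", key, "'")
    old <- base[[key]]
    base[[key]] <- if (is.numeric(old)) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop("config key '", key, "' expects a number, got '", val, "'")
      if (is.integer(old)) as.integer(num) else num
    } else if (is.character(old)) val else base[[key]]
  }
  base
}

# internal: merge user-supplied partial config over the defaults
resolve_config <- function(config = list()) {
  base <- default_config()
  if (length(config)) {
    bad <- setdiff(names(config), names(base))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    base[names(config)] <- config
  }
  base
}

# internal: explicit round-half-up (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)
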