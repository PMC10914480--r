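# Salt-bridge detection and fractional occupancy. A residue pair forms a
# bridge in a frame when the two residues carry opposite charge sign and the
# minimum distance over their charge-site atoms (ASP Odelta, GLU Oepsilon,
# ARG Neta, LYS Nzeta, SEP/TPO phosphate oxygens) is within the cutoff.
# Occupancy is the fraction of frames in which the bridge is present.

#' Salt-bridge detection configuration
#'
#' @param cutoff Contact cutoff in Angstrom; the comparison is inclusive
#'   (distance <= cutoff counts as "within"). Default 4.0.
#' @param range_threshold Residue-separation threshold: pairs with
#'   `|i - j| > range_threshold` are long-range. Default 5.
#' @return List of class `salt_bridge_config`.
#' @export
salt_bridge_config <- function(cutoff = 4.0, range_threshold = 5L) {
  stopifnot(cutoff > 0, range_threshold >= 0)
  structure(list(cutoff = cutoff, range_threshold = as.integer(range_threshold)),
            class = "salt_bridge_config")
}

# Charged residues and their charge-site atom indices; errors if a charged
# residue has no flagged atom (topology defect).
charged_residue_sites <- function(top) {
  resids <- unique(top$resid)
  resname <- top$resname[match(resids, top$resid)]
  sign <- residue_charge_sign(resname)
  charged <- which(sign != 0)
  sites <- lapply(charged, function(k) {
    idx <- which(top$resid == resids[k] & top$charge_site)
    if (length(idx) == 0) {
      stop("charged residue ", resname[k], " ", resids[k],
           " has no charge-site atom (topology defect)", call. = FALSE)
    }
    idx
  })
  list(resid = resids[charged], sign = sign[charged], sites = sites)
}

#' Salt bridges present in one frame
#'
#' @param frame `n_atoms x 3` coordinate matrix (Angstrom).
#' @param top The matching [topology()] with charge-site flags.
#' @param config A [salt_bridge_config()].
#' @return `data.frame` with columns `res_i`, `res_j` (residue numbers,
#'   `res_i < res_j`), one row per occupied bridge.
#' @export
frame_bridges <- function(frame, top, config = salt_bridge_config()) {
  stopifnot(inherits(top, "idr_topology"), nrow(frame) == nrow(top))
  cs <- charged_residue_sites(top)
  pairs <- opposite_pairs(cs)
  if (nrow(pairs) == 0) {
    return(data.frame(res_i = integer(), res_j = integer()))
  }
  hit <- vapply(seq_len(nrow(pairs)), function(r) {
    min_site_distance(frame, cs$sites[[pairs$a[r]]],
                      cs$sites[[pairs$b[r]]]) <= config$cutoff
  }, logical(1))
  data.frame(res_i = cs$resid[pairs$a[hit]], res_j = cs$resid[pairs$b[hit]])
}

opposite_pairs <- function(cs) {
  n <- length(cs$resid)
  if (n < 2) return(data.frame(a = integer(), b = integer()))
  idx <- which(outer(cs$sign, cs$sign) < 0 & upper.tri(matrix(0, n, n)),
               arr.ind = TRUE)
  data.frame(a = idx[, 1], b = idx[, 2])
}

min_site_distance <- function(frame, idx_a, idx_b) {
  a <- frame[idx_a, , drop = FALSE]
  b <- frame[idx_b, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Salt-bridge fractional occupancy over an ensemble
#'
#' For each oppositely charged residue pair, the fraction of frames in which
#' the pair is within the cutoff. Pairs never observed in contact are
#' reported with occupancy 0 so the map covers all candidate pairs.
#'
#' @param ens An [ensemble()] (or one copy of a replica set).
#' @param config A [salt_bridge_config()].
#' @return `data.frame` of class `salt_bridge_map`: columns `res_i`, `res_j`,
#'   `occupancy` in \[0, 1\], and `range_class`
#'   (`"long_range"`/`"short_range"`).
#' @export
occupancy <- function(ens, config = salt_bridge_config()) {
  stopifnot(inherits(ens, "idr_ensemble"))
  nf <- n_frames(ens)
  if (nf < 1) stop("empty ensemble", call. = FALSE)
  top <- ens$topology
  cs <- charged_residue_sites(top)
  pairs <- opposite_pairs(cs)
  counts <- integer(nrow(pairs))
  if (nrow(pairs) > 0) {
    for (k in seq_len(nf)) {
      frame <- get_frame(ens, k)
      for (r in seq_len(nrow(pairs))) {
        if (min_site_distance(frame, cs$sites[[pairs$a[r]]],
                              cs$sites[[pairs$b[r]]]) <= config$cutoff) {
          counts[r] <- counts[r] + 1L
        }
      }
    }
  }
  out <- data.frame(res_i = cs$resid[pairs$a], res_j = cs$resid[pairs$b],
                    occupancy = counts / nf, stringsAsFactors = FALSE)
  out$range_class <- vapply(seq_len(nrow(out)), function(r) {
    classify_separation(out$res_i[r], out$res_j[r], config)
  }, character(1))
  class(out) <- c("salt_bridge_map", "data.frame")
  out
}

#' Classify a residue pair as long- or short-range
#'
#' Long-range means the residues are separated by more than
#' `range_threshold` residues in the sequence (`|i - j| > threshold`);
#' a separation of exactly the threshold is short-range.
#'
#' @param i,j Residue numbers, `i != j`.
#' @param config A [salt_bridge_config()].
#' @return `"long_range"` or `"short_range"`.
#' @export
#' @examples
#' classify_separation(145, 170)  # long_range
#' classify_separation(10, 15)    # short_range (separation 5)
classify_separation <- function(i, j, config = salt_bridge_config()) {
  if (i == j) stop("i and j must differ", call. = FALSE)
  if (abs(i - j) > config$range_threshold) "long_range" else "short_range"
}

#' Export an occupancy map as a square matrix
#'
#' @param map A `salt_bridge_map`.
#' @param resids Residue numbers spanning the matrix (default: range of the
#'   map's residues).
#' @return Symmetric numeric matrix of occupancies with residue-number
#'   dimnames (heatmap-ready).
#' @export
occupancy_matrix <- function(map, resids = NULL) {
  stopifnot(inherits(map, "salt_bridge_map"))
  if (is.null(resids)) {
    if (nrow(map) == 0) return(matrix(0, 0, 0))
    resids <- seq(min(map$res_i), max(map$res_j))
  }
  m <- matrix(0, length(resids), length(resids),
              dimnames = list(resids, resids))
  for (r in seq_len(nrow(map))) {
    i <- as.character(map$res_i[r]); j <- as.character(map$res_j[r])
    m[i, j] <- m[j, i] <- map$occupancy[r]
  }
  m
}
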