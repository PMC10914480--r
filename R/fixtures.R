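# Deterministic all-atom backbone fixtures built from ideal geometry
# (standard bond lengths and angles, user-specified phi/psi). These provide
# backbone-complete frames for the secondary-structure stage and charge-site
# pseudo-atoms for the salt-bridge stage.

# Ideal backbone internal coordinates (Angstrom / degrees), Engh-Huber-like.
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, n_h = 1.01,
  ang_n_ca_c = 111.0, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5, omega = 180.0
)

# Place atom D given A-B-C using bond length |CD|, angle B-C-D and torsion
# A-B-C-D (natural extension reference frame).
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

one_to_three <- function(aa) {
  out <- names(STANDARD_AA3)[match(aa, STANDARD_AA3)]
  if (anyNA(out)) {
    stop("unknown one-letter code '", aa[is.na(out)][1], "'", call. = FALSE)
  }
  # match() finds SEP/TPO last, so plain S/T resolve to SER/THR first
  out
}

#' Build an ideal-geometry backbone ensemble
#'
#' Constructs N, CA, C, O (plus amide H where defined) for each residue from
#' ideal bond lengths/angles and the requested backbone dihedrals, and -- for
#' charged residues (D, E, K, R and annotated phosphosites) -- a single
#' side-chain charge-site pseudo-atom (`OD1`/`OE1`/`NZ`/`NH1`/`O1P`) placed
#' `charge_site_distance` Angstrom from the CA along the outward
#' CB-like direction. Amide H atoms are placed in the peptide plane 1.01 A
#' from N, trans to the preceding carbonyl O; the first residue and prolines
#' carry no H.
#'
#' @param spec `"helix"` (phi = -57, psi = -47), `"extended"`
#'   (phi = psi = 180), `"hairpin"` (two strands joined by a two-residue
#'   turn), or a 2-column matrix / data.frame of per-residue (phi, psi)
#'   in degrees (`"custom"`).
#' @param sequence One-letter amino-acid string.
#' @param phosphosites Character vector like `"S16"` marking phospho
#'   residues (numbered from `first_residue`).
#' @param first_residue Residue number of the first residue (default 1).
#' @param charge_site_distance Distance of the charge-site pseudo-atom from
#'   CA, Angstrom (default 2.5).
#' @return A single-frame [ensemble()].
#' @export
#' @examples
#' helix <- build_backbone_fixture("helix", strrep("A", 20))
build_backbone_fixture <- function(spec, sequence, phosphosites = character(),
                                   first_residue = 1L,
                                   charge_site_distance = 2.5) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  stopifnot(n >= 2)
  phi_psi <- if (is.character(spec)) {
    switch(spec,
      helix = cbind(rep(-57, n), rep(-47, n)),
      extended = cbind(rep(180, n), rep(180, n)),
      hairpin = hairpin_dihedrals(n),
      stop("unknown fixture spec '", spec, "'", call. = FALSE))
  } else {
    m <- as.matrix(spec)
    if (nrow(m) != n || ncol(m) != 2) {
      stop("custom phi/psi must be an n x 2 matrix", call. = FALSE)
    }
    m
  }
  if (any(!is.finite(phi_psi)) || any(abs(phi_psi) > 360)) {
    stop("phi/psi values must be finite angles", call. = FALSE)
  }

  resname <- one_to_three(aa)
  sites <- parse_phosphosites(phosphosites)
  if (nrow(sites) > 0) {
    idx <- sites$residue_number - first_residue + 1L
    if (any(idx < 1 | idx > n)) stop("phosphosite outside span", call. = FALSE)
    if (any(aa[idx] != sites$residue_letter)) {
      stop("phosphosite letter disagrees with sequence", call. = FALSE)
    }
    resname[idx] <- ifelse(sites$residue_letter == "S", "SEP", "TPO")
  }

  # backbone trace
  xyz <- list()  # per residue: list(N=, CA=, C=, O=, H=)
  g <- BB_GEOM
  # residue 1 seeded explicitly
  N1 <- c(0, 0, 0)
  CA1 <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C1 <- CA1 + c(-g$ca_c * cos(ang), g$ca_c * sin(ang), 0)
  xyz[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in 2:n) {
    prev <- xyz[[i - 1]]
    Ni <- place_atom(prev$N, prev$CA, prev$C, g$c_n, g$ang_ca_c_n,
                     phi_psi[i - 1, 2])                      # psi(i-1)
    CAi <- place_atom(prev$CA, prev$C, Ni, g$n_ca, g$ang_c_n_ca, g$omega)
    Ci <- place_atom(prev$C, Ni, CAi, g$ca_c, g$ang_n_ca_c, phi_psi[i, 1])
    xyz[[i]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  # carbonyl O: anti to the next N across the peptide bond (torsion psi+180)
  for (i in 1:n) {
    xyz[[i]]$O <- place_atom(xyz[[i]]$N, xyz[[i]]$CA, xyz[[i]]$C, g$c_o,
                             g$ang_ca_c_o, phi_psi[i, 2] + 180)
  }
  # amide H: in the peptide plane, trans to the preceding carbonyl O
  for (i in 2:n) {
    if (resname[i] == "PRO") next
    co <- xyz[[i - 1]]$C - xyz[[i - 1]]$O
    co <- co / sqrt(sum(co^2))
    xyz[[i]]$H <- xyz[[i]]$N + g$n_h * co
  }

  atom <- character(0); resid <- integer(0); rn <- character(0)
  coords <- NULL
  site_atom <- c(ASP = "OD1", GLU = "OE1", LYS = "NZ", ARG = "NH1",
                 SEP = "O1P", TPO = "O1P")
  for (i in 1:n) {
    names_i <- c("N", "CA", "C", "O", if (!is.null(xyz[[i]]$H)) "H")
    for (a in names_i) {
      atom <- c(atom, a)
      resid <- c(resid, first_residue + i - 1L)
      rn <- c(rn, resname[i])
      coords <- rbind(coords, xyz[[i]][[a]])
    }
    if (resname[i] %in% names(site_atom)) {
      # outward CB-like direction: away from the N/C midpoint through CA
      mid <- (xyz[[i]]$N + xyz[[i]]$C) / 2
      dir <- xyz[[i]]$CA - mid
      dir <- dir / sqrt(sum(dir^2))
      atom <- c(atom, unname(site_atom[resname[i]]))
      resid <- c(resid, first_residue + i - 1L)
      rn <- c(rn, resname[i])
      coords <- rbind(coords, xyz[[i]]$CA + charge_site_distance * dir)
    }
  }
  rownames(coords) <- NULL
  ensemble(topology(atom, resid, rn), coords)
}

# Two antiparallel strands joined by a tight two-residue turn. Strand
# dihedrals are ideal-beta; the turn is a type II' two-residue turn, which
# brings the strands into antiparallel hydrogen-bond register.
hairpin_dihedrals <- function(n) {
  stopifnot(n >= 8)
  turn_start <- floor(n / 2)
  pp <- cbind(rep(-140, n), rep(135, n))
  pp[turn_start, ] <- c(60, -120)
  pp[turn_start + 1, ] <- c(-80, 0)
  pp
}

#' Move a named atom of a fixture ensemble (single frame)
#'
#' Test helper for constructing exact geometries (e.g. placing an ASP OD1 a
#' chosen distance from an ARG NH1 for a salt-bridge positive control).
#'
#' @param ens Single-frame [ensemble()].
#' @param resid Residue number.
#' @param atom Atom name within that residue.
#' @param xyz Length-3 numeric: new coordinates (Angstrom).
#' @return The modified ensemble.
#' @export
set_atom_position <- function(ens, resid, atom, xyz) {
  stopifnot(inherits(ens, "idr_ensemble"), n_frames(ens) == 1,
            length(xyz) == 3)
  i <- which(ens$topology$resid == resid & ens$topology$atom == atom)
  if (length(i) != 1) stop("atom not found: ", resid, "/", atom, call. = FALSE)
  ens$coords[i, , 1] <- xyz
  ens
}
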