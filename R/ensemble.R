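# Containers for conformational ensembles: a topology (ordered residues and
# atoms) plus coordinate frames in Angstrom, one frame per sampled
# conformation.

STANDARD_AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q", GLU = "E",
  GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F",
  PRO = "P", SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  SEP = "S", TPO = "T")

CAP_RESNAMES <- c("ACE", "NME")

ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06)

# Average residue masses (Da) used for one-bead-per-residue chains.
RESIDUE_MASSES <- c(
  A = 71.08, R = 156.19, N = 114.10, D = 115.09, C = 103.14, Q = 128.13,
  E = 129.12, G = 57.05, H = 137.14, I = 113.16, L = 113.16, K = 128.17,
  M = 131.19, F = 147.18, P = 97.12, S = 87.08, T = 101.10, W = 186.21,
  Y = 163.18, V = 99.13)
# SEP/TPO: S/T plus HPO3 (79.98)
RESIDUE_MASSES <- c(RESIDUE_MASSES, SEP = 87.08 + 79.98, TPO = 101.10 + 79.98)

#' Build a topology table
#'
#' @param atom Atom names (PDB conventions, e.g. `"CA"`, `"OD1"`, `"O1P"`).
#' @param resid Integer residue numbers (non-decreasing along the chain).
#' @param resname Three-letter residue names, including `SEP`, `TPO`, `ACE`,
#'   `NME`.
#' @param element Optional element symbols; guessed from the atom name when
#'   missing.
#' @param mass Optional atomic masses (Da); from the element when missing.
#' @return A `data.frame` of class `idr_topology` with one row per atom and a
#'   logical `charge_site` column flagging the side-chain charge-site atoms
#'   (ASP Odelta, GLU Oepsilon, ARG Neta, LYS Nzeta, SEP/TPO phosphate O).
#' @export
topology <- function(atom, resid, resname, element = NULL, mass = NULL) {
  resid <- as.integer(resid)
  n <- length(atom)
  stopifnot(length(resid) == n, length(resname) == n)
  if (is.unsorted(resid)) {
    stop("residue ids must be non-decreasing along the chain", call. = FALSE)
  }
  if (is.null(element)) element <- guess_element(atom)
  if (is.null(mass)) {
    known <- element %in% names(ELEMENT_MASSES)
    if (!all(known)) {
      stop("unknown element '", element[!known][1], "'; supply masses",
           call. = FALSE)
    }
    mass <- unname(ELEMENT_MASSES[element])
  }
  key <- paste(resid, atom)
  if (anyDuplicated(key)) {
    stop("duplicate atom name within residue: ", key[duplicated(key)][1],
         call. = FALSE)
  }
  top <- data.frame(atom = atom, resid = resid, resname = resname,
                    element = element, mass = mass,
                    stringsAsFactors = FALSE)
  top$charge_site <- charge_site_flags(top)
  class(top) <- c("idr_topology", "data.frame")
  top
}

guess_element <- function(atom) {
  # first alphabetic character of the stripped atom name, per PDB conventions
  # for standard protein atoms (covers N, CA, C, O, H, OD1, NZ, O1P, ...)
  a <- sub("^[0-9]+", "", atom)
  toupper(substr(a, 1, 1))
}

# Charge-site atoms per the salt-bridge convention: only the terminal
# side-chain atoms that localise the charge.
charge_site_flags <- function(top) {
  (top$resname == "ASP" & top$atom %in% c("OD1", "OD2")) |
    (top$resname == "GLU" & top$atom %in% c("OE1", "OE2")) |
    (top$resname == "ARG" & top$atom %in% c("NH1", "NH2")) |
    (top$resname == "LYS" & top$atom == "NZ") |
    (top$resname %in% c("SEP", "TPO") &
       top$atom %in% c("O1P", "O2P", "O3P", "OP1", "OP2", "OP3"))
}

# Residue-level charge sign under the integer charge model.
residue_charge_sign <- function(resname) {
  s <- integer(length(resname))
  s[resname %in% c("ARG", "LYS")] <- 1L
  s[resname %in% c("ASP", "GLU")] <- -1L
  s[resname %in% c("SEP", "TPO")] <- -1L  # sign only; magnitude is -2
  s
}

#' Build an ensemble from a topology and coordinate frames
#'
#' @param top An [topology()] object.
#' @param coords Numeric array `n_atoms x 3 x n_frames` (Angstrom), or a list
#'   of `n_atoms x 3` matrices.
#' @return An object of class `idr_ensemble`.
#' @export
ensemble <- function(top, coords) {
  stopifnot(inherits(top, "idr_topology"))
  if (is.list(coords)) {
    coords <- array(unlist(coords),
                    dim = c(nrow(coords[[1]]), 3, length(coords)))
  }
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[1] != nrow(top)) {
    stop("coordinate frames have ", dim(coords)[1], " atoms; topology has ",
         nrow(top), call. = FALSE)
  }
  if (dim(coords)[3] < 1) stop("ensemble must have at least one frame",
                               call. = FALSE)
  if (!all(is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  structure(list(topology = top, coords = coords), class = "idr_ensemble")
}

#' @export
print.idr_ensemble <- function(x, ...) {
  cat(sprintf("<ensemble: %d atoms, %d residues, %d frame(s)>\n",
              nrow(x$topology), length(unique(x$topology$resid)),
              n_frames(x)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param x An `idr_ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "idr_ensemble"))
  dim(x$coords)[3]
}

#' Extract one frame as an `n_atoms x 3` matrix
#' @param x An `idr_ensemble`.
#' @param i Frame index.
#' @return Numeric matrix of coordinates (Angstrom).
#' @export
get_frame <- function(x, i) {
  stopifnot(inherits(x, "idr_ensemble"), i >= 1, i <= n_frames(x))
  x$coords[, , i, drop = TRUE]
}

# Does the topology carry a complete backbone (N, CA, C, O per standard
# residue)? Secondary structure is only defined in that case.
has_backbone <- function(top) {
  std <- top[top$resname %in% names(STANDARD_AA3), ]
  if (nrow(std) == 0) return(FALSE)
  all(vapply(split(std$atom, std$resid),
             function(a) all(c("N", "CA", "C", "O") %in% a), logical(1)))
}
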