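# Secondary-structure assignment from backbone geometry using the
# Kabsch-Sander hydrogen-bond criterion, and aggregation into per-residue
# class-fraction profiles and phosphorylated-minus-unphosphorylated
# difference maps.

SS_CLASSES <- c("H", "G", "I", "E", "B", "T", "S", "C")

KS_COUPLING <- 27.888   # kcal/mol * A, electrostatic H-bond factor
KS_CUTOFF <- -0.5       # kcal/mol; bond counted when E < cutoff
CHAIN_BREAK_CA <- 4.5   # A; consecutive CA further apart than this split the chain

#' Place amide hydrogens on backbone frames
#'
#' Adds an `H` atom to every standard residue that lacks one: in the peptide
#' plane, 1.01 Angstrom from N, trans to the preceding residue's carbonyl O
#' (i.e. along the O->C direction). The first residue of each chain segment
#' and prolines carry no amide H. Existing H atoms are left untouched.
#'
#' @param ens A backbone-complete [ensemble()] (N, CA, C, O per standard
#'   residue).
#' @return A new ensemble with H atoms inserted after each residue's N.
#' @export
place_amide_hydrogens <- function(ens) {
  stopifnot(inherits(ens, "idr_ensemble"))
  top <- ens$topology
  res <- backbone_index(top)    # errors on missing backbone atoms
  n_res <- nrow(res)
  has_h <- !is.na(res$H)
  need <- which(!has_h & res$resname != "PRO" & seq_len(n_res) > 1)
  if (length(need) == 0) return(ens)

  nf <- n_frames(ens)
  new_atoms <- length(need)
  n_old <- nrow(top)
  # insertion position: right after each residue's N atom
  order_key <- rep(seq_len(n_old), each = 1)
  ins_after <- res$N[need]

  atom <- c(top$atom, rep("H", new_atoms))
  resid <- c(top$resid, res$resid[need])
  resname <- c(top$resname, res$resname[need])
  # sort: original order, H slotted right after its residue's N
  pos <- c(order_key, ins_after + 0.5)
  ord <- order(pos)

  coords <- array(NA_real_, c(n_old + new_atoms, 3, nf))
  coords[seq_len(n_old), , ] <- ens$coords
  for (k in seq_len(nf)) {
    f <- ens$coords[, , k, drop = TRUE]
    for (m in seq_along(need)) {
      i <- need[m]
      co <- f[res$C[i - 1], ] - f[res$O[i - 1], ]
      co <- co / sqrt(sum(co^2))
      coords[n_old + m, , k] <- f[res$N[i], ] + 1.01 * co
    }
  }
  coords <- coords[ord, , , drop = FALSE]
  ensemble(topology(atom[ord], resid[ord], resname[ord]), coords)
}

# Index backbone atoms per standard residue; errors with the residue id if a
# backbone atom is missing.
backbone_index <- function(top) {
  std <- which(top$resname %in% names(STANDARD_AA3))
  resids <- unique(top$resid[std])
  idx <- function(resid, name) {
    i <- which(top$resid == resid & top$atom == name)
    if (name %in% c("N", "CA", "C", "O") && length(i) == 0) {
      stop("residue ", resid, " is missing backbone atom ", name,
           call. = FALSE)
    }
    if (length(i) == 0) NA_integer_ else i[1]
  }
  data.frame(
    resid = resids,
    resname = top$resname[match(resids, top$resid)],
    N = vapply(resids, idx, integer(1), name = "N"),
    CA = vapply(resids, idx, integer(1), name = "CA"),
    C = vapply(resids, idx, integer(1), name = "C"),
    O = vapply(resids, idx, integer(1), name = "O"),
    H = vapply(resids, idx, integer(1), name = "H")
  )
}

#' Kabsch-Sander hydrogen-bond energy between two residues
#'
#' \eqn{E = 27.888 (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})} kcal/mol,
#' distances in Angstrom, between the donor's N-H and the acceptor's C=O.
#' A bond is counted when E < -0.5 kcal/mol.
#'
#' @param frame `n_atoms x 3` coordinate matrix.
#' @param top The matching [topology()] (H atoms present, e.g. from
#'   [place_amide_hydrogens()]).
#' @param donor_resid,acceptor_resid Residue numbers; donor needs N and H,
#'   acceptor needs C and O.
#' @return Energy in kcal/mol. `Inf` (no bond possible) if the donor has no
#'   amide H or the residues are sequence-adjacent -- the donor N and
#'   acceptor C of neighbouring residues share a covalent peptide bond and
#'   are never hydrogen-bond partners.
#' @export
hbond_energy <- function(frame, top, donor_resid, acceptor_resid) {
  res <- backbone_index(top)
  d <- match(donor_resid, res$resid)
  a <- match(acceptor_resid, res$resid)
  stopifnot(!is.na(d), !is.na(a))
  if (is.na(res$H[d]) || abs(donor_resid - acceptor_resid) < 2) return(Inf)
  ks_energy(frame[res$N[d], ], frame[res$H[d], ],
            frame[res$C[a], ], frame[res$O[a], ])
}

ks_energy <- function(N, H, C, O) {
  dist <- function(p, q) sqrt(sum((p - q)^2))
  r_on <- dist(O, N); r_ch <- dist(C, H); r_oh <- dist(O, H); r_cn <- dist(C, N)
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5) {
    stop("atomic clash (< 0.5 A) in hydrogen-bond evaluation", call. = FALSE)
  }
  KS_COUPLING * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

#' Assign per-frame secondary structure
#'
#' Kabsch-Sander pattern rules on backbone hydrogen bonds: two consecutive
#' n-turns make a helix (`H` for 4-turns, `G` for 3-turns, `I` for 5-turns),
#' ladders of nonlocal bridge bonds make strand (`E`) with isolated bridges
#' `B`, remaining turn bonds give `T`, bends (CA virtual angle > 70 degrees)
#' give `S`, everything else coil `C`. Overlap priority: H > E > G > I > T >
#' S > C. Chains are split where consecutive CA atoms are further than 4.5
#' Angstrom apart; no bonds are assigned across breaks.
#'
#' Amide hydrogens are placed first if absent. Coarse-grained ensembles have
#' no backbone atoms and are rejected.
#'
#' @param ens A backbone-complete [ensemble()].
#' @return Object of class `ss_assignment`: character matrix
#'   `n_frames x n_residues` with residue numbers as column names.
#' @export
assign_secondary_structure <- function(ens) {
  stopifnot(inherits(ens, "idr_ensemble"))
  if (!has_backbone(ens$topology)) {
    stop("ensemble has no complete backbone (N, CA, C, O); secondary ",
         "structure is undefined for coarse-grained chains", call. = FALSE)
  }
  ens <- place_amide_hydrogens(ens)
  res <- backbone_index(ens$topology)
  nf <- n_frames(ens)
  out <- matrix("C", nf, nrow(res), dimnames = list(NULL, res$resid))
  for (k in seq_len(nf)) {
    out[k, ] <- assign_frame(get_frame(ens, k), res)
  }
  structure(out, class = c("ss_assignment", class(out)))
}

assign_frame <- function(frame, res) {
  n <- nrow(res)
  # chain segments from CA-CA breaks
  ca <- frame[res$CA, , drop = FALSE]
  gap <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
  segment <- cumsum(c(1L, as.integer(gap > CHAIN_BREAK_CA)))

  # hydrogen-bond matrix: HB[d, a] donor d -> acceptor a
  HB <- matrix(FALSE, n, n)
  donors <- which(!is.na(res$H))
  for (d in donors) {
    Nd <- frame[res$N[d], ]; Hd <- frame[res$H[d], ]
    for (a in seq_len(n)) {
      if (abs(a - d) < 2 || segment[a] != segment[d]) next
      e <- ks_energy(Nd, Hd, frame[res$C[a], ], frame[res$O[a], ])
      HB[d, a] <- e < KS_CUTOFF
    }
  }

  turn <- function(nn) {
    t <- logical(n)
    i <- seq_len(n - nn)
    t[i] <- HB[cbind(i + nn, i)] & segment[i] == segment[i + nn]
    t
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)

  helix_mask <- function(t, nn) {
    m <- logical(n)
    for (i in which(t)) {
      if (i > 1 && t[i - 1]) m[i:(i + nn - 1)] <- TRUE
    }
    m
  }
  isH <- helix_mask(t4, 4)
  isG <- helix_mask(t3, 3)
  isI <- helix_mask(t5, 5)

  # bridges between nonlocal residues
  bridge <- matrix(FALSE, n, n)
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      if (abs(i - j) <= 2) next
      par <- (HB[j, i - 1] && HB[i + 1, j]) || (HB[i, j - 1] && HB[j + 1, i])
      anti <- (HB[j, i] && HB[i, j]) ||
        (HB[j + 1, i - 1] && HB[i + 1, j - 1])
      if (par || anti) bridge[i, j] <- TRUE
    }
  }
  bridged <- which(apply(bridge, 1, any))
  isE <- logical(n); isB <- logical(n)
  for (i in bridged) {
    if ((i - 1) %in% bridged || (i + 1) %in% bridged) isE[i] <- TRUE
    else isB[i] <- TRUE
  }

  # turn label: residues spanned by any n-turn
  isT <- logical(n)
  for (nn in 3:5) {
    t <- switch(as.character(nn), "3" = t3, "4" = t4, "5" = t5)
    for (i in which(t)) isT[(i + 1):(i + nn - 1)] <- TRUE
  }

  # bend: virtual CA angle
  isS <- logical(n)
  if (n >= 5) {
    for (i in 3:(n - 2)) {
      if (segment[i - 2] != segment[i + 2]) next
      u <- ca[i, ] - ca[i - 2, ]
      v <- ca[i + 2, ] - ca[i, ]
      cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
      if (acos(pmin(1, pmax(-1, cosang))) > 70 * pi / 180) isS[i] <- TRUE
    }
  }

  lab <- rep("C", n)
  lab[isS] <- "S"
  lab[isT] <- "T"
  lab[isI] <- "I"
  lab[isG] <- "G"
  lab[isB] <- "B"
  lab[isE] <- "E"
  lab[isH] <- "H"
  lab
}

#' Per-residue secondary-structure fractions
#'
#' Fractions of each class per residue, averaged over frames within each
#' copy and then over copies, so each copy carries equal weight. Rows sum
#' to 1.
#'
#' @param assignments An `ss_assignment` matrix, or a list of them (one per
#'   replica copy; all must cover the same residues).
#' @return Object of class `ss_profile`: numeric matrix `residues x classes`
#'   (classes H, G, I, E, B, T, S, C), residue numbers as row names.
#' @export
ss_fractions <- function(assignments) {
  if (!is.list(assignments)) assignments <- list(assignments)
  resids <- colnames(assignments[[1]])
  per_copy <- lapply(assignments, function(a) {
    if (!identical(colnames(a), resids)) {
      stop("assignments cover different residue ranges", call. = FALSE)
    }
    sapply(SS_CLASSES, function(cl) colMeans(a == cl))
  })
  prof <- Reduce(`+`, per_copy) / length(per_copy)
  rownames(prof) <- resids
  structure(prof, class = c("ss_profile", class(prof)))
}

#' Difference between two secondary-structure profiles
#'
#' Per-residue, per-class difference `profile_phos - profile_unphos`; the two
#' profiles must cover the same residue range (entries lie in \[-1, 1\] and
#' rows sum to 0).
#'
#' @param profile_phos,profile_unphos `ss_profile` matrices over the same
#'   residues.
#' @return Matrix of class `ss_profile_diff`.
#' @export
ss_difference <- function(profile_phos, profile_unphos) {
  stopifnot(inherits(profile_phos, "ss_profile"),
            inherits(profile_unphos, "ss_profile"))
  if (!identical(dim(profile_phos), dim(profile_unphos)) ||
      !identical(rownames(profile_phos), rownames(profile_unphos))) {
    stop("profiles cover different residue ranges", call. = FALSE)
  }
  d <- unclass(profile_phos) - unclass(profile_unphos)
  structure(d, class = c("ss_profile_diff", class(d)))
}

#' Collapse an 8-class profile to helix / turn / disordered
#'
#' The three-way reporting used for disordered regions: `H` is alpha-helix,
#' `T` is turn, and everything else (G, I, E, B, S, C) counts as disordered.
#'
#' @param profile An `ss_profile`.
#' @return Matrix `residues x c("helix", "turn", "disordered")`.
#' @export
ss_three_state <- function(profile) {
  stopifnot(inherits(profile, "ss_profile"))
  p <- unclass(profile)
  cbind(helix = p[, "H"], turn = p[, "T"],
        disordered = rowSums(p[, c("G", "I", "E", "B", "S", "C"), drop = FALSE]))
}
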