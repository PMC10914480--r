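# Shared helpers: tiny topologies/ensembles built in code, random rigid
# transforms, and brute-force reference implementations used as oracles.

# A minimal "charge-site only" topology: one CA plus one charge-site atom per
# charged residue, for salt-bridge geometry tests.
make_site_topology <- function(resnames, resids = seq_along(resnames)) {
  site_atom <- c(ASP = "OD1", GLU = "OE1", LYS = "NZ", ARG = "NH1",
                 SEP = "O1P", TPO = "O1P")
  atom <- character(0); rid <- integer(0); rn <- character(0)
  for (k in seq_along(resnames)) {
    atom <- c(atom, "CA")
    rid <- c(rid, resids[k]); rn <- c(rn, resnames[k])
    if (resnames[k] %in% names(site_atom)) {
      atom <- c(atom, unname(site_atom[resnames[k]]))
      rid <- c(rid, resids[k]); rn <- c(rn, resnames[k])
    }
  }
  topology(atom, rid, rn)
}

# Random rotation matrix (uniform via QR of a Gaussian matrix).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(frame, rot, shift) {
  frame %*% t(rot) + matrix(shift, nrow(frame), 3, byrow = TRUE)
}

# Brute-force O(N^2) double-loop radius of gyration:
# Rg^2 = (1/2) sum_ij m_i m_j |r_i - r_j|^2 / M^2
brute_force_rg <- function(frame, masses) {
  n <- nrow(frame)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- acc + masses[i] * masses[j] * sum((frame[i, ] - frame[j, ])^2)
    }
  }
  sqrt(acc / (2 * sum(masses)^2))
}

# Brute-force salt-bridge occupancy: scan every frame, every oppositely
# charged residue pair, every eligible atom pair.
brute_force_occupancy <- function(ens, cutoff) {
  top <- ens$topology
  resids <- unique(top$resid)
  resname <- top$resname[match(resids, top$resid)]
  sign <- ifelse(resname %in% c("ARG", "LYS"), 1,
                 ifelse(resname %in% c("ASP", "GLU", "SEP", "TPO"), -1, 0))
  out <- data.frame(res_i = integer(), res_j = integer(),
                    occupancy = numeric())
  nf <- dim(ens$coords)[3]
  for (a in seq_along(resids)) {
    for (b in seq_along(resids)) {
      if (b <= a || sign[a] * sign[b] >= 0) next
      ia <- which(top$resid == resids[a] & top$charge_site)
      ib <- which(top$resid == resids[b] & top$charge_site)
      hits <- 0
      for (k in seq_len(nf)) {
        f <- ens$coords[, , k]
        found <- FALSE
        for (i in ia) {
          for (j in ib) {
            if (sqrt(sum((f[i, ] - f[j, ])^2)) <= cutoff) found <- TRUE
          }
        }
        if (found) hits <- hits + 1
      }
      out <- rbind(out, data.frame(res_i = resids[a], res_j = resids[b],
                                   occupancy = hits / nf))
    }
  }
  out
}

# Random all-atom-ish ensemble of charged residues in a small box, for the
# occupancy-vs-oracle property test.
random_charged_ensemble <- function(n_res, n_frames_, box = 12) {
  resnames <- sample(c("ASP", "GLU", "ARG", "LYS", "SEP", "GLY", "ALA"),
                     n_res, replace = TRUE)
  top <- make_site_topology(resnames)
  coords <- array(runif(nrow(top) * 3 * n_frames_, 0, box),
                  c(nrow(top), 3, n_frames_))
  ensemble(top, coords)
}

# Reference DSSP labels computed once with an independent implementation
# (mdtraj 1.11 compute_dssp, simplified = FALSE) on the deterministic ideal
# fixtures exactly as built by build_backbone_fixture().
DSSP_REFERENCE <- list(
  helix20 = "CHHHHHHHHHHHHHHHHHHC",
  extended20 = "CCCCCCCCCCCCCCCCCCCC",
  hairpin16 = "CCEEEEETTEEEEECC"
)
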