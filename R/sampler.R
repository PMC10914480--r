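# Coarse-grained charged-chain model and the replica-exchange Monte Carlo
# sampler that generates synthetic conformational ensembles. The model is one
# bead per residue with harmonic bonds, purely repulsive excluded volume, and
# Debye-Hueckel screened electrostatics; bead charges come from the integer
# charge model so a phosphorylated region carries its full phospho charge.

#' Debye screening length from ionic strength
#'
#' Debye-Hueckel limiting-law expression for aqueous 1:1 electrolyte at
#' 298 K: \eqn{\kappa^{-1} = 3.04 / \sqrt{I}} Angstrom with I in mol/L.
#'
#' @param ionic_strength Ionic strength in mol/L (> 0).
#' @return Debye length in Angstrom.
#' @export
#' @examples
#' debye_length(0.150)  # ~7.85 A at physiological salt
debye_length <- function(ionic_strength) {
  stopifnot(ionic_strength > 0)
  3.04 / sqrt(ionic_strength)
}

#' Coarse-grained chain model for a region
#'
#' One bead per residue. Bead charges are the integer per-residue charges of
#' the region (phosphosites as -2e); bead masses are average residue masses.
#'
#' @param region A [region()] object.
#' @param bond_length Virtual CA-CA bond length, Angstrom (default 3.8).
#' @param k_bond Harmonic bond constant, kcal/mol/A^2 (default 20).
#' @param sigma Repulsive-core diameter, Angstrom (default 4.5).
#' @param eps_rep Repulsion strength at r = sigma, kcal/mol (default 1).
#' @param ionic_strength mol/L (default 0.150, the modelled salt).
#' @param dielectric Relative dielectric constant (default 78.4, bulk water).
#' @return Object of class `cg_chain_model`.
#' @export
cg_chain_model <- function(region, bond_length = 3.8, k_bond = 20,
                           sigma = 4.5, eps_rep = 1,
                           ionic_strength = 0.150, dielectric = 78.4) {
  stopifnot(inherits(region, "idr_region"))
  aa <- strsplit(region$sequence, "")[[1]]
  model <- charge_model()
  charges <- as.numeric(model[aa])
  masses <- unname(RESIDUE_MASSES[aa])
  resname3 <- names(STANDARD_AA3)[match(aa, STANDARD_AA3)]
  if (nrow(region$phosphosites) > 0) {
    idx <- region$phosphosites$residue_number - region$first_residue + 1L
    is_ser <- region$phosphosites$residue_letter == "S"
    charges[idx] <- -2
    masses[idx] <- unname(RESIDUE_MASSES[ifelse(is_ser, "SEP", "TPO")])
    resname3[idx] <- ifelse(is_ser, "SEP", "TPO")
  }
  stopifnot(sum(charges) == net_charge(region))
  structure(
    list(region = region, charges = charges, masses = masses,
         resname3 = resname3, bond_length = bond_length, k_bond = k_bond,
         sigma = sigma, eps_rep = eps_rep, ionic_strength = ionic_strength,
         dielectric = dielectric,
         kappa = 1 / debye_length(ionic_strength)),
    class = "cg_chain_model"
  )
}

# Bead topology for a CG model: one CA pseudo-atom per residue, residue
# numbering from the region offset.
cg_topology <- function(model) {
  n <- length(model$charges)
  first <- model$region$first_residue
  topology(atom = rep("CA", n), resid = first:(first + n - 1L),
           resname = model$resname3, element = rep("C", n),
           mass = model$masses)
}

# Initial conformation: fixed-bond-length random walk (the sampler
# equilibrates away any initial overlaps during burn-in).
initial_chain <- function(n, bond_length) {
  dirs <- matrix(stats::rnorm(3 * (n - 1)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rbind(c(0, 0, 0), apply(dirs * bond_length, 2, cumsum))
}

#' Sample a replica set of conformational ensembles
#'
#' Runs `n_copies` independent replica-exchange Monte Carlo simulations of
#' the coarse-grained chain across the temperature ladder, each from its own
#' derived seed, and returns the frames recorded at the rung closest to the
#' analysis temperature, after discarding the burn-in fraction. One frame is
#' recorded every `sweeps_per_frame` sweeps (a sweep is one attempted move
#' per bead); exchanges between neighbouring rungs are attempted every
#' `exchange_stride` sweeps.
#'
#' Per-copy seeds are derived from the master seed as
#' `seed + 10007 * (copy - 1)`, so a fixed master seed makes the whole
#' replica set deterministic.
#'
#' @param model A [cg_chain_model()].
#' @param n_frames Frames to record per copy before burn-in discard
#'   (>= 100 for any statistics; smaller values are allowed for smoke runs).
#' @param seed Master integer seed.
#' @param ladder A [build_temperature_ladder()] object.
#' @param n_copies Independent copies (default 5).
#' @param burn_in Fraction of recorded frames discarded from the start
#'   (default 1/6).
#' @param analysis_temperature Target temperature, K (default 298); frames
#'   come from the ladder rung nearest this value.
#' @param sweeps_per_frame MC sweeps between recorded frames (default 5).
#' @param exchange_stride Sweeps between exchange attempts (default 10).
#' @param max_disp Maximum single-bead displacement, Angstrom (default 1.2).
#' @return Object of class `replica_set`: list with `ensembles` (one
#'   [ensemble()] per copy), `temperature` (K of the recorded rung),
#'   `ladder`, `exchange` (per-copy neighbour attempt/accept counts),
#'   `move_acceptance`, `seeds`, `burn_in`, and `model`.
#' @export
sample_ensemble <- function(model, n_frames, seed, ladder,
                            n_copies = 5, burn_in = 1 / 6,
                            analysis_temperature = 298,
                            sweeps_per_frame = 5, exchange_stride = 10,
                            max_disp = 1.2) {
  stopifnot(inherits(model, "cg_chain_model"),
            inherits(ladder, "temperature_ladder"),
            n_copies >= 1, burn_in >= 0, burn_in < 1)
  n <- length(model$charges)
  if (n < 3) stop("chain of < 3 beads", call. = FALSE)
  rung <- which.min(abs(ladder$temperatures - analysis_temperature))
  top <- cg_topology(model)
  seeds <- as.integer(seed + 10007 * (seq_len(n_copies) - 1))
  keep_from <- floor(burn_in * n_frames) + 1L

  ensembles <- vector("list", n_copies)
  exchange <- vector("list", n_copies)
  move_acc <- numeric(n_copies)
  for (cp in seq_len(n_copies)) {
    set.seed(seeds[cp])
    x0 <- initial_chain(n, model$bond_length)
    res <- .cg_remd_run(x0, model$charges, model$bond_length, model$k_bond,
                        model$sigma, model$eps_rep, model$kappa,
                        model$dielectric, ladder$temperatures, rung - 1L,
                        n_frames * sweeps_per_frame, sweeps_per_frame,
                        exchange_stride, max_disp)
    coords <- res$frames[, , keep_from:n_frames, drop = FALSE]
    ensembles[[cp]] <- ensemble(top, coords)
    exchange[[cp]] <- data.frame(
      rung_low = seq_len(length(ladder$temperatures) - 1),
      attempts = res$exchange_attempts, accepts = res$exchange_accepts)
    move_acc[cp] <- res$move_acceptance
  }
  structure(
    list(ensembles = ensembles, temperature = ladder$temperatures[rung],
         ladder = ladder, exchange = exchange, move_acceptance = move_acc,
         seeds = seeds, burn_in = burn_in, model = model),
    class = "replica_set"
  )
}

#' @export
print.replica_set <- function(x, ...) {
  cat(sprintf(
    "<replica_set: %d copies x %d frames at %.1f K, %d-rung ladder %.0f-%.0f K>\n",
    length(x$ensembles), n_frames(x$ensembles[[1]]), x$temperature,
    length(x$ladder$temperatures), min(x$ladder$temperatures),
    max(x$ladder$temperatures)))
  invisible(x)
}

#' Mean neighbour exchange acceptance rate of a replica set
#' @param rs A `replica_set`.
#' @return Mean accepted/attempted exchange fraction over copies and rungs.
#' @export
exchange_rate <- function(rs) {
  stopifnot(inherits(rs, "replica_set"))
  ex <- do.call(rbind, rs$exchange)
  sum(ex$accepts) / sum(ex$attempts)
}

#' Single-temperature Monte Carlo run of the coarse-grained model
#'
#' Same move set and energy model as [sample_ensemble()] but no ladder and no
#' exchanges; used as a direct-sampling reference for the replica-exchange
#' machinery.
#'
#' @inheritParams sample_ensemble
#' @param temperature Temperature in K.
#' @return A single [ensemble()] (burn-in already discarded).
#' @export
sample_single_temperature <- function(model, n_frames, seed,
                                      temperature = 298, burn_in = 1 / 6,
                                      sweeps_per_frame = 5, max_disp = 1.2) {
  stopifnot(inherits(model, "cg_chain_model"))
  n <- length(model$charges)
  if (n < 3) stop("chain of < 3 beads", call. = FALSE)
  set.seed(as.integer(seed))
  x0 <- initial_chain(n, model$bond_length)
  res <- .cg_remd_run(x0, model$charges, model$bond_length, model$k_bond,
                      model$sigma, model$eps_rep, model$kappa,
                      model$dielectric, as.numeric(temperature), 0L,
                      n_frames * sweeps_per_frame, sweeps_per_frame,
                      1000000L, max_disp)
  keep_from <- floor(burn_in * n_frames) + 1L
  ensemble(cg_topology(model), res$frames[, , keep_from:n_frames, drop = FALSE])
}
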