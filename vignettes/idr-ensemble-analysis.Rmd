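---
title: "Analysing phosphorylation-driven expansion of disordered regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing phosphorylation-driven expansion of disordered regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The splicing regulators PTBP1 and PTBP2 are paralogs with four well-conserved
RNA-recognition motifs joined by intrinsically disordered segments: an
N-terminal region and two linkers (L1, L2). PTBP2 is multiply phosphorylated
in these segments — 9 sites in the N-terminal region, 7 in Linker 1, 2 in
Linker 2. Each phosphoserine/phosphothreonine carries −2e at neutral pH, so
dense phosphorylation injects a large negative charge into a short stretch of
chain: −18e into residues 16–44 of the PTBP2 N-terminal region, −14e into
residues 154–171 of Linker 1. Electrostatic repulsion on this scale extends
the chain, raises the radius of gyration and the N/C-termini distance, and
melts local helical structure, whereas the sparse Linker 2 sites (density
0.032) leave the chain essentially unchanged.

`idrflex` implements the analysis layer for this class of question:

* integer **net-charge and phosphorylation-density bookkeeping** for region
  records (`net_charge()`, `phospho_fraction()`, `charge_introduced()`);
* a **coarse-grained charged-chain sampler** with temperature replica
  exchange that generates synthetic conformational ensembles whose extension
  responds to net charge density (`cg_chain_model()`, `sample_ensemble()`);
* **ensemble observables** — mass-weighted radius of gyration, N/C-termini
  distance — with cross-replica standard errors and a convergence rule
  (`radius_of_gyration()`, `end_to_end_distance()`, `replica_stats()`,
  `check_convergence()`);
* **salt-bridge fractional occupancy** on charge-site atoms
  (`occupancy()`, `classify_separation()`);
* **secondary-structure fraction maps** from a Kabsch–Sander hydrogen-bond
  assignment (`assign_secondary_structure()`, `ss_fractions()`,
  `ss_difference()`);
* a **pipeline** tying the stages together with deterministic, hash-stamped
  text outputs (`run_pipeline()`, `compare_regions()`).

## Region records and the charge model

Charge conventions follow the simulated constructs: Arg/Lys +1e, Asp/Glu
−1e, phosphoserine (SEP) and phosphothreonine (TPO) −2e, histidine neutral
(modelled Nε-protonated), termini capped with neutral ACE/NME so they add no
charge. Phosphorylating one S/T therefore changes the net charge by exactly
−2e, and the phosphorylated net charge of every region equals its
unphosphorylated value plus −2e × (number of sites).

```{r}
library(idrflex)
regs <- load_region_tables()
data.frame(
  region = c("P2Nterm", "P2phosNterm", "P2L1", "P2phosL1"),
  net_charge = sapply(regs[c("P2Nterm", "P2phosNterm", "P2L1", "P2phosL1")],
                      net_charge),
  phospho_fraction = sapply(regs[c("P2Nterm", "P2phosNterm", "P2L1",
                                   "P2phosL1")], phospho_fraction)
)
```

The packaged phosphosite table is the published one. The packaged
*sequences*, however, are synthetic stand-ins
(`inst/extdata/regions_synthetic.tsv`): the source sequences are available
only as a figure, so the fixture encodes every published constraint — region
lengths, unphosphorylated net charges, phosphosite letters and positions,
and the charged residues named in the salt-bridge results (e.g. the
K12/R13 … D42/E50/D53 partners in the N-terminal region, R145/E170 in
Linker 1, K296/E297/R326 in Linker 2) — with neutral filler residues
elsewhere. All charge and density arithmetic depends only on these encoded
constraints. Region spans are a documented choice (Nterm 1–57, P2L1
140–178, P1L1 143–184, P2L2 283–344, P1L2 283–366), selected to cover every
residue number the source results discuss; exact boundary conventions were
not published.

## The coarse-grained sampler

The generator is deliberately minimal: its job is to produce ensembles with
the *statistical structure* the analysis assumes — extension monotone in
charge density, independent copies, replica exchange across a temperature
ladder — not to reproduce atomistic ensembles.

* One bead per residue, virtual CA–CA bonds of 3.8 Å with a stiff harmonic
  term (20 kcal/mol/Å²).
* Purely repulsive excluded volume, `(σ/r)^12` with σ = 4.5 Å (a typical
  residue diameter) and 1 kcal/mol at contact.
* Screened Coulomb electrostatics between charged beads,
  `332.06 q_i q_j exp(−κr) / (ε_r r)` kcal/mol, with ε_r = 78.4 and the
  Debye length from the limiting law `κ⁻¹ = 3.04/√I` Å; at the modelled
  150 mM ionic strength κ⁻¹ ≈ 7.85 Å.
* Moves: single-bead displacement (80%), crankshaft rotation (15%), and
  tail pivot (5%), Metropolis-accepted at each rung's temperature. One sweep
  is one attempted move per bead.
* Temperature ladder: geometric between fixed endpoints 275 K and 500 K.
  A geometric ladder gives approximately uniform neighbour exchange rates;
  the conventional target exchange probability of 0.4 is carried as a
  reported diagnostic, not fitted. The default of 8 rungs places a rung at
  299.5 K, and frames are recorded from the rung nearest the 298 K analysis
  temperature. Exchanges are attempted every 10 sweeps (sweeps are the
  natural attempt unit for Monte Carlo; per-step attempts are an MD
  convention).
* Five independent copies by default, each from a seed derived as
  `master + 10007·(copy−1)`; the first 1/6 of recorded frames is discarded
  as burn-in, mirroring a 50-of-300 discard convention. All randomness runs
  through R's RNG, so a master seed fixes the entire replica set bitwise.

```{r, eval = FALSE}
model <- cg_chain_model(regs$P2phosNterm)
rs <- sample_ensemble(model, n_frames = 4000, seed = 1,
                      ladder = build_temperature_ladder(8))
replica_stats(observable_series(rs))
```

What the generator does **not** emulate: attractive interactions (hydrogen
bonding, hydrophobicity), secondary structure, solvent granularity, or
realistic absolute dimensions — its chains are swollen self-avoiding walks,
systematically more extended than compact atomistic ensembles. Passing
direction checks on these ensembles therefore demonstrates that the
*analysis* recovers charge-driven expansion where it exists; it says nothing
about absolute Rg/Ree magnitudes of real peptides, which are out of scope
throughout.

A consequence worth stating plainly: pivot moves decorrelate a desk-scale
Monte Carlo chain far faster than molecular dynamics decorrelates an
atomistic peptide, so cross-copy standard errors here are much smaller than
those of production simulations. Dense phosphorylation (N-terminal region,
Linker 1) separates phosphorylated from unphosphorylated chains by many
standard errors. The sparse Linker 2 modification (−4e over 62 residues)
produces a real but sub-Å extension that sits at the edge of the ±2·SEM
resolution at the default run length — depending on the seed it may or may
not be nominally significant, which mirrors how marginal that contrast is in
the source data.

## Observables, replica statistics, convergence

`radius_of_gyration()` is the mass-weighted RMS distance from the centre of
mass; bead chains use average residue masses, all-atom frames use element
masses. `end_to_end_distance()` is the CA–CA distance between the first and
last standard residue — caps are excluded, and CA is chosen because it is
the convention least sensitive to cap geometry (the source does not name
the atoms; this is a package decision, not an inference).

`replica_stats()` reports the grand mean of per-copy means and the standard
error of the mean across copies (sample SD, ddof = 1, over copy means
divided by √n). `check_convergence()` declares a run converged only when
SEM/|mean| is strictly below the threshold (default 5%) for **both** Rg and
Ree; a zero mean with nonzero SEM is flagged degenerate and never passes.

`compute_psi()` is the percent-spliced-in formula,
100·included/(included+excluded), kept because it defines the splicing
readout that motivates the structural question; significance testing around
it is deliberately out of scope.

## Salt bridges

A residue pair is bridged in a frame when the two residues carry opposite
sign under the charge model and the *minimum* distance over their
charge-site atoms — Asp Oδ, Glu Oε, Arg Nη, Lys Nζ, and all SEP/TPO
phosphate oxygens — is within 4.0 Å. The comparison is inclusive
("within 4 Å" reads naturally as ≤) and configurable. Minimum-distance
semantics make a residue pair one bridge regardless of how many atom pairs
are simultaneously in contact, which is what makes fractional occupancy a
per-pair quantity in [0, 1]. Histidine is neutral and never a partner.
Pairs separated by more than 5 residues are classified long-range; exactly
5 is short-range (the rule is "more than five"). Occupancy maps export as
tidy tables or symmetric matrices for heatmaps.

## Secondary structure

Assignment uses the Kabsch–Sander electrostatic hydrogen-bond criterion:
E = 27.888·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol, a bond when
E < −0.5. The constants are fixed, not configurable, for comparability with
the standard implementations. Amide hydrogens are placed in the peptide
plane, 1.01 Å from N, trans to the preceding carbonyl (none on prolines or
chain-initial residues). Sequence-adjacent residues share a covalent
peptide bond and are never counted as hydrogen-bonded. Two consecutive
4-turns make α-helix (H), 3-turns 3₁₀ (G), 5-turns π (I); ladders of
nonlocal bridge bonds make strand (E) with isolated bridges B; remaining
turn spans are T; CA virtual angles above 70° are bends (S); otherwise coil
(C). Overlap priority H > E > G > I > T > S > C. Chains split where
consecutive CA atoms are more than 4.5 Å apart. The three-way summary used
for disordered regions maps H → helix, T → turn, and everything else →
disordered.

Coarse-grained ensembles carry no backbone, so the assignment *refuses*
them rather than fabricating labels; in the pipeline the secondary-structure
stage simply does not run for generated bead chains.

The assignment was validated once against an independent DSSP
implementation on the package's deterministic ideal fixtures (20-residue
helix, 20-residue extended chain, 16-residue β-hairpin with a type II′
turn); the reference labels are frozen in the test suite and agreement is
required to be ≥ 95% (it is 100% on all three).

## Ensemble I/O

Ensembles travel as multi-model PDB text: human-inspectable, adequate for
desk-scale frame counts, and round-trippable to 0.001 Å. The reader
validates per-model atom counts (naming the offending model), rejects
altloc codes other than blank/'A', and reports unparseable coordinate
fields by line number. SEP/TPO are accepted as ATOM or HETATM. Charge-site
flags are recomputed from residue+atom names at load time and never stored.

## Numerical and design choices

* **Ladder endpoints exact**, interior geometric; ratio constant to 1e−10.
* **Energy bookkeeping** in the sampler is incremental with a full
  recomputation every 1000 sweeps to cap drift.
* **Analysis rung**: the recorded temperature is the rung nearest 298 K
  (299.5 K with the default 8-rung ladder); with fixed 275/500 endpoints a
  geometric ladder generally has no rung at exactly 298 K.
* **Inclusive cutoff** for salt bridges; strict inequality for the
  convergence threshold (the rule is "< 5%").
* **Tie-breaks** in assignment resolved by the fixed priority order above.
* **Degenerate inputs**: single-residue chains have Ree 0; empty ensembles,
  zero-mass frames, chains under 3 beads, and charged residues without
  flagged atoms are rejected with specific errors.

## Problem sizes used in the tests

The test suite and acceptance checks run the sampler at 5 copies × 20,000
sweeps (4,000 recorded frames) per condition for the direction checks, and
smaller chains (8–30 beads, 60–3,000 frames) for determinism, burn-in,
monotonicity and self-consistency properties. These sizes give clean
separation for the dense-phosphorylation contrasts while keeping a full
run of the suite in the minutes range on one CPU.

## Known limitations

* The generator's purely repulsive chains cannot reproduce compact or
  helical ensembles, salt-bridge maps, or secondary-structure content of
  real peptides; those stages are exercised on constructed all-atom
  fixtures instead.
* The charge model is fixed-integer at pH 7: no titration, no partial
  charges, His always neutral, Cys/Tyr neutral.
* Bend (S) assignment uses only the CA virtual angle; chain-break handling
  is geometric (CA–CA > 4.5 Å).
* Sequences in the packaged tables are constraint-preserving synthetic
  stand-ins, adequate for charge/density arithmetic and ensemble-level
  properties but not for residue-level biological interpretation beyond
  the encoded constraints.
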