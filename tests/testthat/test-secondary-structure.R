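# Hydrogen placement, Kabsch-Sander energies, assignment, and profiles.

test_that("amide hydrogens: none on prolines or the first residue; helix H
           reproduces the builder's geometry", {
  hel <- build_backbone_fixture("helix", "APAAAAAAAA")  # Pro at position 2
  with_h <- place_amide_hydrogens(hel)
  top <- with_h$topology
  expect_false(any(top$atom == "H" & top$resid == 1))
  expect_false(any(top$atom == "H" & top$resid == 2))  # proline
  expect_true(all(3:10 %in% top$resid[top$atom == "H"]))

  # re-placement reproduces stored positions: strip H, place again
  keep <- top$atom != "H"
  stripped <- ensemble(
    topology(top$atom[keep], top$resid[keep], top$resname[keep]),
    with_h$coords[keep, , , drop = FALSE])
  replaced <- place_amide_hydrogens(stripped)
  h_old <- with_h$coords[top$atom == "H", , 1]
  h_new <- replaced$coords[replaced$topology$atom == "H", , 1]
  expect_lt(max(sqrt(rowSums((h_old - h_new)^2))), 0.05)
})

test_that("missing backbone atoms are rejected with the residue id", {
  top <- topology(c("N", "CA", "C", "O", "N", "CA"), c(1, 1, 1, 1, 2, 2),
                  rep(c("ALA", "GLY"), c(4, 2)))
  ens <- ensemble(top, matrix(rnorm(18), 6, 3))
  expect_error(place_amide_hydrogens(ens), "residue 2")
})

test_that("Kabsch-Sander energy: helix i->i+4 bonds, extended none, far
           limit zero", {
  hel <- place_amide_hydrogens(build_backbone_fixture("helix", strrep("A", 12)))
  f <- hel$coords[, , 1]
  # canonical helix hydrogen bond: donor i+4, acceptor i
  e <- hbond_energy(f, hel$topology, donor_resid = 6, acceptor_resid = 2)
  expect_lt(e, -0.5)

  ext <- place_amide_hydrogens(
    build_backbone_fixture("extended", strrep("A", 12)))
  fe <- ext$coords[, , 1]
  expect_gt(hbond_energy(fe, ext$topology, 6, 2), -0.5)
  # neighbouring residues share the peptide bond: never an H-bond
  expect_identical(hbond_energy(fe, ext$topology, 6, 5), Inf)

  # far-separation limit: energy tends to zero
  top <- topology(c("N", "H", "CA", "C", "O", "N", "H", "CA", "C", "O"),
                  rep(c(1, 5), each = 5), rep(c("ALA", "ALA"), each = 5))
  f2 <- rbind(matrix(0.8 * (0:4), 5, 3), 500 + matrix(0.8 * (0:4), 5, 3))
  expect_lt(abs(hbond_energy(f2, top, 5, 1)), 0.05)
})

test_that("clashing frames are rejected", {
  top <- topology(c("N", "H", "CA", "C", "O", "N", "H", "CA", "C", "O"),
                  rep(c(1, 5), each = 5), rep("ALA", 10))
  set.seed(71)
  f <- matrix(rnorm(30, sd = 4), 10, 3)
  f[5, ] <- f[7, ] + c(0.1, 0, 0)   # acceptor O on top of donor H
  expect_error(hbond_energy(f, top, 5, 1), "clash")
})

test_that("assignment matches the frozen reference labels on ideal
           fixtures", {
  agree <- function(lab, ref) {
    mean(strsplit(ref, "")[[1]] == lab)
  }
  hel <- assign_secondary_structure(
    build_backbone_fixture("helix", strrep("A", 20)))
  expect_gte(agree(hel[1, ], DSSP_REFERENCE$helix20), 0.95)

  ext <- assign_secondary_structure(
    build_backbone_fixture("extended", strrep("A", 20)))
  expect_gte(agree(ext[1, ], DSSP_REFERENCE$extended20), 0.95)
  expect_true(all(ext[1, ] == "C"))

  hp <- assign_secondary_structure(
    build_backbone_fixture("hairpin", strrep("A", 16)))
  expect_gte(agree(hp[1, ], DSSP_REFERENCE$hairpin16), 0.95)
  # both strands carry E
  expect_true(all(hp[1, c(4, 5, 12, 13)] == "E"))
})

test_that("assignment is rigid-transform invariant", {
  set.seed(61)
  hel <- build_backbone_fixture("helix", strrep("A", 15))
  base <- assign_secondary_structure(hel)[1, ]
  rot <- random_rotation(); shift <- rnorm(3, sd = 30)
  moved <- hel
  moved$coords[, , 1] <- apply_rigid(hel$coords[, , 1], rot, shift)
  expect_identical(assign_secondary_structure(moved)[1, ], base)
})

test_that("coarse-grained ensembles are refused, never fabricated", {
  regs <- load_region_tables()
  m <- cg_chain_model(regs$P2L1)
  ens <- sample_single_temperature(m, n_frames = 12, seed = 2)
  expect_error(assign_secondary_structure(ens), "no complete backbone")
})

test_that("profiles are row-stochastic and mix frame fractions", {
  hel <- build_backbone_fixture("helix", strrep("A", 12))
  ext <- build_backbone_fixture("extended", strrep("A", 12))
  # 50 helix frames + 50 coil frames
  both <- ensemble(place_amide_hydrogens(hel)$topology, c(
    replicate(50, place_amide_hydrogens(hel)$coords[, , 1], simplify = FALSE),
    replicate(50, place_amide_hydrogens(ext)$coords[, , 1], simplify = FALSE)))
  prof <- ss_fractions(assign_secondary_structure(both))
  expect_equal(unname(rowSums(prof)), rep(1, nrow(prof)), tolerance = 1e-9)
  # an interior residue is helical in exactly half the frames
  expect_equal(unname(prof["6", "H"]), 0.5)

  # all-helix case: fraction 1 at interior residues
  prof_h <- ss_fractions(assign_secondary_structure(hel))
  expect_equal(unname(prof_h["6", "H"]), 1)

  # difference with itself is zero
  d <- ss_difference(prof, prof)
  expect_true(all(d == 0))
  expect_no_error(ss_difference(prof, prof_h))  # same span, fine

  three <- ss_three_state(prof)
  expect_equal(unname(rowSums(three)), rep(1, nrow(three)), tolerance = 1e-9)
})

test_that("difference requires matching residue ranges", {
  a <- ss_fractions(assign_secondary_structure(
    build_backbone_fixture("helix", strrep("A", 10))))
  b <- ss_fractions(assign_secondary_structure(
    build_backbone_fixture("helix", strrep("A", 11))))
  expect_error(ss_difference(a, b), "different residue ranges")
})
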