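# Salt-bridge detection, fractional occupancy, and range classification.

test_that("frame bridges respect the 4 A cutoff and the opposite-sign rule", {
  top <- make_site_topology(c("ASP", "GLY", "ARG", "GLU"))
  # layout: CA then site atom per charged residue
  frame <- matrix(0, nrow(top), 3)
  frame[top$atom == "CA", 1] <- (1:4) * 20
  od1 <- which(top$resname == "ASP" & top$atom == "OD1")
  nh1 <- which(top$resname == "ARG" & top$atom == "NH1")
  oe1 <- which(top$resname == "GLU" & top$atom == "OE1")
  frame[od1, ] <- c(0, 0, 0)
  frame[nh1, ] <- c(3.5, 0, 0)
  frame[oe1, ] <- c(100, 0, 0)

  b <- frame_bridges(frame, top)
  expect_identical(nrow(b), 1L)
  expect_identical(c(b$res_i, b$res_j), c(1L, 3L))

  # same atoms at 4.5 A: pair absent; at exactly 4.0: present (inclusive)
  frame[nh1, 1] <- 4.5
  expect_identical(nrow(frame_bridges(frame, top)), 0L)
  frame[nh1, 1] <- 4.0
  expect_identical(nrow(frame_bridges(frame, top)), 1L)

  # like charges never bridge even in contact
  frame[oe1, ] <- c(0.0, 3.5, 0)   # 3.5 A from ASP OD1
  b2 <- frame_bridges(frame, top)
  expect_false(any(b2$res_i == 1 & b2$res_j == 4))
})

test_that("charged residue without a flagged atom is a topology defect", {
  top <- topology(c("CA", "CA"), 1:2, c("ASP", "ARG"))  # no side-chain atoms
  expect_error(frame_bridges(matrix(0, 2, 3), top), "no charge-site atom")
})

test_that("occupancy counts frames in contact", {
  top <- make_site_topology(c("ASP", "ARG"))
  nf <- 100
  coords <- array(0, c(nrow(top), 3, nf))
  coords[top$atom == "CA", 1, ] <- c(10, 30)
  nh1 <- which(top$atom == "NH1")
  # contact (3 A) in the first 35 frames, apart (9 A) in the rest
  coords[nh1, 1, ] <- c(rep(3, 35), rep(9, nf - 35))
  ens <- ensemble(top, coords)
  m <- occupancy(ens)
  expect_equal(m$occupancy, 0.35)

  coords[nh1, 1, ] <- 3
  expect_equal(occupancy(ensemble(top, coords))$occupancy, 1.0)
})

test_that("occupancy equals the brute-force all-pairs oracle on random
           ensembles", {
  set.seed(23)
  for (rep in 1:4) {
    ens <- random_charged_ensemble(10, 50)
    mine <- occupancy(ens)
    oracle <- brute_force_occupancy(ens, 4.0)
    key <- function(d) paste(d$res_i, d$res_j)
    expect_setequal(key(mine), key(oracle))
    m <- mine[order(mine$res_i, mine$res_j), ]
    o <- oracle[order(oracle$res_i, oracle$res_j), ]
    expect_equal(m$occupancy, o$occupancy)
  }
})

test_that("occupancy map is rigid-transform invariant and monotone in
           cutoff", {
  set.seed(31)
  ens <- random_charged_ensemble(8, 30)
  base <- occupancy(ens)

  rot <- random_rotation(); shift <- rnorm(3, sd = 100)
  moved <- ens
  for (k in seq_len(dim(ens$coords)[3])) {
    moved$coords[, , k] <- apply_rigid(ens$coords[, , k], rot, shift)
  }
  after <- occupancy(moved)
  expect_equal(after$occupancy, base$occupancy, tolerance = 1e-9)

  wider <- occupancy(ens, salt_bridge_config(cutoff = 4.5))
  expect_true(all(wider$occupancy >= base$occupancy))
})

test_that("restricting to charge-site atoms never increases occupancy over
           an all-atom minimum-distance variant", {
  all_atom_occupancy <- function(ens, cutoff) {
    top <- ens$topology
    resids <- unique(top$resid)
    resname <- top$resname[match(resids, top$resid)]
    sgn <- ifelse(resname %in% c("ARG", "LYS"), 1,
                  ifelse(resname %in% c("ASP", "GLU", "SEP", "TPO"), -1, 0))
    nf <- dim(ens$coords)[3]
    out <- numeric(0)
    for (a in seq_along(resids)) for (b in seq_along(resids)) {
      if (b <= a || sgn[a] * sgn[b] >= 0) next
      ia <- which(top$resid == resids[a]); ib <- which(top$resid == resids[b])
      hits <- 0
      for (k in seq_len(nf)) {
        f <- ens$coords[, , k]
        d <- sqrt(outer(rowSums(f[ia, , drop = FALSE]^2),
                        rowSums(f[ib, , drop = FALSE]^2), "+") -
                    2 * f[ia, , drop = FALSE] %*% t(f[ib, , drop = FALSE]))
        if (min(d) <= cutoff) hits <- hits + 1
      }
      out <- c(out, hits / nf)
    }
    out
  }
  set.seed(41)
  ens <- random_charged_ensemble(8, 25)
  restricted <- occupancy(ens)$occupancy
  allatom <- all_atom_occupancy(ens, 4.0)
  expect_true(all(restricted <= allatom + 1e-12))
})

test_that("separation classes follow the more-than-five rule", {
  expect_identical(classify_separation(145, 170), "long_range")
  expect_identical(classify_separation(13, 20), "long_range")    # sep 7
  expect_identical(classify_separation(10, 15), "short_range")   # sep 5
  expect_identical(classify_separation(10, 16), "long_range")    # sep 6
  expect_error(classify_separation(7, 7), "differ")
})

test_that("occupancy matrix export is symmetric", {
  set.seed(53)
  ens <- random_charged_ensemble(8, 20)
  m <- occupancy_matrix(occupancy(ens))
  expect_true(isSymmetric(m))
  expect_true(all(m >= 0 & m <= 1))
})
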