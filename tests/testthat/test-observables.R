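# Radius of gyration, end-to-end distance, replica statistics, the
# convergence rule, and PSI.

two_bead_top <- function() {
  topology(c("CA", "CA"), 1:2, c("GLY", "GLY"), element = c("C", "C"),
           mass = c(1, 1))
}

test_that("Rg of a symmetric dumbbell is half the separation", {
  top <- two_bead_top()
  frame <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(radius_of_gyration(frame, top), 5.0)
})

test_that("Rg of a uniform rod matches the closed form and the double-loop
           oracle", {
  n <- 11
  top <- topology(rep("CA", n), 1:n, rep("GLY", n), element = rep("C", n),
                  mass = rep(1, n))
  frame <- cbind(0:(n - 1), 0, 0)
  closed_form <- sqrt((n^2 - 1) / 12)
  expect_equal(radius_of_gyration(frame, top), closed_form, tolerance = 1e-12)
  expect_equal(brute_force_rg(frame, top$mass), closed_form,
               tolerance = 1e-12)
})

test_that("Rg equals the double-loop oracle on random weighted frames", {
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    top <- topology(rep("CA", n), 1:n, rep("GLY", n), element = rep("C", n),
                    mass = runif(n, 0.5, 20))
    frame <- matrix(rnorm(3 * n, sd = 8), n, 3)
    expect_equal(radius_of_gyration(frame, top),
                 brute_force_rg(frame, top$mass), tolerance = 1e-9)
  }
})

test_that("Rg and Ree are rigid-transform invariant", {
  set.seed(11)
  n <- 20
  top <- topology(rep("CA", n), 1:n, rep("GLY", n), element = rep("C", n),
                  mass = runif(n, 1, 10))
  frame <- matrix(rnorm(3 * n, sd = 5), n, 3)
  for (rep in 1:8) {
    moved <- apply_rigid(frame, random_rotation(), rnorm(3, sd = 50))
    expect_equal(radius_of_gyration(moved, top),
                 radius_of_gyration(frame, top), tolerance = 1e-9)
    expect_equal(end_to_end_distance(moved, top),
                 end_to_end_distance(frame, top), tolerance = 1e-9)
  }
})

test_that("end-to-end distance uses first/last standard-residue CA and
           excludes caps", {
  top <- two_bead_top()
  expect_equal(end_to_end_distance(rbind(c(0, 0, 0), c(3, 4, 0)), top), 5.0)

  # capped chain: ACE/NME must not contribute
  capped <- topology(c("C", "CA", "CA", "N"), 1:4,
                     c("ACE", "GLY", "GLY", "NME"),
                     element = c("C", "C", "C", "N"))
  frame <- rbind(c(-100, 0, 0), c(0, 0, 0), c(3, 4, 0), c(100, 0, 0))
  expect_equal(end_to_end_distance(frame, capped), 5.0)

  single <- topology("CA", 1, "GLY", element = "C")
  expect_equal(end_to_end_distance(matrix(c(1, 2, 3), 1), single), 0.0)

  no_ca <- topology(c("N", "N"), 1:2, c("GLY", "GLY"))
  expect_error(end_to_end_distance(rbind(c(0, 0, 0), c(1, 0, 0)), no_ca),
               "terminal CA")
})

test_that("Ree on the helix fixture equals direct CA1-CA20 geometry", {
  hel <- build_backbone_fixture("helix", strrep("A", 20))
  frame <- hel$coords[, , 1]
  ca <- which(hel$topology$atom == "CA")
  direct <- sqrt(sum((frame[ca[1], ] - frame[ca[20], ])^2))
  expect_equal(end_to_end_distance(frame, hel$topology), direct)
})

test_that("replica statistics: grand mean of copy means, SEM with ddof 1", {
  series <- data.frame(copy = rep(1:5, each = 3), name = "Ree",
                       value = rep(c(10, 12, 14, 11, 13), each = 3))
  st <- replica_stats(series)
  expect_equal(st$grand_mean, 12.0)
  expect_equal(st$sem, sqrt(2.5) / sqrt(5), tolerance = 1e-12)  # ~0.707

  same <- data.frame(copy = rep(1:5, each = 2), name = "Rg", value = 7)
  expect_equal(replica_stats(same)$sem, 0)
  expect_error(replica_stats(data.frame(copy = 1, name = "Rg", value = 1:3)),
               ">= 2 copies")
})

test_that("SEM scales roughly as 1/sqrt(2) when copies double", {
  set.seed(19)
  ratios <- replicate(50, {
    mk <- function(nc) data.frame(copy = rep(seq_len(nc), each = 20),
                                  name = "Rg",
                                  value = rnorm(20 * nc, mean = 10))
    replica_stats(mk(20))$sem / replica_stats(mk(10))$sem
  })
  expect_equal(mean(ratios), 1 / sqrt(2), tolerance = 0.2)
})

test_that("convergence rule: strict < threshold, conjunction, monotone", {
  mk <- function(rg_ratio, ree_ratio) {
    data.frame(name = c("Rg", "Ree"), grand_mean = c(10, 20),
               sem = c(10 * rg_ratio, 20 * ree_ratio))
  }
  expect_true(check_convergence(mk(0.04, 0.04))$converged)
  expect_false(check_convergence(mk(0.04, 0.06))$converged)
  expect_false(check_convergence(mk(0.06, 0.04))$converged)
  # boundary: exactly 5% is not converged
  expect_false(check_convergence(mk(0.05, 0.05))$converged)

  # monotone: shrinking every SEM never flips converged -> not converged
  set.seed(5)
  for (rep in 1:20) {
    r1 <- runif(2, 0, 0.12)
    before <- check_convergence(mk(r1[1], r1[2]))$converged
    shrink <- runif(1, 0.1, 1)
    after <- check_convergence(mk(r1[1] * shrink, r1[2] * shrink))$converged
    expect_true(!before || after)
  }

  # degenerate zero mean is flagged, never passed
  degen <- data.frame(name = c("Rg", "Ree"), grand_mean = c(0, 20),
                      sem = c(0.1, 0.1))
  out <- check_convergence(degen)
  expect_false(out$converged)
  expect_true(out$report$degenerate[out$report$name == "Rg"])
})

test_that("PSI is 100 * included / total", {
  expect_equal(compute_psi(30, 70), 30.0)
  expect_equal(compute_psi(0, 50), 0.0)
  expect_equal(compute_psi(42, 42), 50.0)
  expect_error(compute_psi(0, 0), "zero")
})
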