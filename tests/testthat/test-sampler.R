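# Coarse-grained chain model and the replica-exchange Monte Carlo sampler.

make_neutral_region <- function(n) {
  region("neutral", "PTBP1", "L1", 1, strrep("G", n))
}

test_that("Debye length follows the limiting law", {
  expect_equal(debye_length(0.150), 3.04 / sqrt(0.150))
  expect_error(debye_length(0), "> 0")
})

test_that("chain model carries the region's full charge", {
  regs <- load_region_tables()
  m <- cg_chain_model(regs$P2phosNterm)
  expect_equal(sum(m$charges), -19)
  expect_equal(length(m$charges), 57)
  expect_true(all(m$charges[regs$P2phosNterm$phosphosites$residue_number] == -2))
  expect_error(cg_chain_model(region("tiny", "PTBP1", "L1", 1, "GG")) |>
                 sample_single_temperature(10, 1), "3 beads")
})

test_that("same seed gives bitwise-identical frames; copies differ", {
  m <- cg_chain_model(make_neutral_region(12))
  lad <- build_temperature_ladder(4)
  a <- sample_ensemble(m, n_frames = 60, seed = 5, ladder = lad, n_copies = 2)
  b <- sample_ensemble(m, n_frames = 60, seed = 5, ladder = lad, n_copies = 2)
  expect_identical(a$ensembles[[1]]$coords, b$ensembles[[1]]$coords)
  expect_identical(a$ensembles[[2]]$coords, b$ensembles[[2]]$coords)
  expect_false(identical(a$ensembles[[1]]$coords, a$ensembles[[2]]$coords))
  c_ <- sample_ensemble(m, n_frames = 60, seed = 6, ladder = lad, n_copies = 1)
  expect_false(identical(a$ensembles[[1]]$coords, c_$ensembles[[1]]$coords))
})

test_that("burn-in frames are discarded from recorded statistics", {
  m <- cg_chain_model(make_neutral_region(10))
  lad <- build_temperature_ladder(3)
  rs <- sample_ensemble(m, n_frames = 120, seed = 9, ladder = lad,
                        n_copies = 2, burn_in = 1 / 6)
  expect_equal(n_frames(rs$ensembles[[1]]), 120 - floor(120 / 6))
  rs0 <- sample_ensemble(m, n_frames = 120, seed = 9, ladder = lad,
                         n_copies = 2, burn_in = 0)
  # the retained tail of the zero-burn-in run is exactly the burn-in run
  expect_identical(rs$ensembles[[1]]$coords,
                   rs0$ensembles[[1]]$coords[, , 21:120])
})

test_that("frames are recorded at the rung closest to the analysis
           temperature", {
  m <- cg_chain_model(make_neutral_region(8))
  lad <- build_temperature_ladder(8)
  rs <- sample_ensemble(m, n_frames = 30, seed = 3, ladder = lad, n_copies = 1)
  expect_equal(rs$temperature,
               lad$temperatures[which.min(abs(lad$temperatures - 298))])
})

test_that("mean squared extension is consistent between replica-exchange and
           direct single-temperature sampling of a neutral chain", {
  m <- cg_chain_model(make_neutral_region(16))
  direct <- sample_single_temperature(m, n_frames = 3000, seed = 13,
                                      temperature = 298)
  s_direct <- observable_series(direct, "Ree")
  ref <- mean(s_direct$value^2)

  lad <- build_temperature_ladder(6)
  rs <- sample_ensemble(m, n_frames = 1200, seed = 29, ladder = lad,
                        n_copies = 3, analysis_temperature = 298)
  s_remd <- observable_series(rs, "Ree")
  got <- mean(s_remd$value^2)
  expect_lt(abs(got - ref) / ref, 0.25)
})

test_that("extension grows with charge density (rank order over 5 seeds)", {
  n <- 30
  seqs <- c(zero = strrep("G", n),
            mid = paste(rep(c("G", "G", "E"), length.out = n), collapse = ""),
            max = strrep("E", n))
  lad <- build_temperature_ladder(4)
  mean_obs <- sapply(names(seqs), function(nm) {
    m <- cg_chain_model(region(nm, "PTBP1", "L1", 1, seqs[[nm]]))
    vals <- sapply(1:5, function(sd) {
      rs <- sample_ensemble(m, n_frames = 400, seed = sd, ladder = lad,
                            n_copies = 1)
      s <- observable_series(rs)
      c(Rg = mean(s$value[s$name == "Rg"]),
        Ree = mean(s$value[s$name == "Ree"]))
    })
    rowMeans(vals)
  })
  expect_true(mean_obs["Rg", "zero"] < mean_obs["Rg", "mid"])
  expect_true(mean_obs["Rg", "mid"] < mean_obs["Rg", "max"])
  expect_true(mean_obs["Ree", "zero"] < mean_obs["Ree", "mid"])
  expect_true(mean_obs["Ree", "mid"] < mean_obs["Ree", "max"])
})

test_that("exchange acceptance lies in (0,1) and decreases with wider
           ladder spacing", {
  regs <- load_region_tables()
  m <- cg_chain_model(regs$P2L1)
  wide <- sample_ensemble(m, n_frames = 300, seed = 17,
                          ladder = build_temperature_ladder(3), n_copies = 2)
  narrow <- sample_ensemble(m, n_frames = 300, seed = 17,
                            ladder = build_temperature_ladder(8), n_copies = 2)
  r_wide <- exchange_rate(wide)
  r_narrow <- exchange_rate(narrow)
  expect_gt(r_wide, 0); expect_lt(r_wide, 1)
  expect_gt(r_narrow, 0); expect_lt(r_narrow, 1)
  expect_gt(r_narrow, r_wide)
})
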