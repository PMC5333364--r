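# Pair potentials, system geometry, total and incremental energies.

test_that("LJ pair energy has unit depth at r = 1 and vanishes at the cutoff", {
  s <- 2^(-1 / 6)
  expect_equal(lj_pair_energy(1, sigma = s, shifted = FALSE), -1)
  # shift constant: direct evaluation of the unshifted potential at 2.5 sigma
  expect_equal(lj_pair_energy(2.5 * s, sigma = s, shifted = FALSE),
               -0.016316891136, tolerance = 1e-12)
  expect_equal(lj_pair_energy(2.5 * s, sigma = s, shifted = TRUE), 0)
  expect_equal(lj_pair_energy(1, sigma = s, shifted = TRUE),
               -0.983683108864, tolerance = 1e-12)
  # continuity at the cutoff: approach from below matches the outside value
  expect_equal(lj_pair_energy(2.5 * s - 1e-9, sigma = s), 0,
               tolerance = 1e-7)
  expect_identical(lj_pair_energy(2.5 * s + 1e-9, sigma = s), 0)
  expect_error(lj_pair_energy(0), "positive")
  expect_error(lj_pair_energy(-1), "positive")
})

test_that("FENE bond energy is zero at r0, symmetric, and domain-limited", {
  expect_equal(fene_bond_energy(0.7), 0)
  expect_equal(fene_bond_energy(0.7 + 0.15), 1.8 * log(4 / 3),
               tolerance = 1e-12)
  expect_equal(fene_bond_energy(0.7 - 0.15), fene_bond_energy(0.7 + 0.15))
  expect_error(fene_bond_energy(0.7 + 0.3), "domain")
  expect_error(fene_bond_energy(1.1), "domain")
})

test_that("system_spec enforces the density-box relation and dof count", {
  spec <- system_spec("lj_gas", 64)
  expect_equal(spec$box_length, (64 / 1e-2)^(1 / 3), tolerance = 1e-12)
  expect_equal(spec$dof, 3 * 64)
  # shifted potential is exactly zero at the cutoff
  expect_equal(lj_pair_energy(spec$lj_cutoff, spec$lj_sigma,
                              spec$lj_epsilon, spec$lj_cutoff), 0)
  ps <- system_spec("polymer_solution", 8)
  expect_equal(ps$monomers_per_chain, 13L)
  expect_equal(ps$box_length, (8 * 13 / 1e-2)^(1 / 3), tolerance = 1e-12)
  expect_equal(ps$dof, 3 * 13 * 8)
  expect_equal(ps$lj_sigma, 0.7 * 2^(-1 / 6))
  # minimum-image validity: r_c < L/2
  expect_error(system_spec("lj_gas", 2, density = 0.5), "L/2")
})

test_that("total energy matches trivial constructions", {
  spec <- system_spec("lj_gas", 2)
  L <- spec$box_length
  # farther than the cutoff: zero
  pos <- rbind(c(1, 1, 1), c(1, 1, 1 + spec$lj_cutoff + 0.1))
  expect_equal(total_potential_energy(pos, spec), 0)
  # pair across the periodic boundary at distance 1
  pos <- rbind(c(0.5, 1, 1), c(L - 0.5, 1, 1))
  expect_equal(total_potential_energy(pos, spec),
               lj_pair_energy(1, spec$lj_sigma), tolerance = 1e-12)
  # equilateral triangle at side 1: three times the pair energy
  spec3 <- system_spec("lj_gas", 3)
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)) + 3
  expect_equal(total_potential_energy(tri, spec3),
               3 * lj_pair_energy(1, spec3$lj_sigma), tolerance = 1e-12)
})

test_that("cell-list energy equals the brute-force double loop", {
  set.seed(42)
  spec <- system_spec("lj_gas", 24, density = 0.05)  # L ~ 7.8, cells active
  for (k in 1:100) {
    pos <- random_positions(24, spec$box_length)
    expect_equal(total_potential_energy(pos, spec, "cell"),
                 total_potential_energy(pos, spec, "brute"),
                 tolerance = 1e-12)
  }
  # and both agree with an independent R oracle on a few
  for (k in 1:5) {
    pos <- random_positions(24, spec$box_length)
    expect_equal(total_potential_energy(pos, spec), oracle_energy(pos, spec),
                 tolerance = 1e-9)
  }
})

test_that("polymer energy agrees with the R oracle and validates bonds", {
  spec <- system_spec("polymer_solution", 3)
  set.seed(7)
  cfg <- initial_configuration(spec, "gas", seed = 3, relax_sweeps = 50)
  expect_equal(cfg$potential_energy, oracle_energy(cfg$positions, spec),
               tolerance = 1e-8)
  # a stretched bond is rejected by the configuration validator
  bad <- cfg$positions
  bad[2, ] <- bad[1, ] + c(1.2, 0, 0)
  expect_error(configuration(bad, spec), "FENE")
})

test_that("energy is invariant under rigid translation and relabelling", {
  set.seed(11)
  spec <- system_spec("lj_gas", 16)
  pos <- initial_configuration(spec, "gas", seed = 5,
                               relax_sweeps = 0)$positions
  e0 <- total_potential_energy(pos, spec)
  for (k in 1:5) {
    shift <- runif(3, -spec$box_length, spec$box_length)
    e1 <- total_potential_energy(sweep(pos, 2, shift, "+"), spec)
    expect_equal(e1, e0, tolerance = 1e-9 * 16)
  }
  perm <- sample(16)
  expect_equal(total_potential_energy(pos[perm, ], spec), e0,
               tolerance = 1e-12)
})

test_that("single-site energy differences match full recomputation", {
  spec <- system_spec("lj_gas", 12, density = 0.02)
  set.seed(3)
  cfg <- initial_configuration(spec, "gas", seed = 9, relax_sweeps = 0)
  expect_equal(delta_energy(cfg, 1, cfg$positions[1, ], spec), 0)
  for (k in 1:50) {
    i <- sample(12, 1)
    newp <- (cfg$positions[i, ] + runif(3, -1, 1)) %% spec$box_length
    dE <- delta_energy(cfg, i, newp, spec)
    moved <- cfg$positions
    moved[i, ] <- newp
    expect_equal(dE, total_potential_energy(moved, spec) -
                   cfg$potential_energy, tolerance = 1e-8)
  }
})

test_that("incremental energies of all polymer moves track the total", {
  # run sweeps with every move type and no resynchronisation: the
  # accumulated sum of accepted deltas must match a fresh recomputation
  spec <- system_spec("polymer_solution", 4)
  cfg <- initial_configuration(spec, "gas", seed = 2, relax_sweeps = 100)
  res <- mucadrop:::cpp_run_muca(
    cfg$positions, mucadrop:::spec_as_list(spec),
    w_centers = c(-200, 200), w_lnw = c(0, 0), elo = -1e6, ehi = 1e6,
    beta = 0.8, n_sweeps = 300L, move_mix = default_move_mix(spec),
    d_short = 0.3, r_cl = spec$lj_cutoff, seed = 123L,
    keep_series = FALSE, resync_every = 0L, measure_nd = FALSE)
  expect_gt(sum(res$accepts), 100)
  expect_true(all(res$accepts[c(3, 4, 6)] > 0))  # shift/rotation/chain
  expect_lt(abs(res$e_unresynced - res$e_p), 1e-7)
})

test_that("XYZ snapshots round-trip", {
  spec <- system_spec("lj_gas", 8)
  cfg <- initial_configuration(spec, "gas", seed = 4, relax_sweeps = 0)
  f <- tempfile(fileext = ".xyz")
  write_xyz(cfg, spec, f)
  cfg2 <- read_xyz(f, spec)
  expect_equal(cfg2$positions, cfg$positions, tolerance = 1e-14)
  expect_equal(cfg2$potential_energy, cfg$potential_energy,
               tolerance = 1e-10)
  unlink(f)
})
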