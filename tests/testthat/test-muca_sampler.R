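# Multicanonical machinery: acceptance rule, weight recursion, production
# bookkeeping and move correctness.

test_that("multicanonical acceptance has the right rate and window rule", {
  expect_true(all(muca_accept(rep(1, 100), rep(1, 100))))
  expect_true(all(muca_accept(0, 3, u = runif(50))))
  set.seed(5)
  n <- 1e6
  acc <- mean(muca_accept(rep(0, n), rep(-2, n)))
  p <- exp(-2)
  expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / n))
  # proposals leaving the window carry -Inf / NA weight: always rejected
  expect_false(any(muca_accept(0, -Inf, u = runif(20))))
  expect_false(any(muca_accept(0, NA, u = runif(20))))
})

test_that("weight recursion converges to -ln Omega on an enumerable toy", {
  # 5-level system with known density of states; histograms drawn from the
  # exact multicanonical distribution p ~ Omega * W
  ln_omega <- log(c(1, 10, 100, 10, 1))
  set.seed(42)
  lnw <- rep(0, 5)
  g <- numeric(4)
  for (it in 1:40) {
    p <- exp(ln_omega + lnw)
    p <- p / sum(p)
    H <- as.numeric(stats::rmultinom(1, 20000, p))
    upd <- mucadrop:::muca_weight_update(lnw, H, g)
    lnw <- upd$ln_w
    g <- upd$g
  }
  resid <- (lnw + ln_omega) - mean(lnw + ln_omega)
  expect_lt(max(abs(resid)), 0.05)
  # and the final histogram is flat
  p <- exp(ln_omega + lnw)
  expect_gt(min(p) / mean(p), 0.9)
})

test_that("flat systems converge immediately and production is deterministic", {
  spec <- system_spec("lj_gas", 8)
  cfg <- initial_configuration(spec, "gas", seed = 1, relax_sweeps = 50)
  w <- muca_weights(seq(-2, 2, length.out = 40), rep(0, 40),
                    d_short = 0.4, converged = TRUE)
  r1 <- run_production(cfg, w, spec, n_sweeps = 200, seed = 9)
  r2 <- run_production(cfg, w, spec, n_sweeps = 200, seed = 9)
  expect_identical(r1$series$e_p, r2$series$e_p)
  expect_identical(r1$series$n_d, r2$series$n_d)
  r3 <- run_production(cfg, w, spec, n_sweeps = 200, seed = 10)
  expect_false(identical(r1$series$e_p, r3$series$e_p))
  # zero sweeps: empty series
  r0 <- run_production(cfg, w, spec, n_sweeps = 0, seed = 9)
  expect_equal(nrow(r0$series), 0)
  expect_equal(sum(r0$hist), 0)
})

test_that("merged walker histograms equal the sum of individual walkers", {
  spec <- system_spec("lj_gas", 8)
  cfg <- initial_configuration(spec, "gas", seed = 1, relax_sweeps = 50)
  w <- muca_weights(seq(-3, 1, length.out = 30), rep(0, 30),
                    d_short = 0.4, converged = TRUE)
  both <- run_production(cfg, w, spec, n_sweeps = 150, walkers = 2, seed = 4)
  # walker sub-seeds are fold_seed(seed, k); single runs must reproduce them
  one <- run_production(cfg, w, spec, n_sweeps = 150, walkers = 1, seed = 4)
  expect_equal(sum(both$hist), 300)
  expect_equal(both$hist - one$hist,
               bin_series(both$series$e_p[both$series$walker == 2], w))
  expect_equal(one$hist, bin_series(both$series$e_p[both$series$walker == 1],
                                    w))
})

test_that("null-amplitude displacements leave the energy unchanged", {
  spec <- system_spec("lj_gas", 8)
  cfg <- initial_configuration(spec, "gas", seed = 2, relax_sweeps = 20)
  res <- mucadrop:::cpp_run_muca(
    cfg$positions, mucadrop:::spec_as_list(spec),
    w_centers = c(-5, 5), w_lnw = c(0, 0), elo = -1e6, ehi = 1e6,
    beta = NA_real_, n_sweeps = 50L,
    move_mix = c(1, 0, 0, 0, 0, 0), d_short = 0, r_cl = spec$lj_cutoff,
    seed = 3L, keep_series = TRUE, resync_every = 0L, measure_nd = FALSE)
  expect_true(all(abs(res$series_e - cfg$potential_energy) < 1e-12))
})

test_that("double bridging respects the FENE domain", {
  spec <- system_spec("polymer_solution", 2)
  z <- (seq_len(13) - 7) * spec$fene_r0
  mk <- function(sep) {
    rbind(cbind(8, 8, 8 + z), cbind(8 + sep, 8, 8 + z))
  }
  run_bridge <- function(sep) {
    mucadrop:::cpp_run_muca(
      mk(sep), mucadrop:::spec_as_list(spec),
      w_centers = c(-500, 500), w_lnw = c(0, 0), elo = -1e6, ehi = 1e6,
      beta = 0, n_sweeps = 20L,
      move_mix = c(0, 0, 0, 0, 1, 0), d_short = 0, r_cl = spec$lj_cutoff,
      seed = 11L, keep_series = FALSE, resync_every = 0L,
      measure_nd = FALSE)
  }
  # lateral separation 0.6: the diagonal bridge bond sqrt(0.6^2 + 0.7^2)
  # = 0.92 lies inside [0.4, 1.0) -> proposals are acceptable
  near <- run_bridge(0.6)
  expect_gt(near$accepts[5], 0)
  expect_equal(near$e_unresynced, near$e_p, tolerance = 1e-8)
  # separation 1.2: bridge bond sqrt(1.2^2+0.7^2) = 1.39 >= r0 + R -> all
  # bridging proposals violate the FENE domain and must be rejected
  far <- run_bridge(1.2)
  expect_equal(far$accepts[5], 0)
  expect_equal(far$e_p, total_potential_energy(mk(1.2), spec),
               tolerance = 1e-9)
})

test_that("canonical sampling of two LJ particles matches the radial law", {
  # with W = exp(-beta E) the pair-distance distribution is known exactly:
  # p(r) ~ r^2 exp(-beta v(r)); compare mean pair energy to quadrature
  spec <- system_spec("lj_gas", 2, density = 0.015)
  L <- spec$box_length
  beta <- 2
  cfg <- configuration(rbind(c(1, 1, 1), c(2, 1, 1)), spec)
  res <- mucadrop:::cpp_run_muca(
    cfg$positions, mucadrop:::spec_as_list(spec),
    w_centers = c(-2, 2), w_lnw = c(0, 0), elo = -1e6, ehi = 1e6,
    beta = beta, n_sweeps = 40000L,
    move_mix = c(0.5, 0.5, 0, 0, 0, 0), d_short = 0.4,
    r_cl = spec$lj_cutoff, seed = 17L, keep_series = TRUE,
    resync_every = 2000L, measure_nd = FALSE)
  e <- res$series_e[-(1:5000)]
  v <- function(r) lj_pair_energy(r, spec$lj_sigma, spec$lj_epsilon,
                                  spec$lj_cutoff)
  # exact <v> over the minimum-image cell: radial part within r_c plus the
  # zero-energy remainder of the box
  num <- integrate(function(r) 4 * pi * r^2 * v(r) * exp(-beta * v(r)),
                   0.5, spec$lj_cutoff, rel.tol = 1e-10)$value
  zin <- integrate(function(r) 4 * pi * r^2 * exp(-beta * v(r)),
                   0.5, spec$lj_cutoff, rel.tol = 1e-10)$value
  zout <- L^3 - 4 / 3 * pi * spec$lj_cutoff^3 +
    4 / 3 * pi * 0.5^3 * 0  # r < 0.5 carries weight ~ exp(-beta*170) ~ 0
  ex_mean <- num / (zin + zout)
  block <- tapply(e, rep(1:20, each = length(e) / 20), mean)
  expect_lt(abs(mean(e) - ex_mean),
            4 * stats::sd(block) / sqrt(20) + 1e-4)
})

test_that("polymer production records aggregate sizes consistently", {
  spec <- system_spec("polymer_solution", 3, density = 5e-3)
  cfg <- initial_configuration(spec, "gas", seed = 6, relax_sweeps = 50)
  w <- muca_weights(seq(-120, 20, length.out = 40), rep(0, 40),
                    d_short = 0.3, converged = TRUE)
  run <- run_production(cfg, w, spec, n_sweeps = 150, seed = 8)
  expect_true(all(run$series$n_d %in% 1:3))
  expect_true(all(is.finite(run$series$e_p)))
  expect_equal(sum(run$hist), 150)
  expect_equal(sum(run$hist2d), 150)
  # the 2D histogram marginalizes to the 1D one
  expect_equal(rowSums(run$hist2d), run$hist)
  # recorded n_d agrees with a fresh cluster analysis of the final state
  last <- run$configs[[1]]
  expect_equal(tail(run$series$n_d, 1),
               find_clusters(last, spec)$n_d)
})
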