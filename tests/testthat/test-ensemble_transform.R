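# Density of states arithmetic, kinetic-energy convolution, microcanonical
# temperatures, canonical distributions.

test_that("ln Omega = ln H - ln W, with masking and interior interpolation", {
  w <- muca_weights(seq(0, 9), c(0, 1, 2, 3, 4, 4, 3, 2, 1, 0))
  H <- c(0, 10, 20, 0, 40, 50, 60, 70, 80, 0)
  dos <- estimate_ln_omega(H, w, dof = 6)
  # edge zeros truncate the support
  expect_equal(dos$grid, seq(1, 8))
  # oracle for the effective weight: numerically average the sampler's
  # piecewise-linear-in-ln interpolation over each bin
  lnw_interp <- function(e) approx(w$bin_centers, w$ln_w, xout = e,
                                   rule = 2)$y
  lnw_avg <- vapply(w$bin_centers, function(c0)
    log(integrate(function(e) exp(lnw_interp(e)), c0 - 0.5, c0 + 0.5,
                  rel.tol = 1e-10)$value), numeric(1))
  expect_equal(dos$ln_omega[1], log(10) - lnw_avg[2], tolerance = 1e-8)
  expect_equal(dos$ln_omega[5], log(50) - lnw_avg[6], tolerance = 1e-8)
  # interior zero bin interpolated linearly in ln Omega
  expect_equal(dos$ln_omega[3],
               (dos$ln_omega[2] + dos$ln_omega[4]) / 2)
  expect_error(estimate_ln_omega(rep(0, 10), w), "empty")
  # constant weights: ln Omega = ln H + const
  wflat <- muca_weights(seq(0, 9), rep(2, 10))
  d2 <- estimate_ln_omega(rep(10, 10) * (1:10), wflat)
  expect_equal(diff(d2$ln_omega), diff(log(10 * (1:10))))
})

test_that("point-mass Omega convolves to the ideal-gas power law", {
  # all conformational weight in the first bin at E_p = 0
  dos <- density_of_states(c(0, 0.005), c(0, -Inf), "conformational",
                           dof = 10)
  f <- 10
  tot <- convolve_to_total(dos, beta_min = 1)
  # ln Gamma(E) = const + (f/2-1) ln E
  keep <- tot$grid > 1
  expect_equal(diff(tot$ln_omega[keep]),
               diff((f / 2 - 1) * log(tot$grid[keep])), tolerance = 1e-10)
  b <- micro_beta(tot)
  i <- which(tot$grid > 2 & tot$grid < 40 & !b$boundary)
  expect_equal(b$beta[i], (f / 2 - 1) / tot$grid[i], tolerance = 1e-6)
  # total-energy beta can never be negative
  expect_true(all(b$beta[!b$boundary] >= 0))
})

test_that("Gaussian Omega convolves to quadrature-accurate Gamma", {
  f <- 8
  grid <- seq(-6, 6, by = 0.01)
  dos <- make_toy_dos("single_gaussian", list(mean = 0, sd = 1), grid,
                      dof = f)
  tot <- convolve_to_total(dos, beta_min = 1)
  # independent route: adaptive quadrature of the defining integral
  lnG_quad <- function(E) {
    v <- integrate(function(x) exp(dnorm(x, 0, 1, log = TRUE) +
                                     (f / 2 - 1) * log(E - x)),
                   -6, min(6, E - 1e-12), rel.tol = 1e-10)$value
    log(v) - lgamma(f / 2)
  }
  Es <- c(2, 5, 10, 20)
  got <- approx(tot$grid, tot$ln_omega, xout = Es)$y
  want <- vapply(Es, lnG_quad, numeric(1))
  # equal up to one common additive constant
  expect_equal(diff(got), diff(want), tolerance = 1e-6)
})

test_that("f = 2 reduces the convolution to the cumulative integral", {
  grid <- seq(0, 5, by = 0.01)
  dos <- density_of_states(grid, -0.5 * (grid - 2)^2, "conformational",
                           dof = 2)
  tot <- convolve_to_total(dos, dof = 2, beta_min = 1)
  expect_true(all(diff(tot$ln_omega) >= 0))  # monotone: volume entropy
  # ln Gamma(grid[k]) sums the bins strictly below grid[k]
  csum <- log(cumsum(exp(dos$ln_omega)) * dos$de)
  ia <- match(round(dos$grid[-1] / dos$de), round(tot$grid / tot$de))
  expect_equal(diff(tot$ln_omega[ia]),
               diff(csum[-length(csum)]), tolerance = 1e-9)
})

test_that("five-point derivative reproduces analytic inverse temperatures", {
  grid <- seq(-5, 5, by = 0.01)
  dos <- make_toy_dos("single_gaussian", list(mean = 1, sd = 1.5), grid)
  b <- micro_beta(dos)
  expect_equal(b$beta[!b$boundary], -(grid[!b$boundary] - 1) / 1.5^2,
               tolerance = 1e-8)
  expect_error(micro_beta(density_of_states(1:4, rep(0, 4))), "5 grid")
})

test_that("derivative and expectation estimators of beta(E) agree", {
  f <- 12
  dos <- dg_dos(modes = c(-5, 5), sds = c(1.2, 1.2), n = 2001, dof = f)
  tot <- convolve_to_total(dos, beta_min = 0.5)
  bd <- micro_beta(tot, "derivative")
  be <- micro_beta(tot, "expectation")
  i <- which(tot$grid > 2 & tot$grid < 60)
  expect_equal(bd$beta[i], be$beta[i], tolerance = 1e-4)
  expect_true(all(be$beta[i] >= 0))
})

test_that("canonical distributions are normalized with Gaussian conjugacy", {
  grid <- seq(-30, 20, by = 0.02)
  mu <- -3; s <- 2
  dos <- make_toy_dos("single_gaussian", list(mean = mu, sd = s), grid)
  for (beta in c(-1, 0, 0.5, 2)) {
    cd <- canonical_distribution(dos, beta, strict = FALSE)
    expect_lt(abs(sum(exp(cd$ln_p)) * cd$de - 1), 1e-10)
    expect_equal(cd$mean, mu - beta * s^2, tolerance = 1e-6)
    expect_equal(cd$var, s^2, tolerance = 1e-6)
  }
  # reweighting identity: P_b2 is the renormalized tilt of P_b1
  p1 <- canonical_distribution(dos, 0.5, strict = FALSE)
  p2 <- canonical_distribution(dos, 1.5, strict = FALSE)
  rhs <- p1$ln_p - 1.0 * grid
  rhs <- rhs - (logsumexp(rhs) + log(p1$de))
  expect_equal(p2$ln_p, rhs, tolerance = 1e-9)
  # edge-peaked distribution is flagged in strict mode
  expect_error(canonical_distribution(dos, 30), "edge")
})

test_that("symmetric double-well is equal-height at its symmetry point", {
  dos <- dg_dos(modes = c(-4, 4), sds = c(1, 1))
  cd <- canonical_distribution(dos, 0, strict = FALSE)
  ex <- mucadrop:::locate_extrema(cd$ln_p)
  expect_false(is.null(ex))
  expect_equal(cd$ln_p[ex$i_minus], cd$ln_p[ex$i_plus], tolerance = 1e-10)
})

test_that("Maxwell-Boltzmann convolution equals the Gamma-route distribution", {
  f <- 10
  beta <- 1.3
  dos <- dg_dos(modes = c(-6, 2), sds = c(1, 2), weights = c(0.3, 0.7),
                n = 1201, dof = f)
  tot <- convolve_to_total(dos, beta_min = beta)
  pA <- canonical_distribution(tot, beta, strict = FALSE)
  pc <- canonical_distribution(dos, beta, strict = FALSE)
  pB <- mb_convolve(pc, dof = f, e_grid = tot$grid)
  expect_lt(total_variation(pA, pB), 1e-6)
  # moment identities of the kinetic Gamma kernel
  expect_equal(pB$mean - pc$mean, f / (2 * beta), tolerance = 1e-6)
  expect_equal(pB$var - pc$var, f / (2 * beta^2), tolerance = 1e-5)
  # convolution smooths: peak height cannot grow
  expect_lte(max(exp(pB$ln_p)), max(exp(pc$ln_p)) + 1e-12)
})

test_that("kinetic equipartition holds across a beta scan", {
  f <- 14
  dos <- dg_dos(modes = c(-5, 3), sds = c(0.8, 1.6), weights = c(0.4, 0.6),
                n = 1501, dof = f)
  tot <- convolve_to_total(dos, beta_min = 0.8)
  for (beta in seq(0.8, 2.4, by = 0.4)) {
    ptot <- canonical_distribution(tot, beta, strict = FALSE)
    pcnf <- canonical_distribution(dos, beta, strict = FALSE)
    expect_equal(ptot$mean - pcnf$mean, f / (2 * beta), tolerance = 1e-6)
    expect_equal(ptot$var - pcnf$var, f / (2 * beta^2), tolerance = 1e-5)
    # C_V differs by exactly f/2
    expect_equal(ptot$cv - pcnf$cv, f / 2, tolerance = 1e-4)
  }
})

test_that("specific-heat peaks coincide between the two formulations", {
  f <- 10
  dos <- dg_dos(modes = c(-8, 0), sds = c(1, 2), weights = c(0.45, 0.55),
                n = 1401, dof = f)
  tot <- convolve_to_total(dos, beta_min = 0.5)
  betas <- seq(0.5, 1.6, by = 0.005)
  sc <- specific_heat_scan(dos, betas)
  st <- specific_heat_scan(tot, betas)
  expect_equal(betas[which.max(sc$cv)], betas[which.max(st$cv)],
               tolerance = 0.005 + 1e-12)
})

test_that("density of states files round-trip bit-stably", {
  dos <- dg_dos(n = 301, dof = 6)
  f <- tempfile(fileext = ".dat")
  write_dos(dos, f)
  d2 <- read_dos(f)
  expect_identical(d2$grid, dos$grid)
  expect_identical(d2$ln_omega, dos$ln_omega)
  expect_identical(d2$kind, dos$kind)
  expect_identical(d2$dof, 6)
  unlink(f)
})
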