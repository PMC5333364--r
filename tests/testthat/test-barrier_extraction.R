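# Equal-height / equal-area constructions, landscape, rate relation.

test_that("symmetric double Gaussian: transition at the symmetry point with
           the mixture-density barrier", {
  a <- 4; s <- 1
  dos <- dg_dos(modes = c(-a, a), sds = c(s, s), n = 3201)
  tr <- find_equal_height(dos, bracket = c(-0.5, 0.5))
  expect_equal(tr$beta_eqh, 0, tolerance = 1e-6)
  # analytic mixture oracle at beta = 0: extrema of the continuous density
  mix <- function(e) 0.5 * (dnorm(e, -a, s) + dnorm(e, a, s))
  pk <- optimize(mix, c(-a - s, -a + s), maximum = TRUE)$objective
  barrier_oracle <- log(pk / mix(0))
  expect_equal(tr$barrier, barrier_oracle, tolerance = 1e-3)
  expect_lt(tr$e_minus, tr$e_zero)
  expect_lt(tr$e_zero, tr$e_plus)
})

test_that("unequal mixture weights shift beta_eqh as a dense scan predicts", {
  dos <- dg_dos(modes = c(-4, 4), sds = c(1, 1), weights = c(0.2, 0.8),
                n = 3201)
  tr <- find_equal_height(dos, bracket = c(-0.5, 0.5))
  # brute-force oracle: scan 10^4 beta values, measure the height imbalance
  # directly on the mixture density
  grid <- dos$grid
  dens <- exp(dos$ln_omega)
  imb <- function(b) {
    w <- dens * exp(-b * grid)
    lo <- max(w[grid < 0]); hi <- max(w[grid > 0])
    log(hi) - log(lo)
  }
  betas <- seq(-0.2, 0.2, length.out = 1e4)
  scan <- vapply(betas, imb, numeric(1))
  b_scan <- betas[which.min(abs(scan))]
  expect_equal(tr$beta_eqh, b_scan, tolerance = 1e-4)
  expect_gt(tr$beta_eqh, 0)  # tilting towards the lighter low-E mode
})

test_that("single-peaked systems are rejected as not first-order-like", {
  grid <- seq(-5, 5, by = 0.01)
  dos <- make_toy_dos("single_gaussian", list(mean = 0, sd = 1), grid)
  expect_error(find_equal_height(dos, bracket = c(-1, 1)),
               "not first-order-like")
  expect_error(find_equal_area(dos, bracket = c(-1, 1)),
               "not first-order-like")
})

test_that("equal-height and equal-area are identical on toy landscapes", {
  set.seed(99)
  for (k in 1:10) {
    a <- runif(1, 2.5, 6)
    s1 <- runif(1, 0.6, 1.5); s2 <- runif(1, 0.6, 1.5)
    w1 <- runif(1, 0.25, 0.75)
    dos <- dg_dos(modes = c(-a, a), sds = c(s1, s2),
                  weights = c(w1, 1 - w1), n = 2001)
    trh <- find_equal_height(dos, bracket = c(-1, 1))
    tra <- find_equal_area(dos, bracket = c(-1, 1))
    expect_lt(abs(trh$beta_eqh - tra$beta_eqa), 1e-6)
    expect_lt(abs(trh$barrier - tra$barrier), 1e-6)
    expect_gte(tra$barrier, 0)
  }
})

test_that("cubic back-bending beta(E) equal-areas at its symmetry value", {
  grid <- seq(-6, 6, by = 0.005)
  dos <- make_toy_dos("cubic_backbend",
                      list(beta0 = 1.7, c3 = 0.5, d1 = 2, e0 = 0), grid)
  ans <- attr(dos, "answers")
  mb <- list(grid = grid, beta = ans$beta_of_e(grid),
             boundary = rep(FALSE, length(grid)), kind = "conformational",
             method = "analytic", de = dos$de)
  class(mb) <- "micro_beta"
  tr <- find_equal_area(mb, bracket = c(1.4, 2.0))
  expect_equal(tr$beta_eqa, 1.7, tolerance = 1e-6)
  expect_equal(tr$e_zero, 0, tolerance = 1e-6)
  expect_equal(sort(c(tr$e_minus, tr$e_plus)), c(-2, 2), tolerance = 1e-4)
  # the lobe area from the curve matches the dos-route barrier
  trd <- find_equal_area(dos, bracket = c(1.4, 2.0))
  expect_equal(trd$beta_eqa, 1.7, tolerance = 1e-6)
  expect_equal(tr$barrier, trd$barrier, tolerance = 1e-3)
  # monotone curve: no construction
  mono <- mb
  mono$beta <- 2 - 0.1 * grid^1  # strictly decreasing; still 1 crossing
  expect_error(find_equal_area(mono), "monotone|not first-order")
})

test_that("the barrier is invariant under energy-origin and ln-Omega shifts", {
  dos <- dg_dos(modes = c(-4, 4), sds = c(0.8, 1.4), weights = c(0.4, 0.6),
                n = 1601)
  tr0 <- find_equal_height(dos, c(-1, 1))
  shifted <- density_of_states(dos$grid + 100, dos$ln_omega + 12.3,
                               dos$kind, dos$dof)
  tr1 <- find_equal_height(shifted, c(-1, 1))
  expect_equal(tr1$barrier, tr0$barrier, tolerance = 1e-9)
  expect_equal(tr1$beta_eqh, tr0$beta_eqh, tolerance = 1e-6)
  expect_equal(tr1$e_zero, tr0$e_zero + 100, tolerance = 1e-9)
})

test_that("2D landscape: separable histograms give a flat path and the
           marginal reproduces the 1D free energy", {
  w <- muca_weights(seq(1, 30), -0.05 * seq(1, 30)^2)
  g <- exp(-((1:30) - 15)^2 / 40)
  h <- exp(-((1:8) - 3)^2 / 2)
  H <- round(1e4 * outer(g, h)) + 1
  ls <- build_landscape(H, w)
  expect_true(all(ls$path$n_d == ls$path$n_d[1]))
  # marginalizing exp(-F) over N_D recovers the 1D free energy estimated
  # from the marginal histogram with the same weight convention
  f1 <- -log(rowSums(exp(-ls$f)))
  fref <- -(log(rowSums(H)) - mucadrop:::ln_w_bin_avg(w))
  expect_equal(diff(f1), diff(fref), tolerance = 1e-9)
})

test_that("2D landscape path and saddle match an exhaustive grid search", {
  # two basins connected through a saddle in (E, N_D)
  w <- muca_weights(seq(-20, 9), rep(0, 30))
  nd <- 1:12
  e <- w$bin_centers
  fmodel <- outer(e, nd, function(E, D)
    (E + 15)^2 / 10 * (D / 6) + (E + 3)^2 / 8 * (1 - D / 12) +
      0.5 * (D - 6)^2 * exp(-(E + 9)^2 / 8))
  H <- round(1e6 * exp(-fmodel))
  keep <- rowSums(H) > 0
  ls <- build_landscape(H, w)
  # per-column argmin against direct search on the model
  for (i in which(keep)) {
    expect_equal(ls$path$n_d[ls$path$e_p == e[i]],
                 which.min(ifelse(H[i, ] > 0, -log(H[i, ]), Inf)))
  }
  isad <- which.max(ls$path$f)
  expect_equal(ls$saddle$f, max(ls$path$f))
})

test_that("relative rates follow the barrier exponentially", {
  expect_equal(relative_rate(0), 1)
  expect_equal(relative_rate(log(2)), 0.5)
  # a shift s between formulations multiplies the rate by e^s
  b <- 7.3; s <- 1.1
  expect_equal(relative_rate(b - s) / relative_rate(b), exp(s),
               tolerance = 1e-12)
  expect_error(relative_rate(NA))
})
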