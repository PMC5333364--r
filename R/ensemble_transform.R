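# From sampled histograms to thermodynamics: the conformational density of
# states Omega(E_p), its kinetic-energy convolution Gamma(E), microcanonical
# inverse temperatures in both energy formulations, and canonical energy
# distributions.  All distribution arithmetic is done in the log domain;
# additive constants are fixed by normalization only.

#' Construct a density-of-states object
#'
#' Holds `ln Omega(E_p)` (conformational) or `ln Gamma(E)` (total) on a
#' uniform energy grid, known up to an additive constant.  `NA` entries mark
#' unpopulated (masked) bins.
#'
#' @param grid uniform, increasing energy bin centers.
#' @param ln_omega log density of states per bin (`NA` = masked).
#' @param kind `"conformational"` or `"total"`.
#' @param dof number of momentum degrees of freedom `f` (may be `NA` for
#'   pure toy fixtures).
#' @return object of class `dos`.
#' @export
density_of_states <- function(grid, ln_omega,
                              kind = c("conformational", "total"),
                              dof = NA) {
  kind <- match.arg(kind)
  stopifnot(length(grid) == length(ln_omega), length(grid) >= 2)
  de <- diff(grid)
  stopifnot(all(abs(de - de[1]) < 1e-8 * max(abs(de[1]), 1e-300)))
  d <- list(grid = as.numeric(grid), ln_omega = as.numeric(ln_omega),
            kind = kind, dof = dof, de = de[1])
  class(d) <- "dos"
  d
}

#' @export
print.dos <- function(x, ...) {
  cat(sprintf("dos (%s): %d bins on [%.5g, %.5g], dE = %.4g, f = %s\n",
              x$kind, length(x$grid), x$grid[1], x$grid[length(x$grid)],
              x$de, format(x$dof)))
  invisible(x)
}

# Log of the bin-averaged sampling weight.  The sampler interpolates ln W
# linearly between bin centers, so the stationary density within bin k is
# Omega(E) * W_interp(E); dividing the counts by the bin-centre value of W
# would leave a bias set by the local curvature of ln W (including its
# converged noise) that does not shrink with statistics.  The exact average
# of the piecewise-exponential W over each bin removes it.
ln_w_bin_avg <- function(weights) {
  lw <- weights$ln_w
  de <- weights$de
  n <- length(lw)
  aL <- c(lw[1], (lw[-n] + lw[-1]) / 2)   # value at left edge of each bin
  aR <- c((lw[-n] + lw[-1]) / 2, lw[n])   # value at right edge
  half <- function(a, b) {                # ln of (1/de) * int over half-bin
    m <- pmax(a, b)
    d <- b - a
    r <- ifelse(abs(d) < 1e-12, (a + b) / 2 - m,
                log(abs(expm1(-abs(d)))) - log(abs(d)))
    m + r + log(0.5)
  }
  # each half-bin spans from an edge value to the centre value
  apply(cbind(half(aL, lw), half(lw, aR)), 1, logsumexp)
}

#' Estimate the conformational density of states from a flat-histogram run
#'
#' `ln Omega(E_p) = ln H(E_p) - ln W(E_p)` per bin, up to an additive
#' constant, where `W` is averaged over each bin exactly as the sampler
#' interpolates it.  Bins with zero counts are masked; interior masked bins
#' flanked by populated ones are filled by linear interpolation of
#' `ln Omega`, while masked bins at the edges truncate the support.
#'
#' @param hist a `muca_run`, or a numeric vector of counts on the weight
#'   bins.
#' @param weights the [muca_weights()] used to generate the histogram.
#' @param dof momentum degrees of freedom to attach (e.g. `spec$dof`).
#' @return [density_of_states()] of kind `"conformational"`.
#' @export
estimate_ln_omega <- function(hist, weights, dof = NA) {
  H <- if (inherits(hist, "muca_run")) hist$hist else as.numeric(hist)
  stopifnot(length(H) == length(weights$bin_centers))
  if (all(H == 0)) stop("histogram is empty")
  lo <- ifelse(H > 0, log(H), NA) - ln_w_bin_avg(weights)
  keep <- range(which(H > 0))
  grid <- weights$bin_centers[keep[1]:keep[2]]
  lo <- lo[keep[1]:keep[2]]
  lo <- fill_interior_na(grid, lo)
  density_of_states(grid, lo, "conformational", dof = dof)
}

fill_interior_na <- function(grid, y) {
  na <- which(is.na(y))
  if (length(na)) {
    ok <- which(!is.na(y))
    y[na] <- stats::approx(grid[ok], y[ok], xout = grid[na])$y
  }
  y
}

#' Convolve the conformational density of states to the total-energy ensemble
#'
#' The total-energy microcanonical partition function follows from
#' \eqn{\Omega(E_p)} by integrating out the momenta:
#' \deqn{\Gamma(E) \propto \int dE_p\, \Omega(E_p)\,
#'       \frac{(E - E_p)^{f/2 - 1}}{\Gamma_{fn}(f/2)}, \quad E_p < E,}
#' with \eqn{\Omega(E_p) = 0} below the sampled support.  The integral is
#' evaluated in the log domain by bin-midpoint quadrature (consistent with
#' the histogram provenance of \eqn{\Omega}); the \eqn{(2\pi m/h^2)^{f/2}}
#' prefactor is set to 1 as it cancels in every normalized distribution.
#' Since all \eqn{\Omega \ge 0}, \eqn{\ln\Gamma} is non-decreasing in
#' \eqn{E}, so the total-energy inverse temperature can never be negative.
#'
#' @param dos conformational [density_of_states()].
#' @param dof momentum degrees of freedom `f >= 2` (default: from `dos`).
#' @param beta_min smallest inverse temperature at which the result will be
#'   used; the energy grid is extended upward by `10 * dof/(2*beta_min)`
#'   beyond the conformational grid so that the kinetic tail is covered.
#' @param e_max optional explicit upper end of the energy grid.
#' @return [density_of_states()] of kind `"total"`; the conformational
#'   source is carried in `attr(, "source")` for exact expectation-value
#'   estimators.
#' @export
convolve_to_total <- function(dos, dof = dos$dof, beta_min = 1,
                              e_max = NULL) {
  stopifnot(dos$kind == "conformational", is.finite(dof), dof >= 2)
  de <- dos$de
  lo <- dos$ln_omega
  lo[is.na(lo)] <- -Inf
  if (is.null(e_max))
    e_max <- max(dos$grid) + 10 * dof / (2 * beta_min)
  e_grid <- seq(dos$grid[1] + de, e_max, by = de)
  a <- dof / 2 - 1
  # chunked outer computation of logsumexp_i [lnO_i + a*ln(E_j - E_i)]
  ln_gamma <- numeric(length(e_grid))
  chunk <- max(1L, floor(4e7 / length(dos$grid)))
  for (s in seq(1, length(e_grid), by = chunk)) {
    j <- s:min(s + chunk - 1L, length(e_grid))
    dE <- outer(e_grid[j], dos$grid, "-")
    m <- matrix(rep(lo, each = length(j)), nrow = length(j))
    # strictly positive kinetic energy; the epsilon guards against grid
    # points that coincide up to rounding (relevant only for f = 2 where
    # the kernel does not vanish at the boundary)
    pos <- dE > 1e-9 * de
    kern <- matrix(-Inf, nrow(m), ncol(m))
    kern[pos] <- a * log(dE[pos])
    ln_gamma[j] <- logsumexp_rows(m + kern)
  }
  ln_gamma <- ln_gamma + log(de) - lgamma(dof / 2)
  out <- density_of_states(e_grid, ln_gamma, "total", dof = dof)
  attr(out, "source") <- dos
  out
}

#' Microcanonical inverse temperature
#'
#' For a conformational density of states returns
#' \eqn{\hat\beta(E_p) = d\ln\Omega/dE_p}, for a total-energy one
#' \eqn{\beta(E) = d\ln\Gamma/dE}, via the five-point central stencil
#' \eqn{[f(x-2h) - 8f(x-h) + 8f(x+h) - f(x+2h)]/(12h)}; the outermost two
#' points on each side use one-sided five-point stencils and are flagged as
#' lower accuracy.  For a total-energy density of states that carries its
#' conformational source, `method = "expectation"` instead evaluates the
#' microcanonical expectation-value estimator
#' \eqn{\beta(E) = (f/2 - 1)\,\langle (E - E_p)^{-1} \rangle_E} under the
#' microcanonical density \eqn{\propto \Omega(E_p)(E - E_p)^{f/2-1}}, an
#' independent route used for cross-checks.
#'
#' @param dos a [density_of_states()] (at least 5 grid points).
#' @param method `"derivative"` (default) or `"expectation"`.
#' @return object of class `micro_beta`: `grid`, `beta`, logical `boundary`
#'   flags, `kind`, `method`.
#' @export
micro_beta <- function(dos, method = c("derivative", "expectation")) {
  method <- match.arg(method)
  n <- length(dos$grid)
  if (n < 5) stop("need at least 5 grid points")
  h <- dos$de
  if (method == "derivative") {
    y <- fill_interior_na(dos$grid, dos$ln_omega)
    b <- rep(NA_real_, n)
    i <- 3:(n - 2)
    b[i] <- (y[i - 2] - 8 * y[i - 1] + 8 * y[i + 1] - y[i + 2]) / (12 * h)
    # one-sided five-point stencils, O(h^4) but noisier
    b[1] <- sum(c(-25, 48, -36, 16, -3) * y[1:5]) / (12 * h)
    b[2] <- sum(c(-3, -10, 18, -6, 1) * y[1:5]) / (12 * h)
    b[n - 1] <- -sum(c(-3, -10, 18, -6, 1) * y[n:(n - 4)]) / (12 * h)
    b[n] <- -sum(c(-25, 48, -36, 16, -3) * y[n:(n - 4)]) / (12 * h)
    boundary <- c(TRUE, TRUE, rep(FALSE, n - 4), TRUE, TRUE)
  } else {
    if (dos$kind != "total" || is.null(attr(dos, "source")))
      stop("expectation estimator needs a total-energy dos with its",
           " conformational source attached")
    src <- attr(dos, "source")
    f <- dos$dof
    lo <- src$ln_omega
    lo[is.na(lo)] <- -Inf
    b <- vapply(dos$grid, function(E) {
      dE <- E - src$grid
      okk <- dE > 0
      if (!any(okk)) return(NA_real_)
      num <- logsumexp(lo[okk] + (f / 2 - 2) * log(dE[okk]))
      den <- logsumexp(lo[okk] + (f / 2 - 1) * log(dE[okk]))
      (f / 2 - 1) * exp(num - den)
    }, numeric(1))
    boundary <- rep(FALSE, n)
  }
  out <- list(grid = dos$grid, beta = b, boundary = boundary,
              kind = dos$kind, method = method, de = h)
  class(out) <- "micro_beta"
  out
}

#' Canonical energy probability distribution
#'
#' \eqn{P_\beta(E) = \Gamma(E) e^{-\beta E}/Z_\beta} on the grid of the
#' supplied density of states (conformational variant
#' \eqn{\hat P_\beta(E_p) \propto \Omega(E_p) e^{-\beta E_p}}), normalized
#' so that `sum(p * dE) = 1`.  Moments and the specific heat
#' \eqn{C = \beta^2 \mathrm{Var}(E)} are computed by bin-midpoint
#' quadrature on the same grid.
#'
#' @param dos a [density_of_states()].
#' @param beta inverse temperature.
#' @param strict error when the distribution peaks at the grid edge, which
#'   signals a non-normalizable (or truncated) Boltzmann weight.  Internal
#'   scans disable this.
#' @return object of class `canonical_dist`: `grid`, `ln_p` (normalized),
#'   `beta`, `kind`, `mean`, `var`, `cv` and the log partition sum `ln_z`
#'   (up to the additive constant of the dos).
#' @export
canonical_distribution <- function(dos, beta, strict = TRUE) {
  lw <- dos$ln_omega - beta * dos$grid
  lw[is.na(lw)] <- -Inf
  ln_z <- logsumexp(lw) + log(dos$de)
  if (!is.finite(ln_z)) stop("Boltzmann weight vanishes on the whole grid")
  ln_p <- lw - ln_z
  pk <- which.max(ln_p)
  if (strict && (pk == 1L || pk == length(ln_p)))
    stop("canonical distribution peaks at the grid edge at beta = ", beta,
         "; support truncated or weight non-normalizable")
  p <- exp(ln_p)
  mu <- sum(p * dos$grid) * dos$de
  v <- sum(p * (dos$grid - mu)^2) * dos$de
  out <- list(grid = dos$grid, ln_p = ln_p, beta = beta, kind = dos$kind,
              de = dos$de, mean = mu, var = v, cv = beta^2 * v,
              ln_z = ln_z)
  class(out) <- "canonical_dist"
  out
}

#' @export
print.canonical_dist <- function(x, ...) {
  cat(sprintf(
    "canonical_dist (%s) at beta = %.6g: <E> = %.6g, Var = %.6g, C = %.6g\n",
    x$kind, x$beta, x$mean, x$var, x$cv))
  invisible(x)
}

#' Total-energy distribution via Maxwell-Boltzmann convolution
#'
#' Convolves the conformational canonical distribution
#' \eqn{\hat P_\beta(E_p)} with the kinetic-energy density of `f` momentum
#' degrees of freedom -- a Gamma distribution with shape `f/2` and rate
#' \eqn{\beta} (the energy form of the `f`-dimensional Maxwell-Boltzmann
#' distribution) -- yielding the total-energy distribution
#' \eqn{P_\beta(E)}.  This is an independent route to the same object as
#' `canonical_distribution(convolve_to_total(dos), beta)`; the two must
#' agree, which is used as an internal consistency check.  The kinetic
#' momentum integral also fixes the partition-function relation
#' \eqn{Z_\beta = \beta^{-f/2} \hat Z_\beta} (prefactor 1 in reduced
#' units), exposed as the attribute `ln_z_offset` \eqn{= -(f/2)\ln\beta}.
#'
#' @param p_conf conformational [canonical_distribution()].
#' @param dof momentum degrees of freedom `f`.
#' @param beta inverse temperature; must equal `p_conf$beta`.
#' @param e_grid optional total-energy grid (default: conformational grid
#'   extended upward by `10 * dof/(2*beta)`).
#' @return [canonical_distribution()] of kind `"total"`.
#' @export
mb_convolve <- function(p_conf, dof, beta = p_conf$beta, e_grid = NULL) {
  stopifnot(inherits(p_conf, "canonical_dist"),
            p_conf$kind == "conformational")
  if (abs(beta - p_conf$beta) > 1e-12 * max(abs(beta), 1))
    stop("beta must match the conformational distribution")
  de <- p_conf$de
  if (is.null(e_grid))
    e_grid <- seq(p_conf$grid[1] + de,
                  max(p_conf$grid) + 10 * dof / (2 * beta), by = de)
  ln_p <- numeric(length(e_grid))
  chunk <- max(1L, floor(4e7 / length(p_conf$grid)))
  for (s in seq(1, length(e_grid), by = chunk)) {
    j <- s:min(s + chunk - 1L, length(e_grid))
    dE <- outer(e_grid[j], p_conf$grid, "-")
    kern <- dgamma(dE, shape = dof / 2, rate = beta, log = TRUE)
    kern[dE <= 0] <- -Inf
    m <- matrix(rep(p_conf$ln_p, each = length(j)), nrow = length(j)) + kern
    ln_p[j] <- logsumexp_rows(m)
  }
  ln_p <- ln_p + log(de)
  ln_p <- ln_p - (logsumexp(ln_p) + log(de))  # renormalize on the grid
  p <- exp(ln_p)
  mu <- sum(p * e_grid) * de
  v <- sum(p * (e_grid - mu)^2) * de
  out <- list(grid = e_grid, ln_p = ln_p, beta = beta, kind = "total",
              de = de, mean = mu, var = v, cv = beta^2 * v,
              ln_z = p_conf$ln_z - (dof / 2) * log(beta))
  class(out) <- "canonical_dist"
  attr(out, "ln_z_offset") <- -(dof / 2) * log(beta)
  out
}

#' Total variation distance between two distributions on a common grid
#'
#' @param p,q `canonical_dist` objects on identical grids (an error
#'   otherwise).
#' @return `0.5 * sum |p - q| dE`.
#' @export
total_variation <- function(p, q) {
  ia <- match(round(p$grid / p$de), round(q$grid / q$de))
  if (anyNA(ia)) stop("distributions live on incompatible grids")
  0.5 * sum(abs(exp(p$ln_p) - exp(q$ln_p[ia]))) * p$de
}

#' Canonical moments over a temperature scan
#'
#' Convenience scan of mean energy, variance and specific heat
#' \eqn{C(\beta) = \beta^2 \mathrm{Var}(E)} over a vector of inverse
#' temperatures; used e.g. to locate specific-heat peaks.
#'
#' @param dos a [density_of_states()].
#' @param betas inverse temperatures.
#' @return data frame with columns `beta`, `mean`, `var`, `cv`.
#' @export
specific_heat_scan <- function(dos, betas) {
  rows <- lapply(betas, function(b) {
    cd <- canonical_distribution(dos, b, strict = FALSE)
    data.frame(beta = b, mean = cd$mean, var = cd$var, cv = cd$cv)
  })
  do.call(rbind, rows)
}
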