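# Finite-size transition temperature and free-energy barrier: equal-height
# and equal-area constructions (mathematically identical, implemented as
# independent routes), the two-dimensional (E_p, N_D) landscape, and the
# rate relation.

transition_result <- function(formulation, beta_eqh = NA, beta_eqa = NA,
                              e_minus = NA, e_zero = NA, e_plus = NA,
                              barrier = NA, method = NA) {
  out <- list(formulation = formulation, beta_eqh = beta_eqh,
              beta_eqa = beta_eqa, e_minus = e_minus, e_zero = e_zero,
              e_plus = e_plus, barrier = barrier,
              error = c(beta = NA_real_, barrier = NA_real_),
              method = method)
  class(out) <- "transition_result"
  out
}

#' @export
print.transition_result <- function(x, ...) {
  fmt <- function(v, s) if (is.na(s)) sprintf("%.6g", v)
                        else sprintf("%.6g +- %.2g", v, s)
  cat(sprintf("transition_result (%s, %s):\n", x$formulation, x$method))
  b <- if (!is.na(x$beta_eqh)) x$beta_eqh else x$beta_eqa
  cat("  beta_t  =", fmt(b, x$error[["beta"]]), "\n")
  cat("  barrier =", fmt(x$barrier, x$error[["barrier"]]), "k_B T\n")
  cat(sprintf("  E- = %.6g, E0 = %.6g, E+ = %.6g\n", x$e_minus, x$e_zero,
              x$e_plus))
  invisible(x)
}

# Locate the double-peak structure of a log-probability curve.  A Gaussian-
# smoothed copy (sd in bins) is used only to find the peak REGIONS; the
# returned indices are extrema of the unsmoothed curve, whose values are
# what enters the barrier.  Maxima with prominence below `min_prom` (in ln
# units) are treated as noise.  Returns NULL when no two-peak structure
# exists.
locate_extrema <- function(ln_p, smooth_sd = 2, min_prom = 0.1,
                           warn = FALSE) {
  n <- length(ln_p)
  sm <- gaussian_smooth(ln_p, smooth_sd)
  d <- diff(sm)
  imax <- which(d[-1] < 0 & d[-(n - 1)] >= 0) + 1L
  if (length(imax) >= 2) {
    # prominence filter: a maximum must rise above the deepest smoothed
    # valley separating it from its higher neighbour maxima
    keep <- vapply(imax, function(i) {
      others <- imax[imax != i & sm[imax] >= sm[i]]
      if (!length(others)) return(TRUE)
      j <- others[which.min(abs(others - i))]
      valley <- min(sm[min(i, j):max(i, j)])
      (sm[i] - valley) > min_prom
    }, logical(1))
    imax <- imax[keep]
  }
  if (length(imax) < 2) return(NULL)
  if (length(imax) > 2 && warn)
    warning("more than two prominent peaks; using the outermost pair")
  i1 <- min(imax)
  i2 <- max(imax)
  i0s <- which.min(sm[i1:i2]) + i1 - 1L
  i_minus <- which.max(ln_p[seq_len(i0s)])
  i_plus <- which.max(ln_p[i0s:n]) + i0s - 1L
  if (i_plus - i_minus < 2) return(NULL)
  i_zero <- which.min(ln_p[i_minus:i_plus]) + i_minus - 1L
  list(i_minus = i_minus, i_zero = i_zero, i_plus = i_plus)
}

# signed balance at beta: ln P(high-E peak) - ln P(low-E peak); a large
# sentinel with the correct sign when only one phase is present
peak_balance <- function(dos, beta, smooth_sd, warn = FALSE) {
  cd <- canonical_distribution(dos, beta, strict = FALSE)
  ex <- locate_extrema(cd$ln_p, smooth_sd, warn = warn)
  if (is.null(ex)) {
    # single peak: decide which phase dominates.  For a total-energy dos
    # the grid carries a long kinetic tail, so the divider is the midpoint
    # of the conformational support shifted by the mean kinetic energy.
    src <- attr(dos, "source")
    divider <- if (dos$kind == "total" && !is.null(src))
      mean(range(src$grid)) + dos$dof / (2 * beta)
    else mean(range(dos$grid))
    gas_side <- dos$grid[which.max(cd$ln_p)] > divider
    return(list(h = if (gas_side) 1e9 else -1e9, ex = NULL, cd = cd))
  }
  list(h = cd$ln_p[ex$i_plus] - cd$ln_p[ex$i_minus], ex = ex, cd = cd)
}

# re-read extrema of ln_p around remembered peak indices (used when the
# final bisection point sits so close to balance that the smoothed locator
# drops one marginal peak)
refine_extrema <- function(ln_p, ex, halfwidth = 6L) {
  n <- length(ln_p)
  win <- function(i) max(1L, i - halfwidth):min(n, i + halfwidth)
  i_minus <- win(ex$i_minus)[which.max(ln_p[win(ex$i_minus)])]
  i_plus <- win(ex$i_plus)[which.max(ln_p[win(ex$i_plus)])]
  if (i_plus - i_minus < 2) return(NULL)
  i_zero <- which.min(ln_p[i_minus:i_plus]) + i_minus - 1L
  list(i_minus = i_minus, i_zero = i_zero, i_plus = i_plus)
}

# expand a beta bracket until the balance changes sign
expand_bracket <- function(fn, bracket, max_expand = 60) {
  b1 <- bracket[1]; b2 <- bracket[2]
  h1 <- fn(b1); h2 <- fn(b2)
  k <- 0
  while (sign(h1) == sign(h2) && k < max_expand) {
    if (h1 < 0) b1 <- b1 * 0.8 else b2 <- b2 * 1.25
    h1 <- fn(b1); h2 <- fn(b2)
    k <- k + 1
  }
  if (sign(h1) == sign(h2))
    stop("no double-peak structure in bracket: not first-order-like here")
  c(b1, b2)
}

#' Equal-height transition temperature and barrier
#'
#' Root-finds the inverse temperature \eqn{\beta_{eqh}} at which the two
#' outer maxima of the canonical energy distribution have equal height.  The
#' barrier is the log ratio of peak to valley probability,
#' \eqn{\beta\Delta F = \ln P(E^\pm) - \ln P(E^0)}, in units of
#' \eqn{k_B T}.  Peaks are located on a lightly smoothed copy of the curve
#' but all values are read from the unsmoothed one.
#'
#' @param dos a [density_of_states()] (either energy formulation).
#' @param bracket initial search interval in `beta`, auto-expanded.
#' @param tol bisection tolerance in `beta`.
#' @param smooth_sd Gaussian smoothing width (bins) for peak location.
#' @return a `transition_result` (fields `beta_eqh`, `e_minus`, `e_zero`,
#'   `e_plus`, `barrier`); errors if no double-peak structure exists.
#' @export
find_equal_height <- function(dos, bracket = c(1, 2.5), tol = 1e-8,
                              smooth_sd = 2) {
  last_ex <- NULL
  fn <- function(b) {
    pb <- peak_balance(dos, b, smooth_sd)
    ex <- pb$ex
    if (is.null(ex) && !is.null(last_ex))
      ex <- refine_extrema(pb$cd$ln_p, last_ex)
    if (is.null(ex)) return(pb$h)
    last_ex <<- ex
    pb$cd$ln_p[ex$i_plus] - pb$cd$ln_p[ex$i_minus]
  }
  br <- expand_bracket(fn, bracket)
  b1 <- br[1]; b2 <- br[2]
  h1 <- fn(b1)
  while (b2 - b1 > tol) {
    bm <- (b1 + b2) / 2
    hm <- fn(bm)
    if (hm == 0) { b1 <- b2 <- bm; break }
    if (sign(hm) == sign(h1)) { b1 <- bm; h1 <- hm } else b2 <- bm
  }
  bstar <- (b1 + b2) / 2
  pb <- peak_balance(dos, bstar, smooth_sd, warn = TRUE)
  ex <- pb$ex
  if (is.null(ex) && !is.null(last_ex))
    ex <- refine_extrema(pb$cd$ln_p, last_ex)
  if (is.null(ex))
    stop("no double-peak structure at the equal-height point: ",
         "not first-order-like here")
  lp <- pb$cd$ln_p
  barrier <- (lp[ex$i_minus] + lp[ex$i_plus]) / 2 - lp[ex$i_zero]
  tr <- transition_result(
    formulation = if (dos$kind == "total") "total_E" else "conformational_Ep",
    beta_eqh = bstar,
    e_minus = dos$grid[ex$i_minus], e_zero = dos$grid[ex$i_zero],
    e_plus = dos$grid[ex$i_plus], barrier = barrier,
    method = "equal_height")
  tr
}

#' Equal-area transition temperature and barrier
#'
#' The microcanonical inverse temperature \eqn{\beta(E)} back-bends through
#' a first-order-like transition; a horizontal line \eqn{\beta = const}
#' then crosses it three times and encloses two lobes.  The equal-area
#' inverse temperature \eqn{\beta_{eqa}} makes the two lobes equal,
#' \eqn{\int_{E^-}^{E^+} [\beta(E) - \beta_{eqa}]\, dE = 0}, and the (equal)
#' lobe area is the free-energy barrier.  This is the Maxwell construction
#' in the energy plane and is mathematically identical to the equal-height
#' criterion, because the lobe-area difference telescopes to the difference
#' of the canonical log-probabilities at the outer crossings.
#'
#' For a `dos` input the construction uses the exact discrete derivative on
#' bin midpoints, whose summed areas reproduce differences of
#' \eqn{\ln\Omega} (or \eqn{\ln\Gamma}) without quadrature error; the
#' identity with [find_equal_height()] then holds to root-finding tolerance.
#' For a bare [micro_beta()] curve the crossings and lobes are computed by
#' linear interpolation and trapezoidal areas.
#'
#' @param x a [density_of_states()] or a [micro_beta()] curve.
#' @param ... passed on to methods.
#' @return a `transition_result` with `beta_eqa` and `barrier` (lobe area).
#' @export
find_equal_area <- function(x, ...) UseMethod("find_equal_area")

#' @rdname find_equal_area
#' @param bracket initial search interval in `beta`, auto-expanded.
#' @param tol bisection tolerance in `beta`.
#' @param smooth_sd Gaussian smoothing width (bins) used to locate the outer
#'   crossings (= canonical peaks).
#' @export
find_equal_area.dos <- function(x, bracket = c(1, 2.5), tol = 1e-8,
                                smooth_sd = 2, ...) {
  dos <- x
  y <- fill_interior_na(dos$grid, dos$ln_omega)
  de <- dos$de
  bhalf <- diff(y) / de  # beta on bin midpoints; sums telescope exactly
  area_between <- function(i, j, beta) {
    if (j <= i) return(0)
    sum((bhalf[i:(j - 1)] - beta) * de)
  }
  last_ex <- NULL
  net <- function(b) {
    pb <- peak_balance(dos, b, smooth_sd)
    ex <- pb$ex
    if (is.null(ex) && !is.null(last_ex))
      ex <- refine_extrema(pb$cd$ln_p, last_ex)
    if (is.null(ex)) return(list(a = pb$h, ex = NULL))
    last_ex <<- ex
    # outer crossings of beta(E) with the horizontal line are the canonical
    # peak positions; the net enclosed area decides the balance
    list(a = area_between(ex$i_minus, ex$i_plus, b), ex = ex)
  }
  fn <- function(b) net(b)$a
  br <- expand_bracket(fn, bracket)
  b1 <- br[1]; b2 <- br[2]
  a1 <- fn(b1)
  while (b2 - b1 > tol) {
    bm <- (b1 + b2) / 2
    am <- fn(bm)
    if (am == 0) { b1 <- b2 <- bm; break }
    if (sign(am) == sign(a1)) { b1 <- bm; a1 <- am } else b2 <- bm
  }
  bstar <- (b1 + b2) / 2
  nt <- net(bstar)
  if (is.null(nt$ex))
    stop("no back-bending in beta(E): not first-order-like here")
  ex <- nt$ex
  lobe <- abs(area_between(ex$i_zero, ex$i_plus, bstar))
  # average with the other lobe; they differ only by the residual net area
  lobe2 <- abs(area_between(ex$i_minus, ex$i_zero, bstar))
  transition_result(
    formulation = if (dos$kind == "total") "total_E" else "conformational_Ep",
    beta_eqa = bstar,
    e_minus = dos$grid[ex$i_minus], e_zero = dos$grid[ex$i_zero],
    e_plus = dos$grid[ex$i_plus], barrier = (lobe + lobe2) / 2,
    method = "equal_area")
}

#' @rdname find_equal_area
#' @export
find_equal_area.micro_beta <- function(x, bracket = NULL, tol = 1e-8, ...) {
  E <- x$grid[!is.na(x$beta)]
  b <- x$beta[!is.na(x$beta)]
  if (is.null(bracket)) bracket <- range(b) + c(1, -1) * 1e-3 * diff(range(b))
  crossings <- function(beta) {
    s <- b - beta
    idx <- which(s[-1] * s[-length(s)] < 0)
    xc <- E[idx] + (E[idx + 1] - E[idx]) * s[idx] / (s[idx] - s[idx + 1])
    xz <- E[which(s == 0)]
    sort(c(xc, xz))
  }
  net_area <- function(beta, lim) {
    # trapezoid of (beta(E) - beta) between two energies (on the curve)
    grid2 <- sort(unique(c(lim, E[E > lim[1] & E < lim[2]])))
    bv <- stats::approx(E, b, xout = grid2)$y - beta
    sum(diff(grid2) * (head(bv, -1) + tail(bv, -1)) / 2)
  }
  fn <- function(beta) {
    cr <- crossings(beta)
    if (length(cr) < 3) {
      # single crossing: decide by which phase dominates
      return(if (mean(b > beta) > 0.5) 1e9 else -1e9)
    }
    if (length(cr) > 3)
      warning("more than three crossings; using the outermost pair")
    net_area(beta, c(cr[1], cr[length(cr)]))
  }
  br <- tryCatch(expand_bracket(fn, bracket),
                 error = function(e) stop("monotone beta(E): ",
                                          "no equal-area construction"))
  b1 <- br[1]; b2 <- br[2]
  a1 <- fn(b1)
  while (b2 - b1 > tol) {
    bm <- (b1 + b2) / 2
    am <- fn(bm)
    if (am == 0) { b1 <- b2 <- bm; break }
    if (sign(am) == sign(a1)) { b1 <- bm; a1 <- am } else b2 <- bm
  }
  bstar <- (b1 + b2) / 2
  cr <- crossings(bstar)
  if (length(cr) < 3) stop("monotone beta(E): no equal-area construction")
  e_minus <- cr[1]; e_plus <- cr[length(cr)]
  e_zero <- cr[ceiling(length(cr) / 2)]
  lobe <- abs(net_area(bstar, c(e_zero, e_plus)))
  transition_result(
    formulation = if (x$kind == "total") "total_E" else "conformational_Ep",
    beta_eqa = bstar, e_minus = e_minus, e_zero = e_zero, e_plus = e_plus,
    barrier = lobe, method = "equal_area")
}

#' Two-dimensional free-energy landscape over (E_p, N_D)
#'
#' \eqn{F(E_p, N_D) = -[\ln H(E_p, N_D) - \ln W(E_p)]} up to a constant
#' (shifted so the minimum is 0).  The minimal free-energy path
#' \eqn{N_D^*(E_p)} minimizes F over the droplet size in each populated
#' energy column; at fixed \eqn{E_p} the profile typically resembles a
#' parabola with a single minimum, and columns violating this are counted
#' in `multimin_columns`.  The saddle estimate is the maximum of F along
#' the path.
#'
#' @param hist2d a `muca_run` (uses its 2D histogram) or a counts matrix
#'   (energy bins x droplet size).
#' @param weights the matching [muca_weights()].
#' @return object of class `landscape2d`: `e_grid`, `nd_grid`, `f` matrix
#'   (`NA` = unpopulated), `path` data frame, `saddle`, `multimin_columns`.
#' @export
build_landscape <- function(hist2d, weights) {
  H <- if (inherits(hist2d, "muca_run")) hist2d$hist2d else as.matrix(hist2d)
  stopifnot(nrow(H) == length(weights$bin_centers))
  if (all(H == 0)) stop("2D histogram is empty")
  f <- -(ifelse(H > 0, log(H), NA) - ln_w_bin_avg(weights))
  f <- f - min(f, na.rm = TRUE)
  pop <- which(rowSums(H) > 0)
  path <- do.call(rbind, lapply(pop, function(i) {
    nd <- which.min(f[i, ])
    data.frame(e_p = weights$bin_centers[i], n_d = nd, f = f[i, nd])
  }))
  multimin <- sum(vapply(pop, function(i) {
    v <- f[i, !is.na(f[i, ])]
    if (length(v) < 3) return(FALSE)
    sum(diff(sign(diff(v))) > 0) > 1  # more than one local minimum
  }, logical(1)))
  isad <- which.max(path$f)
  out <- list(e_grid = weights$bin_centers, nd_grid = seq_len(ncol(H)),
              f = f, path = path,
              saddle = path[isad, , drop = FALSE],
              multimin_columns = multimin)
  class(out) <- "landscape2d"
  out
}

#' @export
print.landscape2d <- function(x, ...) {
  cat(sprintf(
    "landscape2d: %d x %d grid, saddle F = %.4g at E_p = %.5g, N_D = %d\n",
    length(x$e_grid), length(x$nd_grid), x$saddle$f, x$saddle$e_p,
    x$saddle$n_d))
  invisible(x)
}

#' Nucleation rate up to the kinetic prefactor
#'
#' Classical nucleation theory relates the rate to the barrier as
#' \eqn{R = \kappa\, e^{-\beta\Delta F}}; the kinetic prefactor
#' \eqn{\kappa} (diffusion, attachment) is set to 1, so this is the
#' relative equilibrium formation rate.
#'
#' @param barrier dimensionless barrier \eqn{\beta\Delta F}.
#' @return `exp(-barrier)`.
#' @export
relative_rate <- function(barrier) {
  stopifnot(all(is.finite(barrier)))
  exp(-barrier)
}

#' Full transition analysis of a production run
#'
#' Runs the complete chain histogram -> \eqn{\Omega(E_p)} ->
#' (\eqn{\Gamma(E)}) -> equal-height and equal-area constructions, in the
#' conformational and/or total energy formulation, and propagates errors by
#' jackknife: the entire extraction is re-run on each leave-one-block-out
#' subsample of the time series.
#'
#' @param run a [run_production()] result.
#' @param weights the [muca_weights()] used for the run.
#' @param spec the [system_spec()].
#' @param formulation `"both"`, `"conformational"` or `"total"`.
#' @param bracket beta search bracket passed to the extractors.
#' @param n_blocks jackknife blocks (0 to skip error estimation).
#' @return named list of `transition_result` objects (per formulation),
#'   each with `beta_eqh`, `beta_eqa`, `barrier` and jackknife errors, plus
#'   the estimated `dos` objects.
#' @export
analyze_run <- function(run, weights, spec,
                        formulation = c("both", "conformational", "total"),
                        bracket = c(1, 2.5), n_blocks = 20) {
  formulation <- match.arg(formulation)
  want_c <- formulation != "total"
  want_t <- formulation != "conformational"
  extract <- function(H) {
    dos_c <- estimate_ln_omega(H, weights, dof = spec$dof)
    res <- list()
    if (want_c) {
      trh <- find_equal_height(dos_c, bracket)
      tra <- find_equal_area(dos_c, bracket)
      trh$beta_eqa <- tra$beta_eqa
      trh$barrier_area <- tra$barrier
      res$conformational <- trh
      res$dos_conformational <- dos_c
    }
    if (want_t) {
      dos_t <- convolve_to_total(dos_c, spec$dof, beta_min = bracket[1])
      trh <- find_equal_height(dos_t, bracket)
      tra <- find_equal_area(dos_t, bracket)
      trh$beta_eqa <- tra$beta_eqa
      trh$barrier_area <- tra$barrier
      res$total <- trh
      res$dos_total <- dos_t
    }
    res
  }
  full <- extract(run$hist)
  if (n_blocks >= 2) {
    jk <- jackknife(run$series$e_p, function(e) {
      r <- extract(bin_series(e, weights))
      bc <- if (want_c) r$conformational$beta_eqh else NA
      bt <- if (want_t) r$total$beta_eqh else NA
      vc <- if (want_c) r$conformational$barrier else NA
      vt <- if (want_t) r$total$barrier else NA
      c(beta_c = bc, bar_c = vc, beta_t = bt, bar_t = vt,
        dbeta = bc - bt, dbar = vc - vt)
    }, n_blocks = n_blocks)
    if (want_c)
      full$conformational$error <- c(beta = unname(jk$sigma["beta_c"]),
                                     barrier = unname(jk$sigma["bar_c"]))
    if (want_t)
      full$total$error <- c(beta = unname(jk$sigma["beta_t"]),
                            barrier = unname(jk$sigma["bar_t"]))
    if (want_c && want_t) {
      # the two formulations derive from the same series: their difference
      # has strongly correlated errors, so it gets its own jackknife
      full$ensemble_difference <- data.frame(
        quantity = c("dbeta_eqa", "dbarrier"),
        value = c(full$conformational$beta_eqh - full$total$beta_eqh,
                  full$conformational$barrier - full$total$barrier),
        sigma = c(unname(jk$sigma["dbeta"]), unname(jk$sigma["dbar"])))
    }
    full$jackknife <- jk
  }
  full
}
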