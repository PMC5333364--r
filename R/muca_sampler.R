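# Multicanonical sampling: energy-window location, iterative determination
# of the weight function W(E_p), and production runs recording (E_p, N_D).

#' Default Monte Carlo move mix
#'
#' Probabilities for the six elementary move types, in the fixed order
#' short displacement, long (uniform-in-box) displacement, monomer shift,
#' bond rotation, double bridging, rigid chain displacement.  Particles use
#' short/long displacements (0.8/0.2); polymers use monomer shifts (0.6),
#' bond rotations (0.2), double bridging (0.1) and whole-chain displacements
#' (0.1).
#'
#' @param spec a [system_spec()].
#' @return named numeric vector of length 6 summing to 1.
#' @export
default_move_mix <- function(spec) {
  if (spec$kind == "lj_gas")
    c(short = 0.8, long = 0.2, monomer = 0, bond_rot = 0,
      bridge = 0, chain = 0)
  else
    c(short = 0, long = 0, monomer = 0.6, bond_rot = 0.2,
      bridge = 0.1, chain = 0.1)
}

#' Multicanonical acceptance rule
#'
#' Accept a proposal with probability `min(1, exp(ln_w_new - ln_w_old))`.
#' Only differences of `ln W` enter, so the additive constant of the weights
#' is irrelevant.  Proposals leaving the energy window carry
#' `ln_w_new = -Inf` and are always rejected.
#'
#' @param ln_w_old,ln_w_new log-weights of current and proposed state.
#' @param u uniform random number(s) in `[0,1)`; drawn if missing.
#' @return logical vector of accept decisions.
#' @export
muca_accept <- function(ln_w_old, ln_w_new, u = runif(length(ln_w_new))) {
  d <- ln_w_new - ln_w_old
  d[is.na(d)] <- -Inf
  u < exp(pmin(d, 0))
}

#' Locate the multicanonical energy window
#'
#' Runs two short canonical (fixed-temperature) simulations at bracketing
#' inverse temperatures: a gas-phase run at `beta_lo` (well below the
#' transition, i.e. hotter) and a droplet-phase run at `beta_hi` (well
#' above).  The window spans from below the droplet-run mean to above the
#' gas-run mean, with margins of several standard deviations so that both
#' canonical peaks at the transition temperature lie strictly inside.
#'
#' @param spec a [system_spec()].
#' @param beta_lo,beta_hi bracketing inverse temperatures.
#' @param n_sweeps sweeps per canonical pre-run.
#' @param seed integer seed.
#' @param margin guard bands in units of the canonical standard deviation
#'   of each pre-run: `margin[1]` below the droplet run, `margin[2]` above
#'   the gas run.  The droplet pre-run is colder than the transition, so
#'   its mean already lies below the droplet peak and needs little margin;
#'   an over-deep window only adds physically irrelevant bins that slow the
#'   flat-histogram walk.
#' @return list with `window = c(lo, hi)`, the two relaxed configurations
#'   (`cfg_gas`, `cfg_droplet`) and the pre-run statistics.
#' @export
locate_energy_window <- function(spec, beta_lo = 1.0, beta_hi = 2.6,
                                 n_sweeps = 3000, seed = 1,
                                 margin = c(2.5, 4)) {
  margin <- rep_len(margin, 2)
  run_can <- function(cfg, beta, k) {
    cpp_run_muca(cfg$positions, spec_as_list(spec),
                 w_centers = c(0, 1), w_lnw = c(0, 0),
                 elo = -1e300, ehi = 1e300, beta = beta,
                 n_sweeps = as.integer(n_sweeps),
                 move_mix = default_move_mix(spec),
                 d_short = 0.5, r_cl = spec$lj_cutoff,
                 seed = as.integer(fold_seed(seed, k)),
                 keep_series = TRUE, resync_every = 2000L,
                 measure_nd = FALSE)
  }
  cfg_gas <- initial_configuration(spec, "gas", seed = fold_seed(seed, 11),
                                   relax_beta = beta_lo)
  cfg_dro <- initial_configuration(spec, "droplet",
                                   seed = fold_seed(seed, 12),
                                   relax_beta = beta_hi)
  rg <- run_can(cfg_gas, beta_lo, 1)
  rd <- run_can(cfg_dro, beta_hi, 2)
  half <- function(x) x[seq(floor(length(x) / 2) + 1, length(x))]
  eg <- half(rg$series_e)
  ed <- half(rd$series_e)
  lo <- mean(ed) - margin[1] * max(stats::sd(ed), 1e-3)
  hi <- mean(eg) + margin[2] * max(stats::sd(eg), 1e-3)
  list(window = c(lo, hi),
       cfg_gas = configuration(rg$positions, spec, validate = FALSE),
       cfg_droplet = configuration(rd$positions, spec, validate = FALSE),
       stats = data.frame(phase = c("gas", "droplet"),
                          beta = c(beta_lo, beta_hi),
                          mean_e = c(mean(eg), mean(ed)),
                          sd_e = c(stats::sd(eg), stats::sd(ed))))
}

#' Construct a multicanonical weight object
#'
#' @param bin_centers increasing, uniformly spaced energy bin centers.
#' @param ln_w log-weight per bin (finite inside the window).
#' @param window energy window `c(lo, hi)`; defaults to the outer bin edges.
#' @param d_short short-displacement amplitude frozen into the weights.
#' @param converged logical convergence status.
#' @return object of class `muca_weights`.
#' @export
muca_weights <- function(bin_centers, ln_w, window = NULL, d_short = 0.5,
                         converged = NA) {
  stopifnot(length(bin_centers) == length(ln_w), length(bin_centers) >= 2)
  de <- diff(bin_centers)
  stopifnot(all(abs(de - de[1]) < 1e-8 * abs(de[1])))
  de <- de[1]
  stopifnot(de > 0, all(is.finite(ln_w)))
  if (is.null(window))
    window <- c(bin_centers[1] - de / 2, bin_centers[length(bin_centers)] +
                  de / 2)
  w <- list(bin_centers = bin_centers, ln_w = ln_w, de = de,
            window = window, interpolation = "linear_in_lnW",
            d_short = d_short, converged = converged)
  class(w) <- "muca_weights"
  w
}

#' @export
print.muca_weights <- function(x, ...) {
  cat(sprintf(
    "muca_weights: %d bins on [%.4g, %.4g], dE = %.4g, converged: %s\n",
    length(x$bin_centers), x$window[1], x$window[2], x$de, x$converged))
  invisible(x)
}

# One accumulated error-weighted weight update (Berg-style recursion).
# For each adjacent bin pair the log-weight difference is corrected by
# (kappa/g) * ln(H_k/H_{k+1}) with kappa = H_k H_{k+1}/(H_k + H_{k+1}) the
# statistical weight of this iteration and g its running sum; returns the
# updated ln W and accumulator.  Kept free of any sampler state so that the
# recursion itself can be validated on enumerable toy histograms.
muca_weight_update <- function(ln_w, H, g = numeric(length(H) - 1)) {
  n <- length(H)
  stopifnot(length(ln_w) == n, length(g) == n - 1)
  Hk <- H[-n]
  Hk1 <- H[-1]
  kap <- ifelse(Hk + Hk1 > 0, Hk * Hk1 / (Hk + Hk1), 0)
  g <- g + kap
  ratio <- ifelse(Hk > 0 & Hk1 > 0, log(Hk / Hk1), 0)
  corr <- ifelse(g > 0, kap / g, 0) * ratio
  list(ln_w = cumsum(c(ln_w[1], diff(ln_w) + corr)), g = g)
}

#' Iteratively determine multicanonical weights
#'
#' Repeats cycles of sampling with the current weight function and updating
#' it from the measured histogram until the histogram is flat.  The update
#' is the error-weighted accumulated recursion: for each pair of adjacent
#' bins the log-weight difference is corrected by
#' \eqn{\hat\kappa_k \ln(H_k/H_{k+1})} where
#' \eqn{\kappa_k = H_k H_{k+1}/(H_k + H_{k+1})} is the statistical weight of
#' the current iteration and \eqn{\hat\kappa_k = \kappa_k / \sum \kappa_k}
#' normalizes over all iterations seen so far.  This accumulation keeps
#' information from early iterations and is far more stable than dividing by
#' the latest histogram alone.  The short-move amplitude is tuned towards a
#' 30--55% acceptance rate during iteration and frozen afterwards (detailed
#' balance holds exactly during production).
#'
#' @param spec a [system_spec()].
#' @param window energy window `c(lo, hi)`, e.g. from
#'   [locate_energy_window()].
#' @param n_bins number of weight bins across the window (>= 50 advised).
#' @param sweeps_per_iter sweeps of the first iteration; later iterations
#'   grow geometrically (factor 1.2, capped at 8x).
#' @param max_iter iteration cap.
#' @param flatness_target convergence requires
#'   `min(H)/mean(H) >= flatness_target` with all bins visited.
#' @param move_mix,d_short move probabilities and initial short-move
#'   amplitude.
#' @param beta_init slope of the initial (canonical) weight guess.
#' @param anchors optional data frame with columns `mean_e` and `beta`
#'   (e.g. the `stats` of [locate_energy_window()]): the initial weights are
#'   then built from a piecewise-linear interpolation of the microcanonical
#'   inverse temperature between these anchor points,
#'   \eqn{\ln W(E) = -\int \beta(E)\,dE}, which typically spans the full
#'   window in the first iteration.
#' @param cfg starting configuration; defaults to a relaxed gas start.
#' @param seed integer seed.
#' @param verbose print per-iteration diagnostics.
#' @return a [muca_weights()] object; its `converged` field reports success,
#'   and `history` holds per-iteration flatness.  On non-convergence the
#'   last weights are returned with `converged = FALSE` and a warning.
#' @export
iterate_weights <- function(spec, window, n_bins = 101,
                            sweeps_per_iter = 2000, max_iter = 60,
                            flatness_target = 0.7,
                            move_mix = default_move_mix(spec),
                            d_short = 0.5, beta_init = 1.8, cfg = NULL,
                            anchors = NULL, seed = 1, verbose = FALSE) {
  stopifnot(length(window) == 2, window[1] < window[2])
  de <- (window[2] - window[1]) / n_bins
  centers <- window[1] + de * (seq_len(n_bins) - 0.5)
  lnw <- if (is.null(anchors)) {
    -beta_init * centers
  } else {
    o <- order(anchors$mean_e)
    bmid <- stats::approx(anchors$mean_e[o], anchors$beta[o],
                          xout = centers + de / 2, rule = 2)$y
    -cumsum(bmid * de)
  }
  if (is.null(cfg))
    cfg <- initial_configuration(spec, "gas", seed = fold_seed(seed, 99),
                                 relax_beta = beta_init)
  pos <- cfg$positions
  g <- numeric(n_bins - 1)
  hist_acc <- numeric(n_bins)
  flat_hist <- numeric(0)
  converged <- FALSE
  sweeps <- sweeps_per_iter
  for (it in seq_len(max_iter)) {
    res <- cpp_run_muca(pos, spec_as_list(spec), centers, lnw,
                        window[1], window[2], beta = NA_real_,
                        n_sweeps = as.integer(round(sweeps)),
                        move_mix = move_mix, d_short = d_short,
                        r_cl = spec$lj_cutoff,
                        seed = as.integer(fold_seed(seed, it)),
                        keep_series = FALSE, resync_every = 2000L,
                        measure_nd = FALSE)
    pos <- res$positions
    H <- res$hist
    hist_acc <- hist_acc + H
    flat <- if (all(H > 0)) min(H) / mean(H) else 0
    flat_hist <- c(flat_hist, flat)
    if (verbose)
      message(sprintf("iter %2d: sweeps %6d flat %.3f d %.3f span %d/%d",
                      it, round(sweeps), flat, d_short, sum(H > 0), n_bins))
    if (flat >= flatness_target) { converged <- TRUE; break }
    upd <- muca_weight_update(lnw, H, g)
    lnw <- upd$ln_w
    g <- upd$g
    # amplitude tuning (frozen for production)
    att <- res$attempts[c(1, 3)]
    acc <- res$accepts[c(1, 3)]
    if (sum(att) > 0) {
      ar <- sum(acc) / sum(att)
      # cap at the pair-minimum distance: larger steps would stall the
      # dense droplet even if the dilute gas still accepts them
      if (ar < 0.30) d_short <- max(0.05, d_short * 0.8)
      else if (ar > 0.55) d_short <- min(1.0, d_short * 1.25)
    }
    sweeps <- min(sweeps * 1.35, 25 * sweeps_per_iter)
  }
  w <- muca_weights(centers, lnw, window, d_short = d_short,
                    converged = converged)
  w$history <- flat_hist
  w$iterations <- it
  w$config <- configuration(pos, spec, validate = FALSE)
  w$seed <- seed
  if (!converged)
    warning("weight iteration did not reach flatness ", flatness_target,
            " within ", max_iter, " iterations (last flatness ",
            signif(tail(flat_hist, 1), 3), ")")
  w
}

#' Production run with fixed multicanonical weights
#'
#' Samples with the converged (frozen) weight function, for which detailed
#' balance holds exactly, and records the `(E_p, N_D)` time series once per
#' sweep together with the energy histogram and the two-dimensional
#' `(E_p, N_D)` histogram.  Several independent walkers (differing only in
#' their sub-seed) may be run; their histograms are summed and their series
#' concatenated, realizing parallel multicanonical sampling as
#' independent-walker merging.
#'
#' @param cfg starting [configuration()] (inside the window), e.g. the
#'   `config` carried by the weights; a list of configurations is cycled
#'   over walkers, so alternating droplet- and gas-side starts cover both
#'   phases even before the walkers tunnel.
#' @param weights a converged [muca_weights()] object.
#' @param spec a [system_spec()].
#' @param n_sweeps sweeps per walker.
#' @param walkers number of independent walkers.
#' @param seed integer seed; the walker id is folded into it.
#' @param r_cl cluster cutoff used for \eqn{N_D} (default: the LJ cutoff).
#' @param measure_nd record droplet sizes (disable for speed in tests).
#' @return object of class `muca_run`: `series` data frame
#'   (`sweep`, `e_p`, `n_d`, `walker`), `hist`, `hist2d`, `bin_centers`,
#'   acceptance summary, final configurations.
#' @export
run_production <- function(cfg, weights, spec, n_sweeps, walkers = 1,
                           seed = 1, r_cl = spec$lj_cutoff,
                           measure_nd = TRUE) {
  stopifnot(inherits(weights, "muca_weights"))
  n_sweeps <- as.integer(n_sweeps)
  nb <- length(weights$bin_centers)
  hist <- numeric(nb)
  hist2d <- matrix(0, nb, spec$n_constituents)
  series <- vector("list", walkers)
  acc <- att <- numeric(6)
  cfgs <- vector("list", walkers)
  starts <- if (inherits(cfg, "configuration")) list(cfg) else cfg
  for (wk in seq_len(walkers)) {
    start <- starts[[(wk - 1L) %% length(starts) + 1L]]
    res <- cpp_run_muca(start$positions, spec_as_list(spec),
                        weights$bin_centers, weights$ln_w,
                        weights$window[1], weights$window[2],
                        beta = NA_real_, n_sweeps = n_sweeps,
                        move_mix = default_move_mix(spec),
                        d_short = weights$d_short, r_cl = r_cl,
                        seed = as.integer(fold_seed(seed, wk)),
                        keep_series = TRUE, resync_every = 2000L,
                        measure_nd = measure_nd)
    hist <- hist + res$hist
    if (measure_nd) hist2d <- hist2d + res$hist2d
    series[[wk]] <- data.frame(
      sweep = seq_len(max(n_sweeps, 0L)),
      e_p = res$series_e,
      n_d = if (measure_nd) res$series_nd
            else rep(NA_integer_, length(res$series_e)),
      walker = rep(wk, length(res$series_e)))
    acc <- acc + res$accepts
    att <- att + res$attempts
    cfgs[[wk]] <- configuration(res$positions, spec, validate = FALSE)
  }
  out <- list(series = do.call(rbind, series),
              hist = hist, hist2d = hist2d,
              bin_centers = weights$bin_centers, de = weights$de,
              window = weights$window,
              acceptance = data.frame(
                move = names(default_move_mix(spec)),
                attempts = att, accepts = acc,
                rate = ifelse(att > 0, acc / att, NA)),
              configs = cfgs, seed = seed, n_sweeps = n_sweeps,
              walkers = walkers, spec_hash = spec_hash(spec))
  class(out) <- "muca_run"
  out
}

#' @export
print.muca_run <- function(x, ...) {
  cat(sprintf("muca_run: %d walker(s) x %d sweeps, %d bins on [%.4g, %.4g]\n",
              x$walkers, x$n_sweeps, length(x$bin_centers), x$window[1],
              x$window[2]))
  cat(sprintf("  flatness min/mean = %.3f\n",
              if (all(x$hist > 0)) min(x$hist) / mean(x$hist) else 0))
  invisible(x)
}

#' Histogram a potential-energy series on weight bins
#'
#' @param e_p numeric vector of energies.
#' @param weights a [muca_weights()] (supplies bin geometry).
#' @return integer vector of counts per bin.
#' @export
bin_series <- function(e_p, weights) {
  edges <- c(weights$bin_centers - weights$de / 2,
             weights$bin_centers[length(weights$bin_centers)] +
               weights$de / 2)
  idx <- findInterval(e_p, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(weights$bin_centers))
  tabulate(idx, nbins = length(weights$bin_centers))
}
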