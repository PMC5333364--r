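# Analytic and synthetic inputs: toy densities of states with closed-form
# answers, seeded synthetic scaling series, and constructed cluster
# configurations.  Every fixture ships its own ground truth so each
# analysis stage can be tested without running a simulation.

#' Analytic toy density of states
#'
#' Families (parameters in `params`):
#' \describe{
#'   \item{`double_gaussian`}{`modes`, `sds`, `weights`: mixture
#'     \eqn{\Omega(E) = \sum_k w_k N(E; m_k, s_k)}; for the symmetric case
#'     (equal widths/weights, modes \eqn{\pm a}) the transition lies at
#'     `beta_eq = 0` by symmetry.}
#'   \item{`single_gaussian`}{`mean`, `sd`: \eqn{\hat\beta(E) = -(E-\mu)/s^2},
#'     no barrier.}
#'   \item{`power_law`}{`exponent` \eqn{k}: \eqn{\Omega \propto E^k} on a
#'     positive grid; the ideal-gas form with \eqn{k = f/2-1}, giving
#'     \eqn{\beta(E) = k/E}.}
#'   \item{`cubic_backbend`}{`beta0`, `c3`, `d1`, `e0`: inverse temperature
#'     \eqn{\beta(E) = \beta_0 - c_3 (E-E_0)^3 + d_1 (E-E_0)}, antisymmetric
#'     about \eqn{E_0} (hence `beta_eq = beta0` exactly) and oriented so
#'     that \eqn{\beta} falls off at the outer crossings, as for a
#'     physical back-bending transition; `ln_omega` is its antiderivative.}
#'   \item{`discrete_levels`}{`ln_omega`: values given per grid point.}
#' }
#'
#' @param family fixture family name.
#' @param params named list of family parameters.
#' @param grid energy grid (uniform).
#' @param dof degrees of freedom to attach (optional).
#' @return a [density_of_states()] with attributes `family`, `params` and
#'   `answers` (closed-form `beta_eq`, crossings, ... where they exist).
#' @export
make_toy_dos <- function(family = c("double_gaussian", "single_gaussian",
                                    "power_law", "cubic_backbend",
                                    "discrete_levels"),
                         params = list(), grid, dof = NA) {
  family <- match.arg(family)
  p <- params
  answers <- list()
  ln_omega <- switch(family,
    double_gaussian = {
      stopifnot(length(p$modes) == 2, length(p$sds) == 2)
      w <- if (is.null(p$weights)) c(0.5, 0.5) else p$weights
      comp <- sapply(1:2, function(k)
        log(w[k]) + stats::dnorm(grid, p$modes[k], p$sds[k], log = TRUE))
      symmetric <- (abs(p$sds[1] - p$sds[2]) < 1e-12 &&
                      abs(w[1] - w[2]) < 1e-12 &&
                      abs(p$modes[1] + p$modes[2]) < 1e-12)
      if (symmetric) answers$beta_eq <- 0
      logsumexp_rows(comp)
    },
    single_gaussian = {
      answers$beta_of_e <- function(E) -(E - p$mean) / p$sd^2
      stats::dnorm(grid, p$mean, p$sd, log = TRUE)
    },
    power_law = {
      stopifnot(all(grid > 0))
      answers$beta_of_e <- function(E) p$exponent / E
      p$exponent * log(grid)
    },
    cubic_backbend = {
      x <- grid - p$e0
      answers$beta_eq <- p$beta0
      answers$crossings <- p$e0 + c(-1, 0, 1) * sqrt(p$d1 / p$c3)
      answers$beta_of_e <- function(E)
        p$beta0 - p$c3 * (E - p$e0)^3 + p$d1 * (E - p$e0)
      p$beta0 * x - p$c3 * x^4 / 4 + p$d1 * x^2 / 2
    },
    discrete_levels = {
      stopifnot(length(p$ln_omega) == length(grid))
      p$ln_omega
    })
  d <- density_of_states(grid, ln_omega, "conformational", dof = dof)
  attr(d, "family") <- family
  attr(d, "params") <- p
  attr(d, "answers") <- answers
  d
}

#' Synthetic finite-size scaling series
#'
#' Deterministic (seeded) noisy data drawn from the scaling models used by
#' the fitters, for fit-recovery tests.
#'
#' @param model `"barrier"` (`tau_eff*sqrt(N) + alpha*log(N) + c`),
#'   `"temperature"` (`beta0 + a N^-1/4 + b N^-1/2 + c N^-3/4`) or
#'   `"difference"` (`k N^-p`).
#' @param params named list of model parameters (`p` defaults to 3/4).
#' @param sizes positive increasing system sizes.
#' @param noise_sigma Gaussian noise sd, recycled over sizes; also the
#'   quoted error bar.
#' @param seed integer seed (fixed seed gives bit-identical series).
#' @return a [scaling_series()] with attribute `truth` (noiseless values).
#' @export
make_scaling_series <- function(model = c("barrier", "temperature",
                                          "difference"),
                                params, sizes, noise_sigma = 0, seed = NULL) {
  model <- match.arg(model)
  stopifnot(all(sizes > 0), all(diff(sizes) > 0))
  p <- params
  truth <- switch(model,
    barrier = p$tau_eff * sqrt(sizes) +
      (if (is.null(p$alpha)) 0 else p$alpha) * log(sizes) + p$c,
    temperature = p$beta0 + p$a * sizes^(-1 / 4) + p$b * sizes^(-1 / 2) +
      p$c * sizes^(-3 / 4),
    difference = p$k * sizes^(-(if (is.null(p$p)) 0.75 else p$p)))
  sg <- rep_len(noise_sigma, length(sizes))
  noise <- if (all(sg == 0)) 0 else with_seed(seed, rnorm(length(sizes), 0, sg))
  # noiseless series carry unit errors: the fit is then an interpolation
  out <- scaling_series(sizes, truth + noise, ifelse(sg > 0, sg, 1))
  attr(out, "truth") <- truth
  attr(out, "model") <- model
  out
}

#' Construct a configuration with prescribed cluster structure
#'
#' Places compact clusters of given sizes in the periodic box such that
#' the connected components at cutoff `r_cl` are exactly `cluster_sizes`:
#' members of a cluster sit on a tight cubic sublattice (axis spacing
#' `0.45 r_cl`, so neighbours are connected), and cluster centres are
#' separated by more than the cluster diameters plus `gap` (> `r_cl`).  For polymer
#' systems each cluster member is a straight rod-shaped chain.
#'
#' @param spec a [system_spec()]; `sum(cluster_sizes)` must equal the number
#'   of constituents.
#' @param cluster_sizes integer vector of intended component sizes.
#' @param gap clear space between cluster hulls (must exceed `r_cl` for the
#'   clusters to stay separate).
#' @param r_cl connectivity cutoff the fixture is built for.
#' @param jitter small uniform coordinate noise (kept well below the
#'   connectivity margins).
#' @param seed integer seed for the jitter.
#' @return a [configuration()]; attribute `cluster_sizes` records the
#'   ground truth (sorted decreasing).
#' @export
make_cluster_fixture <- function(spec, cluster_sizes,
                                 gap = 1.1 * spec$lj_cutoff,
                                 r_cl = spec$lj_cutoff, jitter = 0.02,
                                 seed = 1) {
  stopifnot(sum(cluster_sizes) == spec$n_constituents)
  L <- spec$box_length
  a <- 0.45 * r_cl
  m <- spec$monomers_per_chain
  # diameter of the largest cluster ball, from the actual lattice extent
  kmax <- max(cluster_sizes)
  ball <- lattice_ball(kmax, a, 0)
  diam <- 2 * max(sqrt(rowSums(ball^2)), 0) +
    (if (m > 1) (m - 1) * spec$fene_r0 else 0)
  pitch <- diam + gap
  # greedy centre placement: candidates on a finer grid, kept when their
  # minimum-image distance to all accepted centres is at least `pitch`
  nclust <- length(cluster_sizes)
  ncand <- max(2L, ceiling(nclust^(1 / 3)) + 1L)
  cand <- as.matrix(expand.grid(x = seq_len(ncand), y = seq_len(ncand),
                                z = seq_len(ncand))) * (L / ncand)
  centers <- matrix(NA_real_, 0, 3)
  for (i in seq_len(nrow(cand))) {
    if (nrow(centers) == nclust) break
    ok <- TRUE
    if (nrow(centers)) {
      d <- t(centers) - cand[i, ]
      d <- d - L * round(d / L)
      ok <- min(colSums(d^2)) >= pitch^2
    }
    if (ok) centers <- rbind(centers, cand[i, ])
  }
  if (nrow(centers) < nclust)
    stop("geometric infeasibility: clusters of this size and gap do not",
         " fit in the box")
  pos <- with_seed(seed, {
    rows <- vector("list", length(cluster_sizes))
    for (ci in seq_along(cluster_sizes)) {
      k <- cluster_sizes[ci]
      sites <- lattice_ball(k, a, 0)  # around origin
      if (m == 1) {
        pts <- sweep(sites, 2, centers[ci, ], "+")
      } else {
        pts <- do.call(rbind, lapply(seq_len(k), function(j) {
          z <- (seq_len(m) - (m + 1) / 2) * spec$fene_r0
          cbind(sites[j, 1], sites[j, 2], sites[j, 3] + z)
        }))
        pts <- sweep(pts, 2, centers[ci, ], "+")
      }
      rows[[ci]] <- pts + matrix(runif(length(pts), -jitter, jitter),
                                 nrow(pts))
    }
    do.call(rbind, rows)
  })
  cfg <- configuration(pos, spec, validate = FALSE)
  attr(cfg, "cluster_sizes") <- sort(as.integer(cluster_sizes),
                                     decreasing = TRUE)
  cfg
}
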