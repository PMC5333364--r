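# Model definitions: Lennard-Jones particle gas and FENE bead-spring
# polymer solution in a periodic box at fixed density, reduced units
# (epsilon = k_B = m = 1).

#' Define a coarse-grained system at fixed density
#'
#' Builds the immutable model definition used by all sampling and analysis
#' functions.  Two model kinds are supported: a gas of Lennard-Jones
#' particles (`lj_gas`) with \eqn{\sigma = 2^{-1/6}} so that the pair
#' minimum sits at distance 1, and a dilute solution of linear bead-spring
#' polymers (`polymer_solution`) whose neighbouring monomers are bonded by
#' the FENE potential and whose non-bonded monomers interact via the same
#' truncated-and-shifted Lennard-Jones potential with
#' \eqn{\sigma = r_0\,2^{-1/6}}.
#'
#' The box length follows from the density: \eqn{L = (N M/\rho)^{1/3}} where
#' \eqn{N} counts constituents (particles or chains) and \eqn{M} monomers
#' per chain.  The Lennard-Jones potential is cut off at \eqn{r_c = 2.5\sigma}
#' and shifted by \eqn{-V_{LJ}(r_c)} so that it is continuous (and zero) at
#' the cutoff.  The number of momentum degrees of freedom is \eqn{f = 3NM};
#' for polymers the FENE bonds formally constrain these but the effect is
#' negligible in the temperature ranges of interest, so all \eqn{3 \times 13N}
#' momenta are counted.
#'
#' @param kind `"lj_gas"` or `"polymer_solution"`.
#' @param n_constituents number of particles, or number of chains.
#' @param density number density of particles/monomers per unit volume
#'   (default `1e-2`, the dilute regime where a single macroscopic droplet
#'   coexists with vapour at the transition).
#' @param monomers_per_chain monomers per chain; 1 for the gas, 13 for
#'   polymers.
#' @param lj_epsilon,lj_cutoff_factor well depth and cutoff in units of
#'   sigma (cutoff default `2.5`).
#' @param fene_K,fene_R,fene_r0 FENE bond parameters: stiffness, maximal
#'   extension around `fene_r0`, and equilibrium bond length.
#' @return An object of class `system_spec`.
#' @examples
#' spec <- system_spec("lj_gas", 64)
#' spec$box_length  # (64/0.01)^(1/3)
#' @export
system_spec <- function(kind = c("lj_gas", "polymer_solution"),
                        n_constituents,
                        density = 1e-2,
                        monomers_per_chain = NULL,
                        lj_epsilon = 1,
                        lj_cutoff_factor = 2.5,
                        fene_K = 40,
                        fene_R = 0.3,
                        fene_r0 = 0.7) {
  kind <- match.arg(kind)
  n <- as.integer(n_constituents)
  stopifnot(n >= 1, density > 0)
  if (is.null(monomers_per_chain))
    monomers_per_chain <- if (kind == "lj_gas") 1L else 13L
  m <- as.integer(monomers_per_chain)
  if (kind == "lj_gas" && m != 1L)
    stop("lj_gas has one monomer per constituent")
  nm <- n * m
  L <- (nm / density)^(1 / 3)
  sigma <- if (kind == "lj_gas") 2^(-1 / 6) else fene_r0 * 2^(-1 / 6)
  r_c <- lj_cutoff_factor * sigma
  if (r_c >= L / 2)
    stop("cutoff r_c = ", signif(r_c, 6), " must be < L/2 = ",
         signif(L / 2, 6), " for minimum-image validity")
  # shift = -V_LJ(r_c) of the untruncated potential
  sr6 <- (sigma / r_c)^6
  shift <- -4 * lj_epsilon * (sr6^2 - sr6)
  spec <- list(
    kind = kind,
    n_constituents = n,
    monomers_per_chain = m,
    density = density,
    box_length = L,
    lj_epsilon = lj_epsilon,
    lj_sigma = sigma,
    lj_cutoff = r_c,
    lj_shift = shift,
    fene_K = fene_K,
    fene_R = fene_R,
    fene_r0 = fene_r0,
    dof = 3L * nm
  )
  class(spec) <- "system_spec"
  spec
}

#' @export
print.system_spec <- function(x, ...) {
  cat("system_spec:", x$kind, "\n")
  cat(sprintf("  N = %d constituents x %d monomers, rho = %g, L = %.4f\n",
              x$n_constituents, x$monomers_per_chain, x$density,
              x$box_length))
  cat(sprintf("  LJ: sigma = %.6f, r_c = %.6f, shift = %.8f\n",
              x$lj_sigma, x$lj_cutoff, x$lj_shift))
  if (x$kind == "polymer_solution")
    cat(sprintf("  FENE: K = %g, R = %g, r0 = %g\n",
                x$fene_K, x$fene_R, x$fene_r0))
  cat(sprintf("  momentum degrees of freedom f = %d\n", x$dof))
  invisible(x)
}

spec_hash <- function(spec) {
  fnv1a(paste(unlist(spec), collapse = ","))
}

#' Truncated-and-shifted Lennard-Jones pair energy
#'
#' \eqn{V(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] - V_{LJ}(r_c)} for
#' \eqn{r \le r_c}, and 0 beyond the cutoff, so the potential is continuous
#' at \eqn{r_c}.
#'
#' @param r distance(s), must be positive.
#' @param sigma,epsilon LJ parameters.
#' @param r_c cutoff distance.
#' @param shifted apply the cutoff shift (default `TRUE`).
#' @return energy, vectorized over `r`.
#' @export
lj_pair_energy <- function(r, sigma = 2^(-1 / 6), epsilon = 1,
                           r_c = 2.5 * sigma, shifted = TRUE) {
  if (any(r <= 0)) stop("distance must be positive")
  sr6 <- (sigma / r)^6
  v <- 4 * epsilon * (sr6^2 - sr6)
  if (shifted) {
    sc6 <- (sigma / r_c)^6
    v <- v - 4 * epsilon * (sc6^2 - sc6)
  }
  v[r > r_c] <- 0
  v
}

#' FENE bond energy
#'
#' Finitely extensible nonlinear elastic bond,
#' \eqn{V(r) = -(K R^2/2)\,\ln[1 - (r - r_0)^2/R^2]}, defined only for
#' \eqn{|r - r_0| < R}; it vanishes at \eqn{r = r_0} and diverges at the
#' domain boundary, which bounds bond lengths to \eqn{[r_0 - R, r_0 + R]}.
#'
#' @param r bond length(s).
#' @param K,R,r0 FENE stiffness, extension range, equilibrium length.
#' @return energy, vectorized over `r`.
#' @export
fene_bond_energy <- function(r, K = 40, R = 0.3, r0 = 0.7) {
  if (any(abs(r - r0) >= R))
    stop("bond length outside FENE domain |r - r0| < R")
  -(K * R^2 / 2) * log(1 - (r - r0)^2 / R^2)
}

spec_as_list <- function(spec) unclass(spec)

#' Build a configuration object
#'
#' Wraps coordinates into the periodic box and caches the total potential
#' energy.  For polymers the FENE bond-length domain is validated.
#'
#' @param positions numeric matrix (`N*M` rows, 3 columns) of coordinates.
#' @param spec a [system_spec()].
#' @param validate check bond domains and recompute the energy.
#' @return Object of class `configuration` with elements `positions`,
#'   `chain_index` and `potential_energy`.
#' @export
configuration <- function(positions, spec, validate = TRUE) {
  positions <- as.matrix(positions)
  nm <- spec$n_constituents * spec$monomers_per_chain
  stopifnot(nrow(positions) == nm, ncol(positions) == 3)
  positions <- positions %% spec$box_length
  cfg <- list(
    positions = positions,
    chain_index = rep(seq_len(spec$n_constituents),
                      each = spec$monomers_per_chain),
    potential_energy = NA_real_
  )
  class(cfg) <- "configuration"
  if (validate && spec$kind == "polymer_solution") {
    bl <- bond_lengths(cfg, spec)
    if (any(abs(bl - spec$fene_r0) >= spec$fene_R))
      stop("configuration violates the FENE bond domain")
  }
  cfg$potential_energy <- cpp_total_energy(positions, spec_as_list(spec))
  cfg
}

# minimum-image bond lengths of all chain bonds
bond_lengths <- function(cfg, spec) {
  m <- spec$monomers_per_chain
  if (m < 2) return(numeric(0))
  L <- spec$box_length
  idx <- which(seq_len(nrow(cfg$positions)) %% m != 0)  # bond start indices
  d <- cfg$positions[idx + 1L, , drop = FALSE] -
    cfg$positions[idx, , drop = FALSE]
  d <- d - L * round(d / L)
  sqrt(rowSums(d^2))
}

#' Total potential energy of a configuration
#'
#' Sum of all minimum-image truncated-and-shifted LJ pair terms (bonded
#' monomer pairs excluded) plus all FENE bond terms.  Uses a cell list when
#' the box accommodates one (`L >= 3 r_c`), otherwise an `O(N^2)` loop; the
#' `method = "brute"` route forces the double loop and serves as an
#' independent check.
#'
#' @param cfg a [configuration()] or a bare coordinate matrix.
#' @param spec a [system_spec()].
#' @param method `"cell"` (automatic) or `"brute"`.
#' @return potential energy (scalar).
#' @export
total_potential_energy <- function(cfg, spec, method = c("cell", "brute")) {
  method <- match.arg(method)
  pos <- if (inherits(cfg, "configuration")) cfg$positions else as.matrix(cfg)
  cpp_total_energy(pos %% spec$box_length, spec_as_list(spec),
                   brute = (method == "brute"))
}

#' Energy change of a single-site move
#'
#' Incremental energy difference for displacing one particle/monomer,
#' identical (to tight tolerance) to recomputing the total energy before and
#' after but evaluated locally.  FENE-domain violations return `Inf`,
#' signalling that the proposal must be rejected.
#'
#' @param cfg a [configuration()].
#' @param index site index (1-based).
#' @param new_position length-3 numeric.
#' @param spec a [system_spec()].
#' @return energy difference (may be `Inf`).
#' @export
delta_energy <- function(cfg, index, new_position, spec) {
  stopifnot(length(new_position) == 3)
  cpp_move_delta(cfg$positions, spec_as_list(spec), as.integer(index),
                 as.numeric(new_position) %% spec$box_length)
}

#' Generate an initial configuration
#'
#' Random non-overlapping insertion (gas phase) or a compact cluster seed
#' (droplet phase), followed by a short canonical relaxation run.  Any
#' equilibrated start is acceptable because the multicanonical weights cover
#' the full energy window.
#'
#' @param spec a [system_spec()].
#' @param phase `"gas"` (homogeneous) or `"droplet"` (one compact cluster).
#' @param seed integer seed.
#' @param relax_sweeps canonical relaxation sweeps (0 to skip).
#' @param relax_beta inverse temperature of the relaxation run.
#' @return a [configuration()].
#' @export
initial_configuration <- function(spec, phase = c("gas", "droplet"),
                                  seed = 1,
                                  relax_sweeps = 200,
                                  relax_beta = if (phase == "gas") 1 else 2.5) {
  phase <- match.arg(phase)
  L <- spec$box_length
  m <- spec$monomers_per_chain
  n <- spec$n_constituents
  pos <- with_seed(seed, {
    if (spec$kind == "lj_gas") {
      if (phase == "gas") insert_random(n, L, 0.9 * spec$lj_sigma)
      else lattice_ball(n, 1.1, L) + matrix(runif(3 * n, -0.03, 0.03), n)
    } else {
      if (phase == "gas") polymer_random(n, m, L, spec)
      else polymer_rods(n, m, L, spec)
    }
  })
  cfg <- configuration(pos, spec)
  if (relax_sweeps > 0) {
    res <- cpp_run_muca(cfg$positions, spec_as_list(spec),
                        w_centers = c(0, 1), w_lnw = c(0, 0),
                        elo = -1e300, ehi = 1e300, beta = relax_beta,
                        n_sweeps = as.integer(relax_sweeps),
                        move_mix = default_move_mix(spec),
                        d_short = 0.5, r_cl = spec$lj_cutoff,
                        seed = as.integer(fold_seed(seed, 1)),
                        keep_series = FALSE, resync_every = 0L,
                        measure_nd = FALSE)
    cfg <- configuration(res$positions, spec, validate = FALSE)
  }
  cfg
}

insert_random <- function(n, L, dmin) {
  pos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    for (try in 1:2000) {
      p <- runif(3, 0, L)
      if (i == 1) break
      d <- t(pos[seq_len(i - 1), , drop = FALSE]) - p
      d <- d - L * round(d / L)
      if (min(colSums(d^2)) > dmin^2) break
    }
    pos[i, ] <- p
  }
  pos
}

# first n sites of a cubic lattice (spacing a) ordered by distance from the
# box centre: a compact near-spherical cluster
lattice_ball <- function(n, a, L) {
  k <- ceiling((3 * n / (4 * pi / 6))^(1 / 3)) + 2
  g <- expand.grid(x = -k:k, y = -k:k, z = -k:k)
  r2 <- g$x^2 + g$y^2 + g$z^2
  g <- g[order(r2), ][seq_len(n), ]
  as.matrix(g) * a + L / 2
}

polymer_random <- function(n, m, L, spec) {
  r0 <- spec$fene_r0
  dmin <- 0.85 * spec$lj_sigma
  pos <- matrix(NA_real_, n * m, 3)
  filled <- 0L
  for (c in seq_len(n)) {
    for (try in 1:200) {
      chain <- matrix(NA_real_, m, 3)
      chain[1, ] <- runif(3, 0, L)
      ok <- TRUE
      for (j in seq_len(m - 1)) {
        for (t2 in 1:50) {
          u <- rnorm(3)
          step <- r0 * u / sqrt(sum(u^2))
          p <- chain[j, ] + step
          good <- TRUE
          if (j > 1) {
            d <- t(chain[seq_len(j - 1), , drop = FALSE]) - p
            d <- d - L * round(d / L)
            good <- min(colSums(d^2)) > dmin^2
          }
          if (good && filled > 0) {
            d <- t(pos[seq_len(filled), , drop = FALSE]) - p
            d <- d - L * round(d / L)
            good <- min(colSums(d^2)) > dmin^2
          }
          if (good) break
        }
        if (!good) { ok <- FALSE; break }
        chain[j + 1, ] <- p
      }
      if (ok) break
    }
    pos[filled + seq_len(m), ] <- chain
    filled <- filled + m
  }
  pos
}

# straight rods side by side: a compact aggregate seed
polymer_rods <- function(n, m, L, spec) {
  r0 <- spec$fene_r0
  k <- ceiling(sqrt(n))
  a <- max(0.75, 1.05 * spec$lj_sigma)
  pos <- matrix(NA_real_, n * m, 3)
  for (c in seq_len(n)) {
    ix <- (c - 1) %% k
    iy <- (c - 1) %/% k
    x0 <- L / 2 + (ix - k / 2) * a
    y0 <- L / 2 + (iy - k / 2) * a
    z <- L / 2 + (seq_len(m) - (m + 1) / 2) * r0
    pos[(c - 1) * m + seq_len(m), ] <- cbind(x0, y0, z)
  }
  pos
}

#' Write a configuration as extended XYZ
#'
#' Plain-text XYZ with a comment line carrying the box length and the cached
#' potential energy, so snapshots can be re-read without the spec.
#'
#' @param cfg a [configuration()].
#' @param spec a [system_spec()].
#' @param file path.
#' @export
write_xyz <- function(cfg, spec, file) {
  n <- nrow(cfg$positions)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(as.character(n), con)
  writeLines(sprintf("L=%.17g E_p=%.17g kind=%s spec=%s",
                     spec$box_length, cfg$potential_energy, spec$kind,
                     spec_hash(spec)), con)
  el <- if (spec$kind == "lj_gas") "Ar" else "C"
  writeLines(sprintf("%s %.17g %.17g %.17g", el, cfg$positions[, 1],
                     cfg$positions[, 2], cfg$positions[, 3]), con)
}

#' Read an extended XYZ snapshot
#'
#' @param file path written by [write_xyz()].
#' @param spec the matching [system_spec()].
#' @return a [configuration()].
#' @export
read_xyz <- function(file, spec) {
  lines <- readLines(file)
  n <- as.integer(lines[1])
  toks <- strsplit(trimws(lines[2 + seq_len(n)]), "\\s+")
  pos <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  configuration(pos, spec, validate = FALSE)
}
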