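# Independent oracles used across tests: brute-force energy sums and a
# plain BFS connected-components routine, written without touching the
# package's computational path.

# O(N^2) potential energy in pure R: minimum-image shifted LJ over all
# non-bonded pairs plus FENE over chain bonds.
oracle_energy <- function(pos, spec) {
  L <- spec$box_length
  m <- spec$monomers_per_chain
  n <- nrow(pos)
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pos[i, ] - pos[j, ]
      d <- d - L * round(d / L)
      r <- sqrt(sum(d^2))
      bonded <- m > 1 && ((i - 1) %/% m == (j - 1) %/% m) && abs(i - j) == 1
      if (bonded) {
        e <- e + fene_bond_energy(r, spec$fene_K, spec$fene_R, spec$fene_r0)
      } else if (r <= spec$lj_cutoff) {
        e <- e + lj_pair_energy(r, spec$lj_sigma, spec$lj_epsilon,
                                spec$lj_cutoff)
      }
    }
  }
  e
}

# BFS connected components over constituents at cutoff r_cl
oracle_cluster_sizes <- function(pos, spec, r_cl) {
  L <- spec$box_length
  m <- spec$monomers_per_chain
  nc <- spec$n_constituents
  adj <- matrix(FALSE, nc, nc)
  n <- nrow(pos)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ci <- (i - 1) %/% m + 1
      cj <- (j - 1) %/% m + 1
      if (ci == cj) next
      d <- pos[i, ] - pos[j, ]
      d <- d - L * round(d / L)
      if (sum(d^2) <= r_cl^2) adj[ci, cj] <- adj[cj, ci] <- TRUE
    }
  }
  seen <- rep(FALSE, nc)
  sizes <- integer(0)
  for (s in seq_len(nc)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    k <- 0
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      k <- k + 1
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    sizes <- c(sizes, k)
  }
  sort(sizes, decreasing = TRUE)
}

# uniform random gas configuration (possibly overlapping; fine for energy
# comparisons)
random_positions <- function(n, L) {
  matrix(runif(3 * n, 0, L), n, 3)
}

# a fine double-Gaussian toy dos used by several analysis tests
dg_dos <- function(modes = c(-4, 4), sds = c(1, 1), weights = c(0.5, 0.5),
                   n = 1601, span = 8, dof = NA) {
  grid <- seq(min(modes) - span, max(modes) + span, length.out = n)
  make_toy_dos("double_gaussian",
               list(modes = modes, sds = sds, weights = weights),
               grid, dof = dof)
}
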