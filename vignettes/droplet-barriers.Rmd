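---
title: "Shape-free free-energy barriers of droplet and polymer cluster formation"
author: "mucadrop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-free free-energy barriers of droplet and polymer cluster formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A dilute particle gas (or polymer solution) held at fixed density undergoes a
first-order condensation-evaporation transition as the temperature is
lowered: a homogeneous, entropy-dominated gas gives way to a mixed phase in
which one macroscopic droplet (or polymer aggregate) coexists with the
remaining vapour.  The rate at which the droplet nucleates is controlled, in
classical nucleation theory, by a free-energy barrier $\beta\Delta F$, and
the standard routes to that barrier require knowing the droplet's shape and
surface -- quantities that are ambiguous for particles and essentially
undefined for macromolecular aggregates.

`mucadrop` implements a *shape-free* route: the barrier is read off the
canonical **energy** probability distribution, using the energy itself as
reaction coordinate.  No droplet surface is ever constructed; the droplet
size $N_D$ (largest geometric cluster) is measured only as a secondary
observable for the two-dimensional landscape $F(E_p, N_D)$.

## Models

Two coarse-grained systems are provided, both in a periodic cube at number
density $\rho = N M / L^3 = 10^{-2}$ and in reduced units
($\epsilon = k_B = m = 1$):

* **`lj_gas`** -- $N$ particles with the truncated-and-shifted 12-6
  Lennard-Jones potential, $\sigma = 2^{-1/6}$ (pair minimum at distance 1),
  cutoff $r_c = 2.5\sigma$, shifted by $-V_{LJ}(r_c)$ so the potential is
  continuous at the cutoff.
* **`polymer_solution`** -- $N$ linear bead-spring polymers of $M = 13$
  monomers.  Adjacent monomers are bonded by the FENE potential
  $V(r) = -(K R^2/2)\ln[1-(r-r_0)^2/R^2]$ with $K = 40$, $R = 0.3$,
  $r_0 = 0.7$, which confines bond lengths to $(r_0 - R,\, r_0 + R)$.
  Non-bonded monomer pairs interact with the same LJ potential rescaled to
  $\sigma = r_0\, 2^{-1/6}$.  Directly bonded pairs interact through FENE
  only; excluding the intra-bond LJ term is the conventional reading of
  "non-bonded monomers interact via Lennard-Jones" and is our fixed choice.
  The LJ cutoff stays at $2.5\sigma$ with the rescaled $\sigma$.

The momentum degrees of freedom number $f = 3NM$ in both cases.  For
polymers the FENE bonds formally constrain these, but at the temperatures of
interest the effect is negligible, so all $3 \times 13N$ momenta are
counted in the kinetic-energy convolution below.

## Sampling: multicanonical Monte Carlo

Near the transition the probability of intermediate energies is suppressed
by up to $e^{-40}$; plain canonical sampling never crosses.  The package
samples with an auxiliary weight $W(E_p)$ chosen so that the energy
histogram is flat over a window covering both phases:

1. **Window location** (`locate_energy_window`): two short canonical runs at
   bracketing temperatures -- a hot gas run and a cold droplet run (started
   from a compact cluster so no nucleation wait is incurred) -- give the
   energy anchors; the window spans them with a margin of a few standard
   deviations (default 4).
2. **Weight iteration** (`iterate_weights`): cycles of sampling and
   updating.  The update is the accumulated, error-weighted recursion on
   adjacent-bin log-weight differences
   ($\kappa_k = H_k H_{k+1}/(H_k+H_{k+1})$ as statistical weight), which
   retains the information of all previous iterations and is much more
   stable than dividing by the latest histogram.  Initial weights come from
   a piecewise-linear interpolation of $\beta(E)$ between the two window
   anchors, $\ln W = -\int\beta\,dE$, which typically lets the first
   iteration span the full window.  Iteration stops when
   $\min H / \langle H\rangle \ge 0.7$ with every bin visited (the weights
   only affect sampling *efficiency*; the estimator below is unbiased for
   any weights, so a run that stops at the iteration cap still yields
   correct, if noisier, results and is flagged, not discarded).
3. **Production** (`run_production`): fixed weights (detailed balance holds
   exactly), recording $(E_p, N_D)$ once per sweep, where one sweep is
   $NM$ elementary move attempts.  Independent walkers are merged by
   summing histograms -- the supported parallel mode.

Move set: short cubic displacements (amplitude tuned to 30-55% acceptance
during iteration only, capped at the pair-minimum distance 1.0 so the dense
droplet keeps relaxing, then frozen) and box-uniform teleports for
particles; single-monomer shifts, bond rotations (the shorter chain arm,
unwrapped bond-by-bond, rotated about a random axis through the pivot),
double bridging (tail swap between two chains, accepted only when both new
bonds lie inside the FENE domain) and rigid chain teleports for polymers.
Cluster analysis uses a union-find on the cell list; two particles are
adjacent within $r_{cl}$ (boundary inclusive), two chains are adjacent if
*any* inter-chain monomer pair is.  The default $r_{cl} = r_c$: the
interaction cutoff is the natural connectivity scale, and the cutoff is a
convention, so it remains a parameter.

The sampler uses its own xoshiro256++ generator seeded from a single
integer (walker id folded in), so every artifact is reproducible from the
recorded seed independently of R's RNG state.  Energies are tracked
incrementally and resynchronized against a full recomputation every 2000
sweeps; the maximal drift is recorded and is at the $10^{-13}$ level in
tests.

## From histograms to thermodynamics

The production histogram gives the conformational density of states up to a
constant, $\Omega(E_p) \propto H(E_p)/W(E_p)$ (`estimate_ln_omega`).  All
further arithmetic happens in the log domain with log-sum-exp reductions;
additive constants are fixed by normalization only.

**Kinetic-energy convolution** (`convolve_to_total`): integrating the
momenta out of the $NVE$ partition function leaves
$$\Gamma(E) \propto \int_{-\infty}^{E} dE_p\, \Omega(E_p)\,
  \frac{(E-E_p)^{f/2-1}}{\Gamma_{fn}(f/2)},$$
with $\Omega \equiv 0$ below the sampled support.  The
$(2\pi m/h^2)^{f/2}$ prefactor is set to 1: it cancels in every normalized
distribution.  Because $\Omega \ge 0$, $\ln\Gamma$ is non-decreasing, so
the total-energy microcanonical temperature can never be negative -- unlike
its conformational counterpart $\hat\beta(E_p) = d\ln\Omega/dE_p$.  The
integral is evaluated by bin-midpoint quadrature on the histogram grid
(consistent with the provenance of $\Omega$), extended upward by
$10\,f/(2\beta_{min})$ so the kinetic tail is covered at every temperature
of interest.  For smooth integrands this lattice sum is spectrally
accurate; the same midpoint convention makes the two routes to $P_\beta(E)$
(below) agree to machine precision.

**Microcanonical temperatures** (`micro_beta`): five-point central stencils
of $\ln\Omega$ or $\ln\Gamma$ (one-sided five-point stencils at the edges,
flagged as lower accuracy), plus, for the total ensemble, the independent
expectation estimator
$\beta(E) = (f/2-1)\langle (E-E_p)^{-1}\rangle_E$ under the microcanonical
density $\propto \Omega(E_p)(E-E_p)^{f/2-1}$, used as a cross-check.

**Canonical distributions** (`canonical_distribution`, `mb_convolve`):
$P_\beta(E) = \Gamma(E)e^{-\beta E}/Z_\beta$ and its conformational
analogue.  The two are related by convolution with the kinetic-energy
density of $f$ momenta -- a Gamma distribution with shape $f/2$ and rate
$\beta$ (the energy form of the Maxwell-Boltzmann distribution) -- and
`mb_convolve` provides that second route.  Exact identities used as tests:
$\langle E\rangle = \langle E_p\rangle + f/(2\beta)$,
$\mathrm{Var}(E) = \mathrm{Var}(E_p) + f/(2\beta^2)$,
$C_V^{tot} = C_V^{conf} + f/2$ (hence identical specific-heat peak
locations), and $Z_\beta = \beta^{-f/2}\hat Z_\beta$.

## Transition temperature and barrier

At the **equal-height** temperature $\beta_{eqh}$ the two peaks of
$P_\beta$ are equally high and
$\beta\Delta F = \ln P(E^\pm) - \ln P(E^0)$.  Equivalently, the
**equal-area** temperature $\beta_{eqa}$ balances the two lobes enclosed by
the back-bending microcanonical $\beta(E)$ and the horizontal line
$\beta = \beta_{eqa}$; the lobe area *is* the barrier.  The two
constructions are mathematically identical (the lobe-area difference
telescopes to the peak-height difference), and the package implements them
as separate routes whose agreement to $10^{-6}$ is part of the test suite.

Numerical choices: peaks and crossings are *located* on a Gaussian-smoothed
copy of the curve (width 2 bins, with a 0.1-ln-unit prominence filter
against histogram noise) but all *values* are read from the unsmoothed
curve; the equal-area route uses the half-grid discrete derivative
$(\ln\Omega_{k+1}-\ln\Omega_k)/\Delta E$, whose summed areas reproduce
differences of $\ln\Omega$ without quadrature error; root finding is
bisection on the signed imbalance with automatic bracket expansion and
tolerance $10^{-8}$ in $\beta$; when more than two prominent peaks survive
the filter the outermost pair is used with a warning; masked (zero-count)
interior bins are interpolated linearly in $\ln\Omega$, edge gaps truncate
the support; a distribution peaking at the grid edge signals a truncated
support and is an error in strict contexts.  Since the conformational and
total estimates derive from the same time series, their difference
$\Delta\beta_N = \hat\beta_{eqa} - \beta_{eqa}$ is jackknifed *as a
difference*, which removes most of the (strongly correlated) individual
errors.

Because the kinetic convolution is a physical smoothing, the total-energy
formulation has the smaller barrier; the shift between the two formulations
is roughly constant in $N$ and translates into a multiplicative factor on
nucleation rates, $R \propto e^{-\beta\Delta F}$ (`relative_rate`, kinetic
prefactor $\kappa \equiv 1$ and out of scope).

The 2D landscape $F(E_p, N_D) = -\ln\Omega(E_p, N_D) + const$
(`build_landscape`) is built from the 2D histogram divided by $W(E_p)$; the
minimal path $N_D^*(E_p)$ takes the per-column argmin, and columns with
more than one local minimum (violating the expected single-minimum
parabola-like profile) are counted and reported rather than repaired.

## Finite-size scaling

At fixed density the critical droplet holds $\propto N^{3/4}$ constituents,
its interface scales as the 2/3 power of its volume, so the barrier grows
as $\tau_{eff} N^{1/2}$ with an effective interfacial free energy
$\tau_{eff}$; capillary waves and translational invariance motivate a
logarithmic correction:
$$\beta\Delta F(N) = \tau_{eff}\,N^{1/2} + \alpha \ln N + c,$$
with a *restricted* variant ($\alpha \equiv 0$) to probe the significance
of the log term -- on data with a genuine log correction its $\tau_{eff}$
estimate drifts systematically with the fit cutoff $N_{min}$, which
`nmin_scan` exposes.  The transition temperature approaches its limit as
inverse powers of the critical droplet radius $R_D \propto N^{1/4}$:
$$\beta_N = \beta_0 + a N^{-1/4} + b N^{-1/2} + c N^{-3/4},$$
where the correction ladder in quarter powers is an empirical, physically
motivated choice (the leading term is fixed by $R_D$; sub-leading powers
are not derived, and the ladder is the simplest family consistent with the
leading behaviour -- flagged for sensitivity analysis via `nmin_scan`).
The ensemble difference is fitted to $\Delta\beta_N = k N^{-3/4}$ -- the
inverse transition-droplet volume -- optionally with a free exponent for
model comparison.  All models are linear in their parameters and solved by
weighted least squares on a QR factorization; parameter errors come from
the design covariance and the goodness of fit is
$Q = P(\chi^2_{dof} > \chi^2)$.  For polymers $N$ counts chains, not
monomers.

## Error analysis

All quoted errors are delete-one-block jackknife errors
(`jackknife`): contiguous blocks (default 20) absorb autocorrelation, and
the estimator closure re-runs the *entire* extraction (histogram
$\to \Omega \to \Gamma \to$ barrier) on each leave-one-block-out subsample.
Values are full-sample estimates;
$\sigma^2 = \frac{g-1}{g}\sum_i(\theta_i - \bar\theta)^2$.

## Synthetic fixtures and what tests show

`make_toy_dos` provides analytic densities of states (double/single
Gaussian, power law, cubic back-bending $\beta(E)$, discrete levels) whose
transition temperatures and barriers are known in closed form;
`make_scaling_series` generates seeded noisy data from the scaling laws for
fit-recovery tests; `make_cluster_fixture` builds configurations with
prescribed cluster decompositions.  The cubic back-bend is oriented so that
$\beta(E)$ *falls* through the outer crossings, as it must for a physical
transition (only then are the outer crossings canonical maxima).

These fixtures emulate the *analytic structure* of the problem -- double
peaks, back-bending, kinetic convolution, scaling laws plus Gaussian noise
-- but not the correlated, asymmetric noise of real multicanonical series,
nor critical slowing-down of the droplet interconversion.  Tests passing on
fixtures therefore validate the analysis machinery exactly; statements
about the physics rest on the simulated Lennard-Jones runs, which at
package-test scale use small systems.

## Problem sizes used in the shipped tests

The automated suite runs desk-scale simulations chosen to finish in
minutes on one core: the sampler-correctness oracle uses $N = 2$ particles
(where $\Omega(E_p)$ follows from a one-dimensional radial integral), the
equal-height/equal-area and convolution identities run on $N = 16$, and the
finite-size trend checks use $N \in \{24, 40, 64, 96\}$ with four
independent walkers of $800 N$ sweeps each.  These sizes are the package's chosen
compromise between statistical resolution of the trends (barrier growth,
barrier ordering between ensembles, the sign and decay of
$\Delta\beta_N$) and turnaround; they sit below the sizes where the
asymptotic scaling fits become precise, so the shipped acceptance checks
assert trends and identities, not literature values.  The same pipeline at
$N$ up to a few thousand reproduces the published regime but needs hours
to days of CPU.

## Known limitations

* Window placement relies on the bracketing temperatures enclosing the
  transition; a droplet pre-run below $\beta_t$ would evaporate and yield a
  window missing the droplet peak.  The defaults suit the LJ gas at
  $\rho = 10^{-2}$; other densities need adjusted brackets.
* Flat-histogram sampling flattens $E_p$ only; the orthogonal slow mode
  (droplet size at fixed energy) still limits mixing, which shows as
  residual histogram roughness at larger $N$.  Independent walkers and the
  jackknife make this visible in the quoted errors rather than hiding it.
* The weight iteration reports, but does not fail on, non-convergence at
  the iteration cap; downstream estimates remain unbiased.
* `find_equal_height` requires a genuine double peak; near-critical or
  single-phase inputs error with "not first-order-like".
* Polymer runs are supported end to end but are far more expensive per
  sweep; the shipped tests exercise the polymer machinery at unit-test
  scale (energies, moves, clustering), not full polymer scaling scans.
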