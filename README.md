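# mucadrop

Shape-free measurement of canonical free-energy barriers for droplet and
polymer-cluster formation at fixed density.

## The problem

When a dilute gas of particles — or a dilute solution of polymers — is
cooled at fixed number density, it crosses a first-order
condensation–evaporation transition: a homogeneous vapour gives way to a
mixed phase in which a single macroscopic droplet (or polymer aggregate)
coexists with the remaining gas. The nucleation rate is controlled by a
free-energy barrier, `R ∝ κ·exp(−βΔF)`, and the usual ways of measuring
`βΔF` require identifying the droplet's surface — ambiguous for particles,
hopeless for macromolecules.

`mucadrop` measures the barrier without any droplet-shape input, using the
energy itself as reaction coordinate:

1. **Multicanonical Monte Carlo** with iteratively adapted weights
   `W(E_p)` samples a flat histogram across the transition region, for a
   truncated-and-shifted Lennard-Jones gas (`σ = 2^{-1/6}`,
   `r_c = 2.5σ`) or a FENE bead-spring polymer solution (13 monomers per
   chain, `K = 40`, `R = 0.3`, `r_0 = 0.7`), both at density `ρ = 10⁻²`.
2. The conformational density of states follows as
   `Ω(E_p) ∝ H(E_p)/W(E_p)`, and an explicit kinetic-energy convolution
   `Γ(E) ∝ ∫dE_p Ω(E_p)(E−E_p)^{f/2−1}/Γfn(f/2)` converts it to the
   total-energy ensemble (`f = 3NM` momentum degrees of freedom).
3. The finite-size transition temperature and barrier follow from the
   canonical energy distribution `P_β(E) = Γ(E)e^{−βE}/Z_β`: at the
   **equal-height** temperature `β_eqh` its two peaks are equally high and
   `βΔF = ln P(E^±) − ln P(E^0)`; equivalently the **equal-area**
   construction balances the lobes between the back-bending microcanonical
   `β(E)` and a horizontal line. Both are implemented and must agree to
   `1e-6` (they are the same construction mathematically).
4. **Finite-size scaling**: `βΔF = τ_eff·N^{1/2} + α·ln N + c` (the
   effective interfacial free energy `τ_eff` is the leading coefficient),
   `β_N = β₀ + aN^{−1/4} + bN^{−1/2} + cN^{−3/4}`, and the ensemble
   difference `Δβ_N ∝ N^{−3/4}`. All errors are jackknife errors with the
   full extraction re-run per block.

The two energy formulations differ at finite size: the kinetic convolution
smooths the distribution, so the total-energy barrier is systematically
smaller, and the two equal-area temperatures differ by `O(N^{−3/4})`.

## Worked example

```r
library(mucadrop)

spec <- system_spec("lj_gas", 64)           # rho = 1e-2, L = 18.57
win  <- locate_energy_window(spec, beta_lo = 1.0, beta_hi = 2.23, seed = 7)
w    <- iterate_weights(spec, win$window, n_bins = 72,
                        sweeps_per_iter = 4000, max_iter = 25,
                        anchors = win$stats, cfg = win$cfg_gas, seed = 7)
run  <- run_production(list(w$config, win$cfg_gas), w, spec,
                       n_sweeps = 51200, walkers = 4, seed = 11)
an   <- analyze_run(run, w, spec, bracket = c(1.6, 2.9), n_blocks = 10)
an$conformational
#> transition_result (conformational_Ep, equal_height):
#>   beta_t  = 2.04666 +- 0.0061
#>   barrier = 6.73033 +- 0.68 k_B T
#>   E- = -157.065, E0 = -40.4318, E+ = -5.75703
an$total
#> transition_result (total_E, equal_height):
#>   beta_t  = 2.04212 +- 0.0066
#>   barrier = 6.0624 +- 0.59 k_B T
#>   E- = -100.325, E0 = 6.85197, E+ = 38.3745
```

Reading: at `N = 64` the droplet forms/dissolves at inverse temperature
`β ≈ 2.05`; crossing costs `≈ 6.7 k_BT` measured on the potential-energy
coordinate and `≈ 6.1 k_BT` on the total-energy coordinate (the kinetic
contribution smooths the distribution and lowers the barrier; the relative
formation rate `relative_rate(6.06) ≈ 2.3e-3`). The equal-area route
(`an$conformational$beta_eqa`) agrees with `beta_eqh` to the root-finding
tolerance. Collecting such results over several `N` into a
`scaling_series` and calling `fit_barrier_scaling` /
`fit_temperature_scaling` gives `τ_eff` and the infinite-size `β₀`.

A thin command-line front end over the same functions is installed at
`inst/cli/mucadrop.R` (verbs: `run`, `iterate-weights`, `produce`,
`analyze`, `fss`, `fixtures`).

## Package layout

| file | contents |
|---|---|
| `R/model_core.R` | system definitions, LJ/FENE energies, configurations, XYZ I/O |
| `R/muca_sampler.R` | energy windows, weight iteration, production runs |
| `R/cluster_analysis.R` | largest-cluster (droplet size) identification |
| `R/ensemble_transform.R` | `Ω(E_p)`, kinetic convolution to `Γ(E)`, `β(E)`, canonical distributions |
| `R/barrier_extraction.R` | equal-height/equal-area constructions, 2D landscape, `analyze_run` |
| `R/fss_fitting.R` | weighted least-squares scaling fits and `n_min` scans |
| `R/resampling_stats.R` | block jackknife |
| `R/fixtures.R` | analytic toy densities of states, synthetic scaling data, cluster fixtures |
| `R/io_cli.R` | text formats, run configuration, pipeline driver |
| `src/mucadrop.cpp` | cell lists, incremental energies, MC moves, sweep kernel |

The methods vignette (`vignettes/droplet-barriers.Rmd`) documents the
model, the estimators, every numerical choice and the package's
limitations.
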