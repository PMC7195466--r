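# ligload

Free-energy landscapes and kinetics of substrate-gated enzyme activation,
at desk scale.

## The problem

Certain plant hormone-inactivating dioxygenases are allosterically switched
on by their own substrate: at high hormone concentration, substrate
molecules bridge two enzyme subunits at an oligomer interface, the enzyme
multimerizes, and the multimer inactivates the hormone far faster than the
monomer — a post-translational feedback loop that holds hormone levels
steady.  Two computational analyses underpin that mechanism:

* **Loading energetics.** A 2D free-energy landscape $F(x, y)$ over the
  ligand's center-of-mass position, reconstructed by replica-exchange
  umbrella sampling (REUS) along a 48-point cyclic guiding path (points 0
  and 24 fixed at the interface and active-site poses, string restraint
  2.39 kcal/mol/Å², production restraint 0.48 kcal/mol/Å², 48 × 20 = 960
  production time-units) with the multistate Bennett acceptance ratio
  (MBAR).  The landscape holds two minima — active site at 0, interface at
  +2.5 kcal/mol — joined by two symmetric minimum free-energy paths over
  4.2 kcal/mol saddles, giving a loading barrier of
  $4.2 - 2.5 = 1.7$ kcal/mol from the interfacial pose, only a few times
  kT at 25 °C (0.6 kcal/mol).
* **Kinetics.** Michaelis–Menten parameters from Lineweaver–Burk fits,
  $1/v = (K_m/V_{max})(1/S) + 1/V_{max}$, comparing monomer against
  multimer: ~10-fold lower $K_m$ / >3-fold higher $V_{max}$ for the
  tetramerizing enzyme, 5-fold lower $K_m$ / 22-fold higher $V_{max}$ for
  the dimerizing one.

All-atom simulation of the real system is out of reach for a test suite,
so `ligload` implements the full machinery — analytic potentials with
calibrated minima and saddles, overdamped Langevin dynamics with
composable biases (harmonic umbrella windows, a moving flat-bottom exit
restraint $V_{bias} = k_{bias}(\min(r - r_0(t), 0))^2$), string-method
path optimization, Hamiltonian replica exchange, MBAR with a WHAM oracle,
gridded PMF analysis with minimum free-energy paths and an exact minimax
(widest-path) barrier oracle, Kabsch superposition with windowed RMSF/RMSD
gate analysis, and the kinetics fits — and validates it on seeded
synthetic systems built to carry the quantities above.  The methods
vignette (`vignettes/loading-free-energy.Rmd`) documents every model,
convention and numerical choice.

## Worked example

```r
library(ligload)

pot <- make_ga2ox_landscape()          # calibrated two-minimum loading surface
energy_at(pot, c(2, 0))                # 0        (active-site minimum)
energy_at(pot, c(-2, 0))               # 2.5      (interface minimum)

pmf <- potential_to_grid(pot, grid_spec(c(-2.8, 2.8), c(-2.8, 2.8), 60, 60))
(m <- find_minima(pmf))
#>   ix iy         x           y    value
#> 1 52 30  2.006667 -0.04666667 0.000000
#> 2  9 30 -2.006667 -0.04666667 2.499324

fe <- mfep_on_grid(pmf, m[2, ], m[1, ], branch = "upper")
barrier_from_path(fe, reference = "start")
#> <barrier_report> branch upper: peak 4.200 - baseline 2.499 = barrier 1.700 kcal/mol
minimax_barrier(pmf, m[1, ], m[2, ])   # 4.200357  (grid-exact oracle)

dao <- make_kinetics_fixture("dao_mimetic", seed = 1)
compare_oligomers(fit_lineweaver_burk(dao$monomer),
                  fit_lineweaver_burk(dao$dimer))
#> <oligomer_comparison> monomer vs dimer: Km 5.22-fold lower, Vmax 21.2-fold higher in the multimer
```

The two detected minima are the active-site (0) and interface
(≈2.5 kcal/mol) poses; the path's running maximum reaches the
4.2 kcal/mol saddle, so the barrier out of the interfacial pose is
1.70 kcal/mol, and the minimax value confirms the string peak.  The seeded
rate tables recover the dimer's ~5-fold Km advantage and ~22-fold Vmax
advantage from their noisy (2 % CV) measurements.

The full stochastic pipeline is one call:

```r
report <- run_loading_study(study_config(seed = 1))
print(report)
#> <study_report>
#>   accounting: 48 windows x 20 = 960 production time-units
#>   minima found: 2
#>   interface - active-site offset: 2.54 kcal/mol
#>   upper branch: peak 4.38, barrier 1.80 kcal/mol
#>   lower branch: peak 4.19, barrier 1.62 kcal/mol
#>   PMF 75%-vs-100% RMS: 0.131 kcal/mol; exchange acceptance 0.85
```

(≈5 minutes on one CPU; `run_exit_study()` is the analogous driver for the
biased-exit / gate-fluctuation analysis.)

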