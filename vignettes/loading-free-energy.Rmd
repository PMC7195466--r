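---
title: "Free-energy landscapes and kinetics of substrate-gated enzyme activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy landscapes and kinetics of substrate-gated enzyme activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligload)
```

## The scientific problem

Some plant hormone-inactivating dioxygenases are allosterically activated by
their own substrate: at high hormone concentration, substrate molecules
bridge two enzyme subunits at an oligomer interface, the enzymes multimerize,
and the multimer turns the hormone over far faster than the monomer.  Two
computational questions sit at the heart of that mechanism:

1. **Loading energetics.** Can a substrate bound at the oligomer interface
   reach the active site without external help?  This is answered by a
   two-dimensional free-energy landscape over the ligand's center-of-mass
   position, reconstructed from replica-exchange umbrella sampling (REUS)
   along a cyclic guiding path, with the barrier read off a minimum
   free-energy path (MFEP).  The canonical answer for the system this
   package models: the active site lies 2.5 kcal/mol below the interface,
   two symmetric routes connect them over 4.2 kcal/mol saddles, and the
   barrier measured from the interfacial pose is therefore
   4.2 − 2.5 = 1.7 kcal/mol — only a few times the 0.6 kcal/mol thermal
   fluctuation at 25 °C.
2. **Kinetic consequence.** How much faster is the multimer?  Michaelis-
   Menten fits (Lineweaver-Burk, cross-checked by nonlinear least squares)
   quantify the fold-changes: roughly 10-fold lower Km and more than
   3-fold higher Vmax for the tetramerizing enzyme, and 5-fold lower Km
   with 22-fold higher Vmax for the dimerizing one.

All-atom simulation of the real tetramer is far outside a desk-scale
budget, so `ligload` rebuilds the *machinery* — the samplers, estimators,
path methods and fits — and exercises it on analytic synthetic systems
constructed to carry those published quantities.  Passing tests therefore
demonstrate that the machinery recovers known answers under controlled
conditions; they say nothing further about the real protein.

## The synthetic loading landscape

The fixture surface is a circular valley of radius $R$ carrying two minima
and two saddles:

$$F(x,y) = A(\rho - R)^2 + \tfrac{\Delta}{2}(1-\cos\theta)
  + \tfrac{w}{2}(1-\cos 2\theta)
  + h\,[\,g(\theta - \tfrac{\pi}{2}) + g(\theta + \tfrac{\pi}{2})\,] + F_0,$$

with $(\rho, \theta)$ polar coordinates, $g$ a wrapped Gaussian of angular
width $\sigma$, and defaults $R = 2$, $A = 5$, $\Delta = 2.5$,
$\sigma = 0.35$, $w = 2$ (all energies kcal/mol, lengths nominally Å —
the surface itself is a unitless construction; the labels keep the printed
constants usable).  The active-site minimum sits at $\theta = 0$ and the
interface minimum at $\theta = \pi$.

Two numerical choices deserve comment:

* **The well-shaping term** $\tfrac{w}{2}(1-\cos 2\theta)$ is required for
  the interface pose to be a true minimum: the $\cos\theta$ tilt alone is
  concave at $\theta = \pi$, which would split the interface basin into two
  spurious side-minima.  The term vanishes exactly at both minima, so the
  calibrated depths are untouched; any $w > \Delta/4$ works and $w = 2$
  keeps each branch single-peaked.
* **Calibration.** The bump height $h$ is found by dense 1D scanning plus
  root-finding on the angular profile so that the branch maximum sits
  exactly at $H = 4.2$ above the global minimum; a final constant shift
  puts the active-site minimum at exactly 0.  With $\sigma = 0.35$ the bump
  leakage at the minima is below $10^{-3}$ kcal/mol (tested).  An
  infeasible request ($H \le \Delta$, or a bump-free profile already above
  $H$) is an error, never silently clipped.

The two branches are exactly degenerate by mirror symmetry — the modelled
system's two routes have *nearly* identical barriers, and exact symmetry
makes the two-branch checks deterministic.  An optional `bump_delta`
parameter re-introduces asymmetry.

## Sampling: overdamped Langevin, umbrella windows, replica exchange

Dynamics are overdamped Langevin (Euler-Maruyama), $x \leftarrow x -
(\nabla F + \nabla V_\mathrm{bias})\,dt/\gamma + \sqrt{2\,kT\,dt/\gamma}\,\xi$.
CV-space toy dynamics need no inertia, and the overdamped form has simple,
testable stationary properties (harmonic variance $kT/k$, Boltzmann
histograms).  kT defaults to 0.596 kcal/mol (300 K).

The umbrella protocol mirrors the modelled study: a 48-point cyclic guiding
path with points 0 (interface) and 24 (active site) fixed and windows 47/0
connected; a string phase restrained at 2.39 kcal/mol/Å²; a production REUS
phase at 0.48 kcal/mol/Å² with 20 time-units per window (48 × 20 = 960
total), preceded by 2 time-units of discarded equilibration per window.
The harmonic restraint convention is $V_w(x) = k\,|x - c_w|^2$ (no ½
factor), stated in every output header; the printed constants are carried
in kcal/mol/Å² with the exact conversion 1 kcal = 4.184 kJ, 1 nm = 10 Å.

Numerical sampler parameters are free choices of this package, set once:

* `dt = 5e-5`, `friction = 0.1`: the product of the stiffest curvature
  (~11 kcal/mol/Å²) with $dt/\gamma$ stays near 0.006, keeping the
  Euler-Maruyama variance bias below a percent, while the low friction
  maximises diffusive exploration per protocol time-unit.
* `exchange_interval = 12` steps (0.0006 time-units): replica-exchange
  swap attempts must be frequent enough that replicas circulate the full
  48-window ring many times within a 20-time-unit run — the windows that
  straddle the saddles have bimodal restrained distributions, so the
  free-energy stitching across each saddle relies on exchange transport.
  The ring round-trip time scales as $n^2 \times$ interval, and infrequent
  swapping was the dominant error source for the basin-to-basin
  free-energy difference in development-scale experiments.
* `stride = 200`: 2000 recorded samples per window (96,000 total), enough
  for a stable 60 × 60 PMF while keeping the MBAR solve around a minute.

## Free-energy estimation

`mbar_solve()` implements the multistate Bennett acceptance ratio on
reduced bias energies (the shared unbiased surface cancels), minimising the
convex MBAR objective by BFGS with an analytic gradient and polishing by
self-consistent iteration to a $10^{-8}$ residual; the gauge is $f_1 = 0$
and the unbiased weights are normalized to 1 (both asserted on every run).
`wham_solve()` is the independent binned-histogram oracle; the two agree to
better than 0.1 kcal/mol RMS on shared input (tested).  The 2D PMF is
$-kT\ln\sum_{n\in\text{cell}} w_n$ on a 60 × 60 grid over the sample
bounding box (+5 % padding; the grid is config-exposed and recorded in
outputs), min-shifted to 0, with unoccupied cells flagged `NA` and never
interpolated silently.  No autocorrelation subsampling is applied by
default — stride-thinning already spaces the records — keeping runs
deterministic for testing.

Convergence is monitored the way the modelled protocol did (landscape at
15 vs 20 ns): the PMF from the first 75 % of each window's samples must
agree with the full PMF to 0.2 kcal/mol RMS.

## Reading minima, paths and barriers

* **Minima** are connected equal-value plateaus of occupied cells strictly
  below their surroundings (plateau handling makes detection robust to the
  exact ties of symmetric grids), filtered by topographic prominence: a
  non-global minimum must be separated from any lower one by a key saddle
  at least `min_prominence` (default 0.5 kcal/mol, about three times the
  binning noise of the default budget) above its own value.  Cells with
  fewer than 5 samples cannot nucleate minima — barely-occupied fringe
  cells carry shot noise of order kT.
* **Basin values** are read as the minimum over the 3 × 3 neighborhood of
  the basin cell, which suppresses binning noise at basin bottoms; whether
  the original analysis read its depths at guiding points or grid minima is
  not stated in the source, and this package documents the grid-minima
  convention in its outputs.
* **MFEPs** come from a zero-temperature string on the bilinearly
  interpolated grid: a Bezier-arc initialisation into the requested branch
  half-plane (the half-plane is bounded by the axis through the two
  minima — the fixture's symmetry axis), normal-component steepest descent
  with arc-length reparameterization, pinned endpoints, step annealing
  (the bilinear gradient flips sign discontinuously across cell edges at
  the valley floor, leaving a residual oscillation proportional to the
  step), and a light smoothing term whose strength is annealed with the
  step so its contraction pressure cannot outlive the restoring forces.
* **Barriers** follow the source's definition: peak minus the interfacial
  baseline along the path.  For paths extracted from *sampled* PMFs the
  full-study pipeline reads the profile through a 9-point running mean
  before taking the maximum: the raw maximum of ~100 noisy values is
  biased upward by two to three tenths of a kcal/mol, while the smoothing
  costs only ~0.04 kcal/mol of true peak height at the default grid.  The
  raw maximum remains the default elsewhere, and the exact minimax
  (widest-path) search over the occupied grid — computed by union-find over
  value-sorted cells, ties broken lexicographically — provides the
  grid-exact oracle that every string peak is checked against.
* **Transition-state ensembles** are drawn by seeded weighted resampling
  with replacement (100 draws by default) from the samples of the
  highest-energy cell of each branch; the source text does not define the
  cell set beyond "highest energy states", so this package takes the
  single argmax cell per branch.

## The biased-exit study and gate analysis

`run_exit_study()` emulates the gate-region protocol: eight independent
90-time-unit Langevin runs from identical coordinates (different noise
streams) in a weak binding well, driven outward by the one-sided moving
flat-bottom restraint $V_\mathrm{bias} = k_\mathrm{bias}\,
(\min(r - r_0(t), 0))^2$, $r_0(t) = r_0(0) + c\,t$, with
$k_\mathrm{bias} = 10$ kJ/mol/Å² (2.39 kcal/mol/Å²; the source string
"10 kJ Å⁻²" omits the /mol and is preserved verbatim in the metadata) and
$c = 0.1$ Å per time-unit, so the wall moves 9 length units over a run.
RMSF is computed per 20-time-unit window — frames superposed onto the
window-mean structure (two fit/re-mean passes), unweighted, a final
partial window dropped rather than padded — and averaged over the eight
runs; gate RMSD uses fit-on-whole/report-on-gate superposition against the
initial frame.  The exact RMSF/RMSD conventions of the original
supplementary material are not available in the source text, so the
definitions above are declared as this package's own and recorded in
outputs.  The paired synthetic coordinate ensembles place isotropic
Gaussian jitter on a fixed reference structure, with the gate residues'
(96-106) amplitude doubled in the later half of the windows — a pure
statistical emulation of gate destabilisation during ligand exit, with no
mechanics connecting the pull to the coordinates.

## Kinetics

`fit_lineweaver_burk()` fits ordinary least squares to the double
reciprocal of the replicate means (mean-based fits match how the source
plots were produced; the choice is recorded in the fit tag), with
`fit_mm_nls()` as the direct nonlinear cross-check.  Fixtures use three
replicates (matching the reported n = 3), eight log-spaced concentrations
over 0.5-100 µM and 2 % multiplicative lognormal noise; truth parameters
(monomer Km = 10 µM, Vmax = 1 against dimer 2 µM / 22 or tetramer
1 µM / 3.5) live in metadata, never in filenames.  At these noise settings
the single-draw Vmax fold-change scatters about ±2 % around 22, so exact
integer rounding is a property of the estimator's central value over the
seeded fixture family rather than of each draw; the acceptance suite
asserts the median over a fixed seed ensemble.

The Hill dose-response ($K_{1/2} = 5\,\mu$M, $n_H = 1.5$, chosen so
activation starts below $10^{-6}$ M and saturates near $10^{-4}$ M) and
the first-order activation time course ($\tau = 6$ h, so most activation
develops after several hours) are invented utility models, labelled as
such in their documentation; the modelled experiments propose no
functional forms for those curves.

## Problem sizes and limitations

The default study — 48 windows × 20 time-units at `dt = 5e-5` (19.2
million walker-steps plus equilibration), MBAR over 96,000 samples, a
60 × 60 grid — completes in about five minutes on one CPU; the test suite uses reduced
configurations (8 windows, 2 time-units) for pipeline mechanics and the
full default configuration once for the end-to-end checks.

Known limitations: the stochastic pipeline's saddle heights carry
seed-to-seed scatter of roughly ±0.1-0.2 kcal/mol at the default budget
(the end-to-end checks allow ±0.3); the string method's guiding
path sits slightly inside curved valleys at finite restraint stiffness
(arc means and chords of a curved valley lie inward — visible in the
ring-valley oracle test, which uses a stiffer restraint); and the
synthetic fixtures carry none of the molecular detail — no solvent, no
protein degrees of freedom, no force field — that makes the real problem
hard.
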