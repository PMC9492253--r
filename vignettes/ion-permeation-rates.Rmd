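---
title: "From umbrella windows to relative conduction rates: the methods behind ionpmf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From umbrella windows to relative conduction rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionpmf)
```

## The problem

Ion permeation through a narrow channel pore is well described by the free
energy of the permeating ions as a function of their axial positions — a
potential of mean force (PMF) over one or two collective variables (CVs).
Enhanced-sampling simulations tile this CV space with harmonically
restrained umbrella windows; everything that happens *after* those
simulations is what this package implements:

1. **WHAM** combines the biased window histograms into one unbiased PMF.
2. **Minima detection** identifies the metastable ion configurations
   (states) of the landscape.
3. **NEB** relaxes minimum free-energy paths (MFEPs) between states; path
   snippets are joined, re-relaxed and ranked into candidate conduction
   routes.
4. **1D projection** turns the chosen route into a barrier profile F(λ)
   over the arc length λ.
5. **Kramers rate theory** converts the profile into hopping rates between
   adjacent states, chained through a linear ODE system with an absorbing
   final state; the inverse mean first-passage time is the total conduction
   rate, reported *relative* to a reference system so the unknown friction
   cancels.

A synthetic-landscape generator with exactly known minima, saddles and
barriers stands in for molecular-dynamics data, so every stage can be
validated against ground truth.

## The bias convention and WHAM

Each window applies $U_k(z) = \tfrac{1}{2} k \sum_d (z_d - z^0_{k,d})^2$
per CV (the standard pull-code convention; only the force constant
$k$ = 1000 kJ/mol/nm² and the 0.1 nm window grid are inputs). `wham()`
iterates the self-consistent equations

$$p_i = \frac{n_i}{\sum_k N_k e^{(f_k - U_k(x_i))/k_BT}}, \qquad
  e^{-f_k/k_BT} = \sum_i e^{-U_k(x_i)/k_BT} p_i$$

on a shared grid (100 bins per CV by default, half-open bins with the last
bin closed) until the largest change of any window offset $f_k$ falls below
the tolerance, 10⁻⁶ kJ/mol by default, measured in the same units. Because
the fixed-point iteration alone can need tens of thousands of sweeps, an
L-BFGS-B warm start on the equivalent convex maximum-likelihood objective
precedes it; the converged result is identical and the documented
convergence metric is still the fixed-point offset change. Unsampled bins
carry `NA`, never an interpolated value. Windows with identical centers are
treated as separate windows (pooled statistically, not concatenated), which
is the correct treatment when merging independent runs. Bin edges span the
union of the window centers rather than the data extent, so repeated runs
share a grid; the PMF is shifted so its sampled minimum is zero.

**Choices on degenerate input.** An empty window contributes nothing.
Non-overlapping window clusters yield a warning, because their relative
offsets are then arbitrary. Samples outside the bin range are dropped with
a message and the per-window counts adjusted, which keeps the estimator
consistent on the binned region.

## The synthetic landscape generator

`make_surface()` builds F(z) as a sum of Gaussian components, locates all
stationary points by multi-start BFGS plus Newton polishing on the analytic
gradient/Hessian, classifies them by Hessian eigenvalues (discarding
near-degenerate flat-region points below a curvature floor), and normalizes
the global minimum to zero. The five-state conduction preset digs a
corridor of overlapping Gaussians into a high baseline — a "tube" from the
outer vestibule state down to the inner cavity state — with wells at the
states and small on-axis bumps at the saddles, calibrated iteratively so
declared state and saddle energies are realized. The corridor walls make
detours around a saddle cost far more than crossing it, so every saddle is
well-defined.

Two feasibility constraints shaped the defaults, both consequences of the
stated umbrella protocol rather than of any test outcome:

* a window of stiffness $k$ can only hold samples on a saddle while the
  barrier back into the nearest well stays below roughly
  $k\,(\mathrm{gap}/2)^2/2$; with $k$ = 1000 kJ/mol/nm² and state gaps of
  0.4–0.7 nm this caps resolvable saddles at roughly 20–45 kJ/mol, so the
  preset places its largest (conduction-limiting, > 20 kJ/mol) barriers on
  the long gaps;
* well flanks steeper than about $k \times$ (half window spacing)
  ≈ 50 kJ/mol/nm would push a window's samples entirely off its center, so
  wells are kept at widths ≥ 0.15 nm.

The sampler is Metropolis–Hastings, not Langevin dynamics — only the
stationary distribution matters for WHAM and a Monte Carlo chain is exactly
seedable. Its proposal mixes a local Gaussian walk (standard deviation
$\sqrt{k_BT/k}$, the bias width) with a 10% fraction of independence draws
from the bias distribution, with the exact Hastings correction. The global
moves matter: windows whose biased density is split by a surface feature
(a tube wall) mix poorly under a pure local walk — the same
low-sampling-efficiency regions that force longer simulations in practice.
Burn-in defaults to 10% of the requested samples, mirroring the common
practice of discarding the first tenth of each window. One root seed gives
per-window seeds as `seed + window index`, so any window is independently
reproducible, and a fixed seed reproduces chains bit for bit.

**What the generator does not emulate.** Samples are equilibrium draws with
short Markov-chain autocorrelation; real MD windows carry slow orthogonal
degrees of freedom (water reorganization, filter breathing) whose
correlation times can exceed the window length, plus force-field bias.
Passing tests therefore validate the *analysis chain*, not the convergence
of any particular simulation data set.

## Interpolation, minima and basins

`interpolate_pmf()` uses tensor-product Catmull–Rom (cubic-convolution)
interpolation: it passes exactly through the grid values, reproduces
quadratics, and differentiates analytically. Queries whose 4 × 4 stencil
touches an unsampled bin raise a classed masked-region error — unsampled
means unknown. Optional Gaussian pre-smoothing (in bins) exists for
histogram-noisy PMFs; it is off by default and always recorded on the
object.

`find_minima()` takes strict 8-neighbour local minima of the grid
(plateaus and exact ties yield none — degenerate grids should fail loudly,
and histogram data never ties), refines them by bounded quasi-Newton
descent on the interpolant, merges minima closer than `min_separation`
(default 0.1 nm, one umbrella interval) keeping the lower, and discards
candidates whose connecting ridge to a lower minimum rises less than
`min_prominence` above them — on sampled PMFs, bin noise otherwise sprinkles
spurious shallow minima over every flat region. Detection and refinement may
run on a smoothed copy; *energies are always re-evaluated on the unsmoothed
interpolant*, because smoothing biases well depths by
$\tfrac{1}{2}(\sigma_s h)^2 \nabla^2 F$, which is of order 1 kJ/mol for
sharp wells. The default ceiling (global minimum + 50 kJ/mol) sits above
any barrier this analysis would trust.

`assign_basins()` approximates steepest-descent basin membership with a
coarse fixed-step descent (50 steps) followed by nearest-minimum
assignment; a sample just past a saddle is attributed to the basin it
descends into even when it is Euclidean-closer to the other minimum.

## NEB and path construction

`neb()` relaxes a band of images (32 per snippet by default) under
improved-tangent NEB forces with springs (500 kJ/mol/nm²) along the path.
The optimizer is projected steepest descent with a Barzilai–Borwein
spectral step: on a smooth analytic surface it converges in tens of
iterations, and on histogram-noisy interpolants — where the local stiffness
spans orders of magnitude and momentum methods eject images from the valley
corridor — the spectral step self-scales while per-image displacements stay
capped at half the median image spacing. Images whose next position would
touch an unsampled bin simply stay put for that iteration. A climbing image
on the highest interior node drives the top image onto the saddle; it
latches on once the plain band is relaxed or stagnant, and in any case for
the final quarter of the iteration budget. Convergence means the largest
perpendicular (and climbing) force is below `force_tolerance`.

The default tolerance, 0.5 kJ/mol/nm, is appropriate for analytic surfaces.
On a WHAM PMF the *statistical* gradient noise is
$\sim \sigma_F \sqrt{2} / h$ — tens of kJ/mol/nm at realistic bin counts —
so the pipeline default is 30 kJ/mol/nm together with light geometric
smoothing (1.5 bins). The band's geometry is insensitive to this because
barriers are *not* taken from the convergence criterion: the final path is
re-evaluated on the unsmoothed PMF (`path_energies()`) and the barrier is
the maximum along it.

If a straight seed crosses an unsampled region, the seed is rerouted by a
shortest energy-weighted path over stencil-clean grid cells; if no sampled
route exists, a masked-region error propagates and `build_path_graph()`
records the pair as excluded, as it does for unconverged snippets —
silent barrier underestimates are worse than missing edges.

`enumerate_paths()` joins snippets along every simple path between the
chosen start and end states, re-relaxes each joined band, and ranks by the
quantity that controls rates: the highest energy along the path, with the
path action (∑ segment length × mean energy) breaking ties. Ties are
defined as maximum-energy differences below 0.5 kJ/mol — differences below
the sampling uncertainty of the PMF are not meaningful, and without the
tolerance the primary criterion would be decided by noise between
physically equivalent routes.

## Projection, barriers and the periodic boundary

`project_1d()` measures λ as cumulative Euclidean arc length, re-interpolates
F(λ) with a cubic spline, locates extrema on it, filters adjacent extremum
pairs of amplitude below `min_prominence` (0.25 kJ/mol default; a few
kJ/mol on sampled data) and requires the survivors to alternate
valley/peak. Path endpoints are states by construction.

`barrier(profile, i, j)` is the maximum of F on the directed segment minus
F(state i). When the target state precedes the source, the profile is
continued cyclically *without an energy shift*: within one finite
simulation box the first and last states are distinct configurations of the
same system, so re-entering over the periodic boundary costs the full net
free-energy drop of the cycle plus the local hump before the first state.
This is the only reading under which the re-entry barrier equals the net
drop plus the entry hump, and it is what makes an overall-downhill
conduction cycle rate-limited by its re-entry step.

## Kramers chains, MFPT and relative rates

For each adjacent state pair the hopping rate is

$$r_{i,j} = \frac{\omega(\lambda_i)\,\omega(\lambda_\ddagger)}{2\pi\gamma}
           e^{-\Delta F^\ddagger_{i,j}/k_BT},$$

with $\omega = \sqrt{|d^2F/d\lambda^2|}$ from cubic least-squares fits in a
window of ± max(0.05 nm, 7 node spacings) around each extremum
(`fit_curvature()`; a quadratic fallback handles noisy one-sided windows at
profile endpoints, where a fitted cubic can lose its stationary point). The
curvature at the *intervening peak* is used for the second factor — the
standard overdamped Kramers form; the literal both-valleys convention is
available via `omega_convention = "valley"`. The friction γ is set to 1:
absolute rates are meaningless here, and γ cancels in the relative rates
that are reported.

`solve_chain()` integrates $\dot p = M p$ from $p_1 = 1$ with a
stiff-capable solver (`deSolve::lsoda`, analytic constant Jacobian) on a
log-spaced grid extended until the absorbing final state holds
$1 - 10^{-6}$ of the probability; probability conservation is monitored.
`total_rate()` computes the mean first-passage time as
$\int_0^\infty (1 - p_n)\,dt$ by composite Simpson quadrature in log time
plus an exponential tail correction, and inverts it. When the rate dynamic
range exceeds what 64-bit floating point can integrate (about 15 decades),
`solve_chain()` refuses with a classed overflow error and the documented
fallback applies: `rate_limiting_bound()` returns the single-step Kramers
rate of the highest forward barrier, computed in log space, and every
downstream ratio carries a "≤" flag (`compare_systems()` does this
automatically). That mirrors how a system with an enormous barrier is
honestly reported as an upper bound instead of a number.

`conductance_to_rate()` and `rate_to_barrier_tst()` connect to
experimental scales: a unitary conductance g at driving voltage V carries
gV/e ions per second, and the Eyring relation
$k = (k_BT/h)e^{-\Delta F^\ddagger/k_BT}$ maps a rate to an effective
single barrier. The driving voltage (100 mV) and the TST temperature
(298 K for literature-derived estimates, 310 K for the simulation
temperature) are interpretation choices, exposed as arguments.

## Problem sizes and what the tests show

The validation suite runs at desk scale: the 1D WHAM check uses 23 windows
× 5000 samples; the 2D five-state check uses the full 506-window grid at
2000 samples per window, where minima localize to ~0.01 nm and
adjacent-state barriers to well under 1.5 kJ/mol; the end-to-end
relative-rate check samples two 250-window systems at 8000 samples per
window, a depth chosen so the ~10–15% statistical error of the recovered
rate ratio sits comfortably inside the 25% recovery target; the NEB oracle
check compares against an exact minimax-path search on a 500 × 500 grid
(minimum-spanning-tree route, an NEB-free reference). Rate-chain accuracy
is checked against a first-passage linear solve and `Matrix::expm`. These
sizes keep the whole suite at a few minutes while leaving each statistical
check comfortably powered.

## Known limitations

* No autocorrelation weighting or MBAR-style estimators in WHAM; windows
  are assumed internally equilibrated.
* Basin assignment is approximate near ridges (coarse descent, not exact
  steepest-descent integration).
* No 2D saddle search: barriers come from the 1D projection of the MFEP,
  as in the analysis this package reproduces.
* Kramers rates are overdamped with a memoryless friction; no
  Grote–Hynes corrections, no voltage tilting of the PMF.
* The synthetic generator produces equilibrium samples; it cannot emulate
  slow orthogonal degrees of freedom of real MD data.
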