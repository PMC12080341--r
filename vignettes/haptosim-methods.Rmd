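---
title: "Modelling haptotactic drift of multivalently adhering vesicles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling haptotactic drift of multivalently adhering vesicles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haptosim)
```

## The system and the model

haptosim simulates a micron-scale vesicle adhering to a flat surface
through many weak, reversible DNA bridges, on a surface whose ligand
density increases linearly in one direction. Each bridge is a hybridized
pair of short single-stranded "sticky ends": one on a ligand construct
anchored to the substrate, one on a receptor construct that diffuses in
the vesicle membrane. Because bond formation is slightly more likely on
the denser side of the contact patch, the vesicle drifts up-gradient —
haptotaxis driven purely by adhesion statistics, with no motor or energy
input beyond thermal fluctuations.

The model coarse-grains drastically, and deliberately:

* The adhered vesicle is a **rigid 2D disk** of radius $R$ — the adhesion
  patch. Membrane shape fluctuations, elasticity and the third dimension
  enter only through area bookkeeping: the vesicle is treated as a
  hemisphere of area $3\pi R^2$ for receptor counting.
* **Receptors are not tracked individually when free.** Membrane-anchored
  DNA diffuses with coefficients of order µm²/s, orders of magnitude
  faster than the vesicle moves, so free receptors are taken as uniformly
  distributed in a shell of thickness $L$ (the construct length) around
  the hemisphere. A free receptor therefore contributes an effective
  molar concentration $c_\mathrm{eff}$ corresponding to the number
  density $1/(3\pi R^2 L)$.
* **Ligands are immobile points** drawn from an inhomogeneous Poisson
  process with intensity $\rho_L + \lambda\,(x - x_0)$, each able to
  carry at most one bridge.

### Rate constants

Bridges form and break with

$$k_\mathrm{on} = \alpha\, k_\mathrm{on}^\mathrm{sol}\, c_\mathrm{eff},
\qquad
k_\mathrm{off} = \alpha\, k_\mathrm{on}^\mathrm{sol}\, \rho_0\,
e^{\beta \Delta G_0},$$

where $k_\mathrm{on}^\mathrm{sol}$ is the hybridization rate of the free
oligonucleotides in solution, $\rho_0 = 1$ M the standard concentration,
$\Delta G_0$ the duplex hybridization free energy of the sticky ends and
$\alpha \le 1$ a dimensionless factor absorbing the slowdown caused by
tethering both strands to surfaces. Only the product $\alpha
k_\mathrm{on}^\mathrm{sol}$ matters for trends; all drift velocities are
proportional to it. $k_\mathrm{off}$ is independent of $R$ and $L$;
$k_\mathrm{on}$ falls as $1/R^2$. The ratio
$k_\mathrm{on}/k_\mathrm{off} = e^{-\beta\Delta G_0} c_\mathrm{eff}/\rho_0$
satisfies detailed balance by construction, and multiplying both rates by
a common factor is exactly a rescaling of time (the engine reproduces
this bitwise for power-of-two factors; for other factors IEEE rounding
enters in the last ulp).

$\Delta G_0$ comes from the unified nearest-neighbor model: stacked-pair
enthalpies and entropies plus terminal initiation terms, tabulated at
1 M Na⁺, with the entropic salt correction
$\Delta S[\mathrm{Na^+}] = \Delta S[1\,\mathrm{M}] + 0.368\,(N-1)\ln[\mathrm{Na^+}]$
evaluated at 100 mM NaCl (the annealing buffer of the experimental
system). Dangling ends and tethering contributions are excluded — their
kinetic effect is what $\alpha$ parameterizes. The three named presets
`l5`, `l6`, `l7` correspond to sticky ends of 5, 6 and 7 nt and carry
$k_\mathrm{off} = 1.10$, $0.174$ and $0.0084\ \mathrm{s^{-1}}$ at
$\alpha = 0.1$, $k_\mathrm{on}^\mathrm{sol} = 10^6\,\mathrm{M^{-1}s^{-1}}$,
$T = 293.15$ K. The packaged FASTA
(`inst/extdata/synthetic_sticky_ends.fasta`) holds **synthetic stand-in
sequences**, selected by exhaustive search so that their nearest-neighbor
free energies reproduce these preset rates as closely as the discrete
sequence space allows; they are not the experimental sequences. The 6-
and 7-mer stand-ins reproduce the printed rates to printed precision; the
closest 5-mer reaches $0.976\,\mathrm{s^{-1}}$ against the target
$1.10\,\mathrm{s^{-1}}$, a limitation of the 5-mer sequence space under
this thermodynamic treatment, which is why the engine is normally driven
by the presets rather than by sequences.

### The reaction–diffusion alternation

Simulation proceeds in windows of duration $\Delta t$ with the disk
frozen:

1. **Reaction step.** A Gillespie chain over two channels: total
   formation propensity $k_\mathrm{on} \cdot (\text{free receptors})
   \cdot (\text{free eligible ligands})$ and total breakage propensity
   $k_\mathrm{off} \cdot n_b$. Eligible ligands are those free *at window
   start* and inside the disk; the binding partner and the breaking
   bridge are chosen uniformly. The first event whose cumulative waiting
   time exceeds $\Delta t$ is discarded (time truncates at the window
   edge).
2. **Move step.** The new centre is drawn uniformly from the **feasible
   region** — the intersection of circles of radius $R$ centred on every
   bridged ligand, i.e. all centre positions keeping every anchor inside
   the disk. Only the few bridges whose circles contribute arcs to this
   region's boundary (the *constraining bridges*, $n_{cb}$) limit the
   motion; the rest ride along.

If all bridges are lost the default policy terminates the trajectory and
records the detachment time, mirroring the washing away of non-adhering
vesicles; a `continue` policy that leaves the centre in place and allows
rebinding is available. A disk reaching the declared field margin
truncates the trajectory with a flagged status rather than silently
biasing statistics near an edge.

### Choosing $\Delta t$

$\Delta t$ is a numerical discretization parameter, not physics, but it
has one sharp failure mode. The carpet is *saturated*: at the reference
densities ($\rho_L = 0.021\,\mathrm{nm^{-2}}$ on the surface,
$\rho_R = 0.008\,\mathrm{nm^{-2}}$ over the hemisphere, i.e.
$3\rho_R = 0.024\,\mathrm{nm^{-2}}$ concentrated over the patch) the
mass-action balance leaves only $\sim 1$–$7$ free ligands under a
$0.2$ µm disk. Because eligibility is frozen at window start, a window
whose expected number of binding events approaches that free pool starves
binding, depresses $n_b$ by a few bridges, and thereby *multiplies* the
free-ligand density — which inflates mobility and drift, most strongly
for the strongly bound presets. The default therefore caps both event
count and pool usage:

$$\Delta t = \frac{\min(10,\ 0.2\,L_\mathrm{free})}{k_\mathrm{off}\,
\max(n_b, 1)},$$

with $n_b$ and $L_\mathrm{free}$ the mean-field bridge and free-ligand
numbers at the origin density. In a convergence scan with successively
smaller windows, the 10-events-only rule (no pool cap) inflated the
weak-binding preset's drift by about a factor of two, while windows at
or below the capped default agree with the small-window limit within
statistical error. The residual bias of the default (expected binding
events ≈ 20 % of the free pool) is below the statistical resolution of
any ensemble used here.

### Exact geometry of the feasible region

The region is computed exactly, not polygonally approximated. Candidate
boundary circles are taken in decreasing order of anchor distance to the
current centre; a circle is discarded only when its disk provably
contains the disk of radius $r_\mathrm{reg}$ (the largest vertex–centre
distance) around the current centre, and hence the whole region. Region
vertices are pairwise circle intersections lying inside all candidate
disks; for a convex intersection of congruent disks the farthest boundary
point from an interior point is always a vertex, which makes
$r_\mathrm{reg}$ exact and gives a certified bounding square for
rejection sampling. Sampling is the closed form for one bridge (uniform
in the disk) and exact rejection from the bounding square otherwise; a
sampler that exceeds $10^6$ proposals aborts loudly, since that indicates
a geometry bug rather than a physical state. $n_{cb}$ is the number of
circles owning at least one region vertex (one bridge: $n_{cb} = 1$).
Long equilibrium runs at the reference densities give a time-averaged
$\langle n_{cb}\rangle$ between four and five (4.4 in the packaged
reproduction run), consistent with the canonical value of about five
constraining contacts.

Every 256 windows the engine audits that all anchors remain within
$R(1+10^{-9})$ of the centre, and every window cross-checks the bridge
bookkeeping against the spatial grid pass; both failures are hard errors.

### Random numbers and reproducibility

Each replicate runs on its own xoshiro256++ stream seeded through
splitmix64 from (base seed, replicate index); the generator name is
recorded in trajectory metadata. Ligand fields are drawn with R's own RNG
under a locally-set seed (the caller's RNG state is untouched). Same
seeds, same outputs, bitwise.

## What the synthetic data generator does and does not emulate

The ligand-field generator is exact Poisson thinning, so the *statistical*
structure of the carpet — mean density, gradient slope, independent
counts in disjoint regions — matches the model by construction. Two
consequences of the point-process picture matter when interpreting
results:

* **Quenched disorder is strong.** Over the hundreds of seconds a
  trajectory explores only tens of nanometres, so each vesicle feels a
  single frozen realization of the local ligand pattern. The bias from
  one realization can exceed the gradient signal at these scales. All
  ensemble statistics therefore draw an *independent field per
  replicate*; a shared carpet would give every replicate the same
  spurious drift. (This also bounds what a passing zero-gradient null
  shows about real data: it is a statement about averages over carpets,
  not about any single vesicle.)
* What is *not* emulated: the sigmoidal density profile of real
  ligand-printed surfaces away from their linear central region,
  localization noise of microscopy tracking, vesicle size dispersion
  within a condition, stage drift, and the immobile subpopulation seen in
  experiments (surface defects, nonspecific sticking). The analysis
  module's mobility filter exists for imported experimental tables; on
  simulated ensembles its default excludes nothing.

## Scale of the shipped study conditions

Simulated conditions follow the reference setup: disks of $2R$ = 0.2 µm
(with 1 and 1.8 µm in the size sweep of the original; here the size trend
is demonstrated at $2R$ = 0.1–0.4 µm), $\rho_L = 0.021\,\mathrm{nm^{-2}}$
at the start position, $\rho_R = 0.008\,\mathrm{nm^{-2}}$, gradient slope
$\lambda = \rho_L/10\ \mathrm{\mu m^{-1}}$ scaled up tenfold
($2.1\times10^{-5}\,\mathrm{nm^{-3}}$) in drift ensembles so the directed
component is resolvable against the stochastic one at affordable ensemble
sizes. The packaged ensembles use 200 replicates per kinetic preset with
800 s (l5) and 1600 s (l6) of simulated time in the test suite, and
1000/2000 s in the reproduction script — the weaker-drift preset
integrates longer so both slopes are individually significant; both
presets share replicate seeds and field realizations. These sizes
resolve each preset's drift at roughly four to six standard errors,
which leaves the l5/l6 velocity *ratio* with a statistical spread of
about 30 %: the bootstrap confidence interval, not the point value, is
the meaningful summary at this scale.

## Trajectory statistics

Displacements are projected onto the gradient direction (an isometry,
tested as such). The ensemble mean-displacement curve interpolates every
trajectory onto the sampling grid of the shortest one and carries the
across-vesicle SEM; the drift velocity is the free-intercept OLS slope of
that curve, which on a shared grid equals the mean of per-vesicle slopes
— the bootstrap for the l5/l6 ratio resamples those per-vesicle slopes.
Per-vesicle average velocities are end-to-end displacement over duration,
computed on uncropped trajectories and kept distinct from the fitted
slope. Diffusion coefficients come from the time-averaged MSD over the
first decade of lags ($D$ = slope/4), with a log–log exponent reported so
ballistic trajectories are flagged rather than averaged in. The
directional-bias test reported by `summarizeEnsemble` is a two-sided
one-sample t test of per-vesicle parallel velocities against zero, named
as such in its output because it is this package's choice of test.

One property of the experimental data is *not* asserted by the test
suite: the positive skew of per-vesicle velocity distributions. At the
scaled-down conditions used here the per-vesicle velocity is dominated by
symmetric diffusive and quenched-disorder noise, and the sample skew of a
200-replicate ensemble does not reliably resolve the small asymmetry.

## Closed-form theory

The theory module provides the two time scales
$\tau_r = 1/(2 k_\mathrm{off} n_{cb})$ (bond rearrangement) and
$\tau_d = \pi R^2 n_{cb}/(D_\mathrm{free} n_b^2)$ (exploration of the
feasible region), with Stokes–Einstein $D_\mathrm{free}$; for
experimentally sized vesicles on saturated carpets $\tau_r/\tau_d \ge
10^7$, hence reaction-limited dynamics and $v_\mathrm{drift} \propto
k_\mathrm{off}$ at fixed geometry. Mean-field saturation solves
$\rho_b = K'(\rho_L-\rho_b)(\rho_R^\mathrm{eff}-\rho_b)$ with
$K' = k_\mathrm{on}\pi R^2/k_\mathrm{off}$ and
$\rho_R^\mathrm{eff} = 3\rho_R$; at the reference densities the carpet is
ligand-limited with $\rho_b \approx 0.020\,\mathrm{nm^{-2}}$ — an
interbridge spacing of order 10 nm.

The linear-response drift estimate combines the multivalent free energy
per patch, $\beta f = \rho_L\log(1-\rho_b/\rho_L) +
\rho_R\log(1-\rho_b/\rho_R) + \rho_b$ (standard mean-field mobile-linker
form), with an adhering-disk mobility. The exact prefactor of the
published disk diffusion coefficient is not recoverable from the
available material, so the package uses the form implied by the two time
scales, $D_\mathrm{multi} = \pi R^2 n_{cb}^2 k_\mathrm{off}/(2 n_b^2)$
(feasible-region area explored once per $\tau_r$), isolated in a single
function. The resulting $v^\mathrm{FD} = -D_\mathrm{multi}\,\beta\,
\partial_x V_\mathrm{multi}$ inherits the structural properties that
matter: it vanishes without a gradient, is odd under gradient reversal,
scales with $k_\mathrm{off}$, and is independent of $R$ when $n_b$ grows
as $R^2$ — which is precisely why the observed size dependence of drift
marks the breakdown of linear response, and why every drift number from
this module carries an *overestimate* annotation.

## Numerical choices and degenerate inputs

* Closed-disk convention: a ligand exactly at distance $R$ is under the
  disk; geometry tolerances are $10^{-9}R$.
* The field generator refuses extents where the linear intensity goes
  negative, naming the offending corner; disk queries refuse overhanging
  disks, reporting the overhang distance.
* `dt = 0` reaction windows are exact no-ops; zero total propensity
  leaves the window idle.
* Empty feasible regions cannot occur (the current centre is always a
  member); the code asserts rather than handles.
* Mass-action roots use the numerically stable quadratic form
  $2K'\rho_L\rho_R / (b + \sqrt{b^2 - 4K'^2\rho_L\rho_R})$.
* No pre-equilibration: trajectories start with an empty bridge set
  (binding saturates within the first window at reference densities);
  analyses discard an initial transient instead. An initial bridge set
  can be supplied explicitly.

## Known limitations

* The disk is rigid and its height fixed: no membrane fluctuations, no
  tank-treading/sliding distinction, no hydrodynamics.
* Receptor transport is assumed infinitely fast (uniform shell); at
  vesicle speeds far above those simulated this would break down.
* The linear-response drift prediction is an upper bound, not an
  estimate, on saturated carpets.
* Sequence thermodynamics are duplex-only: no dangling ends, no
  intramolecular structure, no sequence-dependent $\alpha$ or
  $k_\mathrm{on}^\mathrm{sol}$.
* At the packaged scaled-down conditions the l5/l6 drift-velocity ratio
  carries ~25 % statistical uncertainty; resolving it to a few percent
  would need order 100× more computation.
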