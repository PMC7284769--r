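---
title: "Coarse-grained chains in nanopost arrays: model, sampling and observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained chains in nanopost arrays: model, sampling and observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanopost)
```

## The physical problem

A long semiflexible polymer -- the motivating case is double-stranded DNA in
a nanofluidic device -- threaded into a square-lattice array of parallel
nanoposts distributes itself between two kinds of confining space: the
*interstitial volumes* bounded by four posts, and the narrow *passage
apertures* between two adjacent post walls. How much chain sits where, how
far the chain stretches along the post axes, and what internal statistics
the confined fragments adopt are the quantities this package computes, both
by direct simulation of a bead-spring chain and from confinement
free-energy theory.

All quantities are in reduced (Lennard-Jones) units: the bead diameter
$\sigma$ is the length unit, the repulsion strength $\epsilon$ the energy
unit, $k_BT = \epsilon$, and time is
$\tau = \sigma\sqrt{m/\epsilon}$ with unit bead mass.

## Force field

The chain is a touching-bead, discretised worm-like chain:

* **Excluded volume.** Every bead pair, bonded neighbours included,
  repels through the purely repulsive WCA potential
  $U_{\mathrm{WCA}}(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] +
  \epsilon$ for $r < 2^{1/6}\sigma$, zero beyond.
* **Bonds.** Consecutive beads are tied by FENE springs,
  $U_{\mathrm{FENE}}(l) = -\tfrac{\kappa}{2}R_o^2\ln[1 - (l/R_o)^2]$ with
  $\kappa = 30\,\epsilon/\sigma^2$ and $R_o = 1.5\,\sigma$. Together with
  the WCA term this gives an equilibrium bond length
  $\langle l\rangle \simeq 0.97\,\sigma$ and an effective bead width
  $w \simeq 0.9\,\sigma$; both are treated as fixed model constants, not
  refitted quantities.
* **Bending.** Each interior bead carries
  $U_b(\theta) = b\,k_BT\,(1 + \cos\theta)$, with $\theta$ the valence
  angle, so a straight chain costs nothing and a full fold-back costs
  $2b\,k_BT$. The dimensionless stiffness $b$ is 0 for the flexible chain
  and 20 for the DNA-like semiflexible chain; $b = 20$ maps a persistence
  length of about 20 bond lengths ($P \approx b\langle l\rangle \simeq
  19.4\,\sigma$; the exact discrete-chain value is
  $P = -\langle l\rangle/\ln(\coth b - 1/b) \simeq 18.9\,\sigma$).
* **Posts.** Infinitely long cylinders along $x$ on a square lattice of
  spacing $S_p$ in the $(y,z)$ plane; a bead at axis distance $r$ from a
  post of geometric diameter $D_p$ feels the WCA repulsion evaluated at
  the shifted distance $r - D_p/2$. The lattice is treated as infinite:
  posts are looked up around each bead, so no periodic box exists and the
  chain can wander freely.

`chain_energy()` and `chain_forces()` evaluate these terms analytically;
both are validated in the test suite against a brute-force double-loop
oracle ($10^{-12}$ relative) and centred finite differences ($10^{-6}$
relative).

## Array geometry

`post_array(S_p, D_p, w)` derives the confinement descriptors: effective
post diameter $d_p = D_p + w$, passage width $w_p = S_p - d_p$ (quasi-slit
height), quasi-channel diameter $d_c = \sqrt{2}\,S_p - d_p$, the ratio
$d_c/w_p$, and the post volume fraction $F = \pi d_p^2/(4S_p^2)$. The
$\sqrt 2$ in $d_c$ reflects the diagonal of the lattice cell; the package
validates all derived values against the reference three-series geometry
tables to their printed precision.

Two derived energetics matter for partitioning: `passage_barrier()` -- the
potential energy of a bead at the midpoint of an aperture, which reaches
$\sim 1.15\times10^5\,k_BT$ at $S_p = 3.9$ (impassable) and drops to
$\sim 15\,k_BT$ at $S_p = 4.8$ -- and `min_translocation_separation()`
$= D_p + 2w$, the separation at which the aperture width equals the bead
width.

## Sampling

Two independent routes generate equilibrium conformations; their agreement
is itself a test.

**Dynamics** (`run_dynamics()`): velocity-Verlet integration (position
updates identical to leap-frog) at $\mathrm{d}t = 0.005\,\tau$ with either
a single-variable Nose-Hoover coupling (relaxation $0.1\,\tau$, the
default) or a Langevin BAOAB step with the same stationary distribution.
Velocities start Maxwell-Boltzmann with zero total momentum; runs are
bit-reproducible given a seed; a bond reaching $R_o$ or a bead penetrating
a post core aborts with a diagnostic carrying the failing step. A straight
perpendicular start close to posts is first relaxed by a capped-force
("soft push-off") descent. For sampling-oriented runs we set the Langevin
friction to $1/\tau$ rather than $10/\tau$: the heavier friction slows
diffusive relaxation tenfold without changing the sampled ensemble.

**Monte Carlo** (`pivot_sample()`, free chains): Metropolis sampling of
the same Hamiltonian with a mixture of single-bead displacements (relaxes
bond lengths), crankshaft rotations, and pivot moves (decorrelates global
shape). For stiff chains the rotation amplitude is reduced to
$\approx 2.5/\sqrt b$ so the bending penalty at the pivot joint does not
suppress acceptance; amplitudes tune mixing speed only. The sampler
reproduces $\langle l\rangle = 0.971\,\sigma$ for both stiffness values,
the SAW ratio $\langle R_e^2\rangle/\langle R_g^2\rangle \simeq 6.5$, and
agrees with the Langevin dynamics to within 1% on $R_g$ at $N = 60$ for
both $b$ -- the cross-validation the test suite enforces.

## Observables

* `axial_span()`: $R_s = \langle \max(x) - \min(x)\rangle$.
* `occupation_number()`: distinct interstitial cells holding at least one
  bead centre. Cells are half-open lattice tiles; a bead exactly on a
  lattice line belongs to the higher-index cell (a measure-zero
  convention), and a bead inside an aperture is assigned by the same
  tiling -- the simplest consistent rule, since no threshold is physically
  distinguished.
* `gyration()`: $R_g = \sqrt{\langle R_g^2\rangle}$ with axial and lateral
  components that add in quadrature exactly.
* `bond_correlation()`: $\langle\cos\theta_{ij}\rangle$ versus contour
  separation with the persistence length fitted on the initial exponential
  decay. The fit window keeps separations with correlation at least
  $e^{-2}$ (capped at $3b$ bonds), regresses $\ln\langle\cos\rangle$
  through the origin -- the model fixes the intercept at 1 -- and refits
  once with the window capped at $2P/\langle l\rangle$. With-intercept
  fitting shifts $P$ by under $2\%$ on calibration runs, so the choice is
  not load-bearing.
* `structure_factor()`: $S(q) = N^{-2}\langle\sum_{ij}
  \mathrm{sinc}(q\,r_{ij})\rangle$, computed in compiled code and checked
  against a naive double loop; the default grid is 200 log-spaced points
  from $2\pi/(2L)$ to $2\pi/\sigma$.
* `hump_detect()`: the inter-strand correlation hump near $q = 2\pi/S_p$
  is found as the largest interior local maximum of the compensated curve
  $S(q)\,q$ inside a window (default $[0.4, 1.4]\,\sigma^{-1}$, bracketing
  post separations of roughly 4.5--16 $\sigma$); a candidate must exceed
  the compensated values at the window edges by a relative margin of
  $10^{-3}$, which rejects numerically flat backgrounds.

Standard errors come from block averaging with the block length set to
five integrated autocorrelation times.

## Confinement theory

The theory module implements the quasi-channel/quasi-slit free-energy
calculus. For a chain of contour $L$, persistence length $P$ and width $w$
at confinement size $D$: the de Gennes channel free energy
$4.0\,L(Pw)^{1/3}D^{-5/3}$, the Odijk channel free energy
$2.2072\,L P^{-1/3}D^{-2/3}$, and the half-channel slit rule. Equating the
free energy *per unit contour length* of fragments in quasi-channels
($D = d_c$) and quasi-slits ($D = w_p$) yields the partition ratios
$L_{qc}/L_{qs}$: $\tfrac12 (d_c/w_p)^{5/3}$ (both de Gennes),
$0.2759\,(w_p/P)^{2/3}(w_p/w)^{1/3}(d_c/w_p)^{5/3}$ (de Gennes channel,
Odijk slit; the only combination that feels the chain parameters), and
$\tfrac12 (d_c/w_p)^{2/3}$ (both Odijk). The tests re-derive these
numerically from the free-energy functions rather than trusting the closed
forms. The numeric prefactors are order-of-magnitude constants for true
channels and slits; applied to interstitial volumes and apertures they are
semiquantitative by construction.

Regime boundaries (`classify_regime()`): Odijk for $D < P$, extended
de Gennes for $P < D < P^2/w$, classic de Gennes beyond; boundary values
resolve to the stronger-confinement label (an arbitrary but documented
tie-break). Extension laws: $R = L[1 - A(D/P)^{2/3}]$ with $A = 0.18274$
(square) or $0.1701$ (circular) in the Odijk regime, and
$R = L(wP/D^2)^{1/3}$ in the de Gennes regimes. `slope_windows()`
assembles the predicted $S(q)$ slope intervals ($-1$, $-5/3$, $-2$,
saturation) for a given geometry, and `regime_report()` tabulates regimes
and partition ratios for a geometry series. For a semiflexible chain whose
aperture is in the Odijk regime the report keeps both the mixed and the
pure-Odijk entries, since which one governs the interstitial volume
depends on $d_c$ relative to $P$ and the approximations are too coarse to
decide it per geometry.

## Synthetic fixtures

Every observable is testable without simulation: straight rods (exact
span, exact discrete-rod $R_g = l\sqrt{(N^2-1)/12}$, rod-like $S(q)$
slope), helices, a U-turn conformation -- two antiparallel strands in
adjacent cells joined by a semicircular hairpin through the shared
aperture, with occupation exactly 2 and strand separation exactly $S_p$,
the motif behind the $S(q)$ hump -- uniform point clouds over stated cell
sets for occupation counting (deliberately non-physical, so bond
validation is skipped), and synthetic $S(q)$ curves with a Gaussian bump
of known position for the hump detector. Fixtures declare their ground
truth as attributes.

## Scaled-down study sizes

The reference protocol (chains of 1000 beads, $2\times10^8\,\tau$
production, three replicas) is cluster-scale. The package defaults and the
test suite use desk-scale sizes chosen once: sweeps run chains of
$N = 60$--$100$ beads for a few $10^5$ Langevin steps per replica, which
suffices for the qualitative orderings (stiffer chains occupy more cells;
the occupation number has an interior maximum along the constant-$d_p$
series) but *not* for the quantitative maxima positions of the full-scale
study. Free-chain targets use the Monte Carlo sampler, where
$N = 1000$ chains decorrelate in minutes. What passing scaled-down sweep
tests show is that the machinery and the orderings are right -- not that a
60-bead chain reproduces 1000-bead numbers.

## Numerical choices and known limitations

* Bonded pairs feel both WCA and FENE; no 1-2 exclusion.
* $k_BT = \epsilon$ throughout; temperature enters only the samplers.
* The Nose-Hoover coupling is a single thermostat variable; any correct
  NVT scheme is acceptable here because only equilibrium averages are
  reported, and the suite checks the kinetic temperature to 2%.
* The Monte Carlo pivot rejects proposals that drive any pair below
  $0.6\,\sigma$ without evaluating the full energy; the skipped
  configurations have pair energies above $1700\,k_BT$, so the bias is
  below machine precision.
* Equilibrium gyration radii of free 1000-bead chains computed by this
  package are $R_g \approx 29.3\,\sigma$ ($b = 0$) and $\approx 76\,\sigma$
  ($b = 20$). The semiflexible value sits where the Benoit-Doty ideal-chain
  closed form ($74.7\,\sigma$ for $P = 18.9\,\sigma$, $L = 940\,\sigma$)
  plus a small excluded-volume swelling puts it, and both values are
  reproduced independently by the dynamics and the Monte Carlo routes, so
  we report them as the model's equilibrium properties.
* Hydrodynamic interactions, electrostatics, confining top/bottom walls,
  finite post height and driven (electrophoretic) transport are outside
  the model, as is any disordered or hexagonal post arrangement.

## A worked mini-study

```{r example, eval = FALSE}
library(nanopost)

# geometry series at constant effective post diameter d_p = 3.9
plan0 <- sweep_plan("constant_dp", fixed = 3.9,
                    values = c(4.5, 6, 9, 14, 30), N = 60, stiffness = 0,
                    config = sim_config(thermostat = "langevin",
                                        thermostat_tau = 1,
                                        n_equil = 1e5, n_prod = 3e5,
                                        sample_stride = 1500, seed = 71),
                    replicas = 2)
plan20 <- plan0; plan20$stiffness <- 20

res0  <- run_sweep(plan0, sq = TRUE)
res20 <- run_sweep(plan20, sq = TRUE)
render_reports(list(res0, res20), dir = "figures", P = 19.4)

# theory side: regimes and partition ratios for the same geometries
regime_report(build_series(plan0), P = 19.4, w = 0.9)
```
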