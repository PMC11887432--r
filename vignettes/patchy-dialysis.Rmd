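---
title: "Charge regulation of patchy nanoparticles under dialysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge regulation of patchy nanoparticles under dialysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchtitrate)
```

## The problem

When a colloid or protein solution is dialyzed against a buffer, only small
ions cross the membrane. Electroneutrality then forces an asymmetric ion
distribution between the particle-containing compartment (retentate) and the
buffer (permeate): the Donnan effect. The retentate pH differs from the
buffer pH by

$$\Delta\mathrm{pH} = \mathrm{pH}^{ret} - \mathrm{pH}^{perm} = -\log_{10} D_+,$$

where $D_+ = c_+^{ret}/c_+^{perm}$ is the distribution ratio of any
monovalent cation. The particle charge is itself regulated by the retentate
pH through the acid–base equilibrium of its ionizable sites, and
additionally suppressed by electrostatic repulsion between nearby ionized
sites (the polyelectrolyte effect). This package implements a minimal model
that resolves this feedback loop explicitly, with particular attention to
how the *spatial clustering* of ionizable sites — charge patchiness —
amplifies the polyelectrolyte effect.

## The model

A nanoparticle is a rigid sphere of diameter $d_{np}$ (default 1.42 nm,
four ion diameters) carrying $n$ weakly acidic sites (default 10, p$K_A$ =
4.0) as massless point charges on its surface. The sites occupy a single
spherical cap covering a fraction $1-\theta$ of the surface; $\theta = 0$
spreads them over the whole sphere, $\theta = 0.9$ confines them to 10% of
it. Within the cap the sites are spread approximately uniformly by
minimizing a Thomson-style objective $\sum_{i<j} 1/|r_i - r_j|$ under the
cap constraint (projected-gradient descent, iteration budget $10^4$,
objective tolerance $10^{-10}$, deterministic for a given seed). A plain
"minimize the sum of pair distances" prescription would collapse all sites
onto one point; inverse-distance repulsion reproduces the intended
near-uniform coverage.

Small ions (Na⁺, Cl⁻, H⁺, OH⁻) are charged spheres of diameter
$d_{ion} = 0.355$ nm in a dielectric continuum. Excluded volume uses the
offset (augmented) WCA potential with $\sigma = 0.355$ nm,
$\epsilon = 1\,k_BT$, cutoff $2^{1/6}\sigma$, and offsets
$r^{off}_{ij} = (d_i + d_j)/2 - \sigma$: 0 for ion–ion, 0.5325 nm for
nanoparticle–ion and 1.065 nm for nanoparticle–nanoparticle at the default
diameters. Sites have no excluded volume of their own; the core carries no
charge (only sites and ions do). Electrostatics is the bare Coulomb
potential $u = \lambda_B z_i z_j / r$ with $\lambda_B = 0.71$ nm (water at
298 K), evaluated under cubic periodic boundaries by classical Ewald
summation with conducting (tinfoil) boundary conditions. The splitting
parameter and wave-vector cutoff are chosen automatically from the target
relative accuracy ($10^{-3}$ by default); the implementation reproduces the
rocksalt Madelung constant to better than $10^{-4}$ relative at that
setting. Any periodic-electrostatics method meeting the accuracy target is
equivalent for equilibrium averages; Ewald is exact-to-tolerance and simple
at these system sizes (a few hundred charges).

## Reservoir coupling (Grand-Reaction Monte Carlo)

The permeate is a virtual reservoir at prescribed pH and NaCl concentration.
Its composition is resolved with the activity-based pH convention
$\mathrm{pH} = -\log_{10}(\gamma_\pm c_{H^+}/c^\circ)$, the water activity
product $10^{-14}$, and the convention that pH is adjusted by excess HCl
(pH ≤ 7) or NaOH (pH > 7) over the nominal salt; the mean activity
coefficient comes from the Davies equation
$\log_{10}\gamma_\pm = -0.509\,z^2(\sqrt{I}/(1+\sqrt I) - 0.3 I)$ iterated
to self-consistency. Ion exchange with the reservoir uses electroneutral
pair moves ($\varnothing \leftrightarrow$ Na⁺Cl⁻, H⁺Cl⁻, Na⁺OH⁻, H⁺OH⁻)
with constants $K_{ij} = \gamma_\pm^2 c_i c_j / c^{\circ 2}$ and
$K_{H_2O} = 10^{-14}$ fixed. Acid sites titrate by reaction-ensemble moves
with the acceptance rule

$$P_{acc} = \min\Big\{1,\; K^{\xi} \prod_i \frac{N_i!}{(N_i+\xi\nu_i)!}
 \,(V N_A c^\circ)^{\xi\bar\nu}\, e^{-\beta\Delta U}\Big\},$$

where $\xi = \pm 1$ is the direction and $\bar\nu = \sum_i \nu_i$. Three
equivalent implementations of the dissociation run simultaneously to
improve sampling — HA → A⁻ + H⁺ ($K_A$), HA → A⁻ + Na⁺
($K_A K_{NaCl}/K_{HCl}$) and HA + OH⁻ → A⁻ ($K_A/K_w$) — each an exact
combination of previously derived equilibria, so each satisfies detailed
balance with respect to the same distribution. All moves conserve the net
charge exactly, keeping the periodic Coulomb energy well defined at every
step.

Configurational sampling uses single-unit Metropolis moves: uniform
displacements of ions and rigid translations/rotations of nanoparticles
(axis uniform on the sphere, angle uniform up to a maximum). This samples
the same canonical configurational distribution as a thermostatted
dynamics would; since every reported observable is an equilibrium average,
the trajectory itself is irrelevant. A cycle is
`config_moves_per_cycle` configurational trials followed by
`reaction_moves_per_cycle` reaction/exchange trials (defaults 1000 and 250,
a 4:1 mix). Displacement and rotation steps are tuned to 30–50% acceptance
during the equilibration window only and frozen afterwards — tuning during
production would violate detailed balance.

## Closed-form reference theory

For monovalent ions and a nonexchangeable anion concentration $c_{A^-}$,
ideal Donnan electroneutrality gives
$D_+ = \big(c_{A^-} + \sqrt{c_{A^-}^2 + 4I^2}\big)/2I$, with
$D_- = 1/D_+$ and $\psi_{Don} = -(k_BT/e)\ln D_+$. Coupling to the exact
Henderson–Hasselbalch relation
$\alpha = 1/(1 + 10^{pK_A - \mathrm{pH}^{ret}})$ with
$c_{A^-} = \alpha\, c_{acid}$ closes the feedback loop; the package solves
it by damped fixed-point iteration (damping 0.5 — undamped iteration can
oscillate on the steep flank of the titration curve; tolerance $10^{-12}$
in $\alpha$, hard iteration cap with a loud failure, never silent). The
permeate ionic strength includes the H⁺/OH⁻ contributions by default; this
is what makes $\Delta$pH turn back toward zero at very high pH, where
hydroxide becomes comparable to the salt. A flag exposes the
salt-only variant. The non-interacting engine mode (`no_interactions`)
samples exactly this ideal ensemble, so theory and engine must agree within
statistics — this cross-validation is part of the test suite.

## Steric-only partitioning

With charges off, partitioning is pure volume exclusion. Two estimators are
implemented and must agree: Widom insertion
($D_+ = \langle e^{-\beta\Delta U_{ins}}\rangle$ over uniform test-ion
insertions into equilibrated neutral configurations, the excess chemical
potential route) and a charge-free grand-canonical run. At low volume
fraction both approach the excluded-volume estimate
$1 - \phi_{np}(1 + d_{ion}/d_{np})^3$.

## Defaults and their meaning

| parameter | default | meaning |
|---|---|---|
| `d_np` | 1.42 nm | core diameter, 4 ion diameters |
| `n_sites` | 10 | acidic sites per particle |
| `pKa` | 4.0 | site acidity constant |
| `theta` | 0 | patchiness; 0.9 = sites on 10% of surface |
| `sigma` | 0.355 nm | WCA range = ion diameter |
| `bjerrum` | 0.71 nm | water, 298 K |
| `ewald_accuracy` | 1e-3 | relative accuracy of periodic Coulomb energy |
| `n_salt_pairs` | 250 | sets the box volume via $V = N_{salt}/(N_A c_{salt})$ |
| `equilibration_fraction` | 0.30 | discarded as equilibration |
| site radius | $d_{np}/2$ | sites on the core surface (configurable) |

The box is sized from the salt content, and the nanoparticle count is the
integer closest to the requested volume fraction, kept at ≥ 10 to limit
finite-size effects.

## Error analysis

Correlated series are summarised by blocking: block sizes double until the
blocked standard error plateaus (relative change < 5% across two
doublings); the plateau value is the reported SE and the variance inflation
yields an autocorrelation-time estimate. If no plateau is reached the
largest blocked SE is reported (conservative). The first 30% of each run is
discarded as equilibration — a reproducible stand-in for the visual
inspection a human would do, chosen as a generous margin over the observed
relaxation times.

## Numerical choices and degenerate cases

* Ewald real-space cutoff is half the box edge; the box must exceed twice
  the largest interaction cutoff (checked at build time).
* Positions are stored unwrapped; minimum image is applied inside energy
  kernels only, so rigid bodies are never split by the boundary.
* Cached total energy is refreshed from scratch every 500 cycles; the
  incremental bookkeeping agrees with full recomputation to
  $10^{-6}\,k_BT$ per particle over long runs (tested).
* Initial configurations use rejection sampling with a $10^6$-attempt
  budget; an unresolvable overlap is an initialization error.
* In `fixed_fraction` mode the per-site charge is quantised to
  $-\mathrm{round}(N_{sites}\alpha)/N_{sites}$ so an integer number of
  counterions restores exact neutrality (with 100 sites any two-decimal
  $\alpha$ is representable exactly).
* Zero-salt reservoirs have undefined composite constants for the Na⁺/Cl⁻
  moves; those moves are disabled rather than attempted with undefined
  acceptance.
* A degenerate one-site "patch" is placed on the patch axis; a reservoir at
  pH exactly 7 with no salt resolves to pure water (roundoff-scale negative
  concentrations are clamped).

## What the defaults emulate — and what they do not

The default system is a deliberately small, strongly coupled proof-of-
concept: particles are smaller and their sites closer together than in real
proteins, so both the Donnan and polyelectrolyte effects are *stronger*
than in a typical protein solution. The model has only acidic sites, one
patch per particle, monovalent ions, and an implicit solvent; it does not
represent protein shape, mixed acid/base residues, buffering species, or
ion-specific chemistry. Passing tests therefore demonstrate correct
statistical mechanics of this model, not quantitative prediction for any
particular protein.

Two finite-size facts matter when interpreting small test systems. First,
the electroneutral-pair grand-canonical ensemble depletes small ion counts:
$\langle N\rangle = zV\, I_1(2zV)/I_0(2zV)$, an $O(1/4\langle N\rangle)$
effect — negligible at the default 250 pairs, visible below ~10. Second,
distribution-ratio products such as $D_+ D_-$ measured against the
*nominal* reservoir concentrations equal $(\gamma_\pm^{Davies}/
\gamma_\pm^{model})^2$ in interacting runs: they probe the mismatch between
the Davies estimate and the primitive model's true activity coefficient
(a few percent at $I \lesssim 0.25$ M), not a sampling error.

## Problem sizes used in the shipped tests

The test suite and the acceptance script are sized for a single CPU and a
few minutes total: interacting runs use 10 nanoparticles (100 sites) with
25 salt pairs and 300 cycles of 200 configurational + 100 reaction trials;
ideal-engine comparisons use 50 salt pairs and 500 cycles; Widom estimates
use $10^5$ insertions over 100 decorrelated configurations of 30 neutral
particles. These reproduce the qualitative orderings (ionization suppressed
with increasing patchiness; titrating vs fixed-charge equivalence; Donnan
ratios versus theory) with 3-sigma resolution; mapping out full titration
curves at the publication state points simply needs longer runs of the same
code via `run_sweep()`.

## Known limitations

* The mean site distance reported by `mean_site_distance()` depends on an
  averaging convention (nearest-neighbour vs all-pairs) and on the site
  radius; both statistics are reported, and neither is claimed to match any
  specific published tabulation beyond its monotone trend in $\theta$.
* Reservoir activity coefficients use the Davies form with $A = 0.509$,
  $0.3I$; at $I \lesssim 0.1$ M results are insensitive to the exact
  coefficients at the reported precision.
* No dynamics: transport properties and time scales are outside scope.
* Snapshots restore particle data, not engine state; a restored snapshot
  seeds a new run rather than continuing an old one bitwise.

## A worked example

```{r example, eval = FALSE}
library(patchtitrate)

res  <- solve_reservoir(pH = 5, c_salt = 0.05)
tpl  <- nanoparticle_template(theta = 0.75)       # 10 sites on 25% of surface
box  <- box_from_salt(0.05, n_salt_pairs = 25)
st   <- build_system(tpl, n_np = 10, box, res, mode = "full", seed = 4)
ser  <- run_simulation(st, mc_schedule(300, 200, 100, seed = 9))
summ <- summarise_series(ser)
summ$alpha$mean      # ionization degree, suppressed relative to ideal HH
summ$delta_pH$value  # retentate minus permeate pH (negative: acidic shift)

# the ideal reference the run should undershoot:
coupled_hh_donnan(5, 4, count_to_molar(100, box$volume), 0.05)$alpha
```
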