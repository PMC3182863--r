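---
title: "Heterogeneous half-sarcomere networks and residual force enhancement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneous half-sarcomere networks and residual force enhancement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The phenomenon and the model

A contracting muscle fiber that is actively stretched from one length to
another produces more steady tension afterwards than it does when activated
directly at the final length. `sarcomech` implements a mechanistic
explanation of this residual force enhancement (RFE): a fiber is a chain of
half-sarcomeres that are not identical, and mechanical coupling between
slightly stronger and slightly weaker units stores the strain energy of the
stretch in skewed cross-bridge populations and dissipates it far more slowly
than any isolated cross-bridge cycles.

Each half-sarcomere couples three ingredients:

1. **Availability.** The myosin head density able to cycle is
   `N = n0 * zeta * psi(t) * phi(l)`: a reference density `n0 = 1.15e17 m^-2`,
   a per-unit strength multiplier `zeta`, an imposed activation trace
   `psi(t)` shared by all units, and a piecewise-linear filament overlap
   fraction `phi(l)` (plateau 1170--1300 nm, zero at 800 and 1700 nm).
2. **Cross-bridge cycling.** Bound heads are resolved over a discrete strain
   axis in a three-state scheme: detached (D), attached pre-powerstroke
   (A1), attached post-powerstroke (A2). Attachment is localized near zero
   strain; the powerstroke adds `x_ps = 5 nm` of displacement; detachment is
   strain-promoted. Active stress is the Huxley population sum
   `k_cb * (sum a1(x) x + sum a2(x) (x + x_ps))`.
3. **Passive elasticity.** A titin-like element
   `xi * 112 * (exp((l - 625)/136) - 1) N m^-2` (linear continuation below
   the 625 nm offset), with a per-unit stiffness multiplier `xi`.

Heterogeneity enters only through `zeta` and `xi`, drawn from Gaussians with
mean 1 and standard deviations `alpha` and `beta` (draws at or below 0.05
rejected). A fiber is `n_series` half-sarcomeres in series, optionally
`n_myofibrils` such chains in parallel with z-line coupling springs `k_im`;
the total length is imposed and the computer repartitions it every step so
that tension is equal at every series connection.

## What the generator emulates — and what it does not

The multiplier sampler plays the role of the synthetic data: each seed is
one "fiber" with its own pattern of strong and weak half-sarcomeres, and
ensembles of seeds stand in for biological replicates. This captures random,
spatially uncorrelated variation in contractile strength and passive
stiffness. It does not capture spatially correlated variation along a fiber,
time-varying protein turnover, Ca2+ dynamics (activation is an imposed
trace), or 3-D lattice geometry. Passing tests therefore show that the
*mechanism* is reproduced under the stated statistical model of
heterogeneity, not that any particular real fiber follows it.

## Rate laws and the one-time calibration

The kinetic scheme is deliberately minimal, with rates (all s^-1, strains in
nm):

* attachment `f(x) = f0 exp(-x^2 / 2 sigma_f^2)`, `f0 = 8`,
  `sigma_f = 0.5` (total attachment flux 40 s^-1);
* powerstroke `h(x) = h0 / (1 + exp(-(x - x_h0)/x_hw))`, `h0 = 40`,
  `x_h0 = -2.5`, `x_hw = 0.5`; reversal `h_r = 2`;
* detachment `g(x) = min(g0 + g1 (exp(|x|/x_d) - 1), g_cap)` from A2 with
  `g0 = 0.6`, `g1 = 0.02`, `x_d = 1.2`, `g_cap = 40`; A1 detaches at
  `g_a1 + g1 (exp(|x|/x_d) - 1)` with `g_a1 = 2`.

The coefficients were calibrated once, against the single half-sarcomere
ramp-and-hold response (force must decay back to the isometric value within
1% shortly after a stretch) and the standard-protocol ensemble enhancement
(about 13%), and then frozen. The cross-bridge stiffness
`k_cb = 4.4e-13 N nm^-1` per head sets the isometric tension scale
(~240 kPa at optimal length), keeping passive tension a few percent of
active tension at 1200 nm while passive dominates beyond ~1600 nm.

The *shape* of the detachment law matters far more than its scale. Three
properties are needed simultaneously:

* **A monotone, saturating eccentric force-velocity relation.** With the
  frozen law the single-unit eccentric steady force rises from 1.11x to
  1.58x isometric between 0.6 and 19 nm/s of lengthening. If detachment
  instead rises as a steep power of strain (for example quartic), force
  capacity *falls* with drag velocity, and every unit that is even a few
  percent weak yields catastrophically — the model then predicts force
  *depression* at small `alpha`, the opposite of what is observed.
* **Slow cycling near zero strain** (`g ~ 1 s^-1`), so small force deficits
  drive slow creep and the dispersed configuration relaxes over seconds to
  tens of seconds. This is the memory that makes enhancement long-lived.
* **Fast detachment at large strain**, so a rapidly yielding ("popping")
  unit sheds its bridges within tens of milliseconds and the stretch
  transient of a *homogeneous* fiber decays quickly.

## Numerics

* **Strain axis** [-20, 20] nm at 0.25 nm spacing (161 points). The width
  accommodates the drag tails that develop while weak units yield; boundary
  occupancy stays negligible in shipped protocols. Mass advected past the
  edge during extreme yielding is forcibly detached into D (an absorbing,
  mass-conserving boundary) and audited per run (`ripped` counter).
* **Kinetics update.** Integrating-factor step: inflows frozen over the
  step, exits integrated exactly. Unconditionally stable and
  positivity-preserving however steep the detachment, and its fixed point is
  the exact steady state of the rate equations at any step size. Only the
  explicit attachment flux out of D constrains the step
  (`dt * sum(f) < 1`).
* **Force balance.** Damped Newton on interior node positions with the
  analytic tridiagonal Jacobian built from each unit's instantaneous
  stiffness (`k_cb * bound + passive slope`); block-tridiagonal elimination
  for multi-myofibril lattices with all-to-all z-line springs within each
  z-disk ring. Convergence to `max(1e-4 N m^-2, 1e-6 x mean force)`;
  bisection fallback for the two-unit chain.
* **Operator splitting** (kinetics, then balance) at `dt = 1 ms`, with
  adaptive substepping: any step in which a unit carrying significant bound
  mass moves more than 2.5 nm is redone at up to dt/64 so advection and
  strain-dependent detachment co-evolve through fast transitions. At the
  subdivision floor the motion is accepted; a unit still moving that fast is
  in free fall onto its passive curve and its remnant bridges are ripped.
  Halving `dt` changes standard-protocol force traces by well under 0.5%.
* **Pool rescaling.** When availability changes (activation ramp, overlap
  change) all pools are scaled proportionally to match — the simplest
  conservative closure.
* An optional rupture term (`g_r`, `x_r`) and a parallel dashpot
  (`eta_visc`) exist as parameters for exploring stiffer containment of
  yielding units; both are 0 in the frozen defaults because they weaken the
  small-`alpha` enhancement.

## Protocol conventions

Trials run in pairs on a common time grid: linear activation over 1 s, a
1 s isometric hold, a constant-velocity stretch to the final length, and a
hold; the isometric companion sits at the final length throughout. RFE is
the percentage excess of the stretched trial's force over its companion's,
evaluated `t_ss = 6 s` after the end of the length change, on
ensemble-averaged traces (per-seed values are also reported).

Stretch magnitude and velocity are expressed relative to the *initial*
length: the standard 8% stretch at 0.1 L0/s runs from a mean half-sarcomere
length of 1200 nm to 1296 nm in 0.8 s. The final length 1296 nm sits at the
plateau edge of the length-tension relation, which keeps the mean operating
point mechanically stable; expressing the same magnitude relative to the
final length would end the stretch at 1304 nm, just onto the descending
limb, where even a 2% heterogeneous chain slowly phase-separates and the
paired comparison degrades. Both conventions are recorded in the protocol
object.

## Design choices where the design was open

* `alpha` and `beta` are interpreted as standard deviations (coefficients of
  variation) of the multipliers: only that reading makes `alpha = 0.02`
  correspond to about 2% strength variation.
* The ensemble statistic is the RFE of the averaged traces (the figure
  convention); per-seed RFEs are kept alongside.
* Child seeds derive from the master seed by a counter-based affine map
  modulo a large prime, so any ensemble is reproducible from one integer.
* Steady-state length-tension points are accepted when force drift falls
  below 0.01%/s, with a 60 s settle cap.
* The default velocity grid for the velocity-dependence experiment spans
  0.05--0.5 L0/s (a 10x range).
* Default ensemble size is 10 seeds per condition — large enough that the
  ensemble mean is meaningful, small enough for routine runs; a full-size
  (60-seed) run is a single argument away.

## Known limitations

* Enhancement is over-predicted for very slow ramps (below ~0.05 L0/s,
  including the 4 s lattice ramp): long ramps give weak units time to yield
  completely during the stretch, adding configurational divergence on top of
  the stored-strain mechanism. The velocity-independence of RFE therefore
  holds over the shipped 10x velocity range but degrades below it.
* Passive-only heterogeneity (`beta` alone) produces enhancement of only
  about 3--5% under the frozen calibration. With equal active strength, a
  dispersed configuration produces little extra force on the plateau, so
  the beta pathway is structurally weaker here than in the reference
  phenomenology (~7.6%). Raising the passive share of total force raises it
  at the cost of pushing the alpha-driven values out of range.
* Stretches ending low on the ascending limb show mild depression rather
  than the small positive enhancement sometimes reported; the bound for
  ascending-limb enhancement is still respected.
* The quasi-static balance admits near-instantaneous yielding of units whose
  bound population has collapsed; their motion is resolved by substepping
  and audited ripping rather than by explicit viscous dynamics.

## Problem sizes

Shipped tests and the acceptance script use 50 half-sarcomeres in series,
10-seed ensembles (3 for the 6 x 50 lattice, 2 for the 60 s convergence
run), and `dt = 1 ms` — the chain size and time step of the reference
design, with ensembles scaled to one-sixth of the reference count. These
sizes keep a full reproduction under a quarter of an hour on one core while
leaving ensemble means stable to a couple of percentage points.
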