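---
title: "Methods: multiscale Brownian dynamics of nanoparticle tissue transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale Brownian dynamics of nanoparticle tissue transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuebd)
```

## The model

`tissuebd` simulates the journey of drug-delivery nanoparticles through the
interstitial space of a vascularized tissue, idealized as a two-dimensional
rectangle. The left edge is a porous capillary wall: fluid enters there at a
prescribed speed and particles are released from uniformly random points on
it. The bottom and top edges are no-slip walls; the right edge is open and is
expected to stay out of reach (any particle that does reach it is recorded
and reported). Tissue cells are stationary discs of radius 10 um placed at
non-overlapping random positions until they cover 40 % of the rectangle, so
the interstitial porosity is 0.60.

Transport combines three mechanisms:

1. **Advection.** The interstitial Stokes flow driven by the inlet is
   computed once by the Method of Regularized Stokeslets (MRS): point forces
   are collocated on every solid boundary (three edges plus all cell
   circles), each smoothed by the quartic blob
   $\phi_\epsilon(r) = 2\epsilon^4 / \pi (r^2+\epsilon^2)^3$, which
   integrates to one over the plane. Prescribing the boundary velocities
   (inlet speed at the left edge, zero on all no-slip boundaries) gives a
   dense $2N \times 2N$ linear system for the unknown forces, solved by LU
   factorization; the velocity anywhere is the superposition of the $N$
   regularized-Stokeslet kernels. A particle moves with the local fluid
   velocity; its influence back on the flow is neglected.

2. **Diffusion.** Each particle of radius $a$ diffuses with the
   Einstein-Stokes coefficient $D = k_B T / 6\pi\mu a$ (0.91 um^2/s for a
   100 nm particle at 310 K in a 2.5 cP fluid). A Brownian-dynamics step of
   duration $\Delta t$ displaces the particle by
   $S = v\,\Delta t + \sqrt{4D\Delta t}\,e$ with $e$ a uniformly random unit
   vector: the diffusive step length is deterministic, only its direction is
   random. Over many steps this reproduces the 2D mean-squared-displacement
   law $\langle |\Delta x|^2 \rangle = 4Dt$ exactly in expectation.

3. **Capture.** Cell boundaries are sticky: each particle-cell contact
   captures the particle with probability $\rho$ and otherwise reflects it.
   $\rho$ lumps every adhesion and uptake mechanism (van der Waals forces,
   surface charge, corona formation, receptor binding) into one per-contact
   Bernoulli trial, so contacts-before-capture at a wall are geometric with
   mean $1/\rho$.

## The three-tier adaptive stepper

Tissue-scale dispersion takes hours while particle-cell encounters happen on
milliseconds; a single step size cannot serve both. Each step therefore
chooses among three tiers based on $R$, the distance from the particle
centre to its nearest solid feature (edge or cell boundary):

1. Propose a jump at the largest step $\Delta t_m$ (default 0.1 s). If the
   realized jump length is below $R - a$ the particle cannot have crossed
   any boundary, so the move is accepted.
2. Otherwise solve $|v|\,\Delta t_a + \sqrt{4D\Delta t_a} = R - a$ for the
   intermediate step $\Delta t_a$, which by construction cannot produce a
   boundary-crossing jump, and accept the proposal if its realized length
   exceeds the near-wall gate $4a$.
3. Otherwise advance with the fine step $\delta t = 10^{-3}$ s. Only in this
   tier can contacts occur: a move ending within one particle radius of a
   cell boundary (or inside the cell) is a contact, resolved by capture or
   by specular reflection; moves crossing a domain edge are specularly
   reflected off it.

At $\delta t$ the diffusive jump $\sqrt{4D\delta t}$ is comparable to the
particle diameter, fine enough to resolve the encounter kinematics. Because
every capture-relevant move happens at $\delta t$ regardless of
$\Delta t_m$, predictions are insensitive to the choice of $\Delta t_m$ —
the test suite verifies mean penetration depth varies by under 5 % across
$\Delta t_m \in [10^{-3}, 0.1]$ s. A fixed-step reference engine
(`simulate_fixed_step()`), which rejects moves conflicting with cell
interiors and attempts capture inside a thin 0.25 um interaction layer
around each cell, shows the opposite behaviour: its capture rate collapses
(and its penetration depth inflates) as the step grows, because a long fixed
jump simply lands past the layer.

### Numerical and design choices

* **Reflection mechanics.** "Reflected into the fluid" is realized as
  specular reflection about the local tangent, consistent with treating the
  (much larger) cell boundary as locally flat: the penetrating normal
  component of the move is mirrored at the contact plane one particle radius
  outside the cell circle. If the mirrored position is itself invalid the
  move is rejected and the particle stays put. Domain-edge reflection is
  likewise specular. Capture projects the centre to the contact plane.
* **The inlet is reflecting** for particles, so every injected particle
  stays in the tissue; this matters for validation (below).
* **The tier-3 clock always advances** by $\delta t$, whether the fine move
  is accepted, reflected or rejected, so elapsed time is well defined.
* **Tier-2 acceptance uses the realized jump length** ($|S| > 4a$), exactly
  as the stepping rule states, not a pre-jump bound.
* **RNG.** Each particle owns an independent xoshiro256+ stream seeded from
  the master seed and the particle index, so ensembles are reproducible,
  platform-stable, and independent of simulation order; the first $k$
  particles of a run coincide with a $k$-particle run. R-level stochastic
  helpers (packing, `propose_jump()`) use R's RNG.
* **Flow cache.** The cells are stationary, so the flow field is solved
  once and cached on a regular grid (default spacing 0.5 um, the blob
  radius) queried by bilinear interpolation; exact kernel summation remains
  available and the cache agrees with it to within 2 % of the inlet speed in
  the bulk interstitium. Within ~2 um of a boundary the exact field itself
  carries collocation-scale microstructure; particles there are in the
  near-wall tier where advection is negligible compared to diffusion.
* **Degenerate inputs.** Packing at target fraction zero returns a clean
  cell-free field; `solve_intermediate_dt()` refuses $R \le a$ (that is a
  collision, handled by tier 3); coincident collocation points make the MRS
  matrix singular and are reported with a condition estimate.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| cell radius $r$ | 10 | um | stationary tissue cells |
| particle radius $a$ | 0.1 (100 nm) | um | mobile nanoparticle |
| porosity | 0.60 | — | interstitial area fraction (cells cover 40 %) |
| $\rho$ | 0.01 | — | capture probability per contact |
| $\mu$ | 2.5 | cP | interstitial fluid viscosity |
| $T$ | 310 | K | physiological temperature |
| $v_{in}$ | 1 | um/s | inlet fluid speed (0.05–4 in experiments) |
| $\epsilon$ | 0.5 | um | Stokeslet regularization radius |
| $N$ | 6700 | — | collocation points over all boundaries |
| $\Delta t_m$, $\delta t$ | 0.1, $10^{-3}$ | s | largest / finest time step |
| ensemble | 16000 particles, $10^4$ s | — | production run size |

The domain rectangle (default 1000 x 500 um) is chosen deep enough that the
production horizon keeps particles away from the open right edge. Cells keep
a one-radius margin off the inlet edge (entering particles must find fluid)
and a 0.5 um clearance off the no-slip walls — tangent cells would place
cell collocation points arbitrarily close to wall collocation points and
degrade the conditioning of the MRS system.

## Validation against closed forms

For a cell-free domain the depth coordinate follows one-dimensional
half-plane solutions with a reflecting origin:

* pure diffusion: $G(x,t) = e^{-x^2/4Dt}/\sqrt{\pi D t}$, with peak height
  $1/\sqrt{\pi D t}$ — twice the free-space Gaussian peak, since all mass
  folds into $x \ge 0$;
* small drift $v$: $G(x,t) = e^{-(x-vt)^2/4Dt}/\sqrt{\pi D t}$, a Gaussian
  centred at $vt$.

The drifted form keeps the folded prefactor and ignores the reflecting
origin, which is accurate once $vt \gg \sqrt{Dt}$. The simulation, whose
inlet genuinely reflects, shows the exact consequence of that approximation:
the mean depth settles at $vt + D/v$, the constant $D/v$ being the expected
cumulative push-back from the origin (the Skorokhod reflection term). The
validation suite compares the ensemble mean against $vt + D/v$ at three
standard errors and the empirical depth distribution against the
pure-diffusion law by a Kolmogorov–Smirnov distance.

## What the test problems do and do not show

The packaged validation runs are desk-scale by design: ensembles of
2,000–5,000 particles over $10^2$–$10^4$ s on domains of 300 x 150 to
1000 x 2000 um, with collocation counts of 1,000–4,000 chosen to keep at
least the production run's per-cell boundary resolution. Stochastic
comparisons use three-standard-error bands; ordered stochastic means allow a
two-standard-error slack per comparison. The production-scale configuration
(16,000 particles, $10^4$ s, $N = 6700$) is the package default and runs
through exactly the same code path.

The generator emulates the idealized study system — monodisperse circular
cells, a static flow field, mutually non-interacting particles, irreversible
capture. It does not emulate real-tissue features such as polydisperse or
deformable cells, extracellular-matrix heterogeneity, reversible binding or
receptor-level uptake kinetics, particle crowding, or three-dimensional
geometry, so passing tests certify the transport algorithm, not tissue
realism.

Two further limitations are worth stating plainly. First, at fixed blob
radius the collocation solve only enforces boundary conditions *at* the
collocation points; with the production-scale point spacing (several um per
point against $\epsilon = 0.5$ um) fluid leaks between points, cross-section
flux decays with depth, and interior speeds sit well below their
continuum-limit values. Refinement studies in the resolved cell-free regime
(spacing approaching $\epsilon$) show clean self-convergence and
flux conservation to better than 1 %; the under-resolved tissue regime is
the method as specified, and the capture-dominated conclusions (the $\rho$
plateau, step-size robustness) are insensitive to it. Second, the moving
half-plane profile is the model's own near-origin approximation, as
discussed above.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(width = 1000, height = 300, n_collocation = 4000,
                  n_particles = 2000, t_end = 1000, rho = 0.01, seed = 11)
ex <- run_experiment(cfg, quiet = TRUE)
ex$summary$mean_depth          # ~34 um mean penetration at rho = 0.01
ex$summary$captured_fraction   # ~0.97: nearly every particle is taken up
ex$summary$mean_contacts_before_capture  # ~98 = 1/rho, the geometric law
```

Raising $\rho$ tenfold barely changes the outcome: near a cell a particle
makes dozens of $\delta t$-scale contacts per encounter, so the per-encounter
capture probability saturates once $\rho \gtrsim 0.1$. That is the mechanism
behind the plateau in penetration depth — and the reason cell-free in-vitro
assays, which remove the encounters entirely, overstate how strongly particle
size (through $D$ alone) controls tissue penetration.
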