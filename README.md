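# tissuebd

Multiscale Brownian dynamics of drug-delivery nanoparticle transport in
porous biological tissue.

## The problem

How far do drug-delivery nanoparticles penetrate into a tissue, and what
limits them? Cell-free in-vitro assays (collagen matrices, microfluidics)
suggest particle size is decisive: smaller particles diffuse faster and
spread much further. In vivo, distributions are far narrower and the size
effect is modest. `tissuebd` is a simulation tool for exploring why: it
models a tissue as a 2D rectangle whose left edge is a porous capillary
(fluid inlet and particle source), packed to 40 % area with stationary
circular cells (porosity 0.60), and follows individual nanoparticles under
the combined action of

* **advection** — the interstitial Stokes flow, computed by the Method of
  Regularized Stokeslets: point forces on all solid boundaries smoothed by
  the blob \(\phi_\epsilon(r) = 2\epsilon^4/\pi(r^2+\epsilon^2)^3\), solved
  so the no-slip and inlet conditions hold at every collocation point;
* **diffusion** — Einstein–Stokes, \(D = k_B T / 6\pi\mu a\), so a 100 nm
  particle in 2.5 cP interstitial fluid at 310 K has
  \(D \approx 0.91\ \mu m^2/s\);
* **cellular capture** — cell boundaries are sticky walls that capture a
  colliding particle with per-contact probability \(\rho\) (a lumped stand-in
  for adhesion and uptake biophysics) or reflect it otherwise.

The engine is a three-tier time-adaptive Brownian dynamics scheme: jumps of
\(S = v\Delta t + \sqrt{4D\Delta t}\,e\) use the largest step
\(\Delta t_m = 0.1\) s far from boundaries, an intermediate step solved from
\(|v|\Delta t_a + \sqrt{4D\Delta t_a} = R - a\) on approach, and a fine
\(\delta t = 10^{-3}\) s step near walls where contacts are resolved. That
makes hours-long tissue dispersion affordable while still resolving
millisecond particle–cell encounters — and makes predictions insensitive to
\(\Delta t_m\), unlike fixed-step schemes (a fixed-step comparison engine
with a 0.25 µm capture layer is included to demonstrate exactly that).

See `vignettes/tissuebd-methods.Rmd` for the full model description,
parameter table and design choices.

## A worked example

```r
library(tissuebd)

cfg <- run_config(width = 1000, height = 300, n_collocation = 4000,
                  n_particles = 2000, t_end = 1000, rho = 0.01, seed = 11)
ex <- run_experiment(cfg, quiet = TRUE)
print(ex$result)
#> <ensemble_result> 2000 particles: 67 mobile, 1933 captured, 0 exited
#>   mean penetration depth 34.19 um; mean collisions 96.4
round(unlist(ex$summary[c("mean_depth", "mean_depth_se",
                          "captured_fraction",
                          "mean_contacts_before_capture")]), 3)
#>                   mean_depth                mean_depth_se
#>                       34.189                        0.545
#>            captured_fraction mean_contacts_before_capture
#>                        0.967                       97.553
```

Reading those numbers: after 1000 s nearly every particle has been taken
up by a cell, on average only ~34 µm past the capillary wall, and a captured
particle made ~98 contacts before capture — the geometric \(1/\rho\) law.
Because a particle near a cell makes many fine-step contacts per encounter,
the per-encounter capture probability saturates once \(\rho \gtrsim 0.1\):
penetration depth decreases with \(\rho\) and then plateaus. In a cell-free
domain (`target_fraction = 0`) the same engine reproduces the closed-form
half-plane profiles `diffusion_profile()` and
`advection_diffusion_profile()` — the regime where size effects look
dramatic because nothing but \(D\) matters.

A thin command-line wrapper is installed at
`inst/scripts/tissuebd-sim.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/tissuebd-sim.R", package = "tissuebd"))')" \
  --n-particles 2000 --t-end 1000 --rho 0.1 --out out/
```

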