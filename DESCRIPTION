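Package: tissuebd
Title: Multiscale Brownian Dynamics of Nanoparticle Transport in Porous Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates the interstitial transport of drug-delivery
    nanoparticles through a two-dimensional tissue section populated with
    stationary circular cells. The interstitial Stokes flow is computed by
    the Method of Regularized Stokeslets from point forces collocated on
    the domain walls and cell boundaries. Particles are advanced by a
    three-tier time-adaptive Brownian Dynamics scheme that combines
    advection and diffusion, resolves particle-cell encounters at fine
    time steps, and treats cell boundaries as sticky walls that capture a
    colliding particle with a fixed per-contact probability. Includes
    closed-form half-plane diffusion and advection-diffusion reference
    profiles, a fixed-step comparison engine with an interaction-layer
    capture rule, and summaries of penetration depth, particle fate and
    collision statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
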