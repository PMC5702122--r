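# Shared fixtures. The tissue bench (packed domain + solved flow field) is
# expensive, so it is built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Desk-scale tissue bench: 1000 x 300 um, 40 % cells, N = 4000 collocation
# points (~2.8 um spacing), inlet 1 um/s, velocity cached on a 1 um grid.
tissue_bench <- function() {
  if (is.null(.fixture_cache$bench)) {
    dom <- domain_spec(1000, 300)
    cells <- pack_cells(dom, cell_radius = 10, target_fraction = 0.4,
                        seed = 123)
    disc <- discretize_boundaries(dom, cells, n_points = 4000, v_in = 1)
    sys <- solve_forces(disc)
    grid <- build_velocity_grid(sys, dom, resolution = 1)
    .fixture_cache$bench <- list(domain = dom, cells = cells, disc = disc,
                                 system = sys, grid = grid)
  }
  .fixture_cache$bench
}

bench_config <- function(...) {
  run_config(width = 1000, height = 300, ...)
}

# run an ensemble on the shared bench, silencing the right-edge exit warning
# (a handful of exits is expected in the long low-capture runs)
bench_ensemble <- function(config) {
  b <- tissue_bench()
  suppressWarnings(simulate_ensemble(config, cells = b$cells, field = b$grid))
}

# a one-cell field placed by hand
single_cell_field <- function(domain, centre, r = 10) {
  structure(list(centers = matrix(centre, 1, 2,
                                  dimnames = list(NULL, c("x", "y"))),
                 cell_radius = r,
                 achieved_area_fraction = pi * r^2 /
                   (domain$width * domain$height),
                 domain = domain),
            class = "cell_field")
}

# synthetic ensemble_result for analysis-function unit tests
fake_ensemble <- function(x, status = rep("mobile", length(x)),
                          collisions = rep(0L, length(x))) {
  n <- length(x)
  df <- data.frame(id = seq_len(n), x = x, y = rep(0, n),
                   status = factor(status, levels = c("mobile", "captured",
                                                      "exited_right")),
                   capture_cell = rep(NA_integer_, n), collisions = collisions,
                   t_final = rep(1, n), y_entry = rep(0, n))
  structure(df, class = c("ensemble_result", "data.frame"), seed = 0,
            params = list())
}
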