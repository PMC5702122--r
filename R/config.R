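#' Simulation run configuration
#'
#' Collects every tunable of a transport simulation with its default.
#' Geometry: cell radius 10 um, target cell area fraction 0.4 (porosity
#' 0.6), domain 1000 x 500 um. Particle: radius 100 nm, capture probability
#' 0.01. Fluid: viscosity 2.5 cP, temperature 310 K, inlet speed 1 um/s,
#' regularization radius 0.5 um, N = 6700 collocation points. Engine: steps
#' between 1e-3 s and 0.1 s, 16000 particles over 1e4 s.
#'
#' @param width,height Domain extents, micrometres.
#' @param cell_radius Cell radius, micrometres.
#' @param target_fraction Cell area fraction (porosity = 1 - value).
#' @param particle_radius Particle radius, micrometres.
#' @param rho Capture probability per cell contact, in `[0, 1]`.
#' @param viscosity Fluid viscosity, centipoise.
#' @param temperature Kelvin.
#' @param v_in Inlet fluid speed, um/s.
#' @param epsilon Stokeslet regularization (blob) radius, micrometres.
#' @param n_collocation Total collocation points on all solid boundaries.
#' @param dt_max,dt_min Largest/smallest engine time step, seconds.
#' @param n_particles Ensemble size.
#' @param t_end Simulation horizon, seconds.
#' @param seed Master seed (integer); child streams for packing and
#'   particles are derived from it.
#' @param engine `"adaptive"` or `"fixed"`.
#' @param fixed_dt Step of the fixed-step engine, seconds.
#' @param interaction_layer Capture layer of the fixed-step engine,
#'   micrometres.
#' @param grid_resolution Velocity-cache grid spacing, micrometres.
#' @return An object of class `run_config` (a validated named list).
#' @export
run_config <- function(width = 1000, height = 500,
                       cell_radius = 10, target_fraction = 0.4,
                       particle_radius = 0.1, rho = 0.01,
                       viscosity = 2.5, temperature = 310,
                       v_in = 1, epsilon = 0.5, n_collocation = 6700,
                       dt_max = 0.1, dt_min = 1e-3,
                       n_particles = 16000, t_end = 1e4,
                       seed = 1, engine = c("adaptive", "fixed"),
                       fixed_dt = 1e-3, interaction_layer = 0.25,
                       grid_resolution = 0.5) {
  engine <- match.arg(engine)
  cfg <- list(width = width, height = height, cell_radius = cell_radius,
              target_fraction = target_fraction,
              particle_radius = particle_radius, rho = rho,
              viscosity = viscosity, temperature = temperature,
              v_in = v_in, epsilon = epsilon, n_collocation = n_collocation,
              dt_max = dt_max, dt_min = dt_min, n_particles = n_particles,
              t_end = t_end, seed = seed, engine = engine,
              fixed_dt = fixed_dt, interaction_layer = interaction_layer,
              grid_resolution = grid_resolution)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A configuration list to validate.
#' @export
validate_run_config <- function(config) {
  chk <- function(cond, msg) if (!cond) stop("invalid config: ", msg,
                                             call. = FALSE)
  chk(config$width > 0 && config$height > 0, "domain extents must be positive")
  chk(config$cell_radius > 0, "cell_radius must be positive")
  chk(config$target_fraction >= 0 && config$target_fraction < 0.55,
      "target_fraction must lie in [0, 0.55) (disc packing jams near 0.55)")
  chk(config$particle_radius > 0, "particle_radius must be positive")
  chk(config$particle_radius < config$cell_radius,
      "particles must be smaller than cells")
  chk(config$rho >= 0 && config$rho <= 1, "rho must lie in [0, 1]")
  chk(config$viscosity > 0, "viscosity must be positive")
  chk(config$temperature > 0, "temperature must be positive")
  chk(config$v_in >= 0, "v_in must be non-negative")
  chk(config$epsilon > 0, "epsilon must be positive")
  chk(config$n_collocation >= 3, "n_collocation too small")
  chk(config$dt_max >= config$dt_min && config$dt_min > 0,
      "need dt_max >= dt_min > 0")
  chk(config$n_particles >= 0, "n_particles must be non-negative")
  chk(config$t_end > 0, "t_end must be positive")
  chk(config$engine %in% c("adaptive", "fixed"), "unknown engine")
  chk(config$fixed_dt > 0, "fixed_dt must be positive")
  chk(config$interaction_layer > 0, "interaction_layer must be positive")
  chk(config$grid_resolution > 0, "grid_resolution must be positive")
  invisible(config)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}

# named child streams off the master seed, kept below 2^31
.child_seed <- function(seed, stream = c("packing", "particles", "fixture")) {
  stream <- match.arg(stream)
  offset <- c(packing = 1, particles = 2, fixture = 3)[[stream]]
  as.integer((as.numeric(seed) * 1000003 + offset * 7919) %% 2147483647)
}

#' Write / read a run configuration
#'
#' Flat key-value (YAML) serialization. Field order is fixed by
#' [run_config()], so write -> read -> write is byte-identical.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a validated `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run a full experiment
#'
#' Pipeline: pack cells, discretize boundaries, solve the Stokeslet system,
#' cache the velocity grid (flow stages are skipped when `v_in = 0`, and
#' replaced by uniform plug flow when the domain is cell-free), simulate the
#' ensemble, and summarize. Stages are logged with timings. When
#' `out_dir` is given, the cell field, boundary forces, flow grid, ensemble
#' table and JSON summary are written there; a rerun with the same
#' configuration reproduces the files byte-for-byte.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param quiet Suppress stage logging.
#' @return A list: `config`, `domain`, `cells`, `disc`, `system`, `grid`
#'   (the flow stages are `NULL` when skipped), `result`, `summary`.
#' @export
run_experiment <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    say("[%s] done in %.2f s", name, proc.time()[["elapsed"]] - t0)
    val
  }
  domain <- domain_spec(config$width, config$height)
  say("[pack] seed %d", .child_seed(config$seed, "packing"))
  cells <- stage("pack",
                 pack_cells(domain, config$cell_radius,
                            config$target_fraction,
                            seed = .child_seed(config$seed, "packing")))
  disc <- sys <- grid <- NULL
  if (config$v_in > 0 && nrow(cells$centers) > 0) {
    disc <- stage("discretize",
                  discretize_boundaries(domain, cells, config$n_collocation,
                                        config$v_in))
    sys <- stage("solve_flow", solve_forces(disc, config$epsilon,
                                            config$viscosity))
    grid <- stage("velocity_grid",
                  build_velocity_grid(sys, domain, config$grid_resolution))
  } else {
    say("[flow] skipped (%s)",
        if (config$v_in == 0) "no advection" else "cell-free plug flow")
  }
  result <- stage("simulate",
                  simulate_ensemble(config, cells = cells, field = grid))
  summary <- ensemble_summary(result)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cell_field(cells, file.path(out_dir, "cells.csv"))
    if (!is.null(sys)) forces_table(sys, file.path(out_dir, "forces.csv"))
    if (!is.null(grid)) flow_field_table(grid, file.path(out_dir, "flow.csv"))
    write_ensemble(result, file.path(out_dir, "ensemble.csv"))
    ensemble_summary(result, path = file.path(out_dir, "summary.json"))
    say("[write] artifacts in %s", out_dir)
  }
  list(config = config, domain = domain, cells = cells, disc = disc,
       system = sys, grid = grid, result = result, summary = summary)
}

#' Small deterministic fixtures
#'
#' Tiny geometries for fast tests and demonstrations: `cell_free` (no
#' cells), `single_cell` (one cell at the domain centre) and `small_tissue`
#' (a 200 x 100 um domain packed to the default 40 % cell fraction).
#'
#' @param kind One of `"cell_free"`, `"single_cell"`, `"small_tissue"`.
#' @param seed Master seed.
#' @return A list with `domain`, `cells` and a matching reduced `config`.
#' @export
make_fixture <- function(kind = c("cell_free", "single_cell", "small_tissue"),
                         seed = 1) {
  kind <- match.arg(kind)
  switch(kind,
    cell_free = {
      domain <- domain_spec(200, 100)
      config <- run_config(width = 200, height = 100, target_fraction = 0,
                           n_collocation = 300, n_particles = 100,
                           t_end = 10, seed = seed)
      list(domain = domain,
           cells = pack_cells(domain, target_fraction = 0),
           config = config)
    },
    single_cell = {
      domain <- domain_spec(100, 100)
      cells <- structure(list(centers = matrix(c(50, 50), 1, 2,
                                               dimnames = list(NULL, c("x", "y"))),
                              cell_radius = 10,
                              achieved_area_fraction = pi * 100 / 1e4,
                              domain = domain),
                         class = "cell_field")
      config <- run_config(width = 100, height = 100,
                           target_fraction = pi * 100 / 1e4,
                           n_collocation = 200, n_particles = 100,
                           t_end = 10, seed = seed)
      list(domain = domain, cells = cells, config = config)
    },
    small_tissue = {
      domain <- domain_spec(200, 100)
      config <- run_config(width = 200, height = 100,
                           n_collocation = 1200, n_particles = 200,
                           t_end = 100, seed = seed)
      list(domain = domain,
           cells = pack_cells(domain, seed = .child_seed(seed, "fixture")),
           config = config)
    })
}
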