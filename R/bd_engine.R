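#' Einstein-Stokes diffusion coefficient
#'
#' `D = kB T / (6 pi mu a)`, evaluated with the CODATA Boltzmann constant and
#' returned in square micrometres per second. Inputs use the package's
#' working units: particle radius in micrometres, temperature in kelvin,
#' viscosity in centipoise (the single unit conversion in the package).
#'
#' @param radius Particle radius in micrometres (100 nm = 0.1).
#' @param temperature Absolute temperature in kelvin.
#' @param viscosity Dynamic viscosity in centipoise.
#' @return Diffusion coefficient in um^2/s.
#' @examples
#' diffusion_coefficient(0.1)   # ~0.9 um^2/s for a 100 nm particle at 310 K
#' @export
diffusion_coefficient <- function(radius, temperature = 310, viscosity = 2.5) {
  if (any(radius <= 0) || any(temperature <= 0) || any(viscosity <= 0))
    stop("radius, temperature and viscosity must be positive")
  # radius um -> m, viscosity cP -> Pa s; result m^2/s -> um^2/s
  .kB * temperature / (6 * pi * (viscosity * 1e-3) * (radius * 1e-6)) * 1e12
}

#' Nanoparticle specification
#'
#' Bundles the particle radius, its Einstein-Stokes diffusion coefficient and
#' the per-contact capture probability. `rho` lumps the adhesion and uptake
#' biophysics (van der Waals, surface charge, corona, receptor binding) into
#' a single Bernoulli probability applied at each particle-cell contact.
#'
#' @param radius Particle radius in micrometres.
#' @param rho Capture probability per cell contact, in `[0, 1]`.
#' @param temperature Kelvin.
#' @param viscosity Centipoise.
#' @return An object of class `particle_spec` with fields `radius`, `D`,
#'   `rho`, `temperature`, `viscosity`.
#' @export
particle_spec <- function(radius = 0.1, rho = 0.01, temperature = 310,
                          viscosity = 2.5) {
  stopifnot(radius > 0, rho >= 0, rho <= 1)
  structure(list(radius = radius,
                 D = diffusion_coefficient(radius, temperature, viscosity),
                 rho = rho, temperature = temperature, viscosity = viscosity),
            class = "particle_spec")
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf("<particle_spec> a = %g um, D = %.4g um^2/s, rho = %g\n",
              x$radius, x$D, x$rho))
  invisible(x)
}

#' Adaptive time-step policy
#'
#' The engine advances particles with steps `dt_max >= dt >= dt_min`. Far
#' from all boundaries it uses `dt_max`; approaching a boundary it solves for
#' an intermediate step sized so the jump cannot cross the nearest boundary;
#' within the near-wall gate (a realized jump shorter than
#' `gate_factor * radius`) it falls back to the constant fine step `dt_min`,
#' at which particle-cell contacts are resolved.
#'
#' @param dt_max Largest permissible step, seconds.
#' @param dt_min Smallest (contact-resolution) step, seconds.
#' @param gate_factor Near-wall gate in units of particle radius.
#' @return An object of class `step_policy`.
#' @export
step_policy <- function(dt_max = 0.1, dt_min = 1e-3, gate_factor = 4) {
  stopifnot(dt_max >= dt_min, dt_min > 0, gate_factor > 0)
  structure(list(dt_max = dt_max, dt_min = dt_min, gate_factor = gate_factor),
            class = "step_policy")
}

#' Mobile particle state
#'
#' @param position Length-2 position (um).
#' @param time Elapsed time (s).
#' @param status One of `"mobile"`, `"captured"`, `"exited_right"`.
#' @param collisions Number of cell-boundary contacts so far.
#' @param capture_cell Index of the capturing cell (`NA` while mobile).
#' @return An object of class `particle_state`.
#' @export
particle_state <- function(position, time = 0, status = "mobile",
                           collisions = 0L, capture_cell = NA_integer_) {
  stopifnot(length(position) == 2,
            status %in% c("mobile", "captured", "exited_right"))
  structure(list(position = as.numeric(position), time = time, status = status,
                 collisions = as.integer(collisions),
                 capture_cell = capture_cell),
            class = "particle_state")
}

#' Propose a Brownian-dynamics jump
#'
#' `S = v dt + sqrt(4 D dt) e`, where `e` is a unit vector with uniformly
#' random orientation. The diffusive magnitude is deterministic; only the
#' direction is random, so `|S| <= |v| dt + sqrt(4 D dt)` always.
#'
#' @param dt Time step, seconds.
#' @param v Local fluid velocity, length 2 (um/s).
#' @param D Diffusion coefficient (um^2/s).
#' @return Displacement vector, length 2 (um). Uses R's RNG.
#' @export
propose_jump <- function(dt, v = c(0, 0), D) {
  stopifnot(dt > 0, length(v) == 2, D >= 0)
  theta <- runif(1, 0, 2 * pi)
  v * dt + sqrt(4 * D * dt) * c(cos(theta), sin(theta))
}

#' Intermediate adaptive time step
#'
#' The unique positive root of `|v| dt + sqrt(4 D dt) = R - a` (a quadratic
#' in `sqrt(dt)`). A jump proposed at this step can never exceed `R - a`, so
#' the particle cannot cross its nearest boundary within the step.
#'
#' @param R Distance from the particle centre to the nearest boundary (um).
#' @param a Particle radius (um).
#' @param speed Local fluid speed `|v|` (um/s).
#' @param D Diffusion coefficient (um^2/s); `speed` and `D` must not both be
#'   zero.
#' @return The step duration in seconds.
#' @export
solve_intermediate_dt <- function(R, a, speed, D) {
  stopifnot(speed >= 0, D >= 0, speed + D > 0)
  gap <- R - a
  if (gap <= 0)
    stop("R <= a: particle already in contact; collision logic must handle this")
  if (speed == 0) return(gap^2 / (4 * D))
  if (D == 0) return(gap / speed)
  s <- sqrt(4 * D)
  u <- (-s + sqrt(s^2 + 4 * speed * gap)) / (2 * speed)
  u^2
}

#' Resolve a particle-cell contact
#'
#' Applied when an attempted fine step terminates within contact distance
#' (one particle radius) of a cell boundary, or inside the cell. With
#' probability `rho` the particle is captured and its centre is projected to
#' the contact point (distance \eqn{r + a} from the cell centre). Otherwise the
#' boundary is treated as a locally flat wall and the penetrating normal
#' component of the move is specularly mirrored; if the mirrored position is
#' itself invalid (outside the domain or in contact with another cell) the
#' move is rejected and the particle stays put. Either way the contact
#' counter is incremented. Uses R's RNG for the capture draw.
#'
#' @param state A [particle_state()] (pre-move position).
#' @param new_position The attempted (penetrating) position, length 2.
#' @param cell_index Index of the contacted cell in `cells`.
#' @param cells A [pack_cells()] result.
#' @param domain A [domain_spec()].
#' @param spec A [particle_spec()].
#' @return The updated `particle_state`.
#' @export
handle_collision <- function(state, new_position, cell_index, cells, domain,
                             spec) {
  stopifnot(inherits(state, "particle_state"), inherits(spec, "particle_spec"))
  centre <- cells$centers[cell_index, ]
  contact <- cells$cell_radius + spec$radius
  d <- new_position - centre
  dist <- sqrt(sum(d^2))
  state$collisions <- state$collisions + 1L
  if (runif(1) < spec$rho) {
    nh <- d / dist
    state$position <- centre + contact * nh
    state$status <- "captured"
    state$capture_cell <- cell_index
    return(state)
  }
  pen <- contact - dist
  refl <- new_position + 2 * pen * d / dist
  ok <- refl[1] >= 0 && refl[1] < domain$width &&
    refl[2] >= 0 && refl[2] <= domain$height
  if (ok && nrow(cells$centers) > 0) {
    dc <- sqrt((cells$centers[, 1] - refl[1])^2 +
                 (cells$centers[, 2] - refl[2])^2) - cells$cell_radius
    ok <- all(dc >= spec$radius)
  }
  if (ok) state$position <- refl   # else: rejected, particle stays
  state
}

# evaluate the fluid velocity for the R-level stepper
.eval_velocity <- function(position, field, velocity) {
  if (is.null(field)) return(velocity)
  as.numeric(grid_velocity_at(field, position))
}

#' Advance a particle by one adaptive Brownian-dynamics step
#'
#' One step of the three-tier rule. (1) Compute the distance `R` to the
#' nearest solid feature and propose a jump at `dt_max`; accept if the jump
#' is shorter than `R - a`. (2) Otherwise solve for the intermediate step
#' whose maximal jump equals `R - a` and accept the proposed jump if its
#' realized length exceeds `gate_factor * a`. (3) Otherwise take a fine step
#' at `dt_min`: accepted if the new position is interstitial, specularly
#' reflected off a domain edge it crosses, and handed to
#' [handle_collision()] if it contacts a cell. The clock always advances by
#' the attempted step duration in tier 3, so elapsed time is well defined
#' even for rejected fine moves. This R implementation mirrors the compiled
#' ensemble engine and exists for step-level testing and illustration; it
#' uses R's RNG.
#'
#' @param state A [particle_state()] with status `"mobile"`.
#' @param spec A [particle_spec()].
#' @param policy A [step_policy()].
#' @param cells A [pack_cells()] result.
#' @param domain A [domain_spec()].
#' @param field Optional [build_velocity_grid()] cache; if `NULL`, the
#'   constant `velocity` is used everywhere.
#' @param velocity Constant fluid velocity used when `field` is `NULL`.
#' @return The updated `particle_state`, with attribute `"tier"` (1, 2 or 3)
#'   recording which tier fired.
#' @export
advance_particle <- function(state, spec, policy, cells, domain,
                             field = NULL, velocity = c(0, 0)) {
  stopifnot(inherits(state, "particle_state"), state$status == "mobile",
            inherits(spec, "particle_spec"), inherits(policy, "step_policy"))
  pos <- state$position
  nb <- nearest_boundary_distance(pos, cells, domain)  # errors if inside a cell
  v <- .eval_velocity(pos, field, velocity)
  a <- spec$radius
  gap <- nb$R - a

  # tier 1
  S <- propose_jump(policy$dt_max, v, spec$D)
  if (sqrt(sum(S^2)) < gap) {
    state$position <- pos + S
    state$time <- state$time + policy$dt_max
    if (state$position[1] >= domain$width) state$status <- "exited_right"
    attr(state, "tier") <- 1L
    return(state)
  }

  # tier 2
  if (gap > 0) {
    dta <- solve_intermediate_dt(nb$R, a, sqrt(sum(v^2)), spec$D)
    S <- propose_jump(dta, v, spec$D)
    if (sqrt(sum(S^2)) > policy$gate_factor * a) {
      state$position <- pos + S
      state$time <- state$time + dta
      if (state$position[1] >= domain$width) state$status <- "exited_right"
      attr(state, "tier") <- 2L
      return(state)
    }
  }

  # tier 3
  S <- propose_jump(policy$dt_min, v, spec$D)
  newp <- pos + S
  state$time <- state$time + policy$dt_min
  attr(state, "tier") <- 3L
  if (newp[1] < 0) newp[1] <- -newp[1]
  if (newp[2] < 0) newp[2] <- -newp[2]
  if (newp[2] > domain$height) newp[2] <- 2 * domain$height - newp[2]
  if (newp[1] >= domain$width) {
    state$position <- c(domain$width, newp[2])
    state$status <- "exited_right"
    return(state)
  }
  if (nrow(cells$centers) > 0) {
    dc <- sqrt((cells$centers[, 1] - newp[1])^2 +
                 (cells$centers[, 2] - newp[2])^2) - cells$cell_radius
    j <- which.min(dc)
    if (dc[j] < a)
      return(handle_collision(state, newp, j, cells, domain, spec))
  }
  state$position <- newp
  state
}

# build the field descriptor handed to the C++ engines
.field_descriptor <- function(field, velocity) {
  if (is.null(field)) list(v = as.numeric(velocity))
  else list(x = field$x, y = field$y, vx = field$vx, vy = field$vy)
}

.ensemble_from_cpp <- function(raw, n, seed, params) {
  m <- raw$result
  status <- factor(c("mobile", "captured", "exited_right")[m[, 3] + 1],
                   levels = c("mobile", "captured", "exited_right"))
  df <- data.frame(id = seq_len(n), x = m[, 1], y = m[, 2], status = status,
                   capture_cell = ifelse(m[, 4] > 0, as.integer(m[, 4]),
                                         NA_integer_),
                   collisions = as.integer(m[, 5]), t_final = m[, 6],
                   y_entry = m[, 7])
  structure(df, class = c("ensemble_result", "data.frame"),
            seed = seed, params = params,
            tier_counts = if (!is.null(raw$tier_counts))
              setNames(raw$tier_counts, c("dt_max", "dt_adaptive", "dt_min")),
            rejected_moves = raw$rejected)
}

#' Simulate an ensemble of independent nanoparticles
#'
#' Runs `n_particles` mutually non-interacting particles with the three-tier
#' adaptive engine. Each particle enters at `t = 0` at a uniformly random
#' point on the inlet edge and is advanced until the horizon `t_end`, its
#' capture by a cell, or its exit through the open right edge (which is
#' reported with a warning, since it indicates the domain is too shallow for
#' the horizon). Per-particle RNG streams are derived from the master seed,
#' so results are reproducible and independent of particle order.
#'
#' @param config A [run_config()]; its geometry/particle/policy fields define
#'   the run.
#' @param cells Optional pre-packed [pack_cells()] result (otherwise packed
#'   from the config with the config's packing seed).
#' @param field Optional pre-built [build_velocity_grid()]. If omitted:
#'   zero-velocity transport when `v_in = 0`; uniform plug flow `(v_in, 0)`
#'   when the domain is cell-free; otherwise the full Stokeslet solve is
#'   performed.
#' @param engine `"adaptive"` (default) or `"fixed"` (see
#'   [simulate_fixed_step()]).
#' @return An `ensemble_result`: a data frame with one row per particle
#'   (`id`, `x`, `y`, `status`, `capture_cell`, `collisions`, `t_final`,
#'   `y_entry`) and attributes `seed`, `params`, `tier_counts` (how often
#'   each tier fired) and `rejected_moves`.
#' @export
simulate_ensemble <- function(config, cells = NULL, field = NULL,
                              engine = config$engine) {
  stopifnot(inherits(config, "run_config"))
  domain <- domain_spec(config$width, config$height)
  if (is.null(cells))
    cells <- pack_cells(domain, config$cell_radius, config$target_fraction,
                        seed = .child_seed(config$seed, "packing"))
  if (engine == "fixed")
    return(simulate_fixed_step(config, config$fixed_dt,
                               config$interaction_layer, config$rho,
                               cells = cells, field = field))
  spec <- particle_spec(config$particle_radius, config$rho,
                        config$temperature, config$viscosity)
  fd <- .resolve_field(config, domain, cells, field)
  if (config$n_particles == 0)
    return(.ensemble_from_cpp(list(result = matrix(numeric(0), 0, 7),
                                   tier_counts = c(0, 0, 0), rejected = 0),
                              0L, config$seed, .param_snapshot(config, spec)))
  raw <- cpp_simulate_adaptive(config$n_particles, config$t_end,
                               .child_seed(config$seed, "particles"),
                               domain$width, domain$height,
                               cells$centers, cells$cell_radius,
                               spec$radius, spec$D, spec$rho,
                               config$dt_max, config$dt_min, fd)
  res <- .ensemble_from_cpp(raw, config$n_particles, config$seed,
                            .param_snapshot(config, spec))
  .warn_exits(res)
  res
}

#' Simulate with the fixed-step comparison engine
#'
#' Non-adaptive reference engine: a constant time step, rejection of any move
#' that would overlap a cell interior, and capture attempted (with
#' probability `rho` per step) while the particle sits within a thin
#' interaction layer around a cell periphery. Unlike its point-particle
#' ancestors, particles are finite circles of radius `a`. Because capture
#' requires landing the fixed-length jump inside the thin layer, this engine
#' underestimates capture - and so overestimates penetration depth - as the
#' step grows or the layer shrinks.
#'
#' @param config A [run_config()].
#' @param dt Fixed step duration, seconds.
#' @param layer Interaction-layer thickness around each cell, micrometres.
#' @param rho Capture probability per step spent inside the layer.
#' @inheritParams simulate_ensemble
#' @return An `ensemble_result` (without tier counts).
#' @export
simulate_fixed_step <- function(config, dt = config$fixed_dt,
                                layer = config$interaction_layer,
                                rho = config$rho,
                                cells = NULL, field = NULL) {
  stopifnot(inherits(config, "run_config"), dt > 0, layer > 0)
  domain <- domain_spec(config$width, config$height)
  if (is.null(cells))
    cells <- pack_cells(domain, config$cell_radius, config$target_fraction,
                        seed = .child_seed(config$seed, "packing"))
  spec <- particle_spec(config$particle_radius, rho,
                        config$temperature, config$viscosity)
  fd <- .resolve_field(config, domain, cells, field)
  raw <- cpp_simulate_fixed(config$n_particles, config$t_end,
                            .child_seed(config$seed, "particles"),
                            domain$width, domain$height,
                            cells$centers, cells$cell_radius,
                            spec$radius, spec$D, rho, dt, layer, fd)
  params <- .param_snapshot(config, spec)
  params$engine <- "fixed"
  params$fixed_dt <- dt
  params$interaction_layer <- layer
  res <- .ensemble_from_cpp(raw, config$n_particles, config$seed, params)
  .warn_exits(res)
  res
}

.resolve_field <- function(config, domain, cells, field) {
  if (!is.null(field)) return(.field_descriptor(field, NULL))
  if (config$v_in == 0) return(list(v = c(0, 0)))
  if (nrow(cells$centers) == 0) return(list(v = c(config$v_in, 0)))
  disc <- discretize_boundaries(domain, cells, config$n_collocation,
                                config$v_in)
  sys <- solve_forces(disc, config$epsilon, config$viscosity)
  grid <- build_velocity_grid(sys, domain, config$grid_resolution)
  .field_descriptor(grid, NULL)
}

.param_snapshot <- function(config, spec) {
  c(unclass(config), list(D = spec$D))
}

.warn_exits <- function(res) {
  n_exit <- sum(res$status == "exited_right")
  if (n_exit > 0)
    warning(sprintf(paste0("%d particle(s) reached the open right edge; ",
                           "the domain width is too small for this horizon"),
                    n_exit), call. = FALSE)
  invisible(res)
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %d particles: %d mobile, %d captured, %d exited\n",
              nrow(x), sum(x$status == "mobile"), sum(x$status == "captured"),
              sum(x$status == "exited_right")))
  if (nrow(x) > 0)
    cat(sprintf("  mean penetration depth %.2f um; mean collisions %.1f\n",
                mean(x$x), mean(x$collisions)))
  invisible(x)
}

#' Record a single adaptive trajectory
#'
#' Runs one particle of an ensemble with full position recording, for
#' inspection, plotting and trajectory-level invariant checks.
#'
#' @param config A [run_config()].
#' @param particle Index (1-based) of the particle whose path to record; the
#'   RNG stream matches that particle in [simulate_ensemble()].
#' @inheritParams simulate_ensemble
#' @return A data frame `x`, `y`, `t`, `tier` (0 marks the entry point) of
#'   every accepted (or tier-3 attempted) position.
#' @export
simulate_trajectory <- function(config, particle = 1, cells = NULL,
                                field = NULL) {
  stopifnot(inherits(config, "run_config"), particle >= 1)
  domain <- domain_spec(config$width, config$height)
  if (is.null(cells))
    cells <- pack_cells(domain, config$cell_radius, config$target_fraction,
                        seed = .child_seed(config$seed, "packing"))
  spec <- particle_spec(config$particle_radius, config$rho,
                        config$temperature, config$viscosity)
  fd <- .resolve_field(config, domain, cells, field)
  raw <- cpp_simulate_adaptive(as.integer(particle), config$t_end,
                               .child_seed(config$seed, "particles"),
                               domain$width, domain$height,
                               cells$centers, cells$cell_radius,
                               spec$radius, spec$D, spec$rho,
                               config$dt_max, config$dt_min, fd,
                               record_id = as.integer(particle) - 1L)
  tr <- raw$trajectory
  data.frame(x = tr[, 1], y = tr[, 2], t = tr[, 3], tier = as.integer(tr[, 4]))
}
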