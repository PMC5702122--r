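test_that("Einstein-Stokes diffusion coefficient and its scalings", {
  # independent hand evaluation: kB T / (6 pi mu a), SI, then m^2/s -> um^2/s
  D_ref <- 1.380649e-23 * 310 / (6 * pi * 2.5e-3 * 1e-7) * 1e12
  expect_equal(diffusion_coefficient(0.1, 310, 2.5), D_ref, tolerance = 1e-12)
  expect_equal(D_ref, 0.908, tolerance = 5e-3)
  expect_equal(diffusion_coefficient(0.01) / diffusion_coefficient(0.1), 10)
  expect_equal(diffusion_coefficient(0.1, viscosity = 5),
               diffusion_coefficient(0.1, viscosity = 2.5) / 2)
  expect_error(diffusion_coefficient(0), "positive")
  expect_error(diffusion_coefficient(0.1, temperature = -1), "positive")
})

test_that("proposed jumps have fixed diffusive magnitude and random direction", {
  set.seed(8)
  # degenerate diffusion: pure advection
  expect_equal(propose_jump(0.5, v = c(2, -1), D = 0), c(1, -0.5))
  # v = 0: magnitude is exactly sqrt(4 D dt) every draw; direction is uniform
  D <- 0.9; dt <- 0.1
  S <- t(replicate(2000, propose_jump(dt, c(0, 0), D)))
  expect_equal(sqrt(rowSums(S^2)), rep(sqrt(4 * D * dt), 2000),
               tolerance = 1e-12)
  se <- sqrt(4 * D * dt / 2) / sqrt(2000)  # per-component sd of the step
  expect_lt(abs(mean(S[, 1])), 3 * se)
  expect_lt(abs(mean(S[, 2])), 3 * se)
  # triangle bound with drift
  S <- t(replicate(500, propose_jump(dt, c(1, 1), D)))
  expect_true(all(sqrt(rowSums(S^2)) <=
                    sqrt(2) * dt + sqrt(4 * D * dt) + 1e-12))
})

test_that("intermediate step solves |v| dt + sqrt(4 D dt) = R - a", {
  expect_equal(solve_intermediate_dt(5, 0.1, 0, 0.9), 4.9^2 / (4 * 0.9))
  expect_equal(solve_intermediate_dt(5, 0.1, 2, 0), 4.9 / 2)
  for (case in list(c(5, 0.1, 1, 0.9), c(0.7, 0.1, 0.3, 9), c(2, 0.01, 4, 0.1))) {
    dt <- solve_intermediate_dt(case[1], case[2], case[3], case[4])
    resid <- case[3] * dt + sqrt(4 * case[4] * dt) - (case[1] - case[2])
    expect_equal(resid, 0, tolerance = 1e-12)
  }
  expect_error(solve_intermediate_dt(0.05, 0.1, 1, 0.9), "collision")
})

test_that("the three tiers fire according to the distance to the boundary", {
  dom <- domain_spec(200, 100)
  cf <- single_cell_field(dom, c(100, 50))
  spec <- particle_spec(0.1, rho = 0)
  pol <- step_policy()
  set.seed(2)
  # far from everything: the bound |v| dt + sqrt(4 D dt) < R - a forces tier 1
  st <- advance_particle(particle_state(c(50, 25)), spec, pol, cf, dom)
  expect_identical(attr(st, "tier"), 1L)
  expect_equal(st$time, pol$dt_max)
  expect_identical(st$status, "mobile")
  # gap below the 4a gate with v = 0: tier-2 jump equals the gap, so tier 3
  start <- c(100 - 10 - 0.1 - 0.3, 50)  # 0.3 um clearance < 4a = 0.4
  st <- advance_particle(particle_state(start), spec, pol, cf, dom)
  expect_identical(attr(st, "tier"), 3L)
  expect_equal(st$time, pol$dt_min)
  # intermediate gap: tier 2 accepts with a jump of exactly R - a
  start <- c(100 - 10 - 0.1 - 2, 50)  # 2 um clearance, < tier-1 bound ~0.7+...
  st <- advance_particle(particle_state(start), spec, pol, cf, dom)
  if (attr(st, "tier") == 2L) {
    jump <- sqrt(sum((st$position - start)^2))
    expect_equal(jump, 2, tolerance = 1e-10)
  }
})

test_that("collision handling is specular with the geometric capture law", {
  dom <- domain_spec(200, 100)
  cf <- single_cell_field(dom, c(100, 50))
  spec <- particle_spec(0.1, rho = 0)
  # head-on approach ending 0.05 um past the contact plane
  st <- particle_state(c(89.5, 50))
  newp <- c(100 - 10 - 0.1 + 0.05, 50)
  out <- handle_collision(st, newp, 1L, cf, dom, spec)
  expect_identical(out$status, "mobile")
  expect_identical(out$collisions, 1L)
  # post-reflection clearance from the contact plane equals the penetration
  d_after <- sqrt(sum((out$position - c(100, 50))^2)) - 10.1
  expect_equal(d_after, 0.05, tolerance = 1e-12)
  # capture with certainty at rho = 1 lands the centre on the contact circle
  spec1 <- particle_spec(0.1, rho = 1)
  out <- handle_collision(st, newp, 1L, cf, dom, spec1)
  expect_identical(out$status, "captured")
  expect_identical(out$capture_cell, 1L)
  expect_equal(sqrt(sum((out$position - c(100, 50))^2)), 10.1,
               tolerance = 1e-12)
})

test_that("contacts before capture follow the geometric 1/rho law", {
  # micro-benchmark: one cell in a small box, moderate rho, long horizon
  dom <- domain_spec(40, 40)
  cf <- single_cell_field(dom, c(20, 20))
  rho <- 0.2
  cfg <- run_config(width = 40, height = 40, rho = rho, v_in = 0,
                    n_particles = 400, t_end = 2000, seed = 6)
  res <- suppressWarnings(simulate_ensemble(cfg, cells = cf))
  cap <- res$status == "captured"
  expect_gt(mean(cap), 0.95)
  m <- mean(res$collisions[cap])
  se <- sqrt((1 - rho) / rho^2) / sqrt(sum(cap))
  expect_lt(abs(m - 1 / rho), 3 * se)
})

test_that("rho = 1 captures on first contact; rho = 0 never captures", {
  dom <- domain_spec(60, 60)
  cf <- single_cell_field(dom, c(30, 30))
  cfg <- run_config(width = 60, height = 60, rho = 1, v_in = 0,
                    n_particles = 200, t_end = 1000, seed = 9)
  res <- suppressWarnings(simulate_ensemble(cfg, cells = cf))
  cap <- res$status == "captured"
  expect_gt(sum(cap), 50)
  expect_true(all(res$collisions[cap] == 1L))
  # captured centres sit on the contact circle (cell radius + particle radius)
  dcap <- sqrt((res$x[cap] - 30)^2 + (res$y[cap] - 30)^2)
  expect_equal(dcap, rep(10.1, sum(cap)), tolerance = 1e-9)
  cfg0 <- run_config(width = 60, height = 60, rho = 0, v_in = 0,
                     n_particles = 200, t_end = 1000, seed = 9)
  res0 <- suppressWarnings(simulate_ensemble(cfg0, cells = cf))
  expect_identical(sum(res0$status == "captured"), 0L)
  expect_gt(mean(res0$collisions), 0)  # they do collide, they just survive
})

test_that("trajectories never interpenetrate cells or leave the domain", {
  fx <- make_fixture("small_tissue", seed = 4)
  cfg <- fx$config
  cfg$v_in <- 0; cfg$t_end <- 100; cfg$rho <- 0; cfg$n_particles <- 40
  res <- simulate_ensemble(cfg, cells = fx$cells)
  # follow a particle that actually collided with cells
  id <- res$id[which.max(res$collisions)]
  expect_gt(res$collisions[id], 0)
  tr <- simulate_trajectory(cfg, particle = id, cells = fx$cells)
  expect_gt(nrow(tr), 100)
  clear <- vapply(seq_len(nrow(tr)), function(i) {
    min(sqrt((fx$cells$centers[, 1] - tr$x[i])^2 +
               (fx$cells$centers[, 2] - tr$y[i])^2)) - fx$cells$cell_radius
  }, numeric(1))
  expect_gte(min(clear), cfg$particle_radius)
  expect_true(all(tr$x >= 0 & tr$x <= 200 & tr$y >= 0 & tr$y <= 100))
  # the recorded endpoint matches the ensemble row for the same stream
  expect_equal(unlist(tr[nrow(tr), c("x", "y")], use.names = FALSE),
               c(res$x[id], res$y[id]))
})

test_that("ensembles are reproducible and particle streams independent", {
  cfg <- run_config(width = 200, height = 100, target_fraction = 0,
                    v_in = 0.5, n_particles = 30, t_end = 20, seed = 14)
  r1 <- simulate_ensemble(cfg)
  r2 <- simulate_ensemble(cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # the first k particles of a larger run equal a smaller run exactly
  cfg_small <- cfg; cfg_small$n_particles <- 10
  r3 <- simulate_ensemble(cfg_small)
  expect_equal(as.data.frame(r1)[1:10, ], as.data.frame(r3),
               ignore_attr = TRUE)
  # n = 0 gives an empty result
  cfg0 <- cfg; cfg0$n_particles <- 0
  expect_identical(nrow(simulate_ensemble(cfg0)), 0L)
})

test_that("particles reaching the open right edge are reported", {
  cfg <- run_config(width = 30, height = 100, target_fraction = 0,
                    v_in = 2, n_particles = 50, t_end = 100, seed = 2)
  expect_warning(res <- simulate_ensemble(cfg), "right edge")
  exited <- res$status == "exited_right"
  expect_gt(sum(exited), 40)
  expect_true(all(res$x[exited] == 30))
  expect_true(all(res$t_final[exited] < 100))
})

test_that("fixed-step engine matches the adaptive engine when capture is off", {
  fx <- make_fixture("small_tissue", seed = 4)
  cfg <- fx$config
  cfg$v_in <- 0; cfg$rho <- 0; cfg$n_particles <- 800; cfg$t_end <- 200
  ra <- simulate_ensemble(cfg, cells = fx$cells)
  rf <- simulate_fixed_step(cfg, dt = 1e-3, layer = 0.25, rho = 0,
                            cells = fx$cells)
  expect_identical(sum(rf$status == "captured"), 0L)
  ma <- mean_penetration_depth(ra); mf <- mean_penetration_depth(rf)
  expect_lt(abs(ma$mean - mf$mean), 3 * sqrt(ma$se^2 + mf$se^2))
})
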