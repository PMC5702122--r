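test_that("blob kernel has the closed-form peak and unit mass", {
  expect_equal(blob(0, 0.5), 8 / pi, tolerance = 1e-14)
  # unit mass over the plane, by radial quadrature
  for (eps in c(0.1, 0.5, 2)) {
    m <- integrate(function(r) 2 * pi * r * blob(r, eps), 0, Inf,
                   rel.tol = 1e-12)
    expect_equal(m$value, 1, tolerance = 1e-10)
  }
  # monotone decreasing in r
  r <- seq(0, 10, by = 0.1)
  expect_true(all(diff(blob(r, 0.5)) < 0))
  expect_error(blob(1, 0), "positive")
  expect_error(blob(-1, 0.5), "non-negative")
})

test_that("stokeslet kernel is finite at the force point and translation invariant", {
  f <- c(1.3, -0.7); eps <- 0.5; mu <- 2.5
  # self-velocity: the quadratic term vanishes, leaving -f/(8 pi mu)(ln eps^2 - 2)
  u0 <- stokeslet_velocity(f, c(3, 4), c(3, 4), eps, mu)
  expect_equal(u0, -f / (8 * pi * mu) * (log(eps^2) - 2), tolerance = 1e-14)
  # numerical limit from a shrinking offset agrees
  u_near <- stokeslet_velocity(f, c(3 + 1e-7, 4), c(3, 4), eps, mu)
  expect_equal(u_near, u0, tolerance = 1e-8)
  # depends on x only through x - x_k
  shift <- c(17.3, -6.1)
  expect_equal(stokeslet_velocity(f, c(1, 2), c(5, -3), eps, mu),
               stokeslet_velocity(f, c(1, 2) + shift, c(5, -3) + shift, eps, mu),
               tolerance = 1e-14)
  expect_equal(stokeslet_velocity(c(0, 0), c(1, 2), c(5, -3), eps, mu), c(0, 0))
})

test_that("kernel approaches the classical 2D Stokeslet as eps shrinks", {
  f <- c(1, 0.5); mu <- 2.5
  x <- c(10, 3); xk <- c(2, 1)
  d <- x - xk; r2 <- sum(d^2)
  classical <- -f / (8 * pi * mu) * log(r2) + sum(f * d) * d / (4 * pi * mu * r2)
  errs <- vapply(c(1, 0.5, 0.1, 0.01), function(eps) {
    max(abs(stokeslet_velocity(f, x, xk, eps, mu) - classical))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[4], 1e-5)
})

test_that("force solve reproduces every boundary condition", {
  dom <- domain_spec(200, 100)
  cf <- pack_cells(dom, seed = 4)
  disc <- discretize_boundaries(dom, cf, n_points = 800, v_in = 1)
  sys <- solve_forces(disc)
  expect_identical(nrow(sys$forces), disc$n_points)
  v <- velocity_at(sys, disc$points)
  expect_lt(max(abs(v - disc$velocities)) / max(abs(disc$velocities)), 1e-6)
  # inlet points move at (v_in, 0); no-slip points are at rest
  inlet <- disc$segment == "omega1"
  expect_equal(v[inlet, 1], rep(1, sum(inlet)), tolerance = 1e-8)
  expect_lt(max(abs(v[!inlet, ])), 1e-8)
})

test_that("homogeneous boundary conditions give zero forces", {
  dom <- domain_spec(200, 100)
  cf <- pack_cells(dom, target_fraction = 0)
  disc <- discretize_boundaries(dom, cf, n_points = 200, v_in = 0)
  sys <- solve_forces(disc)
  expect_equal(max(abs(sys$forces)), 0, tolerance = 1e-12)
  expect_identical(sys$relative_residual, 0)
})

test_that("forces scale linearly with the prescribed velocities", {
  dom <- domain_spec(200, 100)
  cf <- pack_cells(dom, seed = 4)
  f1 <- solve_forces(discretize_boundaries(dom, cf, 500, v_in = 1))$forces
  f2 <- solve_forces(discretize_boundaries(dom, cf, 500, v_in = 2))$forces
  expect_equal(f2, 2 * f1, tolerance = 1e-8)
})

test_that("coincident collocation points are reported as ill-conditioned", {
  dom <- domain_spec(200, 100)
  cf <- pack_cells(dom, target_fraction = 0)
  disc <- discretize_boundaries(dom, cf, 100, v_in = 1)
  disc$points[2, ] <- disc$points[1, ]  # exact duplicate -> singular matrix
  expect_error(solve_forces(disc), "could not be solved")
})

test_that("cell-free channel flow conserves flux and develops a no-slip profile", {
  dom <- domain_spec(200, 100)
  cf <- pack_cells(dom, target_fraction = 0)
  sys <- solve_forces(discretize_boundaries(dom, cf, 800, v_in = 1))
  # cross-section flux equals the inlet flux (v_in x height) within 1 %
  for (x0 in c(50, 100, 150)) {
    ys <- seq(0.25, 99.75, by = 0.5)
    v <- velocity_at(sys, cbind(x0, ys))
    expect_equal(sum(v[, 1]) * 0.5, 100, tolerance = 0.01)
    expect_lt(max(abs(v[, 2])), 0.05)  # essentially unidirectional
  }
  # no-slip walls push the centreline above the mean speed
  vc <- velocity_at(sys, c(100, 50))
  expect_gt(vc[1], 1)
  expect_lt(vc[1], 2)
})

test_that("interior velocities self-converge under collocation refinement", {
  dom <- domain_spec(200, 100)
  cf <- pack_cells(dom, target_fraction = 0)
  probe <- matrix(c(50, 50, 100, 30, 150, 70), 3, 2, byrow = TRUE)
  vs <- lapply(c(200, 400, 800, 1600), function(N) {
    velocity_at(solve_forces(discretize_boundaries(dom, cf, N, 1)), probe)
  })
  deltas <- vapply(2:4, function(i) max(abs(vs[[i]] - vs[[i - 1]])), numeric(1))
  expect_true(all(diff(deltas) < 0))
})

test_that("velocity grid matches exact evaluation and flags in-cell queries", {
  b <- tissue_bench()
  fine <- build_velocity_grid(b$system, b$domain, resolution = 0.5)
  # node queries reproduce the cached values exactly
  node <- c(fine$x[101], fine$y[51])
  expect_equal(as.numeric(grid_velocity_at(fine, node)),
               c(fine$vx[101, 51], fine$vy[101, 51]), tolerance = 1e-12)
  expect_equal(as.numeric(grid_velocity_at(fine, node)),
               as.numeric(velocity_at(b$system, node)), tolerance = 1e-12)
  # random bulk points (>= 2 um from any boundary): within 2 % of v_in
  set.seed(31)
  pts <- NULL
  while (is.null(pts) || nrow(pts) < 100) {
    p <- cbind(runif(400, 2, 998), runif(400, 2, 298))
    clear <- vapply(seq_len(400), function(i) {
      min(sqrt((b$cells$centers[, 1] - p[i, 1])^2 +
                 (b$cells$centers[, 2] - p[i, 2])^2)) - 10
    }, numeric(1))
    pts <- rbind(pts, p[clear > 2, , drop = FALSE])
  }
  pts <- pts[1:100, ]
  exact <- velocity_at(b$system, pts)
  err_fine <- max(abs(grid_velocity_at(fine, pts) - exact))
  expect_lt(err_fine, 0.02 * 1)
  # refining the resolution 2x reduces the worst interpolation error
  err_coarse <- max(abs(grid_velocity_at(b$grid, pts) - exact))
  expect_lt(err_fine, err_coarse)
  # queries inside a cell are flagged invalid
  inside <- b$cells$centers[1, ]
  expect_true(all(is.na(grid_velocity_at(fine, inside, cells = b$cells))))
})
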