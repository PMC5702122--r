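#' Regularized blob (cutoff) function
#'
#' The radially symmetric smoothing kernel used to regularize a point force,
#' `phi_eps(r) = 2 eps^4 / (pi (r^2 + eps^2)^3)`. It is maximal at \eqn{r = 0},
#' strictly positive, and integrates to 1 over the plane, so the regularized
#' force tends to the point force as `eps -> 0`.
#'
#' @param r Distance(s) from the force location (micrometres), `>= 0`.
#' @param eps Blob radius (micrometres), `> 0`.
#' @return Kernel density value(s), units 1/um^2.
#' @examples
#' blob(0, 0.5)            # 8/pi
#' integrate(function(r) 2 * pi * r * blob(r, 0.5), 0, Inf)$value  # 1
#' @export
blob <- function(r, eps) {
  if (length(eps) != 1 || eps <= 0) stop("eps must be a single positive value")
  if (any(r < 0)) stop("r must be non-negative")
  2 * eps^4 / (pi * (r^2 + eps^2)^3)
}

#' Velocity from a single regularized Stokeslet
#'
#' Closed-form Stokes velocity at `x` induced by a point force `f` at `x_k`
#' regularized with the quartic blob: with \eqn{r = |x - x_k|},
#' \deqn{u(x) = -\frac{f}{8\pi\mu}\Big(\ln(r^2+\epsilon^2) -
#'   \frac{2\epsilon^2}{r^2+\epsilon^2}\Big) +
#'   \frac{(f \cdot (x-x_k))(x-x_k)}{4\pi\mu\,(r^2+\epsilon^2)}}
#' The expression is finite at `x = x_k` (value `-f/(8 pi mu) (ln eps^2 - 2)`),
#' which is the point of the regularization.
#'
#' @param f Force vector, length 2 (model force units; forces solved by
#'   [solve_forces()] are consistent with velocities in um/s).
#' @param x Evaluation position, length 2 (um).
#' @param x_k Force location, length 2 (um).
#' @param eps Blob radius (um), `> 0`.
#' @param mu Dynamic viscosity in centipoise.
#' @return Velocity vector, length 2 (um/s).
#' @export
stokeslet_velocity <- function(f, x, x_k, eps, mu) {
  stopifnot(length(f) == 2, length(x) == 2, length(x_k) == 2,
            eps > 0, mu > 0)
  d <- x - x_k
  s <- sum(d^2) + eps^2
  A <- -(log(s) - 2 * eps^2 / s) / (8 * pi * mu)
  B <- sum(f * d) / (4 * pi * mu * s)
  f * A + d * B
}

#' Solve for boundary point forces
#'
#' Assembles the dense 2N x 2N collocation matrix whose blocks are the
#' regularized-Stokeslet kernel evaluated between all pairs of collocation
#' points and solves (dense LU) for the point forces that reproduce the
#' prescribed boundary velocities at every collocation point. The solution
#' makes the superposed velocity satisfy the no-slip and inlet boundary
#' conditions exactly up to the linear-solver residual.
#'
#' @param disc A [discretize_boundaries()] result.
#' @param eps Blob radius in micrometres (default 0.5).
#' @param mu Fluid viscosity in centipoise (default 2.5).
#' @return An object of class `stokeslet_system`: `disc`, `forces` (N x 2),
#'   `eps`, `mu`, `residual` (max absolute BC residual, um/s) and
#'   `relative_residual` (residual / max prescribed speed; 0 when all
#'   prescribed velocities vanish).
#' @export
solve_forces <- function(disc, eps = 0.5, mu = 2.5) {
  stopifnot(inherits(disc, "boundary_disc"), eps > 0, mu > 0)
  P <- disc$points
  n <- nrow(P)
  dx <- outer(P[, 1], P[, 1], "-")
  dy <- outer(P[, 2], P[, 2], "-")
  s <- dx^2 + dy^2 + eps^2
  t1 <- -(log(s) - 2 * eps^2 / s) / (8 * pi * mu)
  t2 <- 1 / (4 * pi * mu * s)
  Axx <- t1 + t2 * dx * dx
  Axy <- t2 * dx * dy
  Ayy <- t1 + t2 * dy * dy
  A <- rbind(cbind(Axx, Axy), cbind(Axy, Ayy))
  b <- c(disc$velocities[, 1], disc$velocities[, 2])
  F <- tryCatch(solve(A, b), error = function(e) {
    stop(sprintf(paste0("MRS collocation matrix could not be solved (%s); ",
                        "reciprocal condition estimate %.3g. Coincident ",
                        "collocation points are the usual cause."),
                 conditionMessage(e), rcond(A)))
  })
  res <- max(abs(A %*% F - b))
  umax <- max(abs(b))
  forces <- cbind(F[seq_len(n)], F[n + seq_len(n)])
  colnames(forces) <- c("fx", "fy")
  structure(list(disc = disc, forces = forces, eps = eps, mu = mu,
                 residual = res,
                 relative_residual = if (umax > 0) res / umax else 0),
            class = "stokeslet_system")
}

#' @export
print.stokeslet_system <- function(x, ...) {
  cat(sprintf("<stokeslet_system> N = %d forces (eps = %g um, mu = %g cP), BC residual %.2e\n",
              nrow(x$forces), x$eps, x$mu, x$residual))
  invisible(x)
}

#' Evaluate the interstitial velocity field
#'
#' Linear superposition of all N regularized-Stokeslet contributions at one
#' or more positions. Smooth everywhere (including at the collocation
#' points).
#'
#' @param system A [solve_forces()] result.
#' @param x A position (length 2) or an m x 2 matrix of positions (um).
#' @return An m x 2 matrix of velocities (um/s); a length-2 vector if `x`
#'   was a single position.
#' @export
velocity_at <- function(system, x) {
  stopifnot(inherits(system, "stokeslet_system"))
  single <- is.null(dim(x))
  q <- if (single) matrix(x, 1, 2) else as.matrix(x)
  stopifnot(ncol(q) == 2)
  v <- cpp_velocity_eval(system$disc$points, system$forces, system$eps,
                         system$mu, q)
  colnames(v) <- c("vx", "vy")
  if (single) drop(v) else v
}

#' Precompute the velocity field on a regular grid
#'
#' The cells are stationary, so the flow field is static; evaluating the full
#' N-term superposition at every Brownian-dynamics step would dominate the
#' run time. This caches exact velocities at the nodes of a regular grid over
#' the whole rectangle and serves queries by bilinear interpolation. Exact
#' evaluation remains available through [velocity_at()].
#'
#' @param system A [solve_forces()] result.
#' @param domain A [domain_spec()].
#' @param resolution Target grid spacing in micrometres (actual spacing is
#'   rounded down so nodes span the domain exactly).
#' @return An object of class `velocity_grid`: node coordinates `x`, `y` and
#'   node velocity matrices `vx`, `vy` (length(x) rows by length(y) columns).
#' @export
build_velocity_grid <- function(system, domain, resolution = 2) {
  stopifnot(inherits(system, "stokeslet_system"),
            inherits(domain, "domain_spec"), resolution > 0)
  xs <- seq(0, domain$width, length.out = max(2, ceiling(domain$width / resolution) + 1))
  ys <- seq(0, domain$height, length.out = max(2, ceiling(domain$height / resolution) + 1))
  nodes <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  v <- cpp_velocity_eval(system$disc$points, system$forces, system$eps,
                         system$mu, nodes)
  structure(list(x = xs, y = ys,
                 vx = matrix(v[, 1], length(xs), length(ys)),
                 vy = matrix(v[, 2], length(xs), length(ys)),
                 resolution = c(xs[2] - xs[1], ys[2] - ys[1])),
            class = "velocity_grid")
}

#' @export
print.velocity_grid <- function(x, ...) {
  cat(sprintf("<velocity_grid> %d x %d nodes, spacing %.3g x %.3g um\n",
              length(x$x), length(x$y), x$resolution[1], x$resolution[2]))
  invisible(x)
}

#' Query a cached velocity grid
#'
#' Bilinear interpolation of the cached node velocities. Queries that fall
#' inside a cell disc are not fluid positions; when `cells` is supplied such
#' rows are returned as `NA`.
#'
#' @param grid A [build_velocity_grid()] result.
#' @param x A position (length 2) or an m x 2 matrix of positions.
#' @param cells Optional [pack_cells()] result used to flag in-cell queries.
#' @return Velocities as in [velocity_at()]; `NA` rows for in-cell queries.
#' @export
grid_velocity_at <- function(grid, x, cells = NULL) {
  stopifnot(inherits(grid, "velocity_grid"))
  single <- is.null(dim(x))
  q <- if (single) matrix(x, 1, 2) else as.matrix(x)
  fx <- (q[, 1] - grid$x[1]) / grid$resolution[1]
  fy <- (q[, 2] - grid$y[1]) / grid$resolution[2]
  fx <- pmin(pmax(fx, 0), length(grid$x) - 1)
  fy <- pmin(pmax(fy, 0), length(grid$y) - 1)
  ix <- pmin(floor(fx), length(grid$x) - 2) + 1
  iy <- pmin(floor(fy), length(grid$y) - 2) + 1
  tx <- fx - (ix - 1); ty <- fy - (iy - 1)
  bil <- function(M) {
    (1 - tx) * (1 - ty) * M[cbind(ix, iy)] +
      tx * (1 - ty) * M[cbind(ix + 1, iy)] +
      (1 - tx) * ty * M[cbind(ix, iy + 1)] +
      tx * ty * M[cbind(ix + 1, iy + 1)]
  }
  v <- cbind(vx = bil(grid$vx), vy = bil(grid$vy))
  if (!is.null(cells) && nrow(cells$centers) > 0) {
    inside <- vapply(seq_len(nrow(q)), function(i) {
      any((cells$centers[, 1] - q[i, 1])^2 +
            (cells$centers[, 2] - q[i, 2])^2 < cells$cell_radius^2)
    }, logical(1))
    v[inside, ] <- NA_real_
  }
  if (single) drop(v) else v
}

#' Export the flow field and boundary forces as tables
#'
#' `flow_field_table` returns (and optionally writes) the cached grid as a
#' long table of `(x, y, vx, vy)`; `forces_table` returns the collocation
#' points with their solved forces, suitable for quiver-style plots.
#'
#' @param grid A [build_velocity_grid()] result.
#' @param system A [solve_forces()] result.
#' @param path Optional CSV output path.
#' @return A data frame (invisibly written to `path` when given).
#' @export
flow_field_table <- function(grid, path = NULL) {
  stopifnot(inherits(grid, "velocity_grid"))
  df <- data.frame(x = rep(grid$x, times = length(grid$y)),
                   y = rep(grid$y, each = length(grid$x)),
                   vx = as.vector(grid$vx), vy = as.vector(grid$vy))
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}

#' @rdname flow_field_table
#' @export
forces_table <- function(system, path = NULL) {
  stopifnot(inherits(system, "stokeslet_system"))
  df <- data.frame(x = system$disc$points[, 1], y = system$disc$points[, 2],
                   fx = system$forces[, 1], fy = system$forces[, 2],
                   segment = system$disc$segment)
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
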