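#' Half-plane diffusion profile
#'
#' Time-dependent concentration profile (probability density over depth) of
#' a particle released at the origin of a semi-infinite one-dimensional
#' domain with a reflecting wall at `x = 0`:
#' `G(x, t) = exp(-x^2 / (4 D t)) / sqrt(pi D t)`, valid for `x >= 0`. The
#' peak height is `1 / sqrt(pi D t)` - twice the unreflected Gaussian peak -
#' because all mass folds into the right half plane.
#'
#' @param x Depth position(s), micrometres, `>= 0`.
#' @param t Elapsed time, seconds, `> 0`.
#' @param D Diffusion coefficient, um^2/s, `> 0`.
#' @return Density value(s), 1/um.
#' @examples
#' diffusion_profile(0, t = 100, D = 0.9)  # 1 / sqrt(pi * 0.9 * 100)
#' @export
diffusion_profile <- function(x, t, D) {
  stopifnot(t > 0, D > 0)
  if (any(x < 0)) stop("the half-plane solution is valid only for x >= 0")
  exp(-x^2 / (4 * D * t)) / sqrt(pi * D * t)
}

#' Half-plane advection-diffusion profile
#'
#' Profile of a particle released at the origin and carried by a constant
#' drift `v` towards positive depth while diffusing:
#' `G(x, t) = exp(-(x - v t)^2 / (4 D t)) / sqrt(pi D t)`, a Gaussian of
#' standard deviation `sqrt(2 D t)` centred at `v t`, with the same
#' half-plane prefactor as [diffusion_profile()] (to which it reduces at
#' `v = 0`). The moving Gaussian with this prefactor is the model's own
#' approximation near the reflecting origin; it is accurate once
#' `v t >> sqrt(D t)`.
#'
#' @inheritParams diffusion_profile
#' @param v Drift speed, um/s.
#' @return Density value(s), 1/um.
#' @export
advection_diffusion_profile <- function(x, t, D, v) {
  stopifnot(t > 0, D > 0)
  exp(-(x - v * t)^2 / (4 * D * t)) / sqrt(pi * D * t)
}

#' Tabulate an analytic profile for overlay plotting
#'
#' @param t,D,v Profile parameters as in [advection_diffusion_profile()].
#' @param x_max Largest depth tabulated; defaults to the peak location plus
#'   five standard deviations.
#' @param n Number of grid points.
#' @param path Optional CSV output path.
#' @return A data frame with columns `x` and `G`.
#' @export
analytic_profile_table <- function(t, D, v = 0, x_max = NULL, n = 512,
                                   path = NULL) {
  if (is.null(x_max)) x_max <- v * t + 5 * sqrt(2 * D * t)
  x <- seq(0, x_max, length.out = n)
  df <- data.frame(x = x, G = advection_diffusion_profile(x, t, D, v))
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
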