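#' Mean tissue penetration depth
#'
#' Arithmetic mean of the final X-coordinate over all particles in the
#' ensemble, captured and mobile alike (captured particles count at their
#' capture site, exited particles at the domain width), with its standard
#' error.
#'
#' @param result An `ensemble_result` from [simulate_ensemble()].
#' @return A list with `mean`, `se` and `n` (micrometres).
#' @export
mean_penetration_depth <- function(result) {
  stopifnot(inherits(result, "ensemble_result"))
  if (nrow(result) == 0) stop("empty ensemble")
  n <- nrow(result)
  list(mean = mean(result$x),
       se = stats::sd(result$x) / sqrt(n),
       n = n)
}

#' Depth histogram of an ensemble
#'
#' Bins the final X-coordinates from zero outward. With `normalize = TRUE`
#' the counts are scaled to unit area (`sum(density) * bin_width = 1`) so the
#' histogram overlays directly on [diffusion_profile()] /
#' [advection_diffusion_profile()].
#'
#' @param result An `ensemble_result`.
#' @param bin_width Bin width in micrometres (default 10, one cell radius).
#' @param normalize Return unit-area densities instead of raw counts.
#' @return A data frame with `mid` (bin midpoint), `count` and `density`.
#' @export
depth_histogram <- function(result, bin_width = 10, normalize = FALSE) {
  stopifnot(inherits(result, "ensemble_result"), bin_width > 0)
  if (nrow(result) == 0) stop("empty ensemble")
  breaks <- seq(0, max(result$x, 0) + bin_width, by = bin_width)
  h <- graphics::hist(result$x, breaks = breaks, plot = FALSE)
  df <- data.frame(mid = h$mids, count = h$counts,
                   density = h$counts / (nrow(result) * bin_width))
  if (normalize) df$count <- NULL
  df
}

#' Collision and capture statistics
#'
#' Summarizes the per-particle contact counts recorded by the engine:
#' fraction captured, the distribution of contacts, and the mean number of
#' contacts a captured particle made before its capture. With a per-contact
#' capture probability `rho`, contacts-before-capture at an isolated flat
#' wall follow a geometric law with mean `1/rho`.
#'
#' @param result An `ensemble_result`.
#' @return A list: `n`, `captured_fraction`, `exited_fraction`,
#'   `mean_collisions`, `mean_contacts_before_capture` (`NA` when nothing was
#'   captured) and `collision_quantiles`.
#' @export
collision_statistics <- function(result) {
  stopifnot(inherits(result, "ensemble_result"))
  cap <- result$status == "captured"
  list(n = nrow(result),
       captured_fraction = mean(cap),
       exited_fraction = mean(result$status == "exited_right"),
       mean_collisions = mean(result$collisions),
       mean_contacts_before_capture =
         if (any(cap)) mean(result$collisions[cap]) else NA_real_,
       collision_quantiles = stats::quantile(result$collisions,
                                             c(0, 0.25, 0.5, 0.75, 1)))
}

#' Dosing back-of-envelope
#'
#' How many injected particles reach a target tissue, and what volume
#' fraction they occupy there: `delivered = volume x concentration x
#' fraction`; `volume_fraction = delivered x (4/3) pi a^3 / tissue_volume`.
#' With typical numbers (1 ml at 1e8 particles/ml, 1 % delivery, 100 nm
#' radius, 1 cm^3 of tissue) about a million particles arrive, occupying a
#' volume fraction of order 1e-9 - small enough to justify treating
#' particles as mutually non-interacting.
#'
#' @param injected_volume_ml Injected solution volume, millilitres.
#' @param concentration_per_ml Particle concentration, particles/ml.
#' @param delivery_fraction Fraction of injected particles reaching the
#'   tissue.
#' @param particle_radius Particle radius, micrometres.
#' @param tissue_volume_cm3 Target tissue volume, cubic centimetres.
#' @return A list with `delivered_count` and `volume_fraction`.
#' @examples
#' dosing_worked_example()  # ~1e6 particles, volume fraction ~4e-9
#' @export
dosing_worked_example <- function(injected_volume_ml = 1,
                                  concentration_per_ml = 1e8,
                                  delivery_fraction = 0.01,
                                  particle_radius = 0.1,
                                  tissue_volume_cm3 = 1) {
  stopifnot(injected_volume_ml > 0, concentration_per_ml > 0,
            delivery_fraction >= 0, particle_radius > 0,
            tissue_volume_cm3 > 0)
  delivered <- injected_volume_ml * concentration_per_ml * delivery_fraction
  a_cm <- particle_radius * 1e-4
  list(delivered_count = delivered,
       volume_fraction = delivered * (4 / 3) * pi * a_cm^3 / tissue_volume_cm3)
}

#' Summary report for an ensemble run
#'
#' Key-value summary of an ensemble: mean depth with standard error,
#' particle fates, collision statistics and the parameter snapshot. Written
#' as JSON when `path` is given.
#'
#' @param result An `ensemble_result`.
#' @param bin_width Histogram bin width passed to [depth_histogram()].
#' @param path Optional JSON output path.
#' @return A list (invisibly written to `path` when given).
#' @export
ensemble_summary <- function(result, bin_width = 10, path = NULL) {
  depth <- mean_penetration_depth(result)
  coll <- collision_statistics(result)
  hist <- depth_histogram(result, bin_width)
  out <- list(n_particles = depth$n,
              mean_depth = depth$mean,
              mean_depth_se = depth$se,
              peak_depth = hist$mid[which.max(hist$count)],
              captured_fraction = coll$captured_fraction,
              exited_fraction = coll$exited_fraction,
              mean_collisions = coll$mean_collisions,
              mean_contacts_before_capture = coll$mean_contacts_before_capture,
              tier_counts = as.list(attr(result, "tier_counts")),
              seed = attr(result, "seed"))
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(out)
}

#' Export an ensemble as a plain table
#'
#' @param result An `ensemble_result`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(result, path) {
  stopifnot(inherits(result, "ensemble_result"))
  write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
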