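#' Rectangular tissue domain
#'
#' Defines the two-dimensional tissue section through which particles move.
#' The origin is the bottom-left corner. The left edge (`omega1`) is the
#' porous capillary wall where particles enter and fluid is driven in; the
#' bottom (`omega2`) and top (`omega3`) edges are no-slip walls; the right
#' edge is open and assumed far enough that particles rarely reach it
#' (violations are reported by the simulator). X measures tissue depth.
#'
#' @param width,height Domain extents in micrometres.
#' @return An object of class `domain_spec` with fields `width` and `height`.
#' @examples
#' dom <- domain_spec(1000, 500)
#' @export
domain_spec <- function(width = 1000, height = 500) {
  stopifnot(is.numeric(width), is.numeric(height),
            length(width) == 1, length(height) == 1,
            width > 0, height > 0)
  structure(list(width = as.numeric(width), height = as.numeric(height)),
            class = "domain_spec")
}

#' @export
print.domain_spec <- function(x, ...) {
  cat(sprintf("<domain_spec> %g x %g um (origin bottom-left; left edge = inlet)\n",
              x$width, x$height))
  invisible(x)
}

#' Pack non-overlapping cells into a domain
#'
#' Random sequential addition: uniform center proposals are accepted if the
#' disc does not overlap a previously placed cell and respects the placement
#' margins. The cell count is fixed up front as
#' `n = round(target_fraction * width * height / (pi r^2))`, so the achieved
#' area fraction differs from the target only by rounding. A margin keeps
#' cells away from the inlet edge so that entering particles always find
#' interstitial space, and a small clearance keeps cell discs off the no-slip
#' walls so that cell and wall collocation points cannot coincide.
#'
#' @param domain A [domain_spec()].
#' @param cell_radius Cell radius in micrometres.
#' @param target_fraction Target cell area fraction of the domain
#'   (porosity = 1 - target_fraction). Must be below ~0.55, where random
#'   sequential addition of discs jams.
#' @param seed Optional integer seed; packing is deterministic given the seed.
#' @param inlet_margin Minimum gap between any cell boundary and the inlet
#'   edge, in micrometres (default: one cell radius).
#' @param wall_clearance Minimum gap between any cell boundary and the
#'   bottom/top walls, in micrometres.
#' @param max_attempts Proposal budget before packing is declared failed.
#' @return An object of class `cell_field`: `centers` (n x 2 matrix),
#'   `cell_radius`, `achieved_area_fraction`, `domain`.
#' @examples
#' dom <- domain_spec(200, 100)
#' cf <- pack_cells(dom, cell_radius = 10, target_fraction = 0.4, seed = 1)
#' cf$achieved_area_fraction
#' @export
pack_cells <- function(domain, cell_radius = 10, target_fraction = 0.4,
                       seed = NULL, inlet_margin = cell_radius,
                       wall_clearance = 0.5, max_attempts = NULL) {
  stopifnot(inherits(domain, "domain_spec"),
            cell_radius > 0, cell_radius < min(domain$width, domain$height) / 2,
            target_fraction >= 0, target_fraction < 0.55)
  w <- domain$width; h <- domain$height; r <- cell_radius
  area <- w * h
  n <- round(target_fraction * area / (pi * r^2))
  if (n == 0) {
    return(structure(list(centers = matrix(numeric(0), 0, 2,
                                           dimnames = list(NULL, c("x", "y"))),
                          cell_radius = r, achieved_area_fraction = 0,
                          domain = domain),
                     class = "cell_field"))
  }
  xlo <- inlet_margin + r; xhi <- w - r
  ylo <- r + wall_clearance; yhi <- h - r - wall_clearance
  if (xlo >= xhi || ylo >= yhi)
    stop("domain too small for the requested cell radius and margins")
  if (is.null(max_attempts)) max_attempts <- max(200000, 5000 * n)
  if (!is.null(seed)) {
    old <- .save_rng_state(); on.exit(.restore_rng_state(old))
    set.seed(seed)
  }

  # spatial bins (size 2r) so overlap checks only touch the 3x3 neighbourhood
  bs <- 2 * r
  nbx <- max(1L, ceiling(w / bs)); nby <- max(1L, ceiling(h / bs))
  bins <- vector("list", nbx * nby)
  bin_of <- function(x, y) {
    bx <- min(nbx - 1L, max(0L, as.integer(x / bs)))
    by <- min(nby - 1L, max(0L, as.integer(y / bs)))
    bx + nbx * by + 1L
  }
  centers <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
  placed <- 0L
  attempts <- 0L
  min2 <- (2 * r)^2
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    px <- runif(1, xlo, xhi); py <- runif(1, ylo, yhi)
    bx <- as.integer(px / bs); by <- as.integer(py / bs)
    ok <- TRUE
    for (jy in max(0L, by - 1L):min(nby - 1L, by + 1L)) {
      for (jx in max(0L, bx - 1L):min(nbx - 1L, bx + 1L)) {
        for (i in bins[[jx + nbx * jy + 1L]]) {
          if ((px - centers[i, 1])^2 + (py - centers[i, 2])^2 < min2) {
            ok <- FALSE; break
          }
        }
        if (!ok) break
      }
      if (!ok) break
    }
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- c(px, py)
      b <- bin_of(px, py)
      bins[[b]] <- c(bins[[b]], placed)
    }
  }
  if (placed < n) {
    stop(sprintf(paste0("cell packing failed: placed %d of %d cells ",
                        "(achieved fraction %.3f vs target %.3f) ",
                        "after %d attempts"),
                 placed, n, placed * pi * r^2 / area, target_fraction,
                 attempts))
  }
  structure(list(centers = centers, cell_radius = r,
                 achieved_area_fraction = n * pi * r^2 / area,
                 domain = domain),
            class = "cell_field")
}

#' @export
print.cell_field <- function(x, ...) {
  cat(sprintf("<cell_field> %d cells of radius %g um, area fraction %.4f\n",
              nrow(x$centers), x$cell_radius, x$achieved_area_fraction))
  invisible(x)
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Discretize solid boundaries into collocation points
#'
#' Distributes `n_points` collocation points over the three solid domain
#' edges and all cell boundaries, proportionally to segment length with
#' largest-remainder rounding. Points are equispaced along each segment
#' (cell-centred, so corner points never coincide). The prescribed boundary
#' velocity is `(v_in, 0)` on the inlet edge and zero on the no-slip walls
#' and cell boundaries.
#'
#' @param domain A [domain_spec()].
#' @param cells A [pack_cells()] result (may be empty).
#' @param n_points Total number of collocation points.
#' @param v_in Inlet speed in micrometres per second (along +X).
#' @return An object of class `boundary_disc`: `points` (N x 2), `velocities`
#'   (N x 2), `segment` (label per point), `counts` (points per segment),
#'   `n_points`, `v_in`.
#' @export
discretize_boundaries <- function(domain, cells, n_points = 6700, v_in = 1) {
  stopifnot(inherits(domain, "domain_spec"), inherits(cells, "cell_field"),
            v_in >= 0)
  n_cells <- nrow(cells$centers)
  n_seg <- 3L + n_cells
  if (n_points < n_seg)
    stop("n_points must be at least the number of boundary segments")
  lens <- c(domain$height, domain$width, domain$width,
            rep(2 * pi * cells$cell_radius, n_cells))
  counts <- .largest_remainder(n_points * lens / sum(lens), n_points)
  if (any(counts[seq_len(3)] < 1))
    stop("n_points too small to place a point on every domain edge")
  if (n_cells > 0 && any(counts[-seq_len(3)] < 3))
    stop("n_points too small to place at least 3 points per cell")

  seg_names <- c("omega1", "omega2", "omega3",
                 if (n_cells > 0) paste0("cell_", seq_len(n_cells)))
  pts <- vector("list", n_seg)
  # domain edges: cell-centred equispacing along the segment
  s1 <- (seq_len(counts[1]) - 0.5) / counts[1] * domain$height
  pts[[1]] <- cbind(0, s1)
  s2 <- (seq_len(counts[2]) - 0.5) / counts[2] * domain$width
  pts[[2]] <- cbind(s2, 0)
  s3 <- (seq_len(counts[3]) - 0.5) / counts[3] * domain$width
  pts[[3]] <- cbind(s3, domain$height)
  if (n_cells > 0) {
    r <- cells$cell_radius
    for (i in seq_len(n_cells)) {
      m <- counts[3 + i]
      th <- (seq_len(m) - 0.5) / m * 2 * pi
      pts[[3 + i]] <- cbind(cells$centers[i, 1] + r * cos(th),
                            cells$centers[i, 2] + r * sin(th))
    }
  }
  points <- do.call(rbind, pts)
  colnames(points) <- c("x", "y")
  segment <- rep(seg_names, counts)
  velocities <- matrix(0, nrow(points), 2, dimnames = list(NULL, c("vx", "vy")))
  velocities[segment == "omega1", 1] <- v_in
  structure(list(points = points, velocities = velocities, segment = segment,
                 counts = setNames(counts, seg_names), n_points = nrow(points),
                 v_in = v_in),
            class = "boundary_disc")
}

#' @export
print.boundary_disc <- function(x, ...) {
  cat(sprintf("<boundary_disc> N = %d collocation points on %d segments (v_in = %g um/s)\n",
              x$n_points, length(x$counts), x$v_in))
  invisible(x)
}

# apportion fractional quotas to integers summing to `total`
.largest_remainder <- function(quota, total) {
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Distance to the nearest solid boundary
#'
#' Minimum distance from an interstitial position to any solid feature: the
#' inlet edge, the two no-slip walls, or any cell boundary (`|x - center| -
#' r`). Ties are broken deterministically in favour of the lowest feature
#' index, with edges indexed before cells (`omega1`, `omega2`, `omega3`,
#' `cell_1`, ...).
#'
#' @param x Position, numeric length 2 (micrometres).
#' @param cells A [pack_cells()] result.
#' @param domain A [domain_spec()].
#' @return A list with `R` (distance, > 0) and `feature` (label).
#' @export
nearest_boundary_distance <- function(x, cells, domain) {
  stopifnot(length(x) == 2, inherits(cells, "cell_field"),
            inherits(domain, "domain_spec"))
  if (x[1] < 0 || x[1] > domain$width || x[2] < 0 || x[2] > domain$height)
    stop("position outside the domain")
  d <- c(x[1], x[2], domain$height - x[2])
  labels <- c("omega1", "omega2", "omega3")
  if (nrow(cells$centers) > 0) {
    dc <- sqrt((cells$centers[, 1] - x[1])^2 + (cells$centers[, 2] - x[2])^2) -
      cells$cell_radius
    if (any(dc < 0)) stop("position inside a cell")
    d <- c(d, dc)
    labels <- c(labels, paste0("cell_", seq_len(nrow(cells$centers))))
  }
  i <- which.min(d)  # which.min returns the first (lowest-index) minimum
  list(R = unname(d[i]), feature = labels[i])
}

#' Write / read a cell field as plain text
#'
#' One row per cell (`x`, `y`, `r`), preceded by comment header lines holding
#' the domain fields. Coordinates are written with 17 significant digits so a
#' read-back reproduces the field bit-exactly.
#'
#' @param cells A [pack_cells()] result.
#' @param path File path.
#' @return `write_cell_field` returns `path` invisibly; `read_cell_field`
#'   returns a `cell_field`.
#' @export
write_cell_field <- function(cells, path) {
  stopifnot(inherits(cells, "cell_field"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# width %.17g", cells$domain$width),
               sprintf("# height %.17g", cells$domain$height),
               sprintf("# cell_radius %.17g", cells$cell_radius),
               "x,y,r"), con)
  if (nrow(cells$centers) > 0) {
    writeLines(sprintf("%.17g,%.17g,%.17g",
                       cells$centers[, 1], cells$centers[, 2],
                       cells$cell_radius), con)
  }
  invisible(path)
}

#' @rdname write_cell_field
#' @export
read_cell_field <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_field <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, " "), hdr)]
    as.numeric(sub(paste0("^# ", key, " "), "", ln))
  }
  dom <- domain_spec(get_field("width"), get_field("height"))
  r <- get_field("cell_radius")
  body <- lines[!startsWith(lines, "#")]
  tab <- read.csv(text = body)
  centers <- as.matrix(tab[, c("x", "y"), drop = FALSE])
  dimnames(centers) <- list(NULL, c("x", "y"))
  structure(list(centers = centers, cell_radius = r,
                 achieved_area_fraction = nrow(centers) * pi * r^2 /
                   (dom$width * dom$height),
                 domain = dom),
            class = "cell_field")
}
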