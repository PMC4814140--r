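# Sphere-fitting pore-radius profiling along a channel axis.
#
# The pore radius at an axial position z is the radius of the largest probe
# sphere whose centre lies in the slice plane (within a lateral bound of the
# axis) and that touches no atom:
#     radius(z) = max_{c in plane} min_i ( |atom_i - c| - vdw_i )
# The maximisation is done by multi-start Nelder-Mead in axis-local lateral
# coordinates, which makes the result invariant under rigid motions of the
# structure when the axis is transformed along with it.

#' Construct a channel axis
#'
#' A channel axis is an origin (conventionally the midpoint between the two
#' NPA asparagines, z = 0), a unit direction (z increasing toward the
#' non-cytosolic side), an axial range, and an orthonormal lateral basis
#' (u, v) completing the direction to a right-handed frame.  Carrying the
#' lateral basis on the axis makes all profiling computations axis-local and
#' exactly equivariant under rigid motions.
#'
#' @param origin Length-3 numeric, axis origin (Angstrom).
#' @param direction Length-3 numeric, axis direction (normalised internally).
#' @param z_min,z_max Axial range relative to the origin (Angstrom).
#' @param u,v Optional lateral basis vectors; derived deterministically from
#'   \code{direction} when absent.
#' @return Object of class \code{channel_axis}.
#' @export
channel_axis <- function(origin, direction, z_min, z_max, u = NULL, v = NULL) {
  d <- direction / sqrt(sum(direction^2))
  if (!all(is.finite(d))) stop("invalid axis direction")
  if (z_min >= z_max) stop("z_min must be < z_max")
  if (is.null(u)) {
    seed <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- seed - sum(seed * d) * d
    u <- u / sqrt(sum(u^2))
  } else {
    u <- u - sum(u * d) * d
    u <- u / sqrt(sum(u^2))
  }
  if (is.null(v)) v <- c(d[2] * u[3] - d[3] * u[2],
                         d[3] * u[1] - d[1] * u[3],
                         d[1] * u[2] - d[2] * u[1])
  structure(list(origin = as.numeric(origin), direction = d,
                 u = u, v = v, z_min = z_min, z_max = z_max),
            class = "channel_axis")
}

#' @export
print.channel_axis <- function(x, ...) {
  cat(sprintf("<channel_axis> origin (%.2f, %.2f, %.2f) direction (%.3f, %.3f, %.3f) z [%.1f, %.1f]\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$direction[1], x$direction[2], x$direction[3],
              x$z_min, x$z_max))
  invisible(x)
}

#' Apply a rigid transform to a channel axis
#'
#' @param axis A \code{channel_axis}.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector.
#' @return Transformed \code{channel_axis}.
#' @export
transform_axis <- function(axis, rotation = diag(3), translation = c(0, 0, 0)) {
  channel_axis(origin = as.numeric(rotation %*% axis$origin) + translation,
               direction = as.numeric(rotation %*% axis$direction),
               z_min = axis$z_min, z_max = axis$z_max,
               u = as.numeric(rotation %*% axis$u),
               v = as.numeric(rotation %*% axis$v))
}

# coordinates in the axis frame: columns (u, v, z)
axis_local <- function(xyz, axis) {
  rel <- sweep(xyz, 2, axis$origin)
  cbind(rel %*% axis$u, rel %*% axis$v, rel %*% axis$direction)
}

#' Fit a channel axis to pore-lining atoms
#'
#' The direction is the principal axis (largest-variance eigenvector of the
#' coordinate covariance) of the selected atoms; the lateral basis is taken
#' from the remaining eigenvectors, so the whole frame co-rotates with the
#' structure.  The origin is the centroid projected onto the axis, or, when
#' \code{npa_anchor} is given (the midpoint of the two NPA asparagine
#' side-chain amide carbons), that anchor's projection, putting z = 0 at the
#' NPA region.
#'
#' @param structure An \code{aqp_structure}.
#' @param selection Optional integer vector of atom rows (default all atoms).
#' @param npa_anchor Optional length-3 point anchoring z = 0.
#' @param orient Length-3 vector; the direction sign is chosen to have a
#'   positive dot product with it (default lab +z, the non-cytosolic side).
#' @return A \code{channel_axis} with z range covering the selection.
#' @export
fit_axis <- function(structure, selection = NULL, npa_anchor = NULL,
                     orient = c(0, 0, 1)) {
  xyz <- coords(structure)
  if (!is.null(selection)) xyz <- xyz[selection, , drop = FALSE]
  if (nrow(xyz) < 3) stop("axis fit needs at least 3 atoms")
  ctr <- colMeans(xyz)
  ev <- eigen(stats::cov(xyz), symmetric = TRUE)
  if (ev$values[3] < 1e-9 * max(ev$values[1], 1e-12) ||
      ev$values[1] < 1e-12)
    stop("degenerate (planar or linear) atom selection; axis undefined")
  d <- ev$vectors[, 1]
  if (sum(d * orient) < 0) d <- -d
  origin <- ctr
  if (!is.null(npa_anchor))
    origin <- ctr + sum((npa_anchor - ctr) * d) * d
  zloc <- as.numeric(sweep(xyz, 2, origin) %*% d)
  channel_axis(origin = origin, direction = d,
               z_min = min(zloc), z_max = max(zloc),
               u = ev$vectors[, 2])
}

#' Probe parameters for pore profiling
#'
#' @param z_step Axial sampling step (Angstrom).
#' @param lateral_bound Maximum lateral drift of the probe centre from the
#'   axis (Angstrom); slices whose optimum drifts beyond it are treated as
#'   vestibule/bulk and trimmed from the profile ends.
#' @param n_restarts Number of local-search starts per slice (>= 1); the
#'   first start is on the axis, the rest at seeded random lateral offsets.
#' @param seed Seed for the random restarts.
#' @param z_cutoff Atoms further than this from the slice plane are ignored
#'   (Angstrom); slices with no atoms inside the cutoff are flagged as bulk.
#' @return List of class \code{probe_params}.
#' @export
probe_params <- function(z_step = 0.25, lateral_bound = 5, n_restarts = 8,
                         seed = 1L, z_cutoff = 12) {
  stopifnot(z_step > 0, n_restarts >= 1, lateral_bound > 0, z_cutoff > 0)
  structure(list(z_step = z_step, lateral_bound = lateral_bound,
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 z_cutoff = z_cutoff), class = "probe_params")
}

# objective: probe radius for centre at lateral (p1, p2) in slice plane z0;
# soft penalty outside the lateral bound keeps optim inside the search disc
slice_radius_fn <- function(local, vdw, z0, bound) {
  function(p) {
    dx <- local[, 1] - p[1]; dy <- local[, 2] - p[2]; dz <- local[, 3] - z0
    r <- min(sqrt(dx * dx + dy * dy + dz * dz) - vdw)
    drift <- sqrt(p[1]^2 + p[2]^2)
    if (drift > bound) r <- r - 100 * (drift - bound)^2
    r
  }
}

#' Sphere-fitting pore-radius profile
#'
#' Computes, at each axial step, the largest probe-sphere radius over centres
#' in the slice plane (HOLE-style max-min optimisation, multi-start
#' Nelder-Mead).  Slices with no atoms within \code{z_cutoff} get an infinite
#' radius and slices whose optimal centre drifts beyond the lateral bound are
#' considered vestibule openings; both are trimmed from the profile ends.
#' Negative radii (fully occluded slices) are clamped to zero.
#'
#' @param structure An \code{aqp_structure}.
#' @param axis A \code{channel_axis} (z = 0 conventionally at the NPA region).
#' @param params A \code{probe_params} object.
#' @return Object of class \code{pore_profile}: data frame with columns
#'   \code{z}, \code{radius}, \code{cx}, \code{cy}, \code{cz} (probe centre,
#'   global coordinates), \code{drift} and \code{flagged}.
#' @export
profile_pore <- function(structure, axis, params = probe_params()) {
  local <- axis_local(coords(structure), axis)
  vdw <- structure$atoms$vdw
  zs <- seq(axis$z_min, axis$z_max, by = params$z_step)
  if (!length(zs)) stop("axis z-range does not intersect the atom cloud")
  nr <- params$n_restarts
  starts <- matrix(0, nr, 2)
  if (nr > 1) {
    rs <- local_rng(params$seed, {
      ang <- runif(nr - 1, 0, 2 * pi)
      rad <- params$lateral_bound * sqrt(runif(nr - 1))
      cbind(rad * cos(ang), rad * sin(ang))
    })
    starts[-1, ] <- rs
  }
  res <- lapply(zs, function(z0) {
    keep <- abs(local[, 3] - z0) <= params$z_cutoff
    if (!any(keep))
      return(list(radius = Inf, p = c(0, 0), flagged = TRUE))
    fn <- slice_radius_fn(local[keep, , drop = FALSE], vdw[keep], z0,
                          params$lateral_bound)
    best <- NULL
    for (i in seq_len(nr)) {
      o <- optim(starts[i, ], fn, method = "Nelder-Mead",
                 control = list(fnscale = -1, reltol = 1e-12, maxit = 800))
      if (is.null(best) || o$value > best$value) best <- o
    }
    drift <- sqrt(sum(best$par^2))
    # a probe larger than the lateral search disc, or a centre pinned at its
    # edge, means the slice is outside the channel (vestibule/bulk)
    list(radius = best$value, p = best$par,
         flagged = drift > 0.999 * params$lateral_bound ||
           best$value > params$lateral_bound)
  })
  radius <- vapply(res, `[[`, numeric(1), "radius")
  flagged <- vapply(res, `[[`, logical(1), "flagged")
  pmat <- t(vapply(res, `[[`, numeric(2), "p"))
  centres <- sweep(pmat[, 1, drop = FALSE] %*% rbind(axis$u) +
                   pmat[, 2, drop = FALSE] %*% rbind(axis$v) +
                   matrix(zs, ncol = 1) %*% rbind(axis$direction),
                   2, axis$origin, "+")
  drift <- sqrt(rowSums(pmat^2))
  keep <- rep(TRUE, length(zs))
  lo <- 1L
  while (lo <= length(zs) && flagged[lo]) { keep[lo] <- FALSE; lo <- lo + 1L }
  hi <- length(zs)
  while (hi >= 1 && flagged[hi]) { keep[hi] <- FALSE; hi <- hi - 1L }
  out <- data.frame(z = zs, radius = pmax(radius, 0),
                    cx = centres[, 1], cy = centres[, 2], cz = centres[, 3],
                    drift = drift, flagged = flagged)[keep, ]
  rownames(out) <- NULL
  structure(out, class = c("pore_profile", "data.frame"),
            axis = axis, params = params)
}

#' Minimum pore diameter in an axial window
#'
#' @param profile A \code{pore_profile}.
#' @param z_window Length-2 numeric, axial window (Angstrom).
#' @return Minimum diameter (2 x minimum radius) within the window.
#' @export
min_diameter <- function(profile, z_window) {
  stopifnot(length(z_window) == 2)
  sel <- profile$z >= min(z_window) & profile$z <= max(z_window)
  if (!any(sel)) stop("z window does not overlap the profile")
  2 * min(profile$radius[sel])
}

#' Align pore profiles on a common axial grid
#'
#' Profiles must share the z = 0 anchoring convention (NPA region).  Each
#' profile is linearly interpolated onto the common grid; the per-z mean and
#' standard deviation across structures are returned alongside the
#' per-structure radii.
#'
#' @param profiles Named list of \code{pore_profile} objects.
#' @param z_step Grid step; defaults to the smallest step among the inputs.
#' @return Data frame with columns \code{z}, one radius column per profile,
#'   \code{mean} and \code{sd}.
#' @export
align_profiles <- function(profiles, z_step = NULL) {
  stopifnot(length(profiles) >= 1)
  if (is.null(names(profiles)) || any(names(profiles) == ""))
    names(profiles) <- paste0("profile", seq_along(profiles))
  lo <- max(vapply(profiles, function(p) min(p$z), numeric(1)))
  hi <- min(vapply(profiles, function(p) max(p$z), numeric(1)))
  if (lo >= hi) stop("profiles have non-overlapping z ranges")
  if (is.null(z_step))
    z_step <- min(vapply(profiles, function(p) min(diff(p$z)), numeric(1)))
  grid <- seq(lo, hi, by = z_step)
  mat <- vapply(profiles, function(p) approx(p$z, p$radius, xout = grid)$y,
                numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid),
                dimnames = list(NULL, names(profiles)))
  out <- data.frame(z = grid, mat, check.names = FALSE)
  out$mean <- rowMeans(mat)
  out$sd <- apply(mat, 1, sd)
  out
}

#' Write a pore profile as CSV
#'
#' Columns \code{z_A}, \code{radius_A}, \code{cx}, \code{cy}, \code{cz}.
#'
#' @param profile A \code{pore_profile}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(z_A = profile$z, radius_A = profile$radius,
                   cx = profile$cx, cy = profile$cy, cz = profile$cz)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
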