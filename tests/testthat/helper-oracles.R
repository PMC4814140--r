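# Independent oracles used across the suite.  These deliberately use naive
# algorithms (dense grids, per-frame loops, direct SVD) so they stay
# independent of the implementation paths they check.

# dense lateral grid search for the slice pore radius (max-min over centres)
grid_slice_radius <- function(st, axis, z0, step = 0.05, bound = 3,
                              z_cutoff = 8) {
  loc <- aqpscope:::axis_local(coords(st), axis)
  vdw <- st$atoms$vdw
  keep <- abs(loc[, 3] - z0) <= z_cutoff
  loc <- loc[keep, , drop = FALSE]; vdw <- vdw[keep]
  g <- expand.grid(x = seq(-bound, bound, step), y = seq(-bound, bound, step))
  g <- g[g$x^2 + g$y^2 <= bound^2, ]
  d <- sqrt(outer(g$x, loc[, 1], "-")^2 + outer(g$y, loc[, 2], "-")^2 +
              matrix((loc[, 3] - z0)^2, nrow(g), nrow(loc), byrow = TRUE))
  d <- sweep(d, 2, vdw, "-")
  max(apply(d, 1, min))
}

# per-frame state-machine enumeration of full pore traversals
oracle_count_events <- function(z, r, lo, hi, lateral_radius = Inf) {
  nev <- 0L
  for (j in seq_len(ncol(z))) {
    side <- 0L; valid <- TRUE
    for (t in seq_len(nrow(z))) {
      zc <- z[t, j]
      if (zc < lo) s <- -1L else if (zc > hi) s <- 1L else s <- 0L
      if (s == 0L) {
        if (r[t, j] > lateral_radius) valid <- FALSE
      } else {
        if (side != 0L && s != side && valid) nev <- nev + 1L
        side <- s
        valid <- TRUE
      }
    }
  }
  nev
}

# closed-form Kabsch superposition rmsd via SVD
kabsch_rmsd <- function(mobile, fixed) {
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  a <- sweep(mobile, 2, cm); b <- sweep(fixed, 2, cf)
  s <- svd(t(a) %*% b)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- a %*% t(R)
  sqrt(mean(rowSums((moved - b)^2)))
}

rot_z <- function(theta) aqpscope:::rotation_about(c(0, 0, 1), theta)
rot_x <- function(theta) aqpscope:::rotation_about(c(1, 0, 0), theta)

# tiny trajectory builder from an explicit frames x atoms x 3 array
toy_traj <- function(coords, dt = 1, ...) {
  trajectory(times = dt * (seq_len(dim(coords)[1]) - 1), coords = coords, ...)
}

lab_axis <- function(z_min = -20, z_max = 20)
  channel_axis(c(0, 0, 0), c(0, 0, 1), z_min, z_max)
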