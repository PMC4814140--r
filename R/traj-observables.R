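# Trajectory-derived observables: permeation events, collective-diffusion
# osmotic permeability, hydrogen-bond profiles, density grids, chi1 rotamer
# populations, and umbrella-sampling PMFs via WHAM.

#' Construct a trajectory object
#'
#' @param times Strictly increasing frame times (default unit: ns).
#' @param coords Numeric array of dimension (n_frames, n_atoms, 3), Angstrom.
#' @param topology Optional data frame with one row per atom; recognised
#'   columns: \code{atom}, \code{mol} (molecule grouping), \code{species},
#'   \code{name}, \code{resno}, \code{resname}, \code{element}.  Missing
#'   columns are filled with defaults (each atom its own molecule).
#' @param box Optional per-frame orthorhombic box lengths: matrix
#'   (n_frames x 3) or length-3 vector (constant box), Angstrom.
#' @param time_unit Unit of \code{times}: "ns", "ps" or "s".
#' @return Object of class \code{aqp_trajectory}.
#' @export
trajectory <- function(times, coords, topology = NULL, box = NULL,
                       time_unit = c("ns", "ps", "s")) {
  time_unit <- match.arg(time_unit)
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3)
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  if (length(times) != nf) stop("length(times) must equal the frame count")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(topology)) topology <- data.frame(atom = seq_len(na))
  if (is.null(topology$atom)) topology$atom <- seq_len(na)
  if (nrow(topology) != na) stop("topology rows must equal the atom count")
  if (is.null(topology$mol)) topology$mol <- seq_len(na)
  if (is.null(topology$species)) topology$species <- "X"
  if (is.null(topology$name)) topology$name <- "X"
  if (is.null(topology$resno)) topology$resno <- topology$mol
  if (is.null(topology$resname)) topology$resname <- "MOL"
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
    stopifnot(nrow(box) == nf, ncol(box) == 3)
  }
  structure(list(times = as.numeric(times), coords = coords,
                 topology = topology, box = box, time_unit = time_unit),
            class = "aqp_trajectory")
}

#' @export
print.aqp_trajectory <- function(x, ...) {
  cat("<aqp_trajectory>", dim(x$coords)[1], "frames x", dim(x$coords)[2],
      "atoms,", utils::tail(x$times, 1) - x$times[1], x$time_unit, "\n")
  invisible(x)
}

.time_to_s <- c(ns = 1e-9, ps = 1e-12, s = 1)

# per-frame, per-atom axial coordinate (and lateral distance) in axis frame
traj_axis_coords <- function(traj, axis) {
  o <- axis$origin; d <- axis$direction; u <- axis$u; v <- axis$v
  nf <- dim(traj$coords)[1]; na <- dim(traj$coords)[2]
  cx <- matrix(traj$coords[, , 1], nf, na)
  cy <- matrix(traj$coords[, , 2], nf, na)
  cz <- matrix(traj$coords[, , 3], nf, na)
  z <- (cx - o[1]) * d[1] + (cy - o[2]) * d[2] + (cz - o[3]) * d[3]
  pu <- (cx - o[1]) * u[1] + (cy - o[2]) * u[2] + (cz - o[3]) * u[3]
  pv <- (cx - o[1]) * v[1] + (cy - o[2]) * v[2] + (cz - o[3]) * v[3]
  list(z = z, r = sqrt(pu^2 + pv^2))
}

# average atom-wise frame x atom matrix into frame x molecule
by_molecule <- function(mat, mol) {
  mols <- sort(unique(mol))
  if (length(mols) == ncol(mat) && all(mol == seq_len(ncol(mat))))
    return(list(mat = mat, mols = mols))
  agg <- t(rowsum(t(mat), group = mol))
  cnt <- as.vector(table(mol)[as.character(sort(unique(mol)))])
  list(mat = sweep(agg, 2, cnt, "/"), mols = sort(unique(mol)))
}

# unwrap axial coordinates by minimum-image increments between frames
unwrap_axial <- function(z, box_len) {
  dz <- diff(z)
  dz <- dz - box_len * round(dz / box_len)
  rbind(z[1, , drop = FALSE],
        matrix(z[1, ], nrow(dz), ncol(dz), byrow = TRUE) + apply(dz, 2, cumsum))
}

#' Count full permeation events through a channel
#'
#' A permeation event is recorded when a molecule's axial coordinate moves
#' from below \code{z_bounds[1]} to above \code{z_bounds[2]} (or the
#' reverse), by a path that stays within \code{lateral_radius} of the axis
#' while between the bounds.  Re-crossings without full traversal and paths
#' that leave the lateral corridor are not counted.  Axial coordinates are
#' unwrapped by minimum-image increments when the trajectory carries box
#' information; apparent box-size jumps without box information raise an
#' error.
#'
#' @param traj An \code{aqp_trajectory}.
#' @param axis A \code{channel_axis}.
#' @param z_bounds Length-2 numeric, channel entry/exit planes (Angstrom).
#' @param lateral_radius Lateral corridor radius (Angstrom).
#' @param molecules Optional molecule ids to track (default: all).
#' @return Data frame of class \code{permeation_events} with columns
#'   \code{molecule}, \code{t_enter}, \code{t_exit}, \code{direction}.
#' @export
count_permeations <- function(traj, axis, z_bounds, lateral_radius = Inf,
                              molecules = NULL) {
  stopifnot(length(z_bounds) == 2, z_bounds[1] < z_bounds[2])
  ax <- traj_axis_coords(traj, axis)
  zm <- by_molecule(ax$z, traj$topology$mol)
  rm_ <- by_molecule(ax$r, traj$topology$mol)
  z <- zm$mat; r <- rm_$mat; mols <- zm$mols
  if (!is.null(molecules)) {
    keep <- mols %in% molecules
    z <- z[, keep, drop = FALSE]; r <- r[, keep, drop = FALSE]
    mols <- mols[keep]
  }
  span <- z_bounds[2] - z_bounds[1]
  if (!is.null(traj$box)) {
    bl <- abs(as.numeric(traj$box %*% axis$direction))
    z <- unwrap_axial(z, mean(bl))
  } else if (nrow(z) > 1 && max(abs(diff(z))) > span) {
    stop("coordinates appear wrapped across periodic boundaries but the ",
         "trajectory has no box information; cannot unwrap")
  }
  lo <- z_bounds[1]; hi <- z_bounds[2]
  times <- traj$times
  out <- list()
  for (j in seq_along(mols)) {
    code <- ifelse(z[, j] < lo, -1L,
            ifelse(z[, j] > hi, 1L,
            ifelse(r[, j] <= lateral_radius, 0L, 2L)))
    rl <- rle(code)
    starts <- cumsum(c(1L, rl$lengths[-length(rl$lengths)]))
    side <- 0L; valid <- TRUE; enter <- NA_integer_
    for (k in seq_along(rl$values)) {
      v <- rl$values[k]
      if (v == 2L) {
        valid <- FALSE
      } else if (v == 0L) {
        if (is.na(enter)) enter <- starts[k]
      } else { # a side: -1 or 1
        if (side != 0L && v != side && valid) {
          out[[length(out) + 1L]] <- data.frame(
            molecule = mols[j],
            t_enter = times[if (is.na(enter)) starts[k] else enter],
            t_exit = times[starts[k]],
            direction = if (v == 1L) "+z" else "-z",
            stringsAsFactors = FALSE)
        }
        side <- v; valid <- TRUE; enter <- NA_integer_
      }
    }
  }
  ev <- if (length(out)) do.call(rbind, out) else
    data.frame(molecule = integer(0), t_enter = numeric(0),
               t_exit = numeric(0), direction = character(0))
  class(ev) <- c("permeation_events", "data.frame")
  ev
}

#' Collective-diffusion osmotic permeability
#'
#' Implements the collective coordinate model of single-channel osmotic
#' permeability: per frame pair, dn = sum of axial displacements of the
#' waters inside the pore divided by the pore length L; the cumulative n(t)
#' performs a random walk whose diffusion constant D_n (from the slope of
#' its mean-square displacement over a lag range) gives
#' p_f = v_w * D_n, with v_w the single-water volume.  D_n and p_f are
#' computed per time window and summarised as mean and standard deviation
#' across windows; the headline estimate uses the window-averaged MSD curve.
#'
#' @param traj An \code{aqp_trajectory} (times in \code{traj$time_unit}).
#' @param axis A \code{channel_axis}.
#' @param pore_z Length-2 numeric, axial extent of the pore (Angstrom).
#' @param window_length Window length in time units of the trajectory;
#'   default: one seventh of the trajectory.
#' @param v_w Single-water molecular volume in cm^3 (default 2.99e-23, bulk
#'   water).
#' @param lag_frac MSD lag-fit range as a fraction of the window length
#'   (default 10--50\%).
#' @param n_lags Number of lag points used for the slope fit.
#' @param molecules Molecule ids of the water subset (default: all molecules,
#'   or those with topology species "W" when present).
#' @return Object of class \code{permeability_estimate}: list with
#'   \code{pf} (cm^3 s^-1), \code{D_n} (s^-1), \code{D_n_native} (per native
#'   time unit), \code{L}, \code{v_w}, \code{windows} (per-window data
#'   frame), \code{pf_mean}, \code{pf_sd} and the averaged \code{msd} curve.
#' @export
collective_pf <- function(traj, axis, pore_z, window_length = NULL,
                          v_w = 2.99e-23, lag_frac = c(0.1, 0.5),
                          n_lags = 12, molecules = NULL) {
  stopifnot(length(pore_z) == 2, pore_z[1] < pore_z[2])
  if (is.null(molecules) && any(traj$topology$species == "W"))
    molecules <- unique(traj$topology$mol[traj$topology$species == "W"])
  ax <- traj_axis_coords(traj, axis)
  zm <- by_molecule(ax$z, traj$topology$mol)
  z <- zm$mat
  if (!is.null(molecules)) z <- z[, zm$mols %in% molecules, drop = FALSE]
  L <- pore_z[2] - pore_z[1]
  inside <- z >= pore_z[1] & z <= pore_z[2]
  nf <- nrow(z)
  if (nf < 10) stop("trajectory too short for a permeability estimate")
  if (!any(inside)) stop("no water molecules inside the pore region")
  dz <- diff(z)
  if (!is.null(traj$box)) {
    # minimum-image increments across the periodic axial boundary
    bl <- mean(abs(as.numeric(traj$box %*% axis$direction)))
    dz <- dz - bl * round(dz / bl)
  }
  ins2 <- inside[-nf, , drop = FALSE] & inside[-1, , drop = FALSE]
  dn <- rowSums(dz * ins2) / L
  n <- c(0, cumsum(dn))
  dt <- diff(traj$times)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("collective_pf requires uniformly spaced frames")
  dt <- dt[1]
  total_t <- (nf - 1) * dt
  if (is.null(window_length)) window_length <- total_t / 7
  W <- max(4L, as.integer(round(window_length / dt)))
  n_windows <- floor((nf - 1) / W)
  if (n_windows < 1) stop("window_length exceeds the trajectory length")
  lags <- unique(pmax(1L, as.integer(round(
    seq(lag_frac[1] * W, lag_frac[2] * W, length.out = n_lags)))))
  msd_of <- function(nw) {
    vapply(lags, function(l) {
      d <- nw[(1 + l):length(nw)] - nw[1:(length(nw) - l)]
      mean(d * d)
    }, numeric(1))
  }
  unit <- .time_to_s[[traj$time_unit]]
  win <- lapply(seq_len(n_windows), function(w) {
    idx <- ((w - 1) * W + 1):(w * W + 1)
    msd <- msd_of(n[idx])
    slope <- coef(lm(msd ~ I(lags * dt) + 0))[1]
    Dn <- max(slope / 2, 0)
    data.frame(window = w, t_start = traj$times[idx[1]],
               D_n_native = Dn, D_n = Dn / unit, pf = v_w * Dn / unit)
  })
  win <- do.call(rbind, win)
  msd_mat <- vapply(seq_len(n_windows), function(w) {
    idx <- ((w - 1) * W + 1):(w * W + 1)
    msd_of(n[idx])
  }, numeric(length(lags)))
  msd_mean <- rowMeans(matrix(msd_mat, nrow = length(lags)))
  slope <- coef(lm(msd_mean ~ I(lags * dt) + 0))[1]
  Dn_native <- max(unname(slope) / 2, 0)
  structure(list(pf = v_w * Dn_native / unit, D_n = Dn_native / unit,
                 D_n_native = Dn_native, L = L, v_w = v_w,
                 windows = win, pf_mean = mean(win$pf), pf_sd = sd(win$pf),
                 msd = data.frame(lag = lags * dt, msd = msd_mean),
                 n_collective = n),
            class = "permeability_estimate")
}

#' @export
print.permeability_estimate <- function(x, ...) {
  cat(sprintf("<permeability_estimate> pf = %.3g cm^3 s^-1 (D_n = %.3g s^-1, L = %.1f A)\n",
              x$pf, x$D_n, x$L))
  cat(sprintf("  windows: %d, pf mean +/- sd = %.3g +/- %.3g cm^3 s^-1\n",
              nrow(x$windows), x$pf_mean, x$pf_sd))
  invisible(x)
}

# -- hydrogen bonds ----------------------------------------------------------

#' Enumerate donor-H-acceptor triples between a solute and partner residues
#'
#' Donors are N/O atoms with a hydrogen attached (same molecule, within
#' 1.25 Angstrom in the first frame); acceptors are N/O atoms.  Triples are
#' built in both directions (solute donates to partner and vice versa).
#'
#' @param traj An \code{aqp_trajectory} whose topology has \code{name} and
#'   \code{element} columns.
#' @param solute_atoms Atom indices of the solute molecule.
#' @param partners Named list mapping a partner label to its atom indices.
#' @return Data frame with columns \code{donor}, \code{h}, \code{acceptor},
#'   \code{partner}.
#' @export
hbond_triples <- function(traj, solute_atoms, partners) {
  top <- traj$topology
  el <- if (!is.null(top$element)) toupper(top$element)
        else toupper(substr(top$name, 1, 1))
  xyz1 <- traj$coords[1, , , drop = FALSE][1, , ]
  polar <- function(idx) idx[el[idx] %in% c("N", "O")]
  hydro <- function(idx) idx[el[idx] == "H"]
  attached_h <- function(d, pool) {
    if (!length(pool)) return(integer(0))
    dd <- sqrt(colSums((t(xyz1[pool, , drop = FALSE]) - xyz1[d, ])^2))
    pool[dd < 1.25]
  }
  rows <- list()
  add <- function(donors, hpool, acceptors, label) {
    for (d in donors) {
      hs <- attached_h(d, hpool)
      for (h in hs) for (acc in acceptors)
        rows[[length(rows) + 1L]] <<- data.frame(
          donor = d, h = h, acceptor = acc, partner = label,
          stringsAsFactors = FALSE)
    }
  }
  sol_d <- polar(solute_atoms); sol_h <- hydro(solute_atoms)
  for (label in names(partners)) {
    p <- partners[[label]]
    add(sol_d, sol_h, polar(p), label)
    add(polar(p), hydro(p), polar(solute_atoms), label)
  }
  if (!length(rows)) return(data.frame(donor = integer(0), h = integer(0),
                                       acceptor = integer(0),
                                       partner = character(0)))
  do.call(rbind, rows)
}

#' Hydrogen-bond profile along the pore axis
#'
#' Counts geometric hydrogen bonds per frame (donor-acceptor distance <=
#' \code{criterion["dist"]} Angstrom and donor-H-acceptor angle >=
#' \code{criterion["angle"]} degrees) for each donor-H-acceptor triple, and
#' averages the per-partner counts in axial bins of the solute position.
#'
#' @param traj An \code{aqp_trajectory}.
#' @param triples Data frame as returned by \code{\link{hbond_triples}}; the
#'   hydrogen column must be resolved (no NA) -- supply hydrogens or build
#'   triples from a topology that has them.
#' @param solute_atom Atom index used for the solute's axial position.
#' @param axis A \code{channel_axis}.
#' @param bin_width Axial bin width (Angstrom).
#' @param criterion Named vector with elements \code{dist} (Angstrom) and
#'   \code{angle} (degrees); default 3.5 Angstrom, 150 degrees.
#' @return Object of class \code{hbond_profile}: data frame with columns
#'   \code{z}, \code{partner}, \code{mean_count}, \code{n_frames}.
#' @export
hbond_profile <- function(traj, triples, solute_atom, axis, bin_width = 0.5,
                          criterion = c(dist = 3.5, angle = 150)) {
  if (!nrow(triples)) stop("no donor-H-acceptor triples supplied")
  if (anyNA(triples$h))
    stop("hydrogens missing from hydrogen-bond triples; ",
         "supply a topology with hydrogens")
  nf <- dim(traj$coords)[1]
  at <- function(i, k) traj$coords[, i, k]
  dist2 <- function(i, j) {
    (at(i, 1) - at(j, 1))^2 + (at(i, 2) - at(j, 2))^2 + (at(i, 3) - at(j, 3))^2
  }
  bonded <- matrix(FALSE, nf, nrow(triples))
  for (t in seq_len(nrow(triples))) {
    d <- triples$donor[t]; h <- triples$h[t]; acc <- triples$acceptor[t]
    da <- sqrt(dist2(d, acc))
    v1 <- cbind(at(d, 1) - at(h, 1), at(d, 2) - at(h, 2), at(d, 3) - at(h, 3))
    v2 <- cbind(at(acc, 1) - at(h, 1), at(acc, 2) - at(h, 2),
                at(acc, 3) - at(h, 3))
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    bonded[, t] <- da <= criterion[["dist"]] & ang >= criterion[["angle"]]
  }
  ax <- traj_axis_coords(traj, axis)
  zsol <- ax$z[, solute_atom]
  zbin <- (floor(zsol / bin_width) + 0.5) * bin_width
  partners <- unique(triples$partner)
  rows <- list()
  for (p in partners) {
    cnt <- rowSums(bonded[, triples$partner == p, drop = FALSE])
    agg <- tapply(cnt, zbin, mean)
    nfr <- tapply(cnt, zbin, length)
    rows[[p]] <- data.frame(z = as.numeric(names(agg)), partner = p,
                            mean_count = as.numeric(agg),
                            n_frames = as.integer(nfr))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$partner, out$z), ]
  rownames(out) <- NULL
  structure(out, class = c("hbond_profile", "data.frame"),
            criterion = criterion, bin_width = bin_width)
}

# -- density grids -----------------------------------------------------------

#' Time-averaged number-density grid
#'
#' Bins the selected atoms' positions over all frames into cubic voxels and
#' normalises by frame count and voxel volume, so that the grid integral
#' equals the mean number of selected particles inside the grid bounds.
#'
#' @param traj An \code{aqp_trajectory}.
#' @param atoms Atom indices to bin (default: all atoms).
#' @param voxel Voxel edge length (Angstrom, > 0).
#' @param bounds Optional 2x3 matrix (rows: min, max) of grid bounds;
#'   default: the data range, padded to whole voxels.
#' @return Object of class \code{density_grid}: list with \code{grid} (3-D
#'   array, number per Angstrom^3), \code{origin}, \code{voxel}, \code{dims},
#'   \code{n_frames}.
#' @export
density_grid <- function(traj, atoms = NULL, voxel = 1, bounds = NULL) {
  if (voxel <= 0) stop("voxel size must be positive")
  if (is.null(atoms)) atoms <- seq_len(dim(traj$coords)[2])
  nf <- dim(traj$coords)[1]
  x <- as.vector(traj$coords[, atoms, 1])
  y <- as.vector(traj$coords[, atoms, 2])
  z <- as.vector(traj$coords[, atoms, 3])
  if (is.null(bounds)) {
    mins <- c(min(x), min(y), min(z)) - 1e-9
    maxs <- c(max(x), max(y), max(z)) + 1e-9
  } else {
    mins <- bounds[1, ]; maxs <- bounds[2, ]
  }
  dims <- pmax(1L, as.integer(ceiling((maxs - mins) / voxel)))
  ix <- floor((x - mins[1]) / voxel) + 1L
  iy <- floor((y - mins[2]) / voxel) + 1L
  iz <- floor((z - mins[3]) / voxel) + 1L
  ok <- ix >= 1L & ix <= dims[1] & iy >= 1L & iy <= dims[2] &
        iz >= 1L & iz <= dims[3]
  lin <- (iz[ok] - 1L) * dims[1] * dims[2] + (iy[ok] - 1L) * dims[1] + ix[ok]
  counts <- tabulate(lin, nbins = prod(dims))
  grid <- array(counts / (nf * voxel^3), dim = dims)
  structure(list(grid = grid, origin = mins, voxel = voxel, dims = dims,
                 n_frames = nf, mean_inside = sum(counts) / nf),
            class = "density_grid")
}

#' Integral of a density grid
#'
#' @param grid A \code{density_grid}.
#' @return Mean number of particles inside the grid bounds.
#' @export
grid_integral <- function(grid) sum(grid$grid) * grid$voxel^3

#' Write a density grid as plain text
#'
#' Header lines carry origin, voxel size and dimensions; values follow one
#' per line with the x index varying fastest.
#'
#' @param grid A \code{density_grid}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_density_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("# voxel %.6f", grid$voxel),
    sprintf("# dims %d %d %d", grid$dims[1], grid$dims[2], grid$dims[3]),
    format(as.vector(grid$grid), digits = 10)), con)
  invisible(path)
}

# -- dihedrals ---------------------------------------------------------------

dihedral_angles <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cr(n1, b2n)
  # sign convention matching the field's torsion implementations (bio3d)
  ang <- unname(atan2(-rowSums(m1 * n2), rowSums(n1 * n2))) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

#' Chi1 dihedral series and rotamer populations
#'
#' Computes the side-chain chi1 dihedral (N-CA-CB-CG) of one residue per
#' frame, assigns each frame to the nearest rotamer basin (g- at -60, t at
#' 180, g+ at +60 degrees) and counts basin transitions.
#'
#' @param traj An \code{aqp_trajectory} whose topology has \code{name} and
#'   \code{resno} columns.
#' @param resno Residue number.
#' @param chain Optional chain filter (topology column \code{chain}).
#' @param gamma_names Atom names accepted for the gamma position.
#' @return Object of class \code{dihedral_series}: list with \code{angles}
#'   (degrees, in (-180, 180]), \code{basin} (factor g-/t/g+),
#'   \code{populations} (proportions), \code{transitions}, \code{resno}.
#' @export
chi1_populations <- function(traj, resno, chain = NULL,
                             gamma_names = c("CG", "CG1", "OG", "OG1", "SG")) {
  top <- traj$topology
  sel <- top$resno == resno
  if (!is.null(chain) && !is.null(top$chain)) sel <- sel & top$chain == chain
  find <- function(names_) {
    i <- which(sel & top$name %in% names_)
    if (!length(i))
      stop("missing atom ", paste(names_, collapse = "/"),
           " for residue ", resno)
    i[1]
  }
  iN <- find("N"); iCA <- find("CA"); iCB <- find("CB"); iCG <- find(gamma_names)
  pm <- function(i) matrix(traj$coords[, i, ], ncol = 3)
  ang <- dihedral_angles(pm(iN), pm(iCA), pm(iCB), pm(iCG))
  centers <- c("g-" = -60, "t" = 180, "g+" = 60)
  circ_dist <- vapply(centers, function(ctr) {
    d <- abs(ang - ctr)
    pmin(d, 360 - d)
  }, numeric(length(ang)))
  basin <- factor(names(centers)[apply(matrix(circ_dist, ncol = 3), 1,
                                       which.min)],
                  levels = names(centers))
  structure(list(angles = ang, basin = basin,
                 populations = prop.table(table(basin)),
                 transitions = sum(basin[-1] != basin[-length(basin)]),
                 resno = resno, times = traj$times),
            class = "dihedral_series")
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat("<dihedral_series> residue", x$resno, "-", length(x$angles),
      "frames,", x$transitions, "basin transitions\n")
  print(round(x$populations, 3))
  invisible(x)
}

# -- WHAM --------------------------------------------------------------------

#' Construct an umbrella-sampling window
#'
#' @param center Restraint centre on the reaction coordinate (Angstrom).
#' @param spring_k Harmonic spring constant (kJ mol^-1 Angstrom^-2, > 0).
#' @param samples Sampled reaction-coordinate values under the bias.
#' @return Object of class \code{umbrella_window}.
#' @export
umbrella_window <- function(center, spring_k, samples) {
  if (spring_k <= 0) stop("spring constant must be positive")
  if (!length(samples)) stop("umbrella window has no samples")
  structure(list(center = center, spring_k = spring_k,
                 samples = as.numeric(samples)), class = "umbrella_window")
}

#' Weighted histogram analysis (WHAM) free-energy profile
#'
#' Self-consistent WHAM reconstruction of the unbiased potential of mean
#' force from harmonically biased umbrella windows: iterates the coupled
#' equations for the unbiased bin probabilities and window free energies
#' until the maximum change in window free energies falls below \code{tol}.
#' The profile is shifted so that its minimum over the bulk region (default:
#' the whole grid) is zero.
#'
#' @param windows List of \code{umbrella_window} objects with pairwise
#'   overlapping sample ranges along the coordinate.
#' @param temperature Temperature in Kelvin.
#' @param grid Bin centres for the profile; default 201 bins spanning the
#'   sampled range.
#' @param tol Convergence tolerance on window free energies (kJ/mol).
#' @param max_iter Maximum number of WHAM iterations.
#' @param bulk_region Optional length-2 numeric; the profile is shifted so
#'   its minimum inside this region is zero.
#' @return Object of class \code{pmf_profile}: data frame with columns
#'   \code{z} and \code{G} (kJ/mol; NA for unvisited bins), plus attributes
#'   \code{iterations}, \code{temperature}, \code{n_windows}.
#' @export
wham_pmf <- function(windows, temperature = 298, grid = NULL, tol = 1e-6,
                     max_iter = 10000, bulk_region = NULL) {
  stopifnot(length(windows) >= 2)
  windows <- windows[order(vapply(windows, `[[`, numeric(1), "center"))]
  rng <- t(vapply(windows, function(w) range(w$samples), numeric(2)))
  for (i in seq_len(length(windows) - 1)) {
    if (rng[i + 1, 1] > rng[i, 2])
      stop("umbrella windows ", i, " and ", i + 1,
           " do not overlap along the reaction coordinate (",
           sprintf("%.3f > %.3f", rng[i + 1, 1], rng[i, 2]), ")")
  }
  all_s <- unlist(lapply(windows, `[[`, "samples"))
  if (is.null(grid)) grid <- seq(min(all_s), max(all_s), length.out = 201)
  h <- diff(grid[1:2])
  edges <- c(grid - h / 2, grid[length(grid)] + h / 2)
  RT <- .R_kJ * temperature
  nw <- length(windows); nb <- length(grid)
  counts <- t(vapply(windows, function(w) {
    idx <- findInterval(w$samples, edges, rightmost.closed = TRUE)
    as.numeric(tabulate(idx[idx >= 1 & idx <= nb], nbins = nb))
  }, numeric(nb)))
  Ni <- rowSums(counts)
  nz <- colSums(counts)
  U <- t(vapply(windows, function(w) 0.5 * w$spring_k * (grid - w$center)^2,
                numeric(nb)))
  expU <- exp(-U / RT)
  f <- rep(0, nw)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- colSums((Ni * exp(f / RT)) * expU)
    P <- nz / denom
    fn <- -RT * log(as.numeric(expU %*% P))
    fn <- fn - fn[1]
    delta <- max(abs(fn - f))
    f <- fn
    if (delta < tol) break
    if (iter >= max_iter)
      stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kJ/mol)",
                   max_iter, delta))
  }
  G <- -RT * log(P)
  G[nz == 0] <- NA_real_
  ref_sel <- if (is.null(bulk_region)) rep(TRUE, nb)
             else grid >= bulk_region[1] & grid <= bulk_region[2]
  ref <- min(G[ref_sel], na.rm = TRUE)
  G <- G - ref
  out <- data.frame(z = grid, G = G)
  structure(out, class = c("pmf_profile", "data.frame"),
            iterations = iter, temperature = temperature, n_windows = nw,
            window_f = f, convergence_tol = tol)
}

#' Free-energy barrier of a PMF
#'
#' @param pmf A \code{pmf_profile} (or data frame with columns z, G).
#' @param region Length-2 numeric; the barrier is the maximum G inside the
#'   region minus the minimum G in the flanking bulk (grid points outside
#'   the region; the global minimum if the region spans the whole grid).
#' @return Barrier height in kJ/mol.
#' @export
barrier_height <- function(pmf, region) {
  stopifnot(length(region) == 2)
  region <- sort(region)
  inside <- pmf$z >= region[1] & pmf$z <= region[2] & is.finite(pmf$G)
  if (!any(inside)) stop("region contains no PMF grid points")
  flank <- !(pmf$z >= region[1] & pmf$z <= region[2]) & is.finite(pmf$G)
  base <- if (any(flank)) min(pmf$G[flank]) else min(pmf$G[inside])
  max(pmf$G[inside]) - base
}

#' Arrhenius-type permeability ratio of two barriers
#'
#' The expected ratio of permeabilities of two pathways with free-energy
#' barriers \code{barrier_high} and \code{barrier_low} (kJ/mol) at the given
#' temperature: exp((high - low) / RT).  With barriers of 20 and 15 kJ/mol
#' at 298 K this is about 7.5, i.e. an order of magnitude.
#'
#' @param barrier_high,barrier_low Barrier heights in kJ/mol.
#' @param temperature Temperature in Kelvin.
#' @return Dimensionless permeability ratio.
#' @export
permeability_ratio <- function(barrier_high, barrier_low, temperature = 298) {
  exp((barrier_high - barrier_low) / (.R_kJ * temperature))
}

# -- trajectory I/O ----------------------------------------------------------

#' Write a trajectory in the plain frame-matrix CSV dialect
#'
#' Long-format CSV with columns frame, time, atom, mol, species, name, x, y,
#' z (plus bx, by, bz when the trajectory has box information).
#'
#' @param traj An \code{aqp_trajectory}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_trajectory <- function(traj, path) {
  nf <- dim(traj$coords)[1]; na <- dim(traj$coords)[2]
  df <- data.frame(
    frame = rep(seq_len(nf), each = na),
    time = rep(traj$times, each = na),
    atom = rep(traj$topology$atom, nf),
    mol = rep(traj$topology$mol, nf),
    species = rep(traj$topology$species, nf),
    name = rep(traj$topology$name, nf),
    x = as.vector(t(traj$coords[, , 1])),
    y = as.vector(t(traj$coords[, , 2])),
    z = as.vector(t(traj$coords[, , 3])))
  if (!is.null(traj$box)) {
    df$bx <- rep(traj$box[, 1], each = na)
    df$by <- rep(traj$box[, 2], each = na)
    df$bz <- rep(traj$box[, 3], each = na)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory
#'
#' Reads either the plain frame-matrix CSV dialect written by
#' \code{\link{write_trajectory}} or a binary DCD file (via bio3d; frame
#' times are then \code{dt * (0:(n-1))}).
#'
#' @param path Input path.
#' @param format "csv" or "dcd" ("auto" decides by extension).
#' @param dt Frame spacing used for DCD input (native time unit).
#' @param time_unit Time unit of the trajectory.
#' @return An \code{aqp_trajectory}.
#' @export
read_trajectory <- function(path, format = c("auto", "csv", "dcd"), dt = 1,
                            time_unit = "ns") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "dcd") "dcd" else "csv"
  if (format == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    nf <- nrow(xyz); na <- ncol(xyz) / 3
    coords <- array(NA_real_, c(nf, na, 3))
    for (k in 1:3) coords[, , k] <- xyz[, seq(k, by = 3, length.out = na)]
    return(trajectory(times = dt * (seq_len(nf) - 1), coords = coords,
                      time_unit = time_unit))
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  frames <- sort(unique(df$frame))
  atoms <- sort(unique(df$atom))
  nf <- length(frames); na <- length(atoms)
  df <- df[order(df$frame, df$atom), ]
  coords <- array(NA_real_, c(nf, na, 3))
  coords[, , 1] <- matrix(df$x, nf, na, byrow = TRUE)
  coords[, , 2] <- matrix(df$y, nf, na, byrow = TRUE)
  coords[, , 3] <- matrix(df$z, nf, na, byrow = TRUE)
  first <- df[df$frame == frames[1], ]
  topology <- data.frame(atom = first$atom, mol = first$mol,
                         species = first$species, name = first$name)
  times <- df$time[!duplicated(df$frame)]
  box <- if ("bx" %in% names(df)) {
    b <- df[!duplicated(df$frame), c("bx", "by", "bz")]
    as.matrix(b)
  } else NULL
  trajectory(times = times, coords = coords, topology = topology, box = box,
             time_unit = time_unit)
}
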