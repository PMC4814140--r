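# Synthetic-data generators with known ground truth: toy channel structures,
# Brownian pore trajectories, umbrella-sampling windows, stopped-flow traces,
# and the published yeast complementation / transport-rate fixtures.
#
# Every generator is deterministic given (parameters, seed); the seed and the
# ground truth are recorded on the returned object so downstream tests never
# re-derive them.

#' Synthetic cylindrical channel structure
#'
#' Stacked rings of pseudo-atoms whose centres sit at
#' \code{inner_radius + vdw} from the z axis, so that the sphere-fitting
#' pore radius equals \code{inner_radius} at every slice.  Geometry is
#' deterministic; the seed is only recorded in the ground-truth metadata.
#'
#' @param inner_radius Wall (probe-accessible) radius in Angstrom (> 0).
#' @param length Channel length in Angstrom (rings span -length/2 ..
#'   +length/2).
#' @param atoms_per_ring Atoms per ring (>= 6; fewer would leave gaps larger
#'   than an atom diameter).
#' @param vdw Van der Waals radius assigned to the wall atoms (Angstrom).
#' @param ring_spacing Axial distance between rings (Angstrom).
#' @param seed Recorded in the metadata (geometry is deterministic).
#' @return An \code{aqp_structure} with attribute \code{truth}: list with
#'   \code{inner_radius}, \code{axis} (a \code{channel_axis} along lab z).
#' @export
make_cylinder_structure <- function(inner_radius = 2, length = 30,
                                    atoms_per_ring = 16, vdw = 1.5,
                                    ring_spacing = 0.5, seed = 1L) {
  if (inner_radius <= 0) stop("inner radius must be positive")
  if (atoms_per_ring < 6)
    stop("atoms_per_ring < 6 leaves a leaky wall; refusing")
  make_ring_structure(function(z) inner_radius, length, atoms_per_ring, vdw,
                      ring_spacing, seed,
                      truth_extra = list(inner_radius = inner_radius),
                      id = "synthetic cylinder")
}

#' Synthetic hourglass channel structure
#'
#' Two cones meeting at z = 0: wall radius
#' r(z) = throat_radius + (end_radius - throat_radius) * |z| / (length/2),
#' so the minimum sphere-fitting radius is \code{throat_radius} at the
#' throat.
#'
#' @param throat_radius Probe-accessible radius at z = 0 (Angstrom).
#' @param end_radius Probe-accessible radius at the channel ends (Angstrom).
#' @inheritParams make_cylinder_structure
#' @return An \code{aqp_structure} with ground-truth attribute as in
#'   \code{\link{make_cylinder_structure}}.
#' @export
make_hourglass_structure <- function(throat_radius = 1.5, end_radius = 3,
                                     length = 30, atoms_per_ring = 16,
                                     vdw = 1.5, ring_spacing = 0.5,
                                     seed = 1L) {
  if (throat_radius <= 0 || end_radius < throat_radius)
    stop("need 0 < throat_radius <= end_radius")
  slope <- (end_radius - throat_radius) / (length / 2)
  make_ring_structure(function(z) throat_radius + slope * abs(z), length,
                      atoms_per_ring, vdw, ring_spacing, seed,
                      truth_extra = list(throat_radius = throat_radius,
                                         end_radius = end_radius),
                      id = "synthetic hourglass")
}

make_ring_structure <- function(radius_fn, length, atoms_per_ring, vdw,
                                ring_spacing, seed, truth_extra, id) {
  zs <- seq(-length / 2, length / 2, by = ring_spacing)
  rows <- lapply(seq_along(zs), function(i) {
    # stagger alternate rings by half an angular step
    ang <- 2 * pi * (seq_len(atoms_per_ring) - 1) / atoms_per_ring +
      (i %% 2) * pi / atoms_per_ring
    a <- radius_fn(zs[i]) + vdw
    data.frame(name = paste0("C", seq_len(atoms_per_ring)),
               element = "C", resname = "CYL", resno = i, chain = "A",
               x = a * cos(ang), y = a * sin(ang), z = zs[i],
               stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  atoms$vdw <- vdw
  st <- as_structure(atoms, id = id)
  attr(st, "truth") <- c(truth_extra, list(
    vdw = vdw, length = length, seed = seed,
    axis = channel_axis(c(0, 0, 0), c(0, 0, 1), -length / 2, length / 2)))
  st
}

#' Add a filter-like residue to a synthetic channel
#'
#' Plants a residue at the channel wall with either a side chain whose tip
#' atom sits at a chosen distance from the axis (mode "sidechain") or a
#' backbone carbonyl oxygen at that distance (mode "carbonyl", for LEP-like
#' residues).  Used to build ground-truth cases for geometric filter
#' annotation.
#'
#' @param structure An \code{aqp_structure} (wall along lab z).
#' @param resno Residue number of the new residue.
#' @param resname Three-letter residue name (e.g. "HIS").
#' @param z Axial position of the residue (Angstrom).
#' @param axial_distance Distance of the tip (or carbonyl O) from the axis.
#' @param tip_atom Name of the side-chain tip atom (mode "sidechain").
#' @param mode "sidechain" or "carbonyl".
#' @param angle Azimuthal placement angle in radians.
#' @param wall_radius Radial position of the backbone atoms; defaults to
#'   \code{axial_distance + 4}.
#' @return The structure with the residue appended.
#' @export
add_filter_residue <- function(structure, resno, resname, z, axial_distance,
                               tip_atom = "NE2",
                               mode = c("sidechain", "carbonyl"),
                               angle = 0, wall_radius = NULL) {
  mode <- match.arg(mode)
  if (is.null(wall_radius)) wall_radius <- axial_distance + 4
  dirv <- c(cos(angle), sin(angle), 0)
  at <- function(name, r, dz = 0) {
    data.frame(name = name, element = infer_element(name), resname = resname,
               resno = resno, chain = "A",
               x = r * dirv[1], y = r * dirv[2], z = z + dz,
               stringsAsFactors = FALSE)
  }
  newatoms <- if (mode == "sidechain") {
    rbind(at("N", wall_radius, 1.2), at("CA", wall_radius),
          at("C", wall_radius, -1.2), at("O", wall_radius + 0.5, -1.9),
          at("CB", (wall_radius + axial_distance) / 2),
          at(tip_atom, axial_distance))
  } else {
    rbind(at("N", wall_radius, 1.2), at("CA", wall_radius),
          at("C", (wall_radius + axial_distance) / 2, -0.6),
          at("O", axial_distance, -0.6))
  }
  newatoms$vdw <- assign_vdw(newatoms$element)
  keep_cols <- c("name", "element", "resname", "resno", "chain",
                 "x", "y", "z", "vdw")
  all_atoms <- rbind(structure$atoms[, keep_cols], newatoms[, keep_cols])
  out <- as_structure(all_atoms, id = structure$id,
                      model_number = structure$model_number)
  attr(out, "truth") <- attr(structure, "truth")
  out
}

#' Brownian single-pore trajectory with known ground truth
#'
#' Independent 1-D Brownian walkers along the pore axis (with a small
#' reflected lateral jitter), with reflecting axial walls, periodic axial
#' re-injection, or free boundaries.  The expected collective diffusion
#' constant for walkers confined to the pore is D_n = n D / L^2 with
#' L the pore length.
#'
#' @param n_molecules Number of walkers.
#' @param D Axial diffusion constant (Angstrom^2 per time unit).
#' @param pore_z Length-2 numeric, pore extent (Angstrom).
#' @param n_frames Number of frames.
#' @param dt Frame spacing (native time unit, default ns).
#' @param boundary "reflect" (confined to the pore), "periodic" (wrapped over
#'   \code{z_range}, box info attached) or "none" (free).
#' @param z_range Domain for periodic/free boundaries (default: the pore
#'   padded by 10 Angstrom each side).
#' @param drift Deterministic axial drift per time unit.
#' @param start "uniform" (inside the pore) or "below" (all walkers at
#'   \code{z_range[1]}).
#' @param lateral_step Per-frame lateral random-walk step (Angstrom).
#' @param lateral_bound Lateral reflection bound (Angstrom).
#' @param seed RNG seed.
#' @param time_unit Time unit of \code{dt}.
#' @return An \code{aqp_trajectory} (topology species "W") with attribute
#'   \code{truth}: list with \code{D}, \code{expected_Dn} (per time unit),
#'   \code{crossings} (full pore traversals per the generator's own scan),
#'   and \code{seed}.
#' @export
make_brownian_trajectory <- function(n_molecules = 50, D = 1,
                                     pore_z = c(-10, 10), n_frames = 10000,
                                     dt = 0.01,
                                     boundary = c("reflect", "periodic",
                                                  "none"),
                                     z_range = NULL, drift = 0,
                                     start = c("uniform", "below"),
                                     lateral_step = 0.05, lateral_bound = 2,
                                     seed = 1L, time_unit = "ns") {
  boundary <- match.arg(boundary)
  start <- match.arg(start)
  if (dt <= 0) stop("dt must be positive")
  if (D <= 0) stop("diffusion constant must be positive")
  if (is.null(z_range)) z_range <- pore_z + c(-10, 10)
  L <- pore_z[2] - pore_z[1]
  reflect_into <- function(m, lo, hi) {
    p <- 2 * (hi - lo)
    y <- (m - lo) %% p
    lo + ifelse(y > hi - lo, p - y, y)
  }
  dat <- local_rng(seed, {
    z0 <- if (start == "uniform") runif(n_molecules, pore_z[1], pore_z[2])
          else rep(z_range[1], n_molecules)
    steps <- matrix(rnorm((n_frames - 1) * n_molecules, mean = drift * dt,
                          sd = sqrt(2 * D * dt)), n_frames - 1, n_molecules)
    zfree <- rbind(z0, sweep(apply(steps, 2, cumsum), 2, z0, "+"))
    x <- apply(matrix(rnorm(n_frames * n_molecules, sd = lateral_step),
                      n_frames, n_molecules), 2, cumsum)
    y <- apply(matrix(rnorm(n_frames * n_molecules, sd = lateral_step),
                      n_frames, n_molecules), 2, cumsum)
    list(zfree = zfree, x = reflect_into(x, -lateral_bound, lateral_bound),
         y = reflect_into(y, -lateral_bound, lateral_bound))
  })
  zfree <- dat$zfree
  z <- switch(boundary,
    reflect = reflect_into(zfree, pore_z[1], pore_z[2]),
    periodic = ((zfree - z_range[1]) %% (z_range[2] - z_range[1])) +
      z_range[1],
    none = zfree)
  dimnames(z) <- NULL
  coords <- array(NA_real_, c(n_frames, n_molecules, 3))
  coords[, , 1] <- dat$x
  coords[, , 2] <- dat$y
  coords[, , 3] <- z
  box <- if (boundary == "periodic")
    c(2 * lateral_bound + 2, 2 * lateral_bound + 2,
      z_range[2] - z_range[1]) else NULL
  topo <- data.frame(atom = seq_len(n_molecules), mol = seq_len(n_molecules),
                     species = "W", name = "OW")
  traj <- trajectory(times = dt * (seq_len(n_frames) - 1), coords = coords,
                     topology = topo, box = box, time_unit = time_unit)
  # generator-side traversal log on the unwrapped paths (no lateral gate)
  crossings <- 0L
  for (j in seq_len(n_molecules)) {
    side <- 0L
    for (zc in zfree[, j]) {
      s <- if (zc < pore_z[1]) -1L else if (zc > pore_z[2]) 1L else 0L
      if (s != 0L) {
        if (side != 0L && s != side) crossings <- crossings + 1L
        side <- s
      }
    }
  }
  attr(traj, "truth") <- list(D = D, expected_Dn = n_molecules * D / L^2,
                              crossings = crossings, pore_z = pore_z,
                              seed = seed)
  traj
}

#' Umbrella-sampling windows drawn from a known free-energy profile
#'
#' Exact (rejection) sampling from the biased Boltzmann density
#' exp(-(G(z) + k/2 (z - c)^2) / RT) for each window centre c, using the
#' harmonic bias as the proposal envelope.
#'
#' @param pmf_fn Function z -> G(z) in kJ/mol (the ground-truth profile).
#' @param centers Window centres covering the coordinate range.
#' @param spring_k Spring constant (kJ mol^-1 Angstrom^-2, > 0).
#' @param n_per_window Samples per window.
#' @param temperature Temperature (K).
#' @param seed RNG seed.
#' @return List of \code{\link{umbrella_window}} objects with attribute
#'   \code{truth} (the pmf function, parameters and seed).
#' @export
make_umbrella_samples <- function(pmf_fn, centers, spring_k,
                                  n_per_window = 2000, temperature = 298,
                                  seed = 1L) {
  if (spring_k <= 0) stop("spring constant must be positive")
  RT <- .R_kJ * temperature
  sigma <- sqrt(RT / spring_k)
  zgrid <- seq(min(centers) - 4 * sigma, max(centers) + 4 * sigma,
               length.out = 2001)
  gmin <- min(pmf_fn(zgrid))
  windows <- local_rng(seed, {
    lapply(centers, function(ctr) {
      out <- numeric(0)
      while (length(out) < n_per_window) {
        prop <- rnorm(2 * n_per_window, ctr, sigma)
        acc <- runif(length(prop)) < exp(-(pmf_fn(prop) - gmin) / RT)
        out <- c(out, prop[acc])
      }
      umbrella_window(ctr, spring_k, out[seq_len(n_per_window)])
    })
  })
  attr(windows, "truth") <- list(pmf_fn = pmf_fn, centers = centers,
                                 spring_k = spring_k,
                                 temperature = temperature, seed = seed)
  windows
}

#' Synthetic single-exponential stopped-flow trace
#'
#' @param k True rate constant (s^-1, > 0).
#' @param amplitude,offset Signal amplitude and baseline.
#' @param noise_sd Gaussian noise standard deviation (signal units).
#' @param n_points Number of points (>= 10).
#' @param t_max Trace duration (default 5 / k, five time constants).
#' @param direction "rising" or "falling".
#' @param channel Trace channel label.
#' @param seed RNG seed.
#' @return An \code{\link{sf_trace}} with attribute \code{truth}.
#' @export
make_trace <- function(k, amplitude = 1, offset = 0, noise_sd = 0,
                       n_points = 200, t_max = NULL,
                       direction = c("rising", "falling"),
                       channel = "fluorescence", seed = 1L) {
  direction <- match.arg(direction)
  if (k <= 0) stop("rate constant must be positive")
  if (n_points < 10) stop("a trace needs at least 10 points")
  if (is.null(t_max)) t_max <- 5 / k
  times <- seq(0, t_max, length.out = n_points)
  s <- if (direction == "rising") amplitude * (1 - exp(-k * times)) + offset
       else amplitude * exp(-k * times) + offset
  if (noise_sd > 0)
    s <- s + local_rng(seed, rnorm(n_points, sd = noise_sd))
  tr <- sf_trace(times, s, channel = channel,
                 meta = list(true_k = k, noise_sd = noise_sd, seed = seed))
  attr(tr, "truth") <- list(k = k, amplitude = amplitude, offset = offset,
                            noise_sd = noise_sd, seed = seed)
  tr
}

#' Synthetic AtTIP2;1-like reference sequence
#'
#' A synthetic 250-residue stand-in for the AtTIP2;1 sequence carrying the
#' published anchor residues of the extended selectivity filter -- His63
#' (H2P), His131 (LCP), Ile185 (H5P), Gly194 (LEP), Arg200 (HEP) -- and the
#' two NPA motifs with asparagines at residues 83 and 197.  It is not the
#' natural sequence; everything between the anchors is filler with a
#' membrane-protein-like composition, and it contains exactly two N-P-[AST]
#' motifs and exactly two histidines.
#'
#' @return A \code{sequence_record}.
#' @export
tip2_like_sequence <- function() {
  seqstr <- paste0(
    "IVASATMVVGIVLILAAWLAAVSLLLVVIASTTAYGVLLILTAATVGGWA",
    "WASYAAGGSYILHLYMAGVMVLGGTSVLMASVNPAYLLGGVIILAAVVAV",
    "SAIATLLVLTMGLLSLLLLWAMISVLLAVLHWSGLSIVLAGAAITYAAAL",
    "GLLAGLMTVYMGLSLALIIAMYILGAMIISMLGMITGGWLVLYGGLNPAR",
    "LAATTLAALISSLYWILATTSGMGSVVGTVWTIGIASMAGISSYTLITYA")
  sequence_record("AtTIP2;1-like (synthetic)", seqstr)
}

#' Point-substitute residues in a sequence record
#'
#' @param record A \code{sequence_record}.
#' @param pos Integer positions (1-based).
#' @param aa Replacement one-letter amino acids (recycled).
#' @return A new \code{sequence_record} with a mutation-tagged id.
#' @export
mutate_sequence <- function(record, pos, aa) {
  s <- strsplit(record$residues, "")[[1]]
  aa <- rep_len(toupper(aa), length(pos))
  tags <- paste0(s[pos], pos, aa)
  s[pos] <- aa
  sequence_record(paste0(record$id, " ", paste(tags, collapse = "+")),
                  paste(s, collapse = ""))
}

# -- published fixtures -------------------------------------------------------

#' Published yeast transport rates (raw specificity-table input)
#'
#' Raw single-exponential transport rates (+/- standard error of the fit)
#' for ammonia (unit 1e-2 s^-1) and water (s^-1) measured in yeast
#' expressing AtTIP2;1, wild-type human AQP1, HsAQP1 selectivity-filter
#' mutants, or carrying the empty vector (the background row).  Input for
#' \code{\link{build_specificity_table}}.
#'
#' @return Data frame with columns \code{construct}, \code{filter_code},
#'   \code{ammonia_rate}, \code{ammonia_se}, \code{water_rate},
#'   \code{water_se}, \code{is_background}.
#' @export
reference_transport_rates <- function() {
  read.csv(system.file("extdata", "yeast_transport_rates.csv",
                       package = "aqpscope"),
           stringsAsFactors = FALSE)
}

#' Published filter codes with growth-complementation outcomes
#'
#' The 14 selectivity-filter codes (order H2P, LCP, H5P, LEP, HEP) of the
#' AtTIP2;1 and HsAQP1 constructs assayed for ammonia-uptake growth
#' complementation, with the observed +/- outcome.  Three HsAQP1 constructs
#' (H180I, N127H+H180I, and the F56H+N127H+H180I triple) are marked
#' \code{in_vivo_exception}: despite in-vitro ammonia transport they failed
#' to complement, attributed to insufficient water permeability.
#'
#' @return Data frame with columns \code{construct}, \code{host},
#'   \code{code}, \code{complementation}, \code{in_vivo_exception}.
#' @export
reference_complementation <- function() {
  read.csv(system.file("extdata", "complementation_codes.csv",
                       package = "aqpscope"),
           stringsAsFactors = FALSE)
}
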