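test_that("a linear traversal is exactly one +z event", {
  z <- seq(-20, 20, length.out = 100)
  coords <- array(0, c(100, 1, 3)); coords[, 1, 3] <- z
  tr <- toy_traj(coords)
  ev <- count_permeations(tr, lab_axis(), c(-10, 10), lateral_radius = 5)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, "+z")
  expect_lt(ev$t_enter, ev$t_exit)
})

test_that("oscillation inside the bounds produces no events", {
  z <- 5 * sin(seq(0, 20 * pi, length.out = 500))
  coords <- array(0, c(500, 1, 3)); coords[, 1, 3] <- z
  ev <- count_permeations(toy_traj(coords), lab_axis(), c(-10, 10))
  expect_equal(nrow(ev), 0L)
})

test_that("a path that leaves the lateral corridor is not an event", {
  n <- 50
  coords <- array(0, c(n, 1, 3))
  coords[, 1, 3] <- seq(-20, 20, length.out = n)
  coords[25, 1, 1] <- 8  # darts sideways mid-channel
  ev <- count_permeations(toy_traj(coords), lab_axis(), c(-10, 10),
                          lateral_radius = 5)
  expect_equal(nrow(ev), 0L)
  # without the lateral gate the traversal counts
  ev2 <- count_permeations(toy_traj(coords), lab_axis(), c(-10, 10))
  expect_equal(nrow(ev2), 1L)
})

test_that("event counting matches the per-frame state-machine oracle", {
  tr <- make_brownian_trajectory(n_molecules = 50, D = 5, pore_z = c(-5, 5),
                                 n_frames = 10000, dt = 0.01,
                                 boundary = "none", z_range = c(-30, 30),
                                 lateral_step = 0.3, lateral_bound = 3,
                                 seed = 42)
  ax <- lab_axis()
  for (lat in c(Inf, 2.5)) {
    ev <- count_permeations(tr, ax, c(-5, 5), lateral_radius = lat)
    loc <- aqpscope:::traj_axis_coords(tr, ax)
    expect_equal(nrow(ev),
                 oracle_count_events(loc$z, loc$r, -5, 5,
                                     lateral_radius = lat))
  }
})

test_that("wrapped coordinates without box information raise an unwrap error", {
  tr <- make_brownian_trajectory(n_molecules = 5, D = 20, pore_z = c(-5, 5),
                                 n_frames = 2000, dt = 0.05,
                                 boundary = "periodic", z_range = c(-8, 8),
                                 seed = 9)
  tr_nobox <- tr; tr_nobox$box <- NULL
  expect_error(count_permeations(tr_nobox, lab_axis(), c(-5, 5)), "wrapped")
  # with the box present unwrapping works
  expect_s3_class(count_permeations(tr, lab_axis(), c(-5, 5)),
                  "permeation_events")
})

test_that("collective D_n recovers N D / L^2 for Brownian walkers", {
  tr <- make_brownian_trajectory(n_molecules = 50, D = 1, pore_z = c(-10, 10),
                                 n_frames = 1e5, dt = 0.01,
                                 boundary = "periodic", z_range = c(-10, 10),
                                 seed = 101)
  est <- collective_pf(tr, lab_axis(), c(-10, 10), window_length = 1)
  truth <- attr(tr, "truth")$expected_Dn
  expect_lt(abs(est$D_n_native / truth - 1), 0.15)
  expect_equal(est$pf, est$v_w * est$D_n)
  expect_gt(nrow(est$windows), 10)
})

test_that("pf is zero for frozen waters and linear in the water volume", {
  coords <- array(rep(seq(-8, 8, length.out = 20), each = 50), c(50, 20, 3))
  coords[, , 1] <- 0; coords[, , 2] <- 0
  tr <- toy_traj(coords, dt = 0.1)
  est <- collective_pf(tr, lab_axis(), c(-10, 10), window_length = 2)
  expect_equal(est$pf, 0)
  tr2 <- make_brownian_trajectory(n_molecules = 10, D = 1,
                                  pore_z = c(-10, 10), n_frames = 2000,
                                  dt = 0.01, seed = 5)
  a <- collective_pf(tr2, lab_axis(), c(-10, 10), window_length = 5,
                     v_w = 2.99e-23)
  b <- collective_pf(tr2, lab_axis(), c(-10, 10), window_length = 5,
                     v_w = 2 * 2.99e-23)
  expect_equal(b$pf, 2 * a$pf)
})

test_that("hydrogen bonds are counted by the geometric criterion", {
  # solute: N donor with one H; partner: acceptor O.  100 frames scripted
  # with the pair bonded in a 30% duty cycle.
  nf <- 100
  coords <- array(0, c(nf, 3, 3))
  on <- rep(c(rep(TRUE, 3), rep(FALSE, 7)), 10)
  coords[, 1, 1] <- 0                       # N at origin, z = 2 bin
  coords[, 1, 3] <- 2.2
  coords[, 2, 1] <- 1.0                     # H along +x
  coords[, 2, 3] <- 2.2
  coords[, 3, 1] <- ifelse(on, 2.9, 6.0)    # acceptor O
  coords[, 3, 3] <- 2.2
  top <- data.frame(atom = 1:3, mol = c(1, 1, 2),
                    species = c("S", "S", "P"),
                    name = c("N", "H1", "O"),
                    element = c("N", "H", "O"), resno = c(1, 1, 131))
  tr <- toy_traj(coords, topology = top)
  triples <- data.frame(donor = 1L, h = 2L, acceptor = 3L, partner = "LCP")
  prof <- hbond_profile(tr, triples, solute_atom = 1, axis = lab_axis(),
                        bin_width = 1)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$mean_count, 0.3)
  # ideal 2.9 A / 180 degree geometry counts, 4.0 A does not
  coords2 <- coords[1:2, , , drop = FALSE]
  coords2[2, 3, 1] <- 4.0
  tr2 <- toy_traj(coords2, topology = top)
  prof2 <- hbond_profile(tr2, triples, 1, lab_axis(), bin_width = 1)
  expect_equal(prof2$mean_count, 0.5)  # bonded in frame 1 only
  # bent geometry fails the angle cutoff
  coords3 <- coords[1, , , drop = FALSE]
  coords3[1, 3, 1] <- 1.0; coords3[1, 3, 2] <- 2.9  # 90 degrees at H
  tr3 <- toy_traj(coords3, topology = top)
  prof3 <- hbond_profile(tr3, triples, 1, lab_axis(), bin_width = 1)
  expect_equal(prof3$mean_count, 0)
  # triple enumeration finds the N-H...O pair, and flags missing hydrogens
  tt <- hbond_triples(tr, solute_atoms = 1:2, partners = list(LCP = 3))
  expect_equal(nrow(tt), 1L)
  expect_equal(unlist(tt[1, 1:3], use.names = FALSE), c(1L, 2L, 3L))
  trH <- data.frame(donor = 1L, h = NA_integer_, acceptor = 3L,
                    partner = "LCP")
  expect_error(hbond_profile(tr, trH, 1, lab_axis()), "hydrogens")
})

test_that("density grids integrate to the mean particle count", {
  # one static particle: all density in a single voxel
  coords <- array(0, c(5, 1, 3))
  coords[, 1, ] <- matrix(rep(c(0.5, 0.5, 0.5), each = 5), 5, 3)
  g <- density_grid(toy_traj(coords), voxel = 1,
                    bounds = rbind(c(0, 0, 0), c(3, 3, 3)))
  expect_equal(grid_integral(g), 1, tolerance = 1e-9)
  expect_equal(sum(g$grid > 0), 1L)
  # uniform cloud: integral conserved across voxel sizes
  set.seed(8)
  nf <- 40; na <- 200
  u <- array(runif(nf * na * 3, 0, 10), c(nf, na, 3))
  tr <- toy_traj(u)
  b <- rbind(c(0, 0, 0), c(10, 10, 10))
  g1 <- density_grid(tr, voxel = 1, bounds = b)
  g2 <- density_grid(tr, voxel = 2, bounds = b)
  expect_equal(grid_integral(g1), na, tolerance = 1e-6)
  expect_equal(grid_integral(g1), grid_integral(g2), tolerance = 1e-9)
  # per-voxel density within 5 binomial SDs of the uniform expectation
  p <- 1 / 1000
  expected <- nf * na * p
  sd5 <- 5 * sqrt(nf * na * p * (1 - p))
  counts1 <- g1$grid * nf * 1^3
  expect_true(all(abs(counts1 - expected) <= sd5))
  expect_error(density_grid(tr, voxel = 0), "positive")
})

test_that("chi1 dihedrals match constructed geometry and bio3d", {
  place <- function(theta) {
    coords <- array(0, c(1, 4, 3))
    coords[1, 1, ] <- c(1.4, 0, -0.5)                 # N
    coords[1, 2, ] <- c(0, 0, 0)                      # CA
    coords[1, 3, ] <- c(0, 0, 1.5)                    # CB
    coords[1, 4, ] <- c(cos(theta * pi / 180) * 1.4,
                        sin(theta * pi / 180) * 1.4, 2.0)  # CG
    coords
  }
  top <- data.frame(atom = 1:4, mol = 1, name = c("N", "CA", "CB", "CG"),
                    resno = 131)
  for (theta in c(60, -60, 175)) {
    tr <- toy_traj(place(theta), topology = top)
    res <- chi1_populations(tr, 131)
    ref <- bio3d::torsion.xyz(as.vector(t(tr$coords[1, , ])), atm.inc = 4)
    expect_equal(abs(res$angles[1]), abs(theta), tolerance = 0.1)
    expect_equal(res$angles[1], ref[1], tolerance = 0.1,
                 ignore_attr = TRUE)
  }
  # mirror image flips the sign
  tr60 <- toy_traj(place(60), topology = top)
  mir <- tr60; mir$coords[, , 2] <- -mir$coords[, , 2]
  expect_equal(chi1_populations(mir, 131)$angles[1],
               -chi1_populations(tr60, 131)$angles[1], tolerance = 1e-9)
  # scripted two-state trajectory: transition count equals the script
  nf <- 100
  thetas <- ifelse(((seq_len(nf) - 1) %/% 10) %% 2 == 0, 60, 180)
  coords <- array(0, c(nf, 4, 3))
  for (i in seq_len(nf)) coords[i, , ] <- place(thetas[i])[1, , ]
  tr <- toy_traj(coords, topology = top)
  res <- chi1_populations(tr, 131)
  expect_equal(res$transitions, 9L)
  expect_equal(unname(res$populations[c("g+", "t")]), c(0.5, 0.5),
               ignore_attr = TRUE)
  expect_error(chi1_populations(toy_traj(coords[, 1:3, , drop = FALSE],
                                         topology = top[1:3, ]), 131),
               "missing atom")
})

test_that("WHAM recovers flat and harmonic reference profiles", {
  flat <- make_umbrella_samples(function(z) 0 * z, centers = seq(-5, 5, 1),
                                spring_k = 2, n_per_window = 6000, seed = 2)
  pmf <- wham_pmf(flat, grid = seq(-5, 5, by = 0.5))
  g <- pmf$G[is.finite(pmf$G)]
  expect_lt(diff(range(g)), 0.5)
  a <- 0.5
  harm <- make_umbrella_samples(function(z) 0.5 * a * z^2,
                                centers = seq(-8, 8, 1), spring_k = 4,
                                n_per_window = 2000, seed = 3)
  pmf2 <- wham_pmf(harm, grid = seq(-8, 8, length.out = 121))
  sel <- abs(pmf2$z) <= 6 & is.finite(pmf2$G)
  curv <- coef(lm(G ~ I(0.5 * z^2), data = pmf2[sel, ]))[2]
  expect_lt(abs(curv / a - 1), 0.10)
  # doubling the sample count shrinks the flat-profile error (same seed)
  rms <- function(n) {
    w <- make_umbrella_samples(function(z) 0 * z, centers = seq(-5, 5, 1),
                               spring_k = 2, n_per_window = n, seed = 4)
    p <- wham_pmf(w, grid = seq(-5, 5, by = 0.5))
    sqrt(mean(p$G[is.finite(p$G)]^2))
  }
  expect_lt(rms(4000), rms(1000))
})

test_that("WHAM rejects non-overlapping windows and reports non-convergence", {
  set.seed(1)
  w1 <- umbrella_window(0, 50, rnorm(100, 0, 0.1))
  w2 <- umbrella_window(10, 50, rnorm(100, 10, 0.1))
  expect_error(wham_pmf(list(w1, w2)), "overlap")
  set.seed(2)
  w3 <- umbrella_window(0.5, 50, rnorm(200, 0.5, 0.3))
  w4 <- umbrella_window(1.0, 50, rnorm(200, 1.0, 0.3))
  expect_error(wham_pmf(list(w1, w3, w4), tol = 1e-12, max_iter = 2),
               "converge")
})

test_that("barrier heights read off PMF profiles correctly", {
  z <- seq(-10, 10, 0.1)
  bump <- function(h) data.frame(z = z, G = h * exp(-z^2 / 4))
  expect_equal(barrier_height(bump(15), c(-3, 3)), 15, tolerance = 0.01)
  flat <- data.frame(z = z, G = 0 * z)
  expect_equal(barrier_height(flat, c(-3, 3)), 0)
  dw <- data.frame(z = z, G = 4 * (((z / 3)^2 - 1)^2))
  expect_equal(barrier_height(dw, c(-1, 1)), 4, tolerance = 0.01)
  expect_error(barrier_height(flat, c(50, 60)), "no PMF grid points")
})

test_that("the 15 vs 20 kJ/mol barrier difference is an order of magnitude", {
  z <- seq(-10, 10, 0.05)
  pmf_channel <- data.frame(z = z, G = 15 * exp(-z^2 / 4))
  pmf_membrane <- data.frame(z = z, G = 20 * exp(-z^2 / 4))
  b1 <- barrier_height(pmf_channel, c(-4, 4))
  b2 <- barrier_height(pmf_membrane, c(-4, 4))
  ratio <- permeability_ratio(b2, b1)
  expect_equal(ratio, exp((20 - 15) * 1000 / (8.314 * 298)),
               tolerance = 1e-3)
  expect_gt(ratio, 5)
  expect_lt(ratio, 12)
})

test_that("trajectories round-trip through the frame-matrix CSV dialect", {
  tr <- make_brownian_trajectory(n_molecules = 4, D = 1, pore_z = c(-5, 5),
                                 n_frames = 20, dt = 0.1,
                                 boundary = "periodic", seed = 6)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(back$coords, tr$coords, tolerance = 1e-9)
  expect_equal(back$times, tr$times)
  expect_equal(back$topology$mol, tr$topology$mol)
  expect_equal(back$box, tr$box, ignore_attr = TRUE)
})
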