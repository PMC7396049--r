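test_that("flat-potential Boltzmann sampling is uniform along z", {
  sc <- channel_scenario(potential_flat(), n_waters = 1000, n_frames = 100,
                         seed = 101)
  traj <- sample_boltzmann_trajectory(sc)
  z <- as.vector(traj$coords[, 3, ])
  counts <- table(cut(z, breaks = seq(-40, 40, by = 4)))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
  # x,y stay inside the counting cylinder
  r <- sqrt(traj$coords[, 1, ]^2 + traj$coords[, 2, ]^2)
  expect_lte(max(r), sc$counting_radius)
})

test_that("Gaussian barrier depletes density by the Boltzmann factor", {
  H <- 1
  sc <- channel_scenario(potential_gaussians(H, center = 0, sigma = 4),
                         n_waters = 5000, n_frames = 100, seed = 102)
  traj <- sample_boltzmann_trajectory(sc)
  z <- as.vector(traj$coords[, 3, ])
  at0 <- sum(abs(z) < 0.5)
  bulk <- sum(z > -36 & z < -30) / 6
  expected <- exp(-H / thermal_energy(sc$temperature))
  expect_lt(abs(at0 / bulk - expected) / expected, 0.10)
})

test_that("generation is bit-identical under the same seed", {
  sc <- channel_scenario(potential_gaussians(2), n_waters = 200,
                         n_frames = 10, seed = 7)
  expect_identical(sample_boltzmann_trajectory(sc)$coords,
                   sample_boltzmann_trajectory(sc)$coords)
  expect_identical(simulate_langevin_1d(sc)$coords,
                   simulate_langevin_1d(sc)$coords)
})

test_that("non-normalizable potential is rejected", {
  bad <- structure(function(z) -Inf * (abs(z) < 5), class = "function")
  sc <- channel_scenario(bad, n_waters = 10, n_frames = 1, seed = 1)
  expect_error(sample_boltzmann_trajectory(sc),
               class = "aquaflux_scenario_error")
})

test_that("Langevin sampler matches the closed-form harmonic variance", {
  k <- 1
  sc <- channel_scenario(potential_harmonic(k), box_z = c(-40, 40),
                         n_waters = 200, n_frames = 500, seed = 103)
  traj <- simulate_langevin_1d(sc, friction = 1, dt = 0.02,
                               steps_per_frame = 10, burn_in = 500)
  z <- as.vector(traj$coords[, 3, ])
  expect_equal(length(z), 1e5)
  target <- thermal_energy(sc$temperature) / k
  expect_lt(abs(stats::var(z) - target) / target, 0.10)
})

test_that("Langevin walkers collect at the minimum as T -> 0", {
  sc <- channel_scenario(potential_harmonic(1, center = 2), temperature = 1,
                         n_waters = 100, n_frames = 50, seed = 104)
  traj <- simulate_langevin_1d(sc, friction = 1, dt = 0.02, burn_in = 2000)
  z <- as.vector(traj$coords[, 3, ])
  expect_lt(stats::sd(z), 0.2)
  expect_lt(abs(mean(z) - 2), 0.1)
})

test_that("unstable Langevin step is rejected", {
  sc <- channel_scenario(n_waters = 10, n_frames = 5, seed = 1)
  expect_error(simulate_langevin_1d(sc, friction = 10, dt = 0.5),
               class = "aquaflux_parameter_error")
})

test_that("both generators agree on the stationary z distribution", {
  # flat potential: the Euler-Maruyama step has no drift term, so the
  # reflected walk is exactly uniform and the two histograms must agree
  sc_b <- channel_scenario(potential_flat(), box_z = c(-10, 10),
                           z_lo = -5, z_hi = 5, n_waters = 200,
                           n_frames = 100, seed = 105)
  sc_l <- channel_scenario(potential_flat(), box_z = c(-10, 10),
                           z_lo = -5, z_hi = 5, n_waters = 200,
                           n_frames = 100, seed = 106)
  zb <- as.vector(sample_boltzmann_trajectory(sc_b)$coords[, 3, ])
  zl <- as.vector(simulate_langevin_1d(sc_l, friction = 0.05, dt = 0.5,
                                       steps_per_frame = 40,
                                       burn_in = 400)$coords[, 3, ])
  p <- suppressWarnings(stats::ks.test(zb, zl)$p.value)
  expect_gt(p, 0.01)
})

test_that("single-file fixture is an arithmetic chain anchored at z = 0", {
  traj <- build_single_file_fixture(2.8, c(-40, 40))
  z <- sort(frame_coords(traj, 1)[, 3])
  # multiples of 2.8 filling [-40, 40]: 14 on each side of 0, plus 0
  expect_equal(length(z), 29L)
  expect_equal(z, 2.8 * (-14:14), tolerance = 1e-12)
  expect_true(any(z == 0))
  # and exactly the members with |z| < 10 (strict) number 7
  expect_equal(sum(z > -10 & z < 10), 7L)

  expect_equal(n_atoms(build_single_file_fixture(25, c(-10, 10))), 1L)
  expect_error(build_single_file_fixture(0, c(-10, 10)),
               class = "aquaflux_input_error")
})

test_that("cylinder shell puts atoms at inner_radius + vdW from the axis", {
  traj <- build_cylinder_shell(4.5, c(-5, 5), element = "C")
  r <- sqrt(rowSums(frame_coords(traj, 1)[, 1:2]^2))
  expect_equal(r, rep(4.5 + vdw_radius("C"), length(r)), tolerance = 1e-9)
  expect_false(any(traj$atoms$is_water))
  expect_error(build_cylinder_shell(4.5, c(5, 5)),
               class = "aquaflux_input_error")
})

test_that("rigid perturbation: exact under Kabsch, noise scales as sigma*sqrt(3)", {
  set.seed(9)
  base <- toy_trajectory(water_z = seq(-8, 8, by = 2), n_frames = 1)
  R <- rotation_matrix(c(1, 2, 3), 1.1)
  moved <- perturb_structure(base, rotation = R, translation = c(4, -2, 1))
  fit <- kabsch_superpose(frame_coords(moved, 1), frame_coords(base, 1))
  expect_lt(fit$rmsd, 1e-6)

  n <- 10000
  big <- new_trajectory(
    tibble::tibble(serial = 1:n, name = "OH2", residue_name = "HOH",
                   chain_id = "W", residue_seq = 1:n, element = "O",
                   is_water = TRUE, vdw_radius = 1.52),
    array(rnorm(3 * n, sd = 5), c(n, 3, 1)))
  sigma <- 0.7
  noisy <- perturb_structure(big, noise_sd = sigma, seed = 42)
  nofit <- sqrt(mean(rowSums((frame_coords(noisy, 1) -
                                frame_coords(big, 1))^2)))
  expect_lt(abs(nofit - sigma * sqrt(3)) / (sigma * sqrt(3)), 0.05)
  # determinism of the noise under seed
  noisy2 <- perturb_structure(big, noise_sd = sigma, seed = 42)
  expect_identical(noisy$coords, noisy2$coords)
})
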