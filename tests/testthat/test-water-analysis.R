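# A trajectory whose per-frame water z positions are given explicitly:
# zs is a list with one numeric vector per frame (all frames same length).
waters_at <- function(zs) {
  nw <- length(zs[[1]])
  atoms <- tibble::tibble(
    serial = seq_len(nw), name = "OH2", residue_name = "HOH",
    chain_id = "W", residue_seq = seq_len(nw), element = "O",
    is_water = TRUE, vdw_radius = 1.52)
  coords <- array(0, c(nw, 3, length(zs)))
  for (f in seq_along(zs)) coords[, 3, f] <- zs[[f]]
  new_trajectory(atoms, coords, times = seq_along(zs) - 1)
}

test_that("density profile is the hand-computed time average over frames", {
  # one bin [0, 1) holding 2 waters in frame 1 and 4 in frame 2
  traj <- waters_at(list(c(0.2, 0.8, 5, 5), c(0.1, 0.4, 0.6, 0.9)))
  traj$coords[3:4, 3, 1] <- 5 # frame 1: two waters parked outside the bin
  spec <- channel_spec(z_lo = 0, z_hi = 1)
  prof <- density_profile(traj, spec, dz = 1, z_range = c(0, 1))
  expect_equal(prof$n_mean, 3) # (2 + 4) / 2 frames
  expect_equal(prof$density, 3) # N / dz with dz = 1
})

test_that("bins never visited have zero density; no waters warns", {
  traj <- waters_at(list(c(-5, 5), c(-5, 5)))
  prof <- density_profile(traj, channel_spec(), dz = 1)
  expect_equal(prof$density[prof$z_center == 0.5], 0)

  dry <- toy_trajectory(with_protein = TRUE)
  dry$atoms$is_water[] <- FALSE
  expect_warning(p0 <- density_profile(dry, channel_spec(), dz = 1))
  expect_true(all(p0$density == 0))
})

test_that("counts are conserved: sum of bin averages = mean in-region total", {
  sc <- channel_scenario(potential_gaussians(1.5), n_waters = 300,
                         n_frames = 40, seed = 51)
  traj <- sample_boltzmann_trajectory(sc)
  spec <- scenario_spec(sc)
  prof <- density_profile(traj, spec, dz = 1, z_range = c(-40, 40))
  z <- traj$coords[, 3, ]
  in_region <- z >= -40 & z < 40 # all waters are inside the cylinder here
  expect_equal(sum(prof$n_mean), mean(colSums(in_region)))
})

test_that("halving the resolution merges bins exactly", {
  # 32 frames: counts / 32 is exact in binary, so the merge identity is
  # bitwise, not just approximate
  sc <- channel_scenario(n_waters = 200, n_frames = 32, seed = 52)
  traj <- sample_boltzmann_trajectory(sc)
  spec <- scenario_spec(sc)
  fine <- density_profile(traj, spec, dz = 1, z_range = c(-40, 40))
  coarse <- density_profile(traj, spec, dz = 2, z_range = c(-40, 40))
  merged <- fine$n_mean[seq(1, 79, by = 2)] + fine$n_mean[seq(2, 80, by = 2)]
  expect_identical(coarse$n_mean, merged)
})

test_that("the time average is invariant under frame permutation", {
  sc <- channel_scenario(n_waters = 100, n_frames = 20, seed = 53)
  traj <- sample_boltzmann_trajectory(sc)
  spec <- scenario_spec(sc)
  prof <- density_profile(traj, spec, dz = 2, z_range = c(-40, 40))
  perm <- traj
  perm$coords <- traj$coords[, , sample(20), drop = FALSE]
  prof_p <- density_profile(perm, spec, dz = 2, z_range = c(-40, 40))
  expect_identical(prof$n_mean, prof_p$n_mean)
})

test_that("radial gating excludes waters outside the counting cylinder", {
  traj <- waters_at(list(c(0.5, 0.5)))
  traj$coords[2, 1, 1] <- 10 # second water 10 A off axis
  prof <- density_profile(traj, channel_spec(counting_radius = 6), dz = 1)
  expect_equal(prof$n_mean[prof$z_center == 0.5], 1)
})

test_that("single-file detection: canonical chain, broken chain, empty channel", {
  spec <- channel_spec()
  chain <- build_single_file_fixture(2.8, c(-40, 40), spec = spec)
  rep1 <- detect_single_file(chain, spec, hb_cutoff = 3.5)
  expect_equal(rep1$n_file, 7L)
  z <- rep1$chain_z[[1]]
  expect_equal(z, sort(z))
  expect_true(all(diff(z) <= 3.5))
  expect_true(all(z > -10 & z < 10))

  sparse <- build_single_file_fixture(5, c(-40, 40), spec = spec)
  rep2 <- detect_single_file(sparse, spec, hb_cutoff = 3.5)
  expect_equal(rep2$n_file, 1L) # every run is a single water

  empty <- waters_at(list(c(30, 35))) # nothing inside the channel
  rep3 <- detect_single_file(empty, spec, hb_cutoff = 3.5)
  expect_equal(rep3$n_file, 0L)
})

test_that("the longest hydrogen-bonded run wins, gaps split chains", {
  spec <- channel_spec()
  # run of 3 below the gap, run of 2 above it
  traj <- waters_at(list(c(-6, -3.5, -1, 4, 6.5)))
  rep <- detect_single_file(traj, spec, hb_cutoff = 3)
  expect_equal(rep$n_file, 3L)
  expect_equal(rep$chain_z[[1]], c(-6, -3.5, -1))
})
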