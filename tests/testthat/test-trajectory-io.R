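test_that("multi-MODEL PDB reading: frames, atoms, water flags, elements", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(path, models = 2, atoms_per_model = 10)
  traj <- read_pdb_trajectory(path)
  expect_equal(n_frames(traj), 2L)
  expect_equal(n_atoms(traj), 10L)
  expect_equal(sum(traj$atoms$is_water), 5L)
  oh2 <- traj$atoms[traj$atoms$name == "OH2", ]
  expect_true(all(oh2$is_water))
  expect_true(all(oh2$element == "O"))
  # alpha carbons in ALA are carbon, not calcium
  expect_true(all(traj$atoms$element[traj$atoms$name == "CA"] == "C"))
  expect_true(all(traj$atoms$vdw_radius > 0))
})

test_that("degenerate PDB inputs raise format errors", {
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), empty)
  expect_error(read_pdb_trajectory(empty), class = "aquaflux_format_error")

  no_atoms <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    TEST", "END"), no_atoms)
  expect_error(read_pdb_trajectory(no_atoms), class = "aquaflux_format_error")

  uneven <- withr::local_tempfile(fileext = ".pdb")
  lines <- pdb_fixture_lines(models = 2, atoms_per_model = 6)
  lines <- lines[-3] # drop one atom from MODEL 1
  writeLines(lines, uneven)
  expect_error(read_pdb_trajectory(uneven), class = "aquaflux_format_error")
})

test_that("PDB write -> read round trip preserves coordinates and identity", {
  traj <- toy_trajectory(water_z = c(-2.25, 0.125, 3), n_frames = 3,
                         frame_shift = 0.5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_trajectory(traj, path)
  back <- read_pdb_trajectory(path)
  expect_equal(n_frames(back), 3L)
  expect_equal(back$atoms$serial, traj$atoms$serial)
  expect_equal(back$atoms$name, traj$atoms$name)
  expect_equal(back$atoms$residue_name, traj$atoms$residue_name)
  expect_equal(back$atoms$is_water, traj$atoms$is_water)
  expect_lt(max(abs(back$coords - traj$coords)), 1e-3)
})

test_that("XYZ reading, round trip and header-mismatch error", {
  traj <- toy_trajectory(water_z = c(-5, 0, 5), n_frames = 2,
                         frame_shift = 0.25, with_protein = FALSE)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(traj, path)
  back <- read_xyz_trajectory(path)
  expect_equal(n_frames(back), 2L)
  expect_equal(n_atoms(back), 3L)
  expect_true(all(back$atoms$is_water))
  expect_lt(max(abs(back$coords - traj$coords)), 1e-3)
  expect_equal(back$times, traj$times)

  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("4", "frame 0", "O 0 0 0", "O 1 0 0", "O 2 0 0"), bad)
  expect_error(read_xyz_trajectory(bad), class = "aquaflux_format_error")
})

test_that("XYZ water identification respects the protein-atom prefix", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("4", "frame 0", "C 0 0 0", "O 0 0 1", "O 0 0 5", "O 0 0 8"),
             path)
  traj <- read_xyz_trajectory(path, n_protein_atoms = 2)
  expect_equal(traj$atoms$is_water, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("atom selections compose: heavy + hydrogens = all", {
  atoms <- tibble::tibble(
    serial = 1:6, name = c("N", "H", "CA", "HA", "OH2", "H1"),
    residue_name = c("ALA", "ALA", "ALA", "ALA", "HOH", "HOH"),
    chain_id = c("A", "A", "A", "A", "W", "W"),
    residue_seq = c(1L, 1L, 1L, 1L, 2L, 2L),
    element = c("N", "H", "C", "H", "O", "H"),
    is_water = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    vdw_radius = vdw_radius(c("N", "H", "C", "H", "O", "H"))
  )
  traj <- new_trajectory(atoms, array(rnorm(18), c(6, 3, 1)))
  n_all <- length(select_atoms(traj, "all"))
  n_heavy <- length(select_atoms(traj, "heavy"))
  n_h <- length(select_atoms(traj, function(a) toupper(a$element) == "H"))
  expect_equal(n_heavy + n_h, n_all)
  expect_equal(select_atoms(traj, "water_oxygen"), 5L)
  # all four protein atoms here are backbone names, so no sidechain atoms
  expect_length(select_atoms(traj, "sidechain"), 0L)
})

test_that("profile CSV/JSON writing: row counts, sentinels, exact round trip", {
  sc <- channel_scenario(n_waters = 50, n_frames = 10, seed = 3)
  dens <- density_profile(sample_boltzmann_trajectory(sc), scenario_spec(sc),
                          dz = 1, z_range = c(-10, 10))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_profile(dens, csv, "csv")
  back <- read_profile(csv)
  expect_equal(nrow(back), 20L)
  expect_identical(back$value, dens$density) # exact, not approximate

  # a masked free-energy bin is written as an explicit sentinel row
  dens2 <- dens
  dens2$density[3] <- 0
  dens2$n_mean[3] <- 0
  fep <- boltzmann_invert(dens2, z_A = 0)
  json <- withr::local_tempfile(fileext = ".json")
  write_profile(fep, json, "json")
  fb <- read_profile(json)
  expect_equal(nrow(fb), nrow(fep))
  expect_true(is.na(fb$dG[3]))
  expect_equal(fb$dG[-3], fep$dG[-3])
  expect_equal(attr(fb, "kBT"), attr(fep, "kBT"))
  expect_error(write_profile(fep[0, ], withr::local_tempfile()),
               class = "aquaflux_input_error")
})
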