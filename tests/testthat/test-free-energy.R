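make_profile <- function(density, z_centers = seq_along(density) - 0.5,
                         dz = 1, spec = NULL) {
  as_density_profile(tibble::tibble(z_center = z_centers, density = density),
                     dz = dz, spec = spec)
}

test_that("thermal energy: value, rounding, linearity, domain", {
  expect_equal(thermal_energy(298), 0.0019872041 * 298)
  expect_equal(round(thermal_energy(298), 1), 0.6)
  expect_equal(thermal_energy(596), 2 * thermal_energy(298))
  expect_error(thermal_energy(0), class = "aquaflux_input_error")
  expect_error(thermal_energy(-10), class = "aquaflux_input_error")
})

test_that("difference error is twice the thermal energy", {
  expect_equal(round(difference_error(298), 1), 1.2)
  expect_equal(difference_error(149), difference_error(298) / 2)
  for (T in c(100, 298, 400)) {
    expect_equal(difference_error(T), 2 * thermal_energy(T))
  }
})

test_that("Boltzmann inversion reproduces closed-form values", {
  kBT <- thermal_energy(298)
  # uniform density: dG identically zero
  fep0 <- boltzmann_invert(make_profile(rep(2, 10)), z_A = 0.5)
  expect_true(all(fep0$dG == 0))

  # density rho_A / e -> dG = kBT; ratio 1/2 -> kBT ln 2
  fep <- boltzmann_invert(make_profile(c(1, exp(-1), 0.5)), z_A = 0.5)
  expect_equal(fep$dG[2], kBT, tolerance = 1e-10)
  expect_equal(fep$dG[2], 0.5922, tolerance = 1e-4)
  expect_equal(fep$dG[3], kBT * log(2), tolerance = 1e-10)
  expect_equal(fep$dG[3], 0.4105, tolerance = 1e-4)
  # per-point and difference error bands
  expect_true(all(fep$error == kBT))
  expect_equal(attr(fep, "diff_error"), 2 * kBT)
})

test_that("reference handling: snap to bin, zero-density reference, default", {
  prof <- make_profile(c(1, 2, 3, 4), z_centers = c(0.5, 1.5, 2.5, 3.5))
  fep <- boltzmann_invert(prof, z_A = 1.4) # snaps to 1.5
  expect_equal(attr(fep, "z_A"), 1.5)
  expect_identical(fep$dG[2], 0)

  prof0 <- make_profile(c(1, 0, 3))
  expect_error(boltzmann_invert(prof0, z_A = 1.5),
               class = "aquaflux_reference_error")

  # default reference: populated bin nearest the cytoplasmic mouth
  spec <- channel_spec(z_lo = 0, z_hi = 4) # extracellular +z, mouth at 0
  profd <- make_profile(c(0, 2, 3, 4), z_centers = c(0.5, 1.5, 2.5, 3.5),
                        spec = spec)
  fepd <- boltzmann_invert(profd)
  expect_equal(attr(fepd, "z_A"), 1.5) # first *populated* bin from the mouth
})

test_that("empty bins are masked, never infinite; pseudocount unmasks", {
  prof <- make_profile(c(2, 0, 1))
  fep <- boltzmann_invert(prof, z_A = 0.5)
  expect_true(fep$masked[2])
  expect_true(is.na(fep$dG[2]))
  expect_false(any(is.infinite(fep$dG), na.rm = TRUE))

  fep_pc <- boltzmann_invert(prof, z_A = 0.5, pseudocount = 0.1)
  expect_false(any(fep_pc$masked))
  expect_true(is.finite(fep_pc$dG[2]))
})

test_that("changing the reference shifts dG by a constant", {
  set.seed(61)
  prof <- make_profile(runif(20, 0.1, 3))
  a <- boltzmann_invert(prof, z_A = 0.5)
  b <- boltzmann_invert(prof, z_A = 10.5)
  d <- a$dG - b$dG
  expect_lt(max(d) - min(d), 1e-9)
  # pairwise differences are reference-invariant
  expect_equal(a$dG[5] - a$dG[12], b$dG[5] - b$dG[12], tolerance = 1e-9)
})

test_that("dG scales exactly linearly with the inversion temperature", {
  prof <- make_profile(c(1, 0.5, 0.25, 1))
  cold <- boltzmann_invert(prof, z_A = 0.5, temperature = 298)
  hot <- boltzmann_invert(prof, z_A = 0.5, temperature = 596)
  expect_equal(hot$dG, 2 * cold$dG, tolerance = 1e-12)
})

test_that("barrier extraction: flat, argmax, ties, masked peak, errors", {
  spec <- channel_spec(z_lo = 0, z_hi = 6)
  flat <- boltzmann_invert(make_profile(rep(1, 6), spec = spec), z_A = 0.5)
  expect_equal(extract_barrier(flat, spec)$barrier_height, 0)

  prof <- make_profile(c(1, 0.5, 0.2, 0.5, 0.2, 1), spec = spec)
  fep <- boltzmann_invert(prof, z_A = 0.5)
  rep1 <- extract_barrier(fep, spec)
  expect_equal(rep1$barrier_height, thermal_energy(298) * log(5),
               tolerance = 1e-10)
  expect_equal(rep1$barrier_z, 2.5) # tie with z = 4.5 resolved to smaller z

  # masked peak bin: barrier computed from the remaining bins
  prof2 <- make_profile(c(1, 0.5, 0, 0.5, 0.25, 1), spec = spec)
  fep2 <- boltzmann_invert(prof2, z_A = 0.5)
  rep2 <- extract_barrier(fep2, spec)
  expect_equal(rep2$barrier_z, 4.5)

  # report at a user-supplied selectivity-filter position
  rep3 <- extract_barrier(fep, spec, sf_z = 4.3)
  expect_equal(rep3$sf_z, 4.5)
  expect_equal(rep3$dG_sf, fep$dG[5])

  all_masked <- boltzmann_invert(
    make_profile(c(1, 0, 0), z_centers = c(-20.5, 2.5, 3.5), dz = 1,
                 spec = channel_spec(z_lo = 0, z_hi = 6)), z_A = -20.5)
  expect_error(extract_barrier(all_masked),
               class = "aquaflux_analysis_error")
})

test_that("the reference bin is exactly zero on every inverted profile", {
  set.seed(62)
  for (i in 1:10) {
    prof <- make_profile(runif(30, 0.05, 5))
    zA <- sample(prof$z_center, 1)
    fep <- boltzmann_invert(prof, z_A = zA)
    expect_identical(fep$dG[fep$z_center == attr(fep, "z_A")], 0)
  }
})
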