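#' Thermal energy and free-energy difference uncertainty
#'
#' `thermal_energy()` returns `kB * T` in kcal/mol (kB =
#' 0.0019872041 kcal/(mol K)); at 298 K this is 0.592 kcal/mol, the
#' per-point uncertainty attached to every Boltzmann-inverted free-energy
#' value. `difference_error()` returns `2 kB T`, the bound on any
#' *difference* of two such values (two +/- kBT measurements subtracted),
#' 1.18 kcal/mol at 298 K.
#'
#' @param temperature Kelvin; must be > 0.
#' @return Energy in kcal/mol.
#' @export
#' @examples
#' thermal_energy(298)
#' difference_error(298)
thermal_energy <- function(temperature = 298) {
  check_number(temperature, "temperature")
  if (temperature <= 0) abort_input("`temperature` must be > 0 K.")
  .kB * temperature
}

#' @rdname thermal_energy
#' @export
difference_error <- function(temperature = 298) {
  2 * thermal_energy(temperature)
}

#' Boltzmann inversion of a density profile into a free-energy profile
#'
#' In an equilibrated isothermal ensemble the water density along the
#' channel is proportional to the Boltzmann weight of the free energy, so
#' the profile relative to a reference bin `z_A` is
#' `dG(z_i) = kBT * ln(rho(z_A) / rho(z_i))`, with `dG(z_A) = 0` exactly.
#' Bins with zero density are masked (`NA`), never mapped to infinity: the
#' inversion is undefined there and silently padding counts would bias
#' barriers. An optional pseudo-count (waters added to every bin's mean
#' count) is available for exploratory use but off by default.
#'
#' @param profile A [density_profile()] (or [as_density_profile()]) tibble.
#' @param z_A Reference axial position (Angstrom); snapped to the nearest
#'   bin center (recorded in the result). Default: the populated bin
#'   nearest the cytoplasmic channel mouth (the permeation "start"), i.e.
#'   the end of the channel extent opposite `extracellular_side`.
#' @param temperature Kelvin. Default 298.
#' @param pseudocount Waters added to every bin's `n_mean` before the
#'   ratio. Default 0.
#' @return Tibble of class `"free_energy_profile"`: `z_center`, `dG`
#'   (kcal/mol, `NA` where masked), `error` (+/- kBT per point), `masked`;
#'   attributes `z_A` (bin center used), `kBT`, `temperature`,
#'   `diff_error` (+/- 2 kBT for differences), `spec`, `dz`.
#' @export
#' @examples
#' sc <- channel_scenario(potential_gaussians(2), n_waters = 2000,
#'                        n_frames = 100, seed = 11)
#' traj <- sample_boltzmann_trajectory(sc)
#' dens <- density_profile(traj, scenario_spec(sc), z_range = c(-40, 40))
#' fep <- boltzmann_invert(dens, z_A = -35, temperature = 298)
#' extract_barrier(fep)
boltzmann_invert <- function(profile, z_A = NULL, temperature = 298,
                             pseudocount = 0) {
  if (!inherits(profile, "density_profile")) {
    profile <- as_density_profile(profile)
  }
  kBT <- thermal_energy(temperature)
  dz <- attr(profile, "dz")
  spec <- attr(profile, "spec")
  dens <- profile$density + pseudocount / (dz %||% 1)
  populated <- dens > 0
  if (!any(populated)) abort_reference("all bins are empty; nothing to invert.")
  if (is.null(z_A)) {
    if (!is.null(spec)) {
      mouth <- if (spec$side_sign > 0) spec$z_lo else spec$z_hi
    } else {
      mouth <- min(profile$z_center)
    }
    ref_idx <- which(populated)[which.min(abs(profile$z_center[populated] - mouth))]
  } else {
    check_number(z_A, "z_A")
    ref_idx <- which.min(abs(profile$z_center - z_A))
    if (!populated[ref_idx]) {
      abort_reference(sprintf(
        "reference bin at z = %.3g has zero density; pick a populated z_A.",
        profile$z_center[ref_idx]))
    }
  }
  dG <- ifelse(populated, kBT * log(dens[ref_idx] / dens), NA_real_)
  dG[ref_idx] <- 0 # exact, not up to rounding of the ratio
  out <- tibble(z_center = profile$z_center, dG = dG, error = kBT,
                masked = !populated)
  attr(out, "z_A") <- profile$z_center[ref_idx]
  attr(out, "kBT") <- kBT
  attr(out, "temperature") <- temperature
  attr(out, "diff_error") <- 2 * kBT
  attr(out, "spec") <- spec
  attr(out, "dz") <- dz
  class(out) <- c("free_energy_profile", class(out))
  out
}

#' Extract the permeation barrier from a free-energy profile
#'
#' The barrier height is the maximum unmasked `dG` inside the channel
#' extent, relative to the (zero) reference; its location is the argmax
#' (ties resolved toward the smallest z). When `sf_z` is supplied, the
#' profile value at the bin nearest the selectivity filter is reported
#' alongside, so both readings of "barrier at the SF" are available.
#'
#' @param profile A [boltzmann_invert()] result.
#' @param spec A [channel_spec()]; defaults to the one carried by the
#'   profile. Its `z_lo`/`z_hi` delimit the search.
#' @param sf_z Optional axial position of the selectivity filter
#'   (Angstrom), e.g. `sf_z` from [pore_radius_profile()].
#' @return One-row tibble of class `"barrier_report"`: `barrier_height`
#'   (kcal/mol), `barrier_z` (Angstrom), `dG_sf`, `sf_z`, `z_A`,
#'   `baseline`.
#' @export
extract_barrier <- function(profile, spec = NULL, sf_z = NULL) {
  spec <- spec %||% attr(profile, "spec")
  if (is.null(spec)) abort_input("no channel spec available; pass `spec`.")
  inside <- profile$z_center >= spec$z_lo & profile$z_center <= spec$z_hi &
    !profile$masked
  if (!any(inside)) {
    abort_analysis("all bins inside the channel extent are masked.")
  }
  zc <- profile$z_center[inside]
  dg <- profile$dG[inside]
  h <- max(dg)
  bz <- min(zc[dg >= h - 1e-12])
  dg_sf <- NA_real_
  sfz_used <- NA_real_
  if (!is.null(sf_z)) {
    k <- which.min(abs(profile$z_center - sf_z))
    sfz_used <- profile$z_center[k]
    dg_sf <- profile$dG[k]
  }
  out <- tibble(barrier_height = h, barrier_z = bz, dG_sf = dg_sf,
                sf_z = sfz_used, z_A = attr(profile, "z_A") %||% NA_real_,
                baseline = "dG relative to reference bin z_A (dG(z_A) = 0)")
  class(out) <- c("barrier_report", class(out))
  out
}
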