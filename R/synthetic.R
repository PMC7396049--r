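#' One-dimensional potentials for synthetic channel scenarios
#'
#' A potential is a vectorized function `U(z)` in kcal/mol with a
#' human-readable `description` attribute; generated scenarios construct
#' potentials that vanish in the bulk so the bulk density is the natural
#' reference. `potential_gaussians()` sums Gaussian bumps/wells (a barrier
#' is a positive height at the selectivity filter); `potential_harmonic()`
#' is a quadratic well used to validate the Langevin sampler against its
#' closed-form stationary variance; `potential_flat()` is zero everywhere.
#'
#' @param height Peak height(s), kcal/mol (negative for a well).
#' @param center Center(s), Angstrom.
#' @param sigma Width(s) (Gaussian sigma), Angstrom.
#' @param k Spring constant, kcal/mol/A^2.
#' @return A function `U(z)` with attributes `description` and `params`.
#' @export
#' @examples
#' U <- potential_gaussians(height = 2.5, center = 0, sigma = 2)
#' U(c(-10, 0, 10))
potential_gaussians <- function(height, center = 0, sigma = 2) {
  p <- vctrs_recycle(height, center, sigma)
  f <- function(z) {
    out <- numeric(length(z))
    for (i in seq_along(p$height)) {
      out <- out + p$height[i] * exp(-(z - p$center[i])^2 / (2 * p$sigma[i]^2))
    }
    out
  }
  structure(f, class = c("potential_1d", "function"),
            description = sprintf("sum of %d gaussian(s)", length(p$height)),
            params = p)
}

vctrs_recycle <- function(height, center, sigma) {
  n <- max(length(height), length(center), length(sigma))
  list(height = rep_len(height, n), center = rep_len(center, n),
       sigma = rep_len(sigma, n))
}

#' @rdname potential_gaussians
#' @export
potential_flat <- function() {
  structure(function(z) numeric(length(z)),
            class = c("potential_1d", "function"),
            description = "flat (U = 0)", params = list())
}

#' @rdname potential_gaussians
#' @export
potential_harmonic <- function(k, center = 0) {
  check_number(k, "k", positive = TRUE)
  structure(function(z) 0.5 * k * (z - center)^2,
            class = c("potential_1d", "function"),
            description = sprintf("harmonic well, k = %g kcal/mol/A^2", k),
            params = list(k = k, center = center))
}

#' Describe a synthetic channel scenario
#'
#' A scenario fixes everything a generator needs: the simulation box extent
#' along the axis, the channel extent and counting-cylinder radius, the
#' temperature, the number of waters per frame and frames, the 1-D
#' potential the waters feel, and the seed. Defaults mirror a typical
#' aquaporin setup: a 298 K system in a box spanning -40..40 A along z with
#' the single-file channel region at -10..10 A.
#'
#' @param potential A `potential_1d` function (kcal/mol).
#' @param box_z Axial extent of the box, `c(lo, hi)` Angstrom.
#' @param z_lo,z_hi Channel extent (Angstrom).
#' @param counting_radius Counting-cylinder radius (Angstrom).
#' @param temperature Kelvin.
#' @param n_waters Waters per frame.
#' @param n_frames Number of frames.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `"channel_scenario"`.
#' @export
channel_scenario <- function(potential = potential_flat(),
                             box_z = c(-40, 40), z_lo = -10, z_hi = 10,
                             counting_radius = 6, temperature = 298,
                             n_waters = 100, n_frames = 100, seed = NULL) {
  if (!is.function(potential)) abort_scenario("`potential` must be a function U(z).")
  if (length(box_z) != 2L || box_z[1] >= box_z[2]) {
    abort_scenario("`box_z` must be c(lo, hi) with lo < hi.")
  }
  if (z_lo >= z_hi || z_lo < box_z[1] || z_hi > box_z[2]) {
    abort_scenario("channel extent must lie inside `box_z` with z_lo < z_hi.")
  }
  check_number(temperature, "temperature", positive = TRUE)
  check_number(counting_radius, "counting_radius", positive = TRUE)
  if (n_waters < 1L || n_frames < 1L) {
    abort_scenario("`n_waters` and `n_frames` must be >= 1.")
  }
  structure(
    list(potential = potential, box_z = box_z, z_lo = z_lo, z_hi = z_hi,
         counting_radius = counting_radius, temperature = temperature,
         n_waters = as.integer(n_waters), n_frames = as.integer(n_frames),
         seed = seed),
    class = "channel_scenario"
  )
}

#' @export
print.channel_scenario <- function(x, ...) {
  cat(sprintf(
    "<channel_scenario: %d waters x %d frames, T = %g K, box z [%g, %g], %s>\n",
    x$n_waters, x$n_frames, x$temperature, x$box_z[1], x$box_z[2],
    attr(x$potential, "description") %||% "custom potential"))
  invisible(x)
}

#' Channel spec corresponding to a scenario
#'
#' @param scenario A [channel_scenario()].
#' @return A [channel_spec()] with the scenario's extent and radius.
#' @export
scenario_spec <- function(scenario) {
  channel_spec(z_lo = scenario$z_lo, z_hi = scenario$z_hi,
               counting_radius = scenario$counting_radius)
}

# Piecewise-constant Boltzmann weights on a fine z grid; shared by the
# exact sampler and the ground-truth record.
boltzmann_grid <- function(scenario, grid_dz = 0.01) {
  z <- seq(scenario$box_z[1] + grid_dz / 2, scenario$box_z[2] - grid_dz / 2,
           by = grid_dz)
  kBT <- .kB * scenario$temperature
  u <- scenario$potential(z)
  if (!all(is.finite(u))) {
    abort_scenario("potential is not finite on the sampled domain.")
  }
  w <- exp(-(u - min(u)) / kBT)
  if (!all(is.finite(w)) || sum(w) <= 0) {
    abort_scenario("potential is not normalizable on the sampled domain.")
  }
  list(z = z, w = w, dz = grid_dz, kBT = kBT)
}

# Uniform points in a disc of given radius (in the plane perpendicular to z).
runif_disc <- function(n, radius) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th))
}

#' Sample an exact Boltzmann-distributed water trajectory
#'
#' Draws every water z-position i.i.d. from the density proportional to
#' `exp(-U(z)/kBT)` by inverse-CDF sampling on a fine grid (default 0.01 A
#' cells: the weight is taken piecewise-constant per cell and positions are
#' uniform within a cell). x and y are uniform in the counting cylinder.
#' Because draws are i.i.d. from the exact stationary distribution, the
#' time-averaged density profile converges to the Boltzmann weight with no
#' burn-in or autocorrelation, which is what makes desk-scale recovery of
#' the imposed potential by Boltzmann inversion a sharp test.
#'
#' @param scenario A [channel_scenario()].
#' @param grid_dz Inverse-CDF grid cell (Angstrom). Default 0.01.
#' @return A [new_trajectory()] of water oxygens (1 ps frame spacing).
#' @export
#' @examples
#' sc <- channel_scenario(potential_gaussians(2.5), n_waters = 50,
#'                        n_frames = 10, seed = 1)
#' traj <- sample_boltzmann_trajectory(sc)
sample_boltzmann_trajectory <- function(scenario, grid_dz = 0.01) {
  g <- boltzmann_grid(scenario, grid_dz)
  nw <- scenario$n_waters
  nf <- scenario$n_frames
  n <- nw * nf
  with_seed(scenario$seed, {
    idx <- sample.int(length(g$z), n, replace = TRUE, prob = g$w)
    z <- g$z[idx] + runif(n, -g$dz / 2, g$dz / 2)
    xy <- runif_disc(n, scenario$counting_radius)
    coords <- array(0, dim = c(nw, 3L, nf))
    coords[, 1, ] <- xy[, 1]
    coords[, 2, ] <- xy[, 2]
    coords[, 3, ] <- z
    new_trajectory(water_atom_table(nw), coords, times = seq_len(nf) - 1)
  })
}

#' Overdamped 1-D Langevin sampler in a channel potential
#'
#' Euler--Maruyama integration of `dz = -U'(z)/gamma dt + sqrt(2 kBT dt /
#' gamma) xi`, with reflecting walls at the box ends. The stationary
#' distribution is the Boltzmann weight, so long runs must agree with
#' [sample_boltzmann_trajectory()]; unlike it, successive frames are
#' correlated, which exercises the time-average in the density profile the
#' way a real trajectory does.
#'
#' @param scenario A [channel_scenario()].
#' @param friction Friction coefficient gamma (1/ps). Default 1.
#' @param dt Integration step (ps); must satisfy `dt * friction < 1`.
#' @param steps_per_frame Integration steps between recorded frames.
#' @param burn_in Discarded initial steps. Default `10 * steps_per_frame`.
#' @return A [new_trajectory()] of water oxygens.
#' @export
simulate_langevin_1d <- function(scenario, friction = 1, dt = 0.05,
                                 steps_per_frame = 10L,
                                 burn_in = 10L * steps_per_frame) {
  check_number(friction, "friction", positive = TRUE)
  check_number(dt, "dt", positive = TRUE)
  if (dt * friction >= 1) {
    abort_parameter("unstable step: need dt * friction < 1.")
  }
  kBT <- .kB * scenario$temperature
  lo <- scenario$box_z[1]
  hi <- scenario$box_z[2]
  U <- scenario$potential
  h <- 1e-4
  force_z <- function(z) -(U(z + h) - U(z - h)) / (2 * h)
  nw <- scenario$n_waters
  nf <- scenario$n_frames
  sigma <- sqrt(2 * kBT * dt / friction)
  reflect <- function(z) {
    # fold positions back into [lo, hi]
    span <- hi - lo
    z <- (z - lo) %% (2 * span)
    lo + ifelse(z > span, 2 * span - z, z)
  }
  with_seed(scenario$seed, {
    z <- runif(nw, lo, hi)
    step <- function(z) reflect(z + (dt / friction) * force_z(z) +
                                  sigma * rnorm(nw))
    for (i in seq_len(burn_in)) z <- step(z)
    coords <- array(0, dim = c(nw, 3L, nf))
    for (f in seq_len(nf)) {
      for (i in seq_len(steps_per_frame)) z <- step(z)
      xy <- runif_disc(nw, scenario$counting_radius)
      coords[, 1, f] <- xy[, 1]
      coords[, 2, f] <- xy[, 2]
      coords[, 3, f] <- z
    }
    new_trajectory(water_atom_table(nw), coords,
                   times = (seq_len(nf) - 1) * dt * steps_per_frame)
  })
}

#' Single-file water chain fixture
#'
#' A single frame with water oxygens on the channel axis at a fixed
#' hydrogen-bond spacing: one water exactly at axial coordinate 0, the
#' chain extended symmetrically until it fills `z_extent`. With the
#' canonical 2.8 A O--O hydrogen-bond spacing, exactly seven members fall
#' strictly inside the default -10..10 A channel.
#'
#' @param spacing O--O spacing (Angstrom), > 0.
#' @param z_extent Axial extent filled by the chain, `c(lo, hi)`.
#' @param spec [channel_spec()] giving the axis the chain sits on.
#' @return A single-frame [new_trajectory()].
#' @export
build_single_file_fixture <- function(spacing = 2.8, z_extent = c(-40, 40),
                                      spec = channel_spec()) {
  check_number(spacing, "spacing", positive = TRUE)
  if (z_extent[1] > 0 || z_extent[2] < 0) {
    abort_input("`z_extent` must contain 0 (the chain is anchored there).")
  }
  k_lo <- floor(z_extent[1] / spacing)
  k_hi <- floor(z_extent[2] / spacing)
  z <- spacing * seq.int(k_lo, k_hi)
  z <- z[z >= z_extent[1] & z <= z_extent[2]]
  n <- length(z)
  pts <- matrix(spec$anchor, n, 3, byrow = TRUE) + outer(z, spec$axis)
  new_trajectory(water_atom_table(n), array(pts, dim = c(n, 3L, 1L)),
                 times = 0)
}

#' Cylindrical pseudo-protein shell fixture
#'
#' Places atoms of one element on a cylinder around the channel axis so
#' that the accessible pore radius (surface-to-axis, after subtracting the
#' atoms' van der Waals radius) equals `inner_radius` exactly. Rings are
#' spaced `atom_spacing` apart axially and around the circumference.
#'
#' @param inner_radius Target accessible radius (Angstrom).
#' @param z_extent Axial extent covered by the shell, `c(lo, hi)`.
#' @param atom_spacing Ring and circumferential spacing (Angstrom).
#' @param element Element of the shell atoms. Default `"C"`.
#' @param spec [channel_spec()] giving the axis.
#' @return A single-frame [new_trajectory()] of non-water atoms.
#' @export
build_cylinder_shell <- function(inner_radius, z_extent, atom_spacing = 1,
                                 element = "C", spec = channel_spec()) {
  check_number(inner_radius, "inner_radius", positive = TRUE)
  check_number(atom_spacing, "atom_spacing", positive = TRUE)
  if (z_extent[1] >= z_extent[2]) {
    abort_input("`z_extent` must be c(lo, hi) with lo < hi.")
  }
  shell_r <- inner_radius + vdw_radius(element)
  zs <- seq(z_extent[1], z_extent[2], by = atom_spacing)
  n_around <- max(6L, ceiling(2 * pi * shell_r / atom_spacing))
  th <- seq(0, 2 * pi, length.out = n_around + 1L)[seq_len(n_around)]
  basis <- axis_plane_basis(spec)
  pts <- do.call(rbind, lapply(zs, function(z) {
    matrix(spec$anchor, n_around, 3, byrow = TRUE) +
      outer(shell_r * cos(th), basis$u) + outer(shell_r * sin(th), basis$v) +
      matrix(z * spec$axis, n_around, 3, byrow = TRUE)
  }))
  n <- nrow(pts)
  atoms <- tibble(
    serial = seq_len(n), name = element, residue_name = "CYL",
    chain_id = "X", residue_seq = rep(seq_along(zs), each = n_around),
    element = toupper(element), is_water = FALSE,
    vdw_radius = vdw_radius(element)
  )
  new_trajectory(atoms, array(pts, dim = c(n, 3L, 1L)), times = 0)
}

#' Rigid-body + noise perturbation of a frame
#'
#' Applies `x -> R x + t + eps`, `eps ~ N(0, noise_sd^2 I)`, to one frame
#' of a trajectory; the fixture for validating superposition and RMSD.
#'
#' @param traj A trajectory.
#' @param rotation 3x3 orthonormal matrix (proper or improper).
#' @param translation 3-vector (Angstrom).
#' @param noise_sd Isotropic Gaussian noise sd per coordinate (Angstrom).
#' @param seed Integer seed for the noise; `NULL` uses the current stream.
#' @param frame Frame to perturb (default last).
#' @return A single-frame [new_trajectory()].
#' @export
perturb_structure <- function(traj, rotation = diag(3),
                              translation = c(0, 0, 0), noise_sd = 0,
                              seed = NULL, frame = n_frames(traj)) {
  if (!is.matrix(rotation) || !all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    abort_input("`rotation` must be a 3x3 orthonormal matrix.")
  }
  if (length(translation) != 3L) abort_input("`translation` must be a 3-vector.")
  check_number(noise_sd, "noise_sd")
  if (noise_sd < 0) abort_input("`noise_sd` must be >= 0.")
  m <- frame_coords(traj, frame)
  out <- m %*% t(rotation) + matrix(translation, nrow(m), 3, byrow = TRUE)
  if (noise_sd > 0) {
    out <- out + with_seed(seed, matrix(rnorm(length(out), 0, noise_sd),
                                        nrow(out), 3))
  }
  new_trajectory(traj$atoms, array(out, dim = c(nrow(out), 3L, 1L)),
                 times = traj$times[frame])
}

#' Rotation matrix about an axis
#'
#' Rodrigues' formula; convenience for building test transforms.
#'
#' @param axis Rotation axis (3-vector, normalized internally).
#' @param angle Angle in radians.
#' @return 3x3 proper rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
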