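#' Time-averaged water density profile along the channel
#'
#' Counts water oxygens per axial bin and frame, averages over frames, and
#' divides by the bin width: `N(z_i)` is the time average of the number of
#' waters whose oxygen lies in `[z_i, z_i + dz)` *and* within the counting
#' cylinder, and `rho(z_i) = N(z_i) / dz` is the density in waters per
#' Angstrom. Bins tile `z_range` half-open (left-closed); frames are
#' weighted equally. The radial gate is essential: without it the bulk
#' reservoir would dominate every bin and bury the channel signal.
#'
#' @param traj A trajectory.
#' @param spec A [channel_spec()]; supplies the axis and counting radius.
#' @param dz Bin width (Angstrom). Default 1.
#' @param z_range Axial range to bin, `c(lo, hi)`. Default the channel
#'   extent of `spec`; widen it (e.g. to the box extent) to include bulk
#'   reference bins for Boltzmann inversion.
#' @return Tibble of class `"density_profile"`: `z_center`, `n_mean`
#'   (waters), `density` (waters/Angstrom); attributes `dz`, `t_f`
#'   (duration, ps), `dt` (frame spacing, ps), `n_frames`, `spec`,
#'   `z_range`.
#' @export
#' @examples
#' sc <- channel_scenario(n_waters = 200, n_frames = 20, seed = 7)
#' traj <- sample_boltzmann_trajectory(sc)
#' density_profile(traj, scenario_spec(sc), dz = 2, z_range = c(-40, 40))
density_profile <- function(traj, spec, dz = 1, z_range = NULL) {
  check_number(dz, "dz", positive = TRUE)
  z_range <- z_range %||% c(spec$z_lo, spec$z_hi)
  if (z_range[1] >= z_range[2]) abort_input("`z_range` must be c(lo, hi).")
  n_bins <- floor((z_range[2] - z_range[1]) / dz + 1e-9)
  if (n_bins < 1L) abort_input("`z_range` narrower than one bin.")
  z_lo <- z_range[1]
  z_centers <- z_lo + (seq_len(n_bins) - 0.5) * dz
  idx <- select_atoms(traj, "water_oxygen")
  nf <- n_frames(traj)
  counts <- numeric(n_bins)
  if (length(idx) == 0L) {
    warn("trajectory contains no water oxygens; returning an all-zero profile.")
  } else {
    # flatten atoms x frames once; memory is n_waters * n_frames doubles
    nw <- length(idx)
    flat <- matrix(aperm(traj$coords[idx, , , drop = FALSE], c(1, 3, 2)),
                   ncol = 3L)
    ac <- axis_coords(flat, spec)
    inside <- ac$r <= spec$counting_radius &
      ac$z >= z_lo & ac$z < z_lo + n_bins * dz
    bin <- floor((ac$z[inside] - z_lo) / dz) + 1L
    bin[bin > n_bins] <- n_bins # guard the z == upper-edge float case
    counts <- tabulate(bin, nbins = n_bins)
  }
  n_mean <- counts / nf
  out <- tibble(z_center = z_centers, n_mean = n_mean, density = n_mean / dz)
  attr(out, "dz") <- dz
  attr(out, "t_f") <- trajectory_duration(traj)
  attr(out, "dt") <- if (nf > 1L) mean(diff(traj$times)) else NA_real_
  attr(out, "n_frames") <- nf
  attr(out, "spec") <- spec
  attr(out, "z_range") <- c(z_lo, z_lo + n_bins * dz)
  class(out) <- c("density_profile", class(out))
  out
}

#' Detect the single-file water chain in each frame
#'
#' Candidate waters are the oxygens inside the counting cylinder (any z).
#' Sorted by axial position, a chain is a maximal run of consecutive
#' candidates whose 3-D O--O distance stays within `hb_cutoff` (the
#' hydrogen-bond criterion); the longest such run is the single file, and
#' the report counts its members strictly inside the channel extent.
#'
#' @param traj A trajectory.
#' @param spec A [channel_spec()].
#' @param hb_cutoff Maximum O--O hydrogen-bond distance (Angstrom).
#'   Default 3.5.
#' @param frames Frame indices to analyse. Default all frames.
#' @return Tibble of class `"single_file_report"`, one row per frame:
#'   `frame` (0-based), `time` (ps), `n_file` (members strictly inside the
#'   channel), `chain_z` (list column of their axial positions, sorted);
#'   attribute `hb_cutoff`.
#' @export
detect_single_file <- function(traj, spec, hb_cutoff = 3.5, frames = NULL) {
  check_number(hb_cutoff, "hb_cutoff", positive = TRUE)
  frames <- frames %||% seq_len(n_frames(traj))
  idx <- select_atoms(traj, "water_oxygen")
  rows <- lapply(frames, function(f) {
    if (length(idx) == 0L) {
      return(tibble(frame = f - 1L, time = traj$times[f], n_file = 0L,
                    chain_z = list(numeric(0))))
    }
    m <- frame_coords(traj, f)[idx, , drop = FALSE]
    ac <- axis_coords(m, spec)
    keep <- ac$r <= spec$counting_radius
    m <- m[keep, , drop = FALSE]
    z <- ac$z[keep]
    if (length(z) == 0L) {
      return(tibble(frame = f - 1L, time = traj$times[f], n_file = 0L,
                    chain_z = list(numeric(0))))
    }
    ord <- order(z)
    m <- m[ord, , drop = FALSE]
    z <- z[ord]
    if (length(z) == 1L) {
      runs <- list(1L)
    } else {
      gap <- sqrt(rowSums((m[-1, , drop = FALSE] -
                             m[-nrow(m), , drop = FALSE])^2)) > hb_cutoff
      run_id <- cumsum(c(0L, gap))
      runs <- split(seq_along(z), run_id)
    }
    # longest run; ties resolved toward the run with the most members in
    # the channel, then toward the channel center
    len <- lengths(runs)
    cand <- which(len == max(len))
    if (length(cand) > 1L) {
      n_in <- vapply(runs[cand], function(i)
        sum(z[i] > spec$z_lo & z[i] < spec$z_hi), integer(1))
      cand <- cand[n_in == max(n_in)]
      if (length(cand) > 1L) {
        mid <- (spec$z_lo + spec$z_hi) / 2
        cand <- cand[which.min(vapply(runs[cand], function(i)
          abs(mean(z[i]) - mid), numeric(1)))]
      }
    }
    best <- runs[[cand[1]]]
    zb <- z[best]
    inside <- zb > spec$z_lo & zb < spec$z_hi
    tibble(frame = f - 1L, time = traj$times[f],
           n_file = sum(inside), chain_z = list(zb[inside]))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "hb_cutoff") <- hb_cutoff
  class(out) <- c("single_file_report", class(out))
  out
}
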