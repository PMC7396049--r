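#' Pore-radius profile along the channel axis
#'
#' For each axial slice the pore radius is the radius of the largest probe
#' sphere, centered in the slice plane, that touches no atom (an atom at
#' distance `d` with van der Waals radius `r_vdw` limits the probe to
#' `d - r_vdw`). The probe center starts on the nominal axis and is
#' re-centered within the plane by local hill-climbing (0.1 A steps), a
#' deliberately simple stand-in for the Monte-Carlo center search of
#' full pore-profiling programs; radii are capped at `max_probe`. Slices
#' with no atom within `max_probe + max(vdw)` of the axis are masked.
#' The selectivity filter (SF) is the unmasked minimum (ties: smallest z).
#'
#' @param traj A trajectory; non-water atoms define the pore wall.
#' @param spec A [channel_spec()].
#' @param dz Slice spacing (Angstrom). Default 0.5.
#' @param max_probe Radius cap (Angstrom). Default 10.
#' @param frame Frame to profile (default last).
#' @return Tibble of class `"pore_profile"`: `z_center`, `radius`,
#'   `masked`; attributes `sf_z`, `sf_radius`, `dz`, `max_probe`.
#' @export
pore_radius_profile <- function(traj, spec, dz = 0.5, max_probe = 10,
                                frame = n_frames(traj)) {
  check_number(dz, "dz", positive = TRUE)
  check_number(max_probe, "max_probe", positive = TRUE)
  idx <- select_atoms(traj, "protein")
  if (length(idx) == 0L) abort_input("no non-water atoms to profile against.")
  m <- frame_coords(traj, frame)[idx, , drop = FALSE]
  vdw <- traj$atoms$vdw_radius[idx]
  ac <- axis_coords(m, spec)
  basis <- axis_plane_basis(spec)
  max_vdw <- max(vdw)
  n_bins <- max(1L, floor((spec$z_hi - spec$z_lo) / dz + 1e-9))
  z_centers <- spec$z_lo + (seq_len(n_bins) - 0.5) * dz
  reach <- max_probe + max_vdw

  probe_radius <- function(p, pts, pvdw) {
    d <- sqrt(rowSums(sweep(pts, 2L, p)^2)) - pvdw
    min(max_probe, max(0, min(d)))
  }

  radius <- rep(NA_real_, n_bins)
  step <- 0.1
  moves <- cbind(c(step, -step, 0, 0, step, step, -step, -step),
                 c(0, 0, step, -step, step, -step, step, -step))
  for (b in seq_len(n_bins)) {
    zc <- z_centers[b]
    p0 <- spec$anchor + zc * spec$axis
    # masked when nothing is reachable from the nominal axis point
    if (min(sqrt(rowSums(sweep(m, 2L, p0)^2))) > reach) next
    near <- abs(ac$z - zc) <= reach
    pts <- m[near, , drop = FALSE]
    pvdw <- vdw[near]
    off <- c(0, 0)
    best <- probe_radius(p0, pts, pvdw)
    for (iter in seq_len(500L)) {
      improved <- FALSE
      for (k in seq_len(nrow(moves))) {
        cand <- off + moves[k, ]
        if (sqrt(sum(cand^2)) > max_probe) next
        p <- p0 + cand[1] * basis$u + cand[2] * basis$v
        r <- probe_radius(p, pts, pvdw)
        if (r > best + 1e-9) {
          best <- r
          off <- cand
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    radius[b] <- best
  }
  masked <- is.na(radius)
  out <- tibble(z_center = z_centers, radius = radius, masked = masked)
  if (all(masked)) {
    sf_z <- NA_real_
    sf_r <- NA_real_
  } else {
    r_min <- min(radius[!masked])
    sf_z <- min(z_centers[!masked & radius <= r_min + 1e-12])
    sf_r <- r_min
  }
  attr(out, "sf_z") <- sf_z
  attr(out, "sf_radius") <- sf_r
  attr(out, "dz") <- dz
  attr(out, "max_probe") <- max_probe
  class(out) <- c("pore_profile", class(out))
  out
}

#' Zone pore-lining residues
#'
#' A residue lines the pore if any of its atoms lies within
#' `contact_cutoff` of the channel axis segment (`z_lo`..`z_hi`). Lining
#' residues are zoned by the axial position of their closest atom:
#' inside `npa_window` is the NPA region (the mid-channel asparagine
#' motifs), beyond the channel midpoint toward the extracellular side is
#' the extracellular vestibule, and the opposite side is cytoplasmic.
#' Non-lining residues get zone `"none"`.
#'
#' @param traj A trajectory; non-water atoms are considered.
#' @param spec A [channel_spec()].
#' @param contact_cutoff Distance to the axis segment (Angstrom). Default 4.
#' @param npa_window Axial window of the NPA region, `c(lo, hi)`. Default
#'   `c(-5, 5)`.
#' @param frame Frame to analyse (default last).
#' @return Tibble of class `"residue_zoning"`: `chain_id`, `residue_seq`,
#'   `residue_name`, `min_axis_dist` (Angstrom), `closest_z` (Angstrom),
#'   `lining`, `zone`.
#' @export
zone_lining_residues <- function(traj, spec, contact_cutoff = 4,
                                 npa_window = c(-5, 5),
                                 frame = n_frames(traj)) {
  check_number(contact_cutoff, "contact_cutoff", positive = TRUE)
  if (length(npa_window) != 2L || npa_window[1] > npa_window[2]) {
    abort_input("`npa_window` must be c(lo, hi).")
  }
  idx <- select_atoms(traj, "protein")
  m <- frame_coords(traj, frame)[idx, , drop = FALSE]
  atoms <- traj$atoms[idx, , drop = FALSE]
  ac <- axis_coords(m, spec)
  # distance to the axis *segment* [z_lo, z_hi]: radial inside, corner
  # distance beyond the ends
  over <- pmax(ac$z - spec$z_hi, spec$z_lo - ac$z, 0)
  seg_dist <- sqrt(ac$r^2 + over^2)
  df <- tibble(chain_id = atoms$chain_id, residue_seq = atoms$residue_seq,
               residue_name = atoms$residue_name, dist = seg_dist, z = ac$z)
  mid <- (spec$z_lo + spec$z_hi) / 2
  if (nrow(df) == 0L) {
    res <- tibble(chain_id = character(0), residue_seq = integer(0),
                  residue_name = character(0), min_axis_dist = numeric(0),
                  closest_z = numeric(0), lining = logical(0),
                  zone = character(0))
    attr(res, "contact_cutoff") <- contact_cutoff
    attr(res, "npa_window") <- npa_window
    class(res) <- c("residue_zoning", class(res))
    return(res)
  }
  res <- df |>
    dplyr::group_by(.data$chain_id, .data$residue_seq, .data$residue_name) |>
    dplyr::summarise(
      min_axis_dist = min(.data$dist),
      closest_z = .data$z[which.min(.data$dist)],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      lining = .data$min_axis_dist <= contact_cutoff,
      zone = dplyr::case_when(
        !.data$lining ~ "none",
        .data$closest_z >= npa_window[1] &
          .data$closest_z <= npa_window[2] ~ "npa_region",
        (.data$closest_z - mid) * spec$side_sign > 0 ~ "extracellular_vestibule",
        TRUE ~ "cytoplasmic"
      )
    ) |>
    dplyr::arrange(.data$chain_id, .data$residue_seq)
  attr(res, "contact_cutoff") <- contact_cutoff
  attr(res, "npa_window") <- npa_window
  class(res) <- c("residue_zoning", class(res))
  res
}
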