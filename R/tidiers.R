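strip_profile_class <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' @export
tidy.density_profile <- function(x, ...) strip_profile_class(x)

#' @export
tidy.free_energy_profile <- function(x, ...) strip_profile_class(x)

#' @export
tidy.pore_profile <- function(x, ...) strip_profile_class(x)

#' @export
tidy.rmsd_series <- function(x, ...) strip_profile_class(x)

#' @export
tidy.residue_zoning <- function(x, ...) strip_profile_class(x)

#' @export
tidy.equilibration_report <- function(x, ...) strip_profile_class(x)

#' @export
tidy.barrier_report <- function(x, ...) strip_profile_class(x)

#' One row per chain member across frames
#' @param x A [detect_single_file()] report.
#' @param ... Unused.
#' @export
tidy.single_file_report <- function(x, ...) {
  strip_profile_class(x) |>
    dplyr::select("frame", "time", "chain_z") |>
    tidyr_unnest_chain()
}

# minimal unnest to avoid a tidyr dependency for one list column
tidyr_unnest_chain <- function(df) {
  n <- lengths(df$chain_z)
  tibble(frame = rep(df$frame, n), time = rep(df$time, n),
         z = unlist(df$chain_z))
}

#' @export
tidy.kabsch_fit <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2)))
  tibble(term = c("tx", "ty", "tz", "rotation_angle"),
         estimate = c(x$translation, ang))
}

#' @export
glance.kabsch_fit <- function(x, ...) tibble(rmsd = x$rmsd)

#' @export
glance.density_profile <- function(x, ...) {
  tibble(n_bins = nrow(x), dz = attr(x, "dz"),
         n_frames = attr(x, "n_frames"), t_f = attr(x, "t_f"),
         dt = attr(x, "dt"), mean_total_waters = sum(x$n_mean))
}

#' @export
glance.free_energy_profile <- function(x, ...) {
  tibble(z_A = attr(x, "z_A"), kBT = attr(x, "kBT"),
         temperature = attr(x, "temperature"),
         diff_error = attr(x, "diff_error"),
         n_masked = sum(x$masked), dG_max = max(x$dG, na.rm = TRUE))
}

#' @export
glance.pore_profile <- function(x, ...) {
  tibble(sf_z = attr(x, "sf_z"), sf_radius = attr(x, "sf_radius"),
         n_masked = sum(x$masked), n_slices = nrow(x))
}

#' @export
glance.rmsd_series <- function(x, ...) {
  tibble(n_frames = nrow(x), selection = attr(x, "selection"),
         fitted = attr(x, "fitted"), rmsd_mean = mean(x$rmsd),
         rmsd_max = max(x$rmsd), rmsd_final = x$rmsd[nrow(x)])
}

#' @export
glance.single_file_report <- function(x, ...) {
  tibble(n_frames = nrow(x), hb_cutoff = attr(x, "hb_cutoff"),
         n_file_mean = mean(x$n_file), n_file_last = x$n_file[nrow(x)])
}
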