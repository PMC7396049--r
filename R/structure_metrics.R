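#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares optimal rotation and translation mapping `mobile` onto
#' `reference`, computed from the SVD of the covariance of the centered
#' coordinate sets with the usual reflection correction, so the returned
#' rotation is always proper (determinant +1).
#'
#' @param mobile,reference `n x 3` coordinate matrices, same `n >= 3`.
#' @return A list of class `"kabsch_fit"`: `rotation` (3x3),
#'   `translation` (3-vector, applied after rotation) and `rmsd` (Angstrom)
#'   of the superposed coordinates. `apply_transform()` applies the fit.
#' @export
#' @examples
#' x <- matrix(rnorm(12), 4, 3)
#' R <- rotation_matrix(c(1, 1, 0), 0.7)
#' y <- x %*% t(R) + 2
#' kabsch_superpose(x, y)$rmsd
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L) {
    abort_input("coordinate matrices must have 3 columns.")
  }
  if (nrow(mobile) != nrow(reference)) {
    abort_input("mobile and reference must have the same number of atoms.")
  }
  if (nrow(mobile) < 3L) abort_input("superposition needs at least 3 atoms.")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(reference, 2L, cr)
  H <- crossprod(P, Q) # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  transl <- cr - drop(R %*% cm)
  fitted <- mobile %*% t(R) + matrix(transl, nrow(mobile), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  structure(list(rotation = R, translation = transl, rmsd = rmsd),
            class = "kabsch_fit")
}

#' @export
print.kabsch_fit <- function(x, ...) {
  cat(sprintf("<kabsch_fit: rmsd %.4f A>\n", x$rmsd))
  invisible(x)
}

#' @rdname kabsch_superpose
#' @param coords `n x 3` matrix to transform.
#' @param fit A `"kabsch_fit"`.
#' @export
apply_transform <- function(coords, fit) {
  as.matrix(coords) %*% t(fit$rotation) +
    matrix(fit$translation, nrow(coords), 3, byrow = TRUE)
}

rmsd_pair <- function(x, y) sqrt(mean(rowSums((x - y)^2)))

#' RMSD time series against a reference frame
#'
#' One RMSD value per frame, over an atom selection. With `fitted = TRUE`
#' (the default) each frame is first superposed onto the reference by
#' [kabsch_superpose()] on the same selection; with `fitted = FALSE` the
#' raw (no-fit) deviation is reported, which is the right mode when the
#' simulation itself restrained the frame of reference. RMSD is the plain
#' arithmetic form `sqrt(sum |x_i - y_i|^2 / N)`, unweighted.
#'
#' @param traj A trajectory.
#' @param reference Reference coordinates: a frame index into `traj`, an
#'   `n_atoms x 3` matrix (full atom table before selection), or a
#'   single-frame trajectory with the same atom table. Default frame 1.
#' @param selection Atom selection (see [select_atoms()]). Default
#'   `"heavy"`.
#' @param fitted Superpose before measuring? Default `TRUE`.
#' @return A tibble of class `"rmsd_series"`: `time` (ps), `rmsd`
#'   (Angstrom); attributes `selection`, `fitted`.
#' @export
rmsd_series <- function(traj, reference = 1L, selection = "heavy",
                        fitted = TRUE) {
  idx <- select_atoms(traj, selection)
  if (length(idx) == 0L) abort_input("empty atom selection.")
  ref <- if (inherits(reference, "trajectory")) {
    frame_coords(reference, 1L)
  } else if (is.matrix(reference)) {
    reference
  } else {
    frame_coords(traj, as.integer(reference))
  }
  if (nrow(ref) != n_atoms(traj)) {
    abort_input("reference must cover the full atom table.")
  }
  ref <- ref[idx, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_coords(traj, f)[idx, , drop = FALSE]
    if (fitted) kabsch_superpose(m, ref)$rmsd else rmsd_pair(m, ref)
  }, numeric(1))
  out <- tibble(time = traj$times, rmsd = vals)
  attr(out, "selection") <- if (is.character(selection)) selection else "custom"
  attr(out, "fitted") <- fitted
  class(out) <- c("rmsd_series", class(out))
  out
}

#' Detect the equilibration plateau of an RMSD series
#'
#' Sliding-window range rule: the onset is the earliest time from which
#' every subsequent window of length `window` has `max - min <= tolerance`;
#' the plateau band is the min/max of the values from the onset to the end.
#' A series that never settles (e.g. unbounded drift) has no onset.
#'
#' @param series An [rmsd_series()] tibble (or any data frame with `time`
#'   and `rmsd` columns).
#' @param window Window length in ps. Default 2000 (2 ns).
#' @param tolerance Maximum within-window range in Angstrom. Default 0.5.
#' @return One-row tibble of class `"equilibration_report"`: `onset_time`
#'   (ps, `NA` if none), `plateau_lo`, `plateau_hi` (Angstrom), `window`,
#'   `tolerance`.
#' @export
detect_equilibration <- function(series, window = 2000, tolerance = 0.5) {
  if (!all(c("time", "rmsd") %in% names(series))) {
    abort_input("`series` needs `time` and `rmsd` columns.")
  }
  check_number(window, "window", positive = TRUE)
  check_number(tolerance, "tolerance", positive = TRUE)
  t <- series$time
  v <- series$rmsd
  n <- length(v)
  span <- t[n] - t[1]
  if (window > span) abort_input("`window` is longer than the series.")
  # window start indices and the index just past each window
  ends <- findInterval(t + window, t, rightmost.closed = FALSE)
  starts <- which(t + window <= t[n] + 1e-9)
  ok <- vapply(starts, function(i) {
    w <- v[i:ends[i]]
    (max(w) - min(w)) <= tolerance
  }, logical(1))
  onset_idx <- if (all(ok)) {
    1L
  } else {
    last_bad <- max(starts[!ok])
    cand <- last_bad + 1L
    if (cand > max(starts)) NA_integer_ else cand
  }
  if (is.na(onset_idx)) {
    rep <- tibble(onset_time = NA_real_, plateau_lo = NA_real_,
                  plateau_hi = NA_real_, window = window,
                  tolerance = tolerance)
  } else {
    tailv <- v[onset_idx:n]
    rep <- tibble(onset_time = t[onset_idx], plateau_lo = min(tailv),
                  plateau_hi = max(tailv), window = window,
                  tolerance = tolerance)
  }
  class(rep) <- c("equilibration_report", class(rep))
  rep
}
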