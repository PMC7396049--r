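#' Define the channel axis and counting geometry
#'
#' The channel is modelled as a straight axis (default +z through the
#' origin) with an axial extent `[z_lo, z_hi]` and a counting cylinder of
#' radius `counting_radius` around the axis. Axial coordinates reported by
#' every analysis are projections onto this axis relative to `anchor`.
#' Water counting is gated radially by the cylinder: without it, bulk water
#' far from the pore would dominate the per-slab counts and flatten the
#' channel signal.
#'
#' @param axis Direction of the channel axis (3-vector, any length; it is
#'   normalized). Default `+z`.
#' @param anchor A point on the axis (Angstrom); axial coordinate 0.
#' @param z_lo,z_hi Channel extent along the axis (Angstrom). Default
#'   `[-10, 10]`, the span of a typical aquaporin single-file region.
#' @param counting_radius Radius (Angstrom) of the cylinder inside which
#'   waters are counted. Default 6.
#' @param extracellular_side Which end of the axis faces the extracellular
#'   medium, `"+z"` or `"-z"` (in axis coordinates). Default `"+z"`.
#' @return An object of class `"channel_spec"`.
#' @export
#' @examples
#' channel_spec()
#' channel_spec(z_lo = -12, z_hi = 12, counting_radius = 5)
channel_spec <- function(axis = c(0, 0, 1), anchor = c(0, 0, 0),
                         z_lo = -10, z_hi = 10, counting_radius = 6,
                         extracellular_side = c("+z", "-z")) {
  if (!is.numeric(axis) || length(axis) != 3L || !all(is.finite(axis))) {
    abort_input("`axis` must be a finite 3-vector.")
  }
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) abort_input("`axis` must be non-zero.")
  axis <- axis / nrm
  if (!is.numeric(anchor) || length(anchor) != 3L || !all(is.finite(anchor))) {
    abort_input("`anchor` must be a finite 3-vector.")
  }
  check_number(z_lo, "z_lo")
  check_number(z_hi, "z_hi")
  if (z_lo >= z_hi) abort_input("`z_lo` must be < `z_hi`.")
  check_number(counting_radius, "counting_radius", positive = TRUE)
  extracellular_side <- match.arg(extracellular_side)
  structure(
    list(
      axis = axis, anchor = anchor, z_lo = z_lo, z_hi = z_hi,
      counting_radius = counting_radius,
      extracellular_side = extracellular_side,
      side_sign = if (extracellular_side == "+z") 1 else -1
    ),
    class = "channel_spec"
  )
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf(
    "<channel_spec: axis (%.2f, %.2f, %.2f), extent [%g, %g] A, r = %g A, extracellular %s>\n",
    x$axis[1], x$axis[2], x$axis[3], x$z_lo, x$z_hi, x$counting_radius,
    x$extracellular_side))
  invisible(x)
}

# Axial (z) and radial (r) coordinates of an n x 3 coordinate matrix in the
# frame of a channel_spec.
axis_coords <- function(xyz, spec) {
  d <- sweep(xyz, 2L, spec$anchor)
  z <- drop(d %*% spec$axis)
  r2 <- rowSums(d^2) - z^2
  list(z = z, r = sqrt(pmax(r2, 0)))
}

# Two unit vectors spanning the plane perpendicular to the axis.
axis_plane_basis <- function(spec) {
  a <- spec$axis
  ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(a[2] * ref[3] - a[3] * ref[2],
         a[3] * ref[1] - a[1] * ref[3],
         a[1] * ref[2] - a[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(a[2] * u[3] - a[3] * u[2],
         a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  list(u = u, v = v)
}
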