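# Bondi-style van der Waals radii (Angstrom), used by the pore profiler and
# the cylinder-shell fixture. Unknown elements fall back to 1.70 (carbon).
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  CL = 1.75, BR = 1.85, I = 1.98, NA. = 2.27, K = 2.75, MG = 1.73,
  CA = 2.31, FE = 2.00, ZN = 1.39, MN = 2.05, CU = 1.40
)

#' Van der Waals radius of an element
#'
#' Looks up a fixed, built-in Bondi-style table; elements absent from the
#' table get the carbon radius (1.70 A).
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Numeric vector of radii in Angstrom.
#' @export
#' @examples
#' vdw_radius(c("O", "C", "H"))
vdw_radius <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA." # sodium; avoid clash with R's missing value
  r <- unname(.vdw_radii[key])
  r[is.na(r)] <- 1.70
  r
}

.default_water_residues <- c("HOH", "TIP3", "WAT", "SOL")

# Backbone atom names (CHARMM/PDB conventions) used by the "sidechain" preset.
.backbone_names <- c(
  "N", "CA", "C", "O", "OXT", "OT1", "OT2",
  "H", "HN", "HA", "HA1", "HA2", "HT1", "HT2", "HT3", "H1", "H2", "H3"
)

#' Construct a trajectory object
#'
#' A trajectory couples one atom table (a tibble, shared by every frame) with
#' a `n_atoms x 3 x n_frames` coordinate array and per-frame times.
#' Coordinates are Angstrom, times picoseconds, frame indices 0-based in
#' exported metadata.
#'
#' @param atoms Tibble with columns `serial`, `name`, `residue_name`,
#'   `chain_id`, `residue_seq`, `element`, `is_water`, `vdw_radius`.
#' @param coords Numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @param times Numeric vector of frame times (ps), non-decreasing.
#' @return An object of class `"trajectory"`.
#' @export
new_trajectory <- function(atoms, coords, times = NULL) {
  atoms <- as_tibble(atoms)
  required <- c("serial", "name", "residue_name", "chain_id", "residue_seq",
                "element", "is_water", "vdw_radius")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort_input(paste0("atom table lacks column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    abort_input("`coords` must be an n_atoms x 3 x n_frames array.")
  }
  if (dim(coords)[1] != nrow(atoms)) {
    abort_input("coordinate rows must match the atom table length.")
  }
  nf <- dim(coords)[3]
  if (nf < 1L) abort_input("a trajectory needs at least one frame.")
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1L)
  if (length(times) != nf) abort_input("`times` must have one entry per frame.")
  if (any(diff(times) < 0)) abort_input("frame times must be non-decreasing.")
  if (anyDuplicated(atoms$serial)) {
    abort_input("atom serial numbers must be unique within the atom table.")
  }
  if (any(atoms$vdw_radius <= 0)) abort_input("vdw_radius must be > 0.")
  structure(
    list(atoms = atoms, coords = coords, times = as.numeric(times)),
    class = "trajectory"
  )
}

#' Number of frames / atoms, duration
#'
#' @param traj A [new_trajectory()] object.
#' @return Integer count, or duration in ps (last minus first frame time).
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
trajectory_duration <- function(traj) {
  traj$times[n_frames(traj)] - traj$times[1]
}

#' Coordinates of one frame
#'
#' @param traj A trajectory.
#' @param frame 1-based frame index; default the last frame.
#' @return `n_atoms x 3` numeric matrix (Angstrom).
#' @export
frame_coords <- function(traj, frame = n_frames(traj)) {
  nf <- n_frames(traj)
  if (frame < 1 || frame > nf) {
    abort_input(sprintf("frame %d outside 1..%d.", frame, nf))
  }
  m <- traj$coords[, , frame, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  colnames(m) <- c("x", "y", "z")
  m
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d atoms, %d frames, %.1f ps>\n",
              n_atoms(x), n_frames(x), trajectory_duration(x)))
  cat(sprintf("  waters: %d; elements: %s\n",
              sum(x$atoms$is_water),
              paste(sort(unique(x$atoms$element)), collapse = " ")))
  invisible(x)
}

#' @export
as_tibble.trajectory <- function(x, ...) {
  nf <- n_frames(x)
  na <- n_atoms(x)
  out <- tibble(
    frame = rep(seq_len(nf) - 1L, each = na),
    time = rep(x$times, each = na),
    serial = rep(x$atoms$serial, nf),
    x = as.vector(x$coords[, 1, ]),
    y = as.vector(x$coords[, 2, ]),
    z = as.vector(x$coords[, 3, ])
  )
  dplyr::left_join(out, x$atoms, by = "serial")
}

#' Select atom indices by preset, predicate, or explicit index
#'
#' Selections are defined on the atom table, so the same index set applies to
#' every frame. Presets: `"all"`, `"heavy"` (non-hydrogen), `"protein"`
#' (non-water), `"sidechain"` (protein minus backbone atom names),
#' `"water"`, `"water_oxygen"`.
#'
#' @param traj A trajectory.
#' @param selection Preset name, logical/integer vector, or a predicate
#'   function taking the atom tibble and returning a logical vector.
#' @return Sorted integer vector of atom indices (rows of the atom table).
#' @export
select_atoms <- function(traj, selection = "all") {
  atoms <- traj$atoms
  if (is.function(selection)) {
    keep <- selection(atoms)
    if (!is.logical(keep) || length(keep) != nrow(atoms)) {
      abort_input("a selection function must return one logical per atom.")
    }
    return(which(keep))
  }
  if (is.logical(selection)) {
    if (length(selection) != nrow(atoms)) {
      abort_input("logical selection must have one entry per atom.")
    }
    return(which(selection))
  }
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (any(idx < 1L | idx > nrow(atoms))) abort_input("selection index out of range.")
    return(sort(unique(idx)))
  }
  selection <- match.arg(selection,
    c("all", "heavy", "protein", "sidechain", "water", "water_oxygen"))
  el <- toupper(atoms$element)
  switch(selection,
    all = seq_len(nrow(atoms)),
    heavy = which(el != "H"),
    protein = which(!atoms$is_water),
    sidechain = which(!atoms$is_water & !(toupper(atoms$name) %in% .backbone_names)),
    water = which(atoms$is_water),
    water_oxygen = which(atoms$is_water & el == "O")
  )
}

#' Merge two single-frame structures into one
#'
#' Concatenates the atom tables (serials renumbered) and coordinates of two
#' single-frame trajectories; used to stack fixture geometries such as two
#' cylinder shells of different radii.
#'
#' @param a,b Single-frame trajectories.
#' @return A single-frame trajectory.
#' @export
merge_structures <- function(a, b) {
  if (n_frames(a) != 1L || n_frames(b) != 1L) {
    abort_input("merge_structures() expects single-frame trajectories.")
  }
  atoms <- dplyr::bind_rows(a$atoms, b$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  coords <- array(rbind(frame_coords(a, 1), frame_coords(b, 1)),
                  dim = c(nrow(atoms), 3L, 1L))
  new_trajectory(atoms, coords, times = a$times[1])
}

# Build a minimal atom table for generated (fixture) structures.
water_atom_table <- function(n) {
  tibble(
    serial = seq_len(n),
    name = "OH2",
    residue_name = "HOH",
    chain_id = "W",
    residue_seq = seq_len(n),
    element = "O",
    is_water = TRUE,
    vdw_radius = vdw_radius("O")
  )
}
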