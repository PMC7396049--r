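# Three-letter codes used to keep alpha-carbons ("CA") distinct from
# calcium ions when inferring elements from atom names.
.amino3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO",
             "SER", "THR", "TRP", "TYR", "VAL")

.two_letter_elements <- c("CL", "BR", "NA", "MG", "FE", "ZN", "MN", "CU", "CA")

infer_element <- function(name, residue_name) {
  stripped <- toupper(gsub("[0-9']", "", trimws(name)))
  resid <- toupper(trimws(residue_name))
  two <- substr(stripped, 1, 2)
  is_ion <- !(resid %in% c(.amino3, .default_water_residues)) &
    two %in% .two_letter_elements & nchar(stripped) <= 2
  out <- substr(stripped, 1, 1)
  out[is_ion] <- two[is_ion]
  out[out == ""] <- "X"
  out
}

#' Read a (multi-MODEL) PDB file as a trajectory
#'
#' Each `MODEL` block becomes one frame; a file without `MODEL` records is a
#' single-frame trajectory. Waters are flagged by residue name; elements
#' missing from the element column are inferred from the atom name; van der
#' Waals radii come from the built-in table ([vdw_radius()]).
#'
#' @param path PDB file.
#' @param water_residues Residue names treated as water.
#'   Default `c("HOH", "TIP3", "WAT", "SOL")`.
#' @param dt Frame spacing in ps used for frame times (the PDB format
#'   carries none); frame `i` gets time `i * dt`.
#' @return A [new_trajectory()] object.
#' @export
read_pdb_trajectory <- function(path, water_residues = .default_water_residues,
                                dt = 1) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) abort_format("no ATOM/HETATM records in PDB file.")
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts)) {
      abort_format("unbalanced MODEL/ENDMDL records.")
    }
    counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts, model_ends)
    if (length(unique(counts)) != 1L) {
      abort_format("MODEL blocks contain differing numbers of atom records.")
    }
  }
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- p$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  na <- nrow(p$atom)
  nf <- nrow(xyz)
  element <- toupper(trimws(p$atom$elesy))
  blank <- is.na(element) | element == ""
  element[blank] <- infer_element(p$atom$elety[blank], p$atom$resid[blank])
  atoms <- tibble(
    serial = p$atom$eleno,
    name = trimws(p$atom$elety),
    residue_name = trimws(p$atom$resid),
    chain_id = ifelse(is.na(p$atom$chain), "", p$atom$chain),
    residue_seq = p$atom$resno,
    element = element,
    is_water = toupper(trimws(p$atom$resid)) %in% toupper(water_residues),
    vdw_radius = vdw_radius(element)
  )
  coords <- array(0, dim = c(na, 3L, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  }
  new_trajectory(atoms, coords, times = (seq_len(nf) - 1L) * dt)
}

#' Write a trajectory as a multi-MODEL PDB file
#'
#' @param traj A trajectory.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb_trajectory <- function(traj, path) {
  atoms <- traj$atoms
  nm <- ifelse(nchar(atoms$name) >= 4,
               sprintf("%-4s", substr(atoms$name, 1, 4)),
               sprintf(" %-3s", atoms$name))
  hdr <- sprintf("ATOM  %5d %s %-3s %1s%4d    ",
                 atoms$serial %% 100000L, nm,
                 substr(atoms$residue_name, 1, 3),
                 substr(paste0(atoms$chain_id, "A"), 1, 1),
                 atoms$residue_seq %% 10000L)
  out <- character(0)
  for (f in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, f)
    rec <- sprintf("%s%8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   hdr, m[, 1], m[, 2], m[, 3], 1, 0,
                   substr(atoms$element, 1, 2))
    out <- c(out, sprintf("MODEL     %4d", f), rec, "ENDMDL")
  }
  out <- c(out, "END")
  tryCatch(writeLines(out, path),
           error = function(e) abort_io(conditionMessage(e)))
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ layout: atom count, comment line, then one
#' `element x y z` line per atom, repeated per frame. XYZ carries no residue
#' information, so waters are identified as the oxygen atoms that are not
#' claimed by a protein-atom prefix: the first `n_protein_atoms` records of
#' each frame are treated as protein.
#'
#' @param path XYZ file.
#' @param n_protein_atoms Number of leading atoms per frame that belong to
#'   the protein (never flagged as water). Default 0.
#' @param dt Frame spacing (ps) used when the comment lines carry no
#'   `time=` token.
#' @param water_element Element symbol of water positions. Default `"O"`.
#' @return A [new_trajectory()] object.
#' @export
read_xyz_trajectory <- function(path, n_protein_atoms = 0, dt = 1,
                                water_element = "O") {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(length(lines))] # keep blanks inside frames as errors
  pos <- 1L
  frames <- list()
  times <- numeric(0)
  elements <- NULL
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1L) abort_format("invalid XYZ atom-count header.")
    if (pos + 1L + n > length(lines)) {
      abort_format("XYZ frame truncated: header atom count exceeds file body.")
    }
    comment <- lines[pos + 1L]
    tm <- regmatches(comment, regexec("time=\\s*([-+0-9.eE]+)", comment))[[1]]
    body <- lines[pos + 1L + seq_len(n)]
    parts <- strsplit(trimws(body), "\\s+")
    if (any(lengths(parts) < 4L)) {
      abort_format("XYZ atom line with fewer than 4 fields.")
    }
    el <- vapply(parts, `[[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz)) abort_format("non-numeric coordinate in XYZ file.")
    if (is.null(elements)) {
      elements <- el
    } else if (length(el) != length(elements)) {
      abort_format("XYZ frames contain differing atom counts.")
    }
    frames[[length(frames) + 1L]] <- xyz
    times <- c(times, if (length(tm) == 2L) as.numeric(tm[2]) else
      (length(frames) - 1L) * dt)
    pos <- pos + 2L + n
  }
  if (length(frames) == 0L) abort_format("no frames in XYZ file.")
  na <- length(elements)
  is_water <- toupper(elements) == toupper(water_element) &
    seq_len(na) > n_protein_atoms
  atoms <- tibble(
    serial = seq_len(na),
    name = elements,
    residue_name = ifelse(is_water, "HOH", "UNK"),
    chain_id = ifelse(is_water, "W", "A"),
    residue_seq = seq_len(na),
    element = toupper(elements),
    is_water = is_water,
    vdw_radius = vdw_radius(elements)
  )
  coords <- array(unlist(frames), dim = c(na, 3L, length(frames)))
  # unlist() concatenates column-major per frame: rebuild explicitly
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  new_trajectory(atoms, coords, times = times)
}

#' Write a trajectory as multi-frame XYZ
#'
#' @inheritParams write_pdb_trajectory
#' @export
write_xyz_trajectory <- function(traj, path) {
  out <- character(0)
  for (f in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, f)
    out <- c(out,
             sprintf("%d", n_atoms(traj)),
             sprintf("frame %d time= %.6f", f - 1L, traj$times[f]),
             sprintf("%s %14.6f %14.6f %14.6f", traj$atoms$element,
                     m[, 1], m[, 2], m[, 3]))
  }
  tryCatch(writeLines(out, path),
           error = function(e) abort_io(conditionMessage(e)))
  invisible(path)
}

profile_value_column <- function(profile) {
  if (inherits(profile, "density_profile")) "density"
  else if (inherits(profile, "free_energy_profile")) "dG"
  else if (inherits(profile, "pore_profile")) "radius"
  else if ("value" %in% names(profile)) "value"
  else abort_input("not a recognized profile object.")
}

profile_metadata <- function(profile) {
  keep <- c("dz", "t_f", "dt", "n_frames", "kBT", "temperature", "z_A",
            "diff_error", "sf_z", "sf_radius", "max_probe", "z_range")
  meta <- attributes(profile)[intersect(keep, names(attributes(profile)))]
  meta$type <- setdiff(class(profile), c("tbl_df", "tbl", "data.frame"))[1]
  meta
}

#' Write a profile to CSV or JSON
#'
#' Columns are `z_center`, `value` and, when the profile carries a
#' per-point error, `error_lo`/`error_hi`. Masked bins (no data) are written
#' as explicit `NA` (CSV) / `null` (JSON) rows, never dropped. JSON output
#' embeds the profile metadata (bin width, duration, kBT, reference, ...).
#'
#' @param profile A density, free-energy or pore profile tibble.
#' @param path Output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (nrow(profile) == 0L) abort_input("cannot write an empty profile.")
  vc <- profile_value_column(profile)
  df <- tibble(z_center = profile$z_center, value = profile[[vc]])
  if ("error" %in% names(profile)) {
    df$error_lo <- df$value - profile$error
    df$error_hi <- df$value + profile$error
  }
  ok <- tryCatch({
    if (format == "csv") {
      readr::write_csv(df, path, na = "NA")
    } else {
      jsonlite::write_json(list(metadata = profile_metadata(profile),
                                data = df),
                           path, auto_unbox = TRUE, digits = NA, na = "null",
                           pretty = TRUE)
    }
    TRUE
  }, error = function(e) abort_io(conditionMessage(e)))
  invisible(path)
}

#' Read a profile written by [write_profile()]
#'
#' JSON profiles are restored with their class and metadata; CSV profiles
#' come back as a plain tibble of the written columns.
#'
#' @param path File written by [write_profile()].
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return A tibble.
#' @export
read_profile <- function(path, format = NULL) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  format <- format %||% (if (grepl("\\.json$", path)) "json" else "csv")
  if (format == "csv") {
    return(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
  }
  obj <- jsonlite::fromJSON(path)
  df <- as_tibble(obj$data)
  meta <- obj$metadata
  type <- meta$type
  meta$type <- NULL
  value_name <- switch(type %||% "profile",
                       density_profile = "density",
                       free_energy_profile = "dG",
                       pore_profile = "radius",
                       "value")
  names(df)[names(df) == "value"] <- value_name
  if (all(c("error_lo", "error_hi") %in% names(df))) {
    df$error <- (df$error_hi - df$error_lo) / 2
    df$error_lo <- NULL
    df$error_hi <- NULL
  }
  for (nm in names(meta)) attr(df, nm) <- meta[[nm]]
  if (!is.null(type)) class(df) <- c(type, class(df))
  df
}

#' Reclass a plain table of binned water counts as a density profile
#'
#' For pre-binned data read from CSV: supply `z_center` plus either
#' `density` (waters/Angstrom) or `n_mean` (waters/bin).
#'
#' @param df Data frame with `z_center` and `density` and/or `n_mean`.
#' @param dz Bin width (Angstrom); inferred from `z_center` spacing if omitted.
#' @param spec Optional [channel_spec()] carried along for downstream stages.
#' @return A `density_profile` tibble.
#' @export
as_density_profile <- function(df, dz = NULL, spec = NULL) {
  df <- as_tibble(df)
  if (!"z_center" %in% names(df)) abort_input("`z_center` column required.")
  if (is.null(dz)) {
    if (nrow(df) < 2L) abort_input("cannot infer `dz` from a single bin.")
    dz <- stats::median(diff(sort(df$z_center)))
  }
  if ("value" %in% names(df) && !"density" %in% names(df)) {
    names(df)[names(df) == "value"] <- "density"
  }
  if (!"density" %in% names(df) && "n_mean" %in% names(df)) {
    df$density <- df$n_mean / dz
  }
  if (!"n_mean" %in% names(df) && "density" %in% names(df)) {
    df$n_mean <- df$density * dz
  }
  if (!"density" %in% names(df)) abort_input("`density` or `n_mean` required.")
  attr(df, "dz") <- dz
  attr(df, "spec") <- spec
  class(df) <- unique(c("density_profile", class(df)))
  df
}
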