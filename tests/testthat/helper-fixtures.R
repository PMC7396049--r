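# Fixtures are generated in code; nothing binary is stored.

# A small mixed protein/water trajectory: 3 protein atoms (ALA backbone-ish)
# and `n_waters` waters at given z positions, replicated over frames with an
# optional per-frame z offset.
toy_trajectory <- function(water_z = c(-2, 0, 2), n_frames = 2,
                           frame_shift = 0, with_protein = TRUE) {
  nw <- length(water_z)
  atoms <- water_atoms <- tibble::tibble(
    serial = seq_len(nw), name = "OH2", residue_name = "HOH",
    chain_id = "W", residue_seq = seq_len(nw), element = "O",
    is_water = TRUE, vdw_radius = 1.52
  )
  prot <- tibble::tibble(
    serial = nw + 1:3, name = c("N", "CA", "CB"), residue_name = "ALA",
    chain_id = "A", residue_seq = 1L, element = c("N", "C", "C"),
    is_water = FALSE, vdw_radius = c(1.55, 1.70, 1.70)
  )
  if (with_protein) atoms <- dplyr::bind_rows(water_atoms, prot)
  n <- nrow(atoms)
  coords <- array(0, dim = c(n, 3, n_frames))
  for (f in seq_len(n_frames)) {
    wz <- water_z + (f - 1) * frame_shift
    m <- cbind(rep(0.5, nw), rep(-0.5, nw), wz)
    if (with_protein) {
      m <- rbind(m, cbind(c(8, 9, 10), c(0, 0, 0), c(-3, 0, 3)))
    }
    coords[, , f] <- m
  }
  new_trajectory(atoms, coords, times = seq_len(n_frames) - 1)
}

# Text of a small multi-MODEL PDB, built line by line.
pdb_fixture_lines <- function(models = 2, atoms_per_model = 10) {
  out <- character(0)
  for (m in seq_len(models)) {
    out <- c(out, sprintf("MODEL     %4d", m))
    for (a in seq_len(atoms_per_model)) {
      is_wat <- a > atoms_per_model / 2
      out <- c(out, sprintf(
        "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        a, if (is_wat) " OH2" else " CA ", if (is_wat) "HOH" else "ALA",
        if (is_wat) "W" else "A", a, a * 1.0, m * 0.5, a - m * 1.0, 1, 0,
        if (is_wat) "O" else "C"))
    }
    out <- c(out, "ENDMDL")
  }
  c(out, "END")
}

write_pdb_fixture <- function(path, ...) {
  writeLines(pdb_fixture_lines(...), path)
  path
}

# Independent brute-force oracle for optimal-rotation RMSD: coarse search
# over ZYZ Euler angles followed by Nelder-Mead refinement of the best
# grid point. Never calls the Kabsch path.
euler_zyz <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

rmsd_rotation_oracle <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  obj <- function(ang) {
    R <- euler_zyz(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  grid <- expand.grid(a = seq(0, 2 * pi, by = 0.25),
                      b = seq(0, pi, by = 0.25),
                      c = seq(0, 2 * pi, by = 0.25))
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  fit <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  fit$value
}
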