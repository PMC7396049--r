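.log_levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L)

make_logger <- function(level = "INFO", file = NULL) {
  threshold <- .log_levels[[match.arg(level, names(.log_levels))]]
  function(lvl, msg) {
    if (.log_levels[[lvl]] >= threshold) {
      line <- sprintf("[%s] %s", lvl, msg)
      message(line)
      if (!is.null(file)) cat(line, "\n", file = file, append = TRUE)
    }
    invisible(NULL)
  }
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config not found: %s", path))
  if (grepl("\\.json$", path)) jsonlite::fromJSON(path) else yaml::read_yaml(path)
}

config_spec <- function(cfg) {
  ch <- cfg$channel %||% list()
  channel_spec(
    axis = unlist(ch$axis %||% c(0, 0, 1)),
    anchor = unlist(ch$anchor %||% c(0, 0, 0)),
    z_lo = ch$z_lo %||% -10, z_hi = ch$z_hi %||% 10,
    counting_radius = ch$counting_radius %||% 6,
    extracellular_side = ch$extracellular_side %||% "+z"
  )
}

validate_run_config <- function(cfg) {
  if (!is.list(cfg)) abort_config("config must be a named list (or file path).")
  if (is.null(cfg$trajectory)) abort_config("config needs a `trajectory` path.")
  if (is.null(cfg$out_dir)) abort_config("config needs an `out_dir`.")
  cfg$dz <- cfg$dz %||% 1
  cfg$temperature <- cfg$temperature %||% 298
  cfg$hb_cutoff <- cfg$hb_cutoff %||% 3.5
  cfg$selection <- cfg$selection %||% "heavy"
  cfg$fitted <- cfg$fitted %||% TRUE
  cfg$window <- cfg$window %||% 2000
  cfg$tolerance <- cfg$tolerance %||% 0.5
  cfg$pore_dz <- cfg$pore_dz %||% 0.5
  cfg$max_probe <- cfg$max_probe %||% 10
  cfg$contact_cutoff <- cfg$contact_cutoff %||% 4
  cfg$npa_window <- unlist(cfg$npa_window %||% c(-5, 5))
  cfg$pseudocount <- cfg$pseudocount %||% 0
  cfg$log_level <- cfg$log_level %||% "INFO"
  for (nm in c("dz", "temperature", "hb_cutoff", "window", "tolerance",
               "pore_dz", "max_probe", "contact_cutoff")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort_config(sprintf("config field `%s` must be a positive number.", nm))
    }
  }
  tryCatch(config_spec(cfg),
           error = function(e) abort_config(conditionMessage(e)))
  cfg
}

read_any_trajectory <- function(path, cfg) {
  fmt <- cfg$format %||% (if (grepl("\\.xyz$", path)) "xyz" else "pdb")
  if (fmt == "xyz") {
    read_xyz_trajectory(path, n_protein_atoms = cfg$n_protein_atoms %||% 0,
                        dt = cfg$dt %||% 1)
  } else {
    read_pdb_trajectory(path,
                        water_residues = cfg$water_residues %||%
                          .default_water_residues,
                        dt = cfg$dt %||% 1)
  }
}

#' Run the full permeation analysis pipeline
#'
#' Orchestrates every stage on one trajectory: RMSD + equilibration,
#' water density, Boltzmann-inverted free energy + barrier, pore radius,
#' single-file detection, residue zoning. Each stage's result is written
#' to `out_dir` (`rmsd.csv`, `equilibration.json`, `density.csv`,
#' `free_energy.csv`, `pore_radius.csv`, `single_file.json`,
#' `zoning.json`, `barrier.json`) together with a `manifest.json` echoing
#' the fully resolved configuration. A stage whose prerequisites failed is
#' skipped with a logged reason; an invalid configuration aborts before
#' any input is touched.
#'
#' @param config A named list or a YAML/JSON file path. Required fields:
#'   `trajectory`, `out_dir`. Optional: `reference` (structure path),
#'   `format`, `channel` (axis/anchor/z_lo/z_hi/counting_radius/
#'   extracellular_side), `dz`, `z_range`, `temperature`, `z_A`,
#'   `pseudocount`, `hb_cutoff`, `selection`, `fitted`, `window`,
#'   `tolerance`, `pore_dz`, `max_probe`, `contact_cutoff`, `npa_window`,
#'   `sf_from_pore` (use the pore profile's SF for the barrier report),
#'   `seed`, `log_level`.
#' @return Invisibly, a list with `results` (the stage objects) and
#'   `paths` (files written).
#' @export
run_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  cfg <- validate_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- make_logger(cfg$log_level, file.path(cfg$out_dir, "run.log"))
  spec <- config_spec(cfg)
  results <- list()
  paths <- character(0)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log("WARN", sprintf("stage %s skipped: %s", name, conditionMessage(e)))
      NULL
    })
  }
  out_path <- function(f) file.path(cfg$out_dir, f)

  log("INFO", sprintf("reading trajectory %s", cfg$trajectory))
  traj <- read_any_trajectory(cfg$trajectory, cfg)
  reference <- if (!is.null(cfg$reference)) {
    frame_coords(read_any_trajectory(cfg$reference, cfg), 1L)
  } else {
    1L
  }

  results$rmsd <- run_stage("rmsd", rmsd_series(traj, reference,
                                                selection = cfg$selection,
                                                fitted = cfg$fitted))
  if (!is.null(results$rmsd)) {
    readr::write_csv(results$rmsd, out_path("rmsd.csv"))
    paths <- c(paths, out_path("rmsd.csv"))
    results$equilibration <- run_stage("equilibration",
      detect_equilibration(results$rmsd, cfg$window, cfg$tolerance))
    if (!is.null(results$equilibration)) {
      jsonlite::write_json(as.list(results$equilibration),
                           out_path("equilibration.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      paths <- c(paths, out_path("equilibration.json"))
    }
  }

  results$density <- run_stage("density",
    density_profile(traj, spec, dz = cfg$dz,
                    z_range = unlist(cfg$z_range %||% NULL)))
  if (!is.null(results$density)) {
    write_profile(results$density, out_path("density.csv"), "csv")
    paths <- c(paths, out_path("density.csv"))
    results$free_energy <- run_stage("free_energy",
      boltzmann_invert(results$density, z_A = cfg$z_A,
                       temperature = cfg$temperature,
                       pseudocount = cfg$pseudocount))
  } else {
    log("WARN", "stage free_energy skipped: no density profile")
  }
  if (!is.null(results$free_energy)) {
    write_profile(results$free_energy, out_path("free_energy.csv"), "csv")
    paths <- c(paths, out_path("free_energy.csv"))
  }

  results$pore <- run_stage("pore_radius",
    pore_radius_profile(traj, spec, dz = cfg$pore_dz,
                        max_probe = cfg$max_probe))
  if (!is.null(results$pore)) {
    write_profile(results$pore, out_path("pore_radius.csv"), "csv")
    paths <- c(paths, out_path("pore_radius.csv"))
  }

  if (!is.null(results$free_energy)) {
    sf_z <- if (isTRUE(cfg$sf_from_pore) && !is.null(results$pore)) {
      attr(results$pore, "sf_z")
    } else {
      cfg$sf_z %||% NULL
    }
    results$barrier <- run_stage("barrier",
      extract_barrier(results$free_energy, spec, sf_z = sf_z))
    if (!is.null(results$barrier)) {
      jsonlite::write_json(as.list(results$barrier), out_path("barrier.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      paths <- c(paths, out_path("barrier.json"))
    }
  } else {
    log("WARN", "stage barrier skipped: no free-energy profile")
  }

  results$single_file <- run_stage("single_file",
    detect_single_file(traj, spec, hb_cutoff = cfg$hb_cutoff))
  if (!is.null(results$single_file)) {
    sf <- results$single_file
    jsonlite::write_json(
      list(hb_cutoff = cfg$hb_cutoff,
           frames = purrr::pmap(list(sf$frame, sf$time, sf$n_file, sf$chain_z),
                                function(f, t, n, z)
                                  list(frame = f, time = t, n_file = n,
                                       chain_z = z))),
      out_path("single_file.json"), auto_unbox = TRUE, digits = NA)
    paths <- c(paths, out_path("single_file.json"))
  }

  results$zoning <- run_stage("zoning",
    zone_lining_residues(traj, spec, contact_cutoff = cfg$contact_cutoff,
                         npa_window = cfg$npa_window))
  if (!is.null(results$zoning)) {
    jsonlite::write_json(results$zoning, out_path("zoning.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    paths <- c(paths, out_path("zoning.json"))
  }

  manifest <- list(
    package = "aquaflux",
    version = as.character(utils::packageVersion("aquaflux")),
    seed = cfg$seed %||% NA,
    config = cfg[setdiff(names(cfg), "log_level")]
  )
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  paths <- c(paths, out_path("manifest.json"))
  log("INFO", sprintf("wrote %d outputs to %s", length(paths), cfg$out_dir))
  invisible(list(results = results, paths = paths))
}

build_potential <- function(p) {
  if (is.null(p) || identical(p$type %||% "flat", "flat")) {
    return(potential_flat())
  }
  switch(p$type,
    gaussians = potential_gaussians(unlist(p$height), unlist(p$center %||% 0),
                                    unlist(p$sigma %||% 2)),
    harmonic = potential_harmonic(p$k, p$center %||% 0),
    abort_config(sprintf("unknown potential type `%s`.", p$type))
  )
}

#' Generate a synthetic scenario and write it with its ground truth
#'
#' Builds the scenario from a config, samples the trajectory (exact
#' Boltzmann draws by default, Langevin if requested), writes it as
#' multi-MODEL PDB or XYZ, and records `ground_truth.json` with the
#' imposed potential, the expected Boltzmann density ratios on the
#' analysis bins and the true barrier height, so a recovery test can
#' compare end to end.
#'
#' @param config Named list or YAML/JSON path. Fields: `out_dir`, `seed`
#'   (mandatory), `potential` (`type` = flat/gaussians/harmonic plus
#'   parameters), `box_z`, `z_lo`, `z_hi`, `counting_radius`,
#'   `temperature`, `n_waters`, `n_frames`, `generator`
#'   (`"boltzmann"`/`"langevin"`), `format` (`"pdb"`/`"xyz"`), `dz`.
#' @return Invisibly, list with the `trajectory`, the `scenario` and
#'   `paths` written.
#' @export
run_synthetic <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  cfg <- config
  if (is.null(cfg$out_dir)) abort_config("config needs an `out_dir`.")
  if (is.null(cfg$seed)) {
    abort_config("synthetic generation requires an explicit `seed`.")
  }
  potential <- build_potential(cfg$potential)
  scenario <- tryCatch(
    channel_scenario(
      potential = potential,
      box_z = unlist(cfg$box_z %||% c(-40, 40)),
      z_lo = cfg$z_lo %||% -10, z_hi = cfg$z_hi %||% 10,
      counting_radius = cfg$counting_radius %||% 6,
      temperature = cfg$temperature %||% 298,
      n_waters = cfg$n_waters %||% 100, n_frames = cfg$n_frames %||% 100,
      seed = cfg$seed),
    error = function(e) abort_config(conditionMessage(e)))
  traj <- if (identical(cfg$generator %||% "boltzmann", "langevin")) {
    simulate_langevin_1d(scenario, friction = cfg$friction %||% 1,
                         dt = cfg$langevin_dt %||% 0.05)
  } else {
    sample_boltzmann_trajectory(scenario)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- cfg$format %||% "pdb"
  traj_path <- file.path(cfg$out_dir, paste0("trajectory.", fmt))
  if (fmt == "xyz") write_xyz_trajectory(traj, traj_path)
  else write_pdb_trajectory(traj, traj_path)

  dz <- cfg$dz %||% 1
  zc <- seq(scenario$box_z[1] + dz / 2, scenario$box_z[2] - dz / 2, by = dz)
  u <- potential(zc)
  kBT <- thermal_energy(scenario$temperature)
  # true barrier on a fine grid, independent of the analysis binning
  zf <- seq(scenario$z_lo, scenario$z_hi, by = 0.01)
  uf <- potential(zf)
  u_min <- min(potential(seq(scenario$box_z[1], scenario$box_z[2], by = 0.01)))
  gt <- list(
    potential = list(description = attr(potential, "description"),
                     params = attr(potential, "params")),
    temperature = scenario$temperature, kBT = kBT, seed = cfg$seed,
    dz = dz, z_centers = zc, U = u,
    expected_density_ratio = exp(-(u - u_min) / kBT),
    barrier_height = max(uf) - u_min
  )
  gt_path <- file.path(cfg$out_dir, "ground_truth.json")
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA)
  invisible(list(trajectory = traj, scenario = scenario,
                 paths = c(traj_path, gt_path)))
}
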