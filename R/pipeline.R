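#' Run configuration for the pipeline drivers
#'
#' Assembles the synthetic-world parameters, rank rule, flow rates and
#' seeds consumed by [run_phase1()], [run_phase2()] and [run_phase3()].
#' All randomness in a run is derived from the single `seed`.
#'
#' @param seed root integer seed.
#' @param vdot_max,period,dt,n_frames passed to [waveform_config()].
#' @param train_rates trained inlet flow rates (L/min).
#' @param target_rate untrained rate for interpolation (L/min).
#' @param n_particles,n_injectors passed to [aerosol_spec()].
#' @param mu,sigma_g,rho aerosol size/density parameters.
#' @param rank,energy rank rule for [dmd_fit()] (default: full rank).
#' @param noise_sd measurement-noise s.d. for generated fluid decks (m/s).
#' @param rw_sd particle random-walk step s.d. (m).
#' @param m_frames retained snapshot count for particle decks.
#' @param out_dir optional output directory; when set, the drivers persist
#'   their reports and bundles there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, vdot_max = 50, period = 2.4, dt = 0.015,
                       n_frames = 160L, train_rates = c(40, 50, 60),
                       target_rate = 55, n_particles = 6000L,
                       n_injectors = 20L, mu = 0.42, sigma_g = 3.5,
                       rho = 4390, rank = NULL, energy = NULL,
                       noise_sd = 0, rw_sd = 2e-4, m_frames = 144L,
                       out_dir = NULL) {
  structure(list(seed = as.integer(seed), vdot_max = vdot_max,
                 period = period, dt = dt, n_frames = as.integer(n_frames),
                 train_rates = train_rates, target_rate = target_rate,
                 n_particles = as.integer(n_particles),
                 n_injectors = as.integer(n_injectors), mu = mu,
                 sigma_g = sigma_g, rho = rho, rank = rank,
                 energy = energy, noise_sd = noise_sd, rw_sd = rw_sd,
                 m_frames = as.integer(m_frames), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' Unknown keys are rejected; missing keys take the [run_config()]
#' defaults.
#'
#' @param path JSON file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, raw)
}

default_world <- function(cfg) {
  geo <- toy_airway_geometry()
  wf <- waveform_config(vdot_max = cfg$vdot_max, period = cfg$period,
                        dt = cfg$dt, n_frames = cfg$n_frames)
  list(geometry = geo, spec = field_spec(geo, wf))
}

#' Phase I driver: particle deposition reconstruction
#'
#' Generates (or loads) a particle ensemble, keeps deposited trajectories,
#' truncates the deck to `m_frames` snapshots, fits exact DMD, and runs
#' the deposition comparison ([particle_phase_pipeline()]): radial PDFs
#' about the carina for truth and reconstruction plus their Bhattacharyya
#' coefficient.
#'
#' @param cfg a [run_config()].
#' @return List: `ensemble` (deposited-only), `model`, the
#'   [particle_phase_pipeline()] result (`pdf_truth`, `pdf_dmd`,
#'   `bhattacharyya`, `rmse`), and `n_deposited`.
#' @export
run_phase1 <- function(cfg = run_config()) {
  world <- default_world(cfg)
  deck <- generate_flow_snapshots(world$spec, cfg$vdot_max,
                                  noise_sd = cfg$noise_sd, seed = cfg$seed)
  aero <- aerosol_spec(mu = cfg$mu, sigma_g = cfg$sigma_g, rho = cfg$rho,
                       n_particles = cfg$n_particles,
                       n_injectors = cfg$n_injectors)
  ens <- advect_particles(deck, aero, world$geometry, seed = cfg$seed,
                          rw_sd = cfg$rw_sd)
  dep <- filter_deposited(ens)
  frames <- seq_len(min(cfg$m_frames, dim(dep$trajectories)[3]))
  dep$trajectories <- dep$trajectories[, , frames, drop = FALSE]
  dep$times <- dep$times[frames]
  traj_deck <- as_snapshot_set(dep)
  model <- dmd_fit(build_pair(traj_deck), rank = cfg$rank,
                   energy = cfg$energy)
  res <- particle_phase_pipeline(dep, model, p0 = world$geometry$p0)
  out <- list(ensemble = dep, model = model, pdf_truth = res$pdf_truth,
              pdf_dmd = res$pdf_dmd, bhattacharyya = res$bhattacharyya,
              rmse = res$rmse, n_deposited = sum(ens$deposited))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    summary <- list(
      bhattacharyya = res$bhattacharyya,
      n_deposited = out$n_deposited,
      n_particles = cfg$n_particles,
      mean_rmse_m = mean(res$rmse),
      pdf = list(breaks = res$pdf_truth$breaks,
                 density_truth = res$pdf_truth$density,
                 density_dmd = res$pdf_dmd$density))
    jsonlite::write_json(summary, file.path(cfg$out_dir, "phase1.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Phase II driver: fluid-field reconstruction error
#'
#' Generates a fluid deck at the baseline rate, discards the trailing
#' near-zero frames, fits exact DMD on the retained deck, reconstructs on
#' the same frame grid and assembles the full-field and region error
#' table.
#'
#' @param cfg a [run_config()].
#' @param vdot flow rate (L/min); default `cfg$vdot_max`.
#' @return List: `model`, `truth`, `recon`, `report` (an `error_report`).
#' @export
run_phase2 <- function(cfg = run_config(), vdot = cfg$vdot_max) {
  world <- default_world(cfg)
  deck <- generate_flow_snapshots(world$spec, vdot,
                                  noise_sd = cfg$noise_sd, seed = cfg$seed)
  deck <- drop_trailing_low_energy(deck)
  model <- dmd_fit(build_pair(deck), rank = cfg$rank, energy = cfg$energy)
  recon <- reconstruct_deck(model, deck$times - deck$times[1])
  recon$times <- deck$times
  report <- region_error_table(deck, recon)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report$table,
                       file.path(cfg$out_dir, "phase2_errors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(model = model, truth = deck, recon = recon, report = report)
}

#' Phase III driver: Koopman-operator interpolation
#'
#' Fits DMD models at each trained flow rate, interpolates the reduced
#' operator, POD basis and amplitudes to the target rate, reconstructs the
#' interpolated deck and evaluates it against a held-out generated deck at
#' the same rate.
#'
#' @param cfg a [run_config()].
#' @return List: `models` (per trained rate), `pset` (the interpolation),
#'   `truth` (held-out deck), `recon`, `report`.
#' @export
run_phase3 <- function(cfg = run_config()) {
  world <- default_world(cfg)
  trim <- function(v) drop_trailing_low_energy(
    generate_flow_snapshots(world$spec, v, noise_sd = cfg$noise_sd,
                            seed = cfg$seed + round(v)))
  models <- lapply(cfg$train_rates, function(v)
    dmd_fit(build_pair(trim(v)), rank = cfg$rank, energy = cfg$energy))
  pset <- dmd_interpolate(models, cfg$target_rate)
  truth <- trim(cfg$target_rate)
  recon <- reconstruct_interpolated(pset, truth$times - truth$times[1])
  recon$times <- truth$times
  report <- region_error_table(truth, recon)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report$table,
                       file.path(cfg$out_dir, "phase3_errors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(models = models, pset = pset, truth = truth, recon = recon,
       report = report)
}
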