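# Reproducible runs from a single YAML configuration.
#
# A run configuration names an experiment (single | pack | tissue |
# sweep | ensemble | validate) and overrides defaults that otherwise
# reproduce the production setup: 2048 x 2048 lattice at 100 nm pitch,
# eps = 0.8 kf^2, threshold 1e-4, at most 2000 iterations, ABL of 500
# pixels with kappa = 61.36e2 Np/cm.

default_run_config <- function() {
  list(
    experiment = "single",
    grid = list(n = 2048L, h = 0.1),
    medium = list(vf = 1500, vs = 1950, rho_f = 1000, rho_s = 1000),
    optical = list(I0 = 1, mu = 1, beta = 1, Cp = 1),
    cbs = list(c_eps = 0.8, error_threshold = 1e-4, max_iter = 2000L),
    abl = list(d = 500L, kappa = 61.36e2),
    source = list(x = 0, y = 0, radius = 2.75),
    frequency = list(f = 183, f_min = 2197 / 300, f_max = 2197, n_points = 300L),
    roi = list(shape = "circle", size = 50),
    packing = list(fraction = 0.4, n_disks = 0L,  # 0 = derive from fraction
                   radius = 2.75,
                   overlap_energy_unit = 1000, max_sweeps = 5000L),
    detectors = list(kind = "center_line", radius = 51, count = 200),
    ensemble = list(n_realizations = 5L, vs_list = c(1950, 1500, 1200)),
    seed = 1L,
    output_dir = "pacbs-run")
}

#' Read, validate and resolve a run configuration
#'
#' Reads a YAML file, overlays it on the defaults, rejects unknown keys
#' and checks cross-field constraints (ABL thinner than half the grid,
#' feasible packing fraction, positive sizes) before any computation.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Optional named list applied after the file (as CLI
#'   flags would be).
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user, context = "config")
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides, "overrides")
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

merge_config <- function(base, user, context) {
  if (length(user) == 0) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0)
    stop("unknown ", context, " key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
      merge_config(base[[k]], user[[k]], paste0(context, "$", k))
    else user[[k]]
  }
  base
}

validate_run_config <- function(cfg) {
  ok_exp <- c("single", "pack", "tissue", "sweep", "ensemble", "validate")
  if (!cfg$experiment %in% ok_exp)
    stop("experiment must be one of: ", paste(ok_exp, collapse = ", "))
  if (cfg$grid$n < 64 || cfg$grid$n %% 2 != 0)
    stop("grid$n must be even and >= 64")
  if (cfg$grid$h <= 0) stop("grid$h must be positive (um)")
  if (cfg$abl$d >= cfg$grid$n / 2)
    stop("abl$d = ", cfg$abl$d, " violates the constraint d < n/2 = ",
         cfg$grid$n / 2)
  if (cfg$medium$vf <= 0 || cfg$medium$vs <= 0)
    stop("sound speeds must be positive")
  if (!is.null(cfg$packing$fraction) &&
      (cfg$packing$fraction <= 0 || cfg$packing$fraction >= 0.9))
    stop("packing$fraction must lie in (0, 0.9)")
  invisible(cfg)
}

# Hash of the resolved configuration (md5 of its canonical YAML), so
# every artifact can be traced to the exact settings that produced it.
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

config_objects <- function(cfg) {
  list(
    grid = sim_grid(cfg$grid$n, cfg$grid$h),
    medium = acoustic_medium(cfg$medium$vf, cfg$medium$vs,
                             cfg$medium$rho_f, cfg$medium$rho_s),
    optical = optical_params(cfg$optical$I0, cfg$optical$mu,
                             cfg$optical$beta, cfg$optical$Cp),
    config = cbs_config(cfg$cbs$c_eps, cfg$cbs$error_threshold,
                        cfg$cbs$max_iter, cfg$abl$d, cfg$abl$kappa),
    source_disk = disk(c(cfg$source$x, cfg$source$y), cfg$source$radius),
    roi = roi_spec(cfg$roi$shape, cfg$roi$size),
    freqs = frequency_grid(cfg$frequency$f_min, cfg$frequency$f_max,
                           cfg$frequency$n_points))
}

run_packing <- function(cfg, obj) {
  n_disks <- cfg$packing$n_disks
  if (n_disks <= 0)
    n_disks <- n_disks_for_fraction(obj$roi, cfg$packing$radius,
                                    cfg$packing$fraction)
  pk <- packing_config(n_disks, cfg$packing$radius,
                       cfg$packing$overlap_energy_unit,
                       cfg$packing$max_sweeps, cfg$seed)
  pack_disks(obj$roi, pk)
}

#' Execute a configured run
#'
#' Dispatches on `config$experiment` and writes all artifacts (CSV
#' spectra and center lines, phantom CSV/JSON, a run log with
#' per-iteration convergence errors, and a copy of the resolved
#' configuration) into `config$output_dir`.
#'
#' Experiments: `single` solves one disk and exports the center line
#' and its analytic comparison; `pack` generates and writes a phantom;
#' `tissue` packs a phantom and solves the CBS field over it; `sweep`
#' runs a frequency sweep at ring detectors and exports the average
#' spectrum; `ensemble` computes center-line ensemble statistics;
#' `validate` reports CBS-vs-analytic errors.
#'
#' @param config A `run_config` from [read_run_config()].
#' @return Invisibly, a list of the objects the experiment produced
#'   (also serialized under `output_dir`).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  obj <- config_objects(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(config))
  tag <- paste0("config_hash=", hash)
  yaml::write_yaml(unclass(config),
                   file.path(config$output_dir, "resolved-config.yaml"))
  log_path <- file.path(config$output_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  logf("pacbs run: experiment=%s %s", config$experiment, tag)

  out <- switch(config$experiment,
    pack = {
      tr <- run_packing(config, obj)
      write_phantom(tr, file.path(config$output_dir, "phantom.csv"))
      logf("packed %d disks in %d proposals (energy %g)",
           length(tr$disks), tr$proposals, tr$final_energy)
      list(realization = tr)
    },
    single = {
      f <- config$frequency$f
      sol <- solve_cbs(obj$source_disk, obj$medium, obj$optical, f,
                       obj$grid, obj$config)
      logf("f=%g MHz: %d iterations, converged=%s", f, sol$iterations,
           sol$converged)
      logf("error trace: %s", paste(signif(sol$error_trace, 4), collapse = " "))
      write_field(sol, file.path(config$output_dir, "field-center"),
                  rows = center_row_index(obj$grid), comment = tag)
      cmp <- compare_cbs_analytic(sol, list(disks = obj$source_disk,
                                            medium = obj$medium,
                                            optical = obj$optical))
      jsonlite::write_json(cmp, file.path(config$output_dir, "validation.json"),
                           auto_unbox = TRUE, digits = NA)
      list(solution = sol, comparison = cmp)
    },
    tissue = {
      tr <- run_packing(config, obj)
      write_phantom(tr, file.path(config$output_dir, "phantom.csv"))
      f <- config$frequency$f
      sol <- solve_cbs(tr$disks, obj$medium, obj$optical, f, obj$grid,
                       obj$config)
      logf("f=%g MHz: %d iterations, converged=%s", f, sol$iterations,
           sol$converged)
      write_field(sol, file.path(config$output_dir, "field-center"),
                  rows = center_row_index(obj$grid), comment = tag)
      list(realization = tr, solution = sol)
    },
    sweep = {
      tr <- run_packing(config, obj)
      det <- detector_set("ring", center = obj$roi$origin,
                          radius = config$detectors$radius,
                          count = config$detectors$count)
      scene <- list(disks = tr$disks, medium = obj$medium,
                    optical = obj$optical, grid = obj$grid,
                    config = obj$config)
      sp <- frequency_sweep(scene, obj$freqs, "cbs", det)
      write_spectrum_csv(sp, file.path(config$output_dir, "spectrum.csv"),
                         comment = tag)
      avg <- data.frame(frequency_MHz = obj$freqs$values,
                        mean_amplitude = average_spectrum(sp))
      write.csv(avg, file.path(config$output_dir, "average-spectrum.csv"),
                row.names = FALSE)
      for (k in seq_len(nrow(sp$convergence)))
        logf("f=%g MHz: %d iterations, converged=%s",
             sp$convergence$f[k], sp$convergence$iterations[k],
             sp$convergence$converged[k])
      list(realization = tr, spectrum = sp)
    },
    ensemble = {
      n_disks <- config$packing$n_disks
      if (n_disks <= 0)
        n_disks <- n_disks_for_fraction(obj$roi, config$packing$radius,
                                        config$packing$fraction)
      pk <- packing_config(n_disks, config$packing$radius,
                           config$packing$overlap_energy_unit,
                           config$packing$max_sweeps, config$seed)
      st <- ensemble_center_line_stats(
        obj$roi, pk, config$frequency$f, config$ensemble$vs_list,
        config$ensemble$n_realizations, config$seed, obj$grid,
        obj$medium, obj$optical, obj$config)
      df <- data.frame(vs = st$vs, cbs_mean = st$cbs_mean, cbs_sd = st$cbs_sd,
                       dpa_mean = st$dpa_mean, dpa_sd = st$dpa_sd)
      write.csv(df, file.path(config$output_dir, "ensemble-stats.csv"),
                row.names = FALSE)
      logf("ensemble: %d/%d realizations", st$n_effective, st$n_requested)
      for (msg in st$failures) logf("excluded: %s", msg)
      list(stats = st)
    },
    validate = {
      f <- config$frequency$f
      sol <- solve_cbs(obj$source_disk, obj$medium, obj$optical, f,
                       obj$grid, obj$config)
      cmp <- compare_cbs_analytic(sol, list(disks = obj$source_disk,
                                            medium = obj$medium,
                                            optical = obj$optical))
      logf("f=%g MHz: outside rel L2 %.4g; %d iterations", f,
           cmp$outside$rel_l2, sol$iterations)
      jsonlite::write_json(cmp, file.path(config$output_dir, "validation.json"),
                           auto_unbox = TRUE, digits = NA)
      list(solution = sol, comparison = cmp)
    })
  invisible(out)
}
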