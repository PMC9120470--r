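#' Flow velocity scaling rule for the diameter sweep
#'
#' Linear-in-diameter velocity rule anchored at the measured pairs 20 mm/s at
#' 200 um and 40 mm/s at 400 um, clamped below 0.05 mm (capillary-scale flow
#' does not keep falling linearly). The anchors fix a slope of 100 (mm/s)/mm
#' through the origin; the linear form between and beyond the anchors is an
#' assumption consistent with the two measured pairs.
#'
#' @param D lumen diameter(s) (mm); vectorized.
#' @param anchors_D,anchors_u the two anchor diameters (mm) and velocities
#'   (mm/s).
#' @param clamp_D diameter below which the velocity is held at its value at
#'   `clamp_D`.
#' @return Velocity (mm/s).
#' @export
velocity_for_diameter <- function(D, anchors_D = c(0.2, 0.4),
                                  anchors_u = c(20, 40), clamp_D = 0.05) {
  slope <- diff(anchors_u) / diff(anchors_D)
  intercept <- anchors_u[1] - slope * anchors_D[1]
  intercept + slope * pmax(D, clamp_D)
}

#' Reference flat-top irradiation schedule
#'
#' The single-burst schedule used throughout the diameter sweep: 3000 W peak,
#' 50 us micro-pulses at 10% duty (300 W average), 3 mm spot, one flat-top
#' 80 ms macro-pulse starting at 0.05 s.
#'
#' @param on_start burst start time (s), default 0.05.
#' @param on_duration burst duration (s), default 0.08.
#' @return A `pulse_train`.
#' @export
reference_train <- function(on_start = 0.05, on_duration = 0.08) {
  pulse_train(peak_power = 3000, micro_pulse_duration = 50e-6,
              duty_cycle = 0.10, spot_diameter = 3,
              macro_pulses = data.frame(start = on_start,
                                        duration = on_duration, scale = 1))
}

# write one run's outputs (traces CSV, summary JSON, config echo, log)
.write_run <- function(sim, out_dir, scene_defaults = character()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$traces, file.path(out_dir, "traces.csv"),
                   row.names = FALSE)
  write_scene(sim$scene, file.path(out_dir, "config.yaml"))
  d <- sim$diagnostics
  summary_obj <- list(
    package_version = as.character(utils::packageVersion("photocoag")),
    diameter_mm = sim$scene$diameter,
    duration_s = sim$duration, dt_s = sim$dt,
    grid = list(nx = sim$grid$nx, nz = sim$grid$nz,
                dx_mm = sim$grid$dx, dz_mm = sim$grid$dz),
    delivered_energy_J = sim$energy$delivered_J,
    diagnostics = d,
    tau_max_Pa = max(sim$traces$tau_max_Pa),
    T_wall_peak_C = max(sim$traces$T_wall_prox_C, sim$traces$T_wall_dist_C),
    post_pulse_decay_time_s = post_pulse_decay_time(sim),
    defaulted_config_keys = scene_defaults)
  writeLines(jsonlite::toJSON(summary_obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(out_dir, "summary.json"))
  log_line(file.path(out_dir, "run.log"), "INFO",
           sprintf("run complete: D = %g mm, Omega_max = %.4g, verdict = %s",
                   sim$scene$diameter, d$omega_max_lumen,
                   if (d$coagulated) "coagulated" else "not coagulated"))
  invisible(out_dir)
}

# append a timestamped, level-tagged line to a plain-text log
log_line <- function(path, level, msg) {
  cat(sprintf("%s [%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              level, msg), file = path, append = TRUE)
  invisible(NULL)
}

#' Simulate one configured run, optionally writing a run directory
#'
#' Thin orchestration over [run_simulation()]: accepts either a
#' `vessel_scene` or a path to a YAML config, runs the simulation, and (if
#' `out_dir` is given) writes `traces.csv`, `summary.json`, a `config.yaml`
#' echo of the fully resolved scene (so every defaulted value is on record)
#' and a timestamped log. Outputs are deterministic: the same configuration
#' produces byte-identical trace CSVs.
#'
#' @param scene a `vessel_scene` or a config file path for [load_scene()].
#' @param train a `pulse_train`; default [reference_train()].
#' @param out_dir optional output directory.
#' @param ... further arguments to [run_simulation()].
#' @return The `coag_sim`, invisibly when `out_dir` is given.
#' @export
simulate_run <- function(scene, train = reference_train(), out_dir = NULL,
                         ...) {
  if (is.character(scene)) scene <- load_scene(scene)
  defaults <- attr(scene, "defaults_used")
  sim <- run_simulation(scene, train, ...)
  if (!is.null(out_dir)) {
    .write_run(sim, out_dir, scene_defaults = defaults %||% character())
    return(invisible(sim))
  }
  sim
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sweep lumen diameters under a shared irradiation schedule
#'
#' Runs one simulation per diameter (velocities from the explicit list or the
#' measured-flow scaling rule), collects the comparison table, and optionally
#' writes per-diameter run directories plus the combined CSV. A failed run is
#' recorded and does not abort the sweep.
#'
#' @param diameters lumen diameters (mm), positive, unique, sorted; default
#'   the five-diameter sweep {0.05, 0.1, 0.2, 0.5, 1} mm spanning the studied
#'   range.
#' @param train shared `pulse_train`; default [reference_train()].
#' @param velocities optional explicit per-diameter velocity list (mm/s);
#'   default applies [velocity_for_diameter()].
#' @param duration,dt,output_every passed to [run_simulation()].
#' @param nx_lumen,dz grid resolution (cells across the lumen; axial spacing
#'   in mm).
#' @param out_dir optional output directory; per-diameter runs go into
#'   subdirectories `D_<diameter>` and the combined table into
#'   `sweep_table.csv`.
#' @param scene_args named list of extra arguments passed to every
#'   [vessel_scene()] call (e.g. `list(vessel_class = "venule")`).
#' @return An object of class `coag_sweep`: the comparison `table`
#'   (diameter_mm, u_peak_mm_s, tau_max_Pa, T_wall_peak_C, Omega_max,
#'   verdict, post_pulse_decay_time_s, failed) plus the list of `coag_sim`
#'   objects (`sims`).
#' @export
run_sweep <- function(diameters = c(0.05, 0.1, 0.2, 0.5, 1.0),
                      train = reference_train(), velocities = NULL,
                      duration = 0.2, dt = 1e-3, output_every = 5 * dt,
                      nx_lumen = 20, dz = 0.2,
                      out_dir = NULL, scene_args = list()) {
  if (any(diameters <= 0)) stop("sweep diameters must be positive")
  if (anyDuplicated(diameters)) stop("sweep diameters must be unique")
  if (is.unsorted(diameters)) stop("sweep diameters must be sorted")
  if (is.null(velocities)) velocities <- velocity_for_diameter(diameters)
  if (length(velocities) != length(diameters))
    stop("one velocity per diameter is required")

  sims <- vector("list", length(diameters))
  rows <- vector("list", length(diameters))
  for (i in seq_along(diameters)) {
    D <- diameters[i]
    res <- tryCatch({
      scene <- do.call(vessel_scene,
                       c(list(diameter = D, u_peak = velocities[i]),
                         scene_args))
      grid <- sim_grid(scene, spot_diameter = train$spot_diameter,
                       nx_lumen = nx_lumen, dz = dz)
      sim <- run_simulation(scene, train, grid = grid, duration = duration,
                            dt = dt, output_every = output_every)
      if (!is.null(out_dir))
        .write_run(sim, file.path(out_dir, sprintf("D_%g", D)))
      sim
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (!is.null(out_dir)) {
        dir.create(file.path(out_dir, sprintf("D_%g", D)),
                   recursive = TRUE, showWarnings = FALSE)
        writeLines(conditionMessage(res),
                   file.path(out_dir, sprintf("D_%g", D), "FAILED"))
      }
      rows[[i]] <- data.frame(
        diameter_mm = D, u_peak_mm_s = velocities[i], tau_max_Pa = NA_real_,
        T_wall_peak_C = NA_real_, Omega_max = NA_real_,
        verdict = NA_character_, post_pulse_decay_time_s = NA_real_,
        failed = TRUE)
    } else {
      sims[[i]] <- res
      d <- res$diagnostics
      rows[[i]] <- data.frame(
        diameter_mm = D, u_peak_mm_s = velocities[i],
        tau_max_Pa = max(res$traces$tau_max_Pa),
        T_wall_peak_C = max(res$traces$T_wall_prox_C,
                            res$traces$T_wall_dist_C),
        Omega_max = d$omega_max_lumen,
        verdict = if (d$coagulated) "coagulated" else "not coagulated",
        post_pulse_decay_time_s = post_pulse_decay_time(res),
        failed = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "sweep_table.csv"),
                     row.names = FALSE)
  }
  structure(list(table = tab, sims = sims, train = train),
            class = "coag_sweep")
}

#' @export
print.coag_sweep <- function(x, ...) {
  cat(sprintf("Diameter sweep: %d vessels under a shared schedule (%.4g J)\n",
              nrow(x$table), train_energy(x$train)))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
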