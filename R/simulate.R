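#' Run a coupled photocoagulation simulation
#'
#' Orchestrates one irradiation experiment: pulsed-light heat deposition
#' (flat-top beam, Beer-Lambert attenuation), operator-split
#' advection-diffusion heat transfer with temperature-dependent blood
#' viscosity and the quasi-steady laminar velocity profile, wall shear stress
#' extraction, and Arrhenius damage accumulation for blood (lumen) and tissue
#' (perivascular) with their respective kinetics. Fully deterministic: the
#' same configuration always produces identical traces.
#'
#' @param scene a `vessel_scene`.
#' @param train a `pulse_train`; defaults to the single 300 W-average,
#'   50 ms flat-top burst starting at 0.05 s.
#' @param grid a `sim_grid`, or `NULL` to build the default grid for the
#'   scene and the train's spot (20 cells across the lumen).
#' @param duration simulated time (s), default 0.2.
#' @param dt outer time step (s), default 1e-3. Diffusion is implicit
#'   (unconditionally stable); advection sub-steps internally to respect its
#'   CFL limit, so `dt` controls accuracy, not stability.
#' @param output_every trace recording interval (s), default `5 * dt`.
#' @param bc depth-boundary condition: `"farfield"` (tissue held at baseline
#'   far from the vessel, the physical default) or `"insulated"` (zero-flux,
#'   for energy-conservation checks).
#' @return An object of class `coag_sim`: trace data.frame (`traces` with
#'   columns time_s, T_wall_prox_C, T_wall_dist_C, T_center_C, tau_prox_Pa,
#'   tau_dist_Pa, tau_max_Pa, u_center_mm_s, Omega_max), final damage fields
#'   (`omega_blood`, `omega_tissue`), first threshold-crossing times
#'   (`t_cross_blood`), the final `field_state`, energy bookkeeping and the
#'   scalar `diagnostics` summary.
#' @export
run_simulation <- function(scene, train = pulse_train(), grid = NULL,
                           duration = 0.2, dt = 1e-3, output_every = 5 * dt,
                           bc = c("farfield", "insulated")) {
  stopifnot(inherits(scene, "vessel_scene"), inherits(train, "pulse_train"))
  bc <- match.arg(bc)
  if (is.null(grid)) grid <- sim_grid(scene, spot_diameter = train$spot_diameter)
  n_steps <- as.integer(ceiling(duration / dt))
  rec_every <- max(1L, as.integer(round(output_every / dt)))

  sys <- .diffusion_system(scene, grid, dt, bc = bc)
  state <- field_state(scene, grid)
  prof <- deposition_profile(scene, grid)
  spot_cols <- as.numeric(grid$spot_z)
  area <- spot_area(train$spot_diameter)
  cellvol <- grid$dx * grid$dz        # per unit section thickness (mm^2)

  omega_b <- matrix(0, grid$nx, grid$nz)
  omega_t <- matrix(0, grid$nx, grid$nz)
  t_cross <- matrix(NA_real_, grid$nx, grid$nz)
  thr <- scene$arrhenius_blood$threshold
  lum_rows <- grid$i_prox:grid$i_dist
  j_mid <- which.min(abs(grid$z - grid$L / 2))
  j_exit <- max(which(grid$spot_z))
  i_mid <- lum_rows[ceiling(length(lum_rows) / 2)]
  kf_prox <- 2 * sys$kx[grid$i_prox - 1L] * sys$kx[grid$i_prox] /
    (sys$kx[grid$i_prox - 1L] + sys$kx[grid$i_prox])
  kf_dist <- 2 * sys$kx[grid$i_dist] * sys$kx[grid$i_dist + 1L] /
    (sys$kx[grid$i_dist] + sys$kx[grid$i_dist + 1L])

  adv_sum <- 0; cond_sum <- 0
  e_dep <- 0
  T_peak <- scene$T0

  rec <- function(st, om) {
    sh <- wall_shear(st, grid)
    sw <- grid$spot_z
    data.frame(
      time_s = st$t,
      T_wall_prox_C = max(st$T_C[grid$i_prox, sw]),
      T_wall_dist_C = max(st$T_C[grid$i_dist, sw]),
      T_center_C = st$T_C[i_mid, j_mid],
      tau_prox_Pa = sh$tau_prox_max,
      tau_dist_Pa = sh$tau_dist_max,
      tau_max_Pa = sh$tau_max,
      u_center_mm_s = st$flow$u_centers[i_mid, j_mid],
      Omega_max = max(om[lum_rows, sw]))
  }
  traces <- vector("list", n_steps %/% rec_every + 2L)
  traces[[1L]] <- rec(state, omega_b)
  n_rec <- 1L

  for (k in seq_len(n_steps)) {
    t0 <- (k - 1L) * dt; t1 <- k * dt
    P <- train_energy(train, t0, t1) / dt
    S <- outer(prof * (P / area), spot_cols)
    state <- step_heat(state, scene, grid, S, dt, sys = sys)
    e_dep <- e_dep + sum(S) * cellvol * dt
    T_peak <- max(T_peak, max(state$T_C))

    omega_b <- accumulate_damage(omega_b, state$T_C, dt, scene$arrhenius_blood)
    omega_t <- accumulate_damage(omega_t, state$T_C, dt, scene$arrhenius_tissue)
    crossed <- is.na(t_cross) & omega_b >= thr
    t_cross[crossed] <- state$t

    if (P > 0) {
      theta <- state$T_C - scene$T0
      adv <- sum(scene$rhoC_blood * state$flow$u_centers[lum_rows, j_exit] *
                   theta[lum_rows, j_exit]) * grid$dx
      cond <- sum(pmax(0, kf_prox *
                         (theta[grid$i_prox, grid$spot_z] -
                            theta[grid$i_prox - 1L, grid$spot_z]) / grid$dx) +
                  pmax(0, kf_dist *
                         (theta[grid$i_dist, grid$spot_z] -
                            theta[grid$i_dist + 1L, grid$spot_z]) / grid$dx)) *
        grid$dz
      adv_sum <- adv_sum + adv * dt
      cond_sum <- cond_sum + cond * dt
    }

    if (k %% rec_every == 0L || k == n_steps) {
      n_rec <- n_rec + 1L
      traces[[n_rec]] <- rec(state, omega_b)
    }
  }

  traces <- do.call(rbind, traces[seq_len(n_rec)])
  diag <- .diagnostics_summary(scene, grid, train, omega_b, omega_t,
                               adv_sum, cond_sum, T_peak)
  structure(
    list(traces = traces, scene = scene, train = train, grid = grid,
         omega_blood = omega_b, omega_tissue = omega_t,
         t_cross_blood = t_cross, state = state,
         energy = list(
           deposited_J_per_mm = e_dep,
           delivered_J = train_energy(train, 0, duration)),
         diagnostics = diag, dt = dt, duration = duration, bc = bc),
    class = "coag_sim")
}

#' @export
print.coag_sim <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("Photocoagulation simulation: %g mm lumen, %.3g s simulated\n",
              x$scene$diameter, x$duration))
  cat(sprintf("  peak temperature    %.1f degC%s\n", d$T_peak,
              if (d$rupture_risk) "  [rupture risk: > 100 degC]" else ""))
  cat(sprintf("  peak wall shear     %.3g Pa\n", max(x$traces$tau_max_Pa)))
  cat(sprintf("  max lumen Omega     %.3g -> %s\n", d$omega_max_lumen,
              if (d$coagulated) "coagulated (cross-lumen band)"
              else "not coagulated"))
  invisible(x)
}

#' @export
summary.coag_sim <- function(object, ...) {
  d <- object$diagnostics
  structure(list(scene = object$scene, diagnostics = d,
                 decay_time = post_pulse_decay_time(object),
                 energy = object$energy),
            class = "summary.coag_sim")
}

#' @export
print.summary.coag_sim <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("Diagnostics for %g mm lumen (%s)\n",
              x$scene$diameter, x$scene$vessel_class))
  cat(sprintf("  Peclet number                 %.3g\n", d$peclet))
  cat(sprintf("  advected/conducted flux ratio %.3g\n", d$convective_ratio))
  cat(sprintf("  spot transit time             %.4g s (longest macro-pulse %.4g s%s)\n",
              d$transit_time, d$longest_macro_pulse,
              if (d$pulse_exceeds_transit) ", pulse outlasts transit" else ""))
  cat(sprintf("  max Omega  lumen %.3g, tissue %.3g\n",
              d$omega_max_lumen, d$omega_max_tissue))
  cat(sprintf("  verdict: %s (%d band station%s)\n",
              if (d$coagulated) "coagulated" else "not coagulated",
              d$band_stations, if (d$band_stations == 1) "" else "s"))
  cat(sprintf("  post-pulse wall decay time    %.4g s\n", x$decay_time))
  cat(sprintf("  delivered energy              %.4g J\n", x$energy$delivered_J))
  invisible(x)
}

#' Plot simulation traces
#'
#' Two stacked panels over time: wall/center temperatures and wall shear
#' stress; the irradiation window is shaded.
#'
#' @param x a `coag_sim`.
#' @param ... ignored.
#' @export
plot.coag_sim <- function(x, ...) {
  tr <- x$traces
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  shade <- function() {
    m <- x$train$macro_pulses
    usr <- graphics::par("usr")
    for (i in seq_len(nrow(m)))
      graphics::rect(m$start[i], usr[3], m$start[i] + m$duration[i], usr[4],
                     col = grDevices::adjustcolor("orange", 0.15), border = NA)
  }
  graphics::plot(tr$time_s, tr$T_wall_prox_C, type = "l", col = "firebrick",
                 xlab = "time (s)", ylab = "temperature (degC)",
                 ylim = range(tr$T_wall_prox_C, tr$T_wall_dist_C,
                              tr$T_center_C),
                 main = sprintf("%g mm lumen", x$scene$diameter))
  shade()
  graphics::lines(tr$time_s, tr$T_wall_dist_C, col = "darkorange")
  graphics::lines(tr$time_s, tr$T_center_C, col = "steelblue")
  graphics::legend("topright", c("proximal wall", "distal wall", "center"),
                   col = c("firebrick", "darkorange", "steelblue"),
                   lty = 1, bty = "n", cex = 0.8)
  graphics::plot(tr$time_s, tr$tau_max_Pa, type = "l",
                 xlab = "time (s)", ylab = "wall shear stress (Pa)")
  shade()
  invisible(x)
}
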