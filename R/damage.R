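#' Arrhenius damage accumulation rate
#'
#' First-order denaturation rate A exp(-Ea / (R T)) at a temperature given in
#' degrees C (converted to kelvin internally).
#'
#' @param T_C temperature (degC); vectorized, matrices preserved.
#' @param params an [arrhenius_params()].
#' @return Damage rate (1/s).
#' @export
damage_rate <- function(T_C, params) {
  stopifnot(inherits(params, "arrhenius_params"))
  params$A * exp(-params$Ea / (params$R_gas * (T_C + 273.15)))
}

#' Accumulate Arrhenius thermal damage over a time step
#'
#' Omega <- Omega + A exp(-Ea / (R T)) dt, per cell. Omega is dimensionless,
#' non-negative and non-decreasing in time; Omega = 1 conventionally marks
#' coagulation.
#'
#' @param omega current damage field (matrix or vector).
#' @param T_C temperature field (degC), same shape.
#' @param dt time step (s), >= 0.
#' @param params an [arrhenius_params()].
#' @return Updated damage field.
#' @export
accumulate_damage <- function(omega, T_C, dt, params) {
  if (dt < 0) stop("dt must be non-negative")
  if (dt == 0) return(omega)
  omega + damage_rate(T_C, params) * dt
}

#' Coagulation verdict from a damage field
#'
#' The vessel counts as coagulated only if the damage threshold is met across
#' a full lumen cross-section at some axial station inside the spot window (a
#' flow-blocking band); damage confined to one wall leaves a patent channel
#' and flow persists past the partial coagulum.
#'
#' @param omega damage field over the whole grid (nx x nz matrix).
#' @param grid the `sim_grid`.
#' @param threshold damage threshold, default 1.
#' @return List with `coagulated` (logical), `omega_max` (max over the lumen
#'   inside the spot window) and `band_stations` (number of axial stations
#'   with a full cross-lumen band at threshold).
#' @export
coagulation_verdict <- function(omega, grid, threshold = 1) {
  lum <- omega[grid$i_prox:grid$i_dist, grid$spot_z, drop = FALSE]
  band <- apply(lum >= threshold, 2L, all)
  list(coagulated = any(band), omega_max = max(lum),
       band_stations = sum(band))
}

#' Peclet number of the lumen flow
#'
#' u_mean D / alpha: the ratio of axial advective to conductive transport
#' rates across the lumen.
#'
#' @param u_mean mean flow velocity (mm/s).
#' @param D lumen diameter (mm).
#' @param alpha thermal diffusivity (mm^2/s).
#' @return Dimensionless Peclet number.
#' @export
peclet_number <- function(u_mean, D, alpha) {
  if (alpha <= 0) stop("thermal diffusivity must be positive")
  u_mean * D / alpha
}

# scalar diagnostics assembled at the end of a run; flux accumulators come
# from the simulation loop (time-integrated over irradiation).
.diagnostics_summary <- function(scene, grid, train, omega_blood,
                                 omega_tissue, adv_sum, cond_sum, T_peak) {
  u_mean <- if (scene$velocity_is == "peak") (2 / 3) * scene$u_peak
            else scene$u_peak
  vb <- coagulation_verdict(omega_blood, grid,
                            scene$arrhenius_blood$threshold)
  omax_t <- max(omega_tissue[!grid$lumen_x, grid$spot_z])
  tt <- transit_time(grid$spot_diameter, u_mean)
  longest_macro <- if (nrow(train$macro_pulses))
    max(train$macro_pulses$duration) else 0
  list(
    peclet = peclet_number(u_mean, scene$diameter, scene$alpha_blood),
    convective_ratio = if (cond_sum > 0) adv_sum / cond_sum else 0,
    transit_time = as.numeric(tt),
    longest_macro_pulse = longest_macro,
    pulse_exceeds_transit = longest_macro > as.numeric(tt),
    omega_max_lumen = vb$omega_max,
    omega_max_tissue = omax_t,
    coagulated = vb$coagulated,
    band_stations = vb$band_stations,
    T_peak = T_peak,
    rupture_risk = T_peak > scene$rupture_T_C)
}

#' Post-pulse wall-temperature decay time
#'
#' Exponential-equivalent decay time of the proximal-wall temperature excess
#' after the last macro-pulse ends: (t_end - t_off) / log(E_off / E_end),
#' where E is the wall temperature excess over baseline at pulse-off and at
#' the end of the recorded traces. Larger lumens hold their heat longer
#' (relaxation time grows as D^2), so this increases with diameter.
#'
#' @param sim a `coag_sim` from [run_simulation()].
#' @return Decay time (s); `NA` if the trace does not extend past the pulse,
#'   `Inf` if the wall has not cooled at all by the end of the record.
#' @export
post_pulse_decay_time <- function(sim) {
  stopifnot(inherits(sim, "coag_sim"))
  tr <- sim$traces
  m <- sim$train$macro_pulses
  if (!nrow(m)) return(NA_real_)
  t_off <- max(m$start + m$duration)
  after <- tr$time_s >= t_off
  if (sum(after) < 2) return(NA_real_)
  T0 <- sim$scene$T0
  e0 <- tr$T_wall_prox_C[which(after)[1L]] - T0
  e1 <- tr$T_wall_prox_C[nrow(tr)] - T0
  if (e0 <= 0) return(NA_real_)
  if (e1 >= e0) return(Inf)
  if (e1 <= 0) return(0)
  (tr$time_s[nrow(tr)] - tr$time_s[which(after)[1L]]) / log(e0 / e1)
}
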