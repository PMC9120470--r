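#' Thermal relaxation time of a vessel lumen
#'
#' Characteristic conductive cooling time of a heated cylindrical structure of
#' diameter D: D^2 / (16 alpha). Selective photothermolysis confines damage to
#' the vessel by keeping the pulse duration at or below this time.
#'
#' @param D lumen diameter (mm).
#' @param alpha thermal diffusivity (mm^2/s), default 0.15.
#' @return Relaxation time (s). Vectorized over `D`.
#' @export
thermal_relaxation_time <- function(D, alpha = 0.15) {
  if (any(D <= 0)) stop("diameter must be positive")
  if (any(alpha <= 0)) stop("thermal diffusivity must be positive")
  D^2 / (16 * alpha)
}

#' Adiabatic temperature rise from an absorbed fluence
#'
#' Instantaneous-deposition estimate delta-T = mua * Phi / (rho C): the energy
#' a unit volume of blood absorbs from fluence Phi, divided by its heat
#' capacity, ignoring conduction and flow during the pulse.
#'
#' @param fluence radiant exposure Phi (J/mm^2).
#' @param mua absorption coefficient (1/mm), default 0.3 (blood at 1.07 um).
#' @param rhoC volumetric heat capacity (J/(mm^3 K)), default 0.004.
#' @return Temperature rise (K). Vectorized over `fluence`.
#' @export
temperature_rise <- function(fluence, mua = 0.3, rhoC = 0.004) {
  if (any(mua <= 0)) stop("absorption coefficient must be positive")
  if (any(rhoC <= 0)) stop("volumetric heat capacity must be positive")
  if (any(fluence < 0)) stop("fluence must be non-negative")
  mua * fluence / rhoC
}

#' Beam spot area
#' @param spot_diameter spot diameter (mm).
#' @return Area (mm^2) of the circular spot.
#' @export
spot_area <- function(spot_diameter) {
  if (any(spot_diameter <= 0)) stop("spot diameter must be positive")
  pi * (spot_diameter / 2)^2
}

#' Blood transit time through a segment
#'
#' Time for blood moving at the given mean velocity to traverse the segment.
#' Heat advected out of the irradiation spot within the pulse duration is lost
#' to coagulation, so pulses much longer than the spot transit time waste
#' energy downstream.
#'
#' @param segment_length length traversed (mm).
#' @param mean_velocity mean flow velocity (mm/s).
#' @return Transit time (s). A zero velocity with a positive length returns
#'   `Inf` with attribute `no_flow = TRUE` rather than an error; a zero-length
#'   segment returns 0.
#' @export
transit_time <- function(segment_length, mean_velocity) {
  if (segment_length < 0) stop("segment length must be non-negative")
  if (mean_velocity < 0) stop("mean velocity must be non-negative")
  if (segment_length == 0) return(0)
  if (mean_velocity == 0)
    return(structure(Inf, no_flow = TRUE))
  segment_length / mean_velocity
}

#' Construct a pulsed-laser irradiation schedule
#'
#' A pulse train is a macro-pulse schedule of flat-top irradiation bursts,
#' each burst internally composed of micro-pulses (default 50 us at the
#' repetition rate implied by the duty cycle). The thermal solver treats the
#' micro-pulse structure as its average-power envelope because the micro-pulse
#' period (0.5 ms at 10% duty) is far below every thermal time scale in play.
#'
#' @param peak_power micro-pulse peak power (W), default 3000.
#' @param micro_pulse_duration micro-pulse duration (s), default 50e-6.
#' @param duty_cycle on-fraction of the micro-pulse train, default 0.10. The
#'   repetition rate is `duty_cycle / micro_pulse_duration` (2000 Hz at the
#'   defaults) and the average power `peak_power * duty_cycle` (300 W).
#' @param spot_diameter beam spot diameter (mm), default 3.
#' @param macro_pulses data.frame with columns `start` (s), `duration` (s),
#'   `scale` (peak-power scale factor in (0, 1]); rows chronological and
#'   non-overlapping. Default: one 80 ms burst starting at 0.05 s.
#' @return An object of class `pulse_train`.
#' @export
pulse_train <- function(peak_power = 3000, micro_pulse_duration = 50e-6,
                        duty_cycle = 0.10, spot_diameter = 3,
                        macro_pulses = data.frame(start = 0.05,
                                                  duration = 0.08,
                                                  scale = 1)) {
  if (peak_power < 0) stop("peak power must be non-negative")
  if (micro_pulse_duration <= 0) stop("micro-pulse duration must be positive")
  if (duty_cycle <= 0 || duty_cycle > 1)
    stop("duty cycle must lie in (0, 1]")
  if (spot_diameter <= 0) stop("spot diameter must be positive")
  mp <- as.data.frame(macro_pulses)
  if (!all(c("start", "duration", "scale") %in% names(mp)))
    stop("macro_pulses needs columns start, duration, scale")
  if (nrow(mp)) {
    if (any(mp$duration < 0) || any(mp$start < 0) || any(mp$scale < 0))
      stop("macro-pulse entries must be non-negative")
    if (is.unsorted(mp$start, strictly = FALSE))
      stop("macro-pulse entries must be chronologically ordered")
    if (nrow(mp) > 1 &&
        any(mp$start[-1] < (mp$start + mp$duration)[-nrow(mp)]))
      stop("macro-pulse entries must not overlap")
  }
  structure(
    list(peak_power = peak_power,
         micro_pulse_duration = micro_pulse_duration,
         duty_cycle = duty_cycle,
         repetition_rate = duty_cycle / micro_pulse_duration,
         average_power = peak_power * duty_cycle,
         spot_diameter = spot_diameter,
         macro_pulses = mp),
    class = "pulse_train")
}

#' Instantaneous envelope power of a pulse train
#'
#' The micro-pulse-averaged delivered power at time `t`:
#' `average_power * scale` inside a macro-pulse, 0 outside.
#'
#' @param train a `pulse_train`.
#' @param t time(s) (s); vectorized.
#' @return Power (W).
#' @export
train_power <- function(train, t) {
  stopifnot(inherits(train, "pulse_train"))
  p <- numeric(length(t))
  for (i in seq_len(nrow(train$macro_pulses))) {
    m <- train$macro_pulses[i, ]
    on <- t >= m$start & t < m$start + m$duration
    p[on] <- train$average_power * m$scale
  }
  p
}

#' Energy delivered by a pulse train over an interval
#'
#' Exact integral of the envelope power over `[t0, t1]` (the whole schedule if
#' the interval is omitted). Bookkeeping identity: average power times total
#' scaled on-time.
#'
#' @param train a `pulse_train`.
#' @param t0,t1 integration bounds (s).
#' @return Energy (J).
#' @export
train_energy <- function(train, t0 = -Inf, t1 = Inf) {
  stopifnot(inherits(train, "pulse_train"))
  m <- train$macro_pulses
  if (!nrow(m)) return(0)
  overlap <- pmax(0, pmin(m$start + m$duration, t1) - pmax(m$start, t0))
  sum(train$average_power * m$scale * overlap)
}

#' Total on-time covered by macro-pulses
#' @param train a `pulse_train`.
#' @return Summed (unscaled) macro-pulse duration (s).
#' @export
train_on_time <- function(train) sum(train$macro_pulses$duration)

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf(
    "Pulse train: %g W peak, %g us micro-pulses, %.0f%% duty (%g Hz), %g W avg, %g mm spot\n",
    x$peak_power, x$micro_pulse_duration * 1e6, 100 * x$duty_cycle,
    x$repetition_rate, x$average_power, x$spot_diameter))
  m <- x$macro_pulses
  for (i in seq_len(nrow(m)))
    cat(sprintf("  macro-pulse %d: t = %.4g s, %.4g ms, power scale %.2g\n",
                i, m$start[i], 1e3 * m$duration[i], m$scale[i]))
  cat(sprintf("  total delivered energy %.4g J\n", train_energy(x)))
  invisible(x)
}

#' Stacked-pulse irradiation protocol for large vessels
#'
#' Generates the two-stage schedule used for coagulating large
#' (0.5-1 mm) vessels: an initial long macro-pulse, about five times the
#' selective-photothermolysis relaxation time, conditions the vessel by
#' raising viscosity and collapsing flow (clamped to 100-200 ms for
#' D >= 0.5 mm, the empirically workable irradiation window), followed by
#' shorter macro-pulses of one relaxation time each at reduced power that
#' complete hemostasis. For venules the peak-power scale is halved and every
#' duration (and gap) doubled, keeping the delivered energy fixed, which
#' reduces one-sided cavitation and rupture.
#'
#' The follow-up pulse count, their power scale and the inter-pulse gap are
#' implementation choices (not experimentally pinned down); they are recorded
#' in the `assumptions` attribute of the result.
#'
#' @param D lumen diameter (mm).
#' @param alpha thermal diffusivity (mm^2/s).
#' @param vessel_class `"arteriole"` or `"venule"`.
#' @param initial_factor multiple of the relaxation time for the initial
#'   pulse; default 5.
#' @param initial_clamp two-element range (s) the initial duration is clamped
#'   to for D >= `clamp_min_D`; default `c(0.1, 0.2)`.
#' @param clamp_min_D diameter (mm) above which the clamp applies; default 0.5.
#' @param n_followup number of follow-up macro-pulses; default 3.
#' @param followup_scale peak-power scale of follow-up pulses; default 0.5.
#' @param gap inter-pulse gap (s); default 0.05.
#' @param peak_power,micro_pulse_duration,duty_cycle,spot_diameter passed to
#'   [pulse_train()].
#' @return A `pulse_train` whose macro-pulse schedule realizes the protocol,
#'   with attribute `assumptions` listing non-measured defaults used.
#' @export
stacked_protocol <- function(D, alpha = 0.15,
                             vessel_class = c("arteriole", "venule"),
                             initial_factor = 5,
                             initial_clamp = c(0.1, 0.2), clamp_min_D = 0.5,
                             n_followup = 3, followup_scale = 0.5,
                             gap = 0.05,
                             peak_power = 3000, micro_pulse_duration = 50e-6,
                             duty_cycle = 0.10, spot_diameter = 3) {
  vessel_class <- match.arg(vessel_class)
  trt <- thermal_relaxation_time(D, alpha)
  init_dur <- initial_factor * trt
  if (D >= clamp_min_D)
    init_dur <- min(max(init_dur, initial_clamp[1]), initial_clamp[2])
  durations <- c(init_dur, rep(trt, n_followup))
  scales <- c(1, rep(followup_scale, n_followup))
  gaps <- rep(gap, length(durations))
  if (vessel_class == "venule") {
    scales <- scales / 2
    durations <- durations * 2
    gaps <- gaps * 2
  }
  start <- cumsum(c(0, (durations + gaps)[-length(durations)]))
  train <- pulse_train(
    peak_power = peak_power, micro_pulse_duration = micro_pulse_duration,
    duty_cycle = duty_cycle, spot_diameter = spot_diameter,
    macro_pulses = data.frame(start = start, duration = durations,
                              scale = scales))
  attr(train, "assumptions") <- c(
    sprintf("initial pulse fixed at %g x thermal relaxation time", initial_factor),
    sprintf("%d follow-up pulses at power scale %g (not experimentally specified)",
            n_followup, followup_scale),
    sprintf("inter-pulse gap %g s (not experimentally specified)", gap))
  train
}

#' Closed-form dosimetry report for one vessel
#'
#' Evaluates the selective-photothermolysis arithmetic for a vessel of
#' diameter `D`: thermal relaxation time, the fluence and pulse energy needed
#' to raise blood from baseline to the coagulation onset temperature (or the
#' temperature rise delivered by a supplied pulse energy), the spot transit
#' time of flowing blood, and the two safety/efficacy flags: rupture risk when
#' the predicted temperature exceeds `rupture_T_C`, and a warning when the
#' recommended pulse duration exceeds the blood transit time through the spot
#' (heat is then advected away during the pulse).
#'
#' @param D lumen diameter (mm).
#' @param spot_diameter beam spot diameter (mm), default 3.
#' @param vessel_class `"arteriole"` or `"venule"`.
#' @param energy optional delivered pulse energy (J); if `NULL` the energy
#'   required to reach `coag_onset_C` is computed instead.
#' @param alpha,mua,rhoC,T0 physical parameters as in [vessel_scene()].
#' @param coag_onset_C target coagulation onset temperature (degC).
#' @param rupture_T_C rupture-risk temperature (degC).
#' @param mean_velocity mean blood velocity (mm/s); default is 2/3 of the
#'   peak velocity from [velocity_for_diameter()] (planar parabolic profile).
#' @return An object of class `dosimetry_report`.
#' @export
dosimetry_report <- function(D, spot_diameter = 3,
                             vessel_class = c("arteriole", "venule"),
                             energy = NULL,
                             alpha = 0.15, mua = 0.3, rhoC = 0.004, T0 = 37,
                             coag_onset_C = 55, rupture_T_C = 100,
                             mean_velocity = (2 / 3) * velocity_for_diameter(D)) {
  vessel_class <- match.arg(vessel_class)
  trt <- thermal_relaxation_time(D, alpha)
  area <- spot_area(spot_diameter)
  if (is.null(energy)) {
    fluence <- (coag_onset_C - T0) * rhoC / mua
    energy <- fluence * area
  } else {
    fluence <- energy / area
  }
  dT <- temperature_rise(fluence, mua, rhoC)
  tt <- transit_time(spot_diameter, mean_velocity)
  structure(
    list(D = D, spot_diameter = spot_diameter, vessel_class = vessel_class,
         thermal_relaxation_time = trt,
         fluence = fluence, predicted_dT = dT, predicted_T = T0 + dT,
         pulse_energy = energy,
         transit_time = as.numeric(tt),
         rupture_risk = (T0 + dT) > rupture_T_C,
         reaches_coag_onset = (T0 + dT) >= coag_onset_C,
         pulse_exceeds_transit = trt > as.numeric(tt),
         coag_onset_C = coag_onset_C, rupture_T_C = rupture_T_C, T0 = T0),
    class = "dosimetry_report")
}

#' @export
print.dosimetry_report <- function(x, ...) {
  cat(sprintf("Dosimetry for a %g mm %s, %g mm spot\n",
              x$D, x$vessel_class, x$spot_diameter))
  cat(sprintf("  thermal relaxation time  %.4g s\n", x$thermal_relaxation_time))
  cat(sprintf("  pulse energy             %.4g J (fluence %.4g J/mm^2)\n",
              x$pulse_energy, x$fluence))
  cat(sprintf("  predicted temperature    %.1f degC (rise %.1f K from %g degC)\n",
              x$predicted_T, x$predicted_dT, x$T0))
  cat(sprintf("  spot transit time        %.4g s\n", x$transit_time))
  if (x$rupture_risk)
    cat(sprintf("  FLAG: predicted temperature exceeds %g degC rupture threshold\n",
                x$rupture_T_C))
  if (!x$reaches_coag_onset)
    cat(sprintf("  FLAG: predicted temperature below %g degC coagulation onset\n",
                x$coag_onset_C))
  if (x$pulse_exceeds_transit)
    cat("  FLAG: relaxation-time pulse outlasts blood transit through the spot\n")
  invisible(x)
}

#' Serialize a dosimetry report or pulse train to JSON
#' @param x a `dosimetry_report` or `pulse_train`.
#' @param path optional file to write; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
as_json <- function(x, path = NULL) {
  obj <- unclass(x)
  asm <- attr(x, "assumptions")
  if (!is.null(asm)) obj$assumptions <- asm
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                          dataframe = "columns", pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
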