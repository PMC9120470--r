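# Independent closed-form oracles used across the suite. These are derived by
# hand, not by calling the solver under test.

# Two-layer planar Couette-Poiseuille profile: viscosity mu1 on [0, a], mu2 on
# (a, d], no-slip walls, constant pressure gradient G. Integrating
# d/dx(mu du/dx) = G once gives mu du/dx = G x + C1; integrating per layer and
# enforcing continuity at a and u(d) = 0 fixes C1 and the profile.
two_layer_profile <- function(x, a, d, mu1, mu2, G) {
  C1 <- -(G * a^2 / (2 * mu1) + G * (d^2 - a^2) / (2 * mu2)) /
    (a / mu1 + (d - a) / mu2)
  u1 <- function(x) (G * x^2 / 2 + C1 * x) / mu1
  ua <- u1(a)
  u2 <- function(x) ua + (G * (x^2 - a^2) / 2 + C1 * (x - a)) / mu2
  ifelse(x <= a, u1(x), u2(x))
}

# Constant-temperature Arrhenius damage accumulated over time t.
arrhenius_closed_form <- function(T_C, t, A = 7.6e66, Ea = 4.48e5,
                                  R_gas = 8.314) {
  A * t * exp(-Ea / (R_gas * (T_C + 273.15)))
}

# Spatial variance (about the centroid) of a non-negative field along grid
# coordinates; for a diffusing point release it grows as 2 * alpha * t per
# axis.
field_variance <- function(theta, coord, axis = c("x", "z")) {
  axis <- match.arg(axis)
  w <- if (axis == "x") rowSums(theta) else colSums(theta)
  m <- sum(w * coord) / sum(w)
  sum(w * (coord - m)^2) / sum(w)
}

# Small scene used widely in the unit tests: modest vessel, coarse-but-valid
# grid, cheap to simulate.
quick_scene <- function(D = 0.2, ...) vessel_scene(D, ...)

quick_grid <- function(scene, nx_lumen = 10, dz = 0.4, spot = 3)
  sim_grid(scene, spot_diameter = spot, nx_lumen = nx_lumen, dz = dz)
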