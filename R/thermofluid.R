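# Coupled quasi-steady laminar flow + transient advection-diffusion heat
# transfer on the planar 2D longitudinal section. Depth (x) resolves the beam
# path and the lumen band; the axial coordinate (z) carries the flow. Time
# integration is operator-split: explicit upwind advection with CFL-limited
# sub-steps, then backward-Euler diffusion + source with a pre-factorized
# sparse operator (unconditionally stable for the stiff conduction part).

#' Calibrate the axial pressure gradient from the baseline flow
#'
#' Fixes the pressure gradient G (Pa/mm) from the uniform-viscosity parabolic
#' profile at baseline temperature: for a planar gap of width D,
#' u_peak = |G| D^2 / (8 mu0), so G = -8 mu0 u_peak / D^2 (negative: the
#' pressure falls toward +z, driving flow in +z).
#'
#' @param scene a `vessel_scene`.
#' @return Pressure gradient G (Pa/mm).
#' @export
calibrate_pressure_gradient <- function(scene) {
  u_pk <- if (scene$velocity_is == "peak") scene$u_peak else 1.5 * scene$u_peak
  mu0 <- viscosity_at(scene$viscosity, scene$T0)
  -8 * mu0 * u_pk / scene$diameter^2
}

#' Quasi-steady laminar velocity profile across the lumen gap
#'
#' Solves the unidirectional momentum balance d/dx(mu du/dx) = G across the
#' planar lumen gap with no-slip walls, for a viscosity profile sampled at
#' uniformly spaced faces spanning wall to wall. Integrating once gives
#' mu du/dx = G x + C1; the constant follows from u(D) = 0, and u(x) is
#' recovered by trapezoidal quadrature of (G x + C1) / mu (exact for uniform
#' viscosity, where the integrand is linear and the profile an exact
#' parabola at the faces).
#'
#' @param mu_profile dynamic viscosity (Pa s) at the `n + 1` faces of the
#'   lumen gap, wall to wall; all positive.
#' @param D lumen gap width (mm).
#' @param G axial pressure gradient (Pa/mm); negative drives flow toward +z.
#' @param target_flow optional volumetric flow per unit section thickness
#'   (mm^2/s); if given, G (and the whole linear-in-G solution) is rescaled so
#'   the profile carries exactly this flow (fixed-flow-rate drive).
#' @return List with `x` (face positions, mm), `u` (face velocities, mm/s),
#'   `G`, `C1` (wall shear integration constant, Pa), `flow_rate` (mm^2/s),
#'   `tau_prox`, `tau_dist` (wall shear magnitudes, Pa).
#' @export
solve_velocity_profile <- function(mu_profile, D, G, target_flow = NULL) {
  mu <- as.numeric(mu_profile)
  n <- length(mu) - 1L
  if (n < 2) stop("need at least 3 viscosity faces across the lumen")
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("viscosity profile must be finite and positive across the lumen")
  dx <- D / n
  s <- seq(0, D, length.out = n + 1L)
  w <- dx * c(0.5, rep(1, n - 1L), 0.5)
  f1 <- 1 / mu
  I1 <- sum(w * f1)
  Is <- sum(w * s * f1)
  C1 <- -G * Is / I1
  g <- (G * s + C1) * f1
  u <- c(0, cumsum((g[-1L] + g[-(n + 1L)]) / 2 * dx))
  u[n + 1L] <- 0
  if (!is.null(target_flow)) {
    Q <- sum(w * u)
    if (Q == 0) stop("cannot rescale a zero-flow profile to a target flow")
    fac <- target_flow / Q
    u <- u * fac; G <- G * fac; C1 <- C1 * fac
  }
  tau_prox <- abs(C1)            # mu du/dx at x = 0 is exactly C1
  tau_dist <- abs(G * D + C1)
  list(x = s, u = u, G = G, C1 = C1, flow_rate = sum(w * u),
       tau_prox = tau_prox, tau_dist = tau_dist)
}

# viscosity at the lumen faces from the cell-centered temperature field:
# interior faces average the two adjacent lumen cells, wall faces average the
# lumen cell with its tissue neighbor. Returns (nx_lumen + 1) x nz matrix.
.face_viscosity <- function(scene, grid, Tmat) {
  rows <- (grid$i_prox - 1L):(grid$i_dist + 1L)   # tissue, lumen band, tissue
  Tb <- Tmat[rows, , drop = FALSE]
  Tf <- (Tb[-1L, , drop = FALSE] + Tb[-nrow(Tb), , drop = FALSE]) / 2
  viscosity_at(scene$viscosity, Tf)
}

# velocity + shear fields across all axial stations, vectorized over z.
# Returns u at lumen faces and cell centers, wall shear per station.
.velocity_field <- function(scene, grid, Tmat, G0, Q0 = NULL) {
  n <- grid$nx_lumen
  nz <- grid$nz
  D <- scene$diameter
  dxl <- D / n
  muf <- .face_viscosity(scene, grid, Tmat)      # (n+1) x nz
  s <- seq(0, D, length.out = n + 1L)
  w <- dxl * c(0.5, rep(1, n - 1L), 0.5)
  f1 <- 1 / muf
  I1 <- colSums(w * f1)
  Is <- colSums((w * s) * f1)
  C1 <- -G0 * Is / I1
  g <- f1 * (G0 * s) + sweep(f1, 2L, C1, `*`)
  incr <- (g[-1L, , drop = FALSE] + g[-(n + 1L), , drop = FALSE]) / 2 * dxl
  uf <- rbind(0, apply(incr, 2L, cumsum))
  uf[n + 1L, ] <- 0
  Gz <- rep(G0, nz)
  if (!is.null(Q0)) {                            # fixed-flow-rate drive
    Q <- colSums(w * uf)
    fac <- ifelse(Q == 0, 1, Q0 / Q)
    uf <- sweep(uf, 2L, fac, `*`)
    Gz <- Gz * fac
    C1 <- C1 * fac
  }
  uc <- (uf[-1L, , drop = FALSE] + uf[-(n + 1L), , drop = FALSE]) / 2
  u_centers <- matrix(0, grid$nx, nz)
  u_centers[grid$i_prox:grid$i_dist, ] <- uc
  tau_prox <- abs(C1)
  tau_dist <- abs(Gz * D + C1)
  list(u_faces = uf, u_centers = u_centers, mu_faces = muf,
       tau_prox = tau_prox, tau_dist = tau_dist, G = Gz, C1 = C1)
}

#' Wall shear stress from a field state
#'
#' Evaluates tau = mu_wall |du/dx| one-sided at each lumen wall, per axial
#' station, using a second-order one-sided difference on the face velocities
#' (exact for the parabolic profile). Reports per-wall maxima over the spot
#' window.
#'
#' @param state a `field_state` (see [field_state()]).
#' @param grid the `sim_grid` the state lives on.
#' @return List with per-station vectors `tau_prox`, `tau_dist` (Pa) and
#'   scalars `tau_prox_max`, `tau_dist_max`, `tau_max` (maxima over the spot
#'   window).
#' @export
wall_shear <- function(state, grid) {
  uf <- state$flow$u_faces
  muf <- state$flow$mu_faces
  n <- nrow(uf) - 1L
  dxl <- grid$dx
  tau_p <- muf[1L, ] * abs((-3 * uf[1L, ] + 4 * uf[2L, ] - uf[3L, ]) / (2 * dxl))
  tau_d <- muf[n + 1L, ] *
    abs((3 * uf[n + 1L, ] - 4 * uf[n, ] + uf[n - 1L, ]) / (2 * dxl))
  sw <- grid$spot_z
  list(tau_prox = tau_p, tau_dist = tau_d,
       tau_prox_max = max(tau_p[sw]), tau_dist_max = max(tau_d[sw]),
       tau_max = max(tau_p[sw], tau_d[sw]))
}

# Backward-Euler diffusion operator, flux form on the uniform grid.
# Solves (rhoC/dt I - L) theta_new = rhoC/dt theta + S, with theta = T - T0.
# bc = "farfield": Dirichlet theta = 0 on the depth (x) boundaries, zero-flux
# on the axial ends (advection owns the inflow/outflow).
# bc = "insulated": zero-flux everywhere (for conservation tests).
.diffusion_system <- function(scene, grid, dt, bc = c("farfield", "insulated")) {
  bc <- match.arg(bc)
  nx <- grid$nx; nz <- grid$nz
  N <- nx * nz
  kx <- ifelse(grid$lumen_x, scene$alpha_blood * scene$rhoC_blood,
               scene$alpha_tissue * scene$rhoC_tissue)
  rhoC_x <- ifelse(grid$lumen_x, scene$rhoC_blood, scene$rhoC_tissue)
  rhoC_vec <- rep(rhoC_x, nz)

  # x-face conductances (harmonic mean across region boundaries)
  cW <- 2 * kx[-nx] * kx[-1L] / (kx[-nx] + kx[-1L]) / grid$dx^2
  ixf <- rep(seq_len(nx - 1L), nz)
  jxf <- rep(seq_len(nz), each = nx - 1L)
  p1 <- ixf + (jxf - 1L) * nx
  q1 <- p1 + 1L
  v1 <- cW[ixf]
  # z-face conductances (uniform region along z)
  izf <- rep(seq_len(nx), nz - 1L)
  jzf <- rep(seq_len(nz - 1L), each = nx)
  p2 <- izf + (jzf - 1L) * nx
  q2 <- p2 + nx
  v2 <- kx[izf] / grid$dz^2

  dvec <- rhoC_vec / dt
  acc <- function(idx, val) {
    a <- numeric(N); t <- tapply(val, idx, sum)
    a[as.integer(names(t))] <- t; a
  }
  dvec <- dvec + acc(p1, v1) + acc(q1, v1) + acc(p2, v2) + acc(q2, v2)
  if (bc == "farfield") {
    b1 <- 1L + (seq_len(nz) - 1L) * nx
    bn <- nx + (seq_len(nz) - 1L) * nx
    dvec[b1] <- dvec[b1] + 2 * kx[1L] / grid$dx^2
    dvec[bn] <- dvec[bn] + 2 * kx[nx] / grid$dx^2
  }
  A <- Matrix::sparseMatrix(
    i = c(seq_len(N), p1, q1, p2, q2),
    j = c(seq_len(N), q1, p1, q2, p2),
    x = c(dvec, -v1, -v1, -v2, -v2),
    dims = c(N, N))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE)
  list(chol = ch, rhoC_vec = rhoC_vec, dt = dt, bc = bc, kx = kx)
}

# one or more explicit upwind advection sub-steps along +z.
# theta is the temperature excess over baseline, so the inflow carries 0.
.advect_upwind <- function(theta, u, dz, dt, cfl = 0.5) {
  umax <- max(u)
  if (umax <= 0) return(theta)
  n_sub <- max(1L, as.integer(ceiling(umax * dt / (cfl * dz))))
  dts <- dt / n_sub
  nz <- ncol(theta)
  for (s in seq_len(n_sub)) {
    upwind <- cbind(0, theta[, -nz, drop = FALSE])
    theta <- theta - (dts / dz) * u * (theta - upwind)
  }
  theta
}

#' Initial field state for a scene on a grid
#'
#' Temperature at baseline everywhere, viscosity from the curve at baseline,
#' and the baseline parabolic velocity profile under the calibrated pressure
#' gradient.
#'
#' @param scene a `vessel_scene`.
#' @param grid a `sim_grid`.
#' @return An object of class `field_state`: temperature matrix `T_C`
#'   (nx x nz), time `t`, the flow sub-state (face/center velocities, face
#'   viscosities, per-station wall shear) and drive constants.
#' @export
field_state <- function(scene, grid) {
  Tmat <- matrix(scene$T0, grid$nx, grid$nz)
  G0 <- calibrate_pressure_gradient(scene)
  flow0 <- .velocity_field(scene, grid, Tmat, G0)
  Q0 <- if (scene$drive_mode == "flow") {
    n <- grid$nx_lumen
    w <- (scene$diameter / n) * c(0.5, rep(1, n - 1L), 0.5)
    sum(w * flow0$u_faces[, 1L])
  } else NULL
  structure(list(T_C = Tmat, t = 0, flow = flow0, G0 = G0, Q0 = Q0),
            class = "field_state")
}

#' Advance the temperature field by one time step
#'
#' Operator-split step of
#' rhoC dT/dt + rhoC u dT/dz = div(k grad T) + S:
#' explicit upwind advection (CFL-limited sub-steps, inflow at baseline),
#' then backward-Euler diffusion with the step-averaged source, then refresh
#' of the viscosity and quasi-steady velocity fields from the new
#' temperatures.
#'
#' @param state a `field_state`.
#' @param scene,grid the scene and grid the state lives on.
#' @param sys diffusion system built by the internal constructor (pass the
#'   `sys` element of a running simulation, or leave `NULL` to build one for
#'   a single step).
#' @param S source matrix (W/mm^3), e.g. from [deposit()]; may be 0.
#' @param dt time step (s).
#' @return The advanced `field_state`.
#' @export
step_heat <- function(state, scene, grid, S, dt, sys = NULL) {
  stopifnot(inherits(state, "field_state"))
  if (is.null(sys)) sys <- .diffusion_system(scene, grid, dt)
  if (!isTRUE(all.equal(sys$dt, dt)))
    stop("dt must match the dt the diffusion system was factorized for")
  theta <- state$T_C - scene$T0
  theta <- .advect_upwind(theta, state$flow$u_centers, grid$dz, dt)
  rhs <- sys$rhoC_vec * as.numeric(theta) / dt + as.numeric(S)
  theta_new <- matrix(as.numeric(Matrix::solve(sys$chol, rhs)),
                      grid$nx, grid$nz)
  if (any(!is.finite(theta_new)))
    stop(sprintf("temperature field diverged at t = %.6g s", state$t + dt))
  state$T_C <- theta_new + scene$T0
  state$t <- state$t + dt
  state$flow <- .velocity_field(scene, grid, state$T_C, state$G0,
                                Q0 = state$Q0)
  state
}
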