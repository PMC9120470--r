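---
title: "Modeling laser coagulation of large blood vessels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling laser coagulation of large blood vessels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photocoag)
```

## The problem

Near-infrared (1.07 um) laser light is strongly absorbed by hemoglobin, so a
pulsed beam can heat blood selectively, denature its proteins, and occlude a
vessel — hemostasis without contact. This works reliably for microvasculature
but fails, often dramatically, for lumen diameters of 0.5–1 mm. Two effects
conspire against large vessels: blood flows through them fast enough to carry
heat out of the irradiation spot during the pulse, and the shear stress at
the vessel wall — where a forming coagulum must anchor — rises with diameter
and with the heating-induced viscosity changes, tearing partial coagula free.
`photocoag` packages the quantitative side of this picture: the closed-form
dosimetry arithmetic, a deterministic 2D thermofluid simulator with
temperature-dependent blood rheology and Arrhenius damage kinetics, and a
stacked-pulse protocol generator for the large-vessel regime.

## Dosimetry arithmetic

Selective photothermolysis rests on two closed forms. The thermal relaxation
time of a cylindrical lumen of diameter $D$,

$$\tau_r = \frac{D^2}{16\,\alpha},$$

with thermal diffusivity $\alpha = 0.15\ \mathrm{mm^2/s}$, is the conductive
cooling time of the target: pulses no longer than $\tau_r$ confine heat to
the vessel. The adiabatic temperature rise of blood receiving a fluence
$\Phi$ is

$$\Delta T = \frac{\mu_a\,\Phi}{\rho C},$$

with absorption coefficient $\mu_a = 0.3\ \mathrm{mm^{-1}}$ at 1.07 um and
volumetric heat capacity $\rho C = 0.004\ \mathrm{J\,mm^{-3}\,K^{-1}}$.
`dosimetry_report()` combines these with the beam spot area, the blood
transit time through the spot, and two flags: predicted temperatures above
100 °C (vapor-bubble rupture risk) and relaxation-time pulses that outlast
the spot transit time (heat advected away before it can coagulate). The
pulse-train arithmetic is bookkeeping: 50 us micro-pulses at a 10% duty
cycle imply a 2000 Hz repetition rate and an average power of 10% of peak
(300 W at the 3000 W limit).

For a 1 mm lumen at the measured-flow velocity the report makes the failure
mode of the classical prescription explicit: $\tau_r = 0.42$ s, but blood
crosses the 3 mm spot in 45 ms.

## The coupled thermofluid model

`run_simulation()` advances temperature $T(x, z, t)$ on a planar longitudinal
section: $x$ is depth along the beam axis, $z$ the vessel axis. The lumen is
a band of width $D$ between two perivascular tissue margins; blood flows
toward $+z$. The planar (rather than axisymmetric) section was chosen because
it can represent one-sided illumination: with blood-only absorption the
proximal (beam-side) wall receives more power than the distal wall, an
asymmetry that matters for rupture and that an axisymmetric model cannot
express.

The governing balance is

$$\rho C\,\partial_t T + \rho C\,u(x,z)\,\partial_z T =
  \nabla\!\cdot\!(k\nabla T) + S(x,z,t),
  \qquad k = \alpha\,\rho C\ \text{per region},$$

with inflow at baseline (37 °C), advective outflow, and far-field tissue
held at baseline on the depth boundaries. The source $S$ is the flat-top
beam attenuated by Beer–Lambert decay through the absorbing lumen,
discretized cell-averaged so the depth integral of deposited power
telescopes exactly to the delivered irradiance times
$1 - e^{-\tau_{\rm total}}$ — deposited power can never exceed delivered
power, and energy bookkeeping in the solver is exact per step. Scattering is
folded into a single effective attenuation coefficient (default equal to
$\mu_a$); there is no photon-transport simulation. The 50 us micro-pulse
structure is averaged into the macro-pulse envelope for the thermal solve:
at 0.5 ms period it is two orders of magnitude below the fastest thermal
time scale in play, so resolving it would change nothing but the step count.

### Flow with temperature-dependent viscosity

Blood viscosity $\mu(T)$ enters through a piecewise-linear lookup curve.
Measured whole-blood rheology thins with warming down to a minimum at 55 °C
and stiffens steeply above it as coagulation begins; the default curve in
`default_viscosity_curve()` is a synthetic realization of exactly that
shape (baseline 3.5 mPa s at 37 °C, minimum 2.6 mPa s at 55 °C, two orders
of magnitude stiffening by 100 °C, clamped beyond the end knots). It is
deliberately documented as synthetic — no tabulated measurements ship with
the package — and is replaceable by a two-column CSV of measured values.

The momentum balance is treated quasi-steadily, one axial station at a time:
$\partial_x(\mu\,\partial_x u) = G$ across the lumen gap with no-slip walls.
Integrating once gives $\mu\,\partial_x u = Gx + C_1$, and the profile
follows by quadrature of $(Gx + C_1)/\mu$ — exact at the grid faces for
uniform viscosity, where it reproduces the planar Poiseuille parabola. This
lubrication-style treatment neglects axial momentum coupling between
stations (volumetric flow may vary along $z$ under the fixed-gradient
drive); it is the price of a model that runs in seconds, and it is the flow
physics the shear diagnostics need: wall shear stress is
$\tau = \mu_{\rm wall}\,|\partial_x u|$ one-sided at each wall.

Two drive modes are available. The default, fixed pressure gradient,
calibrates $G = -8\mu_0 u_{\rm peak}/D^2$ once from the baseline parabola
and holds it, so heating-induced viscosity changes feed back on the velocity
field — the "pinching" effect by which a long conditioning pulse collapses
flow in a large vessel. Fixed flow rate, which rescales $G$ each step to
conserve the baseline volumetric flow, is available for comparison.

Reported flow measurements for these vessels are quoted inconsistently as
peak or average velocities; rather than silently resolving that, the scene
carries an explicit `velocity_is` field (default `"peak"`, matching the
parabolic-profile phrasing of the measurements), and the sweep's velocity
rule interpolates linearly between the two measured anchors, 20 mm/s at
200 um and 40 mm/s at 400 um, clamped below 0.05 mm.

### Numerics

Time integration is operator-split. Diffusion plus source is backward Euler:
the flux-form operator is assembled sparse once per run, Cholesky-factorized
(via the Matrix package), and reused every step — unconditionally stable, so
the stiff conduction across a 2.5 um cell never constrains the step.
Advection is explicit first-order upwind along $z$, sub-stepped to keep the
CFL number at or below 0.5; at unit CFL the scheme is an exact translation
operator, which the tests exploit as an oracle. The outer step (default
1 ms) therefore controls accuracy, not stability. Degenerate inputs are
handled explicitly: zero power leaves the field at exact equilibrium, zero
velocity zeroes the shear and the measured convective ratio, and a
non-finite field aborts with the divergence time rather than propagating
NaN.

The default grid puts 20 cells across the lumen (the resolution floor for
the wall shear gradient), a tissue margin of $2D$ on each side of the lumen
with the far-field condition at its edge, and an axial extent of the spot
plus 2 mm of run-in and run-out at 0.2 mm spacing. Halving both spacings
moves the peak wall temperature by under 5% (tested), and verdicts are
stable under refinement at the study scenarios.

### Damage kinetics and diagnostics

Thermal damage accumulates as the Arrhenius integral
$\Omega = \int A\,e^{-E_a/RT}\,dt$ with $T$ in kelvin, evaluated separately
for blood (lumen) and perivascular tissue with their respective parameter
sets. The shipped kinetics ($A = 7.6\times10^{66}\ \mathrm{s^{-1}}$,
$E_a = 4.48\times10^5\ \mathrm{J/mol}$) are standard
protein-coagulation literature values, not measurements made here; every
conclusion the package draws from $\Omega$ is a threshold crossing
($\Omega \ge 1$), which is robust to parameter choices within the standard
range. At baseline 37 °C the shipped kinetics accrue $\Omega < 10^{-9}$
over a run — no spurious damage.

The coagulation verdict is deliberately stricter than "$\Omega$ reached 1
somewhere": it requires the threshold across a full lumen cross-section at
some axial station inside the spot (a flow-blocking band). The observed
failure mode of large-vessel coagulation is precisely a hot wall with a
patent channel — a partial coagulum that shears off — so a pointwise
criterion would overcall success.

Because the published convective/conductive (Nusselt-style) numbers for
these vessels come from external correlations that are not reproduced here,
the diagnostics report two quantities the simulator can actually measure:
the Péclet number $u_{\rm mean} D/\alpha$ and the time-averaged ratio of
heat advected out of the downstream spot edge to heat conducted across the
lumen walls. The package does not claim to reproduce any particular Nusselt
range.

## The diameter sweep and what it shows

`run_sweep()` runs the five-diameter comparison {0.05, 0.1, 0.2, 0.5, 1} mm
under the shared reference schedule — one 80 ms flat-top burst at 300 W
average starting at 0.05 s, 3 mm spot — and tabulates peak wall shear, peak
wall temperature, maximum lumen $\Omega$, the band verdict, and the
post-pulse wall-temperature decay time. Under these conditions every
diameter reaches $\Omega \ge 1$ somewhere in the lumen, peak wall shear is
monotone nondecreasing in diameter, and the post-pulse decay time increases
with diameter, the $D^2$ ordering of the relaxation-time formula.

The decay time is measured as the exponential-equivalent constant
$(t_{\rm end} - t_{\rm off})/\log(E_{\rm off}/E_{\rm end})$ of the
proximal-wall temperature excess. One subtlety is worth recording: right
after pulse-off the wall sits on a thin near-wall thermal boundary layer
(width $\sqrt{4\alpha t_{\rm pulse}} \approx 0.22$ mm regardless of $D$)
whose local smoothing dominates the first tens of milliseconds. A record
much shorter than the bulk relaxation time of the largest vessel measures
that transient, not the $D^2$ relaxation, so the decay-ordering check runs
with a 0.5 s record — commensurate with the 0.42 s relaxation time of the
1 mm lumen — while the damage and shear checks, whose quantities peak during
or just after the pulse, use a 0.2 s record. Problem sizes throughout are
the default grid (20 cells across the lumen, 0.2 mm axial spacing, 1 ms
steps); a full five-diameter sweep takes seconds to a few tens of seconds.

## Stacked-pulse protocol generation

`stacked_protocol()` encodes the large-vessel irradiation strategy: an
initial conditioning macro-pulse of five relaxation times (clamped to the
empirically workable 100–200 ms window for $D \ge 0.5$ mm) collapses flow by
driving wall viscosity up, then shorter macro-pulses of one relaxation time
each at reduced power complete hemostasis in the now quasi-stagnant lumen.
The factor five, the default of three follow-up pulses at half power, and
the 50 ms gap are implementation choices — the experimental reports
constrain only "approximately five times longer" and the 100–200 ms window —
and every generated schedule carries them in an `assumptions` attribute. For
venules, which rupture more readily under one-sided heating, the generator
halves the peak-power scale and doubles every duration and gap, an
energy-preserving transformation (asserted exactly in the tests).

## Known limitations

The model stops where the mechanics of an actual coagulum begin: there is no
interface tracking of the growing coagulum, no density change or detachment
event, no vessel-wall elasticity, and no vapor-bubble dynamics — temperatures
above 100 °C are flagged, not capped, so super-boiling values should be read
as "rupture regime", not predictions. Tissue perfusion other than the vessel
itself is absent. The quasi-1D flow treatment cannot represent recirculation
or axial pressure redistribution. The synthetic viscosity curve and
literature Arrhenius constants mean absolute $\Omega$ magnitudes and shear
values are indicative; orderings, thresholds and the closed-form dosimetry
are the quantities the test suite pins down. Simulated irradiation is a
flat-top beam; real beams are closer to Gaussian.
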