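---
title: "Hyperbolic bioheat and thermoelastic vibration of laser-heated skin: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{thermoskin methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoskin)
```

## The model

`thermoskin` simulates the transient thermomechanical response of skin tissue
to a laser heating source.  The tissue is treated as a single homogeneous,
isotropic, linear thermoelastic layer occupying the half-space $z \ge 0$ in
cylindrical coordinates, with an axisymmetric temperature and displacement
field (radial displacement $u$, depth displacement $v$).

Heat conduction follows the Cattaneo–Vernotte (C–V) law
$q_i + \tau \dot q_i = -k T_{,i}$, which replaces Fourier's law with a
finite-speed (hyperbolic) model; $\tau$ is the thermal relaxation time.
Combined with the energy balance, blood perfusion and the thermoelastic
coupling term, the temperature equation is

$$ \rho c\,(\dot T + \tau \ddot T)
   = k \nabla^2 T + \rho_b c_b G_b (T_b - T) - \tau \rho_b c_b G_b \dot T
   + Q_L + \tau \dot Q_L
   - \mathfrak{B} T_0 (\dot \varepsilon_{kk} + \tau \ddot\varepsilon_{kk}), $$

where $\mathfrak{B} = E\alpha_T/(1-2\nu)$ is the thermal-stress modulus and
$\varepsilon_{kk}$ the volumetric strain.  The displacement components obey
the Navier equations with a thermal-stress body force
$-\mathfrak{B}\,\partial T/\partial r$ (and $\partial/\partial z$), plus an
optional structural damping term whose coefficient has no established value
and defaults to zero.  Metabolic heat is neglected.  The $\tau \to 0$ limit of
the temperature equation is the classical (parabolic) Pennes bioheat model;
the package's finite-difference solver exposes that limit directly
(`fd_solve(..., mode = "parabolic")`).

The laser source is separable, $Q_L(z, t) = f_1(z) f_2(t)$: a
double-exponential axial deposition profile
$f_1(z) = I_0 \mu_a (O_1 e^{-e_1 \hat z} - O_2 e^{-e_2 \hat z})$
whose constants are diffuse-reflectance fit functions (`gardner_fit()`),
and a normalized time profile $0 \le f_2 \le 1$ from one of six families:
single pulse, repetitive pulse, repeating-sequence stairs (applied in the
cooling stage, the heating stage, or symmetrically, at equal delivered
energy), step, repetitive ramp, and raised-cosine harmonic.

All quantities are nondimensionalized with the optical penetration depth
$\delta = 1/\sqrt{3\mu_a(\mu_a + \mu_s(1-g))}$ as the length scale, the
diffusion time $t^* = \delta^2/\alpha$ (with $\alpha = k/\rho c$) as the time
scale, and $\theta = (T - T_0)/T_0$ as the temperature variable
(`nondim_groups()` collects the resulting fourteen coefficient groups).

## Galerkin reduction

The three coupled PDEs are reduced to a three degree-of-freedom system by a
one-term Galerkin projection:

$$ \hat u = J_1(\hat r)\,[e^{-\hat z^2} q + \mathcal{A}\, \hat z e^{-\hat z} q], \quad
   \hat v = \cos(\pi \hat r) e^{-\hat r^2} [e^{-\hat z^2} p + \mathcal{B}\, \hat z e^{-\hat z} p], \quad
   \theta = e^{-\hat r^2} e^{-\hat z^2} s. $$

These shapes satisfy the essential conditions by construction: $J_1(0) = 0$
(no radial displacement on the axis), all radial derivatives of $\hat v$ and
$\theta$ vanish at $\hat r = 0$ (axisymmetry), and every factor decays at
infinity.  The free surface carries mixed traction conditions (zero shear and
normal stress at $\hat z = 0$) which the basis cannot satisfy pointwise; they
are imposed heuristically by projecting the two surface-stress residuals onto
the radial weights and solving for the time-dependent ratios
$\mathcal{A} q = d_1 p$ and $\mathcal{B} p = d_2 q + d_3 s$
(`bc_parameters()`).  The products are substituted algebraically *before*
time differentiation, which keeps the reduced system linear with constant
coefficients; with this substitution the projected traction residuals vanish
identically (tested).

Every reduced coefficient is defined operationally as the Galerkin quadrature
of the corresponding residual term.  Separability makes each coefficient a
product of a radial and an axial one-dimensional integral, evaluated by
adaptive quadrature (`stats::integrate`, tolerance $10^{-9}$) with analytic
shape-function derivatives.  Terms with $1/\hat r$ factors use Bessel
identities ($J_1'' + J_1'/r - J_1/r^2 = -J_1$, $J_1' + J_1/r = J_0$) so no
numerical singularity arises.

**Radial truncation.** The weighted-residual integrals are taken with weight
$d\hat r\, d\hat z$ as stated.  Radial integrands built purely from Bessel
products (for example $\int J_1^2\, d\hat r$) have no decaying factor and
grow logarithmically with the truncation radius, so the radial domain is
truncated at the $J_1$ zero nearest $\hat r = 12$ (13.3237; ending at a zero
minimizes the bias from the oscillatory tail).  This truncation is part of
the model definition: the heuristic traction elimination uses the same
integrals, so boundary-condition satisfaction is exact for any truncation.
Coefficients with Gaussian decay are insensitive to the truncation radius at
$10^{-8}$ relative (tested); the Bessel-product coefficients are not, which
is inherent to the basis choice.

## Source mollification and the source-rate term

The C–V law requires the source *rate* $\tau \dot Q_L$ in the temperature
equation.  For idealized switching profiles (pulses, steps, stairs) that term
is distributional.  The package mollifies every discontinuity with a linear
ramp of half-width $\varepsilon$ (default $10^{-3}$ of the shortest protocol
feature, centered on the nominal switch time), so $\dot f_2$ exists
everywhere and equals the ramp slope.  Delivered energy is preserved exactly
by the centered ramps (up to the clipped ramp at $t = 0$).

This choice has a physical consequence worth stating plainly.  The pair of
C–V terms acts in opposite directions: the thermal inertia
$\rho c \tau \ddot T$ delays the response, while the mollified
$\tau \dot Q_L$ term injects an impulse at each switching edge that is the
first-order Taylor advance of the source by $\tau$.  For pulse heating the
two nearly cancel, so the maximum temperature is almost independent of the
relaxation time (it rises by about a percent over $\tau = 1\ldots5$ s in the
bundled configuration).  If the source-rate term is dropped — which is what
happens silently when an ideal, non-mollified switching profile is
differentiated classically — the inertia acts alone and the maximum
temperature *decreases* with $\tau$.  Reports of the latter behaviour for
this model are therefore consistent with numerics that never evaluated the
switching deltas.  The package keeps the term, as the governing equations
require; the acceptance suite records the resulting relaxation-time trend as
a known deviation.

## Parameters

| Parameter | Default | Units | Note |
|---|---|---|---|
| $\rho$, $c$, $k$ | 1000, 4187, 0.628 | kg/m³, J/(kg·K), W/(m·K) | bundled skin values |
| $E$, $\nu$, $\alpha_T$ | 100 MPa, 0.4, $10^{-4}$ | Pa, –, 1/K | linear single-layer skin |
| $\tau$ | 3 | s | C–V relaxation time |
| damping | 0 | kg/(m³·s) | no established value; config-overridable |
| $\rho_b$, $c_b$, $G_b$ | 1060, 3860, $1.87\times10^{-3}$ | kg/m³, J/(kg·K), 1/s | blood |
| $T_b$ | $T_0$ | K | arterial temperature; offset $\theta_b = 0$ by default |
| $I_0$, $R_d$ | $3\times10^5$, 0.05 | W/m², – | laser intensity, diffuse reflectance |
| $\mu_a$, $\mu_s$, $g$ | 18, 8000, 0.9 | 1/m, 1/m, – | see below |
| $O_1, O_2, e_1, e_2$ | fit at $R_d$ | – | `gardner_fit()`; overridable |

Temperatures are stored in kelvin ($T_0 = 310.15$ K for 37 °C) and reported
in °C.  The absorption and scattering coefficients are not independently
tabulated for the validation data this package reproduces; they were fixed
*once* by matching the four single-pulse validation temperatures (43.8, 45.6,
49.4, 53.1 °C for 5, 8, 10, 15 s exposures of a 122 kW/m² pulse, coupling
off) over a two-parameter scan, giving $\mu_a = 18$ m⁻¹ and
$\mu_s = 8000$ m⁻¹ at $g = 0.9$ ($\delta \approx 4.8$ mm,
$t^* \approx 151$ s).  With that preset all four computed maxima fall within
1.1 °C of the reference values (the acceptance suite recomputes them).  The
reference increments between successive exposures are *not* reproducible by
this model: they imply an accelerating temperature rise mid-exposure, while
the reduced model's response is monotone-concave there for every physical
optical setting we scanned; the acceptance test records this as a deviation.

## Time integration

The reduced system $M\ddot x + C\dot x + Kx = P(t)$, $x = (q, p, s)$, is
converted to first order by mass-matrix inversion and integrated with
`deSolve` from homogeneous initial conditions.  The elastic wave frequencies
exceed the thermal rates by roughly seven orders of magnitude and are
practically undamped, so the default integrator is `radau` (L-stable) when
the thermoelastic coupling is on, and `lsoda` otherwise; a constant analytic
Jacobian is supplied.  Integration restarts at every profile corner, so steps
never straddle a mollification ramp regardless of the step-size cap; within a
segment the forcing is linear (or harmonic) and smooth.  Default tolerances
are `rtol = 1e-6`, `atol = 1e-9`; halving them changes the probe temperature
by less than $10^{-5}$ relative (tested).  The fast elastic modes are excited
only adiabatically (ramp times vastly exceed the elastic period), so the
reduced dynamics are quasi-static in the mechanical coordinates with a
superposed negligible ripple; implicit methods damp that ripple numerically
without affecting the thermal solution.

## Field reconstruction and metrics

`reconstruct_fields()` evaluates the one-mode expansions at arbitrary grids
and times (cubic-spline interpolation of the dense trajectory) and converts
to dimensional units: $T = T_0(1+\theta)$ in °C, displacements scaled by
$\delta$.  `summarize_run()` reports the maximum probe temperature (probe
default $(\hat r, \hat z) = (0, 0)$, the beam axis on the surface — the
hottest point of the separable mode), its peak time, the first-overshoot
magnitude, and for periodic sources integrated over at least three periods
the steady oscillation amplitude (half the peak-to-trough range over the last
three periods).  Depth-versus-radial displacement comparisons are made on
field maxima over the heated region rather than at a single probe, because
the radial displacement vanishes identically on the axis by symmetry.

## The finite-difference oracle

`fd_solve()` is an intentionally simple, independent solver for the
*uncoupled* hyperbolic bioheat equation: second-order central differences on
a uniform axisymmetric grid (axis limit $(1/\hat r)\partial_{\hat r} \to
\partial^2_{\hat r}$ at $\hat r = 0$, ghost-node Neumann at the surface,
homogeneous Dirichlet at the truncation boundaries $\hat r = \hat z = 12$),
explicit central time stepping with the damping term treated implicitly, and
a CFL-bounded default step.  It never implements the thermoelastic coupling;
its role is bounded verification: the $\tau \to 0$ mode reproduces the Pennes
limit within 1% relative $L_2$ at $\tau/t^* = 10^{-3}$, grid refinement shows
second-order convergence, and a lumped-balance limit is checked in closed
form.

**What the oracle does and does not confirm.**  The reduced model's
temperature *row* is verified exactly (to $10^{-4}$) against an independently
constructed scalar oscillator built from closed-form Gaussian integrals, so
the assembly and integration are sound.  Against the full finite-difference
solution, however, the one-mode reduction carries a genuine model error: the
projected source is radially uniform while the temperature basis fixes a
Gaussian radial profile, so the reduction sees a radial diffusion sink the
effectively one-dimensional true solution does not have, partly compensated
by the $\int I\,d\hat r / \int I^2\,d\hat r$ source amplification.  The
measured peak-temperature gap is tens of percent (either sign depending on
horizon), far from the few-percent level one might hope for; supplying the
basis's own Gaussian radial weight to the oracle
(`fd_solve(radial_weight = ...)`) flips the sign of the gap without closing
it.  Passing temperature validation therefore shows that the calibrated
one-mode model reproduces the validation maxima, not that a one-term Galerkin
basis converges to the PDE solution.

## Scenario runner and reproducibility

`run_scenario()` ties configuration, assembly, integration, reconstruction
and reporting together; presets cover the studied source families and the
validation cases.  All outputs are delimited text plus a YAML echo of the
configuration and a log of every derived constant ($\lambda$, $\mu$,
$\mathfrak{B}$, $\alpha$, $\delta$, $t^*$, all nondimensional groups,
$d_1$–$d_3$), and re-running a preset is byte-identical.  A thin command-line
wrapper is installed at `inst/cli/simulate.R`.  Typical problem sizes: the
reduced system integrates 2000 output points in well under a second
(uncoupled) to a few seconds (coupled); the oracle grid is $121 \times 121$;
the full test suite runs in about half a minute.

## Known limitations

- One-term bases in each coordinate: the API accepts higher mode counts in
  principle, but only the one-mode reduction is assembled and tested; the
  quantitative gap to the PDE solution is documented above.
- Single homogeneous tissue layer, constant properties, no metabolic heat,
  no damage (Arrhenius) integral, no radial beam profile in the source.
- The structural damping coefficient enters with the sign conventions of the
  reduced equations as stated; with a positive coefficient that term is
  destabilizing, so the default (zero) should be changed only knowingly.
- Bessel-product radial integrals are truncation-defined (see above); the
  heuristic traction elimination inherits that definition.
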