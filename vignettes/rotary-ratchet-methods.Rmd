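---
title: "Models and methods for AC-driven rotary Brownian-ratchet motors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for AC-driven rotary Brownian-ratchet motors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotaratchet)
```

## The physical model

`rotaratchet` studies a nanoscale rotor arm attached to a pivot on a fixed
platform, immersed in water and driven by an alternating electric field. At
these scales inertia is negligible, so the rotor angle $\vartheta$ obeys the
overdamped Langevin equation

$$\lambda \frac{d\vartheta}{dt} = -\frac{\partial U(\vartheta, t)}{\partial \vartheta} + \eta(t),
\qquad \langle \eta(t)\eta(t')\rangle = 2 k_B T \lambda\, \delta(t - t'),$$

with damping constant $\lambda$ and thermal white noise obeying the
fluctuation–dissipation relation. The landscape has two parts:

$$U(\vartheta, t) = \frac{4a}{\pi} \cos(\vartheta - \varphi_{\text{axis}})\, E(t)
 \;-\; b \sum_n \exp\!\big(-c\,(\vartheta - \vartheta_0 - n\,\Delta\vartheta)^2\big).$$

The second term is the motor-intrinsic landscape: a ring of $n$ Gaussian
wells of depth $b$ and inverse squared width $c$, spaced by
$\Delta\vartheta = 2\pi/n$ (the spacing must divide a full turn so the
landscape is single-valued on the circle) and offset by $\vartheta_0$, the
motor's orientation relative to the field axis. The first term is the dipole
coupling to the external field: $E(t)$ is a square wave of period $T$
(+1 for the first half period, −1 for the second), and
$\varphi_{\text{axis}}$ orients the field axis in the laboratory frame so
that stepwise axis-rotation experiments can be expressed naturally
($\varphi_{\text{axis}} = 0$ recovers the plain $\cos\vartheta$ coupling).
The square wave averages to zero over every full period: the drive exerts no
net time-averaged torque, and any sustained rotation is a genuine ratchet
effect arising from the interplay of the switching field with the asymmetric
placement of the wells. A motor whose wells sit at 0° or 90° to the field
axis is mirror-symmetric and cannot rectify; intermediate orientations (45°
for a two-well motor) ratchet, with mirror-image orientations ratcheting in
opposite directions.

A Fourier-smoothed drive is available in two dialects for
comparison with other conventions (`smoothed_square_wave`): the standard
partial sum $\tfrac{4}{\pi}\sum_{\text{odd } n \le N} \sin(2\pi n t/T)/n$,
which converges to the square wave, and a raw partial sum
$\sum_{n\le N}\sin(nt/T)/n$, which converges to a sawtooth and is kept only
as a documented legacy variant. The default integrator uses the exact square
wave: the discontinuity is in time, not in angle, so an Euler–Maruyama
scheme needs no smoothing.

## Units, parameters and calibration

Energies are expressed in units of $k_B T$ and angles in radians internally
(degrees at all I/O boundaries). In these units the free diffusion
coefficient is $D = k_B T/\lambda$. The package defaults are

| parameter | default | meaning |
|---|---|---|
| $b$ | 8 $k_BT$ | well depth: deep enough that dwell positions are well defined |
| $c$ | 20 rad$^{-2}$ | well inverse width ($\sigma \approx 9$°) |
| $a$ | 8 $k_BT$ | field coupling; the field term has amplitude $4a/\pi \approx 10\,k_BT$ |
| $\lambda$ | 0.1 $k_BT\,$s/rad$^2$ | damping, giving $D = 10$ rad$^2$/s |
| $T$ | 0.2 s | drive period (5 Hz) |
| $dt$ | $2\times10^{-5}$ s | integration step |

The damping is chosen so that free diffusion ($D = 10$ rad$^2$/s, the
scale obtained from $\zeta_r \approx 4\times10^{-22}$ N m s and
$k_BT \approx 4\times10^{-21}$ J) makes 5 Hz driving commensurate with the
well relaxation time: each half cycle is long enough for the rotor to slide
into the currently favoured well region but short enough that the ratchet
does not fully equilibrate. The field coupling is set so that the field
term is comparable to the maximal well force; at this point a biased
(45°-oriented) two-well motor takes a net ratchet step in roughly every
second to tenth field cycle — hopping is stochastic, observable on a
40–64 s record, and far from deterministic sliding, which is the regime the
irreversibility analysis is meant for. With a substantially weaker coupling
the hop rate collapses (at $a = 4$, barely one hop per 40 s) and
finite-record drift estimates become sign-indefinite. The stability bound
$dt < 0.1\,\lambda/\max|U''|$ is enforced at simulation time against the
supplied landscape.

Voltage sweeps map the applied amplitude linearly onto the field term,
`amplitude_scale = V / V_ref` with $V_{\text{ref}} = 20$ V by default; the
mapping from volts to landscape energy is not otherwise constrained, so
linearity is the minimal assumption.

## Synthetic tracking data

`render_tip_positions` converts a simulated trajectory into the kind of
table that centroid tracking of TIRF videos produces: 250 frames/s, a tip at
fixed radius (275 nm) from the platform centre, and isotropic Gaussian
localization noise (20 nm by default, a typical single-emitter centroid
precision). Within each exposure the *position* of the tip is averaged, not
its angle — that is what the centroid of a moving emitter actually measures —
so fast rotation blurs the tip inward and shortens the apparent radius, as
in real video. The generator does not emulate pixelation, point-spread
functions, bleaching, blinking, or platform drift (a clean stand-in for
tracking output, not for raw video); passing tests on this data therefore
validates the analysis chain downstream of spot tracking, not the tracking
itself. Angles recovered from noise-free renders agree with ground truth to
$10^{-9}$ rad, and localization noise propagates to angular noise as
$\sigma/r$ in the small-angle regime.

## Trajectory statistics

Angles come from `atan2` against the platform centre (counter-clockwise
positive), are unwrapped by the shortest-arc rule (a jump of exactly 180°
resolves toward +180°, a tie that only pathological synthetic inputs hit),
and accumulate across full turns. The angular velocity of a segment is the
endpoint formula $\Omega = (\vartheta_{\text{last}} - \vartheta_{\text{first}})/\Delta t$
— deliberately not a regression slope, matching standard practice in rotary
single-particle assays. Derived summaries: signed speed histograms with
CW/CCW fractions; speed versus field-axis orientation fitted with
$\Omega(\varphi) = A \sin(k(\varphi - \varphi_0)) + m$ where the default
$k = 2$ encodes the 180° periodicity of the response (reversing field
polarity equals rotating the axis by half a turn); turns per field cycle
$\Omega/(360° f)$ as the directional bias efficiency, undefined for DC or
field-off segments; and dwell positions as circularly detected peaks of the
wrapped-angle histogram with a relative prominence threshold (0.2 of the
tallest bin by default).

Per-segment speeds over a 1.6 s dwell are noisy for a stochastic hopper, so
ensemble aggregation (averaging per-axis speeds over replicate motors, after
subtracting each motor's fitted phase) is used before asserting the
sinusoidal shape quantitatively.

## Irreversibility analysis

For a driven motor sampled at multiples of the field period, the package
collects all overlapping jump pairs
$(\vartheta_0 \bmod 360°, \Delta\vartheta)$ at lag $nT$, estimates the
transition density $p(\vartheta_0, \Delta\vartheta)$ with a bivariate
Gaussian-kernel KDE (periodic in $\vartheta_0$ by sample replication at
$\pm360°$; Silverman's rule per dimension unless overridden), and computes
the entropy production per lag

$$\frac{\Delta s}{k_B}(\Delta\theta)
 = \Big\langle \ln \frac{p(\vartheta_0, \Delta\theta)}
                        {p(\vartheta_0 + \Delta\theta \bmod 360°, -\Delta\theta)}
   \Big\rangle_{\vartheta_0},$$

averaged uniformly over a 36-point grid of starting angles (an unweighted
average; occupancy weighting is deliberately not used). For a ratcheting
motor this curve is linear in $\Delta\theta$ with slope
$\omega_{\text{eff}}/D_{\text{eff}}$ and independent of the lag; a
through-origin least-squares slope is fitted per lag and pooled.

Numerical choices that matter:

* **Displacement grid.** The through-origin fit weights large
  $|\Delta\theta|$ most, so the default grid spans ±2.5 standard deviations
  of the *shortest*-lag jump distribution — the region where both the
  forward and the reversed density are supported by samples at every lag.
  On the drift-diffusion oracle (Gaussian propagator, exact slope
  $\omega/D$) a grid pushed into unsampled KDE tails biases the slope
  upward by tens of percent; the default grid recovers $\omega/D$ within a
  few percent at $10^6$ frames.
* **Density floor.** Densities below $10^{-12}$ of the evaluated maximum
  are floored and the affected grid cells dropped from the
  $\vartheta_0$-average; displacements where more than half the cells drop
  are flagged low-confidence.
* **Exclusion of unbiased motors.** Rescaling a curve by its slope is
  ill-defined when the slope is consistent with zero. A motor is excluded
  when a block bootstrap (100 resamples of contiguous stretches of jump
  pairs, shortest lag) yields a 95% interval covering zero; a fixed numeric
  threshold can be supplied instead.
* **Effective coefficients.** $\omega_{\text{eff}}$ is the mean
  stroboscopic displacement over one period divided by $T$;
  $D_{\text{eff}}$ comes from the through-origin weighted fit of the
  displacement variance at lags $\{2, 4, 6\}T$ against $2nT$. Stroboscopic
  sampling removes the deterministic intra-cycle motion. For strongly
  non-Gaussian hop statistics (a two-well motor makes discrete ±180°
  steps) the KDE slope systematically exceeds $\omega_{\text{eff}}/D_{\text{eff}}$
  — for a Poissonian stepper the exact log-ratio slope is
  $\ln(r_+/r_-)/L$ versus $2(r_+ - r_-)/\big((r_+ + r_-)L\big)$ for the
  coefficient ratio — which is why the collapse analysis renormalizes each
  motor's trend to unit slope before pooling rather than asserting the
  absolute scale.
* **MSD.** $\text{MSD}(\tau) = 2D\tau + (\omega\tau)^2$ is fitted with
  $1/\text{MSD}^2$ weights (relative error), since the ballistic term
  dominates by orders of magnitude at long lags and would otherwise swamp
  the linear term; the crossover time is $t_c = 2D/\omega^2$, flagged
  absent when the quadratic coefficient is not resolved.

## Spring-loaded operation

A linear torsional spring of stiffness $\kappa$ (default 0.5 $k_BT$/rad²)
adds a restoring torque $-\kappa(\vartheta - \vartheta_{\text{anchor}})$.
The real single-stranded-DNA loop is a nonlinear entropic spring; linearity
is the minimal model reproducing the observed sequence of behaviours:
processive winding while the drive is on, stall when the spring torque
balances what the ratchet can deliver, and processive rotation in the
opposite direction once the drive stops. The default stiffness puts the
stall winding at a few radians, reached within a 20 s drive phase at the
default motor speed. Note the stall winding reflects the ratchet's maximum
deliverable torque, which is much larger than $\lambda\,\omega_{\text{eff}}$
(the friction torque of the net drift) — the net speed averages over long
dwells between hops. Reversal is not certain: at the default stiffness the
spring torque at stall ($\kappa\,\Delta\theta \approx 1.6\,k_BT$/rad after
a one-hop winding) only partially suppresses the $8\,k_BT$ well barrier, so
a minority of replicate runs (roughly one in ten, as the reversal-fraction
computation in the bundled analyses shows) stay pinned at the stall angle
for the whole 20 s unwinding phase, and runs that never ratchet forward
contribute sign noise.

## Mechanics calculators

For a rotor arm of length $L$ in a fluid of viscosity $\eta$ the rotational
friction coefficient is $\zeta_r = \pi\eta L^3$; at angular velocity
$\omega$ the frictional torque is $\tau = \zeta_r\omega$ and the dissipated
power $\zeta_r\omega^2$, convertible to $k_BT$/s at a stated temperature
(293 K default — with $k_BT = 4.045$ pN nm this maps 250 pN nm/s to
$\approx 62\,k_BT$/s) and to an ATP-hydrolysis equivalent at a stated free
energy per ATP (25 $k_BT$ default, within the physiological range). Under a
load torque $\tau$, the velocity is $\omega_{\text{eff}} - \tau/\zeta_r$ and
the nominal efficiency
$\varepsilon(\tau) = (\omega_{\text{eff}} - \tau/\zeta_r)\tau / (\zeta_{\text{eff}}\,\omega_{\text{eff}}^2)$
is a downward parabola with roots at zero and stall, maximized at
$\tau^* = \zeta_r\omega_{\text{eff}}/2$ with bound
$\varepsilon \le \zeta_r/(4\zeta_{\text{eff}})$. The effective drive
friction $\zeta_{\text{eff}}$ depends on the microscopic drive mechanism
and is always an input, never computed. Note that $\pi\eta L^3$ with
$L = 550$ nm in water gives $5.2\times10^{-22}$ N m s while the headline
analyses use the rounded $4\times10^{-22}$ N m s as given input; the
calculators accept either.

## Problem sizes and what the tests show

The bundled analyses use desk-scale problem sizes chosen to make every
statistical claim resolvable: ensembles of 10–20 motors at 64 s (320 field
cycles) for drift and irreversibility, $10^6$-frame synthetic
drift-diffusion records for the closed-form oracle, 200 replicate seeds for
the fluctuation–dissipation check, and 50 seeds for the spring-reversal
fraction. Equilibrium checks (Boltzmann histogram, dwell positions) use
shallower wells ($b = 2.5$) than the driven-motor default: with $8\,k_BT$
wells inter-well hopping is far too rare for a field-off trajectory to mix
across the circle in any reasonable record, while $2.5\,k_BT$ wells mix in
seconds yet keep clearly resolved dwell peaks. Samples entering the
$\chi^2$ comparison are subsampled two seconds apart so they are
effectively independent.

These simulations share the idealizations of the model: a rigid rotor with
a single angular degree of freedom, ideal square-wave fields, linear
voltage coupling, no platform drift, no photophysics. Passing tests
demonstrate the internal consistency of the simulator and estimators under
the model, and the estimators' accuracy against closed-form references —
not the quantitative parameters of any particular experimental motor, whose
landscape calibration is unknown.

## A worked example

```{r example, eval = FALSE}
library(rotaratchet)

motor <- rotor_landscape(2, minima_offset = pi / 4)
drive <- field_protocol(data.frame(duration = 64, waveform = "square",
                                   period = 0.2))
traj <- simulate_motor(motor, drive, sim_config(seed = 1, theta_init = pi / 4))
angular_velocity(traj)                 # net speed, deg/s
entropy_production(traj, T_field = 0.2) # irreversibility curve and slope
mechanics_report(25, zeta_r = 4e-22)    # torque, power, ATP equivalent
```

## Known limitations

* The integrator is Euler–Maruyama; the landscape is smooth in angle and
  the drive discontinuity is in time only, so no higher-order scheme is
  used, but very stiff landscapes require proportionally small steps.
* The KDE entropy-production slope is an asymptotically consistent but
  finite-sample-biased estimator; absolute slopes should be interpreted
  via the renormalized collapse or against a matched reference process.
* The linear spring, linear voltage map and single-angle kinematics are
  minimal models; nonlinear springs, electro-osmotic flow and 2D/3D rotor
  excursions are out of scope.
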