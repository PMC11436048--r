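---
title: "Pressure-balance modelling of capillary rise in looped microcapillary strips"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pressure-balance modelling of capillary rise in looped microcapillary strips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcfrise)
```

## The problem

Melt-extruded microcapillary film (MCF) carries ten parallel bores of
roughly 200 µm internal diameter. Dipped vertically into a blood sample, it
acts as a low-cost "dip-and-test" strip: the sample rises by capillary
action, and the height and velocity of the rise report on the fluid's
viscosity — and therefore on clotting, once a dried agonist (thrombin,
collagen) inside the strip activates the sample. A straight vertical strip
equilibrates within tens of seconds, which leaves too little time for slow
stimulation responses to register. Coiling one or two loops into the strip
near the inlet adds purely frictional path length: flow slows, the advancing
sample spends longer in the stimulus-loaded "stimulation zone", and the
measurable response window stretches — without changing where the rise
ultimately stops.

`mcfrise` implements the quasi-steady pressure-balance model of this system,
the analysis chain used on measured height time series, a seeded synthetic
data generator, and a simulate → analyze → report pipeline.

## The model

For an elliptical bore with semi-axes $a \ge b$, the wetting (Laplace)
pressure drawing liquid in is

$$P_0 = \left(\frac{1}{a} + \frac{1}{b}\right)\gamma\cos\theta,$$

with $\gamma$ the surface tension and $\theta$ the contact angle. In the
circular limit $a=b=r$ this is the familiar $2\gamma\cos\theta/r$ — that
limit is why the axes are interpreted as *semi*-axes, the convention under
which the circular-tube Laplace form is recovered exactly. Balancing $P_0$
against the hydrostatic head and Poiseuille friction over the whole wetted
length $L(t)$ gives the meniscus velocity

$$\frac{dH}{dt} = \frac{d_h^2}{32\,\mu}\;
  \frac{P_0 - \rho g H(t)}{L(t)},$$

where $d_h$ is the hydraulic diameter of the bore, $\mu$ the dynamic
viscosity and $\rho$ the density. For a straight strip $L = H$; a looped
strip adds its loop-region length, $L = H + L_{loop}$, once the front has
passed the loop. Three properties follow directly and are what the tests
assert:

* **Equilibrium is loop-invariant.** Flow stops at
  $H_{eq} = P_0/(\rho g)$, which does not contain $L_{loop}$: loops add
  friction, not head.
* **Loops slow flow in order.** At any height below equilibrium,
  $v_{straight} > v_{1\,loop} > v_{2\,loops}$ whenever the loop lengths
  increase.
* **Straight strips are affine in $1/H$:**
  $v = (kP_0)\cdot\frac1H - k\rho g$ with $k = d_h^2/(32\mu)$, so a
  noiseless $(1/H, v)$ profile is recovered exactly by linear regression.

The hydraulic diameter uses $4A/P$ with Ramanujan's second perimeter
approximation (relative error $<10^{-6}$ over the eccentricities of
interest, verified in the tests against quadrature of the exact elliptic
integral); for a circle it reduces exactly to the bore diameter. A measured
$d_h$ may be supplied directly.

### Residence time in the loop

The stimulation time is set by how long the front spends inside the loop.
Writing the front position along the strip as $\ell$, the general
propagation law is $d\ell/dt = k(P_0 - \rho g\, z(\ell))/\ell$ with
elevation $z(\ell) = \ell$ before the loop, $z = $ `loop_entry_height`
inside it, and $z = \ell - L_{loop}$ after it (where the law reduces to the
looped-strip balance above). Because the loop diameter (9–14 mm) is small
against the equilibrium height (~76 mm), the in-loop elevation is
approximated as constant, which integrates in closed form:

$$t_{res} = \frac{\ell_2^2 - \ell_1^2}{2k\,(P_0 - \rho g\, z_{loop})},
\qquad \ell_1 = z_{loop},\ \ell_2 = z_{loop} + L_{loop}.$$

The tests cross-check this against quadrature. Residence time scales
linearly with $\mu$ and grows with loop length — the design lever of the
looped format.

## Parameters

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `rho` | g/mL | preset | fluid density (0.998 water, 1.025 PRP, 1.055 WB) |
| `mu` | cP | preset | dynamic viscosity (1.04 water, 1.7 PRP, 6 WB) |
| `gamma_cos_theta` | N/m | calibrated | wetting product; see below |
| bore diameter | mm | 0.2 | circular 200 µm bore |
| `loop_length` | mm | 43 / 58 | loop-region length, one / two loops |
| `loop_diameter` | mm | 14 / 9 | nominal loop diameter (metadata) |
| `strip_length` | mm | 100/150/160 | straight / 1-loop / 2-loop formats |
| `g` | m/s² | 9.81 | gravitational acceleration |
| `H0` | mm | 0.1 | integration start height |
| `eps_eq` | – | 1e-6 | equilibrium saturation fraction |

All interfaces speak mm, s, cP and g/mL; conversion to SI happens once, in
a single internal module.

**Identifiability.** An equilibrium height determines only the *product*
$\gamma\cos\theta$, never the factors separately, so the package estimates
the product (`estimate_gamma_cos_theta`) and accepts separate $\gamma$,
$\theta$ only as optional inputs from which the product is derived. This
deliberately avoids an unidentifiable two-parameter fit. The shipped fluid
presets calibrate the product from measured straight-strip equilibria
(76.3 mm water, 75.4 mm PRP, 72.7 mm WB in the 200 µm bore); HBS, PPP and
RBC presets carry assumed values and are flagged as such.

## The analysis chain

Observed data arrive as per-capillary height time series.
`finite_difference_velocity` forms $\Delta H/\Delta t$ from consecutive
sample pairs using the *actual* timestamps, assigning each velocity to the
midpoint height and time — the midpoint rule makes the estimate
second-order accurate, which the tests verify by its $\Delta t^2$
convergence against the analytic velocity. Analysis is restricted to the
reciprocal-height window $1/H \in [0.0125, 0.06]$ mm⁻¹ (heights
16.7–80 mm): below ~17 mm the velocities are large, the sampling intervals
short, and timing noise dominates; near equilibrium the quasi-steady model
underestimates drag.

`fit_viscosity` inverts the model for $\mu$ by bounded scalar least squares
on velocity-space residuals (not $1/H$-space), consistent with roughly
uniform noise on measured heights; since the model velocity is exactly
proportional to $1/\mu$, the problem is well-posed with a single minimum.
Group statistics use one-way ANOVA with Tukey HSD post hoc comparisons
(delegated to `stats::aov` / `stats::TukeyHSD`; the test suite checks them
against a hand decomposition and a Monte-Carlo studentized-range
simulation), with a Shapiro–Wilk normality p-value reported alongside but
gating nothing. The significance threshold is 0.05.

## The synthetic-data generator

`simulate_strip` emulates what the measured data look like: 10 replicate
capillaries per strip, fixed-interval time-lapse sampling with Gaussian
timestamp jitter (SD 0.05 s), additive Gaussian height noise (SD 0.5 mm,
the order of pixel-level image annotation scatter), and
replicate-to-replicate variability as a 3% coefficient of variation on the
wetting product. The 3% figure is the package's own calibration: with ten
replicates per group, it implies a within-group SD at the 30 s readout of
about 2.5 mm, the dispersion consistent with the group-separation F
statistics in the hundreds reported for this assay format, whereas the
larger spread printed on *equilibrium* heights (±9 mm) also contains
end-point measurement error. Each (strip, capillary) pair draws from its
own seeded RNG stream (derived by integer mixing from the master seed), so
changing the number of replicates in one strip never shifts another's
draws, and identical seed plus configuration is bitwise-reproducible.

With all noise parameters zero the generator returns exactly the model
trajectory. The generator emulates the *statistical structure* of strip
data, not its physics beyond the model: it will not reproduce the
experimentally observed late-time drag excess (real velocities fall below
the model as the meniscus nears equilibrium), dynamic contact-angle
effects, strip bending, or inter-donor variability. Passing
parameter-recovery tests therefore demonstrates that the analysis chain is
a consistent inverse of the model at realistic noise — not that the model
captures every feature of real strips.

`stimulated_viscosity_trajectory` adds a phenomenological viscosity ramp
(baseline → linear rise after an onset time → saturation) to emulate
coagulation qualitatively. It reproduces the observed orderings — higher
stimulus ⇒ lower heights, looped strips amplify the difference, and a steep
enough ramp stalls the front inside the loop ("could not pass the loop") —
but it is an invented stand-in, not a clotting kinetics model.

## Numerical choices

* The straight-strip ODE is singular at $H = 0$ (infinite initial
  velocity), so integration starts at `H0 = 0.1` mm.
* Trajectories are integrated with `deSolve::lsoda` at `rtol = 1e-8`,
  `atol = 1e-10`. The raw ODE is smooth and approaches $H_{eq}$ from below;
  the saturation clamp at $(1-\epsilon)H_{eq}$ and at the device's vertical
  extent is applied to the monotone solution afterwards, which is
  equivalent to stopping the front there and keeps the solver away from a
  rate discontinuity.
* `time_to_height` evaluates the separated integral
  $t(H) = \int_{H_0}^{H} (h + L_{loop})/(k(P_0-\rho g h))\,dh$ by adaptive
  quadrature at `rel.tol = 1e-10`; ODE and quadrature routes agree to
  better than $10^{-4}$ relative over randomized configurations (asserted
  in the tests).
* Timestamp jitter can reorder or collide capture times; the generator
  sorts and minimally separates them, and all downstream velocity
  calculations use the recorded timestamps.

## Problem sizes in the shipped tests

The test suite exercises the pipeline at sizes chosen to be statistically
meaningful while staying quick: parameter recovery uses 100 seeded
experiments of one 10-capillary strip sampled at 4 Hz for 60 s; the group
comparison study uses 100 seeded three-device experiments of 10 capillaries
read out at 30 s; oracle-equivalence checks use 20 randomized
configurations. The full suite runs in well under a minute.

The 30 s group-comparison study uses whole blood. That is the assay's
target sample, and under this model it is also the informative choice: with
water's time constant of ~6.5 s, all three device formats have essentially
equilibrated by 30 s, so the model compresses the between-device height
differences that the real experiment (whose late-time flow is slower than
the model's) still shows at that readout; whole blood at 30 s is mid-rise,
where loop friction dominates the signal.

## Known limitations

* No dynamic contact angle, inertial, centrifugal or Dean-flow terms: the
  quasi-steady Poiseuille balance is the whole model, and it is known to
  overestimate velocity as the meniscus approaches equilibrium.
* The in-loop elevation is treated as constant; fine structure of height
  within the loop (±half a loop diameter) is ignored.
* The elliptical bore geometry of real MCF is approximated by a circular
  200 µm bore unless measured semi-axes or $d_h$ are supplied.
* The stimulation ramp is qualitative; dose–response magnitudes are not
  calibrated to any measured thrombin/collagen series.
* Whether the 58 mm two-loop region is total or per-loop extra length is
  ambiguous in the source description; it is treated as the total
  $L_{loop}$.
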