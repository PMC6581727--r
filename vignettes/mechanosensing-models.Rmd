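---
title: "Minimal biophysical models of cell-wall mechanosensing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal biophysical models of cell-wall mechanosensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wallsense)
```

## The question the models address

Plant cells are pressurized: turgor puts the cell wall under tension, and
that tension both drives growth and threatens integrity. Many wall- and
membrane-associated proteins are candidate mechanosensors, but it is unclear
*which* mechanical cue — stress (force per area, in Pa), strain (relative
deformation ΔL/L₀), or strain rate — is actually accessible to a given
sensor. wallsense implements minimal one-dimensional spring–dashpot models
that answer the narrower, tractable question: given how a sensor is coupled
to the wall, what part of an imposed mechanical signal is transmitted to the
force in the sensor, and hence available to downstream signalling?

Everything is one-dimensional: stress and strain are treated as scalars, the
configuration where both are unidirectional. Downstream transduction,
two-dimensional stress patterns, and feedback of the sensor on wall
mechanics are out of scope.

## The wall

The wall is viscoelastoplastic in the Lockhart/Ortega sense: a spring of
elastic modulus $K_w$ in series with a dashpot of viscosity $\eta_w$ and a
frictional yield block with threshold $Y$. Under an imposed stress history
$\sigma(t)$,

$$\dot\varepsilon(t) \;=\; \frac{\dot\sigma(t)}{K_w}
  \;+\; \frac{\max(\sigma(t) - Y,\, 0)}{\eta_w},$$

so the wall is purely elastic below yield and flows irreversibly above it.
The wall relaxation time is $\tau_w = \eta_w/K_w$; under fixed strain with
the block engaged, stress relaxes as $e^{-t/\tau_w}$
(`stress_relaxation_fixed_strain()` provides this closed form as a test
oracle). The yield is sharp — `max(·, 0)` with no smoothing — matching the
frictional-block picture; below $Y$ the block does not slide, so the wall
does not relax there. Stress steps are handled by the discrete derivative
(the elastic jump is resolved over one grid step), and the tests verify
convergence under grid refinement.

## Input waveforms

All scenario inputs are a constant background (turgor-generated stress, or a
steady expansion rate) plus one transient pulse (a transient external load).
`pulse_spec()` parameterizes the pulse by baseline, amplitude, center and
full width at half maximum; shapes are `gaussian` and `raised_cosine`. The
published curves the presets emulate state no numerical pulse parameters, so
the presets fix them once, as reconstructions recorded in each preset's
`notes`:

* **amplitude = baseline** — the transient doubles the background;
* **FWHM = 2 reference times** — the regime signatures require the rise and
  the fall of the pulse to be separated on the sensor's memory scale
  ($\tau_s$ or $\tau_c$). A pulse much narrower than $\tau_c$ merges the
  short-lived sensor's two response peaks into one and lets the plastic
  strain gained during the pulse fill the long-lived sensor's dip; both
  effects can be shown analytically with the exponential smoothing kernel,
  and disappear once rise and fall are ~2 reference times apart;
* **raised-cosine shape** — compact support. Gaussian tails leak plastic
  strain into the pre/post-pulse windows and dilute the compression
  transient behind the short-lived sensor's second peak. The stress rate of
  a raised cosine is continuous, so the elastic term of the wall law stays
  well defined.

Internally everything is dimensionless: stress in units of $\sigma_0$, time
in units of the scenario's reference time, forces in
$F_0 = (K_s/K_w)\,\sigma_0$ (minor sensor) or $(k_s/k_w)\,\sigma_0$ (major
sensor). Normalized stress is $(\sigma - Y)/\sigma_0$ in a growing wall and
$\sigma/\sigma_0$ in an elastic one; expansion rate is normalized by
$1/\tau_0 = \sigma_0/(K_w \tau_s)$ or $\sigma_0/(K_w \tau_c)$.

## Sensor attached to a minor load-bearing structure

A sensor inserted in a matrix component or the plasma membrane is a spring
$K_s$ (sensor plus structure) in series with a dashpot $\eta_s$ (structure
remodeling/turnover), the branch in parallel with the bulk wall and carrying
negligible load — so it is strain-driven by the wall. The branch force obeys

$$\frac{dF}{dt} \;=\; K_s\,\dot\varepsilon(t) \;-\; \frac{F}{\tau_s},
\qquad \tau_s = \eta_s/K_s,$$

i.e. $F$ is $K_s \tau_s$ times the exponential moving average of the strain
rate over $\tau_s$. Because the wall relaxes no faster than any constituent,
$\tau_s \le \tau_w$; pairings violating this emit a warning (one published
caption states a ratio of 2 for the fast-branch panel, which contradicts
this constraint; the preset uses the regime-faithful 0.2 and keeps the
caption value in its notes). Sensor binding is taken as fast: sensors are
always attached, which the source analysis argues changes only the magnitude
of sensing, not its character.

Consequences, each a tested closed form:

* constant strain rate $r$: $F \to K_s \tau_s r$; in normalized units steady
  output equals steady input;
* constant stress above yield: $F \to (K_s/K_w)(\tau_s/\tau_w)(\sigma - Y)$,
  so a fast-relaxing branch ($\tau_s \ll \tau_w$) is blind to permanent
  stress while $\tau_s = \tau_w$ transmits it perfectly — in fact with
  matched times the normalized output overlaps the normalized input
  *exactly* after a transient (the branch ODE composed with the wall law is
  the identity filter at $\tau_s=\tau_w$), which the overlap test verifies
  to the grid's accuracy;
* below yield, a stress step $\Delta\sigma$ produces
  $(K_s/K_w)\Delta\sigma\, e^{-t/\tau_s}$: only variations faster than
  $\tau_s$ are seen.

The integrator is the per-step exact exponential update
$F_{i+1} = F_i e^{-\Delta t/\tau_s} + K_s\tau_s(1-e^{-\Delta t/\tau_s})
\bar{\dot\varepsilon}_{i+1/2}$; it is exact for constant input and second
order otherwise, and `F_init = "steady"` starts the branch at the fixed
point of the background so traces open on their plateau.

## Sensor attached to a major load-bearing structure

A sensor bound to, e.g., a cellulose microfibril is a soft spring ($k_s$,
length $l$, with $k_s \ll k_w \simeq K_w/l$) in parallel with a wall
segment, the pair in series with the rest of the wall. The series
arrangement means the segment carries the whole-wall stress, so the segment
strain is the wall strain, and a bond formed at time $t_b$ carries

$$F(t; t_b) \;=\; k_s l\,\bigl(\varepsilon(t) - \varepsilon(t_b)\bigr).$$

The bond detaches with the force-dependent rate
$1/\tau_d = (1/\tau_c)\, f(|F|/F_c)$, a Bell-type slip bond: $\tau_c$ is the
maximal (zero-force) mean lifetime, $F_c$ the force scale above which
detachment accelerates sharply, and the default amplification is
$f(x) = e^{\beta x}$ with $f(0)=1$. The hazard uses the *magnitude* of the
spring deformation: a bond sheared in compression detaches like one sheared
in tension. (An early design draft clipped compressive forces to zero; that
choice provably erases two of the signature behaviours — the elastic-wall
low-$F_c$ sensor's response to *decreasing* stress, and the short-lived
sensor's second detachment-force peak, which comes from bonds deposited at
elevated strain that later detach deformed in the opposite sense — so the
magnitude convention is used throughout.)

On detachment a sensor immediately rebinds in an unstretched state: total
sensor number is conserved and the attached fraction is identically 1. This
is the parsimonious closure of "re-associates in an unstretched state";
rebinding kinetics are not modelled.

### Deterministic population (renewal) solution

With binding flux $b(t_b)$ and survival
$S(t;t_b) = \exp(-\int_{t_b}^t h(F(t';t_b))\,dt')$, the detachment flux
obeys the Volterra renewal equation
$b(t) = \int b(t_b)\, S(t;t_b)\, h(t;t_b)\, dt_b$. `population_response()`
solves it by forward time stepping over cohorts: each step, every cohort
loses the mass $\mu(1-e^{-\Delta H})$, and the lost mass is gathered into a
freshly bound cohort at the loss-weighted mean strain. Conservation
therefore holds to machine precision *by construction*, not as an accuracy
statement. Numerical choices that matter:

* **Stationary initialization.** Instead of simulating a burn-in, both
  solvers start from the analytic stationary age distribution under the
  background input ($b_0 = 1/\int S_0$, ages extended backward along the
  background loading path, cumulative hazard computed on an 8× refined age
  grid). This is an infinite burn-in at zero cost and makes the pre-pulse
  plateau exact from the first sample.
* **Hazard substepping.** Where the hazard is stiff (low $F_c$: rates reach
  tens per $\tau_c$), each step's cumulative hazard is refined with
  substeps keeping $h\,\Delta t \lesssim 0.05$ (capped at 256), and the
  detaching mass within each substep carries the endpoint-weighted force
  $(h_a F_a + h_b e^{-\Delta H} F_b)/(h_a + h_b e^{-\Delta H})$.
* **Outputs.** $D(t)$ is the loss-weighted mean $|F|$ of the bonds detaching
  in each step; $R(t)$ is the pointwise mean hazard of the attached
  population, so the floor $R \ge 1/\tau_c$ is exact.

Residual discretization error in stationary detachment forces is first
order in $\Delta t$ (about 0.5% at $\Delta t = 0.01\,\tau_c$, halving with
$\Delta t$, verified against a fine-quadrature stationary-age oracle);
presets use $\Delta t = 0.005\,\tau_c$ (the low-$F_c$ elastic preset
$0.0025\,\tau_c$, where detach–rebind ratcheting puts structure on the
scale $F_c/(k_s l |\dot\varepsilon|) \approx 0.17\,\tau_c$).

### Stochastic ensemble

`simulate_ensemble()` is the validation twin: independent bonds accumulate
the same discrete hazard; detachment happens when the integrated hazard
crosses an Exp(1) threshold (inverse-transform sampling with linear
interpolation of the cumulative hazard inside a substep), the event
`(time, force)` is recorded, and the bond rebinds unstretched. Initial ages
are drawn from the same stationary age distribution, and a seed is
mandatory. Binned event rates (Poisson standard errors) and mean detachment
forces (SD/√n) are compared against flux-weighted bin averages of the
renewal solution; the acceptance suite requires agreement within 3 standard
errors in every half-$\tau_c$ bin with 10⁴ sensors, on all six major-sensor
presets.

### Regimes and presets

`classify_regime()` operationalizes the taxonomy: $F_c$ is *high* when
$F_c > 10 (k_s/k_w)\sigma_{background}$ (the bond lives out its natural
lifetime), the sensor is *long-lived* when $\tau_c \ge \tau_w$, and the wall
is *elastic* when the background stress is below yield. The presets
(`list_scenarios()`) realize the panels:

| preset | regime | output | signature |
|---|---|---|---|
| fig4C | minor, $\tau_s = 0.2\tau_w$ | $F/F_0$ | steady output ≈ 0.2× matched case |
| fig4D | minor, $\tau_s = \tau_w$ | $F/F_0$ | output overlaps input |
| fig4E | minor, strain-rate input | $F/F_0$ | pulse smoothed over $\tau_s$ |
| fig5C | long-lived, high $F_c$ | $D/F_0$ | one peak, then one dip |
| fig5D | short-lived, high $F_c$ | $D/F_0$ | two consecutive peaks |
| fig5E | high $F_c$, strain-rate input | $D/F_0$ | smoothing over $\tau_c$ |
| fig5F | low $F_c$, viscous wall | $R\,\tau_c$ | single peak |
| fig5G | low $F_c$, elastic wall | $R\,\tau_c$ | two peaks, jump at the stress-derivative sign change |
| fig5H | low $F_c$, strain-rate input | $R\,\tau_c$ | weakly smoothed peak |

Parameter choices the source leaves open, decided once and recorded in the
preset notes:

* The high-$F_c$ stress presets use a *finite*
  $F_c = 10 (k_s/k_w)\sigma_{background}$, the bottom edge of the
  high-force band. With a strictly constant hazard ($F_c=\infty$) the
  exponential-age population mean turns $D(t)$ into an exact lag–lead
  filter of the input — at $\tau_c = \tau_w$ literally `baseline + pulse` —
  and neither the long-lived dip nor the short-lived second peak can exist.
  Those features are *force-selection* effects: stretched bonds detach
  preferentially, so the post-pulse population detaches under-stretched.
  The strain-rate high-$F_c$ preset keeps $F_c = \infty$, where its
  defining identity (steady normalized output = steady normalized input)
  is exact.
* The low-$F_c$ panel force scales follow the dimensional reconstructions
  $F_c = 0.5(k_s/k_w)\sigma_0$ (elastic), $0.5\,k_s l\,\sigma_0\tau_c/\eta_w$
  (viscous) and $0.5\,k_s l\,\dot\varepsilon_0\tau_c$ (strain-rate), the
  printed forms being dimensionally incomplete.
* The viscous-wall panel uses $\tau_w = 0.1\,\tau_c$: a wall with
  $\tau_w = \tau_c$ contracts elastically on the falling flank of the pulse
  ($\dot\sigma/K_w$ beats $(\sigma-Y)/\eta_w$), which is the elastic
  signature; a genuinely viscous wall never contracts under this input.
* Presets use Bell steepness $\beta = 3$ (the package default stays 5). In
  an elastic wall the stationary population has zero force dispersion, so
  loading starts in lockstep, and a sharper bond produces a grid-converged
  synchronization echo — small extra local maxima the smooth published
  curves do not show. $\beta = 3$ is still a sharp slip bond
  ($f(F_c) \approx 20$) and damps the echo below the 2% detection
  threshold with at least five-fold margin on every preset.
* The panel-letter/ratio pairing of the published captions is internally
  inconsistent; presets are keyed by regime, with regime-name aliases
  (`long_lived_high_Fc`, …) and notes holding the caption values.

### Signature detection

`summarize_trace()` finds local extrema by topographic prominence, with the
threshold expressed as a fraction of the post-burn-in output range (default
2%); steady levels are medians of the first and last 10% of the window, and
the "discontinuity" of the elastic low-$F_c$ regime is the largest
sample-to-sample jump, located at the stress-derivative sign change. The
thresholds are not part of the science; they are chosen so every preset
passes its signature with at least 5× prominence margin, and are exposed as
arguments.

## What the synthetic inputs do and do not capture

The generator produces idealized signals: a noiseless constant background
with one smooth transient. Real walls see fluctuating turgor, spatially
heterogeneous mechanics, wall synthesis and remodeling that move $K_w$,
$\eta_w$ and $Y$ on growth timescales, and sensors with dispersed kinetic
parameters. Passing tests therefore show that the *models* behave as their
analysis says under the stated conditions — not that real sensors do. Two
robustness statements are nevertheless checked mechanically: strain-rate
driven responses of the major sensor are exactly independent of $\eta_w$
and $Y$ (the wall drops out of the strain path), and the minor sensor's
response depends on wall parameters only through the ratio
$\tau_s/\tau_w$.

## Known limitations

* One-dimensional, scalar stress and strain only.
* Immediate unstretched rebinding; no free-sensor pool, no rebinding delay.
* The renewal solver merges each step's rebinding into a single cohort at
  the loss-weighted mean strain; residual first-order bias is ~0.5% of the
  stationary detachment force at $\Delta t = 0.01 \tau_c$.
* The deterministic lag–lead identity at $F_c=\infty$ means high-$F_c$
  regime signatures depend on where in the high-force band $F_c$ sits;
  the presets sit at its bottom edge, where selection is mild but present.
* Problem sizes used throughout (30 reference times, $\Delta t =
  0.005$–$0.01$ reference times, 10⁴ sensors) are the package's validation
  conditions; they keep every preset deterministic-to-stochastic comparison
  inside three binned standard errors.
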