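---
title: "Methods: dosimetry, thermal regulation and expression readout of a 1.8 GHz exposure system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosimetry, thermal regulation and expression readout of a 1.8 GHz exposure system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfdosim)
```

`rfdosim` implements the computational side of a far-field radiofrequency
(RF) cell-culture exposure protocol: converting probe readings into the
incident power flux a Petri dish receives, checking that the plane-wave
assumptions behind that conversion hold, bounding thermal artifacts,
simulating the hot-water PID temperature regulation of the exposure box, and
analysing the biological readout (qPCR relative expression across an
amplitude ladder, with hormetic dose–response classification). This
vignette is the package's account of those methods: the models, the
assumptions, the tunable parameters, and the choices made where the design
was genuinely open.

## 1. The dosimetry chain

A small dipole E-field probe sits at the sample position; a spectrum
analyzer measures the electrical power `P_MES` (in dBm) delivered through an
SMA cable of known attenuation. The chain to incident plane-wave power flux
is

$$P_{ELEC} = \frac{P_{MES}[\mathrm W]}{A_{CABLE}}, \qquad
  U_{ELEC} = \sqrt{P_{ELEC} \, Z_0}, \qquad
  E = AF \cdot U_{ELEC}, \qquad
  P_{EMG} = \frac{E^2}{\eta_0},$$

with `dbm_to_watt()` handling the dBm→W step
($P[\mathrm W] = 10^{P[\mathrm{dBm}]/10}/1000$). The calibration constants
live in one object, `rf_calibration()`, whose defaults are the measured
constants of the characterised system: cable attenuation −3.896 dB at
1.77 GHz (linear coefficient $A_{CABLE} = 0.40776$), antenna factor
$AF = 179.89\,\mathrm{m^{-1}}$, port impedance $Z_0 = 50\,\Omega$, air wave
impedance $\eta_0 = 377\,\Omega$. All gain/attenuation quantities in the
package are relative dB; all absolute powers are dBm — the two are never
interchanged, which prevents the classic unit bug.

Two conventions deserve emphasis:

* **Below-floor readings are flags, not numbers.** The analyzer cannot
  measure below −75 dBm. Any reading at `NA` or under the configured floor
  propagates through `probe_chain()` and `build_exposure_table()` as a typed
  `below_floor` flag and renders as `---` in written tables. Nothing is ever
  imputed.
* **Printed-precision reproduction.** The published characterisation table
  of this system prints E and $P_{EMG}$ to two significant figures, and a
  few of its cells are internally rounded (its E at the +20 dBm rung prints
  2.05 V/m where the chain with the printed constants gives 2.038; its
  $2.9\times10^{-n}$ flux cells compute to $2.97\times10^{-n}$). The package
  always reports the chain's unrounded output; tests compare each printed
  cell to within one unit in its last printed digit, the granularity the
  source values actually carry.

### Far-field validity

The E-only flux formula holds only for a locally plane wave, which requires
the sample beyond the far-field bound $d \ge 2D^2/\lambda$
(`min_farfield_distance()`). For the 5.5 cm antenna diagonal and
$\lambda = 16.5$ cm this gives 3.67 cm, comfortably under the 16.8 cm
antenna-to-sample distance. When a frequency rather than a wavelength is
supplied, propagation speed in air is fixed at $2.998\times10^8$ m/s.

### Field-map statistics

Gridded field maps (1 mm pixels by default) over the observation plane feed
three validity statistics, all evaluated on the **Petri mask**: the pixel
centers *strictly inside* the dish circle (52 mm diameter by default,
centered on the grid). Strict insideness is a fixed boundary convention —
whether the quoted ~52 mm is an inner or outer diameter is not stated
anywhere, so the package picks one convention and documents it; at 1 mm
pitch the choice moves the statistics by well under their meaningful
precision.

* `inhomogeneity_percent()` — $100\,\sigma(P)/\bar P$ over the mask, with
  the *population* standard deviation: the masked grid is the entire
  population of pixels, not a sample from one (a `sd_type = "sample"`
  option exists). The statistic is scale-invariant.
* `polarization_ratios()` — $(\bar E_z/\bar E_x,\ \bar E_y/\bar E_x)$ of
  mask-mean component magnitudes; small values mean clean linear
  x-polarization.
* `plane_wave_ratio()` — mask-mean of $|E|^2/2\eta$ over mask-mean of
  $|\Re(\tfrac12 \vec E \times \vec H^*)|$; exactly 1 for an ideal plane
  wave with $\vec H = \hat z \times \vec E / \eta$. Maps without H raise an
  error rather than silently assuming plane-wave structure, because the
  statistic exists precisely to *test* that assumption.

The reference values these statistics are known to take on the actual box
(≈7% inhomogeneity, ratios 0.053/0.015, plane-wave ratio ≈1.01) come from
full-wave simulation of the physical system, which is out of scope here;
the package reaches them only through `gen_field_map()`, which *constructs*
maps with those targets. Passing tests therefore anchor the definitions of
the statistics, not the field of any physical box.

### Safety reference levels

`icnirp_limits()` implements the general-public, 30-min-averaged,
whole-body reference levels for 400–2000 MHz:
$E_{max} = 1.375\sqrt{f_{MHz}}$ V/m, $H_{max} = 0.0037\sqrt{f_{MHz}}$ A/m,
$S_{max} = f_{MHz}/200$ W/m². Out-of-band frequencies raise an explicit
error — the formulas are not extrapolated. `exposure_margin()` is the plain
flux ratio; at 1800 MHz the strongest exposure used
($2.9\times10^{-3}$ W/m²) sits at $3.2\times10^{-4}$ of the limit.

## 2. Thermal budget and regulation

### Lossless heating bound

`delta_t_budget()` computes the worst-case temperature rise if every
incident watt were stored:
$\Delta T = P_{EMG} \cdot \mathrm{Surf}_{PETRI} \cdot \Delta t / (C V)$.
Units are part of the contract (flux W/m², duration hours, capacity
Wh/(m³·K), volume m³) and are not silently converted. With water
($C = 1160$ Wh/(m³·K), the `C_WATER_WH_PER_M3K` constant) the strongest
15-min exposure bounds at $1.2\times10^{-3}$ °C. A kidney-tissue constant
(`C_KIDNEY_WH_PER_M3K` = 1012 Wh/(m³·K), i.e. 3644 J/(L·K)) is shipped;
note that the commonly quoted $1.37\times10^{-3}$ °C figure for that
variant does not follow from these inputs, which give $1.33\times10^{-3}$ —
the function reports what the formula yields.

### Plant model and its (synthetic) parameters

The regulation loop is simulated against a first-order-plus-dead-time
(FOPDT) plant, $\tau\,dT/dt = -(T - T_{amb}) + K\,u(t-\theta)$, the standard
lumped model for a slow thermal enclosure. No plant constants for the
physical box are published, so `plant_model()` ships an explicitly
**synthetic** fixture — $K = 30$ °C/duty, $\tau = 600$ s, $\theta = 20$ s,
ambient 22 °C, hood disturbance −0.9 °C — chosen once so the simulated loop
shows the regulation behaviour the physical system is reported to have:
an initial heating phase, transient dips under 1 °C on hood opening, and
steady regulation at 37 ± 0.2 °C. These values are study conditions, not
fit parameters.

### Controller

`imc_pid_gains()` applies Internal Model Control tuning for FOPDT:
$k_p = \tau/(K(\lambda_c + \theta))$, integral time $\tau$, derivative time
0. PI-without-derivative is the usual IMC outcome for slow thermal plants;
the derivative slot exists and is zero. The single tuning knob is the
closed-loop time constant $\lambda_c$ (default 120 s — about five dead
times, a conservative industrial default).

`simulate_regulation()` integrates the loop with a fixed 0.5 s explicit
step (configurable; it must stay ≤ PWM period/10). The controller runs once
per 5 s PWM period, and within each period the heater is modelled at its
mean value — the duty — because $\tau$ is two orders of magnitude above the
period, making sub-period switching dynamics irrelevant. Three
implementation details matter for realism:

* **Anti-windup**: the integrator only accumulates while the output is
  unsaturated (conditional integration); without it the deep cold start
  would wind the integral up and overshoot badly after hood events.
* **Bumpless start**: when integral action exists, the integrator is
  initialised to hold the starting temperature, so a run started at the
  setpoint is an equilibrium. With an all-zero controller the duty is zero
  and the plant relaxes to ambient, as it must.
* **Hood events** add the disturbance step to the *sensed air temperature*
  while open: opening the hood admits room air quickly (fast air path)
  while the heated walls and water loop (the slow FOPDT state) barely move
  in 30 s. The controller reacts to the sensed dip, which is what the
  physical PT100 sees.

`trace_metrics()` summarises a run: maximum deviation, and the fraction of
samples inside a ±0.2 °C band outside event windows (each window extends a
configurable 60 s past hood closing, covering the controller's recovery).

### Plant identification

`identify_fopdt()` recovers $(K, \tau, \theta)$ from an open-loop step
response by the two-point method: $K = \Delta T_{ss}/\Delta u$ with the
final value from the tail, and from the 28.3% and 63.2% rise times
$\tau = 1.5\,(t_{63.2} - t_{28.3})$, $\theta = t_{63.2} - \tau$ — exact for
a true FOPDT response, with linear interpolation between samples. Noisy
traces are first smoothed with a centered running mean (~1% of the trace
length) because first-crossing detection on raw noise is biased early; the
smoothing engages only when the trace tail is rough, so noiseless traces
are untouched and recover all three parameters within 2%. Non-settling
traces and zero steps raise identification errors instead of returning
numbers.

## 3. The qPCR expression pipeline

### Relative quantification

`relative_quantities()` implements single-reference-gene ΔCt
quantification: per sample $\Delta Ct = Ct_{target} - Ct_{ref}$, relative
quantity $2^{-\Delta Ct}$, normalised to the control (sham) condition.
Where the control normalisation is ambiguous, the package defaults to
dividing by the **arithmetic mean** of the control replicate quantities, so
that the control condition's mean fold change is exactly 1 — the property
downstream summaries rely on. The classic $2^{-\Delta\Delta Ct}$ form,
which subtracts the mean control ΔCt on the cycle scale and therefore
normalises by the *geometric* mean, is available as `norm = "geometric"`;
the two coincide as control noise vanishes and differ by under 1% at
typical replicate scatter.

`relative_expression()` reports mean fold change ± SEM with n per
condition, plus a per-gene one-way ANOVA across conditions
(`stats::aov`) followed by Tukey's HSD (`stats::TukeyHSD`), keeping only
the contrasts of each exposure condition against the control — the
comparisons the study design defines. The ANOVA runs on linear fold changes
by default with a `log2_scale` option, since the appropriate scale is a
genuinely open choice; on these effect sizes the two agree on every
qualitative call. With two groups Tukey reduces to the pairwise t-test, a
property the test suite checks numerically to anchor the multiple-comparison
machinery. Shapiro–Wilk normality (`normality_check()`) is advisory: the
pipeline reports p but does not switch tests. Significance stars use strict
thresholds (<0.05 \*, <0.01 \*\*, <0.001 \*\*\*, <0.0001 \*\*\*\*; boundary
values take the weaker label).

### Dose–response shape classification

Hormetic (biphasic, U-shaped) amplitude responses — strong responses at
both ends of the amplitude ladder with an unresponsive interior — are the
phenomenon of interest, but "U-shaped" needs an operational rule.
`classify_dose_response()` uses a deterministic one, which is a package
design choice rather than anything externally prescribed, and both of its
knobs (`alpha`, `spearman_threshold`) are exposed:

1. no significant condition → `flat`;
2. the significant conditions form exactly **two same-direction runs
   anchored at the two ladder ends** with a non-significant gap between →
   `biphasic-U` (up) or `biphasic-inverted` (down). Anchored *runs*, not
   single extreme rungs, so a profile responding at −40 **and** −30 dBm
   plus +10 dBm still reads as one U;
3. otherwise, significant fold changes monotone in amplitude
   (Spearman $|\rho| \ge 0.8$ over the significant rungs) →
   `monotonic-up`/`-down`;
4. anything else → `mixed`.

The ladder is ordered by generator power (equivalently log flux), control
excluded. Fewer than three non-control conditions is `not-classifiable`.

## 4. Synthetic data: what it emulates, what it does not

No raw Ct data are deposited for this system, so the generators define the
study conditions the pipeline is tested under.

* `gen_ct_table()` draws reference Ct ~ Normal(baseline, sd) and target
  Ct = baseline − log2(fold) + Normal(0, sd): Gaussian on the cycle scale,
  hence lognormal in quantity — the standard qPCR noise picture. Defaults
  are the study design: n = 3 biological replicates, sd = 0.15 cycles
  (typical replicate scatter). The shipped `effect_profile()`s encode the
  *reported* effect sizes (`kiaa_biphasic`: 2.5-fold at +10 dBm, 5-fold at −30
  and −40 dBm, unresponsive between; `krt79_peak`: 10-fold at −10 dBm,
  0.5-fold at 0 dBm); every otherwise-undescribed condition sits at fold 1.
  They are parameter reconstructions, not data.
* `gen_probe_ladder()` inverts the dosimetry chain exactly, adds optional
  Gaussian noise in dB (multiplicative in power, matching instrument
  behaviour), and applies the sensitivity floor.
* `gen_field_map()` rescales a lognormal field affinely so the mask mean
  and coefficient of variation hit their targets *exactly*, builds
  x-dominant E components at the requested mean ratios, and attaches the
  ideal plane-wave H companion (optionally detuned via `h_scale`).

Every generator embeds its ground truth as an attribute and is
deterministic per seed. What the synthetic data deliberately **omits**:
primer-efficiency deviations from 2.0, technical-replicate structure,
batch/day effects, heavy-tailed or correlated Ct noise, spatial dose
variation within a dish, and any mechanistic ROS model. Parameter-recovery
tests passing on these generators therefore demonstrate the pipeline's
correctness, not robustness of the biology to those real-world
complications.

## 5. Problem sizes and numerical choices

The test suite and the acceptance script use: the 10-rung published
measurement ladder; 61 × 61-pixel field maps (1 mm pitch, 2109 masked
pixels); a 2400 s regulation run at 0.5 s steps with two 30 s hood
openings; a 5000 s identification step response; single seeded Ct tables at
n = 3 plus a 500-table replicate for log-scale bias — sizes chosen so every
statistic is stable at three digits while the whole suite runs in seconds.
Ties and degenerate inputs are decided, not left to chance: all-identical
ANOVA groups return p = 1; zero-variance replicate sets are flagged
non-computable rather than tested; all-zero power maps and zero-Ex
polarization raise errors; boundary p-values take the weaker star.

## 6. Known limitations

The package characterises the exposure *computationally*: it does not do
full-wave electromagnetics, antenna design, probe drivers, or firmware. The
plant parameters are synthetic stand-ins. The dose–response rule is one
reasonable operationalisation among several — with only 5–6 amplitude
rungs, any classifier is coarse, and two significant rungs always look
monotone to a rank correlation. The ΔΔCt pipeline assumes Ct values are
already biological-replicate level and equal primer efficiencies; both are
conventional but unverifiable from Ct tables alone.
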