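---
title: "Models and methods behind stenoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stenoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stenoflow)
```

# The measurement problem

Aortic stenosis severity is graded from the peak velocity of the
transvalvular jet and quantities derived from it: the modified Bernoulli
pressure gradients, the velocity-time integral (VTI), and the
continuity-equation valve area. Doppler echocardiography measures only the
velocity component parallel to the acoustic beam; single-direction (1Dir)
phase-contrast CMR measures only the through-plane component. Both
underestimate the jet by a factor $\cos\theta$ when the jet axis is tilted
by $\theta$ from the measurement direction. Three-direction (3Dir)
phase-contrast encoding recovers the full vector, and the pixel-wise speed
$V = \sqrt{V_x^2 + V_y^2 + V_z^2}$ is invariant to jet orientation.

`stenoflow` implements this measurement chain end to end, driven by a
synthetic flow phantom whose ground truth is known exactly, so every stage
can be validated against an oracle and the 1Dir / 3Dir / Doppler comparison
can be exercised as a complete study without any patient data.

# The flow phantom

Each acquisition plane is a 2D+time, three-component velocity field on a
pixel grid (array order `[frame, y, x]`, `x` = column, `y` = row, `z` =
plane normal; 0-based plane indices). Defaults follow typical clinical
acquisitions: 96×96 pixels at 1.95 mm, 20 frames at 40 ms (an 800 ms
cardiac cycle). The grid origin sits on a pixel centre so a centred jet is
sampled exactly at its core, which keeps the sampled peak speed invariant
to tilt.

The anatomy is a circular lumen (aortic radius 15 mm by default) carrying:

* **Baseline flow** — a radial power-law profile
  $v(r) = v_p\,(1-(r/R)^n)$ through-plane; $n = 2$ (parabolic, the
  analytically integrable Poiseuille shape, integrated flux
  $\tfrac{v_p}{2}\pi R^2$) for aortic planes, and a blunter $n = 8$ profile
  for the LVOT plane, where real outflow-tract profiles are relatively
  flat. The default centreline speed is 50 cm/s.
* **Stenotic jets** — one or more Gaussian cores (velocity
  $s(t)\,e^{-d^2/2\sigma^2}$, $d$ = distance from the jet axis, so the
  in-plane footprint shears with tilt) directed along an axis tilted by
  `tilt_polar` from the plane normal. The through-plane contribution is
  $s(t)\cos\theta$ and the in-plane parts $s(t)\sin\theta(\cos\phi,
  \sin\phi)$, so the sampled speed at the core equals $s(t)$ at every tilt.
* **Systolic waveform** — a half-sine over the ejection window
  ($T_{sys} = 300$ ms by default), zero in diastole; a constant negative
  diastolic fraction is available as a crude regurgitation option but is
  off by default because its flow pattern is otherwise unconstrained.

Severity is drawn from conventional clinical grading bands on peak jet
velocity — none < 2, mild 2–3, moderate 3–4, severe > 4 m/s — with the jet
amplitude set so that the *total* centreline speed (jet plus baseline)
lands in the band. The jet core radius shrinks with grade (≈ 6.5–7.5 mm for
no stenosis down to 3.2–4.0 mm for severe): since the integrated Gaussian
flux is $\approx 2\pi\sigma^2 s$, this maps the effective orifice area
($\mathrm{EOA} = SV/\int v_{peak}\,dt$) onto its clinical range while
keeping stroke volumes physiologic. Jet tilt is uniform on 5–35°; the jet
decays (×1, ×1, ×0.85) and broadens (×1, ×1.1, ×1.25) across planes 0, 1, 2
above the valve, so the highest peaks occur at planes 0–1 — magnitudes
chosen as plausible, since only the phenomenon (not its size) is
established. The LVOT centreline speed is solved so the LVOT-plane
integrated flux equals the plane-0 flux: volume conservation across the
valve holds by construction, which is what makes the cine-SV and
continuity-equation valve areas mutually consistent.

`ground_truth_summary()` integrates the configured fields directly
(rectangle rule in time, matching the quantification stage) to produce the
oracle record: per-plane peak speed and stroke volume, and the effective
orifice area at the highest-peak plane.

What the phantom does **not** emulate: computational-fluid-dynamics realism
(no turbulence, no intravoxel dephasing, no post-stenotic recirculation),
3D volumetric coverage, eddy-current or Maxwell phase errors, or the true
spatial structure of patient jets — the Gaussian core is a stand-in with a
well-defined peak, not a claim of fidelity. Tests passing on the phantom
therefore validate the *processing chain*, not the biological realism of
any particular field.

# The simulated Doppler arm

Continuous-wave Doppler is modelled as the per-frame maximum over lumen
pixels and aortic planes of $|\vec v \cdot \hat b|$ for each candidate
acoustic window $\hat b$; the window with the highest envelope is kept, as
a sonographer would. The default window set is the plane normal plus rings
at 5–35° polar angle (8 azimuths each), so the best window is nearly — but
not exactly — aligned with the jet. LVOT velocities are interrogated
through-plane at the LVOT plane (pulsed-wave convention) and the valve area
follows $AVA = A_{LVOT}\cdot VTI_{LVOT}/VTI_{AV}$ with
$A_{LVOT} = \pi (D/2)^2$. The simulator is deterministic: all measurement
noise in the comparison enters through the MR encoding.

# Velocity encoding and decoding

Balanced four-point encoding uses the conventional Hadamard moment rows
$h_1 = (-1,-1,-1)$, $h_2 = (+1,+1,-1)$, $h_3 = (+1,-1,+1)$,
$h_4 = (-1,+1,+1)$ with phases
$\varphi_i = \frac{\pi}{4\,V_{enc}}(h_i \cdot \vec v) + \varphi_{bg}$.
The normalization $\alpha = 1/4$ is a deliberate choice: each *decoded*
component then wraps exactly at $\pm V_{enc}$ (the operational meaning of
Venc on a scanner) while any individual encoding phase stays unwrapped up
to $4\,V_{enc}$. The encoded images are
$m\,e^{j\varphi_i}$ plus independent complex Gaussian noise (default
$\sigma = 0.04$ of the lumen magnitude); noise is added in image space —
k-space sampling, undersampling and iterative recovery are out of scope.

Decoding forms, per direction $d$, the argument of the complex product
$\prod_i z_i^{c_{d,i}}$ with sign vectors $c_x = (-1,+1,+1,-1)$,
$c_y = (-1,+1,-1,+1)$, $c_z = (-1,-1,+1,+1)$. Working on complex products
rather than subtracting wrapped phases removes any order-of-wrapping
ambiguity, and because $\sum_i c_{d,i} = 0$, any phase common to the four
encodings — including a spatially varying background offset — cancels
identically. Consequently no background-offset correction stage exists (or
is needed) downstream. The magnitude image is the pixel-wise minimum across
the four encodings; zero-magnitude pixels decode to 0 and are counted.

Aliasing is detected by two wrap signatures: sign reversal against the 3×3
spatial median inside the blood pool while the median exceeds
$V_{enc}/2$, and frame-to-frame jumps exceeding $V_{enc}$; a direction is
flagged at ≥ 4 pixel-frames (configurable), so an isolated noise pixel
never triggers salvage. The Venc scout mimics the scanner workflow:
candidates 200/300/400 cm/s tried in order with a noise-free
encode/decode, escalating by 100 cm/s until alias-free.

# Phase unwrapping

The default salvage is temporal: each pixel's time series is re-integrated
by adding multiples of $2\,V_{enc}$ wherever the frame-to-frame jump
exceeds $V_{enc}$ (a phase jump of $\pi$), anchored on the pixel's first
low-flow frame ($|v| < V_{enc}/2$) — for pulsatile aortic flow the
diastolic frames provide trustworthy anchors and the aliased jet core is
temporally transient, which is why temporal-first was chosen over purely
spatial schemes. A spatial pass (region growing from a low-velocity seed)
and a temporal-then-spatial hybrid are available. The method is exact for
temporally smooth flows with $|v| < 2\,V_{enc}$ and true frame-to-frame
change below $V_{enc}$, and it is idempotent. A pixel that never drops
below the anchor threshold (e.g. velocity aliased in every frame) has no
trustworthy anchor: the dataset is flagged `salvage_failed` and returned
unchanged, and the subject is excluded from cohort tables with a logged
reason. Unwrapping is only attempted when aliasing is actually detected.

# Quantification

Pixels are retained when (a) their time-minimum magnitude reaches
`mag_frac` (default 0.15) of the maximum within the region of interest and
(b) their temporal-mean flow magnitude — $|v_z|$ in 1Dir mode, the speed in
3Dir mode — reaches `flow_frac`·Venc (default 0.05). The cut-offs are not
externally standardized; they are configuration keys, learned once and
applied uniformly. The flow criterion is applied to the average flow
*magnitude*; applying it to the signed average instead is the other
defensible reading of a "total phase accumulation" threshold, and the
magnitude reading was chosen because it also suppresses zero-mean
oscillating noise.

Per frame, the peak-velocity curve takes the maximum over retained pixels
($|v_z|$ or speed according to mode); the plane with the highest peak is
selected (ties to the lowest plane index, i.e. closest to the valve).
Derived quantities, in the units of the clinical literature:

* $V_{peak}$ (m/s): curve maximum. $PG = 4V_{peak}^2$ (mmHg).
* $V_{mean}$ (m/s): average of the curve over the ejection window (frames
  above 5% of the curve maximum) by default — Doppler envelopes are
  averaged over ejection — with full-cycle averaging as an option.
* $MG$ (mmHg): time-average of $4v(t)^2$ over the same window (note
  $MG \neq 4V_{mean}^2$, and $MG \le PG$ always).
* $VTI$ (cm): trapezoidal integral of the curve over the full cycle.
  Whether clinical systems integrate systole only is not standardized;
  full-cycle is the default and the window is configurable.
* $SV$ (mL): $\sum_t \sum_{roi} v_z\,A_{px}\,\Delta t$. The through-plane
  component is integrated in *both* modes, because volumetric flux through
  a plane is the normal component by definition; using the speed would
  double-count in-plane motion.
* Valve areas: $AVA_{Cine} = SV_{cine}/VTI_{AV}$,
  $AVA_{Flow} = SV_{PC}/VTI_{AV}$ (mL/cm = cm²), and the TTE-style
  continuity area when an LVOT diameter and VTI are supplied.

## A note on the ejection window and closed forms

For a densely sampled half-sine curve spanning exactly the systole, the
mean velocity has the closed form $\bar v = \tfrac{2}{\pi}V_p$ and the mean
gradient $2V_p^2\cdot 4/4 = \tfrac{1}{2}\cdot 4V_p^2$. The 5% ejection
floor, applied to such a curve, *excludes* the lowest-velocity tail frames
and therefore sits ≈ 3% above the closed form — an inherent property of
threshold-defined windows, not a numerical error. The closed-form checks in
the test suite therefore evaluate systole-only curves with the full-curve
mean (which *is* the ejection-period mean for such a curve), while the
cohort pipeline uses the thresholded window consistently for all three
methods, so the comparison between methods is unaffected. Relatedly, with
image noise the per-frame spatial maximum in diastole is a positive noise
floor that the 5% criterion can retain; this dilutes CMR $V_{mean}$ and
$MG$ relative to the noise-free Doppler simulation — planar-CMR and Doppler
averaging are genuinely different estimators, and the comparison tables
measure exactly that difference.

# Statistics

Method agreement uses Pearson correlation (Fisher-z 95% interval with
$SE = 1/\sqrt{n-3}$, two-sided $t$ p-value — computed via `cor.test`),
Bland-Altman bias ± SD with 1.96·SD limits of agreement (differences are
method − reference, so a method reading low has negative bias), and a
comparison of the two correlation coefficients. Because both CMR modes are
correlated against the *same* reference sample, the correct comparison is
Steiger's Z for dependent overlapping correlations (using the correlation
between the two CMR methods); the independent-sample Fisher z test is also
provided and the choice is recorded in the table. Normality is checked with
a one-sample KS statistic against a normal with estimated parameters; since
the parameters come from the same sample the asymptotic p-value is
conservative (the Lilliefors situation), and the result carries that caveat
rather than a Lilliefors table. The cohort table reports, per parameter,
rows for 1Dir-vs-reference and 3Dir-vs-reference; the reference is the
simulated Doppler exam for velocity-derived quantities and valve areas, and
the cine stroke volume for SV (which echocardiography does not measure).
A severity filter reproduces the moderate+severe subgroup design.

# Reproducibility and problem sizes

`run_cohort()` drives the full pipeline from a single master seed: subject
seeds and per-plane noise seeds are drawn from seeded streams, so identical
(configuration, seed) pairs give byte-identical CSV outputs. The default
cohort is 23 subjects at the clinical severity mix (3 none / 7 mild / 9
moderate / 4 severe). The test-suite and acceptance runs use reduced
phantom sizes (48–64 pixel grids, 12–16 frames) — the package's chosen
balance between discretization error and turnaround; the validated
properties (projection law, flux conservation, wrap/unwrap exactness) are
resolution-robust well below these sizes, with discretization tolerances of
1–2% stated alongside each check.

# Known limitations

* The Gaussian-jet phantom validates the processing chain, not jet
  hemodynamics; absolute biases measured on it (e.g. the Doppler-vs-CMR
  mean-gradient gap above) should not be read as clinical estimates.
* The regurgitation option is a constant diastolic backflow fraction, far
  cruder than real regurgitant jets.
* The simulated Doppler arm is noise-free and geometry-perfect except for
  window misalignment; real TTE variability (acoustic windows, reader
  variation) is absent, so cohort correlations on the phantom are much
  higher than clinical ones.
* Temporal unwrapping assumes the true frame-to-frame change stays below
  Venc; extremely fast systolic upstrokes at coarse temporal resolution can
  defeat it, which is surfaced as `salvage_failed` rather than silently
  mis-corrected.
* No k-space simulation: acceleration, undersampling artifacts and
  reconstruction-specific noise structure are outside the model.
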