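---
title: "Quantifying thiaminase I activity from 4-NTP microplate kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying thiaminase I activity from 4-NTP microplate kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ntpassay)
```

## The measurement

Thiaminase I inactivates thiamine (vitamin B1) by base exchange, replacing
its thiazole moiety with an organic nucleophile. When 4-nitrothiophenol
(4-NTP) — a yellow, favoured nucleophile co-substrate — is supplied in
excess thiamine, each catalytic event consumes one 4-NTP, so enzyme
activity can be read out colorimetrically as the loss of 411 nm absorbance
in a 96-well plate. Each sample occupies two arms of replicate wells:
*experimental* wells contain 200 µM 4-NTP plus 400 µM thiamine,
*control* wells contain 4-NTP only, so the velocity difference between the
arms isolates enzymatic 4-NTP loss from non-enzymatic decay. Wells hold
97 µl of solution plus (typically) 3 µl of sample extract or culture
supernatant, and absorbance is read every minute for an hour at a 1 cm
standardised path length.

`ntpassay` turns those raw kinetic reads into gated, unit-converted
activity estimates. The chain is:

1. **Parse** (`read_plate_timeseries()`, `read_layout()`): rectangular
   well x time OD grid plus the well-to-sample/role map and sample-prep
   parameters.
2. **Maximum velocity** (`window_slopes()`, `max_velocity()`): for each
   well, the steepest rate of OD decrease over any 10-min window.
3. **Background subtraction** (`group_velocities()`): per sample,
   mean(experimental vmax) − mean(control vmax) = net velocity.
4. **Molar conversion** (`od_rate_to_raw_activity()`): Beer–Lambert with
   ε = 13,650 M⁻¹cm⁻¹ and the 10⁻⁴ L reaction volume, giving a raw
   activity in pmol 4-NTP degraded·min⁻¹ (≡ pmol thiamine·min⁻¹ by 1:1
   stoichiometry).
5. **Detection gate** (`gate_activity()`): floor at 4.8 pmol·min⁻¹; a
   t-test band up to 25 pmol·min⁻¹; acceptance above.
6. **Specific activity** (`to_specific_activity()`): normalisation per
   gram of tissue or per ml of supernatant.
7. **Dilution-series analysis** (`analyze_dilution_series()`): linear
   range and limit of detection from a 1:1 serial dilution.

## Maximum velocity over sliding windows

For a well trace $A(t_i)$, every observed time point $t_0$ with
$t_0 + w \le t_{\max}$ opens a closed window $[t_0, t_0 + w]$
($w$ = 10 min by default; 51 windows on the standard 1-min/60-min grid,
11 readings each). The window's velocity is the ordinary least-squares
slope of OD on time over the readings in the window; the well's maximum
velocity is

$$V_{\max} = -\min_{t_0} \hat\beta(t_0) \times 1000 \quad
[\mathrm{mOD\,min^{-1}}],$$

i.e. the most negative signed slope, since 4-NTP *disappears*. Design
choices, all of which were genuinely open:

* **OLS rather than endpoint slopes.** Kinetic plate software computes
  "rates of change" without an exact published estimator. OLS over all
  readings in the window is standard for kinetic reads and has strictly
  lower variance than the two-endpoint difference; the endpoint estimator
  remains available (`method = "endpoint"`) for sensitivity checks. Both
  agree exactly on linear traces.
* **Window enumeration.** "All possible 10-min intervals" is taken
  literally as every observed time point admitting a full closed window;
  sub-minute starts have no data to distinguish them.
* **Ties break to the earliest window.** The greatest rates occur early in
  the run (substrate is most abundant); on an exactly linear trace every
  window ties and the first is reported.
* **Independent maximisation per arm.** Experimental and control wells are
  maximised over their own windows *before* averaging and subtracting —
  the literal order of the procedure. The max statistic is positively
  biased in both arms under noise; the bias is common to both arms and
  largely cancels in the subtraction (the null-calibration analysis below
  measures what remains).
* **Negative net velocities are kept** through the kinetics stage for
  diagnostics and clipped to zero only at gating, where activity is
  reported (physical activity is non-negative).

## Units and conversions

A net velocity $v$ in mOD·min⁻¹ converts to raw activity

$$a = \frac{v/1000}{\varepsilon}\, V_{\mathrm{rxn}} \times 10^{12}
\quad [\mathrm{pmol\,min^{-1}}],$$

with $\varepsilon = 13{,}650$ M⁻¹cm⁻¹ and $V_{\mathrm{rxn}} = 10^{-4}$ L.
The map is linear and exactly invertible (`raw_activity_to_od_rate()`);
the 4.8 pmol·min⁻¹ floor corresponds to 6.55 mOD lost over one 10-min
window. Specific activity divides the raw activity by the amount of
original sample actually present in the well, using 1 ml = 1 g throughout:

* tissue: $a \cdot \left[\frac{m}{m + b}\, q\right]^{-1} \cdot d / 1000$
  in nmol·min⁻¹·g⁻¹, with $m$ the tissue mass (g), $b$ the buffer volume
  (ml), $q$ the aliquot (ml, default 0.003) and $d$ the dilution factor —
  the standard 1 g + 2.5 ml prep gives the factor $(\frac{1}{3.5}\cdot
  0.003)^{-1}$;
* supernatant: $a \cdot q^{-1} \cdot d / 1000$ in nmol·min⁻¹·ml⁻¹, so the
  floor maps to 1.6 nmol·min⁻¹·ml⁻¹ at the 3 µl aliquot.

## The detection gate

Raw activities are routed by value: `negative_net` (≤ 0) and
`below_floor` (≤ 4.8 pmol·min⁻¹) report zero; `above_band`
(> 25 pmol·min⁻¹) reports the activity unconditionally; the band in
between must be substantiated by an unpaired two-sided t-test on the
per-well maximum velocities of the two arms at α = 0.05. Boundary
conventions follow the inequality directions of the assay definition:
closed at the floor (4.8 itself reports zero), closed at 25 (still
tested). The Welch (unequal-variance) variant is the default — a robust
choice at 2–4 wells per arm — with Student's pooled test available via
`gating_policy(test_variant = "student")`. A band activity whose arms
have fewer than two wells cannot be tested and is gated `untestable`
(reported zero, with a warning). If both arms are numerically constant
(noise-free data), a nonzero mean difference counts as p = 0 and a zero
difference as p = 1, since the t statistic is undefined there.

The unit of replication for the test is the well, the only replication
the procedure defines at gate time; standard errors across biological
replicate preparations are computed separately (`replicate_summary()`)
and well-level spread is reported as the `se_vmax_exp` diagnostic.

## Dilution-series analysis

A 1:1 serial dilution of a high-activity supernatant should show activity
proportional to the dilution fraction. `analyze_dilution_series()` fits
$\log_2(\text{activity})$ on $\log_2(\text{dilution})$ by OLS over the
detectable points (activity above the floor's volumetric equivalent,
1.6 nmol·min⁻¹·ml⁻¹ by default); a proportional series has slope exactly 1.
A point is *proportional* when its activity deviates from the fitted line
by at most 30% (relative). The proportionality criterion had to be chosen
here — no quantitative rule is standard — and 30% is deliberately loose:
it tolerates replicate-level scatter at deep dilutions while still
catching saturation or depletion curvature; it is a tunable argument.
Starting from 534 nmol·min⁻¹·ml⁻¹, the deepest dilution whose activity
stays above the 1.6 floor is 1/256 (534/256 ≈ 2.09; the next dilution,
534/512 ≈ 1.04, falls below), which is both the last nominal-above-floor
and, in simulated noiseless runs, the last measured-detectable dilution —
the two readings of "detection limit" coincide here.

## The synthetic-plate generator

No public plate-reader data exist for this assay, so validation rests on
a generator with known ground truth. Per well, 4-NTP concentration
follows

$$\frac{dC}{dt} = -k_{bg} C - v_{enz}, \qquad C(0) = c_0 = 200\ \mu M,
\qquad C \ge 0,$$

integrated exactly on the read grid with a hard floor at zero, and
$OD = \varepsilon \ell C + \text{baseline} + \epsilon_t$ with
$\epsilon_t \sim N(0, \sigma^2)$ i.i.d. read noise. Choices:

* **Zero-order enzymatic consumption** ($v_{enz}$, mol·L⁻¹·min⁻¹):
  thiamine at 400 µM is in large excess relative to what an hour of
  turnover consumes, and the assay itself relies on a near-linear early
  phase; the simplest model consistent with both is a constant enzymatic
  rate while substrate remains. Real traces may curve as 4-NTP thins out;
  that substrate dependence is uncharacterised and deliberately not
  modelled.
* **First-order background decay** ($k_{bg}$, min⁻¹) shared by the
  experimental and control wells of a sample — exactly the component the
  control subtraction exists to remove.
* **Noise** $\sigma$ = 2 mOD by default, a typical plate-reader read-noise
  scale, additive and i.i.d.; no drift, no inter-well optical crosstalk,
  no temperature effects.
* **Seeding**: one master seed; per-well substream seeds are drawn once
  from it, so plates are reproducible well-by-well and bit-for-bit.

A control well's parameters always equal its experimental partner's with
$v_{enz} = 0$. True raw activity is $v_{enz} V_{\mathrm{rxn}}$; e.g.
$v_{enz} = 4.84\times10^{-8}$ M·min⁻¹ is 4.84 pmol·min⁻¹ and declines at
0.66 mOD·min⁻¹ — the floor condition.

What passing tests on this generator do **not** show: robustness to
curvature in the enzymatic rate, correlated or drifting noise, pipetting
volume errors, or condensation/evaporation artefacts. They do show that
the estimator chain is correct and well-calibrated under the model the
assay's own linear-phase logic assumes.

## Validation studies and problem sizes

The test-suite and `scripts/acceptance.R` studies use these sizes, chosen
to estimate each quantity to comfortably better precision than the
tolerance being checked:

* windowed-slope oracle equivalence: 1000 random traces (12–40 reads,
  regular and irregular grids) against exhaustive enumeration with
  `stats::lm`;
* noiseless recovery: 12-sample plates spanning 6–500 pmol·min⁻¹,
  recovered to ≤ 0.5% (window OLS is exact on linear traces; the margin
  covers depletion-edge effects);
* noisy recovery: raw 2–500 pmol·min⁻¹ × 10 fixed-seed plates at 2 mOD
  noise; median absolute relative error above the test band is ~0.2%;
* gate calibration: 2000 null samples (identical arms, raw fixed at
  10 pmol·min⁻¹ inside the band), pass fraction checked against the 99%
  binomial band around α. Empirically the rate runs slightly below
  nominal (≈ 0.04), consistent with the mild conservatism of a
  two-sample t-test applied to max-of-windows statistics, whose
  distribution is right-skewed rather than normal;
* dilution linearity: 100 seeded series from 534 nmol·min⁻¹·ml⁻¹ at 2 mOD
  noise; every log2–log2 slope falls within 1 ± 0.1.

## Degenerate inputs and numerical conventions

* Time comparisons use an absolute tolerance of 10⁻⁹ min when deciding
  window membership, so binary-representation jitter cannot drop a
  boundary reading.
* Vmax ties are resolved with a relative tolerance of 10⁻⁹ before taking
  the earliest window.
* Uneven read grids are accepted at parse time; windows then hold however
  many readings fall in the closed interval (at least two, else the
  window is skipped; a run shorter than one window is an error).
* The substrate-depletion flag fires when a well loses ≥ 80% of its
  initial OD over the run; flagged samples' reported activities
  understate the truth (the window velocity caps at substrate exhaustion)
  and should be re-assayed at higher dilution. The 80% threshold is a
  pragmatic default: it triggers well before the first 10-min window
  itself is distorted on the standard grid.
* Negative OD readings (already-blanked exports) are accepted and
  counted; control subtraction removes shared offsets, so blanked and raw
  exports quantify identically.

## Known limitations

* The t-test band decision uses wells as replicates; with the 2+2 format
  the test has very little power and band activities will often gate
  `tested_fail` even when real.
* Activities large enough to exhaust 200 µM 4-NTP within the first window
  (≳ 5 nmol·min⁻¹ raw) are not recoverable at any window length — only
  the depletion flag and a dilute re-assay help.
* The generator's noise and kinetics are idealised (see above); the
  calibration numbers quoted here are statements about that model, not
  about any particular instrument.
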