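---
title: "Tracer-normalized determination of 210Po in urine: model, design choices and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracer-normalized determination of 210Po in urine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(po210assay)
```

## The measurement problem

Workers in industries that process naturally occurring radioactive
materials (NORM) — smelting, refining, phosphate and metal processing —
can inhale ²¹⁰Po, a volatile, highly radiotoxic alpha emitter of the
uranium series (half-life 138.4 d). Internal exposure is monitored by
radiochemical analysis of 24-hour urine collections: a known activity of
²⁰⁹Po tracer is added to each sample, polonium is chemically isolated and
auto-deposited on a silver disc, and the disc is counted for several days
on a silicon (PIPS) alpha spectrometer. The spectrum shows two
well-separated peaks — the ²⁰⁹Po tracer line near 4883 keV and the ²¹⁰Po
analyte line near 5304 keV — and the analyte activity follows from the
ratio of the two peak areas (isotope dilution), so that neither the
detector efficiency nor the chemical yield needs to be known for the
result itself.

Two backgrounds matter at the sub-mBq/l level this method reaches:

* **detector background** — a few counts per week in each energy window,
  measured per detector on bare discs; and
* **reagent-derived ²¹⁰Po** — the reagents themselves contribute tens of
  counts to the analyte window over a multi-day count. This is the
  dominant background and is quantified from a series of full-procedure
  blanks.

`po210assay` implements the complete calculation chain from the raw
channel/count spectra to reportable activity concentrations, detection
limits, uncertainty budgets, quality-control statistics and worker-level
summaries, together with a Poisson spectrum/campaign simulator so that
every stage can be verified against known truth.

## The calculation chain

For one analytical sample let $N_{Po}$ and $N_{tr}$ be the gross counts
in the analyte and tracer windows, $t$ the live counting time (s),
$B_{Po}$ and $B_{tr}$ the detector background count rates (1/s) in the
two windows, $A_{tr}$ the added tracer activity (Bq) and $V$ the analyzed
aliquot volume (l).

**Reagent-blank constant.** Each full-procedure blank $i$ (analyte-free
matrix plus tracer) yields

$$K_i = \frac{(N_{Po,blank_i} - B_{Po} t_{blank_i})\, A_{tr,blank_i}}
             {N_{tr,blank_i} - B_{tr} t_{blank_i}} \quad [\mathrm{Bq}],$$

and $K$ is the arithmetic mean over the series with relative standard
uncertainty $s(K_i)/(K\sqrt{n})$. $K$ is, physically, the ²¹⁰Po activity
introduced by the reagents: dividing a blank's net analyte counts by its
net tracer counts cancels the counting time, efficiency and recovery, and
multiplying by the tracer activity restores Bq.

**Blank-equivalent counts.** For an analytical sample the reagent
contribution under *its* counting conditions is

$$N' = \frac{K\,(N_{tr} - B_{tr} t)}{A_{tr}},$$

again with time, efficiency and recovery entering only through the
sample's own net tracer counts — no separate normalization is needed.

**Activity concentration.**

$$C_{lab} = \frac{(N_{Po} - N' - B_{Po} t)\, A_{tr}}
                 {(N_{tr} - B_{tr} t)\, V} \quad [\mathrm{Bq/l}].$$

**Detection limit.** The minimum detectable activity concentration is the
Currie-type quantity

$$MDC = \frac{\left(4.66\sqrt{N' + B_{Po} t} + 3\right) A_{tr}}
             {V\,(N_{tr} - B_{tr} t)},$$

i.e. 4.66 standard deviations of the blank counts plus a small-count
constant, scaled to concentration units by the tracer normalization.

**Uncertainty.** The combined relative uncertainty $u_{lab}$ is the
quadrature sum of the Poisson relative uncertainties of the analyte and
tracer peaks (gross counts over net counts), the relative uncertainty of
$K$ propagated through $N'$, and the certificate and weighing
uncertainties of the tracer addition; the expanded uncertainty is
$U_{lab} = 2\,u_{lab}\,C_{lab}$ (coverage factor $k = 2$, ~95 %
confidence).

**Tracer recovery.** As a quality-control quantity the chemical yield is
$R = N_{tr} / (t\,E\,A_{tr})$ with the detector counting efficiency $E$
measured on a certified source; it does not enter $C_{lab}$.

**Performance statistics.** Repeatability is summarized as
$CV = SD/\bar{C} \times 100\,\%$ (sample SD, $n-1$). Proficiency-test
results are scored by $z = (C_{lab}-C_{ref})/\hat\sigma$,
$\delta_x = (C_{lab}-C_{ref})/C_{ref}\times 100\,\%$ and
$E_n = (C_{lab}-C_{ref})/\sqrt{U_{lab}^2+U_{ref}^2}$, satisfactory iff
$|z|<2$, $-25\,\% < \delta_x < 50\,\%$ and $|E_n|<1$ (strict
inequalities, magnitude criteria). Worker-level reporting converts
concentrations to daily excretion $A_{day} = C\,V_{24h}$ and expresses it
relative to the group median $A_{Me}$; dietary ²¹⁰Po is deliberately not
subtracted before normalization.

## Design choices in genuinely open places

Several points of the calculation are under-determined by common practice
and had to be fixed here; each is switchable where a second convention is
defensible.

**The radical in the MDC.** A literal reading of the detection-limit
formula without the square root, $4.66\,(N'+B_{Po}t)+3$, is dimensionally
inconsistent (it scales linearly rather than as the standard deviation of
the blank counts) and yields values ~7× too high at this method's
counting conditions: with ~65 reagent-blank counts over a 6-day count it
gives ≈ 0.007 Bq/l, whereas the square-root form gives ≈ 0.0009 Bq/l, in
line with the sub-0.001 Bq/l capability this class of method is known
for. The default is therefore the Currie-style `currie_sqrt` form; the
literal `as_printed` variant is retained behind a flag for auditability,
and the package's checks document the contrast.

**The sign of the background term in $K_i$.** Adding the detector
background to a blank's analyte counts ($+B_{Po}t$) would double-count a
contribution that the concentration equation subtracts separately, and
would make $K$ overestimate the reagent activity by the background
equivalent. The default `net` mode subtracts it (clamped at zero for
under-fluctuating blanks); the `as_printed` mode with the plus sign is
preserved so both conventions can be compared. Neither is asserted to be
the historically intended one.

**ROI windows.** The method identifies the two peaks but fixes no
integration windows. The defaults span −60/+40 keV around the nominal
4883.0 keV (²⁰⁹Po) and 5304.3 keV (²¹⁰Po) lines — asymmetric to catch
low-energy tailing of deposited alpha sources — and are configurable. At
any FWHM within the 24 keV quality bound the two windows are separated by
dozens of peak widths, so cross-talk is negligible (verified to < 0.1 %
in the test suite).

**Energy-grid convention.** Channels are 0-based; a channel belongs to an
ROI when its *center* energy falls in the half-open window
$[e_{low}, e_{high})$. This makes ROI integration exactly additive under
any split of a window, which the suite asserts property-style.

**FWHM.** Reported by linear interpolation at half the modal-bin height,
without peak-shape fitting — it is used only as a stability/quality
metric, not in any activity calculation.

**Other conventions.** $K$ aggregates by arithmetic mean (median
available); a single-blank series carries a configured default relative
uncertainty of 30 %, a deliberately conservative figure reflecting the
typical blank-to-blank spread until a real series exists. Negative
concentrations are reported as-is and flagged below the MDC — clamping
would bias blank-level QC statistics. Decay correction (to collection
date, and for decay during counting, with the 138.4 d half-life) is off
by default and explicit when enabled. Recovery uses gross tracer counts
by default with a net-counts switch. The group median uses the
mean-of-middle-two convention for even $n$. The robust standard deviation
$\hat\sigma$ behind the z-score is always an external input from the
exercise organizer, never computed here. Report rounding is half-up on
the magnitude: concentrations to 4 decimals, scores to one decimal,
relative bias to one decimal below 10 % and whole percent above.

## What the simulator emulates — and what it does not

`simulationConfig()` describes a measurement campaign; its defaults are
the conditions under which the method was validated and routinely
operated, fixed once:

| parameter | default | rationale |
|---|---|---|
| `trueC` | 0.022 Bq/l | the level of the pooled repeatability sample |
| `aliquotVolume` | 0.5 l | standard aliquot of a 24-h collection |
| `liveTime` | 518 400 s (6 d) | typical multi-day count |
| `tracerActivity` | 0.0489 Bq | 0.1 g of the 0.4891 Bq/g tracer solution |
| `efficiency` | 0.25 | typical PIPS close-geometry efficiency |
| `recoveryMean`, `recoverySd` | 0.714, 0.079 | the observed long-term yield distribution, truncated to (0, 1] |
| `reagentBlankRate` | 65 counts / 6 d | center of the observed 60–70 blank counts |
| `bkgRate210Po`, `bkgRateTracer` | 3×10⁻⁶ 1/s | single counts per week per window |
| `fwhm` | 20 keV | inside the 24 keV quality bound |
| axis | 1024 channels × 6 keV | places both lines mid-spectrum |

Expected channel counts are two Gaussian peaks (tracer area
$A_{tr} t E R$; analyte area $(C V + A_{reagent}) t E R$) on a flat
continuum, sampled channel-wise as Poisson counting noise — the only
noise source that enters the calculation chain. A campaign draws one
recovery per sample/blank and either draws ROI totals directly or builds
full spectra (`spectra = TRUE`) that exercise the I/O and integration
path; one seeded stream makes each campaign reproducible.

Deliberately *not* modelled: the radiochemistry itself (digestion,
coprecipitation and deposition appear only as the scalar recovery draw),
peak tailing (a truncated-exponential low-energy tail exists behind
`tailFraction` but defaults to 0), electronic noise, drift or dead time
(live time is taken as given), and interfering alpha emitters (the
chemistry removes them in practice). Passing tests therefore demonstrate
the correctness and statistical calibration of the *calculation chain*
under ideal counting statistics — not the chemistry's robustness on real
matrices, which only laboratory validation can show.

## Numerical and verification notes

* All arithmetic is double precision; the only clamping is $K_i \ge 0$
  in net mode.
* Errors name the offending sample or line, so a campaign failure is
  traceable.
* The test suite verifies, among else: exact round-trips of the SPE and
  two-column readers/writers; calibration against a closed-form
  normal-equations solution (1e−9 relative); the analytic FWHM of a
  dense Gaussian peak; the $K \leftrightarrow N'$ round-trip identity to
  1e−9 on random blanks; efficiency invariance of $\hat C$ at $E = 0.1$
  vs $0.3$; and end-to-end unbiasedness of simulated campaigns, where
  the standard error of the campaign mean includes the $K$-estimate
  uncertainty shared by all samples.
* Problem sizes were chosen so the whole suite runs in seconds: 200
  samples and 20 blanks for the campaign-level checks (the blank count
  representing a multi-year blank series), 60 blanks for the blank-count
  level check, 80 samples for the blank-only centering check, and a
  1000-baseline/4000-evaluation history for the control-chart
  false-alarm rate.

## Known limitations

* No intake reconstruction or biokinetic modelling: `doseScreening()`
  is a labelled coefficient product for externally estimated intakes,
  not a bioassay-derived dose.
* No peak deconvolution; overlapping contaminant peaks would bias ROI
  totals undetected.
* The z-score cannot be recomputed without the organizer's robust SD.
* The repeatability CV of the six archived validation concentrations
  evaluates to 7.655 %, which one-decimal half-up rounding reports as
  7.7 %; the archived summary value is 7.6 %, consistent with truncation
  or with computation from unrounded inputs.
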