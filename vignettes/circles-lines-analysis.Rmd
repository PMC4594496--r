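---
title: "Analyzing bimanual Circles-Lines coupling in single cases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing bimanual Circles-Lines coupling in single cases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circleslines)
```

## The paradigm and what the package models

In the Circles-Lines task a subject draws continuously for 15 s blocks under
four conditions: unimanual lines with the right hand (L), unimanual circles
with the left hand (C), congruent bimanual lines (LL), and non-congruent
circles-left / lines-right (CL). In neurologically healthy people the
non-congruent condition produces *bimanual coupling*: the right hand's
nominally straight lines become oval because the circling hand's motor
program intrudes. The size of that intrusion, and whether a given patient
shows it at all, is the scientific quantity of interest; its absence with
spared execution points to impaired motor intention/planning.

Because individual patients are compared against a *small* control group
(typically n = 12), ordinary z-scores are anticonservative; the package
therefore implements the single-case inferential tests designed for exactly
this situation, and a simulator that makes the whole chain testable without
access to patient recordings.

## The synthetic trajectory generator

One hand's drawing is modeled as harmonic motion in device coordinates
(x lateral, y vertical, millimetres):

* line: $y(t) = A \sin(2\pi f t + \phi)$,
  $x(t) = \alpha A \cos(2\pi f t + \phi)$,
* circle: $x(t) = A\cos(2\pi f t + \phi)$, $y(t) = A\sin(2\pi f t + \phi)$,

with amplitude $A$ (default 50 mm), drawing frequency $f$ (default 1 Hz),
ovalization ratio $\alpha \in [0,1]$ (0 = perfectly straight), isotropic
Gaussian jitter (SD in mm), and a default sampling rate of 100 Hz (a typical
digitizing-tablet rate; at least 20 Hz is enforced so that cycle
segmentation remains well-posed). The session layout follows the paradigm:
30 s initial rest, 24 experimental blocks of 15 s (six per condition)
alternating with 15 s rests, 30 s final rest — 765 s in total. The block
order is a seeded shuffle constrained to at most three consecutive identical
conditions, the package's reading of "pseudo-random" block presentation.

Coupling is modeled mechanistically as additive lateral contamination: in CL
blocks the right hand's x receives `coupling` times the left hand's
noiseless circular x-component, in phase with its own stroke cycle. A
noiseless session with line $\alpha = 0$ therefore shows a right-hand
OI(CL) − OI(LL) difference of exactly $100 \times$ `coupling`, which is the
invariant the test suite recovers over seed sweeps. The two hands drift
apart in the pathology this paradigm probes — non-congruent drawing can
become asynchronous — and the generator exposes a per-stroke starting phase
through which such a lag can be imposed, but no default asynchrony is
modeled because no quantitative value is available to anchor it.

Normative cohorts are drawn from a bivariate normal with the requested
per-task means, SDs and inter-task correlation; only mean ± SD and r are
ever reported for such samples, so a Gaussian model is the natural minimal
choice. The generator returns both the scores and the *realized* sample
summary, which is what the single-case tests should consume.

## The Ovalization Index

For each complete drawing cycle the index is

$$OI_{cycle} = 100\,\frac{\mathrm{sd}(x - \bar x)}{h/\sqrt 2},$$

with $h$ the cycle's vertical semi-extent (half the y-range) and sd the
population (n-denominator) standard deviation over the cycle's samples.
This is the unique affine-invariant normalization that makes the task's
stated anchors exact: over one uniformly sampled period a circle of radius
$r$ has $\mathrm{sd}(x) = r/\sqrt 2$ and $h = r$, scoring 100; a straight
vertical stroke scores 0; an ellipse with lateral/vertical semi-axis ratio
$a/b$ scores $100\,a/b$. The "vertical" reference is the device frame's
y-axis, not a per-stroke regression line — the deviation measured is from an
*absolute* vertical. The block-level score is the mean over the block's
cycles (robust to slow drift across strokes, and matching per-movement
aggregation), clipped to [0, 100] since jitter can push sd(x) above the
circular bound; the condition-level score is the mean over the condition's
six blocks.

Numerical conventions, all tested:

* **Smoothing.** Both coordinates are smoothed with a centered moving
  average over 0.1 s before anything else. The filter attenuates the lateral
  and vertical harmonics of the drawing frequency by the same factor, so the
  index of a clean stroke is untouched (anchors remain exact to ~1e-13)
  while high-frequency jitter — which otherwise inflates sd(x) in nearly
  straight strokes and biases the coupling effect low — is suppressed by
  roughly the square root of the window length.
* **Cycle segmentation.** Cycles are the half-open intervals
  $[\mathrm{max}_i, \mathrm{max}_{i+1})$ between successive maxima of the
  smoothed vertical signal; only complete cycles count. Maxima must have
  topographic prominence of at least 5% of the block's vertical range
  (the rise above the key saddles toward higher terrain), which discards
  jitter extrema without dropping genuine peaks; on a plateau the first
  sample is the extremum.
* **Degenerate input.** A trajectory with no complete cycle raises a
  no-cycle error; a cycle with zero vertical extent is skipped with a
  warning, and an error is raised only if every cycle is degenerate.

Drawing frequency is the number of complete cycles divided by the time they
span — identically the inverse mean cycle duration, an identity the suite
checks to 1e-9.

## Single-case tests

All tests refer their statistic to Student's *t* with $n - 1$ degrees of
freedom and report two-tailed probabilities; no multiple-testing correction
is applied anywhere, matching standard practice for these designs.

* **RSDT** (`rsdt`). The case's scores are standardized against the control
  means and SDs, $z_x, z_y$, and the statistic is the positive root of the
  small-sample-corrected quadratic
  $a\psi^4 + b\psi^2 + c = 0$ with
  $a = (1+r)(1-r^2)$,
  $b = (1-r)\left[4(n-1)^2 + 4(1+r)(n-1) + (1+r)(5+r)\right]$,
  $c = -2(z_x - z_y)^2\,\frac{n(n-1)^2}{n+1}$,
  signed by $z_x - z_y$. For large $n$ it converges to
  $(z_x - z_y)/\sqrt{2-2r}$, and its defining property — an empirical
  type-I error near the nominal 5% even at n = 12 — is verified by Monte
  Carlo in the suite (2000 null replicates, r = 0.8).
* **UDT** (`udt`), for tasks sharing a scale:
  $t = \left[(x - y) - (\bar X - \bar Y)\right] /
  \left[s_{x-y}\sqrt{1 + 1/n}\right]$ with
  $s_{x-y} = \sqrt{s_x^2 + s_y^2 - 2 r s_x s_y}$. Its closed form doubles as
  an independent cross-check on the standardized machinery.
* **Two-case comparison** (`case_comparison`):
  $z = (d_1 - d_2)/(s\sqrt 2)$, where $s$ is the control SD of the score
  being compared. This form reproduces all three independently reported
  statistic/p pairs available for it (−2.4/0.03, |2.24|/0.05, |1.19|/0.26),
  which fixes both the formula and the $n-1$ degrees of freedom; the sign is
  reported as case 1 minus case 2.
* **Deficit test** (`deficit_test`):
  $t = (x - \bar X)/(s\sqrt{1+1/n})$, the single-score case-versus-controls
  test, provided for cohort screening.

Validation against reported worked examples uses ±0.2 on RSDT statistics
and ±0.05 on comparisons, because the published inputs are rounded to 1–2
decimals. A handful of published statistics are *not* recoverable from the
rounded summaries that accompany them (the MN− behavioral RSDT, the pre-SMA
statistics, the frequency comparison); the fixtures carry these verbatim in
`annotations` fields with discrepancy notes, and nothing in the package
recomputes against them. Likewise the published MN− CL−LL difference (24.4)
differs from the difference of the rounded condition means (24.5): the
original evidently used unrounded means, so the printed 24.4 is shipped as
an annotation and used as the comparison input.

## The pipeline

`run_behavioral_analysis()` takes two cases' condition scores plus the
normative summary and emits one row per test (RSDT per case; two-case
comparison on the CL−LL differences, and on drawing frequency when
frequency norms are supplied). The SD of the CL−LL difference is taken from
the summary ($s_{x-y}$ above) unless the realized sample value is supplied
directly — the shipped fixture carries the reported 6.8, which is the
realized value rather than the summary-implied 7.26. `run_roi_analysis()`
applies the identical statistics to per-condition activation estimates
(beta values) for the three regions of interest (pre-SMA, left PPC, right
PPC); beta extraction itself is upstream image analysis and out of scope —
the betas are consumed as tabular data. `end_to_end()` chains simulation,
metrics and both analyses into a report directory (TSV tables, run log with
seed, parameters and package version); every number written is formatted
deterministically, so a rerun under the same seed is byte-identical. Report
rows carry an 8-character digest of their numeric inputs, and skipped
blocks are logged with reasons rather than silently dropped.

## What the simulations do and do not show

The generator emulates the paradigm's block structure, harmonic drawing
kinematics, controllable coupling and sensor jitter. It does not emulate
slow positional drift, fatigue, tremor spectra, velocity asymmetries of
real pen strokes, tablet quantization, or pathological temporal
(phase-locking) abnormalities. Passing the suite therefore demonstrates
that the metrics recover constructed ground truth and that the statistics
have their nominal operating characteristics — not that the OI is optimal
for any particular patient population.

Problem sizes used by the test suite, chosen to exercise each property at
desk scale: full 765 s sessions at 100 Hz for structural and recovery
checks (20-seed sweeps for coupling recovery); 2000 Monte-Carlo replicates
for the RSDT type-I calibration; cohorts of n = 10^4 for the
law-of-large-numbers check on the cohort generator; 100 seeded runs for the
power property of the simulated design (controls drawn from the cohort
generator with the CL target raised by the coupling effect, the patient
simulated as a full uncoupled session).

## Known limitations

* The OI's noise robustness comes from a fixed 0.1 s smoothing window; for
  drawing frequencies above ~3 Hz the window removes a noticeable fraction
  of the signal itself (it cancels from the index only while both
  coordinates keep the same dominant frequency).
* The RSDT assumes bivariate-normal control scores; with n = 12 controls
  there is little power to detect violations.
* The two-case comparison treats each case's score as fixed (measurement
  error within a case is not propagated).
* One published pairing (right PPC, T = 1.4 with p = 0.019 described as
  non-significant) is internally inconsistent (p ≈ 0.19 at df = 11); it is
  flagged in the fixture annotations and left unresolved.
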