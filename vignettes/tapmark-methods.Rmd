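---
title: "Quantifying mild motor impairment in RBD: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mild motor impairment in RBD: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapmark)
```

## The problem

REM sleep behavior disorder (RBD) is a strong prodromal marker of the
synucleinopathies. A fraction of RBD patients already show *mild motor
impairment* (MMI) — subtle bradykinesia that escapes a standard motor
exam.  `tapmark` implements a quantitative pipeline around a thumb–index
finger-tapping task recorded with a distance sensor: each subject taps as
widely and rapidly as possible for 15 s per hand, and the per-cycle
kinematics define an objective MMI criterion.  Two companion modalities
characterize the flagged patients: striatal dopamine-transporter SPECT
(specific binding ratios and left–right asymmetry) and ROI-to-ROI
resting-state functional connectivity of the sensorimotor network.

Because no subject-level data are distributable, the package ships a
synthetic cohort generator that emulates the joint structure of all
modalities.  Every downstream stage is exercised and tested against that
generator; the generator itself is first-class, tested code.

## Tapping kinematics

**Model of the waveform.** The generator produces a train of
raised-cosine half-cycles: cycle $k$ has excursion
$A_k = A + s\,(k-1)$ (clipped below at 1 mm) above a constant baseline,
and the opening/closing half-cycle durations are chosen so that the peak
opening and closing speeds hit closed-form targets.  With symmetric
cycles and no decrement the waveform is a pure raised cosine with peak
speed $A \pi f$ and period $1/f$ — which is what makes closed-form
oracles possible (a 60 mm, 3 Hz train must yield 45 cycles in 15 s,
amplitude 60 mm and peak speeds $0.06\pi\cdot3 = 0.5655$ m/s).  The
raised-cosine family is a modeling choice: the source task only fixes
the task parameters (15 s, as wide and fast as possible) and the
measured quantities, not the waveform morphology.

**Measurement.** `preprocess_waveform()` low-passes the distance trace
with a 4th-order zero-phase Butterworth filter (default cutoff 20 Hz,
comfortably above the 2–4 Hz tapping band and its first harmonics) and
differentiates by central differences.  Zero-phase filtering is applied
with odd-reflection end padding; without it, forward–backward recursive
filtering leaves edge transients large enough to corrupt the first and
last cycle.  `segment_cycles()` detects closing minima with two
deterministic rules: prominence at least 20 % of the global excursion
(scale-adaptive, so a 10 mm bradykinetic train is segmented as reliably
as a 60 mm one) and minimum separation 100 ms (deeper valley wins, ties
to the earlier sample).  The first/last samples are accepted as boundary
valleys when they sit at valley level so complete boundary cycles are
not lost.  Retention drops cycles shorter than 100 ms or with excursion
below 5 mm (sensor jitter); retention can only remove cycles, never
create them.

**Per-cycle parameters.** Amplitude is the in-cycle maximum minus the
mean of the two bounding valley values — robust to baseline drift; the
alternative (in-cycle minimum) is not used, and this convention is a
documented package choice.  Peak open speed is the largest positive
speed between the opening valley and the in-cycle maximum; peak close
speed the largest magnitude between maximum and closing valley; both in
m/s.  Summaries are arithmetic means over retained cycles plus
per-parameter decrement slopes (OLS of value on cycle index, requiring
at least 3 cycles).

## The MMI classifier

The normative model is fitted on healthy controls only: per parameter
(amplitude, open speed, close speed) and per side, the mean and sample
SD ($n-1$ denominator, documented so cutoffs are reproducible), with
cutoffs at mean $-\,2$ SD.  Sides are fitted separately to respect hand
dominance.  A subject is MMI when **at least one of the six parameters
is strictly below its cutoff** — "less than" is read literally, so a
value exactly at the cutoff is not flagged.  Progressive decrement is
the analogous rule on the slopes (slopes are negative; "less than" means
more steeply negative).  The two criteria are independent: a subject can
be flagged on either alone.

Under the null (patients drawn from the HC distribution, independent
Gaussian parameters, population-true cutoffs) the expected flag rate is
$1-(1-\Phi(-2))^6 = 12.90\,\%$; the suite verifies this analytically
derived specificity by simulation at $n = 10^5$.  Real parameters are
correlated across sides and parameters, which makes the realized false
positive rate lower than the independent-parameter bound.

## SPECT quantification

Uptake is the specific binding ratio
$\mathrm{SBR} = (C_\text{striatal} - C_\text{cereb})/C_\text{cereb}$
per striatal VOI (caudate, anterior putamen, posterior putamen, each
side) with the cerebellum as reference, and asymmetry
$\mathrm{AI} = |R-L|/(R+L)$ per region.  AI is computed on SBR values
(not raw counts), since asymmetry is reported alongside uptake; SBR
values driven negative by noise are clipped to zero with a warning
before AI, which keeps AI in $[0,1]$.  Percent differences versus HC use
group arithmetic means: $100\,(\bar x_{HC}-\bar x_g)/\bar x_{HC}$.
Group comparisons are one-way ANOVAs with Tukey–Kramer post-hoc tests.
The generator's default group means encode the graded reduction
(posterior putamen > anterior putamen > caudate, right-dominant in the
MMI group); between-subject SBR SD defaults to 0.35, a realistic spread
for cerebellum-referenced striatal uptake in older adults.

## Functional connectivity

Per subject: ROI time series (default 30 sensorimotor labels, 180
volumes at TR 2.5 s) are band-passed to 0.008–0.09 Hz with a 2nd-order
zero-phase Butterworth filter, pairwise Pearson-correlated, and Fisher
z-transformed ($z = \operatorname{atanh} r$, capped at
$\operatorname{atanh}(1-10^{-7})$ so degenerate perfect correlations
stay finite and visible).  Group inference fits, per ROI pair and per
pairwise contrast, a linear model of $z$ on a group indicator plus
centered age and sex (M = 0, F = 1), restricted to the two groups
compared — this mirrors the two-group rows of the published contrast
tables; a single three-group model is a possible alternative but is not
the default.  Benjamini–Hochberg FDR is applied across all 435 unique
pairs within each contrast ("analysis" scope, the stricter default); a
per-seed scope (adjusting within each seed ROI's family) is exposed as
an option because connectivity toolboxes offer both and the choice is
rarely reported.

Sampling theory anchors the tests: for $T$ volumes the null SD of $z$
is $1/\sqrt{T-3}$ (0.0752 at $T=180$), and for a true $r=0.5$ the mean
$z$ is $\operatorname{atanh}(0.5)=0.5493$.  Under the global null the
mean false-discovery proportion of BH at $q=0.05$ is 0.05 under
independence and below it under the positive dependence induced by
shared subjects — the suite checks the empirical mean FDP stays
controlled.

## Group statistics and report

Continuous variables: one-way ANOVA with Tukey–Kramer post-hoc tests
(`stats::aov` + `TukeyHSD`, exact for unequal group sizes).
Polysomnographic measures and disease duration: pooled-variance
two-sample t (Student's form, since no unequal-variance qualification
is made; Welch is an option).  Discrete variables: Pearson chi-square
without continuity correction (correction exposed as an option).
Correlations: Pearson $r$ with the $t$-approximation
$t = r\sqrt{(n-2)/(1-r^2)}$; partial correlations residualize both
variables on an intercept + covariates and test with
$df = n - 2 - k$.  A variable fully explained by the covariates yields
a null partial correlation ($r=0$, $p=1$) rather than a 0/0 artifact.
Tapping–uptake correlations pair each hand with the contralateral
striatum.  No correction is applied across the correlation tables,
matching the per-test two-tailed 0.05 threshold convention; the report
documents this as a caveat.

## Synthetic cohort: what it does and does not emulate

Defaults are fixed at the emulated study conditions: 20 HC / 15 RBD-N /
8 RBD-MMI; 15-s waveforms at 200 Hz (the sensor's rate is not public;
200 Hz is comfortably above the tapping harmonics); tap frequency
$\mathcal N(3.2, 0.35)$ Hz; HC amplitudes 60/55 mm (R/L) with 9 mm
between-subject SD and MMI amplitudes 38/35 mm; decrement-slope
distributions per parameter and side taken from the healthy-control
statistics (amplitude $-0.17\pm0.28$ R, $-0.31\pm0.32$ L; open speed
$-0.009\pm0.007$, $-0.013\pm0.006$; close speed $-0.012\pm0.008$,
$-0.016\pm0.009$), identical across groups so decrement is not a group
effect; clinical scores, polysomnographic measures and head motion as
truncated normals around the group summary statistics, with motor-exam
items drawn as small integers matching the group means; connectivity
effects of $\Delta r = 0.3$ on the cortico-striatal (reduced in RBD)
and cerebello-cortical (elevated in MMI) pairs.

The cohort generator subtracts the amplitude-slope-induced component
from the configured speed-slope targets, so the speed-slope
distributions recovered by the kinematics stage match the configuration
(round-trip property).

Not emulated: voxel-level images, hemodynamics, scanner noise spectra,
physiological confounds, head-motion artifacts in the time series, or
REM-sleep physiology.  Passing tests therefore demonstrate that the
*measurement and inference machinery* is correct under a known
generative model — not that the pipeline is robust to every artifact of
real recordings.

## Numerical choices and limitations

* Zero-phase filtering uses odd-reflection padding (200 samples or the
  series length, whichever is smaller).
* Valley detection is fully deterministic; ties broken by earliest
  sample.
* Fisher z capped at $\operatorname{atanh}(1-10^{-7})$; zero-variance
  ROI columns produce `NA` pairs with a warning; zero residual variance
  marks a pair missing rather than producing infinite T.
* Randomness flows through one seeded interface: a master seed fans out
  to fixed per-stage, per-subject child seeds, so stages can be toggled
  without perturbing the others and identical configurations are
  byte-identical on disk.
* Problem sizes used by the test-suite simulations (e.g. 300–500
  replicates for FDR properties, $10^5$ subjects for classifier
  specificity, 1000 replicates for Fisher-z theory) were chosen to keep
  Monte-Carlo error well inside the asserted tolerances while the whole
  suite runs in minutes.
* The classifier reports exact counts, not percentages: with 8 MMI
  among 23 patients the published rounding of the rate is ambiguous
  (36 % vs 34.8 %), and counts are the unambiguous quantity.
* `summarize_uptake()` takes region labels at face value; the
  anterior/posterior putamen split happens upstream of this package and
  any labeling convention issues must be resolved there.
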