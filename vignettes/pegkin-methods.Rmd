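---
title: "Quantifying pegboard fine-motor decline in Parkinsonism: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pegboard fine-motor decline in Parkinsonism: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pegkin)
```

## The problem

The Purdue Pegboard Test (PPT) is a timed manual-dexterity test: the score
is the number of pegs placed in 30 s (dominant hand, non-dominant hand, or
both hands simultaneously) or the number of assemblies completed in 60 s.
It is objective, cheap, and reliable, which makes it attractive as a
progression marker for Parkinson's disease (PD) and the atypical
parkinsonian syndromes (progressive supranuclear palsy, PSP; multiple
system atrophy, MSA), where the standard motor-examination instrument
(MDS-UPDRS-III) is subjective and imaging markers are expensive.

`pegkin` implements the full analysis chain such a study needs:

1. **kinematics** — condition triaxial accelerometer recordings captured
   while a subject performs the pegboard, and extract two features per
   sensor: the *standard deviation of acceleration* (movement vigor) and
   *approximate entropy* (movement irregularity);
2. **longitudinal statistics** — one-year change scores, mixed-design
   ANCOVAs, FDR-corrected post hoc families, and correlations between
   motor-scale worsening and pegboard decline;
3. **prediction** — backward-elimination linear regression of follow-up
   pegboard score on baseline imaging and demographic candidates;
4. **synthetic data** — generators for all three kinds of input, with
   planted effects whose recovery is the package's main test surface,
   because the patient-level data such analyses run on cannot ship with a
   package.

## Signal model of the synthetic accelerometer trials

Pegboard motion is quasi-periodic: reach, grasp, transport, insert, repeat.
The generator models each axis of a trial as

\[
a(t) \;=\; \sqrt{1-\lambda}\, A \sum_h w_h \sin\!\big(h\,[2\pi f t +
\phi_0 + \theta_{c(t)}]\big) \;+\; \varepsilon(t) \;+\; \text{spikes},
\]

where \(f\) is the movement rate (default 1.5 cycles/s), \(w_h\) are
normalized harmonic weights (default fundamental plus two decaying
harmonics), \(\theta_{c}\) is a per-cycle phase jitter, and
\(\varepsilon\) is broadband noise band-limited to the 1-50 Hz analysis
band. The single dial \(\lambda \in [0,1]\) ("irregularity") sets the
fraction of signal variance carried by the noise, and also scales the
jitter SD (\(0.6\lambda\) rad).

Two design properties matter:

* the total movement-band variance is fixed by the amplitude \(A\): the SD
  of acceleration is \(A/\sqrt2\) **regardless of irregularity**, and
* approximate entropy rises monotonically with \(\lambda\), saturating
  near the pure-noise entropy above \(\lambda \approx 0.6\).

So the two kinematic features are independently dialable, which is what
makes planted-effect recovery a meaningful test. The noise is band-limited
*at generation* so that the analysis band-pass does not bleed planted
variance out of the signal. Spike artifacts are isolated samples of
\(\pm m \times\) the clean-signal SD; the generator realizes exactly
`round(rate x duration)` of them at uniform times at least 3 samples
apart and records their indices, giving despiking tests exact ground
truth. This model makes no claim of biomechanical realism (no
reach-vs-grasp substructure, no device noise model); what passing tests
show is that the *pipeline* recovers effects of the planted kind, not that
the waveforms resemble any particular patient.

## Conditioning pipeline

The pipeline order is fixed: spike removal, band-pass filtering, optional
decimation, features.

**Spike removal** is a Hampel running-median filter: within a centred
window (default 11 samples) a sample deviating from the window median by
more than `threshold` (default 5) times \(1.4826 \times\) MAD is replaced
by that median. One sweep is not idempotent - removing a spike can unmask
a neighbour that the spike's inflated MAD had shielded - so the filter
iterates to a fixed point (convergence is fast because spikes are
isolated). Edge samples without a full window are left untouched.

**Filtering** is a 4th-order Butterworth band-pass, 1-50 Hz, applied
forward and backward (zero net phase; the magnitude response is squared).
Edge transients are controlled by odd-reflection padding of length
\(10 f_s / f_{low}\): the 1 Hz corner's settling transient needs roughly
ten low-corner periods to decay below \(10^{-6}\), which the package
verifies against DC input. Two numerical notes: (a) at 2000 Hz sampling
the normalized low corner is 0.001 of Nyquist, near the conditioning limit
of a direct-form IIR in double precision - linearity holds to about
\(10^{-7}\) relative there, and to \(10^{-10}\) at 200 Hz, which is where
the linearity contract is asserted; (b) the dual pass squares the
magnitude response, so the stopband check at 200 Hz is against
\(|H|^2 \approx 1.5\times10^{-5}\) for the single pass.

**Decimation** is integer-factor subsampling, allowed only when the new
Nyquist frequency still clears the filter's upper corner
(default target 200 Hz after the 50 Hz low-pass), so no separate
anti-alias stage is needed. Its purpose is to make the \(O(N^2)\) entropy
computation tractable on long records (a 30 s trial at 2000 Hz is 60,000
samples; at 200 Hz it is 6,000). The factor is recorded in provenance.

## Kinematic features

The **SD of acceleration** is the sample standard deviation (denominator
\(N-1\); at the record lengths involved the distinction from \(N\) is
below 0.01%).

**Approximate entropy** is the classical Pincus statistic
\(\mathrm{ApEn}(m, r, N) = \Phi_m(r) - \Phi_{m+1}(r)\), with self-matches
included and Chebyshev template distance - the de facto standard for
physiological series, as opposed to the sample-entropy variant which
excludes self-matches. Parameters default to \(m = 2\) and
\(r = 0.2 \times\) series SD; both are configurable and stamped into
provenance, since published pegboard work does not print them. The kernel
is compiled (Rcpp) and is tested for exact agreement with a naive
double-loop counting oracle. A zero-variance series returns 0 by
convention (every template matches every other).

Per-axis values are averaged across x, y, z to one value per sensor per
task, matching field practice for wrist/forearm/head sensor arrays
(labels NDH, NDB, DH, DB, HD: non-dominant hand and brachioradialis,
dominant hand and brachioradialis, head).

## Cohort statistics

**Change scores** are `visit2 - visit1` per subject per task; subjects
missing a visit are excluded listwise within the analysis and the
exclusion is logged, mirroring how published cohorts handle missing
clinical scales.

**ANOVA/ANCOVA** use Type III sums of squares with sum-to-zero factor
coding and centred covariates, computed by explicit block model
comparison (drop a term's columns, compare residual sums of squares).
For designs with one between factor and no factor interactions among
regressors this reproduces the conventional Type III table exactly; the
implementation is cross-checked in the tests against `car::Anova` and,
for the mixed design, against `stats::aov`'s error-stratum decomposition.
The mixed-design ANCOVA uses the orthonormal-contrast decomposition: the
between-subject stratum is an ANCOVA on subject means; the within main
effect and the within-by-between interaction come from contrast scores
pooled across the \(k-1\) orthonormal polynomial contrasts, with
covariates entering both strata as between-subject regressors. With more
than two within levels the package estimates the Greenhouse-Geisser
epsilon from the contrast-residual covariance, runs a Mauchly sphericity
test, and reports corrected p-values alongside uncorrected ones.

Whether published change-score ANOVAs carried the same covariates as the
longitudinal models is ambiguous in this literature; `pegkin` exposes the
covariate set as an argument (`oneway_anova(..., covariates =)`) and the
pipeline includes them by default, toggleable in the run configuration.

**Post hoc families** are explicit objects: p-values are
Benjamini-Hochberg adjusted *within the declared family only* - the five
sensors of one task, or the group pairs of one task's change scores -
never pooled across tasks. Benjamini-Yekutieli is available as an option.
Sensor-level group comparisons default to Welch's t; the pooled-variance
Student t is an option (at the group sizes typical here the two are
nearly identical).

**Correlations** between motor-scale change and pegboard change use
Spearman's rank-order coefficient (the motor-scale change is not
normal); accelerometry-pegboard associations use Pearson. The cohort
generator plants the Spearman target through a Gaussian copula
(\(\rho_{pearson} = 2\sin(\pi\rho_s/6)\)), so the rank correlation is
invariant to the marginal scales chosen for the two change scores.

## Backward-elimination regression

Starting from 40 candidates (age, sex, disease duration, cognition, and
free-water FW / tissue fractional anisotropy FAt for 13 gray-matter
regions and 5 white-matter tracts), the least significant term is removed
until all remaining terms have \(p < 0.05\). Design choices:

* demographics are eliminable like any other candidate (published final
  models retain sex and cognition but not age, so nothing was protected);
* ties on the maximum p are broken by smaller \(|t|\), then column name,
  making the trace deterministic;
* exactly collinear columns are resolved before elimination by dropping
  one member of each aliased set (deterministic via the pivoted QR),
  logged in the trace;
* the final model is a fixed point: re-running elimination on the
  retained set removes nothing (tested).

Standardized betas are computed on z-scored outcome and predictors;
adjusted \(R^2 = 1 - (1-R^2)(n-1)/(n-k-1)\). The synthetic default
(`predictor_design()`) uses \(n = 151\) so a seven-term final model has
143 residual degrees of freedom, a planted basal-ganglia-dominated
support, and noise chosen so the planted \(R^2\) is near 0.24 - a
structural, illustrative reproduction only: actual published coefficients
derive from patient imaging data that a synthetic design cannot and does
not target.

## Synthetic cohort defaults

Group sizes (PD 164, PSP 39, MSA 23, HC 53), visit-1 score distributions,
one-year declines per task, demographics, and clinical scales are set to
published magnitudes for multisite parkinsonism pegboard cohorts: e.g.
both-hands decline of \(-1.27 \pm 3.53\) pegs/year in PD against
\(+0.89 \pm 3.63\) in controls. Quantities no study prints are explicit
assumptions: the motor-scale change SD is derived from the two visit SDs
under an assumed test-retest correlation of 0.7; cognition change SD is 2
points; sites are sampled uniformly. Scores are clamped at zero (they are
counts), which slightly biases change means upward in the
lowest-scoring groups; tests that assert exact null behaviour therefore
use designs whose scores stay far from the clamp. Scores are continuous
by default; an integer-rounding option exists and warns that planted
correlations become approximate under discreteness.

The accelerometry study simulator (`simulate_accel_features()`) draws
each subject's per-sensor amplitude from the `accel_sd_reference()` grid
(PD/HC SD-of-acceleration ratio near 0.6 on task-engaged sensors) and
raises irregularity from 0.10 to 0.40 (subject SD 0.06) in the PD group
on the `task_relevant_sensors()` of the simulated task. Those
irregularity values were chosen once, as a clearly parkinsonian
regularity contrast; they are the study condition, not a tuning knob.

## Problem sizes and numerical choices

Simulated power and calibration studies use sizes chosen to make the
suites precise yet quick to re-run: accelerometry power runs use 4 s
trials at 200 Hz (the feature contrast between groups is carried by
between-subject amplitude/irregularity spread, not record length, so
shorter records mainly widen within-group noise slightly); calibration
suites use 1,000 null replicates, bounding the type-I error estimate's
binomial SE at 0.7 percentage points; recovery suites use 100 replicates.
Full-length 30 s / 2000 Hz records are used where the contract under test
is about the record itself (filter gains, DC suppression, despiking at
realistic density).

Other numerical conventions: tolerance ties in elimination are resolved
at \(10^{-12}\); the Hampel iteration caps at 20 sweeps; ApEn on a
constant series short-circuits to 0; the spectrum is computed on demeaned
series and normalized so its one-sided sum equals \(N\times\) the
population variance.

## Known limitations

* The signal model is phenomenological; it supports property-based
  validation, not waveform-level realism, and device-specific noise is
  out of scope.
* The mixed ANCOVA assumes complete within-factor cells per subject
  (incomplete subjects are dropped and logged), Gaussian residuals, and
  covariates constant within subject.
* Published regression coefficients for patient imaging data are not
  reproducible from synthetic designs and are treated as structural
  anchors only.
* The cohort generator draws Gaussian marginals around published means
  and SDs; no study publishes subject-level distributions, so normality
  here is an assumption, flagged rather than asserted as fact.
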