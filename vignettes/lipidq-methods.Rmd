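---
title: "Quantification and QC for targeted serum lipidomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification and QC for targeted serum lipidomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`lipidq` post-processes integrated peak areas from a targeted (MRM)
serum-lipidomics batch into QC-filtered lipid concentrations and group
statistics. This vignette explains the model behind each stage, the tunable
parameters and their defaults, what the synthetic batch generator does and
does not emulate, and the numerical and design choices that were genuinely
open.

## The measurement model

One batch consists of injections of four kinds: study samples (`SPL`),
pooled batch QCs (`BQC`, equal-volume pool of all study sera, injected at
fixed run-order intervals), a response-QC dilution ladder (`RQC`, serial
dilutions of pooled extract), and process blanks (`PBLK`, extraction
without serum). Every injection yields one integrated peak area per
monitored species. The area of species $i$ in injection $s$ is modelled as

$$A_{si} \;=\; c_{si}\, R_{k(i)}\, 2^{d_i(t_s)}\, \varepsilon_{si}
\;+\; \text{(isotopologue cross-talk)},$$

where $c_{si}$ is the true concentration, $R_{k(i)}$ a class response
factor, $d_i(t)$ a smooth instrument drift in log2 units over run order
$t$, and $\varepsilon$ multiplicative (log-normal) analytical noise. Each
lipid class carries one internal standard (ISTD) spiked at a known amount
per sample, which is subject to the same response factor and drift family.

Processing inverts this model stage by stage; stages only move forward:
`raw -> isotope_corrected -> drift_corrected -> normalized ->
concentration`.

### Isotopic co-integration correction

At unit mass resolution, a lipid with one more double bond elutes nearby
and its two-heavy-isotope (M+2) peak is co-integrated with the
monoisotopic peak of its saturated neighbour. With $n$ carbons and
natural ${}^{13}$C abundance $p = 0.0107$, isotopologue counts are
binomial, so the inflation fraction is

$$p_{M2} = \binom{n}{2}\Big(\frac{p}{1-p}\Big)^2 ,$$

carbon-only (H/O/N heavy isotopes contribute negligibly at M+2). The
correction subtracts $p_{M2}(\text{interferer}) \times
\text{corrected(interferer)}$ from each declared target, processing each
within-class chain from its most unsaturated member down, and clamps at
zero. Interference is declared in the panel (same class, one more double
bond, same intact-molecule carbon count), never inferred from masses. The
analogous M+1 factor $n\,p/(1-p)$ is provided for panels that declare
1-Da overlaps.

### BQC-anchored drift correction

BQCs are replicates of one material, so their areas trace $d_i(t)$
directly. Per species, a loess curve (span 0.75, degree 1, tricube
weights) is fitted to log2 BQC areas over run order; at least 4
non-missing BQC points are required, otherwise the species keeps its
uncorrected values. Prediction inside the BQC range evaluates the loess
surface; beyond the first/last BQC the curve continues linearly with the
boundary slope. The fitted shape is subtracted from every injection and
the values are recentred so that the median BQC level is preserved
exactly — the correction removes the drift's shape, not the signal level,
keeping raw-area thresholds meaningful downstream.

The correction is kept per species only if it reduces the linear-scale CV
of the study samples by more than 2 percentage points (strict
inequality); otherwise the species reverts. The rule is read in
percentage points rather than relative percent, the common convention
when CVs are themselves reported in percent, and is configurable
(`cv_gain_percent`). Two subtleties are worth noting:

* With the pooled-QC cadence of this design (a BQC every 10 study
  samples, about 12 per batch), the loess fit carries noticeable noise;
  the CV rule is what keeps that noise from being injected into species
  that have little drift to remove.
* Applying the correction twice finds almost nothing the second time; a
  few percent of species can clear the rule again purely through fit
  noise, which is why the rule is evaluated once, in the fixed stage
  order.

### ISTD normalization and the BQC-average fallback

Default normalization divides each analyte area by its class ISTD area in
the same injection, cancelling injection-scale effects the ISTD shares
with its class. When the ISTD signal itself is noisy, that division adds
noise instead of removing any; the fallback divides by the average BQC
ISTD area instead. The mode is chosen per class by comparing the median
study-sample CV across the class's species under both modes (ties go to
per-sample). The median across species is used because the comparison
needs one number per class and the median is robust to a single wild
species.

Concentrations follow by one-point calibration:
$c_{si} = \text{ratio}_{si} \times \text{amount}_{\text{ISTD}}
/ V_{\text{serum}}$, with pmol/µL numerically equal to µmol/L. Response
factors are assumed to be 1; as with any one-point ISTD scheme the output
is a relative quantification expressed on a concentration scale, and the
emitted metadata says so.

### QC filtering

A species enters analysis only if it passes all four criteria: (i)
signal-to-blank ratio > 5 (median BQC raw area over median blank raw
area; a blank median of zero passes), (ii) median BQC raw area > 500
counts, (iii) analytical CV < 25% on normalized BQC values, (iv) RQC
linearity $R^2 > 0.8$ from ordinary least squares of area on dilution
fraction. The stages on which each criterion is judged were an open
choice: (i)–(ii) use raw areas (background and detector counts are
area-domain quantities), (iii) uses normalized values (the precision the
data carry into analysis), and (iv) uses drift-corrected areas so slow
sensitivity changes do not mask genuine response linearity. Criterion
(ii) can alternatively be judged as min-over-study-samples
(`raw_area_basis = "spl_min"`). Without an RQC ladder criterion (iv) is
flagged as not evaluable rather than failed.

Missing areas are never imputed: they are excluded pairwise from CVs,
medians and regressions, and cells that were zero or missing stay missing
after correction. CVs are undefined (flagged) below 3 values or at a
non-positive mean.

### Derived metrics and statistics

Class totals sum the surviving species of each class per sample; the
number of species actually summed is reported alongside, since totals
built from different survivor sets are not blindly comparable. The ratio
metrics are total cholesteryl esters over clinical total cholesterol
(CE converted from µmol/L to mmol/L so the ratio is dimensionless) and
the three ceramide risk ratios Cer d18:1/16:0, /18:0 and /24:1 over
Cer d18:1/24:0.

Group comparisons are two-tailed Welch's t-tests on linear-scale
concentrations (the scale the figures report; a log2 option exists),
with star tiers at p ≤ 0.05 / 0.01 / 0.001, boundaries inclusive. Raw
p-values drive the tiers; a Benjamini–Hochberg column is always emitted
alongside. Degenerate inputs are resolved explicitly: two zero-variance
groups give t = 0, p = 1 when means agree and a flagged p = 0 when they
do not. PCA runs on study samples only, on log2 values centred and
scaled per variable; variables with missing or non-positive values are
dropped (listwise deletion, logged), loading signs follow a fixed
largest-entry-positive convention, and the top-30 loadings are ranked by
their norm in the PC1–PC2 plane.

## The synthetic batch generator

`simulate_batch()` emulates the run design the pipeline assumes: a
lead-in BQC, the RQC ladder (1, 1/2, 1/4, 1/8), blanks split between
batch start and end, a BQC after every 10 study samples, the ladder and
remaining blanks again, and a lead-out BQC. The default cohort is 10
healthy beagles (HB), 45 hypothyroid (HT) and 39 hypercortisolism (CS)
dogs; the default panel holds 301 species in 27 classes, each with one
ISTD.

Ground truth: per-species median concentrations are drawn log-normally
(spread 0.5) around class-typical serum values (e.g. 30 µmol/L for a PC
species, 100 for a CE); study-sample truths multiply these by the group
fold map and log-normal between-animal variation (30% CV, a typical
within-group biological spread for serum lipid species). BQC truth is the
mean of study-sample truths (equal-volume pooling); RQC truths are the
BQC truth times the dilution, which also thins the ISTDs since they enter
the extract before dilution; blanks carry 1% of the median BQC signal and
full-strength ISTD (the ISTD arrives with the extraction mix).

Instrument drift is one full sine cycle per batch at the class level
(random phase, amplitude 0.5 log2 by default). Species of a class share
that pattern but not its exact size or timing: each species' curve gets a
modest log-normal amplitude jitter (sd 0.15) and a phase jitter (sd 0.5
rad). This decorrelation is deliberate and physical — ionization drift is
analyte-specific — and it is what gives per-species drift correction real
work to do beyond what ISTD normalization already cancels. A generator
whose species all drift in lock-step with their ISTD makes the correction
step pointless by construction, which contradicts the premise of the
method. Response factors are class-level (20 000 counts per µmol/L,
log-normal spread 0.3) and shared with the ISTD, which is what one-point
class calibration assumes. Analytical noise is log-normal at 8% CV.
Isotopic cross-talk adds $p_{M2} \times$ the interferer's clean area for
every declared link; when cross-talk is disabled the emitted panel
declares no links, since correcting interference that was never generated
would subtract real signal.

Clinical chemistry columns are derived from the truth: total cholesterol
tracks the true CE pool so that the CE/TC ratio centres near 0.9, and
clinical TG tracks the true TG pool.

What the generator does *not* emulate: chromatographic peak shapes and
integration errors, retention-time shifts, batch-to-batch effects
(everything is one batch), detector saturation, missingness mechanisms
(missing areas arise only by explicit construction in tests), and any
correlation structure between lipid species beyond the class-level group
effects. Consequently, passing tests demonstrate that the algorithms
invert the stated measurement model correctly and behave sensibly at
realistic noise — not that the pipeline is robust to every pathology of
real LC-MS data.

Fold-change magnitudes are stylized (1.5–3×) with directions taken from
the disease biology the pipeline is meant to resolve: broad HT-dominated
hyperlipidemia (TG, DG, diacyl phospholipids, ceramides, SM, LPC), lower
LPC/LPC-P/PC-O/PC-P in CS, and S1P increased in both diseases with CS
highest. Species-level overrides (a stronger HT effect on Cer d18:1/24:0
than on the rest of its class, and a CS increase of Cer d18:1/18:0) shape
the ceramide ratios' directions. Tests therefore assert directions and
orderings, never magnitudes.

## Numerical choices and degenerate inputs

* Loess on constant input returns the constant and reproduces exactly
  collinear input to numerical precision (degree-1 local regression);
  both are tested.
* Extrapolation beyond the BQC range is linear from the boundary slope of
  a unit-step evaluation grid.
* RQC $R^2$ is the squared Pearson correlation (OLS with intercept);
  a through-origin option was considered and rejected as the default
  because an intercept absorbs the blank background.
* Interference chains are processed in topological order; cycles are a
  configuration error, caught at entry.
* CSV output uses 17 significant digits so areas round-trip bit-exactly.
* Seeding: one integer seed drives the whole batch; identical config and
  seed give bit-identical output.

## Statistical calibration of the test surface

Under a null fold map on drift-free reduced batches, the fraction of
Welch p-values at or below 0.05 sits within two binomial standard errors
of 0.05 when tests run on the log2 scale, where the generator's null is
exactly Gaussian (the test suite runs this over 200 seeds). Two
deviations from nominal behaviour are properties of the data, not the
test, and are deliberately left visible: on the linear scale the
log-normal skew makes Welch mildly conservative, and with instrument
drift switched on the smooth run-order correlation shared by samples
inflates within-group variance estimates relative to the variance of
group-mean differences, again conservatively. Neither affects the
directional findings at the default effect sizes.

## Problem sizes used by the test suite

The suite validates on the full default batch (94 study samples plus QCs,
301 species) where the design itself is under test, and on reduced panels
(2–6 classes, 10–30 study samples) for property checks and the 200-seed
calibration loop; the acceptance script uses the same sizes. These sizes
were chosen so the whole suite exercises every code path at full design
scale at least once while property loops stay quick to iterate on.

## Known limitations

* One batch only: no between-batch harmonization or bridging QCs.
* Response factors are unity; absolute accuracy is limited accordingly.
* The drift-correction acceptance rule judges precision (SPL CV), not
  accuracy; a correction that recentres slightly off-level can pass the
  rule while shifting a species' scale by a few percent (bounded by BQC
  count and noise).
* The fallback normalization comparison uses a class-level median; a
  class with heterogeneous species behaviour gets one mode for all its
  species, as the method prescribes.
* S1P is treated as just another quantified class; its separate
  derivatization chemistry is upstream of this package's input boundary,
  as is peak integration itself.
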