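---
title: "Methods: growth-adjusted drug-sensitivity indices for organoid screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth-adjusted drug-sensitivity indices for organoid screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codrp)
```

## Scope and data model

`codrp` analyses ex-vivo drug screens of patient-derived cancer organoids.
Its inputs are three plain-CSV tables: a long-format plate table
(`patient_id, drug, conc_uM, replicate, readout`; `conc_uM = 0` marks the
DMSO vehicle wells), a per-patient growth table (mean live-organoid area on
day 1 and day 3 of treatment), and a clinical table (one row per patient ×
drug line with a RECIST 1.1 label and, where recorded, the signed percent
tumor-size change). The screening design the defaults assume is a 7-point,
3-fold serial dilution from 50 µM plus one DMSO control condition, each
with three technical replicates, read out as ATP luminescence after a
3-day drug exposure of ~5000 cells per spot. Everything upstream of these
tables — cell isolation, culture, imaging, segmentation — is out of scope;
the package consumes their tabular products.

## Dose-response model

Viability at dose $c$ is the replicate mean divided by the DMSO control
mean (a single-control design leaves no plate median or positive control
to normalise against). The dose-response curve is the decreasing
four-parameter logistic

$$v(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
 {1 + 10^{\,h\,(\log_{10} c - \log_{10}\mathrm{EC}_{50})}},\qquad h > 0,$$

fitted by bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) on the per-dose means. Constraints and starts:

* bounds: $\mathrm{bottom} \in [0, 1]$, $\mathrm{top} \in [0.5, 1.5]$,
  $h \in (0, 10]$, $\log_{10}\mathrm{EC}_{50}$ within the tested grid
  ± 1 decade;
* starts from the raw curve: top = max mean, bottom = min mean, EC50 = the
  dose whose mean is nearest the half-range, $h = 1$;
* convergence tolerances `ftol = ptol = 1e-15`, 500 iterations, so
  noiseless data are recovered to numerical precision.

Three situations produce no trustworthy curve and set `fallbackUsed`
instead of parameters: fewer than four distinct doses, a flat profile
(mean-viability range below 0.05 — a 4PL is unidentifiable without a dose
effect), and data that *rise* along ascending dose by more than 0.25
anywhere (largest upward excursion; generous against the ≈0.06 SD of a
triplicate mean at 10% replicate CV). Downstream AUC then uses the
trapezoid on the observed means. Fitted curves whose optimizer exits
abnormally or returns bottom > top are treated the same way.

## AUC, indices and classification

The AUC convention is pinned deliberately, since dose-response software
differs and cohorts may use different grids: viability is clipped to
$[0, 1]$, integrated over $x = \log_{10} c$ across the tested range by
adaptive quadrature (`stats::integrate`, rel. tol $10^{-10}$), and divided
by the range width. The result is dimensionless, lies in $[0, 1]$, equals
1 for a drug with no effect anywhere on the grid, and is comparable across
grids. Higher AUC = more resistant; this sign convention is what the
composite's reference-point logic requires. Unclipped viabilities are kept
for QC.

Per drug and per metric the cohort is standardised with the sample
(n − 1) SD — the small-cohort convention; population SD is available via
`sd_mode` for sensitivity checks. Z-scoring is never pooled across drugs.
The AUC index of a patient is simply $Z_{AUC}$.

The CODRP index places each patient at $(Z_{growth}, Z_{AUC})$, where the
growth rate is $(A_3 - A_1)/A_1$ from the day-1 and day-3 mean areas (the
day-1 baseline, not day 0: the first day after exposure begins defines the
interval the screen observes), and measures the Euclidean distance from
the reference point $(-4.5, -4.5)$:

$$\mathrm{CODRP} = \sqrt{(Z_{growth} + 4.5)^2 + (Z_{AUC} + 4.5)^2}.$$

−4.5 is an extreme lower tail of the standard normal, i.e. an idealised
maximally sensitive, maximally slow-growing sample; resistance increases
with distance from it, so both a larger AUC and faster growth push a
patient outward. The distances are re-Z-scored across the cohort, and a
patient is called **sensitive** when the index is ≤ −0.17, otherwise
**resistant**. Numerical conventions fixed here because no source states
them:

* the −0.17 cutoff is a stored operating constant, not re-derived from the
  cohort (its derivation was never published; the package applies the same
  value to every drug);
* ties at the cutoff are sensitive (inclusive rule), so calls are
  deterministic;
* a zero-variance metric (all AUCs equal, or all distances equal — the
  latter occurs in two-patient cohorts with opposite AUC/growth ordering)
  is an error naming the offending column, never a silent 0/0;
* if the cohort's growth rates are constant up to numerical noise
  (SD ≤ $10^{-8} \cdot \max(|\mathrm{mean}|, 1)$ — measured areas carry
  nowhere near eight significant digits), the growth term carries no
  information and the CODRP index is *defined* to reduce exactly to the
  AUC index, with a warning. Exact standardisation is scale-invariant, so
  without this rule an infinitesimal jitter would still produce O(1)
  growth Z-scores and arbitrary calls; the reduction makes the
  no-heterogeneity limit well-defined and testable.

## Clinical adjudication and concordance

RECIST labels map to binary ground truth as: PR → sensitive,
PD → resistant, SD with a documented size *decrease* → sensitive, SD with
an increase → resistant, SD without a recorded change and NE → not
evaluable. Labels are taken *at sampling time*: a patient sampled at
progression on a drug counts as clinically resistant to it even if an
earlier response occurred. Not-evaluable patients (and calls without any
adjudication, which warn) are excluded from all denominators. Sensitivity
is TP/(TP+FN) over clinically sensitive patients, specificity TN/(TN+FP)
over clinically resistant ones; raw percentages are kept and rounded to
one decimal only for reporting.

The packaged fixtures transcribe the 14-patient EGFR-mutant NSCLC cohort
of the study this pipeline operationalises (mutation tokens verbatim; the
prose of that study counts one exon-19 deletion more than its own table —
the fixture follows the table). Two footnoted stable-disease cases with
documented shrinkage (−20% and −10%) adjudicate as sensitive, which is
what yields the cohort's 7/7 sensitive/resistant split for afatinib. The
screening-call table stores the published organoid calls under mode
`codrp`; the AUC-mode calls are *derived* — the four samples reported as
AUC-discordant flip — and are labelled as such in `screening.csv`'s
documentation, since per-mode calls were never printed per patient.

## What the generator emulates — and what it does not

`simulateCohort()` draws, per patient: a latent class
(P(sensitive) = `frac_sensitive`, default 0.5), a class-conditional
lognormal IC50 (log10 means −1 and +1, i.e. 0.1 µM vs 10 µM — two decades,
matching the gap between TKI-sensitive and resistant lines; within-class
SD 0.3 decades), a uniform Hill slope in [0.8, 2], and a growth rate built
from the driver $t = u + \delta \cdot \mathbb{1}[\mathrm{resistant}]$ with
$u \sim N(0,1)$ and $\delta = 0.5$: cohorts are sampled at progression,
where resistant disease is the more proliferative, as the discordant
cases of the underlying study imply. Growth rates have mean 1.0 and SD 0.4
(organoid area roughly doubling in two days, with realistic spread).

The key coupling is the **proliferation-dependent potency artifact**: the
*assayed* potency is shifted by the growth driver,
$\log_{10}\mathrm{IC50}_{obs} = \log_{10}\mathrm{IC50} - \gamma t$, so
fast-growing organoids read out as more sensitive than their class. In a
fixed-length exposure this is the classic confound between division rate
and drug effect. $\gamma \ge 0$ is calibrated per cohort by root-finding
(`stats::uniroot` on the closed-form noiseless AUC) so that the realised
Pearson correlation between growth rate and noiseless AUC equals
`growth_auc_corr` (default −0.5) *exactly*. The negative growth–AUC
correlation is therefore an emergent, controlled property, and the
composite index genuinely has something to correct: under this model the
growth term removes a confound from the AUC signal. Coupling growth
directly to the class-determined AUC instead (a plain copula on the
marginals) would make the growth term *cancel* the AUC signal inside the
distance — at correlation −0.5 the two index modes become provably
equivalent — which contradicts the method's premise; that is why the
artifact construction was chosen. The correlation magnitude itself is an
assumption, not an estimate: only its sign is documented for real
cohorts.

Well readouts are the 4PL viability times a per-patient luminescence scale
(lognormal around 5×10⁴) times multiplicative Gaussian noise with CV
`replicate_cv` (default 0.10, a typical HTS replicate CV; no noise
statistics were published). Clinical labels equal the latent class unless
`label_noise` > 0. Everything is driven by one mandatory seed and is
bit-reproducible.

Not emulated: spatial plate effects and edge wells, organoid imaging and
segmentation error, label ambiguity beyond a flip probability,
inter-assay drift, and immune co-culture. Passing simulation tests
therefore demonstrates the *algorithmic* claim — that the composite
recovers class labels better than AUC alone when growth confounds the
assay — not the clinical performance of any real screen.

`benchmarkIndices()` repeats the full pipeline over independent cohorts
and scores both modes against the simulated labels. The packaged study
sizes — 30 patients × 100 runs for the head-to-head comparison, 100
profiles for noisy parameter recovery, 200 patients for the correlation
check — keep every Monte-Carlo estimate stable to a percent or two while
the whole suite runs in well under a minute.

## Known limitations

* The −0.17 cutoff is treated as a constant; deriving an operating point
  from a new cohort (e.g. by Youden's J on a labelled subset) is left to
  the user, deliberately outside the headline path.
* With a single DMSO condition, control noise propagates into every
  viability value of a patient; the package does not model it separately.
* Cohort Z-scoring makes every index *relative to the screened cohort*: a
  patient's call can change when the cohort around them changes. That is
  inherent to the method, not an implementation choice.
* Two-patient drugs are scoreable but fragile (a single tie in distances
  is an error by design); meaningful cohorts start around n ≥ 5.
* The trapezoid fallback underestimates curvature between widely spaced
  doses; profiles using it are flagged in the `method` column and should
  be reviewed.
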