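---
title: "Methods: profiling and classifying NMDA-receptor variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling and classifying NMDA-receptor variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grinfun)
```

## What the package computes

NMDA receptors are glutamate- and glycine-gated channels whose
disease-associated missense variants perturb several properties at
once: agonist potency, maximal open probability, Mg²⁺ block,
deactivation time course, divalent permeability, and surface
trafficking.  `grinfun` estimates each property from its raw assay
readout, combines them into synaptic and non-synaptic charge-transfer
composites, and issues a rule-based gain-/loss-of-function call per
variant.  A synthetic-data module generates every assay from a known
ground-truth profile, which is how the estimators are validated.

## Concentration–response fitting

Agonist curves follow `Response(%) = 100/(1 + (EC50/[A])^N)`; blocker
curves follow `(100 − min)/(1 + ([B]/IC50)^N) + min` with the residual
response `min` constrained non-negative (open-channel blockers often
leave a measurable pedestal; an unconstrained minimum can drift
negative on noisy data and distort the IC50).  Fitting is constrained
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with the
potency parameterized as log₁₀(EC50): potencies are strictly positive
and their sampling error is approximately log-normal, so confidence
intervals are formed as z-based normal intervals on the log parameter
and back-transformed.  A z (not t) quantile is used deliberately;
composite curves pool hundreds of points, where the two are
indistinguishable, and the same convention makes the 99% half-width of
the permeability screen reproduce its ±3.4 mV threshold from a 1.3 mV
SEM (a t quantile at n = 15 would give ±3.9 mV, inconsistent with the
stated threshold).

Composite (pooled, many-cell) agonist fits are preceded by per-cell
normalization: a preliminary pooled fit supplies the curve shape, each
cell's maximum is the linear projection of its responses onto that
shape, and cells are rescaled to the geometric mean of those maxima.
The final pooled fit then estimates a *free* shared maximum, and
responses are interpreted as percent of that fitted maximum.  Two
numerically tempting alternatives were rejected after simulation:
rescaling every cell to its own independently fitted maximum of 100
transfers the per-cell top-estimate noise into the pooled fit and
biases EC50 by roughly ±3% at realistic noise; fixing the pooled
maximum at exactly 100 does the same through the noise floor of the
normalization.  The free-maximum composite is unbiased in the same
simulations.

Two potencies are called significantly different when their 95%
intervals are disjoint — the convention used in the packaged summary
tables — and the pipeline supplements that with Welch t-tests on
per-cell open-probability and tau values (an intentional proxy: the
original analyses used one-way ANOVA with Dunnett's post-hoc tests,
which operate on raw per-cell data this package's users may not have).

## Deactivation kinetics

Decay segments (from one sample after the end of the agonist
application) are fit with `A_f·exp(−t/τ_f) + A_s·exp(−t/τ_s)` and
summarised by the amplitude-weighted tau, a convex combination of the
two time constants.  Degenerate fits — time constants within 5% of one
another, or either amplitude fraction collapsing below 1% — are refit
as single exponentials, because the two-component amplitudes are not
identifiable there.  Traces whose peak is below 3 baseline standard
deviations are reported as `too_small_to_measure` rather than fit;
that status later feeds the starred Indeterminant classification
(variants whose currents were too small to measure deactivation but
that completed every other assay).  Rise time is the linear
interpolation of the 10% and 90% crossings of the peak;
desensitization extent compares the mean current over the last 10% of
a prolonged application to the peak.  Panel summaries fit each cell
and then average (fit-then-average), matching the use of a *mean*
weighted time constant in the composite scoring.

## Open probability from MTSEA potentiation

Covalent modification of an engineered cysteine in the channel gate
locks receptors open; the current ratio after/before modification (the
potentiation) is `γ_ratio / P_open`, with the single-channel
conductance ratio γ_ratio = 0.67 a parameter, not a constant.  A fully
locked-open receptor can at most fall to γ_ratio times the control
current, so potentiation *below* γ_ratio implies P_open > 1 and is
flagged as a labeling failure (`no_potentiation`) rather than
reported; potentiation between γ_ratio and 1 is a legitimate
high-open-probability receptor (the packaged tables contain variants
at P_open ≈ 1).  The per-cell estimate is scale-invariant in the two
currents.

## Permeability screen

Reversal potentials are interpolated linearly between the two voltage
steps bracketing zero current (no polynomial I–V model is imposed);
with several crossings the one nearest 0 mV is used and flagged.  The
screen statistic is the variant-minus-wild-type difference in the
Ba²⁺-induced reversal shift, with ±3.4 mV (the 99% half-width of the
wild-type shift) as the decision threshold.  The predicted −6 mV
junction-potential shift of the Ba²⁺ solution is deliberately *not*
corrected, matching the recording convention of the source data.

## Charge-transfer composites and classification

The synaptic composite multiplies six ratios (tau, open probability,
surface expression, fitted-response ratios at 3 µM glycine and 1 mM
glutamate, and 1 mM Mg²⁺ inhibition); the non-synaptic composite drops
the tau term and evaluates glutamate at 0.1 µM, the ambient
extracellular concentration scale.  Response ratios use each
construct's fitted Hill slope, falling back to N = 1 with a warning
when no fit exists (per-variant slopes are rarely published, which is
why recomputing published composite columns from potencies alone does
not reproduce them exactly).  When a direct percent-inhibition
measurement at 1 mM Mg²⁺ is absent the term is derived from the fitted
IC50.

Classification proceeds in a fixed order: (1) unmeasurable tau with
all other assays complete → `Indeterminant*`; (2) all directional
votes agree → `GoF`/`LoF`, with high confidence for significant
changes at or beyond 2-fold and moderate below (the 2-fold cutoff is a
configurable approximation — the upstream confidence scheme's exact
cutoffs are not published); (3) conflicting or absent votes fall back
on the composites: both suprathreshold in opposite directions →
`Indeterminant`, otherwise > 2.5-fold rescues to `Possible GoF` and
< 0.4-fold to `Possible LoF`; (4) anything else is `no change`.  The
procedure is total (every input reaches a call) and independent of
assay ordering, both property-tested.

## Cross-assay regressions

`regress_tau_vs_ec50()` regresses log₁₀ tau fold on log₁₀ glutamate
EC50 fold across variants, excluding potencies below 30 nM
(sub-30 nM EC50s can be inflated by trace agonist contamination of the
perfusion system).  On the packaged tables this yields slope −0.846,
r² 0.759 — the expected near-reciprocal coupling between binding
stability and deactivation.  The intercept depends on which pooled
wild-type tau reference set is used and is therefore not a stable
quantity of this analysis.  For the glycine–glutamate potency coupling
the axis orientation of the published fit is ambiguous (the two OLS
orientations satisfy slope₁·slope₂ = r²); `regress_gly_vs_glu()`
exposes both, and the package's regression tests report a sensitivity
table over orientation × inclusion-filter combinations (r² stays above
0.85 throughout, so the conclusion — proportional potency shifts in
the two co-agonists — does not depend on the choice).

## The synthetic-data module

Each generator draws from a `gt_profile()` holding the true parameter
values; presets mirror the wild-type GluN1/GluN2A and GluN1/GluN2B
summary rows plus illustrative gain-, loss-, and trafficking-variant
profiles.  The noise model is:

* multiplicative unit-mean lognormal noise on steady-state responses
  (concentration–response points, MTSEA pair currents), CV 0.10;
* additive Gaussian noise on current-trace samples (SD ~2 pA) and on
  I–V difference currents (SD 12 nA against kilo-nA currents);
* unit-mean lognormal per-cell jitter on kinetic parameters and peak
  currents (CV 0.30 on the 2A background, 0.22 on 2B), emulating
  cell-to-cell biology.

The CVs were calibrated once, forward from the published dispersion:
CV 0.10 makes the composite EC50 confidence interval at 113 simulated
cells reproduce the printed [3.4, 3.6] µM almost exactly, and the
per-cell kinetic jitter reproduces the printed tau SEMs at the
published cell counts (2.2 ms at n = 37; 23 ms at n = 26).  Two
dispersions are deliberately *under*-modeled.  First, the published
per-cell spread of open probability implies a per-current CV so large
that the mean of per-pair ratio estimates would be biased upward ~17%
purely through E[1/X] > 1/E[X]; we model assay noise at CV 0.10 (≈1%
ratio bias) and attribute the remainder to cell biology the generator
does not emulate.  Second, I–V noise is recording-level only: the
printed 1.3 mV SEM of the wild-type reversal shift is dominated by
biological variation, and under that dispersion the ±3.4 mV screen
could not call a ±4 mV shift reliably at any published sample size —
the screen's round-trip validation therefore probes the measurement
chain, not biological scatter.  Consequently, passing recovery tests
demonstrates estimator correctness under the stated noise model, not
robustness to every source of variability in real recordings.

Other generator choices: concentration series default to half-log
spacing over 0.01×–100× the true potency (9 points; the published
series are not printed); trace onsets are single-exponential with a
5 ms 10–90% rise (onset kinetics are not modeled in the source
analyses; the measured 10–90% time is ~5% shorter than the nominal
value because the application window truncates the asymptote); the
deactivation trace duration defaults to 6 slow time constants and the
generator refuses sampling intervals that undersample the fast
component.  Seeds are explicit arguments everywhere; a fixed seed
gives bitwise-identical output, and `noise_off()` zeroes every noise
source for exact round-trip tests.

## 3D missense tolerance

`mtr3d_map()` assigns each residue the pooled
observed/expected missense-fraction ratio over a spatial window: the
residue plus its 30 nearest resolved residues by Euclidean distance
between α-carbons (the representative atom is a package choice; ties
break deterministically by distance, then chain, then index).  Pooling
counts before ratioing is the default because per-residue counts are
sparse; averaging per-residue ratios is available behind
`aggregate = "mean_ratio"`.  Expected counts enter only as fractions,
so the score is invariant to rescaling the null model.  Chain termini
yield reduced windows (min(31, n) residues), reported via `n_window`.
Structure/count reconciliation is explicit: residues missing counts
raise an error listing them, and unresolved residues are dropped with
a warning.  The synthetic fixtures are an ideal α-helix plus Poisson
counts with an optional missense-depleted cluster, which the map must
recover as a local minimum.

## Problem sizes used in the packaged tests

The test suite simulates at the published sample sizes where a printed
interval is the acceptance band (113-cell concentration–response
panels, 37/26 traces, 122/84 MTSEA pairs) and at 3–15 cells elsewhere;
bias properties use 200 replicate small panels and the permeability
round-trip uses 200 screen decisions at 12–15 cells each.  These sizes
are the package's validation design and complete in a few minutes on a
single core.

## Known limitations

* The generator is phenomenological: no Markov gating scheme, no
  solution-exchange artifacts, no liquid-junction correction, no
  voltage dependence of Mg²⁺ block beyond a fixed holding potential.
* Significance proxies (CI overlap, Welch tests) approximate the
  original ANOVA/Dunnett analyses; supplied flags take precedence when
  available.
* Published composite charge-transfer columns cannot be reproduced
  exactly from published potencies because per-variant Hill slopes and
  same-day references are not printed; the packaged transcriptions are
  used verbatim for threshold counts and regressions instead.
* The two-state `ec50_po_relation()` is a stand-in occupancy argument
  for exploring the potency/open-probability trend, not a mechanistic
  receptor model.
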