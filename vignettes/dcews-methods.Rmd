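---
title: "Dynamic complexity early warning signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic complexity early warning signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcews)
```

## The scientific problem

Complex-systems accounts of sports injury hold that an athlete's
psychophysiological state behaves like a multistable dynamical system:
injury is a phase transition out of a healthy attractor, and shortly
before such a transition the weakening attractor shows *critical
fluctuations* — a short window of increased, turbulent variability across
many monitored factors. If those fluctuations can be detected in routine
monitoring data, they constitute an early warning signal (EWS) on which a
practitioner could act.

`dcews` implements a complete, testable version of this analysis for
athlete-monitoring panels: daily self-reports (recovery, self-efficacy,
motivation, mood, perceived performance, enjoyment, perceived exertion)
and sensor-derived session loads (distance, sprints, duration, seconds in
heart-rate zone 5), together with an injury log (onset, time-loss,
traumatic vs. overuse mechanism). Because real club data of this kind is
access-restricted, the package ships a synthetic cohort generator that is
itself a first-class, tested module.

## The dynamic complexity index

For each factor, normalized onto its analysis scale with range
$s = \mathrm{norm}_{\max} - \mathrm{norm}_{\min}$, dynamic complexity is
computed in an overlapping moving window of $m$ occasions (default 7,
step 1) as the product of two measures:

**Fluctuation measure F.** The window is decomposed into maximal monotone
segments: maximal runs of same-direction nonzero steps. Each segment
contributes its absolute value change divided by its length in
occasions, and

$$F = \frac{\sum_{\text{segments}} |\Delta \text{value}| / \Delta t}
          {s\,(m - 1)} .$$

A constant window gives $F = 0$; full-scale alternation on every step
gives $F = 1$. Plateaus (equal consecutive values) inside a
same-direction run are absorbed into it, diluting its slope; a plateau
across which the direction reverses — and any leading or trailing
plateau — belongs to no segment. We chose this symmetric plateau rule,
rather than attaching a reversal plateau to the preceding segment,
because the measure should not depend on the direction of time: with the
asymmetric rule the window $(0, 1, 1, 0.5)$ would score differently from
its mirror image $(0.5, 1, 1, 0)$, which has no substantive
interpretation. The symmetric rule leaves all plateau-free windows
unchanged and makes time-reversal invariance an exact property that the
test suite checks on tens of thousands of windows.

**Distribution measure D.** The sorted window values $y_{(1)} \le \dots
\le y_{(m)}$ are compared with the ideal equidistant spread over the full
theoretical scale, whose pairwise gaps are $d^{\mathrm{ideal}}_{ij} =
(j - i)\, s/(m-1)$. Only shortfalls count:

$$D = 1 - \frac{\sum_{i<j} \max\!\bigl(0,\; d^{\mathrm{ideal}}_{ij} -
        (y_{(j)} - y_{(i)})\bigr)}{\sum_{i<j} d^{\mathrm{ideal}}_{ij}} .$$

A constant window gives $D = 0$ and a full-range equidistant window
gives $D = 1$ (telescoping of adjacent gaps forces equality). Both
measures, and their product $DC = F \times D$, lie in $[0, 1]$.

The literature defers the exact formulation of $F$ and $D$ to software;
the formulas above are this package's documented variant, chosen for
exact normalization and for being checkable against brute-force oracles
(exhaustive segment enumeration and exhaustive pairwise sums). The test
suite verifies both measures against such oracles on *every* length-7
window over a five-value grid ($5^7$ windows). Numerical agreement with
other implementations is not claimed.

Each window's value is assigned to its **last** occasion, so the first
$m - 1$ occasions are undefined and the analysis starts on occasion $m$.
The scale range $s$ is always the *theoretical* normalized range (for
example $0.7$ for a 6–20 category-ratio scale divided by 20), never the
observed range.

## Two-stage significance testing: cumulative complexity peaks

Critical fluctuations should appear in *several* factors at once. The
package therefore flags, per factor, occasions whose DC exceeds the
factor's mean by more than $z_{\mathrm{crit}} = \Phi^{-1}(1-\alpha)$
sample standard deviations (one-sided, default $\alpha = 0.05$,
$z_{\mathrm{crit}} \approx 1.645$; only elevated complexity is of
interest). The per-occasion count of flagged factors forms a new series,
and a second one-sided z-test on that series marks *cumulative
complexity peaks* (CCPs) — the warning signal.

Two standardization baselines are provided. The default standardizes
over the player's entire defined series, which matches a retrospective
design, is deterministic, and empirically keeps the background CCP rate
low (the count series' standard deviation is inflated by genuine peaks,
which suppresses spurious flags). The `"running"` baseline standardizes
each occasion against up to 50 preceding values, which is the choice a
real-time system would need, but it raises the background flag rate
noticeably; we examined both on synthetic cohorts and kept the
whole-series default. A factor (or count series) with zero variance is
never significant. On independent Gaussian null series the per-factor
flag rate matches the nominal one-sided tail mass to within a fraction
of a percentage point; the suite checks this on 1,000 replicate series
of 200 occasions.

## Evaluation against the injury log

Injuries with an onset before occasion $m$ or in the last seven
occasions are ineligible (the window cannot observe their pre-injury
period). For each eligible injury and pre-injury window length $W$, the
window is the $W$ occasions strictly before onset, minus any occasions
belonging to an earlier injury period. At least one CCP inside the
window counts the injury as **one** true positive (the remaining window
occasions are left out — the signal already appeared); no CCP counts it
as **one** false negative, not $W$ of them. Window occasions are removed
from the negative pool in both cases; we apply this exclusion
symmetrically (the source analysis states it only for the true-positive
case) so that the pool does not depend on the outcome being scored.
Injured occasions are likewise excluded (turbulence during injury is
expected), as are the first $m - 1$ occasions. Every remaining occasion
is a false positive if it carries a CCP, a true negative otherwise. A
window entirely swallowed by a previous injury period makes that injury
unevaluable, which is reported rather than silently counted.

Per player, sensitivity, specificity and accuracy are computed as
percentages, with zero-denominator cases reported as missing and
excluded from cohort averages (not imputed as zero). Because injuries
are rare, cohort averages of these per-player rates are optimistic, so a
pooled group-level check is added: precision, recall and
$F_1 = 2PR/(P+R)$ over the summed counts, with $F_1 = 0$ when there are
no true positives.

**Window search.** The optimal $W$ is sought stepwise over 1–10: the
window grows while the objective improves, and the last improving window
is the optimum. The objective is cohort mean sensitivity (the source
procedure's "better results" is not defined; sensitivity is the quantity
the analysis is about), with exact ties broken by higher cohort mean
specificity and then by the smaller window; `f1` and `accuracy` are
available as alternatives. Note a structural property of the trailing
window assignment: turbulence anywhere in the pre-injury period also
elevates DC at the occasion just before onset, so sensitivity tends to
saturate already at $W = 1$ and the tie-break chain, not sensitivity
itself, usually determines the chosen $W$. Consequently the chosen $W$
estimates the depth of the turbulent period only approximately (typically
within about one occasion); the per-$W$ table is always returned so the
search path can be inspected.

**Attribution.** For each true positive, the factors showing a
significant DC peak on the CCP occasions inside the window are
collected; each injury is labelled `psychological-only`, `sensor-only`,
`physiological-only` (physiological self-reports and/or sensors),
`self-report-only` (psychological and physiological self-reports, no
sensors) or `combination`, mirroring how such results are narrated in
practice. The checks are ordered from most to least specific, so a
single label is always produced.

## The synthetic cohort generator

The generator emulates the *shape* of a two-season professional youth
football monitoring data set; no empirical per-factor distributions are
published for such data, so the defaults are plausible rather than
calibrated:

* 23 players, series lengths uniform on 155–430 occasions (the reported
  cohort shape), eleven raw factors on their native scales;
* each factor follows a bounded AR(1) process (default autocorrelation
  0.4, configurable) with factor-specific mean and spread; session-level
  factors are occasionally split over two sessions per occasion so the
  daily-load construction is exercised;
* injuries arrive at 0.83 per 100 occasions (about 2.8 per player over a
  full series), placed uniformly at random outside the first and last
  seven occasions, with non-overlapping injured periods of 1–15
  occasions; time-loss occasions are flagged, not deleted, so the
  evaluation can exclude them exactly;
* a configurable fraction of injuries (default 0.3, the order of the
  detected fraction reported for real data) is preceded by an injected
  destabilization window: in the `lead` occasions before onset (default
  6) the selected factors (default 4) oscillate with alternating sign
  and amplitude $(\mathrm{gain} - 1)$ times the factor's series standard
  deviation, clipped to the raw bounds. `gain = 1` is exactly the
  identity, making the effect size a single knob. Alternation raises
  both $F$ and $D$, which is the qualitative picture of critical
  fluctuations;
* missingness is applied last, completely at random (default 10%); the
  real missingness mechanism is uncharacterized, and MCAR is the
  assumption under which the simple imputer is unbiased.

What the generator does **not** emulate: calendar structure (matches vs.
training days, weekends), feedback between load and injury risk,
injury-induced changes in the measured factors outside the injected
window, and non-random missingness. Passing the recovery tests therefore
shows that the pipeline detects the kind of multivariate turbulence the
theory describes when it is present, and stays quiet when it is absent —
not that real injuries are predictable at these rates.

## Preprocessing choices

Players enter the analysis if they have at least one eligible injury and
no factor missing on strictly more than 20% of occasions. Missing values
are imputed by per-factor linear interpolation over the occasion index
with nearest-edge fill: deterministic, bound-preserving, and recorded in
the output metadata. (The original analysis used chained-equations
multiple imputation; a deterministic imputer was substituted so that
every downstream number is reproducible, and the interface accepts
alternative methods.) The internal load is `srpe = RPE × session
duration`, summed over a day's sessions; duplicate single-administration
self-reports on one occasion are averaged. Both `duration` and `srpe`
are kept in the default factor set (duration also enters `srpe`); the
set is an argument everywhere.

## Numerical and degenerate-input conventions

* Undefined DC cells (first $m-1$ occasions, or windows touching missing
  values) are `NA` and are excluded from standardization, counting and
  pooling.
* Zero-variance series never produce flags; zero-denominator metrics are
  `NA`; an entirely missing factor, a sensor factor with no positive
  values, and RPE without a matching session duration are hard errors
  that name the offending factor or occasion.
* Window-search ties are resolved at `1e-9` tolerance; the smaller
  window always wins a full tie.
* The moving-window kernel is implemented in C++ (Rcpp) for speed; the
  exported R functions `fluctuation_measure()` and
  `distribution_measure()` are the reference implementations, and the
  two are cross-checked in the tests.

## Problem sizes used by the test suite

The suite exercises the exhaustive window grid ($5^7$ windows), $10^4$
fuzzed windows for the bound and symmetry properties, 1,000 Gaussian
null series of 200 occasions for calibration, 1,000 fuzzed small
instances for the counting rules, and ten 20-player, 300-occasion
cohorts (plus three null cohorts) for end-to-end parameter recovery.
These sizes give stable Monte-Carlo behaviour while keeping a full run
in the low minutes on one core.

## A worked run

```{r example, eval = FALSE}
cfg <- pipeline_config(simulation = sim_config(seed = 3), ews_window = 6)
res <- run_pipeline(cfg)
res
#> Early-warning-signal pipeline: 20 players analysed (of 23)
#> Chosen pre-injury window W = 6
#> Cohort of 20 players (W = 6):
#>   mean sensitivity 31.6%  mean specificity 96.4%  mean accuracy 95.6%
#>   pooled precision 0.088  recall 0.358  F1 0.142
head(res$attribution$factor_counts)
```

The profile — a minority of injuries preceded by a detected signal, high
specificity and accuracy, and a much lower pooled F1 driven by false
positives on the long non-injury stretches — is exactly the imbalance
phenomenon the pooled metric is there to expose.

## Known limitations

* The chosen pre-injury window is a coarse estimate of the turbulence
  depth (see the window-search note above).
* Whole-series standardization is retrospective; a deployable real-time
  system would need the running baseline and would pay for it with more
  false alarms.
* No multiple-testing correction is applied across factors, matching the
  source procedure; the second-stage CCP test partially absorbs this.
* Synthetic defaults are plausible, not calibrated to restricted data.
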