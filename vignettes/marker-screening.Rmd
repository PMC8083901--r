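---
title: "Methods: SL-pair screening, IHC calling and the constrained survival screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SL-pair screening, IHC calling and the constrained survival screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slmarker)
```

This vignette documents the statistical model behind each stage of the
package, the tunable parameters and their defaults, the numerical
conventions, what the synthetic-data generators do and do not emulate, and
the design choices made where more than one reasonable convention exists.

## 1. Expression screen

### Model

The screening substrate is a positive intensity matrix (genes × samples)
with a cancer/control labelling. Columns are quantile-normalized: every
column is mapped onto the common reference distribution given by the
row-wise mean of the per-column sorted values, preserving within-column
ranks. Tied values receive the average of the reference values spanned by
their tied ranks, which makes the operation exactly idempotent — a property
the test suite asserts, alongside agreement with `limma`'s implementation
on tie-free data.

For gene $g$ and cancer sample $j$, the statistic is the log ratio

$$ r_{gj} = \log_2 \frac{x_{gj}}{\bar x_{g,\text{ctrl}}}, $$

where $\bar x_{g,\text{ctrl}}$ is the *linear-scale* mean over control
samples. Averaging controls on the linear scale (rather than the log scale)
is a deliberate choice: intensities are the measured quantity, and the
resulting reference is the plain arithmetic control mean. Log base 2 is
used throughout; cutoffs quoted as fold changes convert via $\log_2 c$.

A gene is called **up** in a sample when $r_{gj} \ge \log_2 c$, **down**
when $r_{gj} \le -\log_2 c$, **neutral** otherwise. The boundary is
inclusive: exactly $c$-fold counts as a call. The default cutoff is $c =
1.5$, chosen deliberately lenient so that cancer genes that rarely reach
2-fold dysregulation can still contribute; a relaxed $c = 1.4$ is the
conventional choice when transferring markers to an external validation
cohort where the stricter cutoff leaves too few patients per subset.

For an ordered pair $(A, B)$ the four pattern fractions $f_{uu}, f_{ud},
f_{du}, f_{dd}$ are the proportions of cancer samples showing that joint
call pattern; samples where either gene is neutral count only in the
denominator, so the four fractions plus the neutral-involving fraction
partition 1.

### Permutation null and FDR

The null distribution of a fraction is generated by rearranging which
samples form the control set, keeping class sizes fixed, and recomputing
log ratios, calls and the fraction over the relabelled cancer set.
Quantile normalization is label-free, so it need not be redone per
rearrangement. With $N$ random rearrangements the upper-tail p-value uses
the add-one estimator $p = (1 + \#\{f^* \ge f_{\text{obs}}\}) / (N + 1)$,
which cannot return 0 and is never anti-conservative. The default is $N =
10{,}000$; every stochastic operation takes an explicit seed (CLI default
20210415). For small cohorts an exact mode enumerates all
$\binom{n}{n_{\text{ctrl}}}$ control choices, in which case $p$ is the
exact tail proportion without the add-one correction.

q-values follow Storey's method: $\hat\pi_0(\lambda) = \#\{p >
\lambda\}/(m(1-\lambda))$ on the grid $\lambda = 0.05, 0.10, \ldots,
0.95$, smoothed with a 3-df cubic smoothing spline and read off at
$\lambda = 0.95$, then clipped to $(0, 1]$. With fewer than 20 p-values
the smoother is unstable, so a fixed $\lambda = 0.5$ estimate is used
instead. Forcing $\pi_0 = 1$ recovers Benjamini–Hochberg exactly, which
the tests verify to $10^{-10}$.

By default only the (up,up) and (down,up) fractions are permutation-tested
— these are the two patterns panel selection uses — but all four are
available via the `patterns` argument.

### Panel selection

A pair enters the initial panel when $\max(f_{uu}, f_{du}) \ge 0.15$. Pairs
containing *KRAS* are held to a stricter $f_{du} \ge 0.25$ for
qualification *via the (down,up) route only* — the rationale being that
KRAS participates in very many SL pairs while its mutation rate in oral
cancer is low, so the lenient threshold would flood the panel; (up,up)
qualification for KRAS pairs uses the ordinary threshold. An include-list
lets prior-knowledge pairs enter regardless of their fractions, flagged
`"prior-knowledge"`.

## 2. IHC panel

Stains are protein + compartment assays (nucleus N, cytoplasm C, membrane
M) scored per tissue core with ordinal grades $0, \pm, 1+, 2+, 3+$. The
grade coding $\{0, 0.5, 1, 2, 3\}$ is a package convention — the grades are
ordinal labels, and a numeric coding is needed for core averaging; the
half-step for $\pm$ places "indeterminate" between negative and weakly
positive. Patient-level scores are arithmetic means over available
cancerous cores (nominally three; core loss is routine and tolerated down
to one), with percent-positive averaged the same way.

Each stain carries a cutoff rule over (mean grade, percent). The rule
grammar supports one or two atoms (`<`, `<=`, `>`, `>=` on a grade `k+` or
a percent `k%`) joined by `and`/`or`, parsed at panel load time so
malformed rules fail early, not at call time. A patient is called **over**
iff the over-rule holds, **under** otherwise, so the two calls partition
the score space by construction. One packaged rule deserves note: the
EGFR(M) under-criterion is conventionally printed conjunctively
("<1+ and <10%"), which would leave scores like (1.5, 5%) uncalled; the
packaged panel stores the logical complement "<1+ or <10%" so that the
partition property holds and (1.5, 5%) is under-called, consistent with
the over-rule "≥1+ and ≥10%" failing. The TP53(N) rule is percent-only:
">0%" for over, so under means exactly zero percent positive.

Pairs of stains are enumerated as all $\binom{n}{2}$ unordered pairs minus
pairs assaying the same protein in two compartments:
$\binom{29}{2} - 8 = 398$ for the default panel. A *marker* binds an
ordered stain tuple to a direction pattern (↑ = over, ↓ = under); a
patient is in the marker's subset iff every component matches, and
patients lacking any component call are excluded marker-wise
(complete-case per marker). Paired membership is exactly the logical AND
of the single-stain memberships, which the tests assert.

## 3. Survival screen

Follow-up is administratively censored at the 120-month horizon ("10-year
overall survival"): later events become censorings at 120. For each marker
the screen requires at least 5 patients in the subset *and* in its
complement — the published convention gives the subset-side rule; the
symmetric guard on the complement is a package addition to prevent
degenerate fits — and then runs:

* a two-group log-rank test (χ², 1 df);
* univariate Cox proportional hazards on the marker indicator;
* stage-adjusted Cox with the binary stage III–IV vs I–II covariate
  (grade, where used, is coded intermediate+high vs low).

Ties use the Efron approximation by default (least biased of the common
choices; the `ties` argument exposes Breslow — note that exact invariance
of the estimate under patient duplication holds for Breslow but only
approximately for Efron). Hazard ratios are reported with 95% Wald CIs on
the log scale; the model LR χ² is twice the log partial-likelihood gain
over the null model. Monotone likelihood (complete separation) is flagged
via `converged = FALSE`, never silently reported as an ordinary estimate.
No multiplicity correction is applied across the marker screen — the
headline selection mirrors per-test α = 0.05 — but a Benjamini–Hochberg
column over the tested markers is emitted for reference.

Stepwise covariate entry minimizes AIC in both directions around a
protected base model (the marker plus stage can never be dropped). Note
that a null candidate enters when its LR χ² exceeds the AIC penalty of 2,
which happens with probability ≈ 0.16 per candidate; occasional entry of a
noise covariate is expected behaviour of AIC, not a defect.

Two significant markers are combined by intersecting risk subsets. A
marker whose subset is associated with *better* survival (HR < 1) is
protective; by default its **complement** contributes to the joint risk
subset (`combine_protective = "complement"`), since the poor-survival side
of a protective marker is everything outside its subset. The switch
`"as-is"` is provided because published tables are sometimes ambiguous on
this point. The joint indicator passes the same subset-size guard and is
fitted stage-adjusted.

## 4. Synthetic-data generators

`simulate_expression()` draws per-gene log2 means from $N(8, 1.5^2)$ and
i.i.d. sample noise with standard deviation chosen so that a background
gene produces a spurious fold-change call at a configurable rate (default
10% at the 1.5-fold cutoff, both tails combined; the calibration treats
the log2 ratio as approximately normal with variance $\sigma^2(1 +
1/n_{\text{ctrl}})$, ignoring the small linear-scale-averaging bias). For
each planted pair, a target-fraction share of cancer samples receives a
coordinated $\log_2 3$ shift in the pattern's directions, leaving the
control mean untouched, so planted samples are called with probability
≈ 0.997. Default dimensions mirror a typical screening cohort: 57 cancer,
22 control samples.

`simulate_cohort()` (default 160 patients) draws per-stain over/under
calls — free stains at a given prevalence with optional exchangeable
latent-Gaussian dependence; stains inside a planted marker via joint
membership at the marker's prevalence, members forced to the pattern and
non-members drawing component calls at a marginal rate excluding the joint
event. Three cores per call are generated by rejection sampling grade
triples (and a percent) against the stain's rule, so re-aggregating the
noisy cores reproduces the intended call exactly — a property the tests
assert. Survival times are exponential with hazard $\lambda_0
\exp(\beta_{\text{stage}} z_{\text{stage}} + \sum_k \beta_k m_{ik})$,
with defaults $\lambda_0 = 0.01$/month, stage HR $3.15$ across III–IV vs
I–II, stage probabilities $(0.43, 0.17, 0.13, 0.27)$, and independent
exponential censoring at rate $0.005$/month — magnitudes chosen to look
like a 10-year oral-cancer follow-up with roughly two-thirds of events
observed. Clinical covariates other than stage (grade, lymph-node status,
age, sex, habits) are drawn from cohort-like marginals but are independent
of survival by default; they exist so the stepwise-AIC and adjustment code
paths run against realistic tables.

What the generators do **not** emulate: probe-level microarray artifacts,
batch effects, correlated gene–gene background structure beyond the
planted pairs, inter-rater scoring disagreement, informative censoring,
non-proportional hazards, or correlation between habits and markers.
Passing tests therefore demonstrate that the machinery is correct and
well-calibrated under a clean generative model — not that any particular
biological cohort will reproduce a given marker.

## 5. Numerical choices and degenerate inputs

* Fractions compare with `>=` on exactly representable ratios $k/n$, so
  permutation tail counts are exact.
* The Kaplan–Meier estimator uses the standard deaths-before-censorings
  convention at tied times.
* Per-pair permutation seeds are derived from one master seed by a single
  `sample.int` draw, keeping every derived seed within 32-bit range and
  the whole screen reproducible from one integer.
* Zero-event strata, constant covariates and unmatchable markers are
  rejected or reported as statuses (`skipped_small_subset`,
  `not_converged`, `error: …`); the screen never aborts on one bad
  marker.
* Exact permutation enumeration refuses more than 50,000 control-set
  choices; beyond that, Monte-Carlo sampling is the intended mode.

## 6. Problem sizes used by the test and acceptance suites

The validity and recovery simulations run at sizes chosen to make
Monte-Carlo error small relative to the asserted margins while keeping the
suites quick to run: 500 null pairs × 500 rearrangements for permutation
validity; 10,000 rearrangements against the exact $\binom{5}{2}$
enumeration; 1,000 random vectors for the q-value/BH identity; 60–200
replicates of 160-patient cohorts for the planted hazard-ratio scenarios
(HR 3 at prevalence 0.20, HR 7.5 at prevalence 0.08, matching the
magnitude of a headline paired marker); and 25 null cohorts for the
screen's false-positive rate. The hazard-ratio simulations use a compact
3-stain panel — the marker estimate's sampling behaviour depends on the
cohort and the planted effect, not on how many unrelated stains surround
it.

One statistical subtlety the acceptance numbers surface: the *univariate*
HR estimate under a planted HR of 3 centres near 2.6–2.8, not 3.0. This is
Cox non-collapsibility — the marginal (stage-ignoring) hazard ratio is
attenuated relative to the conditional one when an independent prognostic
factor (the stage effect) is omitted — not an estimation bias; the
stage-adjusted estimate centres on the planted value.

## 7. Known limitations

* The expression screen assumes gene-level, positive, complete intensity
  matrices; probe mapping, missing values and batch correction are out of
  scope.
* The survival screen fits one binary indicator (plus stage) per model;
  competing risks, time-varying effects and multi-level stage coding are
  not modelled.
* The pattern-fraction statistic ignores the magnitude of dysregulation
  beyond the call cutoff; two cohorts with identical call patterns are
  indistinguishable to it.
* With 398 × 4 paired markers and no multiplicity control on the headline
  p-values, the screen is a hypothesis generator; the q-value column and
  external validation are the guards against over-reading it.
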