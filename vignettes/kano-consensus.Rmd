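---
title: "Kano classification with consensus analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kano classification with consensus analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kanocca)
```

## The problem

Kano questionnaires measure how individual quality attributes of a product
or intervention relate to end-user satisfaction. Each respondent answers
two questions per attribute — how they would feel if the attribute were
present (*functional*) and if it were absent (*dysfunctional*) — on a
five-option scale from "I like it that way" to "I dislike it that way".
Each answer pair maps to one of six categories: must-be (M),
one-dimensional (O), attractive (A), indifferent (I), reverse (R) and
questionable (Q). The analytical difficulty is that individual
classifications for the same attribute are typically spread across several
categories, so the attribute-level verdict depends on the aggregation
rule. This package implements three such rules side by side, plus the
Timko importance coefficients and a Bayesian cultural-consensus layer that
asks whether the respondents share a single latent answer key at all.

The package's worked example is a published survey of 205 caregivers in
the Philippines rating 14 attributes of vaccine-confidence messaging
(`vaccine_messaging_manifest()`, `vaccine_messaging_results()`).

## Pair classification and tallying

`classify_pair()` is a total mapping over the 5×5 answer grid; its cell
census is A=3, O=1, M=3, I=9, R=7, Q=2. Attributes whose presence mostly
annoys respondents (modal reverse) are re-analysed as their own negation
by swapping the two questions (`recode_reverse()`, an involution); the
manifest's `reverse_recoded` flag triggers this at tally time and the
attribute id gains an `R` suffix (B4 → B4R).

Missing answers are excluded pairwise per attribute, so the effective `n`
can differ between attributes. The source study does not describe its
handling of incomplete questionnaires; pairwise exclusion is this
package's choice and matches per-attribute percentage reporting.

## The three attribute-level rules

* **Original (modal)** — the most frequent individual category wins.
* **Revised (Blauth)** — if (M+O+A) > (I+R+Q) the grade is max(M, O, A),
  otherwise max(I, R, Q).
* **Consensus (CCA)** — if the consensus model's posterior item truth
  exceeds 0.5 the grade is max(M, O, A), otherwise max(I, R, Q).

Three numerical conventions matter and are applied uniformly:

1. **Tie-break priority M > O > A > I > R > Q.** The published table
   contains one observable modal tie (A = I = 29 for the
   resource-information attribute) and it resolves to A, which this
   priority reproduces; the classical literature states no rule.
2. **Strict inequalities.** Equality — a pooled 50/50 split, or item truth
   exactly 0.5 — takes the low-relevancy branch. Every tie or boundary
   hit raises a `tie` flag (`classification_tie()`) so reports surface
   fragile classifications instead of silently resolving them.
3. **Counts, not rounded percentages.** Rules operate on raw counts in
   production. Printed percentage rows are accepted for fixture-style
   analyses, but rounding can flip the Blauth inequality: the
   trusted-messenger row's rounded percentages split exactly 50/50, so
   its published revised grade (M) is not reproducible from the printed
   table — the package returns I with the tie flag set.

## Timko coefficients

With per-category counts A, O, M, I (R and Q excluded throughout):

$$\mathrm{better} = \frac{A + O}{A + O + M + I}, \qquad
  \mathrm{worse} = \frac{O + M}{A + O + M + I}.$$

Both lie in [0, 1]; `worse` is reported as a magnitude, without its
conventional negative sign. Attributes answered entirely with R/Q have
undefined coefficients: `better_coefficient()` raises an error, and
`coefficient_table(undefined = "na")` emits an explicit `NA` marker
instead of a silent 0. The quadrant plane splits at 0.5 on each axis, and
coordinates exactly at 0.5 fall to the lower/left side. One published
attribute (shareability) has `better` exactly 0.5 on the rounded
percentages; the published figure shows it top-left, this package reports
it bottom-left with the boundary surfaced — a rounding artifact, not a
disagreement about the data.

## The General Condorcet Model

Individual categories are dichotomized into "relevant" bits (M, O, A → 1;
I, R, Q → 0; the `relevance_with_reverse` variant also counts R as 1 and
feeds the scree analysis, so respondents for whom an attribute matters
*negatively* still count as caring). The binary matrix is modelled by a
General Condorcet Model: respondent $i$ has competency $\theta_i$ and
guessing bias $g_i$, item $k$ has difficulty $\delta_k$ and latent truth
$z_k$, and with the Rasch-type effective accuracy

$$D_{ik} = \frac{\theta_i(1-\delta_k)}
  {\theta_i(1-\delta_k) + \delta_k(1-\theta_i)}$$

(the degenerate 0/0 case is defined as 0.5), the response law is

$$P(Y_{ik}=1) = \begin{cases}
  D_{ik} + (1-D_{ik})\,g_i & z_k = 1\\
  (1-D_{ik})\,g_i & z_k = 0.
\end{cases}$$

### Priors

Competencies and biases get hierarchical Beta priors
$\theta_i \sim \mathrm{Beta}(\mu_\theta \kappa_\theta,
(1-\mu_\theta)\kappa_\theta)$ with $\mu \sim U(0,1)$,
$\kappa \sim U(2, 200)$, and likewise for $g_i$; difficulties are uniform
and truths Bernoulli(0.5). The hierarchical choice is deliberate: with
only 14 binary observations per respondent, independent flat priors pull
every poorly informed posterior-mean competency toward 0.5, which
destroys cohort-level summaries (a grand mean near 0.49 regardless of the
generating value, in our simulations). Partial pooling lets the cohort
level be estimated from all respondents jointly and is what consensus
software in this tradition does. `prior = "uniform"` remains available.

### Sampler

`fit_gcm()` runs, per chain: exact Gibbs updates for each $z_k$; adaptive
random-walk Metropolis on the logit scale for every continuous parameter
(target acceptance 0.44, adaptation during burn-in only); a joint
$(z_k, \delta_k)$ *mode-jump* move proposing the flipped truth together
with a fresh difficulty from its prior, because the conditional Gibbs
update alone can lock a chain into one truth configuration; and *group
translation* moves that shift the whole $\theta$ vector (with
$\mu_\theta$) or the whole $g$ vector (with $\mu_g$) by a common logit
offset, because the posterior has a ridge coupling the overall competency
level, the bias level and the truth key, along which per-parameter walks
mix very slowly. Defaults are 3 chains × 10,000 samples after 2,000
burn-in; posterior means use every post-burn-in iteration, while thinned
draws (`thin = 10`) are stored for split-Rhat diagnostics and
posterior-predictive checks. Convergence is declared at split-Rhat < 1.1.
Per-chain seeds derive from one master seed, so a fit is bit-reproducible.

The item truth is the posterior mean of $z_k$; the binary truth value is
its indicator against 0.5 — an interpretation consistent with the
published table's two truth columns (0.69 → 1, 0.45 → 0), though the
source does not define the distinction explicitly. The implementation was
cross-checked against an independent JAGS formulation of the identical
model in the test suite; the two agree on item truths and cohort means on
a common fixture.

### What the model can and cannot recover

A caveat that shapes how cohort summaries should be read: at 14 items,
competency around 0.34 and difficulties reaching 0.9, the *answer key* is
still recovered sharply for easy-to-moderate items, but the cohort-level
competency/bias locations are weakly identified. Items that are relevant
but very hard generate "1" answers that the likelihood can almost equally
attribute to guessing, so posterior bias drifts upward and competency
compensates downward; simulating from published cohort estimates and
refitting lands near (0.30, 0.43) rather than (0.34, 0.34), and the same
happens under an independent JAGS fit of the same model. Point estimates
from this model family at this problem size are therefore not a
self-recovering fixed point, and small differences in reported cohort
means between studies should not be over-read. Hard, ambiguous-truth
items are exactly the ones the resilience analysis drops
(`resilience_rerun()`).

## Consensus-group detection

`scree_analysis()` omits zero-variance respondents (their correlations
are undefined), computes the respondent-respondent Pearson correlation
matrix across items, and examines its eigenvalue spectrum. The one-group
verdict requires both:

* a dominant first eigenvalue — first-to-second ratio at or above the
  threshold (default 3, the classical rule of thumb); and
* a *unipolar* first eigenvector: loadings sharing one sign (|loading|
  ≤ 0.1 treated as negligible; a bipolar split is declared when at least
  5% of respondents, and no fewer than 2, load in each direction). Two
  groups with strongly opposed answer keys are mutually anti-correlated
  and produce one dominant but bipolar eigenvalue, which a ratio-only
  rule would mistake for a single culture.

A regime caveat: with many more respondents than items (here 205 vs 14)
the correlation matrix has rank at most the item count, its ~14 nonzero
eigenvalues must sum to the respondent count, and the second eigenvalue
is inflated by sampling noise alone. The classical 3:1 rule of thumb
originates from factor analysis with communality-adjusted diagonals,
where noise eigenvalues are far smaller. At the case study's competency
level the raw-eigenvalue ratio of genuinely single-culture data sits
around 2.3–2.9, below 3: the threshold is conservative in this regime and
flags "≥ 2 groups" even when one group generated the data. The threshold
is configurable; the qualitative scree shape (one eigenvalue 2–3 times
the runner-up, then a flat tail) remains informative, and the
posterior-predictive check (`posterior_predictive_check()`, same
statistic) provides a calibrated alternative. We keep 3 as the default
because it is the field's stated convention, and report the raw ratio
alongside the verdict.

## Synthetic data

Two generators make every stage testable without external data:

* `fixture_from_percentages()` reconstructs a deterministic
  respondent-level survey from printed per-attribute percentage rows, one
  canonical grid cell per category (A → Like/Neutral, O → Like/Dislike,
  M → MustBe/Dislike, I → Neutral/Neutral, R → Dislike/Like,
  Q → Like/Like), so tallying round-trips exactly. Only rows whose
  percentages are integers summing to exactly 100 qualify; printed rows
  summing to 98–101 after rounding are rejected by name (8 of the case
  study's 14 rows qualify).
* `generate_gcm_survey()` draws a binary relevance matrix from the GCM,
  then emits a six-way category per cell from an `emission_model()`:
  high-relevancy bits draw from {M, O, A} (default equal thirds),
  low-relevancy bits from {I, R, Q} (default 0.8/0.1/0.1, echoing the
  empirical dominance of I). By construction the survey dichotomizes back
  to exactly the generated binary matrix. Canonical-cell placement keeps
  fixtures deterministic given the category; `cells = "uniform"` spreads
  pairs over all grid cells of the category for stress tests.
  `generate_two_culture_survey()` splits respondents between two answer
  keys for misfit and detection tests, returning culture labels for
  oracle checks.

`cohort_gcm_params()` encodes the study conditions: 205 respondents,
competency ~ Beta moment-matched to mean 0.34/sd 0.14, bias to mean
0.34/sd 0.172, the study's 14 binary truths and printed difficulties.
These are the package's fixed reference levels, not tuning knobs. What
the generators do **not** emulate: real response styles (acquiescence,
fatigue), within-respondent correlation beyond the single latent key,
sociodemographic structure, or item wording effects — so passing
parameter-recovery tests demonstrates internal consistency of the
model-and-fitter pair, not validity on arbitrary real surveys.

## Pipeline and problem sizes

`run_pipeline()` chains tally → original/revised classification →
dichotomization → scree → GCM fit → consensus classification → Timko →
optional resilience rerun, with stage-named error context, and a config +
seed fixes every reported number (`pipeline_config()` makes the seed
mandatory). `write_report()` emits full-precision CSVs plus a JSON
metadata echo; rounding happens only in the printed display, to avoid the
rounding traps above.

The test suite exercises study-scale runs (205×14, full MCMC settings,
five seeds) in its end-to-end checks and deliberately smaller
configurations (40–100 respondents, 6–20 items, shortened chains)
elsewhere; the small sizes were chosen so each property is still sharply
decided while the whole suite stays comfortably runnable on one CPU.

## Known limitations

* Cohort-level competency/bias are weakly identified at 14 items (see
  above); the eigenvalue-ratio threshold is conservative when respondents
  far outnumber items.
* The multi-culture verdict is detection only ("≥ 2"), not a mixture fit;
  no continuous-response consensus variants.
* No significance testing of modal classifications and no
  self-stated-importance weighting; classification fragility is surfaced
  through tie flags and the coefficient plane instead.
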