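---
title: "Methods: weight analysis and DerSimonian–Laird synthesis of path coefficients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weight analysis and DerSimonian–Laird synthesis of path coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaweight)
```

## The synthesis problem

Primary studies of technology acceptance estimate structural models in
which latent constructs predict one another: performance expectancy and
effort expectancy predict attitude and behavioral intention, intention
predicts actual use, and so on. Each study reports, for each path it
examines, a standardized regression coefficient β, a sample size n, and a
significance verdict. A synthesis across such studies must answer two
different questions:

1. **How consistently** does a predictor matter? — answered by *weight
   analysis*, which scores each path by the fraction of examinations in
   which it was significant.
2. **How strongly** does it matter on average? — answered by a
   *random-effects meta-analysis* of the effect sizes.

`metaweight` implements both, plus the publication-bias diagnostics and
theory-level reporting that normally accompany them.

## Data model and harmonization

The unit of input is a *path record*: one (dataset, predictor, outcome)
examination with β (possibly absent), n, a binary significance label, and
a country. The triple (dataset, predictor, outcome) is unique within a
corpus. Construct names are harmonized through a many-to-one alias map
(e.g. *perceived usefulness* → *performance expectancy*); resolution is
deliberately single-pass, so maps must be written in canonical-target
form — a chain `a → b`, `b → c` stops at `b`. This keeps `canonicalize()`
idempotent for well-formed maps and makes malformed maps visible rather
than silently transitive.

Only paths examined at least `min_examinations = 3` times enter either
analysis, the usual inclusion rule in weight-analytic synthesis. Records
without a usable β still count toward the weights but are excluded from
pooling; the two analyses therefore legitimately draw on slightly
different subsets (the packaged count table has E = 78 for performance
expectancy → behavioral intention while the packaged effect table pools
k = 77).

## Weight analysis

For a path with S significant results among E examinations, W = S/E.
Classification follows the standard thresholds, all boundaries inclusive:
*best* requires E ≥ 5 and W ≥ 0.800; *promising* requires E < 5 with
W = 1; *well-utilized* is any predictor with E ≥ 5; the residual class
(E < 5, W < 1) is unnamed in the weight-analysis literature's shorthand,
and we call it *experimental* so that the classification is a total
function. Weights are kept in full double precision and rounded to three
decimals only at the report layer.

## Effect transforms

Standardized βs are converted with the Peterson–Brown approximation
r = β + 0.05λ. Two conventions coexist in the literature: applying λ = 1
throughout, or zeroing λ for negative βs. The default here is λ = 1 for
**all** coefficients — matching the reference analysis the fixtures come
from — with `negative_lambda_zero = TRUE` exposing the original
convention. A conversion landing at |r| ≥ 1 is an error, never a silent
clamp: a standardized coefficient that extreme is a data problem the
analyst must resolve.

Fisher's transform z = atanh(r) stabilizes the variance; SE(z) =
1/√(n − 3). Because a printed SE column is merely a rounded derivative of
the (exact, integer) sample size, `read_effect_fixture()` recomputes SEs
from n by default. This choice is not cosmetic: with recomputed SEs the
Egger regression on the packaged table reproduces the published
coefficients to their printed precision, which shows the original
computation also used exact SEs.

## Pooling

Fixed-effect weights w = 1/SE² give the pooled z̄ and Cochran's
Q = Σw(z − z̄)². Between-study variance uses the one-step (non-iterated)
DerSimonian–Laird moment estimator

τ² = max(0, (Q − (k − 1)) / (Σw − Σw²/Σw)),

and random-effects weights 1/(SE² + τ²) give the pooled effect, its
standard error 1/√Σw*, a normal-theory CI (critical value 1.959964 at
95% — z, not t, matching the reference analysis's z scores and two-tailed
P values), and I² = max(0, (Q − (k − 1))/Q) × 100. Everything is
back-transformed to the correlation scale with tanh, which is monotone,
so interval bounds keep their order. Subgroup pooling re-estimates τ²
independently within each group: the reference analysis reports per-group
I², which implies separate heterogeneity models, and a common-τ² variant
is deliberately out of scope.

Degenerate inputs are handled explicitly: k < 2 is an error; identical
effects give Q = 0, τ² = 0 and a pooled value equal to the common effect;
Q ≤ k − 1 truncates τ² (and I²) at zero, collapsing the random-effects
model onto the fixed-effect one.

## Publication-bias diagnostics

The Egger test regresses the standard normal deviate z/SE on precision
1/SE by *unweighted* OLS — the variant produced by a spreadsheet
regression tool, which is what the packaged results were computed with —
with t-based inference on k − 2 df. An intercept with P < .10 flags
asymmetry. The weighted-Egger variant is out of scope.

Trim-and-fill follows the canonical rank-based formulation: estimate the
number k0 of studies missing from one flank (L0 estimator by default, R0
optionally), trim the k0 most extreme opposite-flank effects, re-estimate
the center on the trimmed set, iterate to stability (50 iterations
maximum, non-convergence is an error), then impute mirror images
(2 × center − z, donor's SE) and re-pool with random effects. τ² is
re-estimated on the augmented set — some implementations freeze it; we
document rather than hide the choice. The trimmed flank defaults to the
sign of the Kendall correlation between centered effects and SEs. On the
packaged 77-study table L0 estimates k0 = 0 (confirmed against an
independent implementation of the same procedure) while the conservative
R0 estimator imputes missing small-effect studies and shrinks the pooled
estimate, reproducing the directional statement published alongside the
table; the test suite exercises both.

Funnel data are emitted orientation-free (points, center, contours whose
half-width at SE s and level ℓ is q(ℓ)·s); plotting conventions — SE
increasing downward — are a rendering concern, not a data one.

## The synthetic-corpus generator

`generate_corpus()` draws, per study, a true effect
z ~ Normal(atanh(true_r), τ²), a sample size uniform on `n_range`, an
observed effect z_obs ~ Normal(z, 1/(n − 3)), reconstructs
β = tanh(z_obs) − 0.05 (so the conversion round-trips exactly), labels
significance by the two-tailed Fisher z test at α = .05, and suppresses
nonsignificant studies with probability `bias_prob`. The defaults are the
conditions of the packaged evidence base: true_r = 0.34, τ = 0.25 on the
z scale (the DL estimate on the packaged table is τ̂ ≈ 0.20), 77 studies,
n between 67 and 1292 (the observed range), no suppression.

What the generator emulates — and what it does not: it reproduces the
random-effects structure, the sample-size-driven precision, the binary
significance labelling, and one-parameter selective publication acting
only on nonsignificant studies. It does **not** model correlated paths
within a dataset, moderator-driven heterogeneity, heterogeneous test
procedures across primary studies, or reporting error. Passing recovery
and coverage tests therefore validate the estimator under the assumed
model, not against every pathology of real corpora.

The α = .05 z-test labelling is a deliberate simplification: primary
studies used heterogeneous tests, but only binary labels survive
extraction, and this choice makes the significant fraction analytically
checkable against the closed-form power of the z test.

## Problem sizes used in the test suite

The simulation-backed tests run at the sizes a desk check of this design
calls for: 500 replicate corpora (k = 77, τ = 0.25, n ∈ [100, 500]) for
estimator calibration and CI coverage, 200 replicates for the size of the
Egger intercept test under a symmetric null, and 20 seeds at
`bias_prob = 0.8` with 60 studies in a low-power regime (true r = 0.15,
n ∈ [30, 200]) for the selective-publication signature, chosen by power
analysis so that roughly two-thirds of generated studies are
nonsignificant and suppression bites.

## Known limitations and one data inconsistency

* DL confidence intervals under-cover at high τ²; the coverage test
  accepts 90–98% rather than nominal 95%.
* The Peterson–Brown conversion is an approximation; no attempt is made
  to reconstruct partial correlations from t statistics.
* REML, Paule–Mandel and Hartung–Knapp variants, meta-regression and
  multivariate pooling are out of scope.
* The packaged effect table's published companion row (overall pooled
  effect 0.339, Q = 1212.594, I² = 93.732) is internally inconsistent
  with the table itself: the published per-study Q components sum to
  1221.361, matching this package's computation (Q = 1221.385, pooled
  r = 0.337, I² = 93.778) to within the 3-decimal rounding of the
  inputs. The package reports what the table implies; the test suite
  keeps assertions against the published row as documented failures
  rather than widening tolerances to paper over the discrepancy. The
  printed per-study "z score" column matches no standard formula and is
  not reproduced.
* Statements in the published narrative that disagree with the published
  tables (a technology-characteristics path printed as .554 in prose and
  0.654 in the table) are resolved in favor of the pipeline's own output
  on the tabulated data.
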