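---
title: "Statistical implication analysis for binary outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical implication analysis for binary outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The implicative framework

Most association measures for binary variables — the correlation
coefficient, the chi-square statistic, odds ratios — are symmetric: they
return the same value whichever variable comes first. Many clinical and
developmental questions are not symmetric. Achieving one outcome (say,
independent work at the end of a treatment program) may in practice
entail having achieved another (symptomatic remission), while the
converse need not hold. The *statistical implication* of B by A is a
probabilistic version of logical implication: B is very often observed
when A is present, and counterexamples — subjects with A but without B —
are rare relative to what chance would produce. It is weaker than strict
logical implication (counterexamples exist, they are merely rare) and
must not be read as causality.

`implicate` analyzes a subjects-by-outcomes matrix of 0/1 variables: it
scores every ordered pair with a full-information implication index,
attaches bootstrap confidence intervals and significance, classifies each
unordered pair (reciprocal, one-way, none), assembles a directed
implication graph, optionally repeats the analysis within the levels of a
binary baseline stratum, and ships a synthetic-cohort generator with
planted implicative structure so the whole chain can be validated without
patient data.

## The index

For an ordered pair (A, B), let the fourfold table be `a` (both), `b`
(A without B — the counterexamples), `c` (B without A), `d` (neither),
with `n = a + b + c + d`. Cell probabilities are smoothed with a
per-cell pseudo-count $\alpha$ (default 0.5, the Jeffreys choice):
$\pi_{ij} = (n_{ij} + \alpha)/(n + 4\alpha)$, which keeps every cell and
margin strictly positive. The index is

$$
\iota_{A \Rightarrow B} \;=\; \frac{1}{2}\left[
\ln\frac{\pi_{11}\,\pi_{+0}}{\pi_{10}\,\pi_{+1}}
\;+\;
\ln\frac{\pi_{00}\,\pi_{1+}}{\pi_{10}\,\pi_{0+}}
\right].
$$

The first term compares the odds of B among subjects with A against the
marginal odds of B (direct evidence); the second compares the odds of
not-A among subjects without B against the marginal odds of not-A
(contrapositive evidence — "A implies B" is logically "not B implies
not A"). Both terms are penalized by the counterexample cell
$\pi_{10}$. The index is exactly invariant under the contrapositive
relabelling — `iota(a, b, c, d) == iota(d, b, c, a)` for every table —
which the test suite verifies as an identity, not approximately.

Properties of the definition, all property-tested:

* range $(-\infty, \infty)$ before smoothing, finite for every table
  after smoothing (including zero counterexamples and constant columns);
* 0 exactly when the smoothed table factorizes (e.g. any uniform table);
* strictly decreasing in `b` with the other cells fixed;
* asymmetric in magnitude: the two directions of a pair generally
  differ, and under a planted one-way implication the forward value
  exceeds the backward one in essentially every replication at the
  cohort scales used here.

There are no established anchors for what counts as a small or large
value; the package reports raw values, their intervals, and
between-direction comparisons only.

### A structural property worth knowing

Both bracket terms are positive exactly when the smoothed determinant
$\pi_{11}\pi_{00} - \pi_{10}\pi_{01}$ is positive (expand either
numerator-minus-denominator and the cross terms cancel). Hence

$$\mathrm{sign}(\iota_{A \Rightarrow B}) =
  \mathrm{sign}(\iota_{B \Rightarrow A})$$

for *every* table: the two directions of a pair always agree in sign and
differ only in magnitude, by
$\iota_{A\Rightarrow B} - \iota_{B\Rightarrow A} =
\ln(\pi_{01}/\pi_{10}) + \ln(\pi_{1+}\pi_{+0}/(\pi_{0+}\pi_{+1}))$.
The consequences for inference are discussed below; they are the
package's most important limitation to understand before reading its
output.

## The counterexample-rarity intensity

As a comparator, `gras_intensity()` implements the classical intensity
built from counterexample rarity alone: under independence the
counterexample count is approximately Poisson with mean
$\lambda = (a+b)(b+d)/n$, and the intensity is the upper-tail
probability $P(N \ge b)$, close to 1 when counterexamples are rarer than
chance predicts. It uses no contrapositive information, and it is
undefined when a margin is empty (`a + b = 0` or `b + d = 0`): a
constant variable carries no implicative information. The full
implication index remains finite there thanks to smoothing, but the
result is flagged `degenerate_margin`.

## Bootstrap inference

Subjects are the sampling unit. Each replicate redraws n rows with
replacement and recomputes the index on the replicate's fourfold table.
Because the statistic depends on the data only through the four cell
counts, redrawing rows induces exactly a multinomial distribution on
those counts; the implementation samples that multinomial directly,
which is two orders of magnitude faster than materializing index vectors
and distributionally identical. The test suite cross-checks it against
an explicit row-resampling implementation.

Defaults, chosen once: 2000 replicates (configurable; enough for stable
2.5%/97.5% quantiles), 95% percentile intervals, significance declared
when the interval excludes zero, no multiple-testing correction (a
Bonferroni option widens per-pair interval levels but is off by
default, matching common practice of reporting each directed test at the
0.05 level). Replicates in which a resampled column is constant are kept
— smoothing keeps the index finite, and rejecting them would bias the
interval — and their fraction is reported per result.

Calibration is validated by the shipped checks: under independence at
the reference scale (n = 219, margins 0.5/0.5, 1000 replicates) the
directed-pair rejection rate over 500 Monte-Carlo repetitions is
required to lie within 5% ± 2%, and `scripts/acceptance.R` recomputes
the same rate on demand.

**Seeding.** One root seed governs a run. Every (source, target,
stratum) triple hashes to its own substream, so results are invariant to
the order in which pairs are computed, and adding an outcome to the
analysis leaves all previously analyzed pairs bit-identical. Identical
data, configuration and seed give byte-identical output files.

### Percentile intervals and the sign-symmetry property

The percentile interval excludes zero on the positive side exactly when
fewer than 2.5% of replicates fall at or below zero. By the
sign-symmetry property, a replicate's index is non-positive in one
direction exactly when it is non-positive in the other — so under
percentile intervals, *significance is a symmetric property of the
unordered pair*. A pair is either reciprocal or unconnected; the
`forward_only` / `backward_only` classifications, while implemented and
reachable for results produced by other means, cannot arise from a
same-data percentile bootstrap with this index. Direction must be read
from the magnitudes (`iota_forward` vs `iota_backward` in
`classify_pairs()`, or the per-direction detection and ordering rates in
`recovery_experiment()`), not from one-sided significance.

We examined the obvious alternative, a normal-approximation interval
(estimate ± z × bootstrap SE, available as `ci_method = "normal"`). It
does break the symmetry, but in the wrong direction: the reverse
direction's counterexample cell is typically large, so its bootstrap SE
is small, and across a wide grid of realistic designs at n ≈ 200 the
reverse direction is flagged *more* often than the forward one. No
standard bootstrap interval on this index yields well-powered one-way
significance; an index whose two directions can differ in sign would be
required, and that is outside this package's pinned definition. The
percentile method was kept as the default because it is the standard
reading of "the 95% CI was checked for zero" and because it is the
best calibrated of the options.

## Pair classification and the implication graph

`classify_pairs()` labels each unordered pair `reciprocal`,
`forward_only`, `backward_only` or `none`, where only significant
results with *positive* index count as implications — a significantly
negative index is evidence against an implication and is excluded from
the graph (it remains in the results table). `build_graph()` keeps
exactly the significant positive directed results as weighted edges;
isolated outcomes remain as nodes. `export_graph()` emits DOT (edge
labels `ι=estimate [low, high]` at 3 decimals) or JSON
(`nodes` + `edges` arrays); both are deterministic text.

## The synthetic cohort generator

`cohort_spec()` defines root outcomes by baseline Bernoulli
probabilities and planted links by a conditional law: a link
(source → target, ε, q) sets P(target = 1 | source = 1) = 1 − ε and
P(target = 1 | source = 0) = q, so the planted direction and the
counterexample rate are explicit inputs rather than emergent properties.
Several links into one target combine by noisy-OR — the target fails
with probability ∏ε over links whose source is present, falling back to
q when none is — preserving "counterexamples are rare when any source is
present". The link graph must be acyclic; generation follows a
topological order. A latent-severity generator (thresholding a shared
continuous trait) would be a natural extension but makes the planted
direction ambiguous, which is why the conditional specification was
chosen. An optional binary stratum can override baseline probabilities
and link lists per stratum value, so an implication can be planted in
one subgroup only.

`hub_cohort_spec()` freezes a reference design emulating a three-year
early-intervention psychosis cohort at a realistic program scale
(n = 219):
four end-of-program outcomes — `working`, `living` (independently),
`symptomatic` (remission), `functional` (recovery) — with `working` as a
hub implying the other three, a tight symptomatic↔functional coupling
that presents as a reciprocal implication, and `living` as the weakly
coupled outcome. Outcome margins are documented placeholders:
P(working) = 0.36, consistent with per-stratum end-of-program working
rates of 51.6% among baseline workers and 25.5% among baseline
non-workers at a 40% baseline-work share; living ≈ 0.78, symptomatic ≈ 0.72,
functional ≈ 0.74, plausible for program completers with assertive
housing support. Counterexample rates: 0.12 (working→living, the weak
link), 0.05 (working→symptomatic), 0.10 (working→functional), 0.08
(symptomatic→functional). The stratified variant plants the
working→functional link only in the baseline non-working stratum,
mirroring a subgroup in which that implication fails to hold.

What the generator deliberately does *not* emulate: instrument scoring
and item overlap between scales (inputs are already dichotomized),
missing-data mechanisms (generated cohorts are complete; missingness
handling is exercised separately), demographic covariates, and any
longitudinal structure. Passing validation on these cohorts shows the
chain recovers known conditional-Bernoulli structure at this scale;
it cannot certify behavior under instrument artefacts real data may
carry.

## Numerical choices and degenerate inputs

* Smoothing α = 0.5 per cell everywhere, exposed as a parameter.
* Quantiles use R's default (type 7) interpolation.
* Degenerate tables (a constant column) yield finite indices, a
  `degenerate_margin` flag, `NA` intensity, and stay in the analysis.
* Strata with fewer than 2 complete rows are skipped with a warning,
  not an error; per-link baseline rates q into a shared target must
  agree, and cyclic link graphs are rejected at spec construction.
* CSV parsing maps configurable truthy/falsy/missing tokens and reports
  the exact row, column and token on failure.

## Validation scales

The shipped validation uses the cohort scale of the motivating design
throughout: n = 219 subjects; 500 Monte-Carlo repetitions × 1000
bootstrap replicates for type-I calibration (band 5% ± 2%); 100
repetitions for direction recovery under a planted link (ε = 0.05,
q = 0.5, source prevalence 0.5), requiring the forward index to exceed
the backward in ≥ 90% and forward significance in ≥ 80%; and a single
seeded hub-cohort run for the graph-level checks. These sizes keep the
full suite under half a minute on one core while leaving Monte-Carlo
noise well inside the asserted bands.

## Known limitations

* Directionality is magnitude-based, not significance-based, under the
  default inference (see the sign-symmetry discussion): graphs built
  from percentile-bootstrap results contain either both directions of a
  pair or neither. Reports should therefore quote both directed values.
* Percentile intervals can be slightly narrow at small n; no BCa or
  studentized intervals are implemented.
* The analysis is cross-sectional; nothing here orders events in time,
  and implication must not be read as causation.
* Complete-case analysis only; no imputation of missing outcomes.
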