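---
title: "Designing and optimizing tissue-culture media with vitropt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and optimizing tissue-culture media with vitropt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitropt)
```

## The problem

Micropropagation performance of woody plants depends strongly on the mineral
and hormone composition of the culture medium, and the responses of interest
pull in different directions: media that maximize shoot proliferation tend
to raise the incidence of shoot-tip necrosis and hyperhydricity and to lower
plantlet quality. vitropt implements a complete workflow for this problem,
built around the published study of two pear rootstocks (OHF 69 and
Pyrodwarf) in which six factors were varied — KNO3, NH4NO3, a grouped
meso-nutrient multiplier, a grouped micro-nutrient multiplier (all in
multiples of the standard MS formulation), and the hormones BA and IBA
(mg/l) — and five responses were recorded: proliferation rate (PR), shoot
length (SL), quality index (QI), shoot-tip necrosis (STN, %) and
hyperhydricity/vitrification (Vitri, %).

The workflow has four stages:

1. **Experimental design.** A six-factor, three-level Box–Behnken design
   (48 edge runs) spans the factor space economically.
2. **Surrogate modelling.** Each response is modelled from the design data
   by gene expression programming (GEP; symbolic regression over a fixed
   function set) and by M5' model trees (piecewise-linear regression
   trees), giving closed-form, inspectable models.
3. **Input ranking.** The Gamma test estimates, for any subset of inputs,
   the variance of the output noise that no smooth model could remove;
   comparing leave-one-out input subsets ranks the medium components by
   importance.
4. **Optimization.** A mono-objective genetic algorithm maximizes or
   minimizes one response at a time; NSGA-II and MOPSO search for
   Pareto-optimal media across all five responses simultaneously.

## The design module

`generate_bbd(6)` constructs the 48-run design from six three-factor
blocks, each crossed over all eight sign combinations with the remaining
factors at their mid level. The block incidence sets are packaged data,
chosen so the generated run set equals the published 48-row table exactly
(the test suite compares against a shipped transcription). Centre
replicates default to zero because the published table contains no all-zero
row; `center_replicates` adds them for standard response-surface use.
Constructions for 3, 4, 5 and 7 factors use the standard
balanced-incomplete-block templates.

Coded-to-actual conversion is piecewise linear about the mid level, because
two factors have asymmetric level triples (micro-nutrients 0.5/2.25/4).
The printed mid level of IBA is 0.13; the package stores the exact midpoint
0.125 and treats 0.13 as display rounding (configurable via
`pear_factors(iba_mid = 0.13)`).

## Gene expression programming

Chromosomes are three genes of head length 8 (tail length 9), decoded
breadth-first (Karva order) into expression trees over the terminals A–F
and a per-gene pool of ten random numerical constants on [-10, 10], and
linked by addition. The function set is the published sixteen-operator set
(+, -, *, /, sqrt, cbrt, sin, cos, arctg, square, cube, exp, ln, inverse,
tanh, two-input average). Operator rates follow the published training
setup: mutation 0.044, inversion 0.1, one-point recombination 0.1,
two-point 0.3, gene recombination 0.1, gene transposition 0.1. Fitness is
the root relative squared error (RRSE), zero for a perfect fit and one for
the mean predictor.

Choices the published setup leaves open, and what this package does:

* **Protected arithmetic.** Division by values below 1e-12, ln(0) and
  inverse(0) return a sentinel (`NA`) that gives the individual
  worst-possible fitness; ln and sqrt act on the absolute value of their
  argument; exp is clamped at exp(700). This keeps every genotype
  evaluable, the standard practice in symbolic regression.
* **Selection.** Roulette wheel on fitness 1000/(1 + RRSE) with single
  elitism by default; tournament-2 (`selection = "tournament"`) applies
  much stronger selection pressure and is usually the better choice for
  recovery benchmarks.
* **Head sampling.** Head symbols are drawn with equal probability mass on
  the function class and the terminal class. Sampling uniformly over the
  23 individual symbols makes a head position a function 70% of the time,
  which buries the additive structures polynomial surfaces need.
* **Linear scaling** (`linear_scaling = TRUE`, default). Each candidate is
  scored after an optimal affine rescaling of its output (two constants by
  least squares), which are folded back into the returned expression. This
  relieves the search of output-scale constant tuning without changing the
  model class.
* **Gene-wise least squares** (`gene_ols = FALSE` by default). As an
  option, the three gene sub-trees can be treated as discovered basis
  functions whose linker weights are set by least squares. The default
  stays plain addition — the linker of the published setup — but additive
  polynomial surfaces are recovered far more reliably with the option on,
  and the synthetic end-to-end tests use it.
* **Constant polish.** Each generation, a handful of hill-climbing
  proposals perturb the incumbent's constant pools and are accepted only
  when RRSE improves.
* **Stopping.** 500 generations or RRSE below 1e-6, whichever first.

Elitism makes the best-RRSE trace non-increasing, which the tests assert.

## M5' model trees

Trees are grown by choosing, at each node, the attribute/threshold split
maximizing the standard deviation reduction

    SDR = sd(T) - sum(|Ti|/|T| sd(Ti)),

with population (n-denominator) standard deviations, since the splitting
criterion carries no Bessel correction. Candidate thresholds are midpoints
between adjacent observed values. Growth stops when a node holds fewer than
`2 * min_instances` rows (default 4 per leaf) or its response sd falls
below 5% of the root sd. Pruning replaces a subtree by a single linear
model whenever the complexity-penalized error estimate
`err (n + v)/(n - v)` does not increase; ties at numerical precision favour
the simpler model, so exactly linear data collapse to one exact leaf.
Smoothing is off by default so that exported rules equal the leaf models
coefficient for coefficient, matching the flat coefficients of the
published rule sets.

One caveat worth knowing: the SDR criterion sees a regime change only when
it shifts the response *distribution*. A symmetric hinge (slopes -1/+1
through zero) leaves the response distribution identical on both sides of
the kink, so the root split lands elsewhere; a level-shifted break is
localized to within one grid step, and the recovery tests use that form.

Rule sets are ordered and evaluated first-match; the final rule must be
unconditional. The published rule tables end in progressively weaker
conditions, and the printed last rule of the necrosis panel carries a
condition (`C <= 1`) that does not complete a partition of the factor
space; the fixture keeps its model as the default rule and records the
printed condition in a note.

## The Gamma test

For a dataset (x_i, y_i), i = 1..M, and each neighbour order k = 1..p, the
module computes the mean squared distance to the k-th nearest neighbour in
input space, delta(k), and half the mean squared difference of the
corresponding outputs, gamma(k); the intercept of the least-squares line
gamma = A delta + Gamma estimates the variance of the output noise, and
the slope A indexes model complexity. Inputs are min-max standardized to
[0, 1] before the distance computation (the convention of the Gamma-test
literature); the output is left unscaled so Gamma is in output-variance
units. Negative intercepts are legitimate sampling outcomes and are never
clamped.

The neighbour count defaults to p = 10 (the community convention; the
published tables do not state theirs). Exactly coincident input rows make
the k-th neighbour ill-defined and raise an error by default;
`allow_ties = TRUE` switches to deterministic index-order tie-breaking,
which the pipeline uses because masking a factor out of a designed
experiment always projects distinct runs onto duplicate rows.

Input importance is ranked by leave-one-out masks: removing an important
input raises Gamma the most (its information cannot be reconstructed from
the remaining inputs). Because the published per-output Gamma tables came
from replicate-level data that is not printed, with an unstated p, only
ranking-level behaviour is checked in the tests, on data with known
structure.

## Optimizers

All optimizers work over box bounds in actual units; the pear bounds are
the experimental ranges (KNO3/NH4NO3 0.5–2, Mesos 0.5–2.5, Micros 0.5–4,
BA 0.5–3, IBA 0.05–0.2). The published multi-objective media list IBA
0.02, below the experimental range, so reproduction runs widen the IBA
bound (`pear_bounds(iba_low = 0.02)`).

* `ga_optimize()` is a real-coded GA (tournament selection, blend
  crossover, gaussian mutation with reflection at the bounds, elitism)
  plus a small clamped local search around the incumbent so boundary
  optima are reached exactly.
* `nsga2_optimize()` is the canonical multi-objective GA (fast
  non-dominated sorting with crowding-distance selection); the published
  study names its method only "multi-objective GA", and NSGA-II is the
  standard choice.
* `mopso_optimize()` keeps an external archive of non-dominated solutions,
  pruned by crowding distance at capacity; leaders are drawn by binary
  tournament on crowding distance so sparse regions of the front attract
  the swarm. The velocity update is the textbook form
  v' = w v + c1 r1 (pbest - x) + c2 r2 (gbest - x) with w = 0.9 and
  c1 = c2 = 2 inside the stated coefficient ranges; positions are clamped
  to the bounds with velocities zeroed at clamped coordinates.
* `select_representative()` picks one medium from an archive by maximizing
  a weighted sum of direction-normalized, min–max-scaled objectives. The
  published study reports a single medium per method without stating the
  selection rule; this scalarization is a documented stand-in.

Population sizes and iteration counts are not stated in the source study;
the defaults are 100 individuals/particles and 250 iterations. Predicted
STN and Vitri are clamped below at zero when reported (negative
percentages are not physical); raw model values remain available.

## The synthetic-data generator

`make_truth_surface("pear-like")` draws five quadratic response surfaces
over the six factors with magnitudes matching the real responses (PR ~0–13,
SL ~0–10, QI 0–5, STN/Vitri 0–100, clipped). Each surface follows the
effect-sparsity assumption standard in response-surface work: three active
main effects, curvature on two of them, and one two-factor interaction.
That choice also keeps the truth within reach of a three-gene, head-8
chromosome (a dense 15-term quadratic is not expressible in ~12 additive
terms, so no engine of this architecture could recover it).
`simulate_responses()` adds gaussian replicate noise after clipping, so
near-zero percentage responses can straddle zero the way near-zero necrosis
observations do, and returns both replicate-level values and treatment
means. Identical seeds give bit-identical datasets.

What passing tests on synthetic data do show: the full pipeline — design,
fitting, ranking, optimization — recovers known smooth, sparse, quadratic
ground truth at the study's sample size (48 treatment means). What they do
not show: behaviour under model misspecification (real dose–response
relationships are not exactly quadratic), non-gaussian or heteroscedastic
replicate noise, and measurement artefacts such as ordinal scoring of the
quality index.

## The published model fixtures

`get_model(rootstock, output, kind)` returns the transcribed published
models: ten GEP equations and ten M5' rule sets.
`predict_media_response()` evaluates all five responses of one rootstock
at a medium, handling the two letter conventions (the equation table maps
A = NH4NO3, B = KNO3; the rule table swaps the first two).

The typeset equations use stacked fractions and superscripts that survive
text extraction only as flattened juxtapositions ("E2", "9.3446A",
"(3.1775-C3)2"). Every equation was therefore reconstructed by enumerating
candidate readings of each ambiguous token (power, product, quotient and
digit-splitting interpretations) and adopting the reading that best
reproduces the printed anchor values: the mono-objective optimum of that
response (printed to 4–5 significant digits at 4-decimal inputs) and the
two multi-objective media predictions (printed to 2 decimals at 2-decimal
media). Each fixture's `note` field records its anchors and residuals.

Two precision floors limit what any reconstruction can achieve. The
optimum inputs are printed to four decimals, so a model with gradient g
can deviate by about `0.00005 * sum |g|` at the re-evaluated optimum; for
the steep percentage-scale models that is several hundredths. The media
are printed to two decimals, so re-evaluated predictions carry roughly
`0.005 * sum |g|` of rounding noise — 0.01 to 0.1 depending on the model.
The adopted readings reproduce the six PR/SL/QI optima at 1e-5 to 2.5e-3
relative and the media predictions to within a few hundredths, which is at
or near those floors; the near-zero STN/Vitri optima (0.0001–0.02 on a
percent scale) sit below them. The acceptance suite asserts the printed
tolerances verbatim, so the expectations beyond the floors fail loudly
rather than silently, with the residuals documented here and in the
fixture notes.

The published rule tables print identical SL, QI, STN and Vitrification
rule sets for both rootstocks (only PR differs); the fixtures record this
verbatim and flag it in their notes, as it is likely a typesetting
duplication.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit seed; the pipeline derives
per-stage child seeds from one global seed, so stages can be re-run
independently yet reproducibly, and identical configurations produce
byte-identical artifacts. The test suite exercises the recovery benchmarks
at deliberately modest sizes — 48-run designs, 150–500-point Gamma-test
samples, 40–100-member populations, 200–800 generations, best-of-two or
best-of-five seed sweeps — which complete in a few minutes while leaving
comfortable margins on every asserted property.

## Known limitations

* GEP with the published three-gene architecture approximates dense
  response surfaces only coarsely; the engine options (`tournament`
  selection, `gene_ols`) are there for users who want recovery rather
  than fidelity to the published configuration.
* The Gamma test needs replicate-scale sample sizes to estimate noise
  variance accurately; at 48 treatment means its value is ranking, not
  estimation.
* The fixtures are faithful to the printed models only up to the printing
  precision of their anchors, as quantified above, and are not
  biologically meaningful outside the experimental region.
* Box bounds are the only constraint type; mixture or budget constraints
  on media composition are out of scope.
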