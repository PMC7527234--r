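---
title: "Scoring, ranking and evaluating embryo cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, ranking and evaluating embryo cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryorank)
```

## The model

Each embryo in a patient cohort carries a five-class morphology
probability vector $p \in \Delta^4$ from an upstream classifier (the
softmax over ordinal day-5 quality classes 1–5; classes 1–2 are
non-blastocysts, 3–5 blastocysts, and class 5 alone meets the freezing
criterion). The transfer score is the linear functional

$$s(p) = w^\top p,$$

and within a cohort embryos are ranked by $s$, the top-1 being the SET
pick and the top-2 the DET picks. Because every $p$ sums to one, adding
a constant to all five weights shifts every score equally: only the
*relative* weights matter for ranking, and any linear rescaling of the
classifier output common to all embryos preserves the within-cohort
order. (A nonlinear monotone rescaling, such as moving between logits
and softmax probabilities, does not in general; this package scores
probabilities throughout.)

Score ties are broken by the lowest embryo index in the cohort's input
order. This makes every ranking, fitness value and selection a
deterministic function of its inputs; it matters mainly for degenerate
inputs (identical probability rows, all-zero weights) and is exercised
directly by the tests.

## The genetic algorithm

`ga_evolve()` learns $w$ from labelled training cohorts in four phases
per cycle:

* **Fitness.** For each cohort, score all embryos, take the argmax, and
  add one point iff the picked embryo's true class equals the highest
  class present in that cohort. Fitness is an integer in
  $[0, n_\text{cohorts}]$.
* **Selection.** The `elite_count` (default 20) highest-fitness
  specimens survive, ties broken by earlier index.
* **Crossover.** Elites are paired by uniform random sampling without
  replacement; each pair, with probability `crossover_prob` (default
  0.20), swaps the components flagged by a random binary 5-mask (each
  bit set with probability 0.5, configurable); offspring replace their
  parents in the elite pool.
* **Mutation.** Each (post-crossover) elite spawns
  `mutants_per_specimen` (default 5) mutants by adding a perturbation
  whose components are non-zero with probability `mutation_prob`
  (default 0.20) and then uniform on `[mutation_low, mutation_high]`
  (default $[-1, 1]$).

The stated mechanism sizes (20 elites, each with 5 mutants) produce 120
candidates against a population size of 100. We rebuild each generation
as the 20 elites plus their 100 mutants and remove the surplus uniformly
at random **from the mutants only**, so elites always survive. Keeping
the elites deterministically is what makes the algorithm properly
elitist: with crossover and mutation switched off, the best fitness is
provably non-decreasing across generations, a property the test suite
asserts. A `keep_overflow` flag disables the truncation entirely.

Initialization draws every component uniformly from
`[init_low, init_high]` (default $[-10, 10]$, spanning the magnitude of
the published weights); mutation is a local perturbation an order of
magnitude smaller. Both ranges are configurable.

The run stops when the whole population attains a single fitness value,
or after `max_generations` (default 1000) cycles; the returned specimen
is drawn uniformly at random from the final population and the result
records the generation count, convergence flag and best-fitness trace.
In practice, on cohorts with realistic classifier noise the best fitness
plateaus within a few dozen generations while mutation keeps the
population's fitness spread slightly above zero, so the convergence
test rarely fires and the cap is the usual stopping rule; the random
final draw then still lands within a point or two of the best specimen
because the population is concentrated around the elites.

All randomness flows through R's generator, seeded once on entry from
`config$seed`; two runs with the same seed are identical to the last
bit.

## Training data and identifiability

The clinical eligibility rules for *evaluation* cohorts — 2–12 embryos,
at least one of blastocyst class — are enforced by the generator and the
table validator when `eligibility = TRUE` (the default). Training sets,
however, should be generated **unfiltered** (`eligibility = FALSE`): if
every training cohort contains a blastocyst, the fitness target (the
highest class available) is always a class-3+ embryo, and the objective
is exactly invariant under swapping the class-1 and class-2 weights —
their order is unidentifiable and ends up random. Cohorts whose best
embryo is a non-blastocyst are precisely the ones that pin down the
non-blastocyst end of the weight vector. The package's training
protocol (used by the `demo` subcommand and the tests) therefore trains
on unfiltered cohorts and evaluates on eligibility-filtered ones.

## The synthetic generator

`synth_cohorts()` emulates the statistical structure of a clinical
selection study; all of its calibration targets are plain config fields:

* **Cohorts.** `n_cohorts` (default 97) cohorts of uniform size 2–12.
* **Class mix.** Default `(0.25, 0.25, 0.20, 0.15, 0.15)` over classes
  1–5: about half of fertilized embryos reaching blastocyst stage by
  day 5 is a realistic blastulation rate, and every class keeps well
  over 10% mass so all five weights see training signal.
* **Classifier.** Given a true class $k$, the probability vector is
  Dirichlet with concentration $c$ on class $k$ and
  $\mathrm{decay}^{|j-k|}$ (decay default 0.5) on wrong classes $j$ —
  the adjacency-banded confusion structure of an ordinal grader, under
  which higher true class gives stochastically higher-class probability
  mass and a monotone weight vector is the right answer. With
  exchangeable wrong-class mass (decay 1) that is *not* true: sacrificing
  the few cohorts whose best embryo is class 3 can then pay for many
  top-class-4/5 cohorts and the in-sample optimum is frequently
  non-monotone, which we observed directly before adopting the banded
  structure. The concentration is calibrated by bisection (tolerance
  0.005, Monte-Carlo size $10^4$ under a fixed internal seed, marginal
  over the class mix) so the argmax accuracy matches
  `target_argmax_accuracy` (default 0.91).
* **Outcomes.** Implantation is Bernoulli with a logistic model in
  class, slope `class_logit_slope` (default 0.5 log-odds per class) and
  the intercept solved numerically so the marginal rate among
  transferred blastocyst-class embryos equals
  `blastocyst_implantation_rate` (default 0.441). Blastocysts are
  transferred with probability `transfer_prob` (default 0.6);
  non-blastocysts are never transferred by the generator, so their
  outcomes stay unknown and the evaluator's exclusion logic is
  exercised, mirroring the partial-outcome structure of clinical data.
* **Raters.** Each of `n_raters` (default 15) simulated embryologists
  gets an accuracy drawn uniformly from `rater_accuracy_range` (default
  0.64–0.70) and calls each known outcome correctly with that
  probability, independently per embryo.
* **Potentials.** Implantation potentials are Beta-distributed given
  the outcome — shapes `(4, 2)` for implanted and the mirror `(2, 4)`
  for failed embryos — so scores near 0.5 are the least informative
  band, and the expected implanted fraction of any score bin has a
  closed form through `pbeta` that the tests compare against.
* **Euploid mode.** `synth_euploid()` restricts true classes to
  {4, 5}, transfers everything, balances outcomes 50/50 (the prevalence
  of a screened single-transfer set is a modelling choice, not an
  inference) and attaches potentials.

Every generator output is a pure function of `(config, seed)`.

## Evaluation statistics

* **Exact intervals.** `clopper_pearson()` inverts the incomplete beta
  function (`qbeta`), with the closed-form endpoints at 0 and $n$
  successes; it agrees with `binom.test` to $10^{-10}$ in the tests.
* **Selection accuracy.** SET is judged on the top pick; DET is correct
  when *at least one* of the two picks satisfies the criterion. The
  at-least-one rule is the only reading under which DET accuracy is
  guaranteed to dominate SET accuracy, which is the pattern such
  studies report; the stricter both-picks rule is available as
  `det_rule = "both"`. Cohorts in which no embryo can satisfy the
  criterion (e.g. no class-5 embryo under the HQB criterion) are judged
  against the highest-available-class fallback and reported as a
  separate stratum rather than silently merged. Under the
  highest-available-class criterion, SET selection accuracy times the
  cohort count equals the GA's fitness — a cross-module identity the
  suite checks.
* **ROC/AUC.** The AUC is computed as the tie-corrected rank statistic
  (midranks), identical to exhaustive pairwise concordance, and the
  curve is swept over all distinct thresholds. The interval is a seeded
  stratified bootstrap (default 2000 resamples, percentile, clipped to
  cover the point estimate in degenerate corners); an asymptotic
  normal (Hanley–McNeil) interval is the alternative. The bootstrap was
  preferred as the default because it is distribution-free at the small
  evaluable sample sizes typical here (tens of outcomes).
* **Rater comparison.** A two-sided one-sample t-test of the rater
  accuracies against the reference system accuracy, with the t-based CI
  of the rater mean. A zero-variance panel (reachable on synthetic
  data) reports $p = 1$ with a `degenerate_variance` flag instead of
  failing.
* **Score bins.** Implanted fractions below 0.33, within 0.33–0.66 and
  above 0.66, plus the at-or-above-0.80 band reported separately and
  flagged as overlapping so totals are never double-counted; the
  summary of miscalled embryos reports the fraction of their scores in
  the low-confidence 0.51–0.63 band.

## Numerical and degenerate-input choices

Probability rows summing to within $[0.99, 1.01]$ are renormalized
(tolerating rounded text files); anything further off is rejected with
its line number. Implantation calls use `potential >= threshold` with
the default threshold 0.5, the point of minimal confidence; 0.47 is a
meaningful alternative operating point and the threshold is everywhere
a parameter. Empty score bins report an undefined fraction with a zero
count rather than NaN arithmetic.

## Problem sizes used by the test suite

The suite trains the GA on 200 synthetic cohorts and evaluates on 97
held-out cohorts across 20 seeded replicates (capped at 150 generations,
past the observed fitness plateau), calibrates the classifier on $10^4$
draws and the implantation rate on $10^4$ embryos, and checks the AUC
against exhaustive pairwise enumeration on instances of up to 12 items.
These sizes were chosen as the smallest at which the measured quantities
are stable against their asserted bands.

## Limitations

The generator reproduces marginal rates and the ordinal error structure
of a day-5 morphology classifier, not real image features: its
probability vectors are conditionally Dirichlet, its implantation model
is a single-covariate logistic in class, and its potential distributions
are sharper than a real implantation classifier (synthetic AUCs run
near 0.95 where clinical reports sit near 0.77). Passing tests
therefore demonstrate the correctness and calibration of the algorithms
— not clinical performance, which can only be established on real
cohorts with verified outcomes. Ploidy-aware re-ranking, transfers of
three or more embryos, and any use of sub-grades (expansion, ICM/TE
letters) are out of scope; the classifier itself is a pluggable
probability source and is not modelled.
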