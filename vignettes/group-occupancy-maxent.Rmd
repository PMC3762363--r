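---
title: "Methods: maximum entropy analysis of group occupancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum entropy analysis of group occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupmaxent)
```

## The data model and its assumptions

The package works on discretized occupancy series: T time bins, N animals,
each entry a zone code in 1..Z. The joint *configuration* at bin t is the
vector of all animals' zones. Three assumptions underlie everything
downstream:

* **Exchangeable bins.** All estimators are plug-in functionals of the
  empirical configuration distribution; temporal order within a session is
  ignored (train/test splits randomize bins, dwell-time statistics are the
  one deliberate exception). Modeling temporal correlation is out of scope.
* **Complete tracking.** The reader rejects missing entries. Imputing
  tracking gaps would silently distort the configuration distribution the
  whole analysis rests on, so gaps must be resolved upstream; this is a
  deliberate, documented strictness.
* **Enumerable state space.** All fitting, sampling and comparison work on
  the exact Z^N probability table; a guard (10^7 states) refuses larger
  systems rather than switching to approximate inference, which is a
  non-goal. For temporally structured simulation of large systems,
  `sample_markov_series()` never enumerates the table beyond conditionals.

Working at a coarser bin than the raw acquisition rate (e.g. 240 ms over
40 ms frames) makes single-frame tracking noise irrelevant; `rebin()` takes
the modal zone per bin, breaking ties by the zone occupied earliest within
the bin (a deterministic, order-respecting rule that keeps rebinning
idempotent on blockwise-constant data).

## Information quantities

All logarithms are base 2; every output is in bits. Entropies, mutual
information, the fraction of one animal's location uncertainty readable from
a set of others, and the multi-information

$$I_N = \sum_i H(x_i) - H(x_1,\dots,x_N)$$

are plug-in estimates with no finite-sample bias correction. This is a
fidelity choice: the intended regime is T of order 10^5 bins per session,
where plug-in bias on the reported quantities is small relative to the
effects of interest, and a correction would change the meaning of the
decomposition identities below, which hold *exactly* for plug-in estimates.
Distributions carry their `sample_count` so users can assess bias (e.g. by
the shuffling analysis described under "noise floors"). Mutual-information
values that come out a rounding error below zero are clamped to 0.

## The maximum entropy hierarchy

The order-k model p⁽ᵏ⁾ is the unique maximizer of entropy among all joint
distributions reproducing every empirical marginal over animal subsets of
size ≤ k. It has the log-linear (Potts) form with one indicator feature per
subset–zone combination; `maxent()` parameterizes log₂ p as a sum of
parameter blocks, one array per animal subset.

* `order = 1` is computed as the product of single-animal marginals (closed
  form, no iteration).
* `order = N` is the input distribution itself — the chain endpoint
  H[p⁽ᴺ⁾] = H holds by construction.
* Intermediate orders are fitted by **generalized iterative scaling**
  (multiplicative per-subset updates, accumulating log-factors into the
  parameter blocks) followed, if needed, by **exact-gradient ascent** on the
  dual (average log₂-likelihood) with backtracking line search. Convergence
  is declared when the worst absolute deviation between a model marginal and
  its constraint is ≤ `tol` (default 10⁻⁶, exposed in `maxent_control()`;
  identity-sensitive tests tighten it to 10⁻⁹). These tolerances and
  iteration caps are engineering choices, all surfaced in the control
  object.

`decompose()` fits the whole hierarchy and reports
I₍ₖ₎ = H[p⁽ᵏ⁻¹⁾] − H[p⁽ᵏ⁾]; the telescoping identity ΣI₍ₖ₎ = I_N then holds
to floating-point accuracy, and the entropy chain is monotone up to the
convergence tolerance.

### Zero marginal cells

A zero cell in a constraint table sends its parameter to −∞. When any
constrained cell falls below 1/(10T), all constraint tables are mixed with
the uniform distribution using one **common** weight w = Z^order/(10T), the
smallest weight that lifts every cell of the highest-order tables above that
floor. The floor sits at or below sampling noise (a cell that small has at
most a handful of counts), so the perturbation is statistically negligible;
the common-weight form matters because mixed tables remain exact marginals
of the single mixed joint (1−w)p + w·uniform — flooring cells per table
would leave the constraint set without any exactly-satisfying distribution
and stall the scaling algorithm above tolerance. Analytic inputs (tables
with `sample_count = 0`) use a 10⁻¹² floor, and dense inputs are never
perturbed at all.

### Gauge

Indicator features sum to one per animal, so the parameterization is
over-complete: the fitted distribution is unique, the parameters are not.
`coef(model, gauge = "zero.sum")` returns the unique representative in
which every block sums to zero along each zone axis, computed as the ANOVA
(effects) decomposition of log₂ p — well-defined whenever the table is
strictly positive, and the form in which interaction signs and strengths are
comparable across models and groups. The L1 fit (below) is reported in its
own implicit gauge instead, because its scientific content is the exact-zero
pattern the penalty selects.

## Sparse interaction maps

With `epsilon > 0`, `maxent()` maximizes the penalized dual
(average log₂-likelihood − ε·Σ|λ|, the lasso penalty taken over *all*
parameter blocks, singleton fields included — unusual, but kept as the
convention this analysis family prints). The solver is proximal-gradient
(soft-threshold) FISTA with backtracking, adaptive restart and a monotone
safeguard, stopped on the KKT residual of the penalized problem; the
soft-threshold step produces exact zeros. The default ε₀ = 2⁻¹⁶ is the
conventional operating point of this analysis family; `sparsity_curve()`
traces the accuracy/sparsity tradeoff (divergence to the unpenalized fit,
fraction of exact zeros per order) so users can choose their own.

Two caveats that the package's own experiments quantify, and that users of
interaction maps should know:

* **Zero patterns are gauge-dependent.** Because the parameterization is
  over-complete, a sparse generating representation need not be the
  minimal-L1 representation of its own distribution; entry-level support
  recovery against "planted" zeros is therefore ill-posed in general, and
  the package's acceptance experiment documents the measured gap. Ranked
  coupling *strengths* (the interaction map) are the robust readout.
* **Support is not monotone along the penalty path.** As ε grows and
  couplings are removed, previously-zero singleton fields can re-activate to
  compensate; the fraction-zero curves of the interaction orders are
  monotone in practice, the tiny singleton block need not be.
* At penalties far below the sampling noise of a marginal cell
  (≈ √(p/T)), noise-driven parameters cannot be thresholded to zero; exact
  zeros in that regime mark only the constraints the optimizer could satisfy
  for free.

`interaction_map()` lists nonzero couplings ranked by |strength| with
deterministic tie-breaks; "dominant" interactions are whatever `top_k` or
`threshold` the user sets — the package deliberately exposes both rather
than fixing a selection rule.

## Model evaluation

`split_train_test()` halves the bins at random by seed;
`evaluate_model()` compares a model fitted on one half with the raw
empirical probabilities of the other (no smoothing of test-set
probabilities), reporting the base-2 Jensen–Shannon divergence and the
fraction of observed configurations whose model probability falls inside the
per-state 95% **Wilson score** interval at the test sample size — the
"confidence funnel" of the model-versus-data scatter that `plot()` draws.
The Wilson interval is an explicit choice (well-behaved at small counts)
documented so the coverage statistic is reproducible.

### Noise floors

Finite samples put spurious weight into every order of the decomposition.
The package's convention for calibrating this is `shuffle_animals()`:
permuting time bins independently per animal preserves each animal's
marginal exactly while destroying all inter-animal structure, so the
decomposition of a shuffled series measures the pure finite-sample floor;
higher-order contributions of real data are interpreted against it.

## The synthetic generator

`generator_spec()` defaults describe the study conditions the package is
designed around: N = 4 animals, Z = 10 zones, 12-hour sessions at 240 ms
bins (180,000 bins), heterogeneous individual zone preferences, sparse and
predominantly negative couplings, and power-law-like dwell times.
Where the emulated setting fixes no value, defaults were chosen once as
field-plausible and documented here:

* Singleton fields are N(0, `preference_concentration`²) with default sd 1
  in log₂ units, giving occupancy histograms with roughly an order of
  magnitude between preferred and avoided zones.
* Couplings are exactly zero with probability `sparsity` = 0.8; nonzero
  entries are `scale`·N(−1, 0.75): mostly negative (suppressed
  configurations), with a minority of weaker positive couplings.
* The dwell-time law is a discretized Pareto truncated at the session
  length; its tail exponent is a free choice, default 2.0.

Two sampling dialects exist because exact stationarity and power-law dwell
times cannot both hold in one simple chain: `"gibbs"` (single-animal
resampling from the model conditional) is stationarity-preserving and is
used wherever tests need the empirical law to converge to the model table;
`"semi-markov"` draws per-animal Pareto dwell durations with destinations
from the model conditional, reproducing realistic dwell statistics at the
price of only-approximate stationarity. `simulate()` gives plain i.i.d.
draws.

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: temporal correlation beyond dwell persistence,
circadian/day structure and non-stationarity across a session, tracking
noise and identity swaps, and any physical-exclusion geometry of a real
arena. Tests certify the estimators and fitting machinery on data whose
ground truth is known, not the ethology.

## Group comparison

Animal labels are arbitrary, so `min_permutation_distance()` minimizes the
Jensen–Shannon divergence over all N! relabelings (exhaustive, hence exactly
optimal, guarded at N ≤ 8; ties broken by the lexicographically smallest
permutation for reproducibility). `similarity_matrix()` applies this
pairwise; following the convention of this analysis family, cohort
comparisons use the regularized third-order model distributions fitted on
full sessions at the default ε₀ (a flag allows raw empirical tables for
diagnostics). Day boundaries are input annotations (`cohort_summary()`
arguments), never inferred from timestamps. Statistical testing of cohort
differences is out of scope.

## Problem sizes used by the test suite

Chosen to exercise every property at full strength while keeping the whole
suite fast to run routinely:

* simplex-oracle equivalence: all systems with N ≤ 3, Z ≤ 3, against an
  independent augmented-Lagrangian maximizer over the full simplex;
* decomposition identities: 100 random dense distributions at N = 4, Z = 4
  (random probability tables rather than sampled counts, so the identities
  are tested free of smoothing effects);
* coupling recovery and noise floors: N = 4, Z = 10, 10⁵ samples;
* order discrimination and the regularization path: N = 4, Z = 5,
  10⁵ samples;
* cohort contrast: two cohorts of four groups, 5·10⁴ bins each.

## Known limitations

Exact enumeration bounds the reachable systems (Z^N ≤ 10⁷); plug-in
estimates are biased at small T (no correction is applied, by design); the
semi-Markov dialect is only approximately stationary; exact-zero patterns of
the penalized fit are gauge- and noise-dependent as discussed above; and the
package models configurations, not trajectories — transition structure,
approach/avoidance dynamics and event-level behaviors are outside its scope.
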