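# groupmaxent

Maximum entropy models of multi-animal group occupancy.

When several animals share an arena, how much of the group's behavior is
individual habit, and how much is social? `groupmaxent` answers this for
discretized occupancy data: time series in which, every few hundred
milliseconds, each animal in a small group is assigned to one of Z regions of
interest. The joint *configuration* of the group at time t is the vector
(x₁, …, x_N) of all animals' zones. The package quantifies how strongly
configurations are shaped by dependencies between animals, attributes that
structure to pairwise, triplet and higher-order interactions, infers sparse
maps of the functional interactions, and compares groups.

## The model

The total correlation of the group is the **multi-information**

  I_N = Σᵢ H(xᵢ) − H(x₁, …, x_N)   [bits],

the Kullback–Leibler divergence of the empirical joint configuration
distribution from the product of the individual zone preferences. To split
I_N by interaction order, the package fits the hierarchy of **maximum
entropy models** p⁽¹⁾, p⁽²⁾, …, p⁽ᴺ⁾, where p⁽ᵏ⁾ is the most random joint
distribution consistent with all empirical marginals over animal subsets of
size ≤ k. Each p⁽ᵏ⁾ has the Potts / log-linear form

  p(x₁, …, x_N) = (1/Z) · exp₂( Σᵢ αᵢ(xᵢ) + Σᵢ<ⱼ βᵢⱼ(xᵢ,xⱼ) + Σᵢ<ⱼ<ₖ γᵢⱼₖ(xᵢ,xⱼ,xₖ) + … )

with one indicator feature per animal subset and zone combination. Model
entropies decrease monotonically to the empirical entropy,
H[p⁽¹⁾] ≥ H[p⁽²⁾] ≥ … ≥ H[p⁽ᴺ⁾] = H, and the drops

  I₍ₖ₎ = H[p⁽ᵏ⁻¹⁾] − H[p⁽ᵏ⁾],  with  I₍₂₎ + … + I₍ₙ₎ = I_N,

are the per-order interaction contributions. Fitting uses generalized
iterative scaling with an exact-gradient ascent refinement; an optional L1
(lasso) penalty ε₀·Σ|λ| over all parameters gives a sparse model whose
nonzero signed couplings form the group's functional interaction map.
Groups are compared by the Jensen–Shannon divergence between their fitted
models, minimized over the N! relabelings of the (arbitrary) animal
identities. A synthetic generator produces ground-truth models and occupancy
series (heterogeneous zone preferences, sparse predominantly negative
couplings, power-law-like dwell times) so that every stage of the pipeline
can be validated against known truth.

## Worked example

```r
library(groupmaxent)

## a synthetic group: 4 animals, 5 zones, third-order ground truth
spec <- generator_spec(n_animals = 4, n_zones = 5, order = 3,
                       coupling_scale = c(0.6, 0.4),
                       session_bins = 100000, seed = 1)
truth  <- ground_truth_model(spec)
series <- simulate(truth, nsim = 100000, seed = 2)
series
#> Occupancy series: 100000 bins x 4 animals, 5 zones, bin 0.24 s (6.67 h total)
#>   animals: m1, m2, m3, m4

dist <- empirical_distribution(series)
decompose(dist)
#> Correlation-order decomposition (4 animals x 5 zones)
#>   multi-information I_N = 0.1125 bits
#>   model entropies (bits): p1=8.4348  p2=8.3500  p3=8.3243  p4=8.3224
#>   per-order contributions (bits):
#>     I2 = 0.0848  (75.4% of I_N)
#>     I3 = 0.0258  (22.9% of I_N)
#>     I4 = 0.0019  (1.7% of I_N)
```

The group carries 0.11 bits of correlation beyond individual preferences;
three quarters of it is pairwise, but a fifth needs triplet interactions —
the order-attribution the package exists for. Cross-validation confirms the
third-order model explains held-out data:

```r
halves <- split_train_test(series, seed = 3)
fit3 <- maxent(empirical_distribution(halves$train), order = 3)
evaluate_model(fit3, empirical_distribution(halves$test))
#> Model evaluation (order 3) on 50000 held-out bins:
#>   Jensen-Shannon divergence: 0.00354
#>   95% funnel coverage: 0.877 over 617 observed states
```

The sparse interaction map at the default penalty ε₀ = 2⁻¹⁶ ranks the
dominant signed couplings (negative = socially avoided configurations):

```r
sparse <- maxent(dist, order = 3, epsilon = 2^-16)
head(interaction_map(sparse), 3)
#>   order animals zones  strength
#> 1     2     1,4   3,1 -1.452308
#> 2     2     2,3   5,5 -1.114199
#> 3     3   2,3,4 1,3,1 -1.041473
```

`info_report(series)` gives the complementary readout: the fraction of each
animal's location uncertainty readable from the joint location of the others
versus the naive sum of pairwise terms (their gap is the group's synergy).
`similarity_matrix()` and `cohort_summary()` compare whole cohorts of groups,
and `read_series()` / `read_legend()` ingest real delimited occupancy data.

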