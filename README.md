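# heiderdyn

Structural-balance dynamics on **directed** signed networks, with the
"looking-glass self" self-evaluation index.

Classical balance theory concerns symmetric relations: a complete
network of ±1 ties relaxes into two internally friendly, mutually
hostile camps.  Real sympathy is not symmetric.  heiderdyn simulates
the continuous relation dynamics

```
dx_ij/dt = (1 - x_ij^2) * Σ_{k≠i,j} x_ik x_kj ,      x_ij ∈ [-1, 1]
```

on fully connected directed networks, where a common friend or common
enemy `k` pulls the relation `i → j` up and a mixed third party pulls
it down.  Generic initial conditions freeze at a ±1 corner state that
is usually *jammed* — stationary (`s_ij = sign(Σ_k s_ik s_kj)`) but not
balanced.  The package classifies these frozen states into unlabeled
**class graphs** (the coarsest partition of actors with sign-uniform
relation blocks), identifies the recurring two-, three- and four-class
archetypes (HB, CII, CIII, CIV) with their closed-form stability
conditions (`N1 > N2 + 2`, `N1 + N2 > N3 + 2`,
`N1 + N2 > N3 + N4 + 2`), and computes each actor's self-evaluation

```
F_i = ½ Σ_k (1 + s_ik) s_ki
```

— the reciprocity balance over the actors `i` likes; persistent
negative `F_i` marks positions (the "rejected aspirant" class of CIII,
the small classes of CIV) whose liking is structurally unreciprocated.
It is aimed at computational social scientists studying signed-network
balance, jammed states, and sociometric group structure.

Monte-Carlo ensembles (uniform(−1, 1) initial relations) reproduce the
frequency statistics of the terminal class graphs, and a UCINET-DL /
CSV reader plus `(X − Y)/5` preprocessing supports Sampson-style
analyses of real valued sociomatrices.

## Worked example

```r
library(heiderdyn)

ev <- evolve(random_initial(7, seed = 2))
ev
#> <evolution_result> n = 7, converged to a corner at t = 4.443 (tol = 1e-08)

classify_state(ev$sign)
#> # A tibble: 1 × 7
#>   kind     N1    N2    N3    N4     c key
#>   <chr> <int> <int> <int> <int> <int> <chr>
#> 1 CIII      2     4     1     0     3 4,2,1#+---+++-.

self_evaluation(ev$sign)
#> # A tibble: 7 × 2
#>   actor     f
#>   <int> <int>
#> 1     1     2
#> 2     2     2
#> 3     3     1
#> 4     4     2
#> 5     5    -2
#> 6     6     2
#> 7     7     1
```

This run froze into the three-class archetype CIII with sizes
(N1, N2, N3) = (2, 4, 1): two mutually hostile friendly classes and a
single "aspirant" actor (actor 5) who likes the first class, is
rejected by it, and turns away from the second class that likes him —
hence his self-evaluation `F = -N1 = -2`, while everyone else scores
`N1 - 1 = 1` or `N2 - N3 - 1 = 2`.  The closed forms per class:

```r
template_self_evaluations(template_spec("CIII", c(3, 3, 1)))
#> # A tibble: 3 × 3
#>   class  size     f
#>   <int> <int> <int>
#> 1     1     3     2
#> 2     2     3     1
#> 3     3     1    -3
```

Ensembles and the combinatorial side-computation:

```r
r <- run_ensemble(7, k_runs = 2000, seed = 1)
glance(r)             # converged, asymmetric and CIII+CIV fractions
frequency_table(r)    # class-size configurations, most frequent first
round(sapply(c(7, 9, 11), partition_ratio), 1)
#> [1] 1.2 2.6 5.1     # S(n,4)/S(n,3): why 4-class graphs take over
```

A thin CLI wraps the same functions
(`inst/cli/heiderdyn-cli.R simulate | ensemble | check | template |
sociomatrix`).

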