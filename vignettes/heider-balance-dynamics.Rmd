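---
title: "Relation dynamics, class graphs and the looking-glass self"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relation dynamics, class graphs and the looking-glass self}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heiderdyn)
```

## The model

heiderdyn simulates the removal of cognitive dissonance on a fully
connected, *directed* signed network of `n` actors.  Every ordered pair
of distinct actors carries a continuous relation `x_ij ∈ [-1, 1]`
(positive: `i` likes `j`), evolving under

```
dx_ij/dt = (1 - x_ij^2) * sum_{k != i,j} x_ik * x_kj .
```

A third actor who is a common friend or a common enemy of `i` and `j`
strengthens their relation; a mixed third party weakens it.  The factor
`1 - x_ij^2` confines relations to `[-1, 1]` and makes every corner of
the hypercube (`x_ij = ±1`) a fixed point.  Starting from generic
continuous relations, the system freezes at such a corner.  For
*symmetric* relations the generic frozen state is the classical
two-clique structural balance; when symmetry is not imposed the frozen
states are usually *jammed*: stationary but not balanced.

A frozen corner is stationary exactly when each link agrees with the
sign of its triad sum, `s_ij = sign(sum_k s_ik s_kj)`.  With an odd
number of actors the sum of `n - 2` odd terms cannot vanish, which is
why the shipped experiments use odd `n`; even `n` is allowed by the API
but draws a warning, and zero triad sums are reported explicitly
(`is_stationary()`), never silently resolved.

## Self-evaluation

Borrowing the looking-glass-self idea — one's self-image is assembled
from the perceived opinions of others one cares about — each actor gets
the index

```
F_i = (1/2) * sum_k (1 + s_ik) * s_ki ,
```

the sum of reciprocal relations over the actors `i` likes.  Disliked
actors contribute nothing.  `F_i` is an integer in `[-(n-1), n-1]`;
negative values mark actors whose liking is mostly unreciprocated.

## Class graphs and archetypes

`refine_classes()` reduces a frozen state to its classes of
structurally equivalent actors: the coarsest partition whose
within-class and between-class relation blocks each carry one sign.  On
a complete network such a partition is automatically equitable (every
member of a class has the same number of friendly out- and in-links
into each class), so it is the signed analogue of color refinement.
The implementation refines from the trivial partition downward using
count-based splits plus sign-uniformity splits; all split keys are
label-invariant, and a standard lattice argument shows the fixed point
is the *unique coarsest* sign-uniform partition, independent of node
labeling and split order (the test suite checks this against a
brute-force search over all set partitions for small `n`).

Four archetype class graphs recur (`make_template()`,
`identify_template()`):

* **HB** — two internally friendly, mutually hostile cliques; the
  symmetric balanced state.
* **CII** — friendly class 1 rejects an internally hostile class 2
  whose members nevertheless like class 1.  Stationary iff
  `N1 > N2 + 2`; `F = N1 - 1` in class 1 and `-N1` in class 2.
* **CIII** — two hostile cliques plus a small "aspirant" class 3 that
  likes class 1 but is rejected by it, dislikes its own members, and is
  liked by class 2 it turns away from.  Stationary iff
  `N1 + N2 > N3 + 2`; per-class `F = (N1-1, N2-N3-1, -N1)`.
* **CIV** — two hostile cliques plus two small internally hostile,
  mutually friendly classes 3 and 4 attached crosswise.  Stationary iff
  `N1 + N2 > N3 + N4 + 2`; per-class
  `F = (N1-N3-1, N2-N4-1, N4-N2, N3-N1)`.

The precise arrow patterns of CIII/CIV are fixed by requiring that
direct evaluation of `F` on the constructed matrices reproduces the
closed forms above and that the sign-condition stationarity matches the
closed-form inequalities for every size split with `5 ≤ n ≤ 11` — an
exhaustive cross-check in the test suite, which is also the authority
should any closed form and the sign condition ever disagree.
Templates with trailing empty classes delegate to the archetype they
degenerate to (a CIV with an empty fourth class is a CIII with classes
1 and 2 swapping roles; a CIII with an empty third class is plain HB).

`canonical_key()` canonicalizes class graphs by iterated color
refinement with exact permutation search inside residual ties — exact
for the ≤ 6-class graphs in scope, truncated beyond.

## Ensembles

`run_ensemble()` draws every initial relation independently from the
uniform density on (-1, 1) (`ρ(x) = 1/2`), integrates each network to a
corner, classifies the frozen state, and tallies class graphs.  Per-run
seeds are pre-drawn from the master seed, so results are reproducible
and single runs can be replayed.  Typical findings, reproduced by the
acceptance tests at sample size 2000 per `n` (the published experiments
used 10^4):

* `n = 7`: about 73–74% of converged runs end in CIII or CIV; the
  leading configuration is CIII (3, 3, 1) at about 15% of the sample.
* `n = 9`: the leading CIII/CIV size configurations cover ≈ 78% of the
  sample.
* `n = 11`: CIII + CIV together reach ≈ 88–90% of the sample.

The drift from three- towards four-class graphs with growing `n` is
explained by a counting argument: the number of ways to split `n`
actors into four nonempty groups grows much faster than into three.
`stirling2()` and `partition_ratio()` make this exact:
`S(n,4)/S(n,3)` ≈ 1.2, 2.6, 5.1 at `n` = 7, 9, 11.

### What "asymmetric" counts

Two statistics are deliberately kept apart.  The label-free
`asymmetric_fraction()` counts frozen states that differ from their
transpose; it is exactly 0 for symmetric initial conditions.  The
published "about 73 percent" at `n = 7`, however, tabulates the CIII
and CIV class graphs, and the two notions differ measurably: besides
CIII/CIV (≈ 74% of converged runs) the dynamics also produces ≈ 6% of
two-class non-transpose-symmetric states — typically an internally
friendly clique together with a hostile singleton that everyone likes —
which are stationary but outside the four archetypes and are reported
as `"other"`.  The acceptance checks therefore compare the CIII + CIV
share with the published percentage; `glance()` on an ensemble reports
both numbers.

## Numerical choices

* **Integrator.**  `deSolve::lsodar` drives a C implementation of the
  right-hand side.  Solver tolerances (`rtol = atol = 1e-10`) are two
  orders tighter than the corner criterion `max |1 - |x_ij|| ≤ 1e-8`.
  A root function stops the integration the moment every relation
  enters the corner band (firing marginally inside the band so the
  criterion holds strictly at the reported state); integration is
  chunked in 250-unit blocks so runs that never freeze do bounded
  work.  A trajectory can graze a *saddle* corner — momentarily within
  the band although some link opposes its triad sum — so a stop is
  accepted only when the frozen sign pattern has no strict sign
  violation; otherwise integration continues until the trajectory
  settles at an attracting corner.  This is what makes every converged
  state sign-stationary, an invariant the test suite asserts.
* **Boundary safeguard.**  The exact flow cannot leave `[-1, 1]`, but
  an adaptive step can overshoot by a rounding error, and outside the
  cube the raw vector field may point outward (a spurious finite-time
  blow-up that collapses the step size).  The C derivative therefore
  evaluates the field on the state clamped to `[-1, 1]` — identical
  dynamics inside the domain — and `evolve()` additionally clips
  checkpoint states, erroring if a state ever drifts past
  `1 + 1e-6` (which would indicate solver misconfiguration).
* **`t_max = 1000`** model-time units: at `n = 7–11` virtually all runs
  freeze well before `t = 100`, giving converged fractions ≈ 99.9%,
  comfortably above the published 97%.  Runs that exhaust `t_max` (or
  whose solver call fails) count as non-converged and are never
  classified.
* **Sample sizes.**  The test suite runs 2000 networks per size; the
  acceptance script runs the published 10^4 at `n = 7` and 9 and 2000
  at `n = 11`.  All frequency checks use ± 3 binomial standard
  deviations of the sample actually drawn.

## What the generator does and does not emulate

The synthetic ensembles reproduce the study's stated conditions:
complete directed networks, i.i.d. uniform(-1, 1) initial relations, no
noise during evolution.  Real sociometric data differ in every one of
these respects — sparse nominations, bounded integer scales,
correlated reciprocity — so passing ensemble tests says nothing about
how real groups behave, only that the dynamics, classifier and
statistics are implemented faithfully.  The sociomatrix pipeline
(`read_sociomatrix()`, `combine_signed()`, `drop_actors()`,
`analyze_sociomatrix()`) handles real valued matrices: positive and
negative nomination matrices are combined as `(X - Y)/scale` with the
default `scale = 5` keeping ranked nominations inside `(-1, 1)`, and
actors too weakly connected for the evolution to freeze are reported as
non-converged rather than forced.  Actor indices in every report refer
to the original file ordering, also after `drop_actors()`.

## Known limitations

* Only complete networks: no sparse or weighted generalizations.
* Class-graph canonicalization is exact up to ~6 classes.
* `stirling2()` uses double arithmetic: exact while values stay below
  2^53 (ample for the sizes here).
* Large-scale regimes (`n` in the several tens and the reported
  instability near `n ≈ 100`) are reachable through the API but outside
  the tested envelope; the rank-frequency scaling fit across sizes is
  provided as-is and is checked only for structural validity.
```{r session, eval = FALSE}
# A minimal end-to-end run:
ev <- evolve(random_initial(7, seed = 1))
classify_state(ev$sign)
self_evaluation(ev$sign)
```
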