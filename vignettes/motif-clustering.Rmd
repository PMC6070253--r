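---
title: "Functional clustering of species by assembly motifs: model and methods"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`motifclust` identifies the functional structure of ecosystems — the
clustering of species into effect groups that best explains an observed
ecosystem function — from presence/absence composition data alone. This
vignette documents the model, the algorithmic and numerical choices, what
the virtual-ecology simulator does and does not emulate, and the known
limitations.

## The assembly-motif model

Two assumptions underpin the model: the function of an ecosystem depends on
its species composition, and species can be functionally redundant. A
partition of the `s` observed species into `sigma` functional groups maps
every ecosystem onto an *assembly motif* — the set of groups represented in
it — and ecosystems sharing a motif are expected to function alike.

Given a sample of `n` ecosystems with observed function values, the
modelled function of ecosystem `A` with motif `k` is the unweighted average
over its own species `i` of the mean observed function of the ecosystems
that share motif `k` and contain `i` (the species-motif cluster). This is a
purely associative model: it presupposes no functional form for the
diversity-function relationship, and accommodates idiosyncratic responses
in which a species' effect depends on who it co-occurs with.

Two statistics evaluate a clustering:

* `R^2 = 1 - RSS_modelling / TSS` — explanatory ability;
* `E = 1 - RSS_predicting / TSS` — predictive ability, from leave-one-out
  cross-validation; it may be negative (worse than predicting the mean).

### Cross-validation details

Leave-one-out is taken over ecosystems with the species partition held
fixed: only the cluster means are recomputed without the focal ecosystem.
A species term whose depleted cluster becomes empty is dropped from the
average; the prediction is undefined only when the focal ecosystem is the
sole representative of its motif (or, in a rarer degenerate case, when no
species term survives). The *predicting ratio* is the fraction of
ecosystems with a defined prediction; it decreases from 1 towards 0 as
`sigma` grows and motif clusters shrink.

Because `RSS_predicting` can only sum over the predictable subset, the
package normalizes the model-level efficiency by the total sum of squares of
that same subset (`tss = "subset"`, the default), keeping models that leave
different subsets predictable on a comparable scale. The literal
normalization by the full-sample TSS is available via `tss = "full"` for
sensitivity checks; the two coincide when everything is predictable.

### Arithmetic caveat on R²

The modelled value is an average of cluster means, not a least-squares
projection, so `R^2` is not structurally confined to `[0, 1]`: on
adversarial or tiny samples the single-group model can produce
`RSS_modelling > TSS`, i.e. a negative `R^2`. The package never clamps the
value. On the structured data the method targets, `R^2` behaves as a
variance proportion and increases to 1 along the clustering tree. For the
same reason, adding one duplicated ecosystem can slightly *decrease* `R^2`
(duplicating the whole sample, by contrast, changes nothing — this is the
invariant the test suite asserts).

## Building the divisive tree

Exhaustive search over species clusterings is hopeless: the number of
partitions of `s` species is the Bell number (`count_partitions()`), already
203 at `s = 6` and ~1e11 at `s = 16`. The tree sidesteps this. Starting from
one group (`sigma = 1`), each level splits exactly one group in two and
keeps the split maximizing `R^2`; the process ends in singletons
(`sigma = s`), producing one nested partition per group count.

One group is split as follows:

1. **Nucleus.** Every member species is trialled as a singleton; the
   isolation with the highest `R^2` becomes the nucleus of the new group
   (ties: lowest species index).
2. **Move path.** Rounds of steepest ascent: every remaining member is
   trialled in the new group and the single best move is made (ties: lowest
   species index). The walk continues to the end of the group rather than
   stopping at the first non-improving round — a locally flat round would
   otherwise trap the search — and the clustering with the maximal `R^2`
   seen anywhere along the path is kept.

Splitting a group of `q` species therefore scores exactly
`q + (q-1) + ... + 2 = q(q+1)/2 - 1` candidate clusterings, and a full tree
at most `s[(s+1)(s+2)/6 - 1]` (`max_evaluations()`): 50 at `s = 6`, 800 at
`s = 16`, against 203 and ~1e11 possible clusterings. All comparisons are
exact floating-point `>` with deterministic candidate ordering, so a tree
build is bit-reproducible. Level candidates (one per splittable group) are
resolved by largest `R^2`, ties towards the group containing the lowest
species index.

The greedy search is not globally optimal at any level; this is the price
of the evaluation bound. Two residual failure modes are documented under
Limitations.

## Evaluating the tree

Deeper levels predict fewer ecosystems, which would make levels
incomparable. The tree statistics therefore evaluate each ecosystem at its
own deepest predictable level `sigma_prime(A)` — the largest level (up to
the one under evaluation) at which its leave-one-out prediction is defined.
We read the selection of that level as "the deepest level with a defined
prediction": the last prediction available is taken as the best one for
that ecosystem. At the tree base every ecosystem of a sample with `n >= 2`
is predictable (in the degenerate case where an ecosystem shares no species
with any other, the package falls back to the leave-one-out grand mean at
`sigma = 1`), so the tree predicting ratio is 1 by construction and
`R^2_tree`, `E_tree` — normalized by the full-sample TSS — always refer to
all `n` ecosystems. They are bounded above by their model-level
counterparts.

### Validated depth

Model-level efficiency should rise while splits isolate real groups; its
first strict decrease (or loss of definition) flags an overfitted split,
which is rejected together with all deeper levels. `sigma_max()` is the
level before that first decrease.

### Choosing the number of groups

`AICc_tree(sigma) = n log(RSS_tree_modelling / n) + 2m + 2m(m+1)/(n-m+1)`,
where `m` is the number of assembly motifs observed at that level — the
model's parametrization. Choices worth making explicit:

* `m` counts the motifs of the level-`sigma` classification, not the motifs
  actually used across the per-ecosystem `sigma_prime` levels; the
  parametrization belongs to the `sigma`-model being scored.
* The correction denominator is `n - m + 1` as the method defines it;
  the textbook `n - m - 1` variant is available
  (`aicc_denominator = "n-m-1"`) for sensitivity checks.
* The criterion is undefined when the denominator is non-positive or when
  the RSS is numerically zero. "Numerically zero" uses a floor of
  `1e-12 * TSS`: noise-free data leave RSS of order 1e-29 made of
  floating-point crumbs, and `n log(RSS/n)` of such a residual is rounding
  noise. Levels at or below the floor fit perfectly and are preferred by
  `sigma_opt()` over any finite criterion, the smallest such level winning
  (parsimony); all other ties also resolve to the smallest level.
* The argmin is searched over the validated levels `1..sigma_max` by
  default; the nominal range `1..(s-1)` is available via
  `sigma_opt_range = "full"`.

## The virtual-ecology simulator

`generate_dataset()` emulates designed biodiversity experiments with a
known functional structure:

* a hidden partition of the species into true groups (`group_sizes`);
* one mean function per *possible* motif (all `2^sigma - 1`, observed or
  not), drawn independently and uniformly on `mean_interval`. Means may
  collide — nothing forces distinct motifs to differ — and collisions are a
  legitimate, hard feature of the generated data;
* an observation design: `full_factorial` (all `2^s - 1` combinations,
  optionally excluding monocultures) or `sample` (uniform without
  replacement among pluri-species combinations);
* per-ecosystem noise `F = mean * (1 + cv * z)`, with `z` a standard normal
  truncated at ±2 and rescaled by the analytic standard deviation of the
  truncated law (≈ 0.8796) so that `sd(z) = 1`. The rescaling is analytic,
  not per-batch empirical, to keep draws independent and deterministic;
  the noise standard deviation is thus exactly `cv` times the motif mean.
  Truncation avoids sign flips for moderate `cv`; at `cv >= 0.44` negative
  function values become possible and are allowed.

Two standard designs are preconfigured for the replicated experiments, and
their defaults are the study conditions, not tuning knobs: a *microbial*
design (6 species, all 63 combinations including monocultures, means on
0.4–1.4 function units, `cv = 0.08`, base structure 1/2/3) and a
*grassland* design (16 species, 2048 of the 65519 pluri-species
combinations sampled, means on 50–550 g m⁻², `cv = 0.17`, base structure
1/2/6/7). Experiments that vary the true number of groups derive nested
structures from the base by a deterministic rule (split the largest group
into near-halves; merge the two largest), mirroring how structures refine
from trunk to leaves of a clustering tree.

What the simulator does *not* emulate: abundances, environmental
covariates, non-uniform species occurrence, observation error in the
composition itself, or any smooth diversity-function trend. Passing the
recovery experiments therefore shows that the procedure inverts its own
generative model under realistic noise — not that real communities satisfy
the redundancy assumption.

### Seeds and reproducibility

Every stochastic path takes an explicit seed. Replicated experiments draw
one sub-seed per replicate upfront from the base seed (a single
`sample.int` stream, in replicate order), so any replicate can be
regenerated in isolation and results are reproducible bit-for-bit. Motif
means and noise are re-drawn after each design sampling.

## Recovery scoring

Partitions are compared by the pair-counting Jaccard index: pairs of
species co-grouped in both partitions over pairs co-grouped in at least
one; 1 exactly at equality up to labels; the all-singletons vs
all-singletons case (0/0) is defined as agreement. Experiments score the
recovered tree both at the AICc-selected level (`jaccard_opt`) and at the
level with the true number of groups (`jaccard_true`). The headline
failure rates use `jaccard_true`: the selected level answers "how many
groups?" while the Jaccard at the true level answers "are the right species
together?", and conflating them would count every mis-selection of `sigma`
as a mis-clustering even when the tree level at the true `sigma` is exact.
Both columns are always reported.

When sampling is sparse, species of the largest groups are the hardest to
separate; `merge_largest_groups()` provides the coarser reference (two
largest true groups merged) against which partial recovery is scored
(`jaccard_merged`).

## Problem sizes used by the tests

The test suite runs the microbial-design experiments at 100 replicates per
structure (as in the full study conditions) and the grassland-design
experiments at 20 replicates per structure and 20–25 per sampling size — a
scale chosen so the whole suite completes in a few minutes on one CPU while
keeping Monte-Carlo error on failure fractions near one percentage point.
`scripts/acceptance.R` uses 100/20/25 replicates for the same experiments.

## Known limitations

* **Greedy hierarchy.** A level may adopt a split that is incompatible with
  the true partition yet legitimately better at that coarseness; divisive
  refinement can then never reach the truth. And within one split, the
  growing group admits no removals: a species that enters wrongly at the
  noise-dominated two-member stage stays. Both modes are rare at moderate
  noise but measurable (a few percent of grassland-design datasets); fixing
  them would require exceeding the method's evaluation bound.
* **Sole representatives.** An ecosystem alone in its motif is tree-modelled
  at a coarser level, so `R^2_tree` stays below 1 even on noise-free data
  whenever the true structure contains singleton groups and monocultures
  are observed.
* **Selection at small true `sigma` and very deep structures.** The AICc
  optimum is biased upward when the truth has very few groups and downward
  for structures close to all-singletons; the validated depth restriction
  mitigates but does not remove this.
* `R^2` outside `[0, 1]` on adversarial inputs (see above); values are
  reported unclamped.
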