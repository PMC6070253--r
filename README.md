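# motifclust

Which species — or groups of interchangeable species — govern an ecosystem
function? `motifclust` answers this from observational data alone: a table
of species presence/absence per ecosystem and one measured function per
ecosystem (biomass production, substrate oxidation, nutrient recycling,
...). No monoculture performances, trait data or interaction networks are
required.

## The model

Species are clustered into σ functional *effect* groups. The combination of
groups represented in an ecosystem is its **assembly motif**; ecosystems
sharing a motif are assumed to function alike. For an ecosystem *A* with
motif *k*, the modelled function averages, over the species *i* ∈ *A*, the
mean observed function of the ecosystems that share motif *k* and contain
*i*:

    F_modelled(A) = mean_{i in A} mean( F_observed over A_{i,k} )

A clustering is scored by its coefficient of determination and its
leave-one-out cross-validated efficiency (a Nash–Sutcliffe-type
coefficient):

    R²(σ) = 1 − RSS_modelling / TSS        E(σ) = 1 − RSS_predicting / TSS

Because exhaustive search over all species clusterings is impossible (203
partitions for 6 species, ~10¹¹ for 16 — the Bell numbers), `motifclust`
builds a **hierarchical divisive tree**: starting from one group, each level
splits one group in two, choosing the split that maximizes R². A full tree
costs at most `s[(s+1)(s+2)/6 − 1]` clustering evaluations (50 for s = 6,
800 for s = 16). Whole-tree statistics (`R²_tree`, `E_tree`) evaluate every
ecosystem at its own deepest predictable level, so all levels refer to the
same *n* ecosystems, and a small-sample corrected Akaike criterion
(`AICc_tree`) selects the optimal number of groups σ″.

A virtual-ecology simulator generates datasets with a known hidden
structure — per-motif mean functions drawn uniformly, multiplicative
truncated-normal noise with relative error `cv` — and replicated experiments
score how reliably the hidden partition is recovered (pair-counting Jaccard
index).

## Worked example

Simulate a 6-species microcosm experiment (all 63 combinations assembled,
true groups of sizes 1/2/3, 8% relative error), then recover the structure:

```r
library(motifclust)

cfg <- simulation_config(
  group_sizes = c(1, 2, 3), mean_interval = c(0.4, 1.4), cv = 0.08, seed = 2026
)
vd <- generate_dataset(cfg)
tree <- build_tree(vd$sample)
tree
#> <motif_tree> 6 species, 63 ecosystems, 6 levels
#>   evaluations: 47 (bound 50)
#>   sigma_max = 4 (validated depth), sigma_opt = 3 (AICc optimum)
#>   at sigma_opt: R2_tree = 0.9036, E_tree = 0.8754
#>     group 1: sp01
#>     group 2: sp02, sp03
#>     group 3: sp04, sp05, sp06

tidy(tree)[, c("sigma", "m", "r_squared", "efficiency", "r2_tree", "e_tree", "aicc")]
#> # A tibble: 6 × 7
#>   sigma     m r_squared efficiency r2_tree e_tree  aicc
#>   <int> <int>     <dbl>      <dbl>   <dbl>  <dbl> <dbl>
#> 1     1     1     0.180      0.127   0.180  0.127 -192.
#> 2     2     3     0.540      0.439   0.507  0.445 -220.
#> 3     3     7     0.937      0.904   0.904  0.875 -313.
#> 4     4    15     0.956      0.907   0.915  0.867 -297.
#> 5     5    31     0.975      0.905   0.924  0.852 -222.
#> 6     6    63     1         NA       0.924  0.852 7846.

jaccard_partitions(tree$partitions[[tree$sigma_opt]], vd$true_partition)
#> [1] 1
```

Reading the output: R² rises to 1 as groups are added (at σ = s every
distinct composition is its own motif), but the cross-validated efficiency
peaks at the validated depth σ_max = 4, and the tree AICc is minimal at
σ″ = 3 — the true number of groups. The recovered partition matches the
hidden one exactly (Jaccard = 1), and the tree explains 90% of the observed
variance while predicting 88% of it out-of-sample.

Real data enter through `read_eco_sample("composition.csv")` (one id
column, binary species columns, one function column); `autoplot(tree)`
draws the fit/selection diagnostics; `write_tree_json()` /
`write_tree_newick()` export the fitted artifact.

A command-line wrapper ships in `inst/cli/motifclust.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","motifclust.R",package="motifclust"))')" \
  fit --input sample.csv --output tree.json --stats stats.csv --newick tree.nwk
```

with further subcommands `simulate`, `experiment` and `compare`.

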