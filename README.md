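# gcmigrate

Evolutionary inference of B cell migration between germinal-center (GC)
follicles from spatially resolved BCR heavy-chain repertoires.

During affinity maturation, B cells proliferate, hypermutate and are selected
inside GCs, each housed in a distinct follicle. Spatial repertoire data (one
row per UMI: V(D)J sequence, follicle assignment, XY position, compartment)
shows that some lineages span several follicles. `gcmigrate` is for
immunologists and computational biologists who want to quantify that
spreading process: how often cells migrate, whether migration is local or
driven by memory-cell re-entry, whether a single per-cell rate explains all
lineages, and how migrant lineages fare in their destination follicles.

## The model in brief

Somatic hypermutation is used as a molecular clock: the germline divergence
*x* of a sequence proxies its evolutionary age. Under a clock-like migration
model, cells migrate at a constant rate *m* per unit divergence, so

* pairs of clones at pairwise divergence *x* sit in different follicles with
  probability `1 − exp(−x/β)` (Bernoulli MLE of β on all same-lineage pairs
  of distinct unique sequences);
* the number of migration events on a lineage's phylogeny — label-changing
  branches under maximum-parsimony follicle labelling (uniform-cost
  Sankoff/Fitch with deterministic tie-breaks) — scales as `N ~ Poisson(mT)`
  with total tree divergence *T*, giving `m = ΣN/ΣT` and per-lineage rates
  `m̂ᵢ = Nᵢ/Tᵢ`;
* clonal groups (identical sequences ≥1% diverged, seen ≥2 times) are
  multifollicular with probability `1 − (1−p)^size`, capturing migration
  during SHM-suppressed clonal bursts.

Rate homogeneity is tested by resampling migrations as a single-rate Poisson
process along the observed trees (conditioned on ≥1 event) and comparing
survival functions of `m̂ᵢ` against the mean ± 2 sd envelope; a gamma-Poisson
grid search bounds the admissible coefficient of variation across lineages.
Fate analysis decomposes trees into single-follicle subtrees at migration
branches and compares post-migration divergence against migrations shuffled
uniformly along branch length.

Everything is validated against an agent-based synthetic tonsil
(`simulate_tonsil()`) with complete ground truth — genealogies, true
migration events, per-lineage rates — plus a `reentry_variant()` that shares
genealogies seed-for-seed and differs only in migration destination law.

## Worked example

Simulate a 15-follicle tonsil at the default per-division migration
probability 0.02 and SHM rate 1e-3 /site/division — i.e. a true rate of one
migration per 5% divergence, m = 20 — then recover it:

```r
library(gcmigrate)

params <- sim_params(n_follicles = 15, n_lineages = 80, generations = 12,
                     division_prob = 0.6, follicle_capacity = 4000,
                     sample_prob = 0.15, migration_prob = 0.02,
                     burst_prob = 0, stagger_entry = FALSE)
sim <- simulate_tonsil(params, seed = 42)

trees <- analyze_trees(build_lineage_trees(sim$records, mode = "true",
                                           truth = sim$truth)$trees)
estimate_rates(trees)
#> rate_estimates: 78 trees; 241 migrations over T = 12.15 ; m = 19.84 = (5.04%)^-1

pairwise_migration_curve(sim$records, seed = 1)
#> migration_curve: 42688 same-lineage pairs; beta = 0.04579 ; intercept excess = 0.316

poisson_resample(trees, n_boot = 100, seed = 2)
#> homogeneity_result: 69 lineages with >=1 migration; refit m = 19.84 ;
#>   observed survival inside mean+/-2sd at 100% of grid points

related_pair_distances(sim$records, seed = 3)
#> distance_distribution: 19569 related cross-follicle pairs; tail fraction 0.0819 (vs 0.5 under re-entry)
```

Reading the output: the tree-based rate recovers the true m = 20 within 1%
(`(5.04%)^-1`); the pairwise β ≈ 0.046 approximates the true δ/q = 0.05 from
pairwise paths alone; the per-lineage rate survival sits fully inside the
single-rate Poisson envelope, as it should in this rate-homogeneous world;
and related cross-follicle pairs are far closer than unrelated ones (tail
fraction 0.08 ≪ 0.5), the signature of local migration rather than
memory-cell re-entry (`reentry_variant()` gives ≈ 0.5).

The full chain (clustering → spatial statistics → clock fits → trees →
homogeneity → fate) runs via `run_pipeline(run_config(...))`, or from the
shell through the CLI:

```sh
Rscript inst/cli/gcmigrate.R simulate --outdir sim --seed 1
Rscript inst/cli/gcmigrate.R all --input sim/repertoire.tsv --outdir out --tree-mode nj --seed 1
```

On real data, supply an AIRR-style TSV (`read_repertoire_table()` documents
the dialect; `"EF"` marks extrafollicular records) and either per-lineage
newick trees (`--tree-mode import`) or the built-in neighbor-joining fallback.

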