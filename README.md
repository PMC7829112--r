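# asvoverlap

Quantifying how much of a gut microbial community survives an
environmental shift — and how much evolutionary opportunity that
community holds.

`asvoverlap` is an R package for comparing 16S rRNA amplicon sequence
variant (ASV) communities between two host groups (for example, mice on
a fiber-rich standard diet versus a fiber-free Western diet). It is
aimed at microbiome researchers who have denoised ASV count tables in
hand and want a transparent, fully reproducible answer to "how much of
each group's community is unique, shared, or merely amplified?" —
together with the permutation null needed to read that answer, and two
companion analyses: a classical distance-phylogenetics chain for
individual gut taxa and a back-of-the-envelope calculator contrasting
microbial with host reproductive capacity.

## The statistic

Let $p_g(i)$ be ASV $i$'s mean relative abundance in group $g$ (per-sample
proportions averaged with equal weight). Aligning two groups $A, B$ on the
union of their ASVs, each group's community is partitioned into three
non-negative components that sum to 100%:

- **Unique**$_g$: abundance in ASVs with zero mean abundance in the other
  group;
- **Shared** $= \sum_i \min(p_A(i), p_B(i))$ over ASVs present in both
  groups — identical from either group's perspective;
- **Increased**$_g$: each group's excess above the shared minimum on
  co-occurring ASVs.

To judge whether an observed between-group Shared value is small, a
random-split permutation null repeatedly divides one group's samples into
two pseudo-groups of five and recomputes Shared within the group.

Before partitioning, tables pass the conventional filter chain: samples
with fewer than 1000 reads are dropped (exactly 1000 is retained),
ASVs with mitochondrial/chloroplast/eukaryotic/uncharacterized taxonomy
are removed, and only ASVs observed in at least two samples with at least
1% group-mean relative abundance in one of the groups are kept.

## Worked example

A built-in six-ASV fixture (also shipped as TSVs under
`inst/extdata/toy/`) is small enough to check by hand:

```r
library(asvoverlap)
fx <- make_toy_fixture()
compare_groups(fx$table, fx$taxonomy, fx$metadata, c("SD", "WD"))
#> Community overlap comparison
#>   groups: SD (n = 2), WD (n = 3)
#>   ASVs retained after filtering: 5
#> Community overlap partition (SD vs WD)
#>               SD  WD
#> Unique     18.75  35
#> Shared     65.00  65
#> Increased  16.25   0
#> Total     100.00 100
#> 2 co-occurring ASVs
```

Reading the table: 18.75% of the SD community sits in ASVs absent from
WD, 65% of either community is common to both (per-ASV minima), and SD
holds 16.25% excess abundance on the co-occurring ASVs. Each column
closes to 100%.

The same interface scales to a simulated strong diet shift with a
permutation null (here 20% of 150 ASVs can occur in both groups):

```r
sim <- simulate_community(community_spec(overlap_fraction = 0.2, seed = 1))
compare_groups(sim$table, sim$taxonomy, sim$metadata, c("SD", "WD"),
               null = list(group = "WD", n_splits = 100, split_size = 5, seed = 2))
#> Community overlap comparison
#>   groups: SD (n = 4), WD (n = 10)
#>   ASVs retained after filtering: 46
#> Community overlap partition (SD vs WD)
#>               SD     WD
#> Unique     51.76  66.68
#> Shared      3.11   3.11
#> Increased  45.13  30.21
#> Total     100.00 100.00
#> 13 co-occurring ASVs
#> Random-split null for group 'WD': 100 splits of 5+5 samples
#>   shared%: mean 81.36, sd 2.56, range [76.17, 87.01]
```

Between the diet groups only 3.1% of the community is shared, while
random splits *within* the Western-diet group share 81% on average —
the shift, not sampling noise, dissolved the overlap.

Other entry points: `build_nj_tree()` runs aligned FASTA through
complete deletion, Tamura–Nei composite-likelihood distances, and
neighbor joining to a Newick tree; `repro_comparison()` prints the
reproductive-events arithmetic; `run_pipeline()` executes
simulate/filter/overlap/null end to end with a checksummed manifest;
`inst/cli/asvoverlap.R` wraps it all for the shell:

```r
repro_comparison()
#> Reproductive-events comparison
#>   gut bacterial events per lifetime : 3.172e+17
#>   human births per day              : 2232
#>   years for equal human events      : 3.893e+11
#>   multiples of the universe's age   : 28.2
```

One human gut accrues in a lifetime as many bacterial reproductive
events as the pre-agricultural human population would accumulate in
roughly 3.9 × 10¹¹ years — about 28 ages of the universe.

See `vignettes/community-overlap.Rmd` for the full model description,
parameter meanings, and design decisions.

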