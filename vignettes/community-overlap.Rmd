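---
title: "Partitioning community overlap between host groups: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning community overlap between host groups: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asvoverlap)
```

## The question the package answers

When the gut environment changes — most drastically, when dietary fiber is
removed — the microbial community reorganizes. A direct way to quantify how
much of a community survives such a shift is to compare amplicon sequence
variant (ASV) relative abundances between two host groups and ask: of each
group's total community abundance, how much sits in ASVs absent from the
other group, how much is common to both, and how much is excess in one
group? `asvoverlap` implements that partition, the permutation null needed
to interpret it, the conventional 16S pre-filters, a synthetic community
generator with known ground truth, a distance-based phylogenetics chain for
examining the evolutionary divergence of individual gut taxa, and a small
calculator that contrasts the reproductive (and hence evolutionary)
capacity of a gut microbiota with that of its host species.

## The overlap partition

Let $p_g(i)$ be the mean relative abundance of ASV $i$ in group $g$,
obtained by normalizing each sample column to proportions and averaging
with equal weight per sample. For the pair of groups $(A, B)$, aligned on
the union of their ASVs:

* **unique**$_g = \sum_{i \,:\, p_{g'}(i) = 0} p_g(i)$ — abundance in ASVs
  absent from the other group $g'$;
* **shared**$ = \sum_{i \,:\, p_A(i) > 0,\, p_B(i) > 0} \min(p_A(i), p_B(i))$
  — the group-symmetric common part of the co-occurring ASVs;
* **increased**$_g = \sum_{i} (p_g(i) - \min(p_A(i), p_B(i)))$ over the
  co-occurring ASVs — each group's excess above the common part.

All three are reported as percentages. The per-ASV minimum is the unique
choice that makes the three components close exactly to 100% for each
group while keeping the shared component identical from either group's
perspective; both properties are enforced by tests on randomly generated
profiles. "Absent" means a mean abundance of exactly zero after filtering
— no pseudo-counts are added.

Equal-weight sample averaging (rather than pooling raw counts) prevents
deeply sequenced samples from dominating a group's profile; pooling is
available via `weighting = "pooled"` for sensitivity analysis.

```{r toy}
fx <- make_toy_fixture()
cmp <- compare_groups(fx$table, fx$taxonomy, fx$metadata, c("SD", "WD"))
cmp
```

The toy fixture is small enough to verify by hand. After the mitochondrial
ASV `tox1` is removed, the per-sample proportions are exact fractions; the
SD profile is (0.1875, 0.3125, 0, 0, 0.5) over `asv1`–`asv5` and the WD
profile (0, 0.15, 0.25, 0.1, 0.5), giving unique 18.75/35, shared
$\min(0.3125, 0.15) + \min(0.5, 0.5) = 0.65$, and increased 16.25/0
percent — the values printed above.

## Filters

The filter chain runs in a fixed order — sample depth, taxonomy,
prevalence/abundance — mirroring conventional 16S practice:

1. **Depth.** Samples with *fewer than* `min_reads_per_sample` (default
   1000) total reads are removed; a sample with exactly 1000 reads is
   retained. The comparison is strict-below by design, and tests pin the
   999/1000 boundary.
2. **Taxonomy.** An ASV is removed iff any rank of its lineage matches one
   of `excluded_taxon_labels` (default: uncharacterized, Mitochondria,
   Chloroplast, Eukaryota), case-insensitively. ASVs missing from the
   taxonomy table count as uncharacterized and are removed — losing an
   annotation should fail safe, not retain a dubious sequence.
3. **Prevalence/abundance.** An ASV is kept iff it is observed (count
   > 0) in at least `min_prevalence_samples` samples overall (default 2)
   AND its group-mean relative abundance reaches
   `min_group_mean_abundance` (default 1%) in at least one of the two
   compared groups.

Two genuinely open readings of the prevalence/abundance rule are exposed
as configuration rather than guessed silently:

* *Group mean vs. every sample.* Requiring 1% in **every** sample of a
  group is so stringent at group sizes around 10 that almost no ASV
  survives, defeating the purpose of keeping the prevalent community;
  the default therefore uses the group **mean** of per-sample proportions,
  with `abundance_scope = "every"` available.
* *AND vs. OR.* Whether both criteria or either criterion must hold to
  keep an ASV is set by `prevalence_abundance_logic`; the default AND is
  the aggressive-filtering reading.

Re-running the chain on its own output removes nothing further in
practice: stages 2 and 3 are idempotent by construction, and stage 1 can
only re-trigger if removing ASVs pushed a sample that sat exactly at the
depth boundary below it — not the case away from razor-edge depths, and
verified on simulated tables in the tests.

## The random-split permutation null

A between-group shared percentage is meaningless without knowing how much
two groups drawn from the *same* population would share, given finite
sampling and compositional noise. `random_split_null()` draws `n_splits`
(default 100) random partitions of one group's samples into two
pseudo-groups of `split_size` (default 5) each and recomputes the shared
percentage for every split, treating pseudo-groups exactly like real
groups — including re-applying the prevalence/abundance filter within the
split (disable with `refilter = FALSE` to filter once globally instead).

Design choices:

* Splits are sampled uniformly and independently across iterations, so
  duplicate configurations can occur among the 100; with only
  $\binom{10}{5}/2 = 126$ distinct 5+5 splits of 10 samples this is the
  simplest defensible reading. `unique_splits = TRUE` enforces
  distinctness instead (and errors once the supply is exhausted, which
  the tests exercise at 126 vs 127).
* The null is seeded and bit-reproducible; the seed is stored in the
  result object and in every pipeline artifact.

For calibration, the tests simulate both groups from one common
composition and check that the between-group shared percentage falls
inside the central 95% of the 100-split null, and that a strong
simulated diet shift (`overlap_fraction = 0.2`) drives the between-group
shared more than three null standard deviations below the null mean.

## The synthetic community generator

Raw reads behind the motivating comparisons are not publicly deposited,
so the package carries its own data-generating model with known ground
truth. `simulate_community()` draws, per group, a mean composition over
the ASVs assigned to that group's support, then per-sample compositions
from a Dirichlet centred on the group mean, then counts from a
multinomial at a per-sample depth:

* **Support overlap.** Exactly `round(overlap_fraction * n_asvs)` ASVs
  get non-zero expectation in both groups; the remainder is split between
  the groups. `identical_groups = TRUE` makes both groups use one common
  mean vector (the no-difference condition used for null calibration).
* **Abundance weights** are log-normal (sdlog 1.5), giving the
  heavy-tailed rank-abundance profile typical of 16S data.
* **Overdispersion.** The Dirichlet concentration (default 50) sets
  within-group compositional variability; 16S data are strongly
  overdispersed relative to multinomial sampling, and a concentration of
  this order reproduces that qualitatively.
* **Depth** is `depth_min + Poisson(depth_mean - depth_min)` (defaults
  1000 and 20,000), so no sample falls below the depth-filter boundary
  while depths still vary realistically.
* **Contaminants** (default 5% of ASVs) run through the same abundance
  machinery and differ only in carrying a flagged lineage — removing them
  is the taxonomy filter's job, which is exactly what the tests check.
* The default group sizes, 4 and 10, reflect the unbalanced two-diet
  design the package is aimed at.

The generator emulates compositional overlap, depth variation, and
contamination. It does **not** emulate sequencing error, chimeras,
phylogenetic correlation between ASV abundances, or sample-to-sample
depth/composition dependence; a passing test suite therefore demonstrates
correctness of the statistics under a Dirichlet-multinomial world, not
robustness to every artifact of real amplicon data.

Ground truth includes the per-group expectation vectors and the true
shared abundance fraction $\sum_i \min(p_A(i), p_B(i))$, which lets the
tests verify parameter recovery: the measured shared percentage is
monotone in `overlap_fraction` (Monte-Carlo over 20 replicates per
level), zero at disjoint supports, and near 100% for identical groups at
very high concentration.

## Distance phylogenetics

The chain for examining divergence of individual taxa from full-length
16S alignments is deliberately classical:

1. **Complete deletion.** Every alignment column containing a gap, `N`,
   or an IUPAC ambiguity code in *any* sequence is removed; the retained
   position count is reported. Ambiguity codes are treated as missing
   data here.
2. **Distances.** Pairwise distances use the Tamura–Nei (TN93) model —
   unequal base frequencies, separate purine (`k1`) and pyrimidine
   (`k2`) transition/transversion ratios. The model parameters are
   estimated **once for the whole alignment** by maximizing the sum of
   pairwise log-likelihoods (a composite likelihood), with each pair's
   divergence profiled out by 1-D optimization; distances are then
   computed per pair under the common parameters, in expected
   substitutions per site. With a single pair the composite likelihood
   coincides with the full likelihood, which the tests exploit by
   checking against an independent 3-parameter joint optimizer built on
   an eigendecomposed rate matrix. Under uniform frequencies and equal
   rates the estimate collapses to the Jukes–Cantor closed form
   $-\tfrac{3}{4}\ln(1 - \tfrac{4p}{3})$, checked analytically at
   $p = 0.1$. This is a shared-parameter reimplementation of the
   composite-likelihood idea, not a bit-for-bit clone of any particular
   GUI package's internals.
3. **Neighbor joining.** Classical Saitou–Nei agglomeration with the
   standard Q-criterion. Ties in Q are broken deterministically by the
   lowest active-node index pair. Negative branch lengths, which NJ can
   legitimately produce, are retained with a warning (clamping to zero is
   available via `clamp_negative = TRUE`) because retention preserves the
   exact-recovery property on additive matrices: for any tree-metric
   input the algorithm returns the generating topology with branch
   lengths exact to $10^{-10}$, which the tests verify on 100 random
   trees of up to 12 taxa and cross-check against an independent NJ
   implementation.
4. **Newick I/O** goes through `ape`, and trees are `ape::phylo` objects
   throughout, so the whole of that ecosystem's tooling applies.

Numerical choices: the per-pair divergence is optimized on a bounded
interval with tolerance $10^{-9}$ and the two rate ratios by Nelder–Mead
on the log scale (relative tolerance $10^{-10}$); a pair whose profiled
divergence lands at the upper bound is reported as saturated, by error,
with the pair named — saturation is not silently mapped to a large
number. Identical sequences short-circuit to distance zero. The joint
pair distribution is linear in three exponentials of the divergence, so
the likelihood is evaluated from three precomputed coefficient matrices
per parameter setting, keeping the full chain fast enough to run
end-to-end topology-recovery experiments (8 taxa, 1200 positions, 50
replicates) inside the test suite.

`simulate_alignment()` evolves sites independently along a tree under
TN93 from stationary root frequencies, using the same closed-form
transition probabilities. It exists so the chain can be tested end to
end against a known topology; its correctness is itself pinned by
closed-form limits (identical sequences at zero branch lengths, the
saturation mismatch fraction $\tfrac{3}{4}(1 - e^{-4d/3})$ for long
branches under the symmetric model, stationary base composition).

## Reproductive-events arithmetic

The calculator makes one point quantitatively: the evolutionary
opportunity (counted as reproductive events) inside a single human gut
dwarfs that of the host species. With the defaults — $1.1 \times 10^{13}$
bacterial cells produced per gut per day, a 79-year lifespan, a
365-day year, and a pre-agricultural human population of $5 \times 10^6$
females bearing 4.4 offspring over a 27-year generation:

```{r evo}
repro_comparison()
```

All outputs are pure arithmetic in the parameters, satisfy the closure
identity `years_equivalent * births_per_day * days_per_year =
lifetime_events` to relative $10^{-12}$, and scale with the expected
degree in every input (both property-tested). Two numerical notes:

* The lifetime event count from straight multiplication is
  $3.17185 \times 10^{17}$; rounded presentations of the same arithmetic
  sometimes quote $3.16 \times 10^{17}$. The package reports the straight
  product and makes no attempt to reproduce a particular rounding path.
* The fiber calculator reports losses of 75% and 86.7% for intakes of
  80–150 g/day against 20 g/day, both as $100(1 - \mathrm{us}/\mathrm{hg})$.
  No combination of these three intakes yields a loss above 90%; quoted
  upper-bound losses above that level must rest on additional inputs, so
  the calculator does not emit one.

The year length is fixed at 365 days by default (configurable) — with
parameters this coarse, calendar precision is noise.

## Problem sizes and reproducibility

Every stochastic computation takes an explicit seed and is bit-reproducible
under it; `run_pipeline()` writes an MD5-checksummed manifest so identical
configurations are verifiable at a glance. The shipped experiments use
problem sizes chosen to make the statistical checks decisive while staying
lightweight: 150-ASV communities at depth 20,000 for the overlap analyses,
100 null splits, 100 random trees (up to 12 taxa) for the NJ exactness
property, and 50 seeded replicates of the 8-taxon, 1200-position end-to-end
recovery experiment.

## Known limitations

* The partition treats ASVs as unrelated labels; no phylogenetic or
  functional similarity softens the unique/shared boundary.
* The null requires at least `2 * split_size` samples in the reference
  group and says nothing about groups smaller than that.
* Composite-likelihood distances assume a single stationary TN93 process
  across the alignment; rate variation across sites and non-stationary
  composition are not modelled.
* The generator's independence assumptions (see above) mean simulation
  results bound, but do not guarantee, behavior on real amplicon data.
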