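---
title: "Comparing SAG and MAG collections: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing SAG and MAG collections: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagmag)
```

Single-amplified genomes (SAGs) and metagenome-assembled genomes (MAGs)
are the two main culture-independent routes to genomes of uncultivated
marine prokaryoplankton, and they sample the same community through
very different lenses: SAGs descend from individually sorted cells, so
their lineage frequencies track cell abundances; MAGs are consensus
assemblies binned from community shotgun reads, which favors abundant,
low-diversity populations for assembly yet can recover rare lineages
from deep datasets while collapsing strain variation. **sagmag**
implements the comparative computations needed to quantify these
differences on one community: compositional differential abundance,
rank-wise taxonomic richness, pangenome accumulation, KEGG-module gene
content, chimera consensus calling, 16S conflict auditing and
fragment-recruitment comparison, together with a synthetic-data
generator that plants known effects so every stage can be validated
end to end.

## Compositional differential abundance

Lineage counts per sample are compositional: only relative information
is meaningful, and rare lineages produce spurious significance if
treated as plain counts. The pipeline follows the Dirichlet
Monte-Carlo / centered-log-ratio approach:

1. **Prevalence filter.** Only lineages observed in strictly more than
   90% of the samples of *every* observation method (SAG, MAG,
   amplicon, shotgun) are tested. This removes the noise floor of
   unevenly recovered rare lineages.
2. **Dirichlet Monte Carlo.** For each sample, `n_mc` probability
   vectors are drawn from the Dirichlet posterior with concentration
   `counts + 0.5`. The half-count prior is the published convention of
   this procedure; it is the only mechanism by which zero counts enter
   the analysis, and it is exposed as `prior_mass`.
3. **CLR transform.** Each instance is centered-log-ratio transformed.
   `clr_transform()` is defined in natural logarithms (`ln x_i - mean_j
   ln x_j`), but `differential_abundance()` reports *differences in
   base-2 CLR units*, the effect scale on which the conventional dual
   cutoff lives: an estimated difference of 2 is roughly a four-fold
   shift. In natural-log units an 8-fold shift would sit at
   `ln(8) * 19/20 = 1.97`, just below the cutoff, which makes clear
   that the cutoff was formulated on the log2 scale.
4. **Games-Howell across methods.** For every Monte-Carlo index and
   lineage, the per-sample CLR values are compared across the four
   methods with the Games-Howell post-hoc test. Per-instance estimated
   differences and p-values are averaged arithmetically over instances
   (the "expected" convention). Whether to test per instance and
   average after (default) or average the CLR values first is exposed
   as `mc_mode`, since either reading is defensible; the default is
   the one that propagates count uncertainty into the p-value.
5. **Dual cutoff.** A lineage/method pair is flagged when
   `|expected difference| > 2` *and* `expected p < 1e-3`, both strict.

The Games-Howell test assumes neither equal variances nor equal sample
sizes: each pair uses the Welch standard error and Welch-Satterthwaite
degrees of freedom, and refers `|t| * sqrt(2)` to the studentized range
distribution with `k` groups, which controls the familywise error over
all pairs. `studentized_range_sf()` evaluates the distribution by
Gauss-Legendre quadrature of the standard double-integral form (outer
integral over the chi scale factor, inner over the normal-range CDF).
Node counts were chosen so the absolute error stays below 1e-8 over
the `(q, k, df)` range the test visits (more outer nodes are used for
`df < 6`, where the scale density is wide relative to its peak); the
implementation is vectorized over `(q, df)`, which is what makes
Monte-Carlo-scale testing affordable (about 0.1 ms per evaluation
instead of ~0.5 ms for the classical implementation, which is also
less accurate in the far tail at small `df`).

## Exact paired signed-rank test

Recruitment fractions are compared per identity threshold across
samples with the paired Wilcoxon signed-rank test. Zero differences
are discarded before ranking (the classic convention; the
zero-inclusive Pratt variant is available through `zero_policy`), ties
receive mid-ranks, and for up to 25 nonzero differences the p-value is
exact:
the full distribution of the positive-rank sum over all `2^m` sign
assignments is computed by convolution over doubled (hence integer)
ranks, which is identical to complete enumeration. Beyond 25 pairs a
normal approximation with tie correction (`Var = sum(r^2)/4`, which
absorbs mid-rank ties) and a 0.5 continuity correction takes over.

## Greedy identity clustering

Three stages reduce to one primitive: greedy incremental clustering
under an identity threshold with a coverage requirement — species-like
dereplication of genomes at 95% ANI, "unigene" clustering of genes at
95% nucleotide identity with 90% coverage of the shorter sequence, and
protein-family clustering at various amino-acid identities. Sequences
are processed longest-first (ties by identifier) and join the
*best-scoring* acceptable representative rather than the first
acceptable one; this deviates from the incremental tools being stood
in for, deliberately, because it makes the partition deterministic and
insensitive to accidental tie order, and the brute-force replay oracle
in the test suite applies the same rule. ANI dereplication keeps the
first-acceptable rule, ranking genomes by completeness, because there
the ranking itself encodes the preference.

Pairwise identity comes from a global Needleman-Wunsch alignment with
affine gap costs (defaults: match +1, mismatch -1, gap open -3, gap
extend -1), with end gaps penalized. Identity is matches divided by
alignment columns *after trimming terminal gap runs*, so identity and
coverage stay decoupled: a short gene contained in a longer one can be
100% identical at low coverage of the longer sequence. Wildcards (`N`,
`X`) count as columns but never as matches. Score ties are broken
deterministically (more matches, then more aligned columns, then gap
runs pushed to the alignment ends, where they are trimmed); on random
small instances the resulting identity equals the maximum identity
over all optimal-score alignments found by exhaustive enumeration.
No k-mer prefiltering or banding is attempted: the package targets
desk-scale catalogs, not millions of genes.

## Pangenome accumulation

Accumulation (rarefaction) curves count distinct clusters — a genome's
multiple genes in one cluster count once. The permutation estimator
averages cumulative richness over 1000 random genome orderings; its
analytic twin uses the hypergeometric miss probability
`choose(N - n_c, g) / choose(N, g)` per cluster, evaluated via
log-gamma. The two must agree within Monte-Carlo error, which the test
suite checks against each other and against vegan's exact accumulator.

## Chimera consensus calling

Contamination estimators disagree enough that single-tool calls are
unreliable, so two layers are provided. The *default* call flags a
genome whose clade separation score exceeds 0.45 (strictly) at any
rank, optionally restricted to ranks with reference representation
above 0.5. The *consensus* call demands, at one rank strictly above
genus, CSS >= 0.85 and RRS >= 0.5 simultaneously, plus a second,
independent contamination estimate >= 10%. Evaluating the three
clade-score conditions at a single qualifying rank is the coherent
reading of "contamination detected above the genus level"; the
evidence rank reported is the qualifying rank with the highest CSS.
Both thresholds and the rank boundary are configurable, and the test
suite verifies monotonicity (relaxing a threshold never removes a
call) and that consensus calls are a subset of default calls.

## Synthetic data: what it emulates, and what it does not

The generator provides every input with planted truth, under the
conditions the analyses assume:

* **Community.** A single true composition drawn from a Dirichlet with
  power-law-ranked concentrations (`20 / rank^0.7` over 40 lineages by
  default) — a few dominant lineages and a long rare tail, the shape
  of epipelagic prokaryoplankton surveys. Four methods observe
  `renormalize(truth * bias)` through multinomial sampling at
  log-normal depths (mean 50,000 counts per sample, 20 samples per
  method by default). Differential lineages are planted as
  multiplicative biases.
* **Collections.** SAG lineages are drawn proportional to abundance
  (randomized cell sorting); MAG lineages proportional to
  `abundance^0.3`, enriching rare lineages the way
  abundance-correlation binning does. Completeness means are 69%
  (SAG) and 71% (MAG), the values of the filtered real collections.
* **Gene catalogs.** Core and flexible gene families with elevated
  flexible-gene dropout in MAGs (0.6 by default, vs 0.1 for SAGs) —
  the planted form of "MAGs are depleted in flexible genes" — plus
  per-copy point mutations and per-family KO labels grouped into
  modules.
* **Quality reports.** Planted chimeras receive evidence satisfying
  every consensus condition at a rank above genus; clean genomes
  receive evidence failing at least one, in one of three modes (low
  CSS, poorly represented, or second-estimator disagreement). Planted
  16S conflicts substitute a different-domain or different-phylum
  taxonomy for one copy.
* **Recruitment.** Each reference set covers each lineage
  independently with a set-specific probability, redrawn per sample;
  recruited reads get `1 - |N(0, 0.03)|` identity and normal alignment
  lengths around 150 bp with mass below the 100 bp filter.

What passing these tests shows is that each statistical procedure
recovers exactly the structure it claims to detect, at the stated
error rates, on data satisfying its assumptions. What it does not show
is robustness to the features real data add: taxonomy assignment
error, non-multinomial overdispersion within methods, chimeric reads,
strain microdiversity within 95% clusters, reference-database biases
shared between estimators, and gene-calling artifacts. The package's
claims are therefore about the computations, not about any particular
ocean.

## Numerical and design choices

* Every stochastic function takes an explicit integer seed and
  restores the caller's RNG state; identical seeds give byte-identical
  outputs, including through the file-level `run_stage()` front-end,
  whose provenance headers are derived from parameter digests rather
  than timestamps.
* Sample variances use the n-1 denominator throughout (required by
  Welch-Satterthwaite). Zero-variance groups are errors in
  `games_howell()` and reported exclusions in `compare_categories()`.
* Module overlap uses `|A ∩ B| / min(|A|, |B|)` so that a nested
  submodule counts as full overlap (the anti-double-counting purpose
  of the merge); Jaccard is available as an alternative. Merging is by
  connected components, so overlap is transitive by design.
* The 5% module-retention prevalence is computed over pooled SAGs and
  MAGs by default; a per-collection switch exists because the source
  phrasing admits both readings.
* The isolate-median standardization falls back to the median over all
  compared genomes when no isolate carries a category, and drops the
  category (with a message) if that is also zero. An even number of
  isolates uses the midpoint median.
* The epipelagic depth cutoff in `filter_genomes_metadata()` defaults
  to 100 m; this is a configuration choice (the boundary of the sunlit
  layer), not a value taken from any particular dataset.
* Accumulation curves are computed per collection subset; pooling is
  available by passing `subset = "all"`.
* Rank labels compare case-sensitively after prefix stripping, and an
  empty label ("unassigned") never equals anything, including another
  empty label — so unassigned taxa can neither create nor mask
  richness overlaps or 16S conflicts.

## Problem sizes

The bundled tests and the acceptance script run the composition
calibration at 20 lineages x 10 samples x 200 Monte-Carlo instances
over 100 replicates per scenario, the chimera fixture at 500 genomes
with 20 planted chimeras, clustering oracles at up to 12 sequences per
instance with exhaustive alignment enumeration up to length 8, and
gene catalogs of tens of genomes; these sizes were chosen so each
property is measured at meaningful statistical resolution while a full
run stays in the minutes range on one core. All sizes scale up through
function arguments.

## Known limitations

Clustering is quadratic in the number of sequences and intended for
desk-scale catalogs. KEGG modules are treated as flat KO sets (the
75% completeness fraction), not as boolean reaction graphs. The
recruitment model abstracts read mapping to a per-lineage coverage
coin flip, so it cannot exhibit mapping-specific artifacts. The
Games-Howell confidence intervals use the equal-`n` studentized-range
quantile convention with the pair's own Welch degrees of freedom,
matching standard practice.
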