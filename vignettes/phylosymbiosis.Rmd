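---
title: "Testing phylosymbiosis with cervsym: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing phylosymbiosis with cervsym}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the analysis

Phylosymbiosis asks whether the compositional relationships among
host-associated microbial communities recapitulate the hosts' phylogeny.
`cervsym` implements the standard cross-sectional design for closely related
host species sampled with replicates (for instance, several deer species in
one collection, each contributing a few fecal samples): build community
dissimilarities, summarize each species by a profile, cluster profiles into
a dendrogram, and ask whether that dendrogram is closer to the host tree
than random trees are. The two complementary routes are

1. a **matrix-level test**: Mantel correlation between host genetic
   distances and community dissimilarities, and
2. a **topology-level test**: Robinson–Foulds (RF) and Matching Cluster (MC)
   distances between the host tree and a UPGMA dendrogram, referenced
   against the uniform distribution over rooted bifurcating leaf-labeled
   topologies.

Both routes are permutation/randomization tests and make no parametric
assumption about the distances themselves. The topology route treats the
dendrogram estimate as fixed; what is randomized is the null topology. The
matrix route randomizes sample labels. Neither corrects for phylogenetic
non-independence beyond what the null already encodes.

# Data model and preprocessing

An `otu_table` couples an integer count matrix (samples × OTUs) with
seven-rank semicolon taxonomy strings and per-sample host metadata
(`host_species`, `genus`, `tribe`, `replicate`). Two TSV dialects are read
and written: the QIIME-classic orientation (`#OTU ID` header, OTUs as rows,
trailing `taxonomy` column) and plain samples-as-rows.

Preprocessing follows the common 16S workflow:

- **Singleton filtering** removes OTUs whose *total* count across all
  samples is 1 — these are dominated by sequencing error and inflate
  richness estimators.
- **Rarefaction** subsamples each sample without replacement (multivariate
  hypergeometric) to a fixed depth, default 9,683 reads — a typical MiSeq
  post-QC depth. Samples under the target are dropped, never padded.
  Rarefaction takes an explicit integer seed; there is no hidden RNG state.
  OTUs emptied by rarefaction are pruned by default so that downstream
  presence/absence metrics see the rarefied support (a flag retains them,
  since whether pruning should follow normalization is a genuine judgment
  call).
- **Rank aggregation** produces relative-abundance tables at any rank;
  OTUs unassigned at that rank are pooled as `unclassified_<parent>` under
  their deepest assigned ancestor, so composition tables always sum to one.

Alpha diversity uses base-2 logarithms for Shannon and equitability (the
convention of the classic QIIME toolchain; with ~1,000–2,000 OTUs per
sample this puts Shannon in the 7–10 bit range) and the bias-corrected
Chao1, `S + F1(F1-1)/(2(F2+1))`, which stays defined when no doubletons are
observed. Empty samples yield `NA` indices rather than zeros.

# Distances and ordination

Jaccard dissimilarity is computed on presence/absence; a pair of empty
samples is defined as distance 0 with a warning rather than `NaN`.
UniFrac is computed on the OTU tree as rooted in the input file: a branch
counts toward a sample when any descendant leaf is present in it.
Weighted UniFrac is **raw** (unnormalized) by default — the historical
default of the toolchain this pipeline mirrors — with the standard
normalization (dividing by the abundance-weighted root-to-tip lengths)
behind a flag. PCoA is classical scaling of `-d²/2`; negative eigenvalues
are reported but excluded from coordinates, no Cailliez correction is
applied unless requested, and axis signs are canonicalized (first non-zero
loading positive) so runs are comparable.

# Dendrogram and congruence

`species_profile()` collapses replicates to one row per species, either by
pooling counts or (default) by averaging relative-abundance profiles. The
mean profile is rescaled to integers with an adaptive factor chosen so no
OTU with non-zero mean abundance rounds to zero — presence/absence is
preserved exactly, which is what the downstream Jaccard + UPGMA consume.

`upgma()` is size-weighted average-linkage clustering with node height at
half the merge distance; on an ultrametric input matrix it reproduces the
generating tree exactly. Ties between merge candidates are broken by the
lexicographically smallest pair of cluster labels, making the dendrogram a
deterministic function of its input.

Rooted RF is the symmetric difference between the trees' sets of
non-trivial clusters, normalized by `2(n-2)`, its maximum over bifurcating
trees on `n` leaves. MC is the minimum-weight perfect matching between the
two cluster sets (padded with empty clusters if a tree is multifurcating),
with pair weight `|C1 Δ C2|`; the assignment is solved exactly — by
exhaustive matching enumeration up to 6 clusters and by the Hungarian
algorithm beyond. The MC normalizer is the metric's true maximum over tree
pairs, obtained by exact enumeration for `n ≤ 7` (shape representatives
against all labeled topologies, cached per session). For larger trees exact
diameter enumeration is quadratic in the topology count and impractical, so
the analytic bound `n(n-2)` is used and recorded in the result
(`normalizer_kind = "upper_bound"`). Published normalized values from other
toolchains may use other conventions, so normalized scores should be
compared only within one convention; the result object therefore also
carries `normalized_by_null_mean`, the observed distance divided by the
null mean — the random-expectation normalization — for readers who prefer
that scale.

`congruence_test()` scores the observed distance against uniformly random
rooted bifurcating topologies. Sampling is by sequential random leaf
insertion (each new leaf attaches above a uniformly chosen node or above
the root), which is exactly uniform over the `(2n-3)!!` labeled topologies.
For `n ≤ 8` the default mode enumerates all topologies and the p-value is
an exact tail probability; otherwise 80,000 Monte-Carlo draws are used. The
p-value counts topologies *at least as congruent* (distance ≤ observed):
ties enter the tail, and the plain proportion k/N is reported by default
with the conservative (k+1)/(N+1) variant behind a flag. With 7 leaves the
exact RF null is heavily concentrated near its maximum (mean 9.47 of 10,
SD 1.12), which is why even one matching internal node is already
informative, and why p-values under the null are lattice-valued rather
than uniform.

# Permutation statistics

Mantel uses Pearson correlation over distance-matrix upper triangles
(Spearman behind a flag), with simultaneous row/column permutation of one
matrix and a one-sided tail for positive association; 9,999 permutations by
default. ANOSIM uses Clarke's statistic
`R = (r̄_between - r̄_within) / (M/2)` with `M = n(n-1)/2` and average ranks
for ties — the standard divisor, verified identical to the reference
ecology implementation — with 999 label permutations. Both report the
plain-proportion p-value and are bit-reproducible given `(seed, n_perm)`.
Repeated ANOSIM tests at tribe/genus/species level are reported without
multiplicity correction, mirroring common practice in this analysis; treat
the per-level p-values accordingly. One-way ANOVA across host species uses
the classical F test with an explicit error when all within-group variances
are zero.

# The codivergence generator

`simulate_microbiota()` exists so every stage above can be validated
end-to-end with known truth. Its model:

1. Each OTU's species-level **presence** evolves along the host tree under
   a two-state gain/loss Markov process started at stationarity. Presence,
   not abundance, carries the phylosymbiosis signal because the headline
   metrics (Jaccard, unweighted UniFrac, UPGMA topology) are
   presence-driven.
2. The **signal dial** `s ∈ [0, 1]`: with probability `1 - s` an OTU's
   presence pattern is shuffled across species. This gives `s` a model-free
   interpretation — `s = 1` is pure codivergence, `s = 0` an exact null in
   which community structure is independent of the host tree — without
   touching the marginal presence frequencies.
3. Species-level expected abundances are log-normal(0, `abundance_sigma`)
   per species × OTU, masked by presence.
4. Each replicate inherits its species profile, loses each OTU with
   probability `replicate_dropout`, and draws exactly `depth` reads
   multinomially.

Defaults mirror a zoo-collection cross-sectional study: 7 species × 3
replicates, 2,000 OTUs, 9,683 reads per sample, dropout 0.05, σ = 1.
The gain/loss rates default to 0.25 + 0.25 per unit tree height. This was a
deliberate design point, not an arbitrary one: the resolvability of a merge
at depth `h` scales with the gap `e^{-r·2h1} - e^{-r·2h2}` between
consecutive node depths in flip-probability space, which vanishes for deep
nodes when the total rate `r` is large (saturation) and for shallow nodes
when `r` is small. Total rate 0.5 maximizes the deep-node gap for
unit-height trees; with rates 1 + 1, deep splits saturate and topology
recovery at full signal collapses to ~30%.

`simulate_host_tree()` draws pure-birth (Yule) trees rescaled to unit
height. A random Yule tree can, however, contain internal branches or
merge-height gaps so small that no finite community sample could resolve
them — an *unidentifiable* truth that would confound benchmarking. The
benchmark tree `reference_host_tree()` therefore takes the first Yule seed
whose internal branches are all ≥ 0.05 and whose internal node heights are
pairwise ≥ 0.12 apart. The condition is structural (set by the same
signal-to-noise analysis as the rates, before any benchmarking) and the
search is deterministic, so the reference tree is fixed and reproducible.

What the generator does **not** emulate: sequencing error and chimeras
(it starts from a post-clustering table), compositional abundance
correlations between OTUs, phylogenetic structure in *abundances* (only
presence evolves on the tree; abundance effects are i.i.d.), diet or
environmental covariates, and within-species host genetic structure.
Passing tests therefore demonstrate the correctness and calibration of the
*pipeline*, not that real fecal microbiota evolve by this model.

# Validation design and problem sizes

The test suite checks every distance and estimator against independent
oracles: brute-force cluster-set enumeration and factorial matching
enumeration for RF/MC (all 4-leaf topology pairs and 200 random 6-leaf
pairs), exact topology enumeration against Monte-Carlo nulls at 80,000
draws, chi-square uniformity of the topology sampler at 150,000 draws,
UPGMA round-trips on 100 random ultrametric trees, hand-enumerated UniFrac
branch sets and the star-tree identity with Jaccard, closed-form alpha
diversity to 1e-12, type-I error of Mantel/ANOSIM (500 null simulations
each, nominal 5%), and exhaustive-enumeration checks of small permutation
tests. End-to-end power uses 100 generator seeds at `s = 1` (low noise:
dropout 0, σ = 0.5) and 200 seeds at `s = 0` on the reference tree; the
observed operating characteristics are ~98% exact topology recovery, 100%
congruence significance at α = 0.05, and a null rejection rate within
binomial error of 0.05. These sizes keep the full suite under a couple of
minutes on one core while leaving Monte-Carlo margins (3 standard errors)
comfortably interpretable.

# Numerical and degenerate-input policy

- Distance matrices are validated (symmetry, zero diagonal, finiteness) to
  1e-8 and symmetrized to remove serialization fuzz.
- UPGMA writes branch lengths at 12 significant digits; ultrametricity
  holds to 1e-9.
- Two empty samples: Jaccard 0 with warning; weighted UniFrac errors on any
  empty sample (relative abundances undefined).
- Constant vectors: Spearman co-occurrence reports `NA` for the pair;
  Mantel errors on zero-variance triangles; ANOVA errors when every group
  has zero variance.
- Multifurcating inputs to RF/MC are legal; MC pads with empty clusters,
  RF simply compares smaller cluster sets. Exact congruence nulls and
  enumeration are guarded at 9 leaves; `mode = "auto"` switches to
  Monte-Carlo beyond 8.
- All stochastic functions take explicit seeds; the pipeline derives one
  seed per stage from the config seed by a fixed string hash, so any stage
  can be reproduced in isolation and a rerun of `run_analysis()` is
  byte-identical.

# Known limitations

- The topology null treats all rooted bifurcating topologies as equally
  likely; a UPGMA dendrogram estimated from noisy data is not uniform on
  that space even without signal, so null p-values are conservative in the
  bulk (they concentrate near 1) and the test's real operating
  characteristics are the simulated ones above.
- The MC normalizer for trees with more than 7 leaves is an upper bound,
  so normalized MC values are then conservative (biased low); raw values
  and p-values are unaffected.
- Rarefaction to a single depth discards reads; alternatives (e.g.
  coverage-based normalization) are out of scope here because the pipeline
  deliberately mirrors the classic workflow.
- Mantel tests on distance matrices have known sensitivity to
  autocorrelation; the topology-level test is the more specific instrument
  for phylosymbiosis, which is why both are reported.
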