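---
title: "Benchmarking cell lineage tree reconstruction from microsatellite signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking cell lineage tree reconstruction from microsatellite signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mslineage)
```

## The problem

Every cell of a multicellular organism descends from the zygote through a
binary tree of cell divisions — the cell lineage tree.  Microsatellite (MS)
loci mutate by replication slippage at rates high enough (around 1e-5 per
locus per division in wild-type tissue, around 1e-2 in mismatch-repair
deficient mice) that the vector of repeat counts over a panel of roughly a
hundred loci gives each sampled cell a nearly unique genomic signature.
Distances between signatures can then be fed to standard phylogenetic
algorithms to reconstruct the lineage relations among single cells.

Cell lineages differ from species phylogenies in ways that matter for
method choice: the trees are shallow (tens to hundreds of divisions), all
loci are completely linked (each cell has a single parent cell), depths
vary enormously between cell types, and the mutation process is a
stepwise random walk on repeat number rather than a substitution process.
`mslineage` implements a benchmarking framework for this setting: the
distance measures, tree building algorithms, tree quality statistics, a
forward simulator that generates ground-truth lineages, and the ranking
and reliability machinery needed to compare methods.

## Signatures and the root

A dataset (`ms_dataset`) is a matrix of integer repeat counts, one row per
cell and one column per *allele key* (a locus/allele-index pair; autosomal
loci contribute two keys, chromosome-X loci in males one).  Tables in the
two-columns-per-locus supplementary layout are read with
`read_allele_table()`; `"X"` and empty cells become missing values.  Two
data-cleaning rules are applied at parse time:

* **Allelic dropout.** An autosomal locus with exactly one measured allele
  in a cell is treated as a dropout (the other allele failed to amplify,
  so the measured size is unreliable) and both alleles are masked for that
  cell.  X-linked single-allele loci are exempt.  The underlying principle
  is to analyze only loci showing the expected number of alleles.
* **Phase ambiguity.** The table layout does not encode phase, so the two
  alleles of a heterozygous autosomal locus are stored sorted by value.
  When, for a pair of cells, either cell's two alleles differ by fewer
  than 2 repeat units (but are not equal), the sorted matching is
  ambiguous and the locus is dropped for that pair
  (`shared_valid_alleles()`, `min_allele_sep`).  The threshold is
  configurable; 2 units is the smallest difference that survives a
  single-step mutation on either allele without the order flipping.

Distances between a pair of cells use only the alleles measured in both;
a pair sharing fewer than 25 alleles is flagged unreliable (the panel's
working minimum).

The tree root is the putative zygote's signature
(`compute_root_signature()`): a designated bulk/tail sample for mice, the
per-allele median over cells for humans (lower median, so root values
stay integral), and for multi-individual trees a weighted mean of the
per-organism zygotes, weighted by cell count by default.

## Distance measures

With $x_i^k$ the repeat count of cell $i$ at shared allele $k$, $r^k$ the
root value, and $S_{ij}$ the shared allele set:

* **Absolute**: $\frac{1}{|S_{ij}|}\sum_k |x_i^k - x_j^k|$ — mean repeat
  difference; grows with divergence, so it carries depth information.
* **Normalized absolute**:
  $\frac{1}{|S_{ij}|}\sum_k \frac{|x_i^k - x_j^k|}{|x_i^k - r^k| + |x_j^k - r^k|}$.
  Each allele's difference is normalized by the two cells' total
  deviation from the root at that allele, so loci with few mutations get
  large weight and the overall depth scale cancels.  Alleles at which
  both cells equal the root (a 0/0 term) carry no information about
  relative divergence and are skipped.  This normalizer is this package's
  transcription choice: it is the form consistent with signatures being
  deviations from the putative zygote and with the measure's documented
  property of eliminating depth.
* **Euclidean**: $\sqrt{\frac{1}{|S_{ij}|}\sum_k (x_i^k - x_j^k)^2}$.
  The mean (rather than sum) of squares keeps pairs with different
  shared-allele counts comparable, consistent with the other measures
  being averages; this, too, is a transcription choice.
* **Equal-or-not**: the number of shared alleles at which the two cells
  differ (optionally normalized to a fraction).
* **Maximum likelihood** (`ml_distance()`): the integer number of
  divisions $t$ maximizing
  $\prod_k P(x_i^k - x_j^k \mid t, \mu_k)$, where the per-division
  transition law mutates with probability $\mu_k$ and then steps by a
  draw from the step model — the symmetric stepwise model (SMM, a single
  repeat up or down with equal probability) or a multistep model (MMM,
  symmetric truncated geometric magnitudes, $p = 0.5$, up to 5 units;
  the magnitude law is configurable since only symmetry is prescribed).
  Transition probabilities are computed exactly by conditioning the
  mutation count on Binomial($t$, $\mu$) and convolving the step law
  (`step_transition_probability()`).  Rates come from a
  `rate_model()`: equal (mouse default 1/30; human 1/1000), distinct
  mono-/di-nucleotide rates (1/22, 1/32), or linear in repeat number
  (slope 0.0183, intercept 1/2000, evaluated at the pair's mean repeat
  count, since the parameterizing length is otherwise ambiguous).
  The likelihood is maximized over an integer grid $0..t_{\max}$
  (default 1000) with summed log likelihoods; no continuous refinement
  is attempted because divisions are integral and the binomial
  likelihood is only defined at integer $t$.  Near-identical
  length-dependent rates are pooled to three significant digits so one
  transition table serves a rate group.

`build_distance_matrix()` assembles the symmetric matrix over all pairs,
records per-pair shared-allele counts and reliability flags, and can
append the root signature as a `"(root)"` pseudo-leaf for outgroup
rooting.

## Tree building and depths

`neighbor_joining()` is a from-scratch NJ with one correction: a negative
branch length arising at a join is set to zero and the deficit moved to
its sibling branch, preserving the cherry's summed length; topology is
unaffected (it depends only on the distance matrix).  Q-criterion ties
break on the lexicographically smallest label pair, so results are
deterministic.  Trees are rooted by the `"(root)"` outgroup: the root is
placed at the pseudo-leaf's attachment point and the pseudo-leaf removed
(`root_tree()`).  `upgma()` (average linkage, via phangorn) serves the
equal-depth scenarios; its input is label-sorted first so tie handling is
deterministic.

Because the normalized-absolute measure destroys depth,
`assign_normabs_depths()` re-derives depths for its topologies from the
absolute-distance matrix: each leaf's depth is its absolute distance to
the root; sibling pairs are then collapsed bottom-up, the parent's
root distance being $(d_{a,root} + d_{b,root} - d_{ab})/2$ with the
standard reduction $d_{u,k} = (d_{a,k} + d_{b,k} - d_{ab})/2$, until the
root is reached.  Parent depths are clamped into
$[0, \min(\text{child depths})]$ so depths and branch lengths stay
non-negative.  Note these depths are in units of mean absolute repeat
change, a monotone proxy for divisions (equal to divisions times the
expected per-division change for small $\mu t$; back mutations compress
the scale at large $\mu t$).

## Tree quality statistics

Given a leaf labeling into groups (individuals or cell types):

* **QLC** (quality of the largest cluster): each node — internal nodes
  plus, as trivial one-leaf clades, the leaves, so singleton groups are
  scoreable — is scored for a group by recall (fraction of the group
  under the node) times purity (fraction of the node's leaves in the
  group), zero when purity is at or below 1/2; a group takes its best
  node and the tree the mean over groups.  1 exactly when every group is
  one clade.
* **TE** (tree entropy): for each pair of groups, restricted to the
  pair's leaves, count each group's maximal single-group clades
  ($c_a$ clusters of $n_a$ cells, $c_b$ of $n_b$); the number of
  equivalent states is
  $\binom{n_a-1}{c_a-1}\binom{n_b-1}{c_b-1}$ — the compositions of each
  group into that many clusters — and the pair's entropy is its natural
  log.  This is the reading under which one-clade-per-group gives
  exactly 0 at any group size, matching the published anchor values.
  The scalar TE is the mean over pairs; for higher-is-better reporting
  within a comparison set use `te_transform()` (max observed minus
  value).
* **HS** (hypergeometric score): every node/group pair gets the exact
  upper-tail hypergeometric probability of the observed group count in
  the node's subtree (`hypergeometric_tail()`); Benjamini-Hochberg FDR
  control at 20% across all node-by-group tests marks the significant
  clades, and the tree's HS is the mean over groups of each group's
  smallest p-value (0 = maximal enrichment).  BH is this package's
  choice of FDR procedure; the combination across groups (mean of
  per-group minima) is likewise a documented transcription choice.

Depth separation between two groups uses the leaf depth distributions
(`leaf_depths()`): the two-sample Kolmogorov-Smirnov test
(`ks_statistic()`), the normalized mean distance
$|\bar x - \bar y| / \sqrt{s_x^2 + s_y^2}$ (`normalized_distance()`,
higher = better separated), and the overlap percentage
(`overlap_percentage()`): orienting $x$ as the lower-mean sample, each
$x$ point counts the $y$ points at or below it and each $y$ point the
$x$ points at or above it (ties count as penetration — the conservative
rule, reporting more overlap), scaled to a percentage of the maximum
$2 n_x n_y$.  It is 0 for disjoint ranges, driven by extreme cells, and
decreases with better separation.

## The simulator

`simulate_replicate()` generates ground truth: a scaffold from root to
per-individual zygotes to per-type ancestors, with a random
coalescent-shaped binary subtree (rescaled to the configured depth,
branch lengths rounded to whole divisions) down to the sampled cells.
Along each branch of $t$ divisions every locus mutates
Binomial($t$, $\mu$) times, stepping by the step model; repeat counts
pushed below 1 reflect at 1 (events counted).  Initial repeat counts are
uniform integers in 10–30 — a typical panel range, needed only by the
length-dependent rate model.  Each locus carries one simulated allele
(the framework treats a locus' two alleles as two independent loci, and
most analyzed loci are X-linked single-allele).  Every recorded mutation
event can be replayed (`replay_events()`), and replay reproducing every
leaf exactly is a tested invariant.  Defaults mirror the benchmark
conditions: topology A (deep leaves below shallow ancestors) vs B (the
reverse), 3 individuals with 5 cell types, rates 1/100–1/10000, 50–500
loci.

Two purpose-built scenarios:

* `simulate_two_stage()` — two sibling individuals; stage 1 runs 40
  divisions from the mother's zygote to each sibling's zygote, stage 2
  runs `ratio * stage1` divisions from each zygote down a random binary
  subtree to each cell.  The API ratio is stage2/stage1 (the simulation
  study's axis); the reciprocal convention, under which the published
  operating point 0.2 means stage2/stage1 = 5, is accepted via
  `ratio_convention = "stage1_over_stage2"`.
* `simulate_depth_pair()` — two cohorts at true depths (20, 50)
  (shallow) or (250, 300) (deep) below a shared root, isolating
  depth-recovery performance.

`separation_fraction()` reconstructs each replicate and reports the
fraction in which every individual's cells form a clade of the cell
topology.  Separation is judged on the cells' splits (unrooted
monophyly, `forms_clan()`): under the normalized-absolute measure the
root pseudo-leaf is *exactly* equidistant (distance 1) from every cell —
every allele either cancels or contributes a full unit — so its NJ
attachment point carries no grouping information, and conditioning
separation on it would measure rooting noise rather than clustering.

What the simulator does *not* emulate: PCR/electrophoresis measurement
noise, realistic allelic dropout structure (only a uniform missingness
mask is offered), aneuploidy, locus-specific rate heterogeneity beyond
the configured rate models, and selection of stem-cell hierarchies.
Passing simulation benchmarks therefore demonstrates correctness of the
algorithms under the stepwise mutation model, not robustness to every
noise source in real capillary data.

## Ranking and reliability

`score_clustering()` emits long-format score rows; `rank_methods()`
turns them into the benchmark's four summaries per score (average score,
normalized average, average rank, times ranked best), sharing ranks on
ties and orienting every score as higher-is-better before normalizing by
the per-dataset best.  `partition_similarity()` compares topologies as
the shared fraction of internal-edge bipartitions.  `bootstrap_loci()`
resamples loci with replacement (keeping an autosomal locus' two alleles
together), reporting per-clade support and group monophyly support over
100 resamples by default.  `permutation_test()` shuffles whole-cell
labels over a fixed topology and reports
$(1 + \#\{\text{permuted} \ge \text{observed}\})/(1 + n_{perm})$,
orientation-aware.

## Problem sizes and numerical choices

The shipped test and acceptance runs use scaled simulation sizes chosen
as this package's own defaults: 200 replicates for the two-stage and
depth-pair studies (the original study used 1000), 200 simulated pairs
for ML divergence recovery, 100 bootstrap resamples, and 999
permutations.  Tolerances: NJ/UPGMA exactness is asserted via partition
identity and metric equality at 1e-6; ultrametricity at 1e-9 relative;
ML recovery within 15% of truth; transition-table mutation counts are
truncated where the binomial tail falls below 1e-14, and FFT round-off
in step convolutions is clamped at zero.  Degenerate inputs are defined:
empty shared-allele sets are errors, all-identical datasets produce
zero distances and zero depths, a zero-spread depth comparison returns 0
(equal means) or infinity with a warning (different means), and
all-skipped normalized-absolute pairs return distance 0.

## Known limitations

* The Table-1-style reproduction of published per-dataset scores
  requires the original supplementary allele tables, which are not
  redistributable here; the reproduction test documents the expected
  file layout and runs when the tables are supplied.
* Quartet amalgamation (QMC) and Bayesian genealogy samplers (BATWING)
  are external tools by design; their output trees can be scored via
  `read_newick()`.
* Absolute-distance depths are in mean-repeat-change units, not
  divisions; converting to divisions requires the mutation rate and
  saturates for $\mu t$ near or above 1.
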