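---
title: "Assessing marker utility across a rapid radiation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing marker utility across a rapid radiation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Rapid species radiations leave very short internal branches in the species
tree. Over such internodes, ancestral polymorphism frequently fails to sort
into the descendant lineages (incomplete lineage sorting, ILS), so individual
gene trees disagree with each other and with the species tree; a single
episode of ancient hybridization adds a systematic, directional discordance
on top of the stochastic one — classically visible as a mitochondrial
topology that conflicts with the combined nuclear topology. A practical
question for anyone planning a phylogenetic study is therefore: *which
markers are worth sequencing?* `radsplit` implements a complete, testable
version of the marker-utility workflow used in colobine-monkey phylogenetics:
characterize each locus, infer per-locus and combined trees with support,
count how many reference nodes each locus recovers (stratified by support),
rank and classify the loci, and test topology conflicts formally.

Because the original data live in sequence archives, the package ships a
first-class synthetic-data module whose defaults emulate the study design:
18 taxa (14 ingroup, 4 outgroup), 44 slow nuclear non-coding loci of 337-868
aligned positions at about 4% mean pairwise divergence, and one fast
~16.5 kb mitochondrial partition (17 sub-partitions sharing a single
non-recombining gene tree) at about 18.5% divergence.

## The coalescent simulator

`sample_gene_tree()` implements the standard multispecies coalescent: one
haploid lineage per species (matching a one-individual-per-species sampling
design), branch lengths in coalescent units of $2N$ generations, and within
any branch carrying $j$ lineages a coalescence rate of $\binom{j}{2}$ per
unit time. Above the root, everything coalesces. The simulation sweeps
epochs delimited by speciation times, so simultaneous (zero-length)
internodes and an introgression pulse are handled exactly.

Introgression is a single pulse, not continuous migration: at time $t_e$
each lineage in the recipient branch jumps to the donor branch with
probability $p$. This is the simplest generator of the
mito-nuclear-discordance pattern: applying the pulse to the mitochondrial
gene tree only (`mt_introgression`) moves the recipient taxa into the
donor's clade in the mitochondrial tree while the nuclear loci continue to
track the species tree.

Three analytic laws anchor the implementation and are asserted in the test
suite:

* the mean coalescence time of two lineages in one population is 1;
* for three taxa with internal branch $T$, the probability that the gene
  tree matches the species topology is $1 - \tfrac{2}{3}e^{-T}$;
* two JC69 sequences at total distance $t$ mismatch at a fraction
  $\tfrac{3}{4}(1 - e^{-4t/3})$ of sites.

### The default species tree and calibration

The default 18-taxon tree (`default_species_tree()`) mirrors the combined
nuclear topology of the emulated study: an odd-nosed clade with *Pygathrix*
sister to *Rhinopithecus*, *Presbytis* joining the odd-nosed group
(clade 1), *Semnopithecus* + *Trachypithecus* (clade 2), a monophyletic
African pair, and four outgroup primates. The radiation's inter-generic
internodes are set to 0.6 coalescent units — short enough that roughly a
third of nuclear gene trees are locally discordant
($1-\tfrac{2}{3}e^{-0.6} \approx 0.63$ concordance per node), which is the
regime the method is meant for. No published values exist for these
internodes; they are configuration, not estimates.

Substitution rates are specified as *divergence targets*. The shipped
constants (0.001435 and 0.01739 expected substitutions/site per coalescent
unit for nuclear and mitochondrial loci) were calibrated once, by
simulation on the default tree, so that the default bundle reaches ~4%
mean pairwise nuclear and ~18.5% mitochondrial p-distance; per-locus rate
multipliers follow each panel marker's nominal divergence relative to its
class mean, so fast loci (e.g. a 22.6%-divergent outlier) stay fast in
simulation. Default models are HKY85+G ($\kappa = 4$, $\alpha = 0.70$) for
nuclear loci and GTR+I+G ($I = 0.43$, $\alpha = 1.10$, strong transition
bias, mitochondrial base composition) for the mitochondrial partition.

What the simulator does *not* emulate: indels and alignment error (all
alignments are gap-free), within-locus recombination, base-composition
drift across lineages, and population-size changes. Tests passing on this
generator therefore validate the *inference machinery*, not robustness to
alignment artifacts.

## Inference engines

**Likelihood.** `log_likelihood()` is Felsenstein pruning over compressed
site patterns with a small C++ kernel. GTR-family models are scaled to mean
rate 1 at stationarity, so branch lengths are expected
substitutions/site. `+G` uses Yang's mean-of-category discretization with
$k=4$ equal-probability classes; `+I` is a zero-rate class of weight $I$,
with the gamma rates rescaled by $1/(1-I)$ so the overall mean rate stays 1.
Gaps, `?` and IUPAC codes enter as partial likelihood 1 over compatible
states. The suite verifies pruning against explicit summation over all
internal-state assignments (tolerance $10^{-10}$), against an independent
implementation (phangorn), and against the pulley principle (re-rooting
invariance).

**Branch lengths and tree search.** Branch lengths are optimized
coordinate-wise by Brent search on $[0, 10]$ substitutions/site, sweeping
until the log-likelihood gain falls under `tol` (default $10^{-6}$); the
trace is monotone by construction. The ML topology search is NNI
hill-climbing: every internal edge's two rearrangements are evaluated with
branch-length re-optimization, the best strict improvement is accepted, and
ties break on the lexicographically smallest canonical Newick so the search
is deterministic. For more than 8 taxa, candidate screening re-optimizes
only the central (rearranged) edge — the single edge whose bipartition the
move changes — and the winner is then fully re-optimized; for 8 or fewer
taxa every candidate is fully optimized, which is what lets a 4-taxon
search provably equal exhaustive evaluation.

**Parsimony.** `fitch_score()` uses bit-coded state sets; missing data
carries the full state set. The heuristic search is random-order stepwise
addition followed by NNI swapping, with an automatic exhaustive search for
seven or fewer taxa (all $1\cdot3\cdots(2n-5)$ topologies). TBR swapping is
a recognized extension, not implemented.

**Distance methods.** p-distance and K2P with pairwise deletion; a pair
sharing no comparable sites is an error rather than a silent `NA`.
Neighbor joining clamps a negative pendant estimate to zero and shifts the
deficit to its sibling, preserving the pair's summed length; on additive
inputs it is exact (asserted against generated additive matrices).

**Supports.** Bayesian posteriors of the emulated workflow are proxied
throughout by nonparametric bootstrap proportions: columns are resampled,
trees re-inferred, and each split of the point-estimate tree (or of the
majority-rule consensus of the replicates) is annotated with its replicate
frequency. The congruence threshold (default 0.95, mirroring a
strict-posterior convention) is configurable — 0.70 is the common choice
when supports are bootstrap proportions.

**Model selection.** `select_model_aic()` fits the twelve-model ladder
{JC69, K80, HKY85, GTR} × {none, +I, +G} on a fixed NJ base topology:
free parameters (frequencies via log-ratio transform, exchangeabilities,
$\kappa$, $I$, $\alpha$ on transformed scales) by Nelder-Mead (Brent when
one-dimensional), alternating with branch-length sweeps, warm-starting each
candidate from the previous one's branch lengths. AIC counts
substitution-model parameters ($I$ counted whenever it was estimated, even
if it lands on 0); branch lengths are shared across candidates on the
fixed topology and cancel from the ranking. Initialization: empirical base
frequencies, $\kappa = 2$, $\alpha = 0.5$, and $I = 0.1$ (a boundary start
of exactly 0 would pin the logit transform).

## Congruence scoring

`reference_nodes()` enumerates the reference tree's internal bipartitions
whose outgroup-free side holds at least two ingroup taxa, numbered in
preorder (13 for the default 18-taxon design); a published numbered subset
can be supplied instead. A gene tree recovers a node when the node's
bipartition, restricted to the taxa shared with the gene tree, occurs among
the gene tree's bipartitions; recovered nodes are stratified by the *gene
tree's own* support on the matching edge (threshold 0.95 by default;
edges without recorded support count as weak). Loci are ranked by total
recovered nodes, then strong count, then name, and classified good /
medium / poor by tertiles with ties sharing the better class. Where the
source workflow read its strata off per-gene Bayesian consensus trees,
this package uses each locus's bootstrap majority-rule consensus.

## Topology tests

`sh_test()` and `kh_test()` consume a sites × topologies matrix of
per-site log-likelihoods (`sitewise_lnL()`, which sums exactly to the
total). Both use RELL resampling — resample site indices, re-add
log-likelihoods, never re-optimize — with $B = 10{,}000$ replicates by
default and replicate seeds derived from one master seed. The SH test
centers each topology's resampled totals on its own mean and compares the
observed $\delta_i = \max_j \ell_j - \ell_i$ with the null distribution of
$\max_j \tilde R_j - \tilde R_i$; the ML topology's $p$ is exactly 1 by
construction, $p$-values are monotone in $\delta$, and the test is
conservative under the exchangeable null (asserted at a 7% empirical cap
on nominal-5% rejections). The KH test is the two-sided paired version for
exactly two topologies. The AU test (multiscale bootstrap) is deliberately
out of scope; reports label results SH/KH.

## The pipeline

`run_pipeline()` chains simulate (or replay user FASTA alignments) →
characterize → infer → score → test, writing TSV tables, support-annotated
Newick trees, a manifest and a per-stage log under `out/`. Every stage
seeds deterministically from one master seed, so a config + seed pair
reproduces the run byte-for-byte. Combined ("concatenated") analyses use a
single model on the concatenation — per-partition joint likelihood is out
of scope — while each locus gets its own AIC-selected model when
`model_policy = "aic"`. The mitochondrial sub-partitions are concatenated
for the combined mitochondrial tree, matching their shared single-locus
history.

## Problem sizes and numerical choices

The test suite runs the engines at oracle-checkable sizes (4-9 taxa;
enumeration, Sankoff DP, brute-force split tallies, a CLT oracle for KH)
and the full 18-taxon design for the simulator and congruence tests; the
end-to-end discordance scenario uses the full 44-locus nuclear panel and a 6 kb
three-part mitochondrial partition with a total (proportion 1)
introgression pulse shortly after the recipient branch arises, sizes at
which the expected pattern is essentially deterministic. The acceptance script characterizes the full default bundle
(44 nuclear loci + 17 mitochondrial sub-partitions), infers both combined
trees under HKY85+G, scores all 44 nuclear loci against 100-replicate NJ
bootstrap consensus trees, and runs the discordance scenario at the sizes
above. Monte-Carlo assertions use 3 standard-error bands; likelihood
oracle comparisons use $10^{-10}$; branch lengths live in $[0, 10]$ with
optimization tolerance $10^{-6}$ lnL units.

## Known limitations

* NNI-based searches can in principle stop in local optima that TBR would
  escape; at the emulated design's signal levels the suite shows this does
  not occur for clean data, but it is the main caveat for harder problems.
* The K2P correction is undefined past saturation
  ($1 - 2P - Q \le 0$); such pairs raise an error and the caller falls
  back to p-distances (the pipeline does this automatically).
* AIC model fits use a fixed base topology, the standard shortcut of
  desktop model-selection tools; model ranks are insensitive to this at
  the divergences simulated here.
* The congruence score compares bipartitions only; quartet- or
  distance-based congruence is out of scope (Robinson-Foulds appears only
  as a test oracle).
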