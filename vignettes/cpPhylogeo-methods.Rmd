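---
title: "Methods and design of cpPhylogeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of cpPhylogeo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpPhylogeo)
```

# Scope

cpPhylogeo implements the full analysis chain used in intraspecific
phylogeography of a single non-recombining, maternally inherited locus —
typically a chloroplast DNA spacer sequenced across the populations of one
plant species. Because cpDNA moves only with seed, its spatial structure
reflects seed dispersal, not pollen flow. The chain is:

1. read an aligned FASTA, drop indel-bearing columns, collapse sequences to
   haplotypes;
2. per-population and pooled diversity statistics (Nei's haplotype
   diversity and its sampling variance, nucleotide diversity, Watterson's
   estimator);
3. a minimum spanning network over haplotypes with all co-minimal
   alternative connections;
4. nested clade analysis: hierarchical nesting of the network, clade (Dc)
   and nested clade (Dn) distances, permutation tests, a nested
   contingency test, and an inference key encoded as an editable decision
   table;
5. pairwise Hudson FST with island-model gene flow (Nm) and an isolation by
   distance test;
6. a neighbor-joining tree under the Kimura two-parameter model with
   nonparametric bootstrap;
7. classic and generalized skyline plots of effective size history from an
   ultrametric genealogy;
8. a structured-coalescent simulator that generates data with the
   statistical structure the analysis assumes, so every stage is testable
   without external downloads.

A packaged example dataset — the haplotype-by-population count table,
site coordinates and clade memberships from a range-wide cpDNA spacer
survey of an endangered desert shrub (eight populations, 77 individuals,
38 haplotypes, one monomorphic deme) — serves as a frequency-only input
that exercises the count-based half of the pipeline.

# Statistics

## Diversity

Haplotype diversity uses Nei's unbiased estimator
$h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$ with the sampling variance

$$V(h) = \frac{2}{n(n-1)}\left\{2(n-2)\left[\sum p_i^3 -
\left(\sum p_i^2\right)^2\right] + \sum p_i^2 -
\left(\sum p_i^2\right)^2\right\}.$$

Nucleotide diversity $\pi$ is the mean pairwise difference per site over
all $\binom{n}{2}$ pairs; sites where either sequence carries N are
excluded per pair, with a per-pair effective length. Field software labels
differ here: several programs print "nucleotide difference" computed as
$\pi$, and back-calculation from published tables (segregating sites and
sample sizes) confirms that the printed quantity in our example dataset is
$\pi$, not Watterson's $\theta_W$. Watterson's estimator
$\theta_W = S / a_n / L$ is therefore provided separately under its own
name, and no standard deviation of $\pi$ is reported (the published
variance formulas differ between program releases).

## Mutational steps and the network

Pairwise haplotype distances count sites with differing unambiguous bases.
The network is Kruskal's minimum spanning tree with deterministic
tie-breaking (weight, then lexicographic endpoint pair), augmented with
every non-tree pair whose direct distance equals the minimax (bottleneck)
path weight between its endpoints. These "alternative" edges are exactly
the co-minimal connections that classic minimum-spanning-network software
emits, and they make the output independent of input order: a test shuffles
the haplotype order and asserts the same edge set. No median (inferred)
haplotypes are created; multi-step edges carry their step count.

## Nested clade analysis

Nesting follows the classic linking rules: tips of the cladogram unite with
the interior unit one connection away into 1-step clades; the formed clades
are pruned and the pass repeats on the residue; the same rules lift 1-step
clades to 2-step clades and so on, until a level holds a single clade (the
total cladogram). Three situations the printed rules leave open are
resolved as follows:

* **Reticulation loops** are broken, for nesting only, at the cycle edge
  joining the two lowest-frequency haplotypes (summed frequency, then
  lowest single frequency, then lexicographic order); removed edges are
  recorded in the design object.
* **Stranded units** — a unit left alone after a pruning pass — attach to
  the adjacent nested category of smallest size, ties broken toward the
  clade whose connecting unit was an anchor (interior) unit, then by clade
  id.
* **Disconnected residues**: pruning can disconnect the interior residue,
  so each pass operates per connected component.

A clade is a *tip* when exactly one mutational connection leaves it toward
the other members of its nesting clade, and *interior* otherwise;
connections are counted on the full network including loop edges, so all
members of a reticulation cycle nested together are interior.

Dc is the count-weighted mean great-circle distance of a clade's
individuals from the clade's own geographic centre; Dn measures the same
individuals from the nesting clade's centre. Centres are count-weighted
means of the populations' unit vectors on the sphere, renormalised — this
is well-defined at all longitudes, unlike raw latitude/longitude averaging,
and a test verifies invariance under uniform longitude translation.
Significance comes from permuting individuals' population labels among the
member clades of each nesting clade, holding clade sizes fixed;
`p_small`/`p_large` count permuted statistics at or beyond the observed
one, including the observed arrangement in numerator and denominator so
p is never zero. Interior-minus-tip contrasts (size-weighted) are
recomputed per permutation. An exact-enumeration mode exists for tiny
nesting clades and is checked against an independent brute-force oracle.
The nested contingency test permutes the same labels and compares Pearson
chi-square statistics.

## The inference key

The 1995 interpretation key is shipped as a decision table
(`inst/extdata/inference_key.tsv`: step, condition, yes-target, no-target),
so that later key revisions can be swapped in without touching code. Two of
the key's questions are about geography that a count table cannot answer
verbatim, and are operationalised:

* *range overlap*: clades are treated as allopatric when their population
  sets do not overlap (when every member clade is flagged, allopatry means
  the flagged clades fall into at least two range-disjoint groups);
* *deep separation*: the connecting edges between the flagged clades and
  the rest carry more mutational steps than the network-wide mean edge
  weight.

The canonical chains are preserved: significantly small tip Dc with no Dn
reversal and overlapping ranges exits 1-2-3-4-No as restricted gene flow
with isolation by distance; the allopatric deep-branch variant exits
1-2-3-4-9 as past fragmentation. Conclusions are restricted to the
enumerated outcomes (restricted gene flow with IBD, restricted gene flow
with some long-distance dispersal, long-distance colonization, past
fragmentation, contiguous range expansion, inconclusive), and a
non-significant nested contingency test short-circuits to inconclusive.

## Population structure and isolation by distance

FST for sequence data is the Hudson–Slatkin–Maddison estimator
$F_{ST} = 1 - H_w/H_b$, with $H_w$ the unweighted mean of the two
within-population mean pairwise differences and $H_b$ the between-
population mean — the default for sequence data in the standard desktop
software for this analysis. Negative estimates are clamped to zero and
flagged; $H_b = 0$ is reported as not applicable. Gene flow uses the
haploid maternal island-model relation $F_{ST} = 1/(1 + 2Nm)$, i.e.
$Nm = (1 - F_{ST})/(2 F_{ST})$.

Isolation by distance correlates pairwise Nm with pairwise great-circle
distance (haversine, radius 6371 km). Because pairwise matrix entries are
not independent, significance uses a Mantel permutation of population
identities rather than an ordinary regression test; the plain regression
F-test is still emitted for comparability with the older presentation.
Pairs with non-finite Nm (undifferentiated pairs) are excluded from the
correlation.

## Phylogeny

Kimura two-parameter distances use pairwise deletion by default (complete
deletion by flag): $d = -\tfrac12 \ln\left((1-2P-Q)\sqrt{1-2Q}\right)$ with
transition and transversion proportions P and Q over comparable sites;
log-domain violations are flagged as saturation. Neighbor joining is the
standard Saitou–Nei agglomeration; negative branch lengths are clamped to
zero with the deficit moved to the sister branch so path lengths through
the parent are preserved. The bootstrap resamples alignment columns with
replacement and scores each internal bipartition of the full-data tree by
the percentage of replicate trees containing it; replicates with a
saturated distance are dropped and counted. The resampling-based NJ
bootstrap is used throughout — a parsimony-style branch-swapping search
would not be meaningful around a distance method.

## Demography

The package reconstructs effective-size history with the deterministic
classic and generalized skyline estimators on an ultrametric genealogy,
as the desk-testable analogue of Bayesian MCMC skylines: per coalescent
interval with $i$ lineages and duration $\tau$,
$\hat N = i(i-1)\tau/2$ divided by the generation time; the generalized
variant pools adjacent intervals until the composite duration reaches
$\varepsilon$ and uses the constant-size maximum-likelihood estimate
$\sum \binom{i_j}{2}\tau_j / m$ over the $m$ pooled coalescences (the
classic estimator is the $m = 1$ case; both are verified against an
independent implementation). With a mutation rate $\mu$ (substitutions per
site per year; default $3\times10^{-9}$, a typical chloroplast spacer
rate) branch lengths in substitutions/site convert to years as
$\tau/\mu$. Without a generation time the reported quantity is
$N \times$ generation time and is labelled as such. Real-data genealogies
from NJ are made ultrametric by mean path-length smoothing after midpoint
rooting — explicitly an approximation that averages away lineage rate
variation, so skyline output on real data supports qualitative (declining
vs growing), not numeric, statements.

# The synthetic-data generator

The generator realises exactly the model the island-model formula assumes:
a structured coalescent over d demes with symmetric migration, one
non-recombining haploid locus, finite-sites mutation. Defaults emulate the
packaged survey's design: 8 demes with samples (10, 10, 10, 10, 8, 10, 10,
9), L = 881 sites, A/T-rich base composition (A = T = 0.368,
C = G = 0.132, i.e. 73.6% A+T), per-site θ = 0.005 (survey-scale
per-locus diversity), Nm = 0.3 (mid-range of the strong differentiation
regime,
FST ≈ 0.6).

Two calibration choices deserve note:

* **Migration scaling.** With time in units of N generations and
  per-lineage migration rate M, the finite-island expectation is
  $F_{ST} = 1/(1 + 2NM\,d/(d-1))$. The generator therefore sets the
  per-lineage rate to $Nm\,(d-1)/d$ so that the *stated* relation
  $F_{ST} = 1/(1+2Nm)$ holds for any deme count; a 200-replicate test
  confirms mean pairwise FST within 15% of 0.5 at Nm = 0.5.
* **Finite sites, not infinite sites.** Mutations land on uniformly chosen
  sites with the new base drawn from the stationary composition excluding
  the current base. Homoplasy is wanted: it produces the reticulation
  loops that exercise the network's loop-breaking rules.

Mutations are Poisson on branches at rate θL/2 per lineage per coalescent
time unit, so Watterson's estimator recovers θ (verified to within 10%
at n = 20 over 500 replicates). Deme coordinates are placed on a grid at
roughly 50 km spacing.

Three named scenarios support behaviour-level tests of the inference key:
`ibd_stepping_stone` (linear demes, nearest-neighbour migration),
`fragmentation` (two deme clusters, no migration between them, merged into
one ancestral pool t_split = 8 coalescent time units ago), and
`range_expansion` (all demes founded from one deme 0.05 time units ago).
The scenario tests assert majority outcomes over 20 replicates: the
fragmentation scenario reaches "past fragmentation" and the stepping-stone
scenario "restricted gene flow with isolation by distance" somewhere in
the nesting hierarchy in at least half the replicates, mirroring how such
analyses are reported clade by clade.

What the generator does *not* emulate: selection, recombination (cpDNA is
assumed non-recombining), sequencing error, indel evolution (simulated
alignments are gap-free), and spatially realistic habitat geometry. Tests
passing on simulated data therefore validate the estimators under the
model's own assumptions; they cannot certify behaviour on data violating
them.

# Reproducibility and numerical conventions

* Every stochastic routine takes a mandatory seed; the pipeline derives
  child seeds from the master seed by a fixed offset scheme (+1 NCA
  permutations, +2 contingency, +3 bootstrap, +4 Mantel), so a bundle
  rerun under the same seed is byte-identical (tested).
* Column indices are 0-based in the API (`kept_columns`), 1-based only in
  prose reports.
* Haplotype labels are assigned by first appearance (H01, H02, ...); the
  packaged fixture carries the published labels directly.
* N is a wildcard for haplotype identity (two sequences differing only at
  an N collapse, with the fully resolved sequence kept as representative)
  but N-bearing site pairs never count toward differences.
* Permutation p-values include the observed arrangement (p > 0 always);
  ties are compared with a 1e-9 slack to make integer-valued statistics
  robust to floating error.
* Test problem sizes are chosen to keep the full suite at a few minutes on
  one core: exhaustive oracles run at ≤ 7 network nodes / ≤ 8 individuals
  / ≤ 8 taxa, simulation recoveries at 100–500 replicates with 20–40
  sequences, scenario checks at 20 replicates with 200 permutations.

# Known limitations

* The skyline module is a deterministic stand-in for Bayesian skyline
  inference: no credible intervals, and real-data input depends on the
  ultrametricization approximation above.
* Dc/Dn values on the packaged fixture cannot be compared against the
  original survey's figures (those numbers are not machine-readable); NCA
  correctness rests on the exhaustive-enumeration oracles and the
  scenario-level behaviour tests instead.
* The published pairwise Nm/FST table of the survey is internally
  inconsistent with the stated island-model formula for several pairs
  (consistent instead with a 1/(1+4Nm) convention); this package follows
  the stated haploid relation throughout.
* The nested clade inference key is used as a hypothesis-generating
  device; the long-running debate about its error rates is out of scope.

# Session info

```{r}
sessionInfo()
```
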