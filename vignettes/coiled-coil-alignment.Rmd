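---
title: "Region- and register-aware alignment of coiled-coil proteins"
author: "CoilAlign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region- and register-aware alignment of coiled-coil proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoilAlign)
```

## The problem

The heptad repeat of coiled coils places hydrophobic residues at
positions `a` and `d`, charged residues at `e` and `g`, and hydrophilic
residues at `b`, `c` and `f`. Two unrelated coiled-coil proteins
therefore share both an amino-acid composition and a periodic pattern,
and a fixed substitution matrix such as BLOSUM62 — whose log-odds are
taken against the average composition of conserved protein blocks —
systematically over-scores their similarity. In ortholog searches this
produces false best hits and, historically, led to masking coiled-coil
segments entirely, at the price of missing true orthologs.

CoilAlign instead keeps the coiled-coil residues and re-scores them
with substitution matrices that are aware of (i) the local composition
and (ii) the heptad register.

## The scoring model

**Compositional adjustment at fixed relative entropy.** A substitution
matrix is the rounded log-odds of a joint target distribution
$q_{ab}$ against a background product $c^{(1)}_a c^{(2)}_b$, in
half-bit units: $s_{ab} = \mathrm{round}\!\left(2\log_2 q_{ab}/(c^{(1)}_a
c^{(2)}_b)\right)$. Its relative entropy
$H = \sum_{ab} q_{ab}\log_2 \frac{q_{ab}}{c^{(1)}_a c^{(2)}_b}$
measures the information per aligned residue pair (0.70 bits for
BLOSUM62, computed from the standard public target-frequency table that
ships with the package). `adjustMatrix()` re-derives the matrix for a
specific pair of sequence compositions: among all joint distributions
with the observed row/column compositions as marginals and the base
matrix's relative entropy, it picks the one closest (in KL divergence)
to the base target distribution. Keeping $H$ fixed preserves the
matrix's per-pair information content while removing the compositional
mismatch.

The constrained problem is solved on its Lagrangian stationarity
family
$q_{ab} = \exp\left(\alpha \log q^{(0)}_{ab} + (1-\alpha)\log(c^{(1)}_a
c^{(2)}_b) + \rho_a + \sigma_b\right)$
by a damped Newton iteration over $(\rho, \sigma, \alpha)$ (40 free
parameters after removing the scaling redundancy). Convergence is
declared at residuals below $10^{-10}$ (marginals and entropy), with at
most 100 iterations; a failed Newton run falls back to a monotone
bisection on $\alpha$ with an inner Sinkhorn projection, and if the
target entropy is unreachable for the given compositions (extremely
skewed inputs) the base matrix is returned with a warning flag. In
batch searches consecutive solves are warm-started; since the optimum
is unique this changes nothing but the iteration count. When the
constraints are already satisfied (compositions equal to the base
background) the base matrix is returned unchanged, published integer
scores included.

**Region switching.** Proteins are partitioned at a coiled-coil
probability cutoff of 0.8 (a residue with probability exactly 0.8 is
coiled-coil; the comparison is documented as `>=` and configurable).
Matrices are adjusted for the coiled-coil subsequence pair, the
non-coiled-coil pair, and the full-length pair, and the aligner picks
per residue pair: both coiled-coil &rarr; coiled-coil matrix; neither
&rarr; non-coiled-coil matrix; mixed &rarr; full-length matrix.
Regions shorter than `minRegionLen = 20` residues on either side reuse
the next-coarser matrix (cc/non-cc fall back to full-length; register
groups to the coiled-coil matrix) — tiny samples make the adjustment
unstable and 20 residues is below one meaningful compositional
estimate.

**Registers (ccalignx).** Coiled-coil residues are further split into
the interface (`a`, `d`), intermediate (`e`, `g`) and outside (`b`,
`c`, `f`) groups, with their own adjusted matrices. When both residues
are coiled-coil the register of the more confident prediction decides
the group; ties go to the query (a symmetric max-probability rule is
available for score-symmetry work). A bonus of `beta = 1` half-bit
(configurable) is added when the two registers agree exactly — the
heptad phase is conserved in true homologs but random between
unrelated coils. The bonus is awarded per aligned residue pair, the
simplest reading of a per-pair scoring rule.

**Register weights.** Register groups differ in how much phylogenetic
signal they carry; `buildRegisterMatrices()` estimates group-specific
matrices from conserved gapless blocks (BLOSUM-style clustered pair
counting, 62% clustering identity) and `computeRegisterWeights()`
turns their entropies into multiplicative weights. The default scheme
divides each group entropy by the median group entropy; normalising by
the base-matrix entropy and per-register variants are provided. The
default entropies (interface 0.45, intermediate 0.32, outside 0.28
bits) are typical estimates from conserved-block data; the shipped
synthetic block fixture reproduces their ordering, not their values,
which depend on the underlying block collection. Weights pre-scale the
unrounded log-odds before integer rounding (one scaled copy per
register), keeping the dynamic programming integer-only. Weights are
applied in both coiled-coil modes by default (`weightsScheme = "off"`
disables them).

**Alignment and statistics.** The aligner is a Smith-Waterman-Gotoh
local alignment with affine gaps, `gapOpen = 11`, `gapExtend = 1` (the
BLAST protein defaults; the first gapped position costs open +
extend), with deterministic traceback (diagonal > up > left on ties).
Raw scores map to bit scores as $(\lambda S - \ln K)/\ln 2$ with
$\lambda = 0.267$, $K = 0.041$ (standard gapped BLOSUM62/11/1 values).
Letters outside the 20-residue alphabet are mapped to `X`, excluded
from compositions, and scored by the base matrix's `X` column, so
appending unalignable runs never changes a score.

## Search and graph post-processing

`allVsAll()` aligns every protein against every other species and
keeps the top 50 hits per query and species. `reciprocalBestHits()`
accepts a pair when each protein is the other's unique best hit with
both bit scores at least 30; an exact tie disqualifies the query
(conservative, since the data cannot distinguish the candidates).
`combineVotes()` accepts a link when at least two of three methods
agree. `pruneSpurious()` tentatively removes, per group, the node of
highest betweenness centrality when it exceeds twice the component
median (components under five nodes are left alone; one node at a
time, for determinism); if the group falls apart into at least two
sub-groups of two or more proteins the split is accepted and the node
re-joins the sub-group it shares most links with, otherwise the link
was backed up and the node is restored. `mergeGroups()` merges scored
group pairs in decreasing score order — requiring a stricter score
when the species sets overlap, to avoid merging paralogs — and refuses
any merge that would push the cluster's group-graph diameter beyond
four edges. Both thresholds are required inputs, as no universal
values exist.

## The synthetic family generator

`simulateFamilies()` emulates the inputs of a coiled-coil ortholog
benchmark with no external data: per family an ancestral protein with
two coiled-coil domains (35-49 residues each, i.e. 5-7 heptads; random
register phase) and three linkers (55-75 residues), residues drawn
from register-group tables (hydrophobic mass 0.8 at `a`/`d`, charged
mass 0.7 at `e`/`g`, polar mass 0.85 outside; linkers from the
BLOSUM62 background), two descendants by independent per-site
substitution at rate 0.55 with replacements drawn from the positional
table (register-conditional, so the heptad structure persists), and
three decoys per family that share the architecture distribution and
the tables but no ancestry. Annotations are 0.95 inside domains, 0.05
outside. An optional per-family composition tilt (`compositionTilt`)
redistributes within-class frequencies log-normally to emulate
family-level composition bias; it is off by default. Everything is
reproducible from the seed (default 42).

The defaults put about 30% of residues in coiled-coils and produce
proteins of roughly 270 residues; with 200 families this keeps the
full benchmark grid (three modes, four linker lengths, 200 x 800
alignments each) under 15 minutes on one CPU, which is the problem
size the package's reference benchmark uses.

What the generator does *not* emulate — and hence what passing
benchmarks do and do not show: real substitution processes are
chemically structured (the generator redraws from position tables),
real families diverge far more deeply and unevenly than a uniform
0.55 per-site rate, there are no insertions/deletions by default, and
real proteomes mix coiled-coil with non-coiled-coil proteins of widely
varying length. Results on this generator demonstrate the machinery
end-to-end and the relative behaviour of the scoring modes under
controlled conditions; they are not estimates of performance on real
proteomes. Notably, under these conditions the register-overlap bonus
(ccalignx) is the decisive discriminator, while region-specific
adjustment alone (ccalign) does not beat a fixed matrix: decoys here
share the query's composition class exactly, so fixed-matrix score
inflation is uniform within a query's candidate list and cancels in
the ranking, and the adjustment can only discount the true pair's
common-letter identity signal. In real proteomes, where composition
varies across families and genomes, that inflation is not uniform —
which is precisely the case compositional adjustment addresses.

## The excision benchmark

`makeArtificial()` rebuilds the benchmark construction for coiled-coil
sensitivity: every coiled-coil interval is excised together with a
flanking linker of `l` residues, overlapping windows are merged, and
the pieces are concatenated with their annotations. Shorter linkers
remove unique non-coiled-coil context and make the true homolog harder
to recognise; the default sweep is l = 10, 25, 50, 100.
`evaluateBestHits()` sweeps a bit-score threshold over each query's
best hit, computes FDR = 1 - correct/predictions (a best hit is
correct when it is any annotated ortholog of the query), and reports
the fraction of gold pairs recovered at the loosest threshold with FDR
at most 5%. Curve points with fewer than ten predictions are omitted
from the reported curve. `runBenchmark()` wires the generator, the
excision, the batch search and the evaluation into the full grid.

## Numerical choices and degenerate inputs

* Compositions use a pseudocount mass of 20 (one per amino acid) so
  the adjustment solver always sees strictly positive compositions; a
  mass of 0 is allowed but can produce degenerate vectors.
* Score rounding is half-away-from-zero, applied after any weight
  scaling of the unrounded log-odds.
* Empty alignments (no positive-scoring pair) return raw score 0 with
  empty coordinates.
* Register gaps inside a coiled-coil run inherit the register of the
  nearest labelled coiled-coil residue (ties to the left); a run with
  no labels stays coiled-coil but joins no register group (with a
  warning).
* The shipped BLOSUM62 target-frequency table is the standard public
  4-decimal table; at that precision the re-derived integer scores
  differ from the published matrix in a handful of rare-pair cells, so
  base matrices keep their published scores and the
  scores-equal-rounded-log-odds identity is enforced for adjusted
  matrices, which carry full-precision distributions.

## Known limitations

* No heuristic seeding: every pair gets a full dynamic program, which
  is exact but not built for proteome-scale all-vs-all runs beyond the
  benchmark sizes above.
* Bit scores use fixed Karlin-Altschul parameters rather than
  per-matrix estimates; E-values are out of scope.
* The register-group matrices default to compositionally adjusted
  versions of the coiled-coil matrix restricted to group subsequences;
  block-derived group matrices are supported but used for weight
  estimation.
* Registers are taken from the input annotation; the package never
  predicts coiled-coils or registers itself.
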