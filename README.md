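# CoilAlign

Coiled-coil proteins are notoriously hard to place in ortholog searches:
the seven-residue heptad repeat (`abcdefg`, hydrophobic `a`/`d`
interface, charged `e`/`g`, hydrophilic `b`/`c`/`f` outside) imposes a
strong compositional and periodic signal that standard substitution
matrices mistake for homology. A fixed BLOSUM62 score therefore inflates
the similarity of unrelated coiled-coil proteins and can bury the true
ortholog below compositional look-alikes.

CoilAlign implements a region- and register-aware local protein
aligner for exactly this situation, aimed at people building ortholog
maps or benchmarking remote-homology detection for coiled-coil-rich
proteomes (centrosome, cytoskeleton, motor proteins, ...).

## The method

Given per-residue coiled-coil probabilities and heptad registers (from
any external predictor; threshold p >= 0.8), each protein is split
into coiled-coil and non-coiled-coil subsequences. For every pair of
proteins, the base matrix is **compositionally adjusted at fixed
relative entropy** separately for the coiled-coil pair, the
non-coiled-coil pair, and the full-length pair: the adjusted joint
distribution Q minimises KL(Q || Q0) subject to

* row marginals = query-region composition,
* column marginals = subject-region composition,
* relative entropy sum q_ab log2(q_ab / c1_a c2_b) = H(base) (0.70
  bits for BLOSUM62),

solved by a damped Newton iteration on the Lagrangian stationarity
family. A modified Smith-Waterman-Gotoh alignment (affine gaps 11/1)
then switches the matrix per residue pair: coiled-coil matrix when both
residues are coiled-coil, non-coiled-coil matrix when neither is, and
the full-length matrix in the mixed case (`mode = "ccalign"`). The
extended mode (`"ccalignx"`) further subdivides coiled-coils into the
register groups a/d, e/g, b/c/f with their own adjusted matrices —
selected by the register of the more confident prediction — and awards
a bonus score to residue pairs whose registers agree. Scores from the
heptad positions are weighted by their relative information (group
entropy normalised by the median entropy). Raw scores convert to bit
scores via (lambda S - ln K)/ln 2.

On top of the aligner the package provides all-vs-all search with
top-50-per-species truncation, reciprocal-best-hit calling (bit-score
cutoff 30), 2-of-3 method voting, betweenness-centrality pruning of
spurious links, orthologous-group merging with a diameter-4 cap, a
coiled-coil excision benchmark (FDR curves, recall at 5% FDR), and a
seeded generator of synthetic coiled-coil protein families so that
everything runs without external data.

## Worked example

```r
library(CoilAlign)

sim <- simulateFamilies(familySpec(nFamilies = 3L, seed = 7L))
A <- sim$proteomes$sp1[["fam0001_sp1"]]   # query
B <- sim$proteomes$sp2[["fam0001_sp2"]]   # true ortholog
D <- sim$proteomes$sp2[["dec0001_sp2"]]   # unrelated decoy, same
                                          # coiled-coil architecture
A
#> CCProtein fam0001_sp1 ( sp1 ), 267 aa, 30.3% coiled-coil at p>=0.8

for (m in c("plain", "ccalign", "ccalignx")) {
  al <- ccAlign(A, B, alignParams(m)); ad <- ccAlign(A, D, alignParams(m))
  cat(sprintf("%-9s true: %3d (%5.1f bits)  decoy: %3d (%5.1f bits)\n",
              m, al@rawScore, al@bitScore, ad@rawScore, ad@bitScore))
}
#> plain     true: 110 ( 47.0 bits)  decoy:  46 ( 22.3 bits)
#> ccalign   true:  74 ( 33.1 bits)  decoy:  39 ( 19.6 bits)
#> ccalignx  true: 137 ( 57.4 bits)  decoy:  46 ( 22.3 bits)

ccAlign(A, B, alignParams("ccalignx"))
#> Alignment fam0001_sp1 x fam0001_sp2: raw 137, 57.4 bits,
#>   q[17-264] s[17-264], 250 pair(s), 81 register bonus
```

The true pair and the decoy share coiled-coil composition; the
adjusted modes strip the compositional part of both scores, and the
register-overlap bonus (81 matched pairs here) rewards the conserved
heptad phase that only true homologs keep.

The shipped BLOSUM62 probability tables reproduce the matrix's
relative entropy:

```r
round(relEntropyBits(blosum62()), 2)
#> 0.7
```

A thin command-line wrapper for shell pipelines lives at
`inst/cli/coilalign` (subcommands `align`, `search`, `rbh`, `vote`,
`prune`, `merge`, `simulate`).

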