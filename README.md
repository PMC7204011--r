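# dotprint

Sequence-only analysis of repeat proteins through dot-plot fingerprints.

Tandem repeat proteins — TPR and PPR arrays, β-propellers, solenoids,
leucine-rich repeats — are hard to compare by ordinary alignment: their
internal sequence degeneracy confounds pairwise alignments, and unit
boundaries drift. But a repeat protein is by construction similar to
*itself*, and that self-similarity is a stable, structure-like signature.
`dotprint` computes windowed self-similarity dot plots, binarizes them
into sparse fingerprints, and compares fingerprints with a sliding
Jaccard metric, giving a repeat-length-agnostic way to detect repeat
proteins, measure their evolutionary relationships, and cluster them —
with no structural information required.

## The method in brief

For a sequence $s$ and substitution matrix $M$ (BLOSUM62), the grey
matrix is the clamped windowed score
$G(i,j) = \mathrm{clamp}(\sum_{k=-h}^{h} M(s_{i+k}, s_{j+k}), 0, 255)$
with a 25-residue window. Upper-triangle cells with $G \ge 31$ (the black
point) are the fingerprint's **pixels**; the self-identity diagonal is
ignored. Two fingerprints are compared by sliding the smaller along the
larger's diagonal and maximizing the Jaccard index
$J_X = |A \cap B| / |A \cup B|$ over all shifts; $J_D = 1 - J_X$ is the
distance. A chain with ≥ 121 residues and ≥ 0.42 pixels/residue is
classified repeat-containing. On top of this core sit:

* **Deconvolution** — per-residue pixel profiles → repeat segments;
  off-diagonal pixel distances → repeat unit periods.
* **Evolution experiments** — BLOSUM-weighted point mutations and random
  insertions with exponential decay fits ($J_X = e^{-bz}$, half-life
  $z_{50} = \ln 2/b$), plus an alphabet-permutation Monte Carlo that
  destroys sequence identity while preserving the pattern.
* **Consensus fingerprints** — trim gap-rich alignment columns (≥ 20%),
  pad termini with 25 neutral gaps, average member grey matrices,
  re-binarize.
* **Clustering** — McQuitty/WPGMA hierarchical clustering of $J_D$
  matrices with 50-level dendrogram cuts, and top-k sparsified Markov
  clustering (MCL) for larger collections, with medoid and purity
  reporting.
* **Synthetic benchmarks** — tandem-repeat and control generators with
  machine-readable ground truth, so everything is testable offline.

## Worked example

```r
library(dotprint)
bl62 <- loadSubstitutionMatrix("BLOSUM62")

# a synthetic tandem repeat protein: 6 copies of a 25-residue unit at 20%
# unit divergence, with ground truth
truth <- makeTandemProtein(repeatSpec(unitLength = 25, copies = 6,
                                      unitDivergence = 0.2), seed = 7)
fp <- fingerprint(truth$seq, bl62)
fp
#> DotPlot: n = 200 residues, window 25, black point 31, 363 pixels (1.815 px/residue)

classifyRepeat(fp)        # density 1.82 >= 0.42 and length 200 >= 121
#> [1] TRUE

estimatePeriods(fp)       # pixel lines at multiples of the 25-residue unit
#>   period support
#> 1     25     123
#> 2     50      98
#> 3     75      70

# a composition-matched shuffle has an information-free fingerprint
ctrl <- shuffleSequence(truth$seq, seed = 8)
pixelDensity(fingerprint(ctrl, bl62))
#> [1] 0

# fingerprints of homologs stay close: a 6-member family at 15% divergence
fam <- makeFamily(truth$seq, members = 6, divergence = 0.15, seed = 9)
plots <- lapply(fam, fingerprint, matrix = bl62)
round(pairwiseMatrix(plots), 3)   # sliding Jaccard distances J_D
#>       m1    m2    m3    m4    m5    m6
#> m1 0.000 0.112 0.065 0.057 0.064 0.054
#> m2 0.112 0.000 0.146 0.120 0.108 0.122
#> m3 0.065 0.146 0.000 0.091 0.119 0.088
#> m4 0.057 0.120 0.091 0.000 0.089 0.045
#> m5 0.064 0.108 0.119 0.089 0.000 0.085
#> m6 0.054 0.122 0.088 0.045 0.085 0.000
```

The periods table reads directly off the fingerprint geometry: 123 pixels
support the unit-length spacing of 25 residues, with harmonics at 50 and
75. The family's pairwise $J_D \le 0.15$ sits far below the 0.875
coherence threshold used to call consensus groups.

A command-line wrapper is installed at `exec/dotprint` with subcommands
`fingerprint`, `compare`, `scan`, `decay`, `insert`, `shuffle`,
`consensus`, `cluster`, `synth`, and `export-mcl`; every run writes a JSON
manifest (parameters, input digests, seed) and stochastic subcommands are
bit-reproducible given `--seed`.

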