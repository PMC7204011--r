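---
title: "Dot-plot fingerprints: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dot-plot fingerprints: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotprint)
```

## The model

A tandem repeat protein is, tautologically, similar to itself: each repeat
unit resembles its sibling units. `dotprint` captures that internal
similarity in a *dot-plot fingerprint*. For a sequence $s$ of length $n$
and a substitution matrix $M$ (BLOSUM62 by default), the grey matrix is the
windowed self-similarity score

$$G(i,j) \;=\; \mathrm{clamp}\!\left(\sum_{k=-h}^{h} M\!\left(s_{i+k},\,
s_{j+k}\right),\; 0,\; 255\right), \qquad h = \tfrac{W-1}{2},$$

with window $W = 25$ residues and the sum running over in-range offsets
only (windows are truncated at the sequence ends rather than padded with
invented residues, so $G$ is defined everywhere). Cells of the strict
upper triangle with $G(i,j) \ge 31$ — the *black point* — are the
fingerprint's pixels; the self-identity diagonal is excluded because it
records only trivial self-matches. Tandem repeats of unit length $u$
appear as pixel lines parallel to the diagonal at distances $u, 2u, 3u,
\dots$

Two fingerprints $A$ and $B$ are compared by *sliding*: the smaller plot
is translated along the larger plot's self-identity diagonal, and at each
shift the Jaccard index

$$J_X = \frac{|A_{\mathrm{shifted}} \cap B|}{|A| + |B| -
|A_{\mathrm{shifted}} \cap B|}$$

is evaluated; the maximum over all shifts with at least one residue of
overlap is the similarity, and $J_D = 1 - J_X$ the distance. Sliding
compensates for length differences and terminal insertions or deletions.
Two plots with $J_X \ge 0.5$ are nearly indistinguishable by eye, and
pattern similarity usually remains recognizable down to $J_X \approx 0.1$.

A chain is classified repeat-containing when it is at least 121 residues
long and its fingerprint carries at least 0.42 upper-triangle pixels per
residue — the census thresholds calibrated on repeat proteins of known
structure against non-repeat PDB controls. Deconvolution recovers the
repeat residues (per-residue pixel counts thresholded into segments) and
the unit length (the dominant off-diagonal pixel distances).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `window` | 25 | residues | scoring window; also the terminal pad length |
| `blackPoint` | 31 | grey value | binarization threshold (white point 30) |
| `densityCutoff` | 0.42 | pixels/residue | repeat census information floor |
| `minLength` | 121 | residues | census length floor (benchmark sets used > 100) |
| gap trim | 0.20 | fraction | alignment columns with ≥ 20% gaps are removed |
| `pad` | 25 | residues | neutral gap wings against edge effects |
| `coherence` | 0.875 | $J_D$ | maximal within-cluster distance for a coherent family |
| `cutLevels` | 50 | — | evenly spaced dendrogram cut heights |
| `kT` | 0.04 | per-residue score | Metropolis temperature of the alphabet shuffle |
| `inflation` | 2.0 | — | MCL inflation exponent |
| `k` | 1400 | edges/node | top-k sparsification before graph clustering |

The grey scale deserves a note. The original interactive dot-plot tools
map windowed scores onto a 0–255 greyramp through an internal
normalization that is not published; `dotprint` uses the raw clamped
window sum, which preserves the qualitative behavior (repeat lines far
above background) but means absolute pixel densities are only comparable
*within* this package's convention. The black point is exposed as a
parameter so the scale can be recalibrated if bit-compatibility with
another implementation is ever needed.

## Neutral characters, hygiene, and coordinates

The placeholder `X` and the gap symbol `-` score zero against everything:
neutral characters neither create nor destroy signal. This is what makes
gap-padded, partially gapped consensus sequences scoreable. Sequences
containing ambiguity codes (`B`, `Z`, `U`, `O`, `J`) are rejected by
default; `mapToX = TRUE` maps them to `X` instead. All pixel, segment,
and ground-truth coordinates are 0-based with half-open intervals, and
only the strict upper triangle is stored — halving storage and matching
the "top half triangle" census convention.

## Evolution experiments

`mutateOnce` substitutes one uniformly chosen residue; the replacement
$b \neq a$ is drawn with probability $\propto 2^{M(a,b)/2}$, the
Boltzmann-like back-transform of half-bit log-odds scores.
Self-substitutions are excluded so every round changes a residue — but a
site hit twice can revert, so identity is *measured* from the sequences,
never inferred from the round count. `decayExperiment` applies cumulative
rounds (one per residue of length by default), slide-compares each mutant
against the original, and averages over replicates;
`fitExponential` then fits $J_X = e^{-bz}$, with $z$ the percent identity
loss, reporting the half-life $z_{50} = \ln 2 / b$ and flagging fits with
$R^2 \ge 0.98$ as clean. A fitted $b \le 0$ leaves $z_{50}$ undefined;
plateaued curves with positive $b$ are caught by the $R^2$ flag instead.

`insertionExperiment` grows the sequence by single residues (drawn from
the sequence's own composition, so the experiment is neutral with respect
to composition bias; uniform draws are available) and reports the
half-loss insertion rate — the percent of original length inserted when
mean $J_X$ first crosses 0.5, linearly interpolated between bracketing
measurements. `shuffleAlphabetMC` searches bijective alphabet
replacements by Metropolis Monte Carlo (key-pair swaps, per-residue score
normalization so that $kT = 0.04$ lives on an $O(1)$ scale, best of 10
restarts) and then asks whether the fingerprint survives a remapping that
destroys nearly all sequence identity.

## The synthetic benchmark and what it does (not) show

All tests run against generated data with known ground truth. The
generator emits tandem repeat proteins (ancestral unit drawn from BLOSUM62
background frequencies, copies independently substituted at a controlled
divergence through the same BLOSUM62 kernel, optional single-residue
insertions, random flanks), i.i.d. non-repeat controls,
composition-matched shuffles, and star-phylogeny families whose
substitution-only alignments are trivially columnwise.

`makeStandardSet()` fixes the study conditions for the decay and insertion
experiments: 20 chains, unit length 20–40, 4–8 copies, 35-residue flanks
(lengths 150–390), and per-copy unit divergence uniform on 0.35–0.55. The
divergence range is calibrated so the set's pixel-density distribution
matches the census statistics of natural repeat proteins of known
structure (mean ≈ 0.66 pixels/residue with a long right tail), not the
2–3× denser plots of designed repeat arrays. That calibration matters
scientifically: chains with saturated fingerprints (≳ 1.2 pixels/residue)
have windowed scores so far above the black point that the first
mutations delete almost no pixels, producing a sigmoidal decay with a
shoulder rather than a single exponential. With natural-like densities
the measured substitution half-life centers near 8% identity loss and
insertions reach half-loss near 1% of length — an order of magnitude more
damaging per percent of change — but the fraction of chains passing the
strict $R^2 \ge 0.98$ single-exponential test stays below what is
reported for real repeat proteins, which we attribute to the unpublished
grey-scale normalization noted above.

What passing these tests does *not* show: real proteins have domain
architecture, composition bias, low-complexity regions, and
insertion/deletion histories the generator does not model; shuffled
controls are information-free in a way real non-repeat proteins (density
≈ 0.14 pixels/residue) are not. Classification margins measured here are
therefore optimistic upper bounds.

## Numerical and design choices

* **Empty-union convention.** $J_X = 0$ when both plots have no pixels:
  information-free plots carry no evidence of similarity, and returning 1
  would glue all of them together in clustering.
* **Union scope.** The union counts *all* pixels of both plots, including
  those outside the overlap window, penalizing size mismatch; only
  diagonal-parallel shifts are searched (no reflections).
* **Tie-breaking.** Equal-$J_X$ shifts resolve toward the smallest
  absolute offset, negative before positive, so self-comparison always
  reports offset 0. Medoid ties resolve lexicographically. All outputs are
  sorted before writing, so evaluation order never changes results.
* **Segment smoothing.** Deconvolution closes gaps of ≤ 2 residues and
  drops runs shorter than 3: windowed scoring blurs unit boundaries by
  about one residue, and these small tolerances prevent salt-and-pepper
  segmentation.
* **Consensus averaging.** The consensus is the cell-wise mean of member
  *grey* matrices, binarized at the standard black point — not a vote over
  member pixel sets — so family-conserved marginal signal can rise above
  threshold while member-specific noise is diluted below it. Consensus
  deconvolution thresholds the averaged score itself (cutoffs 10–50 on the
  grey scale) via `consensusProfile()`.
* **Coherent-group scoring.** Candidate (linkage, cut height) groupings
  are scored by the number of members covered by coherent clusters
  (median pairwise $J_D \le 0.875$), coarser partitions winning ties.
  Scoring by the bare count of coherent clusters is degenerate — it
  rewards fragmenting one family into many coherent pairs.
* **MCL regularization.** The hand-rolled Markov clustering adds unit
  self-loops before column normalization (the standard guard against
  period-two oscillation), prunes entries below $10^{-12}$ each sweep, and
  reads clusters as connected components of the converged matrix's
  support. Inflation defaults to 2.0, the usual MCL convention, since the
  original large-scale runs do not report their value.
* **Decay fitting.** Nonlinear least squares on the original scale
  (Levenberg–Marquardt), started from the log-linear slope; $R^2$ is
  computed against the curve's own variance.

## Problem sizes

The shipped experiments are scaled to desk size: decay uses 12 replicates
per chain with roughly 40 recorded rounds (the full-scale reference is
1001 replicates recording every round), insertion curves use 6 replicates
up to 20% of length, classification benchmarks use 50 repeat and 50
control chains, and clustering benchmarks use 4 planted families of 5
members. Oracle-equivalence tests run exact brute-force references up to
60 residues (fingerprints) and 100 residues (sliding).

## Known limitations

Local (Smith–Waterman-style) matching of split or rearranged patterns is
out of scope, as are DNA dot plots, deletion experiments, indel length
distributions beyond single residues, and structure-aware repeat
classes. The absolute grey scale is package-specific (see above), so
densities should not be compared numerically against other dot-plot
implementations without recalibrating the black point.
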