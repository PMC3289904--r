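---
title: "Detecting ameliorated gene transfer: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ameliorated gene transfer: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtsignal)
```

# The problem

Bacterial genomes differ widely in GC content, and a gene acquired by
horizontal transfer carries the compositional imprint of its donor.
Amelioration — the gradual drift of the acquired gene toward the host's
base composition — is strongly position-dependent: the first and second
codon positions are constrained by the encoded protein, while the third is
nearly neutral and tracks the host's mutational bias. In a high-GC host an
anciently acquired low-GC gene therefore shows *near-saturated GC3 with
depressed GC1/GC2*, and may also retain its donor's stop codon: across
bacteria, TAA dominates in low-GC genomes and TGA in high-GC genomes, with
TAG rare throughout. This vignette documents how `hgtsignal` formalises
these observations, the parameters that matter, and the design decisions
taken where conventions differ between tools.

# Composition statistics

**GC content** is `(G + C) / (A + C + G + T)`. Ambiguity bases (`N`) are
excluded from numerator *and* denominator, so the estimator is unbiased
under ambiguity rather than silently counting `N` as AT.

**Windowed profiles** report one point per *complete* window; a trailing
partial window is dropped so the point count is deterministic,
`floor((L - window)/step) + 1`. Points are indexed by window *centers*
(`start + window/2`, 0-based), which keeps plots symmetric under sequence
reversal. Typical window sizes are 500 bp for a whole contig and 40 bp for
a single gene; codon-position profiles default to a 10-codon window moved
in 1-codon steps, the convention popularised by frame-analysis plotting
tools.

**GC1/GC2/GC3** are computed over all codons *including the start codon*
and, by default, *excluding the terminal stop codon*
(`drop_stop = TRUE`). The stop codon is the subject of its own analysis
(the census below), and excluding it keeps that signal out of GC3; because
published GC figures rarely state this convention, both variants are
computable via the flag, and they differ by well under half a percentage
point for genes of ordinary length. With the stop excluded, the identity
`mean(GC1, GC2, GC3) = GC(cds)` holds exactly and is property-tested.

**The outlier report** is this package's formalisation of the amelioration
signature (it is a package-defined score, not a literature statistic). For
each gene on a contig we compute GC3 and the mean of GC1 and GC2, then
standardise both across the contig's genes: `z3` and `z12`. A gene is
flagged when `z3 >= z` and `z12 <= -z` simultaneously, with `z = 2` by
default — two standard deviations in *each* of two quasi-independent
directions, a conservative joint criterion whose null flag rate is well
below the marginal 2.3% tail. At least three genes are required; with a
degenerate (constant) column the z-scores are defined as zero so nothing
can be flagged spuriously.

**Protein molecular weight** is the sum of IUPAC average residue masses
plus one water (18.0153 Da), reported in kilodaltons; Dps-family subunits,
the motivating protein family, fall around 16–26 kD.

# Stop-codon usage

The census reads each gene's last in-frame codon strand-awarely. Genes
whose CDS is out of frame or does not end in TAA/TAG/TGA are treated as
*partial*: excluded from the denominator and reported separately, never
imputed — draft contigs routinely truncate genes at their edges, and a
guessed stop would bias the fractions. Fractions over complete genes sum to
one by construction. Genomic GC for multi-replicon genomes is
length-weighted.

The cross-genome trend is measured with the **Spearman rank correlation**
of each stop codon's fraction against genomic GC. The relationship is
visibly monotone but not linear across real genome panels, so a rank
statistic is the robust default; Pearson is available behind `method`, and
raw counts behind `use_counts` (the trend's sign is the same either way).
At least four genomes are required, and a constant-GC panel is rejected as
a degenerate predictor.

# Distances, neighbor joining, bootstrap

Pairwise protein alignment is global Needleman–Wunsch/Gotoh with affine
gaps, scored by BLOSUM62 with gap opening 10 and extension 0.5 (ClustalX's
classical defaults; a gap of length L costs `open + L*extend`). These
choices are assumptions, exposed as arguments. The observed mismatch
fraction `D` is measured over columns with no gap in either row, and
corrected for multiple hits with the ClustalX protein correction
`d = -ln(1 - D - D²/5)`, defined for `D < 0.85`; beyond the domain the
function either errors (analysis mode) or falls back to raw `D`
(`fallback_raw = TRUE`, the default inside bootstrap resampling, where a
single extreme replicate must not abort the run).

Neighbor joining follows Saitou–Nei: join the pair minimising
`Q(i,j) = (m-2) d(i,j) - R_i - R_j`, with the standard branch-length
formulas and distance reduction. Two numerical conventions matter:

- **Ties** in `Q` (exact equality, as arises with degenerate all-equal
  matrices) are broken by the lexicographically smallest label pair, with
  internal nodes inheriting their smallest descendant label. This makes
  the output invariant under taxon order, which in turn makes bootstrap
  supports order-invariant.
- **Negative branch lengths**, which NJ can produce off additivity, are
  clamped to zero with the deficit transferred to the sibling edge, the
  standard display convention; path lengths through the join are preserved.

On additive matrices NJ is consistent: the generating topology and branch
lengths are recovered exactly, which the tests verify on 200 random trees
of 4–12 taxa at tolerance 1e-9 (and cross-check against an independent NJ
implementation off additivity).

**Bootstrap support** resamples alignment *columns* with replacement —
never distances — rebuilds the distance matrix and NJ tree per replicate,
and reports, for each internal edge of the full-alignment tree, the
percentage of replicates containing the same bipartition (integer percent,
matching the conventional figure annotation; 1000 replicates is the
classical choice, and the seed is a mandatory argument consumed without
touching global RNG state). **Outgroup rooting** places the root at the
midpoint of the outgroup's pendant edge; supports travel with their
bipartitions (edge-associated labels), and re-rooting is an involution.

# Synteny

Neighborhoods are **k genes per side of an anchor** (default `k = 8`)
rather than a fixed number of base pairs, because published synteny figures
omit variable-length spacer regions; gene rank is the meaningful offset.
Neighborhoods are normalised so the anchor is transcribed rightwards, the
convention used when drawing such figures.

Ortholog matching is **reciprocal best hit by global alignment score**,
accepted only when the score reaches 30% of the self-score of the shorter
protein — a self-contained criterion that needs no external search tool.
Groups are the transitive closure of pairwise RBHs, built by offering edges
in decreasing score order and rejecting any edge that would put two genes
of one genome in the same group.

Two adjacent genes are classified, taking the one with the smaller start as
upstream: equal strands are *co-directional*; upstream `+` / downstream `-`
is **face-to-face** (convergent, transcribed toward each other); upstream
`-` / downstream `+` is **back-to-back** (divergent). These terms are used
inconsistently in the literature; this mapping is the one under which the
two orientations of a gene pair flanking an anchor are distinct, and it is
stated here prominently because results depend on it.

# Synthetic data: what it emulates, what it does not

Every generator is a pure function of its specification and a mandatory
seed (byte-identical reruns), and returns a truth record sufficient to
score downstream analyses.

- `gen_genome` samples codons with *independent* base distributions at
  positions 1+2 (`target_gc12`) and 3 (`target_gc3`) — the minimal model
  that decouples GC12 from GC3. Defaults (27 genes of mean 150 codons,
  GC12 0.62, GC3 0.85, TGA-dominated stops) emulate a high-GC
  actinobacterial contig with overall GC near 0.69. Genes start with ATG,
  internal stop codons are rejection-sampled away, strands are random, and
  intergenic spacers (Poisson, mean 80 bp, floor 10 bp) match the overall
  GC.
- `insert_foreign_gene` adds one gene with `gc3 = 0.95`, `gc12 = 0.35` and
  stop TAA at a random intergenic position — a strong, unambiguous
  amelioration signature.
- `gen_genome_panel` spreads genome GC across `[0.30, 0.75]` (the range
  spanned by common bacterial genomes) and couples stop weights to GC via
  `TAA ∝ exp(s(0.5−t))`, `TGA ∝ exp(s(t−0.5))`, TAG flat and low. The
  default strength `s = 3` gives a strong, clearly monotone trend;
  `s = 0` is the exchangeable null used for permutation calibration. The
  default panel size of 30 genomes matches the scale of classical
  stop-codon surveys.
- `simulate_protein_family` evolves a uniform random root protein along a
  random tree under a 20-state Jukes–Cantor-type process (Poisson events,
  uniform replacement among the other 19 residues), so the expected
  mismatch fraction at path length `t` is `19/20 (1 − e^{−20t/19})` — a
  closed form the tests check against simulation. No indels are simulated,
  so the leaves are a true alignment and bootstrap operates on it directly.
- `gen_synteny_trio` plants a conserved gene block (diverged by ~5% codon
  replacement per genome) among private random genes in three genomes.

**Limitations.** The codon model has no amino-acid realism (no codon-usage
table, no selection on protein content), intergenic DNA carries no signal
(no promoters or RBS), the substitution model has no rate heterogeneity or
exchangeability structure, and no indels, duplications or rearrangements
are generated. Passing tests therefore demonstrate correctness of the
*statistics and algorithms* under controlled conditions, not robustness to
every property of real genomes; on real data, alignment quality and paralogy
are the dominant additional error sources.

# Problem sizes and tolerances used by the test suite

The suite verifies NJ on 200 random additive matrices (4–12 taxa, exact to
1e-9), alignment scores against exhaustive enumeration on 100 random pairs
of length ≤ 8 (enumeration is exponential; length 8 keeps it exact and
quick), composition profiles against naive loops on 100 random sequences,
topology recovery on 50 simulated 8-taxon families of 1000 residues
(≥ 90% expected), stop-codon trends on twenty 30-genome panels
(|Spearman| > 0.8 per panel for TAA and TGA), and foreign-gene detection on
ten 27-gene fixtures built on a GC3 = 0.70 host, where the planted gene
must attain the maximum `z3` and be the only flagged outlier. Branch
lengths in the tree simulations are drawn from [0.02, 0.2] so that even
the longest leaf-to-leaf paths keep the observed mismatch fraction inside
the Kimura correction domain.

# Degenerate inputs, by policy

- All-`N` windows yield `NA` profile points; all-`N` sequences error.
- Zero distances and all-equal distance matrices are legal NJ input; the
  result is deterministic via the lexicographic tie-break.
- Identical sequences give a zero-distance matrix and arbitrary but
  reproducible topology; bootstrap still reports supports.
- Partial CDS are flagged and excluded from codon statistics, never
  rejected or imputed.
- `GTG`/`TTG` initiators translate to `M` only behind `allow_alt_start`
  (common in Actinobacteria, translation table 11 behaviour).
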