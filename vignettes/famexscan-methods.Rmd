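---
title: "Methods: detecting and dissecting a gene-family expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and dissecting a gene-family expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Some bacterial genomes carry an extraordinary number of paralogues of a
single protein family — the best-studied cases are solute-binding proteins
(SBPs) of tripartite transporters, where a single chromosome can encode
hundreds of TctC-like periplasmic binding proteins. Two mechanisms can build
such an expansion: repeated within-genome duplication (lineage-specific
expansion, LSE) and horizontal gene transfer (HGT) from other lineages.
famexscan implements the comparative-genomics workflow that separates these
signals for one "focal" genome:

1. **Census** the family by sequence search against characterised query
   proteins.
2. **Profile the GC landscape** — windowed GC content and GC skew, the
   replication origin/terminus from the cumulative skew reversal, and
   low-GC genomic islands (the classic compositional signature of recently
   acquired DNA).
3. **Contrast family gene density** inside versus outside islands: a family
   grown mainly by recent HGT should concentrate in islands; an LSE-grown
   family should avoid them.
4. **Census tandem arrays** of consecutive family genes, the footprint of
   local duplication.
5. **Classify provenance** of every member by its best database hit:
   same-genome (LSE), close-lineage (vertical descent from a shared
   ancestor) or distant-lineage (HGT candidate).

Every stage is testable without downloads because the package ships a
seeded synthetic-genome generator with complete ground truth.

## Alignment model

The census and provenance stages need pairwise protein alignment with
reproducible, documented semantics, so the package implements it exactly
rather than shelling out to a search tool:

* **Local (Smith–Waterman) and global (Needleman–Wunsch) alignment** under
  affine gaps: a gap of length $k$ costs $o + k e$ (defaults $o = 11$,
  $e = 1$, BLOSUM62). Insertions and deletions may abut; with BLOSUM62's
  minimum of $-4$ and $e = 1$ an adjacent indel pair can be strictly
  optimal, and allowing the transition makes the three-state dynamic
  program provably equivalent to the "gap as one jump" formulation used by
  the brute-force oracle in the test suite.
* **Determinism.** Ties are broken by a fixed state preference
  (aligned pair > gap in subject > gap in query) at every cell, and the
  local traceback starts at the first maximal cell in row-major order.
* **E-values** use Karlin–Altschul statistics
  $E = K m n e^{-\lambda S}$ with the standard gapped BLOSUM62/11/1
  parameters $\lambda = 0.267$, $K = 0.041$ and the per-pair search space
  $m n$. No database-size or edge-length correction is applied: the
  published-style cutoff ($10^{-15}$) is treated as a per-comparison
  threshold, which is a documented dialect difference from a database
  E-value. Only relative ranking and a fixed cutoff matter downstream.
* **Percent identity** is computed from the global end-to-end alignment,
  with gap columns counted in the denominator, so identity is symmetric
  and comparable across pairs; "best hit" in the provenance stage means
  highest percent identity, with raw global score and then lexicographic
  ids as tie-breaks.
* Ambiguity codes (X, B, Z, and J/U/O remapped to X) score 0 against
  everything: they neither help nor hurt an alignment.

The search is an exact scan of annotated proteomes. This deliberately
differs from a translated genome search: genes missed by the annotation are
invisible to the census. For desk-scale proteomes exactness is affordable
and removes heuristic seeding as a source of irreproducibility.

## GC landscape

GC content and GC skew $(G-C)/(G+C)$ are computed in 10 kb sliding windows
advanced in 1 kb steps (the window follows common practice for bacterial
chromosome plots; the step is a package choice — dense enough to resolve
island edges at a tenth of the window length, and cheap). Windows wrap on
circular contigs. Ambiguous bases are excluded from numerator and
denominator; windows with no informative base are flagged undefined.

**Replication landmarks.** On most bacterial chromosomes the leading strand
is G-rich, so the cumulative skew curve falls until the origin and rises
until the terminus. The raw cumulative extremum is sensitive to short
compositional excursions (a cluster of same-strand genes can carry enough
G–C imbalance to displace the minimum by one or two window widths), so
each extremum is refined by a local piecewise-linear changepoint fit: over
the ±150 windows around the raw extremum, the two-slope "V" with the
least-squares breakpoint is taken as the landmark, which averages the
excursion noise over ~300 windows instead of trusting a single cell.
Positions are the centre of the chosen window, modulo the contig length;
ties go to the earliest window. Swapping the min/max convention only
relabels the two positions; a flat or single-extremum curve is flagged
degenerate. Localization precision is inherently about one window:
overlapping windows smear the skew transition across a full window width,
so recovery on planted replichores (±0.05 mean skew per replichore) is
asserted to within two window sizes (20 kb on a 1 Mb replicon), not to the
step.

**Low-GC islands.** The detector is purely compositional: windows below
`mean − 1.5 SD` of the window-GC distribution are marked, marked runs are
converted to intervals spanning window *centres* (so edges are resolved at
step rather than window precision), runs closer than 5 kb are merged, and
merged runs shorter than 8 kb are dropped. Two design points deserve
explanation:

* *Centre-based intervals.* Using full window extents would pad every
  island by roughly one window size on each side and cap the achievable
  overlap with a planted island of 10–30 kb well below 0.9; centre-based
  intervals are nearly unbiased.
* *Overdispersion guard.* In a compositionally homogeneous genome the
  window-GC spread is pure base-sampling noise
  ($\sigma \approx \sqrt{p(1-p)/w}$), and a mean − 1.5 SD threshold would
  mark ~7 % of windows regardless; because neighbouring windows share 90 %
  of their content, those marks arrive in runs long enough to pass the
  8 kb filter. Islands are therefore only called when the observed SD
  exceeds twice the binomial noise floor — a cheap test for genuine
  compositional heterogeneity that returns an empty island set on
  homogeneous genomes.

This detector intentionally replaces ensemble island predictors (which
combine composition with mobility genes, tRNA sites and comparative
evidence); island sets from such services are treated as qualitative
guidance only, not as a reproduction target.

**Density contrast.** A gene is "inside" an island iff its midpoint falls
in an island interval (unambiguous for edge-straddling genes). Densities
are genes per Mb; the conservation identities (counts sum to the family
size, lengths sum to the genome length) are asserted on every run. With no
islands the inside density is undefined and flagged rather than invented.

## Tandem arrays

A tandem array is a maximal run of family genes consecutive in gene order
(rank along the contig), strand-agnostic, never spanning contig breaks, and
closing the ring on circular contigs. The strictest reading — zero
intervening non-family genes — is the default; `max_intervening` exposes
looser readings. The array-size frequency table conserves the family size
($\sum_k k \, n_k$ equals the census size) by construction, and that
identity is checked cross-stage in the pipeline report.

## Provenance classification

Every focal family member is compared against a family-restricted database:
the family members of the focal genome itself plus those of companion
genomes, each tagged with a lineage label path. The best non-self hit
(highest global percent identity; ties by raw score, then lexicographic
ids) yields a three-way category:

* `self_genome` — best hit is another member of the focal genome: the LSE
  signal;
* `close_lineage` — best hit's lineage contains the configured close-group
  label: consistent with vertical descent from a pre-expansion ancestor;
* `distant` — anything else: an HGT candidate.

The direction of any transfer is *not* inferred — distinguishing donor from
recipient (or repeated loss in relatives) requires phylogenetic
reconciliation, which is out of scope by design. Fractions are stored at
full precision and printed at one decimal place.

## The synthetic generator

`generate_focal_genome()` builds, deterministically from a seed, a circular
chromosome with the statistical structure the analysis assumes, and records
the complete truth. Defaults (the study conditions of the test suite):
1 Mb at 64 % GC; low-GC islands at 58 % GC covering 10 % of the length
(2–4 islands, ≥ 15 kb each); GC skew amplitude ±0.03 switching sign at a
quarter and three quarters of the length; 300 family members among 200
unrelated decoy genes; origin fractions 0.60/0.25/0.15 for
duplication/vertical/HGT; an array-size distribution dominated by
singletons with rare arrays up to nine genes; HGT members placed inside
islands with probability 0.7; a transcription-factor-labelled decoy planted
next to 16 % of family genes.

**Divergence design.** The generator must guarantee that each member's
*labelled* relative is its nearest database neighbour, with margins that
survive binomial sampling noise, while every family sequence — donors and
orthologs included — stays easily detectable by the seed query. Both
constraints are met by a symmetric-pair construction: a member and its
labelled relative (duplicate sibling, ortholog, or donor) each diverge by
half the configured relationship divergence from a common ancestor, and
that ancestor's own depth from the family seed is chosen so that every
sequence ends at the same total radiation depth (default 0.55, about 49 %
identity to the seed — far above the detection threshold). The ordered
relationship divergences (siblings 0.25 ≈ 78 % identity, ortholog pairs
0.35 ≈ 68 %, member–donor pairs 0.45 ≈ 57 %) then sit against *cross*
relationships near 30 % identity, a gap of ≥ 15 points that makes
provenance recovery a test of the pipeline rather than of luck. The
nearest-relative structure is itself verified per seed before recovery is
asserted.

**Mutation model.** Substitution-only by default: a Binomial(length,
divergence) number of positions is replaced, the replacement drawn with
probability ∝ exp(BLOSUM62/2) so exchanges are biochemically plausible
(keeping detectability realistic), and the initiator methionine fixed. An
optional indel rate exists (default 0) for alignment-robustness tests;
keeping lengths fixed makes the identity arithmetic of the truth checks
exact.

**Composition.** Coding sequence is written with GC-biased synonymous
codon choice. Because only the degenerate positions are free, the
third-position bias is calibrated against the fixed-position GC of the
background amino-acid composition so that realized coding GC tracks the
regional target (background or island); without this calibration, gene
bodies would sit ~9 GC points below the intergenic background and
masquerade as islands. The HGT compositional signature is carried by the
island nucleotide composition only — no codon-usage or oligonucleotide
modelling — matching the evidence the analysis actually uses.

**What the generator does not emulate.** Real intergenic/coding GC
structure, operons, variable gene length within the family, gene loss,
selection, rearrangement, and annotation error. Passing recovery tests
therefore demonstrates the pipeline's correctness under its stated
assumptions, not its robustness to real-data pathology; the file-format
round trip (GFF3 + FASTA in, identical census out) is tested separately.

## Problem sizes and numerical choices

The test suite runs the full recovery battery at the default study
conditions: exact family recovery on one 1 Mb fixture (300 members + 200
decoys); provenance recovery over 10 seeds at n = 300 (tolerance ±5
percentage points per category); island and replication-landmark recovery
over 20 seeds (Jaccard ≥ 0.8; ±2 window sizes); and a 20-seed uniform
placement null under which the density fold ratio stays near 1. Default
protein lengths are drawn from 130–210 residues — the scale of a compact
periplasmic binding domain — which keeps the exhaustive all-pairs global
alignments of the provenance stage affordable while leaving alignment
statistics (≈ 4-point identity SD per pair) far inside the designed
margins. Alignment arithmetic is integer; E-values underflow to zero
harmlessly far below any cutoff in use; interval arithmetic is 0-based
half-open everywhere inside the package, converting only at the
GFF3/GenBank boundary.

## Known limitations

* The census sees only annotated CDS; unannotated ORFs are invisible.
* Per-pair E-values are not database-size corrected (documented dialect).
* The island detector is compositional only and will not reproduce
  ensemble island calls on real genomes, where it serves as a transparent
  approximation.
* Provenance is label-driven; it cannot distinguish HGT direction or
  repeated loss, and close-group membership is exactly as good as the
  supplied lineage labels.
* Draft (multi-contig) genomes truncate arrays and windows at contig
  breaks, understating array sizes.
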