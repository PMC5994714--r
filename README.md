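# famexscan

Detection and provenance analysis of gene-family expansions in bacterial
genomes.

Some bacterial chromosomes carry hundreds of paralogues of a single protein
family — the extreme cases are solute-binding proteins (SBPs) of tripartite
tricarboxylate transporters (TTT), where one genome can encode over 400
TctC-like binding proteins. famexscan is for microbial comparative
genomicists who want to census such a family in an annotated genome and ask
*how it grew*: by repeated within-genome duplication (lineage-specific
expansion, LSE) or by horizontal gene transfer (HGT).

The pipeline:

1. **Family census** — exact Smith–Waterman local alignment of every
   annotated protein against characterised query proteins, affine gaps
   (open 11, extend 1, BLOSUM62), accepting genes with Karlin–Altschul
   E-value `E = K·m·n·e^(−λS) ≤ 1e-15`.
2. **GC landscape** — GC content and GC skew `(G−C)/(G+C)` in 10 kb sliding
   windows; replication origin and terminus from the cumulative-skew
   reversal (minimum = origin, maximum = terminus, refined by a local
   two-slope changepoint fit).
3. **Low-GC islands** — a transparent compositional detector
   (windows below `mean − 1.5·SD`, runs merged within 5 kb, islands ≥ 8 kb)
   and the island-vs-backbone family gene **density contrast** in genes/Mb.
4. **Tandem arrays** — maximal runs of family genes consecutive in gene
   order, and their size-frequency table.
5. **Best-hit provenance** — every member's best non-self hit (highest
   global percent identity) across a family-restricted multi-genome
   database, classified as `self_genome` (LSE), `close_lineage` (vertical)
   or `distant` (HGT candidate).
6. **Synthetic data** — a seeded generator that plants all of the above
   with full ground truth, so the whole pipeline is testable offline.

## Worked example

Simulate a 1 Mb genome under the default study conditions (300 planted
family members among 200 decoys, 10 % of the genome in 58 %-GC islands on a
64 %-GC backbone, origin fractions 0.60/0.25/0.15 for
duplication/vertical/HGT) and run the full pipeline, including two
close-lineage and one distant-lineage companion proteomes:

```r
library(famexscan)
report <- run_pipeline(pipeline_config(simulate = TRUE, seed = 1))
report
```

```
<summary_report> SYNTH_FOCAL_1
  family census: 300 of 500 CDS (60.0 %)
  replication: origin 247000, terminus 748000
  islands: 4 covering 9.9 % of the genome
  density: 333.3 per Mb in islands vs 296.3 per Mb outside (fold 0.89)
  arrays: 114 array(s), largest 17
  provenance: self_genome 60.0 %, close_lineage 25.0 %, distant 15.0 %
  neighborhood: 48 family genes (16.0 %) near a transcription_factor gene
```

Reading the output: the census recovered exactly the 300 planted members
(none of the 200 decoys); the replication origin and terminus were located
within 3 kb of the planted quarter points (250 kb / 750 kb); the island
caller recovered the planted 10 % island cover; under the default
conditions HGT members are placed *into* islands with probability 0.7, so
the family density inside and outside islands is similar (fold ≈ 0.9) —
contrast this with a real LSE-dominated genome, where the published density
contrast is 13.5 vs 57.3 genes/Mb (about 4-fold); the best-hit
classification recovered the planted 60/25/15 origin split exactly; and
16 % of family genes have a transcription-factor gene within two positions,
as planted. (With a family this dense, independently placed arrays often
end up adjacent in gene order, so the largest realized run can exceed the
largest planted array size.)

Each stage is also available on its own (`find_family_members()`,
`gc_content_track()`, `gc_skew_track()`, `locate_replication_extremes()`,
`detect_low_gc_islands()`, `gene_density_contrast()`, `detect_arrays()`,
`best_hit_classification()`, `neighborhood_context()`), consuming standard
GFF3 + FASTA inputs via `read_annotated_genome()` and writing BED/bedGraph/
TSV/JSON artifacts via `write_report()`.

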