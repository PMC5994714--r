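# Shared fixtures built in code.

# A tiny two-contig genome with hand-placed genes for io / array /
# neighbourhood logic tests. Gene bodies are arbitrary codons.
tiny_genome <- function(circular = TRUE) {
  dna <- function(n) paste(rep("ACGT", ceiling(n / 4)), collapse = "")
  contigs <- Biostrings::DNAStringSet(c(ctg1 = substr(dna(5000), 1, 5000),
                                        ctg2 = substr(dna(2000), 1, 2000)))
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6", "h1", "h2"),
    contig_id = c(rep("ctg1", 6), "ctg2", "ctg2"),
    start = c(100L, 400L, 700L, 1500L, 2500L, 4000L, 100L, 600L),
    end = c(340L, 640L, 940L, 1740L, 2740L, 4240L, 400L, 900L),
    strand = c("+", "-", "+", "+", "-", "+", "+", "-"),
    product = c("family SBP homolog", "family SBP homolog",
                "LysR family transcriptional regulator",
                "family SBP homolog", "hypothetical protein",
                "family SBP homolog", "family SBP homolog",
                "sensor histidine kinase"))
  prot <- Biostrings::AAStringSet(stats::setNames(
    rep("MKVLAAGF", nrow(genes)), genes$gene_id))
  annotated_genome("TINY", contigs, genes, prot,
                   lineage = c("Bacteria", "TestGroup"),
                   circular = circular)
}

# Small-but-complete synthetic configuration used across module tests;
# deliberately much smaller than the default study conditions.
small_synth <- function(seed, ...) {
  args <- list(seed = seed, genome_length = 2e5, n_family = 30L,
               n_background = 60L, n_close_companions = 1L,
               n_distant_companions = 1L, companion_background_genes = 10L,
               tagged_neighbor_fraction = 0.3)
  args <- utils::modifyList(args, list(...))
  do.call(synth_config, args)
}
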