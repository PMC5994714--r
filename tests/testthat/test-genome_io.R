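write_gff_fixture <- function(dir, lines, fasta) {
  gff <- file.path(dir, "toy.gff3")
  fna <- file.path(dir, "toy.fna")
  writeLines(c("##gff-version 3", lines), gff)
  writeLines(fasta, fna)
  list(gff = gff, fna = fna)
}

test_that("GFF3 1-based inclusive coordinates become 0-based half-open", {
  d <- withr::local_tempdir()
  seqchr <- paste(rep("ACGTGC", 100), collapse = "")
  f <- write_gff_fixture(
    d,
    "ctg1\tsrc\tCDS\t101\t200\t.\t+\t0\tID=gA;product=thing;translation=MK",
    c(">ctg1", seqchr))
  g <- read_annotated_genome(f$gff, f$fna)
  expect_equal(g$genes$start, 100L)
  expect_equal(g$genes$end, 200L)
  expect_equal(g$genes$end - g$genes$start, 100L)
  expect_equal(g$genes$order_index, 0L)
})

test_that("CDS translation follows the bacterial code with stop trimmed", {
  d <- withr::local_tempdir()
  seqchr <- paste0("TT", "ATGAAATAA", paste(rep("A", 50), collapse = ""))
  f <- write_gff_fixture(
    d, "ctg1\tsrc\tCDS\t3\t11\t.\t+\t0\tID=gA;product=p",
    c(">ctg1", seqchr))
  g <- read_annotated_genome(f$gff, f$fna)
  expect_equal(as.character(g$proteome[["gA"]]), "MK")
  # reverse strand: reverse complement then translate
  f2 <- write_gff_fixture(
    d, "ctg1\tsrc\tCDS\t3\t11\t.\t-\t0\tID=gB;product=p",
    c(">ctg1", paste0("TT", as.character(Biostrings::reverseComplement(
      Biostrings::DNAString("ATGAAATAA"))),
      paste(rep("A", 50), collapse = ""))))
  g2 <- read_annotated_genome(f2$gff, f2$fna)
  expect_equal(as.character(g2$proteome[["gB"]]), "MK")
})

test_that("CDS with length not divisible by three is skipped with a warning", {
  d <- withr::local_tempdir()
  seqchr <- paste(rep("ATGAAATAA", 20), collapse = "")
  f <- write_gff_fixture(
    d, c("ctg1\tsrc\tCDS\t1\t9\t.\t+\t0\tID=ok;product=p",
         "ctg1\tsrc\tCDS\t19\t28\t.\t+\t0\tID=bad;product=p"),
    c(">ctg1", seqchr))
  expect_warning(g <- read_annotated_genome(f$gff, f$fna),
                 "not divisible by 3")
  expect_equal(g$genes$gene_id, "ok")
  expect_equal(attr(g, "n_skipped_cds"), 1L)
})

test_that("a two-gene GenBank toy is parsed with ordered genes", {
  d <- withr::local_tempdir()
  gb <- file.path(d, "toy.gbk")
  seqchr <- tolower(paste(rep("atgaaataa", 30), collapse = ""))
  writeLines(c(
    "LOCUS       ctgA                 270 bp    DNA     circular BCT",
    "DEFINITION  synthetic toy record.",
    "FEATURES             Location/Qualifiers",
    "     CDS             10..18",
    "                     /locus_tag=\"t1\"",
    "                     /product=\"first protein\"",
    "                     /translation=\"MK\"",
    "     CDS             complement(100..108)",
    "                     /locus_tag=\"t2\"",
    "                     /product=\"second protein\"",
    "ORIGIN",
    paste0("        1 ", seqchr),
    "//"), gb)
  g <- read_annotated_genome(gb, format = "genbank")
  expect_equal(nrow(g$genes), 2L)
  expect_equal(g$genes$order_index, c(0L, 1L))
  expect_equal(g$genes$gene_id, c("t1", "t2"))
  expect_equal(g$genes$start, c(9L, 99L))
  expect_equal(g$genes$strand, c("+", "-"))
  expect_equal(as.character(g$proteome[["t1"]]), "MK")
})

test_that("gene order and coordinates survive a GFF3 round trip", {
  sim <- generate_focal_genome(small_synth(101))
  d <- withr::local_tempdir()
  write_synthetic_dataset(sim, NULL, d)
  gid <- sim$genome$genome_id
  back <- read_annotated_genome(file.path(d, paste0(gid, ".gff3")),
                                file.path(d, paste0(gid, ".fna")))
  expect_equal(back$genes$gene_id, sim$genome$genes$gene_id)
  expect_equal(back$genes$start, sim$genome$genes$start)
  expect_equal(back$genes$end, sim$genome$genes$end)
  expect_equal(back$genes$order_index, sim$genome$genes$order_index)
  # computed translations reproduce the planted proteome exactly
  expect_equal(as.character(back$proteome[names(sim$genome$proteome)]),
               as.character(sim$genome$proteome))
  # order invariant: starts non-decreasing within contig
  expect_true(all(diff(back$genes$start) > 0))
})

test_that("BED and bedGraph writing round-trips and formats values", {
  d <- withr::local_tempdir()
  iv <- tibble::tibble(contig_id = c("ctg1", "ctg1"),
                       start = c(600L, 100L), end = c(900L, 600L))
  p <- write_intervals(iv, file.path(d, "x.bed"), "bed")
  expect_equal(readLines(p), c("ctg1\t100\t600", "ctg1\t600\t900"))
  back <- read_intervals(p)
  expect_equal(back$start, c(100L, 600L))
  expect_equal(back$end, c(600L, 900L))

  tr <- tibble::tibble(contig_id = "c", start = c(0L, 10L, 20L),
                       end = c(10L, 20L, 30L),
                       value = c(0.5, 1 / 3, 0.25))
  p2 <- write_intervals(tr, file.path(d, "x.bedGraph"), "bedGraph")
  lines <- readLines(p2)
  expect_length(lines, 3)
  expect_match(lines[2], "0\\.3333$")
  back2 <- read_intervals(p2)
  expect_equal(back2$value, c(0.5, 0.3333, 0.25))

  p3 <- write_intervals(iv[0, ], file.path(d, "empty.bed"), "bed")
  expect_match(readLines(p3), "^#")
  expect_equal(nrow(read_intervals(p3)), 0L)
  expect_error(write_intervals(iv, file.path(d, "y.bedGraph"), "bedGraph"),
               "value")
})

test_that("the genome container enforces its invariants", {
  g <- tiny_genome()
  expect_equal(g$genes$order_index[g$genes$contig_id == "ctg1"], 0:5)
  bad <- g$genes
  bad$end[1] <- 99999L
  expect_error(annotated_genome("x", g$contigs, bad, g$proteome),
               "out of bounds")
  dup <- g$genes
  dup$gene_id[2] <- dup$gene_id[1]
  expect_error(annotated_genome("x", g$contigs, dup, Biostrings::AAStringSet()),
               "duplicate")
})

test_that("functional tags derive from product labels via the keyword map", {
  g <- tiny_genome()
  tf <- vapply(g$genes$functional_tags, function(t)
    "transcription_factor" %in% t, logical(1))
  expect_equal(g$genes$gene_id[tf], "g3")
  hk <- vapply(g$genes$functional_tags, function(t)
    "histidine_kinase" %in% t, logical(1))
  expect_equal(g$genes$gene_id[hk], "h2")
})
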