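test_that("the generator is deterministic under its seed", {
  a <- generate_focal_genome(small_synth(55))
  b <- generate_focal_genome(small_synth(55))
  expect_identical(as.character(a$genome$contigs), as.character(b$genome$contigs))
  expect_identical(a$genome$genes, b$genome$genes)
  expect_identical(as.character(a$genome$proteome),
                   as.character(b$genome$proteome))
  expect_identical(a$truth$family, b$truth$family)
  ca <- generate_companion_genomes(small_synth(55), a$truth)
  cb <- generate_companion_genomes(small_synth(55), b$truth)
  expect_identical(lapply(ca, function(g) as.character(g$proteome)),
                   lapply(cb, function(g) as.character(g$proteome)))
  c2 <- generate_focal_genome(small_synth(56))
  expect_false(identical(as.character(a$genome$contigs),
                         as.character(c2$genome$contigs)))
})

test_that("planted islands cover the configured fraction and are GC-poor", {
  for (seed in c(57, 58)) {
    cfg <- small_synth(seed)
    sim <- generate_focal_genome(cfg)
    isl <- sim$truth$islands
    expect_equal(sum(isl$end - isl$start),
                 round(cfg$island_fraction * cfg$genome_length))
    s <- sim$genome$contigs[[1]]
    gc_of <- function(from0, to0) {
      f <- Biostrings::letterFrequency(
        Biostrings::subseq(s, from0 + 1L, to0), c("G", "C"))
      sum(f) / (to0 - from0)
    }
    island_gc <- sum(vapply(seq_len(nrow(isl)), function(k)
      gc_of(isl$start[k], isl$end[k]) * (isl$end[k] - isl$start[k]),
      numeric(1))) / sum(isl$end - isl$start)
    whole <- Biostrings::letterFrequency(s, c("G", "C"))
    outside_gc <- (sum(whole) - island_gc * sum(isl$end - isl$start)) /
      (cfg$genome_length - sum(isl$end - isl$start))
    expect_lt(island_gc, outside_gc)
    expect_lt(abs(island_gc - cfg$island_gc), 0.02)
  }
})

test_that("origin labels, arrays and island membership agree with the layout", {
  cfg <- small_synth(59)
  sim <- generate_focal_genome(cfg)
  fam <- sim$truth$family
  expect_equal(nrow(fam), cfg$n_family)
  expect_setequal(unique(fam$origin), c("duplication", "vertical", "hgt"))
  # duplication members always share their sequence cluster with a sibling
  dup <- fam[fam$origin == "duplication", ]
  expect_true(all(table(dup$cluster_id) >= 2))
  # non-HGT members stay out of islands under the default placement
  expect_true(all(!fam$island_member[fam$origin != "hgt"]))
  # every family gene carries an array label and labels are consecutive runs
  expect_true(all(!is.na(fam$array_id)))
})

test_that("mutate_protein hits its divergence target and preserves length", {
  base <- paste0("M", paste(rep("ACDEFGHIKLMNPQRSTVWY", 15), collapse = ""))
  expect_equal(mutate_protein(base, 0), base)
  pids <- vapply(1:30, function(s)
    percent_identity(base, mutate_protein(base, 0.25, seed = s)),
    numeric(1))
  expect_equal(mean(pids), 75, tolerance = 3)
  expect_true(all(nchar(vapply(1:5, function(s)
    mutate_protein(base, 0.4, seed = s), "")) == nchar(base)))
  expect_error(mutate_protein(base, 1), "target_divergence")
  # indels change length but stay rare
  longer <- mutate_protein(base, 0.1, seed = 1, indel_rate = 0.02)
  expect_false(nchar(longer) == 0)
})

test_that("each member's nearest database relative matches its origin label", {
  cfg <- small_synth(61)
  sim <- generate_focal_genome(cfg)
  comps <- generate_companion_genomes(cfg, sim$truth)
  rel <- attr(comps, "planted_relatives")
  fam <- sim$truth$family
  sch <- scoring_scheme()
  # database of all focal family + companion family proteins
  seqs <- as.character(sim$truth$family_proteins)
  labels <- tibble::tibble(id = names(seqs), where = "focal")
  for (g in comps) {
    fam_ids <- g$genes$gene_id[g$genes$product == "family SBP homolog"]
    s <- as.character(g$proteome[fam_ids])
    seqs <- c(seqs, s)
    labels <- rbind(labels, tibble::tibble(id = fam_ids, where = g$genome_id))
  }
  enc <- lapply(seqs, famexscan:::aa_encode, scheme = sch)
  pid <- famexscan:::nw_pid_cpp(enc, enc, sch$substitution_matrix,
                                sch$gap_open, sch$gap_extend)$pid
  ok <- 0L
  for (i in seq_len(nrow(fam))) {
    row <- pid[i, ]; row[i] <- -1
    best <- labels$id[which.max(row)]
    want <- switch(fam$origin[i],
                   duplication = fam$gene_id[fam$cluster_id %in%
                                               fam$cluster_id[i] &
                                               fam$gene_id != fam$gene_id[i]],
                   vertical = ,
                   hgt = rel$companion_gene_id[rel$focal_gene_id ==
                                                 fam$gene_id[i]])
    if (best %in% want) ok <- ok + 1L
  }
  expect_gte(ok / nrow(fam), 0.93)
})

test_that("without vertical or HGT members companions carry no family genes", {
  cfg <- small_synth(63,
                     origin_fractions = c(duplication = 1, vertical = 0,
                                          hgt = 0))
  sim <- generate_focal_genome(cfg)
  comps <- generate_companion_genomes(cfg, sim$truth)
  for (g in comps)
    expect_false(any(g$genes$product == "family SBP homolog"))
  hits <- lapply(comps, function(g)
    find_family_members(sim$truth$queries, g))
  expect_true(all(vapply(hits, function(h) nrow(h$hits), integer(1)) == 0L))
})

test_that("synthetic datasets are written in consumable standard formats", {
  cfg <- small_synth(65)
  sim <- generate_focal_genome(cfg)
  comps <- generate_companion_genomes(cfg, sim$truth)
  d <- withr::local_tempdir()
  write_synthetic_dataset(sim, comps, d)
  expect_true(all(file.exists(file.path(
    d, c("queries.faa", "truth.tsv", "lineage.tsv",
         paste0(sim$genome$genome_id, ".gff3"),
         paste0(sim$genome$genome_id, ".fna"),
         "CLOSE1.faa", "DIST1.gff3")))))
  lin <- utils::read.delim(file.path(d, "lineage.tsv"))
  expect_true("Rhizobacteria" %in%
                unlist(strsplit(lin$lineage[lin$genome_id == "CLOSE1"], ",")))
  tr <- utils::read.delim(file.path(d, "truth.tsv"))
  expect_equal(nrow(tr), cfg$n_family)
})

test_that("infeasible packing is rejected before any output", {
  cfg <- synth_config(seed = 67, genome_length = 6e4, n_family = 200L,
                      n_background = 300L)
  expect_error(generate_focal_genome(cfg), "packing|island")
})
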