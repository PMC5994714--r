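test_that("planted origins are recovered from best hits on a small fixture", {
  cfg <- small_synth(33)
  sim <- generate_focal_genome(cfg)
  comps <- generate_companion_genomes(cfg, sim$truth)
  hits <- find_family_members(sim$truth$queries, sim$genome)
  comp_hits <- lapply(comps, function(g)
    find_family_members(sim$truth$queries, g))
  db <- family_database(c(list(sim$genome), unname(comps)),
                        c(list(hits), unname(comp_hits)))
  rep <- best_hit_classification(
    sim$genome$proteome[family_members(hits)], db,
    sim$genome$genome_id, "Rhizobacteria")
  expect_equal(sum(rep$counts), nrow(sim$truth$family))
  expect_equal(sum(rep$fractions), 1, tolerance = 1e-9)
  m <- merge(sim$truth$family, rep$assignments, by = "gene_id")
  map <- c(duplication = "self_genome", vertical = "close_lineage",
           hgt = "distant")
  agree <- mean(map[m$origin] == m$category)
  expect_gte(agree, 0.9)
  # no assignment ever picks the query protein itself
  expect_false(any(rep$assignments$best_genome_id == sim$genome$genome_id &
                     rep$assignments$best_gene_id ==
                       rep$assignments$gene_id))
})

test_that("a focal-only database classifies everything as self genome", {
  seqs <- Biostrings::AAStringSet(c(a = "MKVLAAGFWDERT",
                                    b = "MKVLAAGFWDSRT",
                                    c = "MKVLAAGYWDERT"))
  db <- protein_database(
    tibble::tibble(genome_id = "G1", gene_id = names(seqs)), seqs,
    list(G1 = c("Bacteria", "X")))
  rep <- best_hit_classification(seqs, db, "G1", "CloseGroup")
  expect_equal(unname(rep$counts[["self_genome"]]), 3L)
  expect_equal(unname(rep$fractions[["self_genome"]]), 1)
})

test_that("identical duplicates in another genome win without self-matching", {
  seqs <- c(a = "MKVLAAGFWDERT", b = "MNVLAAGFWDSRT", c = "MKVLAAGYWQERT")
  ent <- tibble::tibble(genome_id = rep(c("G1", "CLONE"), each = 3),
                        gene_id = rep(names(seqs), 2))
  db <- protein_database(ent, Biostrings::AAStringSet(rep(seqs, 2)),
                         list(G1 = c("Bacteria", "Close", "G1"),
                              CLONE = c("Bacteria", "Close", "CLONE")))
  rep <- best_hit_classification(Biostrings::AAStringSet(seqs), db, "G1",
                                 "Close")
  # best hit is the identical copy in the clone genome, never the self entry
  expect_true(all(rep$assignments$best_genome_id == "CLONE"))
  expect_equal(rep$assignments$best_gene_id, names(seqs))
  expect_true(all(rep$assignments$identity == 100))
  expect_equal(unname(rep$counts[["close_lineage"]]), 3L)
})

test_that("identity ties break by score then lexicographic ids", {
  seqs <- c(q = "MKVLAAGFWD")
  ent <- tibble::tibble(genome_id = c("B", "A", "A"),
                        gene_id = c("z1", "z2", "z1"))
  db <- protein_database(
    ent, Biostrings::AAStringSet(c("MKVLAAGFWD", "MKVLAAGFWD",
                                   "MKVLAAGFWD")),
    list(A = c("Bacteria", "Close"), B = c("Bacteria", "Far")))
  rep <- best_hit_classification(Biostrings::AAStringSet(seqs), db, "G1",
                                 "Close")
  expect_equal(rep$assignments$best_genome_id, "A")
  expect_equal(rep$assignments$best_gene_id, "z1")
})

test_that("best hits equal a brute-force all-pairs identity scan", {
  cfg <- small_synth(37)
  sim <- generate_focal_genome(cfg)
  fam_ids <- sim$truth$family$gene_id[1:8]
  seqs <- sim$genome$proteome[fam_ids]
  ent <- tibble::tibble(genome_id = "G1", gene_id = fam_ids)
  db <- protein_database(ent, seqs, list(G1 = c("Bacteria", "X")))
  rep <- best_hit_classification(seqs, db, "G1", "X")
  sch <- scoring_scheme()
  for (i in seq_along(fam_ids)) {
    cand <- setdiff(seq_along(fam_ids), i)
    al <- lapply(cand, function(j)
      global_align(as.character(seqs[[i]]), as.character(seqs[[j]]), sch))
    pid <- vapply(al, `[[`, numeric(1), "pid")
    score <- vapply(al, `[[`, numeric(1), "score")
    best <- cand[order(-pid, -score, fam_ids[cand])][1]
    expect_equal(rep$assignments$best_gene_id[i], fam_ids[best])
  }
})

test_that("summary fractions are printed at one decimal place", {
  f <- provenance_fractions(c(self_genome = 234L, close_lineage = 98L,
                              distant = 102L))
  expect_equal(f$percent_label, c("53.9", "22.6", "23.5"))
  expect_equal(sum(f$fraction), 1, tolerance = 1e-12)
})

test_that("array best-hit geography reproduces a planted mixed pattern", {
  set.seed(43)
  base <- paste0("M", random_aa_string(179,
                                       rownames(blosum62_matrix())[1:20]))
  anc_arr <- mutate_protein(base, 0.4)     # array-internal cluster ancestor
  ext <- mutate_protein(base, 0.4)         # external in-genome gene
  donor <- mutate_protein(base, 0.4)       # distant-genome donor
  arr_members <- c(
    stats::setNames(vapply(1:3, function(i) mutate_protein(anc_arr, 0.05),
                           ""), paste0("arr_clu", 1:3)),
    stats::setNames(vapply(1:4, function(i) mutate_protein(ext, 0.08), ""),
                    paste0("arr_ext", 1:4)),
    stats::setNames(vapply(1:2, function(i) mutate_protein(donor, 0.08), ""),
                    paste0("arr_hgt", 1:2)))
  focal_seqs <- c(arr_members, ext_gene = ext)
  ent <- rbind(
    tibble::tibble(genome_id = "G1", gene_id = names(focal_seqs)),
    tibble::tibble(genome_id = "DIST", gene_id = "donor1"))
  db <- protein_database(
    ent, Biostrings::AAStringSet(c(focal_seqs, donor1 = donor)),
    list(G1 = c("Bacteria", "Close", "G1"),
         DIST = c("Bacteria", "Far", "DIST")))
  rep <- best_hit_classification(Biostrings::AAStringSet(focal_seqs), db,
                                 "G1", "Close")
  array <- structure(list(member_gene_ids = names(arr_members),
                          contig_id = "chr", size = 9L),
                     class = "array_record")
  map <- array_best_hit_map(array, rep)
  expect_equal(sum(map$location == "within_array"), 3L)
  expect_equal(sum(map$location == "same_genome"), 4L)
  expect_equal(sum(map$location == "other_genome"), 2L)
  # permutation invariance and size-1 arrays
  arr_perm <- array
  arr_perm$member_gene_ids <- rev(array$member_gene_ids)
  map2 <- array_best_hit_map(arr_perm, rep)
  expect_setequal(paste(map$gene_id, map$location),
                  paste(map2$gene_id, map2$location))
  single <- structure(list(member_gene_ids = "ext_gene", contig_id = "chr",
                           size = 1L), class = "array_record")
  expect_equal(nrow(array_best_hit_map(single, rep)), 1L)
  bad <- structure(list(member_gene_ids = "missing", contig_id = "chr",
                        size = 1L), class = "array_record")
  expect_error(array_best_hit_map(bad, rep), "missing")
})
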