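test_that("GC content and skew windows match hand values", {
  gc <- gc_content_track("GCGCGCGCGC", 10, 10, circular = FALSE)
  expect_equal(gc$windows$value, 1)
  at <- gc_content_track("ATATATATAT", 10, 10, circular = FALSE)
  expect_equal(at$windows$value, 0)
  expect_equal(gc_skew_track("GGGGGGGGGG", 10, 10, FALSE)$windows$value, 1)
  expect_equal(gc_skew_track("CCCCCCCCCC", 10, 10, FALSE)$windows$value, -1)
  expect_equal(gc_skew_track("GCGCGCGCGC", 10, 10, FALSE)$windows$value, 0)
})

test_that("windows with no informative base are flagged undefined", {
  sk <- gc_skew_track("AATTAATTAA", 10, 10, FALSE)
  expect_false(sk$windows$defined)
  gc <- gc_content_track("NNNNNNNNNN", 10, 10, FALSE)
  expect_false(gc$windows$defined)
})

test_that("window values equal the naive counting oracle", {
  set.seed(71)
  seqchr <- paste(sample(c("A", "C", "G", "T", "N"), 20000, TRUE,
                         prob = c(.2, .3, .3, .19, .01)), collapse = "")
  for (circular in c(FALSE, TRUE)) {
    gc <- gc_content_track(seqchr, 1000, 700, circular)
    sk <- gc_skew_track(seqchr, 1000, 700, circular)
    for (k in seq_len(nrow(gc$windows))) {
      o <- oracle_window_gc(seqchr, gc$windows$start[k], 1000, circular)
      expect_equal(gc$windows$value[k], o$gc)
      expect_equal(sk$windows$value[k], o$skew)
    }
  }
})

test_that("replication extremes are recovered from planted replichores", {
  for (seed in c(5, 6, 7)) {
    cfg <- small_synth(seed)
    sim <- generate_focal_genome(cfg)
    sk <- gc_skew_track(sim$genome$contigs[[1]], 10000, 1000, TRUE)
    ex <- locate_replication_extremes(sk)
    tol <- 2 * 10000
    expect_lte(abs(ex$origin - sim$truth$breakpoints[["origin"]]), tol)
    expect_lte(abs(ex$terminus - sim$truth$breakpoints[["terminus"]]), tol)
    expect_false(ex$degenerate)
  }
})

test_that("constant skew is flagged degenerate and polarity swaps the labels", {
  const <- gc_skew_track(paste(rep("GGGGGGGGGGCC", 2000), collapse = ""),
                         1200, 600, FALSE)
  expect_true(locate_replication_extremes(const)$degenerate)

  cfg <- small_synth(9)
  sim <- generate_focal_genome(cfg)
  sk <- gc_skew_track(sim$genome$contigs[[1]], 10000, 1000, TRUE)
  flipped <- sk
  flipped$windows$value <- -flipped$windows$value
  a <- locate_replication_extremes(sk)
  b <- locate_replication_extremes(flipped)
  expect_equal(a$origin, b$terminus)
  expect_equal(a$terminus, b$origin)
})

test_that("a homogeneous genome yields no islands", {
  set.seed(81)
  seqchr <- paste(random_dna <- sample(c("A", "C", "G", "T"), 2e5, TRUE,
                                       prob = c(.18, .32, .32, .18)),
                  collapse = "")
  gc <- gc_content_track(seqchr, 10000, 1000, TRUE)
  isl <- detect_low_gc_islands(gc)
  expect_equal(nrow(isl$intervals), 0L)
})

test_that("planted low-GC islands are recovered with high overlap", {
  for (seed in c(15, 16, 17)) {
    sim <- generate_focal_genome(small_synth(seed))
    gc <- gc_content_track(sim$genome$contigs[[1]], 10000, 1000, TRUE)
    isl <- detect_low_gc_islands(gc, contig = sim$genome$contigs[[1]])
    isl$intervals$contig_id <- "chr"
    expect_gte(interval_jaccard(isl$intervals, sim$truth$islands), 0.8)
    expect_true(all(isl$intervals$mean_gc < isl$threshold_gc))
    expect_lte(isl$threshold_gc, isl$genome_mean_gc)
  }
})

test_that("a deeper threshold never lengthens the island set", {
  sim <- generate_focal_genome(small_synth(18))
  gc <- gc_content_track(sim$genome$contigs[[1]], 10000, 1000, TRUE)
  tot <- vapply(c(1.0, 1.5, 2.0, 3.0), function(k)
    island_total_length(detect_low_gc_islands(gc, sd_multiplier = k)),
    numeric(1))
  expect_true(all(diff(tot) <= 0))
})

test_that("density contrast conserves counts and lengths", {
  sim <- generate_focal_genome(small_synth(19))
  hits <- find_family_members(sim$truth$queries, sim$genome)
  islands <- structure(list(
    intervals = tibble::tibble(contig_id = "chr",
                               start = sim$truth$islands$start,
                               end = sim$truth$islands$end,
                               mean_gc = 0.58),
    genome_mean_gc = 0.63, threshold_gc = 0.6,
    contig_length = genome_length(sim$genome)), class = "island_set")
  rep <- gene_density_contrast(hits, sim$genome, islands)
  expect_equal(rep$n_inside + rep$n_outside, nrow(hits$hits))
  expect_equal(rep$len_inside_mb + rep$len_outside_mb,
               genome_length(sim$genome) / 1e6, tolerance = 1e-9)
  expect_equal(rep$density_outside, rep$n_outside / rep$len_outside_mb)
  # planted truth: island membership by midpoint matches the generator
  expect_equal(rep$n_inside, sum(sim$truth$family$island_member))
})

test_that("an empty island set gives a flagged all-outside report", {
  sim <- generate_focal_genome(small_synth(19))
  hits <- find_family_members(sim$truth$queries, sim$genome)
  empty <- structure(list(
    intervals = tibble::tibble(contig_id = character(), start = integer(),
                               end = integer(), mean_gc = numeric()),
    genome_mean_gc = 0.63, threshold_gc = 0.6,
    contig_length = genome_length(sim$genome)), class = "island_set")
  rep <- gene_density_contrast(hits, sim$genome, empty)
  expect_equal(rep$n_inside, 0L)
  expect_false(rep$fold_ratio_defined)
  expect_true(is.na(rep$density_inside))
})

test_that("neighbourhood scan recovers the planted tagged fraction", {
  sim <- generate_focal_genome(small_synth(23))
  hits <- find_family_members(sim$truth$queries, sim$genome)
  res <- neighborhood_context(hits, sim$genome, "transcription_factor",
                              radius_genes = 2L)
  planted <- sim$truth$family$gene_id[sim$truth$family$tagged_neighbor]
  expect_setequal(res$gene_ids, planted)
  expect_equal(res$count, length(planted))
  expect_equal(res$fraction, length(planted) / nrow(sim$truth$family))
  # the generator met its 30 % target on this fixture
  expect_equal(res$fraction, 0.3, tolerance = 0.051)
})

test_that("neighbourhood fraction is monotone in the radius", {
  sim <- generate_focal_genome(small_synth(23))
  hits <- find_family_members(sim$truth$queries, sim$genome)
  fr <- vapply(1:4, function(r)
    neighborhood_context(hits, sim$genome, "transcription_factor",
                         r)$fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_error(neighborhood_context(hits, sim$genome, "nonsense_tag"),
               "known tags")
})

test_that("adjacency counting in gene order works on a hand fixture", {
  g <- tiny_genome()
  res <- neighborhood_context(c("g2", "g6"), g, "transcription_factor", 2L)
  expect_equal(res$gene_ids, "g2")  # g3 (TF) is 1 step from g2, 3+ from g6
})
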