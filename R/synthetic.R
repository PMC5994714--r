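# Seeded synthetic genome generator with full ground truth.
#
# Emulates the genomic situation the analysis assumes: a circular high-GC
# chromosome with a few low-GC islands, a replichore-structured GC skew, a
# planted protein family whose members arose by within-genome duplication,
# vertical descent or horizontal transfer from a compositionally distinct
# donor pool, tandem arrays of duplicates, regulatory genes planted next to
# a known fraction of family genes, and companion close-/distant-lineage
# proteomes carrying the orthologs and donors.

# background amino-acid frequencies (typical bacterial proteome, rounded)
AA_FREQS <- c(A = 0.095, R = 0.055, N = 0.035, D = 0.053, C = 0.011,
              Q = 0.037, E = 0.060, G = 0.080, H = 0.021, I = 0.055,
              L = 0.103, K = 0.042, M = 0.024, F = 0.039, P = 0.048,
              S = 0.058, T = 0.054, W = 0.013, Y = 0.028, V = 0.073)
AA20 <- names(AA_FREQS)

#' Configuration for the synthetic genome generator
#'
#' Defaults describe the study conditions the generator emulates: a 1 Mb
#' circular chromosome at 64 % GC with low-GC (58 %) islands covering 10 %
#' of the length, a 300-member planted family among 200 unrelated decoy
#' genes, origin fractions 0.60 / 0.25 / 0.15 for duplication / vertical /
#' HGT, and an array-size distribution mirroring a heavily expanded family
#' (mostly singletons, some pairs, rare long arrays up to nine genes).
#'
#' The three divergence knobs are *relationship* divergences between a
#' member and its labelled nearest relative: duplicate siblings at
#' `within_genome_divergence`, ortholog pairs at `ortholog_divergence`,
#' member-donor pairs at `donor_divergence`; they must be ordered
#' within < ortholog < donor. `family_radiation_divergence` is the depth of
#' every lineage from the family seed protein and is chosen deeper than all
#' three so that cross-relationships are far below each member's labelled
#' relative.
#'
#' @param seed integer RNG seed; every generator output is a deterministic
#'   function of it.
#' @param genome_length chromosome length in bases.
#' @param background_gc,island_gc GC fractions of bulk DNA and islands.
#' @param island_fraction fraction of the genome covered by islands.
#' @param skew_amplitude GC skew bias s: P(G) = gc/2 (1+s) on one replichore
#'   and gc/2 (1-s) on the other.
#' @param replichore_breakpoints origin and terminus as fractions of length.
#' @param n_family,n_background counts of planted family members and decoy
#'   genes.
#' @param origin_fractions named fractions (duplication, vertical, hgt)
#'   summing to 1.
#' @param array_size_probs named probability vector over tandem-array sizes
#'   for duplication-origin members.
#' @param within_genome_divergence,ortholog_divergence,donor_divergence
#'   relationship divergences (expected substituted fraction).
#' @param family_radiation_divergence depth of each lineage from the seed.
#' @param p_island_hgt probability an HGT member is placed inside an island.
#' @param p_island_other island probability for non-HGT family members.
#' @param uniform_placement if TRUE, ignore the island preferences and place
#'   every gene uniformly (the null model for density contrasts).
#' @param n_close_companions,n_distant_companions companion genome counts.
#' @param companion_background_genes decoys per companion genome.
#' @param protein_length_range residue length range for generated proteins.
#' @param tagged_neighbor_fraction fraction of family genes given a
#'   transcription-factor-labelled neighbour.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         genome_length = 1e6,
                         background_gc = 0.64,
                         island_gc = 0.58,
                         island_fraction = 0.10,
                         skew_amplitude = 0.03,
                         replichore_breakpoints = c(0.25, 0.75),
                         n_family = 300L,
                         n_background = 200L,
                         origin_fractions = c(duplication = 0.60,
                                              vertical = 0.25, hgt = 0.15),
                         array_size_probs = c(`1` = 294, `2` = 48, `3` = 6,
                                              `4` = 3, `5` = 1, `9` = 1) / 353,
                         within_genome_divergence = 0.25,
                         ortholog_divergence = 0.35,
                         donor_divergence = 0.45,
                         family_radiation_divergence = 0.55,
                         p_island_hgt = 0.7,
                         p_island_other = 0,
                         uniform_placement = FALSE,
                         n_close_companions = 2L,
                         n_distant_companions = 1L,
                         companion_background_genes = 25L,
                         protein_length_range = c(130L, 210L),
                         tagged_neighbor_fraction = 0.16) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              background_gc = background_gc, island_gc = island_gc,
              island_fraction = island_fraction,
              skew_amplitude = skew_amplitude,
              replichore_breakpoints = replichore_breakpoints,
              n_family = as.integer(n_family),
              n_background = as.integer(n_background),
              origin_fractions = origin_fractions,
              array_size_probs = array_size_probs,
              within_genome_divergence = within_genome_divergence,
              ortholog_divergence = ortholog_divergence,
              donor_divergence = donor_divergence,
              family_radiation_divergence = family_radiation_divergence,
              p_island_hgt = p_island_hgt, p_island_other = p_island_other,
              uniform_placement = isTRUE(uniform_placement),
              n_close_companions = as.integer(n_close_companions),
              n_distant_companions = as.integer(n_distant_companions),
              companion_background_genes = as.integer(companion_background_genes),
              protein_length_range = as.integer(protein_length_range),
              tagged_neighbor_fraction = tagged_neighbor_fraction)
  fr <- c(cfg$background_gc, cfg$island_gc, cfg$island_fraction,
          cfg$p_island_hgt, cfg$p_island_other, cfg$tagged_neighbor_fraction,
          cfg$origin_fractions)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (abs(sum(cfg$origin_fractions) - 1) > 1e-9)
    stop("origin_fractions must sum to 1")
  if (!all(c("duplication", "vertical", "hgt") %in%
           names(cfg$origin_fractions)))
    stop("origin_fractions must be named duplication/vertical/hgt")
  if (!(cfg$within_genome_divergence < cfg$ortholog_divergence &&
        cfg$ortholog_divergence < cfg$donor_divergence))
    stop("divergences must be ordered within < ortholog < donor")
  if (cfg$family_radiation_divergence <= cfg$donor_divergence)
    warning("family_radiation_divergence should exceed donor_divergence ",
            "for a clean nearest-relative structure")
  if (abs(sum(cfg$array_size_probs) - 1) > 1e-9)
    stop("array_size_probs must sum to 1")
  if (cfg$genome_length < 5e4) stop("genome_length too small")
  class(cfg) <- "synth_config"
  cfg
}

random_protein <- function(len) {
  paste0("M", paste(sample(AA20, len - 1L, replace = TRUE, prob = AA_FREQS),
                    collapse = ""))
}

# BLOSUM62-biased replacement weights: P(b | a) over b != a proportional to
# exp(B62[a,b] / 2), favouring exchangeable residues.
replacement_weights <- function() {
  if (!is.null(.famex_cache$repl_w)) return(.famex_cache$repl_w)
  b <- blosum62_matrix()[AA20, AA20]
  w <- exp(b / 2)
  diag(w) <- 0
  w <- sweep(w, 1, rowSums(w), "/")
  .famex_cache$repl_w <- w
  w
}

#' Mutate a protein by BLOSUM-biased substitutions
#'
#' Substitutes a Binomial(length - 1, target_divergence) number of positions
#' (the initiator methionine is kept fixed), replacements drawn with
#' probability proportional to `exp(BLOSUM62 / 2)` so exchanges are
#' realistic. Length is preserved unless `indel_rate > 0`, in which case a
#' Binomial number of single/short indels is applied after substitution.
#'
#' @param parent amino-acid sequence (character or `AAString`).
#' @param target_divergence expected substituted fraction in `[0, 1)`.
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @param indel_rate optional per-site indel probability (default 0).
#' @return Mutated sequence (character).
#' @export
mutate_protein <- function(parent, target_divergence, seed = NULL,
                           indel_rate = 0) {
  if (target_divergence < 0 || target_divergence >= 1)
    stop("target_divergence must lie in [0, 1)")
  parent <- as_single_aa(parent)
  run <- function() mutate_protein_impl(parent, target_divergence, indel_rate)
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

mutate_protein_impl <- function(parent, d, indel_rate) {
  chars <- strsplit(parent, "", fixed = TRUE)[[1]]
  n <- length(chars)
  mutable <- 2:n
  k <- stats::rbinom(1L, length(mutable), d)
  if (k > 0) {
    pos <- sample(mutable, k)
    W <- replacement_weights()
    for (p in pos) {
      a <- chars[p]
      if (a %in% AA20) chars[p] <- sample(AA20, 1L, prob = W[a, ])
    }
  }
  if (indel_rate > 0) {
    ni <- stats::rbinom(1L, n, indel_rate)
    for (z in seq_len(ni)) {
      at <- sample(2:length(chars), 1L)
      len <- sample(1:3, 1L)
      if (stats::runif(1) < 0.5) {
        ins <- sample(AA20, len, replace = TRUE, prob = AA_FREQS)
        chars <- append(chars, ins, after = at)
      } else if (length(chars) - len > 10L) {
        drop <- at:min(at + len - 1L, length(chars))
        chars <- chars[-drop]
      }
    }
  }
  paste(chars, collapse = "")
}

# ---- codon machinery -------------------------------------------------------

codon_sets <- function() {
  if (!is.null(.famex_cache$codon_sets)) return(.famex_cache$codon_sets)
  gc11 <- Biostrings::getGeneticCode("11")
  s <- split(names(gc11), gc11)
  .famex_cache$codon_sets <- s
  s
}

codon_gc_count <- function(codons)
  vapply(strsplit(codons, ""), function(x) sum(x %in% c("G", "C")),
         numeric(1))

# sample a GC-biased synonymous codon for every residue of aa_vec; only the
# degenerate positions are free, so the per-position bias t3 is calibrated
# (empirically, against the fixed-position GC of the background amino-acid
# composition) so that realized coding GC tracks gc_target
encode_codons <- function(aa_vec, gc_target) {
  sets <- codon_sets()
  t3 <- min(0.98, max(0.02, (gc_target - 0.3236) / 0.357))
  out <- character(length(aa_vec))
  for (a in unique(aa_vec)) {
    idx <- which(aa_vec == a)
    cods <- sets[[a]]
    if (is.null(cods)) cods <- sets[["X"]] %||% "NNN"
    gcc <- codon_gc_count(cods)
    w <- t3^gcc * (1 - t3)^(3 - gcc)
    out[idx] <- sample(cods, length(idx), replace = TRUE, prob = w)
  }
  stops <- c("TAA", "TAG", "TGA")
  gcc <- codon_gc_count(stops)
  stop_cod <- sample(stops, 1L, prob = t3^gcc * (1 - t3)^(3 - gcc))
  c(out, stop_cod)
}

gene_dna <- function(protein, gc_target, strand) {
  cods <- encode_codons(strsplit(protein, "", fixed = TRUE)[[1]], gc_target)
  dna <- paste(cods, collapse = "")
  if (strand == "-")
    dna <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(dna)))
  dna
}

random_dna_vec <- function(n, gc, skew = 0) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2 * (1 - skew), gc / 2 * (1 + skew),
                  (1 - gc) / 2))
}

DECOY_PRODUCTS <- c("hypothetical protein", "conserved protein of unknown function",
                    "membrane protein", "dehydrogenase", "acyl-CoA synthetase",
                    "aminotransferase", "outer membrane lipoprotein")

# ---- focal genome ----------------------------------------------------------

#' Generate the focal synthetic genome with ground truth
#'
#' Deterministic given `config$seed`. Background nucleotides are i.i.d. at
#' `background_gc` with the G/C split biased by `+s` on one replichore and
#' `-s` on the other so the cumulative skew has recoverable extremes;
#' islands are placed non-overlapping at `island_gc`; family members are
#' synthesized from a seed protein by the mutation process implied by their
#' origin label; duplication-origin members are partly arranged in tandem
#' arrays; HGT members fall inside islands with probability `p_island_hgt`;
#' decoy genes tile the rest; transcription-factor-labelled decoys are
#' planted next to a configured fraction of family genes.
#'
#' @param config a [synth_config()].
#' @return List with `genome` (an [annotated_genome()]) and `truth` (a
#'   `synthetic_truth` list: per-member origin/island/array labels, planted
#'   islands, replichore breakpoints, the seed query protein and the family
#'   protein set used to derive companion genomes).
#' @export
generate_focal_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, generate_focal_impl(config))
}

generate_focal_impl <- function(cfg) {
  L <- cfg$genome_length
  b <- sort(as.integer(round(cfg$replichore_breakpoints * L)))
  s <- cfg$skew_amplitude

  # background with replichore-structured skew: [b1, b2) is G-rich
  seqv <- random_dna_vec(L, cfg$background_gc, -s)
  seqv[(b[1] + 1L):b[2]] <- random_dna_vec(b[2] - b[1], cfg$background_gc, s)

  # islands
  island_total <- round(cfg$island_fraction * L)
  k <- max(2L, as.integer(round(island_total / 25000)))
  w <- stats::runif(k, 0.7, 1.3)
  ilens <- round(island_total * w / sum(w))
  ilens[k] <- island_total - sum(ilens[-k])
  min_gap <- 20000L
  avail <- L - sum(ilens) - (k + 1L) * min_gap
  if (avail < 0) stop("infeasible island packing for this genome length")
  gw <- stats::runif(k + 1L, 0.5, 1.5)
  gaps <- min_gap + floor(avail * gw / sum(gw))
  istart <- cumsum(c(gaps[1], utils::head(ilens, -1) + gaps[2:k]))
  islands <- tibble::tibble(start = as.integer(istart),
                            end = as.integer(istart + ilens))
  for (i in seq_len(nrow(islands))) {
    mid <- (islands$start[i] + islands$end[i]) / 2
    isl_skew <- if (mid >= b[1] && mid < b[2]) s else -s
    seqv[(islands$start[i] + 1L):islands$end[i]] <-
      random_dna_vec(islands$end[i] - islands$start[i], cfg$island_gc,
                     isl_skew)
  }

  # ---- family proteins with origin structure
  plen <- as.integer(round(mean(cfg$protein_length_range)))
  seed_protein <- random_protein(plen)
  n <- cfg$n_family
  nd <- as.integer(round(cfg$origin_fractions[["duplication"]] * n))
  nv <- as.integer(round(cfg$origin_fractions[["vertical"]] * n))
  nh <- n - nd - nv
  if (min(nd, nv, nh) < 0) stop("origin fractions incompatible with n_family")

  fam <- vector("list", n)
  rad <- cfg$family_radiation_divergence
  # Each member and its labelled relative (duplicate sibling / ortholog /
  # donor) diverge symmetrically, rel/2 each, from a common ancestor whose
  # own depth from the family seed is chosen so every member (and every
  # companion relative) ends up at the same total radiation depth; this
  # keeps the whole family, donors included, uniformly detectable by the
  # seed query while the relationship identities stay ordered
  # within > ortholog > donor.
  anc_depth <- function(rel) max(0, 1 - (1 - rad) / (1 - rel / 2))
  idx <- 0L
  # duplication: sequence clusters of >= 2 siblings around a cluster ancestor
  cluster_id <- 0L
  remaining <- nd
  a_dup <- anc_depth(cfg$within_genome_divergence)
  while (remaining > 0L) {
    cluster_id <- cluster_id + 1L
    size <- if (remaining <= 3L) remaining else
      min(remaining, sample(2:5, 1L))
    if (size == 1L) size <- 2L  # never a lone "duplicate"
    size <- min(size, remaining)
    if (remaining - size == 1L) size <- size + 1L  # avoid stranding one
    size <- min(size, remaining)
    anc <- mutate_protein_impl(seed_protein, a_dup, 0)
    for (z in seq_len(size)) {
      idx <- idx + 1L
      fam[[idx]] <- list(origin = "duplication", cluster = cluster_id,
                         protein = mutate_protein_impl(
                           anc, cfg$within_genome_divergence / 2, 0),
                         ancestor = NA_character_)
    }
    remaining <- remaining - size
  }
  nd <- idx  # realized (>= 2 per cluster may shift the split by at most 1)
  a_vert <- anc_depth(cfg$ortholog_divergence)
  for (z in seq_len(nv)) {
    idx <- idx + 1L
    anc <- mutate_protein_impl(seed_protein, a_vert, 0)
    fam[[idx]] <- list(origin = "vertical", cluster = NA_integer_,
                       protein = mutate_protein_impl(
                         anc, cfg$ortholog_divergence / 2, 0),
                       ancestor = anc)
  }
  nh <- n - idx
  a_hgt <- anc_depth(cfg$donor_divergence)
  for (z in seq_len(max(0L, nh))) {
    idx <- idx + 1L
    anc <- mutate_protein_impl(seed_protein, a_hgt, 0)
    fam[[idx]] <- list(origin = "hgt", cluster = NA_integer_,
                       protein = mutate_protein_impl(
                         anc, cfg$donor_divergence / 2, 0),
                       ancestor = anc)
  }
  fam <- fam[seq_len(idx)]
  origins <- vapply(fam, `[[`, "", "origin")

  # decoys
  dec_len <- sample(cfg$protein_length_range[1]:cfg$protein_length_range[2],
                    cfg$n_background, replace = TRUE)
  decoys <- vapply(dec_len, random_protein, "")

  # ---- placement units
  p_island <- if (cfg$uniform_placement) {
    rep(cfg$island_fraction, length(fam))
  } else {
    ifelse(origins == "hgt", cfg$p_island_hgt, cfg$p_island_other)
  }
  fam_in_island <- stats::runif(length(fam)) < p_island
  dec_in_island <- stats::runif(length(decoys)) <
    (if (cfg$uniform_placement) cfg$island_fraction else cfg$island_fraction)

  # arrays: duplication members placed outside islands are grouped into
  # tandem arrays drawn from array_size_probs; everything else is a
  # singleton unit
  arr_pool <- which(origins == "duplication" & !fam_in_island)
  arr_pool <- sample(arr_pool)
  sizes <- integer(0)
  while (sum(sizes) < length(arr_pool)) {
    sizes <- c(sizes, sample(as.integer(names(cfg$array_size_probs)), 1L,
                             prob = cfg$array_size_probs))
  }
  if (length(sizes)) sizes[length(sizes)] <-
    length(arr_pool) - sum(utils::head(sizes, -1))
  sizes <- sizes[sizes > 0]
  units_bg <- list()
  at <- 0L
  for (sz in sizes) {
    units_bg[[length(units_bg) + 1L]] <- list(type = "family",
                                              members = arr_pool[(at + 1L):(at + sz)])
    at <- at + sz
  }
  for (i in which(origins != "duplication" & !fam_in_island))
    units_bg[[length(units_bg) + 1L]] <- list(type = "family", members = i)
  for (i in which(!dec_in_island))
    units_bg[[length(units_bg) + 1L]] <- list(type = "decoy", members = i)
  units_isl <- list()
  for (i in which(fam_in_island))
    units_isl[[length(units_isl) + 1L]] <- list(type = "family", members = i)
  for (i in which(dec_in_island))
    units_isl[[length(units_isl) + 1L]] <- list(type = "decoy", members = i)

  gene_len <- function(u) {
    lens <- vapply(u$members, function(i) {
      p <- if (u$type == "family") fam[[i]]$protein else decoys[i]
      (nchar(p) + 1L) * 3L
    }, integer(1))
    sum(lens) + (length(lens) - 1L) * 60L  # 60 bp intra-array spacers
  }

  # segments: islands and the gaps between them
  seg_isl <- islands
  gstart <- c(0L, islands$end)
  gend <- c(islands$start, L)
  seg_bg <- tibble::tibble(start = gstart, end = gend)
  seg_bg <- seg_bg[seg_bg$end - seg_bg$start > 3000L, , drop = FALSE]

  place_units <- function(units, segments) {
    if (!length(units)) return(NULL)
    cap <- (segments$end - segments$start) * 0.85
    assign_seg <- integer(length(units))
    units <- units[sample(length(units))]
    for (u in seq_along(units)) {
      ul <- gene_len(units[[u]])
      ok <- which(cap >= ul)
      if (!length(ok)) stop("infeasible packing: too many genes for length")
      pick <- if (length(ok) == 1L) ok else
        sample(ok, 1L, prob = cap[ok])
      assign_seg[u] <- pick
      cap[pick] <- cap[pick] - ul - 60
    }
    placed <- NULL
    for (sg in unique(assign_seg)) {
      us <- units[assign_seg == sg]
      tot <- sum(vapply(us, gene_len, integer(1)))
      free <- (segments$end[sg] - segments$start[sg]) - tot
      gw <- stats::runif(length(us) + 1L, 0.2, 1.8)
      gaps <- 30L + floor((free - 30L * (length(us) + 1L)) * gw / sum(gw))
      pos <- segments$start[sg]
      for (z in seq_along(us)) {
        pos <- pos + gaps[z]
        u <- us[[z]]
        strand <- sample(c("+", "-"), 1L)
        gpos <- pos
        for (i in u$members) {
          p <- if (u$type == "family") fam[[i]]$protein else decoys[i]
          glen <- (nchar(p) + 1L) * 3L
          placed <- rbind(placed, tibble::tibble(
            type = u$type, member = i, start = as.integer(gpos),
            end = as.integer(gpos + glen), strand = strand))
          gpos <- gpos + glen + 60L
        }
        pos <- gpos - 60L
      }
    }
    placed
  }

  placed <- rbind(place_units(units_bg, seg_bg),
                  place_units(units_isl, seg_isl))
  if (is.null(placed)) stop("configuration places no genes on the genome")
  placed <- placed[order(placed$start), , drop = FALSE]

  # write genes into the sequence with region-matched codon GC
  in_island <- function(pos) any(pos >= islands$start & pos < islands$end)
  for (r in seq_len(nrow(placed))) {
    p <- if (placed$type[r] == "family") fam[[placed$member[r]]]$protein
    else decoys[placed$member[r]]
    gc_t <- if (in_island(placed$start[r])) cfg$island_gc else
      cfg$background_gc
    dna <- gene_dna(p, gc_t, placed$strand[r])
    seqv[(placed$start[r] + 1L):placed$end[r]] <-
      strsplit(dna, "", fixed = TRUE)[[1]]
  }

  # ids by genomic order
  placed$gene_id <- sprintf("FG_%05d", seq_len(nrow(placed)) * 10L)
  products <- ifelse(placed$type == "family", "family SBP homolog",
                     sample(DECOY_PRODUCTS, nrow(placed), replace = TRUE))

  # plant transcription-factor neighbours next to a known family fraction
  fam_rows <- which(placed$type == "family")
  n_tag <- as.integer(round(cfg$tagged_neighbor_fraction * length(fam_rows)))
  tagged_family <- character(0)
  if (n_tag > 0L) {
    inner <- fam_rows[fam_rows > 4L & fam_rows < nrow(placed) - 4L]
    tagged_rows <- integer(0)
    for (pass in 1:2) for (r in sample(inner)) {
      if (length(tagged_rows) >= n_tag) break
      if (r %in% tagged_rows) next
      nb <- intersect(c(r - 2L, r - 1L, r + 1L, r + 2L),
                      seq_len(nrow(placed)))
      nb <- nb[placed$type[nb] == "decoy" &
                 products[nb] %in% DECOY_PRODUCTS]
      # the decoy may only neighbour this family gene (or ones already
      # counted), so the planted fraction stays exact
      ok <- nb[vapply(nb, function(d) {
        fam_near <- intersect((d - 2L):(d + 2L), fam_rows)
        all(fam_near %in% c(r, tagged_rows))
      }, logical(1))]
      if (length(ok)) {
        products[ok[1]] <- "LysR family transcriptional regulator"
        tagged_rows <- c(tagged_rows, r)
      }
    }
    tagged_family <- placed$gene_id[tagged_rows]
  }

  genome_seq <- Biostrings::DNAStringSet(paste(seqv, collapse = ""))
  names(genome_seq) <- "chr"
  genes <- tibble::tibble(gene_id = placed$gene_id, contig_id = "chr",
                          start = placed$start, end = placed$end,
                          strand = placed$strand, product = products)
  prots <- vapply(seq_len(nrow(placed)), function(r)
    if (placed$type[r] == "family") fam[[placed$member[r]]]$protein
    else decoys[placed$member[r]], "")
  proteome <- Biostrings::AAStringSet(stats::setNames(prots, placed$gene_id))
  genome <- annotated_genome(
    sprintf("SYNTH_FOCAL_%d", cfg$seed), genome_seq, genes, proteome,
    lineage = c("Bacteria", "Proteobacteria", "Alphaproteobacteria",
                "Rhizobacteria", "FocalGenus"),
    circular = TRUE)

  fam_tab <- placed[placed$type == "family", , drop = FALSE]
  fam_origin <- origins[fam_tab$member]
  fam_cluster <- vapply(fam_tab$member, function(i)
    fam[[i]]$cluster %||% NA_integer_, integer(1))
  mid <- (fam_tab$start + fam_tab$end) / 2
  island_member <- vapply(mid, in_island, logical(1))
  arrays <- detect_arrays(fam_tab$gene_id, genome)
  array_id <- rep(NA_integer_, nrow(fam_tab))
  for (a in seq_along(arrays)) {
    array_id[match(arrays[[a]]$member_gene_ids, fam_tab$gene_id)] <- a
  }

  truth <- structure(list(
    family = tibble::tibble(gene_id = fam_tab$gene_id, origin = fam_origin,
                            cluster_id = fam_cluster,
                            island_member = island_member,
                            array_id = array_id,
                            tagged_neighbor = fam_tab$gene_id %in%
                              tagged_family),
    family_proteins = proteome[fam_tab$gene_id],
    relative_ancestors = stats::setNames(
      vapply(fam_tab$member, function(i) fam[[i]]$ancestor, ""),
      fam_tab$gene_id),
    islands = islands,
    breakpoints = c(origin = b[1], terminus = b[2]),
    seed_protein = seed_protein,
    queries = Biostrings::AAStringSet(c(FAMSEED = seed_protein)),
    config = cfg), class = "synthetic_truth")
  list(genome = genome, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d family genes (%s), %d island(s), ori %d / ter %d\n",
    nrow(x$family),
    paste(sprintf("%s=%d", names(table(x$family$origin)),
                  as.integer(table(x$family$origin))), collapse = ", "),
    nrow(x$islands), x$breakpoints[["origin"]], x$breakpoints[["terminus"]]))
  invisible(x)
}

# ---- companion genomes -----------------------------------------------------

#' Generate close- and distant-lineage companion genomes
#'
#' Close companions carry an ortholog of every vertical-origin focal member
#' (at `ortholog_divergence`); distant companions carry the donor of every
#' HGT-origin member (at `donor_divergence`), so each HGT member's nearest
#' database neighbour is its donor. Companions also carry their own decoy
#' genes. Lineages are set so close companions share the focal close-group
#' label ("Rhizobacteria") and distant companions do not.
#'
#' @param config the [synth_config()] used for the focal genome.
#' @param truth the `synthetic_truth` returned by [generate_focal_genome()].
#' @return Named list of [annotated_genome()]s; attribute `planted_relatives`
#'   maps focal members to their planted companion relative.
#' @export
generate_companion_genomes <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"),
            inherits(truth, "synthetic_truth"))
  withr::with_seed(derive_seed(config$seed, 7L),
                   generate_companions_impl(config, truth))
}

generate_companions_impl <- function(cfg, truth) {
  fam <- truth$family
  prot <- truth$family_proteins
  specs <- list()
  for (i in seq_len(cfg$n_close_companions))
    specs[[sprintf("CLOSE%d", i)]] <- list(
      gc = 0.62, lineage = c("Bacteria", "Proteobacteria",
                             "Alphaproteobacteria", "Rhizobacteria",
                             sprintf("CloseGenus%d", i)))
  for (i in seq_len(cfg$n_distant_companions))
    specs[[sprintf("DIST%d", i)]] <- list(
      gc = 0.48, lineage = c("Bacteria", "Proteobacteria",
                             "Betaproteobacteria", "DonorGroup",
                             sprintf("DistantGenus%d", i)))
  carry <- stats::setNames(vector("list", length(specs)), names(specs))
  vgenes <- fam$gene_id[fam$origin == "vertical"]
  if (length(vgenes) && cfg$n_close_companions > 0L) {
    tgt <- sample(sprintf("CLOSE%d", seq_len(cfg$n_close_companions)),
                  length(vgenes), replace = TRUE)
    for (k in seq_along(vgenes)) {
      seqd <- mutate_protein_impl(truth$relative_ancestors[[vgenes[k]]],
                                  cfg$ortholog_divergence / 2, 0)
      carry[[tgt[k]]] <- c(carry[[tgt[k]]],
                           stats::setNames(seqd, vgenes[k]))
    }
  }
  hgenes <- fam$gene_id[fam$origin == "hgt"]
  if (length(hgenes) && cfg$n_distant_companions > 0L) {
    tgt <- sample(sprintf("DIST%d", seq_len(cfg$n_distant_companions)),
                  length(hgenes), replace = TRUE)
    for (k in seq_along(hgenes)) {
      seqd <- mutate_protein_impl(truth$relative_ancestors[[hgenes[k]]],
                                  cfg$donor_divergence / 2, 0)
      carry[[tgt[k]]] <- c(carry[[tgt[k]]],
                           stats::setNames(seqd, hgenes[k]))
    }
  }
  role_of <- stats::setNames(
    ifelse(fam$origin == "vertical", "ortholog", "donor"), fam$gene_id)

  out <- list()
  relatives <- NULL
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    fam_seqs <- carry[[nm]] %||% character(0)
    n_dec <- cfg$companion_background_genes
    dec_len <- sample(cfg$protein_length_range[1]:cfg$protein_length_range[2],
                      n_dec, replace = TRUE)
    dec <- vapply(dec_len, random_protein, "")
    planted_ids <- if (length(fam_seqs))
      sprintf("%s_F%04d", nm, seq_along(fam_seqs)) else character(0)
    if (length(fam_seqs))
      relatives <- rbind(relatives, tibble::tibble(
        focal_gene_id = names(fam_seqs), companion = nm,
        companion_gene_id = planted_ids,
        role = unname(role_of[names(fam_seqs)])))
    prots <- c(unname(fam_seqs), dec)
    ids <- c(planted_ids, sprintf("%s_B%04d", nm, seq_along(dec)))
    labels <- c(rep("family SBP homolog", length(fam_seqs)),
                sample(DECOY_PRODUCTS, n_dec, replace = TRUE))
    ord <- sample(length(prots))
    prots <- prots[ord]; ids <- ids[ord]; labels <- labels[ord]
    pos <- 200L
    rows <- NULL
    segs <- character(0)
    segs <- c(segs, paste(random_dna_vec(200L, sp$gc), collapse = ""))
    for (z in seq_along(prots)) {
      strand <- sample(c("+", "-"), 1L)
      dna <- gene_dna(prots[z], sp$gc, strand)
      glen <- nchar(dna)
      rows <- rbind(rows, tibble::tibble(
        gene_id = ids[z], contig_id = "chr", start = pos,
        end = pos + glen, strand = strand, product = labels[z]))
      segs <- c(segs, dna, paste(random_dna_vec(150L, sp$gc), collapse = ""))
      pos <- pos + glen + 150L
    }
    contig <- Biostrings::DNAStringSet(paste(segs, collapse = ""))
    names(contig) <- "chr"
    proteome <- Biostrings::AAStringSet(stats::setNames(prots, ids))
    out[[nm]] <- annotated_genome(nm, contig, rows, proteome,
                                  lineage = sp$lineage, circular = FALSE)
  }
  attr(out, "planted_relatives") <- relatives
  out
}

# ---- emission to standard formats ------------------------------------------

write_gff3 <- function(genome, path) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(genome$contigs),
                     Biostrings::width(genome$contigs)))
  g <- genome$genes
  lines <- c(lines, sprintf(
    "%s\tfamexscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;product=%s",
    g$contig_id, g$start + 1L, g$end, g$strand, g$gene_id,
    gsub(";", "%3B", g$product, fixed = TRUE)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic dataset to standard files
#'
#' Emits, per genome, `<id>.gff3`, `<id>.fna` and `<id>.faa`, plus
#' `queries.faa`, `truth.tsv` (per family member: origin, island, array) and
#' `lineage.tsv` (genome_id, comma-separated lineage) -- the same formats a
#' real dataset would arrive in, so the pipeline consumes them unchanged.
#'
#' @param focal list returned by [generate_focal_genome()].
#' @param companions list returned by [generate_companion_genomes()] (may be
#'   `NULL`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(focal, companions = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- c(list(focal$genome), companions)
  lin <- NULL
  for (g in genomes) {
    write_gff3(g, file.path(dir, paste0(g$genome_id, ".gff3")))
    Biostrings::writeXStringSet(g$contigs,
                                file.path(dir, paste0(g$genome_id, ".fna")))
    Biostrings::writeXStringSet(g$proteome,
                                file.path(dir, paste0(g$genome_id, ".faa")))
    lin <- rbind(lin, data.frame(genome_id = g$genome_id,
                                 lineage = paste(g$lineage, collapse = ",")))
  }
  Biostrings::writeXStringSet(focal$truth$queries,
                              file.path(dir, "queries.faa"))
  utils::write.table(as.data.frame(focal$truth$family),
                     file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(lin, file.path(dir, "lineage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
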