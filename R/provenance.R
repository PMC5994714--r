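# Best-hit provenance: classify every family member of a focal genome by
# where its closest non-self relative lives (same genome = lineage-specific
# expansion, close lineage = vertical descent, distant lineage = horizontal
# transfer candidate).

#' Construct a family-restricted protein database
#'
#' Entries are the family members of each genome (the database is
#' family-restricted: best hits are sought only among family members of
#' other genomes, plus the focal genome's own members for the LSE signal).
#'
#' @param entries tibble with `genome_id`, `gene_id`; `(genome_id, gene_id)`
#'   must be unique.
#' @param sequences `AAStringSet` parallel to `entries`.
#' @param lineage_map named list: genome_id -> character vector of lineage
#'   labels; every genome in `entries` must be present.
#' @return A `protein_database`.
#' @export
protein_database <- function(entries, sequences, lineage_map) {
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("genome_id", "gene_id") %in% names(entries)))
  if (length(sequences) != nrow(entries))
    stop("sequences and entries differ in length")
  key <- paste(entries$genome_id, entries$gene_id, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (genome_id, gene_id) in database")
  missing_lin <- setdiff(unique(entries$genome_id), names(lineage_map))
  if (length(missing_lin))
    stop("no lineage for genome(s): ", paste(missing_lin, collapse = ", "))
  if (!methods::is(sequences, "AAStringSet"))
    sequences <- Biostrings::AAStringSet(sequences)
  structure(list(entries = entries, sequences = sequences,
                 lineage_map = lineage_map),
            class = "protein_database")
}

#' Build a protein database from a set of genomes and their family hits
#'
#' @param genomes list of [annotated_genome()]s (with lineages set).
#' @param hits_list list of `family_hits`, parallel to `genomes`.
#' @return A [protein_database()] of all family members across genomes.
#' @export
family_database <- function(genomes, hits_list) {
  stopifnot(length(genomes) == length(hits_list))
  entries <- NULL; seqs <- NULL
  lineage_map <- list()
  for (k in seq_along(genomes)) {
    g <- genomes[[k]]
    ids <- family_members(hits_list[[k]])
    if (!length(ids)) { lineage_map[[g$genome_id]] <- g$lineage; next }
    entries <- rbind(entries, tibble::tibble(genome_id = g$genome_id,
                                             gene_id = ids))
    s <- g$proteome[ids]
    seqs <- if (is.null(seqs)) s else Biostrings::AAStringSet(
      c(as.character(seqs), as.character(s)))
    lineage_map[[g$genome_id]] <- g$lineage
  }
  if (is.null(entries)) stop("no family members in any genome")
  protein_database(entries, seqs, lineage_map)
}

#' Read a protein database from per-genome FASTA files and a lineage TSV
#'
#' @param fasta_paths named character vector: genome_id -> protein FASTA of
#'   that genome's family members.
#' @param lineage_file TSV with columns `genome_id` and `lineage`
#'   (comma-separated labels).
#' @return A [protein_database()].
#' @export
read_protein_database <- function(fasta_paths, lineage_file) {
  lin <- utils::read.delim(lineage_file, stringsAsFactors = FALSE)
  lineage_map <- stats::setNames(
    lapply(strsplit(lin$lineage, ","), trimws), lin$genome_id)
  entries <- NULL; seqs <- NULL
  for (gid in names(fasta_paths)) {
    s <- Biostrings::readAAStringSet(fasta_paths[[gid]])
    names(s) <- sub("\\s.*$", "", names(s))
    entries <- rbind(entries, tibble::tibble(genome_id = gid,
                                             gene_id = names(s)))
    seqs <- if (is.null(seqs)) s else Biostrings::AAStringSet(
      c(as.character(seqs), as.character(s)))
  }
  protein_database(entries, seqs, lineage_map)
}

#' Classify family members by their best non-self database hit
#'
#' Each focal family sequence is globally aligned against every database
#' entry except itself; the best hit is the entry with the highest percent
#' identity (ties broken by higher raw alignment score, then lexicographic
#' `(genome_id, gene_id)`). Categories: `self_genome` when the best hit is
#' another member of the focal genome (the lineage-specific expansion
#' signal); `close_lineage` when the best genome's lineage contains
#' `close_group_label`; `distant` otherwise (horizontal transfer
#' candidates). Transfer direction is not inferred.
#'
#' @param family_sequences named `AAStringSet` (or character vector) of the
#'   focal genome's family members.
#' @param database a [protein_database()] containing (at least) the focal
#'   entries and one non-self entry.
#' @param focal_genome_id genome id of the focal genome in the database.
#' @param close_group_label lineage label defining the close group.
#' @param scheme a [scoring_scheme()].
#' @return A `provenance_report`: tibble of assignments plus per-category
#'   counts and fractions (fractions sum to 1).
#' @export
best_hit_classification <- function(family_sequences, database,
                                    focal_genome_id, close_group_label,
                                    scheme = scoring_scheme()) {
  qn <- names(family_sequences)
  if (is.null(qn)) stop("family sequences must be named by gene id")
  if (methods::is(family_sequences, "XStringSet"))
    family_sequences <- as.character(family_sequences)
  ent <- database$entries
  if (nrow(ent) < 2L) stop("database too small after self-exclusion")
  eq <- aa_encode_set(family_sequences, scheme)
  ed <- aa_encode_set(as.character(database$sequences), scheme)
  r <- nw_pid_cpp(eq, ed, scheme$substitution_matrix,
                  scheme$gap_open, scheme$gap_extend)
  pid <- r$pid; score <- r$score

  is_close <- vapply(ent$genome_id, function(g)
    close_group_label %in% database$lineage_map[[g]], logical(1))
  n <- length(qn)
  best_idx <- integer(n)
  for (i in seq_len(n)) {
    self <- ent$genome_id == focal_genome_id & ent$gene_id == qn[i]
    cand <- which(!self)
    if (!length(cand)) stop("database empty after self-exclusion for ", qn[i])
    o <- cand[order(-pid[i, cand], -score[i, cand],
                    ent$genome_id[cand], ent$gene_id[cand])]
    best_idx[i] <- o[1]
  }
  bg <- ent$genome_id[best_idx]
  category <- ifelse(bg == focal_genome_id, "self_genome",
                     ifelse(is_close[best_idx], "close_lineage", "distant"))
  assignments <- tibble::tibble(
    gene_id = qn, best_genome_id = bg,
    best_gene_id = ent$gene_id[best_idx],
    identity = pid[cbind(seq_len(n), best_idx)],
    score = score[cbind(seq_len(n), best_idx)],
    category = category)
  provenance_report(assignments, focal_genome_id, close_group_label)
}

provenance_report <- function(assignments, focal_genome_id,
                              close_group_label) {
  counts <- vapply(c("self_genome", "close_lineage", "distant"),
                   function(k) sum(assignments$category == k), integer(1))
  structure(list(assignments = assignments, counts = counts,
                 fractions = counts / max(1L, sum(counts)),
                 focal_genome_id = focal_genome_id,
                 close_group_label = close_group_label),
            class = "provenance_report")
}

#' Summarise provenance category counts as printed percentages
#'
#' The summary arithmetic used in reports: counts over the family size,
#' rendered at 1 decimal place by default.
#'
#' @param counts named integer vector (categories -> counts).
#' @param digits decimal places for the printed percentage.
#' @return Tibble with `category`, `count`, `fraction` and `percent_label`.
#' @export
provenance_fractions <- function(counts, digits = 1) {
  total <- sum(counts)
  tibble::tibble(
    category = names(counts),
    count = as.integer(counts),
    fraction = counts / total,
    percent_label = format_percent(counts, total, digits))
}

#' @export
print.provenance_report <- function(x, ...) {
  cat(sprintf("<provenance_report> focal %s (close group '%s'), %d members\n",
              x$focal_genome_id, x$close_group_label, sum(x$counts)))
  f <- provenance_fractions(x$counts)
  for (k in seq_len(nrow(f)))
    cat(sprintf("  %-14s %4d (%s %%)\n", f$category[k], f$count[k],
                f$percent_label[k]))
  invisible(x)
}

#' Best-hit geography within a tandem array
#'
#' For each member of an array, reports whether its best hit lies inside
#' the same array, elsewhere in the focal genome, or in another genome.
#' Invariant to member order.
#'
#' @param array an `array_record` from [detect_arrays()].
#' @param report a `provenance_report` covering all array members.
#' @return Tibble with `gene_id`, `best_gene_id`, `best_genome_id`,
#'   `identity` and `location` in
#'   `c("within_array", "same_genome", "other_genome")`.
#' @export
array_best_hit_map <- function(array, report) {
  ids <- array$member_gene_ids
  a <- report$assignments
  miss <- setdiff(ids, a$gene_id)
  if (length(miss))
    stop("array member(s) missing from provenance report: ",
         paste(miss, collapse = ", "))
  a <- a[match(ids, a$gene_id), , drop = FALSE]
  loc <- ifelse(a$best_genome_id != report$focal_genome_id, "other_genome",
                ifelse(a$best_gene_id %in% ids, "within_array",
                       "same_genome"))
  tibble::tibble(gene_id = ids, best_gene_id = a$best_gene_id,
                 best_genome_id = a$best_genome_id,
                 identity = a$identity, location = loc)
}

#' Write provenance assignments as TSV
#' @param report a `provenance_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(report, path) {
  utils::write.table(as.data.frame(report$assignments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
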