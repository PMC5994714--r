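# Family-member census: local-alignment search of a proteome with query
# proteins under a Karlin-Altschul E-value cutoff.

#' Find family members in an annotated genome's proteome
#'
#' Every protein of the genome is aligned locally (Smith-Waterman, affine
#' gaps) against every query; a gene is accepted as a family member iff its
#' minimum E-value over queries is at or below `cutoff` (default 1e-15, the
#' classic stringent homology-census threshold). E-values are per-pair
#' `K * m * n * exp(-lambda * S)`. The best query is the one achieving the
#' minimum E-value, ties broken by higher raw score, then lexicographic
#' query id. The result is invariant to the order of queries and of the
#' proteome.
#'
#' @param queries named character vector or `AAStringSet` of query proteins
#'   (at least one).
#' @param genome an [annotated_genome()] with a non-empty proteome, or an
#'   `AAStringSet` to search directly.
#' @param scheme a [scoring_scheme()].
#' @param cutoff E-value threshold; hits with `evalue <= cutoff` are kept.
#' @return A `family_hits` object: tibble of accepted hits (`gene_id`,
#'   `best_query_id`, `score`, `evalue`) plus `genome_id` and `cutoff`
#'   fields.
#' @export
find_family_members <- function(queries, genome, scheme = scoring_scheme(),
                                cutoff = 1e-15) {
  if (length(queries) == 0L) stop("need at least one query sequence")
  if (inherits(genome, "annotated_genome")) {
    proteome <- genome$proteome
    genome_id <- genome$genome_id
  } else {
    proteome <- genome
    genome_id <- "proteome"
  }
  if (methods::is(queries, "XStringSet")) queries <- as.character(queries)
  if (methods::is(proteome, "XStringSet")) proteome <- as.character(proteome)
  if (length(proteome) == 0L) stop("proteome is empty")
  qn <- names(queries) %||% paste0("query", seq_along(queries))
  gn <- names(proteome)
  if (is.null(gn)) stop("proteome sequences must be named by gene id")

  # canonical order for determinism regardless of input order
  qo <- order(qn); queries <- queries[qo]; qn <- qn[qo]
  go <- order(gn); proteome <- proteome[go]; gn <- gn[go]

  eq <- aa_encode_set(queries, scheme)
  eg <- aa_encode_set(proteome, scheme)
  scores <- sw_scores_cpp(eq, eg, scheme$substitution_matrix,
                          scheme$gap_open, scheme$gap_extend)
  qlen <- nchar(queries); glen <- nchar(proteome)
  ev <- scheme$K * outer(qlen, glen) * exp(-scheme$lambda * scores)

  hits <- lapply(seq_along(gn), function(j) {
    e <- ev[, j]; s <- scores[, j]
    best <- order(e, -s, qn)[1]
    if (e[best] <= cutoff)
      tibble::tibble(gene_id = gn[j], best_query_id = qn[best],
                     score = s[best], evalue = e[best])
    else NULL
  })
  hits <- do.call(rbind, c(hits, list(NULL)))
  if (is.null(hits))
    hits <- tibble::tibble(gene_id = character(), best_query_id = character(),
                           score = integer(), evalue = numeric())
  structure(list(genome_id = genome_id, hits = hits, cutoff = cutoff),
            class = "family_hits")
}

#' @export
print.family_hits <- function(x, ...) {
  cat(sprintf("<family_hits> %s: %d member(s) at E <= %g\n",
              x$genome_id, nrow(x$hits), x$cutoff))
  invisible(x)
}

#' Gene ids of accepted family members
#' @param hits a `family_hits` object.
#' @return Character vector of member gene ids.
#' @export
family_members <- function(hits) hits$hits$gene_id

#' Write a family hit table as TSV
#' @param hits a `family_hits` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_family_hits <- function(hits, path) {
  utils::write.table(as.data.frame(hits$hits), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
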