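# Tandem-array census: runs of consecutive family genes in gene order.

#' Detect tandem arrays of family genes
#'
#' Two family genes belong to the same array iff at most `max_intervening`
#' non-family genes separate them in gene order on the same contig (default
#' 0: strictly adjacent). Strand is ignored; on a circular contig the gene
#' order ring is closed, so an array may wrap past the origin. Every family
#' gene belongs to exactly one array (a partition).
#'
#' @param family a `family_hits` object or character vector of gene ids.
#' @param genome an [annotated_genome()].
#' @param max_intervening maximum number of intervening non-family genes.
#' @return List of `array_record`s, each with `member_gene_ids` (in gene
#'   order), `contig_id` and `size`.
#' @export
detect_arrays <- function(family, genome, max_intervening = 0L) {
  ids <- if (inherits(family, "family_hits")) family_members(family)
  else as.character(family)
  out <- list()
  for (ctg in unique(genome$genes$contig_id)) {
    g <- genome$genes[genome$genes$contig_id == ctg, , drop = FALSE]
    g <- g[order(g$order_index), , drop = FALSE]
    fam_pos <- which(g$gene_id %in% ids)
    if (!length(fam_pos)) next
    # group consecutive family positions whose rank gap leaves at most
    # max_intervening non-family genes between them
    grp <- cumsum(c(1L, diff(fam_pos) > max_intervening + 1L))
    groups <- split(fam_pos, grp)
    circ <- isTRUE(genome$circular[[ctg]])
    if (circ && length(groups) > 1L) {
      n <- nrow(g)
      first <- groups[[1]]; last <- groups[[length(groups)]]
      wrap_gap <- (first[1] + n) - last[length(last)]
      if (wrap_gap <= max_intervening + 1L) {
        groups[[1]] <- c(last, first)
        groups[[length(groups)]] <- NULL
      }
    }
    for (gp in groups) {
      out[[length(out) + 1L]] <- structure(
        list(member_gene_ids = g$gene_id[gp], contig_id = ctg,
             size = length(gp)),
        class = "array_record")
    }
  }
  out
}

#' Build an array-size frequency table
#'
#' @param arrays list of `array_record`s from [detect_arrays()], or a named
#'   integer vector of size -> count (e.g. a published table column).
#' @return An `array_table`: named integer vector of counts indexed by array
#'   size, with the implied family size as attribute.
#' @export
array_frequency_table <- function(arrays) {
  if (is.numeric(arrays)) {
    counts <- arrays
    if (is.null(names(counts))) stop("counts vector must be named by size")
  } else {
    sizes <- vapply(arrays, function(a) a$size, integer(1))
    counts <- if (length(sizes)) table(sizes) else
      table(integer(0))
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  counts <- counts[order(as.integer(names(counts)))]
  storage.mode(counts) <- "integer"
  structure(counts, class = "array_table",
            family_size = sum(as.integer(names(counts)) * counts))
}

#' Family size implied by an array table
#'
#' Sum over sizes of `size * count`; equals the number of family genes when
#' the table came from a full partition.
#'
#' @param x an `array_table`.
#' @return Integer family size.
#' @export
family_size <- function(x) {
  stopifnot(inherits(x, "array_table"))
  attr(x, "family_size")
}

#' @export
print.array_table <- function(x, ...) {
  cat("<array_table> size -> count\n")
  for (k in seq_along(x))
    cat(sprintf("  %s\t%d\n", names(x)[k], x[[k]]))
  cat(sprintf("  family size %d in %d array(s)\n", family_size(x),
              sum(unclass(x))))
  invisible(x)
}

#' Write one or more array tables as a TSV
#'
#' Mirrors a published per-genome table: one row per array size, one column
#' per genome.
#'
#' @param tables named list of `array_table`s (names are genome labels).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_array_tables <- function(tables, path) {
  sizes <- sort(unique(as.integer(unlist(lapply(tables, names)))))
  df <- data.frame(array_size = sizes)
  for (nm in names(tables)) {
    v <- stats::setNames(rep(0L, length(sizes)), sizes)
    v[names(tables[[nm]])] <- unclass(tables[[nm]])
    df[[nm]] <- as.integer(v)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
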