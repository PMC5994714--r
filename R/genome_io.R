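# Reading, validating and writing annotated genomes and interval tracks.
#
# Internal coordinate convention: 0-based half-open everywhere. GFF3 and
# GenBank are 1-based inclusive and are converted at the format boundary;
# BED and bedGraph are already 0-based half-open and pass through untouched.

#' Default keyword map for deriving functional tags from product labels
#'
#' The census of regulatory neighbours needs a notion of e.g. "transcription
#' factor" genes; annotations encode this only in free-text product labels,
#' so tags are derived by case-insensitive keyword match. The map is
#' configurable (any named list of character keyword vectors, or a YAML file
#' with the same structure).
#'
#' @return Named list mapping tag name to keyword vector.
#' @export
default_tag_map <- function() {
  list(
    transcription_factor = c("transcription factor", "transcriptional regulator",
                             "dna-binding response regulator"),
    histidine_kinase = c("histidine kinase", "sensor kinase"),
    ABC_component = c("abc transporter"),
    TRAP_component = c("trap transporter"),
    flagellar = c("flagell")
  )
}

derive_tags <- function(products, tag_map = default_tag_map()) {
  low <- tolower(products)
  lapply(low, function(p) {
    hit <- vapply(tag_map, function(kws) any(vapply(
      kws, function(k) grepl(k, p, fixed = TRUE), logical(1))), logical(1))
    names(tag_map)[hit]
  })
}

#' Construct an annotated genome
#'
#' The container every analysis stage consumes: contig nucleotide sequences,
#' an ordered gene table, the proteome, a lineage label path and per-contig
#' circularity.
#'
#' @param genome_id single string.
#' @param contigs `DNAStringSet` named by contig id.
#' @param genes data frame with columns `gene_id`, `contig_id`, `start`,
#'   `end` (0-based half-open), `strand` ("+"/"-"), `product`. Sorted and
#'   given `order_index` (0-based rank by start within contig) on
#'   construction; a `functional_tags` list-column is derived from `product`
#'   via `tag_map` if absent.
#' @param proteome `AAStringSet` named by gene id (subset of `genes$gene_id`).
#' @param lineage ordered character vector of taxon labels, most inclusive
#'   first.
#' @param circular logical, recycled over contigs (named or unnamed).
#' @param tag_map keyword map, see [default_tag_map()].
#' @return Object of class `annotated_genome`.
#' @export
annotated_genome <- function(genome_id, contigs, genes, proteome,
                             lineage = character(), circular = TRUE,
                             tag_map = default_tag_map()) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  if (!methods::is(contigs, "DNAStringSet"))
    contigs <- Biostrings::DNAStringSet(contigs)
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contigs must have unique names")
  genes <- tibble::as_tibble(genes)
  req <- c("gene_id", "contig_id", "start", "end", "strand", "product")
  miss <- setdiff(req, names(genes))
  if (length(miss)) stop("genes table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in genes table")
  if (!all(genes$contig_id %in% names(contigs)))
    stop("gene contig_id not found among contigs")
  clen <- stats::setNames(Biostrings::width(contigs), names(contigs))
  bad <- genes$start < 0 | genes$start >= genes$end |
    genes$end > clen[genes$contig_id]
  if (any(bad))
    stop("gene coordinates out of bounds for: ",
         paste(utils::head(genes$gene_id[bad], 5), collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  genes <- genes[order(genes$contig_id, genes$start), , drop = FALSE]
  genes$order_index <- stats::ave(genes$start, genes$contig_id,
                                  FUN = seq_along) - 1L
  genes$order_index <- as.integer(genes$order_index)
  if (!"functional_tags" %in% names(genes))
    genes$functional_tags <- derive_tags(genes$product, tag_map)
  if (!methods::is(proteome, "AAStringSet"))
    proteome <- Biostrings::AAStringSet(proteome)
  if (length(proteome) && !all(names(proteome) %in% genes$gene_id))
    stop("proteome contains ids absent from the gene table")
  circ <- rep_len(as.logical(circular), length(contigs))
  names(circ) <- names(contigs)
  structure(list(genome_id = genome_id, contigs = contigs, genes = genes,
                 proteome = proteome, lineage = as.character(lineage),
                 circular = circ),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf(
    "<annotated_genome> %s: %d contig(s), %s bp, %d genes, %d proteins%s\n",
    x$genome_id, length(x$contigs),
    format(sum(Biostrings::width(x$contigs)), big.mark = ","),
    nrow(x$genes), length(x$proteome),
    if (length(x$lineage)) paste0(" [", paste(x$lineage, collapse = " > "), "]")
    else ""))
  invisible(x)
}

#' Total genome length in bases
#' @param genome an `annotated_genome`.
#' @return Integer total contig length.
#' @export
genome_length <- function(genome) sum(Biostrings::width(genome$contigs))

gff3_unescape <- function(x) {
  x <- gsub("%3B", ";", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%26", "&", x, fixed = TRUE)
  gsub("%2C", ",", x, fixed = TRUE)
}

#' Read an annotated genome from GFF3 (+ FASTA) or a GenBank flat file
#'
#' CDS features become genes; coordinates are converted from the 1-based
#' inclusive source convention to the internal 0-based half-open one. The
#' proteome is taken from `translation` attributes when present and
#' otherwise computed from the CDS nucleotide sequence under the bacterial
#' genetic code (table 11), with the trailing stop trimmed. CDS whose length
#' is not a multiple of three (and that carry no translation) are skipped
#' with a warning; the number skipped is reported in attribute
#' `n_skipped_cds`.
#'
#' @param annotation path to a GFF3 or GenBank flat file.
#' @param sequences optional path to the genome FASTA (required for GFF3
#'   files without embedded sequence; ignored for GenBank, which embeds it).
#' @param format `"auto"` (by extension/content), `"gff3"` or `"genbank"`.
#' @param genome_id identifier; defaults to the annotation file stem.
#' @param lineage,circular,tag_map passed to [annotated_genome()].
#' @return An `annotated_genome`.
#' @export
read_annotated_genome <- function(annotation, sequences = NULL,
                                  format = c("auto", "gff3", "genbank"),
                                  genome_id = NULL, lineage = character(),
                                  circular = TRUE,
                                  tag_map = default_tag_map()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|gbff|genbank)$", annotation,
                        ignore.case = TRUE)) "genbank" else "gff3"
  }
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(annotation))
  if (format == "genbank") {
    parsed <- parse_genbank(annotation)
  } else {
    parsed <- parse_gff3_cds(annotation, sequences)
  }
  contigs <- parsed$contigs
  feats <- parsed$features
  if (nrow(feats) == 0L) stop("no CDS features found in ", annotation)

  # translations: use provided ones, compute the rest
  prot <- feats$translation
  need <- is.na(prot)
  skipped <- logical(nrow(feats))
  if (any(need)) {
    for (k in which(need)) {
      len <- feats$end[k] - feats$start[k]
      if (len %% 3L != 0L) {
        warning(sprintf("CDS %s length %d not divisible by 3; skipped",
                        feats$gene_id[k], len))
        skipped[k] <- TRUE
        next
      }
      dna <- Biostrings::subseq(contigs[[feats$contig_id[k]]],
                                start = feats$start[k] + 1L,
                                end = feats$end[k])
      if (feats$strand[k] == "-") dna <- Biostrings::reverseComplement(dna)
      aa <- as.character(Biostrings::translate(
        dna, genetic.code = Biostrings::getGeneticCode("11"),
        if.fuzzy.codon = "solve"))
      prot[k] <- sub("\\*$", "", aa)
    }
  }
  keep <- !skipped
  genes <- tibble::tibble(gene_id = feats$gene_id[keep],
                          contig_id = feats$contig_id[keep],
                          start = feats$start[keep], end = feats$end[keep],
                          strand = feats$strand[keep],
                          product = feats$product[keep])
  prot <- prot[keep]
  has_prot <- !is.na(prot) & nzchar(prot)
  proteome <- Biostrings::AAStringSet(prot[has_prot])
  names(proteome) <- genes$gene_id[has_prot]
  g <- annotated_genome(genome_id, contigs, genes, proteome,
                        lineage = lineage, circular = circular,
                        tag_map = tag_map)
  attr(g, "n_skipped_cds") <- sum(skipped)
  g
}

parse_gff3_cds <- function(annotation, sequences) {
  gr <- tryCatch(rtracklayer::import(annotation, format = "gff3"),
                 error = function(e)
                   stop("malformed GFF3 in ", annotation, ": ",
                        conditionMessage(e)))
  if (is.null(sequences))
    stop("GFF3 input requires a genome FASTA via `sequences`")
  contigs <- Biostrings::readDNAStringSet(sequences)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  mc <- S4Vectors::mcols(gr)
  pick <- function(col, default) {
    if (col %in% names(mc)) {
      v <- as.character(mc[[col]])
      ifelse(is.na(v) | !nzchar(v), default, v)
    } else rep(default, length(gr))
  }
  ids <- pick("ID", NA_character_)
  lt <- pick("locus_tag", NA_character_)
  ids <- ifelse(is.na(ids), lt, ids)
  if (anyNA(ids))
    stop("GFF3 CDS features without ID or locus_tag in ", annotation)
  tibble_out <- tibble::tibble(
    gene_id = ids,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    product = gff3_unescape(pick("product", "hypothetical protein")),
    translation = pick("translation", NA_character_))
  list(contigs = contigs, features = tibble_out)
}

# Minimal GenBank flat-file reader for bacterial records: LOCUS /
# FEATURES CDS (plain and complement() locations) with locus_tag, product
# and translation qualifiers / ORIGIN sequence. join() locations are
# rejected (no multi-exon models).
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("not a GenBank flat file (no LOCUS): ", path)
  ends <- c(locus_i[-1] - 1L, length(lines))
  contigs <- character(0)
  feats <- list()
  for (r in seq_along(locus_i)) {
    block <- lines[locus_i[r]:ends[r]]
    locus <- strsplit(trimws(block[1]), "\\s+")[[1]]
    contig_id <- locus[2]
    ori <- grep("^ORIGIN", block)
    if (!length(ori)) stop("GenBank record ", contig_id, " has no ORIGIN")
    seq_lines <- block[(ori[1] + 1L):length(block)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    seqchr <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
    contigs[contig_id] <- seqchr
    fstart <- grep("^FEATURES", block)
    if (!length(fstart)) next
    fblock <- block[(fstart[1] + 1L):(ori[1] - 1L)]
    # feature lines start at col 6; qualifier/continuation lines at col 22
    is_feat <- grepl("^ {5}\\S", fblock)
    idx <- which(is_feat)
    for (k in seq_along(idx)) {
      hdr <- fblock[idx[k]]
      key <- sub("^ +(\\S+).*$", "\\1", hdr)
      if (key != "CDS") next
      last <- if (k < length(idx)) idx[k + 1] - 1L else length(fblock)
      body <- fblock[idx[k]:last]
      loc <- sub("^ +\\S+ +", "", body[1])
      qstart <- grep("^ +/", body)
      if (length(qstart) && qstart[1] > 2)
        loc <- paste0(loc, paste(trimws(body[2:(qstart[1] - 1)]),
                                 collapse = ""))
      strand <- "+"
      if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
      }
      if (grepl("join|order", loc))
        stop("multi-segment CDS locations are not supported (", loc, ")")
      nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
      if (length(nums) != 2)
        stop("cannot parse CDS location '", loc, "' in ", contig_id)
      qual <- parse_gb_qualifiers(body[grep("^ +/", body)[1]:length(body)])
      feats[[length(feats) + 1L]] <- tibble::tibble(
        gene_id = qual[["locus_tag"]] %||% qual[["gene"]] %||%
          sprintf("%s_cds%04d", contig_id, k),
        contig_id = contig_id,
        start = as.integer(nums[1]) - 1L,
        end = as.integer(nums[2]),
        strand = strand,
        product = qual[["product"]] %||% "hypothetical protein",
        translation = qual[["translation"]] %||% NA_character_)
    }
  }
  list(contigs = Biostrings::DNAStringSet(contigs),
       features = if (length(feats)) do.call(rbind, feats)
       else tibble::tibble(gene_id = character(), contig_id = character(),
                           start = integer(), end = integer(),
                           strand = character(), product = character(),
                           translation = character()))
}

parse_gb_qualifiers <- function(qlines) {
  txt <- paste(trimws(qlines), collapse = "\n")
  # continuation lines belong to the previous qualifier
  parts <- strsplit(txt, "\n/", fixed = TRUE)[[1]]
  parts[1] <- sub("^/", "", parts[1])
  out <- list()
  for (p in parts) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0) { out[[p]] <- TRUE; next }
    key <- substr(p, 1, eq - 1)
    val <- substr(p, eq + 1, nchar(p))
    val <- gsub('"', "", val)
    if (key == "translation") val <- gsub("\\s", "", val)
    else val <- gsub("\n", " ", val)
    out[[key]] <- val
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

intervals_to_table <- function(intervals) {
  if (inherits(intervals, "island_set")) return(intervals$intervals)
  if (inherits(intervals, "window_track"))
    return(tibble::tibble(contig_id = intervals$contig_id,
                          start = intervals$windows$start,
                          end = intervals$windows$end,
                          value = intervals$windows$value))
  tibble::as_tibble(intervals)
}

#' Write intervals or a window track as BED / bedGraph
#'
#' BED output is 3-column (contig, start, end); bedGraph adds the value
#' column formatted to 4 decimals. Both formats are 0-based half-open, i.e.
#' the internal convention, so no coordinate conversion happens. Rows are
#' sorted by contig then start; an empty input writes a single header
#' comment so the file is self-describing.
#'
#' @param intervals an `island_set`, a `window_track`, or a data frame with
#'   `contig_id`, `start`, `end` (and `value` for bedGraph).
#' @param path output file path.
#' @param format `"bed"` or `"bedGraph"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path, format = c("bed", "bedGraph")) {
  format <- match.arg(format)
  tab <- intervals_to_table(intervals)
  if (format == "bedGraph" && !"value" %in% names(tab))
    stop("bedGraph output requires a 'value' column")
  if (nrow(tab) == 0L) {
    writeLines(sprintf("# famexscan empty %s track", format), path)
    return(invisible(path))
  }
  tab <- tab[order(tab$contig_id, tab$start), , drop = FALSE]
  lines <- if (format == "bed") {
    sprintf("%s\t%d\t%d", tab$contig_id, tab$start, tab$end)
  } else {
    keep <- if ("defined" %in% names(tab)) tab$defined else
      !is.na(tab$value)
    tab <- tab[keep, , drop = FALSE]
    sprintf("%s\t%d\t%d\t%.4f", tab$contig_id, tab$start, tab$end, tab$value)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED or bedGraph file written by [write_intervals()]
#'
#' @param path file path.
#' @return Tibble with `contig_id`, `start`, `end` (and `value` for
#'   bedGraph); zero rows for an empty track.
#' @export
read_intervals <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(tibble::tibble(contig_id = character(), start = integer(),
                          end = integer()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- length(parts[[1]])
  out <- tibble::tibble(
    contig_id = vapply(parts, `[[`, "", 1),
    start = as.integer(vapply(parts, `[[`, "", 2)),
    end = as.integer(vapply(parts, `[[`, "", 3)))
  if (ncol >= 4) out$value <- as.numeric(vapply(parts, `[[`, "", 4))
  out
}
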