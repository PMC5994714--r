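# User-facing pairwise alignment operations (the engine lives in src/).

as_single_aa <- function(x) {
  if (methods::is(x, "XString") || methods::is(x, "XStringSet"))
    x <- as.character(x)
  if (length(x) != 1L) stop("expected a single sequence")
  unname(x)
}

#' Optimal local (Smith-Waterman) alignment of two protein sequences
#'
#' Exact affine-gap local alignment. A gap of length k costs
#' `gap_open + k * gap_extend`; gaps in the two sequences may abut. The
#' traceback is deterministic (diagonal preferred over a gap in the subject,
#' preferred over a gap in the query; the maximal cell earliest in row-major
#' order wins ties), and the E-value is the per-pair Karlin-Altschul
#' statistic `K * m * n * exp(-lambda * S)`.
#'
#' @param a,b amino-acid sequences (character or Biostrings `AAString`).
#' @param scheme a [scoring_scheme()].
#' @return An `alignment_result`: list with `score`, `query_span` and
#'   `subject_span` (0-based half-open residue intervals), `identities`,
#'   `alignment_length` and `evalue`.
#' @examples
#' local_align("MKV", "MKV")$score  # 14 under BLOSUM62
#' @export
local_align <- function(a, b, scheme = scoring_scheme()) {
  a <- as_single_aa(a); b <- as_single_aa(b)
  ea <- aa_encode(a, scheme); eb <- aa_encode(b, scheme)
  r <- align_pair_cpp(ea, eb, scheme$substitution_matrix,
                      scheme$gap_open, scheme$gap_extend, TRUE)
  structure(list(
    score = r$score,
    query_span = c(start = r$q_start, end = r$q_end),
    subject_span = c(start = r$s_start, end = r$s_end),
    identities = r$identities,
    alignment_length = r$columns,
    evalue = karlin_altschul_evalue(r$score, nchar(a), nchar(b), scheme)
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> score %d, %d/%d identities, E = %.3g, query [%d,%d) subject [%d,%d)\n",
    x$score, x$identities, x$alignment_length, x$evalue,
    x$query_span[["start"]], x$query_span[["end"]],
    x$subject_span[["start"]], x$subject_span[["end"]]))
  invisible(x)
}

#' Global percent identity between two protein sequences
#'
#' End-to-end (Needleman-Wunsch) alignment under the same affine-gap scheme
#' as [local_align()], with terminal gaps penalised. Identity is
#' `100 * identical columns / alignment columns`, gap columns counting in
#' the denominator, so the statistic is symmetric in its arguments.
#'
#' @inheritParams local_align
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(a, b, scheme = scoring_scheme()) {
  a <- as_single_aa(a); b <- as_single_aa(b)
  ea <- aa_encode(a, scheme); eb <- aa_encode(b, scheme)
  r <- align_pair_cpp(ea, eb, scheme$substitution_matrix,
                      scheme$gap_open, scheme$gap_extend, FALSE)
  if (r$columns == 0) return(0)
  100 * r$identities / r$columns
}

#' Global alignment details (score, identities, columns)
#'
#' Lower-level companion to [percent_identity()] exposing the raw global
#' score used as a tie-break in best-hit ranking.
#'
#' @inheritParams local_align
#' @return List with `score`, `identities`, `columns`, `pid`.
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  a <- as_single_aa(a); b <- as_single_aa(b)
  ea <- aa_encode(a, scheme); eb <- aa_encode(b, scheme)
  r <- align_pair_cpp(ea, eb, scheme$substitution_matrix,
                      scheme$gap_open, scheme$gap_extend, FALSE)
  list(score = r$score, identities = r$identities, columns = r$columns,
       pid = if (r$columns > 0) 100 * r$identities / r$columns else 0)
}

#' Pairwise percent-identity matrix for a set of family members
#'
#' @param members named character vector or `AAStringSet` of at least two
#'   amino-acid sequences.
#' @param scheme a [scoring_scheme()].
#' @return Symmetric numeric matrix of percent identities with 100 on the
#'   diagonal, dimnames taken from the member names.
#' @export
similarity_matrix <- function(members, scheme = scoring_scheme()) {
  nms <- names(members)
  if (methods::is(members, "XStringSet")) members <- as.character(members)
  if (length(members) < 2L) stop("need at least 2 members")
  if (is.null(nms)) nms <- paste0("seq", seq_along(members))
  enc <- aa_encode_set(members, scheme)
  r <- nw_pid_cpp(enc, enc, scheme$substitution_matrix,
                  scheme$gap_open, scheme$gap_extend)
  m <- r$pid
  # enforce exact symmetry / diagonal (floating identity is already exact,
  # this guards the container contract)
  m <- (m + t(m)) / 2
  diag(m) <- 100
  dimnames(m) <- list(nms, nms)
  m
}
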