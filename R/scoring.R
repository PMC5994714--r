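# Scoring schemes and amino-acid encoding for the alignment engine.

# Alphabet the substitution matrix is indexed by. The 20 standard residues
# come first; B/Z/X are accepted and scored 0 against everything (ambiguity
# codes carry no evidence). J, U and O are remapped to X on encoding.
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X")

#' Default BLOSUM62 substitution matrix
#'
#' The 20 standard amino acids use the classic BLOSUM62 entries (as shipped
#' with Biostrings); the ambiguity codes B, Z and X score 0 against every
#' residue including themselves.
#'
#' @return An integer matrix with dimnames over the supported alphabet.
#' @export
blosum62_matrix <- function() {
  if (!is.null(.famex_cache$blosum62)) return(.famex_cache$blosum62)
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  b <- env$BLOSUM62
  std <- AA_ORDER[1:20]
  m <- matrix(0L, nrow = length(AA_ORDER), ncol = length(AA_ORDER),
              dimnames = list(AA_ORDER, AA_ORDER))
  m[std, std] <- b[std, std]
  storage.mode(m) <- "integer"
  .famex_cache$blosum62 <- m
  m
}

#' Construct an alignment scoring scheme
#'
#' Bundles a symmetric substitution matrix, affine gap penalties (a gap of
#' length k costs `gap_open + k * gap_extend`, so a single-residue gap costs
#' `gap_open + gap_extend`) and the Karlin-Altschul parameters `lambda` and
#' `K` used to turn raw local scores into E-values. The defaults are
#' BLOSUM62 with gap open 11 / extend 1 and the standard gapped parameters
#' lambda = 0.267, K = 0.041 for that combination. E-values here use the
#' per-pair search space m * n without database-size or edge corrections, so
#' they are a per-comparison statistic rather than a BLAST database E-value.
#'
#' @param substitution_matrix symmetric integer matrix with residue dimnames;
#'   default [blosum62_matrix()].
#' @param gap_open,gap_extend positive integer penalties; `gap_extend` must
#'   not exceed `gap_open`.
#' @param lambda,K positive Karlin-Altschul parameters matching the
#'   matrix/gap combination.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(substitution_matrix = NULL, gap_open = 11L,
                           gap_extend = 1L, lambda = 0.267, K = 0.041) {
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62_matrix()
  m <- substitution_matrix
  if (is.null(dimnames(m)) || !identical(rownames(m), colnames(m)))
    stop("substitution matrix must have identical row and column names")
  if (!isTRUE(all.equal(m, t(m))))
    stop("substitution matrix must be symmetric")
  storage.mode(m) <- "integer"
  gap_open <- as.integer(gap_open)
  gap_extend <- as.integer(gap_extend)
  if (gap_open <= 0L || gap_extend <= 0L)
    stop("gap penalties must be positive")
  if (gap_extend > gap_open)
    stop("gap_extend must not exceed gap_open")
  if (!(lambda > 0) || !(K > 0))
    stop("lambda and K must be positive")
  structure(list(substitution_matrix = m, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "<scoring_scheme> %d-letter matrix, gap open %d / extend %d, lambda %.3f, K %.3f\n",
    nrow(x$substitution_matrix), x$gap_open, x$gap_extend, x$lambda, x$K))
  invisible(x)
}

# Encode an amino-acid string as 0-based indices into the scheme's matrix.
# Case-insensitive; J/U/O collapse to X; anything else errors with the
# offending position.
aa_encode <- function(x, scheme) {
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    stop("sequence must be a single non-empty string")
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  chars[chars %in% c("J", "U", "O")] <- "X"
  idx <- match(chars, rownames(scheme$substitution_matrix))
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1]
    stop(sprintf("invalid amino-acid residue '%s' at position %d",
                 chars[p], p))
  }
  idx - 1L
}

aa_encode_set <- function(seqs, scheme) {
  if (methods::is(seqs, "AAStringSet") || methods::is(seqs, "XStringSet"))
    seqs <- as.character(seqs)
  lapply(unname(as.character(seqs)), aa_encode, scheme = scheme)
}

#' Karlin-Altschul E-value for a raw local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with `m`, `n` the lengths of the two
#' sequences compared. Strictly decreasing in the score at fixed lengths.
#'
#' @param score raw alignment score (vectorised).
#' @param m,n sequence lengths.
#' @param scheme a [scoring_scheme()].
#' @return Numeric E-value(s), >= 0.
#' @export
karlin_altschul_evalue <- function(score, m, n, scheme = scoring_scheme()) {
  if (any(m <= 0) || any(n <= 0)) stop("sequence lengths must be positive")
  scheme$K * m * n * exp(-scheme$lambda * score)
}
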