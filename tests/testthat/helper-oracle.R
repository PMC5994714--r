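# Independent oracles, deliberately written with different algorithms from
# the package implementation.

# Cubic ("jump") alignment score oracle: a gap of length k costs
# open + k * extend and is taken in one move, so any gap arrangement
# (including abutting insertions and deletions) is reachable.
oracle_align_score <- function(a, b, scheme, local = TRUE) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  S <- scheme$substitution_matrix
  go <- scheme$gap_open; ge <- scheme$gap_extend
  n <- length(A); m <- length(B)
  H <- matrix(-Inf, n + 1, m + 1)
  H[1, 1] <- 0
  for (i in 0:n) {
    for (j in 0:m) {
      if (i == 0 && j == 0) next
      best <- if (local) 0 else -Inf
      if (i > 0 && j > 0)
        best <- max(best, H[i, j] + S[A[i], B[j]])
      if (i > 0)
        for (k in 1:i) best <- max(best, H[i - k + 1, j + 1] - go - k * ge)
      if (j > 0)
        for (k in 1:j) best <- max(best, H[i + 1, j - k + 1] - go - k * ge)
      H[i + 1, j + 1] <- best
    }
  }
  if (local) max(H) else H[n + 1, m + 1]
}

# Affine global alignment with explicit matrices and traceback, mirroring
# the documented tie-break rules (state preference M > X > Y everywhere),
# written independently in plain R. Returns the traceback column classes.
oracle_global_pid <- function(a, b, scheme) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  S <- scheme$substitution_matrix
  go <- scheme$gap_open; ge <- scheme$gap_extend
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  tM <- tX <- tY <- matrix(3L, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 1:n) { X[i + 1, 1] <- -(go + i * ge); tX[i + 1, 1] <- if (i == 1) 0L else 1L }
  for (j in 1:m) { Y[1, j + 1] <- -(go + j * ge); tY[1, j + 1] <- if (j == 1) 0L else 2L }
  pick <- function(vm, vx, vy) {     # preference M > X > Y on ties
    v <- max(vm, vx, vy)
    st <- if (v == vm) 0L else if (v == vx) 1L else 2L
    list(v = v, st = st)
  }
  for (i in 1:n) for (j in 1:m) {
    d <- pick(M[i, j], X[i, j], Y[i, j])
    M[i + 1, j + 1] <- d$v + S[A[i], B[j]]; tM[i + 1, j + 1] <- d$st
    u <- pick(M[i, j + 1] - go - ge, X[i, j + 1] - ge,
              Y[i, j + 1] - go - ge)
    X[i + 1, j + 1] <- u$v; tX[i + 1, j + 1] <- u$st
    l <- pick(M[i + 1, j] - go - ge, X[i + 1, j] - go - ge,
              Y[i + 1, j] - ge)
    Y[i + 1, j + 1] <- l$v; tY[i + 1, j + 1] <- l$st
  }
  fin <- pick(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  i <- n; j <- m; st <- fin$st
  ident <- 0L; cols <- 0L
  while (i > 0 || j > 0) {
    if (st == 0L) {
      cols <- cols + 1L
      if (A[i] == B[j]) ident <- ident + 1L
      st <- tM[i + 1, j + 1]; i <- i - 1; j <- j - 1
    } else if (st == 1L) {
      cols <- cols + 1L
      st <- tX[i + 1, j + 1]; i <- i - 1
    } else {
      cols <- cols + 1L
      st <- tY[i + 1, j + 1]; j <- j - 1
    }
  }
  list(score = fin$v, identities = ident, columns = cols,
       pid = 100 * ident / cols)
}

# Run-length tandem-array oracle over flags in gene order.
oracle_array_sizes <- function(is_family, circular, max_intervening = 0L) {
  n <- length(is_family)
  pos <- which(is_family)
  if (!length(pos)) return(integer(0))
  groups <- list(pos[1])
  if (length(pos) > 1) for (k in 2:length(pos)) {
    gap <- pos[k] - pos[k - 1] - 1L
    if (gap <= max_intervening)
      groups[[length(groups)]] <- c(groups[[length(groups)]], pos[k])
    else groups[[length(groups) + 1L]] <- pos[k]
  }
  if (circular && length(groups) > 1) {
    first <- groups[[1]]; last <- groups[[length(groups)]]
    wrap_gap <- (first[1] + n) - last[length(last)] - 1L
    if (wrap_gap <= max_intervening) {
      groups[[1]] <- c(last, first)
      groups[[length(groups)]] <- NULL
    }
  }
  sort(vapply(groups, length, integer(1)))
}

# Naive sliding-window base counter.
oracle_window_gc <- function(seq_chr, start0, window, circular) {
  chars <- strsplit(seq_chr, "", fixed = TRUE)[[1]]
  L <- length(chars)
  idx <- ((start0 + seq_len(window) - 1L) %% L) + 1L
  if (!circular && start0 + window > L) stop("window out of bounds")
  w <- chars[idx]
  g <- sum(w == "G"); c <- sum(w == "C")
  acgt <- sum(w %in% c("A", "C", "G", "T"))
  list(gc = if (acgt > 0) (g + c) / acgt else NA_real_,
       skew = if (g + c > 0) (g - c) / (g + c) else NA_real_)
}

random_aa_string <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
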