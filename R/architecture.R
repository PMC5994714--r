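# Genome architecture: sliding-window GC statistics, replication landmarks
# from cumulative GC skew, low-GC island calling and family gene density
# contrasts.

window_starts <- function(len, window, step, circular) {
  if (window < 1 || step < 1) stop("window_size and step must be >= 1")
  if (circular) {
    seq.int(0L, len - 1L, by = step)
  } else {
    if (len < window)
      stop("contig shorter than window_size on a linear contig")
    seq.int(0L, len - window, by = step)
  }
}

window_base_counts <- function(contig, window, step, circular) {
  if (methods::is(contig, "DNAStringSet")) contig <- contig[[1]]
  if (!methods::is(contig, "DNAString"))
    contig <- Biostrings::DNAString(toupper(as.character(contig)))
  len <- length(contig)
  starts0 <- window_starts(len, window, step, circular)
  s <- contig
  if (circular && window > 1L)
    s <- Biostrings::xscat(contig, Biostrings::subseq(contig, 1L,
                                                      min(window - 1L, len)))
  v <- Biostrings::Views(s, start = starts0 + 1L, width = window)
  counts <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
  list(starts = starts0, counts = counts, len = len)
}

new_window_track <- function(contig_id, window, step, statistic, starts,
                             value, defined, contig_length) {
  structure(list(
    contig_id = contig_id, window_size = as.integer(window),
    step = as.integer(step), statistic = statistic,
    contig_length = as.integer(contig_length),
    windows = tibble::tibble(start = as.integer(starts),
                             end = as.integer(starts + window),
                             value = unname(as.numeric(value)),
                             defined = unname(as.logical(defined)))),
    class = "window_track")
}

#' @export
print.window_track <- function(x, ...) {
  v <- x$windows$value[x$windows$defined]
  cat(sprintf(
    "<window_track> %s %s: %d windows of %d bp (step %d), range [%.4f, %.4f], mean %.4f\n",
    x$statistic, x$contig_id, nrow(x$windows), x$window_size, x$step,
    min(v), max(v), mean(v)))
  invisible(x)
}

#' Sliding-window GC content
#'
#' GC content per window is `(#G + #C) / (#A + #C + #G + #T)`; ambiguity
#' codes are excluded from numerator and denominator. Windows advance by
#' `step`; on a circular contig the final windows wrap past the origin (the
#' reported `end` may exceed the contig length, meaning modular
#' coordinates). A window with no unambiguous base is flagged undefined and
#' excluded from track summaries.
#'
#' @param contig `DNAString`/`DNAStringSet`/character nucleotide sequence.
#' @param window_size,step window length and advance in bases (defaults
#'   10 kb / 1 kb).
#' @param circular whether the contig is circular.
#' @param contig_id label stored in the track.
#' @return A `window_track` with statistic `"gc_content"`, values in [0,1].
#' @export
gc_content_track <- function(contig, window_size = 10000L, step = 1000L,
                             circular = TRUE, contig_id = "contig") {
  w <- window_base_counts(contig, window_size, step, circular)
  denom <- rowSums(w$counts)
  gc <- (w$counts[, "G"] + w$counts[, "C"]) / denom
  new_window_track(contig_id, window_size, step, "gc_content",
                   w$starts, ifelse(denom > 0, gc, NA_real_), denom > 0,
                   w$len)
}

#' Sliding-window GC skew
#'
#' Skew per window is `(#G - #C) / (#G + #C)`; windows with no G or C are
#' flagged undefined. Window geometry as in [gc_content_track()].
#'
#' @inheritParams gc_content_track
#' @return A `window_track` with statistic `"gc_skew"`, values in [-1,1].
#' @export
gc_skew_track <- function(contig, window_size = 10000L, step = 1000L,
                          circular = TRUE, contig_id = "contig") {
  w <- window_base_counts(contig, window_size, step, circular)
  g <- w$counts[, "G"]; c <- w$counts[, "C"]
  denom <- g + c
  new_window_track(contig_id, window_size, step, "gc_skew",
                   w$starts, ifelse(denom > 0, (g - c) / denom, NA_real_),
                   denom > 0, w$len)
}

#' Locate replication origin and terminus from the cumulative GC skew
#'
#' In most bacterial chromosomes the leading strand is G-rich, so windowed
#' GC skew is negative approaching the origin and positive after it; the
#' cumulative skew curve therefore attains its minimum at the origin and its
#' maximum at the terminus. Positions are reported as the centre (base
#' coordinate, modulo contig length) of the extreme window; ties go to the
#' earliest window. A near-flat cumulative curve, or extremes falling in
#' adjacent windows, is flagged degenerate.
#'
#' @param skew a `window_track` with statistic `"gc_skew"`.
#' @return List with `origin`, `terminus` (base coordinates), `degenerate`
#'   flag and the cumulative curve.
#' @export
locate_replication_extremes <- function(skew) {
  stopifnot(inherits(skew, "window_track"), skew$statistic == "gc_skew")
  w <- skew$windows
  if (sum(w$defined) < 10L)
    stop("need at least 10 defined skew windows")
  v <- ifelse(w$defined, w$value, 0)
  cum <- cumsum(v)
  n <- length(cum)
  imin <- which.min(cum)  # first index on ties
  imax <- which.max(cum)
  # refine each extremum by a local piecewise-linear (V-shape) fit: the
  # argmin alone is sensitive to short compositional excursions, whereas
  # the breakpoint of a two-slope fit over the surrounding windows averages
  # the noise out. The curve is treated as circular (total skew ~ 0).
  refine <- function(i0) {
    half <- min(150L, n %/% 4L)
    if (half < 5L) return(i0)
    js <- (i0 - half):(i0 + half)
    jj <- ((js - 1L) %% n) + 1L
    y <- cum[jj] + cum[n] * ((js - 1L) %/% n)
    x <- seq_along(js)
    best_sse <- Inf; best <- i0
    for (cidx in (half %/% 2L):(length(js) - half %/% 2L)) {
      left <- (x - cidx) * (x < cidx)
      right <- (x - cidx) * (x >= cidx)
      fit <- stats::lm.fit(cbind(1, left, right), y)
      sse <- sum(fit$residuals^2)
      if (sse < best_sse) { best_sse <- sse; best <- js[cidx] }
    }
    ((best - 1L) %% n) + 1L
  }
  imin_r <- refine(imin)
  imax_r <- refine(imax)
  centre <- function(i)
    as.integer((w$start[i] + skew$window_size %/% 2L) %% skew$contig_length)
  vals <- w$value[w$defined]
  degenerate <- (max(vals) - min(vals)) < 1e-12 ||
    (max(cum) - min(cum)) < 1e-9 || abs(imax - imin) <= 1L
  list(origin = centre(imin_r), terminus = centre(imax_r),
       origin_window = imin_r, terminus_window = imax_r,
       degenerate = degenerate, cumulative = cum)
}

#' Call low-GC genomic islands from a GC window track
#'
#' A compositional island detector: the threshold is
#' `mean - sd_multiplier * SD` of the defined window values; windows below
#' threshold are marked, runs of marked windows become candidate intervals
#' (spanning window centres, so interval edges are resolved to the step
#' rather than the window size), runs closer than `merge_gap` are merged and
#' merged runs shorter than `min_island_length` are dropped. Interval mean
#' GC is recomputed from the sequence when it is supplied.
#'
#' @param gc a `window_track` with statistic `"gc_content"`.
#' @param sd_multiplier threshold depth in SD units (default 1.5).
#' @param min_island_length minimum island length in bases (default 8 kb).
#' @param merge_gap maximum gap merged between marked runs (default 5 kb).
#' @param contig optional nucleotide sequence for exact interval mean GC.
#' @return An `island_set`: intervals tibble (`contig_id`, `start`, `end`,
#'   `mean_gc`) plus `genome_mean_gc` and `threshold_gc`.
#' @export
detect_low_gc_islands <- function(gc, sd_multiplier = 1.5,
                                  min_island_length = 8000L,
                                  merge_gap = 5000L, contig = NULL) {
  stopifnot(inherits(gc, "window_track"), gc$statistic == "gc_content")
  w <- gc$windows[gc$windows$defined, , drop = FALSE]
  if (nrow(w) < 10L) stop("need at least 10 defined GC windows")
  mu <- mean(w$value); sdev <- stats::sd(w$value)
  thr <- mu - sd_multiplier * sdev
  # overdispersion guard: in a compositionally homogeneous genome the
  # window-to-window spread is pure base-sampling noise, sd ~ sqrt(p(1-p)/w);
  # islands only exist when the spread clearly exceeds it
  noise_sd <- sqrt(mu * (1 - mu) / gc$window_size)
  homogeneous <- sdev < 2 * noise_sd
  marked <- if (homogeneous) rep(FALSE, nrow(w)) else w$value < thr
  halfstep <- gc$step / 2
  centres <- (w$start + w$end) / 2
  runs <- rle(marked)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  iv <- NULL
  for (k in which(runs$values)) {
    iv <- rbind(iv, c(centres[idx_start[k]] - halfstep,
                      centres[idx_end[k]] + halfstep))
  }
  empty <- function() structure(
    list(intervals = tibble::tibble(contig_id = character(),
                                    start = integer(), end = integer(),
                                    mean_gc = numeric()),
         genome_mean_gc = mu, threshold_gc = thr,
         contig_length = gc$contig_length),
    class = "island_set")
  if (is.null(iv)) return(empty())
  iv[, 1] <- pmax(0, iv[, 1])
  iv[, 2] <- pmin(gc$contig_length, iv[, 2])
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  # merge runs separated by <= merge_gap
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (k in 2:nrow(iv)) {
    if (iv[k, 1] - merged[nrow(merged), 2] <= merge_gap)
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[k, 2])
    else merged <- rbind(merged, iv[k, , drop = FALSE])
  }
  keep <- (merged[, 2] - merged[, 1]) >= min_island_length
  merged <- merged[keep, , drop = FALSE]
  if (nrow(merged) == 0L) return(empty())
  mean_gc <- vapply(seq_len(nrow(merged)), function(k) {
    if (is.null(contig)) {
      inwin <- centres >= merged[k, 1] & centres < merged[k, 2]
      mean(w$value[inwin])
    } else {
      s <- contig
      if (methods::is(s, "DNAStringSet")) s <- s[[1]]
      if (!methods::is(s, "DNAString"))
        s <- Biostrings::DNAString(toupper(as.character(s)))
      seg <- Biostrings::subseq(s, merged[k, 1] + 1L, merged[k, 2])
      f <- Biostrings::letterFrequency(seg, c("A", "C", "G", "T"))
      unname((f[["G"]] + f[["C"]]) / sum(f))
    }
  }, numeric(1))
  structure(list(
    intervals = tibble::tibble(contig_id = gc$contig_id,
                               start = as.integer(round(merged[, 1])),
                               end = as.integer(round(merged[, 2])),
                               mean_gc = mean_gc),
    genome_mean_gc = mu, threshold_gc = thr,
    contig_length = gc$contig_length),
    class = "island_set")
}

#' @export
print.island_set <- function(x, ...) {
  cat(sprintf(
    "<island_set> %d island(s), %s bp total; genome mean GC %.3f, threshold %.3f\n",
    nrow(x$intervals),
    format(sum(x$intervals$end - x$intervals$start), big.mark = ","),
    x$genome_mean_gc, x$threshold_gc))
  invisible(x)
}

#' Total island length in bases
#' @param islands an `island_set`.
#' @return Numeric total length.
#' @export
island_total_length <- function(islands)
  sum(islands$intervals$end - islands$intervals$start)

#' Build a density report from raw counts and region lengths
#'
#' The arithmetic core of the island density contrast, exposed so printed
#' counts and region fractions can be fed in directly. Densities are in
#' genes per Mb; `fold_ratio = density_outside / density_inside`, reported
#' as `Inf` with `fold_ratio_defined = FALSE` when no gene lies inside.
#'
#' @param n_inside,n_outside family gene counts inside / outside islands.
#' @param len_inside_mb,len_outside_mb region lengths in Mb (both > 0).
#' @return A `density_report` list.
#' @export
density_report <- function(n_inside, n_outside, len_inside_mb,
                           len_outside_mb) {
  if (len_inside_mb <= 0 || len_outside_mb <= 0)
    stop("region lengths must be positive")
  di <- n_inside / len_inside_mb
  dd <- n_outside / len_outside_mb
  structure(list(
    n_inside = n_inside, n_outside = n_outside,
    len_inside_mb = len_inside_mb, len_outside_mb = len_outside_mb,
    density_inside = di, density_outside = dd,
    fold_ratio = if (di > 0) dd / di else Inf,
    fold_ratio_defined = di > 0),
    class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf(
    "<density_report> inside: %d genes / %.3f Mb = %.1f per Mb; outside: %d genes / %.3f Mb = %.1f per Mb; fold %.2f\n",
    x$n_inside, x$len_inside_mb, x$density_inside,
    x$n_outside, x$len_outside_mb, x$density_outside, x$fold_ratio))
  invisible(x)
}

#' Contrast family-gene density inside versus outside low-GC islands
#'
#' A gene is inside iff its midpoint falls in an island interval. Counts are
#' conserved (`n_inside + n_outside` equals the family size) and region
#' lengths sum to the genome length.
#'
#' @param family a `family_hits` object (or character vector of gene ids).
#' @param genome an [annotated_genome()].
#' @param islands an `island_set` (intervals may span several contigs).
#' @return A [density_report()].
#' @export
gene_density_contrast <- function(family, genome, islands) {
  ids <- if (inherits(family, "family_hits")) family_members(family)
  else as.character(family)
  genes <- genome$genes[genome$genes$gene_id %in% ids, , drop = FALSE]
  iv <- islands$intervals
  glen <- genome_length(genome)
  ilen <- sum(iv$end - iv$start)
  if (ilen <= 0) {
    # no islands: every gene is outside and the inside density is undefined
    return(structure(list(
      n_inside = 0L, n_outside = nrow(genes),
      len_inside_mb = 0, len_outside_mb = glen / 1e6,
      density_inside = NA_real_,
      density_outside = nrow(genes) / (glen / 1e6),
      fold_ratio = NA_real_, fold_ratio_defined = FALSE),
      class = "density_report"))
  }
  if (glen - ilen <= 0)
    stop("non-island region must have positive length")
  if (any(iv$end > stats::setNames(Biostrings::width(genome$contigs),
                                   names(genome$contigs))[iv$contig_id]))
    stop("island intervals exceed contig bounds")
  mid <- (genes$start + genes$end) / 2
  inside <- vapply(seq_len(nrow(genes)), function(k) {
    on <- iv$contig_id == genes$contig_id[k]
    any(mid[k] >= iv$start[on] & mid[k] < iv$end[on])
  }, logical(1))
  density_report(sum(inside), sum(!inside), ilen / 1e6, (glen - ilen) / 1e6)
}

#' Fraction of family genes with a tagged gene in their neighbourhood
#'
#' Counts family genes having at least one gene carrying `tag` within
#' `radius_genes` positions in gene order (either direction, same contig;
#' the order ring is closed on circular contigs). Fraction is count over
#' family size, so it is non-decreasing in the radius.
#'
#' @param family a `family_hits` object or character vector of gene ids.
#' @param genome an [annotated_genome()].
#' @param tag functional tag to look for (see [default_tag_map()]).
#' @param radius_genes neighbourhood radius in gene ranks (>= 1).
#' @return List with `count`, `fraction` and the counted `gene_ids`.
#' @export
neighborhood_context <- function(family, genome, tag = "transcription_factor",
                                 radius_genes = 2L) {
  if (radius_genes < 1L) stop("radius_genes must be >= 1")
  ids <- if (inherits(family, "family_hits")) family_members(family)
  else as.character(family)
  tags_present <- unique(unlist(genome$genes$functional_tags))
  known <- unique(c(names(default_tag_map()), tags_present))
  if (!tag %in% known)
    stop("unknown tag '", tag, "'; known tags: ",
         paste(sort(known), collapse = ", "))
  hit_ids <- character(0)
  for (ctg in unique(genome$genes$contig_id)) {
    g <- genome$genes[genome$genes$contig_id == ctg, , drop = FALSE]
    g <- g[order(g$order_index), , drop = FALSE]
    n <- nrow(g)
    tagged <- vapply(g$functional_tags, function(t) tag %in% t, logical(1))
    fam <- g$gene_id %in% ids
    if (!any(fam) || !any(tagged)) next
    tpos <- which(tagged)
    circ <- isTRUE(genome$circular[[ctg]])
    for (i in which(fam)) {
      d <- abs(tpos - i)
      if (circ) d <- pmin(d, n - d)
      if (any(d <= radius_genes & d > 0))  # a gene's own tags never count
        hit_ids <- c(hit_ids, g$gene_id[i])
    }
  }
  list(count = length(hit_ids),
       fraction = if (length(ids)) length(hit_ids) / length(ids) else NA_real_,
       gene_ids = hit_ids)
}

#' Jaccard overlap between two interval sets
#'
#' Length of the intersection over length of the union, computed with
#' IRanges. Used to score recovery of planted islands.
#'
#' @param a,b data frames with `start`, `end` (0-based half-open), or
#'   `island_set` objects.
#' @return Jaccard index in [0, 1].
#' @export
interval_jaccard <- function(a, b) {
  tab <- function(x) if (inherits(x, "island_set")) x$intervals else
    tibble::as_tibble(x)
  a <- tab(a); b <- tab(b)
  if (nrow(a) == 0L && nrow(b) == 0L) return(1)
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  ra <- IRanges::reduce(IRanges::IRanges(a$start + 1L, a$end))
  rb <- IRanges::reduce(IRanges::IRanges(b$start + 1L, b$end))
  inter <- sum(IRanges::width(IRanges::intersect(ra, rb)))
  uni <- sum(IRanges::width(IRanges::union(ra, rb)))
  inter / uni
}
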