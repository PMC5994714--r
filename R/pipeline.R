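# End-to-end orchestration: io -> search -> architecture/islands -> arrays
# -> provenance -> consolidated report.

#' Build a validated pipeline configuration
#'
#' Either point at on-disk inputs (`focal_gff3` + `focal_fasta` +
#' `queries_fasta`, optionally companion genomes and a lineage table) or set
#' `simulate = TRUE` to generate the synthetic dataset internally from
#' `synth` / `seed`. Unknown keys are rejected.
#'
#' @param ... configuration values; see Details.
#' @details Recognised keys: `simulate`, `seed`, `synth` (a [synth_config()]),
#'   `focal_gff3`, `focal_fasta`, `queries_fasta`, `companion_gff3`
#'   (named vector), `companion_fasta` (named vector), `lineage_tsv`,
#'   `focal_lineage`, `cutoff`, `window_size`, `step`, `sd_multiplier`,
#'   `min_island_length`, `merge_gap`, `close_group_label`, `radius_genes`,
#'   `neighborhood_tag`, `max_intervening`, `out_dir`, `scheme`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    simulate = FALSE, seed = 1L, synth = NULL,
    focal_gff3 = NULL, focal_fasta = NULL, queries_fasta = NULL,
    companion_gff3 = NULL, companion_fasta = NULL, lineage_tsv = NULL,
    focal_lineage = NULL,
    cutoff = 1e-15, window_size = 10000L, step = 1000L,
    sd_multiplier = 1.5, min_island_length = 8000L, merge_gap = 5000L,
    close_group_label = "Rhizobacteria", radius_genes = 2L,
    neighborhood_tag = "transcription_factor", max_intervening = 0L,
    out_dir = NULL, scheme = NULL)
  user <- list(...)
  if (length(user) == 1L && is.list(user[[1]]) && is.null(names(user)))
    user <- user[[1]]
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  if (!cfg$simulate && (is.null(cfg$focal_gff3) || is.null(cfg$queries_fasta)))
    stop("either simulate = TRUE or focal_gff3 + focal_fasta + queries_fasta")
  if (is.null(cfg$scheme)) cfg$scheme <- scoring_scheme()
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#' @param path YAML file whose keys match [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Run the full family-expansion analysis pipeline
#'
#' Stages run in dependency order: input (or simulation), family census by
#' local-alignment search, GC landscape (content, skew, replication
#' extremes), low-GC island calling, density contrast, tandem arrays,
#' best-hit provenance (skipped gracefully when no companion genomes are
#' available) and the neighbourhood scan. When `out_dir` is set,
#' intermediate artifacts (hit TSV, bedGraph tracks, island BED, array TSV,
#' provenance TSV, summary JSON) are written so any stage can be inspected
#' or rerun in isolation. The report is a deterministic function of the
#' inputs and configuration.
#'
#' @param config a [pipeline_config()].
#' @return A `summary_report` list; see its print method for the headline
#'   numbers.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  truth <- NULL
  companions <- list()
  if (config$simulate) {
    synth <- config$synth %||% synth_config(seed = config$seed)
    sim <- stage("simulate", generate_focal_genome(synth))
    focal <- sim$genome
    truth <- sim$truth
    queries <- truth$queries
    if (synth$n_close_companions + synth$n_distant_companions > 0L)
      companions <- stage("simulate",
                          generate_companion_genomes(synth, truth))
  } else {
    focal <- stage("io", read_annotated_genome(
      config$focal_gff3, config$focal_fasta,
      lineage = config$focal_lineage %||% character()))
    queries <- stage("io", Biostrings::readAAStringSet(config$queries_fasta))
    names(queries) <- sub("\\s.*$", "", names(queries))
    if (!is.null(config$companion_gff3)) {
      lin <- if (!is.null(config$lineage_tsv)) {
        lt <- utils::read.delim(config$lineage_tsv,
                                stringsAsFactors = FALSE)
        stats::setNames(lapply(strsplit(lt$lineage, ","), trimws),
                        lt$genome_id)
      } else list()
      for (nm in names(config$companion_gff3)) {
        companions[[nm]] <- stage("io", read_annotated_genome(
          config$companion_gff3[[nm]], config$companion_fasta[[nm]],
          genome_id = nm, lineage = lin[[nm]] %||% character()))
      }
      if (!is.null(config$lineage_tsv) &&
          focal$genome_id %in% names(lin) && !length(focal$lineage))
        focal$lineage <- lin[[focal$genome_id]]
    }
  }

  hits <- stage("search", find_family_members(
    queries, focal, scheme = config$scheme, cutoff = config$cutoff))

  contig_id <- names(focal$contigs)[1]
  circ <- isTRUE(focal$circular[[contig_id]])
  gc <- stage("architecture", gc_content_track(
    focal$contigs[[contig_id]], config$window_size, config$step, circ,
    contig_id))
  skew <- stage("architecture", gc_skew_track(
    focal$contigs[[contig_id]], config$window_size, config$step, circ,
    contig_id))
  extremes <- stage("architecture", locate_replication_extremes(skew))
  islands <- stage("islands", detect_low_gc_islands(
    gc, config$sd_multiplier, config$min_island_length, config$merge_gap,
    contig = focal$contigs[[contig_id]]))
  density <- if (nrow(islands$intervals) > 0L && nrow(hits$hits) > 0L)
    stage("density", gene_density_contrast(hits, focal, islands))
  else NULL

  arrays <- stage("arrays", detect_arrays(hits, focal,
                                          config$max_intervening))
  array_tab <- array_frequency_table(arrays)

  provenance <- NULL
  if (length(companions) && nrow(hits$hits) > 0L) {
    comp_hits <- lapply(companions, function(g) stage(
      "search", find_family_members(queries, g, scheme = config$scheme,
                                    cutoff = config$cutoff)))
    db <- stage("provenance", family_database(
      c(list(focal), unname(companions)), c(list(hits), unname(comp_hits))))
    provenance <- stage("provenance", best_hit_classification(
      focal$proteome[family_members(hits)], db, focal$genome_id,
      config$close_group_label, scheme = config$scheme))
  }

  neigh <- if (nrow(hits$hits) > 0L)
    stage("neighborhood", neighborhood_context(
      hits, focal, config$neighborhood_tag, config$radius_genes))
  else NULL

  n_genes <- nrow(focal$genes)
  n_fam <- nrow(hits$hits)
  report <- structure(list(
    genome_id = focal$genome_id,
    parameters = list(cutoff = config$cutoff,
                      window_size = config$window_size, step = config$step,
                      sd_multiplier = config$sd_multiplier,
                      min_island_length = config$min_island_length,
                      merge_gap = config$merge_gap,
                      close_group_label = config$close_group_label,
                      radius_genes = config$radius_genes,
                      max_intervening = config$max_intervening,
                      seed = config$seed),
    census = list(family_size = n_fam, total_cds = n_genes,
                  family_fraction = n_fam / n_genes,
                  family_percent_label = format_percent(n_fam, n_genes)),
    replication = list(origin = extremes$origin,
                       terminus = extremes$terminus,
                       degenerate = extremes$degenerate),
    islands = list(n = nrow(islands$intervals),
                   total_length = island_total_length(islands),
                   fraction_of_genome = island_total_length(islands) /
                     genome_length(focal),
                   genome_mean_gc = islands$genome_mean_gc,
                   threshold_gc = islands$threshold_gc),
    density = density,
    array_table = array_tab,
    provenance = if (is.null(provenance)) list(skipped = TRUE) else
      provenance,
    neighborhood = if (is.null(neigh)) list(skipped = TRUE) else
      list(tag = config$neighborhood_tag, count = neigh$count,
           fraction = neigh$fraction, denominator = n_fam,
           percent_label = format_percent(neigh$count, max(1L, n_fam))),
    objects = list(hits = hits, gc = gc, skew = skew, islands = islands,
                   arrays = arrays, truth = truth)),
    class = "summary_report")

  if (!is.null(config$out_dir))
    write_report(report, config$out_dir)
  report
}

#' @export
print.summary_report <- function(x, ...) {
  cat(sprintf("<summary_report> %s\n", x$genome_id))
  cat(sprintf("  family census: %d of %d CDS (%s %%)\n",
              x$census$family_size, x$census$total_cds,
              x$census$family_percent_label))
  cat(sprintf("  replication: origin %d, terminus %d%s\n",
              x$replication$origin, x$replication$terminus,
              if (x$replication$degenerate) " [degenerate]" else ""))
  cat(sprintf("  islands: %d covering %.1f %% of the genome\n",
              x$islands$n, 100 * x$islands$fraction_of_genome))
  if (!is.null(x$density))
    cat(sprintf("  density: %.1f per Mb in islands vs %.1f per Mb outside (fold %.2f)\n",
                x$density$density_inside, x$density$density_outside,
                x$density$fold_ratio))
  cat(sprintf("  arrays: %d array(s), largest %s\n",
              sum(unclass(x$array_table)),
              if (length(x$array_table)) names(x$array_table)[
                length(x$array_table)] else "-"))
  if (!isTRUE(x$provenance$skipped)) {
    f <- provenance_fractions(x$provenance$counts)
    cat(sprintf("  provenance: %s\n",
                paste(sprintf("%s %s %%", f$category, f$percent_label),
                      collapse = ", ")))
  } else cat("  provenance: skipped (no companion genomes)\n")
  if (!isTRUE(x$neighborhood$skipped))
    cat(sprintf("  neighborhood: %d family genes (%s %%) near a %s gene\n",
                x$neighborhood$count, x$neighborhood$percent_label,
                x$neighborhood$tag))
  invisible(x)
}

report_to_list <- function(x) {
  out <- list(
    genome_id = x$genome_id, parameters = x$parameters,
    census = x$census,
    replication = x$replication[c("origin", "terminus", "degenerate")],
    islands = x$islands,
    array_table = list(sizes = as.integer(names(x$array_table)),
                       counts = as.integer(unclass(x$array_table)),
                       family_size = family_size(x$array_table)))
  if (!is.null(x$density))
    out$density <- unclass(x$density)
  if (!isTRUE(x$provenance$skipped)) {
    f <- provenance_fractions(x$provenance$counts)
    out$provenance <- list(category = f$category, count = f$count,
                           fraction = f$fraction,
                           percent_label = f$percent_label)
  } else out$provenance <- list(skipped = TRUE)
  out$neighborhood <- x$neighborhood[setdiff(names(x$neighborhood),
                                             "gene_ids")]
  out
}

#' Write all report artifacts to a directory
#'
#' Emits `hits.tsv`, `gc.bedGraph`, `skew.bedGraph`, `islands.bed`,
#' `arrays.tsv`, `provenance.tsv` (when computed) and `summary.json`. The
#' JSON is byte-identical across reruns on the same inputs and
#' configuration.
#'
#' @param report a `summary_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  o <- report$objects
  write_family_hits(o$hits, file.path(dir, "hits.tsv"))
  write_intervals(o$gc, file.path(dir, "gc.bedGraph"), "bedGraph")
  write_intervals(o$skew, file.path(dir, "skew.bedGraph"), "bedGraph")
  write_intervals(o$islands, file.path(dir, "islands.bed"), "bed")
  write_array_tables(stats::setNames(list(report$array_table),
                                     report$genome_id),
                     file.path(dir, "arrays.tsv"))
  if (!isTRUE(report$provenance$skipped))
    write_provenance(report$provenance, file.path(dir, "provenance.tsv"))
  jsonlite::write_json(report_to_list(report),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
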