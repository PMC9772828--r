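# End-to-end orchestration: PSI quantification -> event filtering ->
# exon classification -> ortholog mapping -> element scoring ->
# paired comparison, with a run manifest recording inputs, seed and
# per-stage record counts.

#' Compare element scores between species over ortholog pairs
#'
#' For each species-exclusivity class and each element-score metric, a
#' paired Wilcoxon signed-rank test compares the species-A against the
#' species-B scores of the pairs in that class. The p-values of all
#' performed tests form one family, adjusted with Holm's method.
#'
#' @param pairs Scored ortholog table ([attach_element_scores()] output
#'   with an `exclusivity` column from [species_exclusive_sets()]).
#' @param metrics Element metrics to compare (column stems; default all
#'   four: `bp_seq`, `bp_motif`, `ss3`, `ss5`).
#' @param classes Exclusivity classes to test.
#' @return `data.frame` with columns `class`, `metric`, `n`, `median_a`,
#'   `median_b`, `W`, `p`, `p_holm`. Metrics with fewer than 2 complete
#'   pairs in a class are skipped.
#' @export
compare_element_scores <- function(pairs,
                                   metrics = c("bp_seq", "bp_motif",
                                               "ss3", "ss5"),
                                   classes = c("A-exclusive",
                                               "B-exclusive")) {
  stopifnot("exclusivity" %in% names(pairs))
  rows <- list()
  for (cl in classes) {
    sub <- pairs[pairs$exclusivity == cl, , drop = FALSE]
    for (m in metrics) {
      ca <- paste0(m, "_a"); cb <- paste0(m, "_b")
      if (!ca %in% names(pairs) || !cb %in% names(pairs)) next
      ok <- !(is.na(sub[[ca]]) | is.na(sub[[cb]]))
      if (sum(ok) < 2L) next
      a <- sub[[ca]][ok]; b <- sub[[cb]][ok]
      wt <- tryCatch(wilcoxon_signed_rank(a, b), error = function(e) NULL)
      if (is.null(wt)) next
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, metric = m, n = wt$n,
        median_a = stats::median(a), median_b = stats::median(b),
        W = wt$W, p = wt$p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(class = character(), metric = character(),
                      n = integer(), median_a = numeric(),
                      median_b = numeric(), W = numeric(), p = numeric(),
                      p_holm = numeric()))
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Run the comparative splicing pipeline
#'
#' Executes the full analysis on in-memory inputs (typically a
#' [gen_species_pair()] result) or on files: per-event PSI summaries,
#' the support/SD/read filters, exon classification, ortholog mapping
#' through the chains, element scoring, species-exclusive partitioning
#' and the paired element-score comparison. Results and a manifest are
#' written to `out_dir` when given.
#'
#' @param pair List with `genome_a`, `genome_b`, `transcripts_a`,
#'   `transcripts_b`, `chains`, `events_a`, `events_b` (see
#'   [gen_species_pair()]); alternatively `paths` may be given.
#' @param paths Named list of file paths (`genome_a`, `genome_b`,
#'   `gff_a`, `gff_b`, `chain`, `events_a`, `events_b`) used when `pair`
#'   is `NULL`; missing files raise an error naming the entry.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param min_support,max_sd,min_mean_reads Event filters
#'   (see [filter_events()]).
#' @param delta_psi_min,apply_delta Exclusivity thresholds
#'   (see [species_exclusive_sets()]).
#' @param bp_model Branch-point model.
#' @param donor_model,acceptor_model Optional splice-site models.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return List with `summary_a`, `summary_b`, `pairs` (scored, with
#'   exclusivity), `comparison` and `manifest`.
#' @export
run_pipeline <- function(pair = NULL, paths = NULL, out_dir = NULL,
                         min_support = 3L, max_sd = 0.2,
                         min_mean_reads = 10,
                         delta_psi_min = 0.2, apply_delta = TRUE,
                         bp_model = default_bp_model(),
                         donor_model = NULL, acceptor_model = NULL,
                         seed = NA_integer_) {
  checksums <- NULL
  if (is.null(pair)) {
    if (is.null(paths)) stop("either 'pair' or 'paths' must be given")
    need <- c("genome_a", "genome_b", "gff_a", "gff_b", "chain",
              "events_a", "events_b")
    for (nm in need) {
      if (is.null(paths[[nm]]))
        stop("missing input: supply '", nm, "' in paths")
      if (!file.exists(paths[[nm]]))
        stop("input file for '", nm, "' not found: ", paths[[nm]])
    }
    checksums <- vapply(paths[need], function(p)
      unname(tools::md5sum(p)), character(1))
    pair <- list(genome_a = read_fasta(paths$genome_a),
                 genome_b = read_fasta(paths$genome_b),
                 transcripts_a = read_gff_transcripts(paths$gff_a),
                 transcripts_b = read_gff_transcripts(paths$gff_b),
                 chains = read_chain(paths$chain),
                 events_a = read_event_table(paths$events_a),
                 events_b = read_event_table(paths$events_b))
  }
  summarize_side <- function(events) {
    s <- summarize_events(events)
    coord <- unique(events[, c("event_id", "chrom", "strand",
                               "exon_start", "exon_end")])
    merge(s, coord, by = "event_id", sort = FALSE)
  }
  summary_a <- summarize_side(pair$events_a)
  summary_b <- summarize_side(pair$events_b)
  kept_a <- filter_events(summary_a, min_support, max_sd, min_mean_reads)
  kept_b <- filter_events(summary_b, min_support, max_sd, min_mean_reads)
  pairs <- build_ortholog_table(pair$transcripts_a, pair$transcripts_b,
                                pair$chains, kept_a, kept_b)
  pairs <- species_exclusive_sets(pairs, delta_psi_min, apply_delta)
  pairs <- attach_element_scores(pairs, pair$transcripts_a,
                                 pair$transcripts_b, pair$genome_a,
                                 pair$genome_b, bp_model, donor_model,
                                 acceptor_model)
  comparison <- compare_element_scores(pairs)
  manifest <- list(
    tool = "orthosplice",
    version = as.character(utils::packageVersion("orthosplice")),
    seed = seed,
    parameters = list(min_support = min_support, max_sd = max_sd,
                      min_mean_reads = min_mean_reads,
                      delta_psi_min = delta_psi_min,
                      apply_delta = apply_delta),
    input_checksums = as.list(checksums),
    counts = list(events_a = nrow(summary_a), events_b = nrow(summary_b),
                  kept_a = nrow(kept_a), kept_b = nrow(kept_b),
                  pairs = nrow(pairs),
                  unmapped_a = if (is.null(attr(pairs, "unmapped"))) 0L
                               else nrow(attr(pairs, "unmapped")),
                  comparisons = nrow(comparison)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(summary_a, file.path(out_dir, "summary_a.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summary_b, file.path(out_dir, "summary_b.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pairs, file.path(out_dir, "ortholog_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(comparison, file.path(out_dir, "comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(summary_a = summary_a, summary_b = summary_b, pairs = pairs,
       comparison = comparison, manifest = manifest)
}

#' Human-readable pipeline report
#'
#' Text summary of a [run_pipeline()] result: pair counts per
#' exclusivity class, per-metric five-number summaries per class, and
#' the manifest seed.
#'
#' @param results List returned by [run_pipeline()].
#' @return Character vector of report lines (also printed).
#' @export
splice_report <- function(results) {
  pairs <- results$pairs
  lines <- c("orthosplice pipeline report",
             sprintf("seed: %s", results$manifest$seed),
             sprintf("ortholog pairs: %d", nrow(pairs)))
  if (nrow(pairs) == 0L) {
    lines <- c(lines, "zero pairs: nothing to summarize")
  } else {
    tab <- table(pairs$exclusivity)
    lines <- c(lines, "pairs per class:",
               sprintf("  %s: %d", names(tab), as.integer(tab)))
    for (m in c("bp_seq", "bp_motif", "ss3", "ss5")) {
      ca <- paste0(m, "_a")
      if (!ca %in% names(pairs) || all(is.na(pairs[[ca]]))) next
      for (cl in unique(pairs$exclusivity)) {
        v <- pairs[[ca]][pairs$exclusivity == cl]
        v <- v[!is.na(v)]
        if (length(v) == 0L) next
        fv <- stats::fivenum(v)
        lines <- c(lines, sprintf(
          "  %s [%s, species A] min/q1/med/q3/max: %s", m, cl,
          paste(signif(fv, 4), collapse = "/")))
      }
    }
  }
  if (nrow(results$comparison) > 0L) {
    lines <- c(lines, "paired comparisons (Holm-adjusted):",
               sprintf("  %s %s: n=%d, W=%g, p=%.3g, p_holm=%.3g",
                       results$comparison$class,
                       results$comparison$metric, results$comparison$n,
                       results$comparison$W, results$comparison$p,
                       results$comparison$p_holm))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
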