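# Cassette-exon percent-spliced-in (PSI) from splice-junction read
# counts, event-level summaries and filters, and exon classification.
# Events live in a long-format data.frame with one row per event and
# sample: event_id, sample, ijc (inclusion junction count, summed over
# the upstream and downstream junctions), sjc (skipping junction count),
# plus optional exon coordinates (chrom, strand, exon_start, exon_end).

#' PSI from junction counts
#'
#' Junction-count PSI with effective-length normalization:
#' `psi = (ijc/inc_eff_len) / (ijc/inc_eff_len + sjc/skip_eff_len)`.
#' With the defaults (2, 1), this is the junction-count-only estimator
#' used by standard event quantifiers: an included transcript offers two
#' supporting junctions, a skipping transcript one.
#'
#' @param ijc,sjc Non-negative integer vectors of inclusion and skipping
#'   junction read counts.
#' @param inc_eff_len,skip_eff_len Effective junction lengths
#'   (defaults 2 and 1).
#' @return Numeric vector of PSI values in `[0, 1]`; `NA` where both
#'   counts are zero.
#' @export
psi_from_junction_counts <- function(ijc, sjc, inc_eff_len = 2,
                                     skip_eff_len = 1) {
  stopifnot(length(ijc) == length(sjc), inc_eff_len > 0, skip_eff_len > 0)
  if (any(ijc < 0, na.rm = TRUE) || any(sjc < 0, na.rm = TRUE))
    stop("junction counts must be non-negative")
  inc <- ijc / inc_eff_len
  skp <- sjc / skip_eff_len
  psi <- inc / (inc + skp)
  psi[ijc == 0 & sjc == 0] <- NA_real_
  psi
}

#' Summarize a splice event over samples
#'
#' Mean and SD of PSI over samples with defined PSI (SD with the n-1
#' denominator; 0 when a single sample is defined), mean total junction
#' reads per sample, and the exon class from [classify_exon()].
#'
#' @param ijc,sjc Per-sample junction counts for one event.
#' @param inc_eff_len,skip_eff_len Passed to [psi_from_junction_counts()].
#' @param alt_threshold Passed to [classify_exon()].
#' @return List with `mean_psi`, `sd_psi`, `mean_junction_reads`,
#'   `n_samples` (samples with defined PSI) and `class`.
#' @export
summarize_event <- function(ijc, sjc, inc_eff_len = 2, skip_eff_len = 1,
                            alt_threshold = 0.9) {
  psi <- psi_from_junction_counts(ijc, sjc, inc_eff_len, skip_eff_len)
  ok <- !is.na(psi)
  if (!any(ok)) stop("no sample with defined PSI")
  n <- sum(ok)
  m <- mean(psi[ok])
  s <- if (n > 1L) stats::sd(psi[ok]) else 0
  list(mean_psi = m, sd_psi = s,
       mean_junction_reads = mean(ijc + sjc),
       n_samples = n,
       class = classify_exon(m, alt_threshold))
}

#' Summarize an event table
#'
#' Applies [summarize_event()] per `event_id` of a long-format count
#' table. The number of samples with defined PSI is reported as the
#' event's `support`.
#'
#' @param events `data.frame` with columns `event_id`, `sample`, `ijc`,
#'   `sjc`.
#' @inheritParams summarize_event
#' @return `data.frame` with one row per event: `event_id`, `support`,
#'   `mean_psi`, `sd_psi`, `mean_junction_reads`, `class`, in first-seen
#'   event order.
#' @export
summarize_events <- function(events, inc_eff_len = 2, skip_eff_len = 1,
                             alt_threshold = 0.9) {
  stopifnot(all(c("event_id", "ijc", "sjc") %in% names(events)))
  ids <- unique(events$event_id)
  rows <- lapply(ids, function(id) {
    e <- events[events$event_id == id, ]
    s <- summarize_event(e$ijc, e$sjc, inc_eff_len, skip_eff_len,
                         alt_threshold)
    data.frame(event_id = id, support = s$n_samples, mean_psi = s$mean_psi,
               sd_psi = s$sd_psi,
               mean_junction_reads = s$mean_junction_reads,
               class = s$class)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter splice events
#'
#' Keeps events supported by at least `min_support` datasets, with an SD
#' of PSI strictly below `max_sd`, and a mean junction read count of at
#' least `min_mean_reads`. Input order is preserved.
#'
#' @param summaries `data.frame` from [summarize_events()] (columns
#'   `support`, `sd_psi`, `mean_junction_reads`).
#' @param min_support Minimal number of supporting datasets (inclusive).
#' @param max_sd SD threshold (strict: events with `sd_psi == max_sd` are
#'   dropped).
#' @param min_mean_reads Minimal mean junction read count (inclusive).
#' @return The kept rows of `summaries`.
#' @export
filter_events <- function(summaries, min_support = 3L, max_sd = 0.2,
                          min_mean_reads = 10) {
  stopifnot(all(c("support", "sd_psi", "mean_junction_reads") %in%
                names(summaries)))
  keep <- summaries$support >= min_support &
    summaries$sd_psi < max_sd &
    summaries$mean_junction_reads >= min_mean_reads
  out <- summaries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify an exon from its mean PSI
#'
#' Alternative when PSI is below the threshold, constitutive when above;
#' a PSI exactly at the threshold satisfies neither strict inequality and
#' is left unclassified.
#'
#' @param mean_psi Mean PSI in `[0, 1]` (vectorized).
#' @param alt_threshold Classification threshold (default 0.9).
#' @return Character vector: `"alternative"`, `"constitutive"` or
#'   `"unclassified"` (also used for `NA` input).
#' @export
classify_exon <- function(mean_psi, alt_threshold = 0.9) {
  if (any(mean_psi < 0 | mean_psi > 1, na.rm = TRUE))
    stop("PSI outside [0, 1]")
  out <- rep("unclassified", length(mean_psi))
  out[!is.na(mean_psi) & mean_psi < alt_threshold] <- "alternative"
  out[!is.na(mean_psi) & mean_psi > alt_threshold] <- "constitutive"
  out
}

#' Total exclusion of an exon across its skipping events
#'
#' An exon can be skipped through several distinct events (for example
#' alone or together with a neighbouring exon). The total percentage of
#' transcripts excluding the exon is the sum of the per-event exclusion
#' fractions, capped at 100%.
#'
#' @param exclusions Numeric vector of exclusion fractions (`1 - psi`),
#'   one per distinct skipping event involving the exon.
#' @return Percent of transcripts excluding the exon, in `[0, 100]`.
#' @export
total_exclusion <- function(exclusions) {
  if (length(exclusions) == 0L) return(0)
  if (any(exclusions < 0)) stop("exclusion fractions must be non-negative")
  min(100, 100 * sum(exclusions))
}

#' Read a junction-count event table
#'
#' Long-format TSV with columns `event_id`, `sample`, `ijc`, `sjc` and
#' optionally `chrom`, `strand`, `exon_start`, `exon_end` (0-based
#' half-open exon coordinates).
#'
#' @param path Path to the TSV file.
#' @return `data.frame` of events.
#' @export
read_event_table <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("event_id", "sample", "ijc", "sjc")
  if (!all(need %in% names(ev)))
    stop("event table must have columns ", paste(need, collapse = ", "))
  if (any(ev$ijc < 0) || any(ev$sjc < 0))
    stop("junction counts must be non-negative")
  ev
}
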