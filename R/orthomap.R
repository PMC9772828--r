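# Cross-species exon mapping through UCSC chain alignments and
# construction of the orthologous-exon table with species-exclusive
# classification. Mapping projects an interval through the aligned
# blocks of the single highest-scoring overlapping chain (no chain
# stitching) and returns the target-side hull of the mapped bases.

#' Map an interval through chain alignments
#'
#' Projects `interval` through the aligned blocks of the highest-scoring
#' chain on its chromosome. The mapped result is the target-side hull of
#' all projected bases; it is returned only when the fraction of the
#' interval's bases falling inside aligned blocks is at least
#' `min_ratio`.
#'
#' @param interval A [genomic_interval] on the chain source assembly.
#' @param chains List of `chain_alignment` objects (see [read_chain()]).
#' @param min_ratio Minimal mapped-base fraction (default 0.9).
#' @return A [genomic_interval] on the target assembly, or `NULL` when
#'   the interval's chromosome has no chain or too few bases map.
#' @export
map_interval <- function(interval, chains, min_ratio = 0.9) {
  stopifnot(inherits(interval, "genomic_interval"))
  cand <- Filter(function(ch) ch$t_name == interval$chrom &&
                   interval$start < ch$t_end && interval$end > ch$t_start,
                 chains)
  if (length(cand) == 0L) return(NULL)
  ch <- cand[[which.max(vapply(cand, function(c) c$score, numeric(1)))]]
  t0 <- ch$t_start
  q0 <- ch$q_start
  mapped <- 0L
  q_lo <- Inf; q_hi <- -Inf
  for (i in seq_len(nrow(ch$blocks))) {
    size <- ch$blocks$size[i]
    ov_s <- max(interval$start, t0)
    ov_e <- min(interval$end, t0 + size)
    if (ov_s < ov_e) {
      mapped <- mapped + (ov_e - ov_s)
      q_lo <- min(q_lo, q0 + (ov_s - t0))
      q_hi <- max(q_hi, q0 + (ov_e - t0))
    }
    t0 <- t0 + size + ch$blocks$dt[i]
    q0 <- q0 + size + ch$blocks$dq[i]
  }
  if (mapped / interval_width(interval) < min_ratio) return(NULL)
  if (ch$q_strand == "-") {
    start <- ch$q_size - q_hi
    end <- ch$q_size - q_lo
    strand <- if (interval$strand == "+") "-" else "+"
  } else {
    start <- q_lo; end <- q_hi; strand <- interval$strand
  }
  genomic_interval(ch$q_name, start, end, strand)
}

# internal: one row per exon across a transcript list
exon_catalog <- function(transcripts) {
  rows <- lapply(transcripts, function(tx) {
    data.frame(tx = tx$id, exon_index = seq_len(nrow(tx$exons)),
               chrom = tx$chrom, strand = tx$strand,
               start = tx$exons$start, end = tx$exons$end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

match_event <- function(summaries, chrom, start, end) {
  if (is.null(summaries)) return(NULL)
  hit <- summaries$chrom == chrom & summaries$exon_start == start &
    summaries$exon_end == end
  if (!any(hit)) return(NULL)
  summaries[which(hit)[1L], , drop = FALSE]
}

#' Build the orthologous-exon table
#'
#' Maps every internal exon of species A through the chains; a pair is
#' emitted when the mapped interval reciprocally overlaps an annotated
#' species-B exon (overlap at least `min_ratio` of both the mapped
#' interval and the B exon). Duplicate pairs arising from the same exon
#' in multiple transcript contexts (different flanking exons) are
#' deduplicated, keeping the first in input order. PSI and class labels
#' are attached from the event summaries where the exon coordinates
#' match.
#'
#' @param transcripts_a,transcripts_b Lists of [transcript_model]s.
#' @param chains Chain alignments from species A to species B.
#' @param events_a,events_b Filtered event summary tables with columns
#'   `chrom`, `exon_start`, `exon_end`, `mean_psi`, `class` (e.g. built
#'   by [summarize_events()] joined to exon coordinates); may be `NULL`.
#' @param min_ratio Mapping and reciprocal-overlap threshold.
#' @return `data.frame` with one row per ortholog pair (transcript ids,
#'   exon indices, coordinates, `psi_a`, `psi_b`, `class_a`, `class_b`).
#'   Unmapped species-A exons are reported in the `"unmapped"` attribute.
#' @export
build_ortholog_table <- function(transcripts_a, transcripts_b, chains,
                                 events_a = NULL, events_b = NULL,
                                 min_ratio = 0.9) {
  cat_a <- exon_catalog(transcripts_a)
  cat_b <- exon_catalog(transcripts_b)
  internal_a <- cat_a[cat_a$exon_index > 1L, , drop = FALSE]
  pairs <- list()
  unmapped <- list()
  seen <- character()
  for (i in seq_len(nrow(internal_a))) {
    ea <- internal_a[i, ]
    iv <- genomic_interval(ea$chrom, ea$start, ea$end, ea$strand)
    mp <- map_interval(iv, chains, min_ratio)
    if (is.null(mp)) {
      unmapped[[length(unmapped) + 1L]] <- ea
      next
    }
    bx <- cat_b[cat_b$chrom == mp$chrom, , drop = FALSE]
    if (nrow(bx) > 0L) {
      ov <- pmin(bx$end, mp$end) - pmax(bx$start, mp$start)
      recip <- ov / pmax(interval_width(mp), bx$end - bx$start)
      bx <- bx[ov > 0 & recip >= min_ratio, , drop = FALSE]
    }
    if (nrow(bx) == 0L) {
      unmapped[[length(unmapped) + 1L]] <- ea
      next
    }
    eb <- bx[1L, ]
    key <- paste(ea$chrom, ea$start, ea$end, eb$chrom, eb$start, eb$end,
                 sep = ":")
    if (key %in% seen) next
    seen <- c(seen, key)
    ev_a <- match_event(events_a, ea$chrom, ea$start, ea$end)
    ev_b <- match_event(events_b, eb$chrom, eb$start, eb$end)
    pairs[[length(pairs) + 1L]] <- data.frame(
      tx_a = ea$tx, exon_index_a = ea$exon_index, chrom_a = ea$chrom,
      start_a = ea$start, end_a = ea$end, strand_a = ea$strand,
      tx_b = eb$tx, exon_index_b = eb$exon_index, chrom_b = eb$chrom,
      start_b = eb$start, end_b = eb$end, strand_b = eb$strand,
      psi_a = if (is.null(ev_a)) NA_real_ else ev_a$mean_psi,
      psi_b = if (is.null(ev_b)) NA_real_ else ev_b$mean_psi,
      class_a = if (is.null(ev_a)) "unclassified" else ev_a$class,
      class_b = if (is.null(ev_b)) "unclassified" else ev_b$class,
      stringsAsFactors = FALSE)
  }
  out <- if (length(pairs) > 0L) do.call(rbind, pairs) else
    data.frame(tx_a = character(), exon_index_a = integer(),
               chrom_a = character(), start_a = integer(),
               end_a = integer(), strand_a = character(),
               tx_b = character(), exon_index_b = integer(),
               chrom_b = character(), start_b = integer(),
               end_b = integer(), strand_b = character(),
               psi_a = numeric(), psi_b = numeric(),
               class_a = character(), class_b = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "unmapped") <- if (length(unmapped) > 0L)
    do.call(rbind, unmapped) else NULL
  out
}

#' Partition ortholog pairs into species-exclusive sets
#'
#' A pair is A-exclusive when the exon is alternative in species A,
#' constitutive in species B and (when the threshold is enabled) the PSI
#' difference is at least `delta_psi_min`; symmetrically for B-exclusive.
#' Remaining pairs are labeled both-alternative, both-constitutive, or
#' unclassified (including pairs with missing PSI and exclusive-pattern
#' pairs failing the PSI-difference threshold).
#'
#' @param pairs `data.frame` from [build_ortholog_table()].
#' @param delta_psi_min Minimal |psi_a - psi_b| for exclusivity
#'   (default 0.2; 0.15 is a commonly used softer choice).
#' @param apply_delta Apply the PSI-difference threshold (default `TRUE`).
#' @return `pairs` with an `exclusivity` column added. The partition is
#'   exhaustive and mutually exclusive.
#' @export
species_exclusive_sets <- function(pairs, delta_psi_min = 0.2,
                                   apply_delta = TRUE) {
  dpsi <- abs(pairs$psi_a - pairs$psi_b)
  delta_ok <- if (apply_delta) !is.na(dpsi) & dpsi >= delta_psi_min
              else rep(TRUE, nrow(pairs))
  lab <- rep("unclassified", nrow(pairs))
  lab[pairs$class_a == "alternative" & pairs$class_b == "alternative"] <-
    "both-alternative"
  lab[pairs$class_a == "constitutive" & pairs$class_b == "constitutive"] <-
    "both-constitutive"
  a_ex <- pairs$class_a == "alternative" &
    pairs$class_b == "constitutive" & delta_ok
  b_ex <- pairs$class_b == "alternative" &
    pairs$class_a == "constitutive" & delta_ok
  lab[a_ex] <- "A-exclusive"
  lab[b_ex] <- "B-exclusive"
  pairs$exclusivity <- lab
  pairs
}

# internal: element scores of one exon in one species
element_scores <- function(transcripts, tx_id, exon_index, genome,
                           bp_model, donor_model, acceptor_model,
                           min_dist = 10L, max_dist = 100L) {
  out <- c(bp_seq = NA_real_, bp_motif = NA_real_, ss3 = NA_real_,
           ss5 = NA_real_)
  tx <- transcripts[[tx_id]]
  if (is.null(tx) || !tx$chrom %in% names(genome)) return(out)
  intron <- tryCatch(extract_intron_upstream(tx, exon_index, genome),
                     error = function(e) NULL)
  if (!is.null(intron)) {
    bp <- tryCatch(best_branchpoint(intron$seq, bp_model, min_dist,
                                    max_dist),
                   error = function(e) NULL)
    if (!is.null(bp)) {
      out["bp_seq"] <- bp$score
      out["bp_motif"] <- bp$score +
        bp_distance_logodds(bp$distance, min_dist, max_dist)
    }
  }
  if (!is.null(acceptor_model)) {
    w <- tryCatch(acceptor_window(tx, exon_index, genome),
                  error = function(e) NULL)
    if (!is.null(w))
      out["ss3"] <- tryCatch(suppressWarnings(score_3ss(w, acceptor_model)),
                             error = function(e) NA_real_)
  }
  if (!is.null(donor_model)) {
    w <- tryCatch(donor_window(tx, exon_index, genome),
                  error = function(e) NULL)
    if (!is.null(w))
      out["ss5"] <- tryCatch(suppressWarnings(score_5ss(w, donor_model)),
                             error = function(e) NA_real_)
  }
  out
}

#' Attach splicing-element scores to ortholog pairs
#'
#' For each pair and each species: branch-point sequence score (best
#' candidate under `bp_model`), branch-point motif score (sequence score
#' plus the distance log-odds of [bp_distance_logodds()]), and 3'/5'
#' splice-site scores under the supplied maximum-entropy models. Missing
#' sequence or absent candidates leave `NA`s; the pair is retained.
#' With `include_flanks = TRUE` the same scores are also computed for
#' the flanking upstream and downstream exons.
#'
#' @param pairs `data.frame` from [build_ortholog_table()].
#' @param transcripts_a,transcripts_b Named transcript lists.
#' @param genome_a,genome_b Named chromosome sequence vectors.
#' @param bp_model Branch-point model (default [default_bp_model()]).
#' @param donor_model,acceptor_model `maxent_model`s or `NULL` to skip
#'   splice-site scoring.
#' @param include_flanks Also score the flanking exons (columns prefixed
#'   `up_`/`dn_`).
#' @return `pairs` with columns `bp_seq_a/b`, `bp_motif_a/b`, `ss3_a/b`,
#'   `ss5_a/b` (and flank columns when requested).
#' @export
attach_element_scores <- function(pairs, transcripts_a, transcripts_b,
                                  genome_a, genome_b,
                                  bp_model = default_bp_model(),
                                  donor_model = NULL,
                                  acceptor_model = NULL,
                                  include_flanks = FALSE) {
  score_side <- function(transcripts, genome, tx_col, idx_col, offset = 0L) {
    t(vapply(seq_len(nrow(pairs)), function(i) {
      element_scores(transcripts, pairs[[tx_col]][i],
                     pairs[[idx_col]][i] + offset, genome, bp_model,
                     donor_model, acceptor_model)
    }, numeric(4)))
  }
  add <- function(mat, suffix, prefix = "") {
    colnames(mat) <- paste0(prefix, c("bp_seq", "bp_motif", "ss3", "ss5"),
                            suffix)
    cbind(pairs, as.data.frame(mat))
  }
  if (nrow(pairs) == 0L) {
    for (nm in c("bp_seq_a", "bp_motif_a", "ss3_a", "ss5_a",
                 "bp_seq_b", "bp_motif_b", "ss3_b", "ss5_b"))
      pairs[[nm]] <- numeric(0)
    return(pairs)
  }
  pairs <- add(score_side(transcripts_a, genome_a, "tx_a", "exon_index_a"),
               "_a")
  pairs <- add(score_side(transcripts_b, genome_b, "tx_b", "exon_index_b"),
               "_b")
  if (include_flanks) {
    pairs <- add(score_side(transcripts_a, genome_a, "tx_a",
                            "exon_index_a", -1L), "_a", "up_")
    pairs <- add(score_side(transcripts_a, genome_a, "tx_a",
                            "exon_index_a", 1L), "_a", "dn_")
    pairs <- add(score_side(transcripts_b, genome_b, "tx_b",
                            "exon_index_b", -1L), "_b", "up_")
    pairs <- add(score_side(transcripts_b, genome_b, "tx_b",
                            "exon_index_b", 1L), "_b", "dn_")
  }
  pairs
}
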