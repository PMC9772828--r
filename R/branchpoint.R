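# Branch-point candidate enumeration and scoring in the 3' region of an
# intron. A candidate is an adenine presented as a 9-nt window (nonamer)
# with the branch-point adenine at position 6 (five nt upstream, three nt
# downstream), the registration consistent with the conserved CCTAA core
# at nonamer positions 2-6. Distance convention: distance = number of
# intron nucleotides strictly 3' of the branch-point adenine, i.e.
# L - 1 - p for a 0-based adenine index p in an intron of length L.

#' Compute the AG dinucleotide exclusion zone (AGEZ) of an intron
#'
#' The AGEZ is the maximal region immediately upstream of the terminal
#' 3' splice-site AG that contains no other AG dinucleotide. Functional
#' branch points typically lie within it.
#'
#' @param intron_seq Intron sequence ending with the 3' splice-site
#'   dinucleotide AG; at least 4 nt.
#' @param on_no_ag What to do when the intron does not end in AG:
#'   `"error"` (default) or `"warn"` (warn and compute the zone upstream
#'   of the final two nucleotides anyway).
#' @return Integer length of the AGEZ in nucleotides.
#' @export
compute_agez <- function(intron_seq, on_no_ag = c("error", "warn")) {
  on_no_ag <- match.arg(on_no_ag)
  intron_seq <- toupper(intron_seq)
  L <- nchar(intron_seq)
  if (L < 4L) stop("intron shorter than 4 nt")
  if (substr(intron_seq, L - 1L, L) != "AG") {
    msg <- "intron does not end in the 3' splice-site AG"
    if (on_no_ag == "error") stop(msg) else warning(msg)
  }
  body <- substr(intron_seq, 1L, L - 2L)
  hits <- gregexpr("(?=AG)", body, perl = TRUE)[[1L]]
  hits <- hits[hits > 0L]
  # an AG must lie fully within the body (start <= L - 3 in 1-based terms)
  hits <- hits[hits <= L - 3L]
  if (length(hits) == 0L) return(L - 2L)
  nearest_end <- max(hits) + 1L   # 1-based end of the closest upstream AG
  (L - 2L) - nearest_end
}

#' Enumerate branch-point candidates in an intron
#'
#' One candidate per adenine whose distance to the 3' splice site lies in
#' `[min_dist, max_dist]`, with a full N-free 9-nt window available.
#' Candidates are sorted by increasing distance. The terminal splice-site
#' AG never yields a candidate.
#'
#' @param intron_seq Intron sequence (5' to 3', ending with the 3' splice
#'   site AG).
#' @param min_dist,max_dist Distance window (nt from the branch-point
#'   adenine to the 3' splice site); defaults 10 and 100.
#' @return `data.frame` with columns `pos` (0-based index of the adenine
#'   within the intron), `nonamer`, `distance`, `agez`, `in_agez`. Zero
#'   rows when no candidate exists.
#' @export
enumerate_bp_candidates <- function(intron_seq, min_dist = 10L,
                                    max_dist = 100L) {
  stopifnot(min_dist >= 1L, max_dist >= min_dist)
  intron_seq <- toupper(intron_seq)
  L <- nchar(intron_seq)
  empty <- data.frame(pos = integer(), nonamer = character(),
                      distance = integer(), agez = integer(),
                      in_agez = logical())
  if (L < 9L) return(empty)
  agez <- compute_agez(intron_seq, on_no_ag = "warn")
  chars <- strsplit(intron_seq, "", fixed = TRUE)[[1L]]
  a_pos <- which(chars == "A") - 1L            # 0-based
  a_pos <- a_pos[a_pos < L - 2L]               # never the terminal AG
  dist <- L - 1L - a_pos
  keep <- dist >= min_dist & dist <= max_dist &
    a_pos >= 5L & a_pos + 3L <= L - 1L
  a_pos <- a_pos[keep]; dist <- dist[keep]
  if (length(a_pos) == 0L) return(empty)
  nonamer <- substr(rep(intron_seq, length(a_pos)), a_pos - 4L, a_pos + 4L)
  ok <- !grepl("N", nonamer, fixed = TRUE)
  a_pos <- a_pos[ok]; dist <- dist[ok]; nonamer <- nonamer[ok]
  if (length(a_pos) == 0L) return(empty)
  o <- order(dist)
  data.frame(pos = a_pos[o], nonamer = nonamer[o], distance = dist[o],
             agez = agez, in_agez = dist[o] <= agez + 1L)
}

#' Build a position weight matrix branch-point model
#'
#' Log-odds model over the 9-nt branch-point window: the score of a
#' nonamer is `sum over positions of log2(p_pos(base) / background(base))`.
#'
#' @param nonamers Character vector of 9-nt training sequences (adenine at
#'   position 6).
#' @param background Named per-base background probabilities, summing to 1.
#' @param pseudocount Added to every cell before normalization.
#' @return Object of class `bp_model` with `kind = "pwm"`.
#' @export
bp_model_pwm <- function(nonamers,
                         background = c(A = 0.25, C = 0.25, G = 0.25,
                                        T = 0.25),
                         pseudocount = 0.5) {
  stopifnot(all(nchar(nonamers) == 9L))
  nonamers <- toupper(nonamers)
  if (any(substr(nonamers, 6L, 6L) != "A"))
    stop("training nonamers must have the branch-point adenine at position 6")
  if (abs(sum(background) - 1) > 1e-8)
    stop("background must sum to 1")
  bases <- c("A", "C", "G", "T")
  mat <- matrix(pseudocount, nrow = 4L, ncol = 9L,
                dimnames = list(bases, NULL))
  for (s in nonamers) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (j in 1:9) mat[ch[j], j] <- mat[ch[j], j] + 1
  }
  mat <- sweep(mat, 2L, colSums(mat), "/")
  structure(list(kind = "pwm", pwm = mat, background = background[bases],
                 floor = -Inf),
            class = "bp_model")
}

#' Load a precomputed branch-point score table
#'
#' Supports published scaled-vector (SVM) branch-point scores supplied as
#' a tab-separated table with columns `nonamer`, `distance`, `agez`,
#' `score`. Scoring looks candidates up by nonamer and distance; a
#' candidate absent from the table gets `NA`.
#'
#' @param path Path to the TSV score table.
#' @param floor Acceptance floor for [best_branchpoint()] (default 0, the
#'   usual decision-value cutoff for SVM scores).
#' @return Object of class `bp_model` with `kind = "table"`.
#' @export
bp_model_table <- function(path, floor = 0) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("nonamer", "distance", "score") %in% names(tab)))
  tab$nonamer <- toupper(tab$nonamer)
  structure(list(kind = "table", table = tab, floor = floor),
            class = "bp_model")
}

#' Default bundled branch-point model
#'
#' A PWM log-odds model trained on the bundled CAMK2B exon 16 branch-point
#' nonamers (see [camk2b_branchpoints()]) with a uniform background. This
#' desk-scale model preserves the ranking structure of branch-point
#' strength; reproducing published scaled-vector decision values requires
#' the published classifier's model files via [bp_model_table()].
#'
#' @return A `bp_model`.
#' @export
default_bp_model <- function() {
  bp_model_pwm(camk2b_branchpoints()$nonamer)
}

#' Reported CAMK2B exon 16 branch points
#'
#' The bundled table of branch-point calls for the intron upstream of
#' CAMK2B exon 16 in five vertebrate contexts: AGEZ length, distance of
#' the branch-point adenine to the 3' splice site, nonamer sequence and
#' the published scaled-vector model score.
#'
#' @return `data.frame` with columns `species`, `agez`, `distance`,
#'   `nonamer`, `svb_score`.
#' @export
camk2b_branchpoints <- function() {
  path <- system.file("extdata", "camk2b_exon16_branchpoints.tsv",
                      package = "orthosplice", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$nonamer <- toupper(tab$nonamer)
  tab
}

#' Score branch-point candidates under a model
#'
#' @param candidates `data.frame` from [enumerate_bp_candidates()], or a
#'   single nonamer string.
#' @param model A `bp_model`.
#' @return The candidate `data.frame` with a `score` column appended (or a
#'   numeric scalar when `candidates` is a single string).
#' @export
score_bp_candidates <- function(candidates, model) {
  stopifnot(inherits(model, "bp_model"))
  if (is.character(candidates)) {
    stopifnot(length(candidates) == 1L)
    return(score_one_nonamer(toupper(candidates), NA_integer_, model))
  }
  if (nrow(candidates) == 0L) {
    candidates$score <- numeric()
    return(candidates)
  }
  candidates$score <- vapply(seq_len(nrow(candidates)), function(i) {
    score_one_nonamer(candidates$nonamer[i], candidates$distance[i], model)
  }, numeric(1))
  candidates
}

score_one_nonamer <- function(nonamer, distance, model) {
  if (nchar(nonamer) != 9L) stop("nonamer must be 9 nt")
  if (grepl("N", nonamer, fixed = TRUE))
    stop("score undefined: N in nonamer window")
  if (model$kind == "pwm") {
    ch <- strsplit(nonamer, "", fixed = TRUE)[[1L]]
    sum(vapply(1:9, function(j)
      log2(model$pwm[ch[j], j] / model$background[[ch[j]]]), numeric(1)))
  } else {
    hit <- model$table$nonamer == nonamer &
      (is.na(distance) | model$table$distance == distance)
    if (!any(hit)) NA_real_ else model$table$score[which(hit)[1L]]
  }
}

#' Log2-odds of a branch-point distance under the bundled distance prior
#'
#' Used to form the branch-point *motif* score, which augments the
#' sequence score with the distance to the 3' splice site. The prior is a
#' gamma density (shape 4, scale 7; mode 21 nt) over the search window,
#' compared against a uniform background on `[min_dist, max_dist]`.
#'
#' @param distance Distance(s) in nt from the branch-point adenine to the
#'   3' splice site.
#' @param min_dist,max_dist Search window used as the uniform background.
#' @return Numeric log2-odds, same length as `distance`.
#' @export
bp_distance_logodds <- function(distance, min_dist = 10L, max_dist = 100L) {
  prior <- stats::dgamma(distance, shape = 4, scale = 7)
  norm <- sum(stats::dgamma(min_dist:max_dist, shape = 4, scale = 7))
  log2((prior / norm) / (1 / (max_dist - min_dist + 1L)))
}

#' Best branch point of an intron
#'
#' The highest-scoring candidate; ties are broken by smaller distance.
#' Returns `NULL` when no candidate scores above the model's acceptance
#' floor (always `-Inf` for PWM models, 0 by default for score tables).
#'
#' @inheritParams enumerate_bp_candidates
#' @param model A `bp_model`.
#' @return One-row candidate `data.frame` with score, or `NULL`.
#' @export
best_branchpoint <- function(intron_seq, model = default_bp_model(),
                             min_dist = 10L, max_dist = 100L) {
  cand <- enumerate_bp_candidates(intron_seq, min_dist, max_dist)
  if (nrow(cand) == 0L) return(NULL)
  cand <- score_bp_candidates(cand, model)
  cand <- cand[!is.na(cand$score) & cand$score > model$floor, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  # order() on (-score, distance): max score, ties to the smaller distance
  best <- cand[order(-cand$score, cand$distance)[1L], , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Summed branch-point strength around the top candidate
#'
#' Sums the scores of all candidates whose branch-point adenines lie
#' within `proximity_window` nt of the top-scoring candidate (the top
#' candidate included). Captures introns where several nearby weak branch
#' points jointly provide the strength of a single strong one.
#'
#' @param scored Candidate `data.frame` with a `score` column
#'   (from [score_bp_candidates()]), all from one intron.
#' @param proximity_window Maximal distance (nt) between a candidate's
#'   adenine and the top candidate's adenine.
#' @return Numeric summed score.
#' @export
summed_bp_strength <- function(scored, proximity_window = 5L) {
  if (!is.data.frame(scored) || nrow(scored) == 0L)
    stop("no branch-point candidates to sum")
  stopifnot("score" %in% names(scored))
  top <- order(-scored$score, scored$distance)[1L]
  near <- abs(scored$distance - scored$distance[top]) <= proximity_window
  sum(scored$score[near])
}

#' Scan point mutations of the best branch-point nonamer
#'
#' For each requested nonamer position (1-9 of the current best
#' candidate) and each substitution, the intron is mutated, candidates
#' are re-enumerated and re-scored, and the new best score is reported
#' together with its change versus wild type. Mutating the branch-point
#' adenine itself removes that candidate from enumeration, so the new
#' best is whatever other candidate remains (or `NA` if none).
#'
#' @inheritParams best_branchpoint
#' @param positions Integer positions in 1-9 (nonamer coordinates of the
#'   current best candidate).
#' @return `data.frame` with columns `position`, `ref`, `alt`,
#'   `mut_nonamer`, `best_score`, `delta` (new best minus wild-type best).
#' @export
scan_bp_mutations <- function(intron_seq, model = default_bp_model(),
                              positions = 1:9, min_dist = 10L,
                              max_dist = 100L) {
  if (any(positions < 1L | positions > 9L))
    stop("positions must lie in 1..9")
  wt <- best_branchpoint(intron_seq, model, min_dist, max_dist)
  if (is.null(wt)) stop("no wild-type branch point to mutate")
  intron_seq <- toupper(intron_seq)
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (j in positions) {
    idx <- wt$pos - 6L + j               # 0-based intron index of nonamer pos j
    ref <- substr(intron_seq, idx + 1L, idx + 1L)
    for (alt in bases) {
      mut <- intron_seq
      substr(mut, idx + 1L, idx + 1L) <- alt
      nb <- best_branchpoint(mut, model, min_dist, max_dist)
      ns <- if (is.null(nb)) NA_real_ else nb$score
      mut_nonamer <- wt$nonamer
      substr(mut_nonamer, j, j) <- alt
      rows[[length(rows) + 1L]] <- data.frame(
        position = j, ref = ref, alt = alt, mut_nonamer = mut_nonamer,
        best_score = ns, delta = ns - wt$score)
    }
  }
  do.call(rbind, rows)
}
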