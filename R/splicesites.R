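# Maximum-entropy splice-site scoring. A model assigns each admissible
# window sequence a probability, factorized into component distributions
# over position subsets; the reported score is log2 of the ratio between
# the model probability and a per-base background, the convention of the
# published maximum-entropy splice-site tools. Windows follow the
# published layout: donor = last 3 exonic + first 6 intronic nt (9-mer,
# GT at intronic positions 1-2); acceptor = last 20 intronic + first 3
# exonic nt (23-mer, AG at intronic positions 19-20).

all_kmers <- function(k, alphabet = c("A", "C", "G", "T")) {
  if (k == 0L) return("")
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), k),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  # vary the first position slowest so kmers come out in dictionary order
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste, collapse = "")
}

#' Construct a maximum-entropy splice-site model
#'
#' @param site_kind `"donor"` or `"acceptor"`.
#' @param window Window length (9 for donor, 23 for acceptor under the
#'   published convention; toy lengths are allowed).
#' @param components List of components, each a list with `positions`
#'   (integer vector of window positions) and `probs` (named numeric
#'   vector over the k-mers at those positions, summing to 1). The model
#'   probability of a window is the product over components.
#' @param background Named per-base background probabilities.
#' @param check_consensus If `TRUE`, [score_5ss()] / [score_3ss()] warn on
#'   windows violating the GT/AG consensus; `"strict"` makes that an error;
#'   `FALSE` disables the check.
#' @return Object of class `maxent_model`.
#' @export
maxent_model <- function(site_kind = c("donor", "acceptor"),
                         window,
                         components,
                         background = c(A = 0.25, C = 0.25, G = 0.25,
                                        T = 0.25),
                         check_consensus = TRUE) {
  site_kind <- match.arg(site_kind)
  stopifnot(length(components) >= 1L)
  for (comp in components) {
    stopifnot(all(comp$positions >= 1L), all(comp$positions <= window))
    if (abs(sum(comp$probs) - 1) > 1e-6)
      stop("component distribution does not sum to 1")
    if (any(nchar(names(comp$probs)) != length(comp$positions)))
      stop("component k-mer names inconsistent with its positions")
  }
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  structure(list(site_kind = site_kind, window = as.integer(window),
                 components = components,
                 background = background[c("A", "C", "G", "T")],
                 check_consensus = check_consensus),
            class = "maxent_model")
}

#' Build a maxent model from a full joint distribution
#'
#' Convenience wrapper for toy models and for distributions produced by
#' [train_maxent()].
#'
#' @inheritParams maxent_model
#' @param probs Named numeric vector over all window k-mers, summing to 1.
#' @return A `maxent_model`.
#' @export
maxent_model_from_joint <- function(site_kind, probs,
                                    background = c(A = 0.25, C = 0.25,
                                                   G = 0.25, T = 0.25),
                                    check_consensus = FALSE) {
  k <- unique(nchar(names(probs)))
  stopifnot(length(k) == 1L)
  maxent_model(site_kind, window = k,
               components = list(list(positions = seq_len(k), probs = probs)),
               background = background, check_consensus = check_consensus)
}

score_window <- function(window, model, strict = FALSE) {
  stopifnot(inherits(model, "maxent_model"))
  window <- toupper(window)
  if (nchar(window) != model$window)
    stop("window must be ", model$window, " nt, got ", nchar(window))
  if (grepl("[^ACGT]", window))
    stop("window contains characters outside A/C/G/T")
  if (!isFALSE(model$check_consensus)) {
    viol <- consensus_violation(window, model)
    if (!is.null(viol)) {
      if (strict || identical(model$check_consensus, "strict"))
        stop(viol)
      warning(viol)
    }
  }
  ch <- strsplit(window, "", fixed = TRUE)[[1L]]
  logp <- 0
  for (comp in model$components) {
    kmer <- paste(ch[comp$positions], collapse = "")
    p <- comp$probs[[kmer]]
    if (is.null(p) || is.na(p)) stop("window k-mer ", kmer,
                                     " not covered by model component")
    logp <- logp + log2(p)
  }
  logbg <- sum(log2(model$background[ch]))
  unname(logp - logbg)
}

consensus_violation <- function(window, model) {
  if (model$site_kind == "donor" && model$window == 9L) {
    if (substr(window, 4L, 5L) != "GT")
      return(paste0("non-canonical donor: expected GT at intronic ",
                    "positions 1-2, got ", substr(window, 4L, 5L)))
  }
  if (model$site_kind == "acceptor" && model$window == 23L) {
    if (substr(window, 19L, 20L) != "AG")
      return(paste0("non-canonical acceptor: expected AG at intronic ",
                    "positions 19-20, got ", substr(window, 19L, 20L)))
  }
  NULL
}

#' Score a 5' splice-site (donor) window
#'
#' @param window9 Donor window: last 3 exonic + first 6 intronic nt
#'   (for models of the standard 9-nt window), N-free.
#' @param model A donor `maxent_model`.
#' @param strict Error instead of warn on non-canonical GT.
#' @return log2 odds score (model vs background).
#' @export
score_5ss <- function(window9, model, strict = FALSE) {
  if (model$site_kind != "donor") stop("model is not a donor model")
  score_window(window9, model, strict)
}

#' Score a 3' splice-site (acceptor) window
#'
#' @param window23 Acceptor window: last 20 intronic + first 3 exonic nt
#'   (for models of the standard 23-nt window), N-free.
#' @param model An acceptor `maxent_model`.
#' @param strict Error instead of warn on non-canonical AG.
#' @return log2 odds score (model vs background).
#' @export
score_3ss <- function(window23, model, strict = FALSE) {
  if (model$site_kind != "acceptor") stop("model is not an acceptor model")
  score_window(window23, model, strict)
}

#' Train a maximum-entropy distribution by iterative scaling
#'
#' Finds the maximum-entropy joint distribution over windows of length
#' `window` (full-table representation, so desk scale: `window <= 6`)
#' whose marginals match the given constraints, via iterative
#' proportional fitting from the uniform distribution.
#'
#' @param constraints List of constraints, each a list with `positions`
#'   (integer vector) and `probs` (named numeric vector over the k-mers
#'   at those positions, summing to 1).
#' @param window Window length.
#' @param alphabet Symbol set (default DNA).
#' @param tol Convergence tolerance on the maximal absolute deviation of
#'   any constrained marginal.
#' @param max_iter Maximal number of scaling sweeps.
#' @return Named numeric vector: the fitted distribution over all window
#'   k-mers, with attribute `iterations`.
#' @export
train_maxent <- function(constraints, window,
                         alphabet = c("A", "C", "G", "T"),
                         tol = 1e-8, max_iter = 1000L) {
  if (window > 6L) stop("full-table training is desk scale: window <= 6")
  for (con in constraints) {
    if (abs(sum(con$probs) - 1) > 1e-6)
      stop("constraint marginal does not sum to 1")
    if (any(con$positions < 1L | con$positions > window))
      stop("constraint positions outside window")
  }
  kmers <- all_kmers(window, alphabet)
  p <- rep(1 / length(kmers), length(kmers))
  names(p) <- kmers
  # precompute, per constraint, the membership of each window in a cell
  memb <- lapply(constraints, function(con) {
    sub <- vapply(strsplit(kmers, "", fixed = TRUE), function(ch)
      paste(ch[con$positions], collapse = ""), character(1))
    split(seq_along(kmers), factor(sub, levels = names(con$probs)))
  })
  for (it in seq_len(max_iter)) {
    dev <- 0
    for (ci in seq_along(constraints)) {
      target <- constraints[[ci]]$probs
      for (cell in names(target)) {
        idx <- memb[[ci]][[cell]]
        cur <- sum(p[idx])
        dev <- max(dev, abs(cur - target[[cell]]))
        if (target[[cell]] == 0) {
          p[idx] <- 0
        } else if (cur > 0) {
          p[idx] <- p[idx] * (target[[cell]] / cur)
        } else {
          stop("inconsistent constraints: required mass on an ",
               "impossible cell (", cell, ")")
        }
      }
    }
    p <- p / sum(p)
    # convergence check on fresh marginals
    dev <- 0
    for (ci in seq_along(constraints)) {
      target <- constraints[[ci]]$probs
      got <- vapply(names(target), function(cell)
        sum(p[memb[[ci]][[cell]]]), numeric(1))
      dev <- max(dev, max(abs(got - unlist(target))))
    }
    if (dev < tol) {
      attr(p, "iterations") <- it
      return(p)
    }
  }
  stop("iterative scaling did not converge after ", max_iter,
       " sweeps (residual ", signif(dev, 3),
       "); constraints may be inconsistent")
}

#' Extract the donor (5' splice site) window of an exon
#'
#' Last 3 exonic + first 6 intronic nucleotides at the exon's 3' end, in
#' transcription orientation.
#'
#' @param transcript A [transcript_model].
#' @param exon_index Exon index in transcription order; must have a
#'   downstream intron.
#' @param genome Named character vector of chromosome sequences.
#' @return 9-nt character window.
#' @export
donor_window <- function(transcript, exon_index, genome) {
  n <- nrow(transcript$exons)
  if (exon_index < 1L || exon_index >= n)
    stop("exon ", exon_index, " has no downstream intron")
  ex <- transcript$exons[exon_index, ]
  chromseq <- genome[[transcript$chrom]]
  if (is.null(chromseq)) stop("chromosome absent from genome")
  if (transcript$strand == "+") {
    w <- substr(chromseq, ex$end - 2L, ex$end + 6L)
  } else {
    w <- revcomp(substr(chromseq, ex$start - 5L, ex$start + 3L))
  }
  if (nchar(w) != 9L) stop("donor window truncated by sequence end")
  w
}

#' Extract the acceptor (3' splice site) window of an exon
#'
#' Last 20 intronic + first 3 exonic nucleotides at the exon's 5' end, in
#' transcription orientation.
#'
#' @inheritParams donor_window
#' @param exon_index Exon index in transcription order; must have an
#'   upstream intron.
#' @return 23-nt character window.
#' @export
acceptor_window <- function(transcript, exon_index, genome) {
  n <- nrow(transcript$exons)
  if (exon_index < 2L || exon_index > n)
    stop("exon ", exon_index, " has no upstream intron")
  ex <- transcript$exons[exon_index, ]
  chromseq <- genome[[transcript$chrom]]
  if (is.null(chromseq)) stop("chromosome absent from genome")
  if (transcript$strand == "+") {
    w <- substr(chromseq, ex$start - 19L, ex$start + 3L)
  } else {
    w <- revcomp(substr(chromseq, ex$end - 2L, ex$end + 20L))
  }
  if (nchar(w) != 23L) stop("acceptor window truncated by sequence end")
  w
}
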