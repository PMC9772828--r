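# Sequence and annotation I/O plus the coordinate model shared by all other
# modules. All internal coordinates are 0-based half-open ([start, end));
# GFF3 I/O converts at the boundary, BED output stays 0-based half-open.

#' Create a genomic interval
#'
#' Intervals are 0-based half-open, the convention used internally
#' throughout the package. `start` is the 0-based position of the first
#' base, `end` the position one past the last base.
#'
#' @param chrom Sequence (chromosome) name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:[%d,%d)/%s\n", x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

interval_width <- function(x) x$end - x$start

#' Create a transcript model
#'
#' A transcript is an ordered set of non-overlapping exons on one
#' chromosome and strand. Exons are stored in transcription order
#' (5' to 3' of the mRNA), so for minus-strand transcripts the first
#' exon has the largest genomic coordinates.
#'
#' @param id Transcript identifier.
#' @param gene Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with integer columns `start`, `end`
#'   (0-based half-open, genomic coordinates), one row per exon, in any
#'   order; they are sorted into transcription order.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(id, gene, chrom, strand, exons) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            nrow(exons) >= 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  if (any(exons$start < 0L) || any(exons$start >= exons$end))
    stop("transcript ", id, ": invalid exon coordinates")
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("transcript ", id, ": overlapping exons")
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  rownames(exons) <- NULL
  structure(list(id = id, gene = gene, chrom = chrom, strand = strand,
                 exons = exons),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript %s (gene %s) %s/%s, %d exon(s)\n",
              x$id, x$gene, x$chrom, x$strand, nrow(x$exons)))
  invisible(x)
}

#' Read a FASTA file
#'
#' Sequences are uppercased on read (soft-masking is ignored) and the
#' alphabet is restricted to A, C, G, T, N. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path),
             error = function(e) stop("malformed FASTA '", path, "': ",
                                      conditionMessage(e), call. = FALSE)),
    warning = function(w) {
      if (grepl("invalid one-letter sequence", conditionMessage(w)))
        stop("record in '", path,
             "' contains characters outside A/C/G/T/N", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  seqs <- toupper(as.character(set))
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stop("duplicate FASTA record name: ", nm[duplicated(nm)][1L])
  if (any(!nzchar(seqs)))
    stop("empty sequence for FASTA record: ", nm[!nzchar(seqs)][1L])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("record ", nm[bad][1L], " contains characters outside A/C/G/T/N")
  names(seqs) <- nm
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse-complement a DNA sequence
#'
#' @param seq Character scalar over the alphabet A/C/G/T/N (case-insensitive).
#' @return The reverse complement, uppercase. `N` maps to `N`.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!nzchar(seq)) return("")
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains characters outside A/C/G/T/N")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Read transcript models from a GFF3 file
#'
#' Exon features are grouped by their parent transcript. GFF3 1-based
#' inclusive coordinates are converted to the internal 0-based half-open
#' convention, and minus-strand exons are ordered in transcription order.
#'
#' @param path Path to a GFF3 file with `exon` features carrying `Parent`
#'   (or `transcript_id`) attributes.
#' @return Named list of [transcript_model] objects, keyed by transcript id.
#' @export
read_gff_transcripts <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  g <- rtracklayer::import(path, format = "gff3")
  ex <- g[g$type == "exon"]
  if (length(ex) == 0L) stop("no exon features in ", path)
  if (is.null(ex$Parent))
    stop("exon without a parent transcript in ", path)
  parents <- as.character(sapply(as.list(ex$Parent), function(p) {
    if (length(p) == 0L) NA_character_ else p[[1L]]
  }))
  if (anyNA(parents) || length(parents) != length(ex))
    stop("exon without a parent transcript in ", path)
  genes <- if (!is.null(ex$gene_id)) as.character(ex$gene_id)
           else rep(NA_character_, length(ex))
  # gene attribution via parent mRNA features when present
  mrna <- g[g$type %in% c("mRNA", "transcript")]
  gene_of_tx <- NULL
  if (length(mrna) > 0L) {
    gp <- as.character(sapply(as.list(mrna$Parent), function(p) {
      if (length(p) == 0L) NA_character_ else p[[1L]]
    }))
    gene_of_tx <- stats::setNames(gp, as.character(mrna$ID))
  }
  out <- list()
  for (tx in unique(parents)) {
    i <- which(parents == tx)
    gene <- genes[i][!is.na(genes[i])][1L]
    if (is.na(gene) && !is.null(gene_of_tx) && tx %in% names(gene_of_tx))
      gene <- unname(gene_of_tx[tx])
    if (is.na(gene)) gene <- tx
    chrom <- as.character(GenomicRanges::seqnames(ex))[i]
    strand <- as.character(GenomicRanges::strand(ex))[i]
    if (length(unique(chrom)) != 1L || length(unique(strand)) != 1L)
      stop("transcript ", tx, ": exons on multiple chromosomes or strands")
    if (!strand[1L] %in% c("+", "-"))
      stop("transcript ", tx, ": undefined strand")
    exons <- data.frame(start = GenomicRanges::start(ex)[i] - 1L,
                        end = GenomicRanges::end(ex)[i])
    out[[tx]] <- transcript_model(tx, gene, chrom[1L], strand[1L], exons)
  }
  out
}

#' Write transcript models to a GFF3 file
#'
#' Inverse of [read_gff_transcripts()]; internal 0-based half-open
#' coordinates are converted back to GFF3 1-based inclusive.
#'
#' @param transcripts List of [transcript_model] objects.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return Invisibly, `path`.
#' @export
write_gff_transcripts <- function(transcripts, path, source = "orthosplice") {
  lines <- "##gff-version 3"
  for (tx in transcripts) {
    ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
    lines <- c(lines,
      sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              tx$chrom, source, min(ex$start) + 1L, max(ex$end), tx$strand,
              tx$gene),
      sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              tx$chrom, source, min(ex$start) + 1L, max(ex$end), tx$strand,
              tx$id, tx$gene),
      sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
              tx$chrom, source, ex$start + 1L, ex$end, tx$strand,
              tx$id, seq_len(nrow(ex)), tx$id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Extract the intron upstream of an exon
#'
#' Returns the genomic sequence between the 3' end of the upstream exon
#' and the 5' start of the given exon, both in transcription order. For
#' minus-strand transcripts the sequence is reverse-complemented, so the
#' returned string always reads 5' to 3' and ends with the 3' splice-site
#' dinucleotide (canonically AG).
#'
#' @param transcript A [transcript_model].
#' @param exon_index Exon index in transcription order (1-based); must be
#'   at least 2, the first exon has no upstream intron.
#' @param genome Named character vector of chromosome sequences, as
#'   returned by [read_fasta()].
#' @return List with elements `seq` (intron sequence) and `interval`
#'   (a [genomic_interval] of the intron in genome coordinates).
#' @export
extract_intron_upstream <- function(transcript, exon_index, genome) {
  stopifnot(inherits(transcript, "transcript_model"))
  n <- nrow(transcript$exons)
  if (exon_index < 2L || exon_index > n)
    stop("exon ", exon_index, " has no upstream intron (transcript has ",
         n, " exons)")
  if (!transcript$chrom %in% names(genome))
    stop("chromosome ", transcript$chrom, " absent from genome")
  up <- transcript$exons[exon_index - 1L, ]
  ex <- transcript$exons[exon_index, ]
  if (transcript$strand == "+") {
    start <- up$end; end <- ex$start
  } else {
    start <- ex$end; end <- up$start
  }
  if (end - start < 4L)
    stop("intron upstream of exon ", exon_index, " is shorter than 4 nt")
  seq <- substr(genome[[transcript$chrom]], start + 1L, end)
  if (transcript$strand == "-") seq <- revcomp(seq)
  list(seq = seq,
       interval = genomic_interval(transcript$chrom, start, end,
                                   transcript$strand))
}

#' Read a UCSC chain file
#'
#' Parses pairwise alignment chains in UCSC chain format. Each chain
#' holds the source (`t`) and target (`q`) interval and an ordered list
#' of aligned blocks `(size, dt, dq)` where `dt`/`dq` are the unaligned
#' gaps following the block on the source/target side. Block arithmetic
#' is checked against the header spans.
#'
#' @param path Path to a chain file.
#' @return List of `chain_alignment` objects.
#' @export
read_chain <- function(path) {
  if (!file.exists(path)) stop("chain file not found: ", path)
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (f[1L] != "chain" || length(f) < 12L)
      stop("line ", i, ": expected chain header")
    hdr <- list(score = as.numeric(f[2L]),
                t_name = f[3L], t_size = as.integer(f[4L]),
                t_strand = f[5L],
                t_start = as.integer(f[6L]), t_end = as.integer(f[7L]),
                q_name = f[8L], q_size = as.integer(f[9L]),
                q_strand = f[10L],
                q_start = as.integer(f[11L]), q_end = as.integer(f[12L]),
                id = if (length(f) >= 13L) f[13L] else NA_character_)
    if (hdr$t_strand != "+")
      stop("line ", i, ": chain source strand must be '+'")
    blocks <- list()
    i <- i + 1L
    repeat {
      if (i > n) stop("truncated chain: missing final block line")
      b <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      if (length(b) == 1L && nzchar(b)) {
        blocks[[length(blocks) + 1L]] <- c(size = as.integer(b), dt = 0L,
                                           dq = 0L)
        i <- i + 1L
        break
      } else if (length(b) == 3L) {
        blocks[[length(blocks) + 1L]] <- c(size = as.integer(b[1L]),
                                           dt = as.integer(b[2L]),
                                           dq = as.integer(b[3L]))
        i <- i + 1L
      } else {
        stop("line ", i, ": malformed chain block line")
      }
    }
    bl <- do.call(rbind, blocks)
    bl <- as.data.frame(bl)
    if (any(bl$size <= 0L)) stop("chain block with non-positive size")
    t_span <- sum(bl$size) + sum(bl$dt)
    q_span <- sum(bl$size) + sum(bl$dq)
    if (t_span != hdr$t_end - hdr$t_start ||
        q_span != hdr$q_end - hdr$q_start)
      stop("chain block arithmetic inconsistent with header spans")
    chains[[length(chains) + 1L]] <-
      structure(c(hdr, list(blocks = bl)), class = "chain_alignment")
  }
  if (length(chains) == 0L) stop("no chains found in ", path)
  chains
}

#' Write chain alignments to a UCSC chain file
#'
#' @param chains List of `chain_alignment` objects as from [read_chain()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chain <- function(chains, path) {
  out <- character()
  for (k in seq_along(chains)) {
    ch <- chains[[k]]
    id <- if (is.na(ch$id)) as.character(k) else ch$id
    out <- c(out, sprintf("chain %s %s %d %s %d %d %s %d %s %d %d %s",
                          format(ch$score, scientific = FALSE),
                          ch$t_name, ch$t_size, ch$t_strand,
                          ch$t_start, ch$t_end,
                          ch$q_name, ch$q_size, ch$q_strand,
                          ch$q_start, ch$q_end, id))
    bl <- ch$blocks
    nb <- nrow(bl)
    if (nb > 1L)
      out <- c(out, sprintf("%d\t%d\t%d", bl$size[-nb], bl$dt[-nb],
                            bl$dq[-nb]))
    out <- c(out, as.character(bl$size[nb]), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Construct a chain alignment in code
#'
#' Convenience constructor used by the synthetic-data generator and in
#' tests. Gap columns `dt`/`dq` of the final block must be zero.
#'
#' @param t_name,t_size,t_start,t_end Source sequence name, length and span.
#' @param q_name,q_size,q_start,q_end Target sequence name, length and span.
#' @param blocks `data.frame` with columns `size`, `dt`, `dq`.
#' @param q_strand Target strand (`"+"` or `"-"`); chain convention puts
#'   minus-strand target coordinates on the reversed sequence.
#' @param score Chain score.
#' @param id Chain id.
#' @return A `chain_alignment` object.
#' @export
chain_alignment <- function(t_name, t_size, t_start, t_end,
                            q_name, q_size, q_start, q_end,
                            blocks, q_strand = "+", score = 1000,
                            id = NA_character_) {
  blocks <- data.frame(size = as.integer(blocks$size),
                       dt = as.integer(blocks$dt),
                       dq = as.integer(blocks$dq))
  if (any(blocks$size <= 0L)) stop("chain block sizes must be positive")
  if (sum(blocks$size) + sum(blocks$dt) != t_end - t_start ||
      sum(blocks$size) + sum(blocks$dq) != q_end - q_start)
    stop("chain block arithmetic inconsistent with spans")
  structure(list(score = score, t_name = t_name,
                 t_size = as.integer(t_size), t_strand = "+",
                 t_start = as.integer(t_start), t_end = as.integer(t_end),
                 q_name = q_name, q_size = as.integer(q_size),
                 q_strand = q_strand,
                 q_start = as.integer(q_start), q_end = as.integer(q_end),
                 id = id, blocks = blocks),
            class = "chain_alignment")
}

#' Write branch-point positions as BED6
#'
#' One line per candidate; the BED score field is the model score
#' multiplied by 100 and rounded.
#'
#' @param candidates `data.frame` of branch-point candidates (see
#'   [enumerate_bp_candidates()]) with columns `chrom`, `bp_pos`
#'   (0-based genomic position of the branch-point adenine), `strand`,
#'   `score` and `name`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bp_bed <- function(candidates, path) {
  stopifnot(all(c("chrom", "bp_pos", "strand", "score", "name") %in%
                names(candidates)))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   candidates$chrom, candidates$bp_pos,
                   candidates$bp_pos + 1L, candidates$name,
                   as.integer(round(candidates$score * 100)),
                   candidates$strand)
  writeLines(lines, path)
  invisible(path)
}
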