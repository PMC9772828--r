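test_that("read_fasta parses records, wraps lines and uppercases", {
  p <- write_tmp(c(">s1", "ACGT"), ".fa")
  expect_identical(read_fasta(p), c(s1 = "ACGT"))

  p <- write_tmp(c(">a", "AC", "GT", ">b", "TT"), ".fa")
  expect_identical(read_fasta(p), c(a = "ACGT", b = "TT"))

  p <- write_tmp(c(">soft", "acgtn"), ".fa")
  expect_identical(read_fasta(p), c(soft = "ACGTN"))
})

test_that("read_fasta rejects duplicate names and bad alphabet", {
  p <- write_tmp(c(">s1", "AC", ">s1", "GT"), ".fa")
  expect_error(read_fasta(p), "duplicate")
  p <- write_tmp(c(">s1", "ACXT"), ".fa")
  expect_error(read_fasta(p), "malformed|A/C/G/T/N")
})

test_that("FASTA write/read round-trip is the identity", {
  seqs <- c(one = strrep("ACGTN", 40), two = "TTTT")
  p <- tempfile(fileext = ".fa")
  write_fasta(seqs, p, width = 17)
  expect_identical(read_fasta(p), seqs)
})

test_that("revcomp handles palindromes, N and the empty string", {
  expect_identical(revcomp("ACGT"), "ACGT")
  expect_identical(revcomp("AAGN"), "NCTT")
  expect_identical(revcomp(""), "")
  expect_error(revcomp("ACXT"), "A/C/G/T/N")
})

test_that("GFF3 coordinates convert to 0-based half-open", {
  p <- write_tmp(c("##gff-version 3",
                   "chr1\tsrc\tmRNA\t11\t40\t.\t+\t.\tID=t1",
                   "chr1\tsrc\texon\t11\t20\t.\t+\t.\tID=e1;Parent=t1",
                   "chr1\tsrc\texon\t31\t40\t.\t+\t.\tID=e2;Parent=t1"),
                 ".gff3")
  tx <- read_gff_transcripts(p)[["t1"]]
  expect_equal(tx$exons$start, c(10L, 30L))
  expect_equal(tx$exons$end, c(20L, 40L))
})

test_that("minus-strand exons come out in transcription order", {
  p <- write_tmp(c("##gff-version 3",
                   "chr1\tsrc\tmRNA\t11\t40\t.\t-\t.\tID=t1",
                   "chr1\tsrc\texon\t11\t20\t.\t-\t.\tID=e1;Parent=t1",
                   "chr1\tsrc\texon\t31\t40\t.\t-\t.\tID=e2;Parent=t1"),
                 ".gff3")
  tx <- read_gff_transcripts(p)[["t1"]]
  expect_equal(tx$exons$start, c(30L, 10L))
  expect_equal(tx$exons$end, c(40L, 20L))
})

test_that("overlapping exons and orphan exons are rejected", {
  p <- write_tmp(c("##gff-version 3",
                   "chr1\tsrc\texon\t11\t20\t.\t+\t.\tID=e1;Parent=t1",
                   "chr1\tsrc\texon\t16\t25\t.\t+\t.\tID=e2;Parent=t1"),
                 ".gff3")
  expect_error(read_gff_transcripts(p), "overlap")
  p <- write_tmp(c("##gff-version 3",
                   "chr1\tsrc\texon\t11\t20\t.\t+\t.\tID=e1"),
                 ".gff3")
  expect_error(read_gff_transcripts(p), "parent")
})

test_that("GFF3 round-trip preserves 1-based coordinates exactly", {
  txs <- list(t1 = transcript_model("t1", "g1", "chr9", "+",
                                    data.frame(start = c(4, 99, 220),
                                               end = c(50, 150, 300))),
              t2 = transcript_model("t2", "g2", "chr9", "-",
                                    data.frame(start = c(400, 500),
                                               end = c(450, 570))))
  p <- tempfile(fileext = ".gff3")
  write_gff_transcripts(txs, p)
  back <- read_gff_transcripts(p)
  for (id in names(txs)) {
    expect_equal(back[[id]]$exons, txs[[id]]$exons)
    expect_identical(back[[id]]$strand, txs[[id]]$strand)
  }
  # and raw 1-based columns are what the models imply
  raw <- read.delim(p, header = FALSE, comment.char = "#")
  ex <- raw[raw$V3 == "exon", ]
  expect_setequal(ex$V4, c(5, 100, 221, 401, 501))
  expect_setequal(ex$V5, c(50, 150, 300, 450, 570))
})

test_that("extract_intron_upstream slices and orients the intron", {
  g <- toy_genome()
  txs <- toy_transcripts()
  plus <- extract_intron_upstream(txs$txP, 2, g)
  expect_identical(plus$seq, "GTCCAG")
  expect_equal(plus$interval$start, 4)
  expect_equal(plus$interval$end, 10)
  # same coordinates on the minus strand of the reverse-complement genome
  minus <- extract_intron_upstream(txs$txM, 2, g)
  expect_identical(minus$seq, "GTCCAG")
  expect_error(extract_intron_upstream(txs$txP, 1, g), "no upstream intron")
})

test_that("plus-strand extraction equals flipped-strand extraction on the
          reverse-complemented genome", {
  set.seed(42)
  for (i in 1:5) {
    len <- 60L
    chrom <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
    e1 <- c(0L, 10L); e2 <- c(40L, 50L)
    txp <- transcript_model("p", "g", "c", "+",
                            data.frame(start = c(e1[1], e2[1]),
                                       end = c(e1[2], e2[2])))
    # mirrored coordinates on the reverse complement
    txm <- transcript_model("m", "g", "c", "-",
                            data.frame(start = len - c(e1[2], e2[2]),
                                       end = len - c(e1[1], e2[1])))
    a <- extract_intron_upstream(txp, 2, c(c = chrom))
    b <- extract_intron_upstream(txm, 2, c(c = revcomp(chrom)))
    expect_identical(a$seq, b$seq)
  }
})

test_that("chain parsing traces blocks and validates arithmetic", {
  p <- write_tmp(c("chain 100 chrA 1000 + 0 1000 chrB 1000 + 0 1000 1",
                   "1000", ""), ".chain")
  ch <- read_chain(p)
  expect_length(ch, 1)
  expect_equal(nrow(ch[[1]]$blocks), 1)
  expect_equal(ch[[1]]$blocks$size, 1000L)

  p <- write_tmp(c("chain 100 chrA 2000 + 0 200 chrB 2100 + 0 250 1",
                   "100\t0\t50", "100", ""), ".chain")
  ch <- read_chain(p)[[1]]
  expect_equal(ch$blocks$size, c(100L, 100L))
  expect_equal(ch$blocks$dq, c(50L, 0L))

  # truncated final line
  p <- write_tmp(c("chain 100 chrA 2000 + 0 200 chrB 2100 + 0 250 1",
                   "100\t0\t50"), ".chain")
  expect_error(read_chain(p), "truncated")

  # header span disagrees with blocks
  p <- write_tmp(c("chain 100 chrA 2000 + 0 300 chrB 2100 + 0 250 1",
                   "100\t0\t50", "100", ""), ".chain")
  expect_error(read_chain(p), "inconsistent")
})

test_that("chain write/read round-trip preserves structure", {
  ch <- chain_alignment("chrA", 2000, 0, 200, "chrB", 2100, 10, 260,
                        data.frame(size = c(100, 100), dt = c(0, 0),
                                   dq = c(50, 0)), id = "7")
  p <- tempfile(fileext = ".chain")
  write_chain(list(ch), p)
  back <- read_chain(p)[[1]]
  expect_equal(back$blocks, ch$blocks)
  expect_equal(back$t_start, ch$t_start)
  expect_equal(back$q_end, ch$q_end)
})

test_that("interval and transcript invariants are enforced", {
  expect_error(genomic_interval("c", 5, 5), "start < end")
  expect_error(genomic_interval("c", -1, 5), "start < end")
  expect_error(genomic_interval("c", 1, 5, "x"), "strand")
  expect_error(transcript_model("t", "g", "c", "+",
                                data.frame(start = numeric(),
                                           end = numeric())))
})
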