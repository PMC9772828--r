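identity_chain <- function(len = 1000L) {
  chain_alignment("chrA", len, 0L, len, "chrB", len, 0L, len,
                  data.frame(size = len, dt = 0L, dq = 0L))
}

insertion_chain <- function() {
  # 50-nt target-side insertion after the first 100 aligned bases
  chain_alignment("chrA", 2000L, 0L, 200L, "chrB", 2100L, 0L, 250L,
                  data.frame(size = c(100L, 100L), dt = c(0L, 0L),
                             dq = c(50L, 0L)))
}

test_that("interval mapping projects through chain blocks", {
  iv <- genomic_interval("chrA", 100, 200)
  expect_equal(unclass(map_interval(iv, list(identity_chain())))[1:3],
               list(chrom = "chrB", start = 100L, end = 200L))
  mp <- map_interval(iv, list(insertion_chain()))
  expect_equal(mp$start, 150)
  expect_equal(mp$end, 250)
  # unknown chromosome: silently unmapped
  expect_null(map_interval(genomic_interval("chrX", 1, 10),
                           list(identity_chain())))
})

test_that("the mapped-base ratio rule drops poorly covered intervals", {
  # only the first 60 of 100 bases fall inside an aligned block
  ch <- chain_alignment("chrA", 1000L, 0L, 160L, "chrB", 1000L, 0L, 60L,
                        data.frame(size = 60L, dt = 100L, dq = 0L))
  iv <- genomic_interval("chrA", 0, 100)
  expect_null(map_interval(iv, list(ch), min_ratio = 0.9))
  expect_equal(map_interval(iv, list(ch), min_ratio = 0.5)$end, 60)
})

test_that("mapping agrees with the rtracklayer liftOver oracle", {
  ch <- insertion_chain()
  p <- tempfile(fileext = ".chain")
  write_chain(list(ch), p)
  rt <- rtracklayer::import.chain(p)
  set.seed(33)
  for (i in 1:20) {
    s <- sample(0:150, 1); w <- sample(5:40, 1)
    iv <- genomic_interval("chrA", s, s + w)
    mine <- map_interval(iv, list(ch), min_ratio = 0)
    gr <- GenomicRanges::GRanges("chrA",
                                 IRanges::IRanges(s + 1L, s + w))
    hit <- unlist(rtracklayer::liftOver(gr, rt))
    if (length(hit) == 0) {
      expect_null(mine)
    } else {
      expect_equal(mine$start, min(GenomicRanges::start(hit)) - 1L)
      expect_equal(mine$end, max(GenomicRanges::end(hit)))
    }
  }
})

test_that("minus-strand chains flip coordinates onto the forward strand", {
  # one aligned block of 100, target on the reverse strand of a 500-nt
  # chromosome; reverse-strand coords [10, 110) = forward [390, 490)
  ch <- chain_alignment("chrA", 1000L, 0L, 100L, "chrB", 500L, 10L, 110L,
                        data.frame(size = 100L, dt = 0L, dq = 0L),
                        q_strand = "-")
  mp <- map_interval(genomic_interval("chrA", 0, 100), list(ch))
  expect_equal(mp$chrom, "chrB")
  expect_equal(mp$start, 390)
  expect_equal(mp$end, 490)
  expect_equal(mp$strand, "-")
})

test_that("mapping back through the inverted chain contains the origin", {
  ch <- insertion_chain()
  inv <- chain_alignment("chrB", 2100L, 0L, 250L, "chrA", 2000L, 0L, 200L,
                         data.frame(size = c(100L, 100L), dt = c(50L, 0L),
                                    dq = c(0L, 0L)))
  iv <- genomic_interval("chrA", 20, 180)
  there <- map_interval(iv, list(ch), min_ratio = 0)
  back <- map_interval(there, list(inv), min_ratio = 0)
  expect_lte(back$start, iv$start)
  expect_gte(back$end, iv$end)
})

test_that("ortholog tables deduplicate multi-transcript contexts", {
  # the same exon [100, 160) embedded in three transcripts with
  # different flanks
  mk <- function(id, flank) transcript_model(
    id, "g", "chrA", "+",
    data.frame(start = c(flank, 100), end = c(flank + 50, 160)))
  txa <- list(t1 = mk("t1", 0), t2 = mk("t2", 10), t3 = mk("t3", 20))
  txb <- list(u1 = transcript_model("u1", "g", "chrB", "+",
                                    data.frame(start = c(0, 100),
                                               end = c(50, 160))))
  pairs <- build_ortholog_table(txa, txb, list(identity_chain()))
  expect_equal(nrow(pairs), 1)
  expect_identical(pairs$tx_a, "t1")

  # an A exon with no B counterpart lands in the unmapped side channel
  txa2 <- list(t4 = transcript_model("t4", "g", "chrA", "+",
                                     data.frame(start = c(300, 400),
                                                end = c(350, 460))))
  pairs2 <- build_ortholog_table(txa2, txb, list(identity_chain()))
  expect_equal(nrow(pairs2), 0)
  expect_equal(nrow(attr(pairs2, "unmapped")), 1)
})

test_that("species-exclusive partition follows the PSI definitions", {
  mk_pair <- function(psi_a, psi_b) data.frame(
    psi_a = psi_a, psi_b = psi_b,
    class_a = classify_exon(psi_a), class_b = classify_exon(psi_b))
  p <- species_exclusive_sets(mk_pair(0.6, 0.97))
  expect_identical(p$exclusivity, "A-exclusive")
  p <- species_exclusive_sets(mk_pair(0.97, 0.6))
  expect_identical(p$exclusivity, "B-exclusive")
  p <- species_exclusive_sets(mk_pair(0.85, 0.85))
  expect_identical(p$exclusivity, "both-alternative")
  p <- species_exclusive_sets(mk_pair(0.88, 0.95))
  expect_identical(p$exclusivity, "unclassified")  # delta 0.07 < 0.2
  p <- species_exclusive_sets(mk_pair(0.88, 0.95), apply_delta = FALSE)
  expect_identical(p$exclusivity, "A-exclusive")
  p <- species_exclusive_sets(mk_pair(0.88, 0.95), delta_psi_min = 0.05)
  expect_identical(p$exclusivity, "A-exclusive")
  missing <- data.frame(psi_a = NA_real_, psi_b = 0.95,
                        class_a = "unclassified",
                        class_b = "constitutive")
  expect_identical(species_exclusive_sets(missing)$exclusivity,
                   "unclassified")
})

test_that("the exclusivity partition is exhaustive and exclusive", {
  pair <- gen_species_pair(synth_config(seed = 21, n_genes = 25))
  res <- run_pipeline(pair)
  expect_true(all(res$pairs$exclusivity %in%
                  c("A-exclusive", "B-exclusive", "both-alternative",
                    "both-constitutive", "unclassified")))
  expect_equal(sum(table(res$pairs$exclusivity)), nrow(res$pairs))
})

test_that("element scores attach symmetrically for identical elements", {
  cfg <- synth_config(seed = 31, n_genes = 12, frac_a_exclusive = 0.25,
                      frac_b_exclusive = 0)
  pair <- gen_species_pair(cfg)
  res <- run_pipeline(pair)
  cass <- res$pairs[grepl("_t1$", res$pairs$tx_a) &
                    res$pairs$exon_index_a == 2, ]
  shared <- pair$truth$gene[pair$truth$type == "shared"]
  rows <- cass[sub("_t1", "", cass$tx_a) %in% shared, ]
  expect_true(nrow(rows) > 0)
  expect_equal(rows$bp_seq_a, rows$bp_seq_b)
  weak <- cass[sub("_t1", "", cass$tx_a) %in%
               pair$truth$gene[pair$truth$type == "A-exclusive"], ]
  expect_true(all(weak$bp_seq_a < weak$bp_seq_b))

  # recomputation is bitwise identical
  res2 <- run_pipeline(pair)
  expect_identical(res$pairs$bp_seq_a, res2$pairs$bp_seq_a)
})

test_that("missing sequence leaves scores absent but keeps the pair", {
  pair <- gen_species_pair(synth_config(seed = 41, n_genes = 4))
  genome_a <- pair$genome_a
  names(genome_a) <- "other_chrom"
  pairs <- build_ortholog_table(pair$transcripts_a, pair$transcripts_b,
                                pair$chains)
  scored <- attach_element_scores(pairs, pair$transcripts_a,
                                  pair$transcripts_b, genome_a,
                                  pair$genome_b)
  expect_true(all(is.na(scored$bp_seq_a)))
  expect_true(any(!is.na(scored$bp_seq_b)))
  expect_equal(nrow(scored), nrow(pairs))
})
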