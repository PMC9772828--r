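test_that("generation is deterministic for a fixed seed", {
  a <- gen_species_pair(synth_config(seed = 5, n_genes = 8))
  b <- gen_species_pair(synth_config(seed = 5, n_genes = 8))
  expect_identical(a, b)
  c <- gen_species_pair(synth_config(seed = 6, n_genes = 8))
  expect_false(identical(a$genome_a, c$genome_a))
})

test_that("zero divergence without planted differences gives identical
          genomes and an identity chain", {
  cfg <- synth_config(seed = 4, n_genes = 5, divergence = 0,
                      indel_prob = 0, frac_a_exclusive = 0,
                      frac_b_exclusive = 0)
  p <- gen_species_pair(cfg)
  expect_identical(unname(p$genome_a), unname(p$genome_b))
  expect_equal(nrow(p$chains[[1]]$blocks), 1)
})

test_that("planted branch points are recovered as the best candidate", {
  p <- gen_species_pair(synth_config(seed = 7, n_genes = 15))
  m <- default_bp_model()
  for (g in seq_len(nrow(p$truth))) {
    tx <- p$transcripts_a[[paste0(p$truth$gene[g], "_t1")]]
    intr <- extract_intron_upstream(tx, 2, p$genome_a)
    best <- best_branchpoint(intr$seq, m)
    expect_identical(best$nonamer, p$truth$nonamer_a[g])
    expect_equal(best$distance, p$config$bp_distance)
    # planted score within 0.5 of its target
    expect_lte(abs(best$score - p$truth$bp_target_a[g]), 0.5)
  }
})

test_that("planted genomes carry canonical splice sites", {
  p <- gen_species_pair(synth_config(seed = 13, n_genes = 6))
  for (tx in p$transcripts_a) {
    intr <- extract_intron_upstream(tx, 2, p$genome_a)
    expect_identical(substr(intr$seq, 1, 2), "GT")
    expect_identical(substr(intr$seq, nchar(intr$seq) - 1,
                            nchar(intr$seq)), "AG")
  }
})

test_that("the logistic link is monotone and saturates", {
  link <- list(b0 = 0, b1 = 2, b2 = 0.5, b3 = 0.5)
  expect_gt(true_psi_from_elements(100, 0, 0, link), 1 - 1e-10)
  lo <- true_psi_from_elements(1, 0, 0, link)
  hi <- true_psi_from_elements(2, 0, 0, link)
  expect_lt(lo, hi)
  # calibrated intercept puts the reference score at 0.5
  link2 <- list(b0 = -2 * 3, b1 = 2, b2 = 0, b3 = 0)
  expect_equal(true_psi_from_elements(3, link = link2), 0.5)
})

test_that("junction read simulation matches its contract", {
  all_in <- gen_junction_reads(1, 500, 10, seed = 2)
  expect_true(all(all_in$sjc == 0))
  r1 <- gen_junction_reads(0.5, 2000, 100, seed = 3)
  r2 <- gen_junction_reads(0.5, 2000, 100, seed = 3)
  expect_identical(r1, r2)
  psi <- psi_from_junction_counts(r1$ijc, r1$sjc)
  expect_lt(abs(mean(psi) - 0.5), 0.02)
})

test_that("genotype mixtures average the allele inclusion fractions", {
  het <- gen_genotype_mixture(1, 0, 2000, 50, seed = 4)
  psi <- psi_from_junction_counts(het$ijc, het$sjc)
  expect_lt(abs(mean(psi) - 0.5), 0.02)
  wt <- gen_genotype_mixture(0.995, 0.995, 2000, 20, seed = 5)
  expect_gt(mean(psi_from_junction_counts(wt$ijc, wt$sjc)), 0.98)
  hom <- gen_genotype_mixture(0.005, 0.005, 2000, 20, seed = 6)
  expect_lt(mean(psi_from_junction_counts(hom$ijc, hom$sjc)), 0.02)
})

test_that("Hill data generation is exact without noise and seeded", {
  d0 <- gen_hill_data(1.2, 1.3, 15, noise_sd = 0, seed = 9)
  expect_equal(d0$activity, hill(d0$conc, 1.2, 1.3, 15))
  d1 <- gen_hill_data(1.2, 1.3, 15, noise_sd = 0.05, n_replicates = 3,
                      seed = 10)
  d2 <- gen_hill_data(1.2, 1.3, 15, noise_sd = 0.05, n_replicates = 3,
                      seed = 10)
  expect_identical(d1, d2)
})

test_that("phosphosite tables realize the planted group structure", {
  isoforms <- c("FL", "d13", "d16_17", "d13_16")
  counts <- c("FL" = 5, "d13_16" = 17, "FL&d13" = 3,
              "FL&d13&d16_17&d13_16" = 10)
  tabs <- gen_phospho_tables(counts, isoforms, miss_rate = 0.15,
                             n_low_loc = 4, seed = 12)
  expect_length(tabs, 2)
  merged <- merge_replicates(tabs, normalize = TRUE)
  present <- !is.na(as.matrix(merged[, isoforms]))
  pattern <- apply(present, 1, function(r)
    paste(isoforms[r], collapse = "&"))
  expect_equal(sum(pattern == "d13_16"), 17)
  expect_equal(sum(pattern == "FL"), 5)
  expect_equal(sum(pattern == "FL&d13"), 3)
  # low-localization extras are filtered during merging
  expect_equal(nrow(merged), sum(counts))

  # no missingness: complete where planted
  full <- gen_phospho_tables(counts, isoforms, miss_rate = 0,
                             n_low_loc = 0, seed = 13)
  expect_false(anyNA(full[[1]][full[[1]]$site_id %in%
    full[[1]]$site_id[seq_len(5)], "FL"]))
  t1 <- gen_phospho_tables(counts, isoforms, seed = 14)
  t2 <- gen_phospho_tables(counts, isoforms, seed = 14)
  expect_identical(t1, t2)
})

test_that("the pipeline recovers planted species-exclusive exons", {
  cfg <- synth_config(seed = 17, n_genes = 40)
  pair <- gen_species_pair(cfg)
  res <- run_pipeline(pair)
  truth <- pair$truth
  planted <- truth$gene[truth$true_psi_a < 0.85 & truth$true_psi_b > 0.95]
  cass <- res$pairs[res$pairs$exon_index_a == 2, ]
  called <- sub("_t1", "", cass$tx_a[cass$exclusivity == "A-exclusive"])
  sensitivity <- mean(planted %in% called)
  expect_gte(sensitivity, 0.95)
})

test_that("written files load back into the same objects", {
  pair <- gen_species_pair(synth_config(seed = 23, n_genes = 5))
  dir <- file.path(tempdir(), "synthpair")
  paths <- write_species_pair(pair, dir)
  expect_identical(read_fasta(paths[["genome_a"]]), pair$genome_a)
  back_tx <- read_gff_transcripts(paths[["gff_a"]])
  expect_equal(back_tx[["g001_t1"]]$exons,
               pair$transcripts_a[["g001_t1"]]$exons)
  back_chain <- read_chain(paths[["chain"]])
  expect_equal(back_chain[[1]]$blocks, pair$chains[[1]]$blocks)
  back_ev <- read_event_table(paths[["events_a"]])
  expect_equal(back_ev$ijc, pair$events_a$ijc)
})
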