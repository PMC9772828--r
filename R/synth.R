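# Seeded synthetic-data generation. The generator emulates the
# structure the comparative analysis assumes: two species with
# orthologous three-exon genes whose middle (cassette) exon carries a
# planted branch-point of controlled strength, canonical GT/AG splice
# sites, an AG-depleted 3' intron region giving a controllable AGEZ,
# junction reads drawn from a PSI that depends on element strength
# through a logistic link, heterozygote allele mixtures, Hill activation
# curves and replicate phosphosite tables. All draws go through a single
# integer seed; per-operation sub-seeds are derived deterministically.

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# remove every AG dinucleotide by a left-to-right G -> C replacement
strip_ag <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n >= 2L)
    for (i in 2:n) if (ch[i - 1L] == "A" && ch[i] == "G") ch[i] <- "C"
  paste(ch, collapse = "")
}

#' Synthetic-data configuration
#'
#' Defaults encode the study conditions of the comparative analysis:
#' cassette exons at sequencing depth 2000 junction reads over 9 samples
#' per species, a planted branch-point weakening of 1.5 PWM log-odds
#' units in species-exclusive exons, and a logistic PSI link anchored so
#' that a strong branch point yields near-constitutive inclusion
#' (PSI 0.97) while the weakened branch point drops inclusion into the
#' alternative range.
#'
#' @param seed Integer master seed.
#' @param n_genes Number of orthologous three-exon genes.
#' @param exon_length Exon length (nt).
#' @param intron_length_range Range of intron lengths (nt).
#' @param spacer_length Intergenic spacer length (nt).
#' @param divergence Substitution rate applied to species B outside
#'   planted elements.
#' @param indel_prob Probability that a spacer carries an insertion in
#'   species B (creates chain gaps).
#' @param indel_length_range Length range of those insertions.
#' @param frac_a_exclusive,frac_b_exclusive Fractions of genes whose
#'   cassette exon is planted weak in species A (resp. B) and strong in
#'   the other.
#' @param bp_delta Branch-point weakening in PWM log-odds units.
#' @param bp_distance Planted distance of the branch-point adenine to the
#'   3' splice site (nt).
#' @param agez_target Planted AGEZ length (nt) for strong-branch-point
#'   introns.
#' @param link Logistic PSI link parameters: list with `b1`, `b2`, `b3`
#'   (slopes for branch-point, 3'ss, 5'ss scores) and `ref_psi` (the
#'   inclusion level anchored at the strong branch-point score; sets the
#'   intercept).
#' @param depth Junction reads per sample.
#' @param n_samples Samples per species.
#' @param het_allele_psi Allele inclusion fractions of the simulated
#'   heterozygote (one near-fully-including, one near-fully-skipping
#'   allele).
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_genes = 40L,
                         exon_length = 60L,
                         intron_length_range = c(120L, 180L),
                         spacer_length = 120L,
                         divergence = 0.02,
                         indel_prob = 0.5,
                         indel_length_range = c(10L, 50L),
                         frac_a_exclusive = 0.3,
                         frac_b_exclusive = 0.1,
                         bp_delta = 1.5,
                         bp_distance = 26L,
                         agez_target = 44L,
                         link = list(b1 = 2, b2 = 0, b3 = 0,
                                     ref_psi = 0.97),
                         depth = 2000L,
                         n_samples = 9L,
                         het_allele_psi = c(0.995, 0.005)) {
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

#' Logistic link from element scores to the true inclusion fraction
#'
#' `pi = 1 / (1 + exp(-(b0 + b1*bp + b2*ss3 + b3*ss5)))`, monotone
#' increasing in every score. Missing scores contribute zero.
#'
#' @param bp_score,ss3,ss5 Element scores (vectors recycle).
#' @param link List with `b0`, `b1`, `b2`, `b3`.
#' @return Inclusion fraction(s) in `(0, 1)`.
#' @export
true_psi_from_elements <- function(bp_score, ss3 = 0, ss5 = 0, link) {
  stopifnot(all(c("b0", "b1", "b2", "b3") %in% names(link)))
  z <- link$b0 + link$b1 * ifelse(is.na(bp_score), 0, bp_score) +
    link$b2 * ifelse(is.na(ss3), 0, ss3) +
    link$b3 * ifelse(is.na(ss5), 0, ss5)
  1 / (1 + exp(-z))
}

# greedy search for a nonamer scoring within 0.5 of target under model
plant_nonamer <- function(target, model, max_steps = 60L) {
  bases <- c("A", "C", "G", "T")
  consensus <- sapply(1:9, function(j) bases[which.max(model$pwm[, j])])
  consensus[6L] <- "A"
  cur <- paste(consensus, collapse = "")
  cur_score <- score_bp_candidates(cur, model)
  hi <- cur; hi_score <- cur_score
  if (target > hi_score + 0.5)
    stop("unsatisfiable planted branch-point score ", target,
         " (model maximum ", round(hi_score, 2), ")")
  for (step in seq_len(max_steps)) {
    if (abs(cur_score - target) <= 0.5) return(cur)
    best <- NULL; best_gap <- abs(cur_score - target)
    for (j in setdiff(1:9, 6L)) {
      for (b in bases) {
        if (substr(cur, j, j) == b) next
        cand <- cur
        substr(cand, j, j) <- b
        s <- score_bp_candidates(cand, model)
        gap <- abs(s - target)
        if (gap < best_gap) { best <- cand; best_gap <- gap }
      }
    }
    if (is.null(best)) break
    cur <- best
    cur_score <- score_bp_candidates(cur, model)
  }
  if (abs(cur_score - target) > 0.5)
    stop("unsatisfiable planted branch-point score ", target)
  cur
}

# build one intron carrying a planted BP nonamer; returns the sequence
build_intron <- function(length, nonamer, bp_distance, agez_target,
                         model) {
  d <- bp_distance
  stopifnot(d >= 7L, length >= d + 40L)
  # layout (0-based): donor prefix | filler | nonamer | tail | AG
  # BP adenine index p = length - 1 - d; nonamer covers p-5 .. p+3
  p <- length - 1L - d
  donor <- "GTAAGT"
  filler_len <- (p - 5L) - nchar(donor)
  tail_len <- d - 5L                      # between nonamer end and final AG
  filler <- strip_ag(random_dna(filler_len))
  tail <- strip_ag(random_dna(tail_len))
  seq <- paste0(donor, filler, nonamer, tail, "AG")
  stopifnot(nchar(seq) == length)
  # set the AGEZ by planting one AG ending at body position (L-2) - agez
  agez <- min(agez_target, length - 10L)
  ag_end <- (length - 2L) - agez          # 1-based end of planted AG
  planted_ag_a <- -10L                    # 0-based A of the planted AG
  if (ag_end >= 8L && (ag_end < p - 4L || ag_end > p + 5L)) {
    substr(seq, ag_end - 1L, ag_end) <- "AG"
    planted_ag_a <- ag_end - 2L
  }
  # suppress competing candidates so the planted nonamer is the best
  for (iter in 1:50) {
    best <- best_branchpoint(seq, model)
    if (is.null(best) || best$pos == p) break
    q <- best$pos                         # 0-based competing adenine
    if (q >= p - 5L && q <= p + 3L) break # inside planted window; keep
    if (q == planted_ag_a) break          # keep the AGEZ-defining AG
    if (q < nchar(donor) || q >= length - 2L) break
    substr(seq, q + 1L, q + 1L) <- "T"
  }
  seq
}

# replace the planted nonamer of an intron built by build_intron and
# re-run the competitor suppression so the new nonamer is the best call
swap_nonamer <- function(intron, nonamer, bp_distance, model) {
  L <- nchar(intron)
  p <- L - 1L - bp_distance
  if (substr(intron, p - 4L, p + 4L) == nonamer) return(intron)
  substr(intron, p - 4L, p + 4L) <- nonamer
  for (iter in 1:50) {
    best <- best_branchpoint(intron, model)
    if (is.null(best) || best$pos == p) break
    q <- best$pos
    if (q >= p - 5L && q <= p + 3L) break
    if (q < 6L || q >= L - 2L) break
    substr(intron, q + 1L, q + 1L) <- "T"
  }
  intron
}

#' Generate a synthetic two-species dataset
#'
#' Produces paired genomes (one chromosome each), transcript
#' annotations, a chain alignment relating them, per-sample junction
#' counts for every cassette exon in both species, and a truth table of
#' all planted values. Each gene has three exons; the middle exon is the
#' cassette exon. Genes are assigned (deterministically per seed) to be
#' A-exclusive (branch point weakened by `bp_delta` in species A),
#' B-exclusive, or shared-strong.
#'
#' @param config A [synth_config].
#' @return List with `genome_a`, `genome_b` (named sequence vectors),
#'   `transcripts_a`, `transcripts_b` (named [transcript_model] lists),
#'   `chains`, `events_a`, `events_b` (long-format junction count
#'   tables with exon coordinates), `truth` (`data.frame` of planted
#'   values) and `config`.
#' @export
gen_species_pair <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  model <- default_bp_model()
  strong_score <- score_bp_candidates("CCCTAACAA", model)
  with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_genes
    n_a_ex <- round(config$frac_a_exclusive * n)
    n_b_ex <- round(config$frac_b_exclusive * n)
    type <- rep("shared", n)
    if (n_a_ex > 0L) type[seq_len(n_a_ex)] <- "A-exclusive"
    if (n_b_ex > 0L) type[n_a_ex + seq_len(n_b_ex)] <- "B-exclusive"
    weak_score <- strong_score - config$bp_delta
    nona_strong <- plant_nonamer(strong_score, model)
    nona_weak <- plant_nonamer(weak_score, model)
    seg_a <- character(); seg_b <- character()
    exon_rows <- list()
    truth <- list()
    pos_a <- 0L; pos_b <- 0L
    push <- function(a, b) {
      seg_a[[length(seg_a) + 1L]] <<- a
      seg_b[[length(seg_b) + 1L]] <<- b
      pos_a <<- pos_a + nchar(a)
      pos_b <<- pos_b + nchar(b)
    }
    diverge <- function(s) {
      if (config$divergence <= 0 || nchar(s) == 0L) return(s)
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      hit <- which(stats::runif(length(ch)) < config$divergence)
      for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "T"), ch[i]), 1L)
      paste(ch, collapse = "")  # substitutions avoid G: no new AG or GT
    }
    for (g in seq_len(n)) {
      # intergenic spacer, possibly with an insertion in B
      sp <- random_dna(config$spacer_length)
      half <- config$spacer_length %/% 2L
      push(substr(sp, 1L, half), diverge(substr(sp, 1L, half)))
      if (stats::runif(1) < config$indel_prob) {
        ins <- random_dna(sample(config$indel_length_range[1L]:
                                   config$indel_length_range[2L], 1L))
        push("", ins)
      }
      push(substr(sp, half + 1L, config$spacer_length),
           diverge(substr(sp, half + 1L, config$spacer_length)))
      # three exons and two introns; intron 1 carries the planted BP
      target_a <- if (type[g] == "A-exclusive") weak_score else strong_score
      target_b <- if (type[g] == "B-exclusive") weak_score else strong_score
      nona_a <- if (type[g] == "A-exclusive") nona_weak else nona_strong
      nona_b <- if (type[g] == "B-exclusive") nona_weak else nona_strong
      L1 <- sample(config$intron_length_range[1L]:
                     config$intron_length_range[2L], 1L)
      L2 <- sample(config$intron_length_range[1L]:
                     config$intron_length_range[2L], 1L)
      ex <- replicate(3L, {
        s <- random_dna(config$exon_length)
        substr(s, 1L, 1L) <- "C"   # avoid exonic G after intronic AG caveats
        s
      })
      intron1_a <- build_intron(L1, nona_a, config$bp_distance,
                                config$agez_target, model)
      # the orthologous intron shares the sequence; only the planted
      # branch-point nonamer differs between the species
      intron1_b <- swap_nonamer(intron1_a, nona_b, config$bp_distance,
                                model)
      intron2 <- build_intron(L2, nona_strong, config$bp_distance,
                              config$agez_target, model)
      starts_a <- integer(3L); starts_b <- integer(3L)
      starts_a[1L] <- pos_a; starts_b[1L] <- pos_b
      push(ex[1L], diverge(ex[1L]))
      push(intron1_a, intron1_b)
      starts_a[2L] <- pos_a; starts_b[2L] <- pos_b
      push(ex[2L], ex[2L])           # cassette exon kept identical
      push(intron2, intron2)
      starts_a[3L] <- pos_a; starts_b[3L] <- pos_b
      push(ex[3L], diverge(ex[3L]))
      exon_rows[[g]] <- list(gene = sprintf("g%03d", g),
                             starts_a = starts_a, starts_b = starts_b)
      sc_a <- score_bp_candidates(nona_a, model)
      sc_b <- score_bp_candidates(nona_b, model)
      truth[[g]] <- data.frame(
        gene = sprintf("g%03d", g), type = type[g],
        nonamer_a = nona_a, nonamer_b = nona_b,
        bp_target_a = target_a, bp_target_b = target_b,
        bp_score_a = sc_a, bp_score_b = sc_b,
        stringsAsFactors = FALSE)
    }
    final_sp <- random_dna(config$spacer_length)
    push(final_sp, diverge(final_sp))
    genome_a <- c(chrA = paste(seg_a, collapse = ""))
    genome_b <- c(chrB = paste(seg_b, collapse = ""))
    # transcripts
    mk_tx <- function(rows, which, chrom) {
      out <- list()
      for (r in rows) {
        starts <- if (which == "a") r$starts_a else r$starts_b
        id <- paste0(r$gene, "_t1")
        out[[id]] <- transcript_model(
          id, r$gene, chrom, "+",
          data.frame(start = starts, end = starts + config$exon_length))
      }
      out
    }
    transcripts_a <- mk_tx(exon_rows, "a", "chrA")
    transcripts_b <- mk_tx(exon_rows, "b", "chrB")
    # chain from aligned segment structure
    blocks <- list()
    cur <- 0L
    flush_gap <- function(dt, dq) {
      blocks[[length(blocks) + 1L]] <<- c(size = cur, dt = dt, dq = dq)
      cur <<- 0L
    }
    for (i in seq_along(seg_a)) {
      la <- nchar(seg_a[[i]]); lb <- nchar(seg_b[[i]])
      if (la == lb) cur <- cur + la else flush_gap(la, lb)
    }
    blocks[[length(blocks) + 1L]] <- c(size = cur, dt = 0L, dq = 0L)
    bl <- as.data.frame(do.call(rbind, blocks))
    chains <- list(chain_alignment(
      "chrA", nchar(genome_a), 0L, nchar(genome_a),
      "chrB", nchar(genome_b), 0L, nchar(genome_b),
      blocks = bl, score = 1000, id = "1"))
    truth <- do.call(rbind, truth)
    # anchor the logistic intercept at the strong score
    link <- config$link
    link$b0 <- log(link$ref_psi / (1 - link$ref_psi)) -
      link$b1 * strong_score
    truth$true_psi_a <- true_psi_from_elements(truth$bp_score_a,
                                               link = link)
    truth$true_psi_b <- true_psi_from_elements(truth$bp_score_b,
                                               link = link)
    # junction counts per cassette exon
    mk_events <- function(which, transcripts, sub) {
      rows <- list()
      for (g in seq_len(n)) {
        tx <- transcripts[[paste0(truth$gene[g], "_t1")]]
        psi <- if (which == "a") truth$true_psi_a[g] else
          truth$true_psi_b[g]
        cnt <- gen_junction_reads(psi, config$depth, config$n_samples,
                                  derive_seed(config$seed,
                                              1000L * sub + g))
        rows[[g]] <- data.frame(
          event_id = paste0(truth$gene[g], "_e2"),
          chrom = tx$chrom, strand = tx$strand,
          exon_start = tx$exons$start[2L], exon_end = tx$exons$end[2L],
          sample = sprintf("s%02d", seq_len(config$n_samples)),
          ijc = cnt$ijc, sjc = cnt$sjc, stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    }
    events_a <- mk_events("a", transcripts_a, 1L)
    events_b <- mk_events("b", transcripts_b, 2L)
    list(genome_a = genome_a, genome_b = genome_b,
         transcripts_a = transcripts_a, transcripts_b = transcripts_b,
         chains = chains, events_a = events_a, events_b = events_b,
         truth = truth, config = config)
  })
}

#' Write a synthetic species pair to disk
#'
#' Emits the FASTA genomes, GFF3 annotations, chain file, junction count
#' tables and truth table into a directory.
#'
#' @param pair Result of [gen_species_pair()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of the written paths.
#' @export
write_species_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome_a = file.path(dir, "species_a.fa"),
    genome_b = file.path(dir, "species_b.fa"),
    gff_a = file.path(dir, "species_a.gff3"),
    gff_b = file.path(dir, "species_b.gff3"),
    chain = file.path(dir, "a_to_b.chain"),
    events_a = file.path(dir, "events_a.tsv"),
    events_b = file.path(dir, "events_b.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_fasta(pair$genome_a, paths[["genome_a"]])
  write_fasta(pair$genome_b, paths[["genome_b"]])
  write_gff_transcripts(pair$transcripts_a, paths[["gff_a"]])
  write_gff_transcripts(pair$transcripts_b, paths[["gff_b"]])
  write_chain(pair$chains, paths[["chain"]])
  utils::write.table(pair$events_a, paths[["events_a"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(pair$events_b, paths[["events_b"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(pair$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Simulate junction reads for a cassette exon
#'
#' Per sample, `depth` junction reads are drawn; a read supports
#' inclusion with probability `w = 2*pi / (1 + pi)`, the
#' junction-opportunity weight under which the effective-length (2, 1)
#' PSI estimator of [psi_from_junction_counts()] is unbiased for the
#' true inclusion fraction `pi` (an included transcript exposes two
#' junctions, a skipping transcript one).
#'
#' @param true_psi True inclusion fraction in `[0, 1]`.
#' @param depth Junction reads per sample.
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @return `data.frame` with columns `sample`, `ijc`, `sjc`.
#' @export
gen_junction_reads <- function(true_psi, depth, n_samples, seed) {
  stopifnot(true_psi >= 0, true_psi <= 1, depth > 0)
  with_seed(seed, {
    w <- 2 * true_psi / (1 + true_psi)
    ijc <- stats::rbinom(n_samples, depth, w)
    data.frame(sample = seq_len(n_samples), ijc = ijc,
               sjc = depth - ijc)
  })
}

#' Simulate junction reads for a two-allele genotype
#'
#' Reads are drawn from an equal mixture of two alleles with their own
#' inclusion fractions, emulating wild-type (both alleles including),
#' heterozygous (one including, one skipping) and homozygous (both
#' skipping) genotypes.
#'
#' @param psi_allele1,psi_allele2 Allele inclusion fractions in `[0, 1]`.
#' @inheritParams gen_junction_reads
#' @return `data.frame` with columns `sample`, `ijc`, `sjc`.
#' @export
gen_genotype_mixture <- function(psi_allele1, psi_allele2, depth,
                                 n_samples, seed) {
  stopifnot(psi_allele1 >= 0, psi_allele1 <= 1,
            psi_allele2 >= 0, psi_allele2 <= 1)
  gen_junction_reads((psi_allele1 + psi_allele2) / 2, depth, n_samples,
                     seed)
}

#' Simulate a Hill activation dataset
#'
#' @param vmax,h,ec50 True Hill parameters.
#' @param x_grid Concentrations (nM); default 16 log-spaced points
#'   between 1 and 4000.
#' @param noise_sd Gaussian noise SD added to activities.
#' @param n_replicates Replicates per concentration.
#' @param seed Integer seed.
#' @return `data.frame` with columns `replicate`, `conc`, `activity`.
#' @export
gen_hill_data <- function(vmax, h, ec50,
                          x_grid = exp(seq(log(1), log(4000),
                                           length.out = 16L)),
                          noise_sd = 0, n_replicates = 1L, seed = 1L) {
  with_seed(seed, {
    conc <- rep(x_grid, times = n_replicates)
    rep_id <- rep(seq_len(n_replicates), each = length(x_grid))
    v <- hill(conc, vmax, h, ec50) +
      stats::rnorm(length(conc), 0, noise_sd)
    data.frame(replicate = rep_id, conc = conc, activity = v)
  })
}

#' Simulate replicate phosphosite intensity tables
#'
#' Sites are assigned to isoform-overlap groups with configured
#' exclusive counts (one entry per isoform subset, names joined by
#' `&`); intensities are lognormal; missing values are introduced at a
#' configured rate (never in both replicates of the same cell, so the
#' planted group structure survives merging); a configured number of
#' extra sites receives a localization probability below 0.75 and is
#' expected to be filtered out.
#'
#' @param group_counts Named integer vector: exact number of sites
#'   present in exactly that isoform subset (e.g.
#'   `c("FL" = 5, "FL&d13" = 3)`).
#' @param isoforms Character vector of all isoform (sample) names.
#' @param n_replicates Number of replicate tables (default 2).
#' @param miss_rate Per-cell missingness rate (applied to one replicate
#'   of a cell at a time).
#' @param n_low_loc Number of extra sites with localization probability
#'   below 0.75.
#' @param seed Integer seed.
#' @return List of `data.frame`s (one per replicate) with columns
#'   `site_id`, `localization_prob` and one intensity column per isoform.
#' @export
gen_phospho_tables <- function(group_counts, isoforms,
                               n_replicates = 2L, miss_rate = 0.1,
                               n_low_loc = 0L, seed = 1L) {
  stopifnot(!is.null(names(group_counts)), n_replicates >= 1L)
  with_seed(seed, {
    site_rows <- list()
    k <- 0L
    for (grp in names(group_counts)) {
      members <- strsplit(grp, "&", fixed = TRUE)[[1L]]
      if (!all(members %in% isoforms))
        stop("group '", grp, "' names unknown isoforms")
      for (j in seq_len(group_counts[[grp]])) {
        k <- k + 1L
        site_rows[[k]] <- list(site_id = sprintf("site%04d", k),
                               members = members, loc = stats::runif(1, 0.8, 1))
      }
    }
    for (j in seq_len(n_low_loc)) {
      k <- k + 1L
      site_rows[[k]] <- list(site_id = sprintf("site%04d", k),
                             members = sample(isoforms,
                                              sample(length(isoforms), 1L)),
                             loc = stats::runif(1, 0, 0.74))
    }
    base_int <- matrix(NA_real_, nrow = k, ncol = length(isoforms),
                       dimnames = list(NULL, isoforms))
    for (i in seq_len(k)) {
      m <- site_rows[[i]]$members
      base_int[i, m] <- stats::rlnorm(length(m), meanlog = 20, sdlog = 1)
    }
    tabs <- vector("list", n_replicates)
    miss_rep <- matrix(sample.int(n_replicates, k * length(isoforms),
                                  replace = TRUE),
                       nrow = k)
    for (r in seq_len(n_replicates)) {
      vals <- base_int * exp(stats::rnorm(length(base_int), 0, 0.1))
      if (miss_rate > 0 && n_replicates > 1L) {
        drop <- !is.na(base_int) & miss_rep == r &
          matrix(stats::runif(length(base_int)) < miss_rate, nrow = k)
        vals[drop] <- NA_real_
      }
      tab <- data.frame(site_id = vapply(site_rows, `[[`, "", "site_id"),
                        localization_prob = vapply(site_rows, `[[`,
                                                   0, "loc"),
                        stringsAsFactors = FALSE)
      tab <- cbind(tab, as.data.frame(vals))
      tabs[[r]] <- tab
    }
    tabs
  })
}
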