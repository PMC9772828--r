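test_that("a model equal to its background scores zero everywhere", {
  m <- flat_donor_model()
  set.seed(1)
  for (i in 1:10) {
    w <- paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE),
               collapse = "")
    expect_equal(score_5ss(w, m), 0, tolerance = 1e-12)
  }
  ma <- flat_donor_model(window = 23L, site_kind = "acceptor")
  expect_equal(score_3ss(strrep("A", 23), ma), 0, tolerance = 1e-12)
})

test_that("window validation and consensus flagging work", {
  m <- flat_donor_model()
  expect_error(score_5ss("ACGT", m), "9 nt")
  expect_error(score_5ss("ACGTNACGT", m), "A/C/G/T")
  m$check_consensus <- TRUE
  expect_warning(score_5ss("AAAAAAAAA", m), "non-canonical")
  expect_silent(v <- score_5ss("AAAGTAAGT", m))
  expect_error(score_5ss("AAAAAAAAA", m, strict = TRUE), "non-canonical")
  ma <- flat_donor_model(23L, "acceptor")
  ma$check_consensus <- TRUE
  expect_warning(score_3ss(strrep("C", 23), ma), "non-canonical")
  good <- paste0(strrep("C", 18), "AG", "CCC")
  expect_silent(score_3ss(good, ma))
})

test_that("single-position marginals train to the product distribution", {
  fit <- train_maxent(
    list(list(positions = 1L, probs = c(A = 0.75, C = 0.25)),
         list(positions = 2L, probs = c(A = 0.5, C = 0.5))),
    window = 2L, alphabet = c("A", "C"))
  expect_equal(unname(fit[["AA"]]), 0.375, tolerance = 1e-8)
  expect_equal(unname(fit[["CA"]]), 0.125, tolerance = 1e-8)
  expect_equal(sum(fit), 1, tolerance = 1e-12)
})

test_that("a full-joint constraint reproduces that distribution", {
  set.seed(7)
  q <- runif(16)
  q <- q / sum(q)
  names(q) <- orthosplice:::all_kmers(2L)
  fit <- train_maxent(list(list(positions = 1:2, probs = q)), window = 2L)
  expect_equal(as.numeric(fit[names(q)]), as.numeric(q), tolerance = 1e-8)
})

test_that("overlapping pairwise constraints match the closed-form
          conditional-independence oracle", {
  # oracle: with constraints on (1,2) and (2,3), the max-entropy joint is
  # the Markov factorization p12(x1,x2) * p23(x2,x3) / p2(x2)
  set.seed(11)
  for (rep in 1:3) {
    q <- array(runif(64), dim = c(4, 4, 4))
    q <- q / sum(q)
    b <- c("A", "C", "G", "T")
    p12 <- apply(q, c(1, 2), sum)
    p23 <- apply(q, c(2, 3), sum)
    p2 <- apply(q, 2, sum)
    name2 <- as.vector(outer(b, b, paste0))
    c12 <- setNames(as.vector(p12), as.vector(outer(b, b, paste0)))
    c23 <- setNames(as.vector(p23), as.vector(outer(b, b, paste0)))
    fit <- train_maxent(list(list(positions = 1:2, probs = c12),
                             list(positions = 2:3, probs = c23)),
                        window = 3L, tol = 1e-10)
    oracle <- sapply(names(fit), function(k) {
      i <- match(substr(k, 1, 1), b)
      j <- match(substr(k, 2, 2), b)
      l <- match(substr(k, 3, 3), b)
      p12[i, j] * p23[j, l] / p2[j]
    })
    expect_lt(max(abs(fit - oracle)), 1e-6)
    # entropy dominance: the source joint q satisfies both constraints
    ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    expect_gte(ent(fit) + 1e-9, ent(as.vector(q)))
  }
})

test_that("inconsistent constraints are rejected", {
  expect_error(
    train_maxent(list(list(positions = 1L, probs = c(A = 1, C = 0)),
                      list(positions = 1:2,
                           probs = c(AA = 0, AC = 0, CA = 0.5, CC = 0.5))),
                 window = 2L, alphabet = c("A", "C"), max_iter = 50),
    "inconsistent|converge")
})

test_that("trained marginals match their targets within tolerance", {
  set.seed(3)
  p1 <- runif(4); p1 <- p1 / sum(p1)
  p3 <- runif(4); p3 <- p3 / sum(p3)
  b <- c("A", "C", "G", "T")
  fit <- train_maxent(list(list(positions = 1L, probs = setNames(p1, b)),
                           list(positions = 3L, probs = setNames(p3, b))),
                      window = 3L, tol = 1e-9)
  got <- sapply(b, function(x) sum(fit[substr(names(fit), 1, 1) == x]))
  expect_equal(unname(got), p1, tolerance = 1e-7)
})

test_that("scores are monotone in single-position factor probabilities", {
  base <- stats::setNames(c(0.4, 0.3, 0.2, 0.1), c("A", "C", "G", "T"))
  comps <- lapply(1:5, function(j) list(positions = j, probs = base))
  m <- maxent_model("donor", 5L, comps, check_consensus = FALSE)
  low <- score_5ss("TTTTT", m)
  mid <- score_5ss("TTCTT", m)
  hi <- score_5ss("TTATT", m)
  expect_lt(low, mid)
  expect_lt(mid, hi)
})

test_that("window extraction matches the published layout", {
  # gene: exon1 [6,10), intron [10,40), exon2 [40,44) on chrE (+)
  intron <- paste0("GTAAGT", strrep("C", 17), "TTTTTAG")
  chrom <- paste0("ACGACG", "TGCA", intron, "GATT", "ACGTAC")
  g <- c(chrE = chrom)
  tx <- transcript_model("t", "g", "chrE", "+",
                         data.frame(start = c(6, 40), end = c(10, 44)))
  expect_identical(donor_window(tx, 1, g), paste0("GCA", "GTAAGT"))
  expect_identical(acceptor_window(tx, 2, g),
                   paste0(substr(intron, 11, 30), "GAT"))
  # the same gene on the minus strand of the reverse complement
  gm <- c(chrE = revcomp(chrom))
  L <- nchar(chrom)
  txm <- transcript_model("t", "g", "chrE", "-",
                          data.frame(start = L - c(10, 44),
                                     end = L - c(6, 40)))
  expect_identical(donor_window(txm, 1, gm), donor_window(tx, 1, g))
  expect_identical(acceptor_window(txm, 2, gm), acceptor_window(tx, 2, g))
})

test_that("scoring is bit-stable across runs", {
  set.seed(5)
  probs <- runif(4^3); probs <- probs / sum(probs)
  names(probs) <- orthosplice:::all_kmers(3L)
  m <- maxent_model_from_joint("donor", probs)
  w <- "ACG"
  expect_identical(score_5ss(w, m), score_5ss(w, m))
})
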