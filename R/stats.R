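# Statistical machinery for the comparative analyses: paired Wilcoxon
# signed-rank with an exact small-sample distribution, Holm adjustment,
# variance-gated two-sample t tests, Pearson correlation matrices with
# missing data, min-max normalization, replicate merging of phosphosite
# tables, and exclusive (upset-style) set intersections.

#' Paired Wilcoxon signed-rank test
#'
#' Differences equal to zero are dropped (standard signed-rank
#' convention). For `n <= exact_limit` non-zero pairs the two-sided
#' p-value is exact, computed from the full distribution of the signed
#' rank sum over all `2^n` sign assignments (evaluated by dynamic
#' programming; ties handled by doubled midranks). For larger `n` a
#' normal approximation with tie correction and continuity correction is
#' used. The reported statistic `W` is the smaller of the positive and
#' negative rank sums.
#'
#' @param a,b Equal-length numeric vectors of paired observations; pairs
#'   with a missing value are dropped.
#' @param exact_limit Largest `n` for which the exact distribution is
#'   used (default 25).
#' @return List with `W`, `n` (non-zero pairs), `p` (two-sided) and
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_signed_rank <- function(a, b, exact_limit = 25L) {
  stopifnot(length(a) == length(b))
  ok <- !(is.na(a) | is.na(b))
  d <- a[ok] - b[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate pairing: all differences are zero")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  W <- min(w_plus, w_minus)
  if (n <= exact_limit) {
    # distribution of 2*W+ over sign assignments; doubled ranks are
    # integers even with midrank ties
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1L)   # counts[s+1] = #assignments with sum s
    counts[1L] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), counts[seq_len(total + 1L - ri)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    w2 <- round(2 * w_plus)
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(W = W, n = n, p = p, method = method)
}

#' Holm step-down adjustment of p-values
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
holm_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "holm")
}

#' Variance-gated two-sample test
#'
#' Selects between Student's t test (equal variances) and Welch's t test
#' with an F test on the variances at `alpha_var`. Optionally a
#' Shapiro-Wilk normality gate can be reported alongside (it does not
#' change the test selection by default, mirroring workflows where
#' normality is additionally judged from Q-Q plots).
#'
#' @param a,b Numeric vectors, each of length at least 3.
#' @param alpha_var Significance level for the variance F test.
#' @param normality_gate If `TRUE`, Shapiro-Wilk p-values for both groups
#'   are included in the result.
#' @return List with `test` (`"student"` or `"welch"`), `statistic`,
#'   `p`, `df`, `var_test_p` and optionally `shapiro_p` (length 2).
#' @export
gated_two_sample_test <- function(a, b, alpha_var = 0.05,
                                  normality_gate = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 observations")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(test = "student", statistic = 0, p = 1,
                  df = length(a) + length(b) - 2, var_test_p = 1))
    # zero variance but different means: difference is certain
    return(list(test = "student", statistic = Inf, p = 0,
                df = length(a) + length(b) - 2, var_test_p = 1))
  }
  vt <- stats::var.test(a, b)
  equal_var <- vt$p.value >= alpha_var
  tt <- stats::t.test(a, b, var.equal = equal_var)
  out <- list(test = if (equal_var) "student" else "welch",
              statistic = unname(tt$statistic), p = tt$p.value,
              df = unname(tt$parameter), var_test_p = vt$p.value)
  if (normality_gate)
    out$shapiro_p <- c(stats::shapiro.test(a)$p.value,
                       stats::shapiro.test(b)$p.value)
  out
}

#' Pearson correlation matrix with pairwise-complete observations
#'
#' @param x Numeric matrix or data.frame (columns = samples, rows =
#'   features, e.g. phosphosite intensities); missing values allowed.
#' @return Symmetric correlation matrix with unit diagonal; entries for
#'   column pairs with fewer than 2 complete rows are `NA`.
#' @export
pearson_corr_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 columns")
  m <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs",
                                   method = "pearson"))
  # enforce NA where fewer than 2 complete pairs exist
  present <- !is.na(x)
  npairs <- crossprod(present)
  m[npairs < 2L] <- NA_real_
  diag(m) <- 1
  m
}

#' Min-max normalization
#'
#' Rescales to `[0, 1]` via `(x - min(x)) / (max(x) - min(x))`, with
#' missing values ignored for the range and preserved in the output.
#'
#' @param values Numeric vector with `max > min` among non-missing values.
#' @return Normalized vector.
#' @export
minmax_normalize <- function(values) {
  lo <- min(values, na.rm = TRUE)
  hi <- max(values, na.rm = TRUE)
  if (!is.finite(lo) || !is.finite(hi) || hi == lo)
    stop("min-max normalization undefined for a constant vector")
  (values - lo) / (hi - lo)
}

#' Merge replicate phosphosite tables
#'
#' Each replicate table has a `site_id` column (unique per table), a
#' `localization_prob` column, and intensity columns (one per sample)
#' with `NA` for sites not observed in a sample. Sites are first filtered
#' to `localization_prob >= min_localization`; each table's intensity
#' values are then min-max normalized over the table's full intensity
#' range; finally sites are merged across replicates, averaging values
#' present in several replicates and keeping single-replicate values
#' as-is.
#'
#' @param tables List of replicate `data.frame`s with identical sample
#'   (intensity) columns.
#' @param min_localization Localization-probability filter (default 0.75).
#' @param normalize Min-max normalize each table before merging
#'   (default `TRUE`).
#' @return Merged `data.frame` with `site_id` and the sample columns.
#' @export
merge_replicates <- function(tables, min_localization = 0.75,
                             normalize = TRUE) {
  stopifnot(length(tables) >= 1L)
  samp_cols <- setdiff(names(tables[[1L]]), c("site_id",
                                              "localization_prob"))
  for (tab in tables) {
    if (!identical(setdiff(names(tab), c("site_id", "localization_prob")),
                   samp_cols))
      stop("replicate tables disagree on sample columns")
    if (anyDuplicated(tab$site_id))
      stop("duplicate site_id within one replicate table")
  }
  prepped <- lapply(tables, function(tab) {
    tab <- tab[tab$localization_prob >= min_localization, , drop = FALSE]
    if (normalize && nrow(tab) > 0L) {
      vals <- as.matrix(tab[, samp_cols, drop = FALSE])
      lo <- min(vals, na.rm = TRUE); hi <- max(vals, na.rm = TRUE)
      if (hi == lo) stop("constant intensities: cannot min-max normalize")
      tab[, samp_cols] <- (vals - lo) / (hi - lo)
    }
    tab
  })
  sites <- unique(unlist(lapply(prepped, function(t) t$site_id)))
  out <- data.frame(site_id = sites, stringsAsFactors = FALSE)
  for (sc in samp_cols) {
    vals <- sapply(prepped, function(tab) {
      tab[[sc]][match(sites, tab$site_id)]
    })
    vals <- matrix(vals, nrow = length(sites))
    out[[sc]] <- rowMeans(vals, na.rm = TRUE)
    out[[sc]][!is.finite(out[[sc]])] <- NA_real_
  }
  out
}

#' Exclusive set intersections (upset-style)
#'
#' For every non-empty subset of the named sets, counts the elements
#' present in all sets of the subset and absent from all others -- the
#' "exclusive intersection" displayed on top of upset plots.
#'
#' @param sets Named list of vectors (treated as sets).
#' @return List with `intersections` (`data.frame` with columns `subset`
#'   -- member names joined by `&` -- `degree` and `size`; only non-empty
#'   intersections are listed, largest first) and `totals` (named per-set
#'   element counts).
#' @export
exclusive_intersections <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  elements <- unique(unlist(sets, use.names = FALSE))
  totals <- vapply(sets, length, integer(1))
  if (length(elements) == 0L)
    return(list(intersections = data.frame(subset = character(),
                                           degree = integer(),
                                           size = integer()),
                totals = totals))
  memb <- vapply(sets, function(s) elements %in% s,
                 logical(length(elements)))
  memb <- matrix(memb, nrow = length(elements),
                 dimnames = list(NULL, names(sets)))
  pattern <- apply(memb, 1L, function(row)
    paste(names(sets)[row], collapse = "&"))
  tab <- table(pattern)
  inter <- data.frame(subset = names(tab),
                      degree = lengths(strsplit(names(tab), "&",
                                                fixed = TRUE)),
                      size = as.integer(tab), stringsAsFactors = FALSE)
  inter <- inter[order(-inter$size, inter$degree, inter$subset), ,
                 drop = FALSE]
  rownames(inter) <- NULL
  list(intersections = inter, totals = totals)
}
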