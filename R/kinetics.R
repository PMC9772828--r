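# Hill-equation modelling of calmodulin-dependent kinase activation:
# V = Vmax * x^h / (EC50^h + x^h), with no basal-activity offset
# (V(0) = 0), the three-parameter "allosteric sigmoidal" model. x is the
# calmodulin concentration in nM, V the activity (normalized units),
# h the Hill coefficient.

#' Hill equation
#'
#' @param x Activator (calmodulin) concentration(s), nM; must be positive.
#' @param vmax Maximal activity (> 0).
#' @param h Hill coefficient (> 0).
#' @param ec50 Half-maximal activator concentration, nM (> 0).
#' @return Activity `vmax * x^h / (ec50^h + x^h)`.
#' @export
hill <- function(x, vmax, h, ec50) {
  if (any(x <= 0)) stop("concentrations must be positive")
  if (vmax <= 0 || h <= 0 || ec50 <= 0)
    stop("Hill parameters must be positive")
  vmax * x^h / (ec50^h + x^h)
}

#' Fit the Hill equation by nonlinear least squares
#'
#' Unweighted least squares via Levenberg-Marquardt from data-driven
#' starting values: `vmax0 = max(v)`, `ec50_0 = x` nearest half-maximal
#' activity, `h0 = 1`. Standard errors come from the Jacobian at the
#' optimum. If the first fit fails, a small set of perturbed restarts is
#' attempted before giving up.
#'
#' @param x Concentrations (nM, positive); at least 4 distinct values.
#' @param v Activities, same length as `x`.
#' @return List with `params` (named: `vmax`, `h`, `ec50`), `se` (named
#'   standard errors), `converged` (logical), `rss` and `fit` (the
#'   underlying `nls` object).
#' @export
fit_hill <- function(x, v) {
  stopifnot(length(x) == length(v))
  ok <- !(is.na(x) | is.na(v))
  x <- x[ok]; v <- v[ok]
  if (length(unique(x)) < 4L)
    stop("need at least 4 distinct concentrations")
  if (any(x <= 0)) stop("concentrations must be positive")
  if (stats::sd(v) == 0)
    stop("no transition in the data: activities are constant")
  vmax0 <- max(v)
  ec50_0 <- x[which.min(abs(v - vmax0 / 2))]
  if (ec50_0 <= 0) ec50_0 <- stats::median(x)
  starts <- list(c(vmax = vmax0, h = 1, ec50 = ec50_0),
                 c(vmax = vmax0 * 1.2, h = 2, ec50 = ec50_0 * 2),
                 c(vmax = vmax0 * 0.8, h = 0.7, ec50 = ec50_0 / 2),
                 c(vmax = vmax0, h = 1, ec50 = exp(mean(log(x)))))
  fit <- NULL
  errs <- character()
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ vmax * x^h / (ec50^h + x^h),
                        start = as.list(s0),
                        lower = c(vmax = 1e-12, h = 1e-12, ec50 = 1e-12),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("Hill fit did not converge after restarts: ",
         paste(unique(errs), collapse = "; "))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  list(params = c(vmax = unname(est["vmax"]), h = unname(est["h"]),
                  ec50 = unname(est["ec50"])),
       se = c(vmax = unname(se["vmax"]), h = unname(se["h"]),
              ec50 = unname(se["ec50"])),
       converged = TRUE,
       rss = sum(stats::resid(fit)^2),
       fit = fit)
}

#' Normalize activation curves to a reference isoform's fitted Vmax
#'
#' Every activity value is divided by the fitted maximal activity of the
#' reference curve, putting all isoforms on a V/Vmax(reference) scale.
#'
#' @param curves `data.frame` with columns `isoform`, `conc` (nM) and
#'   `activity` (and optionally `replicate`).
#' @param reference Isoform name used as reference.
#' @return `curves` with `activity` rescaled; the reference fit's Vmax is
#'   attached as attribute `reference_vmax`.
#' @export
normalize_to_reference <- function(curves, reference) {
  stopifnot(all(c("isoform", "conc", "activity") %in% names(curves)))
  if (nrow(curves) == 0L) return(curves)
  ref <- curves[curves$isoform == reference, ]
  if (nrow(ref) == 0L) stop("reference isoform '", reference,
                            "' absent from curves")
  fit <- fit_hill(ref$conc, ref$activity)
  vref <- fit$params[["vmax"]]
  if (vref <= 0) stop("reference Vmax must be positive")
  curves$activity <- curves$activity / vref
  attr(curves, "reference_vmax") <- vref
  curves
}

#' Pool plateau activities and test isoforms against a reference
#'
#' Pools observations with concentrations inside `range` (inclusive at
#' both ends), then compares each non-reference isoform's pooled
#' activities against the reference with [gated_two_sample_test()], and
#' Holm-adjusts the resulting p-value family.
#'
#' @param curves `data.frame` with columns `isoform`, `conc`, `activity`
#'   (typically after [normalize_to_reference()]).
#' @param reference Reference isoform name.
#' @param range Concentration window to pool, nM (default 100 to 1000).
#' @return `data.frame` with one row per tested isoform: `isoform`, `n`,
#'   `mean`, `ref_mean`, `test`, `statistic`, `p`, `p_holm`. Isoforms
#'   with an empty pool are dropped with a warning.
#' @export
pool_plateau_and_test <- function(curves, reference,
                                  range = c(100, 1000)) {
  stopifnot(all(c("isoform", "conc", "activity") %in% names(curves)))
  pool <- curves[curves$conc >= range[1L] & curves$conc <= range[2L], ]
  ref <- pool$activity[pool$isoform == reference]
  if (length(ref) < 3L)
    stop("reference isoform has fewer than 3 observations in the plateau")
  others <- setdiff(unique(pool$isoform), reference)
  dropped <- setdiff(unique(curves$isoform), c(others, reference))
  if (length(dropped) > 0L)
    warning("isoform(s) without plateau observations excluded: ",
            paste(dropped, collapse = ", "))
  if (length(others) == 0L) stop("no isoform to test against the reference")
  rows <- lapply(others, function(iso) {
    vals <- pool$activity[pool$isoform == iso]
    gt <- gated_two_sample_test(vals, ref)
    data.frame(isoform = iso, n = length(vals), mean = mean(vals),
               ref_mean = mean(ref), test = gt$test,
               statistic = gt$statistic, p = gt$p)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Bundled CaMKII-beta isoform kinetic parameters
#'
#' Hill parameters (Vmax, Hill coefficient h, EC50 in nM calmodulin, with
#' standard errors) of purified CaMKII-beta splice isoforms assayed
#' in vitro against the Syntide 2 and tau-441 substrates, on the
#' V/Vmax(FL) scale. Used as ground truth for round-trip fitting checks
#' and as defaults for the synthetic activation-curve generator.
#'
#' @return `data.frame` with columns `isoform`, `substrate`, `vmax`,
#'   `vmax_se`, `h`, `h_se`, `ec50`, `ec50_se`.
#' @export
camk2b_kinetic_params <- function() {
  path <- system.file("extdata", "camk2b_kinetics.tsv",
                      package = "orthosplice", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
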