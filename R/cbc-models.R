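#' Complete-blood-count log-ratios
#'
#' Natural-log neutrophil-to-lymphocyte (NLR), neutrophil-to-WBC (NWR) and
#' lymphocyte-to-WBC (LWR) ratios. By construction
#' \code{log NWR - log LWR = log NLR} exactly.
#'
#' @param neutrophils,lymphocytes,wbc positive counts (1e9/L), vectorised
#' @return data.frame with columns `log_nlr`, `log_nwr`, `log_lwr`
#' @export
cbc_log_ratios <- function(neutrophils, lymphocytes, wbc) {
  if (any(neutrophils <= 0) || any(lymphocytes <= 0) || any(wbc <= 0))
    stop("cell counts must be strictly positive")
  data.frame(log_nlr = log(neutrophils / lymphocytes),
             log_nwr = log(neutrophils / wbc),
             log_lwr = log(lymphocytes / wbc))
}

#' Paired ratio change between visits
#'
#' Geometric-mean month-3 / baseline ratio for a paired quantity (e.g. the
#' neutrophil/WBC ratio), with a t-interval on the log differences. The
#' estimate is reported as a percentage of baseline, so 87 means the month-3
#' value is on average 87% of baseline.
#'
#' @param bl_values,mo3_values positive paired measurements; names (subject
#'   ids) are used for pairing when present, otherwise positional pairing is
#'   assumed
#' @param conf_level confidence level (default 0.95)
#' @return list with `estimate_pct`, `ci_pct` (length 2), `p.value`
#'   (one-sample t on log differences vs 0), `n_pairs`
#' @export
paired_ratio_change <- function(bl_values, mo3_values, conf_level = 0.95) {
  if (!is.null(names(bl_values)) && !is.null(names(mo3_values))) {
    shared <- intersect(names(bl_values), names(mo3_values))
    if (length(shared) < length(bl_values) || length(shared) < length(mo3_values))
      warning("dropping unpaired subjects: ",
              length(bl_values) + length(mo3_values) - 2 * length(shared))
    bl_values <- bl_values[shared]; mo3_values <- mo3_values[shared]
  } else if (length(bl_values) != length(mo3_values))
    stop("unnamed inputs must have equal length")
  if (length(bl_values) < 3) stop("need at least 3 pairs")
  if (any(bl_values <= 0) || any(mo3_values <= 0)) stop("values must be positive")
  d <- log(mo3_values / bl_values)
  n <- length(d)
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    est <- exp(m)
    return(list(estimate_pct = 100 * est, ci_pct = c(100 * est, 100 * est),
                p.value = if (m == 0) 1 else 0, n_pairs = n))
  }
  se <- s / sqrt(n)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  p <- 2 * stats::pt(-abs(m / se), df = n - 1)
  list(estimate_pct = 100 * exp(m),
       ci_pct = 100 * exp(c(m - tq * se, m + tq * se)),
       p.value = p, n_pairs = n)
}

#' Logistic regression with Wald inference
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()]) with Wald standard errors from the observed
#' information, odds ratios per unit covariate, and confidence intervals on
#' the log-odds scale. Complete or quasi-complete separation is detected
#' (diverging coefficients / saturated fitted probabilities) and reported as
#' an error.
#'
#' @param design data.frame or matrix of covariates (no intercept column)
#' @param outcome binary vector (logical or 0/1)
#' @param conf_level Wald CI level (default 0.95)
#' @return `LogisticFit` data.frame: one row per term with `coef`, `se`,
#'   `or`, `ci_low`, `ci_high`, `p.value`; attributes `converged`, `n`
#' @export
logistic_fit <- function(design, outcome, conf_level = 0.95) {
  outcome <- as.numeric(outcome)
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary")
  if (length(unique(outcome)) < 2)
    stop("separation: outcome is constant")
  df <- as.data.frame(design)
  dat <- cbind(df, .y = outcome)
  form <- if (ncol(df) == 0) .y ~ 1 else .y ~ .
  fit <- suppressWarnings(
    stats::glm(form, data = dat, family = stats::binomial()))
  qd <- qr(stats::model.matrix(fit))
  if (qd$rank < ncol(stats::model.matrix(fit))) stop("design is rank deficient")
  mu <- fit$fitted.values
  if (!fit$converged || any(abs(stats::coef(fit)) > 15) ||
      all(mu > 1 - 1e-8 | mu < 1e-8))
    stop("separation: logistic fit did not converge to a finite optimum")
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(term = rownames(sm), coef = sm[, 1], se = sm[, 2],
                    or = exp(sm[, 1]),
                    ci_low = exp(sm[, 1] - z * sm[, 2]),
                    ci_high = exp(sm[, 1] + z * sm[, 2]),
                    p.value = sm[, 4], row.names = NULL)
  attr(out, "converged") <- fit$converged
  attr(out, "n") <- length(outcome)
  class(out) <- c("LogisticFit", class(out))
  out
}

#' Logistic response model on a CBC log-ratio
#'
#' Models the probability of good-or-moderate EULAR response at month 3 as
#' a function of one baseline CBC log-ratio, either unadjusted or adjusted
#' for the a-priori covariates (biologic type, age, smoking status, disease
#' duration, mHAQ, concomitant MTX, number of prior biologics). Odds-ratio
#' scaling follows the reporting convention: per 1 natural-log unit for the
#' ratios, per 10 years for age and disease duration, per unit mHAQ, per
#' additional prior biologic.
#'
#' @param cbc_table data.frame with `neutrophils`, `lymphocytes`, `wbc`
#' @param meta data.frame with the response and covariate columns; the
#'   response is either a logical `response` column or an `eular` column
#'   ("good"/"moderate" vs "none")
#' @param ratio_choice "nlr", "nwr" or "lwr"
#' @param adjusted include the a-priori covariates (default TRUE)
#' @param covariate_names names of the adjustment columns present in `meta`
#' @return list with `fit` (a `LogisticFit`), `forest` (term, OR, CI, p,
#'   export-ready), `n_used`, `n_dropped` (listwise deletion count)
#' @export
response_model <- function(cbc_table, meta,
                           ratio_choice = c("nlr", "nwr", "lwr"),
                           adjusted = TRUE,
                           covariate_names = c("tnfi", "age", "smoker",
                                               "duration", "mhaq", "mtx",
                                               "prior_biologics")) {
  ratio_choice <- match.arg(ratio_choice)
  lr <- cbc_log_ratios(cbc_table$neutrophils, cbc_table$lymphocytes,
                       cbc_table$wbc)
  x <- lr[[paste0("log_", ratio_choice)]]
  outcome <- if (!is.null(meta$response)) as.logical(meta$response)
             else meta$eular %in% c("good", "moderate", "GR")
  design <- data.frame(ratio = x)
  names(design) <- paste0("log_", ratio_choice)
  if (adjusted) {
    miss <- setdiff(covariate_names, names(meta))
    if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
    cov <- meta[covariate_names]
    # reporting scale: decade units for age and disease duration
    if ("age" %in% names(cov)) cov$age <- cov$age / 10
    if ("duration" %in% names(cov)) cov$duration <- cov$duration / 10
    design <- cbind(design, cov)
  }
  cc <- stats::complete.cases(design) & !is.na(outcome)
  n_dropped <- sum(!cc)
  fit <- logistic_fit(design[cc, , drop = FALSE], outcome[cc])
  forest <- fit[fit$term != "(Intercept)",
                c("term", "or", "ci_low", "ci_high", "p.value")]
  list(fit = fit, forest = forest, n_used = sum(cc), n_dropped = n_dropped)
}

#' Genotype-by-response association test
#'
#' Pearson chi-square test of association for an R x C genotype-by-response
#' count table (no continuity correction for tables larger than 2x2), with
#' an option to pool several tables by summation before testing.
#'
#' @param ... one or more R x C count matrices; multiple tables are summed
#'   when `pool = TRUE`, otherwise only the first is tested
#' @param pool sum the supplied tables before testing (default TRUE)
#' @return list with `statistic`, `p.value`, `table` (the tested table)
#' @export
genotype_association <- function(..., pool = TRUE) {
  tabs <- lapply(list(...), as.matrix)
  if (!length(tabs)) stop("no table supplied")
  if (!all(vapply(tabs, function(t) all(dim(t) >= 2), TRUE)))
    stop("tables must be at least 2x2")
  if (!all(vapply(tabs, function(t) all(t >= 0 & t == round(t)), TRUE)))
    stop("counts must be nonnegative integers")
  tab <- if (pool) Reduce(`+`, tabs) else tabs[[1]]
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: zero margin")
  correct <- all(dim(tab) == 2)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p.value = ht$p.value, table = tab)
}
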