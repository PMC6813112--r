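#' Log counts-per-million transformation
#'
#' Converts a genes x samples count matrix to log2 counts per million with a
#' damping prior: \code{log2((count + prior) / (libsize + 2 * prior) * 1e6)}.
#'
#' @param counts nonnegative count matrix, genes x samples
#' @param prior_count pseudo-count added to every observation (default 0.5)
#' @param lib_size optional library sizes; column sums by default
#' @return matrix of log2-CPM values, same dimensions as `counts`
#' @export
log_cpm <- function(counts, prior_count = 0.5, lib_size = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (any(lib_size <= 0)) stop("zero or negative library size")
  if (length(lib_size) != ncol(counts)) stop("lib_size length mismatch")
  t(log2(t(counts + prior_count) / (lib_size + 2 * prior_count) * 1e6))
}

#' Mean-variance precision weights for log-CPM
#'
#' Fits per-gene residual standard deviations (on the quarter-root variance
#' scale, i.e. sqrt of the residual SD) against average log expression with
#' lowess (span 0.5), then predicts the trend at each observation's fitted
#' log expression and converts it to a precision weight
#' \code{predicted_sqrt_sd^-4}. Genes with larger expected variance therefore
#' receive proportionally smaller weights in the linear model.
#'
#' @param logcpm matrix of log2-CPM values, genes x samples
#' @param design model matrix (samples x coefficients), full rank
#' @param span lowess span for the trend fit (default 0.5)
#' @return weight matrix of the same shape as `logcpm`, strictly positive
#' @export
voom_weights <- function(logcpm, design, span = 0.5) {
  logcpm <- as.matrix(logcpm)
  design <- as.matrix(design)
  n <- ncol(logcpm)
  if (nrow(design) != n) stop("design rows must match samples")
  df_resid <- n - qr(design)$rank
  if (df_resid < 2) stop("need >= 2 residual degrees of freedom")
  fit <- stats::lm.fit(design, t(logcpm))
  s <- sqrt(colSums(as.matrix(fit$residuals)^2) / df_resid)
  if (all(s < 1e-10)) stop("all genes constant: no variance to model")
  sx <- rowMeans(logcpm)
  sy <- sqrt(s)
  keep <- s > 1e-10
  lo <- stats::lowess(sx[keep], sy[keep], f = span)
  fitted_vals <- t(as.matrix(fit$fitted.values))   # genes x samples
  trend <- stats::approx(lo$x, lo$y, xout = as.vector(fitted_vals),
                         rule = 2, ties = mean)$y
  w <- matrix(trend, nrow(logcpm), n)^-4
  w[!is.finite(w)] <- max(w[is.finite(w)])
  dimnames(w) <- dimnames(logcpm)
  w
}

#' Per-feature weighted least squares
#'
#' Fits the same design to every feature by weighted least squares with
#' feature-specific observation weights, returning coefficients, unscaled
#' coefficient standard errors, residual variances and degrees of freedom.
#'
#' @param y response matrix, features x samples
#' @param design model matrix, samples x p, full rank
#' @param weights positive weight matrix of the same shape as `y`, or NULL
#'   for unit weights
#' @return list with `coefficients` (features x p), `stdev_unscaled`
#'   (features x p; multiply by sqrt residual variance for the SE), `sigma2`
#'   (weighted RSS / df), `df_residual`
#' @export
fit_weighted_lm <- function(y, design, weights = NULL) {
  y <- as.matrix(y)
  design <- as.matrix(design)
  n <- ncol(y); p <- ncol(design)
  qd <- qr(design)
  if (qd$rank < p) {
    bad <- colnames(design)[qd$pivot[(qd$rank + 1):p]]
    stop("design is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  df <- n - p
  if (is.null(weights)) weights <- matrix(1, nrow(y), n)
  if (any(weights <= 0)) stop("weights must be strictly positive")
  G <- nrow(y)
  coefs <- matrix(NA_real_, G, p, dimnames = list(rownames(y), colnames(design)))
  stdu <- coefs
  sig2 <- numeric(G)
  for (g in seq_len(G)) {
    fit <- stats::lm.wfit(design, y[g, ], weights[g, ])
    coefs[g, ] <- fit$coefficients
    R <- qr.R(fit$qr)
    xtxinv <- chol2inv(R)
    stdu[g, ] <- sqrt(diag(xtxinv))
    sig2[g] <- if (df > 0) sum(weights[g, ] * fit$residuals^2) / df else NA_real_
  }
  if (df == 0) warning("zero residual degrees of freedom: variances undefined")
  list(coefficients = coefs, stdev_unscaled = stdu, sigma2 = sig2,
       df_residual = df)
}

# Invert the trigamma function by Newton iteration on 1/psi'(x);
# used by the method-of-moments prior fit.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks per-feature residual variances toward a common prior estimated by
#' closed-form method of moments on the log variances (trigamma inversion),
#' and recomputes t-statistics with the posterior variances
#' \code{(d0 * s0^2 + df * s^2) / (d0 + df)} on `d0 + df` degrees of freedom.
#' `d0 = 0` reproduces ordinary per-feature t-statistics; `d0 = Inf` pools
#' every feature to the common prior variance.
#'
#' @param fits result of [fit_weighted_lm()]
#' @param coef name or index of the coefficient to test (default last column)
#' @param prior optional list(df0, s02) to bypass estimation (used for limit
#'   checks); estimated from the data when NULL
#' @return data.frame with columns `effect`, `t`, `p.value`, `s2_post`,
#'   `df_total`, plus attributes `df_prior` and `s2_prior`
#' @export
ebayes_moderate <- function(fits, coef = ncol(fits$coefficients), prior = NULL) {
  s2 <- fits$sigma2
  if (any(!is.finite(s2))) stop("non-finite residual variances")
  df <- fits$df_residual
  if (is.null(prior)) {
    if (length(s2) < 10) stop("need >= 10 features to estimate the prior")
    z <- log(pmax(s2, 1e-300))
    e <- z - digamma(df / 2) + log(df / 2)
    n <- length(e)
    evar <- mean((e - mean(e))^2) * n / (n - 1) - trigamma(df / 2)
    if (is.finite(evar) && evar > 0) {
      df0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(mean(e) + digamma(df0 / 2) - log(df0 / 2))
    } else {
      df0 <- Inf
      s02 <- exp(mean(e))
    }
  } else {
    df0 <- prior$df0; s02 <- prior$s02
  }
  s2_post <- if (is.infinite(df0)) rep(s02, length(s2))
             else (df0 * s02 + df * s2) / (df0 + df)
  eff <- fits$coefficients[, coef]
  su <- fits$stdev_unscaled[, coef]
  tmod <- eff / (su * sqrt(s2_post))
  df_tot <- df0 + df
  p <- 2 * stats::pt(-abs(tmod), df = df_tot)
  out <- data.frame(effect = eff, t = tmod, p.value = p,
                    s2_post = s2_post, df_total = df_tot)
  attr(out, "df_prior") <- df0
  attr(out, "s2_prior") <- s02
  out
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR adjustment: \code{q_i = min_{j: p_j >= p_i} p_j * n / rank_j},
#' capped at 1.
#'
#' @param p vector of p-values in [0, 1]; NA not allowed
#' @return q-values in the original order
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p))) stop("NA/NaN p-values not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}

#' Differential expression for one contrast
#'
#' Runs the full precision-weighted pipeline for a single contrast on a
#' feature matrix. Counts are filtered (features must have at least
#' `min_samples` samples with count >= `min_count`), transformed to log2-CPM
#' and given mean-variance precision weights; intensity matrices are assumed
#' already on the log scale and modelled with unit weights. Paired month-3
#' vs baseline contrasts include one indicator per subject; group contrasts
#' at baseline compare responders to non-responders. Extra covariate columns
#' named in `covariates` are taken from `meta`.
#'
#' @param mat features x samples matrix (raw counts if `is_counts`, log
#'   intensities otherwise); column names must match `meta$sample`
#' @param meta data.frame with columns `sample`, `subject`, `visit`
#'   ("BL"/"MO3"), `eular` (for group contrasts)
#' @param contrast "MO3-BL" (paired within subject) or "GR-NR" (baseline
#'   samples only; good vs non-responders)
#' @param is_counts TRUE to apply the count route (filter, log-CPM,
#'   precision weights)
#' @param covariates character vector of additional `meta` columns to adjust
#'   for
#' @param min_count,min_samples count filter: keep features with at least
#'   `min_samples` samples at count >= `min_count`
#' @return EffectTable data.frame: `feature`, `effect` (log2 scale), `t`,
#'   `p.value`, `q.value`, `mean_expr`, `df_residual`
#' @export
run_differential <- function(mat, meta, contrast = c("MO3-BL", "GR-NR"),
                             is_counts = TRUE, covariates = character(),
                             min_count = 10, min_samples = 3) {
  contrast <- match.arg(contrast)
  mat <- as.matrix(mat)
  if (is.null(colnames(mat)) || !identical(colnames(mat), as.character(meta$sample)))
    stop("matrix columns must match meta$sample in order")
  if (contrast == "GR-NR") {
    keep_s <- meta$visit == "BL"
    meta <- meta[keep_s, , drop = FALSE]
    mat <- mat[, keep_s, drop = FALSE]
    grp <- factor(ifelse(meta$eular %in% c("good", "GR"), "GR", "NR"),
                  levels = c("NR", "GR"))
    if (min(table(grp)) < 2) stop("contrast needs >= 2 samples per level")
    design <- stats::model.matrix(~grp)
    colnames(design)[ncol(design)] <- "GR-NR"
  } else {
    visit <- factor(meta$visit, levels = c("BL", "MO3"))
    if (min(table(visit)) < 2) stop("contrast needs >= 2 samples per level")
    subject <- factor(meta$subject)
    design <- stats::model.matrix(~subject + visit)
    colnames(design)[ncol(design)] <- "MO3-BL"
  }
  for (cv in covariates) {
    v <- meta[[cv]]
    if (is.null(v)) stop("covariate '", cv, "' not in meta")
    mm <- stats::model.matrix(~v)[, -1, drop = FALSE]
    colnames(mm) <- paste0(cv, seq_len(ncol(mm)))
    design <- cbind(design, mm)
  }
  # contrast column kept last so downstream default coef picks it up
  cc <- which(colnames(design) %in% c("MO3-BL", "GR-NR"))
  design <- cbind(design[, -cc, drop = FALSE], design[, cc, drop = FALSE])
  if (is_counts) {
    keep <- rowSums(mat >= min_count) >= min_samples
    if (!any(keep)) stop("no features pass the count filter")
    mat <- mat[keep, , drop = FALSE]
    y <- log_cpm(mat)
    w <- voom_weights(y, design)
  } else {
    y <- mat
    w <- NULL
  }
  fits <- fit_weighted_lm(y, design, w)
  mod <- ebayes_moderate(fits)
  data.frame(feature = rownames(y),
             effect = mod$effect, t = mod$t, p.value = mod$p.value,
             q.value = bh_fdr(mod$p.value),
             mean_expr = rowMeans(y), df_residual = fits$df_residual,
             row.names = NULL)
}
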