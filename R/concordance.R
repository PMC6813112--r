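#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (average ranks on ties).
#' Constant input is rejected rather than returning NA.
#'
#' @param x,y equal-length numeric vectors, n >= 3
#' @return correlation in [-1, 1]
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for a constant vector")
  stats::cor(rank(x), rank(y), method = "pearson")
}

# Closed-form per-feature contrast effects used for both the observed
# statistic and the permutation null: precision-weighted paired difference
# for the within-subject MO3-BL contrast, weighted group-mean difference for
# the baseline GR-NR contrast. For the paired design with subject fixed
# effects these equal the weighted-LS contrast coefficient.
contrast_effects <- function(mat, meta, contrast, weights = NULL,
                             flip = NULL, perm = NULL) {
  if (contrast == "MO3-BL") {
    subj <- unique(meta$subject)
    ibl <- match(paste0(subj, ".BL"), paste0(meta$subject, ".", meta$visit))
    imo <- match(paste0(subj, ".MO3"), paste0(meta$subject, ".", meta$visit))
    d <- mat[, imo, drop = FALSE] - mat[, ibl, drop = FALSE]
    w <- if (is.null(weights)) matrix(1, nrow(mat), length(subj))
         else 1 / (1 / weights[, imo, drop = FALSE] + 1 / weights[, ibl, drop = FALSE])
    s <- if (is.null(flip)) rep(1, length(subj)) else flip
    as.vector(((d * w) %*% s) / rowSums(w))
  } else {
    grp <- ifelse(meta$eular %in% c("good", "GR"), "GR", "NR")
    if (!is.null(perm)) grp <- grp[perm]
    w <- if (is.null(weights)) matrix(1, nrow(mat), ncol(mat)) else weights
    gsel <- grp == "GR"
    mg <- ((mat * w) %*% gsel) / (w %*% gsel)
    mn <- ((mat * w) %*% !gsel) / (w %*% !gsel)
    as.vector(mg - mn)
  }
}

# Prepare one dataset for the permutation engine: baseline subsetting for
# GR-NR, count transform and precision weights where applicable.
prep_concordance_data <- function(mat, meta, contrast, is_counts) {
  mat <- as.matrix(mat)
  if (contrast == "GR-NR") {
    keep <- meta$visit == "BL"
    meta <- meta[keep, , drop = FALSE]
    mat <- mat[, keep, drop = FALSE]
  }
  if (is_counts) {
    y <- log_cpm(mat)
    if (contrast == "GR-NR") {
      design <- stats::model.matrix(~factor(meta$eular))
    } else {
      design <- stats::model.matrix(~factor(meta$subject) + factor(meta$visit))
    }
    w <- voom_weights(y, design)
  } else {
    y <- mat
    w <- NULL
  }
  list(y = y, w = w, meta = meta)
}

#' Cross-cohort concordance of contrast effects with a permutation null
#'
#' Computes the Spearman correlation of two datasets' per-feature contrast
#' effects over their shared features, and assesses it against a permutation
#' null built by re-randomising the contrast labels independently within
#' each dataset: for the paired month-3 vs baseline contrast the null flips
#' BL/MO3 within subject (sign-flip null, preserving pairing); for the
#' baseline responder contrast it permutes group labels across subjects.
#' Effects (observed and null) are computed by the same closed-form weighted
#' estimator, with precision weights held fixed across permutations.
#' The p-value is two-sided on |rho|:
#' \code{p = (1 + #\{|rho_null| >= |rho_obs|\}) / (n_perm + 1)}.
#'
#' @param matrixA,matrixB features x samples matrices (shared feature names
#'   are matched by row name)
#' @param metaA,metaB matching metadata (`sample`, `subject`, `visit`,
#'   `eular`)
#' @param contrast "MO3-BL" or "GR-NR"
#' @param n_perm number of permutations (>= 99; default 1000)
#' @param seed integer seed; each dataset draws from its own derived seed so
#'   the p-value is invariant to swapping A and B
#' @param is_counts TRUE to run both matrices through the count route
#' @return ConcordanceResult list: `rho`, `p.value`, `n_features`,
#'   `n_permutations`, `seed`, `subset`
#' @export
permutation_concordance <- function(matrixA, metaA, matrixB, metaB,
                                    contrast = c("MO3-BL", "GR-NR"),
                                    n_perm = 1000, seed = 1L,
                                    is_counts = TRUE, subset = "all features") {
  contrast <- match.arg(contrast)
  if (n_perm < 99) stop("n_perm must be >= 99")
  shared <- intersect(rownames(matrixA), rownames(matrixB))
  if (length(shared) < 50) stop("need >= 50 shared features")
  A <- prep_concordance_data(matrixA[shared, , drop = FALSE], metaA, contrast, is_counts)
  B <- prep_concordance_data(matrixB[shared, , drop = FALSE], metaB, contrast, is_counts)

  effA <- contrast_effects(A$y, A$meta, contrast, A$w)
  effB <- contrast_effects(B$y, B$meta, contrast, B$w)
  rho_obs <- spearman_rho(effA, effB)

  null_effects <- function(dat, sub_seed) {
    set.seed(sub_seed)
    if (contrast == "MO3-BL") {
      n_sub <- length(unique(dat$meta$subject))
      vapply(seq_len(n_perm), function(i)
        contrast_effects(dat$y, dat$meta, contrast, dat$w,
                         flip = sample(c(-1, 1), n_sub, replace = TRUE)),
        numeric(nrow(dat$y)))
    } else {
      n <- nrow(dat$meta)
      vapply(seq_len(n_perm), function(i)
        contrast_effects(dat$y, dat$meta, contrast, dat$w,
                         perm = sample.int(n)),
        numeric(nrow(dat$y)))
    }
  }
  # sub-seeds derive from each dataset's content, so each dataset keeps its
  # own null stream and the p-value is invariant to swapping A and B
  data_seed <- function(dat)
    seed + as.integer(round(sum(abs(dat$y))) %% 10007)
  nullA <- null_effects(A, data_seed(A))
  nullB <- null_effects(B, data_seed(B))
  rho_null <- vapply(seq_len(n_perm),
                     function(i) spearman_rho(nullA[, i], nullB[, i]),
                     numeric(1))
  p <- (1 + sum(abs(rho_null) >= abs(rho_obs))) / (n_perm + 1)
  structure(list(rho = rho_obs, p.value = p, n_features = length(shared),
                 n_permutations = n_perm, seed = seed, subset = subset,
                 null_rho = rho_null, effects_A = stats::setNames(effA, shared),
                 effects_B = stats::setNames(effB, shared)),
            class = "ConcordanceResult")
}

#' Most variable features at baseline
#'
#' Ranks features by the variance of baseline log-CPM across all baseline
#' samples (both response groups pooled) and returns the top fraction. Ties
#' are broken by feature identifier so the subset is deterministic.
#'
#' @param logcpm_baseline features x baseline-samples matrix of log-CPM
#' @param fraction fraction of features to keep, in (0, 1]
#' @return character vector of feature names
#' @export
top_variable_subset <- function(logcpm_baseline, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  v <- apply(logcpm_baseline, 1, stats::var)
  n_keep <- max(1L, floor(length(v) * fraction + 1e-9))
  ord <- order(-v, rownames(logcpm_baseline))
  out <- rownames(logcpm_baseline)[ord][seq_len(n_keep)]
  if (length(out) == 0) stop("empty subset")
  out
}
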