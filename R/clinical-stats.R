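#' DAS28-CRP composite disease activity score
#'
#' Computes the 28-joint disease activity score based on C-reactive protein:
#' \deqn{0.56\sqrt{TJC28} + 0.28\sqrt{SJC28} + 0.36\,\ln(CRP+1) + 0.014\,GH + 0.96}
#' where TJC28/SJC28 are tender and swollen joint counts (0-28), CRP is in
#' mg/L and GH is the patient global health assessment on a 0-100 visual
#' analogue scale.
#'
#' @param tjc28 integer tender joint count, 0-28 (vectorised)
#' @param sjc28 integer swollen joint count, 0-28
#' @param crp C-reactive protein, mg/L, >= 0
#' @param gh patient global health VAS, 0-100
#' @return numeric score(s); monotone nondecreasing in every argument
#' @examples
#' das28_crp(9, 7, 5, 50)   # 4.7258
#' @export
das28_crp <- function(tjc28, sjc28, crp, gh) {
  if (any(!is.finite(tjc28)) || any(tjc28 < 0) || any(tjc28 > 28) ||
      any(tjc28 != round(tjc28)))
    stop("tjc28 must be an integer in [0, 28]")
  if (any(!is.finite(sjc28)) || any(sjc28 < 0) || any(sjc28 > 28) ||
      any(sjc28 != round(sjc28)))
    stop("sjc28 must be an integer in [0, 28]")
  if (any(!is.finite(crp)) || any(crp < 0)) stop("crp must be >= 0 mg/L")
  if (any(!is.finite(gh)) || any(gh < 0) || any(gh > 100))
    stop("gh must be in [0, 100]")
  0.56 * sqrt(tjc28) + 0.28 * sqrt(sjc28) + 0.36 * log(crp + 1) +
    0.014 * gh + 0.96
}

#' EULAR response classification from baseline and follow-up DAS28
#'
#' Applies the standard EULAR response matrix to a baseline and a follow-up
#' DAS28-CRP score. "good" requires a follow-up score <= 3.2 together with an
#' improvement > 1.2; "none" is an improvement <= 0.6, or an improvement
#' <= 1.2 with follow-up disease activity still above 5.1; everything else
#' is "moderate".
#'
#' @param das_bl baseline DAS28-CRP (vectorised)
#' @param das_fu follow-up DAS28-CRP
#' @return data.frame with columns `value` (factor good/moderate/none),
#'   `das_bl`, `das_fu`, `improvement`
#' @export
eular_classify <- function(das_bl, das_fu) {
  if (any(!is.finite(das_bl)) || any(das_bl < 0) ||
      any(!is.finite(das_fu)) || any(das_fu < 0))
    stop("DAS28 scores must be finite and >= 0")
  n <- max(length(das_bl), length(das_fu))
  das_bl <- rep_len(das_bl, n); das_fu <- rep_len(das_fu, n)
  imp <- das_bl - das_fu
  value <- ifelse(das_fu <= 3.2 & imp > 1.2, "good",
           ifelse(imp <= 0.6 | (imp <= 1.2 & das_fu > 5.1), "none",
                  "moderate"))
  data.frame(value = factor(value, levels = c("good", "moderate", "none")),
             das_bl = das_bl, das_fu = das_fu, improvement = imp)
}

#' Yates continuity-corrected chi-square test for a 2x2 table
#'
#' Association test for a 2x2 contingency table with Yates' continuity
#' correction, as used for the categorical attributes of the cohort
#' descriptive table. Degenerate tables (a zero row or column margin) are
#' rejected rather than returning NaN.
#'
#' @param table_2x2 2x2 matrix of nonnegative integer counts
#' @return list with `statistic` (corrected X^2) and `p.value` (chi-square_1
#'   upper tail)
#' @export
chi_square_yates <- function(table_2x2) {
  tab <- as.matrix(table_2x2)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: a row or column margin is zero")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test used for the continuous attributes of the cohort
#' descriptive table. The exact null distribution is enumerated when the
#' pooled sample size is at most 20 and there are no ties; otherwise the
#' normal approximation with the tie correction is used.
#'
#' @param x,y numeric samples, both non-empty
#' @return list with `statistic` (rank-sum W) and `p.value`
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = !exact))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Drug-level exclusion filter for non-responders
#'
#' Removes EULAR non-responders whose month-3 serum drug level is below
#' 800 ng/mL (strictly below; a level of exactly 800 is retained), the
#' pharmacokinetic criterion guarding against apparent non-response driven by
#' anti-drug antibodies or non-adherence. Responders are never removed.
#'
#' @param meta data.frame with at least columns `eular` ("good"/"moderate"/
#'   "none" or "GR"/"NR") and `drug_level_mo3` (ng/mL, may be NA)
#' @param threshold exclusion threshold, ng/mL (default 800)
#' @param on_missing what to do with a non-responder lacking a drug level:
#'   "keep" (default, with a warning) or "drop"
#' @return the filtered data.frame, with attribute `filter_log` describing
#'   every decision taken
#' @export
cohort_filter <- function(meta, threshold = 800, on_missing = c("keep", "drop")) {
  on_missing <- match.arg(on_missing)
  if (!all(c("eular", "drug_level_mo3") %in% names(meta)))
    stop("meta must contain 'eular' and 'drug_level_mo3'")
  is_nr <- meta$eular %in% c("none", "NR")
  lev <- meta$drug_level_mo3
  drop_low <- is_nr & !is.na(lev) & lev < threshold
  miss_nr <- is_nr & is.na(lev)
  drop <- drop_low
  if (any(miss_nr)) {
    if (on_missing == "drop") drop <- drop | miss_nr
    else warning(sum(miss_nr), " non-responder(s) with missing drug level kept")
  }
  log_df <- data.frame(
    row = seq_len(nrow(meta)),
    non_responder = is_nr,
    drug_level_mo3 = lev,
    action = ifelse(drop, "excluded", "retained"),
    reason = ifelse(drop_low, sprintf("NR drug level < %g ng/mL", threshold),
             ifelse(miss_nr, "NR missing drug level", "")))
  out <- meta[!drop, , drop = FALSE]
  attr(out, "filter_log") <- log_df
  out
}

#' Cohort descriptive table with responder vs non-responder tests
#'
#' Builds a Table-1-style summary comparing good responders and
#' non-responders: continuous attributes are reported as mean (SD) per group
#' with a two-sample Wilcoxon p-value; categorical attributes as N (%) per
#' group with a Yates-corrected chi-square p-value on the 2x2 table of the
#' attribute's first declared level against the rest.
#'
#' @param meta data.frame of per-subject attributes including a `group`
#'   column with exactly two levels (e.g. "GR"/"NR")
#' @param types named character vector mapping attribute column names to
#'   "continuous" or "categorical"
#' @return data.frame with one row per attribute: summaries for each group
#'   and the p-value; single-level categoricals get NA with a flag
#' @export
table1_summary <- function(meta, types) {
  if (!"group" %in% names(meta)) stop("meta must contain a 'group' column")
  grp <- factor(meta$group)
  if (nlevels(grp) != 2) stop("'group' must have exactly two levels")
  bad <- setdiff(unname(types), c("continuous", "categorical"))
  if (length(bad)) stop("unknown attribute type(s): ", paste(bad, collapse = ", "))
  g1 <- levels(grp)[1]; g2 <- levels(grp)[2]
  rows <- lapply(names(types), function(at) {
    v <- meta[[at]]
    if (types[[at]] == "continuous") {
      s <- function(z) sprintf("%.3g (%.3g)", mean(z, na.rm = TRUE),
                               stats::sd(z, na.rm = TRUE))
      p <- wilcoxon_rank_sum(v[grp == g1 & !is.na(v)],
                             v[grp == g2 & !is.na(v)])$p.value
      data.frame(attribute = at, type = "continuous",
                 summary1 = s(v[grp == g1]), summary2 = s(v[grp == g2]),
                 p.value = p, flag = "")
    } else {
      f <- factor(v)
      if (nlevels(f) < 2)
        return(data.frame(attribute = at, type = "categorical",
                          summary1 = NA_character_, summary2 = NA_character_,
                          p.value = NA_real_, flag = "single-level"))
      lev1 <- levels(f)[1]
      tab <- rbind(c(sum(f == lev1 & grp == g1, na.rm = TRUE),
                     sum(f != lev1 & grp == g1, na.rm = TRUE)),
                   c(sum(f == lev1 & grp == g2, na.rm = TRUE),
                     sum(f != lev1 & grp == g2, na.rm = TRUE)))
      s <- function(i) sprintf("%d (%.0f%%)", tab[i, 1], 100 * tab[i, 1] / sum(tab[i, ]))
      data.frame(attribute = at, type = "categorical",
                 summary1 = s(1), summary2 = s(2),
                 p.value = chi_square_yates(tab)$p.value, flag = "")
    }
  })
  out <- do.call(rbind, rows)
  names(out)[3:4] <- paste0(c(g1, g2))
  out
}
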