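#' Cell-type specificity scores from a reference
#'
#' For every gene and cell type, the log2 fold difference between the cell
#' type's reference expression and the mean of all other cell types, with a
#' pseudocount bounding the ratio for dropout genes:
#' \code{score(g, c) = log2((ref_cg + eps) / (mean_{c' != c} ref_c'g + eps))}.
#' A gene expressed equally everywhere scores 0 for every cell type.
#'
#' @param reference `CellTypeReference` or a cell-type x gene matrix
#' @param pseudocount eps added to numerator and denominator (default 1)
#' @return genes x cell-types matrix of scores
#' @export
specificity_scores <- function(reference, pseudocount = 1) {
  prof <- if (inherits(reference, "CellTypeReference")) reference$profiles
          else as.matrix(reference)
  if (nrow(prof) < 2) stop("need at least 2 cell types")
  if (any(prof < 0)) stop("reference profiles must be nonnegative")
  k <- nrow(prof)
  tot <- colSums(prof)
  sc <- sapply(seq_len(k), function(c) {
    others <- (tot - prof[c, ]) / (k - 1)
    log2((prof[c, ] + pseudocount) / (others + pseudocount))
  })
  colnames(sc) <- rownames(prof)
  sc
}

#' Marker gene sets per cell type
#'
#' Assigns gene g to cell type c iff `score(g, c) >= threshold` and c is the
#' argmax of g's scores; the argmax rule makes the sets disjoint. Sets
#' falling below `min_size` are excluded with a warning.
#'
#' @param scores genes x cell-types specificity matrix
#' @param threshold minimum log2 specificity (default 2, i.e. 4-fold)
#' @param min_size minimum set size to retain (default 10)
#' @return named list of character vectors (gene identifiers) per cell type
#' @export
build_marker_sets <- function(scores, threshold = 2, min_size = 10) {
  if (threshold <= 0) stop("threshold must be positive")
  best <- max.col(scores, ties.method = "first")
  best_score <- scores[cbind(seq_len(nrow(scores)), best)]
  assign <- ifelse(best_score >= threshold, colnames(scores)[best], NA)
  sets <- lapply(stats::setNames(colnames(scores), colnames(scores)),
                 function(ct) rownames(scores)[!is.na(assign) & assign == ct])
  small <- names(sets)[vapply(sets, length, 0L) < min_size]
  if (length(small))
    warning("excluding marker set(s) below min_size: ",
            paste(small, collapse = ", "))
  sets[setdiff(names(sets), small)]
}

#' Correlation between contrast effects and cell-type specificity
#'
#' Spearman correlation between per-gene contrast effects (e.g. month 3 vs
#' baseline) and a cell type's specificity scores over the shared genes —
#' the genome-wide view of whether genes specific to that cell type move
#' with the contrast.
#'
#' @param effect_table EffectTable from [run_differential()]
#' @param scores genes x cell-types specificity matrix
#' @param cell_type column of `scores` to use
#' @return list with `rho`, `n_genes`, `cell_type`, and `data` (per-gene
#'   effect and score, for 2D density display)
#' @export
effect_specificity_correlation <- function(effect_table, scores, cell_type) {
  shared <- intersect(effect_table$feature, rownames(scores))
  if (length(shared) < 100) stop("need >= 100 shared genes")
  eff <- effect_table$effect[match(shared, effect_table$feature)]
  sp <- scores[shared, cell_type]
  list(rho = spearman_rho(eff, sp), n_genes = length(shared),
       cell_type = cell_type,
       data = data.frame(feature = shared, effect = eff, specificity = sp))
}

#' Marker-set mean effect with a permutation p-value
#'
#' The set statistic is the mean contrast effect over the set's genes (from
#' the same closed-form weighted estimator used genome-wide). The null
#' re-randomises the contrast labels (within cohort when two cohorts are
#' supplied, averaging the per-cohort statistics) and recomputes the set
#' mean; the p-value is two-sided:
#' \code{(1 + #\{|null| >= |obs|\}) / (n_perm + 1)}.
#'
#' @param cohorts list of one or two cohort lists, each with elements `mat`
#'   (features x samples), `meta`, and `is_counts`
#' @param contrast "GR-NR" or "MO3-BL"
#' @param gene_set character vector of feature names
#' @param compartment "innate" or "adaptive" label carried into the result
#' @param cell_type label carried into the result
#' @param n_perm permutations (default 1000)
#' @param seed integer seed
#' @param min_size minimum usable set size (default 10)
#' @return `CellTypeSetResult` list: `cell_type`, `compartment`,
#'   `mean_effect`, `p.value`, `set_size`, `n_permutations`
#' @export
set_effect_with_permutation <- function(cohorts, contrast, gene_set,
                                        compartment = NA_character_,
                                        cell_type = NA_character_,
                                        n_perm = 1000, seed = 1L,
                                        min_size = 10) {
  if (!is.null(cohorts$mat)) cohorts <- list(cohorts)
  preps <- lapply(cohorts, function(co) {
    p <- prep_concordance_data(co$mat, co$meta, contrast, co$is_counts)
    if (contrast == "GR-NR" &&
        min(table(p$meta$eular %in% c("good", "GR"))) < 2)
      stop("contrast groups need >= 2 samples")
    p$set_idx <- match(intersect(gene_set, rownames(p$y)), rownames(p$y))
    p
  })
  sizes <- vapply(preps, function(p) length(p$set_idx), 0L)
  if (any(sizes < min_size))
    stop("gene set smaller than min_size after matching features")
  set_mean <- function(p, flip = NULL, perm = NULL) {
    eff <- contrast_effects(p$y, p$meta, contrast, p$w, flip = flip, perm = perm)
    mean(eff[p$set_idx])
  }
  obs <- mean(vapply(preps, set_mean, numeric(1)))
  set.seed(seed)
  null_stat <- vapply(seq_len(n_perm), function(i) {
    mean(vapply(preps, function(p) {
      if (contrast == "MO3-BL")
        set_mean(p, flip = sample(c(-1, 1), length(unique(p$meta$subject)),
                                  replace = TRUE))
      else set_mean(p, perm = sample.int(nrow(p$meta)))
    }, numeric(1)))
  }, numeric(1))
  p <- (1 + sum(abs(null_stat) >= abs(obs))) / (n_perm + 1)
  structure(list(cell_type = cell_type, compartment = compartment,
                 mean_effect = obs, p.value = p,
                 set_size = min(sizes), n_permutations = n_perm, seed = seed),
            class = "CellTypeSetResult")
}

#' Innate vs adaptive compartment summary
#'
#' Aggregates per-cell-type set results into compartment-level means and a
#' sign-concordance flag: TRUE when every innate set moves in one direction
#' and every adaptive set in the other (the innate/adaptive balance
#' pattern).
#'
#' @param results list of `CellTypeSetResult` objects covering both
#'   compartments
#' @return list with `mean_innate`, `mean_adaptive`, `concordant` (flag),
#'   `direction` ("innate-up" / "adaptive-up" / NA), and the per-set table
#' @export
innate_adaptive_summary <- function(results) {
  tab <- do.call(rbind, lapply(results, function(r)
    data.frame(cell_type = r$cell_type, compartment = r$compartment,
               mean_effect = r$mean_effect, p.value = r$p.value,
               set_size = r$set_size)))
  if (!all(c("innate", "adaptive") %in% tab$compartment))
    stop("need at least one result per compartment")
  inn <- tab$mean_effect[tab$compartment == "innate"]
  ada <- tab$mean_effect[tab$compartment == "adaptive"]
  concordant <- (all(inn > 0) && all(ada < 0)) || (all(inn < 0) && all(ada > 0))
  direction <- if (!concordant) NA_character_
               else if (all(inn > 0)) "innate-up" else "adaptive-up"
  list(mean_innate = mean(inn), mean_adaptive = mean(ada),
       concordant = concordant, direction = direction, sets = tab)
}
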