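#' Run configuration for the synthetic two-cohort analysis
#'
#' Assembles and validates a configuration for the orchestrated analyses.
#' Every stochastic stage draws from a named sub-seed derived from the
#' master seed, so a configuration fully determines the outputs. Configs can
#' be round-tripped through YAML.
#'
#' @param seed master integer seed
#' @param n_genes genes in the synthetic reference
#' @param marker_fraction fraction of marker genes in the reference
#' @param cohort_sizes list of c(GR, NR) subject counts per cohort
#' @param treatment_neutrophil_multiplier,response_innate_shift generator
#'   effect sizes (defaults: the study conditions)
#' @param n_perm permutation count for concordance and set statistics
#' @param fdr_level FDR threshold used in reports
#' @param variable_fraction top-variable-gene fraction
#' @param marker_threshold,marker_min_size marker-set construction settings
#' @param out_dir output directory (created on run)
#' @return validated config list of class `RunConfig`
#' @export
run_config <- function(seed = 1L, n_genes = 600, marker_fraction = 0.5,
                       cohort_sizes = list(C1 = c(19, 21), C2 = c(21, 15)),
                       treatment_neutrophil_multiplier = 0.87,
                       response_innate_shift = 0.10,
                       n_perm = 1000, fdr_level = 0.05,
                       variable_fraction = 0.1,
                       marker_threshold = 2, marker_min_size = 10,
                       out_dir = "results") {
  stopifnot(seed == round(seed), n_perm >= 99, n_genes >= 6,
            fdr_level > 0, fdr_level < 1)
  seeds <- list(reference = seed * 13L + 1L)
  for (i in seq_along(cohort_sizes))
    seeds[[paste0("cohort_", names(cohort_sizes)[i])]] <- seed * 13L + 1L + i
  seeds$concordance <- seed * 13L + 11L
  seeds$sets <- seed * 13L + 12L
  seeds$cbc <- seed * 13L + 13L
  structure(list(seed = as.integer(seed), seeds = seeds, n_genes = n_genes,
                 marker_fraction = marker_fraction,
                 cohort_sizes = cohort_sizes,
                 treatment_neutrophil_multiplier = treatment_neutrophil_multiplier,
                 response_innate_shift = response_innate_shift,
                 n_perm = n_perm, fdr_level = fdr_level,
                 variable_fraction = variable_fraction,
                 marker_threshold = marker_threshold,
                 marker_min_size = marker_min_size, out_dir = out_dir),
            class = "RunConfig")
}

#' @rdname run_config
#' @param path YAML file
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$cohort_sizes <- lapply(cfg$cohort_sizes, unlist)
  do.call(run_config, cfg[setdiff(names(cfg), "seeds")])
}

simulate_cohorts <- function(config) {
  ref <- generate_reference(config$n_genes, config$marker_fraction,
                            seed = config$seeds$reference)
  cohorts <- lapply(names(config$cohort_sizes), function(nm) {
    sz <- config$cohort_sizes[[nm]]
    par <- generator_params(
      n_subjects_gr = sz[1], n_subjects_nr = sz[2],
      treatment_neutrophil_multiplier = config$treatment_neutrophil_multiplier,
      response_innate_shift = config$response_innate_shift,
      seed = config$seeds[[paste0("cohort_", nm)]])
    generate_cohort(par, ref, cohort = nm)
  })
  names(cohorts) <- names(config$cohort_sizes)
  list(reference = ref, cohorts = cohorts)
}

write_manifest <- function(config, files, path) {
  manifest <- list(package_version = as.character(utils::packageVersion("tnfblood")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed, seeds = config$seeds,
                   files = lapply(files, function(f)
                     list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Treatment-signature analysis across cohorts
#'
#' Orchestrates the month-3 vs baseline arm of the study on synthetic (or
#' pre-simulated) cohorts: per-cohort precision-weighted differential
#' expression, cross-cohort concordance with a sign-flip permutation null,
#' the neutrophil effect-vs-specificity correlation, and the paired
#' neutrophil/WBC CBC ratio change. Results are written as TSV/JSON under
#' the configured output directory together with a seed/version manifest.
#'
#' @param config a [run_config()] object
#' @param data optional pre-built list from the simulation stage (elements
#'   `reference`, `cohorts`); simulated from the config seeds when NULL
#' @return (invisibly) list with `effect_tables`, `concordance`,
#'   `neutrophil_correlation`, `cbc_ratio_change`, `manifest_path`
#' @export
run_treatment_analysis <- function(config, data = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(data)) data <- simulate_cohorts(config)
  if (length(data$cohorts) < 1) stop("need at least one cohort")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  eff <- lapply(data$cohorts, function(co)
    run_differential(co$counts, co$meta, "MO3-BL", is_counts = TRUE))
  files <- character()
  for (nm in names(eff)) {
    f <- file.path(config$out_dir, paste0("treatment_effects_", nm, ".tsv"))
    write_meta_tsv(eff[[nm]], f); files <- c(files, f)
  }
  conc <- NULL
  if (length(data$cohorts) >= 2) {
    c1 <- data$cohorts[[1]]; c2 <- data$cohorts[[2]]
    conc <- permutation_concordance(c1$counts, c1$meta, c2$counts, c2$meta,
                                    "MO3-BL", n_perm = config$n_perm,
                                    seed = config$seeds$concordance)
    f <- file.path(config$out_dir, "treatment_concordance.json")
    jsonlite::write_json(conc[c("rho", "p.value", "n_features",
                                "n_permutations", "seed", "subset")],
                         f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  scores <- specificity_scores(data$reference)
  neut <- lapply(eff, function(e)
    effect_specificity_correlation(e, scores, "neutrophils"))
  cbc_change <- lapply(data$cohorts, function(co) {
    cb <- co$cbc
    nwr <- cb$neutrophils / cb$wbc
    bl <- stats::setNames(nwr[cb$visit == "BL"], cb$subject[cb$visit == "BL"])
    mo <- stats::setNames(nwr[cb$visit == "MO3"], cb$subject[cb$visit == "MO3"])
    paired_ratio_change(bl, mo)
  })
  f <- file.path(config$out_dir, "treatment_summary.json")
  jsonlite::write_json(list(
    neutrophil_specificity_rho = lapply(neut, `[[`, "rho"),
    cbc_nwr_change = cbc_change), f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  mf <- write_manifest(config, files,
                       file.path(config$out_dir, "treatment_manifest.json"))
  invisible(list(effect_tables = eff, concordance = conc,
                 neutrophil_correlation = neut,
                 cbc_ratio_change = cbc_change, manifest_path = mf))
}

#' Baseline responder vs non-responder analysis
#'
#' Orchestrates the baseline arm: per-cohort GR-NR differential expression,
#' all-gene and top-variable-subset cross-cohort concordance, per-cell-type
#' marker-set statistics combined across cohorts, the innate/adaptive
#' compartment summary, and logistic response models on the CBC log-ratios.
#'
#' @inheritParams run_treatment_analysis
#' @param cbc_population optional [generate_cbc_population()] result for the
#'   registry-scale response model; simulated from the config seed when NULL
#' @return (invisibly) list with `effect_tables`, `concordance_all`,
#'   `concordance_variable`, `set_results`, `innate_adaptive`, `cbc_models`,
#'   `manifest_path`
#' @export
run_baseline_response_analysis <- function(config, data = NULL,
                                           cbc_population = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(data)) data <- simulate_cohorts(config)
  for (co in data$cohorts)
    if (!any(co$meta$eular %in% c("GR", "good")) ||
        !any(co$meta$eular %in% c("NR", "none")))
      stop("cohort lacks EULAR labels for both response groups")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  eff <- lapply(data$cohorts, function(co)
    run_differential(co$counts, co$meta, "GR-NR", is_counts = TRUE))
  for (nm in names(eff)) {
    f <- file.path(config$out_dir, paste0("baseline_effects_", nm, ".tsv"))
    write_meta_tsv(eff[[nm]], f); files <- c(files, f)
  }
  c1 <- data$cohorts[[1]]; c2 <- data$cohorts[[2]]
  conc_all <- permutation_concordance(c1$counts, c1$meta, c2$counts, c2$meta,
                                      "GR-NR", n_perm = config$n_perm,
                                      seed = config$seeds$concordance)
  bl_cols <- c(c1$meta$visit == "BL", c2$meta$visit == "BL")
  pooled_bl <- log_cpm(cbind(c1$counts, c2$counts)[, bl_cols])
  topvar <- top_variable_subset(pooled_bl, config$variable_fraction)
  conc_var <- permutation_concordance(
    c1$counts[topvar, ], c1$meta, c2$counts[topvar, ], c2$meta, "GR-NR",
    n_perm = config$n_perm, seed = config$seeds$concordance,
    subset = sprintf("top %.0f%% variable", 100 * config$variable_fraction))
  scores <- specificity_scores(data$reference)
  sets <- build_marker_sets(scores, config$marker_threshold,
                            config$marker_min_size)
  cohort_list <- lapply(data$cohorts, function(co)
    list(mat = co$counts, meta = co$meta, is_counts = TRUE))
  set_results <- lapply(names(sets), function(ct)
    set_effect_with_permutation(cohort_list, "GR-NR", sets[[ct]],
                                compartment = blood_compartments[[ct]],
                                cell_type = ct, n_perm = config$n_perm,
                                seed = config$seeds$sets))
  ia <- innate_adaptive_summary(set_results)
  f <- file.path(config$out_dir, "baseline_celltype_sets.tsv")
  write_meta_tsv(ia$sets, f); files <- c(files, f)
  if (is.null(cbc_population))
    cbc_population <- generate_cbc_population(1962, target_or = 1.2,
                                              seed = config$seeds$cbc)
  meta_cbc <- cbind(data.frame(response = cbc_population$response),
                    cbc_population$covariates)
  cbc_models <- lapply(c("nlr", "nwr", "lwr"), function(rc)
    list(unadjusted = response_model(cbc_population$cbc, meta_cbc, rc,
                                     adjusted = FALSE),
         adjusted = response_model(cbc_population$cbc, meta_cbc, rc,
                                   adjusted = TRUE)))
  names(cbc_models) <- c("nlr", "nwr", "lwr")
  f <- file.path(config$out_dir, "baseline_cbc_forest.tsv")
  write_meta_tsv(cbc_models$nlr$adjusted$forest, f); files <- c(files, f)
  f <- file.path(config$out_dir, "baseline_summary.json")
  jsonlite::write_json(list(
    concordance_all = conc_all[c("rho", "p.value", "n_features")],
    concordance_variable = conc_var[c("rho", "p.value", "n_features", "subset")],
    innate_adaptive = ia[c("mean_innate", "mean_adaptive", "concordant",
                           "direction")]),
    f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  mf <- write_manifest(config, files,
                       file.path(config$out_dir, "baseline_manifest.json"))
  invisible(list(effect_tables = eff, concordance_all = conc_all,
                 concordance_variable = conc_var, set_results = set_results,
                 innate_adaptive = ia, cbc_models = cbc_models,
                 manifest_path = mf))
}
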