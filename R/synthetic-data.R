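#' Synthetic whole-blood reference and cohort generator
#'
#' The generator emulates the structure the downstream analyses assume: bulk
#' whole-blood counts arise as negative-binomial draws around cell-type
#' mixture means, anti-TNF treatment multiplies the neutrophil fraction at
#' month 3 by a fixed ratio (default 0.87 of baseline), good responders
#' carry a higher innate (neutrophil + monocyte) fraction at baseline, and
#' complete blood counts derive from the same underlying fractions. Ground
#' truth (fractions, marker assignments, seeds) is returned for
#' parameter-recovery tests.
#'
#' @name synthetic_data
NULL

blood_cell_types <- c("neutrophils", "monocytes", "B", "CD4 T", "CD8 T", "NK")

blood_compartments <- c(neutrophils = "innate", monocytes = "innate",
                        "B" = "adaptive", "CD4 T" = "adaptive",
                        "CD8 T" = "adaptive", "NK" = "adaptive")

#' Generate a cell-type reference expression matrix
#'
#' Builds a cell-type x gene mean-expression reference for the six major
#' blood cell populations. A designated fraction of genes are markers,
#' expressed `marker_fold` times higher in exactly one cell type (split
#' evenly across cell types); the rest are shared genes with a common
#' lognormal baseline across all types.
#'
#' @param n_genes number of genes (>= number of cell types)
#' @param marker_fraction fraction of genes designated as markers, in (0,1)
#' @param seed integer RNG seed
#' @param marker_fold enrichment of a marker in its own cell type (default 20)
#' @return object of class `CellTypeReference`: list with `cell_types`,
#'   `profiles` (cell types x genes, nonnegative), `compartment_map`,
#'   and `marker_truth` (per-gene cell type or NA for shared genes)
#' @export
generate_reference <- function(n_genes, marker_fraction, seed, marker_fold = 20) {
  if (!is.numeric(marker_fraction) || marker_fraction <= 0 || marker_fraction >= 1)
    stop("marker_fraction must lie in (0, 1)")
  k <- length(blood_cell_types)
  if (n_genes < k) stop("n_genes must be at least the number of cell types")
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  n_marker <- floor(n_genes * marker_fraction / k) * k
  marker_ct <- rep(blood_cell_types, each = n_marker / k)
  base <- exp(stats::rnorm(n_genes, mean = log(50), sd = 0.6))
  prof <- matrix(rep(base, each = k), nrow = k,
                 dimnames = list(blood_cell_types, genes))
  # markers: low shared background, high in the assigned cell type
  for (i in seq_len(n_marker)) {
    prof[, i] <- base[i] / marker_fold
    prof[marker_ct[i], i] <- base[i]
  }
  truth <- c(marker_ct, rep(NA_character_, n_genes - n_marker))
  names(truth) <- genes
  structure(list(cell_types = blood_cell_types, profiles = prof,
                 compartment_map = blood_compartments, marker_truth = truth),
            class = "CellTypeReference")
}

#' Generator parameters for a synthetic treated cohort
#'
#' @param n_subjects_gr,n_subjects_nr subjects per response group
#' @param baseline_fractions named simplex vector over the six cell types
#'   (defaults are typical whole-blood proportions)
#' @param treatment_neutrophil_multiplier month-3 neutrophil fraction as a
#'   ratio of baseline, in (0, 2); default 0.87
#' @param response_innate_shift additive fraction added to good responders'
#'   baseline neutrophil + monocyte mass before renormalisation
#' @param library_size_mean,library_size_cv library size distribution
#'   (lognormal)
#' @param nb_dispersion_range per-gene negative-binomial dispersion drawn
#'   log-uniformly from this range
#' @param subject_effect_sd log-scale between-subject expression variation
#'   shared by a subject's two visits
#' @param fraction_noise_sd log-scale between-subject variation of the
#'   cell-type fractions (applied per type, then renormalised)
#' @param seed integer RNG seed
#' @return validated list of class `GeneratorParams`
#' @export
generator_params <- function(n_subjects_gr = 19, n_subjects_nr = 21,
                             baseline_fractions = c(neutrophils = 0.55,
                               monocytes = 0.08, "B" = 0.08, "CD4 T" = 0.15,
                               "CD8 T" = 0.08, "NK" = 0.06),
                             treatment_neutrophil_multiplier = 0.87,
                             response_innate_shift = 0.10,
                             library_size_mean = 2e5, library_size_cv = 0.2,
                             nb_dispersion_range = c(0.01, 0.1),
                             subject_effect_sd = 0.1,
                             fraction_noise_sd = 0.10, seed = 1L) {
  if (abs(sum(baseline_fractions) - 1) > 1e-9)
    stop("baseline_fractions must sum to 1")
  if (any(baseline_fractions < 0)) stop("baseline_fractions must be nonnegative")
  if (!setequal(names(baseline_fractions), blood_cell_types))
    stop("baseline_fractions must be named by the six blood cell types")
  if (treatment_neutrophil_multiplier <= 0 || treatment_neutrophil_multiplier >= 2)
    stop("treatment_neutrophil_multiplier must lie in (0, 2)")
  if (n_subjects_gr < 1 || n_subjects_nr < 1 || library_size_mean <= 0)
    stop("counts and library size must be positive")
  innate <- sum(baseline_fractions[c("neutrophils", "monocytes")])
  if (response_innate_shift < 0 || innate + response_innate_shift >= 1)
    stop("response_innate_shift would produce negative adaptive fractions")
  structure(list(n_subjects_gr = n_subjects_gr, n_subjects_nr = n_subjects_nr,
                 baseline_fractions = baseline_fractions[blood_cell_types],
                 treatment_neutrophil_multiplier = treatment_neutrophil_multiplier,
                 response_innate_shift = response_innate_shift,
                 library_size_mean = library_size_mean,
                 library_size_cv = library_size_cv,
                 nb_dispersion_range = nb_dispersion_range,
                 subject_effect_sd = subject_effect_sd,
                 fraction_noise_sd = fraction_noise_sd,
                 seed = as.integer(seed)),
            class = "GeneratorParams")
}

# Back-solve DAS28-CRP components from a target score by random
# partitioning of the variable part across the four terms, respecting the
# range caps of each component. Returns tjc, sjc, crp, gh.
solve_das28_components <- function(target) {
  caps <- c(0.56 * sqrt(28), 0.28 * sqrt(28), 0.36 * log(301), 0.014 * 100)
  rem <- target - 0.96
  for (i in 1:200) {
    w <- stats::rgamma(4, shape = c(3, 2, 2, 1.5))
    terms <- rem * w / sum(w)
    if (all(terms <= caps)) break
  }
  terms <- pmin(terms, caps)
  list(tjc = round((terms[1] / 0.56)^2), sjc = round((terms[2] / 0.28)^2),
       crp = exp(terms[3] / 0.36) - 1, gh = round(terms[4] / 0.014))
}

# Draw DAS28 component sets whose recomputed scores fall in the intended
# EULAR class (good or none); rejection loop guards against rounding drift.
draw_clinical_scores <- function(responder) {
  for (i in 1:200) {
    if (responder) {
      fu <- stats::runif(1, 1.8, 2.9)
      bl <- fu + stats::runif(1, 1.6, 2.6)
    } else {
      bl <- stats::runif(1, 4.5, 5.8)
      fu <- bl - stats::runif(1, -0.3, 0.45)
    }
    cb <- solve_das28_components(bl)
    cf <- solve_das28_components(fu)
    sb <- das28_crp(cb$tjc, cb$sjc, cb$crp, cb$gh)
    sf <- das28_crp(cf$tjc, cf$sjc, cf$crp, cf$gh)
    cls <- as.character(eular_classify(sb, sf)$value)
    if ((responder && cls == "good") || (!responder && cls == "none"))
      return(list(bl = cb, fu = cf, das_bl = sb, das_fu = sf))
  }
  stop("failed to back-solve DAS28 components for the requested class")
}

perturb_simplex <- function(frac, sd) {
  x <- frac * exp(stats::rnorm(length(frac), 0, sd))
  x / sum(x)
}

#' Generate a paired-visit whole-blood cohort
#'
#' Simulates a cohort of good responders and non-responders sampled at
#' baseline and month 3. Counts for gene g in sample i are negative binomial
#' with mean `libsize_i * sum_c fraction_ic * profile_cg` (mixture means
#' renormalised per sample); the month-3 neutrophil fraction is the baseline
#' fraction times `treatment_neutrophil_multiplier` (then renormalised);
#' good responders' baseline innate fractions are raised by
#' `response_innate_shift` before renormalisation. CBC values derive from
#' the true fractions with lognormal jitter, and DAS28-CRP components are
#' back-solved so that EULAR classification reproduces the group labels.
#'
#' @param params a [generator_params()] object
#' @param reference a [generate_reference()] object
#' @param cohort cohort label stored in the metadata (default "C1")
#' @return list with `counts` (genes x samples, BL and MO3 columns), `meta`
#'   (sample, subject, cohort, visit, eular, DAS28 components and scores,
#'   drug, drug_level_mo3, demographics), `cbc` (subject, visit,
#'   neutrophils, lymphocytes, wbc in 1e9/L), and `truth` (per-subject
#'   fractions at both visits, marker assignments, params echo)
#' @export
generate_cohort <- function(params, reference, cohort = "C1") {
  stopifnot(inherits(params, "GeneratorParams"),
            inherits(reference, "CellTypeReference"))
  set.seed(params$seed)
  prof <- reference$profiles
  genes <- colnames(prof)
  k <- nrow(prof)
  n_sub <- params$n_subjects_gr + params$n_subjects_nr
  groups <- rep(c("GR", "NR"), c(params$n_subjects_gr, params$n_subjects_nr))
  subjects <- sprintf("%s_S%02d", cohort, seq_len(n_sub))

  disp <- exp(stats::runif(length(genes), log(params$nb_dispersion_range[1]),
                           log(params$nb_dispersion_range[2])))

  frac_bl <- matrix(0, n_sub, k, dimnames = list(subjects, rownames(prof)))
  frac_mo3 <- frac_bl
  for (s in seq_len(n_sub)) {
    f <- perturb_simplex(params$baseline_fractions, params$fraction_noise_sd)
    if (groups[s] == "GR") {
      innate <- c("neutrophils", "monocytes")
      f[innate] <- f[innate] * (1 + params$response_innate_shift / sum(f[innate]))
      f <- f / sum(f)
    }
    frac_bl[s, ] <- f
    # month-3 neutrophil fraction is multiplier x baseline fraction; the
    # remaining cell types expand proportionally to restore the simplex
    g <- f
    g["neutrophils"] <- f["neutrophils"] * params$treatment_neutrophil_multiplier
    rest <- setdiff(names(g), "neutrophils")
    g[rest] <- f[rest] * (1 - g["neutrophils"]) / (1 - f["neutrophils"])
    frac_mo3[s, ] <- g
  }

  samples <- as.vector(t(outer(subjects, c("BL", "MO3"), paste, sep = "_")))
  visit <- rep(c("BL", "MO3"), n_sub)
  subj_of_sample <- rep(subjects, each = 2)
  group_of_sample <- rep(groups, each = 2)

  libsize <- exp(stats::rnorm(length(samples), log(params$library_size_mean),
                              params$library_size_cv))
  subj_eff <- matrix(stats::rnorm(n_sub * length(genes), 0,
                                  params$subject_effect_sd),
                     n_sub, length(genes), dimnames = list(subjects, genes))

  counts <- matrix(0L, length(genes), length(samples),
                   dimnames = list(genes, samples))
  for (i in seq_along(samples)) {
    f <- if (visit[i] == "BL") frac_bl[subj_of_sample[i], ]
         else frac_mo3[subj_of_sample[i], ]
    mu <- as.vector(f %*% prof) * exp(subj_eff[subj_of_sample[i], ])
    mu <- mu / sum(mu) * libsize[i]
    counts[, i] <- stats::rnbinom(length(genes), mu = mu, size = 1 / disp)
  }

  # CBC derived from the same fractions: deterministic mapping plus jitter
  wbc <- exp(stats::rnorm(n_sub, log(7), 0.2))
  lymph_types <- c("B", "CD4 T", "CD8 T", "NK")
  cbc <- do.call(rbind, lapply(c("BL", "MO3"), function(v) {
    fr <- if (v == "BL") frac_bl else frac_mo3
    neut <- fr[, "neutrophils"] * wbc * exp(stats::rnorm(n_sub, 0, 0.04))
    lymph <- rowSums(fr[, lymph_types]) * wbc * exp(stats::rnorm(n_sub, 0, 0.04))
    over <- (neut + lymph) > wbc * 1.02
    if (any(over)) {
      sc <- (wbc * 1.02 / (neut + lymph))[over]
      neut[over] <- neut[over] * sc; lymph[over] <- lymph[over] * sc
    }
    data.frame(subject = subjects, visit = v, neutrophils = neut,
               lymphocytes = lymph, wbc = wbc, row.names = NULL)
  }))

  clin <- lapply(groups == "GR", draw_clinical_scores)
  drug <- sample(c("adalimumab", "infliximab"), n_sub, replace = TRUE)
  drug_level <- exp(stats::rnorm(n_sub, log(4000), 0.6))   # all above filter
  meta <- data.frame(
    sample = samples, subject = subj_of_sample, cohort = cohort,
    visit = visit, eular = group_of_sample,
    das_bl = rep(vapply(clin, `[[`, 0, "das_bl"), each = 2),
    das_fu = rep(vapply(clin, `[[`, 0, "das_fu"), each = 2),
    tjc28_bl = rep(vapply(clin, function(z) z$bl$tjc, 0), each = 2),
    sjc28_bl = rep(vapply(clin, function(z) z$bl$sjc, 0), each = 2),
    crp_bl = rep(vapply(clin, function(z) z$bl$crp, 0), each = 2),
    gh_bl = rep(vapply(clin, function(z) z$bl$gh, 0), each = 2),
    drug = rep(drug, each = 2),
    drug_level_mo3 = rep(drug_level, each = 2),
    age = rep(round(stats::rnorm(n_sub, 55, 12)), each = 2),
    female = rep(stats::rbinom(n_sub, 1, 0.8) == 1, each = 2),
    ccp_pos = rep(stats::rbinom(n_sub, 1,
                  ifelse(groups == "GR", 0.8, 0.4)) == 1, each = 2),
    rf_pos = rep(stats::rbinom(n_sub, 1,
                 ifelse(groups == "GR", 0.8, 0.55)) == 1, each = 2),
    row.names = NULL)

  truth <- list(fractions_bl = frac_bl, fractions_mo3 = frac_mo3,
                marker_truth = reference$marker_truth,
                nb_dispersion = stats::setNames(disp, genes),
                params = unclass(params), seed = params$seed)
  list(counts = counts, meta = meta, cbc = cbc, truth = truth)
}

#' Generate a registry-scale CBC population with a known response model
#'
#' Draws baseline complete blood counts for `n` patients together with a
#' binary good-or-moderate response generated from a logistic model whose
#' slope on the natural-log neutrophil-to-lymphocyte ratio is
#' `log(target_or)`, plus small effects for the standard adjustment
#' covariates (biologic type, age, smoking, disease duration, mHAQ,
#' concomitant MTX, number of prior biologics).
#'
#' @param n number of patients (>= 50)
#' @param target_or true odds ratio of response per unit log-NLR (> 0);
#'   default 1.2
#' @param covariate_spec optional data.frame of covariates (n rows); the
#'   built-in registry-like covariates are generated when NULL. Constant
#'   columns are rejected.
#' @param seed integer RNG seed
#' @return list with `cbc` (neutrophils, lymphocytes, wbc in 1e9/L),
#'   `response` (logical good-or-moderate), `covariates`, and `truth`
#'   (the generating slope and intercept)
#' @export
generate_cbc_population <- function(n, target_or = 1.2, covariate_spec = NULL,
                                    seed = 1L) {
  if (n < 50) stop("n must be >= 50")
  if (target_or <= 0) stop("target_or must be positive")
  set.seed(seed)
  if (is.null(covariate_spec)) {
    covariate_spec <- data.frame(
      tnfi = stats::rbinom(n, 1, 0.6),
      age = round(stats::rnorm(n, 56, 12)),
      smoker = stats::rbinom(n, 1, 0.35),
      duration = pmax(0.1, stats::rnorm(n, 8, 7)),
      mhaq = pmin(3, pmax(0, stats::rnorm(n, 0.5, 0.4))),
      mtx = stats::rbinom(n, 1, 0.5),
      prior_biologics = stats::rpois(n, 0.6))
  } else {
    if (nrow(covariate_spec) != n) stop("covariate_spec must have n rows")
  }
  if (any(vapply(covariate_spec, function(v) length(unique(v)) < 2, TRUE)))
    stop("degenerate covariate spec: constant column(s)")
  log_nlr <- stats::rnorm(n, log(2.2), 0.55)
  wbc <- exp(stats::rnorm(n, log(7), 0.25))
  r <- exp(log_nlr)
  neut <- wbc * 0.9 * r / (1 + r)
  lymph <- wbc * 0.9 / (1 + r)
  # modest covariate effects on the log-odds scale
  cov_beta <- c(tnfi = 0.1, age = -0.005, smoker = -0.15, duration = -0.01,
                mhaq = -0.3, mtx = log(1.23), prior_biologics = -0.2)
  eta <- log(target_or) * log_nlr
  for (nm in intersect(names(cov_beta), names(covariate_spec)))
    eta <- eta + cov_beta[[nm]] * covariate_spec[[nm]]
  intercept <- 0.4 - mean(eta - log(target_or) * log_nlr)
  eta <- intercept + eta
  response <- stats::runif(n) < stats::plogis(eta)
  list(cbc = data.frame(subject = sprintf("P%05d", seq_len(n)),
                        neutrophils = neut, lymphocytes = lymph, wbc = wbc),
       response = response, covariates = covariate_spec,
       truth = list(slope_log_nlr = log(target_or), target_or = target_or,
                    intercept = intercept, covariate_effects = cov_beta,
                    seed = seed))
}

#' Generate paired plasma-protein intensity matrices for two cohorts
#'
#' Lognormal protein intensities (log2 scale on output) for two
#' independently sampled cohorts measured at baseline and month 3, with a
#' designated subset of proteins carrying the same month-3 shift in both
#' cohorts — the structure behind cross-cohort concordance of treatment
#' effects.
#'
#' @param n_features number of proteins (default 170)
#' @param n_subjects subjects per cohort (one pair of samples each)
#' @param n_affected number of proteins with a shared treatment shift
#' @param effect_sd SD of the shared log2 shifts (0 gives a null dataset)
#' @param noise_sd residual log2 noise SD
#' @param seed integer RNG seed
#' @return list of two cohorts, each with `intensity` (log2, features x
#'   samples) and `meta`, plus `truth` (affected features and their shifts)
#' @export
generate_protein_matrix <- function(n_features = 170, n_subjects = 20,
                                    n_affected = 25, effect_sd = 0.5,
                                    noise_sd = 0.4, seed = 1L) {
  if (n_features < 10 || n_subjects < 3) stop("degenerate dimensions")
  if (n_affected > n_features) stop("n_affected exceeds n_features")
  set.seed(seed)
  feats <- sprintf("prot%03d", seq_len(n_features))
  base <- stats::rnorm(n_features, 20, 2)
  shift <- numeric(n_features)
  affected <- sample(feats, n_affected)
  shift[match(affected, feats)] <- stats::rnorm(n_affected, 0, effect_sd)
  make_cohort <- function(label) {
    subjects <- sprintf("%s_S%02d", label, seq_len(n_subjects))
    samples <- as.vector(t(outer(subjects, c("BL", "MO3"), paste, sep = "_")))
    visit <- rep(c("BL", "MO3"), n_subjects)
    subj_mean <- matrix(stats::rnorm(n_features * n_subjects, 0, 0.5),
                        n_features, n_subjects)
    y <- matrix(base, n_features, length(samples),
                dimnames = list(feats, samples))
    y <- y + subj_mean[, rep(seq_len(n_subjects), each = 2)]
    y <- y + outer(shift, as.numeric(visit == "MO3"))
    y <- y + matrix(stats::rnorm(length(y), 0, noise_sd), nrow(y))
    meta <- data.frame(sample = samples, subject = rep(subjects, each = 2),
                       cohort = label, visit = visit, eular = "GR",
                       row.names = NULL)
    list(intensity = y, meta = meta)
  }
  list(cohort1 = make_cohort("P1"), cohort2 = make_cohort("P2"),
       truth = list(affected = affected,
                    shift = stats::setNames(shift, feats), seed = seed))
}

#' Serialize and reload generator truth
#'
#' Ground-truth objects are written as JSON (matrices as row-major arrays
#' with dimnames preserved) so recovery tests can reload exactly what was
#' generated.
#'
#' @param truth list as returned in a generator's `truth` element
#' @param path file path to write to / read from
#' @return `read_truth` returns the reloaded list
#' @export
write_truth <- function(truth, path) {
  encode <- function(x) {
    if (is.matrix(x))
      list(`.matrix` = TRUE, nrow = nrow(x), dimnames = dimnames(x),
           data = as.vector(x))
    else if (is.atomic(x) && (length(x) != 1 || !is.null(names(x))))
      list(`.vector` = TRUE, names = names(x), data = unname(x))
    else if (is.list(x)) lapply(x, encode)
    else x
  }
  jsonlite::write_json(encode(truth), path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  decode <- function(x) {
    if (is.list(x) && isTRUE(x$`.matrix`))
      matrix(x$data, nrow = x$nrow,
             dimnames = if (is.null(x$dimnames)) NULL else x$dimnames)
    else if (is.list(x) && isTRUE(x$`.vector`))
      stats::setNames(x$data, x$names)
    else if (is.list(x)) lapply(x, decode)
    else x
  }
  decode(jsonlite::read_json(path, simplifyVector = TRUE))
}
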