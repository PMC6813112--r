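test_that("reference generator: marker layout, determinism, preconditions", {
  ref <- generate_reference(600, 0.5, seed = 1)
  expect_equal(sum(!is.na(ref$marker_truth)), 300)
  expect_equal(unname(table(ref$marker_truth)), rep(50L, 6), ignore_attr = TRUE)
  expect_true(all(colSums(ref$profiles) > 0))
  expect_equal(anyDuplicated(ref$cell_types), 0)
  expect_setequal(names(ref$compartment_map), ref$cell_types)
  expect_identical(ref, generate_reference(600, 0.5, seed = 1))
  expect_false(identical(ref$profiles,
                         generate_reference(600, 0.5, seed = 2)$profiles))
  expect_error(generate_reference(5, 0.5, seed = 1), "at least")
  expect_error(generate_reference(600, 0, seed = 1))
  expect_error(generate_reference(600, 1.2, seed = 1))
})

test_that("generator parameters validate the simplex and effect ranges", {
  expect_error(generator_params(baseline_fractions = c(neutrophils = 0.5,
    monocytes = 0.1, "B" = 0.1, "CD4 T" = 0.1, "CD8 T" = 0.1, "NK" = 0.05)),
    "sum to 1")
  expect_error(generator_params(treatment_neutrophil_multiplier = 2.5))
  expect_error(generator_params(treatment_neutrophil_multiplier = 0))
  expect_error(generator_params(n_subjects_gr = 0))
  expect_error(generator_params(response_innate_shift = 0.5),
               "negative adaptive")
})

test_that("cohort generator: simplex truth, effect recovery, determinism", {
  ref <- small_reference()
  co <- study_cohort()
  # per-subject fractions sum to 1 at both visits
  expect_true(all(abs(rowSums(co$truth$fractions_bl) - 1) < 1e-9))
  expect_true(all(abs(rowSums(co$truth$fractions_mo3) - 1) < 1e-9))
  # true neutrophil fraction ratio equals the multiplier exactly
  r <- co$truth$fractions_mo3[, "neutrophils"] /
    co$truth$fractions_bl[, "neutrophils"]
  expect_equal(unname(r), rep(0.87, nrow(co$truth$fractions_bl)),
               tolerance = 1e-9)
  # responders carry the designed innate excess at baseline
  innate_bl <- rowSums(co$truth$fractions_bl[, c("neutrophils", "monocytes")])
  gr <- grepl("GR", co$meta$eular[match(rownames(co$truth$fractions_bl),
                                        co$meta$subject)])
  expect_gt(mean(innate_bl[gr]), mean(innate_bl[!gr]))
  # EULAR labels are consistent with the generated DAS28 components
  sub_meta <- co$meta[co$meta$visit == "BL", ]
  das_bl <- das28_crp(sub_meta$tjc28_bl, sub_meta$sjc28_bl, sub_meta$crp_bl,
                      sub_meta$gh_bl)
  expect_equal(das_bl, sub_meta$das_bl, tolerance = 1e-9)
  cls <- eular_classify(sub_meta$das_bl, sub_meta$das_fu)$value
  expect_true(all((cls == "good") == (sub_meta$eular == "GR")))
  # CBC sanity: positive, neutrophils + lymphocytes bounded by WBC
  expect_true(all(co$cbc$neutrophils > 0 & co$cbc$lymphocytes > 0))
  expect_true(all(co$cbc$neutrophils + co$cbc$lymphocytes <=
                    co$cbc$wbc * 1.02 + 1e-9))
  # byte-identical under the same seed
  co2 <- generate_cohort(generator_params(seed = 202), ref)
  expect_identical(co$counts, co2$counts)
  expect_identical(co$meta, co2$meta)
})

test_that("null cohort yields null month-3 differences and FDR control", {
  ref <- small_reference()
  co <- null_cohort(seed = 404, n_gr = 10, n_nr = 10)
  et <- run_differential(co$counts, co$meta, "MO3-BL")
  neut <- names(ref$marker_truth)[!is.na(ref$marker_truth) &
                                    ref$marker_truth == "neutrophils"]
  eff <- et$effect[et$feature %in% neut]
  # mean marker effect within 3 SE of zero
  expect_lt(abs(mean(eff)) / (sd(eff) / sqrt(length(eff))), 3)
  expect_lte(mean(et$q.value < 0.05), 0.07)
})

test_that("CBC population generator embeds the requested odds ratio", {
  pop <- generate_cbc_population(2000, target_or = 1.2, seed = 51)
  expect_equal(pop$truth$slope_log_nlr, log(1.2))
  expect_equal(nrow(pop$cbc), 2000)
  expect_true(is.logical(pop$response))
  # identical under the same seed
  pop2 <- generate_cbc_population(2000, target_or = 1.2, seed = 51)
  expect_identical(pop$cbc, pop2$cbc)
  expect_identical(pop$response, pop2$response)
  expect_error(generate_cbc_population(10), ">= 50")
  expect_error(generate_cbc_population(100, target_or = -1))
  expect_error(generate_cbc_population(100, covariate_spec =
    data.frame(a = rep(1, 100))), "degenerate covariate")
  # small n with separation reported by the fitter
  tiny <- data.frame(x = c(rep(-2, 5), rep(2, 5)))
  expect_error(logistic_fit(tiny, c(rep(0, 5), rep(1, 5))), "separation")
})

test_that("null CBC fits are calibrated: CI covers OR 1 in >=93% of runs", {
  cover <- logical(100)
  for (i in 1:100) {
    pop <- generate_cbc_population(300, target_or = 1.0, seed = 600 + i)
    lr <- cbc_log_ratios(pop$cbc$neutrophils, pop$cbc$lymphocytes,
                         pop$cbc$wbc)
    fit <- logistic_fit(data.frame(log_nlr = lr$log_nlr), pop$response)
    cover[i] <- fit$ci_low[2] <= 1 && 1 <= fit$ci_high[2]
  }
  expect_gte(sum(cover), 93)
})

test_that("protein generator: shared shifts across cohorts, null centring", {
  prot <- generate_protein_matrix(n_subjects = 12, effect_sd = 0.6, seed = 61)
  expect_equal(nrow(prot$cohort1$intensity), 170)
  expect_identical(rownames(prot$cohort1$intensity),
                   rownames(prot$cohort2$intensity))
  # per-cohort effect estimates correlate through the shared truth
  e1 <- tnfblood:::contrast_effects(prot$cohort1$intensity,
                                    prot$cohort1$meta, "MO3-BL")
  e2 <- tnfblood:::contrast_effects(prot$cohort2$intensity,
                                    prot$cohort2$meta, "MO3-BL")
  aff <- match(prot$truth$affected, rownames(prot$cohort1$intensity))
  expect_gt(cor(e1[aff], prot$truth$shift[prot$truth$affected]), 0.7)
  expect_gt(cor(e1, e2, method = "spearman"), 0.1)
  # zero-effect generator: cross-cohort correlation centred at zero
  rhos <- vapply(1:20, function(i) {
    p <- generate_protein_matrix(n_subjects = 10, effect_sd = 0, seed = 700 + i)
    cor(tnfblood:::contrast_effects(p$cohort1$intensity, p$cohort1$meta, "MO3-BL"),
        tnfblood:::contrast_effects(p$cohort2$intensity, p$cohort2$meta, "MO3-BL"),
        method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 2 * sd(rhos) / sqrt(length(rhos)) + 0.05)
  expect_identical(generate_protein_matrix(seed = 62)$cohort1$intensity,
                   generate_protein_matrix(seed = 62)$cohort1$intensity)
})

test_that("truth files round-trip through serialization", {
  co <- study_cohort()
  path <- tempfile(fileext = ".json")
  write_truth(co$truth, path)
  back <- read_truth(path)
  expect_equal(back$fractions_bl, co$truth$fractions_bl)
  expect_equal(back$fractions_mo3, co$truth$fractions_mo3)
  expect_equal(back$nb_dispersion, co$truth$nb_dispersion)
  expect_equal(back$marker_truth, co$truth$marker_truth)
  expect_equal(back$seed, co$truth$seed)
  expect_equal(back$params$treatment_neutrophil_multiplier,
               co$truth$params$treatment_neutrophil_multiplier)
})
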