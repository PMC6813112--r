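# Shared fixtures, built once per test run.

fixture_env <- new.env()

# small reference: 300 genes, half markers (25 per cell type)
small_reference <- function() {
  if (is.null(fixture_env$ref))
    fixture_env$ref <- generate_reference(300, 0.5, seed = 101)
  fixture_env$ref
}

# default-condition cohort (study sizes, multiplier 0.87, innate shift)
study_cohort <- function() {
  if (is.null(fixture_env$cohort))
    fixture_env$cohort <- generate_cohort(
      generator_params(seed = 202), small_reference())
  fixture_env$cohort
}

# null cohort: no treatment effect, no response shift
null_cohort <- function(seed = 303, n_gr = 8, n_nr = 8, ref = small_reference()) {
  generate_cohort(
    generator_params(n_subjects_gr = n_gr, n_subjects_nr = n_nr,
                     treatment_neutrophil_multiplier = 1,
                     response_innate_shift = 0, seed = seed),
    ref)
}

# naive O(n^2) step-up FDR, straight from the definition
bh_naive <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(seq_len(n), function(i)
    min(1, min((p * n / r)[p >= p[i]])), numeric(1))
}
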