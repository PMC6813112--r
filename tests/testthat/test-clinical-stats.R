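test_that("DAS28-CRP formula evaluates correctly and is monotone", {
  expect_equal(das28_crp(0, 0, 0, 0), 0.96)
  expect_equal(das28_crp(9, 7, 5, 50), 4.7258, tolerance = 1e-3)
  # monotone nondecreasing in every argument
  base <- das28_crp(9, 7, 5, 50)
  expect_gte(das28_crp(28, 7, 5, 50), base)
  expect_gte(das28_crp(9, 28, 5, 50), base)
  expect_gte(das28_crp(9, 7, 50, 50), base)
  expect_gte(das28_crp(9, 7, 5, 100), base)
  # out-of-range inputs rejected
  expect_error(das28_crp(-1, 0, 0, 0))
  expect_error(das28_crp(0, 29, 0, 0))
  expect_error(das28_crp(2.5, 0, 0, 0))
  expect_error(das28_crp(0, 0, -1, 0))
  expect_error(das28_crp(0, 0, 0, 101))
})

test_that("EULAR response matrix classifies the plane exhaustively", {
  cases <- list(
    list(5.2, 3.0, "good"),      # fu <= 3.2, improvement 2.2
    list(5.2, 5.0, "none"),      # improvement 0.2 <= 0.6
    list(5.2, 3.9, "moderate"),  # improvement 1.3, fu > 3.2
    list(6.4, 5.3, "none"),      # improvement 1.1 <= 1.2 and fu > 5.1
    list(6.0, 4.9, "moderate"),  # improvement 1.1, fu <= 5.1
    list(4.0, 3.2, "moderate"),  # fu at the 3.2 boundary, improvement 0.8
    list(4.51, 3.2, "good"),     # fu == 3.2 still counts, improvement 1.31
    list(3.9, 3.2, "moderate"))  # fu low but improvement only 0.7
  for (cs in cases)
    expect_equal(as.character(eular_classify(cs[[1]], cs[[2]])$value), cs[[3]],
                 info = sprintf("bl=%.1f fu=%.1f", cs[[1]], cs[[2]]))
  # exhaustive and deterministic over a grid
  grid <- expand.grid(bl = seq(0, 9, by = 0.3), fu = seq(0, 9, by = 0.3))
  lab <- eular_classify(grid$bl, grid$fu)$value
  expect_false(any(is.na(lab)))
  expect_identical(lab, eular_classify(grid$bl, grid$fu)$value)
  expect_error(eular_classify(-1, 2))
})

test_that("Yates chi-square matches closed form and is swap-invariant", {
  tab <- matrix(c(16, 3, 8, 13), 2, byrow = TRUE)
  res <- chi_square_yates(tab)
  # closed form n(max(|ad-bc|-n/2,0))^2 / product of margins
  n <- sum(tab)
  num <- n * max(abs(tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]) - n / 2, 0)^2
  stat <- num / prod(c(rowSums(tab), colSums(tab)))
  expect_equal(res$statistic, stat, tolerance = 1e-12)
  expect_equal(res$p.value, stats::pchisq(stat, 1, lower.tail = FALSE))
  # row and column swaps leave the test unchanged
  expect_equal(chi_square_yates(tab[2:1, ])$p.value, res$p.value)
  expect_equal(chi_square_yates(tab[, 2:1])$p.value, res$p.value)
  expect_equal(chi_square_yates(t(tab))$p.value, res$p.value)
  # identical proportions: zero statistic
  flat <- chi_square_yates(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)
  expect_error(chi_square_yates(matrix(c(0, 0, 5, 5), 2)), "degenerate")
  expect_error(chi_square_yates(matrix(c(1.5, 2, 3, 4), 2)))
})

test_that("Wilcoxon rank-sum: exact enumeration, null, and shift detection", {
  # C(6,3) = 20 arrangements; the observed split is one of two extremes
  expect_equal(wilcoxon_rank_sum(1:3, 4:6)$p.value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(2, 4, 6), c(2, 4, 6))$p.value, 1,
               tolerance = 0.05)
  set.seed(5)
  x <- rnorm(40); y <- rnorm(40, mean = 2)
  expect_lt(wilcoxon_rank_sum(x, y)$p.value, 0.01)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3))
  # exact and approximate branches agree on tie-free 10+10 samples
  set.seed(6)
  for (i in 1:5) {
    a <- rnorm(10); b <- rnorm(10, 0.5)
    pe <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    pa <- wilcoxon_rank_sum(c(a, 0.123), b)$p.value  # push past exact cutoff
    pe2 <- stats::wilcox.test(c(a, 0.123), b, exact = TRUE)$p.value
    expect_lt(abs(pa - pe2), 0.02)
  }
})

test_that("drug-level filter removes only low-level non-responders", {
  meta <- data.frame(
    subject = paste0("S", 1:5),
    eular = c("NR", "GR", "NR", "NR", "GR"),
    drug_level_mo3 = c(500, 500, 800, NA, NA))
  expect_warning(out <- cohort_filter(meta), "missing drug level")
  expect_identical(out$subject, c("S2", "S3", "S4", "S5"))  # NR@500 excluded
  expect_true("S3" %in% out$subject)   # exactly 800 retained (strict below)
  log_df <- attr(out, "filter_log")
  expect_equal(sum(log_df$action == "excluded"), 1)
  out2 <- suppressWarnings(cohort_filter(meta, on_missing = "drop"))
  expect_false("S4" %in% out2$subject)
})

test_that("descriptive table reports group summaries and the right tests", {
  set.seed(7)
  meta <- data.frame(
    group = rep(c("GR", "NR"), c(19, 21)),
    ccp = rep(c("pos", "neg", "pos", "neg"), c(16, 3, 8, 13)),
    age = c(rnorm(19, 54, 13), rnorm(21, 56, 13)),
    onelevel = "x")
  tab <- table1_summary(meta, c(ccp = "categorical", age = "continuous",
                                onelevel = "categorical"))
  # the categorical p is the Yates chi-square of the reconstructed 2x2
  expect_equal(tab$p.value[tab$attribute == "ccp"],
               chi_square_yates(matrix(c(3, 16, 13, 8), 2, byrow = TRUE))$p.value)
  expect_equal(tab$p.value[tab$attribute == "age"],
               wilcoxon_rank_sum(meta$age[1:19], meta$age[20:40])$p.value)
  expect_true(is.na(tab$p.value[tab$attribute == "onelevel"]))
  expect_equal(tab$flag[tab$attribute == "onelevel"], "single-level")
  expect_error(table1_summary(meta, c(age = "numeric")), "unknown attribute")
})
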