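test_that("log-CPM matches its closed form and is scale invariant", {
  m <- matrix(c(0, 1e6), 1, 2, dimnames = list("g1", c("a", "b")))
  lc <- log_cpm(m, prior_count = 0.5, lib_size = c(1e6, 1e6))
  expect_equal(lc[1, 1], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-9)
  # count == libsize (single-gene library)
  expect_equal(lc[1, 2], log2((1e6 + 0.5) / (1e6 + 1) * 1e6), tolerance = 1e-9)
  set.seed(11)
  # scale invariance up to the fixed damping prior (exact as counts grow)
  counts <- matrix(rpois(200, 500), 20, 10)
  expect_equal(log_cpm(2 * counts, lib_size = 2 * colSums(counts)),
               log_cpm(counts, lib_size = colSums(counts)),
               tolerance = 5e-3)
  expect_error(log_cpm(counts, lib_size = c(0, rep(1, 9))), "library size")
  expect_error(log_cpm(-counts))
})

test_that("precision weights track the mean-variance trend", {
  set.seed(12)
  n <- 20; G <- 400
  design <- cbind(1, rep(0:1, each = n / 2))
  # homoscedastic input: weights nearly flat
  y <- matrix(rnorm(G * n, 8, 1), G, n)
  w <- voom_weights(y, design)
  expect_equal(dim(w), dim(y))
  expect_true(all(w > 0))
  expect_lt(sd(w) / mean(w), 0.3)
  # decreasing true SD in expression: weights increase with expression
  mu <- seq(4, 12, length.out = G)
  sds <- seq(1.5, 0.3, length.out = G)
  y2 <- matrix(rnorm(G * n, rep(mu, n), rep(sds, n)), G, n)
  w2 <- voom_weights(y2, design)
  expect_gt(cor(mu, rowMeans(w2), method = "spearman"), 0.8)
  expect_error(voom_weights(matrix(5, 10, 6), design[1:6, ]), "constant")
})

test_that("precision weights agree with the reference voom implementation", {
  skip_if_not_installed("limma")
  set.seed(13)
  G <- 300; n <- 12
  counts <- matrix(rnbinom(G * n, mu = rexp(G, 1 / 200), size = 5), G, n,
                   dimnames = list(sprintf("g%03d", 1:G), sprintf("s%02d", 1:n)))
  lib <- rep(round(mean(colSums(counts))), n)  # equal library sizes
  design <- cbind(1, rep(0:1, each = 6))
  lc <- log_cpm(counts, lib_size = lib)
  w <- voom_weights(lc, design)
  v <- limma::voom(counts, design, lib.size = lib)
  expect_gt(cor(as.vector(w), as.vector(v$weights)), 0.99)
  expect_lt(median(abs(w - v$weights) / v$weights), 0.05)
})

test_that("weighted least squares matches the normal-equations oracle", {
  set.seed(14)
  n <- 8
  X <- cbind(1, rep(0:1, each = 4), rnorm(n))
  W <- c(4, 4, 1, 1, 2, 2, 3, 3)
  y <- matrix(rnorm(5 * n), 5, n)
  fit <- fit_weighted_lm(y, X, matrix(W, 5, n, byrow = TRUE))
  for (g in 1:5) {
    beta <- solve(t(X) %*% diag(W) %*% X, t(X) %*% diag(W) %*% y[g, ])
    expect_equal(unname(fit$coefficients[g, ]), as.vector(beta),
                 tolerance = 1e-10)
    r <- y[g, ] - X %*% beta
    expect_equal(fit$sigma2[g], sum(W * r^2) / (n - 3), tolerance = 1e-10)
    expect_equal(unname(fit$stdev_unscaled[g, ]),
                 sqrt(diag(solve(t(X) %*% diag(W) %*% X))), tolerance = 1e-10)
  }
  # unit weights, binary covariate: coefficient is the group-mean difference
  X2 <- cbind(1, rep(0:1, each = 4))
  fit2 <- fit_weighted_lm(y, X2)
  for (g in 1:5)
    expect_equal(unname(fit2$coefficients[g, 2]),
                 mean(y[g, 5:8]) - mean(y[g, 1:4]))
  # saturated design flagged
  expect_warning(fit_weighted_lm(y[, 1:2], cbind(1, 0:1)), "zero residual")
  expect_error(fit_weighted_lm(y, cbind(X2, X2[, 2])), "rank deficient")
})

test_that("moderated t has the right limits and null behaviour", {
  set.seed(15)
  n <- 12; G <- 200
  y <- matrix(rnorm(G * n), G, n,
              dimnames = list(sprintf("g%03d", 1:G), NULL))
  X <- cbind(1, rep(0:1, each = 6))
  fits <- fit_weighted_lm(y, X)
  # d0 -> 0: ordinary two-sample t
  m0 <- ebayes_moderate(fits, prior = list(df0 = 0, s02 = 1))
  tt <- apply(y, 1, function(v) stats::t.test(v[7:12], v[1:6],
                                              var.equal = TRUE)$statistic)
  expect_equal(unname(m0$t), unname(tt), tolerance = 1e-8)
  # d0 -> Inf: every posterior variance equals the prior
  mi <- ebayes_moderate(fits, prior = list(df0 = Inf, s02 = 0.9))
  expect_true(all(abs(mi$s2_post - 0.9) < 1e-12))
  # estimated prior: null p-values approximately uniform
  m <- ebayes_moderate(fits)
  expect_gt(stats::ks.test(m$p.value, "punif")$p.value, 0.01)
  expect_gt(attr(m, "df_prior"), 0)
  expect_error(ebayes_moderate(list(sigma2 = c(1, NaN), df_residual = 3,
                                    coefficients = matrix(0, 2, 1),
                                    stdev_unscaled = matrix(1, 2, 1))))
})

test_that("moderated results agree with the reference eBayes implementation", {
  skip_if_not_installed("limma")
  set.seed(16)
  n <- 10; G <- 150
  y <- matrix(rnorm(G * n, sd = rep(sqrt(rchisq(G, 4) / 4), n)), G, n)
  X <- cbind(1, rep(0:1, each = 5))
  fits <- fit_weighted_lm(y, X)
  m <- ebayes_moderate(fits)
  lf <- limma::eBayes(limma::lmFit(y, X))
  expect_equal(attr(m, "df_prior"), lf$df.prior, tolerance = 1e-6)
  expect_equal(attr(m, "s2_prior"), lf$s2.prior, tolerance = 1e-6)
  expect_equal(unname(m$t), unname(lf$t[, 2]), tolerance = 1e-8)
  expect_equal(unname(m$p.value), unname(lf$p.value[, 2]), tolerance = 1e-8)
})

test_that("BH step-up matches the naive definition and hand cases", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(17)
  for (i in 1:10) {
    p <- round(runif(50), sample(c(1, 2, 6), 1))  # induce ties sometimes
    q <- bh_fdr(p)
    expect_equal(q, bh_naive(p), tolerance = 1e-12)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    # monotone in p-rank
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_fdr(c(0.1, NA)))
  expect_error(bh_fdr(c(0.1, 1.2)))
})

test_that("differential pipeline recovers designed treatment effects", {
  ref <- small_reference()
  co <- study_cohort()
  et <- run_differential(co$counts, co$meta, "MO3-BL")
  expect_true(all(c("feature", "effect", "t", "p.value", "q.value",
                    "mean_expr", "df_residual") %in% names(et)))
  expect_true(all(et$p.value >= 0 & et$p.value <= 1))
  sig_down <- et$feature[et$q.value < 0.05 & et$effect < 0]
  expect_gt(length(sig_down), 5)
  neut <- names(ref$marker_truth)[!is.na(ref$marker_truth) &
                                    ref$marker_truth == "neutrophils"]
  # neutrophil markers strongly enriched among significant down genes
  enrich <- stats::phyper(sum(sig_down %in% neut) - 1, length(neut),
                          nrow(et) - length(neut), length(sig_down),
                          lower.tail = FALSE)
  expect_lt(enrich, 1e-6)
  # identical input, identical output (no RNG in the pipeline)
  expect_identical(et, run_differential(co$counts, co$meta, "MO3-BL"))
  # permuting sample labels destroys the enrichment
  set.seed(18)
  meta_perm <- co$meta
  perm <- sample(nrow(meta_perm))
  meta_perm$visit <- meta_perm$visit[perm]
  meta_perm$subject <- meta_perm$subject[perm]
  keep <- ave(seq_len(nrow(meta_perm)), meta_perm$subject,
              FUN = length) == 2 &
    ave(meta_perm$visit == "BL", meta_perm$subject, FUN = sum) == 1
  et_p <- run_differential(co$counts[, keep], meta_perm[keep, ], "MO3-BL")
  expect_lt(sum(et_p$q.value < 0.05), length(sig_down))
})
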