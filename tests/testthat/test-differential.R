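# Fixtures for the differential machinery: counts with known means and
# dispersions, normalization factors either trivial or from real decay fits.

make_params <- function(a, b, s) {
  structure(list(a = a, b = b, size_factors = s), class = "fourc_vst")
}

# A degenerate decay object whose per-sample curves are the constants
# given on the transformed scale.
constant_decay <- function(values) {
  structure(list(mode = "symmetric", lambda = 1,
                 samples = lapply(values, function(v) {
                   list(both = list(knots = numeric(0), xrange = c(3, 6),
                                    intercept = v, coef = numeric(0),
                                    constant = TRUE, value = v))
                 }),
                 sample_names = paste0("s", seq_along(values))),
            class = "fourc_decay")
}

test_that("normalization factors are back-transformed fits, unit geomean", {
  params <- make_params(1, 0.1, s = c(1, 1))
  # constant fits whose back-transform equals 2 and 8 on the count scale
  fit <- constant_decay(c(vst(2, params, 1), vst(8, params, 2)))
  n <- normalization_factors(fit, d = c(1e4, 1e5), params)
  expect_equal(n[1, ], c(0.5, 2), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(n[2, ], c(0.5, 2), tolerance = 1e-9, ignore_attr = TRUE)

  # identical fits in all samples: factors all 1
  fit1 <- constant_decay(rep(vst(5, params, 1), 2))
  n1 <- normalization_factors(fit1, d = c(1e4, 1e5), params)
  expect_equal(as.vector(n1), rep(1, 4))
})

test_that("the per-fragment geometric mean of factors is 1 on a real fit", {
  set.seed(61)
  d <- grid_distances(400)
  sim <- simulate_counts(d, simulation_truth(seed = 61), c("A", "A", "B", "B"))
  an <- analyze_counts(sim$counts, d, c("A", "A", "B", "B"))
  n <- normalization_factors(an$decay, d[an$tested], an$vst_params)
  expect_lt(max(abs(exp(rowMeans(log(n))) - 1)), 1e-8)
  expect_true(all(n > 0 & is.finite(n)))
})

test_that("dispersion estimation recovers the truth and shrinks outliers", {
  set.seed(62)
  g <- 2000; m <- 6
  K <- matrix(rnbinom(g * m, mu = 300, size = 1 / 0.05), g, m)
  N <- matrix(1, g, m)
  cond <- rep(c("A", "B"), each = 3)
  disp <- estimate_dispersions(K, N, cond)
  expect_lt(abs(median(disp$dispersion) - 0.05) / 0.05, 0.3)

  # an outlier MLE is pulled toward the trend
  i <- which.max(disp$mle)
  expect_lt(abs(log(disp$dispersion[i]) - log(disp$trend[i])),
            abs(log(disp$mle[i]) - log(disp$trend[i])))

  # Poisson data: MLEs sit at the floor and the shrunken estimates stay an
  # order of magnitude below any real overdispersion level
  set.seed(63)
  KP <- matrix(rpois(1000 * m, 300), 1000, m)
  dp <- estimate_dispersions(KP, matrix(1, 1000, m), cond)
  expect_lt(median(dp$mle), 1e-6)
  expect_lt(median(dp$dispersion), 0.005)
})

test_that("the Wald test is exact on perfect nulls and label-symmetric", {
  set.seed(64)
  g <- 150; half <- matrix(rnbinom(g * 3, mu = 150, size = 20), g, 3)
  K <- cbind(half, half)          # condition B is a copy of condition A
  N <- matrix(1, g, 6)
  cond <- rep(c("A", "B"), each = 3)
  disp <- estimate_dispersions(K, N, cond)
  res <- nb_wald_test(K, N, cond, c("A", "B"), disp$dispersion)
  expect_equal(max(abs(res$log2FoldChange)), 0)
  expect_equal(min(res$pvalue), 1)

  # swapping the contrast negates the LFC and preserves the p-value
  set.seed(65)
  K2 <- matrix(rnbinom(g * 6, mu = 200, size = 20), g, 6)
  disp2 <- estimate_dispersions(K2, N, cond)
  ab <- nb_wald_test(K2, N, cond, c("A", "B"), disp2$dispersion)
  ba <- nb_wald_test(K2, N, cond, c("B", "A"), disp2$dispersion)
  expect_equal(ab$log2FoldChange, -ba$log2FoldChange, tolerance = 1e-8)
  expect_equal(ab$pvalue, ba$pvalue, tolerance = 1e-8)

  # a global rescaling of the factor matrix changes nothing
  N7 <- (N * 7) / exp(rowMeans(log(N * 7)))
  r7 <- nb_wald_test(K2, N7, cond, c("A", "B"), disp2$dispersion)
  expect_equal(ab$stat, r7$stat, tolerance = 1e-10)
})

test_that("planted fold changes are estimated accurately", {
  set.seed(66)
  g <- 2000; m <- 6
  idx <- sample(g, g * 0.05)
  mu <- matrix(200, g, m)
  mu[idx, 1:3] <- 800                      # 4-fold up in condition A
  K <- matrix(rnbinom(g * m, mu = mu, size = 1 / 0.05), g, m)
  N <- matrix(1, g, m)
  cond <- rep(c("A", "B"), each = 3)
  disp <- estimate_dispersions(K, N, cond)
  res <- nb_wald_test(K, N, cond, c("A", "B"), disp$dispersion)
  expect_equal(mean(res$log2FoldChange[idx]), 2, tolerance = 0.2)
  # flagged as differential and cross-referenced with interaction calls
  called <- seq_len(g) %in% idx[1:10]
  out <- call_differential(res, padj_thresh = 0.01, interaction_called = called)
  expect_true(all(out$label[idx[1:10]] == "interaction+differential"))
  expect_gt(sum(out$differential[idx]), 0.8 * length(idx))
  expect_lt(mean(out$differential[-idx]), 0.01)
})

test_that("separated fragments are flagged, empty input returns empty", {
  K <- rbind(c(0, 0, 0, 40, 50, 60), c(30, 20, 25, 28, 22, 26))
  N <- matrix(1, 2, 6)
  cond <- rep(c("A", "B"), each = 3)
  res <- nb_wald_test(K, N, cond, c("A", "B"), c(0.05, 0.05))
  expect_equal(res$flag[1], "separated")
  expect_lt(res$log2FoldChange[1], -5)
  expect_equal(res$flag[2], "ok")

  empty <- call_differential(res[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("results agree with an independent NB-GLM implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(67)
  g <- 300; m <- 6
  idx <- sample(g, 20)
  mu <- matrix(150, g, m); mu[idx, 1:3] <- 600
  K <- matrix(rnbinom(g * m, mu = mu, size = 1 / 0.05), g, m)
  N <- matrix(exp(rnorm(g * m, 0, 0.05)), g, m)
  N <- N / exp(rowMeans(log(N)))
  cond <- rep(c("A", "B"), each = 3)
  disp <- estimate_dispersions(K, N, cond)
  res <- nb_wald_test(K, N, cond, c("A", "B"), disp$dispersion)

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      K, data.frame(condition = factor(cond, levels = c("B", "A"))),
      ~condition)
    DESeq2::normalizationFactors(dds) <- N
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds, contrast = c("condition", "A", "B"))
  })
  ok <- !is.na(res$pvalue) & !is.na(ref$pvalue)
  expect_gt(cor(res$log2FoldChange[ok], ref$log2FoldChange[ok]), 0.98)
  expect_lt(median(abs(res$log2FoldChange[ok] - ref$log2FoldChange[ok])), 0.1)
  # both implementations find the same strong signals
  expect_gt(cor(res$pvalue[ok] < 0.01, ref$pvalue[ok] < 0.01), 0.8)
})
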