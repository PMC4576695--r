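## Differential contact testing: Eq.-2-style normalization factors from the
## back-transformed decay fits, trend-shrunken NB dispersions, and a
## per-fragment NB-GLM Wald test, all vectorized across fragments.

#' Normalization factors from the back-transformed decay fits
#'
#' `n_ij = v^{-1}(f_j(d_i))` scaled to unit geometric mean across samples
#' per fragment, so that the distance-dependent expected signal (and library
#' size) enters the differential NB-GLM as a multiplicative offset while
#' per-fragment scale cancels.
#'
#' @param fit A `fourc_decay` from [fit_decay()].
#' @param d Signed distances, aligned with the fragments to be tested
#'   (no zeros; trans fragments use the plateau).
#' @param params A `fourc_vst`.
#' @return Matrix of positive normalization factors, fragments x samples,
#'   with per-fragment geometric mean 1 (to 1e-8).
#' @export
normalization_factors <- function(fit, d, params) {
  f <- fitted_decay_matrix(fit, d)
  if (anyNA(f)) stop("fitted decay undefined for fragment(s): ",
                     paste(utils::head(which(rowSums(is.na(f)) > 0)), collapse = ", "))
  v0 <- vst_core(0, params$a, params$b)
  n_raw <- inverse_vst(pmax(f, v0), params)
  if (any(!is.finite(n_raw))) {
    stop("non-finite back-transformed fit at fragment(s): ",
         paste(utils::head(which(rowSums(!is.finite(n_raw)) > 0)), collapse = ", "))
  }
  # keep factors strictly positive when a fitted value sits at the
  # transform's lower boundary
  n_raw <- pmax(n_raw, 1e-3)
  n <- n_raw / exp(rowMeans(log(n_raw)))
  dimnames(n) <- dimnames(f)
  n
}

## NB log-likelihood summed over samples, vectorized over fragments:
## K, MU are g x m matrices, alpha a length-g vector.
nb_loglik <- function(K, MU, alpha) {
  r <- 1 / alpha
  rowSums(lgamma(K + r) - lgamma(r) - lgamma(K + 1) +
            r * log(r / (r + MU)) + K * log(MU / (r + MU)))
}

## Cox-Reid adjustment -0.5 log det(X' W X) for the group-means design
## (block-diagonal information: one weight sum per condition group), which
## removes the downward bias of the dispersion MLE from profiling the means.
cox_reid <- function(MU, alpha, groups) {
  W <- MU / (1 + alpha * MU)
  out <- 0
  for (lev in unique(groups)) {
    out <- out - 0.5 * log(rowSums(W[, groups == lev, drop = FALSE]))
  }
  out
}

## Profiled per-condition means: for each fragment and condition group,
## solve sum_j n_j (k_j - q n_j) / (1 + alpha q n_j) = 0 for q by Newton
## (alpha = 0 gives the closed form q = sum k / sum n).
profile_group_means <- function(K, N, groups, alpha) {
  g <- nrow(K)
  MU <- matrix(0, g, ncol(K))
  for (lev in unique(groups)) {
    jj <- which(groups == lev)
    Kg <- K[, jj, drop = FALSE]; Ng <- N[, jj, drop = FALSE]
    q <- rowSums(Kg) / rowSums(Ng)
    if (any(alpha > 0)) {
      for (it in 1:25) {
        MUg <- q * Ng
        denom <- 1 + alpha * MUg
        f <- rowSums(Ng * (Kg - MUg) / denom)
        fp <- -rowSums(Ng^2 * (1 + alpha * Kg) / denom^2)
        step <- f / fp
        step[!is.finite(step)] <- 0
        q_new <- pmax(q - step, 1e-10)
        if (max(abs(q_new - q) / pmax(q, 1e-8)) < 1e-10) { q <- q_new; break }
        q <- q_new
      }
    }
    MU[, jj] <- pmax(q, 1e-10) * Ng
  }
  MU
}

## Vectorized ternary search for the maximizer of `objfun(alpha)` on the
## log scale within [lo, hi] (per-fragment bounds).
maximize_alpha <- function(objfun, lo, hi, iter = 40L) {
  lo <- log(lo); hi <- log(hi)
  for (i in seq_len(iter)) {
    m1 <- lo + (hi - lo) / 3
    m2 <- hi - (hi - lo) / 3
    better <- objfun(exp(m1)) < objfun(exp(m2))
    lo <- ifelse(better, m1, lo)
    hi <- ifelse(better, hi, m2)
  }
  exp((lo + hi) / 2)
}

#' Trend-shrunken NB dispersion estimates
#'
#' Per-fragment NB dispersion maximum-likelihood estimates (with the
#' per-condition means profiled out) are shrunk toward a robustly fitted
#' mean-dispersion trend `alpha(mu) = a/mu + b` by taking the mode of the
#' posterior that combines the per-fragment likelihood with a log-normal
#' prior centered on the trend. The prior variance is the observed spread
#' of the log MLEs around the trend minus the expected sampling variance
#' (approximated by `trigamma((m - p)/2)`), floored at `0.25^2`.
#'
#' @param counts Count matrix over tested fragments (fragments x samples).
#' @param n Normalization factors, same shape ([normalization_factors()]).
#' @param condition Per-sample condition labels.
#' @return List: `dispersion` (final, MAP), `mle`, `trend` (per fragment),
#'   `trend_coef` (a, b), `prior_var`.
#' @export
estimate_dispersions <- function(counts, n, condition) {
  K <- as.matrix(counts); N <- as.matrix(n)
  condition <- as.character(condition)
  m <- ncol(K); p <- length(unique(condition))
  if (m - p < 1) stop("need at least one residual degree of freedom")
  nonzero <- rowSums(K) > 0
  alpha_lo <- 1e-8; alpha_hi <- 30
  K1 <- K[nonzero, , drop = FALSE]; N1 <- N[nonzero, , drop = FALSE]
  g <- nrow(K1)
  MU <- profile_group_means(K1, N1, condition, rep(0, g))
  MU <- pmax(MU, 1e-8)
  obj <- function(a) nb_loglik(K1, MU, a) + cox_reid(MU, a, condition)
  mle <- maximize_alpha(obj, rep(alpha_lo, g), rep(alpha_hi, g))
  # re-profile the means at the MLE and refine once
  MU <- pmax(profile_group_means(K1, N1, condition, mle), 1e-8)
  mle <- maximize_alpha(obj, rep(alpha_lo, g), rep(alpha_hi, g))
  mu_bar <- rowMeans(K1 / N1)
  tc <- fit_alpha_trend(mu_bar, mle)
  # the least-squares trend tracks the mean of the right-skewed MLE sampling
  # distribution; divide out the log-normal mean/median factor so the trend
  # (and hence the prior center) tracks the typical dispersion
  tc <- tc / exp(trigamma((m - p) / 2) / 2)
  tc["b"] <- max(tc["b"], 1e-8)
  trend <- pmax(tc["a"] / mu_bar + tc["b"], 1e-8)
  lr <- log(pmax(mle, 1e-8)) - log(trend)
  informative <- mle > 1e-6
  spread2 <- if (sum(informative) >= 10) stats::mad(lr[informative])^2 else 0
  prior_var <- max(spread2 - trigamma((m - p) / 2), 0.25^2)
  logpost <- function(a) {
    nb_loglik(K1, MU, a) + cox_reid(MU, a, condition) +
      stats::dnorm(log(a), log(trend), sqrt(prior_var), log = TRUE)
  }
  map <- maximize_alpha(logpost, rep(alpha_lo, g), rep(alpha_hi, g))
  expand <- function(x) { out <- rep(NA_real_, nrow(K)); out[nonzero] <- x; out }
  list(dispersion = expand(map), mle = expand(mle), trend = expand(trend),
       trend_coef = tc, prior_var = prior_var)
}

## Vectorized IRLS for the two-column NB GLM (intercept + condition
## indicator) with multiplicative offsets. Returns beta (log scale), the
## standard error of the indicator coefficient from the expected-information
## matrix, and a convergence flag.
nb_glm2_irls <- function(K, N, x, alpha, tol = 1e-8, max_iter = 100L) {
  g <- nrow(K)
  q1 <- rowSums(K[, x == 0, drop = FALSE]) / rowSums(N[, x == 0, drop = FALSE])
  q2 <- rowSums(K[, x == 1, drop = FALSE]) / rowSums(N[, x == 1, drop = FALSE])
  b1 <- log(pmax(q1, 1e-12)); b2 <- log(pmax(q2, 1e-12)) - b1
  X2 <- matrix(x, g, length(x), byrow = TRUE)
  logN <- log(N)
  conv <- rep(FALSE, g)
  for (it in seq_len(max_iter)) {
    eta <- b1 + b2 * X2
    MU <- exp(eta + logN)
    W <- MU / (1 + alpha * MU)
    Z <- eta + (K - MU) / MU
    S11 <- rowSums(W); S12 <- rowSums(W * X2); S22 <- rowSums(W * X2^2)
    T1 <- rowSums(W * Z); T2 <- rowSums(W * X2 * Z)
    det <- S11 * S22 - S12^2
    nb1 <- (S22 * T1 - S12 * T2) / det
    nb2 <- (S11 * T2 - S12 * T1) / det
    bad <- !is.finite(nb1) | !is.finite(nb2)
    nb1[bad] <- b1[bad]; nb2[bad] <- b2[bad]
    delta <- pmax(abs(nb1 - b1), abs(nb2 - b2))
    b1 <- nb1; b2 <- nb2
    conv <- delta < tol
    if (all(conv)) break
  }
  eta <- b1 + b2 * X2
  MU <- exp(eta + logN)
  W <- MU / (1 + alpha * MU)
  S11 <- rowSums(W); S12 <- rowSums(W * X2); S22 <- rowSums(W * X2^2)
  det <- S11 * S22 - S12^2
  se2 <- sqrt(S11 / det)
  list(beta0 = b1, beta = b2, se = se2, converged = conv)
}

#' Per-fragment NB-GLM Wald test between two conditions
#'
#' Fits, for every fragment, a negative-binomial GLM with log link and mean
#' `mu_ij = exp(x_j' beta) * n_ij` (normalization factors as multiplicative
#' offset) by iteratively reweighted least squares, and tests the condition
#' coefficient with a Wald statistic using expected-information standard
#' errors. Two-sided normal P-values are BH-adjusted across the tested
#' fragments.
#'
#' @param counts Count matrix over tested fragments.
#' @param n Normalization factors, same shape.
#' @param condition Per-sample condition labels.
#' @param contrast Character vector `c(A, B)`: the reported log2 fold change
#'   is `log2(A / B)`.
#' @param dispersions Per-fragment dispersions
#'   ([estimate_dispersions()]`$dispersion`); missing values are treated as
#'   untestable.
#' @return A data.frame of class `fourc_differential`: `baseMean`,
#'   `log2FoldChange`, `lfcSE`, `stat`, `pvalue`, `padj`, `dispersion`,
#'   `flag` (`"ok"`, `"not_converged"`, `"all_zero"`).
#' @export
nb_wald_test <- function(counts, n, condition, contrast, dispersions) {
  K <- as.matrix(counts); N <- as.matrix(n)
  condition <- as.character(condition)
  stopifnot(length(contrast) == 2, all(contrast %in% condition))
  jj <- which(condition %in% contrast)
  K <- K[, jj, drop = FALSE]; N <- N[, jj, drop = FALSE]
  x <- as.numeric(condition[jj] == contrast[1])  # 1 = numerator condition
  alpha <- pmax(dispersions, 1e-8)
  testable <- is.finite(alpha) & rowSums(K) > 0
  res <- data.frame(baseMean = rowMeans(K / N),
                    log2FoldChange = NA_real_, lfcSE = NA_real_,
                    stat = NA_real_, pvalue = NA_real_, padj = NA_real_,
                    dispersion = dispersions, flag = "all_zero",
                    stringsAsFactors = FALSE)
  if (any(testable)) {
    fit <- nb_glm2_irls(K[testable, , drop = FALSE], N[testable, , drop = FALSE],
                        x, alpha[testable])
    res$log2FoldChange[testable] <- fit$beta / log(2)
    res$lfcSE[testable] <- fit$se / log(2)
    res$stat[testable] <- fit$beta / fit$se
    pv <- 2 * stats::pnorm(-abs(fit$beta / fit$se))
    pv[!fit$converged] <- NA_real_
    res$pvalue[testable] <- pv
    res$flag[testable] <- ifelse(fit$converged, "ok", "not_converged")
    # separation: one group all zero gives a boundary estimate; keep the
    # (large) LFC but flag it
    zeroA <- rowSums(K[testable, x == 1, drop = FALSE]) == 0
    zeroB <- rowSums(K[testable, x == 0, drop = FALSE]) == 0
    res$flag[testable][zeroA | zeroB] <- "separated"
  }
  res$padj <- stats::p.adjust(res$pvalue, method = "BH")
  rownames(res) <- rownames(counts)
  class(res) <- c("fourc_differential", "data.frame")
  res
}

#' Flag differential fragments and cross-reference interaction calls
#'
#' @param results A `fourc_differential` from [nb_wald_test()].
#' @param padj_thresh Adjusted-P threshold (default 0.01).
#' @param interaction_called Optional logical vector (same fragments): was
#'   the fragment called as an interaction in the relevant condition?
#' @return `results` with `differential` (logical) and `label`
#'   (`"interaction+differential"`, `"differential"`, or `"ns"`) appended.
#' @export
call_differential <- function(results, padj_thresh = 0.01,
                              interaction_called = NULL) {
  differential <- !is.na(results$padj) & results$padj < padj_thresh
  results$differential <- differential
  if (is.null(interaction_called)) interaction_called <- rep(FALSE, nrow(results))
  results$label <- ifelse(differential & interaction_called,
                          "interaction+differential",
                          ifelse(differential, "differential", "ns"))
  results
}

#' MA plot of a differential 4C comparison
#'
#' @param results A `fourc_differential`.
#' @param padj_thresh Highlight threshold (default 0.01).
#' @export
plot_ma <- function(results, padj_thresh = 0.01) {
  sig <- !is.na(results$padj) & results$padj < padj_thresh
  plot(log10(results$baseMean + 1), results$log2FoldChange,
       pch = 16, cex = 0.5, col = ifelse(sig, "red", "grey50"),
       xlab = "log10 mean normalized count", ylab = "log2 fold change")
  graphics::abline(h = 0, col = "grey30")
  invisible(NULL)
}
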