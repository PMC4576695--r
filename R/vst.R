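## Variance-stabilizing transformation for NB counts with a mean-dependent
## dispersion trend alpha(mu) = a/mu + b, so var(k) = (1+a)*mu + b*mu^2.

#' Median-of-ratios size factors
#'
#' Library-size normalization factors computed as the per-sample median of
#' count ratios to the per-fragment geometric mean, rescaled to unit
#' geometric mean across samples. Falls back to total-count ratios (with a
#' warning) when no fragment has all-positive counts.
#'
#' @param counts Non-negative integer matrix, fragments x samples.
#' @return Positive numeric vector of per-sample size factors with geometric
#'   mean 1.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (any(pos)) {
    geo <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
    s <- apply(counts[pos, , drop = FALSE] / geo, 2, stats::median)
  } else {
    warning("no fragment with all-positive counts; using total-count ratios")
    tot <- colSums(counts)
    s <- tot / exp(mean(log(tot)))
  }
  s / exp(mean(log(s)))
}

# Robust fit of a dispersion trend alpha(mu) = a/mu + b by iterated least
# squares on the design (1/mu, 1), excluding the top/bottom 5% of residuals
# each iteration. Returns c(a, b) with a >= 0 and b >= floor.
fit_alpha_trend <- function(mu, alpha, max_iter = 10L, tol = 1e-6,
                            trim = 0.05, b_floor = 1e-8) {
  ok <- is.finite(mu) & mu > 0 & is.finite(alpha)
  mu <- mu[ok]; alpha <- alpha[ok]
  if (length(mu) < 10) stop("too few fragments to fit a dispersion trend")
  X <- cbind(1 / mu, 1)
  keep <- rep(TRUE, length(mu))
  ab <- c(0, 0)
  for (it in seq_len(max_iter)) {
    fit <- stats::lm.fit(X[keep, , drop = FALSE], alpha[keep])
    new_ab <- fit$coefficients
    r <- alpha - X %*% new_ab
    qs <- stats::quantile(r, c(trim, 1 - trim))
    keep <- r >= qs[1] & r <= qs[2]
    if (max(abs(new_ab - ab)) < tol) { ab <- new_ab; break }
    ab <- new_ab
  }
  c(a = max(ab[1], 0), b = max(ab[2], b_floor))
}

#' Fit the dispersion trend underlying the variance-stabilizing transform
#'
#' Per-fragment method-of-moments dispersions are computed from
#' size-factor-normalized counts and a trend `alpha(mu) = a/mu + b` is
#' fitted robustly (iterated least squares with 5% two-sided residual
#' trimming).
#'
#' @param counts Count matrix, fragments x samples.
#' @param s Size factors from [size_factors()].
#' @param min_fragments Minimum number of fragments with positive mean
#'   (default 50).
#' @return Named numeric `c(a, b)`.
#' @export
fit_dispersion_trend <- function(counts, s = size_factors(counts),
                                 min_fragments = 50L) {
  q <- sweep(as.matrix(counts), 2, s, "/")
  mu <- rowMeans(q)
  v <- apply(q, 1, stats::var)
  ok <- mu > 0
  if (sum(ok) < min_fragments) {
    stop("fewer than ", min_fragments, " fragments with positive mean; ",
         "consider fitting jointly across viewpoints")
  }
  alpha <- pmax(0, (v[ok] - mu[ok]) / mu[ok]^2)
  fit_alpha_trend(mu[ok], alpha)
}

#' Fit variance-stabilizing transformation parameters
#'
#' @param counts Count matrix (typically restricted to the fragments that
#'   survive the low-count filter; see [filter_low_counts()]).
#' @param s Optional precomputed size factors.
#' @return An object of class `fourc_vst` holding the dispersion-trend
#'   coefficients `a`, `b` and the size factors.
#' @export
fit_vst <- function(counts, s = size_factors(counts)) {
  ab <- fit_dispersion_trend(counts, s)
  structure(list(a = unname(ab["a"]), b = unname(ab["b"]), size_factors = s),
            class = "fourc_vst")
}

#' @export
print.fourc_vst <- function(x, ...) {
  cat(sprintf("<VST: alpha(mu) = %.4g/mu + %.4g, %d size factors>\n",
              x$a, x$b, length(x$size_factors)))
  invisible(x)
}

vst_core <- function(q, a, b) {
  log2((1 + a + 2 * b * q + 2 * sqrt(b * q * (1 + a + b * q))) / (4 * b))
}

inv_vst_core <- function(u, a, b) {
  y <- 4 * b * 2^u
  pmax((y - (1 + a))^2 / (4 * b * y), 0)
}

#' Variance-stabilizing transformation of counts
#'
#' Transforms counts so their standard deviation is approximately
#' independent of the mean under NB noise with dispersion trend
#' `a/mu + b`: with `q = k/s_j`,
#' `v(k) = log2((1 + a + 2bq + 2*sqrt(bq(1 + a + bq))) / (4b))`, the
#' closed-form antiderivative of `1/(ln2 * sd(q))`. `v` is strictly
#' increasing and asymptotically `log2`-like: `v(2q) - v(q) -> 1` for large
#' `q`.
#'
#' @param k Count value, vector, or fragments x samples matrix.
#' @param params A `fourc_vst` from [fit_vst()].
#' @param j Sample index (or indices, recycled over `k`); ignored when `k`
#'   is a matrix whose columns already correspond to the samples.
#' @return Transformed values, same shape as `k`.
#' @export
vst <- function(k, params, j = NULL) {
  stopifnot(inherits(params, "fourc_vst"))
  if (any(k < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (is.matrix(k)) {
    q <- sweep(k, 2, params$size_factors, "/")
  } else {
    if (is.null(j)) j <- 1L
    q <- k / params$size_factors[j]
  }
  vst_core(q, params$a, params$b)
}

#' Inverse of the variance-stabilizing transformation
#'
#' Back-transforms values on the stabilized scale to the raw count scale of
#' sample `j`. The transform family admits an exact algebraic inverse;
#' round trips are exact to machine precision.
#'
#' @param u Transformed value(s); must be `>= vst(0, params, j)`.
#' @inheritParams vst
#' @return Count-scale values (including the size factor of sample `j`).
#' @export
inverse_vst <- function(u, params, j = NULL) {
  stopifnot(inherits(params, "fourc_vst"))
  v0 <- vst_core(0, params$a, params$b)
  if (any(u < v0 - 1e-9, na.rm = TRUE)) {
    stop("value below transform range: u < v(0) = ", signif(v0, 6))
  }
  u <- pmax(u, v0)
  if (is.matrix(u)) {
    q <- inv_vst_core(u, params$a, params$b)
    sweep(q, 2, params$size_factors, "*")
  } else {
    if (is.null(j)) j <- 1L
    inv_vst_core(u, params$a, params$b) * params$size_factors[j]
  }
}
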