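## Smooth monotone decreasing fit of transformed counts vs log10 distance.
##
## The curve is an I-spline expansion: I-splines (cumulative sums of a
## B-spline partition of unity) are monotone increasing from 0 to 1, so a
## free intercept plus non-positive coefficients yields a smooth monotone
## non-increasing curve. The constrained least-squares problem (with a
## second-difference roughness penalty on the coefficients) is solved by
## non-negative least squares after a sign flip.

ispline_basis <- function(x, knots, xrange, order = 4L) {
  p <- length(knots) + order - 1L
  if (length(x) == 0) return(matrix(0, 0, p))
  x <- pmin(pmax(x, xrange[1]), xrange[2])  # constant extrapolation
  kall <- c(rep(xrange[1], order), knots, rep(xrange[2], order))
  B <- splines::splineDesign(kall, x, ord = order)
  n <- ncol(B)
  # I_i = sum_{j>=i} B_j; drop I_1 == 1 (absorbed by the intercept)
  vapply(2:n, function(i) rowSums(B[, i:n, drop = FALSE]), numeric(nrow(B)))
}

# Monotone non-increasing penalized least squares of y on x.
fit_monotone_side <- function(x, y, lambda = 1) {
  xr <- range(x)
  if (diff(xr) <= 0) {
    return(list(knots = numeric(0), xrange = xr, intercept = mean(y),
                coef = numeric(0), constant = TRUE, value = mean(y)))
  }
  knots <- unique(stats::quantile(x, seq(0.1, 0.9, by = 0.1), names = FALSE))
  knots <- knots[knots > xr[1] & knots < xr[2]]
  I <- ispline_basis(x, knots, xr)
  p <- ncol(I); n <- length(y)
  if (p >= 3) {
    D <- diff(diag(p), differences = 2)
    A <- rbind(cbind(1, -1, -I), cbind(0, 0, sqrt(n * lambda) * D))
    rhs <- c(y, rep(0, nrow(D)))
  } else {
    A <- cbind(1, -1, -I)
    rhs <- y
  }
  sol <- pracma::lsqnonneg(A, rhs)$x
  list(knots = knots, xrange = xr, intercept = sol[1] - sol[2],
       coef = sol[-(1:2)], constant = FALSE)
}

eval_monotone_side <- function(side, x) {
  if (length(x) == 0) return(numeric(0))
  if (isTRUE(side$constant) || length(side$coef) == 0) {
    return(rep(side$intercept, length(x)))
  }
  I <- ispline_basis(x, side$knots, side$xrange)
  side$intercept - as.vector(I %*% side$coef)
}

#' Fit the monotone distance-decay trend of the 4C signal
#'
#' Per sample, regresses the transformed counts on `log10(|d|)` with a
#' smooth monotone non-increasing spline. `symmetric` mode pools both sides
#' of the viewpoint into one fit (so `f(d) = f(-d)`); `per_side` fits left
#' (`d < 0`) and right (`d > 0`) independently, falling back to symmetric
#' with a warning when a side has fewer than `min_side` fragments.
#' Trans fragments (`d` = `NA`) and masked fragments are never fitted.
#'
#' @param v_matrix Transformed count matrix (fragments x samples).
#' @param d Signed distances ([fragment_distances()]), aligned with rows.
#' @param mode `"symmetric"` or `"per_side"`.
#' @param lambda Roughness penalty on the spline coefficients (default 1).
#' @param masked Logical vector marking fragments excluded from the fit
#'   (viewpoint-proximal zone; see [mask_viewpoint_zone()]).
#' @param min_side Minimum fragments per fitted side (default 30).
#' @return Object of class `fourc_decay` with the per-sample (and per-side)
#'   spline representations.
#' @export
fit_decay <- function(v_matrix, d, mode = c("symmetric", "per_side"),
                      lambda = 1, masked = NULL, min_side = 30L) {
  mode <- match.arg(mode)
  v_matrix <- as.matrix(v_matrix)
  stopifnot(length(d) == nrow(v_matrix))
  if (is.null(masked)) masked <- rep(FALSE, nrow(v_matrix))
  use <- !masked & !is.na(d) & d != 0
  if (sum(use) < min_side) stop("too few cis fragments to fit the decay trend")
  samples <- lapply(seq_len(ncol(v_matrix)), function(j) {
    y <- v_matrix[use, j]
    dd <- d[use]
    if (mode == "symmetric") {
      list(both = fit_monotone_side(log10(abs(dd)), y, lambda))
    } else {
      sides <- list()
      for (sd_name in c("left", "right")) {
        sel <- if (sd_name == "left") dd < 0 else dd > 0
        if (sum(sel) < min_side) {
          warning("fewer than ", min_side, " fragments on the ", sd_name,
                  " side; falling back to a symmetric fit")
          sides[[sd_name]] <- fit_monotone_side(log10(abs(dd)), y, lambda)
        } else {
          sides[[sd_name]] <- fit_monotone_side(log10(abs(dd[sel])), y[sel], lambda)
        }
      }
      sides
    }
  })
  colnames_v <- colnames(v_matrix)
  if (is.null(colnames_v)) colnames_v <- paste0("sample", seq_len(ncol(v_matrix)))
  structure(list(mode = mode, lambda = lambda, samples = samples,
                 sample_names = colnames_v),
            class = "fourc_decay")
}

#' @export
print.fourc_decay <- function(x, ...) {
  cat(sprintf("<decay fit: %s, %d samples, lambda = %g>\n",
              x$mode, length(x$samples), x$lambda))
  invisible(x)
}

#' Evaluate the fitted decay trend
#'
#' Beyond the largest fitted `|d|` the curve extrapolates as a constant
#' plateau. The viewpoint fragment itself (`d = 0`) is always masked and
#' cannot be evaluated.
#'
#' @param fit A `fourc_decay` from [fit_decay()].
#' @param j Sample index.
#' @param d Signed distance(s) in nt; `NA` (trans fragments) evaluates to
#'   the plateau value `f_j(Inf)`.
#' @return Fitted values `f_j(d)`.
#' @export
evaluate_fit <- function(fit, j, d) {
  stopifnot(inherits(fit, "fourc_decay"))
  if (any(d == 0, na.rm = TRUE)) stop("d = 0: the viewpoint fragment is masked")
  s <- fit$samples[[j]]
  out <- numeric(length(d))
  trans <- is.na(d)
  if (fit$mode == "symmetric") {
    out[!trans] <- eval_monotone_side(s$both, log10(abs(d[!trans])))
    out[trans] <- decay_plateau(fit, j)
  } else {
    left <- !trans & d < 0
    right <- !trans & d > 0
    out[left] <- eval_monotone_side(s$left, log10(abs(d[left])))
    out[right] <- eval_monotone_side(s$right, log10(d[right]))
    out[trans] <- decay_plateau(fit, j)
  }
  out
}

# Plateau value f_j(Inf): curve value at the far boundary of the fitted
# range; in per_side mode, the mean of the two sides' boundary values.
decay_plateau <- function(fit, j) {
  s <- fit$samples[[j]]
  at_end <- function(side) eval_monotone_side(side, side$xrange[2])
  if (fit$mode == "symmetric") at_end(s$both) else mean(c(at_end(s$left), at_end(s$right)))
}

# Fitted-value matrix f_j(d_i) for all fragments (plateau for trans).
fitted_decay_matrix <- function(fit, d) {
  sapply(seq_along(fit$samples), function(j) {
    out <- rep(NA_real_, length(d))
    ok <- is.na(d) | d != 0
    out[ok] <- evaluate_fit(fit, j, d[ok])
    out
  })
}

#' Residuals of the transformed counts from the decay trend
#'
#' `r_ij = v(k_ij) - f_j(d_i)` for all cis fragments with `d != 0`; trans
#' fragments are measured against the per-sample plateau `f_j(Inf)`.
#'
#' @inheritParams fit_decay
#' @param fit A `fourc_decay`.
#' @return Residual matrix, same shape as `v_matrix` (NA at `d == 0`).
#' @export
residual_matrix <- function(v_matrix, fit, d) {
  v_matrix <- as.matrix(v_matrix)
  stopifnot(length(d) == nrow(v_matrix))
  f <- fitted_decay_matrix(fit, d)
  r <- v_matrix - f
  dimnames(r) <- dimnames(v_matrix)
  r
}

#' Plot the decay fit for one sample
#'
#' Points are the transformed counts against log10 distance; the solid line
#' is the monotone fit and the dashed line the fit plus `3 * sigma`.
#'
#' @inheritParams residual_matrix
#' @param j Sample index.
#' @param sigma Optional residual scale (drawn as fit + 3 sigma when given).
#' @export
plot_decay_fit <- function(v_matrix, fit, d, j = 1, sigma = NULL) {
  ok <- !is.na(d) & d != 0
  x <- log10(abs(d[ok]))
  plot(x, v_matrix[ok, j], pch = 16, cex = 0.4, col = "grey40",
       xlab = "log10 |distance| (nt)", ylab = "v(k)",
       main = fit$sample_names[j])
  g <- seq(min(x), max(x), length.out = 400)
  side_sign <- if (fit$mode == "per_side") c(-1, 1) else 1
  for (sgn in side_sign) {
    yy <- evaluate_fit(fit, j, sgn * 10^g)
    graphics::lines(g, yy, col = "darkgreen", lwd = 2)
    if (!is.null(sigma)) graphics::lines(g, yy + 3 * sigma, col = "blue", lty = 2)
  }
  invisible(NULL)
}
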