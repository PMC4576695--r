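## Interaction calling: count filter, viewpoint masking, Eq.-style z-scores,
## one-sided normal P-values with BH adjustment, and the replicate-aware
## calling rule.

#' Filter fragments on median count across samples
#'
#' Keeps fragment `i` iff `median_j(k_ij) >= min_median`. The default of 40
#' removes the noisy low-coverage tail before fitting the transformation and
#' the decay trend.
#'
#' @param counts Count matrix, fragments x samples.
#' @param min_median Minimum median count (default 40).
#' @return Logical vector over fragments (TRUE = kept).
#' @export
filter_low_counts <- function(counts, min_median = 40) {
  apply(as.matrix(counts), 1, stats::median) >= min_median
}

#' Mask the viewpoint-proximal zone
#'
#' The fragments immediately around the viewpoint carry extreme ligation
#' frequencies that obscure specific signal. Walking outward from the
#' viewpoint separately on each side over the kept fragments, the zone
#' boundary is the first position where the mean signal increases between
#' successive fragments; everything strictly between the viewpoint and that
#' position is masked (the first locally increasing fragment itself is
#' kept). The viewpoint fragment is always masked. A hard cap bounds the
#' zone when the signal decreases monotonically to the chromosome end.
#'
#' @param fragments Fragment table (to order fragments by position).
#' @param kept Logical vector from [filter_low_counts()].
#' @param v_mean Mean transformed signal per fragment (same length as
#'   fragments; only kept fragments are inspected).
#' @param viewpoint A `fourc_viewpoint`.
#' @param max_mask_distance Cap on masked fragments per side (default 20).
#' @return Logical vector over fragments (TRUE = masked). Fragments dropped
#'   by the count filter are FALSE here; downstream code combines both.
#' @export
mask_viewpoint_zone <- function(fragments, kept, v_mean, viewpoint,
                                max_mask_distance = 20L) {
  masked <- rep(FALSE, nrow(fragments))
  vp_row <- which(fragments$index == viewpoint$fragment_index)
  masked[vp_row] <- TRUE
  on_chrom <- fragments$chrom == viewpoint$chrom
  for (dir in c(-1, 1)) {
    if (dir < 0) {
      side <- which(on_chrom & kept & fragments$midpoint < viewpoint$midpoint)
      side <- side[order(fragments$midpoint[side], decreasing = TRUE)]
    } else {
      side <- which(on_chrom & kept & fragments$midpoint > viewpoint$midpoint)
      side <- side[order(fragments$midpoint[side])]
    }
    if (!length(side)) next
    sig <- v_mean[side]
    inc <- which(diff(sig) > 0)
    t <- if (length(inc)) inc[1] + 1L else NA_integer_
    n_mask <- if (is.na(t)) {
      warning("signal decreases monotonically away from the viewpoint; ",
              "masking up to the cap")
      min(length(side), max_mask_distance)
    } else {
      min(t - 1L, max_mask_distance)
    }
    masked[side[seq_len(n_mask)]] <- TRUE
  }
  masked
}

#' z-scores from decay-fit residuals
#'
#' Per sample, `sigma_j` is the median absolute deviation of the residuals
#' (scaled by the 1.4826 normal-consistency constant, so that the normal
#' P-values downstream are calibrated) and `z_ij = r_ij / sigma_j`.
#'
#' @param residuals Residual matrix over the tested (kept, unmasked)
#'   fragments ([residual_matrix()]).
#' @param min_fragments Minimum number of tested fragments per sample.
#' @return List with `z` (matrix) and `sigma` (per-sample scale).
#' @export
z_scores <- function(residuals, min_fragments = 20L) {
  residuals <- as.matrix(residuals)
  if (nrow(residuals) < min_fragments) {
    stop("fewer than ", min_fragments, " tested fragments")
  }
  sigma <- apply(residuals, 2, stats::mad, na.rm = TRUE)
  if (any(sigma <= 0)) stop("degenerate residual scale (sigma = 0)")
  z <- sweep(residuals, 2, sigma, "/")
  list(z = z, sigma = sigma)
}

#' One-sided P-values with per-sample BH adjustment
#'
#' `p_ij = 1 - Phi(z_ij)`; the Benjamini-Hochberg adjustment is applied per
#' sample across all tested fragments (the tested family of that sample).
#'
#' @param z z-score matrix.
#' @return List with `p` and `padj` matrices.
#' @export
p_values <- function(z) {
  z <- as.matrix(z)
  p <- stats::pnorm(z, lower.tail = FALSE)
  padj <- apply(p, 2, stats::p.adjust, method = "BH")
  if (is.null(dim(padj))) padj <- matrix(padj, ncol = ncol(z), dimnames = dimnames(z))
  list(p = p, padj = padj)
}

#' Call specific viewpoint interactions per condition
#'
#' A fragment is called for a condition iff `z > z_thresh` in all replicates
#' of the condition and the adjusted P-value is below `p_thresh` in at least
#' one replicate. With a single replicate the rule degenerates to both
#' thresholds on that replicate (a warning is emitted).
#'
#' @param z z-score matrix (tested fragments x samples).
#' @param padj Adjusted P-value matrix, same shape.
#' @param conditions Character/factor vector of per-sample condition labels.
#' @param z_thresh z-score threshold (default 3).
#' @param p_thresh Adjusted-P threshold (default 0.01).
#' @return Logical matrix, tested fragments x conditions.
#' @export
call_interactions <- function(z, padj, conditions, z_thresh = 3, p_thresh = 0.01) {
  z <- as.matrix(z); padj <- as.matrix(padj)
  conditions <- as.character(conditions)
  stopifnot(ncol(z) == length(conditions), all(dim(z) == dim(padj)))
  levs <- unique(conditions)
  calls <- sapply(levs, function(cond) {
    jj <- which(conditions == cond)
    if (length(jj) == 1) {
      warning("condition '", cond, "' has a single replicate; ",
              "calling rule degenerates to one sample")
    }
    all_z <- rowSums(z[, jj, drop = FALSE] > z_thresh) == length(jj)
    any_p <- rowSums(padj[, jj, drop = FALSE] < p_thresh) >= 1
    all_z & any_p
  })
  calls <- matrix(calls, ncol = length(levs), dimnames = list(rownames(z), levs))
  calls
}
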