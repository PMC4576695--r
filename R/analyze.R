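#' Run the statistical analysis on a count matrix
#'
#' Convenience wrapper tying together the per-viewpoint statistics on an
#' assembled count matrix: low-count filter, variance-stabilizing
#' transformation (fitted on the kept fragments), viewpoint-zone masking,
#' monotone decay fit, z-scores, one-sided P-values with per-sample BH
#' adjustment, and the replicate-aware calling rule. Useful when counts come
#' from [simulate_counts()] or an external counting step rather than from
#' BAM files.
#'
#' @param counts Count matrix, fragments x samples.
#' @param d Signed distances to the viewpoint (`NA` = trans, `0` =
#'   viewpoint fragment), aligned with rows of `counts`.
#' @param conditions Per-sample condition labels.
#' @param min_median Low-count filter threshold (default 40).
#' @param mode Decay fit mode (`"symmetric"` or `"per_side"`).
#' @param lambda Decay fit roughness penalty.
#' @param z_thresh,p_thresh Calling thresholds (defaults 3 and 0.01).
#' @param mask Apply the viewpoint-zone masking heuristic (default TRUE).
#' @return List: `kept`, `masked` (logical over all fragments), `tested`
#'   (logical over all fragments), `vst_params`, `v`, `decay`, `residuals`,
#'   `z`, `sigma`, `p`, `padj`, `calls` (all over tested fragments).
#' @export
analyze_counts <- function(counts, d, conditions,
                           min_median = 40, mode = "symmetric", lambda = 1,
                           z_thresh = 3, p_thresh = 0.01, mask = TRUE) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(d), ncol(counts) == length(conditions))
  kept <- filter_low_counts(counts, min_median)
  params <- fit_vst(counts[kept, , drop = FALSE])
  v <- vst(counts[kept, , drop = FALSE], params)
  dk <- d[kept]
  masked_kept <- dk == 0 & !is.na(dk)
  if (mask) {
    # minimal positional table: masking only needs an ordering by distance
    ft <- data.frame(index = seq_len(sum(kept)) - 1L,
                     chrom = ifelse(is.na(dk), "trans", "cis"),
                     midpoint = ifelse(is.na(dk), NA_real_, dk))
    vp <- structure(list(name = "viewpoint", chrom = "cis",
                         fragment_index = if (any(masked_kept)) ft$index[which(masked_kept)[1]] else -1L,
                         midpoint = 0), class = "fourc_viewpoint")
    masked_kept <- masked_kept |
      mask_viewpoint_zone(ft, rep(TRUE, nrow(ft)), rowMeans(v), vp)
  }
  fit <- fit_decay(v, dk, mode = mode, lambda = lambda, masked = masked_kept)
  tested_kept <- !masked_kept
  r <- residual_matrix(v, fit, dk)[tested_kept, , drop = FALSE]
  zs <- z_scores(r)
  pv <- p_values(zs$z)
  calls <- call_interactions(zs$z, pv$padj, conditions, z_thresh, p_thresh)
  kept_idx <- which(kept)
  tested <- logical(length(d)); tested[kept_idx[tested_kept]] <- TRUE
  masked <- logical(length(d)); masked[kept_idx[masked_kept]] <- TRUE
  list(kept = kept, masked = masked, tested = tested,
       vst_params = params, v = v, decay = fit, residuals = r,
       z = zs$z, sigma = zs$sigma, p = pv$p, padj = pv$padj, calls = calls)
}
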