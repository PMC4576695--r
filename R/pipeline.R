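## Pipeline orchestration and standard-format exports.

#' Read and validate a run configuration
#'
#' The YAML configuration holds the genome path, viewpoint definitions
#' (name, primer, both enzymes, protocol variant), the sample sheet
#' (sample, condition, replicate, bam) and thresholds. Missing threshold
#' fields get the package defaults.
#'
#' @param path Path to a YAML config file, or a list with the same
#'   structure.
#' @return Validated config list of class `fourc_config`.
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(min_end_length = 20, min_median = 40, z_thresh = 3,
                   padj_thresh = 0.01, slack = 0, lambda = 1,
                   mode = "symmetric", min_mapq = 0, seed = 1,
                   output_dir = "fourc_output")
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  stopifnot(!is.null(cfg$genome), !is.null(cfg$viewpoint), !is.null(cfg$samples))
  if (!is.list(path) || is.character(cfg$genome)) {
    if (is.character(cfg$genome) && !file.exists(cfg$genome)) {
      stop("genome file not found: ", cfg$genome)
    }
  }
  vp <- cfg$viewpoint
  for (fld in c("name", "primer", "first_enzyme", "second_enzyme", "protocol")) {
    if (is.null(vp[[fld]])) stop("viewpoint config lacks field '", fld, "'")
  }
  cfg$samples <- as.data.frame(do.call(rbind, lapply(cfg$samples, as.data.frame)),
                               stringsAsFactors = FALSE)
  if (any(!nzchar(cfg$samples$condition))) stop("empty condition labels")
  for (bam in cfg$samples$bam) {
    if (!file.exists(bam)) stop("BAM file not found: ", bam)
  }
  with_thresholds <- c("min_end_length", "min_median", "z_thresh", "padj_thresh", "lambda")
  if (any(unlist(cfg[with_thresholds]) < 0)) stop("thresholds must be non-negative")
  class(cfg) <- c("fourc_config", "list")
  cfg
}

#' Run the 4C analysis pipeline
#'
#' Executes the requested stages in dependency order: `digest` (fragment
#' reference + viewpoint), `count` (fragment-end read counting + QC),
#' `fit` (low-count filter, VST, viewpoint masking, monotone decay fit),
#' `call` (z-scores, P-values, interaction calls), `diff` (normalization
#' factors, dispersions, Wald test; needs >= 2 conditions), `export`
#' (bedGraph/BED tracks). Results are returned and, when `output_dir` is
#' set, written as TSV/BED/bedGraph artifacts with a run log. Outputs are
#' deterministic functions of (inputs, config, seed).
#'
#' @param config A `fourc_config` (or path to one; see [read_config()]).
#' @param stages Character subset of
#'   `c("digest", "count", "fit", "call", "diff", "export")`.
#' @param state A previous return value, so later stages can be re-run
#'   without recomputing earlier ones.
#' @return A list with the accumulated artifacts (`fragments`, `viewpoint`,
#'   `counts`, `kept`, `masked`, `vst_params`, `v`, `decay`, `z`, `sigma`,
#'   `p`, `padj`, `calls`, `results`, `differential`).
#' @export
run_pipeline <- function(config, stages = c("digest", "count", "fit", "call"),
                         state = list()) {
  if (!inherits(config, "fourc_config")) config <- read_config(config)
  all_stages <- c("digest", "count", "fit", "call", "diff", "export")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- c(sprintf("fourc run, seed %s", config$seed))
  st <- state
  need <- function(what, stage_needed) {
    if (is.null(st[[what]])) {
      stop("stage needs '", what, "': run stage '", stage_needed, "' first")
    }
    st[[what]]
  }

  if ("digest" %in% stages) {
    genome <- read_genome(config$genome)
    e1 <- enzyme("first", config$viewpoint$first_enzyme$site,
                 config$viewpoint$first_enzyme$cut_offset %||% 0L)
    e2 <- enzyme("second", config$viewpoint$second_enzyme$site,
                 config$viewpoint$second_enzyme$cut_offset %||% 0L)
    frags <- annotate_ends(digest_genome(genome, e1), genome, e2,
                           config$min_end_length)
    vp <- locate_viewpoint(config$viewpoint$primer, genome, frags,
                           name = config$viewpoint$name)
    st$genome <- genome; st$fragments <- frags; st$viewpoint <- vp
    st$d <- fragment_distances(frags, vp)
    log_lines <- c(log_lines, sprintf(
      "digest: %d fragments (%d valid), viewpoint fragment %d",
      nrow(frags), sum(frags$is_valid), vp$fragment_index))
    if (!is.null(out_dir)) {
      write_fragment_reference(frags, file.path(out_dir, "fragments.tsv"),
                               file.path(out_dir, "fragments_valid.bed"))
    }
  }

  if ("count" %in% stages) {
    frags <- need("fragments", "digest")
    cm <- make_count_matrix(config$samples, frags,
                            protocol = config$viewpoint$protocol,
                            slack = config$slack, min_mapq = config$min_mapq)
    st$counts <- cm
    log_lines <- c(log_lines, sprintf(
      "count: %s", paste(sprintf("%s %.1f%% valid", cm$qc$sample,
                                 100 * cm$qc$valid_fraction), collapse = ", ")))
    if (!is.null(out_dir)) {
      utils::write.table(cbind(frags[, c("index", "chrom", "start", "end")],
                               cm$counts),
                         file.path(out_dir, "counts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cm$qc, file.path(out_dir, "qc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("fit" %in% stages) {
    frags <- need("fragments", "digest")
    cm <- need("counts", "count")
    d <- st$d
    kept <- filter_low_counts(cm$counts, config$min_median) & frags$is_valid
    params <- fit_vst(cm$counts[kept, , drop = FALSE])
    v <- vst(cm$counts[kept, , drop = FALSE], params)
    masked_kept <- mask_viewpoint_zone(frags[kept, , drop = FALSE],
                                       rep(TRUE, sum(kept)),
                                       rowMeans(v), st$viewpoint)
    decay <- fit_decay(v, d[kept], mode = config$mode, lambda = config$lambda,
                       masked = masked_kept)
    st$kept <- kept; st$vst_params <- params; st$v <- v
    st$masked_kept <- masked_kept; st$decay <- decay
    log_lines <- c(log_lines, sprintf(
      "fit: %d kept fragments, %d masked, VST a=%.3g b=%.3g, %s fit",
      sum(kept), sum(masked_kept), params$a, params$b, config$mode))
  }

  if ("call" %in% stages) {
    frags <- need("fragments", "digest")
    v <- need("v", "fit")
    tested <- !st$masked_kept
    r <- residual_matrix(v, st$decay, st$d[st$kept])[tested, , drop = FALSE]
    zs <- z_scores(r)
    pv <- p_values(zs$z)
    calls <- call_interactions(zs$z, pv$padj, config$samples$condition,
                               config$z_thresh, config$padj_thresh)
    ft <- frags[st$kept, ][tested, ]
    results <- cbind(ft[, c("index", "chrom", "start", "end")],
                     distance = st$d[st$kept][tested], zs$z,
                     padj = pv$padj, calls)
    st$z <- zs$z; st$sigma <- zs$sigma; st$p <- pv$p; st$padj <- pv$padj
    st$calls <- calls; st$results <- results; st$tested <- tested
    log_lines <- c(log_lines, sprintf(
      "call: %d tested fragments, %s", nrow(results),
      paste(sprintf("%s: %d calls", colnames(calls), colSums(calls)),
            collapse = ", ")))
    if (!is.null(out_dir)) {
      utils::write.table(results, file.path(out_dir, "calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      called_any <- rowSums(calls) > 0
      bed <- sprintf("%s\t%d\t%d\t%s:%s", ft$chrom[called_any],
                     ft$start[called_any], ft$end[called_any],
                     st$viewpoint$name,
                     apply(calls[called_any, , drop = FALSE], 1,
                           function(x) paste(colnames(calls)[x], collapse = ",")))
      writeLines(bed, file.path(out_dir, "calls.bed"))
    }
  }

  if ("diff" %in% stages) {
    v <- need("v", "fit")
    tested <- !st$masked_kept
    conds <- unique(config$samples$condition)
    if (length(conds) < 2) stop("differential testing needs >= 2 conditions")
    kc <- st$counts$counts[st$kept, , drop = FALSE][tested, , drop = FALSE]
    n <- normalization_factors(st$decay, st$d[st$kept][tested], st$vst_params)
    disp <- estimate_dispersions(kc, n, config$samples$condition)
    res <- nb_wald_test(kc, n, config$samples$condition,
                        contrast = conds[1:2], dispersions = disp$dispersion)
    called_first <- if (!is.null(st$calls)) st$calls[, conds[1]] else NULL
    res <- call_differential(res, config$padj_thresh, called_first)
    st$normalization_factors <- n; st$dispersions <- disp; st$differential <- res
    log_lines <- c(log_lines, sprintf(
      "diff: %s vs %s, %d differential fragments",
      conds[1], conds[2], sum(res$differential, na.rm = TRUE)))
    if (!is.null(out_dir)) {
      ft <- st$fragments[st$kept, ][tested, ]
      utils::write.table(cbind(ft[, c("index", "chrom", "start", "end")], res),
                         file.path(out_dir, "differential.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("export" %in% stages) {
    v <- need("v", "fit")
    if (!is.null(out_dir)) {
      export_tracks(v, st$fragments[st$kept, , drop = FALSE],
                    sample_names = config$samples$sample, dir = out_dir)
      log_lines <- c(log_lines, "export: per-sample bedGraph tracks written")
    }
  }

  if (!is.null(out_dir)) {
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  message(paste(log_lines, collapse = "\n"))
  st
}

#' Export per-sample signal tracks
#'
#' Writes one bedGraph per sample with the transformed signal over the
#' fragment intervals (sorted by chrom, start), and optionally bigWig when
#' the `rtracklayer` writer is available.
#'
#' @param v_matrix Signal matrix over fragments (e.g. transformed counts).
#' @param fragments Fragment table rows matching `v_matrix`.
#' @param sample_names Names used in the output file names.
#' @param dir Output directory.
#' @param format `"bedGraph"` (always available) or `"bigWig"`.
#' @return Character vector of written paths.
#' @export
export_tracks <- function(v_matrix, fragments, sample_names = colnames(v_matrix),
                          dir = ".", format = c("bedGraph", "bigWig")) {
  format <- match.arg(format)
  v_matrix <- as.matrix(v_matrix)
  if (is.null(sample_names)) sample_names <- paste0("sample", seq_len(ncol(v_matrix)))
  ord <- order(fragments$chrom, fragments$start)
  paths <- character(0)
  for (j in seq_len(ncol(v_matrix))) {
    if (format == "bedGraph") {
      path <- file.path(dir, paste0(sample_names[j], ".bedGraph"))
      writeLines(sprintf("%s\t%d\t%d\t%s", fragments$chrom[ord],
                         fragments$start[ord], fragments$end[ord],
                         formatC(v_matrix[ord, j], format = "g", digits = 8)),
                 path)
    } else {
      if (!requireNamespace("rtracklayer", quietly = TRUE)) {
        stop("bigWig export needs the rtracklayer package")
      }
      path <- file.path(dir, paste0(sample_names[j], ".bw"))
      gr <- GenomicRanges::GRanges(fragments$chrom[ord],
                                   IRanges::IRanges(fragments$start[ord] + 1L,
                                                    fragments$end[ord]),
                                   score = v_matrix[ord, j])
      chrlen <- tapply(fragments$end, fragments$chrom, max)
      GenomeInfoDb::seqlengths(gr) <- chrlen[GenomeInfoDb::seqlevels(gr)]
      rtracklayer::export.bw(gr, path)
    }
    paths <- c(paths, path)
  }
  paths
}

#' Read a bedGraph written by [export_tracks()]
#'
#' @param path bedGraph path.
#' @return data.frame with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", col.names = c("chrom", "start", "end", "value"))
  df
}
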