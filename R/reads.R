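## Read processing: demultiplexing, trim-rescue and fragment-end counting.

#' Demultiplex a FASTQ file by viewpoint primer
#'
#' Each read is assigned to the unique viewpoint whose (barcode +) primer
#' matches the read prefix with at most `max_mismatch` mismatches; the
#' matched prefix is trimmed off. Reads matching no primer, or more than
#' one, go to the `undetermined` stream.
#'
#' @param fastq Input FASTQ path.
#' @param primers Named character vector of primer sequences (names =
#'   viewpoint names). No primer may be a prefix of another.
#' @param barcodes Optional named character vector of per-viewpoint barcodes
#'   prepended to the primer.
#' @param max_mismatch Maximum Hamming mismatches in the prefix (default 0).
#' @param outdir Directory for the per-viewpoint (and undetermined) FASTQ
#'   output.
#' @return A data.frame tally: viewpoint, reads assigned; the
#'   `undetermined` row counts unassigned plus ambiguous reads.
#' @export
demultiplex <- function(fastq, primers, barcodes = NULL, max_mismatch = 0L,
                        outdir = dirname(fastq)) {
  primers <- toupper(primers)
  if (!is.null(barcodes)) primers <- paste0(toupper(barcodes[names(primers)]), primers)
  np <- nchar(primers)
  for (i in seq_along(primers)) for (k in seq_along(primers)) {
    if (i != k && np[i] <= np[k] && substr(primers[k], 1, np[i]) == primers[i])
      stop("primer '", names(primers)[i], "' is a prefix of '", names(primers)[k], "'")
  }
  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq", with.qualities = TRUE)
  quals <- S4Vectors::mcols(reads)$qualities
  seqs <- as.character(reads)
  nhit <- integer(length(seqs))
  hit <- integer(length(seqs))
  for (i in seq_along(primers)) {
    pref <- substr(seqs, 1, np[i])
    d <- mapply(function(x, p) sum(charToRaw(x) != charToRaw(p)),
                pref, rep(primers[i], length(pref)), USE.NAMES = FALSE)
    ok <- nchar(pref) == np[i] & d <= max_mismatch
    nhit <- nhit + ok
    hit[ok] <- i
  }
  hit[nhit != 1L] <- 0L
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_fq <- function(sel, trim, path) {
    if (!any(sel)) { file.create(path); return(invisible()) }
    s <- Biostrings::DNAStringSet(substring(seqs[sel], trim + 1L))
    q <- Biostrings::BStringSet(substring(as.character(quals[sel]), trim + 1L))
    names(s) <- names(reads)[sel]
    Biostrings::writeXStringSet(s, path, format = "fastq", qualities = q)
  }
  out <- character(0)
  for (i in seq_along(primers)) {
    path <- file.path(outdir, paste0(names(primers)[i], ".fastq"))
    write_fq(hit == i, np[i], path)
    out[names(primers)[i]] <- path
  }
  und <- file.path(outdir, "undetermined.fastq")
  write_fq(hit == 0L, 0L, und)
  data.frame(viewpoint = c(names(primers), "undetermined"),
             reads = c(tabulate(hit, length(primers)), sum(hit == 0L)),
             file = c(out, und), row.names = NULL)
}

#' Trim unaligned reads at the second-cutter site for re-alignment
#'
#' Reads that run through the second-enzyme cutting site into the ligated
#' fragment often fail to align uniquely; truncating them at the cut
#' position of the first site occurrence rescues them for a second
#' alignment pass.
#'
#' @param sequences Character vector of read sequences (typically the reads
#'   an external aligner reported as unaligned).
#' @param second_enzyme The second cutter, a [enzyme()].
#' @param min_length Reads shorter than this after truncation are dropped
#'   (returned as `NA`); default 20.
#' @return Character vector: truncated sequence where the site occurs,
#'   unchanged sequence otherwise, `NA` for dropped reads.
#' @export
trim_to_second_site <- function(sequences, second_enzyme, min_length = 20L) {
  pos <- regexpr(second_enzyme$site, toupper(sequences), fixed = TRUE)
  cutat <- ifelse(pos > 0, pos - 1L + second_enzyme$cut_offset, NA_integer_)
  out <- ifelse(is.na(cutat), sequences, substr(sequences, 1L, cutat))
  out[!is.na(cutat) & cutat < min_length] <- NA_character_
  out
}

# 0-based 5' terminus and (chrom, strand) of each BAM record.
read_bam_termini <- function(bam, min_mapq = 0L) {
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags, what = "mapq")
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  keep <- is.na(S4Vectors::mcols(ga)$mapq) | S4Vectors::mcols(ga)$mapq >= min_mapq
  n_low <- sum(!keep)
  ga <- ga[keep]
  strand <- as.character(BiocGenerics::strand(ga))
  data.frame(chrom = as.character(GenomicAlignments::seqnames(ga)),
             # plus-strand 5' end = 0-based start; minus-strand 5' end =
             # half-open alignment end
             terminus = ifelse(strand == "+",
                               BiocGenerics::start(ga) - 1L,
                               BiocGenerics::end(ga)),
             strand = strand,
             stringsAsFactors = FALSE) -> df
  attr(df, "n_low_mapq") <- n_low
  df
}

# Expected (coordinate, strand) of a protocol-conforming read for each
# fragment end. Reads are anchored at restriction cut sites:
#  * first_cutter_primer: reads start at the fragment boundaries and point
#    toward the fragment middle (left end: + strand at `start`; right end:
#    - strand at `end`).
#  * second_cutter_primer: reads start at the second-enzyme cut sites inside
#    the fragment and point toward the fragment ends (left end: - strand at
#    start + left_end_length; right end: + strand at end - right_end_length).
fragment_end_targets <- function(fragments, protocol) {
  protocol <- match.arg(protocol, c("first_cutter_primer", "second_cutter_primer"))
  f <- fragments
  if (protocol == "first_cutter_primer") {
    left <- data.frame(index = f$index, chrom = f$chrom, coord = f$start,
                       strand = "+", end = "left")
    right <- data.frame(index = f$index, chrom = f$chrom, coord = f$end,
                        strand = "-", end = "right")
  } else {
    has <- f$has_second_site
    if (is.null(has)) stop("second_cutter_primer protocol needs annotated ends")
    left <- data.frame(index = f$index[has], chrom = f$chrom[has],
                       coord = f$start[has] + f$left_end_length[has],
                       strand = "-", end = "left")
    right <- data.frame(index = f$index[has], chrom = f$chrom[has],
                        coord = f$end[has] - f$right_end_length[has],
                        strand = "+", end = "right")
  }
  rbind(left, right)
}

#' Count protocol-valid reads onto fragment ends for one sample
#'
#' A read is assigned to a fragment end iff its 5' alignment terminus lies
#' within `slack` nt of the required cut-site coordinate and its strand
#' matches the protocol rule (see Details). The counts of both ends of a
#' fragment are combined. Reads failing the rules are tallied by rejection
#' reason; reads conforming to the rules but landing on invalid fragments
#' are counted separately for QC and excluded from the returned counts.
#'
#' @details With a `first_cutter_primer` protocol reads start at the
#'   fragment boundaries (first-cutter sites) and are oriented toward the
#'   fragment middle; with a `second_cutter_primer` protocol reads start at
#'   the second-cutter site inside the fragment and are oriented toward the
#'   fragment ends.
#'
#' @param bam Path to a BAM file (one viewpoint-library).
#' @param fragments Annotated fragment table ([annotate_ends()]).
#' @param protocol `"first_cutter_primer"` or `"second_cutter_primer"`.
#' @param slack Allowed deviation (nt) of the 5' terminus from the required
#'   coordinate (default 0, strict).
#' @param min_mapq Minimum mapping quality (default 0).
#' @return A list: `counts` (integer vector over all fragments, in fragment
#'   table order; nonzero only on valid fragments), `stats` (total records,
#'   assigned to valid / invalid fragments, rejections by reason).
#' @export
count_reads <- function(bam, fragments, protocol = "first_cutter_primer",
                        slack = 0L, min_mapq = 0L) {
  reads <- read_bam_termini(bam, min_mapq)
  unknown <- setdiff(unique(reads$chrom), unique(fragments$chrom))
  if (length(unknown)) {
    stop("BAM chromosome(s) absent from fragment table: ",
         paste(unknown, collapse = ", "))
  }
  targets <- fragment_end_targets(fragments, protocol)
  key <- function(chrom, coord, strand) paste(chrom, coord, strand)
  tkey <- key(targets$chrom, targets$coord, targets$strand)
  hit <- rep(NA_integer_, nrow(reads))
  for (off in seq(-slack, slack)) {
    m <- match(key(reads$chrom, reads$terminus + off, reads$strand), tkey)
    upd <- is.na(hit) & !is.na(m)
    hit[upd] <- m[upd]
  }
  # classify misses: right coordinate but wrong strand vs not at a cut site
  flip <- ifelse(reads$strand == "+", "-", "+")
  wrong_strand <- is.na(hit) &
    !is.na(match(key(reads$chrom, reads$terminus, flip), tkey))
  frag_idx <- targets$index[hit]
  valid <- fragments$is_valid[match(frag_idx, fragments$index)]
  counts <- integer(nrow(fragments))
  tab <- table(factor(frag_idx[!is.na(hit) & valid],
                      levels = fragments$index))
  counts <- as.integer(tab)
  stats <- list(total = nrow(reads) + attr(reads, "n_low_mapq"),
                processed = nrow(reads),
                low_mapq = attr(reads, "n_low_mapq"),
                assigned_valid = sum(!is.na(hit) & valid, na.rm = TRUE),
                assigned_invalid = sum(!is.na(hit) & !valid, na.rm = TRUE),
                rejected_wrong_strand = sum(wrong_strand),
                rejected_not_at_cut_site = sum(is.na(hit) & !wrong_strand))
  list(counts = counts, stats = stats)
}

#' Assemble a fragments x samples count matrix from BAM files
#'
#' @param sample_sheet data.frame with columns `sample`, `condition`,
#'   `replicate`, `bam`.
#' @inheritParams count_reads
#' @return A list of class `fourc_counts`: `counts` (matrix, rows = fragment
#'   indices, columns = samples), `samples` (the sample sheet), `qc`
#'   (per-sample QC stats incl. the valid-fragment fraction).
#' @export
make_count_matrix <- function(sample_sheet, fragments,
                              protocol = "first_cutter_primer",
                              slack = 0L, min_mapq = 0L) {
  stopifnot(all(c("sample", "condition", "bam") %in% names(sample_sheet)))
  res <- lapply(sample_sheet$bam, count_reads, fragments = fragments,
                protocol = protocol, slack = slack, min_mapq = min_mapq)
  counts <- sapply(res, `[[`, "counts")
  dimnames(counts) <- list(fragments$index, sample_sheet$sample)
  qc <- do.call(rbind, lapply(res, function(r) as.data.frame(r$stats)))
  qc$sample <- sample_sheet$sample
  qc$valid_fraction <- mapply(qc_valid_fraction, qc$assigned_valid,
                              qc$processed)
  structure(list(counts = counts, samples = sample_sheet, qc = qc),
            class = "fourc_counts")
}

#' @export
print.fourc_counts <- function(x, ...) {
  cat(sprintf("<4C count matrix: %d fragments x %d samples>\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Fraction of aligned reads assigned to valid fragments
#'
#' A routine QC number for a 4C library; values around 0.7-0.95 are typical
#' for a good library. A warning is emitted below `floor`.
#'
#' @param assigned_valid Reads assigned to valid fragments.
#' @param total_aligned Total aligned reads (> 0).
#' @param floor Warning threshold (default 0.5).
#' @return The fraction.
#' @export
qc_valid_fraction <- function(assigned_valid, total_aligned, floor = 0.5) {
  stopifnot(total_aligned > 0)
  frac <- assigned_valid / total_aligned
  if (frac < floor) {
    warning(sprintf("only %.1f%% of aligned reads map to valid fragments", 100 * frac))
  }
  frac
}
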