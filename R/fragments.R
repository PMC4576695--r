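## All genomic coordinates in the fragment table are 0-based, half-open.

# All cut coordinates of `enz` on `chrom_seq` (a DNAString), both strands.
# Overlapping occurrences all count; N never matches. For an occurrence of
# the site on the forward strand starting at 0-based position s, the cut is
# at s + cut_offset; for an occurrence of the reverse complement, the
# enzyme's offset applies from the 5' end of the minus strand, i.e. at
# s + nchar(site) - cut_offset. Identical for palindromic sites with a
# symmetric offset.
cut_positions <- function(chrom_seq, enz) {
  L <- nchar(enz$site)
  fwd <- Biostrings::start(Biostrings::matchPattern(enz$site, chrom_seq, fixed = TRUE)) - 1L
  cuts <- fwd + enz$cut_offset
  rc <- reverse_complement(enz$site)
  if (rc != enz$site) {
    rev <- Biostrings::start(Biostrings::matchPattern(rc, chrom_seq, fixed = TRUE)) - 1L
    cuts <- c(cuts, rev + L - enz$cut_offset)
  }
  sort(unique(cuts))
}

#' Digest a genome in silico with the first restriction enzyme
#'
#' Fragments are the maximal intervals between consecutive cut sites of the
#' first cutter; the two terminal intervals of each chromosome are retained
#' (they carry only one true restriction end) and empty intervals are
#' dropped. Coordinates are 0-based half-open.
#'
#' @param genome A genome as returned by [read_genome()].
#' @param first_enzyme The first cutter, a [enzyme()].
#' @return A `data.frame` with one row per fragment: `index` (0-based,
#'   genome-wide in chromosome order), `chrom`, `start`, `end`, `midpoint`.
#' @export
digest_genome <- function(genome, first_enzyme) {
  genome <- read_genome(genome)
  stopifnot(inherits(first_enzyme, "fourc_enzyme"))
  per_chrom <- lapply(seq_along(genome), function(ci) {
    n <- Biostrings::width(genome)[ci]
    cuts <- cut_positions(genome[[ci]], first_enzyme)
    bounds <- unique(c(0L, cuts[cuts > 0L & cuts < n], n))
    data.frame(chrom = names(genome)[ci],
               start = bounds[-length(bounds)],
               end = bounds[-1],
               stringsAsFactors = FALSE)
  })
  frags <- do.call(rbind, per_chrom)
  frags <- frags[frags$end > frags$start, , drop = FALSE]
  frags$index <- seq_len(nrow(frags)) - 1L
  frags$midpoint <- (frags$start + frags$end) / 2
  rownames(frags) <- NULL
  frags[, c("index", "chrom", "start", "end", "midpoint")]
}

#' Annotate fragment ends with the second cutter and flag valid fragments
#'
#' A fragment end is the region between a fragment boundary and the nearest
#' second-enzyme cut site strictly inside the fragment. A fragment is valid
#' if it contains at least one second-enzyme site and at least one of its
#' ends is at least `min_end_length` nt long; one sub-threshold end does not
#' invalidate a fragment whose other end is long enough.
#'
#' @param fragments Fragment table from [digest_genome()].
#' @param genome The same genome the fragments were derived from.
#' @param second_enzyme The second cutter, a [enzyme()].
#' @param min_end_length Minimum fragment-end length in nt (default 20).
#' @return The fragment table with columns `left_end_length`,
#'   `right_end_length` (NA when no second site), `has_second_site`,
#'   `left_end_valid`, `right_end_valid`, `is_valid` appended.
#' @export
annotate_ends <- function(fragments, genome, second_enzyme, min_end_length = 20L) {
  genome <- read_genome(genome)
  stopifnot(inherits(second_enzyme, "fourc_enzyme"))
  fragments$left_end_length <- NA_integer_
  fragments$right_end_length <- NA_integer_
  fragments$has_second_site <- FALSE
  for (chrom in unique(fragments$chrom)) {
    if (!chrom %in% names(genome)) stop("chromosome absent from genome: ", chrom)
    cuts <- cut_positions(genome[[chrom]], second_enzyme)
    sel <- which(fragments$chrom == chrom)
    st <- fragments$start[sel]; en <- fragments$end[sel]
    # first and last cut strictly inside (start, end)
    lo <- findInterval(st, cuts) + 1L      # index of first cut > start
    hi <- findInterval(en - 1e-9, cuts)    # index of last cut < end
    has <- lo <= hi & hi >= 1L & lo <= length(cuts)
    fragments$has_second_site[sel] <- has
    ok <- which(has)
    fragments$left_end_length[sel[ok]] <- as.integer(cuts[lo[ok]] - st[ok])
    fragments$right_end_length[sel[ok]] <- as.integer(en[ok] - cuts[hi[ok]])
  }
  fragments$left_end_valid <- !is.na(fragments$left_end_length) &
    fragments$left_end_length >= min_end_length
  fragments$right_end_valid <- !is.na(fragments$right_end_length) &
    fragments$right_end_length >= min_end_length
  fragments$is_valid <- fragments$has_second_site &
    (fragments$left_end_valid | fragments$right_end_valid)
  fragments
}

#' Locate the viewpoint fragment from its primer sequence
#'
#' The primer and its reverse complement are searched exactly in the genome;
#' the fragment containing the match start is the viewpoint fragment.
#'
#' @param primer Primer sequence (length >= 15 to guard against spurious
#'   matches).
#' @param genome Genome as for [digest_genome()].
#' @param fragments Annotated fragment table.
#' @param name Viewpoint name.
#' @param max_mismatch Maximum number of mismatches allowed in the primer
#'   match (default 0, exact).
#' @return A list of class `fourc_viewpoint` with `name`, `primer`, `chrom`,
#'   `fragment_index`, `midpoint`.
#' @export
locate_viewpoint <- function(primer, genome, fragments, name = "viewpoint",
                             max_mismatch = 0L) {
  genome <- read_genome(genome)
  primer <- toupper(primer)
  if (nchar(primer) < 15) stop("primer too short (< 15 nt)")
  hits <- list()
  for (chrom in names(genome)) {
    for (pat in unique(c(primer, reverse_complement(primer)))) {
      m <- Biostrings::matchPattern(pat, genome[[chrom]], fixed = TRUE,
                                    max.mismatch = max_mismatch)
      if (length(m)) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, pos = Biostrings::start(m) - 1L)
      }
    }
  }
  if (!length(hits)) stop("primer not found in genome")
  hits <- do.call(rbind, hits)
  idx <- mapply(function(chrom, pos) {
    sel <- fragments$chrom == chrom & fragments$start <= pos & fragments$end > pos
    fragments$index[sel][1]
  }, hits$chrom, hits$pos)
  idx <- unique(idx[!is.na(idx)])
  if (length(idx) == 0) stop("primer not found in genome")
  if (length(idx) > 1) stop("ambiguous primer: matches in more than one fragment")
  row <- fragments[fragments$index == idx, ]
  structure(list(name = name, primer = primer, chrom = row$chrom,
                 fragment_index = idx, midpoint = row$midpoint),
            class = "fourc_viewpoint")
}

#' @export
print.fourc_viewpoint <- function(x, ...) {
  cat(sprintf("<viewpoint %s: fragment %d on %s, midpoint %.1f>\n",
              x$name, x$fragment_index, x$chrom, x$midpoint))
  invisible(x)
}

#' Signed genomic distance of each fragment to the viewpoint
#'
#' The distance is measured between fragment midpoints; fragments left of
#' the viewpoint get negative distances. Fragments on other chromosomes
#' (trans) have no defined distance and get `NA`.
#'
#' @param fragments Fragment table.
#' @param viewpoint A `fourc_viewpoint` from [locate_viewpoint()].
#' @return Numeric vector of signed distances in nt, aligned with the rows
#'   of `fragments`; `NA` for trans fragments.
#' @export
fragment_distances <- function(fragments, viewpoint) {
  d <- fragments$midpoint - viewpoint$midpoint
  d[fragments$chrom != viewpoint$chrom] <- NA_real_
  d
}

#' Write the fragment reference as TSV and BED
#'
#' The TSV carries all annotation columns; the BED (0-based half-open)
#' contains only the valid fragments.
#'
#' @param fragments Annotated fragment table.
#' @param tsv,bed Output paths (either may be `NULL` to skip).
#' @return Invisibly, the fragment table.
#' @export
write_fragment_reference <- function(fragments, tsv = NULL, bed = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(fragments, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed) && !is.null(fragments$is_valid)) {
    v <- fragments[fragments$is_valid, ]
    writeLines(sprintf("%s\t%d\t%d\tfrag_%d", v$chrom, v$start, v$end, v$index), bed)
  }
  invisible(fragments)
}
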