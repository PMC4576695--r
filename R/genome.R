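#' Load a genome from FASTA or character vectors
#'
#' A genome is represented as a named [Biostrings::DNAStringSet] with unique
#' chromosome names, stored uppercase and restricted to the A/C/G/T/N
#' alphabet.
#'
#' @param x Path to a (multi-record) FASTA file, a named character vector of
#'   chromosome sequences, or a `DNAStringSet`.
#' @return A validated `DNAStringSet`.
#' @export
read_genome <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    seqs <- Biostrings::readDNAStringSet(x)
    # keep only the first word of FASTA headers as chromosome name
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  } else if (is.character(x)) {
    if (is.null(names(x))) stop("genome character vector must be named by chromosome")
    seqs <- Biostrings::DNAStringSet(toupper(x))
  } else if (methods::is(x, "DNAStringSet")) {
    seqs <- x
  } else {
    stop("cannot interpret 'x' as a genome")
  }
  if (length(seqs) == 0) stop("genome is empty")
  if (anyDuplicated(names(seqs))) stop("duplicated chromosome names")
  if (any(Biostrings::width(seqs) == 0)) stop("empty chromosome sequence")
  af <- Biostrings::alphabetFrequency(seqs)
  bad <- rowSums(af[, !colnames(af) %in% c("A", "C", "G", "T", "N"),
                    drop = FALSE])
  if (any(bad > 0)) stop("genome contains letters outside {A,C,G,T,N}")
  seqs
}

#' Define a restriction enzyme
#'
#' @param name Enzyme name (free text, e.g. `"DpnII"`).
#' @param site Recognition sequence, length >= 4, letters A/C/G/T only
#'   (no ambiguity codes).
#' @param cut_offset Cut position within the recognition sequence, measured
#'   in nt from its 5' end; an integer in `[0, nchar(site)]`. DpnII
#'   (`GATC`) cuts at offset 0, NlaIII (`CATG`) at offset 4.
#' @return An object of class `fourc_enzyme`.
#' @export
enzyme <- function(name, site, cut_offset = 0L) {
  site <- toupper(site)
  if (nchar(site) < 4) stop("recognition site must be at least 4 nt")
  if (grepl("[^ACGT]", site)) stop("recognition site may only contain A/C/G/T")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0 || cut_offset > nchar(site)) {
    stop("cut_offset must lie within [0, nchar(site)]")
  }
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "fourc_enzyme")
}

#' @export
print.fourc_enzyme <- function(x, ...) {
  cat(sprintf("<enzyme %s: %s, cut at +%d>\n", x$name, x$site, x$cut_offset))
  invisible(x)
}

reverse_complement <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
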