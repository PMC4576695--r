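## Synthetic data generator: toy genomes with planted restriction sites,
## distance-decaying NB count matrices with spiked interactions, and
## protocol-conforming alignment records, so the whole pipeline is testable
## without external data.

random_seq_without <- function(n, forbidden, max_tries = 200L) {
  pats <- unique(c(forbidden, vapply(forbidden, reverse_complement, "")))
  w <- max(nchar(pats))
  v <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  for (i in seq_len(max_tries)) {
    s <- paste(v, collapse = "")
    hit <- integer(0)
    for (p in pats) {
      m <- gregexpr(p, s, fixed = TRUE)[[1]]
      if (m[1] > 0) hit <- c(hit, as.integer(m))
    }
    if (!length(hit)) return(v)
    # re-randomize every clashing window and rescan (new clashes can appear
    # at window boundaries; the expected number shrinks geometrically)
    for (pos in unique(hit)) {
      idx <- pos:min(pos + w - 1L, n)
      v[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
    }
  }
  stop("could not generate site-free background sequence")
}

#' Generate a toy genome with planted restriction sites
#'
#' The background sequence is generated free of accidental occurrences of
#' either recognition site (and their reverse complements); first-cutter
#' sites are planted at jittered spacing, and one second-cutter site is
#' planted inside each resulting fragment (at a jittered interior position)
#' so all fragments are valid by construction.
#'
#' @param n_chrom Number of chromosomes.
#' @param length Chromosome length in nt.
#' @param first_site,second_site Recognition sequences to plant.
#' @param site_spacing Mean spacing of first-cutter sites (nt); jittered by
#'   +-25%.
#' @param seed Random seed (reproducible: same seed, same FASTA).
#' @return List: `genome` (DNAStringSet), `first_sites`, `second_sites`
#'   (planted 0-based positions per chromosome).
#' @export
make_toy_genome <- function(n_chrom = 1L, length = 20000L,
                            first_site = "GATC", second_site = "CATG",
                            site_spacing = 1000L, seed = 1L) {
  if (site_spacing < 4L * (nchar(first_site) + nchar(second_site))) {
    stop("site_spacing too small for the given recognition sites")
  }
  set.seed(seed)
  L1 <- nchar(first_site); L2 <- nchar(second_site)
  s1 <- strsplit(first_site, "")[[1]]; s2 <- strsplit(second_site, "")[[1]]
  chroms <- character(n_chrom)
  first_pos <- second_pos <- vector("list", n_chrom)
  for (ci in seq_len(n_chrom)) {
    v <- random_seq_without(length, c(first_site, second_site))
    # plant first-cutter sites at jittered spacing
    pos <- c()
    at <- site_spacing
    while (at + L1 < length - site_spacing / 2) {
      p <- at + sample(seq(-site_spacing %/% 4, site_spacing %/% 4), 1)
      v[(p + 1L):(p + L1)] <- s1
      pos <- c(pos, p)
      at <- at + site_spacing
    }
    # one second-cutter site inside each fragment, away from the ends
    bounds <- c(0L, pos, length)
    spos <- c()
    for (i in seq_len(base::length(bounds) - 1L)) {
      lo <- bounds[i] + L1 + 60L
      hi <- bounds[i + 1] - L2 - 60L
      if (hi <= lo) next
      p <- sample(seq(lo, hi), 1)
      v[(p + 1L):(p + L2)] <- s2
      spos <- c(spos, p)
    }
    first_pos[[ci]] <- pos
    second_pos[[ci]] <- spos
    # planting next to background can create chimeric occurrences that
    # cross a planted-site boundary; re-randomize the offending background
    # letters (never touching planted sites) until only planted sites remain
    chroms[ci] <- repair_chimeric_sites(v, c(first_site, second_site),
                                        planted = list(first = pos, second = spos))
  }
  names(chroms) <- paste0("chr", seq_len(n_chrom))
  genome <- Biostrings::DNAStringSet(chroms)
  for (ci in seq_len(n_chrom)) {
    found <- Biostrings::start(Biostrings::matchPattern(first_site, genome[[ci]])) - 1L
    stopifnot(identical(sort(found), sort(as.integer(first_pos[[ci]]))))
  }
  list(genome = genome, first_sites = first_pos, second_sites = second_pos)
}

repair_chimeric_sites <- function(v, sites, planted, max_iter = 100L) {
  n <- base::length(v)
  lens <- c(rep(nchar(sites[1]), base::length(planted$first)),
            rep(nchar(sites[2]), base::length(planted$second)))
  pstart <- c(planted$first, planted$second)           # 0-based
  protected <- logical(n)
  for (i in seq_along(pstart)) protected[(pstart[i] + 1L):(pstart[i] + lens[i])] <- TRUE
  pats <- unique(c(sites, vapply(sites, reverse_complement, "")))
  for (iter in seq_len(max_iter)) {
    s <- paste(v, collapse = "")
    extra <- integer(0); extra_len <- integer(0)
    for (p in pats) {
      m <- gregexpr(p, s, fixed = TRUE)[[1]]
      if (m[1] > 0) {
        keep <- !(as.integer(m) - 1L) %in% pstart
        extra <- c(extra, as.integer(m)[keep])
        extra_len <- c(extra_len, rep(nchar(p), sum(keep)))
      }
    }
    if (!base::length(extra)) return(s)
    for (i in seq_along(extra)) {
      span <- extra[i]:(extra[i] + extra_len[i] - 1L)   # 1-based letters
      span <- span[!protected[span]]
      v[span] <- sample(c("A", "C", "G", "T"), base::length(span), replace = TRUE)
    }
  }
  stop("could not repair chimeric recognition sites")
}

#' Simulation truth parameters
#'
#' Defaults reproduce the calibration conditions used throughout the test
#' suite: a power-law signal decay with constant background,
#' `mu = A * (|d|/distance_unit)^(-gamma) + B`, NB dispersion trend
#' `alpha(mu) = a/mu + b`, and optional multiplicative (log2-additive)
#' interaction spikes and condition-specific differential effects.
#'
#' @param A Decay amplitude (expected counts at one `distance_unit`).
#' @param gamma Decay exponent (> 0).
#' @param B Constant background level (expected counts at large distance and
#'   on trans chromosomes).
#' @param a,b Dispersion trend coefficients (`a/mu + b`); `a = b = 0` gives
#'   Poisson counts.
#' @param distance_unit Distance (nt) at which the power law equals `A`
#'   (default 1000, i.e. distances enter the power law in kb).
#' @param size_factors_range Library size factors are drawn log-uniform in
#'   this range and rescaled to unit geometric mean.
#' @param spikes data.frame (`fragment_index`, `log2_effect`): interaction
#'   spikes applied in all samples.
#' @param differential data.frame (`fragment_index`, `condition`,
#'   `log2_effect`): condition-specific effects.
#' @param seed Random seed.
#' @return List of class `fourc_truth`.
#' @export
simulation_truth <- function(A = 5000, gamma = 1.2, B = 20, a = 3, b = 0.05,
                             distance_unit = 1000, size_factors_range = c(0.7, 1.4),
                             spikes = NULL, differential = NULL, seed = 1L) {
  if (gamma <= 0) stop("gamma must be positive (the decay must decrease)")
  structure(list(A = A, gamma = gamma, B = B, a = a, b = b,
                 distance_unit = distance_unit,
                 size_factors_range = size_factors_range,
                 spikes = spikes, differential = differential, seed = seed),
            class = "fourc_truth")
}

#' Simulate a 4C count matrix with known truth
#'
#' Expected counts follow `mu_ij = s_j * (A * (|d_i|/unit)^(-gamma) + B) *
#' 2^(spike_i + diff_{i,cond(j)})`; trans fragments get `mu = s_j * B`; the
#' viewpoint fragment (`d = 0`) gets a large pile-up mean. Counts are NB
#' with dispersion `a/mu + b` (Poisson when `a = b = 0`).
#'
#' @param d Signed fragment distances (`NA` = trans), e.g. from
#'   [fragment_distances()].
#' @param truth A `fourc_truth` from [simulation_truth()].
#' @param conditions Character vector of condition labels, one per sample.
#' @return List: `counts` (fragments x samples), `mu`, `size_factors`,
#'   `conditions`, `truth`.
#' @export
simulate_counts <- function(d, truth, conditions = c("A", "A", "B", "B")) {
  stopifnot(inherits(truth, "fourc_truth"))
  set.seed(truth$seed)
  ns <- length(conditions)
  sf <- exp(stats::runif(ns, log(truth$size_factors_range[1]),
                         log(truth$size_factors_range[2])))
  sf <- sf / exp(mean(log(sf)))
  base <- ifelse(is.na(d), truth$B,
                 truth$A * pmax(abs(d) / truth$distance_unit, 1e-12)^(-truth$gamma) + truth$B)
  vp <- !is.na(d) & d == 0
  if (any(vp)) {
    base[vp] <- 4 * max(base[!vp], truth$B)
  }
  effect <- matrix(0, length(d), ns)
  if (!is.null(truth$spikes)) {
    effect[truth$spikes$fragment_index + 1L, ] <-
      effect[truth$spikes$fragment_index + 1L, ] + truth$spikes$log2_effect
  }
  if (!is.null(truth$differential)) {
    for (r in seq_len(nrow(truth$differential))) {
      jj <- which(conditions == truth$differential$condition[r])
      i <- truth$differential$fragment_index[r] + 1L
      effect[i, jj] <- effect[i, jj] + truth$differential$log2_effect[r]
    }
  }
  mu <- outer(base, sf) * 2^effect
  alpha <- truth$a / mu + truth$b
  k <- if (truth$a == 0 && truth$b == 0) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / alpha)
  }
  counts <- matrix(as.integer(k), nrow(mu), ns,
                   dimnames = list(NULL, paste0("s", seq_len(ns))))
  list(counts = counts, mu = mu, size_factors = sf,
       conditions = conditions, truth = truth)
}

#' Emit protocol-conforming alignment records (BAM) for simulated counts
#'
#' For each fragment the simulated count is split between the two fragment
#' ends; each read gets the exact 5' terminus and strand the protocol rules
#' require, so [count_reads()] recovers the input counts exactly. An
#' optional fraction of decoy records violating the rules (shifted start or
#' flipped strand) exercises the rejection paths.
#'
#' @param genome Genome (for read sequences and the BAM header).
#' @param fragments Annotated fragment table.
#' @param counts Integer count vector over fragments (one sample).
#' @param protocol `"first_cutter_primer"` or `"second_cutter_primer"`.
#' @param read_length Read length in nt (default 24; reads are clipped at
#'   chromosome boundaries).
#' @param decoy_fraction Decoy records as a fraction of the true records
#'   (default 0).
#' @param bam Output BAM path (without requiring the `.bam` suffix).
#' @param seed Random seed.
#' @return List: `bam` (path), `n_true`, `n_decoy`.
#' @export
simulate_alignments <- function(genome, fragments, counts,
                                protocol = "first_cutter_primer",
                                read_length = 24L, decoy_fraction = 0,
                                bam = tempfile(fileext = ".bam"), seed = 1L) {
  genome <- read_genome(genome)
  set.seed(seed)
  counts <- as.integer(counts)
  stopifnot(length(counts) == nrow(fragments))
  targets <- fragment_end_targets(fragments, protocol)
  left <- targets[targets$end == "left", ]
  right <- targets[targets$end == "right", ]
  li <- match(fragments$index, left$index)
  ri <- match(fragments$index, right$index)
  emittable <- !is.na(li) & !is.na(ri)
  n_left <- stats::rbinom(nrow(fragments), counts, 0.5)
  n_right <- counts - n_left
  rec <- data.frame(
    chrom = rep(c(fragments$chrom[emittable], fragments$chrom[emittable]),
                c(n_left[emittable], n_right[emittable])),
    terminus = rep(c(left$coord[li[emittable]], right$coord[ri[emittable]]),
                   c(n_left[emittable], n_right[emittable])),
    strand = rep(c(left$strand[li[emittable]], right$strand[ri[emittable]]),
                 c(n_left[emittable], n_right[emittable])),
    stringsAsFactors = FALSE)
  n_true <- nrow(rec)
  n_decoy <- round(decoy_fraction * n_true)
  if (n_decoy > 0) {
    pick <- sample(n_true, n_decoy, replace = TRUE)
    dec <- rec[pick, ]
    # decoys violate the rules unambiguously: a pure strand flip at a shared
    # cut site would look like a legitimate read of the neighboring fragment,
    # so flipped decoys are also shifted off the cut coordinate
    flip <- seq_len(n_decoy) %% 2 == 0
    dec$strand[flip] <- ifelse(dec$strand[flip] == "+", "-", "+")
    dec$terminus[flip] <- dec$terminus[flip] - 5L
    dec$terminus[!flip] <- dec$terminus[!flip] + 3L
    rec <- rbind(rec, dec)
  }
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  plus <- rec$strand == "+"
  len <- chrom_len[rec$chrom]
  # clip the read at the chromosome boundary on the non-terminus side only;
  # a record whose 5' terminus itself falls outside the chromosome (possible
  # for shifted decoys) is dropped, never moved
  start0 <- ifelse(plus, rec$terminus, pmax(rec$terminus - read_length, 0L))
  end0 <- ifelse(plus, pmin(rec$terminus + read_length, len), rec$terminus)
  ok <- ifelse(plus, rec$terminus >= 0 & rec$terminus < len,
               rec$terminus > 0 & rec$terminus <= len) & end0 > start0
  rec <- rec[ok, ]; start0 <- start0[ok]; end0 <- end0[ok]
  # read sequences from the reference (reverse-complemented on the minus
  # strand) so that the records are fully valid SAM
  seqs <- character(nrow(rec))
  for (chrom in unique(rec$chrom)) {
    cs <- as.character(genome[[chrom]])
    sel <- rec$chrom == chrom
    seqs[sel] <- substring(cs, start0[sel] + 1L, end0[sel])
  }
  minus <- rec$strand == "-"
  if (any(minus)) {
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  }
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome), chrom_len))
  lines <- sprintf("read%d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                   seq_len(nrow(rec)), ifelse(minus, 16L, 0L), rec$chrom,
                   start0 + 1L, end0 - start0, seqs)
  sam <- tempfile(fileext = ".sam")
  writeLines(c(header, lines), sam)
  dest <- sub("\\.bam$", "", bam)
  out <- Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  list(bam = out, n_true = n_true, n_decoy = nrow(rec) - n_true)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
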