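# Shared fixtures, built in code. The toy dataset (genome, fragment
# reference, viewpoint, distances) is built once per test run and memoized.

dpnII <- enzyme("DpnII", "GATC", 0L)
nlaIII <- enzyme("NlaIII", "CATG", 4L)

.toy_cache <- new.env(parent = emptyenv())

toy_dataset <- function() {
  if (!is.null(.toy_cache$ds)) return(.toy_cache$ds)
  toy <- make_toy_genome(n_chrom = 2, length = 60000, site_spacing = 1000,
                         seed = 3)
  frags <- annotate_ends(digest_genome(toy$genome, dpnII), toy$genome, nlaIII)
  cis <- frags[frags$chrom == "chr1", ]
  vprow <- cis[which.min(abs(cis$midpoint - 30000)), ]
  gseq <- as.character(toy$genome[[1]])
  primer <- substr(gseq, vprow$start + 11, vprow$start + 30)
  vp <- locate_viewpoint(primer, toy$genome, frags, name = "vp1")
  ds <- list(toy = toy, genome = toy$genome, fragments = frags,
             primer = primer, viewpoint = vp,
             d = fragment_distances(frags, vp))
  .toy_cache$ds <- ds
  ds
}

# Distances emulating a dense cis fragment grid around a viewpoint:
# 1000 fragments per side at 500 nt spacing, plus the viewpoint fragment.
grid_distances <- function(n_side = 1000, spacing = 500) {
  c(0, -(seq_len(n_side)) * spacing, seq_len(n_side) * spacing)
}

# Write a BAM from explicit alignment records (0-based start, half-open end).
make_test_bam <- function(records, chrom_lengths) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  lines <- sprintf("q%d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                   seq_len(nrow(records)),
                   ifelse(records$strand == "-", 16L, 0L),
                   records$chrom, records$start0 + 1L,
                   records$end0 - records$start0,
                   strrep("A", records$end0 - records$start0))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(header, lines), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

# log2 effect that shifts a fragment with expected base count `base_mu` by
# `n_sigma` residual-scale units on the variance-stabilized scale (the
# plateau sd of the transform is sqrt(b)/ln 2); at large counts this is
# n_sigma * sqrt(b)/ln2 log2 units, at low counts proportionally more.
spike_log2_effect <- function(base_mu, n_sigma = 6, a = 3, b = 0.05) {
  params <- structure(list(a = a, b = b, size_factors = 1),
                      class = "fourc_vst")
  sigma <- sqrt(b) / log(2)
  target <- inverse_vst(vst(base_mu, params) + n_sigma * sigma, params)
  log2(target / base_mu)
}

decay_base_mu <- function(d, truth) {
  ifelse(is.na(d), truth$B,
         truth$A * (abs(d) / truth$distance_unit)^(-truth$gamma) + truth$B)
}
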