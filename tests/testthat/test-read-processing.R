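write_test_fastq <- function(seqs, path = tempfile(fileext = ".fastq")) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- paste0("read", seq_along(seqs))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(
                                strrep("I", nchar(seqs))))
  path
}

test_that("demultiplexing assigns by primer prefix and trims it", {
  primers <- c(vp1 = "ACGTACGTAC", vp2 = "TTGGCCAATT")
  reads <- c(paste0("ACGTACGTAC", "GGGGGGGG"),    # exact vp1
             paste0("TTGGCCAATT", "CCCCCCCC"),    # exact vp2
             paste0("ACGAACGTAC", "AAAAAAAA"),    # 1 mismatch in vp1
             strrep("T", 18))                     # no primer
  fq <- write_test_fastq(reads)
  out <- tempfile()

  tally0 <- demultiplex(fq, primers, max_mismatch = 0, outdir = out)
  expect_equal(tally0$reads[tally0$viewpoint == "vp1"], 1L)
  expect_equal(tally0$reads[tally0$viewpoint == "undetermined"], 2L)
  vp1 <- Biostrings::readDNAStringSet(file.path(out, "vp1.fastq"), format = "fastq")
  expect_equal(as.character(vp1[[1]]), "GGGGGGGG")

  tally1 <- demultiplex(fq, primers, max_mismatch = 1, outdir = tempfile())
  expect_equal(tally1$reads[tally1$viewpoint == "vp1"], 2L)
  expect_equal(tally1$reads[tally1$viewpoint == "undetermined"], 1L)

  expect_error(demultiplex(fq, c(a = "ACGT", b = "ACGTACGT"), outdir = out),
               "prefix")
})

test_that("trim-rescue truncates at the cut position of the first site", {
  nla0 <- enzyme("NlaIII", "CATG", 0L)
  expect_equal(trim_to_second_site("AAAATTTTCATGGGGG", nla0, min_length = 5),
               "AAAATTTT")
  expect_equal(trim_to_second_site("AAAATTTTGGGG", nla0), "AAAATTTTGGGG")
  # read beginning with the site truncates to empty -> dropped
  expect_true(is.na(trim_to_second_site("CATGAAAA", nla0)))
  # cut offset shifts the truncation point
  nla4 <- enzyme("NlaIII", "CATG", 4L)
  expect_equal(trim_to_second_site("AATTCATGGG", nla4, min_length = 4),
               "AATTCATG")
})

test_that("fragment-end counting follows protocol start and strand rules", {
  frags <- data.frame(index = 0L, chrom = "chr1", start = 100L, end = 200L,
                      midpoint = 150, left_end_length = 30L,
                      right_end_length = 30L, has_second_site = TRUE,
                      left_end_valid = TRUE, right_end_valid = TRUE,
                      is_valid = TRUE)
  recs <- data.frame(
    chrom = "chr1",
    start0 = c(100L, 176L, 150L, 76L),
    end0   = c(124L, 200L, 174L, 100L),
    strand = c("+", "-", "+", "-"))
  # (+,start 100) left hit; (-,end 200) right hit; (+,150) not at cut site;
  # (-, 5' terminus 100) right coordinate but wrong strand
  bam <- make_test_bam(recs, c(chr1 = 400L))
  res <- count_reads(bam, frags, protocol = "first_cutter_primer")
  expect_equal(res$counts, 2L)
  expect_equal(res$stats$assigned_valid, 2L)
  expect_equal(res$stats$rejected_not_at_cut_site, 1L)
  expect_equal(res$stats$rejected_wrong_strand, 1L)

  # second-cutter protocol: cuts at 130 and 170; left end wants (-, end 130),
  # right end wants (+, start 170)
  recs2 <- data.frame(chrom = "chr1",
                      start0 = c(106L, 170L, 100L),
                      end0   = c(130L, 194L, 124L),
                      strand = c("-", "+", "+"))
  bam2 <- make_test_bam(recs2, c(chr1 = 400L))
  res2 <- count_reads(bam2, frags, protocol = "second_cutter_primer")
  expect_equal(res2$counts, 2L)
  # the (+,100) read matches the first-cutter rule, not this protocol
  expect_equal(res2$stats$rejected_not_at_cut_site +
                 res2$stats$rejected_wrong_strand, 1L)

  # slack rescues off-by-one termini
  recs3 <- data.frame(chrom = "chr1", start0 = 101L, end0 = 125L, strand = "+")
  bam3 <- make_test_bam(recs3, c(chr1 = 400L))
  expect_equal(count_reads(bam3, frags)$counts, 0L)
  expect_equal(count_reads(bam3, frags, slack = 1L)$counts, 1L)

  # unknown chromosome in the BAM is an error naming it
  bam4 <- make_test_bam(data.frame(chrom = "chrX", start0 = 0L, end0 = 24L,
                                   strand = "+"), c(chrX = 100L))
  expect_error(count_reads(bam4, frags), "chrX")
})

test_that("simulated alignments round-trip through counting exactly", {
  ds <- toy_dataset()
  set.seed(21)
  counts <- rpois(nrow(ds$fragments), 30)
  al <- simulate_alignments(ds$genome, ds$fragments, counts, seed = 7)
  res <- count_reads(al$bam, ds$fragments)
  valid <- ds$fragments$is_valid
  expect_identical(res$counts[valid], counts[valid])
  # conservation: every record is either assigned or tallied as rejected
  s <- res$stats
  expect_equal(s$assigned_valid + s$assigned_invalid +
                 s$rejected_wrong_strand + s$rejected_not_at_cut_site,
               s$processed)
})

test_that("decoy records are rejected without perturbing the counts", {
  ds <- toy_dataset()
  set.seed(22)
  counts <- rpois(nrow(ds$fragments), 20)
  al <- simulate_alignments(ds$genome, ds$fragments, counts,
                            decoy_fraction = 0.2, seed = 8)
  expect_gt(al$n_decoy, 0)
  res <- count_reads(al$bam, ds$fragments)
  valid <- ds$fragments$is_valid
  expect_identical(res$counts[valid], counts[valid])
  expect_equal(res$stats$rejected_wrong_strand +
                 res$stats$rejected_not_at_cut_site, al$n_decoy)

  # protocol mismatch rejects every read
  res_sw <- count_reads(al$bam, ds$fragments, protocol = "second_cutter_primer")
  expect_true(all(res_sw$counts == 0))
})

test_that("valid-fragment QC fraction is computed and warns when low", {
  expect_equal(qc_valid_fraction(90, 100), 0.9)
  expect_warning(f <- qc_valid_fraction(0, 100), "valid fragments")
  expect_equal(f, 0)
})
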