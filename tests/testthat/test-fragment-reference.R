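test_that("in-silico digestion cuts at recognition sites on both strands", {
  fr <- digest_genome(c(chr1 = "AAAAGATCCCGATCTTTT"), dpnII)
  expect_equal(fr$start, c(0L, 4L, 10L))
  expect_equal(fr$end, c(4L, 10L, 18L))
  expect_equal(fr$midpoint, c(2, 7, 14))

  # no site: one fragment spanning the chromosome
  fr0 <- digest_genome(c(chr1 = "AAAAAA"), dpnII)
  expect_equal(nrow(fr0), 1L)
  expect_equal(c(fr0$start, fr0$end), c(0L, 6L))

  # cut at coordinate 0: empty terminal interval is dropped
  fr2 <- digest_genome(c(chr1 = "GATCGATC"), dpnII)
  expect_equal(fr2$start, c(0L, 4L))
  expect_equal(fr2$end, c(4L, 8L))

  expect_error(digest_genome(c(chr1 = ""), dpnII), "empty")
})

test_that("digestion counts overlapping occurrences and ignores N bases", {
  # AAAA / overlapping AAAAA gives cuts at 4,5,6 (occurrences at 4,5,6)
  enzA <- enzyme("polyA", "AAAA", 0L)
  fr <- digest_genome(c(chr1 = "GGGGAAAAAAGG"), enzA)
  expect_equal(sort(unique(fr$start)), c(0L, 4L, 5L, 6L))
  # N never matches a site
  frN <- digest_genome(c(chr1 = "AAAAGANCCCTTTT"), enzyme("x", "GATC", 0L))
  expect_equal(nrow(frN), 1L)
})

test_that("fragments tile each chromosome exactly on random toy genomes", {
  for (seed in 1:3) {
    toy <- make_toy_genome(n_chrom = 2, length = 15000, site_spacing = 800,
                           seed = seed)
    fr <- digest_genome(toy$genome, dpnII)
    for (chrom in c("chr1", "chr2")) {
      f <- fr[fr$chrom == chrom, ]
      f <- f[order(f$start), ]
      expect_equal(sum(f$end - f$start), 15000)
      expect_true(all(f$start[-1] == f$end[-nrow(f)]))   # adjacent, disjoint
    }
    # index is a 0-based ordinal over the whole table
    expect_equal(fr$index, seq_len(nrow(fr)) - 1L)
  }
})

test_that("digestion is strand-symmetric for non-palindromic enzymes", {
  set.seed(9)
  n <- 5000
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  enz <- enzyme("asym", "GACGC", 1L)   # non-palindromic site
  fwd <- digest_genome(c(chr1 = s), enz)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rev <- digest_genome(c(chr1 = rc), enz)
  # boundaries of the reverse-complemented genome are mirror images
  mirrored <- sort(n - fwd$end)
  expect_equal(sort(rev$start), mirrored)
})

test_that("fragment-end annotation applies the one-valid-end rule", {
  # fragment [0, 100): second-enzyme cuts at 8 and 75 -> ends 8 and 25
  chr <- paste0(strrep("A", 4), "CATG", strrep("A", 63), "CATG", strrep("A", 25))
  fr <- annotate_ends(digest_genome(c(chr1 = chr), dpnII),
                      c(chr1 = chr), nlaIII, min_end_length = 20)
  expect_equal(fr$left_end_length, 8L)
  expect_equal(fr$right_end_length, 25L)
  expect_false(fr$left_end_valid)
  expect_true(fr$right_end_valid)
  expect_true(fr$is_valid)

  # no second site at all
  fr0 <- annotate_ends(digest_genome(c(chr1 = strrep("A", 50)), dpnII),
                       c(chr1 = strrep("A", 50)), nlaIII)
  expect_false(fr0$has_second_site)
  expect_false(fr0$is_valid)
  expect_true(is.na(fr0$left_end_length))

  # both ends below threshold: 8 and 12
  chr2 <- paste0(strrep("A", 4), "CATG", strrep("A", 16), "CATG", strrep("A", 12))
  fr2 <- annotate_ends(digest_genome(c(chr1 = chr2), dpnII),
                       c(chr1 = chr2), nlaIII, min_end_length = 20)
  expect_equal(fr2$left_end_length, 8L)
  expect_equal(fr2$right_end_length, 12L)
  expect_false(fr2$is_valid)
})

test_that("validity is monotone in the end-length threshold", {
  ds <- toy_dataset()
  thresholds <- c(5, 20, 50, 120)
  valid_sets <- lapply(thresholds, function(t) {
    annotate_ends(digest_genome(ds$genome, dpnII), ds$genome, nlaIII,
                  min_end_length = t)$is_valid
  })
  for (i in seq_len(length(thresholds) - 1)) {
    # raising the threshold never turns an invalid fragment valid
    expect_true(all(valid_sets[[i]] | !valid_sets[[i + 1]]))
  }
})

test_that("viewpoint location searches both strands and detects ambiguity", {
  ds <- toy_dataset()
  vp <- locate_viewpoint(ds$primer, ds$genome, ds$fragments)
  expect_s3_class(vp, "fourc_viewpoint")
  row <- ds$fragments[ds$fragments$index == vp$fragment_index, ]
  expect_true(row$chrom == "chr1")

  # reverse complement of the primer finds the same fragment
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ds$primer)))
  vp_rc <- locate_viewpoint(rc, ds$genome, ds$fragments)
  expect_equal(vp_rc$fragment_index, vp$fragment_index)

  expect_error(locate_viewpoint(strrep("T", 25), ds$genome, ds$fragments),
               "not found")
  expect_error(locate_viewpoint("ACGTACGTACGT", ds$genome, ds$fragments),
               "too short")
  # a primer occurring in two fragments is ambiguous
  g2 <- c(chrA = paste0("TTACGTTGCAATGCTGATTG", strrep("A", 10), "GATC",
                        strrep("C", 10), "TTACGTTGCAATGCTGATTG"))
  fr2 <- digest_genome(g2, dpnII)
  expect_error(locate_viewpoint("TTACGTTGCAATGCTGATTG", g2, fr2), "ambiguous")
})

test_that("distances are signed midpoint differences, undefined in trans", {
  fr <- digest_genome(c(chr1 = "AAAAGATCCCGATCTTTT", chr2 = strrep("A", 30)),
                      dpnII)
  fr$is_valid <- TRUE
  vp <- structure(list(name = "v", chrom = "chr1", fragment_index = 1L,
                       midpoint = 7), class = "fourc_viewpoint")
  d <- fragment_distances(fr, vp)
  expect_equal(d[1:3], c(-5, 0, 7))
  expect_true(is.na(d[4]))   # chr2 fragment is trans
})
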