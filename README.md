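# fourc

Analysis of circularized chromosome conformation capture (4C-seq)
experiments in R: from a reference genome and aligned reads to called
viewpoint interactions and differential contacts between conditions.

4C-seq measures how often one genomic region — the *viewpoint*, defined by
an inverse-PCR primer — touches the rest of the genome. Read counts per
restriction fragment decay smoothly with genomic distance from the
viewpoint and flatten into background; specific chromatin interactions
(e.g. enhancer–promoter loops) sit on top of that trend as localized
peaks. `fourc` separates the two and adds replicate-aware differential
testing:

1. **Fragment reference** — cut the genome in silico with the first
   restriction enzyme, annotate fragment ends with the second, flag valid
   fragments, and locate the viewpoint fragment from its primer.
2. **Counting** — assign aligned reads (BAM) to fragment ends only when
   their 5' terminus sits at the expected cut site with the
   protocol-defined orientation; everything else is tallied by rejection
   reason for QC.
3. **Variance stabilization** — transform counts `k` with
   `v(q) = log2[(1 + a + 2bq + 2*sqrt(bq(1 + a + bq))) / (4b)]`,
   `q = k/s_j`, the closed form that stabilizes NB counts with dispersion
   trend `alpha(mu) = a/mu + b`; `a`, `b` and the size factors `s_j` are
   fitted per viewpoint.
4. **Decay trend** — fit a smooth monotone non-increasing curve `f_j(d)`
   of the transformed counts against `log10 |d|` (I-spline basis,
   non-positive coefficients, roughness penalty), symmetric around the
   viewpoint or separately per side.
5. **Interaction calling** — z-scores
   `z_ij = (v(k_ij) - f_j(d_i)) / sigma_j` with
   `sigma_j = 1.4826 * MAD` of the residuals; one-sided normal P-values,
   Benjamini–Hochberg adjustment per sample, and a call when `z > 3` in
   all replicates of a condition and adjusted `P < 0.01` in at least one.
6. **Differential contacts** — per-fragment normalization factors
   `n_ij = v^-1(f_j(d_i))`, scaled to unit geometric mean across samples,
   enter a negative-binomial GLM as offsets; dispersions are shrunk toward
   a fitted mean–dispersion trend (empirical Bayes) and condition effects
   are tested with a Wald statistic.

A synthetic-data generator (`make_toy_genome`, `simulate_counts`,
`simulate_alignments`) produces toy genomes with planted restriction
sites, NB counts with known decay/dispersion/spikes, and
protocol-conforming BAMs, so the full pipeline runs and is tested without
any external data.

## Worked example

A 150 kb toy chromosome, DpnII/NlaIII digestion, one central viewpoint,
two conditions with two replicates, and three planted interactions
(fragments 60, 170, 210 at 2.5 log2 over the trend):

```r
library(fourc)

toy <- make_toy_genome(n_chrom = 1, length = 150000, site_spacing = 600,
                       seed = 42)
dpnII  <- enzyme("DpnII", "GATC", 0)
nlaIII <- enzyme("NlaIII", "CATG", 4)
frags <- annotate_ends(digest_genome(toy$genome, dpnII), toy$genome, nlaIII)
vprow <- frags[which.min(abs(frags$midpoint - 75000)), ]
primer <- substr(as.character(toy$genome[[1]]), vprow$start + 11, vprow$start + 30)
vp <- locate_viewpoint(primer, toy$genome, frags, name = "demo")
d <- fragment_distances(frags, vp)

spikes <- data.frame(fragment_index = c(60, 170, 210), log2_effect = 2.5)
sim <- simulate_counts(d, simulation_truth(spikes = spikes, seed = 42),
                       conditions = c("A", "A", "B", "B"))
counts <- sapply(1:4, function(j) {
  bam <- simulate_alignments(toy$genome, frags, sim$counts[, j], seed = j)$bam
  count_reads(bam, frags)$counts
})

an <- analyze_counts(counts, d, conditions = c("A", "A", "B", "B"))
an$vst_params
#> <VST: alpha(mu) = 2.54/mu + 0.04693, 4 size factors>
round(an$sigma, 3)
#> [1] 0.349 0.304 0.346 0.299
called <- which(an$tested)[rowSums(an$calls) > 0]
data.frame(fragment = frags$index[called],
           distance_kb = round(d[called] / 1000, 1),
           z_rep1 = round(an$z[match(called, which(an$tested)), 1], 2),
           padj_rep1 = signif(an$padj[match(called, which(an$tested)), 1], 2))
#>   fragment distance_kb z_rep1 padj_rep1
#> 1       60       -38.5   5.02   1.9e-05
#> 2      170        27.5   7.84   5.0e-13
#> 3      210        51.5   5.16   1.4e-05
```

The fitted dispersion trend (`2.54/mu + 0.047`) recovers the generating
values (`3/mu + 0.05`); the per-sample residual scales sit at the
theoretical VST plateau `sqrt(b)/ln 2 ~ 0.32`; and the three called
fragments are exactly the three planted interactions, with no false
positives among the ~200 tested fragments.

`plot_decay_fit(an$v, an$decay, d[an$kept], j = 1, sigma = an$sigma[1])`
draws the per-sample profile with the monotone fit and the fit + 3σ band;
`export_tracks()` writes per-sample bedGraph (or bigWig) tracks for genome
browsers.

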