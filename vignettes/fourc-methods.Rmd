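---
title: "Statistical methods for 4C-seq interaction calling with fourc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for 4C-seq interaction calling with fourc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourc)
```

## The problem

Circularized chromosome conformation capture (4C) measures how often a fixed
genomic region — the *viewpoint* — contacts every other region of the
genome. After crosslinking, two rounds of restriction digestion, ligation,
circularization and inverse PCR, sequencing reads accumulate on restriction
fragments in proportion to their contact frequency with the viewpoint. Two
features dominate any 4C profile: a strong, smooth decrease of signal with
genomic distance from the viewpoint, flattening into a constant background,
and — superimposed on it — localized peaks reflecting specific chromatin
interactions (for example enhancer–promoter loops). The analytical task is
to separate the two: to call fragments whose signal stands out from the
distance trend, with false-discovery-rate control, and to test whether
contact frequencies differ between biological conditions using replicate
information.

`fourc` implements this as a pipeline: an in-silico restriction-fragment
reference, protocol-aware read counting onto fragment ends, a
variance-stabilizing transformation (VST) for negative-binomial counts, a
smooth monotone fit of the distance decay, z-score-based peak calling, and
a negative-binomial GLM Wald test for differential contacts.

## Fragment reference and read counting

The genome is cut in silico at every occurrence of the first enzyme's
recognition sequence (both strands; for the palindromic 4-cutters typical
of 4C the two strands coincide). Fragments are the intervals between
consecutive cut sites; the terminal interval of each chromosome is kept but
has only one true restriction end. Coordinates are 0-based, half-open
throughout; BED exports share this convention.

*Fragment ends* are the regions between a fragment boundary and the nearest
second-enzyme site inside the fragment. A fragment is *valid* — usable for
analysis — if it contains a second-enzyme site and at least one end is at
least `min_end_length` (default 20 nt) long; a single short end does not
invalidate a fragment whose other end passes. This mirrors the molecular
reality that only fragments cut by both enzymes circularize and amplify
efficiently.

Reads are assigned to fragment ends only if they look like genuine 4C
products: the 5' alignment terminus must sit exactly at the expected cut
coordinate (a `slack` parameter, default 0 nt, absorbs aligner round-off if
needed) and the read must point in the protocol-defined direction. With a
primer at the first-cutter site, reads start at the fragment boundary and
point into the fragment; with a primer at the second-cutter site, reads
start at the interior second-enzyme cut and point outward. For minus-strand
alignments the 5' terminus is the (half-open) alignment end. Both ends of a
fragment are summed. Everything else is tallied by rejection reason, and
the fraction of aligned reads landing on valid fragments is reported as a
QC number (healthy libraries sit around 70–95%).

## Variance stabilization

Counts span orders of magnitude: on the raw scale the viewpoint-proximal
fragments dominate the variance; on the log scale the distal low-count
fragments do. Neither is acceptable for residual-based peak calling. We
assume NB counts whose dispersion follows the two-parameter trend

$$\alpha(\mu) = \frac{a}{\mu} + b,$$

so that $\mathrm{Var}(K) = (1+a)\,\mu + b\,\mu^2$. The trend is fitted
per viewpoint on the count-filtered fragments: per-fragment
method-of-moments dispersions from size-factor-normalized counts, then an
iterated least-squares fit on the design $(1/\mu, 1)$ that drops the top
and bottom 5% of residuals each iteration (at most 10 iterations,
convergence tolerance $10^{-6}$; $a$ is clamped at 0 and $b$ at
$10^{-8}$). Size factors are median-of-ratios, rescaled to unit geometric
mean. The transformation is the closed-form antiderivative of
$1/\sqrt{\mathrm{Var}(\mu)}$ in log2 units,

$$v(q) = \log_2 \frac{1 + a + 2bq + 2\sqrt{bq(1+a+bq)}}{4b}, \qquad
q = k_{ij}/s_j ,$$

which is strictly increasing, finite at zero
($v(0) = \log_2\!\frac{1+a}{4b}$), and asymptotically log2-like
($v(2q) - v(q) \to 1$). By the delta method the stabilized standard
deviation plateaus at $\sqrt{b}/\ln 2$ across the whole dynamic range. The
family admits an exact algebraic inverse,
$q = (y - (1+a))^2 / (4by)$ with $y = 4b\,2^{u}$, so back-transforming
fitted values (needed for the differential normalization factors) is exact
to machine precision rather than relying on numerical root finding.

Two honest caveats, verified by simulation in the test suite: first,
stabilization is a second-moment property — the transformed counts keep a
mild negative skew (approximately log-gamma with shape $1/b$), so the far
left tail of null z-scores is heavier than Gaussian even though the right
tail, the one used for one-sided peak calling, is well calibrated. Second,
at means below a few tens of counts discreteness limits how flat the
sd-versus-mean curve can be; the default median-count filter keeps the
analysis out of that regime.

## The monotone distance-decay fit

The expected transformed signal is modeled as a smooth, monotone
non-increasing function $f_j(d)$ of $\log_{10}|d|$, where $d$ is the
signed distance between fragment midpoints and the viewpoint midpoint.
Monotonicity encodes the physics (unspecific contact frequency decays with
genomic distance); smoothness avoids absorbing genuine peaks into the
trend. We use an I-spline basis — cumulative sums of an order-4 B-spline
partition of unity, each basis function increasing from 0 to 1 — with
knots at the deciles of the fitted $\log_{10}|d|$ values, a free
intercept, and coefficients constrained non-positive, solved by
non-negative least squares after a sign flip. A second-difference roughness
penalty $\lambda$ (default 1) on the spline coefficients, scaled by the
number of data points so that the data/penalty balance does not depend on
sample size, controls wiggliness. The curve extrapolates as a constant
plateau beyond the largest fitted distance.

`symmetric` mode pools both sides of the viewpoint ($f_j(d) = f_j(-d)$
exactly); `per_side` mode fits left and right independently — useful at
domain boundaries — and falls back to symmetric (with a warning) when a
side has fewer than 30 fragments. Trans-chromosomal fragments have no
distance; they are excluded from the fit and, downstream, compared against
the plateau value $f_j(\infty)$ (in `per_side` mode, the mean of the two
sides' boundary values). Whether trans fragments should be z-scored at all
is a judgment call; the plateau convention treats them as
"infinitely far" background, which is conservative for peak calling.

## Peak calling

The analysis order is: first drop fragments with a median count below 40
across samples (noise floor), then mask the viewpoint-proximal zone, then
fit VST parameters and the decay on what remains. The masking heuristic
walks outward from the viewpoint over the kept fragments, separately per
side, and masks everything up to (but not including) the first fragment
where the mean transformed signal increases between successive fragments —
the point where the monotone pile-up around the viewpoint ends; a hard cap
(default 20 fragments per side) bounds the zone on pathological monotone
profiles. The viewpoint fragment itself is always masked.

Residuals $r_{ij} = v(k_{ij}) - f_j(d_i)$ are standardized per sample by a
robust scale, $\sigma_j = 1.4826 \cdot \mathrm{MAD}_i(r_{ij})$ (median
centered). The 1.4826 normal-consistency constant matters: the z-scores
$z_{ij} = r_{ij}/\sigma_j$ are converted to one-sided normal P-values
$p_{ij} = 1 - \Phi(z_{ij})$, and those are only calibrated if the null
z-scores have unit scale on the normal's terms. P-values are adjusted by
Benjamini–Hochberg per sample, the family being that sample's tested
(kept, unmasked) fragments; the family choice is per viewpoint because
that is the unit at which users interpret a contact profile. A fragment is
called an interaction for a condition when $z > 3$ in **all** replicates
of the condition and the adjusted P-value is below 0.01 in **at least
one** — the conjunction makes calls robust to single-replicate artifacts
while the FDR clause controls error rates. With a single replicate the
rule degenerates and a warning is emitted.

## Differential contacts

Comparisons between conditions work on raw counts with the fitted decay
carried as per-fragment, per-sample normalization factors

$$n_{ij} = \frac{v^{-1}(f_j(d_i))}
{\left(\prod_{j'=1}^{J} v^{-1}(f_{j'}(d_i))\right)^{1/J}},$$

so each sample's distance dependence (and library size, which the inverse
transform includes) becomes a multiplicative GLM offset while the
per-fragment scale cancels — the geometric mean across samples is 1 for
every fragment by construction (asserted to $10^{-8}$). Back-transformed
values at the transform's lower boundary are floored at $10^{-3}$ counts
to keep the factors strictly positive. Note the factors are only defined
up to a global constant; inference is exactly invariant under global
rescaling, while rescaling a single sample's factors genuinely changes its
effective exposure and therefore the estimates — that is the model working
as intended, not an invariance.

Testing uses a per-fragment NB GLM with log link, mean
$\mu_{ij} = \exp(x_j^\top\beta)\, n_{ij}$, and a single condition factor.
Dispersion estimation follows an empirical-Bayes recipe: (1) per-fragment
dispersion maximum likelihood with the per-condition means profiled out
and a Cox–Reid adjustment $-\tfrac12 \log\det(X^\top W X)$ (without it the
profiled MLE is biased low by roughly $(m-p)/m$ and the Wald test becomes
anticonservative — measured null type-I error up to 12% at nominal 1% on
2v2 designs); (2) the robust $a/\mu + b$ trend refitted to the MLEs;
(3) the final estimate is the mode of the posterior combining the
likelihood with a log-normal prior centered on the trend, whose variance
is the observed spread of log MLEs around the trend minus the expected
sampling variance (approximated by $\psi_1((m-p)/2)$), floored at
$0.25^2$. The one-dimensional optimizations run as vectorized ternary
searches on $\log\alpha \in [\log 10^{-8}, \log 30]$ (40 iterations,
resolving $\alpha$ to far below the prior width) across all fragments at
once.

The Wald statistic is $\hat\beta_c / \mathrm{SE}$ with standard errors
from the expected (Fisher) information, IRLS tolerance $10^{-8}$, at most
100 iterations; observed information would differ slightly, and the
expected version pairs naturally with the IRLS weights. Two-sided normal
P-values are BH-adjusted per viewpoint across the tested fragments. No
fold-change shrinkage is applied. Fragments with a condition entirely at
zero are reported with their (large) boundary fold change and flagged
`separated`; non-convergent fits are flagged and excluded from the
adjustment. Differential fragments (adjusted P < 0.01 by default) are
cross-referenced with the interaction calls of the relevant condition.

## The synthetic-data generator

The generator emulates the features of real 4C data the method actually
relies on: `make_toy_genome` plants first-cutter sites at jittered spacing
and a second-cutter site inside each fragment on an otherwise site-free
background (accidental chimeric occurrences created by planting are
repaired locally, so the digestion oracle is the planting list itself);
`simulate_counts` draws NB counts around
$\mu_{ij} = s_j\,(A\,(|d_i|/\text{unit})^{-\gamma} + B)\cdot
2^{\text{spike}_i + \text{diff}_{i,\text{cond}(j)}}$; and
`simulate_alignments` emits BAM records whose 5' termini and strands
satisfy the protocol rules exactly, plus an optional fraction of
rule-violating decoys for testing the rejection paths.

Defaults are chosen once to represent a realistic single-viewpoint
experiment and are used unchanged throughout the tests: amplitude
$A = 5000$, exponent $\gamma = 1.2$, background $B = 20$ expected counts,
dispersion trend $3/\mu + 0.05$, library-size factors log-uniform in
[0.7, 1.4], 4 samples in 2 conditions, fragments every ~500 nt. The
distance enters the power law in kb (`distance_unit = 1000`): with these
amplitudes that places the count-filter boundary around 100 kb from the
viewpoint, the scale at which long-range interactions are reported in
compact genomes. The power-law-plus-background family matches the
qualitative shape the method assumes (monotone decay into flat noise); the
method itself is non-parametric in the trend, so any monotone family would
exercise the same code paths. Spike effects are specified in residual-scale
units: a "+6σ" spike shifts $v$ by $6\sqrt{b}/\ln 2$, which at low counts
corresponds to a larger fold change than the large-count limit — fixtures
compute the per-fragment multiplicative effect through the transform.

What the generator does **not** model: PCR duplicates, sequencing error,
mappability and GC biases, undigested or self-ligated fragments, and any
real spatial genome organization (domains, compartments). Passing tests
therefore demonstrate the statistical machinery is correct and calibrated
under its own assumptions, not that those assumptions hold in any
particular laboratory dataset.

## Numerical choices and problem sizes

Calibration checks in the test suite run at sizes chosen to make
Monte-Carlo error small relative to the tolerances: 200 null simulations
of 2000 cis fragments × 4 samples for FDR control of the calling rule;
200 replicates of 400 fragments × 6 samples for the Wald type-I error;
2000 fragments for fold-change recovery (planted 4-fold changes recovered
within ±0.2 log2 units); four 300 kb genomes for end-to-end spike
recovery through BAM counting. The decay fit resolves its monotonicity
contract on a 1000-point grid at tolerance $10^{-9}$; VST round trips are
exact to $10^{-15}$ and asserted at $10^{-6}$.

Degenerate inputs are handled explicitly: counts constant across samples
give a zero dispersion trend (clamped at the $10^{-8}$ floor); a constant
transformed signal fits a constant trend; signal increasing with distance
fits the best constant (the monotone projection); an all-zero residual
scale raises an error rather than producing infinite z-scores; a missing
second-enzyme site flags the fragment invalid rather than dropping it from
the reference.

## Known limitations

* One condition factor; no multi-factor designs or continuous covariates.
* Calling operates per fragment; no multi-scale/windowed aggregation, so
  very broad contact changes are better served by domain-level methods.
* The left tail of the null z-distribution is heavier than Gaussian (see
  the variance-stabilization section); depletion calling (negative z)
  would need a calibrated left tail and is deliberately not offered.
* Trans-chromosomal z-scores depend on the plateau convention; treat trans
  calls as exploratory.
* Bias correction for fragment length, GC content or mappability is out of
  scope; in differential comparisons per-fragment biases largely cancel.
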