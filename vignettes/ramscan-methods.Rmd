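---
title: "Calling regions of altered methylation from enrichment sequencing: models, filters and design choices"
author: "ramscan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling regions of altered methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramscan)
```

## The measurement model

Methylation-enrichment sequencing (MethylPlex/MBD-style chemistry) captures
methylated, GC-rich DNA, so the local density of aligned reads is a proxy
for regional methylation. `ramscan` works entirely at the level of read
*start* positions: reads are short and single-ended, a window is credited
whenever a read starts inside it, and read extent plays no role. The genome
is tiled into 100 bp windows shifted by 50 bp, so each interior position
belongs to exactly two windows; on the bundled 25 canonical hg19 chromosome
lengths that is `r format(countTiledWindows(hg19GenomeSpec()), big.mark =
",")` windows. Partial terminal windows are dropped so that every window
has identical width — downstream logic (midpoint TSS distances, per-window
NB means) relies on constant width. Coordinates are 0-based half-open on
disk (BED) and 1-based closed in memory (`GRanges`); `rtracklayer` performs
the shift.

Windows with adequate coverage — strictly more than 20 reads in at least 3
samples — enter testing. The threshold is strict (`> 20`, not `>= 20`) and
the filter is idempotent.

## The count model and the exact test

Counts for window $w$ and sample $i$ are modelled as negative binomial
with mean $\mu_{wg(i)}$ and dispersion $\phi_w$:
$\operatorname{Var} = \mu + \phi \mu^2$. Samples are first *equalised*:
counts are linearly scaled to the geometric mean of the effective library
sizes (library size × normalisation factor). Methylation windows use plain
library-size normalisation by default; TMM (trimmed mean of M-values, 30%
M-trim, 5% A-trim, upper-quartile reference, via `edgeR::calcNormFactors`)
is the default for the RNA-seq branch and available for windows by
configuration. The rationale: genome-wide methylation windows include the
signal regions themselves, so a trimmed-mean correction is the appropriate
tool only where composition bias is expected — expression data — while the
window branch keeps the simplest normalisation that the within-group
consistency filter (below) can reason about.

Dispersion is estimated in two stages on equalised counts:

* **Common $\phi$** maximises the summed per-window NB *conditional*
  log-likelihood (conditioning on group totals removes the means) over
  $\phi \in [10^{-6}, 10]$.
* **Tagwise $\phi_w$** maximises the window's own conditional
  log-likelihood plus `prior_df` (default 10) times the mean per-window
  log-likelihood of the whole data set — an empirical-Bayes compromise
  whose shrinkage grows with `prior_df` and whose
  $\text{prior\_df} \to \infty$ limit is exactly the common estimate.

Numerically, both stages share one machinery: the mean conditional
log-likelihood profile is evaluated on a dense grid of 121 log-spaced
$\phi$ values and interpolated with a cubic spline; golden-section search
on $\log\phi$ (60 iterations, terminal bracket below $10^{-12}$ relative)
then maximises the spline (common) or the window likelihood plus the
weighted spline (tagwise, vectorised across windows). Sharing the spline is
what makes the infinite-shrinkage limit exact to optimiser precision rather
than to grid resolution. Windows without replication anywhere raise an
error instructing a fixed-$\phi$ run; data with no overdispersion drive the
estimate to the lower bound.

The test itself conditions on the window total $t = S_A + S_B$ of the
rounded equalised group sums. With $n_A$, $n_B$ samples per group and
common per-sample mean, the probability parameter cancels and

$$\Pr(S_A = a \mid t) \propto \binom{a + r_A - 1}{a}
\binom{t - a + r_B - 1}{t - a}, \qquad r_g = n_g/\phi,$$

which degenerates to $\mathrm{Binomial}(t, n_A/(n_A+n_B))$ as
$\phi \to 0$. The two-sided p-value doubles the smaller tail (capped at 1);
the alternative "minlik" rule — summing probabilities of splits no more
likely than observed — is available by configuration, but doubling is the
default because it is monotone in the tail mass and therefore better
behaved under BH adjustment. Group sums are rounded to the nearest integer
before the test; at the counts where testing is meaningful (tens of reads
per sample) the rounding perturbation is far below the test's discreteness.
The log2 fold-change reported alongside uses a 0.5 pseudo-count per group
sum. In every comparison the *second* group is the higher dose;
`direction = "hyper"` means elevated counts (methylation) in it.

## The RAM filters

Nominal significance (default $\alpha = 0.001$ on p; q optional) only
nominates candidates. Two post-filters follow:

1. **Within-group consistency.** Each sample's CPM (count per million of
   effective library size) is compared with the *opposite* group's median
   CPM: for a hyper call, a higher-group sample is consistent if it
   exceeds the lower group's median, and a lower-group sample if it falls
   below the higher group's median (reflected for hypo). The candidate
   survives when at least half (configurable) of each group is consistent.
   Medians rather than means make the rule robust to the single-sample
   outliers that exact-test statistics are known to chase; comparisons are
   strict, so a window identical across groups has zero consistent
   samples. A fraction of exactly one half passes.
2. **Neighbourhood support.** The candidate needs either (a) one of its
   two overlapping neighbours (start ± 50 bp) nominally differential
   (p < 0.05) in the same direction, or (b) another candidate of the same
   direction starting within 500 bp ("two windows within a stretch" —
   the pair includes the candidate itself, so one *other* candidate
   suffices). Same-direction coherence is required in both branches.

Both filters only remove candidates and are idempotent; overlapping
surviving windows are merged (`mergeRams`) for reporting only, never
before statistics. The default $\alpha$ on nominal p reflects that the
post-filters, not the threshold alone, control the operating point; the
whole tuple lives in one `ramConfig()` object so that every contrast —
including the FDR estimator's — runs under identical settings.

## The sex-based empirical FDR

Male and female samples differ structurally on the sex chromosomes
(females lack Y; X carries a dosage difference), and much less elsewhere.
Running the identical pipeline on random sets of six males versus six
females therefore yields hits whose autosomal fraction estimates — under
the conservative assumption that *all* autosomal sex differences are false
positives — an upper bound on the pipeline's FDR. `sexBasedFdr` draws
`n_sets` (default 8) sets without replacement within a set (sets may
overlap), reruns the full pipeline per set, and averages the autosomal
fraction over sets with at least one hit; empty sets are excluded with a
warning, since their ratio is undefined. The synthetic generator makes the
bound testable: with sex-only effects the autosomal hits follow the exact
conditional rejection probabilities of the test (computable per window),
and with injected autosomal male/female effects the estimate must — and
does, by set inclusion — dominate the realized FDR.

## Genomic context

CpG-island context uses edge distances on merged islands: overlap ⇒
`island`, gap ≤ 2 kb ⇒ `shore`, ≤ 4 kb ⇒ `shelf`, else `open_sea`
(precedence island > shore > shelf; distances from island *edges*, the
standard convention). Interval classes are decided by window overlap;
TSS distance alone is measured from the window *midpoint*, since a
distance to a point is cleanest from a point. Nearest-TSS ties break to
the lower TSS coordinate, then the lexicographically smaller gene id.
Promoters are −500/+100 bp around the TSS on the plus strand and the
reflected −100/+500 bp window on the minus strand; the transcription
start region (TSR) defaults to ±50 bp of the TSS and accepts a
configurable width, because experimentally curated TSR catalogues are
proprietary. Intergenic means "no genic, promoter or TSR class"; the
repeat flag is orthogonal. Per-chromosome summaries report hyper/hypo
windows per megabase; cross-comparison accounting (`overlapSets`)
reports every Venn cell, the union, the pooled total and the
exactly-one count, with windows identified by chromosome and start.

## Expression integration

RNA-seq differential expression runs the same NB machinery with TMM
normalisation; DE calls require q < 0.10 and a 2-fold change. Integration
pairs a RAM within 5 kb of a gene's TSS with that gene when the gene's
expression changes nominally (p < 0.05 by default, exposed in
configuration) in the *opposite* direction to methylation. "Inverse
correlation" is implemented as sign opposition of the effect estimates,
not a sample-level correlation coefficient: with at most six samples per
group a per-gene correlation is unstable, and direction is what the
biology asserts. One candidate per gene and comparison is kept — the RAM
with the smallest p.

## The synthetic-data generator

The generator emulates the statistical structure of the real assay, not
its chemistry:

* **Genome/annotation.** Chromosome lengths uniform around a mean
  (`lengthJitter`, 0 for fixed); CpG islands and genes as Poisson
  processes placed *without overlap* by sampling starts in gap space, so
  interval counts keep their exact Poisson law; repeats cover a target
  fraction; exons partition each gene with first/last exon pinned to the
  gene ends, making the TSS the 5′ gene end by construction.
* **Reads.** 50 bp bins (half a window) receive NB counts with
  dispersion $2\phi$ so that 100 bp window counts are marginally
  NB$(\mu, \phi)$ exactly where intensity is locally constant;
  $\phi = 0$ gives Poisson. Bin intensities multiply a CGI enrichment
  factor (default 8; enrichment chemistry concentrates reads in
  CG-dense regions), a sex structure (chrY intensity 0 in females by
  default, chrX doubled in females), and $2^{\mathrm{log2FC}}$ inside
  spiked spans for samples in the spike's higher group — each span
  scaled once, however many overlapping windows describe it. Read
  positions are uniform within their bin. Per-sample seeds are split
  from the master seed, so extending a sample sheet never perturbs
  existing samples' reads.
* **Exposure groups.** BPA trichotomisation is the measured mapping:
  ≤ 0.83 ng/g (or non-detect) → `non_detect`, 3.50–5.79 → `low`,
  35.44–96.76 → `high`. Concentrations in the gaps map to `unassigned`
  and are excluded from comparisons — the study *selected* samples in
  those bands and never classified gap values, so the generator does not
  invent a rule for them.
* **Expression.** Gene counts are NB around a baseline mean with truth
  effects applied to the higher group of each DE gene's comparison;
  coupled (window, gene) pairs are validated to have opposite-signed
  effects.

What the generator does *not* emulate: base-resolution methylation,
sequencing error, fragment-length effects, GC-dependent amplification
bias, or spatial autocorrelation beyond the shared-bin structure of
overlapping windows. Passing recovery tests on this generator therefore
demonstrates the statistical machinery — calibration, dispersion
moderation, filter behaviour, FDR bounding — not robustness to every
artefact of real libraries.

## Problem sizes and expected behaviour in the test-bed

The packaged simulations run at deliberately modest scale, chosen to hold
window-level means near the real assay's working point (tens of reads per
window) while keeping full pipelines fast: three 200 kb chromosomes
(~12,000 windows) with 12 samples for recovery experiments, 40 spiked runs
of 3 consecutive windows (about 1% of windows — the same order as the RAM
fraction among tested windows in enrichment data), depth 3 × 10⁵ reads per
sample (window mean ≈ 50), dispersion 0.1, and the default
$\alpha = 0.001$ with both filters. Under these conditions the caller
recovers essentially all fully spiked windows with false calls well under
15% of calls; windows straddling a spike boundary carry half the effect by
construction and are scored as neither true nor false. Null calibration is
checked at 5,000 windows (type-I error within [0.035, 0.065] at the 5%
level, and uniformity of p up to one discreteness atom of the conditional
law); dispersion recovery at 2,000 windows returns a common $\phi$ within
[0.15, 0.25] of a true 0.2 across 20 replicates.

## Known limitations

* Two-group exact testing only: multi-factor designs, covariates
  (e.g. gestational age) and GLM-based likelihood-ratio tests are out of
  scope; the two-group design is what makes the exact conditional test
  fully specifiable and enumerable.
* Numerical equality with any particular external implementation of
  moderated-dispersion testing is not claimed; agreement is distributional
  (and cross-checked against an independent implementation at loose
  tolerance in the tests).
* The consistency filter's definition of per-sample "change" (CPM against
  the opposite group's median) is one defensible reading of a rule whose
  operational details admit alternatives; it is isolated behind
  `ramConfig()` and documented here.
* The sex-based FDR bound is exactly that — an upper bound, inflated to
  the extent that true autosomal sex differences exist in the data at
  hand.
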