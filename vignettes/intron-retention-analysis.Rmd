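---
title: "Characterizing intron retention from junction and spanning counts"
author: "intronscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing intron retention from junction and spanning counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronscape)
```

## Motivation

When the catalytic core of the spliceosome is perturbed — for example when the
U6 snRNA loses a modification it normally carries — splicing efficiency drops
first at introns that were marginal to begin with: introns with weak donor and
acceptor sites, short polypyrimidine (PY) tracts, and short overall length.
A standard way to detect this genome-wide is to compare, between wild-type and
knockout cell lines, the balance of *junction* reads (spliced) and
*exon–intron spanning* reads (unspliced) at each splice site, then ask whether
the introns that become more retained share sequence features, whether they
are enriched for snoRNA hosts, and whether their host genes lose expression.

`intronscape` implements that analysis as a reusable, testable pipeline, with
a synthetic-data generator that produces a small annotated genome and
replicate count tables with known ground truth, so every stage can be
validated by parameter recovery rather than by eye.

## Retention metrics and group calls

For a splice site with `nonsplit` spanning reads and `split` junction reads,
the retention metric is

$$\theta = \frac{\text{nonsplit}}{\text{nonsplit} + \text{split}},$$

higher values meaning more retention; it is undefined when both counts are 0.
Fractional junction usage among junctions sharing an acceptor (or donor) is

$$\psi_j = \frac{\text{split}_j}{\sum_{j'} \text{split}_{j'}},$$

which sums to 1 within a group. These are the *raw* metrics; no latent-space
denoising is applied — significance comes from the replicate structure.

A site enters testing only if its total coverage reaches `min_reads`
(default 20) in **every** replicate of both conditions. Tested sites get a
pooled-variance two-tailed Student's t-test between conditions; sites with
`p < alpha` (default 0.05, optionally BH-adjusted) are labelled `up` or
`down` by the sign of `delta = mean(KO) − mean(WT)`, all others `ns`.
Degenerate inputs follow two explicit rules: if both groups have zero
variance and equal means, the site is `ns` (`t = 0`, `p = 1`); if the means
differ with zero variance, `p` is set to 0 and the site is flagged
`degenerate` so it can be audited. A site whose metric is undefined in any
replicate is dropped and recorded in the result's attributes.

## Intron sequence features

All coordinates are 0-based half-open internally; GTF input is converted on
read. Only introns whose donor pairs with exactly one acceptor (and vice
versa) in the data are analyzed, which removes alternative splice sites and
multi-isoform ambiguity.

**PY-tract length.** Over the 3'-terminal `min(50, length)` nt of the intron,
pyrimidine fractions (C or T; U accepted as T; N counts as non-pyrimidine)
are computed in sliding 5-nt windows with step 1. The tract is anchored at
the *earliest* window start from which every window through the end of the
interval stays at or above 0.5 — a single later dip disqualifies earlier
starts — and its length is the distance from that anchor to the interval end
(0 when no anchor exists). The interval includes the terminal AG dinucleotide
by default; `py_offset` can exclude it. Consequences of these choices: the
result is either 0 or between 5 and 50, and with the AG included the smallest
nonzero value actually attainable is 7.

**Splice-site scores.** The default scorer is a position weight matrix in
bits, $\sum_i \log_2 p(b_i, i)/q(b_i)$, over MaxEntScan-convention windows
(donor: 3 exonic + 6 intronic nt; acceptor: 20 intronic + 3 exonic nt), with
built-in consensus-weighted matrices. Externally trained k-mer score tables
can be dropped in via `read_maxent_table()`; sequences containing N score
`NA`. The built-in matrices are self-contained defaults, not trained models —
rankings (strong vs weak sites) are meaningful, absolute bit values are not
comparable to published maximum-entropy scores.

**Other features.** Intron length is `end − start`; GC content excludes N
from the denominator; snoRNA hosting requires the snoRNA interval to be fully
contained in the intron (nested, as intronic snoRNAs are), with a `partial`
option for any-overlap.

## Group statistics

Each feature is standardized across groups with the modified Z-score

$$z_i = \frac{x_i - \bar{x}}{\mathrm{MAD}}, \qquad
\mathrm{MAD} = \mathrm{median}\left(|v - \bar{x}|\right),$$

where $x_i$ is the group median, $\bar{x}$ the median over **all** introns
(groups pooled), and the MAD is taken over all values' absolute deviations
from $\bar{x}$. No consistency constant (1.4826) is applied. Because the
display of interest is the shift of the `up`/`down` groups against the
stable background, $\Delta z = z_{\text{group}} - z_{\text{ns}}$ is emitted
alongside raw $z$ and is the default display; when the MAD is 0 the score is
undefined and flagged. Group differences are tested with the two-sided
Wilcoxon rank-sum test: exact (via the null distribution of the
Mann–Whitney U) when the pooled sample is at most 12 and tie-free, otherwise
a normal approximation with tie and continuity corrections. snoRNA-host
enrichment between `up` and `ns` introns, and the overlap of significant
gene sets between two knockout lines, use the closed-form 2×2 chi-squared
test ($N(ad-bc)^2$ over the marginal product, df = 1, Yates optional, with a
warning when an expected cell is below 5).

## Expression coupling

Gene-level differential expression is deliberately minimal infrastructure:
genes under 50 total raw reads are excluded; median-of-ratios size factors
(geometric-mean pseudo-reference, median taken on the log scale) normalize
the matrix; `log2FC = log2((mean_KO + 0.5)/(mean_WT + 0.5))`; p-values come
from a two-sided Welch t-test on `log2(normalized + 0.5)` with BH adjustment;
calls require FDR < 0.05 and |log2FC| > 0.5. This is **not** a negative
binomial GLM — no dispersion sharing, no shrinkage — and any externally
produced DE table with `gene_id` and `log2fc` columns can be substituted in
the association step. The retention–expression association partitions genes
with tested introns into those holding at least `k = 2` up-retained introns
versus the rest, compares their log2FC distributions by Wilcoxon, and reports
the median log2FC of all remaining genes as the baseline.

## The synthetic cohort

`sim_config()` fixes the study conditions; a seed fully determines every
output. Defaults describe a two-condition experiment (WT vs KO, 3 replicates
each) over 100 single-transcript genes × 5 introns:

* **Counts.** Site coverage is Poisson (mean 100). Nonsplit reads are
  beta-binomial around the intron's true θ with overdispersion ρ = 0.01
  (ρ = 0 degenerates to binomial exactly). Baseline θ is 0.05; the 20% of
  introns drawn as *affected* shift to θ = 0.25 in the KO only.
* **Sequences.** Affected introns draw shorter lengths (log-normal, median
  ≈ 490 vs ≈ 1340 nt), shorter PY-tract targets (7–17 nt, median 12, vs
  20–30, median 25) and weak-tier donors (GT fixed, other positions uniform)
  versus strong-tier donors (consensus-concentrated). The terminal 50 nt of
  each intron are constructed to realize the PY target *exactly*, which is
  asserted by calling `py_tract_length()` during generation; with the
  acceptor AG fixed inside the window, targets are clamped to the realizable
  {0} ∪ [7, 50]. Acceptor strength is not an independent dial — it emerges
  from the PY construction, which is precisely the coupling the analysis
  should detect. Half the genes are placed on the minus strand and
  reverse-complemented into the contig, exercising strand handling
  throughout.
* **snoRNAs.** Introns long enough to nest a 70–150 nt gene host a snoRNA
  with baseline probability 0.05, with 4-fold odds in affected introns.
* **Expression.** Gene counts are negative binomial, mean 500; genes with
  ≥ 2 affected introns are scaled by $2^{-1}$ in the KO. The dispersion
  default is 0.003 (size 300), i.e. near-Poisson variation as seen between
  deeply sequenced isogenic cell-line replicates at high expression. This
  value is chosen *jointly* with the simplified DE stage: a 4-df Welch
  t-test has no dispersion sharing, so the designed effect (|log2FC| = 1 at
  mean 500, 3 + 3) is reliably detectable only when replicate noise is near
  the counting floor. With biological-scale dispersion (0.01–0.1) this DE
  stage is underpowered, which is a property of the simplification, not of
  the data model; substitute a real NB-GLM table for real data.

What the generator does **not** emulate: read-level alignment artifacts,
coverage bias along introns, multi-isoform structure, correlated replicate
effects, or trained splice-site models. Passing parameter-recovery tests
therefore demonstrates the internal consistency of the statistics on data
satisfying the model's assumptions — not performance on real libraries.

## Numerical choices and problem sizes

Sliding windows step 1 nt; window positions are 1-based within the interval.
Exact Wilcoxon switches to the approximation above a pooled size of 12 so
enumeration stays sub-second. The chi-squared test uses no Yates correction
by default (genomic tables are large). All tables are written as TSV with a
JSON manifest carrying MD5 hashes, so reruns can be compared byte-for-byte.
The shipped test suite and the acceptance script run cohorts of 500–1,000
introns, 100–2,000 genes and 3 + 3 replicates — sizes at which every
property check completes in seconds while Monte-Carlo tolerances
(2 standard errors around nominal rates) remain tight.

## Limitations

The t-test on 3 + 3 replicate proportions is approximate; its null
calibration is verified by simulation at the default settings rather than
guaranteed analytically. The built-in splice-site matrices are conventions,
not trained models. The DE stage is a documented simplification. The
single-splice-site filter discards genuinely alternative sites by design;
`psi` metrics are computed but the headline analysis is retention (θ).
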