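# intronscape

Characterize intron retention from splice-junction and exon–intron spanning
read counts: which introns become more retained after a perturbation, what
their sequences have in common, and what that does to gene expression.

The package is written for transcriptomics analysts comparing wild-type and
knockout (or otherwise perturbed) RNA-seq cohorts — the typical setting being
a spliceosome perturbation, where splicing fails first at introns with weak
splice sites and short polypyrimidine tracts.

## What it computes

* **Retention metric.** Per splice site, θ = nonsplit / (nonsplit + split),
  the fraction of reads spanning the exon–intron boundary; ψ gives fractional
  junction usage within a shared-acceptor (or donor) group. Sites with ≥ 20
  reads in every replicate are tested with a pooled-variance two-tailed
  Student's t-test and classified `up` / `down` / `ns` by sign of
  Δθ = mean(KO) − mean(WT) at p < 0.05.
* **Intron features.** Length, GC, donor/acceptor weight-matrix scores in
  bits (MaxEntScan-convention windows; external k-mer score tables can be
  plugged in), snoRNA-host status (full containment), and the
  polypyrimidine-tract length: the distance from the earliest position in
  the 3'-terminal 50 nt where the C/T fraction of sliding 5-nt windows
  reaches 0.5 *and stays there* through the intron end.
* **Group statistics.** Feature medians per group standardized by the
  modified Z-score, z = (x_i − x̄)/MAD with x̄ and MAD over all introns and
  no consistency constant, reported relative to the `ns` baseline (Δz);
  Wilcoxon rank-sum tests between groups (exact for pooled n ≤ 12 without
  ties); 2×2 chi-squared tests for snoRNA-host enrichment and for the
  overlap of significant gene sets between two knockout lines;
  Benjamini–Hochberg adjustment.
* **Expression coupling.** A minimal DE stage (median-of-ratios
  normalization, Welch t on log2 counts, BH; ≥ 50-read filter, calls at
  FDR < 0.05 and |log2FC| > 0.5) feeds a Wilcoxon comparison of log2
  fold-changes between genes holding ≥ 2 up-retained introns and the rest.
* **Synthetic cohorts.** `sim_config()` / `simulate_dataset()` generate a
  small annotated genome (FASTA/GTF/BED-compatible) whose introns realize
  configurable PY-tract lengths exactly, plus beta-binomial splice counts
  and negative-binomial gene counts with a truth table, so the whole
  analysis is testable by parameter recovery.
* **Utilities.** SAM-text CIGAR parsing and a fixed-region
  insertion-fraction check (soft-clipped reads excluded) for verifying
  single-nucleotide insertions in edited lines.

## Worked example

```r
library(intronscape)
run <- demo_run(seed = 1)            # 100 genes x 5 introns, 3 + 3 replicates
print(run)
```

```
intronscape synthetic analysis run (seed 1)

Retention calls (theta): 500 sites tested, KO vs WT, alpha = 0.05
  up: 106  down: 9  ns: 385

Differential expression, KO vs WT (FDR < 0.05, |log2FC| > 0.5)
  up: 0  down: 19  ns: 81  filtered: 0

Recovery vs truth: sensitivity 0.990, false-call rate 0.042
snoRNA-host odds ratio (up vs ns): 2.10 (p = 0.0315)
Expression association (>=2 up introns): median log2FC -0.925 vs 0.032 (p = 2.1e-07)
```

Reading the output: of the ~100 introns simulated as retention-affected,
99% are called `up`, while 4.2% of unaffected introns are mis-called —
consistent with the 5% test level. The `up` group's feature shifts are in
`run$group_stats` (all four hallmark features — length, donor score,
acceptor score, PY-tract length — shift negative relative to `ns`). Genes
carrying ≥ 2 up-retained introns lose about one log2 unit of expression
(median −0.93 vs +0.03 for other tested genes), recovering the simulated
coupling. `demo_run(seed = 1, out_dir = "...")` additionally writes every
table as TSV plus a JSON manifest with MD5 hashes.

A thin command-line wrapper is included at `inst/cli/intronscape.R`
(subcommands `demo`, `insertion-check`, `retention`, `de`).

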