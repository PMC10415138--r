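#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across genes (restricted to
#' genes with a positive geometric mean over samples) of the ratio of the
#' gene's count to its geometric mean.
#'
#' @param counts Non-negative numeric matrix, genes x samples (>= 2 samples).
#' @return List with `size_factors` (one per sample) and `normalized`
#'   (counts divided by their sample's size factor).
#' @export
normalize_median_of_ratios <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2L)
  if (any(counts < 0)) stop("negative counts")
  log_gm <- rowMeans(log(counts))
  usable <- is.finite(log_gm)   # genes positive in all samples
  if (!any(usable)) stop("no gene has positive counts in every sample")
  # median taken on the log scale (the canonical median-of-ratios estimator)
  sf <- apply(counts[usable, , drop = FALSE], 2L, function(col) {
    exp(stats::median(log(col) - log_gm[usable]))
  })
  list(size_factors = sf, normalized = sweep(counts, 2L, sf, "/"))
}

# vectorized Welch t-test over rows of two matrices
.welch_rows <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1L, stats::var); v2 <- apply(x2, 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zero <- se2 == 0
  p[zero & m1 == m2] <- 1
  p[zero & m1 != m2] <- 0
  list(t = t, p = p)
}

#' Minimal gene-level differential expression
#'
#' Infrastructure DE stage: genes with fewer than `min_reads` total raw reads
#' are excluded (`filtered`); remaining counts are normalized by
#' median-of-ratios; `log2fc = log2((mean_alt + 0.5) / (mean_ref + 0.5))` on
#' normalized counts; p-values come from a two-sided Welch t-test on
#' `log2(normalized + 0.5)` and are BH-adjusted. Genes are called `up`/`down`
#' when `FDR < fdr_cut` and `|log2fc| > lfc_cut`, otherwise `ns`. This is a
#' deliberately simple stage (no dispersion modelling); an externally
#' produced DE table can be substituted wherever one is consumed.
#'
#' @param counts Integer matrix, genes x samples.
#' @param design Named character vector or factor assigning each sample
#'   (column) to one of two conditions; reference level first.
#' @param min_reads Minimum total raw reads per gene (default 50).
#' @param fdr_cut FDR threshold for calls (default 0.05).
#' @param lfc_cut Absolute log2 fold-change threshold (default 0.5).
#' @return Object of class `de_results`: data.frame with `gene_id`,
#'   `base_mean`, `log2fc`, `p`, `fdr`, `call`.
#' @export
differential_expression <- function(counts, design, min_reads = 50L,
                                    fdr_cut = 0.05, lfc_cut = 0.5) {
  stopifnot(is.matrix(counts), length(design) == ncol(counts))
  design <- as.factor(design)
  if (nlevels(design) != 2L) stop("design must have exactly two conditions")
  if (any(table(design) < 2L)) stop("need >= 2 replicates per condition")
  ref <- levels(design)[1L]; alt <- levels(design)[2L]

  filtered <- rowSums(counts) < min_reads
  norm <- normalize_median_of_ratios(counts)$normalized
  x1 <- norm[, design == ref, drop = FALSE]
  x2 <- norm[, design == alt, drop = FALSE]
  log2fc <- log2((rowMeans(x2) + 0.5) / (rowMeans(x1) + 0.5))
  wt <- .welch_rows(log2(x1 + 0.5), log2(x2 + 0.5))

  out <- data.frame(
    gene_id = rownames(counts),
    base_mean = rowMeans(norm),
    log2fc = log2fc, p = wt$p, fdr = NA_real_,
    call = "ns", stringsAsFactors = FALSE
  )
  out$p[filtered] <- NA_real_
  out$log2fc[filtered] <- NA_real_
  tested <- !filtered
  out$fdr[tested] <- benjamini_hochberg(out$p[tested])
  sig <- tested & out$fdr < fdr_cut & abs(out$log2fc) > lfc_cut
  out$call[sig & out$log2fc > 0] <- "up"
  out$call[sig & out$log2fc < 0] <- "down"
  out$call[filtered] <- "filtered"
  rownames(out) <- NULL
  structure(out, conditions = c(ref, alt), min_reads = min_reads,
            fdr_cut = fdr_cut, lfc_cut = lfc_cut,
            class = c("de_results", "data.frame"))
}

#' @export
print.de_results <- function(x, ...) {
  cond <- attr(x, "conditions")
  tab <- table(factor(x$call, levels = c("up", "down", "ns", "filtered")))
  cat(sprintf("Differential expression, %s vs %s (FDR < %g, |log2FC| > %g)\n",
              cond[2], cond[1], attr(x, "fdr_cut"), attr(x, "lfc_cut")))
  cat(sprintf("  up: %d  down: %d  ns: %d  filtered: %d\n",
              tab["up"], tab["down"], tab["ns"], tab["filtered"]))
  invisible(x)
}

#' Compare significant calls between two knockout lines
#'
#' Partitions up- and down-called genes into line-1-only, line-2-only and
#' shared sets over the common tested universe, and quantifies the
#' downregulated-gene overlap with [overlap_analysis()] (chi-squared over the
#' shared universe, plus the fraction of line-2 calls recurring in line 1).
#'
#' @param de1,de2 Two [differential_expression()] results.
#' @return List with `universe_size`, per-direction partitions (`down`,
#'   `up`: counts `only_1`, `only_2`, `both`), and `down_overlap` /
#'   `up_overlap` from [overlap_analysis()].
#' @export
compare_kos <- function(de1, de2) {
  u <- intersect(de1$gene_id[de1$call != "filtered"],
                 de2$gene_id[de2$call != "filtered"])
  if (length(u) == 0L) stop("no shared tested genes between the two results")
  part <- function(dir) {
    a <- intersect(de1$gene_id[de1$call == dir], u)
    b <- intersect(de2$gene_id[de2$call == dir], u)
    list(only_1 = length(setdiff(a, b)), only_2 = length(setdiff(b, a)),
         both = length(intersect(a, b)),
         overlap = overlap_analysis(a, b, u))
  }
  down <- part("down"); up <- part("up")
  list(universe_size = length(u),
       down = down[c("only_1", "only_2", "both")],
       up = up[c("only_1", "only_2", "both")],
       down_overlap = down$overlap, up_overlap = up$overlap)
}
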