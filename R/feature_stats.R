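#' Modified Z-score of group medians
#'
#' Robust standardization placing heterogeneous intron features on one scale:
#' for each group i, `z_i = (x_i - xbar) / MAD`, where `x_i` is the group
#' median, `xbar` the median over all values (all groups pooled), and
#' `MAD = median(|v - xbar|)` over all values. No consistency constant is
#' applied. When a group labelled `"ns"` is present, `delta_z = z_i - z_ns`
#' is also reported, expressing each group's shift relative to the
#' non-significant baseline.
#'
#' @param values Numeric vector of feature values (NAs dropped with a message).
#' @param groups Group label per value.
#' @return Data.frame with one row per group: `group`, `n`, `group_median`,
#'   `global_median`, `mad`, `z`, `delta_z`. `z` is NA (with a warning) when
#'   MAD is 0.
#' @export
modified_zscore <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  drop <- !is.finite(values)
  if (all(drop)) stop("no finite feature values")
  if (any(drop)) {
    message(sum(drop), " non-finite feature value(s) dropped")
    values <- values[!drop]; groups <- groups[!drop]
  }
  xbar <- stats::median(values)
  mad_ <- stats::median(abs(values - xbar))
  med <- tapply(values, groups, stats::median)
  n <- tapply(values, groups, length)
  if (mad_ == 0) {
    warning("MAD is 0; modified Z-scores undefined")
    z <- rep(NA_real_, length(med))
  } else {
    z <- (med - xbar) / mad_
  }
  out <- data.frame(
    group = names(med), n = as.integer(n),
    group_median = as.numeric(med), global_median = xbar, mad = mad_,
    z = as.numeric(z), stringsAsFactors = FALSE
  )
  out$delta_z <- if ("ns" %in% out$group) out$z - out$z[out$group == "ns"] else NA_real_
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum test
#'
#' Two-sided two-sample Wilcoxon (Mann-Whitney) test. In `auto` mode the
#' exact null distribution is used when `n_x + n_y <= 12` and there are no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction is applied. The exact two-sided p-value is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param x,y Non-empty numeric samples.
#' @param mode `"auto"` (default), `"exact"` or `"normal_approx"`.
#' @return List with `statistic` (the Mann-Whitney U for `x`), `p`, and the
#'   `mode` actually used.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  ties <- anyDuplicated(c(x, y)) > 0L
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2   # Mann-Whitney U for x
  if (mode == "auto") {
    mode <- if (nx + ny <= 12L && !ties) "exact" else "normal_approx"
  }
  if (mode == "exact") {
    if (ties) stop("exact mode is not defined with ties")
    p <- min(1, 2 * min(stats::pwilcox(u, nx, ny),
                        stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE)))
  } else {
    mu <- nx * ny / 2
    n <- nx + ny
    tie_tab <- table(r)
    sigma2 <- (nx * ny / 12) * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1   # all values tied: no evidence either way
    } else {
      z <- u - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  list(statistic = u, p = min(1, p), mode = mode)
}

#' Chi-squared test of independence for a 2x2 table
#'
#' Closed form `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with df = 1;
#' optional Yates continuity correction. A zero row or column marginal is an
#' error; a warning is emitted when any expected cell count is below 5.
#'
#' @param table 2x2 numeric matrix of non-negative counts.
#' @param yates Apply the continuity correction (default `FALSE`).
#' @return List with `chi2`, `df`, `p`, and `expected`.
#' @export
chi_squared_2x2 <- function(table, yates = FALSE) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(table < 0)) stop("negative cell counts")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  N <- a + b + c + d
  if (N == 0) stop("empty table")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal; chi-squared undefined")
  expected <- outer(rs, cs) / N
  if (any(expected < 5)) warning("expected cell count below 5; test may be unreliable")
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - N / 2)
  chi2 <- N * num^2 / (rs[1] * rs[2] * cs[1] * cs[2])
  list(chi2 = unname(chi2), df = 1L,
       p = stats::pchisq(unname(chi2), df = 1L, lower.tail = FALSE),
       expected = expected)
}

#' Overlap between two significant-gene sets
#'
#' Quantifies how much of set B recurs in set A (e.g. genes downregulated in
#' two independent knockout lines) as `|A intersect B| / |B|`, and tests the
#' association over the shared universe with a 2x2 chi-squared test.
#'
#' @param set_a,set_b Character id vectors (subsets of `universe`).
#' @param universe Character vector of all tested ids.
#' @param yates Passed to [chi_squared_2x2()].
#' @return List with `shared_fraction`, `table`, `chi2`, `p`.
#' @export
overlap_analysis <- function(set_a, set_b, universe, yates = FALSE) {
  if (length(universe) == 0L) stop("empty universe")
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("sets must be subsets of the universe")
  }
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("in_A", "not_A"), c("in_B", "not_B")))
  frac <- if (length(set_b)) length(intersect(set_a, set_b)) / length(set_b) else NA_real_
  ct <- tryCatch(chi_squared_2x2(tab, yates = yates),
                 error = function(e) list(chi2 = NA_real_, df = 1L, p = NA_real_))
  list(shared_fraction = frac, table = tab, chi2 = ct$chi2, p = ct$p)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0,1]`.
#' @return Adjusted p-values.
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Group-wise feature statistics (Z-score and p-value matrices)
#'
#' For each feature column, computes the modified Z-score per retention group
#' and pairwise Wilcoxon rank-sum p-values between groups (up vs ns, down vs
#' ns, up vs down), producing the standardized-median heatmap matrix and its
#' companion -log10(p) matrix.
#'
#' @param features A [compute_features()] table (or any data.frame) with a
#'   `group` column.
#' @param feature_cols Feature columns to analyze; defaults to the numeric
#'   intron features present.
#' @return Object of class `feature_group_stats`: list with `stats` (long
#'   per-feature-per-group data.frame), `z_matrix`, `delta_z_matrix`, and
#'   `p_matrix` (features x comparisons).
#' @export
group_feature_stats <- function(features,
                                feature_cols = intersect(
                                  c("intron_length", "gc_fraction", "ss5_score",
                                    "ss3_score", "py_tract_length"),
                                  names(features))) {
  stopifnot("group" %in% names(features), length(feature_cols) > 0)
  groups_present <- intersect(c("up", "down", "ns"), unique(features$group))
  comparisons <- list(up_vs_ns = c("up", "ns"), down_vs_ns = c("down", "ns"),
                      up_vs_down = c("up", "down"))
  stats_rows <- list()
  z_mat <- matrix(NA_real_, length(feature_cols), length(groups_present),
                  dimnames = list(feature_cols, groups_present))
  dz_mat <- z_mat
  p_mat <- matrix(NA_real_, length(feature_cols), length(comparisons),
                  dimnames = list(feature_cols, names(comparisons)))
  for (f in feature_cols) {
    v <- as.numeric(features[[f]])
    zs <- suppressWarnings(modified_zscore(v, features$group))
    zs$feature <- f
    stats_rows[[f]] <- zs
    for (g in intersect(groups_present, zs$group)) {
      z_mat[f, g] <- zs$z[zs$group == g]
      dz_mat[f, g] <- zs$delta_z[zs$group == g]
    }
    for (cmp in names(comparisons)) {
      gs <- comparisons[[cmp]]
      if (all(gs %in% features$group)) {
        xv <- v[features$group == gs[1] & is.finite(v)]
        yv <- v[features$group == gs[2] & is.finite(v)]
        if (length(xv) && length(yv)) {
          p_mat[f, cmp] <- wilcoxon_rank_sum(xv, yv)$p
        }
      }
    }
  }
  res <- list(stats = do.call(rbind, c(stats_rows, make.row.names = FALSE)),
              z_matrix = z_mat, delta_z_matrix = dz_mat, p_matrix = p_mat)
  class(res) <- "feature_group_stats"
  res
}

#' @export
print.feature_group_stats <- function(x, ...) {
  cat("Feature statistics by retention group\n\n")
  cat("delta Z (group median shift vs ns baseline, median/MAD units):\n")
  print(round(x$delta_z_matrix, 3))
  cat("\n-log10(p), Wilcoxon rank-sum:\n")
  print(round(-log10(x$p_matrix), 2))
  invisible(x)
}

#' Plot feature group statistics
#'
#' Draws the delta-Z heatmap (features x groups) alongside the -log10(p)
#' comparison matrix using base graphics.
#'
#' @param x A `feature_group_stats` object.
#' @param ... Ignored.
#' @export
plot.feature_group_stats <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(6, 8, 3, 2))
  on.exit(graphics::par(op))
  .img <- function(m, main) {
    m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    graphics::image(t(m), axes = FALSE, main = main,
                    col = grDevices::hcl.colors(25, "Blue-Red 2"))
    graphics::axis(1, at = seq(0, 1, length.out = ncol(m)), labels = colnames(m),
                   las = 2, cex.axis = .8)
    graphics::axis(2, at = seq(0, 1, length.out = nrow(m)), labels = rownames(m),
                   las = 1, cex.axis = .8)
  }
  .img(x$delta_z_matrix, "delta Z vs ns")
  .img(-log10(x$p_matrix), "-log10(p)")
  invisible(x)
}

#' snoRNA-host enrichment across retention groups
#'
#' Builds the (group) x (snoRNA host / none) contingency table between two
#' retention groups and tests it with [chi_squared_2x2()].
#'
#' @param group Group label per intron.
#' @param snorna Logical snoRNA-host flag per intron.
#' @param groups The two groups to contrast (default up vs ns).
#' @return List with `table`, `odds_ratio`, `chi2`, `p`.
#' @export
snorna_enrichment <- function(group, snorna, groups = c("up", "ns")) {
  stopifnot(length(group) == length(snorna))
  sel <- group %in% groups
  tab <- table(factor(group[sel], levels = groups),
               factor(ifelse(snorna[sel], "snoRNA", "none"),
                      levels = c("snoRNA", "none")))
  tab <- unclass(tab)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  ct <- tryCatch(suppressWarnings(chi_squared_2x2(tab)),
                 error = function(e) list(chi2 = NA_real_, p = NA_real_))
  list(table = tab, odds_ratio = or, chi2 = ct$chi2, p = ct$p)
}

#' Retention-expression association
#'
#' Partitions genes with tested introns into those holding at least `k`
#' introns called `up` (more retained) and the rest, and compares their
#' log2 fold changes with a two-sided Wilcoxon rank-sum test. The median
#' log2FC of all other genes in the DE table (no tested introns) is reported
#' as the reference baseline.
#'
#' @param de Data.frame with columns `gene_id` and `log2fc` (e.g. a
#'   [differential_expression()] result).
#' @param calls A [call_retention()] result (or data.frame with `site_id`,
#'   `group`).
#' @param intron_genes Data.frame mapping `intron_id` to `gene_id`.
#' @param k Minimum number of up-retained introns (default 2).
#' @return List with the two group sizes and medians, `median_other_genes`,
#'   Wilcoxon `p`, and the per-gene table used (`gene_id`, `n_up`, `log2fc`,
#'   `group`).
#' @export
expression_association <- function(de, calls, intron_genes, k = 2L) {
  stopifnot(all(c("gene_id", "log2fc") %in% names(de)))
  map <- intron_genes[match(calls$site_id, intron_genes$intron_id), "gene_id"]
  if (all(is.na(map))) stop("no retention calls could be mapped to genes")
  n_up <- tapply(calls$group == "up", map, sum)
  tested_genes <- names(n_up)
  tab <- data.frame(gene_id = tested_genes, n_up = as.integer(n_up),
                    stringsAsFactors = FALSE)
  tab$log2fc <- de$log2fc[match(tab$gene_id, de$gene_id)]
  tab <- tab[!is.na(tab$log2fc), , drop = FALSE]
  tab$group <- ifelse(tab$n_up >= k, "high_retention", "other_tested")
  x <- tab$log2fc[tab$group == "high_retention"]
  y <- tab$log2fc[tab$group == "other_tested"]
  other <- de$log2fc[!de$gene_id %in% tab$gene_id]
  p <- if (length(x) && length(y)) wilcoxon_rank_sum(x, y)$p else NA_real_
  if (is.na(p)) message("a partition is empty; association p-value unavailable")
  list(
    n_high_retention = length(x), n_other_tested = length(y), k = k,
    median_high_retention = if (length(x)) stats::median(x) else NA_real_,
    median_other_tested = if (length(y)) stats::median(y) else NA_real_,
    median_other_genes = if (length(other)) stats::median(other) else NA_real_,
    p = p, genes = tab
  )
}
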