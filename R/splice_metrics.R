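#' Splicing-efficiency metric theta
#'
#' theta is the fraction of reads at a splice site that span the exon-intron
#' boundary rather than the junction: `nonsplit / (nonsplit + split)`. Higher
#' theta means more intron retention. Undefined (NA) when both counts are 0.
#'
#' @param nonsplit,split Non-negative integer vectors (recycled).
#' @return Numeric vector in `[0,1]`, NA where total coverage is 0.
#' @export
compute_theta <- function(nonsplit, split) {
  if (any(nonsplit < 0, na.rm = TRUE) || any(split < 0, na.rm = TRUE)) {
    stop("negative counts")
  }
  tot <- nonsplit + split
  ifelse(tot == 0, NA_real_, nonsplit / tot)
}

#' Fractional junction usage psi within a donor/acceptor group
#'
#' For junctions sharing an acceptor (psi3) or donor (psi5), each junction's
#' psi is its share of the group's junction reads. Values within a group sum
#' to 1; all-zero groups yield NA for every member.
#'
#' @param split Junction read counts.
#' @param group Grouping key (shared acceptor for psi3, shared donor for psi5);
#'   a single group may be implied by omitting it.
#' @return Numeric vector of psi values aligned with `split`.
#' @export
compute_psi <- function(split, group = NULL) {
  if (any(split < 0, na.rm = TRUE)) stop("negative counts")
  if (is.null(group)) group <- rep(1L, length(split))
  stopifnot(length(group) == length(split))
  denom <- stats::ave(split, group, FUN = sum)
  ifelse(denom == 0, NA_real_, split / denom)
}

#' Coverage filter over sites and replicates
#'
#' A site is retained only if its total coverage (split + nonsplit) reaches
#' `min_reads` in every replicate of every condition.
#'
#' @param counts Long data.frame with columns `site_id`, `sample_id`, `split`,
#'   `nonsplit`.
#' @param min_reads Minimum per-replicate coverage (default 20).
#' @return Character vector of retained site ids.
#' @export
filter_coverage <- function(counts, min_reads = 20L) {
  cov <- counts$split + counts$nonsplit
  keep <- tapply(cov, counts$site_id, function(x) all(x >= min_reads))
  names(keep)[keep]
}

# vectorized pooled-variance two-sample t-test; returns list(t, df, p, degenerate)
.pooled_t <- function(m1, v1, n1, m2, v2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(t), df)
  degen <- sp2 == 0
  # both groups constant: equal means -> no evidence (t=0, p=1);
  # different means -> p forced to 0 and flagged
  eq <- degen & (m1 == m2)
  ne <- degen & (m1 != m2)
  t[eq] <- 0; p[eq] <- 1
  t[ne] <- sign(m2[ne] - m1[ne]) * Inf; p[ne] <- 0
  list(t = t, df = df, p = p, degenerate = ne)
}

#' Call retention-change groups from splice counts
#'
#' Applies the coverage filter, computes the chosen metric per site and
#' replicate, and tests each site with a pooled-variance two-tailed Student's
#' t-test between the two conditions. Sites with `p < alpha` are labelled
#' `up` or `down` by the sign of `delta = mean(alt) - mean(ref)`; all others
#' are `ns`. Sites with an undefined metric in any replicate are dropped.
#'
#' @param counts Long data.frame with columns `site_id`, `sample_id`,
#'   `condition`, `split`, `nonsplit`.
#' @param conditions Length-2 character vector, reference condition first.
#'   Defaults to the order of first appearance in `counts$condition`.
#' @param metric `"theta"` (retention; default) or `"psi"` (needs an
#'   `acceptor_group` column mapping each site to its shared-acceptor group).
#' @param min_reads Per-replicate coverage threshold (default 20).
#' @param alpha Significance threshold for group assignment (default 0.05).
#' @param delta_floor Optional minimum `|delta|` for an up/down call
#'   (default 0).
#' @param adjust If `TRUE`, apply Benjamini-Hochberg to the p-values before
#'   thresholding (off by default).
#' @return Object of class `retention_calls`: a data.frame with one row per
#'   tested site (`site_id`, per-condition means, `delta`, `t`, `p`,
#'   optionally `p_adj`, `group`, `degenerate`) plus attributes recording the
#'   parameters and the ids dropped at each stage.
#' @export
call_retention <- function(counts, conditions = NULL, metric = c("theta", "psi"),
                           min_reads = 20L, alpha = 0.05, delta_floor = 0,
                           adjust = FALSE) {
  metric <- match.arg(metric)
  stopifnot(all(c("site_id", "sample_id", "condition", "split", "nonsplit") %in%
                  names(counts)))
  if (is.null(conditions)) conditions <- unique(counts$condition)
  stopifnot(length(conditions) == 2L)
  counts <- counts[counts$condition %in% conditions, , drop = FALSE]

  keep <- filter_coverage(counts, min_reads)
  low_cov <- setdiff(unique(counts$site_id), keep)
  counts <- counts[counts$site_id %in% keep, , drop = FALSE]

  if (metric == "theta") {
    counts$value <- compute_theta(counts$nonsplit, counts$split)
  } else {
    if (!"acceptor_group" %in% names(counts)) {
      stop("psi metric requires an 'acceptor_group' column")
    }
    counts$value <- stats::ave(
      seq_len(nrow(counts)), counts$sample_id, FUN = function(i) {
        compute_psi(counts$split[i], counts$acceptor_group[i])
      })
  }

  bad <- tapply(counts$value, counts$site_id, function(x) any(is.na(x)))
  undefined <- names(bad)[bad]
  if (length(undefined)) {
    counts <- counts[!counts$site_id %in% undefined, , drop = FALSE]
  }
  if (nrow(counts) == 0L) stop("no sites left after filtering")

  is_ref <- counts$condition == conditions[1L]
  agg <- function(sel, fun) {
    tapply(counts$value[sel], counts$site_id[sel], fun)
  }
  ids <- sort(unique(counts$site_id))
  m1 <- agg(is_ref, mean)[ids]; v1 <- agg(is_ref, stats::var)[ids]
  n1 <- agg(is_ref, length)[ids]
  m2 <- agg(!is_ref, mean)[ids]; v2 <- agg(!is_ref, stats::var)[ids]
  n2 <- agg(!is_ref, length)[ids]
  if (any(n1 < 2) || any(n2 < 2)) stop("need >= 2 replicates per condition")

  tt <- .pooled_t(m1, v1, n1, m2, v2, n2)
  p_use <- if (adjust) stats::p.adjust(tt$p, method = "BH") else tt$p
  delta <- m2 - m1
  group <- rep("ns", length(ids))
  sig <- p_use < alpha & abs(delta) > delta_floor
  group[sig & delta > 0] <- "up"
  group[sig & delta < 0] <- "down"

  out <- data.frame(
    site_id = ids, metric = metric,
    mean_ref = as.numeric(m1), mean_alt = as.numeric(m2),
    delta = as.numeric(delta), t = as.numeric(tt$t), p = as.numeric(tt$p),
    group = group, degenerate = as.logical(tt$degenerate),
    stringsAsFactors = FALSE
  )
  if (adjust) out$p_adj <- as.numeric(p_use)
  rownames(out) <- NULL
  structure(out,
            conditions = conditions, alpha = alpha, min_reads = min_reads,
            delta_floor = delta_floor, adjust = adjust,
            dropped_low_coverage = low_cov, dropped_undefined = undefined,
            class = c("retention_calls", "data.frame"))
}

#' @export
print.retention_calls <- function(x, ...) {
  cond <- attr(x, "conditions")
  cat(sprintf("Retention calls (%s): %d sites tested, %s vs %s, alpha = %g\n",
              x$metric[1], nrow(x), cond[2], cond[1], attr(x, "alpha")))
  tab <- table(factor(x$group, levels = c("up", "down", "ns")))
  cat(sprintf("  up: %d  down: %d  ns: %d\n", tab["up"], tab["down"], tab["ns"]))
  nd <- length(attr(x, "dropped_low_coverage"))
  nu <- length(attr(x, "dropped_undefined"))
  if (nd + nu > 0) {
    cat(sprintf("  dropped: %d below coverage, %d with undefined metric\n", nd, nu))
  }
  invisible(x)
}

#' @export
summary.retention_calls <- function(object, ...) {
  print(object)
  cat("\n  delta quantiles by group:\n")
  for (g in intersect(c("up", "down", "ns"), unique(object$group))) {
    q <- stats::quantile(object$delta[object$group == g], c(.25, .5, .75))
    cat(sprintf("    %-4s median %+.3f  IQR [%+.3f, %+.3f]\n", g, q[2], q[1], q[3]))
  }
  invisible(object)
}
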