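# Independent brute-force oracles used to verify the package implementations.
# These deliberately re-derive each quantity from its definition with naive
# loops, sharing no code with the functions under test.

# polypyrimidine tract: test every suffix start, recompute every window
oracle_py_tract <- function(seq, window = 5L, threshold = 0.5) {
  x <- strsplit(toupper(seq), "")[[1L]]
  x[x == "U"] <- "T"
  W <- length(x)
  if (W < window) return(0L)
  n_windows <- W - window + 1L
  frac <- function(p) mean(x[p:(p + window - 1L)] %in% c("C", "T"))
  for (p in seq_len(n_windows)) {
    all_high <- TRUE
    for (q in p:n_windows) {
      if (frac(q) < threshold) { all_high <- FALSE; break }
    }
    if (all_high) return(W - p + 1L)
  }
  0L
}

# modified Z-score straight from its definition
oracle_modified_z <- function(values, groups, g) {
  xbar <- median(values)
  mad_ <- median(abs(values - xbar))
  (median(values[groups == g]) - xbar) / mad_
}

# exact two-sided Wilcoxon p by full enumeration of label assignments
oracle_wilcoxon_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  us <- apply(idx, 2L, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# per-position wmm score by a plain loop
oracle_wmm_score <- function(seq, probs, background) {
  b <- strsplit(seq, "")[[1L]]
  s <- 0
  for (i in seq_along(b)) {
    s <- s + unname(log2(probs[b[i], i] / background[b[i]]))
  }
  s
}

random_dna_string <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_cigar <- function() {
  n_ops <- sample(1:6, 1)
  ops <- sample(c("M", "I", "D", "N", "S", "=", "X"), n_ops, replace = TRUE)
  # S only at the ends, per the SAM spec
  if (n_ops > 2) ops[2:(n_ops - 1)][ops[2:(n_ops - 1)] == "S"] <- "M"
  if (!any(ops %in% c("M", "=", "X"))) ops[1] <- "M"
  lens <- sample(1:80, n_ops, replace = TRUE)
  paste0(paste0(lens, ops, collapse = ""))
}

# minimal SAM writer for fixtures
write_sam <- function(reads, path, contig = "chr2", contig_len = 100000L) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len))
  body <- vapply(seq_len(nrow(reads)), function(i) {
    span <- sum(as.integer(
      regmatches(reads$cigar[i], gregexpr("[0-9]+(?=[MX=DN])", reads$cigar[i], perl = TRUE))[[1]]))
    sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
            reads$qname[i], contig, reads$pos[i] + 1L, reads$cigar[i],
            strrep("A", 10L))
  }, "")
  writeLines(c(hdr, body), path)
}
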