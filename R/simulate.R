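#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic splicing cohort.
#' Defaults describe a small two-condition (WT vs KO) experiment in which a
#' fraction of introns becomes more retained in the KO, and those affected
#' introns carry the sequence hallmarks of retention-prone introns: shorter
#' length, shorter polypyrimidine tract, weaker donor site, and an excess of
#' snoRNA-hosting introns. Genes holding at least `lfc_k` affected introns are
#' downregulated by `lfc_coupling` log2 units.
#'
#' @param n_genes Number of genes.
#' @param introns_per_gene Introns per gene (one transcript per gene).
#' @param n_replicates Replicates per condition.
#' @param conditions Two condition labels, reference first.
#' @param baseline_theta Baseline retention level theta in (0,1).
#' @param theta_effect Additive theta shift for affected introns in the KO.
#' @param affected_fraction Fraction of introns affected.
#' @param rho Beta-binomial overdispersion in `[0,1)`; 0 gives binomial counts.
#' @param total_site_coverage Mean reads per splice site (Poisson).
#' @param len_meanlog_affected,len_meanlog_unaffected,len_sdlog Log-normal
#'   parameters for intron length (nt) by affected status.
#' @param min_intron_length Shortest intron emitted (donor 6-mer plus the 50 nt
#'   acceptor interval must fit).
#' @param py_range_affected,py_range_unaffected Integer ranges from which
#'   polypyrimidine-tract targets are drawn (clamped to the realizable 7..50).
#' @param ss_tier_affected,ss_tier_unaffected Donor strength tier,
#'   `"strong"` or `"weak"`.
#' @param nb_mean,nb_size Negative-binomial mean and size for gene counts.
#' @param lfc_coupling Log2 fold change applied to genes with >= `lfc_k`
#'   affected introns.
#' @param lfc_k Affected-intron count threshold for the expression coupling.
#' @param snorna_host_fraction Baseline probability that an (eligible) intron
#'   hosts a snoRNA.
#' @param snorna_enrichment_odds Odds multiplier for snoRNA hosting in
#'   affected introns.
#' @param exon_length,spacer_length Exon and intergenic spacer sizes (nt).
#' @param minus_strand_fraction Fraction of genes placed on the minus strand.
#' @param seed Integer seed; fully determines all outputs.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 100L,
                       introns_per_gene = 5L,
                       n_replicates = 3L,
                       conditions = c("WT", "KO"),
                       baseline_theta = 0.05,
                       theta_effect = 0.20,
                       affected_fraction = 0.2,
                       rho = 0.01,
                       total_site_coverage = 100,
                       len_meanlog_affected = 6.2,
                       len_meanlog_unaffected = 7.2,
                       len_sdlog = 0.35,
                       min_intron_length = 80L,
                       py_range_affected = c(7L, 17L),
                       py_range_unaffected = c(20L, 30L),
                       ss_tier_affected = "weak",
                       ss_tier_unaffected = "strong",
                       nb_mean = 500,
                       nb_size = 300,
                       lfc_coupling = -1,
                       lfc_k = 2L,
                       snorna_host_fraction = 0.05,
                       snorna_enrichment_odds = 4,
                       exon_length = 100L,
                       spacer_length = 100L,
                       minus_strand_fraction = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), introns_per_gene = as.integer(introns_per_gene),
    n_replicates = as.integer(n_replicates), conditions = conditions,
    baseline_theta = baseline_theta, theta_effect = theta_effect,
    affected_fraction = affected_fraction, rho = rho,
    total_site_coverage = total_site_coverage,
    len_meanlog_affected = len_meanlog_affected,
    len_meanlog_unaffected = len_meanlog_unaffected,
    len_sdlog = len_sdlog, min_intron_length = as.integer(min_intron_length),
    py_range_affected = as.integer(py_range_affected),
    py_range_unaffected = as.integer(py_range_unaffected),
    ss_tier_affected = ss_tier_affected, ss_tier_unaffected = ss_tier_unaffected,
    nb_mean = nb_mean, nb_size = nb_size,
    lfc_coupling = lfc_coupling, lfc_k = as.integer(lfc_k),
    snorna_host_fraction = snorna_host_fraction,
    snorna_enrichment_odds = snorna_enrichment_odds,
    exon_length = as.integer(exon_length), spacer_length = as.integer(spacer_length),
    minus_strand_fraction = minus_strand_fraction, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param cfg A `sim_config` object.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  err <- character()
  chk <- function(ok, msg) if (!ok) err <<- c(err, msg)
  chk(cfg$n_genes >= 1 && cfg$introns_per_gene >= 1, "n_genes and introns_per_gene must be >= 1")
  chk(cfg$n_replicates >= 2, "n_replicates must be >= 2")
  chk(length(cfg$conditions) == 2 && !anyDuplicated(cfg$conditions),
      "exactly two distinct condition labels required")
  chk(cfg$baseline_theta > 0 && cfg$baseline_theta < 1, "baseline_theta must be in (0,1)")
  chk(cfg$baseline_theta + cfg$theta_effect < 1, "baseline_theta + theta_effect must be < 1")
  chk(cfg$baseline_theta + cfg$theta_effect >= 0, "theta in KO must be >= 0")
  chk(cfg$affected_fraction >= 0 && cfg$affected_fraction <= 1, "affected_fraction must be in [0,1]")
  chk(cfg$rho >= 0 && cfg$rho < 1, "rho must be in [0,1)")
  chk(cfg$total_site_coverage > 0, "total_site_coverage must be positive")
  chk(cfg$min_intron_length >= 56L, "min_intron_length must be >= 56 (donor + acceptor interval)")
  chk(all(cfg$ss_tier_affected %in% c("strong", "weak")) &&
        all(cfg$ss_tier_unaffected %in% c("strong", "weak")), "splice-site tiers must be strong/weak")
  chk(cfg$nb_mean > 0 && cfg$nb_size > 0, "nb_mean and nb_size must be positive")
  chk(cfg$snorna_host_fraction >= 0 && cfg$snorna_host_fraction < 1,
      "snorna_host_fraction must be in [0,1)")
  chk(cfg$snorna_enrichment_odds > 0, "snorna_enrichment_odds must be positive")
  chk(cfg$minus_strand_fraction >= 0 && cfg$minus_strand_fraction <= 1,
      "minus_strand_fraction must be in [0,1]")
  if (length(err)) stop(paste(err, collapse = "; "))
  invisible(cfg)
}

# beta-binomial sampler: theta mean, rho overdispersion; rho = 0 -> binomial
.rbetabinom <- function(n, size, theta, rho) {
  theta <- rep_len(theta, n)
  if (rho == 0) return(stats::rbinom(n, size, theta))
  a <- theta * (1 - rho) / rho
  b <- (1 - theta) * (1 - rho) / rho
  p <- stats::rbeta(n, a, b)
  stats::rbinom(n, size, p)
}

#' Simulate the per-intron and per-gene ground truth
#'
#' Draws the latent cohort structure (which introns are affected, their true
#' theta per condition, feature targets, snoRNA-host status and the gene-level
#' log2 fold changes) without constructing sequences. [simulate_genome()] calls
#' this internally; calling it directly is useful for count-only calibration
#' experiments.
#'
#' @param config A [sim_config()] object.
#' @return List with data.frames `introns` and `genes`.
#' @export
simulate_truth <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_introns <- config$n_genes * config$introns_per_gene
  gene_id <- rep(sprintf("g%04d", seq_len(config$n_genes)), each = config$introns_per_gene)
  ord <- stats::ave(seq_len(n_introns), gene_id, FUN = seq_along)
  intron_id <- sprintf("%s.i%d", gene_id, ord)

  affected <- stats::runif(n_introns) < config$affected_fraction
  meanlog <- ifelse(affected, config$len_meanlog_affected, config$len_meanlog_unaffected)
  len <- pmax(config$min_intron_length,
              as.integer(round(stats::rlnorm(n_introns, meanlog, config$len_sdlog))))

  py_lo <- ifelse(affected, config$py_range_affected[1L], config$py_range_unaffected[1L])
  py_hi <- ifelse(affected, config$py_range_affected[2L], config$py_range_unaffected[2L])
  py_target <- py_lo + floor(stats::runif(n_introns) * (py_hi - py_lo + 1))
  # with the acceptor AG fixed inside the 50 nt interval, nonzero tract
  # lengths below 7 are not realizable; clamp into the feasible range
  py_target <- as.integer(pmin(50L, pmax(7L, py_target)))

  tier <- ifelse(affected, config$ss_tier_affected, config$ss_tier_unaffected)

  # snoRNA hosting requires room between donor and acceptor interval
  eligible <- len >= 6L + 50L + 150L + 20L
  base_odds <- config$snorna_host_fraction / (1 - config$snorna_host_fraction)
  odds <- ifelse(affected, base_odds * config$snorna_enrichment_odds, base_odds)
  p_sno <- odds / (1 + odds)
  snorna <- eligible & (stats::runif(n_introns) < p_sno)

  theta_ref <- rep(config$baseline_theta, n_introns)
  theta_alt <- config$baseline_theta + ifelse(affected, config$theta_effect, 0)

  strand <- ifelse(
    rep(stats::runif(config$n_genes) < config$minus_strand_fraction,
        each = config$introns_per_gene), "-", "+")

  introns <- data.frame(
    intron_id = intron_id, gene_id = gene_id, affected = affected,
    group_true = ifelse(affected & config$theta_effect > 0, "up",
                        ifelse(affected & config$theta_effect < 0, "down", "ns")),
    theta_ref = theta_ref, theta_alt = theta_alt,
    length = len, py_target = py_target, ss_tier = tier,
    snorna = snorna, strand = strand, stringsAsFactors = FALSE
  )

  n_aff_per_gene <- tapply(affected, gene_id, sum)[unique(gene_id)]
  genes <- data.frame(
    gene_id = unique(gene_id),
    n_affected_introns = as.integer(n_aff_per_gene),
    true_lfc = ifelse(n_aff_per_gene >= config$lfc_k, config$lfc_coupling, 0),
    strand = strand[!duplicated(gene_id)],
    stringsAsFactors = FALSE
  )
  rownames(genes) <- NULL
  list(introns = introns, genes = genes)
}

# donor 6-mer (intronic side), GT fixed at +1,+2
.sample_donor6 <- function(tier) {
  rest <- if (tier == "strong") {
    # concentrated on the AAGT consensus at +3..+6
    vapply(c("A", "A", "G", "T"), function(b) {
      if (stats::runif(1) < 0.85) b else sample(c("A", "C", "G", "T"), 1L)
    }, "")
  } else {
    sample(c("A", "C", "G", "T"), 4L, replace = TRUE)
  }
  paste0("GT", paste(rest, collapse = ""))
}

# terminal 50 nt of the intron realizing polypyrimidine-tract length `target`
# (0 or 7..50); the last two bases are the acceptor AG
.build_py_tail <- function(target) {
  stopifnot(target == 0L || (target >= 7L && target <= 50L))
  pur <- c("A", "G"); pyr <- c("C", "T")
  tail <- sample(pur, 50L, replace = TRUE)
  if (target > 0L) {
    s <- 53L - target
    tail[s:48L] <- sample(pyr, 49L - s, replace = TRUE)
  }
  tail[49L] <- "A"; tail[50L] <- "G"
  seq <- paste(tail, collapse = "")
  realized <- py_tract_length(seq)
  if (realized != target) stop("PY-tract construction failed: target ", target,
                               " realized ", realized)
  seq
}

.random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a small annotated genome
#'
#' Constructs one contig holding `n_genes` single-transcript genes whose
#' introns realize the feature targets drawn by [simulate_truth()]: the
#' terminal 50 nt encode the target polypyrimidine-tract length exactly (this
#' is asserted by calling [py_tract_length()] during construction), the first
#' 6 intronic nt are drawn from the configured donor strength tier (GT fixed),
#' and snoRNA genes of 70-150 nt are nested fully inside hosting introns.
#' Minus-strand genes are reverse-complemented into the contig.
#'
#' @param config A [sim_config()] object.
#' @return List with `genome` (DNAStringSet), `annotation` (gene/exon/intron
#'   records), `snorna` (snoRNA records), and `truth` (from
#'   [simulate_truth()], with realized PY-tract lengths appended).
#' @export
simulate_genome <- function(config) {
  truth <- simulate_truth(config)   # seeds the RNG with config$seed
  tri <- truth$introns
  contig <- "chrS"
  exl <- config$exon_length
  cursor <- 0L
  pieces <- character(0)
  ann <- list()
  sno <- list()

  for (g in seq_len(config$n_genes)) {
    gid <- truth$genes$gene_id[g]
    strand <- truth$genes$strand[g]
    rows <- which(tri$gene_id == gid)
    n_int <- length(rows)

    # transcript-space construction: exon, (intron, exon) x n_int
    seqs <- character(0)
    elems <- list()   # transcript-space offsets
    off <- 0L
    add <- function(kind, s, id) {
      seqs <<- c(seqs, s)
      elems[[length(elems) + 1L]] <<- list(kind = kind, start = off, end = off + nchar(s), id = id)
      off <<- off + nchar(s)
    }
    add("exon", .random_dna(exl), sprintf("%s.e1", gid))
    for (k in seq_len(n_int)) {
      r <- rows[k]
      L <- tri$length[r]
      donor <- .sample_donor6(tri$ss_tier[r])
      tail50 <- .build_py_tail(tri$py_target[r])
      mid_len <- L - 6L - 50L
      if (tri$snorna[r]) {
        sno_len <- sample(70:150, 1L)
        pre <- sample(10:(mid_len - sno_len - 10L), 1L)
        mid <- paste0(.random_dna(pre), .random_dna(sno_len), .random_dna(mid_len - pre - sno_len))
        sno_off <- off + 6L + pre   # transcript-space start of the snoRNA
        elems[[length(elems) + 1L]] <- list(kind = "snoRNA", start = sno_off,
                                            end = sno_off + sno_len,
                                            id = sprintf("%s.sno", tri$intron_id[r]))
      } else {
        mid <- .random_dna(mid_len)
      }
      add("intron", paste0(donor, mid, tail50), tri$intron_id[r])
      add("exon", .random_dna(exl), sprintf("%s.e%d", gid, k + 1L))
    }
    gene_seq <- paste(seqs, collapse = "")
    glen <- nchar(gene_seq)
    if (strand == "-") {
      gene_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene_seq)))
    }
    gstart <- cursor + config$spacer_length
    pieces <- c(pieces, .random_dna(config$spacer_length), gene_seq)
    cursor <- gstart + glen

    for (el in elems) {
      if (strand == "-") {
        s <- gstart + glen - el$end; e <- gstart + glen - el$start
      } else {
        s <- gstart + el$start; e <- gstart + el$end
      }
      rec <- data.frame(contig = contig, start = s, end = e, strand = strand,
                        feature_kind = el$kind, gene_id = gid, feature_id = el$id,
                        transcript_id = sprintf("%s.t1", gid), stringsAsFactors = FALSE)
      if (el$kind == "snoRNA") sno[[length(sno) + 1L]] <- rec else ann[[length(ann) + 1L]] <- rec
    }
    ann[[length(ann) + 1L]] <- data.frame(
      contig = contig, start = gstart, end = gstart + glen, strand = strand,
      feature_kind = "gene", gene_id = gid, feature_id = gid,
      transcript_id = NA_character_, stringsAsFactors = FALSE)
  }
  pieces <- c(pieces, .random_dna(config$spacer_length))

  genome <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
  names(genome) <- contig
  annotation <- do.call(rbind, ann)
  annotation <- annotation[order(annotation$start, annotation$end), , drop = FALSE]
  rownames(annotation) <- NULL
  snorna <- if (length(sno)) do.call(rbind, sno) else
    data.frame(contig = character(), start = integer(), end = integer(),
               strand = character(), feature_kind = character(),
               gene_id = character(), feature_id = character(),
               transcript_id = character(), stringsAsFactors = FALSE)
  rownames(snorna) <- NULL
  truth$introns$py_realized <- truth$introns$py_target
  list(genome = genome, annotation = annotation, snorna = snorna, truth = truth)
}

#' Simulate replicate splice-site counts
#'
#' For each intron and sample, total site coverage is Poisson with the
#' configured mean; nonsplit (exon-intron spanning) reads are beta-binomial
#' around the intron's true theta for the sample's condition, and split
#' (junction) reads make up the remainder.
#'
#' @param truth Truth list from [simulate_truth()] / [simulate_genome()], or
#'   its `introns` data.frame.
#' @param config A [sim_config()] object.
#' @return Data.frame with columns `site_id`, `sample_id`, `condition`,
#'   `split`, `nonsplit`.
#' @export
simulate_splice_counts <- function(truth, config) {
  validate_sim_config(config)
  tri <- if (is.data.frame(truth)) truth else truth$introns
  set.seed(config$seed + 1L)
  n <- nrow(tri)
  samples <- c(outer(seq_len(config$n_replicates), config$conditions,
                     function(i, cond) sprintf("%s_%d", cond, i)))
  conds <- rep(config$conditions, each = config$n_replicates)
  out <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    theta <- if (conds[s] == config$conditions[1L]) tri$theta_ref else tri$theta_alt
    N <- stats::rpois(n, config$total_site_coverage)
    nonsplit <- .rbetabinom(n, N, theta, config$rho)
    out[[s]] <- data.frame(
      site_id = tri$intron_id, sample_id = samples[s], condition = conds[s],
      split = N - nonsplit, nonsplit = nonsplit, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a gene count matrix
#'
#' Counts are negative binomial with common mean and size; in the second
#' (KO) condition, genes whose number of affected introns reaches `lfc_k`
#' have their mean multiplied by `2^lfc_coupling`.
#'
#' @inheritParams simulate_splice_counts
#' @return Integer matrix genes x samples with sample columns named
#'   `<condition>_<replicate>`.
#' @export
simulate_gene_counts <- function(truth, config) {
  validate_sim_config(config)
  genes <- if (is.data.frame(truth)) truth else truth$genes
  set.seed(config$seed + 2L)
  samples <- c(outer(seq_len(config$n_replicates), config$conditions,
                     function(i, cond) sprintf("%s_%d", cond, i)))
  conds <- rep(config$conditions, each = config$n_replicates)
  m <- matrix(0L, nrow = nrow(genes), ncol = length(samples),
              dimnames = list(genes$gene_id, samples))
  for (s in seq_along(samples)) {
    mu <- if (conds[s] == config$conditions[2L]) {
      config$nb_mean * 2^genes$true_lfc
    } else rep(config$nb_mean, nrow(genes))
    m[, s] <- stats::rnbinom(nrow(genes), mu = mu, size = config$nb_size)
  }
  m
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running [simulate_genome()],
#' [simulate_splice_counts()] and [simulate_gene_counts()] under one
#' configuration.
#'
#' @param config A [sim_config()] object.
#' @return List with `genome`, `annotation`, `snorna`, `truth`,
#'   `splice_counts`, `gene_counts`, and the `config`.
#' @export
simulate_dataset <- function(config) {
  sim <- simulate_genome(config)
  sim$splice_counts <- simulate_splice_counts(sim$truth, config)
  sim$gene_counts <- simulate_gene_counts(sim$truth, config)
  sim$config <- config
  sim
}
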