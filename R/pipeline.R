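#' Pipeline configuration
#'
#' Assembles and validates the thresholds and simulation settings for a full
#' synthetic run of the analysis. Unknown keys are rejected; omitted keys take
#' their defaults.
#'
#' @param sim A [sim_config()] object (the synthetic cohort definition).
#' @param min_reads Splice-site coverage threshold (default 20).
#' @param alpha Retention-call significance threshold (default 0.05).
#' @param de_min_reads Gene-level raw-read filter (default 50).
#' @param fdr DE FDR threshold (default 0.05).
#' @param lfc DE absolute log2 fold-change threshold (default 0.5).
#' @param k Up-retained-intron count for the expression association
#'   (default 2).
#' @param out_dir Output directory; `NULL` keeps results in memory only.
#' @param ... Must be empty; present so misspelled keys error by name.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), min_reads = 20L, alpha = 0.05,
                            de_min_reads = 50L, fdr = 0.05, lfc = 0.5, k = 2L,
                            out_dir = NULL, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown configuration key(s): ", paste(names(extra), collapse = ", "))
  }
  cfg <- list(sim = sim, min_reads = as.integer(min_reads), alpha = alpha,
              de_min_reads = as.integer(de_min_reads), fdr = fdr, lfc = lfc,
              k = as.integer(k), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config` object.
#' @export
validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  err <- character()
  chk <- function(ok, msg) if (!ok) err <<- c(err, msg)
  chk(inherits(cfg$sim, "sim_config"), "sim must be a sim_config object")
  chk(cfg$min_reads >= 0, "min_reads must be non-negative")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0,1)")
  chk(cfg$de_min_reads >= 0, "de_min_reads must be non-negative")
  chk(cfg$fdr > 0 && cfg$fdr < 1, "fdr must be in (0,1)")
  chk(cfg$lfc >= 0, "lfc must be non-negative")
  chk(cfg$k >= 1, "k must be >= 1")
  if (length(err)) stop(paste(err, collapse = "; "))
  validate_sim_config(cfg$sim)
  invisible(cfg)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a cohort, computes retention calls (theta metric), intron
#' features on the emitted genome, group feature statistics, snoRNA-host
#' enrichment, differential expression and the retention-expression
#' association, and compares the calls against the simulation truth. With
#' `out_dir` set, every table is written as TSV along with a JSON manifest
#' recording the package version, configuration, seed, row counts and MD5
#' hashes of all outputs.
#'
#' @param config A [pipeline_config()] object.
#' @return Object of class `intronscape_run`: list with `calls`, `features`,
#'   `group_stats`, `snorna_enrichment`, `de`, `association`, `recovery`,
#'   `truth`, `config`, and (if written) `files` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_pipeline_config(config)
  sim <- simulate_dataset(config$sim)

  calls <- call_retention(sim$splice_counts, conditions = config$sim$conditions,
                          metric = "theta", min_reads = config$min_reads,
                          alpha = config$alpha)

  introns <- sim$annotation[sim$annotation$feature_kind == "intron", , drop = FALSE]
  introns <- unique_ss_filter(introns)
  feats <- compute_features(introns, sim$genome)
  feats$snorna <- annotate_snorna_overlap(introns, sim$snorna)
  feats$group <- calls$group[match(feats$intron_id, calls$site_id)]
  feats$group[is.na(feats$group)] <- "untested"

  tested <- feats[feats$group %in% c("up", "down", "ns"), , drop = FALSE]
  gstats <- group_feature_stats(tested)
  sno <- snorna_enrichment(tested$group, tested$snorna)

  de <- differential_expression(sim$gene_counts,
                                design = factor(
                                  rep(config$sim$conditions, each = config$sim$n_replicates),
                                  levels = config$sim$conditions),
                                min_reads = config$de_min_reads,
                                fdr_cut = config$fdr, lfc_cut = config$lfc)
  assoc <- expression_association(de, calls,
                                  intron_genes = data.frame(
                                    intron_id = sim$truth$introns$intron_id,
                                    gene_id = sim$truth$introns$gene_id,
                                    stringsAsFactors = FALSE),
                                  k = config$k)

  truth <- sim$truth$introns
  called_up <- calls$site_id[calls$group == "up"]
  tested_ids <- calls$site_id
  aff <- truth$intron_id[truth$affected]
  unaff <- truth$intron_id[!truth$affected]
  recovery <- list(
    n_tested = length(tested_ids),
    sensitivity = mean(intersect(aff, tested_ids) %in% called_up),
    false_call_rate = mean(
      calls$group[calls$site_id %in% unaff] != "ns"),
    delta_z_up = gstats$delta_z_matrix[, "up"]
  )

  res <- list(calls = calls, features = feats, group_stats = gstats,
              snorna_enrichment = sno, de = de, association = assoc,
              recovery = recovery, truth = sim$truth, config = config)
  class(res) <- "intronscape_run"

  if (!is.null(config$out_dir)) {
    res <- .write_run(res, sim, config)
  }
  res
}

.write_run <- function(res, sim, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  files <- c(
    genome = write_genome_fasta(sim$genome, p("genome.fa")),
    annotation = write_annotation(sim$annotation, p("annotation.gtf"), "gtf"),
    snorna = write_annotation(sim$snorna, p("snorna.bed"), "bed"),
    splice_counts = .write_tsv(sim$splice_counts, p("splice_counts.tsv")),
    gene_counts = write_counts(sim$gene_counts, p("gene_counts.tsv"), "gene_id"),
    calls = .write_tsv(as.data.frame(res$calls), p("retention_calls.tsv")),
    features = .write_tsv(res$features, p("feature_table.tsv")),
    group_stats = .write_tsv(res$group_stats$stats, p("group_feature_stats.tsv")),
    z_matrix = .write_tsv(data.frame(feature = rownames(res$group_stats$delta_z_matrix),
                                     res$group_stats$delta_z_matrix,
                                     check.names = FALSE),
                          p("delta_z_matrix.tsv")),
    p_matrix = .write_tsv(data.frame(feature = rownames(res$group_stats$p_matrix),
                                     res$group_stats$p_matrix, check.names = FALSE),
                          p("p_matrix.tsv")),
    de = .write_tsv(as.data.frame(res$de), p("de_results.tsv")),
    truth_introns = .write_tsv(res$truth$introns, p("truth_introns.tsv")),
    truth_genes = .write_tsv(res$truth$genes, p("truth_genes.tsv"))
  )
  manifest <- list(
    package = "intronscape",
    version = as.character(utils::packageVersion("intronscape")),
    seed = config$sim$seed,
    thresholds = list(min_reads = config$min_reads, alpha = config$alpha,
                      de_min_reads = config$de_min_reads, fdr = config$fdr,
                      lfc = config$lfc, k = config$k),
    sim = unclass(config$sim),
    rows = list(retention_calls = nrow(res$calls), features = nrow(res$features),
                de = nrow(res$de), introns = nrow(res$truth$introns),
                genes = nrow(res$truth$genes)),
    md5 = as.list(stats::setNames(unname(tools::md5sum(unname(files))),
                                  names(files)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$files <- files
  res$manifest <- manifest
  res
}

#' @export
print.intronscape_run <- function(x, ...) {
  cat("intronscape synthetic analysis run (seed ", x$config$sim$seed, ")\n\n", sep = "")
  print(x$calls)
  cat("\n")
  print(x$de)
  cat(sprintf("\nRecovery vs truth: sensitivity %.3f, false-call rate %.3f\n",
              x$recovery$sensitivity, x$recovery$false_call_rate))
  cat(sprintf("snoRNA-host odds ratio (up vs ns): %.2f (p = %.3g)\n",
              x$snorna_enrichment$odds_ratio, x$snorna_enrichment$p))
  cat(sprintf("Expression association (>=%d up introns): median log2FC %.3f vs %.3f (p = %.3g)\n",
              x$association$k, x$association$median_high_retention,
              x$association$median_other_tested, x$association$p))
  invisible(x)
}

#' Run the bundled demonstration analysis
#'
#' One-command synthetic end-to-end run with default study conditions
#' (100 genes x 5 introns, 3 + 3 replicates).
#'
#' @param seed Integer seed.
#' @param out_dir Optional output directory for TSV tables and the manifest.
#' @return An `intronscape_run` object.
#' @export
demo_run <- function(seed = 1L, out_dir = NULL) {
  run_pipeline(pipeline_config(sim = sim_config(seed = seed), out_dir = out_dir))
}
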