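test_that("PY-tract worked examples and brute-force oracle agree", {
  expect_equal(py_tract_length(strrep("T", 50)), 50L)
  expect_equal(py_tract_length(strrep("A", 50)), 0L)
  expect_equal(py_tract_length(paste0(strrep("A", 25), strrep("T", 25))), 27L)
  expect_equal(py_tract_length("ACG"), 0L)          # shorter than one window
  expect_equal(py_tract_length(strrep("U", 50)), 50L)
  expect_error(py_tract_length("ACGTX"), "invalid characters")

  set.seed(52)
  for (i in 1:2000) {
    s <- random_dna_string(sample(c(5, 12, 50), 1),
                           alphabet = c("A", "C", "G", "T", "N"))
    expect_identical(py_tract_length(s), oracle_py_tract(s))
  }
})

test_that("converting purines to pyrimidines never shortens the PY tract", {
  set.seed(53)
  for (i in 1:300) {
    s <- strsplit(random_dna_string(50), "")[[1]]
    pur <- which(s %in% c("A", "G"))
    if (length(pur) == 0) next
    before <- py_tract_length(paste(s, collapse = ""))
    s[sample(pur, 1)] <- sample(c("C", "T"), 1)
    after <- py_tract_length(paste(s, collapse = ""))
    expect_gte(after, before)
  }
})

test_that("wmm scoring matches the analytic cases and a per-position oracle", {
  unif <- wmm_model(matrix(0.25, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_equal(score_splice_site("ACGTACGTA", unif), 0)

  # consensus weight 1 at 9 positions over a uniform background: 9 * log2(4) bits
  cons <- "GTAAGTAAA"
  probs <- sapply(strsplit(cons, "")[[1]], function(b) {
    p <- c(A = 0, C = 0, G = 0, T = 0); p[b] <- 1; p
  })
  expect_equal(score_splice_site(cons, wmm_model(probs)), 18)

  set.seed(54)
  for (i in 1:50) {
    raw <- matrix(rexp(36), 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
    probs <- sweep(raw, 2, colSums(raw), "/")
    m <- wmm_model(probs)
    s <- random_dna_string(9)
    expect_equal(score_splice_site(s, m),
                 oracle_wmm_score(s, m$probs, m$background), tolerance = 1e-12)
  }

  # additivity over positions
  m <- default_donor_model()
  s <- "CAGGTAAGT"
  singles <- sapply(1:9, function(i) {
    log2(m$probs[substr(s, i, i), i] / m$background[substr(s, i, i)])
  })
  expect_equal(score_splice_site(s, m), sum(singles))

  expect_true(is.na(score_splice_site("CAGGTNAGT", m)))
  expect_error(score_splice_site("CAGG", m), "width")
})

test_that("tabulated score models look k-mers up with optional defaults", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("kmer\tscore", "AAA\t1.5", "CCC\t-2"), f)
  m <- read_maxent_table(f)
  expect_equal(score_splice_site(c("AAA", "CCC"), m), c(1.5, -2))
  expect_error(score_splice_site("GGG", m), "absent")
  m2 <- read_maxent_table(f, default = 0)
  expect_equal(score_splice_site("GGG", m2), 0)
})

test_that("the unique splice-site filter removes ambiguous donor/acceptor pairings", {
  introns <- data.frame(
    contig = "c1", strand = "+",
    start = c(100L, 100L, 500L),          # first two share a donor
    end = c(200L, 300L, 600L),
    feature_id = c("a", "b", "c"), gene_id = "g", stringsAsFactors = FALSE
  )
  kept <- unique_ss_filter(introns)
  expect_identical(kept$feature_id, "c")

  two <- introns[c(1, 3), ]
  expect_identical(unique_ss_filter(two)$feature_id, c("a", "c"))
  expect_equal(nrow(unique_ss_filter(introns[0, ])), 0L)
})

test_that("feature computation handles GC with N exclusion and strand symmetry", {
  # hand-built genome: exon(4) + intron(60) + exon(4) on the plus strand
  intron_seq <- paste0("GTAAGT", strrep("A", 2), "GANC", strrep("G", 5),
                       strrep("C", 41), "AG")
  expect_equal(nchar(intron_seq), 60)
  plus_seq <- paste0("AAAG", intron_seq, "GTTT")
  genome <- Biostrings::DNAStringSet(c(c1 = plus_seq))
  introns <- data.frame(contig = "c1", start = 4L, end = 64L, strand = "+",
                        feature_id = "i1", gene_id = "g1", stringsAsFactors = FALSE)
  ft <- compute_features(introns, genome)
  expect_equal(ft$intron_length, 60)
  b <- strsplit(intron_seq, "")[[1]]
  expect_equal(ft$gc_fraction, mean(b[b != "N"] %in% c("G", "C")))

  # the same construct reverse-complemented and annotated on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(plus_seq)))
  genome_m <- Biostrings::DNAStringSet(c(c1 = rc))
  introns_m <- data.frame(contig = "c1", start = 4L, end = 64L, strand = "-",
                          feature_id = "i1", gene_id = "g1", stringsAsFactors = FALSE)
  ft_m <- compute_features(introns_m, genome_m)
  for (col in c("intron_length", "gc_fraction", "ss5_score", "ss3_score",
                "py_tract_length")) {
    expect_equal(ft_m[[col]], ft[[col]], info = col)
  }

  # GANC: N excluded from the GC denominator
  g2 <- Biostrings::DNAStringSet(c(c2 = "GANC"))
  i2 <- data.frame(contig = "c2", start = 0L, end = 4L, strand = "+",
                   feature_id = "x", gene_id = "g", stringsAsFactors = FALSE)
  expect_equal(compute_features(i2, g2)$gc_fraction, 2 / 3)
})

test_that("snoRNA hosting requires full containment on half-open intervals", {
  introns <- data.frame(contig = "c1", start = 50L, end = 500L, strand = "+",
                        feature_id = "i", gene_id = "g", stringsAsFactors = FALSE)
  sno <- function(s, e) data.frame(contig = "c1", start = s, end = e)
  expect_true(annotate_snorna_overlap(introns, sno(100L, 150L)))
  expect_false(annotate_snorna_overlap(introns, sno(480L, 520L)))
  expect_false(annotate_snorna_overlap(introns, sno(500L, 550L)))
  expect_true(annotate_snorna_overlap(introns, sno(480L, 520L), partial = TRUE))
  expect_false(annotate_snorna_overlap(introns, sno(500L, 550L), partial = TRUE))
})
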