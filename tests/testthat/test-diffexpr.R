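test_that("median-of-ratios size factors match the worked example and reference", {
  m <- matrix(c(10, 20, 30, 60), 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sf <- normalize_median_of_ratios(m)
  expect_equal(unname(sf$size_factors), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(sf$normalized[, 1], sf$normalized[, 2])

  ident <- matrix(rep(c(5, 50, 500), 3), 3,
                  dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(unname(normalize_median_of_ratios(ident)$size_factors), rep(1, 3))

  # genes with a zero are excluded from factor estimation but still normalized
  withzero <- rbind(m, g3 = c(0, 100))
  sf2 <- normalize_median_of_ratios(withzero)
  expect_equal(unname(sf2$size_factors), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(unname(sf2$normalized["g3", ]), c(0, 100 / sqrt(2)))

  set.seed(71)
  big <- matrix(rnbinom(600, mu = 200, size = 5) + 1, 100, 6,
                dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  expect_equal(unname(normalize_median_of_ratios(big)$size_factors),
               unname(DESeq2::estimateSizeFactorsForMatrix(big)),
               tolerance = 1e-8)

  expect_error(normalize_median_of_ratios(matrix(c(0, 1, 1, 0), 2)), "positive")
})

test_that("scaling one sample shifts the size factors and normalized counts coherently", {
  # with the geometric-mean pseudo-reference, scaling sample j by c multiplies
  # the ratio sf_j / sf_k (k != j) by c and rescales every normalized count by
  # the single constant c^(1/m)
  set.seed(72)
  m <- matrix(rpois(60, 100) + 1, 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  base <- normalize_median_of_ratios(m)
  m2 <- m; m2[, 3] <- m2[, 3] * 4
  scaled <- normalize_median_of_ratios(m2)
  expect_equal(scaled$size_factors[3] / scaled$size_factors[1],
               4 * base$size_factors[3] / base$size_factors[1],
               tolerance = 1e-12)
  expect_equal(scaled$normalized, base$normalized * 4^(1 / 6), tolerance = 1e-9)
  # hence relative expression between samples is untouched
  expect_equal(scaled$normalized[, 3] / scaled$normalized[, 1],
               base$normalized[, 3] / base$normalized[, 1], tolerance = 1e-12)
})

test_that("differential expression applies the read filter and thresholds", {
  set.seed(73)
  n <- 50
  design <- factor(rep(c("WT", "KO"), each = 3), levels = c("WT", "KO"))
  cnt <- matrix(rnbinom(n * 6, mu = 300, size = 300), n, 6,
                dimnames = list(sprintf("g%02d", 1:n), paste0(design, "_", 1:3)))
  cnt[1, ] <- c(8, 8, 8, 8, 8, 9)        # 49 raw reads in total
  cnt[2:6, 4:6] <- rnbinom(15, mu = 60, size = 300)   # strong true down genes
  de <- differential_expression(cnt, design)
  expect_identical(de$call[1], "filtered")
  expect_true(is.na(de$fdr[1]))
  expect_identical(de$call[2:6], rep("down", 5))
  expect_true(all(de$call %in% c("up", "down", "ns", "filtered")))

  # deterministic re-run
  expect_identical(de, differential_expression(cnt, design))

  # log2FC is antisymmetric under condition swap
  de_swap <- differential_expression(cnt, factor(design, levels = c("KO", "WT")))
  tested <- de$call != "filtered"
  expect_equal(de$log2fc[tested], -de_swap$log2fc[tested], tolerance = 1e-12)
})

test_that("knockout comparison partitions calls and quantifies the overlap", {
  de <- structure(data.frame(
    gene_id = sprintf("g%03d", 1:200),
    call = c(rep("down", 40), rep("up", 10), rep("ns", 150)),
    stringsAsFactors = FALSE
  ), class = c("de_results", "data.frame"))
  res_same <- suppressWarnings(compare_kos(de, de))
  expect_equal(res_same$down$both, 40)
  expect_equal(res_same$down$only_1, 0)
  expect_equal(res_same$down_overlap$shared_fraction, 1)

  de2 <- de
  de2$call <- c(rep("ns", 20), rep("down", 40), rep("ns", 140))
  res <- compare_kos(de, de2)
  expect_equal(res$down$both, 20)
  expect_equal(res$down$only_1, 20)
  expect_equal(res$down$only_2, 20)
  expect_equal(res$down_overlap$shared_fraction, 0.5)

  de3 <- de
  de3$call <- c(rep("ns", 40), rep("down", 40), rep("ns", 120))
  expect_equal(compare_kos(de, de3)$down$both, 0)
})

test_that("a shared-effect cohort recovers its designed knockout overlap", {
  set.seed(74)
  design <- factor(rep(c("WT", "KO"), each = 3), levels = c("WT", "KO"))
  n_u <- 2000L; n_down <- 200L; n_shared <- 140L   # 70% of line-2 calls shared
  down1 <- seq_len(n_down)
  down2 <- c(seq_len(n_shared), n_down + seq_len(n_down - n_shared))
  mk <- function(down_idx) {
    mu <- matrix(500, n_u, 6)
    mu[down_idx, design == "KO"] <- round(500 * 2^-1.5)
    matrix(rnbinom(n_u * 6, mu = mu, size = 300), n_u, 6,
           dimnames = list(sprintf("g%04d", seq_len(n_u)), paste0(design, 1:3)))
  }
  ko <- suppressWarnings(compare_kos(differential_expression(mk(down1), design),
                                     differential_expression(mk(down2), design)))
  expect_lt(abs(ko$down_overlap$shared_fraction - 0.7), 0.1)
  expect_lt(ko$down_overlap$p, 1e-10)
})
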