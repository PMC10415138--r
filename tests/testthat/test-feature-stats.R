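test_that("modified Z-score matches its definition and handles degenerate spread", {
  z <- modified_zscore(c(1, 2, 3, 4, 5), c("B", "B", "B", "A", "A"))
  expect_equal(z$global_median[1], 3)
  expect_equal(z$mad[1], 1)
  expect_equal(z$z[z$group == "A"], 1.5)

  # group median equal to the global median gives z = 0
  z0 <- modified_zscore(c(1, 3, 5, 3), c("a", "b", "a", "b"))
  expect_equal(z0$z[z0$group == "b"], 0)

  expect_warning(res <- modified_zscore(rep(2, 6), rep(c("a", "b"), 3)), "MAD")
  expect_true(all(is.na(res$z)))

  # delta_z is relative to the ns baseline
  zd <- modified_zscore(c(1:8), rep(c("up", "ns"), each = 4))
  expect_equal(zd$delta_z[zd$group == "ns"], 0)
  expect_equal(zd$delta_z[zd$group == "up"],
               zd$z[zd$group == "up"] - zd$z[zd$group == "ns"])
})

test_that("modified Z-score agrees with direct evaluation on random configurations", {
  set.seed(61)
  for (i in 1:200) {
    v <- rnorm(sample(10:60, 1))
    g <- sample(c("up", "down", "ns"), length(v), replace = TRUE)
    if (length(unique(g)) < 2) next
    z <- modified_zscore(v, g)
    for (gg in unique(g)) {
      expect_equal(z$z[z$group == gg], oracle_modified_z(v, g, gg),
                   tolerance = 1e-12)
    }
    # location/scale equivariance
    z2 <- modified_zscore((v - 3.7) / 2.5, g)
    expect_equal(z2$z, z$z, tolerance = 1e-9)
  }
})

test_that("Wilcoxon exact mode equals full enumeration for small tie-free samples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 4), c(2, 3))$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty")

  set.seed(62)
  for (nx in 1:5) for (ny in 1:5) {
    if (nx + ny > 10 || nx + ny < 3) next
    for (rep in 1:5) {
      v <- sample(seq_len(50), nx + ny)   # distinct -> tie-free
      x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
      ours <- wilcoxon_rank_sum(x, y)
      expect_identical(ours$mode, "exact")
      expect_equal(ours$p, oracle_wilcoxon_exact(x, y), tolerance = 1e-12)
    }
  }
})

test_that("Wilcoxon normal approximation matches the reference implementation", {
  set.seed(63)
  for (i in 1:20) {
    x <- rnorm(50); y <- rnorm(50, 0.3)
    ours <- wilcoxon_rank_sum(x, y)
    expect_identical(ours$mode, "normal_approx")
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_lt(abs(ours$p - ref$p.value), 1e-6)
  }
  # tie correction path
  x <- rep(1:5, 6); y <- rep(2:6, 6)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_lt(abs(wilcoxon_rank_sum(x, y)$p - ref$p.value), 1e-6)
})

test_that("chi-squared 2x2 follows the closed form with its invariances", {
  tab <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE)
  res <- chi_squared_2x2(tab)
  expect_equal(res$chi2, 60 * (400 - 100)^2 / 810000)  # = 6.6667
  expect_equal(res$chi2, 20 / 3, tolerance = 1e-12)
  expect_equal(res$p, pchisq(20 / 3, 1, lower.tail = FALSE))

  expect_equal(chi_squared_2x2(matrix(c(10, 10, 10, 10), 2))$chi2, 0)
  expect_equal(chi_squared_2x2(matrix(c(10, 10, 10, 10), 2))$p, 1)

  expect_lt(chi_squared_2x2(tab, yates = TRUE)$chi2, res$chi2)

  # invariant under transposition and row/column swaps
  expect_equal(chi_squared_2x2(t(tab))$chi2, res$chi2)
  expect_equal(chi_squared_2x2(tab[2:1, ])$chi2, res$chi2)
  expect_equal(chi_squared_2x2(tab[, 2:1])$chi2, res$chi2)

  # cross-check against the standard implementation on random tables
  set.seed(64)
  for (i in 1:25) {
    m <- matrix(rpois(4, 30) + 1, 2)
    expect_equal(suppressWarnings(chi_squared_2x2(m))$chi2,
                 unname(chisq.test(m, correct = FALSE)$statistic),
                 tolerance = 1e-10)
    expect_equal(suppressWarnings(chi_squared_2x2(m, yates = TRUE))$chi2,
                 unname(chisq.test(m, correct = TRUE)$statistic),
                 tolerance = 1e-10)
  }

  expect_error(chi_squared_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "marginal")
  expect_warning(chi_squared_2x2(matrix(c(2, 3, 3, 2), 2)), "expected")
})

test_that("overlap analysis reports the shared fraction and delegates the test", {
  u <- sprintf("g%05d", 1:10000)
  a <- u[1:100]; b <- u[c(1:47, 101:153)]
  res <- suppressWarnings(overlap_analysis(a, b, u))
  expect_equal(res$shared_fraction, 0.47)
  direct <- suppressWarnings(
    chi_squared_2x2(matrix(c(47, 53, 53, 9847), 2, byrow = TRUE)))
  expect_equal(res$chi2, direct$chi2)
  expect_equal(res$p, direct$p)

  expect_equal(suppressWarnings(overlap_analysis(a, a, u))$shared_fraction, 1)
  expect_equal(suppressWarnings(overlap_analysis(a, u[200:299], u))$shared_fraction, 0)
  expect_error(overlap_analysis(a, b, character(0)), "empty universe")
})

test_that("Benjamini-Hochberg adjustment follows the step-up recurrence", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0,1\\]")
  # step-up transform: adjusted >= raw and order-preserving
  p <- c(0.001, 0.01, 0.02, 0.5)
  adj <- benjamini_hochberg(p)
  expect_true(all(adj >= p))
  expect_identical(order(adj), order(p))
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("expression association recovers coupling and degrades gracefully", {
  calls <- data.frame(
    site_id = sprintf("g%02d.i%d", rep(1:20, each = 3), 1:3),
    group = "ns", stringsAsFactors = FALSE
  )
  # genes 1..5 get two up-retained introns each
  calls$group[calls$site_id %in% sprintf("g%02d.i%d", rep(1:5, each = 2), 1:2)] <- "up"
  map <- data.frame(intron_id = calls$site_id,
                    gene_id = substr(calls$site_id, 1, 3), stringsAsFactors = FALSE)
  de <- data.frame(gene_id = c(sprintf("g%02d", 1:20), "x1", "x2"),
                   log2fc = c(rep(-1, 5), rep(0, 15), 0.2, -0.2),
                   stringsAsFactors = FALSE)
  res <- expression_association(de, calls, map, k = 2)
  expect_equal(res$n_high_retention, 5)
  expect_equal(res$median_high_retention, -1)
  expect_equal(res$median_other_tested, 0)
  expect_equal(res$median_other_genes, 0)
  expect_lt(res$p, 0.01)

  # k beyond any gene's up-intron count empties the partition
  expect_message(res2 <- expression_association(de, calls, map, k = 5),
                 "empty")
  expect_true(is.na(res2$p))
})

test_that("group feature stats assemble the Z and p matrices coherently", {
  set.seed(65)
  n <- 300
  grp <- sample(c("up", "down", "ns"), n, replace = TRUE, prob = c(.2, .1, .7))
  ft <- data.frame(
    intron_length = round(rlnorm(n, 7, .5) * ifelse(grp == "up", 0.35, 1)),
    py_tract_length = pmax(0, round(rnorm(n, 25, 5)) - 10 * (grp == "up")),
    group = grp
  )
  gs <- group_feature_stats(ft)
  expect_identical(rownames(gs$z_matrix), c("intron_length", "py_tract_length"))
  expect_identical(colnames(gs$p_matrix), c("up_vs_ns", "down_vs_ns", "up_vs_down"))
  expect_true(all(gs$delta_z_matrix[, "up"] < 0))
  expect_equal(unname(gs$delta_z_matrix[, "ns"]), c(0, 0))
  expect_true(all(gs$p_matrix[, "up_vs_ns"] < 0.01))
  # p-values match direct Wilcoxon calls
  direct <- wilcoxon_rank_sum(ft$intron_length[grp == "up"],
                              ft$intron_length[grp == "ns"])$p
  expect_equal(gs$p_matrix["intron_length", "up_vs_ns"], direct)
})
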