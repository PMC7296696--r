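# Frozen expected values were computed by hand or with the independent
# oracles in helper-oracles.R before being asserted here.

test_that("quantile ranks map ascending ranks onto 1..100 with ceiling and average ties", {
  expect_equal(unname(quantile_ranks(c(a = 1, b = 2, c = 3, d = 4))),
               c(25, 50, 75, 100))
  x <- stats::runif(200)
  q <- quantile_ranks(x)
  expect_equal(q[which.max(x)][[1]], 100L)
  expect_equal(q[which.min(x)][[1]], 1L)
  expect_true(all(q >= 1 & q <= 100))

  # ties get the average rank before the ceiling
  expect_equal(unname(quantile_ranks(c(1, 2, 2, 3))),
               as.integer(ceiling(100 * c(1, 2.5, 2.5, 4) / 4)))
  expect_error(quantile_ranks(rep(3, 5)), "constant")
})

test_that("pooling counts every pathway occurrence and drops empty bins", {
  q1 <- c(g1 = 50L, g2 = 50L)
  expect_equal(pool_quantiles(list(q1), gene_set("i", "g1"))$fraction, 50)

  # a gene important in two pathways contributes twice
  q2 <- list(c(shared = 40L), c(shared = 40L))
  tab <- pool_quantiles(q2, gene_set("i", "shared"))
  expect_equal(tab$n_important, 2L)
  expect_equal(tab$n_total, 2L)

  tab2 <- pool_quantiles(list(c(a = 10L, b = 90L)), gene_set("i", "a"))
  expect_equal(tab2$quantile, c(10L, 90L))  # no empty bins
  expect_true(all(tab2$n_total >= tab2$n_important))
  expect_true(all(tab2$fraction >= 0 & tab2$fraction <= 100))
})

test_that("quantile regression reproduces closed-form OLS including adjusted r-squared", {
  exact <- data.frame(quantile = 1:3, fraction = c(10, 20, 30))
  f <- suppressWarnings(fit_quantile_regression(exact))  # exact fit: summary.lm warns
  expect_equal(f$coefficients$estimate, c(0, 10), tolerance = 1e-12)
  expect_equal(f$adj_r_squared, 1, tolerance = 1e-12)

  flat <- data.frame(quantile = 1:3, fraction = rep(10, 3))
  expect_equal(suppressWarnings(fit_quantile_regression(flat))$coefficients$estimate[2],
               0, tolerance = 1e-12)

  pts <- data.frame(quantile = 1:4, fraction = c(1, 3, 2, 4))
  f2 <- fit_quantile_regression(pts)
  expect_equal(f2$coefficients$estimate, c(0.5, 0.8), tolerance = 1e-12)
  h <- ols_hand(pts$quantile, pts$fraction)
  expect_equal(f2$coefficients$std.error[2], h$se_slope, tolerance = 1e-12)
  expect_equal(f2$coefficients$p.value[2], h$p_slope, tolerance = 1e-12)
  expect_equal(f2$adj_r_squared, h$adj_r2, tolerance = 1e-12)

  expect_error(fit_quantile_regression(pts[1:2, ]), ">= 3")
})

test_that("z-normalization centres, scales by sample sd, and is affine-invariant", {
  expect_equal(unname(znormalize(c(1, 2, 3))), c(-1, 0, 1))
  x <- stats::rnorm(50, 10, 4)
  z <- znormalize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_equal(znormalize(2 * x + 5), z, tolerance = 1e-10)
  expect_error(znormalize(rep(1, 4)), "zero-variance")
})

test_that("one-sided KS statistic and p-value follow the explicit CDF definition", {
  r <- ks_cdf_compare(c(3, 4), c(1, 2))
  expect_equal(r$statistic, 1)
  expect_equal(r$p.value, exp(-2 * 1 * 2 * 2 / 4), tolerance = 1e-12)

  same <- ks_cdf_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  # shift in the unfavourable direction clamps at zero
  rev <- ks_cdf_compare(c(1, 2), c(3, 4))
  expect_equal(rev$statistic, 0)
  expect_error(ks_cdf_compare(numeric(0), 1), "non-empty")
})

test_that("welch test matches the hand formula with Welch-Satterthwaite df", {
  w <- welch_test(c(3, 4, 5), c(1, 2, 3))
  expect_equal(w$statistic, 2 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(w$df, 4, tolerance = 1e-12)
  expect_equal(w$p.value, stats::pt(2 / sqrt(2 / 3), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(w$p.value, 0.035242, tolerance = 1e-4)

  same <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 0.5)

  set.seed(3)
  big <- welch_test(stats::rnorm(10, 10, 1), stats::rnorm(10, 0, 1))
  expect_lt(big$p.value, 1e-6)

  expect_false(welch_test(1, c(1, 2))$testable)
})

test_that("wilcoxon test: exact tail by enumeration, ties via normal approximation", {
  r <- wilcoxon_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r$statistic, 9)
  expect_equal(r$p.value, 1 / 20)  # 1 of choose(6,3) assignments as extreme
  expect_true(r$exact)

  same <- wilcoxon_test(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p.value, 0.5)
  rev <- wilcoxon_test(c(1, 2, 3), c(4, 5, 6))
  expect_gt(rev$p.value, 0.5)

  # tie-laden large samples switch to the corrected normal approximation
  set.seed(9)
  x <- sample(1:5, 40, replace = TRUE); y <- sample(1:5, 40, replace = TRUE)
  rt <- wilcoxon_test(x, y)
  expect_false(rt$exact)
  ref <- stats::wilcox.test(x, y, alternative = "greater",
                            exact = FALSE, correct = FALSE)
  expect_equal(rt$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("BH adjustment matches the step-up formula and dominates Bonferroni", {
  b <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(b$p_adjusted, rep(0.04, 4), tolerance = 1e-12)
  expect_equal(bh_fdr(0.5)$p_adjusted, 0.5)
  expect_true(all(bh_fdr(rep(0, 5))$rejected))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(15)
  for (i in 1:20) {
    p <- stats::runif(sample(3:40, 1))^2
    expect_equal(bh_fdr(p)$p_adjusted, bh_hand(p), tolerance = 1e-12)
    bonf <- stats::p.adjust(p, "bonferroni") < 0.05
    expect_true(all(bonf <= bh_fdr(p)$rejected))  # BH rejects a superset
  }
})

test_that("fisher-z comparison matches the atanh arithmetic", {
  expect_equal(fisher_z(0.5, 0.5, 50, 50)$z, 0)
  expect_equal(fisher_z(0.5, 0.5, 50, 50)$p.value, 1)
  fz <- fisher_z(0.9, 0.3, 100, 100)
  expect_equal(fz$z, (atanh(0.9) - atanh(0.3)) / sqrt(2 / 97), tolerance = 1e-12)
  expect_equal(fz$z, 8.0973, tolerance = 1e-4)
  expect_error(fisher_z(0.5, 0.5, 3, 50), "n > 3")
})

test_that("per-pathway tests form FDR families per test type and skip untestables", {
  co <- generate_cohort(synthetic_spec(n_pathways = 10, seed = 31))
  profs <- lapply(co$graphs, pagerank_centrality, variant = "ssc")
  tt <- pathway_tests(profs, co$important)
  expect_equal(nrow(tt), 10L)
  expect_true(all(tt$welch_p >= 0 & tt$welch_p <= 1, na.rm = TRUE))
  ok <- !is.na(tt$welch_p)
  expect_equal(tt$welch_p_adj[ok],
               bh_hand(tt$welch_p[ok]), tolerance = 1e-12)
  expect_equal(tt$wilcoxon_p_adj[!is.na(tt$wilcoxon_p)],
               bh_hand(tt$wilcoxon_p[!is.na(tt$wilcoxon_p)]), tolerance = 1e-12)

  # a profile whose pathway has no important genes is untestable
  lone <- pagerank_centrality(path_graph(c("q1", "q2", "q3")), "ssc")
  tt2 <- pathway_tests(c(profs, list(lone)), co$important)
  expect_true(is.na(tt2$welch_p[11]))
  expect_false(tt2$welch_significant[11])
})

test_that("the validation pipeline is deterministic and reports every configured model", {
  co <- generate_cohort(synthetic_spec(n_pathways = 25, seed = 17))
  m <- data.frame(model = c("degree", "pagerank", "katz"),
                  variant = c("ssc", "ssc", "ssc"))
  v1 <- ssc_validation(co, models = m)
  v2 <- ssc_validation(co, models = m)
  expect_identical(v1$regression, v2$regression)
  expect_identical(v1$tests, v2$tests)
  expect_setequal(unique(v1$regression$model), m$model)
  expect_equal(nrow(v1$ks), 3L)
  expect_s3_class(v1, "ssc_validation")
  expect_output(print(v1), "ssc_validation")
  s <- summary(v1)
  expect_s3_class(s, "summary.ssc_validation")

  d <- file.path(tempdir(), "vrep")
  write_validation_report(v1, d)
  expect_true(all(file.exists(file.path(
    d, c("regression.tsv", "pathway_tests.tsv", "ks.tsv", "summary.json")))))
})

test_that("sensitivity scan covers the grid and compares SSC to undirected via fisher-z", {
  co <- generate_cohort(synthetic_spec(n_pathways = 20, seed = 53))
  fl <- filter_pathways(co$graphs, co$important,
                        models = data.frame(model = "pagerank", variant = "ssc"))
  tab <- sensitivity_scan(fl$kept, co$important, alphas = c(0.3, 0.6, 0.85))
  expect_equal(nrow(tab), 3 * 4)
  expect_setequal(unique(tab$variant), c("source", "sink", "ssc", "undirected"))
  ssc_rows <- tab[tab$variant == "ssc", ]
  expect_true(all(is.finite(ssc_rows$fisher_z)))
  expect_true(all(is.na(tab$fisher_z[tab$variant == "source"])))
  # fisher-z rows agree with direct recomputation from the stored correlations
  for (i in seq_len(nrow(ssc_rows))) {
    und <- tab[tab$variant == "undirected" & tab$alpha == ssc_rows$alpha[i], ]
    fz <- fisher_z(ssc_rows$r[i], und$r, ssc_rows$n_bins[i], und$n_bins)
    expect_equal(ssc_rows$fisher_z[i], fz$z, tolerance = 1e-12)
  }
  # the default grid has 81 alpha values
  expect_length(seq(0.1, 0.9, by = 0.01), 81L)
})

test_that("pooled CDF quantiles z-normalize within pathways before pooled ranking", {
  co <- generate_cohort(synthetic_spec(n_pathways = 6, seed = 61))
  profs <- lapply(co$graphs, katz_centrality, variant = "ssc")
  cq <- pooled_cdf_quantiles(profs, co$important)
  expect_equal(nrow(cq), sum(vapply(co$graphs, n_nodes, 1L)))
  expect_true(all(cq$quantile >= 1 & cq$quantile <= 100))
  # affine shifts must not change the pooled quantiles (up to floating-point
  # splitting of exact cross-pathway ties in the ranking)
  shifted <- lapply(profs, function(p) { p$scores <- 3 * p$scores + 7; p })
  cq2 <- pooled_cdf_quantiles(shifted, co$important)
  expect_lte(max(abs(cq2$quantile - cq$quantile)), 1)
  expect_gt(mean(cq2$quantile == cq$quantile), 0.95)
})
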