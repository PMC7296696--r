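#' Within-pathway quantile ranks
#'
#' Ranks the nodes of one pathway ascending by centrality score and maps
#' the ranks onto 100 quantiles: `Q(v) = ceiling(100 * rank(v) / n)`. The
#' maximum-score node lands in quantile 100, the lowest in quantile
#' `ceiling(100 / n)` (quantile 1 once `n >= 100`). Ties take average
#' ranks before the ceiling (deterministic, order-independent, and
#' consistent with the Wilcoxon tie convention used in the two-sample
#' tests). A constant profile is a contract error -- the pathway filter
#' removes those upstream.
#'
#' @param profile a `centrality_profile`, or a bare numeric score vector.
#' @return integer vector of quantile scores in 1..100, named by node.
#' @export
quantile_ranks <- function(profile) {
  scores <- if (inherits(profile, "centrality_profile")) profile$scores else profile
  if (length(scores) < 1L) stop("empty profile")
  if (diff(range(scores)) == 0) {
    stop("constant centrality profile: quantile ranking undefined ",
         "(the pathway filter should have excluded this pathway)")
  }
  r <- rank(scores, ties.method = "average")
  q <- as.integer(ceiling(100 * r / length(scores)))
  names(q) <- names(scores)
  q
}

#' Pool quantile counts across pathways
#'
#' Builds the per-quantile table of pooled important and total gene
#' counts. A gene occurring in several pathways contributes one
#' observation per pathway (each occurrence is a distinct observation).
#' The importance fraction is `F_i = 100 * important_i / total_i` per
#' populated quantile; empty quantiles are omitted.
#'
#' @param quantiles list of per-pathway quantile vectors (named by node
#'   id), as produced by [quantile_ranks()].
#' @param important a `gene_set`.
#' @return data frame of class `quantile_table` with columns `quantile`,
#'   `n_important`, `n_total`, `fraction` (percent).
#' @export
pool_quantiles <- function(quantiles, important) {
  stopifnot(inherits(important, "gene_set"), length(quantiles) >= 1L)
  q <- unlist(quantiles, use.names = FALSE)
  nm <- unlist(lapply(quantiles, names), use.names = FALSE)
  imp <- nm %in% important$genes
  tot <- tabulate(q, nbins = 100L)
  impc <- tabulate(q[imp], nbins = 100L)
  keep <- tot > 0L
  out <- data.frame(quantile = seq_len(100L)[keep],
                    n_important = impc[keep], n_total = tot[keep],
                    fraction = 100 * impc[keep] / tot[keep])
  class(out) <- c("quantile_table", "data.frame")
  out
}

#' Ordinary least-squares fit of importance fraction on quantile
#'
#' Fits `fraction = a1 * quantile + a0` by OLS over the populated
#' quantiles and reports the coefficient table plus the adjusted
#' r-squared.
#'
#' @param table a `quantile_table` from [pool_quantiles()], or any data
#'   frame with columns `quantile` and `fraction`.
#' @return object of class `quantile_fit`: list with `coefficients` (data
#'   frame: `term, estimate, std.error, statistic, p.value`),
#'   `adj_r_squared`, `r` (signed correlation), `n`, and the underlying
#'   `lm` fit.
#' @export
fit_quantile_regression <- function(table) {
  if (nrow(table) < 3L) {
    stop("need >= 3 populated quantile bins for the regression, got ",
         nrow(table))
  }
  fit <- stats::lm(fraction ~ quantile, data = table)
  s <- summary(fit)
  co <- as.data.frame(s$coefficients)
  names(co) <- c("estimate", "std.error", "statistic", "p.value")
  co <- cbind(term = c("(Intercept)", "Coefficient"), co)
  rownames(co) <- NULL
  structure(
    list(coefficients = co, adj_r_squared = s$adj.r.squared,
         r = stats::cor(table$quantile, table$fraction),
         n = nrow(table), fit = fit),
    class = "quantile_fit"
  )
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat("<quantile_fit> slope = ", format(x$coefficients$estimate[2], digits = 4),
      " (p = ", format(x$coefficients$p.value[2], digits = 3),
      "), adj r^2 = ", format(x$adj_r_squared, digits = 3),
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Z-normalize a centrality profile within its pathway
#'
#' `(C(v) - mean) / sd` using the sample (n-1 denominator) standard
#' deviation; affine-invariant and mean-centred by construction. A
#' zero-variance profile is a contract error.
#'
#' @param profile a `centrality_profile` or numeric vector.
#' @return numeric vector of normalized scores (named by node).
#' @export
znormalize <- function(profile) {
  scores <- if (inherits(profile, "centrality_profile")) profile$scores else profile
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0) stop("zero-variance profile: z-normalization undefined")
  (scores - mean(scores)) / s
}

#' Pooled CDF quantile scores
#'
#' The cumulative-density comparison operates on a second, pooled kind of
#' quantile (distinct from the within-pathway [quantile_ranks()]): scores
#' are z-normalized within each pathway, pooled across pathways, and the
#' pooled sample is placed into 100 quantiles by pooled rank. Returns the
#' pooled quantile score per observation plus its importance flag.
#'
#' @param profiles list of `centrality_profile`s (one per pathway, same
#'   model/variant).
#' @param important a `gene_set`.
#' @return data frame with columns `node_id`, `pathway_id`, `quantile`,
#'   `important`.
#' @export
pooled_cdf_quantiles <- function(profiles, important) {
  z <- lapply(profiles, znormalize)
  v <- unlist(z, use.names = FALSE)
  nm <- unlist(lapply(z, names), use.names = FALSE)
  pid <- rep(vapply(profiles, function(p) p$pathway_id, ""),
             vapply(z, length, 1L))
  r <- rank(v, ties.method = "average")
  data.frame(node_id = nm, pathway_id = pid,
             quantile = as.integer(ceiling(100 * r / length(v))),
             important = nm %in% important$genes,
             stringsAsFactors = FALSE)
}

#' One-sided two-sample Kolmogorov-Smirnov comparison
#'
#' Tests whether the CDF of the important genes' scores lies below that of
#' the other genes (i.e. important genes shifted towards higher values):
#' `D = sup_x (F_other(x) - F_important(x))`, clamped at 0, with the
#' asymptotic one-sided p-value `exp(-2 D^2 m n / (m + n))`.
#'
#' @param important_scores,other_scores numeric samples (non-empty).
#' @return list with `statistic` and `p.value`.
#' @export
ks_cdf_compare <- function(important_scores, other_scores) {
  if (!length(important_scores) || !length(other_scores)) {
    stop("both samples must be non-empty for the KS comparison")
  }
  m <- length(important_scores); n <- length(other_scores)
  x <- sort(unique(c(important_scores, other_scores)))
  F_imp <- vapply(x, function(t) mean(important_scores <= t), 0)
  F_oth <- vapply(x, function(t) mean(other_scores <= t), 0)
  D <- max(0, F_oth - F_imp)
  p <- min(1, exp(-2 * D^2 * m * n / (m + n)))
  list(statistic = D, p.value = p)
}

#' One-sided Welch two-sample t-test
#'
#' Tests whether important genes have a higher mean raw centrality than
#' the other genes: `t = (mean_imp - mean_oth) / sqrt(s2_imp/N_imp +
#' s2_oth/N_oth)` with Welch-Satterthwaite degrees of freedom and the
#' one-sided alternative `mean_imp > mean_oth`.
#'
#' @param important_scores,other_scores numeric samples with >= 2
#'   observations each (variances must be defined).
#' @return list with `statistic`, `df`, `p.value`, `n_important`,
#'   `n_other`; or a list with `testable = FALSE` when a group is too
#'   small (excluded from any FDR family).
#' @export
welch_test <- function(important_scores, other_scores) {
  n1 <- length(important_scores); n2 <- length(other_scores)
  if (n1 < 2L || n2 < 2L) {
    return(list(testable = FALSE, statistic = NA_real_, df = NA_real_,
                p.value = NA_real_, n_important = n1, n_other = n2))
  }
  v1 <- stats::var(important_scores); v2 <- stats::var(other_scores)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    # identical constant groups: no evidence either way
    return(list(testable = TRUE, statistic = 0, df = n1 + n2 - 2,
                p.value = 0.5, n_important = n1, n_other = n2))
  }
  t <- (mean(important_scores) - mean(other_scores)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(testable = TRUE, statistic = t, df = df,
       p.value = stats::pt(t, df, lower.tail = FALSE),
       n_important = n1, n_other = n2)
}

#' One-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Alternative: important genes stochastically larger. Uses the exact
#' Mann-Whitney distribution when the combined sample size is <= 50 and
#' there are no ties; otherwise the normal approximation with average-rank
#' tie correction (no continuity correction).
#'
#' @param important_scores,other_scores non-empty numeric samples.
#' @return list with `statistic` (the Mann-Whitney U of the important
#'   group), `p.value`, `exact` flag, `n_important`, `n_other`.
#' @export
wilcoxon_test <- function(important_scores, other_scores) {
  n1 <- length(important_scores); n2 <- length(other_scores)
  if (!n1 || !n2) stop("both samples must be non-empty for the Wilcoxon test")
  all_x <- c(important_scores, other_scores)
  r <- rank(all_x, ties.method = "average")
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(all_x) > 0L
  N <- n1 + n2
  if (!ties && N <= 50L) {
    p <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    return(list(statistic = U, p.value = p, exact = TRUE,
                n_important = n1, n_other = n2))
  }
  tie_tab <- table(all_x)
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 == 0) {
    return(list(statistic = U, p.value = 0.5, exact = FALSE,
                n_important = n1, n_other = n2))
  }
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  list(statistic = U, p.value = stats::pnorm(z, lower.tail = FALSE),
       exact = FALSE, n_important = n1, n_other = n2)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard BH step-up adjustment (monotonicity enforced); the rejection
#' flag is `p_adj < level`. One family should contain all pathways for one
#' (model, variant, test type).
#'
#' @param p numeric p-values in \[0, 1\] (NAs pass through unadjusted and
#'   are never flagged).
#' @param level FDR level (default 0.05).
#' @return list with `p_adjusted` and logical `rejected`.
#' @export
bh_fdr <- function(p, level = 0.05) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  adj <- rep(NA_real_, length(p))
  adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  list(p_adjusted = adj, rejected = !is.na(adj) & adj < level)
}

#' Fisher-Z comparison of two correlation coefficients
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p-value; used to compare the linear-fit correlations
#' of two centrality variants.
#'
#' @param r1,r2 correlation coefficients.
#' @param n1,n2 numbers of points behind each correlation (> 3).
#' @return list with `z` and `p.value`.
#' @export
fisher_z <- function(r1, r2, n1, n2) {
  if (n1 <= 3 || n2 <= 3) stop("Fisher-Z comparison needs n > 3 per fit")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p.value = 2 * stats::pnorm(-abs(z)))
}

#' Per-pathway two-sample tests with FDR control
#'
#' Runs the Welch and Wilcoxon one-sided tests (important > other, raw
#' centrality values) within each pathway for one model/variant, then
#' applies BH-FDR separately per test type (one family per centrality
#' method and test, matching the per-method correction). Pathways where a
#' group is empty (or too small for Welch) are marked untestable and kept
#' out of the FDR family.
#'
#' @param profiles list of `centrality_profile`s (one per pathway).
#' @param important a `gene_set`.
#' @param level FDR level.
#' @return data frame with one row per pathway: test statistics, raw and
#'   adjusted p-values, rejection flags, group sizes.
#' @export
pathway_tests <- function(profiles, important, level = 0.05) {
  rows <- lapply(profiles, function(p) {
    imp <- p$scores[names(p$scores) %in% important$genes]
    oth <- p$scores[!(names(p$scores) %in% important$genes)]
    w <- if (length(imp) && length(oth)) welch_test(imp, oth) else
      list(testable = FALSE, statistic = NA_real_, df = NA_real_, p.value = NA_real_)
    wx <- if (length(imp) && length(oth)) wilcoxon_test(imp, oth) else
      list(statistic = NA_real_, p.value = NA_real_)
    data.frame(pathway_id = p$pathway_id, model = p$model, variant = p$variant,
               n_important = length(imp), n_other = length(oth),
               welch_t = w$statistic, welch_p = w$p.value,
               wilcoxon_stat = wx$statistic, wilcoxon_p = wx$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  fw <- bh_fdr(out$welch_p, level)
  fx <- bh_fdr(out$wilcoxon_p, level)
  out$welch_p_adj <- fw$p_adjusted
  out$welch_significant <- fw$rejected
  out$wilcoxon_p_adj <- fx$p_adjusted
  out$wilcoxon_significant <- fx$rejected
  out
}

#' Run the full validation pipeline
#'
#' For each configured (model, variant): compute centrality profiles on
#' the filtered pathways, pool within-pathway quantile ranks, fit the
#' importance-fraction regression, compare pooled CDFs of important vs
#' other genes (one-sided KS), and run the per-pathway Welch/Wilcoxon
#' tests with BH-FDR control.
#'
#' @param graphs list of `pathway_graph`s, or a `synthetic_cohort`.
#' @param important a `gene_set` (taken from the cohort if omitted).
#' @param models model/variant grid (default [default_models()]).
#' @param filter apply [filter_pathways()] first (default TRUE).
#' @param fdr_level FDR level for the per-pathway tests.
#' @param katz_alpha Katz dampening factor (also used by the filter).
#' @return object of class `ssc_validation`: list with `filter_report`,
#'   `regression` (per model/variant coefficient rows + adj r-squared),
#'   `fits` (list of `quantile_fit`s), `ks` (per model/variant KS results),
#'   `tests` (per-pathway test table), `models`, `n_pathways`.
#' @export
ssc_validation <- function(graphs, important = NULL, models = default_models(),
                           filter = TRUE, fdr_level = 0.05, katz_alpha = 0.1) {
  if (inherits(graphs, "synthetic_cohort")) {
    if (is.null(important)) important <- graphs$important
    graphs <- graphs$graphs
  }
  stopifnot(inherits(important, "gene_set"))
  if (filter) {
    fl <- filter_pathways(graphs, important, katz_alpha = katz_alpha,
                          models = models)
    report <- fl$report
    graphs <- fl$kept
  } else {
    report <- NULL
  }
  if (length(graphs) < 1L) stop("no pathways left after filtering")
  keys <- paste(models$model, models$variant, sep = ".")
  fits <- vector("list", nrow(models)); names(fits) <- keys
  ks <- vector("list", nrow(models))
  reg_rows <- vector("list", nrow(models))
  test_rows <- vector("list", nrow(models))
  for (i in seq_len(nrow(models))) {
    a <- if (models$model[i] == "katz") katz_alpha else NULL
    profs <- lapply(graphs, centrality, model = models$model[i],
                    variant = models$variant[i], alpha = a)
    fits[[i]] <- fit_quantile_regression(
      pool_quantiles(lapply(profs, quantile_ranks), important))
    co <- fits[[i]]$coefficients
    co$model <- models$model[i]; co$variant <- models$variant[i]
    co$adj_r_squared <- fits[[i]]$adj_r_squared
    reg_rows[[i]] <- co
    cdfq <- pooled_cdf_quantiles(profs, important)
    k <- if (any(cdfq$important) && any(!cdfq$important)) {
      ks_cdf_compare(cdfq$quantile[cdfq$important], cdfq$quantile[!cdfq$important])
    } else list(statistic = NA_real_, p.value = NA_real_)
    ks[[i]] <- data.frame(model = models$model[i], variant = models$variant[i],
                          ks_statistic = k$statistic, ks_p = k$p.value,
                          stringsAsFactors = FALSE)
    test_rows[[i]] <- pathway_tests(profs, important, level = fdr_level)
  }
  structure(
    list(filter_report = report,
         regression = do.call(rbind, reg_rows),
         fits = fits,
         ks = do.call(rbind, ks),
         tests = do.call(rbind, test_rows),
         models = models, fdr_level = fdr_level,
         n_pathways = length(graphs)),
    class = "ssc_validation"
  )
}

#' @export
print.ssc_validation <- function(x, ...) {
  cat("<ssc_validation> ", x$n_pathways, " pathways, ",
      nrow(x$models), " model/variants\n", sep = "")
  sl <- x$regression[x$regression$term == "Coefficient",
                     c("model", "variant", "estimate", "p.value", "adj_r_squared")]
  rownames(sl) <- NULL
  print(sl, digits = 3)
  invisible(x)
}

#' @export
summary.ssc_validation <- function(object, ...) {
  sig <- stats::aggregate(
    cbind(welch = object$tests$welch_significant,
          wilcoxon = object$tests$wilcoxon_significant),
    by = list(model = object$tests$model, variant = object$tests$variant),
    FUN = function(z) sum(z, na.rm = TRUE))
  out <- list(regression = object$regression, ks = object$ks,
              significant_pathways = sig,
              fdr_level = object$fdr_level, n_pathways = object$n_pathways)
  class(out) <- "summary.ssc_validation"
  out
}

#' @export
print.summary.ssc_validation <- function(x, ...) {
  cat("Validation over", x$n_pathways, "pathways\n\nQuantile regression:\n")
  print(x$regression[x$regression$term == "Coefficient", ], digits = 3)
  cat("\nKS CDF comparison (important below other):\n")
  print(x$ks, digits = 3)
  cat("\nFDR-significant pathways (level ", x$fdr_level, "):\n", sep = "")
  print(x$significant_pathways)
  invisible(x)
}

#' Plot the pooled quantile regression
#'
#' Scatter of importance fraction per quantile with the fitted line, for
#' one model/variant of a validation object.
#'
#' @param x an `ssc_validation`.
#' @param model,variant which fit to show.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted `quantile_fit`.
#' @export
plot.ssc_validation <- function(x, model = "pagerank", variant = "ssc", ...) {
  key <- paste(model, variant, sep = ".")
  f <- x$fits[[key]]
  if (is.null(f)) stop("no fit for ", key)
  d <- f$fit$model
  graphics::plot(d$quantile, d$fraction,
                 xlab = "centrality quantile",
                 ylab = "% important genes",
                 main = paste0(model, " / ", variant), ...)
  graphics::abline(f$fit, col = "red3", lwd = 2)
  invisible(f)
}

#' Dampening-factor sensitivity scan for PageRank
#'
#' Recomputes the four PageRank variants over a grid of alpha values,
#' refits the quantile regression for each, and compares the SSC fit's
#' correlation against the undirected fit's via Fisher-Z at every alpha.
#'
#' @param graphs list of `pathway_graph`s or a `synthetic_cohort`
#'   (pathways are assumed already filtered).
#' @param important a `gene_set` (from the cohort if omitted).
#' @param alphas grid of dampening factors in (0, 1); default
#'   `seq(0.1, 0.9, by = 0.01)` (81 values).
#' @param beta PageRank restart constant.
#' @return data frame with one row per (alpha, variant): slope, slope p,
#'   adjusted r-squared, correlation, and for the ssc rows the Fisher-Z
#'   statistic/p against the undirected fit at the same alpha.
#' @export
sensitivity_scan <- function(graphs, important = NULL,
                             alphas = seq(0.1, 0.9, by = 0.01), beta = 0.15) {
  if (inherits(graphs, "synthetic_cohort")) {
    if (is.null(important)) important <- graphs$important
    graphs <- graphs$graphs
  }
  stopifnot(all(alphas > 0 & alphas < 1))
  variants <- c("source", "sink", "ssc", "undirected")
  rows <- list()
  for (a in alphas) {
    fits <- list()
    for (v in variants) {
      profs <- lapply(graphs, pagerank_centrality, variant = v,
                      alpha = a, beta = beta)
      fits[[v]] <- fit_quantile_regression(
        pool_quantiles(lapply(profs, quantile_ranks), important))
    }
    for (v in variants) {
      f <- fits[[v]]
      fz <- if (v == "ssc") {
        if (f$n > 3 && fits$undirected$n > 3) {
          fisher_z(f$r, fits$undirected$r, f$n, fits$undirected$n)
        } else {
          warning("too few quantile bins for Fisher-Z at alpha = ", a)
          list(z = NA_real_, p.value = NA_real_)
        }
      } else list(z = NA_real_, p.value = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        alpha = a, variant = v,
        slope = f$coefficients$estimate[2],
        slope_p = f$coefficients$p.value[2],
        adj_r_squared = f$adj_r_squared, r = f$r, n_bins = f$n,
        fisher_z = fz$z, fisher_z_p = fz$p.value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write validation report tables
#'
#' Writes the regression table (columns mirroring a tidy coefficient
#' table: term, estimate, std.error, statistic, p.value), the per-pathway
#' test table, and the KS table as TSV, plus a JSON summary.
#'
#' @param v an `ssc_validation`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_validation_report <- function(v, dir) {
  stopifnot(inherits(v, "ssc_validation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(v$regression, file.path(dir, "regression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(v$tests, file.path(dir, "pathway_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(v$ks, file.path(dir, "ks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(v$filter_report)) {
    write_filter_report(v$filter_report, file.path(dir, "filter_report.tsv"))
  }
  jsonlite::write_json(
    list(n_pathways = v$n_pathways, fdr_level = v$fdr_level,
         slopes = stats::setNames(
           as.list(v$regression$estimate[v$regression$term == "Coefficient"]),
           paste(v$regression$model[v$regression$term == "Coefficient"],
                 v$regression$variant[v$regression$term == "Coefficient"],
                 sep = "."))),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
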