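#' Welch two-sample t-test from raw samples or printed summaries
#'
#' Computes the unequal-variance (Welch) t-statistic
#' `t = (m2 - m1) / sqrt(s1^2/n1 + s2^2/n2)` with Welch--Satterthwaite
#' degrees of freedom and a two-sided p-value.  Because the statistic
#' depends on the data only through (n, mean, sd), the function accepts
#' either raw numeric vectors or `list(n =, mean =, sd =)` summaries --
#' which allows published group-summary tables to be re-tested directly.
#'
#' @param group1,group2 numeric vectors, or lists with `n`, `mean`, `sd`.
#' @param feature optional feature name carried through to the result.
#' @return A `feature_test`: list with `feature`, `t` (signed,
#'   group2 - group1 in the numerator), `df`, `p`.
#' @export
welch_t <- function(group1, group2, feature = NA_character_) {
  g1 <- as_summary(group1); g2 <- as_summary(group2)
  if (g1$n < 2 || g2$n < 2) stop("need at least 2 observations per group")
  if (g1$sd == 0 && g2$sd == 0) {
    if (g1$mean == g2$mean)
      return(structure(list(feature = feature, t = 0, df = g1$n + g2$n - 2,
                            p = 1), class = "feature_test"))
    stop("degenerate: both group variances are zero")
  }
  v1 <- g1$sd^2 / g1$n; v2 <- g2$sd^2 / g2$n
  t <- (g2$mean - g1$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(feature = feature, t = t, df = df, p = p),
            class = "feature_test")
}

as_summary <- function(g) {
  if (is.list(g)) {
    stopifnot(all(c("n", "mean", "sd") %in% names(g)))
    list(n = g$n, mean = g$mean, sd = g$sd)
  } else {
    list(n = length(g), mean = mean(g), sd = stats::sd(g))
  }
}

#' @export
print.feature_test <- function(x, ...) {
  cat(sprintf("Welch t = %.4f, df = %.2f, p = %.4f%s\n", x$t, x$df, x$p,
              if (is.na(x$feature)) "" else paste0("  [", x$feature, "]")))
  invisible(x)
}

#' Welch t-tests for every feature of a cohort
#' @param cohort cohort data.frame with a `ruptured` column.
#' @return data.frame with `feature`, `t`, `abs_t`, `df`, `p`, ordered as
#'   the columns appear.
#' @export
cohort_t_tests <- function(cohort) {
  X <- cohort_matrix(cohort)
  y <- cohort$ruptured
  if (length(unique(y)) != 2) stop("cohort must contain both classes")
  res <- lapply(colnames(X), function(f) {
    x1 <- X[y == 1, f]; x0 <- X[y == 0, f]
    x1 <- x1[!is.na(x1)]; x0 <- x0[!is.na(x0)]
    if (length(x1) < 2 || length(x0) < 2 ||
        (stats::sd(x1) == 0 && stats::sd(x0) == 0))
      return(data.frame(feature = f, t = 0, df = NA_real_, p = 1))
    w <- welch_t(x1, x0, feature = f)
    data.frame(feature = f, t = w$t, df = w$df, p = w$p)
  })
  out <- do.call(rbind, res)
  out$abs_t <- abs(out$t)
  out
}

#' Rank features by |t| and keep the top k
#'
#' Features are ordered by decreasing absolute Welch t-statistic, ties
#' broken lexicographically by feature name.
#'
#' @param cohort cohort data.frame.
#' @param k number of features to retain before pruning (default 20).
#' @return data.frame of the k top-ranked features with their statistics.
#' @export
rank_top_k <- function(cohort, k = 20) {
  tt <- cohort_t_tests(cohort)
  if (k > nrow(tt)) stop("k exceeds the number of features")
  ord <- order(-tt$abs_t, tt$feature)
  tt[ord[seq_len(k)], , drop = FALSE]
}

#' Prune correlated features from a ranked list
#'
#' Greedy scan in rank order: a feature is removed iff its absolute
#' Pearson correlation with any already-retained feature exceeds the
#' threshold.  Constant (zero-variance) columns have undefined
#' correlation and are removed with reason `"zero variance"`.
#'
#' @param cohort cohort data.frame.
#' @param ranked data.frame from [rank_top_k()] (or a character vector of
#'   ranked names).
#' @param threshold absolute-correlation threshold (default 0.5).
#' @return A `selection_result`: `retained`, `removed` (with the
#'   triggering correlation and partner), `k`, `threshold`, `ranked`.
#' @export
prune_correlated <- function(cohort, ranked, threshold = 0.5) {
  names_ranked <- if (is.data.frame(ranked)) ranked$feature else as.character(ranked)
  X <- cohort_matrix(cohort)
  if (!all(names_ranked %in% colnames(X)))
    stop("ranked features missing from the cohort")
  retained <- character(0)
  removed <- data.frame(feature = character(0), partner = character(0),
                        correlation = numeric(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (f in names_ranked) {
    x <- X[, f]
    if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
      removed <- rbind(removed, data.frame(feature = f, partner = NA_character_,
                                           correlation = NA_real_,
                                           reason = "zero variance"))
      next
    }
    hit <- NULL
    for (g in retained) {
      r <- suppressWarnings(stats::cor(x, X[, g],
                                       use = "pairwise.complete.obs"))
      if (!is.na(r) && (abs(r) > threshold || abs(r) > 1 - 1e-12)) {
        hit <- list(g = g, r = r); break
      }
    }
    if (is.null(hit)) retained <- c(retained, f)
    else removed <- rbind(removed,
                          data.frame(feature = f, partner = hit$g,
                                     correlation = hit$r,
                                     reason = "correlated"))
  }
  structure(list(retained = retained, removed = removed,
                 k = length(names_ranked), threshold = threshold,
                 ranked = if (is.data.frame(ranked)) ranked else NULL),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d ranked, %d retained, %d removed (|r| > %.2g)\n",
              x$k, length(x$retained), nrow(x$removed), x$threshold))
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Full feature-selection stage: t-test ranking plus correlation pruning
#'
#' Ranks all features by absolute Welch t-statistic, keeps the top `k`,
#' and prunes correlated redundancy.  By default selection is fit on the
#' full cohort, replicating the published protocol; the leakage-free
#' variant that re-runs selection inside each training fold is available
#' through the `nested` argument of the classification stage.
#'
#' @param cohort cohort data.frame.
#' @param k candidates retained before pruning (default 20).
#' @param threshold correlation threshold for pruning (default 0.5).
#' @return A `selection_result`.
#' @export
select_features <- function(cohort, k = 20, threshold = 0.5) {
  prune_correlated(cohort, rank_top_k(cohort, k), threshold)
}
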