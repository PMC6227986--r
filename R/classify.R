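#' Classifier specification
#'
#' The four classifier families used for rupture-risk prediction, with
#' their default hyperparameters: `"svm"` (support vector machine, linear
#' kernel, unit cost), `"rf"` (random forest, 100 trees, sqrt(d) features
#' per split), `"knn"` (k-nearest neighbours, k = 5, Euclidean distance)
#' and `"sd"` (subspace discriminant: 30 linear-discriminant learners on
#' random feature subspaces of size ceiling(d/2), aggregated by mean
#' posterior).  Features are median-imputed and z-scored using training
#' data only inside every cross-validation fold.
#'
#' @param family one of `"svm"`, `"rf"`, `"knn"`, `"sd"`.
#' @param cost SVM cost parameter.
#' @param ntree random-forest tree count.
#' @param k KNN neighbour count.
#' @param n_learners subspace-discriminant ensemble size.
#' @param standardize z-score features inside each training fold.
#' @param seed integer seed for the stochastic families.
#' @return A `model_spec`.
#' @export
model_spec <- function(family = c("svm", "rf", "knn", "sd"), cost = 1,
                       ntree = 100, k = 5, n_learners = 30,
                       standardize = TRUE, seed = 1) {
  family <- match.arg(family)
  structure(list(family = family, cost = cost, ntree = ntree, k = k,
                 n_learners = n_learners, standardize = standardize,
                 seed = seed),
            class = "model_spec")
}

# fit on a preprocessed matrix; returns a closure scoring new cases
# (score = continuous decision value for class 1)
fit_model <- function(spec, X, y) {
  yf <- factor(y, levels = c(0, 1))
  if (spec$family == "svm") {
    fit <- e1071::svm(x = X, y = yf, kernel = "linear", cost = spec$cost,
                      scale = FALSE)
    # e1071 names the decision-value column "<first>/<second>"; a positive
    # margin favors the first-named class
    function(Xn) {
      dv <- attr(stats::predict(fit, Xn, decision.values = TRUE),
                 "decision.values")
      sgn <- if (grepl("^1", colnames(dv)[1])) 1 else -1
      as.numeric(dv[, 1]) * sgn
    }
  } else if (spec$family == "rf") {
    fit <- randomForest::randomForest(x = X, y = yf, ntree = spec$ntree,
                                      mtry = max(1, floor(sqrt(ncol(X)))))
    function(Xn) stats::predict(fit, Xn, type = "prob")[, "1"] - 0.5
  } else if (spec$family == "knn") {
    k <- min(spec$k, nrow(X))
    function(Xn) {
      pr <- class::knn(X, Xn, yf, k = k, prob = TRUE)
      frac <- attr(pr, "prob")
      ifelse(pr == "1", frac, 1 - frac) - 0.5
    }
  } else {
    d <- ncol(X)
    m <- max(1L, ceiling(d / 2))
    subs <- lapply(seq_len(spec$n_learners), function(i)
      sort(sample.int(d, m)))
    fits <- lapply(subs, function(sb) {
      tryCatch(MASS::lda(x = X[, sb, drop = FALSE], grouping = yf),
               error = function(e) NULL)
    })
    function(Xn) {
      post <- matrix(NA_real_, nrow(Xn), length(subs))
      for (i in seq_along(subs)) {
        if (is.null(fits[[i]])) next
        pr <- stats::predict(fits[[i]], Xn[, subs[[i]], drop = FALSE])
        post[, i] <- pr$posterior[, "1"]
      }
      rowMeans(post, na.rm = TRUE) - 0.5
    }
  }
}

impute_fit <- function(X) apply(X, 2, stats::median, na.rm = TRUE)
impute_apply <- function(X, med) {
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- med[j]
  }
  X
}
scale_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  list(mu = mu, sd = sdv)
}
scale_apply <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

preprocess_fold <- function(Xtr, Xte, standardize) {
  med <- impute_fit(Xtr)
  med[is.na(med)] <- 0
  Xtr <- impute_apply(Xtr, med); Xte <- impute_apply(Xte, med)
  if (standardize) {
    sc <- scale_fit(Xtr)
    Xtr <- scale_apply(Xtr, sc); Xte <- scale_apply(Xte, sc)
  }
  list(train = Xtr, test = Xte)
}

#' Leave-one-out cross-validated evaluation
#'
#' Exactly n folds: fold i trains on all cases but i and predicts case i.
#' Median imputation, standardization and (optionally) feature selection
#' are fitted on each training fold only.  Decision scores are pooled
#' across folds for the ROC curve.
#'
#' @param cohort cohort data.frame with `ruptured` labels.
#' @param spec a `model_spec`.
#' @param features character vector of feature names to use (e.g. the
#'   `retained` set of [select_features()]); `NULL` uses all features.
#'   Ignored when `nested = TRUE`.
#' @param nested if `TRUE`, re-run feature selection inside each training
#'   fold (the leakage-free variant); the default `FALSE` uses the
#'   `features` given, replicating the published protocol in which
#'   selection is fit once on the full cohort.
#' @param k,threshold selection parameters for `nested = TRUE`.
#' @return An `evaluation_report`: per-case `predictions` (truth, pred,
#'   score), `accuracy` (%), `roc`, `auc`, `optimal` operating point, and
#'   the model metadata.
#' @export
loocv_evaluate <- function(cohort, spec, features = NULL, nested = FALSE,
                           k = 20, threshold = 0.5) {
  n <- nrow(cohort)
  if (n < 3) stop("need at least 3 cases")
  y <- cohort$ruptured
  if (length(unique(y)) != 2) stop("cohort must contain both classes")
  set.seed(spec$seed)
  score <- pred <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tr <- cohort[-i, , drop = FALSE]
    feats <- if (nested) select_features(tr, k = k, threshold = threshold)$retained
             else if (is.null(features)) colnames(cohort_matrix(cohort))
             else features
    Xtr <- cohort_matrix(tr)[, feats, drop = FALSE]
    Xte <- cohort_matrix(cohort[i, , drop = FALSE])[, feats, drop = FALSE]
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) {           # degenerate fold
      maj <- as.integer(names(which.max(table(ytr))))
      pred[i] <- maj; score[i] <- maj - 0.5
      next
    }
    pp <- preprocess_fold(Xtr, Xte, spec$standardize)
    sc <- fit_model(spec, pp$train, ytr)(pp$test)
    score[i] <- sc
    pred[i] <- as.integer(sc > 0)
  }
  roc <- roc_curve(score, y)
  structure(list(
    predictions = data.frame(case_id = cohort$case_id, truth = y,
                             pred = pred, score = score),
    accuracy = 100 * mean(pred == y), folds = n, roc = roc, auc = roc$auc,
    optimal = roc$optimal, spec = spec, features = features,
    nested = nested),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report (%s, %d folds): accuracy %.2f%%, AUC %.3f\n",
              x$spec$family, x$folds, x$accuracy, x$auc))
  cat(sprintf("  optimal operating point: sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$optimal$sensitivity, 100 * x$optimal$specificity))
  invisible(x)
}

#' Repeated stratified train/test-split evaluation
#'
#' Randomly divides the cohort into a training set (default 80%) and a
#' test set (20%), stratified by class, trains the model and records the
#' test accuracy; repeated `reps` times (default 30).
#'
#' @param cohort cohort data.frame.
#' @param spec a `model_spec`.
#' @param features feature names to use; `NULL` for all.
#' @param train_frac training fraction (default 0.8).
#' @param reps number of random splits (default 30).
#' @param seed seed for the split sequence.
#' @return A `split_report`: per-repeat `accuracies` (%), their `mean`
#'   and `sd`.
#' @export
repeated_split_evaluate <- function(cohort, spec, features = NULL,
                                    train_frac = 0.8, reps = 30, seed = 1) {
  y <- cohort$ruptured
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  n1 <- round(train_frac * length(idx1)); n0 <- round(train_frac * length(idx0))
  if (n1 < 1 || n0 < 1 || n1 >= length(idx1) || n0 >= length(idx0))
    stop("stratified split impossible: a class has too few cases")
  if (reps == 1) warning("a single split: reporting sd = 0")
  set.seed(seed)
  feats <- if (is.null(features)) colnames(cohort_matrix(cohort)) else features
  acc <- numeric(reps)
  for (r in seq_len(reps)) {
    tr <- c(sample(idx1, n1), sample(idx0, n0))
    te <- setdiff(seq_along(y), tr)
    Xtr <- cohort_matrix(cohort[tr, , drop = FALSE])[, feats, drop = FALSE]
    Xte <- cohort_matrix(cohort[te, , drop = FALSE])[, feats, drop = FALSE]
    pp <- preprocess_fold(Xtr, Xte, spec$standardize)
    sc <- fit_model(spec, pp$train, y[tr])(pp$test)
    acc[r] <- 100 * mean(as.integer(sc > 0) == y[te])
  }
  structure(list(accuracies = acc, mean = mean(acc),
                 sd = if (reps == 1) 0 else stats::sd(acc),
                 reps = reps, train_frac = train_frac, spec = spec),
            class = "split_report")
}

#' @export
print.split_report <- function(x, ...) {
  cat(sprintf("split_report (%s, %d x %.0f/%.0f): accuracy %.2f (+/- %.2f) %%\n",
              x$spec$family, x$reps, 100 * x$train_frac,
              100 * (1 - x$train_frac), x$mean, x$sd))
  invisible(x)
}

#' ROC curve, AUC and the optimal operating point
#'
#' Sweeps thresholds over the unique decision scores to build the ROC
#' staircase, integrates the AUC by trapezoid (equivalent to the
#' normalized Mann--Whitney U statistic, with ties counted half), and
#' picks the operating point maximizing Youden's J = sensitivity +
#' specificity - 1, breaking ties toward higher sensitivity.
#'
#' @param scores continuous decision values (larger = more rupture-like).
#' @param labels binary labels (1 = ruptured).
#' @return List: `points` (data.frame `fpr`, `tpr`, `threshold`), `auc`,
#'   and `optimal` (fpr, tpr, sensitivity, specificity, threshold,
#'   youden).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) != 2)
    stop("ROC undefined: need both classes among the labels")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # cut after each group of tied scores
  bounds <- which(diff(s) != 0)
  cuts <- c(0, bounds, length(s))
  tp <- cumsum(l)[cuts[-1]]; fp <- cumsum(1 - l)[cuts[-1]]
  tpr <- c(0, tp / np); fpr <- c(0, fp / nn)
  thr <- c(Inf, s[cuts[-1]])
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[which.max(tpr[best])]
  optimal <- list(fpr = fpr[best], tpr = tpr[best],
                  sensitivity = tpr[best], specificity = 1 - fpr[best],
                  threshold = thr[best], youden = j[best])
  list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
       auc = auc, optimal = optimal)
}

#' Paired comparison of models against a baseline
#'
#' For leave-one-out reports, a paired t-test on the per-case 0/1
#' correctness differences; for repeated-split reports, a paired t-test
#' on the per-repeat accuracies.  All-zero differences give t = 0, p = 1.
#'
#' @param reports named list of `evaluation_report` or `split_report`
#'   objects sharing the same folds/splits.
#' @param baseline name of the baseline model in `reports` (default
#'   `"svm"`).
#' @return data.frame with `model`, `t`, `p` for each non-baseline model.
#' @export
compare_to_baseline <- function(reports, baseline = "svm") {
  if (!baseline %in% names(reports)) stop("baseline report not found")
  per_case <- function(rep) {
    if (inherits(rep, "evaluation_report"))
      as.integer(rep$predictions$pred == rep$predictions$truth)
    else rep$accuracies
  }
  base <- per_case(reports[[baseline]])
  out <- lapply(setdiff(names(reports), baseline), function(nm) {
    d <- base - per_case(reports[[nm]])
    if (all(d == 0)) return(data.frame(model = nm, t = 0, p = 1))
    if (stats::sd(d) == 0)   # constant nonzero difference: certain direction
      return(data.frame(model = nm, t = sign(mean(d)) * Inf, p = 0))
    tt <- stats::t.test(d)
    data.frame(model = nm, t = unname(tt$statistic), p = tt$p.value)
  })
  do.call(rbind, out)
}
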