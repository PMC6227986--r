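# a small linearly separable cohort: two informative features with class
# means far apart relative to noise
separable_cohort <- function(n_per = 20, gap = 3, sd = 0.5, seed = 1) {
  set.seed(seed)
  y <- rep(c(1L, 0L), each = n_per)
  data.frame(case_id = sprintf("c%03d", seq_len(2 * n_per)), ruptured = y,
             fa = rnorm(2 * n_per, ifelse(y == 1, gap, -gap), sd),
             fb = rnorm(2 * n_per, ifelse(y == 1, gap, -gap), sd),
             check.names = FALSE)
}

test_that("ROC handles perfect, degenerate and noisy scores correctly", {
  r <- roc_curve(c(5, 4, 3, -1, -2, -4), c(1, 1, 1, 0, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$optimal$fpr, 0)
  expect_equal(r$optimal$tpr, 1)

  r0 <- roc_curve(rep(0.3, 10), rep(c(1, 0), 5))
  expect_equal(r0$auc, 0.5)

  # AUC equals the normalized Mann-Whitney U statistic
  set.seed(3)
  sc <- rnorm(40); lb <- rep(c(1, 0), 20)
  r2 <- roc_curve(sc, lb)
  u <- unname(wilcox.test(sc[lb == 1], sc[lb == 0], exact = FALSE)$statistic)
  expect_equal(r2$auc, u / (20 * 20), tolerance = 1e-12)

  # binormal closed form: scores = label + N(0, sigma)
  set.seed(4)
  n <- 4000; lb <- rep(c(1, 0), n / 2); sigma <- 0.8
  sc <- lb + rnorm(n, 0, sigma)
  r3 <- roc_curve(sc, lb)
  expect_equal(r3$auc, pnorm(1 / (sigma * sqrt(2))), tolerance = 0.02)

  expect_error(roc_curve(rnorm(5), rep(1, 5)), "both classes")
})

test_that("leave-one-out produces one fold per case and flawless separable fits", {
  co <- separable_cohort()
  for (fam in c("svm", "rf", "knn", "sd")) {
    rep_ <- loocv_evaluate(co, model_spec(fam, seed = 2))
    expect_equal(nrow(rep_$predictions), nrow(co))
    expect_equal(rep_$folds, nrow(co))
    expect_equal(rep_$accuracy, 100)
    expect_equal(rep_$auc, 1)
  }
})

test_that("label permutation drops accuracy to the chance band", {
  co <- separable_cohort(n_per = 20)
  set.seed(77)
  co$ruptured <- sample(co$ruptured)
  rep_ <- loocv_evaluate(co, model_spec("svm", seed = 1))
  # binomial 95% band around 50% for n = 40 (LOOCV folds are dependent,
  # so allow a margin beyond the iid band)
  expect_gt(rep_$accuracy, 20)
  expect_lt(rep_$accuracy, 80)
})

test_that("fold preprocessing uses training data only", {
  X <- matrix(c(1, 2, 3, 4, NA, 6), ncol = 2)
  Xte <- matrix(c(100, 200), ncol = 2)
  pp <- vafamorph:::preprocess_fold(X, Xte, standardize = TRUE)
  # imputation median and scaling come from the training rows alone
  med <- median(c(4, 6))
  mu <- mean(c(4, med, 6)); sdv <- sd(c(4, med, 6))
  expect_equal(pp$test[1, 2], (200 - mu) / sdv)
  expect_equal(pp$train[2, 2], (med - mu) / sdv)
  expect_false(anyNA(pp$train))
})

test_that("repeated stratified splits reproduce and respect boundaries", {
  co <- separable_cohort()
  rs <- repeated_split_evaluate(co, model_spec("svm"), reps = 10, seed = 5)
  expect_length(rs$accuracies, 10)
  expect_equal(rs$mean, 100)
  expect_equal(rs$sd, 0)
  rs2 <- repeated_split_evaluate(co, model_spec("svm"), reps = 10, seed = 5)
  expect_identical(rs$accuracies, rs2$accuracies)
  expect_warning(repeated_split_evaluate(co, model_spec("svm"), reps = 1,
                                         seed = 1), "single split")
  tiny <- co[c(1, 21:40), ]
  expect_error(repeated_split_evaluate(tiny, model_spec("svm"), seed = 1),
               "stratified split impossible")
})

test_that("model comparison returns zero for identical models and detects crippling", {
  co <- separable_cohort()
  r1 <- loocv_evaluate(co, model_spec("svm", seed = 1))
  cmp <- compare_to_baseline(list(svm = r1, same = r1))
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)

  # a label-shuffled (crippled) competitor loses significantly in most seeds
  wins <- vapply(1:10, function(sd) {
    co2 <- separable_cohort(seed = 50 + sd)
    good <- loocv_evaluate(co2, model_spec("svm", seed = 1))
    co_bad <- co2
    set.seed(sd); co_bad[, c("fa", "fb")] <- co_bad[sample(nrow(co_bad)),
                                                    c("fa", "fb")]
    bad <- loocv_evaluate(co_bad, model_spec("svm", seed = 1))
    bad$predictions$truth <- co2$ruptured
    bad$predictions$pred <- bad$predictions$pred  # same folds, broken features
    cmp <- compare_to_baseline(list(svm = good, crippled = bad))
    cmp$p < 0.05
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("classification pipelines are deterministic under a fixed seed", {
  co <- simulate_cohort(cohort_spec(seed = 19))
  sel <- select_features(co)
  a <- loocv_evaluate(co, model_spec("rf", seed = 7), features = sel$retained)
  b <- loocv_evaluate(co, model_spec("rf", seed = 7), features = sel$retained)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$accuracy, b$accuracy)
})
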