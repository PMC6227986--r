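#' Published group summaries for the five discriminative features
#'
#' The five geometric characteristics reported to separate ruptured from
#' un-ruptured vertebral-artery fusiform aneurysms, with per-group means
#' and standard deviations (12 ruptured vs 25 un-ruptured cases), mapped
#' onto this package's canonical feature names:
#' proximal/distal area ratio of the aneurysm (unitless), total maximum
#' diameter of the nearby distal vessel (mm^2), total solidity of the
#' aneurysm (mm), maximum centerline curvature of the nearby distal
#' vessel (1/mm), and the curvature ratio between the aneurysm and the
#' nearby proximal vessel (unitless).
#'
#' @return A data.frame with columns `feature`, `mean_ruptured`,
#'   `sd_ruptured`, `mean_unruptured`, `sd_unruptured`, `t_printed`,
#'   `p_printed`.
#' @export
reference_group_summaries <- function() {
  data.frame(
    feature = c(
      "ratio.aneurysm_proximal_half-aneurysm_distal_half.area.mean",
      "first_distal.d_max.integral",
      "aneurysm.solidity.integral",
      "first_distal.curvature.max",
      "ratio.aneurysm-first_proximal.curvature.mean"),
    mean_ruptured = c(0.95, 27.55, 10.35, 0.29, -0.65),
    sd_ruptured = c(0.25, 14.82, 2.90, 0.12, 0.91),
    mean_unruptured = c(1.21, 40.76, 12.88, 0.46, 0.72),
    sd_unruptured = c(0.34, 21.78, 4.58, 0.38, 3.16),
    t_printed = c(2.6469, 2.1634, 2.0398, 2.0191, 2.0107),
    p_printed = c(0.0129, 0.0384, 0.0497, 0.0519, 0.0531),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic labeled cohort
#'
#' Describes a cohort of ruptured / un-ruptured cases in feature space:
#' a small set of planted informative features drawn per group from
#' Normal(mean, sd), with all remaining features identically distributed
#' standard-normal noise in both groups.  Defaults reproduce the study
#' conditions: 12 ruptured vs 25 un-ruptured cases, with the five
#' published group summaries planted.
#'
#' @param n_ruptured,n_unruptured group sizes (default 12 and 25).
#' @param planted data.frame in the format of
#'   [reference_group_summaries()]; `NULL` plants nothing.
#' @param seed integer seed making the cohort reproducible.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_ruptured = 12, n_unruptured = 25,
                        planted = reference_group_summaries(), seed = 1) {
  if (n_ruptured <= 0 || n_unruptured <= 0) stop("group counts must be positive")
  if (!is.null(planted)) {
    if (any(planted$sd_ruptured <= 0) || any(planted$sd_unruptured <= 0))
      stop("planted standard deviations must be positive")
    bad <- setdiff(planted$feature, feature_names())
    if (length(bad))
      stop("planted feature name(s) not in the 571-feature schema: ",
           paste(bad, collapse = ", "))
  }
  structure(list(n_ruptured = n_ruptured, n_unruptured = n_unruptured,
                 planted = planted, seed = seed),
            class = "cohort_spec")
}

#' Simulate a labeled feature cohort
#'
#' Draws a cohort table per a [cohort_spec()]: columns follow the
#' canonical 571-feature schema, planted features are Normal(mean, sd)
#' per group, all other features are standard normal in both groups.
#' Bit-reproducible given the spec's seed.
#'
#' @param spec a `cohort_spec`.
#' @return A data.frame with `case_id`, `ruptured` (integer 0/1) and the
#'   571 feature columns.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  fn <- feature_names()
  n <- spec$n_ruptured + spec$n_unruptured
  ruptured <- c(rep(1L, spec$n_ruptured), rep(0L, spec$n_unruptured))
  X <- matrix(stats::rnorm(n * length(fn)), n, length(fn),
              dimnames = list(NULL, fn))
  if (!is.null(spec$planted)) {
    for (i in seq_len(nrow(spec$planted))) {
      p <- spec$planted[i, ]
      X[ruptured == 1L, p$feature] <-
        stats::rnorm(spec$n_ruptured, p$mean_ruptured, p$sd_ruptured)
      X[ruptured == 0L, p$feature] <-
        stats::rnorm(spec$n_unruptured, p$mean_unruptured, p$sd_unruptured)
    }
  }
  df <- data.frame(case_id = sprintf("case_%03d", seq_len(n)),
                   ruptured = ruptured, check.names = FALSE,
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(X, check.names = FALSE))
}

#' Feature columns of a cohort table
#' @param cohort a cohort data.frame.
#' @return Numeric matrix of the feature columns.
#' @export
cohort_matrix <- function(cohort) {
  as.matrix(cohort[, setdiff(colnames(cohort), c("case_id", "ruptured")),
                   drop = FALSE])
}
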