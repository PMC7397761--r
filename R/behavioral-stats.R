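#' Mean confidence level per subject and task
#'
#' The metacognitive-bias measure: the arithmetic mean of the confidence
#' percentage across trials, without subtracting task performance.
#'
#' @param trials Trial tibble (any number of subjects/tasks).
#' @return Tibble with `subject`, `task`, `n_trials`, `mean_confidence`
#'   (0-100 scale).
#' @export
compute_confidence_level <- function(trials) {
  assert_trial_table(trials)
  if (!"confidence_pct" %in% names(trials)) {
    abort("`trials` must contain a `confidence_pct` column.")
  }
  if (nrow(trials) == 0) abort("`trials` is empty.")
  trials |>
    dplyr::group_by(.data$subject, .data$task) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     mean_confidence = mean(.data$confidence_pct),
                     .groups = "drop")
}

#' Per-subject, per-task behavioral summary
#'
#' Computes the subject x task summary table the statistics layer consumes:
#' type-I d' (log-linear corrected), mean confidence level, AUROC2 (NA when a
#' cell has no correct or no incorrect trials), and optionally the
#' nonhierarchical MLE Mratio point estimate.
#'
#' @param trials Trial tibble.
#' @param n_levels Confidence levels in the raw data.
#' @param collapse_to Bins for the meta-d' fit (see [build_counts()]).
#' @param include_mratio Add an MLE `mratio_point` column (slower).
#' @return Tibble with one row per subject x task.
#' @export
summarize_subject_tasks <- function(trials, n_levels = 11, collapse_to = 4,
                                    include_mratio = FALSE) {
  cells <- counts_by_subject_task(trials, n_levels, collapse_to = NULL)
  conf <- compute_confidence_level(trials)
  out <- purrr::map_dfr(seq_len(nrow(cells)), function(r) {
    ct <- cells$counts[[r]]
    sdt <- compute_dprime(ct, correction = "loglinear")
    au <- tryCatch(compute_auroc2(ct), error = function(e) NA_real_)
    tibble::tibble(subject = cells$subject[r], task = cells$task[r],
                   dprime = sdt$dprime, criterion = sdt$criterion, auroc2 = au)
  })
  out <- dplyr::left_join(out, conf, by = c("subject", "task"))
  if (include_mratio) {
    mr <- fit_metad_pointwise(trials, n_levels, collapse_to) |>
      dplyr::select("subject", "task", mratio_point = "mratio")
    out <- dplyr::left_join(out, mr, by = c("subject", "task"))
  }
  out
}

#' Paired t test with Cohen's dz
#'
#' Classical two-sided paired t test on the difference scores, with the
#' paired-design effect size dz = mean(diff) / sd(diff) (equivalently
#' t / sqrt(n)).
#'
#' @param x,y Paired per-subject values of equal length >= 3.
#' @param alpha Significance level before correction.
#' @param m_comparisons Number of comparisons for the Bonferroni-corrected
#'   significance flag.
#' @return One-row tibble with `t`, `df`, `p`, `dz`, `n`,
#'   `significant_after_correction`.
#' @export
paired_ttest <- function(x, y, alpha = 0.05, m_comparisons = 1) {
  if (length(x) != length(y)) abort("`x` and `y` must be paired (equal length).")
  if (length(x) < 3) abort("At least 3 pairs are required.")
  d <- x - y
  n <- length(d)
  if (sd(d) <= 1e-12 * (abs(mean(d)) + 1)) {
    # identical pairs carry no evidence of a difference (the t -> 0 limit);
    # a nonzero constant shift makes t undefined
    if (mean(d) == 0) {
      return(tibble::tibble(t = 0, df = n - 1, p = 1, dz = 0, n = n,
                            significant_after_correction = FALSE))
    }
    abort("Difference scores have zero variance; the paired t test is degenerate.")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
    dz = mean(d) / sd(d), n = n,
    significant_after_correction = ht$p.value < bonferroni_threshold(alpha, m_comparisons)
  )
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level.
#' @param m Number of comparisons, >= 1.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 6) # the alpha/6 threshold for 4-task pairings
#' @export
bonferroni_threshold <- function(alpha, m) {
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  assert_scalar_number(m, "m", lower = 1)
  alpha / m
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' Pearson's r with the two-sided p value and a confidence interval obtained
#' by the Fisher z transform: `atanh(r) +/- z_crit / sqrt(n - 3)`, mapped back
#' with `tanh`.
#'
#' @param x,y Numeric vectors of equal length >= 4 with non-zero variance.
#' @param conf Confidence level of the interval (default 0.95).
#' @param alpha,m_comparisons As in [paired_ttest()].
#' @return One-row tibble with `r`, `ci_lower`, `ci_upper`, `p`, `n`,
#'   `significant_after_correction`.
#' @export
pearson_with_ci <- function(x, y, conf = 0.95, alpha = 0.05, m_comparisons = 1) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 4) abort("At least 4 observations are required.")
  if (anyNA(x) || anyNA(y) || !all(is.finite(c(x, y)))) {
    abort("`x` and `y` must be finite and complete.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Zero variance in `x` or `y`; the correlation is undefined.")
  }
  ht <- stats::cor.test(x, y)
  n <- length(x)
  ci <- fisher_ci(unname(ht$estimate), n, conf)
  tibble::tibble(
    r = unname(ht$estimate), ci_lower = ci[1], ci_upper = ci[2],
    p = ht$p.value, n = n,
    significant_after_correction = ht$p.value < bonferroni_threshold(alpha, m_comparisons)
  )
}

# Fisher-z interval for a correlation coefficient at sample size n.
fisher_ci <- function(r, n, conf = 0.95) {
  zr <- atanh(r)
  half <- qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
  tanh(c(zr - half, zr + half))
}

#' Regression-based outlier and influence screening for paired variables
#'
#' Fits the simple linear regression of `y` on `x` and flags observations by
#' three standard diagnostics: leverage (hat value) above `2 (k + 1) / n`
#' with k = 1 predictor, absolute (externally) studentized residual above 3,
#' and Cook's distance above `4 / n`. The union of flagged points is returned
#' with per-test attribution.
#'
#' @param x,y Numeric vectors of equal length >= 5.
#' @return Tibble of flagged observations with `index`, the three diagnostic
#'   values, and logical columns `leverage_flag`, `residual_flag`,
#'   `cooks_flag`.
#' @export
influence_outliers <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 5) abort("At least 5 observations are required.")
  if (sd(x) == 0) abort("Degenerate regression: `x` has zero variance.")
  fit <- stats::lm(y ~ x)
  lev <- stats::hatvalues(fit)
  stud <- stats::rstudent(fit)
  cook <- stats::cooks.distance(fit)
  out <- tibble::tibble(
    index = seq_len(n), leverage = unname(lev),
    studentized_residual = unname(stud), cooks_distance = unname(cook),
    leverage_flag = lev > 2 * 2 / n,
    residual_flag = abs(stud) > 3,
    cooks_flag = cook > 4 / n
  )
  dplyr::filter(out, .data$leverage_flag | .data$residual_flag | .data$cooks_flag)
}

#' Exclude subjects with very low performance in any task
#'
#' Applies the exclusion rule of the nonhierarchical analysis path: a subject
#' whose type-I d' falls below `threshold` in any task is removed entirely,
#' and the exclusions are logged with the offending task(s).
#'
#' @param summaries Tibble with columns `subject`, `task`, `dprime`, covering
#'   every task for every subject.
#' @param threshold Exclusion threshold on d' (default 0.10).
#' @return A list of class `exclusion_result` with elements `retained` (the
#'   filtered summary tibble) and `exclusions` (subject, task, dprime of every
#'   offending cell).
#' @export
exclude_low_performance <- function(summaries, threshold = 0.10) {
  if (!all(c("subject", "task", "dprime") %in% names(summaries))) {
    abort("`summaries` needs columns subject, task, dprime.")
  }
  tasks_per_subject <- summaries |>
    dplyr::count(.data$subject) |>
    dplyr::pull(.data$n)
  if (length(unique(tasks_per_subject)) > 1) {
    abort("Every subject must have a summary row for every task.")
  }
  offending <- summaries |>
    dplyr::filter(.data$dprime < threshold) |>
    dplyr::select("subject", "task", "dprime")
  retained <- summaries |>
    dplyr::filter(!.data$subject %in% offending$subject)
  structure(list(retained = retained, exclusions = offending,
                 threshold = threshold),
            class = "exclusion_result")
}

#' @export
print.exclusion_result <- function(x, ...) {
  cat(sprintf("<exclusion_result> %d subject(s) excluded at d' < %.2f\n",
              dplyr::n_distinct(x$exclusions$subject), x$threshold))
  if (nrow(x$exclusions) > 0) print(as.data.frame(x$exclusions), row.names = FALSE)
  invisible(x)
}
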