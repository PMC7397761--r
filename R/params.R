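#' Generative parameters for one subject performing one task
#'
#' Bundles the type-I and type-II signal-detection parameters that drive the
#' trial simulator: type-I sensitivity `dprime`, type-I criterion `criterion`,
#' type-II sensitivity `metad` (meta-d', in d' units), and the ordered vector
#' of `2 * (n_levels - 1)` type-2 confidence cutpoints. Cutpoints live on the
#' meta-level decision axis: the first `n_levels - 1` sit below the scaled
#' criterion `(criterion / dprime) * metad` (response "S1" side), the rest
#' above it (response "S2" side), and the whole vector is strictly ascending.
#'
#' When `type2_criteria` is omitted, [default_type2_criteria()] places the
#' cutpoints so that confidence usage is roughly uniform under the generative
#' model.
#'
#' @param dprime Type-I sensitivity, `>= 0`.
#' @param metad Type-II sensitivity meta-d'; defaults to `dprime` (an
#'   SDT-optimal, "ideal observer" configuration with Mratio 1).
#' @param criterion Type-I decision criterion c.
#' @param n_levels Number of ordinal confidence levels K (default 11,
#'   a 0-100% scale in 10% steps).
#' @param type2_criteria Optional ascending numeric vector of length
#'   `2 * (n_levels - 1)`; computed from the other parameters when `NULL`.
#' @return An object of class `subject_task_params`.
#' @examples
#' p <- subject_task_params(dprime = 2, metad = 1.5)
#' p$type2_criteria
#' @export
subject_task_params <- function(dprime, metad = dprime, criterion = 0,
                                n_levels = 11, type2_criteria = NULL) {
  assert_scalar_number(dprime, "dprime", lower = 0)
  assert_scalar_number(metad, "metad", lower = 0)
  assert_scalar_number(criterion, "criterion")
  assert_scalar_number(n_levels, "n_levels", lower = 2)
  n_levels <- as.integer(n_levels)
  cprime <- if (dprime > 0) criterion / dprime else criterion
  scaled_criterion <- cprime * metad
  if (is.null(type2_criteria)) {
    type2_criteria <- default_type2_criteria(dprime, metad, criterion, n_levels)
  }
  G <- n_levels - 1L
  if (length(type2_criteria) != 2L * G) {
    abort(sprintf("`type2_criteria` must have length 2 * (n_levels - 1) = %d.", 2L * G))
  }
  if (any(diff(type2_criteria) <= 0)) {
    abort("`type2_criteria` must be strictly ascending (non-monotone type-2 criteria).")
  }
  if (any(type2_criteria[seq_len(G)] >= scaled_criterion) ||
      any(type2_criteria[G + seq_len(G)] <= scaled_criterion)) {
    abort("`type2_criteria` must straddle the scaled type-1 criterion: the first n_levels - 1 cutpoints below it, the rest above it.")
  }
  structure(
    list(dprime = dprime, metad = metad, criterion = criterion,
         cprime = cprime, scaled_criterion = scaled_criterion,
         n_levels = n_levels, type2_criteria = type2_criteria),
    class = "subject_task_params"
  )
}

#' @export
print.subject_task_params <- function(x, ...) {
  cat(sprintf("<subject_task_params> d' = %.3f, meta-d' = %.3f (Mratio %.3f), c = %.3f, K = %d\n",
              x$dprime, x$metad,
              if (x$dprime > 0) x$metad / x$dprime else NA_real_,
              x$criterion, x$n_levels))
  invisible(x)
}

#' Default type-2 confidence cutpoints
#'
#' Places the `2 * (n_levels - 1)` type-2 criteria at the quantiles of the
#' response-conditional distribution of the type-2 decision variable, so that
#' under the generative model each confidence level is used with roughly equal
#' probability. On each response side, the conditional distribution is the
#' stimulus mixture of `Normal(+/- metad / 2, 1)` truncated to that side of the
#' scaled criterion, with stimulus weights given by the type-I model.
#'
#' @inheritParams subject_task_params
#' @return Ascending numeric vector of length `2 * (n_levels - 1)`.
#' @export
default_type2_criteria <- function(dprime, metad = dprime, criterion = 0,
                                   n_levels = 11) {
  n_levels <- as.integer(n_levels)
  cprime <- if (dprime > 0) criterion / dprime else criterion
  mc <- cprime * metad
  mu1 <- c(-dprime / 2, dprime / 2)   # type-I means (S1, S2)
  mu2 <- c(-metad / 2, metad / 2)     # type-II means (S1, S2)

  side_cuts <- function(upper) {
    # response probabilities per stimulus under the type-I model
    p_resp <- if (upper) 1 - pnorm(criterion - mu1) else pnorm(criterion - mu1)
    w <- p_resp / sum(p_resp)
    # truncated-mixture CDF of the type-2 variable on this response side
    if (upper) {
      base <- pnorm(mc - mu2)
      cdf <- function(t) sum(w * (pnorm(t - mu2) - base) / (1 - base))
      bracket <- c(mc, mc + abs(metad) + 12)
    } else {
      base <- pnorm(mc - mu2)
      cdf <- function(t) sum(w * pnorm(t - mu2) / base)
      bracket <- c(mc - abs(metad) - 12, mc)
    }
    probs <- seq_len(n_levels - 1L) / n_levels
    vapply(probs, function(p) {
      stats::uniroot(function(t) cdf(t) - p, bracket, tol = 1e-9)$root
    }, numeric(1))
  }

  lower_q <- side_cuts(upper = FALSE)  # ascending quantiles below mc
  upper_q <- side_cuts(upper = TRUE)   # ascending quantiles above mc
  # Below the criterion confidence grows away from mc, so the cutpoints are the
  # lower-side quantiles as-is (ascending towards mc).
  c(lower_q, upper_q)
}

#' Group-level generative configuration for multi-task simulations
#'
#' Describes the stated world of a multi-task confidence experiment: `n_tasks`
#' tasks of `n_trials` two-alternative forced-choice trials each, rated on an
#' `n_levels`-point confidence scale, for `n_subjects` participants whose
#' per-task log metacognitive efficiency log(meta-d'/d') is drawn from a
#' multivariate Gaussian with task means `mu_logM`, spreads `sigma_logM` and
#' cross-task correlation matrix `rho`. Per-subject, per-task type-I
#' sensitivity d' is drawn uniformly from `dprime_range` and the type-I
#' criterion from `Normal(0, criterion_sd)`.
#'
#' Defaults mirror the experimental design the package targets: 4 tasks of 40
#' trials on an 11-level 0-100% scale, group Mratio about 0.8, cross-task
#' correlation 0.6, and d' heterogeneity spanning the observed task means.
#'
#' @param n_tasks Number of tasks T.
#' @param n_subjects Number of simulated participants.
#' @param n_trials Trials per task.
#' @param n_levels Confidence levels K.
#' @param mu_logM Length-`n_tasks` vector of group-mean log-Mratio.
#' @param sigma_logM Length-`n_tasks` vector of group SDs of log-Mratio
#'   (entries may be 0 for a degenerate spread).
#' @param rho `n_tasks x n_tasks` correlation matrix (unit diagonal, entries in
#'   `[-1, 1]`, positive semidefinite) or a single scalar used for every
#'   off-diagonal entry.
#' @param dprime_range Length-2 range for uniform per-subject d' draws.
#' @param criterion_sd SD of the per-subject type-I criterion draw.
#' @param seed Optional integer seed making [simulate_group()] reproducible.
#' @return An object of class `group_config`.
#' @examples
#' cfg <- group_config(n_tasks = 2, n_subjects = 20, rho = 0.6, seed = 1)
#' @export
group_config <- function(n_tasks = 4, n_subjects = 100, n_trials = 40,
                         n_levels = 11,
                         mu_logM = rep(log(0.8), n_tasks),
                         sigma_logM = rep(0.5, n_tasks),
                         rho = 0.6,
                         dprime_range = c(0.5, 2.5),
                         criterion_sd = 0.1,
                         seed = NULL) {
  assert_scalar_number(n_tasks, "n_tasks", lower = 1)
  assert_scalar_number(n_subjects, "n_subjects", lower = 1)
  assert_scalar_number(n_trials, "n_trials", lower = 1)
  assert_scalar_number(n_levels, "n_levels", lower = 2)
  n_tasks <- as.integer(n_tasks)
  if (length(mu_logM) != n_tasks || length(sigma_logM) != n_tasks) {
    abort("`mu_logM` and `sigma_logM` must have length `n_tasks`.")
  }
  if (any(sigma_logM < 0)) abort("`sigma_logM` entries must be >= 0.")
  if (is.matrix(rho)) {
    if (nrow(rho) != n_tasks) abort("`rho` must be `n_tasks` x `n_tasks`.")
  } else {
    assert_scalar_number(rho, "rho", lower = -1, upper = 1)
    r <- matrix(rho, n_tasks, n_tasks)
    diag(r) <- 1
    rho <- r
  }
  check_correlation_matrix(rho)
  if (length(dprime_range) != 2L || dprime_range[1] > dprime_range[2] ||
      dprime_range[1] < 0) {
    abort("`dprime_range` must be an increasing pair of non-negative values.")
  }
  assert_scalar_number(criterion_sd, "criterion_sd", lower = 0)
  structure(
    list(n_tasks = n_tasks, n_subjects = as.integer(n_subjects),
         n_trials = as.integer(n_trials), n_levels = as.integer(n_levels),
         mu_logM = as.numeric(mu_logM), sigma_logM = as.numeric(sigma_logM),
         rho = rho, dprime_range = as.numeric(dprime_range),
         criterion_sd = criterion_sd, seed = seed),
    class = "group_config"
  )
}

#' @export
print.group_config <- function(x, ...) {
  cat(sprintf("<group_config> %d tasks x %d trials x %d subjects, K = %d levels\n",
              x$n_tasks, x$n_trials, x$n_subjects, x$n_levels))
  cat("  mu_logM:    ", paste(signif(x$mu_logM, 3), collapse = ", "), "\n")
  cat("  sigma_logM: ", paste(signif(x$sigma_logM, 3), collapse = ", "), "\n")
  if (x$n_tasks > 1) {
    cat("  rho (upper triangle): ",
        paste(signif(x$rho[upper.tri(x$rho)], 3), collapse = ", "), "\n")
  }
  invisible(x)
}
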