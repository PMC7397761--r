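#' Simulate 2AFC trials with confidence ratings for one subject and task
#'
#' Generates trial-level data from the type-II signal-detection model that the
#' meta-d' estimators in this package fit. Each trial: the stimulus class is
#' drawn uniformly from S1/S2; type-I evidence `x1 ~ Normal(+/- dprime/2, 1)`
#' is compared to the criterion to produce the response; a second, type-II
#' evidence sample is drawn from `Normal(+/- metad/2, 1)` truncated to the
#' response-consistent side of the scaled criterion `(c/d') * metad`, and
#' binned by the type-2 criteria to produce the ordinal confidence level.
#' Because confidence is generated by the same model the estimators assume,
#' meta-d' fits on these data are consistent, which makes parameter-recovery
#' checks meaningful.
#'
#' @param params A [subject_task_params()] object.
#' @param n_trials Number of trials, `>= 1`.
#' @param seed Optional integer seed; fixed seeds give byte-identical output.
#' @param subject,task Identifiers stamped into the output columns.
#' @return A tibble with one row per trial and columns `subject`, `task`,
#'   `trial`, `stimulus`, `response`, `accurate`, `confidence_level` (0-based
#'   ordinal level) and `confidence_pct` (level mapped onto 0-100%).
#' @examples
#' p <- subject_task_params(dprime = 2)
#' head(simulate_subject_task(p, n_trials = 10, seed = 1))
#' @export
simulate_subject_task <- function(params, n_trials, seed = NULL,
                                  subject = "s1", task = "t1") {
  if (!inherits(params, "subject_task_params")) {
    abort("`params` must be created with subject_task_params().")
  }
  assert_scalar_number(n_trials, "n_trials", lower = 1)
  n_trials <- as.integer(n_trials)
  with_local_seed(seed, {
    sim <- sim_trials_core(params, n_trials)
    tibble::tibble(
      subject = subject, task = task, trial = seq_len(n_trials),
      stimulus = sim$stimulus, response = sim$response,
      accurate = sim$accurate, confidence_level = sim$confidence_level,
      confidence_pct = sim$confidence_level * (100 / (params$n_levels - 1L))
    )
  })
}

# Vectorised trial generator; consumes the current RNG stream.
sim_trials_core <- function(params, n_trials) {
  K <- params$n_levels
  G <- K - 1L
  s2 <- stats::runif(n_trials) < 0.5
  mu1 <- ifelse(s2, params$dprime / 2, -params$dprime / 2)
  x1 <- stats::rnorm(n_trials, mean = mu1, sd = 1)
  resp_s2 <- x1 > params$criterion
  mu2 <- ifelse(s2, params$metad / 2, -params$metad / 2)
  mc <- params$scaled_criterion

  # type-2 evidence: truncated normal on the response-consistent side of mc,
  # sampled by inverse CDF
  p_mc <- pnorm(mc - mu2)
  u <- stats::runif(n_trials)
  q <- ifelse(resp_s2, p_mc + u * (1 - p_mc), u * p_mc)
  q <- pmin(pmax(q, 1e-15), 1 - 1e-15)
  x2 <- mu2 + qnorm(q)

  conf <- integer(n_trials)
  cuts_s1 <- params$type2_criteria[seq_len(G)]
  cuts_s2 <- params$type2_criteria[G + seq_len(G)]
  if (any(resp_s2)) {
    conf[resp_s2] <- findInterval(x2[resp_s2], cuts_s2)
  }
  if (any(!resp_s2)) {
    conf[!resp_s2] <- G - findInterval(x2[!resp_s2], cuts_s1)
  }

  list(
    stimulus = ifelse(s2, "S2", "S1"),
    response = ifelse(resp_s2, "S2", "S1"),
    accurate = as.integer(s2 == resp_s2),
    confidence_level = conf
  )
}

#' Draw ground-truth subject parameters for a simulated group
#'
#' Samples the per-subject, per-task generative parameters implied by a
#' [group_config()]: log-Mratio vectors from the multivariate Gaussian
#' `MVN(mu_logM, diag(sigma) rho diag(sigma))`, d' uniform on `dprime_range`,
#' and the type-I criterion from `Normal(0, criterion_sd)`; meta-d' is then
#' `exp(logM) * d'`. This is the "truth sidecar" of [simulate_group()],
#' exposed separately so large-sample properties of the parameter draw can be
#' checked without generating trials.
#'
#' @param config A [group_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A tibble with columns `subject`, `task`, `logM`, `dprime`,
#'   `criterion`, `metad`.
#' @export
draw_group_params <- function(config, seed = config$seed) {
  if (!inherits(config, "group_config")) {
    abort("`config` must be created with group_config().")
  }
  with_local_seed(seed, draw_group_params_core(config))
}

draw_group_params_core <- function(config) {
  n <- config$n_subjects
  t_n <- config$n_tasks
  Sigma <- diag(config$sigma_logM, t_n) %*% config$rho %*% diag(config$sigma_logM, t_n)
  L <- matrix_sqrt(Sigma)
  zmat <- matrix(stats::rnorm(n * t_n), n, t_n)
  logM <- sweep(zmat %*% t(L), 2, config$mu_logM, "+")
  dprime <- matrix(stats::runif(n * t_n, config$dprime_range[1], config$dprime_range[2]),
                   n, t_n)
  criterion <- matrix(stats::rnorm(n * t_n, 0, config$criterion_sd), n, t_n)
  subj_ids <- sprintf("s%03d", seq_len(n))
  task_ids <- sprintf("task%d", seq_len(t_n))
  tibble::tibble(
    subject = rep(subj_ids, each = t_n),
    task = rep(task_ids, times = n),
    logM = as.vector(t(logM)),
    dprime = as.vector(t(dprime)),
    criterion = as.vector(t(criterion)),
    metad = exp(as.vector(t(logM))) * as.vector(t(dprime))
  )
}

#' Simulate a multi-task group with correlated metacognitive efficiency
#'
#' Draws ground-truth parameters with [draw_group_params()] and generates
#' trials for every subject x task cell with the generative scheme of
#' [simulate_subject_task()]. The sample correlation matrix of the true
#' per-subject log-Mratio values converges to `config$rho` as the number of
#' subjects grows.
#'
#' @param config A [group_config()]; a non-positive-semidefinite `rho` is
#'   rejected at construction time.
#' @param seed Optional seed overriding `config$seed`.
#' @return A trial tibble (as in [simulate_subject_task()]) with the
#'   ground-truth parameter table attached as attribute `"truth"` (retrieve it
#'   with `attr(trials, "truth")`).
#' @examples
#' cfg <- group_config(n_tasks = 2, n_subjects = 5, n_trials = 20, seed = 1)
#' trials <- simulate_group(cfg)
#' attr(trials, "truth")
#' @export
simulate_group <- function(config, seed = config$seed) {
  if (!inherits(config, "group_config")) {
    abort("`config` must be created with group_config().")
  }
  with_local_seed(seed, {
    truth <- draw_group_params_core(config)
    n_cells <- nrow(truth)
    n_tr <- config$n_trials
    parts <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      params <- subject_task_params(
        dprime = truth$dprime[i], metad = truth$metad[i],
        criterion = truth$criterion[i], n_levels = config$n_levels
      )
      sim <- sim_trials_core(params, n_tr)
      parts[[i]] <- tibble::tibble(
        subject = truth$subject[i], task = truth$task[i], trial = seq_len(n_tr),
        stimulus = sim$stimulus, response = sim$response,
        accurate = sim$accurate, confidence_level = sim$confidence_level,
        confidence_pct = sim$confidence_level * (100 / (config$n_levels - 1L))
      )
    }
    out <- dplyr::bind_rows(parts)
    attr(out, "truth") <- truth
    attr(out, "n_levels") <- config$n_levels
    out
  })
}

#' Write / read simulated trials with their ground-truth sidecar
#'
#' `write_trials()` stores a trial table as plain CSV; when the table carries a
#' `"truth"` attribute (as produced by [simulate_group()]) the ground-truth
#' parameters are written alongside as a JSON sidecar named
#' `<path>.truth.json`.
#'
#' @param trials Trial tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  assert_trial_table(trials)
  readr::write_csv(trials, path)
  truth <- attr(trials, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         dataframe = "columns", digits = NA)
  }
  invisible(path)
}
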