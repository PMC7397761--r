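#' Configuration of a full analysis run
#'
#' Collects everything [run_full_pipeline()] needs: the data (a trial tibble
#' or a [group_config()] to simulate from), the confidence binning for
#' meta-d' fitting, the exclusion threshold and multiple-comparison settings,
#' and the MCMC configuration. Defaults reproduce the target experimental
#' design: 40 trials on an 11-level scale, alpha = .05 over all task
#' pairings, and a d' < 0.10 exclusion rule for the nonhierarchical path.
#'
#' @param trials Trial tibble, or `NULL` to simulate from `sim_config`.
#' @param sim_config A [group_config()] used when `trials` is `NULL`.
#' @param n_levels,collapse_to Confidence scale and fitting bins.
#' @param exclusion_threshold d' threshold for the nonhierarchical path.
#' @param alpha Family-wise significance level.
#' @param mcmc An [mcmc_config()].
#' @param seed Seed for simulation and fitting.
#' @param verbose Log stage-by-stage progress.
#' @return Object of class `run_config`.
#' @export
run_config <- function(trials = NULL, sim_config = NULL, n_levels = 11,
                       collapse_to = 4, exclusion_threshold = 0.10,
                       alpha = 0.05, mcmc = mcmc_config(), seed = 1,
                       verbose = TRUE) {
  if (is.null(trials) && is.null(sim_config)) {
    abort("Provide `trials` or a `sim_config` to simulate from.")
  }
  structure(
    list(trials = trials, sim_config = sim_config, n_levels = n_levels,
         collapse_to = collapse_to, exclusion_threshold = exclusion_threshold,
         alpha = alpha, mcmc = mcmc, seed = seed, verbose = isTRUE(verbose)),
    class = "run_config"
  )
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full multi-task metacognition analysis
#'
#' Sequences the whole analysis on one trial table: per-cell counts; the
#' type-I d' table with all pairwise paired t tests (Bonferroni-corrected
#' over task pairings); confidence levels with paired tests and Pearson
#' correlations; the hierarchical fit with group Mratio posteriors, pairwise
#' Mratio difference distributions and correlation posteriors with 95% HDIs;
#' and the nonhierarchical Mratio correlations after the d' exclusion rule.
#'
#' @param config A [run_config()].
#' @return A list of class `metacov_report` with elements `subject_summary`,
#'   `dprime_ttests`, `dprime_correlations`, `confidence_ttests`,
#'   `confidence_correlations`, `group_mratio`, `mratio_differences`,
#'   `rho_summary`, `nonhier_correlations`, `exclusions`, `posterior`, and
#'   `meta` (seed, settings, package version).
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  v <- config$verbose

  trials <- config$trials
  if (is.null(trials)) {
    pipeline_log(v, "Simulating group data (seed %d)...", config$seed)
    cfg <- config$sim_config
    trials <- simulate_group(cfg, seed = cfg$seed %||% config$seed)
  }
  assert_trial_table(trials)
  validate_trials(trials, config$n_levels)

  tasks <- sort(unique(trials$task))
  n_pairs <- choose(length(tasks), 2)
  pipeline_log(v, "Input: %d trials, %d subjects, %d tasks.",
               nrow(trials), dplyr::n_distinct(trials$subject), length(tasks))

  pipeline_log(v, "Stage 1: subject x task summaries (d', confidence, AUROC2)...")
  summary_tbl <- summarize_subject_tasks(trials, config$n_levels,
                                         config$collapse_to)

  pairwise <- function(value_col, m) {
    wide <- tidyr::pivot_wider(summary_tbl[c("subject", "task", value_col)],
                               names_from = "task",
                               values_from = dplyr::all_of(value_col))
    purrr::map_dfr(utils::combn(tasks, 2, simplify = FALSE), function(pr) {
      tt <- paired_ttest(wide[[pr[1]]], wide[[pr[2]]],
                         alpha = config$alpha, m_comparisons = m)
      cr <- pearson_with_ci(wide[[pr[1]]], wide[[pr[2]]],
                            alpha = config$alpha, m_comparisons = m)
      dplyr::bind_cols(tibble::tibble(task_i = pr[1], task_j = pr[2]),
                       dplyr::rename_with(tt, ~ paste0("t_", .x)),
                       dplyr::rename_with(cr, ~ paste0("r_", .x)))
    })
  }

  pipeline_log(v, "Stage 2: paired tests and correlations over %d task pairs (alpha = %.3g/%d)...",
               n_pairs, config$alpha, max(n_pairs, 1))
  dprime_pairs <- if (n_pairs > 0) pairwise("dprime", n_pairs) else NULL
  confidence_pairs <- if (n_pairs > 0) pairwise("mean_confidence", n_pairs) else NULL

  pipeline_log(v, "Stage 3: hierarchical model (%d chains x %d samples)...",
               config$mcmc$n_chains, config$mcmc$n_samples)
  mc <- config$mcmc
  mc$seed <- mc$seed %||% derive_seed(config$seed, 99)
  posterior <- fit_hmetad_multitask(trials, config$n_levels, config$collapse_to,
                                    mcmc = mc)
  gm <- group_mratio(posterior)
  corr_report <- if (n_pairs > 0) summarize_correlations(posterior) else NULL

  pipeline_log(v, "Stage 4: nonhierarchical MLE path with d' < %.2f exclusion...",
               config$exclusion_threshold)
  point <- fit_metad_pointwise(trials, config$n_levels, config$collapse_to)
  excl <- exclude_low_performance(point, config$exclusion_threshold)
  pipeline_log(v, "  excluded %d subject(s).",
               dplyr::n_distinct(excl$exclusions$subject))
  nonhier <- if (n_pairs > 0) {
    wide <- tidyr::pivot_wider(excl$retained[c("subject", "task", "mratio")],
                               names_from = "task", values_from = "mratio")
    purrr::map_dfr(utils::combn(tasks, 2, simplify = FALSE), function(pr) {
      dplyr::bind_cols(
        tibble::tibble(task_i = pr[1], task_j = pr[2]),
        pearson_with_ci(wide[[pr[1]]], wide[[pr[2]]],
                        alpha = config$alpha, m_comparisons = n_pairs))
    })
  } else NULL

  structure(
    list(subject_summary = summary_tbl,
         dprime_tests = dprime_pairs,
         confidence_tests = confidence_pairs,
         group_mratio = gm,
         mratio_differences = if (!is.null(corr_report)) corr_report$differences,
         rho_summary = if (!is.null(corr_report)) corr_report$correlations,
         nonhier_correlations = nonhier,
         exclusions = excl$exclusions,
         posterior = posterior,
         meta = list(seed = config$seed, alpha = config$alpha,
                     n_comparisons = n_pairs,
                     exclusion_threshold = config$exclusion_threshold,
                     n_levels = config$n_levels, collapse_to = config$collapse_to,
                     mcmc = mc[c("n_chains", "n_samples", "n_burnin", "seed")],
                     package_version = as.character(utils::packageVersion("metacov")))),
    class = "metacov_report"
  )
}

#' @export
print.metacov_report <- function(x, ...) {
  cat(sprintf("<metacov_report> %d subjects, %d tasks (seed %s)\n",
              dplyr::n_distinct(x$subject_summary$subject),
              dplyr::n_distinct(x$subject_summary$task),
              format(x$meta$seed)))
  cat("\nGroup Mratio (posterior):\n")
  print(as.data.frame(x$group_mratio), digits = 3, row.names = FALSE)
  if (!is.null(x$rho_summary)) {
    cat("\nCross-task correlations in log-Mratio:\n")
    print(as.data.frame(x$rho_summary), digits = 3, row.names = FALSE)
  }
  invisible(x)
}

validate_trials <- function(trials, n_levels) {
  bad <- which(trials$confidence_level < 0 | trials$confidence_level >= n_levels |
                 trials$confidence_level != floor(trials$confidence_level))
  if (length(bad) > 0) {
    abort(sprintf("Malformed confidence_level at row(s) %s (must be an integer in 0..%d).",
                  paste(head(bad, 5), collapse = ", "), n_levels - 1))
  }
  if ("confidence_pct" %in% names(trials)) {
    badp <- which(trials$confidence_pct < 0 | trials$confidence_pct > 100)
    if (length(badp) > 0) {
      abort(sprintf("Malformed confidence_pct at row(s) %s (must lie in [0, 100]).",
                    paste(head(badp, 5), collapse = ", ")))
    }
  }
  bad_acc <- which((trials$response == trials$stimulus) != (trials$accurate == 1))
  if (length(bad_acc) > 0) {
    abort(sprintf("`accurate` disagrees with stimulus/response at row(s) %s.",
                  paste(head(bad_acc, 5), collapse = ", ")))
  }
  grid <- table(trials$subject, trials$task)
  if (any(grid == 0)) {
    missing <- which(grid == 0, arr.ind = TRUE)
    abort(sprintf("Subject %s is missing task %s.",
                  rownames(grid)[missing[1, 1]], colnames(grid)[missing[1, 2]]))
  }
  invisible(trials)
}

#' Read a trial table from delimited text
#'
#' Reads a CSV of trial-level data, optionally renaming columns from another
#' dialect via `mapping` (a named character vector `c(canonical = "raw_name")`
#' for externally deposited datasets), validates the schema, and recomputes
#' `confidence_pct` from `confidence_level` when absent.
#'
#' @param path CSV path.
#' @param n_levels Expected confidence levels.
#' @param mapping Optional column mapping.
#' @return Validated trial tibble.
#' @export
read_trials <- function(path, n_levels = 11, mapping = NULL) {
  trials <- readr::read_csv(path, show_col_types = FALSE)
  if (!is.null(mapping)) {
    trials <- dplyr::rename(trials, !!!rlang::set_names(mapping, names(mapping)))
  }
  missing <- setdiff(required_trial_cols, names(trials))
  if (length(missing) > 0) {
    abort(sprintf("Trial file is missing required column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(trials),
                   c(required_trial_cols, "trial", "confidence_pct"))
  if (length(extra) > 0) {
    warn(sprintf("Ignoring unknown column(s): %s.", paste(extra, collapse = ", ")))
  }
  if (!"confidence_pct" %in% names(trials)) {
    trials$confidence_pct <- trials$confidence_level * (100 / (n_levels - 1))
  }
  validate_trials(trials, n_levels)
  trials
}

#' Write a report bundle to a directory
#'
#' Writes every tibble of a [run_full_pipeline()] bundle as CSV, the posterior
#' draws and summary via [write_posterior()], and a `report.json` with the
#' run metadata (seed, settings, package version).
#'
#' @param bundle A `metacov_report`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the paths written, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "metacov_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  tbls <- c("subject_summary", "dprime_tests", "confidence_tests",
            "group_mratio", "mratio_differences", "rho_summary",
            "nonhier_correlations", "exclusions")
  for (nm in tbls) {
    if (!is.null(bundle[[nm]])) {
      p <- file.path(dir, paste0(nm, ".csv"))
      readr::write_csv(bundle[[nm]], p)
      paths <- c(paths, p)
    }
  }
  paths <- c(paths, write_posterior(bundle$posterior, dir))
  meta_path <- file.path(dir, "report.json")
  jsonlite::write_json(bundle$meta, meta_path, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, meta_path)
  invisible(paths)
}

#' Read sampler settings from a key-value configuration file
#'
#' Parses a plain-text file of `key = value` lines (`#` comments allowed)
#' into an [hmeta_model_spec()] and an [mcmc_config()]. Recognised keys:
#' `n_chains`, `n_samples`, `n_burnin`, `seed`, `mu_prior_mean`,
#' `mu_prior_sd`, `sigma_prior_shape`, `sigma_prior_rate`,
#' `gamma_prior_mean`, `gamma_prior_sd`. Unknown keys raise an error so
#' typos do not silently fall back to defaults.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `spec` and `mcmc`.
#' @examples
#' cfg_file <- tempfile()
#' writeLines(c("n_chains = 2", "n_samples = 500", "seed = 7"), cfg_file)
#' read_sampler_config(cfg_file)$mcmc$n_chains
#' @export
read_sampler_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    abort(sprintf("Malformed config line(s): %s.",
                  paste(lines[bad], collapse = "; ")))
  }
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- as.numeric(trimws(vapply(kv, `[[`, character(1), 2)))
  if (anyNA(vals)) abort("Config values must be numeric.")
  mcmc_keys <- c("n_chains", "n_samples", "n_burnin", "seed")
  spec_keys <- c("mu_prior_mean", "mu_prior_sd", "sigma_prior_shape",
                 "sigma_prior_rate", "gamma_prior_mean", "gamma_prior_sd")
  unknown <- setdiff(keys, c(mcmc_keys, spec_keys))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(keys)) abort("Duplicated config keys.")
  named <- stats::setNames(as.list(vals), keys)
  mcmc <- do.call(mcmc_config, named[intersect(keys, mcmc_keys)])
  spec <- do.call(hmeta_model_spec, named[intersect(keys, spec_keys)])
  list(spec = spec, mcmc = mcmc)
}
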