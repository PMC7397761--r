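#' Tabulate confidence-by-response counts for one subject and task
#'
#' Builds the canonical input of all SDT estimators in this package: for each
#' stimulus class, a length-`2K` vector of counts ordered from the
#' highest-confidence "S1" response down to confidence 0, then from
#' confidence 0 up to the highest-confidence "S2" response. Optionally the
#' `n_levels` original confidence levels are collapsed into `collapse_to`
#' equal-width bins first (useful when few trials leave the full scale
#' sparse), preserving the total count.
#'
#' @param trials Trial tibble for a single subject x task cell.
#' @param n_levels Number of confidence levels K the data were recorded on.
#' @param collapse_to Optional smaller number of levels K' to collapse to.
#' @return An object of class `counts_table`: a list with integer vectors
#'   `nR_S1`, `nR_S2` (length `2K`) and `n_levels`.
#' @examples
#' p <- subject_task_params(dprime = 1.5)
#' tr <- simulate_subject_task(p, 40, seed = 1)
#' build_counts(tr, n_levels = 11, collapse_to = 4)
#' @export
build_counts <- function(trials, n_levels = 11, collapse_to = NULL) {
  assert_trial_table(trials)
  if (nrow(trials) == 0) abort("`trials` is empty; counts are undefined.")
  if (dplyr::n_distinct(trials$subject) > 1 || dplyr::n_distinct(trials$task) > 1) {
    abort("`trials` mixes multiple subjects or tasks; build counts per subject x task cell.")
  }
  assert_scalar_number(n_levels, "n_levels", lower = 2)
  n_levels <- as.integer(n_levels)
  lev <- trials$confidence_level
  if (any(lev < 0 | lev >= n_levels)) {
    abort("`confidence_level` values must lie in 0 .. n_levels - 1.")
  }
  K <- n_levels
  if (!is.null(collapse_to)) {
    assert_scalar_number(collapse_to, "collapse_to", lower = 2, upper = n_levels)
    Kp <- as.integer(collapse_to)
    lev <- floor(lev * Kp / K)
    K <- Kp
  }
  counts_from_levels(trials$stimulus, trials$response, lev, K)
}

counts_from_levels <- function(stimulus, response, level, K) {
  # canonical cell index: 1 = (resp S1, conf K-1) ... K = (resp S1, conf 0),
  # K+1 = (resp S2, conf 0) ... 2K = (resp S2, conf K-1)
  cell <- ifelse(response == "S1", K - level, K + 1L + level)
  nR_S1 <- tabulate(cell[stimulus == "S1"], nbins = 2L * K)
  nR_S2 <- tabulate(cell[stimulus == "S2"], nbins = 2L * K)
  new_counts_table(nR_S1, nR_S2, K)
}

new_counts_table <- function(nR_S1, nR_S2, n_levels) {
  structure(list(nR_S1 = nR_S1, nR_S2 = nR_S2, n_levels = as.integer(n_levels)),
            class = "counts_table")
}

#' @export
print.counts_table <- function(x, ...) {
  K <- x$n_levels
  cat(sprintf("<counts_table> K = %d levels, %d trials\n", K,
              sum(x$nR_S1) + sum(x$nR_S2)))
  lab <- c(paste0("S1.", (K - 1):0), paste0("S2.", 0:(K - 1)))
  m <- rbind(nR_S1 = x$nR_S1, nR_S2 = x$nR_S2)
  colnames(m) <- lab
  print(m)
  invisible(x)
}

#' Serialize a counts table to delimited text
#'
#' The file starts with a header line declaring K and the column ordering
#' (highest-confidence "S1" response through highest-confidence "S2"
#' response), followed by a small CSV with one row per stimulus class.
#'
#' @param counts A `counts_table`.
#' @param path Output path.
#' @return `path` invisibly; `read_counts()` returns a `counts_table`.
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "counts_table"))
  K <- counts$n_levels
  header <- sprintf(
    "# metacov counts_table n_levels=%d ordering=resp-S1 conf %d..0 then resp-S2 conf 0..%d",
    K, K - 1, K - 1)
  body <- c(
    paste(c("stimulus", paste0("cell", seq_len(2 * K))), collapse = ","),
    paste(c("S1", counts$nR_S1), collapse = ","),
    paste(c("S2", counts$nR_S2), collapse = ",")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  lines <- readLines(path)
  m <- regmatches(lines[1], regexec("n_levels=([0-9]+)", lines[1]))[[1]]
  if (length(m) < 2) abort("Missing `n_levels` header in counts file.")
  K <- as.integer(m[2])
  df <- utils::read.csv(text = lines[-1], check.names = FALSE)
  if (ncol(df) != 2 * K + 1) abort("Counts file width does not match declared n_levels.")
  new_counts_table(as.numeric(df[df$stimulus == "S1", -1]),
                   as.numeric(df[df$stimulus == "S2", -1]), K)
}

# Nested per-cell counts for a multi-subject, multi-task trial table.
counts_by_subject_task <- function(trials, n_levels, collapse_to = NULL) {
  assert_trial_table(trials)
  trials |>
    dplyr::group_by(.data$subject, .data$task) |>
    dplyr::group_modify(function(d, key) {
      tibble::tibble(counts = list(build_counts(
        dplyr::mutate(d, subject = key$subject, task = key$task),
        n_levels = n_levels, collapse_to = collapse_to
      )))
    }) |>
    dplyr::ungroup()
}
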