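#' Type-I sensitivity and criterion from a counts table
#'
#' Computes d' = z(hit rate) - z(false-alarm rate) and the criterion
#' c = -0.5 * (z(hit) + z(fa)), where z is the inverse cumulative normal, from
#' the response marginals of a counts table (collapsing over confidence).
#' "S2" is treated as the signal class; in 2AFC the choice is arbitrary and
#' only fixes the sign convention.
#'
#' @param counts A `counts_table` from [build_counts()].
#' @param correction `"loglinear"` (default) adds 0.5 to each response count
#'   and 1 to each stimulus total, keeping rates away from 0 and 1; `"none"`
#'   uses raw rates and errors on a 0 or 1 rate (infinite estimate).
#' @return A one-row tibble with `dprime`, `criterion`, `hit_rate`, `fa_rate`.
#' @examples
#' tr <- simulate_subject_task(subject_task_params(2), 400, seed = 1)
#' compute_dprime(build_counts(tr, 11))
#' @export
compute_dprime <- function(counts, correction = c("loglinear", "none")) {
  stopifnot(inherits(counts, "counts_table"))
  correction <- match.arg(correction)
  K <- counts$n_levels
  n_s1 <- sum(counts$nR_S1)
  n_s2 <- sum(counts$nR_S2)
  if (n_s1 == 0 || n_s2 == 0) {
    abort("Both stimulus classes must be present to estimate d'.")
  }
  s2_resp <- (K + 1):(2 * K)
  hits <- sum(counts$nR_S2[s2_resp])
  fas <- sum(counts$nR_S1[s2_resp])
  if (correction == "loglinear") {
    hr <- (hits + 0.5) / (n_s2 + 1)
    fr <- (fas + 0.5) / (n_s1 + 1)
  } else {
    hr <- hits / n_s2
    fr <- fas / n_s1
    if (hr %in% c(0, 1) || fr %in% c(0, 1)) {
      abort("Hit or false-alarm rate of 0 or 1 gives an infinite d'; use correction = \"loglinear\".")
    }
  }
  tibble::tibble(
    dprime = qnorm(hr) - qnorm(fr),
    criterion = -0.5 * (qnorm(hr) + qnorm(fr)),
    hit_rate = hr,
    fa_rate = fr
  )
}

#' Nonparametric area under the type-II ROC curve
#'
#' Builds the type-II ROC from the cumulative confidence distributions of
#' correct versus incorrect trials (sweeping a confidence threshold from the
#' highest level down) and returns the trapezoidal area. 0.5 is chance-level
#' metacognitive sensitivity, 1 is perfect separation of correct from
#' incorrect trials. Unlike meta-d'/d', AUROC2 is not corrected for type-I
#' performance.
#'
#' @param counts A `counts_table`.
#' @return Scalar area in `[0, 1]`.
#' @export
compute_auroc2 <- function(counts) {
  stopifnot(inherits(counts, "counts_table"))
  K <- counts$n_levels
  # per-confidence-level counts (index 1 = level 0) for correct / incorrect
  correct <- rev(counts$nR_S1[1:K]) + counts$nR_S2[(K + 1):(2 * K)]
  incorrect <- counts$nR_S1[(K + 1):(2 * K)] + rev(counts$nR_S2[1:K])
  H <- sum(correct)
  F <- sum(incorrect)
  if (H == 0 || F == 0) {
    abort("AUROC2 is undefined without at least one correct and one incorrect trial.")
  }
  # cumulative from the highest confidence level down
  tpr <- c(0, cumsum(rev(correct)) / H)
  fpr <- c(0, cumsum(rev(incorrect)) / F)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}
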