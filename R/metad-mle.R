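# Type-II (meta-d') multinomial likelihood.
#
# The model: given the type-1 response, confidence arises from a second
# evidence sample drawn from Normal(+/- metad/2, 1) on the response-consistent
# side of the scaled criterion mc = (c/d') * metad, partitioned by 2(K-1)
# ordered type-2 criteria. The likelihood is the product over stimulus x
# response x confidence cells of the response-conditional cell probabilities;
# the type-1 response rates depend only on (d', c), which are fixed at their
# empirical point estimates, so they drop out of the optimisation.

# Criteria are parameterised by log-gaps `gam` (length 2(K-1)): the first
# K-1 gaps stack downward from mc (response-S1 side), the rest upward
# (response-S2 side). Any real `gam` yields admissible, strictly ordered
# criteria.
gaps_to_criteria <- function(metad, cprime, gam, K) {
  mc <- cprime * metad
  G <- K - 1L
  g <- exp(gam)
  lower <- mc - rev(cumsum(g[seq_len(G)]))
  upper <- mc + cumsum(g[G + seq_len(G)])
  list(mc = mc, cuts = c(lower, mc, upper))
}

# Scalar log-likelihood; nS1/nS2 in the canonical 2K ordering.
metad_loglik <- function(metad, gam, cprime, nS1, nS2, K) {
  cc <- gaps_to_criteria(metad, cprime, gam, K)
  mu <- metad / 2
  P1 <- pnorm(cc$cuts + mu)  # stimulus S1 (mean -mu): Phi(cut - (-mu))
  P2 <- pnorm(cc$cuts - mu)  # stimulus S2
  p1 <- diff(c(0, P1, 1))
  p2 <- diff(c(0, P2, 1))
  d1 <- P1[K]               # P(x < mc | S1)
  d2 <- P2[K]
  cond1 <- p1 / c(rep(d1, K), rep(1 - d1, K))
  cond2 <- p2 / c(rep(d2, K), rep(1 - d2, K))
  sum(nS1 * log(pmax(cond1, 1e-300))) + sum(nS2 * log(pmax(cond2, 1e-300)))
}

#' Maximum-likelihood meta-d' for a single subject and task
#'
#' Fits the equal-variance type-II SDT model: meta-d' is the type-I
#' sensitivity that, fed through an ideal confidence-generating observer,
#' would reproduce the observed response-conditional confidence distributions.
#' The type-1 criterion is fixed at the empirical relative criterion
#' c' = c/d' (scaled by meta-d' on the meta level), and the 2(K-1) type-2
#' criteria are free, kept ordered by a cumulative-gap reparameterisation, so
#' no constrained optimiser is needed. Metacognitive efficiency is reported as
#' Mratio = meta-d'/d'.
#'
#' A log-linear pad of `1/(2K)` per cell is applied only when an entire
#' response-conditional cell family is empty (common at 40 trials); with a
#' single observed confidence level the fit is degenerate and meta-d' is
#' reported as 0 with `convergence = "degenerate"`.
#'
#' @param counts A `counts_table`; collapse an 11-level scale to ~4 bins first
#'   (see [build_counts()]) when trials are few.
#' @param metad_max Upper search bound for meta-d'.
#' @return An object of class `metad_fit` with elements `metad`, `mratio`,
#'   `dprime`, `criterion`, `type2_criteria`, `loglik`, `convergence`.
#' @examples
#' tr <- simulate_subject_task(subject_task_params(2, metad = 1.5), 400, seed = 1)
#' fit <- fit_metad_mle(build_counts(tr, 11, collapse_to = 4))
#' glance(fit)
#' @export
fit_metad_mle <- function(counts, metad_max = 10) {
  stopifnot(inherits(counts, "counts_table"))
  K <- counts$n_levels
  G <- K - 1L
  sdt <- compute_dprime(counts, correction = "loglinear")
  dprime <- sdt$dprime
  cprime <- if (abs(dprime) > 1e-12) sdt$criterion / dprime else sdt$criterion

  nS1 <- counts$nR_S1
  nS2 <- counts$nR_S2

  # degenerate input: a single observed confidence level carries no type-II
  # information (the type-II ROC is the diagonal)
  lev_used <- used_levels(nS1 + nS2, K)
  if (length(lev_used) <= 1L) {
    return(new_metad_fit(0, dprime, sdt$criterion, cprime,
                         gaps_to_criteria(0, cprime, rep(log(0.5), 2 * G), K)$cuts,
                         loglik = NA_real_, convergence = "degenerate",
                         n_levels = K))
  }

  # log-linear pad only when a response-conditional family is empty
  fam_tot <- c(sum(nS1[1:K]), sum(nS1[(K + 1):(2 * K)]),
               sum(nS2[1:K]), sum(nS2[(K + 1):(2 * K)]))
  if (any(fam_tot == 0)) {
    nS1 <- nS1 + 1 / (2 * K)
    nS2 <- nS2 + 1 / (2 * K)
  }

  obj <- function(par) {
    md <- par[1]
    if (md < 0 || md > metad_max) return(1e10)
    -metad_loglik(md, par[-1], cprime, nS1, nS2, K)
  }
  starts <- list(
    c(max(dprime, 0.1), rep(log(0.5), 2 * G)),
    c(max(dprime / 2, 0.05), rep(log(0.8), 2 * G))
  )
  best <- NULL
  for (p0 in starts) {
    fit <- optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-12))
    # polish from the current optimum
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  metad <- best$par[1]
  cuts <- gaps_to_criteria(metad, cprime, best$par[-1], K)$cuts
  new_metad_fit(metad, dprime, sdt$criterion, cprime, cuts,
                loglik = -best$value,
                convergence = if (best$convergence == 0) "ok" else "maxit",
                n_levels = K)
}

used_levels <- function(cell_totals, K) {
  lev_of_cell <- c((K - 1):0, 0:(K - 1))
  sort(unique(lev_of_cell[cell_totals > 0]))
}

new_metad_fit <- function(metad, dprime, criterion, cprime, cuts,
                          loglik, convergence, n_levels) {
  structure(
    list(metad = metad,
         mratio = if (abs(dprime) > 1e-12) metad / dprime else NA_real_,
         dprime = dprime, criterion = criterion, cprime = cprime,
         type2_criteria = cuts[-n_levels],  # drop the central mc entry
         loglik = loglik, convergence = convergence, n_levels = n_levels),
    class = "metad_fit"
  )
}

#' @export
print.metad_fit <- function(x, ...) {
  cat(sprintf("<metad_fit> meta-d' = %.3f, d' = %.3f, Mratio = %.3f (%s)\n",
              x$metad, x$dprime, x$mratio, x$convergence))
  invisible(x)
}

#' @rdname fit_metad_mle
#' @param x A `metad_fit`.
#' @param ... Unused.
#' @export
tidy.metad_fit <- function(x, ...) {
  tibble::tibble(
    term = c("metad", "mratio", "dprime", "criterion"),
    estimate = c(x$metad, x$mratio, x$dprime, x$criterion)
  )
}

#' @rdname fit_metad_mle
#' @export
glance.metad_fit <- function(x, ...) {
  tibble::tibble(metad = x$metad, mratio = x$mratio, dprime = x$dprime,
                 criterion = x$criterion, loglik = x$loglik,
                 convergence = x$convergence)
}

#' Per-subject, per-task maximum-likelihood meta-d' point estimates
#'
#' Convenience wrapper running [fit_metad_mle()] on every subject x task cell
#' of a trial table; this is the "nonhierarchical" estimation path, to be
#' combined with [exclude_low_performance()] before correlating Mratio across
#' tasks.
#'
#' @param trials Multi-subject trial tibble.
#' @param n_levels Confidence levels the data were recorded on.
#' @param collapse_to Bins used for fitting (default 4; see [build_counts()]).
#' @return Tibble with `subject`, `task`, `dprime`, `criterion`, `metad`,
#'   `mratio`, `convergence`.
#' @export
fit_metad_pointwise <- function(trials, n_levels = 11, collapse_to = 4) {
  cells <- counts_by_subject_task(trials, n_levels, collapse_to)
  fits <- purrr::map(cells$counts, fit_metad_mle)
  dplyr::bind_cols(
    cells[c("subject", "task")],
    purrr::map_dfr(fits, glance)[c("dprime", "criterion", "metad", "mratio", "convergence")]
  )
}
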