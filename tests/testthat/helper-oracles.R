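# Independent brute-force oracles. These deliberately re-derive quantities
# from first principles (loops, enumeration, direct formulas) and share no
# code with the package implementations they check.

# Trapezoidal AUROC2 by explicit enumeration of cumulative ROC points.
# `correct`, `incorrect`: counts per confidence level, ascending (level 0 first).
oracle_auroc2 <- function(correct, incorrect) {
  K <- length(correct)
  H <- sum(correct)
  F <- sum(incorrect)
  tpr <- 0
  fpr <- 0
  area <- 0
  ch <- 0
  cf <- 0
  for (k in K:1) { # sweep threshold from the top confidence level down
    ch <- ch + correct[k]
    cf <- cf + incorrect[k]
    tpr_new <- ch / H
    fpr_new <- cf / F
    area <- area + (fpr_new - fpr) * (tpr_new + tpr) / 2
    tpr <- tpr_new
    fpr <- fpr_new
  }
  area
}

# Independent type-II cell probabilities: explicit criteria (not gaps), direct
# normalisation of truncated-normal masses.
oracle_t2_loglik <- function(metad, criteria_s1, criteria_s2, cprime, nS1, nS2, K) {
  mc <- cprime * metad
  cuts <- c(-Inf, criteria_s1, mc, criteria_s2, Inf)
  if (any(diff(cuts) < 0)) return(-Inf)
  ll <- 0
  for (stim in 1:2) {
    mu <- if (stim == 1) -metad / 2 else metad / 2
    masses <- pnorm(cuts[-1] - mu) - pnorm(cuts[-length(cuts)] - mu)
    p_s1_resp <- pnorm(mc - mu)
    probs <- c(masses[1:K] / p_s1_resp, masses[(K + 1):(2 * K)] / (1 - p_s1_resp))
    n <- if (stim == 1) nS1 else nS2
    ll <- ll + sum(n * log(pmax(probs, 1e-300)))
  }
  ll
}

# Exhaustive grid search over meta-d' with nested criteria optimisation at
# every grid point (warm-started along the grid for speed; the search over
# meta-d' itself is exhaustive).
oracle_grid_metad <- function(counts, step = 0.005, metad_max = 5) {
  K <- counts$n_levels
  G <- K - 1L
  sdt <- compute_dprime(counts, correction = "loglinear")
  cprime <- sdt$criterion / sdt$dprime
  nS1 <- counts$nR_S1
  nS2 <- counts$nR_S2
  fam <- c(sum(nS1[1:K]), sum(nS1[(K + 1):(2 * K)]),
           sum(nS2[1:K]), sum(nS2[(K + 1):(2 * K)]))
  if (any(fam == 0)) {
    nS1 <- nS1 + 1 / (2 * K)
    nS2 <- nS2 + 1 / (2 * K)
  }
  # criteria as offsets below/above the scaled criterion, optimised on the
  # log scale to keep the ordering
  obj <- function(md, par) {
    lo <- exp(par[1:G])
    hi <- exp(par[G + 1:G])
    mc <- cprime * md
    -oracle_t2_loglik(md, mc - rev(cumsum(lo)), mc + cumsum(hi),
                      cprime, nS1, nS2, K)
  }
  grid <- seq(0, metad_max, by = step)
  par <- rep(log(0.5), 2 * G)
  best_ll <- -Inf
  best_md <- NA_real_
  lls <- numeric(length(grid))
  for (i in seq_along(grid)) {
    o <- optim(par, function(p) obj(grid[i], p), method = "Nelder-Mead",
               control = list(maxit = 600, reltol = 1e-10))
    par <- o$par
    lls[i] <- -o$value
    if (lls[i] > best_ll) {
      best_ll <- lls[i]
      best_md <- grid[i]
    }
  }
  list(metad = best_md, loglik = best_ll, grid = grid, logliks = lls)
}

# d' and criterion straight from the defining formulas.
oracle_dprime <- function(hit_rate, fa_rate) {
  c(dprime = qnorm(hit_rate) - qnorm(fa_rate),
    criterion = -0.5 * (qnorm(hit_rate) + qnorm(fa_rate)))
}

# Paired t statistic from the difference-score definition.
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  se <- sd(d) / sqrt(n)
  t <- mean(d) / se
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1), dz = mean(d) / sd(d))
}

# Small simulated count table for oracle-equivalence checks.
random_count_table <- function(seed, n_levels = 3, n_trials = 60) {
  withr::with_seed(seed, {
    p <- subject_task_params(
      dprime = runif(1, 0.8, 2.5),
      metad = runif(1, 0.4, 2.5),
      criterion = rnorm(1, 0, 0.2),
      n_levels = n_levels
    )
    build_counts(simulate_subject_task(p, n_trials), n_levels = n_levels)
  })
}
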