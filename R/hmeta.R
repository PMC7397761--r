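#' Model specification for the hierarchical multi-task meta-d' model
#'
#' Collects the priors of the hierarchical model. Per task t the group mean
#' of log(meta-d'/d') has a `Normal(0, 1)` prior and the group SD an
#' `InvSqrtGamma(0.001, 0.001)` prior (i.e. `1/sigma^2 ~ Gamma(0.001, 0.001)`);
#' each off-diagonal entry of the cross-task correlation matrix has an
#' element-wise `Uniform(-1, 1)` prior with non-positive-semidefinite states
#' rejected at evaluation. Each subject's log-Mratio vector across tasks is a
#' draw from `MVN(mu, diag(sigma) rho diag(sigma))`. Subject-level type-2
#' criteria are given weakly informative ordered priors via independent
#' normals on the log-gaps between consecutive criteria, centred on the
#' empirical scaled criterion by construction.
#'
#' @param mu_prior_mean,mu_prior_sd Normal prior on each group mean `mu_M`.
#' @param sigma_prior_shape,sigma_prior_rate Gamma prior on each precision
#'   `1/sigma_M^2`.
#' @param gamma_prior_mean,gamma_prior_sd Normal prior on the log-gaps of the
#'   subject-level type-2 criteria.
#' @param sigma_bounds Hard bounds keeping the nearly improper SD prior
#'   numerically sane.
#' @return An object of class `hmeta_model_spec`.
#' @export
hmeta_model_spec <- function(mu_prior_mean = 0, mu_prior_sd = 1,
                             sigma_prior_shape = 0.001, sigma_prior_rate = 0.001,
                             gamma_prior_mean = log(0.5), gamma_prior_sd = 1,
                             sigma_bounds = c(1e-6, 1e3)) {
  structure(
    list(mu_prior_mean = mu_prior_mean, mu_prior_sd = mu_prior_sd,
         sigma_prior_shape = sigma_prior_shape, sigma_prior_rate = sigma_prior_rate,
         gamma_prior_mean = gamma_prior_mean, gamma_prior_sd = gamma_prior_sd,
         sigma_bounds = sigma_bounds),
    class = "hmeta_model_spec"
  )
}

#' MCMC settings
#'
#' @param n_chains Number of chains (>= 2, so that R-hat is defined).
#' @param n_samples Kept samples per chain (after burn-in).
#' @param n_burnin Burn-in iterations per chain, discarded; proposal step
#'   sizes are adapted only during burn-in.
#' @param seed Base seed; chain c uses a seed derived from it.
#' @param keep_subject_draws Store per-subject log-Mratio draws (memory heavy
#'   for large groups); posterior means per subject are always kept.
#' @param adapt Adapt proposal step sizes during burn-in.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_samples = 10000, n_burnin = 1000,
                        seed = NULL, keep_subject_draws = FALSE, adapt = TRUE) {
  assert_scalar_number(n_chains, "n_chains", lower = 2)
  assert_scalar_number(n_samples, "n_samples", lower = 10)
  assert_scalar_number(n_burnin, "n_burnin", lower = 0)
  structure(
    list(n_chains = as.integer(n_chains), n_samples = as.integer(n_samples),
         n_burnin = as.integer(n_burnin), seed = seed,
         keep_subject_draws = isTRUE(keep_subject_draws), adapt = isTRUE(adapt)),
    class = "mcmc_config"
  )
}

# Vectorised (across subjects) type-II log-likelihood for one task.
t2_loglik_vec <- function(md, cprime, gam, cnt1, cnt2, K) {
  G <- K - 1L
  mc <- cprime * md
  g <- exp(gam)
  cs1 <- g[, seq_len(G), drop = FALSE]
  cs2 <- g[, G + seq_len(G), drop = FALSE]
  if (G > 1) {
    for (j in 2:G) {
      cs1[, j] <- cs1[, j - 1] + cs1[, j]
      cs2[, j] <- cs2[, j - 1] + cs2[, j]
    }
  }
  cuts <- cbind(mc - cs1[, G:1, drop = FALSE], mc, mc + cs2) # N x (2K-1)
  mu <- md / 2
  ll <- numeric(length(md))
  for (s in 1:2) { # stimulus S1 then S2
    P <- pnorm(if (s == 1) cuts + mu else cuts - mu)
    p <- cbind(P[, 1], P[, -1, drop = FALSE] - P[, -(2 * K - 1), drop = FALSE],
               1 - P[, 2 * K - 1])
    d <- P[, K]
    p[, 1:K] <- p[, 1:K] / d
    p[, (K + 1):(2 * K)] <- p[, (K + 1):(2 * K)] / (1 - d)
    cnt <- if (s == 1) cnt1 else cnt2
    ll <- ll + rowSums(cnt * log(pmax(p, 1e-300)))
  }
  # saturated cell probabilities (huge meta-d') produce 0/0; treat as impossible
  ll[!is.finite(ll)] <- -Inf
  ll
}

# Multivariate-normal log-density of the N x T matrix of subject log-Mratios;
# -Inf when the implied covariance is not positive definite.
mvn_loglik_mat <- function(logM, mu, sigma, rho) {
  T_n <- length(mu)
  Sigma <- (sigma %o% sigma) * rho
  U <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(U)) return(-Inf)
  centered <- sweep(logM, 2, mu)
  zmat <- forwardsolve(t(U), t(centered))
  -0.5 * nrow(logM) * T_n * log(2 * pi) - nrow(logM) * sum(log(diag(U))) -
    0.5 * sum(zmat^2)
}

# With the likelihood disabled the posterior IS the prior, which is fully
# known, so draw from it exactly (ancestrally): group parameters from their
# priors -- the correlation matrix by element-wise Uniform(-1,1) draws with
# rejection of non-positive-semidefinite states -- then subject effects from
# the implied multivariate Gaussian. iid draws, no Markov chain needed.
run_prior_chain <- function(dat, spec, mcmc, chain_seed) {
  with_local_seed(chain_seed, {
    N <- dat$N; T_n <- dat$T
    P_n <- nrow(dat$pairs)
    n_keep <- mcmc$n_samples
    keep_mu <- matrix(NA_real_, n_keep, T_n)
    keep_sigma <- matrix(NA_real_, n_keep, T_n)
    keep_rho <- matrix(NA_real_, n_keep, max(P_n, 1))
    keep_logM <- if (mcmc$keep_subject_draws) array(NA_real_, c(n_keep, N, T_n)) else NULL
    sum_mratio <- matrix(0, N, T_n)
    for (k in seq_len(n_keep)) {
      mu <- rnorm(T_n, spec$mu_prior_mean, spec$mu_prior_sd)
      tau <- stats::rgamma(T_n, shape = spec$sigma_prior_shape,
                           rate = spec$sigma_prior_rate)
      sigma <- pmin(pmax(1 / sqrt(tau), spec$sigma_bounds[1]), spec$sigma_bounds[2])
      rho <- diag(T_n)
      if (P_n > 0) {
        repeat {
          r <- runif(P_n, -1, 1)
          rho[cbind(dat$pairs$i, dat$pairs$j)] <- r
          rho[cbind(dat$pairs$j, dat$pairs$i)] <- r
          ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
          if (min(ev) >= 0) break
        }
        keep_rho[k, ] <- rho[cbind(dat$pairs$i, dat$pairs$j)]
      }
      keep_mu[k, ] <- mu
      keep_sigma[k, ] <- sigma
      L <- matrix_sqrt((sigma %o% sigma) * rho)
      logM <- sweep(matrix(rnorm(N * T_n), N, T_n) %*% t(L), 2, mu, "+")
      if (!is.null(keep_logM)) keep_logM[k, , ] <- logM
      sum_mratio <- sum_mratio + exp(pmin(logM, 700))
    }
    list(mu = keep_mu, sigma = keep_sigma,
         rho = if (P_n > 0) keep_rho else NULL,
         logM = keep_logM,
         subject_mratio_mean = sum_mratio / n_keep,
         steps = NULL)
  })
}

# One MCMC chain; returns kept draws and acceptance diagnostics.
run_hmeta_chain <- function(dat, spec, mcmc, chain_seed, prior_only) {
  if (prior_only) return(run_prior_chain(dat, spec, mcmc, chain_seed))
  with_local_seed(chain_seed, {
    N <- dat$N; T_n <- dat$T; K <- dat$K
    G2 <- 2L * (K - 1L)
    pairs <- dat$pairs
    P_n <- nrow(pairs)

    logM <- matrix(0, N, T_n)
    gam <- lapply(seq_len(T_n), function(t) {
      matrix(spec$gamma_prior_mean, N, G2)
    })
    mu <- rep(spec$mu_prior_mean, T_n)
    sigma <- rep(0.5, T_n)
    rho <- diag(T_n)

    task_ll <- function(t, logM_col, gam_t) {
      t2_loglik_vec(exp(logM_col) * dat$dhat[, t], dat$cprime[, t], gam_t,
                    dat$cnt1[[t]], dat$cnt2[[t]], K)
    }
    ll <- vapply(seq_len(T_n), function(t) task_ll(t, logM[, t], gam[[t]]),
                 numeric(N))
    ll <- matrix(ll, N, T_n)

    step_logM <- rep(0.2, T_n)
    step_gam <- rep(0.08, T_n)
    step_sigma <- rep(0.15, T_n)
    step_rho <- rep(0.12, max(P_n, 1))
    step_scale <- rep(0.3, T_n)
    step_shift <- rep(0.1, T_n)
    step_rho_nc <- rep(0.2, max(P_n, 1))
    acc <- list(logM = rep(0, T_n), gam = rep(0, T_n),
                sigma = rep(0, T_n), rho = rep(0, max(P_n, 1)),
                scale = rep(0, T_n), shift = rep(0, T_n),
                rho_nc = rep(0, max(P_n, 1)))
    window <- 25L
    n_group_sweeps <- 5L

    n_iter <- mcmc$n_burnin + mcmc$n_samples
    keep_mu <- matrix(NA_real_, mcmc$n_samples, T_n)
    keep_sigma <- matrix(NA_real_, mcmc$n_samples, T_n)
    keep_rho <- matrix(NA_real_, mcmc$n_samples, max(P_n, 1))
    keep_logM <- if (mcmc$keep_subject_draws) {
      array(NA_real_, c(mcmc$n_samples, N, T_n))
    } else NULL
    sum_mratio <- matrix(0, N, T_n)

    cur_mvn <- mvn_loglik_mat(logM, mu, sigma, rho)

    for (iter in seq_len(n_iter)) {
      Sigma <- (sigma %o% sigma) * rho

      # --- subject-level log-Mratio, task by task, vectorised over subjects
      for (t in seq_len(T_n)) {
        if (T_n > 1) {
          w <- solve(Sigma[-t, -t, drop = FALSE], Sigma[-t, t])
          cond_var <- max(Sigma[t, t] - sum(Sigma[t, -t] * w), 1e-12)
          cond_mean <- mu[t] +
            as.vector(sweep(logM[, -t, drop = FALSE], 2, mu[-t]) %*% w)
        } else {
          cond_var <- Sigma[1, 1]
          cond_mean <- rep(mu[1], N)
        }
        prop <- logM[, t] + rnorm(N) * step_logM[t]
        ll_prop <- task_ll(t, prop, gam[[t]])
        log_acc <- (ll_prop + dnorm(prop, cond_mean, sqrt(cond_var), log = TRUE)) -
          (ll[, t] + dnorm(logM[, t], cond_mean, sqrt(cond_var), log = TRUE))
        take <- !is.na(log_acc) & log(runif(N)) < log_acc
        logM[take, t] <- prop[take]
        ll[take, t] <- ll_prop[take]
        acc$logM[t] <- acc$logM[t] + mean(take)
      }

      # --- subject-level type-2 criterion log-gaps (block per subject)
      for (t in seq_len(T_n)) {
        prop <- gam[[t]] + matrix(rnorm(N * G2), N, G2) * step_gam[t]
        ll_prop <- task_ll(t, logM[, t], prop)
        lp_prop <- rowSums(dnorm(prop, spec$gamma_prior_mean,
                                 spec$gamma_prior_sd, log = TRUE))
        lp_cur <- rowSums(dnorm(gam[[t]], spec$gamma_prior_mean,
                                spec$gamma_prior_sd, log = TRUE))
        log_acc <- (ll_prop + lp_prop) - (ll[, t] + lp_cur)
        take <- !is.na(log_acc) & log(runif(N)) < log_acc
        gam[[t]][take, ] <- prop[take, ]
        ll[take, t] <- ll_prop[take]
        acc$gam[t] <- acc$gam[t] + mean(take)
      }

      # --- group means: conjugate Gibbs draw
      Sigma_inv <- chol2inv(chol((sigma %o% sigma) * rho))
      A <- N * Sigma_inv + diag(1 / spec$mu_prior_sd^2, T_n)
      b <- Sigma_inv %*% colSums(logM) +
        spec$mu_prior_mean / spec$mu_prior_sd^2
      U_A <- chol(A)
      mu <- as.vector(solve(A, b) + backsolve(U_A, rnorm(T_n)))
      cur_mvn <- mvn_loglik_mat(logM, mu, sigma, rho)

      # --- joint shift move: translate a task's group mean together with all
      # of its subject effects. The centered MVN term is invariant, so only
      # the mu prior and the task likelihood enter; with small sigma this is
      # the move that lets the pinched block drift as one.
      for (t in seq_len(T_n)) {
        delta <- rnorm(1) * step_shift[t]
        logM_col <- logM[, t] + delta
        ll_prop <- task_ll(t, logM_col, gam[[t]])
        log_acc <- sum(ll_prop) - sum(ll[, t]) +
          dnorm(mu[t] + delta, spec$mu_prior_mean, spec$mu_prior_sd, log = TRUE) -
          dnorm(mu[t], spec$mu_prior_mean, spec$mu_prior_sd, log = TRUE)
        if (is.finite(log_acc) && log(runif(1)) < log_acc) {
          logM[, t] <- logM_col
          mu[t] <- mu[t] + delta
          ll[, t] <- ll_prop
          acc$shift[t] <- acc$shift[t] + 1
        }
      }
      cur_mvn <- mvn_loglik_mat(logM, mu, sigma, rho)

      # --- joint scale move: contract/expand a task's subject deviations
      # together with its group SD. The sigma posterior has a funnel (small
      # sigma pinches every logM towards mu) that elementwise updates cross
      # very slowly; this move jumps between funnel regimes directly.
      # Deterministic map (logM, sigma) -> (mu + c (logM - mu), c sigma) with
      # symmetric log-scale step, Jacobian c^(N+1).
      for (t in seq_len(T_n)) {
        cc <- exp(rnorm(1) * step_scale[t])
        s_prop <- sigma[t] * cc
        if (s_prop < spec$sigma_bounds[1] || s_prop > spec$sigma_bounds[2]) next
        logM_prop <- logM
        logM_prop[, t] <- mu[t] + cc * (logM[, t] - mu[t])
        sigma_new <- sigma; sigma_new[t] <- s_prop
        ll_prop <- task_ll(t, logM_prop[, t], gam[[t]])
        mvn_prop <- mvn_loglik_mat(logM_prop, mu, sigma_new, rho)
        a <- spec$sigma_prior_shape; bb <- spec$sigma_prior_rate
        lp_sig <- function(s) -(2 * a + 1) * log(s) - bb / s^2
        log_acc <- (sum(ll_prop) + mvn_prop + lp_sig(s_prop)) -
          (sum(ll[, t]) + cur_mvn + lp_sig(sigma[t])) + (N + 1) * log(cc)
        if (is.finite(log_acc) && log(runif(1)) < log_acc) {
          logM <- logM_prop
          sigma <- sigma_new
          ll[, t] <- ll_prop
          cur_mvn <- mvn_prop
          acc$scale[t] <- acc$scale[t] + 1
        }
      }

      # --- non-centered correlation move: propose rho', keep each subject's
      # standardized coordinates eta = L^-1 (logM - mu) fixed and remap
      # logM' = mu + L' eta. The MVN prior ratio cancels the map's Jacobian
      # exactly, so acceptance reduces to the likelihood ratio (the rho prior
      # is flat on admissible states). This updates rho against the data
      # directly instead of through the shrunk subject configuration.
      if (P_n > 0) {
        for (p in seq_len(P_n)) {
          i <- pairs$i[p]; j <- pairs$j[p]
          r_prop <- rho[i, j] + rnorm(1) * step_rho_nc[p]
          if (abs(r_prop) >= 1) next
          rho_new <- rho
          rho_new[i, j] <- rho_new[j, i] <- r_prop
          Sig_cur <- (sigma %o% sigma) * rho
          Sig_new <- (sigma %o% sigma) * rho_new
          U_cur <- tryCatch(chol(Sig_cur), error = function(e) NULL)
          U_new <- tryCatch(chol(Sig_new), error = function(e) NULL)
          if (is.null(U_cur) || is.null(U_new)) next
          eta <- forwardsolve(t(U_cur), t(sweep(logM, 2, mu)))      # T x N
          logM_prop <- sweep(t(t(U_new) %*% eta), 2, mu, "+")       # N x T
          ll_prop <- vapply(seq_len(T_n),
                            function(t) task_ll(t, logM_prop[, t], gam[[t]]),
                            numeric(N))
          ll_prop <- matrix(ll_prop, N, T_n)
          log_acc <- sum(ll_prop) - sum(ll)
          if (is.finite(log_acc) && log(runif(1)) < log_acc) {
            rho <- rho_new
            logM <- logM_prop
            ll <- ll_prop
            cur_mvn <- mvn_loglik_mat(logM, mu, sigma, rho)
            acc$rho_nc[p] <- acc$rho_nc[p] + 1
          }
        }
      }

      # Group-scale updates cost only a T x T Cholesky plus an N x T solve,
      # a sliver of the subject-level likelihood work, so several sweeps per
      # iteration sharply reduce autocorrelation in sigma and rho.
      for (group_sweep in seq_len(n_group_sweeps)) {
        # --- group SDs: random walk on the log scale
        for (t in seq_len(T_n)) {
          phi <- log(sigma[t])
          phi_prop <- phi + rnorm(1) * step_sigma[t]
          s_prop <- exp(phi_prop)
          if (s_prop < spec$sigma_bounds[1] || s_prop > spec$sigma_bounds[2]) next
          sigma_new <- sigma; sigma_new[t] <- s_prop
          mvn_prop <- mvn_loglik_mat(logM, mu, sigma_new, rho)
          # InvSqrtGamma(a, b) density on sigma plus log-scale Jacobian
          a <- spec$sigma_prior_shape; bb <- spec$sigma_prior_rate
          lp <- function(s) -(2 * a + 1) * log(s) - bb / s^2 + log(s)
          if (log(runif(1)) < (mvn_prop + lp(s_prop)) - (cur_mvn + lp(sigma[t]))) {
            sigma <- sigma_new
            cur_mvn <- mvn_prop
            acc$sigma[t] <- acc$sigma[t] + 1
          }
        }

        # --- correlations: element-wise Uniform(-1,1) prior, PSD by rejection
        if (P_n > 0) {
          for (p in seq_len(P_n)) {
            i <- pairs$i[p]; j <- pairs$j[p]
            r_prop <- rho[i, j] + rnorm(1) * step_rho[p]
            if (abs(r_prop) >= 1) next
            rho_new <- rho
            rho_new[i, j] <- rho_new[j, i] <- r_prop
            mvn_prop <- mvn_loglik_mat(logM, mu, sigma, rho_new)
            if (log(runif(1)) < mvn_prop - cur_mvn) {
              rho <- rho_new
              cur_mvn <- mvn_prop
              acc$rho[p] <- acc$rho[p] + 1
            }
          }
        }
      }

      # --- step-size adaptation, burn-in only
      if (mcmc$adapt && iter <= mcmc$n_burnin && iter %% window == 0) {
        tune <- function(step, rate, target) {
          pmin(pmax(step * exp(0.6 * (rate - target)), 1e-4), 5)
        }
        step_logM <- tune(step_logM, acc$logM / window, 0.44)
        step_gam <- tune(step_gam, acc$gam / window, 0.25)
        step_sigma <- tune(step_sigma, acc$sigma / (window * n_group_sweeps), 0.44)
        step_scale <- tune(step_scale, acc$scale / window, 0.44)
        step_shift <- tune(step_shift, acc$shift / window, 0.44)
        if (P_n > 0) step_rho_nc <- tune(step_rho_nc, acc$rho_nc / window, 0.44)
        if (P_n > 0) {
          step_rho <- tune(step_rho, acc$rho / (window * n_group_sweeps), 0.44)
        }
        acc <- lapply(acc, function(a) a * 0)
      }

      if (iter > mcmc$n_burnin) {
        k <- iter - mcmc$n_burnin
        keep_mu[k, ] <- mu
        keep_sigma[k, ] <- sigma
        if (P_n > 0) keep_rho[k, ] <- rho[cbind(pairs$i, pairs$j)]
        if (!is.null(keep_logM)) keep_logM[k, , ] <- logM
        sum_mratio <- sum_mratio + exp(logM)
      }
    }

    list(mu = keep_mu, sigma = keep_sigma,
         rho = if (P_n > 0) keep_rho else NULL,
         logM = keep_logM,
         subject_mratio_mean = sum_mratio / mcmc$n_samples,
         steps = list(logM = step_logM, gam = step_gam,
                      sigma = step_sigma, rho = step_rho))
  })
}

#' Fit the hierarchical multi-task meta-d' model
#'
#' Estimates group-level log-Mratio means, spreads, and the full cross-task
#' correlation matrix of metacognitive efficiency by MCMC. Each subject's
#' log(meta-d'/d') vector across tasks is modelled as a multivariate Gaussian
#' draw; the subject-level likelihood is the response-conditional multinomial
#' of the type-II SDT model (see [fit_metad_mle()]), with type-I d' and
#' criterion fixed per subject and task at their empirical point estimates
#' (log-linear-corrected). No edge correction is applied to the type-II
#' counts: zero cells are handled naturally by the likelihood. All subjects
#' are retained; low-performance exclusion is a concern of the
#' nonhierarchical path only.
#'
#' The sampler is Metropolis-within-Gibbs: vectorised random-walk updates for
#' subject-level parameters, a conjugate Gibbs draw for the group means,
#' log-scale random walks for the group SDs, and element-wise updates of the
#' correlation matrix under its Uniform(-1, 1) prior with rejection of
#' non-positive-definite states. With `prior_only = TRUE` the likelihood is
#' disabled; the posterior is then exactly the joint prior, which is sampled
#' ancestrally (iid draws, correlation matrices by PSD rejection of
#' element-wise uniform draws), so the marginal of each correlation is
#' exactly its prior (a prior-predictive check).
#'
#' @param trials Multi-subject trial tibble, or a nested tibble with columns
#'   `subject`, `task`, `counts` (list of `counts_table`) as produced
#'   internally; every subject must have data for every task.
#' @param n_levels Confidence levels in the raw data.
#' @param collapse_to Confidence bins used for fitting (default 4).
#' @param spec A [hmeta_model_spec()].
#' @param mcmc An [mcmc_config()].
#' @param prior_only Disable the likelihood (sample from the joint prior).
#' @return An object of class `hmeta_posterior`; see [tidy.hmeta_posterior()],
#'   [group_mratio()] and [summarize_correlations()].
#' @examples
#' \donttest{
#' cfg <- group_config(n_tasks = 2, n_subjects = 15, n_trials = 60, seed = 2)
#' fit <- fit_hmetad_multitask(simulate_group(cfg),
#'   mcmc = mcmc_config(n_chains = 2, n_samples = 300, n_burnin = 150, seed = 2))
#' group_mratio(fit)
#' }
#' @export
fit_hmetad_multitask <- function(trials, n_levels = 11, collapse_to = 4,
                                 spec = hmeta_model_spec(),
                                 mcmc = mcmc_config(),
                                 prior_only = FALSE) {
  cells <- if (is.data.frame(trials) && "counts" %in% names(trials)) {
    trials
  } else {
    counts_by_subject_task(trials, n_levels, collapse_to)
  }
  subjects <- sort(unique(cells$subject))
  tasks <- sort(unique(cells$task))
  N <- length(subjects); T_n <- length(tasks)
  grid <- tidyr::expand_grid(subject = subjects, task = tasks)
  missing <- dplyr::anti_join(grid, cells, by = c("subject", "task"))
  if (nrow(missing) > 0) {
    abort(paste0("Every subject needs counts for every task; missing: ",
                 paste(paste(missing$subject, missing$task, sep = "/"),
                       collapse = ", ")))
  }

  K <- cells$counts[[1]]$n_levels
  dhat <- cprime <- matrix(NA_real_, N, T_n)
  cnt1 <- cnt2 <- vector("list", T_n)
  for (t in seq_len(T_n)) {
    cnt1[[t]] <- matrix(0, N, 2 * K)
    cnt2[[t]] <- matrix(0, N, 2 * K)
  }
  for (r in seq_len(nrow(cells))) {
    s <- match(cells$subject[r], subjects)
    t <- match(cells$task[r], tasks)
    ct <- cells$counts[[r]]
    sdt <- compute_dprime(ct, correction = "loglinear")
    d <- max(sdt$dprime, 0.01) # keep the Mratio parameterisation well defined
    dhat[s, t] <- d
    cprime[s, t] <- sdt$criterion / d
    cnt1[[t]][s, ] <- ct$nR_S1
    cnt2[[t]][s, ] <- ct$nR_S2
  }

  pairs <- if (T_n > 1) {
    idx <- utils::combn(T_n, 2)
    tibble::tibble(i = idx[1, ], j = idx[2, ],
                   pair = paste(tasks[idx[1, ]], tasks[idx[2, ]], sep = "~"))
  } else {
    tibble::tibble(i = integer(), j = integer(), pair = character())
  }

  dat <- list(N = N, T = T_n, K = K, dhat = dhat, cprime = cprime,
              cnt1 = cnt1, cnt2 = cnt2, pairs = pairs)

  base_seed <- mcmc$seed %||% sample.int(2^30, 1)
  chains <- lapply(seq_len(mcmc$n_chains), function(ch) {
    run_hmeta_chain(dat, spec, mcmc, derive_seed(base_seed, ch), prior_only)
  })

  bind_draws <- function(name) {
    # iterations x chains x dim
    d3 <- dim(chains[[1]][[name]])[2]
    arr <- array(NA_real_, c(mcmc$n_samples, mcmc$n_chains, d3))
    for (ch in seq_along(chains)) arr[, ch, ] <- chains[[ch]][[name]]
    arr
  }
  draws <- list(mu = bind_draws("mu"), sigma = bind_draws("sigma"))
  if (nrow(pairs) > 0) draws$rho <- bind_draws("rho")
  if (mcmc$keep_subject_draws) {
    draws$logM <- array(NA_real_, c(mcmc$n_samples, mcmc$n_chains, N, T_n))
    for (ch in seq_along(chains)) draws$logM[, ch, , ] <- chains[[ch]]$logM
  }

  subject_mratio <- Reduce(`+`, lapply(chains, `[[`, "subject_mratio_mean")) /
    mcmc$n_chains

  param_tbl <- summarize_group_draws(draws, tasks, pairs)
  bad <- param_tbl$rhat > 1.1
  if (any(bad, na.rm = TRUE)) {
    warn(paste0("R-hat > 1.1 for: ",
                paste(param_tbl$term[which(bad)], collapse = ", "),
                "; consider longer chains."))
  }

  structure(
    list(draws = draws, tasks = tasks, subjects = subjects, pairs = pairs,
         summary = param_tbl, subject_mratio = subject_mratio,
         dhat = dhat, cprime = cprime, n_levels = K,
         spec = spec, mcmc = mcmc, prior_only = prior_only,
         seed = base_seed),
    class = "hmeta_posterior"
  )
}

summarize_group_draws <- function(draws, tasks, pairs) {
  one <- function(arr, dim_idx, term) {
    x <- arr[, , dim_idx]
    if (is.null(dim(x))) x <- matrix(x, ncol = 1)
    pooled <- as.vector(x)
    hdi <- compute_hdi(pooled)
    tibble::tibble(term = term, mean = mean(pooled),
                   median = stats::median(pooled),
                   hdi_lower = hdi[[1]], hdi_upper = hdi[[2]],
                   excludes_zero = hdi[[1]] > 0 | hdi[[2]] < 0,
                   rhat = compute_rhat(x))
  }
  out <- list()
  for (t in seq_along(tasks)) {
    out[[length(out) + 1]] <- one(draws$mu, t, paste0("mu_logM[", tasks[t], "]"))
    out[[length(out) + 1]] <- one(draws$sigma, t, paste0("sigma_logM[", tasks[t], "]"))
  }
  if (!is.null(draws$rho)) {
    for (p in seq_len(nrow(pairs))) {
      out[[length(out) + 1]] <- one(draws$rho, p, paste0("rho[", pairs$pair[p], "]"))
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.hmeta_posterior <- function(x, ...) {
  cat(sprintf("<hmeta_posterior> %d subjects x %d tasks, %d chains x %d kept samples%s\n",
              length(x$subjects), length(x$tasks), x$mcmc$n_chains,
              x$mcmc$n_samples, if (x$prior_only) " (prior only)" else ""))
  print(as.data.frame(x$summary), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Tidy draws or summaries of a hierarchical posterior
#'
#' `tidy()` returns the per-parameter posterior summary (mean, median, 95%
#' HDI, whether the HDI excludes zero, and R-hat). `glance()` returns one-row
#' fit metadata.
#'
#' @param x An `hmeta_posterior`.
#' @param ... Unused.
#' @export
tidy.hmeta_posterior <- function(x, ...) {
  x$summary
}

#' @rdname tidy.hmeta_posterior
#' @export
glance.hmeta_posterior <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(x$subjects), n_tasks = length(x$tasks),
    n_chains = x$mcmc$n_chains, n_samples = x$mcmc$n_samples,
    n_burnin = x$mcmc$n_burnin, max_rhat = max(x$summary$rhat, na.rm = TRUE),
    prior_only = x$prior_only
  )
}

# Pooled draws of a group-level parameter as a plain vector.
pooled_draws <- function(posterior, name, dim_idx) {
  as.vector(posterior$draws[[name]][, , dim_idx])
}

#' Posterior summary of the group-level Mratio per task
#'
#' Transforms the posterior draws of the group mean log-Mratio `mu_M[t]` to
#' the Mratio scale (`exp(mu)`), the scale on which group metacognitive
#' efficiency is reported, and summarises them.
#'
#' @param posterior An `hmeta_posterior`.
#' @return Tibble with `task`, `mratio_mean`, `mratio_median`, `hdi_lower`,
#'   `hdi_upper`.
#' @export
group_mratio <- function(posterior) {
  stopifnot(inherits(posterior, "hmeta_posterior"))
  purrr::map_dfr(seq_along(posterior$tasks), function(t) {
    m <- exp(pooled_draws(posterior, "mu", t))
    hdi <- compute_hdi(m)
    tibble::tibble(task = posterior$tasks[t], mratio_mean = mean(m),
                   mratio_median = stats::median(m),
                   hdi_lower = hdi[[1]], hdi_upper = hdi[[2]])
  })
}

#' Cross-task correlation report
#'
#' For every task pairing, summarises the posterior of the correlation in
#' log-Mratio (mean, 95% HDI, and whether the HDI excludes zero — the
#' Bayesian significance rule used throughout this package) and the posterior
#' of the difference in group Mratio on the exponentiated scale
#' (`exp(mu_i) - exp(mu_j)`).
#'
#' @param posterior An `hmeta_posterior` fitted on at least two tasks.
#' @return An object of class `correlation_report`: a list with tibbles
#'   `correlations` and `differences`.
#' @export
summarize_correlations <- function(posterior) {
  stopifnot(inherits(posterior, "hmeta_posterior"))
  if (is.null(posterior$draws$rho)) {
    abort("The posterior contains no correlation draws (a single task was fitted).")
  }
  pairs <- posterior$pairs
  correlations <- purrr::map_dfr(seq_len(nrow(pairs)), function(p) {
    r <- pooled_draws(posterior, "rho", p)
    hdi <- compute_hdi(r)
    tibble::tibble(
      task_i = posterior$tasks[pairs$i[p]], task_j = posterior$tasks[pairs$j[p]],
      pair = pairs$pair[p], rho_mean = mean(r),
      hdi_lower = hdi[[1]], hdi_upper = hdi[[2]],
      excludes_zero = hdi[[1]] > 0 | hdi[[2]] < 0
    )
  })
  differences <- purrr::map_dfr(seq_len(nrow(pairs)), function(p) {
    d <- exp(pooled_draws(posterior, "mu", pairs$i[p])) -
      exp(pooled_draws(posterior, "mu", pairs$j[p]))
    hdi <- compute_hdi(d)
    tibble::tibble(
      task_i = posterior$tasks[pairs$i[p]], task_j = posterior$tasks[pairs$j[p]],
      pair = pairs$pair[p], diff_mean = mean(d),
      hdi_lower = hdi[[1]], hdi_upper = hdi[[2]],
      excludes_zero = hdi[[1]] > 0 | hdi[[2]] < 0
    )
  })
  structure(list(correlations = correlations, differences = differences),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Cross-task correlations in log-Mratio (posterior mean, 95% HDI):\n")
  print(as.data.frame(x$correlations), digits = 3, row.names = FALSE)
  cat("\nGroup Mratio differences, exp(mu_i) - exp(mu_j):\n")
  print(as.data.frame(x$differences), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Export posterior draws as delimited text and a JSON summary
#'
#' @param posterior An `hmeta_posterior`.
#' @param dir Output directory (created if needed).
#' @return Paths of the files written, invisibly.
#' @export
write_posterior <- function(posterior, dir) {
  stopifnot(inherits(posterior, "hmeta_posterior"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  long <- tidy_group_draws(posterior)
  draws_path <- file.path(dir, "posterior_draws.csv")
  readr::write_csv(long, draws_path)
  summary_path <- file.path(dir, "posterior_summary.json")
  jsonlite::write_json(
    list(summary = posterior$summary,
         seed = posterior$seed,
         mcmc = posterior$mcmc[c("n_chains", "n_samples", "n_burnin")]),
    summary_path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(c(draws_path, summary_path))
}

tidy_group_draws <- function(posterior) {
  tasks <- posterior$tasks
  pairs <- posterior$pairs
  grab <- function(name, labels) {
    arr <- posterior$draws[[name]]
    purrr::map_dfr(seq_along(labels), function(d) {
      x <- arr[, , d]
      if (is.null(dim(x))) x <- matrix(x, ncol = 1)
      tibble::tibble(
        term = labels[d],
        chain = rep(seq_len(ncol(x)), each = nrow(x)),
        iteration = rep(seq_len(nrow(x)), times = ncol(x)),
        value = as.vector(x)
      )
    })
  }
  out <- dplyr::bind_rows(
    grab("mu", paste0("mu_logM[", tasks, "]")),
    grab("sigma", paste0("sigma_logM[", tasks, "]"))
  )
  if (!is.null(posterior$draws$rho)) {
    out <- dplyr::bind_rows(out, grab("rho", paste0("rho[", pairs$pair, "]")))
  }
  out
}
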