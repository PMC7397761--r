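test_that("HDI: degenerate, discrete-window and normal cases", {
  expect_equal(compute_hdi(rep(0.4, 50)), c(lower = 0.4, upper = 0.4))

  # 1..100 at mass .95: every width-94 window ties; leftmost wins
  expect_equal(compute_hdi(1:100, 0.95), c(lower = 1, upper = 95))

  x <- withr::with_seed(8, rnorm(1e6))
  h <- compute_hdi(x)
  expect_lt(abs(h[["lower"]] + 1.96), 0.02)
  expect_lt(abs(h[["upper"]] - 1.96), 0.02)

  expect_error(compute_hdi(1:100, mass = 1.2), "between 0 and 1")
  expect_error(compute_hdi(c(1, 2, 3)), "10")
})

test_that("R-hat: degenerate limit, separated chains, converged sampler", {
  n <- 500
  ch <- withr::with_seed(4, rnorm(n))
  # identical copies: no between-chain variance; degenerate limit sqrt((n-1)/n)
  expect_equal(compute_rhat(cbind(ch, ch, ch)), sqrt((n - 1) / n),
               tolerance = 1e-6)

  # chains from Normal(0,1) and Normal(5,1): plug the closed form
  chains <- withr::with_seed(5, cbind(rnorm(1000), rnorm(1000, 5)))
  got <- compute_rhat(chains)
  W <- mean(c(var(chains[, 1]), var(chains[, 2])))
  B <- 1000 * var(colMeans(chains))
  expect_equal(got, sqrt((999 / 1000 * W + B / 1000) / W), tolerance = 1e-12)
  expect_gt(got, 3)

  # well-mixed: iid draws from the same target
  mixed <- withr::with_seed(6, matrix(rnorm(3000), ncol = 3))
  expect_lt(compute_rhat(mixed), 1.05)

  expect_error(compute_rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
  expect_error(compute_rhat(list(rnorm(10), rnorm(12))), "equal length")
})

test_that("correlation summaries flag HDIs that exclude zero correctly", {
  # build a synthetic posterior object: constant rho draws at 0.5
  make_post <- function(rho_draws) {
    n <- length(rho_draws) / 2
    mu <- array(NA_real_, c(n, 2, 2))
    mu[, , 1] <- withr::with_seed(71, rnorm(2 * n, 0.2, 0.01))
    mu[, , 2] <- withr::with_seed(72, rnorm(2 * n, -0.1, 0.01))
    draws <- list(
      mu = mu,
      sigma = array(0.5, c(n, 2, 2)),
      rho = array(rho_draws, c(n, 2, 1))
    )
    structure(list(
      draws = draws, tasks = c("A", "B"),
      pairs = tibble::tibble(i = 1L, j = 2L, pair = "A~B"),
      subjects = "s1", mcmc = mcmc_config(n_chains = 2, n_samples = n)
    ), class = "hmeta_posterior")
  }
  post <- make_post(rep(0.5, 4000))
  rep1 <- summarize_correlations(post)
  expect_equal(rep1$correlations$rho_mean, 0.5)
  expect_equal(rep1$correlations$hdi_lower, 0.5)
  expect_equal(rep1$correlations$hdi_upper, 0.5)
  expect_true(rep1$correlations$excludes_zero)

  # uniform draws on (-1,1): HDI about [-.95, .95], zero not excluded
  post_u <- make_post(withr::with_seed(7, runif(4000, -1, 1)))
  rep2 <- summarize_correlations(post_u)
  expect_lt(abs(rep2$correlations$hdi_upper - rep2$correlations$hdi_lower - 1.9), 0.05)
  expect_false(rep2$correlations$excludes_zero)

  # difference distributions use the exponentiated group means
  expect_equal(rep1$differences$diff_mean, exp(0.2) - exp(-0.1), tolerance = 0.01)
})

test_that("hierarchical fit recovers null and positive correlations (reduced scale)", {
  mc <- mcmc_config(n_chains = 2, n_samples = 700, n_burnin = 350, seed = 303)

  cfg0 <- group_config(n_tasks = 2, n_subjects = 60, n_trials = 400,
                       mu_logM = c(0, 0), sigma_logM = c(0.4, 0.4), rho = 0,
                       dprime_range = c(1, 2.5), seed = 301)
  fit0 <- fit_hmetad_multitask(simulate_group(cfg0), mcmc = mc)
  s0 <- summarize_correlations(fit0)$correlations
  expect_lt(abs(s0$rho_mean), 0.15)
  expect_true(s0$hdi_lower <= 0 && s0$hdi_upper >= 0)

  cfg6 <- group_config(n_tasks = 2, n_subjects = 60, n_trials = 400,
                       mu_logM = c(0, 0), sigma_logM = c(0.4, 0.4), rho = 0.6,
                       dprime_range = c(1, 2.5), seed = 302)
  fit6 <- fit_hmetad_multitask(simulate_group(cfg6), mcmc = mc)
  s6 <- summarize_correlations(fit6)$correlations
  expect_lt(abs(s6$rho_mean - 0.6), 0.2)
  expect_gt(s6$rho_mean, s0$rho_mean)
})

test_that("posterior HDIs on the group mean shrink with more subjects", {
  mc <- mcmc_config(n_chains = 2, n_samples = 500, n_burnin = 300, seed = 99)
  width <- vapply(c(30, 120), function(n) {
    cfg <- group_config(n_tasks = 2, n_subjects = n, n_trials = 40,
                        mu_logM = c(-0.2, -0.2), sigma_logM = c(0.4, 0.4),
                        rho = 0.5, seed = 400 + n)
    fit <- suppressWarnings(fit_hmetad_multitask(simulate_group(cfg), mcmc = mc))
    s <- tidy(fit)
    mu_rows <- grepl("^mu_logM", s$term)
    mean(s$hdi_upper[mu_rows] - s$hdi_lower[mu_rows])
  }, numeric(1))
  expect_lt(width[2], width[1])
})

test_that("subjects missing a task are rejected, draws stay in bounds", {
  cfg <- group_config(n_tasks = 2, n_subjects = 8, n_trials = 40, seed = 19)
  tr <- simulate_group(cfg)
  tr_missing <- dplyr::filter(tr, !(subject == "s003" & task == "task2"))
  expect_error(fit_hmetad_multitask(tr_missing,
                                    mcmc = mcmc_config(n_chains = 2, n_samples = 20,
                                                       n_burnin = 10, seed = 1)),
               "s003")

  fit <- suppressWarnings(
    fit_hmetad_multitask(tr, mcmc = mcmc_config(n_chains = 2, n_samples = 200,
                                                n_burnin = 100, seed = 17)))
  expect_true(all(fit$draws$rho >= -1 & fit$draws$rho <= 1))
  expect_true(all(fit$draws$sigma > 0))
  s <- tidy(fit)
  expect_true(all(s$hdi_lower <= s$median & s$median <= s$hdi_upper))
})

test_that("hierarchical fits are reproducible under a fixed seed", {
  cfg <- group_config(n_tasks = 2, n_subjects = 10, n_trials = 40, seed = 77)
  tr <- simulate_group(cfg)
  mc <- mcmc_config(n_chains = 2, n_samples = 150, n_burnin = 80, seed = 55)
  f1 <- suppressWarnings(fit_hmetad_multitask(tr, mcmc = mc))
  f2 <- suppressWarnings(fit_hmetad_multitask(tr, mcmc = mc))
  expect_identical(f1$draws, f2$draws)
  expect_identical(tidy(f1), tidy(f2))
})
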