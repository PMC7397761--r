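test_that("ideal-observer data recover Mratio near 1 at large samples", {
  p <- subject_task_params(dprime = 2, metad = 2)
  tr <- simulate_subject_task(p, 10000, seed = 13)
  fit <- fit_metad_mle(build_counts(tr, 11, collapse_to = 4))
  expect_gt(fit$mratio, 0.9)
  expect_lt(fit$mratio, 1.1)
  expect_identical(fit$convergence, "ok")
})

test_that("constant confidence is a flagged degenerate fit with meta-d' 0", {
  tr <- simulate_subject_task(subject_task_params(dprime = 1.5), 100, seed = 2)
  tr$confidence_level <- 5L
  fit <- fit_metad_mle(build_counts(tr, 11))
  expect_identical(fit$convergence, "degenerate")
  expect_equal(fit$metad, 0)
})

test_that("the fitted optimum beats random admissible parameter vectors", {
  ct <- random_count_table(17, n_levels = 4, n_trials = 120)
  fit <- fit_metad_mle(ct)
  K <- ct$n_levels
  sdt <- compute_dprime(ct, correction = "loglinear")
  cprime <- sdt$criterion / sdt$dprime
  withr::with_seed(99, {
    for (i in 1:100) {
      md <- runif(1, 0, 5)
      gam <- rnorm(2 * (K - 1), log(0.5), 1)
      ll <- metacov:::metad_loglik(md, gam, cprime, ct$nR_S1, ct$nR_S2, K)
      expect_lte(ll, fit$loglik + 1e-6)
    }
  })
})

test_that("MLE matches the package-independent likelihood at its optimum", {
  ct <- random_count_table(23, n_levels = 3, n_trials = 200)
  fit <- fit_metad_mle(ct)
  K <- ct$n_levels
  crit <- fit$type2_criteria
  oracle_ll <- oracle_t2_loglik(fit$metad, crit[1:(K - 1)], crit[K:(2 * K - 2)],
                                fit$cprime, ct$nR_S1, ct$nR_S2, K)
  expect_equal(fit$loglik, oracle_ll, tolerance = 1e-8)
})

test_that("median MLE Mratio over subjects recovers the generating value", {
  for (m in c(0.5, 1.0)) {
    mr <- vapply(1:50, function(s) {
      d <- withr::with_seed(1000 * m + s, runif(1, 1, 2.5))
      p <- subject_task_params(dprime = d, metad = m * d)
      tr <- simulate_subject_task(p, 400, seed = 2000 * m + s)
      fit_metad_mle(build_counts(tr, 11, collapse_to = 4))$mratio
    }, numeric(1))
    expect_lt(abs(median(mr) - m), 0.1)
  }
})

test_that("pointwise fitting covers every subject x task cell", {
  cfg <- group_config(n_tasks = 2, n_subjects = 6, n_trials = 60, seed = 12)
  tr <- simulate_group(cfg)
  pt <- fit_metad_pointwise(tr)
  expect_equal(nrow(pt), 12)
  expect_true(all(c("dprime", "metad", "mratio", "convergence") %in% names(pt)))
  expect_true(all(is.finite(pt$mratio)))
})

test_that("tidy and glance expose the fit in broom style", {
  ct <- random_count_table(5, n_levels = 4, n_trials = 100)
  fit <- fit_metad_mle(ct)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_true(all(c("metad", "mratio") %in% td$term))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$metad, fit$metad)
})
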