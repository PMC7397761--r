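test_that("simulated trials have the declared schema and internal consistency", {
  p <- subject_task_params(dprime = 1.5, metad = 1.2, criterion = 0.1)
  tr <- simulate_subject_task(p, 500, seed = 1, subject = "s1", task = "mem")
  expect_equal(nrow(tr), 500)
  expect_setequal(unique(tr$stimulus), c("S1", "S2"))
  expect_true(all(tr$accurate == as.integer(tr$response == tr$stimulus)))
  expect_true(all(tr$confidence_level %in% 0:10))
  expect_equal(tr$confidence_pct, tr$confidence_level * 10)
})

test_that("fixed seeds give exact reproducibility without touching the caller's RNG", {
  p <- subject_task_params(dprime = 2)
  a <- simulate_subject_task(p, 200, seed = 7)
  set.seed(123)
  outer_draw1 <- runif(1)
  b <- simulate_subject_task(p, 200, seed = 7)
  expect_identical(a, b)

  cfg <- group_config(n_tasks = 2, n_subjects = 8, n_trials = 30, seed = 42)
  g1 <- simulate_group(cfg)
  g2 <- simulate_group(cfg)
  expect_identical(g1, g2)
  set.seed(123)
  expect_identical(runif(1), outer_draw1)
})

test_that("accuracy is at chance when d' = 0 and nondecreasing in d'", {
  acc <- vapply(c(0, 1, 2, 3), function(d) {
    p <- subject_task_params(dprime = d, metad = d)
    mean(simulate_subject_task(p, 10000, seed = 11)$accurate)
  }, numeric(1))
  expect_lt(abs(acc[1] - 0.5), 0.015)
  expect_true(all(diff(acc) >= 0))
})

test_that("empirical type-I d' recovers the generating d' at large samples", {
  for (d in c(0.5, 1.5, 2.5)) {
    p <- subject_task_params(dprime = d, metad = d, criterion = 0.1)
    tr <- simulate_subject_task(p, 2e5, seed = round(100 * d))
    est <- compute_dprime(build_counts(tr, 11))
    expect_lt(abs(est$dprime - d), 0.05)
  }
})

test_that("invalid parameters are rejected", {
  expect_error(subject_task_params(dprime = -1), "dprime")
  expect_error(
    subject_task_params(dprime = 1, type2_criteria = sort(rnorm(20), decreasing = TRUE)),
    "monotone|ascending"
  )
  bad_rho <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(group_config(n_tasks = 3, rho = bad_rho), "positive semidefinite")
})

test_that("group parameter draws follow the configured multivariate Gaussian", {
  rho <- matrix(c(1, 0.6, 0.3, 0.6, 1, 0.0, 0.3, 0.0, 1), 3, 3)
  cfg <- group_config(n_tasks = 3, n_subjects = 5000, n_trials = 10,
                      mu_logM = c(-0.2, 0, 0.2), sigma_logM = c(0.5, 0.4, 0.3),
                      rho = rho, seed = 5)
  truth <- draw_group_params(cfg)
  wide <- tidyr::pivot_wider(truth[c("subject", "task", "logM")],
                             names_from = "task", values_from = "logM")
  lm_mat <- as.matrix(wide[-1])
  expect_true(all(abs(cor(lm_mat) - rho) < 0.05))
  expect_true(all(abs(colMeans(lm_mat) - cfg$mu_logM) < 0.05))

  # independence case
  cfg0 <- group_config(n_tasks = 4, n_subjects = 2000, n_trials = 10,
                       rho = 0, seed = 6)
  t0 <- draw_group_params(cfg0)
  w0 <- as.matrix(tidyr::pivot_wider(t0[c("subject", "task", "logM")],
                                     names_from = "task", values_from = "logM")[-1])
  off <- cor(w0)[upper.tri(diag(4))]
  expect_true(all(abs(off) < 0.05))
})

test_that("zero group spread makes every subject's logM equal the group mean", {
  cfg <- group_config(n_tasks = 2, n_subjects = 20, n_trials = 10,
                      mu_logM = c(-0.3, 0.1), sigma_logM = c(0, 0), seed = 3)
  truth <- draw_group_params(cfg)
  expect_equal(truth$logM[truth$task == "task1"], rep(-0.3, 20))
  expect_equal(truth$logM[truth$task == "task2"], rep(0.1, 20))
})

test_that("simulate_group emits the full subject x task x trial grid", {
  cfg <- group_config(n_tasks = 4, n_subjects = 6, n_trials = 40,
                      n_levels = 11, seed = 9)
  tr <- simulate_group(cfg)
  expect_equal(nrow(tr), 6 * 4 * 40)
  expect_true(all(tr$confidence_level %in% 0:10))
  expect_equal(dplyr::n_distinct(tr$task), 4)
  truth <- attr(tr, "truth")
  expect_equal(nrow(truth), 6 * 4)
  expect_equal(truth$metad, exp(truth$logM) * truth$dprime)
})

test_that("trial tables round-trip through CSV with their truth sidecar", {
  cfg <- group_config(n_tasks = 2, n_subjects = 3, n_trials = 10, seed = 2)
  tr <- simulate_group(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, path)
  expect_true(file.exists(paste0(path, ".truth.json")))
  back <- read_trials(path)
  expect_equal(back, tr, ignore_attr = TRUE)
})
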