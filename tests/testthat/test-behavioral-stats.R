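test_that("confidence level is the plain per-cell mean of confidence_pct", {
  tr <- tibble::tibble(
    subject = "s1", task = "t1", trial = 1:3, stimulus = "S1",
    response = "S1", accurate = 1L,
    confidence_level = c(0L, 5L, 10L), confidence_pct = c(0, 50, 100)
  )
  out <- compute_confidence_level(tr)
  expect_equal(out$mean_confidence, 50)

  tr_max <- dplyr::mutate(tr, confidence_pct = 100)
  expect_equal(compute_confidence_level(tr_max)$mean_confidence, 100)

  tr40 <- simulate_subject_task(subject_task_params(1.5), 40, seed = 3)
  got <- compute_confidence_level(tr40)$mean_confidence
  expect_equal(got, sum(tr40$confidence_pct) / 40, tolerance = 1e-12)

  expect_error(compute_confidence_level(tr[0, ]), "empty")
})

test_that("paired t test matches the difference-score definition", {
  withr::with_seed(11, {
    for (i in 1:20) {
      n <- sample(5:60, 1)
      x <- rnorm(n)
      y <- rnorm(n, 0.3)
      got <- paired_ttest(x, y)
      want <- oracle_paired_t(x, y)
      expect_equal(got$t, want$t, tolerance = 1e-10)
      expect_equal(got$df, want$df)
      expect_equal(got$p, want$p, tolerance = 1e-10)
      expect_equal(got$dz, want$dz, tolerance = 1e-10)
      expect_equal(got$dz, got$t / sqrt(n), tolerance = 1e-10)
    }
  })
})

test_that("paired t test edge cases and df bookkeeping", {
  x <- rnorm(20)
  same <- paired_ttest(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$dz, 0)
  expect_equal(same$p, 1)

  # constant shift plus noise: strong effect, hand-computed dz
  withr::with_seed(12, {
    x2 <- rnorm(40)
    y2 <- x2 + 1 + rnorm(40, 0, 0.1)
  })
  shift <- paired_ttest(x2, y2)
  expect_lt(shift$p, 0.001)
  d <- x2 - y2
  expect_equal(shift$dz, mean(d) / sd(d), tolerance = 1e-12)

  # exact constant shift: degenerate
  expect_error(paired_ttest(x, x + 1), "degenerate|zero variance")

  # n = 181 sample gives df = 180
  withr::with_seed(13, {
    a <- rnorm(181)
    b <- rnorm(181, 0.2)
  })
  expect_equal(paired_ttest(a, b)$df, 180)
})

test_that("Bonferroni threshold arithmetic is exact", {
  expect_equal(round(bonferroni_threshold(0.05, 6), 3), 0.008)
  expect_equal(bonferroni_threshold(0.05, 6) * 6, 0.05)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
})

test_that("Pearson correlation with Fisher-z interval behaves correctly", {
  x <- 1:30
  perfect <- pearson_with_ci(x, 2 * x + 3)
  expect_equal(perfect$r, 1)

  withr::with_seed(21, {
    xa <- rnorm(5000)
    ya <- rnorm(5000)
  })
  null_r <- pearson_with_ci(xa, ya)
  expect_lt(abs(null_r$r), 0.05)
  expect_true(null_r$ci_lower <= 0 && null_r$ci_upper >= 0)
  expect_true(null_r$ci_lower <= null_r$r && null_r$r <= null_r$ci_upper)

  expect_error(pearson_with_ci(rep(1, 10), rnorm(10)), "variance")
  expect_error(pearson_with_ci(rnorm(3), rnorm(3)), "4")
})

test_that("Fisher-z CI coverage is near nominal under the null at n = 181", {
  hits <- withr::with_seed(31, {
    mean(replicate(1000, {
      x <- rnorm(181)
      y <- rnorm(181)
      ci <- metacov:::fisher_ci(cor(x, y), 181)
      ci[1] <= 0 && 0 <= ci[2]
    }))
  })
  expect_gt(hits, 0.93) # 95% nominal, Monte-Carlo error ~0.7%
  expect_lt(hits, 0.97)
})

test_that("influence screening flags constructed outliers by the right test", {
  # collinear cloud with one gross vertical outlier
  x <- seq(0, 10, length.out = 50)
  y <- 2 * x + withr::with_seed(41, rnorm(50, 0, 0.05))
  y[25] <- y[25] + 8
  fl <- influence_outliers(x, y)
  row <- fl[fl$index == 25, ]
  expect_equal(nrow(row), 1)
  expect_true(row$residual_flag)
  expect_true(row$cooks_flag)

  # on-line point at extreme x: leverage only
  x2 <- c(seq(0, 1, length.out = 40), 8)
  y2 <- 1.5 * x2 + withr::with_seed(42, c(rnorm(40, 0, 0.2), 0))
  fl2 <- influence_outliers(x2, y2)
  row2 <- fl2[fl2$index == 41, ]
  expect_true(row2$leverage_flag)
  expect_false(row2$residual_flag)

  # homogeneous Gaussian cloud: union rate at its simulated null level
  withr::with_seed(43, {
    xn <- rnorm(200)
    yn <- rnorm(200)
  })
  fln <- influence_outliers(xn, yn)
  expect_lte(nrow(fln) / 200, 0.16)
  expect_lt(sum(fln$residual_flag) / 200, 0.01)
})

test_that("low-performance exclusion removes whole subjects and logs cells", {
  summaries <- tidyr::expand_grid(subject = sprintf("s%d", 1:5),
                                  task = c("a", "b")) |>
    dplyr::mutate(dprime = c(1.2, 1.0, 0.05, 0.9, 1.4, 1.1, 0.8, 0.7, 1.3, 0.6))
  res <- exclude_low_performance(summaries, threshold = 0.10)
  expect_equal(unique(res$exclusions$subject), "s2")  # row 3 is s2/a
  expect_false("s2" %in% res$retained$subject)
  expect_equal(nrow(res$retained), 8)
  # bookkeeping: retained + excluded covers the input exactly
  expect_equal(nrow(res$retained) +
                 sum(summaries$subject %in% res$exclusions$subject),
               nrow(summaries))

  none <- exclude_low_performance(dplyr::mutate(summaries, dprime = 1))
  expect_equal(nrow(none$exclusions), 0)
  expect_equal(nrow(none$retained), nrow(summaries))

  ident <- exclude_low_performance(summaries, threshold = 0)
  expect_equal(nrow(ident$retained), nrow(summaries))
})

test_that("subject x task summaries assemble d', confidence and AUROC2", {
  cfg <- group_config(n_tasks = 2, n_subjects = 4, n_trials = 60, seed = 51)
  tr <- simulate_group(cfg)
  s <- summarize_subject_tasks(tr, include_mratio = TRUE)
  expect_equal(nrow(s), 8)
  expect_true(all(c("dprime", "mean_confidence", "auroc2", "mratio_point") %in% names(s)))
  expect_true(all(s$mean_confidence >= 0 & s$mean_confidence <= 100))
})
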