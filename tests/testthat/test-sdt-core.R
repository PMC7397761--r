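test_that("counts land in the canonical cells and conserve trials", {
  K <- 11
  tr <- tibble::tibble(
    subject = "s1", task = "t1", trial = 1:2,
    stimulus = c("S1", "S2"), response = c("S1", "S2"),
    accurate = c(1L, 1L), confidence_level = c(K - 1L, K - 1L),
    confidence_pct = 100
  )
  ct <- build_counts(tr, n_levels = K)
  expect_equal(which(ct$nR_S1 == 1), 1L)        # resp S1, top confidence
  expect_equal(which(ct$nR_S2 == 1), 2L * K)    # resp S2, top confidence
  expect_equal(sum(ct$nR_S1) + sum(ct$nR_S2), nrow(tr))

  expect_error(build_counts(tr[0, ], n_levels = K), "empty")
  tr_mixed <- dplyr::mutate(tr, subject = c("s1", "s2"))
  expect_error(build_counts(tr_mixed, n_levels = K), "mixes")
})

test_that("collapsing 11 levels to 4 bins matches brute-force re-tabulation", {
  p <- subject_task_params(dprime = 1.2, metad = 1.0)
  tr <- simulate_subject_task(p, 40, seed = 21)
  ct <- build_counts(tr, n_levels = 11, collapse_to = 4)
  expect_length(ct$nR_S1, 8)
  expect_equal(sum(ct$nR_S1) + sum(ct$nR_S2), 40)
  # brute force: re-bin each trial and count cells one by one
  for (stim in c("S1", "S2")) {
    expected <- numeric(8)
    rows <- tr[tr$stimulus == stim, ]
    for (i in seq_len(nrow(rows))) {
      lev <- floor(rows$confidence_level[i] * 4 / 11)
      cell <- if (rows$response[i] == "S1") 4 - lev else 5 + lev
      expected[cell] <- expected[cell] + 1
    }
    got <- if (stim == "S1") ct$nR_S1 else ct$nR_S2
    expect_equal(got, expected)
  }
})

test_that("counts tables serialize and parse losslessly", {
  ct <- random_count_table(3, n_levels = 4, n_trials = 80)
  path <- withr::local_tempfile(fileext = ".csv")
  write_counts(ct, path)
  expect_match(readLines(path, n = 1), "n_levels=4")
  back <- read_counts(path)
  expect_equal(back$nR_S1, ct$nR_S1)
  expect_equal(back$nR_S2, ct$nR_S2)
  expect_equal(back$n_levels, ct$n_levels)
})

test_that("d' and criterion match the defining inverse-normal formulas", {
  # symmetric rates: d' = 0
  ct <- new_counts_toy(hit = 30, miss = 30, fa = 30, cr = 30)
  est <- compute_dprime(ct, correction = "none")
  expect_equal(est$dprime, 0, tolerance = 1e-12)

  # z(0.8413) = +1.00, z(0.1587) = -1.00 to the printed precision
  ct2 <- new_counts_toy(hit = 8413, miss = 1587, fa = 1587, cr = 8413)
  est2 <- compute_dprime(ct2, correction = "none")
  oracle <- oracle_dprime(0.8413, 0.1587)
  expect_equal(est2$dprime, unname(oracle["dprime"]), tolerance = 1e-10)
  expect_equal(est2$dprime, 2.0, tolerance = 1e-3)
  expect_equal(est2$criterion, unname(oracle["criterion"]), tolerance = 1e-10)

  # invariant: dprime == z(hit) - z(fa) exactly as returned
  expect_equal(est2$dprime, qnorm(est2$hit_rate) - qnorm(est2$fa_rate))

  # extreme rates without correction are an error
  ct3 <- new_counts_toy(hit = 10, miss = 0, fa = 2, cr = 8)
  expect_error(compute_dprime(ct3, correction = "none"), "infinite")
  expect_s3_class(compute_dprime(ct3, correction = "loglinear"), "tbl_df")
})

test_that("d' is strictly increasing in hit rate at fixed false-alarm rate", {
  hr <- seq(0.2, 0.95, by = 0.05)
  d <- qnorm(hr) - qnorm(0.15)
  got <- vapply(hr, function(h) {
    ct <- new_counts_toy(hit = round(1000 * h), miss = round(1000 * (1 - h)),
                         fa = 150, cr = 850)
    compute_dprime(ct, correction = "none")$dprime
  }, numeric(1))
  expect_true(all(diff(got) > 0))
  expect_equal(got, d, tolerance = 1e-10)
})

test_that("AUROC2 matches the hand-enumerated trapezoid and its edge cases", {
  # 3-level toy: correct 1/2/7, incorrect 6/3/1 by ascending confidence
  ct <- counts_from_conf_acc(correct = c(1, 2, 7), incorrect = c(6, 3, 1))
  expect_equal(compute_auroc2(ct), oracle_auroc2(c(1, 2, 7), c(6, 3, 1)),
               tolerance = 1e-10)

  # perfect separation
  ct_perfect <- counts_from_conf_acc(correct = c(0, 0, 9), incorrect = c(4, 0, 0))
  expect_equal(compute_auroc2(ct_perfect), 1.0)

  # confidence independent of accuracy at large samples -> near 0.5
  set.seed(31)
  n <- 20000
  acc <- rbinom(n, 1, 0.7)
  conf <- sample(0:10, n, replace = TRUE)
  tr <- tibble::tibble(subject = "s", task = "t", trial = 1:n,
                       stimulus = "S1",
                       response = ifelse(acc == 1, "S1", "S2"),
                       accurate = acc, confidence_level = conf,
                       confidence_pct = conf * 10)
  expect_lt(abs(compute_auroc2(build_counts(tr, 11)) - 0.5), 0.02)

  # undefined without both outcomes
  ct_all_correct <- counts_from_conf_acc(correct = c(3, 3, 3), incorrect = c(0, 0, 0))
  expect_error(compute_auroc2(ct_all_correct), "undefined|incorrect")
})

test_that("AUROC2 is invariant to monotone relabelings of the confidence scale", {
  p <- subject_task_params(dprime = 1.5, metad = 1.2, n_levels = 5)
  tr <- simulate_subject_task(p, 400, seed = 41)
  base <- compute_auroc2(build_counts(tr, 5))
  # squash levels {0,1,2,3,4} -> {0,0,1,2,3}: monotone but not strict, changes area;
  # use a strictly monotone relabeling instead: {0,1,2,3,4} -> {0,2,3,7,9} on a 10-level scale
  relabel <- c(0L, 2L, 3L, 7L, 9L)
  tr2 <- dplyr::mutate(tr, confidence_level = relabel[confidence_level + 1L])
  expect_equal(compute_auroc2(build_counts(tr2, 10)), base, tolerance = 1e-12)
})
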