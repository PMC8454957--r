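test_that("EZ closed forms reproduce the worked example", {
  est <- estimate_ez(tibble::tibble(pc = 0.802, vrt = 0.112, mrt = 0.723))
  expect_equal(est$v, 0.0999, tolerance = 1e-3)
  expect_equal(est$a, 0.1400, tolerance = 1e-3)
  expect_equal(est$ter, 0.300, tolerance = 1e-2)
  # internal consistency: the estimates imply the observed accuracy back
  expect_equal(ez_implied_pc(est$v, est$a), 0.802, tolerance = 1e-6)
})

test_that("pc = 0.5 signals a degenerate drift with v = 0", {
  expect_warning(
    est <- estimate_ez(tibble::tibble(pc = 0.5, vrt = 0.1, mrt = 0.6)),
    class = "persbo_degenerate_drift"
  )
  expect_identical(est$v, 0)
  expect_true(is.na(est$a))
})

test_that("invalid summary statistics are rejected", {
  expect_error(estimate_ez(tibble::tibble(pc = 0.8, vrt = -0.1, mrt = 0.6)),
               class = "persbo_invalid_input")
  expect_error(estimate_ez(tibble::tibble(pc = 1, vrt = 0.1, mrt = 0.6)),
               class = "persbo_invalid_input")
})

test_that("perfect accuracy is edge-corrected to 1 - 1/(2n)", {
  trials <- tibble::tibble(correct = rep(1, 50), rt = seq(0.4, 0.9, length.out = 50))
  expect_equal(ez_summary(trials)$pc, 1 - 1 / 100)
  # null accuracy symmetric correction
  trials0 <- tibble::tibble(correct = c(rep(0, 49), 1, 1),
                            rt = seq(0.4, 0.9, length.out = 51))
  expect_gt(ez_summary(trials0)$pc, 0)
})

test_that("summary statistics use correct responses only", {
  trials <- tibble::tibble(correct = c(1, 1, 1, 0, 0),
                           rt = c(0.5, 0.6, 0.7, 5, 9))
  st <- ez_summary(trials)
  expect_equal(st$mrt, 0.6)
  expect_equal(st$vrt, var(c(0.5, 0.6, 0.7)))
})

test_that("estimate_ez is scale-consistent in s", {
  st <- tibble::tibble(pc = 0.75, vrt = 0.08, mrt = 0.65)
  e1 <- estimate_ez(st, s = 0.1)
  e2 <- estimate_ez(st, s = 0.2)
  expect_equal(e2$v / e1$v, 2)
  expect_equal(e2$a / e1$a, 2)
  expect_equal(e2$ter, e1$ter)
  expect_equal(ez_implied_pc(e1$v, e1$a, 0.1), ez_implied_pc(e2$v, e2$a, 0.2))
})

test_that("score_block is deterministic and order-invariant", {
  trials <- simulate_trials(v = 0.08, a = 0.12, ter = 0.3, n = 120, seed = 11)
  v1 <- score_block(trials)
  expect_identical(v1, score_block(trials))
  expect_identical(v1, score_block(trials[sample.int(120), ]))
  all_wrong <- tibble::tibble(correct = rep(0, 10), rt = runif(10, 0.3, 1))
  expect_error(score_block(all_wrong), class = "persbo_scoring_error")
})

test_that("simulated accuracy matches the EZ-implied closed form", {
  tr <- simulate_trials(v = 0.1, a = 0.14, ter = 0.3, n = 10000, seed = 1)
  expect_equal(mean(tr$correct), ez_implied_pc(0.1, 0.14), tolerance = 0.02)
  # zero drift is symmetric
  tr0 <- simulate_trials(v = 0, a = 0.12, ter = 0.3, n = 4000, seed = 2)
  expect_equal(mean(tr0$correct), 0.5, tolerance = 0.03)
  # reproducible
  expect_identical(tr[1:50, ], simulate_trials(v = 0.1, a = 0.14, ter = 0.3,
                                               n = 10000, seed = 1)[1:50, ])
  expect_error(simulate_trials(0.1, 0.12, 0.3, n = 0, seed = 1),
               class = "persbo_invalid_input")
  expect_error(simulate_trials(0.1, 0.12, 0.3, n = 10, seed = 1, dt = 0.01),
               class = "persbo_invalid_input")
})

test_that("baseline split partitions the 50 trials reproducibly", {
  trials <- simulate_trials(v = 0.06, a = 0.12, ter = 0.3, n = 50, seed = 5)
  sp <- split_baseline(trials, seed = 7)
  idx <- sort(c(sp$idx_ability[[1]], sp$idx_norm[[1]]))
  expect_identical(idx, 1:50)
  expect_length(sp$idx_ability[[1]], 25)
  expect_identical(sp, split_baseline(trials, seed = 7))
  expect_false(identical(sp$idx_ability, split_baseline(trials, seed = 8)$idx_ability))
  expect_error(split_baseline(trials[1:40, ], seed = 1),
               class = "persbo_protocol_error")
})

test_that("half-block drift rates correlate positively across a heterogeneous cohort", {
  coh <- generate_cohort(n = 40, seed = 31)
  expect_gt(cor(coh$p_raw, coh$v_base), 0)
})

test_that("normalized performance is the guarded drift ratio", {
  expect_equal(normalized_performance(1.2, 1.2), 1)
  expect_equal(normalized_performance(2, 1), 2)
  x <- c(0.3, 1.7)
  expect_equal(normalized_performance(x, x), c(1, 1))
  expect_error(normalized_performance(0.5, 0), class = "persbo_invalid_baseline")
  expect_error(normalized_performance(0.5, -1), class = "persbo_invalid_baseline")
})

test_that("trial CSV round-trips through the on-disk dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  trials <- simulate_trials(v = 0.08, a = 0.12, ter = 0.3, n = 20, seed = 3) |>
    dplyr::mutate(subject_id = "S01", block_id = "baseline", .before = 1)
  write_trials(trials, path)
  back <- read_trials(path)
  expect_named(back, c("subject_id", "block_id", "trial", "correct", "rt"))
  expect_equal(back$rt, round(trials$rt, 4))
  scores <- score_blocks(back)
  expect_named(scores, c("subject_id", "block_id", "pc", "vrt", "mrt", "n",
                         "v", "a", "ter", "s"))
  out <- withr::local_tempfile(fileext = ".csv")
  write_scores(scores, out)
  expect_true(file.exists(out))
})
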