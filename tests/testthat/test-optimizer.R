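# small helper: a state pre-loaded with n pseudo-observations on the burn-in grid
seeded_state <- function(n, config = protocol_config(seed = 3)) {
  grid <- stim_grid(config$burn_space)
  state <- new_protocol(config)
  rows <- withr::with_seed(99, {
    tibble::tibble(
      subject_id = sprintf("S%02d", rep(1:ceiling(n / 3), each = 3)[1:n]),
      block_id = paste0("stim", rep(1:3, length.out = n)),
      frequency = grid$frequency[sample.int(nrow(grid), n, replace = TRUE)],
      current = grid$current[sample.int(nrow(grid), n, replace = TRUE)],
      p_raw = runif(n, 0.02, 0.18),
      y_raw = 1 + runif(n, -0.4, 0.8)
    )
  })
  for (i in seq_len(n)) state <- update(state, rows[i, ])
  state
}

test_that("proposals are burn-in random draws before 60 assignments and EI afterwards", {
  st59 <- seeded_state(59)
  rec <- propose_next(st59, p_raw = 0.06)
  expect_identical(rec$phase, "burn_in")
  burn_grid <- stim_grid(search_space("burn_in"))
  expect_true(any(burn_grid$frequency == rec$frequency &
                    burn_grid$current == rec$current))
  expect_gt(rec$current, 0)

  st60 <- seeded_state(60)
  rec2 <- propose_next(st60, p_raw = 0.06)
  expect_identical(rec2$phase, "pbo")
  expect_true("acq" %in% names(rec2))
  opt_grid <- stim_grid(search_space("optimization"))
  expect_true(any(opt_grid$frequency == rec2$frequency &
                    opt_grid$current == rec2$current))
  # determinism: same state and seed -> same recommendation
  expect_identical(rec2, propose_next(seeded_state(60), p_raw = 0.06))
})

test_that("updates append, flag exclusions, and reject duplicates", {
  st <- seeded_state(10)
  obs <- tibble::tibble(subject_id = "S90", block_id = "stim1",
                        frequency = 20, current = 0.5, p_raw = 0.05,
                        y_raw = 3.6)
  st2 <- update(st, obs)
  expect_equal(nrow(st2$history), 11)
  expect_true(dplyr::last(st2$history$excluded))
  # the surrogate ignores the excluded point
  m_before <- protocol_model(st, "pbo")
  m_after <- protocol_model(st2, "pbo")
  expect_equal(m_after$n, m_before$n)
  # ordinary score increases the model size
  obs2 <- obs; obs2$block_id <- "stim2"; obs2$y_raw <- 1.2
  expect_equal(protocol_model(update(st2, obs2), "pbo")$n, m_before$n + 1)
  expect_error(update(st2, obs), class = "persbo_protocol_error")
})

test_that("recommendations are a pure function of the logged history", {
  st <- seeded_state(62)
  rebuilt <- new_protocol(st$config)
  for (i in seq_len(nrow(st$history))) {
    rebuilt <- update(rebuilt, st$history[i, c("subject_id", "block_id",
                                               "frequency", "current",
                                               "p_raw", "y_raw")])
  }
  expect_identical(propose_next(st, 0.1), propose_next(rebuilt, 0.1))
})

test_that("a protocol state survives the JSON round trip", {
  st <- seeded_state(61)
  path <- withr::local_tempfile(fileext = ".json")
  write_state(st, path)
  back <- read_state(path)
  expect_equal(back$history, st$history)
  # JSON number serialization is near-exact; the recommendation must agree
  r1 <- propose_next(back, 0.07); r2 <- propose_next(st, 0.07)
  expect_identical(r1[c("frequency", "current", "phase")],
                   r2[c("frequency", "current", "phase")])
  expect_equal(r1$acq, r2$acq)
})

test_that("the full synthetic protocol respects the study counts and stopping rule", {
  surf <- make_surface(seed = 2, config = surface_config(noise_sd = 0.1))
  coh <- generate_cohort(n = 10, seed = 6)
  cfg <- protocol_config(n_subjects = 10, burn_in_subjects = 4, seed = 5,
                         restarts = 2)
  run <- run_protocol(coh, cfg, surf, mode = "pbo", observe = "fast")
  expect_equal(nrow(run$history), 30)
  expect_identical(run$history$phase, rep(c("burn_in", "pbo"), c(12, 18)))
  expect_equal(sort(unique(run$history$subject_id[run$history$phase == "burn_in"])),
               sprintf("S%02d", 1:4))
  # burn-in never assigns sham; trace has one entry per iteration
  expect_true(all(run$history$current[run$history$phase == "burn_in"] > 0))
  expect_equal(run$trace$iter, 1:30)
  # stopping criterion
  expect_error(propose_next(run$state, 0.05), class = "persbo_protocol_complete")
  # cohort too small
  expect_error(run_protocol(coh[1:5, ], cfg, surf),
               class = "persbo_protocol_error")
})

test_that("random mode draws only sham-free parameters during burn-in", {
  surf <- make_surface(seed = 2, config = surface_config(noise_sd = 0.1))
  coh <- generate_cohort(n = 8, seed = 6)
  cfg <- protocol_config(n_subjects = 8, burn_in_subjects = 4, seed = 11,
                         restarts = 2)
  run <- run_protocol(coh, cfg, surf, mode = "random", observe = "fast",
                      trace = FALSE)
  burn <- run$history$phase == "burn_in"
  expect_true(all(run$history$current[burn] > 0))
  expect_true(all(run$history$frequency %in% 5:50))
})

test_that("with a constant baseline the personalized and standard fits agree", {
  withr::with_seed(13, {
    d <- tibble::tibble(x1 = runif(20), x2 = runif(20), p = 0.37)
    d$y <- 1 + d$x1 * d$x2 + rnorm(20, 0, 0.05)
  })
  q <- withr::with_seed(14, tibble::tibble(x1 = runif(15), x2 = runif(15), p = 0.37))
  pers <- gp_fit(d, personalized = TRUE, restarts = 3, seed = 4)
  std <- gp_fit(d, personalized = FALSE, restarts = 3, seed = 4)
  expect_equal(predict(pers, q)$mu, predict(std, q)$mu, tolerance = 1e-6)
  expect_equal(predict(pers, q)$sigma2, predict(std, q)$sigma2, tolerance = 1e-6)
})

test_that("best_inferred equals the exhaustive posterior-mean scan", {
  st <- seeded_state(70)
  model <- protocol_model(st, "pbo")
  space <- search_space("optimization")
  bi <- best_inferred(model, p = 0.3, space)
  grid <- stim_grid(space)
  cand <- normalize_coords(grid, space); cand$p <- 0.3
  mu <- predict(model, cand, scale = "raw")$mu
  expect_equal(bi$mu, max(mu))
  expect_equal(c(bi$frequency, bi$current),
               c(grid$frequency[which.max(mu)], grid$current[which.max(mu)]))
  expect_true(any(grid$frequency == bi$frequency & grid$current == bi$current))
})

synthetic_history <- function(n_subjects, noise_sd, seed) {
  surf <- make_surface(seed = seed, config = surface_config(noise_sd = noise_sd))
  space <- search_space("optimization")
  grid <- stim_grid(space)
  withr::with_seed(seed + 1, {
    rows <- purrr::map(seq_len(n_subjects), function(s) {
      p_raw <- 0.2 * rbeta(1, 2, 5)
      idx <- sample.int(nrow(grid), 3)
      g <- grid[idx, ]
      u <- normalize_coords(dplyr::mutate(g, p_raw = p_raw), space)
      tibble::tibble(subject_id = sprintf("S%02d", s),
                     block_id = paste0("stim", 1:3),
                     frequency = g$frequency, current = g$current,
                     p_raw = p_raw,
                     y_raw = surface_value(surf, u$x1, u$x2, u$p[1]) +
                       rnorm(3, 0, noise_sd))
    })
    dplyr::bind_rows(rows)
  })
}

test_that("participant-level cross-validation splits 80/20 and tracks the noise floor", {
  hist_low <- synthetic_history(50, noise_sd = 0.02, seed = 21)
  cv <- cross_validate(hist_low, seed = 2, restarts = 3)
  expect_equal(cv$n_train_subjects, 40)
  expect_equal(cv$n_test_subjects, 10)
  expect_lt(cv$mse, 0.05)
  # with noise in the plausible range, MSE is of the order of the noise variance
  hist_mid <- synthetic_history(50, noise_sd = 0.5, seed = 22)
  cv2 <- cross_validate(hist_mid, seed = 2, restarts = 3)
  expect_gt(cv2$mse, 0.25 / 4)
  expect_lt(cv2$mse, 0.25 * 4)
  expect_error(cross_validate(hist_low[hist_low$subject_id %in%
                                         sprintf("S%02d", 1:4), ]),
               class = "persbo_split_error")
})
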