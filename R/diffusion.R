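#' Summary statistics for EZ-diffusion estimation
#'
#' Reduces one block of two-choice trials to the three sufficient statistics
#' of the EZ-diffusion model: proportion correct, and the variance and mean
#' of correct-response reaction times. Response times of error trials are
#' discarded, following the EZ convention. Perfect (or null) accuracy is
#' edge-corrected to `1 - 1/(2n)` (resp. `1/(2n)`) so the logit is finite.
#'
#' @param trials a data frame with columns `correct` (0/1) and `rt` (seconds).
#' @return a one-row tibble with columns `pc`, `vrt`, `mrt`, `n`.
#' @export
#' @examples
#' trials <- simulate_trials(v = 0.1, a = 0.14, ter = 0.3, n = 200, seed = 1)
#' ez_summary(trials)
ez_summary <- function(trials) {
  stopifnot(is.data.frame(trials))
  correct <- trials$correct
  rt <- trials$rt
  n <- nrow(trials)
  if (n < 2L) abort_persbo("need at least 2 trials.", "invalid_input")
  if (!all(correct %in% c(0, 1))) {
    abort_persbo("`correct` must be 0 or 1.", "invalid_input")
  }
  if (any(!is.finite(rt)) || any(rt <= 0)) {
    abort_persbo("all response times must be positive.", "invalid_input")
  }
  pc <- mean(correct)
  if (pc == 1) pc <- 1 - 1 / (2 * n)
  if (pc == 0) pc <- 1 / (2 * n)
  crt <- rt[correct == 1]
  if (length(crt) < 2L) {
    abort_persbo("need at least 2 correct responses to form an RT distribution.",
                 "scoring_error")
  }
  tibble(pc = pc, vrt = var(crt), mrt = mean(crt), n = n)
}

#' Closed-form EZ-diffusion parameter estimates
#'
#' Maps summary statistics (proportion correct `pc`, correct-RT variance
#' `vrt`, correct-RT mean `mrt`) to drift rate `v`, boundary separation `a`
#' and non-decision time `ter` using the EZ-diffusion closed forms with
#' within-trial noise `s`:
#' \deqn{L = logit(pc), \quad
#'       v = sign(pc - 1/2)\, s \left[\frac{L (L pc^2 - L pc + pc - 1/2)}{vrt}\right]^{1/4}}
#' \deqn{a = s^2 L / v, \quad
#'       ter = mrt - \frac{a}{2v}\cdot\frac{1 - e^{-va/s^2}}{1 + e^{-va/s^2}}}
#'
#' `pc` exactly 1/2 carries no directional evidence: the drift is degenerate
#' (`v = 0`, `a` undefined) and a warning of class
#' `persbo_degenerate_drift` is raised.
#'
#' @param stats a data frame with columns `pc`, `vrt`, `mrt` (one or more
#'   rows; extra columns such as `n` are carried through).
#' @param s diffusion scaling constant (conventionally 0.1).
#' @return `stats` with columns `v`, `a`, `ter`, `s` appended.
#' @export
#' @examples
#' estimate_ez(tibble::tibble(pc = 0.802, vrt = 0.112, mrt = 0.723))
estimate_ez <- function(stats, s = 0.1) {
  stopifnot(is.data.frame(stats), all(c("pc", "vrt", "mrt") %in% names(stats)))
  check_scalar_number(s, "s", positive = TRUE)
  pc <- stats$pc; vrt <- stats$vrt; mrt <- stats$mrt
  if (any(pc <= 0 | pc >= 1)) {
    abort_persbo("`pc` must lie strictly in (0, 1); apply the edge correction first.",
                 "invalid_input")
  }
  if (any(vrt <= 0)) abort_persbo("`vrt` must be > 0.", "invalid_input")

  L <- qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  v <- sign(pc - 0.5) * s * x^(1 / 4)
  a <- s^2 * L / v
  y <- exp(-v * a / s^2)
  ter <- mrt - (a / (2 * v)) * (1 - y) / (1 + y)

  deg <- pc == 0.5
  if (any(deg)) {
    warn_persbo("pc = 0.5: drift degenerate (v = 0, boundary undefined).",
                "degenerate_drift")
    v[deg] <- 0; a[deg] <- NA_real_; ter[deg] <- NA_real_
  }
  dplyr::mutate(as_tibble(stats), v = v, a = a, ter = ter, s = s)
}

#' Drift rate of a single trial block
#'
#' @param trials data frame with `correct` and `rt` columns for one block.
#' @param s diffusion scaling constant.
#' @return the estimated drift rate (numeric scalar).
#' @export
score_block <- function(trials, s = 0.1) {
  estimate_ez(ez_summary(trials), s = s)$v
}

#' EZ-diffusion estimates for every (subject, block)
#'
#' Tidy wrapper around [score_block()]: groups a trial-level table by
#' `subject_id` and `block_id` and returns one row of EZ estimates per block.
#'
#' @param trials data frame with `subject_id`, `block_id`, `correct`, `rt`.
#' @param s diffusion scaling constant.
#' @return tibble with columns `subject_id`, `block_id`, `pc`, `vrt`, `mrt`,
#'   `n`, `v`, `a`, `ter`, `s`.
#' @export
score_blocks <- function(trials, s = 0.1) {
  stopifnot(all(c("subject_id", "block_id") %in% names(trials)))
  trials |>
    group_by(.data$subject_id, .data$block_id) |>
    group_modify(~ ez_summary(.x)) |>
    ungroup() |>
    estimate_ez(s = s)
}

#' Split a baseline block into ability and normalization halves
#'
#' The 50-trial baseline block is randomly partitioned into two disjoint
#' 25-trial halves. One half yields the subject's baseline ability `p_raw`
#' (the personalization covariate); the other yields `v_base`, the drift rate
#' used to normalize stimulation-block performance. Using separate halves
#' removes the mechanical dependency between the covariate and the score.
#'
#' @param trials data frame of exactly 50 baseline trials (`correct`, `rt`).
#' @param seed integer seed making the partition reproducible.
#' @param s diffusion scaling constant.
#' @return a one-row tibble with `p_raw`, `v_base`, `split_seed`, and
#'   list-columns `idx_ability`, `idx_norm` holding the row indices of the
#'   two halves.
#' @export
split_baseline <- function(trials, seed, s = 0.1) {
  stopifnot(is.data.frame(trials))
  if (nrow(trials) != 50L) {
    abort_persbo("baseline block must contain exactly 50 trials.", "protocol_error")
  }
  idx_ability <- withr::with_seed(seed, sort(sample.int(50L, 25L)))
  idx_norm <- setdiff(seq_len(50L), idx_ability)
  p_raw <- score_block(trials[idx_ability, , drop = FALSE], s = s)
  v_base <- score_block(trials[idx_norm, , drop = FALSE], s = s)
  tibble(p_raw = p_raw, v_base = v_base, split_seed = as.integer(seed),
         idx_ability = list(idx_ability), idx_norm = list(idx_norm))
}

#' Normalized performance score
#'
#' The optimization objective: stimulation-block drift rate divided by the
#' held-out baseline drift rate. A value of 1 means performance identical to
#' baseline; values above 1 mean improvement.
#'
#' @param v_stim drift rate(s) measured during stimulation.
#' @param v_base positive baseline drift rate(s).
#' @return `v_stim / v_base`.
#' @export
normalized_performance <- function(v_stim, v_base) {
  if (any(!is.finite(v_base)) || any(v_base <= 0)) {
    abort_persbo("`v_base` must be finite and > 0.", "invalid_baseline")
  }
  v_stim / v_base
}

#' Simulate two-choice diffusion trials
#'
#' Euler discretization of the first-passage Wiener process with drift `v`,
#' boundary separation `a`, unbiased start `a/2`, within-trial noise `s` and
#' non-decision time `ter`. Used as the generative oracle for the EZ closed
#' forms and as the trial-level engine of the synthetic cohort.
#'
#' @param v drift rate.
#' @param a boundary separation (> 0).
#' @param ter non-decision time (seconds).
#' @param n number of trials.
#' @param seed integer seed.
#' @param s within-trial noise (diffusion scale).
#' @param dt Euler step in seconds (must be at most 0.001).
#' @param max_time decision-time cap in seconds; the rare unabsorbed path is
#'   classified by its terminal position.
#' @return tibble with columns `trial`, `correct`, `rt`.
#' @export
simulate_trials <- function(v, a, ter, n, seed, s = 0.1, dt = 0.001,
                            max_time = 10) {
  check_scalar_number(a, "a", positive = TRUE)
  check_scalar_number(s, "s", positive = TRUE)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort_persbo("`n` must be a positive count.", "invalid_input")
  }
  if (!is.numeric(dt) || dt <= 0 || dt > 0.001) {
    abort_persbo("`dt` must be in (0, 0.001].", "invalid_input")
  }
  n <- as.integer(n)
  max_steps <- ceiling(max_time / dt)
  withr::with_seed(seed, {
    pos <- rep(a / 2, n)
    correct <- integer(n)
    rt <- rep(ter + max_time, n)
    active <- seq_len(n)
    sd_step <- s * sqrt(dt)
    for (step in seq_len(max_steps)) {
      if (!length(active)) break
      pos[active] <- pos[active] + v * dt + rnorm(length(active), 0, sd_step)
      hit_up <- active[pos[active] >= a]
      hit_dn <- active[pos[active] <= 0]
      if (length(hit_up)) {
        correct[hit_up] <- 1L
        rt[hit_up] <- ter + step * dt
      }
      if (length(hit_dn)) rt[hit_dn] <- ter + step * dt
      active <- setdiff(active, c(hit_up, hit_dn))
    }
    if (length(active)) correct[active] <- as.integer(pos[active] > a / 2)
    tibble(trial = seq_len(n), correct = correct, rt = rt)
  })
}

#' Read / write trial-level CSV logs
#'
#' The trial CSV dialect has columns
#' `subject_id,block_id,trial,correct,rt_seconds`; internally the RT column
#' is named `rt`.
#'
#' @param path file path.
#' @return `read_trials()`: tibble with columns `subject_id`, `block_id`,
#'   `trial`, `correct`, `rt`.
#' @export
read_trials <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("subject_id", "block_id", "trial", "correct", "rt_seconds")
  if (!all(req %in% names(df))) {
    abort_persbo(sprintf("trial CSV must have columns %s.",
                         paste(req, collapse = ", ")), "invalid_input")
  }
  rename(df, rt = "rt_seconds")
}

#' @rdname read_trials
#' @param trials tibble of trials as returned by [read_trials()].
#' @export
write_trials <- function(trials, path) {
  trials |>
    rename(rt_seconds = "rt") |>
    mutate(rt_seconds = round(.data$rt_seconds, 4)) |>
    readr::write_csv(path)
  invisible(path)
}

#' @rdname read_trials
#' @param scores tibble of per-block estimates (e.g. from [score_blocks()]),
#'   with at least `subject_id`, `block_id`, `v`, `a`, `ter` and optionally
#'   `score`.
#' @export
write_scores <- function(scores, path) {
  cols <- intersect(c("subject_id", "block_id", "v", "a", "ter", "score"),
                    names(scores))
  readr::write_csv(scores[cols], path)
  invisible(path)
}
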