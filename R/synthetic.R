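#' Configuration of the synthetic ground-truth response surface
#'
#' The surface is a Gaussian bump over unit-scale (frequency, current) whose
#' peak location travels linearly with the baseline coordinate `p`: from
#' `path_start` (high frequency and current, serving low-ability subjects)
#' at `p = 0` to `path_end` (low frequency and current) at `p = 1`. This
#' encodes the qualitative personalization structure the optimizer is meant
#' to recover: the optimal parameters depend on baseline ability. Expected
#' scores stay within `score_range` (realistic normalized-performance
#' values; observed study scores spanned roughly 0.5–3.8).
#'
#' @param base score far from the bump (1 would mean "no change from
#'   baseline"; 0.9 leaves most of the space slightly below baseline).
#' @param amplitude bump height above `base`.
#' @param width bump standard deviation in unit coordinates.
#' @param path_start,path_end unit-scale `(x1, x2)` peak locations at
#'   `p = 0` and `p = 1`.
#' @param noise_sd additive observation noise of the fast sampling path.
#' @param score_range admissible expected-score range.
#' @param multimodal add a second, smaller off-path bump (stress tests).
#' @return list of class `persbo_surface_config`.
#' @export
surface_config <- function(base = 0.9, amplitude = 1.8, width = 0.3,
                           path_start = c(0.9, 0.9), path_end = c(0.1, 0.1),
                           noise_sd = 0.25, score_range = c(0.5, 3.8),
                           multimodal = FALSE) {
  stopifnot(base >= score_range[1], base + amplitude <= score_range[2],
            width > 0, noise_sd >= 0)
  structure(
    list(base = base, amplitude = amplitude, width = width,
         path_start = path_start, path_end = path_end, noise_sd = noise_sd,
         score_range = score_range, multimodal = multimodal),
    class = "persbo_surface_config"
  )
}

#' Build a ground-truth baseline-dependent response surface
#'
#' Constructs a deterministic map from unit coordinates `(x1, x2, p)` to an
#' expected normalized-performance score (see [surface_config()]), with its
#' optimum path `x*(p)` recorded exactly. The seed jitters the peak path
#' endpoints (within ±0.05) and the bump width (±10%), so replicated
#' recovery experiments see genuinely different ground truths while the
#' high-to-low shift of the optimum with ability is preserved by
#' construction.
#'
#' @param seed integer seed.
#' @param config a [surface_config()].
#' @return object of class `persbo_surface` with elements `value(x1,x2,p)`,
#'   `optimum(p)`, `noise_sd`, `config`, `seed`.
#' @export
make_surface <- function(seed = 1, config = surface_config()) {
  stopifnot(inherits(config, "persbo_surface_config"))
  jit <- withr::with_seed(seed, list(
    start = config$path_start + runif(2, -0.05, 0.05),
    end = config$path_end + runif(2, -0.05, 0.05),
    width = config$width * runif(1, 0.9, 1.1)
  ))
  # keep the built-in direction: start strictly above end in both coords
  jit$start <- pmax(jit$start, jit$end + 0.3)
  bump2 <- if (config$multimodal) {
    list(loc = c(0.2, 0.85), amp = 0.6 * config$amplitude, width = 0.15)
  } else NULL

  path_at <- function(p) {
    cbind(jit$start[1] + p * (jit$end[1] - jit$start[1]),
          jit$start[2] + p * (jit$end[2] - jit$start[2]))
  }
  value <- function(x1, x2, p) {
    pk <- path_at(p)
    v <- config$base + config$amplitude *
      exp(-((x1 - pk[, 1])^2 + (x2 - pk[, 2])^2) / (2 * jit$width^2))
    if (!is.null(bump2)) {
      v <- v + bump2$amp *
        exp(-((x1 - bump2$loc[1])^2 + (x2 - bump2$loc[2])^2) / (2 * bump2$width^2))
    }
    v
  }
  optimum <- function(p) {
    pk <- path_at(p)
    out <- tibble(x1 = pk[, 1], x2 = pk[, 2])
    if (!is.null(bump2)) {
      # numeric refinement: the main bump may not dominate everywhere
      for (i in seq_along(p)) {
        g <- tidyr::expand_grid(x1 = seq(0, 1, length.out = 101),
                                x2 = seq(0, 1, length.out = 101))
        vals <- value(g$x1, g$x2, rep(p[i], nrow(g)))
        j <- which.max(vals)
        if (vals[j] > value(out$x1[i], out$x2[i], p[i])) {
          out$x1[i] <- g$x1[j]; out$x2[i] <- g$x2[j]
        }
      }
    }
    out
  }
  structure(
    list(value = value, optimum = optimum, noise_sd = config$noise_sd,
         config = config, seed = as.integer(seed), path = jit),
    class = "persbo_surface"
  )
}

#' @rdname make_surface
#' @param surface a `persbo_surface`.
#' @param x1,x2,p unit-scale coordinates (vectorized).
#' @export
surface_value <- function(surface, x1, x2, p) {
  stopifnot(inherits(surface, "persbo_surface"))
  surface$value(x1, x2, p)
}

#' @rdname make_surface
#' @export
surface_optimum <- function(surface, p) {
  stopifnot(inherits(surface, "persbo_surface"))
  surface$optimum(p)
}

#' @export
print.persbo_surface <- function(x, ...) {
  cat(sprintf("<persbo_surface: base %.2f + bump %.2f (width %.2f), optimum (%.2f, %.2f) -> (%.2f, %.2f), noise_sd %.2f>\n",
              x$config$base, x$config$amplitude, x$path$width,
              x$path$start[1], x$path$start[2], x$path$end[1], x$path$end[2],
              x$noise_sd))
  invisible(x)
}

#' Simulate one scored stimulation block for a subject
#'
#' The full-pipeline observation model: the block's target drift rate is the
#' surface value at the assigned parameters times the subject's true
#' baseline drift; trial data are simulated from the diffusion process and
#' scored by EZ estimation, so the returned score carries realistic
#' finite-trial estimation noise.
#'
#' @param surface a [make_surface()] ground truth.
#' @param p_unit the subject's unit-scale baseline coordinate.
#' @param v0 the subject's true baseline drift rate.
#' @param params one-row data frame with `frequency`, `current` on the grid.
#' @param space the [search_space()] used for normalization.
#' @param v_base normalizing drift rate (defaults to `v0`; in a protocol run
#'   this is the estimated half-block baseline drift).
#' @param n_trials trials per block (default 50).
#' @param seed integer seed.
#' @param a,ter,s diffusion nuisance parameters for trial generation.
#' @return list with `trials` (tibble) and `score` (normalized performance).
#' @export
sample_subject <- function(surface, p_unit, v0, params, space = search_space(),
                           v_base = v0, n_trials = 50, seed = 1,
                           a = 0.12, ter = 0.3, s = 0.1) {
  stopifnot(inherits(surface, "persbo_surface"))
  xy <- normalize_coords(params, space)
  v_target <- surface_value(surface, xy$x1, xy$x2, p_unit) * v0
  trials <- simulate_trials(v_target, a, ter, n = n_trials, seed = seed, s = s)
  v_stim <- score_block(trials, s = s)
  list(trials = trials, score = normalized_performance(v_stim, v_base))
}

#' Generate a synthetic cohort
#'
#' Draws `n` subjects whose true baseline drift rates follow a Beta(2, 5)
#' distribution rescaled to `baseline_bounds` — skewed toward low abilities,
#' as observed in practice — and simulates a 50-trial baseline block per
#' subject, split into the usual 25-trial ability/normalization halves. The
#' simulated baseline block is redrawn (bounded retries) if either half
#' yields a non-positive drift estimate, since the protocol requires a
#' positive normalizing drift.
#'
#' @param n cohort size (default 50).
#' @param seed master seed; the cohort is fully reproducible from it.
#' @param baseline_bounds raw drift range of the ability distribution.
#' @param beta_shape Beta shape parameters of the ability distribution.
#' @param a,ter,s diffusion nuisance parameters of the baseline blocks.
#' @return tibble with columns `subject_id`, `v_true`, `p_raw`, `v_base`,
#'   and list-column `trials` (the 50 baseline trials).
#' @export
generate_cohort <- function(n = 50, seed = 1, baseline_bounds = c(0, 0.2),
                            beta_shape = c(2, 5), a = 0.12, ter = 0.3,
                            s = 0.1) {
  stopifnot(n >= 1)
  v_true <- withr::with_seed(seed, {
    baseline_bounds[1] + diff(baseline_bounds) * rbeta(n, beta_shape[1], beta_shape[2])
  })
  rows <- purrr::map(seq_len(n), function(i) {
    for (attempt in 1:25) {
      trial_seed <- derive_seed(seed, i, attempt, 1L)
      trials <- simulate_trials(v_true[i], a, ter, n = 50, seed = trial_seed, s = s)
      split <- tryCatch(
        split_baseline(trials, seed = derive_seed(seed, i, attempt, 2L), s = s),
        persbo_error = function(e) NULL
      )
      if (!is.null(split) && split$p_raw > 0 && split$v_base > 0) {
        return(tibble(subject_id = sprintf("S%02d", i), v_true = v_true[i],
                      p_raw = split$p_raw, v_base = split$v_base,
                      trials = list(trials)))
      }
    }
    abort_persbo(sprintf("subject %d: no usable baseline block in 25 attempts.", i),
                 "degenerate_data")
  })
  bind_rows(rows)
}

#' Write a cohort's baseline trials in the trial-CSV dialect
#'
#' @param cohort a [generate_cohort()] tibble.
#' @param path CSV file path.
#' @export
write_cohort_trials <- function(cohort, path) {
  cohort |>
    select("subject_id", "trials") |>
    tidyr::unnest("trials") |>
    mutate(block_id = "baseline", .after = "subject_id") |>
    write_trials(path)
}
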