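HARTMANN3_ALPHA <- c(1.0, 1.2, 3.0, 3.2)
HARTMANN3_A <- matrix(c(3, 10, 30,
                        0.1, 10, 35,
                        3, 10, 30,
                        0.1, 10, 35), 4, 3, byrow = TRUE)
HARTMANN3_P <- 1e-4 * matrix(c(3689, 1170, 2673,
                               4699, 4387, 7470,
                               1091, 8732, 5547,
                               381, 5743, 8828), 4, 3, byrow = TRUE)

#' Negated Hartmann-3 benchmark function
#'
#' The standard three-dimensional Hartmann function with four local optima,
#' negated so the task is maximization (matching drift-rate maximization):
#' \deqn{f(u) = \sum_{i=1}^4 \alpha_i \exp\Big(-\sum_{j=1}^3 A_{ij}(u_j - P_{ij})^2\Big)}
#' with the published constants. The global maximum is about 3.8628 near
#' `u = (0.1146, 0.5556, 0.8525)` (see [hartmann3_optimum()]).
#'
#' @param u a length-3 vector or an `n x 3` matrix of points in the unit
#'   cube.
#' @return numeric value(s).
#' @export
hartmann3 <- function(u) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  stopifnot(ncol(u) == 3)
  if (any(u < 0) || any(u > 1)) {
    abort_persbo("`u` must lie in the unit cube.", "domain_error")
  }
  vals <- numeric(nrow(u))
  for (i in 1:4) {
    d2 <- sweep(u, 2, HARTMANN3_P[i, ])^2 %*% HARTMANN3_A[i, ]
    vals <- vals + HARTMANN3_ALPHA[i] * exp(-d2)
  }
  drop(vals)
}

#' Locate the global optimum of the negated Hartmann-3
#'
#' Computed at call time by a coarse grid sweep followed by local
#' refinement, rather than hard-coding the literature value.
#'
#' @return list with `u` (length-3 location) and `value`.
#' @export
hartmann3_optimum <- function() {
  g <- as.matrix(tidyr::expand_grid(x1 = seq(0.025, 0.975, length.out = 20),
                                    x2 = seq(0.025, 0.975, length.out = 20),
                                    x3 = seq(0.025, 0.975, length.out = 20)))
  start <- g[which.max(hartmann3(g)), ]
  fit <- optim(start, function(u) -hartmann3(pmin(pmax(u, 0), 1)),
               method = "L-BFGS-B", lower = 0, upper = 1,
               control = list(factr = 1e4))
  list(u = unname(fit$par), value = -fit$value)
}

#' Benchmark configuration
#'
#' Study conditions of the simulation comparison: 60 evaluations per run, 30
#' repeats at each of six noise-variance levels spanning 0 and the range
#' typically estimated from behavioral data (up to 2).
#'
#' @param iterations evaluations per run (default 60).
#' @param repeats runs per (algorithm, noise) cell (default 30).
#' @param noise_levels observation-noise variances.
#' @param algorithms subset of `c("pbo", "bo", "random")`.
#' @param init_points random evaluations at the start of each GP-driven run
#'   (counted inside `iterations`).
#' @param candidate_resolution per-dimension resolution of the 2-D candidate
#'   grid the algorithms select from.
#' @param optimum_resolution per-dimension resolution of the grid on which
#'   the posterior-mean argmax ("identified optimum") is located.
#' @param restarts hyperparameter-fit restarts per refit.
#' @param seed master seed.
#' @return list of class `persbo_benchmark_config`.
#' @export
benchmark_config <- function(iterations = 60, repeats = 30,
                             noise_levels = c(0, 0.01, 0.1, 0.5, 1, 2),
                             algorithms = c("pbo", "bo", "random"),
                             init_points = 10, candidate_resolution = 50,
                             optimum_resolution = 30, restarts = 2,
                             seed = 1) {
  algorithms <- match.arg(algorithms, c("pbo", "bo", "random"),
                          several.ok = TRUE)
  stopifnot(iterations >= 1, repeats >= 1, all(noise_levels >= 0),
            init_points >= 1, init_points <= iterations)
  structure(
    list(iterations = as.integer(iterations), repeats = as.integer(repeats),
         noise_levels = noise_levels, algorithms = algorithms,
         init_points = as.integer(init_points),
         candidate_resolution = as.integer(candidate_resolution),
         optimum_resolution = as.integer(optimum_resolution),
         restarts = as.integer(restarts), seed = as.integer(seed)),
    class = "persbo_benchmark_config"
  )
}

# one (algorithm, noise, repeat) run; returns per-iteration metrics
run_benchmark_once <- function(alg, noise, rep_id, noise_i, config, p_seq,
                               cand2d, opt_grid, u_star) {
  iters <- config$iterations
  alg_i <- match(alg, c("pbo", "bo", "random"))
  eps <- withr::with_seed(derive_seed(config$seed, noise_i, rep_id, alg_i, 2L),
                          rnorm(iters, 0, sqrt(noise)))
  pick_seed <- derive_seed(config$seed, noise_i, rep_id, alg_i, 3L)

  X <- matrix(NA_real_, iters, 2)
  y_obs <- numeric(iters)
  f_true <- numeric(iters)
  best_value <- numeric(iters)
  distance <- numeric(iters)
  hyper <- NULL

  random_picks <- withr::with_seed(pick_seed,
                                   sample.int(nrow(cand2d), iters, replace = TRUE))
  for (t in seq_len(iters)) {
    model <- NULL
    if (alg == "random" || t <= config$init_points) {
      xt <- as.numeric(cand2d[random_picks[t], ])
    } else {
      data <- tibble(x1 = X[1:(t - 1), 1], x2 = X[1:(t - 1), 2],
                     y = y_obs[1:(t - 1)])
      if (alg == "pbo") data$p <- p_seq[1:(t - 1)]
      model <- tryCatch(
        gp_fit(data, personalized = alg == "pbo",
               restarts = config$restarts, init = hyper,
               seed = derive_seed(pick_seed, t)),
        persbo_degenerate_data = function(e) {
          gp_fit(data, personalized = alg == "pbo",
                 hyper = list(sigma_l = 0.2, sigma_p = 0.3, sigma_n2 = 0.1))
        }
      )
      hyper <- model$hyper
      cand <- tibble(x1 = cand2d[, 1], x2 = cand2d[, 2])
      if (alg == "pbo") cand$p <- p_seq[t]
      post <- predict(model, cand, scale = "standardized")
      acq <- expected_improvement(post$mu, post$sigma, max(model$y_std))
      top <- which(acq >= max(acq) - 1e-12)
      pick <- if (length(top) == 1L) top else {
        withr::with_seed(derive_seed(pick_seed, t, 5L),
                         top[sample.int(length(top), 1L)])
      }
      xt <- as.numeric(cand2d[pick, ])
    }
    X[t, ] <- xt
    f_true[t] <- hartmann3(c(xt, p_seq[t]))
    y_obs[t] <- f_true[t] + eps[t]
    best_value[t] <- max(f_true[1:t])

    if (alg == "random") {
      b <- which.max(y_obs[1:t])
      distance[t] <- sqrt(sum((c(X[b, ], p_seq[b]) - u_star)^2))
    } else if (t <= config$init_points && is.null(model)) {
      # before the first fit, fall back to the best noisy query
      b <- which.max(y_obs[1:t])
      distance[t] <- sqrt(sum((c(X[b, ], p_seq[b]) - u_star)^2))
    } else {
      if (alg == "pbo") {
        post <- predict(model, opt_grid, scale = "standardized")
        j <- which.max(post$mu)
        distance[t] <- sqrt(sum((unlist(opt_grid[j, c("x1", "x2", "p")]) - u_star)^2))
      } else {
        post <- predict(model, tibble(x1 = cand2d[, 1], x2 = cand2d[, 2]),
                        scale = "standardized")
        j <- which.max(post$mu)
        distance[t] <- sqrt(sum((as.numeric(cand2d[j, ]) - u_star[1:2])^2))
      }
    }
  }
  tibble(algorithm = alg, noise = noise, rep = rep_id,
         iteration = seq_len(iters), best_value = best_value,
         distance = distance)
}

#' Compare personalized BO, standard BO and random search on Hartmann-3D
#'
#' Reproduces the simulation design: each run makes `iterations` noisy
#' evaluations of the negated Hartmann-3 function, where the third
#' coordinate plays the role of the per-iteration personalization value
#' `p_t` (drawn uniformly, and shared across algorithms within a repeat for
#' pairing). Personalized BO models `(x1, x2, p)` and selects `(x1, x2)` by
#' expected improvement at the current `p_t`; standard BO models `(x1, x2)`
#' only, so the unmodelled `p` acts as extra variability; random search
#' draws uniformly. Per iteration the run records the noise-free objective
#' at the best queried point and the Euclidean distance from the identified
#' optimum (posterior-mean argmax; best noisy query for random search) to
#' the true optimum.
#'
#' @param config a [benchmark_config()].
#' @return tibble of class `persbo_benchmark` with columns `algorithm`,
#'   `noise`, `rep`, `iteration`, `best_value`, `distance`.
#' @export
run_comparison <- function(config = benchmark_config()) {
  stopifnot(inherits(config, "persbo_benchmark_config"))
  res <- config$candidate_resolution
  cand2d <- as.matrix(tidyr::expand_grid(
    x1 = seq(0, 1, length.out = res), x2 = seq(0, 1, length.out = res)))
  ores <- config$optimum_resolution
  opt_grid <- tidyr::expand_grid(x1 = seq(0, 1, length.out = ores),
                                 x2 = seq(0, 1, length.out = ores),
                                 p = seq(0, 1, length.out = ores))
  u_star <- hartmann3_optimum()$u

  cells <- tidyr::expand_grid(noise_i = seq_along(config$noise_levels),
                              rep_id = seq_len(config$repeats))
  out <- purrr::pmap(cells, function(noise_i, rep_id) {
    p_seq <- withr::with_seed(derive_seed(config$seed, noise_i, rep_id, 1L),
                              runif(config$iterations))
    purrr::map(config$algorithms, function(alg) {
      run_benchmark_once(alg, config$noise_levels[noise_i], rep_id, noise_i,
                         config, p_seq, cand2d, opt_grid, u_star)
    })
  })
  structure(bind_rows(purrr::flatten(out)),
            class = c("persbo_benchmark", class(tibble())))
}

#' Mean and SD traces of a benchmark result
#'
#' @param result a [run_comparison()] result.
#' @return tibble with per (algorithm, noise, iteration) mean and SD of the
#'   best-found value and the distance to the true optimum over repeats.
#' @export
summarize_comparison <- function(result) {
  result |>
    group_by(.data$algorithm, .data$noise, .data$iteration) |>
    summarise(
      best_value_mean = mean(.data$best_value),
      best_value_sd = sd(.data$best_value),
      distance_mean = mean(.data$distance),
      distance_sd = sd(.data$distance),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(across(c("best_value_sd", "distance_sd"), ~ tidyr::replace_na(.x, 0)))
}
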