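#' Expected improvement
#'
#' Closed-form expected improvement of a Gaussian predictive distribution
#' over the incumbent `f_plus`:
#' \deqn{\alpha^{EI} = (\mu - f^+)\,\Phi(z) + \sigma\,\phi(z), \qquad
#'       z = (\mu - f^+)/\sigma,}
#' defined as exactly 0 wherever the predictive uncertainty is zero
#' (regardless of the sign of \eqn{\mu - f^+}): a fully determined point can
#' contribute no expected improvement and is never worth re-evaluating.
#'
#' @param mu predictive mean(s).
#' @param sigma predictive standard deviation(s), `>= 0`.
#' @param f_plus incumbent: best included observation so far (same scale as
#'   `mu`).
#' @return EI value(s), always `>= 0`.
#' @export
expected_improvement <- function(mu, sigma, f_plus) {
  if (any(sigma < 0)) abort_persbo("`sigma` must be >= 0.", "invalid_input")
  n <- max(length(mu), length(sigma), length(f_plus))
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n); f_plus <- rep_len(f_plus, n)
  d <- mu - f_plus
  z <- ifelse(sigma > 0, d / sigma, 0)
  out <- ifelse(sigma > 0, d * pnorm(z) + sigma * dnorm(z), 0)
  pmax(out, 0)
}

#' GP upper confidence bound
#'
#' \eqn{\alpha^{UCB} = \mu + \kappa \sigma}; `kappa` trades exploration
#' against exploitation.
#'
#' @inheritParams expected_improvement
#' @param kappa exploration weight, `>= 0`.
#' @export
ucb <- function(mu, sigma, kappa) {
  if (any(sigma < 0) || any(kappa < 0)) {
    abort_persbo("`sigma` and `kappa` must be >= 0.", "invalid_input")
  }
  mu + kappa * sigma
}

#' Theoretically motivated UCB exploration schedule
#'
#' The Srinivas et al. schedule
#' \eqn{\kappa_t = \sqrt{2 \log(t^{d/2+2} \pi^2 / 3\delta)}} for iteration
#' `t` in a `d`-dimensional space at confidence `delta`.
#'
#' @param t iteration number (`>= 1`).
#' @param d input dimension.
#' @param delta confidence parameter in (0, 1).
#' @export
kappa_srinivas <- function(t, d = 3, delta = 0.1) {
  stopifnot(t >= 1, delta > 0, delta < 1)
  sqrt(2 * log(t^(d / 2 + 2) * pi^2 / (3 * delta)))
}

#' Maximize an acquisition function over the stimulation grid
#'
#' Evaluates the acquisition at every lattice member with the query's
#' baseline coordinate held fixed at `p`, and returns a maximizer. The grid
#' is small (at most 782 points), so maximization is exhaustive and exact;
#' ties (within `1e-12` of the maximum) are broken by a seeded uniform draw.
#'
#' @param model a fitted `persbo_gp`.
#' @param p unit-scale baseline coordinate in \[0, 1\] (ignored by a
#'   non-personalized model).
#' @param space a [search_space()] supplying the candidate grid.
#' @param acquisition `"ei"` (default) or `"ucb"`.
#' @param kappa UCB exploration weight (required for `"ucb"`).
#' @param f_plus incumbent on the standardized scale; defaults to the best
#'   standardized training observation in `model`.
#' @param seed integer seed for tie-breaking.
#' @return one-row tibble: `frequency`, `current`, `acq`, `f_plus`, `mu`,
#'   `sigma` (standardized scale).
#' @export
acquire_next <- function(model, p, space, acquisition = c("ei", "ucb"),
                         kappa = NULL, f_plus = NULL, seed = 1) {
  acquisition <- match.arg(acquisition)
  stopifnot(inherits(model, "persbo_gp"))
  if (model$personalized && (!is.numeric(p) || p < 0 || p > 1)) {
    abort_persbo("`p` must lie in [0, 1].", "invalid_input")
  }
  grid <- stim_grid(space)
  if (!nrow(grid)) abort_persbo("empty candidate grid.", "configuration_error")
  cand <- normalize_coords(grid, space)
  if (model$personalized) cand$p <- p
  post <- predict(model, cand, scale = "standardized")
  f_plus <- f_plus %||% max(model$y_std)
  acq <- switch(acquisition,
    ei = expected_improvement(post$mu, post$sigma, f_plus),
    ucb = {
      if (is.null(kappa)) abort_persbo("UCB needs `kappa`.", "configuration_error")
      ucb(post$mu, post$sigma, kappa)
    }
  )
  top <- which(acq >= max(acq) - 1e-12)
  pick <- if (length(top) == 1L) top else {
    withr::with_seed(seed, top[sample.int(length(top), 1L)])
  }
  tibble(frequency = grid$frequency[pick], current = grid$current[pick],
         acq = acq[pick], f_plus = f_plus,
         mu = post$mu[pick], sigma = post$sigma[pick])
}
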