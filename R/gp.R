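#' Hyperparameter bounds for the personalized GP
#'
#' Box constraints used by the marginal-likelihood optimizer, on the natural
#' scale: length scales in \[1e-2, 10\], noise variance in \[1e-4, 4\]. The
#' boxes comfortably enclose the ranges typically estimated on unit-cube
#' inputs with standardized outputs (length scales of a few tenths, noise
#' variance up to about 2).
#'
#' @return named list of length-2 numeric ranges.
#' @export
gp_bounds <- function() {
  list(sigma_l = c(1e-2, 10), sigma_p = c(1e-2, 10), sigma_n2 = c(1e-4, 4))
}

check_hyper <- function(hyper, personalized = TRUE) {
  scales <- c("sigma_l", if (personalized) "sigma_p")
  need <- c(scales, "sigma_n2")
  ok <- all(need %in% names(hyper)) &&
    all(vapply(hyper[scales], function(h) is.numeric(h) && h > 0, TRUE)) &&
    is.numeric(hyper$sigma_n2) && hyper$sigma_n2 >= 0
  if (!ok) {
    abort_persbo("hyperparameters must include strictly positive sigma_l, sigma_n2 (and sigma_p for a personalized model).",
                 "invalid_hyperparameter")
  }
  invisible(hyper)
}

#' Product covariance between two coordinate points
#'
#' The personalized kernel is the product of an exponentiated-quadratic
#' kernel over the stimulation coordinates and one over the baseline
#' coordinate,
#' \deqn{k(\{x_i,p_i\},\{x_j,p_j\}) =
#'   \exp\!\big(-\|x_i-x_j\|^2/2\sigma_l^2\big)\,
#'   \exp\!\big(-(p_i-p_j)^2/2\sigma_p^2\big) + \sigma_n^2\,\delta_{ij},}
#' with independent observation noise added once, only when the two
#' observations are the same measurement (`same_index = TRUE`). Repeated
#' measurements at the same grid point therefore carry independent noise.
#'
#' @param ci,cj numeric coordinate vectors: `(x1, x2, p)` for a personalized
#'   model, `(x1, x2)` otherwise.
#' @param hyper list with `sigma_l`, `sigma_p`, `sigma_n2`.
#' @param same_index logical Kronecker delta: do `ci` and `cj` index the same
#'   observation?
#' @param personalized include the baseline factor?
#' @return scalar covariance.
#' @export
kernel_value <- function(ci, cj, hyper, same_index = FALSE, personalized = TRUE) {
  check_hyper(hyper, personalized)
  if (personalized) {
    stopifnot(length(ci) == 3L, length(cj) == 3L)
    kx <- exp(-sum((ci[1:2] - cj[1:2])^2) / (2 * hyper$sigma_l^2))
    kp <- exp(-(ci[3] - cj[3])^2 / (2 * hyper$sigma_p^2))
    k <- kx * kp
  } else {
    kx <- exp(-sum((ci - cj)^2) / (2 * hyper$sigma_l^2))
    k <- kx
  }
  k + hyper$sigma_n2 * as.numeric(same_index)
}

# signal covariance matrix from cached squared distances
kmat <- function(D2x, D2p, sigma_l, sigma_p) {
  E <- D2x / (2 * sigma_l^2)
  if (!is.null(D2p)) E <- E + D2p / (2 * sigma_p^2)
  exp(-E)
}

# Cholesky of K + (sigma_n2 + jitter) I; NULL if it fails
chol_cov <- function(Ksig, sigma_n2, jitter) {
  Ky <- Ksig + diag(sigma_n2 + jitter, nrow(Ksig))
  tryCatch(chol(Ky), error = function(e) NULL)
}

lml_core <- function(D2x, D2p, y, sigma_l, sigma_p, sigma_n2, jitter,
                     gradient = FALSE) {
  n <- length(y)
  Ksig <- kmat(D2x, D2p, sigma_l, sigma_p)
  L <- chol_cov(Ksig, sigma_n2, jitter)
  if (is.null(L)) {
    abort_persbo("covariance factorization failed despite jitter.",
                 "numerical_failure")
  }
  alpha <- backsolve(L, backsolve(L, y, transpose = TRUE))
  val <- -0.5 * sum(y * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
  if (gradient) {
    Kinv <- chol2inv(L)
    W <- tcrossprod(alpha) - Kinv
    g <- c(
      sigma_l = 0.5 * sum(W * (Ksig * D2x / sigma_l^2)),
      sigma_p = if (is.null(D2p)) NA_real_ else
        0.5 * sum(W * (Ksig * D2p / sigma_p^2)),
      sigma_n2 = 0.5 * sum(diag(W)) * sigma_n2
    )
    attr(val, "gradient") <- g
  }
  val
}

#' Log marginal likelihood of a (personalized) GP
#'
#' Evaluates
#' \deqn{\log p(y \mid Z, \theta) = -\tfrac12 y^\top (K+\sigma_n^2 I)^{-1} y
#'   - \tfrac12 \log|K+\sigma_n^2 I| - \tfrac n2 \log 2\pi}
#' for the product kernel on the coordinates in `data`. `y` is used exactly
#' as supplied (no standardization), so the function can serve as a direct
#' numerical oracle.
#'
#' @param data data frame with unit-scale columns `x1`, `x2`, (`p`) and `y`.
#' @param hyper list with `sigma_l`, `sigma_p`, `sigma_n2`.
#' @param personalized include the baseline kernel factor?
#' @param jitter diagonal jitter added before factorization.
#' @param gradient also return the gradient with respect to the *log*
#'   hyperparameters as attribute `"gradient"`?
#' @return scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(data, hyper, personalized = TRUE,
                                    jitter = 1e-8, gradient = FALSE) {
  check_hyper(hyper, personalized)
  if (nrow(data) < 1L) abort_persbo("need at least one observation.", "invalid_input")
  X <- as.matrix(data[, c("x1", "x2")])
  D2x <- sqdist(X, X)
  D2p <- if (personalized) sqdist(matrix(data$p), matrix(data$p)) else NULL
  lml_core(D2x, D2p, data$y, hyper$sigma_l, hyper$sigma_p %||% 1,
           hyper$sigma_n2, jitter, gradient = gradient)
}

#' Fit the personalized Gaussian-process surrogate
#'
#' Builds the GP surrogate over unit-cube inputs: outputs are standardized to
#' zero mean and unit variance (the GP mean is constant zero afterwards), the
#' covariance is the product kernel of [kernel_value()], and — unless `hyper`
#' is supplied — the length scales and noise variance are estimated by
#' multi-restart L-BFGS-B maximization of the log marginal likelihood over
#' log-parameters within `bounds`.
#'
#' @param data data frame with unit-scale columns `x1`, `x2`, `p` (omitted
#'   for a standard, non-personalized model) and outcome `y` (raw scale).
#' @param personalized model the baseline dimension? `FALSE` gives the
#'   standard-BO surrogate over `(x1, x2)` only.
#' @param hyper optional fixed hyperparameters (list with `sigma_l`,
#'   `sigma_p`, `sigma_n2`); skips estimation.
#' @param bounds hyperparameter boxes, see [gp_bounds()].
#' @param restarts number of optimizer starts (first from `init`, the rest
#'   drawn log-uniformly within bounds under `seed`).
#' @param init optional starting hyperparameters for the first restart
#'   (defaults to `sigma_l = 0.2`, `sigma_p = 0.3`, `sigma_n2 = 0.1`).
#' @param seed integer seed making the fit deterministic.
#' @param jitter diagonal jitter (default 1e-8).
#' @param standardize standardize `y` before fitting (default). With one
#'   observation or zero variance the outputs are centred but not scaled.
#' @param ... unused (tidier methods).
#' @return object of class `persbo_gp`.
#' @export
gp_fit <- function(data, personalized = TRUE, hyper = NULL,
                   bounds = gp_bounds(), restarts = 10, init = NULL,
                   seed = 1, jitter = 1e-8, standardize = TRUE) {
  stopifnot(is.data.frame(data), all(c("x1", "x2", "y") %in% names(data)))
  if (personalized && !"p" %in% names(data)) {
    abort_persbo("personalized model needs a `p` column.", "invalid_input")
  }
  n <- nrow(data)
  if (n < 1L) abort_persbo("need at least one observation.", "invalid_input")
  y_raw <- data$y
  center <- mean(y_raw)
  scale <- if (standardize && n >= 2L && sd(y_raw) > 0) sd(y_raw) else 1
  if (!standardize) center <- 0
  y <- (y_raw - center) / scale

  X <- as.matrix(data[, c("x1", "x2")])
  P <- if (personalized) data$p else NULL
  D2x <- sqdist(X, X)
  D2p <- if (personalized) sqdist(matrix(P), matrix(P)) else NULL

  if (is.null(hyper)) {
    if (n < 3L) abort_persbo("hyperparameter estimation needs >= 3 observations.",
                             "degenerate_data")
    if (sd(y_raw) == 0) abort_persbo("zero output variance: standardization and fitting undefined.",
                                     "degenerate_data")
    hyper <- fit_hyper(D2x, D2p, y, bounds, restarts, init, seed, jitter,
                       personalized)
  } else {
    check_hyper(hyper, personalized)
  }

  Ksig <- kmat(D2x, D2p, hyper$sigma_l, hyper$sigma_p %||% 1)
  L <- chol_cov(Ksig, hyper$sigma_n2, jitter)
  if (is.null(L)) abort_persbo("covariance factorization failed despite jitter.",
                               "numerical_failure")
  alpha <- backsolve(L, backsolve(L, y, transpose = TRUE))
  lml <- -0.5 * sum(y * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)

  structure(
    list(X = X, P = P, y_raw = y_raw, y_std = y, center = center,
         scale = scale, hyper = hyper, personalized = personalized,
         jitter = jitter, L = L, alpha = alpha, lml = lml, n = n,
         seed = as.integer(seed)),
    class = "persbo_gp"
  )
}

fit_hyper <- function(D2x, D2p, y, bounds, restarts, init, seed, jitter,
                      personalized) {
  par_names <- c("sigma_l", if (personalized) "sigma_p", "sigma_n2")
  lb <- log(vapply(bounds[par_names], `[`, 0, 1))
  ub <- log(vapply(bounds[par_names], `[`, 0, 2))
  unpack <- function(th) {
    v <- exp(th)
    list(sigma_l = v[["sigma_l"]],
         sigma_p = if (personalized) v[["sigma_p"]] else 1,
         sigma_n2 = v[["sigma_n2"]])
  }
  fn <- function(th) {
    h <- unpack(th)
    tryCatch(-lml_core(D2x, D2p, y, h$sigma_l, h$sigma_p, h$sigma_n2, jitter),
             persbo_numerical_failure = function(e) 1e10)
  }
  gr <- function(th) {
    h <- unpack(th)
    v <- tryCatch(
      lml_core(D2x, D2p, y, h$sigma_l, h$sigma_p, h$sigma_n2, jitter,
               gradient = TRUE),
      persbo_numerical_failure = function(e) NULL
    )
    if (is.null(v)) return(rep(0, length(th)))
    -attr(v, "gradient")[par_names]
  }
  init <- init %||% list(sigma_l = 0.2, sigma_p = 0.3, sigma_n2 = 0.1)
  th0 <- pmin(pmax(log(unlist(init[par_names])), lb), ub)
  starts <- c(list(th0), withr::with_seed(seed, {
    purrr::map(seq_len(max(restarts - 1, 0)), function(i) {
      setNames(runif(length(lb), lb, ub), par_names)
    })
  }))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, fn, gr, method = "L-BFGS-B", lower = lb, upper = ub),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort_persbo("hyperparameter optimization failed.",
                                  "numerical_failure")
  unpack(setNames(best$par, par_names))
}

#' Posterior prediction from a fitted surrogate
#'
#' Predictive mean and variance at new coordinates,
#' \eqn{\mu = k_*^\top (K+\sigma_n^2 I)^{-1} y} and
#' \eqn{\sigma^2 = k_{**} - k_*^\top (K+\sigma_n^2 I)^{-1} k_*}, with the
#' observation noise on the training diagonal only — the query term is
#' noise-free, so the posterior variance never exceeds the unit prior
#' variance. Negative variances from round-off are clipped at zero.
#'
#' @param object a `persbo_gp` fit.
#' @param newdata data frame with `x1`, `x2` (and `p` for a personalized
#'   model).
#' @param scale `"raw"` (default) undoes the output standardization;
#'   `"standardized"` returns the internal N(0,1) scale on which acquisition
#'   functions operate.
#' @param ... unused.
#' @return tibble with columns `mu`, `sigma2`, `sigma`.
#' @export
predict.persbo_gp <- function(object, newdata,
                              scale = c("raw", "standardized"), ...) {
  scale <- match.arg(scale)
  stopifnot(all(c("x1", "x2") %in% names(newdata)))
  Xs <- as.matrix(newdata[, c("x1", "x2")])
  D2x <- sqdist(Xs, object$X)
  D2p <- if (object$personalized) {
    stopifnot("p" %in% names(newdata))
    sqdist(matrix(newdata$p), matrix(object$P))
  } else NULL
  Kstar <- kmat(D2x, D2p, object$hyper$sigma_l, object$hyper$sigma_p %||% 1)
  mu <- drop(Kstar %*% object$alpha)
  v <- backsolve(object$L, t(Kstar), transpose = TRUE)
  s2 <- pmax(1 - colSums(v^2), 0)
  if (scale == "raw") {
    mu <- mu * object$scale + object$center
    s2 <- s2 * object$scale^2
  }
  tibble(mu = mu, sigma2 = s2, sigma = sqrt(s2))
}

#' @export
print.persbo_gp <- function(x, ...) {
  cat(sprintf("<persbo_gp: %s, n = %d, sigma_l = %.3g%s, sigma_n2 = %.3g, lml = %.3f>\n",
              if (x$personalized) "personalized" else "standard",
              x$n, x$hyper$sigma_l,
              if (x$personalized) sprintf(", sigma_p = %.3g", x$hyper$sigma_p) else "",
              x$hyper$sigma_n2, x$lml))
  invisible(x)
}

#' @rdname gp_fit
#' @param x a `persbo_gp` fit.
#' @exportS3Method generics::tidy
tidy.persbo_gp <- function(x, ...) {
  h <- x$hyper
  out <- tibble(
    term = c("sigma_l", if (x$personalized) "sigma_p", "sigma_n2"),
    estimate = c(h$sigma_l, if (x$personalized) h$sigma_p, h$sigma_n2)
  )
  out
}

#' @rdname gp_fit
#' @exportS3Method generics::glance
glance.persbo_gp <- function(x, ...) {
  tibble(n = x$n, personalized = x$personalized, logLik = x$lml,
         y_center = x$center, y_scale = x$scale)
}

#' Save / restore a surrogate snapshot
#'
#' Serializes everything needed to reproduce predictions bit-for-bit:
#' training inputs, raw outputs, standardization constants, hyperparameters,
#' jitter and seed.
#'
#' @param model a `persbo_gp` fit.
#' @param path JSON file path.
#' @export
write_gp <- function(model, path) {
  jsonlite::write_json(
    list(
      personalized = model$personalized,
      x1 = model$X[, 1], x2 = model$X[, 2],
      p = model$P, y_raw = model$y_raw,
      center = model$center, scale = model$scale,
      hyper = model$hyper, jitter = model$jitter, seed = model$seed
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_gp
#' @export
read_gp <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  data <- tibble(x1 = s$x1, x2 = s$x2, y = s$y_raw)
  if (isTRUE(s$personalized)) data$p <- s$p
  gp_fit(data, personalized = isTRUE(s$personalized),
         hyper = as.list(s$hyper), jitter = s$jitter, seed = s$seed)
}
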