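# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized kernel/Cholesky code paths: kernels are
# evaluated pairwise in loops and linear systems solved densely.

oracle_kernel <- function(a, b, hyper, personalized = TRUE) {
  kx <- exp(-sum((a[1:2] - b[1:2])^2) / (2 * hyper$sigma_l^2))
  if (personalized) kx * exp(-(a[3] - b[3])^2 / (2 * hyper$sigma_p^2)) else kx
}

oracle_gram <- function(Z, hyper, personalized = TRUE, jitter = 1e-8) {
  n <- nrow(Z)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) K[i, j] <- oracle_kernel(Z[i, ], Z[j, ], hyper, personalized)
  }
  K + diag(hyper$sigma_n2 + jitter, n)
}

oracle_predict <- function(train, query, hyper, personalized = TRUE,
                           jitter = 1e-8) {
  cols <- c("x1", "x2", if (personalized) "p")
  Z <- as.matrix(train[, cols])
  Q <- as.matrix(query[, cols])
  Kinv <- solve(oracle_gram(Z, hyper, personalized, jitter))
  mu <- s2 <- numeric(nrow(Q))
  for (m in seq_len(nrow(Q))) {
    ks <- vapply(seq_len(nrow(Z)),
                 function(i) oracle_kernel(Q[m, ], Z[i, ], hyper, personalized), 0)
    mu[m] <- drop(ks %*% Kinv %*% train$y)
    s2[m] <- 1 - drop(ks %*% Kinv %*% ks)
  }
  list(mu = mu, sigma2 = s2)
}

oracle_lml <- function(train, hyper, personalized = TRUE, jitter = 1e-8) {
  cols <- c("x1", "x2", if (personalized) "p")
  Ky <- oracle_gram(as.matrix(train[, cols]), hyper, personalized, jitter)
  y <- train$y
  -0.5 * drop(y %*% solve(Ky) %*% y) -
    0.5 * as.numeric(determinant(Ky, logarithm = TRUE)$modulus) -
    length(y) / 2 * log(2 * pi)
}

random_gp_instance <- function(seed, n_max = 10, personalized = TRUE) {
  withr::with_seed(seed, {
    n <- sample(2:n_max, 1)
    train <- tibble::tibble(x1 = runif(n), x2 = runif(n), p = runif(n),
                            y = rnorm(n))
    query <- tibble::tibble(x1 = runif(3), x2 = runif(3), p = runif(3))
    hyper <- list(sigma_l = runif(1, 0.05, 1), sigma_p = runif(1, 0.05, 1),
                  sigma_n2 = runif(1, 0.01, 0.5))
    list(train = train, query = query, hyper = hyper)
  })
}

# accuracy implied by the EZ forward model
ez_implied_pc <- function(v, a, s = 0.1) 1 / (1 + exp(-v * a / s^2))

# draw y ~ N(0, K) from the generative personalized GP
sample_gp_outputs <- function(Z, hyper, seed, jitter = 1e-8) {
  K <- oracle_gram(Z, hyper, personalized = TRUE, jitter = jitter)
  L <- chol(K)
  withr::with_seed(seed, drop(crossprod(L, rnorm(nrow(Z)))))
}
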