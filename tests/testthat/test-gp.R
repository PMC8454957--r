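test_that("kernel closed forms: zero distance, noise delta, one length scale", {
  hyper <- list(sigma_l = 0.25, sigma_p = 0.4, sigma_n2 = 0.3)
  z <- c(0.3, 0.7, 0.5)
  expect_equal(kernel_value(z, z, hyper, same_index = FALSE), 1)
  expect_equal(kernel_value(z, z, hyper, same_index = TRUE), 1.3)
  zj <- z + c(hyper$sigma_l, 0, 0)
  expect_equal(kernel_value(z, zj, hyper), exp(-0.5))
  expect_error(kernel_value(z, z, list(sigma_l = -1, sigma_p = 1, sigma_n2 = 1)),
               class = "persbo_invalid_hyperparameter")
})

test_that("covariance matrices are symmetric and positive semidefinite", {
  for (seed in 1:10) {
    inst <- random_gp_instance(seed)
    fit <- gp_fit(inst$train, hyper = inst$hyper, jitter = 0,
                  standardize = FALSE)
    Z <- cbind(fit$X, fit$P)
    K <- outer(seq_len(nrow(Z)), seq_len(nrow(Z)),
               Vectorize(function(i, j) oracle_kernel(Z[i, ], Z[j, ], inst$hyper)))
    expect_equal(K, t(K))
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("a single noiseless observation is interpolated exactly", {
  train <- tibble::tibble(x1 = 0.4, x2 = 0.6, p = 0.2, y = 1.7)
  fit <- gp_fit(train, hyper = list(sigma_l = 0.3, sigma_p = 0.3, sigma_n2 = 0),
                standardize = TRUE)
  post <- predict(fit, train)
  expect_equal(post$mu, 1.7, tolerance = 1e-6)
  expect_equal(post$sigma2, 0, tolerance = 1e-6)
})

test_that("predictions revert to the standardized prior far from data", {
  train <- tibble::tibble(x1 = c(0.1, 0.15, 0.2), x2 = c(0.1, 0.12, 0.15),
                          p = c(0.1, 0.2, 0.12), y = c(1, 2, 3))
  fit <- gp_fit(train, hyper = list(sigma_l = 0.02, sigma_p = 0.02, sigma_n2 = 0.1))
  far <- predict(fit, tibble::tibble(x1 = 0.95, x2 = 0.95, p = 0.95),
                 scale = "standardized")
  expect_equal(far$mu, 0, tolerance = 1e-6)
  expect_equal(far$sigma2, 1, tolerance = 1e-6)
})

test_that("predict matches the dense linear-algebra oracle", {
  for (seed in 1:20) {
    inst <- random_gp_instance(seed)
    fit <- gp_fit(inst$train, hyper = inst$hyper, standardize = FALSE)
    post <- predict(fit, inst$query, scale = "standardized")
    ref <- oracle_predict(inst$train, inst$query, inst$hyper)
    expect_equal(post$mu, ref$mu, tolerance = 1e-8)
    expect_equal(post$sigma2, ref$sigma2, tolerance = 1e-8)
  }
})

test_that("posterior variance never exceeds the prior variance", {
  inst <- random_gp_instance(3)
  fit <- gp_fit(inst$train, hyper = inst$hyper, standardize = FALSE)
  q <- withr::with_seed(1, tibble::tibble(x1 = runif(200), x2 = runif(200),
                                          p = runif(200)))
  expect_true(all(predict(fit, q, scale = "standardized")$sigma2 <= 1 + 1e-12))
})

test_that("log marginal likelihood matches closed form and oracle", {
  one <- tibble::tibble(x1 = 0.5, x2 = 0.5, p = 0.5, y = 0)
  hyper0 <- list(sigma_l = 0.3, sigma_p = 0.3, sigma_n2 = 1e-12)
  expect_equal(log_marginal_likelihood(one, hyper0, jitter = 0),
               -0.5 * log(2 * pi), tolerance = 1e-9)
  for (seed in 21:30) {
    inst <- random_gp_instance(seed)
    expect_equal(log_marginal_likelihood(inst$train, inst$hyper),
                 oracle_lml(inst$train, inst$hyper), tolerance = 1e-8)
  }
})

test_that("analytic marginal-likelihood gradient matches finite differences", {
  inst <- random_gp_instance(7)
  g <- attr(log_marginal_likelihood(inst$train, inst$hyper, gradient = TRUE),
            "gradient")
  h <- 1e-6
  for (nm in c("sigma_l", "sigma_p", "sigma_n2")) {
    up <- dn <- inst$hyper
    up[[nm]] <- exp(log(up[[nm]]) + h)
    dn[[nm]] <- exp(log(dn[[nm]]) - h)
    fd <- (log_marginal_likelihood(inst$train, up) -
             log_marginal_likelihood(inst$train, dn)) / (2 * h)
    expect_equal(unname(g[nm]), fd, tolerance = 1e-4)
  }
})

test_that("hyperparameter estimation respects bounds and is seed-reproducible", {
  withr::with_seed(5, {
    d <- tibble::tibble(x1 = runif(25), x2 = runif(25), p = runif(25))
    d$y <- sin(4 * d$x1) + 0.5 * d$p + rnorm(25, 0, 0.1)
  })
  f1 <- gp_fit(d, restarts = 4, seed = 2)
  f2 <- gp_fit(d, restarts = 4, seed = 2)
  expect_identical(f1$hyper, f2$hyper)
  b <- gp_bounds()
  expect_true(f1$hyper$sigma_l >= b$sigma_l[1] && f1$hyper$sigma_l <= b$sigma_l[2])
  expect_true(f1$hyper$sigma_n2 >= b$sigma_n2[1] && f1$hyper$sigma_n2 <= b$sigma_n2[2])
  expect_error(gp_fit(d[1:2, ]), class = "persbo_degenerate_data")
  dz <- d; dz$y <- 1
  expect_error(gp_fit(dz), class = "persbo_degenerate_data")
})

test_that("a huge baseline length scale collapses to the standard surrogate", {
  withr::with_seed(8, {
    d <- tibble::tibble(x1 = runif(15), x2 = runif(15), p = runif(15))
    d$y <- cos(3 * d$x2) + rnorm(15, 0, 0.05)
  })
  hyper <- list(sigma_l = 0.3, sigma_p = 1e6, sigma_n2 = 0.05)
  pers <- gp_fit(d, hyper = hyper)
  std <- gp_fit(d, personalized = FALSE, hyper = hyper)
  q <- withr::with_seed(9, tibble::tibble(x1 = runif(20), x2 = runif(20),
                                          p = runif(20)))
  expect_equal(predict(pers, q)$mu, predict(std, q)$mu, tolerance = 1e-6)
  expect_equal(predict(pers, q)$sigma2, predict(std, q)$sigma2, tolerance = 1e-6)
})

test_that("tidy and glance summarize a fit", {
  inst <- random_gp_instance(12)
  fit <- gp_fit(inst$train, hyper = inst$hyper)
  td <- generics::tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_setequal(td$term, c("sigma_l", "sigma_p", "sigma_n2"))
  gl <- generics::glance(fit)
  expect_equal(gl$n, nrow(inst$train))
  expect_true(gl$personalized)
})

test_that("the JSON snapshot reproduces predictions bit-for-bit", {
  inst <- random_gp_instance(15)
  fit <- gp_fit(inst$train, hyper = inst$hyper)
  path <- withr::local_tempfile(fileext = ".json")
  write_gp(fit, path)
  back <- read_gp(path)
  expect_equal(predict(back, inst$query), predict(fit, inst$query))
})
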