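params_1d <- function(mu, s2 = 1, p = 1) {
  list(means = matrix(mu, ncol = 1), variances = rep(s2, length(mu)),
       mixing = rep(p, length(mu)) / sum(rep(p, length(mu))))
}

test_that("log-likelihood matches closed forms and naive summation", {
  # single point at the mean of a unit-variance 1-D component
  expect_equal(gmm_log_likelihood(matrix(0), params_1d(0)),
               log(1 / sqrt(2 * pi)), tolerance = 1e-12)
  # duplicating every point doubles the total exactly
  set.seed(60)
  x <- matrix(rnorm(40), ncol = 2)
  pars <- list(means = rbind(c(0, 0), c(2, 1)), variances = c(1, 0.5),
               mixing = c(0.3, 0.7))
  expect_equal(gmm_log_likelihood(rbind(x, x), pars),
               2 * gmm_log_likelihood(x, pars), tolerance = 1e-12)
  # naive direct-density computation (no log-sum-exp)
  naive <- sum(log(
    pars$mixing[1] * exp(-rowSums(sweep(x, 2, pars$means[1, ])^2) / 2) /
      (2 * pi * 1)^1 +
    pars$mixing[2] * exp(-rowSums(sweep(x, 2, pars$means[2, ])^2) / 1) /
      (2 * pi * 0.5)^1
  ))
  expect_equal(gmm_log_likelihood(x, pars), naive, tolerance = 1e-10)
  expect_error(gmm_log_likelihood(matrix(NA_real_), params_1d(0)), "non-finite")
})

test_that("E-step responsibilities follow symmetry, dominance and the direct ratio", {
  pars <- params_1d(c(-1, 1), s2 = 1, p = 1)
  expect_equal(unname(gmm_e_step(matrix(0), pars)[1, ]), c(0.5, 0.5),
               tolerance = 1e-12)
  far <- params_1d(c(0, 20), s2 = 1, p = 1)
  expect_gt(gmm_e_step(matrix(0), far)[1, 1], 0.999)

  set.seed(61)
  x <- matrix(rnorm(30, sd = 2), ncol = 3)
  pars <- list(means = rbind(c(0, 0, 0), c(1, -1, 2)), variances = c(1.5, 0.7),
               mixing = c(0.4, 0.6))
  resp <- gmm_e_step(x, pars)
  expect_equal(rowSums(resp), rep(1, nrow(x)), tolerance = 1e-12)
  direct <- t(apply(x, 1, function(pt) {
    d <- vapply(1:2, function(k) {
      pars$mixing[k] *
        prod(dnorm(pt, pars$means[k, ], sqrt(pars$variances[k])))
    }, numeric(1))
    d / sum(d)
  }))
  expect_equal(unname(resp), unname(direct), tolerance = 1e-12)
})

test_that("M-step reduces to weighted means and matches a hand-computed case", {
  x <- matrix(c(0, 0, 10, 10, 0, 2, 10, 12), ncol = 2)
  hard <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  pars <- gmm_m_step(x, hard)
  expect_equal(pars$means, rbind(c(0, 1), c(10, 11)))
  expect_equal(pars$mixing, c(0.5, 0.5))
  # uniform responsibilities put every mean at the global mean
  unif <- matrix(0.5, 4, 2)
  pars_u <- gmm_m_step(x, unif)
  expect_equal(pars_u$means[1, ], colMeans(x))
  expect_equal(pars_u$means[2, ], colMeans(x))
  # hand-computed weighted case: weights (.8,.2) etc. on a 4-point instance
  w <- cbind(c(.8, .6, .1, .2), c(.2, .4, .9, .8))
  pars_w <- gmm_m_step(x, w)
  mu1 <- colSums(w[, 1] * x) / sum(w[, 1])
  expect_equal(pars_w$means[1, ], mu1, tolerance = 1e-12)
  s2_1 <- sum(w[, 1] * rowSums(sweep(x, 2, mu1)^2)) / (2 * sum(w[, 1]))
  expect_equal(pars_w$variances[1], s2_1, tolerance = 1e-12)
  expect_equal(pars_w$mixing, colSums(w) / 4, tolerance = 1e-12)
})

test_that("a one-component fit reproduces the closed-form estimate", {
  set.seed(62)
  x <- matrix(rnorm(300, mean = 3), ncol = 3)
  fit <- gmm_fit(x, k = 1)
  expect_true(fit$converged)
  expect_lte(fit$n_iter, 3)
  expect_equal(fit$params$means[1, ], colMeans(x), tolerance = 1e-9)
  mu <- colMeans(x)
  expect_equal(fit$params$variances[1],
               mean(rowSums(sweep(x, 2, mu)^2)) / 3, tolerance = 1e-9)
  expect_equal(fit$params$mixing, 1)
})

test_that("EM is monotone and conserves probability on varied random problems", {
  set.seed(63)
  for (r in 1:5) {
    n <- sample(50:150, 1)
    d <- sample(1:3, 1)
    x <- rbind(
      matrix(rnorm(n * d), ncol = d),
      matrix(rnorm(n * d, mean = runif(1, 0, 4)), ncol = d)
    )
    fit <- gmm_fit(x, k = 2, n_restarts = 3, seed = r)
    expect_true(all(diff(fit$log_likelihood_trace) >= -1e-9))
    expect_equal(rowSums(fit$responsibilities), rep(1, nrow(x)),
                 tolerance = 1e-12)
    expect_equal(sum(fit$params$mixing), 1, tolerance = 1e-12)
    # label permutation leaves the likelihood unchanged
    perm <- fit$params
    perm$means <- perm$means[2:1, , drop = FALSE]
    perm$variances <- perm$variances[2:1]
    perm$mixing <- perm$mixing[2:1]
    expect_equal(gmm_log_likelihood(x, perm), gmm_log_likelihood(x, fit$params),
                 tolerance = 1e-9)
  }
})

test_that("well-separated spherical components are recovered to tight tolerance", {
  set.seed(64)
  truth_means <- rbind(c(0, 0, 0), c(6, 6, 6))  # 6 sigma separation
  n <- 2000
  z <- rbinom(n, 1, 0.4) + 1
  x <- truth_means[z, ] + matrix(rnorm(n * 3), ncol = 3)
  fit <- gmm_fit(x, k = 2, n_restarts = 5, seed = 65)
  o <- order(fit$params$means[, 1])  # align labels by first coordinate
  expect_lt(max(abs(fit$params$means[o, ] - truth_means)), 0.1)
  expect_lt(max(abs(fit$params$mixing[o] - c(0.6, 0.4))), 0.03)
  expect_lt(max(abs(fit$params$variances - 1)), 0.1)
})

test_that("the final likelihood agrees with an independent EM implementation", {
  set.seed(66)
  x <- rbind(matrix(rnorm(600), ncol = 3),
             matrix(rnorm(600, mean = 4), ncol = 3))
  fit <- gmm_fit(x, k = 2, n_restarts = 5, seed = 66)
  library(mclust)  # Mclust resolves helpers in the attached namespace
  ref <- Mclust(x, G = 2, modelNames = "VII", verbose = FALSE)
  expect_equal(fit$log_likelihood, ref$loglik, tolerance = 1e-4)
})

test_that("fits serialise to JSON and back losslessly", {
  set.seed(67)
  x <- matrix(rnorm(100), ncol = 2)
  fit <- gmm_fit(x, k = 2, n_restarts = 2, seed = 67)
  f <- tempfile(fileext = ".json")
  write_gmm_json(fit, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$means, unname(fit$params$means), tolerance = 1e-12)
  expect_equal(back$mixing, fit$params$mixing, tolerance = 1e-12)
  expect_identical(as.integer(back$seed), 67L)
})
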