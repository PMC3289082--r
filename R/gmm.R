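# Spherical Gaussian mixture fitted by EM. Each component k has mean vector
# mu_k, a single scalar variance sigma2_k shared across the D dimensions,
# and mixing probability p_k. All likelihood work is done in the log domain.

.check_gmm_params <- function(params, D = NULL) {
  stopifnot(is.matrix(params$means), length(params$variances) == nrow(params$means),
            length(params$mixing) == nrow(params$means),
            all(params$variances > 0), all(params$mixing > 0),
            abs(sum(params$mixing) - 1) < 1e-8)
  if (!is.null(D)) stopifnot(ncol(params$means) == D)
  invisible(params)
}

# N x K matrix of log(p_k) + log N(x_n; mu_k, sigma2_k I)
.log_weighted_dens <- function(x, params) {
  N <- nrow(x)
  D <- ncol(x)
  K <- nrow(params$means)
  out <- matrix(0, N, K)
  for (k in seq_len(K)) {
    s2 <- params$variances[k]
    sq <- rowSums(sweep(x, 2, params$means[k, ], "-")^2)
    out[, k] <- log(params$mixing[k]) - 0.5 * D * log(2 * pi * s2) - sq / (2 * s2)
  }
  out
}

.logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Log-likelihood of data under a spherical Gaussian mixture
#'
#' Computes `sum_n log sum_k p_k N(x_n; mu_k, sigma2_k I)` with the
#' log-sum-exp trick, so well-separated points never underflow to `-Inf`.
#'
#' @param x Numeric matrix, one row per observation (scaled-feature space).
#' @param params List with `means` (K x D matrix), `variances` (K positive
#'   scalars, spherical), `mixing` (K probabilities summing to 1).
#' @return The scalar log-likelihood.
#' @export
gmm_log_likelihood <- function(x, params) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite data")
  .check_gmm_params(params, ncol(x))
  sum(.logsumexp_rows(.log_weighted_dens(x, params)))
}

#' E-step: posterior responsibilities
#'
#' `p(k | n) = p_k N(x_n; mu_k, sigma2_k) / sum_j p_j N(x_n; mu_j, sigma2_j)`,
#' evaluated in the log domain so each row sums to 1 even when every raw
#' density underflows.
#'
#' @inheritParams gmm_log_likelihood
#' @return N x K matrix of responsibilities; rows sum to 1.
#' @export
gmm_e_step <- function(x, params) {
  x <- as.matrix(x)
  .check_gmm_params(params, ncol(x))
  lw <- .log_weighted_dens(x, params)
  exp(lw - .logsumexp_rows(lw))
}

#' M-step: maximum-likelihood parameter updates
#'
#' Given responsibilities, each component mean is the responsibility-weighted
#' data mean, the spherical variance is the weighted mean squared distance to
#' that mean divided by the dimension D (floored at `var_floor` to prevent
#' component collapse), and each mixing probability is the average
#' responsibility -- the closed form that the softmax parameterisation of the
#' constrained mixing weights yields at its stationary point. A component
#' whose total responsibility falls below 1e-10 is reinitialised from a
#' random data point (with a message) rather than erroring.
#'
#' @inheritParams gmm_log_likelihood
#' @param resp N x K responsibility matrix with rows summing to 1.
#' @param var_floor Minimum allowed component variance.
#' @return A params list (`means`, `variances`, `mixing`).
#' @export
gmm_m_step <- function(x, resp, var_floor = 1e-6) {
  x <- as.matrix(x)
  resp <- as.matrix(resp)
  stopifnot(nrow(resp) == nrow(x), all(abs(rowSums(resp) - 1) < 1e-6))
  N <- nrow(x)
  D <- ncol(x)
  K <- ncol(resp)
  nk <- colSums(resp)
  dead <- which(nk < 1e-10)
  if (length(dead) > 0) {
    message("reinitialising ", length(dead), " empty mixture component(s)")
    for (k in dead) {
      resp[, k] <- 1e-8
      resp[sample.int(N, 1L), k] <- 1
    }
    resp <- resp / rowSums(resp)
    nk <- colSums(resp)
  }
  means <- matrix(0, K, D)
  variances <- numeric(K)
  for (k in seq_len(K)) {
    means[k, ] <- colSums(resp[, k] * x) / nk[k]
    sq <- rowSums(sweep(x, 2, means[k, ], "-")^2)
    variances[k] <- max(sum(resp[, k] * sq) / (D * nk[k]), var_floor)
  }
  list(means = means, variances = variances, mixing = nk / N)
}

.gmm_init_split <- function(x, k, var_floor) {
  # deterministic baseline: order points by the first feature and cut into
  # k contiguous groups of (near) equal size
  N <- nrow(x)
  D <- ncol(x)
  o <- order(x[, 1])
  grp <- ceiling(seq_len(N) * k / N)[order(o)]
  means <- matrix(0, k, D)
  variances <- numeric(k)
  for (g in seq_len(k)) {
    xx <- x[grp == g, , drop = FALSE]
    means[g, ] <- colMeans(xx)
    v <- sum(sweep(xx, 2, means[g, ], "-")^2) / (D * nrow(xx))
    variances[g] <- max(v, var_floor)
  }
  list(means = means, variances = variances, mixing = rep(1 / k, k))
}

.gmm_init_random <- function(x, k, var_floor) {
  # random responsibilities, then one M-step
  resp <- matrix(stats::runif(nrow(x) * k), nrow(x), k)
  resp <- resp / rowSums(resp)
  gmm_m_step(x, resp, var_floor)
}

#' Fit a spherical Gaussian mixture by EM
#'
#' Alternates [gmm_e_step()] and [gmm_m_step()] from a deterministic
#' starting point (points split into contiguous groups along the first
#' feature) plus `n_restarts` random-responsibility restarts; the run with
#' the best final log-likelihood wins. Iteration stops when the relative
#' log-likelihood change drops below `tol_ll` or after `max_iter`
#' iterations. The log-likelihood never decreases across EM iterations; the
#' full trace is returned so that this invariant can be checked.
#'
#' @param x Numeric matrix of observations (rows) in scaled-feature space.
#' @param k Number of mixture components (the charge classifier uses 2).
#' @param n_restarts Number of random restarts besides the deterministic
#'   start.
#' @param max_iter Maximum EM iterations per start.
#' @param tol_ll Relative log-likelihood convergence tolerance.
#' @param var_floor Minimum component variance.
#' @param seed Optional integer seed for the random restarts (and any
#'   empty-component reinitialisation); the global RNG state is restored on
#'   exit.
#' @return An object of class `gmm_fit`: `params` (means, variances,
#'   mixing), `responsibilities`, `log_likelihood` (final value),
#'   `log_likelihood_trace`, `n_iter`, `converged`, `seed`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(200), ncol = 2), matrix(rnorm(200, 4), ncol = 2))
#' fit <- gmm_fit(x, k = 2, seed = 1)
#' fit$params$means
#' @export
gmm_fit <- function(x, k = 2, n_restarts = 10, max_iter = 500, tol_ll = 1e-8,
                    var_floor = 1e-6, seed = NULL) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite data")
  stopifnot(k >= 1)
  if (nrow(x) < k) stop("fewer observations than mixture components")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }

  run_em <- function(params) {
    trace <- numeric(0)
    ll_prev <- -Inf
    converged <- FALSE
    resp <- NULL
    for (it in seq_len(max_iter)) {
      resp <- gmm_e_step(x, params)
      params <- gmm_m_step(x, resp, var_floor)
      ll <- gmm_log_likelihood(x, params)
      trace <- c(trace, ll)
      if (is.finite(ll_prev) &&
          abs(ll - ll_prev) < tol_ll * (abs(ll_prev) + 1e-12)) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
    }
    list(params = params, responsibilities = gmm_e_step(x, params),
         log_likelihood_trace = trace, n_iter = length(trace),
         converged = converged)
  }

  starts <- c(
    list(.gmm_init_split(x, k, var_floor)),
    if (k > 1) replicate(n_restarts, .gmm_init_random(x, k, var_floor),
                         simplify = FALSE)
  )
  best <- NULL
  for (st in starts) {
    run <- run_em(st)
    if (is.null(best) ||
        run$log_likelihood_trace[run$n_iter] >
          best$log_likelihood_trace[best$n_iter]) {
      best <- run
    }
  }
  best$log_likelihood <- best$log_likelihood_trace[best$n_iter]
  best$seed <- seed
  class(best) <- "gmm_fit"
  best
}

#' @export
print.gmm_fit <- function(x, ...) {
  K <- nrow(x$params$means)
  cat(sprintf("<gmm_fit> %d spherical component(s), %d-dimensional\n",
              K, ncol(x$params$means)))
  cat(sprintf("log-likelihood %.4f after %d iteration(s)%s\n",
              x$log_likelihood, x$n_iter,
              if (x$converged) " (converged)" else " (max_iter reached)"))
  for (k in seq_len(K)) {
    cat(sprintf("  component %d: mixing %.3f, variance %.4f, mean (%s)\n",
                k, x$params$mixing[k], x$params$variances[k],
                paste(sprintf("%.3f", x$params$means[k, ]), collapse = ", ")))
  }
  invisible(x)
}

#' Serialise a fitted mixture to JSON
#'
#' Writes means, variances, mixing probabilities, iteration trace and the
#' seed to a plain-text JSON document for reproducibility.
#'
#' @param fit A `gmm_fit` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmm_json <- function(fit, path) {
  stopifnot(inherits(fit, "gmm_fit"))
  jsonlite::write_json(
    list(
      means = fit$params$means,
      variances = fit$params$variances,
      mixing = fit$params$mixing,
      log_likelihood_trace = fit$log_likelihood_trace,
      n_iter = fit$n_iter,
      converged = fit$converged,
      seed = if (is.null(fit$seed)) NA else fit$seed
    ),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}
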