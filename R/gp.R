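#' Length-scale-weighted Euclidean distance
#'
#' `d(x, x') = sqrt(sum_i ((x_i - x'_i) / L_i)^2)`, the distance the Matern
#' kernel operates on; each ARD length scale sets the relevance of one
#' encoded input dimension.
#'
#' @param x,x2 Numeric vectors of equal length.
#' @param lengthscales Positive numeric vector of the same length.
#' @return Nonnegative scalar distance.
#' @export
weighted_distance <- function(x, x2, lengthscales) {
  if (length(x) != length(x2) || length(x) != length(lengthscales))
    stopf("weighted_distance: length mismatch (%d, %d, %d)",
          length(x), length(x2), length(lengthscales))
  sqrt(sum(((x - x2) / lengthscales)^2))
}

#' Kernel hyperparameters
#'
#' @param sigma2 Signal variance (output scale on standardized outputs).
#' @param lengthscales Positive ARD length scale per encoded dimension.
#' @param noise_var Gaussian observation-noise variance (standardized
#'   units squared); floored at 1e-6.
#' @return An object of class `kernel_hyperparams`.
#' @export
kernel_hyperparams <- function(sigma2, lengthscales, noise_var = 1e-6) {
  if (!is_scalar_number(sigma2) || sigma2 <= 0)
    stopf("sigma2 must be a positive number")
  if (any(!is.finite(lengthscales)) || any(lengthscales <= 0))
    stopf("lengthscales must all be strictly positive")
  if (!is_scalar_number(noise_var) || noise_var <= 0)
    stopf("noise_var must be a positive number")
  structure(list(sigma2 = sigma2, lengthscales = as.numeric(lengthscales),
                 noise_var = max(noise_var, 1e-6)),
            class = "kernel_hyperparams")
}

#' Matern 5/2 covariance between two points
#'
#' `k(x, x') = sigma2 * (1 + sqrt(5) d + 5 d^2 / 3) * exp(-sqrt(5) d)` with
#' `d` the length-scale-weighted Euclidean distance. Twice-differentiable
#' sample paths; the standard surrogate kernel for reaction-yield surfaces.
#'
#' @param x,x2 Encoded input vectors.
#' @param hyperparams A [kernel_hyperparams()] object.
#' @return Covariance value in `(0, sigma2]`.
#' @export
matern52 <- function(x, x2, hyperparams) {
  hp <- hyperparams
  if (hp$sigma2 <= 0 || any(hp$lengthscales <= 0))
    stopf("matern52: hyperparameters must be strictly positive")
  d <- weighted_distance(x, x2, hp$lengthscales)
  hp$sigma2 * (1 + sqrt(5) * d + 5 / 3 * d^2) * exp(-sqrt(5) * d)
}

# Pairwise squared weighted distances between row sets (N1 x d, N2 x d).
weighted_sqdist_matrix <- function(X1, X2, lengthscales) {
  w <- 1 / lengthscales
  X1s <- X1 * rep(w, each = nrow(X1))
  X2s <- X2 * rep(w, each = nrow(X2))
  n1 <- rowSums(X1s * X1s)
  n2 <- rowSums(X2s * X2s)
  D2 <- -2 * tcrossprod(X1s, X2s)
  D2 <- D2 + n1          # recycled down columns
  D2 <- D2 + rep(n2, each = length(n1))
  D2[D2 < 0] <- 0
  D2
}

# Dense Matern 5/2 kernel matrix.
matern52_matrix <- function(X1, X2, sigma2, lengthscales) {
  D2 <- weighted_sqdist_matrix(X1, X2, lengthscales)
  d <- sqrt(D2)
  sigma2 * (1 + sqrt(5) * d + 5 / 3 * D2) * exp(-sqrt(5) * d)
}

# Cholesky with escalating diagonal jitter. `scale` sets the jitter unit
# (signal variance); relative jitter starts at 1e-6 and escalates x10 up to
# 1e-2 before giving up.
chol_with_jitter <- function(K, scale = 1) {
  jit <- 1e-6 * scale
  repeat {
    R <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(R)) return(list(R = R, jitter = jit))
    if (jit >= 1e-2 * scale)
      stopf("covariance matrix is not positive definite even with jitter %g",
            jit)
    jit <- jit * 10
  }
}

#' Log marginal likelihood of a GP
#'
#' The exact Gaussian log-density of the standardized outputs under the
#' zero-mean GP prior with covariance `K(X, X) + noise_var * I`:
#' `-1/2 y' S^-1 y - 1/2 log det S - N/2 log 2 pi`. Maximized to train the
#' hyperparameters; automatically trades data fit against model
#' complexity.
#'
#' @param X Encoded input matrix (N x d).
#' @param y_std Standardized outputs (length N).
#' @param hyperparams A [kernel_hyperparams()].
#' @return Scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(X, y_std, hyperparams) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 1L) stopf("need at least one observation")
  if (length(y_std) != n) stopf("X and y_std disagree on N")
  hp <- hyperparams
  K <- matern52_matrix(X, X, hp$sigma2, hp$lengthscales) +
    diag(hp$noise_var, n)
  ch <- chol_with_jitter(K, scale = hp$sigma2)
  alpha <- backsolve(ch$R, backsolve(ch$R, y_std, transpose = TRUE))
  -0.5 * sum(y_std * alpha) - sum(log(diag(ch$R))) - n / 2 * log(2 * pi)
}

# Negative LML and its gradient w.r.t. theta = (log sigma2, log L, log
# noise_var). The length-scale gradient uses the symmetric-weight identity
# sum_jk W_jk (X_ji - X_ki)^2 = 2 (r' X_i^2 - X_i' W X_i), r = rowSums(W),
# so the whole ARD gradient is two BLAS products instead of a per-dimension
# loop.
gp_nll_grad <- function(theta, X, y) {
  n <- nrow(X)
  d <- ncol(X)
  sigma2 <- exp(theta[1L])
  L <- exp(theta[2L:(d + 1L)])
  noise <- exp(theta[d + 2L])
  D2 <- weighted_sqdist_matrix(X, X, L)
  dd <- sqrt(D2)
  E <- exp(-sqrt(5) * dd)
  Ks <- sigma2 * (1 + sqrt(5) * dd + 5 / 3 * D2) * E
  K <- Ks + diag(noise, n)
  ch <- tryCatch(chol_with_jitter(K, scale = sigma2), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, gradient = rep(0, length(theta))))
  R <- ch$R
  alpha <- backsolve(R, backsolve(R, y, transpose = TRUE))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(R))) + n / 2 * log(2 * pi)
  G <- tcrossprod(alpha) - chol2inv(R)    # dLML/dK = G / 2
  # dK/d log sigma2 = Ks + jitter * I (jitter is proportional to sigma2);
  # dK/d log noise = noise * I
  g_s2 <- -0.5 * (sum(G * Ks) + ch$jitter * sum(diag(G)))
  g_noise <- -0.5 * noise * sum(diag(G))
  W <- G * ((5 / 3) * sigma2 * (1 + sqrt(5) * dd) * E)
  r <- rowSums(W)
  g_L <- -(colSums(X^2 * r) - colSums(X * (W %*% X))) / L^2
  list(value = nll, gradient = c(g_s2, g_L, g_noise))
}

# Multi-restart maximum-likelihood training on standardized outputs.
# Bounds (on scaled inputs): L in [1e-3, 1e3], sigma2 in [1e-8, 1e4],
# noise_var in [1e-6, 10].
train_gp_hyperparams <- function(X, y, n_restarts = 8, seed = 1,
                                 init_theta = NULL) {
  n <- nrow(X)
  d <- ncol(X)
  lower <- c(log(1e-8), rep(log(1e-3), d), log(1e-6))
  upper <- c(log(1e4), rep(log(1e3), d), log(10))
  obj <- memo_objective(function(th) gp_nll_grad(th, X, y))
  fn <- obj$fn
  gr <- obj$gr
  starts <- with_seed(seed, {
    s <- list(c(log(1), rep(log(0.5), d), log(0.01)))
    for (r in seq_len(max(0L, n_restarts - 1L))) {
      s[[r + 1L]] <- c(log(stats::runif(1, 0.3, 3)),
                       log(stats::runif(d, 0.05, 2)),
                       log(stats::runif(1, 1e-4, 0.3)))
    }
    s
  })
  if (!is.null(init_theta) && length(init_theta) == d + 2L)
    starts <- c(list(clamp(init_theta, lower, upper)), starts)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, fn, gr, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stopf("hyperparameter training failed from every restart")
  th <- best$par
  list(hyperparams = kernel_hyperparams(sigma2 = exp(th[1L]),
                                        lengthscales = exp(th[2L:(d + 1L)]),
                                        noise_var = exp(th[d + 2L])),
       logLik = -best$value, theta = th)
}

#' Fit a single-task GP surrogate
#'
#' Encodes the table's conditions, standardizes the yields to mean 0 / sd 1,
#' and trains a zero-mean Matern 5/2 ARD GP by maximizing the log marginal
#' likelihood from multiple randomized restarts.
#'
#' @param table An [experiment_table()] (task labels are ignored; all rows
#'   are treated as one task).
#' @param n_restarts Number of optimizer restarts (first start is a fixed
#'   default; the rest are randomized).
#' @param seed Seed controlling the restart initializations.
#' @param init_theta Optional extra optimizer start in the internal
#'   log-parameterization (the `theta` of a previous fit), for
#'   warm-started refits.
#' @return An object of class `gp_state` with the trained hyperparameters,
#'   cached Cholesky factor, and standardization constants.
#' @export
fit_gp <- function(table, n_restarts = 8, seed = 1, init_theta = NULL) {
  domain <- table_domain(table)
  if (is.null(domain)) stopf("table has no attached domain")
  df <- as.data.frame(table)
  if (nrow(df) < 2L) stopf("fit_gp needs at least 2 observations")
  X <- encode_conditions(df, domain)
  y <- df[[domain$objective]]
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1  # all-identical yields
  y_std <- (y - y_mean) / y_sd
  tr <- train_gp_hyperparams(X, y_std, n_restarts = n_restarts, seed = seed,
                             init_theta = init_theta)
  hp <- tr$hyperparams
  K <- matern52_matrix(X, X, hp$sigma2, hp$lengthscales) +
    diag(hp$noise_var, nrow(X))
  ch <- chol_with_jitter(K, scale = hp$sigma2)
  alpha <- backsolve(ch$R, backsolve(ch$R, y_std, transpose = TRUE))
  structure(list(X = X, y_std = y_std, y_mean = y_mean, y_sd = y_sd,
                 y = y, alpha = alpha, theta = tr$theta,
                 hyperparams = hp, chol = ch$R, jitter = ch$jitter,
                 logLik = tr$logLik, domain = domain,
                 conditions = df[, variable_names(domain), drop = FALSE]),
            class = "gp_state")
}

#' @export
print.gp_state <- function(x, ...) {
  cat(sprintf("Single-task GP: N = %d, encoded dim = %d, logLik = %.3f\n",
              nrow(x$X), ncol(x$X), x$logLik))
  cat(sprintf("  sigma2 = %.4g, noise_var = %.4g\n",
              x$hyperparams$sigma2, x$hyperparams$noise_var))
  cat("  lengthscales:",
      paste(signif(x$hyperparams$lengthscales, 3), collapse = " "), "\n")
  invisible(x)
}

#' Construct a GP state from explicit hyperparameters
#'
#' Builds a ready-to-query `gp_state` without likelihood training — for
#' posteriors under fixed, externally chosen hyperparameters (calibration
#' studies, oracles, priors from earlier campaigns).
#'
#' @param X Encoded input matrix (N x d); may have zero rows.
#' @param y Observations in output units.
#' @param hyperparams A [kernel_hyperparams()].
#' @param domain Optional [reaction_domain()] so conditions can be passed
#'   to [posterior()] directly.
#' @param y_mean,y_sd Standardization constants relating `y` to the
#'   standardized scale the kernel operates on (defaults: already
#'   standardized).
#' @return A `gp_state`.
#' @export
gp_state <- function(X, y, hyperparams, domain = NULL, y_mean = 0,
                     y_sd = 1) {
  X <- as.matrix(X)
  hp <- hyperparams
  y_std <- (y - y_mean) / y_sd
  if (nrow(X) == 0L) {
    ch <- list(R = matrix(0, 0, 0), jitter = 0)
    alpha <- numeric(0)
  } else {
    K <- matern52_matrix(X, X, hp$sigma2, hp$lengthscales) +
      diag(hp$noise_var, nrow(X))
    ch <- chol_with_jitter(K, scale = hp$sigma2)
    alpha <- backsolve(ch$R, backsolve(ch$R, y_std, transpose = TRUE))
  }
  structure(list(X = X, y_std = y_std, y_mean = y_mean, y_sd = y_sd,
                 y = y, alpha = alpha, theta = NULL, hyperparams = hp,
                 chol = ch$R, jitter = ch$jitter, logLik = NA_real_,
                 domain = domain, conditions = NULL),
            class = "gp_state")
}

#' Exact GP posterior at query points
#'
#' Standard exact-GP predictive mean and covariance of the latent yield
#' surface, de-standardized back to percent units. The covariance is
#' symmetrized as `(C + C') / 2`; negative eigenvalues are clipped at zero
#' by the posterior sampler.
#'
#' @param state A `gp_state` from [fit_gp()].
#' @param Xq Query matrix (M x d) in encoded coordinates, or a list /
#'   data frame of conditions, which will be encoded.
#' @return List with `mean` (length M, percent), `cov` (M x M,
#'   percent^2) and `sd` (marginal standard deviations).
#' @export
posterior <- function(state, Xq) {
  Xq <- as_query_matrix(Xq, state$domain)
  if (ncol(Xq) != ncol(state$X))
    stopf("query dimension %d does not match model dimension %d",
          ncol(Xq), ncol(state$X))
  hp <- state$hyperparams
  Kqx <- matern52_matrix(Xq, state$X, hp$sigma2, hp$lengthscales)
  Kqq <- matern52_matrix(Xq, Xq, hp$sigma2, hp$lengthscales)
  V <- backsolve(state$chol, t(Kqx), transpose = TRUE)
  alpha <- state$alpha %||%
    backsolve(state$chol,
              backsolve(state$chol, state$y_std, transpose = TRUE))
  m_std <- drop(Kqx %*% alpha)
  C_std <- Kqq - crossprod(V)
  C_std <- (C_std + t(C_std)) / 2
  mean <- state$y_mean + state$y_sd * m_std
  cov <- state$y_sd^2 * C_std
  list(mean = mean, cov = cov, sd = sqrt(pmax(diag(cov), 0)))
}

#' Marginal posterior mean and sd at query points
#'
#' Cheap diagonal-only counterpart of [posterior()] / [mt_posterior()],
#' used by acquisition scans.
#'
#' @param state A fitted `gp_state` or `mtgp_state`.
#' @param Xq Query matrix in encoded coordinates, or conditions.
#' @param ... Method arguments (`task` for multitask states).
#' @return List with `mean` and `sd` in percent units.
#' @export
posterior_marginals <- function(state, Xq, ...) UseMethod("posterior_marginals")

#' @export
posterior_marginals.gp_state <- function(state, Xq, ...) {
  Xq <- as_query_matrix(Xq, state$domain)
  hp <- state$hyperparams
  Kqx <- matern52_matrix(Xq, state$X, hp$sigma2, hp$lengthscales)
  V <- backsolve(state$chol, t(Kqx), transpose = TRUE)
  alpha <- state$alpha %||%
    backsolve(state$chol,
              backsolve(state$chol, state$y_std, transpose = TRUE))
  m_std <- drop(Kqx %*% alpha)
  v_std <- pmax(hp$sigma2 - colSums(V^2), 0)
  list(mean = state$y_mean + state$y_sd * m_std,
       sd = state$y_sd * sqrt(v_std))
}

as_query_matrix <- function(Xq, domain) {
  if (is.data.frame(Xq)) return(encode_conditions(Xq, domain))
  if (is.list(Xq) && !is.null(names(Xq)))
    return(matrix(encode_condition(Xq, domain), nrow = 1L))
  if (is.null(dim(Xq))) Xq <- matrix(Xq, nrow = 1L)
  as.matrix(Xq)
}

# Factor of a posterior covariance for sampling: symmetrize, eigendecompose,
# clip negative eigenvalues at 0. Returns M x M matrix F with F F' ~= C.
psd_factor <- function(C) {
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(vals), length(vals))
}
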