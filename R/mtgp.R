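#' Intertask covariance (task kernel)
#'
#' The T x T task covariance `B = A A' + diag(d)` of the intrinsic model of
#' coregionalization. The low-rank-plus-diagonal parameterization keeps B
#' positive semidefinite for every parameter setting the optimizer can
#' reach; its off-diagonals encode the intertask correlation learned from
#' the joint data.
#'
#' @param factor T x rank matrix A.
#' @param diag_var Positive length-T vector of per-task diagonal terms.
#' @return An object of class `task_kernel` with the derived matrix `B`.
#' @export
task_kernel <- function(factor, diag_var) {
  A <- as.matrix(factor)
  if (length(diag_var) != nrow(A))
    stopf("diag_var length must equal the number of tasks")
  if (any(diag_var <= 0)) stopf("task diagonal terms must be positive")
  B <- tcrossprod(A) + diag(diag_var, nrow(A))
  structure(list(T = nrow(A), rank = ncol(A), factor = A,
                 diag = as.numeric(diag_var), B = B),
            class = "task_kernel")
}

#' Intertask correlation matrix
#'
#' @param tk A [task_kernel()] (or a fitted `mtgp_state`).
#' @return T x T correlation matrix `B[t,t'] / sqrt(B[t,t] B[t',t'])`.
#' @export
task_correlation <- function(tk) {
  if (inherits(tk, "mtgp_state")) tk <- tk$task_kernel
  s <- sqrt(diag(tk$B))
  tk$B / tcrossprod(s)
}

#' ICM covariance between two (input, task) pairs
#'
#' `k((x, t), (x', t')) = B[t, t'] * m52(x, x')` where `m52` is the Matern
#' 5/2 input kernel with signal variance fixed at 1 (all output scale lives
#' in B, removing the `sigma2 * B` ambiguity).
#'
#' @param x,x2 Encoded input vectors.
#' @param t,t2 1-based task indices.
#' @param input_hp A [kernel_hyperparams()]; its `sigma2` is ignored
#'   (treated as 1).
#' @param tk A [task_kernel()].
#' @return Covariance value.
#' @export
icm_kernel <- function(x, t, x2, t2, input_hp, tk) {
  if (t < 1 || t > tk$T || t2 < 1 || t2 > tk$T)
    stopf("task index out of range [1, %d]", tk$T)
  hp1 <- kernel_hyperparams(1, input_hp$lengthscales, input_hp$noise_var)
  tk$B[t, t2] * matern52(x, x2, hp1)
}

# Negative joint LML and gradient for the ICM model.
# theta = (log L [d], vec(A) [T*rank], log diag [T], log noise). Same
# symmetric-weight identity as gp_nll_grad for the ARD part.
mtgp_nll_grad <- function(theta, X, y, ti, T, rank) {
  n <- nrow(X)
  d <- ncol(X)
  L <- exp(theta[seq_len(d)])
  off <- d
  A <- matrix(theta[off + seq_len(T * rank)], T, rank)
  off <- off + T * rank
  dg <- exp(theta[off + seq_len(T)])
  noise <- exp(theta[off + T + 1L])
  B <- tcrossprod(A) + diag(dg, T)
  D2 <- weighted_sqdist_matrix(X, X, L)
  dd <- sqrt(D2)
  E <- exp(-sqrt(5) * dd)
  M <- (1 + sqrt(5) * dd + 5 / 3 * D2) * E
  Bmat <- B[ti, ti]
  K <- Bmat * M + diag(noise, n)
  sig_scale <- mean(diag(Bmat))
  ch <- tryCatch(chol_with_jitter(K, scale = sig_scale),
                 error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, gradient = rep(0, length(theta))))
  R <- ch$R
  alpha <- backsolve(R, backsolve(R, y, transpose = TRUE))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(R))) + n / 2 * log(2 * pi)
  G <- tcrossprod(alpha) - chol2inv(R)   # dLML/dK = G / 2
  # Task-block aggregation S[u, v] = sum over (i in task u, j in task v) of
  # G_ij * M_ij; gradients of B-parameters follow from dB.
  H <- G * M
  Z <- matrix(0, n, T)
  Z[cbind(seq_len(n), ti)] <- 1
  S <- crossprod(Z, H %*% Z)
  # the diagonal jitter scales with mean(diag(B[ti, ti])), so B-parameters
  # pick up a small extra term through it
  trG <- sum(diag(G))
  cnt <- tabulate(ti, T)
  jfac <- ch$jitter / sig_scale
  gA <- -0.5 * ((S + t(S)) %*% A + jfac * trG * (2 * cnt / n) * A)
  g_dg <- -0.5 * (diag(S) + jfac * trG * cnt / n) * dg
  g_noise <- -0.5 * noise * trG
  W <- G * Bmat * ((5 / 3) * (1 + sqrt(5) * dd) * E)
  r <- rowSums(W)
  g_L <- -(colSums(X^2 * r) - colSums(X * (W %*% X))) / L^2
  list(value = nll, gradient = c(g_L, as.numeric(gA), g_dg, g_noise))
}

#' Fit a multitask GP by the intrinsic model of coregionalization
#'
#' Trains one joint GP on all tasks' data simultaneously: shared Matern 5/2
#' ARD input kernel (signal variance fixed at 1), a trainable T x T task
#' covariance `B = A A' + diag(d)`, and shared Gaussian observation noise,
#' by maximizing the joint log marginal likelihood from multiple restarts.
#' Outputs are standardized per task, so tasks in different yield regimes
#' share statistical strength through shape, not offset.
#'
#' @param table An [experiment_table()] whose `task` column defines the
#'   tasks. Every task must have at least one observation.
#' @param rank Rank of the low-rank factor A; default `min(T, 2)`.
#' @param n_restarts,seed As in [fit_gp()].
#' @param main_task Label of the task of primary interest; defaults to
#'   `"main"` when present, else the first task in order of appearance.
#' @param init_theta Optional extra optimizer start in the internal
#'   parameterization (the `theta` of a previous fit with the same T and
#'   rank), for warm-started refits.
#' @return An object of class `mtgp_state`.
#' @export
fit_mtgp <- function(table, rank = NULL, n_restarts = 8, seed = 1,
                     main_task = NULL, init_theta = NULL) {
  domain <- table_domain(table)
  if (is.null(domain)) stopf("table has no attached domain")
  df <- as.data.frame(table)
  tasks <- unique(df$task)
  T <- length(tasks)
  counts <- table(factor(df$task, levels = tasks))
  if (any(counts < 1L))
    stopf("task '%s' has no observations", tasks[which(counts < 1L)[1]])
  if (is.null(main_task))
    main_task <- if ("main" %in% tasks) "main" else tasks[1]
  if (!main_task %in% tasks)
    stopf("main task '%s' has no observations", main_task)
  # Main task listed first so task index 1 is always the optimization target.
  tasks <- c(main_task, setdiff(tasks, main_task))
  if (is.null(rank)) rank <- min(T, 2L)
  X <- encode_conditions(df, domain)
  ti <- match(df$task, tasks)
  y <- df[[domain$objective]]
  y_mean <- numeric(T)
  y_sd <- numeric(T)
  for (t in seq_len(T)) {
    yt <- y[ti == t]
    y_mean[t] <- mean(yt)
    s <- stats::sd(yt)
    y_sd[t] <- if (is.finite(s) && s > 1e-12) s else 1
  }
  y_std <- (y - y_mean[ti]) / y_sd[ti]
  n <- nrow(X)
  d <- ncol(X)
  np <- d + T * rank + T + 1L
  lower <- c(rep(log(1e-3), d), rep(-10, T * rank), rep(log(1e-6), T),
             log(1e-6))
  upper <- c(rep(log(1e3), d), rep(10, T * rank), rep(log(1e4), T), log(10))
  obj <- memo_objective(function(th)
    mtgp_nll_grad(th, X, y_std, ti, T, rank))
  fn <- obj$fn
  gr <- obj$gr
  starts <- with_seed(seed, {
    s <- list(c(rep(log(0.5), d), rep(0.7, T * rank), rep(log(0.3), T),
                log(0.01)))
    for (r in seq_len(max(0L, n_restarts - 1L))) {
      s[[r + 1L]] <- c(log(stats::runif(d, 0.05, 2)),
                       stats::rnorm(T * rank, 0, 0.7),
                       log(stats::runif(T, 0.05, 1)),
                       log(stats::runif(1, 1e-4, 0.3)))
    }
    s
  })
  if (!is.null(init_theta) && length(init_theta) == np)
    starts <- c(list(clamp(init_theta, lower, upper)), starts)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, fn, gr, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 150, factr = 1e8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stopf("multitask hyperparameter training failed")
  th <- best$par
  L <- exp(th[seq_len(d)])
  A <- matrix(th[d + seq_len(T * rank)], T, rank)
  dg <- exp(th[d + T * rank + seq_len(T)])
  noise <- exp(th[length(th)])
  tk <- task_kernel(A, dg)
  input_hp <- kernel_hyperparams(1, L, noise)
  Bmat <- tk$B[ti, ti]
  M <- matern52_matrix(X, X, 1, L)
  K <- Bmat * M + diag(noise, n)
  ch <- chol_with_jitter(K, scale = mean(diag(Bmat)))
  alpha <- backsolve(ch$R, backsolve(ch$R, y_std, transpose = TRUE))
  structure(list(X = X, task_index = ti, tasks = tasks, main_task = main_task,
                 alpha = alpha, theta = th,
                 y = y, y_std = y_std, y_mean = y_mean, y_sd = y_sd,
                 input_hp = input_hp, task_kernel = tk, chol = ch$R,
                 jitter = ch$jitter, logLik = -best$value, domain = domain,
                 conditions = df[, variable_names(domain), drop = FALSE]),
            class = "mtgp_state")
}

#' @export
print.mtgp_state <- function(x, ...) {
  cat(sprintf("Multitask GP (ICM): N = %d, T = %d tasks, logLik = %.3f\n",
              nrow(x$X), length(x$tasks), x$logLik))
  cat("  tasks:", paste(x$tasks, collapse = ", "),
      sprintf(" (main: %s)\n", x$main_task))
  cat("  task correlations:\n")
  print(round(task_correlation(x), 3))
  invisible(x)
}

# Cross-covariance between query rows (for one target task) and the
# training rows, on standardized scale.
mt_cross_cov <- function(state, Xq, t_idx) {
  M <- matern52_matrix(Xq, state$X, 1, state$input_hp$lengthscales)
  b <- state$task_kernel$B[t_idx, state$task_index]
  sweep(M, 2L, b, "*")
}

#' Construct a multitask GP state from explicit parameters
#'
#' The fixed-parameter counterpart of [fit_mtgp()]: builds a ready-to-query
#' `mtgp_state` from a task kernel and input hyperparameters.
#'
#' @param X Encoded input matrix.
#' @param task_index 1-based task index per row of `X`.
#' @param y Observations in output units.
#' @param input_hp A [kernel_hyperparams()] (its `sigma2` is treated as 1;
#'   scale lives in the task kernel).
#' @param tk A [task_kernel()].
#' @param domain Optional [reaction_domain()].
#' @param tasks Task labels (default `"t1"`, `"t2"`, ...; the first is the
#'   main task).
#' @param y_mean,y_sd Per-task standardization constants.
#' @return An `mtgp_state`.
#' @export
mtgp_state <- function(X, task_index, y, input_hp, tk, domain = NULL,
                       tasks = NULL, y_mean = NULL, y_sd = NULL) {
  X <- as.matrix(X)
  T <- tk$T
  ti <- as.integer(task_index)
  if (any(ti < 1L | ti > T)) stopf("task index out of range [1, %d]", T)
  tasks <- tasks %||% paste0("t", seq_len(T))
  if (is.null(y_mean)) y_mean <- rep(0, T)
  if (is.null(y_sd)) y_sd <- rep(1, T)
  y_std <- (y - y_mean[ti]) / y_sd[ti]
  M <- matern52_matrix(X, X, 1, input_hp$lengthscales)
  K <- tk$B[ti, ti] * M + diag(input_hp$noise_var, nrow(X))
  ch <- chol_with_jitter(K, scale = mean(diag(tk$B)[ti]))
  alpha <- backsolve(ch$R, backsolve(ch$R, y_std, transpose = TRUE))
  structure(list(X = X, task_index = ti, tasks = tasks,
                 main_task = tasks[1L], alpha = alpha, theta = NULL,
                 y = y, y_std = y_std, y_mean = y_mean, y_sd = y_sd,
                 input_hp = input_hp, task_kernel = tk, chol = ch$R,
                 jitter = ch$jitter, logLik = NA_real_, domain = domain,
                 conditions = NULL),
            class = "mtgp_state")
}

#' Multitask GP posterior for one task
#'
#' Exact joint-GP posterior of the latent yield surface restricted to the
#' query points and one target task, de-standardized with that task's
#' constants.
#'
#' @param state An `mtgp_state` from [fit_mtgp()].
#' @param Xq Query matrix in encoded coordinates (or conditions, encoded
#'   on the fly).
#' @param task Task label (default: the main task).
#' @return List with `mean`, `cov`, `sd` in percent units.
#' @export
mt_posterior <- function(state, Xq, task = NULL) {
  task <- task %||% state$main_task
  t_idx <- match(task, state$tasks)
  if (is.na(t_idx)) stopf("unknown task '%s'", task)
  Xq <- as_query_matrix(Xq, state$domain)
  if (ncol(Xq) != ncol(state$X))
    stopf("query dimension %d does not match model dimension %d",
          ncol(Xq), ncol(state$X))
  Kqx <- mt_cross_cov(state, Xq, t_idx)
  Kqq <- state$task_kernel$B[t_idx, t_idx] *
    matern52_matrix(Xq, Xq, 1, state$input_hp$lengthscales)
  V <- backsolve(state$chol, t(Kqx), transpose = TRUE)
  alpha <- state$alpha %||%
    backsolve(state$chol,
              backsolve(state$chol, state$y_std, transpose = TRUE))
  m_std <- drop(Kqx %*% alpha)
  C_std <- Kqq - crossprod(V)
  C_std <- (C_std + t(C_std)) / 2
  mean <- state$y_mean[t_idx] + state$y_sd[t_idx] * m_std
  cov <- state$y_sd[t_idx]^2 * C_std
  list(mean = mean, cov = cov, sd = sqrt(pmax(diag(cov), 0)))
}

#' @export
posterior_marginals.mtgp_state <- function(state, Xq, task = NULL, ...) {
  task <- task %||% state$main_task
  t_idx <- match(task, state$tasks)
  if (is.na(t_idx)) stopf("unknown task '%s'", task)
  Xq <- as_query_matrix(Xq, state$domain)
  Kqx <- mt_cross_cov(state, Xq, t_idx)
  V <- backsolve(state$chol, t(Kqx), transpose = TRUE)
  alpha <- state$alpha %||%
    backsolve(state$chol,
              backsolve(state$chol, state$y_std, transpose = TRUE))
  m_std <- drop(Kqx %*% alpha)
  prior <- state$task_kernel$B[t_idx, t_idx]
  v_std <- pmax(prior - colSums(V^2), 0)
  list(mean = state$y_mean[t_idx] + state$y_sd[t_idx] * m_std,
       sd = state$y_sd[t_idx] * sqrt(v_std))
}
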