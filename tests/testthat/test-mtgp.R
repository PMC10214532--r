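test_that("the ICM kernel factorizes into task and input parts", {
  hp <- kernel_hyperparams(1, c(0.5, 0.5), 1e-4)
  tkI <- task_kernel(matrix(0, 2, 1), c(1, 1))     # B = identity
  x <- c(0.1, 0.9); x2 <- c(0.4, 0.2)
  expect_equal(icm_kernel(x, 1, x2, 2, hp, tkI), 0)
  expect_equal(icm_kernel(x, 1, x, 1, hp, tkI), 1)
  tk <- task_kernel(matrix(c(1, 0.8), 2, 1), c(0.2, 0.3))
  expect_equal(icm_kernel(x, 2, x, 2, hp, tk), tk$B[2, 2])
  expect_equal(icm_kernel(x, 1, x2, 2, hp, tk),
               icm_kernel(x2, 2, x, 1, hp, tk))
  expect_error(icm_kernel(x, 3, x2, 1, hp, tk), "out of range")
  # B is PSD by construction for arbitrary factors
  set.seed(9)
  for (i in 1:10) {
    tkr <- task_kernel(matrix(rnorm(6), 3, 2), runif(3, 1e-4, 1))
    expect_gte(min(eigen(tkr$B, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("a diagonal task kernel reduces to independent single-task GPs", {
  set.seed(13)
  n <- 12
  X <- matrix(runif(n), n, 1)
  ti <- rep(1:2, each = 6)
  y <- rnorm(n)
  hp <- kernel_hyperparams(1, 0.3, 0.05)
  tkD <- task_kernel(matrix(0, 2, 1), c(1.3, 0.7))
  mst <- manual_mtgp_state(X, ti, y, hp, tkD)
  Xq <- matrix(seq(0, 1, length.out = 7), 7, 1)
  pm <- mt_posterior(mst, Xq, task = "t1")
  # single-task GP on task-1 data only, same input kernel scaled by B[1,1]
  hp1 <- kernel_hyperparams(1.3, 0.3, 0.05)
  gst <- manual_gp_state(X[ti == 1, , drop = FALSE], y[ti == 1], hp1)
  ps <- posterior(gst, Xq)
  expect_lt(max(abs(pm$mean - ps$mean)), 1e-6)
  expect_lt(max(abs(pm$cov - ps$cov)), 1e-6)
})

test_that("perfect intertask correlation equals a pooled single-task GP", {
  set.seed(17)
  n1 <- 7
  Xs <- matrix(runif(n1), n1, 1)
  ys <- rnorm(n1)
  # identical data observed in both tasks, B = all-ones (correlation 1)
  X <- rbind(Xs, Xs)
  ti <- rep(1:2, each = n1)
  y <- c(ys, ys)
  hp <- kernel_hyperparams(1, 0.25, 0.05)
  tk1 <- task_kernel(matrix(1, 2, 1), c(1e-9, 1e-9))
  mst <- manual_mtgp_state(X, ti, y, hp, tk1)
  Xq <- matrix(seq(0, 1, length.out = 9), 9, 1)
  pm <- mt_posterior(mst, Xq, task = "t1")
  hp1 <- kernel_hyperparams(1 + 1e-9, 0.25, 0.05)
  gst <- manual_gp_state(X, c(ys, ys), hp1)
  ps <- posterior(gst, Xq)
  expect_lt(max(abs(pm$mean - ps$mean)), 1e-4)
  expect_lt(max(abs(pm$cov - ps$cov)), 1e-4)
})

test_that("mt_posterior matches the brute-force joint-covariance oracle", {
  set.seed(19)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    d <- sample(1:2, 1)
    X <- matrix(runif(n * d), n, d)
    ti <- c(1, 2, sample(1:2, n - 2, replace = TRUE))
    y <- rnorm(n)
    hp <- kernel_hyperparams(1, runif(d, 0.2, 1), runif(1, 0.01, 0.1))
    tk <- task_kernel(matrix(rnorm(2), 2, 1), runif(2, 0.1, 0.5))
    mst <- manual_mtgp_state(X, ti, y, hp, tk)
    Xq <- matrix(runif(3 * d), 3, d)
    p <- mt_posterior(mst, Xq, task = "t1")
    orc <- oracle_mtgp(X, ti, y, hp, tk, Xq, 1)
    expect_equal(p$mean, orc$mean, tolerance = 1e-8)
    expect_equal(p$cov, (orc$cov + t(orc$cov)) / 2, tolerance = 1e-8)
  }
})

test_that("fitting one task through the multitask path matches fit_gp", {
  d1 <- domain_1d()
  set.seed(23)
  x <- runif(14)
  y <- pmin(pmax(55 + 25 * sin(5 * x) + rnorm(14, 0, 1), 0), 100)
  tab <- experiment_table(data.frame(x = x, yield = y, task = "main"), d1)
  g <- fit_gp(tab, seed = 1)
  m <- fit_mtgp(tab, seed = 1)
  grid <- data.frame(x = seq(0, 1, length.out = 15))
  pg <- posterior_marginals(g, grid)
  pm <- posterior_marginals(m, grid)
  expect_equal(pm$mean, pg$mean, tolerance = 1e-4)
  expect_equal(pm$sd, pg$sd, tolerance = 1e-3)
})

test_that("shared-function tasks recover a high intertask correlation", {
  d1 <- domain_1d()
  set.seed(29)
  wins_shared <- 0
  wins_indep <- 0
  n_rep <- 8
  for (r in seq_len(n_rep)) {
    xg <- matrix(seq(0, 1, length.out = 60), 60, 1)
    f_shared <- draw_gp_sample(xg, kernel_hyperparams(1, 0.1))
    f_other <- draw_gp_sample(xg, kernel_hyperparams(1, 0.1))
    i_main <- sample(60, 20, replace = TRUE)
    i_aux <- sample(60, 20, replace = TRUE)
    mk <- function(f_main, f_aux) {
      df <- data.frame(
        x = xg[c(i_main, i_aux), 1],
        yield = pmin(pmax(50 + 15 * c(f_main[i_main], f_aux[i_aux]) +
                            rnorm(40, 0, 1), 0), 100),
        task = rep(c("main", "aux"), each = 20))
      experiment_table(df, d1)
    }
    m_same <- fit_mtgp(mk(f_shared, f_shared), n_restarts = 4, seed = r)
    m_diff <- fit_mtgp(mk(f_shared, f_other), n_restarts = 4, seed = r)
    if (task_correlation(m_same)[1, 2] > 0.5) wins_shared <- wins_shared + 1
    if (abs(task_correlation(m_diff)[1, 2]) < 0.5) wins_indep <- wins_indep + 1
  }
  expect_gte(wins_shared, ceiling(0.7 * n_rep))
  expect_gte(wins_indep, ceiling(0.7 * n_rep))
})

test_that("a divergent auxiliary task does not shrink main-task uncertainty
           the way a similar one does", {
  d1 <- domain_1d()
  set.seed(31)
  n_rep <- 6
  var_similar <- numeric(n_rep)
  var_divergent <- numeric(n_rep)
  grid <- data.frame(x = seq(0, 1, length.out = 25))
  for (r in seq_len(n_rep)) {
    xg <- matrix(seq(0, 1, length.out = 40), 40, 1)
    f <- draw_gp_sample(xg, kernel_hyperparams(1, 0.25))
    f_div <- draw_gp_sample(xg, kernel_hyperparams(1, 0.25))
    x_main <- sample(40, 3)
    x_aux <- sample(40, 25, replace = TRUE)
    mk <- function(f_aux) {
      df <- data.frame(
        x = xg[c(x_main, x_aux), 1],
        yield = pmin(pmax(50 + 12 * c(f[x_main], f_aux[x_aux]) +
                            rnorm(28, 0, 0.5), 0), 100),
        task = rep(c("main", "aux"), c(3, 25)))
      experiment_table(df, d1)
    }
    m_sim <- fit_mtgp(mk(f), n_restarts = 4, seed = r)
    m_div <- fit_mtgp(mk(f_div), n_restarts = 4, seed = r)
    var_similar[r] <- mean(posterior_marginals(m_sim, grid)$sd^2)
    var_divergent[r] <- mean(posterior_marginals(m_div, grid)$sd^2)
  }
  # an unrelated auxiliary task cannot substitute for main-task data: its
  # average predictive variance must not drop below the similar regime's
  expect_gte(mean(var_divergent), mean(var_similar) - 1e-6)
})

test_that("tasks with no observations are rejected by name", {
  d1 <- domain_1d()
  tab <- experiment_table(data.frame(x = c(0.1, 0.9), yield = c(10, 20),
                                     task = "auxA"), d1)
  expect_error(fit_mtgp(tab, main_task = "main"), "main")
})
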