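small_domain <- function() {
  reaction_domain(list(
    continuous_variable("time", 5, 60, "min"),
    categorical_variable("catalyst", c("C1", "C2", "C3"))))
}

grid_conditions <- function(domain, n_cont = 12) {
  expand.grid(time = seq(5, 60, length.out = n_cont),
              catalyst = c("C1", "C2", "C3"),
              stringsAsFactors = FALSE)
}

default_grid <- function() {
  dom <- default_benchmark_domain()
  expand.grid(time = seq(5, 60, length.out = 4),
              temperature = seq(50, 150, length.out = 4),
              loading = seq(1, 10, length.out = 3),
              catalyst = dom$variables$catalyst$levels,
              stringsAsFactors = FALSE)
}

test_that("rho = 1 makes tasks identical and rho = 0 decorrelates them", {
  g <- default_grid()
  fam1 <- make_task_family(3, correlation = 1, seed = 4)
  y1 <- mtbo:::evaluate_yield_df(fam1, 1, g)
  y2 <- mtbo:::evaluate_yield_df(fam1, 2, g)
  expect_equal(y1, y2, tolerance = 1e-12)
  rs <- vapply(1:20, function(s) {
    fam0 <- make_task_family(2, correlation = 0, seed = s)
    cor(mtbo:::evaluate_yield_df(fam0, 1, g),
        mtbo:::evaluate_yield_df(fam0, 2, g))
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.2)
  expect_error(make_task_family(2, correlation = 1.2), "\\[0, 1\\]")
})

test_that("intertask correlation increases monotonically with rho", {
  g <- default_grid()
  rhos <- c(0, 0.25, 0.5, 0.75, 1)
  mean_r <- vapply(rhos, function(rho) {
    mean(vapply(1:20, function(s) {
      fam <- make_task_family(2, correlation = rho, seed = s)
      cor(mtbo:::evaluate_yield_df(fam, 1, g),
          mtbo:::evaluate_yield_df(fam, 2, g))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r) > -0.02))   # nondecreasing up to grid noise
  expect_gt(mean_r[5], 0.99)
})

test_that("yield evaluations are deterministic, bounded and unbiased", {
  fam <- make_task_family(2, correlation = 0.5, noise_sd = 3, seed = 6)
  cond <- list(time = 30, temperature = 100, loading = 5,
               catalyst = "P1-L2")
  a <- evaluate_yield(fam, 1, cond)
  b <- evaluate_yield(fam, 1, cond)
  expect_identical(a, b)
  expect_true(a >= 0 && a <= 100)
  # with a seed, noisy draws are reproducible too
  expect_identical(evaluate_yield(fam, 1, cond, noisy = TRUE, seed = 3),
                   evaluate_yield(fam, 1, cond, noisy = TRUE, seed = 3))
  # zero noise: noisy equals noiseless
  fam0 <- make_task_family(2, correlation = 0.5, noise_sd = 0, seed = 6)
  expect_identical(evaluate_yield(fam0, 1, cond, noisy = TRUE, seed = 1),
                   evaluate_yield(fam0, 1, cond))
  # CLT: the mean of many noisy draws approaches the noiseless value
  set.seed(10)
  draws <- replicate(1000, evaluate_yield(fam, 1, cond, noisy = TRUE))
  expect_lt(abs(mean(draws) - a), 3 * fam$noise_sd / sqrt(1000))
  expect_error(evaluate_yield(fam, 5, cond), "task")
})

test_that("the ground-truth optimum search finds a planted optimum", {
  dom <- small_domain()
  # plant a single dominant bump at time = 35 under catalyst C2
  planted <- list(
    offset = c(-1, 0, -1),
    center1 = matrix(rep(6 / 11, 3), 3, 1),   # scaled coordinate of 35 min
    height1 = c(1, 3, 1),
    width1 = matrix(0.3, 3, 1),
    center2 = matrix(0.5, 3, 1),
    height2 = c(0, 0, 0),
    width2 = matrix(0.5, 3, 1))
  fam <- make_task_family(1, correlation = 1, seed = 2, domain = dom,
                          shared_surface = planted)
  opt <- ground_truth_optimum(fam, 1, grid_density = 21)
  expect_equal(opt$condition$catalyst, "C2")
  expect_lt(abs(opt$condition$time - 35), 1)
  # the refined optimum dominates a fresh dense grid
  g <- grid_conditions(dom, n_cont = 25)
  expect_gte(opt$yield + 1e-9, max(mtbo:::evaluate_yield_df(fam, 1, g)))
  # grid resolution has converged
  opt2 <- ground_truth_optimum(fam, 1, grid_density = 42)
  expect_lt(abs(opt2$yield - opt$yield), 0.5)
})

test_that("table surrogates fit their training data and stay in bounds", {
  dom <- small_domain()
  fam <- make_task_family(1, correlation = 1, noise_sd = 0.5, seed = 8,
                          domain = dom)
  tab <- family_table(fam, 1, 40, seed = 21, label = "main")
  expect_error(train_table_surrogate(tab[1:10, ]), "20")
  bench <- train_table_surrogate(tab, n_restarts = 4, seed = 1)
  expect_s3_class(bench, "benchmark_handle")
  df <- as.data.frame(tab)
  for (r in c(1, 10, 25)) {
    pred <- bench$evaluate(as.list(df[r, 1:2]))
    expect_lt(abs(pred - df$yield[r]), 5)
    expect_true(pred >= 0 && pred <= 100)
  }
})

test_that("a surrogate trained on family samples recovers its surface", {
  dom <- small_domain()
  fam <- make_task_family(1, correlation = 1, noise_sd = 1, seed = 12,
                          domain = dom)
  tab <- family_table(fam, 1, 96, seed = 33, label = "main")
  bench <- train_table_surrogate(tab, n_restarts = 4, seed = 1)
  g <- grid_conditions(dom)
  truth <- mtbo:::evaluate_yield_df(fam, 1, g)
  pred <- vapply(seq_len(nrow(g)), function(r)
    bench$evaluate(as.list(g[r, , drop = FALSE])), numeric(1))
  rmse <- sqrt(mean((pred - truth)^2))
  expect_lt(rmse, 2 * fam$noise_sd)
})

test_that("family specs serialize to JSON and reproduce byte-identically", {
  fam <- make_task_family(3, correlation = 0.7, noise_sd = 2, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_family(fam, path)
  fam2 <- read_family(path)
  cond <- list(time = 12, temperature = 77, loading = 3.3,
               catalyst = "P2-L1")
  expect_identical(evaluate_yield(fam, 2, cond),
                   evaluate_yield(fam2, 2, cond))
})
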