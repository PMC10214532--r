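tiny_domain <- function() {
  reaction_domain(list(continuous_variable("x", 0, 1)))
}

tiny_family <- function(seed = 3, noise_sd = 0) {
  make_task_family(2, correlation = 1, noise_sd = noise_sd, seed = seed,
                   domain = tiny_domain())
}

test_that("campaign bookkeeping matches budget and initialization", {
  bench <- synthetic_benchmark(tiny_family(), task = 1, noisy = FALSE)
  cfg <- campaign_config("STBO", budget = 1, n_init = 2, seed = 4,
                         fit_restarts = 2)
  res <- run_campaign(bench, cfg)
  expect_null(res$error)
  expect_equal(nrow(res$iterations), 3)
  expect_length(res$best_trajectory, 3)
  expect_equal(res$iterations$phase, c("init", "init", "suggest"))
  # incumbent tracking: the trajectory ends at the best measured yield
  expect_equal(res$best_trajectory[3], max(res$iterations$yield))
})

test_that("best trajectories are monotone and reproducible per seed", {
  bench <- synthetic_benchmark(tiny_family(), task = 1, noisy = FALSE)
  cfg <- campaign_config("STBO", budget = 4, n_init = 3, seed = 9,
                         fit_restarts = 2)
  r1 <- run_campaign(bench, cfg)
  r2 <- run_campaign(bench, cfg)
  expect_true(all(diff(r1$best_trajectory) >= 0))
  expect_identical(r1$iterations, r2$iterations)
  r3 <- run_campaign(bench, campaign_config("STBO", budget = 4, n_init = 3,
                                            seed = 10, fit_restarts = 2))
  expect_false(identical(r1$iterations, r3$iterations))
})

test_that("MTBO without auxiliary data behaves exactly like STBO", {
  bench <- synthetic_benchmark(tiny_family(), task = 1, noisy = FALSE)
  a <- run_campaign(bench, campaign_config("STBO", budget = 3, n_init = 3,
                                           seed = 6, fit_restarts = 2))
  b <- run_campaign(bench, campaign_config("MTBO", budget = 3, n_init = 3,
                                           seed = 6, fit_restarts = 2))
  expect_equal(a$best_trajectory, b$best_trajectory, tolerance = 1e-6)
})

test_that("MTBO transfers from a dense correlated auxiliary task", {
  fam <- tiny_family(seed = 15)
  bench <- synthetic_benchmark(fam, task = 1, noisy = FALSE)
  aux <- family_table(fam, 2, 30, seed = 5)
  cfg <- campaign_config("MTBO", budget = 1, auxiliary_tables = list(aux),
                         seed = 2, fit_restarts = 4)
  expect_equal(cfg$n_init, 0L)   # no LHS step when prior data exist
  res <- run_campaign(bench, cfg)
  expect_null(res$error)
  expect_equal(nrow(res$iterations), 1)
  # first suggestion should land in the top decile of the (rho = 1) surface
  g <- data.frame(x = seq(0, 1, length.out = 200))
  surface <- mtbo:::evaluate_yield_df(fam, 1, g)
  first <- res$iterations$noiseless[1]
  expect_gte(first, quantile(surface, 0.9) - 1e-9)
})

test_that("domain mismatches between benchmark and auxiliaries are rejected", {
  bench <- synthetic_benchmark(tiny_family(), task = 1)
  other <- reaction_domain(list(continuous_variable("z", 0, 2)))
  aux <- experiment_table(data.frame(z = c(0.5, 1.5), yield = c(10, 20)),
                          other)
  expect_error(
    run_campaign(bench, campaign_config("MTBO", budget = 1,
                                        auxiliary_tables = list(aux))),
    "domain")
})

test_that("experiments_to_optimum scans suggested experiments only", {
  skeleton <- function(noiseless) {
    structure(list(
      iterations = data.frame(
        x = seq_along(noiseless), yield = noiseless,
        noiseless = noiseless,
        acq_value = NA_real_,
        phase = c("init", rep("suggest", length(noiseless) - 1))),
      best_trajectory = cummax(noiseless),
      domain = tiny_domain(),
      config = list(strategy = "STBO"), error = NULL),
      class = "campaign_result")
  }
  res <- skeleton(c(90, 40, 96, 95.5, 97))
  expect_equal(experiments_to_optimum(res, 96, tol_pct = 1), 2L)
  expect_equal(experiments_to_optimum(res, 97, tol_pct = 0.5), 4L)
  expect_identical(experiments_to_optimum(res, 99.9, tol_pct = 0.5),
                   NA_integer_)
  # brute-force scan over the stored trajectory agrees
  sug <- res$iterations[res$iterations$phase == "suggest", ]
  brute <- min(which(sug$noiseless >= 96 - 1))
  expect_equal(experiments_to_optimum(res, 96, 1), brute)
})

test_that("selection frequencies normalize over declared levels", {
  dom <- reaction_domain(list(
    continuous_variable("x", 0, 1),
    categorical_variable("cat", c("A", "B", "C"))))
  mk <- function(levels) {
    structure(list(
      iterations = data.frame(
        x = seq_along(levels) / 10, cat = levels,
        yield = 50, noiseless = 50, acq_value = 1,
        phase = c("init", rep("suggest", length(levels) - 1))),
      domain = dom, config = list(), error = NULL,
      best_trajectory = rep(50, length(levels))),
      class = "campaign_result")
  }
  r1 <- mk(c("A", "B", "B", "C", "B"))   # suggested: B B C B
  fr <- selection_frequency(r1, "cat")
  expect_equal(fr, c(A = 0, B = 0.75, C = 0.25))
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  # pooled across results, all-one-level case
  r2 <- mk(c("C", "A", "A"))
  fr2 <- selection_frequency(list(r2), "cat")
  expect_equal(unname(fr2["A"]), 1)
  expect_error(selection_frequency(r1, "x"), "not categorical")
  expect_error(selection_frequency(r1, "nope"), "unknown")
})

test_that("compare_strategies aggregates trajectories, CIs and frequencies", {
  fam <- make_task_family(1, correlation = 1, noise_sd = 0, seed = 44,
                          domain = reaction_domain(list(
                            continuous_variable("x", 0, 1),
                            categorical_variable("cat", c("A", "B")))))
  bench <- synthetic_benchmark(fam, task = 1, noisy = FALSE)
  cfgs <- list(stbo = campaign_config("STBO", budget = 2, n_init = 2,
                                      fit_restarts = 2,
                                      optimizer = opt_config(n_restarts = 4)))
  cmp <- compare_strategies(bench, cfgs, n_repeats = 2, base_seed = 3)
  expect_s3_class(cmp, "comparison_summary")
  expect_equal(nrow(cmp$trajectories), 4)   # 2 init + 2 suggested indices
  expect_true(all(cmp$trajectories$ci_halfwidth >= 0))
  fr <- cmp$frequencies$stbo$cat
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_true(is.finite(cmp$truth_yield))
  expect_length(cmp$experiments_to_optimum$stbo, 2)
  # identical repeats have zero CI half-width: aggregate two copies of the
  # same deterministic run
  r <- run_campaign(bench, cfgs$stbo)
  tr <- rbind(r$best_trajectory, r$best_trajectory)
  expect_equal(max(1.96 * apply(tr, 2, sd) / sqrt(2)), 0)
  expect_error(compare_strategies(bench, cfgs, n_repeats = 1), "n_repeats")
  expect_error(compare_strategies(bench, unname(cfgs), n_repeats = 2),
               "named")
})

test_that("suggest_next walks the LHS design then the acquisition argmax", {
  dom <- tiny_domain()
  cfg <- campaign_config("STBO", budget = 1, n_init = 3, seed = 8,
                         fit_restarts = 2)
  empty <- experiment_table(
    data.frame(x = numeric(0), yield = numeric(0)), dom)
  s1 <- suggest_next(empty, cfg, domain = dom)
  design <- lhs_design(dom, 3, seed = mtbo:::derive_seed(8, 0))
  expect_equal(s1$x, design$x[1])
  # idempotent
  expect_identical(suggest_next(empty, cfg, domain = dom), s1)
  # with a full init table, suggestions come from the model and stay valid
  tab <- experiment_table(
    data.frame(x = design$x, yield = c(20, 60, 35)), dom)
  s2 <- suggest_next(tab, cfg, domain = dom)
  expect_true(s2$x >= 0 && s2$x <= 1)
  expect_identical(suggest_next(tab, cfg, domain = dom), s2)
})
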