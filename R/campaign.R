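#' Campaign configuration
#'
#' @param strategy `"STBO"` (single-task) or `"MTBO"` (multitask, trained
#'   jointly on auxiliary campaign tables).
#' @param budget Maximum number of algorithm-suggested experiments.
#' @param n_init Latin-hypercube initialization count. Forced to 0 for
#'   MTBO with auxiliary data: the initialization step is only needed when
#'   there is no previous experimental information to learn from.
#' @param auxiliary_tables List of [experiment_table()]s from completed
#'   auxiliary campaigns (MTBO only). Their task labels are kept; any
#'   label clashing with `"main"` is renamed.
#' @param acquisition An [acq_config()]; default closed-form EI, the
#'   in-silico choice (use qNEI for live noisy experiments).
#' @param optimizer An [opt_config()].
#' @param seed Base seed; every initialization, refit, acquisition and
#'   noisy benchmark draw derives its own stream from it.
#' @param fit_restarts Restarts for each surrogate refit.
#' @param rank Task-kernel rank for MTBO (default `min(T, 2)`).
#' @param warm_start If `TRUE`, each refit adds the previous iteration's
#'   hyperparameters as an extra optimizer start.
#' @return An object of class `campaign_config`.
#' @export
campaign_config <- function(strategy = c("STBO", "MTBO"), budget,
                            n_init = 8, auxiliary_tables = list(),
                            acquisition = acq_config("EI"),
                            optimizer = opt_config(), seed = 1,
                            fit_restarts = 8, rank = NULL,
                            warm_start = FALSE) {
  strategy <- match.arg(strategy)
  if (budget < 1) stopf("budget must be >= 1")
  if (strategy == "MTBO" && length(auxiliary_tables) > 0L) n_init <- 0L
  if (strategy == "STBO" && length(auxiliary_tables) > 0L)
    stopf("STBO does not use auxiliary tables")
  if (n_init == 0L && length(auxiliary_tables) == 0L)
    stopf("n_init must be >= 1 when there is no auxiliary data")
  structure(list(strategy = strategy, budget = as.integer(budget),
                 n_init = as.integer(n_init),
                 auxiliary_tables = auxiliary_tables,
                 acquisition = acquisition, optimizer = optimizer,
                 seed = as.integer(seed),
                 fit_restarts = as.integer(fit_restarts), rank = rank,
                 warm_start = isTRUE(warm_start)),
            class = "campaign_config")
}

same_domain <- function(d1, d2) {
  isTRUE(all.equal(d1$variables, d2$variables)) &&
    identical(d1$objective, d2$objective)
}

# Stack main-task observations and auxiliary tables into one joint table.
combined_table <- function(main_df, aux_tables, domain) {
  parts <- list()
  if (nrow(main_df) > 0L) {
    m <- main_df
    m$task <- "main"
    parts[[1L]] <- m
  }
  for (i in seq_along(aux_tables)) {
    a <- as.data.frame(aux_tables[[i]])
    a$task[a$task == "main"] <- paste0("aux", i)
    parts[[length(parts) + 1L]] <- a
  }
  cols <- c(variable_names(domain), domain$objective, "task")
  parts <- lapply(parts, function(p) p[, cols])
  experiment_table(do.call(rbind, parts), domain)
}

# Fit the configured surrogate on the data available so far. With zero
# main-task observations (MTBO warm start from auxiliary campaigns only),
# the model is trained on the auxiliary data and predictions target the
# auxiliary task whose best observed yield is highest — the most promising
# prior campaign seeds the first suggestion.
fit_campaign_model <- function(main_df, config, domain, seed,
                               init_theta = NULL) {
  aux <- config$auxiliary_tables
  if (config$strategy == "STBO" || length(aux) == 0L) {
    tab <- experiment_table(cbind(main_df, task = "main")[, c(
      variable_names(domain), domain$objective, "task")], domain)
    return(fit_gp(tab, n_restarts = config$fit_restarts, seed = seed,
                  init_theta = init_theta))
  }
  if (nrow(main_df) == 0L) {
    tab <- combined_table(main_df, aux, domain)
    df <- as.data.frame(tab)
    best_by_task <- tapply(df[[domain$objective]], df$task, max)
    target <- names(best_by_task)[which.max(best_by_task)]
    if (length(unique(df$task)) == 1L) {
      return(fit_gp(tab, n_restarts = config$fit_restarts, seed = seed))
    }
    return(fit_mtgp(tab, rank = config$rank,
                    n_restarts = config$fit_restarts, seed = seed,
                    main_task = target))
  }
  tab <- combined_table(main_df, aux, domain)
  fit_mtgp(tab, rank = config$rank, n_restarts = config$fit_restarts,
           seed = seed, main_task = "main", init_theta = init_theta)
}

#' Run a closed-loop optimization campaign against a benchmark
#'
#' The loop of surrogate-guided experimentation: fit the surrogate on all
#' data so far (plus any auxiliary tables), maximize the acquisition,
#' evaluate the benchmark at the suggested condition, append, repeat.
#' Deterministic per seed on noiseless benchmarks. If a model fit fails
#' mid-run the campaign halts gracefully with the error recorded and the
#' partial result returned.
#'
#' @param benchmark A `benchmark_handle` ([synthetic_benchmark()] or
#'   [train_table_surrogate()]).
#' @param config A [campaign_config()].
#' @return An object of class `campaign_result`: an `iterations` data
#'   frame (condition, measured yield, noiseless yield where available,
#'   acquisition value, phase) and the monotone `best_trajectory`.
#' @export
run_campaign <- function(benchmark, config) {
  domain <- benchmark$domain
  for (a in config$auxiliary_tables) {
    if (!same_domain(domain, table_domain(a)))
      stopf("auxiliary table domain does not match the benchmark domain")
  }
  obj <- domain$objective
  rows <- list()
  record <- function(condition, phase, acq_value = NA_real_, seed = NULL,
                     model_logLik = NA_real_) {
    y <- benchmark$evaluate(condition, seed = seed)
    yn <- if (!is.null(benchmark$noiseless)) benchmark$noiseless(condition)
          else NA_real_
    row <- as.data.frame(condition, stringsAsFactors = FALSE)
    row[[obj]] <- y
    row$noiseless <- yn
    row$acq_value <- acq_value
    row$phase <- phase
    row$model_logLik <- model_logLik
    rows[[length(rows) + 1L]] <<- row
  }

  if (config$n_init > 0L) {
    init <- lhs_design(domain, config$n_init,
                       seed = derive_seed(config$seed, 0L))
    for (i in seq_len(nrow(init))) {
      record(as.list(init[i, , drop = FALSE]), "init",
             seed = derive_seed(config$seed, 100L + i))
    }
  }

  err <- NULL
  theta_prev <- NULL
  for (it in seq_len(config$budget)) {
    main_df <- if (length(rows)) do.call(rbind, rows) else
      stats::setNames(data.frame(), character(0))
    main_df <- if (length(rows))
      main_df[, c(variable_names(domain), obj), drop = FALSE] else main_df
    state <- tryCatch(
      fit_campaign_model(main_df, config, domain,
                         seed = derive_seed(config$seed, 400L + it),
                         init_theta = if (config$warm_start) theta_prev),
      error = function(e) e)
    if (inherits(state, "error")) {
      err <- conditionMessage(state)
      break
    }
    theta_prev <- state$theta
    acq <- config$acquisition
    acq$seed <- derive_seed(config$seed, 200L + it)
    opt <- config$optimizer
    opt$seed <- derive_seed(config$seed, 300L + it)
    sugg <- tryCatch(
      maximize_acquisition(state, domain, acq = acq, opt = opt),
      error = function(e) e)
    if (inherits(sugg, "error")) {
      err <- conditionMessage(sugg)
      break
    }
    record(sugg$condition, "suggest", acq_value = sugg$value,
           seed = derive_seed(config$seed, 500L + it),
           model_logLik = state$logLik)
  }

  iterations <- if (length(rows)) do.call(rbind, rows) else
    data.frame(phase = character(0))
  rownames(iterations) <- NULL
  structure(list(iterations = iterations,
                 best_trajectory = if (length(rows))
                   cummax(iterations[[obj]]) else numeric(0),
                 config = config, domain = domain, error = err),
            class = "campaign_result")
}

#' @export
print.campaign_result <- function(x, ...) {
  n_init <- sum(x$iterations$phase == "init")
  n_sug <- sum(x$iterations$phase == "suggest")
  cat(sprintf("%s campaign: %d init + %d suggested experiments\n",
              x$config$strategy, n_init, n_sug))
  cat(sprintf("  best %s: %.2f%%\n", x$domain$objective,
              max(x$best_trajectory)))
  if (!is.null(x$error)) cat("  halted early:", x$error, "\n")
  invisible(x)
}

#' Experiments needed to reach the optimum
#'
#' 1-based index of the first algorithm-suggested experiment whose
#' noiseless yield is within `tol_pct` percentage points of the
#' ground-truth optimum; `NA` if never reached. Initialization experiments
#' do not count.
#'
#' @param result A `campaign_result`.
#' @param truth_yield Ground-truth optimal yield (percent).
#' @param tol_pct Tolerance in percentage points (default 1).
#' @return Integer index or `NA_integer_`.
#' @export
experiments_to_optimum <- function(result, truth_yield, tol_pct = 1) {
  sug <- result$iterations[result$iterations$phase == "suggest", ,
                           drop = FALSE]
  if (nrow(sug) == 0L) return(NA_integer_)
  y <- ifelse(is.na(sug$noiseless), sug[[result$domain$objective]],
              sug$noiseless)
  hit <- which(y >= truth_yield - tol_pct)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Selection frequency of categorical levels
#'
#' Pooled over the algorithm-suggested (non-initialization) experiments of
#' one or more campaign results; fractions over the declared levels sum
#' to 1.
#'
#' @param results A `campaign_result` or list of them.
#' @param variable Name of a categorical domain variable.
#' @return Named numeric vector of fractions (one per declared level).
#' @export
selection_frequency <- function(results, variable) {
  if (inherits(results, "campaign_result")) results <- list(results)
  domain <- results[[1L]]$domain
  if (!variable %in% variable_names(domain))
    stopf("unknown variable '%s'", variable)
  v <- domain$variables[[variable]]
  if (is_continuous(v)) stopf("variable '%s' is not categorical", variable)
  picks <- unlist(lapply(results, function(r) {
    sug <- r$iterations[r$iterations$phase == "suggest", , drop = FALSE]
    as.character(sug[[variable]])
  }))
  if (length(picks) == 0L) stopf("no suggested experiments to count")
  counts <- table(factor(picks, levels = v$levels))
  as.numeric(counts) / length(picks) -> fr
  stats::setNames(fr, v$levels)
}

#' Compare optimization strategies over repeated campaigns
#'
#' Runs each configuration `n_repeats` times with seeds derived from
#' `base_seed`, then aggregates the mean best-yield trajectory with a 95%
#' normal confidence interval (`mean +/- 1.96 sd / sqrt(n)`) per
#' experiment index, the pooled categorical selection frequencies, and —
#' when the benchmark exposes a ground truth — the per-run experiments to
#' optimum.
#'
#' @param benchmark A `benchmark_handle`.
#' @param configs Named list of [campaign_config()]s.
#' @param n_repeats Repeats per configuration (`>= 2`).
#' @param base_seed Base seed for the derived per-run seeds.
#' @param tol_pct Tolerance (percentage points) for
#'   [experiments_to_optimum()]; set e.g. to 5% of the optimum to score
#'   "reached 95% of the optimum".
#' @param keep_results Keep the individual `campaign_result`s.
#' @return An object of class `comparison_summary` with `trajectories`
#'   (strategy, index, mean, ci_halfwidth), `frequencies`,
#'   `experiments_to_optimum`, `truth_yield` and `n_repeats`.
#' @export
compare_strategies <- function(benchmark, configs, n_repeats = 20,
                               base_seed = 1, tol_pct = 1,
                               keep_results = FALSE) {
  if (n_repeats < 2) stopf("n_repeats must be >= 2")
  if (is.null(names(configs)) || any(!nzchar(names(configs))))
    stopf("configs must be a named list")
  for (cfg in configs) {
    for (a in cfg$auxiliary_tables) {
      if (!same_domain(benchmark$domain, table_domain(a)))
        stopf("auxiliary table domain inconsistent with the benchmark")
    }
  }
  truth_yield <- if (!is.null(benchmark$truth)) benchmark$truth()$yield
                 else NA_real_
  traj <- list()
  freqs <- list()
  e2o <- list()
  all_results <- list()
  cat_vars <- categorical_names(benchmark$domain)
  for (k in seq_along(configs)) {
    nm <- names(configs)[k]
    runs <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      cfg <- configs[[k]]
      cfg$seed <- derive_seed(base_seed, k * 1000L + r)
      runs[[r]] <- run_campaign(benchmark, cfg)
    }
    tr <- do.call(rbind, lapply(runs, function(x) x$best_trajectory))
    traj[[nm]] <- data.frame(
      strategy = nm, index = seq_len(ncol(tr)),
      mean = colMeans(tr),
      ci_halfwidth = 1.96 * apply(tr, 2L, stats::sd) / sqrt(n_repeats))
    freqs[[nm]] <- lapply(stats::setNames(cat_vars, cat_vars), function(v)
      selection_frequency(runs, v))
    if (is.finite(truth_yield)) {
      e2o[[nm]] <- vapply(runs, experiments_to_optimum,
                          integer(1), truth_yield = truth_yield,
                          tol_pct = tol_pct)
    }
    if (keep_results) all_results[[nm]] <- runs
  }
  structure(list(trajectories = do.call(rbind, unname(traj)),
                 frequencies = freqs,
                 experiments_to_optimum = e2o,
                 truth_yield = truth_yield, tol_pct = tol_pct,
                 n_repeats = as.integer(n_repeats),
                 results = if (keep_results) all_results),
            class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf("Strategy comparison over %d repeats\n", x$n_repeats))
  for (nm in unique(x$trajectories$strategy)) {
    tr <- x$trajectories[x$trajectories$strategy == nm, ]
    last <- tr[nrow(tr), ]
    cat(sprintf("  %s: final mean best yield %.2f%% (+/- %.2f)\n",
                nm, last$mean, last$ci_halfwidth))
    if (length(x$experiments_to_optimum[[nm]])) {
      cat(sprintf("    median experiments to optimum (tol %.2f): %s\n",
                  x$tol_pct,
                  format(stats::median(x$experiments_to_optimum[[nm]],
                                       na.rm = TRUE))))
    }
  }
  invisible(x)
}

#' Suggest the next experiment (live mode)
#'
#' One suggestion with no benchmark in the loop: either the next pending
#' Latin-hypercube initialization point (when the main table is still
#' shorter than `n_init` and no auxiliary data exist) or the acquisition
#' argmax of the configured surrogate. Pure function of its inputs: the
#' same tables, config and seed always give the same suggestion.
#'
#' @param table Main-task [experiment_table()] (may have zero rows).
#' @param config A [campaign_config()] (its `budget` is ignored here).
#' @param domain The [reaction_domain()]; defaults to the table's.
#' @return Named condition list.
#' @export
suggest_next <- function(table, config, domain = NULL) {
  domain <- domain %||% table_domain(table)
  if (is.null(domain)) stopf("suggest_next needs a domain")
  main_df <- as.data.frame(table)
  n_main <- nrow(main_df)
  no_aux <- length(config$auxiliary_tables) == 0L
  if (no_aux && n_main < config$n_init) {
    init <- lhs_design(domain, config$n_init,
                       seed = derive_seed(config$seed, 0L))
    return(as.list(init[n_main + 1L, , drop = FALSE]))
  }
  main_df <- if (n_main > 0L)
    main_df[, c(variable_names(domain), domain$objective), drop = FALSE]
  else main_df
  it <- n_main + 1L
  state <- fit_campaign_model(main_df, config, domain,
                              seed = derive_seed(config$seed, 400L + it))
  acq <- config$acquisition
  acq$seed <- derive_seed(config$seed, 200L + it)
  opt <- config$optimizer
  opt$seed <- derive_seed(config$seed, 300L + it)
  maximize_acquisition(state, domain, acq = acq, opt = opt)$condition
}
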