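#' Default synthetic benchmark domain
#'
#' Three continuous reaction variables (residence time, temperature,
#' catalyst loading) plus one categorical catalyst variable with eight
#' levels — the shape of a typical cross-coupling screening space with two
#' precatalysts and four ligands.
#'
#' @param n_levels Number of catalyst levels (default 8).
#' @return A [reaction_domain()].
#' @export
default_benchmark_domain <- function(n_levels = 8) {
  if (n_levels <= 4) {
    levels <- paste0("P1-L", seq_len(n_levels))
  } else {
    levels <- paste0("P", rep(1:2, each = ceiling(n_levels / 2)), "-L",
                     rep(seq_len(ceiling(n_levels / 2)), 2))[seq_len(n_levels)]
  }
  reaction_domain(list(
    continuous_variable("time", 5, 60, "min"),
    continuous_variable("temperature", 50, 150, "C"),
    continuous_variable("loading", 1, 10, "mol%"),
    categorical_variable("catalyst", levels)
  ), objective = "yield", maximize = TRUE)
}

# One random smooth latent surface: per-level offset plus two Gaussian
# bumps (per level) over the scaled continuous coordinates. Drawn entirely
# from the current RNG stream.
draw_surface <- function(n_cont, level_labels) {
  nl <- max(length(level_labels), 1L)
  list(
    offset = stats::rnorm(nl, 0, 0.5),
    center1 = matrix(stats::runif(nl * n_cont, 0.1, 0.9), nl, n_cont),
    height1 = stats::runif(nl, 1.2, 2.5),
    width1 = matrix(stats::runif(nl * n_cont, 0.25, 0.55), nl, n_cont),
    center2 = matrix(stats::runif(nl * n_cont, 0, 1), nl, n_cont),
    height2 = stats::runif(nl, -1, 1),
    width2 = matrix(stats::runif(nl * n_cont, 0.3, 0.7), nl, n_cont)
  )
}

eval_surface <- function(surf, xc, li) {
  b1 <- surf$height1[li] *
    exp(-sum(((xc - surf$center1[li, ]) / surf$width1[li, ])^2))
  b2 <- surf$height2[li] *
    exp(-sum(((xc - surf$center2[li, ]) / surf$width2[li, ])^2))
  surf$offset[li] + b1 + b2
}

#' Synthetic family of correlated reaction-yield tasks
#'
#' Generates `n_tasks` ground-truth yield surfaces over a mixed domain.
#' Each task's latent surface is the blend
#' `sqrt(rho) * shared + sqrt(1 - rho) * independent_t`, so `rho` is the
#' fraction of variance drawn from the shared surface and directly
#' controls the intertask correlation: `rho = 1` gives identical tasks
#' (the similar-auxiliary regime), `rho = 0` independent ones (the
#' divergent regime). The latent value is mapped through a saturating
#' logistic transform to a yield in \[0, 100\]% — yields saturate
#' physically at both rails.
#'
#' @param n_tasks Number of tasks (`>= 1`).
#' @param correlation Blend weight `rho` in \[0, 1\].
#' @param noise_sd Gaussian observation-noise standard deviation in
#'   percent applied by noisy evaluations (clamped draws).
#' @param seed Seed; families are fully reproducible from
#'   `(parameters, seed)`.
#' @param domain Optional [reaction_domain()]; default
#'   [default_benchmark_domain()].
#' @param shared_surface Optional replacement for the randomly drawn
#'   shared surface (same structure as the drawn one); lets callers plant
#'   a known optimum, e.g. for calibration studies.
#' @return An object of class `task_family`.
#' @export
make_task_family <- function(n_tasks, correlation, noise_sd = 0, seed = 1,
                             domain = NULL, shared_surface = NULL) {
  if (n_tasks < 1) stopf("n_tasks must be >= 1")
  if (!is_scalar_number(correlation) || correlation < 0 || correlation > 1)
    stopf("correlation rho must lie in [0, 1]")
  if (noise_sd < 0) stopf("noise_sd must be nonnegative")
  domain <- domain %||% default_benchmark_domain()
  cont <- continuous_names(domain)
  cats <- categorical_names(domain)
  # Level index = position in the expanded grid of all categorical combos.
  combo_labels <- if (length(cats)) {
    g <- expand.grid(lapply(cats, function(nm) domain$variables[[nm]]$levels),
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    names(g) <- cats
    g
  } else {
    NULL
  }
  n_combo <- if (is.null(combo_labels)) 1L else nrow(combo_labels)
  surfaces <- with_seed(seed, {
    shared <- draw_surface(length(cont), seq_len(n_combo))
    indep <- lapply(seq_len(n_tasks), function(t)
      draw_surface(length(cont), seq_len(n_combo)))
    list(shared = shared, indep = indep)
  })
  if (!is.null(shared_surface)) surfaces$shared <- shared_surface
  structure(list(n_tasks = as.integer(n_tasks), correlation = correlation,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 domain = domain, combos = combo_labels,
                 shared = surfaces$shared, indep = surfaces$indep,
                 latent_scale = 1.1, latent_shift = -0.1),
            class = "task_family")
}

#' @export
print.task_family <- function(x, ...) {
  cat(sprintf(
    "Synthetic task family: %d task(s), rho = %g, noise_sd = %g%%, seed = %d\n",
    x$n_tasks, x$correlation, x$noise_sd, x$seed))
  print(x$domain)
  invisible(x)
}

family_combo_index <- function(family, condition) {
  if (is.null(family$combos)) return(1L)
  hit <- rep(TRUE, nrow(family$combos))
  for (nm in names(family$combos)) {
    hit <- hit & family$combos[[nm]] == as.character(condition[[nm]])
  }
  which(hit)[1L]
}

family_latent <- function(family, task, xc, li) {
  rho <- family$correlation
  z_sh <- eval_surface(family$shared, xc, li)
  z_in <- eval_surface(family$indep[[task]], xc, li)
  sqrt(rho) * z_sh + sqrt(1 - rho) * z_in
}

family_scaled_continuous <- function(family, condition) {
  cont <- continuous_names(family$domain)
  vapply(cont, function(nm) {
    v <- family$domain$variables[[nm]]
    (condition[[nm]] - v$lower) / (v$upper - v$lower)
  }, numeric(1))
}

#' Evaluate a synthetic benchmark yield
#'
#' Noiseless evaluations are deterministic functions of the family
#' parameters; noisy evaluations add Gaussian noise with the family's
#' `noise_sd` and clamp the result to \[0, 100\].
#'
#' @param family A [make_task_family()] object.
#' @param task Task index in `1:n_tasks`.
#' @param condition Named condition (list or one-row data frame).
#' @param noisy Add observation noise?
#' @param seed Optional seed for the noise draw; if `NULL` the current RNG
#'   stream is used.
#' @return Yield in percent.
#' @export
evaluate_yield <- function(family, task, condition, noisy = FALSE,
                           seed = NULL) {
  if (!is.numeric(task) || task < 1 || task > family$n_tasks)
    stopf("unknown task %s (family has %d tasks)", format(task)[1],
          family$n_tasks)
  if (is.data.frame(condition)) condition <- as.list(condition[1, , drop = FALSE])
  validate_condition(condition, family$domain)
  xc <- family_scaled_continuous(family, condition)
  li <- family_combo_index(family, condition)
  z <- family_latent(family, as.integer(task), xc, li)
  y <- 100 * stats::plogis(family$latent_scale * z + family$latent_shift)
  if (noisy && family$noise_sd > 0) {
    eps <- if (is.null(seed)) stats::rnorm(1, 0, family$noise_sd)
           else with_seed(seed, stats::rnorm(1, 0, family$noise_sd))
    y <- y + eps
  }
  clamp(y, 0, 100)
}

# Vectorized noiseless surface over a data frame of conditions.
evaluate_yield_df <- function(family, task, df) {
  vapply(seq_len(nrow(df)), function(r) {
    evaluate_yield(family, task, as.list(df[r, , drop = FALSE]),
                   noisy = FALSE)
  }, numeric(1))
}

#' Ground-truth optimum of a synthetic task
#'
#' Dense-grid argmax over all categorical combinations and a regular
#' continuous grid, followed by bounded local refinement of the continuous
#' coordinates from the grid incumbent. Refinement never decreases the
#' incumbent.
#'
#' @param family A [make_task_family()] object.
#' @param task Task index.
#' @param grid_density Grid points per continuous dimension (default 21).
#' @return List with `condition` and `yield` (noiseless percent).
#' @export
ground_truth_optimum <- function(family, task, grid_density = 21) {
  domain <- family$domain
  cont <- continuous_names(domain)
  n_combo <- if (is.null(family$combos)) 1L else nrow(family$combos)
  grid1 <- seq(0, 1, length.out = max(grid_density, 2L))
  Xc <- as.matrix(expand.grid(rep(list(grid1), length(cont)),
                              KEEP.OUT.ATTRS = FALSE))
  best <- list(val = -Inf, xc = NULL, li = NULL)
  for (li in seq_len(n_combo)) {
    vals <- vapply(seq_len(nrow(Xc)), function(r)
      family_latent(family, task, Xc[r, ], li), numeric(1))
    k <- which.max(vals)
    if (vals[k] > best$val) best <- list(val = vals[k], xc = Xc[k, ], li = li)
  }
  refined <- stats::optim(
    best$xc,
    function(xc) -family_latent(family, task, clamp(xc, 0, 1), best$li),
    method = "L-BFGS-B", lower = rep(0, length(cont)),
    upper = rep(1, length(cont)))
  if (-refined$value > best$val) {
    best$xc <- clamp(refined$par, 0, 1)
    best$val <- -refined$value
  }
  condition <- list()
  for (j in seq_along(cont)) {
    v <- domain$variables[[cont[j]]]
    condition[[v$name]] <- v$lower + best$xc[j] * (v$upper - v$lower)
  }
  if (!is.null(family$combos)) {
    for (nm in names(family$combos)) {
      condition[[nm]] <- family$combos[best$li, nm]
    }
  }
  condition <- condition[variable_names(domain)]
  list(condition = condition,
       yield = evaluate_yield(family, task, condition, noisy = FALSE))
}

#' Wrap a synthetic task as a benchmark handle
#'
#' @param family A [make_task_family()] object.
#' @param task Task index the campaign optimizes.
#' @param noisy Whether campaign evaluations draw observation noise.
#' @return A `benchmark_handle` with `evaluate(condition)` (measured
#'   yield), `noiseless(condition)` (ground-truth yield), and the domain.
#' @export
synthetic_benchmark <- function(family, task = 1, noisy = TRUE) {
  force(family); force(task); force(noisy)
  structure(list(
    domain = family$domain,
    provenance = "synthetic",
    family = family,
    task = as.integer(task),
    evaluate = function(condition, seed = NULL) {
      evaluate_yield(family, task, condition, noisy = noisy, seed = seed)
    },
    noiseless = function(condition) {
      evaluate_yield(family, task, condition, noisy = FALSE)
    },
    truth = function(grid_density = 21) {
      ground_truth_optimum(family, task, grid_density)
    }), class = "benchmark_handle")
}

#' Train a yield surrogate from an experiment table
#'
#' Fits a regression surrogate (the package's GP) on a user-supplied
#' experiment table and exposes it as a noiseless benchmark whose
#' predictions are clamped to \[0, 100\]. This is the pattern for building
#' in-silico benchmarks out of completed campaigns or literature tables.
#'
#' @param table An [experiment_table()] with at least 20 observations.
#' @param n_restarts,seed Passed to [fit_gp()].
#' @return A `benchmark_handle` with provenance `"table-surrogate"`.
#' @export
train_table_surrogate <- function(table, n_restarts = 8, seed = 1) {
  if (nrow(table) < 20L)
    stopf("train_table_surrogate needs at least 20 observations (got %d)",
          nrow(table))
  state <- fit_gp(table, n_restarts = n_restarts, seed = seed)
  domain <- table_domain(table)
  predict_one <- function(condition) {
    pm <- posterior_marginals(state, as.data.frame(condition,
                                                   stringsAsFactors = FALSE))
    clamp(pm$mean[1], 0, 100)
  }
  structure(list(
    domain = domain,
    provenance = "table-surrogate",
    model = state,
    evaluate = function(condition, seed = NULL) predict_one(condition),
    noiseless = function(condition) predict_one(condition),
    truth = NULL), class = "benchmark_handle")
}

#' @export
print.benchmark_handle <- function(x, ...) {
  cat(sprintf("Benchmark handle (%s)\n", x$provenance))
  print(x$domain)
  invisible(x)
}

#' Serialize a synthetic family specification to JSON
#'
#' Only the constructor arguments are stored; surfaces are regenerated
#' deterministically from the seed on read, so round-trips are
#' byte-identical in their evaluations.
#'
#' @param family A [make_task_family()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_family <- function(family, path) {
  spec <- list(kind = "task_family", n_tasks = family$n_tasks,
               correlation = family$correlation, noise_sd = family$noise_sd,
               seed = family$seed)
  tmp <- tempfile(fileext = ".json")
  write_domain(family$domain, tmp)
  spec$domain <- jsonlite::read_json(tmp, simplifyVector = FALSE)
  unlink(tmp)
  jsonlite::write_json(spec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a synthetic family specification from JSON
#'
#' @param path Path written by [write_family()].
#' @return A [make_task_family()] object.
#' @export
read_family <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(spec$kind, "task_family"))
    stopf("%s is not a task-family spec", path)
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(spec$domain, tmp, auto_unbox = TRUE, digits = NA)
  domain <- read_domain(tmp)
  unlink(tmp)
  make_task_family(spec$n_tasks, spec$correlation, spec$noise_sd, spec$seed,
                   domain = domain)
}
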