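#' Acquisition configuration
#'
#' @param kind `"EI"` (closed-form expected improvement; default for
#'   in-silico studies) or `"qNEI"` (Monte-Carlo q-noisy expected
#'   improvement; default for live experiments, which are noisy).
#' @param mc_samples Number of posterior samples for qNEI (minimum 64).
#' @param seed Seed for the qNEI base samples. The same base samples are
#'   drawn for every candidate evaluation, so the acquisition surface is
#'   deterministic for the optimizer.
#' @param q Batch size for qNEI.
#' @return An object of class `acq_config`.
#' @export
acq_config <- function(kind = c("EI", "qNEI"), mc_samples = 512, seed = 1,
                       q = 1) {
  kind <- match.arg(kind)
  if (kind == "qNEI" && mc_samples < 64)
    stopf("qNEI requires mc_samples >= 64 (got %d)", mc_samples)
  if (q < 1) stopf("batch size q must be >= 1")
  structure(list(kind = kind, mc_samples = as.integer(mc_samples),
                 seed = as.integer(seed), q = as.integer(q)),
            class = "acq_config")
}

#' Closed-form expected improvement
#'
#' `EI = (mu - y*) Phi(z) + sd * phi(z)` with `z = (mu - y*) / sd`: the
#' expected gain of a Gaussian predictive over the incumbent best observed
#' yield `y*`. No exploration jitter is added. Vectorized over `mean` and
#' `sd`; at `sd = 0` it degenerates to `max(mu - y*, 0)`.
#'
#' @param mean Posterior predictive mean(s).
#' @param sd Posterior predictive standard deviation(s), `>= 0`.
#' @param incumbent Best observed objective value `y*`.
#' @return Nonnegative EI value(s).
#' @export
expected_improvement <- function(mean, sd, incumbent) {
  if (any(sd < 0)) stopf("sd must be nonnegative")
  imp <- mean - incumbent
  out <- pmax(imp, 0)
  pos <- sd > 0
  if (any(pos)) {
    z <- imp[pos] / sd[pos]
    out[pos] <- imp[pos] * stats::pnorm(z) + sd[pos] * stats::dnorm(z)
  }
  pmax(out, 0)
}

# Incumbent y*: best observed yield on the model's (main) task.
incumbent_value <- function(state) {
  y <- observed_main_yields(state)
  if (length(y) == 0L) stopf("incumbent undefined: no observations")
  max(y)
}

observed_main_yields <- function(state) {
  if (inherits(state, "mtgp_state")) state$y[state$task_index == 1L]
  else state$y
}

observed_main_inputs <- function(state) {
  if (inherits(state, "mtgp_state")) {
    state$X[state$task_index == 1L, , drop = FALSE]
  } else {
    state$X
  }
}

#' Expected improvement over a candidate set
#'
#' Applies the closed-form EI to the model's posterior marginals at each
#' candidate, using the best observed yield (on the main task, for
#' multitask models) as the incumbent.
#'
#' @param state A `gp_state` or `mtgp_state`.
#' @param Xq Candidate matrix in encoded coordinates (or conditions).
#' @return Numeric vector of EI values (percent units).
#' @export
ei_over_candidates <- function(state, Xq) {
  inc <- incumbent_value(state)
  pm <- posterior_marginals(state, Xq)
  expected_improvement(pm$mean, pm$sd, inc)
}

#' q-noisy expected improvement
#'
#' Monte-Carlo estimate of
#' `E[ max( max_f(candidates) - max_f(observed inputs), 0 ) ]` under the
#' joint posterior over the candidate batch and the observed inputs. Using
#' the posterior maximum over the observed inputs as the (sampled)
#' incumbent makes the acquisition robust to observation noise, where EI's
#' reliance on the best observed value is a biased estimate. The base
#' normal samples are drawn from `config$seed` on every call, so repeated
#' evaluation is reproducible and candidate batches share common random
#' numbers.
#'
#' @param state A `gp_state` or `mtgp_state` with at least one (main-task)
#'   observation.
#' @param Xcand Candidate batch: q x d matrix in encoded coordinates (a
#'   vector is treated as one candidate).
#' @param config An [acq_config()] with `kind = "qNEI"` (its `mc_samples`
#'   and `seed` are used).
#' @return Nonnegative scalar acquisition value.
#' @export
qnei <- function(state, Xcand, config = acq_config("qNEI")) {
  if (config$mc_samples < 64)
    stopf("qNEI requires mc_samples >= 64 (got %d)", config$mc_samples)
  Xcand <- as_query_matrix(Xcand, state$domain)
  # canonical (lexicographic) candidate order makes the estimate exactly
  # invariant under permutations of the batch
  Xcand <- Xcand[do.call(order, as.data.frame(Xcand)), , drop = FALSE]
  q <- nrow(Xcand)
  Xobs <- observed_main_inputs(state)
  if (nrow(Xobs) == 0L) stopf("qNEI undefined: no observations")
  Xall <- rbind(Xcand, Xobs)
  post <- if (inherits(state, "mtgp_state")) {
    mt_posterior(state, Xall)
  } else {
    posterior(state, Xall)
  }
  Fac <- psd_factor(post$cov)
  m <- nrow(Xall)
  Z <- with_seed(config$seed,
                 matrix(stats::rnorm(m * config$mc_samples), m,
                        config$mc_samples))
  draws <- post$mean + Fac %*% Z          # m x mc_samples
  cand_max <- apply(draws[seq_len(q), , drop = FALSE], 2L, max)
  obs_max <- apply(draws[-seq_len(q), , drop = FALSE], 2L, max)
  mean(pmax(cand_max - obs_max, 0))
}
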