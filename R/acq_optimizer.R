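#' Acquisition optimizer configuration
#'
#' @param n_restarts LHS starting points per categorical combination for
#'   the bounded quasi-Newton continuous maximization.
#' @param max_combinations Categorical level combinations are enumerated
#'   exhaustively up to this cap; beyond it, this many are sampled
#'   uniformly.
#' @param seed Seed controlling start placement and any combination
#'   sampling.
#' @param tol Convergence tolerance; also the encoded-space radius used
#'   for duplicate suppression.
#' @param refine_top How many of the best LHS starts per combination are
#'   polished with L-BFGS-B. `NULL` (default) refines every start when at
#'   most two combinations are in play, otherwise the top two per
#'   combination — exhaustive where cheap, focused where the categorical
#'   grid is large.
#' @return An object of class `opt_config`.
#' @export
opt_config <- function(n_restarts = 8, max_combinations = 64, seed = 1,
                       tol = 1e-6, refine_top = NULL) {
  if (n_restarts < 1 || max_combinations < 1)
    stopf("n_restarts and max_combinations must be positive")
  structure(list(n_restarts = as.integer(n_restarts),
                 max_combinations = as.integer(max_combinations),
                 seed = as.integer(seed), tol = tol,
                 refine_top = refine_top),
            class = "opt_config")
}

#' Latin hypercube design over a mixed domain
#'
#' Continuous dimensions get a maximin-scrambled Latin hypercube: exactly
#' one sample per equal-probability stratum per dimension, mapped to the
#' native bounds. Categorical dimensions are assigned by stratified
#' cycling through the declared levels (so every level appears
#' `floor(n / L)` or `ceiling(n / L)` times) and then shuffled.
#' Deterministic for a fixed seed.
#'
#' @param domain A [reaction_domain()].
#' @param n Number of design points (`>= 1`).
#' @param seed Seed.
#' @return A data frame of `n` conditions (one column per variable).
#' @export
lhs_design <- function(domain, n, seed = 1) {
  if (n < 1) stopf("lhs_design needs n >= 1")
  n <- as.integer(n)
  cont <- continuous_names(domain)
  cat_v <- categorical_names(domain)
  with_seed(seed, {
    out <- list()
    if (length(cont)) {
      U <- if (n == 1L) {
        matrix(stats::runif(length(cont)), 1L)
      } else {
        lhs::maximinLHS(n, length(cont))
      }
      for (j in seq_along(cont)) {
        v <- domain$variables[[cont[j]]]
        out[[v$name]] <- v$lower + U[, j] * (v$upper - v$lower)
      }
    }
    for (nm in cat_v) {
      lv <- domain$variables[[nm]]$levels
      cyc <- rep_len(lv, n)
      out[[nm]] <- sample(cyc, n)
    }
    as.data.frame(out, stringsAsFactors = FALSE)[, variable_names(domain),
                                                 drop = FALSE]
  })
}

# Index layout of the encoded vector: where each variable's coordinates sit.
encoding_layout <- function(domain) {
  out <- list()
  i <- 1L
  for (v in domain$variables) {
    k <- if (is_continuous(v)) 1L else length(v$levels)
    out[[v$name]] <- list(variable = v, idx = i:(i + k - 1L))
    i <- i + k
  }
  out
}

# Evaluate the configured acquisition on an M x d matrix of encoded points.
acq_values <- function(state, Xq, acq) {
  if (acq$kind == "EI") {
    ei_over_candidates(state, Xq)
  } else {
    Xq <- as_query_matrix(Xq, state$domain)
    vapply(seq_len(nrow(Xq)), function(i) {
      qnei(state, Xq[i, , drop = FALSE], acq)
    }, numeric(1))
  }
}

#' Maximize the acquisition over a mixed domain
#'
#' Enumerates categorical level combinations (all of them when their
#' number is within `max_combinations`, otherwise a uniform sample of that
#' size); for each combination, runs multi-start bounded L-BFGS-B over the
#' scaled continuous coordinates from Latin hypercube starts. The relaxed
#' one-hot space is never searched: every evaluated point is a valid
#' condition. Ties in acquisition value break toward the lexicographically
#' smallest encoded vector; if the argmax duplicates an already-observed
#' condition (within `tol` in encoded space), the best non-duplicate
#' evaluated candidate is returned instead, which prevents stalling on
#' noise-free benchmarks.
#'
#' @param state A fitted `gp_state` or `mtgp_state`.
#' @param domain The [reaction_domain()] (defaults to the model's).
#' @param acq An [acq_config()].
#' @param opt An [opt_config()].
#' @param exclude Optional matrix of encoded conditions to treat as
#'   already run (defaults to the model's observed main-task inputs).
#' @return List with `condition` (named list), `value` (acquisition at the
#'   returned point) and `encoded` (the encoded vector).
#' @export
maximize_acquisition <- function(state, domain = NULL,
                                 acq = acq_config("EI"),
                                 opt = opt_config(), exclude = NULL) {
  domain <- domain %||% state$domain
  if (is.null(domain) || length(domain$variables) < 1L)
    stopf("maximize_acquisition needs a non-empty domain")
  layout <- encoding_layout(domain)
  cont <- continuous_names(domain)
  cat_v <- categorical_names(domain)
  dmn <- encoded_dim(domain)
  if (is.null(exclude)) exclude <- observed_main_inputs(state)

  combos <- if (length(cat_v)) {
    expand.grid(lapply(cat_v, function(nm) domain$variables[[nm]]$levels),
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  } else {
    data.frame(row.names = 1)
  }
  names(combos) <- cat_v
  n_combo <- max(nrow(combos), 1L)
  if (nrow(combos) > opt$max_combinations) {
    keep <- with_seed(derive_seed(opt$seed, 999L),
                      sample.int(nrow(combos), opt$max_combinations))
    combos <- combos[keep, , drop = FALSE]
    n_combo <- nrow(combos)
  }
  refine_top <- opt$refine_top %||%
    (if (n_combo <= 2L) opt$n_restarts else 2L)

  template_for <- function(ci) {
    v <- numeric(dmn)
    for (nm in cat_v) {
      lv <- layout[[nm]]$variable$levels
      v[layout[[nm]]$idx] <- as.numeric(lv == combos[ci, nm])
    }
    v
  }
  cont_idx <- unlist(lapply(cont, function(nm) layout[[nm]]$idx))

  search <- function(value_fun) {
    cand_vecs <- list()
    cand_vals <- numeric(0)
    record <- function(vec, val) {
      cand_vecs[[length(cand_vecs) + 1L]] <<- vec
      cand_vals[length(cand_vals) + 1L] <<- val
    }
    for (ci in seq_len(n_combo)) {
      tmpl <- template_for(ci)
      if (length(cont) == 0L) {
        record(tmpl, value_fun(matrix(tmpl, 1L)))
        next
      }
      k <- length(cont)
      starts <- with_seed(derive_seed(opt$seed, ci), {
        if (opt$n_restarts == 1L) matrix(stats::runif(k), 1L)
        else lhs::randomLHS(opt$n_restarts, k)
      })
      Xs <- matrix(rep(tmpl, each = nrow(starts)), nrow(starts), dmn)
      Xs[, cont_idx] <- starts
      vals <- value_fun(Xs)
      for (r in seq_len(nrow(starts))) record(Xs[r, ], vals[r])
      ord <- order(vals, decreasing = TRUE)
      f_neg <- function(xc) {
        v <- tmpl
        v[cont_idx] <- clamp(xc, 0, 1)
        -value_fun(matrix(v, 1L))
      }
      for (r in utils::head(ord, refine_top)) {
        res <- tryCatch(
          stats::optim(starts[r, ], f_neg, method = "L-BFGS-B",
                       lower = rep(0, k), upper = rep(1, k),
                       control = list(maxit = 60, factr = 1e9)),
          error = function(e) NULL)
        if (is.null(res)) next
        v <- tmpl
        v[cont_idx] <- clamp(res$par, 0, 1)
        record(v, -res$value)
      }
    }
    list(vecs = cand_vecs, vals = cand_vals)
  }

  acq_fun <- function(Xs) acq_values(state, Xs, acq)
  found <- search(acq_fun)
  degenerate <- max(found$vals) <= 1e-10
  if (degenerate) {
    # acquisition plateau: nothing is expected to improve on the incumbent
    # anywhere (converged or fully-informed surrogate). Fall back to pure
    # exploitation of the posterior mean so the suggestion stays sensible.
    found <- search(function(Xs) posterior_marginals(state, Xs)$mean)
  }
  cand_vecs <- found$vecs
  cand_vals <- found$vals

  pick_best <- function(which_ok) {
    vals <- cand_vals[which_ok]
    vecs <- cand_vecs[which_ok]
    best_val <- max(vals)
    tied <- which(vals >= best_val - 1e-12)
    if (length(tied) > 1L) {
      # lexicographically smallest encoded vector among ties
      ord <- do.call(order, as.data.frame(do.call(rbind, vecs[tied])))
      tied <- tied[ord[1L]]
    }
    list(vec = vecs[[tied[1L]]], val = vals[tied[1L]])
  }

  is_dup <- function(vec) {
    if (is.null(exclude) || nrow(exclude) == 0L) return(FALSE)
    d2 <- rowSums(sweep(exclude, 2L, vec)^2)
    any(d2 < opt$tol^2)
  }

  best <- pick_best(seq_along(cand_vals))
  if (is_dup(best$vec)) {
    ok <- which(!vapply(cand_vecs, is_dup, logical(1)))
    if (length(ok)) best <- pick_best(ok)
  }
  value <- if (degenerate) acq_fun(matrix(best$vec, 1L)) else best$val
  list(condition = decode_vector(best$vec, domain, categorical = "argmax"),
       value = value, encoded = best$vec)
}
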