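# Shared fixtures: small domains, hand-built GP states, and dense-matrix
# oracles kept deliberately independent of the package's linear-algebra
# path (explicit solve() / determinant(), elementwise kernels).

ch_domain <- function() {
  reaction_domain(list(
    continuous_variable("time", 5, 60, "min"),
    continuous_variable("temperature", 50, 150, "C"),
    continuous_variable("loading", 1, 10, "mol%"),
    categorical_variable("solvent",
                         c("toluene", "DMA", "acetonitrile", "DMSO", "NMP")),
    categorical_variable("ligand",
                         c("JohnPhos", "SPhos", "XPhos", "DPEPhos"))
  ), objective = "yield")
}

domain_1d <- function() {
  reaction_domain(list(continuous_variable("x", 0, 1)))
}

random_condition <- function(domain) {
  out <- list()
  for (v in domain$variables) {
    out[[v$name]] <- if (inherits(v, "continuous_variable")) {
      stats::runif(1, v$lower, v$upper)
    } else {
      sample(v$levels, 1)
    }
  }
  out
}

# Thin wrappers over the exported fixed-parameter constructors (kept so
# older fixture call sites read naturally).
manual_gp_state <- function(X, y, hp, domain = NULL, y_mean = 0, y_sd = 1) {
  gp_state(X, y, hp, domain = domain, y_mean = y_mean, y_sd = y_sd)
}

manual_mtgp_state <- function(X, ti, y, input_hp, tk, domain = NULL,
                              y_mean = NULL, y_sd = NULL) {
  mtgp_state(X, ti, y, input_hp, tk, domain = domain, y_mean = y_mean,
             y_sd = y_sd)
}

# Dense-matrix GP oracle: explicit inverse/determinant, scalar kernel calls.
oracle_gp <- function(X, y, hp, Xq) {
  n <- nrow(X)
  m <- nrow(Xq)
  kfun <- function(a, b) matern52(a, b, hp)
  K <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) kfun(X[i, ], X[j, ])))
  K <- K + diag(hp$noise_var + 1e-6 * hp$sigma2, n)
  Kinv <- solve(K)
  lml <- -0.5 * drop(t(y) %*% Kinv %*% y) -
    0.5 * as.numeric(determinant(K, logarithm = TRUE)$modulus) -
    n / 2 * log(2 * pi)
  Kqx <- outer(seq_len(m), seq_len(n),
               Vectorize(function(i, j) kfun(Xq[i, ], X[j, ])))
  Kqq <- outer(seq_len(m), seq_len(m),
               Vectorize(function(i, j) kfun(Xq[i, ], Xq[j, ])))
  list(lml = lml, mean = drop(Kqx %*% Kinv %*% y),
       cov = Kqq - Kqx %*% Kinv %*% t(Kqx))
}

# Dense-matrix ICM oracle over (x, task) pairs.
oracle_mtgp <- function(X, ti, y, input_hp, tk, Xq, tq) {
  n <- nrow(X)
  m <- nrow(Xq)
  kfun <- function(a, ta, b, tb) icm_kernel(a, ta, b, tb, input_hp, tk)
  K <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    kfun(X[i, ], ti[i], X[j, ], ti[j])))
  K <- K + diag(input_hp$noise_var + 1e-6 * mean(diag(tk$B)[ti]), n)
  Kinv <- solve(K)
  Kqx <- outer(seq_len(m), seq_len(n), Vectorize(function(i, j)
    kfun(Xq[i, ], tq, X[j, ], ti[j])))
  Kqq <- outer(seq_len(m), seq_len(m), Vectorize(function(i, j)
    kfun(Xq[i, ], tq, Xq[j, ], tq)))
  list(mean = drop(Kqx %*% Kinv %*% y),
       cov = Kqq - Kqx %*% Kinv %*% t(Kqx))
}

# Quadrature oracle for expected improvement: numerical integration of
# E[max(N(mu, sd^2) - incumbent, 0)].
oracle_ei <- function(mu, sd, incumbent) {
  if (sd == 0) return(max(mu - incumbent, 0))
  stats::integrate(function(y) (y - incumbent) * stats::dnorm(y, mu, sd),
                   lower = incumbent, upper = mu + 12 * sd,
                   rel.tol = 1e-10)$value
}

# Draw one sample path of a Matern 5/2 GP at the rows of X.
draw_gp_sample <- function(X, hp) {
  K <- mtbo:::matern52_matrix(X, X, hp$sigma2, hp$lengthscales)
  Fac <- mtbo:::psd_factor(K)
  drop(Fac %*% stats::rnorm(nrow(X)))
}

# Noisy LHS table from a synthetic family task, labelled for MTBO use.
family_table <- function(family, task, n, seed, label = "aux") {
  df <- lhs_design(family$domain, n, seed = seed)
  df[[family$domain$objective]] <- vapply(seq_len(n), function(i)
    evaluate_yield(family, task, as.list(df[i, , drop = FALSE]),
                   noisy = family$noise_sd > 0,
                   seed = mtbo:::derive_seed(seed, i)), numeric(1))
  df$task <- label
  experiment_table(df, family$domain)
}
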