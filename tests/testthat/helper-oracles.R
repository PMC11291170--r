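# Independent oracles used across the suite.  These deliberately avoid the
# package's own estimation paths: the grid search enumerates the probit
# likelihood directly, and rmse() is the plain definition.

# Lapse-free probit maximum likelihood by exhaustive grid enumeration.
grid_probit_mle <- function(omega, y, Bg = seq(-40, 40, by = 2.5),
                            Sg = seq(5, 40, by = 2.5)) {
  best <- c(B = NA_real_, S = NA_real_, ll = -Inf)
  for (B in Bg) {
    for (S in Sg) {
      p <- pmin(pmax(pnorm((omega - B) / S), 1e-12), 1 - 1e-12)
      ll <- sum(y * log(p) + (1 - y) * log1p(-p))
      if (ll > best[["ll"]]) best <- c(B = B, S = S, ll = ll)
    }
  }
  best
}

# Wald 95% CI for the probit bias via the numerically differentiated
# Hessian at the (Nelder-Mead) optimum, parameterised as (B, log S).
probit_mle_ci <- function(omega, choice) {
  y <- as.integer(choice == 1)
  nll <- function(par) {
    p <- pmin(pmax(pnorm((omega - par[1]) / exp(par[2])), 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log1p(-p))
  }
  fit <- optim(c(0, log(16)), nll, method = "Nelder-Mead",
               control = list(maxit = 500))
  H <- optimHess(fit$par, nll)
  se <- sqrt(diag(solve(H)))[1]
  c(B = fit$par[1], lo = fit$par[1] - 1.96 * se, hi = fit$par[1] + 1.96 * se)
}

rmse <- function(x, truth) sqrt(mean((x - truth)^2))

# Small-but-honest MCMC settings for tests that fit many times
cfg_small <- function(seed = NULL, stride = 10)
  mcmc_config(n_samples = 1500, burn_in = 750, seed = seed,
              refit_stride = stride)

fig5a_truth <- c(PL = 20, PR = -10, D = 10)
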