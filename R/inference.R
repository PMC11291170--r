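#' Prior specification for the bias model
#'
#' Gaussian priors on the two perceptual biases and the decision bias, a
#' gamma prior (shape `alpha_S`, rate `beta_S`; default mean 16 deg) on
#' the per-condition sensitivity noise, and a shared beta prior on all
#' lapse rates.  Setting `flat = TRUE` replaces the Gaussian bias priors
#' with Uniform(-180, 180) on all three biases simultaneously -- the
#' maximum-likelihood limit used as the uninformative reference.
#'
#' @param P0L,P0R,D0 prior means, degrees.
#' @param tauPL,tauPR,tauD prior SDs, degrees; strictly positive.
#' @param alpha_S,beta_S gamma shape and rate for sensitivity noise.
#' @param gamma_lapse,eps_lapse beta parameters for the lapse rates.
#' @param flat if `TRUE`, flat biases priors over (-180, 180).
#' @return An object of class `bias_prior`.
#' @export
bias_prior <- function(P0L = 0, tauPL = 10, P0R = 0, tauPR = 10,
                       D0 = 0, tauD = 10,
                       alpha_S = 8, beta_S = 0.5,
                       gamma_lapse = 1, eps_lapse = 10,
                       flat = FALSE) {
  if (any(c(tauPL, tauPR, tauD, alpha_S, beta_S, gamma_lapse, eps_lapse) <= 0))
    stop("all prior scale parameters must be positive")
  structure(list(P0L = P0L, tauPL = tauPL, P0R = P0R, tauPR = tauPR,
                 D0 = D0, tauD = tauD, alpha_S = alpha_S, beta_S = beta_S,
                 gamma_lapse = gamma_lapse, eps_lapse = eps_lapse,
                 flat = isTRUE(flat)),
            class = "bias_prior")
}

#' @rdname bias_prior
#' @export
flat_prior <- function(alpha_S = 8, beta_S = 0.5,
                       gamma_lapse = 1, eps_lapse = 10) {
  bias_prior(alpha_S = alpha_S, beta_S = beta_S,
             gamma_lapse = gamma_lapse, eps_lapse = eps_lapse, flat = TRUE)
}

#' MCMC settings
#'
#' @param n_samples total number of MCMC iterations (default 5000).
#' @param burn_in iterations discarded before summarising (default 2500).
#' @param seed optional integer seed.
#' @param refit_stride for the online estimator: refit every this many
#'   trials after the first refit at trial 33 (default 1).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_samples = 5000, burn_in = 2500, seed = NULL,
                        refit_stride = 1) {
  stopifnot(burn_in < n_samples, refit_stride >= 1)
  structure(list(n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in), seed = seed,
                 refit_stride = as.integer(refit_stride)),
            class = "mcmc_config")
}

# Split data frame of trials into per-condition omega / y (y = 1 right)
split_conditions <- function(data) {
  out <- lapply(CONDITIONS, function(k) {
    sel <- data$condition == k
    list(omega = as.numeric(data$omega[sel]),
         y = as.integer(data$choice[sel] == 1))
  })
  names(out) <- CONDITIONS
  out
}

# Split-Rhat of a single chain (split in half)
split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  if (n < 2) return(NA_real_)
  halves <- cbind(x[seq_len(n)], x[seq_len(n) + n])
  W <- mean(apply(halves, 2, var))
  B <- n * var(colMeans(halves))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

summarise_draws <- function(draws) {
  qs <- apply(draws, 2, quantile, probs = c(0.16, 0.84), names = FALSE)
  data.frame(parameter = colnames(draws),
             mean = colMeans(draws),
             sd = apply(draws, 2, sd),
             ci68_lo = qs[1, ], ci68_hi = qs[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the joint posterior over perceptual and decision biases
#'
#' Samples the joint posterior of the three-condition psychometric model
#' -- perceptual biases `PL`, `PR`, shared decision bias `D` (the neutral
#' perceptual bias is fixed at 0, so `BN = D`), per-condition sensitivity
#' noise and lapse rates -- by adaptive Metropolis-within-Gibbs.  Scales
#' adapt only during burn-in.  Derived empirical-bias draws
#' `B_k = P_k + D` are appended.  A split-Rhat above 1.1 on any bias
#' parameter sets `converged = FALSE` in the result (flag, not failure:
#' online use cannot stall on diagnostics).
#'
#' @param data a `session_data` data frame (or any data frame with
#'   columns `condition`, `omega`, `choice`), possibly a session prefix.
#' @param prior a [bias_prior()].
#' @param cfg an [mcmc_config()].
#' @return An object of class `bias_posterior` with elements `draws`
#'   (post-burn-in matrix), `summary`, `diagnostics`, `prior`, `n_trials`.
#' @export
fit_posterior <- function(data, prior = flat_prior(), cfg = mcmc_config()) {
  stopifnot(inherits(prior, "bias_prior"), inherits(cfg, "mcmc_config"))
  if (nrow(data) == 0) stop("cannot fit a posterior with no trials")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sp <- split_conditions(data)
  res <- mcmc_psy_cpp(sp$L$omega, sp$L$y, sp$N$omega, sp$N$y,
                      sp$R$omega, sp$R$y,
                      unclass(prior), cfg$n_samples, cfg$burn_in)
  draws <- res$draws
  derived <- cbind(BL = draws[, "PL"] + draws[, "D"],
                   BN = draws[, "D"],
                   BR = draws[, "PR"] + draws[, "D"])
  draws <- cbind(draws, derived)
  rhat <- vapply(c("PL", "PR", "D"), function(p) split_rhat(draws[, p]),
                 numeric(1))
  structure(list(draws = draws,
                 summary = summarise_draws(draws),
                 diagnostics = list(rhat = rhat,
                                    converged = all(rhat < 1.1, na.rm = TRUE),
                                    accept = res$accept),
                 prior = prior, n_trials = nrow(data)),
            class = "bias_posterior")
}

#' @export
print.bias_posterior <- function(x, ...) {
  cat(sprintf("Bias posterior from %d trials (%s prior)\n", x$n_trials,
              if (x$prior$flat) "flat" else "Gaussian"))
  print(x$summary[x$summary$parameter %in%
                    c("PL", "PR", "D", "SL", "SN", "SR"), ],
        row.names = FALSE, digits = 3)
  if (!x$diagnostics$converged)
    cat("warning: split-Rhat > 1.1 on a bias parameter\n")
  invisible(x)
}

#' Posterior summary table
#'
#' Mean, SD and central 68% interval (16th-84th percentiles) for each
#' parameter.
#'
#' @param x a `bias_posterior`, or a matrix/vector of draws.
#' @param ... unused.
#' @return Data frame with columns `parameter`, `mean`, `sd`, `ci68_lo`,
#'   `ci68_hi`.
#' @export
posterior_summary <- function(x, ...) UseMethod("posterior_summary")

#' @export
posterior_summary.bias_posterior <- function(x, ...) x$summary

#' @export
posterior_summary.default <- function(x, ...) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  if (nrow(x) == 0) stop("no draws to summarise")
  summarise_draws(x)
}

# Summaries implied by the prior alone (used before the first refit)
prior_summary <- function(prior) {
  if (prior$flat) {
    m <- c(PL = 0, PR = 0, D = 0)
    s <- rep(360 / sqrt(12), 3)
    lo <- rep(-0.68 * 180, 3); hi <- rep(0.68 * 180, 3)
  } else {
    m <- c(PL = prior$P0L, PR = prior$P0R, D = prior$D0)
    s <- c(prior$tauPL, prior$tauPR, prior$tauD)
    z <- qnorm(0.84)
    lo <- m - z * s; hi <- m + z * s
  }
  data.frame(parameter = c("PL", "PR", "D"), mean = unname(m), sd = s,
             ci68_lo = unname(lo), ci68_hi = unname(hi),
             stringsAsFactors = FALSE)
}

#' Stateful online estimator
#'
#' Accumulates trials and maintains running posterior summaries of the
#' perceptual and decision biases.  Before 33 trials have arrived (one
#' repetition of every unique stimulus on the default grid) the reported
#' estimates are the prior's; from trial 33 onward the model is refit on
#' all accumulated trials every `refit_stride` trials, and estimates are
#' held constant between refits.
#'
#' @param prior a [bias_prior()].
#' @param cfg an [mcmc_config()]; `cfg$refit_stride` controls refit
#'   frequency and `cfg$seed` (plus the trial count) seeds each refit.
#' @param first_fit trial count at which the first refit happens.
#' @return An environment of class `online_estimator` with methods
#'   `step(trial)` (returns the current estimate table), `estimates()`,
#'   `fit()` (last full `bias_posterior` or `NULL`), and fields `n`,
#'   `trials`.
#' @export
online_estimator <- function(prior = bias_prior(), cfg = mcmc_config(),
                             first_fit = 33) {
  est <- new.env(parent = emptyenv())
  est$prior <- prior
  est$cfg <- cfg
  est$first_fit <- first_fit
  est$n <- 0L
  est$last_index <- -Inf
  est$trials <- list()
  est$current <- prior_summary(prior)
  est$last_fit <- NULL
  est$step <- function(trial) {
    idx <- trial$index %||% trial$trial %||% (est$n + 1L)
    if (idx <= est$last_index)
      stop("trials must arrive in schedule order (got index ", idx, ")")
    est$last_index <- idx
    est$n <- est$n + 1L
    est$trials[[est$n]] <- data.frame(condition = trial$condition,
                                      omega = trial$omega,
                                      choice = trial$choice)
    n <- est$n
    if (n >= est$first_fit &&
        (n == est$first_fit ||
         (n - est$first_fit) %% est$cfg$refit_stride == 0)) {
      data <- do.call(rbind, est$trials)
      cfg <- est$cfg
      if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + n
      fit <- fit_posterior(data, est$prior, cfg)
      est$last_fit <- fit
      est$current <- fit$summary[fit$summary$parameter %in% c("PL", "PR", "D"),
                                 c("parameter", "mean", "sd",
                                   "ci68_lo", "ci68_hi")]
      rownames(est$current) <- NULL
    }
    est$current
  }
  est$estimates <- function() est$current
  est$fit <- function() est$last_fit
  class(est) <- "online_estimator"
  est
}

`%||%` <- function(a, b) if (is.null(a)) b else a
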