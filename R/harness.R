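#' Validation scenario
#'
#' Bundles a ground truth, a prior, and the simulation size for the
#' parameter-recovery experiments.
#'
#' @param name label.
#' @param gt a [ground_truth()].
#' @param prior a [bias_prior()] (possibly flat).
#' @param n_simulations number of independent synthetic sessions.
#' @param n_trials trials per session (990 = 30 blocks on the default grid).
#' @param seeds per-simulation seeds; must be distinct.
#' @return A `validation_scenario` list.
#' @export
validation_scenario <- function(name, gt = ground_truth(),
                                prior = flat_prior(),
                                n_simulations = 100, n_trials = 990,
                                seeds = seq_len(n_simulations)) {
  if (anyDuplicated(seeds)) stop("seeds must be distinct per simulation")
  stopifnot(length(seeds) == n_simulations)
  structure(list(name = name, gt = gt, prior = prior,
                 n_simulations = n_simulations, n_trials = n_trials,
                 seeds = seeds),
            class = "validation_scenario")
}

# Refit points of the online estimator under a given stride
refit_points <- function(n_trials, stride, first_fit = 33) {
  seq(first_fit, n_trials, by = stride)
}

#' RMSE and SD curves of online bias estimates
#'
#' For each simulated session, fits the model on growing trial prefixes
#' at the online estimator's refit points (trial 33, then every
#' `cfg$refit_stride` trials) and records the posterior-mean estimates of
#' `PL`, `PR`, `D`.  Across simulations it returns, per refit point,
#' \deqn{RMSE(t) = \sqrt{\mathrm{mean}_s\,(\hat\theta_{s,t} - \theta^*)^2}}
#' and the across-simulation SD of the estimates.  No smoothing applied.
#'
#' @param scenario a [validation_scenario()].
#' @param cfg an [mcmc_config()]; its `refit_stride` sets the curve's
#'   resolution and its seed offsets the per-fit seeds.
#' @param max_trial last refit point (default the full session).
#' @return Data frame with columns `trial`, `parameter`, `rmse`, `sd`,
#'   `mean_est`, of class `rmse_curves`.
#' @export
rmse_sd_curves <- function(scenario, cfg = mcmc_config(n_samples = 2000,
                                                       burn_in = 1000,
                                                       refit_stride = 10),
                           max_trial = scenario$n_trials) {
  pts <- refit_points(max_trial, cfg$refit_stride)
  truth <- c(PL = scenario$gt$biases$PL, PR = scenario$gt$biases$PR,
             D = scenario$gt$biases$D)
  est <- array(NA_real_, c(scenario$n_simulations, length(pts), 3),
               dimnames = list(NULL, pts, names(truth)))
  for (s in seq_len(scenario$n_simulations)) {
    session <- generate_session(scenario$gt, seed = scenario$seeds[s])
    for (i in seq_along(pts)) {
      fit_cfg <- cfg
      fit_cfg$seed <- (cfg$seed %||% 0) + scenario$seeds[s] * 1000 + pts[i]
      fit <- fit_posterior(session[seq_len(pts[i]), ], scenario$prior, fit_cfg)
      est[s, i, ] <- colMeans(fit$draws[, names(truth)])
    }
  }
  rows <- expand.grid(trial = pts, parameter = names(truth),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$rmse <- mapply(function(t, p)
    sqrt(mean((est[, as.character(t), p] - truth[[p]])^2)),
    rows$trial, rows$parameter)
  rows$sd <- mapply(function(t, p) sd(est[, as.character(t), p]),
                    rows$trial, rows$parameter)
  rows$mean_est <- mapply(function(t, p) mean(est[, as.character(t), p]),
                          rows$trial, rows$parameter)
  class(rows) <- c("rmse_curves", "data.frame")
  rows
}

#' Prior-width sweep: bias-variance tradeoff of mismatched priors
#'
#' With prior means held fixed away from the ground truth, narrow
#' (overconfident) priors give low-variability estimates biased toward
#' the prior, while wide (underconfident) priors give less biased but
#' more variable estimates.  Estimates are the posterior means after
#' `n_trials` trials; spread is measured across repetitions.
#'
#' @param widths prior SDs (degrees) applied to all three bias priors.
#' @param gt ground truth (default PL = 20, PR = -20, D = 10).
#' @param prior_means means of the (mismatched) priors for PL, PR, D.
#' @param n_trials trials per simulated session prefix.
#' @param n_reps repetitions per width.
#' @param cfg an [mcmc_config()].
#' @param seed master seed.
#' @return Data frame: `width`, `parameter`, `mean`, `sd` (across reps),
#'   `abs_error` (|mean - truth|).
#' @export
prior_width_sweep <- function(widths = c(1, 2, 4, 8, 16, 32),
                              gt = ground_truth(bias_set(20, -20, 10)),
                              prior_means = c(PL = 10, PR = -10, D = 0),
                              n_trials = 100, n_reps = 20,
                              cfg = mcmc_config(n_samples = 2000,
                                                burn_in = 1000),
                              seed = 1) {
  stopifnot(all(widths > 0))
  truth <- c(PL = gt$biases$PL, PR = gt$biases$PR, D = gt$biases$D)
  grid <- stimulus_grid(n_blocks = ceiling(n_trials / 33))
  out <- list()
  for (w in widths) {
    prior <- bias_prior(P0L = prior_means[["PL"]], tauPL = w,
                        P0R = prior_means[["PR"]], tauPR = w,
                        D0 = prior_means[["D"]], tauD = w)
    est <- matrix(NA_real_, n_reps, 3, dimnames = list(NULL, names(truth)))
    for (r in seq_len(n_reps)) {
      session <- generate_session(gt, schedule = make_schedule(grid),
                                  seed = seed * 10000 + r)
      fit_cfg <- cfg
      fit_cfg$seed <- seed * 10000 + r + round(w * 100)
      fit <- fit_posterior(session[seq_len(n_trials), ], prior, fit_cfg)
      est[r, ] <- colMeans(fit$draws[, names(truth)])
    }
    out[[length(out) + 1L]] <-
      data.frame(width = w, parameter = names(truth),
                 mean = colMeans(est), sd = apply(est, 2, sd),
                 abs_error = abs(colMeans(est) - truth),
                 row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Compare reward strategies with the RL agent
#'
#' Runs [run_rl_experiment()] once per policy on a shared seed set and
#' tabulates per-session mean and SD of the empirical biases and
#' criteria per condition.
#'
#' @param policies character vector of policy kinds.
#' @param n_repeats,n_sessions,grid,agent,seed passed through.
#' @param ... further arguments for [run_rl_experiment()] (e.g. the
#'   estimated policy's estimator settings).
#' @return Data frame: `policy`, `session`, `condition`, `bias_mean`,
#'   `bias_sd`, `psi_mean`, `psi_sd`.
#' @export
strategy_comparison <- function(policies = c("veridical", "random_ambiguous",
                                             "oracle"),
                                n_repeats = 10, n_sessions = 50,
                                grid = stimulus_grid(),
                                agent = agent_state(), seed = 1, ...) {
  out <- lapply(policies, function(pol) {
    ex <- run_rl_experiment(pol, n_repeats = n_repeats,
                            n_sessions = n_sessions, grid = grid,
                            agent = agent, seed = seed, ...)
    cbind(policy = pol, ex$summary)
  })
  do.call(rbind, out)
}

#' Serialize posterior summaries as JSON
#'
#' Parameter-keyed objects `{mean, sd, ci68_lo, ci68_hi}`, matching the
#' package's external interface; conventional fits carry a
#' `"method": "conventional"` tag.
#'
#' @param fit a `bias_posterior` or `conventional_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(fit, path) {
  tab <- if (inherits(fit, "conventional_fit")) fit$recovered else fit$summary
  obj <- lapply(seq_len(nrow(tab)), function(i)
    list(mean = tab$mean[i], sd = tab$sd[i],
         ci68_lo = tab$ci68_lo[i], ci68_hi = tab$ci68_hi[i]))
  names(obj) <- tab$parameter
  if (inherits(fit, "conventional_fit")) obj$method <- "conventional"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
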