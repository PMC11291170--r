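#' Reinforcement-learning observer state
#'
#' A noisy biased observer with one decision criterion per context,
#' updated by a temporal-difference rule.  On each trial the agent draws
#' a percept `omega_hat ~ N(omega - P_k, Sigma_k)`, makes the
#' maximum-a-posteriori choice relative to its criterion `psi_k`, and
#' nudges the criterion by the reward prediction error:
#' `psi_k <- psi_k - alpha_lr * C * (r - q)`.
#'
#' @param psi per-condition decision criteria, degrees (start unbiased).
#' @param alpha_lr learning rate, degrees per trial.
#' @param Sigma per-condition sensory noise SD, degrees.
#' @param P per-condition perceptual biases of the agent, degrees.  The
#'   default reproduces ground-truth empirical biases of +20 / 0 / -10
#'   when the criteria are at zero.
#' @return An object of class `agent_state`.
#' @export
agent_state <- function(psi = c(L = 0, N = 0, R = 0),
                        alpha_lr = 0.04,
                        Sigma = c(L = 16, N = 16, R = 16),
                        P = c(L = 20, N = 0, R = -10)) {
  psi <- rep_len(psi, 3); Sigma <- rep_len(Sigma, 3); P <- rep_len(P, 3)
  names(psi) <- names(Sigma) <- names(P) <- CONDITIONS
  if (any(Sigma <= 0)) stop("sensory noise must be positive")
  if (alpha_lr < 0) stop("learning rate must be nonnegative")
  structure(list(psi = psi, alpha_lr = alpha_lr, Sigma = Sigma, P = P),
            class = "agent_state")
}

#' Noisy biased observation
#'
#' @param omega stimulus direction, degrees.
#' @param condition context label.
#' @param state an [agent_state()].
#' @return A percept drawn from `N(omega - P_k, Sigma_k)`.
#' @export
observe <- function(omega, condition, state) {
  k <- cond_index(condition)
  rnorm(length(omega), omega - state$P[k], state$Sigma[k])
}

#' MAP choice and predicted reward probability
#'
#' `Phi = pnorm((omega_hat - psi) / Sigma)`; choose right when the
#' percept exceeds the criterion (ties go right with `q = 0.5`), and
#' predict reward with probability `q = max(Phi, 1 - Phi)`.
#'
#' @param omega_hat percept, degrees.
#' @param psi decision criterion, degrees.
#' @param Sigma sensory noise SD, degrees.
#' @return List with `choice` (+1/-1) and `q`.
#' @export
choose <- function(omega_hat, psi, Sigma) {
  stopifnot(Sigma > 0)
  Phi <- pnorm((omega_hat - psi) / Sigma)
  choice <- if (omega_hat >= psi) 1L else -1L
  q <- max(Phi, 1 - Phi)
  if (omega_hat == psi) q <- 0.5
  list(choice = choice, q = q)
}

#' Temporal-difference criterion update
#'
#' @param state an [agent_state()].
#' @param condition context label.
#' @param choice +1 or -1.
#' @param r reward indicator, 0 or 1.
#' @param q predicted reward probability in `[0.5, 1]`.
#' @return The updated `agent_state`.
#' @export
update_criterion <- function(state, condition, choice, r, q) {
  stopifnot(r %in% c(0, 1), q >= 0.5, q <= 1, choice %in% c(-1L, 1L))
  k <- cond_index(condition)
  state$psi[k] <- state$psi[k] - state$alpha_lr * choice * (r - q)
  state
}

# Closed-form policies handled by the fast C++ session loop
.rl_policy_codes <- c(veridical = 0L, oracle = 1L, random_ambiguous = 2L,
                      always_ambiguous = 3L, never_ambiguous = 4L)

#' Simulate RL training experiments under a reward strategy
#'
#' Runs `n_repeats` independent synthetic training experiments of
#' `n_sessions` block-randomized sessions each.  Decision criteria
#' persist across sessions within a repeat.  After each session, the
#' per-condition empirical bias is estimated by lapse-free probit
#' maximum likelihood on that session's trials.
#'
#' For the `estimated` policy, each session attaches a fresh online
#' estimator (prior `est_prior`) whose posterior-mean perceptual biases
#' drive a clamped reward boundary, as in real training.
#'
#' @param policy a policy name (see [reward_policy()]) or a
#'   `reward_policy` object whose `kind` is used.
#' @param n_repeats,n_sessions simulation size (defaults 10 and 50).
#' @param grid a [stimulus_grid()] for each session.
#' @param agent an [agent_state()]; the oracle policy rewards at this
#'   agent's true perceptual biases.
#' @param seed master seed; repeat `i` uses `seed + i`.
#' @param est_prior,est_cfg,clamp_step settings for the estimated policy.
#' @return An object of class `rl_experiment`: a list with `results`
#'   (data frame: rep, session, condition, psi_end, empirical_bias),
#'   `summary` (mean and SD across repeats), and the configuration.
#' @export
run_rl_experiment <- function(policy = "veridical", n_repeats = 10,
                              n_sessions = 50, grid = stimulus_grid(),
                              agent = agent_state(), seed = NULL,
                              est_prior = bias_prior(tauPL = 10, tauPR = 10,
                                                     tauD = 10),
                              est_cfg = mcmc_config(n_samples = 1500,
                                                    burn_in = 750,
                                                    refit_stride = 10),
                              clamp_step = 1) {
  kind <- if (inherits(policy, "reward_policy")) policy$kind else policy
  rows <- list()
  for (rep_i in seq_len(n_repeats)) {
    psi <- agent$psi
    for (sess in seq_len(n_sessions)) {
      # per-session reseed: schedules and (pre-drawn) percept noise are
      # then shared across policies run with the same master seed, so
      # policy comparisons use common random numbers
      if (!is.null(seed)) set.seed(seed + rep_i * 100000L + sess)
      sched <- make_schedule(grid)
      if (kind %in% names(.rl_policy_codes)) {
        res <- rl_session_cpp(sched$omega, cond_index(sched$condition) - 1L,
                              psi, agent$P, agent$Sigma, agent$alpha_lr,
                              .rl_policy_codes[[kind]], agent$P)
        psi <- res$psi_end
        choice <- res$choice
      } else if (kind == "estimated") {
        res <- rl_session_estimated(sched, psi, agent, est_prior, est_cfg,
                                    clamp_step)
        psi <- res$psi_end
        choice <- res$choice
      } else stop("unknown policy kind: ", kind)
      names(psi) <- CONDITIONS
      for (k in CONDITIONS) {
        sel <- sched$condition == k
        eb <- probit_mle(sched$omega[sel], choice[sel])$B
        rows[[length(rows) + 1L]] <-
          data.frame(rep = rep_i, session = sess, condition = k,
                     psi_end = psi[[k]], empirical_bias = eb)
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(empirical_bias, psi_end) ~ session + condition,
                          results, function(x) c(mean = mean(x), sd = sd(x)))
  summary <- data.frame(session = agg$session, condition = agg$condition,
                        bias_mean = agg$empirical_bias[, "mean"],
                        bias_sd = agg$empirical_bias[, "sd"],
                        psi_mean = agg$psi_end[, "mean"],
                        psi_sd = agg$psi_end[, "sd"])
  structure(list(results = results, summary = summary, policy = kind,
                 n_repeats = n_repeats, n_sessions = n_sessions,
                 agent = agent),
            class = "rl_experiment")
}

# One session with the estimated policy: agent loop in R with an online
# estimator updating the clamped reward boundary.
rl_session_estimated <- function(sched, psi, agent, est_prior, est_cfg,
                                 clamp_step) {
  estimator <- online_estimator(est_prior, est_cfg)
  state <- boundary_state(clamp_step = clamp_step)
  n <- nrow(sched)
  choice <- integer(n)
  for (t in seq_len(n)) {
    k <- sched$condition[t]
    ki <- cond_index(k)
    omh <- rnorm(1, sched$omega[t] - agent$P[ki], agent$Sigma[ki])
    ch <- choose(omh, psi[ki], agent$Sigma[ki])
    if (k == "N") {
      b <- 0
    } else {
      est <- estimator$estimates()
      target <- est$mean[match(paste0("P", k), est$parameter)]
      state <- update_boundary(state, k, target)
      b <- state$boundary[[k]]
    }
    r <- as.integer(allocate_reward(list(choice = ch$choice,
                                         omega = sched$omega[t]), b))
    psi[ki] <- psi[ki] - agent$alpha_lr * ch$choice * (r - ch$q)
    choice[t] <- ch$choice
    estimator$step(list(index = t, condition = k, omega = sched$omega[t],
                        choice = ch$choice))
  }
  list(psi_end = psi, choice = choice, boundary = state$boundary)
}

#' Lapse-free probit maximum-likelihood psychometric fit
#'
#' Maximises the Bernoulli likelihood of `P(right) = Phi((omega - B)/S)`
#' over `(B, log S)` by Nelder-Mead.  Used as the per-session empirical
#' bias estimator for the RL simulations.
#'
#' @param omega stimulus directions, degrees.
#' @param choice choices coded +1/-1 (or 1/0).
#' @return List with `B`, `S`, and the maximised `loglik`; `B` is `NA`
#'   when all choices are identical (the MLE diverges).
#' @export
probit_mle <- function(omega, choice) {
  y <- as.integer(choice == 1 | choice == 1L)
  if (all(y == 1) || all(y == 0))
    return(list(B = NA_real_, S = NA_real_, loglik = NA_real_))
  nll <- function(par) {
    p <- pnorm((omega - par[1]) / exp(par[2]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log1p(-p))
  }
  # crossing-based initial guess for B
  ag <- stats::aggregate(y, list(omega = omega), mean)
  B0 <- {
    above <- ag$x >= 0.5
    if (all(above)) min(ag$omega) else if (!any(above)) max(ag$omega)
    else stats::approx(ag$x, ag$omega, xout = 0.5, ties = mean)$y
  }
  if (!is.finite(B0)) B0 <- 0
  fit <- optim(c(B0, log(16)), nll, method = "Nelder-Mead",
               control = list(maxit = 500))
  list(B = fit$par[1], S = exp(fit$par[2]), loglik = -fit$value)
}
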