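test_that("extremely narrow priors dominate a short session", {
  pr <- bias_prior(P0L = 20, tauPL = 0.01, P0R = -10, tauPR = 0.01,
                   D0 = 10, tauD = 0.01)
  s <- generate_session(ground_truth(),
                        schedule = make_schedule(stimulus_grid(n_blocks = 1),
                                                 seed = 1), seed = 1)
  fit <- fit_posterior(s, pr, mcmc_config(2000, 1000, seed = 2))
  sm <- fit$summary
  expect_lt(abs(sm$mean[sm$parameter == "PL"] - 20), 0.1)
  expect_lt(abs(sm$mean[sm$parameter == "PR"] - (-10)), 0.1)
  expect_lt(abs(sm$mean[sm$parameter == "D"] - 10), 0.1)
})

test_that("flat-prior posterior agrees with the probit-MLE oracle", {
  s <- generate_session(ground_truth(), seed = 3)
  fit <- fit_posterior(s, flat_prior(), mcmc_config(2000, 1000, seed = 4))
  # posterior mean of B_L within the 95% CI of the leftward-condition MLE
  sel <- s$condition == "L"
  ci <- probit_mle_ci(s$omega[sel], s$choice[sel])
  bl <- mean(fit$draws[, "BL"])
  expect_gt(bl, ci[["lo"]])
  expect_lt(bl, ci[["hi"]])
})

test_that("posterior summaries use mean/SD and 16th-84th percentiles", {
  const <- matrix(5, 100, 1, dimnames = list(NULL, "c"))
  sm <- posterior_summary(const)
  expect_equal(sm$mean, 5)
  expect_equal(sm$sd, 0)
  expect_equal(sm$ci68_lo, 5)
  expect_equal(sm$ci68_hi, 5)
  set.seed(7)
  z <- matrix(rnorm(1e5), ncol = 1, dimnames = list(NULL, "z"))
  smz <- posterior_summary(z)
  expect_equal(smz$ci68_lo, qnorm(0.16), tolerance = 0.02)
  expect_equal(smz$ci68_hi, qnorm(0.84), tolerance = 0.02)
  expect_error(posterior_summary(matrix(numeric(0), 0, 1)), "no draws")
  # linearity of the derived empirical-bias draws
  s <- generate_session(ground_truth(),
                        schedule = make_schedule(stimulus_grid(n_blocks = 3),
                                                 seed = 8), seed = 8)
  fit <- fit_posterior(s, flat_prior(), cfg_small(seed = 9))
  expect_equal(mean(fit$draws[, "BL"]),
               mean(fit$draws[, "PL"]) + mean(fit$draws[, "D"]))
})

test_that("online estimator reports the prior before trial 33 and refits after", {
  pr <- bias_prior(P0L = -10, tauPL = 7, P0R = 10, tauPR = 7, D0 = 0, tauD = 5)
  est <- online_estimator(pr, cfg_small(seed = 1, stride = 10))
  s <- generate_session(ground_truth(),
                        schedule = make_schedule(stimulus_grid(n_blocks = 2),
                                                 seed = 10), seed = 10)
  for (t in 1:10) {
    cur <- est$step(list(index = t, condition = s$condition[t],
                         omega = s$omega[t], choice = s$choice[t]))
  }
  expect_equal(cur$mean[cur$parameter == "PL"], -10)  # exactly the prior mean
  expect_equal(cur$sd[cur$parameter == "PL"], 7)
  expect_error(est$step(list(index = 3, condition = "N", omega = 0,
                             choice = 1L)), "order")
  for (t in 11:33) {
    cur <- est$step(list(index = t, condition = s$condition[t],
                         omega = s$omega[t], choice = s$choice[t]))
  }
  # trial 33 triggered the first refit: estimates are now posterior summaries
  expect_false(isTRUE(all.equal(cur$mean[cur$parameter == "PL"], -10)))
  expect_false(is.null(est$fit()))
  expect_equal(est$fit()$n_trials, 33)
  # held constant between refits
  cur34 <- est$step(list(index = 34, condition = s$condition[34],
                         omega = s$omega[34], choice = s$choice[34]))
  expect_identical(cur34, cur)
})

test_that("posterior contracts as trials accumulate", {
  wins <- 0
  for (i in 1:10) {
    s <- generate_session(ground_truth(), seed = 100 + i)
    f100 <- fit_posterior(s[1:100, ], flat_prior(), cfg_small(seed = 200 + i))
    f900 <- fit_posterior(s[1:900, ], flat_prior(), cfg_small(seed = 300 + i))
    wins <- wins + (sd(f900$draws[, "PL"]) < sd(f100$draws[, "PL"]))
  }
  expect_gte(wins, 9)
})

test_that("flat-prior estimates converge to ground truth at large n", {
  grid <- stimulus_grid(n_blocks = 91)  # 3003 trials
  est <- t(sapply(1:10, function(i) {
    s <- generate_session(ground_truth(),
                          schedule = make_schedule(grid, seed = 400 + i),
                          seed = 400 + i)
    f <- fit_posterior(s, flat_prior(), cfg_small(seed = 500 + i))
    colMeans(f$draws[, c("PL", "PR", "D")])
  }))
  bias <- colMeans(est) - fig5a_truth
  expect_true(all(abs(bias) < 2))
})

test_that("informative priors shrink estimates toward the prior mean", {
  # prior centered at 0, truth PL = 20: posterior mean should lie between
  # the prior mean and the flat-prior estimate (majority over seeds)
  pr <- bias_prior(P0L = 0, tauPL = 10, P0R = 0, tauPR = 10, D0 = 0, tauD = 10)
  between <- 0
  for (i in 1:10) {
    s <- generate_session(ground_truth(), seed = 600 + i)[1:150, ]
    fi <- fit_posterior(s, pr, cfg_small(seed = 700 + i))
    ff <- fit_posterior(s, flat_prior(), cfg_small(seed = 700 + i))
    m_inf <- mean(fi$draws[, "PL"])
    m_flat <- mean(ff$draws[, "PL"])
    between <- between + (m_inf > min(0, m_flat) && m_inf < max(0, m_flat))
  }
  expect_gte(between, 6)
})

test_that("convergence diagnostics are reported but do not alter results", {
  s <- generate_session(ground_truth(),
                        schedule = make_schedule(stimulus_grid(n_blocks = 3),
                                                 seed = 20), seed = 20)
  fit <- fit_posterior(s, flat_prior(), cfg_small(seed = 21))
  expect_named(fit$diagnostics$rhat, c("PL", "PR", "D"))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_type(fit$diagnostics$converged, "logical")
})
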