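test_that("allocate_reward follows the boundary rule", {
  expect_true(allocate_reward(list(choice = -1L, omega = -5), boundary = 0))
  expect_false(allocate_reward(list(choice = 1L, omega = -5), boundary = 0))
  expect_true(allocate_reward(list(choice = 1L, omega = 12), boundary = 10))
  expect_false(allocate_reward(list(choice = -1L, omega = 12), boundary = 10))
  # exact tie is rewarded with probability 1/2
  set.seed(1)
  ties <- replicate(2000, allocate_reward(list(choice = 1L, omega = 3),
                                          boundary = 3))
  expect_lt(abs(mean(ties) - 0.5), 4 * sqrt(0.25 / 2000))
})

test_that("boundary updates are clamped per trial", {
  st <- boundary_state(clamp_step = 1)
  st <- update_boundary(st, "L", 0.4)
  expect_equal(st$boundary[["L"]], 0.4)       # within clamp: lands exactly
  st <- boundary_state(clamp_step = 1)
  st <- update_boundary(st, "L", 5)
  expect_equal(st$boundary[["L"]], 1)         # clamped to 1 deg
  # repeated updates converge in ceiling(|delta|/clamp) steps
  st <- boundary_state(clamp_step = 1)
  target <- -7.3
  steps <- 0
  while (st$boundary[["L"]] != target && steps < 50) {
    st <- update_boundary(st, "L", target)
    steps <- steps + 1
  }
  expect_equal(steps, ceiling(abs(target) / 1))
  expect_error(update_boundary(boundary_state(), "N", 1), "neutral")
})

test_that("strategy_reward implements the six policies", {
  gt <- bias_set(PL = 20, PR = -10, D = 10)
  ver <- reward_policy("veridical")
  expect_true(strategy_reward(list(condition = "N", omega = 3, choice = 1L),
                              ver)$reward)
  orc <- reward_policy("oracle", ground_truth = gt)
  # leftward trial at omega = 15 < P_L = 20: left is correct re the percept
  expect_true(strategy_reward(list(condition = "L", omega = 15, choice = -1L),
                              orc)$reward)
  expect_false(strategy_reward(list(condition = "L", omega = 15, choice = 1L),
                               orc)$reward)
  # ambiguous-trial policies: random is Bernoulli(1/2) inside the interval
  rnd <- reward_policy("random_ambiguous", ground_truth = gt)
  set.seed(2)
  rr <- replicate(2000, strategy_reward(list(condition = "L", omega = 15,
                                             choice = 1L), rnd)$reward)
  expect_lt(abs(mean(rr) - 0.5), 4 * sqrt(0.25 / 2000))
  expect_error(reward_policy("oracle"), "ground-truth")
  expect_error(reward_policy("estimated"), "estimator")
})

test_that("ambiguous policies agree with veridical outside the interval", {
  gt <- bias_set(PL = 20, PR = -10, D = 10)
  pols <- lapply(c("always_ambiguous", "never_ambiguous"), reward_policy,
                 ground_truth = gt)
  ver <- reward_policy("veridical")
  set.seed(3)
  for (i in 1:200) {
    k <- sample(c("L", "N", "R"), 1)
    omega <- runif(1, -40, 40)
    Pk <- switch(k, L = 20, R = -10, N = 0)
    inside <- omega > min(0, Pk) && omega < max(0, Pk)
    if (inside || omega == 0) next       # ties consume RNG; skip them
    trial <- list(condition = k, omega = omega,
                  choice = sample(c(-1L, 1L), 1))
    expected <- strategy_reward(trial, ver)$reward
    for (p in pols) expect_identical(strategy_reward(trial, p)$reward, expected)
  }
})

test_that("the estimated policy's boundary obeys the clamp trajectory-wide", {
  est <- online_estimator(bias_prior(P0L = 0, tauPL = 10, P0R = 0,
                                     tauPR = 10, D0 = 0, tauD = 10),
                          mcmc_config(600, 300, seed = 4, refit_stride = 20))
  pol <- reward_policy("estimated", estimator = est, clamp_step = 1)
  s <- generate_session(ground_truth(),
                        schedule = make_schedule(stimulus_grid(n_blocks = 6),
                                                 seed = 5), seed = 5)
  traj <- list(L = numeric(), R = numeric())
  for (t in seq_len(nrow(s))) {
    rw <- strategy_reward(list(condition = s$condition[t], omega = s$omega[t],
                               choice = s$choice[t]), pol)
    est$step(list(index = t, condition = s$condition[t], omega = s$omega[t],
                  choice = s$choice[t]))
    k <- s$condition[t]
    if (k != "N") traj[[k]] <- c(traj[[k]], rw$boundary)
  }
  for (k in c("L", "R")) expect_true(all(abs(diff(traj[[k]])) <= 1 + 1e-12))
  # and the boundary actually moved toward the leftward perceptual bias
  expect_gt(tail(traj$L, 1), 5)
})

test_that("oracle rewards are maximized by responding at the perceptual bias", {
  # expected reward rate of a fixed criterion psi (percept space), stimuli
  # symmetric around the oracle boundary P, by numerical quadrature
  P <- 20; Sigma <- 16
  omegas <- P + seq(-40, 40, by = 8)
  exp_reward <- function(psi) {
    mean(vapply(omegas, function(om) {
      p_right <- pnorm((om - P - psi) / Sigma)
      if (om > P) p_right else if (om < P) 1 - p_right else 0.5
    }, numeric(1)))
  }
  grid <- seq(-10, 10, by = 0.5)
  vals <- vapply(grid, exp_reward, numeric(1))
  expect_equal(grid[which.max(vals)], 0)
  expect_lt(max(vals) - exp_reward(0), 1e-12)
  # package path: Monte-Carlo reward rate through observe/choose/
  # strategy_reward, unbiased criterion vs offset criteria
  orc <- reward_policy("oracle", ground_truth = bias_set(20, -10, 10))
  state <- agent_state()
  mc_rate <- function(psi, n = 6000) {
    set.seed(6)
    om <- sample(omegas, n, replace = TRUE)
    mean(vapply(seq_len(n), function(i) {
      omh <- observe(om[i], "L", state)
      ch <- choose(omh, psi, 16)
      strategy_reward(list(condition = "L", omega = om[i],
                           choice = ch$choice), orc)$reward
    }, logical(1)))
  }
  expect_gt(mc_rate(0), mc_rate(-6))
  expect_gt(mc_rate(0), mc_rate(6))
})
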