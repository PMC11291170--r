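test_that("block-randomized schedules have the stated arithmetic", {
  sched <- make_schedule(stimulus_grid(), seed = 1)
  expect_equal(nrow(sched), 990)       # 30 x 11 x 3
  one <- make_schedule(stimulus_grid(n_blocks = 1), seed = 1)
  expect_equal(nrow(one), 33)
  expect_equal(nrow(unique(one[, c("condition", "omega")])), 33)
  # every (direction, condition) pair occurs exactly n_blocks times,
  # and exactly once within each block
  counts <- table(sched$condition, sched$omega)
  expect_true(all(counts == 30))
  per_block <- tapply(seq_len(990), sched$block, function(i)
    nrow(unique(sched[i, c("condition", "omega")])))
  expect_true(all(per_block == 33))
})

test_that("schedules are seed-deterministic", {
  a <- make_schedule(stimulus_grid(), seed = 5)
  b <- make_schedule(stimulus_grid(), seed = 5)
  c <- make_schedule(stimulus_grid(), seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_error(make_schedule(stimulus_grid(directions = numeric())),
               "at least one")
})

test_that("bias dynamics evaluate their stated forms", {
  sin_dyn <- decision_dynamics("sinusoid", amplitude = 10, period = 2000)
  expect_equal(decision_bias_at(0, sin_dyn), 0)
  expect_equal(decision_bias_at(1000, sin_dyn), 10)
  expect_equal(decision_bias_at(123, decision_dynamics("stationary", D = 10)),
               10)
  # piecewise across-session perceptual trajectory
  expect_equal(perceptual_bias_at(c(0, 7, 100), P0 = 20, s = 1), rep(20, 3))
  expect_equal(perceptual_bias_at(50, P0 = 20, s = 3, tb1 = 11, tb2 = 41),
               20 / 3)
  expect_equal(perceptual_bias_at(26, P0 = 20, s = 3, tb1 = 11, tb2 = 41),
               20 - (2 / 3) * 20 * 0.5)  # midpoint of the ramp
  # continuity at the breakpoints
  expect_equal(perceptual_bias_at(11 + 1e-9, 20, 3, 11, 41),
               perceptual_bias_at(11, 20, 3, 11, 41), tolerance = 1e-6)
  expect_error(perceptual_bias_at(1, 20, 3, tb1 = 5, tb2 = 5), "smaller")
})

test_that("generated choices follow the generative model", {
  # degenerate probit: choices equal sign(omega - B_k)
  gt0 <- ground_truth(S = 1e-9)
  s <- generate_session(gt0, schedule = make_schedule(stimulus_grid(n_blocks = 2),
                                                      seed = 3), seed = 3)
  ki <- match(s$condition, c("L", "N", "R"))
  Bk <- c(30, 10, 0)[ki]
  off <- s$omega != Bk
  expect_identical(s$choice[off], ifelse(s$omega[off] > Bk[off], 1L, -1L))

  # empirical frequencies converge to choice_probability (4 SE at 300 blocks)
  gt <- ground_truth()
  big <- generate_session(gt, schedule = make_schedule(stimulus_grid(n_blocks = 300),
                                                       seed = 4), seed = 4)
  sel <- big$condition == "L" & big$omega == 16
  theta <- choice_probability(16, psy_params(B = 30, S = 15))
  se <- sqrt(theta * (1 - theta) / sum(sel))
  expect_lt(abs(mean(big$choice[sel] == 1) - theta), 4 * se)

  # seed determinism, byte for byte
  s1 <- generate_session(gt, seed = 12)
  s2 <- generate_session(gt, seed = 12)
  expect_identical(s1, s2)
})

test_that("per-condition probit MLE recovers the generating biases", {
  s <- generate_session(ground_truth(), seed = 42)
  for (k in c("L", "N", "R")) {
    sel <- s$condition == k
    truth <- c(L = 30, N = 10, R = 0)[[k]]
    ci <- probit_mle_ci(s$omega[sel], s$choice[sel])
    expect_gt(truth, ci[["lo"]])
    expect_lt(truth, ci[["hi"]])
  }
})

test_that("serial dependence follows win-stay/lose-shift", {
  expect_error(generate_session(ground_truth(Tse = 1), seed = 1),
               "reward policy")
  # leftward-context trials with a huge perceptual bias make every
  # positive stimulus ambiguous, so always/never policies reward all/none
  grid <- stimulus_grid(directions = seq(8, 40, 8), conditions = "L",
                        n_blocks = 5)
  gt <- ground_truth(bias_set(PL = 1e6, PR = -10, D = 10), Tse = 1)
  pol_win <- reward_policy("always_ambiguous",
                           ground_truth = bias_set(1e6, -10, 10))
  s <- generate_session(gt, schedule = make_schedule(grid, seed = 5),
                        seed = 5, policy = pol_win)
  expect_true(all(s$rewarded))
  expect_true(all(s$choice == s$choice[1]))  # pure win-stay
  pol_lose <- reward_policy("never_ambiguous",
                            ground_truth = bias_set(1e6, -10, 10))
  s2 <- generate_session(gt, schedule = make_schedule(grid, seed = 6),
                         seed = 6, policy = pol_lose)
  expect_false(any(s2$rewarded))
  expect_true(all(diff(s2$choice) != 0))     # pure lose-shift alternation
})

test_that("session CSV round-trips", {
  s <- generate_session(ground_truth(),
                        schedule = make_schedule(stimulus_grid(n_blocks = 1),
                                                 seed = 9), seed = 9)
  path <- tempfile(fileext = ".csv")
  write_session_csv(s, path)
  r <- read_session_csv(path)
  expect_equal(r$omega, s$omega)
  expect_equal(r$choice, s$choice)
  expect_equal(r$condition, s$condition)
})
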