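#' Stimulus grid for a block-randomized 2AFC session
#'
#' The default grid is the motion-direction discrimination design: 11
#' directions from -40 to +40 deg in steps of 8, crossed with three
#' interleaved self-motion contexts, giving 33 unique stimuli per block.
#'
#' @param directions stimulus directions in degrees.
#' @param conditions context labels; a subset of `c("L", "N", "R")`.
#' @param n_blocks number of blocks; each block presents every
#'   (direction, condition) pair exactly once in random order.
#' @return An object of class `stimulus_grid`.
#' @export
stimulus_grid <- function(directions = seq(-40, 40, by = 8),
                          conditions = c("L", "N", "R"),
                          n_blocks = 30) {
  if (length(directions) == 0 || length(conditions) == 0)
    stop("stimulus grid must contain at least one direction and condition")
  stopifnot(all(conditions %in% CONDITIONS), n_blocks >= 1)
  structure(list(directions = directions, conditions = conditions,
                 n_blocks = as.integer(n_blocks)),
            class = "stimulus_grid")
}

#' Block-randomized trial schedule
#'
#' Each block is an independent random permutation of all unique
#' (condition, direction) pairs, so every stimulus is shown once before
#' any is repeated.
#'
#' @param grid a [stimulus_grid()].
#' @param seed integer seed for the permutation RNG.
#' @return Data frame with columns `block`, `condition`, `omega`.
#' @examples
#' nrow(make_schedule(stimulus_grid(), seed = 1))  # 990
#' @export
make_schedule <- function(grid, seed = NULL) {
  stopifnot(inherits(grid, "stimulus_grid"))
  if (!is.null(seed)) set.seed(seed)
  pairs <- expand.grid(condition = grid$conditions, omega = grid$directions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- nrow(pairs)
  idx <- unlist(lapply(seq_len(grid$n_blocks), function(b) sample.int(m)))
  out <- pairs[idx, , drop = FALSE]
  out$block <- rep(seq_len(grid$n_blocks), each = m)
  rownames(out) <- NULL
  out[, c("block", "condition", "omega")]
}

#' Within-session decision-bias dynamics
#'
#' `decision_dynamics("stationary", D = 10)` keeps the decision bias
#' constant; `decision_dynamics("sinusoid", amplitude = 10, period = 2000)`
#' makes it drift as `amplitude * sin(pi * n / period)` with `n` the trial
#' number, emulating slow non-stationarity within a session.
#'
#' @param mode `"stationary"` or `"sinusoid"`.
#' @param D constant decision bias (stationary mode), degrees.
#' @param amplitude,period sinusoid parameters (degrees; trials).
#' @return A `decision_dynamics` list.
#' @export
decision_dynamics <- function(mode = c("stationary", "sinusoid"),
                              D = 10, amplitude = 10, period = 2000) {
  mode <- match.arg(mode)
  structure(list(mode = mode, D = D, amplitude = amplitude, period = period),
            class = "decision_dynamics")
}

#' Decision bias at a given trial index
#'
#' @param n trial index (>= 0).
#' @param dynamics a [decision_dynamics()] object.
#' @return Decision bias in degrees; vectorized over `n`.
#' @export
decision_bias_at <- function(n, dynamics) {
  stopifnot(inherits(dynamics, "decision_dynamics"), all(n >= 0))
  if (dynamics$mode == "stationary") rep(dynamics$D, length(n))
  else dynamics$amplitude * sin(pi * n / dynamics$period)
}

#' Piecewise across-session perceptual-bias trajectory
#'
#' Models a perceptual bias that starts at `P0`, declines linearly between
#' breakpoints `tb1` and `tb2` (in session units by default), and settles
#' at `P0 / s`.  Continuous at both breakpoints.
#'
#' @param t session (or trial) index; vectorized.
#' @param P0 initial bias, degrees.
#' @param s steepness factor, `>= 1`; `s = 1` means no change.
#' @param tb1,tb2 start and end of the change period; `tb1 < tb2`.
#' @return Bias in degrees at each `t`.
#' @examples
#' perceptual_bias_at(50, P0 = 20, s = 3, tb1 = 11, tb2 = 41)  # 20/3
#' @export
perceptual_bias_at <- function(t, P0, s = 3, tb1 = 11, tb2 = 41) {
  if (tb1 >= tb2) stop("tb1 must be smaller than tb2")
  stopifnot(s >= 1)
  mid <- P0 - ((s - 1) * P0 / s) * (t - tb1) / (tb2 - tb1)
  out <- ifelse(t <= tb1, P0, ifelse(t >= tb2, P0 / s, mid))
  out
}

#' Ground truth for a synthetic session
#'
#' Defaults follow the stationary validation configuration: perceptual
#' biases +20 (leftward context) and -10 (rightward context), decision
#' bias +10, sensitivity noise 15 deg in every condition, zero lapses,
#' and no serial choice dependence.
#'
#' @param biases a [bias_set()] of session-level ground-truth biases.
#' @param S per-condition sensitivity noise, degrees (recycled to 3).
#' @param lapses per-condition lapse rates: a 3x2 matrix (rows L, N, R;
#'   columns lambda1, lambda2) or a single number used everywhere.
#' @param decision_dynamics a [decision_dynamics()]; its stationary level
#'   defaults to `biases$D`.
#' @param Tse probability in `[0, 1]` of following a win-stay/lose-shift
#'   serial rule instead of the psychometric draw on any given trial.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(biases = bias_set(PL = 20, PR = -10, D = 10),
                         S = c(L = 15, N = 15, R = 15),
                         lapses = 0,
                         decision_dynamics = NULL,
                         Tse = 0) {
  stopifnot(inherits(biases, "bias_set"))
  S <- rep_len(S, 3)
  names(S) <- CONDITIONS
  if (any(S <= 0)) stop("sensitivity noise must be positive")
  if (is.matrix(lapses)) {
    stopifnot(dim(lapses) == c(3, 2))
  } else {
    lapses <- matrix(lapses, 3, 2)
  }
  dimnames(lapses) <- list(CONDITIONS, c("lambda1", "lambda2"))
  if (Tse < 0 || Tse > 1) stop("Tse must lie in [0, 1]")
  if (is.null(decision_dynamics))
    decision_dynamics <- percbias::decision_dynamics("stationary", D = biases$D)
  structure(list(biases = biases, S = S, lapses = lapses,
                 decision_dynamics = decision_dynamics, Tse = Tse),
            class = "ground_truth")
}

#' Generate a synthetic 2AFC session
#'
#' Simulates choices from the generative psychometric model.  On trial
#' `n` in condition `k` the empirical bias is
#' `B_k(n) = P_k + D(n)` with `P_N = 0`, and the choice is Bernoulli with
#' probability given by [choice_probability()].  If `Tse > 0`, each trial
#' follows a win-stay/lose-shift rule with probability `Tse`: repeat the
#' previous choice if it was rewarded, switch otherwise (which requires a
#' reward policy, since the rule consumes reward feedback).  With a policy
#' attached, reward flags and the reward boundary used on each trial are
#' recorded.
#'
#' @param gt a [ground_truth()].
#' @param schedule a schedule from [make_schedule()]; defaults to the
#'   default grid with the given seed.
#' @param seed integer seed; governs the schedule (when not supplied),
#'   the choice draws, and any policy randomness.
#' @param policy optional [reward_policy()] used to fill reward flags.
#' @return A `session_data` data frame with columns `trial`, `condition`,
#'   `omega`, `choice` (+1/-1), `rewarded` (logical or `NA`),
#'   `boundary` (degrees or `NA`), carrying the ground truth and seed as
#'   attributes.
#' @export
generate_session <- function(gt = ground_truth(), schedule = NULL,
                             seed = NULL, policy = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (gt$Tse > 0 && is.null(policy))
    stop("serial dependence (Tse > 0) requires a reward policy: ",
         "the win-stay/lose-shift rule consumes reward feedback")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schedule)) schedule <- make_schedule(stimulus_grid())
  n <- nrow(schedule)
  ki <- cond_index(schedule$condition)
  Pk <- c(gt$biases$PL, 0, gt$biases$PR)[ki]
  Dn <- decision_bias_at(seq_len(n), gt$decision_dynamics)
  Bk <- Pk + Dn
  Sk <- gt$S[ki]
  l1 <- gt$lapses[ki, 1]
  l2 <- gt$lapses[ki, 2]
  theta <- l1 + (1 - l1 - l2) * pnorm((schedule$omega - Bk) / Sk)

  choice <- integer(n)
  rewarded <- rep(NA, n)
  boundary <- rep(NA_real_, n)
  if (is.null(policy) && gt$Tse == 0) {
    choice <- sample_choice(theta)
  } else {
    for (t in seq_len(n)) {
      serial <- gt$Tse > 0 && t > 1 && runif(1) < gt$Tse
      if (serial) {
        choice[t] <- if (isTRUE(rewarded[t - 1])) choice[t - 1] else -choice[t - 1]
      } else {
        choice[t] <- sample_choice(theta[t])
      }
      if (!is.null(policy)) {
        trial <- list(condition = schedule$condition[t],
                      omega = schedule$omega[t], choice = choice[t])
        rw <- strategy_reward(trial, policy)
        rewarded[t] <- rw$reward
        boundary[t] <- rw$boundary
      }
    }
  }
  out <- data.frame(trial = seq_len(n), condition = schedule$condition,
                    omega = schedule$omega, choice = choice,
                    rewarded = as.logical(rewarded), boundary = boundary,
                    stringsAsFactors = FALSE)
  attr(out, "ground_truth") <- gt
  attr(out, "seed") <- seed
  class(out) <- c("session_data", "data.frame")
  out
}

#' Write / read a session log as CSV
#'
#' Flat-file schema: `trial,condition,direction_deg,choice,rewarded,boundary_deg`.
#'
#' @param session a `session_data` data frame.
#' @param path output file path.
#' @return `write_session_csv` returns `path` invisibly;
#'   `read_session_csv` returns a `session_data` data frame.
#' @export
write_session_csv <- function(session, path) {
  out <- data.frame(trial = session$trial, condition = session$condition,
                    direction_deg = session$omega, choice = session$choice,
                    rewarded = session$rewarded, boundary_deg = session$boundary)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(trial = raw$trial, condition = raw$condition,
                    omega = raw$direction_deg, choice = as.integer(raw$choice),
                    rewarded = as.logical(raw$rewarded),
                    boundary = raw$boundary_deg, stringsAsFactors = FALSE)
  class(out) <- c("session_data", "data.frame")
  out
}
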