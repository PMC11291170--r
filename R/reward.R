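#' Reward-boundary state with per-trial clamping
#'
#' Holds the current reward boundary for each condition and the maximum
#' step by which a boundary may move between consecutive updates.  The
#' clamp (default 1 deg, i.e. 1% of the +/-40 deg stimulus range) is a
#' fail-safe against sudden boundary jumps early in a session when the
#' prior is misaligned with the eventual estimate.
#'
#' @param boundary named numeric vector of per-condition boundaries, degrees.
#' @param clamp_step maximum boundary change per update, degrees.
#' @return An object of class `boundary_state`.
#' @export
boundary_state <- function(boundary = c(L = 0, N = 0, R = 0), clamp_step = 1) {
  stopifnot(clamp_step >= 0, all(CONDITIONS %in% names(boundary)))
  structure(list(boundary = boundary[CONDITIONS], clamp_step = clamp_step),
            class = "boundary_state")
}

#' Move a reward boundary toward a new estimate, clamped
#'
#' The boundary moves toward `new_estimate` by at most `clamp_step`
#' degrees; it lands exactly on the estimate when already within reach.
#' The neutral condition's boundary is conventionally held at 0 by the
#' policies and is not updated here.
#'
#' @param state a [boundary_state()].
#' @param condition `"L"` or `"R"`.
#' @param new_estimate target boundary (typically the posterior mean of
#'   the condition's perceptual bias), degrees.
#' @return The updated `boundary_state`.
#' @export
update_boundary <- function(state, condition, new_estimate) {
  stopifnot(inherits(state, "boundary_state"))
  if (!condition %in% c("L", "R"))
    stop("only the L and R boundaries are updated; neutral stays at 0")
  cur <- state$boundary[[condition]]
  delta <- new_estimate - cur
  step <- sign(delta) * min(abs(delta), state$clamp_step)
  state$boundary[[condition]] <- cur + step
  state
}

#' Allocate reward relative to a boundary
#'
#' Reward is given iff the choice is on the correct side of the boundary:
#' left with `omega < boundary`, or right with `omega > boundary`.  A
#' stimulus exactly on the boundary is rewarded with probability 0.5.
#'
#' @param trial a list (or one-row data frame) with fields `choice`
#'   (+1 right / -1 left) and `omega` (degrees).
#' @param boundary reward boundary in degrees.
#' @return `TRUE` if rewarded.
#' @export
allocate_reward <- function(trial, boundary) {
  stopifnot(is.finite(boundary))
  ch <- trial$choice
  om <- trial$omega
  if (om == boundary) return(runif(1) < 0.5)
  (ch == -1 && om < boundary) || (ch == 1 && om > boundary)
}

#' Reward policy
#'
#' The six reward strategies compared by the package:
#' \describe{
#'   \item{veridical}{reward relative to the true stimulus (boundary 0
#'     everywhere), i.e. assume no perceptual bias.}
#'   \item{oracle}{reward relative to the ground-truth perceptual bias of
#'     each context (only available in simulation).}
#'   \item{estimated}{reward relative to the online posterior-mean
#'     estimate of the perceptual bias, with per-trial clamping -- the
#'     method the package implements.}
#'   \item{random_ambiguous / always_ambiguous / never_ambiguous}{veridical
#'     outside the ambiguous interval; inside it (stimuli strictly between
#'     0 and the context's perceptual bias, where the "correct" answer
#'     depends on whether perception or the screen is trusted) reward
#'     randomly / always / never.}
#' }
#' The neutral condition's boundary is 0 under every policy and its
#' ambiguous set is empty.
#'
#' @param kind one of `"veridical"`, `"oracle"`, `"estimated"`,
#'   `"random_ambiguous"`, `"always_ambiguous"`, `"never_ambiguous"`.
#' @param ground_truth a [bias_set()]; required by `oracle` and by the
#'   ambiguous-trial policies (it defines the ambiguous interval).
#' @param estimator an [online_estimator()]; required by `estimated`.
#' @param clamp_step boundary clamp in degrees (estimated policy only).
#' @return A mutable `reward_policy` object (an environment).
#' @export
reward_policy <- function(kind = c("veridical", "oracle", "estimated",
                                   "random_ambiguous", "always_ambiguous",
                                   "never_ambiguous"),
                          ground_truth = NULL, estimator = NULL,
                          clamp_step = 1) {
  kind <- match.arg(kind)
  needs_gt <- kind %in% c("oracle", "random_ambiguous", "always_ambiguous",
                          "never_ambiguous")
  if (needs_gt && !inherits(ground_truth, "bias_set"))
    stop("policy '", kind, "' requires a ground-truth bias_set")
  if (kind == "estimated" && is.null(estimator))
    stop("the estimated policy requires an attached online estimator")
  pol <- new.env(parent = emptyenv())
  pol$kind <- kind
  pol$ground_truth <- ground_truth
  pol$estimator <- estimator
  pol$state <- boundary_state(clamp_step = clamp_step)
  class(pol) <- "reward_policy"
  pol
}

# Perceptual-bias boundary implied by a bias_set for a condition
gt_boundary <- function(gt, condition) {
  switch(condition, L = gt$PL, R = gt$PR, N = 0)
}

#' Reward a trial under a policy
#'
#' Computes the reward boundary implied by the policy for the trial's
#' condition, applies [allocate_reward()] (or the ambiguous-trial rule),
#' and for the estimated policy advances the clamped boundary toward the
#' estimator's current posterior mean.
#'
#' @param trial list with `condition`, `omega`, `choice`.
#' @param policy a [reward_policy()].
#' @return List with `reward` (logical) and `boundary` (degrees used).
#' @export
strategy_reward <- function(trial, policy) {
  stopifnot(inherits(policy, "reward_policy"))
  k <- trial$condition
  kind <- policy$kind
  if (kind %in% c("random_ambiguous", "always_ambiguous", "never_ambiguous")) {
    Pk <- gt_boundary(policy$ground_truth, k)
    lo <- min(0, Pk); hi <- max(0, Pk)
    if (trial$omega > lo && trial$omega < hi) {
      rw <- switch(kind,
                   random_ambiguous = runif(1) < 0.5,
                   always_ambiguous = TRUE,
                   never_ambiguous = FALSE)
      return(list(reward = rw, boundary = 0))
    }
    return(list(reward = allocate_reward(trial, 0), boundary = 0))
  }
  boundary <- switch(kind,
    veridical = 0,
    oracle = gt_boundary(policy$ground_truth, k),
    estimated = {
      if (k == "N") 0 else {
        est <- policy$estimator$estimates()
        target <- est$mean[match(paste0("P", k), est$parameter)]
        policy$state <- update_boundary(policy$state, k, target)
        policy$state$boundary[[k]]
      }
    })
  list(reward = allocate_reward(trial, boundary), boundary = boundary)
}
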