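#' Generate multi-session synthetic data from the linear hypermodel
#'
#' Session-level perceptual biases are drawn from the linear hyperprior
#' `P_L ~ N(X beta_L, sigma_L)`, `P_R ~ N(X beta_R, sigma_R)` where the
#' covariate rows `X` hold heading direction and eccentricity (degrees),
#' and each session's choices are then simulated from the psychometric
#' model.
#'
#' @param X covariate matrix, one row per session.
#' @param beta_L,beta_R weight vectors, length `ncol(X)`.
#' @param sigma_L,sigma_R residual SDs, degrees.
#' @param D decision bias per session (scalar recycled), degrees.
#' @param S sensitivity noise, degrees.
#' @param n_blocks blocks per session.
#' @param seed master seed; session `j` uses `seed + j`.
#' @return List with `sessions` (list of `session_data`), `truth`
#'   (data frame of session-level `PL`, `PR`, `D`), and `X`.
#' @export
generate_multisession <- function(X, beta_L, beta_R, sigma_L, sigma_R,
                                  D = 10, S = 15, n_blocks = 3,
                                  seed = NULL) {
  X <- as.matrix(X)
  stopifnot(length(beta_L) == ncol(X), length(beta_R) == ncol(X),
            sigma_L > 0, sigma_R > 0)
  J <- nrow(X)
  D <- rep_len(D, J)
  if (!is.null(seed)) set.seed(seed)
  PL <- rnorm(J, drop(X %*% beta_L), sigma_L)
  PR <- rnorm(J, drop(X %*% beta_R), sigma_R)
  grid <- stimulus_grid(n_blocks = n_blocks)
  sessions <- lapply(seq_len(J), function(j) {
    gt <- ground_truth(bias_set(PL[j], PR[j], D[j]), S = S)
    generate_session(gt, schedule = make_schedule(grid), seed = NULL)
  })
  list(sessions = sessions,
       truth = data.frame(PL = PL, PR = PR, D = D), X = X)
}

half_normal_lp <- function(s, scale) {
  if (s <= 0) return(-Inf)
  dnorm(s, 0, scale, log = TRUE) + log(2)
}

# Conjugate multivariate-normal draw of regression weights given
# session-level biases P, covariates X, residual SD sigma, and a
# N(0, prior_sd^2) prior on each weight.
draw_beta <- function(X, P, sigma, prior_sd = 1000) {
  p <- ncol(X)
  prec <- crossprod(X) / sigma^2 + diag(1 / prior_sd^2, p)
  ch <- chol(prec)
  mu <- backsolve(ch, forwardsolve(t(ch), crossprod(X, P) / sigma^2))
  drop(mu + backsolve(ch, rnorm(p)))
}

#' Fit the multi-session hierarchical model
#'
#' Joint MCMC over the hyperprior weights (`beta_L`, `beta_R`), residual
#' SDs (`sigma_L`, `sigma_R`; half-normal(1000) priors -- the minimal
#' proper stand-in for a wide Gaussian on a scale parameter), and every
#' session's psychometric parameters, with session-level perceptual
#' biases tied to the covariates through the linear hyperprior.  Weights
#' get conjugate Gaussian updates; sigmas a random-walk step on the log
#' scale; session parameters the same Metropolis-within-Gibbs sweep as
#' the single-session sampler.  `method = "two_stage"` first fits each
#' session with flat priors and then regresses the posterior means -- a
#' fast approximation.
#'
#' @param sessions list of `session_data` data frames.
#' @param X covariate matrix, one row per session.
#' @param cfg an [mcmc_config()].
#' @param prior a [bias_prior()] supplying the decision-bias prior
#'   (`D0`, `tauD`) and the S/lapse priors for every session.
#' @param intercept add an intercept column to `X`.
#' @param method `"full"` (joint hierarchical fit) or `"two_stage"`.
#' @param beta_prior_sd SD of the Gaussian prior on each weight.
#' @return An object of class `hyper_posterior` with draw matrices for
#'   `beta_L`, `beta_R`, `sigma_L`, `sigma_R` and session-level biases,
#'   plus a summary table.
#' @export
fit_hyper <- function(sessions, X, cfg = mcmc_config(n_samples = 2000,
                                                     burn_in = 1000),
                      prior = bias_prior(tauD = 10),
                      intercept = FALSE, method = c("full", "two_stage"),
                      beta_prior_sd = 1000) {
  method <- match.arg(method)
  X <- as.matrix(X)
  J <- length(sessions)
  stopifnot(J >= 2, nrow(X) == J)
  if (intercept) X <- cbind(intercept = 1, X)
  if (qr(X)$rank < ncol(X))
    warning("covariate matrix is rank deficient; weights are not identifiable")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  p <- ncol(X)

  if (method == "two_stage") {
    fits <- lapply(sessions, fit_posterior, prior = flat_prior(), cfg = cfg)
    PLhat <- vapply(fits, function(f) mean(f$draws[, "PL"]), numeric(1))
    PRhat <- vapply(fits, function(f) mean(f$draws[, "PR"]), numeric(1))
    Dhat <- vapply(fits, function(f) mean(f$draws[, "D"]), numeric(1))
    session_bias <- function(it) cbind(PL = PLhat, PR = PRhat, D = Dhat)
    fixed_bias <- TRUE
  } else {
    sp <- lapply(sessions, split_conditions)
    # per-session parameter vectors (12 each) and proposal scales
    pars <- lapply(seq_len(J), function(j)
      c(0, 0, 0, rep(prior$alpha_S / prior$beta_S, 3),
        rep(prior$gamma_lapse / (prior$gamma_lapse + prior$eps_lapse), 6)))
    scales <- lapply(seq_len(J), function(j)
      c(5, 5, 5, 2, 2, 2, rep(0.03, 6)))
    fixed_bias <- FALSE
  }

  betaL <- rep(0, p); betaR <- rep(0, p)
  sigmaL <- 10; sigmaR <- 10
  ls_scale <- c(L = 0.3, R = 0.3)

  n_keep <- cfg$n_samples - cfg$burn_in
  dr_betaL <- matrix(NA_real_, n_keep, p)
  dr_betaR <- matrix(NA_real_, n_keep, p)
  dr_sigma <- matrix(NA_real_, n_keep, 2,
                     dimnames = list(NULL, c("sigma_L", "sigma_R")))
  dr_PL <- matrix(NA_real_, n_keep, J)
  dr_PR <- matrix(NA_real_, n_keep, J)
  acc_batch <- c(L = 0, R = 0); batch <- 0

  sigma_step <- function(sigma, P, beta, scale_ls) {
    resid <- P - drop(X %*% beta)
    lp <- function(s) sum(dnorm(resid, 0, s, log = TRUE)) +
      half_normal_lp(s, 1000) + log(s)  # Jacobian of the log-scale walk
    prop <- sigma * exp(scale_ls * rnorm(1))
    if (log(runif(1)) < lp(prop) - lp(sigma)) list(s = prop, acc = 1)
    else list(s = sigma, acc = 0)
  }

  for (it in seq_len(cfg$n_samples)) {
    if (!fixed_bias) {
      mPL <- drop(X %*% betaL); mPR <- drop(X %*% betaR)
      for (j in seq_len(J)) {
        sw <- mwg_session_sweep_cpp(
          sp[[j]]$L$omega, sp[[j]]$L$y, sp[[j]]$N$omega, sp[[j]]$N$y,
          sp[[j]]$R$omega, sp[[j]]$R$y, pars[[j]], scales[[j]],
          mPL[j], sigmaL, mPR[j], sigmaR, prior$D0, prior$tauD,
          prior$alpha_S, prior$beta_S, prior$gamma_lapse, prior$eps_lapse)
        pars[[j]] <- sw$par
      }
      PL <- vapply(pars, `[`, numeric(1), 1)
      PR <- vapply(pars, `[`, numeric(1), 2)
      Dj <- vapply(pars, `[`, numeric(1), 3)
    } else {
      sb <- session_bias(it)
      PL <- sb[, "PL"]; PR <- sb[, "PR"]; Dj <- sb[, "D"]
    }
    betaL <- draw_beta(X, PL, sigmaL, beta_prior_sd)
    betaR <- draw_beta(X, PR, sigmaR, beta_prior_sd)
    stL <- sigma_step(sigmaL, PL, betaL, ls_scale["L"])
    stR <- sigma_step(sigmaR, PR, betaR, ls_scale["R"])
    sigmaL <- stL$s; sigmaR <- stR$s
    if (it <= cfg$burn_in) {
      acc_batch <- acc_batch + c(stL$acc, stR$acc)
      if (it %% 50 == 0) {
        batch <- batch + 1
        d <- min(0.05, 1 / sqrt(batch))
        ls_scale <- ls_scale * exp(ifelse(acc_batch / 50 > 0.44, d, -d))
        acc_batch[] <- 0
      }
    } else {
      ii <- it - cfg$burn_in
      dr_betaL[ii, ] <- betaL; dr_betaR[ii, ] <- betaR
      dr_sigma[ii, ] <- c(sigmaL, sigmaR)
      dr_PL[ii, ] <- PL; dr_PR[ii, ] <- PR
    }
  }
  colnames(dr_betaL) <- colnames(dr_betaR) <- colnames(X) %||%
    paste0("x", seq_len(p))
  summary <- rbind(
    cbind(parameter = paste0("betaL_", colnames(dr_betaL)),
          summarise_draws(dr_betaL)[, -1]),
    cbind(parameter = paste0("betaR_", colnames(dr_betaR)),
          summarise_draws(dr_betaR)[, -1]),
    summarise_draws(dr_sigma))
  structure(list(beta_L = dr_betaL, beta_R = dr_betaR, sigma = dr_sigma,
                 session_PL = dr_PL, session_PR = dr_PR,
                 summary = summary, X = X, method = method,
                 intercept = intercept, prior = prior),
            class = "hyper_posterior")
}

#' @export
print.hyper_posterior <- function(x, ...) {
  cat(sprintf("Hyperposterior over %d sessions (%s fit)\n", nrow(x$X),
              x$method))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Construct the next session's prior from the hyperposterior
#'
#' Prior means are the posterior-mean weights dotted with the new
#' session's covariates; prior SDs are the posterior means of the
#' residual SDs.  The decision-bias prior is always centered at zero
#' with a user-supplied width, since the decision bias is not modeled as
#' covariate-dependent.
#'
#' @param hyper a fitted `hyper_posterior`.
#' @param x_new covariate row for the upcoming session.
#' @param tauD decision-bias prior SD, degrees.
#' @return A [bias_prior()].
#' @export
predict_session_prior <- function(hyper, x_new, tauD = 10) {
  stopifnot(inherits(hyper, "hyper_posterior"))
  if (hyper$intercept) x_new <- c(1, x_new)
  if (length(x_new) != ncol(hyper$beta_L))
    stop("covariate row has length ", length(x_new), ", expected ",
         ncol(hyper$beta_L))
  bias_prior(P0L = sum(colMeans(hyper$beta_L) * x_new),
             tauPL = mean(hyper$sigma[, "sigma_L"]),
             P0R = sum(colMeans(hyper$beta_R) * x_new),
             tauPR = mean(hyper$sigma[, "sigma_R"]),
             D0 = 0, tauD = tauD,
             alpha_S = hyper$prior$alpha_S, beta_S = hyper$prior$beta_S,
             gamma_lapse = hyper$prior$gamma_lapse,
             eps_lapse = hyper$prior$eps_lapse)
}
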