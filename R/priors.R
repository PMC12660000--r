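#' Prior specification for the Bayesian multi-state model
#'
#' Independent priors: Normal(0, sigma_beta^2) for each covariate coefficient,
#' Normal(0, sigma_gamma^2) for each key-action effect, and Gamma(shape,
#' scale) for each baseline hazard and each individual speed. Defaults use
#' sigma = 2 for the normal priors — the region where posterior inferences
#' are stable under the prior-sensitivity sweep — and Gamma(1, 1) (prior
#' mean 1) for hazards and speeds; centring the speed prior at 1 softly
#' resolves the lambda-theta scale confounding.
#'
#' @param sigma_beta,sigma_gamma prior standard deviations (> 0).
#' @param lam_shape,lam_scale Gamma shape and scale for baseline hazards.
#' @param theta_shape,theta_scale Gamma shape and scale for speeds.
#' @return An object of class `msm_priors`.
#' @export
msm_priors <- function(sigma_beta = 2, sigma_gamma = 2,
                       lam_shape = 1, lam_scale = 1,
                       theta_shape = 1, theta_scale = 1) {
  vals <- c(sigma_beta, sigma_gamma, lam_shape, lam_scale,
            theta_shape, theta_scale)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all prior hyperparameters must be strictly positive")
  structure(list(sigma_beta = sigma_beta, sigma_gamma = sigma_gamma,
                 lam_shape = lam_shape, lam_scale = lam_scale,
                 theta_shape = theta_shape, theta_scale = theta_scale),
            class = "msm_priors")
}

#' Joint log-prior density of a parameter set
#'
#' @param params an [msm_params()] object.
#' @param priors an [msm_priors()] object.
#' @return Scalar log-density; `-Inf` when a hazard or speed is non-positive.
#' @export
log_prior <- function(params, priors) {
  stopifnot(inherits(params, "msm_params"), inherits(priors, "msm_priors"))
  lam <- c(params$lam[["0"]], params$lam[["1"]])
  theta <- params$theta
  if (any(lam <= 0) || any(theta <= 0)) return(-Inf)
  sum(stats::dnorm(params$beta, 0, priors$sigma_beta, log = TRUE)) +
    sum(stats::dnorm(c(params$gamma1, params$gamma2), 0, priors$sigma_gamma,
                     log = TRUE)) +
    sum(stats::dgamma(lam, shape = priors$lam_shape,
                      scale = priors$lam_scale, log = TRUE)) +
    sum(stats::dgamma(theta, shape = priors$theta_shape,
                      scale = priors$theta_scale, log = TRUE))
}

#' MCMC sampler configuration
#'
#' Controls the Metropolis-within-Gibbs run. Proposal standard deviations
#' are tuned only during burn-in, every `adapt_interval` iterations: a
#' block's proposal sd is multiplied by 1.5 when its running acceptance rate
#' exceeds `accept_high` and by 0.67 when it falls below `accept_low`;
#' kernels are frozen after burn-in so the post-burn-in chain targets the
#' exact posterior. The `"desk"` preset (default) is sized for interactive
#' use; `"paper"` mirrors the large-scale setting of 300,000 iterations with
#' 100,000 burn-in, thinning by 10, and 5 chains.
#'
#' @param n_iter total iterations per chain.
#' @param burn_in iterations discarded (must be `< n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param n_chains number of independently seeded chains.
#' @param seed integer base seed; chain c uses `seed + c - 1`.
#' @param accept_low,accept_high target acceptance-rate window.
#' @param adapt_interval iterations between proposal-scale updates.
#' @param preset `"desk"`, `"paper"`, or `"custom"` (use the values given).
#' @return An object of class `msm_control`.
#' @export
msm_control <- function(n_iter = 20000L, burn_in = 5000L, thin = 5L,
                        n_chains = 5L, seed = 1L,
                        accept_low = 0.2, accept_high = 0.5,
                        adapt_interval = 100L,
                        preset = c("custom", "desk", "paper")) {
  preset <- match.arg(preset)
  if (preset == "desk") {
    n_iter <- 20000L; burn_in <- 5000L; thin <- 5L; n_chains <- 5L
  } else if (preset == "paper") {
    n_iter <- 300000L; burn_in <- 100000L; thin <- 10L; n_chains <- 5L
  }
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter, thin >= 1,
            n_chains >= 1, adapt_interval >= 1,
            accept_low < accept_high, accept_low > 0, accept_high < 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed), accept_low = accept_low,
                 accept_high = accept_high,
                 adapt_interval = as.integer(adapt_interval)),
            class = "msm_control")
}
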