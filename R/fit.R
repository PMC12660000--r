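#' Fit the Bayesian multi-state survival model to action-log data
#'
#' The central model of the package. Actions are states of a
#' time-homogeneous Markov process; the hazard of moving from action `m` to
#' action `l` for respondent `i` in correctness group `g` is
#' \deqn{h_i(m,l) = \lambda_{mlg}\,\theta_i\,
#'   \exp(x_i'\beta + \gamma_{1g} 1[m \in K] + \gamma_{2g} 1[l \in K]),}
#' with group-specific baseline hazards `lambda`, individual speed `theta`,
#' shared covariate effects `beta` and group-specific key-action effects
#' `gamma1` (key start) and `gamma2` (key end). The final sojourn of every
#' respondent is right-censored at their total solution time. Estimation is
#' fully Bayesian via adaptive Metropolis-within-Gibbs MCMC (see
#' [msm_control()]); priors are set by [msm_priors()].
#'
#' @param dataset a [log_dataset()].
#' @param key_actions character vector of key actions, typically from
#'   [select_key_actions()]; may be empty (all gamma effects then drop out
#'   of the likelihood and are sampled from their prior).
#' @param priors an [msm_priors()] object.
#' @param control an [msm_control()] object.
#' @param support `"observed"` (per-group observed pairs, the default) or
#'   `"full"` (all E*E pairs; for simulation studies).
#' @param update which parameter blocks to sample; the others stay fixed at
#'   their initial values (useful for conditional-distribution checks).
#' @param init optional named list (`lam`, `theta`, `beta`, `gamma1`,
#'   `gamma2`) of initial/fixed values overriding the defaults (empirical
#'   hazard rates, unit speeds, zero effects).
#' @param renormalize if `TRUE`, post-process each draw by dividing the
#'   speeds by their geometric mean and multiplying all hazards by it,
#'   resolving the lambda-theta scale confounding for reporting.
#'
#' @return An object of class `msmlog` with components `draws` (list of
#'   per-chain draw matrices, parameters in columns), `acceptance` (per-chain
#'   named vectors of post-burn-in acceptance rates per scalar block),
#'   `suffstats`, `key_actions`, `priors`, `control`, `support_policy`,
#'   `update`, and the matched call. Methods: [summary.msmlog()],
#'   [coef.msmlog()], [predict.msmlog()], [plot.msmlog()],
#'   [simulate.msmlog()], [residuals.msmlog()], [logLik.msmlog()].
#' @examples
#' spec <- make_scenario("S1", n_individuals = 30, n_actions = 4,
#'                       n_covariates = 1, seed = 1)
#' sim <- simulate_logs(spec)
#' fit <- msmlog(sim$dataset, key_actions = spec$key_set,
#'               control = msm_control(n_iter = 300, burn_in = 100,
#'                                     thin = 2, n_chains = 2, seed = 1))
#' fit
#' @export
msmlog <- function(dataset, key_actions = character(0),
                   priors = msm_priors(), control = msm_control(),
                   support = c("observed", "full"),
                   update = c("lambda", "theta", "beta", "gamma"),
                   init = NULL, renormalize = FALSE) {
  stopifnot(inherits(dataset, "log_dataset"),
            inherits(priors, "msm_priors"), inherits(control, "msm_control"))
  support <- match.arg(support)
  update <- match.arg(update, c("lambda", "theta", "beta", "gamma"),
                      several.ok = TRUE)
  if (!all(key_actions %in% dataset$vocabulary))
    stop("key_actions must be members of the dataset vocabulary")

  ss <- compute_sufficient_statistics(dataset, support_policy = support)
  md <- build_mcmc_data(ss, key_actions)
  if (all(vapply(md$per_group, function(pg) pg$S == 0L, logical(1))))
    stop("empty support: no transitions observed")

  chains <- vector("list", control$n_chains)
  accept <- vector("list", control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    res <- run_chain(md, priors, control, chain_seed = control$seed + ch - 1L,
                     init = init, update = update)
    chains[[ch]] <- res$draws
    accept[[ch]] <- res$acceptance
  }

  fit <- structure(list(
    draws = chains, acceptance = accept,
    param_names = colnames(chains[[1L]]),
    suffstats = ss, key_actions = key_actions, priors = priors,
    control = control, support_policy = support, update = update,
    renormalized = FALSE, call = match.call()),
    class = "msmlog")
  if (renormalize) fit <- renormalize_scale(fit)
  fit
}

#' Resolve the hazard-speed scale confounding in stored draws
#'
#' Multiplying every baseline hazard by `c > 0` and dividing every speed by
#' `c` leaves the likelihood unchanged. For reporting, each stored draw can
#' be renormalized so the speeds have geometric mean 1, moving the common
#' scale into the hazards.
#'
#' @param fit an `msmlog` object whose draws include both `lambda` and
#'   `theta` blocks.
#' @return The fit with renormalized draws.
#' @export
renormalize_scale <- function(fit) {
  stopifnot(inherits(fit, "msmlog"))
  ith <- grep("^theta\\[", fit$param_names)
  ila <- grep("^lambda\\[", fit$param_names)
  if (!length(ith) || !length(ila))
    stop("renormalization needs both lambda and theta draws")
  fit$draws <- lapply(fit$draws, function(dr) {
    gm <- exp(rowMeans(log(dr[, ith, drop = FALSE])))
    dr[, ith] <- dr[, ith, drop = FALSE] / gm
    dr[, ila] <- dr[, ila, drop = FALSE] * gm
    dr
  })
  fit$renormalized <- TRUE
  fit
}

# pooled draw matrix across chains
pooled_draws <- function(fit) do.call(rbind, fit$draws)

#' @export
print.msmlog <- function(x, ...) {
  cat("Bayesian multi-state model for action-log data\n")
  cat(sprintf("  %d respondents, %d actions, %d key actions; support: %s\n",
              length(x$suffstats$ids), length(x$suffstats$vocabulary),
              length(x$key_actions), x$support_policy))
  cat(sprintf("  %d chains x %d iterations (burn-in %d, thin %d): %d retained draws, %d parameters\n",
              x$control$n_chains, x$control$n_iter, x$control$burn_in,
              x$control$thin, nrow(pooled_draws(x)), length(x$param_names)))
  cf <- coef(x)
  if (length(cf$beta)) {
    cat("  posterior mean beta:\n")
    print(round(cf$beta, 4))
  }
  cat("  posterior mean gamma1:", round(cf$gamma1, 4),
      " gamma2:", round(cf$gamma2, 4), "\n")
  invisible(x)
}

#' Posterior summary table
#'
#' Posterior mean, standard deviation, 95% highest-posterior-density
#' interval, Gelman-Rubin statistic (when at least two chains were run) and
#' an HPD-excludes-zero significance flag per parameter.
#'
#' @param object an `msmlog` fit.
#' @param pars optional regular expression selecting parameters.
#' @param level credible level for the HPD intervals.
#' @param ... unused.
#' @return A data frame, one row per parameter.
#' @export
summary.msmlog <- function(object, pars = NULL, level = 0.95, ...) {
  dr <- pooled_draws(object)
  keep <- if (is.null(pars)) seq_len(ncol(dr))
          else grep(pars, colnames(dr))
  dr <- dr[, keep, drop = FALSE]
  hpd <- apply(dr, 2L, hpd_interval, level = level)
  rhat <- if (object$control$n_chains >= 2L) {
    gr <- gelman_rubin(object)
    gr[colnames(dr)]
  } else rep(NA_real_, ncol(dr))
  out <- data.frame(
    parameter = colnames(dr),
    mean = colMeans(dr),
    sd = apply(dr, 2L, stats::sd),
    hpd_lo = hpd[1L, ], hpd_hi = hpd[2L, ],
    rhat = unname(rhat),
    significant = hpd[1L, ] > 0 | hpd[2L, ] < 0,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("summary.msmlog", "data.frame")
  out
}

#' @export
print.summary.msmlog <- function(x, n = 20L, ...) {
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more parameters\n")
  invisible(x)
}

#' Posterior-mean parameter estimates
#'
#' @param object an `msmlog` fit.
#' @param ... unused.
#' @return List with components `lam` (per group), `theta`, `beta`,
#'   `gamma1`, `gamma2` at their posterior means (blocks that were not
#'   sampled are returned at their fixed values).
#' @export
coef.msmlog <- function(object, ...) {
  m <- colMeans(pooled_draws(object))
  md_groups <- names(object$suffstats$support)
  out <- list(lam = list(), theta = numeric(0), beta = numeric(0),
              gamma1 = c("0" = 0, "1" = 0), gamma2 = c("0" = 0, "1" = 0))
  for (g in md_groups) {
    sel <- grep(sprintf("^lambda\\[.*\\|g=%s\\]$", g), names(m))
    sup <- object$suffstats$support[[g]]
    if (length(sel) == nrow(sup)) out$lam[[g]] <- unname(m[sel])
  }
  ith <- grep("^theta\\[", names(m))
  if (length(ith))
    out$theta <- stats::setNames(unname(m[ith]),
                                 sub("^theta\\[(.*)\\]$", "\\1", names(m)[ith]))
  ib <- grep("^beta\\[", names(m))
  if (length(ib))
    out$beta <- stats::setNames(unname(m[ib]),
                                sub("^beta\\[(.*)\\]$", "\\1", names(m)[ib]))
  for (g in c("0", "1")) {
    i1 <- match(sprintf("gamma1[g=%s]", g), names(m))
    i2 <- match(sprintf("gamma2[g=%s]", g), names(m))
    if (!is.na(i1)) out$gamma1[[g]] <- unname(m[i1])
    if (!is.na(i2)) out$gamma2[[g]] <- unname(m[i2])
  }
  out
}

#' Assemble an [msm_params()] object from a fitted model
#'
#' Plug-in parameter set at posterior means; fixed blocks keep their fixed
#' values.
#'
#' @param fit an `msmlog` object.
#' @return An [msm_params()] object.
#' @export
params_from_fit <- function(fit) {
  stopifnot(inherits(fit, "msmlog"))
  cf <- coef(fit)
  ss <- fit$suffstats
  lam <- cf$lam
  for (g in c("0", "1"))
    if (is.null(lam[[g]])) lam[[g]] <- rep(1, nrow(ss$support[[g]]))
  theta <- cf$theta
  if (!length(theta)) theta <- stats::setNames(rep(1, length(ss$ids)), ss$ids)
  beta <- cf$beta
  if (!length(beta) && ncol(ss$X))
    beta <- stats::setNames(rep(0, ncol(ss$X)), colnames(ss$X))
  msm_params(vocabulary = ss$vocabulary, support = ss$support, lam = lam,
             theta = theta, beta = beta, gamma1 = cf$gamma1,
             gamma2 = cf$gamma2, key_set = fit$key_actions)
}

#' Predicted embedded-chain transition matrix
#'
#' @param object an `msmlog` fit.
#' @param group 0 or 1.
#' @param covariates covariate vector (inert by row-wise cancellation, kept
#'   for interface fidelity).
#' @param type `"plugin"`: matrix at posterior-mean parameters;
#'   `"draw_mean"`: average of the per-draw matrices.
#' @param ... unused.
#' @return E x E row-stochastic matrix.
#' @export
predict.msmlog <- function(object, group = 1, covariates = NULL,
                           type = c("plugin", "draw_mean"), ...) {
  type <- match.arg(type)
  if (type == "plugin")
    return(transition_matrix(params_from_fit(object), group = group,
                             x = covariates))
  P <- draw_transition_matrices(object, group)
  M <- apply(P, c(2L, 3L), mean)
  dimnames(M) <- list(object$suffstats$vocabulary,
                      object$suffstats$vocabulary)
  M
}

# per-draw transition matrices for one group: draws x E x E array
draw_transition_matrices <- function(fit, group) {
  g <- as.character(group)
  ss <- fit$suffstats
  vocab <- ss$vocabulary
  E <- length(vocab)
  sup <- ss$support[[g]]
  dr <- pooled_draws(fit)
  sel <- grep(sprintf("^lambda\\[.*\\|g=%s\\]$", g), colnames(dr))
  stopifnot(length(sel) == nrow(sup))
  lam <- dr[, sel, drop = FALSE]
  ig2 <- match(sprintf("gamma2[g=%s]", g), colnames(dr))
  g2 <- if (is.na(ig2)) rep(0, nrow(dr)) else dr[, ig2]
  keyl <- vocab[sup[, 2L]] %in% fit$key_actions
  H <- lam * exp(outer(g2, as.numeric(keyl)))
  # normalize within source state
  denom <- t(rowsum(t(H), group = sup[, 1L]))  # draws x (#source states)
  src_levels <- as.integer(colnames(denom))
  P <- array(0, dim = c(nrow(dr), E, E))
  for (j in seq_len(nrow(sup))) {
    s <- match(sup[j, 1L], src_levels)
    P[cbind(seq_len(nrow(dr)), sup[j, 1L], sup[j, 2L])] <- H[, j] / denom[, s]
  }
  P
}

#' Trace plots of posterior draws
#'
#' @param x an `msmlog` fit.
#' @param pars regular expression selecting parameters (default: covariate
#'   and key-action effects).
#' @param max_pars cap on the number of panels.
#' @param ... passed to [graphics::plot()].
#' @export
plot.msmlog <- function(x, pars = "^(beta|gamma)", max_pars = 9L, ...) {
  sel <- grep(pars, x$param_names)
  sel <- utils::head(sel, max_pars)
  if (!length(sel)) stop("no parameters match 'pars'")
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(sel)),
                       mar = c(2.5, 2.5, 2, 0.5))
  on.exit(graphics::par(old))
  for (j in sel) {
    graphics::plot(NA, xlim = c(1, nrow(x$draws[[1L]])),
                   ylim = range(vapply(x$draws, function(d) range(d[, j]),
                                       numeric(2L))),
                   xlab = "", ylab = "", main = x$param_names[j], ...)
    for (ch in seq_along(x$draws))
      graphics::lines(x$draws[[ch]][, j], col = ch)
  }
  invisible(x)
}

#' Simulate datasets from the fitted model
#'
#' Posterior-predictive-style simulation: keeps each respondent's group,
#' covariates, speed (posterior mean) and observed sequence length, and
#' regenerates the action sequence and sojourn times from the fitted
#' hazards.
#'
#' @param object an `msmlog` fit.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return List of [log_dataset()] objects (length `nsim`).
#' @export
simulate.msmlog <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  params <- params_from_fit(object)
  ss <- object$suffstats
  ntr <- numeric(length(ss$ids))
  if (nrow(ss$counts)) {
    agg <- rowsum(ss$counts$count, match(ss$counts$respondent_id, ss$ids))
    ntr[as.integer(rownames(agg))] <- agg
  }
  J <- as.integer(ntr) + 1L  # events = transitions + 1
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    out[[s]] <- simulate_from_params(
      params, ids = ss$ids, group = ss$group, X = ss$X, J = J,
      theta = params$theta[ss$ids])
  }
  out
}

#' Pearson residuals of transition counts
#'
#' Aggregated per group and supported pair: observed transition counts
#' against their expected values under the fitted hazards and observed
#' exposures, `(d - E[d]) / sqrt(E[d])`.
#'
#' @param object an `msmlog` fit.
#' @param ... unused.
#' @return Data frame with columns `group`, `from`, `to`, `observed`,
#'   `expected`, `pearson`.
#' @export
residuals.msmlog <- function(object, ...) {
  params <- params_from_fit(object)
  ss <- object$suffstats
  md <- build_mcmc_data(ss, object$key_actions)
  xb <- if (length(params$beta)) drop(ss$X %*% params$beta) else rep(0, length(ss$ids))
  phi <- params$theta[ss$ids] * exp(xb)
  out <- NULL
  for (g in c("0", "1")) {
    pg <- md$per_group[[g]]
    if (!pg$S || !length(pg$idx)) next
    G <- drop(crossprod(ss$exposure[pg$idx, , drop = FALSE], phi[pg$idx]))
    lh <- pair_log_hazard(params, g)
    expct <- exp(lh) * G[pg$sup[, 1L]]
    out <- rbind(out, data.frame(
      group = as.integer(g),
      from = ss$vocabulary[pg$sup[, 1L]], to = ss$vocabulary[pg$sup[, 2L]],
      observed = pg$d, expected = expct,
      pearson = (pg$d - expct) / sqrt(pmax(expct, .Machine$double.eps)),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' @export
logLik.msmlog <- function(object, ...) {
  ll <- msm_log_likelihood(params_from_fit(object), object$suffstats)
  structure(ll, df = length(object$param_names), class = "logLik")
}
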