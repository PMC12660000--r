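#' Gelman-Rubin convergence diagnostic
#'
#' Classic (non-split) potential scale reduction factor per scalar
#' parameter across parallel chains:
#' `R-hat = sqrt( ((n-1)/n * W + B/n) / W )`, with `W` the mean within-chain
#' variance and `B` n times the variance of the chain means. Values near 1
#' indicate between-chain convergence; 1.1 is the conventional threshold.
#'
#' @param x an `msmlog` fit or a list of draw matrices (chains in the list,
#'   parameters in columns) with at least 2 chains and 10 draws each.
#' @return Named numeric vector of R-hat values. Parameters with zero
#'   within- and between-chain variance (fixed blocks) get `NA`.
#' @export
gelman_rubin <- function(x) {
  chains <- if (inherits(x, "msmlog")) x$draws else x
  stopifnot(is.list(chains), length(chains) >= 2L)
  n <- nrow(chains[[1L]])
  stopifnot(n >= 10L, all(vapply(chains, nrow, 1L) == n))
  M <- length(chains)
  means <- vapply(chains, colMeans, numeric(ncol(chains[[1L]])))
  vars <- vapply(chains, function(d) apply(d, 2L, stats::var),
                 numeric(ncol(chains[[1L]])))
  if (is.null(dim(means))) {  # single parameter
    means <- matrix(means, 1L); vars <- matrix(vars, 1L)
  }
  W <- rowMeans(vars)
  B <- n * apply(means, 1L, stats::var)
  rhat <- sqrt(((n - 1) / n * W + B / n) / W)
  rhat[W == 0] <- NA_real_
  stats::setNames(rhat, colnames(chains[[1L]]))
}

#' Highest posterior density interval
#'
#' Shortest interval containing `ceiling(level * n)` of the sorted draws
#' (sliding-window minimiser); deterministic given the draws.
#'
#' @param draws numeric vector of at least 20 posterior draws.
#' @param level credible level in (0, 1).
#' @return Numeric vector `c(lo, hi)`.
#' @export
hpd_interval <- function(draws, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  n <- length(draws)
  if (n < 20L) stop("need at least 20 draws for an HPD interval")
  x <- sort(draws)
  k <- ceiling(level * n)
  if (k >= n) return(c(x[1L], x[n]))
  width <- x[(k):n] - x[seq_len(n - k + 1L)]
  j <- which.min(width)
  c(x[j], x[j + k - 1L])
}

#' HPD-based significance of an effect
#'
#' An effect is deemed significant when its 95% (or `level`) HPD interval
#' excludes zero; the sign of the posterior mean is reported alongside.
#'
#' @param draws numeric vector of posterior draws.
#' @param level credible level.
#' @return List with `significant` (logical), `sign` (+1/-1/0) and the
#'   `hpd` interval.
#' @export
significance <- function(draws, level = 0.95) {
  h <- hpd_interval(draws, level)
  sig <- h[1L] > 0 || h[2L] < 0
  list(significant = sig,
       sign = if (!sig) 0L else if (h[1L] > 0) 1L else -1L,
       hpd = h)
}

#' Prior-sensitivity sweep
#'
#' Refits the model over a grid of prior settings and tabulates posterior
#' mean, sd and HPD interval per monitored parameter per setting — the
#' standard robustness check that inferences are stable once the normal
#' prior sds reach the weakly-informative regime. The canonical grid varies
#' the normal sds over \{0.5, 1, 2, 5, 10\} and the Gamma (shape, scale)
#' pairs over (1,1), (0.5,2), (0.1,10), (0.01,100), (0.001,1000) — all with
#' prior mean 1.
#'
#' @param dataset a [log_dataset()].
#' @param key_actions character vector of key actions.
#' @param control an [msm_control()].
#' @param grid data frame of prior settings, one row per fit, with any of
#'   the columns `sigma_beta`, `sigma_gamma`, `lam_shape`, `lam_scale`,
#'   `theta_shape`, `theta_scale` (missing columns use [msm_priors()]
#'   defaults).
#' @param pars regular expression selecting the monitored parameters.
#' @param ... further arguments passed to [msmlog()].
#' @return Data frame: one row per (setting, parameter) with the prior
#'   columns, posterior `mean`, `sd`, `hpd_lo`, `hpd_hi`.
#' @export
sensitivity_sweep <- function(dataset, key_actions, control,
                              grid = data.frame(sigma_beta = c(0.5, 1, 2, 5, 10)),
                              pars = "^(beta|gamma)", ...) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  out <- NULL
  for (r in seq_len(nrow(grid))) {
    args <- as.list(grid[r, , drop = FALSE])
    pr <- do.call(msm_priors, args[names(args) %in%
      c("sigma_beta", "sigma_gamma", "lam_shape", "lam_scale",
        "theta_shape", "theta_scale")])
    fit <- msmlog(dataset, key_actions = key_actions, priors = pr,
                  control = control, ...)
    sm <- summary(fit, pars = pars)
    out <- rbind(out, cbind(grid[rep(r, nrow(sm)), , drop = FALSE],
                            sm[, c("parameter", "mean", "sd",
                                   "hpd_lo", "hpd_hi")],
                            row.names = NULL))
  }
  rownames(out) <- NULL
  out
}

#' Default prior-sensitivity grids
#'
#' @param which `"normal_sd"`: the sd grid for the normal priors;
#'   `"gamma"`: the (shape, scale) grid for the Gamma priors (every pair has
#'   prior mean shape*scale = 1).
#' @return Data frame usable as the `grid` of [sensitivity_sweep()].
#' @export
sensitivity_grid <- function(which = c("normal_sd", "gamma")) {
  which <- match.arg(which)
  if (which == "normal_sd") {
    s <- c(0.5, 1, 2, 5, 10)
    data.frame(sigma_beta = s, sigma_gamma = s)
  } else {
    data.frame(lam_shape = c(1, 0.5, 0.1, 0.01, 0.001),
               lam_scale = c(1, 2, 10, 100, 1000))
  }
}
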