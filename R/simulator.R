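#' Simulation scenario specification
#'
#' Presets for the four-scenario parameter-recovery design, each a different
#' level of group heterogeneity and key-action effects:
#' \describe{
#'   \item{S1}{no group differences (identical baseline hazards across
#'     groups), no key-action effects, nonzero covariate effects.}
#'   \item{S2}{key-action effects shared by both groups; no baseline-hazard
#'     heterogeneity.}
#'   \item{S3}{group-heterogeneous baseline hazards for a fraction of pairs;
#'     no key-action effects.}
#'   \item{S4}{group-heterogeneous baseline hazards and group-specific
#'     key-action effects.}
#' }
#' Defaults mirror the reference design: 400 individuals, 50 actions of
#' which the first 10 are key actions, 5 covariates drawn from N(0, 4), and
#' negative-binomial sequence lengths. True baseline hazards are drawn once
#' from log-uniform(0.5, 2) under a fixed construction seed so the "true"
#' transition matrices are reproducible; all off-diagonal transitions are
#' possible.
#'
#' @param scenario_id `"S1"`, `"S2"`, `"S3"` or `"S4"`.
#' @param n_individuals,n_actions,n_covariates design sizes.
#' @param covariate_sd standard deviation of the covariates (default 2,
#'   i.e. variance 4).
#' @param seqlen_r,seqlen_p negative-binomial size and probability for the
#'   number of actions per individual (truncated at >= 2); defaults give an
#'   over-dispersed mean of about 28.
#' @param group_prob probability of the correct group.
#' @param key_set key-action labels; default the first 10 (or fewer) action
#'   labels.
#' @param beta true covariate effects (recycled/truncated to
#'   `n_covariates`); `NULL` uses the scenario preset.
#' @param gamma1,gamma2 true key-action effects `c(g0, g1)`; `NULL` uses the
#'   preset.
#' @param hetero_frac,hetero_factor fraction of pairs whose correct-group
#'   hazard is multiplied by `hetero_factor` in S3/S4.
#' @param theta_shape,theta_scale Gamma distribution of the true individual
#'   speeds; set `theta_fixed = TRUE` to force all speeds to 1.
#' @param theta_fixed logical.
#' @param lam_seed fixed construction seed for the true baseline hazards.
#' @param seed data-generation seed.
#' @return An object of class `msm_scenario`.
#' @export
make_scenario <- function(scenario_id = c("S1", "S2", "S3", "S4"),
                          n_individuals = 400L, n_actions = 50L,
                          n_covariates = 5L, covariate_sd = 2,
                          seqlen_r = 5, seqlen_p = 0.15, group_prob = 0.5,
                          key_set = NULL, beta = NULL,
                          gamma1 = NULL, gamma2 = NULL,
                          hetero_frac = 0.3, hetero_factor = 2,
                          theta_shape = 1, theta_scale = 1,
                          theta_fixed = FALSE, lam_seed = 42L, seed = 1L) {
  scenario_id <- match.arg(scenario_id)
  stopifnot(n_actions >= 2L, n_individuals >= 1L, n_covariates >= 0L,
            group_prob > 0, group_prob < 1)
  labels <- action_labels(n_actions)
  if (is.null(key_set))
    key_set <- utils::head(labels, min(10L, n_actions))
  if (!all(key_set %in% labels)) stop("key_set must be a subset of the labels")

  preset_beta <- rep_len(c(0.5, -0.5, 0.25, -0.25, 0.1),
                         max(n_covariates, 1L))[seq_len(n_covariates)]
  if (is.null(beta)) beta <- preset_beta
  beta <- rep_len(beta, n_covariates)
  if (is.null(gamma1))
    gamma1 <- switch(scenario_id,
                     S1 = c(0, 0), S2 = c(0.5, 0.5), S3 = c(0, 0),
                     S4 = c(0.2, 0.6))
  if (is.null(gamma2))
    gamma2 <- switch(scenario_id,
                     S1 = c(0, 0), S2 = c(0.3, 0.3), S3 = c(0, 0),
                     S4 = c(-0.2, 0.4))
  hetero <- scenario_id %in% c("S3", "S4")

  structure(list(
    scenario_id = scenario_id, n_individuals = as.integer(n_individuals),
    n_actions = as.integer(n_actions), labels = labels,
    n_covariates = as.integer(n_covariates), covariate_sd = covariate_sd,
    seqlen_r = seqlen_r, seqlen_p = seqlen_p, group_prob = group_prob,
    key_set = key_set, beta = beta,
    gamma1 = stats::setNames(as.numeric(gamma1), c("0", "1")),
    gamma2 = stats::setNames(as.numeric(gamma2), c("0", "1")),
    hetero = hetero, hetero_frac = hetero_frac,
    hetero_factor = hetero_factor,
    theta_shape = theta_shape, theta_scale = theta_scale,
    theta_fixed = theta_fixed,
    lam_seed = as.integer(lam_seed), seed = as.integer(seed)),
    class = "msm_scenario")
}

action_labels <- function(E) {
  sprintf(paste0("a%0", nchar(as.character(E)), "d"), seq_len(E))
}

#' @export
print.msm_scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario %s: N=%d, E=%d (%d key), p=%d covariates\n",
              x$scenario_id, x$n_individuals, x$n_actions,
              length(x$key_set), x$n_covariates))
  cat(sprintf("  beta = (%s); gamma1 = (%s); gamma2 = (%s); hazard heterogeneity: %s\n",
              paste(x$beta, collapse = ", "),
              paste(x$gamma1, collapse = ", "),
              paste(x$gamma2, collapse = ", "),
              if (x$hetero) sprintf("%d%% of pairs x%g",
                                    round(100 * x$hetero_frac),
                                    x$hetero_factor) else "none"))
  invisible(x)
}

# true baseline hazards on the full off-diagonal support, reproducible
# under the construction seed
true_parameters <- function(spec) {
  E <- spec$n_actions
  sup <- as.matrix(expand.grid(from = seq_len(E), to = seq_len(E)))
  sup <- sup[sup[, 1L] != sup[, 2L], , drop = FALSE]
  sup <- sup[order(sup[, 1L], sup[, 2L]), , drop = FALSE]
  dimnames(sup) <- list(NULL, c("from", "to"))
  old <- .Random.seed_get()
  set.seed(spec$lam_seed)
  lam0 <- exp(stats::runif(nrow(sup), log(0.5), log(2)))
  lam1 <- lam0
  if (spec$hetero) {
    pick <- sample.int(nrow(sup), size = round(spec$hetero_frac * nrow(sup)))
    lam1[pick] <- lam1[pick] * spec$hetero_factor
  }
  .Random.seed_restore(old)
  list(sup = sup, lam = list("0" = lam0, "1" = lam1))
}

# save/restore the RNG state so the fixed construction seed does not
# disturb the caller's stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic log dataset from the model
#'
#' Draws, per individual: a correctness group, i.i.d. normal covariates, a
#' speed factor, and a negative-binomial sequence length (truncated at 2);
#' then runs the continuous-time mechanism — from state m the sojourn is
#' Exponential with the total outgoing hazard and the next state follows
#' the embedded-chain probabilities — for the required number of
#' transitions over the full off-diagonal support. One extra sojourn after
#' the last action sets the total solution time, so the final state's
#' exposure is right-censored exactly as the model assumes. Timestamps are
#' cumulative sojourn sums starting at 0.
#'
#' @param spec an [make_scenario()] specification.
#' @return List with `dataset` (a [log_dataset()]), `params` (the true
#'   [msm_params()] including per-individual speeds) and `spec`.
#' @export
simulate_logs <- function(spec) {
  stopifnot(inherits(spec, "msm_scenario"))
  set.seed(spec$seed)
  tp <- true_parameters(spec)
  N <- spec$n_individuals
  E <- spec$n_actions
  p <- spec$n_covariates
  labels <- spec$labels

  grp <- stats::rbinom(N, 1L, spec$group_prob)
  X <- matrix(stats::rnorm(N * p, 0, spec$covariate_sd), N, p)
  colnames(X) <- if (p) paste0("x", seq_len(p)) else character(0)
  theta <- if (spec$theta_fixed) rep(1, N)
           else stats::rgamma(N, shape = spec$theta_shape,
                              scale = spec$theta_scale)
  J <- stats::rnbinom(N, size = spec$seqlen_r, prob = spec$seqlen_p)
  while (any(J < 2L))
    J[J < 2L] <- stats::rnbinom(sum(J < 2L), size = spec$seqlen_r,
                                prob = spec$seqlen_p)

  ids <- sprintf("id%04d", seq_len(N))
  params <- msm_params(vocabulary = labels,
                       support = list("0" = tp$sup, "1" = tp$sup),
                       lam = tp$lam,
                       theta = stats::setNames(theta, ids),
                       beta = stats::setNames(spec$beta, colnames(X)),
                       gamma1 = spec$gamma1, gamma2 = spec$gamma2,
                       key_set = spec$key_set)
  ds <- simulate_from_params(params, ids = ids, group = grp, X = X, J = J,
                             theta = theta)
  list(dataset = ds, params = params, spec = spec)
}

# core generative mechanism shared by simulate_logs() and simulate.msmlog()
simulate_from_params <- function(params, ids, group, X, J, theta) {
  vocab <- params$vocabulary
  E <- length(vocab)
  N <- length(ids)
  xb <- if (length(params$beta))
    drop(X[, names(params$beta), drop = FALSE] %*% params$beta)
  else rep(0, N)
  phi <- theta * exp(xb)

  # per-group embedded-chain probabilities and total outgoing rates
  P <- list(); rowrate <- list()
  for (g in c("0", "1")) {
    sup <- params$support[[g]]
    H <- matrix(0, E, E)
    H[sup] <- exp(pair_log_hazard(params, g))
    rr <- rowSums(H)
    P[[g]] <- H / ifelse(rr > 0, rr, 1)
    rowrate[[g]] <- rr
  }

  ev_id <- vector("list", N); ev_ac <- vector("list", N)
  ev_ti <- vector("list", N); total_time <- numeric(N)
  for (i in seq_len(N)) {
    g <- as.character(group[i])
    states <- integer(J[i])
    states[1L] <- sample.int(E, 1L)
    jmax <- J[i]
    for (j in seq_len(J[i] - 1L)) {
      pr <- P[[g]][states[j], ]
      if (rowrate[[g]][states[j]] == 0) { jmax <- j; break }  # absorbing
      states[j + 1L] <- sample.int(E, 1L, prob = pr)
    }
    states <- states[seq_len(jmax)]
    rates <- rowrate[[g]][states] * phi[i]
    soj <- ifelse(rates > 0, stats::rexp(jmax, pmax(rates, 1e-300)), 0)
    times <- cumsum(c(0, soj[-jmax]))
    ev_id[[i]] <- rep(ids[i], jmax)
    ev_ac[[i]] <- vocab[states]
    ev_ti[[i]] <- times
    total_time[i] <- times[jmax] + soj[jmax]
  }
  events <- data.frame(respondent_id = unlist(ev_id),
                       action = unlist(ev_ac),
                       time = unlist(ev_ti), stringsAsFactors = FALSE)
  respondents <- data.frame(respondent_id = ids, group = group,
                            total_time = total_time,
                            stringsAsFactors = FALSE)
  if (ncol(X)) respondents <- cbind(respondents, as.data.frame(X))
  log_dataset(events, respondents, vocabulary = vocab)
}

#' Mean squared error between per-individual transition matrices
#'
#' Per individual, the mean of element-wise squared differences over all
#' E x E entries (2,500 when E = 50; unsupported cells are zeros in both);
#' the individual MSEs are then averaged into one summary per run.
#'
#' @param estimated,truth lists of E x E matrices, one per individual, in
#'   the same order.
#' @return Scalar MSE.
#' @export
evaluate_mse <- function(estimated, truth) {
  stopifnot(length(estimated) == length(truth), length(truth) >= 1L)
  per <- mapply(function(a, b) {
    if (!all(dim(a) == dim(b))) stop("matrix shape mismatch")
    mean((a - b)^2)
  }, estimated, truth)
  mean(per)
}

# per-individual plug-in transition matrices for a parameter set
individual_matrices <- function(params, group) {
  Pg <- list("0" = transition_matrix(params, 0),
             "1" = transition_matrix(params, 1))
  for (g in c("0", "1")) {
    P <- Pg[[g]]
    P[is.na(P)] <- 0  # sources with no supported destination contribute zeros
    Pg[[g]] <- P
  }
  lapply(as.character(group), function(g) Pg[[g]])
}

#' Parameter-recovery replications
#'
#' Repeats the full pipeline — generate a dataset from the scenario, fit
#' the model on the full support, form per-individual plug-in transition
#' matrices from posterior means, and score them against the truth with
#' [evaluate_mse()] — once per replication, with the data seed advanced by
#' the replication index. The returned per-run MSEs are boxplot-ready.
#'
#' @param spec an [make_scenario()] specification.
#' @param n_reps number of replications.
#' @param fit_control an [msm_control()] used for every fit.
#' @param priors an [msm_priors()].
#' @return Data frame with columns `rep`, `mse`.
#' @export
run_replications <- function(spec, n_reps, fit_control, priors = msm_priors()) {
  stopifnot(inherits(spec, "msm_scenario"), n_reps >= 1L)
  out <- data.frame(rep = seq_len(n_reps), mse = NA_real_)
  for (r in seq_len(n_reps)) {
    sp <- spec
    sp$seed <- spec$seed + r - 1L
    sim <- simulate_logs(sp)
    ctl <- fit_control
    ctl$seed <- fit_control$seed + r - 1L
    fit <- msmlog(sim$dataset, key_actions = spec$key_set, priors = priors,
                  control = ctl, support = "full")
    est <- individual_matrices(params_from_fit(fit),
                               sim$dataset$respondents$group)
    tru <- individual_matrices(sim$params, sim$dataset$respondents$group)
    out$mse[r] <- evaluate_mse(est, tru)
  }
  out
}
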