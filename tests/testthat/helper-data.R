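# Small fixture builders, all generated in code.

# hand-built two-respondent dataset
tiny_dataset <- function() {
  ev <- data.frame(
    respondent_id = c("r1", "r1", "r1", "r1", "r2", "r2", "r2"),
    action = c("wb", "ss", "ss_file", "so", "wb", "so", "wb"),
    time = c(1.33, 1.37, 1.86, 1.95, 0.4, 1.1, 1.5),
    stringsAsFactors = FALSE)
  re <- data.frame(respondent_id = c("r1", "r2"), group = c(1, 0),
                   total_time = c(2.5, 2.0), z = c(0.3, -1.2),
                   stringsAsFactors = FALSE)
  log_dataset(ev, re)
}

# random small dataset with both groups, generated via the simulator
random_small_dataset <- function(seed, N = 6, E = 4, p = 2) {
  spec <- make_scenario("S2", n_individuals = N, n_actions = E,
                        n_covariates = p, seqlen_r = 4, seqlen_p = 0.4,
                        key_set = action_label(E, 1), seed = seed)
  simulate_logs(spec)$dataset
}

action_label <- function(E, i) {
  sprintf(paste0("a%0", nchar(as.character(E)), "d"), i)
}

# a minimal fake msmlog fit with hand-chosen constant draws, for exercising
# the posterior-comparison layer without running MCMC
fake_fit <- function(vocab, support, lam_draws, gamma2_draws = NULL,
                     key_actions = character(0), n_draws = 30L) {
  stopifnot(is.list(lam_draws))
  cols <- character(0); vals <- numeric(0)
  for (g in c("0", "1")) {
    sup <- support[[g]]
    cols <- c(cols, sprintf("lambda[%s->%s|g=%s]",
                            vocab[sup[, 1]], vocab[sup[, 2]], g))
    vals <- c(vals, lam_draws[[g]])
  }
  if (!is.null(gamma2_draws)) {
    cols <- c(cols, "gamma2[g=0]", "gamma2[g=1]")
    vals <- c(vals, gamma2_draws)
  }
  draws <- matrix(rep(vals, each = n_draws), nrow = n_draws,
                  dimnames = list(NULL, cols))
  structure(list(
    draws = list(draws), acceptance = list(NULL), param_names = cols,
    suffstats = list(vocabulary = vocab, support = support),
    key_actions = key_actions,
    control = msm_control(n_iter = 2, burn_in = 1, thin = 1, n_chains = 1)),
    class = "msmlog")
}
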