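# Independent oracles used across tests. These deliberately avoid the
# package's computational shortcuts: the likelihood oracle re-scans the raw
# event list with scalar hazard_rate() calls, and the chi-square oracle is a
# direct textbook 2x2 computation.

# event-by-event log-likelihood: no sufficient-statistics shortcut
brute_loglik <- function(params, dataset) {
  ll <- 0
  vocab <- params$vocabulary
  for (i in seq_len(nrow(dataset$respondents))) {
    id <- dataset$respondents$respondent_id[i]
    g <- dataset$respondents$group[i]
    Tt <- dataset$respondents$total_time[i]
    x <- as.numeric(dataset$respondents[i, dataset$covariate_names])
    th <- params$theta[[id]]
    ev <- dataset$events[dataset$events$respondent_id == id, , drop = FALSE]
    J <- nrow(ev)
    rate_out <- function(m) {
      sum(vapply(vocab, function(l) hazard_rate(params, g, th, x, m, l),
                 numeric(1)))
    }
    if (J >= 2) {
      for (j in 2:J) {
        m <- ev$action[j - 1]; l <- ev$action[j]
        h <- hazard_rate(params, g, th, x, m, l)
        if (h <= 0) return(-Inf)
        ll <- ll + log(h) - (ev$time[j] - ev$time[j - 1]) * rate_out(m)
      }
    }
    ll <- ll - (Tt - ev$time[J]) * rate_out(ev$action[J])
  }
  ll
}

# textbook chi-square of independence on a 2x2 table, no correction
chi2_oracle <- function(O) {
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  if (any(E == 0)) return(0)
  sum((O - E)^2 / E)
}

# brute-force elbow: maximum perpendicular distance to the chord
elbow_oracle <- function(y) {
  R <- length(y)
  p1 <- c(1, y[1]); p2 <- c(R, y[R])
  v <- p2 - p1
  d <- vapply(seq_len(R), function(r) {
    w <- c(r, y[r]) - p1
    abs(v[1] * w[2] - v[2] * w[1]) / sqrt(sum(v^2))
  }, numeric(1))
  which.max(d)
}

# batch-means Monte Carlo standard error of the mean of an MCMC trace
mcse_mean <- function(x, n_batch = 30) {
  b <- floor(length(x) / n_batch)
  bm <- colMeans(matrix(x[seq_len(b * n_batch)], nrow = b))
  sd(bm) / sqrt(n_batch)
}

# random parameter set over a random support (for property tests)
random_params <- function(E = 4, p = 2, n_theta = 3, seed = 1,
                          full_support = FALSE) {
  set.seed(seed)
  vocab <- paste0("s", seq_len(E))
  sup <- as.matrix(expand.grid(from = seq_len(E), to = seq_len(E)))
  if (!full_support)
    sup <- sup[stats::runif(nrow(sup)) < 0.7, , drop = FALSE]
  # every source needs at least one destination for transition matrices
  missing <- setdiff(seq_len(E), unique(sup[, 1]))
  for (m in missing) sup <- rbind(sup, c(m, sample.int(E, 1)))
  sup <- sup[order(sup[, 1], sup[, 2]), , drop = FALSE]
  dimnames(sup) <- list(NULL, c("from", "to"))
  key <- sample(vocab, max(1, E %/% 3))
  msm_params(
    vocabulary = vocab,
    support = list("0" = sup, "1" = sup),
    lam = list("0" = stats::rgamma(nrow(sup), 2, 1) + 0.05,
               "1" = stats::rgamma(nrow(sup), 2, 1) + 0.05),
    theta = stats::setNames(stats::rgamma(n_theta, 2, 2) + 0.1,
                            paste0("id", seq_len(n_theta))),
    beta = stats::setNames(stats::rnorm(p, 0, 0.5), paste0("x", seq_len(p))),
    gamma1 = c("0" = stats::rnorm(1, 0, 0.3), "1" = stats::rnorm(1, 0, 0.3)),
    gamma2 = c("0" = stats::rnorm(1, 0, 0.3), "1" = stats::rnorm(1, 0, 0.3)),
    key_set = key)
}
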