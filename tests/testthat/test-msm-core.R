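test_that("sufficient statistics account for every sojourn and censoring", {
  ev <- data.frame(respondent_id = rep("r1", 3), action = c("a", "b", "a"),
                   time = c(1.0, 1.5, 2.0))
  re <- data.frame(respondent_id = "r1", group = 1, total_time = 2.5)
  ss <- compute_sufficient_statistics(log_dataset(ev, re))
  cnt <- ss$counts
  expect_equal(nrow(cnt), 2L)
  expect_equal(cnt$count[cnt$from == "a" & cnt$to == "b"], 1L)
  expect_equal(cnt$count[cnt$from == "b" & cnt$to == "a"], 1L)
  expect_equal(ss$exposure["r1", "a"], 0.5 + 0.5)  # sojourn + censored tail
  expect_equal(ss$exposure["r1", "b"], 0.5)

  # single-event respondent contributes pure censored exposure
  ev2 <- data.frame(respondent_id = "r1", action = "a", time = 1.0)
  re2 <- data.frame(respondent_id = "r1", group = 0, total_time = 3.0)
  ss2 <- compute_sufficient_statistics(log_dataset(ev2, re2))
  expect_equal(nrow(ss2$counts), 0L)
  expect_equal(ss2$exposure["r1", "a"], 2.0)
})

test_that("exposure telescopes to total time minus first event time", {
  for (seed in c(2, 8, 15)) {
    ds <- random_small_dataset(seed, N = 8, E = 5)
    ss <- compute_sufficient_statistics(ds)
    expect_equal(unname(rowSums(ss$exposure)),
                 ss$total_time - ss$first_time, tolerance = 1e-9)
    # transition counts per respondent = sequence length - 1
    len <- table(factor(ds$events$respondent_id, levels = ss$ids))
    d_tot <- vapply(ss$ids, function(id)
      sum(ss$counts$count[ss$counts$respondent_id == id]), numeric(1))
    expect_equal(unname(d_tot), as.numeric(len) - 1)
  }
})

test_that("support policies give observed pairs or the full E x E grid", {
  ds <- tiny_dataset()
  obs <- compute_sufficient_statistics(ds, "observed")
  full <- compute_sufficient_statistics(ds, "full")
  E <- length(ds$vocabulary)
  expect_equal(nrow(full$support[["0"]]), E * E)
  expect_equal(nrow(full$support[["1"]]), E * E)
  # observed support contains exactly the group's transitions
  g1 <- obs$support[["1"]]
  expect_equal(nrow(g1), 3L)  # wb->ss, ss->ss_file, ss_file->so
  expect_true(all(paste(obs$counts$from, obs$counts$to)[
    obs$counts$respondent_id == "r1"] %in%
      paste(ds$vocabulary[g1[, 1]], ds$vocabulary[g1[, 2]])))
})

test_that("hazard rate follows the proportional-hazards form", {
  vocab <- c("m", "l", "k")
  sup <- cbind(from = c(1L, 1L), to = c(2L, 3L))
  par <- msm_params(vocab, support = list("0" = sup, "1" = sup),
                    lam = list("0" = c(2, 1), "1" = c(2, 1)),
                    theta = c(id1 = 1.5), beta = c(x = 1),
                    gamma1 = c("0" = -0.2, "1" = -0.2),
                    gamma2 = c("0" = 0, "1" = 0),
                    key_set = "m")
  # lam=2, theta=1.5, x.beta=-0.1, start in key set with gamma1=-0.2
  expect_equal(hazard_rate(par, 1, 1.5, -0.1, "m", "l"), 3 * exp(-0.3),
               tolerance = 1e-12)
  expect_equal(hazard_rate(par, 1, 1.5, -0.1, "m", "l"), 2.222455,
               tolerance = 1e-6)
  # baseline identity at neutral parameters
  par0 <- msm_params(vocab, support = list("0" = sup, "1" = sup),
                     lam = list("0" = c(2, 1), "1" = c(2, 1)),
                     theta = c(id1 = 1))
  expect_equal(hazard_rate(par0, 0, 1, numeric(0), "m", "l"), 2)
  # outside support -> structural zero
  expect_equal(hazard_rate(par0, 0, 1, numeric(0), "l", "m"), 0)
  # multiplicative in theta
  expect_equal(hazard_rate(par, 1, 3, -0.1, "m", "l"),
               2 * hazard_rate(par, 1, 1.5, -0.1, "m", "l"))
})

test_that("log-likelihood matches closed forms on tiny cases", {
  # one a->b transition, exposure t in a: l = log h - h t, maximised at 1/t
  t_exp <- 0.8
  ev <- data.frame(respondent_id = rep("r1", 2), action = c("a", "b"),
                   time = c(0, t_exp))
  re <- data.frame(respondent_id = "r1", group = 1, total_time = t_exp)
  ss <- compute_sufficient_statistics(log_dataset(ev, re))
  llh <- function(h) {
    par <- msm_params(c("a", "b"),
                      support = list("0" = cbind(from = 1L, to = 2L),
                                     "1" = cbind(from = 1L, to = 2L)),
                      lam = list("0" = h, "1" = h), theta = c(r1 = 1))
    msm_log_likelihood(par, ss)
  }
  for (h in c(0.3, 1, 2.7))
    expect_equal(llh(h), log(h) - h * t_exp, tolerance = 1e-12)
  opt <- optimize(llh, c(0.01, 20), maximum = TRUE)
  expect_equal(opt$maximum, 1 / t_exp, tolerance = 1e-4)
})

test_that("sufficient-statistic likelihood equals the brute-force oracle", {
  for (seed in 1:8) {
    ds <- random_small_dataset(seed, N = 5, E = 4, p = 2)
    ss <- compute_sufficient_statistics(ds, "full")
    par <- random_params(E = 4, p = 2, n_theta = 5, seed = seed + 100,
                         full_support = TRUE)
    par$vocabulary <- ds$vocabulary
    par$support <- ss$support
    par$lam <- list("0" = rep_len(par$lam[["0"]], nrow(ss$support[["0"]])),
                    "1" = rep_len(par$lam[["1"]], nrow(ss$support[["1"]])))
    names(par$theta) <- ds$respondents$respondent_id
    names(par$beta) <- ds$covariate_names
    par$key_set <- ds$vocabulary[1]
    expect_equal(msm_log_likelihood(par, ss), brute_loglik(par, ds),
                 tolerance = 1e-9)
  }
})

test_that("likelihood is additive over respondents and scale-confounded", {
  ds <- random_small_dataset(21, N = 6, E = 4, p = 1)
  ss <- compute_sufficient_statistics(ds, "full")
  par <- random_params(E = 4, p = 1, n_theta = 6, seed = 5,
                       full_support = TRUE)
  par$vocabulary <- ds$vocabulary
  par$support <- ss$support
  names(par$theta) <- ds$respondents$respondent_id
  names(par$beta) <- ds$covariate_names
  par$key_set <- ds$vocabulary[2]
  ll <- msm_log_likelihood(par, ss)

  # additivity: sum of single-respondent likelihoods
  parts <- vapply(seq_len(6), function(i) {
    keep <- ds$events$respondent_id == ds$respondents$respondent_id[i]
    di <- log_dataset(ds$events[keep, , drop = FALSE],
                      ds$respondents[i, , drop = FALSE],
                      vocabulary = ds$vocabulary)
    ssi <- compute_sufficient_statistics(di, "full")
    msm_log_likelihood(par, ssi)
  }, numeric(1))
  expect_equal(sum(parts), ll, tolerance = 1e-9)

  # multiplying lambda by c and dividing theta by c changes nothing
  c0 <- 3.7
  par2 <- par
  par2$lam <- lapply(par$lam, `*`, c0)
  par2$theta <- par$theta / c0
  expect_equal(msm_log_likelihood(par2, ss), ll, tolerance = 1e-9)

  # positive count on a zero-hazard pair -> -Inf
  par3 <- par
  par3$support <- lapply(par$support, function(s) s[1:3, , drop = FALSE])
  par3$lam <- lapply(par$lam, function(l) l[1:3])
  expect_equal(msm_log_likelihood(par3, ss), -Inf)
})

test_that("transition matrix rows are stochastic and covariate-invariant", {
  for (seed in 1:20) {
    par <- random_params(E = 5, p = 2, seed = seed)
    for (g in 0:1) {
      P <- transition_matrix(par, g)
      ok <- setdiff(par$vocabulary, attr(P, "undefined_rows"))
      expect_equal(unname(rowSums(P[ok, , drop = FALSE])),
                   rep(1, length(ok)), tolerance = 1e-12)
      # theta and covariates cancel row-wise
      P2 <- transition_matrix(par, g, theta_i = 17, x = c(2, -3))
      expect_equal(P, P2, tolerance = 1e-15)
    }
  }
})

test_that("transition matrix reproduces hand ratios and flags dead ends", {
  vocab <- c("a", "b", "c")
  sup <- cbind(from = c(1L, 1L), to = c(2L, 3L))
  par <- msm_params(vocab, support = list("0" = sup, "1" = sup),
                    lam = list("0" = c(2, 1), "1" = c(2, 1)),
                    gamma2 = c("0" = log(2), "1" = log(2)),
                    key_set = "c")
  # lam(a->b)=2 vs lam(a->c)=1 boosted by gamma2=ln 2 -> 0.5 / 0.5
  P <- transition_matrix(par, 0)
  expect_equal(P["a", "b"], 0.5, tolerance = 1e-12)
  expect_equal(P["a", "c"], 0.5, tolerance = 1e-12)
  expect_setequal(attr(P, "undefined_rows"), c("b", "c"))
  expect_true(all(is.na(P["b", ])))
  # single destination -> probability one; equal hazards -> one half
  par2 <- msm_params(vocab, support = list("0" = sup, "1" = sup),
                     lam = list("0" = c(1, 1), "1" = c(1, 1)))
  expect_equal(transition_matrix(par2, 1)["a", "b"], 0.5)
  sup1 <- cbind(from = 1L, to = 2L)
  par3 <- msm_params(vocab, support = list("0" = sup1, "1" = sup1),
                     lam = list("0" = 4, "1" = 4))
  expect_equal(transition_matrix(par3, 0)["a", "b"], 1)
})

test_that("sufficient statistics export to sparse CSVs", {
  ds <- tiny_dataset()
  ss <- compute_sufficient_statistics(ds)
  d <- withr::local_tempdir()
  p <- file.path(d, c("counts.csv", "expo.csv"))
  write_sufficient_statistics(ss, p[1], p[2])
  cnt <- read.csv(p[1], stringsAsFactors = FALSE)
  expect_equal(sum(cnt$count), nrow(ds$events) - 2L)  # J_i - 1 per respondent
  ex <- read.csv(p[2], stringsAsFactors = FALSE)
  expect_equal(sum(ex$exposure), sum(ss$exposure))
})
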