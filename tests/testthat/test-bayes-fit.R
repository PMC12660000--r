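test_that("log-prior is the sum of the stated closed-form densities", {
  sup <- cbind(from = 1L, to = 2L)
  mk <- function(lam, theta = c(r1 = 1), beta = c(x = 0),
                 g1 = c("0" = 0, "1" = 0), g2 = c("0" = 0, "1" = 0)) {
    p <- msm_params(c("a", "b"), support = list("0" = sup, "1" = sup),
                    lam = list("0" = lam, "1" = lam), theta = theta,
                    beta = beta, gamma1 = g1, gamma2 = g2)
    p
  }
  pr <- msm_priors(sigma_beta = 2, sigma_gamma = 2, lam_shape = 1,
                   lam_scale = 1, theta_shape = 1, theta_scale = 1)
  # Gamma(1,1) log-density at 1 is -1 (three of them: two lambda, one theta);
  # Normal(0, sigma) at 0 contributes -log(sigma sqrt(2 pi)) each
  expect_equal(log_prior(mk(1), pr),
               3 * (-1) + 5 * dnorm(0, 0, 2, log = TRUE), tolerance = 1e-12)
  # exact normal form at nonzero beta
  p2 <- mk(1, beta = c(x = 0.7))
  expect_equal(log_prior(p2, pr) - log_prior(mk(1), pr),
               dnorm(0.7, 0, 2, log = TRUE) - dnorm(0, 0, 2, log = TRUE),
               tolerance = 1e-12)
  # non-positive hazard or speed -> -Inf (bypass constructor validation)
  p3 <- mk(1); p3$lam[["0"]] <- 0
  expect_equal(log_prior(p3, pr), -Inf)
  p4 <- mk(1); p4$theta <- c(r1 = -1)
  expect_equal(log_prior(p4, pr), -Inf)
})

test_that("identical seeds reproduce draws exactly; chains differ otherwise", {
  ds <- random_small_dataset(3, N = 10, E = 4, p = 1)
  ctl <- msm_control(n_iter = 400, burn_in = 100, thin = 2, n_chains = 2,
                     seed = 5)
  f1 <- msmlog(ds, key_actions = "a1", control = ctl)
  f2 <- msmlog(ds, key_actions = "a1", control = ctl)
  expect_identical(f1$draws, f2$draws)
  expect_false(identical(f1$draws[[1]], f1$draws[[2]]))
})

test_that("single free hazard matches the conjugate gamma posterior", {
  # all parameters fixed except lambda: the marginal must be
  # Gamma(a + d, s / (1 + s e)) for d events and exposure e
  ev <- data.frame(respondent_id = rep("r1", 5),
                   action = c("a", "b", "a", "b", "a"),
                   time = c(0, 0.6, 1.1, 1.9, 2.4))
  re <- data.frame(respondent_id = "r1", group = 0, total_time = 3.1)
  ds <- log_dataset(ev, re)
  a <- 1.5; s <- 0.8
  fit <- msmlog(ds, priors = msm_priors(lam_shape = a, lam_scale = s),
                control = msm_control(n_iter = 12000, burn_in = 2000,
                                      thin = 1, n_chains = 1, seed = 42),
                update = "lambda", init = list(theta = 1))
  dr <- fit$draws[[1]]
  ss <- compute_sufficient_statistics(ds)
  e_a <- ss$exposure["r1", "a"]  # exposure in 'a' incl. censored tail
  d_ab <- 2
  shape <- a + d_ab; scale <- s / (1 + s * e_a)
  x <- dr[, "lambda[a->b|g=0]"]
  expect_lt(abs(mean(x) - shape * scale), 3 * mcse_mean(x))
  v <- (x - mean(x))^2
  expect_lt(abs(mean(v) - shape * scale^2), 3 * mcse_mean(v))
})

test_that("acceptance rates settle inside the adaptation window", {
  spec <- make_scenario("S1", n_individuals = 40, n_actions = 5,
                        n_covariates = 2, key_set = c("a1", "a2"), seed = 2)
  sim <- simulate_logs(spec)
  fit <- msmlog(sim$dataset, key_actions = spec$key_set,
                control = msm_control(n_iter = 3000, burn_in = 1500,
                                      thin = 5, n_chains = 1, seed = 9,
                                      adapt_interval = 100))
  acc <- fit$acceptance[[1]]
  expect_true(all(acc >= 0.2 - 0.05))
  expect_true(all(acc <= 0.5 + 0.05))
})

test_that("Gelman-Rubin follows its closed form and flags divergence", {
  n <- 200
  base <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("p1", "p2")))
  # identical chains: B = 0 so R-hat = sqrt((n-1)/n)
  r <- gelman_rubin(list(base, base))
  expect_equal(unname(r), rep(sqrt((n - 1) / n), 2), tolerance = 1e-12)
  # same-distribution chains at large n: R-hat near 1
  set.seed(1)
  big <- function() matrix(rnorm(10000), ncol = 1,
                           dimnames = list(NULL, "p"))
  r2 <- gelman_rubin(list(big(), big()))
  expect_lt(abs(r2[["p"]] - 1), 0.01)
  # chains centred 10 apart: far beyond the 1.1 threshold
  r3 <- gelman_rubin(list(big(), big() + 10))
  expect_gt(r3[["p"]], 1.1)
  # direct check against the plug-in formula on arbitrary chains
  set.seed(7)
  c1 <- matrix(rnorm(50, 0, 1), ncol = 1, dimnames = list(NULL, "q"))
  c2 <- matrix(rnorm(50, 0.4, 2), ncol = 1, dimnames = list(NULL, "q"))
  W <- mean(c(var(c1), var(c2)))
  B <- 50 * var(c(mean(c1), mean(c2)))
  expect_equal(unname(gelman_rubin(list(c1, c2))),
               sqrt(((49 / 50) * W + B / 50) / W), tolerance = 1e-12)
  expect_error(gelman_rubin(list(c1)), "2")
})

test_that("HPD intervals are shortest intervals at the stated mass", {
  expect_equal(hpd_interval(rep(3.3, 25)), c(3.3, 3.3))
  set.seed(11)
  z <- rnorm(1e6)
  h <- hpd_interval(z)
  expect_equal(h[1], qnorm(0.025), tolerance = 0.02)
  expect_equal(h[2], qnorm(0.975), tolerance = 0.02)
  # asymmetry preserved and shorter than the equal-tail interval
  e <- rexp(2e5)
  he <- hpd_interval(e)
  eq <- quantile(e, c(0.025, 0.975))
  expect_lt(he[1], 0.05)
  expect_lt(diff(he), diff(eq))
  expect_error(hpd_interval(z, level = 1.2), "level")
  expect_error(hpd_interval(rnorm(5)), "20")
})

test_that("significance reads the HPD-excludes-zero rule with sign", {
  set.seed(3)
  sym <- rnorm(500)
  expect_false(significance(sym)$significant)
  expect_equal(significance(sym)$sign, 0L)
  pos <- rexp(500) + 0.01
  expect_true(significance(pos)$significant)
  expect_equal(significance(pos)$sign, 1L)
  weak <- rnorm(100, mean = 0.1)
  expect_false(significance(weak)$significant)
})

test_that("a singleton sensitivity grid reproduces a single fit", {
  ds <- random_small_dataset(6, N = 12, E = 4, p = 1)
  ctl <- msm_control(n_iter = 500, burn_in = 200, thin = 3, n_chains = 1,
                     seed = 4)
  sw <- sensitivity_sweep(ds, key_actions = "a1", control = ctl,
                          grid = data.frame(sigma_beta = 2))
  fit <- msmlog(ds, key_actions = "a1",
                priors = msm_priors(sigma_beta = 2), control = ctl)
  sm <- summary(fit, pars = "^(beta|gamma)")
  expect_equal(sw$mean, sm$mean, tolerance = 1e-12)
  expect_equal(sw$hpd_lo, sm$hpd_lo, tolerance = 1e-12)
})

test_that("the canonical gamma prior grid keeps prior mean one", {
  g <- sensitivity_grid("gamma")
  expect_equal(g$lam_shape * g$lam_scale, rep(1, 5))
  s <- sensitivity_grid("normal_sd")
  expect_equal(s$sigma_beta, c(0.5, 1, 2, 5, 10))
})

test_that("renormalization fixes the speed scale without changing fit", {
  ds <- random_small_dataset(9, N = 10, E = 4, p = 1)
  fit <- msmlog(ds, key_actions = "a1",
                control = msm_control(n_iter = 600, burn_in = 200, thin = 2,
                                      n_chains = 1, seed = 8))
  rn <- renormalize_scale(fit)
  dr <- rn$draws[[1]]
  ith <- grep("^theta\\[", colnames(dr))
  gm <- exp(rowMeans(log(dr[, ith])))
  expect_equal(unname(gm), rep(1, nrow(dr)), tolerance = 1e-12)
  # lambda * theta products per draw are preserved for any pair
  d0 <- fit$draws[[1]]
  la <- grep("^lambda\\[", colnames(dr))[1]
  expect_equal(dr[, la] * dr[, ith[1]], d0[, la] * d0[, ith[1]],
               tolerance = 1e-12)
})

test_that("posterior summary carries HPD, R-hat and significance columns", {
  ds <- random_small_dataset(14, N = 10, E = 4, p = 1)
  fit <- msmlog(ds, key_actions = "a1",
                control = msm_control(n_iter = 600, burn_in = 200, thin = 2,
                                      n_chains = 2, seed = 3))
  sm <- summary(fit)
  expect_true(all(sm$hpd_lo <= sm$mean & sm$mean <= sm$hpd_hi))
  expect_true(all(is.finite(sm$rhat)))
  expect_identical(sm$significant, sm$hpd_lo > 0 | sm$hpd_hi < 0)
  lam_rows <- grepl("^lambda|^theta", sm$parameter)
  expect_true(all(sm$mean[lam_rows] > 0))
})
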