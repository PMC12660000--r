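# Metropolis-within-Gibbs engine for the action-transition MSM.
#
# Every scalar parameter is its own Metropolis block. Given the rest of the
# state, the baseline hazards lambda are mutually conditionally independent
# (the log-target is additive over support pairs), as are the individual
# speeds theta, so those blocks are proposed and accepted element-wise in
# one vectorised sweep; beta and gamma are updated as sequential scalars.
# lambda and theta use Gaussian random walks on the log scale (Jacobian
# included); beta and gamma use Gaussian random walks on the natural scale.
#
# The multiplicative structure of the hazard leaves soft ridges in the
# posterior: the likelihood is exactly invariant under lambda*c, theta/c,
# under beta_k + d with theta_i * exp(-x_ik d), and under gamma + d with
# the key-row (or key-column) lambdas times exp(-d); only the priors
# identify these directions. Single-site updates diffuse slowly along such
# ridges, so each cycle additionally proposes likelihood-invariant "ridge"
# moves along them, accepted by the prior ratio times the transformation
# Jacobian. These are standard reparameterisation Metropolis moves and are
# adapted (burn-in only) like every other block.

# Precompute everything the conditionals need from the sufficient statistics.
build_mcmc_data <- function(suffstats, key_actions) {
  vocab <- suffstats$vocabulary
  E <- length(vocab)
  ids <- suffstats$ids
  N <- length(ids)
  grp <- suffstats$group
  X <- suffstats$X
  key_state <- vocab %in% key_actions

  cnt <- suffstats$counts
  ridx <- match(cnt$respondent_id, ids)
  fidx <- match(cnt$from, vocab)
  tidx <- match(cnt$to, vocab)

  per_group <- list()
  for (g in c("0", "1")) {
    sup <- suffstats$support[[g]]
    S <- nrow(sup)
    d <- numeric(S)
    ing <- which(grp[ridx] == as.integer(g))
    if (length(ing)) {
      key <- paste(sup[, 1L], sup[, 2L])
      pos <- match(paste(fidx[ing], tidx[ing]), key)
      if (anyNA(pos))
        stop("observed transition outside the group support; use support = \"full\"")
      agg <- rowsum(cnt$count[ing], group = pos)
      d[as.integer(rownames(agg))] <- agg
    }
    keym <- key_state[sup[, 1L]]
    keyl <- key_state[sup[, 2L]]
    per_group[[g]] <- list(
      sup = sup, S = S, d = d, keym = keym, keyl = keyl,
      idx = which(grp == as.integer(g)),
      dkey1 = sum(d[keym]), dkey2 = sum(d[keyl]))
  }

  D <- numeric(N)
  if (nrow(cnt)) {
    agg <- rowsum(cnt$count, group = ridx)
    D[as.integer(rownames(agg))] <- agg
  }
  Tx <- if (ncol(X)) drop(crossprod(X, D)) else numeric(0)

  list(vocab = vocab, E = E, ids = ids, N = N, grp = grp, X = X, p = ncol(X),
       Emat = suffstats$exposure, key_state = key_state, D = D, Tx = Tx,
       per_group = per_group)
}

# Initial state: empirical hazards (floored), unit speeds, zero effects;
# entries of `init` override.
initial_state <- function(md, init = NULL) {
  lam <- list()
  for (g in c("0", "1")) {
    pg <- md$per_group[[g]]
    e_from <- colSums(md$Emat[pg$idx, , drop = FALSE])[pg$sup[, 1L]]
    lam[[g]] <- ifelse(e_from > 0, pg$d / e_from, 1)
    lam[[g]] <- pmax(lam[[g]], 1e-3)
  }
  st <- list(lam = lam,
             theta = stats::setNames(rep(1, md$N), md$ids),
             beta = stats::setNames(rep(0, md$p), colnames(md$X)),
             gamma1 = c("0" = 0, "1" = 0), gamma2 = c("0" = 0, "1" = 0))
  if (!is.null(init)) {
    for (nm in intersect(names(init), names(st))) {
      v <- init[[nm]]
      if (nm == "lam") {
        for (g in intersect(names(v), c("0", "1"))) {
          stopifnot(length(v[[g]]) %in% c(1L, length(st$lam[[g]])))
          st$lam[[g]] <- rep_len(v[[g]], length(st$lam[[g]]))
        }
      } else {
        stopifnot(length(v) %in% c(1L, length(st[[nm]])))
        st[[nm]] <- stats::setNames(rep_len(v, length(st[[nm]])),
                                    names(st[[nm]]))
      }
    }
  }
  st
}

# total modified rate out of each source state for group g:
# rowrate[m] = sum_l lambda_mlg * exp(gamma2_g key[l]); length E (zeros where
# the state has no outgoing support)
group_rowrate <- function(md, st, g) {
  pg <- md$per_group[[g]]
  out <- numeric(md$E)
  if (pg$S) {
    lt <- st$lam[[g]] * exp(st$gamma2[[g]] * pg$keyl)
    agg <- rowsum(lt, group = pg$sup[, 1L])
    out[as.integer(rownames(agg))] <- agg
  }
  out
}

run_chain <- function(md, priors, control, chain_seed, init = NULL,
                      update = c("lambda", "theta", "beta", "gamma")) {
  set.seed(chain_seed)
  st <- initial_state(md, init)
  E <- md$E; N <- md$N; p <- md$p
  up_lam <- "lambda" %in% update
  up_theta <- "theta" %in% update
  up_beta <- "beta" %in% update && p > 0
  up_gamma <- "gamma" %in% update
  # ridge moves only make sense when both ends of the ridge are sampled
  ridge_scale <- up_lam && up_theta
  ridge_beta <- up_beta && up_theta
  ridge_gamma <- up_gamma && up_lam
  groups <- c("0", "1")[vapply(c("0", "1"), function(g)
    length(md$per_group[[g]]$idx) > 0 && md$per_group[[g]]$S > 0, logical(1))]

  # proposal scales and acceptance bookkeeping, one entry per scalar block
  sd_lam <- lapply(st$lam, function(v) rep(0.5, length(v)))
  sd_theta <- rep(0.5, N)
  sd_beta <- rep(0.1, p)
  sd_gam1 <- c(0.3, 0.3); sd_gam2 <- c(0.3, 0.3)
  sd_rsc <- 0.1; sd_rbeta <- rep(0.05, p)
  sd_rg1 <- c(0.2, 0.2); sd_rg2 <- c(0.2, 0.2)
  win_lam <- lapply(st$lam, function(v) numeric(length(v)))
  win_theta <- numeric(N); win_beta <- numeric(p)
  win_gam1 <- numeric(2); win_gam2 <- numeric(2)
  win_rsc <- 0; win_rbeta <- numeric(p)
  win_rg1 <- numeric(2); win_rg2 <- numeric(2)
  post_lam <- lapply(st$lam, function(v) numeric(length(v)))
  post_theta <- numeric(N); post_beta <- numeric(p)
  post_gam1 <- numeric(2); post_gam2 <- numeric(2)
  post_rsc <- 0; post_rbeta <- numeric(p)
  post_rg1 <- numeric(2); post_rg2 <- numeric(2)

  ilamsc <- 1 / priors$lam_scale
  ithsc <- 1 / priors$theta_scale
  a_lam <- priors$lam_shape
  a_th <- priors$theta_shape
  isb2 <- 1 / (2 * priors$sigma_beta^2)
  isg2 <- 1 / (2 * priors$sigma_gamma^2)

  xb <- if (p) drop(md$X %*% st$beta) else rep(0, N)
  expxb <- exp(xb)

  n_keep <- (control$n_iter - control$burn_in) %/% control$thin
  par_names <- mcmc_param_names(md, update, groups)
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  kept <- 0L
  n_post <- control$n_iter - control$burn_in

  for (iter in seq_len(control$n_iter)) {
    in_burn <- iter <= control$burn_in
    phi <- st$theta * expxb

    if (up_lam) {
      for (g in groups) {
        pg <- md$per_group[[g]]
        G <- drop(crossprod(md$Emat[pg$idx, , drop = FALSE], phi[pg$idx]))
        C <- exp(st$gamma1[[g]] * pg$keym + st$gamma2[[g]] * pg$keyl) *
          G[pg$sup[, 1L]]
        lam <- st$lam[[g]]
        loglam <- log(lam)
        prop <- loglam + sd_lam[[g]] * stats::rnorm(pg$S)
        lam_p <- exp(prop)
        # conditional on log scale: (d + a) log lam - lam (C + 1/scale)
        delta <- (pg$d + a_lam) * (prop - loglam) -
          (lam_p - lam) * (C + ilamsc)
        acc <- log(stats::runif(pg$S)) < delta
        st$lam[[g]][acc] <- lam_p[acc]
        if (in_burn) win_lam[[g]][acc] <- win_lam[[g]][acc] + 1
        else post_lam[[g]][acc] <- post_lam[[g]][acc] + 1
      }
    }

    if (up_theta || up_beta || up_gamma) {
      romod <- matrix(0, E, 2L)
      for (g in groups) {
        gi <- as.integer(g) + 1L
        romod[, gi] <- exp(st$gamma1[[g]] * md$key_state) *
          group_rowrate(md, st, g)
      }
      WM <- md$Emat %*% romod
      W <- WM[cbind(seq_len(N), md$grp + 1L)]  # sum_m e_im * modified rate
    }

    if (up_theta) {
      theta <- st$theta
      logth <- log(theta)
      prop <- logth + sd_theta * stats::rnorm(N)
      th_p <- exp(prop)
      R <- expxb * W
      delta <- (md$D + a_th) * (prop - logth) - (th_p - theta) * (R + ithsc)
      acc <- log(stats::runif(N)) < delta
      st$theta[acc] <- th_p[acc]
      if (in_burn) win_theta[acc] <- win_theta[acc] + 1
      else post_theta[acc] <- post_theta[acc] + 1
    }

    if (up_beta) {
      thW <- st$theta * W
      for (k in seq_len(p)) {
        bk <- st$beta[k]
        bk_p <- bk + sd_beta[k] * stats::rnorm(1L)
        xb_p <- xb + md$X[, k] * (bk_p - bk)
        expxb_p <- exp(xb_p)
        delta <- md$Tx[k] * (bk_p - bk) - sum(thW * (expxb_p - expxb)) -
          isb2 * (bk_p^2 - bk^2)
        if (log(stats::runif(1L)) < delta) {
          st$beta[k] <- bk_p
          xb <- xb_p
          expxb <- expxb_p
          if (in_burn) win_beta[k] <- win_beta[k] + 1
          else post_beta[k] <- post_beta[k] + 1
        }
      }
      phi <- st$theta * expxb
    }

    if (up_gamma) {
      phi <- st$theta * expxb
      for (g in groups) {
        gi <- as.integer(g) + 1L
        pg <- md$per_group[[g]]
        G <- drop(crossprod(md$Emat[pg$idx, , drop = FALSE], phi[pg$idx]))
        rr <- group_rowrate(md, st, g)  # depends on current gamma2
        # gamma1: only key source states involve it
        SK <- sum(G[md$key_state] * rr[md$key_state])
        g1 <- st$gamma1[[g]]
        g1_p <- g1 + sd_gam1[gi] * stats::rnorm(1L)
        delta <- pg$dkey1 * (g1_p - g1) - (exp(g1_p) - exp(g1)) * SK -
          isg2 * (g1_p^2 - g1^2)
        if (log(stats::runif(1L)) < delta) {
          st$gamma1[[g]] <- g1_p
          if (in_burn) win_gam1[gi] <- win_gam1[gi] + 1
          else post_gam1[gi] <- post_gam1[gi] + 1
        }
        # gamma2: only key destination columns involve it
        keyout <- numeric(E)
        if (any(pg$keyl)) {
          agg <- rowsum(st$lam[[g]][pg$keyl],
                        group = pg$sup[pg$keyl, 1L, drop = TRUE])
          keyout[as.integer(rownames(agg))] <- agg
        }
        Gm1 <- G * exp(st$gamma1[[g]] * md$key_state)
        SK2 <- sum(Gm1 * keyout)
        g2 <- st$gamma2[[g]]
        g2_p <- g2 + sd_gam2[gi] * stats::rnorm(1L)
        delta <- pg$dkey2 * (g2_p - g2) - (exp(g2_p) - exp(g2)) * SK2 -
          isg2 * (g2_p^2 - g2^2)
        if (log(stats::runif(1L)) < delta) {
          st$gamma2[[g]] <- g2_p
          if (in_burn) win_gam2[gi] <- win_gam2[gi] + 1
          else post_gam2[gi] <- post_gam2[gi] + 1
        }
      }
    }

    # likelihood-invariant ridge moves: accepted on prior ratio + Jacobian
    if (ridge_scale) {
      dlt <- sd_rsc * stats::rnorm(1L)
      Ssum <- sum(vapply(groups, function(g) sum(st$lam[[g]]), numeric(1)))
      Stot <- sum(vapply(groups, function(g) md$per_group[[g]]$S, numeric(1)))
      logA <- a_th * N * dlt - a_lam * Stot * dlt -
        (exp(dlt) - 1) * sum(st$theta) * ithsc -
        (exp(-dlt) - 1) * Ssum * ilamsc
      if (log(stats::runif(1L)) < logA) {
        st$theta <- st$theta * exp(dlt)
        for (g in groups) st$lam[[g]] <- st$lam[[g]] * exp(-dlt)
        if (in_burn) win_rsc <- win_rsc + 1 else post_rsc <- post_rsc + 1
      }
    }
    if (ridge_beta) {
      for (k in seq_len(p)) {
        dlt <- sd_rbeta[k] * stats::rnorm(1L)
        xk <- md$X[, k]
        bk <- st$beta[k]
        fac <- exp(-xk * dlt)
        logA <- (bk^2 - (bk + dlt)^2) * isb2 -
          a_th * dlt * sum(xk) -
          sum(st$theta * (fac - 1)) * ithsc
        if (log(stats::runif(1L)) < logA) {
          st$beta[k] <- bk + dlt
          st$theta <- st$theta * fac
          xb <- xb + xk * dlt
          expxb <- exp(xb)
          if (in_burn) win_rbeta[k] <- win_rbeta[k] + 1
          else post_rbeta[k] <- post_rbeta[k] + 1
        }
      }
    }
    if (ridge_gamma) {
      for (g in groups) {
        gi <- as.integer(g) + 1L
        pg <- md$per_group[[g]]
        if (any(pg$keym)) {
          dlt <- sd_rg1[gi] * stats::rnorm(1L)
          g1 <- st$gamma1[[g]]
          logA <- (g1^2 - (g1 + dlt)^2) * isg2 -
            a_lam * dlt * sum(pg$keym) -
            (exp(-dlt) - 1) * sum(st$lam[[g]][pg$keym]) * ilamsc
          if (log(stats::runif(1L)) < logA) {
            st$gamma1[[g]] <- g1 + dlt
            st$lam[[g]][pg$keym] <- st$lam[[g]][pg$keym] * exp(-dlt)
            if (in_burn) win_rg1[gi] <- win_rg1[gi] + 1
            else post_rg1[gi] <- post_rg1[gi] + 1
          }
        }
        if (any(pg$keyl)) {
          dlt <- sd_rg2[gi] * stats::rnorm(1L)
          g2 <- st$gamma2[[g]]
          logA <- (g2^2 - (g2 + dlt)^2) * isg2 -
            a_lam * dlt * sum(pg$keyl) -
            (exp(-dlt) - 1) * sum(st$lam[[g]][pg$keyl]) * ilamsc
          if (log(stats::runif(1L)) < logA) {
            st$gamma2[[g]] <- g2 + dlt
            st$lam[[g]][pg$keyl] <- st$lam[[g]][pg$keyl] * exp(-dlt)
            if (in_burn) win_rg2[gi] <- win_rg2[gi] + 1
            else post_rg2[gi] <- post_rg2[gi] + 1
          }
        }
      }
    }

    # burn-in-only adaptation of proposal scales
    if (in_burn && iter %% control$adapt_interval == 0L) {
      tune <- function(sd, acc_count) {
        rate <- acc_count / control$adapt_interval
        sd * ifelse(rate > control$accept_high, 1.5,
                    ifelse(rate < control$accept_low, 0.67, 1))
      }
      for (g in groups) {
        sd_lam[[g]] <- tune(sd_lam[[g]], win_lam[[g]])
        win_lam[[g]][] <- 0
      }
      sd_theta <- tune(sd_theta, win_theta); win_theta[] <- 0
      if (p) { sd_beta <- tune(sd_beta, win_beta); win_beta[] <- 0 }
      sd_gam1 <- tune(sd_gam1, win_gam1); win_gam1[] <- 0
      sd_gam2 <- tune(sd_gam2, win_gam2); win_gam2[] <- 0
      sd_rsc <- tune(sd_rsc, win_rsc); win_rsc <- 0
      if (p) { sd_rbeta <- tune(sd_rbeta, win_rbeta); win_rbeta[] <- 0 }
      sd_rg1 <- tune(sd_rg1, win_rg1); win_rg1[] <- 0
      sd_rg2 <- tune(sd_rg2, win_rg2); win_rg2[] <- 0
    }

    if (!in_burn && (iter - control$burn_in) %% control$thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- flatten_state(st, md, update, groups)
    }
  }

  acc_rates <- c()
  if (up_lam) for (g in groups)
    acc_rates <- c(acc_rates, post_lam[[g]] / n_post)
  if (up_theta) acc_rates <- c(acc_rates, post_theta / n_post)
  if (up_beta) acc_rates <- c(acc_rates, post_beta / n_post)
  if (up_gamma) for (g in groups) {
    gi <- as.integer(g) + 1L
    acc_rates <- c(acc_rates, post_gam1[gi] / n_post, post_gam2[gi] / n_post)
  }
  names(acc_rates) <- par_names
  if (ridge_scale)
    acc_rates <- c(acc_rates, "ridge:scale" = post_rsc / n_post)
  if (ridge_beta)
    acc_rates <- c(acc_rates, stats::setNames(
      post_rbeta / n_post, sprintf("ridge:beta[%s]", colnames(md$X))))
  if (ridge_gamma) for (g in groups) {
    gi <- as.integer(g) + 1L
    pg <- md$per_group[[g]]
    if (any(pg$keym))
      acc_rates <- c(acc_rates, stats::setNames(
        post_rg1[gi] / n_post, sprintf("ridge:gamma1[g=%s]", g)))
    if (any(pg$keyl))
      acc_rates <- c(acc_rates, stats::setNames(
        post_rg2[gi] / n_post, sprintf("ridge:gamma2[g=%s]", g)))
  }

  list(draws = draws[seq_len(kept), , drop = FALSE],
       acceptance = acc_rates, final_state = st,
       proposal_sd = list(lam = sd_lam, theta = sd_theta, beta = sd_beta,
                          gamma1 = sd_gam1, gamma2 = sd_gam2))
}

mcmc_param_names <- function(md, update, groups) {
  nm <- character(0)
  if ("lambda" %in% update) for (g in groups) {
    sup <- md$per_group[[g]]$sup
    nm <- c(nm, sprintf("lambda[%s->%s|g=%s]", md$vocab[sup[, 1L]],
                        md$vocab[sup[, 2L]], g))
  }
  if ("theta" %in% update) nm <- c(nm, sprintf("theta[%s]", md$ids))
  if ("beta" %in% update && md$p > 0)
    nm <- c(nm, sprintf("beta[%s]", colnames(md$X)))
  if ("gamma" %in% update) for (g in groups)
    nm <- c(nm, sprintf("gamma1[g=%s]", g), sprintf("gamma2[g=%s]", g))
  nm
}

flatten_state <- function(st, md, update, groups) {
  out <- numeric(0)
  if ("lambda" %in% update) for (g in groups) out <- c(out, st$lam[[g]])
  if ("theta" %in% update) out <- c(out, st$theta)
  if ("beta" %in% update && md$p > 0) out <- c(out, st$beta)
  if ("gamma" %in% update) for (g in groups)
    out <- c(out, st$gamma1[[g]], st$gamma2[[g]])
  out
}
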