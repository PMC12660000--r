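#' Parameter set of the action-transition multi-state model
#'
#' Bundles the parameters of the proportional-hazards multi-state model for
#' action logs: group-specific baseline transition hazards `lambda[m->l,g]`
#' on a per-group support of ordered action pairs, individual speed factors
#' `theta_i`, shared covariate coefficients `beta`, and group-specific
#' key-action effects `gamma1` (key start action) and `gamma2` (key end
#' action).
#'
#' @param vocabulary character vector of action states (defines indices).
#' @param support list with elements `"0"` and `"1"`, each a two-column
#'   integer matrix of (from, to) state indices giving the permitted
#'   transitions for that group.
#' @param lam list with elements `"0"` and `"1"`, positive numeric vectors of
#'   baseline hazards aligned with the rows of `support`.
#' @param theta named positive numeric vector of individual speeds.
#' @param beta named numeric vector of covariate coefficients (possibly
#'   length 0).
#' @param gamma1,gamma2 numeric length-2 vectors `c("0" = , "1" = )`: effect
#'   of the start (resp. end) action being a key action, per group.
#' @param key_set character vector of key actions (subset of `vocabulary`).
#' @return An object of class `msm_params`.
#' @export
msm_params <- function(vocabulary, support, lam, theta = numeric(0),
                       beta = numeric(0),
                       gamma1 = c("0" = 0, "1" = 0),
                       gamma2 = c("0" = 0, "1" = 0),
                       key_set = character(0)) {
  stopifnot(is.character(vocabulary), length(vocabulary) >= 1L,
            all(c("0", "1") %in% names(support)),
            all(c("0", "1") %in% names(lam)))
  for (g in c("0", "1")) {
    stopifnot(is.matrix(support[[g]]), ncol(support[[g]]) == 2L,
              length(lam[[g]]) == nrow(support[[g]]))
    if (length(lam[[g]]) && any(lam[[g]] <= 0)) stop("lambda must be > 0")
  }
  if (length(theta) && any(theta <= 0)) stop("theta must be > 0")
  if (!all(key_set %in% vocabulary)) stop("key_set not contained in vocabulary")
  gamma1 <- stats::setNames(as.numeric(gamma1), c("0", "1"))
  gamma2 <- stats::setNames(as.numeric(gamma2), c("0", "1"))
  structure(list(vocabulary = vocabulary, support = support, lam = lam,
                 theta = theta, beta = beta, gamma1 = gamma1,
                 gamma2 = gamma2, key_set = key_set),
            class = "msm_params")
}

#' Sufficient statistics of the multi-state likelihood
#'
#' Reduces a log dataset to the transition counts and state exposure times
#' that the likelihood depends on. Each consecutive event pair contributes
#' one transition count and one sojourn; the trailing interval from the last
#' event to the total solution time adds right-censored exposure to the last
#' state. Time before the first event is not modelled: a respondent enters
#' the state of their first action at that action's timestamp.
#'
#' @param dataset a [log_dataset()].
#' @param support_policy `"observed"` (default): a group's support is the set
#'   of ordered pairs observed at least once in that group — structural zeros
#'   keep the model identified when most of the E*E pairs carry no data;
#'   `"full"`: all E*E ordered pairs (used in simulation studies where every
#'   transition is possible).
#' @return An object of class `msm_suffstats`: per-respondent sparse
#'   transition counts (`counts`: respondent_id, from, to, count), an
#'   N x E `exposure` matrix in minutes, per-group support matrices, group
#'   and covariate data, and bookkeeping (first event time, total time).
#' @export
compute_sufficient_statistics <- function(dataset,
                                          support_policy = c("observed", "full")) {
  stopifnot(inherits(dataset, "log_dataset"))
  support_policy <- match.arg(support_policy)
  vocab <- dataset$vocabulary
  E <- length(vocab)
  ids <- dataset$respondents$respondent_id
  N <- length(ids)

  ev <- dataset$events
  ridx <- match(ev$respondent_id, ids)
  aidx <- match(ev$action, vocab)

  # consecutive pairs within each respondent
  n_ev <- nrow(ev)
  same <- ridx[-1L] == ridx[-n_ev]
  from <- aidx[-n_ev][same]
  to <- aidx[-1L][same]
  pr <- ridx[-n_ev][same]
  gap <- (ev$time[-1L] - ev$time[-n_ev])[same]

  counts <- if (length(from)) {
    stats::aggregate(list(count = rep.int(1L, length(from))),
                     by = list(respondent = pr, from = from, to = to),
                     FUN = sum)
  } else {
    data.frame(respondent = integer(0), from = integer(0), to = integer(0),
               count = integer(0))
  }

  exposure <- matrix(0, N, E, dimnames = list(ids, vocab))
  if (length(from)) {
    sexp <- stats::aggregate(list(expo = gap),
                             by = list(respondent = pr, state = from),
                             FUN = sum)
    exposure[cbind(sexp$respondent, sexp$state)] <- sexp$expo
  }
  # right-censored trailing sojourn in the last state
  last <- c(ridx[-1L] != ridx[-n_ev], TRUE)
  first <- c(TRUE, ridx[-1L] != ridx[-n_ev])
  t_last <- ev$time[last]
  r_last <- ridx[last]
  tail_exp <- dataset$respondents$total_time[r_last] - t_last
  exposure[cbind(r_last, aidx[last])] <-
    exposure[cbind(r_last, aidx[last])] + tail_exp

  grp <- dataset$respondents$group
  support <- list()
  for (g in c("0", "1")) {
    if (support_policy == "full") {
      support[[g]] <- as.matrix(expand.grid(from = seq_len(E), to = seq_len(E)))
    } else {
      ing <- grp[counts$respondent] == as.integer(g)
      pg <- unique(counts[ing, c("from", "to")])
      pg <- pg[order(pg$from, pg$to), , drop = FALSE]
      support[[g]] <- as.matrix(pg)
    }
    dimnames(support[[g]]) <- list(NULL, c("from", "to"))
  }

  X <- as.matrix(dataset$respondents[, dataset$covariate_names, drop = FALSE])
  rownames(X) <- ids
  structure(list(
    counts = data.frame(respondent_id = ids[counts$respondent],
                        from = vocab[counts$from], to = vocab[counts$to],
                        count = counts$count, stringsAsFactors = FALSE),
    exposure = exposure,
    support = support,
    ids = ids, group = grp, X = X,
    first_time = ev$time[first][order(r_last)],  # t_i1 per respondent order
    total_time = dataset$respondents$total_time,
    vocabulary = vocab),
    class = "msm_suffstats")
}

#' @export
print.msm_suffstats <- function(x, ...) {
  cat(sprintf("Multi-state sufficient statistics: %d respondents, %d states\n",
              length(x$ids), length(x$vocabulary)))
  cat(sprintf("  %d distinct (respondent, from, to) count cells; support %d (g=0) / %d (g=1) pairs\n",
              nrow(x$counts), nrow(x$support[["0"]]), nrow(x$support[["1"]])))
  invisible(x)
}

#' Export sufficient statistics as sparse CSV files
#'
#' Writes `respondent_id,from,to,count` and `respondent_id,state,exposure`
#' tables, mainly for debugging and external inspection.
#'
#' @param suffstats an `msm_suffstats` object.
#' @param counts_path,exposure_path output CSV paths.
#' @export
write_sufficient_statistics <- function(suffstats, counts_path, exposure_path) {
  stopifnot(inherits(suffstats, "msm_suffstats"))
  utils::write.csv(suffstats$counts, counts_path, row.names = FALSE)
  expo <- suffstats$exposure
  nz <- which(expo > 0, arr.ind = TRUE)
  utils::write.csv(data.frame(respondent_id = rownames(expo)[nz[, 1]],
                              state = colnames(expo)[nz[, 2]],
                              exposure = expo[nz]),
                   exposure_path, row.names = FALSE)
  invisible(c(counts_path, exposure_path))
}

#' Transition hazard rate between two actions
#'
#' The instantaneous rate (per minute) of moving from action `m` to action
#' `l` for a respondent in group `g`:
#' `h = lambda[m->l,g] * theta * exp(x'beta + gamma1_g 1[m in K] + gamma2_g 1[l in K])`.
#' Hazards are constant over time (time-homogeneous Markov assumption).
#' Pairs outside the group's support are structural zeros.
#'
#' @param params an [msm_params()] object.
#' @param group 0 or 1.
#' @param theta_i individual speed factor.
#' @param x covariate vector (length matching `params$beta`).
#' @param m,l action labels (from and to states).
#' @return Non-negative hazard rate.
#' @export
hazard_rate <- function(params, group, theta_i, x, m, l) {
  stopifnot(inherits(params, "msm_params"))
  g <- as.character(group)
  mi <- match(m, params$vocabulary)
  li <- match(l, params$vocabulary)
  if (is.na(mi) || is.na(li)) stop("unknown action label")
  sup <- params$support[[g]]
  row <- which(sup[, 1L] == mi & sup[, 2L] == li)
  if (!length(row)) return(0)
  xb <- if (length(params$beta)) sum(x * params$beta) else 0
  params$lam[[g]][row] * theta_i *
    exp(xb + params$gamma1[[g]] * (m %in% params$key_set) +
        params$gamma2[[g]] * (l %in% params$key_set))
}

# per-group pair-level modified log-baselines and row aggregates (internal)
# returns, for group g: log lambda + gamma1*key[from] + gamma2*key[to] per pair
pair_log_hazard <- function(params, g) {
  sup <- params$support[[g]]
  keym <- params$vocabulary[sup[, 1L]] %in% params$key_set
  keyl <- params$vocabulary[sup[, 2L]] %in% params$key_set
  log(params$lam[[g]]) + params$gamma1[[g]] * keym + params$gamma2[[g]] * keyl
}

#' Log-likelihood of the multi-state model
#'
#' Evaluates the censored-sojourn likelihood from sufficient statistics:
#' `sum_i [ sum_(m,l) d_iml log h_i(m,l) - sum_m e_im sum_l h_i(m,l) ]`,
#' with `d` the transition counts and `e` the state exposures. A positive
#' count on a pair with zero hazard (outside the support) yields `-Inf`.
#'
#' @param params an [msm_params()]; `theta` must be named by respondent id
#'   and cover every respondent in `suffstats`.
#' @param suffstats an `msm_suffstats` object.
#' @return Scalar log-likelihood.
#' @export
msm_log_likelihood <- function(params, suffstats) {
  stopifnot(inherits(params, "msm_params"), inherits(suffstats, "msm_suffstats"))
  vocab <- suffstats$vocabulary
  E <- length(vocab)
  ids <- suffstats$ids
  theta <- params$theta[ids]
  if (anyNA(theta)) stop("theta missing for some respondents")
  xb <- if (length(params$beta))
    drop(suffstats$X[, names(params$beta), drop = FALSE] %*% params$beta)
  else rep(0, length(ids))
  log_phi <- log(theta) + xb

  ll <- 0
  cnt <- suffstats$counts
  ridx <- match(cnt$respondent_id, ids)
  g_of <- suffstats$group
  for (g in c("0", "1")) {
    sup <- params$support[[g]]
    lh <- pair_log_hazard(params, g)
    key <- paste(sup[, 1L], sup[, 2L])
    # counts of this group mapped onto the support
    ing <- g_of[ridx] == as.integer(g)
    if (any(ing)) {
      ck <- paste(match(cnt$from[ing], vocab), match(cnt$to[ing], vocab))
      pos <- match(ck, key)
      if (anyNA(pos)) return(-Inf)  # observed transition outside support
      ll <- ll + sum(cnt$count[ing] * (lh[pos] + log_phi[ridx[ing]]))
    }
    # exposure term: rate out of each source state
    rate_out <- rep(0, E)
    ro <- rowsum(exp(lh), group = sup[, 1L])
    rate_out[as.integer(rownames(ro))] <- ro
    ig <- which(g_of == as.integer(g))
    if (length(ig))
      ll <- ll - sum(exp(log_phi[ig]) *
                       (suffstats$exposure[ig, , drop = FALSE] %*% rate_out))
  }
  ll
}

#' Embedded-chain transition probability matrix
#'
#' Probability that the next action is `l` given the current action `m`:
#' the m-to-l hazard divided by the total hazard out of `m`. Under the
#' proportional-hazards form the individual speed `theta`, the covariate
#' term `exp(x'beta)` and the key-start effect `gamma1` are common to every
#' destination in a row and cancel, so the matrix depends only on the
#' group's baseline hazards and `gamma2`; the `theta_i` and `x` arguments
#' are retained for interface fidelity.
#'
#' @inheritParams hazard_rate
#' @param theta_i,x accepted and provably inert (row-wise cancellation).
#' @return E x E row-stochastic matrix over the group's support (zeros
#'   elsewhere). Source states with no supported destination get an `NA` row
#'   and are flagged in the `undefined_rows` attribute.
#' @export
transition_matrix <- function(params, group, theta_i = 1, x = NULL) {
  stopifnot(inherits(params, "msm_params"))
  g <- as.character(group)
  vocab <- params$vocabulary
  E <- length(vocab)
  sup <- params$support[[g]]
  h <- exp(pair_log_hazard(params, g))
  P <- matrix(0, E, E, dimnames = list(vocab, vocab))
  P[sup] <- h
  rs <- rowSums(P)
  undef <- which(rs == 0)
  P <- P / rs
  if (length(undef)) P[undef, ] <- NA_real_
  attr(P, "undefined_rows") <- vocab[undef]
  P
}
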