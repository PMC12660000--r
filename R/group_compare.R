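#' Posterior difference in transition probabilities between groups
#'
#' For every stored posterior draw, computes the embedded-chain transition
#' matrix of each correctness group ([transition_matrix()] at speed 1 and
#' the given covariate setting — both provably inert by row-wise
#' cancellation), takes the correct-minus-incorrect difference per ordered
#' pair, and summarises it with the posterior mean and the
#' highest-posterior-density interval. A pair is flagged significant when
#' the HPD interval of the difference excludes zero. Comparison is
#' restricted to pairs supported in both groups; one-group pairs are listed
#' separately, not imputed.
#'
#' @param fit an `msmlog` fit containing lambda draws for both groups.
#' @param covariate_setting named numeric vector of covariate values used
#'   for the evaluation (recorded in the result; it does not affect the
#'   probabilities).
#' @param level credible level for the HPD intervals.
#' @return An object of class `msmlog_groupdiff`: a list with `table` (data
#'   frame: `from`, `to`, `mean_diff`, `hpd_lo`, `hpd_hi`, `significant`,
#'   `direction`, `from_is_key`, `to_is_key`), `excluded` (pairs supported
#'   in only one group), `vocabulary`, `key_actions`, `covariate_setting`
#'   and `level`.
#' @export
transition_difference <- function(fit, covariate_setting = NULL,
                                  level = 0.95) {
  stopifnot(inherits(fit, "msmlog"))
  ss <- fit$suffstats
  vocab <- ss$vocabulary
  for (g in c("0", "1"))
    if (!nrow(ss$support[[g]]))
      stop("group ", g, " has empty support; both groups are required")

  P1 <- draw_transition_matrices(fit, 1)
  P0 <- draw_transition_matrices(fit, 0)

  key <- function(sup) paste(sup[, 1L], sup[, 2L])
  k0 <- key(ss$support[["0"]]); k1 <- key(ss$support[["1"]])
  common <- intersect(k0, k1)
  only <- setdiff(union(k0, k1), common)
  pair_idx <- do.call(rbind, lapply(strsplit(common, " "), as.integer))

  ndraw <- dim(P1)[1L]
  tab <- data.frame(from = vocab[pair_idx[, 1L]], to = vocab[pair_idx[, 2L]],
                    mean_diff = NA_real_, hpd_lo = NA_real_,
                    hpd_hi = NA_real_, significant = NA,
                    direction = NA_integer_, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(pair_idx))) {
    d <- P1[, pair_idx[r, 1L], pair_idx[r, 2L]] -
         P0[, pair_idx[r, 1L], pair_idx[r, 2L]]
    h <- hpd_interval(d, level)
    sig <- h[1L] > 0 || h[2L] < 0
    tab$mean_diff[r] <- mean(d)
    tab$hpd_lo[r] <- h[1L]; tab$hpd_hi[r] <- h[2L]
    tab$significant[r] <- sig
    tab$direction[r] <- if (!sig) 0L else if (h[1L] > 0) 1L else -1L
  }
  tab$from_is_key <- tab$from %in% fit$key_actions
  tab$to_is_key <- tab$to %in% fit$key_actions

  excl <- if (length(only)) {
    oi <- do.call(rbind, lapply(strsplit(only, " "), as.integer))
    data.frame(from = vocab[oi[, 1L]], to = vocab[oi[, 2L]],
               supported_in = ifelse(only %in% k1, 1L, 0L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0),
               supported_in = integer(0))
  }

  structure(list(table = tab, excluded = excl, vocabulary = vocab,
                 key_actions = fit$key_actions,
                 covariate_setting = covariate_setting, level = level,
                 n_draws = ndraw),
            class = "msmlog_groupdiff")
}

#' @export
print.msmlog_groupdiff <- function(x, n = 10L, ...) {
  cat(sprintf("Group difference in transition probabilities (correct - incorrect), %d%% HPD\n",
              round(100 * x$level)))
  cat(sprintf("  %d compared pairs, %d significant, %d excluded (one-group support)\n",
              nrow(x$table), sum(x$table$significant), nrow(x$excluded)))
  sig <- x$table[x$table$significant, , drop = FALSE]
  sig <- sig[order(-abs(sig$mean_diff)), , drop = FALSE]
  if (nrow(sig)) {
    cat("  largest significant differences:\n")
    print.data.frame(utils::head(sig, n), digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Export the group-difference heatmap matrices
#'
#' Writes an E x E CSV of signed posterior-mean differences with
#' non-significant cells set to zero (rows = source action, columns =
#' destination), and a parallel 0/1 significance-mask CSV. Positive cells
#' are transitions the correct group takes with higher probability.
#'
#' @param result an `msmlog_groupdiff` from [transition_difference()].
#' @param path output CSV path for the difference matrix.
#' @param mask_path output CSV path for the significance mask (default:
#'   `path` with a `_mask` suffix).
#' @return Invisibly, the difference matrix.
#' @export
export_heatmap <- function(result, path,
                           mask_path = sub("(\\.[^.]*)?$", "_mask\\1", path)) {
  stopifnot(inherits(result, "msmlog_groupdiff"))
  vocab <- result$vocabulary
  E <- length(vocab)
  M <- matrix(0, E, E, dimnames = list(vocab, vocab))
  S <- matrix(0L, E, E, dimnames = list(vocab, vocab))
  tb <- result$table
  sig <- tb$significant
  M[cbind(match(tb$from[sig], vocab), match(tb$to[sig], vocab))] <-
    tb$mean_diff[sig]
  S[cbind(match(tb$from[sig], vocab), match(tb$to[sig], vocab))] <- 1L
  utils::write.csv(M, path, row.names = TRUE)
  utils::write.csv(S, mask_path, row.names = TRUE)
  invisible(M)
}

#' Export significant transition differences as a network edge list
#'
#' One row per significant ordered pair, sorted by absolute mean difference
#' descending, with key-action flags on both endpoints — directly loadable
#' as a directed-graph edge list.
#'
#' @param result an `msmlog_groupdiff` from [transition_difference()].
#' @param path output CSV path.
#' @return Invisibly, the edge data frame.
#' @export
export_edge_list <- function(result, path) {
  stopifnot(inherits(result, "msmlog_groupdiff"))
  tb <- result$table[result$table$significant, , drop = FALSE]
  tb <- tb[order(-abs(tb$mean_diff)), c("from", "to", "mean_diff", "hpd_lo",
                                        "hpd_hi", "direction", "from_is_key",
                                        "to_is_key"), drop = FALSE]
  rownames(tb) <- NULL
  utils::write.csv(tb, path, row.names = FALSE)
  invisible(tb)
}
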