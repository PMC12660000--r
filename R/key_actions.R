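#' Inverse sequence frequency of each action
#'
#' ISF down-weights ubiquitous actions, by analogy with inverse document
#' frequency: `ISF_i = ln(N / n_i)`, where `N` is the number of respondents
#' and `n_i` the number of sequences containing action `i` at least once.
#' An action present in every sequence gets ISF 0 and therefore carries no
#' weight in the chi-square scores.
#'
#' @param dataset a [log_dataset()].
#' @param denominator `"sequences"` (default): `n_i` counts sequences that
#'   contain the action; `"occurrences"`: `n_i` is the total occurrence count
#'   (an alternative reading, kept switchable).
#' @return Named numeric vector over observed actions.
#' @export
inverse_sequence_frequency <- function(dataset,
                                       denominator = c("sequences", "occurrences")) {
  stopifnot(inherits(dataset, "log_dataset"))
  denominator <- match.arg(denominator)
  N <- nrow(dataset$respondents)
  if (N < 1L) stop("empty dataset")
  ev <- dataset$events
  n_i <- if (denominator == "sequences") {
    tapply(ev$respondent_id, ev$action, function(z) length(unique(z)))
  } else {
    tapply(ev$respondent_id, ev$action, length)
  }
  isf <- log(N / as.numeric(n_i))
  names(isf) <- names(n_i)
  isf
}

#' Per-respondent term frequency
#'
#' Number of occurrences of each action in one respondent's sequence.
#'
#' @param dataset a [log_dataset()].
#' @param id respondent identifier.
#' @return Named integer vector.
#' @export
term_frequency <- function(dataset, id) {
  stopifnot(inherits(dataset, "log_dataset"))
  ev <- respondent_events(dataset, as.character(id))
  if (nrow(ev) == 0L) stop("unknown respondent: ", id)
  tab <- table(ev$action)
  stats::setNames(as.integer(tab), names(tab))
}

#' TF-ISF weighted action frequencies by correctness group
#'
#' Combines term frequency and inverse sequence frequency multiplicatively,
#' `w_ij = TF_ij * ISF_i`, and sums the weights within the correct
#' (`group == 1`) and incorrect (`group == 0`) groups.
#'
#' @inheritParams inverse_sequence_frequency
#' @return List with `w_correct` and `w_incorrect` (named vectors over
#'   actions), `len_correct` and `len_incorrect` (the group totals), and the
#'   `isf` vector used.
#' @export
weighted_frequencies <- function(dataset,
                                 denominator = c("sequences", "occurrences")) {
  stopifnot(inherits(dataset, "log_dataset"))
  denominator <- match.arg(denominator)
  grp <- dataset$respondents$group
  if (!any(grp == 1) || !any(grp == 0)) stop("single-group dataset")
  isf <- inverse_sequence_frequency(dataset, denominator)
  ev <- dataset$events
  g <- grp[match(ev$respondent_id, dataset$respondents$respondent_id)]
  acts <- names(isf)
  tf_c <- table(factor(ev$action[g == 1], levels = acts))
  tf_w <- table(factor(ev$action[g == 0], levels = acts))
  w_correct <- as.numeric(tf_c) * isf
  w_incorrect <- as.numeric(tf_w) * isf
  list(w_correct = w_correct, w_incorrect = w_incorrect,
       len_correct = sum(w_correct), len_incorrect = sum(w_incorrect),
       isf = isf)
}

#' Weighted chi-square discrimination scores for actions
#'
#' For each action a 2x2 table of weighted frequencies is formed — occurrence
#' weight in the correct and incorrect groups against the remaining group
#' totals — and the chi-square statistic of independence computed on the
#' weighted (non-integer) counts, without continuity correction. No p-value
#' is attached: scores are used only to rank actions. An action is flagged
#' `correct_representative` when its weighted occurrence proportion is higher
#' in the correct group.
#'
#' @inheritParams inverse_sequence_frequency
#' @return A data frame of class `score_table`, sorted by `chi2` descending
#'   (ties broken alphabetically), with columns `action`, `isf`, `w_correct`,
#'   `w_incorrect`, `chi2`, `correct_representative`, and attributes
#'   `len_correct`, `len_incorrect`.
#' @seealso [select_key_actions()]
#' @export
chi_square_scores <- function(dataset,
                              denominator = c("sequences", "occurrences")) {
  wf <- weighted_frequencies(dataset, denominator)
  if (wf$len_correct <= 0 || wf$len_incorrect <= 0)
    stop("a group total of weighted frequencies is zero")
  chi2 <- mapply(chi2_2x2, wf$w_correct, wf$w_incorrect,
                 MoreArgs = list(len_c = wf$len_correct,
                                 len_w = wf$len_incorrect))
  rep_flag <- wf$w_correct / wf$len_correct > wf$w_incorrect / wf$len_incorrect
  out <- data.frame(action = names(wf$isf), isf = unname(wf$isf),
                    w_correct = unname(wf$w_correct),
                    w_incorrect = unname(wf$w_incorrect),
                    chi2 = unname(chi2),
                    correct_representative = unname(rep_flag),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$chi2, out$action), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "len_correct") <- wf$len_correct
  attr(out, "len_incorrect") <- wf$len_incorrect
  class(out) <- c("score_table", "data.frame")
  out
}

# chi-square of independence on the 2x2 weighted table
# O = [[wc, ww], [len_c - wc, len_w - ww]]; degenerate margins give 0
chi2_2x2 <- function(wc, ww, len_c, len_w) {
  O <- matrix(c(wc, len_c - wc, ww, len_w - ww), 2L, 2L)
  n <- len_c + len_w
  E <- outer(rowSums(O), colSums(O)) / n
  if (any(E == 0)) return(0)
  sum((O - E)^2 / E)
}

#' Select key actions from a score table
#'
#' Candidates are the correct-representative actions. The default `elbow`
#' strategy locates, on the descending chi-square curve (rank r, score y_r),
#' the rank maximising the perpendicular distance to the chord joining the
#' first and last points, and selects candidates whose score is strictly
#' greater than the elbow action's score (the elbow itself is excluded).
#' `top_k` and `min_score` are explicit overrides.
#'
#' @param table a `score_table` from [chi_square_scores()].
#' @param strategy `"elbow"`, `"top_k"` or `"min_score"`.
#' @param k number of actions for `top_k`.
#' @param min_score score threshold (inclusive) for `min_score`.
#' @return Character vector of key actions ordered by `chi2` descending.
#' @export
select_key_actions <- function(table,
                               strategy = c("elbow", "top_k", "min_score"),
                               k = NULL, min_score = NULL) {
  stopifnot(inherits(table, "score_table"), nrow(table) > 0L)
  strategy <- match.arg(strategy)
  cand <- table[table$correct_representative, , drop = FALSE]
  switch(strategy,
    elbow = {
      if (nrow(table) < 2L)
        stop("elbow undefined for a single-action table; use top_k or min_score")
      y <- table$chi2
      if (diff(range(y)) == 0)
        stop("all scores equal: elbow undefined; use top_k or min_score")
      r <- elbow_rank(y)
      cand$action[cand$chi2 > y[r]]
    },
    top_k = {
      if (is.null(k) || k < 0) stop("top_k strategy needs k >= 0")
      utils::head(cand$action, k)
    },
    min_score = {
      if (is.null(min_score)) stop("min_score strategy needs min_score")
      cand$action[cand$chi2 >= min_score]
    })
}

# rank maximising perpendicular distance from (r, y_r) to the chord
# from (1, y_1) to (R, y_R); first maximum on ties
elbow_rank <- function(y) {
  R <- length(y)
  r <- seq_len(R)
  dx <- R - 1
  dy <- y[R] - y[1]
  d <- abs(dy * (r - 1) - dx * (y - y[1])) / sqrt(dx^2 + dy^2)
  which.max(d)
}

#' @export
print.score_table <- function(x, n = 10L, ...) {
  cat(sprintf("Weighted chi-square action scores (%d actions; group totals %.3f / %.3f)\n",
              nrow(x), attr(x, "len_correct"), attr(x, "len_incorrect")))
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more rows\n")
  invisible(x)
}

#' Scree-style line plot of chi-square scores
#'
#' Plots the descending score curve used for elbow selection and marks the
#' elbow point.
#'
#' @param x a `score_table`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.score_table <- function(x, ...) {
  y <- x$chi2
  graphics::plot(seq_along(y), y, type = "b", pch = 16,
                 xlab = "rank", ylab = expression(chi^2 ~ "score"), ...)
  if (length(y) >= 2L && diff(range(y)) > 0) {
    r <- elbow_rank(y)
    graphics::points(r, y[r], col = 2, cex = 2)
    graphics::text(r, y[r], labels = x$action[r], pos = 4, col = 2)
  }
  invisible(x)
}
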