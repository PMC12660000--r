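#' Construct a log dataset of timestamped action sequences
#'
#' A `log_dataset` bundles long-format action events (one row per action
#' occurrence) with a respondent table carrying the correctness group, the
#' total solution time and numeric covariates. It is the input container for
#' key-action scoring ([chi_square_scores()]) and model fitting ([msmlog()]).
#'
#' @param events data frame with columns `respondent_id`, `action` (character),
#'   `time` (minutes since item onset, non-negative, non-decreasing within a
#'   respondent). Rows with tied timestamps keep their original order.
#' @param respondents data frame with columns `respondent_id`, `group`
#'   (0 = incorrect, 1 = correct), `total_time` (minutes, at least the last
#'   event time) and any further numeric columns, which are taken as
#'   covariates. Covariates are consumed as-is; standardisation is the
#'   caller's responsibility.
#' @param vocabulary optional character vector fixing the action-state
#'   ordering; defaults to the sorted union of observed actions. Every
#'   observed action must be a member.
#'
#' @return An object of class `log_dataset`: a list with elements `events`
#'   (sorted by respondent then time), `respondents`, `vocabulary` and
#'   `covariate_names`.
#' @seealso [read_log()], [write_log()], [collapse_repeats()]
#' @export
log_dataset <- function(events, respondents, vocabulary = NULL) {
  stopifnot(is.data.frame(events), is.data.frame(respondents))
  need_ev <- c("respondent_id", "action", "time")
  if (!all(need_ev %in% names(events)))
    stop("events must have columns: ", paste(need_ev, collapse = ", "))
  need_re <- c("respondent_id", "group", "total_time")
  if (!all(need_re %in% names(respondents)))
    stop("respondents must have columns: ", paste(need_re, collapse = ", "))
  if (nrow(events) == 0L) stop("no events")

  events$respondent_id <- as.character(events$respondent_id)
  events$action <- as.character(events$action)
  events$time <- as.numeric(events$time)
  respondents$respondent_id <- as.character(respondents$respondent_id)

  if (anyNA(events$time) || any(events$time < 0))
    stop("negative or missing event time")
  if (!all(respondents$group %in% c(0, 1)))
    stop("group must be 0 (incorrect) or 1 (correct)")
  if (anyDuplicated(respondents$respondent_id))
    stop("duplicated respondent_id in respondents table")

  miss_ev <- setdiff(events$respondent_id, respondents$respondent_id)
  if (length(miss_ev))
    stop("respondent(s) present in events but missing from respondents table: ",
         paste(utils::head(miss_ev, 5L), collapse = ", "))
  miss_re <- setdiff(respondents$respondent_id, events$respondent_id)
  if (length(miss_re))
    stop("respondent(s) present in respondents table but missing from events: ",
         paste(utils::head(miss_re, 5L), collapse = ", "))

  # stable sort: ties in time keep file order
  ord <- order(match(events$respondent_id, respondents$respondent_id),
               events$time)
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL

  by_id <- split(events$time, events$respondent_id)
  bad <- names(by_id)[vapply(by_id, function(t) any(diff(t) < 0), logical(1))]
  if (length(bad))
    stop("non-monotone event times for respondent(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))

  last_time <- vapply(by_id, function(t) t[length(t)], numeric(1))
  tt <- respondents$total_time[match(names(last_time), respondents$respondent_id)]
  if (any(tt < last_time - 1e-12))
    stop("total_time smaller than last event time for respondent(s): ",
         paste(utils::head(names(last_time)[tt < last_time - 1e-12], 5L),
               collapse = ", "))

  obs <- sort(unique(events$action))
  if (is.null(vocabulary)) {
    vocabulary <- obs
  } else {
    vocabulary <- as.character(vocabulary)
    if (anyDuplicated(vocabulary)) stop("duplicated labels in vocabulary")
    extra <- setdiff(obs, vocabulary)
    if (length(extra))
      stop("observed action(s) not in vocabulary: ",
           paste(utils::head(extra, 5L), collapse = ", "))
  }

  covariate_names <- setdiff(names(respondents), need_re)
  for (cn in covariate_names) {
    if (!is.numeric(respondents[[cn]]))
      stop("covariate column '", cn, "' is not numeric")
  }

  structure(
    list(events = events, respondents = respondents,
         vocabulary = vocabulary, covariate_names = covariate_names),
    class = "log_dataset")
}

#' Read an action-sequence log dataset from CSV files
#'
#' @param events_path CSV with header `respondent_id,action,time` (time in
#'   decimal minutes).
#' @param respondents_path CSV with header
#'   `respondent_id,group,total_time,<covariate...>`.
#' @param vocabulary_path optional text file, one action label per line,
#'   fixing the state ordering.
#' @return A [log_dataset()].
#' @export
read_log <- function(events_path, respondents_path, vocabulary_path = NULL) {
  events <- utils::read.csv(events_path, stringsAsFactors = FALSE,
                            colClasses = c(respondent_id = "character",
                                           action = "character"))
  if (nrow(events) == 0L) stop("no events")
  respondents <- utils::read.csv(respondents_path, stringsAsFactors = FALSE,
                                 colClasses = c(respondent_id = "character"))
  vocab <- if (!is.null(vocabulary_path))
    readLines(vocabulary_path, encoding = "UTF-8")
  log_dataset(events, respondents, vocabulary = vocab)
}

#' Write a log dataset to CSV files
#'
#' Inverse of [read_log()]: writing then reading reproduces the dataset
#' (labels byte-exact, times at full precision).
#'
#' @param dataset a [log_dataset()].
#' @param events_path,respondents_path output CSV paths.
#' @param vocabulary_path optional path for the vocabulary list (one label
#'   per line); written only when supplied.
#' @return Invisibly, the paths written.
#' @export
write_log <- function(dataset, events_path, respondents_path,
                      vocabulary_path = NULL) {
  stopifnot(inherits(dataset, "log_dataset"))
  ev <- dataset$events
  ev$time <- format(ev$time, digits = 17, scientific = FALSE, trim = TRUE)
  utils::write.csv(ev, events_path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  re <- dataset$respondents
  num <- vapply(re, is.double, logical(1))
  re[num] <- lapply(re[num], format, digits = 17, scientific = FALSE,
                    trim = TRUE)
  utils::write.csv(re, respondents_path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  paths <- c(events_path, respondents_path)
  if (!is.null(vocabulary_path)) {
    writeLines(dataset$vocabulary, vocabulary_path, useBytes = TRUE)
    paths <- c(paths, vocabulary_path)
  }
  invisible(paths)
}

#' Merge consecutive repeats of the same action
#'
#' Collapses runs of identical consecutive actions within each respondent to
#' a single event keeping the first timestamp. Repeated occurrences in raw
#' logs are observable events rather than state changes; collapsing them
#' yields the classical multi-state view without self-transitions.
#'
#' @param dataset a [log_dataset()].
#' @param enabled if `FALSE`, the dataset is returned unchanged.
#' @return A [log_dataset()].
#' @export
collapse_repeats <- function(dataset, enabled = TRUE) {
  stopifnot(inherits(dataset, "log_dataset"))
  if (!enabled) return(dataset)
  ev <- dataset$events
  keep <- c(TRUE, !(ev$action[-1L] == ev$action[-nrow(ev)] &
                    ev$respondent_id[-1L] == ev$respondent_id[-nrow(ev)]))
  out <- dataset
  out$events <- ev[keep, , drop = FALSE]
  rownames(out$events) <- NULL
  out
}

#' @export
print.log_dataset <- function(x, ...) {
  n <- nrow(x$respondents)
  cat("Action-sequence log dataset\n")
  cat(sprintf("  %d respondents (%d correct, %d incorrect), %d events, %d actions\n",
              n, sum(x$respondents$group == 1), sum(x$respondents$group == 0),
              nrow(x$events), length(x$vocabulary)))
  if (length(x$covariate_names))
    cat("  covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.log_dataset <- function(object, ...) {
  len <- table(factor(object$events$respondent_id,
                      levels = object$respondents$respondent_id))
  cat("Action-sequence log dataset\n")
  print(object)
  cat("  sequence length: ")
  print(summary(as.integer(len)))
  cat("  total time (min): ")
  print(summary(object$respondents$total_time))
  invisible(object)
}

# ordered event list for one respondent (internal)
respondent_events <- function(dataset, id) {
  dataset$events[dataset$events$respondent_id == id, , drop = FALSE]
}
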