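#' Configuration of a 2-AFC realism study
#'
#' Captures what an investigator specifies when setting up a
#' two-alternative forced-choice study: title, a four-digit passcode
#' shared with the readers, reader instructions, the ordered list of
#' (synthetic, real) image pairs, whether to shuffle pair order, and a
#' contact address. Display conveniences of the original web tool
#' (contrast adjustment, intensity inversion, email delivery) are recorded
#' as metadata only and perform no computation here.
#'
#' @param project_title study title.
#' @param passcode exactly four digits, as text.
#' @param pairs a data frame (or 2-column matrix) with columns
#'   `synthetic` and `real` holding image file paths, in upload order.
#' @param instructions free-text instructions shown to readers.
#' @param shuffle logical; shuffle pair order when building a session.
#' @param shuffle_seed integer seed driving both the pair permutation and
#'   the per-trial left/right coin.
#' @param investigator_contact contact address for result delivery.
#' @param check_files if `TRUE` (default), every referenced image file
#'   must exist.
#' @return An object of class `study_config`.
#' @export
study_config <- function(project_title, passcode, pairs,
                         instructions = "", shuffle = FALSE,
                         shuffle_seed = 1L, investigator_contact = "",
                         check_files = TRUE) {
  if (!grepl("^[0-9]{4}$", passcode)) {
    stop("`passcode` must be exactly 4 digits", call. = FALSE)
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) == 2L && !all(c("synthetic", "real") %in% names(pairs))) {
    names(pairs) <- c("synthetic", "real")
  }
  if (!nrow(pairs) || !all(c("synthetic", "real") %in% names(pairs))) {
    stop("`pairs` must be non-empty with columns `synthetic` and `real`",
         call. = FALSE)
  }
  if (check_files) {
    refs <- c(pairs$synthetic, pairs$real)
    missing <- refs[!file.exists(refs)]
    if (length(missing)) {
      stop("image file not found: ", missing[1L], call. = FALSE)
    }
  }
  structure(list(
    project_title = as.character(project_title),
    passcode = as.character(passcode),
    instructions = as.character(instructions),
    pairs = pairs[, c("synthetic", "real")],
    shuffle = isTRUE(shuffle),
    shuffle_seed = as.integer(shuffle_seed),
    investigator_contact = as.character(investigator_contact)
  ), class = "study_config")
}

#' Materialize the trial sequence of a study
#'
#' Turns a [study_config()] into the ordered list of trials a reader will
#' see. If `shuffle` is set, pair order is a seeded permutation; which
#' side shows the real image is a seeded fair coin per trial. The same
#' config always yields the identical session.
#'
#' @param config a [study_config()].
#' @return A data frame of class `afc_session` with columns `trial_id`
#'   (1..n), `synthetic_ref`, `real_ref`, `left_is_real`.
#' @export
build_session <- function(config) {
  stopifnot(inherits(config, "study_config"))
  n <- nrow(config$pairs)
  rand <- local_rng(config$shuffle_seed, list(
    perm = sample.int(n),
    coin = stats::runif(n) < 0.5
  ))
  ord <- if (config$shuffle) rand$perm else seq_len(n)
  session <- data.frame(
    trial_id = seq_len(n),
    synthetic_ref = config$pairs$synthetic[ord],
    real_ref = config$pairs$real[ord],
    left_is_real = rand$coin,
    stringsAsFactors = FALSE
  )
  class(session) <- c("afc_session", "data.frame")
  session
}

#' Read and write session files
#'
#' A session file is JSON holding the study configuration together with
#' the materialized trial list, so scoring never depends on re-running the
#' shuffling.
#'
#' @param config a [study_config()].
#' @param session the matching [build_session()] output.
#' @param path file path.
#' @return `read_session`: a list with elements `config` and `session`.
#' @export
write_session <- function(config, session, path) {
  obj <- list(
    schema_version = "1.0",
    config = unclass(config),
    trials = as.data.frame(session)
  )
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              dataframe = "rows", pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  cfg <- obj$config
  config <- study_config(cfg$project_title, cfg$passcode,
                         as.data.frame(cfg$pairs),
                         instructions = cfg$instructions,
                         shuffle = cfg$shuffle,
                         shuffle_seed = cfg$shuffle_seed,
                         investigator_contact = cfg$investigator_contact,
                         check_files = FALSE)
  session <- as.data.frame(obj$trials)
  session$trial_id <- as.integer(session$trial_id)
  class(session) <- c("afc_session", "data.frame")
  list(config = config, session = session)
}

#' Read and write 2-AFC response logs
#'
#' The on-disk format is a UTF-8, comma-delimited CSV with header
#' `reader_id,trial_id,chosen_side,confidence,comment`;
#' `chosen_side` is `left` or `right`, `confidence` an integer 1-5,
#' comments quoted.
#'
#' @param path CSV file path.
#' @param log a response-log data frame.
#' @return `read_response_log`: a validated data frame.
#' @export
read_response_log <- function(path) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(comment = "character"))
  validate_response_log(log)
}

#' @rdname read_response_log
#' @export
write_response_log <- function(log, path) {
  log <- validate_response_log(log)
  utils::write.csv(log, path, row.names = FALSE, quote = which(
    names(log) %in% c("reader_id", "chosen_side", "comment")))
  invisible(path)
}

validate_response_log <- function(log) {
  log <- as.data.frame(log, stringsAsFactors = FALSE)
  need <- c("reader_id", "trial_id", "chosen_side", "confidence")
  if (!all(need %in% names(log))) {
    stop("response log must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(log$comment)) log$comment <- ""
  log$trial_id <- as.integer(log$trial_id)
  log$confidence <- as.integer(log$confidence)
  if (!all(log$chosen_side %in% c("left", "right"))) {
    stop("`chosen_side` must be 'left' or 'right'", call. = FALSE)
  }
  if (!all(log$confidence %in% 1:5)) {
    stop("`confidence` must be an integer in 1..5", call. = FALSE)
  }
  log[, c("reader_id", "trial_id", "chosen_side", "confidence", "comment")]
}

#' Score one reader's responses against a session
#'
#' Derives per-trial correctness (did the reader choose the side showing
#' the real image), percent accuracy, the median confidence (lower-median
#' convention for even counts, so the value stays on the 1-5 scale), a
#' 2 x 5 tally of correct/incorrect decisions by confidence level, and
#' exact binomial inference against chance (two-sided p-value and
#' Clopper-Pearson 95% interval versus 1/2). Accuracy credibly below
#' chance (interval upper bound < 0.5) sets an `untrained_flag`: it
#' usually signals a reader who misunderstood the task, and the results
#' deserve caution rather than exclusion.
#'
#' @param session an [build_session()] trial table (or the `session`
#'   element of [read_session()]).
#' @param log a response log (see [read_response_log()]).
#' @param reader_id which reader to score.
#' @return An object of class `reader_summary`.
#' @export
score_responses <- function(session, log, reader_id) {
  log <- validate_response_log(log)
  rows <- log[log$reader_id == reader_id, , drop = FALSE]
  if (!nrow(rows)) stop("no responses for reader ", reader_id,
                        call. = FALSE)
  if (anyDuplicated(rows$trial_id)) {
    stop(sprintf("duplicate response for reader %s, trial %d", reader_id,
                 rows$trial_id[duplicated(rows$trial_id)][1L]),
         call. = FALSE)
  }
  unknown <- setdiff(rows$trial_id, session$trial_id)
  if (length(unknown)) {
    stop(sprintf("response to unknown trial %d", unknown[1L]),
         call. = FALSE)
  }
  missing <- setdiff(session$trial_id, rows$trial_id)
  idx <- match(rows$trial_id, session$trial_id)
  chose_real <- (rows$chosen_side == "left") == session$left_is_real[idx]
  tally <- matrix(0L, 2L, 5L,
                  dimnames = list(c("correct", "incorrect"), 1:5))
  for (i in seq_along(chose_real)) {
    r <- if (chose_real[i]) 1L else 2L
    tally[r, rows$confidence[i]] <- tally[r, rows$confidence[i]] + 1L
  }
  new_reader_summary(reader_id, tally, skipped_trials = missing)
}

new_reader_summary <- function(reader_id, tally,
                               skipped_trials = integer(0)) {
  n_trials <- sum(tally)
  n_correct <- sum(tally["correct", ])
  conf_values <- rep(rep(1:5, 2L), times = as.vector(t(tally)))
  bt <- stats::binom.test(n_correct, n_trials, p = 0.5)
  structure(list(
    reader_id = reader_id,
    n_trials = n_trials,
    n_correct = n_correct,
    percent_accuracy = 100 * n_correct / n_trials,
    percent_accuracy_rounded = round(100 * n_correct / n_trials),
    median_confidence = lower_median(conf_values),
    confidence_tally = tally,
    binomial_p_vs_chance = bt$p.value,
    ci95 = as.numeric(bt$conf.int),
    untrained_flag = bt$conf.int[2L] < 0.5,
    skipped_trials = skipped_trials
  ), class = "reader_summary")
}

lower_median <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}

#' @export
print.reader_summary <- function(x, ...) {
  cat(sprintf(
    "<reader_summary> %s: %d/%d correct (%d%%), median confidence %g, p=%.3g, 95%% CI [%.3f, %.3f]%s\n",
    x$reader_id, x$n_correct, x$n_trials, x$percent_accuracy_rounded,
    x$median_confidence, x$binomial_p_vs_chance, x$ci95[1L], x$ci95[2L],
    if (isTRUE(x$untrained_flag)) "  [below-chance flag]" else ""))
  if (length(x$skipped_trials)) {
    cat("  unanswered trials:", paste(x$skipped_trials, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Pool reader summaries
#'
#' Sums trials, correct decisions and confidence tallies across readers,
#' then recomputes percent accuracy, median confidence and exact binomial
#' inference on the pooled counts. The counts are taken as given; no
#' reconciliation across readers is attempted.
#'
#' @param summaries a list of [score_responses()] results.
#' @return A `reader_summary` with `reader_id = "pooled"`.
#' @export
pooled_summary <- function(summaries) {
  if (inherits(summaries, "reader_summary")) summaries <- list(summaries)
  if (!length(summaries)) stop("`summaries` must be non-empty",
                               call. = FALSE)
  tally <- Reduce(`+`, lapply(summaries, `[[`, "confidence_tally"))
  new_reader_summary("pooled", tally)
}

#' Count decisions at or above a confidence level
#'
#' For the stated correctness, counts decisions with confidence >=
#' `min_confidence` and reports the count together with its percentage of
#' all decisions of that correctness, rounded to the nearest integer.
#'
#' @param summary a `reader_summary`.
#' @param correct `TRUE` for correct decisions, `FALSE` for incorrect.
#' @param min_confidence confidence threshold, 1..5.
#' @return A list with `count`, `total` and `percent`.
#' @export
confidence_fraction <- function(summary, correct, min_confidence) {
  stopifnot(inherits(summary, "reader_summary"))
  if (!min_confidence %in% 1:5) {
    stop("`min_confidence` must be in 1..5", call. = FALSE)
  }
  row <- if (isTRUE(correct)) "correct" else "incorrect"
  total <- sum(summary$confidence_tally[row, ])
  if (total == 0L) {
    stop(sprintf("no %s decisions: percentage undefined", row),
         call. = FALSE)
  }
  count <- sum(summary$confidence_tally[row, min_confidence:5])
  list(count = count, total = total,
       percent = round(100 * count / total))
}

# ---- System Usability Scale -------------------------------------------

#' Canonical SUS response labels
#'
#' The five response options, least to most agreement.
#' @format Character vector of length 5.
#' @export
sus_labels <- c("strongly disagree", "disagree", "neutral", "agree",
                "strongly agree")

#' Score a System Usability Scale questionnaire
#'
#' Ten items with five response options. Odd-numbered items score
#' strongly disagree = 0 up to strongly agree = 4; even-numbered items
#' the reverse. The sum is multiplied by 2.5, giving a score between 0
#' and 100.
#'
#' @param responses character vector of exactly 10 labels from
#'   `sus_labels`, in questionnaire item order (case-insensitive).
#' @return Numeric score in `[0, 100]`.
#' @examples
#' sus_score(rep("neutral", 10))  # 50
#' @export
sus_score <- function(responses) {
  responses <- tolower(trimws(as.character(responses)))
  if (length(responses) != 10L) {
    stop("SUS requires exactly 10 item responses, got ",
         length(responses), call. = FALSE)
  }
  idx <- match(responses, sus_labels)
  if (anyNA(idx)) {
    stop("invalid SUS response label: ", responses[which(is.na(idx))[1L]],
         call. = FALSE)
  }
  raw <- idx - 1L                       # 0..4, favorability for odd items
  item_scores <- ifelse(seq_len(10L) %% 2L == 1L, raw, 4L - raw)
  2.5 * sum(item_scores)
}

#' Read and score a SUS response file
#'
#' CSV with one row per respondent and columns `item1`..`item10` holding
#' the canonical labels.
#'
#' @param path CSV file path.
#' @return A data frame with one row per respondent and a `score` column.
#' @export
read_sus_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- paste0("item", 1:10)
  if (!all(cols %in% names(df))) {
    stop("SUS file must have columns item1..item10", call. = FALSE)
  }
  df$score <- vapply(seq_len(nrow(df)), function(i) {
    sus_score(unlist(df[i, cols], use.names = FALSE))
  }, numeric(1))
  df
}
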