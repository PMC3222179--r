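#' Adaptive administration engine
#'
#' The adaptive loop administers one item at a time: each next item is the
#' unanswered one with the highest information at the provisional person
#' measure, the measure is re-estimated by maximum likelihood after every
#' response once at least three responses are in and the pattern is not all
#' minimum/maximum, and the session stops when the standard error reaches the
#' precision target (subject to a minimum test length) or the bank runs out.
#'
#' @name cat_engine
NULL

#' Stop rules for an adaptive session
#'
#' @param se_threshold precision target in logits; the session may stop once
#'   the measure's standard error is at or below it. Default 0.51, the value
#'   `SD * sqrt(1 - reliability)` of the packaged bank's calibration.
#' @param min_items fewest items that must be administered before the
#'   standard-error rule can fire (default 10).
#' @param max_items hard cap on test length; defaults to the bank size at
#'   session start (`NULL`).
#' @return list of class `cat_rules`.
#' @export
stop_rules <- function(se_threshold = 0.51, min_items = 10L,
                       max_items = NULL) {
  stopifnot(se_threshold > 0, min_items >= 1L)
  if (!is.null(max_items)) stopifnot(max_items >= min_items)
  structure(list(se_threshold = se_threshold,
                 min_items = as.integer(min_items),
                 max_items = if (is.null(max_items)) NULL
                             else as.integer(max_items)),
            class = "cat_rules")
}

# theta0 from the respondent's coarse overall satisfaction rating 0..4
.initial_theta <- c(`0` = -2, `1` = -1, `2` = 0, `3` = 1, `4` = 2)

#' Start an adaptive session
#'
#' @param bank an `rsm_bank`.
#' @param initial_rating optional overall-perception rating `0..4` used to
#'   seed the provisional measure (0 -> -2, 1 -> -1, 2 -> 0, 3 -> +1,
#'   4 -> +2 logits); `NULL` starts at 0.
#' @param rules a [stop_rules()] object.
#' @return list of class `cat_session`: `bank`, `rules` (with `max_items`
#'   resolved to the bank size if unset), `administered` (log data frame),
#'   `current_theta`, `current_se`, `estimation_active`, `stopped`,
#'   `stop_reason`.
#' @export
start_session <- function(bank, initial_rating = NULL, rules = stop_rules()) {
  stopifnot(inherits(bank, "rsm_bank"), inherits(rules, "cat_rules"))
  n_bank <- nrow(bank$items)
  if (!n_bank) stop("cannot start a session on an empty bank", call. = FALSE)
  if (is.null(rules$max_items)) rules$max_items <- n_bank
  if (rules$max_items > n_bank || rules$min_items > n_bank)
    stop("stop rules exceed bank size", call. = FALSE)
  theta0 <- 0
  if (!is.null(initial_rating)) {
    key <- as.character(initial_rating)
    if (!key %in% names(.initial_theta))
      stop("initial_rating must be an integer 0..4", call. = FALSE)
    theta0 <- unname(.initial_theta[key])
  }
  structure(
    list(bank = bank, rules = rules,
         administered = data.frame(step = integer(), item_id = character(),
                                   score = integer(), theta = numeric(),
                                   se = numeric(), stringsAsFactors = FALSE),
         current_theta = theta0, current_se = NA_real_,
         estimation_active = FALSE, stopped = FALSE, stop_reason = "none"),
    class = "cat_session"
  )
}

#' @export
print.cat_session <- function(x, ...) {
  cat(sprintf(
    "Adaptive session: %d item(s) administered, theta %.3f (SE %s)%s\n",
    nrow(x$administered), x$current_theta,
    if (is.na(x$current_se)) "--" else sprintf("%.3f", x$current_se),
    if (x$stopped) paste0(", stopped: ", x$stop_reason) else ""))
  invisible(x)
}

#' Select the next item
#'
#' Returns the unanswered item with the highest information at the current
#' provisional measure. Ties are broken by smaller distance between the
#' provisional measure and the item difficulty, then by lexicographic item
#' id, so administrations are reproducible.
#'
#' @param session a running `cat_session`.
#' @return an item id.
#' @export
select_next_item <- function(session) {
  stopifnot(inherits(session, "cat_session"))
  if (session$stopped) stop("session has stopped", call. = FALSE)
  pool <- session$bank$items[
    !session$bank$items$item_id %in% session$administered$item_id, ,
    drop = FALSE]
  if (!nrow(pool)) stop("no unanswered items remain", call. = FALSE)
  info <- .rsm_ew(session$current_theta, pool$delta, session$bank$taus)$w
  dist <- abs(session$current_theta - pool$delta)
  ord <- order(-info, dist, pool$item_id)
  pool$item_id[ord[1L]]
}

#' Record a response and update the session
#'
#' Appends the response; once at least three responses are in and the
#' pattern is not all-minimum/all-maximum, re-estimates the measure by
#' maximum likelihood after every response. Before estimation activates, a
#' warm-up heuristic nudges the provisional measure by +0.7 logits for an
#' above-midpoint score, -0.7 for below, unchanged at the midpoint, so item
#' selection stays adaptive from the first response. Stop rules are
#' evaluated after every update.
#'
#' @param session a running `cat_session`.
#' @param item_id id of the administered item (must not have been
#'   administered before).
#' @param score integer response in `0..m`.
#' @return the updated `cat_session`.
#' @export
record_response <- function(session, item_id, score) {
  stopifnot(inherits(session, "cat_session"))
  if (session$stopped) stop("session has stopped", call. = FALSE)
  item_id <- as.character(item_id)
  m <- session$bank$n_categories - 1L
  if (item_id %in% session$administered$item_id)
    stop("item '", item_id, "' already administered", call. = FALSE)
  .bank_deltas(session$bank, item_id)  # errors on unknown id
  score <- as.integer(score)
  if (is.na(score) || score < 0L || score > m)
    stop("score must be an integer in 0..", m, call. = FALSE)

  resp <- c(as.integer(session$administered$score), score)
  names(resp) <- c(session$administered$item_id, item_id)

  if (length(resp) >= 3L && !is_extreme_pattern(resp, session$bank)) {
    est <- mle_estimate(resp, session$bank,
                        start_theta = session$current_theta)
    session$current_theta <- est$theta
    session$current_se <- est$se
    session$estimation_active <- TRUE
  } else {
    mid <- m / 2
    session$current_theta <- session$current_theta +
      if (score > mid) 0.7 else if (score < mid) -0.7 else 0
    session$current_se <- NA_real_
    session$estimation_active <- FALSE
  }

  session$administered <- rbind(
    session$administered,
    data.frame(step = nrow(session$administered) + 1L, item_id = item_id,
               score = score, theta = session$current_theta,
               se = session$current_se, stringsAsFactors = FALSE)
  )
  dec <- should_stop(session)
  session$stopped <- dec$stop
  session$stop_reason <- dec$reason
  session
}

#' Evaluate the stop rules
#'
#' Stops when (a) at least `min_items` responses are in, estimation is
#' active, and the standard error is at or below the threshold (inclusive);
#' (b) `max_items` is reached; or (c) the bank is exhausted.
#'
#' @param session a `cat_session`.
#' @return list `stop` (flag) and `reason` (`"se_met"`, `"max_items"`,
#'   `"bank_exhausted"`, `"none"`).
#' @export
should_stop <- function(session) {
  stopifnot(inherits(session, "cat_session"))
  n <- nrow(session$administered)
  if (n >= session$rules$min_items && session$estimation_active &&
      !is.na(session$current_se) &&
      session$current_se <= session$rules$se_threshold)
    return(list(stop = TRUE, reason = "se_met"))
  if (n >= session$rules$max_items)
    return(list(stop = TRUE, reason = "max_items"))
  if (n >= nrow(session$bank$items))
    return(list(stop = TRUE, reason = "bank_exhausted"))
  list(stop = FALSE, reason = "none")
}

#' Run a complete adaptive session against a responder
#'
#' Drives the select/record loop until a stop rule fires, then recomputes
#' the final measure by maximum likelihood over all administered responses
#' (extreme patterns via the extreme-score adjustment).
#'
#' @param bank an `rsm_bank`.
#' @param responder function `item_id -> score`; called once per
#'   administered item. An out-of-range return aborts with the partial log
#'   attached to the error condition (field `session`).
#' @param rules a [stop_rules()] object.
#' @param initial_rating see [start_session()].
#' @return list of class `cat_result`: `estimate` (final `rsm_estimate`),
#'   `log` (administration data frame), `session`, `stop_reason`.
#' @export
run_scripted_session <- function(bank, responder, rules = stop_rules(),
                                 initial_rating = NULL) {
  session <- start_session(bank, initial_rating, rules)
  while (!session$stopped) {
    item <- select_next_item(session)
    score <- responder(item)
    session <- tryCatch(
      record_response(session, item, score),
      error = function(e) {
        cnd <- simpleError(paste0("responder gave an invalid answer for item '",
                                  item, "': ", conditionMessage(e)))
        cnd$session <- session
        stop(cnd)
      }
    )
  }
  resp <- stats::setNames(as.integer(session$administered$score),
                          session$administered$item_id)
  est <- mle_estimate(resp, bank, start_theta = session$current_theta)
  structure(list(estimate = est, log = session$administered,
                 session = session, stop_reason = session$stop_reason),
            class = "cat_result")
}

#' @export
print.cat_result <- function(x, ...) {
  cat(sprintf("Adaptive test complete: %d items, stop rule '%s'\n",
              nrow(x$log), x$stop_reason))
  print(x$estimate)
  invisible(x)
}

#' Write a session log as CSV
#'
#' Columns `step,item_id,score,theta,se,stopped,reason`; `theta`/`se` are
#' blank before estimation became active.
#'
#' @param session a `cat_session` (or the `session` field of a
#'   `cat_result`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(session, path) {
  stopifnot(inherits(session, "cat_session"))
  log <- session$administered
  n <- nrow(log)
  log$stopped <- c(rep(FALSE, max(0L, n - 1L)),
                   if (n) session$stopped else logical())
  log$reason <- c(rep("none", max(0L, n - 1L)),
                  if (n) session$stop_reason else character())
  utils::write.csv(log, path, row.names = FALSE, na = "")
  invisible(path)
}
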