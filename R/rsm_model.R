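#' Rasch rating scale model mathematics
#'
#' Under the rating scale model the probability that a person at measure
#' `theta` scores category `k` (k = 0..m) on item `i` is
#' \deqn{P(X_i = k) = \frac{\exp(k(\theta - \delta_i) - \sum_{j \le k} \tau_j)}
#'                        {\sum_{c=0}^{m} \exp(c(\theta - \delta_i) - \sum_{j \le c} \tau_j)}}
#' with the empty sum equal to zero. All items share the threshold offsets
#' `tau`; only the overall difficulty `delta` varies by item. Exponentials
#' are stabilized by subtracting the maximum log term, so the model evaluates
#' cleanly over the whole working range of `theta`.
#'
#' @name rsm_model
NULL

# cumulative threshold sums c(0, tau1, tau1+tau2, ...), length m+1
.cumtau <- function(taus) c(0, cumsum(taus))

# log unnormalized category weights for one (theta, delta): length m+1
.rsm_lognum <- function(theta, delta, cumtau) {
  k <- seq_along(cumtau) - 1L
  k * (theta - delta) - cumtau
}

#' Category response probabilities
#'
#' @param theta finite person measure (logits).
#' @param delta item overall difficulty (logits).
#' @param taus shared threshold offsets.
#' @return numeric vector of `length(taus) + 1` probabilities over scores
#'   `0..m`, summing to 1.
#' @export
category_probabilities <- function(theta, delta, taus) {
  if (!is.finite(theta)) stop("theta must be finite", call. = FALSE)
  ln <- .rsm_lognum(theta, delta, .cumtau(taus))
  w <- exp(ln - max(ln))
  w / sum(w)
}

# probability matrix: n_items rows x (m+1) categories at a single theta
.rsm_prob_matrix <- function(theta, deltas, taus) {
  cumtau <- .cumtau(taus)
  k <- seq_along(cumtau) - 1L
  ln <- outer(theta - deltas, k) - matrix(cumtau, length(deltas),
                                          length(cumtau), byrow = TRUE)
  ln <- ln - apply(ln, 1L, max)
  w <- exp(ln)
  w / rowSums(w)
}

#' Expected category score of an item
#'
#' `E(theta) = sum k P_k`; strictly increasing in `theta` with limits 0 and
#' `m`. This is the score function component of the maximum-likelihood
#' estimating equation.
#'
#' @inheritParams category_probabilities
#' @return expected score on the `0..m` scale.
#' @export
expected_score <- function(theta, delta, taus) {
  p <- category_probabilities(theta, delta, taus)
  sum((seq_along(p) - 1L) * p)
}

#' Item information (category-score variance)
#'
#' For a polytomous Rasch item the Fisher information at `theta` equals the
#' variance of the category score, `W = sum k^2 P_k - E^2`; the item is most
#' informative where its expected score changes fastest.
#'
#' @inheritParams category_probabilities
#' @return information on the logit^-2 scale, strictly positive for finite
#'   `theta`.
#' @export
score_variance <- function(theta, delta, taus) {
  p <- category_probabilities(theta, delta, taus)
  k <- seq_along(p) - 1L
  e <- sum(k * p)
  sum(k^2 * p) - e^2
}

# vectorized E and W over items at one theta
.rsm_ew <- function(theta, deltas, taus) {
  p <- .rsm_prob_matrix(theta, deltas, taus)
  k <- seq_len(ncol(p)) - 1L
  e <- as.vector(p %*% k)
  w <- as.vector(p %*% k^2) - e^2
  list(e = e, w = w, p = p)
}

#' Test information of an item set
#'
#' Information is additive over items; its reciprocal square root is the
#' standard error of measurement at `theta`.
#'
#' @param theta person measure (logits).
#' @param deltas numeric vector of item difficulties (possibly empty).
#' @param taus shared threshold offsets.
#' @return sum of item informations (0 for an empty set).
#' @export
test_information <- function(theta, deltas, taus) {
  if (!length(deltas)) return(0)
  sum(.rsm_ew(theta, deltas, taus)$w)
}

#' Log-likelihood of a response pattern
#'
#' @param theta person measure (logits).
#' @param responses named integer vector of scores `0..m`, names being item
#'   ids present in `bank` (or a data frame with columns `item_id`, `score`).
#' @param bank an `rsm_bank`.
#' @return `sum_i log P(X_i = x_i | theta)`; 0 for an empty pattern. Concave
#'   in `theta`.
#' @export
log_likelihood <- function(theta, responses, bank) {
  r <- as_responses(responses, bank)
  if (!nrow(r)) return(0)
  p <- .rsm_prob_matrix(theta, r$delta, bank$taus)
  sum(log(p[cbind(seq_len(nrow(r)), r$score + 1L)]))
}

#' Normalize a response pattern
#'
#' Accepts either a named integer vector (`names` = item ids) or a data frame
#' with `item_id` and `score` columns; checks ids against the bank and scores
#' against the category range.
#'
#' @inheritParams log_likelihood
#' @return data frame with columns `item_id`, `score`, `delta`.
#' @export
as_responses <- function(responses, bank) {
  stopifnot(inherits(bank, "rsm_bank"))
  if (is.data.frame(responses)) {
    ids <- as.character(responses$item_id)
    sc <- responses$score
  } else {
    ids <- names(responses)
    sc <- unname(responses)
    if (length(sc) && is.null(ids))
      stop("responses must carry item ids (names or item_id column)",
           call. = FALSE)
  }
  if (anyDuplicated(ids))
    stop("duplicate item_id in response pattern", call. = FALSE)
  m <- bank$n_categories - 1L
  sc <- as.integer(sc)
  if (length(sc) && (anyNA(sc) || any(sc < 0L | sc > m)))
    stop("scores must be integers in 0..", m, call. = FALSE)
  data.frame(item_id = ids, score = sc,
             delta = if (length(ids)) .bank_deltas(bank, ids) else numeric(),
             stringsAsFactors = FALSE)
}
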