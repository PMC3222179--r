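#' Person measure estimation
#'
#' Maximum-likelihood estimation of the person measure from a response
#' pattern under anchored item parameters. The Rasch log-likelihood is
#' concave in `theta` with score function `sum(x_i - E_i)` and (observed =
#' expected) information `sum W_i`, so the Newton-Raphson update
#' `theta <- theta + sum(x_i - E_i) / sum(W_i)` converges reliably; the
#' per-iteration step is capped to guard against overshoot from a distant
#' start. Patterns with every response in the minimum or maximum category
#' have no finite maximizer and are handled by the extreme-score adjustment.
#'
#' @name estimation
NULL

#' @rdname estimation
#' @section Estimate objects:
#' `rsm_estimate`: list with `theta` (logits), `se` (logits; `Inf` when the
#' information is 0), `n_items`, `iterations`, `converged`, `extreme`,
#' `method` (`"newton_raphson"`, `"grid_oracle"` or `"extreme_adjusted"`).
NULL

.new_estimate <- function(theta, se, n_items, iterations, converged,
                          extreme, method) {
  structure(list(theta = theta, se = se, n_items = n_items,
                 iterations = iterations, converged = converged,
                 extreme = extreme, method = method),
            class = "rsm_estimate")
}

#' @export
print.rsm_estimate <- function(x, ...) {
  cat(sprintf("Person measure %.3f logits (SE %.3f), %d items [%s%s]\n",
              x$theta, x$se, x$n_items, x$method,
              if (x$extreme) ", extreme pattern" else ""))
  invisible(x)
}

#' Is a response pattern extreme?
#'
#' @inheritParams log_likelihood
#' @return `TRUE` iff every score is 0 or every score is the maximum
#'   category.
#' @export
is_extreme_pattern <- function(responses, bank) {
  r <- as_responses(responses, bank)
  if (!nrow(r)) return(FALSE)
  m <- bank$n_categories - 1L
  all(r$score == 0L) || all(r$score == m)
}

#' Maximum-likelihood person measure (Newton-Raphson)
#'
#' @inheritParams log_likelihood
#' @param start_theta starting value (logits).
#' @param tol convergence tolerance on the update step (logits).
#' @param max_iter iteration cap.
#' @param max_step largest allowed single update (logits).
#' @param clamp interval the estimate is kept within.
#' @param extreme_adjustment score-point adjustment applied to extreme
#'   patterns (see [adjust_extreme_pattern()]).
#' @return an `rsm_estimate`. Extreme patterns are routed through
#'   [adjust_extreme_pattern()] and flagged rather than diverging.
#' @export
mle_estimate <- function(responses, bank, start_theta = 0, tol = 0.001,
                         max_iter = 50L, max_step = 1.0, clamp = c(-6, 6),
                         extreme_adjustment = 0.3) {
  r <- as_responses(responses, bank)
  if (!nrow(r)) stop("cannot estimate from an empty response pattern",
                     call. = FALSE)
  if (is_extreme_pattern(r, bank))
    return(adjust_extreme_pattern(r, bank, adjustment = extreme_adjustment,
                                  clamp = clamp))
  theta <- start_theta
  total <- sum(r$score)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    ew <- .rsm_ew(theta, r$delta, bank$taus)
    step <- (total - sum(ew$e)) / sum(ew$w)
    step <- max(min(step, max_step), -max_step)
    theta <- max(min(theta + step, clamp[2L]), clamp[1L])
    if (abs(step) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  info <- test_information(theta, r$delta, bank$taus)
  .new_estimate(theta, if (info > 0) 1 / sqrt(info) else Inf, nrow(r),
                iter, converged, FALSE, "newton_raphson")
}

#' Brute-force likelihood grid oracle
#'
#' Evaluates the log-likelihood on a fixed grid and returns the argmax. Slow
#' but assumption-free; kept as an audit tool and as the reference the
#' Newton-Raphson estimator is verified against.
#'
#' @inheritParams log_likelihood
#' @param lower,upper,step grid specification (logits).
#' @return an `rsm_estimate` with method `"grid_oracle"`.
#' @export
grid_oracle <- function(responses, bank, lower = -6, upper = 6, step = 0.001) {
  r <- as_responses(responses, bank)
  if (!nrow(r)) stop("cannot estimate from an empty response pattern",
                     call. = FALSE)
  if (!(lower < upper) || step <= 0) stop("empty theta grid", call. = FALSE)
  grid <- seq(lower, upper, by = step)
  cumtau <- .cumtau(bank$taus)
  k <- seq_along(cumtau) - 1L
  ll <- numeric(length(grid))
  for (i in seq_len(nrow(r))) {
    ln <- outer(grid - r$delta[i], k) - matrix(cumtau, length(grid),
                                               length(cumtau), byrow = TRUE)
    mx <- apply(ln, 1L, max)
    ll <- ll + ln[cbind(seq_along(grid), r$score[i] + 1L)] - mx -
      log(rowSums(exp(ln - mx)))
  }
  theta <- grid[which.max(ll)]
  info <- test_information(theta, r$delta, bank$taus)
  .new_estimate(theta, if (info > 0) 1 / sqrt(info) else Inf, nrow(r),
                length(grid), TRUE, is_extreme_pattern(r, bank),
                "grid_oracle")
}

#' Finite measure for an extreme response pattern
#'
#' An all-minimum (total score 0) or all-maximum (total score N*m) pattern
#' has an unbounded likelihood maximizer. Following common Rasch-software
#' convention, the raw total is moved `adjustment` score points inward
#' (0 -> adjustment, N*m -> N*m - adjustment) and the score equation
#' `sum E_i(theta) = adjusted total` is solved for `theta`.
#'
#' @inheritParams log_likelihood
#' @param adjustment score points, in (0, 1); default 0.3.
#' @param clamp interval the estimate is kept within.
#' @return an `rsm_estimate` with `extreme = TRUE`.
#' @export
adjust_extreme_pattern <- function(responses, bank, adjustment = 0.3,
                                   clamp = c(-6, 6)) {
  r <- as_responses(responses, bank)
  if (!nrow(r)) stop("empty response pattern", call. = FALSE)
  stopifnot(adjustment > 0, adjustment < 1)
  m <- bank$n_categories - 1L
  total <- sum(r$score)
  target <- if (total == 0L) adjustment
            else if (total == nrow(r) * m) nrow(r) * m - adjustment
            else total  # non-extreme: solve the ordinary score equation
  f <- function(th) sum(.rsm_ew(th, r$delta, bank$taus)$e) - target
  # expected score is strictly increasing, so a sign change brackets the root
  lo <- clamp[1L]; hi <- clamp[2L]
  theta <- if (f(lo) >= 0) lo else if (f(hi) <= 0) hi
           else stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  info <- test_information(theta, r$delta, bank$taus)
  .new_estimate(theta, if (info > 0) 1 / sqrt(info) else Inf, nrow(r),
                NA_integer_, TRUE, is_extreme_pattern(r, bank),
                "extreme_adjusted")
}

#' Standard error of measurement
#'
#' @inheritParams test_information
#' @return `1 / sqrt(test information)`; `Inf` when the information is 0.
#' @export
standard_error <- function(theta, deltas, taus) {
  info <- test_information(theta, deltas, taus)
  if (info > 0) 1 / sqrt(info) else Inf
}

#' Standard-error stop threshold from reliability
#'
#' The precision target for adaptive administration is derived from the
#' calibration sample's person statistics: `SE_stop = SD * sqrt(1 - r)`,
#' the error SD implied by a person separation reliability `r`. For the
#' packaged bank (SD 2.09, reliability 0.94) this gives 0.51 logits.
#'
#' @param pop_sd person measure SD of the calibration sample (logits).
#' @param reliability person separation reliability in `[0, 1]`.
#' @return stop threshold in logits.
#' @export
#' @examples
#' stop_se_from_reliability(2.09, 0.94)  # 0.51
stop_se_from_reliability <- function(pop_sd, reliability) {
  stopifnot(pop_sd >= 0, reliability >= 0, reliability <= 1)
  pop_sd * sqrt(1 - reliability)
}
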