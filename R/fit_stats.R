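#' Person-fit diagnostics
#'
#' Residual-based fit of a response pattern to the rating scale model at a
#' given person measure. The standardized residual of one response is
#' `z_i = (x_i - E_i) / sqrt(W_i)`. Outfit MNSQ is the unweighted mean of
#' `z_i^2` (sensitive to off-target outliers); infit MNSQ is the
#' information-weighted version `sum (x_i - E_i)^2 / sum W_i` (sensitive to
#' unexpected on-target patterns). Both have expectation close to 1 under
#' model-consistent responding; an outfit of 2.0 or greater flags a possibly
#' aberrant pattern.
#'
#' @name fit_stats
NULL

#' Standardized residual of one response
#'
#' @param score observed integer score.
#' @param theta person measure (logits).
#' @param delta item difficulty (logits).
#' @param taus shared thresholds.
#' @return `(score - E) / sqrt(W)`.
#' @export
standardized_residual <- function(score, theta, delta, taus) {
  e <- expected_score(theta, delta, taus)
  w <- score_variance(theta, delta, taus)
  (score - e) / sqrt(w)
}

#' Infit and outfit mean squares of a response pattern
#'
#' @inheritParams log_likelihood
#' @param theta the person measure the residuals are taken at (normally the
#'   person's estimate).
#' @param cutoff outfit flag threshold (default 2.0).
#' @return list of class `rsm_fit`: `infit_mnsq`, `outfit_mnsq`, `n_items`,
#'   `flagged` (`outfit_mnsq >= cutoff`).
#' @export
fit_indices <- function(responses, theta, bank, cutoff = 2.0) {
  r <- as_responses(responses, bank)
  if (!nrow(r)) stop("fit statistics need at least one response", call. = FALSE)
  ew <- .rsm_ew(theta, r$delta, bank$taus)
  sq <- (r$score - ew$e)^2
  outfit <- mean(sq / ew$w)
  infit <- sum(sq) / sum(ew$w)
  structure(list(infit_mnsq = infit, outfit_mnsq = outfit,
                 n_items = nrow(r), flagged = outfit >= cutoff),
            class = "rsm_fit")
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("Person fit over %d items: infit MNSQ %.2f, outfit MNSQ %.2f%s\n",
              x$n_items, x$infit_mnsq, x$outfit_mnsq,
              if (x$flagged) " [FLAGGED]" else ""))
  invisible(x)
}

#' @rdname fit_indices
#' @export
outfit_mnsq <- function(responses, theta, bank) {
  fit_indices(responses, theta, bank)$outfit_mnsq
}

#' @rdname fit_indices
#' @export
infit_mnsq <- function(responses, theta, bank) {
  fit_indices(responses, theta, bank)$infit_mnsq
}

#' Flag an aberrant response pattern
#'
#' @param fit an `rsm_fit`.
#' @param cutoff outfit threshold; 2.0 by convention.
#' @return `TRUE` iff `outfit_mnsq >= cutoff`.
#' @export
flag_person <- function(fit, cutoff = 2.0) {
  stopifnot(inherits(fit, "rsm_fit"))
  fit$outfit_mnsq >= cutoff
}
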