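#' Model-based response generation and the CAT-versus-NAT study
#'
#' The study runner replays the efficiency/precision experiment: a cohort of
#' simulated respondents takes the adaptive test, full-length response
#' vectors are then generated at each person's adaptive estimate, and those
#' vectors are re-estimated with the anchored bank parameters as the
#' nonadaptive benchmark. The comparison statistics (paired t on lengths and
#' measures, Pearson correlation, efficiency gain) come from the reporting
#' layer.
#'
#' @name simulation
NULL

#' Draw one response from the model
#'
#' Inverse-CDF sampling: a uniform draw is placed on the cumulative category
#' probabilities at `theta`, so the marginal distribution of scores equals
#' [category_probabilities()]. Uses R's global RNG stream.
#'
#' @inheritParams category_probabilities
#' @return integer score in `0..m`.
#' @export
generate_response <- function(theta, delta, taus) {
  p <- category_probabilities(theta, delta, taus)
  u <- stats::runif(1L)
  sum(u > cumsum(p))  # smallest k with cumulative probability >= u
}

#' Generate a persons-by-items response rectangle
#'
#' @param thetas person measures, one per row.
#' @param bank an `rsm_bank`.
#' @return integer matrix `length(thetas)` x `nrow(bank$items)`, columns
#'   named by item id.
#' @export
generate_response_matrix <- function(thetas, bank) {
  stopifnot(inherits(bank, "rsm_bank"))
  n <- length(thetas)
  J <- nrow(bank$items)
  out <- matrix(NA_integer_, n, J,
                dimnames = list(NULL, bank$items$item_id))
  for (i in seq_len(n)) {
    p <- .rsm_prob_matrix(thetas[i], bank$items$delta, bank$taus)
    u <- stats::runif(J)
    out[i, ] <- as.integer(rowSums(u > t(apply(p, 1L, cumsum))))
  }
  out
}

#' Run the adaptive test for one simulated person
#'
#' Responses are generated from the model at `true_theta`; the session runs
#' under the given stop rules.
#'
#' @param true_theta generating person measure (logits).
#' @param bank an `rsm_bank`.
#' @param rules a [stop_rules()] object.
#' @param initial_rating optional seed rating passed to [start_session()].
#' @return the [run_scripted_session()] result.
#' @export
run_cat_for_person <- function(true_theta, bank, rules = stop_rules(),
                               initial_rating = NULL) {
  responder <- function(item_id) {
    d <- .bank_deltas(bank, item_id)
    generate_response(true_theta, d, bank$taus)
  }
  run_scripted_session(bank, responder, rules, initial_rating)
}

#' Study configuration
#'
#' Defaults reproduce the published study conditions: 200 respondents drawn
#' from Normal(0.71, 1.62^2) logits, stop rules SE 0.51 / minimum 10 items /
#' maximum the full bank.
#'
#' @param n_persons cohort size.
#' @param person_mean,person_sd generating Normal distribution (logits).
#' @param rules a [stop_rules()] object.
#' @param seed master seed; per-person substreams are derived from it.
#' @param nat_at_true generate the nonadaptive vectors at the true measures
#'   instead of the adaptive estimates (default `FALSE`, the study's design).
#' @return list of class `study_config`.
#' @export
study_config <- function(n_persons = 200L, person_mean = 0.71,
                         person_sd = 1.62, rules = stop_rules(),
                         seed = 1L, nat_at_true = FALSE) {
  stopifnot(n_persons >= 1L, person_sd > 0, inherits(rules, "cat_rules"))
  structure(list(n_persons = as.integer(n_persons),
                 person_mean = person_mean, person_sd = person_sd,
                 rules = rules, seed = as.integer(seed),
                 nat_at_true = isTRUE(nat_at_true)),
            class = "study_config")
}

# deterministic per-person substream seed, kept inside 32-bit range
.derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 7919) %% 2147483647)
}

#' Run the CAT-versus-NAT study
#'
#' Two steps mirror the study design: (1) each simulated person takes the
#' adaptive test, responses generated from the model at their true measure;
#' (2) a full-length response vector is generated for each person at their
#' adaptive estimate, and re-estimated with anchored parameters as the
#' nonadaptive measure (extreme vectors via the 0.3 extreme-score
#' adjustment, so the cohort stays intact). Person-fit statistics are
#' computed on the full-length vectors at the nonadaptive estimates.
#'
#' @param config a [study_config()].
#' @param bank an `rsm_bank` (default the packaged IPQ-18 bank).
#' @return list of class `study_result`: `persons` (one row per person:
#'   `person,true_theta,cat_theta,cat_se,cat_length,cat_stop_reason,
#'   nat_theta,nat_se,infit_mnsq,outfit_mnsq,flagged`), `totals`
#'   (`cat_responses`, `nat_responses`), `config`, and `report` (the
#'   [comparison_report()]).
#' @export
run_study <- function(config = study_config(), bank = builtin_ipq18()) {
  stopifnot(inherits(config, "study_config"), inherits(bank, "rsm_bank"))
  n <- config$n_persons
  J <- nrow(bank$items)

  set.seed(config$seed)
  true_theta <- stats::rnorm(n, config$person_mean, config$person_sd)

  rec <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.derive_seed(config$seed, i))
    cat_res <- run_cat_for_person(true_theta[i], bank, config$rules)
    gen_theta <- if (config$nat_at_true) true_theta[i]
                 else cat_res$estimate$theta
    nat_vec <- generate_response_matrix(gen_theta, bank)[1L, ]
    nat_est <- mle_estimate(nat_vec, bank)
    fit <- fit_indices(nat_vec, nat_est$theta, bank)
    rec[[i]] <- data.frame(
      person = i, true_theta = true_theta[i],
      cat_theta = cat_res$estimate$theta, cat_se = cat_res$estimate$se,
      cat_length = nrow(cat_res$log), cat_stop_reason = cat_res$stop_reason,
      nat_theta = nat_est$theta, nat_se = nat_est$se,
      infit_mnsq = fit$infit_mnsq, outfit_mnsq = fit$outfit_mnsq,
      flagged = fit$flagged, stringsAsFactors = FALSE
    )
  }
  persons <- do.call(rbind, rec)
  totals <- list(cat_responses = sum(persons$cat_length),
                 nat_responses = n * J)
  out <- structure(list(persons = persons, totals = totals, config = config,
                        bank_size = J, report = NULL),
                   class = "study_result")
  out$report <- comparison_report(out)
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("CAT-versus-NAT study: %d persons x %d-item bank\n",
              nrow(x$persons), x$bank_size))
  cat(sprintf("  mean adaptive length %.2f items; responses %d vs %d\n",
              mean(x$persons$cat_length), x$totals$cat_responses,
              x$totals$nat_responses))
  print(x$report)
  invisible(x)
}

#' Write per-person study output as CSV
#'
#' @param study a `study_result` (or a list of them, written with a
#'   `replicate` column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(study, path) {
  if (inherits(study, "study_result")) study <- list(study)
  rows <- do.call(rbind, lapply(seq_along(study), function(r) {
    df <- study[[r]]$persons
    cbind(replicate = r, df)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
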