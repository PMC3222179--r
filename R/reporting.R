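#' Study reporting and comparison statistics
#'
#' Descriptive and analytic summaries of a CAT-versus-NAT study: paired t
#' tests on test lengths and person measures, Pearson correlation between
#' the two sets of measures, the efficiency gain in administered responses,
#' moment descriptives of the adaptive measures, and (when demographics are
#' supplied) chi-square independence tables and one-way group comparisons.
#'
#' @name reporting
NULL

#' Efficiency gain of adaptive over full-length administration
#'
#' `1 - cat_total / nat_total`: the fraction of item administrations saved.
#'
#' @param cat_total total responses under adaptive testing.
#' @param nat_total total responses under full-length testing (> 0).
#' @return fraction in `[0, 1)`.
#' @export
#' @examples
#' efficiency_gain(2084, 3600)  # 0.42
efficiency_gain <- function(cat_total, nat_total) {
  stopifnot(nat_total > 0, cat_total >= 0, cat_total <= nat_total)
  1 - cat_total / nat_total
}

#' Paired t test
#'
#' Standard paired t on matched vectors; a zero-variance difference vector
#' is reported with a `degenerate` flag instead of an error (t is `Inf`
#' signed by the mean difference, or `NaN` when all differences are 0).
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return list `t`, `df` (`n - 1`), `p` (two-sided), `mean_diff`,
#'   `degenerate`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    tval <- if (mean(d) == 0) NaN else sign(mean(d)) * Inf
    return(list(t = tval, df = n - 1L,
                p = if (is.nan(tval)) 1 else 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tval <- mean(d) / (sd_d / sqrt(n))
  list(t = tval, df = n - 1L, p = 2 * stats::pt(-abs(tval), n - 1L),
       mean_diff = mean(d), degenerate = FALSE)
}

#' Pearson correlation
#'
#' @param x,y numeric vectors of equal length.
#' @return the product-moment correlation coefficient.
#' @export
pearson_r <- function(x, y) stats::cor(x, y, method = "pearson")

#' Chi-square test of independence
#'
#' Pearson chi-square on an r x c contingency table, without continuity
#' correction; `df = (r - 1)(c - 1)`.
#'
#' @param tab matrix of non-negative counts with positive margins.
#' @return list `chi2`, `df`, `p`.
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), all(rowSums(tab) > 0), all(colSums(tab) > 0))
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Moment descriptives
#'
#' Mean, sample SD (n - 1 denominator), median, moment-coefficient skewness
#' `g1 = m3 / m2^{3/2}` and excess kurtosis `g2 = m4 / m2^2 - 3` (central
#' moments with n denominator). Skewness and kurtosis are `NA` for a
#' constant vector.
#'
#' @param values numeric vector.
#' @return list `n`, `mean`, `sd`, `median`, `skewness`, `kurtosis`.
#' @export
descriptives <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  stopifnot(n >= 1L)
  m <- mean(values)
  cm <- function(p) mean((values - m)^p)
  m2 <- cm(2)
  list(n = n, mean = m, sd = stats::sd(values), median = stats::median(values),
       skewness = if (m2 > 0) cm(3) / m2^1.5 else NA_real_,
       kurtosis = if (m2 > 0) cm(4) / m2^2 - 3 else NA_real_)
}

#' Comparison report for a study
#'
#' Assembles the analytic summary of a `study_result`: paired t on test
#' lengths (adaptive versus the constant full-length arm) and on person
#' measures, the Pearson correlation of the two measure sets, the
#' efficiency gain, and descriptives of the adaptive measures. When a
#' demographics data frame is supplied (columns `person`, `gender`, and any
#' of `age_band`, `department`, `participant`), gender-by-variable
#' chi-square tables and one-way F comparisons of the adaptive measures
#' across each variable's groups are appended.
#'
#' @param study a `study_result`.
#' @param demographics optional data frame as described above.
#' @return list of class `comparison_report`.
#' @export
comparison_report <- function(study, demographics = NULL) {
  stopifnot(inherits(study, "study_result"))
  p <- study$persons
  n <- nrow(p)
  rep <- list(
    n_persons = n,
    paired_t_length = if (n >= 2L)
      paired_t(p$cat_length, rep(study$bank_size, n)) else NULL,
    paired_t_measure = if (n >= 2L)
      paired_t(p$cat_theta, p$nat_theta) else NULL,
    pearson_r = if (n >= 2L) pearson_r(p$cat_theta, p$nat_theta) else NA_real_,
    efficiency_gain = efficiency_gain(study$totals$cat_responses,
                                      study$totals$nat_responses),
    mean_cat_length = mean(p$cat_length),
    descriptives_cat = descriptives(p$cat_theta),
    n_flagged = sum(p$flagged),
    demographics = NULL
  )
  if (!is.null(demographics)) {
    stopifnot(all(c("person", "gender") %in% names(demographics)))
    dm <- merge(p, demographics, by = "person")
    vars <- intersect(c("age_band", "department", "participant"),
                      names(dm))
    rep$demographics <- lapply(stats::setNames(vars, vars), function(v) {
      tab <- table(dm[[v]], dm$gender)
      grp <- factor(dm[[v]])
      aov <- if (nlevels(grp) >= 2L && all(table(grp) >= 2L)) {
        f <- stats::oneway.test(dm$cat_theta ~ grp, var.equal = TRUE)
        list(F = unname(f$statistic), df1 = unname(f$parameter[1L]),
             df2 = unname(f$parameter[2L]), p = f$p.value)
      } else NULL
      list(counts = tab, chi_square = chi_square_independence(tab),
           anova = aov)
    })
  }
  structure(rep, class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("  efficiency gain %.3f (mean length %.2f); r(CAT, NAT) %.4f\n",
              x$efficiency_gain, x$mean_cat_length, x$pearson_r))
  if (!is.null(x$paired_t_length))
    cat(sprintf("  paired t (length): t(%d) = %.2f, p %s\n",
                x$paired_t_length$df, x$paired_t_length$t,
                format.pval(x$paired_t_length$p, digits = 3)))
  if (!is.null(x$paired_t_measure))
    cat(sprintf("  paired t (measure): t(%d) = %.2f, p = %.3f\n",
                x$paired_t_measure$df, x$paired_t_measure$t,
                x$paired_t_measure$p))
  d <- x$descriptives_cat
  cat(sprintf(
    "  adaptive measures: mean %.2f (SD %.2f), median %.2f, skew %.2f, kurt %.2f\n",
    d$mean, d$sd, d$median, d$skewness, d$kurtosis))
  if (x$n_flagged > 0)
    cat(sprintf("  %d pattern(s) flagged by outfit >= 2\n", x$n_flagged))
  if (!is.null(x$demographics))
    for (v in names(x$demographics)) {
      cs <- x$demographics[[v]]$chi_square
      cat(sprintf("  %s x gender: chi2(%d) = %.2f, p = %.3f\n",
                  v, cs$df, cs$chi2, cs$p))
    }
  invisible(x)
}

#' Render a plain-text report
#'
#' @param study a `study_result`.
#' @param demographics optional demographics data frame (see
#'   [comparison_report()]).
#' @param path optional output path; when given the text is written there.
#' @return the report lines, invisibly when `path` is given.
#' @export
render_report <- function(study, demographics = NULL, path = NULL) {
  rep <- comparison_report(study, demographics)
  txt <- utils::capture.output({
    cat(sprintf("CAT-versus-NAT study report (%d persons)\n", rep$n_persons))
    print(rep)
  })
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
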