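# Two-group study statistics: Welch t-tests, Holm-Sidak step-down
# correction, chi-square goodness of fit, and mean +/- SEM summaries.

#' Welch two-sample t-test
#'
#' Two-tailed unpaired t-test with Welch's correction (unequal
#' variances); the Welch-Satterthwaite degrees of freedom are not
#' rounded. Thin wrapper around [stats::t.test()] returning the bare
#' (t, df, p) triple.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop_bad("each sample needs n >= 2")
  if (!all(is.finite(sample_a)) || !all(is.finite(sample_b)))
    stop_bad("samples must be finite")
  if (sd(sample_a) == 0 && sd(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b))
      return(list(t = 0, df = length(sample_a) + length(sample_b) - 2, p = 1))
    stop_bad("zero variance in both samples")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Sorts the m raw p-values ascending, sets the k-th adjusted value to
#' `max_{j<=k} 1 - (1 - p_(j))^(m - j + 1)` clipped to 1, and returns the
#' adjusted values in the original input order. Adjusted values are never
#' below the raw ones and are monotone in the order statistics.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
holm_sidak <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_bad("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, cummax(1 - (1 - p[o])^(m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

#' Chi-square goodness of fit
#'
#' Pearson chi-square against expected cell proportions, no continuity
#' correction, df = k - 1, upper-tail p.
#'
#' @param observed non-negative integer counts.
#' @param expected_proportions proportions summing to 1.
#' @return list with `chi_sq`, `df`, `p`.
#' @export
chi_square_gof <- function(observed, expected_proportions) {
  if (any(observed < 0)) stop_bad("counts must be non-negative")
  if (abs(sum(expected_proportions) - 1) > 1e-8)
    stop_bad("expected proportions must sum to 1")
  if (any(expected_proportions <= 0)) stop_bad("zero expected cell")
  ht <- suppressWarnings(
    stats::chisq.test(observed, p = expected_proportions, correct = FALSE))
  list(chi_sq = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Significance stars
#'
#' The star bands use strict inequalities (`*` 0.01 < p < 0.05, `**`
#' 0.001 < p < 0.01, `***` 0.0001 < p < 0.001, `****` p < 0.0001);
#' boundary values fall to the weaker band, so p = 0.05 exactly is "ns".
#'
#' @param p p-value(s).
#' @return character vector of star codes ("ns" when not significant).
#' @export
significance_stars <- function(p) {
  vapply(p, function(x) {
    if (x < 1e-4) "****" else if (x < 1e-3) "***" else
      if (x < 1e-2) "**" else if (x < 0.05) "*" else "ns"
  }, "")
}

#' Standard error of the mean
#'
#' @param x numeric vector.
#' @return sd(x)/sqrt(n).
#' @export
sem <- function(x) sd(x) / sqrt(length(x))

#' Group comparison summary of a study table
#'
#' For every (measurement, age) cell of a two-genotype study, computes
#' group means and SEMs, the Welch t-test, and star codes. Measurements
#' listed in `adjust_measurements` (e.g. a body-weight timeline measured
#' at many timepoints) additionally get Holm-Sidak adjusted p-values
#' across their ages; stars always reflect the reported p (adjusted where
#' adjustment applies). Cells with fewer than 2 animals in either group
#' are skipped with a warning.
#'
#' @param table a `study_table` with genotypes WT and Ach.
#' @param adjust_measurements character vector of measurement names whose
#'   per-age p-values are jointly Holm-Sidak corrected.
#' @return data.frame of class `group_comparison` with one row per
#'   (measurement_name, age_weeks): means, SEMs, n's, `t_stat`,
#'   `df_welch`, `p_value`, `p_adjusted`, `stars`.
#' @export
summarize_groups <- function(table, adjust_measurements = character()) {
  table <- study_table(table)
  cells <- unique(table[c("measurement_name", "age_weeks")])
  cells <- cells[order(cells$measurement_name, cells$age_weeks), ]
  rows <- list()
  for (r in seq_len(nrow(cells))) {
    mname <- cells$measurement_name[r]; age <- cells$age_weeks[r]
    sub <- table[table$measurement_name == mname &
                   table$age_weeks == age, ]
    wt <- sub$value[sub$genotype == "WT"]
    ach <- sub$value[sub$genotype == "Ach"]
    if (length(wt) < 2L || length(ach) < 2L) {
      warning(sprintf("skipping %s at %s weeks: group with n < 2",
                      mname, age))
      next
    }
    ht <- tryCatch(welch_t(wt, ach), error = function(e) {
      warning(sprintf("skipping %s at %s weeks: %s", mname, age,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(ht)) next
    rows[[length(rows) + 1L]] <- data.frame(
      measurement_name = mname, age_weeks = age,
      n_wt = length(wt), n_ach = length(ach),
      mean_wt = mean(wt), mean_ach = mean(ach),
      sem_wt = sem(wt), sem_ach = sem(ach),
      t_stat = ht$t, df_welch = ht$df, p_value = ht$p,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    warning("no comparable (measurement, age) cells")
    out <- data.frame(measurement_name = character(), age_weeks = numeric(),
                      n_wt = integer(), n_ach = integer(),
                      mean_wt = numeric(), mean_ach = numeric(),
                      sem_wt = numeric(), sem_ach = numeric(),
                      t_stat = numeric(), df_welch = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      stars = character())
    class(out) <- c("group_comparison", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- out$p_value
  for (mname in intersect(adjust_measurements, out$measurement_name)) {
    sel <- out$measurement_name == mname
    out$p_adjusted[sel] <- holm_sidak(out$p_value[sel])
  }
  out$stars <- significance_stars(out$p_adjusted)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> WT vs Ach, mean +/- SEM, Welch t\n")
  df <- as.data.frame(x)
  df$mean_wt <- sprintf("%.4g +/- %.3g", df$mean_wt, df$sem_wt)
  df$mean_ach <- sprintf("%.4g +/- %.3g", df$mean_ach, df$sem_ach)
  print(df[c("measurement_name", "age_weeks", "mean_wt", "mean_ach",
             "p_value", "stars")], row.names = FALSE)
  invisible(x)
}
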