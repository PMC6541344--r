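#' Cohort-characteristic summary of one categorical variable
#'
#' Counts and one-decimal percentages per cohort, with a two-sided Fisher
#' exact test of the levels x cohorts table. `"unknown"` rows are excluded
#' from both the percentages' denominator and the test, and the denominator
#' is the variable's non-missing total within each cohort, applied
#' uniformly. Tables beyond `exact_cap` total observations use a
#' fixed-seed Monte-Carlo estimate of the exact p (>= 1e5 draws).
#'
#' @param trios A `trio_set`.
#' @param variable Name of a categorical trio field (e.g. `"ctd_subtype"`).
#' @param exact_cap Largest total count for which full enumeration is
#'   attempted (the r x c network algorithm); larger tables are simulated.
#' @param mc_seed Seed for the Monte-Carlo branch (private RNG stream).
#' @param mc_draws Monte-Carlo replicates.
#' @return A list of class `categorical_summary`: `variable`, `counts`
#'   (levels x cohorts), `percent` (character, one decimal), `fisher_p`,
#'   `method`.
#' @export
summarize_categorical <- function(trios, variable, exact_cap = 200L,
                                  mc_seed = 1L, mc_draws = 1e5) {
  if (!variable %in% names(trios))
    stop("no such trio variable: ", variable)
  v <- trios[[variable]]
  cohort <- trios$cohort
  keep <- v != "unknown" & cohort != "unknown"
  v <- v[keep]
  cohort <- cohort[keep]
  if (!length(v)) stop("variable '", variable, "' has no known values")
  tab <- table(factor(v), factor(cohort))
  empty <- colSums(tab) == 0
  if (any(empty))
    stop("cohort(s) with zero non-missing observations: ",
         paste(colnames(tab)[empty], collapse = ", "))
  pct <- matrix(format_percent(tab, rep(colSums(tab), each = nrow(tab))),
                nrow = nrow(tab), dimnames = dimnames(tab))
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    p <- 1
    method <- "degenerate"
  } else if (sum(tab) <= exact_cap) {
    p <- stats::fisher.test(tab, conf.int = FALSE)$p.value
    method <- "exact"
  } else {
    p <- with_preserved_seed(mc_seed,
      stats::fisher.test(tab, simulate.p.value = TRUE, B = mc_draws)$p.value)
    method <- "monte-carlo"
  }
  structure(list(variable = variable, counts = unclass(tab), percent = pct,
                 fisher_p = p, method = method),
            class = "categorical_summary")
}

#' @exportS3Method print categorical_summary
print.categorical_summary <- function(x, ...) {
  cat(x$variable, " (Fisher exact p = ", format.pval(x$fisher_p, digits = 2),
      ", ", x$method, ")\n", sep = "")
  disp <- matrix(sprintf("%d (%s)", x$counts, x$percent),
                 nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(as.data.frame(disp))
  invisible(x)
}

#' Cohort-characteristic summary of one continuous variable
#'
#' Shapiro-Wilk normality per cohort; if either rejects at
#' `normality_alpha` and all values are positive, both are log-transformed
#' before an unpaired equal-variance Student's t test — the same rule as
#' [mean_contrast()].
#'
#' @param x,y Numeric vectors for the two cohorts (length >= 3).
#' @param normality_alpha Shapiro-Wilk trigger level.
#' @return A list: group means, `shapiro_p_x`, `shapiro_p_y`,
#'   `transform_applied`, `t_statistic`, `p_value`.
#' @export
summarize_continuous <- function(x, y, normality_alpha = 0.05) {
  mc <- mean_contrast(x, y, normality_alpha = normality_alpha)
  list(mean_x = mc$mean_mothers, mean_y = mc$mean_fathers,
       shapiro_p_x = mc$shapiro_p_mothers, shapiro_p_y = mc$shapiro_p_fathers,
       transform_applied = mc$transform_applied,
       t_statistic = mc$t_statistic, p_value = mc$p_value)
}

#' Full cohort characteristics table
#'
#' Applies [summarize_categorical()] to every phenotype field of the trio
#' table that has at least one known value, producing a study-style
#' characteristics table with between-cohort Fisher tests.
#'
#' @param trios A `trio_set` with both cohorts present.
#' @param variables Fields to summarize; defaults to all categorical trio
#'   phenotype fields except `cohort`.
#' @param ... Passed to [summarize_categorical()].
#' @return A data.frame of class `cohort_table`: one row per variable level
#'   with per-cohort `n (pct)` strings and the variable-level Fisher p.
#' @export
cohort_table <- function(trios, variables = NULL, ...) {
  if (is.null(variables))
    variables <- setdiff(names(TRIO_FACTOR_LEVELS), "cohort")
  rows <- list()
  for (variable in variables) {
    if (all(trios[[variable]] == "unknown")) next
    s <- summarize_categorical(trios, variable, ...)
    disp <- matrix(sprintf("%d (%s)", s$counts, s$percent),
                   nrow = nrow(s$counts), dimnames = dimnames(s$counts))
    rows[[variable]] <- data.frame(
      variable = variable,
      level = rownames(s$counts),
      disp,
      fisher_p = c(s$fisher_p, rep(NA_real_, nrow(s$counts) - 1L)),
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no variable with known values to summarize")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write a cohort characteristics table to TSV
#'
#' @param tab A `cohort_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
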