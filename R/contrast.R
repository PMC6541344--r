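#' Compare mean GRS of mothers and fathers
#'
#' Shapiro-Wilk normality is checked in each group; if either group rejects
#' at `normality_alpha` and all values are positive, both groups are
#' log-transformed before an unpaired, equal-variance Student's t test.
#'
#' @param mother_scores,father_scores Numeric vectors (length >= 3, finite).
#' @param normality_alpha Significance level for the Shapiro-Wilk trigger.
#' @return A list of class `grs_mean_contrast`: `mean_mothers`,
#'   `mean_fathers` (on the original scale), `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `transform_applied` (`"none"` or
#'   `"log"`).
#' @export
mean_contrast <- function(mother_scores, father_scores,
                          normality_alpha = 0.05) {
  for (v in list(mother_scores, father_scores)) {
    if (length(v) < 3L) stop("each group needs at least 3 observations")
    if (any(!is.finite(v))) stop("scores must be finite")
  }
  sw_m <- shapiro_p(mother_scores)
  sw_f <- shapiro_p(father_scores)
  nonnormal <- (!is.na(sw_m) && sw_m < normality_alpha) ||
    (!is.na(sw_f) && sw_f < normality_alpha)
  transform <- "none"
  m <- mother_scores
  f <- father_scores
  if (nonnormal) {
    if (all(mother_scores > 0) && all(father_scores > 0)) {
      m <- log(mother_scores)
      f <- log(father_scores)
      transform <- "log"
    } else {
      tg_log("non-positive scores: log transform skipped", level = "WARN")
    }
  }
  if (stats::sd(m) == 0 && stats::sd(f) == 0 && mean(m) == mean(f)) {
    tt <- list(statistic = 0, parameter = length(m) + length(f) - 2,
               p.value = 1)
  } else {
    tt <- stats::t.test(m, f, var.equal = TRUE)
  }
  structure(list(mean_mothers = mean(mother_scores),
                 mean_fathers = mean(father_scores),
                 t_statistic = unname(tt$statistic),
                 degrees_of_freedom = unname(tt$parameter),
                 p_value = tt$p.value,
                 transform_applied = transform,
                 shapiro_p_mothers = sw_m,
                 shapiro_p_fathers = sw_f),
            class = "grs_mean_contrast")
}

#' Paternal-percentile cutoff
#'
#' The dichotomization cut-point: the nearest-rank empirical quantile of the
#' fathers' score distribution (the `ceiling(n * q)`-th order statistic), so
#' the cutoff is always an observed paternal score.
#'
#' @param father_scores Numeric vector of fathers' scores.
#' @param quantile_level Quantile level in (0, 1); the analysis uses 0.95,
#'   0.90 and 0.75 (top 5th/10th/25th percentiles).
#' @return The cutoff value.
#' @export
percentile_threshold <- function(father_scores, quantile_level) {
  if (quantile_level >= 0.95 && length(father_scores) < 20L)
    warning("fewer than 20 fathers: the ", quantile_level,
            " quantile is poorly determined")
  quantile_nearest_rank(father_scores, quantile_level)
}

#' Dichotomize at a cutoff and test with Fisher's exact test
#'
#' Scores strictly greater than `cutoff` are "high", scores `<= cutoff` are
#' "low". The 2x2 table takes mothers as cases and fathers as controls:
#' `a` = high mothers, `b` = low mothers, `c` = high fathers, `d` = low
#' fathers. The p-value is the conventional two-sided Fisher exact test
#' (hypergeometric enumeration); the odds ratio is the sample cross-product
#' `(a d)/(b c)`, with the Haldane-Anscombe +0.5 correction on all cells
#' when any cell is zero, and a 95% CI by the Woolf logit method on the
#' (corrected) cells.
#'
#' @param mother_scores,father_scores Numeric score vectors.
#' @param cutoff Finite threshold (typically from [percentile_threshold()]).
#' @return A list of class `grs_threshold_contrast` with `cutoff`, counts
#'   `a`,`b`,`c`,`d`, `odds_ratio`, `ci_low`, `ci_high`, `fisher_p`, and
#'   `haldane_corrected`.
#' @export
dichotomize_and_test <- function(mother_scores, father_scores, cutoff) {
  if (!length(mother_scores) || !length(father_scores))
    stop("both score vectors must be non-empty")
  if (!is.finite(cutoff)) stop("'cutoff' must be finite")
  a <- sum(mother_scores > cutoff)
  b <- sum(mother_scores <= cutoff)
  c_ <- sum(father_scores > cutoff)
  d <- sum(father_scores <= cutoff)
  res <- fisher_2x2(a, b, c_, d)
  res$cutoff <- cutoff
  class(res) <- "grs_threshold_contrast"
  res
}

#' Specify a subgroup re-analysis
#'
#' @param cohort `"all"`, `"CHOP"` or `"PCGC"`.
#' @param exclude_overt_phenotype Drop trios whose mother had preeclampsia,
#'   medicated hypertension or pregestational diabetes.
#' @param ctd_subtype Optional defect subtype restriction (e.g. `"ToF"`).
#' @return A list of class `subgroup_spec`.
#' @export
subgroup_spec <- function(cohort = "all", exclude_overt_phenotype = FALSE,
                          ctd_subtype = NULL) {
  structure(list(cohort = match.arg(cohort, c("all", "CHOP", "PCGC")),
                 exclude_overt_phenotype = isTRUE(exclude_overt_phenotype),
                 ctd_subtype = ctd_subtype),
            class = "subgroup_spec")
}

subgroup_label <- function(sg) {
  parts <- sg$cohort
  if (sg$exclude_overt_phenotype) parts <- c(parts, "no-overt-phenotype")
  if (!is.null(sg$ctd_subtype)) parts <- c(parts, sg$ctd_subtype)
  paste(parts, collapse = "/")
}

#' Mothers-as-cases versus fathers-as-controls GRS contrast
#'
#' The central inference of the design. Under no maternal genetic effect,
#' mothers and fathers of affected children have exchangeable genetic risk
#' scores; a maternal excess signals a maternal genetic effect. For each
#' condition (combined, OBESITY, HTN, T2D) the fit computes (i) the mean
#' contrast (equal-variance Student's t, with Shapiro-Wilk-triggered log
#' transform) and (ii), at each requested quantile level, the paternal
#' nearest-rank percentile cutoff, the high/low 2x2 table, the sample odds
#' ratio with Woolf 95% CI and the two-sided Fisher exact p. Cutoffs are
#' always recomputed from the analyzed subgroup's fathers.
#'
#' @param grs A `grs_table` (from [compute_grs()] or [read_grs()]).
#' @param trios Optional `trio_set`; required when `subgroup` filters
#'   anything, and used to restrict the GRS table to the subgroup's parents.
#' @param subgroup A [subgroup_spec()].
#' @param quantile_levels Numeric vector of dichotomization levels.
#' @param min_trios Minimum surviving trio count; smaller subgroups error
#'   (unstable estimates are refused).
#' @return An object of class `grs_contrast` with elements `means` and
#'   `thresholds` (data.frames), `subgroup`, `n_mothers`, `n_fathers`,
#'   `panel_sizes`.
#' @examples
#' sim <- simulate_trios(sim_config(n_trios = 80, seed = 7))
#' roles <- parent_roles(sim$trios)
#' grs <- compute_grs(subset_samples(sim$dosages, names(roles)),
#'                    sim$weights, roles)
#' fit <- grs_contrast(grs, sim$trios)
#' fit
#' @export
grs_contrast <- function(grs, trios = NULL, subgroup = subgroup_spec(),
                         quantile_levels = c(0.95, 0.90, 0.75),
                         min_trios = 10L) {
  stopifnot(inherits(subgroup, "subgroup_spec"))
  if (!is.null(trios)) {
    sub <- filter_trios(trios, cohort = subgroup$cohort,
                        exclude_overt_phenotype = subgroup$exclude_overt_phenotype,
                        ctd_subtype = subgroup$ctd_subtype)
    if (nrow(sub) < min_trios)
      stop("subgroup '", subgroup_label(subgroup), "' leaves only ",
           nrow(sub), " trios (< ", min_trios, "): refusing unstable estimates")
    wanted <- c(sub$mother_id, sub$father_id)
    missing_par <- setdiff(wanted, grs$sample_id)
    if (length(missing_par))
      stop("GRS table lacks ", length(missing_par),
           " parent(s) of the filtered trios")
    grs <- grs[grs$sample_id %in% wanted, , drop = FALSE]
  } else if (subgroup$cohort != "all" || subgroup$exclude_overt_phenotype ||
             !is.null(subgroup$ctd_subtype)) {
    stop("subgroup filtering requires the trio table")
  }
  conditions <- c(combined = "score_combined", OBESITY = "score_obesity",
                  HTN = "score_htn", T2D = "score_t2d")
  mothers <- grs[grs$role == "mother", , drop = FALSE]
  fathers <- grs[grs$role == "father", , drop = FALSE]

  means <- do.call(rbind, lapply(names(conditions), function(cond) {
    mc <- mean_contrast(mothers[[conditions[[cond]]]],
                        fathers[[conditions[[cond]]]])
    data.frame(condition = cond, mean_mothers = mc$mean_mothers,
               mean_fathers = mc$mean_fathers, t_statistic = mc$t_statistic,
               degrees_of_freedom = mc$degrees_of_freedom,
               p_value = mc$p_value, transform_applied = mc$transform_applied,
               stringsAsFactors = FALSE)
  }))

  thresholds <- do.call(rbind, lapply(names(conditions), function(cond) {
    m <- mothers[[conditions[[cond]]]]
    f <- fathers[[conditions[[cond]]]]
    do.call(rbind, lapply(quantile_levels, function(q) {
      cut <- percentile_threshold(f, q)
      tc <- dichotomize_and_test(m, f, cut)
      data.frame(condition = cond, quantile_level = q, cutoff = cut,
                 a = tc$a, b = tc$b, c = tc$c, d = tc$d,
                 odds_ratio = tc$odds_ratio, ci_low = tc$ci_low,
                 ci_high = tc$ci_high, fisher_p = tc$fisher_p,
                 stringsAsFactors = FALSE)
    }))
  }))

  structure(list(means = means, thresholds = thresholds,
                 subgroup = subgroup, quantile_levels = quantile_levels,
                 n_mothers = nrow(mothers), n_fathers = nrow(fathers),
                 panel_sizes = attr(grs, "panel_sizes")),
            class = "grs_contrast")
}

#' @exportS3Method print grs_contrast
print.grs_contrast <- function(x, digits = 3, ...) {
  cat("Maternal GRS contrast (mothers as cases, fathers as controls)\n")
  cat(sprintf("  subgroup: %s | %d mothers, %d fathers\n",
              subgroup_label(x$subgroup), x$n_mothers, x$n_fathers))
  cat("\nMean contrast (Student's t):\n")
  m <- x$means
  m$mean_mothers <- round(m$mean_mothers, digits)
  m$mean_fathers <- round(m$mean_fathers, digits)
  m$t_statistic <- round(m$t_statistic, digits)
  m$p_value <- signif(m$p_value, digits)
  print(m[, c("condition", "mean_mothers", "mean_fathers", "t_statistic",
              "p_value", "transform_applied")], row.names = FALSE)
  cat("\nPaternal-percentile dichotomization (Fisher's exact):\n")
  t <- x$thresholds
  t$cutoff <- round(t$cutoff, digits)
  t$OR <- sprintf("%.2f (%.2f, %.2f)", t$odds_ratio, t$ci_low, t$ci_high)
  t$fisher_p <- signif(t$fisher_p, digits)
  print(t[, c("condition", "quantile_level", "cutoff", "a", "b", "c", "d",
              "OR", "fisher_p")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.grs_contrast <- function(object, ...) {
  structure(list(fit = object), class = "summary.grs_contrast")
}

#' @exportS3Method print summary.grs_contrast
print.summary.grs_contrast <- function(x, ...) {
  print(x$fit)
  top <- x$fit$thresholds[x$fit$thresholds$quantile_level ==
                            max(x$fit$thresholds$quantile_level), ]
  sig <- top$condition[top$fisher_p <= 0.05]
  cat("\nAt the top percentile level, condition(s) with Fisher p <= 0.05: ",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n", sep = "")
  invisible(x)
}

#' Odds ratios of a fitted contrast
#'
#' @param object A `grs_contrast` fit.
#' @param ... Unused.
#' @return Named vector of odds ratios (`condition@level`).
#' @export
coef.grs_contrast <- function(object, ...) {
  t <- object$thresholds
  stats::setNames(t$odds_ratio,
                  sprintf("%s@%g", t$condition, t$quantile_level))
}

#' Write contrast results as a tidy TSV
#'
#' One row per condition x quantile level, mirroring the layout of the
#' study-style results table (means, mean-test p, cutoff, 2x2 cells, OR, CI,
#' Fisher p).
#'
#' @param fit A `grs_contrast`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contrast <- function(fit, path) {
  tidy <- merge(fit$thresholds, fit$means, by = "condition",
                suffixes = c("", "_mean"))
  tidy <- tidy[order(match(tidy$condition,
                           c("combined", "OBESITY", "HTN", "T2D")),
                     -tidy$quantile_level), ]
  names(tidy)[names(tidy) == "p_value"] <- "mean_p"
  cols <- c("condition", "mean_mothers", "mean_fathers", "mean_p",
            "transform_applied", "quantile_level", "cutoff",
            "a", "b", "c", "d", "odds_ratio", "ci_low", "ci_high", "fisher_p")
  utils::write.table(tidy[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
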