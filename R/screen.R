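#' Per-condition Bonferroni threshold
#'
#' The screen divides the 0.05 significance level by the number of SNPs
#' evaluated for the condition. The exact quotient is used for
#' classification; a companion display value rounds to one significant
#' digit, matching how such thresholds are conventionally printed.
#'
#' @param n_snps Number of SNPs in the condition's panel (>= 1).
#' @return `list(threshold=, display=)`.
#' @examples
#' bonferroni_threshold(46)  # threshold 0.001086..., display 0.001
#' @export
bonferroni_threshold <- function(n_snps) {
  if (length(n_snps) != 1L || is.na(n_snps) || n_snps < 1 ||
      n_snps != round(n_snps))
    stop("'n_snps' must be a positive integer")
  thr <- 0.05 / n_snps
  list(threshold = thr, display = signif(thr, 1))
}

#' Classify SNP association p-values against Bonferroni thresholds
#'
#' Each association is classified as `"significant"` (p <= the exact
#' per-condition Bonferroni threshold), `"suggestive"` (threshold < p <
#' 0.05) or `"null"` (p >= 0.05). The p-values are consumed from upstream
#' maternal-effect association results; this screen does not compute them.
#'
#' @param associations A data.frame with columns `snp_id`, `condition` and
#'   `p_value` (optional `nearest_gene`, `location` carried through).
#' @param sizes Named per-condition panel sizes, e.g.
#'   `c(HTN = 31, OBESITY = 30, T2D = 46)` (see [panel_sizes()]).
#' @return The input rows (sorted by condition then p) with `threshold`,
#'   `threshold_display` and `classification` columns added.
#' @export
classify_associations <- function(associations, sizes) {
  need <- c("snp_id", "condition", "p_value")
  missing_cols <- setdiff(need, names(associations))
  if (length(missing_cols))
    stop("association table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  assoc <- associations
  assoc$condition <- normalize_condition(assoc$condition)
  names(sizes) <- normalize_condition(names(sizes))
  no_size <- setdiff(unique(assoc$condition), names(sizes))
  if (length(no_size))
    stop("no panel size for condition(s): ", paste(no_size, collapse = ", "))
  p <- assoc$p_value
  if (anyNA(p) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  thr <- vapply(assoc$condition,
                function(cond) bonferroni_threshold(sizes[[cond]])$threshold,
                numeric(1))
  assoc$threshold <- unname(thr)
  assoc$threshold_display <- signif(assoc$threshold, 1)
  assoc$classification <- ifelse(p <= thr, "significant",
                                 ifelse(p < 0.05, "suggestive", "null"))
  assoc <- assoc[order(match(assoc$condition, CONDITIONS), assoc$p_value), ,
                 drop = FALSE]
  rownames(assoc) <- NULL
  assoc
}

#' Read a SNP association table
#'
#' Delimited text with header columns `snp_id`, `condition`, `p_value`
#' (optional `nearest_gene`, `location`).
#'
#' @param path Path to the file.
#' @return A data.frame.
#' @export
read_associations <- function(path) {
  df <- read_delim_auto(path)
  need <- c("snp_id", "condition", "p_value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("association table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  df$p_value <- as.numeric(df$p_value)
  df
}
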