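#' Construct a GRS weight table
#'
#' A weight table lists the SNPs scored for each condition together with the
#' risk (effect) allele and the per-allele weight, in the schema of published
#' genetic-risk-score definitions: one row per SNP with `snp_id`,
#' `effect_allele`, `other_allele`, `weight` and `condition`
#' (one of `"HTN"`, `"OBESITY"`, `"T2D"`).
#'
#' @param snp_id Character vector of variant identifiers (rsIDs).
#' @param effect_allele,other_allele Single-base allele strings; the effect
#'   allele is the one whose dosage increases the score.
#' @param weight Positive per-allele weights, oriented to the effect allele.
#' @param condition Condition label per SNP: `"HTN"`, `"OBESITY"` or `"T2D"`
#'   (a few common synonyms are normalized).
#' @param chrom,pos Optional chromosome label and 1-based position.
#' @return A `data.frame` of class `grs_weights`.
#' @seealso [read_weight_table()]
#' @export
weight_table <- function(snp_id, effect_allele, other_allele, weight,
                         condition, chrom = NA_character_, pos = NA_integer_) {
  if (length(snp_id) == 0L) {
    wt <- data.frame(snp_id = character(0), chrom = character(0),
                     pos = integer(0), effect_allele = character(0),
                     other_allele = character(0), weight = numeric(0),
                     condition = character(0), stringsAsFactors = FALSE)
    class(wt) <- c("grs_weights", "data.frame")
    return(wt)
  }
  wt <- data.frame(
    snp_id = as.character(snp_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    weight = as.numeric(weight),
    condition = if (length(snp_id)) normalize_condition(condition) else character(0),
    stringsAsFactors = FALSE
  )
  validate_weight_table(wt)
  class(wt) <- c("grs_weights", "data.frame")
  wt
}

validate_weight_table <- function(wt) {
  if (nrow(wt) == 0L) return(invisible(wt))
  if (anyNA(wt$weight) || any(!is.finite(wt$weight)))
    stop("weight table contains missing or non-finite weights")
  if (any(wt$weight <= 0))
    stop("weights must be positive (oriented to the risk allele); offending SNP(s): ",
         paste(wt$snp_id[wt$weight <= 0], collapse = ", "))
  same <- wt$effect_allele == wt$other_allele
  if (any(same))
    stop("effect and other allele identical for SNP(s): ",
         paste(wt$snp_id[same], collapse = ", "))
  dup_within <- duplicated(wt[, c("snp_id", "condition")])
  if (any(dup_within))
    stop("duplicate snp_id within a condition: ",
         paste(unique(wt$snp_id[dup_within]), collapse = ", "))
  dup_across <- unique(wt$snp_id[duplicated(wt$snp_id)])
  if (length(dup_across))
    stop("snp_id appears in more than one condition: ",
         paste(dup_across, collapse = ", "))
  invisible(wt)
}

#' Read a GRS weight table from delimited text
#'
#' Expects a TSV/CSV file with a header naming at least `snp_id`,
#' `effect_allele`, `other_allele`, `weight` and `condition`; optional
#' `chrom`/`pos` columns are carried through. Duplicate SNPs within a
#' condition, SNPs shared between conditions, and non-positive weights are
#' rejected.
#'
#' @param path Path to the file.
#' @param condition_filter Optional character vector restricting to a subset
#'   of conditions.
#' @return A `grs_weights` table; per-condition SNP counts are logged.
#' @export
read_weight_table <- function(path, condition_filter = NULL) {
  df <- read_delim_auto(path)
  need <- c("snp_id", "effect_allele", "other_allele", "weight", "condition")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("weight table ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("weight table ", path, " has a header but no rows")
    return(weight_table(character(0), character(0), character(0),
                        numeric(0), character(0)))
  }
  bad_weight <- suppressWarnings(as.numeric(df$weight))
  if (anyNA(bad_weight)) {
    line <- which(is.na(bad_weight))[1L] + 1L   # +1 for header
    stop("malformed weight on line ", line, " of ", path)
  }
  wt <- weight_table(df$snp_id, df$effect_allele, df$other_allele,
                     bad_weight, df$condition,
                     chrom = if ("chrom" %in% names(df)) df$chrom else NA,
                     pos = if ("pos" %in% names(df)) df$pos else NA)
  if (!is.null(condition_filter)) {
    keep <- normalize_condition(condition_filter)
    wt <- wt[wt$condition %in% keep, , drop = FALSE]
    class(wt) <- c("grs_weights", "data.frame")
  }
  counts <- table(factor(wt$condition, levels = CONDITIONS))
  tg_log("weight table: ", paste(sprintf("%s=%d", names(counts), counts),
                                 collapse = ", "),
         " (total ", nrow(wt), " SNPs)")
  wt
}

#' Write a weight table to TSV
#'
#' @param wt A `grs_weights` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(wt, path) {
  utils::write.table(wt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-condition SNP counts of a weight table
#'
#' @param wt A `grs_weights` table.
#' @return Named integer vector over HTN, OBESITY, T2D.
#' @export
panel_sizes <- function(wt) {
  tab <- table(factor(wt$condition, levels = CONDITIONS))
  stats::setNames(as.integer(tab), names(tab))
}
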