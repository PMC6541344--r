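#' Orient one dosage record to the effect allele
#'
#' If the counted allele already equals the weight entry's effect allele the
#' dosage is unchanged; if it equals the other allele the dosage is flipped
#' to `2 - dosage`. Any other allele pair — including a strand-ambiguous
#' (A/T or C/G) SNP whose labels do not match — is a hard alignment error:
#' no strand complementing is attempted.
#'
#' @param dosage Dosage value(s) in `[0, 2]` (NA allowed).
#' @param counted_allele,other_allele Alleles of the genotype record; the
#'   dosage counts copies of `counted_allele`.
#' @param effect_allele,weight_other_allele Alleles of the weight entry.
#' @param snp_id Identifier used in error messages.
#' @return `list(dosage=, flipped=)`.
#' @export
align_allele_record <- function(dosage, counted_allele, other_allele,
                                effect_allele, weight_other_allele,
                                snp_id = "?") {
  counted_allele <- unname(toupper(counted_allele))
  other_allele <- unname(toupper(other_allele))
  effect_allele <- unname(toupper(effect_allele))
  weight_other_allele <- unname(toupper(weight_other_allele))
  if (identical(counted_allele, effect_allele) &&
      identical(other_allele, weight_other_allele)) {
    list(dosage = dosage, flipped = FALSE)
  } else if (identical(counted_allele, weight_other_allele) &&
             identical(other_allele, effect_allele)) {
    list(dosage = 2 - dosage, flipped = TRUE)
  } else {
    stop("allele alignment failure at ", snp_id, ": genotype alleles ",
         counted_allele, "/", other_allele, " do not match weight alleles ",
         effect_allele, "/", weight_other_allele,
         " in either order (no strand complementing is attempted)")
  }
}

#' Orient every SNP of a dosage matrix to its effect allele
#'
#' SNPs already flagged as oriented pass through unchanged; for the rest the
#' counted allele is compared with the matching weight entry and the dosage
#' column flipped to `2 - dosage` where the counted allele is the non-effect
#' allele. SNPs in the matrix without a weight entry are an error.
#'
#' @param dm A [dosage_matrix()].
#' @param weights A `grs_weights` table.
#' @return A `dosage_matrix` with all SNPs oriented.
#' @export
align_alleles <- function(dm, weights) {
  idx <- match(snp_ids(dm), weights$snp_id)
  if (anyNA(idx))
    stop("SNP(s) absent from the weight table: ",
         paste(snp_ids(dm)[is.na(idx)], collapse = ", "))
  out <- dm
  for (j in which(!dm$oriented)) {
    rec <- align_allele_record(dm$dosage[, j],
                               dm$counted_allele[j], dm$other_allele[j],
                               weights$effect_allele[idx[j]],
                               weights$other_allele[idx[j]],
                               snp_id = snp_ids(dm)[j])
    out$dosage[, j] <- rec$dosage
    if (rec$flipped) {
      out$counted_allele[j] <- dm$other_allele[j]
      out$other_allele[j] <- dm$counted_allele[j]
    }
    out$oriented[j] <- TRUE
  }
  out
}

#' Compute per-condition and combined genetic risk scores
#'
#' For each parent and each condition the score is the weighted sum
#' `S = sum_i w_i g_i` of effect-allele dosages `g_i` in `[0, 2]` over that
#' condition's SNPs, with weights from the weight table; the combined score
#' is the exact sum of the three condition scores. Dosages must already be
#' oriented (see [align_alleles()]).
#'
#' Missing genotypes are handled by `missing_policy`:
#' \describe{
#'   \item{`impute_role_mean`}{(default) replace a missing dosage by the mean
#'     oriented dosage of that SNP among samples of the same parental role —
#'     preserves sample size without biasing the mother-father contrast,
#'     since imputation is within role.}
#'   \item{`drop_sample`}{remove samples with any missing scored genotype.}
#'   \item{`score_available`}{sum over the non-missing SNPs only (no
#'     rescaling).}
#' }
#'
#' @param dm An oriented [dosage_matrix()] of parental dosages.
#' @param weights A `grs_weights` table; every condition must contribute at
#'   least one SNP present in `dm`.
#' @param roles Named character vector mapping sample ids to `"mother"` /
#'   `"father"` (see [parent_roles()]).
#' @param cohorts Optional named character vector mapping sample ids to
#'   cohort labels.
#' @param missing_policy One of `"impute_role_mean"`, `"drop_sample"`,
#'   `"score_available"`.
#' @return A `data.frame` of class `grs_table` with columns `sample_id`,
#'   `role`, `cohort`, `score_htn`, `score_obesity`, `score_t2d`,
#'   `score_combined` and `n_missing_htn` / `n_missing_obesity` /
#'   `n_missing_t2d` (missing scored genotypes per condition, before any
#'   imputation).
#' @export
compute_grs <- function(dm, weights, roles, cohorts = NULL,
                        missing_policy = c("impute_role_mean", "drop_sample",
                                           "score_available")) {
  missing_policy <- match.arg(missing_policy)
  if (!all(dm$oriented))
    stop("dosages must be oriented before scoring; run align_alleles()")
  samples <- sample_ids(dm)
  if (!all(samples %in% names(roles)))
    stop("role unknown for sample(s): ",
         paste(setdiff(samples, names(roles)), collapse = ", "))
  role <- unname(roles[samples])
  if (!all(role %in% c("mother", "father")))
    stop("roles must be 'mother' or 'father'")

  snp_in <- intersect(weights$snp_id, snp_ids(dm))
  wt <- weights[weights$snp_id %in% snp_in, , drop = FALSE]
  sizes <- table(factor(wt$condition, levels = CONDITIONS))
  if (any(sizes == 0))
    stop("condition(s) with zero scored SNPs: ",
         paste(names(sizes)[sizes == 0], collapse = ", "))

  G <- dm$dosage[, wt$snp_id, drop = FALSE]

  n_missing <- vapply(CONDITIONS, function(cond) {
    cols <- wt$snp_id[wt$condition == cond]
    rowSums(is.na(G[, cols, drop = FALSE]))
  }, numeric(nrow(G)))
  if (!is.matrix(n_missing))
    n_missing <- matrix(n_missing, nrow = 1,
                        dimnames = list(NULL, CONDITIONS))

  if (missing_policy == "drop_sample") {
    keep <- rowSums(is.na(G)) == 0L
    if (!any(keep)) stop("drop_sample policy removed every sample")
    if (any(!keep))
      tg_log("drop_sample: removing ", sum(!keep),
             " sample(s) with missing genotypes")
    G <- G[keep, , drop = FALSE]
    samples <- samples[keep]
    role <- role[keep]
    n_missing <- n_missing[keep, , drop = FALSE]
  } else if (missing_policy == "impute_role_mean") {
    all_missing <- rowSums(!is.na(G)) == 0L
    if (any(all_missing))
      stop("sample(s) with every scored genotype missing: ",
           paste(samples[all_missing], collapse = ", "))
    for (r in c("mother", "father")) {
      rows <- which(role == r)
      if (!length(rows)) next
      sub <- G[rows, , drop = FALSE]
      if (anyNA(sub)) {
        means <- colMeans(sub, na.rm = TRUE)
        bad <- is.nan(means) & colSums(is.na(sub)) > 0
        if (any(bad))
          stop("SNP(s) missing for every ", r, ": ",
               paste(colnames(G)[bad], collapse = ", "))
        na_idx <- which(is.na(sub), arr.ind = TRUE)
        sub[na_idx] <- means[na_idx[, 2]]
        G[rows, ] <- sub
      }
    }
  }

  score_one <- function(cond) {
    cols <- wt$condition == cond
    g <- G[, wt$snp_id[cols], drop = FALSE]
    w <- wt$weight[cols]
    if (missing_policy == "score_available" && anyNA(g)) {
      gw <- sweep(g, 2, w, `*`)
      rowSums(gw, na.rm = TRUE)
    } else {
      as.vector(g %*% w)
    }
  }
  s_htn <- score_one("HTN")
  s_ob <- score_one("OBESITY")
  s_t2d <- score_one("T2D")

  out <- data.frame(
    sample_id = samples,
    role = role,
    cohort = if (is.null(cohorts)) NA_character_ else unname(cohorts[samples]),
    score_htn = s_htn,
    score_obesity = s_ob,
    score_t2d = s_t2d,
    score_combined = NA_real_,
    n_missing_htn = as.integer(n_missing[, "HTN"]),
    n_missing_obesity = as.integer(n_missing[, "OBESITY"]),
    n_missing_t2d = as.integer(n_missing[, "T2D"]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("grs_table", "data.frame")
  attr(out, "panel_sizes") <- stats::setNames(as.integer(sizes), names(sizes))
  combine_scores(out)
}

#' Combined score as the exact sum of the three condition scores
#'
#' @param grs A `grs_table` with the three per-condition score columns.
#' @return The table with `score_combined = score_htn + score_obesity +
#'   score_t2d`, exactly.
#' @export
combine_scores <- function(grs) {
  need <- c("score_htn", "score_obesity", "score_t2d")
  missing_cols <- setdiff(need, names(grs))
  if (length(missing_cols))
    stop("component score column(s) absent: ",
         paste(missing_cols, collapse = ", "))
  if (anyNA(grs[need]))
    stop("component scores contain missing values")
  grs$score_combined <- grs$score_htn + grs$score_obesity + grs$score_t2d
  if (!inherits(grs, "grs_table")) class(grs) <- c("grs_table", "data.frame")
  grs
}

#' @exportS3Method print grs_table
print.grs_table <- function(x, ...) {
  cat(sprintf("grs_table: %d parents (%d mothers, %d fathers)\n",
              nrow(x), sum(x$role == "mother"), sum(x$role == "father")))
  ps <- attr(x, "panel_sizes")
  if (!is.null(ps))
    cat("  panel: ", paste(sprintf("%s=%d", names(ps), ps), collapse = ", "),
        "\n", sep = "")
  for (cond in c("combined", "htn", "obesity", "t2d")) {
    col <- paste0("score_", cond)
    cat(sprintf("  %-9s mean mothers %6.2f | mean fathers %6.2f\n", cond,
                mean(x[[col]][x$role == "mother"]),
                mean(x[[col]][x$role == "father"])))
  }
  invisible(x)
}

#' Write a GRS table to TSV
#'
#' @param grs A `grs_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grs <- function(grs, path) {
  utils::write.table(grs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GRS table written by [write_grs()]
#'
#' @param path Path to the TSV.
#' @return A `grs_table`.
#' @export
read_grs <- function(path) {
  df <- read_delim_auto(path)
  need <- c("sample_id", "role", "score_htn", "score_obesity", "score_t2d")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("GRS table lacks column(s): ", paste(missing_cols, collapse = ", "))
  combine_scores(df)
}
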