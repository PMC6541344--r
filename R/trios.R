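TRIO_ID_COLS <- c("family_id", "mother_id", "father_id", "child_id")

TRIO_FACTOR_LEVELS <- list(
  cohort = c("CHOP", "PCGC"),
  ctd_subtype = c("ToF", "D-TGA", "DORV", "VSD", "IAA", "truncus",
                  "aortic arch anomaly", "L-TGA", "complex", "other"),
  child_sex = c("male", "female"),
  extracardiac = c("yes", "no"),
  maternal_preeclampsia = c("yes", "no"),
  maternal_htn_medication = c("yes", "no"),
  maternal_pregestational_diabetes = c("yes", "no"),
  maternal_gestational_diabetes = c("yes", "no"),
  maternal_age_band = c("<20", "20-<25", "25-<30", "30-<35", "35-<40", ">40"),
  paternal_age_band = c("<20", "20-<25", "25-<30", "30-<35", "35-<40", ">40"),
  maternal_bmi_band = c("<18.5", "18.5-<25", "25-<30", ">30")
)

#' Construct a set of case-parent trios
#'
#' One row per trio: the family id, the mother/father/child sample ids, the
#' recruiting cohort, the child's conotruncal defect subtype and the maternal
#' pregnancy phenotype fields used by subgroup and sensitivity analyses.
#' Values outside a field's enumerated levels (and `NA`) are mapped to
#' `"unknown"`.
#'
#' @param df A data.frame with at least `family_id`, `mother_id`, `father_id`
#'   and `child_id`; recognised phenotype columns are validated, others are
#'   dropped with a message.
#' @return A `data.frame` of class `trio_set`.
#' @export
trio_set <- function(df) {
  missing_cols <- setdiff(TRIO_ID_COLS, names(df))
  if (length(missing_cols))
    stop("trio table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(lapply(df[TRIO_ID_COLS], as.character),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$family_id))
    stop("duplicate family_id: ",
         paste(unique(out$family_id[duplicated(out$family_id)]), collapse = ", "))
  ids <- out[, c("mother_id", "father_id", "child_id")]
  clash <- apply(ids, 1L, function(r) anyDuplicated(r) > 0L)
  if (any(clash))
    stop("mother/father/child sample ids not distinct in family: ",
         paste(out$family_id[clash], collapse = ", "))
  for (field in names(TRIO_FACTOR_LEVELS)) {
    levels <- TRIO_FACTOR_LEVELS[[field]]
    if (field %in% names(df)) {
      v <- as.character(df[[field]])
      if (field == "cohort") {
        v <- toupper(trimws(v))
        bad <- !is.na(v) & !(v %in% levels)
        if (any(bad)) stop("cohort must be CHOP or PCGC; saw: ",
                           paste(unique(v[bad]), collapse = ", "))
      }
      v[is.na(v) | !(v %in% levels)] <- "unknown"
    } else {
      v <- rep("unknown", nrow(out))
    }
    out[[field]] <- v
  }
  extra <- setdiff(names(df), c(TRIO_ID_COLS, names(TRIO_FACTOR_LEVELS)))
  if (length(extra))
    tg_log("ignoring unrecognised trio column(s): ",
           paste(extra, collapse = ", "))
  class(out) <- c("trio_set", "data.frame")
  out
}

#' Read a trio pedigree table
#'
#' Tab- or comma-separated with a header, one row per trio. See [trio_set()]
#' for the recognised columns and the handling of unknown phenotype values.
#'
#' @param path Path to the file.
#' @return A `trio_set`.
#' @export
read_trios <- function(path) {
  df <- read_delim_auto(path)
  ts <- trio_set(df)
  counts <- table(ts$cohort)
  tg_log("read ", nrow(ts), " trios (",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), ")")
  ts
}

#' Write a trio set to TSV
#'
#' @param trios A `trio_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trios <- function(trios, path) {
  utils::write.table(trios, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map parental sample ids to roles
#'
#' @param trios A `trio_set`.
#' @return Named character vector: for each parental sample id, `"mother"` or
#'   `"father"`.
#' @export
parent_roles <- function(trios) {
  c(stats::setNames(rep("mother", nrow(trios)), trios$mother_id),
    stats::setNames(rep("father", nrow(trios)), trios$father_id))
}

#' Select a subgroup of trios for re-analysis
#'
#' Filters compose conjunctively: an optional cohort restriction, optional
#' exclusion of trios whose mother had an overt phenotype (preeclampsia,
#' medicated hypertension, or pregestational diabetes), and an optional
#' conotruncal-defect subtype restriction.
#'
#' @param trios A `trio_set`.
#' @param cohort One of `"all"`, `"CHOP"`, `"PCGC"`.
#' @param exclude_overt_phenotype If `TRUE`, drop trios with maternal
#'   preeclampsia == "yes", HTN medication == "yes" or pregestational
#'   diabetes == "yes".
#' @param ctd_subtype Optional subtype label (e.g. `"ToF"`).
#' @return The filtered `trio_set`; errors if no trio survives.
#' @export
filter_trios <- function(trios, cohort = "all",
                         exclude_overt_phenotype = FALSE,
                         ctd_subtype = NULL) {
  cohort <- match.arg(cohort, c("all", "CHOP", "PCGC"))
  keep <- rep(TRUE, nrow(trios))
  if (cohort != "all") keep <- keep & trios$cohort == cohort
  if (exclude_overt_phenotype)
    keep <- keep & trios$maternal_preeclampsia != "yes" &
      trios$maternal_htn_medication != "yes" &
      trios$maternal_pregestational_diabetes != "yes"
  if (!is.null(ctd_subtype)) keep <- keep & trios$ctd_subtype == ctd_subtype
  out <- trios[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("subgroup filter removed every trio")
  class(out) <- c("trio_set", "data.frame")
  out
}
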