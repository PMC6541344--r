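#' Construct a dosage matrix
#'
#' Samples x SNPs matrix of effect-allele dosages in `[0, 2]` (fractional
#' values arise from genotype imputation), with `NA` marking missing
#' genotypes. Each SNP carries the allele its dosages count, the opposite
#' allele, and a per-SNP flag stating whether the counted allele is already
#' the weight table's effect allele (see [align_alleles()]).
#'
#' @param dosage Numeric matrix with sample ids as rownames and snp ids as
#'   colnames.
#' @param counted_allele,other_allele Character vectors (one per SNP): the
#'   allele whose copies the dosages count, and the other allele. May be `NA`
#'   when `oriented` is `TRUE`.
#' @param oriented Logical per SNP: `TRUE` if dosages already count the
#'   effect allele of the matching weight entry.
#' @return An object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosage, counted_allele = NA, other_allele = NA,
                          oriented = FALSE) {
  if (!is.matrix(dosage)) stop("'dosage' must be a matrix")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("'dosage' needs sample ids as rownames and snp ids as colnames")
  if (anyDuplicated(rownames(dosage)))
    stop("sample listed twice: ",
         paste(unique(rownames(dosage)[duplicated(rownames(dosage))]),
               collapse = ", "))
  if (anyDuplicated(colnames(dosage)))
    stop("snp listed twice: ",
         paste(unique(colnames(dosage)[duplicated(colnames(dosage))]),
               collapse = ", "))
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && (any(vals < 0) || any(vals > 2)))
    stop("dosages must lie in [0, 2]")
  p <- ncol(dosage)
  expand <- function(x, what) {
    x <- rep_len(as.vector(x), p)
    stats::setNames(x, colnames(dosage))
  }
  obj <- list(dosage = dosage,
              counted_allele = expand(toupper(as.character(counted_allele))),
              other_allele = expand(toupper(as.character(other_allele))),
              oriented = expand(as.logical(oriented)))
  class(obj) <- "dosage_matrix"
  obj
}

#' @exportS3Method print dosage_matrix
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d samples x %d SNPs (%d missing entries, %s)\n",
              nrow(x$dosage), ncol(x$dosage), sum(is.na(x$dosage)),
              if (all(x$oriented)) "all oriented to effect allele"
              else paste0(sum(!x$oriented), " SNPs not yet oriented")))
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosage)

sample_ids <- function(dm) rownames(dm$dosage)
snp_ids <- function(dm) colnames(dm$dosage)

#' Read parental genotype dosages
#'
#' Two carriers are supported. **VCF** (4.x, via the vcfR parser): dosages
#' are taken from the per-genotype `DS` field when present, otherwise from
#' `GT` hard calls as the ALT-allele count; `./.` becomes `NA`; the counted
#' allele is ALT and allele alignment to the weight table's effect allele is
#' deferred to [align_alleles()]. Multi-allelic records are rejected.
#' **Tabular**: a delimited samples x SNPs grid (first column `sample_id`,
#' one column per SNP, literal `NA` for missing); dosages in this dialect are
#' taken to be already counted on the effect allele.
#'
#' Only SNPs present in the weight table are kept; others are skipped with a
#' log entry.
#'
#' @param path Path to the file.
#' @param weights A `grs_weights` table defining the scored panel.
#' @param format `"auto"` (by file extension), `"vcf"` or `"tabular"`.
#' @return A [dosage_matrix()].
#' @export
read_dosages <- function(path, weights, format = c("auto", "vcf", "tabular")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tabular"
  if (format == "vcf") read_dosages_vcf(path, weights)
  else read_dosages_tabular(path, weights)
}

read_dosages_vcf <- function(path, weights) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  alt <- fix[, "ALT"]
  multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  if (any(multi))
    stop("multi-allelic VCF record(s) not supported: ",
         paste(ids[multi], collapse = ", "))
  keep <- ids %in% weights$snp_id
  if (any(!keep))
    tg_log("skipping ", sum(!keep), " VCF site(s) absent from the weight table")
  if (!any(keep)) stop("no VCF site matches the weight table")

  has_ds <- any(grepl("(^|:)DS(:|$)", vcf@gt[, "FORMAT"]))
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    mat <- ds
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    count_alt <- function(g) {
      if (is.na(g)) return(NA_real_)
      alleles <- strsplit(g, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_real_)
      sum(alleles == "1")
    }
    mat <- apply(gt, c(1, 2), count_alt)
  }
  rownames(mat) <- ids
  mat <- mat[keep, , drop = FALSE]
  if (anyDuplicated(colnames(mat)))
    stop("sample listed twice in VCF: ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  dosage_matrix(t(mat),
                counted_allele = alt[keep],
                other_allele = fix[keep, "REF"],
                oriented = FALSE)
}

read_dosages_tabular <- function(path, weights) {
  df <- read_delim_auto(path)
  if (names(df)[1] != "sample_id")
    stop("tabular dosage file must have 'sample_id' as its first column")
  samples <- as.character(df$sample_id)
  if (anyDuplicated(samples))
    stop("sample listed twice: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  snps <- setdiff(names(df), "sample_id")
  keep <- snps %in% weights$snp_id
  if (any(!keep))
    tg_log("skipping ", sum(!keep), " column(s) absent from the weight table")
  snps <- snps[keep]
  if (!length(snps)) stop("no dosage column matches the weight table")
  mat <- as.matrix(df[, snps, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- samples
  idx <- match(snps, weights$snp_id)
  dosage_matrix(mat,
                counted_allele = weights$effect_allele[idx],
                other_allele = weights$other_allele[idx],
                oriented = TRUE)
}

#' Write a dosage matrix in the tabular dialect
#'
#' Writes the samples x SNPs grid with a `sample_id` first column and `NA`
#' for missing genotypes. Only oriented matrices can be written, since the
#' tabular dialect carries no allele labels.
#'
#' @param dm A `dosage_matrix` with all SNPs oriented.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosages <- function(dm, path) {
  if (!all(dm$oriented))
    stop("tabular dialect requires effect-allele-oriented dosages; ",
         "run align_alleles() first")
  df <- data.frame(sample_id = sample_ids(dm), dm$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
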