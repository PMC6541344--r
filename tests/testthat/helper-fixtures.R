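# Fixture builders shared across the suite. Everything is generated in code;
# no binary data is stored.

toy_weights <- function() {
  weight_table(
    snp_id = c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6"),
    effect_allele = c("A", "C", "G", "T", "A", "C"),
    other_allele = c("G", "T", "A", "C", "T", "G"),
    weight = c(0.5, 1.0, 0.25, 0.8, 0.3, 0.6),
    condition = c("HTN", "HTN", "OBESITY", "OBESITY", "T2D", "T2D")
  )
}

toy_trios_df <- function(n = 4L) {
  data.frame(
    family_id = sprintf("fam%d", seq_len(n)),
    mother_id = sprintf("m%d", seq_len(n)),
    father_id = sprintf("f%d", seq_len(n)),
    child_id = sprintf("c%d", seq_len(n)),
    cohort = rep(c("CHOP", "PCGC"), length.out = n),
    ctd_subtype = rep(c("ToF", "D-TGA"), length.out = n),
    maternal_preeclampsia = rep(c("no", "yes"), length.out = n),
    stringsAsFactors = FALSE
  )
}

toy_dosage_matrix <- function(weights = toy_weights(), n = 4L,
                              seed = 1L, missing = 0) {
  set.seed(seed)
  ids <- c(sprintf("m%d", seq_len(n / 2)), sprintf("f%d", seq_len(n / 2)))
  mat <- matrix(sample(0:2, n * nrow(weights), replace = TRUE),
                nrow = n, dimnames = list(ids, weights$snp_id))
  storage.mode(mat) <- "double"
  if (missing > 0) mat[sample(length(mat), missing)] <- NA_real_
  dosage_matrix(mat, counted_allele = weights$effect_allele,
                other_allele = weights$other_allele, oriented = TRUE)
}

toy_roles <- function(n = 4L) {
  ids <- c(sprintf("m%d", seq_len(n / 2)), sprintf("f%d", seq_len(n / 2)))
  setNames(rep(c("mother", "father"), each = n / 2), ids)
}

# Minimal VCF 4.2 text fixture. `gt` is a samples x sites character matrix
# of GT strings (or numeric DS values when ds = TRUE).
write_toy_vcf <- function(path, ids, ref, alt, gt, ds = FALSE) {
  samples <- rownames(gt)
  fmt <- if (ds) "DS" else "GT"
  header <- c(
    "##fileformat=VCFv4.2",
    if (ds) "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">"
    else "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_along(ids), function(j) {
    paste(c("1", as.character(100 * j), ids[j], ref[j], alt[j], ".", "PASS",
            ".", fmt, as.character(gt[, j])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}

# Independent two-sided Fisher exact p: explicit hypergeometric enumeration
# over the table's support via log-binomial coefficients (the conventional
# "sum of probabilities <= observed" definition, with the same 1e-7 relative
# slack for ties that the classical implementations use).
fisher_p_enum <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; s <- a + c
  k <- max(0, s - n2):min(n1, s)
  logp <- lchoose(n1, k) + lchoose(n2, s - k) - lchoose(n1 + n2, s)
  p <- exp(logp)
  obs <- p[k == a]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# Naive per-sample, per-SNP GRS loop used as the scoring oracle.
grs_brute_force <- function(dosage, weights) {
  scores <- matrix(0, nrow = nrow(dosage), ncol = 3,
                   dimnames = list(rownames(dosage),
                                   c("HTN", "OBESITY", "T2D")))
  for (i in seq_len(nrow(dosage))) {
    for (j in seq_len(nrow(weights))) {
      g <- dosage[i, weights$snp_id[j]]
      scores[i, weights$condition[j]] <-
        scores[i, weights$condition[j]] + weights$weight[j] * g
    }
  }
  scores
}
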