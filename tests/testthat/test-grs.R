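test_that("allele orientation flips dosages and is an involution", {
  # identity orientation
  r <- align_allele_record(2, "A", "G", "A", "G", "rs1")
  expect_equal(r$dosage, 2)
  expect_false(r$flipped)
  # counted allele is the non-effect allele: dosage 2 -> 0
  r <- align_allele_record(2, "G", "A", "A", "G", "rs1")
  expect_equal(r$dosage, 0)
  expect_true(r$flipped)
  # flip twice returns the original dosage for every value incl. fractional
  for (d in c(0, 0.37, 1, 1.61, 2)) {
    once <- align_allele_record(d, "G", "A", "A", "G")$dosage
    twice <- align_allele_record(once, "A", "G", "G", "A")$dosage
    expect_equal(twice, d)
  }
  # allele pair mismatch is a hard error naming the SNP
  expect_error(align_allele_record(1, "A", "G", "C", "T", "rs9"), "rs9")
  # strand-ambiguous labels that do not match are errors, not complements
  expect_error(align_allele_record(1, "A", "T", "C", "G", "rsAT"), "rsAT")
})

test_that("align_alleles orients a whole matrix against the weight table", {
  wt <- toy_weights()
  set.seed(2)
  mat <- matrix(sample(0:2, 4 * 6, replace = TRUE), nrow = 4,
                dimnames = list(c("m1", "m2", "f1", "f2"), wt$snp_id))
  storage.mode(mat) <- "double"
  # store SNPs 1 and 3 counted on the *other* allele
  counted <- wt$effect_allele
  other <- wt$other_allele
  counted[c(1, 3)] <- wt$other_allele[c(1, 3)]
  other[c(1, 3)] <- wt$effect_allele[c(1, 3)]
  dm <- dosage_matrix(mat, counted, other, oriented = FALSE)
  out <- align_alleles(dm, wt)
  expect_true(all(out$oriented))
  expect_equal(out$dosage[, 1], 2 - mat[, 1])
  expect_equal(out$dosage[, 2], mat[, 2])
  expect_equal(out$dosage[, 3], 2 - mat[, 3])
})

test_that("compute_grs equals the naive per-sample weighted sum", {
  wt <- toy_weights()
  for (seed in 1:10) {
    dm <- toy_dosage_matrix(wt, n = 10, seed = seed)
    grs <- compute_grs(dm, wt, toy_roles(10))
    brute <- grs_brute_force(dm$dosage, wt)
    expect_equal(grs$score_htn, unname(brute[grs$sample_id, "HTN"]),
                 tolerance = 1e-9)
    expect_equal(grs$score_obesity, unname(brute[grs$sample_id, "OBESITY"]),
                 tolerance = 1e-9)
    expect_equal(grs$score_t2d, unname(brute[grs$sample_id, "T2D"]),
                 tolerance = 1e-9)
  }
})

test_that("hand-computed scores and edge cases are exact", {
  wt <- weight_table(c("rs1", "rs2", "rs3"), c("A", "C", "G"),
                     c("G", "T", "A"), c(0.5, 1.0, 0.25),
                     c("HTN", "HTN", "HTN"))
  # HTN needs company: give the other conditions a token SNP each
  wt2 <- rbind(wt, weight_table(c("rs4", "rs5"), c("A", "C"), c("G", "T"),
                                c(1, 1), c("OBESITY", "T2D")))
  class(wt2) <- c("grs_weights", "data.frame")
  mat <- matrix(c(2, 1, 0, 0, 0), nrow = 1,
                dimnames = list("m1", wt2$snp_id))
  dm <- dosage_matrix(mat, wt2$effect_allele, wt2$other_allele, TRUE)
  grs <- compute_grs(dm, wt2, c(m1 = "mother"))
  expect_identical(grs$score_htn, 2 * 0.5 + 1 * 1.0 + 0 * 0.25)  # 2.0
  # all-zero dosages give all-zero scores
  dm0 <- dosage_matrix(mat * 0, wt2$effect_allele, wt2$other_allele, TRUE)
  grs0 <- compute_grs(dm0, wt2, c(m1 = "mother"))
  expect_identical(grs0$score_combined, 0)
})

test_that("combined score is exactly the sum of the components", {
  df <- data.frame(sample_id = "x", role = "mother",
                   score_htn = 1.25, score_obesity = 2.50, score_t2d = 0.25)
  expect_identical(combine_scores(df)$score_combined, 4.00)
  expect_error(combine_scores(df[, -3]), "absent")
  # printed per-condition means of the study sum to its printed combined mean
  expect_equal(combine_scores(data.frame(
    sample_id = "published", role = "mother",
    score_htn = 17.8, score_obesity = 3.8, score_t2d = 4.4
  ))$score_combined, 26.0, tolerance = 1e-12)
})

test_that("scores scale linearly and respect bounds", {
  wt <- toy_weights()
  dm <- toy_dosage_matrix(wt, n = 6, seed = 3)
  grs1 <- compute_grs(dm, wt, toy_roles(6))
  dm2 <- dm
  dm2$dosage <- dm$dosage / 2   # halve every dosage (stays in [0, 2])
  grs2 <- compute_grs(dm2, wt, toy_roles(6))
  expect_equal(grs1$score_combined, 2 * grs2$score_combined)
  for (cond in c("htn", "obesity", "t2d")) {
    w_sum <- sum(wt$weight[wt$condition == toupper(sub("htn", "HTN", cond))])
    col <- grs1[[paste0("score_", cond)]]
    expect_true(all(col >= 0))
  }
  expect_true(all(grs1$score_combined <= 2 * sum(wt$weight)))
})

test_that("the three missing policies agree on complete data", {
  wt <- toy_weights()
  dm <- toy_dosage_matrix(wt, n = 8, seed = 4)
  roles <- toy_roles(8)
  g1 <- compute_grs(dm, wt, roles, missing_policy = "impute_role_mean")
  g2 <- suppressMessages(compute_grs(dm, wt, roles,
                                     missing_policy = "drop_sample"))
  g3 <- compute_grs(dm, wt, roles, missing_policy = "score_available")
  expect_equal(g1$score_combined, g2$score_combined)
  expect_equal(g1$score_combined, g3$score_combined)
})

test_that("missing genotypes follow the chosen policy", {
  wt <- toy_weights()
  mat <- matrix(rep(c(0, 1, 2, 1), each = 6), nrow = 4, byrow = TRUE,
                dimnames = list(c("m1", "m2", "f1", "f2"), wt$snp_id))
  mat["m1", "rs1"] <- NA
  dm <- dosage_matrix(mat, wt$effect_allele, wt$other_allele, TRUE)
  roles <- setNames(c("mother", "mother", "father", "father"),
                    rownames(mat))
  # impute_role_mean: m1's rs1 <- mean of mothers' rs1 (= m2's value, 1)
  g <- compute_grs(dm, wt, roles, missing_policy = "impute_role_mean")
  expect_equal(g$score_htn[g$sample_id == "m1"],
               1 * 0.5 + 0 * 1.0)
  expect_equal(g$n_missing_htn[g$sample_id == "m1"], 1L)
  # drop_sample removes m1 only
  g2 <- suppressMessages(compute_grs(dm, wt, roles,
                                     missing_policy = "drop_sample"))
  expect_setequal(g2$sample_id, c("m2", "f1", "f2"))
  # score_available sums the observed SNPs only
  g3 <- compute_grs(dm, wt, roles, missing_policy = "score_available")
  expect_equal(g3$score_htn[g3$sample_id == "m1"], 0 * 1.0)
  # an all-missing sample is refused by name under imputation
  mat2 <- mat
  mat2["m1", ] <- NA
  dm2 <- dosage_matrix(mat2, wt$effect_allele, wt$other_allele, TRUE)
  expect_error(compute_grs(dm2, wt, roles), "m1")
})

test_that("a condition without scored SNPs is an error", {
  wt <- toy_weights()
  dm <- toy_dosage_matrix(wt, n = 4, seed = 1)
  dm_sub <- dosage_matrix(dm$dosage[, 1:4],
                          dm$counted_allele[1:4], dm$other_allele[1:4],
                          TRUE)
  expect_error(compute_grs(dm_sub, wt, toy_roles(4)), "T2D")
})
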