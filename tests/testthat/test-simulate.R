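small_cfg <- function(...) {
  sim_config(panel_sizes = c(HTN = 4L, OBESITY = 3L, T2D = 5L), ...)
}

test_that("generated panels have the configured sizes, bands and determinism", {
  cfg <- sim_config(seed = 101)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 107L)
  expect_equal(as.vector(table(p1$condition)[c("HTN", "OBESITY", "T2D")]),
               c(31L, 30L, 46L))
  expect_true(all(p1$freq > 0.05 & p1$freq < 0.95))
  expect_true(all(p1$weight > 0))
  expect_true(all(p1$effect_allele != p1$other_allele))
  # expected parental GRS in closed form: all weights 1, all f = 0.5
  # gives E[S] = sum over SNPs of 2*0.5*1 = SNP count
  pan <- p1
  pan$weight <- 1
  pan$freq <- 0.5
  expect_equal(panel_moments(pan)$mean, 107)
})

test_that("the prevalence intercept solver hits its target in both modes", {
  for (beta in c(0, 0.4, 1.2)) {
    a <- solve_intercept(beta, 0.01, "linear")
    marg <- integrate(function(z) dnorm(z) * plogis(a + beta * z),
                      -Inf, Inf, rel.tol = 1e-12)$value
    expect_equal(marg, 0.01, tolerance = 1e-8)
    at <- solve_intercept(beta, 0.01, "threshold", 0.95)
    expect_equal(0.95 * plogis(at) + 0.05 * plogis(at + beta), 0.01,
                 tolerance = 1e-8)
  }
  expect_identical(solve_intercept(0, 0.01, "linear"), qlogis(0.01))
})

test_that("simulation is fully deterministic under (seed, config)", {
  cfg <- small_cfg(n_trios = 40, beta_m = 0.5, seed = 7)
  s1 <- simulate_trios(cfg)
  s2 <- simulate_trios(cfg)
  expect_identical(s1$dosages$dosage, s2$dosages$dosage)
  expect_identical(s1$trios, s2$trios)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_trios(cfg, seed = 8)
  expect_false(identical(s1$dosages$dosage, s3$dosages$dosage))
  expect_error(simulate_trios(small_cfg(n_trios = 10)), "seed")
})

test_that("parental genotypes sit in Hardy-Weinberg proportions", {
  cfg <- sim_config(panel_sizes = c(HTN = 2L, OBESITY = 2L, T2D = 2L),
                    n_trios = 10000, seed = 55)
  sim <- simulate_trios(cfg)
  f <- sim$panel$freq
  G <- sim$dosages$dosage[sim$trios$father_id, ]  # fathers: population draw
  n <- nrow(G)
  for (j in seq_along(f)) {
    expected <- c((1 - f[j])^2, 2 * f[j] * (1 - f[j]), f[j]^2)
    for (g in 0:2) {
      obs <- mean(G[, j] == g)
      se <- sqrt(expected[g + 1] * (1 - expected[g + 1]) / n)
      expect_lt(abs(obs - expected[g + 1]), 3 * se + 1e-9)
    }
  }
})

test_that("child dosage expectation is the parental midpoint", {
  cfg <- sim_config(panel_sizes = c(HTN = 1L, OBESITY = 1L, T2D = 1L),
                    n_trios = 35000, seed = 77)
  sim <- simulate_trios(cfg)
  M <- sim$dosages$dosage[sim$trios$mother_id, ]
  F_ <- sim$dosages$dosage[sim$trios$father_id, ]
  C <- sim$dosages$dosage[sim$trios$child_id, ]
  # over >1e5 transmissions the mean deviation from (m + f)/2 vanishes
  dev <- C - (M + F_) / 2
  se <- apply(dev, 2, sd) / sqrt(nrow(dev))
  expect_true(all(abs(colMeans(dev)) < 4 * se + 1e-9))
  expect_true(all(C >= 0 & C <= 2))
})

test_that("the realized unascertained prevalence matches the target", {
  cfg <- small_cfg(n_trios = 500, beta_m = 0.8, seed = 91)
  sim <- simulate_trios(cfg)
  p_hat <- sim$truth$realized_prevalence
  n <- sim$truth$n_drawn
  se <- sqrt(0.01 * 0.99 / n)
  expect_lt(abs(p_hat - 0.01), 3 * se)
})

test_that("fathers are unaffected by maternal ascertainment; mothers shift", {
  cfg <- sim_config(n_trios = 700, beta_m = 1, seed = 13)
  sim <- simulate_trios(cfg)
  mom <- panel_moments(sim$panel)
  f_scores <- as.vector(
    sim$dosages$dosage[sim$trios$father_id, ] %*% sim$panel$weight)
  m_scores <- as.vector(
    sim$dosages$dosage[sim$trios$mother_id, ] %*% sim$panel$weight)
  # fathers' GRS keeps the population law
  z_f <- (mean(f_scores) - mom$mean) / (mom$sd / sqrt(length(f_scores)))
  expect_lt(abs(z_f), qnorm(0.995))
  # ascertained mothers' mean exceeds the population mean by roughly one
  # population SD (rare-disease exponential tilting of a standard normal)
  shift <- (mean(m_scores) - mom$mean) / mom$sd
  expect_gt(shift, 0.7)
})

test_that("missingness is emitted at the configured rate but never used for affection", {
  cfg <- small_cfg(n_trios = 300, missing_rate = 0.1, seed = 19)
  sim <- simulate_trios(cfg)
  rate <- mean(is.na(sim$dosages$dosage))
  expect_lt(abs(rate - 0.1), 0.02)
})

test_that("operating characteristics are deterministic and monotone-shaped", {
  cfg <- small_cfg(n_trios = 120)
  oc1 <- operating_characteristics(cfg, beta_grid = c(0, 1.5),
                                   n_replicates = 8, seed = 3)
  oc2 <- operating_characteristics(cfg, beta_grid = c(0, 1.5),
                                   n_replicates = 8, seed = 3)
  expect_identical(oc1, oc2)
  expect_equal(nrow(oc1), 2L)
  expect_true(all(oc1$mean_or > 0))
  expect_error(operating_characteristics(cfg, numeric(0), 10), "empty")
})

test_that("pedigree phenotype fields are populated and filterable", {
  sim <- simulate_trios(small_cfg(n_trios = 400, seed = 47))
  subtypes <- c("ToF", "D-TGA", "DORV", "VSD", "IAA", "truncus",
                "aortic arch anomaly", "L-TGA", "complex", "other")
  expect_true(all(sim$trios$ctd_subtype %in% subtypes))
  expect_gt(sum(sim$trios$ctd_subtype == "ToF"), 0)
  tof <- filter_trios(sim$trios, ctd_subtype = "ToF")
  expect_true(all(tof$ctd_subtype == "ToF"))
})
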