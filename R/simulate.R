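#' Configuration for the trio simulator
#'
#' Defines the generative model for synthetic case-parent trio cohorts:
#' a SNP panel (31 hypertension + 30 obesity + 46 type-2-diabetes common
#' SNPs by default), random-mating parents in Hardy-Weinberg equilibrium,
#' Mendelian transmission to the child, a logistic (liability) model for the
#' child's affection status driven by the mother's combined GRS, and
#' retention of affected-child trios only (ascertainment).
#'
#' The affection model is `P(affected) = plogis(alpha + beta_m * z_m)` in
#' linear mode, where `z_m` is the mother's combined GRS standardized
#' against the population mean/SD, or
#' `plogis(alpha + beta_m * [GRS_m > population threshold])` in threshold
#' mode. The intercept `alpha` is solved by bisection so that the marginal
#' (unascertained) prevalence equals `baseline_prevalence` (default 1%, the
#' live-birth frequency of congenital heart defects).
#'
#' @param n_trios Number of affected-child trios to retain (default 721,
#'   the pooled study-scale cohort).
#' @param panel Optional panel from [generate_panel()]; when `NULL` a panel
#'   is generated from the sizes/band/weight settings below.
#' @param panel_sizes Named SNP counts per condition.
#' @param freq_band Effect-allele frequency band (uniform draw); kept inside
#'   (0.05, 0.95) so all panel SNPs are common (MAF > 0.05).
#' @param weight_means Mean per-allele weight per condition (gamma draws);
#'   defaults put the simulated per-condition scores at the study scale
#'   (means near 17.8 / 3.8 / 4.4, combined near 26).
#' @param weight_shape Gamma shape for the weight distribution.
#' @param beta_m Maternal effect on the log-odds of offspring affection per
#'   standardized combined GRS (linear mode) or per threshold exceedance
#'   (threshold mode). `0` is the null.
#' @param baseline_prevalence Marginal affection probability in (0, 0.5).
#' @param effect_mode `"linear"` or `"threshold"`.
#' @param threshold_quantile Population quantile of the maternal GRS above
#'   which the threshold effect acts (threshold mode only).
#' @param missing_rate Per-genotype missingness rate applied to the emitted
#'   dosages (the affection model always uses the true genotypes).
#' @param cohort_split Proportion of trios labeled CHOP (the rest PCGC).
#' @param pheno Named list of phenotype-field frequencies used to populate
#'   the pedigree (preeclampsia, HTN medication, pregestational/gestational
#'   diabetes, male sex, extracardiac defects, subtype distribution) so that
#'   subgroup filters are exercisable; defaults follow the study cohorts.
#' @param seed Integer seed; required by [simulate_trios()] unless one is
#'   passed there explicitly.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_trios = 721L,
                       panel = NULL,
                       panel_sizes = c(HTN = 31L, OBESITY = 30L, T2D = 46L),
                       freq_band = c(0.1, 0.9),
                       weight_means = c(HTN = 0.574, OBESITY = 0.127,
                                        T2D = 0.096),
                       weight_shape = 4,
                       beta_m = 0,
                       baseline_prevalence = 0.01,
                       effect_mode = c("linear", "threshold"),
                       threshold_quantile = 0.95,
                       missing_rate = 0,
                       cohort_split = 466 / 721,
                       pheno = NULL,
                       seed = NULL) {
  effect_mode <- match.arg(effect_mode)
  if (n_trios < 1) stop("'n_trios' must be positive")
  if (!is.finite(beta_m)) stop("'beta_m' must be finite")
  if (baseline_prevalence <= 0 || baseline_prevalence >= 0.5)
    stop("'baseline_prevalence' must lie in (0, 0.5)")
  if (length(freq_band) != 2L || freq_band[1] >= freq_band[2] ||
      freq_band[1] < 0.05 || freq_band[2] > 0.95)
    stop("'freq_band' must be an increasing interval within [0.05, 0.95]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must lie in [0, 1)")
  if (threshold_quantile <= 0 || threshold_quantile >= 1)
    stop("'threshold_quantile' must lie in (0, 1)")
  panel_sizes <- unlist(panel_sizes)   # tolerate YAML-style named lists
  if (is.null(names(panel_sizes)) || anyNA(names(panel_sizes)))
    stop("'panel_sizes' must be named by condition (HTN, OBESITY, T2D)")
  names(panel_sizes) <- normalize_condition(names(panel_sizes))
  if (any(panel_sizes < 1)) stop("each condition needs at least one SNP")
  defaults <- list(preeclampsia = 0.02, htn_medication = 0.013,
                   pregestational_diabetes = 0.007,
                   gestational_diabetes = 0.05,
                   male = 0.61, extracardiac = 0.44,
                   subtype_probs = c("ToF" = 0.380, "D-TGA" = 0.196,
                                     "VSD" = 0.180, "DORV" = 0.116,
                                     "aortic arch anomaly" = 0.044,
                                     "truncus" = 0.029, "IAA" = 0.017,
                                     "L-TGA" = 0.016, "complex" = 0.019,
                                     "other" = 0.003))
  pheno <- utils::modifyList(defaults, pheno %||% list())
  structure(list(n_trios = as.integer(n_trios), panel = panel,
                 panel_sizes = panel_sizes, freq_band = freq_band,
                 weight_means = weight_means, weight_shape = weight_shape,
                 beta_m = beta_m, baseline_prevalence = baseline_prevalence,
                 effect_mode = effect_mode,
                 threshold_quantile = threshold_quantile,
                 missing_rate = missing_rate, cohort_split = cohort_split,
                 pheno = pheno, seed = seed),
            class = "sim_config")
}

#' Generate a synthetic SNP panel and weight table
#'
#' Effect-allele frequencies are drawn uniformly in the configured band and
#' per-allele weights from a gamma distribution with per-condition means;
#' alleles are random distinct bases. Deterministic under the seed.
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to the config's); `NULL` uses the current RNG
#'   stream.
#' @return A data.frame of class `sim_panel` (columns `snp_id`, `condition`,
#'   `freq`, `effect_allele`, `other_allele`, `weight`); coercible to a
#'   weight table with [panel_weights()].
#' @export
generate_panel <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- config$panel_sizes[CONDITIONS]
  n <- sum(sizes)
  condition <- rep(names(sizes), sizes)
  freq <- stats::runif(n, config$freq_band[1], config$freq_band[2])
  mean_w <- config$weight_means[condition]
  shape <- config$weight_shape
  weight <- stats::rgamma(n, shape = shape, scale = mean_w / shape)
  bases <- c("A", "C", "G", "T")
  effect <- sample(bases, n, replace = TRUE)
  other <- vapply(effect, function(e) sample(setdiff(bases, e), 1L), "")
  panel <- data.frame(snp_id = sprintf("rs%06d", seq_len(n)),
                      condition = condition, freq = freq,
                      effect_allele = effect, other_allele = unname(other),
                      weight = weight, stringsAsFactors = FALSE)
  class(panel) <- c("sim_panel", "data.frame")
  panel
}

#' Weight table of a simulated panel
#'
#' @param panel A `sim_panel`.
#' @return The corresponding `grs_weights` table (io schema).
#' @export
panel_weights <- function(panel) {
  weight_table(panel$snp_id, panel$effect_allele, panel$other_allele,
               panel$weight, panel$condition)
}

## Population moments of the combined maternal GRS: each SNP contributes an
## independent Binomial(2, f) dosage scaled by its weight.
panel_moments <- function(panel) {
  f <- panel$freq
  w <- panel$weight
  list(mean = sum(2 * f * w), sd = sqrt(sum(w^2 * 2 * f * (1 - f))))
}

#' Solve the liability-model intercept for a target prevalence
#'
#' Bisection (interval tolerance 1e-10) for `alpha` such that the marginal
#' affection probability equals `prevalence`. In linear mode the marginal
#' probability integrates `plogis(alpha + beta * z)` over the standard
#' normal law of the standardized maternal GRS (the combined score over 100+
#' independent SNPs is normal to high accuracy); in threshold mode it is the
#' two-point mixture across the threshold.
#'
#' @param beta Maternal effect.
#' @param prevalence Target marginal prevalence.
#' @param mode `"linear"` or `"threshold"`.
#' @param threshold_quantile Population quantile defining the threshold.
#' @return The intercept `alpha`.
#' @export
solve_intercept <- function(beta, prevalence, mode = "linear",
                            threshold_quantile = 0.95) {
  marginal <- if (mode == "linear") {
    if (beta == 0) return(stats::qlogis(prevalence))
    function(alpha)
      stats::integrate(function(z) stats::dnorm(z) *
                         stats::plogis(alpha + beta * z),
                       -Inf, Inf, rel.tol = 1e-12)$value
  } else {
    q <- threshold_quantile
    function(alpha)
      q * stats::plogis(alpha) + (1 - q) * stats::plogis(alpha + beta)
  }
  lo <- stats::qlogis(prevalence) - abs(beta) - 5
  hi <- stats::qlogis(prevalence) + abs(beta) + 5
  if ((marginal(lo) - prevalence) * (marginal(hi) - prevalence) > 0)
    stop("prevalence solver failed to bracket the intercept")
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (marginal(mid) > prevalence) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

## Hardy-Weinberg genotype draws: n samples x p SNPs of Binomial(2, f).
draw_genotypes <- function(n, freq) {
  p <- length(freq)
  matrix(stats::rbinom(n * p, 2L, rep(freq, each = n)), nrow = n, ncol = p)
}

#' Simulate an ascertained case-parent trio cohort
#'
#' Parents are drawn independently under Hardy-Weinberg equilibrium at each
#' panel SNP (random mating); the child receives one allele per parent per
#' SNP (Mendelian transmission); the child's affection status follows the
#' liability model of [sim_config()], acting through the mother's combined
#' GRS only; only trios with an affected child are retained, by rejection
#' sampling, until `n_trios` are collected. When `beta_m = 0` the affection
#' probability is constant, so the ascertained genotype distribution equals
#' the population distribution and trios are drawn directly.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to the config's seed; required).
#' @return A list of class `trio_sim`: `trios` (a `trio_set`), `dosages`
#'   (a [dosage_matrix()] of mothers, fathers and children, oriented),
#'   `weights` (the panel's `grs_weights`), `panel`, and `truth` (the
#'   generative parameters: `beta_m`, `alpha`, population GRS moments,
#'   threshold, realized unascertained prevalence when rejection sampling
#'   was used).
#' @export
simulate_trios <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed))
    stop("a seed is required (set it in sim_config() or pass it here)")
  set.seed(seed)
  panel <- config$panel %||% generate_panel(config, seed = NULL)
  n <- config$n_trios
  w <- panel$weight
  f <- panel$freq
  mom <- panel_moments(panel)
  beta <- config$beta_m
  alpha <- solve_intercept(beta, config$baseline_prevalence,
                           config$effect_mode, config$threshold_quantile)
  pop_threshold <- mom$mean + mom$sd * stats::qnorm(config$threshold_quantile)

  aff_prob <- function(score) {
    if (config$effect_mode == "linear")
      stats::plogis(alpha + beta * (score - mom$mean) / mom$sd)
    else
      stats::plogis(alpha + beta * (score > pop_threshold))
  }

  n_drawn <- 0L
  n_affected <- 0L
  if (beta == 0) {
    ## Affection is independent of genotype: conditional law = population law.
    G_m <- draw_genotypes(n, f)
  } else {
    G_m <- matrix(0L, nrow = 0, ncol = length(f))
    batch <- min(max(5000L, ceiling(1.25 * n / config$baseline_prevalence)),
                 300000L)
    while (nrow(G_m) < n) {
      cand <- draw_genotypes(batch, f)
      p_aff <- aff_prob(as.vector(cand %*% w))
      hit <- stats::runif(batch) < p_aff
      n_drawn <- n_drawn + batch
      n_affected <- n_affected + sum(hit)
      G_m <- rbind(G_m, cand[hit, , drop = FALSE])
    }
    G_m <- G_m[seq_len(n), , drop = FALSE]
  }
  G_f <- draw_genotypes(n, f)
  ## one transmitted allele per parent: Bernoulli(dosage / 2) per SNP
  G_c <- matrix(stats::rbinom(length(G_m), 1L, G_m / 2) +
                  stats::rbinom(length(G_f), 1L, G_f / 2),
                nrow = n)

  fam <- sprintf("fam%05d", seq_len(n))
  ids <- list(m = sprintf("m%05d", seq_len(n)),
              f = sprintf("f%05d", seq_len(n)),
              c = sprintf("c%05d", seq_len(n)))
  ph <- config$pheno
  yn <- function(p) ifelse(stats::runif(n) < p, "yes", "no")
  n_chop <- round(n * config$cohort_split)
  cohort <- sample(rep(c("CHOP", "PCGC"), c(n_chop, n - n_chop)))
  trios <- trio_set(data.frame(
    family_id = fam, mother_id = ids$m, father_id = ids$f, child_id = ids$c,
    cohort = cohort,
    ctd_subtype = sample(names(ph$subtype_probs), n, replace = TRUE,
                         prob = ph$subtype_probs),
    child_sex = ifelse(stats::runif(n) < ph$male, "male", "female"),
    extracardiac = yn(ph$extracardiac),
    maternal_preeclampsia = yn(ph$preeclampsia),
    maternal_htn_medication = yn(ph$htn_medication),
    maternal_pregestational_diabetes = yn(ph$pregestational_diabetes),
    maternal_gestational_diabetes = yn(ph$gestational_diabetes),
    stringsAsFactors = FALSE))

  dos <- rbind(G_m, G_f, G_c)
  storage.mode(dos) <- "double"
  rownames(dos) <- c(ids$m, ids$f, ids$c)
  colnames(dos) <- panel$snp_id
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(dos)) < config$missing_rate
    dos[mask] <- NA_real_
  }
  dm <- dosage_matrix(dos, counted_allele = panel$effect_allele,
                      other_allele = panel$other_allele, oriented = TRUE)

  structure(list(trios = trios, dosages = dm,
                 weights = panel_weights(panel), panel = panel,
                 truth = list(beta_m = beta, alpha = alpha,
                              effect_mode = config$effect_mode,
                              pop_mean = mom$mean, pop_sd = mom$sd,
                              pop_threshold = pop_threshold,
                              n_drawn = n_drawn, n_affected = n_affected,
                              realized_prevalence =
                                if (n_drawn > 0) n_affected / n_drawn
                                else NA_real_,
                              seed = seed)),
            class = "trio_sim")
}

#' @exportS3Method print trio_sim
print.trio_sim <- function(x, ...) {
  cat(sprintf(paste0("trio_sim: %d affected-child trios, %d panel SNPs, ",
                     "beta_m = %g (%s mode)\n"),
              nrow(x$trios), nrow(x$panel), x$truth$beta_m,
              x$truth$effect_mode))
  invisible(x)
}

#' Restrict a dosage matrix to a set of samples
#'
#' @param dm A `dosage_matrix`.
#' @param ids Sample ids to keep (all must be present).
#' @return The restricted `dosage_matrix`.
#' @export
subset_samples <- function(dm, ids) {
  missing_ids <- setdiff(ids, sample_ids(dm))
  if (length(missing_ids))
    stop("sample(s) absent from dosage matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  dosage_matrix(dm$dosage[ids, , drop = FALSE],
                counted_allele = dm$counted_allele,
                other_allele = dm$other_allele,
                oriented = dm$oriented)
}

#' Operating characteristics of the maternal contrast by simulation
#'
#' For each maternal effect size in `beta_grid`, simulates `n_replicates`
#' ascertained cohorts, runs the full scoring + contrast pipeline on each,
#' and records the empirical rejection rate of the percentile OR test and of
#' the mean contrast at level `alpha`, the mean odds ratio, and the fraction
#' of replicates in which the mothers' mean combined GRS exceeds the
#' fathers'. With `beta = 0` these rejection rates are the design's type-I
#' error; with `beta > 0` they are its power. The SNP panel is generated
#' once from the master seed and held fixed across replicates; per-replicate
#' seeds are drawn from the master seed, so the whole table is reproducible.
#'
#' @param config A [sim_config()]; its `beta_m` is overridden by the grid.
#' @param beta_grid Numeric vector of maternal effects.
#' @param n_replicates Replicates per grid point (>= 100 recommended for
#'   assertions).
#' @param alpha Test level.
#' @param quantile_level Dichotomization level for the OR test.
#' @param seed Master seed.
#' @return A data.frame (class `grs_opchar`): one row per `beta_m` with
#'   `reject_rate_or`, `reject_rate_mean`, `mean_or`,
#'   `prop_mother_mean_higher`, `n_replicates`.
#' @export
operating_characteristics <- function(config, beta_grid, n_replicates,
                                      alpha = 0.05, quantile_level = 0.95,
                                      seed = 1L) {
  if (!length(beta_grid)) stop("'beta_grid' is empty")
  if (n_replicates < 1) stop("'n_replicates' must be positive")
  set.seed(seed)
  if (is.null(config$panel)) config$panel <- generate_panel(config, seed = NULL)
  seeds <- matrix(sample.int(2^31 - 2, n_replicates * length(beta_grid)),
                  nrow = n_replicates)
  rows <- lapply(seq_along(beta_grid), function(j) {
    cfg <- config
    cfg$beta_m <- beta_grid[j]
    rej_or <- rej_mean <- logical(n_replicates)
    ors <- mdiff <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      sim <- simulate_trios(cfg, seed = seeds[r, j])
      roles <- parent_roles(sim$trios)
      dm <- subset_samples(sim$dosages, names(roles))
      grs <- compute_grs(dm, sim$weights, roles)
      m <- grs$score_combined[grs$role == "mother"]
      f <- grs$score_combined[grs$role == "father"]
      tc <- dichotomize_and_test(m, f, percentile_threshold(f, quantile_level))
      mc <- mean_contrast(m, f)
      rej_or[r] <- tc$fisher_p <= alpha
      rej_mean[r] <- mc$p_value <= alpha
      ors[r] <- tc$odds_ratio
      mdiff[r] <- mean(m) - mean(f)
    }
    data.frame(beta_m = beta_grid[j], quantile_level = quantile_level,
               n_replicates = n_replicates,
               reject_rate_or = mean(rej_or),
               reject_rate_mean = mean(rej_mean),
               mean_or = mean(ors),
               prop_mother_mean_higher = mean(mdiff > 0))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("grs_opchar", "data.frame")
  out
}
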