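#' @keywords internal
"_PACKAGE"

#' @importFrom stats fisher.test t.test shapiro.test rbinom runif rgamma
#'   qnorm qlogis dnorm plogis integrate sd var setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

CONDITIONS <- c("HTN", "OBESITY", "T2D")

`%||%` <- function(a, b) if (is.null(a)) b else a

tg_log <- function(..., level = "INFO") {
  message(sprintf("[%s] %s", level, paste0(...)))
}

#' Nearest-rank empirical quantile
#'
#' The q-th quantile of `x` defined as the `ceiling(n * q)`-th order
#' statistic, so the returned cutoff is always an observed value and is
#' deterministic under ties.
#'
#' @param x Numeric vector.
#' @param q Quantile level in (0, 1).
#' @return A single numeric value from `x`.
#' @examples
#' quantile_nearest_rank(1:100, 0.95)  # 95
#' @export
quantile_nearest_rank <- function(x, q) {
  if (length(x) == 0L) stop("cannot take a quantile of an empty vector")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("'q' must be a single probability strictly between 0 and 1")
  if (anyNA(x) || any(!is.finite(x))) stop("'x' contains non-finite values")
  sort(x)[ceiling(length(x) * q)]
}

#' Format a count as a one-decimal percentage
#'
#' The percentage formatter used for cohort characteristic tables:
#' `100 * count / total`, printed with one decimal place.
#'
#' @param count Numerator count(s).
#' @param total Denominator total.
#' @return Character vector like `"40.8"`.
#' @examples
#' format_percent(190, 466)  # "40.8"
#' @export
format_percent <- function(count, total) {
  if (any(total <= 0)) stop("'total' must be positive")
  sprintf("%.1f", 100 * count / total)
}

## 2x2 exact test with the sample odds ratio.
## p from the two-sided Fisher exact test (hypergeometric enumeration,
## conventional "probabilities <= observed" definition as in stats);
## OR = (a d)/(b c) with Haldane-Anscombe +0.5 on every cell when any cell
## is zero; 95% CI by the Woolf logit method on the (corrected) cells.
fisher_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers")
  if (all(cells == 0)) stop("all four cells are zero")
  p <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                          conf.int = FALSE)$p.value
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc[1] * cc[4]) / (cc[2] * cc[3])
  se <- sqrt(sum(1 / cc))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(a = a, b = b, c = c, d = d,
       odds_ratio = or,
       ci_low = exp(log(or) - zq * se),
       ci_high = exp(log(or) + zq * se),
       fisher_p = min(p, 1),
       haldane_corrected = corrected)
}

## Shapiro-Wilk p-value; stats::shapiro.test is defined for 3 <= n <= 5000,
## larger samples are thinned to 5000 evenly spaced order statistics.
## Zero-range samples have no defined W statistic: returns NA.
shapiro_p <- function(x) {
  n <- length(x)
  if (n < 3L) stop("Shapiro-Wilk requires at least 3 observations")
  if (diff(range(x)) == 0) return(NA_real_)
  if (n > 5000L) x <- sort(x)[round(seq(1L, n, length.out = 5000L))]
  stats::shapiro.test(x)$p.value
}

## Sniff the field separator of a delimited text file from its header line.
sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("file is empty: ", path)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

read_delim_auto <- function(path) {
  utils::read.delim(path, sep = sniff_sep(path), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "NA")
}

normalize_condition <- function(x) {
  up <- toupper(trimws(x))
  up[up %in% c("OBESITY", "BMI", "OB")] <- "OBESITY"
  up[up %in% c("T2D", "TD2", "DIABETES")] <- "T2D"
  up[up %in% c("HTN", "HYPERTENSION")] <- "HTN"
  bad <- !(up %in% CONDITIONS)
  if (any(bad))
    stop("unknown condition label(s): ", paste(unique(x[bad]), collapse = ", "))
  up
}

## Run an expression with a private RNG stream, restoring the caller's state.
with_preserved_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
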