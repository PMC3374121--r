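# Inverse-variance fixed-effect meta-analysis and CI-to-SE reconstruction.

#' Reconstruct a log odds ratio and its standard error from a printed CI
#'
#' Published association tables report odds ratios with 95% confidence
#' intervals but not standard errors. Assuming the CI is Wald-type on the
#' log scale, `log_or = ln(OR)` and
#' `se = (ln ci_high - ln ci_low) / (2 * z)`, with `z` the standard normal
#' quantile for the confidence level (1.959964 at 95%). A study printed
#' with a zero OR or zero lower bound has no finite log OR by this route
#' and is returned with `poolable = FALSE`.
#'
#' @param or_estimate,ci_low,ci_high Odds ratio and confidence bounds, with
#'   `0 <= ci_low <= or_estimate <= ci_high`. Vectorized.
#' @param level Confidence level of the printed interval (default 0.95).
#' @return Data.frame: `log_or`, `se`, `source = "ci_reconstructed"`,
#'   `poolable`.
#' @export
se_from_ci <- function(or_estimate, ci_low, ci_high, level = 0.95) {
  if (any(ci_low < 0 | ci_low > or_estimate | or_estimate > ci_high))
    stop("need 0 <= ci_low <= or_estimate <= ci_high")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  degenerate <- ci_low == ci_high & or_estimate > 0
  if (any(degenerate))
    stop("degenerate interval (ci_low == ci_high) has zero standard error")
  poolable <- ci_low > 0 & or_estimate > 0
  z <- qnorm(1 - (1 - level) / 2)
  data.frame(
    log_or = ifelse(poolable, log(or_estimate), NA_real_),
    se = ifelse(poolable, (log(ci_high) - log(ci_low)) / (2 * z), NA_real_),
    source = "ci_reconstructed",
    poolable = poolable,
    stringsAsFactors = FALSE)
}

#' Read a study-effects table
#'
#' Reads a TSV of per-study odds ratios with confidence bounds (columns
#' `study`, `or`, `ci_low`, `ci_high`, optionally `haplogroup` and
#' `subgroup` for filtering) and reconstructs log OR and SE per study via
#' [se_from_ci()]. Non-poolable rows (zero OR / zero lower bound, as
#' printed for a study with no carrier cases) are retained with
#' `poolable = FALSE`; [fixed_effect_meta()] excludes them with a warning.
#'
#' @param file Path to the TSV.
#' @param haplogroup,subgroup Optional filters on the matching columns.
#' @param level Confidence level of the printed intervals.
#' @return Data.frame: `study`, `or`, `ci_low`, `ci_high`, `log_or`, `se`,
#'   `source`, `poolable` (plus any filter columns present).
#' @export
read_study_effects <- function(file, haplogroup = NULL, subgroup = NULL,
                               level = 0.95) {
  df <- read.delim(file, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("study", "or", "ci_low", "ci_high")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("effects table missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(haplogroup)) df <- df[df$haplogroup == haplogroup, ]
  if (!is.null(subgroup)) df <- df[df$subgroup == subgroup, ]
  if (nrow(df) == 0L) stop("no study effects after filtering")
  cbind(df, se_from_ci(df$or, df$ci_low, df$ci_high, level = level))
}

#' Inverse-variance fixed-effect meta-analysis of log odds ratios
#'
#' Pools study effects under a common-effect model: with weights
#' `w_i = 1 / se_i^2`, the pooled log OR is `sum(w_i * logOR_i) / sum(w_i)`
#' with standard error `sum(w_i)^(-1/2)`; significance is the two-sided
#' normal test of the pooled log OR against zero. Cochran's Q is reported
#' descriptively only — no heterogeneity modelling is done.
#'
#' @param effects Data.frame with columns `log_or` and `se` (e.g. from
#'   [se_from_ci()] / [read_study_effects()], or fitted model output); a
#'   `poolable` column, when present, excludes flagged rows with a warning,
#'   as do non-finite `log_or`/`se`.
#' @param level Confidence level for the pooled interval (default 0.95).
#' @return An `fe_meta` list: `pooled_or`, `ci_low`, `ci_high`,
#'   `pooled_log_or`, `se`, `z_stat`, `p_value`, `k` (studies pooled),
#'   `weights` (normalized, named by study when available), `Q`, `Q_df`.
#' @export
fixed_effect_meta <- function(effects, level = 0.95) {
  if (NROW(effects) == 0L) stop("no study effects supplied")
  l <- effects$log_or
  s <- effects$se
  ok <- is.finite(l) & is.finite(s) & s > 0
  if ("poolable" %in% names(effects)) ok <- ok & effects$poolable
  if (!all(ok))
    warning(sum(!ok), " study effect(s) without a finite (log OR, SE) ",
            "excluded from pooling")
  if (!any(ok)) stop("no poolable study effects")
  l <- l[ok]; s <- s[ok]
  w <- 1 / s^2
  pooled <- sum(w * l) / sum(w)
  se_pooled <- 1 / sqrt(sum(w))
  z <- pooled / se_pooled
  zq <- qnorm(1 - (1 - level) / 2)
  wn <- w / sum(w)
  if (!is.null(effects$study)) names(wn) <- effects$study[ok]
  structure(list(
    pooled_or = exp(pooled),
    ci_low = exp(pooled - zq * se_pooled),
    ci_high = exp(pooled + zq * se_pooled),
    pooled_log_or = pooled,
    se = se_pooled,
    z_stat = z,
    p_value = 2 * pnorm(-abs(z)),
    k = sum(ok),
    weights = wn,
    Q = sum(w * (l - pooled)^2),
    Q_df = sum(ok) - 1L), class = "fe_meta")
}

#' @export
print.fe_meta <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Fixed-effect meta-analysis of %d studies\n  pooled OR %.*f (95%% CI %.*f-%.*f), z = %.*f, p = %.3g\n  Q = %.*f on %d df (descriptive)\n",
    x$k, digits, x$pooled_or, digits, x$ci_low, digits, x$ci_high,
    digits, x$z_stat, x$p_value, digits, x$Q, x$Q_df))
  invisible(x)
}

#' Power of the haploid allelic case-control test
#'
#' Analytic power of the two-proportion comparison of derived-allele
#' carrier frequency between cases and controls on the hemizygous Y (one
#' allele per man). With control frequency `p0 = maf` and case frequency
#' `p1 = OR * o / (1 + OR * o)` where `o = p0 / (1 - p0)`, the test
#' statistic uses the pooled frequency
#' `pbar = (n_cases * p1 + n_controls * p0) / (n_cases + n_controls)`, and
#'
#' `power = Phi(delta / sd - z) + Phi(-delta / sd - z)`
#'
#' with `delta = |p1 - p0|`, `sd = sqrt(pbar (1 - pbar) (1/n_cases +
#' 1/n_controls))` and `z` the two-sided critical value at `alpha` (the
#' second term is the far tail, negligible except near the null). Disease
#' prevalence is accepted for the record but does not enter: for an
#' uncommon disease the control-group frequency is effectively the
#' population frequency.
#'
#' @param n_cases,n_controls Group sizes.
#' @param maf Control-group derived-allele frequency, in (0, 1). Vectorized.
#' @param allelic_or Allelic odds ratio to detect (> 0).
#' @param alpha Two-sided significance level (default 0.05).
#' @param prevalence Population disease prevalence; recorded only.
#' @return Power, same length as the longest vector argument. At
#'   `allelic_or = 1` the value is exactly `alpha`.
#' @export
allelic_power <- function(n_cases, n_controls, maf, allelic_or,
                          alpha = 0.05, prevalence = NULL) {
  if (any(maf <= 0 | maf >= 1)) stop("maf must be in (0, 1)")
  if (any(allelic_or <= 0)) stop("allelic_or must be positive")
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must be in (0, 1)")
  if (any(n_cases < 1 | n_controls < 1)) stop("group sizes must be >= 1")
  p0 <- maf
  o <- allelic_or * p0 / (1 - p0)
  p1 <- o / (1 + o)
  if (any(p1 >= 1)) stop("implied case frequency reaches 1")
  pbar <- (n_cases * p1 + n_controls * p0) / (n_cases + n_controls)
  sd <- sqrt(pbar * (1 - pbar) * (1 / n_cases + 1 / n_controls))
  z <- qnorm(1 - alpha / 2)
  delta <- abs(p1 - p0)
  pnorm(delta / sd - z) + pnorm(-delta / sd - z)
}
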