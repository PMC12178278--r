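# Group-level statistics: bootstrap Cohen's d, minimum detectable effect,
# repeated-measures correlation, condition ANOVA, t-test panels with
# Bonferroni correction.

#' Cohen's d with a percentile bootstrap confidence interval
#'
#' One-sample `d = mean(x) / sd(x)`, or paired `d = mean(x - y) /
#' sd(x - y)` when `y` is supplied. The confidence interval is the 2.5 and
#' 97.5 percentile of `d` recomputed over seeded resamples (with
#' replacement, drawn at the subject level) of the input values.
#'
#' @param x Per-subject statistics.
#' @param y Optional paired second set (same length, same subject order).
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Integer seed for the resampling.
#' @param conf Confidence level (default 0.95).
#' @return List with `d`, `ci` (length 2), `n`, and `boot` (the bootstrap
#'   distribution). Zero-SD input yields `d = NA` with a warning.
#' @export
cohens_d <- function(x, y = NULL, n_boot = 1000, seed = 1L, conf = 0.95) {
  if (!is.null(y)) {
    stopifnot(length(x) == length(y))
    x <- x - y
  }
  stopifnot(length(x) >= 2)
  d_of <- function(v) mean(v) / sd(v)
  if (sd(x) == 0) {
    warning("zero standard deviation; Cohen's d undefined")
    return(list(d = NA_real_, ci = c(NA_real_, NA_real_), n = length(x),
                boot = numeric(0)))
  }
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    v <- x[sample.int(length(x), replace = TRUE)]
    if (sd(v) == 0) NA_real_ else d_of(v)
  }, numeric(1)))
  alpha <- (1 - conf) / 2
  list(d = d_of(x),
       ci = unname(quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE)),
       n = length(x), boot = boot)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Subject-level resampling with replacement; the mean is recomputed each
#' iteration and the interval is the matching percentile pair.
#'
#' @param x Per-subject statistics.
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Length-2 numeric vector (lower, upper).
#' @export
bootstrap_mean_ci <- function(x, n_boot = 1000, seed = 1L, conf = 0.95) {
  stopifnot(length(x) >= 2)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(i)
    mean(x[sample.int(length(x), replace = TRUE)]), numeric(1)))
  alpha <- (1 - conf) / 2
  unname(quantile(boot, c(alpha, 1 - alpha)))
}

# Power of a two-sided one-sample t test at effect size d.
one_sample_t_power <- function(d, n, alpha) {
  df <- n - 1
  tc <- qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  pt(-tc, df, ncp = ncp) + 1 - pt(tc, df, ncp = ncp)
}

#' Minimum detectable effect size of a one-sample t test
#'
#' The Cohen's d at which a two-sided one-sample t test with `n` subjects
#' reaches the requested power at level `alpha`, solved through the
#' noncentral t distribution. With n = 8, alpha = 0.05 and 80% power this
#' is 1.16 (to two decimals).
#'
#' @param n Number of subjects (>= 2).
#' @param alpha Significance level.
#' @param power Target power (must exceed `alpha`).
#' @return The minimum detectable |d|.
#' @export
min_detectable_effect <- function(n, alpha = 0.05, power = 0.80) {
  stopifnot(n >= 2, alpha > 0, alpha < 1, power > 0, power < 1)
  if (power <= alpha)
    stopf("requested power (%g) must exceed the significance level (%g)", power, alpha)
  f <- function(d) one_sample_t_power(d, n, alpha) - power
  upper <- 1
  while (f(upper) < 0 && upper < 1e3) upper <- upper * 2
  if (f(upper) < 0) stopf("requested power unattainable")
  uniroot(f, c(1e-8, upper), tol = 1e-10)$root
}

#' Repeated-measures correlation
#'
#' The common within-subject correlation between two variables, from the
#' ANCOVA formulation: `y` is modeled with subject as a factor plus `x`;
#' the coefficient is `sign(b_x) * sqrt(SS_x / (SS_x + SS_error))` with
#' the sums of squares from the sequential ANOVA (x entered after
#' subject), on `df = N - k - 1` error degrees of freedom for `N`
#' observations and `k` subjects. Subjects with fewer than two
#' observations are dropped with a warning.
#'
#' @param subjects Subject identifiers (one per observation).
#' @param x,y Observation vectors.
#' @return List with `r`, `df`, and `p` (two-sided).
#' @export
rm_corr <- function(subjects, x, y) {
  stopifnot(length(subjects) == length(x), length(x) == length(y))
  keep <- complete.cases(subjects, x, y)
  subjects <- subjects[keep]; x <- x[keep]; y <- y[keep]
  counts <- table(subjects)
  if (any(counts < 2)) {
    warning(sprintf("dropping %d subject(s) with fewer than 2 observations",
                    sum(counts < 2)))
    ok <- subjects %in% names(counts)[counts >= 2]
    subjects <- subjects[ok]; x <- x[ok]; y <- y[ok]
  }
  subj <- factor(subjects)
  if (nlevels(subj) < 2) stopf("need at least 2 subjects")
  m <- lm(y ~ subj + x)
  a <- anova(m)
  ss_x <- a["x", "Sum Sq"]; ss_e <- a["Residuals", "Sum Sq"]
  r <- sign(coef(m)[["x"]]) * sqrt(ss_x / (ss_x + ss_e))
  df <- length(x) - nlevels(subj) - 1L
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = unname(r), df = df, p = 2 * pt(-abs(tval), df))
}

#' Bonferroni correction
#'
#' @param p Raw p-value(s).
#' @param family Number of simultaneous tests in the family.
#' @return `min(1, p * family)`, vectorized.
#' @export
bonferroni <- function(p, family) pmin(1, p * family)

# One-sample t test robust to degenerate input: identical values at 0 are
# reported as t = 0, p = 1 (flagged); identical nonzero values as
# t = Inf, p = NA (flagged).
safe_t_test <- function(x, y = NULL) {
  if (!is.null(y)) x <- x - y
  if (sd(x) == 0) {
    if (mean(x) == 0) return(list(t = 0, p = 1, degenerate = TRUE))
    return(list(t = Inf * sign(mean(x)), p = NA_real_, degenerate = TRUE))
  }
  tt <- t.test(x)
  list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
}

#' One-way ANOVA across conditions on per-subject values
#'
#' @param df data.frame with columns `value` and `condition` (one row per
#'   subject x condition).
#' @return List with `F`, `df` (numerator, denominator), `p`, and a
#'   `degenerate` flag (TRUE when the within-group variance is zero).
#' @export
anova_conditions <- function(df) {
  stopifnot(all(c("value", "condition") %in% names(df)))
  fit <- aov(value ~ condition, data = df)
  s <- summary(fit)[[1]]
  total_ss <- sum(s[, "Sum Sq"])
  if (s["Residuals", "Sum Sq"] <= 1e-12 * max(total_ss, .Machine$double.xmin))
    return(list(F = NA_real_, df = unname(s$Df), p = NA_real_, degenerate = TRUE))
  list(F = s["condition", "F value"], df = unname(s$Df),
       p = s["condition", "Pr(>F)"], degenerate = FALSE)
}

#' Group-level test panel for AMIs or slopes
#'
#' For each ROI: a one-sample t test of the per-subject values against
#' zero within each attention condition, and a paired t test between the
#' two conditions, Bonferroni-corrected with the family taken as the
#' number of tests in the panel (3 by default). Effect sizes are
#' one-sample (within condition) and paired (between) Cohen's d with
#' bootstrap confidence intervals.
#'
#' @param values data.frame with `subject`, `roi`, `condition`, `value`
#'   (e.g. from [subject_summary()] or [subject_slopes()] with `slope`
#'   renamed to `value`).
#' @param conditions The two attention conditions to compare (default
#'   AttendLSF and AttendHSF).
#' @param family Bonferroni family size (default: tests per ROI panel, 3).
#' @param n_boot,seed Bootstrap settings passed to [cohens_d()].
#' @return data.frame, one row per ROI x test, with `mean`, `sem`, `t`,
#'   `p_raw`, `p_bonferroni`, `d`, `d_ci_low`, `d_ci_high`, `n`.
#' @export
group_tests <- function(values, conditions = c("AttendLSF", "AttendHSF"),
                        family = 3, n_boot = 1000, seed = 1L) {
  stopifnot(all(c("subject", "roi", "condition", "value") %in% names(values)))
  rows <- list()
  for (roi in unique(values$roi)) {
    per_cond <- lapply(conditions, function(cn) {
      v <- values[values$roi == roi & values$condition == cn, ]
      v[order(v$subject), ]
    })
    names(per_cond) <- conditions
    common <- Reduce(intersect, lapply(per_cond, function(v) v$subject))
    if (length(common) < length(unique(values$subject[values$roi == roi])))
      warning(sprintf("ROI %s: subjects missing a condition excluded listwise", roi))
    for (cn in conditions) {
      x <- per_cond[[cn]]$value[per_cond[[cn]]$subject %in% common]
      tt <- safe_t_test(x)
      dd <- cohens_d(x, n_boot = n_boot, seed = seed)
      rows[[length(rows) + 1]] <- data.frame(
        roi = roi, test = cn, mean = mean(x), sem = sd(x) / sqrt(length(x)),
        t = tt$t, p_raw = tt$p, p_bonferroni = bonferroni(tt$p, family),
        d = dd$d, d_ci_low = dd$ci[1], d_ci_high = dd$ci[2], n = length(x),
        stringsAsFactors = FALSE)
    }
    x1 <- per_cond[[1]]$value[per_cond[[1]]$subject %in% common]
    x2 <- per_cond[[2]]$value[per_cond[[2]]$subject %in% common]
    tt <- safe_t_test(x1, x2)
    dd <- cohens_d(x1, x2, n_boot = n_boot, seed = seed)
    rows[[length(rows) + 1]] <- data.frame(
      roi = roi, test = paste(conditions, collapse = " vs "),
      mean = mean(x1 - x2), sem = sd(x1 - x2) / sqrt(length(x1)),
      t = tt$t, p_raw = tt$p, p_bonferroni = bonferroni(tt$p, family),
      d = dd$d, d_ci_low = dd$ci[1], d_ci_high = dd$ci[2], n = length(x1),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Wilcoxon rank-sum check between hemisphere groups
#'
#' @param values Per-subject statistics.
#' @param hemisphere Grouping factor with two levels (e.g. probe
#'   hemisphere per subject).
#' @return List with `W` and `p`.
#' @export
hemisphere_test <- function(values, hemisphere) {
  g <- split(values, hemisphere)
  if (length(g) != 2) stopf("hemisphere must have exactly two levels")
  wt <- wilcox.test(g[[1]], g[[2]], exact = FALSE)
  list(W = unname(wt$statistic), p = wt$p.value)
}
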