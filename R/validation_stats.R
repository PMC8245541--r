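#' Normalize western-blot band densities to lane total protein
#'
#' Within each blot, every lane's band density is divided by its lane
#' total-protein density (MemCode/Ponceau-style loading control), and
#' the result is expressed relative to the mean of the wild-type lanes
#' of that blot, so the WT group mean is exactly 1 and values are
#' comparable across blots. Doubling every total-protein density
#' leaves the output unchanged (scale invariance).
#'
#' @param table `data.frame` with columns `group` (`"WT"`/`"TG"`),
#'   `band`, `total` and optionally `blot` (single blot assumed when
#'   absent); densities must be positive. Each blot needs >= 2 WT lanes
#'   (the reference mean) and >= 1 TG lane.
#' @return The input with an added `rel_density` column.
#' @export
normalize_blot <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("group", "band", "total") %in% names(table)))
  if (!"blot" %in% names(table)) table$blot <- "blot1"
  if (any(!is.finite(table$total) | table$total <= 0))
    stopf("lane total-protein densities must be positive")
  if (any(!is.finite(table$band) | table$band <= 0))
    stopf("band densities must be positive")
  if (!all(table$group %in% c("WT", "TG")))
    stopf("'group' must be 'WT' or 'TG'")
  table$rel_density <- NA_real_
  for (b in unique(table$blot)) {
    idx <- table$blot == b
    if (sum(idx & table$group == "WT") < 2L ||
        sum(idx & table$group == "TG") < 1L)
      stopf("blot '%s' needs >= 2 WT lanes and >= 1 TG lane", b)
    ratio <- table$band[idx] / table$total[idx]
    wt_mean <- mean(ratio[table$group[idx] == "WT"])
    table$rel_density[idx] <- ratio / wt_mean
  }
  table
}

#' Two-tailed p-value from a t statistic
#'
#' `p = 2 * P(T >= |t|)` under the central t distribution; symmetric
#' in the sign of `t` and monotone decreasing in `|t|`.
#'
#' @param t t statistic(s).
#' @param df degrees of freedom (>= 1).
#' @return Two-tailed p-value(s) in (0, 1].
#' @export
p_from_t <- function(t, df) {
  if (any(!is.finite(t))) stopf("'t' must be finite")
  if (any(df < 1)) stopf("'df' must be >= 1")
  2 * stats::pt(abs(t), df, lower.tail = FALSE)
}

#' Format a p-value in figure-legend style
#'
#' Round half-up to 4 decimals; values below 0.0001 print as
#' `"< 0.0001"`.
#'
#' @param p p-value(s).
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 1e-4, "< 0.0001",
         sprintf("%.4f", round_half_up(p, 4)))
}

#' Unpaired two-tailed Student's t test
#'
#' Pooled-variance two-sample test (`df = n1 + n2 - 2`; the integer
#' degrees of freedom printed in validation figure legends identify the
#' pooled rather than the Welch form). Reports the statistic, the 95%
#' confidence interval of the mean difference, and the effect as
#' `mean(a) - mean(b)` with its pooled standard error; `sign(t)` always
#' equals the sign of the effect. Two degenerate inputs are handled
#' without error: both groups constant and equal gives `t = 0, p = 1`;
#' both constant but unequal gives a floored `p` with `degenerate` set.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return A list of class `bonlac_ttest`: `t`, `df`, `p`, `p_label`,
#'   `ci_low`, `ci_high`, `effect`, `effect_se`, `degenerate`.
#' @export
unpaired_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stopf("each group needs >= 2 values")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stopf("groups must be finite")
  n1 <- length(a); n2 <- length(b)
  df <- n1 + n2 - 2L
  effect <- mean(a) - mean(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  degenerate <- FALSE
  if (se == 0) {
    if (effect == 0) {
      t <- 0; p <- 1
    } else {
      # both groups constant, unequal: evidence is unbounded
      t <- sign(effect) * Inf; p <- .Machine$double.xmin
      degenerate <- TRUE
    }
    ci <- c(effect, effect)
  } else {
    t <- effect / se
    p <- p_from_t(t, df)
    q <- stats::qt(0.975, df)
    ci <- effect + c(-1, 1) * q * se
  }
  structure(list(t = t, df = df, p = p, p_label = format_p(p),
                 ci_low = ci[1], ci_high = ci[2],
                 effect = effect, effect_se = se,
                 degenerate = degenerate),
            class = "bonlac_ttest")
}

#' @export
print.bonlac_ttest <- function(x, ...) {
  cat(sprintf(
    "unpaired two-tailed t test: t = %.4g, df = %d, p = %s\n",
    x$t, x$df, x$p_label))
  cat(sprintf("  effect = %.4g +/- %.4g, 95%% CI [%.4g, %.4g]\n",
              x$effect, x$effect_se, x$ci_low, x$ci_high))
  if (x$degenerate) cat("  (degenerate: both groups constant)\n")
  invisible(x)
}

#' Ordinary least-squares regression of paired fold changes
#'
#' Simple linear regression (e.g. de novo synthesis fold change against
#' total-protein fold change of the validated candidates), reporting
#' slope, intercept, r-squared and the two-tailed p of the slope t test
#' on n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors, >= 3 points.
#' @return A list of class `bonlac_regression`: `slope`, `intercept`,
#'   `r_squared`, `p`, `n`.
#' @export
linear_regression <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stopf("'x' and 'y' must be paired")
  if (length(x) < 3L) stopf("need >= 3 paired points")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stopf("inputs must be finite")
  if (stats::var(x) == 0) stopf("'x' has zero variance")
  fit <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  slope <- unname(stats::coef(fit)[2])
  p <- unname(s$coefficients[2, 4])
  if (!is.finite(p)) p <- 0    # exact fit: zero residual variance
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 p = p, n = length(x)),
            class = "bonlac_regression")
}

#' @export
print.bonlac_regression <- function(x, ...) {
  cat(sprintf(
    "OLS: y = %.4g x + %.4g, r^2 = %.3f, p = %s (n = %d)\n",
    x$slope, x$intercept, x$r_squared, format_p(x$p), x$n))
  invisible(x)
}
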