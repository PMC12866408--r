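## Group-level statistics: genotype effect sizes, one-tailed two-sample
## power / sample-size planning, metric agreement correlations, Welch
## comparisons, and the four-parameter logistic mass-dose curve.

#' Two-group effect size (Cohen's d) and percent difference
#'
#' d = (mean2 - mean1) / SD_pooled with the pooled SD
#' sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)); the percent difference
#' is expressed relative to the reference (first) group mean, so a doubling
#' reads as +100\%.
#'
#' @param ref reference-group values (e.g. wild-type).
#' @param alt comparison-group values (e.g. heterozygous).
#' @return list of class \code{EffectSizeResult}: \code{mean_ref},
#'   \code{mean_alt}, \code{sd_pooled}, \code{d}, \code{percent_diff}.
#' @examples
#' effectSize(c(2, 2.2, 1.8), c(4, 4.1, 3.9))
#' @export
effectSize <- function(ref, alt) {
  n1 <- length(ref); n2 <- length(alt)
  if (n1 < 2 || n2 < 2) stop("need at least 2 values per group")
  s2p <- ((n1 - 1) * var(ref) + (n2 - 1) * var(alt)) / (n1 + n2 - 2)
  m1 <- mean(ref); m2 <- mean(alt)
  d <- if (s2p <= 0) {
    warning("undefined d: pooled SD is zero")
    NA_real_
  } else (m2 - m1) / sqrt(s2p)
  structure(list(mean_ref = m1, mean_alt = m2, sd_pooled = sqrt(s2p),
                 d = d,
                 percent_diff = if (m1 != 0) 100 * (m2 - m1) / m1 else NA_real_),
            class = "EffectSizeResult")
}

#' @export
print.EffectSizeResult <- function(x, ...) {
  cat(sprintf("Effect size: d = %.3f (means %.4g vs %.4g, pooled SD %.4g, %+.1f%%)\n",
              x$d, x$mean_ref, x$mean_alt, x$sd_pooled, x$percent_diff))
  invisible(x)
}

#' Power of a two-sample t-test at a given per-group n
#'
#' Exact noncentral-t power for equal group sizes: df = 2n - 2,
#' noncentrality delta = d sqrt(n / 2).
#'
#' @param d standardized effect size (> 0).
#' @param n per-group sample size (>= 2).
#' @param alpha significance level.
#' @param tails 1 (default) or 2.
#' @return power in (0, 1).
#' @export
powerTwoSampleT <- function(d, n, alpha = 0.05, tails = 1) {
  stopifnot(d > 0, n >= 2, alpha > 0, alpha < 1, tails %in% c(1, 2))
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  crit <- qt(1 - alpha / tails, df)
  1 - pt(crit, df, ncp = ncp)
}

#' Minimal per-group sample size for a one-tailed two-sample t-test
#'
#' Smallest integer n >= 2 whose exact noncentral-t power reaches the target
#' at level alpha.
#'
#' @param d standardized effect size (> 0).
#' @param alpha significance level (default 0.05).
#' @param power target power (default 0.80).
#' @param tails 1 (default) or 2.
#' @return integer n per group; attribute \code{achieved_power} carries the
#'   exact power at that n.
#' @examples
#' sampleSizeTwoSampleT(d = 1.0)  # 13 per group, one-tailed
#' @export
sampleSizeTwoSampleT <- function(d, alpha = 0.05, power = 0.80, tails = 1) {
  stopifnot(d > 0, power > 0, power < 1)
  n <- 2L
  while (powerTwoSampleT(d, n, alpha, tails) < power) {
    n <- n + 1L
    if (n > 1e6) stop("sample size exceeds 1e6; check the effect size")
  }
  structure(n, achieved_power = powerTwoSampleT(d, n, alpha, tails))
}

#' Effect size implied by a relative group difference
#'
#' Converts an anticipated relative difference (e.g. 0.2 for a 20\% change
#' from the reference mean) into Cohen's d:
#' d = (relDiff x meanRef) / sdPooled.
#'
#' @param meanRef reference group mean (> 0).
#' @param relDiff relative difference as a fraction.
#' @param sdPooled pooled SD (> 0).
#' @return Cohen's d.
#' @export
dForRelativeDifference <- function(meanRef, relDiff, sdPooled) {
  stopifnot(meanRef > 0, sdPooled > 0)
  (relDiff * meanRef) / sdPooled
}

#' Sample-size planning table over a set of effect sizes
#'
#' @param d numeric vector of effect sizes.
#' @param alpha,power,tails as in [sampleSizeTwoSampleT()].
#' @return data.frame: d, n_per_group, achieved_power.
#' @export
powerTable <- function(d, alpha = 0.05, power = 0.80, tails = 1) {
  rows <- lapply(d, function(di) {
    n <- sampleSizeTwoSampleT(di, alpha, power, tails)
    data.frame(d = di, n_per_group = as.integer(n),
               achieved_power = attr(n, "achieved_power"))
  })
  do.call(rbind, rows)
}

#' Pearson or Spearman correlation with r^2 and p-value
#'
#' @param x,y paired numeric vectors (>= 3 complete pairs).
#' @param method "pearson" or "spearman".
#' @return list: \code{r}, \code{r2}, \code{p} (two-sided), \code{method},
#'   \code{n}.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired finite values")
  if (sd(x) == 0 || sd(y) == 0) stop("undefined correlation: zero variance")
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value, method = method, n = length(x))
}

#' Per-region Welch comparisons with Bonferroni scaling
#'
#' Convenience two-group comparison applied region-wise: Welch's t-test per
#' region with Bonferroni-adjusted p-values across regions, plus Cohen's d
#' and percent difference.
#'
#' @param df data.frame with columns region, genotype, value.
#' @param ref reference genotype label (default "WT").
#' @return data.frame with one row per region.
#' @export
welchByRegion <- function(df, ref = "WT") {
  stopifnot(all(c("region", "genotype", "value") %in% names(df)))
  regions <- unique(df$region)
  rows <- lapply(regions, function(rg) {
    sub <- df[df$region == rg, ]
    a <- sub$value[sub$genotype == ref]
    b <- sub$value[sub$genotype != ref]
    tt <- stats::t.test(b, a)
    es <- effectSize(a, b)
    data.frame(region = rg, mean_ref = es$mean_ref, mean_alt = es$mean_alt,
               percent_diff = es$percent_diff, d = es$d,
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * length(regions), 1)
  out
}

#' Four-parameter logistic fit of V_T against log10 injected mass
#'
#' f(x) = a + (d - a) / (1 + 10^(b (x - c))) on x = log10(mass): the upper
#' asymptote d holds at tracer (low-mass) doses and the curve falls toward
#' the lower asymptote a as injected mass rises (self-blocking), with
#' inflection c (log10 mass units) and slope b > 0 for a declining curve.
#'
#' @param logMass log10 injected mass values (>= 5 points spanning the
#'   transition).
#' @param vt corresponding V_T values.
#' @return list of class \code{FourPLModel}: \code{a}, \code{b}, \code{c},
#'   \code{d}, \code{rss}.
#' @export
fit4pl <- function(logMass, vt) {
  stopifnot(length(logMass) == length(vt))
  if (length(vt) < 5) stop("need at least 5 points for the 4PL fit")
  rng <- diff(range(vt))
  if (rng < 1e-10 * max(abs(vt), 1))
    stop("degenerate flat data: asymptotes collapse (a = d)")
  residFun <- function(p)
    p[1] + (p[4] - p[1]) / (1 + 10^(p[2] * (logMass - p[3]))) - vt
  starts <- list(
    c(min(vt), 1, stats::median(logMass), max(vt)),
    c(min(vt), 2, mean(range(logMass)), max(vt)),
    c(min(vt) - 0.1 * rng, 0.5, stats::median(logMass), max(vt) + 0.1 * rng))
  best <- NULL
  for (p0 in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = p0, fn = residFun,
      lower = c(-Inf, 1e-3, min(logMass) - 5, -Inf),
      upper = c(Inf, 50, max(logMass) + 5, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("4PL fit failed to converge")
  p <- best$par
  structure(list(a = p[1], b = p[2], c = p[3], d = p[4],
                 rss = best$deviance),
            class = "FourPLModel")
}

#' @export
predict.FourPLModel <- function(object, logMass, ...) {
  object$a + (object$d - object$a) /
    (1 + 10^(object$b * (logMass - object$c)))
}

#' @export
print.FourPLModel <- function(x, ...) {
  cat(sprintf("FourPLModel: lower %.4g, upper %.4g, inflection 10^%.4g, slope %.4g (RSS %.3g)\n",
              x$a, x$d, x$c, x$b, x$rss))
  invisible(x)
}

#' Injected mass producing a fractional drop from the tracer-dose plateau
#'
#' Solves f(x) = d - q (d - a) for the mass (not log mass) at which V_T has
#' fallen by the fraction \code{q} of the full asymptote span; q = 0.5 gives
#' the inflection mass 10^c.
#'
#' @param model a \code{FourPLModel}.
#' @param q fractional drop in (0, 1).
#' @return mass in the original (linear) units, or \code{NA} with a warning
#'   when the asymptotes are too close to define a drop.
#' @export
massAtDrop <- function(model, q) {
  stopifnot(q > 0, q < 1)
  if (abs(model$d - model$a) < 1e-10 * max(abs(model$d), 1)) {
    warning("no solution: asymptotes coincide (flat curve)")
    return(NA_real_)
  }
  10^(model$c + log10(q / (1 - q)) / model$b)
}
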