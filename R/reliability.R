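## Test-retest battery: rTRV, aTRV, Bland-Altman limits of agreement, and
## variance-component ICC.
##
##   rTRV = 100 (test - retest) / mean(test, retest)
##   aTRV = |rTRV|
##   ICC  = animal variance component / sum of positive variance components

#' Relative and absolute test-retest variability
#'
#' rTRV = 100 (test - retest) / mean(test, retest); aTRV is its absolute
#' value. Vectorized over pairs.
#'
#' @param test,retest paired metric values.
#' @return percent values, sign-preserving for \code{rtrv}.
#' @examples
#' rtrv(2.2, 1.8)  # 20
#' atrv(1.8, 2.2)  # 20
#' @export
rtrv <- function(test, retest) {
  m <- (test + retest) / 2
  if (any(m == 0)) stop("undefined metric: zero test-retest mean")
  100 * (test - retest) / m
}

#' @rdname rtrv
#' @export
atrv <- function(test, retest) abs(rtrv(test, retest))

## reshape a long cohort into one row per animal with test/retest columns
pairCohort <- function(cohort, region = NULL, metric = NULL) {
  need <- c("animal", "session", "value")
  if (!all(need %in% names(cohort)))
    stop("cohort must contain columns: ", paste(need, collapse = ", "))
  if (!is.null(region) && "region" %in% names(cohort))
    cohort <- cohort[cohort$region == region, , drop = FALSE]
  if (!is.null(metric) && "metric" %in% names(cohort))
    cohort <- cohort[cohort$metric == metric, , drop = FALSE]
  te <- cohort[cohort$session == "test", c("animal", "value")]
  re <- cohort[cohort$session == "retest", c("animal", "value")]
  m <- merge(te, re, by = "animal", suffixes = c("_test", "_retest"))
  if (anyDuplicated(m$animal))
    stop("multiple test or retest records for one animal")
  gcol <- if ("genotype" %in% names(cohort))
    unique(cohort[, c("animal", "genotype")]) else NULL
  if (!is.null(gcol)) m <- merge(m, gcol, by = "animal")
  m
}

#' Bland-Altman agreement between test and retest sessions
#'
#' Per-animal differences are the rTRV percentages; bias is their mean and
#' the limits of agreement are bias +/- 1.96 SD (sample SD, n - 1
#' denominator).
#'
#' @param cohort long-format data.frame with columns animal, session
#'   ("test"/"retest"), value, and optionally region / metric.
#' @param region,metric optional filters.
#' @return list of class \code{BlandAltmanResult}: \code{bias}, \code{sd},
#'   \code{limits} (percent), \code{differences}, \code{n}.
#' @export
blandAltman <- function(cohort, region = NULL, metric = NULL) {
  m <- pairCohort(cohort, region, metric)
  if (nrow(m) < 2) stop("insufficient data: need at least 2 complete pairs")
  d <- rtrv(m$value_test, m$value_retest)
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, sd = s,
                 limits = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
                 differences = setNames(d, m$animal), n = nrow(m)),
            class = "BlandAltmanResult")
}

#' @export
print.BlandAltmanResult <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f%%, limits [%.2f%%, %.2f%%]\n",
              x$n, x$bias, x$limits[1], x$limits[2]))
  invisible(x)
}

#' Variance-component ICC by REML
#'
#' Fits value ~ genotype * session (fixed) + (1 | animal) + residual by
#' restricted maximum likelihood and reports
#' ICC = sigma^2_animal / (sum of positive variance components). With
#' \code{extraRandomTerms = TRUE}, animal x genotype and animal x session
#' random terms are added (they typically estimate to zero on balanced
#' two-session data and do not change the ICC).
#'
#' Cohorts without a genotype column, or with a single genotype, are fitted
#' without the corresponding fixed effects.
#'
#' @param cohort long-format data.frame (see [blandAltman()]).
#' @param region,metric optional filters.
#' @param extraRandomTerms logical; add the interaction random terms.
#' @param includeFixed logical; set \code{FALSE} to fit an intercept-only
#'   fixed part (the structure under which the REML components coincide with
#'   the one-way ANOVA method-of-moments estimator on balanced data).
#' @return list of class \code{IccResult}: \code{icc}, \code{components}
#'   (named variance components), \code{fixef}, \code{fit} (the lme4 fit).
#' @export
iccReml <- function(cohort, region = NULL, metric = NULL,
                    extraRandomTerms = FALSE, includeFixed = TRUE) {
  if (!is.null(region) && "region" %in% names(cohort))
    cohort <- cohort[cohort$region == region, , drop = FALSE]
  if (!is.null(metric) && "metric" %in% names(cohort))
    cohort <- cohort[cohort$metric == metric, , drop = FALSE]
  if (length(unique(cohort$animal)) < 4)
    stop("need at least 4 animals for the variance-component fit")
  tab <- table(cohort$animal, cohort$session)
  balanced <- all(tab == 1)
  if (!balanced)
    warning("unbalanced test/retest design; fitting available cases")

  hasGeno <- "genotype" %in% names(cohort) &&
    length(unique(cohort$genotype)) > 1
  fixed <- if (!includeFixed) "1"
           else if (hasGeno) "genotype * session" else "session"
  rand <- "(1 | animal)"
  if (extraRandomTerms) {
    if (hasGeno) rand <- paste(rand, "+ (1 | animal:genotype)")
    rand <- paste(rand, "+ (1 | animal:session)")
  }
  form <- stats::as.formula(paste("value ~", fixed, "+", rand))
  ## modular lme4 fit with a coordinate-wise Newton polish of theta on the
  ## REML deviance: derivative-free optimizers stop ~1e-7 short of the
  ## optimum, which matters when comparing against closed-form estimators
  lmod <- lme4::lFormula(form, data = cohort, REML = TRUE,
                         control = lme4::lmerControl(
                           check.conv.singular = "ignore"))
  devf <- do.call(lme4::mkLmerDevfun, lmod)
  opt <- lme4::optimizeLmer(devf)
  th <- opt$par
  lb <- lmod$reTrms$lower
  for (sweep in 1:2) {
    for (j in seq_along(th)) {
      h <- 1e-4 * max(1, abs(th[j]))
      thp <- th; thp[j] <- th[j] + h
      thm <- th; thm[j] <- max(th[j] - h, lb[j])
      fp <- devf(thp); fm <- devf(thm); f0 <- devf(th)
      hess <- (fp - 2 * f0 + fm) / h^2
      grad <- (fp - fm) / (2 * h)
      if (is.finite(hess) && hess > 0) {
        cand <- th
        cand[j] <- max(th[j] - grad / hess, lb[j])
        if (devf(cand) <= f0) th <- cand
      }
    }
  }
  opt$par <- th
  opt$fval <- devf(th)
  fit <- lme4::mkMerMod(environment(devf), opt, lmod$reTrms, fr = lmod$fr)
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual", vc$grp))
  animal <- sum(comp[names(comp) == "animal"])
  pos <- comp[comp > 0]
  icc <- if (length(pos) == 0 || animal <= 0) 0 else animal / sum(pos)
  structure(list(icc = icc, components = comp,
                 fixef = lme4::fixef(fit), fit = fit),
            class = "IccResult")
}

#' @export
print.IccResult <- function(x, ...) {
  cat(sprintf("ICC = %.4f\n  variance components: %s\n", x$icc,
              paste(sprintf("%s = %.4g", names(x$components), x$components),
                    collapse = ", ")))
  invisible(x)
}

#' Closed-form one-way ANOVA ICC (method of moments)
#'
#' Independent estimator used to cross-check the REML fit on balanced
#' two-session data with no fixed-effect structure: with k sessions per
#' animal, sigma^2_between = (MSB - MSW) / k (truncated at 0),
#' sigma^2_within = MSW, ICC = between / (between + within).
#'
#' @param cohort long-format data.frame with animal, session, value.
#' @param region,metric optional filters.
#' @return list: \code{icc}, \code{sigma2_between}, \code{sigma2_within}.
#' @export
iccAnova <- function(cohort, region = NULL, metric = NULL) {
  if (!is.null(region) && "region" %in% names(cohort))
    cohort <- cohort[cohort$region == region, , drop = FALSE]
  if (!is.null(metric) && "metric" %in% names(cohort))
    cohort <- cohort[cohort$metric == metric, , drop = FALSE]
  v <- split(cohort$value, cohort$animal)
  k <- unique(lengths(v))
  if (length(k) != 1) stop("unbalanced design: unequal sessions per animal")
  n <- length(v)
  means <- vapply(v, mean, 0)
  grand <- mean(unlist(v))
  msb <- k * sum((means - grand)^2) / (n - 1)
  msw <- sum(vapply(v, function(x) sum((x - mean(x))^2), 0)) / (n * (k - 1))
  s2b <- max((msb - msw) / k, 0)
  list(icc = if (s2b + msw > 0) s2b / (s2b + msw) else 0,
       sigma2_between = s2b, sigma2_within = msw)
}

#' Test-retest summary report by region and metric
#'
#' For every (region, metric) combination: rTRV and aTRV mean +/- SD per
#' genotype, plus the pooled-genotype ICC — the shape of a radioligand
#' test-retest reliability table.
#'
#' @param cohort long-format cohort with genotype, region and metric columns.
#' @param extraRandomTerms passed to [iccReml()].
#' @return data.frame with one row per region x metric.
#' @export
trtReport <- function(cohort, extraRandomTerms = FALSE) {
  combos <- unique(cohort[, c("region", "metric")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    rg <- combos$region[i]; mt <- combos$metric[i]
    m <- pairCohort(cohort, rg, mt)
    d <- rtrv(m$value_test, m$value_retest)
    out <- data.frame(region = rg, metric = mt)
    for (g in unique(m$genotype)) {
      dg <- d[m$genotype == g]
      out[[paste0("rTRV_mean_", g)]] <- mean(dg)
      out[[paste0("rTRV_sd_", g)]] <- sd(dg)
      out[[paste0("aTRV_mean_", g)]] <- mean(abs(dg))
      out[[paste0("aTRV_sd_", g)]] <- sd(abs(dg))
    }
    out$ICC <- iccReml(cohort, rg, mt,
                       extraRandomTerms = extraRandomTerms)$icc
    out
  })
  do.call(rbind, rows)
}
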