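#' Cohen's kappa with optional disagreement weights
#'
#' Chance-corrected agreement for a square confusion table of ordered
#' categories. With disagreement weights \eqn{w_{ij}} (zero on the diagonal)
#' the statistic is
#' \deqn{\kappa_w = 1 - \frac{\sum_{ij} w_{ij} O_{ij}}{\sum_{ij} w_{ij} E_{ij}}}
#' where \eqn{O} are observed counts and \eqn{E} the expected counts under
#' independence of the two raters. \code{"unweighted"} uses
#' \eqn{w_{ij} = 1[i \neq j]} and reduces to Cohen's kappa; \code{"linear"}
#' uses \eqn{|i-j|/(K-1)}; \code{"quadratic"} uses \eqn{((i-j)/(K-1))^2}.
#'
#' @param table square numeric matrix of nonnegative counts, rows and columns
#'   indexed by the same ordered categories.
#' @param weighting one of \code{"linear"}, \code{"quadratic"},
#'   \code{"unweighted"}.
#' @return Kappa in [-Inf, 1], or \code{NA} (with a warning) when the
#'   expected disagreement is zero (both raters confined to one category), in
#'   which case the statistic is undefined.
#' @export
weighted_kappa <- function(table, weighting = c("linear", "quadratic",
                                                "unweighted")) {
  weighting <- match.arg(weighting)
  table <- as.matrix(table)
  if (nrow(table) != ncol(table)) {
    stop("confusion table must be square", call. = FALSE)
  }
  if (any(table < 0) || sum(table) <= 0) {
    stop("confusion table needs nonnegative counts, at least one positive",
         call. = FALSE)
  }
  k <- nrow(table)
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  w <- switch(weighting,
              unweighted = (d > 0) + 0,
              linear = if (k > 1) d / (k - 1) else d,
              quadratic = if (k > 1) (d / (k - 1))^2 else d)
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  denom <- sum(w * expected)
  if (denom == 0) {
    warning("expected disagreement is zero; kappa undefined")
    return(NA_real_)
  }
  1 - sum(w * table) / denom
}

#' Inter-source agreement report for paired integer measurements
#'
#' Cross-tabulates two paired integer series (e.g., tone counts for the same
#' languages from two databases) over the union of observed values, ordered
#' numerically, and reports unweighted and weighted kappa, Pearson
#' correlation, and the exact-match proportion.
#'
#' @param x,y paired integer vectors of equal length (>= 3).
#' @param weighting weight scheme for the weighted kappa (default linear).
#' @return Object of class \code{agreement_report} with elements
#'   \code{kappa}, \code{weighted_kappa}, \code{pearson_r},
#'   \code{percent_agreement}, \code{n}, \code{table}.
#' @export
agreement_report <- function(x, y, weighting = "linear") {
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have equal length", call. = FALSE)
  }
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  levels <- sort(unique(c(x, y)))
  tab <- table(factor(x, levels = levels), factor(y, levels = levels))
  r <- if (sd(x) > 0 && sd(y) > 0) cor(x, y) else NA_real_
  structure(list(
    kappa = suppressWarnings(weighted_kappa(tab, "unweighted")),
    weighted_kappa = suppressWarnings(weighted_kappa(tab, weighting)),
    pearson_r = r,
    percent_agreement = mean(x == y),
    n = length(x),
    table = tab
  ), class = "agreement_report")
}

#' @method print agreement_report
#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "Agreement over %d paired measurements\n  kappa %.3f, weighted kappa %.3f, r %.3f, exact agreement %.1f%%\n",
    x$n, x$kappa, x$weighted_kappa, x$pearson_r, 100 * x$percent_agreement))
  invisible(x)
}

#' Grouped bias test for between-source measurement differences
#'
#' Tests whether per-language differences between two measurements of the
#' same variable are systematically structured by language family, geographic
#' area, or a covariate (typically humidity). If the differences are pure
#' unbiased noise, family and area random intercepts should explain no
#' variance and the covariate should not improve model fit.
#'
#' Variance components are tested by likelihood-ratio comparison of the
#' two-intercept mixed model against the model without the tested intercept;
#' because the null value (variance zero) lies on the boundary of the
#' parameter space, the reference distribution is the half-half mixture
#' \eqn{\frac{1}{2}\chi^2_0 + \frac{1}{2}\chi^2_1} (the chi-square p-value is
#' halved, and a zero statistic gives p = 1). The covariate is tested by an
#' ordinary 1-df likelihood-ratio test of adding it as a fixed effect. All
#' models are fit by maximum likelihood.
#'
#' @param differences numeric vector of measurement differences.
#' @param family,area grouping labels (>= 2 levels each).
#' @param covariate optional numeric covariate (same length).
#' @return Object of class \code{bias_report}: p-values \code{p_family},
#'   \code{p_area}, \code{p_covariate} (NA if no covariate given), and
#'   \code{direction}, the sign of the mean difference.
#' @export
bias_test <- function(differences, family, area, covariate = NULL) {
  n <- length(differences)
  if (length(family) != n || length(area) != n) {
    stop("grouping vectors must match 'differences' in length", call. = FALSE)
  }
  if (length(unique(family)) < 2 || length(unique(area)) < 2) {
    stop("'family' and 'area' each need at least 2 levels", call. = FALSE)
  }
  direction <- sign(mean(differences))
  if (sd(differences) == 0) {
    return(structure(list(p_family = 1, p_area = 1,
                          p_covariate = if (is.null(covariate)) NA_real_ else 1,
                          direction = direction),
                     class = "bias_report"))
  }
  dat <- data.frame(d = differences, family = factor(family),
                    area = factor(area))
  fit <- function(fml) {
    suppressWarnings(suppressMessages(
      lme4::lmer(fml, data = dat, REML = FALSE)))
  }
  full <- fit(d ~ 1 + (1 | family) + (1 | area))
  no_fam <- fit(d ~ 1 + (1 | area))
  no_area <- fit(d ~ 1 + (1 | family))

  boundary_p <- function(full, reduced) {
    stat <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(reduced))))
    if (stat <= 0) 1 else 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  }
  p_family <- boundary_p(full, no_fam)
  p_area <- boundary_p(full, no_area)

  p_covariate <- NA_real_
  if (!is.null(covariate)) {
    if (length(covariate) != n) {
      stop("'covariate' must match 'differences' in length", call. = FALSE)
    }
    if (sd(covariate) == 0) {
      p_covariate <- 1
    } else {
      dat$cv <- zscore(covariate)
      with_cov <- fit(d ~ 1 + cv + (1 | family) + (1 | area))
      stat <- max(0, 2 * (as.numeric(logLik(with_cov)) -
                            as.numeric(logLik(full))))
      p_covariate <- pchisq(stat, df = 1, lower.tail = FALSE)
    }
  }
  structure(list(p_family = p_family, p_area = p_area,
                 p_covariate = p_covariate, direction = direction),
            class = "bias_report")
}

#' @method print bias_report
#' @export
print.bias_report <- function(x, ...) {
  cat("Grouped bias test on measurement differences\n")
  cat(sprintf("  family variance p = %.3g, area variance p = %.3g\n",
              x$p_family, x$p_area))
  if (!is.na(x$p_covariate)) {
    cat(sprintf("  covariate p = %.3g\n", x$p_covariate))
  }
  cat(sprintf("  mean difference direction: %+d\n", as.integer(x$direction)))
  invisible(x)
}
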