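#' Declare a (generalized) mixed-model specification
#'
#' A small declarative layer over \pkg{lme4} formulas used by the robustness
#' sweeps, so that model structures can be enumerated, compared and ablated
#' programmatically.
#'
#' @param response response column name; for \code{"binomial-logit"} a
#'   length-2 character vector (successes, failures) is also accepted.
#' @param family one of \code{"poisson-log"}, \code{"gaussian-identity"},
#'   \code{"binomial-logit"}.
#' @param fixed character vector of fixed-effect terms; interactions may be
#'   written \code{"a:b"}.
#' @param random list of random terms, each a list with elements
#'   \code{group} (grouping factor column), \code{intercept} (logical) and
#'   \code{slope} (covariate column or \code{NULL}). A slope term always
#'   names its grouping factor by construction. An empty list yields a plain
#'   GLM.
#' @return Object of class \code{model_spec}.
#' @export
model_spec <- function(response,
                       family = c("poisson-log", "gaussian-identity",
                                  "binomial-logit"),
                       fixed = character(),
                       random = list()) {
  family <- match.arg(family)
  if (anyDuplicated(fixed)) stop("duplicate fixed terms", call. = FALSE)
  for (r in random) {
    if (is.null(r$group)) stop("every random term needs a group", call. = FALSE)
    if (!isTRUE(r$intercept) && is.null(r$slope)) {
      stop("a random term needs an intercept, a slope, or both", call. = FALSE)
    }
  }
  keys <- vapply(random, function(r) {
    paste(r$group, isTRUE(r$intercept), r$slope %||% "", sep = "|")
  }, character(1))
  if (anyDuplicated(keys)) stop("duplicate random terms", call. = FALSE)
  structure(list(response = response, family = family,
                 fixed = fixed, random = random),
            class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

spec_formula <- function(spec, drop = character()) {
  fixed <- setdiff(spec$fixed, drop)
  lhs <- if (length(spec$response) == 2L) {
    sprintf("cbind(%s, %s)", spec$response[1], spec$response[2])
  } else spec$response
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  rand <- vapply(spec$random, function(r) {
    inner <- if (isTRUE(r$intercept)) {
      if (is.null(r$slope)) "1" else paste("1 +", r$slope)
    } else paste("0 +", r$slope)
    sprintf("(%s | %s)", inner, r$group)
  }, character(1))
  as.formula(paste(lhs, "~", paste(c(rhs, rand), collapse = " + ")))
}

spec_vars <- function(spec) {
  fixed_vars <- unique(unlist(strsplit(spec$fixed, "[:*]")))
  slope_vars <- unlist(lapply(spec$random, `[[`, "slope"))
  unique(c(fixed_vars, slope_vars))
}

#' Fit a mixed (or plain) regression model from a specification
#'
#' Dispatches to \code{lme4::glmer} / \code{lme4::lmer} (Laplace-approximated
#' maximum likelihood; linear models are fit by ML, not REML, so that nested
#' fits are comparable by likelihood ratio) or to \code{stats::glm} when the
#' specification has no random terms. Numeric predictors are z-scored before
#' entering the model (interactions are formed after scaling), so coefficient
#' magnitudes are comparable across models and datasets; set
#' \code{scale_predictors = FALSE} to opt out.
#'
#' Constant predictor columns cannot be standardized or estimated; terms
#' involving them are dropped from the fit and recorded in the
#' \code{degenerate} field rather than crashing.
#'
#' @param data data frame.
#' @param spec a [model_spec()].
#' @param scale_predictors z-score numeric predictors first (default TRUE).
#' @param optimizer optional \pkg{lme4} optimizer name.
#' @param start optional start values passed to \pkg{lme4}.
#' @return Object of class \code{model_fit}: \code{coefficients} (term,
#'   estimate, se, z, p), \code{logLik}, \code{npar}, \code{converged},
#'   \code{singular}, \code{varcorr}, \code{degenerate}, \code{n},
#'   \code{spec}, and the underlying \code{fit}.
#' @export
fit_mixed <- function(data, spec, scale_predictors = TRUE,
                      optimizer = NULL, start = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  resp_cols <- spec$response
  missing <- setdiff(c(resp_cols, spec_vars(spec),
                       vapply(spec$random, `[[`, character(1), "group")),
                     names(data))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (r in spec$random) {
    if (length(unique(data[[r$group]])) < 2) {
      stop(sprintf("grouping factor '%s' needs >= 2 levels", r$group),
           call. = FALSE)
    }
  }

  dat <- data
  degenerate <- character()
  if (scale_predictors) {
    for (v in spec_vars(spec)) {
      if (is.numeric(dat[[v]]) && !(v %in% resp_cols)) {
        z <- zscore(dat[[v]])
        if (is_degenerate(z)) degenerate <- c(degenerate, v) else dat[[v]] <- z
      }
    }
  } else {
    for (v in spec_vars(spec)) {
      if (is.numeric(dat[[v]]) && sd(dat[[v]]) == 0 && !(v %in% resp_cols)) {
        degenerate <- c(degenerate, v)
      }
    }
  }
  drop_terms <- spec$fixed[vapply(spec$fixed, function(tm) {
    any(strsplit(tm, "[:*]")[[1]] %in% degenerate)
  }, logical(1))]
  eff_spec <- spec
  eff_spec$random <- Filter(function(r) {
    !(!is.null(r$slope) && r$slope %in% degenerate)
  }, spec$random)
  fml <- spec_formula(eff_spec, drop = drop_terms)

  glm_family <- switch(spec$family,
                       "poisson-log" = stats::poisson(link = "log"),
                       "gaussian-identity" = stats::gaussian(),
                       "binomial-logit" = stats::binomial(link = "logit"))

  mixed <- length(eff_spec$random) > 0
  fit <- if (!mixed) {
    glm(fml, data = dat, family = glm_family)
  } else if (spec$family == "gaussian-identity") {
    ctrl <- if (is.null(optimizer)) lme4::lmerControl() else
      lme4::lmerControl(optimizer = optimizer)
    suppressWarnings(suppressMessages(
      lme4::lmer(fml, data = dat, REML = FALSE, control = ctrl,
                 start = start)))
  } else {
    ctrl <- if (is.null(optimizer)) lme4::glmerControl() else
      lme4::glmerControl(optimizer = optimizer)
    suppressWarnings(suppressMessages(
      lme4::glmer(fml, data = dat, family = glm_family, control = ctrl,
                  start = start)))
  }

  if (!mixed) {
    sm <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                        se = sm[, 2], z = sm[, 3],
                        p = 2 * pnorm(-abs(sm[, 3])),
                        row.names = NULL, stringsAsFactors = FALSE)
    converged <- isTRUE(fit$converged)
    singular <- FALSE
    vc <- NULL
  } else {
    sm <- summary(fit)$coefficients
    zcol <- sm[, 3]  # t value for lmer, z value for glmer; Wald z either way
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                        se = sm[, 2], z = zcol,
                        p = 2 * pnorm(-abs(zcol)),
                        row.names = NULL, stringsAsFactors = FALSE)
    msgs <- fit@optinfo$conv$lme4$messages %||% character()
    msgs <- msgs[!grepl("singular", unlist(msgs))]
    converged <- length(msgs) == 0 && fit@optinfo$conv$opt == 0
    singular <- lme4::isSingular(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
  }
  for (tm in drop_terms) {
    coefs <- rbind(coefs, data.frame(term = tm, estimate = NA_real_,
                                     se = NA_real_, z = NA_real_, p = NA_real_,
                                     stringsAsFactors = FALSE))
  }
  ll <- logLik(fit)
  structure(list(coefficients = coefs,
                 logLik = as.numeric(ll),
                 npar = attr(ll, "df"),
                 converged = converged,
                 singular = singular,
                 varcorr = vc,
                 degenerate = degenerate,
                 n = stats::nobs(fit),
                 family = spec$family,
                 spec = spec,
                 fit = fit),
            class = "model_fit")
}

#' @method print model_fit
#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Model fit (%s), n = %d, logLik = %.3f%s\n", x$family, x$n,
              x$logLik, if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$coefficients, digits = 3)
  if (length(x$degenerate)) {
    cat("  degenerate predictors dropped:",
        paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

coef_of <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stop(sprintf("term '%s' not in fit", term), call. = FALSE)
  fit$coefficients[i, ]
}

#' Likelihood-ratio test between nested model fits
#'
#' \eqn{\chi^2 = 2 (\ell_{full} - \ell_{null})} with degrees of freedom equal
#' to the difference in parameter count. The fits must be on the same data
#' (same response, family and number of observations) and the null's fixed
#' terms must be a subset of the full's.
#'
#' @param fit_null,fit_full [fit_mixed()] results.
#' @return List with \code{chi2}, \code{df}, \code{p},
#'   \code{loglik_difference}.
#' @export
lrt <- function(fit_null, fit_full) {
  stopifnot(inherits(fit_null, "model_fit"), inherits(fit_full, "model_fit"))
  if (!identical(fit_null$spec$response, fit_full$spec$response) ||
      !identical(fit_null$family, fit_full$family) ||
      fit_null$n != fit_full$n ||
      !all(fit_null$spec$fixed %in% fit_full$spec$fixed)) {
    stop("fits are not nested on identical data", call. = FALSE)
  }
  df <- fit_full$npar - fit_null$npar
  if (df < 0) stop("null model has more parameters than full", call. = FALSE)
  diff_ll <- fit_full$logLik - fit_null$logLik
  chi2 <- max(0, 2 * diff_ll)
  p <- if (df == 0) 1 else pchisq(chi2, df = df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p, loglik_difference = diff_ll)
}

ablation_structures <- function(family_col, area_col, humidity) {
  ri <- function(g) list(group = g, intercept = TRUE, slope = NULL)
  rs <- function(g) list(group = g, intercept = TRUE, slope = humidity)
  slope_only <- function(g) list(group = g, intercept = FALSE,
                                 slope = humidity)
  list(
    "Full model" = list(rs(family_col), rs(area_col)),
    "No family intercept" = list(slope_only(family_col), rs(area_col)),
    "No family slope" = list(ri(family_col), rs(area_col)),
    "No area intercept" = list(rs(family_col), slope_only(area_col)),
    "No area slope" = list(rs(family_col), ri(area_col))
  )
}

#' Random-effects ablation sweep for the humidity-tone model
#'
#' Fits the Poisson tone-count model under five random-effect structures —
#' the full model (family and area intercepts plus humidity slopes) and the
#' four single-term ablations — and reports the humidity coefficient under
#' each. Divergence between the full model and the area-ablated rows is the
#' signature of an areal (contact/borrowing) confound: the apparent humidity
#' effect is absorbed once areal structure is controlled.
#'
#' @param data data frame with \code{n_tones}, \code{humidity},
#'   \code{family_id}, \code{area_id} columns (names overridable).
#' @param response,humidity,family_col,area_col column names.
#' @return Object of class \code{ablation_table}: data frame with rows
#'   exactly \code{Full model}, \code{No family intercept},
#'   \code{No family slope}, \code{No area intercept}, \code{No area slope}
#'   and columns \code{model}, \code{estimate}, \code{se}, \code{z},
#'   \code{p}, \code{converged}. Fits are attached as attribute
#'   \code{"fits"}.
#' @export
ablation_sweep <- function(data, response = "n_tones", humidity = "humidity",
                           family_col = "family_id", area_col = "area_id") {
  structures <- ablation_structures(family_col, area_col, humidity)
  fits <- lapply(structures, function(rand) {
    fit_mixed(data, model_spec(response, "poisson-log",
                               fixed = humidity, random = rand))
  })
  rows <- lapply(names(fits), function(nm) {
    cc <- coef_of(fits[[nm]], humidity)
    data.frame(model = nm, estimate = cc$estimate, se = cc$se, z = cc$z,
               p = cc$p, converged = fits[[nm]]$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  class(out) <- c("ablation_table", "data.frame")
  out
}

#' Vowel-proportion and vowel-area mixed models
#'
#' Two linear mixed models on the vowel system. The \emph{ratio} model
#' predicts the proportion of vowels in the phoneme inventory,
#' \code{n_vowels / (n_vowels + n_consonants)}, from z-scored humidity,
#' z-scored inventory size and their interaction, with family and area random
#' intercepts; humidity and the interaction are each tested by a 1-df
#' likelihood-ratio test against the nested model without them. The
#' \emph{area} model (fit when a \code{hull_area} column is present) predicts
#' z-scored convex-hull vowel-space area from humidity and the number of
#' vowels, with the same random intercepts, and tests humidity by LRT.
#'
#' A constant humidity column is reported as degenerate (LRT slot carries
#' \code{degenerate = TRUE}) rather than raising an error.
#'
#' @param data data frame with \code{n_vowels}, \code{n_consonants},
#'   \code{humidity}, \code{family_id}, \code{area_id}, and optionally
#'   \code{hull_area}.
#' @return List with components \code{ratio} (fits \code{null},
#'   \code{humidity}, \code{interaction} plus \code{humidity_lrt},
#'   \code{interaction_lrt}) and \code{area} (or NULL).
#' @export
vowel_models <- function(data) {
  need <- c("n_vowels", "n_consonants", "humidity", "family_id", "area_id")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  dat <- data
  dat$vowel_prop <- dat$n_vowels / (dat$n_vowels + dat$n_consonants)
  dat$inventory_size <- dat$n_vowels + dat$n_consonants
  ri <- list(list(group = "family_id", intercept = TRUE, slope = NULL),
             list(group = "area_id", intercept = TRUE, slope = NULL))
  degenerate_h <- sd(dat$humidity) == 0

  m0 <- fit_mixed(dat, model_spec("vowel_prop", "gaussian-identity",
                                  fixed = "inventory_size", random = ri))
  if (degenerate_h) {
    ratio <- list(null = m0, humidity = NULL, interaction = NULL,
                  humidity_lrt = list(degenerate = TRUE),
                  interaction_lrt = list(degenerate = TRUE))
  } else {
    m1 <- fit_mixed(dat, model_spec("vowel_prop", "gaussian-identity",
                                    fixed = c("inventory_size", "humidity"),
                                    random = ri))
    m2 <- fit_mixed(dat, model_spec(
      "vowel_prop", "gaussian-identity",
      fixed = c("inventory_size", "humidity", "humidity:inventory_size"),
      random = ri))
    ratio <- list(null = m0, humidity = m1, interaction = m2,
                  humidity_lrt = lrt(m0, m1),
                  interaction_lrt = lrt(m1, m2))
  }

  area <- NULL
  if ("hull_area" %in% names(data)) {
    dat$hull_area_z <- zscore(dat$hull_area)
    if (!is_degenerate(dat$hull_area_z)) {
      a0 <- fit_mixed(dat, model_spec("hull_area_z", "gaussian-identity",
                                      fixed = "n_vowels", random = ri))
      if (degenerate_h) {
        area <- list(null = a0, humidity = NULL,
                     humidity_lrt = list(degenerate = TRUE))
      } else {
        a1 <- fit_mixed(dat, model_spec("hull_area_z", "gaussian-identity",
                                        fixed = c("n_vowels", "humidity"),
                                        random = ri))
        area <- list(null = a0, humidity = a1, humidity_lrt = lrt(a0, a1))
      }
    }
  }
  list(ratio = ratio, area = area)
}

glm_loglik <- function(beta, X, y, weights, family) {
  eta <- drop(X %*% beta)
  switch(family,
         "poisson-log" = sum(y * eta - exp(eta) - lgamma(y + 1)),
         "gaussian-identity" = -0.5 * sum((y - eta)^2),
         "binomial-logit" = {
           p <- plogis(eta)
           sum(weights * (y * log(p) + (1 - y) * log1p(-p)))
         })
}

#' Optimizer/start-point stability sweep
#'
#' Refits one model specification under every combination of optimizer and
#' random start point and summarizes how far the fixed-effect estimates move.
#' For mixed specifications the optimizers are \pkg{lme4} optimizer names and
#' starts perturb the random-effect Cholesky parameters; for specifications
#' without random terms, the (convex) GLM log-likelihood is maximized with
#' \code{stats::optim} under the requested methods from jittered starts.
#' Individual failures are recorded as failed rows; the sweep continues.
#'
#' @param data data frame.
#' @param spec a [model_spec()].
#' @param optimizers character vector (>= 2) of optimizer names; defaults to
#'   \code{c("bobyqa", "Nelder_Mead", "nloptwrap")} for mixed specs and
#'   \code{c("BFGS", "Nelder-Mead", "CG")} for GLMs.
#' @param n_starts start points per optimizer (start 1 is the default start).
#' @param seed seed for the start-point jitter.
#' @return Object of class \code{stability_report}: \code{runs} (one row per
#'   optimizer x start with the coefficient vector and an \code{ok} flag) and
#'   \code{max_deviation} (named vector: per-coefficient maximum absolute
#'   pairwise deviation across successful runs).
#' @export
estimation_sweep <- function(data, spec, optimizers = NULL, n_starts = 2L,
                             seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  mixed <- length(spec$random) > 0
  if (is.null(optimizers)) {
    optimizers <- if (mixed) c("bobyqa", "Nelder_Mead", "nloptwrap") else
      c("BFGS", "Nelder-Mead", "CG")
  }
  if (length(optimizers) < 2) stop("need >= 2 optimizers", call. = FALSE)
  set.seed(seed)

  if (mixed) {
    ref <- fit_mixed(data, spec)
    theta0 <- lme4::getME(ref$fit, "theta")
    terms <- ref$coefficients$term
    runs <- list()
    for (opt in optimizers) {
      for (s in seq_len(n_starts)) {
        start <- if (s == 1) NULL else {
          th <- theta0 * runif(length(theta0), 0.5, 1.5) + 0.05
          if (spec$family == "gaussian-identity") th else list(theta = th)
        }
        est <- tryCatch({
          f <- fit_mixed(data, spec, optimizer = opt, start = start)
          setNames(f$coefficients$estimate, f$coefficients$term)[terms]
        }, error = function(e) setNames(rep(NA_real_, length(terms)), terms))
        runs[[length(runs) + 1L]] <- c(list(optimizer = opt, start = s),
                                       as.list(est))
      }
    }
  } else {
    # direct ML optimization of the convex GLM log-likelihood
    fixed_rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = "+") else "1"
    dat <- data
    for (v in spec_vars(spec)) {
      if (is.numeric(dat[[v]])) dat[[v]] <- zscore(dat[[v]])
    }
    X <- stats::model.matrix(as.formula(paste("~", fixed_rhs)), dat)
    if (length(spec$response) == 2L) {
      succ <- dat[[spec$response[1]]]
      fail <- dat[[spec$response[2]]]
      y <- succ / (succ + fail)
      weights <- succ + fail
    } else {
      y <- dat[[spec$response]]
      weights <- rep(1, length(y))
    }
    terms <- colnames(X)
    runs <- list()
    for (opt in optimizers) {
      for (s in seq_len(n_starts)) {
        b0 <- if (s == 1) rep(0, ncol(X)) else rnorm(ncol(X), 0, 0.3)
        est <- tryCatch({
          o <- optim(b0, function(b) -glm_loglik(b, X, y, weights,
                                                 spec$family),
                     method = opt,
                     control = list(maxit = 10000, reltol = 1e-14))
          setNames(o$par, terms)
        }, error = function(e) setNames(rep(NA_real_, length(terms)), terms))
        runs[[length(runs) + 1L]] <- c(list(optimizer = opt, start = s),
                                       as.list(est))
      }
    }
  }
  runs <- do.call(rbind, lapply(runs, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  names(runs) <- c("optimizer", "start", terms)
  est_mat <- as.matrix(runs[, terms, drop = FALSE])
  runs$ok <- stats::complete.cases(est_mat)
  ok_mat <- est_mat[runs$ok, , drop = FALSE]
  max_dev <- if (nrow(ok_mat) >= 2) {
    apply(ok_mat, 2, function(col) max(col) - min(col))
  } else setNames(rep(NA_real_, length(terms)), terms)
  structure(list(runs = runs, max_deviation = max_dev,
                 n_failures = sum(!runs$ok)),
            class = "stability_report")
}

#' @method print stability_report
#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Estimation stability sweep: %d runs, %d failed\n",
              nrow(x$runs), x$n_failures))
  cat("  max absolute deviation per coefficient:\n")
  print(signif(x$max_deviation, 4))
  invisible(x)
}
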