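#' Tone-category contingency table with percentages
#'
#' Builds the 2 x K table of tone-category counts for the baseline and
#' trouble-source conditions (turns preceding other-initiated repair) and
#' computes within-condition percentages and per-category percentage
#' differences. Reported percentages are rounded to integers; the reported
#' difference row rounds the \emph{unrounded} percentage differences (the
#' unrounded values are also kept).
#'
#' @param baseline,trouble nonnegative integer count vectors of equal length.
#' @param categories optional category labels.
#' @return Object of class \code{tone_contingency}: \code{counts} (2 x K),
#'   \code{percentages} (rounded), \code{percentages_raw},
#'   \code{differences} (rounded raw differences), \code{differences_raw}.
#' @export
tone_contingency <- function(baseline, trouble, categories = NULL) {
  if (length(baseline) != length(trouble)) {
    stop("count vectors must have equal length", call. = FALSE)
  }
  if (any(baseline < 0) || any(trouble < 0) ||
      any(baseline != round(baseline)) || any(trouble != round(trouble))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  k <- length(baseline)
  if (is.null(categories)) categories <- paste0("t", seq_len(k))
  counts <- rbind(baseline = baseline, trouble_source = trouble)
  colnames(counts) <- categories
  pb <- 100 * baseline / sum(baseline)
  pt <- 100 * trouble / sum(trouble)
  structure(list(
    counts = counts,
    percentages = rbind(baseline = round(pb), trouble_source = round(pt)),
    percentages_raw = rbind(baseline = pb, trouble_source = pt),
    differences = round(pt - pb),
    differences_raw = pt - pb
  ), class = "tone_contingency")
}

#' @method print tone_contingency
#' @export
print.tone_contingency <- function(x, ...) {
  k <- ncol(x$counts)
  show <- rbind(
    baseline = sprintf("%d (%d%%)", x$counts[1, ], x$percentages[1, ]),
    trouble_source = sprintf("%d (%d%%)", x$counts[2, ], x$percentages[2, ]),
    difference = sprintf("%+d", x$differences))
  colnames(show) <- colnames(x$counts)
  print(show, quote = FALSE)
  invisible(x)
}

#' Chi-square test on a tone contingency table
#'
#' Pearson chi-square without continuity correction. The default
#' \code{"homogeneity"} test compares the two condition rows (df = K - 1);
#' \code{"gof"} tests the trouble-source counts against the baseline
#' proportions treated as fixed (also df = K - 1).
#'
#' @param x a [tone_contingency()] object.
#' @param type \code{"homogeneity"} or \code{"gof"}.
#' @return List with \code{chi2}, \code{df}, \code{p}, \code{expected}.
#' @export
contingency_test <- function(x, type = c("homogeneity", "gof")) {
  type <- match.arg(type)
  stopifnot(inherits(x, "tone_contingency"))
  totals <- colSums(x$counts)
  if (any(totals == 0)) {
    stop("zero column total for category: ",
         paste(colnames(x$counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  if (type == "homogeneity") {
    ct <- suppressWarnings(chisq.test(x$counts, correct = FALSE))
  } else {
    ct <- suppressWarnings(chisq.test(
      x$counts[2, ], p = x$counts[1, ] / sum(x$counts[1, ])))
  }
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value), expected = ct$expected)
}

#' Seasonal contour-tone analysis
#'
#' Aggregates tone-token counts to corpus-by-month contour vs. level counts
#' and tests whether monthly humidity predicts the contour-tone share, using
#' a binomial-logit mixed model with a random intercept per source corpus and
#' a 1-df likelihood-ratio test for z-scored humidity.
#'
#' @param tokens token records: \code{corpus_id}, \code{date},
#'   \code{tone_category}, \code{count} (condition, if present, is pooled).
#' @param monthly_humidity data frame with \code{date} (month) and
#'   \code{humidity}; months without humidity are dropped with a warning.
#' @param contour_map named character vector mapping each tone category to
#'   \code{"contour"} or \code{"level"}; defaults to the mapping attached by
#'   [generate_corpus()], if present.
#' @return List with \code{monthly} (month, contour and level counts,
#'   proportion), \code{lrt} (chi2, df, p — or \code{degenerate = TRUE} when
#'   humidity has no variation across the observed months),
#'   \code{n_dropped_months}, and the model fits.
#' @export
seasonal_contour <- function(tokens, monthly_humidity = NULL,
                             contour_map = NULL) {
  if (is.null(monthly_humidity)) {
    monthly_humidity <- attr(tokens, "monthly_humidity")
  }
  if (is.null(monthly_humidity)) {
    stop("'monthly_humidity' is required", call. = FALSE)
  }
  if (is.null(contour_map)) {
    cc <- attr(tokens, "contour_categories")
    if (is.null(cc)) stop("'contour_map' is required", call. = FALSE)
    cats <- unique(tokens$tone_category)
    contour_map <- setNames(ifelse(cats %in% cc, "contour", "level"), cats)
  }
  unmapped <- setdiff(unique(tokens$tone_category), names(contour_map))
  if (length(unmapped)) {
    stop("tone categories without contour/level mapping: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  tokens$class <- unname(contour_map[tokens$tone_category])

  con <- aggregate(count ~ corpus_id + date, FUN = sum,
                   data = tokens[tokens$class == "contour", ])
  lev <- aggregate(count ~ corpus_id + date, FUN = sum,
                   data = tokens[tokens$class == "level", ])
  wide <- merge(con, lev, by = c("corpus_id", "date"), all = TRUE,
                suffixes = c("_contour", "_level"))
  wide$contour <- ifelse(is.na(wide$count_contour), 0, wide$count_contour)
  wide$level <- ifelse(is.na(wide$count_level), 0, wide$count_level)
  wide <- wide[, c("corpus_id", "date", "contour", "level")]

  hum <- monthly_humidity
  merged <- merge(wide, hum, by = "date")
  n_dropped <- length(setdiff(unique(as.character(wide$date)),
                              unique(as.character(hum$date))))
  if (n_dropped > 0) {
    warning(sprintf("%d month(s) without humidity excluded", n_dropped))
  }
  monthly <- aggregate(cbind(contour, level) ~ date, data = merged, FUN = sum)
  monthly$prop_contour <- monthly$contour /
    (monthly$contour + monthly$level)

  zh <- zscore(merged$humidity)
  if (is_degenerate(zh) || length(unique(merged$date)) < 2) {
    return(list(monthly = monthly, lrt = list(degenerate = TRUE),
                n_dropped_months = n_dropped, fit = NULL))
  }
  merged$zh <- zh
  merged$corpus_id <- factor(merged$corpus_id)
  single_corpus <- nlevels(merged$corpus_id) < 2
  if (single_corpus) {
    m0 <- glm(cbind(contour, level) ~ 1, family = stats::binomial(),
              data = merged)
    m1 <- glm(cbind(contour, level) ~ zh, family = stats::binomial(),
              data = merged)
  } else {
    m0 <- suppressWarnings(suppressMessages(
      lme4::glmer(cbind(contour, level) ~ 1 + (1 | corpus_id),
                  family = stats::binomial(), data = merged)))
    m1 <- suppressWarnings(suppressMessages(
      lme4::glmer(cbind(contour, level) ~ zh + (1 | corpus_id),
                  family = stats::binomial(), data = merged)))
  }
  chi2 <- max(0, 2 * (as.numeric(logLik(m1)) - as.numeric(logLik(m0))))
  list(monthly = monthly,
       lrt = list(chi2 = chi2, df = 1,
                  p = pchisq(chi2, 1, lower.tail = FALSE)),
       n_dropped_months = n_dropped,
       fit = m1)
}

#' Phoneme-level vowel/consonant ratio per document
#'
#' Transcribes each document's tokens to phonemes with a user-supplied
#' lexicon, classifies phonemes as vowels or consonants, and reports the
#' vowel-to-consonant ratio and lexicon coverage per document. Tokens absent
#' from the lexicon are skipped and counted against coverage.
#'
#' @param documents data frame with \code{doc_id}, \code{date} and
#'   \code{text} (whitespace-separated tokens), or a named list of token
#'   character vectors.
#' @param lexicon named character vector or data frame (\code{word},
#'   \code{phonemes}) mapping words to space-separated phoneme strings.
#' @param phoneme_classes named character vector mapping phonemes to
#'   \code{"V"} or \code{"C"}.
#' @return Data frame: \code{doc_id}, \code{date}, \code{n_tokens},
#'   \code{coverage}, \code{vowel_count}, \code{consonant_count},
#'   \code{ratio} (vowel phones / consonant phones; \code{NA} and flagged
#'   when undefined), \code{flagged}.
#' @export
vowel_ratio_series <- function(documents, lexicon, phoneme_classes) {
  if (is.data.frame(lexicon)) {
    lexicon <- setNames(as.character(lexicon$phonemes),
                        as.character(lexicon$word))
  }
  if (is.list(documents) && !is.data.frame(documents)) {
    documents <- data.frame(doc_id = names(documents),
                            date = as.Date(NA),
                            text = vapply(documents, paste, character(1),
                                          collapse = " "),
                            stringsAsFactors = FALSE)
  }
  bad <- setdiff(unique(unlist(strsplit(unname(lexicon), "\\s+"))),
                 names(phoneme_classes))
  bad <- bad[nzchar(bad)]
  if (length(bad)) {
    stop("phonemes without V/C class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(documents)), function(i) {
    toks <- strsplit(documents$text[i], "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    n_tok <- length(toks)
    if (n_tok == 0) {
      return(data.frame(doc_id = documents$doc_id[i],
                        date = documents$date[i], n_tokens = 0L,
                        coverage = NA_real_, vowel_count = 0L,
                        consonant_count = 0L, ratio = NA_real_,
                        flagged = TRUE, stringsAsFactors = FALSE))
    }
    known <- toks %in% names(lexicon)
    phones <- unlist(strsplit(lexicon[toks[known]], "\\s+"))
    phones <- phones[nzchar(phones)]
    cls <- phoneme_classes[phones]
    v <- sum(cls == "V")
    cns <- sum(cls == "C")
    data.frame(doc_id = documents$doc_id[i], date = documents$date[i],
               n_tokens = n_tok, coverage = mean(known),
               vowel_count = v, consonant_count = cns,
               ratio = if (cns > 0) v / cns else NA_real_,
               flagged = cns == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Seasonal smooth of a vowel-ratio series against humidity
#'
#' Fits two penalized-spline generalized additive models (\pkg{mgcv}): a
#' periodic trend of the ratio over day of year (cyclic cubic spline, 8 basis
#' functions) and a smooth of the ratio on daily humidity, whose approximate
#' F-test against the intercept-only model is the reported association test.
#' At least two years of data are required for the periodic fit.
#'
#' @param series data frame with \code{date} and \code{ratio} (rows with
#'   missing ratios are dropped).
#' @param covariate data frame with \code{date} and \code{humidity}, matched
#'   to the series by date.
#' @return List: \code{trend} (data frame of day-of-year and fitted trend),
#'   \code{assoc} (\code{F}, \code{edf}, \code{p}, \code{sign} — the sign of
#'   the ratio-humidity correlation), and the two \pkg{mgcv} fits.
#' @export
seasonal_smooth <- function(series, covariate) {
  d <- merge(series[!is.na(series$ratio), c("date", "ratio")],
             covariate[, c("date", "humidity")], by = "date")
  if (nrow(d) < 20) stop("too few matched observations", call. = FALSE)
  span <- as.numeric(max(as.Date(d$date)) - min(as.Date(d$date)))
  if (span < 730) {
    stop("need at least 2 years of data for a periodic fit", call. = FALSE)
  }
  d$doy <- as.integer(format(as.Date(d$date), "%j"))

  trend_fit <- mgcv::gam(ratio ~ s(doy, bs = "cc", k = 8), data = d,
                         knots = list(doy = c(0.5, 366.5)))
  doy_grid <- data.frame(doy = 1:365)
  trend <- data.frame(doy = doy_grid$doy,
                      fit = as.numeric(predict(trend_fit, doy_grid)))

  if (sd(d$humidity) == 0 || sd(d$ratio) == 0) {
    assoc <- list(F = 0, edf = 0, p = 1, sign = 0)
    assoc_fit <- NULL
  } else {
    assoc_fit <- mgcv::gam(ratio ~ s(humidity, k = 5), data = d)
    st <- summary(assoc_fit)$s.table
    assoc <- list(F = unname(st[1, "F"]), edf = unname(st[1, "edf"]),
                  p = unname(st[1, "p-value"]),
                  sign = sign(cor(d$ratio, d$humidity)))
  }
  list(trend = trend, assoc = assoc, trend_fit = trend_fit,
       assoc_fit = assoc_fit)
}
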