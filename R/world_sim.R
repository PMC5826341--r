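#' Configuration for a synthetic cross-linguistic world
#'
#' Defines the generative model for a synthetic sample of languages nested in
#' language families and geographic areas, with spatially autocorrelated
#' humidity, Poisson-distributed tone counts, a second noisy tone measurement,
#' and vowel inventories whose vowel share responds to humidity. The defaults
#' describe a world of 500 languages (50 families of 10) over 25 grid areas
#' with moderate family/area clustering, which is the sampling frame used by
#' the package's own calibration and power analyses.
#'
#' Humidity is built from a latitude gradient (wetter near the equator) plus
#' seeded Gaussian noise shared within a family (families are geographically
#' clustered), then clipped to \code{humidity_range}. Because families cluster
#' in space, humidity is correlated with both family and area membership, which
#' is exactly the structure that makes naive cross-linguistic correlations
#' vulnerable to Galton's problem.
#'
#' The linear predictor for tone counts, on the log scale, is
#' \deqn{\log E[T_i] = \log(\mu_0) + \beta_H z(H_i) + u_{f(i)} + s_{f(i)} z(H_i)
#'   + v_{a(i)} + t_{a(i)} z(H_i) + \gamma b_{a(i)}}
#' where \eqn{z(H)} is z-scored humidity, \eqn{u, s} are family intercepts and
#' slopes, \eqn{v, t} are area intercepts and slopes, and \eqn{b_{a}} is the
#' areal borrowing term scaled by \code{borrowing_strength} (\eqn{\gamma}).
#' Borrowing emulates diffusion of tone through regional contact whose
#' intensity tracks the regional climate (the contact pathway of the wider
#' hypothesis graph): \eqn{b = 0.8\, z(\bar H_{area}) + 0.4\, z(\bar
#' H_{nbh})}, the z-scored area-mean and contact-neighborhood-mean humidity.
#' It is an areal property, not the language's own humidity, and is absorbed
#' by areal controls. Tone counts are Poisson draws capped at 10 tones.
#'
#' @param n_families number of language families.
#' @param languages_per_family languages per family (single count, or a
#'   length-2 range sampled uniformly per family).
#' @param n_areas target number of geographic grid areas.
#' @param humidity_range length-2 numeric, min and max mean specific humidity
#'   (dimensionless mass ratio, kg water vapor per kg air).
#' @param baseline_tones expected tone count at average humidity with all
#'   cluster effects at zero.
#' @param beta_humidity_tone effect of z-scored humidity on log tone rate.
#' @param beta_humidity_vowel effect of z-scored humidity on the vowel-share
#'   logit.
#' @param interaction_vowel coefficient of z(humidity) x z(inventory size) on
#'   the vowel-share logit.
#' @param family_intercept_sd,family_slope_sd,area_intercept_sd,area_slope_sd
#'   standard deviations of the random intercepts/slopes (>= 0).
#' @param borrowing_strength scale of the areal borrowing term on the log
#'   tone rate (>= 0); regional tone convergence driven by contact, not by
#'   the language's own humidity.
#' @param measurement_error_sd standard deviation of the rounded Gaussian
#'   noise added to the second tone measurement (>= 0).
#' @param suppress_complex_below optional humidity quantile in (0, 1]: in
#'   languages below that humidity quantile, tone counts are truncated below
#'   the complex-tone threshold of 3. This is the "strong suppression"
#'   mechanism used for power analyses; \code{NA} (default) disables it.
#' @param seed integer seed; identical config and seed give identical worlds.
#'
#' @return An object of class \code{world_config} (a validated list).
#' @seealso [generate_world()]
#' @export
world_config <- function(n_families = 50,
                         languages_per_family = 10,
                         n_areas = 25,
                         humidity_range = c(0.002, 0.022),
                         baseline_tones = 1.3,
                         beta_humidity_tone = 0,
                         beta_humidity_vowel = 0,
                         interaction_vowel = 0,
                         family_intercept_sd = 0.3,
                         family_slope_sd = 0.1,
                         area_intercept_sd = 0.2,
                         area_slope_sd = 0.1,
                         borrowing_strength = 0,
                         measurement_error_sd = 0.5,
                         suppress_complex_below = NA_real_,
                         seed = 1L) {
  for (nm in c("beta_humidity_tone", "beta_humidity_vowel", "interaction_vowel"))
    check_finite_scalar(get(nm), nm)
  for (nm in c("family_intercept_sd", "family_slope_sd", "area_intercept_sd",
               "area_slope_sd", "borrowing_strength", "measurement_error_sd"))
    check_nonneg(get(nm), nm)
  check_finite_scalar(baseline_tones, "baseline_tones")
  if (baseline_tones <= 0) stop("'baseline_tones' must be > 0", call. = FALSE)
  if (length(humidity_range) != 2L || !all(is.finite(humidity_range)) ||
      humidity_range[1] >= humidity_range[2]) {
    stop("'humidity_range' must be c(min, max) with min < max", call. = FALSE)
  }
  if (n_families < 1 || n_areas < 1) stop("counts must be >= 1", call. = FALSE)
  if (!length(languages_per_family) %in% 1:2 || any(languages_per_family < 1)) {
    stop("'languages_per_family' must be a count or a range", call. = FALSE)
  }
  if (!is.na(suppress_complex_below) &&
      (suppress_complex_below <= 0 || suppress_complex_below > 1)) {
    stop("'suppress_complex_below' must be in (0, 1] or NA", call. = FALSE)
  }
  structure(list(
    n_families = as.integer(n_families),
    languages_per_family = as.integer(languages_per_family),
    n_areas = as.integer(n_areas),
    humidity_range = as.numeric(humidity_range),
    baseline_tones = baseline_tones,
    beta_humidity_tone = beta_humidity_tone,
    beta_humidity_vowel = beta_humidity_vowel,
    interaction_vowel = interaction_vowel,
    family_intercept_sd = family_intercept_sd,
    family_slope_sd = family_slope_sd,
    area_intercept_sd = area_intercept_sd,
    area_slope_sd = area_slope_sd,
    borrowing_strength = borrowing_strength,
    measurement_error_sd = measurement_error_sd,
    suppress_complex_below = suppress_complex_below,
    seed = as.integer(seed)
  ), class = "world_config")
}

#' Generate a synthetic world of languages
#'
#' Draws one synthetic cross-linguistic sample from the generative model
#' described in [world_config()]. Randomness uses R's default Mersenne-Twister
#' generator seeded from \code{config$seed}, so the same config always yields
#' a bit-identical table.
#'
#' @param config a [world_config()] object.
#' @return A data frame (class \code{lingclim_world}) with one row per
#'   language and columns \code{language_id}, \code{family_id}, \code{area_id},
#'   \code{latitude}, \code{longitude}, \code{humidity}, \code{n_tones},
#'   \code{n_tones_alt}, \code{n_vowels}, \code{n_consonants},
#'   \code{tone_class} (\code{none} / \code{noncomplex} / \code{complex},
#'   complex meaning three or more tones).
#' @export
generate_world <- function(config) {
  if (!inherits(config, "world_config")) config <- do.call(world_config, config)
  set.seed(config$seed)

  lpf <- config$languages_per_family
  sizes <- if (length(lpf) == 2L) {
    sample(lpf[1]:lpf[2], config$n_families, replace = TRUE)
  } else rep(lpf, config$n_families)
  n <- sum(sizes)
  fam_idx <- rep(seq_len(config$n_families), sizes)

  # families are geographic clusters: a center plus per-language jitter wide
  # enough that large families straddle several areas, as large real families do
  fam_lon <- runif(config$n_families, -180, 180)
  fam_lat <- runif(config$n_families, -60, 60)
  lon <- fam_lon[fam_idx] + rnorm(n, 0, 15)
  lat <- clip(fam_lat[fam_idx] + rnorm(n, 0, 15), -89, 89)
  lon <- ((lon + 180) %% 360) - 180

  # areas are cells of a fixed longitude x latitude grid
  n_lon <- ceiling(sqrt(config$n_areas))
  n_lat <- ceiling(config$n_areas / n_lon)
  cell_lon <- pmin(n_lon, 1L + floor((lon + 180) / 360 * n_lon))
  cell_lat <- pmin(n_lat, 1L + floor((lat + 90) / 180 * n_lat))
  area_idx <- (cell_lat - 1L) * n_lon + cell_lon

  # humidity: equatorial gradient + family-level and language-level noise,
  # mapped into the configured specific-humidity range
  # smooth squash into (0, 1) rather than a hard clip: a hard clip would
  # pile dry languages onto the range minimum and create humidity ties
  grad <- cos(lat * pi / 180)^2
  fam_noise <- rnorm(config$n_families, 0, 0.15)
  u <- plogis(3 * (grad + fam_noise[fam_idx] + rnorm(n, 0, 0.05) - 0.5))
  hr <- config$humidity_range
  humidity <- hr[1] + u * (hr[2] - hr[1])
  zh <- zscore(humidity)
  if (is_degenerate(zh)) zh <- rep(0, n)

  fam_int <- rnorm(config$n_families, 0, config$family_intercept_sd)
  fam_slope <- rnorm(config$n_families, 0, config$family_slope_sd)
  areas_used <- sort(unique(area_idx))
  area_pos <- match(area_idx, areas_used)
  area_int <- rnorm(length(areas_used), 0, config$area_intercept_sd)
  area_slope <- rnorm(length(areas_used), 0, config$area_slope_sd)

  # areal borrowing: tone propensity converges regionally, and contact
  # intensity tracks the regional climate (the contact/borrowing pathway of
  # the hypothesis graph). The shared component operates at two spatial
  # scales — the area itself and finer contact neighborhoods (a grid twice
  # as fine as the area grid) — so it is the climate of the region, not the
  # language's own humidity, that drives it
  cell_lon2 <- pmin(2L * n_lon, 1L + floor((lon + 180) / 360 * (2L * n_lon)))
  cell_lat2 <- pmin(2L * n_lat, 1L + floor((lat + 90) / 180 * (2L * n_lat)))
  nbh_idx <- (cell_lat2 - 1L) * 2L * n_lon + cell_lon2
  znb <- zscore(stats::ave(humidity, nbh_idx, FUN = mean))
  if (is_degenerate(znb)) znb <- rep(0, n)
  zam <- zscore(stats::ave(humidity, area_idx, FUN = mean))
  if (is_degenerate(zam)) zam <- rep(0, n)
  borrow <- config$borrowing_strength * (0.8 * zam + 0.4 * znb)

  eta <- log(config$baseline_tones) +
    config$beta_humidity_tone * zh +
    fam_int[fam_idx] + fam_slope[fam_idx] * zh +
    area_int[area_pos] + area_slope[area_pos] * zh +
    borrow
  n_tones <- pmin(rpois(n, exp(eta)), 10L)

  if (!is.na(config$suppress_complex_below)) {
    thr <- quantile(humidity, config$suppress_complex_below, names = FALSE)
    dry <- humidity < thr
    n_tones[dry] <- pmin(n_tones[dry], 2L)
  }

  noise <- as.integer(round(rnorm(n, 0, config$measurement_error_sd)))
  n_tones_alt <- pmax(0L, n_tones + noise)

  inv_size <- pmax(8L, rpois(n, 30))
  zi <- zscore(inv_size)
  if (is_degenerate(zi)) zi <- rep(0, n)
  vf <- rnorm(config$n_families, 0, config$family_intercept_sd)
  va <- rnorm(length(areas_used), 0, config$area_intercept_sd)
  eta_v <- qlogis(0.28) +
    config$beta_humidity_vowel * zh +
    config$interaction_vowel * zh * zi +
    0.5 * vf[fam_idx] + 0.5 * va[area_pos] + rnorm(n, 0, 0.15)
  n_vowels <- pmax(1L, rbinom(n, inv_size, plogis(eta_v)))
  n_consonants <- pmax(1L, inv_size - n_vowels)

  tone_class <- cut(n_tones, c(-Inf, 0, 2, Inf),
                    labels = c("none", "noncomplex", "complex"))

  out <- data.frame(
    language_id = sprintf("L%04d", seq_len(n)),
    family_id = sprintf("F%03d", fam_idx),
    area_id = sprintf("A%03d", area_idx),
    latitude = lat,
    longitude = lon,
    humidity = humidity,
    n_tones = n_tones,
    n_tones_alt = n_tones_alt,
    n_vowels = n_vowels,
    n_consonants = n_consonants,
    tone_class = as.character(tone_class),
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- config
  class(out) <- c("lingclim_world", "data.frame")
  out
}

#' Generate a synthetic tone-token corpus
#'
#' Emulates token counts of tone categories from conversational corpora, by
#' corpus, calendar month, and condition. The \code{baseline} condition draws
#' tone categories t1..tK from \code{baseline_probs}; the
#' \code{trouble_source} condition (turns preceding other-initiated repair)
#' adds \code{shift_tone3} to the tone-3 probability, rescaling the remaining
#' categories proportionally. Month-to-month variation modulates the total
#' probability of the contour-tone categories on the logit scale by
#' \code{monthly_contour_effect} times z-scored monthly humidity (a seasonal
#' sinusoid), plus a per-corpus random intercept.
#'
#' @param shift_tone3 additive shift of the tone-3 probability in the
#'   trouble-source condition.
#' @param monthly_contour_effect logit-scale effect of z-scored monthly
#'   humidity on the contour-tone share.
#' @param n_tokens total token count per condition (split evenly across
#'   corpus-month cells).
#' @param seed integer seed.
#' @param baseline_probs baseline tone-category simplex (must sum to 1).
#' @param contour_categories which categories count as contour tones for the
#'   seasonal modulation (default t2..t4, a Mandarin-style reading where only
#'   tone 1 is a level tone).
#' @param n_corpora,n_months number of source corpora and consecutive months.
#' @param corpus_sd standard deviation of the per-corpus intercept on the
#'   contour-share logit.
#' @return A data frame of token records: \code{corpus_id}, \code{date}
#'   (first of month), \code{tone_category}, \code{condition}, \code{count},
#'   with the monthly humidity series attached as attribute
#'   \code{"monthly_humidity"}.
#' @export
generate_corpus <- function(shift_tone3 = 0,
                            monthly_contour_effect = 0,
                            n_tokens = 10000,
                            seed = 1L,
                            baseline_probs = c(0.23, 0.22, 0.21, 0.34),
                            contour_categories = NULL,
                            n_corpora = 4L,
                            n_months = 24L,
                            corpus_sd = 0.3) {
  if (n_tokens <= 0) stop("'n_tokens' must be > 0", call. = FALSE)
  if (abs(sum(baseline_probs) - 1) > 1e-8 || any(baseline_probs < 0)) {
    stop("'baseline_probs' must be a probability simplex", call. = FALSE)
  }
  k <- length(baseline_probs)
  if (k < 3) stop("need at least 3 tone categories", call. = FALSE)
  cats <- paste0("t", seq_len(k))
  if (is.null(contour_categories)) contour_categories <- cats[-1]
  if (!all(contour_categories %in% cats)) {
    stop("'contour_categories' must name tone categories", call. = FALSE)
  }
  if (baseline_probs[3] + shift_tone3 < 0 ||
      baseline_probs[3] + shift_tone3 > 1) {
    stop("'shift_tone3' pushes the tone-3 probability outside [0, 1]",
         call. = FALSE)
  }
  set.seed(seed)

  months <- seq(as.Date("2000-01-01"), by = "month", length.out = n_months)
  moy <- as.integer(format(months, "%m"))
  hum <- 0.012 + 0.006 * sin(2 * pi * (moy - 3) / 12)
  zh <- zscore(hum)
  if (is_degenerate(zh)) zh <- rep(0, n_months)
  corp_int <- rnorm(n_corpora, 0, corpus_sd)

  is_contour <- cats %in% contour_categories
  p_contour0 <- sum(baseline_probs[is_contour])
  per_cell <- n_tokens / (n_corpora * n_months)

  rows <- vector("list", n_corpora * n_months * 2L)
  r <- 0L
  for (ci in seq_len(n_corpora)) {
    for (mi in seq_len(n_months)) {
      # contour-share modulation, shared by both conditions in the cell
      delta <- monthly_contour_effect * zh[mi] + corp_int[ci]
      p_c <- plogis(qlogis(p_contour0) + delta)
      p <- baseline_probs
      p[is_contour] <- p[is_contour] * p_c / p_contour0
      p[!is_contour] <- p[!is_contour] * (1 - p_c) / (1 - p_contour0)

      p_shift <- p
      p3 <- p[3] + shift_tone3
      if (p3 < 0 || p3 > 1) {
        stop("'shift_tone3' pushes the tone-3 probability outside [0, 1]",
             call. = FALSE)
      }
      p_shift[-3] <- p[-3] * (1 - p3) / (1 - p[3])
      p_shift[3] <- p3

      n_cell <- rpois(1, per_cell)
      for (cond in c("baseline", "trouble_source")) {
        pp <- if (cond == "baseline") p else p_shift
        counts <- as.integer(rmultinom(1, n_cell, pp))
        r <- r + 1L
        rows[[r]] <- data.frame(
          corpus_id = sprintf("corpus%02d", ci),
          date = months[mi],
          tone_category = cats,
          condition = cond,
          count = counts,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "monthly_humidity") <- data.frame(date = months, humidity = hum)
  attr(out, "contour_categories") <- contour_categories
  out
}

#' Generate synthetic formant observations
#'
#' Places vowel targets on a template triangle in (F1, F2) space — the
#' point-vowel triangle spanned by /i/-like, /a/-like and /u/-like corners —
#' scales each language's triangle about its centroid by that language's
#' dispersion factor, and adds seeded Gaussian jitter. The first three vowels
#' sit on the corners; further vowels are spaced evenly along the perimeter.
#'
#' @param dispersion_scale numeric vector, one dispersion factor per language
#'   (names, if present, become language ids).
#' @param k_vowels vowels per language (>= 3).
#' @param seed integer seed.
#' @param jitter_sd standard deviation in Hz of the jitter on both formants.
#' @param template 3x2 matrix of (F1, F2) corner frequencies in Hz.
#' @return Data frame with columns \code{language_id}, \code{vowel_label},
#'   \code{f1}, \code{f2}.
#' @export
generate_formants <- function(dispersion_scale,
                              k_vowels = 5L,
                              seed = 1L,
                              jitter_sd = 30,
                              template = rbind(c(300, 800),
                                               c(800, 1100),
                                               c(300, 2300))) {
  if (k_vowels < 3) stop("'k_vowels' must be >= 3", call. = FALSE)
  if (any(!is.finite(dispersion_scale)) || any(dispersion_scale < 0)) {
    stop("'dispersion_scale' must be finite and >= 0", call. = FALSE)
  }
  set.seed(seed)
  ids <- names(dispersion_scale)
  if (is.null(ids)) ids <- sprintf("L%03d", seq_along(dispersion_scale))

  # vowel targets: the three corners, plus extras spaced along the perimeter
  # (perimeter points leave the hull equal to the template triangle)
  seg <- rbind(template[2, ] - template[1, ],
               template[3, ] - template[2, ],
               template[1, ] - template[3, ])
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[4]
  n_extra <- k_vowels - 3L
  tpos <- if (n_extra > 0) total * (2 * seq_len(n_extra) - 1) / (2 * n_extra)
          else numeric()
  extras <- t(vapply(tpos, function(s) {
    i <- min(findInterval(s, cum, rightmost.closed = TRUE), 3L)
    frac <- if (seg_len[i] > 0) (s - cum[i]) / seg_len[i] else 0
    template[i, ] + frac * seg[i, ]
  }, numeric(2)))
  targets <- rbind(template, extras)
  centroid <- colMeans(template)

  rows <- lapply(seq_along(dispersion_scale), function(li) {
    sc <- dispersion_scale[li]
    pts <- sweep(sweep(targets, 2, centroid) * sc, 2, centroid, "+")
    pts <- pts + matrix(rnorm(2 * k_vowels, 0, jitter_sd), ncol = 2)
    data.frame(language_id = ids[li],
               vowel_label = paste0("v", seq_len(k_vowels)),
               f1 = pts[, 1], f2 = pts[, 2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write or read the standard language table
#'
#' The on-disk exchange format is a plain CSV with columns exactly
#' \code{language_id, family_id, area_id, latitude, longitude, humidity,
#' n_tones, n_tones_alt, n_vowels, n_consonants, tone_class}.
#'
#' @param world a data frame from [generate_world()] (or compatible).
#' @param path file path.
#' @return \code{read_language_table} returns the validated data frame.
#' @export
write_language_table <- function(world, path) {
  cols <- c("language_id", "family_id", "area_id", "latitude", "longitude",
            "humidity", "n_tones", "n_tones_alt", "n_vowels", "n_consonants",
            "tone_class")
  missing <- setdiff(cols, names(world))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  write.csv(world[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_language_table
#' @export
read_language_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("language_id", "family_id", "area_id", "humidity", "n_tones")
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    stop("language table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(out$language_id)) {
    stop("duplicated language_id values", call. = FALSE)
  }
  out
}
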