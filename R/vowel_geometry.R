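#' Convex-hull area of a formant point set
#'
#' Area of the convex hull of (F1, F2) points, the standard proxy for the
#' acoustic dispersion of a vowel system. Hull vertices are found with
#' Graham-scan (\code{grDevices::chull}) and the polygon area is computed by
#' the shoelace formula. Degenerate sets (fewer than three distinct points,
#' or collinear points) have area zero.
#'
#' @param points two-column numeric matrix or data frame of (F1, F2)
#'   coordinates in Hz (>= 1 point, all finite).
#' @return Area in Hz^2 (>= 0).
#' @export
hull_area <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1 || ncol(points) != 2) {
    stop("'points' must be an n x 2 matrix with n >= 1", call. = FALSE)
  }
  if (!all(is.finite(points))) {
    stop("non-finite coordinates in 'points'", call. = FALSE)
  }
  if (nrow(points) < 3) return(0)
  h <- chull(points[, 1], points[, 2])
  if (length(h) < 3) return(0)
  x <- points[h, 1]
  y <- points[h, 2]
  j <- c(seq_along(h)[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

formant_transform <- function(f, transform) {
  switch(transform,
         hz = f,
         log = log(f),
         bark = 26.81 * f / (1960 + f) - 0.53)
}

#' Per-language vowel-space areas
#'
#' Groups formant observations by language and computes each language's
#' convex-hull vowel-space area, with optional frequency transforms for
#' sensitivity checks (\code{"hz"} raw hertz, \code{"log"} natural-log hertz,
#' \code{"bark"} the Traunmueller Bark formula). All formant rows of a
#' language are pooled; duplicated rows do not change the hull. Languages
#' with fewer than three non-collinear points get area 0 and are flagged.
#'
#' @param formants data frame with columns \code{language_id}, \code{f1},
#'   \code{f2} (and optionally \code{vowel_label}).
#' @param transform \code{"hz"}, \code{"log"} or \code{"bark"}.
#' @return Data frame with one row per language: \code{language_id},
#'   \code{n_vowels} (distinct vowel labels, or point count),
#'   \code{hull_area}, \code{degenerate}.
#' @export
vowel_space_table <- function(formants, transform = c("hz", "log", "bark")) {
  transform <- match.arg(transform)
  if (nrow(formants) == 0) {
    return(data.frame(language_id = character(), n_vowels = integer(),
                      hull_area = numeric(), degenerate = logical()))
  }
  need <- c("language_id", "f1", "f2")
  missing <- setdiff(need, names(formants))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(formants$f1 <= 0 | formants$f2 <= 0)) {
    stop("formant frequencies must be positive", call. = FALSE)
  }
  rows <- lapply(split(formants, formants$language_id), function(d) {
    pts <- cbind(formant_transform(d$f1, transform),
                 formant_transform(d$f2, transform))
    a <- hull_area(pts)
    nv <- if ("vowel_label" %in% names(d)) {
      length(unique(d$vowel_label))
    } else nrow(d)
    data.frame(language_id = d$language_id[1], n_vowels = nv,
               hull_area = a, degenerate = a == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
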