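# shared fixture builders and independent oracles used across test files

# small fast world for structural checks
tiny_world <- function(seed = 1, ...) {
  generate_world(world_config(seed = seed, n_families = 20,
                              languages_per_family = 8, n_areas = 9, ...))
}

# the Galton's-problem confound fixture: no language-level humidity effect,
# strong climate-tracking areal borrowing, heavy area slope heterogeneity
confound_world <- function(seed) {
  generate_world(world_config(seed = seed, beta_humidity_tone = 0,
                              n_areas = 12, borrowing_strength = 0.8,
                              area_slope_sd = 1.0))
}

# daily vowel-ratio series with a seasonal humidity covariate
make_ratio_series <- function(seed, effect = 0, n_days = 400) {
  set.seed(seed)
  dates <- sort(sample(seq(as.Date("2000-01-01"), by = "day",
                           length.out = 1100), n_days))
  doy <- as.integer(format(dates, "%j"))
  hum <- 0.009 + 0.004 * sin(2 * pi * (doy - 100) / 365) +
    rnorm(n_days, 0, 0.001)
  ratio <- 0.66 + effect * (hum - 0.009) / 0.004 + rnorm(n_days, 0, 0.008)
  list(series = data.frame(date = dates, ratio = ratio),
       cov = data.frame(date = dates, humidity = hum))
}

# independent textbook kappa oracle: (p_o - p_e) / (1 - p_e) with agreement
# weights v = 1 - w, computed from proportions rather than count sums
kappa_oracle <- function(tab, weighting) {
  k <- nrow(tab)
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  v <- switch(weighting,
              unweighted = (d == 0) + 0,
              linear = 1 - d / (k - 1),
              quadratic = 1 - (d / (k - 1))^2)
  p <- tab / sum(tab)
  po <- sum(v * p)
  pe <- sum(v * outer(rowSums(p), colSums(p)))
  (po - pe) / (1 - pe)
}

# independent convex hull: Andrew's monotone chain + shoelace
hull_area_oracle <- function(pts) {
  pts <- unique(pts[order(pts[, 1], pts[, 2]), , drop = FALSE])
  n <- nrow(pts)
  if (n < 3) return(0)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    h <- integer()
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(pts[h[length(h) - 1], ], pts[h[length(h)], ],
                   pts[i, ]) <= 0) {
        h <- h[-length(h)]
      }
      h <- c(h, i)
    }
    h[-length(h)]
  }
  hull <- c(build(seq_len(n)), build(rev(seq_len(n))))
  x <- pts[hull, 1]
  y <- pts[hull, 2]
  j <- c(seq_along(hull)[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# path-enumeration d-separation oracle: enumerate all simple undirected
# paths, check openness by the blocking rules directly
dsep_oracle <- function(g, x, y, z) {
  paths <- lingclim:::dag_all_paths(g, x, y)
  open <- vapply(paths, function(p) lingclim:::path_open(g, p, z), logical(1))
  !any(open)
}

# all labeled DAGs on `nodes`: every orientation/subset of possible edges
# that is acyclic, enumerated via all subsets of ordered pairs
all_dags <- function(nodes) {
  pairs <- t(combn(nodes, 2))
  # each unordered pair is absent, forward, or backward: 3^npairs graphs
  np <- nrow(pairs)
  out <- list()
  states <- rep(0L, np)
  repeat {
    edges <- do.call(rbind, lapply(seq_len(np), function(i) {
      if (states[i] == 0L) NULL
      else if (states[i] == 1L) pairs[i, , drop = FALSE]
      else pairs[i, 2:1, drop = FALSE]
    }))
    if (is.null(edges)) edges <- matrix(character(), ncol = 2)
    g <- tryCatch(causal_graph(nodes, edges), error = function(e) NULL)
    if (!is.null(g)) out[[length(out) + 1L]] <- g
    i <- 1L
    while (i <= np && states[i] == 2L) {
      states[i] <- 0L
      i <- i + 1L
    }
    if (i > np) break
    states[i] <- states[i] + 1L
  }
  out
}

# random DAG on `nodes` via random topological order + edge density
random_dag <- function(nodes, p = 0.4) {
  ord <- sample(nodes)
  edges <- list()
  for (i in seq_along(ord)) {
    for (j in seq_len(i - 1L)) {
      if (runif(1) < p) edges[[length(edges) + 1L]] <- c(ord[j], ord[i])
    }
  }
  causal_graph(nodes, if (length(edges)) do.call(rbind, edges) else
    matrix(character(), ncol = 2))
}

# brute-force ASR oracle: numeric minimization of the weighted
# squared-change criterion over internal node values
asr_oracle <- function(tree, tip_values) {
  n_tip <- length(tree$tip.label)
  x_tip <- tip_values[tree$tip.label]
  len <- tree$edge.length
  if (is.null(len)) len <- rep(1, nrow(tree$edge))
  objective <- function(internal) {
    vals <- c(x_tip, internal)
    sum((vals[tree$edge[, 1]] - vals[tree$edge[, 2]])^2 / len)
  }
  start <- rep(mean(x_tip), tree$Nnode)
  o <- optim(start, objective, method = "BFGS",
             control = list(maxit = 5000, reltol = 1e-15))
  o$par
}

# all permutations of 1..n as a list (n small)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}
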