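#' Construct a causal graph (DAG)
#'
#' A directed acyclic graph of hypothesis variables. Acyclicity is verified by
#' Kahn's algorithm; if the edge set contains a cycle, the error names the
#' nodes involved.
#'
#' @param nodes character vector of variable names.
#' @param edges two-column character matrix or data frame of directed edges
#'   (from, to).
#' @return Object of class \code{causal_graph}.
#' @export
causal_graph <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names", call. = FALSE)
  edges <- as.matrix(edges)
  if (length(edges) == 0) {
    edges <- matrix(character(), ncol = 2)
  }
  if (ncol(edges) != 2) stop("'edges' must have two columns", call. = FALSE)
  mode(edges) <- "character"
  unknown <- setdiff(c(edges), nodes)
  if (length(unknown)) {
    stop("edge endpoints not in nodes: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(edges[, 1] == edges[, 2])) stop("self-loops not allowed",
                                          call. = FALSE)
  key <- paste(edges[, 1], edges[, 2])
  if (anyDuplicated(key)) stop("duplicate edges", call. = FALSE)

  # Kahn's algorithm; peeling sources and sinks repeatedly strips everything
  # except the nodes that actually lie on a cycle
  remaining <- nodes
  es <- edges
  repeat {
    indeg <- table(factor(es[, 2], levels = remaining))
    outdeg <- table(factor(es[, 1], levels = remaining))
    strip <- remaining[indeg == 0 | outdeg == 0]
    if (length(strip) == 0 || length(remaining) == 0) break
    remaining <- setdiff(remaining, strip)
    es <- es[!(es[, 1] %in% strip) & !(es[, 2] %in% strip), , drop = FALSE]
  }
  if (length(remaining)) {
    stop("graph contains a cycle involving: ",
         paste(sort(remaining), collapse = ", "), call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "causal_graph")
}

#' @method print causal_graph
#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf("Causal graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    cat(paste0("  ", x$edges[, 1], " -> ", x$edges[, 2], collapse = "\n"),
        "\n")
  }
  invisible(x)
}

dag_parents <- function(g, v) g$edges[g$edges[, 2] == v, 1]
dag_children <- function(g, v) g$edges[g$edges[, 1] == v, 2]

dag_ancestors <- function(g, vs) {
  # vs together with all their ancestors
  out <- unique(vs)
  frontier <- out
  while (length(frontier)) {
    ps <- unique(unlist(lapply(frontier, dag_parents, g = g)))
    frontier <- setdiff(ps, out)
    out <- c(out, frontier)
  }
  out
}

dag_descendants <- function(g, vs) {
  out <- unique(vs)
  frontier <- out
  while (length(frontier)) {
    cs <- unique(unlist(lapply(frontier, dag_children, g = g)))
    frontier <- setdiff(cs, out)
    out <- c(out, frontier)
  }
  out
}

#' d-separation query
#'
#' Tests whether nodes \code{x} and \code{y} are d-separated given the
#' conditioning set \code{z} under the standard semantics: a path is blocked
#' at a chain or fork node that is conditioned on, and at a collider unless
#' the collider or one of its descendants is conditioned on. The
#' implementation is the linear-time reachability ("Bayes-ball") traversal
#' over (node, direction) states; when the pair is \emph{not} separated, a
#' concrete open path is returned as a witness.
#'
#' @param g a [causal_graph()].
#' @param x,y distinct node names, neither in \code{z}.
#' @param z character vector of conditioned nodes (default empty).
#' @return Object of class \code{separation_result}: \code{x}, \code{y},
#'   \code{z}, \code{separated} (logical), \code{witness} (open path as a
#'   node sequence, or NULL when separated).
#' @export
d_separated <- function(g, x, y, z = character()) {
  stopifnot(inherits(g, "causal_graph"))
  z <- as.character(z)
  unknown <- setdiff(c(x, y, z), g$nodes)
  if (length(unknown)) {
    stop("unknown node names: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (x == y) stop("'x' and 'y' must differ", call. = FALSE)
  if (x %in% z || y %in% z) stop("'x' and 'y' must not be in 'z'",
                                 call. = FALSE)

  active <- dag_ancestors(g, z)  # nodes with self or descendant in z

  # states are (node, direction); direction "up" = arrived moving
  # parent-ward (from a child), "down" = arrived moving child-ward
  state_key <- function(v, d) paste0(v, "|", d)
  visited <- new.env(parent = emptyenv())
  pred <- new.env(parent = emptyenv())
  queue <- list(list(v = x, d = "up", from = NA))
  witness_state <- NULL

  while (length(queue)) {
    s <- queue[[1]]
    queue <- queue[-1]
    key <- state_key(s$v, s$d)
    if (!is.null(visited[[key]])) next
    visited[[key]] <- TRUE
    if (!is.na(s$from)) pred[[key]] <- s$from
    if (s$v == y) {
      witness_state <- key
      break
    }
    nxt <- list()
    if (s$d == "up") {
      if (!(s$v %in% z)) {
        for (p in dag_parents(g, s$v)) nxt <- c(nxt, list(list(v = p, d = "up")))
        for (ch in dag_children(g, s$v)) nxt <- c(nxt, list(list(v = ch, d = "down")))
      }
    } else {
      if (!(s$v %in% z)) {
        for (ch in dag_children(g, s$v)) nxt <- c(nxt, list(list(v = ch, d = "down")))
      }
      if (s$v %in% active) {
        for (p in dag_parents(g, s$v)) nxt <- c(nxt, list(list(v = p, d = "up")))
      }
    }
    for (t in nxt) {
      queue <- c(queue, list(list(v = t$v, d = t$d, from = key)))
    }
  }

  witness <- NULL
  if (!is.null(witness_state)) {
    path <- character()
    key <- witness_state
    while (!is.null(key)) {
      path <- c(sub("\\|.*$", "", key), path)
      key <- pred[[key]]
    }
    # collapse consecutive repeats (direction changes at the same node)
    witness <- path[c(TRUE, path[-1] != path[-length(path)])]
  }
  structure(list(x = x, y = y, z = z,
                 separated = is.null(witness), witness = witness),
            class = "separation_result")
}

#' @method print separation_result
#' @export
print.separation_result <- function(x, ...) {
  given <- if (length(x$z)) paste(x$z, collapse = ", ") else "{}"
  if (x$separated) {
    cat(sprintf("%s and %s are d-separated given %s\n", x$x, x$y, given))
  } else {
    cat(sprintf("%s and %s are NOT d-separated given %s\n  open path: %s\n",
                x$x, x$y, given, paste(x$witness, collapse = " - ")))
  }
  invisible(x)
}

# enumerate all simple undirected paths between a and b as node sequences
dag_all_paths <- function(g, a, b) {
  nbrs <- function(v) unique(c(dag_parents(g, v), dag_children(g, v)))
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == b) {
      paths[[length(paths) + 1L]] <<- path
      return()
    }
    for (w in setdiff(nbrs(v), path)) walk(c(path, w))
  }
  walk(a)
  paths
}

has_edge <- function(g, from, to) {
  any(g$edges[, 1] == from & g$edges[, 2] == to)
}

path_open <- function(g, path, z) {
  # a path is open given z iff every non-collider on it is outside z and
  # every collider has itself or a descendant in z
  if (length(path) <= 2) return(TRUE)
  active <- dag_ancestors(g, z)
  for (k in 2:(length(path) - 1)) {
    collider <- has_edge(g, path[k - 1], path[k]) &&
      has_edge(g, path[k + 1], path[k])
    if (collider) {
      if (!(path[k] %in% active)) return(FALSE)
    } else {
      if (path[k] %in% z) return(FALSE)
    }
  }
  TRUE
}

#' Open backdoor variables after a set of controls
#'
#' Enumerates backdoor paths — paths from the outcome into the exposure whose
#' edge at the exposure points \emph{into} it — that remain open given the
#' controlled set, and returns the variables lying on them (excluding the
#' exposure, the outcome, and mediators on directed exposure-to-outcome
#' paths). An empty result certifies that the chosen controls screen off
#' every non-causal path, i.e. that controlling for anything further back on
#' those paths is redundant under the Markov condition.
#'
#' @param g a [causal_graph()].
#' @param exposure,outcome distinct node names.
#' @param controlled character vector of controlled variables.
#' @return Character vector (possibly empty) of open backdoor variables,
#'   with the open paths attached as attribute \code{"open_paths"}.
#' @export
screening_set <- function(g, exposure, outcome, controlled = character()) {
  stopifnot(inherits(g, "causal_graph"))
  if (exposure == outcome) stop("'exposure' and 'outcome' must differ",
                                call. = FALSE)
  unknown <- setdiff(c(exposure, outcome, controlled), g$nodes)
  if (length(unknown)) {
    stop("unknown node names: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  paths <- dag_all_paths(g, exposure, outcome)
  backdoor <- Filter(function(p) {
    length(p) >= 2 && has_edge(g, p[2], p[1])
  }, paths)
  open <- Filter(function(p) path_open(g, p, controlled), backdoor)

  # mediators: interior nodes of directed exposure -> outcome paths
  directed <- Filter(function(p) {
    all(vapply(seq_len(length(p) - 1),
               function(k) has_edge(g, p[k], p[k + 1]), logical(1)))
  }, paths)
  mediators <- unique(unlist(lapply(directed, function(p) {
    if (length(p) > 2) p[-c(1, length(p))] else character()
  })))

  vars <- unique(unlist(lapply(open, function(p) p[-c(1, length(p))])))
  vars <- setdiff(vars, c(mediators, exposure, outcome))
  structure(sort(vars %||% character()), open_paths = open)
}

#' Read and write causal graphs as JSON edge lists
#'
#' File format: \code{{"nodes": [...], "edges": [[from, to], ...]}}. Reading
#' validates the structure and acyclicity (a cycle is rejected with the nodes
#' on it named); writing round-trips exactly.
#'
#' @param file path to a JSON graph file.
#' @return \code{read_graph} returns a [causal_graph()].
#' @export
read_graph <- function(file) {
  obj <- jsonlite::fromJSON(file, simplifyMatrix = TRUE)
  if (is.null(obj$nodes)) stop("graph file lacks 'nodes'", call. = FALSE)
  edges <- obj$edges
  if (is.null(edges) || length(edges) == 0) {
    edges <- matrix(character(), ncol = 2)
  } else if (is.list(edges)) {
    edges <- do.call(rbind, edges)
  }
  causal_graph(obj$nodes, edges)
}

#' @rdname read_graph
#' @param g a [causal_graph()].
#' @export
write_graph <- function(g, file) {
  stopifnot(inherits(g, "causal_graph"))
  edges <- lapply(seq_len(nrow(g$edges)), function(i) unname(g$edges[i, ]))
  jsonlite::write_json(list(nodes = g$nodes, edges = edges), file,
                       auto_unbox = FALSE)
  invisible(file)
}

#' Example hypothesis graphs
#'
#' Hand-encoded interpretive renderings of the humidity-tone hypothesis as
#' causal graphs, shipped with the package as JSON files. \code{"chain"} is
#' the main production-effort causal chain (ambient humidity through
#' laryngeal desiccation, production cost, token frequency and cultural
#' diffusion to the tone inventory). \code{"context"} embeds that chain in
#' its wider context, adding the contact/borrowing confound pathway (humidity
#' affects disease load and demography, which drive language contact and
#' hence tone borrowing). These encodings are a best-effort reading of prose
#' descriptions and are illustrative, not canonical.
#'
#' @param which \code{"chain"} or \code{"context"}.
#' @return A [causal_graph()].
#' @export
example_graph <- function(which = c("context", "chain")) {
  which <- match.arg(which)
  file <- system.file("extdata",
                      paste0("graph_", which, ".json"),
                      package = "lingclim", mustWork = TRUE)
  read_graph(file)
}
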