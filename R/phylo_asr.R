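#' Read and write newick phylogenies
#'
#' Thin validated wrappers around \pkg{ape}'s newick parser and writer. Trees
#' must have uniquely labeled tips; branch lengths, when present, must be
#' positive. A basic well-formedness scan reports the position of unbalanced
#' parentheses before handing the string to the parser.
#'
#' @param text newick string, or a path to a file containing one.
#' @return \code{read_newick} returns an \pkg{ape} \code{phylo} object.
#' @export
read_newick <- function(text) {
  if (length(text) == 1L && !grepl("[(;]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop(sprintf("malformed newick: unmatched ')' at position %d", i),
           call. = FALSE)
    }
  }
  if (depth != 0L) {
    stop(sprintf("malformed newick: %d unclosed '(' at end of string", depth),
         call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL)
  if (is.null(tree)) stop("malformed newick: parser failure", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("tip labels must be unique", call. = FALSE)
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length <= 0)) {
    stop("branch lengths must be > 0 where given", call. = FALSE)
  }
  tree
}

#' @rdname read_newick
#' @param tree a \code{phylo} object.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Ancestral state reconstruction under Brownian motion
#'
#' Maximum-likelihood ancestral states for a continuous trait under Brownian
#' motion, which coincide with weighted squared-change parsimony: the
#' internal-node values minimize \eqn{\sum_{(u,v) \in E} (x_u - x_v)^2 /
#' \ell_{uv}} over the tree's edges. With tip values fixed, the minimizer
#' solves a sparse linear system in the graph Laplacian of the tree with edge
#' weights \eqn{1/\ell}; trees without branch lengths use unit lengths. Every
#' estimate is a convex combination of tip values and therefore lies within
#' their range, and rescaling all branch lengths by a constant leaves the
#' estimates unchanged.
#'
#' @param tree a \code{phylo} object.
#' @param tip_values numeric vector of trait values named by tip label (every
#'   tip must be covered; all finite).
#' @return Object of class \code{ancestral_estimates}: a numeric vector of
#'   internal-node estimates (named by node number, or node label when
#'   available), with attributes \code{method} and \code{all_states} (states
#'   for all nodes, tips first, in \pkg{ape} node order).
#' @export
asr_brownian <- function(tree, tip_values) {
  tips <- tree$tip.label
  missing <- setdiff(tips, names(tip_values))
  if (length(missing)) {
    stop("missing tip value for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x_tip <- as.numeric(tip_values[tips])
  if (any(!is.finite(x_tip))) stop("tip values must be finite", call. = FALSE)
  n_tip <- length(tips)
  n_node <- tree$Nnode
  n_all <- n_tip + n_node
  len <- tree$edge.length
  if (is.null(len)) len <- rep(1, nrow(tree$edge))
  w <- 1 / len

  i <- tree$edge[, 1]
  j <- tree$edge[, 2]
  # Laplacian of the tree with conductance weights
  L <- Matrix::sparseMatrix(i = c(i, j, i, j), j = c(j, i, i, j),
                            x = c(-w, -w, w, w), dims = c(n_all, n_all))
  int <- (n_tip + 1):n_all
  tipix <- seq_len(n_tip)
  rhs <- -L[int, tipix, drop = FALSE] %*% x_tip
  est <- as.numeric(Matrix::solve(L[int, int, drop = FALSE], rhs))

  labels <- if (!is.null(tree$node.label) &&
                all(nzchar(tree$node.label))) {
    tree$node.label
  } else as.character(int)
  all_states <- c(x_tip, est)
  structure(setNames(est, labels),
            method = "ML under Brownian motion (squared-change parsimony)",
            all_states = all_states,
            class = "ancestral_estimates")
}

#' Phylomorphospace coordinates
#'
#' Coordinates for plotting tips and reconstructed ancestors in a two-trait
#' plane (e.g., humidity by tone count) with tree edges drawn between parent
#' and child nodes. Internal-node positions come from [asr_brownian()] on
#' each trait.
#'
#' @param tree a \code{phylo} object.
#' @param trait_x,trait_y numeric vectors named by tip label.
#' @return List with \code{nodes} (data frame: \code{node}, \code{label},
#'   \code{type} tip/internal, \code{x}, \code{y}) and \code{edges} (data
#'   frame: \code{parent}, \code{child} as node numbers).
#' @export
phylomorpho_layout <- function(tree, trait_x, trait_y) {
  ax <- asr_brownian(tree, trait_x)
  ay <- asr_brownian(tree, trait_y)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  nodes <- data.frame(
    node = seq_len(n_all),
    label = c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label else
                as.character((n_tip + 1):n_all)),
    type = rep(c("tip", "internal"), c(n_tip, tree$Nnode)),
    x = attr(ax, "all_states"),
    y = attr(ay, "all_states"),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(parent = tree$edge[, 1], child = tree$edge[, 2])
  list(nodes = nodes, edges = edges)
}
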