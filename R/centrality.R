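# Weighted signed network centrality. Shortest paths are computed on the
# inverse-absolute-weight distance graph (edge length 1/|w|), the
# convention of the network-psychometrics centrality software: a stronger
# association is a shorter distance, and the sign of an edge is irrelevant
# to path lengths.

check_weight_matrix <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W) ||
      max(abs(W - t(W))) > 1e-8 || any(abs(diag(W)) > 1e-12)) {
    swim_stop("W must be a symmetric weight matrix with zero diagonal",
              "swimnet_domain_error")
  }
  invisible(W)
}

# igraph of the thresholded weight matrix; E()$weight holds the distance
# 1/|w|, E()$weight_signed the signed partial correlation.
weight_graph <- function(W, threshold = 1e-8) {
  check_weight_matrix(W)
  A <- abs(W)
  A[A <= threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g, names = FALSE)
    igraph::E(g)$weight_signed <- W[el]
    igraph::E(g)$weight <- 1 / igraph::E(g)$weight
  }
  g
}

#' Distance graph of a weighted network
#'
#' Converts a partial-correlation weight matrix into the shortest-path
#' distance graph: an edge exists where `|w_ij|` exceeds `threshold`, with
#' length `1 / |w_ij|` (signs ignored).
#'
#' @param W Symmetric weight matrix with zero diagonal.
#' @param threshold Edge-presence threshold on `|w|`, default 1e-8.
#' @return An [igraph][igraph::graph_from_adjacency_matrix] graph whose
#'   edge attribute `weight` is the distance `1/|w|`.
#' @export
distance_graph <- function(W, threshold = 1e-8) {
  weight_graph(W, threshold)
}

#' Node centrality measures of a weighted signed network
#'
#' @description
#' The three standard measures on the inverse-absolute-weight distance
#' graph:
#'
#' * `node_strength()`: sum of the absolute weights of the edges incident
#'   to each node (row sums of `|W|`).
#' * `node_closeness()`: `1 / sum_j d(i, j)` over the weighted
#'   shortest-path distances; 0 for a node that cannot reach every other
#'   node.
#' * `node_betweenness()`: for every unordered pair of other nodes, the
#'   fraction of shortest paths passing through the node, summed
#'   (fractional counting among tied shortest paths).
#'
#' All three are invariant to flipping the sign of every weight.
#'
#' @param W Symmetric weight matrix with zero diagonal.
#' @param threshold Edge-presence threshold on `|w|`, default 1e-8.
#' @return Named numeric vector, one value per node.
#' @examples
#' W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 0.5; W[2, 3] <- W[3, 2] <- 0.5
#' node_strength(W)    # 0.5 1.0 0.5
#' node_betweenness(W) # 0 1 0
#' @export
node_strength <- function(W, threshold = 1e-8) {
  check_weight_matrix(W)
  A <- abs(W)
  A[A <= threshold] <- 0
  stats::setNames(rowSums(A), rownames(W))
}

#' @rdname node_strength
#' @export
node_closeness <- function(W, threshold = 1e-8) {
  check_weight_matrix(W)
  g <- weight_graph(W, threshold)
  D <- igraph::distances(g, weights = igraph::E(g)$weight)
  p <- ncol(W)
  out <- vapply(seq_len(p), function(i) {
    d <- D[i, -i]
    if (length(d) == 0 || any(!is.finite(d))) 0 else 1 / sum(d)
  }, numeric(1))
  stats::setNames(out, rownames(W))
}

#' @rdname node_strength
#' @export
node_betweenness <- function(W, threshold = 1e-8) {
  check_weight_matrix(W)
  g <- weight_graph(W, threshold)
  b <- igraph::betweenness(g, weights = igraph::E(g)$weight,
                           directed = FALSE)
  stats::setNames(as.numeric(b), rownames(W))
}

# (x - mean) / sd; constant vectors map to all zeros with a warning.
zscore <- function(x, label = "values") {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    warning(sprintf("%s are constant across nodes: z-scores set to 0", label),
            call. = FALSE)
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Centrality table with z-scores
#'
#' Computes betweenness, closeness and strength for every node of a
#' weighted network and standardizes each measure to a z-score over all
#' nodes. A dichotomous gender node, when present, is included in the
#' standardization (its z-scores are reported) but flagged as excluded
#' from substantive interpretation, since a fixed attribute does not
#' change over a season.
#'
#' @param x A [pcnetwork()] fit or a symmetric weight matrix.
#' @param groups Optional node groups (taken from the fit when available).
#' @param exclude Character vector of node names to flag as not
#'   interpretable (default `"gender"` where present).
#' @param threshold Edge-presence threshold on `|w|`.
#' @return Data frame with columns `node`, `group`, `excluded`,
#'   `betweenness`, `closeness`, `strength` (raw values) and
#'   `betweenness_z`, `closeness_z`, `strength_z`.
#' @export
centrality_table <- function(x, groups = NULL, exclude = "gender",
                             threshold = 1e-8) {
  if (inherits(x, "pcnetwork")) {
    W <- x$weights
    if (is.null(groups)) groups <- x$nodes$group
    threshold <- x$threshold
  } else {
    W <- as.matrix(x)
  }
  check_weight_matrix(W)
  p <- ncol(W)
  if (p < 2L) {
    swim_stop("centrality standardization needs at least two nodes",
              "swimnet_insufficient_graph")
  }
  nms <- rownames(W)
  if (is.null(nms)) nms <- paste0("V", seq_len(p))
  if (is.null(groups)) groups <- rep(1L, p)
  bet <- node_betweenness(W, threshold)
  clo <- node_closeness(W, threshold)
  str <- node_strength(W, threshold)
  data.frame(
    node = nms,
    group = groups,
    excluded = nms %in% exclude,
    betweenness = as.numeric(bet),
    closeness = as.numeric(clo),
    strength = as.numeric(str),
    betweenness_z = zscore(as.numeric(bet), "betweenness values"),
    closeness_z = zscore(as.numeric(clo), "closeness values"),
    strength_z = zscore(as.numeric(str), "strength values"),
    stringsAsFactors = FALSE
  )
}
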