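#' Graph-theoretic node importance measures
#'
#' One row per node with the measures used to explain node ictogenicity:
#' degree (plus in-/out-degree and their sum and product for directed
#' graphs), average neighbour degree, eigenvector centrality, eigenvector
#' centrality of the Jaccard-dissimilarity matrix, dynamical importance,
#' betweenness centrality, closeness centrality, local clustering
#' coefficient, and local efficiency.
#'
#' Eigenvector centrality of a directed graph follows the in-edge
#' convention: a node is central when its in-neighbours are central
#' (leading eigenvector of the transposed adjacency), matching the direction
#' in which dynamical influence flows through the coupling.  Closeness and
#' clustering for directed graphs are computed on the underlying undirected
#' graph to keep them finite and comparable.
#'
#' @param g a connected `igraph` graph (binary).
#' @return a `data.frame`, one row per node.
#' @examples
#' node_metrics(igraph::make_star(5, mode = "undirected"))
#' @export
node_metrics <- function(g) {
  n <- igraph::vcount(g)
  directed <- igraph::is_directed(g)
  gu <- if (directed) igraph::as_undirected(g, mode = "collapse") else g

  deg_all <- igraph::degree(g, mode = "all")
  nbrs <- igraph::as_adj_list(g, mode = "all")
  and <- vapply(nbrs, function(v) mean(deg_all[as.integer(v)]), numeric(1))

  cl <- igraph::transitivity(gu, type = "local", isolates = "zero")
  out <- data.frame(
    node = seq_len(n),
    degree = if (directed) igraph::degree(g, mode = "in") +
      igraph::degree(g, mode = "out") else igraph::degree(g),
    avg_neighbour_degree = and,
    eigenvector = eigencentrality(g),
    jaccard_eigen = jaccard_eigencentrality(g),
    dyn_importance = dynamical_importance(g),
    betweenness = igraph::betweenness(g, directed = directed),
    closeness = igraph::closeness(gu),
    clustering = cl,
    local_efficiency = igraph::local_efficiency(g, directed = directed)
  )
  if (directed) {
    out$in_degree <- igraph::degree(g, mode = "in")
    out$out_degree <- igraph::degree(g, mode = "out")
    out$degree_sum <- out$in_degree + out$out_degree
    out$degree_product <- out$in_degree * out$out_degree
    out$degree <- NULL  # replaced by the four directed variants
  }
  out
}

# leading-eigenvector centrality, unit maximum; directed graphs use the
# transpose (in-edge) convention
eigencentrality <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  if (igraph::is_directed(g)) A <- t(A)
  if (isSymmetric(A)) {
    v <- eigen(A, symmetric = TRUE)$vectors[, 1]
  } else {
    ev <- eigen(A)
    v <- Re(ev$vectors[, which.max(Re(ev$values))])
  }
  v <- abs(v)
  v / max(v)
}

#' Dynamical importance
#'
#' Relative drop of the leading adjacency eigenvalue when a node is removed:
#' \eqn{DI_i = (\lambda_{max} - \lambda_{max}^{(-i)}) / \lambda_{max}},
#' recomputed exactly for every removal (no perturbative approximation).
#'
#' @param g an `igraph` graph with a positive leading eigenvalue.
#' @return numeric vector of per-node values, each at most 1.
#' @examples
#' dynamical_importance(igraph::make_full_graph(4))  # all 1/3
#' @export
dynamical_importance <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  sym <- isSymmetric(A)
  lead <- function(M) {
    if (nrow(M) == 0) return(0)
    if (sym) max(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    else max(Re(eigen(M, only.values = TRUE)$values))
  }
  lam <- lead(A)
  if (lam <= 0) stop("degenerate graph: leading adjacency eigenvalue is not positive")
  vapply(seq_len(nrow(A)), function(i) {
    (lam - lead(A[-i, -i, drop = FALSE])) / lam
  }, numeric(1))
}

#' Eigenvector centrality on the Jaccard-dissimilarity matrix
#'
#' Builds the node-node dissimilarity matrix
#' \eqn{D_{ij} = 1 - |N(i) \cap N(j)| / |N(i) \cup N(j)|} over neighbourhood
#' sets (in-neighbourhoods for directed graphs) and returns the leading
#' eigenvector of `D`, normalized to unit maximum.
#'
#' @param g an `igraph` graph.
#' @export
jaccard_eigencentrality <- function(g) {
  mode <- if (igraph::is_directed(g)) "in" else "all"
  S <- as.matrix(igraph::similarity(g, method = "jaccard", mode = mode))
  D <- 1 - S
  diag(D) <- 0
  v <- abs(eigen(D, symmetric = TRUE)$vectors[, 1])
  v / max(v)
}
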