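#' Generate an artificial network topology
#'
#' Draws a connected graph from one of four families used to study how
#' network structure shapes ictogenicity: Erdos-Renyi random graphs,
#' configuration-model scale-free graphs with degree distribution
#' \eqn{P(k) \sim k^{-\gamma}}, Watts-Strogatz small-world graphs, and
#' planted rich-club graphs.  Draws with disconnected components are
#' discarded and redrawn (weak connectivity for directed graphs).
#'
#' Mean degree is counted as the mean in-degree for directed graphs (equal to
#' the mean out-degree) and the usual \eqn{2E/N} for undirected graphs.
#'
#' For `rich_club`, `p1` is the connection probability inside the club and
#' `p2` between club and periphery; the periphery-periphery probability is
#' solved so that the expected mean degree equals `mean_degree`.
#'
#' For directed `small_world` graphs the ring lattice is laid down as
#' reciprocal arcs and rewiring moves arc heads only, preserving out-degrees.
#' Directed `scale_free` graphs draw in- and out-degree sequences
#' independently (balanced to a common sum).
#'
#' @param family one of `"random"`, `"scale_free"`, `"small_world"`,
#'   `"rich_club"`.
#' @param n number of nodes.
#' @param mean_degree target mean degree `c`.
#' @param directed logical.
#' @param gamma scale-free exponent (> 1); degree sequence is drawn from a
#'   truncated power law on `[k_min, n - 1]` with `k_min` solved so that the
#'   expected mean degree is `mean_degree`.
#' @param p_rewire Watts-Strogatz rewiring probability.
#' @param club_size,p1,p2 rich-club parameters (club size, internal and
#'   club-periphery connection probabilities).
#' @param seed optional integer seed (the caller's RNG stream is restored).
#' @param max_tries redraw cap for the connectivity loop.
#' @return an `igraph` graph with graph attribute `family` and vertex
#'   attribute `orig_id` (stable node labels used to key simulation noise
#'   streams); rich-club graphs also carry a logical vertex attribute `club`.
#' @examples
#' g <- generate_network("rich_club", n = 64, mean_degree = 6,
#'                       club_size = 10, p1 = 0.7, p2 = 0.2, seed = 1)
#' igraph::vcount(g)
#' @export
generate_network <- function(family = c("random", "scale_free", "small_world",
                                        "rich_club"),
                             n, mean_degree, directed = FALSE,
                             gamma = 3, p_rewire = 0.5,
                             club_size = 10, p1 = 0.7, p2 = 0.2,
                             seed = NULL, max_tries = 1000) {
  family <- match.arg(family)
  stopifnot(n >= 3, mean_degree > 0, mean_degree < n)
  if (family == "scale_free" && gamma <= 1) stop("gamma must be > 1")
  if (family == "rich_club" && club_size >= n) stop("club_size must be < n")
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      g <- switch(family,
        random      = gen_random(n, mean_degree, directed),
        scale_free  = gen_scale_free(n, mean_degree, directed, gamma),
        small_world = gen_small_world(n, mean_degree, directed, p_rewire),
        rich_club   = gen_rich_club(n, mean_degree, directed, club_size, p1, p2)
      )
      if (!is.null(g) && igraph::is_connected(g, mode = "weak")) {
        igraph::V(g)$orig_id <- seq_len(n)
        g <- igraph::set_graph_attr(g, "family", family)
        g <- igraph::set_graph_attr(g, "mean_degree_target", mean_degree)
        return(g)
      }
    }
    stop("could not generate a connected '", family, "' graph in ",
         max_tries, " tries (mean_degree too small?)")
  })
}

gen_random <- function(n, c, directed) {
  igraph::sample_gnp(n, c / (n - 1), directed = directed)
}

# expected value of the truncated rounded power-law degree for a given k_min
powerlaw_mean <- function(k_min, gamma, k_max, m = 4096) {
  u <- (seq_len(m) - 0.5) / m
  k <- pmin(pmax(round(k_min * u^(-1 / (gamma - 1))), 1), k_max)
  mean(k)
}

draw_powerlaw_degrees <- function(n, gamma, c, k_max) {
  if (powerlaw_mean(0.51, gamma, k_max) > c)
    stop("mean_degree too small for a power-law sequence with this gamma")
  k_min <- stats::uniroot(function(km) powerlaw_mean(km, gamma, k_max) - c,
                          c(0.51, k_max), tol = 1e-4)$root
  u <- stats::runif(n)
  pmin(pmax(round(k_min * u^(-1 / (gamma - 1))), 1), k_max)
}

gen_scale_free <- function(n, c, directed, gamma) {
  if (!directed) {
    k <- draw_powerlaw_degrees(n, gamma, c, n - 1)
    if (sum(k) %% 2 == 1) {
      i <- sample.int(n, 1)
      k[i] <- if (k[i] < n - 1) k[i] + 1 else k[i] - 1
    }
    # exact simple realization of the degree sequence where possible
    g <- tryCatch(igraph::sample_degseq(k, method = "vl"),
                  error = function(e) NULL)
    if (is.null(g))
      g <- tryCatch(
        igraph::simplify(igraph::sample_degseq(k, method = "configuration")),
        error = function(e) NULL)
    g
  } else {
    kin <- draw_powerlaw_degrees(n, gamma, c, n - 1)
    kout <- draw_powerlaw_degrees(n, gamma, c, n - 1)
    d <- sum(kout) - sum(kin)
    while (d != 0) {  # balance totals by unit adjustments on random nodes
      i <- sample.int(n, 1)
      if (d > 0 && kin[i] < n - 1) { kin[i] <- kin[i] + 1; d <- d - 1 }
      else if (d < 0 && kout[i] < n - 1) { kout[i] <- kout[i] + 1; d <- d + 1 }
    }
    g <- tryCatch(igraph::sample_degseq(kout, kin, method = "configuration"),
                  error = function(e) NULL)
    if (!is.null(g)) igraph::simplify(g) else NULL
  }
}

gen_small_world <- function(n, c, directed, p_rewire) {
  nei <- max(1L, round(c / 2))
  if (!directed)
    return(igraph::simplify(igraph::sample_smallworld(1, n, nei, p_rewire)))
  # reciprocal ring lattice, then rewire arc heads with probability p_rewire
  ring <- igraph::sample_smallworld(1, n, nei, 0)
  el <- igraph::as_edgelist(ring, names = FALSE)
  el <- rbind(el, el[, 2:1, drop = FALSE])
  adj <- matrix(FALSE, n, n)
  adj[el] <- TRUE
  for (e in seq_len(nrow(el))) {
    if (stats::runif(1) < p_rewire) {
      tails <- el[e, 1]
      cand <- which(!adj[tails, ] & seq_len(n) != tails)
      if (length(cand)) {
        new_head <- cand[sample.int(length(cand), 1)]
        adj[tails, el[e, 2]] <- FALSE
        adj[tails, new_head] <- TRUE
        el[e, 2] <- new_head
      }
    }
  }
  igraph::graph_from_edgelist(el, directed = TRUE)
}

gen_rich_club <- function(n, c, directed, m, p1, p2) {
  np <- n - m
  if (!directed) {
    need <- n * c / 2 - p1 * choose(m, 2) - p2 * m * np
    p3 <- need / choose(np, 2)
  } else {
    # p2 applies to club -> periphery arcs only; periphery -> club arcs
    # occur at the background rate p3
    need <- n * c - p1 * m * (m - 1) - p2 * m * np
    p3 <- need / (np * (np - 1) + np * m)
  }
  if (p3 < 0)
    stop("rich-club spec infeasible: mean_degree too small for (p1, p2)")
  if (p3 > 1) {
    warning("periphery-periphery probability clamped to 1")
    p3 <- 1
  }
  P <- matrix(p3, n, n)
  club <- seq_len(m)
  P[club, club] <- p1
  P[club, -club] <- p2
  if (!directed) P[-club, club] <- p2
  diag(P) <- 0
  if (!directed) {
    A <- matrix(0L, n, n)
    ut <- upper.tri(P)
    A[ut] <- as.integer(stats::runif(sum(ut)) < P[ut])
    A <- A + t(A)
  } else {
    A <- matrix(as.integer(stats::runif(n * n) < P), n, n)
    diag(A) <- 0L
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = if (directed) "directed"
                                           else "undirected")
  igraph::V(g)$club <- seq_len(n) <= m
  g
}

#' Mean degree of a graph
#'
#' Mean in-degree for directed graphs, `2E/N` for undirected ones.
#' @param g an `igraph` graph.
#' @export
mean_degree <- function(g) {
  e <- igraph::ecount(g)
  n <- igraph::vcount(g)
  if (igraph::is_directed(g)) e / n else 2 * e / n
}

#' Read a graph from a delimited file
#'
#' Accepts either a dense adjacency matrix (square, whitespace/comma
#' delimited; entry `(i, j)` is the weight of edge i -> j) or a 2/3-column
#' edge list with 0-based node indices (source, target, optional weight).
#'
#' @param path file path.
#' @param format `"adjacency"` or `"edgelist"`.
#' @param directed logical; for undirected adjacency input the matrix must be
#'   symmetric.
#' @param n_nodes for edge lists, optionally force the node count (isolated
#'   trailing nodes are otherwise dropped).
#' @return an `igraph` graph (weighted when weights are present and not all 1).
#' @export
read_network <- function(path, format = c("adjacency", "edgelist"),
                         directed = FALSE, n_nodes = NULL) {
  format <- match.arg(format)
  tab <- read.table(path, header = FALSE, sep = "", comment.char = "#")
  if (format == "adjacency") {
    A <- as.matrix(tab)
    dimnames(A) <- NULL
    if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
    if (!directed && any(abs(A - t(A)) > 1e-12))
      stop("undirected graph requires a symmetric adjacency matrix")
    mode <- if (directed) "directed" else "undirected"
    g <- igraph::graph_from_adjacency_matrix(A, mode = mode, weighted = TRUE,
                                             diag = FALSE)
    if (!is.null(igraph::E(g)$weight) && all(igraph::E(g)$weight == 1))
      g <- igraph::delete_edge_attr(g, "weight")
    g
  } else {
    el <- as.matrix(tab[, 1:2]) + 1L
    n <- n_nodes %||% max(el)
    g <- igraph::make_empty_graph(n, directed = directed)
    g <- igraph::add_edges(g, t(el))
    if (ncol(tab) >= 3) igraph::E(g)$weight <- tab[, 3]
    g
  }
}

#' Write a graph to a delimited file
#'
#' @param g an `igraph` graph.
#' @param path file path.
#' @param format `"adjacency"` (dense, tab-delimited) or `"edgelist"`
#'   (0-based indices, with a weight column when the graph is weighted).
#' @export
write_network <- function(g, path, format = c("adjacency", "edgelist")) {
  format <- match.arg(format)
  if (format == "adjacency") {
    A <- as.matrix(igraph::as_adjacency_matrix(
      g, attr = if ("weight" %in% igraph::edge_attr_names(g)) "weight" else NULL))
    write.table(A, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  } else {
    el <- igraph::as_edgelist(g, names = FALSE) - 1L
    if ("weight" %in% igraph::edge_attr_names(g))
      el <- cbind(el, igraph::E(g)$weight)
    write.table(el, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
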