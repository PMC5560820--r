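# coerce weighted-graph input (igraph or matrix) to a symmetric weight matrix
as_weight_matrix <- function(g) {
  if (igraph::is_igraph(g)) {
    if (igraph::is_directed(g)) stop("rich-club analysis expects an undirected graph")
    attr <- if ("weight" %in% igraph::edge_attr_names(g)) "weight" else NULL
    W <- as.matrix(igraph::as_adjacency_matrix(g, attr = attr))
  } else {
    W <- as.matrix(g)
    if (nrow(W) != ncol(W) || any(abs(W - t(W)) > 1e-12))
      stop("weight matrix must be square and symmetric")
  }
  diag(W) <- 0
  W
}

drop_negative <- function(W, negative = c("drop", "keep")) {
  negative <- match.arg(negative)
  if (negative == "drop") W[W < 0] <- 0
  W
}

#' Weighted rich-club coefficient at level k
#'
#' The club at richness level `k` is the set of nodes with degree (count of
#' nonzero incident edges) strictly greater than `k`.  The coefficient is
#' the total weight on edges internal to the club divided by the sum of the
#' equally many strongest edge weights anywhere in the network:
#' \deqn{\phi^w(k) = W_{>k} \big/ \sum_{l=1}^{E_{>k}} w_l^{rank}.}
#'
#' @param g undirected weighted graph (`igraph` or symmetric matrix).
#' @param k richness level (degree).
#' @param negative how to treat negative weights (surrogate-corrected
#'   functional networks can produce them): `"drop"` removes those edges,
#'   `"keep"` retains them.
#' @return the coefficient, or `NA` when the club has no internal edge.
#' @export
phi_weighted <- function(g, k, negative = "drop") {
  W <- drop_negative(as_weight_matrix(g), negative)
  phi_weighted_mat(W, k)
}

phi_weighted_mat <- function(W, k) {
  deg <- colSums(W != 0)
  club <- which(deg > k)
  if (length(club) < 2) return(NA_real_)
  sub <- W[club, club, drop = FALSE]
  ut <- upper.tri(sub)
  e_k <- sum(sub[ut] != 0)
  if (e_k == 0) return(NA_real_)
  w_k <- sum(sub[ut])
  all_w <- sort(W[upper.tri(W)][W[upper.tri(W)] != 0], decreasing = TRUE)
  w_k / sum(all_w[seq_len(e_k)])
}

#' Null ensemble for the weighted rich club
#'
#' Each null network applies (1) a uniform permutation of the weights over
#' the existing edges, then (2) degree-preserving double-edge swaps that
#' carry the weights with the edges.  Every draw preserves the degree
#' sequence and the weight multiset of the original network exactly.
#'
#' @param g undirected weighted graph (`igraph` or symmetric matrix).
#' @param n_null ensemble size.
#' @param n_sweeps swap attempts per edge.
#' @param seed optional RNG seed.
#' @param negative negative-weight handling (see [phi_weighted()]).
#' @return list of weight matrices.
#' @export
rc_null_ensemble <- function(g, n_null = 100, n_sweeps = 10, seed = NULL,
                             negative = "drop") {
  W <- drop_negative(as_weight_matrix(g), negative)
  n <- nrow(W)
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  ne <- nrow(idx)
  if (ne < 2) stop("not enough edges for a null ensemble")
  with_seed(seed, lapply(seq_len(n_null), function(r) {
    a <- idx[, 1]; b <- idx[, 2]
    w <- sample(W[idx])              # weight reshuffle on fixed topology
    adj <- matrix(FALSE, n, n)
    adj[cbind(a, b)] <- TRUE; adj[cbind(b, a)] <- TRUE
    n_attempt <- n_sweeps * ne
    for (t in seq_len(n_attempt)) {  # link-and-weight reshuffle
      e <- sample.int(ne, 2)
      x1 <- a[e[1]]; y1 <- b[e[1]]; x2 <- a[e[2]]; y2 <- b[e[2]]
      if (stats::runif(1) < 0.5) { tmp <- x2; x2 <- y2; y2 <- tmp }
      # propose x1-y2 and x2-y1
      if (x1 == y2 || x2 == y1) next
      if (length(unique(c(x1, y1, x2, y2))) < 4) next
      if (adj[x1, y2] || adj[x2, y1]) next
      adj[x1, y1] <- adj[y1, x1] <- FALSE
      adj[x2, y2] <- adj[y2, x2] <- FALSE
      adj[x1, y2] <- adj[y2, x1] <- TRUE
      adj[x2, y1] <- adj[y1, x2] <- TRUE
      b[e[1]] <- y2
      a[e[2]] <- x2  # x2/y2 may have been orientation-flipped above
      b[e[2]] <- y1
    }
    Wn <- matrix(0, n, n)
    Wn[cbind(a, b)] <- w
    Wn[cbind(b, a)] <- w
    Wn
  }))
}

#' Normalized weighted rich-club profile
#'
#' Computes \eqn{\phi^w(k)} over all richness levels with a defined club,
#' the null-ensemble mean \eqn{\phi^{rand}(k)}, the normalized coefficient
#' \eqn{\phi(k) = \phi^w(k)/\phi^{rand}(k)}, and a one-sided permutation
#' p-value per level (the fraction of null coefficients at least as large
#' as the observed one).  Rich-club organization is indicated by a range of
#' `k` with \eqn{\phi(k) > 1}.
#'
#' @inheritParams rc_null_ensemble
#' @return an object of class `rich_club_profile`: a data frame with
#'   columns `k`, `phi_w`, `phi_rand`, `phi`, `p`, `club_size`, plus the
#'   node degrees as an attribute.
#' @export
rich_club_profile <- function(g, n_null = 100, n_sweeps = 10, seed = NULL,
                              negative = "drop") {
  stopifnot(n_null >= 20)
  W <- drop_negative(as_weight_matrix(g), negative)
  deg <- colSums(W != 0)
  ks <- 0:(max(deg) - 1)
  nulls <- rc_null_ensemble(W, n_null = n_null, n_sweeps = n_sweeps,
                            seed = seed, negative = "keep")
  obs <- vapply(ks, function(k) phi_weighted_mat(W, k), numeric(1))
  null_phi <- vapply(nulls, function(Wn)
    vapply(ks, function(k) phi_weighted_mat(Wn, k), numeric(1)),
    numeric(length(ks)))
  null_phi <- matrix(null_phi, nrow = length(ks))
  phi_rand <- rowMeans(null_phi, na.rm = TRUE)
  p <- vapply(seq_along(ks), function(i) {
    nn <- null_phi[i, !is.na(null_phi[i, ])]
    if (is.na(obs[i]) || !length(nn)) return(NA_real_)
    mean(nn >= obs[i])
  }, numeric(1))
  out <- data.frame(k = ks, phi_w = obs, phi_rand = phi_rand,
                    phi = obs / phi_rand, p = p,
                    club_size = vapply(ks, function(k) sum(deg > k),
                                       integer(1)))
  structure(out, degrees = deg, class = c("rich_club_profile", "data.frame"))
}

#' @export
print.rich_club_profile <- function(x, ...) {
  cat("<rich_club_profile>\n")
  print.data.frame(x[!is.na(x$phi), ], row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.rich_club_profile <- function(x, ...) {
  ok <- !is.na(x$phi)
  plot(x$k[ok], x$phi[ok], type = "b", pch = 16, xlab = "degree k",
       ylab = expression(phi(k)), ...)
  abline(h = 1, lty = 2)
  invisible(x)
}

#' Richest club of a profile
#'
#' The richest club is the set of nodes with degree greater than
#' \eqn{k_r = \arg\max_k \phi(k)} (ties resolved toward the smallest `k`).
#'
#' @param profile a [rich_club_profile()].
#' @return list with `k_r` and the integer vector `members`.
#' @export
richest_club <- function(profile) {
  ok <- which(!is.na(profile$phi))
  if (!length(ok)) stop("profile has no defined phi values")
  k_r <- profile$k[ok[which.max(profile$phi[ok])]]
  members <- which(attr(profile, "degrees") > k_r)
  if (!length(members)) stop("richest club is empty")
  list(k_r = k_r, members = members)
}

#' Fraction of the rich club removed by a resection
#'
#' @param members rich-club node set.
#' @param resected resected node set.
#' @return `|members intersect resected| / |members|`.
#' @export
fraction_resected <- function(members, resected) {
  stopifnot(length(members) > 0)
  length(intersect(members, resected)) / length(members)
}
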