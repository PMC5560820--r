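#' Weighted Kendall rank correlation of two NI vectors
#'
#' \deqn{\tau = (P - Q) / (P + Q)} where each node pair contributes the
#' weight \eqn{w_{ij} = |a_i - a_j| \cdot |b_i - b_j|} (the product of the
#' NI distances assigned by the two rankings) to the concordant sum `P` or
#' discordant sum `Q`.  With `weighted = FALSE` all pairs count 1 and the
#' usual Kendall tau of tie-free data is recovered.
#'
#' Exact ties have probability zero for simulated NI but can occur in
#' finite runs; they are broken by adding a deterministic index-proportional
#' jitter of relative size 1e-12 before comparison.
#'
#' @param a,b numeric vectors of equal length (>= 2) over the same nodes.
#' @param weighted use NI-distance product weights.
#' @return tau in `[-1, 1]`.
#' @examples
#' weighted_kendall(c(0.1, 0.2, 0.9), c(0.1, 0.9, 0.2))  # -33/65
#' @export
weighted_kendall <- function(a, b, weighted = TRUE) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  jit <- function(x) {
    if (anyDuplicated(x)) {
      s <- max(abs(x), 1)
      x + seq_along(x) * 1e-12 * s
    } else x
  }
  if (weighted) {
    da0 <- outer(a, a, "-")[upper.tri(diag(length(a)))]
    db0 <- outer(b, b, "-")[upper.tri(diag(length(b)))]
    if (all(abs(da0) * abs(db0) == 0))
      stop("weighted tau undefined: all pair weights are zero")
  }
  a <- jit(a); b <- jit(b)
  da <- outer(a, a, "-")
  db <- outer(b, b, "-")
  ut <- upper.tri(da)
  da <- da[ut]; db <- db[ut]
  w <- if (weighted) abs(da) * abs(db) else rep(1, length(da))
  conc <- sign(da) * sign(db) > 0
  (sum(w[conc]) - sum(w[!conc])) / sum(w)
}

#' Consistency of NI orderings across parameter sets or models
#'
#' Given NI vectors from several calibrated parameter sets (columns of a
#' matrix or a list), computes the weighted Kendall tau for every pair.
#' With two ensembles (`b` supplied, e.g. one per model) all cross pairs
#' are compared; `best = TRUE` returns only the maximizing pair, the
#' "best-pair" reading used when asking whether parameters exist for which
#' two models order nodes identically.
#'
#' @param a list (or columns of a matrix) of NI vectors over the same
#'   nodes.
#' @param b optional second ensemble for cross-comparison.
#' @param best return the maximum tau over cross pairs instead of all.
#' @return numeric vector of tau values (length 1 when `best = TRUE`).
#' @export
ni_consistency <- function(a, b = NULL, best = FALSE) {
  as_list <- function(x) {
    if (is.matrix(x)) lapply(seq_len(ncol(x)), function(j) x[, j]) else x
  }
  a <- as_list(a)
  if (is.null(b)) {
    pairs <- utils::combn(length(a), 2)
    taus <- apply(pairs, 2, function(ij)
      weighted_kendall(a[[ij[1]]], a[[ij[2]]]))
    return(taus)
  }
  b <- as_list(b)
  taus <- as.vector(vapply(a, function(x)
    vapply(b, function(y) weighted_kendall(x, y), numeric(1)),
    numeric(length(b))))
  if (best) max(taus) else taus
}

#' Regress NI on node-importance measures
#'
#' Ordinary least squares of NI on each measure separately (simple
#' regressions) and on all measures jointly, reporting coefficients of
#' determination.  To mirror ensemble analyses, rows from several network
#' realizations of the same topology should be pooled (e.g. with `rbind`)
#' before calling.
#'
#' @param metrics a [node_metrics()] data frame (a `node` column is
#'   ignored); collinear columns are dropped from the joint fit with a
#'   warning.
#' @param ni NI vector aligned with the rows of `metrics`.
#' @return list with `r2_single` (named vector) and `r2_multiple`.
#' @export
regress_ni <- function(metrics, ni) {
  X <- metrics[, setdiff(names(metrics), "node"), drop = FALSE]
  stopifnot(nrow(X) == length(ni))
  r2 <- function(fit) summary(fit)$r.squared
  r2_single <- vapply(names(X), function(v) {
    if (length(unique(X[[v]])) < 2) return(NA_real_)
    r2(lm(ni ~ x, data = data.frame(ni = ni, x = X[[v]])))
  }, numeric(1))
  fit <- lm(ni ~ ., data = cbind(ni = ni, X))
  if (anyNA(coef(fit)))
    warning("collinear measures dropped from the multiple regression: ",
            paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  list(r2_single = r2_single, r2_multiple = r2(fit))
}

#' Measurement-error-corrected regression of NI on node measures
#'
#' Simulation-based NI estimates carry Monte-Carlo noise, which biases the
#' coefficients of determination of [regress_ni()] toward zero by the
#' reliability of the NI estimate.  Given two independent NI replicates
#' (the same experiment under disjoint noise-seed sets), this estimates the
#' reliability of their mean by Spearman-Brown from the replicate
#' correlation and disattenuates the R-squared values of the regression on
#' the mean: \eqn{R^2_{true} = R^2_{obs} (1 + \rho) / (2 \rho)} where
#' \eqn{\rho} is the replicate correlation.  Because noise in the response
#' can only attenuate an R-squared, every observed R-squared is itself a
#' lower bound on the reliability; the working reliability is therefore the
#' larger of the Spearman-Brown estimate and the strongest observed
#' R-squared, which keeps the correction conservative when the equal-noise
#' error model is violated (heteroscedastic NI).  Corrected values are
#' clamped to `[0, 1]`; when even that reliability is below `min_rho` the
#' uncorrected values are returned with a warning.
#'
#' @param metrics a [node_metrics()] data frame (rows pooled across
#'   realizations as in [regress_ni()]).
#' @param ni_a,ni_b independent NI replicates aligned with `metrics`.
#' @param min_rho smallest replicate correlation for which the correction
#'   is applied.
#' @return as [regress_ni()], plus `reliability` (of the replicate mean)
#'   and the uncorrected `r2_single_raw` / `r2_multiple_raw`.
#' @export
regress_ni_reliable <- function(metrics, ni_a, ni_b, min_rho = 0.2) {
  stopifnot(length(ni_a) == length(ni_b))
  fit <- regress_ni(metrics, (ni_a + ni_b) / 2)
  rho <- cor(ni_a, ni_b)
  rel_sb <- 2 * rho / (1 + rho)
  # any observed R^2 is itself a lower bound on the reliability (noise in
  # the response can only attenuate), so the working reliability is the
  # larger of the Spearman-Brown estimate and the strongest observed R^2;
  # this keeps the correction conservative when the equal-noise error model
  # is violated (heteroscedastic NI)
  rel <- max(rel_sb, fit$r2_single, fit$r2_multiple, na.rm = TRUE)
  out <- list(r2_single_raw = fit$r2_single,
              r2_multiple_raw = fit$r2_multiple,
              reliability = rel)
  if (!is.finite(rel) || rel < min_rho) {
    warning("replicates barely correlate (rho = ", signif(rho, 3),
            "); returning uncorrected R^2")
    out$r2_single <- fit$r2_single
    out$r2_multiple <- fit$r2_multiple
  } else {
    out$r2_single <- pmin(fit$r2_single / rel, 1)
    out$r2_multiple <- min(fit$r2_multiple / rel, 1)
  }
  out
}
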