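# Reference sampling intervals defining the noise scale: `sigma` in the
# parameter objects is the standard deviation of the extrinsic noise sampled
# at the model's native step, so the white-noise intensity passed to the
# integrators is sigma * sqrt(tau_ref).  This keeps the dynamics invariant
# under refinement of the integration step dt.
CM_NOISE_REF <- 0.015  # canonical-model time units
WM_NOISE_REF <- 5e-3  # seconds

# expand an igraph into the directed edge arrays the integrators consume
edge_arrays <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  if (!igraph::is_directed(g)) el <- rbind(el, el[, 2:1, drop = FALSE])
  list(src = as.integer(el[, 1] - 1L), dst = as.integer(el[, 2] - 1L),
       n_arcs = nrow(el))
}

node_stream_ids <- function(g) {
  ids <- igraph::vertex_attr(g, "orig_id")
  if (is.null(ids)) seq_len(igraph::vcount(g)) else as.integer(ids)
}

#' Simulate a network of theta-neuron (canonical model) nodes
#'
#' Euler-Maruyama integration of
#' \deqn{\dot\theta_j = (1 - \cos\theta_j) + (1 + \cos\theta_j) I_j(t),}
#' \deqn{I_j(t) = I_0 + \xi_j(t) + \frac{1}{N}\sum_{i \ne j} w\, a_{ij}
#'   \left[1 - \cos(\theta_i - \theta_s^{(i)})\right],}
#' with independent white noise of intensity `sigma` per node.  Returned
#' output is the node activity \eqn{Y_j = 1 - \cos(\theta_j - \theta_s)},
#' subsampled every `stride` steps; full phase rotations through
#' \eqn{\theta_s + \pi} are counted as spikes.
#'
#' Noise streams are keyed by `(seed, orig_id)` so that runs are
#' reproducible bit-for-bit and a node's stream follows it through virtual
#' resections (common-random-number comparisons).  Time is dimensionless;
#' see [cm_time_unit()] for the conversion to Wendling-model seconds.
#'
#' @param g graph (`igraph`); coupling follows edge direction i -> j.
#' @param params a [cm_params()] object (`I0` may be a per-node vector).
#' @param duration simulated time after the transient (model units).
#' @param dt integration step.
#' @param seed integer seed for the simulation noise (independent of R's RNG).
#' @param stride output subsampling (output step `dt * stride`).
#' @param transient settling time discarded before recording.
#' @param n_ref reference network size for the `1/N` coupling prefactor.
#'   Defaults to the current node count; virtual-resection analyses pass the
#'   size of the intact network so that deleting a node changes only the
#'   adjacency, not the per-edge coupling gain.
#' @return an object of class `ictosim` with elements `output` (node x time
#'   matrix), `dt_out`, `duration`, `model`, `params`, `seed`, `node_ids`,
#'   `spike_count`.
#' @export
simulate_cm <- function(g, params, duration = 2000, dt = 1e-3, seed = 1,
                        stride = 20, transient = 20, n_ref = NULL) {
  stopifnot(inherits(params, "cm_params"))
  n <- igraph::vcount(g)
  n_pref <- n_ref %||% n
  ea <- edge_arrays(g)
  I0 <- rep_len(params$I0, n)
  ts <- theta_steady_state(I0)
  res <- simulate_cm_cpp(n, ea$src, ea$dst, rep(params$w, ea$n_arcs),
                         I0, ts, params$sigma * sqrt(CM_NOISE_REF), 1 / n_pref,
                         duration, dt, as.integer(stride), transient,
                         as.double(seed), node_stream_ids(g))
  structure(list(output = res$output, dt_out = res$dt_out,
                 duration = duration, model = "cm", params = params,
                 seed = seed, node_ids = node_stream_ids(g),
                 spike_count = res$spike_count),
            class = "ictosim")
}

#' Simulate a network of Wendling neural masses
#'
#' Euler-Maruyama integration of the 10 ODEs per node, with the extrinsic
#' input of node `j` given by
#' \deqn{p_j(t) = p_0 + \xi_j(t) + \frac{1}{N}\sum_{i \ne j} \lambda\,
#'   a_{ij}\, S(z_2^{(i)} - z_3^{(i)} - z_4^{(i)}),}
#' Gaussian white noise of intensity `sigma` entering the pyramidal input
#' equation.  The returned output is the aggregated pyramidal potential
#' `z2 - z3 - z4` (mV), subsampled every `stride` steps.
#'
#' The default `dt = 1e-4` s resolves the fastest time constant
#' (`1/g = 2` ms) with 20 steps.
#'
#' @inheritParams simulate_cm
#' @param params a [wm_params()] object (`p0` may be a per-node vector).
#' @param duration simulated seconds after the transient.
#' @return an object of class `ictosim` (see [simulate_cm()]).
#' @export
simulate_wm <- function(g, params, duration = 200, dt = 1e-4, seed = 1,
                        stride = 20, transient = 2, n_ref = NULL) {
  stopifnot(inherits(params, "wm_params"))
  n <- igraph::vcount(g)
  n_pref <- n_ref %||% n
  ea <- edge_arrays(g)
  p0 <- rep_len(params$p0, n)
  res <- simulate_wm_cpp(n, ea$src, ea$dst, rep(params$lambda, ea$n_arcs),
                         p0, params$sigma * sqrt(WM_NOISE_REF), 1 / n_pref,
                         wm_const_vec(params),
                         duration, dt, as.integer(stride), transient,
                         as.double(seed), node_stream_ids(g))
  structure(list(output = res$output, dt_out = res$dt_out,
                 duration = duration, model = "wm", params = params,
                 seed = seed, node_ids = node_stream_ids(g),
                 spike_count = NULL),
            class = "ictosim")
}

#' @export
print.ictosim <- function(x, ...) {
  cat(sprintf("<ictosim> %s model: %d nodes, %g time units (dt_out = %g), seed %s\n",
              toupper(x$model), nrow(x$output), x$duration, x$dt_out,
              format(x$seed)))
  invisible(x)
}

#' @export
plot.ictosim <- function(x, nodes = NULL, spread = NULL, ...) {
  y <- x$output
  nodes <- nodes %||% seq_len(min(nrow(y), 10))
  y <- y[nodes, , drop = FALSE]
  spread <- spread %||% (1.1 * max(apply(y, 1, function(r) diff(range(r)))))
  tt <- seq_len(ncol(y)) * x$dt_out
  off <- (seq_along(nodes) - 1) * spread
  matplot(tt, t(y + off), type = "l", lty = 1, col = "grey20",
          xlab = "time", ylab = "node output (offset)", yaxt = "n", ...)
  axis(2, at = off, labels = nodes, las = 1)
  invisible(x)
}

#' Export a simulation as a delimited matrix with a metadata header
#'
#' Writes `#`-prefixed header lines (model, dt, duration, seed) followed by
#' the node x time output matrix, tab-delimited.
#'
#' @param sim an `ictosim` object.
#' @param path file path.
#' @export
write_sim <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# model %s", sim$model), con)
  writeLines(sprintf("# dt_out %.10g", sim$dt_out), con)
  writeLines(sprintf("# duration %.10g", sim$duration), con)
  writeLines(sprintf("# seed %s", format(sim$seed)), con)
  write.table(sim$output, con, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
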