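#' Full width at half maximum of the spikes in a simulation
#'
#' Median width at half of the peak-to-baseline amplitude across the spikes
#' of the (first-node) output trace.  Intended for noiseless suprathreshold
#' single-node runs, where it defines the spike time scale of a model.
#'
#' @param sim an `ictosim` object.
#' @return width in the model's time units.
#' @export
spike_fwhm <- function(sim) {
  x <- sim$output[1, ]
  base <- min(x)
  amp <- max(x) - base
  if (amp < 1e-9) stop("no spikes in the trace")
  above <- x > base + amp / 2
  runs <- rle(above)
  w <- runs$lengths[runs$values]
  # drop pulses truncated by the record boundaries
  if (length(w) && runs$values[1]) w <- w[-1]
  if (length(w) && runs$values[length(runs$values)]) w <- w[-length(w)]
  if (!length(w)) stop("no complete spike in the trace")
  median(w) * sim$dt_out
}

# FWHM of a single uncoupled noiseless node driven `distance` beyond the
# bifurcation; cached
model_fwhm <- function(model, distance, wm_const = wm_params()) {
  key <- paste0("fwhm|", model, "|", signif(distance, 8), "|",
                if (model == "wm") wm_const_key(wm_const) else "")
  cache_get(key, function() {
    g1 <- igraph::make_empty_graph(1, directed = FALSE)
    if (model == "cm") {
      sim <- simulate_cm(g1, cm_params(I0 = distance, sigma = 0, w = 0),
                         duration = 60, dt = 1e-3, stride = 1,
                         transient = 10, seed = 0)
    } else {
      p <- wm_const
      p$p0 <- wm_critical_input(wm_const) + distance
      p$sigma <- 0; p$lambda <- 0
      sim <- simulate_wm(g1, p, duration = 10, dt = 1e-4, stride = 5,
                         transient = 4, seed = 0)
    }
    spike_fwhm(sim)
  })
}

#' Time-unit conversion between the canonical and Wendling models
#'
#' The canonical model's time is dimensionless; window-based spike-epoch
#' logic needs it expressed in Wendling-model seconds.  The conversion scale
#' is the ratio of the full widths at half maximum of the two models' spikes
#' (both measured the same distance beyond their bifurcation): the returned
#' value is the number of canonical time units corresponding to one second.
#'
#' @param distance distance beyond the bifurcation at which both spike
#'   widths are measured.
#' @param wm_const a [wm_params()] object supplying the Wendling constants.
#' @return canonical time units per second.
#' @export
cm_time_unit <- function(distance = 1.2, wm_const = wm_params()) {
  model_fwhm("cm", distance) / model_fwhm("wm", distance, wm_const)
}

# detection windows (in the model's own time units) for a simulation:
# 0.05 s spike-averaging window and 1 s epoch window, canonical-model
# windows scaled by the FWHM ratio
detection_windows <- function(sim) {
  if (sim$model == "wm") {
    list(spike = 0.05, epoch = 1)
  } else {
    distance <- abs(sim$params$I_c - min(sim$params$I0))
    tu <- cm_time_unit(max(distance, 0.1))
    list(spike = 0.05 * tu, epoch = 1 * tu)
  }
}

# windowed amplitude of a noiseless suprathreshold spike train, giving the
# scale genuine spikes reach under the detection window; cached
spike_peak <- function(model, distance, wm_const = wm_params()) {
  key <- paste0("peak|", model, "|", signif(distance, 8), "|",
                if (model == "wm") wm_const_key(wm_const) else "")
  cache_get(key, function() {
    g1 <- igraph::make_empty_graph(1, directed = FALSE)
    if (model == "cm") {
      sim <- simulate_cm(g1, cm_params(I0 = distance, sigma = 0, w = 0),
                         duration = 60, dt = 1e-3, stride = 20,
                         transient = 10, seed = 0)
    } else {
      p <- wm_const
      p$p0 <- wm_critical_input(wm_const) + distance
      p$sigma <- 0; p$lambda <- 0
      sim <- simulate_wm(g1, p, duration = 10, dt = 1e-4, stride = 20,
                         transient = 4, seed = 0)
    }
    wins <- detection_windows(sim)
    x <- sim$output[1, ]
    max(running_mean(abs(x - mean(x)), round(wins$spike / sim$dt_out)))
  })
}

# detection threshold: the larger of 5x the rest-state noise floor of an
# uncoupled node at the same distance and noise level, and half the windowed
# amplitude a genuine noiseless spike reaches; cached per (model, distance,
# sigma)
spike_threshold <- function(model, params) {
  # heterogeneous mean inputs: the noise floor belongs to the resting
  # (deepest subthreshold) node
  if (model == "cm") {
    distance <- abs(params$I_c - min(params$I0))
    key <- paste0("thr|cm|", signif(distance, 8), "|", signif(params$sigma, 8))
  } else {
    distance <- wm_critical_input(params) - min(params$p0)
    key <- paste0("thr|wm|", signif(distance, 8), "|", signif(params$sigma, 8),
                  "|", wm_const_key(params))
  }
  cache_get(key, function() {
    g1 <- igraph::make_empty_graph(1, directed = FALSE)
    if (model == "cm") {
      p <- params; p$w <- 0; p$I0 <- -distance
      sim <- simulate_cm(g1, p, duration = 500, seed = 9999)
    } else {
      p <- params; p$lambda <- 0; p$p0 <- wm_critical_input(params) - distance
      sim <- simulate_wm(g1, p, duration = 30, seed = 9999)
    }
    x <- sim$output[1, ]
    x <- x - mean(x)
    # iteratively clip excursions so rare noise-driven spikes in the
    # calibration run do not inflate the rest-state floor
    for (i in 1:4) if (sd(x) > 0) x <- x[abs(x) < 6 * sd(x)]
    floor_sd <- if (length(x) < 2 || !is.finite(sd(x))) 0 else sd(x)
    max(5 * floor_sd, 0.5 * spike_peak(model, distance, params))
  })
}

#' Detect spiking epochs in a simulation
#'
#' Spikes are local maxima of the mean absolute amplitude of the
#' (mean-removed) node output over a 0.05 s sliding window that exceed a
#' threshold; contiguous epochs of spiking dynamics are then formed by
#' taking the union of 1 s windows centred on each spike.  For the canonical
#' model both windows are scaled by the spike-width ratio of the two models
#' (see [cm_time_unit()]).
#'
#' The default threshold is five (robust) standard deviations of the
#' windowed amplitude of an uncoupled node at the same noise level -- the
#' subthreshold noise floor -- and is cached per parameter set.
#'
#' @param sim an `ictosim` object.
#' @param threshold detection threshold on the windowed amplitude (default:
#'   noise-floor calibration).
#' @param spike_window,epoch_window override the window lengths (model time
#'   units).
#' @return an object of class `spike_epochs`: per-node epoch interval
#'   matrices, per-node time fractions spent in spiking dynamics, and the
#'   total time.
#' @export
detect_spikes <- function(sim, threshold = NULL, spike_window = NULL,
                          epoch_window = NULL) {
  wins <- detection_windows(sim)
  sw <- spike_window %||% wins$spike
  ew <- epoch_window %||% wins$epoch
  thr <- threshold %||% spike_threshold(sim$model, sim$params)
  dt <- sim$dt_out
  total <- ncol(sim$output) * dt
  w_samp <- max(3L, round(sw / dt))
  n <- nrow(sim$output)
  intervals <- vector("list", n)
  fraction <- numeric(n)
  spike_times <- vector("list", n)
  for (j in seq_len(n)) {
    x <- sim$output[j, ]
    m <- running_mean(abs(x - mean(x)), w_samp)
    pk <- local_maxima(m)
    pk <- pk[m[pk] > thr]
    st <- (pk - 1) * dt
    spike_times[[j]] <- st
    if (length(st)) {
      iv <- cbind(pmax(st - ew / 2, 0), pmin(st + ew / 2, total))
      iv <- interval_union(iv)
    } else iv <- matrix(numeric(0), ncol = 2)
    intervals[[j]] <- iv
    fraction[j] <- if (nrow(iv)) sum(iv[, 2] - iv[, 1]) / total else 0
  }
  structure(list(intervals = intervals, fraction = fraction,
                 spike_times = spike_times, total_time = total,
                 model = sim$model),
            class = "spike_epochs")
}

#' Brain network ictogenicity of detected epochs
#'
#' BNI is the average over nodes of the fraction of simulated time spent in
#' spiking dynamics.  Given a list of `spike_epochs` (multiple noise
#' realizations) the per-realization BNIs are averaged.
#'
#' @param epochs a `spike_epochs` object or a list of them.
#' @return scalar in `[0, 1]`.
#' @export
compute_bni <- function(epochs) {
  if (inherits(epochs, "spike_epochs")) return(mean(epochs$fraction))
  mean(vapply(epochs, function(e) mean(e$fraction), numeric(1)))
}

# simulate + detect for one seed
sim_epochs <- function(g, model, params, seed, duration = NULL, ...) {
  sim <- if (model == "cm") {
    simulate_cm(g, params, duration = duration %||% 2000, seed = seed, ...)
  } else {
    simulate_wm(g, params, duration = duration %||% 200, seed = seed, ...)
  }
  detect_spikes(sim)
}

#' BNI of a network under a model and parameter set
#'
#' Simulates the network for each seed, detects spiking epochs and averages
#' the per-node spiking-time fractions.
#'
#' @param g graph.
#' @param model `"cm"` or `"wm"`.
#' @param params matching parameter object.
#' @param seeds integer vector of noise seeds.
#' @param duration simulation length (model time units; default 2000 for the
#'   canonical model, 200 s for the Wendling model).
#' @param ... passed to the simulator.
#' @return list with `bni` (scalar), `node_fractions` (seed-averaged),
#'   `n_seeds`.
#' @export
network_bni <- function(g, model = c("cm", "wm"), params, seeds = 1:3,
                        duration = NULL, ...) {
  model <- match.arg(model)
  eps <- lapply(seeds, function(s)
    sim_epochs(g, model, params, seed = s, duration = duration, ...))
  fr <- rowMeans(matrix(vapply(eps, `[[`, numeric(igraph::vcount(g)),
                               "fraction"), nrow = igraph::vcount(g)))
  list(bni = mean(fr), node_fractions = fr, n_seeds = length(seeds))
}

#' Calibrate the coupling to a reference BNI
#'
#' Bisects on the starred coupling until the network BNI (averaged over
#' noise seeds) is within `tol` of `target_bni`.  All sweeps are performed
#' in the starred parameterization: the noise is fixed through
#' `sigma_star = sigma / distance` and the coupling through the scaled
#' `w_star` (canonical) or `lambda_star` (Wendling).
#'
#' @param g graph.
#' @param model `"cm"` or `"wm"`.
#' @param distance distance to the SNIC bifurcation (`I_c - I0` or
#'   `p_c - p0`).
#' @param sigma_star scaled noise intensity.
#' @param target_bni reference BNI (0.5 in the main analyses; 0.3 and 0.7
#'   for robustness checks).
#' @param tol calibration tolerance on BNI.
#' @param seeds noise seeds per BNI evaluation (at least 3 recommended).
#' @param duration simulation length per evaluation.
#' @param coupling_max upper limit for the bracket search.
#' @param max_iter bisection iteration cap.
#' @param ... passed to the simulator.
#' @return an object of class `icto_calibration`: `coupling_star`, `params`
#'   (raw calibrated parameters), `bni`, `target_bni`, `evaluations`.
#' @export
calibrate_coupling <- function(g, model = c("cm", "wm"), distance = 1.2,
                               sigma_star = 5, target_bni = 0.5, tol = 0.05,
                               seeds = 1:3, duration = NULL,
                               coupling_max = 256, max_iter = 25, ...) {
  model <- match.arg(model)
  pfun <- function(ws) {
    if (model == "cm") cm_from_starred(distance, sigma_star, ws, g)
    else wm_from_starred(distance, sigma_star, ws, g)
  }
  evals <- list()
  f <- function(ws) {
    b <- network_bni(g, model, pfun(ws), seeds = seeds,
                     duration = duration, ...)$bni
    evals[[length(evals) + 1]] <<- c(coupling_star = ws, bni = b)
    b
  }
  b_lo <- f(0)
  if (b_lo > target_bni + tol)
    stop(sprintf("target BNI %.2f unreachable: BNI at zero coupling is already %.3f",
                 target_bni, b_lo))
  if (abs(b_lo - target_bni) <= tol) {
    return(structure(list(coupling_star = 0, params = pfun(0), bni = b_lo,
                          target_bni = target_bni, model = model,
                          distance = distance, sigma_star = sigma_star,
                          evaluations = do.call(rbind, evals)),
                     class = "icto_calibration"))
  }
  lo <- 0; hi <- 1
  b_hi <- f(hi)
  while (b_hi < target_bni && hi < coupling_max) {
    lo <- hi; b_lo <- b_hi
    hi <- hi * 2
    b_hi <- f(hi)
  }
  if (b_hi < target_bni - tol)
    stop(sprintf("target BNI %.2f unreachable: BNI range [%.3f, %.3f] up to coupling %g",
                 target_bni, min(b_lo, b_hi), max(b_lo, b_hi), hi))
  ws <- hi; b <- b_hi
  iter <- 0
  while (abs(b - target_bni) > tol && iter < max_iter) {
    ws <- (lo + hi) / 2
    b <- f(ws)
    if (b < target_bni) lo <- ws else hi <- ws
    iter <- iter + 1
  }
  # return the evaluation closest to the target (the last bisection point is
  # not necessarily the best when BNI estimates are stochastic)
  em <- do.call(rbind, evals)
  best <- which.min(abs(em[, "bni"] - target_bni))
  ws <- em[best, "coupling_star"]; b <- em[best, "bni"]
  structure(list(coupling_star = ws, params = pfun(ws), bni = b,
                 target_bni = target_bni, model = model,
                 distance = distance, sigma_star = sigma_star,
                 evaluations = do.call(rbind, evals)),
            class = "icto_calibration")
}

#' @export
print.icto_calibration <- function(x, ...) {
  cat(sprintf("<icto_calibration> %s: coupling* = %.4g -> BNI = %.3f (target %.2f, distance %.3g)\n",
              toupper(x$model), x$coupling_star, x$bni, x$target_bni,
              x$distance))
  invisible(x)
}

#' Node ictogenicity by virtual resection
#'
#' Removes each node in turn, re-simulates the reduced network with
#' unchanged parameters, and scores the node by the relative BNI drop
#' \eqn{NI_i = (BNI_{pre} - BNI_{post}^i) / BNI_{pre}}.  `NI = 1` means the
#' resection abolished spiking entirely; `NI = 0` means it made no
#' difference; negative values mean the removal increased BNI.
#'
#' With `common_rng = TRUE` the same noise seeds (and per-node noise
#' streams) are reused for the pre- and all post-resection runs, which
#' reduces the Monte-Carlo variance of the BNI differences; otherwise each
#' resection is evaluated on its own derived seeds.
#'
#' @param g graph (vertex attribute `orig_id` keeps noise streams attached
#'   to surviving nodes; it is created if absent).
#' @param model `"cm"` or `"wm"`.
#' @param params calibrated raw parameter object (see
#'   [calibrate_coupling()]).
#' @param seeds noise seeds per BNI evaluation.
#' @param bni_pre reference BNI; computed from `g` when `NULL`.  Supply it
#'   only if it was measured with the same `seeds` and `duration`, otherwise
#'   seed-to-seed BNI differences masquerade as NI.
#' @param n_ref reference network size for the coupling prefactor (used by
#'   [removal_curve()], where `g` itself is already a reduced network).
#' @param common_rng reuse the same noise streams across resections.
#' @param duration simulation length per evaluation.
#' @param ... passed to the simulator.
#' @return an object of class `ni_result`: `ni` vector, `bni_pre`,
#'   `bni_post` vector, `disconnected` flags.
#' @export
node_ictogenicity <- function(g, model = c("cm", "wm"), params, seeds = 1:3,
                              bni_pre = NULL, common_rng = FALSE,
                              duration = NULL, n_ref = NULL, ...) {
  model <- match.arg(model)
  n <- igraph::vcount(g)
  n_ref <- n_ref %||% n
  if (is.null(igraph::vertex_attr(g, "orig_id")))
    igraph::V(g)$orig_id <- seq_len(n)
  if (is.null(bni_pre))
    bni_pre <- network_bni(g, model, params, seeds = seeds,
                           duration = duration, n_ref = n_ref, ...)$bni
  if (bni_pre <= 0) stop("bni_pre must be positive to define NI")
  bni_post <- numeric(n)
  disconnected <- logical(n)
  for (i in seq_len(n)) {
    g2 <- igraph::delete_vertices(g, i)
    disconnected[i] <- igraph::count_components(g2, mode = "weak") > 1
    params_i <- params
    # per-node mean inputs follow the surviving nodes
    if (model == "cm" && length(params$I0) == n) params_i$I0 <- params$I0[-i]
    if (model == "wm" && length(params$p0) == n) params_i$p0 <- params$p0[-i]
    s <- if (common_rng) seeds else seeds * 10000L + i
    # fraction mass over the intact node count: the resected node contributes
    # zero spiking time, so a silent node's removal leaves BNI unchanged
    bni_post[i] <- network_bni(g2, model, params_i, seeds = s,
                               duration = duration, n_ref = n_ref, ...)$bni *
      (n - 1) / n
  }
  structure(list(ni = (bni_pre - bni_post) / bni_pre, bni_pre = bni_pre,
                 bni_post = bni_post, disconnected = disconnected,
                 model = model, common_rng = common_rng),
            class = "ni_result")
}

#' @export
print.ni_result <- function(x, ...) {
  cat(sprintf("<ni_result> %s: BNI_pre = %.3f; NI range [%.3f, %.3f]\n",
              toupper(x$model), x$bni_pre, min(x$ni), max(x$ni)))
  if (any(x$disconnected))
    cat("  note:", sum(x$disconnected), "resections disconnect the graph\n")
  invisible(x)
}

#' BNI under progressive node removal
#'
#' Removes one node per step -- the node with the highest current
#' eigenvector centrality, the highest current NI, or a uniformly random
#' node -- re-simulating the network BNI after each removal with unchanged
#' (calibrated) parameters.  Centralities and NI are recomputed on the
#' reduced network at every step; ties are broken toward the lowest node
#' index.
#'
#' @param g graph.
#' @param model `"cm"` or `"wm"`.
#' @param params calibrated raw parameters.
#' @param strategy `"eigenvector"`, `"ni"` or `"random"`.
#' @param n_remove number of removals (< number of nodes).
#' @param seeds noise seeds per BNI evaluation.
#' @param duration simulation length per evaluation.
#' @param seed RNG seed for the `"random"` strategy.
#' @param ... passed to the simulator.
#' @return a `data.frame` with columns `n_removed`, `bni`, `removed`
#'   (original id of the node removed at that step, `NA` in row one).
#' @export
removal_curve <- function(g, model = c("cm", "wm"), params,
                          strategy = c("eigenvector", "ni", "random"),
                          n_remove, seeds = 1:2, duration = NULL,
                          seed = NULL, ...) {
  model <- match.arg(model)
  strategy <- match.arg(strategy)
  n <- igraph::vcount(g)
  if (n_remove >= n) stop("n_remove must be smaller than the number of nodes")
  if (is.null(igraph::vertex_attr(g, "orig_id")))
    igraph::V(g)$orig_id <- seq_len(n)
  with_seed(seed, {
    cur <- g
    bni <- network_bni(cur, model, params, seeds = seeds,
                       duration = duration, n_ref = n, ...)$bni
    out <- data.frame(n_removed = 0L, bni = bni, removed = NA_integer_)
    for (k in seq_len(n_remove)) {
      pick <- switch(strategy,
        eigenvector = which.max(eigencentrality(cur)),
        ni = which.max(node_ictogenicity(cur, model, params, seeds = seeds,
                                         common_rng = TRUE, n_ref = n,
                                         duration = duration, ...)$ni),
        random = sample.int(igraph::vcount(cur), 1))
      removed_id <- igraph::vertex_attr(cur, "orig_id")[pick]
      cur <- igraph::delete_vertices(cur, pick)
      bni <- if (igraph::vcount(cur) > 0)
        network_bni(cur, model, params, seeds = seeds,
                    duration = duration, n_ref = n, ...)$bni *
          igraph::vcount(cur) / n else 0
      out <- rbind(out, data.frame(n_removed = k, bni = bni,
                                   removed = removed_id))
    }
    out
  })
}
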