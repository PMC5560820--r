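#' Wendling neural mass parameters
#'
#' Returns the parameter set of the 10-equation Wendling neural mass: synaptic
#' gains `A` (excitatory), `B` (slow inhibitory) and `G` (fast inhibitory) in
#' mV, inverse time constants `a`, `b`, `g` in 1/s, intra-mass connectivities
#' `C1`..`C7`, sigmoid parameters (`v0` mV, `e0` 1/s, `r` 1/mV), mean
#' extrinsic input `p0`, white-noise intensity `sigma`, and homogeneous
#' network coupling `lambda`.
#'
#' The default `C7 = 0.8 * C1` is the fast-somatic feedback strength of the
#' original Wendling model; with it the SNIC bifurcation of the uncoupled
#' mass sits at a critical input `p_c` of about 95.41, so the default
#' `p0 = 93.96` leaves every node a distance `p_c - p0 = 1.45` below the
#' bifurcation (resting, but excitable by noise and coupling).
#'
#' @param p0 mean extrinsic input (must be below the critical input).
#' @param sigma noise intensity (the white noise has
#'   \eqn{\langle \xi(t)\xi(t')\rangle = \sigma^2 \delta(t - t')}).
#' @param lambda homogeneous coupling strength.
#' @param A,B,G,a,b,g,C1,C2,C3,C4,C5,C6,C7,v0,e0,r model constants.
#' @return an object of class `wm_params`.
#' @seealso [wm_critical_input()], [simulate_wm()], [wm_from_starred()]
#' @export
wm_params <- function(p0 = 93.96, sigma = 7.25, lambda = 1,
                      A = 5, B = 40, G = 20, a = 100, b = 50, g = 500,
                      C1 = 135, C2 = 0.8 * C1, C3 = 0.25 * C1,
                      C4 = 0.25 * C1, C5 = 0.3 * C1, C6 = 0.1 * C1,
                      C7 = 0.8 * C1, v0 = 6, e0 = 2.5, r = 0.56) {
  p <- list(p0 = p0, sigma = sigma, lambda = lambda,
            A = A, B = B, G = G, a = a, b = b, g = g,
            C1 = C1, C2 = C2, C3 = C3, C4 = C4, C5 = C5, C6 = C6, C7 = C7,
            v0 = v0, e0 = e0, r = r)
  stopifnot(all(unlist(p[c("A", "B", "G", "a", "b", "g")]) > 0),
            sigma >= 0, lambda >= 0)
  class(p) <- "wm_params"
  p
}

wm_const_vec <- function(p)
  c(p$A, p$a, p$B, p$b, p$G, p$g, p$C1, p$C2, p$C3, p$C4, p$C5, p$C6, p$C7,
    p$v0, p$e0, p$r)

wm_const_key <- function(p)
  paste(signif(wm_const_vec(p), 10), collapse = "|")

#' Potential-to-rate sigmoid of the neural mass
#'
#' \eqn{S(v) = 2 e_0 / (1 + e^{r (v_0 - v)})}: the firing-rate response of a
#' population to its mean membrane potential, saturating at `2 e0`.
#'
#' @param v membrane potential (mV).
#' @param e0 half of the maximum firing rate (1/s).
#' @param r sigmoid slope (1/mV).
#' @param v0 potential of half-maximum rate (mV).
#' @export
sigmoid_rate <- function(v, e0 = 2.5, r = 0.56, v0 = 6) {
  2 * e0 / (1 + exp(r * (v0 - v)))
}

#' Drift field of one Wendling neural mass
#'
#' The deterministic right-hand side of the 10 first-order ODEs for a single
#' node given its total input `p` (mean input plus coupling; noise excluded).
#' Mainly useful for equilibrium analysis and testing; simulation is done by
#' the compiled integrator.
#'
#' @param z numeric state of length 10 (`z1..z10`).
#' @param p total node input.
#' @param params a [wm_params()] object.
#' @return numeric length-10 derivative.
#' @export
wm_drift <- function(z, p, params = wm_params()) {
  q <- params
  S <- function(v) sigmoid_rate(v, q$e0, q$r, q$v0)
  c(z[6], z[7], z[8], z[9], z[10],
    q$A * q$a * S(z[2] - z[3] - z[4]) - 2 * q$a * z[6] - q$a^2 * z[1],
    q$A * q$a * (p + q$C2 * S(q$C1 * z[1])) - 2 * q$a * z[7] - q$a^2 * z[2],
    q$B * q$b * q$C4 * S(q$C3 * z[1]) - 2 * q$b * z[8] - q$b^2 * z[3],
    q$G * q$g * q$C7 * S(q$C5 * z[1] - z[5]) - 2 * q$g * z[9] - q$g^2 * z[4],
    q$B * q$b * q$C6 * S(q$C3 * z[1]) - 2 * q$b * z[10] - q$b^2 * z[5])
}

# at equilibrium the 10-D system reduces to a scalar fixed-point problem in
# the pyramidal potential y = z2 - z3 - z4:  y = wm_equilibrium_map(y, p)
wm_equilibrium_map <- function(y, p, q) {
  S <- function(v) sigmoid_rate(v, q$e0, q$r, q$v0)
  z1 <- (q$A / q$a) * S(y)
  z5 <- (q$B / q$b) * q$C6 * S(q$C3 * z1)
  (q$A / q$a) * (p + q$C2 * S(q$C1 * z1)) -
    (q$B / q$b) * q$C4 * S(q$C3 * z1) -
    (q$G / q$g) * q$C7 * S(q$C5 * z1 - z5)
}

#' Critical input of the Wendling neural mass (SNIC point)
#'
#' Locates the input `p_c` at which the resting equilibrium of the uncoupled
#' noiseless mass is annihilated in a saddle-node on the invariant circle,
#' by bisecting on constant input for the disappearance of the lower pair of
#' equilibria of the one-dimensional fixed-point reduction.  The value is
#' cached per parameter set.
#'
#' @param params a [wm_params()] object (only the model constants matter).
#' @param interval search bracket for `p`.
#' @param tol bisection tolerance.
#' @return the critical input `p_c`.
#' @examples
#' wm_critical_input()  # about 95.41 for the default constants
#' @export
wm_critical_input <- function(params = wm_params(), interval = c(40, 200),
                              tol = 1e-3) {
  key <- paste0("pc|", wm_const_key(params))
  cache_get(key, function() {
    grid <- seq(-40, 40, length.out = 8001)
    n_eq <- function(p) {
      gv <- wm_equilibrium_map(grid, p, params) - grid
      sum(diff(sign(gv)) != 0)
    }
    lo <- interval[1]; hi <- interval[2]
    if (n_eq(lo) < 3) stop("no resting equilibrium at the lower bracket")
    if (n_eq(hi) >= 3) stop("resting equilibrium persists at the upper bracket")
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (n_eq(mid) >= 3) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  })
}

# ---- canonical (theta neuron) model ----

#' Canonical model parameters
#'
#' Parameters of the theta-neuron (normal form of the SNIC) network: mean
#' input `I0` (negative for a resting start; the bifurcation sits at
#' `I_c = 0`), white-noise intensity `sigma`, and homogeneous coupling `w`.
#'
#' @param I0 mean input.
#' @param sigma noise intensity.
#' @param w homogeneous coupling strength.
#' @return an object of class `cm_params`.
#' @export
cm_params <- function(I0 = -1.2, sigma = 6, w = 1) {
  stopifnot(sigma >= 0, w >= 0)
  structure(list(I0 = I0, sigma = sigma, w = w, I_c = 0),
            class = "cm_params")
}

#' Steady state of the uncoupled theta neuron
#'
#' \eqn{\theta_s = -\mathrm{Re}\,\cos^{-1}((1 + I_0)/(1 - I_0))}: the stable
#' fixed point of the uncoupled phase dynamics for `I0 < 0` (its mirror
#' image `-theta_s` is the unstable fixed point), and 0 for `I0 >= 0` where
#' no fixed point survives the bifurcation.
#'
#' @param I0 mean input (any numeric vector; the `I0 = 1` singularity of the
#'   formula lies in the `I0 > 0` regime where the steady state is 0).
#' @export
theta_steady_state <- function(I0) {
  out <- numeric(length(I0))
  neg <- I0 < 0
  ratio <- pmin(pmax((1 + I0[neg]) / (1 - I0[neg]), -1), 1)
  out[neg] <- -acos(ratio)
  out
}

#' Phase drift of the theta neuron
#'
#' \eqn{\dot\theta = (1 - \cos\theta) + (1 + \cos\theta) I}.
#'
#' @param theta phase (radians).
#' @param I total input (mean input plus coupling; noise excluded).
#' @export
cm_drift <- function(theta, I) {
  (1 - cos(theta)) + (1 + cos(theta)) * I
}

#' Output of a theta-model node
#'
#' \eqn{Y = 1 - \cos(\theta - \theta_s)}: zero at rest and maximal (2) at
#' half a rotation from the steady state.
#' @param theta phase.
#' @param theta_s node steady state.
#' @export
cm_output <- function(theta, theta_s) 1 - cos(theta - theta_s)

# ---- mean-field estimates of the spiking threshold ----

#' Critical coupling for spiking onset
#'
#' Mean-field estimate of the coupling at which a node of in-degree `k_in`
#' starts to spike, given the bifurcation point `T_bif`, the node's distance
#' parameter `x0`, and the average output `Y_mean` of its in-neighbours:
#' \eqn{C_c = N (T - x_0) / (\langle Y\rangle k_{in})}.  Larger in-degree
#' means smaller critical coupling.
#'
#' @param N network size.
#' @param T_bif bifurcation point of the node input (0 for the canonical
#'   model, `p_c` for the Wendling model).
#' @param x0 mean node input (e.g. `I0` or `p0`).
#' @param Y_mean average output of the resting network.
#' @param k_in node in-degree (>= 1).
#' @export
critical_coupling <- function(N, T_bif, x0, Y_mean, k_in) {
  stopifnot(Y_mean > 0)
  if (any(k_in == 0))
    stop("k_in = 0: node receives no input and cannot be driven to spike")
  N * (T_bif - x0) / (Y_mean * k_in)
}

#' Critical distance to the bifurcation
#'
#' Inverse of [critical_coupling()]: the mean input at which a node of
#' in-degree `k_in` starts to spike under coupling `C`:
#' \eqn{x_{0c} = T - C \langle Y\rangle k_{in} / N}.
#'
#' @inheritParams critical_coupling
#' @param C homogeneous coupling strength.
#' @export
critical_distance <- function(N, T_bif, C, Y_mean, k_in) {
  T_bif - C * Y_mean * k_in / N
}

# ---- starred (scaled) parameters ----
# sigma* = sigma / (T - x0) compares noise to the distance to the
# bifurcation; the starred coupling compares the maximum mean input a node
# can receive from the network to the noise:
#   lambda* = 2 e0 c lambda / (N sigma_p)   (Wendling)
#   w*      = 2 c w / (N sigma_I)           (canonical)

#' Build canonical-model parameters from starred (scaled) values
#'
#' User-facing sweeps are expressed in the scale-free parameters
#' `sigma_star = sigma / (I_c - I0)` and `w_star = 2 c w / (N sigma)`, which
#' make noise and coupling comparable across models and networks.  This
#' converts them to raw `cm_params` for a given graph.
#'
#' @param distance distance to the bifurcation `I_c - I0` (> 0).
#' @param sigma_star scaled noise intensity.
#' @param w_star scaled coupling.
#' @param g the graph the parameters will be used with (supplies `N` and the
#'   mean degree `c`).
#' @return a [cm_params()] object.
#' @export
cm_from_starred <- function(distance, sigma_star, w_star, g) {
  stopifnot(distance > 0)
  sigma <- sigma_star * distance
  n <- igraph::vcount(g)
  cm_params(I0 = -distance, sigma = sigma,
            w = w_star * n * sigma / (2 * mean_degree(g)))
}

#' Starred (scaled) values of canonical-model parameters
#' @param params a [cm_params()] object.
#' @param g the graph the parameters are used with.
#' @return list with `distance`, `sigma_star`, `w_star`.
#' @export
cm_to_starred <- function(params, g) {
  distance <- params$I_c - params$I0
  list(distance = distance,
       sigma_star = params$sigma / distance,
       w_star = 2 * mean_degree(g) * params$w /
         (igraph::vcount(g) * params$sigma))
}

#' Build Wendling parameters from starred (scaled) values
#'
#' As [cm_from_starred()], with `sigma_star = sigma_p / (p_c - p0)` and
#' `lambda_star = 2 e0 c lambda / (N sigma_p)`.
#'
#' @param distance distance to the bifurcation `p_c - p0` (> 0).
#' @param sigma_star scaled noise intensity.
#' @param lambda_star scaled coupling.
#' @param g the graph the parameters will be used with.
#' @param ... constants passed on to [wm_params()].
#' @return a [wm_params()] object with `p0 = p_c - distance`.
#' @export
wm_from_starred <- function(distance, sigma_star, lambda_star, g, ...) {
  stopifnot(distance > 0)
  base <- wm_params(...)
  p_c <- wm_critical_input(base)
  sigma <- sigma_star * distance
  n <- igraph::vcount(g)
  lambda <- lambda_star * n * sigma / (2 * base$e0 * mean_degree(g))
  base$p0 <- p_c - distance
  base$sigma <- sigma
  base$lambda <- lambda
  base
}

#' Starred (scaled) values of Wendling parameters
#' @param params a [wm_params()] object.
#' @param g the graph the parameters are used with.
#' @return list with `distance`, `sigma_star`, `lambda_star`.
#' @export
wm_to_starred <- function(params, g) {
  p_c <- wm_critical_input(params)
  distance <- p_c - params$p0
  list(distance = distance,
       sigma_star = params$sigma / distance,
       lambda_star = 2 * params$e0 * mean_degree(g) * params$lambda /
         (igraph::vcount(g) * params$sigma))
}
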