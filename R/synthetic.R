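#' Synthetic multichannel peri-ictal recording with a planted rich channel
#' subset
#'
#' Emulates an intracranial EEG-like recording with pre-seizure, seizure
#' and post-seizure epochs.  Each channel is an order-2 autoregressive
#' noise process band-passed to 1-40 Hz (EEG-like autocorrelation); the
#' channels of `club` additionally share a common latent signal of the same
#' class whose mixing gain follows the per-epoch `coupling`.  With unit
#' latent and noise variances, a pair of club channels with gain `g` has an
#' analytic zero-lag correlation of \eqn{g^2 / (g^2 + 1)}, returned as the
#' ground truth.
#'
#' @param n_channels number of channels.
#' @param fs sampling rate (Hz).
#' @param epochs named epoch durations in seconds
#'   (`c(pre = 180, ictal = 60, post = 180)`).
#' @param club channel indices sharing the latent signal.
#' @param coupling named per-epoch latent gains; the seizure epoch should
#'   dominate.
#' @param amplitude output scale (arbitrary units, nominally microvolts).
#' @param ar_modulus,ar_freq pole modulus and peak frequency (Hz) of the
#'   AR(2) processes.
#' @param seed RNG seed.
#' @return list with `recording` (a [recording()] with epoch marks),
#'   `truth` (per-epoch analytic correlation matrices), `club`.
#' @examples
#' syn <- synth_recording(n_channels = 6, epochs = c(pre = 10, ictal = 8,
#'                        post = 10), club = 1:3, seed = 1)
#' syn$truth$ictal[1, 2]
#' @export
synth_recording <- function(n_channels = 16, fs = 512,
                            epochs = c(pre = 180, ictal = 60, post = 180),
                            club = 1:4,
                            coupling = c(pre = 0.4, ictal = 1.2, post = 0.4),
                            amplitude = 50, ar_modulus = 0.97, ar_freq = 10,
                            seed = NULL) {
  stopifnot(all(club >= 1), all(club <= n_channels),
            all(names(epochs) %in% names(coupling) |
                  is.null(names(epochs)) == FALSE))
  with_seed(seed, {
    n_tot <- round(sum(epochs) * fs)
    ar <- c(2 * ar_modulus * cos(2 * pi * ar_freq / fs), -ar_modulus^2)
    bp <- signal::butter(2, c(1, 40) / (fs / 2), type = "pass")
    gen <- function() {
      x <- as.numeric(filter(rnorm(n_tot + fs), ar, method = "recursive"))
      x <- x[-(1:fs)]  # drop AR burn-in
      x <- signal::filtfilt(bp, x)
      (x - mean(x)) / sd(x)
    }
    latent <- gen()
    noise <- replicate(n_channels, gen())
    # per-sample latent gain following the epoch schedule
    bounds <- unname(cumsum(c(0, epochs)))
    gain <- numeric(n_tot)
    for (i in seq_along(epochs)) {
      idx <- (round(bounds[i] * fs) + 1):round(bounds[i + 1] * fs)
      gain[idx] <- coupling[[names(epochs)[i]]]
    }
    x <- noise
    for (ch in club)
      x[, ch] <- (noise[, ch] + gain * latent) / sqrt(1 + gain^2)
    x <- x * amplitude
    marks <- lapply(seq_along(epochs), function(i) c(bounds[i], bounds[i + 1]))
    names(marks) <- names(epochs)
    truth <- lapply(names(epochs), function(ep) {
      gsq <- coupling[[ep]]^2
      Ct <- matrix(0, n_channels, n_channels)
      Ct[club, club] <- gsq / (gsq + 1)
      diag(Ct) <- 0
      Ct
    })
    names(truth) <- names(epochs)
    list(recording = recording(x, fs, marks), truth = truth, club = club)
  })
}

#' Weighted graph with a planted rich club
#'
#' Builds a synthetic weighted undirected graph containing a fully
#' connected club with strong, nearly equal internal weights, a handful of
#' high-degree "impostor" nodes whose many edges are weak, and a sparse
#' weak background.  The impostors give the normalized rich-club curve a
#' genuine interior maximum (past the club's degree range the clubs are
#' dominated by weak impostor edges), which is what makes richest-club
#' recovery a meaningful test.
#'
#' @param n nodes.
#' @param club_size size of the planted club (nodes `1:club_size`).
#' @param n_impostors number of high-degree weak-weight nodes.
#' @param seed RNG seed.
#' @return symmetric weight matrix with the club indices in attribute
#'   `club`.
#' @export
planted_club_matrix <- function(n = 28, club_size = 6, n_impostors = 4,
                                seed = NULL) {
  with_seed(seed, {
    club <- seq_len(club_size)
    imp <- club_size + seq_len(n_impostors)
    rest <- setdiff(seq_len(n), c(club, imp))
    W <- matrix(0, n, n)
    add <- function(i, j, w) W[i, j] <<- W[j, i] <<- w
    for (i in club) for (j in club) if (i < j) add(i, j, runif(1, 2.6, 3))
    for (i in imp) for (j in setdiff(seq_len(n), i))
      if (runif(1) < 0.55) add(i, j, runif(1, 0.3, 0.8))
    for (i in rest) for (j in rest)
      if (i < j && runif(1) < 0.18) add(i, j, runif(1, 0.5, 1.5))
    for (i in club) for (j in rest)
      if (runif(1) < 0.25) add(i, j, runif(1, 0.5, 1.5))
    attr(W, "club") <- club
    W
  })
}

#' Hand-computable fixture graphs
#'
#' Small named graphs with closed-form properties, used throughout the test
#' suites: two 4-node weighted rich-club toys (`rc_toy_1` with weights
#' A-B:3, A-C:2, B-C:2, C-D:1, whose level-1 weighted rich-club coefficient
#' is exactly 1, and `rc_toy_2` with weights 1, 2, 2, 3, giving 5/7), a
#' 5-node star (hub dynamical importance 1), a triangle (clustering 1
#' everywhere), a 4-cycle, and a deterministic planted-club weighted graph
#' (`planted_club`, from [planted_club_matrix()] at a fixed seed).
#'
#' @return named list of `igraph` graphs / weight matrices; the planted
#'   club carries its membership as an attribute.
#' @export
fixture_graphs <- function() {
  m4 <- function(w_ab, w_ac, w_bc, w_cd) {
    W <- matrix(0, 4, 4, dimnames = rep(list(c("A", "B", "C", "D")), 2))
    W["A", "B"] <- w_ab; W["A", "C"] <- w_ac
    W["B", "C"] <- w_bc; W["C", "D"] <- w_cd
    W + t(W)
  }
  planted <- planted_club_matrix(seed = 404)
  list(
    rc_toy_1 = m4(3, 2, 2, 1),
    rc_toy_2 = m4(1, 2, 2, 3),
    star5 = igraph::make_star(5, mode = "undirected"),
    triangle = igraph::make_full_graph(3),
    cycle4 = igraph::make_ring(4),
    planted_club = planted
  )
}
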