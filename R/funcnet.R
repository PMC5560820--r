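#' Multichannel recording container
#'
#' @param x numeric matrix, time in rows and channels in columns.
#' @param fs sampling rate (Hz).
#' @param epochs named list of `c(start, end)` boundaries in seconds
#'   (typically `pre`, `ictal`, `post`), ordered and within the record.
#' @param labels optional channel labels.
#' @return an object of class `recording`.
#' @export
recording <- function(x, fs, epochs = NULL, labels = NULL) {
  x <- as.matrix(x)
  stopifnot(fs > 0, nrow(x) > 1)
  if (!is.null(epochs)) {
    b <- unlist(epochs)
    stopifnot(all(b >= 0), all(b <= nrow(x) / fs + 1e-9),
              all(diff(unlist(lapply(epochs, `[`, 1))) >= 0))
  }
  labels <- labels %||% colnames(x) %||% paste0("ch", seq_len(ncol(x)))
  colnames(x) <- labels
  structure(list(x = x, fs = fs, epochs = epochs, labels = labels),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %.1f s at %g Hz\n",
              ncol(x$x), nrow(x$x) / x$fs, x$fs))
  if (!is.null(x$epochs))
    for (nm in names(x$epochs))
      cat(sprintf("  %s: %.1f-%.1f s\n", nm, x$epochs[[nm]][1],
                  x$epochs[[nm]][2]))
  invisible(x)
}

#' Median re-reference and filter a recording
#'
#' Re-references every sample against the median across channels, then
#' applies a zero-phase (forward-backward) Butterworth band-pass between
#' 0.5 and 120 Hz and a band-stop notch between 48 and 52 Hz.
#'
#' @param rec a [recording()].
#' @param band band-pass corner frequencies (Hz).
#' @param notch band-stop corner frequencies (Hz), `NULL` to skip.
#' @param order Butterworth order (applied twice by filtering forwards and
#'   backwards).
#' @return the filtered `recording`.
#' @export
preprocess_recording <- function(rec, band = c(0.5, 120), notch = c(48, 52),
                                 order = 4) {
  stopifnot(inherits(rec, "recording"))
  if (rec$fs <= 2 * band[2])
    stop(sprintf("sampling rate %g Hz too low for a %g Hz band edge",
                 rec$fs, band[2]))
  x <- rec$x - apply(rec$x, 1, median)
  ny <- rec$fs / 2
  bp <- signal::butter(order, band / ny, type = "pass")
  bs <- if (!is.null(notch)) signal::butter(order, notch / ny, type = "stop")
  for (j in seq_len(ncol(x))) {
    x[, j] <- signal::filtfilt(bp, x[, j])
    if (!is.null(notch)) x[, j] <- signal::filtfilt(bs, x[, j])
  }
  recording(x, rec$fs, rec$epochs, rec$labels)
}

#' Cut an epoch into analysis segments and subsegments
#'
#' Divides an epoch into `seg_len`-second segments separated by `spacing`
#' seconds of gap, and each segment into `n_sub` subsegments of `sub_len`
#' samples whose starts are spread evenly over the segment (minimal, equal
#' overlap).
#'
#' @param rec a (preprocessed) [recording()].
#' @param epoch epoch name (entry of `rec$epochs`) or `c(start, end)`
#'   seconds.
#' @param seg_len segment length in seconds.
#' @param spacing gap between consecutive segments in seconds.
#' @param sub_len subsegment length in samples.
#' @param n_sub subsegments per segment.
#' @return list of segments; each has `x` (samples x channels), `t0`
#'   (seconds) and `sub_starts` (0-based sample offsets).
#' @export
segmentize <- function(rec, epoch, seg_len = 8, spacing = 1,
                       sub_len = 1024, n_sub = 10) {
  bounds <- if (is.character(epoch)) rec$epochs[[epoch]] else epoch
  if (is.null(bounds)) stop("unknown epoch: ", epoch)
  if (diff(bounds) < seg_len) {
    warning("epoch shorter than one segment; returning no segments")
    return(list())
  }
  fs <- rec$fs
  seg_samp <- round(seg_len * fs)
  starts <- seq(bounds[1], bounds[2] - seg_len, by = seg_len + spacing)
  sub_starts <- round((seq_len(n_sub) - 1) * (seg_samp - sub_len) / (n_sub - 1))
  lapply(starts, function(t0) {
    i0 <- round(t0 * fs)
    list(x = rec$x[(i0 + 1):(i0 + seg_samp), , drop = FALSE], t0 = t0,
         sub_starts = sub_starts)
  })
}

#' Iterated amplitude-adjusted Fourier transform surrogate
#'
#' Generates a surrogate series with exactly the amplitude distribution of
#' `x` (its sorted values are preserved verbatim) and approximately its
#' power spectrum, by alternating spectrum adjustment and rank-ordered
#' amplitude restoration from a random initial shuffle.  Uses R's RNG; seed
#' with `set.seed()` for reproducibility.
#'
#' @param x numeric series (length >= 64).
#' @param n_iter maximum iterations.
#' @param tol stop when the relative change of the amplitude spectrum
#'   mismatch falls below `tol`.
#' @return surrogate numeric vector.
#' @export
iaaft_surrogate <- function(x, n_iter = 100, tol = 1e-6) {
  n <- length(x)
  stopifnot(n >= 64)
  amp_sorted <- sort(x)
  target_mod <- Mod(fft(x))
  s <- sample(x)
  err_prev <- Inf
  for (it in seq_len(n_iter)) {
    fs <- fft(s)
    mod <- Mod(fs)
    phase_fac <- ifelse(mod > 0, fs / mod, 1)
    s2 <- Re(fft(target_mod * phase_fac, inverse = TRUE)) / n
    s <- amp_sorted[rank(s2, ties.method = "first")]
    err <- sqrt(mean((Mod(fft(s)) - target_mod)^2)) / sqrt(mean(target_mod^2))
    if (is.finite(err_prev) && abs(err_prev - err) < tol * max(err, 1e-300))
      break
    err_prev <- err
  }
  s
}

# Pearson correlation matrices for each subsegment of a segment
subsegment_correlations <- function(xseg, sub_starts, sub_len) {
  lapply(sub_starts, function(s0) {
    sub <- xseg[(s0 + 1):(s0 + sub_len), , drop = FALSE]
    suppressWarnings(cor(sub))
  })
}

#' Zero-lag correlation medians of a segment
#'
#' Pearson equal-time (zero-lag) cross-correlation per channel pair and
#' subsegment, summarized by the elementwise median matrix.  Pairs with a
#' zero-variance subsegment yield `NA` entries (excluded with a warning
#' downstream).
#'
#' @param seg a segment from [segmentize()].
#' @param sub_len subsegment length in samples.
#' @return list with `rho` (the 3-d channel x channel x subsegment array)
#'   and `median` (the median matrix).
#' @export
zero_lag_correlation <- function(seg, sub_len = 1024) {
  cc <- subsegment_correlations(seg$x, seg$sub_starts, sub_len)
  nc <- ncol(seg$x)
  arr <- array(unlist(cc), dim = c(nc, nc, length(cc)))
  list(rho = arr, median = apply(arr, c(1, 2), median))
}

#' Mann-Whitney significance mask for original versus surrogate correlations
#'
#' For each channel pair, a two-sided Mann-Whitney-Wilcoxon U test compares
#' the ensemble of original-subsegment correlations against the surrogate
#' ensemble; Bonferroni-Holm correction over all pairs controls the
#' family-wise error at `alpha`.
#'
#' @param rho_o 3-d array (channels x channels x n original subsegments).
#' @param rho_surr 3-d array (channels x channels x n surrogate
#'   subsegments).
#' @param alpha family-wise significance level.
#' @return list with the 0/1 `s` matrix and the matrix of Holm-adjusted
#'   p-values.
#' @export
significance_mask <- function(rho_o, rho_surr, alpha = 0.05) {
  nc <- dim(rho_o)[1]
  pairs <- which(upper.tri(matrix(0, nc, nc)), arr.ind = TRUE)
  pv <- apply(pairs, 1, function(ij) {
    a <- rho_o[ij[1], ij[2], ]
    b <- rho_surr[ij[1], ij[2], ]
    if (all(is.na(a)) || all(is.na(b))) return(NA_real_)
    suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  })
  padj <- p.adjust(pv, method = "holm")
  s <- matrix(0, nc, nc)
  p_mat <- matrix(NA_real_, nc, nc)
  s[pairs] <- as.numeric(!is.na(padj) & padj < alpha)
  p_mat[pairs] <- padj
  s <- s + t(s)
  p_mat[lower.tri(p_mat)] <- t(p_mat)[lower.tri(p_mat)]
  list(s = s, p_adj = p_mat)
}

#' Surrogate-corrected correlation matrix
#'
#' Elementwise \eqn{C = s\,(\rho_o - \rho_{surr}) / (1 - \rho_{surr})}: the
#' observed zero-lag correlation in excess of the surrogate level, rescaled
#' to the attainable range and zeroed where not significant.
#'
#' @param rho_o median original correlation matrix.
#' @param rho_surr median surrogate correlation matrix (entrywise < 1).
#' @param s 0/1 significance matrix.
#' @return corrected correlation matrix with zero diagonal.
#' @export
corrected_matrix <- function(rho_o, rho_surr, s) {
  off <- row(rho_surr) != col(rho_surr)
  if (any(rho_surr[off] >= 1 - 1e-12))
    stop("rho_surr reaches 1: corrected correlation undefined")
  C <- (rho_o - rho_surr) / (1 - rho_surr) * s
  C[!off] <- 0
  C
}

#' Functional network of one segment
#'
#' Computes Pearson zero-lag correlations on the segment's subsegments,
#' builds `n_surr` IAAFT surrogates per channel (each cut into the same
#' subsegments), takes the median correlation matrices of the two
#' ensembles, masks pairs whose original and surrogate ensembles are not
#' significantly different (Mann-Whitney U, Bonferroni-Holm), and applies
#' the surrogate correction.
#'
#' @param seg one segment from [segmentize()].
#' @param sub_len subsegment length in samples.
#' @param n_surr surrogates per channel.
#' @param alpha family-wise level of the significance mask.
#' @param n_iter IAAFT iteration cap.
#' @return an object of class `functional_net` with `C`, `s`, `rho_o`,
#'   `rho_surr`, `p_adj`, `t0`.
#' @export
segment_network <- function(seg, sub_len = 1024, n_surr = 10, alpha = 0.05,
                            n_iter = 100) {
  nc <- ncol(seg$x)
  co <- subsegment_correlations(seg$x, seg$sub_starts, sub_len)
  surr_mats <- vector("list", n_surr)
  for (k in seq_len(n_surr)) {
    xs <- apply(seg$x, 2, iaaft_surrogate, n_iter = n_iter)
    surr_mats[[k]] <- subsegment_correlations(xs, seg$sub_starts, sub_len)
  }
  cs <- do.call(c, surr_mats)
  arr_o <- array(unlist(co), dim = c(nc, nc, length(co)))
  arr_s <- array(unlist(cs), dim = c(nc, nc, length(cs)))
  rho_o <- apply(arr_o, c(1, 2), median)
  rho_surr <- apply(arr_s, c(1, 2), median)
  msk <- significance_mask(arr_o, arr_s, alpha)
  C <- corrected_matrix(rho_o, rho_surr, msk$s)
  structure(list(C = C, s = msk$s, rho_o = rho_o, rho_surr = rho_surr,
                 p_adj = msk$p_adj, t0 = seg$t0),
            class = "functional_net")
}

#' Functional networks of every epoch of a recording
#'
#' Runs the full inference chain -- segmentation, subsegment correlations,
#' IAAFT surrogates, significance masking, surrogate correction -- for each
#' epoch of a preprocessed recording, and averages the corrected matrices
#' per epoch and over the whole record.
#'
#' @param rec a preprocessed [recording()] with epoch marks.
#' @param spacing gap between segments (seconds).
#' @param n_surr surrogates per channel.
#' @param alpha significance level.
#' @param seed optional RNG seed for the surrogate generation.
#' @param verbose print progress.
#' @return an object of class `funcnet_set`: per-epoch lists of
#'   `functional_net`s, per-epoch mean matrices (`epoch_mean`) and the
#'   overall mean (`overall_mean`).
#' @export
epoch_networks <- function(rec, spacing = 1, n_surr = 10, alpha = 0.05,
                           seed = NULL, verbose = FALSE) {
  stopifnot(!is.null(rec$epochs))
  with_seed(seed, {
    nets <- lapply(names(rec$epochs), function(ep) {
      segs <- segmentize(rec, ep, spacing = spacing)
      if (verbose) message(ep, ": ", length(segs), " segments")
      lapply(segs, segment_network, n_surr = n_surr, alpha = alpha)
    })
    names(nets) <- names(rec$epochs)
    mean_mat <- function(nl) {
      if (!length(nl)) return(NULL)
      Reduce(`+`, lapply(nl, `[[`, "C")) / length(nl)
    }
    epoch_mean <- lapply(nets, mean_mat)
    all_nets <- do.call(c, nets)
    structure(list(networks = nets, epoch_mean = epoch_mean,
                   overall_mean = mean_mat(all_nets),
                   labels = rec$labels),
              class = "funcnet_set")
  })
}

#' @export
print.funcnet_set <- function(x, ...) {
  cat("<funcnet_set>\n")
  for (nm in names(x$networks))
    cat(sprintf("  %s: %d segment networks\n", nm, length(x$networks[[nm]])))
  invisible(x)
}

#' Read a delimited multichannel recording
#'
#' Expects `#`-prefixed header lines `# fs <Hz>` and optionally
#' `# epoch <name> <start> <end>` followed by a channel-per-column table
#' with a label header row.
#'
#' @param path file path.
#' @return a [recording()].
#' @export
read_recording <- function(path) {
  hdr <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, 1)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  close(con); on.exit()
  fs_ln <- grep("^# fs ", hdr, value = TRUE)
  if (!length(fs_ln)) stop("missing '# fs' header line")
  fs <- as.numeric(strsplit(fs_ln, " +")[[1]][3])
  epochs <- NULL
  for (ln in grep("^# epoch ", hdr, value = TRUE)) {
    f <- strsplit(ln, " +")[[1]]
    epochs[[f[3]]] <- as.numeric(f[4:5])
  }
  tab <- read.table(path, header = TRUE, comment.char = "#")
  recording(as.matrix(tab), fs, epochs)
}

#' Write a recording in the delimited format of [read_recording()]
#' @param rec a [recording()].
#' @param path file path.
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs %g", rec$fs), con)
  for (nm in names(rec$epochs))
    writeLines(sprintf("# epoch %s %g %g", nm, rec$epochs[[nm]][1],
                       rec$epochs[[nm]][2]), con)
  write.table(round(rec$x, 6), con, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
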