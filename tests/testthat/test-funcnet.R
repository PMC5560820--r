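test_that("preprocessing re-references and filters as specified", {
  fs <- 512
  tt <- seq(0, 4, by = 1 / fs)[-1]
  # identical channels vanish under median re-referencing
  x <- matrix(rep(sin(2 * pi * 7 * tt), 3), ncol = 3)
  rec <- preprocess_recording(recording(x, fs))
  expect_lt(max(abs(rec$x)), 1e-9)

  # 50 Hz is notched by more than 20 dB, 10 Hz passes nearly untouched
  # (antisymmetric channel pairs keep the median reference at zero)
  x2 <- cbind(sin(2 * pi * 50 * tt), -sin(2 * pi * 50 * tt),
              sin(2 * pi * 10 * tt), -sin(2 * pi * 10 * tt))
  r2 <- preprocess_recording(recording(x2, fs))
  mid <- seq(fs, length(tt) - fs)  # ignore filter edges
  expect_lt(sd(r2$x[mid, 1]) / sd(x2[mid, 1]), 0.1)
  expect_gt(sd(r2$x[mid, 3]) / sd(x2[mid, 3]), 0.8)

  # DC offsets die under the 0.5 Hz high-pass
  x3 <- cbind(rnorm(length(tt)) + 40, rnorm(length(tt)) - 40,
              rnorm(length(tt)) + 40, rnorm(length(tt)) - 40)
  r3 <- preprocess_recording(recording(x3, fs))
  expect_lt(abs(mean(r3$x[mid, 1])), 0.5)

  expect_error(preprocess_recording(recording(x, 200)), "sampling rate")
})

test_that("segmentation follows the 8 s / 1024-sample layout", {
  fs <- 512
  rec <- recording(matrix(rnorm(fs * 20 * 2), ncol = 2), fs,
                   epochs = list(all = c(0, 20)))
  segs <- segmentize(rec, "all")
  expect_length(segs, 2)  # starts at 0 and 9 (8 s + 1 s gap)
  expect_equal(segs[[2]]$t0, 9)
  expect_equal(nrow(segs[[1]]$x), 4096)
  expect_equal(segs[[1]]$sub_starts,
               round((0:9) * (4096 - 1024) / 9))
  # neighbouring subsegments overlap by about 683 samples
  expect_equal(1024 - diff(segs[[1]]$sub_starts)[1], 683, tolerance = 2)

  short <- recording(matrix(rnorm(fs * 5), ncol = 1), fs,
                     epochs = list(all = c(0, 5)))
  expect_warning(out <- segmentize(short, "all"), "shorter")
  expect_length(out, 0)
})

test_that("IAAFT surrogates preserve amplitudes exactly and spectra approximately", {
  set.seed(14)
  x <- as.numeric(filter(rnorm(1024), 0.95, method = "recursive"))
  s <- iaaft_surrogate(x)
  expect_identical(sort(s), sort(x))
  expect_false(identical(s, x))
  # spectral mismatch after convergence is below that of a plain shuffle
  specerr <- function(y) sqrt(mean((Mod(fft(y)) - Mod(fft(x)))^2))
  set.seed(15)
  expect_lt(specerr(s), 0.2 * specerr(sample(x)))

  const <- rep(3, 128)
  expect_identical(iaaft_surrogate(const), const)
})

test_that("significance mask separates clearly distinct ensembles", {
  nc <- 4
  mk <- function(vals, k) array(rep(vals, each = nc * nc), c(nc, nc, k))
  # identical ensembles: nothing significant
  a <- mk(rep(0.3, 10), 10)
  expect_true(all(significance_mask(a, a)$s == 0))
  # fully separated ensembles: everything significant after Holm
  o <- mk(seq(0.8, 0.9, length.out = 10), 10)
  s <- mk(seq(0.0, 0.2, length.out = 100), 100)
  expect_true(all(significance_mask(o, s)$s[upper.tri(diag(nc))] == 1))
})

test_that("the surrogate correction formula is applied elementwise", {
  rho_o <- matrix(c(0, 0.8, 0.8, 0), 2, 2)
  rho_s <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  s1 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(corrected_matrix(rho_o, rho_s, s1)[1, 2], 0.75)
  expect_equal(corrected_matrix(rho_o, rho_s, 0 * s1),
               matrix(0, 2, 2))
  expect_equal(corrected_matrix(rho_s, rho_s, s1)[1, 2], 0)
  expect_error(corrected_matrix(rho_o, matrix(1, 2, 2), s1), "undefined")
  # sign of C follows sign of rho_o - rho_surr where significant
  expect_lt(corrected_matrix(rho_s, rho_o, s1)[1, 2], 0)
})

test_that("segment networks find a planted correlated pair", {
  syn <- synth_recording(n_channels = 5, epochs = c(pre = 10, ictal = 9,
                                                    post = 10),
                         club = c(2, 4), coupling = c(pre = 0, ictal = 2,
                                                      post = 0), seed = 31)
  rec <- preprocess_recording(syn$recording)
  seg <- segmentize(rec, "ictal")[[1]]
  set.seed(77)
  net <- segment_network(seg, n_surr = 8)
  off <- upper.tri(net$C)
  expect_equal(which.max(net$C[off]),
               which(row(net$C)[off] == 2 & col(net$C)[off] == 4))
  expect_true(isSymmetric(net$C))
  expect_equal(diag(net$C), rep(0, 5))
  # C is zero wherever the mask is zero
  expect_true(all(net$C[net$s == 0] == 0))
})

test_that("recordings round-trip through the delimited format", {
  rec <- recording(matrix(rnorm(512 * 4), ncol = 2), 256,
                   epochs = list(pre = c(0, 1), ictal = c(1, 3)))
  path <- tempfile(fileext = ".tsv")
  write_recording(rec, path)
  r2 <- read_recording(path)
  expect_equal(r2$fs, 256)
  expect_equal(r2$epochs$ictal, c(1, 3))
  expect_equal(r2$x, rec$x, tolerance = 1e-5, ignore_attr = TRUE)
  unlink(path)
})

test_that("zero-lag correlation medians behave on constructed channels", {
  fs <- 512
  n <- fs * 8
  set.seed(21)
  base <- as.numeric(filter(rnorm(n), 0.9, method = "recursive"))
  x <- cbind(base, base, rnorm(n))  # duplicated channel pair
  seg <- list(x = x, t0 = 0,
              sub_starts = round((0:9) * (n - 1024) / 9))
  zl <- zero_lag_correlation(seg)
  expect_equal(zl$median[1, 2], 1)
  expect_lt(abs(zl$median[1, 3]), 0.2)
  expect_equal(dim(zl$rho), c(3, 3, 10))
  # x vs -x
  seg2 <- list(x = cbind(base, -base), t0 = 0, sub_starts = seg$sub_starts)
  expect_equal(zero_lag_correlation(seg2)$median[1, 2], -1)
})
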