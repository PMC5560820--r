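test_that("weighted rich-club coefficient matches the hand-computed toys", {
  fx <- fixture_graphs()
  # club {A,B,C} holds the 3 strongest edges: phi = 1
  expect_equal(phi_weighted(fx$rc_toy_1, 1), 1)
  # same topology, weights reversed: (1+2+2) / (3+2+2) = 5/7
  expect_equal(phi_weighted(fx$rc_toy_2, 1), 5 / 7)
  # club containing every edge of the network
  W <- matrix(c(0, 2, 1, 2, 0, 3, 1, 3, 0), 3, 3)
  expect_equal(phi_weighted(W, 1), 1)
  # undefined when the club has no internal edge
  expect_true(is.na(phi_weighted(fx$rc_toy_1, 2)))
})

test_that("phi agrees with a brute-force oracle on random weighted graphs", {
  set.seed(55)
  for (rep in 1:12) {
    n <- sample(6:12, 1)
    W <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (runif(1) < 0.4) W[i, j] <- W[j, i] <- runif(1, 0.1, 5)
    if (all(W == 0)) next
    for (k in 0:(max(colSums(W != 0)) - 1))
      expect_equal(phi_weighted(W, k), phi_oracle(W, k), tolerance = 1e-12)
  }
})

test_that("null draws preserve the degree sequence and weight multiset", {
  W <- fixture_graphs()$planted_club
  nulls <- rc_null_ensemble(W, n_null = 25, seed = 8)
  deg0 <- sort(colSums(W != 0))
  w0 <- sort(W[upper.tri(W)][W[upper.tri(W)] != 0])
  for (Wn in nulls) {
    expect_true(isSymmetric(Wn))
    expect_true(all(diag(Wn) == 0))
    expect_equal(sort(colSums(Wn != 0)), deg0)
    expect_equal(sort(Wn[upper.tri(Wn)][Wn[upper.tri(Wn)] != 0]), w0)
  }
  # at least some draws differ from the original topology
  expect_true(any(vapply(nulls, function(Wn) any((Wn != 0) != (W != 0)),
                         logical(1))))
})

test_that("equal-weight regular rings are invisible to the null", {
  g <- igraph::make_ring(12)
  W <- as.matrix(igraph::as_adjacency_matrix(g)) * 2.5
  prof <- rich_club_profile(W, n_null = 20, seed = 3)
  ok <- !is.na(prof$phi)
  expect_true(all(abs(prof$phi[ok] - 1) < 1e-12))
})

test_that("random graphs with iid weights show no rich club", {
  set.seed(66)
  g <- generate_network("random", 40, 8, seed = 19)
  W <- as.matrix(igraph::as_adjacency_matrix(g))
  W[W != 0] <- runif(sum(W != 0), 0.5, 1.5)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  prof <- rich_club_profile(W, n_null = 40, seed = 4)
  ok <- !is.na(prof$phi) & prof$club_size >= 6
  expect_true(all(abs(prof$phi[ok] - 1) < 0.2))
})

test_that("planted clubs are detected and recovered", {
  W <- fixture_graphs()$planted_club
  prof <- rich_club_profile(W, n_null = 60, seed = 5)
  high <- prof$phi[!is.na(prof$phi) & prof$k >= 8]
  expect_true(any(high > 1))
  rc <- richest_club(prof)
  expect_gte(length(intersect(rc$members, attr(W, "club"))) /
               length(attr(W, "club")), 0.5)

  # recovery across random planted-club graphs
  hits <- vapply(1:10, function(s) {
    W2 <- planted_club_matrix(seed = 600 + s)
    prof2 <- rich_club_profile(W2, n_null = 40, seed = s)
    rc2 <- richest_club(prof2)
    length(intersect(rc2$members, attr(W2, "club"))) /
      length(attr(W2, "club"))
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})

test_that("richest-club selection and resected fractions follow definitions", {
  prof <- structure(
    data.frame(k = 0:3, phi_w = c(0.5, 0.6, 0.9, 0.8),
               phi_rand = c(1, 1, 1, 1), phi = c(0.5, 0.6, 0.9, 0.8),
               p = NA, club_size = c(6, 5, 3, 2)),
    degrees = c(4, 3, 3, 2, 1, 1), class = c("rich_club_profile", "data.frame"))
  rc <- richest_club(prof)
  expect_equal(rc$k_r, 2)
  expect_equal(rc$members, c(1, 2, 3))
  # monotone phi: the largest defined k wins
  prof$phi <- 1:4
  expect_equal(richest_club(prof)$k_r, 3)

  expect_equal(fraction_resected(1:5, 4:10), 0.4)
  expect_equal(fraction_resected(1:3, 1:8), 1)
  expect_equal(fraction_resected(1:3, 7:8), 0)
})
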