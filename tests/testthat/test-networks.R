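test_that("generated graphs are simple, connected, and family-tagged", {
  specs <- list(
    list(family = "random", directed = FALSE),
    list(family = "random", directed = TRUE),
    list(family = "scale_free", directed = FALSE),
    list(family = "scale_free", directed = TRUE),
    list(family = "small_world", directed = FALSE),
    list(family = "small_world", directed = TRUE),
    list(family = "rich_club", directed = FALSE),
    list(family = "rich_club", directed = TRUE)
  )
  for (sp in specs) {
    g <- generate_network(sp$family, n = 40, mean_degree = 6,
                          directed = sp$directed, gamma = 2.5,
                          club_size = 8, seed = 11)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    expect_true(all(diag(A) == 0), info = sp$family)
    expect_true(all(A %in% 0:1), info = sp$family)
    if (!sp$directed) expect_true(isSymmetric(A), info = sp$family)
    expect_true(igraph::is_connected(g, mode = "weak"), info = sp$family)
    expect_identical(igraph::graph_attr(g, "family"), sp$family)
    # single-draw mean degree near the target (scale-free draws are heavy
    # tailed at this size; their mean degree is checked in expectation in
    # the ensemble test below)
    if (sp$family != "scale_free") expect_lt(abs(mean_degree(g) - 6) / 6, 0.15)
  }
})

test_that("directed random graphs have the expected edge count on average", {
  # N = 10, c = 1.6: expected N(N-1)p = N c = 16 directed edges
  ecnt <- vapply(1:500, function(s) {
    igraph::ecount(generate_network("random", 10, 1.6, directed = TRUE,
                                    seed = s))
  }, numeric(1))
  # connectivity filtering biases the count up slightly; allow MC + bias slack
  expect_lt(abs(mean(ecnt) - 16), 1.5)
})

test_that("planted rich club has the requested internal edge probability", {
  internal <- vapply(1:300, function(s) {
    g <- generate_network("rich_club", 64, 6, club_size = 10, p1 = 0.7,
                          p2 = 0.2, seed = 1000 + s)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    club <- which(igraph::V(g)$club)
    sum(A[club, club]) / 2
  }, numeric(1))
  expect_lt(abs(mean(internal) - 0.7 * choose(10, 2)), 1)  # 31.5 expected
})

test_that("ensemble mean degree converges to the target", {
  for (fam in c("random", "scale_free")) {
    md <- vapply(1:300, function(s)
      mean_degree(generate_network(fam, 48, 6, gamma = 2.5, seed = 2000 + s)),
      numeric(1))
    expect_lt(abs(mean(md) - 6), 0.2)
  }
})

test_that("unrewired small world is the ring lattice", {
  g <- generate_network("small_world", 20, 4, p_rewire = 0, seed = 3)
  cl <- igraph::transitivity(g, type = "local")
  expect_true(all(abs(cl - 0.5) < 1e-12))  # nei = 2 ring lattice value
  expect_true(all(igraph::degree(g) == 4))
})

test_that("gamma = 2 scale-free graphs have larger degree variance than gamma = 3", {
  v2 <- vapply(1:30, function(s)
    var(igraph::degree(generate_network("scale_free", 64, 6, gamma = 2,
                                        seed = 300 + s))), numeric(1))
  v3 <- vapply(1:30, function(s)
    var(igraph::degree(generate_network("scale_free", 64, 6, gamma = 3,
                                        seed = 300 + s))), numeric(1))
  expect_gt(mean(v2), mean(v3))
})

test_that("infeasible specs fail after bounded redraws", {
  expect_error(generate_network("random", 40, 0.2, seed = 1, max_tries = 25),
               "connected")
})

test_that("graph files round-trip through both formats", {
  g <- generate_network("random", 12, 3, directed = TRUE, seed = 7)
  for (fmt in c("adjacency", "edgelist")) {
    path <- tempfile(fileext = ".tsv")
    write_network(g, path, format = fmt)
    g2 <- read_network(path, format = fmt, directed = TRUE)
    expect_equal(as.matrix(igraph::as_adjacency_matrix(g2)),
                 as.matrix(igraph::as_adjacency_matrix(g)),
                 ignore_attr = TRUE)
    unlink(path)
  }
  # weighted adjacency round-trip
  W <- fixture_graphs()$rc_toy_1
  path <- tempfile(fileext = ".tsv")
  gw <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE)
  write_network(gw, path)
  g3 <- read_network(path, directed = FALSE)
  expect_equal(unname(as.matrix(igraph::as_adjacency_matrix(g3, attr = "weight"))),
               unname(W))
  unlink(path)
})
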