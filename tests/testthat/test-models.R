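test_that("sigmoid hits its anchor points", {
  expect_equal(sigmoid_rate(6), 2.5)            # half-maximum at v0
  expect_equal(sigmoid_rate(1e3), 5)            # saturation at 2 e0
  expect_equal(sigmoid_rate(0), 5 / (1 + exp(0.56 * 6)), tolerance = 1e-12)
  expect_equal(sigmoid_rate(0), 0.167846, tolerance = 1e-5)
  v <- seq(-20, 20, 0.5)
  expect_true(all(diff(sigmoid_rate(v)) > 0))   # monotone increasing
})

test_that("Wendling drift matches hand evaluation at the origin", {
  d <- wm_drift(rep(0, 10), p = 0)
  S0 <- sigmoid_rate(0)
  expect_equal(d[1:5], rep(0, 5))
  expect_equal(d[6], 5 * 100 * S0)
  expect_equal(d[7], 5 * 100 * (0 + 0.8 * 135 * S0))
  expect_equal(d[8], 40 * 50 * 0.25 * 135 * S0)
  expect_equal(d[10], 40 * 50 * 0.1 * 135 * S0)
})

test_that("Wendling drift vanishes at a located equilibrium", {
  q <- wm_params()
  p <- 90
  # root of the scalar equilibrium reduction, then lift to the full state
  f <- function(y) ictonet:::wm_equilibrium_map(y, p, q) - y
  y_star <- uniroot(f, c(-5, 1.5), tol = 1e-12)$root
  S <- function(v) sigmoid_rate(v)
  z1 <- (q$A / q$a) * S(y_star)
  z3 <- (q$B / q$b) * q$C4 * S(q$C3 * z1)
  z5 <- (q$B / q$b) * q$C6 * S(q$C3 * z1)
  z4 <- (q$G / q$g) * q$C7 * S(q$C5 * z1 - z5)
  z2 <- (q$A / q$a) * (p + q$C2 * S(q$C1 * z1))
  z <- c(z1, z2, z3, z4, z5, 0, 0, 0, 0, 0)
  expect_lt(sqrt(sum(wm_drift(z, p, q)^2)), 1e-8)
  expect_equal(z2 - z3 - z4, y_star, tolerance = 1e-9)
})

test_that("the critical input sits between resting and spiking constant inputs", {
  pc <- wm_critical_input()
  expect_equal(pc, 95.41, tolerance = 1e-3)
  g1 <- igraph::make_empty_graph(1)
  amp <- function(p0) {
    q <- wm_params(p0 = p0, sigma = 0, lambda = 0)
    s <- simulate_wm(g1, q, duration = 4, transient = 4, seed = 1)
    diff(range(s$output))
  }
  expect_lt(amp(pc - 1), 1e-6)   # resting below
  expect_gt(amp(pc + 1), 10)     # large-amplitude spiking above
})

test_that("theta steady state matches its closed forms", {
  expect_equal(theta_steady_state(0), 0)
  expect_equal(theta_steady_state(2), 0)     # no fixed point past the SNIC
  expect_equal(theta_steady_state(-1), -pi / 2)
  expect_equal(theta_steady_state(c(-0.5, 0.25)),
               c(-acos(0.5 / 1.5), 0))
  # stable/unstable pair: drift is zero at both theta_s and -theta_s
  I0 <- -0.7
  ts <- theta_steady_state(I0)
  expect_equal(cm_drift(ts, I0), 0, tolerance = 1e-12)
  expect_equal(cm_drift(-ts, I0), 0, tolerance = 1e-12)
})

test_that("theta drift and output obey their defining identities", {
  expect_equal(cm_drift(pi, I = 123), 2)
  expect_equal(cm_drift(0, I = 0), 0)
  expect_equal(cm_output(0.3, 0.3), 0)               # rest -> zero output
  expect_equal(cm_output(0.3 + pi, 0.3), 2)          # half rotation -> max
})

test_that("critical coupling and critical distance follow the closed forms", {
  expect_equal(critical_coupling(N = 10, T_bif = 0, x0 = -1, Y_mean = 0.5,
                                 k_in = 4), 5)
  expect_equal(critical_coupling(10, 0, -1, 0.5, 8),
               critical_coupling(10, 0, -1, 0.5, 4) / 2)
  expect_equal(critical_coupling(10, 0, 0, 0.5, 4), 0)  # at the bifurcation
  expect_error(critical_coupling(10, 0, -1, 0.5, 0), "k_in = 0")

  expect_equal(critical_distance(10, 0, C = 0, 0.5, 4), 0)
  expect_equal(critical_distance(10, 0, C = 5, 0.5, 4), -1)
  expect_lt(critical_distance(10, 0, 5, 0.5, 6),
            critical_distance(10, 0, 5, 0.5, 2))
})

test_that("starred parameter conversions invert each other", {
  g <- generate_network("random", 20, 4, seed = 9)
  p <- cm_from_starred(distance = 1.3, sigma_star = 5, w_star = 1.7, g)
  st <- cm_to_starred(p, g)
  expect_equal(st$distance, 1.3)
  expect_equal(st$sigma_star, 5)
  expect_equal(st$w_star, 1.7)

  q <- wm_from_starred(distance = 1.45, sigma_star = 5, lambda_star = 1.09, g)
  expect_equal(wm_critical_input(q) - q$p0, 1.45, tolerance = 1e-9)
  stw <- wm_to_starred(q, g)
  expect_equal(stw$sigma_star, 5)
  expect_equal(stw$lambda_star, 1.09)
})
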