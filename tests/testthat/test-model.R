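test_that("mexican-hat kernel values, zero crossing, and decay", {
  p <- nf_params()
  expect_equal(kernel_w(0, p), 0.83)
  expect_true(all(kernel_w(seq(10, 20, by = 1), p) < 1e-6))
  # root-find oracle for the sign change, against the closed form
  dstar <- uniroot(function(d) kernel_w(d, p), c(1, 2), tol = 1e-12)$root
  expect_equal(dstar, sqrt(log(1 / 0.17) / 0.8), tolerance = 1e-9)
  d <- seq(0, 6, by = 0.01)
  expect_true(all(kernel_w(d[d < dstar - 1e-9], p) > 0))
  expect_true(all(kernel_w(d[d > dstar + 1e-9], p) < 0))
  expect_error(kernel_w(-1, p), "nonnegative")
})

test_that("sigmoid firing rate: midpoint, symmetry, monotonicity, saturation", {
  expect_equal(firing_rate(0, 5), 0.5)
  expect_equal(firing_rate(0.2, 5), 1 / (1 + exp(-1)), tolerance = 1e-12)
  u <- seq(-3, 3, by = 0.05)
  expect_equal(firing_rate(-u, 5), 1 - firing_rate(u, 5), tolerance = 1e-12)
  expect_true(all(diff(firing_rate(u, 5)) > 0))
  expect_equal(firing_rate(c(-1000, 1000), 5), c(0, 1))
  expect_true(all(is.finite(firing_rate(c(-1e6, 1e6), 5))))
  expect_error(firing_rate(0, beta = -1), "beta")
})

test_that("kernel mass: closed form, periodic-plane quadrature, uniformity", {
  p <- nf_params()
  expect_equal(kernel_mass(params = p), 0.15 * pi, tolerance = 1e-12)
  m <- fixture("plane65", function() plane_mesh(7.5, 65))
  expect_equal(kernel_mass(m, p), 0.15 * pi, tolerance = 1e-4)
  # brute-force fine-grid trapezoid oracle, independent of vertex weights
  xs <- seq(-7.5, 7.5, length.out = 301)[-301]
  g <- expand.grid(x = xs, y = xs)
  brute <- (xs[2] - xs[1])^2 *
    sum(kernel_w(sqrt(g$x^2 + g$y^2), p))
  expect_equal(kernel_mass(m, p), brute, tolerance = 1e-4)
  # translation invariance: same value at every node
  dist <- all_pairs_distances(plane33(), backend = "analytic")
  masses <- vapply(c(1, 17, 301, 900),
                   function(i) kernel_mass(plane33(), p, dist = dist, node = i),
                   numeric(1))
  expect_lt(diff(range(masses)), 1e-12)
})

test_that("two-patch initial conditions take the prescribed levels", {
  m <- plane33()
  st <- initial_state(m)
  expect_setequal(unique(st$u), c(0, 1))
  expect_setequal(unique(st$a), c(0, 1.5))
  # the recovery patch sits to the right of the activity patch
  xy <- distinct_xy(m)
  expect_gt(mean(xy[st$a > 0, 1]), mean(xy[st$u > 0, 1]))
  tor <- small_torus()
  st2 <- initial_state(tor, u_level = 2, u_size = c(1, 0.8))
  expect_setequal(unique(st2$u), c(0, 2))
  expect_setequal(unique(st2$a), c(0, 1.5))
  expect_error(initial_state(m, u_size = c(1e-6, 1e-6)), "patch")
})

test_that("general-mesh patches cover the requested fraction of nodes", {
  bt <- fixture("bumpy", function() bumpy_torus_mesh(n_theta = 16, n_phi = 32))
  n <- n_nodes(bt)
  st <- initial_state(bt, u_level = 2, node = 1L, a_node = 2L, frac = 0.01)
  expect_equal(sum(st$u != 0), round(0.01 * n))
  expect_equal(sum(st$a != 0), round(0.01 * n))
  expect_error(initial_state(bt, node = 1L), "a_node")
})

test_that("uniform steady state satisfies a = B u and balances the gain", {
  p <- nf_params()
  fp <- uniform_fixed_point(p)
  expect_equal(fp$a, p$B * fp$u)
  Wbar <- kernel_mass(params = p)
  expect_equal((1 + p$B) * fp$u,
               p$A * Wbar * firing_rate(fp$u - p$h, p$beta), tolerance = 1e-10)
})
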