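test_that("recovery variable decays exponentially when B = 0", {
  p <- nf_params(B = 0)
  m <- plane_mesh(7.5, 9)
  dist <- all_pairs_distances(m, backend = "analytic")
  op <- nf_operator(m, dist, p)
  n <- nrow(op$W)
  a0 <- 1.5
  st <- structure(list(u = rep(0, n), a = rep(a0, n), t = 0),
                  class = "nf_state")
  sim <- nf_integrate(op, st, T = 10, params = p)
  # da/dt = -a/tau independently of u when B = 0
  expect_equal(sim$a[, 1], a0 * exp(-sim$times / p$tau), tolerance = 1e-5)
})

test_that("a uniform fixed point stays stationary under time integration", {
  p <- nf_params()
  m <- plane_mesh(7.5, 17)
  dist <- all_pairs_distances(m, backend = "analytic")
  op <- nf_operator(m, dist, p)
  Wbar <- rowSums(op$W)[1]  # discrete kernel mass: exact fixed point of the ODE
  fp <- uniform_fixed_point(p, Wbar = Wbar)
  n <- nrow(op$W)
  st <- structure(list(u = rep(fp$u, n), a = rep(fp$a, n), t = 0),
                  class = "nf_state")
  sim <- nf_integrate(op, st, T = 50, params = p)
  expect_lt(max(abs(sim$u - fp$u)), 1e-6)
  expect_lt(max(abs(sim$a - fp$a)), 1e-6)
})

test_that("halving the integrator tolerances barely changes the final state", {
  m <- plane_mesh(7.5, 17)
  st <- initial_state(m)
  dist <- all_pairs_distances(m, backend = "analytic")
  op <- nf_operator(m, dist)
  s1 <- nf_integrate(op, st, T = 20, atol = 1e-6, rtol = 1e-6)
  s2 <- nf_integrate(op, st, T = 20, atol = 5e-7, rtol = 5e-7)
  nt <- length(s1$times)
  expect_lt(max(abs(s1$u[nt, ] - s2$u[nt, ])), 1e-5)
})

test_that("dimension mismatches are rejected", {
  m <- plane_mesh(7.5, 9)
  op <- nf_operator(m, all_pairs_distances(m, backend = "analytic"))
  st <- structure(list(u = rep(0, 5), a = rep(0, 5), t = 0),
                  class = "nf_state")
  expect_error(nf_integrate(op, st, T = 1), "dimension")
})
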