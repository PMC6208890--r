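test_that("simplex map follows the vertex ordering convention", {
  v1 <- c(0, 0, 0); v2 <- c(2, 1, 0); v3 <- c(-1, 3, 0)
  expect_equal(as.vector(simplex_map(v1, v2, v3, 0, 0)), v1)
  expect_equal(as.vector(simplex_map(v1, v2, v3, 0, 1)), v2)  # s -> second
  expect_equal(as.vector(simplex_map(v1, v2, v3, 1, 0)), v3)  # r -> third
  expect_equal(as.vector(simplex_map(v1, v2, v3, 1 / 3, 1 / 3)),
               (v1 + v2 + v3) / 3)
  expect_error(simplex_map(v1, v2, v3, 0.8, 0.8), "unit simplex")
})

test_that("three-point vertex rule integrates linears exactly on the simplex", {
  rl <- simplex_rule("vertex")
  expect_equal(sum(rl$weights), 0.5)
  expect_equal(integrate_on_simplex(function(r, s) 1, rl), 0.5)
  expect_equal(integrate_on_simplex(function(r, s) r, rl), 1 / 6)
  expect_equal(integrate_on_simplex(function(r, s) r + s, rl), 1 / 3)
  # midpoint rule is exact one degree higher
  rm <- simplex_rule("midpoint")
  expect_equal(integrate_on_simplex(function(r, s) r^2, rm), 1 / 12)
  expect_equal(integrate_on_simplex(function(r, s) r * s, rm), 1 / 24)
})

test_that("collocation equals trapezoid equals FFT on the regular periodic grid", {
  p <- nf_params()
  m <- plane33()
  xy <- distinct_xy(m)
  node <- neurofield:::origin_node(m)
  probes <- c(node, 1, 400)
  drows <- t(vapply(probes, function(i) plane_distance(xy[i, ], xy, 7.5),
                    numeric(nrow(xy))))
  u <- kernel_w(drows[1, ], p)
  Ic <- collocation_integral(m, u, drows, p)
  It <- trapezoid_integral_plane(m, u, p, nodes = probes)
  If <- fft_integral_plane(m, u, p)[probes]
  expect_equal(Ic, It, tolerance = 1e-13)
  expect_equal(If, It, tolerance = 1e-13)
})

test_that("assembled operator reproduces the brute-force per-triangle sum", {
  p <- nf_params()
  tm <- torus_mesh(4.5, 2, 6, 9)
  dist <- all_pairs_distances(tm)
  d1 <- dist$values[1, ]
  u <- kernel_w(d1, p)
  I1 <- collocation_integral(tm, u, d1, p)
  s <- firing_rate(u - p$h, p$beta)
  I2 <- 0
  for (k in seq_len(nrow(tm$triangles)))
    for (j in 1:3) {
      vj <- tm$triangles[k, j]
      I2 <- I2 + tm$areas[k] / 3 * kernel_w(d1[vj], p) * s[vj]
    }
  expect_equal(I1, I2, tolerance = 1e-12)
  # dense operator route gives the same number from the same distances
  op <- nf_operator(tm, dist, p)
  expect_equal(as.vector(op$W %*% s)[1], I2, tolerance = 1e-12)
})

test_that("uniform fields reduce the integral to S(c - h) times the row sum", {
  p <- nf_params()
  m <- plane33()
  dist <- all_pairs_distances(m, backend = "analytic")
  op <- nf_operator(m, dist, p)
  rs <- rowSums(op$W)
  expect_lt(diff(range(rs)) / mean(rs), 1e-12)  # translation invariance
  cvals <- rep(2, nrow(op$W))
  out <- op$W %*% firing_rate(cvals - p$h, p$beta)
  expect_equal(as.vector(out), firing_rate(2 - p$h, p$beta) * rs,
               tolerance = 1e-12)
})

test_that("torus trapezoid rule carries the exact area element", {
  p <- nf_params()
  tm <- torus_mesh(4.5, 2, 24, 48)
  n <- n_nodes(tm)
  # constant kernel (d = 0 everywhere) and saturated S: the sum collapses to
  # w(0) * total parametric area, which the periodic sum gives exactly
  I <- trapezoid_integral_torus(tm, rep(1000, n), matrix(0, 1, n), p)
  expect_equal(I, 0.83 * 4 * pi^2 * 4.5 * 2, tolerance = 1e-9)
  expect_error(trapezoid_integral_torus(tm, rep(1, n + 1), matrix(0, 1, n + 1), p),
               "shape|grid")
  # mirror symmetry phi -> -phi for a phi-symmetric field
  dp <- all_pairs_distances(tm, backend = "parametric")
  ang <- torus_angles(tm)
  u <- kernel_w(dp$values[1, ], p)
  jplus <- which(abs(ang$theta) < 1e-9 & abs(ang$phi - ang$phi[1 + 24]) < 1e-9)
  jminus <- which(abs(ang$theta) < 1e-9 &
                  abs(ang$phi - (2 * pi - ang$phi[1 + 24])) < 1e-9)
  Ipm <- trapezoid_integral_torus(tm, u, dp$values[c(jplus, jminus), ], p)
  expect_equal(Ipm[1], Ipm[2], tolerance = 1e-9)
})

test_that("midpoint-rule collocation converges towards the vertex rule", {
  # interpolating vertex distances to edge midpoints is worst near the
  # evaluation node (the distance cone apex), so agreement is only
  # first-order accurate; assert convergence and closeness on a fine grid
  p <- nf_params()
  gap <- vapply(c(33, 65), function(pp) {
    m <- plane_mesh(7.5, pp)
    xy <- distinct_xy(m)
    node <- neurofield:::origin_node(m)
    drow <- plane_distance(xy[node, ], xy, 7.5)
    u <- kernel_w(drow, p)
    abs(collocation_integral(m, u, drow, p, rule = "midpoint") -
        collocation_integral(m, u, drow, p, rule = "vertex"))
  }, numeric(1))
  expect_lt(gap[2], gap[1])
  expect_lt(gap[2], 0.06 * 0.36)
})
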