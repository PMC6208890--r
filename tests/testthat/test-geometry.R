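test_that("regular periodic plane mesh follows the refinement schedule", {
  m <- plane_mesh(7.5, 9)
  expect_equal(n_nodes(m), 81)
  expect_equal(nrow(m$triangles), 2 * 8^2)
  expect_equal(n_nodes(m, distinct = TRUE), 64)
  # N_m = (2^m * 8 + 1)^2 under quadrisection
  counts <- n_nodes(m)
  for (s in 1:3) {
    m <- refine_mesh(m)
    counts <- c(counts, n_nodes(m))
  }
  expect_equal(counts, (2^(0:3) * 8 + 1)^2)
  expect_equal(n_nodes(plane_mesh(7.5, 65)), 4225)
  expect_error(plane_mesh(7.5, 1), "points_per_side")
})

test_that("every distinct node of the periodic Cartesian mesh touches 6 triangles", {
  for (p in c(9, 17)) {
    m <- plane_mesh(7.5, p)
    ct <- neurofield:::canonical_triangulation(m)
    inc <- tabulate(ct$tri, nbins = ct$n)
    expect_true(all(inc == 6L))
    # which also makes every lumped vertex weight the trapezoidal dx^2
    dx <- 15 / (p - 1)
    expect_equal(vertex_weights(m), rep(dx^2, ct$n), tolerance = 1e-12)
  }
})

test_that("irregular plane mesh is seeded, conforming, and non-degenerate", {
  m1 <- irregular_plane_mesh(7.5, 79, seed = 3)
  m2 <- irregular_plane_mesh(7.5, 79, seed = 3)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$triangles, m2$triangles)
  expect_lt(abs(n_nodes(m1) - 79) / 79, 0.15)
  expect_true(all(m1$areas > 1e-12 * 15^2))
  # interior nodes are off-lattice
  xy <- m1$vertices[, 1:2]
  interior <- abs(xy[, 1]) < 7.5 - 1e-9 & abs(xy[, 2]) < 7.5 - 1e-9
  on_lattice <- function(x) abs(x / (15 / 8) - round(x / (15 / 8))) < 1e-9
  expect_false(any(on_lattice(xy[interior, 1]) & on_lattice(xy[interior, 2])))
  # total area is the full square (conforming cover)
  expect_equal(sum(m1$areas), 15^2, tolerance = 1e-9)
  # periodic identification closes the mesh
  expect_true(m1$closed)
  m3 <- irregular_plane_mesh(7.5, 79, seed = 4)
  expect_false(isTRUE(all.equal(m1$vertices, m3$vertices)))
  expect_error(irregular_plane_mesh(7.5, 5), "target_nodes")
})

test_that("torus grid mesh has the prescribed nodes and closed topology", {
  m <- small_torus()
  expect_equal(n_nodes(m), 9 * 18)
  expect_equal(nrow(m$triangles), 2 * 9 * 18)
  expect_true(m$closed)
  expect_equal(euler_characteristic(m), 0)
  expect_error(torus_mesh(4.5, 2, 2, 18), "at least 3")
  expect_error(torus_mesh(2, 4.5, 9, 18), "R > r")
  # nodes sit exactly on the parameterised surface
  ang <- torus_angles(m)
  expect_equal(m$vertices, torus_point(ang$theta, ang$phi, 4.5, 2),
               tolerance = 1e-12)
})

test_that("quadrisection is conforming and preserves closed topology", {
  m <- small_torus()
  r1 <- refine_mesh(m)
  expect_equal(nrow(r1$triangles), 4 * nrow(m$triangles))
  expect_true(r1$closed)
  expect_equal(euler_characteristic(r1), 0)
  # parent vertices unchanged
  expect_equal(r1$vertices[seq_len(n_nodes(m)), ], m$vertices)
  # reprojection keeps new vertices on the analytic torus
  ang <- torus_angles(r1)
  expect_equal(r1$vertices, torus_point(ang$theta, ang$phi, 4.5, 2),
               tolerance = 1e-12)
})

test_that("refined torus mesh area converges to 4 pi^2 R r at second order", {
  m <- small_torus()
  exact <- 4 * pi^2 * 4.5 * 2
  errs <- abs(sum(m$areas) - exact)
  for (s in 1:3) {
    m <- refine_mesh(m)
    errs <- c(errs, abs(sum(m$areas) - exact))
  }
  ratios <- errs[-1] / errs[-length(errs)]
  expect_true(all(abs(ratios - 0.25) < 0.02))
  expect_lt(errs[length(errs)], 0.2)
})

test_that("angle-defect curvature obeys discrete Gauss-Bonnet", {
  gt <- gaussian_curvature(small_torus())
  expect_equal(sum(gt$defect), 0, tolerance = 1e-10)      # chi = 0
  oct <- octahedron_mesh()
  go <- gaussian_curvature(oct)
  expect_equal(sum(go$defect), 4 * pi, tolerance = 1e-10) # chi = 2
  # open mesh: single triangle has boundary vertices
  open_mesh <- nf_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(c(1, 2, 3)))
  expect_error(gaussian_curvature(open_mesh), "closed")
})

test_that("analytic torus curvature has the closed form cos(theta)/(r(R + r cos theta))", {
  expect_equal(torus_curvature(0, 4.5, 2), 1 / (2 * 6.5), tolerance = 1e-12)
  expect_equal(torus_curvature(pi, 4.5, 2), -0.2, tolerance = 1e-12)
  # discrete estimate approaches the analytic value on a refined mesh
  m <- refine_mesh(refine_mesh(small_torus()))
  ang <- torus_angles(m)
  K <- gaussian_curvature(m)$K
  outer_nodes <- which(abs(ang$theta) < 1e-9)
  expect_equal(mean(K[outer_nodes]), 1 / 13, tolerance = 0.05)
})

test_that("synthetic bumpy torus is closed with sign-varying curvature", {
  bt <- bumpy_torus_mesh(n_theta = 16, n_phi = 32)
  expect_true(bt$closed)
  expect_equal(euler_characteristic(bt), 0)
  K <- gaussian_curvature(bt)$K
  expect_true(min(K) < 0 && max(K) > 0)
})
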