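test_that("minimal-image distance on the periodic square", {
  L <- 7.5
  expect_equal(plane_distance(c(1, 2), c(1, 2), L), 0)
  expect_equal(plane_distance(c(-L, 0), c(L, 0), L), 0)        # identified
  expect_equal(plane_distance(c(0, 0), c(L, L), L), L * sqrt(2))
  # translation invariance modulo the period
  p <- c(-3, 2); q <- c(6, -7)
  into <- function(x) ((x + L) %% (2 * L)) - L
  expect_equal(plane_distance(p, q, L),
               plane_distance(into(p + 4.2), into(q + 4.2), L),
               tolerance = 1e-12)
  expect_error(plane_distance(c(8, 0), c(0, 0), L), "fundamental domain")
})

test_that("fast marching matches analytic distances on a fine flat mesh", {
  m <- fixture("plane65", function() plane_mesh(7.5, 65))
  ct <- neurofield:::canonical_triangulation(m)
  xy <- distinct_xy(m)
  node <- neurofield:::origin_node(m)
  dan <- plane_distance(xy[node, ], xy, 7.5)
  dfm <- surface_distances(m, ct$reps[node])[ct$reps, 1]
  rel <- abs(dfm - dan)[dan > 0] / dan[dan > 0]
  expect_lt(max(rel), 0.02)
})

test_that("graph distances bound fast-marching distances from above", {
  m <- plane33()
  ct <- neurofield:::canonical_triangulation(m)
  src <- ct$reps[c(1, 200)]
  dfm <- surface_distances(m, src, backend = "fmm")
  ddj <- surface_distances(m, src, backend = "dijkstra")
  expect_true(all(ddj - dfm >= -1e-6))
  expect_true(all(dfm >= 0))
})

test_that("torus arcs along the outer equator and meridians converge to arc length", {
  eq_err <- c(); mer_err <- c()
  for (nt in c(16, 32, 64)) {
    tm <- torus_mesh(4.5, 2, nt, 2 * nt)
    d1 <- surface_distances(tm, 1L)[, 1]
    ang <- torus_angles(tm)
    eq <- which(abs(ang$theta) < 1e-9)
    i_eq <- eq[which.min(abs(ang$phi[eq] - pi / 4))]
    eq_err <- c(eq_err, abs(d1[i_eq] - 6.5 * ang$phi[i_eq]))
    mer <- which(abs(ang$phi) < 1e-9)
    i_m <- mer[which.min(abs(ang$theta[mer] - pi / 2))]
    mer_err <- c(mer_err, abs(d1[i_m] - 2 * ang$theta[i_m]))
  }
  expect_true(all(diff(eq_err) < 0)) # error decreases under refinement
  expect_true(all(diff(mer_err) < 0))
  expect_lt(eq_err[3] / (6.5 * pi / 4), 0.005)
  expect_lt(mer_err[3] / pi, 0.005)
})

test_that("all-pairs matrix is symmetric with zero diagonal and finite entries", {
  d <- all_pairs_distances(small_torus())
  expect_equal(dim(d$values), c(162, 162))
  expect_equal(max(abs(d$values - t(d$values))), 0)
  expect_equal(diag(d$values), rep(0, 162))
  expect_true(all(is.finite(d$values)))
  # triangle inequality on sampled triples (backend tolerance)
  set.seed(1)
  for (k in 1:200) {
    ijk <- sample.int(162, 3)
    expect_lte(d$values[ijk[1], ijk[2]],
               d$values[ijk[1], ijk[3]] + d$values[ijk[3], ijk[2]] + 1e-6)
  }
})

test_that("parametric torus backend agrees with fast marching and analytic arcs", {
  tm <- torus_mesh(4.5, 2, 18, 36)
  dp <- all_pairs_distances(tm, backend = "parametric")
  ang <- torus_angles(tm)
  eq <- which(abs(ang$theta) < 1e-9)
  i_eq <- eq[which.min(abs(ang$phi[eq] - pi / 4))]
  expect_equal(dp$values[1, i_eq], 6.5 * ang$phi[i_eq], tolerance = 1e-3)
  # meridian pair theta = 0 -> pi at fixed phi: arc length pi * r
  i_mer <- which(abs(ang$phi) < 1e-9 & abs(ang$theta - pi) < 1e-9)
  expect_equal(dp$values[1, i_mer], 2 * pi, tolerance = 1e-2)
  dfm <- all_pairs_distances(tm, backend = "fmm")
  expect_lt(max(abs(dp$values - dfm$values)), 0.25)
  expect_error(all_pairs_distances(plane33(), backend = "parametric"),
               "torus")
})

test_that("distances are invariant under rigid motion of the embedding", {
  m <- small_torus()
  d0 <- surface_distances(m, 1L)[, 1]
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  m2 <- m
  m2$vertices <- m$vertices %*% rot + matrix(c(5, -3, 2), n_nodes(m), 3,
                                             byrow = TRUE)
  m2$domain <- NULL  # plain surface: metric comes from the embedding alone
  d2 <- surface_distances(m2, 1L)[, 1]
  expect_equal(d2, d0, tolerance = 1e-10)
})

test_that("distance cache round-trips bit-identically and detects mismatch", {
  m <- small_torus()
  f <- withr::local_tempfile(fileext = ".bin")
  d1 <- all_pairs_distances(m, cache_path = f)
  expect_true(file.exists(f))
  d2 <- all_pairs_distances(m, cache_path = f)     # reload
  expect_identical(d2$values, d1$values)
  # different mesh with same cache path: recompute with warning
  m2 <- torus_mesh(4.5, 2, 9, 19)
  expect_warning(d3 <- all_pairs_distances(m2, cache_path = f), "cache")
  expect_equal(dim(d3$values), c(9 * 19, 9 * 19))
})

test_that("disconnected meshes yield flagged infinite distances", {
  v <- rbind(octahedron_mesh()$vertices,
             octahedron_mesh()$vertices + 10)
  tri <- rbind(octahedron_mesh()$triangles,
               octahedron_mesh()$triangles + 6L)
  m <- nf_mesh(v, tri)
  expect_warning(d <- surface_distances(m, 1L), "disconnected")
  expect_true(any(!is.finite(d)))
})
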