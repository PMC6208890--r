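#' Lumped vertex quadrature weights of a triangulation
#'
#' The vertex-rule collocation weight of node j is
#' \eqn{A_j = \sum_{k: j \in \triangle_k} Area(\triangle_k)/3}: each triangle
#' spreads its area equally over its three corners. On the regular periodic
#' Cartesian mesh every distinct node touches six triangles of area
#' \eqn{\Delta x^2/2}, so \eqn{A_j = \Delta x^2} — the trapezoidal weight.
#'
#' @param mesh an `nf_mesh`.
#' @return numeric vector over distinct nodes.
#' @export
vertex_weights <- function(mesh) {
  ct <- canonical_triangulation(mesh)
  w <- numeric(ct$n)
  third <- mesh$areas / 3
  for (j in 1:3) {
    acc <- as.numeric(tapply(third, factor(ct$tri[, j], levels = seq_len(ct$n)),
                             sum, default = 0))
    acc[is.na(acc)] <- 0
    w <- w + acc
  }
  as.numeric(w)
}

#' Assemble the dense collocation interaction operator
#'
#' Entry (i, j) is \eqn{w(d(v_i, v_j)) A_j} with \eqn{A_j} the lumped vertex
#' weight, so that `op$W %*% firing_rate(u - h, beta)` is the vertex-rule
#' collocation approximation of the nonlocal integral at every distinct node
#' (before the gain factor A). Row sums approximate the kernel mass; on a
#' translation-invariant mesh all row sums agree.
#'
#' @param mesh an `nf_mesh`.
#' @param dist an `nf_distances` over the same mesh (any backend).
#' @param params an [nf_params()].
#' @return an `nf_operator`: list(W, weights, params, mesh_hash).
#' @export
nf_operator <- function(mesh, dist, params = nf_params()) {
  wts <- vertex_weights(mesh)
  if (nrow(dist$values) != length(wts))
    stop("distance matrix does not match mesh node count")
  W <- kernel_w(dist$values, params)
  W <- sweep(W, 2, wts, "*")
  structure(list(W = W, weights = wts, params = params,
                 mesh_hash = dist$mesh_hash, backend = dist$backend),
            class = "nf_operator")
}

#' @export
print.nf_operator <- function(x, ...) {
  rs <- range(rowSums(x$W))
  cat("nf_operator:", nrow(x$W), "x", ncol(x$W),
      sprintf("(distances: %s); row sums in [%.6g, %.6g]\n",
              x$backend, rs[1], rs[2]))
  invisible(x)
}

#' Collocation approximation of the nonlocal integral at selected nodes
#'
#' Evaluates \eqn{I(v_i) = \int_\Omega w(d(v_i, x')) S(u(x') - h) d\Omega(x')}
#' by piecewise-linear collocation: the triangle-by-triangle quadrature
#' \eqn{\sum_k 2 Area_k \sum_q \omega_q\, w(d(v_i, T_k(r_q, s_q)))
#' S(u_n(T_k) - h)}. With the default vertex rule this regroups into the
#' lumped weighted sum over nodes; the `midpoint` rule interpolates both u
#' and the vertex distances barycentrically to the edge midpoints
#' (experimental higher-order variant).
#'
#' @param mesh an `nf_mesh`.
#' @param u activity over distinct nodes.
#' @param dist_rows matrix (length(nodes) x n_distinct) of distances from
#'   each evaluation node to every distinct node.
#' @param params an [nf_params()].
#' @param rule "vertex" (default) or "midpoint".
#' @return numeric vector, one integral value per evaluation node.
#' @export
collocation_integral <- function(mesh, u, dist_rows, params = nf_params(),
                                 rule = "vertex") {
  if (is.null(dim(dist_rows))) dist_rows <- matrix(dist_rows, nrow = 1)
  ct <- canonical_triangulation(mesh)
  if (ncol(dist_rows) != ct$n) stop("dist_rows has wrong width")
  s_of_u <- firing_rate(u - params$h, params$beta)
  if (rule == "vertex") {
    wts <- vertex_weights(mesh)
    return(as.vector(kernel_w(dist_rows, params) %*% (wts * s_of_u)))
  }
  rl <- simplex_rule(rule)
  tri <- ct$tri
  out <- numeric(nrow(dist_rows))
  for (q in seq_along(rl$weights)) {
    r <- rl$nodes[q, 1]; s <- rl$nodes[q, 2]
    l <- c(1 - r - s, s, r)
    uq <- l[1] * u[tri[, 1]] + l[2] * u[tri[, 2]] + l[3] * u[tri[, 3]]
    sq <- firing_rate(uq - params$h, params$beta)
    for (i in seq_len(nrow(dist_rows))) {
      dq <- l[1] * dist_rows[i, tri[, 1]] + l[2] * dist_rows[i, tri[, 2]] +
        l[3] * dist_rows[i, tri[, 3]]
      out[i] <- out[i] +
        sum(2 * mesh$areas * rl$weights[q] * kernel_w(dq, params) * sq)
    }
  }
  out
}

# recover the regular periodic grid structure of a plane mesh: distinct nodes
# arranged as an M x M row-major lattice with spacing dx
plane_grid_index <- function(mesh) {
  if (!identical(mesh$domain$type, "plane"))
    stop("not a periodic plane mesh")
  ct <- canonical_triangulation(mesh)
  xy <- mesh$vertices[ct$reps, 1:2, drop = FALSE]
  L <- mesh$domain$L
  xs <- sort(unique(round(xy[, 1], 9)))
  ys <- sort(unique(round(xy[, 2], 9)))
  M <- length(xs)
  if (length(ys) != M || nrow(xy) != M * M)
    stop("mesh nodes do not form a regular Cartesian grid")
  dx <- diff(xs)
  if (max(abs(dx - dx[1])) > 1e-9) stop("grid spacing is not uniform")
  ix <- match(round(xy[, 1], 9), xs)
  iy <- match(round(xy[, 2], 9), ys)
  ord <- order(iy, ix)  # row-major: x fastest
  list(M = M, dx = dx[1], order = ord, xs = xs, ys = ys, L = L)
}

#' Trapezoidal rule for the nonlocal integral on the regular periodic plane
#'
#' Composite trapezoidal rule on the periodic Cartesian grid: uniform weights
#' \eqn{\Delta x^2} over distinct nodes. Errors for non-uniform meshes.
#'
#' @param mesh a regular periodic plane `nf_mesh`.
#' @param u activity over distinct nodes.
#' @param params an [nf_params()].
#' @param nodes distinct-node indices at which to evaluate (default: all).
#' @return numeric vector of integral values at `nodes`.
#' @export
trapezoid_integral_plane <- function(mesh, u, params = nf_params(),
                                     nodes = NULL) {
  g <- plane_grid_index(mesh)
  ct <- canonical_triangulation(mesh)
  xy <- mesh$vertices[ct$reps, 1:2, drop = FALSE]
  if (is.null(nodes)) nodes <- seq_len(ct$n)
  s_of_u <- firing_rate(u - params$h, params$beta)
  out <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    drow <- plane_distance(xy[nodes[i], ], xy, g$L)
    out[i] <- g$dx^2 * sum(kernel_w(drow, params) * s_of_u)
  }
  out
}

#' FFT evaluation of the nonlocal integral on the regular periodic plane
#'
#' The minimal-image kernel makes the integral a circular convolution on the
#' distinct-node grid, evaluated with the 2-D FFT and scaled by
#' \eqn{\Delta x^2}. Agrees with the trapezoidal rule to machine precision.
#'
#' @inheritParams trapezoid_integral_plane
#' @return numeric vector of integral values at every distinct node.
#' @export
fft_integral_plane <- function(mesh, u, params = nf_params()) {
  g <- plane_grid_index(mesh)
  M <- g$M
  # arrange the field on the grid: entry (ix, iy), x index fastest
  s_grid <- matrix(firing_rate(u - params$h, params$beta)[g$order], M, M)
  offs <- wrap_period((seq_len(M) - 1L) * g$dx, 2 * g$L)
  dmat <- sqrt(outer(offs^2, offs^2, "+"))
  kmat <- kernel_w(dmat, params)
  conv <- Re(stats::fft(stats::fft(kmat) * stats::fft(s_grid), inverse = TRUE)) / M^2
  out <- numeric(M * M)
  out[g$order] <- as.vector(conv)
  g$dx^2 * out
}

#' Trapezoidal rule for the nonlocal integral on the torus parameter grid
#'
#' Double periodic trapezoidal sum of Eq. the polar-form integrand including
#' the area element \eqn{r (R + r\cos\theta')\,d\theta' d\phi'} on a regular
#' (theta, phi) grid. Because the geodesic-distance kernel on the torus is
#' not translation invariant in theta, this integral is not a convolution and
#' has no FFT shortcut.
#'
#' @param mesh a regular `torus_mesh()`.
#' @param u activity over distinct nodes (grid order: theta fastest).
#' @param dist_rows distances from each evaluation node to all nodes
#'   (matrix, one row per entry of `nodes`).
#' @param params an [nf_params()].
#' @param nodes node indices corresponding to the rows of `dist_rows`.
#' @return numeric vector of integral values at `nodes`.
#' @export
trapezoid_integral_torus <- function(mesh, u, dist_rows, params = nf_params(),
                                     nodes = NULL) {
  if (!identical(mesh$domain$type, "torus") || is.null(mesh$domain$n_theta))
    stop("requires a regular torus grid mesh")
  if (is.null(dim(dist_rows))) dist_rows <- matrix(dist_rows, nrow = 1)
  nt <- mesh$domain$n_theta; np <- mesh$domain$n_phi
  if (length(u) != nt * np || ncol(dist_rows) != nt * np)
    stop("field/distance shape does not match the torus grid")
  R <- mesh$domain$R; r <- mesh$domain$r
  dth <- 2 * pi / nt; dph <- 2 * pi / np
  theta <- rep((seq_len(nt) - 1) * dth, times = np)
  area_el <- r * (R + r * cos(theta)) * dth * dph
  s_of_u <- firing_rate(u - params$h, params$beta)
  as.vector(kernel_w(dist_rows, params) %*% (area_el * s_of_u))
}
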