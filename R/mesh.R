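#' Triangulated domains for neural field simulations
#'
#' An `nf_mesh` stores a conforming triangulation of the simulation domain:
#' vertex coordinates (planar meshes embed with z = 0), triangle connectivity,
#' and, for the flat periodic square, an identification map that glues opposite
#' boundary vertices together. All numerical layers (geodesic distances,
#' quadrature operators) work on the *distinct* (canonical) nodes; the raw
#' vertex list may contain periodic copies so that every triangle has
#' geometrically consistent corner coordinates.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z).
#' @param triangles integer matrix with 3 columns of 1-based vertex indices.
#' @param periodic_map optional integer vector mapping every vertex to its
#'   canonical representative (identity where no identification is needed).
#' @param domain optional list describing the underlying smooth domain, e.g.
#'   `list(type = "plane", L = 7.5)` or `list(type = "torus", R = 4.5, r = 2)`.
#'
#' @return An object of class `nf_mesh`.
#' @export
nf_mesh <- function(vertices, triangles, periodic_map = NULL, domain = NULL) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) == 2) vertices <- cbind(vertices, 0)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  nv <- nrow(vertices)
  if (nrow(triangles) < 1L || ncol(triangles) != 3L)
    stop("triangles must be an m x 3 index matrix")
  if (min(triangles) < 1L || max(triangles) > nv)
    stop("triangle index out of range")
  if (!is.null(periodic_map)) {
    periodic_map <- as.integer(periodic_map)
    if (length(periodic_map) != nv) stop("periodic_map has wrong length")
  }
  m <- structure(
    list(vertices = vertices, triangles = triangles,
         periodic_map = periodic_map, domain = domain),
    class = "nf_mesh")
  areas <- mesh_areas(m)
  if (any(!is.finite(areas)) || any(areas <= 0))
    stop("mesh contains degenerate (zero-area) triangles")
  m$areas <- areas
  m$closed <- mesh_is_closed(m)
  m
}

#' @export
print.nf_mesh <- function(x, ...) {
  nd <- n_nodes(x)
  cat("nf_mesh:", nrow(x$vertices), "vertices (", nd, "distinct ),",
      nrow(x$triangles), "triangles\n")
  if (!is.null(x$domain))
    cat("  domain:", x$domain$type,
        paste(sprintf("%s=%g", setdiff(names(x$domain), "type"),
                      unlist(x$domain[setdiff(names(x$domain), "type")])),
              collapse = ", "), "\n")
  cat("  closed:", x$closed, " total area:", sum(x$areas), "\n")
  invisible(x)
}

#' Per-triangle areas (half cross-product norm)
#' @param mesh an `nf_mesh`.
#' @return numeric vector of positive areas.
#' @export
mesh_areas <- function(mesh) {
  v <- mesh$vertices
  t1 <- mesh$triangles[, 1]; t2 <- mesh$triangles[, 2]; t3 <- mesh$triangles[, 3]
  e1 <- v[t2, , drop = FALSE] - v[t1, , drop = FALSE]
  e2 <- v[t3, , drop = FALSE] - v[t1, , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

canonical_ids <- function(mesh) {
  if (is.null(mesh$periodic_map)) seq_len(nrow(mesh$vertices))
  else mesh$periodic_map
}

#' Number of distinct nodes of a mesh
#'
#' For periodic meshes this counts identified boundary vertices once; the raw
#' vertex count (used in the classical node-count bookkeeping of regular
#' refinement schedules) is `nrow(mesh$vertices)`.
#' @param mesh an `nf_mesh`.
#' @param distinct count identified nodes once (default FALSE: raw vertices).
#' @export
n_nodes <- function(mesh, distinct = FALSE) {
  if (distinct) length(unique(canonical_ids(mesh))) else nrow(mesh$vertices)
}

# triangles rewritten in canonical (distinct-node) indexing, with the lookup
# from canonical label to compacted 1..n_distinct index
canonical_triangulation <- function(mesh) {
  can <- canonical_ids(mesh)
  reps <- sort(unique(can))
  lookup <- integer(nrow(mesh$vertices))
  lookup[reps] <- seq_along(reps)
  tri <- matrix(lookup[can[mesh$triangles]], ncol = 3)
  list(tri = tri, reps = reps, n = length(reps))
}

# undirected canonical edges as a 2-column matrix plus incidence counts
mesh_edge_table <- function(mesh) {
  ct <- canonical_triangulation(mesh)
  e <- rbind(ct$tri[, c(1, 2)], ct$tri[, c(2, 3)], ct$tri[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  uk <- names(cnt)
  parts <- do.call(rbind, strsplit(uk, " ", fixed = TRUE))
  list(edges = cbind(as.integer(parts[, 1]), as.integer(parts[, 2])),
       count = as.integer(cnt))
}

mesh_is_closed <- function(mesh) {
  et <- mesh_edge_table(mesh)
  all(et$count == 2L)
}

#' Euler characteristic V - E + F of the identified mesh
#' @param mesh an `nf_mesh`.
#' @export
euler_characteristic <- function(mesh) {
  ct <- canonical_triangulation(mesh)
  et <- mesh_edge_table(mesh)
  ct$n - nrow(et$edges) + nrow(ct$tri)
}

#' Regular periodic Cartesian triangulation of the square [-L, L]^2
#'
#' Builds a uniform grid of `points_per_side`^2 vertices (both boundary rows
#' included and identified with their opposite sides through `periodic_map`),
#' each grid cell split into two triangles by a single consistent diagonal.
#' After identification every distinct node is incident to exactly six
#' triangles, which is what makes vertex-rule collocation on this mesh
#' coincide with the trapezoidal rule.
#'
#' @param L half-width of the domain (default 7.5).
#' @param points_per_side number of grid points per side (>= 2).
#' @return an `nf_mesh` with a `plane` domain.
#' @export
plane_mesh <- function(L = 7.5, points_per_side) {
  p <- as.integer(points_per_side)
  if (is.na(p) || p < 2L) stop("points_per_side must be at least 2")
  if (!is.numeric(L) || L <= 0) stop("L must be positive")
  xs <- seq(-L, L, length.out = p)
  g <- expand.grid(x = xs, y = xs)   # x fastest
  vid <- function(i, j) (j - 1L) * p + i      # i = column (x), j = row (y)
  # periodic identification: index p maps to index 1 in each direction
  wrap <- function(i) ifelse(i == p, 1L, i)
  can <- vid(wrap(((seq_len(p * p) - 1L) %% p) + 1L),
             wrap(((seq_len(p * p) - 1L) %/% p) + 1L))
  tri <- matrix(0L, nrow = 2L * (p - 1L)^2, ncol = 3)
  k <- 0L
  for (j in seq_len(p - 1L)) {
    for (i in seq_len(p - 1L)) {
      a <- vid(i, j); b <- vid(i + 1L, j); c <- vid(i, j + 1L); d <- vid(i + 1L, j + 1L)
      tri[k + 1L, ] <- c(a, b, d)
      tri[k + 2L, ] <- c(a, d, c)
      k <- k + 2L
    }
  }
  nf_mesh(cbind(g$x, g$y, 0), tri, periodic_map = can,
          domain = list(type = "plane", L = L))
}

#' Seeded irregular triangulation of the periodic square [-L, L]^2
#'
#' Generates a general mesh whose interior vertices do not lie on a Cartesian
#' lattice: a jittered lattice of interior points is triangulated with a
#' boundary-constrained Delaunay step (package \pkg{deldir}) and relaxed by a
#' few Laplacian smoothing sweeps. Boundary nodes are fixed, equally spaced,
#' and placed identically on opposite sides so that periodic identification is
#' exact; corners are identified to a single node.
#'
#' @param L half-width of the domain.
#' @param target_nodes requested vertex count (the realised count stays within
#'   a few percent; at least 10).
#' @param seed integer seed; fixed seed gives an identical mesh.
#' @param smooth number of Laplacian smoothing sweeps.
#' @return an `nf_mesh` with a `plane` domain.
#' @export
irregular_plane_mesh <- function(L = 7.5, target_nodes, seed = 1L, smooth = 4L) {
  if (target_nodes < 10) stop("target_nodes too small to triangulate the square")
  p <- max(3L, as.integer(round(sqrt(target_nodes))))
  xs <- seq(-L, L, length.out = p)
  hx <- xs[2] - xs[1]
  # fixed boundary ring (counter-clockwise), excluding the duplicate corner
  bx <- c(xs[-p], rep(L, p - 1L), rev(xs)[-p], rep(-L, p - 1L))
  by <- c(rep(-L, p - 1L), xs[-p], rep(L, p - 1L), rev(xs)[-p])
  nb <- length(bx)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  gi <- expand.grid(x = xs[-c(1, p)], y = xs[-c(1, p)])
  ix <- gi$x + stats::runif(nrow(gi), -0.35, 0.35) * hx
  iy <- gi$y + stats::runif(nrow(gi), -0.35, 0.35) * hx
  px <- c(bx, ix); py <- c(by, iy)
  for (it in seq_len(smooth + 1L)) {
    dd <- deldir::deldir(px, py, rw = c(-L, L, -L, L), suppressMsge = TRUE)
    if (it > smooth) break
    # move interior points towards the mean of their Delaunay neighbours
    s <- dd$delsgs
    accx <- accy <- deg <- numeric(length(px))
    for (cols in list(c(5, 6), c(6, 5))) {
      a <- s[[cols[1]]]; b <- s[[cols[2]]]
      accx <- accx + unname(tapply(px[b], factor(a, levels = seq_along(px)),
                                   sum, default = 0))
      accy <- accy + unname(tapply(py[b], factor(a, levels = seq_along(px)),
                                   sum, default = 0))
      deg <- deg + unname(tapply(rep(1, length(a)),
                                 factor(a, levels = seq_along(px)),
                                 sum, default = 0))
    }
    accx[is.na(accx)] <- 0; accy[is.na(accy)] <- 0; deg[is.na(deg)] <- 0
    int <- seq.int(nb + 1L, length(px))
    ok <- int[deg[int] > 0]
    relax <- 0.7
    px[ok] <- (1 - relax) * px[ok] + relax * accx[ok] / deg[ok]
    py[ok] <- (1 - relax) * py[ok] + relax * accy[ok] / deg[ok]
    px[ok] <- pmin(pmax(px[ok], -L + 0.2 * hx), L - 0.2 * hx)
    py[ok] <- pmin(pmax(py[ok], -L + 0.2 * hx), L - 0.2 * hx)
  }
  tri <- deldir::triMat(dd)
  # periodic identification of the fixed boundary ring
  can <- seq_along(px)
  eps <- 1e-9 * L
  on_right <- abs(px - L) < eps; on_top <- abs(py - L) < eps
  for (v in which(on_right | on_top)) {
    tx <- if (on_right[v]) -L else px[v]
    ty <- if (on_top[v]) -L else py[v]
    tgt <- which(abs(px - tx) < eps & abs(py - ty) < eps)
    tgt <- tgt[!(on_right[tgt] | on_top[tgt])]
    if (length(tgt) == 1L) can[v] <- tgt
  }
  nf_mesh(cbind(px, py, 0), tri, periodic_map = can,
          domain = list(type = "plane", L = L))
}

#' Map torus angles to 3D coordinates
#'
#' Uses the standard parameterisation
#' \eqn{(\theta,\phi) \mapsto ((R + r\cos\theta)\cos\phi,
#' (R + r\cos\theta)\sin\phi, r\sin\theta)}.
#' @param theta,phi angle vectors (radians); `theta` winds around the tube,
#'   `phi` around the central axis.
#' @param R,r major and minor radii (R > r > 0).
#' @return n x 3 coordinate matrix.
#' @export
torus_point <- function(theta, phi, R, r) {
  cbind((R + r * cos(theta)) * cos(phi),
        (R + r * cos(theta)) * sin(phi),
        r * sin(theta))
}

#' Recover torus angles from embedded coordinates
#' @param mesh an `nf_mesh` with a torus domain (or any points on the torus).
#' @return data.frame with columns theta, phi.
#' @export
torus_angles <- function(mesh) {
  stopifnot(identical(mesh$domain$type, "torus"))
  v <- mesh$vertices
  R <- mesh$domain$R
  phi <- atan2(v[, 2], v[, 1])
  rho <- sqrt(v[, 1]^2 + v[, 2]^2)
  theta <- atan2(v[, 3], rho - R)
  data.frame(theta = theta %% (2 * pi), phi = phi %% (2 * pi))
}

#' Regular triangulated grid on the torus
#'
#' Places `n_theta * n_phi` distinct nodes at the images of the uniform angle
#' grid \eqn{\theta_i = i\,2\pi/n_\theta}, \eqn{\phi_j = j\,2\pi/n_\phi}
#' (wrap-around identified, no duplicated seam vertices) and splits every
#' rectangular cell into two triangles, yielding a closed genus-1 surface.
#'
#' @param R,r major and minor radii (default 4.5 and 2, R > r > 0).
#' @param n_theta,n_phi grid resolution around the tube and the axis (>= 3).
#' @return a closed `nf_mesh` with a `torus` domain.
#' @export
torus_mesh <- function(R = 4.5, r = 2, n_theta, n_phi) {
  if (!(R > r && r > 0)) stop("need R > r > 0")
  n_theta <- as.integer(n_theta); n_phi <- as.integer(n_phi)
  if (n_theta < 3L || n_phi < 3L) stop("n_theta and n_phi must be at least 3")
  th <- (seq_len(n_theta) - 1L) * 2 * pi / n_theta
  ph <- (seq_len(n_phi) - 1L) * 2 * pi / n_phi
  g <- expand.grid(i = seq_len(n_theta), j = seq_len(n_phi))  # i fastest
  verts <- torus_point(th[g$i], ph[g$j], R, r)
  vid <- function(i, j)
    (((j - 1L) %% n_phi)) * n_theta + ((i - 1L) %% n_theta) + 1L
  tri <- matrix(0L, nrow = 2L * n_theta * n_phi, ncol = 3)
  k <- 0L
  for (j in seq_len(n_phi)) {
    for (i in seq_len(n_theta)) {
      a <- vid(i, j); b <- vid(i + 1L, j); c <- vid(i, j + 1L); d <- vid(i + 1L, j + 1L)
      tri[k + 1L, ] <- c(a, b, d)
      tri[k + 2L, ] <- c(a, d, c)
      k <- k + 2L
    }
  }
  nf_mesh(verts, tri,
          domain = list(type = "torus", R = R, r = r,
                        n_theta = n_theta, n_phi = n_phi))
}

#' Quadrisection refinement
#'
#' Replaces every triangle by four via edge midpoints. Shared edges produce
#' shared midpoints, so a conforming mesh stays conforming; parent vertices
#' are unchanged. On periodic meshes the identification map is propagated to
#' the new midpoints. When the mesh carries a torus domain, new midpoints are
#' reprojected onto the analytic surface, so vertices always lie on the torus
#' while the elements stay planar.
#'
#' @param mesh an `nf_mesh`.
#' @param reproject reproject new vertices onto the attached smooth surface
#'   (default TRUE; only meaningful for torus domains).
#' @return the refined `nf_mesh` (4x the triangles).
#' @export
refine_mesh <- function(mesh, reproject = TRUE) {
  v <- mesh$vertices
  tri <- mesh$triangles
  can <- canonical_ids(mesh)
  nv <- nrow(v)
  m <- nrow(tri)
  # one raw midpoint per unique raw edge; midpoints of identified (periodic
  # copy) edges are themselves identified through the canonical edge key
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  rawkey <- paste(lo, hi)
  first <- !duplicated(rawkey)
  uedge <- cbind(lo[first], hi[first])
  eid <- match(rawkey, rawkey[first])
  mid_raw <- nv + seq_len(nrow(uedge))
  clo <- pmin(can[uedge[, 1]], can[uedge[, 2]])
  chi <- pmax(can[uedge[, 1]], can[uedge[, 2]])
  ckey <- paste(clo, chi)
  newcan <- mid_raw[match(ckey, ckey)]
  ab <- mid_raw[eid[seq_len(m)]]
  bc <- mid_raw[eid[m + seq_len(m)]]
  ca <- mid_raw[eid[2L * m + seq_len(m)]]
  out <- rbind(cbind(tri[, 1], ab, ca),
               cbind(ab, tri[, 2], bc),
               cbind(ca, bc, tri[, 3]),
               cbind(ab, bc, ca))
  vertices <- rbind(v, (v[uedge[, 1], , drop = FALSE] +
                        v[uedge[, 2], , drop = FALSE]) / 2)
  if (reproject && identical(mesh$domain$type, "torus")) {
    idx <- seq.int(nv + 1L, nrow(vertices))
    R <- mesh$domain$R; r <- mesh$domain$r
    p <- vertices[idx, , drop = FALSE]
    phi <- atan2(p[, 2], p[, 1])
    theta <- atan2(p[, 3], sqrt(p[, 1]^2 + p[, 2]^2) - R)
    vertices[idx, ] <- torus_point(theta, phi, R, r)
  }
  pm <- if (is.null(mesh$periodic_map) && all(newcan == mid_raw))
    NULL else c(can, newcan)
  nf_mesh(vertices, out, periodic_map = pm, domain = mesh$domain)
}

#' Discrete Gaussian curvature by vertex angle defect
#'
#' Estimates Gaussian curvature at every distinct node of a closed mesh as the
#' angle defect (2\eqn{\pi} minus the sum of incident corner angles) divided by
#' one third of the incident triangle area. Summed raw defects equal
#' \eqn{2\pi\chi} (discrete Gauss-Bonnet).
#'
#' @param mesh a closed `nf_mesh`.
#' @return list with per-distinct-node `K`, raw `defect`, and `vertex_area`.
#' @export
gaussian_curvature <- function(mesh) {
  if (!isTRUE(mesh$closed))
    stop("angle-defect curvature requires a closed mesh (boundary vertices have undefined defect)")
  ct <- canonical_triangulation(mesh)
  v <- mesh$vertices
  tri <- mesh$triangles
  nrep <- ct$n
  angsum <- numeric(nrep); asum <- numeric(nrep)
  corner_angle <- function(p, q, s) {
    u <- v[q, , drop = FALSE] - v[p, , drop = FALSE]
    w <- v[s, , drop = FALSE] - v[p, , drop = FALSE]
    cosang <- rowSums(u * w) /
      (sqrt(rowSums(u * u)) * sqrt(rowSums(w * w)))
    acos(pmin(1, pmax(-1, cosang)))
  }
  for (j in 1:3) {
    oth <- setdiff(1:3, j)
    ang <- corner_angle(tri[, j], tri[, oth[1]], tri[, oth[2]])
    id <- ct$tri[, j]
    angsum <- angsum + unname(tapply(ang, factor(id, levels = seq_len(nrep)),
                                     sum, default = 0))
    asum <- asum + unname(tapply(mesh$areas, factor(id, levels = seq_len(nrep)),
                                 sum, default = 0))
  }
  angsum <- as.numeric(angsum); asum <- as.numeric(asum)
  angsum[is.na(angsum)] <- 0; asum[is.na(asum)] <- 0
  defect <- 2 * pi - angsum
  list(K = defect / (asum / 3), defect = defect, vertex_area = asum / 3,
       reps = ct$reps)
}

#' Analytic Gaussian curvature of the torus
#'
#' \eqn{K(\theta) = \cos\theta / (r (R + r\cos\theta))}: positive on the outer
#' equator, negative on the inner one.
#' @param theta tube angle (0 = outer equator).
#' @param R,r torus radii.
#' @export
torus_curvature <- function(theta, R, r) {
  cos(theta) / (r * (R + r * cos(theta)))
}

#' Synthetic bumpy closed surface (perturbed torus)
#'
#' A torus whose minor radius is modulated by an angular harmonic,
#' \eqn{\rho(\theta, \phi) = r (1 + a \cos(k_\theta \theta) \sin(k_\phi \phi))},
#' giving a closed genus-1 surface with spatially varying Gaussian curvature.
#' This is a synthetic test geometry for the general-mesh pipeline (folded
#' cortical sheets are the intended real-data analogue): it has no analytic
#' distance function, so all geodesics come from the mesh backends.
#'
#' @param R,r base torus radii.
#' @param n_theta,n_phi grid resolution.
#' @param amp relative modulation amplitude (default 0.15).
#' @param k_theta,k_phi integer wave numbers of the modulation.
#' @return a closed `nf_mesh` with a generic `surface` domain.
#' @export
bumpy_torus_mesh <- function(R = 4.5, r = 2, n_theta = 32, n_phi = 64,
                             amp = 0.15, k_theta = 2, k_phi = 3) {
  base <- torus_mesh(R, r, n_theta, n_phi)
  ang <- torus_angles(base)
  rho <- r * (1 + amp * cos(k_theta * ang$theta) * sin(k_phi * ang$phi))
  v <- torus_point(ang$theta, ang$phi, R, r)
  # move each vertex along the tube-radial direction to the modulated radius
  centre <- cbind(R * cos(ang$phi), R * sin(ang$phi), 0)
  dirn <- (v - centre) / r
  nf_mesh(centre + rho * dirn, base$triangles,
          domain = list(type = "surface"))
}
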