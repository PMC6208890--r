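#' Minimal-image distance on the flat periodic square
#'
#' The connectivity metric on \eqn{[-L, L]^2} with periodic boundary
#' conditions: the Euclidean length of the shortest displacement between two
#' points modulo the period \eqn{2L} in each coordinate. It is invariant under
#' simultaneous translation of both points.
#'
#' @param p,q points as length-2 vectors or n x 2 matrices (recycled).
#' @param L half-width of the domain.
#' @return numeric vector of distances.
#' @export
plane_distance <- function(p, q, L) {
  p <- matrix(as.numeric(p), ncol = 2)
  q <- matrix(as.numeric(q), ncol = 2)
  if (any(abs(p) > L + 1e-12) || any(abs(q) > L + 1e-12))
    stop("points must lie in the fundamental domain [-L, L]^2")
  n <- max(nrow(p), nrow(q))
  p <- p[rep_len(seq_len(nrow(p)), n), , drop = FALSE]
  q <- q[rep_len(seq_len(nrow(q)), n), , drop = FALSE]
  dx <- wrap_period(q[, 1] - p[, 1], 2 * L)
  dy <- wrap_period(q[, 2] - p[, 2], 2 * L)
  sqrt(dx^2 + dy^2)
}

wrap_period <- function(d, period) {
  d - period * round(d / period)
}

# per-triangle side lengths (column j = edge opposite corner j), computed
# with the minimal-image metric for periodic plane meshes so that seam
# triangles carry their true geometric size
mesh_metric_lengths <- function(mesh) {
  v <- mesh$vertices
  tri <- mesh$triangles
  periodic_plane <- identical(mesh$domain$type, "plane")
  L <- mesh$domain$L
  side <- function(a, b) {
    d <- v[b, 1:3, drop = FALSE] - v[a, 1:3, drop = FALSE]
    if (periodic_plane) {
      d[, 1] <- wrap_period(d[, 1], 2 * L)
      d[, 2] <- wrap_period(d[, 2], 2 * L)
    }
    sqrt(rowSums(d^2))
  }
  cbind(side(tri[, 2], tri[, 3]),
        side(tri[, 3], tri[, 1]),
        side(tri[, 1], tri[, 2]))
}

#' Intrinsic distances from source vertices across a triangulated surface
#'
#' Front-propagation (first-order fast marching with obtuse corners split by
#' unfolding) or edge-graph Dijkstra on the triangulation. Both backends are
#' intrinsic: periodic plane meshes are handled through the minimal-image
#' metric. Graph distances overestimate geodesics, so `dijkstra` values bound
#' the `fmm` values from above.
#'
#' @param mesh an `nf_mesh`.
#' @param sources integer vector of source vertex indices (raw, 1-based).
#' @param backend "fmm" (default) or "dijkstra".
#' @param exact_radius metric radius of the exact unfolding patch around each
#'   source used to initialise fast marching (default 1.5 length units, the
#'   excitatory range of the standard kernel; resolution-independent).
#' @return matrix with one column per source and one row per raw vertex.
#' @export
surface_distances <- function(mesh, sources, backend = c("fmm", "dijkstra"),
                              exact_radius = 1.5) {
  backend <- match.arg(backend)
  ct <- canonical_triangulation(mesh)
  len <- mesh_metric_lengths(mesh)
  can <- canonical_ids(mesh)
  lookup <- integer(nrow(mesh$vertices))
  lookup[ct$reps] <- seq_len(ct$n)
  src0 <- lookup[can[sources]] - 1L
  d <- if (backend == "fmm")
    fmm_mesh_cpp(ct$n, ct$tri - 1L, len, as.integer(src0), exact_radius)
  else dijkstra_mesh_cpp(ct$n, ct$tri - 1L, len, as.integer(src0))
  if (any(!is.finite(d)))
    warning("mesh is disconnected: some distances are infinite")
  # expand back to raw vertices
  out <- d[lookup[can], , drop = FALSE]
  dimnames(out) <- NULL
  out
}

mesh_hash <- function(mesh) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(v = round(mesh$vertices, 12), t = mesh$triangles,
               p = mesh$periodic_map), f)
  unname(tools::md5sum(f))
}

#' All-pairs geodesic distance matrix over distinct mesh nodes
#'
#' Computes (or reloads from cache) the symmetric matrix of intrinsic
#' distances between every pair of distinct nodes. Backend output is
#' symmetrised by averaging \eqn{d_{ij}} and \eqn{d_{ji}}; the maximum raw
#' asymmetry is kept as a diagnostic. The cache is a flat binary file keyed by
#' mesh hash and backend; a mismatching cache triggers recomputation with a
#' warning.
#'
#' @param mesh an `nf_mesh`.
#' @param backend "fmm", "dijkstra", "analytic" (periodic plane only:
#'   minimal-image closed form), or "parametric" (regular torus grids only:
#'   eikonal solves in the (theta, phi) parameter domain on a fine reference
#'   grid — the most accurate distance layer for the torus, playing the role
#'   exact polyhedral geodesics play for general meshes).
#' @param cache_path optional cache file path.
#' @param max_nodes guard: refuse matrices larger than this many nodes.
#' @return an `nf_distances` object: list(values, backend, mesh_hash, asymmetry).
#' @export
all_pairs_distances <- function(mesh,
                                backend = c("fmm", "dijkstra", "analytic",
                                            "parametric"),
                                cache_path = NULL, max_nodes = 20000L) {
  backend <- match.arg(backend)
  ct <- canonical_triangulation(mesh)
  if (ct$n > max_nodes)
    stop("distance matrix would need ", ct$n, "^2 entries; raise max_nodes if intended")
  hash <- mesh_hash(mesh)
  if (!is.null(cache_path) && file.exists(cache_path)) {
    cached <- read_distance_cache(cache_path)
    if (identical(cached$mesh_hash, hash) && identical(cached$backend, backend))
      return(cached)
    warning("distance cache does not match mesh/backend; recomputing")
  }
  if (backend == "analytic") {
    if (!identical(mesh$domain$type, "plane"))
      stop("analytic all-pairs distances are only available for periodic plane meshes")
    xy <- mesh$vertices[ct$reps, 1:2, drop = FALSE]
    L <- mesh$domain$L
    dx <- wrap_period(outer(xy[, 1], xy[, 1], "-"), 2 * L)
    dy <- wrap_period(outer(xy[, 2], xy[, 2], "-"), 2 * L)
    vals <- sqrt(dx^2 + dy^2)
    asym <- 0
  } else if (backend == "parametric") {
    if (!identical(mesh$domain$type, "torus") || is.null(mesh$domain$n_theta))
      stop("parametric all-pairs distances require a regular torus grid mesh")
    vals <- torus_parametric_pairs(mesh)
    asym <- max(abs(vals - t(vals)))
    vals <- (vals + t(vals)) / 2
  } else {
    raw <- surface_distances(mesh, ct$reps, backend = backend)
    raw <- raw[ct$reps, , drop = FALSE]
    asym <- max(abs(raw - t(raw)))
    vals <- (raw + t(raw)) / 2
  }
  diag(vals) <- 0
  obj <- structure(list(values = vals, backend = backend, mesh_hash = hash,
                        asymmetry = asym, reps = ct$reps),
                   class = "nf_distances")
  if (!is.null(cache_path)) write_distance_cache(obj, cache_path)
  obj
}

#' @export
print.nf_distances <- function(x, ...) {
  cat("nf_distances:", nrow(x$values), "x", ncol(x$values),
      "(", x$backend, "), max raw asymmetry", format(x$asymmetry), "\n")
  invisible(x)
}

write_distance_cache <- function(obj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("NFDIST01"), con)
  writeBin(nrow(obj$values), con, size = 4L)
  writeBin(nchar(obj$backend), con, size = 4L)
  writeBin(charToRaw(obj$backend), con)
  writeBin(charToRaw(obj$mesh_hash), con)
  writeBin(obj$asymmetry, con, size = 8L)
  writeBin(as.vector(obj$values), con, size = 8L)
  invisible(path)
}

read_distance_cache <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (magic != "NFDIST01") stop("not a neurofield distance cache: ", path)
  n <- readBin(con, "integer", 1L, size = 4L)
  bl <- readBin(con, "integer", 1L, size = 4L)
  backend <- rawToChar(readBin(con, "raw", bl))
  hash <- rawToChar(readBin(con, "raw", 32L))
  asym <- readBin(con, "double", 1L, size = 8L)
  vals <- matrix(readBin(con, "double", n * n, size = 8L), n, n)
  structure(list(values = vals, backend = backend, mesh_hash = hash,
                 asymmetry = asym, reps = NULL),
            class = "nf_distances")
}

# all-pairs distances on a regular torus grid via one parametric eikonal
# solve per theta row (nodes in a row share the field up to a phi shift);
# the reference grid is a multiple of the mesh grid so sources sit exactly
# on reference nodes
torus_parametric_pairs <- function(mesh, ref_mult = NULL) {
  R <- mesh$domain$R; r <- mesh$domain$r
  nt <- mesh$domain$n_theta; np <- mesh$domain$n_phi
  if (is.null(ref_mult)) ref_mult <- max(4L, ceiling(512 / nt))
  rt <- nt * as.integer(ref_mult); rp <- 2L * rt
  ang <- torus_angles(mesh)
  n <- nt * np
  D <- matrix(0, n, n)
  for (i0 in 0:(nt - 1)) {
    f <- torus_eikonal_cpp(R, r, rt, rp, i0 * as.integer(ref_mult), 0L,
                           1e-10, 80L)
    fobj <- structure(list(field = f, R = R, r = r),
                      class = "nf_torus_field")
    row_nodes <- which(abs(ang$theta - i0 * 2 * pi / nt) < 1e-9)
    for (sn in row_nodes)
      D[sn, ] <- torus_field_eval(fobj, ang$theta,
                                  (ang$phi - ang$phi[sn]) %% (2 * pi))
  }
  D
}

#' Geodesic distance field from the point (theta, phi) = (0, 0) on the torus
#'
#' Solves the eikonal equation in the torus parameter domain (metric
#' \eqn{ds^2 = r^2 d\theta^2 + (R + r\cos\theta)^2 d\phi^2}) with Godunov
#' upwind fast sweeping on a fine periodic reference grid. The resulting field
#' is evaluated anywhere by C1 periodic bicubic interpolation, giving a fixed,
#' smooth approximation of geodesic distance from the outer-equator reference
#' point that is independent of any simulation mesh.
#'
#' @param R,r torus radii.
#' @param n_theta_ref,n_phi_ref reference grid resolution.
#' @param tol,maxit sweeping stopping controls.
#' @return an `nf_torus_field` closure object; evaluate with
#'   [torus_field_eval()].
#' @export
torus_distance_field <- function(R = 4.5, r = 2, n_theta_ref = 768L,
                                 n_phi_ref = 1536L, tol = 1e-12, maxit = 80L) {
  f <- torus_eikonal_cpp(R, r, as.integer(n_theta_ref), as.integer(n_phi_ref),
                         0L, 0L, tol, as.integer(maxit))
  structure(list(field = f, R = R, r = r), class = "nf_torus_field")
}

#' Evaluate a torus distance field at angle pairs
#' @param fld an `nf_torus_field`.
#' @param theta,phi angle vectors (radians, any branch).
#' @return distances from the source point (0, 0).
#' @export
torus_field_eval <- function(fld, theta, phi) {
  bicubic_periodic_cpp(fld$field, theta %% (2 * pi), phi %% (2 * pi))
}
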