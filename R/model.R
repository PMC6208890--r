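#' Neural field model parameters
#'
#' The two-variable model couples an activity field u with a slow recovery
#' field a:
#' \deqn{\partial_t u = -u - a + A \int_\Omega w(d(x, x')) S(u(x') - h)\, d\Omega(x'),}
#' \deqn{\tau\, \partial_t a = B u - a,}
#' with mexican-hat connectivity
#' \eqn{w(d) = e^{-d^2} - c_2 e^{-\gamma d^2}} and sigmoidal firing rate
#' \eqn{S(v) = 1 / (1 + e^{-\beta v})}. Defaults: A = 2 (input gain),
#' B = 0.4 (recovery gain), h = 0.8 (firing threshold), tau = 3 (recovery
#' time constant), beta = 5 (sigmoid steepness), c2 = 0.17, gamma = 0.2.
#'
#' @param A,B,h,tau,beta model constants (tau > 0, beta > 0).
#' @param c2,gamma kernel coefficients (inhibitory amplitude and width).
#' @return an `nf_params` list.
#' @export
nf_params <- function(A = 2, B = 0.4, h = 0.8, tau = 3, beta = 5,
                      c2 = 0.17, gamma = 0.2) {
  if (tau <= 0) stop("tau must be positive")
  if (beta <= 0) stop("beta must be positive")
  structure(list(A = A, B = B, h = h, tau = tau, beta = beta,
                 c2 = c2, gamma = gamma),
            class = "nf_params")
}

#' @export
print.nf_params <- function(x, ...) {
  cat(sprintf("nf_params: A=%g B=%g h=%g tau=%g beta=%g  kernel: c2=%g gamma=%g\n",
              x$A, x$B, x$h, x$tau, x$beta, x$c2, x$gamma))
  invisible(x)
}

#' Mexican-hat connectivity kernel
#'
#' \eqn{w(d) = e^{-d^2} - c_2 e^{-\gamma d^2}}: short-range excitation
#' (w(0) = 1 - c2 = 0.83 at defaults) with a longer-range inhibitory
#' surround; the sign change sits at
#' \eqn{d^* = \sqrt{\log(1/c_2)/(1-\gamma)}}.
#'
#' @param d nonnegative distances (vector or matrix).
#' @param params an [nf_params()] object (only c2 and gamma are used).
#' @return kernel weights, same shape as `d`.
#' @export
kernel_w <- function(d, params = nf_params()) {
  if (any(d < 0)) stop("distances must be nonnegative")
  exp(-d^2) - params$c2 * exp(-params$gamma * d^2)
}

#' Sigmoidal firing rate
#'
#' \eqn{S(u) = 1/(1 + e^{-\beta u})}, evaluated overflow-safely: strictly
#' increasing, S(0) = 1/2, S(-u) = 1 - S(u), range (0, 1).
#'
#' @param u activity values (any real).
#' @param beta steepness (> 0).
#' @export
firing_rate <- function(u, beta = 5) {
  if (beta <= 0) stop("beta must be positive")
  x <- beta * u
  out <- ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
  out
}

#' Integral of the connectivity kernel over the domain
#'
#' The "kernel mass" \eqn{\bar W = \int_\Omega w(d(x_0, x'))\, d\Omega(x')}
#' at a reference node, needed to place spatially uniform steady states. On
#' the infinite plane the closed form is
#' \eqn{\pi - c_2 \pi/\gamma} (= 0.15\eqn{\pi} at the defaults); on the
#' periodic square with L = 7.5 the kernel tails are negligible at the
#' half-period so the value is within 1e-4 of that.
#'
#' @param mesh an `nf_mesh` (its vertex quadrature weights are used), or NULL
#'   to return the infinite-plane closed form.
#' @param params an [nf_params()].
#' @param dist optional `nf_distances` for the mesh (computed if missing:
#'   analytically on planes, fast marching otherwise).
#' @param node reference distinct-node index (default: node nearest the
#'   domain origin).
#' @return scalar \eqn{\bar W}.
#' @export
kernel_mass <- function(mesh = NULL, params = nf_params(), dist = NULL,
                        node = NULL) {
  if (is.null(mesh))
    return(pi - params$c2 * pi / params$gamma)
  wts <- vertex_weights(mesh)
  if (is.null(node)) node <- origin_node(mesh)
  if (is.null(dist)) {
    backend <- if (identical(mesh$domain$type, "plane")) "analytic" else "fmm"
    if (backend == "analytic") {
      ct <- canonical_triangulation(mesh)
      xy <- mesh$vertices[ct$reps, 1:2, drop = FALSE]
      drow <- plane_distance(xy[node, ], xy, mesh$domain$L)
    } else {
      ct <- canonical_triangulation(mesh)
      drow <- surface_distances(mesh, ct$reps[node], backend = "fmm")[ct$reps, 1]
    }
  } else {
    drow <- dist$values[node, ]
  }
  sum(wts * kernel_w(drow, params))
}

# index (in distinct-node numbering) of the node nearest the domain origin:
# (0,0) on the plane, the (theta,phi)=(0,0) image on the torus, else the
# vertex closest to the centroid
origin_node <- function(mesh) {
  ct <- canonical_triangulation(mesh)
  v <- mesh$vertices[ct$reps, , drop = FALSE]
  target <- if (identical(mesh$domain$type, "torus"))
    c(mesh$domain$R + mesh$domain$r, 0, 0) else c(0, 0, 0)
  which.min((v[, 1] - target[1])^2 + (v[, 2] - target[2])^2 +
            (v[, 3] - target[3])^2)
}

#' Field state: initial conditions for u and a
#'
#' Sets the activity u to `u_level` inside one patch and the recovery a to
#' `a_level` inside a second, offset patch (zero outside). The offset between
#' the two patches selects the propagation direction of the emerging bump
#' (it moves away from the recovery patch). Patches are rectangles in domain
#' coordinates: (x, y) on the plane, (theta, phi) on the torus; for general
#' meshes use `node`/`frac` to mark a geodesic neighbourhood covering a given
#' fraction of the nodes.
#'
#' @param mesh an `nf_mesh`.
#' @param u_level,a_level patch values (plane defaults 1 and 1.5; use
#'   `u_level = 2` for the torus initial condition).
#' @param u_centre,a_centre patch centres, length-2 (x, y) or (theta, phi).
#' @param u_size,a_size full widths of the rectangular patches.
#' @param node,frac alternative general-mesh patch: the `frac` fraction of
#'   nodes nearest (by fast-marching distance) to vertex `node` for u, and to
#'   `a_node` for a.
#' @param a_node companion source vertex for the recovery patch.
#' @return an `nf_state` list with `u`, `a` (length = distinct nodes), `t = 0`.
#' @export
initial_state <- function(mesh, u_level = 1, a_level = 1.5,
                          u_centre = c(0, 0), a_centre = NULL,
                          u_size = c(2, 2), a_size = NULL,
                          node = NULL, frac = 0.01, a_node = NULL) {
  ct <- canonical_triangulation(mesh)
  n <- ct$n
  u <- numeric(n); a <- numeric(n)
  if (!is.null(node)) {
    npatch <- max(1L, round(frac * n))
    du <- surface_distances(mesh, node)[ct$reps, 1]
    u[order(du)[seq_len(npatch)]] <- u_level
    if (is.null(a_node)) stop("a_node must be given for general-mesh patches")
    da <- surface_distances(mesh, a_node)[ct$reps, 1]
    a[order(da)[seq_len(npatch)]] <- a_level
  } else if (identical(mesh$domain$type, "plane")) {
    if (is.null(a_centre)) a_centre <- u_centre + c(2, 0)
    if (is.null(a_size)) a_size <- u_size
    xy <- mesh$vertices[ct$reps, 1:2, drop = FALSE]
    L <- mesh$domain$L
    inrect <- function(centre, size)
      abs(wrap_period(xy[, 1] - centre[1], 2 * L)) <= size[1] / 2 &
      abs(wrap_period(xy[, 2] - centre[2], 2 * L)) <= size[2] / 2
    u[inrect(u_centre, u_size)] <- u_level
    a[inrect(a_centre, a_size)] <- a_level
  } else if (identical(mesh$domain$type, "torus")) {
    # default offset mirrors the planar setup in arc length at the outer
    # equator: the recovery patch sits one patch-width ahead in phi
    if (is.null(a_centre)) a_centre <- u_centre + c(0, 0.31)
    if (is.null(a_size)) a_size <- u_size
    ang <- torus_angles(mesh)
    th <- ang$theta[ct$reps]; ph <- ang$phi[ct$reps]
    inrect <- function(centre, size)
      abs(wrap_period(th - centre[1], 2 * pi)) <= size[1] / 2 &
      abs(wrap_period(ph - centre[2], 2 * pi)) <= size[2] / 2
    u[inrect(u_centre, u_size)] <- u_level
    a[inrect(a_centre, a_size)] <- a_level
  } else {
    stop("for meshes without a plane/torus domain give node= and a_node=")
  }
  if (!any(u != 0)) stop("u patch contains no mesh nodes")
  if (!any(a != 0)) stop("a patch contains no mesh nodes")
  structure(list(u = u, a = a, t = 0), class = "nf_state")
}

#' Spatially uniform steady state of the model
#'
#' At a uniform steady state the recovery equation forces a = B u, and u
#' solves \eqn{(1 + B) u = A \bar W S(u - h)} with \eqn{\bar W} the kernel
#' mass. Solved by 1-D root bracketing.
#'
#' @param params an [nf_params()].
#' @param Wbar kernel mass (default: infinite-plane closed form).
#' @param interval search bracket for u.
#' @return list(u, a) of the uniform fixed point.
#' @export
uniform_fixed_point <- function(params = nf_params(),
                                Wbar = kernel_mass(params = params),
                                interval = c(-2, 2)) {
  f <- function(u) (1 + params$B) * u -
    params$A * Wbar * firing_rate(u - params$h, params$beta)
  root <- stats::uniroot(f, interval, tol = 1e-14)
  list(u = root$root, a = params$B * root$root)
}
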