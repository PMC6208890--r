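#' Integrate the collocated neural field ODE system in time
#'
#' Solves, for every distinct node i,
#' \deqn{du_i/dt = -u_i - a_i + A (W S(u - h))_i, \qquad
#'       da_i/dt = (B u_i - a_i)/\tau,}
#' with the adaptive Dormand-Prince Runge-Kutta 4(5) pair (deSolve's
#' `ode45`), absolute and relative tolerances 1e-6 by default, and dense
#' output at a fixed stride.
#'
#' @param op an [nf_operator()] (its W matrix already carries the quadrature
#'   weights; the gain A is applied here).
#' @param state0 an `nf_state` from [initial_state()] (or list with u, a).
#' @param T final time.
#' @param params an [nf_params()]; defaults to the operator's.
#' @param dt_out output sampling stride (default 1).
#' @param atol,rtol integrator tolerances.
#' @return an `nf_sim`: list(times, u, a) with one row per sample.
#' @export
nf_integrate <- function(op, state0, T, params = op$params, dt_out = 1,
                         atol = 1e-6, rtol = 1e-6) {
  n <- nrow(op$W)
  if (length(state0$u) != n || length(state0$a) != n)
    stop("state dimension does not match operator")
  y0 <- c(state0$u, state0$a)
  iu <- seq_len(n); ia <- n + iu
  W <- op$W
  A <- params$A; B <- params$B; h <- params$h
  tau <- params$tau; beta <- params$beta
  rhs <- function(t, y, parms) {
    u <- y[iu]; a <- y[ia]
    s <- firing_rate(u - h, beta)
    du <- -u - a + A * as.vector(W %*% s)
    da <- (B * u - a) / tau
    list(c(du, da))
  }
  times <- seq(0, T, by = dt_out)
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "ode45", atol = atol, rtol = rtol)
  if (attr(sol, "istate")[1] < 0)
    stop("time integration failed; last valid time ", max(sol[, 1]))
  structure(list(times = sol[, 1],
                 u = unname(sol[, 1 + iu, drop = FALSE]),
                 a = unname(sol[, 1 + ia, drop = FALSE]),
                 params = params),
            class = "nf_sim")
}

#' @export
print.nf_sim <- function(x, ...) {
  cat("nf_sim:", length(x$times), "samples x", ncol(x$u), "nodes, t in [",
      min(x$times), ",", max(x$times), "]\n")
  cat("  final max(u) =", max(x$u[nrow(x$u), ]), "\n")
  invisible(x)
}

#' One-call simulation on a mesh
#'
#' Convenience wrapper: computes distances (analytic minimal-image on
#' periodic plane meshes, fast marching otherwise), assembles the collocation
#' operator, builds the default two-patch initial condition for the domain,
#' and integrates.
#'
#' @param mesh an `nf_mesh`.
#' @param T final time.
#' @param params an [nf_params()].
#' @param state0 optional initial `nf_state` (default: domain defaults from
#'   [initial_state()]).
#' @param backend distance backend passed to [all_pairs_distances()];
#'   default analytic for planes, fmm otherwise.
#' @param ... passed on to [nf_integrate()].
#' @return an `nf_sim` with the mesh attached.
#' @export
nf_simulate <- function(mesh, T, params = nf_params(), state0 = NULL,
                        backend = NULL, ...) {
  if (is.null(backend))
    backend <- if (identical(mesh$domain$type, "plane")) "analytic"
      else if (identical(mesh$domain$type, "torus") &&
               !is.null(mesh$domain$n_theta)) "parametric"
      else "fmm"
  dist <- all_pairs_distances(mesh, backend = backend)
  op <- nf_operator(mesh, dist, params)
  if (is.null(state0)) {
    state0 <- if (identical(mesh$domain$type, "torus"))
      initial_state(mesh, u_level = 2, u_size = c(1.0, 0.31))
    else initial_state(mesh)
  }
  sim <- nf_integrate(op, state0, T, params = params, ...)
  sim$mesh <- mesh
  sim
}
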