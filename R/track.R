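#' Track the centroid trajectory of a travelling bump
#'
#' At each output sample the bump support is the set of distinct nodes with
#' u above half the current maximum; the centroid is the vertex-area-weighted
#' mean of their positions with the soft weight \eqn{(u - 0.5 \max u)_+}
#' (continuous in the field, so the centroid does not jump as nodes cross
#' the support threshold), computed with circular means on the periodic
#' plane and reprojected onto the surface for curved domains. Speed is the
#' distance between consecutive centroids divided by the sampling stride;
#' Gaussian curvature along the path uses the analytic torus formula when a
#' torus domain is attached and the vertex angle-defect estimate otherwise.
#' Tracking stops (with `status = "extinct"`) once max(u) falls below the
#' tracking floor.
#'
#' @param sim an `nf_sim` (needs `sim$mesh`, or pass `mesh`).
#' @param mesh the simulation mesh (defaults to `sim$mesh`).
#' @param support_frac support threshold as a fraction of max(u) (default 0.5).
#' @param floor tracking floor on max(u) (default 0.2).
#' @return an `nf_trajectory` data.frame with columns
#'   t, x, y, z, step_length, speed, K and a `status` attribute.
#' @export
track_bump <- function(sim, mesh = sim$mesh, support_frac = 0.5, floor = 0.2) {
  stopifnot(!is.null(mesh))
  ct <- canonical_triangulation(mesh)
  pos <- mesh$vertices[ct$reps, , drop = FALSE]
  wts <- vertex_weights(mesh)
  is_plane <- identical(mesh$domain$type, "plane")
  is_torus <- identical(mesh$domain$type, "torus")
  kappa <- if (!is_plane && !is_torus && isTRUE(mesh$closed))
    gaussian_curvature(mesh)$K else NULL
  nt <- length(sim$times)
  cent <- matrix(NA_real_, nt, 3)
  K <- numeric(nt)
  status <- "ok"
  last <- nt
  for (it in seq_len(nt)) {
    u <- sim$u[it, ]
    if (max(u) < floor) {
      status <- "extinct"
      last <- it - 1L
      break
    }
    sel <- u >= support_frac * max(u)
    w <- wts[sel] * (u[sel] - support_frac * max(u))
    if (is_plane) {
      L <- mesh$domain$L
      cent[it, 1:2] <- vapply(1:2, function(cc) {
        ang <- pi * (pos[sel, cc] + L) / L
        m <- atan2(sum(w * sin(ang)), sum(w * cos(ang))) %% (2 * pi)
        m * L / pi - L
      }, numeric(1))
      cent[it, 3] <- 0
      K[it] <- 0
    } else {
      p <- colSums(w * pos[sel, , drop = FALSE]) / sum(w)
      if (is_torus) {
        R <- mesh$domain$R; r <- mesh$domain$r
        phi <- atan2(p[2], p[1])
        theta <- atan2(p[3], sqrt(p[1]^2 + p[2]^2) - R)
        cent[it, ] <- torus_point(theta, phi, R, r)
        K[it] <- torus_curvature(theta, R, r)
      } else {
        nearest <- which.min(colSums((t(pos) - p)^2))
        cent[it, ] <- pos[nearest, ]
        K[it] <- if (is.null(kappa)) NA_real_ else kappa[nearest]
      }
    }
  }
  keep <- seq_len(last)
  step <- c(NA_real_, vapply(keep[-1], function(it) {
    if (is_plane)
      plane_distance(cent[it - 1, 1:2], cent[it, 1:2], mesh$domain$L)
    else sqrt(sum((cent[it, ] - cent[it - 1, ])^2))
  }, numeric(1)))
  dt <- c(NA_real_, diff(sim$times[keep]))
  out <- data.frame(t = sim$times[keep], x = cent[keep, 1], y = cent[keep, 2],
                    z = cent[keep, 3], step_length = step, speed = step / dt,
                    K = K[keep])
  attr(out, "status") <- status
  class(out) <- c("nf_trajectory", "data.frame")
  out
}

#' Maximum drift of a planar bump from its launch line
#'
#' For a bump launched on the line y = y0 and propagating in x, reports
#' max |y(t) - y0|. On regular meshes the drift stays within one mesh
#' spacing; on irregular meshes it shrinks as the mesh is refined.
#'
#' @param traj an `nf_trajectory` from a planar run.
#' @param y0 launch line (default: the first centroid's y).
#' @return scalar maximum absolute deviation.
#' @export
drift_metric <- function(traj, y0 = traj$y[1]) {
  max(abs(traj$y - y0))
}

#' Relative speed variation along a trajectory
#'
#' Standard deviation over mean of the per-step speed after discarding an
#' initial transient; the operational test of "constant speed" propagation.
#'
#' @param traj an `nf_trajectory`.
#' @param discard fraction of initial samples to drop (default 0.1).
#' @return relative standard deviation of speed.
#' @export
speed_rsd <- function(traj, discard = 0.1) {
  v <- traj$speed[-1]
  v <- v[-seq_len(ceiling(discard * length(v)))]
  stats::sd(v) / mean(v)
}

#' @export
plot.nf_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$t, x$speed, type = "l", xlab = "t", ylab = "speed", ...)
  plot(x$t, x$K, type = "l", xlab = "t", ylab = "Gaussian curvature K", ...)
  invisible(x)
}
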