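#' Affine map from the unit simplex onto a triangle
#'
#' \eqn{T(r,s) = (1-r-s) v_1 + s v_2 + r v_3}: T(0,0) is the first vertex,
#' T(0,1) the second, T(1,0) the third (s multiplies the second vertex, r the
#' third). The Jacobian determinant of T is twice the triangle area, which is
#' where the 2 Area factor of triangle quadrature comes from.
#'
#' @param v1,v2,v3 triangle vertices (length-d vectors).
#' @param r,s simplex coordinates, r, s >= 0, r + s <= 1 (vectorised).
#' @return matrix of mapped points (one row per (r, s) pair).
#' @export
simplex_map <- function(v1, v2, v3, r, s) {
  if (any(r < -1e-14) || any(s < -1e-14) || any(r + s > 1 + 1e-14))
    stop("(r, s) must lie in the unit simplex")
  outer(1 - r - s, v1) + outer(s, v2) + outer(r, v3)
}

#' Quadrature rules on the unit simplex
#'
#' `vertex`: the three-point rule \eqn{\int_\sigma G \approx
#' (G(0,0) + G(0,1) + G(1,0))/6} (exact for polynomials of total degree 1;
#' the rule behind vertex-based collocation). `midpoint`: edge-midpoint rule,
#' exact to degree 2, provided as the experimental higher-order option
#' (kernel values at non-vertex points are obtained by barycentric
#' interpolation of vertex distances).
#'
#' @param rule "vertex" or "midpoint".
#' @return list with matrix `nodes` (columns r, s) and vector `weights`
#'   (summing to 1/2, the simplex area).
#' @export
simplex_rule <- function(rule = c("vertex", "midpoint")) {
  rule <- match.arg(rule)
  switch(rule,
    vertex = list(nodes = rbind(c(0, 0), c(0, 1), c(1, 0)),
                  weights = rep(1 / 6, 3)),
    midpoint = list(nodes = rbind(c(0.5, 0), c(0, 0.5), c(0.5, 0.5)),
                    weights = rep(1 / 6, 3)))
}

#' Integrate a function over the unit simplex with a quadrature rule
#' @param G function of (r, s), vectorised or not.
#' @param rule a rule from [simplex_rule()].
#' @return the weighted sum.
#' @export
integrate_on_simplex <- function(G, rule = simplex_rule("vertex")) {
  vals <- mapply(G, rule$nodes[, 1], rule$nodes[, 2])
  sum(rule$weights * vals)
}
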