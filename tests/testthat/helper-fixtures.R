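# shared small fixtures, built in code; expensive ones are cached per session
.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

octahedron_mesh <- function() {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
             c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  tri <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
               c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  nf_mesh(v, tri)
}

small_torus <- function() fixture("small_torus", function() torus_mesh(4.5, 2, 9, 18))

plane33 <- function() fixture("plane33", function() plane_mesh(7.5, 33))

distinct_xy <- function(mesh) {
  ct <- neurofield:::canonical_triangulation(mesh)
  mesh$vertices[ct$reps, 1:2, drop = FALSE]
}
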