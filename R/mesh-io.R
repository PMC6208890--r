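#' Read a triangle mesh from an OFF or PLY file
#'
#' ASCII OFF and PLY are supported. The reader validates face arity (triangles
#' only), checks index ranges, and flags non-manifold or boundary edges: a
#' mesh with boundary edges gets `closed = FALSE`, and edges shared by more
#' than two faces raise a warning recorded in `mesh$nonmanifold`.
#'
#' @param path file path; format chosen by extension (`.off`, `.ply`) unless
#'   `format` is given.
#' @param format "off" or "ply" to override extension detection.
#' @return an `nf_mesh`.
#' @export
read_mesh <- function(path, format = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
         off = read_off(path),
         ply = read_ply(path),
         stop("unsupported mesh format: ", format))
}

#' Write a triangle mesh to an OFF or PLY file
#' @param mesh an `nf_mesh`.
#' @param path output path; extension picks the format unless `format` given.
#' @param format "off" or "ply".
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
         off = write_off(mesh, path),
         ply = write_ply(mesh, path),
         stop("unsupported mesh format: ", format))
  invisible(path)
}

strip_comments <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

finish_loaded_mesh <- function(vertices, triangles, path) {
  m <- nf_mesh(vertices, triangles)
  et <- mesh_edge_table(m)
  if (any(et$count > 2L)) {
    warning("non-manifold edges in ", path)
    m$nonmanifold <- TRUE
  } else {
    m$nonmanifold <- FALSE
  }
  m
}

read_off <- function(path) {
  raw <- readLines(path, warn = FALSE)
  lines <- strip_comments(raw)
  if (length(lines) < 2L || toupper(lines[1]) != "OFF")
    stop("not an OFF file (missing OFF header): ", path)
  counts <- suppressWarnings(as.numeric(strsplit(lines[2], "\\s+")[[1]]))
  if (length(counts) < 2L || any(is.na(counts[1:2])))
    stop("malformed OFF count line: '", lines[2], "'")
  nv <- counts[1]; nf <- counts[2]
  vtxt <- lines[seq.int(3L, 2L + nv)]
  verts <- matrix(suppressWarnings(
    as.numeric(unlist(strsplit(vtxt, "\\s+")))), ncol = 3, byrow = TRUE)
  if (any(is.na(verts))) stop("malformed OFF vertex line in ", path)
  ftxt <- lines[seq.int(3L + nv, 2L + nv + nf)]
  tris <- matrix(0L, nrow = nf, ncol = 3)
  for (k in seq_len(nf)) {
    f <- suppressWarnings(as.integer(strsplit(ftxt[k], "\\s+")[[1]]))
    if (length(f) < 1L || is.na(f[1]) || f[1] != 3L || length(f) < 4L)
      stop("OFF face line ", k, " is not a triangle: '", ftxt[k], "'")
    tris[k, ] <- f[2:4] + 1L
  }
  finish_loaded_mesh(verts, tris, path)
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  writeLines(apply(mesh$vertices, 1, function(v)
    sprintf("%.17g %.17g %.17g", v[1], v[2], v[3])), con)
  writeLines(apply(mesh$triangles, 1, function(t)
    sprintf("3 %d %d %d", t[1] - 1L, t[2] - 1L, t[3] - 1L)), con)
  invisible(path)
}

read_ply <- function(path) {
  raw <- readLines(path, warn = FALSE)
  if (length(raw) < 3L || trimws(raw[1]) != "ply")
    stop("not a PLY file: ", path)
  hdr_end <- which(trimws(raw) == "end_header")[1]
  if (is.na(hdr_end)) stop("PLY header not terminated in ", path)
  hdr <- trimws(raw[seq_len(hdr_end)])
  if (!any(grepl("^format\\s+ascii", hdr)))
    stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("^element\\s+vertex\\s+", "",
                       grep("^element\\s+vertex\\s", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element\\s+face\\s+", "",
                       grep("^element\\s+face\\s", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("PLY missing vertex/face elements: ", path)
  body <- trimws(raw[-seq_len(hdr_end)])
  body <- body[nzchar(body)]
  vtxt <- body[seq_len(nv)]
  vv <- strsplit(vtxt, "\\s+")
  verts <- t(vapply(vv, function(x) as.numeric(x[1:3]), numeric(3)))
  if (any(is.na(verts))) stop("malformed PLY vertex line in ", path)
  ftxt <- body[seq.int(nv + 1L, nv + nf)]
  tris <- matrix(0L, nrow = nf, ncol = 3)
  for (k in seq_len(nf)) {
    f <- suppressWarnings(as.integer(strsplit(ftxt[k], "\\s+")[[1]]))
    if (is.na(f[1]) || f[1] != 3L || length(f) < 4L)
      stop("PLY face line ", k, " is not a triangle: '", ftxt[k], "'")
    tris[k, ] <- f[2:4] + 1L
  }
  finish_loaded_mesh(verts, tris, path)
}

write_ply <- function(mesh, path, scalars = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices)
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nv),
               "property double x", "property double y", "property double z"),
             con)
  if (!is.null(scalars))
    writeLines("property double quality", con)
  writeLines(c(sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  if (is.null(scalars)) {
    writeLines(apply(mesh$vertices, 1, function(v)
      sprintf("%.17g %.17g %.17g", v[1], v[2], v[3])), con)
  } else {
    stopifnot(length(scalars) == nv)
    writeLines(sprintf("%.17g %.17g %.17g %.17g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3], scalars), con)
  }
  writeLines(apply(mesh$triangles, 1, function(t)
    sprintf("3 %d %d %d", t[1] - 1L, t[2] - 1L, t[3] - 1L)), con)
  invisible(path)
}
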