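#' Validate a run configuration
#'
#' A run configuration is a nested list (usually read from a YAML file) with
#' blocks `domain`, `mesh`, `model` (with optional `model$kernel`), `init`,
#' `integration`, `distances`, and an optional top-level `seed`. Unknown keys
#' anywhere are rejected, and invariants (tau > 0, beta > 0, positive radii,
#' T > 0) are checked before any computation starts.
#'
#' @param config list or path to a YAML file.
#' @return the validated config (class `nf_config`).
#' @export
nf_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  allowed <- list(
    domain = c("type", "L", "R", "r"),
    mesh = c("kind", "points_per_side", "n_theta", "n_phi", "refine",
             "target_nodes", "path"),
    model = c("A", "B", "h", "tau", "beta", "kernel"),
    init = c("u_level", "a_level", "u_centre", "a_centre", "u_size",
             "a_size", "node", "a_node", "frac"),
    integration = c("T", "atol", "rtol", "dt_out"),
    distances = c("backend"))
  bad <- setdiff(names(config), c(names(allowed), "seed"))
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  for (blk in names(allowed)) {
    extra <- setdiff(names(config[[blk]]), allowed[[blk]])
    if (length(extra))
      stop("unknown key(s) in ", blk, ": ", paste(extra, collapse = ", "))
  }
  if (!is.null(config$model$kernel)) {
    extra <- setdiff(names(config$model$kernel), c("c2", "gamma"))
    if (length(extra))
      stop("unknown key(s) in model$kernel: ", paste(extra, collapse = ", "))
  }
  dom <- config$domain
  if (is.null(dom$type) || !dom$type %in% c("plane", "torus", "surface"))
    stop("domain$type must be plane, torus, or surface")
  mk <- config$model$kernel
  params <- do.call(nf_params, c(
    config$model[intersect(names(config$model), c("A", "B", "h", "tau", "beta"))],
    mk[intersect(names(mk), c("c2", "gamma"))]))
  Tfinal <- config$integration$T
  if (is.null(Tfinal) || Tfinal <= 0) stop("integration$T must be positive")
  config$.params <- params
  class(config) <- c("nf_config", "list")
  config
}

config_mesh <- function(config) {
  dom <- config$domain
  mesh <- config$mesh
  kind <- if (is.null(mesh$kind)) "regular" else mesh$kind
  m <- if (identical(kind, "file")) {
    read_mesh(mesh$path)
  } else if (identical(dom$type, "plane")) {
    L <- if (is.null(dom$L)) 7.5 else dom$L
    if (identical(kind, "irregular"))
      irregular_plane_mesh(L, mesh$target_nodes,
                           seed = if (is.null(config$seed)) 1L else config$seed)
    else plane_mesh(L, if (is.null(mesh$points_per_side)) 33L else mesh$points_per_side)
  } else if (identical(dom$type, "torus")) {
    torus_mesh(if (is.null(dom$R)) 4.5 else dom$R,
               if (is.null(dom$r)) 2 else dom$r,
               if (is.null(mesh$n_theta)) 18L else mesh$n_theta,
               if (is.null(mesh$n_phi)) 36L else mesh$n_phi)
  } else stop("surface domains need mesh$kind = 'file'")
  nref <- if (is.null(mesh$refine)) 0L else mesh$refine
  for (i in seq_len(nref)) m <- refine_mesh(m)
  m
}

#' Execute a full configured run: mesh, distances, simulation, tracking
#'
#' Runs the pipeline mesh -> distances -> operator -> time integration ->
#' bump tracking, and writes every artefact into a fresh run directory:
#' `config.yaml` (the validated configuration), `log.txt` (package version,
#' seed, config hash, stage timings), `mesh.off`, a distance cache,
#' `snapshots.csv` (u at every output sample), and `traj.csv` (t, x, y, z,
#' step_length, speed, K). Identical config and seed reproduce identical CSV
#' output. The directory must not already exist — runs are never overwritten.
#'
#' @param config list, `nf_config`, or YAML path.
#' @param out_dir run directory to create.
#' @return the trajectory data.frame, invisibly; artefacts on disk.
#' @export
nf_run <- function(config, out_dir) {
  config <- nf_config(config)
  if (dir.exists(out_dir)) stop("run directory already exists: ", out_dir)
  dir.create(out_dir, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  logline <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  cfg_clean <- unclass(config); cfg_clean$.params <- NULL
  yaml::write_yaml(cfg_clean, file.path(out_dir, "config.yaml"))
  cfg_hash <- unname(tools::md5sum(file.path(out_dir, "config.yaml")))
  logline("neurofield ", as.character(utils::packageVersion("neurofield")))
  logline("seed ", if (is.null(config$seed)) "none" else config$seed)
  logline("config hash ", cfg_hash)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      logline("stage ", name, " FAILED: ", conditionMessage(e))
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
    logline("stage ", name, " ok (",
            sprintf("%.2fs", as.numeric(Sys.time() - t0, units = "secs")), ")")
    res
  }
  mesh <- stage("mesh", config_mesh(config))
  write_mesh(mesh, file.path(out_dir, "mesh.off"))
  backend <- config$distances$backend
  if (is.null(backend))
    backend <- if (identical(mesh$domain$type, "plane")) "analytic" else "fmm"
  dist <- stage("distances",
                all_pairs_distances(mesh, backend = backend,
                                    cache_path = file.path(out_dir, "distances.bin")))
  params <- config$.params
  op <- stage("operator", nf_operator(mesh, dist, params))
  init_args <- config$init
  state0 <- stage("init", do.call(initial_state, c(list(mesh = mesh), init_args)))
  intg <- config$integration
  sim <- stage("integrate",
               nf_integrate(op, state0, T = intg$T,
                            params = params,
                            dt_out = if (is.null(intg$dt_out)) 1 else intg$dt_out,
                            atol = if (is.null(intg$atol)) 1e-6 else intg$atol,
                            rtol = if (is.null(intg$rtol)) 1e-6 else intg$rtol))
  sim$mesh <- mesh
  snap <- data.frame(t = sim$times, sim$u, check.names = FALSE)
  names(snap) <- c("t", paste0("u", seq_len(ncol(sim$u))))
  utils::write.csv(snap, file.path(out_dir, "snapshots.csv"), row.names = FALSE)
  traj <- stage("track", track_bump(sim))
  utils::write.csv(traj, file.path(out_dir, "traj.csv"), row.names = FALSE)
  logline("done")
  invisible(traj)
}
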