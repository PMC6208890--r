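base_config <- function(...) {
  utils::modifyList(list(
    domain = list(type = "plane", L = 7.5),
    mesh = list(kind = "regular", points_per_side = 17L),
    model = list(A = 2, B = 0.4, h = 0.8, tau = 3, beta = 5),
    integration = list(T = 10, dt_out = 1),
    seed = 1L), list(...))
}

test_that("configs are validated before any computation", {
  expect_s3_class(nf_config(base_config()), "nf_config")
  bad <- base_config(); bad$model$tau <- 0
  expect_error(nf_config(bad), "tau")
  bad2 <- base_config(); bad2$mesh$frobnicate <- 1
  expect_error(nf_config(bad2), "unknown key")
  bad3 <- base_config(); bad3$extra_block <- list()
  expect_error(nf_config(bad3), "unknown config block")
  bad4 <- base_config(); bad4$integration$T <- -5
  expect_error(nf_config(bad4), "positive")
  bad5 <- base_config(); bad5$domain$type <- "sphere"
  expect_error(nf_config(bad5), "domain")
})

test_that("nf_run produces a complete, reproducible run directory", {
  dir1 <- file.path(withr::local_tempdir(), "run1")
  traj <- nf_run(base_config(), dir1)
  expect_true(all(file.exists(file.path(
    dir1, c("config.yaml", "log.txt", "mesh.off", "distances.bin",
            "snapshots.csv", "traj.csv")))))
  expect_true(all(diff(traj$t) > 0))
  # never overwrite an existing run
  expect_error(nf_run(base_config(), dir1), "exists")
  # identical config + seed => byte-identical trajectory output
  dir2 <- file.path(withr::local_tempdir(), "run2")
  nf_run(base_config(), dir2)
  expect_identical(readBin(file.path(dir1, "traj.csv"), "raw", 1e6),
                   readBin(file.path(dir2, "traj.csv"), "raw", 1e6))
  log <- readLines(file.path(dir1, "log.txt"))
  expect_true(any(grepl("config hash", log)))
  expect_true(any(grepl("stage integrate ok", log)))
})

test_that("a failing stage names itself and leaves partial outputs", {
  cfg <- base_config()
  cfg$init <- list(u_size = c(1e-9, 1e-9))   # empty patch -> init stage fails
  dir3 <- file.path(withr::local_tempdir(), "run3")
  expect_error(nf_run(cfg, dir3), "stage init")
  expect_true(file.exists(file.path(dir3, "mesh.off")))
  expect_true(any(grepl("FAILED", readLines(file.path(dir3, "log.txt")))))
})

test_that("YAML configs round-trip through nf_run", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(base_config(), f)
  dir4 <- file.path(withr::local_tempdir(), "run4")
  traj <- nf_run(f, dir4)
  expect_gt(nrow(traj), 5)
})
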