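small_panel <- function(out_dir, seed = 1L) {
  run_simulate(
    conditions = list(
      low = list(image_size_px = c(256, 320), n_viable = 4, n_netosing = 0,
                 n_necrotic = 0, n_net_strands = 0),
      high = list(image_size_px = c(256, 320), n_viable = 1, n_netosing = 2,
                  n_necrotic = 1, n_net_strands = 2)),
    n_images = 2L, n_replicates = 2L, out_dir = out_dir, seed = seed)
}

test_that("simulate -> quantify bookkeeping: rows per image and condition", {
  td <- withr::local_tempdir()
  sim <- small_panel(td)
  expect_identical(nrow(sim$manifest), 4L)
  expect_true(file.exists(sim$manifest_path))

  cfg <- read_run_config(list(output_dir = file.path(td, "out")))
  res <- suppressWarnings(run_quantify(sim$manifest_path, cfg))
  expect_identical(nrow(res$fields), 4L)
  expect_identical(nrow(res$conditions), 2L)
  expect_true(all(c("field_summary.csv", "condition_summary.csv",
                    "replicate_mean_summary.csv", "run_log.json") %in%
                  list.files(file.path(td, "out"))))
  # higher true NET burden shows up as higher mean percent area NETs
  m <- res$conditions
  expect_gt(m$mean_percent_area_nets[m$condition == "high"],
            m$mean_percent_area_nets[m$condition == "low"])
  # the run log echoes the resolved configuration
  log <- jsonlite::read_json(file.path(td, "out", "run_log.json"))
  expect_identical(log$package, "netquant")
  expect_equal(log$config$detection$ratio_cutoff, 1 / 3, tolerance = 1e-9)
})

test_that("unreadable images are skipped; empty conditions are fatal", {
  td <- withr::local_tempdir()
  sim <- small_panel(td)
  man <- sim$manifest
  man$image <- file.path(td, man$image)        # data-frame manifests need
  man$image[1] <- file.path(td, "missing.tif") # resolvable paths
  w <- capture_warnings(res <- run_quantify(man, list()))
  expect_true(any(grepl("skipping", w)))
  expect_identical(nrow(res$fields), 3L)
  man2 <- man[1:2, ]
  man2$image <- file.path(td, "missing.tif")
  man2$condition <- "ghost"
  expect_error(suppressWarnings(run_quantify(man2, list())),
               "no readable image")
})

test_that("run configs validate keys and resolve defaults", {
  cfg <- read_run_config(list())
  expect_equal(cfg$pixel_size_um, 0.5)
  expect_identical(cfg$detection$tie_rule, "viable")
  expect_identical(cfg$roi, "auto")
  expect_error(read_run_config(list(pixell = 1)), "unknown config key")
  td <- withr::local_tempdir()
  yml <- file.path(td, "cfg.yaml")
  writeLines(c("pixel_size_um: 0.25",
               "roi: {x0: 0, y0: 0, width: 16, height: 16}",
               "binarization:",
               "  red: {method: fixed, fixed_threshold: 40}",
               "detection: {min_circularity: 0.4}",
               "alpha: 0.01"), yml)
  cfg2 <- read_run_config(yml)
  expect_equal(cfg2$pixel_size_um, 0.25)
  expect_s3_class(cfg2$roi, "region_of_interest")
  expect_identical(cfg2$binarization$red$method, "fixed")
  expect_identical(cfg2$binarization$blue$method, "automatic")
  expect_equal(cfg2$detection$min_circularity, 0.4)
  expect_equal(cfg2$alpha, 0.01)
})

test_that("release and mpo front ends run from csv inputs", {
  td <- withr::local_tempdir()
  sim <- generate_release_data(list(slope = 0.06, intercept = 0.02),
                               list(LD1 = c(2, 1, rep(0.2, 12))),
                               noise_sigma = 0.002, n_replicates = 3,
                               seed = 11)
  cal_csv <- file.path(td, "cal.csv"); rel_csv <- file.path(td, "rel.csv")
  write.csv(sim$calibration, cal_csv, row.names = FALSE)
  write.csv(sim$releasate, rel_csv, row.names = FALSE)
  res <- suppressWarnings(run_release(cal_csv, rel_csv, out_dir = td))
  expect_true(file.exists(file.path(td, "release_report.csv")))
  expect_true(all(diff(res$profile$cumulative_pct[
    order(res$profile$timepoint_h)]) >= 0))
  expect_error(run_release(file.path(td, "nope.csv"), rel_csv),
               "calibration file not found")

  pan <- generate_mpo_panel(c(blank = 20, honey10 = 120),
                            net_bound_fraction = 0.95, noise_cv = 0.05,
                            n_replicates = 3, seed = 12)
  mpo_csv <- file.path(td, "mpo.csv")
  write.csv(pan, mpo_csv, row.names = FALSE)
  out <- run_mpo(mpo_csv, out_dir = td)
  expect_true(file.exists(file.path(td, "mpo_report.csv")))
  expect_true(all(out$heparin_check$ratio < 0.2))
})

test_that("comparison front end applies the gate and writes reports", {
  td <- withr::local_tempdir()
  g <- data.frame(group = rep(c("a", "b"), each = 4), value = rep(1:4, 2))
  csv <- file.path(td, "groups.csv")
  write.csv(g, csv, row.names = FALSE)
  cmp <- run_compare(csv, list(), out_dir = td)
  expect_identical(cmp$branch, "rank")            # n = 4 < 6 replicates
  expect_false(any(cmp$pairwise$significant))
  expect_true(file.exists(file.path(td, "comparison_pairwise.csv")))
  expect_true(file.exists(file.path(td, "comparison_log.txt")))
})

test_that("the command-line wrapper is shipped and runnable", {
  cli <- system.file("cli", "netquant.R", package = "netquant")
  expect_true(nzchar(cli))
  td <- withr::local_tempdir()
  g <- data.frame(group = rep(c("a", "b"), each = 6),
                  value = c(rnorm(6), rnorm(6, 10)))
  csv <- file.path(td, "groups.csv")
  write.csv(g, csv, row.names = FALSE)
  rscript <- file.path(R.home("bin"), "Rscript")
  status <- system2(rscript, c(cli, "compare", "--groups", shQuote(csv),
                               "--out", shQuote(td), "--quiet"),
                    stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(td, "comparison_pairwise.csv")))
})
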