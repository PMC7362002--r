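test_that("field generation is a pure function of spec and seed", {
  spec <- field_spec(image_size_px = c(256, 320), n_viable = 2,
                     n_netosing = 1, n_necrotic = 1, n_net_strands = 1,
                     seed = 17)
  a <- generate_field(spec)
  b <- generate_field(spec)
  expect_identical(a$field$blue, b$field$blue)
  expect_identical(a$field$red, b$field$red)
  expect_identical(a$field$green, b$field$green)
  expect_identical(a$truth$objects, b$truth$objects)
  expect_identical(a$truth$net_pixel_mask, b$truth$net_pixel_mask)
  # a different seed changes the scene
  c <- generate_field(field_spec(image_size_px = c(256, 320), n_viable = 2,
                                 n_netosing = 1, n_necrotic = 1,
                                 n_net_strands = 1, seed = 18))
  expect_false(identical(a$field$red, c$field$red))
  # the generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_field(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("object list and ground truth are structurally consistent", {
  spec <- field_spec(image_size_px = c(384, 384), n_viable = 3,
                     n_netosing = 2, n_necrotic = 2, n_net_strands = 1,
                     noise_sigma = 0, background_level = 50, contrast = 40,
                     seed = 23)
  sim <- generate_field(spec)
  obj <- sim$truth$objects
  expect_identical(nrow(obj), 7L)
  expect_identical(sum(obj$class == "viable"), 3L)
  expect_identical(sum(obj$class == "netosing"), 2L)
  expect_identical(sum(obj$class == "necrotic"), 2L)
  # noiseless render: every true NET pixel carries elevated red and only
  # background blue (the corona and strands are the DAPI-negative spill)
  net <- sim$truth$net_pixel_mask
  expect_gt(sum(net), 0)
  expect_true(all(sim$field$red[net] > spec$background_level))
  expect_true(all(sim$field$blue[net] == spec$background_level))
  # all-zero spec renders pure background
  empty <- generate_field(field_spec(image_size_px = c(128, 128),
                                     n_viable = 0, n_netosing = 0,
                                     n_necrotic = 0, n_net_strands = 0,
                                     noise_sigma = 0, seed = 1))
  expect_true(all(empty$field$red == empty$truth$spec$background_level))
  expect_identical(nrow(empty$truth$objects), 0L)
})

test_that("infeasible placement density fails loudly", {
  expect_error(
    generate_field(field_spec(image_size_px = c(96, 96), n_viable = 60,
                              seed = 2)),
    "placement")
})

test_that("classification accuracy degrades as contrast falls", {
  acc_at <- function(contrast) {
    hits <- 0L; tot <- 0L
    for (s in 1:3) {
      sim <- generate_field(field_spec(image_size_px = c(512, 512),
                                       n_viable = 3, n_netosing = 2,
                                       n_necrotic = 1, n_net_strands = 1,
                                       contrast = contrast, seed = 300 + s))
      q <- suppressWarnings(quantify_field(sim$field))
      m <- match_cells_to_truth(q$cells, sim$truth)
      hits <- hits + sum(m$matched & m$detected_class == m$true_class)
      tot <- tot + nrow(m)
    }
    hits / tot
  }
  accs <- vapply(c(10, 4, 1.5), acc_at, numeric(1))
  expect_true(all(diff(accs) <= 0))
  expect_equal(accs[1], 1)
})

test_that("release data generation round-trips through the assay analysis", {
  truth <- list(slope = 0.05, intercept = 0.04)
  conc <- list(SD10 = c(5, 3, 2, rep(0.5, 11)))
  noiseless <- generate_release_data(truth, conc, noise_sigma = 0,
                                     n_replicates = 2, seed = 3)
  res <- run_release(noiseless$calibration, noiseless$releasate)
  expect_equal(res$curve$slope, truth$slope, tolerance = 1e-10)
  prof <- res$profile[order(res$profile$timepoint_h), ]
  expect_equal(prof$interval_conc_pct, conc$SD10, tolerance = 1e-9)
  expect_equal(prof$cumulative_pct, cumsum(conc$SD10), tolerance = 1e-9)
  # determinism
  again <- generate_release_data(truth, conc, noise_sigma = 0,
                                 n_replicates = 2, seed = 3)
  expect_identical(noiseless, again)
})

test_that("noisy release recovery stays within propagated error bounds", {
  truth <- list(slope = 0.05, intercept = 0.04)
  conc <- list(A = c(4, 2, 1, rep(0.25, 11)))
  sigma <- 0.005; nrep <- 4L
  sim <- generate_release_data(truth, conc, noise_sigma = sigma,
                               n_replicates = nrep, seed = 7)
  res <- suppressWarnings(run_release(sim$calibration, sim$releasate))
  prof <- res$profile[order(res$profile$timepoint_h), ]
  # absorbance noise propagates to ~sigma/(slope*sqrt(nrep)) per mean,
  # plus calibration uncertainty; 3x the direct term with a calibration
  # allowance bounds every timepoint
  bound <- 3 * sigma / (truth$slope * sqrt(nrep)) + 0.05
  expect_true(all(abs(prof$interval_conc_pct - conc$A) <= bound))
})

test_that("mpo panel generation matches its stated measurement model", {
  exact <- generate_mpo_panel(c(a = 50, b = 100), control_conc = 120,
                              noise_cv = 0, n_replicates = 2, seed = 5)
  out <- netosis_response_panel(exact)
  expect_equal(sort(unique(round(out$pct_netosis, 10))), c(50, 100))
  # fully NET-bound MPO: the no-heparin arm is identically zero
  bound <- generate_mpo_panel(c(a = 80), net_bound_fraction = 1,
                              noise_cv = 0.2, n_replicates = 3, seed = 6)
  expect_true(all(bound$mpo_conc[!bound$heparin_flag] == 0))
  # determinism
  expect_identical(generate_mpo_panel(c(a = 80), seed = 9),
                   generate_mpo_panel(c(a = 80), seed = 9))
})
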