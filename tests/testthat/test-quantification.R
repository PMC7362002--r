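test_that("percent_area_nets counts red-not-blue pixels over the image", {
  r <- matrix(FALSE, 10, 10); r[1:3, ] <- TRUE          # 30 red
  b <- matrix(FALSE, 10, 10); b[1, ] <- TRUE            # 10 of them blue
  expect_equal(percent_area_nets(r, b), 20)
  expect_equal(percent_area_nets(matrix(FALSE, 5, 5), b[1:5, 1:5]), 0)
  full <- matrix(TRUE, 6, 6)
  expect_equal(percent_area_nets(full, full), 0)
  expect_error(percent_area_nets(r, matrix(FALSE, 9, 10)), "shape")
})

test_that("percent_area_nets agrees with the per-pixel loop on random masks", {
  set.seed(21)
  for (i in 1:5) {
    r <- matrix(runif(32 * 32) < 0.3, 32, 32)
    b <- matrix(runif(32 * 32) < 0.3, 32, 32)
    expect_identical(percent_area_nets(r, b), pan_bruteforce(r, b))
  }
})

test_that("percent_area_nets is monotone in both mask arguments", {
  set.seed(22)
  r <- matrix(runif(64 * 64) < 0.2, 64, 64)
  b <- matrix(runif(64 * 64) < 0.2, 64, 64)
  base <- percent_area_nets(r, b)
  for (i in 1:20) {
    r2 <- r; b2 <- b
    px <- sample(length(r), 25)
    r2[px] <- TRUE                                       # add red-only
    expect_gte(percent_area_nets(r2, b), base)
    b2[sample(length(b), 25)] <- TRUE                    # add blue
    expect_lte(percent_area_nets(r, b2), base)
  }
})

test_that("circularity matches closed-form perimeters for canonical shapes", {
  nr <- 60
  # 1 x 50 line: boundary walk is out-and-back, P = 2 * 49 = 98
  line <- matrix(FALSE, nr, nr); line[5, 1:50] <- TRUE
  cl <- circularity(which(line), nr)
  expect_equal(cl, 4 * pi * 50 / 98^2)
  expect_lt(cl, 0.3)
  # 2 x 40 ribbon: rectangle walk P = 2 * 39 + 2 * 1 = 80
  rib <- matrix(FALSE, nr, nr); rib[10:11, 5:44] <- TRUE
  expect_equal(circularity(which(rib), nr), 4 * pi * 80 / 80^2)
  expect_lt(circularity(which(rib), nr), 0.5)
  # digital disk, radius 20 px: near-unity, unclamped band
  d <- which(disk_mask(nr, nr, 30, 30, 20))
  expect_gt(circularity(d, nr), 0.85)
  expect_lt(circularity(d, nr), 1.1)
  # conventions and contracts
  single <- matrix(FALSE, 8, 8); single[3, 3] <- TRUE
  expect_equal(circularity(which(single), 8), 1)
  expect_error(circularity(integer(), 8), "empty")
})

test_that("discrete-cell identification filters by size and circularity", {
  nr <- 200; nc <- 200
  mk_masks <- function(blue) {
    binary_mask_set(blue, matrix(FALSE, nr, nc), matrix(FALSE, nr, nc),
                    thresholds_used = c(blue = 1, red = 1, green = 1))
  }
  # two disjoint 10 um disks (radius 10 px at 0.5 um/px)
  two <- disk_mask(nr, nc, 50, 50, 10) | disk_mask(nr, nc, 140, 140, 10)
  cells <- find_discrete_cells(mk_masks(two), pixel_size_um = 0.5)
  expect_length(cells, 2L)
  # deterministic order: top-most first
  expect_lt(cells[[1]]$centroid_xy["y"], cells[[2]]$centroid_xy["y"])

  # a 1 um speck falls below the diameter window
  speck <- two | disk_mask(nr, nc, 100, 30, 1)
  expect_length(find_discrete_cells(mk_masks(speck), pixel_size_um = 0.5),
                2L)
  # a 2 x 40 px ribbon fails the circularity filter
  ribbon <- two
  ribbon[180:181, 30:69] <- TRUE
  expect_length(find_discrete_cells(mk_masks(ribbon), pixel_size_um = 0.5),
                2L)
})

test_that("cell measurement reports footprint means, ratio and sentinel", {
  u <- uniform_disk_field(30, 30)
  masks <- binary_mask_set(u$mask, u$mask, matrix(FALSE, 64, 64),
                           thresholds_used = c(blue = 1, red = 1, green = 1))
  reg <- find_discrete_cells(masks, pixel_size_um = 0.5)[[1]]
  rec <- measure_cell(reg, u$field, masks$green_mask)
  expect_equal(rec$blue_red_ratio, 1)
  expect_false(rec$green_positive)

  u2 <- uniform_disk_field(10, 60)
  rec2 <- measure_cell(reg, u2$field, masks$green_mask)
  expect_equal(rec2$blue_red_ratio, 1 / 6, tolerance = 1e-12)

  u3 <- uniform_disk_field(10, 0)
  rec3 <- measure_cell(reg, u3$field, masks$green_mask)
  expect_identical(rec3$blue_red_ratio, Inf)
  expect_identical(classify_cell(rec3), "viable")
})

test_that("classification applies colocalization precedence and tie rule", {
  rec <- function(gp, ratio, blue = ratio * 30, red = 30) {
    list(green_positive = gp, mean_blue = blue, mean_red = red,
         blue_red_ratio = ratio)
  }
  expect_identical(classify_cell(rec(TRUE, 0.5, blue = 20, red = 40)),
                   "netosing")
  expect_identical(classify_cell(rec(FALSE, 1)), "viable")
  expect_identical(classify_cell(rec(FALSE, 0.2)), "necrotic")
  expect_identical(classify_cell(rec(FALSE, 1 / 3)), "viable")
  expect_identical(
    classify_cell(rec(FALSE, 1 / 3),
                  detection_params(tie_rule = "necrotic")), "necrotic")
  # colocalization without dna signal in both channels is not netosis
  expect_identical(classify_cell(rec(TRUE, Inf, blue = 30, red = 0)),
                   "viable")
})

test_that("quantify_field conserves counts and handles blank fields", {
  sim <- generate_field(field_spec(image_size_px = c(512, 512),
                                   n_viable = 3, n_netosing = 2,
                                   n_necrotic = 1, n_net_strands = 1,
                                   seed = 5))
  q <- quantify_field(sim$field)
  s <- q$summary
  expect_identical(s$n_total, s$n_viable + s$n_netosing + s$n_necrotic)
  expect_equal(s$pct_viable + s$pct_netosing + s$pct_necrotic, 100,
               tolerance = 1e-9)
  expect_true(all(q$cells$cell_class %in% c("viable", "netosing",
                                            "necrotic")))
  expect_true(all(is.finite(q$masks$thresholds_used)))

  blank <- generate_field(field_spec(image_size_px = c(512, 512),
                                     n_viable = 0, n_netosing = 0,
                                     n_necrotic = 0, n_net_strands = 0,
                                     seed = 6))
  qb <- suppressWarnings(quantify_field(blank$field))
  expect_identical(qb$summary$n_total, 0L)
  expect_lt(qb$summary$percent_area_nets, 1)
  expect_equal(qb$summary$pct_viable, 0)
})

test_that("quantification is invariant under field translation", {
  sim <- generate_field(field_spec(image_size_px = c(384, 384),
                                   n_viable = 2, n_netosing = 1,
                                   n_necrotic = 1, n_net_strands = 0,
                                   seed = 9))
  roll <- function(m, dy, dx) {
    nr <- nrow(m); nc <- ncol(m)
    m[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
  }
  shifted <- multichannel_field(roll(sim$field$blue, 40, 25),
                                roll(sim$field$red, 40, 25),
                                roll(sim$field$green, 40, 25),
                                pixel_size_um = sim$field$pixel_size_um)
  # automatic thresholds are selected on the raw plane, whose histogram is
  # invariant under a circular shift, so the masks roll exactly
  q1 <- quantify_field(sim$field)
  q2 <- quantify_field(shifted)
  expect_equal(q1$summary$percent_area_nets, q2$summary$percent_area_nets)
  expect_identical(sort(q1$cells$cell_class), sort(q2$cells$cell_class))
})
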