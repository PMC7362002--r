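#' Specification of a synthetic micrograph
#'
#' Parameters of the seeded field generator. The rendered scene mirrors the
#' stain semantics of the assay: viable cells are DAPI-bright disks with a
#' true blue/red intensity ratio of `viable_ratio`; necrotic cells are
#' sytox-bright disks at ratio `necrotic_ratio`; NETosing cells are enlarged
#' boundary-perturbed blobs with blue, red and green all elevated and a
#' red+green decondensation corona spilling beyond the blue core; NET
#' strands are random-walk ribbons elevated in red and green only. Channels
#' are summed with a flat background and additive Gaussian noise clipped at
#' zero.
#'
#' @param image_size_px `(height, width)` in pixels; default `c(1024, 1360)`
#'   approximating one 20x camera frame.
#' @param pixel_size_um Micrometres per pixel; default 0.5.
#' @param n_viable,n_netosing,n_necrotic Cell counts.
#' @param n_net_strands Count of diffuse red+green NET ribbons.
#' @param background_level Per-channel background mean; default 100.
#' @param noise_sigma Additive Gaussian noise SD; default 10.
#' @param contrast Object-peak-to-noise ratio: peak intensity above
#'   background is `contrast * noise_sigma`; default 10.
#' @param viable_ratio True blue/red ratio of viable nuclei; default 3.
#' @param necrotic_ratio True blue/red ratio of necrotic nuclei; default 0.1.
#' @param seed Integer seed making the generator a pure function of
#'   `(spec, seed)`.
#' @return Object of class `"field_spec"`.
#' @export
field_spec <- function(image_size_px = c(1024L, 1360L), pixel_size_um = 0.5,
                       n_viable = 5L, n_netosing = 3L, n_necrotic = 2L,
                       n_net_strands = 2L, background_level = 100,
                       noise_sigma = 10, contrast = 10,
                       viable_ratio = 3, necrotic_ratio = 0.1, seed = 1L) {
  stopifnot(length(image_size_px) == 2L, all(image_size_px >= 64L),
            pixel_size_um > 0, n_viable >= 0L, n_netosing >= 0L,
            n_necrotic >= 0L, n_net_strands >= 0L, background_level >= 0,
            noise_sigma >= 0, contrast > 0, viable_ratio > 0,
            necrotic_ratio > 0)
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um,
                 n_viable = as.integer(n_viable),
                 n_netosing = as.integer(n_netosing),
                 n_necrotic = as.integer(n_necrotic),
                 n_net_strands = as.integer(n_net_strands),
                 background_level = background_level,
                 noise_sigma = noise_sigma, contrast = contrast,
                 viable_ratio = viable_ratio,
                 necrotic_ratio = necrotic_ratio,
                 seed = as.integer(seed)),
            class = "field_spec")
}

# Stamp a radial profile into a plane with pmax semantics.
# center: (row, col) 1-based; radius_px scalar; value(dist) -> intensity.
stamp <- function(plane, center, radius_px, intensity_fn) {
  nr <- nrow(plane); nc <- ncol(plane)
  r0 <- max(1L, floor(center[1L] - radius_px))
  r1 <- min(nr, ceiling(center[1L] + radius_px))
  c0 <- max(1L, floor(center[2L] - radius_px))
  c1 <- min(nc, ceiling(center[2L] + radius_px))
  rr <- r0:r1; cc <- c0:c1
  d <- sqrt(outer((rr - center[1L])^2, (cc - center[2L])^2, "+"))
  v <- intensity_fn(d)
  plane[rr, cc] <- pmax(plane[rr, cc], v)
  plane
}

# Perturbed-boundary membership: angular radius R(theta) = R*(1 + amp*sin(k
# theta + phase)). Returns a function(dist, theta) -> logical inside.
perturbed_radius <- function(radius_px, wobble, k, phase) {
  function(theta) radius_px * (1 + wobble * sin(k * theta + phase))
}

#' Generate a synthetic three-channel field with ground truth
#'
#' Seeded renderer for [field_spec()]. Objects are placed by rejection
#' sampling with a clearance margin so no two objects merge (an error is
#' raised after 10^4 failed placements). The same seed always reproduces a
#' bit-identical field and ground truth.
#'
#' @param spec A [field_spec()].
#' @return List with `field` (a [multichannel_field()]) and `truth`
#'   (class `"ground_truth_field"`): `objects` data frame (`class`,
#'   `centroid_x`, `centroid_y` 0-based, `radius_px`, true channel peaks)
#'   and `net_pixel_mask`, the boolean plane of true NET pixels (strands
#'   plus NETosing-cell corona spill).
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  withr::with_seed(spec$seed, generate_field_impl(spec))
}

generate_field_impl <- function(spec) {
  nr <- spec$image_size_px[1L]; nc <- spec$image_size_px[2L]
  ppu <- 1 / spec$pixel_size_um                       # px per um
  # peak above background; a noiseless spec keeps unit noise scale so
  # contrast still sets the absolute object intensity
  amp <- spec$contrast * if (spec$noise_sigma > 0) spec$noise_sigma else 1
  blue <- matrix(0, nr, nc); red <- matrix(0, nr, nc)
  green <- matrix(0, nr, nc)
  net_mask <- matrix(FALSE, nr, nc)

  classes <- c(rep("viable", spec$n_viable),
               rep("netosing", spec$n_netosing),
               rep("necrotic", spec$n_necrotic))
  n_obj <- length(classes)
  placed <- matrix(numeric(0), ncol = 3L)             # row, col, clearance R
  margin <- 6

  place <- function(radius_px) {
    fails <- 0L
    repeat {
      cy <- stats::runif(1, radius_px + 3, nr - radius_px - 3)
      cx <- stats::runif(1, radius_px + 3, nc - radius_px - 3)
      ok <- TRUE
      if (nrow(placed) > 0L) {
        d <- sqrt((placed[, 1L] - cy)^2 + (placed[, 2L] - cx)^2)
        ok <- all(d > placed[, 3L] + radius_px + margin)
      }
      if (ok) return(c(cy, cx))
      fails <- fails + 1L
      if (fails >= 10000L) {
        stop("infeasible placement density: 10^4 failed placements",
             call. = FALSE)
      }
    }
  }

  objects <- data.frame(class = character(), centroid_x = numeric(),
                        centroid_y = numeric(), radius_px = numeric(),
                        peak_blue = numeric(), peak_red = numeric(),
                        peak_green = numeric(), stringsAsFactors = FALSE)

  for (cl in classes) {
    if (cl == "netosing") {
      r_out <- stats::runif(1, 5, 10) * ppu           # blob radius 5-10 um
      ctr <- place(r_out * 1.15)
      placed <- rbind(placed, c(ctr, r_out * 1.15))
      r_core <- 0.5 * r_out
      wob <- perturbed_radius(r_out, 0.12, sample(3:5, 1L),
                              stats::runif(1, 0, 2 * pi))
      # local window
      r0 <- max(1L, floor(ctr[1L] - 1.2 * r_out))
      r1 <- min(nr, ceiling(ctr[1L] + 1.2 * r_out))
      c0 <- max(1L, floor(ctr[2L] - 1.2 * r_out))
      c1 <- min(nc, ceiling(ctr[2L] + 1.2 * r_out))
      rr <- r0:r1; cc <- c0:c1
      dy <- matrix(rr - ctr[1L], length(rr), length(cc))
      dx <- matrix(cc - ctr[2L], length(rr), length(cc), byrow = TRUE)
      d <- sqrt(dy^2 + dx^2)
      theta <- atan2(dy, dx)
      rb <- wob(theta)                                # boundary radius
      inside <- d <= rb
      core <- d <= r_core
      corona <- inside & !core
      # red+green: flat in core, radial falloff 1 -> 0.7 across the corona
      fall <- matrix(1, length(rr), length(cc))
      fall[corona] <- 1 - 0.3 * (d[corona] - r_core) / (rb[corona] - r_core)
      redv <- matrix(0, length(rr), length(cc))
      redv[inside] <- amp * fall[inside]
      greenv <- redv
      bluev <- matrix(0, length(rr), length(cc))
      bluev[core] <- amp
      red[rr, cc] <- pmax(red[rr, cc], redv)
      green[rr, cc] <- pmax(green[rr, cc], greenv)
      blue[rr, cc] <- pmax(blue[rr, cc], bluev)
      net_mask[rr, cc] <- net_mask[rr, cc] | corona
      objects <- rbind(objects, data.frame(
        class = cl, centroid_x = ctr[2L] - 1, centroid_y = ctr[1L] - 1,
        radius_px = r_out, peak_blue = amp, peak_red = amp,
        peak_green = amp, stringsAsFactors = FALSE))
    } else {
      r_px <- stats::runif(1, 3, 5) * ppu             # nucleus radius 3-5 um
      ctr <- place(r_px)
      placed <- rbind(placed, c(ctr, r_px))
      if (cl == "viable") {
        pb <- amp; pr <- amp / spec$viable_ratio; pg <- 0
      } else {
        pr <- amp; pb <- amp * spec$necrotic_ratio; pg <- 0
      }
      disk <- function(peak) {
        function(d) ifelse(d <= r_px, peak, 0)
      }
      if (pb > 0) blue <- stamp(blue, ctr, r_px, disk(pb))
      if (pr > 0) red <- stamp(red, ctr, r_px, disk(pr))
      objects <- rbind(objects, data.frame(
        class = cl, centroid_x = ctr[2L] - 1, centroid_y = ctr[1L] - 1,
        radius_px = r_px, peak_blue = pb, peak_red = pr, peak_green = pg,
        stringsAsFactors = FALSE))
    }
  }

  # NET strands: persistent random-walk ribbons, red+green, clear of cells
  strands_placed <- 0L
  fails <- 0L
  while (strands_placed < spec$n_net_strands) {
    if (fails >= 10000L) {
      stop("infeasible placement density for NET strands", call. = FALSE)
    }
    n_steps <- sample(150:300, 1L)
    thick <- stats::runif(1, 1, 2)                    # ribbon radius, px
    y <- stats::runif(1, 10, nr - 10)
    x <- stats::runif(1, 10, nc - 10)
    dir <- stats::runif(1, 0, 2 * pi)
    pts <- matrix(NA_real_, n_steps, 2L)
    ok <- TRUE
    for (s in seq_len(n_steps)) {
      dir <- dir + stats::rnorm(1, 0, 0.25)
      y <- y + 2 * sin(dir); x <- x + 2 * cos(dir)
      if (y < 5 || y > nr - 5 || x < 5 || x > nc - 5) {
        dir <- dir + pi / 2                           # bounce off the border
        y <- min(max(y, 5), nr - 5); x <- min(max(x, 5), nc - 5)
      }
      if (nrow(placed) > 0L) {
        d <- sqrt((placed[, 1L] - y)^2 + (placed[, 2L] - x)^2)
        if (any(d <= placed[, 3L] + thick + margin)) { ok <- FALSE; break }
      }
      pts[s, ] <- c(y, x)
    }
    if (!ok) { fails <- fails + 1L; next }
    for (s in seq_len(n_steps)) {
      rr0 <- max(1L, floor(pts[s, 1L] - thick))
      rr1 <- min(nr, ceiling(pts[s, 1L] + thick))
      cc0 <- max(1L, floor(pts[s, 2L] - thick))
      cc1 <- min(nc, ceiling(pts[s, 2L] + thick))
      rr <- rr0:rr1; cc <- cc0:cc1
      d <- sqrt(outer((rr - pts[s, 1L])^2, (cc - pts[s, 2L])^2, "+"))
      hit <- d <= thick
      red[rr, cc][hit] <- pmax(red[rr, cc][hit], amp)
      green[rr, cc][hit] <- pmax(green[rr, cc][hit], 0.9 * amp)
      net_mask[rr, cc][hit] <- TRUE
    }
    strands_placed <- strands_placed + 1L
  }

  add_noise <- function(p) {
    pmax(p + spec$background_level +
           stats::rnorm(length(p), 0, spec$noise_sigma), 0)
  }
  field <- multichannel_field(
    matrix(add_noise(blue), nr, nc),
    matrix(add_noise(red), nr, nc),
    matrix(add_noise(green), nr, nc),
    pixel_size_um = spec$pixel_size_um,
    source_id = sprintf("synthetic(seed=%d)", spec$seed))

  truth <- structure(list(objects = objects, net_pixel_mask = net_mask,
                          spec = spec),
                     class = "ground_truth_field")
  list(field = field, truth = truth)
}

#' True NET-pixel percentage of a ground truth field
#'
#' @param truth A `"ground_truth_field"`.
#' @return `100 * |net_pixel_mask| / total pixels`.
#' @export
true_percent_area_nets <- function(truth) {
  stopifnot(inherits(truth, "ground_truth_field"))
  100 * sum(truth$net_pixel_mask) / length(truth$net_pixel_mask)
}

#' Match detected cells to ground-truth objects by proximity
#'
#' Greedy nearest-centroid matching within `max_dist_px`; used to score
#' per-cell classification accuracy against a generated field.
#'
#' @param cells Cell table from [quantify_field()].
#' @param truth A `"ground_truth_field"`.
#' @param max_dist_px Maximum centroid distance for a match; default 15.
#' @return Data frame with one row per ground-truth object: `true_class`,
#'   `matched` (logical), `detected_class` (`NA` when unmatched).
#' @export
match_cells_to_truth <- function(cells, truth, max_dist_px = 15) {
  obj <- truth$objects
  out <- data.frame(true_class = obj$class, matched = FALSE,
                    detected_class = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(cells) == 0L || nrow(obj) == 0L) return(out)
  used <- rep(FALSE, nrow(cells))
  for (i in seq_len(nrow(obj))) {
    d <- sqrt((cells$centroid_x - obj$centroid_x[i])^2 +
              (cells$centroid_y - obj$centroid_y[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= max_dist_px) {
      out$matched[i] <- TRUE
      out$detected_class[i] <- cells$cell_class[j]
      used[j] <- TRUE
    }
  }
  out
}

#' Generate a synthetic calibration + releasate data set
#'
#' Emulates the release-assay layout: a serial-dilution standard curve read
#' at 340 nm and replicated releasate absorbances over the default 14-point
#' sampling schedule, with seeded Gaussian absorbance noise.
#'
#' @param true_curve List with `slope` and `intercept` of the true
#'   absorbance/concentration line.
#' @param true_interval_conc Named list, one numeric vector of true interval
#'   concentrations (% v/v) per template, each matching `timepoints_h`.
#' @param noise_sigma Absorbance noise SD (>= 0).
#' @param n_replicates Replicate template punches per timepoint; default 4.
#' @param seed Integer seed.
#' @param timepoints_h Sampling schedule; default [release_schedule_h()].
#' @param cal_concentrations Standard-curve dilution series (% v/v).
#' @return List of data frames `calibration` (`concentration_pct`,
#'   `absorbance`) and `releasate` (`template_id`, `timepoint_h`,
#'   `replicate`, `absorbance`), plus `truth` (the inputs echoed).
#' @export
generate_release_data <- function(true_curve, true_interval_conc,
                                  noise_sigma = 0.005, n_replicates = 4L,
                                  seed = 1L,
                                  timepoints_h = release_schedule_h(),
                                  cal_concentrations =
                                    c(0, 0.15625, 0.3125, 0.625, 1.25,
                                      2.5, 5, 10)) {
  stopifnot(noise_sigma >= 0, n_replicates >= 1L)
  if (!is.list(true_interval_conc) || is.null(names(true_interval_conc))) {
    stop("true_interval_conc must be a named list of per-template vectors",
         call. = FALSE)
  }
  for (tid in names(true_interval_conc)) {
    if (length(true_interval_conc[[tid]]) != length(timepoints_h)) {
      stop("template '", tid, "': interval concentrations must match the ",
           length(timepoints_h), "-point schedule", call. = FALSE)
    }
  }
  withr::with_seed(seed, {
    cal <- data.frame(
      concentration_pct = cal_concentrations,
      absorbance = true_curve$intercept +
        true_curve$slope * cal_concentrations +
        stats::rnorm(length(cal_concentrations), 0, noise_sigma))
    rel <- NULL
    for (tid in names(true_interval_conc)) {
      conc <- true_interval_conc[[tid]]
      for (rep_i in seq_len(n_replicates)) {
        rel <- rbind(rel, data.frame(
          template_id = tid, timepoint_h = timepoints_h,
          replicate = rep_i,
          absorbance = true_curve$intercept + true_curve$slope * conc +
            stats::rnorm(length(conc), 0, noise_sigma),
          stringsAsFactors = FALSE))
      }
    }
    list(calibration = cal, releasate = rel,
         truth = list(curve = true_curve,
                      interval_conc = true_interval_conc,
                      timepoints_h = timepoints_h))
  })
}

#' Generate a synthetic MPO panel
#'
#' Emulates the MPO assay layout: heparin-treated wells report the full
#' (NET-bound plus free) MPO, replicates without heparin report only the
#' free fraction `1 - net_bound_fraction`. Positive-control rows (condition
#' `"positive_control"`, 100% response) are included per experiment.
#' Measurement noise is seeded lognormal at coefficient of variation
#' `noise_cv` (0 gives exact values).
#'
#' @param true_response_pct Named numeric vector of true percent-NETosis
#'   responses per condition.
#' @param control_conc True MPO concentration of the positive control.
#' @param net_bound_fraction Fraction of MPO that is NET-bound, in \[0, 1\].
#' @param noise_cv Lognormal measurement CV (>= 0).
#' @param n_replicates Replicates per condition per arm; default 3.
#' @param seed Integer seed.
#' @param experiment_id Experiment label; default `"exp1"`.
#' @param no_heparin_conditions Conditions also run without heparin;
#'   defaults to all conditions.
#' @return Data frame with columns `experiment_id`, `sample_id`,
#'   `condition`, `heparin_flag`, `mpo_conc`.
#' @export
generate_mpo_panel <- function(true_response_pct, control_conc = 100,
                               net_bound_fraction = 0.95, noise_cv = 0.1,
                               n_replicates = 3L, seed = 1L,
                               experiment_id = "exp1",
                               no_heparin_conditions = NULL) {
  stopifnot(net_bound_fraction >= 0, net_bound_fraction <= 1,
            noise_cv >= 0, control_conc > 0)
  if (is.null(names(true_response_pct))) {
    stop("true_response_pct must be a named vector of conditions",
         call. = FALSE)
  }
  if (is.null(no_heparin_conditions)) {
    no_heparin_conditions <- names(true_response_pct)
  }
  sdlog <- sqrt(log(1 + noise_cv^2))
  noisy <- function(m, n) {
    if (noise_cv == 0 || all(m == 0)) return(rep(m, length.out = n))
    m * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
  }
  withr::with_seed(seed, {
    rows <- NULL
    add <- function(cond, hep, true_conc) {
      vals <- noisy(true_conc, n_replicates)
      data.frame(experiment_id = experiment_id,
                 sample_id = paste0(cond, if (hep) "_hep" else "_nohep",
                                    "_", seq_len(n_replicates)),
                 condition = cond, heparin_flag = hep, mpo_conc = vals,
                 stringsAsFactors = FALSE)
    }
    for (cond in names(true_response_pct)) {
      full <- control_conc * true_response_pct[[cond]] / 100
      rows <- rbind(rows, add(cond, TRUE, full))
      if (cond %in% no_heparin_conditions) {
        rows <- rbind(rows, add(cond, FALSE, (1 - net_bound_fraction) * full))
      }
    }
    rows <- rbind(rows, add("positive_control", TRUE, control_conc))
    rownames(rows) <- NULL
    rows
  })
}
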