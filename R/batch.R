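#' Resolve a run configuration
#'
#' Reads a YAML configuration (or takes an equivalent list), fills every
#' defaulted value, and validates the result. The resolved configuration is
#' echoed into every run log so a run can be reproduced bit-identically.
#'
#' @param config Path to a YAML file or a named list. Recognized keys:
#'   `pixel_size_um`, `channel_map` (named blue/red/green plane indices or
#'   file names), `roi` (`"auto"` or a list `x0, y0, width, height`),
#'   `binarization` (per-channel lists with `method` and optional
#'   `fixed_threshold`), `detection` (arguments of [detection_params()]),
#'   `alpha`, `parametric_min_n`, `output_dir`, `seed`.
#' @return List of class `"run_config"` with all values resolved.
#' @export
read_run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  known <- c("pixel_size_um", "channel_map", "roi", "binarization",
             "detection", "alpha", "parametric_min_n", "output_dir", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  get <- function(key, default) if (is.null(config[[key]])) default
                                else config[[key]]
  bin_cfg <- get("binarization", list())
  bin <- list()
  for (ch in c("blue", "red", "green")) {
    b <- if (is.null(bin_cfg[[ch]])) bin_cfg else bin_cfg[[ch]]
    method <- if (is.null(b$method)) "automatic" else b$method
    bin[[ch]] <- binarization_params(method = method,
                                     fixed_threshold = b$fixed_threshold)
  }
  det <- do.call(detection_params, get("detection", list()))
  roi_cfg <- get("roi", "auto")
  if (!identical(roi_cfg, "auto")) {
    roi_cfg <- region_of_interest(roi_cfg$x0, roi_cfg$y0, roi_cfg$width,
                                  roi_cfg$height)
  }
  out <- list(pixel_size_um = get("pixel_size_um", 0.5),
              channel_map = get("channel_map",
                                list(blue = 3L, red = 1L, green = 2L)),
              roi = roi_cfg,
              binarization = bin,
              detection = det,
              alpha = get("alpha", 0.05),
              parametric_min_n = get("parametric_min_n", 6L),
              output_dir = get("output_dir", NULL),
              seed = get("seed", 1L))
  stopifnot(out$pixel_size_um > 0, out$alpha > 0, out$alpha < 1)
  structure(out, class = "run_config")
}

# Serialize the resolved config plus run metadata to JSON.
write_run_log <- function(path, config, extra = list()) {
  cfg <- unclass(config)
  cfg$detection <- unclass(cfg$detection)
  cfg$binarization <- lapply(cfg$binarization, unclass)
  if (inherits(cfg$roi, "region_of_interest")) cfg$roi <- unclass(cfg$roi)
  log <- c(list(package = "netquant",
                package_version = as.character(
                  utils::packageVersion("netquant")),
                r_version = paste(R.version$major, R.version$minor,
                                  sep = "."),
                config = cfg),
           extra)
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Quantify a batch of fields grouped by condition
#'
#' Runs [quantify_field()] on every image of a grouping manifest and
#' aggregates per condition, both over images and over replicate means
#' (fields are nested in replicate punches nested in conditions).
#'
#' @param manifest Data frame (or CSV path) with columns `condition`,
#'   `replicate`, `image` (raster path). Unreadable images are skipped with
#'   a warning; a condition with no readable image is an error.
#' @param config A [read_run_config()] result, list, or YAML path.
#' @return List with `fields` (one summary row per image, with condition
#'   and replicate), `conditions` (per-condition mean/SD over images),
#'   `replicate_means` (per-condition mean/SD over replicate means) and
#'   `results` (the `"net_quant"` objects). When `config$output_dir` is set,
#'   writes `field_summary.csv`, `condition_summary.csv`, per-image cell
#'   tables and `run_log.json` there.
#' @export
run_quantify <- function(manifest, config = list()) {
  config <- as_run_config(config)
  manifest_dir <- "."
  if (is.character(manifest)) {
    manifest_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest)
  }
  need <- c("condition", "replicate", "image")
  if (!all(need %in% names(manifest))) {
    stop("manifest needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  # manifests carry image paths relative to their own location so a
  # simulated or archived data set stays portable; reports keep the
  # manifest's own (relative) names
  paths <- manifest$image
  rel <- !grepl("^(/|[A-Za-z]:)", paths)
  paths[rel] <- file.path(manifest_dir, paths[rel])

  rows <- NULL; results <- list()
  for (i in seq_len(nrow(manifest))) {
    fq <- tryCatch({
      field <- load_field(paths[i],
                          channel_map = config$channel_map,
                          pixel_size_um = config$pixel_size_um)
      quantify_field(field,
                     roi = if (identical(config$roi, "auto")) NULL
                           else config$roi,
                     bin_params = config$binarization,
                     det_params = config$detection)
    }, error = function(e) {
      warning("skipping image '", paths[i], "': ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(fq)) next
    row <- cbind(data.frame(condition = manifest$condition[i],
                            replicate = manifest$replicate[i],
                            image = manifest$image[i],
                            stringsAsFactors = FALSE),
                 fq$summary)
    rows <- rbind(rows, row)
    results[[manifest$image[i]]] <- fq
  }
  missing_conds <- setdiff(unique(manifest$condition),
                           unique(rows$condition))
  if (length(missing_conds)) {
    stop("condition(s) with no readable image: ",
         paste(missing_conds, collapse = ", "), call. = FALSE)
  }

  agg <- function(df) {
    conds <- unique(df$condition)
    do.call(rbind, lapply(conds, function(cd) {
      s <- df[df$condition == cd, , drop = FALSE]
      data.frame(condition = cd, n = nrow(s),
                 mean_percent_area_nets = mean(s$percent_area_nets),
                 sd_percent_area_nets = stats::sd(s$percent_area_nets),
                 mean_pct_netosing = mean(s$pct_netosing),
                 sd_pct_netosing = stats::sd(s$pct_netosing),
                 mean_pct_necrotic = mean(s$pct_necrotic),
                 sd_pct_necrotic = stats::sd(s$pct_necrotic),
                 stringsAsFactors = FALSE)
    }))
  }
  conditions <- agg(rows)
  rep_means <- do.call(rbind, lapply(split(
    rows, list(rows$condition, rows$replicate), drop = TRUE),
    function(s) data.frame(condition = s$condition[1L],
                           replicate = s$replicate[1L],
                           percent_area_nets = mean(s$percent_area_nets),
                           pct_netosing = mean(s$pct_netosing),
                           pct_necrotic = mean(s$pct_necrotic),
                           stringsAsFactors = FALSE)))
  rep_means <- rep_means[order(rep_means$condition, rep_means$replicate), ,
                         drop = FALSE]
  rownames(rep_means) <- NULL
  replicate_means <- agg(rep_means)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rows, file.path(config$output_dir,
                                     "field_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(conditions, file.path(config$output_dir,
                                           "condition_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(replicate_means,
                     file.path(config$output_dir,
                               "replicate_mean_summary.csv"),
                     row.names = FALSE)
    for (img in names(results)) {
      write_cell_table(results[[img]]$cells,
                       file.path(config$output_dir,
                                 paste0(tools::file_path_sans_ext(
                                   basename(img)), "_cells.csv")))
    }
    write_run_log(file.path(config$output_dir, "run_log.json"), config,
                  list(n_images = nrow(rows)))
  }
  list(fields = rows, conditions = conditions,
       replicate_means = replicate_means, results = results)
}

as_run_config <- function(config) {
  if (inherits(config, "run_config")) config else read_run_config(config)
}

#' Simulate a multi-condition synthetic image panel
#'
#' Writes seeded synthetic fields to TIFF together with a grouping manifest
#' consumable unchanged by [run_quantify()], plus ground-truth tables.
#'
#' @param conditions Named list; each element is a list of [field_spec()]
#'   arguments for that condition (the generator defaults apply to any
#'   argument left unset).
#' @param n_images Images per condition; default 2.
#' @param n_replicates Replicate punches per condition (images are dealt
#'   round-robin); default 1.
#' @param out_dir Output directory (created).
#' @param seed Base seed; image k of condition j runs at
#'   `seed + 1000 * j + k`.
#' @return List with `manifest` (data frame), `truth` (list of
#'   `"ground_truth_field"`), and the manifest CSV path.
#' @export
run_simulate <- function(conditions, n_images = 2L, n_replicates = 1L,
                         out_dir, seed = 1L) {
  stopifnot(is.list(conditions), length(conditions) >= 1L,
            !is.null(names(conditions)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- NULL; truths <- list()
  for (j in seq_along(conditions)) {
    cond <- names(conditions)[j]
    for (k in seq_len(n_images)) {
      args <- conditions[[j]]
      args$seed <- seed + 1000L * j + k
      spec <- do.call(field_spec, args)
      sim <- generate_field(spec)
      img_name <- sprintf("%s_%02d.tif", cond, k)
      img <- file.path(out_dir, img_name)
      # planes scaled jointly so channel ratios survive the 16-bit write
      write_field_tiff(sim$field, img,
                       max_intensity = spec$background_level +
                         2 * spec$contrast * spec$noise_sigma)
      utils::write.csv(sim$truth$objects,
                       file.path(out_dir,
                                 sprintf("%s_%02d_truth.csv", cond, k)),
                       row.names = FALSE)
      manifest <- rbind(manifest, data.frame(
        condition = cond,
        replicate = ((k - 1L) %% n_replicates) + 1L,
        image = img_name, stringsAsFactors = FALSE))
      truths[[img_name]] <- sim$truth
    }
  }
  path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  list(manifest = manifest, truth = truths, manifest_path = path)
}

#' Release-assay workflow: fit, invert, cumulate
#'
#' Fits the standard curve from a calibration table, inverts every releasate
#' absorbance, averages replicates per template and timepoint, and computes
#' cumulative release.
#'
#' @param calibration Data frame or CSV path with columns
#'   `concentration_pct`, `absorbance`.
#' @param releasate Data frame or CSV path with columns `template_id`,
#'   `timepoint_h`, `replicate`, `absorbance`.
#' @param out_dir Optional output directory for `release_report.csv`.
#' @return List with `curve` (the `"calibration_curve"`), `per_sample`
#'   (releasate with concentrations appended) and `profile` (per template
#'   and timepoint: mean interval and cumulative percentages).
#' @export
run_release <- function(calibration, releasate, out_dir = NULL) {
  if (is.character(calibration)) {
    if (!file.exists(calibration)) {
      stop("calibration file not found: ", calibration, call. = FALSE)
    }
    calibration <- utils::read.csv(calibration)
  }
  if (is.character(releasate)) {
    if (!file.exists(releasate)) {
      stop("releasate file not found: ", releasate, call. = FALSE)
    }
    releasate <- utils::read.csv(releasate)
  }
  curve <- fit_standard_curve(calibration$concentration_pct,
                              calibration$absorbance)
  releasate$interval_conc_pct <-
    absorbance_to_concentration(curve, releasate$absorbance)
  agg <- stats::aggregate(interval_conc_pct ~ template_id + timepoint_h,
                          data = releasate, FUN = mean)
  profile <- cumulative_release(agg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(profile, file.path(out_dir, "release_report.csv"),
                     row.names = FALSE)
  }
  list(curve = curve, per_sample = releasate, profile = profile)
}

#' MPO workflow: normalization and heparin background check
#'
#' @param panel Data frame or CSV path with columns `experiment_id`,
#'   `sample_id`, `condition`, `heparin_flag`, `mpo_conc`.
#' @param out_dir Optional output directory for `mpo_report.csv` and
#'   `heparin_check.csv`.
#' @param cutoff Negligibility cutoff for [heparin_background_check()].
#' @return List with `response` (normalized heparin-arm rows) and
#'   `heparin_check` (per-condition ratios, `NULL` when no condition has
#'   both arms).
#' @export
run_mpo <- function(panel, out_dir = NULL, cutoff = 0.2) {
  if (is.character(panel)) {
    if (!file.exists(panel)) stop("MPO file not found: ", panel,
                                  call. = FALSE)
    panel <- utils::read.csv(panel)
  }
  response <- netosis_response_panel(panel)
  check <- tryCatch(heparin_background_check(panel, cutoff = cutoff),
                    error = function(e) NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(response, file.path(out_dir, "mpo_report.csv"),
                     row.names = FALSE)
    if (!is.null(check)) {
      utils::write.csv(check, file.path(out_dir, "heparin_check.csv"),
                       row.names = FALSE)
    }
  }
  list(response = response, heparin_check = check)
}

#' Group-comparison workflow
#'
#' @param groups Data frame or CSV path with columns `group`, `value`.
#' @param config A [read_run_config()] result, list, or YAML path (supplies
#'   `alpha` and `parametric_min_n`).
#' @param out_dir Optional output directory for `comparison_pairwise.csv`
#'   and `comparison_log.txt`.
#' @return The `"group_comparison"` object.
#' @export
run_compare <- function(groups, config = list(), out_dir = NULL) {
  config <- as_run_config(config)
  if (is.character(groups)) {
    if (!file.exists(groups)) stop("groups file not found: ", groups,
                                   call. = FALSE)
    groups <- utils::read.csv(groups)
  }
  if (!all(c("group", "value") %in% names(groups))) {
    stop("groups needs columns 'group' and 'value'", call. = FALSE)
  }
  cmp <- compare_groups(groups$value, groups$group, alpha = config$alpha,
                        parametric_min_n = config$parametric_min_n)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cmp$pairwise,
                     file.path(out_dir, "comparison_pairwise.csv"),
                     row.names = FALSE)
    txt <- c(utils::capture.output(print(cmp)))
    writeLines(txt, file.path(out_dir, "comparison_log.txt"))
  }
  cmp
}
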