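#' Construct a multi-channel fluorescence field
#'
#' A field holds the three registered intensity planes of one epifluorescence
#' micrograph: blue (DAPI, intact nuclei), red (sytox orange, extracellular /
#' permeable-cell DNA) and green (immunostained neutrophil elastase).
#' Intensities are kept on their native camera scale; nothing is rescaled to
#' \[0, 1\], so that downstream ratio-based classification is invariant to the
#' bit depth of the source images.
#'
#' @param blue,red,green Numeric matrices of non-negative, finite intensities.
#'   All three must share identical dimensions.
#' @param pixel_size_um Micrometres per pixel (> 0). The default 0.5 um/px
#'   corresponds to a typical 20x field.
#' @param source_id Free-text provenance label.
#'
#' @return An object of class `"multichannel_field"`: a list with elements
#'   `blue`, `red`, `green`, `pixel_size_um`, `source_id`.
#' @export
#' @examples
#' f <- multichannel_field(matrix(0, 8, 8), matrix(1, 8, 8), matrix(2, 8, 8))
#' dim(f$blue)
multichannel_field <- function(blue, red, green, pixel_size_um = 0.5,
                               source_id = "") {
  blue  <- as_plane(blue,  "blue")
  red   <- as_plane(red,   "red")
  green <- as_plane(green, "green")
  if (!identical(dim(blue), dim(red)) || !identical(dim(blue), dim(green))) {
    stop("channel planes must share identical dimensions (blue ",
         paste(dim(blue), collapse = "x"), ", red ",
         paste(dim(red), collapse = "x"), ", green ",
         paste(dim(green), collapse = "x"), ")", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number", call. = FALSE)
  }
  structure(
    list(blue = blue, red = red, green = green,
         pixel_size_um = as.numeric(pixel_size_um),
         source_id = as.character(source_id)),
    class = "multichannel_field"
  )
}

# Coerce one channel to a validated numeric matrix.
as_plane <- function(x, channel) {
  if (is.array(x) && length(dim(x)) == 3L && dim(x)[3L] == 1L) {
    x <- x[, , 1L]
  }
  if (!is.matrix(x)) stop("channel '", channel, "' is not a 2-D plane",
                          call. = FALSE)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("channel '", channel,
                               "' contains non-finite intensities",
                               call. = FALSE)
  if (any(x < 0)) stop("channel '", channel,
                       "' contains negative intensities", call. = FALSE)
  x
}

#' @export
print.multichannel_field <- function(x, ...) {
  cat("Multi-channel fluorescence field",
      if (nzchar(x$source_id)) paste0("[", x$source_id, "]"), "\n")
  cat(sprintf("  %d x %d px at %.3g um/px (%.0f x %.0f um)\n",
              nrow(x$blue), ncol(x$blue), x$pixel_size_um,
              nrow(x$blue) * x$pixel_size_um, ncol(x$blue) * x$pixel_size_um))
  for (ch in c("blue", "red", "green")) {
    cat(sprintf("  %-5s range [%.4g, %.4g]\n", ch, min(x[[ch]]), max(x[[ch]])))
  }
  invisible(x)
}

# Read a raster file on its native intensity scale.
# TIFF planes come back as stored integers (as.is); PNG planes, which the
# reader normalizes to [0, 1], are rescaled by 2^bitdepth - 1.
read_raster <- function(file) {
  if (!file.exists(file)) stop("image file not found: ", file, call. = FALSE)
  ext <- tolower(tools::file_ext(file))
  if (ext %in% c("tif", "tiff")) {
    planes <- tiff::readTIFF(file, as.is = TRUE, all = TRUE)
    if (!is.list(planes)) planes <- list(planes)
  } else if (ext == "png") {
    img <- png::readPNG(file, info = TRUE)
    depth <- attr(img, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    planes <- list(img * (2^depth - 1))
  } else {
    stop("unsupported raster format '", ext, "' for ", file, call. = FALSE)
  }
  # split h x w x c arrays into per-plane matrices
  out <- list()
  for (p in planes) {
    if (is.matrix(p)) {
      out[[length(out) + 1L]] <- p
    } else if (is.array(p) && length(dim(p)) == 3L) {
      for (k in seq_len(dim(p)[3L])) out[[length(out) + 1L]] <- p[, , k]
    } else {
      stop("unexpected raster structure in ", file, call. = FALSE)
    }
  }
  out
}

#' Load a multi-channel field from raster files
#'
#' Reads one multi-plane raster (TIFF directory stack or RGB TIFF/PNG) or one
#' file per channel, on the native intensity scale (8- and 16-bit inputs are
#' both supported and keep their stored values).
#'
#' @param path Path to a single multi-plane raster, or `NULL` when
#'   `channel_map` names one file per channel.
#' @param channel_map Named list or vector with entries `blue`, `red` and
#'   `green`, each assigned exactly once. Values are either 1-based plane
#'   indices into `path` (e.g. `c(red = 1, green = 2, blue = 3)`) or file
#'   paths of single-plane rasters.
#' @param pixel_size_um Micrometres per pixel; default 0.5.
#' @param source_id Provenance label; defaults to the file name(s).
#'
#' @return A [multichannel_field()].
#' @export
load_field <- function(path = NULL, channel_map, pixel_size_um = 0.5,
                       source_id = NULL) {
  channel_map <- as.list(channel_map)
  for (ch in c("blue", "red", "green")) {
    if (sum(names(channel_map) == ch) != 1L) {
      stop("channel_map must assign channel '", ch, "' exactly once",
           call. = FALSE)
    }
  }
  channel_map <- channel_map[c("blue", "red", "green")]
  vals <- unlist(channel_map, use.names = FALSE)

  if (is.numeric(vals)) {
    if (is.null(path)) {
      stop("plane-index channel_map requires 'path' to a multi-plane raster",
           call. = FALSE)
    }
    planes <- read_raster(path)
    idx <- as.integer(vals)
    if (any(idx < 1L | idx > length(planes))) {
      stop("channel_map plane index out of range: file '", path, "' has ",
           length(planes), " plane(s)", call. = FALSE)
    }
    picked <- planes[idx]
    src <- basename(path)
  } else if (is.character(vals)) {
    picked <- lapply(seq_along(vals), function(i) {
      p <- read_raster(vals[i])
      if (length(p) != 1L) {
        stop("file for channel '", names(channel_map)[i], "' (", vals[i],
             ") must contain a single plane; got ", length(p), call. = FALSE)
      }
      p[[1L]]
    })
    src <- paste(basename(vals), collapse = "+")
  } else {
    stop("channel_map values must be all plane indices or all file paths",
         call. = FALSE)
  }
  multichannel_field(picked[[1L]], picked[[2L]], picked[[3L]],
                     pixel_size_um = pixel_size_um,
                     source_id = if (is.null(source_id)) src else source_id)
}

cell_table_columns <- c("label_id", "centroid_x", "centroid_y", "area_um2",
                        "circularity", "mean_blue", "mean_red", "mean_green",
                        "blue_red_ratio", "green_positive", "cell_class")

# An empty, correctly-typed cell table.
empty_cell_table <- function() {
  data.frame(label_id = integer(), centroid_x = numeric(),
             centroid_y = numeric(), area_um2 = numeric(),
             circularity = numeric(), mean_blue = numeric(),
             mean_red = numeric(), mean_green = numeric(),
             blue_red_ratio = numeric(), green_positive = logical(),
             cell_class = character(), stringsAsFactors = FALSE)
}

#' Write a detected-cell table to CSV
#'
#' One row per detected cell with the fixed column set
#' `label_id, centroid_x, centroid_y, area_um2, circularity, mean_blue,
#' mean_red, mean_green, blue_red_ratio, green_positive, cell_class`.
#' An infinite blue/red ratio (cell with zero mean red) is serialized as the
#' literal token `"inf"`.
#'
#' @param records Data frame of cell records (as returned in the `cells`
#'   element of [quantify_field()]).
#' @param path Destination CSV path.
#' @return Invisibly, the path written.
#' @seealso [read_cell_table()]
#' @export
write_cell_table <- function(records, path) {
  missing_cols <- setdiff(cell_table_columns, names(records))
  if (length(missing_cols)) {
    stop("cell table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- records[, cell_table_columns, drop = FALSE]
  ratio <- out$blue_red_ratio
  out$blue_red_ratio <- ifelse(is.infinite(ratio), "inf",
                               format(ratio, digits = 15, trim = TRUE,
                                      scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a detected-cell table written by [write_cell_table()]
#'
#' @param path CSV path.
#' @return Data frame with the canonical cell-table columns; the `"inf"`
#'   ratio sentinel is parsed back to `Inf`.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("cell table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(blue_red_ratio = "character",
                                        cell_class = "character"))
  if (nrow(tab) == 0L) return(empty_cell_table())
  tab$blue_red_ratio <- ifelse(tab$blue_red_ratio == "inf", Inf,
                               as.numeric(tab$blue_red_ratio))
  tab$green_positive <- as.logical(tab$green_positive)
  tab$label_id <- as.integer(tab$label_id)
  tab[, cell_table_columns]
}

#' Write a field's channel planes to disk
#'
#' Utility used by the simulation front end: writes the three planes as one
#' 3-plane TIFF stack in RGB plane order (red, green, blue — the
#' [read_run_config()] default channel map) scaled to 16-bit.
#'
#' @param field A [multichannel_field()].
#' @param path Destination `.tif` path.
#' @param max_intensity Full-scale intensity mapped to 65535; defaults to the
#'   maximum over the three planes.
#' @return Invisibly, the path.
#' @export
write_field_tiff <- function(field, path, max_intensity = NULL) {
  stopifnot(inherits(field, "multichannel_field"))
  planes <- list(field$red, field$green, field$blue)
  if (is.null(max_intensity)) max_intensity <- max(unlist(lapply(planes, max)), 1)
  scaled <- lapply(planes, function(p) pmin(p / max_intensity, 1))
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}
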