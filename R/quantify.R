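#' Detection parameters for discrete-cell identification
#'
#' Size and shape filters for calling discrete cells, plus the intensity
#' rules that classify each cell. Defaults bracket the ~8.5 um diameter of a
#' human neutrophil.
#'
#' @param min_equiv_diameter_um,max_equiv_diameter_um Equivalent-circle
#'   diameter window (um) for a discrete cell; defaults 4 and 30.
#' @param min_circularity Minimum circularity `4*pi*A/P^2`; default 0.5.
#' @param ratio_cutoff Blue/red mean-intensity boundary between viable and
#'   necrotic; default 1/3 (the 1:3 rule).
#' @param green_positive_fraction Minimum fraction of a cell footprint that
#'   must be green-mask-positive to call three-channel colocalization;
#'   default 0.5.
#' @param tie_rule Class assigned when the blue/red ratio equals
#'   `ratio_cutoff` exactly; `"viable"` (default) or `"necrotic"`.
#' @return An object of class `"detection_params"`.
#' @export
detection_params <- function(min_equiv_diameter_um = 4,
                             max_equiv_diameter_um = 30,
                             min_circularity = 0.5,
                             ratio_cutoff = 1 / 3,
                             green_positive_fraction = 0.5,
                             tie_rule = c("viable", "necrotic")) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(min_equiv_diameter_um > 0,
            min_equiv_diameter_um < max_equiv_diameter_um,
            min_circularity >= 0, min_circularity <= 1,
            ratio_cutoff > 0,
            green_positive_fraction > 0, green_positive_fraction <= 1)
  structure(list(min_equiv_diameter_um = min_equiv_diameter_um,
                 max_equiv_diameter_um = max_equiv_diameter_um,
                 min_circularity = min_circularity,
                 ratio_cutoff = ratio_cutoff,
                 green_positive_fraction = green_positive_fraction,
                 tie_rule = tie_rule),
            class = "detection_params")
}

#' Per-channel binary mask set
#'
#' Bundles the three channel masks with the thresholds that produced them,
#' so every downstream report can echo its binarization.
#'
#' @param blue_mask,red_mask,green_mask Logical matrices of one shape.
#' @param thresholds_used Named numeric vector (`blue`, `red`, `green`);
#'   defaults to the `"threshold"` attributes of the masks.
#' @return An object of class `"binary_mask_set"`.
#' @export
binary_mask_set <- function(blue_mask, red_mask, green_mask,
                            thresholds_used = NULL) {
  masks <- list(blue_mask = blue_mask, red_mask = red_mask,
                green_mask = green_mask)
  for (nm in names(masks)) {
    if (!is.matrix(masks[[nm]]) || !is.logical(masks[[nm]])) {
      stop(nm, " must be a logical matrix", call. = FALSE)
    }
  }
  if (!identical(dim(blue_mask), dim(red_mask)) ||
      !identical(dim(blue_mask), dim(green_mask))) {
    stop("mask dimensions must match", call. = FALSE)
  }
  if (is.null(thresholds_used)) {
    thresholds_used <- c(
      blue = thr_attr(blue_mask), red = thr_attr(red_mask),
      green = thr_attr(green_mask))
  }
  structure(list(blue_mask = blue_mask, red_mask = red_mask,
                 green_mask = green_mask,
                 thresholds_used = thresholds_used),
            class = "binary_mask_set")
}

thr_attr <- function(m) {
  t <- attr(m, "threshold")
  if (is.null(t)) NA_real_ else as.numeric(t)
}

#' Percent area NETs
#'
#' The fraction of image pixels positive in the red (extracellular DNA)
#' mask but not the blue (intact nuclei) mask, times 100. The denominator is
#' the full image area.
#'
#' @param red_mask,blue_mask Logical matrices of one shape.
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' r <- matrix(FALSE, 10, 10); r[1:3, 1:10] <- TRUE  # 30 red px
#' b <- matrix(FALSE, 10, 10); b[1, 1:10] <- TRUE    # 10 of them also blue
#' percent_area_nets(r, b)  # 20
percent_area_nets <- function(red_mask, blue_mask) {
  if (!identical(dim(red_mask), dim(blue_mask))) {
    stop("red and blue masks must have the same shape", call. = FALSE)
  }
  if (length(red_mask) == 0L) stop("empty image", call. = FALSE)
  100 * sum(red_mask & !blue_mask) / length(red_mask)
}

# 8-connected components of a logical mask, via an edge graph over
# foreground pixels. Returns a list of sorted linear-index vectors, ordered
# by each component's first pixel in row-major (top-most, then left-most)
# order.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  if (length(fg) == 0L) return(list())
  id <- integer(nr * nc)
  id[fg] <- seq_along(fg)
  edge_list <- vector("list", 4L)
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  for (si in seq_along(shifts)) {
    dr <- shifts[[si]][1L]; dc <- shifts[[si]][2L]
    rr <- seq.int(max(1L, 1L - dr), min(nr, nr - dr))
    cc <- seq.int(max(1L, 1L - dc), min(nc, nc - dc))
    if (length(rr) == 0L || length(cc) == 0L) next
    both <- which(mask[rr, cc, drop = FALSE] &
                  mask[rr + dr, cc + dc, drop = FALSE])
    if (length(both)) {
      sr <- ((both - 1L) %% length(rr)) + 1L
      sc <- ((both - 1L) %/% length(rr)) + 1L
      ia <- (cc[sc] - 1L) * nr + rr[sr]
      ib <- (cc[sc] + dc - 1L) * nr + (rr[sr] + dr)
      edge_list[[si]] <- rbind(id[ia], id[ib])
    }
  }
  edges <- as.vector(do.call(cbind, edge_list))
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  comps <- split(fg, memb)
  # row-major key of each component's first pixel
  first_key <- vapply(comps, function(px) {
    r <- ((px - 1L) %% nr) + 1L
    c <- ((px - 1L) %/% nr) + 1L
    min((r - 1) * nc + (c - 1))
  }, numeric(1))
  comps <- comps[order(first_key)]
  lapply(unname(comps), sort)
}

# Perimeter of a connected pixel set by Moore-neighbour boundary tracing:
# the closed 8-connected contour walk, with straight steps counting 1 pixel
# and diagonal steps sqrt(2). Returns 0 for a single pixel.
chain_perimeter <- function(pixels, nr) {
  n_px <- length(pixels)
  if (n_px == 1L) return(0)
  r <- ((pixels - 1L) %% nr) + 1L
  c <- ((pixels - 1L) %/% nr) + 1L
  r0 <- min(r); c0 <- min(c)
  h <- max(r) - r0 + 3L; w <- max(c) - c0 + 3L
  m <- matrix(FALSE, h, w)
  m[cbind(r - r0 + 2L, c - c0 + 2L)] <- TRUE
  # clockwise Moore neighbourhood starting north
  offs <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L,
                   1L, 0L, 1L, -1L, 0L, -1L, -1L, -1L),
                 ncol = 2L, byrow = TRUE)
  top <- which(r - r0 + 2L == min(r - r0 + 2L))
  sp <- c(min(r) - r0 + 2L, min(c[top]) - c0 + 2L)  # top-most, left-most

  # one tracing step: from state (p, b) scan the Moore neighbourhood of p
  # clockwise starting just after the backtrack b; returns the next state
  # and the step length, or NULL for an isolated pixel
  advance <- function(p, b) {
    db <- b - p
    i0 <- which(offs[, 1L] == db[1L] & offs[, 2L] == db[2L])
    for (k in 1:8) {
      i <- ((i0 - 1L + k) %% 8L) + 1L
      q <- p + offs[i, ]
      if (m[q[1L], q[2L]]) {
        ip <- ((i0 - 1L + k - 1L) %% 8L) + 1L
        len <- if (offs[i, 1L] != 0L && offs[i, 2L] != 0L) sqrt(2) else 1
        return(list(p = q, b = p + offs[ip, ], len = len))
      }
    }
    NULL
  }

  # the walk's state (pixel, backtrack) is eventually periodic and one
  # period is the closed boundary: record the cumulative length at each
  # state's first visit and return the length accumulated around the cycle
  st <- advance(sp, sp + c(0L, -1L))                # enter from the west
  if (is.null(st)) return(0)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  cum <- 0
  steps <- 0L
  repeat {
    key <- paste(st$p[1L], st$p[2L], st$b[1L], st$b[2L])
    prev <- seen[[key]]
    if (!is.null(prev)) return(cum - prev)          # closed one cycle
    seen[[key]] <- cum
    st <- advance(st$p, st$b)
    cum <- cum + st$len
    steps <- steps + 1L
    if (steps > 8L * n_px + 8L) return(cum)         # safety stop
  }
}

#' Circularity of a connected pixel region
#'
#' `4*pi*A/P^2` with `A` the pixel count and `P` the boundary-walk perimeter
#' ([chain_perimeter] on the 8-connected contour). A perfect disk scores near
#' 1; elongated or ragged regions score lower. Discretization can push values
#' slightly above 1 and they are reported unclamped. A single-pixel region is
#' assigned 1 by convention (point-like disk).
#'
#' @param pixels Linear indices of the region's pixels (column-major).
#' @param nr Number of rows of the parent mask.
#' @return Dimensionless circularity.
#' @export
circularity <- function(pixels, nr) {
  if (length(pixels) == 0L) stop("empty region", call. = FALSE)
  if (length(pixels) == 1L) return(1)
  p <- chain_perimeter(pixels, nr)
  if (p <= 0) return(1)
  4 * pi * length(pixels) / p^2
}

# Geometry features of one connected region.
region_features <- function(pixels, nr, pixel_size_um) {
  r <- ((pixels - 1L) %% nr) + 1L
  c <- ((pixels - 1L) %/% nr) + 1L
  area_px <- length(pixels)
  area_um2 <- area_px * pixel_size_um^2
  list(pixels = pixels,
       area_px = area_px,
       area_um2 = area_um2,
       equiv_diameter_um = 2 * sqrt(area_um2 / pi),
       circularity = circularity(pixels, nr),
       centroid_xy = c(x = mean(c) - 1, y = mean(r) - 1))
}

#' Identify discrete cells by size and circularity
#'
#' Candidate cells are the 8-connected components of the union of the blue
#' and red masks (viable cells can be red-negative and necrotic cells nearly
#' blue-negative, so neither channel alone suffices). A component is kept iff
#' its equivalent-circle diameter lies in
#' `[min_equiv_diameter_um, max_equiv_diameter_um]` and its circularity is at
#' least `min_circularity`; diffuse NET strands fail the circularity filter.
#' Components are labelled deterministically by their top-most, then
#' left-most pixel.
#'
#' @param masks A [binary_mask_set()].
#' @param params A [detection_params()].
#' @param pixel_size_um Micrometres per pixel.
#' @return List of region feature lists (`pixels`, `area_um2`,
#'   `equiv_diameter_um`, `circularity`, `centroid_xy`).
#' @export
find_discrete_cells <- function(masks, params = detection_params(),
                                pixel_size_um = 0.5) {
  stopifnot(inherits(masks, "binary_mask_set"),
            inherits(params, "detection_params"))
  cand <- label_components(masks$blue_mask | masks$red_mask)
  nr <- nrow(masks$blue_mask)
  feats <- lapply(cand, region_features, nr = nr,
                  pixel_size_um = pixel_size_um)
  keep <- vapply(feats, function(f) {
    f$equiv_diameter_um >= params$min_equiv_diameter_um &&
      f$equiv_diameter_um <= params$max_equiv_diameter_um &&
      f$circularity >= params$min_circularity
  }, logical(1))
  feats[keep]
}

#' Measure one detected cell
#'
#' Computes background-subtracted mean channel intensities over the cell
#' footprint, the blue/red ratio (with an infinite sentinel when the mean red
#' intensity is exactly zero), and the green colocalization flag (fraction of
#' footprint pixels inside the green mask at least
#' `green_positive_fraction`).
#'
#' @param region One region from [find_discrete_cells()].
#' @param field The background-subtracted [multichannel_field()].
#' @param green_mask Logical green-channel mask.
#' @param params A [detection_params()].
#' @param label_id Integer label for the record.
#' @return One-row data frame with the cell-table columns (class not yet
#'   assigned unless [classify_cell()] is applied).
#' @export
measure_cell <- function(region, field, green_mask,
                         params = detection_params(), label_id = 1L) {
  px <- region$pixels
  if (any(px < 1L | px > length(field$blue))) {
    stop("region lies outside the field", call. = FALSE)
  }
  mb <- mean(field$blue[px])
  mr <- mean(field$red[px])
  mg <- mean(field$green[px])
  ratio <- if (mr == 0) Inf else mb / mr
  gfrac <- mean(green_mask[px])
  data.frame(label_id = as.integer(label_id),
             centroid_x = unname(region$centroid_xy["x"]),
             centroid_y = unname(region$centroid_xy["y"]),
             area_um2 = region$area_um2,
             circularity = region$circularity,
             mean_blue = mb, mean_red = mr, mean_green = mg,
             blue_red_ratio = ratio,
             green_positive = gfrac >= params$green_positive_fraction,
             cell_class = NA_character_,
             stringsAsFactors = FALSE)
}

#' Classify a measured cell as viable, NETosing or necrotic
#'
#' NETosing takes precedence: a cell with three-channel colocalization
#' (`green_positive` and non-zero blue and red means) is NETosing regardless
#' of its ratio. Otherwise the blue/red ratio decides: above the 1:3 cutoff
#' viable, below it necrotic, and a ratio exactly at the cutoff follows
#' `tie_rule` (default viable). An infinite ratio (zero red) is viable.
#'
#' @param record One-row data frame from [measure_cell()] (or any list with
#'   `green_positive`, `mean_blue`, `mean_red`, `blue_red_ratio`).
#' @param params A [detection_params()].
#' @return `"viable"`, `"netosing"` or `"necrotic"`.
#' @export
classify_cell <- function(record, params = detection_params()) {
  if (isTRUE(record$green_positive) && record$mean_blue > 0 &&
      record$mean_red > 0) {
    return("netosing")
  }
  ratio <- record$blue_red_ratio
  if (ratio > params$ratio_cutoff) return("viable")
  if (ratio < params$ratio_cutoff) return("necrotic")
  params$tie_rule
}

# One-row summary data frame; percentages all 0 when no cells detected.
field_quantification <- function(percent_area_nets, classes) {
  n_viable <- sum(classes == "viable")
  n_netosing <- sum(classes == "netosing")
  n_necrotic <- sum(classes == "necrotic")
  n_total <- length(classes)
  pct <- function(n) if (n_total > 0L) 100 * n / n_total else 0
  data.frame(percent_area_nets = percent_area_nets,
             n_viable = n_viable, n_netosing = n_netosing,
             n_necrotic = n_necrotic, n_total = n_total,
             pct_viable = pct(n_viable), pct_netosing = pct(n_netosing),
             pct_necrotic = pct(n_necrotic))
}

#' Quantify NETosis in one field
#'
#' The end-to-end scoring of a three-channel micrograph:
#' per-channel background subtraction over a NET-free ROI, per-channel
#' binarization, percent-area-NETs (red-not-blue pixels over the full image),
#' discrete-cell identification on the blue-or-red union, and per-cell
#' viable/NETosing/necrotic classification.
#'
#' @param field A [multichannel_field()].
#' @param roi A [region_of_interest()] containing no NETs, shared by all
#'   channels; when `NULL` the darkest tile proposed by [auto_roi()] on the
#'   channel sum is used.
#' @param bin_params A single [binarization_params()] applied to all
#'   channels, or a named list with elements `blue`, `red`, `green`.
#' @param det_params A [detection_params()].
#' @return An object of class `"net_quant"`: list with `summary` (one-row
#'   data frame: `percent_area_nets`, class counts and percentages),
#'   `cells` (cell table), `masks` (a [binary_mask_set()]), `roi`,
#'   `background` (per-channel levels subtracted) and `params`.
#' @export
quantify_field <- function(field, roi = NULL,
                           bin_params = binarization_params(),
                           det_params = detection_params()) {
  stopifnot(inherits(field, "multichannel_field"),
            inherits(det_params, "detection_params"))
  if (inherits(bin_params, "binarization_params")) {
    bin_params <- list(blue = bin_params, red = bin_params,
                       green = bin_params)
  }
  if (!all(c("blue", "red", "green") %in% names(bin_params))) {
    stop("bin_params must cover channels blue, red and green", call. = FALSE)
  }
  if (is.null(roi)) {
    roi <- auto_roi(field$blue + field$red + field$green)
  }

  sub <- list(); bg <- c(blue = NA_real_, red = NA_real_, green = NA_real_)
  masks <- list()
  for (ch in c("blue", "red", "green")) {
    s <- subtract_background(field[[ch]], roi)
    bg[[ch]] <- attr(s, "background")
    attr(s, "background") <- NULL
    sub[[ch]] <- s
    if (bin_params[[ch]]$method == "automatic") {
      # select the threshold on the raw plane, where the noise distribution
      # is intact (zero-clamping after subtraction distorts the histogram
      # statistics the separation guard relies on), then carry it onto the
      # subtracted scale; subtraction is monotone so the mask is identical
      thr_raw <- auto_threshold(field[[ch]])
      if (is.na(thr_raw)) {
        warning("channel '", ch, "': no separable foreground; empty mask",
                call. = FALSE)
        m <- matrix(FALSE, nrow(s), ncol(s))
        attr(m, "threshold") <- NA_real_
      } else {
        thr <- max(thr_raw - bg[[ch]], 0)
        m <- s > thr
        attr(m, "threshold") <- thr
      }
      masks[[ch]] <- m
    } else {
      masks[[ch]] <- binarize(s, bin_params[[ch]])
    }
  }
  sub_field <- multichannel_field(sub$blue, sub$red, sub$green,
                                  pixel_size_um = field$pixel_size_um,
                                  source_id = field$source_id)
  mask_set <- binary_mask_set(masks$blue, masks$red, masks$green)

  pan <- percent_area_nets(mask_set$red_mask, mask_set$blue_mask)
  regions <- find_discrete_cells(mask_set, det_params,
                                 pixel_size_um = field$pixel_size_um)
  if (length(regions)) {
    rows <- lapply(seq_along(regions), function(i) {
      rec <- measure_cell(regions[[i]], sub_field, mask_set$green_mask,
                          det_params, label_id = i)
      rec$cell_class <- classify_cell(rec, det_params)
      rec
    })
    cells <- do.call(rbind, rows)
  } else {
    cells <- empty_cell_table()
  }

  structure(list(summary = field_quantification(pan, cells$cell_class),
                 cells = cells,
                 masks = mask_set,
                 roi = roi,
                 background = bg,
                 params = list(binarization = bin_params,
                               detection = det_params),
                 source_id = field$source_id,
                 pixel_size_um = field$pixel_size_um),
            class = "net_quant")
}

#' @export
print.net_quant <- function(x, ...) {
  s <- x$summary
  cat("NET quantification",
      if (nzchar(x$source_id)) paste0("[", x$source_id, "]"), "\n")
  cat(sprintf("  percent area NETs: %.2f%%\n", s$percent_area_nets))
  cat(sprintf("  cells: %d (viable %d, NETosing %d, necrotic %d)\n",
              s$n_total, s$n_viable, s$n_netosing, s$n_necrotic))
  thr <- x$masks$thresholds_used
  cat(sprintf("  thresholds: blue %.4g, red %.4g, green %.4g\n",
              thr[["blue"]], thr[["red"]], thr[["green"]]))
  invisible(x)
}

#' @export
summary.net_quant <- function(object, ...) {
  s <- object$summary
  cat("Field quantification\n")
  print(s, row.names = FALSE)
  if (s$n_total > 0L) {
    cat("\nPer-cell records:\n")
    print(object$cells, row.names = FALSE, digits = 4)
  }
  invisible(s)
}

#' Plot a quantified field
#'
#' Renders the RGB composite of the (raw-scale) masks with detected-cell
#' centroids marked by class: viable circles, NETosing triangles, necrotic
#' crosses.
#'
#' @param x A `"net_quant"` object.
#' @param ... Passed to [graphics::plot].
#' @export
plot.net_quant <- function(x, ...) {
  m <- x$masks
  h <- nrow(m$red_mask); w <- ncol(m$red_mask)
  img <- array(0, dim = c(h, w, 3))
  img[, , 1] <- m$red_mask
  img[, , 2] <- m$green_mask * 0.8
  img[, , 3] <- m$blue_mask
  graphics::plot(NA, xlim = c(0, w), ylim = c(h, 0), asp = 1,
                 xlab = "x [px]", ylab = "y [px]", ...)
  graphics::rasterImage(grDevices::as.raster(img), 0, h, w, 0)
  if (nrow(x$cells)) {
    pchs <- c(viable = 1, netosing = 2, necrotic = 4)
    graphics::points(x$cells$centroid_x, x$cells$centroid_y,
                     pch = pchs[x$cells$cell_class], col = "white", cex = 1.5)
  }
  invisible(x)
}
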