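# Nuclei-density quantification from H&E raster images: tile decomposition,
# grayscale tissue detection, Otsu + local-adaptive nuclei segmentation with
# watershed splitting, shape filtering, and per-slide density.

#' Configuration of the density quantifier
#'
#' @param tile_px Tile edge in pixels; 1000 px at 0.5 um/px gives the
#'   conventional 0.25 mm^2 tile.
#' @param microns_per_pixel Image resolution (um/px); must be supplied here
#'   when the source carries no resolution metadata.
#' @param tissue_intensity_cutoff Grayscale value below which a pixel counts
#'   as tissue (slide background is brighter). Default 0.9 keeps faint eosin
#'   as tissue.
#' @param min_tissue_fraction Tiles below this tissue fraction contribute
#'   neither nuclei nor area to the density (default 0.05).
#' @param adaptive_window_px Odd window size of the local mean threshold.
#' @param adaptive_offset A pixel is locally dark when it is at least this
#'   far below its window mean.
#' @param watershed_min_distance_px Minimum separation of distance-transform
#'   maxima used to seed watershed splitting of oversized components.
#' @param nucleus_area_min_um2,nucleus_area_max_um2 Area band (um^2) of the
#'   shape filter; defaults 8-120 um^2 span lymphocyte to stromal nuclei.
#' @param min_circularity Shape-filter floor on `4*pi*area/perimeter^2`.
#' @return A `density_config`.
#' @export
density_config <- function(tile_px = 1000L, microns_per_pixel = 0.5,
                           tissue_intensity_cutoff = 0.9,
                           min_tissue_fraction = 0.05,
                           adaptive_window_px = 51L,
                           adaptive_offset = 0.02,
                           watershed_min_distance_px = 7L,
                           nucleus_area_min_um2 = 8,
                           nucleus_area_max_um2 = 120,
                           min_circularity = 0.25) {
  stopifnot(tile_px > 0, microns_per_pixel > 0,
            tissue_intensity_cutoff > 0, tissue_intensity_cutoff < 1,
            min_tissue_fraction >= 0, min_tissue_fraction <= 1,
            adaptive_window_px >= 3,
            nucleus_area_min_um2 < nucleus_area_max_um2,
            min_circularity >= 0, min_circularity <= 1)
  structure(
    list(tile_px = as.integer(tile_px),
         microns_per_pixel = microns_per_pixel,
         tissue_intensity_cutoff = tissue_intensity_cutoff,
         min_tissue_fraction = min_tissue_fraction,
         adaptive_window_px = as.integer(adaptive_window_px),
         adaptive_offset = adaptive_offset,
         watershed_min_distance_px = as.integer(watershed_min_distance_px),
         nucleus_area_min_um2 = nucleus_area_min_um2,
         nucleus_area_max_um2 = nucleus_area_max_um2,
         min_circularity = min_circularity),
    class = "density_config"
  )
}

#' Partition an image into tiles
#'
#' Cuts the image into `tile_px` x `tile_px` tiles in row-major order (top
#' row of tiles first, left to right). Edge tiles keep their true, smaller
#' dimensions; every pixel belongs to exactly one tile.
#'
#' @param image Path, EBImage `Image`, or `[x, y(, ch)]` array in `[0, 1]`.
#' @param config A [density_config()].
#' @return List of tiles, each a list with `tile_id`, `x0`, `y0` (0-based
#'   offsets), `width`, `height`, `pixels`.
#' @export
tile_image <- function(image, config = density_config()) {
  img <- if (is.character(image)) load_image(image) else image
  if (inherits(img, "Image")) img <- EBImage::imageData(img)
  d <- dim(img)
  if (length(d) < 2 || d[1] < 1 || d[2] < 1) stop("image must have >= 1 pixel")
  w <- d[1]; h <- d[2]
  tp <- config$tile_px
  xs <- seq(1, w, by = tp)
  ys <- seq(1, h, by = tp)
  tiles <- list()
  k <- 0L
  for (y0 in ys) {        # row-major: scan tile rows first
    for (x0 in xs) {
      k <- k + 1L
      xi <- x0:min(x0 + tp - 1L, w)
      yi <- y0:min(y0 + tp - 1L, h)
      px <- if (length(d) == 3) img[xi, yi, , drop = FALSE] else
        img[xi, yi, drop = FALSE]
      tiles[[k]] <- list(tile_id = k, x0 = x0 - 1L, y0 = y0 - 1L,
                         width = length(xi), height = length(yi),
                         pixels = px)
    }
  }
  tiles
}

#' Fraction of a tile occupied by tissue
#'
#' The tile is converted to grayscale (Rec. 709 luma) and the tissue
#' fraction is the proportion of pixels darker than
#' `tissue_intensity_cutoff`; tissue is darker than bare slide.
#'
#' @param tile A tile from [tile_image()], or a raw pixel array.
#' @param config A [density_config()].
#' @return Fraction in `[0, 1]`.
#' @export
tissue_fraction <- function(tile, config = density_config()) {
  px <- if (is.list(tile)) tile$pixels else tile
  mean(to_gray(px) < config$tissue_intensity_cutoff)
}

#' Segment nuclei in one tile
#'
#' The segmentation contract: (1) grayscale conversion; (2) candidate
#' nuclei mask = pixels dark under *both* a per-tile global Otsu threshold
#' and a local adaptive mean threshold (window `adaptive_window_px`, offset
#' `adaptive_offset`); (3) connected components; (4) components larger than
#' `nucleus_area_max_um2` are split by a watershed seeded at local maxima of
#' the Euclidean distance transform separated by at least
#' `watershed_min_distance_px`; (5) every surviving region is reported with
#' centroid, area (um^2) and circularity (`4*pi*area/perimeter^2`, clamped
#' to 1). A tile with zero tissue fraction yields an empty table, not an
#' error. Apply [shape_filter()] afterwards for the refined counts.
#'
#' @param tile A tile from [tile_image()], or a raw pixel array.
#' @param config A [density_config()].
#' @return data.frame with `centroid_x`, `centroid_y` (tile-local px),
#'   `area_um2`, `circularity`.
#' @export
segment_nuclei <- function(tile, config = density_config()) {
  px <- if (is.list(tile)) tile$pixels else tile
  gray <- to_gray(px)
  empty <- data.frame(centroid_x = numeric(0), centroid_y = numeric(0),
                      area_um2 = numeric(0), circularity = numeric(0))
  if (tissue_fraction(gray, config) == 0) return(empty)

  thr_otsu <- EBImage::otsu(EBImage::Image(clamp(gray, 0, 1)))
  dark_global <- gray < thr_otsu
  win <- config$adaptive_window_px
  if (win %% 2 == 0) win <- win + 1L
  win <- min(win, 2L * (min(dim(gray)) %/% 2L) - 1L)  # window <= tile
  if (win < 3) return(empty)
  box <- matrix(1 / (win * win), win, win)
  local_mean <- EBImage::filter2(EBImage::Image(gray), box)
  dark_local <- gray < (EBImage::imageData(local_mean) - config$adaptive_offset)
  cand <- dark_global & dark_local
  if (!any(cand)) return(empty)

  lab <- EBImage::bwlabel(EBImage::Image(cand * 1))
  labm <- EBImage::imageData(lab)
  mpp2 <- config$microns_per_pixel^2
  areas_px <- tabulate(labm[labm > 0])
  max_px <- config$nucleus_area_max_um2 / mpp2
  big <- which(areas_px > max_px)
  if (length(big)) {
    labm <- split_components(labm, big, config)
  }

  region_features(labm, mpp2)
}

# Watershed-split oversized components: seeds are local maxima of the
# Euclidean distance transform, enforced >= min_distance apart by a
# disc-dilation maximum filter; regions grow by EBImage::propagate.
split_components <- function(labm, big_ids, config) {
  d <- config$watershed_min_distance_px
  brush_size <- max(3L, 2L * (d %/% 2L) + 1L)
  brush <- EBImage::makeBrush(brush_size, shape = "disc")
  next_label <- max(labm)
  for (id in big_ids) {
    sub <- labm == id
    dm <- EBImage::distmap(EBImage::Image(sub * 1))
    dmd <- EBImage::imageData(dm)
    dil <- EBImage::imageData(EBImage::dilate(dm, brush))
    seeds <- (abs(dmd - dil) < 1e-6) & (dmd > 1)
    seed_lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(seeds * 1)))
    n_seeds <- max(seed_lab)
    if (n_seeds <= 1) next                      # nothing to split
    ws <- EBImage::propagate(EBImage::Image(-dmd), EBImage::Image(seed_lab),
                             mask = EBImage::Image(sub))
    wsd <- EBImage::imageData(ws)
    labm[sub] <- 0
    pos <- wsd > 0
    labm[pos] <- next_label + wsd[pos]
    next_label <- next_label + n_seeds
  }
  labm
}

region_features <- function(labm, mpp2) {
  if (max(labm) == 0) {
    return(data.frame(centroid_x = numeric(0), centroid_y = numeric(0),
                      area_um2 = numeric(0), circularity = numeric(0)))
  }
  # relabel contiguously so computeFeatures sees dense labels
  ids <- sort(unique(labm[labm > 0]))
  labm[labm > 0] <- match(labm[labm > 0], ids)
  limg <- EBImage::Image(labm)
  shp <- EBImage::computeFeatures.shape(limg)
  mom <- EBImage::computeFeatures.moment(limg)
  area_px <- shp[, "s.area"]
  perim <- pmax(shp[, "s.perimeter"], 1)
  data.frame(
    centroid_x = unname(mom[, "m.cx"]),
    centroid_y = unname(mom[, "m.cy"]),
    area_um2 = unname(area_px * mpp2),
    circularity = unname(pmin(1, 4 * pi * area_px / perim^2))
  )
}

#' Shape-filter nuclei detections
#'
#' Keeps detections whose area lies in
#' `[nucleus_area_min_um2, nucleus_area_max_um2]` and whose circularity is
#' at least `min_circularity`; input order is preserved.
#'
#' @param detections data.frame from [segment_nuclei()].
#' @param config A [density_config()].
#' @return The filtered data.frame.
#' @export
shape_filter <- function(detections, config = density_config()) {
  keep <- detections$area_um2 >= config$nucleus_area_min_um2 &
    detections$area_um2 <= config$nucleus_area_max_um2 &
    detections$circularity >= config$min_circularity
  detections[keep, , drop = FALSE]
}

#' Nuclei density of a slide image
#'
#' Runs the full quantifier: the image is tiled ([tile_image()]), each
#' tile's tissue fraction measured, nuclei segmented ([segment_nuclei()])
#' and shape-filtered ([shape_filter()]). Tiles whose tissue fraction falls
#' below `min_tissue_fraction` contribute neither nuclei nor area. The
#' density is total nuclei divided by total tissue area in mm^2 over the
#' contributing tiles; per-tile results are retained for audit.
#'
#' @param image Path, array/`Image`, or a list of such (several images
#'   pooled into one density estimate, e.g. pre-cut tiles).
#' @param config A [density_config()].
#' @return A `density_result`: list with `total_nuclei`,
#'   `total_tissue_area_mm2`, `density` (cells/mm^2, `NA` when no tile
#'   passes the tissue floor), `tiles` (data.frame: `tile_id`,
#'   `tissue_fraction`, `tissue_area_mm2`, `n_nuclei`, `included`) and the
#'   `config` echo.
#' @examples
#' slide <- generate_slide(tile_spec(250, 250, target_density = 2500), 1, 2)
#' compute_density(slide$image, density_config(tile_px = 250))
#' @export
compute_density <- function(image, config = density_config()) {
  if (is.list(image) && !is.null(image$image)) image <- image$image
  images <- if (is.list(image) && !inherits(image, "Image") &&
                is.null(dim(image))) image else list(image)
  images <- lapply(images, function(im) {
    if (is.list(im) && !is.null(im$image)) im$image else im
  })
  rows <- list()
  k <- 0L
  for (img in images) {
    for (tile in tile_image(img, config)) {
      k <- k + 1L
      tf <- tissue_fraction(tile, config)
      area <- tf * tile$width * tile$height *
        (config$microns_per_pixel / 1000)^2
      included <- tf >= config$min_tissue_fraction
      n <- if (included) {
        nrow(shape_filter(segment_nuclei(tile, config), config))
      } else {
        NA_integer_
      }
      rows[[k]] <- data.frame(tile_id = k, tissue_fraction = tf,
                              tissue_area_mm2 = area,
                              n_nuclei = n, included = included)
    }
  }
  tiles <- do.call(rbind, rows)
  inc <- tiles$included
  total_nuclei <- sum(tiles$n_nuclei[inc])
  total_area <- sum(tiles$tissue_area_mm2[inc])
  structure(
    list(total_nuclei = total_nuclei,
         total_tissue_area_mm2 = total_area,
         density = if (total_area > 0) total_nuclei / total_area else NA_real_,
         tiles = tiles, config = config),
    class = "density_result"
  )
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf(
    "<density_result> %d nuclei over %.3f mm^2 tissue: %s cells/mm^2 (%d/%d tiles used)\n",
    x$total_nuclei, x$total_tissue_area_mm2,
    if (is.na(x$density)) "undefined" else sprintf("%.0f", x$density),
    sum(x$tiles$included), nrow(x$tiles)))
  invisible(x)
}

#' Write a density report
#'
#' Emits the per-slide JSON report (counts, areas, density and a config
#' echo) and optionally the per-tile CSV.
#'
#' @param result A `density_result`.
#' @param json_path Output JSON path.
#' @param csv_path Optional per-tile CSV path.
#' @return `json_path`, invisibly.
#' @export
write_density_report <- function(result, json_path, csv_path = NULL) {
  stopifnot(inherits(result, "density_result"))
  payload <- list(
    total_nuclei = result$total_nuclei,
    total_tissue_area_mm2 = result$total_tissue_area_mm2,
    density = result$density,
    tiles_used = sum(result$tiles$included),
    tiles_total = nrow(result$tiles),
    config = unclass(result$config)
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  if (!is.null(csv_path)) {
    utils::write.csv(result$tiles, csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
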