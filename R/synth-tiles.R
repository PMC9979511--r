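# Ground-truthed H&E-like image tiles: eosin-pink tissue, near-white slide
# background, and hematoxylin-dark elliptical nuclei at a known density.

#' Specify a synthetic H&E-like tile
#'
#' Defaults follow the 20x whole-slide scan convention: 0.5 um/px and a
#' 1000 x 1000 px tile, i.e. 0.25 mm^2 of slide per full-tissue tile.
#'
#' @param width_px,height_px Tile size in pixels.
#' @param microns_per_pixel Physical resolution (um/px, > 0).
#' @param target_density Expected nuclei per mm^2 of tissue (>= 0); the
#'   realized count is Poisson with this mean times the tissue area.
#' @param tissue_mask_fraction Fraction of the tile covered by tissue in
#'   `[0, 1]`; the tissue occupies the leftmost columns, the rest is bare
#'   slide.
#' @param overlap_allowed When `FALSE` (default), nuclei are rejection-
#'   sampled so that bounding-circle boundaries stay >= 2 px apart.
#' @param seed Integer seed; the same spec renders byte-identical tiles.
#' @return A `tile_spec`.
#' @export
tile_spec <- function(width_px = 1000L, height_px = 1000L,
                      microns_per_pixel = 0.5, target_density = 3400,
                      tissue_mask_fraction = 1, overlap_allowed = FALSE,
                      seed = 1L) {
  stopifnot(width_px >= 1, height_px >= 1, microns_per_pixel > 0,
            target_density >= 0,
            tissue_mask_fraction >= 0, tissue_mask_fraction <= 1)
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         microns_per_pixel = microns_per_pixel,
         target_density = target_density,
         tissue_mask_fraction = tissue_mask_fraction,
         overlap_allowed = isTRUE(overlap_allowed), seed = as.integer(seed)),
    class = "tile_spec"
  )
}

# Rendering constants: nucleus geometry (px at 0.5 um/px) and H&E-like
# colours chosen so tissue luma (~0.80) sits below the default tissue
# cutoff 0.9 and bare slide (>= 0.945) above it.
.tile_palette <- list(
  background = 0.97, background_noise = 0.006,
  tissue_rgb = c(0.91, 0.77, 0.83), tissue_noise = 0.012,
  nucleus_rgb = c(0.28, 0.22, 0.47), nucleus_jitter = 0.05,
  major_range = c(10, 16), minor_ratio_range = c(0.65, 0.95),
  edge_soft = 0.12, boundary_sep_px = 2, center_margin_px = 9
)

#' Generate one ground-truthed tile
#'
#' Renders an RGB tile with eosin-pale tissue inside the mask, near-white
#' slide outside it, and dark elliptical nuclei (major axis 10-16 px, soft
#' Gaussian-like edges, mild intensity jitter) placed uniformly at random in
#' the tissue at the spec's target density. The realized nucleus count is
#' Poisson(target_density x tissue mm^2); the returned truth table has
#' exactly one row per rendered nucleus.
#'
#' @param spec A [tile_spec()].
#' @return List with `image` (`width x height x 3` array in `[0, 1]`),
#'   `truth` (data.frame: `center_x`, `center_y`, `major_axis`,
#'   `minor_axis`, `angle`), `mask` (logical `width x height` tissue mask)
#'   and `tissue_area_mm2`.
#' @examples
#' tile <- generate_tile(tile_spec(200, 200, target_density = 2000, seed = 3))
#' nrow(tile$truth)
#' @export
generate_tile <- function(spec) {
  stopifnot(inherits(spec, "tile_spec"))
  pal <- .tile_palette
  w <- spec$width_px; h <- spec$height_px
  mpp <- spec$microns_per_pixel
  ncol_tissue <- round(spec$tissue_mask_fraction * w)
  mask <- matrix(FALSE, w, h)
  if (ncol_tissue > 0) mask[seq_len(ncol_tissue), ] <- TRUE
  area_mm2 <- sum(mask) * (mpp / 1000)^2

  with_seed(spec$seed, {
    n_target <- stats::rpois(1, spec$target_density * area_mm2)
    truth <- place_nuclei(n_target, ncol_tissue, h, spec$overlap_allowed,
                          pal, area_mm2)
    img <- render_tile(truth, mask, pal)
    list(image = img, truth = truth, mask = mask, tissue_area_mm2 = area_mm2)
  })
}

# Uniform placement in the tissue columns with optional non-overlap
# rejection (bounding circles of radius major/2 kept >= boundary_sep apart).
place_nuclei <- function(n, ncol_tissue, h, overlap_allowed, pal, area_mm2) {
  empty <- data.frame(center_x = numeric(0), center_y = numeric(0),
                      major_axis = numeric(0), minor_axis = numeric(0),
                      angle = numeric(0))
  if (n == 0) return(empty)
  m <- pal$center_margin_px
  if (ncol_tissue < 2 * m + 1 || h < 2 * m + 1) {
    stop("tissue region too small to place nuclei (needs > ",
         2 * m, " px in both directions)")
  }
  xs <- ys <- maj <- mnr <- ang <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 200L * n + 1000L
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    x <- stats::runif(1, m, ncol_tissue - m)
    y <- stats::runif(1, m, h - m)
    a <- stats::runif(1, pal$major_range[1], pal$major_range[2])
    if (!overlap_allowed && placed > 0) {
      lim <- (a + maj[seq_len(placed)]) / 2 + pal$boundary_sep_px
      d2 <- (xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2
      if (any(d2 < lim^2)) next
    }
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y; maj[placed] <- a
    mnr[placed] <- a * stats::runif(1, pal$minor_ratio_range[1],
                                    pal$minor_ratio_range[2])
    ang[placed] <- stats::runif(1, 0, pi)
  }
  if (placed < n) {
    stop(sprintf(paste0(
      "could not place %d non-overlapping nuclei after %d attempts; ",
      "achievable maximum here is about %.0f cells/mm^2"),
      n, max_attempts, placed / area_mm2))
  }
  data.frame(center_x = xs, center_y = ys, major_axis = maj,
             minor_axis = mnr, angle = ang)
}

render_tile <- function(truth, mask, pal) {
  w <- nrow(mask); h <- ncol(mask)
  npix <- w * h
  base <- ifelse(mask, 0, pal$background +
                   stats::rnorm(npix, 0, pal$background_noise))
  tn <- stats::rnorm(npix, 0, pal$tissue_noise)
  planes <- lapply(1:3, function(ch) {
    plane <- base
    plane[mask] <- pal$tissue_rgb[ch] + tn[mask]
    plane
  })
  n <- nrow(truth)
  if (n) {
    shade <- stats::runif(n, -pal$nucleus_jitter, pal$nucleus_jitter)
    soft <- pal$edge_soft
    # alpha-blend soft-edged ellipses (alpha = 0.5 on the boundary, 1
    # inside, 0 beyond the soft edge), touching only the bounding box of
    # each nucleus so rendering stays linear in nucleus count
    for (i in seq_len(n)) {
      cx <- truth$center_x[i]; cy <- truth$center_y[i]
      a <- truth$major_axis[i] / 2; b <- truth$minor_axis[i] / 2
      theta <- truth$angle[i]
      r <- ceiling(a + 2)
      xs <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
      ys <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
      dx <- outer(xs - cx, rep(1, length(ys)))
      dy <- outer(rep(1, length(xs)), ys - cy)
      u <- (dx * cos(theta) + dy * sin(theta)) / a
      v <- (-dx * sin(theta) + dy * cos(theta)) / b
      alpha <- clamp((1 + soft / 2 - sqrt(u^2 + v^2)) / soft, 0, 1)
      rgb <- pal$nucleus_rgb + shade[i]
      for (ch in 1:3) {
        planes[[ch]][xs, ys] <- planes[[ch]][xs, ys] * (1 - alpha) +
          rgb[ch] * alpha
      }
    }
  }
  img <- array(0, c(w, h, 3))
  for (ch in 1:3) img[, , ch] <- planes[[ch]]
  clamp(img, 0, 1)
}

#' Generate a grid of tiles as one slide
#'
#' Builds a rows x cols slide from per-tile specs, aggregating the ground
#' truth. All tiles must share one resolution. The aggregate truth count is
#' exactly the sum of per-tile truth counts and the total tissue area the
#' sum of per-tile mask areas; `truth` carries slide-global coordinates.
#'
#' @param specs A list of [tile_spec()] (row-major order), or a single spec
#'   recycled to the grid with derived per-tile seeds.
#' @param rows,cols Grid dimensions.
#' @param compose Also stitch the tiles into one `image` (default `TRUE`).
#' @return List with `tiles` (per-tile [generate_tile()] results), `truth`
#'   (aggregated, with `tile_row`, `tile_col` and global `center_x`,
#'   `center_y`), `total_count`, `total_tissue_area_mm2`,
#'   `microns_per_pixel`, and (if `compose`) the stitched `image` and
#'   `mask`.
#' @export
generate_slide <- function(specs, rows, cols, compose = TRUE) {
  if (inherits(specs, "tile_spec")) {
    base <- specs
    specs <- lapply(seq_len(rows * cols), function(i) {
      s <- base
      s$seed <- derive_seed(base$seed, "slide-tile", i)
      s
    })
  }
  stopifnot(length(specs) == rows * cols,
            all(vapply(specs, inherits, logical(1), "tile_spec")))
  mpp <- unique(vapply(specs, `[[`, numeric(1), "microns_per_pixel"))
  if (length(mpp) != 1) {
    stop("inconsistent microns_per_pixel across tiles: ",
         paste(mpp, collapse = ", "))
  }
  ws <- vapply(specs, `[[`, integer(1), "width_px")
  hs <- vapply(specs, `[[`, integer(1), "height_px")
  if (compose && (length(unique(ws)) != 1 || length(unique(hs)) != 1)) {
    stop("composing a slide image requires equally sized tiles")
  }

  tiles <- lapply(specs, generate_tile)
  truth <- do.call(rbind, lapply(seq_along(tiles), function(i) {
    tr <- tiles[[i]]$truth
    if (!nrow(tr)) return(NULL)
    r <- (i - 1) %/% cols; cc <- (i - 1) %% cols
    tr$tile_row <- r + 1L
    tr$tile_col <- cc + 1L
    tr$center_x <- tr$center_x + cc * ws[i]
    tr$center_y <- tr$center_y + r * hs[i]
    tr
  }))
  out <- list(
    tiles = tiles,
    truth = truth,
    total_count = sum(vapply(tiles, function(t) nrow(t$truth), integer(1))),
    total_tissue_area_mm2 = sum(vapply(tiles, `[[`, numeric(1),
                                       "tissue_area_mm2")),
    microns_per_pixel = mpp
  )
  if (compose) {
    W <- cols * ws[1]; H <- rows * hs[1]
    img <- array(0, c(W, H, 3))
    msk <- matrix(FALSE, W, H)
    for (i in seq_along(tiles)) {
      r <- (i - 1) %/% cols; cc <- (i - 1) %% cols
      xi <- cc * ws[1] + seq_len(ws[1])
      yi <- r * hs[1] + seq_len(hs[1])
      img[xi, yi, ] <- tiles[[i]]$image
      msk[xi, yi] <- tiles[[i]]$mask
    }
    out$image <- img
    out$mask <- msk
  }
  out
}

#' Write a generated tile (or slide) to disk
#'
#' Writes the RGB image and single-channel tissue mask as PNG and the truth
#' table as CSV (`tile_id`, `center_x`, `center_y`, `major`, `minor`,
#' `angle`).
#'
#' @param tile Result of [generate_tile()].
#' @param dir Output directory (created if needed).
#' @param id Tile identifier used in file names.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_tile <- function(tile, dir, id = "tile") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(id, ".png"))
  mask_path <- file.path(dir, paste0(id, "_mask.png"))
  truth_path <- file.path(dir, paste0(id, "_truth.csv"))
  save_image(tile$image, img_path)
  save_image(tile$mask * 1, mask_path)
  tr <- tile$truth
  utils::write.csv(
    data.frame(tile_id = id, center_x = tr$center_x, center_y = tr$center_y,
               major = tr$major_axis, minor = tr$minor_axis,
               angle = tr$angle),
    truth_path, row.names = FALSE)
  invisible(c(image = img_path, mask = mask_path, truth = truth_path))
}
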