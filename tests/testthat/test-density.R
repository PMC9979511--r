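# Density quantifier: tiling, tissue detection, segmentation against
# ground truth, shape filtering, aggregation rules.

cfg_small <- function(...) density_config(tile_px = 500L, ...)

test_that("tiling partitions the image exactly, edge tiles kept true-sized", {
  img <- array(runif(2000 * 2000 * 3), c(2000, 2000, 3))
  tiles <- tile_image(img, density_config(tile_px = 1000))
  expect_length(tiles, 4)
  expect_true(all(vapply(tiles, `[[`, integer(1), "width") == 1000))

  img2 <- array(runif(1500 * 1000 * 3), c(1500, 1000, 3))
  tiles2 <- tile_image(img2, density_config(tile_px = 1000))
  expect_length(tiles2, 2)
  expect_equal(vapply(tiles2, `[[`, integer(1), "width"), c(1000L, 500L))

  # reassembling the tiles reproduces the image pixel for pixel
  rebuilt <- array(NA_real_, dim(img2))
  for (t in tile_image(img2, density_config(tile_px = 700))) {
    rebuilt[t$x0 + seq_len(t$width), t$y0 + seq_len(t$height), ] <- t$pixels
  }
  expect_identical(rebuilt, img2)
})

test_that("tissue fraction reads the grayscale cutoff as specified", {
  cfg <- density_config()
  white <- array(1, c(50, 50, 3))
  expect_equal(tissue_fraction(white, cfg), 0)
  dark <- array(0.3, c(50, 50, 3))
  expect_equal(tissue_fraction(dark, cfg), 1)
  tile <- generate_tile(tile_spec(300, 300, target_density = 1500,
                                  tissue_mask_fraction = 0.5, seed = 3))
  expect_equal(tissue_fraction(tile$image, cfg), 0.5, tolerance = 0.02)
})

test_that("segmentation finds well-separated nuclei one-to-one", {
  tile <- generate_tile(tile_spec(500, 500, target_density = 800, seed = 17))
  cfg <- cfg_small()
  det <- shape_filter(segment_nuclei(tile$image, cfg), cfg)
  expect_equal(nrow(det), nrow(tile$truth))
  # centroid matching: every detection within 3 px of a distinct truth
  used <- logical(nrow(tile$truth))
  for (i in seq_len(nrow(det))) {
    d2 <- (tile$truth$center_x - det$centroid_x[i])^2 +
      (tile$truth$center_y - det$centroid_y[i])^2
    j <- which.min(replace(d2, used, Inf))
    expect_lt(sqrt(d2[j]), 3)
    used[j] <- TRUE
  }
  expect_true(all(used))
})

test_that("blank tiles give empty detections, not errors", {
  white <- array(0.97, c(200, 200, 3))
  expect_equal(nrow(segment_nuclei(white, density_config())), 0)
})

test_that("oversized clumps are watershed-split into their nuclei", {
  # two touching nuclei, centers 10 px apart, rendered directly
  truth <- data.frame(center_x = c(95, 105), center_y = c(100, 100),
                      major_axis = c(12, 12), minor_axis = c(9, 9),
                      angle = c(0, 0))   # major axes along x: the pair fuses
  mask <- matrix(TRUE, 200, 200)
  img <- synovkit:::with_seed(1, synovkit:::render_tile(
    truth, mask, synovkit:::.tile_palette))
  # area band set so the merged clump exceeds the maximum and must split
  cfg <- density_config(tile_px = 200, nucleus_area_max_um2 = 40)
  det <- segment_nuclei(img, cfg)
  expect_equal(nrow(det), 2)
  expect_equal(sort(det$centroid_x), c(95, 105), tolerance = 3)
  # without the splitting trigger the clump stays one component
  cfg_wide <- density_config(tile_px = 200, nucleus_area_max_um2 = 500)
  expect_equal(nrow(segment_nuclei(img, cfg_wide)), 1)
})

test_that("shape filter enforces the area band and circularity floor", {
  cfg <- density_config(nucleus_area_min_um2 = 8, nucleus_area_max_um2 = 120,
                        min_circularity = 0.25)
  det <- data.frame(
    centroid_x = 1:10, centroid_y = 1:10,
    area_um2 = c(1, 5, 9, 20, 40, 60, 80, 100, 119, 300),
    circularity = c(0.9, 0.9, 0.9, 0.1, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9)
  )
  kept <- shape_filter(det, cfg)
  # 1 and 5 um^2 below floor, 300 above ceiling, one fails circularity
  expect_equal(kept$centroid_x, c(3, 5, 6, 7, 8, 9))
  expect_equal(nrow(shape_filter(det[0, ], cfg)), 0)
  # narrowing the band never increases the count
  tighter <- shape_filter(det, density_config(nucleus_area_min_um2 = 15,
                                              nucleus_area_max_um2 = 90,
                                              min_circularity = 0.5))
  expect_lte(nrow(tighter), nrow(kept))
})

test_that("density excludes sparse tiles from count and area alike", {
  t1 <- generate_tile(tile_spec(400, 400, target_density = 3000, seed = 21))
  blank <- array(0.97, c(400, 400, 3))
  cfg <- density_config(tile_px = 400)
  with_tissue <- compute_density(t1$image, cfg)
  with_blanks <- compute_density(list(t1$image, blank, blank), cfg)
  expect_equal(with_blanks$density, with_tissue$density)
  expect_equal(sum(with_blanks$tiles$included), 1)

  all_blank <- compute_density(blank, cfg)
  expect_true(is.na(all_blank$density))
  expect_equal(all_blank$total_tissue_area_mm2, 0)
})

test_that("zero-density tissue reports zero cells per mm^2", {
  tile <- generate_tile(tile_spec(300, 300, target_density = 0, seed = 2))
  res <- compute_density(tile$image, density_config(tile_px = 300))
  expect_equal(res$total_nuclei, 0)
  expect_equal(res$density, 0)
})

test_that("whole-image and tile-wise densities agree within 1 percent", {
  slide <- generate_slide(tile_spec(500, 500, target_density = 3400,
                                    seed = 23), rows = 2, cols = 2)
  whole <- compute_density(slide$image, density_config(tile_px = 1000))
  tiled <- compute_density(slide$image, density_config(tile_px = 500))
  expect_lt(abs(whole$density - tiled$density) / tiled$density, 0.01)
  truth_density <- slide$total_count / slide$total_tissue_area_mm2
  expect_lt(abs(tiled$density - truth_density) / truth_density, 0.05)
})

test_that("the JSON report echoes counts, density and config", {
  tile <- generate_tile(tile_spec(250, 250, target_density = 2000, seed = 9))
  res <- compute_density(tile$image, density_config(tile_px = 250))
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_density_report(res, jp, cp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$total_nuclei, res$total_nuclei)
  expect_equal(back$density, res$density, tolerance = 1e-12)
  expect_equal(back$config$tile_px, 250)
  expect_equal(nrow(utils::read.csv(cp)), nrow(res$tiles))
})
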