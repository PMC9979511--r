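# Tile generator: ground-truth bookkeeping, determinism, overlap control,
# slide aggregation.

test_that("zero target density yields a background-only tile", {
  tile <- generate_tile(tile_spec(200, 150, target_density = 0, seed = 1))
  expect_equal(nrow(tile$truth), 0)
  gray <- synovkit:::to_gray(tile$image)
  # all tissue, no nuclei: everything is pale eosin
  expect_true(all(gray > 0.7))
  expect_equal(tile$tissue_area_mm2, 200 * 150 * (0.5 / 1000)^2)
})

test_that("realized counts follow the target density and truth is exact", {
  spec <- tile_spec(1000, 1000, microns_per_pixel = 0.5,
                    target_density = 3400, seed = 12)
  tile <- generate_tile(spec)
  n <- nrow(tile$truth)
  # 0.25 mm^2 at full tissue: expect 850 +/- Poisson error (~6 sd window)
  expect_gt(n, 850 - 6 * sqrt(850))
  expect_lt(n, 850 + 6 * sqrt(850))
  expect_true(all(tile$truth$major_axis > 0 & tile$truth$minor_axis > 0))
  expect_true(all(tile$truth$center_x >= 1 & tile$truth$center_x <= 1000))
  expect_true(all(tile$truth$center_y >= 1 & tile$truth$center_y <= 1000))
})

test_that("tiles are byte-identical under a fixed seed", {
  s <- tile_spec(300, 300, target_density = 2000, seed = 99)
  a <- generate_tile(s)
  b <- generate_tile(s)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  s2 <- s; s2$seed <- 100L
  expect_false(identical(generate_tile(s2)$image, a$image))
})

test_that("non-overlapping placement respects the 2 px boundary gap", {
  tile <- generate_tile(tile_spec(500, 500, target_density = 5000,
                                  overlap_allowed = FALSE, seed = 4))
  tr <- tile$truth
  d <- as.matrix(dist(cbind(tr$center_x, tr$center_y)))
  lim <- outer(tr$major_axis, tr$major_axis, `+`) / 2 + 2
  diag(d) <- Inf
  expect_true(all(d >= lim - 1e-9))
})

test_that("impossible non-overlap densities fail with the achievable max", {
  expect_error(
    generate_tile(tile_spec(120, 120, target_density = 60000, seed = 2)),
    "achievable maximum")
})

test_that("the tissue mask fraction controls tissue area", {
  tile <- generate_tile(tile_spec(400, 400, target_density = 1000,
                                  tissue_mask_fraction = 0.5, seed = 6))
  expect_equal(mean(tile$mask), 0.5)
  expect_equal(tile$tissue_area_mm2, 0.5 * 400 * 400 * (0.5 / 1000)^2)
  # nuclei live in the tissue half only
  expect_true(all(tile$truth$center_x <= 200 + 1))
  # background half is near-white
  gray <- synovkit:::to_gray(tile$image)
  expect_true(all(gray[250:400, ] >= 0.94))
})

test_that("slides aggregate truth additively and share one resolution", {
  base <- tile_spec(250, 250, target_density = 2000)
  specs <- lapply(1:4, function(i) {
    s <- base
    s$seed <- 100L + i
    s$target_density <- c(0, 0, 2000, 2000)[i]
    s
  })
  slide <- generate_slide(specs, rows = 2, cols = 2)
  per_tile <- vapply(slide$tiles, function(t) nrow(t$truth), integer(1))
  expect_equal(per_tile[1:2], c(0L, 0L))
  expect_equal(slide$total_count, sum(per_tile))
  expect_equal(nrow(slide$truth), slide$total_count)
  expect_equal(slide$total_tissue_area_mm2,
               sum(vapply(slide$tiles, `[[`, numeric(1), "tissue_area_mm2")))
  # global truth coordinates fall inside the right quadrants
  q3 <- slide$truth[slide$truth$tile_row == 2 & slide$truth$tile_col == 1, ]
  expect_true(all(q3$center_y > 250 & q3$center_x <= 250))

  # uniform grid recovers its density from the aggregated truth
  uni <- generate_slide(tile_spec(250, 250, target_density = 3000, seed = 8),
                        rows = 3, cols = 3)
  lambda <- 3000 * uni$total_tissue_area_mm2
  expect_lt(abs(uni$total_count - lambda), 5 * sqrt(lambda))  # Poisson window

  # single-tile grid is generate_tile
  one <- generate_slide(list(tile_spec(200, 200, seed = 77)), 1, 1)
  expect_identical(one$tiles[[1]]$image,
                   generate_tile(tile_spec(200, 200, seed = 77))$image)

  bad <- list(tile_spec(100, 100, microns_per_pixel = 0.5),
              tile_spec(100, 100, microns_per_pixel = 0.25))
  expect_error(generate_slide(bad, 1, 2), "inconsistent microns_per_pixel")
})

test_that("tiles round-trip through PNG with truth CSV intact", {
  dir <- withr::local_tempdir()
  tile <- generate_tile(tile_spec(150, 150, target_density = 2000, seed = 13))
  paths <- write_tile(tile, dir, "t1")
  expect_true(all(file.exists(paths)))
  img <- synovkit:::load_image(paths[["image"]])
  expect_equal(dim(img)[1:2], c(150, 150))
  expect_equal(img[, , 1], tile$image[, , 1], tolerance = 1 / 255)
  tr <- utils::read.csv(paths[["truth"]])
  expect_equal(nrow(tr), nrow(tile$truth))
})
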