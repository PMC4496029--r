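# A tiny 11-band grid (600-1100 nm @ 50 nm) for hand-built cubes: band 2 is
# the 650 nm red reference, band 6 (850 nm) the closest to the 860 nm NIR
# reference, bands 6-10 span the 850-1050 nm NIR window.
tiny_grid <- function() build_band_grid(c(600, 1100), 50, exclusions = list(),
                                        keep_nm = c(600, 1100))

tiny_cube <- function(spectra) {
  # spectra: list of per-pixel band vectors, laid out as a 1 x n cube
  n <- length(spectra)
  vals <- array(NA_real_, c(1, n, 11))
  for (i in seq_len(n)) vals[1, i, ] <- spectra[[i]]
  reflectance_cube(vals, tiny_grid())
}

spec_with <- function(red, nir) {
  s <- rep(nir, 11); s[1:5] <- red; s
}

test_that("NDVI follows (NIR - red)/(NIR + red) with a zero-denominator guard", {
  cube <- tiny_cube(list(spec_with(0.05, 0.45),   # -> 0.80
                         spec_with(0.30, 0.30),   # -> 0.00 (red = NIR)
                         spec_with(0.00, 0.00)))  # -> 0 by convention
  ndvi <- compute_ndvi(cube)
  expect_equal(ndvi[1, 1], 0.8)
  expect_equal(ndvi[1, 2], 0)
  expect_equal(ndvi[1, 3], 0)
})

test_that("vegetation mask is an inclusive conjunction of NDVI and mean-NIR tests", {
  cube <- tiny_cube(list(spec_with(0.05, 0.45), spec_with(0.03, 0.17),
                         spec_with(0.10, 0.50)))
  ndvi <- compute_ndvi(cube)
  d <- dim(cube$values)
  nirm <- rowMeans(matrix(cube$values[, , 6:10], d[1] * d[2]))
  # thresholds set to the exact computed values -> boundary pixels included
  cfg_eq <- mask_config(ndvi_min = ndvi[1, 2], nir_mean_min = nirm[2])
  expect_true(vegetation_mask(cube, cfg_eq)[1, 2])
  # one criterion failing excludes the pixel, however strong the other is
  cfg_hi <- mask_config(ndvi_min = ndvi[1, 3] + 1e-6, nir_mean_min = 0)
  expect_false(vegetation_mask(cube, cfg_hi)[1, 3])
  expect_true(vegetation_mask(cube)[1, 1])   # 0.80 NDVI, 0.45 NIR
  expect_false(vegetation_mask(cube)[1, 2])  # NIR mean below 0.21
})

test_that("masking is idempotent: pixels that passed still pass when isolated", {
  sc <- fx_scene()
  mask <- fx_mask()
  keep <- which(mask)
  sub <- crowndetect:::cube_matrix(sc$cube)[keep, , drop = FALSE]
  cube2 <- reflectance_cube(array(sub, c(nrow(sub), 1, ncol(sub))),
                            sc$cube$grid)
  expect_true(all(vegetation_mask(cube2)))
})

test_that("crown-pixel extraction respects mask, truth bookkeeping and dimensions", {
  sc <- fx_scene()
  mask <- fx_mask()
  ds <- extract_crown_pixels(sc$cube, sc$map, mask)
  expect_lte(n_pixels(ds), sum(sc$map$crown_table$n_pixels))
  # all-true mask recovers the full crown bookkeeping
  all_true <- matrix(TRUE, nrow(mask), ncol(mask))
  ds_all <- extract_crown_pixels(sc$cube, sc$map, all_true)
  expect_equal(n_pixels(ds_all), sum(sc$map$crown_table$n_pixels))
  cs <- crown_summary_(ds_all)
  expect_equal(cs$n_pixels[order(cs$crown_id)],
               sc$map$crown_table$n_pixels[order(sc$map$crown_table$crown_id)])
  # dimension mismatch is an error
  expect_error(extract_crown_pixels(sc$cube, sc$map, mask[1:10, 1:10]),
               "dimensions differ")
})

test_that("an empty crown map yields an empty dataset, not an error", {
  sc <- fx_scene()
  empty <- crown_map(matrix(0L, nrow(sc$map$crown_id_raster),
                            ncol(sc$map$crown_id_raster)),
                     data.frame(crown_id = integer(0), species_id = integer(0),
                                n_pixels = integer(0)))
  ds <- extract_crown_pixels(sc$cube, empty, fx_mask())
  expect_equal(n_pixels(ds), 0L)
})
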