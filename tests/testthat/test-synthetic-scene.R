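test_that("library size, vegetation shape and determinism follow the config", {
  lib <- fx_library()
  cfg <- fx_config()
  expect_length(lib$species_id,
                cfg$n_focal_species + cfg$n_background_species)
  expect_equal(sum(lib$is_focal), cfg$n_focal_species)
  expect_true(all(lib$means >= 0 & lib$means <= 1))
  expect_true(all(lib$between_sd >= 0) && all(lib$within_sd >= 0))
  # every mean passes the NDVI part of the vegetation filter
  ndvi <- crowndetect:::spectrum_ndvi(lib$means, lib$grid)
  expect_true(all(ndvi >= 0.7))
  # spectra are smooth: adjacent-band steps bounded
  expect_lt(max(abs(t(apply(lib$means, 1, diff)))), 0.35)
  # same seed twice -> identical library
  lib2 <- make_spectral_library(cfg, fx_grid())
  expect_identical(lib$means, lib2$means)
})

test_that("focal means respect the configured separability floor", {
  lib <- fx_library()
  cfg <- fx_config()
  sdt <- sqrt(cfg$between_crown_sd^2 + cfg$within_crown_sd^2)
  for (i in which(lib$is_focal))
    for (j in which(!lib$is_focal))
      expect_gte(crowndetect:::spectral_separation(
        lib$means[i, ], lib$means[j, ],
        sdt * lib$means[i, ], sdt * lib$means[j, ]), cfg$separability)
})

test_that("an infeasible separability request fails explicitly", {
  cfg <- scene_config(height = 60, width = 60, crowns_per_focal = 2,
                      n_background_species = 5, crowns_per_background = 2,
                      separability = 500)
  expect_error(make_spectral_library(cfg, fx_grid()), "separability")
})

test_that("scene bookkeeping matches the config and truth raster", {
  sc <- fx_scene()
  cfg <- fx_config()
  tab <- sc$map$crown_table
  expect_equal(nrow(tab),
               cfg$n_focal_species * cfg$crowns_per_focal +
                 cfg$n_background_species * cfg$crowns_per_background)
  # raster counts equal the table, crowns disjoint by construction
  for (i in sample(nrow(tab), 10))
    expect_equal(sum(sc$map$crown_id_raster == tab$crown_id[i]),
                 tab$n_pixels[i])
  expect_equal(dim(sc$cube$values)[1:2], c(cfg$height, cfg$width))
})

test_that("with zero contamination every crown pixel passes the vegetation filter", {
  cfg <- scene_config(height = 70, width = 70, n_focal_species = 2,
                      crowns_per_focal = 4, n_background_species = 8,
                      crowns_per_background = 2, shadow_fraction = 0,
                      liana_fraction = 0, seed = 3)
  lib <- make_spectral_library(cfg, fx_grid())
  sc <- generate_scene(cfg, lib)
  mask <- vegetation_mask(sc$cube)
  expect_true(all(mask[sc$map$crown_id_raster > 0]))
})

test_that("contaminant pixels fail the vegetation filter", {
  sc <- fx_scene()
  mask <- vegetation_mask(sc$cube)
  expect_true(all(!mask[sc$contaminated]))
})

test_that("a scene with no focal crowns contains only background truth", {
  cfg <- scene_config(height = 60, width = 60, crowns_per_focal = 0,
                      n_background_species = 6, crowns_per_background = 2,
                      seed = 5)
  lib <- make_spectral_library(cfg, fx_grid())
  sc <- generate_scene(cfg, lib)
  expect_true(all(sc$map$crown_table$species_id > cfg$n_focal_species))
})

test_that("the reference inventory is mirrored exactly by the dataset generator", {
  ds <- generate_crown_dataset(scene_config(seed = 2),
                               fixture("inv_lib", make_spectral_library(
                                 scene_config(seed = 2), fx_grid())),
                               inventory = reference_inventory())
  cs <- crown_summary_(ds)
  expect_equal(nrow(cs), 460L)
  expect_equal(sum(cs$n_pixels), 25492L)
  counts <- table(factor(cs$species_id %in% 1:3, levels = c(TRUE, FALSE)))
  expect_equal(unname(counts[["FALSE"]]), 322L)
  per_focal <- table(cs$species_id[cs$species_id %in% 1:3])
  expect_equal(unname(c(per_focal)), c(50L, 44L, 44L))
  per_pix <- tapply(cs$n_pixels, cs$species_id %in% 1:3, sum)
  expect_equal(unname(per_pix[["TRUE"]]), 10726L + 3325L + 2091L)
})

test_that("no crown id maps to two species and dataset files are byte-identical under a seed", {
  ds <- fx_dataset()
  cs <- crown_summary_(ds)   # errors internally if a crown had two species
  expect_equal(anyDuplicated(cs$crown_id), 0L)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_pixel_dataset(ds, f1)
  write_pixel_dataset(generate_crown_dataset(fx_config(), fx_library()), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))
})

test_that("nearest-mean separability increases with the separability dial", {
  g <- fx_grid()
  acc <- vapply(c(0.8, 1.5, 2.5), function(sep) {
    mean(vapply(1:2, function(s) nearest_mean_separability(
      make_spectral_library(scene_config(separability = sep, seed = s), g),
      n_per_species = 30, seed = s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
})
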